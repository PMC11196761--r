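#' Read a GFF3 file into an annotation set
#'
#' Parses the nine-column GFF3 format (1-based inclusive coordinates),
#' percent-decodes attribute values, resolves `Parent` relationships, and
#' groups every feature under its owning gene. Features whose parent chain
#' does not reach a `gene` feature (of any hierarchy depth, including
#' CDS-only sets where CDS rows attach directly to the gene) are wrapped
#' under a synthetic gene spanning them, flagged with `synthetic=true`.
#' `##` directives and `#` comments are preserved for round-trip; an
#' embedded `##FASTA` section is skipped.
#'
#' @param path Path to a GFF3 file.
#' @param label Source label for the resulting set (defaults to file name).
#' @return An [annotation_set()].
#' @export
parse_gff3 <- function(path, label = basename(path)) {
  lines <- readr::read_lines(path)
  fasta <- which(lines == "##FASTA")
  if (length(fasta) > 0) lines <- lines[seq_len(fasta[1] - 1L)]
  is_meta <- startsWith(lines, "#")
  is_blank <- !nzchar(trimws(lines))
  pragmas <- lines[is_meta & !is_blank]
  body_idx <- which(!is_meta & !is_blank)
  if (length(body_idx) == 0) {
    return(new_annotation_set(empty_features(), label, pragmas))
  }
  parts <- strsplit(lines[body_idx], "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 9L)) {
    bad <- body_idx[which(nf != 9L)[1]]
    rlang::abort(sprintf("line %d: expected 9 tab-separated columns, got %d",
                         bad, nf[which(nf != 9L)[1]]))
  }
  m <- matrix(unlist(parts), ncol = 9L, byrow = TRUE)
  start <- suppressWarnings(as.integer(m[, 4]))
  end <- suppressWarnings(as.integer(m[, 5]))
  bad <- which(is.na(start) | is.na(end) | m[, 4] != as.character(start) |
                 m[, 5] != as.character(end))
  if (length(bad) > 0) {
    rlang::abort(sprintf("line %d: non-integer coordinate '%s'..'%s'",
                         body_idx[bad[1]], m[bad[1], 4], m[bad[1], 5]))
  }
  bad <- which(start > end | start < 1L)
  if (length(bad) > 0) {
    rlang::abort(sprintf("line %d: invalid interval %d..%d (need 1 <= start <= end)",
                         body_idx[bad[1]], start[bad[1]], end[bad[1]]))
  }
  attrs <- lapply(m[, 9], parse_gff3_attributes)
  ids <- vapply(attrs, function(a) {
    if ("ID" %in% names(a)) a[["ID"]] else NA_character_
  }, character(1))
  has_id <- !is.na(ids)
  ids[!has_id] <- sprintf(".anon.%d", which(!has_id))
  parents <- lapply(attrs, function(a) {
    if ("Parent" %in% names(a)) strsplit(a[["Parent"]], ",", fixed = TRUE)[[1]]
    else character()
  })
  features <- tibble::tibble(
    seqid = m[, 1], source = m[, 2], type = m[, 3],
    start = start, end = end, score = m[, 6], strand = m[, 7],
    phase = m[, 8], id = ids, parents = parents, attributes = attrs,
    has_id = has_id, line = body_idx)
  features <- add_ftype(features)
  # Duplicate gene IDs are an error naming both lines (finalize reports
  # line numbers carried in `line`).
  finalize_annotation_set(features, label, pragmas, orphans = "wrap")
}

empty_features <- function() {
  tibble::tibble(seqid = character(), source = character(), type = character(),
                 start = integer(), end = integer(), score = character(),
                 strand = character(), phase = character(), id = character(),
                 parents = list(), attributes = list(), has_id = logical(),
                 line = integer(), ftype = character(), gene_id = character())
}

parse_gff3_attributes <- function(s) {
  if (s == "." || !nzchar(s)) return(stats::setNames(character(), character()))
  kv <- strsplit(s, ";", fixed = TRUE)[[1]]
  kv <- kv[nzchar(trimws(kv))]
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=?", "", kv)
  stats::setNames(gff3_decode(vals), gff3_decode(trimws(keys)))
}

# GFF3 percent-encoding of the reserved characters ; = & , % (plus tab and
# newline) in attribute values; commas inside Parent stay as separators.
gff3_encode <- function(x) {
  x <- gsub("%", "%25", x, fixed = TRUE)
  x <- gsub(";", "%3B", x, fixed = TRUE)
  x <- gsub("=", "%3D", x, fixed = TRUE)
  x <- gsub("&", "%26", x, fixed = TRUE)
  x <- gsub(",", "%2C", x, fixed = TRUE)
  x <- gsub("\t", "%09", x, fixed = TRUE)
  gsub("\n", "%0A", x, fixed = TRUE)
}

gff3_decode <- function(x) {
  vapply(x, function(s) utils::URLdecode(s), character(1), USE.NAMES = FALSE)
}

serialize_attributes <- function(attrs, parents, id, has_id) {
  out <- character()
  if (has_id) out <- c(out, paste0("ID=", gff3_encode(id)))
  if (length(parents) > 0) {
    out <- c(out, paste0("Parent=",
                         paste(gff3_encode(parents), collapse = ",")))
  }
  rest <- attrs[!names(attrs) %in% c("ID", "Parent")]
  if (length(rest) > 0) {
    out <- c(out, paste0(gff3_encode(names(rest)), "=", gff3_encode(rest)))
  }
  if (length(out) == 0) "." else paste(out, collapse = ";")
}

#' Write an annotation set as sorted GFF3
#'
#' Emits a topologically and positionally sorted GFF3 file (see
#' [sort_topological()]): genes ordered by natural seqid then position, every
#' child line after its parent line. Attributes are serialized `ID` first,
#' then `Parent`, then the remaining attributes in stored order, with GFF3
#' percent-encoding.
#'
#' @param aset An [annotation_set()].
#' @param path Output file path.
#' @param natural_seqids Use natural-alphanumeric seqid order ("chr2" before
#'   "chr10"); set `FALSE` for purely lexicographic order.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(aset, path, natural_seqids = TRUE) {
  stopifnot(inherits(aset, "annotation_set"))
  f <- sort_topological(aset, natural_seqids = natural_seqids)
  pragmas <- aset$pragmas
  if (!any(grepl("^##gff-version", pragmas))) {
    pragmas <- c("##gff-version 3", pragmas)
  }
  if (nrow(f) == 0) {
    readr::write_lines(pragmas, path)
    return(invisible(path))
  }
  attr_col <- vapply(seq_len(nrow(f)), function(i) {
    serialize_attributes(f$attributes[[i]], f$parents[[i]], f$id[i],
                         f$has_id[i])
  }, character(1))
  lines <- paste(f$seqid, f$source, f$type, f$start, f$end, f$score,
                 f$strand, f$phase, attr_col, sep = "\t")
  readr::write_lines(c(pragmas, lines), path)
  invisible(path)
}

#' Topologically sort the features of an annotation set
#'
#' Produces a deterministic total order: seqids in natural-alphanumeric
#' order (optionally lexicographic), genes by start, then end, then ID;
#' every feature precedes all of its descendants; siblings by start, then
#' feature-type rank (mRNA < exon < CDS < UTR < other), then ID.
#'
#' @inheritParams write_gff3
#' @return The feature tibble in sorted order.
#' @export
sort_topological <- function(aset, natural_seqids = TRUE) {
  stopifnot(inherits(aset, "annotation_set"))
  f <- aset$features
  if (nrow(f) == 0) return(f)
  rows <- seq_len(nrow(f))
  gene_rows <- rows[f$ftype == "gene"]
  seq_key <- if (natural_seqids) natural_key(f$seqid) else f$seqid
  gene_rows <- gene_rows[order(seq_key[gene_rows], f$start[gene_rows],
                               f$end[gene_rows], f$id[gene_rows])]
  # children adjacency: feature row -> child rows (by first parent id)
  parent1 <- vapply(f$parents, function(p) {
    if (length(p) == 0) NA_character_ else p[[1]]
  }, character(1))
  kid_of <- match(parent1, f$id)
  children <- split(rows, factor(kid_of, levels = rows))
  rank <- ftype_rank(f$ftype)
  out <- integer(0)
  emitted <- logical(nrow(f))
  for (g in gene_rows) {
    stack <- g
    while (length(stack) > 0) {
      cur <- stack[[1]]
      stack <- stack[-1]
      if (emitted[cur]) next
      emitted[cur] <- TRUE
      out <- c(out, cur)
      kids <- children[[as.character(cur)]]
      if (length(kids) > 0) {
        kids <- kids[order(f$start[kids], rank[kids], f$id[kids])]
        stack <- c(kids, stack)
      }
    }
  }
  if (!all(emitted)) {
    left <- f$id[!emitted]
    rlang::abort(sprintf(
      "features not reachable from any gene (orphan or cycle): %s",
      paste(unique(left), collapse = ", ")))
  }
  f[out, ]
}

#' Read a BED file of evidence intervals
#'
#' BED is 0-based half-open; intervals are converted to 1-based inclusive
#' coordinates on read.
#'
#' @param path Path to a BED file (>= 3 columns).
#' @return A tibble with `seqid`, `start`, `end` (1-based inclusive),
#'   `name`, `strand`.
#' @export
read_bed <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track") & !startsWith(lines, "browser")]
  if (length(lines) == 0) {
    return(tibble::tibble(seqid = character(), start = integer(),
                          end = integer(), name = character(),
                          strand = character()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3L)) {
    rlang::abort(sprintf("BED line %d: fewer than 3 columns",
                         which(nf < 3L)[1]))
  }
  s0 <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 2)))
  e0 <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 3)))
  if (anyNA(s0) || anyNA(e0)) {
    rlang::abort(sprintf("BED line %d: non-integer coordinate",
                         which(is.na(s0) | is.na(e0))[1]))
  }
  tibble::tibble(
    seqid = vapply(parts, `[[`, "", 1),
    start = s0 + 1L, end = e0,
    name = vapply(parts, function(p) if (length(p) >= 4) p[[4]] else NA_character_,
                  character(1)),
    strand = vapply(parts, function(p) if (length(p) >= 6) p[[6]] else ".",
                    character(1)))
}

#' Write evidence intervals as BED
#'
#' @param intervals Tibble with `seqid`, `start`, `end` (1-based inclusive)
#'   and optionally `name`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  name <- if ("name" %in% names(intervals)) intervals$name else "."
  readr::write_lines(
    paste(intervals$seqid, intervals$start - 1L, intervals$end,
          name, sep = "\t"),
    path)
  invisible(path)
}
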