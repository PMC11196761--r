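#' Annotation sets
#'
#' An `annotation_set` wraps a tibble of GFF3 features for one annotation
#' source (e.g. one liftover flank variant, or the native target annotation).
#' The feature table carries the nine GFF3 columns plus parsed `id`,
#' `parents` (list of character) and `attributes` (list of named character,
#' in file order), the resolved owning `gene_id` per feature, and the source
#' line number where known.
#'
#' @param features A tibble (or data frame) with at least `seqid`, `type`,
#'   `start`, `end` and `id` columns. Missing GFF3 columns are filled with
#'   defaults (`source` = label, `score`/`phase` = ".", `strand` = ".").
#' @param label Source name stored with the set and used as the default
#'   GFF3 `source` column.
#' @param pragmas Character vector of `##` directive / comment lines to
#'   preserve on write.
#' @param orphans How to treat features whose parent chain does not reach a
#'   `gene` feature: `"wrap"` groups them under a synthetic flagged gene,
#'   `"error"` aborts.
#' @return An object of class `annotation_set`.
#' @export
annotation_set <- function(features, label, pragmas = character(),
                           orphans = c("error", "wrap")) {
  orphans <- match.arg(orphans)
  features <- tibble::as_tibble(features)
  n <- nrow(features)
  if (!all(c("seqid", "type", "start", "end", "id") %in% names(features))) {
    rlang::abort("features must have seqid, type, start, end and id columns")
  }
  if (!"source" %in% names(features)) features$source <- label
  if (!"score" %in% names(features)) features$score <- "."
  if (!"strand" %in% names(features)) features$strand <- "."
  if (!"phase" %in% names(features)) features$phase <- "."
  if (!"parents" %in% names(features)) {
    features$parents <- rep(list(character()), n)
  }
  if (!"attributes" %in% names(features)) {
    features$attributes <- rep(list(character()), n)
  }
  if (!"has_id" %in% names(features)) features$has_id <- rep(TRUE, n)
  if (!"line" %in% names(features)) features$line <- rep(NA_integer_, n)
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  bad <- which(is.na(features$start) | is.na(features$end) |
                 features$start < 1L | features$start > features$end)
  if (length(bad) > 0) {
    rlang::abort(sprintf(
      "invalid coordinates (need 1 <= start <= end) for feature(s): %s",
      paste(features$id[bad], collapse = ", ")))
  }
  features <- add_ftype(features)
  finalize_annotation_set(features, label, pragmas, orphans = orphans)
}

# Feature-type normalization used for sorting and gene detection.
add_ftype <- function(features) {
  known <- c(gene = "gene", mRNA = "mRNA", exon = "exon", CDS = "CDS",
             five_prime_UTR = "UTR", three_prime_UTR = "UTR")
  features$ftype <- dplyr::coalesce(known[features$type], "other")
  features
}

ftype_rank <- function(ftype) {
  c(gene = 0L, mRNA = 1L, exon = 2L, CDS = 3L, UTR = 4L, other = 5L)[ftype]
}

new_annotation_set <- function(features, label, pragmas = character()) {
  structure(list(label = label, features = features, pragmas = pragmas),
            class = "annotation_set")
}

# Resolve feature -> owning gene, wrap or reject orphans, enforce unique
# gene IDs. Row order is preserved.
finalize_annotation_set <- function(features, label, pragmas = character(),
                                    orphans = "error") {
  gene_rows <- which(features$ftype == "gene")
  gids <- features$id[gene_rows]
  dup <- duplicated(gids)
  if (any(dup)) {
    first <- gene_rows[match(gids[dup][1], gids)]
    second <- gene_rows[dup][1]
    rlang::abort(sprintf(
      "duplicate gene ID '%s' (lines %s and %s)",
      gids[dup][1],
      ifelse(is.na(features$line[first]), first, features$line[first]),
      ifelse(is.na(features$line[second]), second, features$line[second])))
  }
  features$gene_id <- resolve_gene_ids(features)

  orphan_rows <- which(is.na(features$gene_id))
  if (length(orphan_rows) > 0 && orphans == "error") {
    rlang::abort(sprintf(
      "feature(s) without a resolvable gene ancestor: %s",
      paste(unique(features$id[orphan_rows]), collapse = ", ")))
  }
  if (length(orphan_rows) > 0) {
    features <- wrap_orphans(features, orphan_rows, label)
  }
  new_annotation_set(features, label, pragmas)
}

# Walk parent chains to the root; the owning gene is the root when the root
# is a gene feature, NA otherwise. Cycles are reported.
resolve_gene_ids <- function(features) {
  is_gene <- features$ftype == "gene"
  # Parent lookup by first matching id (multi-row features such as segmented
  # CDS share one id and one parent set).
  first_parent <- vapply(features$parents, function(p) {
    if (length(p) == 0) NA_character_ else p[[1]]
  }, character(1))
  parent_row <- match(first_parent, features$id)
  gene_id <- rep(NA_character_, nrow(features))
  gene_id[is_gene] <- features$id[is_gene]
  for (i in which(!is_gene)) {
    seen <- integer()
    cur <- i
    repeat {
      j <- parent_row[cur]
      if (is.na(j)) break   # no parent or unresolvable -> orphan root
      if (j %in% seen) {
        rlang::abort(sprintf(
          "cycle in parent graph: %s",
          paste(features$id[c(seen, j)], collapse = " -> ")))
      }
      seen <- c(seen, j)
      if (is_gene[j]) {
        gene_id[i] <- features$id[j]
        break
      }
      cur <- j
    }
  }
  gene_id
}

# Group parentless non-gene hierarchies under synthetic flagged genes.
wrap_orphans <- function(features, orphan_rows, label) {
  roots <- orphan_rows[vapply(features$parents[orphan_rows], function(p) {
    length(p) == 0 || !any(p %in% features$id)
  }, logical(1))]
  extra <- list()
  for (r in roots) {
    desc <- orphan_rows[descends_from(features, orphan_rows, features$id[r])]
    desc <- union(r, desc)
    gid <- paste0("synthetic-gene:", features$id[r])
    extra[[length(extra) + 1]] <- tibble::tibble(
      seqid = features$seqid[r], source = features$source[r], type = "gene",
      start = min(features$start[desc]), end = max(features$end[desc]),
      score = ".", strand = features$strand[r], phase = ".",
      id = gid, parents = list(character()),
      attributes = list(c(ID = gid, synthetic = "true")),
      has_id = TRUE, line = NA_integer_, ftype = "gene", gene_id = gid)
    features$parents[[r]] <- gid
    features$gene_id[desc] <- gid
  }
  dplyr::bind_rows(features, dplyr::bind_rows(extra))
}

descends_from <- function(features, rows, ancestor_id) {
  vapply(rows, function(i) {
    cur <- features$parents[[i]]
    depth <- 0
    while (length(cur) > 0 && depth < 100) {
      if (ancestor_id %in% cur) return(TRUE)
      j <- match(cur[1], features$id)
      if (is.na(j)) return(FALSE)
      cur <- features$parents[[j]]
      depth <- depth + 1
    }
    FALSE
  }, logical(1))
}

#' @export
print.annotation_set <- function(x, ...) {
  ng <- sum(x$features$ftype == "gene")
  cat(sprintf("<annotation_set '%s': %d genes, %d features on %d seqid(s)>\n",
              x$label, ng, nrow(x$features),
              dplyr::n_distinct(x$features$seqid)))
  invisible(x)
}

#' Gene spans of an annotation set
#'
#' One row per gene feature with its span, strand, length and source column.
#' Duplicated gene-span rows (malformed input) are merged to their enclosing
#' interval with a warning.
#'
#' @param aset An `annotation_set`.
#' @return A tibble with columns `id`, `seqid`, `start`, `end`, `strand`,
#'   `length`, `source`.
#' @export
gene_spans <- function(aset) {
  stopifnot(inherits(aset, "annotation_set"))
  g <- dplyr::filter(aset$features, .data$ftype == "gene")
  if (anyDuplicated(g$id)) {
    rlang::warn("duplicate gene span rows merged to their enclosing interval")
    g <- g |>
      dplyr::group_by(.data$id) |>
      dplyr::summarise(seqid = dplyr::first(.data$seqid),
                       start = min(.data$start), end = max(.data$end),
                       strand = dplyr::first(.data$strand),
                       source = dplyr::first(.data$source), .groups = "drop")
  }
  g |>
    dplyr::transmute(.data$id, .data$seqid, .data$start, .data$end,
                     .data$strand, length = .data$end - .data$start + 1L,
                     .data$source)
}

#' Gene IDs of an annotation set
#' @param aset An `annotation_set`.
#' @return Character vector of gene feature IDs.
#' @export
gene_ids <- function(aset) {
  aset$features$id[aset$features$ftype == "gene"]
}

#' Validate an annotation set
#'
#' Reports (never silently fixes) structural violations: children outside
#' their owning gene's span, and gene spans that do not equal the union of
#' their children's intervals.
#'
#' @param aset An `annotation_set`.
#' @return A tibble with columns `issue`, `feature_id`, `detail`; zero rows
#'   when the set is clean.
#' @export
validate_annotation <- function(aset) {
  f <- aset$features
  genes <- dplyr::filter(f, .data$ftype == "gene")
  kids <- dplyr::filter(f, .data$ftype != "gene", !is.na(.data$gene_id))
  issues <- list()
  if (nrow(kids) > 0) {
    m <- match(kids$gene_id, genes$id)
    out <- which(kids$start < genes$start[m] | kids$end > genes$end[m])
    if (length(out) > 0) {
      issues[[length(issues) + 1]] <- tibble::tibble(
        issue = "child_outside_gene_span", feature_id = kids$id[out],
        detail = sprintf("[%d,%d] outside gene %s [%d,%d]",
                         kids$start[out], kids$end[out], kids$gene_id[out],
                         genes$start[m][out], genes$end[m][out]))
    }
    span <- kids |>
      dplyr::group_by(.data$gene_id) |>
      dplyr::summarise(cs = min(.data$start), ce = max(.data$end),
                       .groups = "drop")
    m2 <- match(span$gene_id, genes$id)
    mis <- which(span$cs != genes$start[m2] | span$ce != genes$end[m2])
    if (length(mis) > 0) {
      issues[[length(issues) + 1]] <- tibble::tibble(
        issue = "gene_span_mismatch", feature_id = span$gene_id[mis],
        detail = sprintf("children span [%d,%d], gene span [%d,%d]",
                         span$cs[mis], span$ce[mis],
                         genes$start[m2][mis], genes$end[m2][mis]))
    }
  }
  if (length(issues) == 0) {
    return(tibble::tibble(issue = character(), feature_id = character(),
                          detail = character()))
  }
  dplyr::bind_rows(issues)
}

#' Natural-alphanumeric ordering key
#'
#' Orders "chr2" before "chr10" by zero-padding embedded integers, the way
#' genome browsers order sequence names.
#'
#' @param x Character vector.
#' @return Character keys; `order(natural_key(x))` gives the natural order.
#' @export
natural_key <- function(x) {
  m <- gregexpr("\\d+", x)
  regmatches(x, m) <- lapply(regmatches(x, m), function(d) {
    if (length(d) == 0) return(d)
    sprintf("%015d", as.numeric(d))
  })
  x
}
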