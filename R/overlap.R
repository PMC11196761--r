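#' Fractional gene-span intersection between two annotation sets
#'
#' The bedtools-intersect step of the unification protocol: every pair of a
#' query gene and a target gene whose spans share at least `min_bp` bases on
#' the same seqid yields one overlap record with the intersection length and
#' the coverage fractions `f_query` (overlap / query gene length — the
#' bedtools `F` parameter swept by the protocol) and `f_target`. Overlap is
#' computed on gene spans, strand-agnostic by default.
#'
#' @param query,target [annotation_set()] objects on the same assembly.
#' @param min_bp Minimum intersection length in bp (>= 1).
#' @param same_strand If `TRUE`, only same-strand pairs are reported.
#' @return A tibble sorted by (`query_id`, `target_id`) with columns
#'   `query_id`, `target_id`, `seqid`, `query_start`, `query_end`,
#'   `target_start`, `target_end`, `overlap_bp`, `f_query`, `f_target`.
#' @export
intersect_genes <- function(query, target, min_bp = 1L, same_strand = FALSE) {
  stopifnot(min_bp >= 1L)
  q <- gene_spans(query)
  t <- gene_spans(target)
  shared <- intersect(unique(q$seqid), unique(t$seqid))
  if (nrow(q) > 0 && nrow(t) > 0 && length(shared) == 0) {
    rlang::warn(sprintf(
      "no shared seqids between sets: query has {%s}, target has {%s}",
      paste(sort(unique(q$seqid)), collapse = ", "),
      paste(sort(unique(t$seqid)), collapse = ", ")))
  }
  if (nrow(q) == 0 || nrow(t) == 0 || length(shared) == 0) {
    return(empty_overlap_records())
  }
  gr <- function(x) {
    GenomicRanges::GRanges(
      seqnames = x$seqid,
      ranges = IRanges::IRanges(x$start, x$end),
      strand = ifelse(x$strand %in% c("+", "-"), x$strand, "*"))
  }
  hits <- suppressWarnings(GenomicRanges::findOverlaps(
    gr(q), gr(t), minoverlap = as.integer(min_bp),
    ignore.strand = !same_strand))
  qi <- S4Vectors::queryHits(hits)
  ti <- S4Vectors::subjectHits(hits)
  ov <- pmin(q$end[qi], t$end[ti]) - pmax(q$start[qi], t$start[ti]) + 1L
  tibble::tibble(
    query_id = q$id[qi], target_id = t$id[ti], seqid = q$seqid[qi],
    query_start = q$start[qi], query_end = q$end[qi],
    target_start = t$start[ti], target_end = t$end[ti],
    overlap_bp = ov,
    f_query = ov / q$length[qi], f_target = ov / t$length[ti]) |>
    dplyr::distinct(.data$query_id, .data$target_id, .keep_all = TRUE) |>
    dplyr::arrange(.data$query_id, .data$target_id)
}

empty_overlap_records <- function() {
  tibble::tibble(query_id = character(), target_id = character(),
                 seqid = character(), query_start = integer(),
                 query_end = integer(), target_start = integer(),
                 target_end = integer(), overlap_bp = integer(),
                 f_query = double(), f_target = double())
}

#' Filter overlap records by minimum query coverage fraction
#'
#' @param records Overlap records from [intersect_genes()].
#' @param f_min Minimum `f_query`, in (0, 1].
#' @return The records with `f_query >= f_min`.
#' @export
filter_by_fraction <- function(records, f_min) {
  if (!is.numeric(f_min) || length(f_min) != 1 || is.na(f_min) ||
      f_min <= 0 || f_min > 1) {
    rlang::abort("f_min must be a single number in (0, 1]")
  }
  dplyr::filter(records, .data$f_query >= f_min)
}

#' Connected components of the query-target overlap graph
#'
#' Builds the bipartite graph whose edges are overlap records and returns its
#' connected components, classified by cardinality: `1:1` (one gene each
#' side), `1:N` (one query split across several targets), `N:1` (several
#' queries merged into one target), and `N:M` (two or more genes on both
#' sides — the complex many-to-many loci that need manual curation).
#' Components are sorted by the leftmost genomic position of any member.
#'
#' @param records Overlap records from one [intersect_genes()] call.
#' @return A tibble with one row per component: `component_id`, `seqid`,
#'   `start`, `n_query`, `n_target`, `cardinality`, and list columns
#'   `query_ids`, `target_ids`, `edges` (a tibble of the member records).
#' @export
overlap_components <- function(records) {
  if (nrow(records) == 0) {
    return(tibble::tibble(component_id = integer(), seqid = character(),
                          start = integer(), n_query = integer(),
                          n_target = integer(), cardinality = character(),
                          query_ids = list(), target_ids = list(),
                          edges = list()))
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = paste0("q\r", records$query_id),
               to = paste0("t\r", records$target_id)),
    directed = FALSE)
  memb <- igraph::components(g)$membership
  rec_comp <- unname(memb[paste0("q\r", records$query_id)])
  comps <- records |>
    dplyr::mutate(.comp = rec_comp) |>
    dplyr::group_by(.data$.comp) |>
    dplyr::summarise(
      seqid = .data$seqid[which.min(pmin(.data$query_start, .data$target_start))],
      start = min(pmin(.data$query_start, .data$target_start)),
      query_ids = list(sort(unique(.data$query_id))),
      target_ids = list(sort(unique(.data$target_id))),
      edges = list(dplyr::pick("query_id", "target_id")),
      .groups = "drop") |>
    dplyr::mutate(
      n_query = lengths(.data$query_ids),
      n_target = lengths(.data$target_ids),
      cardinality = dplyr::case_when(
        n_query == 1 & n_target == 1 ~ "1:1",
        n_query == 1 ~ "1:N",
        n_target == 1 ~ "N:1",
        TRUE ~ "N:M")) |>
    dplyr::arrange(natural_key(.data$seqid), .data$start) |>
    dplyr::mutate(component_id = dplyr::row_number()) |>
    dplyr::select("component_id", "seqid", "start", "n_query", "n_target",
                  "cardinality", "query_ids", "target_ids", "edges")
  comps
}

#' Per-chromosome synteny link counts
#'
#' Counts overlap records for each ordered (query seqid, target seqid) pair,
#' the input a chord diagram of inter-annotation synteny is drawn from. The
#' query-side seqid is looked up in `query`, which should be the query set in
#' its *original* (pre-lift) coordinates so that relocations between
#' assemblies show up off the diagonal; the target-side seqid comes from
#' `target`.
#'
#' @param records Overlap records from [intersect_genes()] (computed on the
#'   lifted coordinates).
#' @param query Annotation set giving each query gene's original seqid.
#' @param target Target annotation set.
#' @return A tibble `query_seqid`, `target_seqid`, `n`; `sum(n)` equals the
#'   number of records whose genes are present in both sets.
#' @export
synteny_links <- function(records, query, target) {
  q <- gene_spans(query)
  t <- gene_spans(target)
  records |>
    dplyr::mutate(
      query_seqid = q$seqid[match(.data$query_id, q$id)],
      target_seqid = t$seqid[match(.data$target_id, t$id)]) |>
    dplyr::filter(!is.na(.data$query_seqid), !is.na(.data$target_seqid)) |>
    dplyr::count(.data$query_seqid, .data$target_seqid, name = "n") |>
    dplyr::arrange(natural_key(.data$query_seqid),
                   natural_key(.data$target_seqid))
}

#' Export overlap records as a delimited table
#'
#' @param records Overlap records.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_overlap_table <- function(records, path) {
  records |>
    dplyr::select("query_id", "target_id", "seqid", "overlap_bp",
                  "f_query", "f_target") |>
    readr::write_tsv(path)
  invisible(path)
}

#' Export overlap records as paired BED intervals
#'
#' Twelve-column BEDPE-style output (both intervals 0-based half-open) for
#' loading gene-pair overlaps into a genome browser.
#'
#' @param records Overlap records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedpair <- function(records, path) {
  readr::write_lines(paste(
    records$seqid, records$query_start - 1L, records$query_end,
    records$seqid, records$target_start - 1L, records$target_end,
    records$query_id, records$target_id,
    records$overlap_bp,
    sprintf("%.6g", records$f_query), sprintf("%.6g", records$f_target),
    ".", sep = "\t"), path)
  invisible(path)
}
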