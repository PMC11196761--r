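#' Default threshold sweep grid
#'
#' Candidate values for the query coverage fraction threshold, spanning the
#' protocol's sweep range 0.0001 to 1 and including the conventional
#' reporting points 0.0001, 0.30 and 1.
#'
#' @return A sorted numeric vector in (0, 1].
#' @export
default_f_grid <- function() {
  c(0.0001, 0.001, 0.01, 0.05, 0.1, 0.2, 0.25, 0.3, 0.4, 0.5, 0.75, 0.9, 1.0)
}

#' Sweep the overlap-fraction threshold
#'
#' Evaluates candidate match thresholds against the per-gene best-coverage
#' data already computed by [select_best_variant()] (no re-intersection).
#' For each grid value `f` it reports the number of query genes matched at
#' `best_f >= f`, the number of distinct target genes hit at `f_query >= f`,
#' and — when a reference table of known-equivalent query pairs is given —
#' the pair concordance: among pairs whose two members both map at `>= f`,
#' the fraction sharing at least one common target gene at `>= f`.
#' (The conditional form is what makes the sweep informative: the
#' unconditional fraction can only shrink as `f` rises.)
#'
#' @param selection A `lift_selection` from [select_best_variant()].
#' @param reference_pairs Optional two-column table of known-equivalent
#'   query gene IDs.
#' @param grid Threshold grid, sorted ascending in (0, 1].
#' @return A `threshold_sweep` tibble: `f_value`, `n_query_matched`,
#'   `n_target_matched`, `n_pairs_mapped`, `pair_concordance` (NA when no
#'   pair has both members mapped, or when no pairs are supplied).
#' @export
sweep_threshold <- function(selection, reference_pairs = NULL,
                            grid = default_f_grid()) {
  stopifnot(inherits(selection, "lift_selection"))
  if (length(grid) == 0) rlang::abort("threshold grid must be nonempty")
  if (any(grid <= 0 | grid > 1)) rlang::abort("grid values must lie in (0, 1]")
  grid <- sort(grid)
  recs <- selection$records
  best_f <- selection$genes$best_f

  targets_of <- split(
    data.frame(target = recs$target_id, f = recs$f_query),
    recs$query_id)

  pairs <- NULL
  if (!is.null(reference_pairs) && nrow(reference_pairs) > 0) {
    pairs <- tibble::as_tibble(reference_pairs)
    names(pairs)[1:2] <- c("first", "second")
  }

  rows <- purrr::map(grid, function(f) {
    n_q <- sum(best_f >= f)
    n_t <- dplyr::n_distinct(recs$target_id[recs$f_query >= f])
    n_mapped <- NA_integer_
    conc <- NA_real_
    if (!is.null(pairs)) {
      hit <- function(id) {
        d <- targets_of[[id]]
        if (is.null(d)) character() else d$target[d$f >= f]
      }
      ta <- lapply(pairs$first, hit)
      tb <- lapply(pairs$second, hit)
      both <- lengths(ta) > 0 & lengths(tb) > 0
      n_mapped <- sum(both)
      if (n_mapped > 0) {
        share <- purrr::map2_lgl(ta[both], tb[both],
                                 ~ length(intersect(.x, .y)) > 0)
        conc <- mean(share)
      }
    }
    tibble::tibble(f_value = f, n_query_matched = n_q, n_target_matched = n_t,
                   n_pairs_mapped = n_mapped, pair_concordance = conc)
  }) |> dplyr::bind_rows()
  class(rows) <- c("threshold_sweep", class(rows))
  rows
}

#' Select the optimal overlap threshold from a sweep
#'
#' `max_concordance` (default) returns the smallest grid value among the
#' maximizers of pair concordance — the threshold at which known-equivalent
#' pairs most often agree on a target gene, with the most permissive such
#' threshold preferred. `knee` returns the grid point with the steepest drop
#' in matched query genes per unit threshold (discrete difference), the edge
#' of the count plateau.
#'
#' @param points A `threshold_sweep` from [sweep_threshold()].
#' @param objective `"max_concordance"` or `"knee"`.
#' @return The selected `f_value` (numeric scalar) with the objective
#'   attached as attribute `objective`.
#' @export
select_optimal_threshold <- function(points,
                                     objective = c("max_concordance", "knee")) {
  objective <- match.arg(objective)
  stopifnot(nrow(points) >= 2)
  points <- dplyr::arrange(points, .data$f_value)
  f <- if (objective == "max_concordance") {
    conc <- points$pair_concordance
    ok <- !is.na(conc)
    if (!any(ok)) rlang::abort("no concordance values; supply reference pairs")
    if (length(unique(conc[ok])) == 1) {
      rlang::warn("concordance equal at all thresholds; returning smallest grid value")
      min(points$f_value[ok])
    } else {
      cmax <- max(conc[ok])
      min(points$f_value[ok & conc == cmax])
    }
  } else {
    n <- points$n_query_matched
    fv <- points$f_value
    drop_rate <- (n[-length(n)] - n[-1]) / (fv[-1] - fv[-length(fv)])
    fv[-1][which.max(drop_rate)]
  }
  structure(f, objective = objective)
}

#' Export a threshold sweep as a wide table
#'
#' Matched-model counts laid out with one column per threshold, the
#' conventional presentation of a coverage sweep.
#'
#' @param points A `threshold_sweep`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_sweep_table <- function(points, path) {
  wide <- points |>
    dplyr::transmute(f = sprintf("F >= %g", .data$f_value),
                     .data$n_query_matched) |>
    tidyr::pivot_wider(names_from = "f", values_from = "n_query_matched")
  readr::write_tsv(wide, path)
  invisible(path)
}
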