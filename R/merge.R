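#' Merge configuration
#'
#' Thresholds and modes for the unification protocol. `f_match` is the
#' minimum query coverage fraction at which the target model is considered
#' the same gene (default 0.30, the calibrated optimum); `f_intergenic` is
#' the near-zero cutoff below which a mapped query gene is considered to lie
#' in intergenic space (default 0.0001). Queries below `f_match` are
#' "rescued": retained in the unified annotation under their own IDs.
#'
#' @param f_match Matched threshold in (0, 1].
#' @param f_intergenic Intergenic threshold, 0 < f_intergenic < f_match.
#' @param variant_preference Ordered character vector of lift-variant labels
#'   used to break best-coverage ties; defaults to the order the variants
#'   are supplied in (the un-padded lift first is the conventional choice).
#' @param same_strand Require same-strand overlap (default `FALSE`,
#'   bedtools-style strand-agnostic).
#' @param confidence_attribute Optional attribute key on target genes
#'   marking a high-confidence tier; passed through to reports only, never
#'   altering merge decisions.
#' @return A `merge_config` list.
#' @export
merge_config <- function(f_match = 0.30, f_intergenic = 1e-4,
                         variant_preference = NULL, same_strand = FALSE,
                         confidence_attribute = NULL) {
  if (!(f_intergenic > 0 && f_intergenic < f_match && f_match <= 1)) {
    rlang::abort("need 0 < f_intergenic < f_match <= 1")
  }
  structure(list(f_match = f_match, f_intergenic = f_intergenic,
                 variant_preference = variant_preference,
                 same_strand = isTRUE(same_strand),
                 confidence_attribute = confidence_attribute),
            class = "merge_config")
}

#' A lift variant
#'
#' One liftover run of the query annotation (e.g. flanking padding of 0 or
#' 500 nt), together with the query gene IDs the liftover failed to place.
#'
#' @param label Variant label, e.g. `"flank0"`.
#' @param aset [annotation_set()] of the lifted query genes.
#' @param unmapped_ids Query gene IDs absent from this variant.
#' @return A `lift_variant` list.
#' @export
lift_variant <- function(label, aset, unmapped_ids = character()) {
  stopifnot(inherits(aset, "annotation_set"))
  present <- intersect(unmapped_ids, gene_ids(aset))
  if (length(present) > 0) {
    rlang::abort(sprintf("IDs listed as unmapped but present in variant '%s': %s",
                         label, paste(present, collapse = ", ")))
  }
  structure(list(label = label, aset = aset,
                 unmapped_ids = unique(unmapped_ids)),
            class = "lift_variant")
}

as_variant_list <- function(variants) {
  if (inherits(variants, "lift_variant")) variants <- list(variants)
  if (inherits(variants, "annotation_set")) {
    variants <- list(lift_variant(variants$label, variants))
  }
  labels <- vapply(variants, `[[`, "", "label")
  if (anyDuplicated(labels)) {
    rlang::abort(sprintf("duplicate lift-variant label(s): %s",
                         paste(unique(labels[duplicated(labels)]), collapse = ", ")))
  }
  variants
}

#' Select the best lift variant per query gene
#'
#' For each query gene, the lift variant achieving the highest best query
#' coverage fraction (max `f_query` over target genes) is kept; genes mapped
#' in only one variant use that variant; genes in no variant are unmapped.
#' Ties are broken by the configured variant preference order.
#'
#' @param variants A `lift_variant`, annotation set, or list of them.
#' @param target Target [annotation_set()].
#' @param cfg A [merge_config()].
#' @return A `lift_selection`: list with `genes` (tibble: `query_id`,
#'   `source`, `chosen_variant`, `best_f`, `best_target_id`,
#'   `n_matched_targets`), `records` (all chosen-variant overlap records,
#'   with a `variant` column), `cfg`, and `target_label`.
#' @export
select_best_variant <- function(variants, target, cfg = merge_config()) {
  variants <- as_variant_list(variants)
  stopifnot(length(variants) >= 1, inherits(target, "annotation_set"))
  labels <- vapply(variants, `[[`, "", "label")
  pref <- cfg$variant_preference %||% labels
  missing_pref <- setdiff(labels, pref)
  pref <- c(pref, missing_pref)

  per_variant <- purrr::map(variants, function(v) {
    recs <- intersect_genes(v$aset, target, same_strand = cfg$same_strand)
    spans <- gene_spans(v$aset)
    best <- if (nrow(recs) == 0) {
      tibble::tibble(query_id = character(), best_f = double(),
                     best_target_id = character(),
                     n_matched_targets = integer())
    } else {
      recs |>
        dplyr::group_by(.data$query_id) |>
        dplyr::summarise(
          best_f = max(.data$f_query),
          best_target_id = .data$target_id[order(-.data$f_query,
                                                 .data$target_id)][1],
          n_matched_targets = sum(.data$f_query >= cfg$f_match),
          .groups = "drop")
    }
    genes <- tibble::tibble(query_id = spans$id, source = spans$source) |>
      dplyr::left_join(best, by = "query_id") |>
      dplyr::mutate(best_f = dplyr::coalesce(.data$best_f, 0),
                    n_matched_targets = dplyr::coalesce(.data$n_matched_targets, 0L),
                    variant = v$label)
    list(genes = genes, records = dplyr::mutate(recs, variant = v$label))
  })

  all_genes <- dplyr::bind_rows(purrr::map(per_variant, "genes"))
  chosen <- all_genes |>
    dplyr::mutate(.pref = match(.data$variant, pref)) |>
    dplyr::group_by(.data$query_id) |>
    dplyr::arrange(dplyr::desc(.data$best_f), .data$.pref, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::select(-".pref") |>
    dplyr::rename(chosen_variant = "variant")

  unmapped <- setdiff(unique(unlist(purrr::map(variants, "unmapped_ids"))),
                      chosen$query_id)
  if (length(unmapped) > 0) {
    chosen <- dplyr::bind_rows(chosen, tibble::tibble(
      query_id = unmapped, source = NA_character_,
      best_f = 0, best_target_id = NA_character_, n_matched_targets = 0L,
      chosen_variant = NA_character_))
  }
  chosen <- dplyr::arrange(chosen, .data$query_id) |>
    dplyr::select("query_id", "source", "chosen_variant", "best_f",
                  "best_target_id", "n_matched_targets")

  all_records <- dplyr::bind_rows(purrr::map(per_variant, "records"))
  chosen_records <- dplyr::semi_join(
    all_records,
    chosen |> dplyr::transmute(.data$query_id, variant = .data$chosen_variant),
    by = c("query_id", "variant"))

  structure(list(genes = chosen, records = chosen_records, cfg = cfg,
                 target_label = target$label),
            class = "lift_selection")
}

#' @export
print.lift_selection <- function(x, ...) {
  cat(sprintf("<lift_selection: %d query genes vs target '%s', %d overlap records>\n",
              nrow(x$genes), x$target_label, nrow(x$records)))
  invisible(x)
}

#' Classify query genes into fates
#'
#' Applies the threshold rules of the unification protocol to the per-gene
#' best coverage: `matched` (`best_f >= f_match`; the target model is kept),
#' `rescued_overlapping` (`f_intergenic <= best_f < f_match`),
#' `rescued_intergenic` (mapped but `best_f < f_intergenic`, i.e. the gene
#' lies between target genes), and `unmapped` (placed by no lift variant).
#' The categories are exhaustive and mutually exclusive over the query gene
#' universe.
#'
#' @param selection A `lift_selection` from [select_best_variant()].
#' @param cfg A [merge_config()]; defaults to the one used for selection.
#' @return A `gene_fates` tibble: `query_id`, `source`, `chosen_variant`,
#'   `best_target_id`, `best_f`, `category`. The chosen-variant overlap
#'   records and the config are attached as attributes for downstream steps.
#' @export
classify_genes <- function(selection, cfg = selection$cfg) {
  stopifnot(inherits(selection, "lift_selection"))
  fates <- selection$genes |>
    dplyr::mutate(category = dplyr::case_when(
      is.na(.data$chosen_variant) ~ "unmapped",
      .data$best_f >= cfg$f_match ~ "matched",
      .data$best_f >= cfg$f_intergenic ~ "rescued_overlapping",
      TRUE ~ "rescued_intergenic")) |>
    dplyr::select("query_id", "source", "chosen_variant", "best_target_id",
                  "best_f", "category")
  attr(fates, "records") <- selection$records
  attr(fates, "cfg") <- cfg
  class(fates) <- c("gene_fates", class(fates))
  fates
}

rescued_categories <- c("rescued_overlapping", "rescued_intergenic")

#' Merge annotations into a unified set
#'
#' Assembles the unified annotation: all target gene models (IDs unchanged)
#' plus every rescued query gene model in its chosen-variant coordinates,
#' keeping the query's own identifier. Matched query models are not added —
#' their loci are already represented by the target models. Every unified
#' gene carries machine-readable provenance attributes (`merge_origin`,
#' and for rescued genes `merge_variant`, `merge_category`, `merge_f`).
#'
#' When `known_pairs` links two query sources (e.g. the pre-existing
#' pairing of the two v4 annotations) and both members of a pair were
#' rescued at overlapping positions, a single gene is emitted (first-column
#' ID primary; the partner is recorded in `merge_collapsed_with` and in the
#' translation table).
#'
#' @param fates `gene_fates` from [classify_genes()].
#' @param variants The lift variants used for selection.
#' @param target Target [annotation_set()].
#' @param cfg A [merge_config()].
#' @param known_pairs Optional two-column tibble/data frame of
#'   known-equivalent query gene IDs.
#' @param label Label for the unified set.
#' @return A `unified_annotation`: list with `aset` (the unified
#'   [annotation_set()]), `fates`, `collapsed` (tibble of collapsed pairs),
#'   and `counts`.
#' @export
merge_annotations <- function(fates, variants, target, cfg = merge_config(),
                              known_pairs = NULL, label = "unified") {
  stopifnot(inherits(fates, "gene_fates"), inherits(target, "annotation_set"))
  variants <- as_variant_list(variants)
  vmap <- stats::setNames(variants, vapply(variants, `[[`, "", "label"))
  rescued <- dplyr::filter(fates, .data$category %in% rescued_categories)

  # known-pair collapsing among rescued genes with overlapping intervals
  collapsed <- tibble::tibble(kept_id = character(), dropped_id = character())
  drop_ids <- character()
  if (!is.null(known_pairs) && nrow(rescued) > 0 && nrow(known_pairs) > 0) {
    kp <- tibble::as_tibble(known_pairs)
    names(kp)[1:2] <- c("first", "second")
    spans <- rescued_spans(rescued, vmap)
    kp <- kp |>
      dplyr::filter(.data$first %in% rescued$query_id,
                    .data$second %in% rescued$query_id)
    if (nrow(kp) > 0) {
      a <- spans[match(kp$first, spans$id), ]
      b <- spans[match(kp$second, spans$id), ]
      ok <- a$seqid == b$seqid & a$start <= b$end & b$start <= a$end
      kp <- kp[which(ok), ]
      if (nrow(kp) > 0) {
        collapsed <- tibble::tibble(kept_id = kp$first, dropped_id = kp$second)
        drop_ids <- collapsed$dropped_id
      }
    }
  }

  rescued_feats <- purrr::map(seq_len(nrow(rescued)), function(i) {
    qid <- rescued$query_id[i]
    if (qid %in% drop_ids) return(NULL)
    v <- vmap[[rescued$chosen_variant[i]]]
    fs <- v$aset$features[v$aset$features$gene_id %in% qid, , drop = FALSE]
    is_g <- fs$ftype == "gene"
    fs$attributes[is_g] <- lapply(fs$attributes[is_g], function(a) {
      a[["merge_origin"]] <- fs$source[is_g][1]
      a[["merge_variant"]] <- rescued$chosen_variant[i]
      a[["merge_category"]] <- rescued$category[i]
      a[["merge_f"]] <- format(rescued$best_f[i], digits = 6)
      partner <- collapsed$dropped_id[collapsed$kept_id == qid]
      if (length(partner) > 0) {
        a[["merge_collapsed_with"]] <- paste(partner, collapse = ",")
      }
      a
    })
    fs
  })
  rescued_feats <- dplyr::bind_rows(rescued_feats)
  if (nrow(rescued_feats) == 0) rescued_feats <- empty_features()

  clash <- intersect(rescued_feats$id[rescued_feats$ftype == "gene"],
                     gene_ids(target))
  if (length(clash) > 0) {
    rlang::abort(sprintf(
      "rescued query gene ID(s) collide with target gene IDs: %s",
      paste(clash, collapse = ", ")))
  }

  tf <- target$features
  is_g <- tf$ftype == "gene"
  tf$attributes[is_g] <- lapply(tf$attributes[is_g], function(a) {
    a[["merge_origin"]] <- target$label
    a
  })

  unified_features <- dplyr::bind_rows(tf, rescued_feats)
  aset <- new_annotation_set(unified_features, label)
  n_rescued_kept <- sum(rescued_feats$ftype == "gene")
  counts <- list(
    n_target = length(gene_ids(target)),
    n_rescued = nrow(rescued),
    n_collapsed = nrow(collapsed),
    n_unified = length(gene_ids(aset)))
  stopifnot(counts$n_unified ==
              counts$n_target + counts$n_rescued - counts$n_collapsed)
  structure(list(aset = aset, fates = fates, collapsed = collapsed,
                 counts = counts),
            class = "unified_annotation")
}

rescued_spans <- function(rescued, vmap) {
  purrr::map(unique(rescued$chosen_variant), function(vl) {
    gene_spans(vmap[[vl]]$aset)
  }) |>
    dplyr::bind_rows() |>
    dplyr::distinct(.data$id, .keep_all = TRUE)
}

#' @export
print.unified_annotation <- function(x, ...) {
  cat(sprintf(
    "<unified_annotation: %d genes (%d target + %d rescued - %d collapsed)>\n",
    x$counts$n_unified, x$counts$n_target, x$counts$n_rescued,
    x$counts$n_collapsed))
  invisible(x)
}

#' Build the identifier translation table
#'
#' One row per unified gene linking identifiers across annotation sources:
#' matched query genes collapse onto their shared target gene's row (one
#' column per query source, multiple IDs comma-separated); rescued genes
#' keep their own row with `unified_id` equal to their query ID; target
#' genes hit by no query at the match threshold appear as `target_only`
#' rows; unmapped query genes are retained as rows with an empty
#' `unified_id`. A query gene matching several targets at the threshold
#' contributes to each such target's row (its primary, best-coverage target
#' is listed in `best_target` on rescued rows and drives `unified_id`
#' placement for matched rows).
#'
#' @param fates `gene_fates` from [classify_genes()] (carrying its overlap
#'   records).
#' @param target Target [annotation_set()].
#' @param known_pairs Optional two-column pair table joining query sources.
#' @param collapsed Optional collapsed-pair tibble from
#'   [merge_annotations()] (`$collapsed`).
#' @param support Optional per-gene support tibble from
#'   [evidence_support()]; adds a `supported` column.
#' @return A tibble: one column per query source, then `target_id`,
#'   `unified_id`, `category`, `best_f`, `chosen_variant` (and `supported`).
#' @export
build_translation_table <- function(fates, target, known_pairs = NULL,
                                    collapsed = NULL, support = NULL) {
  stopifnot(inherits(fates, "gene_fates"))
  records <- attr(fates, "records")
  cfg <- attr(fates, "cfg")
  sources <- unique(stats::na.omit(fates$source))
  if (length(sources) == 0) sources <- "query"
  src_of <- function(ids) {
    s <- fates$source[match(ids, fates$query_id)]
    dplyr::coalesce(s, sources[1])
  }
  missing_src <- is.na(fates$source)

  # matched rows: group every (query, target) edge at >= f_match for
  # matched queries by target gene
  matched <- dplyr::filter(fates, .data$category == "matched")
  edge <- records |>
    dplyr::semi_join(matched, by = "query_id") |>
    dplyr::filter(.data$f_query >= cfg$f_match)
  matched_rows <- if (nrow(edge) > 0) {
    edge |>
      dplyr::mutate(source = src_of(.data$query_id)) |>
      dplyr::group_by(.data$target_id) |>
      dplyr::summarise(
        best_f = max(.data$f_query),
        chosen_variant = paste(sort(unique(.data$variant)), collapse = ","),
        ids_by_source = list(split(sort(unique(.data$query_id)),
                                   src_of(sort(unique(.data$query_id))))),
        .groups = "drop") |>
      dplyr::mutate(unified_id = .data$target_id, category = "matched")
  } else {
    tibble::tibble(target_id = character(), best_f = double(),
                   chosen_variant = character(), ids_by_source = list(),
                   unified_id = character(), category = character())
  }

  tids <- gene_ids(target)
  target_only <- setdiff(tids, matched_rows$target_id)
  to_rows <- tibble::tibble(
    target_id = target_only, best_f = NA_real_,
    chosen_variant = NA_character_,
    ids_by_source = rep(list(stats::setNames(list(), character())),
                        length(target_only)),
    unified_id = target_only, category = "target_only")

  other <- dplyr::filter(fates, .data$category != "matched")
  dropped <- if (!is.null(collapsed)) collapsed$dropped_id else character()
  kp_partner <- function(qid) {
    if (is.null(collapsed)) return(character())
    collapsed$dropped_id[collapsed$kept_id == qid]
  }
  other_rows <- purrr::map(seq_len(nrow(other)), function(i) {
    qid <- other$query_id[i]
    if (qid %in% dropped) return(NULL)
    ids <- c(qid, kp_partner(qid))
    tibble::tibble(
      target_id = other$best_target_id[i],
      best_f = other$best_f[i],
      chosen_variant = other$chosen_variant[i],
      ids_by_source = list(split(ids, src_of(ids))),
      unified_id = if (other$category[i] == "unmapped") NA_character_ else qid,
      category = other$category[i])
  }) |> dplyr::bind_rows()

  rows <- dplyr::bind_rows(matched_rows, to_rows, other_rows)
  for (s in sources) {
    rows[[s]] <- vapply(rows$ids_by_source, function(m) {
      v <- m[[s]]
      if (is.null(v) || length(v) == 0) NA_character_
      else paste(v, collapse = ",")
    }, character(1))
  }
  rows |>
    dplyr::select(dplyr::all_of(sources), "target_id", "unified_id",
                  "category", "best_f", "chosen_variant") |>
    dplyr::left_join(
      if (is.null(support)) {
        tibble::tibble(unified_id = character(), supported = logical())
      } else {
        dplyr::select(support, unified_id = "gene_id", "supported")
      },
      by = "unified_id") |>
    (\(d) if (is.null(support)) dplyr::select(d, -"supported") else d)() |>
    dplyr::arrange(.data$category, .data$unified_id)
}

#' Flag genes by transcript-evidence support
#'
#' A gene is supported iff at least one evidence interval (e.g. a mapped
#' transcript alignment) overlaps its span by at least `min_bp`. Rescued
#' genes thereby partition into supported (likely valid genes) and
#' unsupported (possibly unreliable predictions).
#'
#' @param fates `gene_fates` from [classify_genes()].
#' @param unified A `unified_annotation` from [merge_annotations()] (or an
#'   [annotation_set()]).
#' @param evidence Evidence intervals: tibble with `seqid`, `start`, `end`
#'   (1-based inclusive, as from [read_bed()]).
#' @param min_bp Minimum overlap in bp.
#' @return A tibble `gene_id`, `category` (gene fate for rescued genes,
#'   `"target"` for target-derived genes), `supported`.
#' @export
evidence_support <- function(fates, unified, evidence, min_bp = 1L) {
  aset <- if (inherits(unified, "unified_annotation")) unified$aset else unified
  stopifnot(inherits(aset, "annotation_set"))
  g <- gene_spans(aset)
  supported <- rep(FALSE, nrow(g))
  if (nrow(evidence) > 0 && nrow(g) > 0) {
    hits <- suppressWarnings(GenomicRanges::findOverlaps(
      GenomicRanges::GRanges(g$seqid, IRanges::IRanges(g$start, g$end)),
      GenomicRanges::GRanges(evidence$seqid,
                             IRanges::IRanges(evidence$start, evidence$end)),
      minoverlap = as.integer(min_bp), ignore.strand = TRUE))
    supported[unique(S4Vectors::queryHits(hits))] <- TRUE
  }
  cat_of <- fates$category[match(g$id, fates$query_id)]
  tibble::tibble(gene_id = g$id,
                 category = dplyr::coalesce(cat_of, "target"),
                 supported = supported)
}
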