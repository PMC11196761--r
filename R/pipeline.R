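#' Read a flat key-value run configuration file
#'
#' One `key = value` pair per line, `#` comments allowed. Variant inputs use
#' dotted keys: `query_gff.flank0 = path`, `unmapped.flank0 = path`.
#' Recognized scalar keys: `target_gff`, `out_dir`, `pairs`, `evidence`,
#' `f_match`, `f_intergenic`, `same_strand`, `grid` (comma-separated),
#' `variant_preference` (comma-separated), `sweep` (logical).
#'
#' @param path Path to the config file.
#' @return A named list of (typed) config values.
#' @export
read_run_config <- function(path) {
  lines <- readr::read_lines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl("=", lines, fixed = TRUE)])
  keys <- trimws(sub("=.*$", "", lines))
  vals <- trimws(sub("^[^=]*=", "", lines))
  vals <- gsub('^"|"$', "", vals)
  cfg <- stats::setNames(as.list(vals), keys)
  for (k in c("f_match", "f_intergenic")) {
    if (!is.null(cfg[[k]])) cfg[[k]] <- as.numeric(cfg[[k]])
  }
  for (k in c("same_strand", "sweep")) {
    if (!is.null(cfg[[k]])) cfg[[k]] <- toupper(cfg[[k]]) %in% c("TRUE", "1", "YES")
  }
  for (k in c("grid", "variant_preference")) {
    if (!is.null(cfg[[k]])) {
      v <- trimws(strsplit(cfg[[k]], ",", fixed = TRUE)[[1]])
      cfg[[k]] <- if (k == "grid") as.numeric(v) else v
    }
  }
  cfg
}

config_variants <- function(cfg) {
  qkeys <- grep("^query_gff\\.", names(cfg), value = TRUE)
  if (length(qkeys) == 0) {
    rlang::abort("config must define at least one query_gff.<variant> entry")
  }
  labels <- sub("^query_gff\\.", "", qkeys)
  purrr::map2(qkeys, labels, function(k, lab) {
    aset <- parse_gff3(cfg[[k]], label = lab)
    unk <- cfg[[paste0("unmapped.", lab)]]
    unmapped <- if (!is.null(unk)) readr::read_lines(unk) else character()
    lift_variant(lab, aset, unmapped[nzchar(unmapped)])
  })
}

#' Run the full unification pipeline
#'
#' End-to-end merge: parses the target and every query lift variant,
#' selects the best lift per gene, classifies gene fates, merges into a
#' unified annotation, and writes the unified GFF3, the identifier
#' translation table, a category-count summary JSON (including the
#' query-only / target-only / shared partition), a complex-locus report of
#' non-1:1 overlap components, and a machine-readable run manifest.
#' Outputs are byte-identical across reruns on identical inputs.
#'
#' @param config A config list (see [read_run_config()]) or path to a
#'   config file.
#' @return Invisibly, a list with the in-memory results (`selection`,
#'   `fates`, `unified`, `translation`, `components`, `sweep`, `support`)
#'   and `paths` of the written artifacts.
#' @export
run_merge <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  f_match <- config$f_match %||% 0.30
  f_intergenic <- config$f_intergenic %||% 1e-4
  if (f_intergenic >= f_match) {
    rlang::abort("config error: f_intergenic must be < f_match")
  }
  cfg <- merge_config(f_match = f_match, f_intergenic = f_intergenic,
                      variant_preference = config$variant_preference,
                      same_strand = isTRUE(config$same_strand))
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  target <- parse_gff3(config$target_gff, label = "target")
  variants <- config_variants(config)
  known_pairs <- if (!is.null(config$pairs)) {
    readr::read_tsv(config$pairs, show_col_types = FALSE)
  } else NULL

  selection <- select_best_variant(variants, target, cfg)
  fates <- classify_genes(selection, cfg)
  unified <- merge_annotations(fates, variants, target, cfg,
                               known_pairs = known_pairs)
  support <- NULL
  if (!is.null(config$evidence)) {
    support <- evidence_support(fates, unified, read_bed(config$evidence))
  }
  translation <- build_translation_table(fates, target,
                                         known_pairs = known_pairs,
                                         collapsed = unified$collapsed,
                                         support = support)
  components <- overlap_components(selection$records)
  complex_loci <- dplyr::filter(components, .data$cardinality != "1:1")
  sweep <- NULL
  if (isTRUE(config$sweep) && !is.null(known_pairs)) {
    sweep <- sweep_threshold(selection, known_pairs,
                             grid = config$grid %||% default_f_grid())
  }

  paths <- list(
    unified_gff = file.path(out_dir, "unified.gff3"),
    translation = file.path(out_dir, "translation_table.tsv"),
    summary = file.path(out_dir, "summary.json"),
    complex_loci = file.path(out_dir, "complex_loci.tsv"),
    manifest = file.path(out_dir, "manifest.json"))
  write_gff3(unified$aset, paths$unified_gff)
  readr::write_tsv(translation, paths$translation, na = "")
  complex_loci |>
    dplyr::transmute(.data$component_id, .data$seqid, .data$start,
                     .data$cardinality, .data$n_query, .data$n_target,
                     query_ids = purrr::map_chr(.data$query_ids, paste,
                                                collapse = ","),
                     target_ids = purrr::map_chr(.data$target_ids, paste,
                                                 collapse = ",")) |>
    readr::write_tsv(paths$complex_loci)

  summary <- pipeline_summary(fates, unified, translation, support, sweep)
  jsonlite::write_json(summary, paths$summary, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  manifest <- run_manifest(config, cfg, summary)
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  invisible(list(selection = selection, fates = fates, unified = unified,
                 translation = translation, components = components,
                 sweep = sweep, support = support, paths = paths))
}

pipeline_summary <- function(fates, unified, translation, support = NULL,
                             sweep = NULL) {
  cat_counts <- as.list(table(fates$category))
  out <- list(
    n_query = nrow(fates),
    categories = cat_counts,
    n_target = unified$counts$n_target,
    n_rescued = unified$counts$n_rescued,
    n_collapsed_pairs = unified$counts$n_collapsed,
    n_unified = unified$counts$n_unified,
    partition = list(
      query_only = unified$counts$n_rescued +
        sum(fates$category == "unmapped"),
      target_only = sum(translation$category == "target_only"),
      shared_targets = sum(translation$category == "matched"),
      shared_queries = sum(fates$category == "matched")))
  if (!is.null(support)) {
    out$evidence <- support |>
      dplyr::group_by(.data$category) |>
      dplyr::summarise(n = dplyr::n(), supported = sum(.data$supported),
                       .groups = "drop") |>
      purrr::transpose()
  }
  if (!is.null(sweep)) {
    out$sweep <- purrr::transpose(
      dplyr::select(sweep, -dplyr::any_of("n_pairs_mapped")))
  }
  out
}

run_manifest <- function(config, cfg, summary) {
  inputs <- config[vapply(config, is.character, logical(1))]
  files <- unlist(inputs[grepl("gff|pairs|evidence|unmapped",
                               names(inputs))], use.names = TRUE)
  files <- files[file.exists(files)]
  list(
    package = "liftmerge",
    version = as.character(utils::packageVersion("liftmerge")),
    inputs = as.list(files),
    input_md5 = as.list(stats::setNames(unname(tools::md5sum(files)),
                                        names(files))),
    config = list(f_match = cfg$f_match, f_intergenic = cfg$f_intergenic,
                  same_strand = cfg$same_strand),
    counts = summary$categories)
}

#' Standalone gene-overlap run
#'
#' Parses two GFF3 files and writes the overlap-record table, optionally
#' filtered by a minimum query coverage fraction.
#'
#' @param query_gff,target_gff Input GFF3 paths.
#' @param out Output TSV path.
#' @param f_min Optional minimum `f_query` filter in (0, 1].
#' @param min_bp Minimum overlap in bp.
#' @param same_strand Restrict to same-strand overlaps.
#' @return The records tibble, invisibly.
#' @export
run_intersect <- function(query_gff, target_gff, out, f_min = NULL,
                          min_bp = 1L, same_strand = FALSE) {
  recs <- intersect_genes(parse_gff3(query_gff, "query"),
                          parse_gff3(target_gff, "target"),
                          min_bp = min_bp, same_strand = same_strand)
  if (!is.null(f_min)) recs <- filter_by_fraction(recs, f_min)
  write_overlap_table(recs, out)
  invisible(recs)
}

#' Standalone threshold calibration run
#'
#' Sweeps the coverage threshold against a reference pair table and writes
#' the sweep (long TSV plus a wide one-row layout) and the selected
#' optimum.
#'
#' @param config Config list or file path; must define the query/target
#'   inputs and `pairs`.
#' @param out_dir Output directory (overrides config).
#' @param objective Selection objective, see [select_optimal_threshold()].
#' @return Invisibly, a list with `sweep` and `optimum`.
#' @export
run_calibrate <- function(config, out_dir = NULL,
                          objective = "max_concordance") {
  if (is.character(config)) config <- read_run_config(config)
  out_dir <- out_dir %||% config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- merge_config(f_match = config$f_match %||% 0.30,
                      f_intergenic = config$f_intergenic %||% 1e-4,
                      same_strand = isTRUE(config$same_strand))
  target <- parse_gff3(config$target_gff, label = "target")
  variants <- config_variants(config)
  pairs <- readr::read_tsv(config$pairs, show_col_types = FALSE)
  selection <- select_best_variant(variants, target, cfg)
  sweep <- sweep_threshold(selection, pairs,
                           grid = config$grid %||% default_f_grid())
  optimum <- select_optimal_threshold(sweep, objective)
  readr::write_tsv(sweep, file.path(out_dir, "sweep.tsv"))
  write_sweep_table(sweep, file.path(out_dir, "sweep_wide.tsv"))
  jsonlite::write_json(
    list(objective = objective, optimum = as.numeric(optimum)),
    file.path(out_dir, "optimum.json"), auto_unbox = TRUE, digits = NA)
  invisible(list(sweep = sweep, optimum = optimum))
}

#' Standalone complex-locus classification run
#'
#' Writes the overlap-component report (all components with their
#' cardinality) for two GFF3 inputs.
#'
#' @param query_gff,target_gff Input GFF3 paths.
#' @param out Output TSV path.
#' @param same_strand Restrict to same-strand overlaps.
#' @return The component tibble, invisibly.
#' @export
run_classify_overlaps <- function(query_gff, target_gff, out,
                                  same_strand = FALSE) {
  recs <- intersect_genes(parse_gff3(query_gff, "query"),
                          parse_gff3(target_gff, "target"),
                          same_strand = same_strand)
  comps <- overlap_components(recs)
  comps |>
    dplyr::transmute(.data$component_id, .data$seqid, .data$start,
                     .data$cardinality, .data$n_query, .data$n_target,
                     query_ids = purrr::map_chr(.data$query_ids, paste,
                                                collapse = ","),
                     target_ids = purrr::map_chr(.data$target_ids, paste,
                                                 collapse = ",")) |>
    readr::write_tsv(out)
  invisible(comps)
}

#' Generate a self-contained fixture workspace
#'
#' Writes a complete, seeded test workspace: query and target GFF3s, an
#' unmapped-ID list, transcript-evidence BED, ground-truth and pair tables,
#' and a ready-to-run merge config pointing at them.
#'
#' @param out_dir Output directory.
#' @param seed Integer seed (identical seeds give identical workspaces).
#' @param n_genes,n_seqids Size of the simulated base annotation.
#' @param supported_fraction Fraction of genes given transcript evidence.
#' @return Invisibly, the list of written paths.
#' @export
run_fixtures <- function(out_dir, seed = 1L, n_genes = 100L, n_seqids = 2L,
                         supported_fraction = 0.4) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  base <- simulate_annotation(n_genes, n_seqids, seed = seed, label = "simq")
  edits <- sample_edits(base, seed = seed + 1L)
  fx <- apply_edits(base, edits)
  ev <- simulate_evidence(base, supported_fraction, seed = seed + 2L)
  paired <- simulate_paired_set(base, "simr", jitter = 5L, seed = seed + 3L)
  paths <- list(
    query_gff = file.path(out_dir, "query.gff3"),
    target_gff = file.path(out_dir, "target.gff3"),
    unmapped = file.path(out_dir, "unmapped.txt"),
    evidence = file.path(out_dir, "evidence.bed"),
    truth = file.path(out_dir, "truth.tsv"),
    pairs = file.path(out_dir, "pairs.tsv"),
    config = file.path(out_dir, "merge.cfg"))
  write_gff3(fx$query, paths$query_gff)
  write_gff3(fx$target, paths$target_gff)
  readr::write_lines(fx$unmapped_ids, paths$unmapped)
  write_bed(ev$evidence, paths$evidence)
  fx$truth |>
    dplyr::mutate(derived_target_ids = purrr::map_chr(
      .data$derived_target_ids, paste, collapse = ",")) |>
    readr::write_tsv(paths$truth)
  readr::write_tsv(paired$pairs, paths$pairs)
  readr::write_lines(c(
    sprintf("query_gff.lift0 = %s", paths$query_gff),
    sprintf("unmapped.lift0 = %s", paths$unmapped),
    sprintf("target_gff = %s", paths$target_gff),
    sprintf("evidence = %s", paths$evidence),
    sprintf("out_dir = %s", file.path(out_dir, "merged")),
    "f_match = 0.30",
    "f_intergenic = 0.0001"), paths$config)
  invisible(paths)
}

#' Look up rows of a written translation table by gene ID
#'
#' @param table_path Path to a translation table TSV written by
#'   [run_merge()].
#' @param ids Gene IDs to look up (matched against every ID column).
#' @return The matching rows.
#' @export
run_translate <- function(table_path, ids) {
  tab <- readr::read_tsv(table_path, show_col_types = FALSE)
  id_cols <- setdiff(names(tab), c("category", "best_f", "chosen_variant",
                                   "supported"))
  hit <- rep(FALSE, nrow(tab))
  for (cl in id_cols) {
    vals <- strsplit(dplyr::coalesce(as.character(tab[[cl]]), ""), ",",
                     fixed = TRUE)
    hit <- hit | vapply(vals, function(v) any(v %in% ids), logical(1))
  }
  tab[hit, ]
}
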