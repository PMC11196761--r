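#' Simulate a base gene annotation set
#'
#' Generates non-overlapping gene models laid out left to right on each
#' seqid, with mRNA/exon/CDS children (or gene+CDS rows only in `cds_only`
#' mode, mimicking CDS-only annotations). Gene spans equal the union of
#' their children. Deterministic under `seed`.
#'
#' @param n_genes Total number of genes (spread across seqids).
#' @param n_seqids Number of sequence names (`chr1`, `chr2`, ...).
#' @param gene_len,gap_len Length ranges (bp) for genes and intergenic gaps.
#' @param seed Integer seed.
#' @param label Set label (also the GFF3 `source` column and ID prefix).
#' @param cds_only Emit gene + CDS rows only (no mRNA/exon level).
#' @param exons_per_gene Range of exon counts per gene.
#' @return An [annotation_set()].
#' @export
simulate_annotation <- function(n_genes, n_seqids = 1,
                                gene_len = c(500L, 2000L),
                                gap_len = c(200L, 1500L),
                                seed = 1L, label = "simq",
                                cds_only = FALSE,
                                exons_per_gene = c(1L, 3L)) {
  stopifnot(n_genes >= 1, n_seqids >= 1,
            all(gene_len > 0), all(gap_len > 0))
  # draw uniformly from [a, b] without base sample()'s scalar surprise
  rint <- function(a, b) a + sample.int(b - a + 1L, 1L) - 1L
  withr::with_seed(seed, {
    per_seq <- diff(round(seq(0, n_genes, length.out = n_seqids + 1)))
    rows <- list()
    gi <- 0L
    for (si in seq_len(n_seqids)) {
      seqid <- paste0("chr", si)
      pos <- 0L
      for (k in seq_len(per_seq[si])) {
        gi <- gi + 1L
        gap <- rint(gap_len[1], gap_len[2])
        len <- rint(gene_len[1], gene_len[2])
        s <- pos + gap + 1L
        e <- s + len - 1L
        pos <- e
        strand <- sample(c("+", "-"), 1)
        gid <- sprintf("%s.g%04d", label, gi)
        rows[[length(rows) + 1]] <-
          gene_model_rows(gid, seqid, s, e, strand, label, cds_only,
                          rint(exons_per_gene[1], exons_per_gene[2]))
      }
    }
    annotation_set(dplyr::bind_rows(rows), label)
  })
}

# Feature rows for one gene model; gene span == union of children.
gene_model_rows <- function(gid, seqid, s, e, strand, source,
                            cds_only = FALSE, n_exons = 1L) {
  len <- e - s + 1L
  n_exons <- max(1L, min(n_exons, len %/% 60L))
  if (n_exons == 1L) {
    ex_s <- s
    ex_e <- e
  } else {
    w <- len %/% (2L * n_exons - 1L)
    ex_s <- s + (seq_len(n_exons) - 1L) * 2L * w
    ex_e <- ex_s + w - 1L
    ex_e[n_exons] <- e
  }
  row <- function(type, id, start, end, parents, phase = ".") {
    tibble::tibble(seqid = seqid, source = source, type = type,
                   start = start, end = end, score = ".", strand = strand,
                   phase = phase, id = id, parents = list(parents),
                   attributes = list(character()), has_id = TRUE)
  }
  out <- list(row("gene", gid, s, e, character()))
  if (cds_only) {
    for (i in seq_len(n_exons)) {
      out[[length(out) + 1]] <-
        row("CDS", paste0(gid, ".c", i), ex_s[i], ex_e[i], gid, phase = "0")
    }
  } else {
    tid <- paste0(gid, ".t1")
    out[[length(out) + 1]] <- row("mRNA", tid, s, e, gid)
    for (i in seq_len(n_exons)) {
      out[[length(out) + 1]] <-
        row("exon", paste0(gid, ".e", i), ex_s[i], ex_e[i], tid)
      out[[length(out) + 1]] <-
        row("CDS", paste0(gid, ".c", i), ex_s[i], ex_e[i], tid, phase = "0")
    }
  }
  dplyr::bind_rows(out)
}

edit_ops <- c("keep", "shift", "resize", "split", "merge", "delete",
              "move", "invert_region", "chimera", "unmap")

#' Randomly assign edit operations to genes
#'
#' Draws an edit plan emulating what a genome reannotation does to gene
#' models: most kept (possibly shifted or resized), some split in two, some
#' merged with or chimerically fused to their right neighbor, some deleted,
#' moved, strand-inverted, or dropped from the lift entirely. `merge` and
#' `chimera` consume the immediate right neighbor on the same seqid, which
#' keeps every edit geometrically independent of all others.
#'
#' @param aset Base [annotation_set()].
#' @param weights Named weights over the operations (see Details); names
#'   `resize_matched` / `resize_rescued` control the coverage regime of
#'   resize edits.
#' @param seed Integer seed.
#' @return An edit tibble (`gene_id`, `op`, `value`, `partner`) for
#'   [apply_edits()].
#' @export
sample_edits <- function(aset,
                         weights = c(keep = 0.25, shift = 0.15,
                                     resize_matched = 0.10,
                                     resize_rescued = 0.15, split = 0.10,
                                     merge = 0.08, delete = 0.07,
                                     move = 0.05, invert_region = 0.05,
                                     chimera = 0.05, unmap = 0.05),
                         seed = 1L) {
  g <- gene_spans(aset) |>
    dplyr::arrange(natural_key(.data$seqid), .data$start)
  withr::with_seed(seed, {
    taken <- rep(FALSE, nrow(g))
    out <- list()
    for (i in seq_len(nrow(g))) {
      if (taken[i]) next
      op <- sample(names(weights), 1, prob = weights)
      next_i <- if (i < nrow(g) && g$seqid[i + 1] == g$seqid[i] &&
                      !taken[i + 1]) i + 1L else NA_integer_
      gap_right <- if (!is.na(next_i)) g$start[next_i] - g$end[i] - 1L else 0L
      value <- NA_real_
      partner <- NA_character_
      L <- g$length[i]
      if (op %in% c("merge", "chimera")) {
        if (is.na(next_i)) op <- "keep"
        else {
          partner <- g$id[next_i]
          taken[next_i] <- TRUE
          if (op == "chimera") value <- 0.5
        }
      } else if (op == "shift") {
        f <- stats::runif(1, 0.5, 0.9)
        value <- min(round((1 - f) * L), max(gap_right, 0L))
      } else if (op == "resize_matched") {
        op <- "resize"
        value <- stats::runif(1, 0.45, 0.95)
      } else if (op == "resize_rescued") {
        op <- "resize"
        value <- stats::runif(1, 0.02, 0.25)
      } else if (op == "split") {
        value <- 0.5
      }
      taken[i] <- TRUE
      out[[length(out) + 1]] <- tibble::tibble(
        gene_id = g$id[i], op = op, value = value, partner = partner)
    }
    dplyr::bind_rows(out)
  })
}

#' Apply edit operations to produce a derived target set with ground truth
#'
#' Realizes an edit plan as a target annotation set and computes, *from the
#' edit geometry alone* (never by running the merge pipeline), the gene fate
#' and overlap-graph cardinality the protocol should recover for every base
#' gene. Operations:
#'
#' * `keep` — identical span, new target ID (`1:1`, matched).
#' * `shift` — target shifted right by `value` bp.
#' * `resize` — target keeps the start, length scaled by `value`; coverage
#'   `f = min(1, round(value*L))/L`.
#' * `split` — two target models partitioning the span at fraction `value`
#'   (`1:N`).
#' * `merge` — one target model spanning the gene and its `partner` (`N:1`
#'   for both).
#' * `delete` — no target model (rescued, intergenic).
#' * `move` — target relocated past the end of its seqid (rescued
#'   intergenic; the relocated model becomes target-only).
#' * `invert_region` — target strand-flipped within a window defaulting to
#'   the gene's own span (matched under strand-agnostic overlap; the
#'   same-strand regression case).
#' * `chimera` — one target covering part of the gene plus all of its
#'   `partner`, a second target covering the rest (`N:M` for both genes).
#' * `unmap` — gene absent from the lifted query set (unmapped).
#'
#' @param base Base [annotation_set()] (the simulated query).
#' @param edits Edit tibble (`gene_id`, `op`, `value`, `partner`); genes
#'   without a row are kept.
#' @param cfg [merge_config()] whose thresholds define the expected fates.
#' @param target_label Label/ID prefix for the derived target set.
#' @return A list: `query` (the lifted query set, i.e. `base` minus
#'   unmapped genes), `target`, `unmapped_ids`, and `truth` — a tibble with
#'   `base_gene_id`, `op`, `derived_target_ids` (list), `expected_f`,
#'   `expected_fate`, `expected_cardinality`, `strand_flipped`.
#' @export
apply_edits <- function(base, edits, cfg = merge_config(),
                        target_label = "target") {
  stopifnot(inherits(base, "annotation_set"))
  edits <- tibble::as_tibble(edits)
  if (!all(edits$op %in% edit_ops)) {
    rlang::abort(sprintf("unknown op(s): %s",
                         paste(setdiff(edits$op, edit_ops), collapse = ", ")))
  }
  g <- gene_spans(base)
  missing <- setdiff(c(edits$gene_id, stats::na.omit(edits$partner)), g$id)
  if (length(missing) > 0) {
    rlang::abort(sprintf("edit references unknown gene(s): %s",
                         paste(missing, collapse = ", ")))
  }
  touched <- c(edits$gene_id, stats::na.omit(edits$partner))
  if (anyDuplicated(touched)) {
    rlang::abort(sprintf("conflicting edits on gene(s): %s",
                         paste(unique(touched[duplicated(touched)]),
                               collapse = ", ")))
  }
  edits <- dplyr::bind_rows(
    edits,
    tibble::tibble(gene_id = setdiff(g$id, touched), op = "keep",
                   value = NA_real_, partner = NA_character_))
  g <- g[match(edits$gene_id, g$id), ]
  partner_g <- gene_spans(base)[match(edits$partner, gene_spans(base)$id), ]
  tail_pos <- tapply(gene_spans(base)$end, gene_spans(base)$seqid, max)

  fate_of <- function(f, mapped = TRUE) {
    if (!mapped) return("unmapped")
    if (f >= cfg$f_match) return("matched")
    if (f >= cfg$f_intergenic) return("rescued_overlapping")
    "rescued_intergenic"
  }
  tid <- function(gid, suffix = "") paste0(target_label, ".", gid, suffix)

  target_rows <- list()
  truth <- list()
  unmapped_ids <- character()
  emit_target <- function(id, seqid, s, e, strand) {
    target_rows[[length(target_rows) + 1]] <<-
      gene_model_rows(id, seqid, s, e, strand, target_label)
  }
  emit_truth <- function(gid, op, derived, f, fate, card, flipped = FALSE) {
    truth[[length(truth) + 1]] <<- tibble::tibble(
      base_gene_id = gid, op = op, derived_target_ids = list(derived),
      expected_f = f, expected_fate = fate, expected_cardinality = card,
      strand_flipped = flipped)
  }

  for (i in seq_len(nrow(edits))) {
    op <- edits$op[i]
    gid <- g$id[i]
    s <- g$start[i]; e <- g$end[i]; L <- g$length[i]
    seqid <- g$seqid[i]; strand <- g$strand[i]
    switch(op,
      keep = {
        emit_target(tid(gid), seqid, s, e, strand)
        emit_truth(gid, op, tid(gid), 1, "matched", "1:1")
      },
      shift = {
        d <- as.integer(round(edits$value[i]))
        emit_target(tid(gid), seqid, s + d, e + d, strand)
        ov <- max(0L, L - abs(d))
        f <- ov / L
        emit_truth(gid, op, tid(gid), f, fate_of(f),
                   if (ov >= 1) "1:1" else NA_character_)
      },
      resize = {
        newL <- max(1L, as.integer(round(edits$value[i] * L)))
        emit_target(tid(gid), seqid, s, s + newL - 1L, strand)
        f <- min(L, newL) / L
        emit_truth(gid, op, tid(gid), f, fate_of(f), "1:1")
      },
      split = {
        k <- max(1L, min(L - 1L, as.integer(round(edits$value[i] * L))))
        a <- tid(gid, ".a"); b <- tid(gid, ".b")
        emit_target(a, seqid, s, s + k - 1L, strand)
        emit_target(b, seqid, s + k, e, strand)
        f <- max(k, L - k) / L
        emit_truth(gid, op, c(a, b), f, fate_of(f), "1:N")
      },
      merge = {
        h <- partner_g[i, ]
        id <- tid(gid, ".m")
        emit_target(id, seqid, s, h$end, strand)
        emit_truth(gid, op, id, 1, "matched", "N:1")
        emit_truth(h$id, op, id, 1, "matched", "N:1")
      },
      delete = {
        emit_truth(gid, op, character(), 0, "rescued_intergenic",
                   NA_character_)
      },
      move = {
        dest <- tail_pos[[seqid]] + 10000L
        tail_pos[[seqid]] <- dest + L
        emit_target(tid(gid), seqid, dest, dest + L - 1L, strand)
        emit_truth(gid, op, tid(gid), 0, "rescued_intergenic", NA_character_)
      },
      invert_region = {
        w <- c(s, e)  # window: the gene's own span (strand flip in place)
        flipped <- if (strand == "+") "-" else "+"
        ns <- w[1] + w[2] - e
        ne <- w[1] + w[2] - s
        emit_target(tid(gid), seqid, ns, ne, flipped)
        ov <- max(0L, min(e, ne) - max(s, ns) + 1L)
        f <- ov / L
        emit_truth(gid, op, tid(gid), f, fate_of(f),
                   if (ov >= 1) "1:1" else NA_character_, flipped = TRUE)
      },
      chimera = {
        h <- partner_g[i, ]
        k <- as.integer(round((if (is.na(edits$value[i])) 0.5
                               else edits$value[i]) * L))
        k <- max(1L, min(L - 1L, k))
        a <- tid(gid, ".a"); b <- tid(gid, ".b")
        emit_target(a, seqid, s, s + k - 1L, strand)
        emit_target(b, seqid, s + k, h$end, strand)
        f <- max(k, L - k) / L
        emit_truth(gid, op, c(a, b), f, fate_of(f), "N:M")
        emit_truth(h$id, op, b, 1, "matched", "N:M")
      },
      unmap = {
        unmapped_ids <- c(unmapped_ids, gid)
        emit_truth(gid, op, character(), NA_real_, "unmapped", NA_character_)
      })
  }

  target <- annotation_set(dplyr::bind_rows(target_rows), target_label)
  query <- if (length(unmapped_ids) > 0) {
    keep <- !(base$features$gene_id %in% unmapped_ids)
    new_annotation_set(base$features[keep, ], base$label, base$pragmas)
  } else {
    base
  }
  list(query = query, target = target, unmapped_ids = unmapped_ids,
       truth = dplyr::bind_rows(truth))
}

#' Simulate transcript-evidence intervals with ground truth
#'
#' Places one evidence interval (the middle third of the gene span) inside
#' exactly `floor(supported_fraction * n)` randomly chosen genes.
#'
#' @param aset [annotation_set()] the evidence refers to.
#' @param supported_fraction Fraction of genes to support, in \[0, 1\].
#' @param seed Integer seed.
#' @param ids Optional subset of gene IDs to draw from (default all genes).
#' @return A list: `evidence` (tibble `seqid`, `start`, `end`, `name`;
#'   1-based inclusive, ready for [write_bed()]) and `truth` (tibble
#'   `gene_id`, `supported`).
#' @export
simulate_evidence <- function(aset, supported_fraction, seed = 1L,
                              ids = NULL) {
  stopifnot(supported_fraction >= 0, supported_fraction <= 1)
  g <- gene_spans(aset)
  if (!is.null(ids)) g <- dplyr::filter(g, .data$id %in% ids)
  m <- floor(supported_fraction * nrow(g))
  withr::with_seed(seed, {
    chosen <- if (m > 0) sample(g$id, m) else character()
  })
  sup <- g |> dplyr::filter(.data$id %in% chosen)
  third <- pmax(1L, (sup$end - sup$start + 1L) %/% 3L)
  evidence <- tibble::tibble(
    seqid = sup$seqid,
    start = sup$start + third,
    end = pmin(sup$end, sup$start + 2L * third),
    name = paste0("ev_", sup$id))
  list(evidence = evidence,
       truth = tibble::tibble(gene_id = g$id,
                              supported = g$id %in% chosen))
}

#' Simulate a second query source over the same loci
#'
#' Clones the base set under a new ID namespace and source label, optionally
#' jittering each gene model by up to `jitter` bp, and returns the
#' known-pair table linking the two namespaces — emulating two annotation
#' projects (e.g. one mRNA-level, one CDS-only) that described the same
#' genes.
#'
#' @param base Base [annotation_set()].
#' @param second_label Label / ID prefix for the clone.
#' @param jitter Maximum absolute per-gene coordinate jitter in bp.
#' @param seed Integer seed.
#' @return A list: `aset` (the clone) and `pairs` (tibble `first`,
#'   `second` of gene IDs).
#' @export
simulate_paired_set <- function(base, second_label, jitter = 0L, seed = 1L) {
  f <- base$features
  old_gids <- gene_ids(base)
  rename <- function(x) paste0(second_label, ".", x)
  withr::with_seed(seed, {
    offs <- if (jitter > 0) sample((-jitter):jitter, length(old_gids),
                                   replace = TRUE) else
      rep(0L, length(old_gids))
  })
  off_of <- stats::setNames(offs, old_gids)
  f$start <- unname(pmax(1L, f$start + off_of[f$gene_id]))
  f$end <- unname(f$end + off_of[f$gene_id])
  f$id <- rename(f$id)
  f$gene_id <- rename(f$gene_id)
  f$parents <- lapply(f$parents, rename)
  f$source <- second_label
  list(aset = new_annotation_set(f, second_label),
       pairs = tibble::tibble(first = old_gids, second = rename(old_gids)))
}

#' Combine annotation sets into one
#'
#' Concatenates feature tables (ID namespaces must be disjoint), e.g. to
#' form a combined query from two sources before lifting.
#'
#' @param ... Two or more [annotation_set()] objects.
#' @param label Label for the combined set.
#' @return An [annotation_set()].
#' @export
combine_annotations <- function(..., label = "combined") {
  sets <- list(...)
  feats <- dplyr::bind_rows(lapply(sets, `[[`, "features"))
  if (anyDuplicated(feats$id[feats$ftype == "gene"])) {
    rlang::abort("gene ID namespaces of the combined sets are not disjoint")
  }
  new_annotation_set(feats, label)
}

#' Simulate a calibration fixture with a planted optimal threshold
#'
#' Builds a query set with two sources, a target set, and a reference pair
#' table constructed so the pairs diverge only below a planted threshold
#' `f_star`: concordant pairs sit on identical loci fully covered by one
#' target model (coverage 1), while discordant pairs' two members map to
#' two *different* target models at a coverage just below `f_star` (midway
#' between `f_star` and the next grid value down). Pair concordance is
#' therefore below 1 at every grid value under `f_star` and exactly 1 from
#' the first grid value at or above it, so `max_concordance` selection must
#' recover that grid point.
#'
#' @param f_star Planted optimal threshold (must exceed the smallest grid
#'   value).
#' @param n_pairs Number of reference pairs.
#' @param frac_discordant Fraction of pairs made discordant below `f_star`.
#' @param grid Threshold grid the sweep will use.
#' @param seed Integer seed (gap jitter).
#' @param source_labels Labels of the two query sources.
#' @return A list: `query`, `target`, `pairs`, `f_star`,
#'   `expected_optimum` (the grid point at or immediately above `f_star`).
#' @export
simulate_calibration_truth <- function(f_star, n_pairs = 60,
                                       frac_discordant = 0.4,
                                       grid = default_f_grid(), seed = 1L,
                                       source_labels = c("srcA", "srcB")) {
  grid <- sort(grid)
  below <- grid[grid < f_star]
  if (length(below) == 0) {
    rlang::abort("f_star must exceed the smallest grid value")
  }
  f_disc <- (max(below) + f_star) / 2
  L <- 1000L
  ov <- as.integer(round(f_disc * L))
  n_disc <- round(frac_discordant * n_pairs)
  n_conc <- n_pairs - n_disc

  withr::with_seed(seed, {
    rows_q <- list(); rows_t <- list(); pairs <- list()
    pos <- 0L
    place <- function() {
      gap <- sample(300:800, 1)
      s <- pos + gap + 1L
      pos <<- s + L - 1L
      s
    }
    qrow <- function(id, s, src) {
      tibble::tibble(seqid = "chr1", source = src, type = "gene",
                     start = s, end = s + L - 1L, id = id)
    }
    trow <- function(id, s, e) {
      tibble::tibble(seqid = "chr1", source = "target", type = "gene",
                     start = s, end = e, id = id)
    }
    for (i in seq_len(n_conc)) {
      s <- place()
      a <- sprintf("%s.cp%03d", source_labels[1], i)
      b <- sprintf("%s.cp%03d", source_labels[2], i)
      rows_q[[length(rows_q) + 1]] <- qrow(a, s, source_labels[1])
      rows_q[[length(rows_q) + 1]] <- qrow(b, s, source_labels[2])
      rows_t[[length(rows_t) + 1]] <- trow(sprintf("t.cp%03d", i), s,
                                           s + L - 1L)
      pairs[[length(pairs) + 1]] <- tibble::tibble(first = a, second = b)
    }
    for (i in seq_len(n_disc)) {
      s1 <- place(); s2 <- place()
      a <- sprintf("%s.dp%03d", source_labels[1], i)
      b <- sprintf("%s.dp%03d", source_labels[2], i)
      rows_q[[length(rows_q) + 1]] <- qrow(a, s1, source_labels[1])
      rows_q[[length(rows_q) + 1]] <- qrow(b, s2, source_labels[2])
      rows_t[[length(rows_t) + 1]] <- trow(sprintf("t.d1%03d", i), s1,
                                           s1 + ov - 1L)
      rows_t[[length(rows_t) + 1]] <- trow(sprintf("t.d2%03d", i), s2,
                                           s2 + ov - 1L)
      pairs[[length(pairs) + 1]] <- tibble::tibble(first = a, second = b)
    }
  })
  list(query = annotation_set(dplyr::bind_rows(rows_q), "calib-query"),
       target = annotation_set(dplyr::bind_rows(rows_t), "calib-target"),
       pairs = dplyr::bind_rows(pairs),
       f_star = f_star,
       expected_optimum = min(grid[grid >= f_star]))
}
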