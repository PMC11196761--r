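# two-variant toy scenario: gene "a" covered 0.80 by the plain lift and
# 0.95 by the padded lift; gene "b" present only in the plain lift.
two_variant_fixture <- function() {
  v0 <- toy_set(data.frame(id = c("a", "b"), seqid = "chr1",
                           start = c(100L, 1000L), end = c(199L, 1099L)),
                label = "flank0")
  v500 <- toy_set(data.frame(id = "a", seqid = "chr1",
                             start = 100L, end = 199L), label = "flank500")
  target <- toy_set(data.frame(id = c("x", "y"), seqid = "chr1",
                               start = c(120L, 1000L), end = c(214L, 1099L)),
                    label = "t")
  # v0: a vs x overlap 80 -> f 0.80 ; v500 shifts a's span to cover 95
  v500$features$start[1] <- 120L
  v500$features$end[1] <- 219L
  list(v0 = lift_variant("flank0", v0),
       v500 = lift_variant("flank500", v500),
       target = target)
}

test_that("the variant with the better per-gene coverage wins; single-variant genes keep theirs", {
  fx <- two_variant_fixture()
  sel <- select_best_variant(list(fx$v0, fx$v500), fx$target)
  g <- sel$genes
  expect_equal(g$chosen_variant[g$query_id == "a"], "flank500")
  expect_equal(g$best_f[g$query_id == "a"], 0.95)
  expect_equal(g$chosen_variant[g$query_id == "b"], "flank0")
  expect_equal(g$best_f[g$query_id == "b"], 1.0)
})

test_that("coverage ties break by variant preference order", {
  v1 <- lift_variant("flank0", toy_set(
    data.frame(id = "a", seqid = "chr1", start = 1L, end = 100L), "flank0"))
  v2 <- lift_variant("flank500", toy_set(
    data.frame(id = "a", seqid = "chr1", start = 1L, end = 100L), "flank500"))
  target <- toy_set(data.frame(id = "x", seqid = "chr1",
                               start = 1L, end = 100L))
  sel <- select_best_variant(list(v1, v2), target)
  expect_equal(sel$genes$chosen_variant, "flank0")
  pref <- merge_config(variant_preference = c("flank500", "flank0"))
  sel2 <- select_best_variant(list(v1, v2), target, pref)
  expect_equal(sel2$genes$chosen_variant, "flank500")
  expect_error(select_best_variant(list(v1, v1), target), "duplicate")
})

test_that("fate boundaries follow the matched and intergenic thresholds exactly", {
  spans <- data.frame(
    id = c("hi", "low", "zero"), seqid = "chr1",
    start = c(100L, 1000L, 5000L), end = c(199L, 1999L, 5999L))
  target <- toy_set(data.frame(
    id = c("t1", "t2"), seqid = "chr1",
    start = c(100L, 1990L), end = c(134L, 1999L)))
  # hi: 35/100 = 0.35 ; low: 10/1000 = 0.01 ; zero: no overlap
  variant <- lift_variant("lift0", toy_set(spans, "q"),
                          unmapped_ids = "gone")
  fates <- classify_genes(select_best_variant(variant, target))
  fate_of <- function(id) fates$category[fates$query_id == id]
  expect_equal(fate_of("hi"), "matched")
  expect_equal(fate_of("low"), "rescued_overlapping")
  expect_equal(fate_of("zero"), "rescued_intergenic")
  expect_equal(fate_of("gone"), "unmapped")
  expect_true(is.na(fates$chosen_variant[fates$query_id == "gone"]))
  # boundary: exactly f_match is matched, exactly f_intergenic is overlapping
  expect_equal(merge_config()$f_match, 0.30)
  expect_equal(merge_config()$f_intergenic, 1e-4)
  expect_error(merge_config(f_match = 0.3, f_intergenic = 0.3), "f_intergenic")
})

test_that("every query gene gets exactly one fate and categories sum to the universe", {
  base <- simulate_annotation(150, 3, seed = 71)
  fx <- apply_edits(base, sample_edits(base, seed = 72))
  sel <- select_best_variant(lift_variant("lift0", fx$query, fx$unmapped_ids),
                             fx$target)
  fates <- classify_genes(sel)
  expect_equal(anyDuplicated(fates$query_id), 0)
  expect_setequal(fates$query_id, gene_ids(base))
  expect_equal(sum(table(fates$category)), length(gene_ids(base)))
})

test_that("merged set equals target plus rescued genes with provenance attributes", {
  base <- simulate_annotation(100, 2, seed = 81)
  fx <- apply_edits(base, sample_edits(base, seed = 82))
  variant <- lift_variant("lift0", fx$query, fx$unmapped_ids)
  sel <- select_best_variant(variant, fx$target)
  fates <- classify_genes(sel)
  unified <- merge_annotations(fates, variant, fx$target)
  n_rescued <- sum(fates$category %in%
                     c("rescued_overlapping", "rescued_intergenic"))
  expect_equal(unified$counts$n_unified,
               length(gene_ids(fx$target)) + n_rescued)
  # matched queries are not added; rescued keep their query IDs
  uids <- gene_ids(unified$aset)
  matched_ids <- fates$query_id[fates$category == "matched"]
  expect_length(intersect(uids, matched_ids), 0)
  rescued_ids <- fates$query_id[fates$category %in%
                                  c("rescued_overlapping", "rescued_intergenic")]
  expect_true(all(rescued_ids %in% uids))
  genes <- unified$aset$features[unified$aset$features$ftype == "gene", ]
  origins <- vapply(genes$attributes, function(a) a[["merge_origin"]],
                    character(1))
  expect_false(anyNA(origins))
  cats <- vapply(genes$attributes[genes$id %in% rescued_ids],
                 function(a) a[["merge_category"]], character(1))
  expect_setequal(unique(cats),
                  unique(fates$category[fates$query_id %in% rescued_ids]))
})

test_that("merging with zero rescued genes reproduces the target set", {
  base <- simulate_annotation(20, 1, seed = 91)
  fx <- apply_edits(base, tibble::tibble(gene_id = character(),
                                         op = character(), value = double(),
                                         partner = character()))
  variant <- lift_variant("lift0", fx$query)
  fates <- classify_genes(select_best_variant(variant, fx$target))
  expect_true(all(fates$category == "matched"))
  unified <- merge_annotations(fates, variant, fx$target)
  expect_setequal(gene_ids(unified$aset), gene_ids(fx$target))
})

test_that("remerging the unified set against the same target rescues nothing new", {
  base <- simulate_annotation(80, 2, seed = 95)
  fx <- apply_edits(base, sample_edits(base, seed = 96))
  variant <- lift_variant("lift0", fx$query, fx$unmapped_ids)
  fates <- classify_genes(select_best_variant(variant, fx$target))
  unified <- merge_annotations(fates, variant, fx$target)
  # second pass: the unified set lifted "as is" against the same target
  v2 <- lift_variant("lift0", unified$aset)
  fates2 <- classify_genes(select_best_variant(v2, fx$target))
  rescued1 <- sort(fates$query_id[fates$category %in%
                                    c("rescued_overlapping", "rescued_intergenic")])
  rescued2 <- sort(fates2$query_id[fates2$category %in%
                                     c("rescued_overlapping", "rescued_intergenic")])
  expect_equal(rescued2, rescued1)
})

test_that("rescued/target ID collisions abort the merge", {
  q <- toy_set(data.frame(id = "dup", seqid = "chr1",
                          start = 100L, end = 200L), "q")
  target <- toy_set(data.frame(id = "dup", seqid = "chr1",
                               start = 5000L, end = 5100L), "t")
  variant <- lift_variant("lift0", q)
  fates <- classify_genes(select_best_variant(variant, target))
  expect_equal(fates$category, "rescued_intergenic")
  expect_error(merge_annotations(fates, variant, target), "collide")
})

test_that("known rescued pairs at one locus collapse to a single unified gene", {
  # two query sources annotate the same deleted locus
  q <- toy_set(data.frame(id = c("pgsc.1", "itag.1"), seqid = "chr1",
                          start = c(100L, 120L), end = c(500L, 480L)), "q")
  q$features$source <- c("pgsc", "itag")
  target <- toy_set(data.frame(id = "t1", seqid = "chr1",
                               start = 10000L, end = 10500L), "t")
  variant <- lift_variant("lift0", q)
  fates <- classify_genes(select_best_variant(variant, target))
  pairs <- tibble::tibble(first = "pgsc.1", second = "itag.1")
  unified <- merge_annotations(fates, variant, target, known_pairs = pairs)
  expect_equal(unified$counts$n_collapsed, 1)
  expect_equal(unified$counts$n_unified, 2)  # t1 + collapsed pair
  expect_true("pgsc.1" %in% gene_ids(unified$aset))
  expect_false("itag.1" %in% gene_ids(unified$aset))
  gene <- unified$aset$features[unified$aset$features$id == "pgsc.1", ]
  expect_equal(gene$attributes[[1]][["merge_collapsed_with"]], "itag.1")
  # and the translation table carries both IDs on one row
  tab <- build_translation_table(fates, target, known_pairs = pairs,
                                 collapsed = unified$collapsed)
  row <- tab[!is.na(tab$pgsc) & tab$pgsc == "pgsc.1", ]
  expect_equal(nrow(row), 1)
  expect_equal(row$itag, "itag.1")
  expect_equal(row$unified_id, "pgsc.1")
})

test_that("translation table has one row per unified gene with target-only rows", {
  base <- simulate_annotation(90, 2, seed = 101)
  fx <- apply_edits(base, sample_edits(base, seed = 102))
  variant <- lift_variant("lift0", fx$query, fx$unmapped_ids)
  fates <- classify_genes(select_best_variant(variant, fx$target))
  unified <- merge_annotations(fates, variant, fx$target)
  tab <- build_translation_table(fates, fx$target,
                                 collapsed = unified$collapsed)
  # every unified gene appears exactly once as unified_id; unmapped rows
  # are retained with an empty unified_id
  expect_setequal(stats::na.omit(tab$unified_id), gene_ids(unified$aset))
  expect_equal(sum(is.na(tab$unified_id)),
               sum(fates$category == "unmapped"))
  expect_equal(nrow(tab),
               unified$counts$n_unified + sum(fates$category == "unmapped"))
  # target-only rows are targets hit by no matched query
  to <- tab$target_id[tab$category == "target_only"]
  recs <- attr(fates, "records")
  hit <- unique(recs$target_id[recs$f_query >= 0.30])
  expect_length(intersect(to, hit), 0)
})

test_that("two matched sources sharing a target collapse onto one translation row", {
  q <- toy_set(data.frame(id = c("pgsc.g", "itag.s"), seqid = "chr1",
                          start = c(100L, 110L), end = c(500L, 490L)), "q")
  q$features$source <- c("pgsc", "itag")
  target <- toy_set(data.frame(id = "t1", seqid = "chr1",
                               start = 100L, end = 500L), "t")
  variant <- lift_variant("lift0", q)
  fates <- classify_genes(select_best_variant(variant, target))
  tab <- build_translation_table(fates, target,
                                 known_pairs = tibble::tibble(
                                   first = "pgsc.g", second = "itag.s"))
  expect_equal(nrow(tab), 1)
  expect_equal(tab$pgsc, "pgsc.g")
  expect_equal(tab$itag, "itag.s")
  expect_equal(tab$target_id, "t1")
  expect_equal(tab$unified_id, "t1")
  expect_equal(tab$category, "matched")
})

test_that("a query matching two targets above threshold appears on both rows", {
  q <- toy_set(data.frame(id = "a", seqid = "chr1",
                          start = 100L, end = 299L), "q")
  target <- toy_set(data.frame(id = c("x", "y"), seqid = "chr1",
                               start = c(100L, 200L), end = c(199L, 299L)))
  fates <- classify_genes(select_best_variant(lift_variant("l0", q), target))
  expect_equal(fates$category, "matched")
  tab <- build_translation_table(fates, target)
  expect_equal(nrow(tab), 2)
  expect_true(all(tab$category == "matched"))
  expect_true(all(tab$q == "a"))
})

test_that("evidence intervals flag exactly the genes they fall in", {
  base <- simulate_annotation(50, 2, seed = 111)
  fx <- apply_edits(base, sample_edits(base, seed = 112))
  variant <- lift_variant("lift0", fx$query, fx$unmapped_ids)
  fates <- classify_genes(select_best_variant(variant, fx$target))
  unified <- merge_annotations(fates, variant, fx$target)
  # no evidence: everything unsupported
  none <- evidence_support(fates, unified,
                           tibble::tibble(seqid = character(),
                                          start = integer(), end = integer()))
  expect_false(any(none$supported))
  # an interval inside one intergenic rescued gene supports it alone
  # (an overlapping rescue's locus is shared with a target model, so an
  # intergenic rescue is the unambiguous case)
  rescued_ids <- fates$query_id[fates$category %in%
                                  c("rescued_overlapping", "rescued_intergenic")]
  lone <- fates$query_id[fates$category == "rescued_intergenic" &
                           fates$best_f == 0]
  expect_gt(length(lone), 0)
  g <- gene_spans(unified$aset)
  pick <- g[g$id == lone[1], ]
  ev <- tibble::tibble(seqid = pick$seqid,
                       start = pick$start + 2L, end = pick$start + 10L)
  sup <- evidence_support(fates, unified, ev)
  expect_true(sup$supported[sup$gene_id == pick$id])
  expect_equal(sum(sup$supported), 1)
  expect_equal(unique(sup$category[sup$gene_id %in% rescued_ids]),
               unique(fates$category[fates$query_id %in% rescued_ids]))
})

test_that("raising the match threshold only shrinks the matched set (nested)", {
  base <- simulate_annotation(120, 2, seed = 121)
  fx <- apply_edits(base, sample_edits(base, seed = 122))
  sel <- select_best_variant(lift_variant("lift0", fx$query, fx$unmapped_ids),
                             fx$target)
  prev <- NULL
  for (fm in c(0.1, 0.3, 0.6, 0.9)) {
    cfg <- merge_config(f_match = fm)
    fates <- classify_genes(sel, cfg)
    cur <- sort(fates$query_id[fates$category == "matched"])
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
})
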