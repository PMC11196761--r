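test_that("a minimal gene/mRNA/exon hierarchy parses into one gene model", {
  p <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t100\t500\t.\t+\t.\tID=g1;Name=demo",
    "chr1\tsrc\tmRNA\t100\t500\t.\t+\t.\tID=g1.t1;Parent=g1",
    "chr1\tsrc\texon\t100\t500\t.\t+\t.\tID=g1.e1;Parent=g1.t1"), p)
  a <- parse_gff3(p)
  expect_equal(gene_ids(a), "g1")
  expect_equal(nrow(a$features), 3)
  expect_equal(a$features$gene_id, rep("g1", 3))
  expect_equal(a$features$attributes[[1]][["Name"]], "demo")
})

test_that("CDS-only hierarchies attach CDS rows directly to the gene", {
  p <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "chr1\titag\tgene\t100\t900\t.\t-\t.\tID=s1",
    "chr1\titag\tCDS\t100\t400\t.\t-\t0\tID=s1.c1;Parent=s1",
    "chr1\titag\tCDS\t600\t900\t.\t-\t2\tID=s1.c2;Parent=s1"), p)
  a <- parse_gff3(p)
  expect_equal(gene_ids(a), "s1")
  expect_equal(sum(a$features$type == "CDS"), 2)
  expect_equal(unique(a$features$gene_id), "s1")
  # no mRNA level is fabricated
  expect_false("mRNA" %in% a$features$type)
})

test_that("malformed coordinates and duplicate gene IDs abort with line numbers", {
  p <- withr::local_tempfile(fileext = ".gff3")
  writeLines("chr1\ts\tgene\t500\t100\t.\t+\t.\tID=g1", p)
  expect_error(parse_gff3(p), "line 1.*invalid interval")
  writeLines("chr1\ts\tgene\t1a0\t200\t.\t+\t.\tID=g1", p)
  expect_error(parse_gff3(p), "non-integer")
  writeLines(c("chr1\ts\tgene\t1\t10\t.\t+\t.\tID=g1",
               "chr1\ts\tgene\t50\t80\t.\t+\t.\tID=g1"), p)
  expect_error(parse_gff3(p), "duplicate gene ID 'g1' \\(lines 1 and 2\\)")
  writeLines("chr1\ts\tgene\t1\t10\t.\t+", p)
  expect_error(parse_gff3(p), "expected 9")
})

test_that("features without a gene ancestor are wrapped in a flagged synthetic gene", {
  p <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "chr1\ts\tmRNA\t100\t400\t.\t+\t.\tID=t1",
    "chr1\ts\texon\t100\t400\t.\t+\t.\tID=t1.e1;Parent=t1"), p)
  a <- parse_gff3(p)
  g <- gene_spans(a)
  expect_equal(nrow(g), 1)
  expect_equal(g$start, 100L)
  expect_equal(g$end, 400L)
  gene_row <- a$features[a$features$ftype == "gene", ]
  expect_equal(gene_row$attributes[[1]][["synthetic"]], "true")
  # nothing dropped: both original features now belong to the wrapper
  expect_equal(sum(a$features$gene_id == gene_row$id), 3)
})

test_that("reserved characters in attributes survive a write/parse round trip", {
  a <- annotation_set(tibble::tibble(
    seqid = "chr1", type = "gene", start = 10L, end = 99L, id = "g1",
    attributes = list(c(ID = "g1", Note = "a;b=c,d%e&f"))), "enc")
  p <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(a, p)
  line <- grep("gene", readLines(p), value = TRUE)
  expect_match(line, "Note=a%3Bb%3Dc%2Cd%25e%26f", fixed = TRUE)
  b <- parse_gff3(p, label = "enc")
  expect_equal(b$features$attributes[[1]][["Note"]], "a;b=c,d%e&f")
})

test_that("parse -> write -> parse is the identity on generated fixtures", {
  for (seed in c(2, 9)) {
    base <- simulate_annotation(40, 3, seed = seed,
                                cds_only = (seed == 9))
    p1 <- withr::local_tempfile(fileext = ".gff3")
    p2 <- withr::local_tempfile(fileext = ".gff3")
    write_gff3(base, p1)
    a1 <- parse_gff3(p1, label = base$label)
    write_gff3(a1, p2)
    expect_identical(readLines(p1), readLines(p2))
    expect_same_annotation(a1, parse_gff3(p2, label = base$label))
  }
})

test_that("writing an empty set emits only the version pragma", {
  p <- withr::local_tempfile(fileext = ".gff3")
  a <- parse_gff3({ writeLines("##gff-version 3", p); p })
  write_gff3(a, p)
  expect_equal(readLines(p), "##gff-version 3")
})

test_that("output is positionally sorted with children after parents", {
  # genes inserted out of order, chr10 vs chr2 exercising natural order
  f <- tibble::tibble(
    seqid = c("chr10", "chr2", "chr2", "chr2"),
    type = c("gene", "gene", "mRNA", "gene"),
    start = c(100L, 500L, 500L, 100L),
    end = c(200L, 900L, 900L, 300L),
    id = c("gB", "gC", "gC.t1", "gA"),
    parents = list(character(), character(), "gC", character()))
  a <- annotation_set(f, "sort")
  out <- sort_topological(a)
  expect_equal(out$id, c("gA", "gC", "gC.t1", "gB"))
  # lexicographic mode puts chr10 first
  lex <- sort_topological(a, natural_seqids = FALSE)
  expect_equal(lex$id[1], "gB")
})

test_that("genes with equal start order by end then ID; sort is permutation-invariant", {
  base <- simulate_annotation(50, 2, seed = 5)
  ref <- sort_topological(base)$id
  withr::with_seed(11, {
    for (k in 1:10) {
      perm <- sample(nrow(base$features))
      shuffled <- base
      shuffled$features <- base$features[perm, ]
      expect_equal(sort_topological(shuffled)$id, ref)
    }
  })
  tie <- toy_set(data.frame(id = c("long", "short"), seqid = "chr1",
                            start = 100L, end = c(900L, 300L)))
  expect_equal(sort_topological(tie)$id, c("short", "long"))
})

test_that("every feature is either emitted or reported, never dropped", {
  base <- simulate_annotation(30, 2, seed = 7)
  expect_equal(nrow(sort_topological(base)), nrow(base$features))
  # an unreachable feature (bogus parent chain) is reported by id
  f <- base$features
  f$parents[[2]] <- "no-such-feature"
  f$gene_id[2] <- NA_character_
  broken <- liftmerge:::new_annotation_set(f, "broken")
  expect_error(sort_topological(broken), f$id[2])
})

test_that("validation reports child-outside-gene and span mismatches without fixing them", {
  f <- tibble::tibble(
    seqid = "chr1", type = c("gene", "mRNA"),
    start = c(100L, 50L), end = c(500L, 400L),
    id = c("g1", "g1.t1"), parents = list(character(), "g1"))
  a <- annotation_set(f, "v")
  issues <- validate_annotation(a)
  expect_setequal(issues$issue, c("child_outside_gene_span",
                                  "gene_span_mismatch"))
  # the features themselves are untouched
  expect_equal(a$features$start, c(100L, 50L))
  expect_equal(nrow(validate_annotation(simulate_annotation(20, 1, seed = 1))), 0)
})

test_that("BED intervals convert from 0-based half-open to 1-based inclusive", {
  p <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t99\t200\tev1", p)
  b <- read_bed(p)
  expect_equal(b$start, 100L)
  expect_equal(b$end, 200L)
  write_bed(b, p)
  expect_equal(readLines(p), "chr1\t99\t200\tev1")
  writeLines("chr1\txx\t200", p)
  expect_error(read_bed(p), "line 1")
})

test_that("coordinate and ID parsing agrees with an independent GFF3 reader", {
  base <- simulate_annotation(25, 2, seed = 13)
  p <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(base, p)
  ref <- rtracklayer::import.gff3(p)
  ref_genes <- ref[ref$type == "gene"]
  ours <- gene_spans(parse_gff3(p))
  ord <- match(ours$id, ref_genes$ID)
  expect_false(anyNA(ord))
  expect_equal(ours$start, GenomicRanges::start(ref_genes)[ord])
  expect_equal(ours$end, GenomicRanges::end(ref_genes)[ord])
})
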