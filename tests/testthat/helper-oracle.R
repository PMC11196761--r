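# Independent brute-force all-pairs overlap scan: enumerates every
# (query gene, target gene) combination per seqid and keeps pairs sharing
# >= min_bp. Kept deliberately separate from the package's indexed path.
oracle_intersect <- function(query, target, min_bp = 1, same_strand = FALSE) {
  q <- gene_spans(query)
  t <- gene_spans(target)
  out <- list()
  for (sq in intersect(unique(q$seqid), unique(t$seqid))) {
    qi <- which(q$seqid == sq)
    ti <- which(t$seqid == sq)
    grid <- expand.grid(i = qi, j = ti)
    ov <- pmin(q$end[grid$i], t$end[grid$j]) -
      pmax(q$start[grid$i], t$start[grid$j]) + 1L
    keep <- ov >= min_bp
    if (same_strand) {
      keep <- keep & q$strand[grid$i] == t$strand[grid$j] &
        q$strand[grid$i] %in% c("+", "-")
    }
    if (!any(keep)) next
    i <- grid$i[keep]; j <- grid$j[keep]
    out[[length(out) + 1]] <- data.frame(
      query_id = q$id[i], target_id = t$id[j],
      overlap_bp = ov[keep],
      f_query = ov[keep] / q$length[i],
      f_target = ov[keep] / t$length[j],
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0) {
    return(data.frame(query_id = character(), target_id = character(),
                      overlap_bp = integer(), f_query = double(),
                      f_target = double()))
  }
  res <- do.call(rbind, out)
  res[order(res$query_id, res$target_id), , drop = FALSE]
}

# Canonical feature representation for set-equality checks: positional
# sort, synthetic ids of ID-less features blanked, attribute maps sorted
# by key with ID/Parent represented through the id/parents columns.
canonical_features <- function(aset) {
  f <- aset$features
  f$id[!f$has_id] <- NA_character_
  f$parents <- lapply(f$parents, sort)
  f$attributes <- lapply(f$attributes, function(a) {
    a <- a[!names(a) %in% c("ID", "Parent")]
    a[order(names(a))]
  })
  f <- f[order(f$seqid, f$start, f$end, f$type, f$id, method = "radix"), ]
  f$line <- NULL
  tibble::as_tibble(f[, c("seqid", "source", "type", "start", "end",
                          "score", "strand", "phase", "id", "parents",
                          "attributes", "gene_id")])
}

expect_same_annotation <- function(a, b) {
  expect_equal(canonical_features(a), canonical_features(b))
}

# Small hand-built annotation set: gene spans given as a data frame with
# id, seqid, start, end (strand optional).
toy_set <- function(spans, label = "toy") {
  spans <- tibble::as_tibble(spans)
  if (!"strand" %in% names(spans)) spans$strand <- "+"
  annotation_set(
    tibble::tibble(seqid = spans$seqid, type = "gene", start = spans$start,
                   end = spans$end, strand = spans$strand, id = spans$id),
    label)
}

# Per-query-gene component cardinality lookup from overlap_components().
component_cardinality <- function(comps) {
  if (nrow(comps) == 0) {
    return(tibble::tibble(query_id = character(), cardinality = character()))
  }
  comps |>
    dplyr::select("cardinality", "query_ids") |>
    tidyr::unnest(cols = "query_ids") |>
    dplyr::rename(query_id = "query_ids") |>
    dplyr::distinct()
}
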