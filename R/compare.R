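# Partition comparison and ground-truth evaluation of assemblies.

as_partition_map <- function(p) {
  if (is.data.frame(p)) {
    p <- as.data.table(p)
    if (!"cluster_id" %in% names(p) && "contig_id" %in% names(p))
      setnames(p, "contig_id", "cluster_id")
    return(setNames(as.character(p$cluster_id), p$clone_id))
  }
  setNames(as.character(p), names(p))
}

#' Rand index of two clone partitions
#'
#' Fraction of clone pairs on which the two partitions agree (both together
#' or both apart), computed over the clones present in both.
#'
#' @param p1,p2 partitions: named vectors (clone -> cluster) or data.frames
#'   with `clone_id` and `cluster_id`.
#' @return Rand index in `[0, 1]`.
#' @export
rand_index <- function(p1, p2) {
  m1 <- as_partition_map(p1); m2 <- as_partition_map(p2)
  shared <- intersect(names(m1), names(m2))
  n <- length(shared)
  if (n < 2L) stop("need at least 2 shared clones")
  a <- m1[shared]; b <- m2[shared]
  tab <- table(a, b)
  ch2 <- function(x) sum(x * (x - 1) / 2)
  npairs <- n * (n - 1) / 2
  s_ab <- ch2(tab)
  s_a <- ch2(rowSums(tab)); s_b <- ch2(colSums(tab))
  (npairs + 2 * s_ab - s_a - s_b) / npairs
}

#' Mean cluster overlap between partitions
#'
#' For each cluster of `p1` (of at least `min_cluster` clones on the shared
#' set), the number of distinct `p2` clusters it intersects; the mean over
#' clusters. Near 1 when the partitions are similar; `min_cluster > 1`
#' suppresses the influence of small clusters and singletons.
#'
#' @param p1,p2 partitions as in [rand_index()].
#' @param min_cluster smallest `p1` cluster counted.
#' @export
mean_overlap <- function(p1, p2, min_cluster = 1L) {
  m1 <- as_partition_map(p1); m2 <- as_partition_map(p2)
  shared <- intersect(names(m1), names(m2))
  dt <- data.table(clone = shared, a = m1[shared], b = m2[shared])
  sz <- dt[, .N, by = a]
  keep <- sz[N >= min_cluster, a]
  if (!length(keep)) return(NA_real_)
  dt[a %in% keep, uniqueN(b), by = a][, mean(V1)]
}

# overlap fraction of two intervals relative to the shorter one
interval_overlap_frac <- function(s1, e1, s2, e2) {
  ov <- pmax(0, pmin(e1, e2) - pmax(s1, s2))
  ov / pmin(e1 - s1, e2 - s2)
}

#' Evaluate an assembly against simulator ground truth
#'
#' Per contig (cluster with at least `min_size` clones): the clones' true
#' genomic parts are merged into groups, joining intervals that overlap or
#' lie within one mean clone length of each other; a contig is chimeric
#' when it spans more than one group ("mixes distant genomic regions"). A
#' supplied order is wrong when neither it nor its reversal is monotone in
#' true midpoint coordinate, ignoring conflicts between clones whose true
#' intervals overlap by more than 80% (fingerprints cannot resolve such
#' near-identical clones). Reported statistics mirror the simulated-library
#' benchmark: contig counts, chimeric contigs, parts per contig, wrongly
#' ordered contigs, chimera exclusion, clone coverage by contigs, mean
#' clones and kbp per contig.
#'
#' @param partition data.table (`clone_id`, `cluster_id`; extra columns
#'   ignored) or named vector.
#' @param orders optional named list of `contig_order`/id vectors keyed by
#'   cluster id.
#' @param lib a `sim_library` (ground truth source).
#' @param min_size clusters at least this large count as contigs.
#' @return list of class `truth_evaluation`.
#' @export
evaluate_vs_truth <- function(partition, orders = NULL, lib,
                              min_size = 6L) {
  if (is.null(lib$truth)) stop("library lacks ground truth")
  map <- as_partition_map(partition)
  map <- map[!is.na(map)]
  tr <- lib$truth
  retained <- tr[dropped == FALSE, unique(clone_id)]
  mean_len <- tr[dropped == FALSE, mean(end - start)]
  sz <- table(map)
  contig_ids <- names(sz)[sz >= min_size]
  per <- list()
  # a clone's genomic location is its longest part: an included chimera
  # with a short stray part does not by itself make the contig chimeric
  # (mixing regions means the clones' primary locations mix)
  primary <- tr[order(-(end - start)), .SD[1L], by = clone_id]
  for (cid in contig_ids) {
    ids <- names(map)[map == cid]
    iv <- primary[clone_id %in% ids, .(clone_id, start, end)]
    setorder(iv, start)
    # group intervals: new group when gap to running max end > mean_len
    grp <- integer(nrow(iv)); cur <- 1L; maxend <- iv$end[1]
    for (r in seq_len(nrow(iv))) {
      if (iv$start[r] > maxend + mean_len) { cur <- cur + 1L
        maxend <- iv$end[r] }
      grp[r] <- cur
      maxend <- max(maxend, iv$end[r])
    }
    n_parts <- cur
    chimeric <- n_parts > 1L
    span <- sum(tapply(iv$end, grp, max) - tapply(iv$start, grp, min))
    order_wrong <- NA
    if (!is.null(orders) && cid %in% names(orders) && !chimeric) {
      ids_ord <- orders[[cid]]
      if (inherits(ids_ord, "contig_order")) ids_ord <- ids_ord$order
      main <- primary[clone_id %in% ids_ord,
                      .(start = start[1], end = end[1],
                        mid = (start[1] + end[1]) / 2), by = clone_id]
      main <- main[match(ids_ord, clone_id)][!is.na(clone_id)]
      order_wrong <- order_violations(main) > 0L &&
        order_violations(main[rev(seq_len(nrow(main)))]) > 0L
    }
    per[[cid]] <- data.table(contig_id = cid, n_clones = length(ids),
                             n_parts = n_parts, chimeric = chimeric,
                             span_kbp = span / 1e3,
                             order_wrong = order_wrong)
  }
  per <- rbindlist(per)
  chim_clones <- tr[chimeric == TRUE & !dropped, unique(clone_id)]
  in_contigs <- names(map)[map %in% contig_ids]
  res <- list(
    per_contig = per,
    n_contigs = nrow(per),
    n_chimeric_contigs = sum(per$chimeric),
    mean_parts = if (nrow(per)) mean(per$n_parts) else NA_real_,
    n_order_checked = sum(!is.na(per$order_wrong)),
    n_order_wrong = sum(per$order_wrong, na.rm = TRUE),
    frac_clones_in_contigs = length(intersect(in_contigs, retained)) /
      length(retained),
    n_chimeric_retained = length(chim_clones),
    frac_chimeric_in_contigs = if (length(chim_clones))
      length(intersect(chim_clones, in_contigs)) / length(chim_clones)
      else NA_real_,
    mean_clones_per_contig = if (nrow(per)) mean(per$n_clones) else NA_real_,
    mean_span_kbp = if (nrow(per)) mean(per$span_kbp) else NA_real_)
  class(res) <- "truth_evaluation"
  res
}

# count order conflicts in a sequence of true intervals: pairs appearing in
# ascending contig order whose midpoints are decreasing, unless the two
# intervals overlap by more than 80% of the shorter
order_violations <- function(main) {
  n <- nrow(main)
  if (n < 3L) return(0L)
  bad <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      if (main$mid[j] < main$mid[i]) {
        f <- interval_overlap_frac(main$start[i], main$end[i],
                                   main$start[j], main$end[j])
        if (f <= 0.8) bad <- bad + 1L
      }
    }
  }
  bad
}

#' @export
print.truth_evaluation <- function(x, ...) {
  cat(sprintf(paste0("truth_evaluation: %d contigs, %d chimeric, ",
                     "parts/contig %.2f, order wrong %d/%d, ",
                     "clones in contigs %.1f%%, chimeras in contigs %s\n"),
              x$n_contigs, x$n_chimeric_contigs, x$mean_parts,
              x$n_order_wrong, x$n_order_checked,
              100 * x$frac_clones_in_contigs,
              ifelse(is.na(x$frac_chimeric_in_contigs), "NA",
                     sprintf("%.1f%%", 100 * x$frac_chimeric_in_contigs))))
  invisible(x)
}
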