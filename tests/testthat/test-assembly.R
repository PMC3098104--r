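test_that("select_mtp walks the diametric route between terminal clones", {
  # chain contig: every clone is in the MTP
  chain <- edge_graph(data.frame(a = letters[1:4], b = letters[2:5]))
  igraph::E(chain)$weight <- rep(20, 4)
  mtp <- select_mtp(chain, letters[1:5])
  expect_equal(mtp$clones, letters[1:5])
  expect_equal(length(mtp$log10p), 4L)

  # 5-clique: only the two terminals
  cl5 <- igraph::make_full_graph(5)
  igraph::V(cl5)$name <- paste0("q", 1:5)
  igraph::E(cl5)$weight <- 30
  mtp2 <- select_mtp(cl5, c("q2", "q1", "q3", "q5", "q4"))
  expect_equal(mtp2$clones, c("q2", "q4"))

  # random connected graphs: |MTP| - 1 equals the BFS shortest distance
  set.seed(17)
  for (rep in 1:10) {
    n <- sample(6:12, 1)
    repeat {
      el <- unique(t(replicate(2 * n, sort(sample(paste0("v", 1:n), 2)))))
      g <- edge_graph(data.frame(a = el[, 1], b = el[, 2]),
                      vertices = paste0("v", 1:n))
      if (igraph::components(g)$no == 1) break
    }
    igraph::E(g)$weight <- runif(igraph::ecount(g), 10, 50)
    ends <- sample(paste0("v", 1:n), 2)
    mtp <- select_mtp(g, c(ends[1], ends[2]))
    d <- igraph::distances(g, ends[1], ends[2], weights = NA)[1, 1]
    expect_equal(length(mtp$clones) - 1, unname(d))
  }

  # disconnected terminals: error
  dis <- edge_graph(data.frame(a = c("a", "c"), b = c("b", "d")))
  expect_error(select_mtp(dis, c("a", "d")), "disconnected")
})

test_that("select_mtp is minimal: no proper subchain is significant", {
  ov <- small_overlaps()
  part <- single_linkage(ov, 1e-12)
  big <- part[, .N, by = cluster_id][order(-N)][1, cluster_id]
  ids <- part[cluster_id == big, clone_id]
  og <- build_graph(ov, 1e-12, clones = ids)
  d <- tsp_distances(ids, ov, 1e-12)
  co <- order_clones(ids, d, seed = 5, restarts = 5)
  mtp <- select_mtp(og, co)
  expect_equal(mtp$clones[1], co$order[1])
  expect_equal(mtp$clones[length(mtp$clones)], co$order[length(co$order)])
  # adjacency significance along the MTP
  sig <- ov[significant == TRUE, paste(pmin(c1, c2), pmax(c1, c2))]
  adj <- paste(pmin(mtp$clones[-length(mtp$clones)], mtp$clones[-1]),
               pmax(mtp$clones[-length(mtp$clones)], mtp$clones[-1]))
  expect_true(all(adj %in% sig))
  # minimality: skipping any interior clone breaks the chain somewhere
  if (length(mtp$clones) > 2 && length(mtp$clones) <= 12) {
    for (drop in seq(2, length(mtp$clones) - 1)) {
      sub <- mtp$clones[-drop]
      adj2 <- paste(pmin(sub[-length(sub)], sub[-1]),
                    pmax(sub[-length(sub)], sub[-1]))
      expect_false(all(adj2 %in% sig))
    }
  }
})

test_that("elongate merges end-to-end contigs and reports ambiguity", {
  # two contigs over one chain database, plus the linking middle clone in
  # the pool: merging should reunite them
  db <- estimate_abundances(chain_db(9L, 40L, 25L))
  cfg <- metric_config(tolerance = 0L, reps = 1e4, seed = 2,
                       metrics = "siid", metric = "siid",
                       prefilter_min_k = 1L)
  ov <- suppressWarnings(compute_overlaps(db, cfg))
  ids <- db$clone_ids
  ctgA <- ids[1:4]; ctgB <- ids[6:9]; pool <- ids[5]
  el <- elongate(list(A = ctgA, B = ctgB), pool, ov, 1e-12, seed = 1)
  expect_equal(length(el$contigs), 1L)
  merged <- el$contigs[[1]]$order
  expect_setequal(merged, ids)
  expect_equal(nrow(el$ambiguous), 0L)

  # ambiguous: one contig end reaches two other contigs -> reported, not
  # applied
  db2 <- estimate_abundances(chain_db(12L, 40L, 25L))
  ov2 <- suppressWarnings(compute_overlaps(db2, cfg))
  ids2 <- db2$clone_ids
  # A = middle, B = left, C = right; both B and C adjacent to A's ends is
  # fine; make B and C both adjacent to the SAME end by using overlapping
  # clone ranges
  ctgs <- list(A = ids2[5:8], B = ids2[1:4], C = ids2[9:12])
  el2 <- elongate(ctgs, character(), ov2, 1e-12, seed = 1)
  # A's two ends reach B and C separately: full merge into one contig
  expect_equal(length(el2$contigs), 1L)
  expect_setequal(el2$contigs[[1]]$order, ids2)
})

test_that("elongate respects marker-zone conflicts", {
  db <- estimate_abundances(chain_db(8L, 40L, 25L))
  cfg <- metric_config(tolerance = 0L, reps = 1e4, seed = 2,
                       metrics = "siid", metric = "siid",
                       prefilter_min_k = 1L)
  ov <- suppressWarnings(compute_overlaps(db, cfg))
  ids <- db$clone_ids
  zones <- data.table::data.table(
    clone_id = c(ids[1], ids[8]), zone = c("3BS", "3BL"))
  el <- elongate(list(A = ids[1:4], B = ids[5:8]), character(), ov, 1e-12,
                 zones = zones, seed = 1)
  expect_equal(length(el$contigs), 2L)   # conflicting zones: no merge
})

test_that("verify_contigs classifies the five gap origins", {
  lib <- small_sim()
  db <- small_db()
  ov <- small_overlaps()
  cfg <- attr(ov, "cfg")
  tr <- lib$truth[dropped == FALSE & chimeric == FALSE]
  data.table::setorder(tr, start)
  # a clean genomic window, in true order
  win <- tr[start > quantile(start, 0.3) & start < quantile(start, 0.5)]
  idsA <- win[order(start), clone_id]
  asgA <- data.table::data.table(contig_id = "good", clone_id = idsA,
                                 position = seq_along(idsA))
  repA <- verify_contigs(asgA, db, cfg, overlaps = ov)
  expect_false(grepl("non-connected", repA$categories))

  # two distant genomic windows glued together: non-connected
  lo <- tr[start < quantile(start, 0.15), clone_id]
  hi <- tr[start > quantile(start, 0.85), clone_id]
  asgAB <- data.table::data.table(contig_id = "glued",
                                  clone_id = c(lo, hi))
  repAB <- verify_contigs(asgAB, db, cfg, overlaps = ov)
  expect_gte(repAB$n_components, 2L)
  expect_true(grepl("non-connected", repAB$categories))

  # scrambled order: gaps appear and reordering can heal them
  set.seed(4)
  scr <- data.table::data.table(contig_id = "scram", clone_id = idsA,
                                position = sample(seq_along(idsA)))
  repS <- verify_contigs(scr, db, cfg, overlaps = ov)
  expect_true(repS$gaps > 0 || repS$categories == "")

  # missing clone warns but still reports
  asgM <- data.table::data.table(contig_id = "m",
                                 clone_id = c(idsA[1:6], "nosuchclone"))
  expect_warning(repM <- verify_contigs(asgM, db, cfg, overlaps = ov),
                 "absent")
  expect_equal(repM$n_clones, 6L)
})

test_that("a chimera-bridged contig is diagnosed non-linear", {
  # two separate chains bridged by one artificial chimeric clone that
  # shares bands with both mid-points: the four chain arms around the
  # bridge are long enough to carry rank >= 2 vertices
  b1 <- chain_db(9L, 40L, 25L)$bands
  b2 <- data.table::copy(chain_db(9L, 40L, 25L)$bands)
  b2[, `:=`(clone_id = sub("ch", "zz", clone_id), size = size + 100000L)]
  chim <- rbind(b1[clone_id == "ch05"][1:20],
                b2[clone_id == "zz05"][1:20])[, clone_id := "xchim"]
  db <- estimate_abundances(fingerprint_db(rbind(b1, b2, chim),
                                           tolerance = 0L, k_types = 1L))
  cfg <- metric_config(tolerance = 0L, reps = 1e4, seed = 3,
                       metrics = "siid", metric = "siid",
                       prefilter_min_k = 1L)
  ov <- suppressWarnings(compute_overlaps(db, cfg))
  asg <- data.table::data.table(contig_id = "br", clone_id = db$clone_ids)
  rep <- suppressWarnings(verify_contigs(asg, db, cfg, overlaps = ov))
  expect_true(grepl("non-linear", rep$categories) ||
                grepl("non-connected", rep$categories))
})
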