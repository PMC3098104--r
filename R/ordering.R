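# Global-optimization ordering of a linear cluster. The order criterion is
#   W(Omega) = sum of W over adjacent clones - b(Omega) * W0,
# with W_ij = -log10 Pr(c_i, c_j), b(Omega) the number of adjacent pairs with
# a non-significant overlap and W0 the penalty per such pair. Maximizing
# W(Omega) is an open-path traveling salesman problem with distances
#   d(c_i, c_j) = Wmax - W_ij + W0 * 1{Pr(c_i, c_j) > Pr0}.
# The solver is a multi-start nearest-neighbour construction refined by
# 2-opt and Or-opt moves; the criterion value, not the particular heuristic,
# is the contract.

#' TSP distance matrix for a cluster
#'
#' @param cluster character vector of clone ids (>= 2).
#' @param overlaps an `overlap_set` (uses the primary metric `log10p`).
#' @param pr0 significance cutoff for the gap indicator.
#' @param W0 penalty for a non-significant adjacency; default `-log10(pr0)`
#'   so that one gap costs one threshold-grade link.
#' @param weight_metric optionally the name of another computed metric
#'   (e.g. `"sulston"`) whose `log10p_<metric>` column supplies the edge
#'   weights `W`, while significance (the gap indicator) stays with the
#'   primary metric. The analytic Sulston tail is a smooth function of the
#'   exact band counts, which makes it a better continuous distance for
#'   global ordering than Monte-Carlo-calibrated tails with their per-cell
#'   calibration noise.
#' @return list: `d` (matrix, dimnames = clone ids), `W` (weight matrix),
#'   `sig` (logical adjacency-significance matrix), `Wmax`, `W0`, `pr0`.
#' @export
tsp_distances <- function(cluster, overlaps, pr0, W0 = -log10(pr0),
                          weight_metric = NULL) {
  n <- length(cluster)
  if (n < 2L) stop("cluster must contain at least 2 clones")
  ov <- as.data.table(overlaps)[c1 %in% cluster & c2 %in% cluster]
  wcol <- if (!is.null(weight_metric) &&
              paste0("log10p_", weight_metric) %in% names(ov))
    paste0("log10p_", weight_metric) else "log10p"
  W <- matrix(0, n, n, dimnames = list(cluster, cluster))
  sig <- matrix(FALSE, n, n, dimnames = list(cluster, cluster))
  if (nrow(ov)) {
    idx1 <- match(ov$c1, cluster); idx2 <- match(ov$c2, cluster)
    W[cbind(idx1, idx2)] <- -ov[[wcol]]
    W[cbind(idx2, idx1)] <- -ov[[wcol]]
    s <- ov$log10p < log10(pr0)
    sig[cbind(idx1, idx2)] <- s
    sig[cbind(idx2, idx1)] <- s
  }
  Wmax <- max(W)
  d <- Wmax - W + W0 * !sig
  diag(d) <- 0
  list(d = d, W = W, sig = sig, Wmax = Wmax, W0 = W0, pr0 = pr0)
}

#' Order the clones of a cluster
#'
#' Open-path TSP heuristic: nearest-neighbour construction from multiple
#' start clones plus 2-opt and Or-opt improvement until no gain; the best of
#' all restarts is kept. The orientation is canonical: the lexicographically
#' smaller endpoint comes first.
#'
#' @param cluster clone ids.
#' @param distances result of [tsp_distances()] (or a bare matrix).
#' @param seed RNG seed for restart selection.
#' @param restarts number of restarts (capped at the cluster size).
#' @return object of class `contig_order`: fields `order`, `W` (criterion),
#'   `gaps` (positions i with a non-significant `(i, i+1)` adjacency),
#'   `W0`, `Wmax`.
#' @export
order_clones <- function(cluster, distances, seed = 1L, restarts = 10L) {
  d <- if (is.list(distances)) distances$d else distances
  stopifnot(all(cluster %in% rownames(d)))
  d <- d[cluster, cluster, drop = FALSE]
  n <- length(cluster)
  if (n == 1L) {
    return(structure(list(order = cluster, W = 0, gaps = integer(),
                          W0 = if (is.list(distances)) distances$W0 else 0,
                          Wmax = if (is.list(distances)) distances$Wmax else 0),
                     class = "contig_order"))
  }
  set.seed(seed)
  starts <- if (restarts >= n) seq_len(n) else sample.int(n, restarts)
  ord <- cpp_tsp_path(d, as.integer(starts - 1L)) + 1L
  ids <- cluster[ord]
  if (ids[length(ids)] < ids[1L]) ids <- rev(ids)
  build_contig_order(ids, distances)
}

build_contig_order <- function(ids, distances) {
  W <- if (is.list(distances)) distances$W else NULL
  W0 <- if (is.list(distances)) distances$W0 else 0
  pr0 <- if (is.list(distances)) distances$pr0 else NA_real_
  crit <- NA_real_; gaps <- integer()
  if (!is.null(W) && length(ids) > 1L) {
    adj <- cbind(ids[-length(ids)], ids[-1L])
    wadj <- W[adj]
    gaps <- if (!is.null(distances$sig)) which(!distances$sig[adj])
            else which(wadj < -log10(pr0))
    crit <- sum(wadj) - length(gaps) * W0
  }
  structure(list(order = ids, W = crit, gaps = gaps, W0 = W0,
                 Wmax = if (is.list(distances)) distances$Wmax else NA_real_),
            class = "contig_order")
}

#' @export
print.contig_order <- function(x, ...) {
  cat(sprintf("contig_order: %d clones, W = %.1f, %d gap(s)\n",
              length(x$order), x$W, length(x$gaps)))
  invisible(x)
}

#' Criterion value of an order
#'
#' `W(Omega) = sum adjacent W - b(Omega) * W0`; used by tests and by the
#' jackknife to compare orders.
#' @param ids clone order.
#' @param distances result of [tsp_distances()].
#' @export
order_criterion <- function(ids, distances) {
  build_contig_order(ids, distances)$W
}

#' Detect gaps in an order
#'
#' Positions `i` where the overlap of the adjacent clones `(i, i+1)` is not
#' significant at `pr0` and the adjacency is therefore a gap.
#' @param order a `contig_order` or character vector.
#' @param overlaps an `overlap_set`.
#' @param pr0 cutoff.
#' @export
detect_gaps <- function(order, overlaps, pr0) {
  ids <- if (inherits(order, "contig_order")) order$order else order
  if (length(ids) < 2L) return(integer())
  ov <- as.data.table(overlaps)
  key <- paste(pmin(ids[-length(ids)], ids[-1L]),
               pmax(ids[-length(ids)], ids[-1L]))
  lp <- ov[paste(pmin(c1, c2), pmax(c1, c2)) %in% key,
           setNames(log10p, paste(pmin(c1, c2), pmax(c1, c2)))]
  vals <- lp[key]
  vals[is.na(vals)] <- 0  # unevaluated pair: Pr = 1
  unname(which(vals > log10(pr0)))
}

# Recompute pairwise statistics for a clone subset restricted to a subset of
# band classes, evaluating p-values with the tail models of the full run.
restricted_overlaps <- function(db, cluster, keep_classes, cfg, models, G,
                                metric = cfg$metric) {
  bw <- assign_band_classes(db)
  b <- bw[clone_id %in% cluster & gcl %in% keep_classes]
  if (nrow(b) == 0L)
    return(data.table(c1 = character(), c2 = character(),
                      k_count = integer(), log10p = numeric()))
  setorder(b, clone_id, band_type, size)
  cid <- unique(b$clone_id)
  cnt <- b[, .N, by = clone_id]
  starts <- c(0L, cumsum(cnt$N))
  weighted <- metric == "sind"
  w <- if (weighted) b$w else numeric(0)
  res <- as.data.table(cpp_all_pairs(as.integer(starts), b$band_type, b$size,
                                     w, db$tolerance, 1L))
  if (nrow(res) == 0L)
    return(data.table(c1 = character(), c2 = character(),
                      k_count = integer(), log10p = numeric()))
  res[, c1 := cid[i]][, c2 := cid[j]]
  nb <- setNames(db$clones$n_bands, db$clones$clone_id)  # full band counts
  res[, `:=`(n1 = nb[c1], n2 = nb[c2])]
  if (metric == "sulston") {
    res[, log10p := pmin(0, sulston_score(n1, n2, k, db$tolerance, G))]
  } else {
    bm <- if (weighted) abundance_band_model(db)
          else list(type = "iid", G = mc_universe(G, db$tolerance))
    res[, log10p := {
      mod <- get_tail_model(models, metric, n1[1L], n2[1L], bm, cfg)
      x <- if (weighted) kw else k
      pmin(0, tail_log10p(mod, x))
    }, by = .(round_grid(pmin(n1, n2), cfg$grid),
              round_grid(pmax(n1, n2), cfg$grid))]
  }
  res[, .(c1, c2, k_count = k, log10p)]
}

#' Jackknife stability of a contig order
#'
#' Each replicate drops a random fraction `1 - band_fraction` of the band
#' classes from the whole band universe (all their occurrences), recomputes
#' the cluster's overlaps restricted to the kept bands (evaluated against
#' the tail models of the full run), reorders, and tallies each clone's
#' left/right neighbors after canonical orientation. The instability of a
#' clone is one minus its maximal neighbor frequency, averaged over the two
#' sides present.
#'
#' @param db a `FingerprintDB` (abundances estimated).
#' @param cluster clone ids of the (ordered) cluster.
#' @param overlaps the full `overlap_set` (provides config and tail models).
#' @param band_fraction fraction of band classes kept per replicate
#'   (default 0.95).
#' @param replicates number of jackknife replicates (>= 10).
#' @param seed RNG seed.
#' @param restarts TSP restarts per replicate.
#' @param order_metric metric scored on the kept bands and used for the
#'   replicate orderings (default: the overlap set's primary metric).
#' @return object of class `stability_report`: `neighbor_freq` data.table
#'   (`clone_id`, `side`, `neighbor`, `freq`), `instability` named numeric,
#'   `replicates`, `band_fraction`.
#' @export
jackknife <- function(db, cluster, overlaps, band_fraction = 0.95,
                      replicates = 100L, seed = 1L, restarts = 5L,
                      order_metric = NULL) {
  stopifnot(replicates >= 10L, band_fraction > 0, band_fraction <= 1)
  cfg <- attr(overlaps, "cfg")
  models <- attr(overlaps, "models")
  G <- attr(overlaps, "G")
  if (is.null(db$abundance)) db <- estimate_abundances(db)
  classes <- band_class_table(db)[, unique(gcl)]
  tallies <- list()
  if (is.null(order_metric)) order_metric <- cfg$metric
  for (rep_i in seq_len(replicates)) {
    set.seed(seed + rep_i)
    keep <- sample(classes, size = round(band_fraction * length(classes)))
    ro <- restricted_overlaps(db, cluster, keep, cfg, models, G,
                              metric = order_metric)
    dist <- tsp_distances(cluster, ro, cfg$pr0)
    co <- order_clones(cluster, dist, seed = seed + rep_i,
                       restarts = restarts)
    ids <- co$order
    n <- length(ids)
    tallies[[rep_i]] <- rbind(
      data.table(clone_id = ids[-1L], side = "left", neighbor = ids[-n]),
      data.table(clone_id = ids[-n], side = "right", neighbor = ids[-1L]))
  }
  tal <- rbindlist(tallies)
  freq <- tal[, .(freq = .N / replicates), by = .(clone_id, side, neighbor)]
  inst <- freq[, .(instability = 1 - mean(tapply(freq, side, max))),
               by = clone_id]
  instability <- setNames(inst$instability, inst$clone_id)
  # clones never interior keep instability defined via available sides
  structure(list(neighbor_freq = freq[], instability = instability,
                 replicates = replicates, band_fraction = band_fraction),
            class = "stability_report")
}

#' Skeleton order: drop unstable clones
#'
#' Clones with instability above `threshold` (typically near-identical
#' "parallel" clones) are removed and the remainder reordered; each removed
#' clone is attached to its most significant neighbor among the kept clones.
#'
#' @param order a `contig_order`.
#' @param report a `stability_report` for the same cluster.
#' @param distances result of [tsp_distances()] for the full cluster.
#' @param threshold instability threshold (default 0.3).
#' @param seed,restarts passed to [order_clones()].
#' @return a `contig_order` with an `attached` field (data.table
#'   `clone_id`, `host`).
#' @export
skeleton_order <- function(order, report, distances, threshold = 0.3,
                           seed = 1L, restarts = 10L) {
  ids <- order$order
  unstable <- names(report$instability)[report$instability > threshold]
  unstable <- intersect(ids, unstable)
  keep <- setdiff(ids, unstable)
  attached <- data.table(clone_id = character(), host = character())
  if (length(unstable) && length(keep) >= 2L) {
    co <- order_clones(keep, distances, seed = seed, restarts = restarts)
    W <- distances$W
    attached <- data.table(clone_id = unstable,
                           host = vapply(unstable, function(u) {
                             keep[which.max(W[u, keep])]
                           }, character(1)))
    co$attached <- attached
    return(co)
  }
  order$attached <- attached
  order
}
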