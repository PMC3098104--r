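# Overlap significance metrics. Three p-value metrics for the overlap of two
# clones with n1 and n2 bands sharing k of them:
#   sulston - classical binomial approximation (iid bands, tolerance folded
#             into the per-band match probability (2t+1)/G);
#   siid    - Monte-Carlo calibrated tail under the same iid-uniform band
#             model, accurate also for large k;
#   sind    - Monte-Carlo calibrated tail for the abundance-weighted
#             statistic k_w = -sum ln f_b over shared bands, dropping the
#             identically-distributed assumption.
# For the calibrated metrics the upper tail Pr(K >= k) is approximated by
# exp{-(a0 + a1 k + a2 k^2)} beyond a threshold k0; below k0 the empirical
# Monte-Carlo tail is used directly. Shared genetic markers multiply the
# p-value by exp(-a_mark) each (a_mark = 100 ln 10 by default, making any
# marker-sharing pair more significant than 1e-100).

#' Metric configuration
#'
#' @param tolerance band-matching tolerance `t`.
#' @param G band universe size (count of distinguishable band values across
#'   all types). `NULL` (default) estimates it from the database as the sum
#'   over band types of `span / (2 t + 1)`, the number of tolerance-wide bins
#'   the observed size range supports; for wheat-style HICF data a value such
#'   as 18000 (4 dyes x 4500 scored values) is typical and can be given
#'   explicitly.
#' @param a_mark marker weight added to the exponent per shared marker.
#' @param pr0 significance cutoff `Pr_0`.
#' @param reps Monte-Carlo pairs per tail calibration.
#' @param seed base RNG seed for calibration.
#' @param prefilter_min_k pairs with fewer shared bands are skipped (not
#'   evaluated, never stored); used purely to bound the work.
#' @param metrics which metrics to compute.
#' @param metric metric whose p-value drives significance flags.
#' @param grid band counts are rounded to the nearest multiple of `grid`
#'   when looking up calibrated tail models, so models are shared across
#'   similar clone sizes.
#' @return list of class `metric_config`
#' @export
metric_config <- function(tolerance = 12L, G = NULL, a_mark = 100 * log(10),
                          pr0 = 1e-12, reps = 2e5, seed = 1L,
                          prefilter_min_k = 5L,
                          metrics = c("sulston", "siid", "sind"),
                          metric = "sind", grid = 10L) {
  stopifnot(a_mark > 0, pr0 > 0, pr0 < 1, reps >= 1e4)
  metrics <- match.arg(metrics, c("sulston", "siid", "sind"),
                       several.ok = TRUE)
  if (!metric %in% metrics) metrics <- c(metrics, metric)
  structure(list(tolerance = as.integer(tolerance), G = G, a_mark = a_mark,
                 pr0 = pr0, reps = as.integer(reps), seed = as.integer(seed),
                 prefilter_min_k = as.integer(prefilter_min_k),
                 metrics = metrics, metric = metric, grid = as.integer(grid)),
            class = "metric_config")
}

# Estimate of the raw band-value universe G: the number of distinct size
# values the observed ranges support, summed over band types. The Sulston
# per-band match probability is then (2t+1)/G; the Monte-Carlo calibration
# draws from the tolerance-binned universe G / (2t+1) with exact matching,
# which has the same per-pair collision probability.
estimate_universe <- function(db) {
  spans <- db$bands[, .(span = max(size) - min(size) + 1L), by = band_type]
  max(2L, as.integer(sum(spans$span)))
}

mc_universe <- function(G, tolerance) {
  max(2L, as.integer(round(G / (2 * tolerance + 1))))
}

#' Sulston score
#'
#' Classical binomial approximation to the probability that two random
#' clones with `n1 <= n2` bands share at least `k`: each of the `n1` bands
#' matches some band of clone 2 with probability
#' `p1 = 1 - (1 - (2t+1)/G)^n2`, and the upper binomial tail is returned in
#' log10 units (computed in log space).
#'
#' @param n1,n2 band counts of the two clones (swapped if `n1 > n2`).
#' @param k shared band count, `0 <= k <= min(n1, n2)`.
#' @param tolerance matching tolerance.
#' @param G band universe size.
#' @return log10 p-value (0 for `k = 0`).
#' @export
sulston_score <- function(n1, n2, k, tolerance, G) {
  stopifnot(G > 0)
  if (any(k > pmin(n1, n2))) stop("k exceeds min(n1, n2)")
  lo <- pmin(n1, n2); hi <- pmax(n1, n2)
  p1 <- 1 - (1 - (2 * tolerance + 1) / G)^hi
  out <- pbinom(k - 1, lo, p1, lower.tail = FALSE, log.p = TRUE) / log(10)
  out[k <= 0] <- 0
  out
}

#' Calibrate a Monte-Carlo tail model
#'
#' Simulates `reps` pairs of random clones with `n1` and `n2` bands drawn
#' with replacement from the band universe (duplicate draws collapse), scores
#' the shared-band statistic, and fits `-ln Pr(K >= k) ~ a0 + a1 k + a2 k^2`
#' by least squares over the k-range where the empirical tail lies in
#' `[10/reps, 1e-3]`. Below the validity threshold `k0` (the largest
#' statistic with empirical tail above 1e-3) the empirical tail itself is
#' used. A degenerate fit (< 3 support points) falls back to a linear model
#' with a warning; a fitted tail that is not non-increasing over the
#' evaluation range also falls back.
#'
#' @param n1,n2 band counts.
#' @param band_model `list(type = "iid", G = <universe>)` or
#'   `list(type = "abundance", probs = <class probabilities>, weights =
#'   <-ln f per class>)`.
#' @param reps Monte-Carlo replicates (>= 1e4).
#' @param seed RNG seed.
#' @return object of class `tail_model`.
#' @export
calibrate_tail <- function(n1, n2, band_model, reps = 2e5, seed = 1L) {
  stopifnot(reps >= 1e4)
  set.seed(seed)
  weighted <- identical(band_model$type, "abundance")
  if (weighted) {
    stat <- cpp_mc_weighted(n1, n2, band_model$probs, band_model$weights,
                            as.integer(reps))
  } else {
    stat <- as.numeric(cpp_mc_counts(n1, n2, as.integer(band_model$G),
                                     as.integer(reps)))
  }
  sv <- sort(stat)
  # empirical complementary cdf evaluated at the distinct statistic values
  ux <- unique(sv)
  tail_at <- function(x) 1 - findInterval(x - 1e-9, sv) / length(sv)
  tails <- tail_at(ux)
  k0 <- if (any(tails >= 1e-3)) max(ux[tails >= 1e-3]) else min(ux)
  lo <- 10 / reps
  sel <- tails >= lo & tails <= 1e-3
  fit_x <- ux[sel]; fit_y <- -log(tails[sel])
  lin <- FALSE
  if (length(fit_x) < 3L) {
    warning("degenerate tail fit (", length(fit_x),
            " support points); falling back to linear")
    lin <- TRUE
    # widen to anything below the median so a slope is estimable
    sel2 <- tails <= 0.5 & tails >= lo
    fit_x <- ux[sel2]; fit_y <- -log(tails[sel2])
  }
  kmax_eval <- if (weighted) 10 * max(sv, 1) else max(n1, n2)
  fit_quad <- function() {
    cf <- coef(lm(fit_y ~ fit_x + I(fit_x^2)))
    c(a0 = unname(cf[1]), a1 = unname(cf[2]), a2 = unname(cf[3]))
  }
  fit_lin <- function() {
    if (length(fit_x) < 2L) {
      # degenerate support (e.g. a near-empty tail on a huge universe):
      # a line through the last empirical points, or through the origin
      xx <- utils::tail(ux, 2L); yy <- -log(utils::tail(tails, 2L))
      if (length(xx) < 2L || xx[2] == xx[1])
        return(c(a0 = 0, a1 = max(yy) / max(max(ux), 1), a2 = 0))
      sl <- (yy[2] - yy[1]) / (xx[2] - xx[1])
      return(c(a0 = yy[2] - sl * xx[2], a1 = max(sl, 0), a2 = 0))
    }
    cf <- coef(lm(fit_y ~ fit_x))
    c(a0 = unname(cf[1]), a1 = unname(cf[2]), a2 = 0)
  }
  a <- if (lin || length(fit_x) < 3L) fit_lin() else fit_quad()
  monotone <- function(a) {
    # -ln tail must be non-decreasing in k over [k0, kmax_eval]
    d1 <- a[["a1"]] + 2 * a[["a2"]] * k0
    d2 <- a[["a1"]] + 2 * a[["a2"]] * kmax_eval
    !anyNA(c(d1, d2)) && d1 >= 0 && d2 >= 0
  }
  if (!monotone(a)) a <- fit_lin()
  # beyond the last supported statistic the quadratic is pure
  # extrapolation whose a2 term amplifies fit noise; continue linearly
  # with the slope at the window edge instead (monotone, noise-bounded)
  fit_max <- if (length(fit_x)) max(fit_x) else k0
  slope_end <- max(0, a[["a1"]] + 2 * a[["a2"]] * fit_max)
  structure(list(n1 = n1, n2 = n2, a0 = a[["a0"]], a1 = a[["a1"]],
                 a2 = a[["a2"]], k0 = k0, fit_max = fit_max,
                 slope_end = slope_end,
                 empirical = data.table(x = ux, tail = tails),
                 reps = reps, seed = seed, weighted = weighted),
            class = "tail_model")
}

#' Evaluate a calibrated tail
#'
#' Returns `log10 Pr(K >= x)`: empirical below `k0`, quadratic model above.
#' @param model a `tail_model`
#' @param x statistic values
#' @export
tail_log10p <- function(model, x) {
  emp <- model$empirical
  out <- numeric(length(x))
  below <- x <= model$k0
  if (any(below)) {
    idx <- findInterval(x[below] - 1e-9, emp$x) + 1L
    idx <- pmin(idx, nrow(emp))
    out[below] <- log10(emp$tail[idx])
  }
  if (any(!below)) {
    xx <- x[!below]
    fm <- if (is.null(model$fit_max)) Inf else model$fit_max
    xq <- pmin(xx, fm)
    lnp <- -(model$a0 + model$a1 * xq + model$a2 * xq^2)
    over <- xx > fm
    if (any(over))
      lnp[over] <- lnp[over] - model$slope_end * (xx[over] - fm)
    out[!below] <- pmin(0, lnp / log(10))
  }
  pmin(out, 0)
}

# Cache of tail models on a grid of rounded band counts.
round_grid <- function(n, grid) pmax(grid, as.integer(round(n / grid) * grid))

model_key <- function(metric, g1, g2) {
  a <- pmin(g1, g2); b <- pmax(g1, g2)
  paste(metric, a, b, sep = ":")
}

new_model_cache <- function() new.env(parent = emptyenv())

get_tail_model <- function(cache, metric, n1, n2, band_model, cfg,
                           calibrate = TRUE) {
  g1 <- round_grid(n1, cfg$grid); g2 <- round_grid(n2, cfg$grid)
  key <- model_key(metric, g1, g2)
  if (!is.null(cache[[key]])) return(cache[[key]])
  if (!calibrate) stop("no calibrated tail model for ", key,
                       " and caching disabled")
  seed <- (cfg$seed + 7919 * min(g1, g2) + 104729 * max(g1, g2) +
             1e6 * (metric == "sind")) %% .Machine$integer.max
  cache[[key]] <- calibrate_tail(min(g1, g2), max(g1, g2), band_model,
                                 reps = cfg$reps, seed = as.integer(seed))
  cache[[key]]
}

# Band model descriptors for the two calibrated metrics.
iid_band_model <- function(db, cfg) {
  G <- if (is.null(cfg$G)) estimate_universe(db) else as.integer(cfg$G)
  list(type = "iid", G = mc_universe(G, cfg$tolerance))
}

abundance_band_model <- function(db) {
  if (is.null(db$abundance)) stop("estimate_abundances() first")
  ab <- db$abundance
  list(type = "abundance", probs = ab$f, weights = -log(ab$f))
}

#' P-value of the overlap of two clones
#'
#' Computes the shared-band statistic for the pair and evaluates the chosen
#' metric; shared markers contribute `-a_mark * m` to the log p-value
#' (each shared marker multiplies the p-value by `exp(-a_mark)`).
#'
#' @param fp1,fp2 `Fingerprint`s (from [get_fingerprint()]).
#' @param metric `"sulston"`, `"siid"` or `"sind"`.
#' @param cfg a [metric_config()].
#' @param db the `FingerprintDB` (context: abundances, universe).
#' @param models model cache environment (created on the fly if missing).
#' @param calibrate allow on-demand calibration? If `FALSE` and the model is
#'   missing, an error is thrown.
#' @return one-row data.table: `c1`, `c2`, `k_count`, `k_weighted`, `m`,
#'   `log10p`.
#' @export
p_value <- function(fp1, fp2, metric, cfg, db, models = NULL,
                    calibrate = TRUE) {
  metric <- match.arg(metric, c("sulston", "siid", "sind"))
  if (is.null(models)) models <- new_model_cache()
  sb <- shared_bands(fp1, fp2, cfg$tolerance)
  n1 <- nrow(fp1$bands); n2 <- nrow(fp2$bands)
  m <- length(intersect(fp1$markers, fp2$markers))
  kw <- NA_real_
  if (metric == "sulston") {
    lp <- sulston_score(n1, n2, sb$k, cfg$tolerance,
                        if (is.null(cfg$G)) estimate_universe(db) else cfg$G)
  } else if (metric == "siid") {
    mod <- get_tail_model(models, "siid", n1, n2, iid_band_model(db, cfg),
                          cfg, calibrate)
    lp <- tail_log10p(mod, sb$k)
  } else {
    bw <- assign_band_classes(db)
    b1 <- bw[clone_id == fp1$clone_id][order(band_type, size)]
    kw <- if (nrow(sb$pairs)) sum(b1$w[sb$pairs[, 1]]) else 0
    mod <- get_tail_model(models, "sind", n1, n2, abundance_band_model(db),
                          cfg, calibrate)
    lp <- tail_log10p(mod, kw)
  }
  lp <- pmin(0, lp - cfg$a_mark * m / log(10))
  data.table(c1 = fp1$clone_id, c2 = fp2$clone_id, k_count = sb$k,
             k_weighted = kw, m = m, log10p = lp)
}

#' Compute all pairwise clone overlaps
#'
#' Evaluates the shared-band statistics for every clone pair (a C++
#' two-pointer sweep), skips pairs with fewer than `prefilter_min_k` shared
#' bands, and attaches log10 p-values for each configured metric. Tail
#' models are calibrated once per rounded `(n1, n2)` band-count cell and
#' cached.
#'
#' @param db a `FingerprintDB` (abundances are estimated on the fly when the
#'   `sind` metric is requested).
#' @param cfg a [metric_config()].
#' @return data.table of class `overlap_set` with columns `c1`, `c2`,
#'   `k_count`, `k_weighted`, `m`, one `log10p_<metric>` column per metric,
#'   `log10p` (the primary metric) and `significant`. Attributes: `cfg`,
#'   `db_clones` (clone band counts), `models` (tail-model cache), `G`.
#' @export
compute_overlaps <- function(db, cfg = metric_config()) {
  if ("sind" %in% cfg$metrics && is.null(db$abundance))
    db <- estimate_abundances(db)
  weighted <- "sind" %in% cfg$metrics
  arr <- band_arrays(db, weights = weighted)
  res <- as.data.table(cpp_all_pairs(arr$starts, arr$types, arr$sizes,
                                     arr$weights, db$tolerance,
                                     max(1L, cfg$prefilter_min_k)))
  res[, c1 := arr$clone_ids[i]][, c2 := arr$clone_ids[j]]
  nb <- setNames(db$clones$n_bands, db$clones$clone_id)
  res[, `:=`(n1 = nb[c1], n2 = nb[c2])]
  setnames(res, c("k", "kw"), c("k_count", "k_weighted"))
  # shared markers
  res[, m := 0L]
  if (nrow(db$markers)) {
    mk <- db$markers
    shared <- mk[mk, on = "marker_id", allow.cartesian = TRUE
                 ][clone_id < i.clone_id,
                   .(m = .N), by = .(c1 = clone_id, c2 = i.clone_id)]
    if (nrow(shared)) {
      res[shared, m := i.m, on = c("c1", "c2")]
      res[shared, m := i.m, on = c(c1 = "c2", c2 = "c1")]
    }
  }
  models <- new_model_cache()
  G <- if (is.null(cfg$G)) estimate_universe(db) else as.integer(cfg$G)
  mshift <- cfg$a_mark / log(10)
  for (metric in cfg$metrics) {
    col <- paste0("log10p_", metric)
    if (metric == "sulston") {
      res[, (col) := pmin(0, sulston_score(n1, n2, k_count, db$tolerance, G) -
                            mshift * m)]
    } else {
      bm <- if (metric == "siid")
        list(type = "iid", G = mc_universe(G, db$tolerance))
      else abundance_band_model(db)
      res[, (col) := {
        mod <- get_tail_model(models, metric, n1[1L], n2[1L], bm, cfg)
        x <- if (metric == "siid") k_count else k_weighted
        pmin(0, tail_log10p(mod, x) - mshift * m)
      }, by = .(round_grid(pmin(n1, n2), cfg$grid),
                round_grid(pmax(n1, n2), cfg$grid))]
    }
  }
  res[, log10p := get(paste0("log10p_", cfg$metric))]
  res[, significant := log10p < log10(cfg$pr0)]
  out <- res[, c("c1", "c2", "k_count", "k_weighted", "m",
                 paste0("log10p_", cfg$metrics), "log10p", "significant"),
             with = FALSE]
  setattr(out, "cfg", cfg)
  setattr(out, "db_clones", copy(db$clones))
  setattr(out, "clone_ids", db$clone_ids)
  setattr(out, "models", models)
  setattr(out, "G", G)
  setattr(out, "class", c("overlap_set", class(out)))
  out[]
}

#' Write / read the overlap table TSV
#' @param overlaps an `overlap_set`
#' @param path TSV path
#' @export
write_overlaps <- function(overlaps, path) {
  out <- copy(as.data.table(overlaps))
  out[, significant := as.integer(significant)]
  fwrite(out, path, sep = "\t")
  invisible(path)
}
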