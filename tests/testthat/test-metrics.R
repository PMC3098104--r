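test_that("sulston_score handles edge cases and simple Bernoulli", {
  expect_equal(sulston_score(10, 20, 0, 4, 1000), 0)
  # single band each, p1 chosen via G: p1 = 1 - (1 - (2t+1)/G)^1
  G <- 90L; t <- 4L          # (2t+1)/G = 0.1
  expect_equal(sulston_score(1, 1, 1, t, G), log10(0.1), tolerance = 1e-12)
  expect_error(sulston_score(3, 5, 4, 4, 100), "exceeds")
})

test_that("sulston_score matches brute-force enumeration on a small universe", {
  # draw many random clone pairs on a tiny raw universe, score the greedy
  # shared count, and compare the simulated tail with the formula
  set.seed(31)
  G <- 40L; n1 <- 5L; n2 <- 8L; t <- 1L
  reps <- 3e4
  k_obs <- integer(reps)
  for (r in seq_len(reps)) {
    b1 <- sample.int(G, n1, replace = TRUE)
    b2 <- sample.int(G, n2, replace = TRUE)
    # tolerance-aware greedy matching oracle
    k <- shared_bands(data.frame(band_type = 1, size = sort(b1)),
                      data.frame(band_type = 1, size = sort(b2)), t)$k
    k_obs[r] <- k
  }
  for (k in 1:3) {
    emp <- mean(k_obs >= k)
    thr <- 10^sulston_score(n1, n2, k, t, G)
    # binomial approximation: within 35% relative error in this regime
    expect_lt(abs(thr - emp) / emp, 0.35)
  }
})

test_that("calibrated iid tails agree with the exact combinatorial tail", {
  # exact oracle for n uniform draws from G values with duplicates
  # collapsing: distinct-count via occupancy (Stirling numbers), then the
  # intersection of two uniform random subsets is hypergeometric
  G <- 20L; n <- 5L
  stirling2 <- function(n, k) {
    S <- matrix(0, n + 1, k + 1)
    S[1, 1] <- 1
    for (i in 1:n) for (j in 1:min(i, k))
      S[i + 1, j + 1] <- j * S[i, j + 1] + S[i, j]
    S[n + 1, ]
  }
  s2 <- stirling2(n, n)[-1]                       # distinct sizes 1..n
  p_size <- vapply(1:n, function(s)
    s2[s] * prod(G - seq_len(s) + 1) / G^n, numeric(1))
  exact_tail <- function(k) {
    tot <- 0
    for (s1 in 1:n) for (s2i in 1:n) {
      pj <- sum(vapply(k:min(s1, s2i), function(j)
        choose(s1, j) * choose(G - s1, s2i - j) / choose(G, s2i),
        numeric(1)))
      tot <- tot + p_size[s1] * p_size[s2i] * pj
    }
    tot
  }
  mod <- suppressWarnings(calibrate_tail(n, n, list(type = "iid", G = G),
                                         reps = 5e4, seed = 12))
  for (k in 1:4) {
    p_mod <- 10^tail_log10p(mod, k)
    p_exact <- exact_tail(k)
    if (p_exact > 1e-4)
      expect_lt(abs(log(p_mod / p_exact)), log(2))  # within a factor 2
  }
  # fitted tail is non-increasing
  p_seq <- tail_log10p(mod, 0:n)
  expect_true(all(diff(p_seq) <= 1e-9))
})

test_that("p_value applies the marker term and respects k = 0", {
  db <- toy_db()
  db$markers <- data.table::data.table(clone_id = c("cA", "cC"),
                                       marker_id = "m1")
  cfg <- metric_config(tolerance = 4L, G = 1000L, reps = 1e4, seed = 2,
                       metrics = "sulston", metric = "sulston")
  fa <- get_fingerprint(db, "cA"); fc <- get_fingerprint(db, "cC")
  # cA and cC share no bands but share marker m1
  pv <- p_value(fa, fc, "sulston", cfg, db)
  expect_equal(pv$k_count, 0L)
  expect_equal(pv$m, 1L)
  expect_equal(pv$log10p, -100)   # p multiplied by 10^-100
  # no markers, no shared bands -> p = 1
  db2 <- toy_db()
  pv2 <- p_value(get_fingerprint(db2, "cA"), get_fingerprint(db2, "cC"),
                 "sulston", cfg, db2)
  expect_equal(pv2$log10p, 0)
})

test_that("p_value is monotone in k and symmetric", {
  db <- small_db()
  cfg <- metric_config(reps = 2e4, seed = 4)
  models <- new.env(parent = emptyenv())
  mod <- suppressWarnings(
    calibrate_tail(100, 100, list(type = "iid", G = 2000L), reps = 5e4,
                   seed = 3))
  lp <- tail_log10p(mod, 0:100)
  expect_true(all(diff(lp) <= 1e-9))

  ids <- sim_cache$db$clone_ids[1:4]
  f <- lapply(ids, get_fingerprint, db = db)
  for (pair in list(c(1, 2), c(1, 3), c(2, 4))) {
    a <- suppressWarnings(p_value(f[[pair[1]]], f[[pair[2]]], "siid", cfg,
                                  db, models))
    b <- suppressWarnings(p_value(f[[pair[2]]], f[[pair[1]]], "siid", cfg,
                                  db, models))
    expect_equal(a$log10p, b$log10p)
    expect_equal(a$k_count, b$k_count)
  }
  # missing model with calibration disabled errors
  expect_error(p_value(f[[1]], f[[2]], "siid", cfg, db,
                       new.env(parent = emptyenv()), calibrate = FALSE),
               "caching disabled")
})

test_that("uniform abundances make sind rank exactly like siid", {
  # a circular block design gives every band class exactly the same
  # abundance, so k_w is strictly proportional to k and both calibrated
  # metrics must order pairs identically (ties included)
  G <- 120L; per <- 30L; n_cl <- 40L
  bands <- data.table::rbindlist(lapply(seq_len(n_cl), function(i) {
    v <- ((seq_len(per) + (i - 1L) * 3L - 1L) %% G) + 1L
    data.table::data.table(clone_id = sprintf("u%03d", i), band_type = 1L,
                           size = v * 100L)
  }))
  db <- estimate_abundances(fingerprint_db(bands, tolerance = 0L,
                                           k_types = 1L))
  expect_equal(data.table::uniqueN(db$abundance$f), 1L)   # equal abundances
  cfg <- metric_config(tolerance = 0L, reps = 2e4, seed = 6,
                       prefilter_min_k = 1L,
                       metrics = c("siid", "sind"), metric = "sind")
  ov <- suppressWarnings(compute_overlaps(db, cfg))
  ov <- ov[k_count > 0]
  expect_gt(nrow(ov), 50)
  # both are non-increasing functions of k: ranks agree wherever k differs
  agg <- ov[, .(siid = mean(log10p_siid), sind = mean(log10p_sind),
                v_siid = var(log10p_siid), v_sind = var(log10p_sind)),
            by = k_count][order(k_count)]
  expect_true(all(agg$v_siid < 1e-18, na.rm = TRUE))  # constant within k
  expect_true(all(agg$v_sind < 1e-18, na.rm = TRUE))
  expect_true(all(diff(agg$siid) <= 1e-9))
  expect_true(all(diff(agg$sind) <= 1e-9))
  rho <- cor(ov$log10p_siid, ov$log10p_sind, method = "spearman")
  expect_gt(rho, 0.99)
})

test_that("compute_overlaps stores symmetric records and honors prefiltering", {
  # two identical clones -> one record with maximal k
  bands <- data.table::rbindlist(list(
    data.table::data.table(clone_id = "x1", band_type = 1L,
                           size = (1:30) * 100L),
    data.table::data.table(clone_id = "x2", band_type = 1L,
                           size = (1:30) * 100L)))
  db <- fingerprint_db(bands, tolerance = 0L, k_types = 1L)
  cfg <- metric_config(tolerance = 0L, G = 3000L, reps = 1e4, seed = 1,
                       metrics = "sulston", metric = "sulston",
                       prefilter_min_k = 1L)
  ov <- compute_overlaps(db, cfg)
  expect_equal(nrow(ov), 1L)
  expect_equal(ov$k_count, 30L)

  # prefiltering only skips evaluation; significant set is unchanged
  lib <- small_sim()
  db2 <- estimate_abundances(lib$fdb)
  cfg_pre <- metric_config(reps = 2e4, seed = 9, prefilter_min_k = 5L,
                           metrics = "siid", metric = "siid")
  cfg_all <- metric_config(reps = 2e4, seed = 9, prefilter_min_k = 1L,
                           metrics = "siid", metric = "siid")
  ov_pre <- suppressWarnings(compute_overlaps(db2, cfg_pre))
  ov_all <- suppressWarnings(compute_overlaps(db2, cfg_all))
  sig_pre <- ov_pre[significant == TRUE, paste(c1, c2)]
  sig_all <- ov_all[significant == TRUE, paste(c1, c2)]
  expect_setequal(sig_pre, sig_all)
  expect_gt(length(sig_all), 0)
})

test_that("the three metrics rank overlaps consistently but not identically", {
  # across the full strength range (weak chance pairs to near-duplicates)
  # the three -log p rankings agree strongly but not perfectly
  ov <- small_overlaps()
  sel <- ov[k_count >= 10]
  expect_gt(nrow(sel), 200)
  r1 <- cor(sel$log10p_sulston, sel$log10p_sind, method = "spearman")
  r2 <- cor(sel$log10p_siid, sel$log10p_sind, method = "spearman")
  expect_gt(r1, 0.7); expect_gt(r2, 0.7)
  expect_lt(r1, 1); expect_lt(r2, 1)
})
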