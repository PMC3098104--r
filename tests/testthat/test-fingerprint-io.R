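test_that("sizes files decode offsets and validate records", {
  path <- withr::local_tempfile(fileext = ".sizes")
  writeLines(c("cA 3", "120 180 5120 -1",
               "cB 2", "130 5200 -1"), path)
  db <- read_sizes(path, k_types = 2L, tolerance = 4L)
  expect_equal(db_n_clones(db), 2L)
  fa <- get_fingerprint(db, "cA")
  expect_equal(fa$bands,
               data.table::data.table(band_type = c(1L, 1L, 2L),
                                      size = c(120L, 180L, 120L)))

  # declared count mismatch
  writeLines(c("cX 4", "120 180 200 -1"), path)
  expect_error(read_sizes(path), "declared 4")
  # duplicate clone id
  writeLines(c("cA 1", "10 -1", "cA 1", "20 -1"), path)
  expect_error(read_sizes(path), "duplicate")
  # non-positive size
  writeLines(c("cA 1", "0 -1"), path)
  expect_error(read_sizes(path), "non-positive")
  # empty file -> empty DB
  writeLines(character(), path)
  expect_equal(db_n_clones(read_sizes(path)), 0L)
})

test_that("write_sizes / read_sizes round-trips the database", {
  # offset encoding is invertible when per-type sizes stay below the
  # offset unit; build such a database (the raw encoded values of larger
  # fingerprints round-trip too; see the simulator tests)
  set.seed(12)
  bands <- data.table::rbindlist(lapply(1:15, function(i)
    data.table::data.table(clone_id = sprintf("rt%02d", i),
                           band_type = sample.int(4L, 30, TRUE),
                           size = sample.int(4999L, 30))))
  db <- fingerprint_db(bands, tolerance = 4L, k_types = 4L)
  path <- withr::local_tempfile(fileext = ".sizes")
  write_sizes(db, path)
  db2 <- read_sizes(path, k_types = db$k_types, tolerance = db$tolerance)
  expect_equal(db2$bands, db$bands)
  expect_equal(db2$clones, db$clones)

  tsv <- withr::local_tempfile(fileext = ".tsv")
  sim <- small_sim()$fdb
  write_bands_tsv(sim, tsv)
  db3 <- read_bands_tsv(tsv, tolerance = sim$tolerance,
                        k_types = sim$k_types)
  expect_equal(db3$bands, sim$bands)
})

test_that("shared_bands matches types under tolerance, greedily one-to-one", {
  expect_equal(shared_bands(data.frame(band_type = 1, size = 100),
                            data.frame(band_type = 1, size = 103), 4)$k, 1L)
  expect_equal(shared_bands(data.frame(band_type = 1, size = 100),
                            data.frame(band_type = 2, size = 100), 4)$k, 0L)
  # one band matches at most once
  expect_equal(shared_bands(data.frame(band_type = 1, size = 100),
                            data.frame(band_type = c(1, 1),
                                       size = c(99, 101)), 4)$k, 1L)
})

test_that("shared_bands agrees with multiset intersection at t = 0", {
  set.seed(41)
  for (rep in 1:20) {
    b1 <- random_bands(50); b2 <- random_bands(50)
    k <- shared_bands(b1, b2, 0)$k
    # brute-force multiset intersection per type
    oracle <- sum(vapply(1:2, function(tt) {
      s1 <- sort(b1[band_type == tt, size]); s2 <- sort(b2[band_type == tt, size])
      t1 <- table(s1); t2 <- table(s2)
      shared <- intersect(names(t1), names(t2))
      sum(pmin(t1[shared], t2[shared]))
    }, numeric(1)))
    expect_equal(k, as.integer(oracle))
  }
})

test_that("shared_bands is symmetric and reflexive", {
  set.seed(7)
  for (rep in 1:10) {
    b1 <- random_bands(30); b2 <- random_bands(25)
    expect_equal(shared_bands(b1, b2, 3)$k, shared_bands(b2, b1, 3)$k)
    expect_equal(shared_bands(b1, b1, 3)$k, nrow(b1))
  }
})

test_that("abundance estimation follows the odds formula and caps", {
  # direct formula: pi = 0.5, n_mean = 100 -> f = 0.01
  # build 100 clones with 100 unique bands each; one shared band in half
  set.seed(2)
  bands <- data.table::rbindlist(lapply(1:100, function(i) {
    sz <- (i * 1000L) + seq_len(99L) * 5L   # disjoint per clone
    sz <- c(sz, if (i <= 50) 999999L else (i * 1000L) + 995L)
    data.table::data.table(clone_id = sprintf("c%03d", i), band_type = 1L,
                           size = sz)
  }))
  db <- estimate_abundances(fingerprint_db(bands, tolerance = 0L,
                                           k_types = 1L))
  ab <- db$abundance[size_lo == 999999L]
  expect_equal(ab$pi_b, 0.5)
  expect_equal(ab$f, 0.01, tolerance = 1e-12)

  # ubiquitous band -> f capped at 1
  bands2 <- data.table::data.table(
    clone_id = rep(sprintf("c%d", 1:5), each = 2),
    band_type = 1L,
    size = as.integer(rbind(77L, 1000L + (1:5) * 100L)))
  db2 <- estimate_abundances(fingerprint_db(bands2, tolerance = 0L,
                                            k_types = 1L))
  expect_equal(db2$abundance[size_lo == 77L, f], 1)
})

test_that("abundance estimates recover known generative frequencies", {
  # clones draw bands i.i.d.: band class b present with prob ~ n * f_b
  set.seed(99)
  n_clones <- 400L; n_bands <- 40L
  G <- 500L
  f_true <- c(rep(0.02, 5), rep(0.005, G - 5))
  probs <- f_true / sum(f_true)
  bands <- data.table::rbindlist(lapply(seq_len(n_clones), function(i) {
    v <- unique(sample.int(G, n_bands, replace = TRUE, prob = probs))
    data.table::data.table(clone_id = sprintf("c%04d", i), band_type = 1L,
                           size = v * 100L)
  }))
  db <- estimate_abundances(fingerprint_db(bands, tolerance = 0L,
                                           k_types = 1L))
  ab <- db$abundance[n_clones >= 20]
  # per-draw probability implied by the estimate: f_hat vs probs
  for (r in seq_len(nrow(ab))) {
    cls <- ab$size_lo[r] / 100L
    p_true <- probs[cls]
    # presence prob: 1 - (1 - p)^n; pi_hat estimates it
    pi_true <- 1 - (1 - p_true)^n_bands
    se <- sqrt(pi_true * (1 - pi_true) / n_clones)
    # ~100 classes tested at once: use a 4.5 sigma band so the familywise
    # false-alarm rate stays well below 1
    expect_lt(abs(ab$pi_b[r] - pi_true), 4.5 * se + 1e-9)
  }
})

test_that("buried clones are detected with lexicographic tie-break", {
  bands <- data.table::rbindlist(list(
    data.table::data.table(clone_id = "big", band_type = 1L,
                           size = (1:30) * 100L),
    data.table::data.table(clone_id = "sub", band_type = 1L,
                           size = (5:20) * 100L),
    data.table::data.table(clone_id = "far", band_type = 1L,
                           size = (100:120) * 100L)))
  db <- fingerprint_db(bands, tolerance = 0L, k_types = 1L)
  bur <- find_buried(db, q = 0.9)
  expect_equal(bur$buried, "sub")
  expect_equal(bur$host, "big")

  # identical fingerprints: larger id buried in smaller
  bands2 <- data.table::rbindlist(list(
    data.table::data.table(clone_id = "aa", band_type = 1L, size = (1:10) * 9L),
    data.table::data.table(clone_id = "bb", band_type = 1L, size = (1:10) * 9L)))
  db2 <- fingerprint_db(bands2, tolerance = 0L, k_types = 1L)
  bur2 <- find_buried(db2, q = 1)
  expect_equal(bur2$buried, "bb")
  expect_equal(bur2$host, "aa")

  # disjoint fingerprints: nothing buried
  expect_equal(nrow(find_buried(chain_db(2L, 10L, 0L))), 0L)
})

test_that("simulated nested clones are flagged buried", {
  lib <- small_sim()
  tr <- lib$truth[dropped == FALSE]
  single <- tr[, .N, by = clone_id][N == 1L, clone_id]
  iv <- tr[clone_id %in% single]
  # under the noise model the expected matched fraction of a truly
  # contained clone is tau * (1 - p_missing) ~ 0.89, so containment
  # screening needs q below that; q = 0.8 sits ~3 sigma under the mean
  bur <- find_buried(lib$fdb, q = 0.8)
  # true containments among non-chimeric retained clones
  data.table::setkey(iv, start)
  cont <- character()
  for (r in seq_len(nrow(iv))) {
    hosts <- iv[start <= iv$start[r] & end >= iv$end[r] &
                  clone_id != iv$clone_id[r]]
    if (nrow(hosts)) cont <- c(cont, iv$clone_id[r])
  }
  expect_gte(length(cont), 5)  # the fixed-seed fixture has containments
  expect_gte(mean(cont %in% bur$buried), 0.95)
})
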