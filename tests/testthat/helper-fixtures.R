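# Shared fixtures, all generated in code.

# tiny fingerprint database built by hand
toy_db <- function(tolerance = 4L) {
  bands <- data.table::rbindlist(list(
    data.table::data.table(clone_id = "cA", band_type = c(1, 1, 2),
                           size = c(120, 180, 120)),
    data.table::data.table(clone_id = "cB", band_type = c(1, 1, 2),
                           size = c(122, 181, 300)),
    data.table::data.table(clone_id = "cC", band_type = c(1, 2),
                           size = c(500, 700))))
  fingerprint_db(bands, tolerance = tolerance, k_types = 2L)
}

# random fingerprint data.table
random_bands <- function(n, k_types = 2L, universe = 200L) {
  data.table::data.table(
    band_type = sample.int(k_types, n, replace = TRUE),
    size = sample.int(universe, n, replace = TRUE))
}

# a small simulated library cached per session (simulation is the expensive
# part shared across module tests)
sim_cache <- new.env()
small_sim <- function() {
  if (is.null(sim_cache$lib)) {
    genome <- random_genome(2e6, seed = 424)
    sim_cache$lib <- simulate_clones(genome, sim_config(n_clones = 220),
                                     seed = 77)
  }
  sim_cache$lib
}

small_overlaps <- function() {
  if (is.null(sim_cache$ov)) {
    lib <- small_sim()
    db <- estimate_abundances(lib$fdb)
    sim_cache$db <- db
    sim_cache$ov <- suppressWarnings(
      compute_overlaps(db, metric_config(reps = 2e4, seed = 9)))
  }
  sim_cache$ov
}

small_db <- function() { small_overlaps(); sim_cache$db }

# deterministic chain database: clones tile a synthetic band axis so that
# consecutive clones share exactly `overlap` bands
chain_db <- function(n_clones = 6L, bands_per_clone = 30L, overlap = 20L,
                     tolerance = 0L) {
  step <- bands_per_clone - overlap
  bands <- data.table::rbindlist(lapply(seq_len(n_clones), function(i) {
    lo <- (i - 1L) * step + 1L
    data.table::data.table(clone_id = sprintf("ch%02d", i), band_type = 1L,
                           size = (lo:(lo + bands_per_clone - 1L)) * 50L)
  }))
  fingerprint_db(bands, tolerance = tolerance, k_types = 1L)
}

# overlap table built directly from specified significant pairs
manual_overlaps <- function(pairs, clones,
                            log10p = rep(-20, nrow(pairs))) {
  ov <- data.table::data.table(c1 = pmin(pairs[[1]], pairs[[2]]),
                               c2 = pmax(pairs[[1]], pairs[[2]]),
                               k_count = 10L, k_weighted = 10,
                               m = 0L, log10p = log10p,
                               significant = log10p < -12)
  data.table::setattr(ov, "clone_ids", sort(clones))
  ov
}

# igraph from an edge list, for graph-module oracles
edge_graph <- function(edges, vertices = NULL) {
  if (is.null(vertices)) vertices <- sort(unique(unlist(edges)))
  igraph::graph_from_data_frame(
    data.frame(from = edges[[1]], to = edges[[2]]),
    directed = FALSE, vertices = data.frame(name = vertices))
}
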