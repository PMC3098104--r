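# In-silico BAC library simulator. Clones are sampled between restriction
# sites of a boundary enzyme (HindIII); fingerprints are the typed bands
# produced by a multi-enzyme HICF digest: a fragment bounded by a
# protruding-end enzyme site on one side and any enzyme site / blunt-end
# site / clone end on the other yields one band per distinct protruding-end
# enzyme bounding it (so a fragment between two different protruding-end
# enzymes is counted twice). Observation noise follows a two-component
# uniform error model; scored sizes are scaled into FPC units with band
# types encoded as size offsets.

#' Simulator configuration
#'
#' Defaults emulate a cereal-genome HICF experiment: HindIII clone
#' boundaries; BamHI, EcoRI, XbaI, XhoI as the K = 4 protruding-end
#' (band-typing) enzymes; HaeIII as the blunt-end enzyme; clone lengths
#' about 120 +/- 30 kbp; 5% chimeras; band window 50..500 bp; band count
#' window 50..250; error half-widths epsilon = 0.2 bp (90%) / 3*epsilon
#' (10%); x30 FPC scaling (hence tolerance 12); 5% missing bands.
#'
#' @param n_clones clones to draw.
#' @param mean_len,sd_len target clone length moments in bp (the sampling
#'   rule uses `a = mean_len * lambda`, `sigma = sd_len * lambda` with
#'   `lambda = (N+1)/L` boundary sites per bp).
#' @param p_chimer probability a clone is chimeric (union with one more
#'   independently drawn clone; applied recursively).
#' @param boundary_enzyme,typing_enzymes,blunt_enzyme recognition motifs.
#' @param band_min,band_max retained band length window (bp).
#' @param n_min,n_max retained clone band-count window.
#' @param epsilon,p_eps error model: err ~ U(-eps, eps) w.p. `p_eps`, else
#'   U(-3 eps, 3 eps).
#' @param scale FPC scaling factor for scored sizes.
#' @param offset_unit per-type size offset in scored units.
#' @param p_missing probability a band is lost (false negative).
#' @param n_markers markers placed uniformly on the genome (0 = none);
#'   each clone covering a marker position is anchored to it.
#' @param gc GC content for generated genomes.
#' @return list of class `sim_config`; the derived FPC tolerance
#'   `round(2 * epsilon * scale)` is stored as `$tolerance`.
#' @export
sim_config <- function(n_clones = 1000L, mean_len = 120e3, sd_len = 30e3,
                       p_chimer = 0.05,
                       boundary_enzyme = "AAGCTT",
                       typing_enzymes = c(BamHI = "GGATCC", EcoRI = "GAATTC",
                                          XbaI = "TCTAGA", XhoI = "CTCGAG"),
                       blunt_enzyme = "GGCC",
                       band_min = 50L, band_max = 500L,
                       n_min = 50L, n_max = 250L,
                       epsilon = 0.2, p_eps = 0.90, scale = 30,
                       offset_unit = 5000L, p_missing = 0.05,
                       n_markers = 0L, gc = 0.44) {
  stopifnot(p_chimer >= 0, p_chimer <= 1, p_eps >= 0, p_eps <= 1,
            p_missing >= 0, p_missing <= 1, band_min < band_max, scale > 0)
  structure(list(n_clones = as.integer(n_clones), mean_len = mean_len,
                 sd_len = sd_len, p_chimer = p_chimer,
                 boundary_enzyme = boundary_enzyme,
                 typing_enzymes = typing_enzymes,
                 blunt_enzyme = blunt_enzyme,
                 band_min = as.integer(band_min),
                 band_max = as.integer(band_max),
                 n_min = as.integer(n_min), n_max = as.integer(n_max),
                 epsilon = epsilon, p_eps = p_eps, scale = scale,
                 offset_unit = as.integer(offset_unit),
                 p_missing = p_missing, n_markers = as.integer(n_markers),
                 gc = gc, tolerance = as.integer(round(2 * epsilon * scale))),
            class = "sim_config")
}

#' Generate a random genome sequence
#'
#' I.i.d. bases at the requested GC content; a desk-scale stand-in for a
#' real chromosome sequence.
#'
#' @param length sequence length in bp.
#' @param seed RNG seed (same seed, same sequence).
#' @param gc GC fraction.
#' @return a single character string of A/C/G/T.
#' @export
random_genome <- function(length, seed = NULL, gc = 0.44) {
  if (!is.null(seed)) set.seed(seed)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), length, replace = TRUE, prob = p), collapse = "")
}

#' Write / read a FASTA sequence
#' @param seq character string
#' @param path file path
#' @param name sequence name
#' @export
write_fasta <- function(seq, path, name = "synthetic") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0(">", name), con)
  writeLines(substring(seq, seq(1, nchar(seq), 70),
                       pmin(seq(70, nchar(seq) + 69, 70), nchar(seq))), con)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    s <- Biostrings::readDNAStringSet(path)
    return(as.character(s[[1]]))
  }
  lines <- readLines(path)
  paste(lines[!startsWith(lines, ">")], collapse = "")
}

#' Find restriction sites
#'
#' All (possibly overlapping) motif start positions, 1-based. For the
#' boundary enzyme the caller appends the sentinel cut positions 0 and L.
#'
#' @param seq genome string.
#' @param motif recognition sequence.
#' @return ascending integer start positions.
#' @export
find_sites <- function(seq, motif) {
  self_overlap <- {
    m <- nchar(motif)
    any(vapply(seq_len(m - 1L), function(i)
      substring(motif, 1L, i) == substring(motif, m - i + 1L, m), logical(1)))
  }
  if (self_overlap) {
    hits <- gregexpr(paste0("(?=", motif, ")"), seq, perl = TRUE)[[1]]
  } else {
    hits <- gregexpr(motif, seq, fixed = TRUE)[[1]]
  }
  if (hits[1] == -1L) integer(0) else as.integer(hits)
}

# Cut coordinates (0-based boundaries) of an enzyme: position before the
# site start; fragment between cuts i and j has length cut_j - cut_i.
cut_positions <- function(seq, motif) find_sites(seq, motif) - 1L

#' Simulate a BAC library from a genome sequence
#'
#' Clone sampling: with `R` the ordered boundary-enzyme cut set supplemented
#' by the sequence start and end, a clone picks `i_start` uniformly over
#' `0..N+1`, a direction `s = +/-1` with probability 1/2, and
#' `h = floor(Normal(a, sigma^2))` boundary steps (`a = mean_len * lambda`,
#' `sigma = sd_len * lambda`, `lambda = (N+1)/L`); `i_end = i_start + s h`
#' clipped into range (degenerate draws are redrawn). With probability
#' `p_chimer` the clone is the union of this part and one further
#' independently drawn clone (recursively). Fingerprints are computed by
#' [fingerprint_true()] and degraded by [observe()].
#'
#' @param genome genome character string (e.g. [random_genome()] or
#'   [read_fasta()]).
#' @param cfg a [sim_config()].
#' @param seed RNG seed.
#' @param fingerprints compute fingerprints? `FALSE` samples clone
#'   coordinates only (for clone-geometry parameter studies).
#' @return object of class `sim_library`: `L`, `cuts` (per-enzyme cut
#'   positions), `clones` (list: id, parts, strand, true_bands, observed,
#'   dropped reason), `truth` (data.table clone_id, part, start, end,
#'   strand, chimeric, dropped, reason), `fdb` (FingerprintDB of retained
#'   observed fingerprints), `markers`, `cfg`.
#' @export
simulate_clones <- function(genome, cfg = sim_config(), seed = 1L,
                            fingerprints = TRUE) {
  set.seed(seed)
  L <- nchar(genome)
  bcut <- cut_positions(genome, cfg$boundary_enzyme)
  if (length(bcut) < 2L) stop("fewer than 2 boundary-enzyme sites")
  R <- c(0L, bcut[bcut > 0L & bcut < L], L)   # r_0 .. r_{N+1}
  N <- length(R) - 2L
  lambda <- (N + 1) / L
  a <- cfg$mean_len * lambda; sig <- cfg$sd_len * lambda
  enz <- c(cfg$typing_enzymes, blunt = cfg$blunt_enzyme)
  cuts <- lapply(enz, function(m) cut_positions(genome, m))
  draw_part <- function() {
    repeat {
      i0 <- sample.int(N + 2L, 1L) - 1L
      s <- if (runif(1) < 0.5) 1L else -1L
      h <- floor(rnorm(1, a, sig))
      if (h <= 0) next
      i1raw <- i0 + s * h
      i1 <- max(0L, min(N + 1L, i1raw))   # clip at the sequence ends
      if (i1 == i0) next
      return(c(sort(c(R[i0 + 1L], R[i1 + 1L])), s, as.integer(i1 != i1raw)))
    }
  }
  clones <- vector("list", cfg$n_clones)
  truth <- list()
  for (ci in seq_len(cfg$n_clones)) {
    id <- sprintf("sim%05d", ci)
    parts <- list(draw_part())
    while (runif(1) < cfg$p_chimer) parts <- c(parts, list(draw_part()))
    if (fingerprints) {
      tb <- rbindlist(lapply(parts, function(p)
        fingerprint_true(p[1], p[2], cuts, cfg)))
      obs <- observe(tb, cfg)
    } else {
      tb <- data.table(type = integer(), len = integer())
      obs <- list(bands = data.table(type = integer(), size = integer()),
                  dropped = FALSE, reason = "")
    }
    clones[[ci]] <- list(id = id, parts = parts, true_bands = tb,
                         observed = obs$bands, dropped = obs$dropped,
                         reason = obs$reason)
    truth[[ci]] <- data.table(clone_id = id,
                              part = seq_along(parts),
                              start = vapply(parts, `[`, numeric(1), 1L),
                              end = vapply(parts, `[`, numeric(1), 2L),
                              strand = vapply(parts, `[`, numeric(1), 3L),
                              clipped = vapply(parts, `[`, numeric(1),
                                               4L) > 0,
                              chimeric = length(parts) > 1L,
                              dropped = obs$dropped,
                              reason = obs$reason)
  }
  truth <- rbindlist(truth)
  kept <- !vapply(clones, `[[`, logical(1), "dropped")
  bands <- rbindlist(lapply(clones[kept], function(cl)
    data.table(clone_id = cl$id, band_type = cl$observed$type,
               size = cl$observed$size)))
  markers <- NULL
  if (cfg$n_markers > 0L) {
    mpos <- sort(sample.int(L, cfg$n_markers))
    mk <- truth[dropped == FALSE]
    anchors <- rbindlist(lapply(seq_along(mpos), function(mi) {
      hit <- mk[start <= mpos[mi] & end >= mpos[mi], unique(clone_id)]
      if (length(hit)) data.table(clone_id = hit,
                                  marker_id = sprintf("mrk%04d", mi))
    }))
    markers <- if (nrow(anchors)) anchors else NULL
  }
  fdb <- fingerprint_db(bands, tolerance = cfg$tolerance,
                        k_types = length(cfg$typing_enzymes),
                        markers = markers)
  structure(list(L = L, N_boundary = N, cuts = c(list(boundary = bcut), cuts),
                 clones = clones, truth = truth, fdb = fdb,
                 markers = markers, cfg = cfg, seed = seed),
            class = "sim_library")
}

#' True fingerprint of a clone part
#'
#' Splits the interval `[lo, hi)` at every enzyme cut and the clone ends;
#' each fragment contributes one band per distinct protruding-end (typing)
#' enzyme bounding it. Fragments bounded only by the blunt enzyme or clone
#' ends yield no band. Bands outside the `[band_min, band_max]` window are
#' filtered out.
#'
#' @param lo,hi clone part boundaries (0-based cut coordinates).
#' @param cuts named list of cut positions per enzyme (typing enzymes first,
#'   then `blunt`).
#' @param cfg a [sim_config()].
#' @return data.table (`type` integer, `len` bp).
#' @export
fingerprint_true <- function(lo, hi, cuts, cfg) {
  ntyp <- length(cfg$typing_enzymes)
  pos <- c(lo, hi); lab <- c(0L, 0L)          # 0 = clone end / blunt
  for (kk in seq_len(ntyp)) {
    p <- cuts[[kk]]
    p <- p[p > lo & p < hi]
    pos <- c(pos, p); lab <- c(lab, rep(kk, length(p)))
  }
  pb <- cuts[["blunt"]]
  pb <- pb[pb > lo & pb < hi]
  pos <- c(pos, pb); lab <- c(lab, rep(0L, length(pb)))
  o <- order(pos, lab)
  pos <- pos[o]; lab <- lab[o]
  n <- length(pos)
  if (n < 2L) return(data.table(type = integer(), len = integer()))
  left <- lab[-n]; right <- lab[-1L]
  len <- pos[-1L] - pos[-n]
  out <- rbind(data.table(type = left, len = len),
               data.table(type = right, len = len)[right != left])
  out <- out[type > 0L & len >= cfg$band_min & len <= cfg$band_max]
  setorder(out, type, len)
  out[]
}

#' Observe a true fingerprint with scoring noise
#'
#' Each band length gains an error uniform on `(-eps, eps)` with probability
#' `p_eps`, else uniform on `(-3 eps, 3 eps)`; the scored size is
#' `round(scale * (len + err)) + (type - 1) * offset_unit`. Bands are lost
#' independently with probability `p_missing`; clones whose observed band
#' count falls outside `[n_min, n_max]` are dropped.
#'
#' @param true_bands data.table (`type`, `len`).
#' @param cfg a [sim_config()].
#' @return list: `bands` (data.table `type`, `size`), `dropped`, `reason`.
#' @export
observe <- function(true_bands, cfg) {
  nb <- nrow(true_bands)
  if (nb == 0L)
    return(list(bands = data.table(type = integer(), size = integer()),
                dropped = TRUE, reason = "no_bands"))
  wide <- runif(nb) >= cfg$p_eps
  err <- ifelse(wide, runif(nb, -3 * cfg$epsilon, 3 * cfg$epsilon),
                runif(nb, -cfg$epsilon, cfg$epsilon))
  size <- as.integer(round(cfg$scale * (true_bands$len + err))) +
    (true_bands$type - 1L) * cfg$offset_unit
  keep <- runif(nb) >= cfg$p_missing
  bands <- data.table(type = true_bands$type[keep], size = size[keep])
  n <- nrow(bands)
  if (n < cfg$n_min)
    return(list(bands = bands, dropped = TRUE, reason = "too_few_bands"))
  if (n > cfg$n_max)
    return(list(bands = bands, dropped = TRUE, reason = "too_many_bands"))
  setorder(bands, type, size)
  list(bands = bands, dropped = FALSE, reason = "")
}

#' Closed-form tolerance match probability
#'
#' Probability that two independent observations of the same band differ by
#' less than the tolerance `t` under the two-component uniform error model:
#' `tau = p_eps^2 (1 - (1 - t/(2 eps))^2) + p_3eps^2 (1 - (1 - t/(6 eps))^2)
#' + 2 p_eps p_3eps (t / (3 eps))` with `p_3eps = 1 - p_eps`. Valid for
#' `0 < t <= 2 eps`.
#'
#' @param epsilon narrow error half-width.
#' @param t tolerance (raw, unscaled units).
#' @param p_eps narrow-component probability.
#' @export
tolerance_match_prob <- function(epsilon, t, p_eps = 0.90) {
  if (t <= 0 || t > 2 * epsilon)
    stop("formula valid for 0 < t <= 2*epsilon")
  p3 <- 1 - p_eps
  p_eps^2 * (1 - (1 - t / (2 * epsilon))^2) +
    p3^2 * (1 - (1 - t / (6 * epsilon))^2) +
    2 * p_eps * p3 * (t / (3 * epsilon))
}

#' Summary statistics of a simulated library
#'
#' @param lib a `sim_library`.
#' @return list: sequence length, boundary site count and mean spacing,
#'   true band count and mean length, mean bands per clone (true /
#'   observed), mean clone length (true / observed, kbp), retained clones,
#'   coverage, chimera counts by part multiplicity.
#' @export
summarize_library <- function(lib) {
  tr <- lib$truth
  kept_ids <- tr[dropped == FALSE, unique(clone_id)]
  part_len <- tr[, .(len = sum(end - start), parts = .N), by = clone_id]
  nb_true <- vapply(lib$clones, function(cl) nrow(cl$true_bands), integer(1))
  nb_obs <- vapply(lib$clones, function(cl)
    if (cl$dropped) NA_integer_ else nrow(cl$observed), integer(1))
  tb <- rbindlist(lapply(lib$clones, `[[`, "true_bands"))
  nch <- tr[chimeric == TRUE, .(parts = .N), by = clone_id][, table(parts)]
  list(L = lib$L,
       n_boundary_sites = lib$N_boundary,
       mean_spacing = lib$L / (lib$N_boundary + 1),
       n_true_bands = nrow(tb),
       mean_true_band_len = if (nrow(tb)) mean(tb$len) else NA_real_,
       n_mean_true = mean(nb_true),
       n_mean_obs = mean(nb_obs, na.rm = TRUE),
       mean_clone_len_kbp = mean(part_len$len) / 1e3,
       mean_clone_len_obs_kbp =
         part_len[clone_id %in% kept_ids, mean(len)] / 1e3,
       n_clones_simulated = length(lib$clones),
       n_clones_retained = length(kept_ids),
       coverage = sum(part_len$len) / lib$L,
       n_chimeric = sum(tr[, any(chimeric), by = clone_id]$V1),
       chimera_parts = nch)
}

#' Write the simulated library in FPC-compatible form
#'
#' Emits the offset-encoded sizes file (header comment notes the scaled
#' tolerance), a ground-truth TSV (`clone_id part start end chimeric dropped
#' reason`), the true-partition TSV (`clone_id region`, regions = maximal
#' chains of genomically overlapping retained clones), and a marker TSV if
#' markers were simulated.
#'
#' @param lib a `sim_library`.
#' @param dir output directory (created).
#' @return named character vector of written paths.
#' @export
write_fpc <- function(lib, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sizes <- file.path(dir, "library.sizes")
  con <- file(sizes, "w")
  writeLines(sprintf("# simulated HICF sizes; tolerance %d (scaled units)",
                     lib$cfg$tolerance), con)
  close(con)
  con <- file(sizes, "a")
  for (cl in lib$clones) {
    if (cl$dropped) next
    sz <- cl$observed$size
    writeLines(paste(cl$id, length(sz)), con)
    writeLines(paste(c(sz, -1L), collapse = " "), con)
  }
  close(con)
  truth_path <- file.path(dir, "ground_truth.tsv")
  fwrite(lib$truth, truth_path, sep = "\t")
  part_path <- file.path(dir, "true_partition.tsv")
  fwrite(true_partition(lib), part_path, sep = "\t")
  out <- c(sizes = sizes, truth = truth_path, partition = part_path)
  if (!is.null(lib$markers)) {
    mpath <- file.path(dir, "markers.tsv")
    fwrite(lib$markers, mpath, sep = "\t", col.names = FALSE)
    out <- c(out, markers = mpath)
  }
  out
}

#' True partition of retained clones into genomic regions
#'
#' Regions are maximal groups of retained clones whose genomic intervals
#' chain together (transitive overlap).
#' @param lib a `sim_library`.
#' @return data.table (`clone_id`, `region`).
#' @export
true_partition <- function(lib) {
  tr <- lib$truth[dropped == FALSE]
  iv <- tr[, .(clone_id, start, end)]
  setorder(iv, start)
  reg <- integer(nrow(iv)); cur <- 1L; maxend <- iv$end[1]
  for (r in seq_len(nrow(iv))) {
    if (iv$start[r] > maxend) { cur <- cur + 1L; maxend <- iv$end[r] }
    reg[r] <- cur
    maxend <- max(maxend, iv$end[r])
  }
  iv[, region := reg]
  unique(iv[, .(region = min(region)), by = clone_id])
}
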