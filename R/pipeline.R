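# Pipeline orchestration: the end-to-end assembly run (overlaps -> TENPP /
# adaptive clustering -> linearity split -> ordering -> merging -> MTP) and
# the simulate / verify / compare entry points mirrored by the command-line
# dispatcher in inst/scripts/assembly-tools.R.

#' Assemble contigs from a fingerprint database
#'
#' Runs the full pipeline: estimate band abundances, compute all pairwise
#' overlap p-values, cluster with the adaptive cutoff scheme (TENPP inside
#' large clusters), split non-linear clusters, order each contig by the
#' open-path TSP criterion (buried clones detached first and re-attached to
#' their host), optionally assess order stability by jackknife, merge
#' contigs through the exclusion pools at the relaxed initial cutoff, and
#' select minimal tiling paths.
#'
#' @param db a `FingerprintDB` (e.g. from [read_sizes()]).
#' @param cfg a [metric_config()].
#' @param schedule a [cluster_schedule()].
#' @param bury_q burial threshold used to detach buried clones before
#'   ordering (`NULL` disables burial handling).
#' @param jackknife_replicates 0 disables stability analysis.
#' @param merge merge contigs through exclusion pools afterwards?
#' @param seed seed for ordering restarts and jackknife.
#' @param restarts TSP restarts.
#' @param min_contig smallest cluster ordered as a contig.
#' @param overlaps optionally a precomputed `overlap_set` for `db`.
#' @param order_metric metric supplying the TSP edge weights (default
#'   `"sulston"`: the analytic tail is smooth in the band counts, which
#'   avoids the per-cell noise of the Monte-Carlo-calibrated tails in the
#'   ordering criterion; significance calls stay with `cfg$metric`).
#' @return list of class `assembly_result`: `partition`, `overlaps`,
#'   `contigs` (named list of `contig_order`), `mtps`, `stability` and
#'   `skeletons` (when jackknifing is enabled: per contig the stability
#'   report and the stable skeleton order with unstable clones attached),
#'   `merges`, `ambiguous`, `excluded`, `cfg`, `schedule`.
#' @export
run_assemble <- function(db, cfg = metric_config(),
                         schedule = cluster_schedule(pr0 = cfg$pr0),
                         bury_q = 0.9, jackknife_replicates = 0L,
                         merge = TRUE, seed = 1L, restarts = 10L,
                         min_contig = schedule$rs_min, overlaps = NULL,
                         order_metric = "sulston") {
  if (db_n_clones(db) == 0L) stop("empty fingerprint database")
  db <- estimate_abundances(db)
  if (is.null(overlaps)) overlaps <- compute_overlaps(db, cfg)
  partition <- adaptive_cluster(db, overlaps, schedule, bury_q = bury_q)
  excl_edges <- attr(partition, "excluded_edges")
  cutoffs <- attr(partition, "cluster_cutoffs")
  part <- as.data.table(partition)
  # buried clones: detached before ordering, re-attached afterwards
  buried <- part[startsWith(state, "BURIED:")]
  contigs <- list(); stability <- list(); mtps <- list()
  ordered_ids <- part[state %in% c("FROZEN", "SMALL", "UNRESOLVED")]
  for (cid in unique(ordered_ids$cluster_id)) {
    all_members <- part[cluster_id == cid, clone_id]
    members <- part[cluster_id == cid & !startsWith(state, "BURIED:"),
                    clone_id]
    cutoff <- cutoffs[[cid]]
    if (is.null(cutoff)) cutoff <- cfg$pr0
    # cluster size counts buried clones: they return after ordering
    if (length(all_members) < min_contig || length(members) < 2L) next
    og <- build_graph(overlaps, cutoff, clones = members,
                      exclude_edges = excl_edges)
    sp <- split_nonlinear(og$g)
    pi <- 0L
    for (partids in sp$parts) {
      if (length(partids) < 2L) next
      pi <- pi + 1L
      name <- if (length(sp$parts) > 1L) paste0(cid, ".", pi) else cid
      dist <- tsp_distances(partids, overlaps, cutoff,
                            weight_metric = order_metric)
      co <- order_clones(partids, dist, seed = seed, restarts = restarts)
      contigs[[name]] <- co
    }
  }
  merges <- data.table(); ambiguous <- data.table()
  if (merge && length(contigs) > 1L) {
    assigned <- unlist(lapply(contigs, `[[`, "order"))
    pool <- setdiff(db$clone_ids, c(assigned, buried$clone_id))
    el <- elongate(contigs, pool, overlaps, pr0 = cfg$pr0, seed = seed,
                   restarts = restarts, order_metric = order_metric)
    contigs <- el$contigs
    merges <- el$merges
    ambiguous <- el$ambiguous
  }
  # re-admit temporarily excluded clones whose significant overlaps all
  # point into one local window of a single contig: they are parallel /
  # locally redundant clones, attached without entering the order. A
  # clone whose links spread over distant windows (putative chimera)
  # stays out.
  attached <- data.table(clone_id = character(), cluster_id = character(),
                         host = character())
  if (merge && length(contigs)) {
    assigned <- unlist(lapply(contigs, `[[`, "order"))
    posmap <- rbindlist(lapply(names(contigs), function(nm)
      data.table(clone_id = contigs[[nm]]$order, contig = nm,
                 pos = seq_along(contigs[[nm]]$order))))
    pool <- setdiff(db$clone_ids, c(assigned, buried$clone_id))
    sig <- as.data.table(overlaps)[log10p < log10(cfg$pr0)]
    links <- rbind(sig[c1 %in% pool, .(clone_id = c1, other = c2, log10p)],
                   sig[c2 %in% pool, .(clone_id = c2, other = c1, log10p)])
    links <- links[posmap, on = c(other = "clone_id"), nomatch = NULL]
    if (nrow(links)) {
      for (cl in unique(links$clone_id)) {
        lk <- links[clone_id == cl]
        top <- lk[, .N, by = contig][order(-N)][1]
        lk <- lk[contig == top$contig]
        if (nrow(lk) < 2L) next
        span <- max(lk$pos) - min(lk$pos)
        if (span > max(6L, 2L * nrow(lk))) next  # non-local: keep out
        attached <- rbind(attached,
                          data.table(clone_id = cl, cluster_id = top$contig,
                                     host = lk[order(log10p), other][1L]))
      }
    }
  }
  # order stability and skeleton maps on the final contigs
  skeletons <- list()
  if (jackknife_replicates >= 10L) {
    for (name in names(contigs)) {
      ids <- contigs[[name]]$order
      if (length(ids) < 4L) next
      stability[[name]] <- jackknife(db, ids, overlaps,
                                     replicates = jackknife_replicates,
                                     seed = seed,
                                     order_metric = order_metric)
      dist <- tsp_distances(ids, overlaps, cfg$pr0,
                            weight_metric = order_metric)
      skeletons[[name]] <- skeleton_order(contigs[[name]],
                                          stability[[name]], dist,
                                          seed = seed, restarts = restarts)
    }
  }
  for (name in names(contigs)) {
    ids <- contigs[[name]]$order
    og <- build_graph(overlaps, cfg$pr0, clones = ids)
    if (igraph::components(og$g)$no == 1L)
      mtps[[name]] <- select_mtp(og, contigs[[name]])
  }
  # final partition table including split/merged contig names
  final <- rbindlist(lapply(names(contigs), function(nm)
    data.table(clone_id = contigs[[nm]]$order, cluster_id = nm,
               state = "CONTIG")))
  if (nrow(attached))
    final <- rbind(final, attached[, .(clone_id, cluster_id,
                                       state = "ATTACHED")])
  rest <- part[!clone_id %in% final$clone_id,
               .(clone_id, cluster_id, state)]
  # re-attach buried clones to their host's contig where known
  if (nrow(buried)) {
    hosts <- sub("^BURIED:", "", buried$state)
    hc <- final$cluster_id[match(hosts, final$clone_id)]
    fix <- !is.na(hc) & buried$clone_id %in% rest$clone_id
    if (any(fix)) {
      upd <- data.table(clone_id = buried$clone_id[fix], cluster_id = hc[fix],
                        state = "BURIED")
      rest <- rest[!clone_id %in% upd$clone_id]
      final <- rbind(final, upd)
    }
  }
  structure(list(partition = rbind(final, rest), overlaps = overlaps,
                 contigs = contigs, mtps = mtps, stability = stability,
                 skeletons = skeletons,
                 merges = merges, ambiguous = ambiguous,
                 excluded = list(edges = excl_edges,
                                 vertices = part[state == "EXCLUDED",
                                                 clone_id]),
                 adaptive = partition, cfg = cfg, schedule = schedule),
            class = "assembly_result")
}

#' @export
print.assembly_result <- function(x, ...) {
  npart <- x$partition[state == "CONTIG", uniqueN(cluster_id)]
  cat(sprintf(paste0("assembly_result: %d contigs (%d clones of %d), ",
                     "%d merges, %d TENPP-excluded clones\n"),
              npart, x$partition[state %in% c("CONTIG", "BURIED"), .N],
              nrow(x$partition), nrow(x$merges),
              length(x$excluded$vertices)))
  invisible(x)
}

#' Write assembly outputs
#'
#' Order TSV (`cluster_id position clone_id gap_after instability`),
#' partition TSV, MTP TSV, exclusion report, history log.
#' @param result an `assembly_result`.
#' @param dir output directory.
#' @export
write_assembly <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ord <- rbindlist(lapply(names(result$contigs), function(nm) {
    co <- result$contigs[[nm]]
    n <- length(co$order)
    inst <- rep(NA_real_, n)
    if (nm %in% names(result$stability))
      inst <- unname(result$stability[[nm]]$instability[co$order])
    data.table(cluster_id = nm, position = seq_len(n), clone_id = co$order,
               gap_after = as.integer(seq_len(n) %in% co$gaps),
               instability = inst)
  }))
  fwrite(ord, file.path(dir, "orders.tsv"), sep = "\t")
  fwrite(result$partition, file.path(dir, "partition.tsv"), sep = "\t")
  mtp <- rbindlist(lapply(names(result$mtps), function(nm)
    data.table(cluster_id = nm, position = seq_along(result$mtps[[nm]]$clones),
               clone_id = result$mtps[[nm]]$clones)))
  if (nrow(mtp)) fwrite(mtp, file.path(dir, "mtp.tsv"), sep = "\t")
  fwrite(result$excluded$edges, file.path(dir, "excluded_edges.tsv"),
         sep = "\t")
  writeLines(jsonlite::toJSON(attr(result$adaptive, "history"),
                              dataframe = "rows", auto_unbox = TRUE),
             file.path(dir, "history.json"))
  invisible(dir)
}

#' Simulate a library and write it out
#'
#' @param out_dir output directory.
#' @param genome_length length of the generated genome (ignored when
#'   `fasta` is given).
#' @param fasta optional FASTA file with a real sequence.
#' @param cfg a [sim_config()].
#' @param seed RNG seed (genome seed is derived).
#' @return the `sim_library` (invisibly, with paths in `$paths`).
#' @export
run_simulate <- function(out_dir, genome_length = 1e7, fasta = NULL,
                         cfg = sim_config(), seed = 1L) {
  genome <- if (!is.null(fasta)) read_fasta(fasta)
            else random_genome(genome_length, seed = seed, gc = cfg$gc)
  lib <- simulate_clones(genome, cfg, seed = seed + 1L)
  paths <- write_fpc(lib, out_dir)
  sm <- summarize_library(lib)
  writeLines(jsonlite::toJSON(sm[!vapply(sm, inherits, logical(1), "table")],
                              auto_unbox = TRUE, digits = NA),
             file.path(out_dir, "summary.json"))
  lib$paths <- c(paths, summary = file.path(out_dir, "summary.json"))
  invisible(lib)
}

#' Verify external contigs from files
#'
#' @param sizes_path FPC sizes file.
#' @param contigs_path assignment TSV (`contig_id clone_id [position]`).
#' @param cfg a [metric_config()].
#' @param ... passed to [read_sizes()].
#' @export
run_verify <- function(sizes_path, contigs_path, cfg = metric_config(),
                       ...) {
  db <- read_sizes(sizes_path, tolerance = cfg$tolerance, ...)
  verify_contigs(read_assignment(contigs_path), db, cfg)
}

#' Compare two partitions from files
#'
#' @param path_a,path_b assignment TSVs.
#' @return list with the Rand index and both mean-overlap directions.
#' @export
run_compare <- function(path_a, path_b) {
  a <- read_assignment(path_a); b <- read_assignment(path_b)
  shared <- intersect(a$clone_id, b$clone_id)
  if (length(shared) < 2L) stop("partitions share fewer than 2 clones")
  list(rand_index = rand_index(a, b),
       mean_overlap_ab = mean_overlap(a, b),
       mean_overlap_ba = mean_overlap(b, a),
       n_shared_clones = length(shared))
}
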