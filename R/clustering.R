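# Clone clustering. Single-linkage clustering at a p-value cutoff is exactly
# the connected components of the net of significant overlaps at that cutoff.
# The adaptive scheme starts from a liberal cutoff, lets TENPP remove
# putative false overlaps and chimeric clones inside large clusters, freezes
# reasonably sized ("rs") clusters, and tightens the cutoff on whatever
# remains large - protecting good clusters from dissolving under stringency
# they do not need.

#' Clustering schedule
#'
#' @param pr0 initial (liberal) cutoff; default 1e-12.
#' @param step stringency multiplier per round; default 1e-3.
#' @param max_rounds cap on rounds.
#' @param rs_min,rs_max reasonable-size cluster bounds (6..500 by default).
#' @param large_threshold clusters above this size get TENPP and further
#'   rounds (default = `rs_max`).
#' @export
cluster_schedule <- function(pr0 = 1e-12, step = 1e-3, max_rounds = 10L,
                             rs_min = 6L, rs_max = 500L,
                             large_threshold = rs_max) {
  stopifnot(step < 1, pr0 < 1, rs_min >= 2, rs_max >= rs_min)
  structure(list(pr0 = pr0, step = step, max_rounds = as.integer(max_rounds),
                 rs_min = as.integer(rs_min), rs_max = as.integer(rs_max),
                 large_threshold = as.integer(large_threshold)),
            class = "cluster_schedule")
}

#' Single-linkage clustering at a cutoff
#'
#' Clusters are the connected components of the graph whose edges are the
#' overlaps significant at `cutoff` (the single-linkage / threshold-graph
#' equivalence). Cluster ids are deterministic: the smallest member id.
#'
#' @param overlaps an `overlap_set`.
#' @param cutoff p-value cutoff.
#' @param clones clone universe (default: all clones of the overlap set).
#' @param exclude_edges overlaps to ignore (e.g. TENPP-excluded).
#' @return data.table (`clone_id`, `cluster_id`, `size`).
#' @export
single_linkage <- function(overlaps, cutoff, clones = NULL,
                           exclude_edges = NULL) {
  og <- build_graph(overlaps, cutoff, clones = clones,
                    exclude_edges = exclude_edges)
  partition_from_graph(og$g)
}

partition_from_graph <- function(g) {
  if (igraph::vcount(g) == 0L)
    return(data.table(clone_id = character(), cluster_id = character(),
                      size = integer()))
  comp <- igraph::components(g)
  dt <- data.table(clone_id = igraph::V(g)$name,
                   comp = comp$membership)
  dt[, cluster_id := min(clone_id), by = comp]
  dt[, size := .N, by = comp]
  setorder(dt, cluster_id, clone_id)
  dt[, .(clone_id, cluster_id, size)]
}

#' Adaptive-cutoff clustering
#'
#' Round `r` (cutoff `Pr_r = pr0 * step^(r-1)`): (1) build the net of
#' significant overlaps over the still-unfrozen clones, omitting previously
#' excluded elements; (2) apply [tenpp()] within components larger than the
#' large-cluster threshold; (3) recompute components; (4) freeze components
#' of reasonable size (rs_min..rs_max); (5) leave smaller components and
#' singletons unfrozen; (6) tighten the cutoff and repeat while large
#' components remain. Frozen clusters never change afterwards. If the
#' schedule is exhausted with large clusters remaining these are flagged
#' `UNRESOLVED`.
#'
#' @param db a `FingerprintDB` (used for the clone universe and optional
#'   burial handling).
#' @param overlaps an `overlap_set` over `db`.
#' @param schedule a [cluster_schedule()].
#' @param lmin,lmax TENPP parallel-path bounds.
#' @param bury_q if non-`NULL`, buried clones (threshold `bury_q`) are
#'   removed before clustering and re-attached to their host's cluster.
#' @return object of class `clone_partition`: data.table (`clone_id`,
#'   `cluster_id`, `state`, `round`), attributes `history` (per-round log),
#'   `excluded_edges`, `cluster_cutoffs` (freeze cutoff per cluster),
#'   `schedule`.
#' @export
adaptive_cluster <- function(db, overlaps, schedule = cluster_schedule(),
                             lmin = 2L, lmax = 5L, bury_q = NULL) {
  clones <- db$clone_ids
  buried_map <- NULL
  if (!is.null(bury_q)) {
    bur <- find_buried(db, bury_q)
    if (nrow(bur)) {
      # resolve burial chains (a buried clone's host may itself be buried)
      host <- setNames(bur$host, bur$buried)
      for (it in seq_len(nrow(bur))) {
        chained <- bur$host %in% bur$buried
        if (!any(chained)) break
        bur[chained, host := host[bur$host[chained]]]
      }
      buried_map <- bur
      clones <- setdiff(clones, bur$buried)
    }
  }
  active <- clones
  excl_edges <- data.table(c1 = character(), c2 = character(),
                           reason = character())
  rows <- list(); history <- list()
  cluster_cutoffs <- list()
  cutoff <- schedule$pr0
  r <- 0L
  repeat {
    r <- r + 1L
    og <- build_graph(overlaps, cutoff, clones = active,
                      exclude_edges = excl_edges)
    part <- partition_from_graph(og$g)
    excl_v_round <- character()
    # round 1: the whole net is tested against parallel paths before any
    # clustering; later rounds re-apply TENPP only inside clusters that
    # are still too large for freezing
    large_ids <- if (r == 1L) unique(part[size > 1L, cluster_id])
                 else unique(part[size > schedule$large_threshold,
                                  cluster_id])
    for (cid in large_ids) {
      memb <- part[cluster_id == cid, clone_id]
      sub <- igraph::induced_subgraph(og$g, memb)
      sog <- structure(list(g = sub, pr0 = cutoff,
                            excluded_vertices = character(),
                            excluded_edges = data.table(c1 = character(),
                                                        c2 = character(),
                                                        reason = character())),
                       class = "overlap_graph")
      filt <- tenpp(sog, lmin, lmax)
      excl_edges <- rbind(excl_edges, filt$excluded_edges)
      if (length(filt$excluded_vertices)) {
        excl_v_round <- c(excl_v_round, filt$excluded_vertices)
        excl_edges <- rbind(excl_edges,
                            data.table(c1 = character(), c2 = character(),
                                       reason = character()))
      }
    }
    if (length(excl_v_round)) {
      active <- setdiff(active, excl_v_round)
      rows[[length(rows) + 1L]] <-
        data.table(clone_id = excl_v_round, cluster_id = NA_character_,
                   state = "EXCLUDED", round = r)
    }
    # recompute components after exclusions
    og <- build_graph(overlaps, cutoff, clones = active,
                      exclude_edges = excl_edges)
    part <- partition_from_graph(og$g)
    frozen <- part[size >= schedule$rs_min & size <= schedule$rs_max]
    if (nrow(frozen)) {
      rows[[length(rows) + 1L]] <-
        frozen[, .(clone_id, cluster_id, state = "FROZEN", round = r)]
      for (cid in unique(frozen$cluster_id)) cluster_cutoffs[[cid]] <- cutoff
      active <- setdiff(active, frozen$clone_id)
    }
    n_large <- part[size > schedule$rs_max, uniqueN(cluster_id)]
    history[[r]] <- data.table(round = r, cutoff = cutoff,
                               frozen_clusters = uniqueN(frozen$cluster_id),
                               frozen_clones = nrow(frozen),
                               excluded_clones = length(excl_v_round),
                               large_left = n_large)
    if (n_large == 0L || r >= schedule$max_rounds) break
    cutoff <- cutoff * schedule$step
  }
  # leftovers at the final cutoff: small clusters / singletons / unresolved
  og <- build_graph(overlaps, cutoff, clones = active,
                    exclude_edges = excl_edges)
  part <- partition_from_graph(og$g)
  if (nrow(part)) {
    part[, state := ifelse(size > schedule$rs_max, "UNRESOLVED",
                           ifelse(size == 1L, "SINGLETON", "SMALL"))]
    rows[[length(rows) + 1L]] <- part[, .(clone_id, cluster_id, state,
                                          round = r)]
    for (cid in unique(part$cluster_id)) cluster_cutoffs[[cid]] <- cutoff
  }
  out <- rbindlist(rows)
  # re-attach buried clones to their host's cluster
  if (!is.null(buried_map)) {
    hostrow <- out[match(buried_map$host, clone_id)]
    add <- data.table(clone_id = buried_map$buried,
                      cluster_id = hostrow$cluster_id,
                      state = ifelse(is.na(hostrow$cluster_id), "EXCLUDED",
                                     paste0("BURIED:", buried_map$host)),
                      round = hostrow$round)
    out <- rbind(out, add)
  }
  setorder(out, cluster_id, clone_id, na.last = TRUE)
  setattr(out, "history", rbindlist(history))
  setattr(out, "excluded_edges", excl_edges)
  setattr(out, "cluster_cutoffs", cluster_cutoffs)
  setattr(out, "schedule", schedule)
  setattr(out, "class", c("clone_partition", class(out)))
  out[]
}

#' Write a partition TSV (`clone_id cluster_id state round`)
#' @param partition a `clone_partition`
#' @param path output TSV
#' @export
write_partition <- function(partition, path) {
  fwrite(as.data.table(partition), path, sep = "\t")
  invisible(path)
}

#' Read an external contig/cluster assignment TSV
#'
#' Expected columns: `contig_id`, `clone_id` and optionally `position`.
#' @param path TSV path (with or without header).
#' @export
read_assignment <- function(path) {
  a <- fread(path)
  if (!"contig_id" %in% names(a)) {
    if ("cluster_id" %in% names(a)) {
      setnames(a, "cluster_id", "contig_id")
    } else if ("clone_id" %in% names(a)) {
      # header present but group column named otherwise (e.g. "region")
      grp <- setdiff(names(a), c("clone_id", "position"))[1L]
      setnames(a, grp, "contig_id")
    } else {
      setnames(a, seq_len(min(3L, ncol(a))),
               c("contig_id", "clone_id",
                 "position")[seq_len(min(3L, ncol(a)))])
    }
  }
  a[, contig_id := as.character(contig_id)]
  a[, clone_id := as.character(clone_id)]
  a[]
}
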