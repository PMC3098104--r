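# Contig elongation and merging, minimal tiling path (MTP) selection, and
# verification of externally supplied contigs. Merging re-admits the clones
# and overlaps temporarily excluded earlier (TENPP pools, singletons):
# contigs displaying significant end-to-end overlaps - possibly via one or
# two intermediate clones - are merged if the union keeps a linear topology
# and no marker-zone conflict arises; ambiguous branching elongations are
# reported, never auto-resolved.

#' Select the minimal tiling path of a contig
#'
#' The MTP is the shortest path, in edge count, between the contig's two
#' terminal clones on the net of significant overlaps; among shortest paths
#' the one with the largest summed edge weight is preferred. By
#' construction the MTP contains the terminal clones, every adjacent MTP
#' pair overlaps significantly, and no shorter qualifying chain exists.
#'
#' @param og an `overlap_graph` restricted to the contig's clones.
#' @param order a `contig_order` (or character vector); its endpoints are
#'   the terminal clones.
#' @return object of class `mtp`: `clones` (ordered ids), `log10p`
#'   (adjacent p-values, from edge weights).
#' @export
select_mtp <- function(og, order) {
  g <- if (inherits(og, "overlap_graph")) og$g else og
  ids <- if (inherits(order, "contig_order")) order$order else order
  from <- ids[1L]; to <- ids[length(ids)]
  stopifnot(all(c(from, to) %in% igraph::V(g)$name))
  if (from == to)
    return(structure(list(clones = from, log10p = numeric()), class = "mtp"))
  dfrom <- igraph::distances(g, v = from, weights = NA)[1, ]
  if (!is.finite(dfrom[to]))
    stop("terminal clones ", from, " and ", to,
         " are disconnected; split the contig first")
  L <- dfrom[to]
  dto <- igraph::distances(g, v = to, weights = NA)[1, ]
  nm <- igraph::V(g)$name
  onpath <- dfrom + dto == L  # vertices on some shortest path
  # DP over BFS layers: maximize summed edge weight among shortest paths
  best <- setNames(rep(-Inf, length(nm)), nm)
  prev <- setNames(rep(NA_character_, length(nm)), nm)
  best[from] <- 0
  el <- igraph::as_edgelist(g)
  w <- igraph::E(g)$weight
  if (is.null(w)) w <- rep(1, nrow(el))
  ed <- data.table(a = el[, 1], b = el[, 2], w = w)
  ed <- rbind(ed, ed[, .(a = b, b = a, w)])
  ed <- ed[onpath[a] & onpath[b] & dfrom[b] == dfrom[a] + 1]
  setorder(ed, a, b)
  for (lev in seq_len(L)) {
    step <- ed[dfrom[a] == lev - 1]
    if (nrow(step) == 0L) break
    for (r in seq_len(nrow(step))) {
      cand <- best[step$a[r]] + step$w[r]
      if (cand > best[step$b[r]]) {
        best[step$b[r]] <- cand
        prev[step$b[r]] <- step$a[r]
      }
    }
  }
  path <- to
  while (path[1L] != from) path <- c(prev[path[1L]], path)
  structure(list(clones = unname(path),
                 log10p = -vapply(seq_len(length(path) - 1L), function(i) {
                   ed[a == path[i] & b == path[i + 1L], w][1L]
                 }, numeric(1))),
            class = "mtp")
}

contig_ends <- function(order) {
  ids <- if (inherits(order, "contig_order")) order$order else order
  c(ids[1L], ids[length(ids)])
}

#' Elongate and merge contigs via temporarily excluded elements
#'
#' Re-admits the exclusion pools (TENPP-excluded clones, singletons, small
#' leftovers) and the full overlap set at a relaxed cutoff. Two contigs are
#' merge candidates when an end clone of one connects to an end clone of the
#' other directly or through at most `max_intermediates` pool clones. A
#' merge is applied only if (a) neither end has competing candidates
#' (ambiguous branchings are reported, not resolved), (b) the merged clone
#' set stays topologically linear, and (c) no marker-zone conflict arises.
#' Accepted merges are reordered. Pool clones adjacent to a single contig
#' end are attached as singleton elongations under the same rules.
#'
#' @param contigs named list of `contig_order` (or id vectors).
#' @param pool character vector of re-admissible clone ids.
#' @param overlaps the full `overlap_set`.
#' @param pr0 relaxed cutoff for merging.
#' @param zones optional data.table (`clone_id`, `zone`); contigs carrying
#'   different zone labels are never merged.
#' @param max_intermediates intermediate pool clones allowed in a junction.
#' @param seed,restarts passed to reordering.
#' @param order_metric weight metric for reordering (see [tsp_distances()]).
#' @return list: `contigs` (updated named list), `merges` (log data.table),
#'   `ambiguous` (data.table of reported, unapplied elongations).
#' @export
elongate <- function(contigs, pool, overlaps, pr0, zones = NULL,
                     max_intermediates = 2L, seed = 1L, restarts = 10L,
                     order_metric = NULL) {
  stopifnot(is.list(contigs))
  if (is.null(names(contigs)))
    names(contigs) <- paste0("ctg", seq_along(contigs))
  merges <- data.table(from = character(), to = character(),
                       via = character())
  ambiguous <- data.table(contig = character(), end = character(),
                          candidates = character())
  zone_of <- function(ids) {
    if (is.null(zones)) return(character())
    sort(unique(zones[clone_id %in% ids, zone]))
  }
  repeat {
    all_ids <- unlist(lapply(contigs, function(x)
      if (inherits(x, "contig_order")) x$order else x))
    pool_use <- setdiff(pool, all_ids)
    og <- build_graph(overlaps, pr0, clones = c(all_ids, pool_use))
    g <- og$g
    # candidate end-to-end connections
    ends <- rbindlist(lapply(names(contigs), function(nm) {
      e <- contig_ends(contigs[[nm]])
      data.table(contig = nm, end = c("5p", "3p"), clone = unique(e))
    }))
    member_of <- setNames(rep(names(contigs), vapply(contigs, function(x)
      length(if (inherits(x, "contig_order")) x$order else x), integer(1))),
      all_ids)
    cands <- list()
    for (r in seq_len(nrow(ends))) {
      src <- ends$clone[r]
      # bounded search: neighbors within max_intermediates+1 edges through
      # pool clones only
      frontier <- src; seen <- src
      via <- setNames(list(character()), src)
      for (depth in seq_len(max_intermediates + 1L)) {
        nxt <- character()
        for (v in frontier) {
          nbs <- igraph::V(g)$name[as.integer(igraph::neighbors(g, v))]
          for (w in setdiff(nbs, seen)) {
            via[[w]] <- c(via[[v]], if (v != src) v)
            tgt <- member_of[w]
            if (!is.na(tgt) && tgt != ends$contig[r]) {
              # must hit the OTHER contig at one of its ends
              if (w %in% contig_ends(contigs[[tgt]]))
                cands[[length(cands) + 1L]] <-
                  data.table(contig = ends$contig[r], end = ends$end[r],
                             clone = src, target = tgt, hit = w,
                             via = paste(via[[w]], collapse = ","))
              next
            }
            if (is.na(tgt) && depth <= max_intermediates) {
              nxt <- c(nxt, w); seen <- c(seen, w)
            }
          }
        }
        frontier <- unique(nxt)
        if (!length(frontier)) break
      }
    }
    cands <- if (length(cands)) unique(rbindlist(cands)) else NULL
    applied <- FALSE
    if (!is.null(cands) && nrow(cands)) {
      # ambiguity: an end connecting to more than one other contig
      amb <- cands[, .(n_targets = uniqueN(target)), by = .(contig, end)]
      amb <- amb[n_targets > 1L]
      if (nrow(amb)) {
        for (r in seq_len(nrow(amb))) {
          cc <- cands[contig == amb$contig[r] & end == amb$end[r]]
          ambiguous <- rbind(ambiguous,
                             data.table(contig = amb$contig[r],
                                        end = amb$end[r],
                                        candidates = paste(unique(cc$target),
                                                           collapse = ",")))
        }
        cands <- cands[!amb, on = c("contig", "end")]
      }
      if (nrow(cands)) {
        for (r in seq_len(nrow(cands))) {
          a <- cands$contig[r]; b <- cands$target[r]
          if (!(a %in% names(contigs)) || !(b %in% names(contigs))) next
          ia <- if (inherits(contigs[[a]], "contig_order"))
            contigs[[a]]$order else contigs[[a]]
          ib <- if (inherits(contigs[[b]], "contig_order"))
            contigs[[b]]$order else contigs[[b]]
          za <- zone_of(ia); zb <- zone_of(ib)
          if (length(za) && length(zb) && !identical(za, zb)) next
          via_cl <- setdiff(strsplit(cands$via[r], ",")[[1]], "")
          merged <- c(ia, ib, via_cl)
          sub <- igraph::induced_subgraph(g, merged)
          if (igraph::components(sub)$no > 1L) next
          lc <- linearity_check(sub)
          if (!lc$is_linear) next
          dist <- tsp_distances(merged, overlaps, pr0,
                                weight_metric = order_metric)
          co <- order_clones(merged, dist, seed = seed, restarts = restarts)
          contigs[[a]] <- co
          contigs[[b]] <- NULL
          merges <- rbind(merges, data.table(from = b, to = a,
                                             via = cands$via[r]))
          applied <- TRUE
          break  # rebuild bookkeeping after each merge
        }
      }
    }
    if (!applied) break
  }
  # singleton elongation: pool clones adjacent to exactly one contig end
  all_ids <- unlist(lapply(contigs, function(x)
    if (inherits(x, "contig_order")) x$order else x))
  pool_use <- setdiff(pool, all_ids)
  if (length(pool_use)) {
    og <- build_graph(overlaps, pr0, clones = c(all_ids, pool_use))
    g <- og$g
    for (nm in names(contigs)) {
      ids <- if (inherits(contigs[[nm]], "contig_order"))
        contigs[[nm]]$order else contigs[[nm]]
      for (endcl in contig_ends(ids)) {
        nbs <- intersect(igraph::V(g)$name[
          as.integer(igraph::neighbors(g, endcl))], pool_use)
        for (w in nbs) {
          cand <- c(ids, w)
          sub <- igraph::induced_subgraph(g, cand)
          if (igraph::components(sub)$no > 1L) next
          lc <- linearity_check(sub)
          if (!lc$is_linear) next
          dist <- tsp_distances(cand, overlaps, pr0,
                                weight_metric = order_metric)
          co <- order_clones(cand, dist, seed = seed, restarts = restarts)
          if (length(co$gaps) > 0L) next
          contigs[[nm]] <- co
          ids <- co$order
          pool_use <- setdiff(pool_use, w)
          merges <- rbind(merges, data.table(from = w, to = nm,
                                             via = "singleton"))
        }
      }
    }
  }
  list(contigs = contigs, merges = merges, ambiguous = ambiguous)
}

#' Verify externally supplied contigs
#'
#' Recomputes the net of significant overlaps within each contig and
#' classifies problems the way gaps in fingerprint contigs arise:
#' `non-connected` (the net has >= 2 components), `buried-conflict`
#' (connectivity is lost once buried clones are detached), `reorder-fixable`
#' (the supplied order has gaps that a reordering removes), `marker-conflict`
#' (a marker shared by clones without significant overlap), `non-linear`
#' (the topology fails [linearity_check()]).
#'
#' @param assignment data.table (`contig_id`, `clone_id`, optional
#'   `position`).
#' @param db a `FingerprintDB`.
#' @param cfg a [metric_config()].
#' @param overlaps optionally a precomputed `overlap_set` for `db`.
#' @param bury_q burial threshold for the buried-conflict test.
#' @return object of class `verification_report`: data.table per contig with
#'   diagnostics and a `categories` string column.
#' @export
verify_contigs <- function(assignment, db, cfg = metric_config(),
                           overlaps = NULL, bury_q = 0.9) {
  assignment <- as.data.table(assignment)
  missing <- setdiff(assignment$clone_id, db$clone_ids)
  if (length(missing)) {
    warning("clones absent from the database: ",
            paste(missing, collapse = ", "))
    assignment <- assignment[!clone_id %in% missing]
  }
  if (is.null(overlaps)) overlaps <- compute_overlaps(db, cfg)
  buried_all <- find_buried(db, bury_q)
  out <- list()
  for (cid in unique(assignment$contig_id)) {
    rows <- assignment[contig_id == cid]
    ids <- rows$clone_id
    if (length(ids) < 2L) {
      out[[cid]] <- data.table(contig_id = cid, n_clones = length(ids),
                               connected = TRUE, n_components = 1L,
                               gaps = 0L, linear = TRUE,
                               branching = "", categories = "")
      next
    }
    og <- build_graph(overlaps, cfg$pr0, clones = ids)
    comp <- igraph::components(og$g)
    connected <- comp$no == 1L
    categories <- character()
    if (!connected) categories <- c(categories, "non-connected")
    # linearity per component
    linear <- TRUE; branching <- character()
    for (ci in seq_len(comp$no)) {
      memb <- igraph::V(og$g)$name[comp$membership == ci]
      if (length(memb) < 3L) next
      lc <- linearity_check(igraph::induced_subgraph(og$g, memb))
      if (!lc$is_linear) { linear <- FALSE
        branching <- c(branching, lc$branching) }
    }
    if (!linear) categories <- c(categories, "non-linear")
    # buried-conflict: connectivity lost after detaching buried clones
    bur <- buried_all[buried %in% ids & host %in% ids]
    if (connected && nrow(bur)) {
      keep <- setdiff(ids, bur$buried)
      if (length(keep) >= 2L) {
        sub <- igraph::induced_subgraph(og$g, keep)
        if (igraph::components(sub)$no > 1L)
          categories <- c(categories, "buried-conflict")
      }
    }
    # gaps in the supplied order; fixable by reordering?
    gaps <- NA_integer_
    if ("position" %in% names(rows) && !anyNA(rows$position)) {
      ord <- rows[order(position), clone_id]
      gaps <- length(detect_gaps(ord, overlaps, cfg$pr0))
      if (gaps > 0L && connected) {
        dist <- tsp_distances(ids, overlaps, cfg$pr0)
        co <- order_clones(ids, dist)
        if (length(co$gaps) == 0L)
          categories <- c(categories, "reorder-fixable")
      }
    }
    # marker-conflict: a shared marker on non-overlapping clones
    if (nrow(db$markers)) {
      mk <- db$markers[clone_id %in% ids]
      dup <- mk[, .(clones = list(clone_id)), by = marker_id][
        lengths(clones) > 1L]
      if (nrow(dup)) {
        ov <- as.data.table(overlaps)
        sig <- ov[significant == TRUE, paste(pmin(c1, c2), pmax(c1, c2))]
        for (r in seq_len(nrow(dup))) {
          cl <- dup$clones[[r]]
          prs <- t(combn(sort(cl), 2L))
          if (any(!paste(prs[, 1], prs[, 2]) %in% sig)) {
            categories <- c(categories, "marker-conflict")
            break
          }
        }
      }
    }
    out[[cid]] <- data.table(contig_id = cid, n_clones = length(ids),
                             connected = connected,
                             n_components = comp$no,
                             gaps = gaps, linear = linear,
                             branching = paste(sort(unique(branching)),
                                               collapse = ","),
                             categories = paste(unique(categories),
                                                collapse = ";"))
  }
  rep <- rbindlist(out)
  setattr(rep, "class", c("verification_report", class(rep)))
  rep[]
}
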