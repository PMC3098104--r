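# The net of significant overlaps. Vertices are clones, edges are overlaps
# significant at a cutoff Pr_0, weighted by W = -log10 Pr. The topology of
# this net drives everything downstream: the TENPP filter removes elements
# not proven by parallel paths, the diametric path and vertex ranks diagnose
# whether a cluster is linear (as a chromosome segment must be), and the
# same net later provides the minimal tiling path.

#' Build the net of significant overlaps
#'
#' @param overlaps an `overlap_set` (or data.table with `c1`, `c2`, `log10p`).
#' @param pr0 significance cutoff; edges are pairs with `Pr < pr0`.
#' @param clones vertex set (isolated clones are retained); defaults to the
#'   clone universe recorded in the overlap set.
#' @param exclude_edges optional data.table (`c1`, `c2`) of overlaps to leave
#'   out (e.g. previously TENPP-excluded).
#' @return object of class `overlap_graph`: fields `g` (igraph, edge weight
#'   `W = -log10 Pr`), `pr0`, `excluded_vertices` (character),
#'   `excluded_edges` (data.table `c1`, `c2`, `reason`).
#' @export
build_graph <- function(overlaps, pr0, clones = NULL, exclude_edges = NULL) {
  ov <- as.data.table(overlaps)
  if (is.null(clones)) clones <- attr(overlaps, "clone_ids")
  if (is.null(clones)) clones <- sort(unique(c(ov$c1, ov$c2)))
  ed <- ov[log10p < log10(pr0) & c1 %in% clones & c2 %in% clones,
           .(c1, c2, weight = -log10p)]
  if (!is.null(exclude_edges) && nrow(exclude_edges)) {
    key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    ed <- ed[!key(c1, c2) %in% key(exclude_edges$c1, exclude_edges$c2)]
  }
  g <- igraph::graph_from_data_frame(ed, directed = FALSE,
                                     vertices = data.frame(name = clones))
  structure(list(g = g, pr0 = pr0,
                 excluded_vertices = character(),
                 excluded_edges = data.table(c1 = character(),
                                             c2 = character(),
                                             reason = character())),
            class = "overlap_graph")
}

#' @export
print.overlap_graph <- function(x, ...) {
  cat(sprintf("overlap_graph: %d vertices, %d edges at Pr0 = %g",
              igraph::vcount(x$g), igraph::ecount(x$g), x$pr0))
  if (length(x$excluded_vertices) || nrow(x$excluded_edges))
    cat(sprintf(" (excluded: %d vertices, %d edges)",
                length(x$excluded_vertices), nrow(x$excluded_edges)))
  cat("\n")
  invisible(x)
}

# CSR adjacency of an igraph for the C++ path search (0-based).
graph_csr <- function(g) {
  n <- igraph::vcount(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  deg <- tabulate(c(el[, 1], el[, 2]), nbins = n)
  ptr <- c(0L, cumsum(deg))
  idx <- integer(sum(deg))
  pos <- ptr[-length(ptr)]
  for (r in seq_len(nrow(el))) {
    a <- el[r, 1]; b <- el[r, 2]
    pos[a] <- pos[a] + 1L; idx[pos[a]] <- b - 1L
    pos[b] <- pos[b] + 1L; idx[pos[b]] <- a - 1L
  }
  list(n = n, ptr = as.integer(ptr), idx = as.integer(idx), el = el)
}

#' Does a parallel path exist?
#'
#' Tests for a simple path of `lmin..lmax` edges between two vertices that
#' avoids a forbidden edge (the direct connection) or a forbidden vertex.
#'
#' @param og an `overlap_graph` (or igraph).
#' @param endpoints character vector of two clone ids.
#' @param forbidden_edge logical: forbid the direct edge between the
#'   endpoints?
#' @param forbidden_vertex clone id to avoid, or `NULL`.
#' @param lmin,lmax path length bounds in edges (default 2..5).
#' @export
parallel_path_exists <- function(og, endpoints, forbidden_edge = FALSE,
                                 forbidden_vertex = NULL, lmin = 2L,
                                 lmax = 5L) {
  g <- if (inherits(og, "overlap_graph")) og$g else og
  stopifnot(all(endpoints %in% igraph::V(g)$name))
  csr <- graph_csr(g)
  u <- match(endpoints[1], igraph::V(g)$name) - 1L
  v <- match(endpoints[2], igraph::V(g)$name) - 1L
  if (!is.null(forbidden_vertex)) {
    av <- match(forbidden_vertex, igraph::V(g)$name)
    # reuse the vertex kernel machinery by passing avoid through edge search
    # with a modified CSR: simplest is to delete the vertex
    g2 <- igraph::delete_vertices(g, av)
    if (!all(endpoints %in% igraph::V(g2)$name)) return(FALSE)
    csr <- graph_csr(g2)
    u <- match(endpoints[1], igraph::V(g2)$name) - 1L
    v <- match(endpoints[2], igraph::V(g2)$name) - 1L
    return(as.logical(cpp_edge_support(csr$n, csr$ptr, csr$idx, u, v,
                                       as.integer(lmin), as.integer(lmax))) &&
             TRUE)
  }
  if (forbidden_edge)
    as.logical(cpp_edge_support(csr$n, csr$ptr, csr$idx, u, v,
                                as.integer(lmin), as.integer(lmax)))
  else {
    # no forbidden element: a direct edge still does not count below lmin,
    # the same bounded search applies without the edge ban
    d <- igraph::distances(g, endpoints[1], endpoints[2])[1, 1]
    if (is.finite(d) && d >= lmin && d <= lmax) return(TRUE)
    as.logical(cpp_edge_support(csr$n, csr$ptr, csr$idx, u, v,
                                as.integer(lmin), as.integer(lmax)))
  }
}

#' TENPP: temporal exclusion of elements not proven by parallel paths
#'
#' One pass, two phases in order. Phase 1: every edge with no parallel
#' simple path of `lmin..lmax` edges connecting its endpoints (avoiding the
#' edge itself) is moved to the excluded pool. Phase 2, on the edge-filtered
#' graph: every vertex with at least one pair of neighbors lacking a
#' `lmin..lmax`-edge path that avoids the vertex is moved to the excluded
#' pool together with its incident edges. The pass is not iterated to a
#' fixpoint; the adaptive clustering loop provides repetition.
#'
#' @param og an `overlap_graph`.
#' @param lmin,lmax parallel-path length bounds for the edge phase
#'   (default 2..5; the direct edge itself never counts).
#' @param lmin_vertex minimum length for the vertex phase (default 1: a
#'   direct edge between two neighbors of `c0` proves their connection
#'   without `c0`, so thin-coverage triangles survive).
#' @return the filtered `overlap_graph`, exclusions appended.
#' @export
tenpp <- function(og, lmin = 2L, lmax = 5L, lmin_vertex = 1L) {
  g <- og$g
  excl_e <- og$excluded_edges
  if (igraph::ecount(g) > 0) {
    csr <- graph_csr(g)
    sup <- cpp_edge_support(csr$n, csr$ptr, csr$idx,
                            as.integer(csr$el[, 1] - 1L),
                            as.integer(csr$el[, 2] - 1L),
                            as.integer(lmin), as.integer(lmax))
    if (any(!sup)) {
      bad <- csr$el[!sup, , drop = FALSE]
      nm <- igraph::V(g)$name
      excl_e <- rbind(excl_e,
                      data.table(c1 = pmin(nm[bad[, 1]], nm[bad[, 2]]),
                                 c2 = pmax(nm[bad[, 1]], nm[bad[, 2]]),
                                 reason = "tenpp_edge"))
      g <- igraph::delete_edges(g, which(!sup))
    }
  }
  excl_v <- og$excluded_vertices
  if (igraph::ecount(g) > 0) {
    csr <- graph_csr(g)
    deg <- igraph::degree(g)
    check <- which(deg >= 2L)
    if (length(check)) {
      sup <- cpp_vertex_support(csr$n, csr$ptr, csr$idx,
                                as.integer(check - 1L),
                                as.integer(lmin_vertex), as.integer(lmax))
      bad <- check[!sup]
      if (length(bad)) {
        excl_v <- c(excl_v, igraph::V(g)$name[bad])
        g <- igraph::delete_vertices(g, bad)
      }
    }
  }
  structure(list(g = g, pr0 = og$pr0,
                 excluded_vertices = excl_v, excluded_edges = excl_e),
            class = "overlap_graph")
}

#' Diametric path of a connected net
#'
#' The longest, in number of edges, among the shortest paths between all
#' vertex pairs. Ties are broken deterministically by the lexicographically
#' smallest sorted endpoint pair.
#'
#' @param og an `overlap_graph` or igraph (must be connected).
#' @return character vector of clone ids along one diametric path.
#' @export
diametric_path <- function(og) {
  g <- if (inherits(og, "overlap_graph")) og$g else og
  comp <- igraph::components(g)
  if (comp$no > 1) {
    sizes <- table(comp$membership)
    stop("graph is disconnected (", comp$no, " components of sizes ",
         paste(sizes, collapse = ", "), ")")
  }
  if (igraph::vcount(g) == 1L) return(igraph::V(g)$name)
  d <- igraph::distances(g, weights = NA)
  dm <- max(d)
  idx <- which(d == dm, arr.ind = TRUE)
  nm <- igraph::V(g)$name
  pairs <- data.table(a = pmin(nm[idx[, 1]], nm[idx[, 2]]),
                      b = pmax(nm[idx[, 1]], nm[idx[, 2]]))
  setorder(pairs, a, b)
  sp <- igraph::shortest_paths(g, from = pairs$a[1], to = pairs$b[1],
                               weights = NA)$vpath[[1]]
  igraph::V(g)$name[as.integer(sp)]
}

#' Vertex ranks relative to a path
#'
#' The rank of a vertex is its shortest-path edge distance to the nearest
#' path vertex; path vertices have rank 0. Ranks of 2 and higher flag
#' non-short offshoots, i.e. a possibly non-linear cluster.
#'
#' @param og an `overlap_graph` or igraph.
#' @param path character vector of path clone ids.
#' @return named integer vector of ranks.
#' @export
vertex_ranks <- function(og, path) {
  g <- if (inherits(og, "overlap_graph")) og$g else og
  stopifnot(all(path %in% igraph::V(g)$name))
  d <- igraph::distances(g, v = path, weights = NA)
  r <- apply(d, 2, min)
  storage.mode(r) <- "integer"
  setNames(r, igraph::V(g)$name)
}

#' Linearity diagnosis
#'
#' A cluster is topologically linear when no vertex lies further than
#' `max_rank` from the diametric path. Branching vertices are the path
#' vertices adjacent to offshoots that contain rank >= 2 vertices; removing
#' them splits the cluster into linear parts.
#'
#' @param og an `overlap_graph` or igraph (connected).
#' @param path optionally a precomputed diametric path.
#' @param max_rank largest admissible rank (default 1).
#' @return list: `is_linear`, `branching` (clone ids), `ranks`, `path`.
#' @export
linearity_check <- function(og, path = NULL, max_rank = 1L) {
  g <- if (inherits(og, "overlap_graph")) og$g else og
  if (is.null(path)) path <- diametric_path(g)
  r <- vertex_ranks(g, path)
  branching <- character()
  if (any(r > max_rank)) {
    off <- igraph::delete_vertices(g, path)
    comp <- igraph::components(off)
    for (ci in seq_len(comp$no)) {
      memb <- igraph::V(off)$name[comp$membership == ci]
      if (max(r[memb]) >= 2L) {
        nb <- unique(unlist(lapply(memb, function(v)
          igraph::V(g)$name[as.integer(igraph::neighbors(g, v))])))
        branching <- union(branching, intersect(nb, path))
      }
    }
  }
  list(is_linear = all(r <= max_rank), branching = sort(branching),
       ranks = r, path = path)
}

#' Split a cluster into linear parts
#'
#' Repeatedly removes branching-node clones (recording them) and recomputes
#' connected components until every component passes [linearity_check()].
#'
#' @param og an `overlap_graph` or igraph.
#' @param max_rank largest admissible rank.
#' @return list: `parts` (list of character clone-id vectors, each linear),
#'   `removed` (clone ids excluded at branching nodes).
#' @export
split_nonlinear <- function(og, max_rank = 1L) {
  g <- if (inherits(og, "overlap_graph")) og$g else og
  removed <- character()
  parts <- list()
  comp <- igraph::components(g)
  queue <- lapply(seq_len(comp$no),
                  function(ci) igraph::V(g)$name[comp$membership == ci])
  while (length(queue)) {
    memb <- queue[[1]]; queue <- queue[-1]
    sub <- igraph::induced_subgraph(g, memb)
    if (igraph::vcount(sub) <= 2L) { parts <- c(parts, list(memb)); next }
    lc <- linearity_check(sub, max_rank = max_rank)
    if (lc$is_linear || length(lc$branching) == 0L) {
      parts <- c(parts, list(memb))
    } else {
      removed <- c(removed, lc$branching)
      sub2 <- igraph::delete_vertices(sub, lc$branching)
      comp2 <- igraph::components(sub2)
      for (ci in seq_len(comp2$no))
        queue <- c(queue, list(igraph::V(sub2)$name[comp2$membership == ci]))
    }
  }
  list(parts = parts, removed = sort(unique(removed)))
}

#' Export a net in Pajek format
#'
#' Writes a standard `.net` file: `*Vertices` with quoted labels, `*Edges`
#' with weights; readable back by igraph and Pajek.
#'
#' @param og an `overlap_graph` or igraph.
#' @param path output file.
#' @export
export_pajek <- function(og, path) {
  g <- if (inherits(og, "overlap_graph")) og$g else og
  nm <- igraph::V(g)$name
  el <- igraph::as_edgelist(g, names = FALSE)
  w <- igraph::E(g)$weight
  if (is.null(w)) w <- rep(1, nrow(el))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("*Vertices %d", length(nm)), con)
  writeLines(sprintf("%d \"%s\"", seq_along(nm), nm), con)
  writeLines("*Edges", con)
  if (nrow(el))
    writeLines(sprintf("%d %d %g", el[, 1], el[, 2], w), con)
  invisible(path)
}
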