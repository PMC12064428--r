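# Monmonier maximum-difference barrier detection: Delaunay triangulation of
# population coordinates, its Voronoi dual, greedy maximum-difference path
# tracing and locus-bootstrap support.

circumcircle <- function(p1, p2, p3) {
  ax <- p1[1]; ay <- p1[2]; bx <- p2[1]; by <- p2[2]; cx <- p3[1]; cy <- p3[2]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  if (abs(d) < 1e-12) return(NULL)  # collinear
  ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
           (cx^2 + cy^2) * (ay - by)) / d
  uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
           (cx^2 + cy^2) * (bx - ax)) / d
  c(ux, uy, sqrt((ax - ux)^2 + (ay - uy)^2))
}

# Brute-force Delaunay triangulation by the empty-circumcircle property.
# O(n^4) but populations number a few dozen at most.
delaunay_triangles <- function(xy) {
  n <- nrow(xy)
  if (n < 3) stop("need at least 3 populations")
  tris <- list()
  for (i in seq_len(n - 2)) for (j in seq(i + 1, n - 1)) for (k in seq(j + 1, n)) {
    cc <- circumcircle(xy[i, ], xy[j, ], xy[k, ])
    if (is.null(cc)) next
    d2 <- (xy[, 1] - cc[1])^2 + (xy[, 2] - cc[2])^2
    inside <- d2 < cc[3]^2 * (1 - 1e-9)
    inside[c(i, j, k)] <- FALSE
    if (!any(inside)) tris[[length(tris) + 1L]] <- c(i, j, k)
  }
  if (!length(tris))
    stop("degenerate (collinear) population coordinates: no triangulation; ",
         "jitter the coordinates slightly")
  do.call(rbind, tris)
}

#' Build the barrier graph
#'
#' Delaunay triangulation of the population coordinates plus its Voronoi
#' dual: every Delaunay edge is crossed by exactly one dual edge, which is
#' annotated with the genetic distance between the two populations it
#' separates. Dual edges of hull edges extend outward and are clipped to a
#' bounding box at three times the point-set diameter.
#'
#' @param pop_table a population table (see [read_population_table()]) or a
#'   two-column coordinate matrix with rownames.
#' @param D symmetric genetic distance matrix with dimnames matching the
#'   population ids.
#' @return a `barrier_graph`: list(xy, pop_ids, triangles, edges) where
#'   `edges` has columns i, j, t1, t2 (adjacent triangle indices, NA =
#'   outside), dist, and the dual-segment endpoints x0, y0, x1, y1.
#' @export
build_barrier_graph <- function(pop_table, D) {
  xy <- if (is.matrix(pop_table)) pop_table else pop_coordinates(pop_table)
  ids <- rownames(xy)
  D <- as.matrix(D)
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-8)))
    stop("distance matrix must be symmetric")
  if (!all(ids %in% rownames(D)))
    stop("distance matrix lacks some populations")
  D <- D[ids, ids]
  tri <- delaunay_triangles(xy)
  # edge table keyed on i < j
  ekey <- function(a, b) paste(pmin(a, b), pmax(a, b))
  edges <- unique(do.call(rbind, lapply(seq_len(nrow(tri)), function(t)
    cbind(c(tri[t, 1], tri[t, 1], tri[t, 2]),
          c(tri[t, 2], tri[t, 3], tri[t, 3])))))
  edges <- t(apply(edges, 1, sort))
  edges <- unique(edges)
  t1 <- rep(NA_integer_, nrow(edges)); t2 <- t1
  for (e in seq_len(nrow(edges))) {
    hit <- which(apply(tri, 1, function(v)
      all(edges[e, ] %in% v)))
    t1[e] <- hit[1]
    if (length(hit) > 1) t2[e] <- hit[2]
  }
  # circumcenters and dual segments
  cc <- t(apply(tri, 1, function(v)
    circumcircle(xy[v[1], ], xy[v[2], ], xy[v[3], ])[1:2]))
  diam <- max(dist(xy))
  ctr <- colMeans(xy)
  seg <- matrix(NA_real_, nrow(edges), 4)
  for (e in seq_len(nrow(edges))) {
    if (!is.na(t2[e])) {
      seg[e, ] <- c(cc[t1[e], ], cc[t2[e], ])
    } else {
      # hull edge: extend from the circumcenter through the edge midpoint
      mid <- (xy[edges[e, 1], ] + xy[edges[e, 2], ]) / 2
      dirv <- mid - cc[t1[e], ]
      nv <- sqrt(sum(dirv^2))
      if (nv < 1e-12) { # circumcenter on the edge: use outward normal
        ev <- xy[edges[e, 2], ] - xy[edges[e, 1], ]
        dirv <- c(-ev[2], ev[1])
        if (sum(dirv * (mid - ctr)) < 0) dirv <- -dirv
        nv <- sqrt(sum(dirv^2))
      }
      # orient outward relative to the centroid
      if (sum(dirv * (mid - ctr)) < 0) dirv <- -dirv
      far <- cc[t1[e], ] + dirv / sqrt(sum(dirv^2)) * 3 * diam
      seg[e, ] <- c(cc[t1[e], ], far)
    }
  }
  ed <- data.frame(i = edges[, 1], j = edges[, 2], t1 = t1, t2 = t2,
                   dist = D[cbind(edges[, 1], edges[, 2])],
                   x0 = seg[, 1], y0 = seg[, 2], x1 = seg[, 3], y1 = seg[, 4])
  ed$pair <- paste(ids[ed$i], ids[ed$j], sep = "|")
  structure(list(xy = xy, pop_ids = ids, triangles = tri, edges = ed),
            class = "barrier_graph")
}

#' Replace the edge distances of a barrier graph
#'
#' The triangulation depends only on geometry, so bootstrap replicates reuse
#' it and swap in a resampled distance matrix.
#' @param graph a `barrier_graph`.
#' @param D symmetric distance matrix over the graph's populations.
#' @return the updated graph.
#' @export
set_edge_distances <- function(graph, D) {
  D <- as.matrix(D)[graph$pop_ids, graph$pop_ids]
  graph$edges$dist <- D[cbind(graph$edges$i, graph$edges$j)]
  graph
}

# deterministic ordering: distance descending, then pair id ascending
edge_order <- function(edges, idx) {
  idx[order(-edges$dist[idx], edges$pair[idx])]
}

#' Trace one Monmonier maximum-difference barrier
#'
#' Starts at the dual edge with the largest genetic distance and extends
#' both ends stepwise, always crossing next the adjacent Delaunay edge with
#' the largest distance not yet in the path, never revisiting a Voronoi
#' vertex (triangle). An end stops when it exits through the outer boundary
#' or the path closes a loop. Ties are broken deterministically (distance
#' descending, then population-pair id ascending). When every distance is
#' equal the barrier is flagged non-informative.
#'
#' @param graph a `barrier_graph`.
#' @param masked integer edge indices excluded from this barrier (used for
#'   iterative multi-barrier extraction).
#' @return a `barrier`: list(edge_idx in path order, pairs, dists,
#'   noninformative, closed_loop).
#' @export
monmonier <- function(graph, masked = integer(0)) {
  ed <- graph$edges
  avail <- setdiff(seq_len(nrow(ed)), masked)
  if (!length(avail)) stop("no unmasked edges left")
  start <- edge_order(ed, avail)[1]
  noninf <- length(unique(ed$dist[avail])) == 1L
  in_path <- rep(FALSE, nrow(ed)); in_path[start] <- TRUE
  visited_tri <- logical(nrow(graph$triangles))
  path <- c(start)  # ordered; end A grows on the left, end B on the right
  # each active end sits at a triangle it is about to enter
  ends <- list(A = ed$t1[start], B = ed$t2[start])  # NA => already outside
  closed <- FALSE
  tri_edges <- function(t) which((ed$t1 == t | (!is.na(ed$t2) & ed$t2 == t)))
  repeat {
    # candidates per active end
    cand <- lapply(ends, function(t) {
      if (is.na(t) || closed) return(integer(0))
      ce <- setdiff(tri_edges(t), which(in_path))
      ce <- setdiff(ce, masked)
      edge_order(ed, ce)
    })
    lens <- lengths(cand)
    if (all(lens == 0)) break
    # pick the end whose best candidate has the larger distance;
    # ties resolved on the pair id (ascending), then end A first
    best <- vapply(cand, function(x)
      if (length(x)) ed$dist[x[1]] else -Inf, numeric(1))
    top <- names(best)[best == max(best)]
    side <- if (length(top) == 1L) top else
      top[order(vapply(top, function(s) ed$pair[cand[[s]][1]], ""))][1]
    e <- cand[[side]][1]
    t_now <- ends[[side]]
    visited_tri[t_now] <- TRUE
    in_path[e] <- TRUE
    if (side == "A") path <- c(e, path) else path <- c(path, e)
    t_next <- if (!is.na(ed$t2[e]) && ed$t2[e] != t_now) ed$t2[e] else
      if (ed$t1[e] != t_now) ed$t1[e] else NA_integer_
    if (!is.na(t_next) && visited_tri[t_next]) {
      closed <- TRUE
      ends[[side]] <- NA_integer_
    } else {
      ends[[side]] <- t_next   # NA when exiting through the hull
    }
    if (is.na(ends$A) && is.na(ends$B)) break
  }
  structure(list(edge_idx = path, pairs = ed$pair[path],
                 dists = ed$dist[path], noninformative = noninf,
                 closed_loop = closed),
            class = "barrier")
}

#' Extract several barriers by iterative masking
#'
#' After each barrier is traced its edges are masked and the algorithm
#' reruns, so barriers never share a dual edge. No automatic "optimal m" is
#' applied: mean bootstrap support per barrier (see [bootstrap_support()])
#' lets the operator trade off barrier count against support.
#'
#' @param graph a `barrier_graph`.
#' @param m number of barriers.
#' @return list of `barrier` objects.
#' @export
extract_barriers <- function(graph, m = 1L) {
  masked <- integer(0)
  out <- vector("list", m)
  for (b in seq_len(m)) {
    if (length(masked) >= nrow(graph$edges)) { out <- out[seq_len(b - 1)]; break }
    out[[b]] <- monmonier(graph, masked)
    masked <- c(masked, out[[b]]$edge_idx)
  }
  out
}

#' Locus-bootstrap support for barrier edges
#'
#' Loci are resampled with replacement; the genetic distance matrix is
#' recomputed with the same estimator per replicate, and the barrier(s)
#' retraced on the fixed triangulation. The support of a dual edge is the
#' percentage of replicates whose barrier(s) include it.
#'
#' @param G a [genotype_matrix()].
#' @param graph a `barrier_graph` built from the observed distances.
#' @param n_boot number of replicates (default 100).
#' @param m number of barriers traced per replicate (default 1).
#' @param distance_fun function(G) -> distance matrix; defaults to
#'   [pairwise_fst_nei()].
#' @param seed RNG seed.
#' @return numeric vector, one support value in [0, 100] per graph edge.
#' @export
bootstrap_support <- function(G, graph, n_boot = 100L, m = 1L,
                              distance_fun = pairwise_fst_nei, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  L <- n_loci(G)
  hits <- numeric(nrow(graph$edges))
  for (b in seq_len(n_boot)) {
    idx <- sample.int(L, L, replace = TRUE)
    Gb <- genotype_matrix(G$calls[, idx, , drop = FALSE], G$individual_ids,
                          G$pop_ids, G$loci[idx], G$missing)
    gb <- set_edge_distances(graph, distance_fun(Gb))
    bars <- extract_barriers(gb, m)
    used <- unique(unlist(lapply(bars, `[[`, "edge_idx")))
    hits[used] <- hits[used] + 1
  }
  100 * hits / n_boot
}
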