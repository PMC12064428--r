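# Shared fixtures and independent oracles, built in code at test time.

# Small genotype matrix from an explicit list: calls[[pop]][[ind]] is an
# L x 2 matrix of allele sizes.
make_genotypes <- function(pop_calls, loci = NULL) {
  pops <- rep(names(pop_calls), vapply(pop_calls, length, integer(1)))
  mats <- unlist(pop_calls, recursive = FALSE)
  L <- nrow(mats[[1]])
  calls <- array(NA_integer_, c(length(mats), L, 2))
  for (i in seq_along(mats)) calls[i, , ] <- as.matrix(mats[[i]])
  genotype_matrix(calls, sprintf("i%03d", seq_along(mats)), pops,
                  loci %||% sprintf("L%02d", seq_len(L)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent rarefaction oracle: brute-force enumeration of all g-subsets
# of the gene copies, averaging the distinct-allele count.
ar_bruteforce <- function(counts, g) {
  copies <- rep(seq_along(counts), counts)
  subsets <- combn(length(copies), g)
  mean(apply(subsets, 2, function(ix) length(unique(copies[ix]))))
}

# Independent minimum-spanning-tree weight: enumerate all spanning trees
# (edge subsets of size n-1) of a complete graph given a distance matrix.
mst_bruteforce <- function(D) {
  n <- nrow(D)
  pairs <- t(combn(n, 2))
  w <- D[pairs]
  best <- Inf
  for (sel in combn(nrow(pairs), n - 1, simplify = FALSE)) {
    # connectivity check via union-find
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (e in sel) {
      ra <- find(pairs[e, 1]); rb <- find(pairs[e, 2])
      if (ra != rb) parent[ra] <- rb
    }
    if (length(unique(vapply(seq_len(n), find, integer(1)))) == 1L)
      best <- min(best, sum(w[sel]))
  }
  best
}

# Independent Monmonier oracle: separate Delaunay construction (determinant
# in-circle predicate) and an edge-key based trace of the maximum-difference
# path. Returns the ordered population-pair labels of the first barrier.
oracle_first_barrier <- function(xy, D) {
  n <- nrow(xy); ids <- rownames(xy)
  ccw <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) -
    (b[2] - a[2]) * (c[1] - a[1])
  incircle <- function(a, b, c, d) {
    if (ccw(a, b, c) < 0) { tmp <- b; b <- c; c <- tmp }
    det(rbind(c(a[1] - d[1], a[2] - d[2], sum(a^2) - sum(d^2)),
              c(b[1] - d[1], b[2] - d[2], sum(b^2) - sum(d^2)),
              c(c[1] - d[1], c[2] - d[2], sum(c^2) - sum(d^2))))
  }
  tris <- list()
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    if (abs(ccw(xy[i, ], xy[j, ], xy[k, ])) < 1e-12) next
    ok <- TRUE
    for (d in setdiff(1:n, c(i, j, k)))
      if (incircle(xy[i, ], xy[j, ], xy[k, ], xy[d, ]) > 1e-9) {
        ok <- FALSE; break
      }
    if (ok) tris[[length(tris) + 1]] <- c(i, j, k)
  }
  tris <- do.call(rbind, tris)
  ekey <- function(i, j) paste(min(i, j), max(i, j))
  emap <- new.env()
  for (t in seq_len(nrow(tris))) {
    v <- tris[t, ]
    for (pr in list(v[1:2], v[c(1, 3)], v[2:3])) {
      k <- ekey(pr[1], pr[2])
      emap[[k]] <- c(emap[[k]], t)
    }
  }
  ekeys <- ls(emap)
  einfo <- lapply(ekeys, function(k) {
    v <- as.integer(strsplit(k, " ")[[1]])
    list(tris = emap[[k]], dist = D[v[1], v[2]],
         pair = paste(ids[v[1]], ids[v[2]], sep = "|"))
  })
  names(einfo) <- ekeys
  ord <- order(-vapply(einfo, `[[`, numeric(1), "dist"),
               vapply(einfo, `[[`, character(1), "pair"))
  start <- ekeys[ord[1]]
  used <- start
  endverts <- list(A = einfo[[start]]$tris[1],
                   B = if (length(einfo[[start]]$tris) > 1)
                     einfo[[start]]$tris[2] else NA)
  visited <- integer(0)
  path <- start
  closed <- FALSE
  incident <- function(t) {
    v <- tris[t, ]
    c(ekey(v[1], v[2]), ekey(v[1], v[3]), ekey(v[2], v[3]))
  }
  repeat {
    cands <- lapply(endverts, function(t) {
      if (is.na(t) || closed) return(character(0))
      ce <- setdiff(incident(t), used)
      if (!length(ce)) return(character(0))
      ce[order(-vapply(einfo[ce], `[[`, numeric(1), "dist"),
               vapply(einfo[ce], `[[`, character(1), "pair"))]
    })
    if (all(lengths(cands) == 0)) break
    bd <- vapply(cands, function(x)
      if (length(x)) einfo[[x[1]]]$dist else -Inf, numeric(1))
    top <- names(bd)[bd == max(bd)]
    side <- if (length(top) == 1) top else
      top[order(vapply(top, function(s) einfo[[cands[[s]][1]]]$pair, ""))][1]
    e <- cands[[side]][1]
    tnow <- endverts[[side]]
    visited <- c(visited, tnow)
    used <- c(used, e)
    path <- if (side == "A") c(e, path) else c(path, e)
    tn <- setdiff(einfo[[e]]$tris, tnow)
    if (!length(tn)) tn <- NA
    if (!is.na(tn) && tn %in% visited) {
      closed <- TRUE; endverts[[side]] <- NA
    } else endverts[[side]] <- tn
    if (is.na(endverts$A) && is.na(endverts$B)) break
  }
  unname(vapply(path, function(k) einfo[[k]]$pair, character(1)))
}

subset_loci_fixture <- function(G, idx) {
  genotype_matrix(G$calls[, idx, , drop = FALSE], G$individual_ids,
                  G$pop_ids, G$loci[idx], G$missing)
}

random_barrier_case <- function(seed) {
  set.seed(seed)
  n <- sample(4:8, 1)
  xy <- cbind(runif(n), runif(n))
  rownames(xy) <- sprintf("P%02d", 1:n)
  D <- matrix(0, n, n, dimnames = list(rownames(xy), rownames(xy)))
  D[lower.tri(D)] <- runif(n * (n - 1) / 2)
  D <- D + t(D)
  list(xy = xy, D = D)
}
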