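# Bayesian admixture inference: Gibbs sampler over latent gene-copy origins,
# replicate-run alignment (label-switching correction), clustering-mode
# detection and the cluster-number selection metrics used for hierarchical
# analyses of population structure.

recode_genotypes <- function(G) {
  n <- n_individuals(G); L <- n_loci(G)
  geno <- matrix(-1L, n, 2L * L)
  n_alleles <- integer(L)
  allele_sizes <- vector("list", L)
  for (l in seq_len(L)) {
    obs <- c(G$calls[, l, 1], G$calls[, l, 2])
    sizes <- sort(unique(obs[obs != G$missing]))
    if (!length(sizes)) stop("locus ", G$loci[l], " has no observed alleles")
    allele_sizes[[l]] <- sizes
    n_alleles[l] <- length(sizes)
    for (cpy in 1:2) {
      x <- G$calls[, l, cpy]
      idx <- match(x, sizes) - 1L
      idx[x == G$missing] <- -1L
      geno[, 2L * (l - 1L) + cpy] <- idx
    }
  }
  list(geno = geno, n_alleles = n_alleles, allele_sizes = allele_sizes)
}

#' Fit the admixture model by Gibbs sampling
#'
#' Alternates (i) latent cluster-of-origin draws for every gene copy given
#' the current membership vectors q and cluster allele frequencies, (ii)
#' Dirichlet-conjugate frequency updates, and (iii) Dirichlet updates of each
#' individual's q. Missing gene copies are skipped. With
#' `prior_model = "correlated"` the frequency prior is centred on the pooled
#' sample frequencies with concentration `(1-F)/F` (a simplified F-model);
#' the default independent prior is Dirichlet(lambda). With
#' `locprior_pops` supplied, per-population mixture weights (a simplified
#' r-parameterized location prior) inform the q updates, which helps under
#' weak differentiation.
#'
#' @param G a [genotype_matrix()].
#' @param K number of clusters (>= 1).
#' @param burnin,iters burn-in and retained MCMC sweeps.
#' @param thin store every `thin`-th post-burn-in sweep (default 10).
#' @param prior_model `"independent"` (default) or `"correlated"`.
#' @param locprior_pops optional character vector of population labels per
#'   individual activating the location prior (e.g. `G$pop_ids`).
#' @param alpha admixture Dirichlet concentration (default 1).
#' @param lambda allele-frequency prior mass per allele (default 1).
#' @param F_prior drift parameter of the correlated prior (default 0.05).
#' @param loc_r strength of the location prior (default 1).
#' @param alpha_update Metropolis-update alpha during sampling (uniform
#'   prior on (0, 10], random-walk proposal; default FALSE keeps alpha
#'   fixed).
#' @param seed RNG seed.
#' @return an `admix_run`: list with `q` (posterior-mean membership matrix,
#'   rows sum to 1), `loglik_trace`, `lnP` (the mean - variance/2 marginal
#'   likelihood estimate), `K`, `seed`, `flags`.
#' @export
fit_admixture <- function(G, K, burnin = 2000L, iters = 4000L, thin = 10L,
                          prior_model = c("independent", "correlated"),
                          locprior_pops = NULL, alpha = 1, lambda = 1,
                          F_prior = 0.05, loc_r = 1, alpha_update = FALSE,
                          seed = NULL) {
  prior_model <- match.arg(prior_model)
  stopifnot(K >= 1, burnin > 0, iters > 0, thin >= 1)
  rec <- recode_genotypes(G)
  flags <- character(0)
  if (K > 1 && all(rec$n_alleles == 1L))
    flags <- c(flags, "monomorphic dataset with K > 1")
  if (prior_model == "independent") {
    prior_conc <- rep(lambda, sum(rec$n_alleles))
  } else {
    # pooled sample frequencies as the ancestral profile
    prior_conc <- unlist(lapply(seq_len(n_loci(G)), function(l) {
      obs <- c(G$calls[, l, 1], G$calls[, l, 2])
      obs <- obs[obs != G$missing]
      tab <- tabulate(match(obs, rec$allele_sizes[[l]]),
                      nbins = rec$n_alleles[l])
      (tab / sum(tab)) * (1 - F_prior) / F_prior
    }))
  }
  if (!is.null(locprior_pops)) {
    stopifnot(length(locprior_pops) == n_individuals(G))
    pop_levels <- unique(locprior_pops)
    pop_index <- match(locprior_pops, pop_levels) - 1L
    n_pops <- length(pop_levels)
  } else {
    pop_index <- integer(0); n_pops <- 0L
  }
  if (!is.null(seed)) set.seed(seed)
  if (K == 1L) {
    # degenerate: q is identically 1; still produce a likelihood trace
    fit <- .gibbs_admixture(rec$geno, rec$n_alleles, 1L, as.integer(burnin),
                            as.integer(iters), as.integer(thin), alpha,
                            prior_conc, pop_index, n_pops, loc_r, FALSE)
  } else {
    fit <- .gibbs_admixture(rec$geno, rec$n_alleles, as.integer(K),
                            as.integer(burnin), as.integer(iters),
                            as.integer(thin), alpha, prior_conc, pop_index,
                            n_pops, loc_r, alpha_update)
  }
  q <- fit$q
  rownames(q) <- G$individual_ids
  structure(list(q = q, loglik_trace = as.numeric(fit$loglik_trace),
                 lnP = estimate_lnP(fit$loglik_trace), K = as.integer(K),
                 alpha_final = fit$alpha, seed = seed, flags = flags),
            class = "admix_run")
}

#' @export
print.admix_run <- function(x, ...) {
  cat(sprintf("admix_run: K = %d, %d individuals, lnP = %.2f\n",
              x$K, nrow(x$q), x$lnP))
  invisible(x)
}

#' Estimate ln P(X|K) from a log-likelihood trace
#'
#' The marginal-likelihood estimate used by STRUCTURE:
#' `mean(trace) - var(trace)/2`, with the sample variance (divisor n - 1).
#'
#' @param loglik_trace numeric vector, length >= 2.
#' @return a single number.
#' @export
estimate_lnP <- function(loglik_trace) {
  x <- as.numeric(loglik_trace)
  if (length(x) < 2L) stop("trace must have length >= 2")
  mean(x) - var(x) / 2
}

#' Pairwise similarity of two aligned q-matrices
#'
#' `G' = 1 - ||Qa - Qb||_F / sqrt(2 n)`: 1 for identical matrices, 0 for
#' orthogonal hard assignments. Symmetric and invariant to a joint label
#' permutation.
#'
#' @param qa,qb individuals x K matrices (same shape).
#' @return similarity in [0, 1].
#' @export
similarity_score <- function(qa, qb) {
  qa <- as.matrix(qa); qb <- as.matrix(qb)
  stopifnot(all(dim(qa) == dim(qb)))
  1 - sqrt(sum((qa - qb)^2)) / sqrt(2 * nrow(qa))
}

best_permutation <- function(qref, q) {
  K <- ncol(q)
  if (K <= 8L) {
    perms <- permutations_of(K)
    scores <- vapply(seq_len(nrow(perms)), function(i)
      sum(qref * q[, perms[i, ], drop = FALSE]), numeric(1))
    as.integer(unname(perms[which.max(scores), ]))
  } else {
    # greedy column matching on cross-products
    cp <- crossprod(qref, q)  # K x K
    perm <- integer(K)
    used <- logical(K)
    for (step in seq_len(K)) {
      cp2 <- cp; cp2[, used] <- -Inf
      idx <- which(cp2 == max(cp2), arr.ind = TRUE)[1, ]
      perm[idx[1]] <- idx[2]
      used[idx[2]] <- TRUE
      cp[idx[1], ] <- -Inf
    }
    perm
  }
}

permutations_of <- function(K) {
  if (K == 1L) return(matrix(1L, 1, 1))
  sub <- permutations_of(K - 1L)
  do.call(rbind, lapply(seq_len(K), function(pos) {
    cbind(sub[, seq_len(pos - 1L), drop = FALSE], K,
          sub[, seq(pos, K - 1L)[seq_len(K - pos)], drop = FALSE])
  }))
}

#' Align replicate runs to a common cluster labelling
#'
#' Corrects label switching across replicate runs: each run's cluster labels
#' are permuted to maximize agreement (summed elementwise product) with an
#' incrementally built reference (the running mean of already-aligned runs).
#' The optimal permutation is found exactly for K <= 8 by enumeration of the
#' assignment problem; a greedy matching is used beyond.
#'
#' @param runs list of `admix_run` objects (or bare q matrices) sharing K and
#'   individuals.
#' @return list with `runs` (aligned copies), `permutations` (list of integer
#'   vectors: new column j was old column perm[j]).
#' @export
align_runs <- function(runs) {
  qs <- lapply(runs, function(r) if (inherits(r, "admix_run")) r$q else as.matrix(r))
  K <- unique(vapply(qs, ncol, integer(1)))
  if (length(K) != 1L) stop("runs disagree on K")
  n <- unique(vapply(qs, nrow, integer(1)))
  if (length(n) != 1L) stop("runs disagree on individuals")
  perms <- vector("list", length(qs))
  perms[[1]] <- seq_len(K)
  ref <- qs[[1]]
  nref <- 1
  for (i in seq_along(qs)[-1]) {
    perm <- best_permutation(ref / nref, qs[[i]])
    qs[[i]] <- qs[[i]][, perm, drop = FALSE]
    perms[[i]] <- perm
    ref <- ref + qs[[i]]
    nref <- nref + 1
  }
  aligned <- runs
  for (i in seq_along(aligned)) {
    if (inherits(aligned[[i]], "admix_run")) aligned[[i]]$q <- qs[[i]]
    else aligned[[i]] <- qs[[i]]
  }
  list(runs = aligned, permutations = perms)
}

#' Group aligned runs into clustering modes
#'
#' Single-linkage grouping on pairwise similarity: runs in one mode are
#' connected by similarities >= `threshold`. The major mode is the largest
#' group; `mean_q` averages member runs.
#'
#' @param aligned_runs list of aligned `admix_run` objects or q matrices.
#' @param threshold similarity threshold (default 0.9).
#' @return list of mode groups: `member_runs`, `mean_q`, `similarity` (mean
#'   pairwise similarity within the mode, 1 for singletons), ordered by
#'   decreasing size.
#' @export
detect_modes <- function(aligned_runs, threshold = 0.9) {
  qs <- lapply(aligned_runs, function(r)
    if (inherits(r, "admix_run")) r$q else as.matrix(r))
  m <- length(qs)
  S <- diag(1, m)
  if (m > 1)
    for (i in seq_len(m - 1)) for (j in seq(i + 1, m))
      S[i, j] <- S[j, i] <- similarity_score(qs[[i]], qs[[j]])
  # single linkage: union-find over edges above threshold
  parent <- seq_len(m)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (m > 1)
    for (i in seq_len(m - 1)) for (j in seq(i + 1, m))
      if (S[i, j] >= threshold) parent[find(j)] <- find(i)
  comp <- vapply(seq_len(m), find, integer(1))
  groups <- split(seq_len(m), comp)
  modes <- lapply(groups, function(idx) {
    mq <- Reduce(`+`, qs[idx]) / length(idx)
    sim <- if (length(idx) == 1L) 1 else
      mean(S[idx, idx][upper.tri(diag(length(idx)))])
    list(member_runs = idx, mean_q = mq, similarity = sim)
  })
  modes[order(-vapply(modes, function(g) length(g$member_runs), integer(1)))]
}

#' Cluster-count metrics across replicate runs
#'
#' For each run, population-level membership is summarized two ways (median
#' and mean of member individuals' q per cluster); a cluster counts as
#' "populated" if at least one population reaches q >= `threshold` for it.
#' MedMedK / MedMeanK are the medians of the populated-cluster count across
#' runs (using the median / mean population summary respectively); MaxMedK /
#' MaxMeanK are the maxima.
#'
#' @param runs list of `admix_run` objects or q matrices (need not be
#'   aligned: the counts are label-invariant).
#' @param pop_ids population label per individual.
#' @param threshold assignment threshold (default 0.5).
#' @param pops populations to summarize (default: those present); a listed
#'   population without members is an error.
#' @return named numeric vector (MedMedK, MedMeanK, MaxMedK, MaxMeanK).
#' @export
puechmaille_metrics <- function(runs, pop_ids, threshold = 0.5,
                                pops = unique(pop_ids)) {
  qs <- lapply(runs, function(r)
    if (inherits(r, "admix_run")) r$q else as.matrix(r))
  counts <- vapply(qs, function(q) {
    med <- t(vapply(pops, function(p) {
      rows <- q[pop_ids == p, , drop = FALSE]
      if (!nrow(rows)) stop("empty population: ", p)
      apply(rows, 2, median)
    }, numeric(ncol(q))))
    mea <- t(vapply(pops, function(p)
      colMeans(q[pop_ids == p, , drop = FALSE]), numeric(ncol(q))))
    c(med = sum(apply(med, 2, function(col) any(col >= threshold))),
      mean = sum(apply(mea, 2, function(col) any(col >= threshold))))
  }, numeric(2))
  c(MedMedK = median(counts["med", ]), MedMeanK = median(counts["mean", ]),
    MaxMedK = max(counts["med", ]), MaxMeanK = max(counts["mean", ]))
}

#' Evaluate candidate cluster numbers K
#'
#' Applies the two-criterion selection rule: criterion 1 requires that at
#' least one of the four populated-cluster metrics increases relative to
#' K - 1; criterion 2 rejects K values whose replicate runs fall into
#' conflicting clustering modes (major-mode internal similarity below the
#' threshold, or multiple modes whose mean q matrices disagree). The
#' selected K is the largest one passing both. The lnP trajectory (mean and
#' sd of per-run lnP) is reported alongside.
#'
#' @param runs_by_K named list: K value (as character or integer) -> list of
#'   `admix_run` objects.
#' @param pop_ids population label per individual.
#' @param q_threshold threshold for the populated-cluster metrics (0.5).
#' @param sim_threshold mode-conflict similarity threshold (0.9).
#' @return list with `table` (data.frame per K: metrics, n_modes,
#'   criterion1, criterion2, lnP_mean, lnP_sd) and `selected_K` (NA if no K
#'   passes both criteria).
#' @export
evaluate_K <- function(runs_by_K, pop_ids, q_threshold = 0.5,
                       sim_threshold = 0.9) {
  Ks <- as.integer(names(runs_by_K))
  ord <- order(Ks)
  Ks <- Ks[ord]; runs_by_K <- runs_by_K[ord]
  rows <- list()
  prev_metrics <- NULL
  for (j in seq_along(Ks)) {
    runs <- runs_by_K[[j]]
    met <- puechmaille_metrics(runs, pop_ids, q_threshold)
    aligned <- align_runs(runs)$runs
    modes <- detect_modes(aligned, sim_threshold)
    major <- modes[[1]]
    conflict <- major$similarity < sim_threshold
    if (length(modes) > 1) {
      for (a in seq_len(length(modes) - 1)) for (b in seq(a + 1, length(modes)))
        if (similarity_score(modes[[a]]$mean_q, modes[[b]]$mean_q) <
            sim_threshold) conflict <- TRUE
    }
    crit1 <- if (is.null(prev_metrics)) TRUE else any(met > prev_metrics)
    lnPs <- vapply(runs, function(r)
      if (inherits(r, "admix_run")) r$lnP else NA_real_, numeric(1))
    rows[[j]] <- data.frame(K = Ks[j], t(met), n_modes = length(modes),
                            criterion1 = crit1, criterion2 = !conflict,
                            lnP_mean = mean(lnPs), lnP_sd = sd(lnPs))
    prev_metrics <- met
  }
  tab <- do.call(rbind, rows)
  pass <- tab$K[tab$criterion1 & tab$criterion2]
  list(table = tab, selected_K = if (length(pass)) max(pass) else NA_integer_)
}
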