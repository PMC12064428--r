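# Diversity and differentiation statistics: observed/expected/unbiased
# heterozygosity, inbreeding coefficient, rarefied allelic richness,
# Nei's FST with sample-size correction, Jost's D and PCoA.

# Per-population per-locus summaries on typed copies only.
locus_pop_stats <- function(G) {
  pops <- unique(G$pop_ids)
  L <- n_loci(G)
  out <- vector("list", length(pops))
  names(out) <- pops
  for (p in pops) {
    rows <- which(G$pop_ids == p)
    st <- vector("list", L)
    for (l in seq_len(L)) {
      a1 <- G$calls[rows, l, 1]; a2 <- G$calls[rows, l, 2]
      typed <- a1 != G$missing & a2 != G$missing
      copies <- c(a1[typed], a2[typed])
      tab <- table(copies)
      st[[l]] <- list(n = sum(typed),                  # typed diploids
                      counts = as.integer(tab),
                      alleles = as.integer(names(tab)),
                      het = if (sum(typed)) mean(a1[typed] != a2[typed]) else NA_real_)
    }
    out[[p]] <- st
  }
  out
}

#' Observed, expected and unbiased expected heterozygosity
#'
#' Per population and locus on typed copies only: `Ho` = fraction of
#' heterozygous individuals, `He = 1 - sum(p^2)`, and
#' `uHe = (2n/(2n-1)) He` with n the number of typed diploid individuals.
#' Locus means are reported with standard errors across loci (sd/sqrt(L)).
#'
#' @param G a [genotype_matrix()].
#' @return list with `per_locus` (data.frame pop, locus, n, Ho, He, uHe) and
#'   `summary` (data.frame per pop: Ho, He, uHe with `*_se`).
#' @export
heterozygosity <- function(G) {
  st <- locus_pop_stats(G)
  per <- do.call(rbind, lapply(names(st), function(p) {
    do.call(rbind, lapply(seq_along(st[[p]]), function(l) {
      s <- st[[p]][[l]]
      if (s$n == 0) return(data.frame(pop = p, locus = G$loci[l], n = 0L,
                                      Ho = NA_real_, He = NA_real_,
                                      uHe = NA_real_))
      pr <- s$counts / sum(s$counts)
      He <- 1 - sum(pr^2)
      data.frame(pop = p, locus = G$loci[l], n = s$n, Ho = s$het, He = He,
                 uHe = 2 * s$n / (2 * s$n - 1) * He,
                 stringsAsFactors = FALSE)
    }))
  }))
  se <- function(x) sd(x, na.rm = TRUE) / sqrt(sum(!is.na(x)))
  summ <- do.call(rbind, lapply(split(per, per$pop), function(d)
    data.frame(pop = d$pop[1],
               Ho = mean(d$Ho, na.rm = TRUE), Ho_se = se(d$Ho),
               He = mean(d$He, na.rm = TRUE), He_se = se(d$He),
               uHe = mean(d$uHe, na.rm = TRUE), uHe_se = se(d$uHe),
               stringsAsFactors = FALSE)))
  rownames(summ) <- NULL
  list(per_locus = per, summary = summ)
}

# Nei's unbiased within-population gene diversity at one locus:
# Hs = n/(n-1) * (1 - sum p^2 - Ho/(2n))
unbiased_hs_locus <- function(counts, n, ho) {
  if (n < 2) return(NA_real_)
  pr <- counts / sum(counts)
  n / (n - 1) * (1 - sum(pr^2) - ho / (2 * n))
}

#' Inbreeding coefficient per population
#'
#' `FIS = 1 - Ho/Hs`, with Ho and the unbiased within-population gene
#' diversity Hs averaged over loci before taking the ratio (the basic-stats
#' convention).
#'
#' @param G a [genotype_matrix()].
#' @return data.frame per pop: Ho, Hs, FIS.
#' @export
fis <- function(G) {
  st <- locus_pop_stats(G)
  do.call(rbind, lapply(names(st), function(p) {
    hs <- vapply(st[[p]], function(s)
      if (s$n >= 2) unbiased_hs_locus(s$counts, s$n, s$het) else NA_real_,
      numeric(1))
    ho <- vapply(st[[p]], function(s) if (s$n) s$het else NA_real_, numeric(1))
    mho <- mean(ho, na.rm = TRUE); mhs <- mean(hs, na.rm = TRUE)
    data.frame(pop = p, Ho = mho, Hs = mhs,
               FIS = if (mhs > 0) 1 - mho / mhs else NA_real_,
               stringsAsFactors = FALSE)
  }))
}

#' Rarefied allelic richness
#'
#' Expected number of distinct alleles in a standardized subsample of `g`
#' gene copies, by the hypergeometric expectation
#' `AR = sum_i [1 - choose(N - N_i, g)/choose(N, g)]` with N typed copies
#' and N_i copies of allele i. Loci where `g` exceeds N yield NA with a
#' warning.
#'
#' @param G a [genotype_matrix()].
#' @param g rarefaction size in gene copies. The conventional "rarefaction
#'   size = 8 individuals" corresponds to `g = 16` for diploids.
#' @return list with `per_locus` (pop, locus, N, AR) and `summary` (per pop
#'   mean AR with SE across loci).
#' @export
allelic_richness <- function(G, g = 16L) {
  st <- locus_pop_stats(G)
  warned <- FALSE
  per <- do.call(rbind, lapply(names(st), function(p) {
    do.call(rbind, lapply(seq_along(st[[p]]), function(l) {
      s <- st[[p]][[l]]
      N <- sum(s$counts)
      if (N < g) {
        if (!warned) {
          warning("rarefaction size g exceeds typed copies at some loci; NA",
                  call. = FALSE)
          warned <<- TRUE
        }
        ar <- NA_real_
      } else {
        ar <- sum(1 - exp(lchoose(N - s$counts, g) - lchoose(N, g)))
      }
      data.frame(pop = p, locus = G$loci[l], N = N, AR = ar,
                 stringsAsFactors = FALSE)
    }))
  }))
  summ <- do.call(rbind, lapply(split(per, per$pop), function(d)
    data.frame(pop = d$pop[1], AR = mean(d$AR, na.rm = TRUE),
               AR_se = sd(d$AR, na.rm = TRUE) / sqrt(sum(!is.na(d$AR))),
               stringsAsFactors = FALSE)))
  rownames(summ) <- NULL
  list(per_locus = per, summary = summ)
}

# Nei/Nei-Chesser corrected Hs, Ht, Ho per locus for a set of populations.
nei_locus_components <- function(G, pops = unique(G$pop_ids)) {
  st <- locus_pop_stats(G)[pops]
  L <- n_loci(G)
  out <- data.frame(locus = G$loci, Ho = NA_real_, Hs = NA_real_,
                    Ht = NA_real_)
  for (l in seq_len(L)) {
    s <- lapply(st, `[[`, l)
    keep <- vapply(s, function(x) x$n >= 2, logical(1))
    s <- s[keep]
    k <- length(s)
    if (k < 2) next
    ns <- vapply(s, `[[`, numeric(1), "n")
    nh <- k / sum(1 / ns)                       # harmonic mean sample size
    alleles <- sort(unique(unlist(lapply(s, `[[`, "alleles"))))
    P <- t(vapply(s, function(x) {
      v <- numeric(length(alleles))
      v[match(x$alleles, alleles)] <- x$counts / sum(x$counts)
      v
    }, numeric(length(alleles))))
    ho <- mean(vapply(s, `[[`, numeric(1), "het"))
    hs_obs <- 1 - mean(rowSums(P^2))
    hs <- nh / (nh - 1) * (hs_obs - ho / (2 * nh))
    pbar <- colMeans(P)
    ht_obs <- 1 - sum(pbar^2)
    ht <- ht_obs + hs / (nh * k) - ho / (2 * nh * k)
    out$Ho[l] <- ho; out$Hs[l] <- hs; out$Ht[l] <- ht
  }
  out
}

#' Nei's FST with sample-size correction
#'
#' `FST = 1 - Hs/Ht` with within- and total gene diversities corrected for
#' sample size via the harmonic mean of population sizes, computed per
#' locus; the multi-locus estimate combines loci as a ratio of sums.
#'
#' @param G a [genotype_matrix()].
#' @param pops populations to include (default all).
#' @return for `overall_fst` a list (fst, per_locus data.frame, fst_se);
#'   for `pairwise_fst_nei` a symmetric matrix with zero diagonal.
#' @export
overall_fst <- function(G, pops = unique(G$pop_ids)) {
  comp <- nei_locus_components(G, pops)
  ok <- !is.na(comp$Hs) & !is.na(comp$Ht) & comp$Ht > 0
  fst_locus <- 1 - comp$Hs[ok] / comp$Ht[ok]
  list(fst = 1 - sum(comp$Hs[ok]) / sum(comp$Ht[ok]),
       fst_se = sd(fst_locus) / sqrt(length(fst_locus)),
       per_locus = comp)
}

#' @rdname overall_fst
#' @export
pairwise_fst_nei <- function(G) {
  pops <- unique(G$pop_ids)
  k <- length(pops)
  M <- matrix(0, k, k, dimnames = list(pops, pops))
  if (k >= 2)
    for (i in seq_len(k - 1)) for (j in seq(i + 1, k))
      M[i, j] <- M[j, i] <- overall_fst(G, pops[c(i, j)])$fst
  M
}

#' Jost's D differentiation
#'
#' Per locus `D = (Ht - Hs)/(1 - Hs) * k/(k - 1)` with unbiased Hs and Ht
#' and k populations; loci are combined by arithmetic mean, with SE across
#' loci.
#'
#' @param G a [genotype_matrix()].
#' @param pops populations to include (default all).
#' @return list (D, D_se, per_locus); `pairwise_jost_d` returns a matrix.
#' @export
jost_dest <- function(G, pops = unique(G$pop_ids)) {
  comp <- nei_locus_components(G, pops)
  k <- length(pops)
  ok <- !is.na(comp$Hs) & comp$Hs < 1
  d <- (comp$Ht[ok] - comp$Hs[ok]) / (1 - comp$Hs[ok]) * k / (k - 1)
  list(D = mean(d), D_se = sd(d) / sqrt(length(d)),
       per_locus = data.frame(locus = comp$locus[ok], D = d))
}

#' @rdname jost_dest
#' @export
pairwise_jost_d <- function(G) {
  pops <- unique(G$pop_ids)
  k <- length(pops)
  M <- matrix(0, k, k, dimnames = list(pops, pops))
  if (k >= 2)
    for (i in seq_len(k - 1)) for (j in seq(i + 1, k))
      M[i, j] <- M[j, i] <- jost_dest(G, pops[c(i, j)])$D
  M
}

#' Principal coordinates analysis
#'
#' Gower double-centering of `-D^2/2` followed by eigendecomposition;
#' coordinates are eigenvectors scaled by the square root of their (positive)
#' eigenvalues. Negative eigenvalues are dropped and reported.
#'
#' @param D symmetric distance matrix (or `dist`).
#' @return list: `coordinates` (n x m), `eigenvalues` (all), `explained`
#'   (proportion of the positive-eigenvalue sum), `n_negative`.
#' @export
pcoa <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-8)))
    stop("distance matrix must be symmetric")
  A <- -0.5 * D^2
  J <- diag(n) - matrix(1 / n, n, n)
  B <- J %*% A %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  pos <- e$values > max(e$values, 0) * 1e-9
  coords <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(e$values[pos]), nrow = sum(pos))
  rownames(coords) <- rownames(D)
  colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  list(coordinates = coords, eigenvalues = e$values,
       explained = e$values[pos] / sum(e$values[pos]),
       n_negative = sum(e$values < -max(abs(e$values)) * 1e-9))
}

#' Grouped diversity report
#'
#' Reproduces the familiar report layout: one row per group of populations
#' (e.g. all / east / west / reference species) with population and
#' individual counts, rarefied allelic richness, observed and expected
#' heterozygosity, FIS, FST and Jost's D, each with standard errors across
#' loci (FIS: across populations).
#'
#' @param G a [genotype_matrix()].
#' @param groups named list: group label -> character vector of pop ids.
#' @param g rarefaction size in gene copies (default 16, i.e. 8 diploids).
#' @return data.frame, one row per group.
#' @export
diversity_report <- function(G, groups, g = 16L) {
  rows <- lapply(names(groups), function(lab) {
    pops <- groups[[lab]]
    sub <- subset_individuals(G, G$pop_ids %in% pops)
    het <- heterozygosity(sub)
    ar <- allelic_richness(sub, g)
    fst <- overall_fst(sub)
    d <- jost_dest(sub)
    f <- fis(sub)
    # pool population summaries, SE across populations for FIS,
    # across loci (pooled per-pop locus values) for the rest
    data.frame(group = lab, N_pop = length(pops),
               N_ind = n_individuals(sub),
               AR = mean(ar$summary$AR, na.rm = TRUE),
               AR_se = mean(ar$summary$AR_se, na.rm = TRUE),
               Ho = mean(het$summary$Ho), Ho_se = mean(het$summary$Ho_se),
               He = mean(het$summary$He), He_se = mean(het$summary$He_se),
               FIS = mean(f$FIS, na.rm = TRUE),
               FIS_se = sd(f$FIS, na.rm = TRUE) /
                 sqrt(sum(!is.na(f$FIS))),
               FST = fst$fst, FST_se = fst$fst_se,
               D_EST = d$D, D_EST_se = d$D_se,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
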