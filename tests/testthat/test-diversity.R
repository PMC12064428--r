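# genotype helpers: gm(a, b) is one individual's L x 2 call matrix
gm1 <- function(...) matrix(c(...), ncol = 2, byrow = TRUE)

test_that("heterozygosity matches hand arithmetic", {
  # one pop, one locus: genotypes AA AA AB AB BB -> p = (0.6, 0.4), n = 5
  G <- make_genotypes(list(p1 = list(gm1(150, 150), gm1(150, 150),
                                     gm1(150, 152), gm1(150, 152),
                                     gm1(152, 152))))
  h <- heterozygosity(G)
  expect_equal(h$per_locus$Ho, 0.4)
  expect_equal(h$per_locus$He, 1 - (0.6^2 + 0.4^2))
  expect_equal(h$per_locus$uHe, 10 / 9 * 0.48)

  # fixed locus -> Ho = He = 0; two alleles at 0.5 -> He = 0.5
  G2 <- make_genotypes(list(p1 = list(gm1(150, 150, 150, 152),
                                      gm1(150, 150, 152, 150))))
  h2 <- heterozygosity(G2)
  expect_equal(h2$per_locus$He, c(0, 0.5))
  expect_equal(h2$per_locus$Ho, c(0, 1))
})

test_that("FIS covers its sign cases", {
  # all-heterozygote two-allele pop of 2: Ho = 1, Hs = 0.5 -> FIS = -1
  G <- make_genotypes(list(p1 = list(gm1(150, 152), gm1(150, 152))))
  expect_equal(fis(G)$FIS, -1)
  # Ho = 0 with diversity present -> FIS = 1
  G2 <- make_genotypes(list(p1 = list(gm1(150, 150), gm1(152, 152))))
  expect_equal(fis(G2)$FIS, 1)
})

test_that("rarefied allelic richness equals the hypergeometric form", {
  # counts {3,1}, N = 4, g = 2 -> 1.5 (brute-force verified)
  G <- make_genotypes(list(p1 = list(gm1(150, 150), gm1(150, 152))))
  ar <- allelic_richness(G, g = 2)
  expect_equal(ar$per_locus$AR, 1.5)
  expect_equal(ar_bruteforce(c(3, 1), 2), 1.5)

  # monomorphic -> 1 for any g; g = N -> observed allele count
  G1 <- make_genotypes(list(p1 = list(gm1(150, 150), gm1(150, 150))))
  expect_equal(allelic_richness(G1, g = 3)$per_locus$AR, 1)
  expect_equal(allelic_richness(G, g = 4)$per_locus$AR, 2)

  # g larger than typed copies -> NA with warning
  expect_warning(arna <- allelic_richness(G, g = 10), "exceeds")
  expect_true(is.na(arna$per_locus$AR))

  # brute-force equality on random configurations with N <= 12
  set.seed(71)
  for (case in 1:25) {
    k <- sample(2:5, 1)
    counts <- as.vector(rmultinom(1, sample(4:12, 1), runif(k) + 0.2))
    counts <- counts[counts > 0]
    N <- sum(counts)
    g <- sample(seq_len(N - 1), 1)
    hyper <- sum(1 - exp(lchoose(N - counts, g) - lchoose(N, g)))
    expect_equal(hyper, ar_bruteforce(counts, g), tolerance = 1e-12)
  }
})

test_that("Nei FST behaves at its endpoints and is label-invariant", {
  # two pops fixed for different alleles -> 1
  G <- make_genotypes(list(
    p1 = replicate(6, gm1(150, 150), simplify = FALSE),
    p2 = replicate(6, gm1(152, 152), simplify = FALSE)))
  expect_equal(overall_fst(G)$fst, 1)
  expect_equal(pairwise_fst_nei(G)["p1", "p2"], 1)

  # identical observed frequencies, equal n -> near zero (may be slightly
  # negative from the unbiased correction)
  comp <- list(gm1(150, 150), gm1(150, 152), gm1(152, 152),
               gm1(150, 152), gm1(150, 150), gm1(152, 152))
  Geq <- make_genotypes(list(p1 = comp, p2 = comp))
  expect_lte(overall_fst(Geq)$fst, 0.01)

  # label-permutation invariance
  ds <- simulate_recovery_dataset(n = 40, L = 6, seed = 73)
  Gr <- ds$genotypes
  Gr$pop_ids <- rep(c("a", "b"), each = 20)
  M1 <- pairwise_fst_nei(Gr)
  Gr2 <- Gr; Gr2$pop_ids <- rep(c("b", "a"), each = 20)
  M2 <- pairwise_fst_nei(Gr2)
  expect_equal(M1["a", "b"], M2["b", "a"])
})

test_that("FST tracks planted divergence and its F-model expectation", {
  # two clusters drifted F from a common ancestor: E[Nei FST] = F/(2-F)
  est <- vapply(c(0.05, 0.2, 0.5), function(f) {
    cfg <- sim_config(n_clusters = 2, cluster_species = c("a", "b"),
                      n_loci_nuclear = 48, drift_F = f, seed = 74)
    fr <- simulate_allele_frequencies(cfg)
    q <- rbind(matrix(rep(c(1, 0), 50), ncol = 2, byrow = TRUE),
               matrix(rep(c(0, 1), 50), ncol = 2, byrow = TRUE))
    G <- simulate_admixed_genotypes(fr$freq, q,
                                    rep(c("pa", "pb"), each = 50),
                                    seed = 75)
    overall_fst(G)$fst
  }, numeric(1))
  expect_true(all(diff(est) > 0))           # monotone in divergence
  expect_lt(abs(est[2] - 0.2 / 1.8) / (0.2 / 1.8), 0.25)
})

test_that("Jost's D matches a hand-computed two-population fixture", {
  # pop1: allele counts (6, 2); pop2: (2, 6); n = 4 diploids each
  G <- make_genotypes(list(
    p1 = list(gm1(150, 150), gm1(150, 150), gm1(150, 152), gm1(150, 152)),
    p2 = list(gm1(152, 152), gm1(152, 152), gm1(150, 152), gm1(150, 152))))
  # independent hand computation (Nei-Chesser unbiased components):
  ho <- (0.5 + 0.5) / 2
  hs_obs <- 1 - mean(c(0.75^2 + 0.25^2, 0.25^2 + 0.75^2))
  nh <- 4
  hs <- nh / (nh - 1) * (hs_obs - ho / (2 * nh))
  ht_obs <- 1 - 2 * 0.5^2
  ht <- ht_obs + hs / (nh * 2) - ho / (2 * nh * 2)
  d_hand <- (ht - hs) / (1 - hs) * 2
  expect_equal(jost_dest(G)$D, d_hand)

  # endpoints: Hs = Ht -> 0; fully differentiated fixed pops -> 1
  Gfix <- make_genotypes(list(
    p1 = replicate(5, gm1(150, 150), simplify = FALSE),
    p2 = replicate(5, gm1(152, 152), simplify = FALSE)))
  expect_equal(jost_dest(Gfix)$D, 1)
})

test_that("PCoA recovers geometry", {
  # three equidistant points: two equal positive eigenvalues
  D3 <- matrix(1, 3, 3) - diag(3)
  p3 <- pcoa(D3)
  ev <- p3$eigenvalues[p3$eigenvalues > 1e-9]
  expect_length(ev, 2)
  expect_equal(ev[1], ev[2])

  # planar configurations are recovered up to isometry
  set.seed(76)
  X <- matrix(rnorm(14), 7, 2)
  D <- as.matrix(dist(X))
  co <- pcoa(D)$coordinates
  expect_equal(as.matrix(dist(co[, 1:2])), D, tolerance = 1e-8,
               ignore_attr = TRUE)
  # against the base-R oracle
  cmd <- cmdscale(D, k = 2)
  expect_equal(abs(cor(co[, 1], cmd[, 1])), 1, tolerance = 1e-6)

  # duplicated point -> coincident coordinates
  D8 <- as.matrix(dist(rbind(X, X[1, ])))
  co8 <- pcoa(D8)$coordinates
  expect_equal(co8[8, ], co8[1, ], tolerance = 1e-8)
})

test_that("grouped report has the expected layout", {
  ds <- simulate_dataset(sim_config(seed = 77))
  G <- ds$genotypes
  groups <- list(all = unique(G$pop_ids),
                 east = ds$pops$pop_id[ds$pops$region == "east"],
                 west = ds$pops$pop_id[ds$pops$region == "west"])
  rep_tab <- diversity_report(G, groups, g = 8)
  expect_equal(rep_tab$group, c("all", "east", "west"))
  expect_true(all(c("AR", "Ho", "He", "FIS", "FST", "D_EST") %in%
                    names(rep_tab)))
  expect_true(all(rep_tab$Ho >= 0 & rep_tab$Ho <= 1))
  expect_true(all(rep_tab$N_ind > 0))
})
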