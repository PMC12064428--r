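test_that("allele-frequency profiles follow the F-model", {
  # K = 1: single profile, every locus sums to 1
  cfg1 <- sim_config(n_clusters = 1, cluster_species = "sp1", seed = 3)
  fr1 <- simulate_allele_frequencies(cfg1)
  expect_equal(dim(fr1$freq), c(1, 16, 8))
  expect_equal(apply(fr1$freq, c(1, 2), sum), matrix(1, 1, 16))

  # F -> 0 limit: cluster profiles collapse onto the ancestral profile
  cfg0 <- sim_config(n_clusters = 2, cluster_species = c("a", "b"),
                     drift_F = 1e-5, seed = 4)
  fr0 <- simulate_allele_frequencies(cfg0)
  expect_lt(max(abs(sweep(fr0$freq, 2:3, fr0$ancestral))), 0.02)

  # F = 0 / F = 1 rejected
  expect_error(sim_config(drift_F = 0), "strictly in")
  expect_error(sim_config(drift_F = 1), "strictly in")

  # mean across many replicate cluster draws approximates the ancestral
  # profile (clusters are iid around it): use many clusters as replicates
  cfgM <- sim_config(n_clusters = 400,
                     cluster_species = paste0("s", 1:400),
                     n_loci_nuclear = 2, drift_F = 0.3, seed = 5)
  frM <- simulate_allele_frequencies(cfgM)
  expect_lt(max(abs(colMeans(frM$freq[, 1, ]) - frM$ancestral[1, ])), 0.02)
})

test_that("admixed genotype generation matches its closed forms", {
  # q = (1, 0) and cluster 1 fixed: every call is the fixed allele size
  freq <- array(0, c(2, 3, 2))
  freq[1, , 1] <- 1   # cluster 1 fixed for allele index 1 -> size 150
  freq[2, , 2] <- 1   # cluster 2 fixed for allele index 2 -> size 152
  G <- simulate_admixed_genotypes(freq, matrix(c(1, 0), 1), "p1", seed = 1)
  expect_true(all(G$calls == 150L))

  # q = (0.5, 0.5) between two fixed clusters: heterozygote proportion 1/2
  n <- 4000
  q <- matrix(0.5, n, 2)
  G2 <- simulate_admixed_genotypes(freq, q, rep("p1", n), seed = 2)
  het <- mean(G2$calls[, 1, 1] != G2$calls[, 1, 2])
  expect_lt(abs(het - 0.5), 4 * sqrt(0.25 / n))

  # dimension mismatch is an error
  expect_error(simulate_admixed_genotypes(freq, matrix(1, 1, 3), "p1"),
               "clusters")
})

test_that("missing-data injection is binomial and recorded", {
  rec <- simulate_recovery_dataset(n = 100, L = 10, seed = 7)
  G <- rec$genotypes

  G0 <- inject_missing(G, 0, seed = 1)
  expect_identical(G0$calls, G$calls)

  G5 <- inject_missing(G, 0.05, seed = 1)
  m <- sum(attr(G5, "missing_mask"))
  expect_gte(m, qbinom(5e-4, 1000, 0.05))
  expect_lte(m, qbinom(1 - 5e-4, 1000, 0.05))
  # both copies go missing together
  miss1 <- G5$calls[, , 1] == MISSING_CODE
  miss2 <- G5$calls[, , 2] == MISSING_CODE
  expect_true(all((miss1 == miss2)[attr(G5, "missing_mask")]))

  # an all-missing individual still serializes and round-trips
  Gall <- inject_missing(G, 0.99, seed = 2)
  f <- tempfile()
  write_structure(Gall, f)
  expect_identical(read_structure(f)$calls, Gall$calls)
})

test_that("environment simulation links covariates to the index", {
  # beta = 0: expected index identical across populations
  cfg <- sim_config(env_coefficients = rep(0, 5), seed = 11)
  env <- simulate_environment(cfg)
  expect_equal(length(unique(env$expected_index)), 1L)

  # intercept only at inverse-logit(-1.0986) = 0.25: LLN over many pops
  pops <- data.frame(pop_id = sprintf("q%04d", 1:1500), region = "west",
                     lat = runif(1500, 45, 47), lon = runif(1500, 6, 9),
                     n = 30L)
  cfgL <- sim_config(pops = pops, env_coefficients = rep(0, 5),
                     env_intercept = log(0.25 / 0.75), seed = 12)
  envL <- simulate_environment(cfgL)
  expect_lt(abs(mean(envL$introgression_index) - 0.25), 0.01)

  # single positive coefficient: expected index is monotone in the covariate
  cfgS <- sim_config(env_covariates = "x", env_coefficients = 0.7, seed = 13)
  envS <- simulate_environment(cfgS)
  expect_equal(cor(envS$x, envS$expected_index, method = "spearman"), 1)

  # counts realize the index within rounding (half-units of 1/(2n))
  expect_true(all(abs((env$n_had + 0.5 * env$n_ad) /
                        (env$n_pure + env$n_ad + env$n_had) -
                        env$introgression_index) < 1e-12))
})

test_that("cp haplotypes follow founders with single-step minors", {
  cfg0 <- sim_config(minor_hap_rate = 0, seed = 21)
  ids <- sprintf("i%02d", 1:40)
  pops <- rep(cfg0$pops$pop_id[1:2], each = 20)
  cp <- simulate_cp_haplotypes(cfg0, individual_ids = ids, pop_ids = pops,
                               seed = 1)
  hl <- grep("^cp", names(cp))
  # rate 0: fixed within every population
  for (p in unique(pops))
    expect_equal(nrow(unique(cp[cp$pop_id == p, hl])), 1L)

  # rate 0.1: minor-carrier count is binomial around 10% (one-step variants)
  cfg1 <- sim_config(minor_hap_rate = 0.1, seed = 21)
  ids2 <- sprintf("j%03d", 1:400)
  pops2 <- rep(cfg1$pops$pop_id[1], 400)
  cp2 <- simulate_cp_haplotypes(cfg1, individual_ids = ids2,
                                pop_ids = pops2, seed = 2)
  founder <- as.integer(cp2[1, hl])  # majority haplotype
  steps <- apply(cp2[hl], 1, function(h) sum(abs(as.integer(h) - founder)))
  minors <- sum(steps > 0)
  expect_true(all(steps %in% c(0L, 1L)))
  expect_gte(minors, qbinom(5e-4, 400, 0.1))
  expect_lte(minors, qbinom(1 - 5e-4, 400, 0.1))
})

test_that("full dataset honours truth invariants", {
  ds <- simulate_dataset(sim_config(seed = 31))
  expect_lt(max(abs(rowSums(ds$truth$true_q) - 1)), 1e-12)
  expect_lt(max(abs(apply(ds$truth$frequencies, c(1, 2), sum) - 1)), 1e-12)
  expect_equal(nrow(ds$truth$true_q), sum(ds$pops$n))

  # empirical allele frequencies converge on the truth for a single-cluster
  # sample: at n gene copies the multinomial expectation of the L1 error is
  # sum_i sqrt(2 p_i (1 - p_i) / (pi n)); assert below 1.5x that bound at
  # n = 5000 (the folded-normal mean; 1.5x leaves ~4 sd of slack)
  freq <- simulate_allele_frequencies(
    sim_config(n_clusters = 1, cluster_species = "s", n_loci_nuclear = 1,
               seed = 32))$freq
  p <- freq[1, 1, ]
  Gc <- simulate_admixed_genotypes(freq, matrix(1, 2500, 1),
                                   rep("p", 2500), seed = 33)
  obs <- table(factor(c(Gc$calls[, 1, 1], Gc$calls[, 1, 2]),
                      levels = 150 + 2 * (0:7))) / 5000
  l1_5000 <- sum(abs(as.numeric(obs) - p))
  expect_lt(l1_5000, 1.5 * sum(sqrt(2 * p * (1 - p) / (pi * 5000))))
  # and the error shrinks with sample size (n = 250 vs 5000 copies)
  Gs <- simulate_admixed_genotypes(freq, matrix(1, 125, 1),
                                   rep("p", 125), seed = 34)
  obs_s <- table(factor(c(Gs$calls[, 1, 1], Gs$calls[, 1, 2]),
                        levels = 150 + 2 * (0:7))) / 250
  expect_lt(l1_5000, sum(abs(as.numeric(obs_s) - p)))
})
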