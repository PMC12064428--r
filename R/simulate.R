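# Synthetic-data generator: nuclear SSR genotypes under an F-model of
# correlated cluster frequencies with admixed individuals, chloroplast
# haplotypes with lineage structure, and environment-linked introgression.
# Every downstream stage of the pipeline is testable against the truth
# tables produced here.

#' Simulation configuration
#'
#' Describes the synthetic world: cluster number and drift, locus counts,
#' populations with coordinates and sample sizes, admixture, missing data
#' and the logit-linear environment -> introgression link. Defaults emulate
#' a two-species white-oak system (a focal species with a west and an east
#' intraspecific cluster, plus a donor species) typed at 16 nuclear and 8
#' chloroplast SSR loci with 17-47 individuals per population.
#'
#' @param n_clusters number of genetic clusters K (default 3: focal west,
#'   focal east, donor species).
#' @param cluster_species character vector mapping each cluster to a species
#'   label; length `n_clusters`.
#' @param n_loci_nuclear,n_loci_cp locus counts (defaults 16 and 8).
#' @param alleles_per_locus alleles segregating per nuclear locus (default 8).
#' @param pops data.frame with columns `pop_id`, `region`, `lat`, `lon`, `n`
#'   (defaults to [default_populations()]).
#' @param drift_F per-cluster drift parameter F in (0,1) (recycled; default
#'   0.15).
#' @param admixture_alpha Dirichlet concentration for generic admixed q draws
#'   (default 1).
#' @param missing_rate per-individual-per-locus dropout probability in [0,1)
#'   (default 0.02).
#' @param env_covariates names of the environmental covariates.
#' @param env_coefficients logit-scale coefficients linking covariates to the
#'   expected introgression index; same length as `env_covariates`. The
#'   default plants a strong negative longitude-like effect and positive
#'   wetness/precipitation effects.
#' @param env_intercept logit-scale intercept (default -1.5, i.e. a baseline
#'   index of about 0.18).
#' @param env_precision beta-distribution precision of the realized index
#'   around its expectation (default 30).
#' @param cp_fraction fraction of individuals typed at chloroplast loci
#'   (default 0.5: every second individual).
#' @param minor_hap_rate per-individual probability of carrying a one-step
#'   mutant of the population founder haplotype (default 0.05).
#' @param motif_start_nuclear,motif_step_nuclear,motif_start_cp,motif_step_cp
#'   allele-size ladder: size = start + step * index.
#' @param seed master seed expanded into per-stage substreams.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_clusters = 3L,
                       cluster_species = c("pubescens", "pubescens", "petraea"),
                       n_loci_nuclear = 16L,
                       n_loci_cp = 8L,
                       alleles_per_locus = 8L,
                       pops = default_populations(),
                       drift_F = 0.15,
                       admixture_alpha = 1,
                       missing_rate = 0.02,
                       env_covariates = c("longitude", "prec_wettest_quarter",
                                          "wetness_index", "northness",
                                          "temp_seasonality"),
                       env_coefficients = c(-0.8, 0.4, 0.4, 0.2, 0.2),
                       env_intercept = -1.5,
                       env_precision = 30,
                       cp_fraction = 0.5,
                       minor_hap_rate = 0.05,
                       motif_start_nuclear = 150L, motif_step_nuclear = 2L,
                       motif_start_cp = 80L, motif_step_cp = 1L,
                       seed = 1L) {
  stopifnot(n_clusters >= 1, n_loci_nuclear >= 1, n_loci_cp >= 1,
            alleles_per_locus >= 1)
  drift_F <- rep_len(drift_F, n_clusters)
  if (any(!is.finite(drift_F)) || any(drift_F <= 0) || any(drift_F >= 1))
    stop("drift_F must lie strictly in (0,1)")
  stop_if_not_scalar_prob(missing_rate, "missing_rate", open_upper = TRUE)
  stop_if_not_scalar_prob(minor_hap_rate, "minor_hap_rate", open_upper = TRUE)
  if (admixture_alpha <= 0) stop("admixture_alpha must be positive")
  if (env_precision <= 0) stop("env_precision must be positive")
  if (length(cluster_species) != n_clusters)
    stop("cluster_species must have one entry per cluster")
  if (length(env_coefficients) != length(env_covariates))
    stop("env_coefficients length must match env_covariates")
  need <- c("pop_id", "region", "lat", "lon", "n")
  if (!all(need %in% names(pops))) stop("pops needs columns: ",
                                        paste(need, collapse = ", "))
  if (any(pops$n < 1)) stop("all population sizes must be >= 1")
  structure(list(n_clusters = as.integer(n_clusters),
                 cluster_species = cluster_species,
                 n_loci_nuclear = as.integer(n_loci_nuclear),
                 n_loci_cp = as.integer(n_loci_cp),
                 alleles_per_locus = as.integer(alleles_per_locus),
                 pops = pops, drift_F = drift_F,
                 admixture_alpha = admixture_alpha,
                 missing_rate = missing_rate,
                 env_covariates = env_covariates,
                 env_coefficients = env_coefficients,
                 env_intercept = env_intercept,
                 env_precision = env_precision,
                 cp_fraction = cp_fraction,
                 minor_hap_rate = minor_hap_rate,
                 motif_start_nuclear = as.integer(motif_start_nuclear),
                 motif_step_nuclear = as.integer(motif_step_nuclear),
                 motif_start_cp = as.integer(motif_start_cp),
                 motif_step_cp = as.integer(motif_step_cp),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Default synthetic population layout
#'
#' Twelve populations in a rectangular study window, six in a `west` and six
#' in an `east` region, with sample sizes drawn uniformly from 17-47
#' individuals (the range of the emulated study design).
#'
#' @param n_west,n_east population counts per region.
#' @param seed seed for coordinates and sample sizes.
#' @return data.frame with columns pop_id, region, lat, lon, n.
#' @export
default_populations <- function(n_west = 6L, n_east = 6L, seed = 20L) {
  set.seed(seed)
  n <- n_west + n_east
  region <- rep(c("west", "east"), c(n_west, n_east))
  lon <- c(runif(n_west, 6, 10.5), runif(n_east, 11, 17))
  lat <- runif(n, 45.5, 48.2)
  data.frame(pop_id = sprintf("P%03d", 200 + seq_len(n)),
             region = region, lat = lat, lon = lon,
             n = sample(17:47, n, replace = TRUE),
             stringsAsFactors = FALSE)
}

#' Simulate cluster allele-frequency profiles (F-model)
#'
#' Ancestral frequencies per locus are drawn from a flat Dirichlet simplex;
#' each cluster's frequencies are drawn from
#' Dirichlet(ancestral * (1-F)/F), so small F means strong correlation with
#' the ancestral pool and F -> 1 means strong drift.
#'
#' @param config a [sim_config()].
#' @param seed optional seed override.
#' @return list with `freq` (K x L x A array) and `ancestral` (L x A matrix);
#'   allele dimension indexed on the repeat ladder.
#' @export
simulate_allele_frequencies <- function(config, seed = NULL) {
  K <- config$n_clusters; L <- config$n_loci_nuclear
  A <- config$alleles_per_locus
  if (A < 2) stop("alleles_per_locus must be >= 2 to simulate frequencies")
  conc <- (1 - config$drift_F) / config$drift_F
  if (any(!is.finite(conc)) || any(conc <= 0))
    stop("non-finite drift concentration: F must be strictly inside (0,1)")
  set.seed(seed %||% derive_seed(config$seed, "allele_frequencies"))
  ancestral <- rdirichlet(L, rep(1, A))
  freq <- array(NA_real_, c(K, L, A))
  for (k in seq_len(K))
    for (l in seq_len(L))
      freq[k, l, ] <- rdirichlet(1L, ancestral[l, ] * conc[k])
  list(freq = freq, ancestral = ancestral)
}

#' Simulate diploid genotypes under the admixture model
#'
#' For each of the two gene copies of each individual at each locus, a source
#' cluster is drawn from the individual's membership vector q, then an allele
#' from that cluster's frequency vector. Allele indices are encoded as sizes
#' on the repeat ladder `motif_start + motif_step * (index - 1)`.
#'
#' @param freq K x L x A cluster frequency array.
#' @param true_q individuals x K matrix; rows must sum to 1.
#' @param pop_ids population label per individual.
#' @param individual_ids optional ids (default ind_00001, ...).
#' @param motif_start,motif_step allele-size ladder.
#' @param seed RNG seed.
#' @return a [genotype_matrix()].
#' @export
simulate_admixed_genotypes <- function(freq, true_q, pop_ids,
                                       individual_ids = NULL,
                                       motif_start = 150L, motif_step = 2L,
                                       seed = NULL) {
  K <- dim(freq)[1]; L <- dim(freq)[2]; A <- dim(freq)[3]
  true_q <- as.matrix(true_q)
  if (ncol(true_q) != K) stop("q has ", ncol(true_q), " columns but ", K,
                              " clusters were simulated")
  if (max(abs(rowSums(true_q) - 1)) > 1e-9) stop("q rows must sum to 1")
  n <- nrow(true_q)
  if (length(pop_ids) != n) stop("pop_ids length mismatch")
  if (!is.null(seed)) set.seed(seed)
  sizes <- motif_start + motif_step * (seq_len(A) - 1L)
  calls <- array(NA_integer_, c(n, L, 2L))
  for (i in seq_len(n)) {
    z <- sample.int(K, 2L * L, replace = TRUE, prob = true_q[i, ])
    for (l in seq_len(L)) {
      for (cpy in 1:2) {
        k <- z[(l - 1L) * 2L + cpy]
        calls[i, l, cpy] <- sizes[sample.int(A, 1L, prob = freq[k, l, ])]
      }
    }
  }
  genotype_matrix(calls,
                  individual_ids %||% sprintf("ind_%05d", seq_len(n)),
                  pop_ids, sprintf("L%02d", seq_len(L)))
}

#' Inject locus dropout
#'
#' Each individual x locus cell goes missing (both gene copies together, the
#' usual SSR dropout pattern) independently with probability `rate`. The
#' positions are recorded in the `missing_mask` attribute of the result.
#'
#' @param G a [genotype_matrix()].
#' @param rate dropout probability in [0,1).
#' @param seed RNG seed.
#' @return a [genotype_matrix()] with attribute `missing_mask` (n x L logical).
#' @export
inject_missing <- function(G, rate, seed = NULL) {
  stop_if_not_scalar_prob(rate, "rate", open_upper = TRUE)
  if (!is.null(seed)) set.seed(seed)
  n <- n_individuals(G); L <- n_loci(G)
  mask <- matrix(runif(n * L) < rate, n, L)
  calls <- G$calls
  calls[, , 1][mask] <- G$missing
  calls[, , 2][mask] <- G$missing
  out <- genotype_matrix(calls, G$individual_ids, G$pop_ids, G$loci, G$missing)
  attr(out, "missing_mask") <- mask
  out
}

#' Simulate chloroplast haplotypes
#'
#' Each population inherits a founder haplotype from its lineage; a fraction
#' of individuals (`minor_hap_rate`) carry a minor haplotype differing from
#' the founder by a single +/- one-repeat step at one locus. The marker is
#' haploid and uniform within an individual.
#'
#' @param config a [sim_config()].
#' @param lineage_map named list `region -> list(lineage = label, founder =
#'   integer allele-size vector of length n_loci_cp)`; defaults to a
#'   Balkan-like east founder and an Apennine-like west founder two steps
#'   apart.
#' @param individual_ids,pop_ids individuals to type (already subsampled to
#'   the cp fraction).
#' @param seed RNG seed.
#' @return data.frame: individual_id, pop_id, one column per cp locus,
#'   lineage.
#' @export
simulate_cp_haplotypes <- function(config, lineage_map = NULL,
                                   individual_ids, pop_ids, seed = NULL) {
  Lc <- config$n_loci_cp
  base <- config$motif_start_cp + config$motif_step_cp * 4L
  if (is.null(lineage_map)) {
    east <- rep(base, Lc)
    west <- east; west[1] <- west[1] + config$motif_step_cp
    west[2] <- west[2] + config$motif_step_cp
    lineage_map <- list(east = list(lineage = "Balkan", founder = east),
                        west = list(lineage = "Apennine", founder = west))
  }
  if (!is.null(seed)) set.seed(seed)
  pops <- config$pops
  reg <- setNames(pops$region, pops$pop_id)
  n <- length(individual_ids)
  hap <- matrix(NA_integer_, n, Lc)
  lin <- character(n)
  for (i in seq_len(n)) {
    info <- lineage_map[[reg[[pop_ids[i]]]]]
    if (is.null(info)) stop("no founder haplotype for region ",
                            reg[[pop_ids[i]]])
    h <- as.integer(info$founder)
    if (runif(1) < config$minor_hap_rate) {
      l <- sample.int(Lc, 1L)
      h[l] <- h[l] + sample(c(-1L, 1L), 1L) * config$motif_step_cp
    }
    hap[i, ] <- h
    lin[i] <- info$lineage
  }
  out <- data.frame(individual_id = individual_ids, pop_id = pop_ids,
                    hap, lineage = lin, stringsAsFactors = FALSE)
  names(out)[2L + seq_len(Lc)] <- sprintf("cp%02d", seq_len(Lc))
  out
}

#' Simulate environmental covariates and population introgression targets
#'
#' Covariates are standard-normal per population. The expected introgression
#' index is `inverse-logit(intercept + X beta)`; the realized index is drawn
#' from a beta distribution with that mean and precision `env_precision`,
#' then converted to admixed / highly-admixed individual counts that realize
#' the index within rounding (half-units of 1/(2n)).
#'
#' @param config a [sim_config()].
#' @param seed RNG seed.
#' @return data.frame: pop_id, covariates, `expected_index`,
#'   `introgression_index` (realized as counts), `n_pure`, `n_ad`, `n_had`.
#' @export
simulate_environment <- function(config, seed = NULL) {
  set.seed(seed %||% derive_seed(config$seed, "environment"))
  pops <- config$pops
  p <- length(config$env_covariates)
  X <- matrix(rnorm(nrow(pops) * p), nrow(pops), p,
              dimnames = list(pops$pop_id, config$env_covariates))
  eta <- config$env_intercept + drop(X %*% config$env_coefficients)
  mu <- inv_logit(eta)
  phi <- config$env_precision
  y <- rbeta(nrow(pops), mu * phi, (1 - mu) * phi)
  n <- pops$n
  h <- pmin(pmax(round(2 * n * y), 0L), 2L * n)  # index in half-units
  n_had <- pmax(0L, as.integer(h - n))
  n_ad <- as.integer(h - 2L * n_had)
  if (any(n_ad + n_had > n))
    stop("infeasible introgression index for population sizes")
  realized <- (n_had + 0.5 * n_ad) / n
  data.frame(pop_id = pops$pop_id, X, expected_index = mu,
             introgression_index = realized,
             n_pure = n - n_ad - n_had, n_ad = n_ad, n_had = n_had,
             stringsAsFactors = FALSE, check.names = FALSE)
}

# q-vectors at the category midpoints used by the classifier:
# pure 0.9375, admixed 0.75, highly admixed 0.5 membership to the focal
# species, remainder assigned to the donor cluster.
midpoint_q <- function(category, own_cluster, donor_cluster, K,
                       other_cluster = NULL, own_share = 0.9) {
  qf <- switch(category, pure = 0.9375, admixed = 0.75,
               highly_admixed = 0.5,
               stop("unknown category ", category))
  q <- numeric(K)
  if (is.null(other_cluster)) {
    q[own_cluster] <- qf
  } else {
    q[own_cluster] <- qf * own_share
    q[other_cluster] <- qf * (1 - own_share)
  }
  q[donor_cluster] <- q[donor_cluster] + (1 - qf)
  q
}

#' Simulate a complete synthetic dataset
#'
#' Orchestrates the full stated world: cluster frequencies, environment and
#' introgression targets, per-individual truth q at category midpoints,
#' admixture-model genotypes, locus dropout, and chloroplast haplotypes for
#' a subsample of individuals. The truth table carries everything needed to
#' validate downstream inference.
#'
#' @param config a [sim_config()].
#' @return list with elements `genotypes` ([genotype_matrix()]), `cp`
#'   (haplotype data.frame), `pops` (population table), `env` (environment
#'   table with the realized introgression index) and `truth` (list: true_q,
#'   frequencies, ancestral, categories, cluster_species, missing_mask).
#' @export
simulate_dataset <- function(config) {
  fr <- simulate_allele_frequencies(config)
  env <- simulate_environment(config)
  pops <- config$pops
  species <- config$cluster_species
  focal <- names(sort(table(species), decreasing = TRUE))[1]
  focal_clusters <- which(species == focal)
  donor <- which(species != focal)[1]
  if (is.na(donor)) donor <- focal_clusters[1]
  regions <- sort(unique(pops$region))
  # map each region to one focal intraspecific cluster (recycled if fewer)
  region_cluster <- setNames(
    focal_clusters[((seq_along(regions) - 1L) %% length(focal_clusters)) + 1L],
    regions)

  set.seed(derive_seed(config$seed, "individuals"))
  rows <- list(); qs <- list(); cats <- list()
  for (j in seq_len(nrow(pops))) {
    np <- pops$n[j]
    cat_j <- rep(c("pure", "admixed", "highly_admixed"),
                 c(env$n_pure[j], env$n_ad[j], env$n_had[j]))
    own <- region_cluster[[pops$region[j]]]
    other <- setdiff(focal_clusters, own)
    other <- if (length(other)) other[1] else NULL
    qj <- t(vapply(cat_j, midpoint_q, numeric(config$n_clusters),
                   own_cluster = own, donor_cluster = donor,
                   K = config$n_clusters, other_cluster = other))
    rows[[j]] <- data.frame(pop_id = pops$pop_id[j],
                            idx = seq_len(np), stringsAsFactors = FALSE)
    qs[[j]] <- qj; cats[[j]] <- cat_j
  }
  meta <- do.call(rbind, rows)
  true_q <- do.call(rbind, qs)
  categories <- unlist(cats, use.names = FALSE)
  ids <- sprintf("%s_i%02d", meta$pop_id, meta$idx)
  rownames(true_q) <- ids

  G <- simulate_admixed_genotypes(fr$freq, true_q, meta$pop_id,
                                  individual_ids = ids,
                                  motif_start = config$motif_start_nuclear,
                                  motif_step = config$motif_step_nuclear,
                                  seed = derive_seed(config$seed, "genotypes"))
  G <- inject_missing(G, config$missing_rate,
                      seed = derive_seed(config$seed, "missing"))

  set.seed(derive_seed(config$seed, "cp_subsample"))
  cp_idx <- which(seq_along(ids) %% round(1 / max(config$cp_fraction, 1e-9)) == 0)
  if (!length(cp_idx)) cp_idx <- seq_along(ids)
  cp <- simulate_cp_haplotypes(config,
                               individual_ids = ids[cp_idx],
                               pop_ids = meta$pop_id[cp_idx],
                               seed = derive_seed(config$seed, "cp"))

  pop_table <- data.frame(pop_id = pops$pop_id, region = pops$region,
                          lat = pops$lat, lon = pops$lon, n = pops$n,
                          stringsAsFactors = FALSE)
  class(pop_table) <- c("population_table", "data.frame")
  list(genotypes = G, cp = cp, pops = pop_table, env = env,
       truth = list(true_q = true_q, frequencies = fr$freq,
                    ancestral = fr$ancestral, categories = categories,
                    cluster_species = species,
                    region_cluster = region_cluster,
                    missing_mask = attr(G, "missing_mask")))
}

#' Simulate an admixture parameter-recovery dataset
#'
#' A minimal world used to benchmark the Gibbs sampler: K clusters with
#' F-model frequencies and no missing data. By default individuals follow
#' the hybrid-zone composition observed in white-oak surveys -- mostly pure
#' trees with admixed and highly admixed minorities (proportions 510 : 126 :
#' 39, i.e. 75.6% / 18.7% / 5.8%) -- with q at the category midpoints
#' (0.9375 / 0.75 / 0.5 membership to a uniformly chosen home cluster).
#' `q_mode = "dirichlet"` instead draws q ~ Dirichlet(alpha), a much harder
#' world in which most individuals are strongly admixed and the posterior
#' itself is wide.
#'
#' @param K,n,L,A clusters, individuals, loci, alleles per locus.
#' @param F_drift drift parameter of the F-model.
#' @param q_mode `"categories"` (default) or `"dirichlet"`.
#' @param alpha Dirichlet concentration for `q_mode = "dirichlet"`.
#' @param category_probs pure / admixed / highly-admixed proportions.
#' @param seed RNG seed.
#' @return list(genotypes, true_q, freq).
#' @export
simulate_recovery_dataset <- function(K = 2L, n = 200L, L = 16L, A = 8L,
                                      F_drift = 0.2,
                                      q_mode = c("categories", "dirichlet"),
                                      alpha = 1,
                                      category_probs = c(pure = 510, admixed = 126,
                                                         highly_admixed = 39) / 675,
                                      seed = 1L) {
  q_mode <- match.arg(q_mode)
  cfg <- sim_config(n_clusters = K,
                    cluster_species = paste0("sp", seq_len(K)),
                    n_loci_nuclear = L, alleles_per_locus = A,
                    drift_F = F_drift, seed = seed)
  fr <- simulate_allele_frequencies(cfg, seed = derive_seed(seed, "rec_freq"))
  set.seed(derive_seed(seed, "rec_q"))
  if (q_mode == "dirichlet") {
    true_q <- rdirichlet(n, rep(alpha, K))
  } else {
    home_q <- c(pure = 0.9375, admixed = 0.75, highly_admixed = 0.5)
    cat_i <- sample(names(category_probs), n, replace = TRUE,
                    prob = category_probs)
    home <- sample.int(K, n, replace = TRUE)
    true_q <- t(vapply(seq_len(n), function(i) {
      q <- rep((1 - home_q[[cat_i[i]]]) / max(K - 1, 1), K)
      q[home[i]] <- home_q[[cat_i[i]]]
      if (K == 1L) q <- 1
      q
    }, numeric(K)))
  }
  G <- simulate_admixed_genotypes(fr$freq, true_q,
                                  pop_ids = rep("pop1", n),
                                  seed = derive_seed(seed, "rec_geno"))
  list(genotypes = G, true_q = true_q, freq = fr$freq)
}
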