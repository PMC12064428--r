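# Species assignment from cluster memberships: summing within-species
# cluster q-values, thresholding into pure / admixed / highly admixed, and
# the population-level introgression index.

#' Sum cluster memberships within species
#'
#' When a species is represented by more than one intraspecific cluster, the
#' membership proportions of those clusters are added before classification.
#'
#' @param Q individuals x K membership matrix.
#' @param cluster_species_map character vector of length K giving the
#'   species of each cluster.
#' @return individuals x species matrix of summed q-values (rows sum to 1).
#' @export
species_q_sums <- function(Q, cluster_species_map) {
  Q <- as.matrix(Q)
  if (length(cluster_species_map) != ncol(Q))
    stop("cluster_species_map must name a species for every cluster")
  species <- unique(cluster_species_map)
  out <- vapply(species, function(sp)
    rowSums(Q[, cluster_species_map == sp, drop = FALSE]), numeric(nrow(Q)))
  out <- matrix(out, nrow = nrow(Q), dimnames = list(rownames(Q), species))
  out
}

#' Classify individuals from species-level q-values
#'
#' An individual is `pure:<species>` if its largest species q-value exceeds
#' `t_pure` (strictly), `admixed` if it lies in (`t_adm`, `t_pure`] and
#' `highly_admixed` at or below `t_adm`. The closed lower edge is assigned
#' to `highly_admixed`; this single-point convention is documented because
#' verbal interval descriptions leave q = `t_adm` ambiguous.
#'
#' @param species_q individuals x species matrix (from [species_q_sums()]).
#' @param t_pure,t_adm thresholds with 0.5 < t_adm < t_pure < 1 (defaults
#'   0.875 and 0.625, the values proposed by simulation studies in oaks:
#'   pure trees, backcrosses and F1 hybrids expected at q = 1, 0.75, 0.5).
#' @return data.frame: individual_id, category, max_q, species (the argmax
#'   species; for non-pure individuals the most-represented one).
#' @export
classify <- function(species_q, t_pure = 0.875, t_adm = 0.625) {
  if (!(0.5 < t_adm && t_adm < t_pure && t_pure < 1))
    stop("thresholds must satisfy 0.5 < t_adm < t_pure < 1")
  species_q <- as.matrix(species_q)
  max_q <- apply(species_q, 1, max)
  argmax <- colnames(species_q)[max.col(species_q, ties.method = "first")]
  category <- ifelse(max_q > t_pure, paste0("pure:", argmax),
                     ifelse(max_q > t_adm, "admixed", "highly_admixed"))
  data.frame(individual_id = rownames(species_q) %||%
               sprintf("ind_%05d", seq_len(nrow(species_q))),
             category = category, max_q = max_q, species = argmax,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Population introgression index
#'
#' `I = (n_highly_admixed + 0.5 * n_admixed) / n` where `n` counts the
#' classified individuals of the population after exclusions.
#'
#' @param categories character vector of categories (`pure:*`, `admixed`,
#'   `highly_admixed`) for the individuals entering the index.
#' @param n optional denominator; defaults to `length(categories)`.
#' @return index in [0, 1].
#' @export
introgression_index <- function(categories, n = length(categories)) {
  if (n == 0) stop("introgression index undefined for n = 0")
  n_had <- sum(categories == "highly_admixed")
  n_ad <- sum(categories == "admixed")
  (n_had + 0.5 * n_ad) / n
}

#' Per-population classification summary and introgression index
#'
#' Individuals classified as pure members of a non-focal species are
#' excluded before computing the denominator and the index (they are not
#' part of the focal species' gene pool).
#'
#' @param assignments data.frame from [classify()] plus a `pop_id` column.
#' @param focal_species species whose introgression is quantified.
#' @return data.frame per population: n (after exclusion), n_pure (pure
#'   focal), n_ad, n_had, n_excluded, introgression_index.
#' @export
population_summary <- function(assignments, focal_species) {
  if (!"pop_id" %in% names(assignments))
    stop("assignments needs a pop_id column")
  pops <- unique(assignments$pop_id)
  rows <- lapply(pops, function(p) {
    a <- assignments[assignments$pop_id == p, ]
    pure_other <- grepl("^pure:", a$category) &
      a$category != paste0("pure:", focal_species)
    kept <- a[!pure_other, ]
    if (!nrow(kept))
      stop("population ", p, " is empty after excluding non-focal pure ",
           "individuals")
    data.frame(pop_id = p, n = nrow(kept),
               n_pure = sum(kept$category == paste0("pure:", focal_species)),
               n_ad = sum(kept$category == "admixed"),
               n_had = sum(kept$category == "highly_admixed"),
               n_excluded = sum(pure_other),
               introgression_index = introgression_index(kept$category),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
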