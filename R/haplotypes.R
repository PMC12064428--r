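# Chloroplast haplotype analysis: haplotype calling from haploid cpSSR
# profiles, minimum spanning networks under the stepwise mutation distance,
# Pons-Petit haplotype diversity / differentiation, and the east-vs-west
# rank test.

#' Call multilocus chloroplast haplotypes
#'
#' Individuals with identical allele vectors across all cpSSR loci share a
#' haplotype label (H01, H02, ... in order of decreasing frequency).
#' Individuals missing any cp locus are excluded and counted.
#'
#' @param cp data.frame with `individual_id`, `pop_id` and one integer
#'   column per cp locus (additional non-locus columns such as `lineage`
#'   are carried through); missing calls as NA or the sentinel.
#' @param loci names of the locus columns; defaults to columns matching
#'   `^cp`.
#' @param missing missing sentinel (default -9).
#' @return list with `table` (data.frame individual_id, pop_id, haplotype
#'   label, haplotype string), `haplotypes` (label -> allele matrix row),
#'   `n_excluded`.
#' @export
call_haplotypes <- function(cp, loci = grep("^cp", names(cp), value = TRUE),
                            missing = MISSING_CODE) {
  if (!length(loci)) stop("no cp locus columns found")
  H <- as.matrix(cp[, loci, drop = FALSE])
  storage.mode(H) <- "integer"
  bad <- apply(H, 1, function(r) anyNA(r) || any(r == missing))
  n_excl <- sum(bad)
  if (n_excl) message(n_excl, " individual(s) excluded for missing cp loci")
  H <- H[!bad, , drop = FALSE]
  keep <- cp[!bad, , drop = FALSE]
  key <- apply(H, 1, paste, collapse = "-")
  freq <- sort(table(key), decreasing = TRUE)
  labels <- setNames(sprintf("H%02d", seq_along(freq)), names(freq))
  hap_mat <- do.call(rbind, lapply(names(freq), function(k)
    as.integer(strsplit(k, "-")[[1]])))
  rownames(hap_mat) <- labels
  colnames(hap_mat) <- loci
  tab <- data.frame(individual_id = keep$individual_id,
                    pop_id = keep$pop_id,
                    haplotype = unname(labels[key]),
                    haplotype_string = key, stringsAsFactors = FALSE)
  if ("lineage" %in% names(keep)) tab$lineage <- keep$lineage
  list(table = tab, haplotypes = hap_mat, n_excluded = n_excl)
}

#' Stepwise distance between haplotypes
#'
#' Sum over loci of the absolute repeat-count difference: allele-size
#' difference divided by the per-locus motif length (default 1, i.e.
#' mononucleotide motifs; raw bp differences are used where a motif is
#' unknown).
#'
#' @param hap_mat haplotype x locus allele-size matrix.
#' @param motif_lengths per-locus motif lengths (recycled; default 1).
#' @return symmetric integer-valued distance matrix.
#' @export
stepwise_distance <- function(hap_mat, motif_lengths = 1) {
  motif_lengths <- rep_len(motif_lengths, ncol(hap_mat))
  steps <- sweep(hap_mat, 2, motif_lengths, "/")
  as.matrix(dist(steps, method = "manhattan"))
}

#' Minimum spanning network of haplotypes
#'
#' Kruskal's minimum spanning tree on the stepwise distance, retaining all
#' co-minimal tie edges: whenever an edge joins two components, every other
#' edge of the same weight joining those components is kept too (network,
#' not tree). Node weight is haplotype frequency.
#'
#' @param called result of [call_haplotypes()], or a haplotype x locus
#'   matrix.
#' @param motif_lengths per-locus motif lengths for [stepwise_distance()].
#' @return list: `edges` (data.frame from, to, weight), `nodes` (data.frame
#'   haplotype, frequency), `mst_weight` (total weight of a spanning tree).
#' @export
msn <- function(called, motif_lengths = 1) {
  if (is.list(called) && !is.data.frame(called)) {
    hap_mat <- called$haplotypes
    freq <- table(called$table$haplotype)[rownames(hap_mat)]
  } else {
    hap_mat <- as.matrix(called)
    freq <- setNames(rep(1L, nrow(hap_mat)),
                     rownames(hap_mat) %||% paste0("H", seq_len(nrow(hap_mat))))
    rownames(hap_mat) <- names(freq)
  }
  n <- nrow(hap_mat)
  nodes <- data.frame(haplotype = rownames(hap_mat),
                      frequency = as.integer(freq), stringsAsFactors = FALSE)
  if (n == 1L)
    return(list(edges = data.frame(from = character(0), to = character(0),
                                   weight = numeric(0)),
                nodes = nodes, mst_weight = 0))
  D <- stepwise_distance(hap_mat, motif_lengths)
  cand <- which(upper.tri(D), arr.ind = TRUE)
  ord <- order(D[cand], cand[, 1], cand[, 2])
  cand <- cand[ord, , drop = FALSE]
  w <- D[cand]
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  edges <- list(); mst_w <- 0
  pos <- 1L
  while (pos <= nrow(cand)) {
    # process one weight class at a time so co-minimal ties are kept
    same <- which(w == w[pos] & seq_along(w) >= pos)
    block <- cand[same, , drop = FALSE]
    # record component pairs joined within this class before merging
    comp_pairs <- t(apply(block, 1, function(e)
      sort(c(find(e[1]), find(e[2])))))
    joinable <- comp_pairs[, 1] != comp_pairs[, 2]
    if (any(joinable)) {
      # union the components; count one spanning edge per actual merge
      for (r in which(joinable)) {
        e <- block[r, ]
        ra <- find(e[1]); rb <- find(e[2])
        edges[[length(edges) + 1L]] <-
          data.frame(from = rownames(hap_mat)[e[1]],
                     to = rownames(hap_mat)[e[2]],
                     weight = w[pos], stringsAsFactors = FALSE)
        if (ra != rb) { parent[rb] <- ra; mst_w <- mst_w + w[pos] }
      }
    }
    pos <- max(same) + 1L
  }
  list(edges = do.call(rbind, edges) %||%
         data.frame(from = character(0), to = character(0),
                    weight = numeric(0)),
       nodes = nodes, mst_weight = mst_w)
}

#' Pons-Petit haplotype diversity and differentiation
#'
#' Within-population unbiased haplotype diversity
#' `h_k = n_k/(n_k - 1) (1 - sum p_i^2)`, averaged to hS; total diversity hT
#' with the small-sample correction based on the harmonic mean sample size;
#' `GST = (hT - hS)/hT`. Standard errors by leave-one-population-out
#' jackknife. Populations with fewer than 2 typed individuals are excluded
#' with a warning.
#'
#' @param hap_table data.frame with `pop_id` and `haplotype` columns (from
#'   [call_haplotypes()]`$table`).
#' @return list: hS, hT, GST, hS_se, GST_se, per_population (data.frame
#'   pop_id, n, h).
#' @export
pons_petit <- function(hap_table) {
  tab <- table(hap_table$pop_id, hap_table$haplotype)
  n_k <- rowSums(tab)
  small <- n_k < 2
  if (any(small)) {
    warning("excluding population(s) with n < 2: ",
            paste(rownames(tab)[small], collapse = ", "), call. = FALSE)
    tab <- tab[!small, , drop = FALSE]
    n_k <- n_k[!small]
  }
  core <- function(tab, n_k) {
    K <- nrow(tab)
    P <- tab / n_k
    h_k <- n_k / (n_k - 1) * (1 - rowSums(P^2))
    hS <- mean(h_k)
    nh <- K / sum(1 / n_k)
    pbar <- colMeans(P)
    # haploid total diversity with the small-sample correction term
    hT <- 1 - sum(pbar^2) + hS / (nh * K)
    # guard: a single shared fixed haplotype gives hT = hS = 0
    GST <- if (hT > 0) (hT - hS) / hT else NA_real_
    c(hS = hS, hT = hT, GST = GST)
  }
  est <- core(tab, n_k)
  K <- nrow(tab)
  if (K > 2) {
    jk <- t(vapply(seq_len(K), function(k)
      core(tab[-k, , drop = FALSE], n_k[-k]), numeric(3)))
    jse <- function(col) sqrt((K - 1) / K * sum((col - mean(col))^2))
    hS_se <- jse(jk[, "hS"]); GST_se <- jse(jk[, "GST"])
  } else {
    hS_se <- NA_real_; GST_se <- NA_real_
  }
  P <- tab / n_k
  list(hS = unname(est["hS"]), hT = unname(est["hT"]),
       GST = unname(est["GST"]), hS_se = hS_se, GST_se = GST_se,
       per_population = data.frame(pop_id = rownames(tab), n = as.integer(n_k),
                                   h = n_k / (n_k - 1) * (1 - rowSums(P^2)),
                                   stringsAsFactors = FALSE, row.names = NULL))
}

#' Compare haplotype diversity between two groups of populations
#'
#' Two-sided Mann-Whitney U test on per-population diversities: exact for
#' small samples without ties, normal approximation with tie correction
#' otherwise.
#'
#' @param h_east,h_west numeric vectors of per-population diversities.
#' @return list: U (statistic for the first group), p_value, exact.
#' @export
compare_groups <- function(h_east, h_west) {
  wt <- suppressWarnings(wilcox.test(h_east, h_west, exact = NULL,
                                     correct = TRUE))
  ties <- any(duplicated(c(h_east, h_west)))
  exact <- length(h_east) < 50 && length(h_west) < 50 && !ties
  list(U = unname(wt$statistic), p_value = wt$p.value, exact = exact)
}
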