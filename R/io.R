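# Genotype container and file IO: STRUCTURE-format genotypes (one-row and
# two-row dialects), CSV/TSV population / environment / haplotype tables and
# q-matrix TSV files.

#' Construct a diploid genotype matrix
#'
#' The central genotype container: allele calls are integer fragment sizes in
#' base pairs (bp), stored as an individuals x loci x 2 array with a sentinel
#' value ([MISSING_CODE]) for missing calls. The two gene copies at a locus
#' are unordered.
#'
#' @param calls integer array `n x L x 2` of allele sizes (bp) or the missing
#'   sentinel.
#' @param individual_ids character vector of length `n`.
#' @param pop_ids character vector of length `n` with population labels.
#' @param loci character vector of length `L` with locus names.
#' @param missing missing-data sentinel (default -9).
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, individual_ids, pop_ids, loci,
                            missing = MISSING_CODE) {
  if (length(dim(calls)) != 3L || dim(calls)[3] != 2L)
    stop("`calls` must be an n x L x 2 array")
  n <- dim(calls)[1]; L <- dim(calls)[2]
  if (length(individual_ids) != n) stop("individual_ids length mismatch")
  if (length(pop_ids) != n) stop("pop_ids length mismatch")
  if (length(loci) != L) stop("loci length mismatch")
  storage.mode(calls) <- "integer"
  bad <- calls != missing & calls <= 0L & !is.na(calls)
  if (any(bad)) stop("allele sizes must be positive or the missing sentinel")
  structure(list(calls = calls,
                 individual_ids = as.character(individual_ids),
                 pop_ids = as.character(pop_ids),
                 loci = as.character(loci),
                 missing = as.integer(missing)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals, %d loci, %d populations\n",
              length(x$individual_ids), length(x$loci),
              length(unique(x$pop_ids))))
  miss <- mean(x$calls == x$missing)
  cat(sprintf("  missing calls: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' Number of individuals / loci of a genotype matrix
#' @param G a [genotype_matrix()].
#' @return integer count.
#' @export
n_individuals <- function(G) length(G$individual_ids)

#' @rdname n_individuals
#' @export
n_loci <- function(G) length(G$loci)

#' Subset a genotype matrix by individuals
#' @param G a [genotype_matrix()].
#' @param idx logical or integer index over individuals.
#' @return a [genotype_matrix()].
#' @export
subset_individuals <- function(G, idx) {
  genotype_matrix(G$calls[idx, , , drop = FALSE], G$individual_ids[idx],
                  G$pop_ids[idx], G$loci, G$missing)
}

#' Read a STRUCTURE-format genotype file
#'
#' Supports the one-row dialect (one line per individual, two columns per
#' locus) and the two-row dialect (two lines per individual, one column per
#' locus). An optional first line of locus names is auto-detected (a line
#' with two fewer fields than the data lines, or non-numeric fields beyond
#' the two label columns).
#'
#' @param path file path.
#' @param dialect `"one-row"` or `"two-row"`.
#' @param missing missing sentinel (default -9).
#' @return a [genotype_matrix()].
#' @export
read_structure <- function(path, dialect = c("one-row", "two-row"),
                           missing = MISSING_CODE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty genotype file: ", path)
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  loci <- NULL
  # header detection: first row shorter than the rest, or all-alpha fields
  if (length(unique(nf)) > 1L && nf[1] < max(nf[-1])) {
    loci <- fields[[1]]
    fields <- fields[-1]; nf <- nf[-1]
  } else if (suppressWarnings(all(is.na(as.numeric(fields[[1]]))))) {
    loci <- fields[[1]]
    fields <- fields[-1]; nf <- nf[-1]
  }
  if (length(unique(nf)) != 1L)
    stop(sprintf("ragged rows in %s: line %d has %d fields, expected %d",
                 path, which(nf != nf[1])[1] + !is.null(loci), nf[nf != nf[1]][1],
                 nf[1]))
  mat <- do.call(rbind, fields)
  ids <- mat[, 1]; pops <- mat[, 2]
  geno <- suppressWarnings(matrix(as.integer(mat[, -(1:2), drop = FALSE]),
                                  nrow = nrow(mat)))
  if (anyNA(geno)) stop("non-integer allele call in ", path)
  if (dialect == "one-row") {
    if (ncol(geno) %% 2L != 0L)
      stop("one-row dialect requires an even number of genotype columns")
    L <- ncol(geno) %/% 2L
    n <- nrow(geno)
    calls <- array(NA_integer_, c(n, L, 2L))
    calls[, , 1] <- geno[, seq(1L, 2L * L, by = 2L)]
    calls[, , 2] <- geno[, seq(2L, 2L * L, by = 2L)]
  } else {
    if (nrow(geno) %% 2L != 0L)
      stop("two-row dialect requires an even number of data rows")
    n <- nrow(geno) %/% 2L
    L <- ncol(geno)
    r1 <- seq(1L, 2L * n, by = 2L)
    if (!all(ids[r1] == ids[r1 + 1L]))
      stop("two-row dialect: consecutive rows must share the individual id")
    calls <- array(NA_integer_, c(n, L, 2L))
    calls[, , 1] <- geno[r1, , drop = FALSE]
    calls[, , 2] <- geno[r1 + 1L, , drop = FALSE]
    ids <- ids[r1]; pops <- pops[r1]
  }
  if (is.null(loci)) loci <- sprintf("L%02d", seq_len(L))
  if (length(loci) != L) loci <- sprintf("L%02d", seq_len(L))
  genotype_matrix(calls, ids, pops, loci, missing)
}

#' Write a STRUCTURE-format genotype file
#'
#' Inverse of [read_structure()]; round-trips bit-exactly including missing
#' sentinels. A locus-name header line is written when `header = TRUE`.
#'
#' @param G a [genotype_matrix()].
#' @param path output path.
#' @param dialect `"one-row"` or `"two-row"`.
#' @param header write the locus-name line (default TRUE).
#' @return `path`, invisibly.
#' @export
write_structure <- function(G, path, dialect = c("one-row", "two-row"),
                            header = TRUE) {
  dialect <- match.arg(dialect)
  n <- n_individuals(G); L <- n_loci(G)
  con <- file(path, "w"); on.exit(close(con))
  if (header) writeLines(paste(G$loci, collapse = " "), con)
  if (dialect == "one-row") {
    geno <- matrix(NA_integer_, n, 2L * L)
    geno[, seq(1L, 2L * L, by = 2L)] <- G$calls[, , 1]
    geno[, seq(2L, 2L * L, by = 2L)] <- G$calls[, , 2]
    writeLines(paste(G$individual_ids, G$pop_ids,
                     apply(geno, 1, paste, collapse = " ")), con)
  } else {
    for (i in seq_len(n)) {
      writeLines(paste(G$individual_ids[i], G$pop_ids[i],
                       paste(G$calls[i, , 1], collapse = " ")), con)
      writeLines(paste(G$individual_ids[i], G$pop_ids[i],
                       paste(G$calls[i, , 2], collapse = " ")), con)
    }
  }
  invisible(path)
}

read_delim_sniff <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
             check.names = FALSE)
}

#' Read a population table
#'
#' Expects columns `pop_id`, `lat`, `lon` (or `x`, `y`), `n` and optionally
#' `region`. Delimiter (comma or tab) is auto-detected.
#'
#' @param path CSV/TSV path.
#' @return data.frame with class `population_table`.
#' @export
read_population_table <- function(path) {
  df <- read_delim_sniff(path)
  names(df)[names(df) == "longitude"] <- "lon"
  names(df)[names(df) == "latitude"] <- "lat"
  if (!"pop_id" %in% names(df)) stop("population table needs a pop_id column")
  if (anyDuplicated(df$pop_id)) stop("duplicate pop_id in population table")
  has_geo <- all(c("lat", "lon") %in% names(df))
  has_xy <- all(c("x", "y") %in% names(df))
  if (!has_geo && !has_xy)
    stop("population table needs lat/lon or x/y columns")
  cc <- if (has_geo) c("lat", "lon") else c("x", "y")
  if (!all(is.finite(as.matrix(df[cc])))) stop("non-finite coordinates")
  df$pop_id <- as.character(df$pop_id)
  class(df) <- c("population_table", "data.frame")
  df
}

#' Read an environment table
#'
#' One row per population: `pop_id`, covariate columns and (optionally) the
#' `introgression_index` response.
#'
#' @param path CSV/TSV path.
#' @param genotypes optional [genotype_matrix()]; population ids are
#'   cross-checked and unknown ids raise an error naming the offenders.
#' @return data.frame.
#' @export
read_env_table <- function(path, genotypes = NULL) {
  df <- read_delim_sniff(path)
  if (!"pop_id" %in% names(df)) stop("environment table needs a pop_id column")
  df$pop_id <- as.character(df$pop_id)
  if (!is.null(genotypes)) {
    unknown <- setdiff(df$pop_id, unique(genotypes$pop_ids))
    if (length(unknown))
      stop("environment table has pop_ids absent from the genotypes: ",
           paste(unknown, collapse = ", "))
  }
  df
}

#' Read a haplotype table
#'
#' Columns: `individual_id`, `pop_id`, one column per cpSSR locus (allele
#' sizes in bp) and optionally `lineage`.
#'
#' @param path CSV/TSV path.
#' @return data.frame.
#' @export
read_haplotype_table <- function(path) {
  df <- read_delim_sniff(path)
  need <- c("individual_id", "pop_id")
  if (!all(need %in% names(df)))
    stop("haplotype table needs individual_id and pop_id columns")
  df$individual_id <- as.character(df$individual_id)
  df$pop_id <- as.character(df$pop_id)
  df
}

#' Write / read a q-matrix TSV
#'
#' Layout: `individual_id`, `pop_id`, `q_1` .. `q_K`.
#'
#' @param Q numeric matrix individuals x K of membership proportions.
#' @param individual_ids,pop_ids row labels.
#' @param path file path.
#' @return `write_qmatrix` returns `path`; `read_qmatrix` returns a list
#'   with elements `Q`, `individual_ids`, `pop_ids`.
#' @export
write_qmatrix <- function(Q, individual_ids, pop_ids, path) {
  df <- data.frame(individual_id = individual_ids, pop_id = pop_ids,
                   Q, check.names = FALSE)
  names(df)[-(1:2)] <- paste0("q_", seq_len(ncol(Q)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_qmatrix
#' @export
read_qmatrix <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  qc <- grep("^q_", names(df))
  list(Q = as.matrix(df[, qc, drop = FALSE]),
       individual_ids = as.character(df$individual_id),
       pop_ids = as.character(df$pop_id))
}

#' Project geographic coordinates to a local planar system
#'
#' Local equirectangular projection about the mean latitude: adequate for the
#' Delaunay geometry of a regional study extent (distance error well below 1%
#' for spans of a few hundred km). Input in decimal degrees, output in km.
#'
#' @param lat,lon numeric vectors in decimal degrees.
#' @return a two-column matrix (x, y) in kilometres.
#' @export
project_equirectangular <- function(lat, lon) {
  R <- 6371.0088
  lat0 <- mean(lat) * pi / 180
  cbind(x = R * (lon * pi / 180) * cos(lat0),
        y = R * (lat * pi / 180))
}

#' Planar coordinates of a population table
#'
#' Uses x/y columns directly if present, otherwise projects lat/lon with
#' [project_equirectangular()].
#' @param pop_table a [read_population_table()] data.frame.
#' @return two-column matrix with rownames = pop_id.
#' @export
pop_coordinates <- function(pop_table) {
  if (all(c("x", "y") %in% names(pop_table))) {
    xy <- cbind(x = pop_table$x, y = pop_table$y)
  } else {
    xy <- project_equirectangular(pop_table$lat, pop_table$lon)
  }
  rownames(xy) <- pop_table$pop_id
  xy
}
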