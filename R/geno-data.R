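#' Genotype dataset container
#'
#' A `geno_data` object bundles the layers of a multi-sample SNP dataset:
#' the locus table, the sample metadata, hard-called allele dosages, and
#' (when available) Phred-scaled genotype likelihoods with per-entry depth
#' and genotype quality. All downstream stages of the package operate on
#' this container.
#'
#' @param loci data.frame with columns `chrom`, `pos` (1-based bp), `ref`,
#'   `alt`, sorted by (chrom, pos).
#' @param samples data.frame with columns `id`, `population`, `region`,
#'   `habitat` (one of `"marine"`/`"freshwater"`), `latitude`.
#' @param dosage integer matrix (samples x loci) of alt-allele counts in
#'   \{0, 1, 2\}; `NA` marks missing genotypes.
#' @param pl optional integer array (samples x loci x 3) of Phred-scaled,
#'   min-normalised genotype likelihoods (smallest value 0). `NA` slices mark
#'   entries with no likelihood information.
#' @param depth,gq optional matrices (samples x loci) of read depth and
#'   genotype quality (second-smallest PL).
#'
#' @return An object of class `geno_data`.
#' @export
geno_data <- function(loci, samples, dosage, pl = NULL, depth = NULL, gq = NULL) {
  stopifnot(is.data.frame(loci), is.data.frame(samples))
  need_loci <- c("chrom", "pos", "ref", "alt")
  if (!all(need_loci %in% names(loci)))
    stop("loci table must have columns: ", paste(need_loci, collapse = ", "))
  need_meta <- c("id", "population", "region", "habitat", "latitude")
  if (!all(need_meta %in% names(samples)))
    stop("sample table must have columns: ", paste(need_meta, collapse = ", "))
  if (!all(samples$habitat %in% c("marine", "freshwater")))
    stop("habitat must be 'marine' or 'freshwater'")
  ord <- order(loci$chrom, loci$pos)
  if (!identical(ord, seq_len(nrow(loci))))
    stop("loci must be sorted by (chrom, pos)")
  dosage <- as.matrix(dosage)
  if (nrow(dosage) != nrow(samples) || ncol(dosage) != nrow(loci))
    stop("dosage must be samples x loci")
  lid <- locus_ids(loci)
  if (anyDuplicated(lid)) stop("duplicate loci (chrom:pos)")
  dimnames(dosage) <- list(samples$id, lid)
  if (!is.null(pl)) {
    if (!all(dim(pl)[1:2] == dim(dosage)) || dim(pl)[3] != 3)
      stop("pl must be samples x loci x 3")
    dimnames(pl) <- list(samples$id, lid, c("RR", "RA", "AA"))
  }
  for (nm in c("depth", "gq")) {
    m <- get(nm)
    if (!is.null(m)) {
      m <- as.matrix(m)
      if (!all(dim(m) == dim(dosage))) stop(nm, " must be samples x loci")
      dimnames(m) <- dimnames(dosage)
      assign(nm, m)
    }
  }
  rownames(loci) <- NULL
  rownames(samples) <- NULL
  structure(list(loci = loci, samples = samples, dosage = dosage,
                 pl = pl, depth = depth, gq = gq),
            class = "geno_data")
}

#' Locus identifiers
#'
#' Canonical `chrom:pos` ids for a locus table (or a `geno_data`).
#'
#' @param loci a locus data.frame with `chrom` and `pos`, or a `geno_data`.
#' @return Character vector of ids.
#' @export
locus_ids <- function(loci) {
  if (inherits(loci, "geno_data")) loci <- loci$loci
  paste(loci$chrom, loci$pos, sep = ":")
}

#' @export
print.geno_data <- function(x, ...) {
  cat("geno_data:", nrow(x$samples), "samples x", nrow(x$loci), "loci\n")
  cat("  populations:", length(unique(x$samples$population)),
      " regions:", length(unique(x$samples$region)), "\n")
  cat("  habitats:", paste(names(table(x$samples$habitat)),
                           table(x$samples$habitat), collapse = ", "), "\n")
  cat("  layers:", paste(c("dosage",
                           if (!is.null(x$pl)) "PL",
                           if (!is.null(x$depth)) "DP",
                           if (!is.null(x$gq)) "GQ"), collapse = ", "), "\n")
  miss <- mean(is.na(x$dosage))
  cat(sprintf("  missing genotypes: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' Subset a genotype dataset
#'
#' `x[i, j]` keeps samples `i` and loci `j` (indices, logical masks, sample
#' ids or `chrom:pos` locus ids). Locus order is preserved.
#'
#' @param x a `geno_data`.
#' @param i,j sample and locus selectors.
#' @param ... ignored.
#' @return A `geno_data`.
#' @export
`[.geno_data` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$samples))
  if (missing(j)) j <- seq_len(nrow(x$loci))
  if (is.character(i)) i <- match(i, x$samples$id)
  if (is.character(j)) j <- match(j, locus_ids(x$loci))
  i <- seq_len(nrow(x$samples))[i]
  j <- seq_len(nrow(x$loci))[j]
  if (anyNA(i)) stop("unknown sample selector")
  if (anyNA(j)) stop("unknown locus selector")
  j <- sort(j)  # keep genomic order
  geno_data(x$loci[j, , drop = FALSE], x$samples[i, , drop = FALSE],
            x$dosage[i, j, drop = FALSE],
            pl = if (!is.null(x$pl)) x$pl[i, j, , drop = FALSE],
            depth = if (!is.null(x$depth)) x$depth[i, j, drop = FALSE],
            gq = if (!is.null(x$gq)) x$gq[i, j, drop = FALSE])
}

#' Linear-scale genotype likelihoods
#'
#' Converts the stored Phred-scaled PL layer to linear-scale likelihoods
#' normalised to sum to one per entry. Entries without likelihood
#' information are `NA`.
#'
#' @param ds a `geno_data` with a PL layer.
#' @return samples x loci x 3 numeric array.
#' @export
gl_linear <- function(ds) {
  if (is.null(ds$pl)) stop("dataset has no genotype-likelihood (PL) layer")
  gl <- 10^(-ds$pl / 10)
  tot <- gl[, , 1] + gl[, , 2] + gl[, , 3]
  gl / as.vector(rep(tot, 3))  # broadcast over third margin
}

# indices of samples belonging to given population labels
pop_index <- function(ds, populations) {
  idx <- which(ds$samples$population %in% populations)
  if (length(idx) == 0L)
    stop("no samples from population(s): ", paste(populations, collapse = ", "))
  idx
}
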