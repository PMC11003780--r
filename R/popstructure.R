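#' Per-locus alternate-allele frequencies
#'
#' Dosage source: mean dosage / 2 over non-missing samples. GL source:
#' frequencies of expected dosages under per-sample posteriors with a
#' uniform genotype prior updated once by the sample-wide frequency (a
#' single EM sweep), which converges to the dosage estimate at high depth.
#'
#' @param ds a `geno_data`.
#' @param scope `"global"` or a population label (or vector of labels).
#' @param source `"dosage"` or `"gl"`.
#' @return Named numeric vector of frequencies; loci with no information in
#'   scope are `NA`.
#' @export
allele_frequencies <- function(ds, scope = "global",
                               source = c("dosage", "gl")) {
  source <- match.arg(source)
  idx <- if (identical(scope, "global")) seq_len(nrow(ds$samples))
  else pop_index(ds, scope)
  if (source == "dosage") {
    d <- ds$dosage[idx, , drop = FALSE]
    n <- colSums(!is.na(d))
    p <- ifelse(n > 0, colSums(d, na.rm = TRUE) / (2 * n), NA_real_)
    return(stats::setNames(p, locus_ids(ds$loci)))
  }
  eg <- expected_dosage(ds, idx)
  stats::setNames(colMeans(eg) / 2, locus_ids(ds$loci))
}

# expected dosages from GLs: one EM sweep (uniform prior -> HWE prior at the
# sweep-estimated frequency). Missing entries get the prior mean 2*p.
expected_dosage <- function(ds, idx = seq_len(nrow(ds$samples))) {
  if (is.null(ds$pl)) stop("dataset has no genotype-likelihood layer")
  gl <- gl_linear(ds)[idx, , , drop = FALSE]
  e0 <- gl[, , 2] + 2 * gl[, , 3]           # uniform-prior posterior mean
  p1 <- colMeans(e0, na.rm = TRUE) / 2
  p1 <- pmin(pmax(p1, 1e-9), 1 - 1e-9)
  n <- dim(gl)[1]
  w0 <- matrix((1 - p1)^2, n, length(p1), byrow = TRUE)
  w1 <- matrix(2 * p1 * (1 - p1), n, length(p1), byrow = TRUE)
  w2 <- matrix(p1^2, n, length(p1), byrow = TRUE)
  q0 <- gl[, , 1] * w0; q1 <- gl[, , 2] * w1; q2 <- gl[, , 3] * w2
  tot <- q0 + q1 + q2
  eg <- (q1 + 2 * q2) / tot
  na <- is.na(eg)
  if (any(na)) eg[na] <- (2 * p1)[col(eg)[na]]
  dimnames(eg) <- list(ds$samples$id[idx], locus_ids(ds$loci))
  eg
}

#' Weir-Cockerham F_ST between two populations
#'
#' The 1984 two-population theta, combined across loci as a ratio of sums:
#' `theta = sum(a) / sum(a + b + c)` with the standard among-population (a),
#' among-individual (b) and within-individual (c) variance components
#' computed from sample sizes, allele frequencies and observed
#' heterozygosity. Loci need at least `min_individuals` called diploids in
#' each population. Negative estimates are possible and returned as
#' computed.
#'
#' @param ds a `geno_data`.
#' @param popA,popB population labels.
#' @param min_individuals per-population minimum called diploids per locus.
#' @return List with `theta`, `n_loci` used, and the component sums.
#' @export
wc_fst <- function(ds, popA, popB, min_individuals = 2) {
  iA <- pop_index(ds, popA); iB <- pop_index(ds, popB)
  dA <- ds$dosage[iA, , drop = FALSE]; dB <- ds$dosage[iB, , drop = FALSE]
  nA <- colSums(!is.na(dA)); nB <- colSums(!is.na(dB))
  ok <- nA >= min_individuals & nB >= min_individuals
  comp <- wc_components(colSums(dA, na.rm = TRUE)[ok] / (2 * nA[ok]),
                        colSums(dB, na.rm = TRUE)[ok] / (2 * nB[ok]),
                        colMeans(dA == 1L, na.rm = TRUE)[ok],
                        colMeans(dB == 1L, na.rm = TRUE)[ok],
                        nA[ok], nB[ok])
  denom <- sum(comp$a + comp$b + comp$c)
  if (!is.finite(denom) || denom == 0)
    stop("no usable polymorphic loci shared by ", popA, " and ", popB)
  list(theta = sum(comp$a) / denom, n_loci = sum(ok),
       sum_a = sum(comp$a), sum_denom = denom)
}

# per-locus WC84 variance components for r = 2 populations (vectorised)
wc_components <- function(pA, pB, hA, hB, nA, nB) {
  r <- 2
  nbar <- (nA + nB) / r
  nc <- (r * nbar - (nA^2 + nB^2) / (r * nbar)) / (r - 1)
  pbar <- (nA * pA + nB * pB) / (r * nbar)
  s2 <- (nA * (pA - pbar)^2 + nB * (pB - pbar)^2) / ((r - 1) * nbar)
  hbar <- (nA * hA + nB * hB) / (r * nbar)
  a <- nbar / nc * (s2 - 1 / (nbar - 1) *
                      (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                              (2 * nbar - 1) / (4 * nbar) * hbar)
  c <- hbar / 2
  bad <- !is.finite(a) | !is.finite(b) | !is.finite(c)
  a[bad] <- 0; b[bad] <- 0; c[bad] <- 0
  list(a = a, b = b, c = c)
}

#' Pairwise F_ST matrix
#'
#' Populations with fewer than `min_individuals` samples are dropped (with a
#' log attached as attribute `"dropped"`); theta is computed for every
#' remaining pair.
#'
#' @param ds a `geno_data` (typically filtered and distance-thinned).
#' @param min_individuals minimum samples per population.
#' @return An `fst_matrix`: symmetric matrix of theta with zero diagonal;
#'   attribute `"n_loci"` holds the per-pair locus counts.
#' @export
fst_matrix <- function(ds, min_individuals = 2) {
  tab <- table(ds$samples$population)
  keep <- names(tab)[tab >= min_individuals]
  dropped <- setdiff(names(tab), keep)
  if (length(keep) < 2) stop("fewer than two populations remain")
  k <- length(keep)
  th <- matrix(0, k, k, dimnames = list(keep, keep))
  nl <- matrix(NA_integer_, k, k, dimnames = list(keep, keep))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    f <- wc_fst(ds, keep[i], keep[j], min_individuals = min_individuals)
    th[i, j] <- th[j, i] <- f$theta
    nl[i, j] <- nl[j, i] <- f$n_loci
  }
  structure(th, class = c("fst_matrix", "matrix"), n_loci = nl,
            dropped = dropped)
}

#' @export
print.fst_matrix <- function(x, digits = 4, ...) {
  cat("Weir-Cockerham pairwise F_ST (", nrow(x), " populations)\n", sep = "")
  print(round(unclass(x), digits))
  dr <- attr(x, "dropped")
  if (length(dr)) cat("dropped (too few samples):",
                      paste(dr, collapse = ", "), "\n")
  invisible(x)
}

#' Fit a PCA of genotypes
#'
#' Dosages (hard calls, `source = "dosage"`, missing entries imputed with
#' the per-population locus mean) or genotype-likelihood expected dosages
#' (`source = "gl"`) are centered at `2 p` and scaled by
#' `sqrt(2 p (1 - p))` with `p` estimated from the fitting samples
#' (Patterson scaling), then decomposed by SVD. The stored eigenvectors are
#' in locus space so new samples can be projected with the training
#' constants. Loci with more than `max_missing` missing data or minor
#' allele frequency below `maf_min` among the fitting samples are removed
#' before fitting.
#'
#' When both habitats occur among the fitting samples the sign of PC1 is
#' fixed so the freshwater centroid is positive; remaining PCs are oriented
#' by their largest-magnitude loading.
#'
#' @param ds a `geno_data`.
#' @param samples sample ids used to fit (default: all).
#' @param maf_min minimum minor allele frequency (`>=` retained).
#' @param source `"gl"` or `"dosage"`.
#' @param max_missing maximum tolerated per-locus missing fraction
#'   (strictly-above removed).
#' @return A `pca_model`: locus ids, `center`, `scale`, `rotation`
#'   (loci x k), `eigenvalues`, training `scores`, `method`, sample ids.
#' @export
pca_fit <- function(ds, samples = ds$samples$id, maf_min = 0.05,
                    source = c("gl", "dosage"), max_missing = 0.2) {
  source <- match.arg(source)
  idx <- match(samples, ds$samples$id)
  if (anyNA(idx)) stop("unknown sample id among fitting samples")
  if (length(idx) < 2) stop("need at least two samples")
  miss <- colMeans(is.na(ds$dosage[idx, , drop = FALSE]))
  X <- if (source == "gl") expected_dosage(ds, idx)
  else {
    d <- ds$dosage[idx, , drop = FALSE]
    # impute with per-population locus mean among the fitting samples
    pops <- ds$samples$population[idx]
    for (pp in unique(pops)) {
      rows <- which(pops == pp)
      sub <- d[rows, , drop = FALSE]
      cm <- colMeans(sub, na.rm = TRUE)
      na <- which(is.na(sub), arr.ind = TRUE)
      if (nrow(na)) sub[na] <- cm[na[, 2]]
      d[rows, ] <- sub
    }
    # loci missing in an entire population: fall back to overall mean
    cm_all <- colMeans(d, na.rm = TRUE)
    na <- which(is.na(d), arr.ind = TRUE)
    if (nrow(na)) d[na] <- cm_all[na[, 2]]
    d
  }
  p <- colMeans(X) / 2
  maf <- pmin(p, 1 - p)
  keep <- miss <= max_missing & !is.na(maf) & maf >= maf_min
  if (sum(keep) < 2) stop("fewer than two loci pass the PCA filters")
  X <- X[, keep, drop = FALSE]
  p <- p[keep]
  center <- 2 * p
  scale <- sqrt(2 * p * (1 - p))
  Z <- sweep(sweep(X, 2, center), 2, scale, "/")
  if (all(abs(Z) < 1e-12)) stop("no genotypic variance among fitting samples")
  sv <- svd(Z)
  k <- sum(sv$d > 1e-9 * sv$d[1])
  rot <- sv$v[, seq_len(k), drop = FALSE]
  scores <- Z %*% rot
  # deterministic orientation
  hab <- ds$samples$habitat[idx]
  for (cc in seq_len(k)) {
    flip <- FALSE
    if (cc == 1 && all(c("marine", "freshwater") %in% hab)) {
      flip <- mean(scores[hab == "freshwater", 1]) <
        mean(scores[hab == "marine", 1])
    } else {
      flip <- rot[which.max(abs(rot[, cc])), cc] < 0
    }
    if (flip) { rot[, cc] <- -rot[, cc]; scores[, cc] <- -scores[, cc] }
  }
  dimnames(scores) <- list(ds$samples$id[idx], paste0("PC", seq_len(k)))
  structure(list(loci = locus_ids(ds$loci)[keep], center = center,
                 scale = scale, rotation = rot,
                 eigenvalues = sv$d[seq_len(k)]^2 / sum(keep),
                 scores = scores, method = source,
                 samples = ds$samples$id[idx]),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat("PCA model (", x$method, "): ", length(x$samples), " samples x ",
      length(x$loci), " loci, ", ncol(x$rotation), " components\n", sep = "")
  ve <- x$eigenvalues / sum(x$eigenvalues)
  cat("  variance explained (PC1..):",
      paste(sprintf("%.1f%%", 100 * utils::head(ve, 4)), collapse = " "), "\n")
  invisible(x)
}

#' Project samples onto a fitted PCA space
#'
#' Query genotypes are centered and scaled with the model's training
#' constants (never query-derived). Missing entries are replaced by the
#' query sample's own population mean dosage at that locus; model loci
#' absent from the query dataset contribute zero (an error is raised when
#' more than half are absent).
#'
#' @param model a [pca_fit()] result.
#' @param ds a `geno_data` containing the query samples.
#' @param samples query sample ids (default: all in `ds`).
#' @param source `"dosage"` (hard calls) or `"gl"` (expected dosages).
#' @return scores matrix (samples x k).
#' @export
pca_project <- function(model, ds, samples = ds$samples$id,
                        source = c("dosage", "gl")) {
  source <- match.arg(source)
  idx <- match(samples, ds$samples$id)
  if (anyNA(idx)) stop("unknown sample id among query samples")
  pos <- match(model$loci, locus_ids(ds$loci))
  if (mean(is.na(pos)) > 0.5)
    stop("more than half of the model loci are absent from the dataset")
  present <- !is.na(pos)
  X <- if (source == "gl") expected_dosage(ds, idx)[, pos[present], drop = FALSE]
  else {
    d <- ds$dosage[idx, pos[present], drop = FALSE]
    pops <- ds$samples$population[idx]
    for (pp in unique(pops)) {
      rows <- which(pops == pp)
      sub <- d[rows, , drop = FALSE]
      cm <- colMeans(sub, na.rm = TRUE)
      na <- which(is.na(sub), arr.ind = TRUE)
      if (nrow(na)) sub[na] <- cm[na[, 2]]
      d[rows, ] <- sub
    }
    na <- which(is.na(d), arr.ind = TRUE)  # population entirely missing
    if (nrow(na)) d[na] <- model$center[present][na[, 2]]
    d
  }
  Z <- matrix(0, length(idx), length(model$loci))
  Z[, present] <- sweep(sweep(X, 2, model$center[present]), 2,
                        model$scale[present], "/")
  scores <- Z %*% model$rotation
  dimnames(scores) <- list(ds$samples$id[idx],
                           paste0("PC", seq_len(ncol(scores))))
  scores
}
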