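#' Training-set specification for ecotype classification
#'
#' Names the reference populations whose individuals train the per-cluster
#' classifier, by habitat class. The defaults mirror a Pacific training
#' design (marine and freshwater reference populations with near-fixed
#' ecotype haplotypes); any population labels present in the dataset can be
#' supplied.
#'
#' @param marine,freshwater character vectors of population labels.
#' @return A `training_spec` list.
#' @export
training_spec <- function(marine, freshwater) {
  stopifnot(length(marine) >= 1, length(freshwater) >= 1)
  structure(list(marine = marine, freshwater = freshwater),
            class = "training_spec")
}

training_index <- function(ds, training) {
  pops <- ds$samples$population
  miss <- setdiff(c(training$marine, training$freshwater), pops)
  if (length(miss))
    stop("training population(s) absent from dataset: ",
         paste(miss, collapse = ", "))
  idx <- which(pops %in% c(training$marine, training$freshwater))
  labels <- ifelse(pops[idx] %in% training$freshwater, "freshwater", "marine")
  list(idx = idx, labels = labels)
}

#' Score one LD cluster: PCA, QDA model selection, PFG
#'
#' Runs the per-cluster classification pipeline: build the cluster PCA
#' (`method = "gl"`: covariance of genotype-likelihood expected dosages over
#' all samples; `method = "projected"`: hard-call PCA fitted on the training
#' samples only, queries projected with the training constants), select the
#' QDA model over 1..4 components by LOO-CV, and emit the Probability of
#' Freshwater Genotype for every individual. Clusters whose best accuracy
#' does not exceed the gate are flagged `retained = FALSE` and downstream
#' indices exclude them.
#'
#' @param ds a `geno_data`.
#' @param cluster an [ld_cluster()] (or locus-id character vector).
#' @param training a [training_spec()].
#' @param method `"gl"` or `"projected"`.
#' @param k_max,accuracy_gate,priors_mode passed to [select_model()].
#' @param maf_min PCA minor-allele-frequency filter.
#' @return A `cluster_assignment`: cluster id, fitted `pca` and `qda`
#'   models, per-individual `pfg` (named vector over all samples),
#'   `retained` flag and candidate accuracies; `NULL` when no QDA model is
#'   feasible.
#' @export
score_cluster <- function(ds, cluster, training, method = c("gl", "projected"),
                          k_max = 4, accuracy_gate = 0.75,
                          priors_mode = c("proportions", "equal"),
                          maf_min = 0.05) {
  method <- match.arg(method)
  priors_mode <- match.arg(priors_mode)
  members <- if (inherits(cluster, "ld_cluster")) cluster$members else cluster
  cid <- if (inherits(cluster, "ld_cluster")) cluster$id else "cluster"
  tr <- training_index(ds, training)
  sub <- ds[, members]
  if (method == "gl") {
    pca <- pca_fit(sub, maf_min = maf_min, source = "gl")
    all_scores <- pca$scores
  } else {
    pca <- pca_fit(sub, samples = ds$samples$id[tr$idx], maf_min = maf_min,
                   source = "dosage")
    qidx <- setdiff(seq_len(nrow(ds$samples)), tr$idx)
    qscores <- if (length(qidx))
      pca_project(pca, sub, ds$samples$id[qidx], source = "dosage")
    else NULL
    all_scores <- matrix(NA_real_, nrow(ds$samples), ncol(pca$scores),
                         dimnames = list(ds$samples$id,
                                         colnames(pca$scores)))
    all_scores[rownames(pca$scores), ] <- pca$scores
    if (!is.null(qscores)) all_scores[rownames(qscores), ] <- qscores
  }
  train_scores <- all_scores[ds$samples$id[tr$idx], , drop = FALSE]
  qda <- select_model(train_scores, tr$labels, k_max = k_max,
                      accuracy_gate = accuracy_gate,
                      priors_mode = priors_mode)
  if (is.null(qda)) return(NULL)
  pfg <- qda_posterior(qda, all_scores[, seq_len(qda$k), drop = FALSE])
  names(pfg) <- rownames(all_scores)
  structure(list(cluster = cid, method = method, pca = pca, qda = qda,
                 pfg = pfg, retained = qda$retained,
                 accuracies = qda$accuracies,
                 loo_accuracy = qda$loo_accuracy),
            class = "cluster_assignment")
}

#' Parallelism Index per population
#'
#' For each retained cluster, the per-population PI is the mean PFG across
#' that population's individuals (the proportion of individuals carrying
#' the freshwater-adapted haplotype); the overall PI of a population is the
#' unweighted mean across retained clusters.
#'
#' @param assignments list of [score_cluster()] results.
#' @param ds the `geno_data` the assignments refer to.
#' @param include_training whether training populations appear in the table
#'   (default `TRUE`; they anchor the 0 and 1 ends).
#' @return A `parallelism_table`: data.frame with `population`, `region`,
#'   `habitat`, `pi`, `n_clusters`; attribute `"per_cluster"` holds the
#'   population x cluster PI matrix.
#' @export
parallelism_index <- function(assignments, ds, include_training = TRUE) {
  assignments <- Filter(function(a) !is.null(a) && isTRUE(a$retained),
                        assignments)
  if (length(assignments) == 0) stop("no retained clusters")
  pops <- unique(ds$samples$population)
  per <- matrix(NA_real_, length(pops), length(assignments),
                dimnames = list(pops,
                                vapply(assignments, `[[`, "", "cluster")))
  for (ai in seq_along(assignments)) {
    pfg <- assignments[[ai]]$pfg[ds$samples$id]
    per[, ai] <- tapply(pfg, factor(ds$samples$population, levels = pops),
                        mean, na.rm = TRUE)[pops]
  }
  scored <- rowSums(!is.na(per)) > 0
  if (any(!scored))
    warning("population(s) with no scored individuals excluded: ",
            paste(pops[!scored], collapse = ", "))
  per <- per[scored, , drop = FALSE]
  meta <- ds$samples[match(rownames(per), ds$samples$population), ]
  out <- data.frame(population = rownames(per), region = meta$region,
                    habitat = meta$habitat,
                    pi = rowMeans(per, na.rm = TRUE),
                    n_clusters = rowSums(!is.na(per)))
  rownames(out) <- NULL
  structure(out, per_cluster = per, class = c("parallelism_table",
                                              "data.frame"))
}

#' @export
print.parallelism_table <- function(x, digits = 3, ...) {
  cat("Parallelism Index (mean PFG across individuals, then across",
      ncol(attr(x, "per_cluster")), "retained clusters)\n")
  y <- as.data.frame(x)
  y$pi <- round(y$pi, digits)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Fit the full genetic-parallelism model
#'
#' The package's central fit: for every LD cluster, build the cluster PCA,
#' select a quadratic discriminant classifier of marine vs freshwater
#' haplotypes by leave-one-out cross-validation on the training samples,
#' gate clusters on LOO accuracy, score every individual's Probability of
#' Freshwater Genotype (PFG), and aggregate to the per-population
#' Parallelism Index (PI).
#'
#' @param ds a `geno_data` (filtered; see [filter_sites()]).
#' @param clusters list of [ld_cluster()] objects, or a cluster-definition
#'   data.frame/TSV path with columns `id`, `chrom`, `start`, `end`.
#' @param training a [training_spec()].
#' @param method `"gl"` (genotype-likelihood covariance PCA over all
#'   samples) or `"projected"` (training-only hard-call PCA, queries
#'   projected).
#' @param refine refine each cluster to its most habitat-parallel LD
#'   component first (see [refine_cluster()]).
#' @param split_gap_bp split clusters at member gaps above this before
#'   refinement (`NULL` to skip).
#' @param r2_threshold LD-network threshold used by splitting/refinement.
#' @param k_max,accuracy_gate,priors_mode,maf_min see [score_cluster()].
#' @return A `parallelism_fit` with the per-cluster assignments, the
#'   [parallelism_index()] table, and the settings used. Methods:
#'   `print`, `summary`, `predict` (PFG/PI for new samples), `plot`.
#' @export
fit_parallelism <- function(ds, clusters, training,
                            method = c("gl", "projected"), refine = TRUE,
                            split_gap_bp = 1e6, r2_threshold = 0.5,
                            k_max = 4, accuracy_gate = 0.75,
                            priors_mode = c("proportions", "equal"),
                            maf_min = 0.05) {
  method <- match.arg(method)
  priors_mode <- match.arg(priors_mode)
  if (is.character(clusters) && length(clusters) == 1 &&
      file.exists(clusters))
    clusters <- read_clusters(clusters)
  if (is.data.frame(clusters)) clusters <- clusters_from_table(ds, clusters)
  stopifnot(length(clusters) >= 1)
  tr <- training_index(ds, training)
  ref_ids <- ds$samples$id[tr$idx]
  if (!is.null(split_gap_bp))
    clusters <- do.call(c, lapply(clusters, split_noncontiguous,
                                  max_gap_bp = split_gap_bp))
  if (refine)
    clusters <- lapply(clusters, function(cl) {
      if (length(cl$members) < 2) return(cl)
      tryCatch(refine_cluster(ds, cl, threshold = r2_threshold,
                              reference_samples = ref_ids),
               error = function(e) cl)
    })
  assignments <- lapply(clusters, function(cl)
    tryCatch(score_cluster(ds, cl, training, method = method, k_max = k_max,
                           accuracy_gate = accuracy_gate,
                           priors_mode = priors_mode, maf_min = maf_min),
             error = function(e) NULL))
  ok <- !vapply(assignments, is.null, logical(1))
  assignments <- assignments[ok]
  if (length(assignments) == 0) stop("no cluster could be scored")
  pi_tab <- parallelism_index(assignments, ds)
  structure(list(assignments = assignments, clusters = clusters[ok],
                 pi = pi_tab, training = training, method = method,
                 settings = list(refine = refine, split_gap_bp = split_gap_bp,
                                 r2_threshold = r2_threshold, k_max = k_max,
                                 accuracy_gate = accuracy_gate,
                                 priors_mode = priors_mode,
                                 maf_min = maf_min),
                 samples = ds$samples),
            class = "parallelism_fit")
}

#' @export
print.parallelism_fit <- function(x, ...) {
  nret <- sum(vapply(x$assignments, `[[`, logical(1), "retained"))
  cat("Genetic-parallelism fit (", x$method, " PCA): ",
      length(x$assignments), " clusters scored, ", nret, " retained\n",
      sep = "")
  print(x$pi)
  invisible(x)
}

#' @export
summary.parallelism_fit <- function(object, ...) {
  acc <- do.call(rbind, lapply(object$assignments, function(a) data.frame(
    cluster = a$cluster, k = a$qda$k, loo_accuracy = a$loo_accuracy,
    retained = a$retained)))
  by_region <- stats::aggregate(pi ~ region, as.data.frame(object$pi), mean)
  out <- list(clusters = acc, pi = object$pi, pi_by_region = by_region,
              method = object$method)
  class(out) <- "summary.parallelism_fit"
  out
}

#' @export
print.summary.parallelism_fit <- function(x, ...) {
  cat("Per-cluster classifier accuracy (LOO-CV,", x$method, "PCA):\n")
  print(x$clusters, row.names = FALSE)
  cat("\nMean PI by region:\n")
  print(x$pi_by_region, row.names = FALSE)
  invisible(x)
}

#' Predict PFG for new samples from a fitted parallelism model
#'
#' New individuals are projected onto each retained cluster's stored PCA
#' space with the training constants and scored by the stored QDA model.
#'
#' @param object a [fit_parallelism()] result.
#' @param newdata a `geno_data` carrying the model loci.
#' @param ... ignored.
#' @return Matrix of PFG (samples x retained clusters) with an attached
#'   `"pi"` attribute (per-sample mean across clusters).
#' @export
predict.parallelism_fit <- function(object, newdata, ...) {
  ret <- Filter(function(a) isTRUE(a$retained), object$assignments)
  out <- matrix(NA_real_, nrow(newdata$samples), length(ret),
                dimnames = list(newdata$samples$id,
                                vapply(ret, `[[`, "", "cluster")))
  for (ai in seq_along(ret)) {
    a <- ret[[ai]]
    sc <- pca_project(a$pca, newdata, source = "dosage")
    out[, ai] <- qda_posterior(a$qda, sc[, seq_len(a$qda$k), drop = FALSE])
  }
  attr(out, "pi") <- rowMeans(out, na.rm = TRUE)
  out
}

#' Plot the Parallelism Index by region
#'
#' One point per population, grouped by biogeographic region.
#'
#' @param x a [fit_parallelism()] result.
#' @param ... passed to [graphics::boxplot()].
#' @export
plot.parallelism_fit <- function(x, ...) {
  tab <- as.data.frame(x$pi)
  graphics::boxplot(pi ~ region, tab, ylab = "Parallelism Index",
                    xlab = "region", ylim = c(0, 1), ...)
  graphics::points(jitter(as.integer(factor(tab$region)), 0.2), tab$pi,
                   pch = ifelse(tab$habitat == "freshwater", 19, 1))
  invisible(x)
}
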