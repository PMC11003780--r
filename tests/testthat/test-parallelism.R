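test_that("QDA fit recovers per-class moments in one dimension", {
  set.seed(1)
  x <- matrix(c(rnorm(20, -3, 0.5), rnorm(25, 3, 1.2)), ncol = 1)
  lab <- rep(c("marine", "freshwater"), c(20, 25))
  m <- qda_fit(x, lab, k = 1)
  expect_equal(m$fits$marine$mu, mean(x[1:20, 1]), ignore_attr = TRUE)
  expect_equal(m$fits$marine$sigma[1, 1], var(x[1:20, 1]),
               tolerance = 1e-6)
  expect_equal(m$fits$freshwater$mu, mean(x[21:45, 1]),
               ignore_attr = TRUE)
  expect_equal(unname(m$priors), c(20, 25) / 45)
  # a training freshwater point far from the marine centroid
  expect_gt(qda_posterior(m, 3), 0.99)
  # symmetric classes give 0.5 at the common midpoint
  x2 <- matrix(c(-2, -1, 1, 2, -2, -1, 1, 2), ncol = 1)
  m2 <- qda_fit(x2, rep(c("marine", "freshwater"), each = 4), k = 1)
  expect_equal(qda_posterior(m2, 0), 0.5, tolerance = 1e-10)
})

test_that("posterior equals the independent Gaussian-density oracle", {
  set.seed(42)
  for (rep in 1:100) {
    k <- sample(1:4, 1)
    nM <- sample((k + 1):(k + 8), 1); nF <- sample((k + 1):(k + 8), 1)
    x <- rbind(matrix(rnorm(nM * k, -1), ncol = k),
               matrix(rnorm(nF * k, 1.5), ncol = k))
    lab <- rep(c("marine", "freshwater"), c(nM, nF))
    m <- qda_fit(x, lab, k = k,
                 priors_mode = sample(c("proportions", "equal"), 1))
    pt <- rnorm(k, 0, 2)
    expect_equal(qda_posterior(m, pt), oracle_qda_pfg(m, pt),
                 tolerance = 1e-10)
  }
})

test_that("posterior agrees with MASS::qda on well-conditioned data", {
  skip_if_not_installed("MASS")
  set.seed(7)
  k <- 3
  x <- rbind(matrix(rnorm(40 * k, -1), ncol = k),
             matrix(rnorm(35 * k, 1), ncol = k))
  lab <- rep(c("marine", "freshwater"), c(40, 35))
  m <- qda_fit(x, lab, k = k)
  ref <- MASS::qda(x, grouping = factor(lab))
  pts <- matrix(rnorm(20 * k), ncol = k)
  got <- qda_posterior(m, pts)
  want <- predict(ref, pts)$posterior[, "freshwater"]
  expect_equal(got, unname(want), tolerance = 1e-8)
})

test_that("LOO-CV matches a brute-force refit oracle on a small set", {
  set.seed(11)
  x <- matrix(rnorm(8, rep(c(-1, 1), each = 4), 1.5), ncol = 1)
  lab <- rep(c("marine", "freshwater"), each = 4)
  acc <- loo_cv_accuracy(x, lab, k = 1)
  # oracle: explicit per-fold refits with plain dnorm arithmetic
  correct <- logical(8)
  for (i in 1:8) {
    xi <- x[-i, , drop = FALSE]; li <- lab[-i]
    muM <- mean(xi[li == "marine", 1]); sdM <- sd(xi[li == "marine", 1])
    muF <- mean(xi[li == "freshwater", 1])
    sdF <- sd(xi[li == "freshwater", 1])
    dM <- dnorm(x[i, 1], muM, sdM) * mean(li == "marine")
    dF <- dnorm(x[i, 1], muF, sdF) * mean(li == "freshwater")
    pred <- if (dF / (dM + dF) > 0.5) "freshwater" else "marine"
    correct[i] <- pred == lab[i]
  }
  expect_equal(acc, mean(correct))
})

test_that("LOO accuracy is 1 on separable clusters and near 0.5 on
           shuffled labels", {
  sim <- small_parallel_sim(seed = 19, n_train = 15, n_query = 5,
                            n_clusters = 1)
  tr <- training_spec("TR-MAR", "TR-FW")
  in_cl <- sim$data$loci$pos >= 2e6 & sim$data$loci$pos <= 2.4e6
  cl <- ld_cluster("c1", "chr1", locus_ids(sim$data$loci)[in_cl],
                   sim$data$loci$pos[in_cl])
  a <- score_cluster(sim$data, cl, tr, method = "gl")
  expect_equal(a$loo_accuracy, 1.0)
  expect_true(a$retained)
  # label-shuffled overlapping classes
  set.seed(23)
  x <- matrix(rnorm(60), ncol = 1)
  lab <- sample(rep(c("marine", "freshwater"), 30))
  acc <- loo_cv_accuracy(x, lab, k = 1)
  # binomial 95% band around 0.5 for n = 60
  expect_lt(abs(acc - 0.5), 1.96 * sqrt(0.25 / 60) + 0.05)
})

test_that("model selection ties break to the smallest k and the gate is
           strict", {
  # construct scores where k = 1 already separates perfectly: all
  # accuracies tie at 1 -> k = 1 chosen
  set.seed(5)
  x <- cbind(rep(c(-4, 4), each = 10) + rnorm(20, 0, 0.1),
             rnorm(20), rnorm(20), rnorm(20))
  lab <- rep(c("marine", "freshwater"), each = 10)
  m <- select_model(x, lab)
  expect_equal(m$k, 1)
  expect_equal(m$loo_accuracy, 1.0)
  expect_true(m$retained)
  expect_length(m$accuracies, 4)
  # boundary: best accuracy exactly 0.75 -> retained FALSE
  # 8 fixed scores for which exactly 6 of 8 folds classify correctly
  x2 <- matrix(c(-1.81, -0.76, -2.09, 1.07, 1.43, -0.07, 1.63, 1.96),
               ncol = 1)
  lab2 <- rep(c("marine", "freshwater"), each = 4)
  acc2 <- loo_cv_accuracy(x2, lab2, k = 1)
  expect_equal(acc2, 0.75)
  m2 <- select_model(x2[, 1, drop = FALSE], lab2, k_max = 1)
  expect_false(m2$retained)
})

test_that("training populations score at their own ends of the PFG scale", {
  sim <- small_parallel_sim(seed = 29, q_query = 0.3, n_train = 15,
                            n_query = 15, n_clusters = 2)
  tr <- training_spec("TR-MAR", "TR-FW")
  for (m in c("gl", "projected")) {
    fit <- suppressWarnings(fit_parallelism(
      sim$data, data.frame(id = c("c1", "c2"), chrom = "chr1",
                           start = c(2e6, 4e6), end = c(2.4e6, 4.4e6)),
      tr, method = m))
    tab <- as.data.frame(fit$pi)
    expect_gte(tab$pi[tab$population == "TR-FW"], 0.95)
    expect_lte(tab$pi[tab$population == "TR-MAR"], 0.05)
  }
})

test_that("the two PCA methods rank individuals concordantly", {
  sim <- small_parallel_sim(seed = 37, q_query = 0.5, n_train = 15,
                            n_query = 25, n_clusters = 1, depth = 60,
                            missing_rate = 0)
  tr <- training_spec("TR-MAR", "TR-FW")
  ct <- data.frame(id = "c1", chrom = "chr1", start = 2e6, end = 2.4e6)
  a_gl <- fit_parallelism(sim$data, ct, tr, method = "gl")
  a_pr <- fit_parallelism(sim$data, ct, tr, method = "projected")
  p1 <- a_gl$assignments[[1]]$pfg
  p2 <- a_pr$assignments[[1]]$pfg[names(p1)]
  expect_gte(cor(p1, p2, method = "spearman"), 0.95)
})

test_that("parallelism table averages PFG as specified", {
  # two clusters with per-population PI 0.2 and 0.8 -> overall 0.5
  ds <- toy_ds(matrix(1L, 4, 2), population = rep("P1", 4),
               habitat = rep("freshwater", 4))
  a1 <- structure(list(cluster = "c1", retained = TRUE,
                       pfg = setNames(rep(0.2, 4), ds$samples$id)),
                  class = "cluster_assignment")
  a2 <- structure(list(cluster = "c2", retained = TRUE,
                       pfg = setNames(rep(0.8, 4), ds$samples$id)),
                  class = "cluster_assignment")
  tab <- parallelism_index(list(a1, a2), ds)
  expect_equal(tab$pi, 0.5)
  # all-1 PFG -> PI = 1; unretained clusters are ignored
  a3 <- structure(list(cluster = "c3", retained = FALSE,
                       pfg = setNames(rep(0, 4), ds$samples$id)),
                  class = "cluster_assignment")
  tab2 <- parallelism_index(list(a1, a2, a3), ds)
  expect_equal(ncol(attr(tab2, "per_cluster")), 2)
})

test_that("PI recovers the planted freshwater-haplotype frequency and is
           monotone across a gradient", {
  qs <- c(0.05, 0.25, 0.5, 0.75, 0.95)
  pis <- vapply(seq_along(qs), function(i) {
    sim <- small_parallel_sim(seed = 300 + i, q_query = qs[i],
                              n_query = 20, n_train = 15, n_clusters = 4)
    tr <- training_spec("TR-MAR", "TR-FW")
    fit <- suppressWarnings(fit_parallelism(
      sim$data, data.frame(id = paste0("c", 1:4), chrom = "chr1",
                           start = (1:4) * 2e6, end = (1:4) * 2e6 + 4e5),
      tr, method = "gl"))
    tab <- as.data.frame(fit$pi)
    tab$pi[tab$population == "QU"]
  }, numeric(1))
  expect_true(all(diff(pis) > 0))
  expect_lt(max(abs(pis - qs)), 0.15)
})

test_that("fit object methods work", {
  sim <- small_parallel_sim(seed = 51, n_train = 12, n_query = 8,
                            n_clusters = 1)
  tr <- training_spec("TR-MAR", "TR-FW")
  fit <- fit_parallelism(sim$data,
                         data.frame(id = "c1", chrom = "chr1",
                                    start = 2e6, end = 2.4e6),
                         tr, method = "projected")
  expect_output(print(fit), "Parallelism Index")
  expect_output(print(summary(fit)), "accuracy")
  pred <- predict(fit, sim$data)
  expect_equal(dim(pred), c(nrow(sim$data$samples), 1))
  # predictions for training individuals match the stored PFG closely
  stored <- fit$assignments[[1]]$pfg
  expect_equal(unname(pred[names(stored), 1]), unname(stored),
               tolerance = 0.05)
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})
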