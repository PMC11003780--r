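# shared fixture builders and independently coded oracles

# minimal geno_data from a dosage matrix (samples x loci)
toy_ds <- function(dosage, chrom = NULL, pos = NULL,
                   population = NULL, habitat = NULL, region = NULL,
                   latitude = NULL, gq = NULL, pl = NULL, depth = NULL) {
  n <- nrow(dosage); L <- ncol(dosage)
  if (is.null(chrom)) chrom <- rep("chr1", L)
  if (is.null(pos)) pos <- seq_len(L) * 1000
  if (is.null(population)) population <- rep("P1", n)
  if (is.null(habitat)) habitat <- rep(c("marine", "freshwater"),
                                       length.out = n)
  if (is.null(region)) region <- rep("R1", n)
  if (is.null(latitude)) latitude <- rep(50, n)
  loci <- data.frame(chrom = chrom, pos = pos,
                     ref = rep("A", L), alt = rep("C", L))
  samples <- data.frame(id = sprintf("S%02d", seq_len(n)),
                        population = population, region = region,
                        habitat = habitat, latitude = latitude)
  geno_data(loci, samples, dosage, pl = pl, depth = depth, gq = gq)
}

# exact (noise-free) PL layer encoding given dosages with certainty
certain_pl <- function(dosage, big = 255) {
  n <- nrow(dosage); L <- ncol(dosage)
  pl <- array(big, c(n, L, 3))
  for (g in 0:2) {
    sel <- which(dosage == g)
    slice <- pl[, , g + 1]; slice[sel] <- 0; pl[, , g + 1] <- slice
  }
  na <- which(is.na(dosage))
  for (k in 1:3) { slice <- pl[, , k]; slice[na] <- NA; pl[, , k] <- slice }
  pl
}

# a small two-population training + query simulation used across modules
small_parallel_sim <- function(seed = 1, q_query = 0.5, n_query = 20,
                               n_train = 15, delta = 1, noise = 0.05,
                               n_clusters = 2, n_loci = 25,
                               n_neutral = 100, depth = 20,
                               missing_rate = 0.02) {
  pops <- list(
    pop_spec("TR-MAR", "Pacific", "marine", 61, n_train, 0.02, 0),
    pop_spec("TR-FW", "Pacific", "freshwater", 61, n_train, 0.05, 1),
    pop_spec("QU", "Europe", "freshwater", 45, n_query, 0.05, q_query))
  cls <- lapply(seq_len(n_clusters), function(i)
    cluster_spec(paste0("c", i), "chr1", i * 2e6, i * 2e6 + 4e5, n_loci,
                 delta = delta, within_class_noise = noise))
  simulate_dataset(sim_config(pops, cls, n_loci_neutral = n_neutral,
                              genome = c(chr1 = 1e7), depth_mean = depth,
                              missing_rate = missing_rate, seed = seed))
}

# ---- oracles (coded independently of the package internals) -------------

# brute-force mean pairwise difference per site across all chromosome pairs
oracle_pi_pairwise <- function(dosage) {
  n <- nrow(dosage)
  alleles <- matrix(NA_integer_, 2 * n, ncol(dosage))
  for (i in seq_len(n)) {
    alleles[2 * i - 1, ] <- ifelse(dosage[i, ] >= 1, 1L, 0L)
    alleles[2 * i, ] <- ifelse(dosage[i, ] == 2, 1L, 0L)
  }
  m <- nrow(alleles)
  tot <- 0; np <- 0
  for (a in seq_len(m - 1)) for (b in (a + 1):m) {
    tot <- tot + mean(alleles[a, ] != alleles[b, ])
    np <- np + 1
  }
  tot / np
}

# Weir-Cockerham (1984) theta for one locus, two populations, written as
# scalar arithmetic straight from the published variance components
oracle_wc_theta_locus <- function(nA, nB, pA, pB, hA, hB) {
  r <- 2
  nbar <- (nA + nB) / 2
  nc <- (r * nbar - (nA^2 + nB^2) / (r * nbar)) / (r - 1)
  pbar <- (nA * pA + nB * pB) / (r * nbar)
  s2 <- (nA * (pA - pbar)^2 + nB * (pB - pbar)^2) / ((r - 1) * nbar)
  hbar <- (nA * hA + nB * hB) / (r * nbar)
  a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - (r - 1) * s2 / r -
                              hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - (r - 1) * s2 / r -
                                (2 * nbar - 1) * hbar / (4 * nbar))
  cc <- hbar / 2
  c(a = a, d = a + b + cc)
}

# breadth-first-search connected components over an adjacency matrix
oracle_bfs_components <- function(adj) {
  n <- nrow(adj)
  seen <- logical(n)
  comps <- list()
  for (s in seq_len(n)) {
    if (seen[s]) next
    queue <- s; seen[s] <- TRUE; comp <- integer()
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      comp <- c(comp, v)
      nb <- which(adj[v, ] & !seen)
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    comps[[length(comps) + 1]] <- sort(comp)
  }
  comps
}

# multivariate normal log-density via solve() and det() (no Cholesky)
oracle_mvn_logdens <- function(x, mu, sigma) {
  k <- length(mu)
  d <- x - mu
  -0.5 * (k * log(2 * pi) + log(det(sigma)) +
            drop(t(d) %*% solve(sigma) %*% d))
}

# QDA posterior of the freshwater class from first principles
oracle_qda_pfg <- function(model, x) {
  lm_ <- oracle_mvn_logdens(x, model$fits$marine$mu,
                            model$fits$marine$sigma) +
    log(model$priors[["marine"]])
  lf_ <- oracle_mvn_logdens(x, model$fits$freshwater$mu,
                            model$fits$freshwater$sigma) +
    log(model$priors[["freshwater"]])
  1 / (1 + exp(lm_ - lf_))
}

# base-level overlap F1 between two interval sets on one genome
oracle_interval_f1 <- function(truth, called) {
  # truth/called: data.frames with chrom, start, end (1-based inclusive)
  ov <- 0
  if (nrow(truth) && nrow(called)) {
    for (i in seq_len(nrow(truth))) for (j in seq_len(nrow(called))) {
      if (truth$chrom[i] != called$chrom[j]) next
      lo <- max(truth$start[i], called$start[j])
      hi <- min(truth$end[i], called$end[j])
      if (hi >= lo) ov <- ov + (hi - lo + 1)
    }
  }
  st <- sum(truth$end - truth$start + 1)
  sc <- sum(called$end - called$start + 1)
  if (st + sc == 0) return(NA_real_)
  2 * ov / (st + sc)
}

# exhaustive maximum-probability path of the two-state ROH HMM
# (enumerates all 2^n state sequences; independent of the Viterbi code)
oracle_hmm_best_path <- function(e_hw, e_az, pos, entry, exit, pri_az) {
  n <- length(e_hw)
  best <- -Inf; best_path <- NULL
  d <- diff(pos)
  t_in <- 1 - exp(-entry * d); t_out <- 1 - exp(-exit * d)
  for (mask in 0:(2^n - 1)) {
    st <- as.integer(intToBits(mask))[1:n]  # 1 = AZ
    lp <- if (st[1] == 1) log(pri_az) + e_az[1] else
      log(1 - pri_az) + e_hw[1]
    for (t in 2:n) {
      lp <- lp + log(if (st[t - 1] == 0 && st[t] == 1) t_in[t - 1]
                     else if (st[t - 1] == 0) 1 - t_in[t - 1]
                     else if (st[t] == 0) t_out[t - 1]
                     else 1 - t_out[t - 1])
      lp <- lp + if (st[t] == 1) e_az[t] else e_hw[t]
    }
    if (lp > best) { best <- lp; best_path <- st }
  }
  list(logp = best, path = best_path)
}

demo_config_path <- function() {
  p <- system.file("extdata", "demo_config.yaml", package = "fwparallel")
  if (p == "") p <- file.path("..", "..", "inst", "extdata",
                              "demo_config.yaml")
  p
}

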