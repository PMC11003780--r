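test_that("simulation is bit-reproducible given the seed", {
  cfg <- sim_config(list(
    pop_spec("A", "R1", "marine", 60, 5, 0.05, 0),
    pop_spec("B", "R1", "freshwater", 60, 5, 0.05, 1)),
    list(cluster_spec("c1", "chr1", 1e6, 1.2e6, 10)),
    n_loci_neutral = 50, genome = c(chr1 = 5e6), seed = 9)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1$data$dosage, s2$data$dosage)
  expect_identical(s1$data$pl, s2$data$pl)
  expect_identical(s1$truth$tracts, s2$truth$tracts)
})

test_that("no-drift limit: population frequencies equal the ancestral ones", {
  cfg <- sim_config(list(
    pop_spec("A", "R1", "marine", 10, 20, fst_drift = 0),
    pop_spec("B", "R1", "freshwater", 10, 20, fst_drift = 0)),
    n_loci_neutral = 500, genome = c(chr1 = 5e6), seed = 2)
  sim <- simulate_dataset(cfg, add_likelihoods = FALSE)
  expect_equal(sim$truth$pop_freq["A", ], sim$truth$pop_freq["B", ])
  # and realized Weir-Cockerham theta is near zero
  th <- wc_fst(sim$data, "A", "B")$theta
  expect_lt(abs(th), 0.02)
})

test_that("fixed freshwater haplotype forces FF karyotypes and dosage 2", {
  cfg <- sim_config(list(
    pop_spec("M", "R1", "marine", 60, 5, 0.05, freshwater_hap_freq = 0),
    pop_spec("F", "R1", "freshwater", 60, 8, 0.05, freshwater_hap_freq = 1)),
    list(cluster_spec("c1", "chr1", 1e6, 1.2e6, 12, delta = 1,
                      within_class_noise = 0)),
    n_loci_neutral = 20, genome = c(chr1 = 5e6), seed = 4)
  sim <- simulate_dataset(cfg, add_likelihoods = FALSE)
  expect_true(all(sim$truth$karyotype[6:13, "c1"] == "FF"))
  expect_true(all(sim$truth$karyotype[1:5, "c1"] == "MM"))
  cl_loci <- sim$data$loci$chrom == "chr1" & sim$data$loci$pos >= 1e6 &
    sim$data$loci$pos <= 1.2e6
  d <- sim$data$dosage[6:13, cl_loci, drop = FALSE]
  expect_true(all(d == 2))
})

test_that("Balding-Nichols drift reproduces the F_ST expectation of an
           independent resimulation oracle", {
  # oracle: direct Balding-Nichols resimulation with plain rbeta/rbinom,
  # averaged over replicates
  oracle_theta <- function(F, n, L, reps, seed) {
    set.seed(seed)
    replicate(reps, {
      p0 <- rbeta(L, 0.8, 0.8)
      p0 <- pmin(pmax(p0, 1e-6), 1 - 1e-6)
      pA <- rbeta(L, p0 * (1 - F) / F, (1 - p0) * (1 - F) / F)
      pB <- rbeta(L, p0 * (1 - F) / F, (1 - p0) * (1 - F) / F)
      gA <- matrix(rbinom(n * L, 1, rep(pA, each = n)) +
                     rbinom(n * L, 1, rep(pA, each = n)), n)
      gB <- matrix(rbinom(n * L, 1, rep(pB, each = n)) +
                     rbinom(n * L, 1, rep(pB, each = n)), n)
      comp <- mapply(function(j) oracle_wc_theta_locus(
        n, n, mean(gA[, j]) / 2, mean(gB[, j]) / 2,
        mean(gA[, j] == 1), mean(gB[, j] == 1)), seq_len(L))
      sum(comp["a", ]) / sum(comp["d", ])
    })
  }
  oth <- oracle_theta(F = 0.1, n = 25, L = 400, reps = 60, seed = 99)
  mu <- mean(oth); se <- sd(oth) / sqrt(length(oth))
  cfg <- sim_config(list(
    pop_spec("A", "R1", "marine", 60, 25, fst_drift = 0.1),
    pop_spec("B", "R1", "freshwater", 60, 25, fst_drift = 0.1)),
    n_loci_neutral = 5000, genome = c(chr1 = 2e7), seed = 1)
  sim <- simulate_dataset(cfg, add_likelihoods = FALSE)
  th <- wc_fst(sim$data, "A", "B")$theta
  # 3 Monte-Carlo SE of the oracle expectation, plus the sampling spread of
  # a single 5000-locus realisation (approximated by the replicate SD)
  expect_lt(abs(th - mu), 3 * se + 3 * sd(oth))
})

test_that("planted autozygosity hits its target coverage and F1 vs truth", {
  cfg <- sim_config(list(
    pop_spec("A", "R1", "marine", 60, 6, 0.05, inbreeding_f = 0.25),
    pop_spec("B", "R1", "freshwater", 60, 2, 0.05, inbreeding_f = 0)),
    n_loci_neutral = 4000, genome = c(chr1 = 1e7), depth_mean = 20,
    base_error = 0.005, missing_rate = 0, seed = 21)
  sim <- simulate_dataset(cfg)
  G <- sum(sim$truth$genome)
  for (id in sim$data$samples$id[1:6]) {
    tr <- sim$truth$tracts[sim$truth$tracts$sample == id, ]
    covered <- sum(tr$end - tr$start + 1)
    expect_lt(abs(covered / G - 0.25), 0.01)   # stopping rule trims exactly
    # non-overlap within individual
    for (ch in unique(tr$chrom)) {
      b <- tr[tr$chrom == ch, ]; b <- b[order(b$start), ]
      if (nrow(b) > 1) expect_true(all(b$start[-1] > b$end[-nrow(b)]))
    }
    called <- call_roh(sim$data, id)
    expect_gte(oracle_interval_f1(tr, called), 0.9)
  }
  # no tracts for the non-inbred population
  expect_false(any(sim$truth$tracts$sample %in% sim$data$samples$id[7:8]))
})

test_that("zero inbreeding leaves the dataset unchanged", {
  cfg <- sim_config(list(
    pop_spec("A", "R1", "marine", 60, 4, 0.05),
    pop_spec("B", "R1", "freshwater", 60, 4, 0.05)),
    n_loci_neutral = 100, genome = c(chr1 = 5e6), seed = 3)
  sim <- simulate_dataset(cfg, add_likelihoods = FALSE)
  out <- plant_autozygosity(sim$data, sim$truth, c(A = 0, B = 0))
  expect_identical(out$data$dosage, sim$data$dosage)
  expect_identical(nrow(out$truth$tracts), 0L)
})

test_that("PL encoding matches the closed-form binomial computation", {
  # the half-error heterozygote case d = 10, eps = 0.01, alt = 5 by hand:
  lik <- dbinom(5, 10, c(0.01, 0.5, 1 - 0.01))
  ph <- -10 * log10(lik)
  oracle_pl_5 <- round(ph - min(ph))
  expect_identical(min(oracle_pl_5), 0)  # het is the maximum likelihood
  # every simulated PL vector must equal the closed form for its realised
  # (depth, alt) pair; enumerate the possible alt counts per entry
  set.seed(40)
  dos <- matrix(sample(0:2, 30, replace = TRUE), 3, 10)
  ds <- likelihoods_from_truth(toy_ds(dos), depth_mean = 10,
                               base_error = 0.01, missing_rate = 0,
                               seed = 17)
  seen_5_of_10 <- FALSE
  for (i in 1:3) for (j in 1:10) {
    d <- ds$depth[i, j]
    if (d == 0) next
    match_a <- NA
    for (a in 0:d) {
      l2 <- dbinom(a, d, c(0.01, 0.5, 0.99))
      p2 <- -10 * log10(pmax(l2, 1e-300))
      p2 <- round(p2 - min(p2))
      if (all(p2 == ds$pl[i, j, ])) { match_a <- a; break }
    }
    expect_false(is.na(match_a))
    if (d == 10 && identical(match_a, 5L)) seen_5_of_10 <- TRUE
    if (d == 10 && !is.na(match_a) && match_a == 5)
      expect_equal(ds$pl[i, j, ], oracle_pl_5, ignore_attr = TRUE)
  }
})

test_that("likelihood layer behaves at the noiseless and uninformative limits", {
  set.seed(8)
  dos <- matrix(sample(0:2, 60, replace = TRUE), 6, 10)
  ds0 <- toy_ds(dos)
  hi <- likelihoods_from_truth(ds0, depth_mean = 200, base_error = 1e-4,
                               missing_rate = 0, seed = 1)
  expect_equal(unname(hi$dosage), dos)  # argmax recovers truth at high depth
  # depth 0 entries are missing with flat likelihoods removed
  lo <- likelihoods_from_truth(ds0, depth_mean = 0.3, base_error = 0.01,
                               missing_rate = 0, seed = 2)
  z <- lo$depth == 0
  expect_true(any(z))
  expect_true(all(is.na(lo$dosage[z])))
  expect_true(all(is.na(lo$pl[, , 1][z])))
})

test_that("mean observed heterozygosity matches the Hardy-Weinberg
           expectation within 3 SE", {
  cfg <- sim_config(list(
    pop_spec("A", "R1", "marine", 60, 40, fst_drift = 0),
    pop_spec("B", "R1", "freshwater", 60, 2, fst_drift = 0)),
    n_loci_neutral = 800, genome = c(chr1 = 1e7), seed = 31)
  sim <- simulate_dataset(cfg, add_likelihoods = FALSE)
  p <- sim$truth$pop_freq["A", ]
  p <- p[!is.na(p)]
  expected <- mean(2 * p * (1 - p))
  h <- observed_heterozygosity(sim$data)[1:40]
  se <- sd(h) / sqrt(length(h))
  expect_lt(abs(mean(h) - expected), 3 * se)
})

test_that("fixture bundle round-trips and has the stated shapes", {
  sim <- small_parallel_sim(seed = 6, n_query = 5, n_train = 4,
                            n_neutral = 40, n_clusters = 1, n_loci = 8)
  td <- withr::local_tempdir()
  b <- write_fixture_bundle(sim$data, sim$truth, td)
  expect_true(all(file.exists(b)))
  ds2 <- read_vcf(b[["vcf"]], b[["metadata"]])
  expect_equal(unname(sim$data$dosage), unname(ds2$dosage))
  expect_equal(unname(sim$data$pl), unname(ds2$pl))
  # second write is byte-identical
  p2 <- file.path(td, "again.vcf")
  write_vcf(ds2, p2)
  expect_identical(readLines(b[["vcf"]]), readLines(p2))
  # truth BED has one line per planted tract
  expect_equal(length(readLines(b[["roh_bed"]])), nrow(sim$truth$tracts))
  # beagle: 3 header columns + 3 per sample
  hdr <- strsplit(readLines(b[["beagle"]], n = 1), "\t")[[1]]
  expect_length(hdr, 3 + 3 * nrow(sim$data$samples))
})
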