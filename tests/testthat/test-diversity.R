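test_that("folded SFS tallies minor-allele counts", {
  # monomorphic 3-site dataset -> eta = (3, 0, ...)
  ds <- toy_ds(matrix(0L, 3, 3))
  sfs <- folded_sfs(ds, "P1")
  expect_equal(sfs$counts, c(3, 0, 0, 0))
  expect_equal(sfs$L, 3)
  # one diploid, one het site -> eta_1 = 1
  ds <- toy_ds(matrix(c(0L, 1L), 1, 2))
  sfs <- folded_sfs(ds, "P1")
  expect_equal(sfs$counts, c(1, 1))
  # random complete-data fixture equals a direct per-site tally
  set.seed(14)
  dos <- matrix(sample(0:2, 8 * 40, replace = TRUE, prob = c(4, 2, 1)),
                8, 40)
  sfs <- folded_sfs(toy_ds(dos), "P1")
  tal <- table(factor(pmin(colSums(dos), 16 - colSums(dos)), levels = 0:8))
  expect_equal(sfs$counts, as.numeric(tal))
})

test_that("pi equals the brute-force mean pairwise difference exactly", {
  # closed form: n = 2 chromosomes, 1 site, eta_1 = 1 -> pi = 1
  sfs <- structure(list(counts = c(0, 1), n = 2, L = 1),
                   class = "folded_sfs")
  expect_equal(pi_from_sfs(sfs), 1)
  # all monomorphic -> 0
  expect_equal(pi_from_sfs(folded_sfs(toy_ds(matrix(2L, 4, 5)), "P1")), 0)
  # random complete matrices, several shapes
  set.seed(3)
  for (rep in 1:5) {
    n <- sample(3:6, 1); L <- sample(20:60, 1)
    dos <- matrix(sample(0:2, n * L, replace = TRUE), n, L)
    got <- pi_from_sfs(folded_sfs(toy_ds(dos), "P1"))
    expect_equal(got, oracle_pi_pairwise(dos), tolerance = 1e-12)
  }
})

test_that("SFS projection keeps pi consistent under random missingness", {
  set.seed(10)
  dos <- matrix(sample(0:2, 20 * 400, replace = TRUE, prob = c(5, 3, 2)),
                20, 400)
  full_pi <- pi_from_sfs(folded_sfs(toy_ds(dos), "P1"))
  holed <- dos
  holed[sample(length(holed), 0.05 * length(holed))] <- NA
  proj_pi <- pi_from_sfs(folded_sfs(toy_ds(holed), "P1"))
  expect_lt(abs(proj_pi - full_pi) / full_pi, 0.05)
})

test_that("observed heterozygosity counts het fractions", {
  dos <- rbind(c(0L, 2L, 0L, 2L), c(1L, 1L, 1L, 1L),
               c(1L, 1L, 1L, NA), c(1L, 0L, 0L, NA))
  dos <- rbind(dos, c(1L, 1L, 1L, 0L))
  dos[5, ] <- c(1L, 1L, 1L, 0L)
  ds <- toy_ds(dos)
  h <- observed_heterozygosity(ds)
  expect_equal(unname(h[1]), 0)
  expect_equal(unname(h[2]), 1)
  expect_equal(unname(h[3]), 1)       # over 3 called sites
  expect_equal(unname(h[4]), 1 / 3)
  expect_error(observed_heterozygosity(toy_ds(matrix(NA_integer_, 1, 2))),
               "no called genotypes")
})

test_that("a confidently heterozygous sample yields no ROH", {
  dos <- matrix(1L, 2, 60)
  ds <- toy_ds(dos, pos = seq_len(60) * 1e4, pl = certain_pl(dos))
  segs <- call_roh(ds, "S01", roh_params(freq_source = "supplied"),
                   freqs = setNames(rep(0.5, 60), locus_ids(ds$loci)))
  expect_equal(nrow(segs), 0)
})

test_that("noiseless hom run flanked by hets is called exactly at its
           outermost hom sites", {
  g <- c(1L, 1L, rep(0L, 30), 1L, 1L)
  dos <- rbind(g, g)  # two samples so frequencies are defined
  pos <- seq_along(g) * 1e4
  ds <- toy_ds(dos, pos = pos, pl = certain_pl(dos))
  segs <- call_roh(ds, "S01", roh_params(freq_source = "supplied",
                                         min_sites = 5),
                   freqs = setNames(rep(0.5, length(g)),
                                    locus_ids(ds$loci)))
  expect_equal(nrow(segs), 1)
  expect_equal(segs$start, pos[3])
  expect_equal(segs$end, pos[32])
})

test_that("Viterbi equals the exhaustive best path on small instances", {
  params <- roh_params(min_sites = 1, freq_source = "supplied")
  pri_az <- params$az_entry_rate / (params$az_entry_rate +
                                      params$az_exit_rate)
  set.seed(123)
  for (rep in 1:12) {
    n <- sample(6:13, 1)
    pos <- sort(sample.int(3e6, n))
    g <- sample(0:2, n, replace = TRUE, prob = c(3, 2, 3))
    p <- runif(n, 0.2, 0.8)
    dos <- rbind(g, g)
    # noisy PLs: random but valid
    pl <- certain_pl(dos, big = sample(10:60, 1))
    ds <- toy_ds(dos, pos = pos, pl = pl)
    freqs <- setNames(p, locus_ids(ds$loci))
    segs <- call_roh(ds, "S01", params, freqs = freqs)
    # oracle: enumerate every state path over the same emissions
    gl <- gl_linear(ds)[1, , ]
    pc <- pmin(pmax(p, 1e-6), 1 - 1e-6)
    e_hw <- log(gl[, 1] * (1 - pc)^2 + gl[, 2] * 2 * pc * (1 - pc) +
                  gl[, 3] * pc^2)
    e_az <- log(gl[, 1] * (1 - pc) + gl[, 3] * pc +
                  gl[, 2] * params$az_het_emission)
    oracle <- oracle_hmm_best_path(e_hw, e_az, pos,
                                   params$az_entry_rate,
                                   params$az_exit_rate, pri_az)
    runs <- rle(oracle$path)
    ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1
    oseg <- data.frame(start = pos[starts[runs$values == 1]],
                       end = pos[ends[runs$values == 1]])
    expect_equal(nrow(segs), nrow(oseg))
    if (nrow(oseg)) {
      expect_equal(segs$start, oseg$start)
      expect_equal(segs$end, oseg$end)
    }
  }
})

test_that("planted 1 Mb tract is recovered with high overlap", {
  cfg <- sim_config(list(
    pop_spec("A", "R1", "marine", 60, 10, 0.05, inbreeding_f = 0.1),
    pop_spec("B", "R1", "freshwater", 60, 2, 0.05)),
    n_loci_neutral = 4000, genome = c(chr1 = 1e7), depth_mean = 20,
    base_error = 0.005, missing_rate = 0, tract_mean_bp = 1e6, seed = 55)
  sim <- simulate_dataset(cfg)
  tr <- sim$truth$tracts
  big <- tr[tr$end - tr$start + 1 > 5e5, ]
  expect_gt(nrow(big), 0)
  id <- big$sample[1]
  segs <- call_roh(sim$data, id)
  tri <- tr[tr$sample == id, ]
  # Jaccard on the union of intervals
  f1 <- oracle_interval_f1(tri, segs)
  expect_gte(f1, 0.8)
})

test_that("ROH summaries follow their definitions and reject overlaps", {
  expect_equal(
    roh_summary(data.frame(sample = character(), chrom = character(),
                           start = numeric(), end = numeric()),
                genome_length = 1e7)$n_roh, integer(0))
  segs <- data.frame(sample = "S1", chrom = "chr1",
                     start = 1, end = 1e6)
  s <- roh_summary(segs, genome_length = 1e7)
  expect_equal(s$n_roh, 1L)
  expect_equal(s$f_roh, 1e6 / 1e7)
  bad <- rbind(segs, data.frame(sample = "S1", chrom = "chr1",
                                start = 5e5, end = 2e6))
  expect_error(roh_summary(bad, genome_length = 1e7), "overlapping")
})

test_that("F_ROH increases with planted inbreeding", {
  lvls <- c(0.02, 0.08, 0.15, 0.22, 0.3)
  pops <- lapply(seq_along(lvls), function(i)
    pop_spec(paste0("P", i), "R1", if (i == 1) "marine" else "freshwater",
             50, 6, 0.05, inbreeding_f = lvls[i]))
  cfg <- sim_config(pops, n_loci_neutral = 3000, genome = c(chr1 = 1e7),
                    depth_mean = 20, base_error = 0.005,
                    missing_rate = 0, seed = 66)
  sim <- simulate_dataset(cfg)
  segs <- do.call(rbind, lapply(sim$data$samples$id, function(s)
    call_roh(sim$data, s)))
  rs <- roh_summary(segs, genome_length = 1e7, ds = sim$data)
  truth_f <- rep(lvls, each = 6)
  expect_gte(cor(rs$f_roh, truth_f, method = "spearman"), 0.9)
})
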