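#' Simulation configuration
#'
#' Describes a synthetic study: a set of populations in named biogeographic
#' regions and two habitats, neutral loci drifting under the Balding-Nichols
#' model, and planted high-LD "parallel clusters" carrying a marine and a
#' freshwater haplotype class. Read depth, base error and missingness control
#' the genotype-likelihood layer.
#'
#' @param populations list of [pop_spec()] objects; at least two populations
#'   spanning both habitats.
#' @param clusters list of [cluster_spec()] objects (may be empty).
#' @param n_loci_neutral number of neutral loci.
#' @param ancestral_beta length-2 shape parameters of the Beta distribution
#'   of ancestral allele frequencies.
#' @param genome named numeric vector of chromosome lengths (bp).
#' @param depth_mean mean read depth (Poisson lambda, reads/site).
#' @param base_error per-base error probability epsilon.
#' @param missing_rate probability that a genotype is masked at random
#'   (genotypes with zero reads are always missing).
#' @param tract_mean_bp mean length (bp) of planted autozygous tracts.
#' @param seed integer seed; the whole simulation is deterministic given it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(populations, clusters = list(), n_loci_neutral = 1000,
                       ancestral_beta = c(0.8, 0.8),
                       genome = c(chr1 = 1e7, chr2 = 1e7),
                       depth_mean = 20, base_error = 0.005,
                       missing_rate = 0.02, tract_mean_bp = 1e6, seed = 1) {
  stopifnot(length(populations) >= 2, depth_mean > 0,
            base_error >= 0, base_error <= 1,
            missing_rate >= 0, missing_rate <= 1,
            length(ancestral_beta) == 2, all(ancestral_beta > 0),
            length(genome) >= 1, all(genome > 0), !is.null(names(genome)))
  genome <- stats::setNames(as.numeric(genome), names(genome))
  habs <- vapply(populations, function(p) p$habitat, character(1))
  if (!all(c("marine", "freshwater") %in% habs))
    stop("populations must span both habitats")
  cl_ids <- vapply(clusters, function(cl) cl$id, character(1))
  if (anyDuplicated(cl_ids)) stop("duplicate cluster ids")
  for (cl in clusters) {
    if (!cl$chrom %in% names(genome))
      stop("cluster ", cl$id, " on unknown chromosome ", cl$chrom)
    if (cl$end > genome[[cl$chrom]])
      stop("cluster ", cl$id, " extends past chromosome end")
  }
  populations <- lapply(populations, function(p) {
    p$freshwater_hap_freq <- rep_len(p$freshwater_hap_freq,
                                     max(1L, length(clusters)))
    if (length(clusters) && length(p$freshwater_hap_freq) != length(clusters))
      stop("freshwater_hap_freq must be supplied for every cluster")
    p
  })
  structure(list(populations = populations, clusters = clusters,
                 n_loci_neutral = as.integer(n_loci_neutral),
                 ancestral_beta = ancestral_beta, genome = genome,
                 depth_mean = depth_mean, base_error = base_error,
                 missing_rate = missing_rate, tract_mean_bp = tract_mean_bp,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Population specification for the simulator
#'
#' @param name,region population and biogeographic-region labels.
#' @param habitat `"marine"` or `"freshwater"`.
#' @param latitude degrees.
#' @param n_individuals diploid sample size.
#' @param fst_drift Balding-Nichols drift parameter F in \[0, 1);
#'   `F = 0` means the population frequency equals the ancestral frequency.
#' @param freshwater_hap_freq frequency of the freshwater haplotype class in
#'   this population, one value per cluster (recycled if scalar).
#' @param inbreeding_f target autozygous genome fraction in \[0, 1).
#' @return A `pop_spec` list.
#' @export
pop_spec <- function(name, region, habitat, latitude, n_individuals,
                     fst_drift = 0.05, freshwater_hap_freq = 0,
                     inbreeding_f = 0) {
  habitat <- match.arg(habitat, c("marine", "freshwater"))
  stopifnot(n_individuals >= 1, fst_drift >= 0, fst_drift < 1,
            all(freshwater_hap_freq >= 0), all(freshwater_hap_freq <= 1),
            inbreeding_f >= 0, inbreeding_f < 1)
  structure(list(name = name, region = region, habitat = habitat,
                 latitude = latitude, n_individuals = as.integer(n_individuals),
                 fst_drift = fst_drift,
                 freshwater_hap_freq = freshwater_hap_freq,
                 inbreeding_f = inbreeding_f),
            class = "pop_spec")
}

#' Parallel LD-cluster specification for the simulator
#'
#' A planted cluster carries two haplotype classes (marine and freshwater)
#' whose per-locus allele frequencies differ by `delta`: a haplotype carries
#' the class-typical allele with probability (1 + delta)/2 on its own class
#' background and (1 - delta)/2 on the other.
#'
#' @param id,chrom labels; `start`,`end` bp bounds (`end > start`).
#' @param n_loci number of loci planted in the cluster.
#' @param delta marine-freshwater allele-frequency contrast in (0, 1].
#' @param within_class_noise SD of per-locus jitter on the class
#'   frequencies. The default emulates the residual within-class
#'   polymorphism real ecotype haplotype groups carry; set to 0 for exactly
#'   fixed classes.
#' @return A `cluster_spec` list.
#' @export
cluster_spec <- function(id, chrom, start, end, n_loci, delta = 1,
                         within_class_noise = 0.05) {
  if (!(delta > 0 && delta <= 1)) stop("delta must be in (0, 1]")
  stopifnot(end > start, n_loci >= 1, within_class_noise >= 0)
  structure(list(id = as.character(id), chrom = chrom, start = start,
                 end = end, n_loci = as.integer(n_loci), delta = delta,
                 within_class_noise = within_class_noise),
            class = "cluster_spec")
}

#' Simulate a genotype dataset with known ground truth
#'
#' Neutral loci: ancestral frequencies are Beta-distributed and each
#' population's frequency is drawn from the Balding-Nichols distribution
#' `Beta(p0 (1-F)/F, (1-p0)(1-F)/F)` (or equals `p0` when `F = 0`);
#' haplotype alleles are Bernoulli draws. Cluster loci are generated
#' haplotype-first: each individual draws two haplotype classes (freshwater
#' with the population's `freshwater_hap_freq`), then per-locus alleles with
#' the class frequencies, so within-cluster LD is high by construction.
#' Autozygous tracts are then planted per [plant_autozygosity()] and the
#' genotype-likelihood layer added per [likelihoods_from_truth()].
#'
#' @param config a [sim_config()].
#' @param add_likelihoods if `FALSE`, return error-free hard genotypes
#'   (no PL/DP/GQ layer, no missingness).
#' @return A list with elements `data` (a [geno_data()]) and `truth`
#'   (a `sim_truth`: true dosages, per-population true allele frequencies,
#'   per-individual cluster karyotypes MM/MF/FF, planted tracts, and the
#'   underlying haplotype pair array).
#' @export
simulate_dataset <- function(config, add_likelihoods = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  gen <- config$genome
  # --- locus placement ---------------------------------------------------
  n_neu <- config$n_loci_neutral
  alloc <- if (n_neu > 0) {
    a <- round(n_neu * gen / sum(gen))
    a[1] <- a[1] + n_neu - sum(a)
    a
  } else setNames(rep(0, length(gen)), names(gen))
  loci <- list()
  for (ch in names(gen)) {
    if (alloc[[ch]] > 0) {
      pos <- sort(sample.int(gen[[ch]], alloc[[ch]]))
      loci[[length(loci) + 1L]] <- data.frame(
        chrom = ch, pos = pos, cluster = NA_character_)
    }
  }
  for (cl in config$clusters) {
    pos <- sort(sample(seq(cl$start, cl$end), cl$n_loci))
    loci[[length(loci) + 1L]] <- data.frame(
      chrom = cl$chrom, pos = pos, cluster = cl$id)
  }
  loci <- do.call(rbind, loci)
  loci <- loci[!duplicated(loci[c("chrom", "pos")]), ]
  loci <- loci[order(loci$chrom, loci$pos), ]
  rownames(loci) <- NULL
  L <- nrow(loci)
  bases <- c("A", "C", "G", "T")
  loci$ref <- sample(bases, L, replace = TRUE)
  loci$alt <- vapply(loci$ref, function(b) sample(setdiff(bases, b), 1), "")
  neutral_idx <- which(is.na(loci$cluster))

  # --- sample table ------------------------------------------------------
  pops <- config$populations
  samples <- do.call(rbind, lapply(pops, function(p) data.frame(
    id = sprintf("%s_%02d", p$name, seq_len(p$n_individuals)),
    population = p$name, region = p$region, habitat = p$habitat,
    latitude = p$latitude)))
  n_tot <- nrow(samples)
  n_cl <- length(config$clusters)

  # --- allele frequencies ------------------------------------------------
  p0 <- rep(NA_real_, L)
  p0[neutral_idx] <- stats::rbeta(length(neutral_idx),
                                  config$ancestral_beta[1],
                                  config$ancestral_beta[2])
  p0 <- pmin(pmax(p0, 1e-6), 1 - 1e-6)
  pop_freq <- matrix(NA_real_, length(pops), L,
                     dimnames = list(vapply(pops, `[[`, "", "name"),
                                     locus_ids(loci)))
  # class frequencies per cluster locus (shared across populations)
  class_freq <- matrix(NA_real_, 2, L, dimnames = list(c("M", "F"), NULL))
  for (ci in seq_len(n_cl)) {
    cl <- config$clusters[[ci]]
    idx <- which(!is.na(loci$cluster) & loci$cluster == cl$id)
    fM <- (1 - cl$delta) / 2
    fF <- (1 + cl$delta) / 2
    if (cl$within_class_noise > 0) {
      fM <- fM + stats::rnorm(length(idx), 0, cl$within_class_noise)
      fF <- fF + stats::rnorm(length(idx), 0, cl$within_class_noise)
    }
    class_freq["M", idx] <- pmin(pmax(fM, 0), 1)
    class_freq["F", idx] <- pmin(pmax(fF, 0), 1)
  }

  # --- haplotypes --------------------------------------------------------
  hap <- array(0L, c(n_tot, L, 2),
               dimnames = list(samples$id, locus_ids(loci), NULL))
  karyo <- if (n_cl > 0)
    matrix(NA_character_, n_tot, n_cl,
           dimnames = list(samples$id,
                           vapply(config$clusters, `[[`, "", "id")))
  else NULL
  row0 <- 0L
  for (pi in seq_along(pops)) {
    p <- pops[[pi]]
    n <- p$n_individuals
    rows <- row0 + seq_len(n)
    # neutral frequencies for this population
    pp <- p0[neutral_idx]
    if (p$fst_drift > 0) {
      Fd <- p$fst_drift
      pp <- stats::rbeta(length(pp), pp * (1 - Fd) / Fd,
                         (1 - pp) * (1 - Fd) / Fd)
      pp <- pmin(pmax(pp, 0), 1)
    }
    pop_freq[pi, neutral_idx] <- pp
    for (h in 1:2)
      hap[rows, neutral_idx, h] <-
        matrix(stats::rbinom(n * length(neutral_idx), 1L,
                             rep(pp, each = n)), n)
    # cluster loci, haplotype-class first
    for (ci in seq_len(n_cl)) {
      cl <- config$clusters[[ci]]
      idx <- which(!is.na(loci$cluster) & loci$cluster == cl$id)
      q <- p$freshwater_hap_freq[ci]
      cls <- matrix(stats::rbinom(n * 2, 1L, q), n, 2)  # 1 = freshwater
      karyo[rows, ci] <- c("MM", "MF", "FF")[rowSums(cls) + 1L]
      for (h in 1:2) {
        fr <- as.numeric(cls[, h])  # 1 = freshwater-class haplotype
        freq <- outer(fr, class_freq["F", idx]) +
          outer(1 - fr, class_freq["M", idx])
        hap[rows, idx, h] <- matrix(stats::rbinom(length(freq), 1L, freq), n)
      }
      pop_freq[pi, idx] <- q * class_freq["F", idx] +
        (1 - q) * class_freq["M", idx]
    }
    row0 <- row0 + n
  }

  truth <- structure(list(
    hap = hap,
    karyotype = karyo,
    pop_freq = pop_freq,
    tracts = data.frame(sample = character(), chrom = character(),
                        start = numeric(), end = numeric()),
    genome = gen,
    clusters = config$clusters), class = "sim_truth")
  truth$true_dosage <- hap[, , 1] + hap[, , 2]

  ds <- geno_data(loci[c("chrom", "pos", "ref", "alt")], samples,
                  truth$true_dosage)
  # --- autozygosity ------------------------------------------------------
  inb <- vapply(pops, `[[`, numeric(1), "inbreeding_f")
  if (any(inb > 0)) {
    planted <- plant_autozygosity(ds, truth,
                                  setNames(inb, vapply(pops, `[[`, "", "name")),
                                  tract_length_dist = config$tract_mean_bp)
    ds <- planted$data; truth <- planted$truth
  }
  # --- genotype likelihoods ---------------------------------------------
  if (add_likelihoods) {
    ds <- likelihoods_from_truth(ds, truth$true_dosage, config$depth_mean,
                                 config$base_error, config$missing_rate)
  }
  list(data = ds, truth = truth)
}

#' Plant autozygous tracts into simulated haplotypes
#'
#' For each individual, non-overlapping tracts with exponentially distributed
#' lengths are drawn until the covered genome fraction reaches the
#' population's target; the final tract is trimmed so the covered fraction
#' hits the target exactly. Within a tract the second haplotype is
#' overwritten by the first, so all tract sites are homozygous before
#' likelihood noise. Tracts are recorded in the truth record.
#'
#' @param ds a `geno_data` whose dosages equal the truth haplotype sums.
#' @param truth the matching `sim_truth` (carries the haplotype pairs).
#' @param pop_inbreeding named vector of target autozygous fractions per
#'   population (values in \[0, 1)).
#' @param tract_length_dist mean tract length in bp (exponential).
#' @return list with updated `data` and `truth`.
#' @export
plant_autozygosity <- function(ds, truth, pop_inbreeding,
                               tract_length_dist = 1e6) {
  if (any(pop_inbreeding >= 1)) stop("target autozygous fraction must be < 1")
  gen <- truth$genome
  G <- sum(gen)
  tracts <- list()
  hap <- truth$hap
  pos_by_chrom <- split(seq_len(nrow(ds$loci)), ds$loci$chrom)
  for (si in seq_len(nrow(ds$samples))) {
    f <- pop_inbreeding[[ds$samples$population[si]]]
    if (is.null(f) || is.na(f) || f <= 0) next
    target <- f * G
    have <- list()  # per chrom list of (start,end)
    covered <- 0
    guard <- 0L
    while (covered < target && guard < 10000L) {
      guard <- guard + 1L
      ch <- sample(names(gen), 1, prob = gen)
      len <- max(1, round(stats::rexp(1, 1 / tract_length_dist)))
      len <- min(len, target - covered)         # trim to hit target exactly
      start <- sample.int(max(1, gen[[ch]] - len), 1)
      end <- start + len - 1
      ex <- have[[ch]]
      if (!is.null(ex) && any(start <= ex[, 2] & end >= ex[, 1])) next
      have[[ch]] <- rbind(ex, c(start, end))
      covered <- covered + len
      tracts[[length(tracts) + 1L]] <- data.frame(
        sample = ds$samples$id[si], chrom = ch, start = start, end = end)
      in_tract <- pos_by_chrom[[ch]]
      in_tract <- in_tract[ds$loci$pos[in_tract] >= start &
                             ds$loci$pos[in_tract] <= end]
      if (length(in_tract))
        hap[si, in_tract, 2] <- hap[si, in_tract, 1]
    }
  }
  truth$hap <- hap
  truth$true_dosage <- hap[, , 1] + hap[, , 2]
  if (length(tracts))
    truth$tracts <- rbind(truth$tracts, do.call(rbind, tracts))
  ds$dosage[] <- truth$true_dosage
  list(data = ds, truth = truth)
}

#' Genotype likelihoods, depth and quality from true dosages
#'
#' Per site and sample: read depth `d ~ Poisson(depth_mean)`; alt-read count
#' `~ Binomial(d, e(g))` with `e(0) = eps`, `e(1) = 0.5`, `e(2) = 1 - eps`;
#' the three genotype likelihoods are the binomial probabilities, stored
#' Phred-scaled and min-normalised (integer PL); GQ is the second-smallest
#' PL; the hard call is the maximum-likelihood genotype. Entries are missing
#' at rate `missing_rate` or when `d = 0`.
#'
#' @param ds a `geno_data` (its dosage layer is taken as the truth unless
#'   `true_dosage` is given).
#' @param true_dosage optional samples x loci matrix in \{0, 1, 2\}.
#' @param depth_mean,base_error,missing_rate see [sim_config()].
#' @param seed optional; if given, `set.seed()` is called first.
#' @return A `geno_data` with PL/DP/GQ layers and hard calls re-derived
#'   from the likelihoods.
#' @export
likelihoods_from_truth <- function(ds, true_dosage = NULL, depth_mean = 20,
                                   base_error = 0.005, missing_rate = 0,
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- if (is.null(true_dosage)) ds$dosage else true_dosage
  stopifnot(all(g %in% 0:2))
  n <- nrow(g); L <- ncol(g)
  d <- matrix(stats::rpois(n * L, depth_mean), n, L)
  erate <- matrix(c(base_error, 0.5, 1 - base_error)[g + 1L], n, L)
  alt <- matrix(stats::rbinom(n * L, as.vector(d), as.vector(erate)), n, L)
  lik <- array(NA_real_, c(n, L, 3))
  lik[, , 1] <- stats::dbinom(alt, d, base_error)
  lik[, , 2] <- stats::dbinom(alt, d, 0.5)
  lik[, , 3] <- stats::dbinom(alt, d, 1 - base_error)
  # Phred scale, min-normalised, integer (VCF PL convention)
  ph <- -10 * log10(pmax(lik, 1e-300))
  mn <- pmin(ph[, , 1], ph[, , 2], ph[, , 3])
  pl <- round(ph - as.vector(rep(mn, 3)))
  miss <- matrix(stats::runif(n * L) < missing_rate, n, L) | d == 0L
  call_from_pl <- function(pl, miss) {
    p1 <- pl[, , 1]; p2 <- pl[, , 2]; p3 <- pl[, , 3]
    dose <- ifelse(p1 <= p2 & p1 <= p3, 0L, ifelse(p2 <= p3, 1L, 2L))
    # second-smallest PL (the smallest is 0 after min-normalisation)
    gq <- p1 + p2 + p3 - pmin(p1, p2, p3) - pmax(p1, p2, p3)
    dose[miss] <- NA_integer_
    gq[miss] <- NA_real_
    list(dose = dose, gq = gq)
  }
  cc <- call_from_pl(pl, miss)
  pl[as.vector(rep(miss, 3))] <- NA_real_
  geno_data(ds$loci, ds$samples, cc$dose, pl = pl, depth = d, gq = cc$gq)
}
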