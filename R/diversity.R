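#' Folded site frequency spectrum of a population
#'
#' Per site, the minor-allele count among non-missing chromosomes is
#' tallied. Sites whose effective (non-missing) chromosome count differs
#' are projected down to the population's minimum complete chromosome count
#' by hypergeometric projection, which keeps downstream diversity estimates
#' unbiased under random missingness. Monomorphic sites contribute to the
#' zero class and to `L`.
#'
#' @param ds a `geno_data`.
#' @param population population label.
#' @param n_project optional target haploid sample size; defaults to the
#'   minimum non-missing chromosome count across sites (sites with fewer
#'   chromosomes than the target are dropped from the spectrum and `L`).
#' @return A `folded_sfs`: list with `counts` (eta_0 .. eta_floor(n/2)),
#'   `n` (haploid size) and `L` (total sites represented).
#' @export
folded_sfs <- function(ds, population, n_project = NULL) {
  idx <- pop_index(ds, population)
  d <- ds$dosage[idx, , drop = FALSE]
  n_chr <- 2L * colSums(!is.na(d))
  alt <- colSums(d, na.rm = TRUE)
  ok <- n_chr >= 2L
  if (!any(ok)) stop("no sites with at least one called diploid in ", population)
  n_chr <- n_chr[ok]; alt <- alt[ok]
  m <- if (is.null(n_project)) min(n_chr) else as.integer(n_project)
  if (m < 2L) stop("projection target below 2 chromosomes")
  drop <- n_chr < m
  n_chr <- n_chr[!drop]; alt <- alt[!drop]
  counts <- numeric(m %/% 2 + 1L)
  for (n_i in unique(n_chr)) {
    sel <- n_chr == n_i
    for (k in unique(alt[sel])) {
      w <- sum(alt[sel] == k)
      if (n_i == m) {
        j <- min(k, m - k)
        counts[j + 1L] <- counts[j + 1L] + w
      } else {
        # hypergeometric projection of count k of n_i down to m chromosomes
        pj <- stats::dhyper(0:m, k, n_i - k, m)
        fold <- pmin(0:m, m - (0:m))
        for (jj in 0:m)
          counts[fold[jj + 1L] + 1L] <- counts[fold[jj + 1L] + 1L] +
            w * pj[jj + 1L]
      }
    }
  }
  structure(list(counts = counts, n = m, L = length(alt)),
            class = "folded_sfs")
}

#' Nucleotide diversity from a folded SFS
#'
#' `pi = [ sum_j j (n - j) eta_j / C(n, 2) ] / L`, the average proportion of
#' differing sites between two chromosomes.
#'
#' @param sfs a [folded_sfs()].
#' @return Per-site nucleotide diversity.
#' @export
pi_from_sfs <- function(sfs) {
  stopifnot(inherits(sfs, "folded_sfs"))
  if (sfs$L == 0) stop("SFS represents zero sites")
  n <- sfs$n
  j <- seq_along(sfs$counts) - 1L
  sum(j * (n - j) * sfs$counts) / choose(n, 2) / sfs$L
}

#' Observed individual heterozygosity
#'
#' Fraction of non-missing sites at which the sample is heterozygous.
#'
#' @param ds a `geno_data`.
#' @param sample sample id (or vector of ids).
#' @return Named numeric vector of H_O values.
#' @export
observed_heterozygosity <- function(ds, sample = ds$samples$id) {
  i <- match(sample, ds$samples$id)
  if (anyNA(i)) stop("unknown sample id")
  vapply(i, function(si) {
    g <- ds$dosage[si, ]
    g <- g[!is.na(g)]
    if (length(g) == 0L) stop("sample ", ds$samples$id[si],
                              " has no called genotypes")
    mean(g == 1L)
  }, numeric(1), USE.NAMES = FALSE) -> h
  stats::setNames(h, ds$samples$id[i])
}

#' ROH HMM parameters
#'
#' Two-state (Hardy-Weinberg vs autozygous) hidden Markov model settings.
#' Transition probabilities over an inter-site distance `d` bp are
#' `1 - exp(-rate * d)`. Results depend on these settings; they are stored
#' with every call.
#'
#' @param az_entry_rate per-bp intensity of entering the autozygous state.
#' @param az_exit_rate per-bp intensity of leaving it.
#' @param az_het_emission residual heterozygote emission probability inside
#'   autozygous tracts (genotyping error allowance).
#' @param min_sites minimum number of sites for a reported segment.
#' @param freq_source `"sample"` (population allele frequencies from the
#'   dataset) or `"supplied"` (pass `freqs` to [call_roh()]).
#' @return An `roh_params` list.
#' @export
roh_params <- function(az_entry_rate = 5e-9, az_exit_rate = 5e-7,
                       az_het_emission = 0.01, min_sites = 10,
                       freq_source = c("sample", "supplied")) {
  stopifnot(az_entry_rate > 0, az_exit_rate > 0,
            az_het_emission >= 0, az_het_emission < 1)
  structure(list(az_entry_rate = az_entry_rate, az_exit_rate = az_exit_rate,
                 az_het_emission = az_het_emission,
                 min_sites = as.integer(min_sites),
                 freq_source = match.arg(freq_source)),
            class = "roh_params")
}

# log-sum-exp of two values
lse2 <- function(a, b) {
  m <- pmax(a, b)
  m + log(exp(a - m) + exp(b - m))
}

#' Call runs of homozygosity from genotype likelihoods
#'
#' Two-state HMM over the sites of each chromosome. Emissions use the
#' linear-scale genotype likelihoods: under Hardy-Weinberg,
#' `P(D) = GL0 (1-p)^2 + GL1 2p(1-p) + GL2 p^2`; under autozygosity,
#' `P(D) = GL0 (1-p) + GL2 p + GL1 * az_het_emission`. The Viterbi path is
#' decoded and maximal autozygous runs of at least `min_sites` sites are
#' reported, bounded by the outermost member sites; the mean posterior
#' autozygosity (forward-backward) over each segment is attached.
#'
#' @param ds a `geno_data` with a PL layer.
#' @param sample sample id.
#' @param params an [roh_params()].
#' @param freqs optional named per-locus alt-allele frequencies (required
#'   when `freq_source = "supplied"`); defaults to the dosage-based
#'   frequencies of the sample's own population.
#' @return data.frame with columns `sample`, `chrom`, `start`, `end`,
#'   `n_sites`, `mean_posterior` (zero rows when no run qualifies).
#' @export
call_roh <- function(ds, sample, params = roh_params(), freqs = NULL) {
  si <- match(sample, ds$samples$id)
  if (is.na(si)) stop("unknown sample id: ", sample)
  if (is.null(ds$pl)) stop("ROH calling needs genotype likelihoods (PL)")
  if (params$freq_source == "supplied") {
    if (is.null(freqs)) stop("freq_source='supplied' but no freqs given")
    p_all <- freqs[locus_ids(ds$loci)]
  } else {
    pop <- ds$samples$population[si]
    p_all <- allele_frequencies(ds, scope = pop)
  }
  gl <- gl_linear(ds)[si, , , drop = TRUE]
  if (is.null(dim(gl))) gl <- matrix(gl, ncol = 3)
  out <- list()
  for (ch in unique(ds$loci$chrom)) {
    idx <- which(ds$loci$chrom == ch & !is.na(gl[, 1]) & !is.na(p_all))
    if (length(idx) < 2L) next
    p <- pmin(pmax(p_all[idx], 1e-6), 1 - 1e-6)
    g0 <- gl[idx, 1]; g1 <- gl[idx, 2]; g2 <- gl[idx, 3]
    e_hw <- log(g0 * (1 - p)^2 + g1 * 2 * p * (1 - p) + g2 * p^2)
    e_az <- log(g0 * (1 - p) + g2 * p + g1 * params$az_het_emission)
    pos <- ds$loci$pos[idx]
    d <- diff(pos)
    t_in <- pmin(pmax(1 - exp(-params$az_entry_rate * d), 1e-300), 1 - 1e-12)
    t_out <- pmin(pmax(1 - exp(-params$az_exit_rate * d), 1e-300), 1 - 1e-12)
    T_hh <- log(1 - t_in);  T_ha <- log(t_in)
    T_aa <- log(1 - t_out); T_ah <- log(t_out)
    n <- length(idx)
    pri_az <- params$az_entry_rate /
      (params$az_entry_rate + params$az_exit_rate)
    # Viterbi
    v_h <- numeric(n); v_a <- numeric(n)
    bt <- matrix(0L, n, 2)  # backtrace: 1 = from HW, 2 = from AZ
    v_h[1] <- log(1 - pri_az) + e_hw[1]
    v_a[1] <- log(pri_az) + e_az[1]
    for (t in 2:n) {
      hh <- v_h[t - 1] + T_hh[t - 1]; ah <- v_a[t - 1] + T_ah[t - 1]
      ha <- v_h[t - 1] + T_ha[t - 1]; aa <- v_a[t - 1] + T_aa[t - 1]
      if (hh >= ah) { v_h[t] <- hh + e_hw[t]; bt[t, 1] <- 1L }
      else { v_h[t] <- ah + e_hw[t]; bt[t, 1] <- 2L }
      if (ha >= aa) { v_a[t] <- ha + e_az[t]; bt[t, 2] <- 1L }
      else { v_a[t] <- aa + e_az[t]; bt[t, 2] <- 2L }
    }
    state <- integer(n)
    state[n] <- if (v_a[n] > v_h[n]) 2L else 1L
    for (t in n:2) state[t - 1] <- bt[t, state[t]]
    # forward-backward posterior of AZ
    f_h <- numeric(n); f_a <- numeric(n)
    f_h[1] <- log(1 - pri_az) + e_hw[1]; f_a[1] <- log(pri_az) + e_az[1]
    for (t in 2:n) {
      f_h[t] <- lse2(f_h[t - 1] + T_hh[t - 1], f_a[t - 1] + T_ah[t - 1]) +
        e_hw[t]
      f_a[t] <- lse2(f_h[t - 1] + T_ha[t - 1], f_a[t - 1] + T_aa[t - 1]) +
        e_az[t]
    }
    b_h <- numeric(n); b_a <- numeric(n)
    for (t in (n - 1):1) {
      b_h[t] <- lse2(T_hh[t] + e_hw[t + 1] + b_h[t + 1],
                     T_ha[t] + e_az[t + 1] + b_a[t + 1])
      b_a[t] <- lse2(T_ah[t] + e_hw[t + 1] + b_h[t + 1],
                     T_aa[t] + e_az[t + 1] + b_a[t + 1])
    }
    post_az <- 1 / (1 + exp((f_h + b_h) - (f_a + b_a)))
    # maximal AZ runs
    r <- rle(state == 2L)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths >= params$min_sites)) {
      seg <- starts[k]:ends[k]
      out[[length(out) + 1L]] <- data.frame(
        sample = sample, chrom = ch,
        start = pos[starts[k]], end = pos[ends[k]],
        n_sites = length(seg),
        mean_posterior = mean(post_az[seg]))
    }
  }
  if (length(out) == 0L)
    return(data.frame(sample = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      n_sites = integer(), mean_posterior = numeric()))
  do.call(rbind, out)
}

#' ROH summaries per sample
#'
#' `N_ROH` (count), `S_ROH` (summed length, bp; segment length is
#' `end - start + 1`) and `F_ROH = S_ROH / genome_length`. No length cut-off
#' is applied.
#'
#' @param segments data.frame as returned by [call_roh()] (possibly for
#'   several samples row-bound together).
#' @param genome_length autosomal genome length in bp; defaults, when a
#'   dataset is supplied, to the summed per-chromosome span of observed
#'   positions.
#' @param ds optional `geno_data` used for the genome-length default and to
#'   include samples with zero segments.
#' @return data.frame with columns `sample`, `n_roh`, `s_roh`, `f_roh`.
#' @export
roh_summary <- function(segments, genome_length = NULL, ds = NULL) {
  if (is.null(genome_length)) {
    if (is.null(ds)) stop("supply genome_length or ds")
    genome_length <- sum(tapply(ds$loci$pos, ds$loci$chrom,
                                function(p) max(p) - min(p)))
  }
  stopifnot(genome_length > 0)
  ids <- if (!is.null(ds)) ds$samples$id else unique(segments$sample)
  # overlapping segments within a sample violate the segment invariant
  if (nrow(segments)) {
    by <- split(segments, paste(segments$sample, segments$chrom))
    for (b in by) {
      b <- b[order(b$start), ]
      if (nrow(b) > 1 && any(b$start[-1] <= b$end[-nrow(b)]))
        stop("overlapping ROH segments for sample ", b$sample[1])
    }
  }
  out <- data.frame(sample = ids, n_roh = rep(0L, length(ids)),
                    s_roh = rep(0, length(ids)),
                    f_roh = rep(0, length(ids)))
  if (nrow(segments)) {
    len <- segments$end - segments$start + 1
    agg_n <- tapply(len, segments$sample, length)
    agg_s <- tapply(len, segments$sample, sum)
    m <- match(names(agg_n), out$sample)
    out$n_roh[m] <- as.integer(agg_n)
    out$s_roh[m] <- as.numeric(agg_s)
  }
  out$f_roh <- out$s_roh / genome_length
  if (any(out$f_roh > 1)) stop("F_ROH above 1: check genome_length")
  out
}
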