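#' Read a multi-sample VCF with sample metadata
#'
#' Parses GT (alt-allele dosages) and, when present, PL, DP and GQ fields.
#' Sample order follows the VCF; metadata rows are joined by sample id.
#'
#' @param path VCF file (plain or gzipped).
#' @param metadata_path TSV with columns `id`, `population`, `region`,
#'   `habitat`, `latitude` (or a data.frame).
#' @return A [geno_data()].
#' @export
read_vcf <- function(path, metadata_path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  meta <- if (is.data.frame(metadata_path)) metadata_path else
    utils::read.delim(metadata_path, stringsAsFactors = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  loci <- data.frame(chrom = fix$CHROM, pos = as.numeric(fix$POS),
                     ref = fix$REF, alt = fix$ALT)
  ids <- colnames(v@gt)[-1]
  missing_meta <- setdiff(ids, meta$id)
  if (length(missing_meta))
    stop("samples in VCF absent from metadata: ",
         paste(missing_meta, collapse = ", "))
  samples <- meta[match(ids, meta$id), , drop = FALSE]
  gt <- vcfR::extract.gt(v, element = "GT")
  dos <- matrix(NA_integer_, nrow(loci), length(ids))
  dos[gt %in% c("0/0", "0|0")] <- 0L
  dos[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  dos[gt %in% c("1/1", "1|1")] <- 2L
  fmt <- unique(unlist(strsplit(v@gt[, 1], ":")))
  pl <- NULL
  if ("PL" %in% fmt) {
    plc <- vcfR::extract.gt(v, element = "PL")
    pl <- array(NA_real_, c(length(ids), nrow(loci), 3))
    ok <- !is.na(plc) & plc != "."
    if (any(ok)) {
      parts <- matrix(NA_real_, length(plc), 3)
      sp <- strsplit(plc[ok], ",", fixed = TRUE)
      parts[ok, ] <- t(vapply(sp, function(x) as.numeric(x[1:3]), numeric(3)))
      for (k in 1:3) pl[, , k] <- t(matrix(parts[, k], nrow(loci)))
    }
  }
  num_layer <- function(el) {
    if (!el %in% fmt) return(NULL)
    m <- vcfR::extract.gt(v, element = el, as.numeric = TRUE)
    t(m)
  }
  ds <- geno_data(loci, samples, t(dos), pl = pl,
                  depth = num_layer("DP"), gq = num_layer("GQ"))
  ds
}

#' Write a genotype dataset as VCF v4.2
#'
#' Emits GT plus any of PL/DP/GQ the dataset carries. Missing genotypes are
#' written `./.` with PL and GQ `.`.
#'
#' @param ds a `geno_data`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(ds, path) {
  n <- nrow(ds$samples); L <- nrow(ds$loci)
  fmt <- c("GT", if (!is.null(ds$pl)) "PL", if (!is.null(ds$depth)) "DP",
           if (!is.null(ds$gq)) "GQ")
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s>", unique(ds$loci$chrom)),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           if ("PL" %in% fmt) "##FORMAT=<ID=PL,Number=G,Type=Integer,Description=\"Phred-scaled genotype likelihoods\">",
           if ("DP" %in% fmt) "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           if ("GQ" %in% fmt) "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", ds$samples$id), collapse = "\t"))
  gt_str <- matrix("./.", n, L)
  gt_str[!is.na(ds$dosage) & ds$dosage == 0L] <- "0/0"
  gt_str[!is.na(ds$dosage) & ds$dosage == 1L] <- "0/1"
  gt_str[!is.na(ds$dosage) & ds$dosage == 2L] <- "1/1"
  cells <- gt_str
  if ("PL" %in% fmt) {
    pls <- matrix(".", n, L)
    ok <- !is.na(ds$pl[, , 1])
    pls[ok] <- paste(ds$pl[, , 1][ok], ds$pl[, , 2][ok], ds$pl[, , 3][ok],
                     sep = ",")
    cells <- matrix(paste(cells, pls, sep = ":"), n, L)
  }
  if ("DP" %in% fmt) {
    dps <- matrix(".", n, L)
    ok <- !is.na(ds$depth)
    dps[ok] <- as.character(ds$depth[ok])
    cells <- matrix(paste(cells, dps, sep = ":"), n, L)
  }
  if ("GQ" %in% fmt) {
    gqs <- matrix(".", n, L)
    ok <- !is.na(ds$gq)
    gqs[ok] <- as.character(ds$gq[ok])
    cells <- matrix(paste(cells, gqs, sep = ":"), n, L)
  }
  body <- vapply(seq_len(L), function(j) paste(
    c(ds$loci$chrom[j], ds$loci$pos[j], ".", ds$loci$ref[j], ds$loci$alt[j],
      ".", "PASS", ".", paste(fmt, collapse = ":"), cells[, j]),
    collapse = "\t"), "")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write / read beagle-style genotype-likelihood text
#'
#' Three header columns (`marker`, `allele1`, `allele2`) followed by three
#' linear-scale, normalised likelihood columns per sample. Only the GL layer
#' travels through this format.
#'
#' @param ds a `geno_data` with a PL layer.
#' @param path output (input) file.
#' @param metadata sample metadata table or TSV path (see [read_vcf()]).
#' @param digits decimal digits written.
#' @return `path` invisibly, or a [geno_data()] with dosages all-missing and
#'   the GL layer filled.
#' @export
write_beagle <- function(ds, path, digits = 6) {
  gl <- gl_linear(ds)
  n <- nrow(ds$samples); L <- nrow(ds$loci)
  allele_code <- function(b) match(b, c("A", "C", "G", "T")) - 1L
  out <- matrix("", L, 3 + 3 * n)
  out[, 1] <- paste(ds$loci$chrom, ds$loci$pos, sep = "_")
  out[, 2] <- allele_code(ds$loci$ref)
  out[, 3] <- allele_code(ds$loci$alt)
  for (i in seq_len(n)) {
    for (k in 1:3) {
      v <- gl[i, , k]
      v[is.na(v)] <- 1 / 3  # uninformative entry
      out[, 3 + 3 * (i - 1) + k] <- formatC(v, digits = digits, format = "f")
    }
  }
  hdr <- c("marker", "allele1", "allele2",
           rep(ds$samples$id, each = 3))
  utils::write.table(rbind(hdr, out), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_beagle
#' @export
read_beagle <- function(path, metadata) {
  meta <- if (is.data.frame(metadata)) metadata else
    utils::read.delim(metadata, stringsAsFactors = FALSE)
  raw <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  hdr <- as.character(raw[1, ])
  ids <- unique(hdr[-(1:3)])
  if (length(hdr) != 3 + 3 * length(ids))
    stop("malformed beagle file: expected 3 columns per sample")
  body <- raw[-1, , drop = FALSE]
  mk <- strsplit(body[, 1], "_", fixed = TRUE)
  bases <- c("A", "C", "G", "T")
  loci <- data.frame(
    chrom = vapply(mk, function(x) paste(x[-length(x)], collapse = "_"), ""),
    pos = as.numeric(vapply(mk, function(x) x[length(x)], "")),
    ref = bases[as.integer(body[, 2]) + 1L],
    alt = bases[as.integer(body[, 3]) + 1L])
  ord <- order(loci$chrom, loci$pos)
  loci <- loci[ord, ]
  missing_meta <- setdiff(ids, meta$id)
  if (length(missing_meta))
    stop("samples in beagle file absent from metadata: ",
         paste(missing_meta, collapse = ", "))
  samples <- meta[match(ids, meta$id), , drop = FALSE]
  n <- length(ids); L <- nrow(loci)
  gl <- array(NA_real_, c(n, L, 3))
  for (i in seq_len(n))
    for (k in 1:3)
      gl[i, , k] <- as.numeric(body[ord, 3 + 3 * (i - 1) + k])
  tot <- gl[, , 1] + gl[, , 2] + gl[, , 3]
  gl <- gl / as.vector(rep(tot, 3))
  # store as (real-valued) Phred with min 0 so gl_linear() round-trips
  pl <- -10 * log10(pmax(gl, 1e-300))
  mn <- pmin(pl[, , 1], pl[, , 2], pl[, , 3])
  pl <- pl - as.vector(rep(mn, 3))
  geno_data(loci, samples, matrix(NA_integer_, n, L), pl = pl)
}

#' Site filter configuration
#'
#' Holds the site/genotype retention thresholds. All inequalities are
#' applied strictly as worded: genotypes are kept when GQ is strictly above
#' `min_gq`; sites are kept when their missing fraction is strictly below
#' `max_missing_frac` and their minor allele frequency strictly above
#' `maf_min`.
#'
#' @param biallelic_only drop records whose REF/ALT are not single bases.
#' @param max_missing_frac sites with missing fraction `>=` this are dropped.
#' @param min_gq genotypes with GQ `<=` this are set missing (skipped when
#'   the dataset has no GQ layer or `min_gq` is `NA`).
#' @param maf_min sites with minor allele frequency `<=` this are dropped
#'   (`NA` to skip; MAF uses hard calls over non-missing samples).
#' @return A `filter_config` list.
#' @export
filter_config <- function(biallelic_only = TRUE, max_missing_frac = 0.25,
                          min_gq = 20, maf_min = NA) {
  stopifnot(max_missing_frac >= 0, max_missing_frac <= 1)
  structure(list(biallelic_only = biallelic_only,
                 max_missing_frac = max_missing_frac,
                 min_gq = min_gq, maf_min = maf_min),
            class = "filter_config")
}

#' Apply site and genotype filters
#'
#' Order of application: (1) drop non-biallelic records; (2) mask genotypes
#' whose GQ is not strictly above `min_gq`; (3) drop sites whose missing
#' fraction is not strictly below `max_missing_frac`; (4) drop sites whose
#' minor allele frequency is not strictly above `maf_min`. A per-step log of
#' record counts is attached as attribute `"filter_log"`.
#'
#' @param ds a `geno_data`.
#' @param cfg a [filter_config()].
#' @return A filtered `geno_data` (possibly with zero loci, with a warning).
#' @export
filter_sites <- function(ds, cfg = filter_config()) {
  stopifnot(inherits(cfg, "filter_config"))
  log <- data.frame(step = character(), kept = integer(), masked = integer())
  keep <- rep(TRUE, nrow(ds$loci))
  if (isTRUE(cfg$biallelic_only)) {
    keep <- nchar(ds$loci$ref) == 1L & nchar(ds$loci$alt) == 1L &
      ds$loci$ref %in% c("A", "C", "G", "T") &
      ds$loci$alt %in% c("A", "C", "G", "T")
    ds <- ds[, which(keep)]
    log <- rbind(log, data.frame(step = "biallelic", kept = sum(keep),
                                 masked = 0L))
  }
  if (!is.null(ds$gq) && !is.na(cfg$min_gq)) {
    mask <- !is.na(ds$gq) & ds$gq <= cfg$min_gq
    ds$dosage[mask] <- NA_integer_
    if (!is.null(ds$pl)) ds$pl[as.vector(rep(mask, 3))] <- NA_real_
    ds$gq[mask] <- NA_real_
    log <- rbind(log, data.frame(step = "gq_mask", kept = nrow(ds$loci),
                                 masked = sum(mask)))
  }
  miss_frac <- colMeans(is.na(ds$dosage))
  keep <- miss_frac < cfg$max_missing_frac
  ds <- ds[, which(keep)]
  log <- rbind(log, data.frame(step = "missingness", kept = sum(keep),
                               masked = 0L))
  if (!is.na(cfg$maf_min)) {
    p <- colMeans(ds$dosage, na.rm = TRUE) / 2
    maf <- pmin(p, 1 - p)
    keep <- !is.na(maf) & maf > cfg$maf_min
    ds <- ds[, which(keep)]
    log <- rbind(log, data.frame(step = "maf", kept = sum(keep), masked = 0L))
  }
  if (nrow(ds$loci) == 0L) warning("all sites removed by filters")
  attr(ds, "filter_log") <- log
  ds
}

#' Thin sites by genomic distance
#'
#' Greedy left-to-right pass per chromosome: keep the first site, then keep
#' each next site only if it is at least `min_gap_bp` from the last kept
#' site ("no closer than" semantics, so a gap exactly equal to `min_gap_bp`
#' is allowed).
#'
#' @param ds a `geno_data` with loci sorted by (chrom, pos).
#' @param min_gap_bp minimum allowed distance between adjacent kept sites.
#' @return A thinned `geno_data`.
#' @export
thin_by_distance <- function(ds, min_gap_bp = 10000) {
  keep <- logical(nrow(ds$loci))
  for (ch in unique(ds$loci$chrom)) {
    idx <- which(ds$loci$chrom == ch)
    last <- -Inf
    for (j in idx) {
      if (ds$loci$pos[j] - last >= min_gap_bp) {
        keep[j] <- TRUE
        last <- ds$loci$pos[j]
      }
    }
  }
  ds[, which(keep)]
}

#' Read / write LD-cluster definitions
#'
#' TSV with columns `id`, `chrom`, `start`, `end` (1-based inclusive bp).
#'
#' @param path TSV file.
#' @return data.frame of cluster definitions, or `path` invisibly.
#' @export
read_clusters <- function(path) {
  cl <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "chrom", "start", "end")
  if (!all(need %in% names(cl)))
    stop("cluster table must have columns: ", paste(need, collapse = ", "))
  cl$id <- as.character(cl$id)
  cl
}

#' @rdname read_clusters
#' @param clusters data.frame with columns `id`, `chrom`, `start`, `end`.
#' @export
write_clusters <- function(clusters, path) {
  utils::write.table(clusters[c("id", "chrom", "start", "end")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a complete simulated fixture bundle
#'
#' Emits, under `out_dir`: `sim.vcf` (GT:PL:DP:GQ), `sim.beagle.tsv`,
#' `metadata.tsv`, `clusters.tsv` (planted cluster bounds), `truth_roh.bed`
#' (0-based half-open planted tracts) and `truth_karyotype.tsv`.
#' A VCF round trip reproduces dosages and PLs exactly.
#'
#' @param ds a `geno_data` with PL/DP/GQ layers.
#' @param truth matching `sim_truth`.
#' @param out_dir output directory (created if needed).
#' @return Named character vector of the written paths.
#' @export
write_fixture_bundle <- function(ds, truth, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(vcf = file.path(out_dir, "sim.vcf"),
             beagle = file.path(out_dir, "sim.beagle.tsv"),
             metadata = file.path(out_dir, "metadata.tsv"),
             clusters = file.path(out_dir, "clusters.tsv"),
             roh_bed = file.path(out_dir, "truth_roh.bed"),
             karyotype = file.path(out_dir, "truth_karyotype.tsv"))
  write_vcf(ds, paths[["vcf"]])
  write_beagle(ds, paths[["beagle"]])
  utils::write.table(ds$samples, paths[["metadata"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cl <- do.call(rbind, lapply(truth$clusters, function(x) data.frame(
    id = x$id, chrom = x$chrom, start = x$start, end = x$end)))
  if (is.null(cl)) cl <- data.frame(id = character(), chrom = character(),
                                    start = numeric(), end = numeric())
  write_clusters(cl, paths[["clusters"]])
  bed <- truth$tracts
  utils::write.table(
    data.frame(bed$chrom, bed$start - 1L, bed$end, bed$sample),
    paths[["roh_bed"]], sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  ka <- truth$karyotype
  kd <- if (is.null(ka)) data.frame(sample = rownames(truth$true_dosage))
  else data.frame(sample = rownames(ka), as.data.frame(ka))
  utils::write.table(kd, paths[["karyotype"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths
}
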