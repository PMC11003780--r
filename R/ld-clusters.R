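#' Pairwise composite LD (r-squared) between loci
#'
#' Squared Pearson correlation of genotype dosages over pairwise-complete
#' samples (the composite measure appropriate for unphased data). `NA` is
#' returned when fewer than two complete pairs exist or when either locus is
#' monomorphic among the complete set.
#'
#' @param ds a `geno_data`.
#' @param locusA,locusB locus ids (`chrom:pos`) or column indices.
#' @param samples sample ids used (default: all).
#' @return r-squared value (or `NA`).
#' @export
ld_r2 <- function(ds, locusA, locusB, samples = ds$samples$id) {
  idx <- match(samples, ds$samples$id)
  j <- vapply(list(locusA, locusB), function(l)
    if (is.character(l)) match(l, locus_ids(ds$loci)) else as.integer(l),
    integer(1))
  if (anyNA(j)) stop("unknown locus")
  x <- ds$dosage[idx, j[1]]; y <- ds$dosage[idx, j[2]]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2) return(NA_real_)
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) return(NA_real_)
  stats::cor(x[ok], y[ok])^2
}

#' LD matrix over a set of loci
#'
#' @param ds a `geno_data`.
#' @param loci locus ids or indices (default: all loci).
#' @param samples sample ids used (default: all).
#' @return An `ld_matrix`: list with the locus table and the symmetric
#'   r-squared matrix (unit diagonal; `NA` where undefined).
#' @export
ld_matrix <- function(ds, loci = seq_len(nrow(ds$loci)),
                      samples = ds$samples$id) {
  j <- if (is.character(loci)) match(loci, locus_ids(ds$loci)) else
    as.integer(loci)
  if (anyNA(j)) stop("unknown locus")
  j <- sort(j)
  idx <- match(samples, ds$samples$id)
  d <- ds$dosage[idx, j, drop = FALSE]
  r2 <- suppressWarnings(stats::cor(d, use = "pairwise.complete.obs"))^2
  diag(r2) <- 1
  structure(list(loci = ds$loci[j, , drop = FALSE], r2 = r2),
            class = "ld_matrix")
}

#' Connected components of the LD network
#'
#' Builds a graph with an edge wherever `r2 >= threshold` (undefined values
#' carry no edge) and returns its connected components, sorted by size
#' descending with ties broken by the leftmost member position.
#'
#' @param ldm an [ld_matrix()].
#' @param threshold edge threshold in (0, 1].
#' @return List of integer vectors indexing `ldm$loci`.
#' @export
ld_network_components <- function(ldm, threshold = 0.5) {
  stopifnot(threshold > 0, threshold <= 1)
  adj <- !is.na(ldm$r2) & ldm$r2 >= threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  groups <- split(seq_len(nrow(adj)), comp$membership)
  sizes <- lengths(groups)
  leftmost <- vapply(groups, function(g) min(ldm$loci$pos[g]), numeric(1))
  groups <- groups[order(-sizes, leftmost)]
  names(groups) <- NULL
  lapply(groups, unname)
}

#' LD-cluster object
#'
#' @param id cluster label.
#' @param chrom chromosome.
#' @param members locus ids (`chrom:pos`) in genomic order.
#' @param positions bp positions of the members.
#' @param provenance one of `"input"`, `"split"`, `"refined"`.
#' @return An `ld_cluster` list with bounding `start`/`end`.
#' @export
ld_cluster <- function(id, chrom, members, positions,
                       provenance = "input") {
  o <- order(positions)
  structure(list(id = as.character(id), chrom = chrom,
                 members = members[o], positions = positions[o],
                 start = min(positions), end = max(positions),
                 provenance = provenance),
            class = "ld_cluster")
}

#' @export
print.ld_cluster <- function(x, ...) {
  cat(sprintf("LD cluster %s (%s): %d loci, %s:%d-%d\n", x$id,
              x$provenance, length(x$members), x$chrom, x$start, x$end))
  invisible(x)
}

# build ld_cluster objects for ds loci inside the rows of a cluster table
clusters_from_table <- function(ds, cluster_table) {
  ids <- locus_ids(ds$loci)
  out <- list()
  for (i in seq_len(nrow(cluster_table))) {
    row <- cluster_table[i, ]
    j <- which(ds$loci$chrom == row$chrom & ds$loci$pos >= row$start &
                 ds$loci$pos <= row$end)
    if (length(j) == 0) next
    out[[length(out) + 1L]] <- ld_cluster(row$id, row$chrom, ids[j],
                                          ds$loci$pos[j])
  }
  out
}

#' Split a cluster spanning non-contiguous regions
#'
#' Cuts the (position-ordered) member list wherever the gap between
#' adjacent members exceeds `max_gap_bp`; children are labelled with
#' suffixes `a`, `b`, `c`, ... in genomic order. A cluster with no large
#' gap is returned unchanged (single child, no suffix).
#'
#' @param cluster an [ld_cluster()].
#' @param max_gap_bp gap threshold (strictly-above splits).
#' @return List of `ld_cluster` objects.
#' @export
split_noncontiguous <- function(cluster, max_gap_bp = 1e6) {
  gaps <- diff(cluster$positions)
  cut <- which(gaps > max_gap_bp)
  if (length(cut) == 0) return(list(cluster))
  bounds <- c(0, cut, length(cluster$positions))
  out <- list()
  for (k in seq_len(length(bounds) - 1)) {
    sel <- (bounds[k] + 1):bounds[k + 1]
    out[[k]] <- ld_cluster(paste0(cluster$id, letters[k]), cluster$chrom,
                           cluster$members[sel], cluster$positions[sel],
                           provenance = "split")
  }
  out
}

#' Refine a cluster to its most habitat-parallel LD component
#'
#' Builds the within-cluster LD network among the reference samples,
#' scores each connected component by the mean per-locus absolute
#' marine-freshwater allele-frequency difference `|p_F - p_M|` over the
#' reference samples, and returns the best-scoring component as the refined
#' cluster (ties: larger component, then leftmost). The winning score is
#' attached as attribute `"parallel_score"`.
#'
#' @param ds a `geno_data`.
#' @param cluster an [ld_cluster()] with at least two member loci.
#' @param threshold LD network edge threshold.
#' @param reference_samples sample ids defining the training domain; both
#'   habitats must be represented among them.
#' @return A refined `ld_cluster`.
#' @export
refine_cluster <- function(ds, cluster, threshold = 0.5,
                           reference_samples = ds$samples$id) {
  if (length(cluster$members) < 2) stop("cluster has fewer than two loci")
  ridx <- match(reference_samples, ds$samples$id)
  if (anyNA(ridx)) stop("unknown reference sample id")
  hab <- ds$samples$habitat[ridx]
  if (!all(c("marine", "freshwater") %in% hab))
    stop("both habitats must be represented among reference samples")
  ldm <- ld_matrix(ds, cluster$members, samples = reference_samples)
  comps <- ld_network_components(ldm, threshold)
  sub <- ds[reference_samples, cluster$members]
  pF <- colMeans(sub$dosage[sub$samples$habitat == "freshwater", ,
                            drop = FALSE], na.rm = TRUE) / 2
  pM <- colMeans(sub$dosage[sub$samples$habitat == "marine", ,
                            drop = FALSE], na.rm = TRUE) / 2
  dp <- abs(pF - pM)
  # ld_matrix sorts loci genomically; map back
  ord_ids <- locus_ids(ldm$loci)
  score <- vapply(comps, function(g) mean(dp[match(ord_ids[g],
                                                   colnames(sub$dosage))]),
                  numeric(1))
  if (all(is.na(score))) stop("no component has a defined parallelism score")
  best <- order(-score, -lengths(comps),
                vapply(comps, function(g) min(ldm$loci$pos[g]), numeric(1)))[1]
  sel <- comps[[best]]
  out <- ld_cluster(cluster$id, cluster$chrom, ord_ids[sel],
                    ldm$loci$pos[sel], provenance = "refined")
  attr(out, "parallel_score") <- score[best]
  attr(out, "component_scores") <- score
  out
}
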