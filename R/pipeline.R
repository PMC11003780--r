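#' Assemble a pipeline configuration
#'
#' Either point at input files (`vcf`, `metadata`, `clusters`) or embed a
#' `simulate` block (arguments to [sim_config()], with populations and
#' clusters given as plain lists). Exactly one of the two must be present.
#' Thresholds default to the package-wide defaults. Configurations can also
#' be read from a YAML file with the same structure.
#'
#' @param x a named list or a YAML file path.
#' @return A validated `pipeline_config`.
#' @export
pipeline_config <- function(x) {
  if (is.character(x) && length(x) == 1) x <- yaml::read_yaml(x)
  stopifnot(is.list(x))
  has_files <- !is.null(x$vcf)
  has_sim <- !is.null(x$simulate)
  if (has_files == has_sim)
    stop("config needs exactly one of: input paths (vcf/metadata), simulate block")
  if (has_files) {
    for (f in c(x$vcf, x$metadata, x$clusters))
      if (!file.exists(f)) stop("input file not found: ", f)
  }
  defaults <- list(
    filter = list(max_missing_frac = 0.25, min_gq = 20, maf_min = 0.01),
    roh = list(az_entry_rate = 5e-9, az_exit_rate = 5e-7,
               az_het_emission = 0.01, min_sites = 10),
    thin_gap_bp = 10000, r2_threshold = 0.5, split_gap_bp = 1e6,
    accuracy_gate = 0.75, pca_method = "both", refine = TRUE,
    seed = 1)
  for (nm in names(defaults))
    if (is.null(x[[nm]])) x[[nm]] <- defaults[[nm]]
  structure(x, class = "pipeline_config")
}

sim_config_from_block <- function(block) {
  pops <- lapply(block$populations, function(p) do.call(pop_spec, p))
  cls <- lapply(block$clusters, function(cl) do.call(cluster_spec, cl))
  args <- block[setdiff(names(block), c("populations", "clusters"))]
  if (!is.null(args$genome)) args$genome <- unlist(args$genome)
  if (!is.null(args$ancestral_beta))
    args$ancestral_beta <- unlist(args$ancestral_beta)
  do.call(sim_config, c(list(populations = pops, clusters = cls), args))
}

#' Run the full analysis pipeline
#'
#' Executes, in order: data acquisition (simulation or VCF input), site
#' filtering, genetic diversity (per-population SFS and pi, per-sample
#' heterozygosity, ROH calling and F_ROH summaries), population structure
#' (distance thinning, pairwise F_ST, genome-wide PCA), LD-cluster
#' preparation, parallelism scoring (PFG and PI, for the configured PCA
#' method or both), and the regional statistics. Every intermediate table
#' is written under `out_dir` so each stage is independently auditable, and
#' a run log records seed, thresholds and per-stage record counts. The run
#' is deterministic given the configured seed.
#'
#' @param config a [pipeline_config()] (or list / YAML path coercible to
#'   one).
#' @param out_dir output directory.
#' @return A `pipeline_result`: list of the key tables plus `paths` to all
#'   written artifacts.
#' @export
run_pipeline <- function(config, out_dir) {
  config <- if (inherits(config, "pipeline_config")) config else
    pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c("fwparallel pipeline run",
                 paste0("package_version: ",
                        as.character(utils::packageVersion("fwparallel"))),
                 paste0("seed: ", config$seed))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  paths <- character()
  emit <- function(tag, file, tab) {
    p <- file.path(out_dir, file)
    utils::write.table(tab, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths[[tag]] <<- p
    log_lines <<- c(log_lines, sprintf("%s: %d records", file,
                                       if (is.data.frame(tab) ||
                                           is.matrix(tab)) nrow(tab)
                                       else length(tab)))
    p
  }

  # --- data --------------------------------------------------------------
  truth <- NULL
  if (!is.null(config$simulate)) {
    sim <- stage("simulate", {
      sc <- sim_config_from_block(config$simulate)
      sc$seed <- as.integer(config$seed)
      simulate_dataset(sc)
    })
    ds <- sim$data; truth <- sim$truth
    cluster_tab <- do.call(rbind, lapply(truth$clusters, function(x)
      data.frame(id = x$id, chrom = x$chrom, start = x$start, end = x$end)))
    p <- file.path(out_dir, "input.vcf")
    write_vcf(ds, p); paths[["input_vcf"]] <- p
  } else {
    ds <- stage("read", read_vcf(config$vcf, config$metadata))
    cluster_tab <- read_clusters(config$clusters)
  }
  log_lines <- c(log_lines, sprintf("input: %d samples x %d loci",
                                    nrow(ds$samples), nrow(ds$loci)))

  # --- filtering ---------------------------------------------------------
  fl <- config$filter
  ds_f <- stage("filter", filter_sites(ds, filter_config(
    max_missing_frac = fl$max_missing_frac, min_gq = fl$min_gq,
    maf_min = fl$maf_min)))
  flog <- attr(ds_f, "filter_log")
  log_lines <- c(log_lines, sprintf("filter %s: %d kept (%d masked)",
                                    flog$step, flog$kept, flog$masked))
  p <- file.path(out_dir, "filtered.vcf")
  write_vcf(ds_f, p); paths[["filtered_vcf"]] <- p

  # --- diversity ---------------------------------------------------------
  pops <- unique(ds_f$samples$population)
  div <- stage("diversity", {
    pi_tab <- do.call(rbind, lapply(pops, function(pp) {
      sfs <- folded_sfs(ds_f, pp)
      data.frame(population = pp, n_chromosomes = sfs$n, n_sites = sfs$L,
                 pi = pi_from_sfs(sfs))
    }))
    het <- observed_heterozygosity(ds_f)
    het_tab <- data.frame(sample = names(het),
                          population = ds_f$samples$population, h_o = het)
    rp <- do.call(roh_params, config$roh)
    segs <- do.call(rbind, lapply(ds_f$samples$id, function(s)
      call_roh(ds_f, s, rp)))
    rs <- roh_summary(segs, ds = ds_f)
    rs$population <- ds_f$samples$population[match(rs$sample,
                                                   ds_f$samples$id)]
    list(pi = pi_tab, het = het_tab, segs = segs, roh = rs)
  })
  emit("pi", "pi_by_population.tsv", div$pi)
  emit("het", "heterozygosity.tsv", div$het)
  emit("roh_summary", "roh_summary.tsv", div$roh)
  bed <- div$segs
  p <- file.path(out_dir, "roh_segments.bed")
  utils::write.table(
    if (nrow(bed)) data.frame(bed$chrom, bed$start - 1L, bed$end, bed$sample)
    else data.frame(character(), integer(), integer(), character()),
    p, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  paths[["roh_bed"]] <- p
  log_lines <- c(log_lines, sprintf("roh_segments.bed: %d records",
                                    nrow(bed)))

  # --- population structure ---------------------------------------------
  ds_thin <- stage("thin", thin_by_distance(ds_f, config$thin_gap_bp))
  log_lines <- c(log_lines, sprintf("thinned: %d loci", nrow(ds_thin$loci)))
  fst <- stage("fst", fst_matrix(ds_thin))
  emit("fst", "fst_matrix.tsv",
       data.frame(population = rownames(fst), as.data.frame(unclass(fst))))
  pca <- stage("pca", pca_fit(ds_f, source = if (is.null(ds_f$pl))
    "dosage" else "gl", maf_min = 0.01))
  emit("pca", "pca_scores.tsv",
       data.frame(sample = rownames(pca$scores),
                  population = ds_f$samples$population,
                  pca$scores[, seq_len(min(4, ncol(pca$scores))),
                             drop = FALSE]))

  # --- clusters & parallelism -------------------------------------------
  if (is.null(cluster_tab) || nrow(cluster_tab) == 0)
    stop("pipeline stage 'clusters' failed: no LD clusters defined")
  emit("clusters", "clusters.tsv", cluster_tab)
  tr_block <- config$training
  training <- stage("training_spec", training_spec(
    marine = unlist(tr_block$marine), freshwater = unlist(tr_block$freshwater)))
  methods <- if (identical(config$pca_method, "both"))
    c("gl", "projected") else config$pca_method
  fits <- list()
  for (m in methods) {
    fit <- stage(paste0("parallelism_", m), fit_parallelism(
      ds_f, cluster_tab, training, method = m, refine = config$refine,
      split_gap_bp = config$split_gap_bp,
      r2_threshold = config$r2_threshold,
      accuracy_gate = config$accuracy_gate))
    fits[[m]] <- fit
    ret <- Filter(function(a) isTRUE(a$retained), fit$assignments)
    pfg <- do.call(cbind, lapply(ret, `[[`, "pfg"))
    colnames(pfg) <- vapply(ret, `[[`, "", "cluster")
    emit(paste0("pfg_", m), paste0("pfg_matrix_", m, ".tsv"),
         data.frame(sample = rownames(pfg), pfg, check.names = FALSE))
    emit(paste0("pi_", m), paste0("parallelism_index_", m, ".tsv"),
         as.data.frame(fit$pi))
  }

  # --- regional statistics ----------------------------------------------
  stats_out <- stage("stats", {
    meta <- ds_f$samples[!duplicated(ds_f$samples$population),
                         c("population", "region", "habitat", "latitude")]
    ptab <- merge(div$pi, meta, by = "population")
    froh_pop <- stats::aggregate(f_roh ~ population, div$roh, mean)
    names(froh_pop)[2] <- "froh"
    ftab <- merge(froh_pop, meta, by = "population")
    # each comparison needs its own minimum design; a run with too few
    # populations or regions skips that table rather than aborting
    opt <- function(expr) tryCatch(expr, error = function(e) NULL)
    lm_fit <- opt(lm_diversity(ptab))
    glm_fit <- if (all(ftab$froh > 0)) opt(glm_froh(ftab)) else NULL
    an_pi <- opt(one_way_anova(ptab$pi, ptab$region))
    tk_pi <- opt(tukey(ptab$pi, ptab$region))
    icc <- opt(icc_predictors(ptab$latitude, ptab$habitat))
    pi_fit <- fits[[1]]$pi
    an_PI <- opt(one_way_anova(pi_fit$pi, pi_fit$region))
    tk_PI <- opt(tukey(pi_fit$pi, pi_fit$region))
    list(lm = lm_fit, glm = glm_fit, anova_pi = an_pi, tukey_pi = tk_pi,
         icc = icc, anova_PI = an_PI, tukey_PI = tk_PI)
  })
  if (!is.null(stats_out$lm))
    emit("lm", "lm_diversity.tsv", stats_out$lm$coefficients)
  if (!is.null(stats_out$glm))
    emit("glm", "glm_froh.tsv", stats_out$glm$coefficients)
  an_tab <- do.call(rbind, lapply(
    c(pi = "anova_pi", PI = "anova_PI"), function(nm) {
      a <- stats_out[[nm]]
      if (is.null(a)) return(NULL)
      data.frame(test = paste0(nm, "_regions"), F = a$F, df1 = a$df1,
                 df2 = a$df2, p = a$p)
    }))
  if (!is.null(an_tab)) emit("anova", "anova_tests.tsv", an_tab)
  if (!is.null(stats_out$tukey_PI))
    emit("tukey", "tukey_PI.tsv", stats_out$tukey_PI)
  log_lines <- c(log_lines,
                 sprintf("icc_predictors: %.4f",
                         if (is.null(stats_out$icc)) NA else stats_out$icc),
                 sprintf("thresholds: gq>%s missing<%s maf>%s gap>=%s r2>=%s gate>%s",
                         fl$min_gq, fl$max_missing_frac, fl$maf_min,
                         config$thin_gap_bp, config$r2_threshold,
                         config$accuracy_gate))
  log_path <- file.path(out_dir, "run_log.txt")
  writeLines(log_lines, log_path)
  paths[["run_log"]] <- log_path
  structure(list(data = ds_f, truth = truth, diversity = div, fst = fst,
                 pca = pca, fits = fits, stats = stats_out,
                 paths = unlist(paths)),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("fwparallel pipeline result:", length(x$paths), "artifacts\n")
  for (p in x$paths) cat(" ", p, "\n")
  invisible(x)
}
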