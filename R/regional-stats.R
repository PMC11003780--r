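#' Linear model of nucleotide diversity on latitude and habitat
#'
#' Ordinary least squares of per-population pi on latitude and habitat,
#' with habitat coded marine = 1 (so a positive habitat coefficient means
#' higher diversity in marine populations; the coding is recorded in the
#' result). Sequential (type-I) F tests are reported per predictor in the
#' order latitude then habitat, together with the coefficient table and
#' adjusted R-squared.
#'
#' @param pop_table data.frame with columns `pi`, `latitude`, `habitat`
#'   (and optionally `population`).
#' @return A `fit_result` list: `coefficients` (estimate, se, statistic,
#'   p), `anova` (term, F, df1, df2, p), `adj_r_squared`, `family`,
#'   `habitat_coding`.
#' @export
lm_diversity <- function(pop_table) {
  check_pop_table(pop_table, "pi")
  tab <- pop_table
  tab$habitat_marine <- as.integer(tab$habitat == "marine")
  fit <- stats::lm(pi ~ latitude + habitat_marine, data = tab)
  if (any(is.na(stats::coef(fit)))) stop("rank-deficient design")
  constant <- stats::var(tab$pi) < .Machine$double.eps
  s <- suppressWarnings(summary(fit))
  an <- suppressWarnings(stats::anova(fit))
  fit_result(
    coefficients = coef_table(s),
    anova = anova_table(an),
    adj_r_squared = if (constant) 0 else s$adj.r.squared,
    family = "gaussian_identity",
    habitat_coding = "marine = 1, freshwater = 0",
    model = fit)
}

#' Gamma log-link model of F_ROH on latitude and habitat
#'
#' Gamma GLM with log link fitted by iteratively reweighted least squares
#' (relative tolerance 1e-8, at most 50 iterations); dispersion is the
#' Pearson estimate. Habitat is coded marine = 1. Sequential F tests use
#' the Pearson dispersion. An adjusted deviance-based pseudo R-squared is
#' reported.
#'
#' @param pop_table data.frame with columns `froh` (strictly positive),
#'   `latitude`, `habitat` (and optionally `population`).
#' @return A `fit_result` (family `gamma_log`, with `dispersion`).
#' @export
glm_froh <- function(pop_table) {
  check_pop_table(pop_table, "froh")
  tab <- pop_table
  bad <- which(!(tab$froh > 0))
  if (length(bad)) {
    who <- if ("population" %in% names(tab)) tab$population[bad] else bad
    stop("non-positive F_ROH response for: ", paste(who, collapse = ", "))
  }
  tab$habitat_marine <- as.integer(tab$habitat == "marine")
  fit <- stats::glm(froh ~ latitude + habitat_marine, data = tab,
                    family = stats::Gamma(link = "log"),
                    control = stats::glm.control(epsilon = 1e-8, maxit = 50))
  if (!fit$converged) stop("IRLS did not converge in 50 iterations")
  disp <- sum(stats::residuals(fit, type = "pearson")^2) / fit$df.residual
  s <- summary(fit, dispersion = disp)
  an <- stats::anova(fit, test = "F")  # uses the Pearson dispersion
  dev_r2 <- 1 - fit$deviance / fit$null.deviance
  n <- nrow(tab); p <- length(stats::coef(fit)) - 1
  fit_result(
    coefficients = coef_table(s),
    anova = anova_table(an),
    adj_r_squared = 1 - (1 - dev_r2) * (n - 1) / (n - p - 1),
    family = "gamma_log",
    habitat_coding = "marine = 1, freshwater = 0",
    dispersion = disp,
    model = fit)
}

check_pop_table <- function(tab, response) {
  need <- c(response, "latitude", "habitat")
  if (!all(need %in% names(tab)))
    stop("table must have columns: ", paste(need, collapse = ", "))
  if (nrow(tab) < 3) stop("need at least three populations")
  if (!all(c("marine", "freshwater") %in% tab$habitat))
    stop("both habitats must be present")
  invisible(tab)
}

coef_table <- function(s) {
  ct <- stats::coef(s)
  data.frame(term = rownames(ct), estimate = ct[, 1], se = ct[, 2],
             statistic = ct[, 3], p = ct[, 4], row.names = NULL)
}

anova_table <- function(an) {
  an <- as.data.frame(an)
  fcol <- grep("^F", names(an), value = TRUE)[1]
  pcol <- grep("^Pr", names(an), value = TRUE)[1]
  rows <- rownames(an) != "Residuals" & !is.na(an[[fcol]])
  df2 <- if ("Residuals" %in% rownames(an))
    an["Residuals", "Df"] else utils::tail(an$`Resid. Df`, 1)
  data.frame(term = rownames(an)[rows], F = an[[fcol]][rows],
             df1 = an$Df[rows], df2 = rep(df2, sum(rows)),
             p = an[[pcol]][rows], row.names = NULL)
}

fit_result <- function(...) structure(list(...), class = "fit_result")

#' @export
print.fit_result <- function(x, digits = 4, ...) {
  cat("Model family:", x$family, " (habitat coding:", x$habitat_coding,
      ")\n")
  co <- x$coefficients
  co[-1] <- lapply(co[-1], signif, digits)
  print(co, row.names = FALSE)
  cat("\nSequential (type-I) tests:\n")
  an <- x$anova
  an[-1] <- lapply(an[-1], signif, digits)
  print(an, row.names = FALSE)
  cat(sprintf("\nAdjusted R-squared: %.4f\n", x$adj_r_squared))
  invisible(x)
}

#' One-way ANOVA with small-group removal
#'
#' Groups with fewer than two observations are removed before the standard
#' between/within decomposition.
#'
#' @param values numeric response.
#' @param groups group labels.
#' @return List with `F`, `df1`, `df2`, `p`, `ms_between`, `ms_within`,
#'   `groups_used`, `removed`.
#' @export
one_way_anova <- function(values, groups) {
  groups <- as.character(groups)
  tab <- table(groups)
  keep <- names(tab)[tab >= 2]
  removed <- setdiff(names(tab), keep)
  sel <- groups %in% keep
  values <- values[sel]; groups <- factor(groups[sel])
  if (nlevels(groups) < 2) stop("fewer than two eligible groups")
  an <- stats::anova(stats::lm(values ~ groups))
  list(F = an$`F value`[1], df1 = an$Df[1], df2 = an$Df[2],
       p = an$`Pr(>F)`[1], ms_between = an$`Mean Sq`[1],
       ms_within = an$`Mean Sq`[2], groups_used = levels(groups),
       removed = removed)
}

#' Tukey post-hoc pairwise comparisons
#'
#' Studentized-range tests on the one-way ANOVA mean squares. The `kramer`
#' variant applies the unequal-sample-size correction
#' `SE = sqrt(MSW/2 (1/n_i + 1/n_j))` per pair; the `hsd` variant uses the
#' harmonic mean group size for every pair. The two coincide at equal n.
#'
#' @inheritParams one_way_anova
#' @param variant `"kramer"` (default) or `"hsd"`.
#' @return data.frame with one row per pair: `diff`, `se`, `q`, `p_adj`.
#' @export
tukey <- function(values, groups, variant = c("kramer", "hsd")) {
  variant <- match.arg(variant)
  an <- one_way_anova(values, groups)
  groups <- as.character(groups)
  sel <- groups %in% an$groups_used
  values <- values[sel]; groups <- groups[sel]
  means <- tapply(values, groups, mean)
  ns <- tapply(values, groups, length)
  k <- length(means)
  n_h <- k / sum(1 / ns)
  out <- list()
  lv <- names(means)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    se <- if (variant == "kramer")
      sqrt(an$ms_within / 2 * (1 / ns[i] + 1 / ns[j]))
    else sqrt(an$ms_within / n_h)
    q <- abs(means[i] - means[j]) / se
    out[[length(out) + 1L]] <- data.frame(
      pair = paste(lv[j], lv[i], sep = "-"),
      diff = unname(means[j] - means[i]), se = unname(se), q = unname(q),
      p_adj = stats::ptukey(q, k, an$df2, lower.tail = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Intraclass correlation of latitude within habitat groups
#'
#' ICC(1) from the one-way ANOVA of latitude grouped by habitat:
#' `(MSB - MSW) / (MSB + (kbar - 1) MSW)` with `kbar` the average group
#' size. Used as a collinearity diagnostic between the latitude and habitat
#' predictors; values below 0.5 indicate no strong correlation. Negative
#' values are reported as computed. Note this use of ICC on a predictor
#' pair is a diagnostic convention, not a variance-components estimate.
#'
#' @param latitude numeric.
#' @param habitat group labels (both habitats required).
#' @return ICC value.
#' @export
icc_predictors <- function(latitude, habitat) {
  habitat <- factor(habitat)
  if (nlevels(habitat) < 2) stop("need at least two habitat groups")
  an <- stats::anova(stats::lm(latitude ~ habitat))
  msb <- an$`Mean Sq`[1]; msw <- an$`Mean Sq`[2]
  kbar <- mean(table(habitat))
  (msb - msw) / (msb + (kbar - 1) * msw)
}

#' Gene-swamping condition
#'
#' In a two-allele model with antagonistic environmental effects, migration
#' is expected to swamp local selection when `m/s > alpha/|1 - alpha|`.
#'
#' @param m migration rate (>= 0).
#' @param s selection coefficient (> 0).
#' @param alpha antagonistic environmental effect (>= 0, != 1).
#' @return List with `threshold` (`alpha/|1-alpha|`), `ratio` (`m/s`) and
#'   logical `swamping`.
#' @export
swamping_expected <- function(m, s, alpha) {
  if (s <= 0) stop("selection coefficient s must be positive")
  if (m < 0) stop("migration rate m must be non-negative")
  if (alpha < 0) stop("alpha must be non-negative")
  if (alpha == 1) stop("threshold undefined at alpha = 1")
  threshold <- alpha / abs(1 - alpha)
  list(threshold = threshold, ratio = m / s, swamping = m / s > threshold)
}
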