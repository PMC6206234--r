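# critical value used throughout for 95% intervals; full-precision normal
# quantile, not the rounded 1.96
Z95 <- 1.959964

or_result <- function(label, or, se, counts, p_chi2 = NA_real_) {
  structure(list(label = label,
                 or_estimate = or,
                 ci_low = exp(log(or) - Z95 * se),
                 ci_high = exp(log(or) + Z95 * se),
                 se_log_or = se,
                 p_value = 2 * stats::pnorm(-abs(log(or) / se)),
                 p_chi2 = p_chi2,
                 counts_used = counts,
                 estimable = TRUE),
            class = "or_result")
}

inestimable_result <- function(label, counts) {
  structure(list(label = label, or_estimate = NA_real_, ci_low = NA_real_,
                 ci_high = NA_real_, se_log_or = NA_real_,
                 p_value = NA_real_, p_chi2 = NA_real_,
                 counts_used = counts, estimable = FALSE),
            class = "or_result")
}

#' @export
print.or_result <- function(x, ...) {
  if (!x$estimable) {
    cat(sprintf("<or_result> %s: inestimable (zero cell)\n", x$label))
  } else {
    cat(sprintf("<or_result> %s: OR %.2f (%.2f-%.2f), p = %.4g\n",
                x$label, x$or_estimate, x$ci_low, x$ci_high, x$p_value))
  }
  invisible(x)
}

#' Odds ratio for a 2x2 table with Woolf confidence interval
#'
#' `OR = (a d)/(b c)` with `SE(log OR) = sqrt(1/a + 1/b + 1/c + 1/d)`
#' (Woolf), a 95% CI `exp(log OR +/- 1.959964 SE)` and a two-sided Wald
#' p-value. A zero cell yields an inestimable result unless the
#' Haldane-Anscombe +0.5 correction is requested.
#'
#' @param a,b,c,d Exposed cases, unexposed cases, exposed controls,
#'   unexposed controls.
#' @param label Label carried into the result.
#' @param haldane Add 0.5 to every cell when any cell is zero.
#' @return An `or_result`.
#' @export
two_by_two_or <- function(a, b, c, d, label = "2x2", haldane = FALSE) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  cells <- c(a = unname(a), b = unname(b), c = unname(c), d = unname(d))
  if (any(cells == 0)) {
    if (!haldane) return(inestimable_result(label, cells))
    cells <- cells + 0.5
  }
  or <- (cells["a"] * cells["d"]) / (cells["b"] * cells["c"])
  se <- sqrt(sum(1 / cells))
  or_result(label, unname(or), unname(se), c(a = a, b = b, c = c, d = d))
}

#' Pearson chi-square test for an r x k count table
#'
#' Classical Pearson statistic with `df = (r-1)(k-1)`, no continuity
#' correction; cells whose expected count is zero contribute zero.
#'
#' @param tab Non-negative count matrix with positive row and column sums.
#' @return List with `chi2`, `df`, `p_value`.
#' @export
pearson_chi2 <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) stop("counts must be non-negative")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("degenerate table: zero row or column margin")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  cells <- ifelse(expected > 0, (tab - expected)^2 / expected, 0)
  chi2 <- sum(cells)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  list(chi2 = chi2, df = df,
       p_value = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Maximum-likelihood logistic regression
#'
#' Binomial IRLS fit (via `stats::glm.fit`) accepting replicate weights,
#' so grouped count data and row-expanded individual data give identical
#' estimates. The covariance matrix is the inverse observed information.
#'
#' @param x Design matrix (without intercept column).
#' @param y 0/1 case indicator.
#' @param weights Replicate counts (default 1 per row).
#' @param add_intercept Prepend an intercept column (default TRUE).
#' @return A list of class `logistic_fit`: `coefficients`, `vcov`,
#'   `log_likelihood`, `converged`, `iterations`.
#' @export
fit_logistic <- function(x, y, weights = NULL, add_intercept = TRUE) {
  x <- as.matrix(x)
  if (is.null(colnames(x)) && ncol(x) > 0)
    colnames(x) <- paste0("x", seq_len(ncol(x)))
  if (add_intercept)
    x <- cbind("(Intercept)" = 1, x)
  if (is.null(weights)) weights <- rep(1, length(y))
  keep <- weights > 0
  x <- x[keep, , drop = FALSE]; y <- y[keep]; w <- weights[keep]
  if (qr(x)$rank < ncol(x)) stop("design matrix not full rank")
  if (!any(y[w > 0] == 1) || !any(y[w > 0] == 0))
    stop("need at least one case and one control")
  fit <- suppressWarnings(
    stats::glm.fit(x, y, weights = w, family = stats::binomial(),
                   control = list(epsilon = 1e-12, maxit = 100)))
  beta <- fit$coefficients
  if (!fit$converged) stop("logistic fit did not converge in 100 iterations")
  if (any(abs(beta) > 15))
    stop("apparent complete separation: |coefficient| > 15")
  eta <- drop(x %*% beta)
  mu <- stats::plogis(eta)
  info <- crossprod(x, x * (w * mu * (1 - mu)))
  vc <- solve(info)
  dimnames(vc) <- list(colnames(x), colnames(x))
  ll <- sum(w * (y * log(mu) + (1 - y) * log1p(-mu)))
  structure(list(coefficients = beta, vcov = vc, log_likelihood = ll,
                 converged = fit$converged, iterations = fit$iter),
            class = "logistic_fit")
}

#' Wald odds-ratio summary for one coefficient of a logistic fit
#'
#' @param fit A `logistic_fit`.
#' @param term Coefficient name.
#' @param label Result label.
#' @return An `or_result` for `exp(beta[term])`.
#' @export
or_from_fit <- function(fit, term, label = term) {
  beta <- fit$coefficients[[term]]
  se <- sqrt(fit$vcov[term, term])
  out <- or_result(label, exp(beta), se, counts = NULL)
  out
}

model_coding <- function(model) {
  switch(model,
         het       = list(exposed = 2L, reference = 1L),  # dose1 vs dose0
         hom       = list(exposed = 3L, reference = 1L),  # dose2 vs dose0
         dominant  = list(exposed = c(2L, 3L), reference = 1L),
         recessive = list(exposed = 3L, reference = c(1L, 2L)),
         stop("unknown model: ", model))
}

#' Single-locus association contrast under a genetic model
#'
#' Computes, from a [genotype_counts()] table: `het` (dose 1 vs 0), `hom`
#' (dose 2 vs 0), `dominant` (dose 1+2 vs 0) and `recessive` (dose 2 vs
#' 0+1) as 2x2 Woolf odds ratios; `additive` as the exponentiated
#' per-dose coefficient of a grouped logistic regression; and
#' `genotype_chi2` as the 2-df Pearson test of the full 3x2 table.
#' For the 2x2 models the Pearson chi-square p-value of the collapsed
#' table is attached as `p_chi2` alongside the Wald `p_value`.
#'
#' @param counts A `genotype_counts`.
#' @param model One of `"het"`, `"hom"`, `"dominant"`, `"recessive"`,
#'   `"additive"`, `"genotype_chi2"`.
#' @return An `or_result`, or for `genotype_chi2` the [pearson_chi2()]
#'   list.
#' @export
genotype_contrast <- function(counts, model) {
  stopifnot(inherits(counts, "genotype_counts"))
  label <- paste(counts$rsid, model)
  if (model == "genotype_chi2") {
    return(pearson_chi2(cbind(case = counts$case, control = counts$control)))
  }
  if (model == "additive") {
    dose <- c(0, 1, 2, 0, 1, 2)
    y <- c(1, 1, 1, 0, 0, 0)
    w <- c(counts$case, counts$control)
    fit <- fit_logistic(cbind(dose = dose), y, weights = w)
    out <- or_from_fit(fit, "dose", label)
    out$counts_used <- rbind(case = counts$case, control = counts$control)
    out$p_chi2 <- pearson_chi2(
      cbind(case = counts$case, control = counts$control))$p_value
    return(out)
  }
  mc <- model_coding(model)
  a <- sum(counts$case[mc$exposed]);    b <- sum(counts$case[mc$reference])
  c <- sum(counts$control[mc$exposed]); d <- sum(counts$control[mc$reference])
  out <- two_by_two_or(a, b, c, d, label = label)
  if (out$estimable)
    out$p_chi2 <- pearson_chi2(matrix(c(a, b, c, d), 2))$p_value
  out
}

genotype_design <- function(dose, model) {
  switch(model,
         additive  = cbind(geno = dose),
         dominant  = cbind(geno = as.numeric(dose >= 1)),
         recessive = cbind(geno = as.numeric(dose == 2)),
         het       = cbind(geno = as.numeric(dose == 1)),
         hom       = cbind(geno = as.numeric(dose == 2)),
         stop("unknown model: ", model))
}

covariate_design <- function(subjects, covariates) {
  cols <- NULL
  if ("age_months" %in% covariates)
    cols <- cbind(cols, age_months = subjects$age_months)
  if ("sex" %in% covariates)
    cols <- cbind(cols, male = as.numeric(subjects$sex == "male"))
  cols
}

#' Covariate-adjusted single-locus odds ratio
#'
#' Individual-level logistic regression of case status on the genotype
#' coding of the chosen model plus covariates (age in continuous months;
#' sex as a male indicator). With no covariates this reduces exactly to
#' [genotype_contrast()] on the tabulated counts (het/hom restrict the
#' data to the two genotype classes compared).
#'
#' @param cohort A `cohort`.
#' @param rsid Panel rsID.
#' @param model `"het"`, `"hom"`, `"dominant"`, `"recessive"` or
#'   `"additive"`.
#' @param covariates Subset of `c("age_months", "sex")`.
#' @return An `or_result` for the genotype coefficient.
#' @export
adjusted_contrast <- function(cohort, rsid, model,
                              covariates = c("age_months", "sex")) {
  s <- cohort$subjects
  dose <- s[[rsid]]
  keep <- !is.na(dose)
  if (model == "het") keep <- keep & dose %in% c(0L, 1L)
  if (model == "hom") keep <- keep & dose %in% c(0L, 2L)
  s <- s[keep, , drop = FALSE]; dose <- dose[keep]
  x <- cbind(genotype_design(dose, model), covariate_design(s, covariates))
  y <- as.numeric(s$status == "case")
  out <- tryCatch({
    fit <- fit_logistic(x, y)
    res <- or_from_fit(fit, "geno", paste(rsid, model, "adjusted"))
    res$counts_used <- table(dose, s$status)
    res
  }, error = function(e) inestimable_result(paste(rsid, model, "adjusted"),
                                            table(dose, s$status)))
  out
}

#' Count protective genotypes per subject
#'
#' Scores each subject by the number of panel SNPs at which the genotype
#' dose falls in the SNP's protective set (for the study panel, any
#' variant-carrying genotype). Subjects missing any panel genotype get
#' `NA` and are excluded from combined analyses (complete-case).
#'
#' @param cohort A `cohort`.
#' @return Integer vector, one score in `0..length(panel)` per subject
#'   (`NA` if incomplete), named by `subject_id`.
#' @export
protective_genotype_count <- function(cohort) {
  s <- cohort$subjects
  score <- rep(0L, nrow(s))
  complete <- rep(TRUE, nrow(s))
  for (snp in cohort$panel) {
    d <- s[[snp$rsid]]
    complete <- complete & !is.na(d)
    score <- score + as.integer(!is.na(d) & d %in% snp$protective_doses)
  }
  score[!complete] <- NA_integer_
  stats::setNames(score, s$subject_id)
}

#' Combined protective-genotype contrast from grouped counts
#'
#' 2x2 odds ratio of carrying many (e.g. 4-5) versus few (0-3)
#' protective genotypes, the high-score group being the exposure.
#'
#' @param case_low,case_high,control_low,control_high Subject counts in
#'   the low/high score groups.
#' @return An `or_result`, with the Pearson p of the 2x2 attached.
#' @export
combined_group_contrast <- function(case_low, case_high,
                                    control_low, control_high) {
  out <- two_by_two_or(case_high, case_low, control_high, control_low,
                       label = "protective 4-5 vs 0-3")
  if (out$estimable)
    out$p_chi2 <- pearson_chi2(matrix(c(case_high, case_low,
                                        control_high, control_low), 2))$p_value
  out
}

#' Combined protective-genotype analysis of a cohort
#'
#' Scores subjects with [protective_genotype_count()], splits at
#' `cutpoint` (score > cutpoint = exposed) and returns the crude contrast
#' together with the grouped counts; optionally a covariate-adjusted
#' contrast.
#'
#' @param cohort A `cohort`.
#' @param cutpoint Highest score counted as "few" (default 3, i.e. 4-5
#'   vs 0-3 on a five-SNP panel).
#' @param covariates Covariates for the adjusted contrast, or `NULL` for
#'   crude only.
#' @return List with `counts` (2x2), `crude` and (if requested)
#'   `adjusted` `or_result`s, and `n_excluded`.
#' @export
combined_analysis <- function(cohort, cutpoint = 3L,
                              covariates = c("age_months", "sex")) {
  score <- protective_genotype_count(cohort)
  s <- cohort$subjects
  keep <- !is.na(score)
  high <- score[keep] > cutpoint
  y <- as.numeric(s$status[keep] == "case")
  counts <- c(case_low = sum(y == 1 & !high), case_high = sum(y == 1 & high),
              control_low = sum(y == 0 & !high),
              control_high = sum(y == 0 & high))
  crude <- combined_group_contrast(counts["case_low"], counts["case_high"],
                                   counts["control_low"],
                                   counts["control_high"])
  out <- list(counts = counts, crude = crude, n_excluded = sum(!keep))
  if (!is.null(covariates)) {
    x <- cbind(geno = as.numeric(high),
               covariate_design(s[keep, , drop = FALSE], covariates))
    out$adjusted <- tryCatch({
      res <- or_from_fit(fit_logistic(x, y), "geno",
                         "protective 4-5 vs 0-3 adjusted")
      res$counts_used <- counts
      res
    }, error = function(e)
      inestimable_result("protective 4-5 vs 0-3 adjusted", counts))
  }
  out
}

subset_cohort <- function(cohort, keep) {
  new_cohort(cohort$panel, cohort$subjects[keep, , drop = FALSE])
}

stratum_keep <- function(subjects, variable, level) {
  switch(variable,
         age  = if (level == "<=18") subjects$age_months <= 18
                else subjects$age_months > 18,
         sex  = subjects$sex == level,
         # site strata: cases from that site against ALL controls
         site = subjects$status == "control" | subjects$site == level,
         stop("unknown stratum variable: ", variable))
}

default_strata <- function() {
  rbind(data.frame(variable = "age", level = c("<=18", ">18")),
        data.frame(variable = "sex", level = c("female", "male")),
        data.frame(variable = "site",
                   level = c("adrenal", "retroperitoneal", "mediastinum",
                             "other")))
}

#' Stratified association analysis
#'
#' Re-estimates an adjusted contrast within subgroups: age (at or below
#' vs above 18 months), sex, and tumor site of origin. Site strata
#' compare the site's cases against all controls (controls carry no
#' site). The target is either a panel rsID (with a genetic model) or
#' `"combined"` for the protective-genotype score.
#'
#' @param cohort A `cohort`.
#' @param target A panel rsID or `"combined"`.
#' @param model Genetic model for an rsID target (default `"dominant"`,
#'   the conventional protective-genotype contrast).
#' @param strata Data.frame with columns `variable`
#'   (`"age"`/`"sex"`/`"site"`) and `level`; defaults to all study
#'   strata.
#' @param covariates Adjustment covariates (age and sex by default).
#' @param cutpoint Passed to [combined_analysis()] for the combined
#'   target.
#' @return Data.frame with one row per stratum: `variable, level, n_case,
#'   n_control, or, ci_low, ci_high, p_value, estimable`.
#' @export
stratified_contrasts <- function(cohort, target, model = "dominant",
                                 strata = default_strata(),
                                 covariates = c("age_months", "sex"),
                                 cutpoint = 3L) {
  rows <- lapply(seq_len(nrow(strata)), function(i) {
    v <- strata$variable[i]; lev <- strata$level[i]
    keep <- stratum_keep(cohort$subjects, v, lev)
    sub <- cohort$subjects[keep, , drop = FALSE]
    n_case <- sum(sub$status == "case")
    n_control <- sum(sub$status == "control")
    res <- if (n_case == 0L || n_control == 0L) {
      inestimable_result(paste(v, lev), NULL)
    } else if (identical(target, "combined")) {
      ca <- combined_analysis(subset_cohort(cohort, keep),
                              cutpoint = cutpoint, covariates = covariates)
      if (is.null(covariates)) ca$crude else ca$adjusted
    } else {
      adjusted_contrast(subset_cohort(cohort, keep), target, model,
                        covariates = covariates)
    }
    data.frame(variable = v, level = lev, n_case = n_case,
               n_control = n_control, or = res$or_estimate,
               ci_low = res$ci_low, ci_high = res$ci_high,
               p_value = res$p_value, estimable = res$estimable,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Full single-locus association table
#'
#' Builds the standard publication layout: for each SNP the het, hom,
#' additive, dominant and recessive contrasts with crude ORs, Wald
#' p-values and Pearson chi-square p-values; adjusted ORs when a cohort
#' (rather than counts alone) is supplied.
#'
#' @param x A `cohort` or a named list of [genotype_counts()].
#' @param covariates Covariates for the adjusted column (cohort input
#'   only).
#' @return Data.frame, one row per SNP x model.
#' @export
association_table <- function(x, covariates = c("age_months", "sex")) {
  is_cohort <- inherits(x, "cohort")
  counts <- if (is_cohort) {
    rs <- panel_rsids(x$panel)
    stats::setNames(lapply(rs, tabulate_genotypes, cohort = x), rs)
  } else x
  models <- c("het", "hom", "additive", "dominant", "recessive")
  rows <- list()
  for (gc in counts) {
    for (m in models) {
      res <- genotype_contrast(gc, m)
      row <- data.frame(rsid = gc$rsid, model = m,
                        or = res$or_estimate, ci_low = res$ci_low,
                        ci_high = res$ci_high, p_value = res$p_value,
                        p_chi2 = res$p_chi2, estimable = res$estimable,
                        stringsAsFactors = FALSE)
      if (is_cohort) {
        adj <- adjusted_contrast(x, gc$rsid, m, covariates)
        row$or_adj <- adj$or_estimate
        row$ci_low_adj <- adj$ci_low
        row$ci_high_adj <- adj$ci_high
        row$p_adj <- adj$p_value
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
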