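# Haplotypes are strings over the panel's per-locus alleles, in panel
# order. Internally they are indexed into the complete 2^L set, built in
# lexicographic string order.

#' All haplotypes over a SNP panel
#'
#' @param panel A `snp_panel`.
#' @return Character vector of the `2^L` haplotype strings, sorted
#'   lexicographically.
#' @export
all_haplotypes <- function(panel) {
  L <- length(panel)
  if (L > 12L) stop("panel too large for exhaustive haplotype enumeration")
  grid <- expand.grid(lapply(panel, function(s)
    c(s$common_allele, s$variant_allele)), stringsAsFactors = FALSE)
  haps <- do.call(paste0, grid)
  sort(haps)
}

# variant-dose vector (0/1 per locus) of each haplotype string
hap_dose_matrix <- function(haps, panel) {
  L <- length(panel)
  m <- matrix(0L, length(haps), L)
  for (j in seq_len(L)) {
    m[, j] <- as.integer(substr(haps, j, j) ==
                           panel[[j]]$variant_allele)
  }
  rownames(m) <- haps
  m
}

#' Enumerate haplotype pairs compatible with an unphased genotype
#'
#' Lists every unordered pair of haplotypes whose locus-wise allele sums
#' equal the genotype's dose vector. With `h` heterozygous loci there
#' are `max(1, 2^(h-1))` such pairs.
#'
#' @param doses Integer vector of variant doses (0/1/2), one per panel
#'   locus, no missing values.
#' @param panel A `snp_panel`.
#' @return Two-column character matrix, one row per unordered pair.
#' @export
enumerate_pairs <- function(doses, panel) {
  stopifnot(length(doses) == length(panel), !anyNA(doses),
            all(doses %in% 0:2))
  het <- which(doses == 1L)
  h <- length(het)
  base1 <- base2 <- character(length(panel))
  for (j in seq_along(panel)) {
    s <- panel[[j]]
    al <- if (doses[j] == 0L) c(s$common_allele, s$common_allele)
          else if (doses[j] == 2L) c(s$variant_allele, s$variant_allele)
          else c(s$common_allele, s$variant_allele)
    base1[j] <- al[1]; base2[j] <- al[2]
  }
  if (h <= 1L) {
    return(matrix(c(paste(base1, collapse = ""),
                    paste(base2, collapse = "")), nrow = 1))
  }
  # fix the first het locus's assignment to avoid double counting
  n_free <- h - 1L
  out <- matrix("", 2L^n_free, 2L)
  for (k in seq_len(2L^n_free)) {
    bits <- as.integer(intToBits(k - 1L))[seq_len(n_free)]
    a1 <- base1; a2 <- base2
    for (t in seq_len(n_free)) {
      j <- het[t + 1L]
      if (bits[t] == 1L) { a1[j] <- base2[j]; a2[j] <- base1[j] }
    }
    out[k, ] <- c(paste(a1, collapse = ""), paste(a2, collapse = ""))
  }
  out
}

# group a dose matrix into unique genotype patterns with counts and the
# index pairs (into `haps`) compatible with each pattern
genotype_patterns <- function(dose_mat, haps, panel) {
  key <- apply(dose_mat, 1L, paste, collapse = "")
  tab <- table(key)
  hap_index <- stats::setNames(seq_along(haps), haps)
  patterns <- lapply(names(tab), function(k) {
    doses <- as.integer(strsplit(k, "")[[1]])
    pairs <- enumerate_pairs(doses, panel)
    i <- hap_index[pairs[, 1]]
    j <- hap_index[pairs[, 2]]
    list(n = as.numeric(tab[[k]]), i = unname(i), j = unname(j),
         mult = ifelse(i == j, 1, 2))
  })
  patterns
}

#' EM estimation of haplotype frequencies from unphased genotypes
#'
#' Standard EM under random mating (Hardy-Weinberg at the haplotype
#' level). The E-step weights each compatible unordered pair `(h1, h2)`
#' proportionally to `theta_h1 theta_h2` (doubled when `h1 != h2`); the
#' M-step sets each frequency to its expected chromosome count over
#' `2N`. Iteration stops when the log-likelihood improves by less than
#' `tol` or after `max_iter` iterations. The log-likelihood is asserted
#' non-decreasing at every step.
#'
#' @param dose_mat Integer matrix, subjects x loci, entries 0/1/2, no
#'   missing values (exclude incomplete subjects upstream).
#' @param panel A `snp_panel` matching the columns.
#' @param tol Log-likelihood convergence tolerance.
#' @param max_iter Iteration cap; non-convergence is flagged with a
#'   warning, never silent.
#' @param init `"product"` (product of single-locus allele frequencies,
#'   deterministic default) or `"uniform"`.
#' @param restarts Number of additional random (Dirichlet) starts; the
#'   fit with the best log-likelihood wins.
#' @param seed Seed for the random restarts.
#' @param group Label carried into the result.
#' @return A list of class `hap_freq_set`: `group`, `n_chromosomes`,
#'   `freq` (named vector over all haplotypes, summing to 1),
#'   `log_likelihood`, `iterations`, `converged`.
#' @export
em_haplotypes <- function(dose_mat, panel, tol = 1e-9, max_iter = 1000L,
                          init = c("product", "uniform"), restarts = 0L,
                          seed = 1L, group = NA_character_) {
  init <- match.arg(init)
  dose_mat <- as.matrix(dose_mat)
  if (nrow(dose_mat) < 1L) stop("need at least one genotype")
  if (anyNA(dose_mat)) stop("missing doses: exclude incomplete subjects")
  haps <- all_haplotypes(panel)
  H <- length(haps)
  patterns <- genotype_patterns(dose_mat, haps, panel)
  n_chrom <- 2 * nrow(dose_mat)

  theta0 <- if (init == "uniform") {
    rep(1 / H, H)
  } else {
    q <- colMeans(dose_mat) / 2
    hd <- hap_dose_matrix(haps, panel)
    th <- apply(hd, 1L, function(z) prod(ifelse(z == 1L, q, 1 - q)))
    th / sum(th)
  }
  starts <- list(theta0)
  if (restarts > 0L) {
    set.seed(seed)
    for (r in seq_len(restarts)) {
      g <- stats::rgamma(H, shape = 1)
      starts[[r + 1L]] <- g / sum(g)
    }
  }

  run_em <- function(theta) {
    ll_old <- -Inf
    iter <- 0L
    converged <- FALSE
    repeat {
      iter <- iter + 1L
      counts <- numeric(H)
      ll <- 0
      for (p in patterns) {
        w <- p$mult * theta[p$i] * theta[p$j]
        tot <- sum(w)
        if (tot <= 0) { ll <- -Inf; break }
        ll <- ll + p$n * log(tot)
        w <- w / tot
        # each pair contributes one copy of each member (two if i == j)
        contrib <- p$n * w
        for (k in seq_along(w)) {
          counts[p$i[k]] <- counts[p$i[k]] + contrib[k]
          counts[p$j[k]] <- counts[p$j[k]] + contrib[k]
        }
      }
      if (!is.finite(ll)) break
      if (ll < ll_old - 1e-8)
        stop("EM log-likelihood decreased: ", ll_old, " -> ", ll)
      theta <- counts / n_chrom
      if (abs(ll - ll_old) < tol) { converged <- TRUE; ll_old <- ll; break }
      ll_old <- ll
      if (iter >= max_iter) break
    }
    list(theta = theta, ll = ll_old, iter = iter, converged = converged)
  }

  fits <- lapply(starts, run_em)
  best <- fits[[which.max(vapply(fits, `[[`, numeric(1), "ll"))]]
  if (!best$converged)
    warning("EM did not converge in ", max_iter, " iterations")
  freq <- stats::setNames(best$theta, haps)
  structure(list(group = group, n_chromosomes = n_chrom, freq = freq,
                 log_likelihood = best$ll, iterations = best$iter,
                 converged = best$converged),
            class = "hap_freq_set")
}

#' @export
print.hap_freq_set <- function(x, ...) {
  cat(sprintf("<hap_freq_set> %s: 2N = %d, logL = %.4f (%d iter%s)\n",
              ifelse(is.na(x$group), "ungrouped", x$group),
              x$n_chromosomes, x$log_likelihood, x$iterations,
              if (x$converged) "" else ", NOT converged"))
  top <- sort(x$freq[x$freq > 0.01], decreasing = TRUE)
  for (h in names(top)) cat(sprintf("  %s %.4f\n", h, top[[h]]))
  invisible(x)
}

#' Expected haplotype chromosome counts
#'
#' @param fit A `hap_freq_set`.
#' @return Named numeric vector `freq * n_chromosomes` (sums to 2N).
#' @export
expected_counts <- function(fit) {
  fit$freq * fit$n_chromosomes
}

#' Haplotype-level case-control association versus a reference haplotype
#'
#' For every haplotype other than the reference, the 2x2 Woolf odds
#' ratio of (this haplotype vs the reference chromosome counts) by
#' status. Haplotypes whose count rounds to zero in either group are
#' inestimable; the reference row carries OR 1 by definition.
#'
#' @param case_counts,control_counts Named numeric vectors of chromosome
#'   counts (expected counts from EM, or printed integer counts).
#' @param reference Reference haplotype string; must have a positive
#'   count in both groups.
#' @param min_count Haplotypes whose count rounds below 1 in both groups
#'   are dropped from the output (default 0.5, i.e. unprintable rows).
#' @return Data.frame: `haplotype, case_count, control_count, or,
#'   ci_low, ci_high, p_value, estimable`, reference first then
#'   lexicographic.
#' @export
haplotype_association <- function(case_counts, control_counts, reference,
                                  min_count = 0.5) {
  haps <- sort(union(names(case_counts), names(control_counts)))
  cc <- stats::setNames(numeric(length(haps)), haps)
  mc <- cc
  cc[names(case_counts)] <- case_counts
  mc[names(control_counts)] <- control_counts
  if (!reference %in% haps || cc[reference] <= 0 || mc[reference] <= 0)
    stop("reference haplotype ", reference,
         " absent or zero in one group")
  keep <- (cc >= min_count) | (mc >= min_count)
  keep[reference] <- TRUE
  haps <- haps[keep]; cc <- cc[keep]; mc <- mc[keep]
  ord <- c(reference, setdiff(haps, reference))
  rows <- lapply(ord, function(h) {
    if (h == reference) {
      return(data.frame(haplotype = h, case_count = cc[[h]],
                        control_count = mc[[h]], or = 1, ci_low = NA_real_,
                        ci_high = NA_real_, p_value = NA_real_,
                        estimable = TRUE, stringsAsFactors = FALSE))
    }
    a <- cc[[h]]; b <- cc[[reference]]
    c_ <- mc[[h]]; d <- mc[[reference]]
    if (round(a) == 0 || round(c_) == 0) {
      return(data.frame(haplotype = h, case_count = a, control_count = c_,
                        or = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, p_value = NA_real_,
                        estimable = FALSE, stringsAsFactors = FALSE))
    }
    res <- two_by_two_or(a, b, c_, d, label = h)
    data.frame(haplotype = h, case_count = a, control_count = c_,
               or = res$or_estimate, ci_low = res$ci_low,
               ci_high = res$ci_high, p_value = res$p_value,
               estimable = TRUE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# per-subject posterior expected copies of each haplotype given theta
posterior_dosage <- function(dose_mat, panel, theta) {
  haps <- names(theta)
  patterns_key <- apply(dose_mat, 1L, paste, collapse = "")
  uniq <- unique(patterns_key)
  hap_index <- stats::setNames(seq_along(haps), haps)
  dosage_by_key <- lapply(uniq, function(k) {
    doses <- as.integer(strsplit(k, "")[[1]])
    pairs <- enumerate_pairs(doses, panel)
    i <- hap_index[pairs[, 1]]; j <- hap_index[pairs[, 2]]
    mult <- ifelse(i == j, 1, 2)
    w <- mult * theta[i] * theta[j]
    w <- w / sum(w)
    d <- numeric(length(haps))
    for (k2 in seq_along(w)) {
      d[i[k2]] <- d[i[k2]] + w[k2]
      d[j[k2]] <- d[j[k2]] + w[k2]
    }
    d
  })
  names(dosage_by_key) <- uniq
  out <- t(vapply(patterns_key, function(k) dosage_by_key[[k]],
                  numeric(length(haps))))
  colnames(out) <- haps
  out
}

#' End-to-end haplotype analysis of a cohort
#'
#' Complete-case subjects only. EM haplotype frequencies are estimated
#' separately in cases and in controls (matching group-specific count
#' reporting); expected chromosome counts feed the association contrast
#' against the reference haplotype. Optionally, covariate-adjusted
#' per-copy ORs are computed by logistic regression on posterior
#' haplotype dosages from a pooled EM fit.
#'
#' @param cohort A `cohort`.
#' @param reference Reference haplotype string.
#' @param adjust Covariates for the optional adjusted ORs, or `NULL`
#'   (default) to skip.
#' @param ... Passed to [em_haplotypes()].
#' @return List with `case_fit`, `control_fit` (`hap_freq_set`s),
#'   `association` (data.frame), `n_excluded`, and `adjusted` when
#'   requested.
#' @export
haplotype_pipeline <- function(cohort, reference, adjust = NULL, ...) {
  s <- cohort$subjects
  rsids <- panel_rsids(cohort$panel)
  dm <- as.matrix(s[, rsids])
  complete <- stats::complete.cases(dm)
  dm <- dm[complete, , drop = FALSE]
  status <- s$status[complete]
  case_fit <- em_haplotypes(dm[status == "case", , drop = FALSE],
                            cohort$panel, group = "case", ...)
  control_fit <- em_haplotypes(dm[status == "control", , drop = FALSE],
                               cohort$panel, group = "control", ...)
  assoc <- haplotype_association(expected_counts(case_fit),
                                 expected_counts(control_fit), reference)
  out <- list(case_fit = case_fit, control_fit = control_fit,
              association = assoc, n_excluded = sum(!complete))
  if (!is.null(adjust)) {
    pooled <- em_haplotypes(dm, cohort$panel, group = "pooled", ...)
    dos <- posterior_dosage(dm, cohort$panel, pooled$freq)
    y <- as.numeric(status == "case")
    covs <- covariate_design(s[complete, , drop = FALSE], adjust)
    adj <- lapply(setdiff(assoc$haplotype[assoc$estimable], reference),
                  function(h) {
      res <- tryCatch({
        fit <- fit_logistic(cbind(hap = dos[, h], covs), y)
        or_from_fit(fit, "hap", h)
      }, error = function(e) inestimable_result(h, NULL))
      data.frame(haplotype = h, or_adj = res$or_estimate,
                 ci_low_adj = res$ci_low, ci_high_adj = res$ci_high,
                 p_adj = res$p_value, stringsAsFactors = FALSE)
    })
    out$adjusted <- do.call(rbind, adj)
  }
  out
}
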