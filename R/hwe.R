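#' Variant-allele frequency from a genotype triple
#'
#' @param counts Genotype counts `(k0, k1, k2)` for dose 0/1/2.
#' @return `q = (2 k2 + k1) / (2 (k0 + k1 + k2))`.
#' @export
allele_frequency <- function(counts) {
  stopifnot(length(counts) == 3L, all(counts >= 0))
  n <- sum(counts)
  if (n == 0) stop("empty genotype triple")
  (2 * counts[3] + counts[2]) / (2 * n)
}

#' Hardy-Weinberg equilibrium goodness-of-fit test
#'
#' One-degree-of-freedom chi-square test of the observed genotype triple
#' against the Hardy-Weinberg expectations `N(1-q)^2, 2Nq(1-q), Nq^2`,
#' without continuity correction. An exact test (conditional on allele
#' counts, mid-free) is available via `method = "exact"`.
#'
#' @param counts Genotype triple `(k0, k1, k2)`.
#' @param rsid Optional SNP label carried into the result.
#' @param method `"chisq"` (default, asymptotic) or `"exact"`.
#' @return A list of class `hwe_result`: `rsid`, `q`, `chi2`, `df`,
#'   `p_value`, `expected`, `flag` (`"ok"` or `"monomorphic"`).
#' @export
hwe_test <- function(counts, rsid = NA_character_, method = c("chisq", "exact")) {
  method <- match.arg(method)
  n <- sum(counts)
  if (n == 0) stop("empty genotype triple")
  q <- allele_frequency(counts)
  if (q == 0 || q == 1) {
    return(structure(list(rsid = rsid, q = q, chi2 = 0, df = 1L,
                          p_value = 1, expected = as.numeric(counts),
                          flag = "monomorphic"),
                     class = "hwe_result"))
  }
  expected <- n * c((1 - q)^2, 2 * q * (1 - q), q^2)
  chi2 <- sum((counts - expected)^2 / expected)
  p <- if (method == "chisq") {
    stats::pchisq(chi2, df = 1L, lower.tail = FALSE)
  } else {
    hwe_exact_p(counts)
  }
  structure(list(rsid = rsid, q = q, chi2 = chi2, df = 1L, p_value = p,
                 expected = expected, flag = "ok"),
            class = "hwe_result")
}

# Exact HWE p-value: sum of probabilities of heterozygote counts no more
# likely than the observed one, conditional on the minor-allele count.
hwe_exact_p <- function(counts) {
  n <- sum(counts)
  nA <- 2 * counts[1] + counts[2]
  nB <- 2 * counts[3] + counts[2]
  rare <- min(nA, nB)
  hets <- seq.int(rare %% 2L, rare, by = 2L)
  logp <- vapply(hets, function(h) {
    hom_rare <- (rare - h) / 2
    hom_comm <- (max(nA, nB) - h) / 2
    lgamma(n + 1) - lgamma(hom_rare + 1) - lgamma(h + 1) -
      lgamma(hom_comm + 1) + h * log(2) +
      lgamma(nA + 1) + lgamma(nB + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  sum(p[p <= p[hets == counts[2]] * (1 + 1e-12)])
}

#' HWE tests across a panel, in controls by default
#'
#' @param x A `cohort` or a named list of [genotype_counts()].
#' @param group `"control"` (default, the conventional QC group) or
#'   `"case"`.
#' @param method Passed to [hwe_test()].
#' @return A data.frame with one row per SNP: `rsid, q, chi2, p_value,
#'   flag`.
#' @export
hwe_panel <- function(x, group = c("control", "case"),
                      method = c("chisq", "exact")) {
  group <- match.arg(group)
  method <- match.arg(method)
  counts <- if (inherits(x, "cohort")) {
    rs <- panel_rsids(x$panel)
    stats::setNames(lapply(rs, tabulate_genotypes, cohort = x), rs)
  } else x
  rows <- lapply(counts, function(gc) {
    r <- hwe_test(gc[[group]], rsid = gc$rsid, method = method)
    data.frame(rsid = r$rsid, q = r$q, chi2 = r$chi2, p_value = r$p_value,
               flag = r$flag, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
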