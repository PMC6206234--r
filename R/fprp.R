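#' Standard error of a log odds ratio from a reported 95% CI
#'
#' `se = (log(ci_high) - log(ci_low)) / (2 * 1.959964)`.
#'
#' @param ci_low,ci_high Positive CI bounds.
#' @return The SE of the log OR.
#' @export
se_from_ci <- function(ci_low, ci_high) {
  if (any(ci_low <= 0) || any(ci_high <= 0)) stop("CI bounds must be positive")
  if (any(ci_low > ci_high)) stop("ci_low must not exceed ci_high")
  (log(ci_high) - log(ci_low)) / (2 * Z95)
}

#' Power to detect a given true odds ratio
#'
#' Power of the two-sided Wald test of the log OR, at significance level
#' `alpha`, when the true odds ratio is `or1` and the estimator's
#' standard error is `se`: with `mu = log(or1)/se` and `z_c` the normal
#' quantile at `1 - alpha/2`,
#' `power = pnorm(-z_c - mu) + 1 - pnorm(z_c - mu)`.
#'
#' @param or1 Hypothesized detectable odds ratio (> 0).
#' @param se Standard error of the log OR (> 0).
#' @param alpha Significance level in (0, 1); in FPRP use, the observed
#'   p-value.
#' @return Power in `[0, 1]`.
#' @export
detection_power <- function(or1, se, alpha) {
  if (any(alpha <= 0 | alpha >= 1)) stop("alpha must be in (0,1)")
  if (any(or1 <= 0)) stop("or1 must be positive")
  if (any(se <= 0)) stop("se must be positive")
  mu <- log(or1) / se
  zc <- stats::qnorm(1 - alpha / 2)
  stats::pnorm(-zc - mu) + stats::pnorm(zc - mu, lower.tail = FALSE)
}

#' False-positive report probability
#'
#' `FPRP = alpha (1 - pi) / (alpha (1 - pi) + (1 - beta) pi)`, the
#' posterior probability that a statistically significant finding is a
#' false positive given the prior probability `pi` of a true
#' association, the observed p-value `alpha`, and the power `1 - beta`
#' to detect the hypothesized true effect.
#'
#' @param alpha Observed p-value in `[0, 1]`.
#' @param power Detection power `1 - beta` in `[0, 1]`.
#' @param prior Prior probability `pi` in `[0, 1]`.
#' @return FPRP in `[0, 1]`.
#' @export
fprp <- function(alpha, power, prior) {
  stopifnot(all(alpha >= 0 & alpha <= 1), all(power >= 0 & power <= 1),
            all(prior >= 0 & prior <= 1))
  num <- alpha * (1 - prior)
  den <- num + power * prior
  out <- ifelse(den == 0, ifelse(prior > 0, 0, 1), num / den)
  # prior = 0 means the association is impossible: any signal is false
  out[prior == 0] <- 1
  out[prior == 1] <- 0
  out
}

#' FPRP table across a prior-probability grid
#'
#' For each finding (label, OR, 95% CI, p-value): recover the SE of the
#' log OR from the CI, compute the power to detect the hypothesized true
#' OR (by default 0.67 for protective estimates, 1.5 for risk
#' estimates) at level `alpha` = the observed p-value, then FPRP at each
#' prior; a finding is noteworthy at a prior when FPRP < `threshold`.
#' A `power` column in `inputs`, when present and non-NA, overrides the
#' internal power model (use to reproduce published tables whose power
#' recipe differs).
#'
#' @param inputs Data.frame with columns `label, or, ci_low, ci_high, p`
#'   and optionally `power`.
#' @param priors Prior probabilities, highest first.
#' @param threshold Noteworthiness cutoff (conventionally 0.2).
#' @param or1 Either `NULL` for the direction-based default policy, a
#'   single OR applied to every row, or a function of the row's OR.
#' @return Data.frame: inputs plus `se_log_or`, `or1`, `power`, one
#'   `fprp_<prior>` and one `noteworthy_<prior>` column per prior.
#' @export
fprp_table <- function(inputs, priors = c(0.25, 0.1, 0.01, 0.001, 1e-4),
                       threshold = 0.2, or1 = NULL) {
  stopifnot(all(c("label", "or", "ci_low", "ci_high", "p") %in% names(inputs)))
  or1_of <- if (is.null(or1)) {
    function(or) ifelse(or < 1, 0.67, 1.5)
  } else if (is.function(or1)) {
    or1
  } else {
    function(or) rep(or1, length(or))
  }
  out <- inputs
  out$se_log_or <- se_from_ci(inputs$ci_low, inputs$ci_high)
  out$or1 <- or1_of(inputs$or)
  internal_power <- detection_power(out$or1, out$se_log_or, inputs$p)
  if ("power" %in% names(inputs)) {
    supplied <- !is.na(inputs$power)
    out$power <- ifelse(supplied, inputs$power, internal_power)
  } else {
    out$power <- internal_power
  }
  for (pr in priors) {
    v <- fprp(inputs$p, out$power, pr)
    out[[paste0("fprp_", format(pr, scientific = FALSE))]] <- v
    out[[paste0("noteworthy_", format(pr, scientific = FALSE))]] <-
      v < threshold
  }
  out
}
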