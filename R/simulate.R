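#' Default haplotype frequency spectrum for simulation
#'
#' The five-locus haplotype frequencies observed in the study's control
#' chromosomes (counts normalized over 1,524 control chromosomes),
#' covering all 24 observed haplotypes. Drawing both chromosomes of each
#' individual independently from this spectrum induces the study's
#' linkage disequilibrium and guarantees Hardy-Weinberg equilibrium at
#' every locus in the source population.
#'
#' @return Named numeric vector summing to 1.
#' @export
default_haplotype_freqs <- function() {
  tab <- study_haplotype_counts()
  stats::setNames(tab$n_control / sum(tab$n_control), tab$haplotype)
}

#' Default per-SNP disease effect model for simulation
#'
#' Dominant protective effects of the magnitude seen in the study:
#' log odds ratio `log(0.6)` for any variant-carrying genotype at
#' rs110419, rs4758051, rs10840002 and rs2168101, and no effect at
#' rs204938 (the null SNP of the panel).
#'
#' @return Named list, per rsID a length-2 numeric `c(dose1, dose2)` of
#'   log-ORs relative to dose 0.
#' @export
default_effect_model <- function() {
  prot <- c(log(0.6), log(0.6))
  list(rs110419 = prot, rs4758051 = prot, rs10840002 = prot,
       rs204938 = c(0, 0), rs2168101 = prot)
}

#' Simulation configuration
#'
#' Defines the generative model of the synthetic case-control cohort:
#' haplotype frequencies (LD structure), group sizes, per-genotype
#' disease effects on the logit scale, baseline log-odds, age and sex
#' distributions, optional covariate effects, and the seed.
#'
#' @param haplotype_freqs Named haplotype frequency vector (must sum to
#'   1 within 1e-9); strings use each SNP's declared alleles in panel
#'   order.
#' @param n_cases,n_controls Target group sizes (case-control sampling
#'   by rejection fills them exactly).
#' @param effect_model Named list, per rsID `c(log-OR dose1, log-OR
#'   dose2)`.
#' @param baseline_logit Disease log-odds for a dose-0 carrier at age 0;
#'   default -2.
#' @param age_mean,age_sd,age_min,age_max Truncated-normal age
#'   distribution in months (defaults match the study controls: mean
#'   33.04, SD 30.30, range 0-132).
#' @param p_male Probability of male sex (default 0.5538).
#' @param beta_age,beta_male Optional covariate log-odds effects
#'   (default 0: no confounding).
#' @param site_probs Multinomial site-of-origin probabilities for cases.
#' @param seed Integer seed; one global RNG stream per run.
#' @param max_attempts Cap on individuals drawn before giving up.
#' @param panel SNP panel.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(haplotype_freqs = default_haplotype_freqs(),
                       n_cases = 313L, n_controls = 762L,
                       effect_model = default_effect_model(),
                       baseline_logit = -2,
                       age_mean = 33.04, age_sd = 30.30,
                       age_min = 0, age_max = 132,
                       p_male = 0.5538,
                       beta_age = 0, beta_male = 0,
                       site_probs = c(adrenal = 0.2173,
                                      retroperitoneal = 0.4026,
                                      mediastinum = 0.3163,
                                      other = 0.0639),
                       seed = 1L, max_attempts = 5e6,
                       panel = study_panel()) {
  if (n_cases <= 0 || n_controls <= 0)
    stop("n_cases and n_controls must be positive")
  if (abs(sum(haplotype_freqs) - 1) > 1e-9)
    stop("haplotype frequencies must sum to 1")
  rsids <- panel_rsids(panel)
  if (!setequal(names(effect_model), rsids))
    stop("effect_model must name every panel SNP")
  ok <- vapply(seq_along(panel), function(j) {
    al <- substr(names(haplotype_freqs), j, j)
    all(al %in% c(panel[[j]]$common_allele, panel[[j]]$variant_allele))
  }, logical(1))
  if (!all(ok)) stop("haplotype strings use undeclared alleles")
  structure(list(haplotype_freqs = haplotype_freqs / sum(haplotype_freqs),
                 n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 effect_model = effect_model,
                 baseline_logit = baseline_logit,
                 age_mean = age_mean, age_sd = age_sd,
                 age_min = age_min, age_max = age_max,
                 p_male = p_male, beta_age = beta_age,
                 beta_male = beta_male,
                 site_probs = site_probs / sum(site_probs),
                 seed = as.integer(seed),
                 max_attempts = max_attempts, panel = panel),
            class = "sim_config")
}

# truncated normal via inverse-CDF (fixed number of uniforms: keeps the
# RNG stream length deterministic)
rtnorm <- function(n, mean, sd, lo, hi) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd),
                    stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

#' Simulate a case-control cohort with haplotype-level LD
#'
#' Each individual draws two haplotypes independently from the
#' configured frequency spectrum (so every locus is in Hardy-Weinberg
#' equilibrium in the source population), genotype doses follow, age
#' and sex are drawn from the configured distributions, and case status
#' is Bernoulli with `logit = baseline + sum(effect(snp, dose)) +
#' beta_age * age + beta_male * male`. Individuals accumulate by
#' rejection until exactly `n_cases` and `n_controls` are reached;
#' tumor sites are assigned to cases multinomially. Deterministic under
#' a fixed seed.
#'
#' @param config A [sim_config()].
#' @return List with `cohort` (a [new_cohort()]), `phased` (data.frame
#'   `subject_id, hap1, hap2`, the ground-truth phase) and `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  panel <- config$panel
  rsids <- panel_rsids(panel)
  haps <- names(config$haplotype_freqs)
  hd <- hap_dose_matrix(haps, panel)
  E <- do.call(rbind, config$effect_model[rsids])  # 5 x 2

  case_rows <- list(); control_rows <- list()
  n_case <- 0L; n_control <- 0L; attempts <- 0
  batch <- max(5000L, 2L * (config$n_cases + config$n_controls))
  while (n_case < config$n_cases || n_control < config$n_controls) {
    if (attempts >= config$max_attempts)
      stop("group sizes unreachable within max_attempts (p(case) ",
           "numerically degenerate?)")
    m <- batch
    attempts <- attempts + m
    h1 <- sample.int(length(haps), m, replace = TRUE,
                     prob = config$haplotype_freqs)
    h2 <- sample.int(length(haps), m, replace = TRUE,
                     prob = config$haplotype_freqs)
    doses <- hd[h1, , drop = FALSE] + hd[h2, , drop = FALSE]
    age <- rtnorm(m, config$age_mean, config$age_sd,
                  config$age_min, config$age_max)
    male <- stats::rbinom(m, 1L, config$p_male)
    logit <- rep(config$baseline_logit, m)
    for (j in seq_along(rsids)) {
      d <- doses[, j]
      logit <- logit + ifelse(d == 0, 0, E[j, pmax(d, 1)])
    }
    logit <- logit + config$beta_age * age + config$beta_male * male
    y <- stats::rbinom(m, 1L, stats::plogis(logit))
    df <- data.frame(y = y, age = age, male = male,
                     h1 = h1, h2 = h2, stringsAsFactors = FALSE)
    df <- cbind(df, doses)
    take_case <- df[df$y == 1L, , drop = FALSE]
    take_ctrl <- df[df$y == 0L, , drop = FALSE]
    if (nrow(take_case) > 0 && n_case < config$n_cases) {
      k <- min(nrow(take_case), config$n_cases - n_case)
      case_rows[[length(case_rows) + 1L]] <- take_case[seq_len(k), ]
      n_case <- n_case + k
    }
    if (nrow(take_ctrl) > 0 && n_control < config$n_controls) {
      k <- min(nrow(take_ctrl), config$n_controls - n_control)
      control_rows[[length(control_rows) + 1L]] <- take_ctrl[seq_len(k), ]
      n_control <- n_control + k
    }
  }
  cases <- do.call(rbind, case_rows)
  controls <- do.call(rbind, control_rows)
  sites <- sample(names(config$site_probs), config$n_cases,
                  replace = TRUE, prob = config$site_probs)
  subjects <- data.frame(
    subject_id = c(sprintf("case_%05d", seq_len(config$n_cases)),
                   sprintf("ctrl_%05d", seq_len(config$n_controls))),
    status = rep(c("case", "control"),
                 c(config$n_cases, config$n_controls)),
    age_months = c(cases$age, controls$age),
    sex = ifelse(c(cases$male, controls$male) == 1L, "male", "female"),
    site = c(sites, rep("not_applicable", config$n_controls)),
    stringsAsFactors = FALSE)
  for (j in seq_along(rsids))
    subjects[[rsids[j]]] <- c(cases[[5L + j]], controls[[5L + j]])
  phased <- data.frame(subject_id = subjects$subject_id,
                       hap1 = haps[c(cases$h1, controls$h1)],
                       hap2 = haps[c(cases$h2, controls$h2)],
                       stringsAsFactors = FALSE)
  list(cohort = new_cohort(panel, subjects), phased = phased,
       config = config)
}

#' Simulate a null cohort (no genetic effects)
#'
#' [simulate_cohort()] with every per-genotype effect set to zero; the
#' workhorse of type-I-error suites.
#'
#' @param n_cases,n_controls Group sizes.
#' @param seed Integer seed.
#' @param ... Further arguments to [sim_config()].
#' @return A `cohort`.
#' @export
simulate_null_cohort <- function(n_cases, n_controls, seed = 1L, ...) {
  null_eff <- lapply(default_effect_model(), function(e) c(0, 0))
  cfg <- sim_config(n_cases = n_cases, n_controls = n_controls,
                    effect_model = null_eff, seed = seed, ...)
  simulate_cohort(cfg)$cohort
}

#' Write a phased-truth table
#'
#' @param phased The `phased` data.frame from [simulate_cohort()].
#' @param path Output TSV path (`subject_id hap1 hap2`).
#' @return `path`, invisibly.
#' @export
write_phased_truth <- function(phased, path) {
  utils::write.table(phased, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
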