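test_that("two_by_two_or reproduces published crude odds ratios", {
  r <- two_by_two_or(118, 150, 355, 279)
  expect_equal(round(r$or_estimate, 2), 0.62)
  expect_equal(round(r$ci_low, 2), 0.46)
  expect_equal(round(r$ci_high, 2), 0.82)
  expect_equal(round(r$p_value, 4), 0.0011)

  bal <- two_by_two_or(10, 10, 10, 10)
  expect_equal(bal$or_estimate, 1)
  expect_equal(bal$p_value, 1)

  rec <- two_by_two_or(16, 297, 28, 734)
  expect_equal(round(rec$or_estimate, 2), 1.41)
  expect_equal(round(rec$ci_low, 2), 0.75)
  expect_equal(round(rec$ci_high, 2), 2.65)

  # CI reconstruction identity
  expect_equal(exp(log(r$or_estimate) + 1.959964 * r$se_log_or),
               r$ci_high, tolerance = 1e-9)

  zero <- two_by_two_or(0, 5, 3, 7)
  expect_false(zero$estimable)
  expect_true(two_by_two_or(0, 5, 3, 7, haldane = TRUE)$estimable)
})

test_that("reciprocal 2x2 tables give exactly inverse odds ratios", {
  set.seed(3)
  for (i in 1:20) {
    k <- sample(1:500, 4)
    f <- two_by_two_or(k[1], k[2], k[3], k[4])
    b <- two_by_two_or(k[2], k[1], k[4], k[3])
    expect_equal(f$or_estimate * b$or_estimate, 1, tolerance = 1e-12)
    expect_equal(f$p_value, b$p_value, tolerance = 1e-12)
  }
})

test_that("pearson_chi2 matches published table p-values and chisq.test", {
  gc <- study_genotype_counts()
  g3 <- genotype_contrast(gc$rs110419, "genotype_chi2")
  expect_equal(round(g3$p_value, 4), 0.0026)
  expect_equal(g3$df, 2L)

  dom <- matrix(c(163, 150, 483, 279), 2)  # dominant-collapsed rs110419
  expect_equal(round(pearson_chi2(dom)$p_value, 4), 6e-04)

  same <- rbind(c(30, 60), c(10, 20))
  expect_equal(pearson_chi2(same)$chi2, 0)
  expect_equal(pearson_chi2(same)$p_value, 1)

  expect_error(pearson_chi2(rbind(c(0, 0), c(5, 3))), "degenerate")

  set.seed(8)
  for (i in 1:10) {
    m <- matrix(sample(1:80, 6), 2)
    ours <- pearson_chi2(m)
    ref <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
    expect_equal(ours$chi2, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ours$p_value, unname(ref$p.value), tolerance = 1e-12)
  }
})

test_that("fit_logistic: grouped equals expanded, slope equals log OR", {
  # grouped 2x2
  x <- c(1, 0, 1, 0); y <- c(1, 1, 0, 0); w <- c(118, 150, 355, 279)
  g <- fit_logistic(cbind(exposed = x), y, weights = w)
  # expanded rows
  xe <- rep(x, w); ye <- rep(y, w)
  e <- fit_logistic(cbind(exposed = xe), ye)
  expect_equal(g$coefficients, e$coefficients, tolerance = 1e-9)

  r <- two_by_two_or(118, 150, 355, 279)
  expect_equal(unname(g$coefficients["exposed"]), log(r$or_estimate),
               tolerance = 1e-9)
  expect_equal(or_from_fit(g, "exposed")$p_value, r$p_value,
               tolerance = 1e-7)

  # intercept-only model recovers the logit of the case fraction
  i0 <- fit_logistic(matrix(nrow = 10, ncol = 0),
                     rep(c(1, 0), c(3, 7)))
  expect_equal(unname(i0$coefficients[1]), qlogis(0.3), tolerance = 1e-9)

  expect_error(fit_logistic(cbind(a = c(1, 1, 0, 0), b = c(2, 2, 0, 0)),
                            c(1, 0, 1, 0)), "full rank")
  expect_error(fit_logistic(cbind(x = 1:4), c(1, 1, 1, 1)),
               "at least one")
})

test_that("fit_logistic matches a brute-force likelihood maximizer", {
  # 3-point grouped toy: doses 0/1/2
  dose <- c(0, 1, 2, 0, 1, 2); y <- c(1, 1, 1, 0, 0, 0)
  w <- c(30, 25, 10, 40, 45, 30)
  fit <- fit_logistic(cbind(dose = dose), y, weights = w)
  nll <- function(b) -sum(w * (y * plogis(b[1] + b[2] * dose, log.p = TRUE) +
                                 (1 - y) * plogis(-(b[1] + b[2] * dose),
                                                  log.p = TRUE)))
  # coarse grid then Nelder-Mead polish, independent of the IRLS path
  grid <- expand.grid(b0 = seq(-2, 2, 0.1), b1 = seq(-2, 2, 0.1))
  v <- apply(grid, 1, nll)
  start <- as.numeric(grid[which.min(v), ])
  o <- optim(start, nll, control = list(reltol = 1e-15, maxit = 5000))
  expect_equal(unname(fit$coefficients), o$par, tolerance = 1e-5)
})

test_that("genotype_contrast reproduces published model rows", {
  gc <- study_genotype_counts()
  add <- genotype_contrast(gc$rs110419, "additive")
  expect_equal(round(add$or_estimate, 2), 0.76)
  expect_equal(round(add$ci_low, 2), 0.63)
  expect_equal(round(add$ci_high, 2), 0.92)
  expect_equal(round(add$p_chi2, 4), 0.0026)

  dom <- genotype_contrast(gc$rs4758051, "dominant")
  expect_equal(round(dom$or_estimate, 2), 0.64)
  expect_equal(round(dom$ci_low, 2), 0.49)
  expect_equal(round(dom$ci_high, 2), 0.84)
  expect_equal(round(dom$p_chi2, 4), 0.0012)

  flat <- genotype_counts("x", c(30, 60, 10), c(60, 120, 20))
  for (m in c("het", "hom", "dominant", "recessive", "additive"))
    expect_equal(genotype_contrast(flat, m)$or_estimate, 1,
                 tolerance = 1e-9, info = m)
})

test_that("dominant contrast equals logistic fit on a carrier indicator", {
  gc <- study_genotype_counts()
  for (r in names(gc)) {
    dom <- genotype_contrast(gc[[r]], "dominant")
    carrier <- c(0, 1, 1, 0, 1, 1)
    y <- c(1, 1, 1, 0, 0, 0)
    w <- c(gc[[r]]$case, gc[[r]]$control)
    fit <- fit_logistic(cbind(z = carrier), y, weights = w)
    expect_equal(unname(fit$coefficients["z"]), log(dom$or_estimate),
                 tolerance = 1e-9, info = r)
  }
})

test_that("protective_genotype_count scores carriers across the panel", {
  doses <- rbind(rep(1, 5), rep(0, 5), c(1, 0, 0, 0, 0), c(2, 2, 1, 1, 2))
  co <- make_dose_cohort(doses[1:2, , drop = FALSE],
                         doses[3:4, , drop = FALSE])
  expect_equal(unname(protective_genotype_count(co)), c(5L, 0L, 1L, 5L))
  co$subjects$rs204938[1] <- NA_integer_
  expect_true(is.na(protective_genotype_count(co)[1]))
})

test_that("combined contrast reproduces the published pooled result", {
  r <- combined_group_contrast(213, 100, 401, 361)
  expect_equal(round(r$or_estimate, 2), 0.52)
  expect_equal(round(r$ci_low, 2), 0.40)
  expect_equal(round(r$ci_high, 2), 0.69)
  expect_true(r$p_value < 1e-4)

  eq <- combined_group_contrast(50, 50, 100, 100)
  expect_equal(eq$or_estimate, 1)
})

test_that("combined_analysis agrees with a direct brute-force tally", {
  sc <- simulate_cohort(sim_config(n_cases = 150, n_controls = 250,
                                   seed = 21))
  co <- sc$cohort
  ca <- combined_analysis(co, covariates = NULL)
  s <- co$subjects
  rs <- panel_rsids(co$panel)
  score <- sapply(seq_len(nrow(s)), function(i)
    sum(unlist(s[i, rs]) >= 1))
  brute <- c(sum(s$status == "case" & score <= 3),
             sum(s$status == "case" & score > 3),
             sum(s$status == "control" & score <= 3),
             sum(s$status == "control" & score > 3))
  expect_equal(unname(ca$counts), brute)
  direct <- two_by_two_or(brute[2], brute[1], brute[4], brute[3])
  expect_equal(ca$crude$or_estimate, direct$or_estimate, tolerance = 1e-12)
})

test_that("adjusted_contrast with no covariates reduces to the crude OR", {
  sc <- simulate_cohort(sim_config(n_cases = 200, n_controls = 400,
                                   seed = 31))
  co <- sc$cohort
  for (m in c("dominant", "recessive", "additive", "het", "hom")) {
    adj <- adjusted_contrast(co, "rs2168101", m, covariates = NULL)
    crude <- genotype_contrast(tabulate_genotypes(co, "rs2168101"), m)
    expect_equal(adj$or_estimate, crude$or_estimate, tolerance = 1e-7,
                 info = m)
  }
})

test_that("adjusted OR matches crude under zero confounding", {
  sc <- simulate_cohort(sim_config(n_cases = 400, n_controls = 800,
                                   seed = 41))
  adj <- adjusted_contrast(sc$cohort, "rs110419", "dominant")
  crude <- genotype_contrast(tabulate_genotypes(sc$cohort, "rs110419"),
                             "dominant")
  # age and sex have zero configured effect: adjustment is a no-op up to
  # Monte-Carlo noise
  expect_equal(log(adj$or_estimate), log(crude$or_estimate),
               tolerance = 0.05)
})

test_that("stratified analysis: full-cover stratum, empty stratum", {
  sc <- simulate_cohort(sim_config(n_cases = 150, n_controls = 300,
                                   seed = 51, age_max = 17))
  co <- sc$cohort  # everyone aged <= 18 months
  strata <- data.frame(variable = "age", level = c("<=18", ">18"))
  tab <- stratified_contrasts(co, "rs2168101", "dominant", strata)
  full <- adjusted_contrast(co, "rs2168101", "dominant")
  expect_equal(tab$or[1], full$or_estimate, tolerance = 1e-9)
  expect_false(tab$estimable[2])  # empty stratum: inestimable, no crash

  # site strata compare site cases against all controls
  tab2 <- stratified_contrasts(co, "combined",
                               strata = data.frame(variable = "site",
                                                   level = "adrenal"))
  expect_equal(tab2$n_control, sum(co$subjects$status == "control"))
})
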