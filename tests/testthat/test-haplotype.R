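test_that("enumerate_pairs lists exactly the compatible phase pairs", {
  panel <- study_panel()
  # fully homozygous: one pair
  expect_equal(nrow(enumerate_pairs(c(0, 2, 0, 2, 0), panel)), 1L)
  # two heterozygous loci: 2 pairs
  expect_equal(nrow(enumerate_pairs(c(1, 1, 0, 0, 2), panel)), 2L)
  # five heterozygous loci: 16 pairs, checked against exhaustive
  # enumeration of all 32 x 32 ordered haplotype pairs
  g <- rep(1L, 5)
  pairs <- enumerate_pairs(g, panel)
  expect_equal(nrow(pairs), 16L)
  haps <- all_haplotypes(panel)
  hd <- t(vapply(haps, function(h) {
    vapply(seq_along(panel), function(j)
      as.integer(substr(h, j, j) == panel[[j]]$variant_allele),
      integer(1))
  }, integer(5)))
  brute <- 0L
  seen <- character()
  for (i in seq_along(haps)) for (j in i:length(haps)) {
    if (all(hd[i, ] + hd[j, ] == g)) {
      brute <- brute + 1L
      seen <- c(seen, paste(sort(c(haps[i], haps[j])), collapse = "|"))
    }
  }
  expect_equal(brute, 16L)
  got <- apply(pairs, 1, function(p) paste(sort(p), collapse = "|"))
  expect_setequal(got, seen)
  # every pair's allele sums reproduce the genotype
  for (k in seq_len(nrow(pairs))) {
    sums <- vapply(seq_along(panel), function(j)
      sum(substr(pairs[k, ], j, j) == panel[[j]]$variant_allele),
      numeric(1))
    expect_equal(sums, as.numeric(g))
  }
})

test_that("EM at a single locus equals allele counting exactly", {
  p1 <- structure(list(snp_def("s1", "A", "G")), class = "snp_panel")
  dm <- matrix(rep(c(0L, 1L, 2L), c(25, 50, 25)), ncol = 1)
  fit <- em_haplotypes(dm, p1)
  expect_equal(unname(fit$freq["G"]), 0.5, tolerance = 1e-12)
  set.seed(33)
  dm2 <- matrix(sample(0:2, 80, TRUE, prob = c(0.5, 0.4, 0.1)), ncol = 1)
  fit2 <- em_haplotypes(dm2, p1)
  expect_equal(unname(fit2$freq["G"]), allele_frequency(tabulate(dm2 + 1L, 3L)),
               tolerance = 1e-12)
})

test_that("EM resolves unambiguous phase by direct counting", {
  p2 <- toy_panel2()
  dm <- rbind(matrix(2L, 50, 2), matrix(0L, 50, 2))
  fit <- em_haplotypes(dm, p2)
  expect_equal(unname(fit$freq[c("AC", "BD")]), c(0.5, 0.5),
               tolerance = 1e-12)
  expect_equal(sum(fit$freq), 1, tolerance = 1e-9)
})

test_that("EM matches a brute-force likelihood maximizer on a toy", {
  p2 <- toy_panel2()
  set.seed(42)
  dm <- cbind(sample(0:2, 10, TRUE), sample(0:2, 10, TRUE))
  fit <- em_haplotypes(dm, p2, tol = 1e-12)
  haps <- all_haplotypes(p2)
  loglik <- function(theta) {
    s <- 0
    for (i in seq_len(nrow(dm))) {
      prs <- enumerate_pairs(dm[i, ], p2)
      w <- sum(apply(prs, 1, function(p)
        (2 - (p[1] == p[2])) * theta[p[1]] * theta[p[2]]))
      s <- s + log(w)
    }
    s
  }
  # softmax-parameterized simplex search from multiple starts
  best <- -Inf; btheta <- NULL
  set.seed(1)
  for (st in 1:15) {
    o <- optim(rnorm(4), function(x) {
      th <- exp(x) / sum(exp(x)); names(th) <- haps; -loglik(th)
    }, method = "Nelder-Mead",
    control = list(maxit = 5000, reltol = 1e-14))
    if (-o$value > best) {
      best <- -o$value
      btheta <- exp(o$par) / sum(exp(o$par))
    }
  }
  names(btheta) <- haps
  expect_equal(fit$log_likelihood, best, tolerance = 1e-8)
  expect_lt(max(abs(fit$freq - btheta)), 1e-4)
})

test_that("EM frequencies are a valid distribution and loglik converges", {
  set.seed(55)
  co <- simulate_null_cohort(150, 150, seed = 55)
  rs <- panel_rsids(co$panel)
  fit <- em_haplotypes(as.matrix(co$subjects[, rs]), co$panel)
  expect_true(fit$converged)
  expect_true(all(fit$freq >= 0))
  expect_equal(sum(fit$freq), 1, tolerance = 1e-9)
  # uniform and product initializations reach the same optimum here
  fit_u <- em_haplotypes(as.matrix(co$subjects[, rs]), co$panel,
                         init = "uniform")
  expect_equal(fit$log_likelihood, fit_u$log_likelihood, tolerance = 1e-6)
})

test_that("relabeling alleles permutes frequencies, preserves likelihood", {
  p2 <- toy_panel2()
  set.seed(77)
  dm <- cbind(sample(0:2, 30, TRUE), sample(0:2, 30, TRUE))
  fit <- em_haplotypes(dm, p2, tol = 1e-12)
  p2r <- structure(list(snp_def("s1", "B", "A"), snp_def("s2", "C", "D")),
                   class = "snp_panel")
  fitr <- em_haplotypes(cbind(2L - dm[, 1], dm[, 2]), p2r, tol = 1e-12)
  expect_equal(fit$log_likelihood, fitr$log_likelihood, tolerance = 1e-8)
  # same multiset of frequencies under the relabeling A<->B at locus 1
  expect_equal(sort(unname(fit$freq)), sort(unname(fitr$freq)),
               tolerance = 1e-6)
})

test_that("expected counts scale frequencies to chromosomes", {
  p1 <- structure(list(snp_def("s1", "A", "G")), class = "snp_panel")
  dm <- matrix(rep(c(0L, 1L, 2L), c(25, 50, 25)), ncol = 1)
  fit <- em_haplotypes(dm, p1)
  ec <- expected_counts(fit)
  expect_equal(unname(ec["G"]), 100)
  expect_equal(sum(ec), fit$n_chromosomes)
})

test_that("haplotype association reproduces the published contrasts", {
  hp <- study_haplotype_counts()
  cc <- stats::setNames(hp$n_case, hp$haplotype)
  mc <- stats::setNames(hp$n_control, hp$haplotype)
  tab <- haplotype_association(cc, mc, "AGAAG")
  expect_equal(tab$haplotype[1], "AGAAG")
  expect_equal(tab$or[1], 1)

  row <- function(h) tab[tab$haplotype == h, ]
  g <- row("GAGAT")
  expect_equal(round(g$or, 2), 0.63)
  expect_equal(round(g$ci_low, 2), 0.47)
  expect_equal(round(g$ci_high, 2), 0.85)
  expect_equal(round(g$p_value, 3), 0.002)
  a <- row("AGGAG")
  expect_equal(round(a$or, 2), 3.58)
  expect_equal(round(a$ci_low, 2), 1.60)
  expect_equal(round(a$ci_high, 2), 7.99)
  # zero-count haplotypes are inestimable, mirroring "/" rows
  for (h in c("AGAAT", "AGGGT", "AAGAT", "GGAGT"))
    expect_false(row(h)$estimable)
  # all published crude ORs reproduce within print rounding
  published <- c(AGAGG = 1.10, AGGAG = 3.58, AGGGG = 1.96, AAAAG = 0.45,
                 AAGAG = 0.77, AAGGG = 1.41, GGAAG = 0.82, GGAAT = 0.84,
                 GGAGG = 0.73, GGGAG = 13.41, GGGAT = 1.34, GGGGG = 4.47,
                 GGGGT = 1.12, GAAAG = 4.47, GAAAT = 2.24, GAGAG = 1.62,
                 GAGAT = 0.63, GAGGG = 1.04, GAGGT = 0.52)
  for (h in names(published))
    expect_lt(abs(row(h)$or - published[[h]]), 0.011)
  expect_error(haplotype_association(cc, mc, "TTTTT"), "reference")
})

test_that("pipeline equals direct counting on fully homozygous subjects", {
  doses_case <- rbind(matrix(0L, 20, 5), matrix(2L, 10, 5))
  doses_ctrl <- rbind(matrix(0L, 15, 5), matrix(2L, 25, 5))
  co <- make_dose_cohort(doses_case, doses_ctrl)
  out <- haplotype_pipeline(co, reference = "AGAAG")
  # common-allele haplotype AGAAG, variant haplotype GAGGT
  expect_equal(unname(expected_counts(out$case_fit)[c("AGAAG", "GAGGT")]),
               c(40, 20))
  expect_equal(unname(expected_counts(out$control_fit)[c("AGAAG", "GAGGT")]),
               c(30, 50))
  direct <- two_by_two_or(20, 40, 50, 30)
  got <- out$association[out$association$haplotype == "GAGGT", ]
  expect_equal(got$or, direct$or_estimate, tolerance = 1e-9)
})

test_that("pipeline recovers simulated haplotype frequencies", {
  co <- simulate_null_cohort(1000, 1000, seed = 99)
  out <- haplotype_pipeline(co, reference = "AGAAG")
  fr <- default_haplotype_freqs()
  for (fit in list(out$case_fit, out$control_fit)) {
    truth <- stats::setNames(numeric(length(fit$freq)), names(fit$freq))
    truth[names(fr)] <- fr
    expect_lt(max(abs(fit$freq - truth)), 0.02)
  }
  expect_equal(out$n_excluded, 0L)
})
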