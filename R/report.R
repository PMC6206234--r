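#' Format helpers for publication-style tables
#'
#' `format_or()` renders odds ratios and CI bounds half-up to 2
#' decimals; `format_p()` renders p-values to 4 significant figures
#' with the `"< 0.0001"` convention below 1e-4; inestimable entries
#' render as `"/"`.
#'
#' @param x Numeric vector.
#' @return Character vector.
#' @export
format_or <- function(x) {
  ifelse(is.na(x), "/",
         # round half-up, the convention of printed tables
         sprintf("%.2f", floor(x * 100 + 0.5) / 100))
}

#' @rdname format_or
#' @export
format_p <- function(x) {
  ifelse(is.na(x), "/",
         ifelse(x < 1e-4, "< 0.0001", as.character(signif(x, 4))))
}

format_or_ci <- function(or, lo, hi) {
  ifelse(is.na(or), "/",
         paste0(format_or(or), " (", format_or(lo), "-", format_or(hi), ")"))
}

#' Render a result object as a publication-style TSV text table
#'
#' Fixed column orders per layout: `"hwe"` (per-SNP HWE QC),
#' `"association"` (SNP x model ORs), `"stratified"`, `"fprp"` and
#' `"haplotype"`. ORs/CIs print to 2 decimals, p-values to 4
#' significant figures (`"< 0.0001"` below 1e-4), inestimable rows as
#' `"/"`; machine-precision p-values are kept in a companion column.
#'
#' @param results Data.frame from the matching pipeline stage.
#' @param layout One of `"hwe"`, `"association"`, `"stratified"`,
#'   `"fprp"`, `"haplotype"`.
#' @return Character scalar of TSV text (header + rows).
#' @export
render_table <- function(results, layout = c("hwe", "association",
                                             "stratified", "fprp",
                                             "haplotype")) {
  layout <- match.arg(layout)
  need <- switch(layout,
    hwe         = c("rsid", "q", "chi2", "p_value", "flag"),
    association = c("rsid", "model", "or", "ci_low", "ci_high",
                    "p_value", "p_chi2"),
    stratified  = c("variable", "level", "n_case", "n_control", "or",
                    "ci_low", "ci_high", "p_value"),
    fprp        = c("label", "or", "ci_low", "ci_high", "p", "power"),
    haplotype   = c("haplotype", "case_count", "control_count", "or",
                    "ci_low", "ci_high", "p_value"))
  if (!all(need %in% names(results)))
    stop("results do not match layout '", layout, "': need columns ",
         paste(setdiff(need, names(results)), collapse = ", "))
  out <- switch(layout,
    hwe = data.frame(rsid = results$rsid,
                     q = sprintf("%.4f", results$q),
                     chi2 = sprintf("%.4f", results$chi2),
                     p = format_p(results$p_value),
                     flag = results$flag),
    association = data.frame(
      rsid = results$rsid, model = results$model,
      or_ci = format_or_ci(results$or, results$ci_low, results$ci_high),
      p = format_p(results$p_value),
      p_chi2 = format_p(results$p_chi2),
      p_exact = results$p_value),
    stratified = data.frame(
      variable = results$variable, level = results$level,
      n_case = results$n_case, n_control = results$n_control,
      or_ci = format_or_ci(results$or, results$ci_low, results$ci_high),
      p = format_p(results$p_value),
      p_exact = results$p_value),
    fprp = {
      fp <- results[, grep("^fprp_", names(results)), drop = FALSE]
      cbind(data.frame(
        label = results$label,
        or_ci = format_or_ci(results$or, results$ci_low, results$ci_high),
        p = format_p(results$p),
        power = sprintf("%.3f", results$power)),
        as.data.frame(lapply(fp, function(v) sprintf("%.3f", v))))
    },
    haplotype = data.frame(
      haplotype = results$haplotype,
      n_case = round(results$case_count),
      n_control = round(results$control_count),
      or_ci = ifelse(results$haplotype == results$haplotype[1] &
                       seq_len(nrow(results)) == 1L, "1.00",
                     format_or_ci(results$or, results$ci_low,
                                  results$ci_high)),
      p = format_p(results$p_value),
      p_exact = ifelse(is.na(results$p_value), "/",
                       as.character(results$p_value))))
  con <- textConnection("txt", "w", local = TRUE)
  utils::write.table(out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)
  paste0(paste(txt, collapse = "\n"), "\n")
}

write_stage <- function(text, path, seed, config_hash) {
  header <- sprintf("# seed=%d config=%s columns: see header row\n",
                    seed, config_hash)
  cat(header, text, sep = "", file = path)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes every stage on a cohort (read from `cohort_path`, or
#' simulated from `sim` when no path is given): demographics, HWE QC in
#' controls, single-locus association (crude and adjusted), combined
#' protective-genotype analysis, stratified analysis, FPRP on all crude
#' contrasts significant at 0.05, and the haplotype EM pipeline. One
#' TSV per stage plus a JSON manifest is written under `out_dir`; any
#' stage error aborts the run and removes partial outputs. Reruns with
#' the same seed are byte-identical.
#'
#' @param out_dir Output directory (created if needed).
#' @param cohort_path Optional cohort TSV; when `NULL` a synthetic
#'   cohort is generated.
#' @param sim A [sim_config()] used when `cohort_path` is `NULL`.
#' @param reference Reference haplotype for the haplotype stage.
#' @param priors FPRP prior grid.
#' @param threshold FPRP noteworthiness threshold.
#' @param covariates Adjustment covariates.
#' @param quiet Suppress stage messages.
#' @return Invisibly, the manifest list.
#' @export
run_all <- function(out_dir, cohort_path = NULL, sim = sim_config(),
                    reference = "AGAAG",
                    priors = c(0.25, 0.1, 0.01, 0.001, 1e-4),
                    threshold = 0.2,
                    covariates = c("age_months", "sex"),
                    quiet = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[ccsnp] ", ...)
  seed <- sim$seed
  config_hash <- substr(digest_config(sim), 1, 8)
  files <- character()
  on_fail <- function(stage, e) {
    unlink(file.path(out_dir, files))
    stop("stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }
  emit <- function(name, text) {
    path <- file.path(out_dir, name)
    write_stage(text, path, seed, config_hash)
    files <<- c(files, name)
    path
  }

  cohort <- tryCatch({
    if (is.null(cohort_path)) {
      say("simulating cohort (seed ", seed, ")")
      simulate_cohort(sim)$cohort
    } else {
      say("reading cohort from ", cohort_path)
      read_cohort(cohort_path, sim$panel)
    }
  }, error = function(e) on_fail("cohort", e))

  tryCatch({
    say("demographics")
    emit("demographics.tsv", demographics_table(cohort))
    say("HWE QC")
    emit("hwe.tsv", render_table(hwe_panel(cohort), "hwe"))
    say("single-locus association")
    assoc <- association_table(cohort, covariates = covariates)
    emit("association.tsv", render_table(assoc, "association"))
    say("combined protective-genotype analysis")
    comb <- combined_analysis(cohort, covariates = covariates)
    emit("combined.tsv", combined_text(comb))
    say("stratified analysis")
    strat <- stratified_contrasts(cohort, "combined",
                                  covariates = covariates)
    emit("stratified.tsv", render_table(strat, "stratified"))
    say("FPRP")
    sig <- assoc[assoc$estimable & !is.na(assoc$p_value) &
                   assoc$p_value < 0.05 & assoc$model != "additive", ]
    sig_add <- assoc[assoc$estimable & assoc$model == "additive" &
                       assoc$p_value < 0.05, ]
    sig <- rbind(sig, sig_add)
    if (nrow(sig)) {
      fin <- data.frame(label = paste(sig$rsid, sig$model),
                        or = sig$or, ci_low = sig$ci_low,
                        ci_high = sig$ci_high, p = sig$p_value)
      emit("fprp.tsv",
           render_table(fprp_table(fin, priors, threshold), "fprp"))
    }
    say("haplotype EM pipeline")
    hap <- haplotype_pipeline(cohort, reference)
    emit("haplotypes.tsv", render_table(hap$association, "haplotype"))
  }, error = function(e) on_fail("analysis", e))

  manifest <- list(
    package = "ccsnp",
    version = as.character(utils::packageVersion("ccsnp")),
    seed = seed,
    config_hash = config_hash,
    input = if (is.null(cohort_path)) "simulated" else cohort_path,
    files = lapply(stats::setNames(files, files), function(f)
      list(md5 = unname(tools::md5sum(file.path(out_dir, f)))))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

digest_config <- function(sim) {
  # stable short hash of the simulation config (text serialization)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(utils::capture.output(utils::str(
    sim[setdiff(names(sim), "panel")])), tmp)
  unname(tools::md5sum(tmp))
}

demographics_table <- function(cohort) {
  s <- cohort$subjects
  case <- s$status == "case"
  row <- function(variable, level, keep) {
    nc <- sum(keep & case); nk <- sum(keep & !case)
    data.frame(variable = variable, level = level, n_case = nc,
               pct_case = sprintf("%.2f", 100 * nc / sum(case)),
               n_control = nk,
               pct_control = sprintf("%.2f", 100 * nk / sum(!case)))
  }
  age_p <- pearson_chi2(rbind(
    c(sum(case & s$age_months <= 18), sum(!case & s$age_months <= 18)),
    c(sum(case & s$age_months > 18), sum(!case & s$age_months > 18))))
  sex_p <- pearson_chi2(rbind(
    c(sum(case & s$sex == "female"), sum(!case & s$sex == "female")),
    c(sum(case & s$sex == "male"), sum(!case & s$sex == "male"))))
  out <- rbind(row("age", "<=18", s$age_months <= 18),
               row("age", ">18", s$age_months > 18),
               row("sex", "female", s$sex == "female"),
               row("sex", "male", s$sex == "male"))
  for (site in c("adrenal", "retroperitoneal", "mediastinum", "other"))
    out <- rbind(out, row("site", site, s$site == site))
  out$p_matching <- c(format_p(age_p$p_value), "",
                      format_p(sex_p$p_value), "", rep("", 4))
  con <- textConnection("txt", "w", local = TRUE)
  utils::write.table(out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)
  paste0(paste(txt, collapse = "\n"), "\n")
}

combined_text <- function(comb) {
  cn <- comb$counts
  df <- data.frame(
    score = c("0-3", "4-5"),
    n_case = c(cn[["case_low"]], cn[["case_high"]]),
    n_control = c(cn[["control_low"]], cn[["control_high"]]),
    or_ci = c("1.00", format_or_ci(comb$crude$or_estimate,
                                   comb$crude$ci_low,
                                   comb$crude$ci_high)),
    p = c("", format_p(comb$crude$p_value)),
    or_ci_adj = c("1.00",
                  if (!is.null(comb$adjusted))
                    format_or_ci(comb$adjusted$or_estimate,
                                 comb$adjusted$ci_low,
                                 comb$adjusted$ci_high) else ""),
    p_adj = c("", if (!is.null(comb$adjusted))
      format_p(comb$adjusted$p_value) else ""))
  con <- textConnection("txt", "w", local = TRUE)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)
  paste0(paste(txt, collapse = "\n"), "\n")
}
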