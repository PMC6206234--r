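# shared fixtures: built in code, no files

toy_panel2 <- function() {
  structure(list(snp_def("s1", "A", "B"), snp_def("s2", "C", "D")),
            class = "snp_panel")
}

# build a cohort directly from dose matrices (rows = subjects)
make_dose_cohort <- function(case_doses, control_doses,
                             panel = study_panel(), age = 24, sex = "female") {
  rsids <- vapply(panel, `[[`, character(1), "rsid")
  nc <- nrow(case_doses); nk <- nrow(control_doses)
  subjects <- data.frame(
    subject_id = c(sprintf("ca%03d", seq_len(nc)),
                   sprintf("co%03d", seq_len(nk))),
    status = rep(c("case", "control"), c(nc, nk)),
    age_months = rep(age, nc + nk),
    sex = rep(sex, nc + nk),
    site = rep(c("adrenal", "not_applicable"), c(nc, nk)),
    stringsAsFactors = FALSE)
  all_doses <- rbind(case_doses, control_doses)
  for (j in seq_along(rsids)) subjects[[rsids[j]]] <- all_doses[, j]
  new_cohort(panel, subjects)
}

# cohort TSV text with a couple of rows, for reader tests
toy_cohort_text <- function() {
  paste(
    "subject_id\tstatus\tage_months\tsex\tsite\trs110419\trs4758051\trs10840002\trs204938\trs2168101",
    "S1\tcase\t24\tM\tadrenal\tAG\tAG\tAG\tAG\tGT",
    "S2\tcase\t7.5\tF\tmediastinum\tGA\tGG\tAA\tAA\tGG",
    "S3\tcontrol\t40\tF\tNA\tGG\tAA\tGG\tGG\tTT",
    "S4\tcontrol\t18\tM\tNA\t./.\tAG\tAG\tAG\tGT",
    sep = "\n")
}

write_toy_cohort <- function() {
  path <- tempfile(fileext = ".tsv")
  writeLines(toy_cohort_text(), path)
  path
}
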