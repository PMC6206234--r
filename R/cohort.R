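#' Define a biallelic SNP
#'
#' A SNP is described by its rsID, its common and variant alleles (the
#' "X>Y" orientation fixes which allele is counted as the dose allele),
#' and the set of genotype doses regarded as protective.
#'
#' @param rsid Identifier string, e.g. `"rs110419"`.
#' @param common_allele Single character, the common (reference) allele.
#' @param variant_allele Single character, the variant allele whose copies
#'   are counted as the genotype dose.
#' @param protective_doses Integer subset of `0:2`; the genotype doses that
#'   count as protective when scoring subjects across the panel.
#' @return An object of class `snp_def`.
#' @export
snp_def <- function(rsid, common_allele, variant_allele,
                    protective_doses = c(1L, 2L)) {
  stopifnot(is.character(rsid), length(rsid) == 1L, nzchar(rsid))
  stopifnot(nchar(common_allele) == 1L, nchar(variant_allele) == 1L)
  if (common_allele == variant_allele)
    stop("common and variant allele must differ for ", rsid)
  protective_doses <- as.integer(protective_doses)
  if (!all(protective_doses %in% 0:2))
    stop("protective_doses must be a subset of 0:2")
  structure(list(rsid = rsid,
                 common_allele = common_allele,
                 variant_allele = variant_allele,
                 protective_doses = sort(unique(protective_doses))),
            class = "snp_def")
}

#' The five-SNP LMO1 study panel
#'
#' The panel of five LMO1 SNPs in study order, with the orientation
#' rs110419 A>G, rs4758051 G>A, rs10840002 A>G, rs204938 A>G and
#' rs2168101 G>T. Every variant-carrying genotype (dose 1 or 2) is
#' protective at each SNP.
#'
#' @return A list of [snp_def()] objects, class `snp_panel`.
#' @export
study_panel <- function() {
  structure(list(
    snp_def("rs110419",   "A", "G"),
    snp_def("rs4758051",  "G", "A"),
    snp_def("rs10840002", "A", "G"),
    snp_def("rs204938",   "A", "G"),
    snp_def("rs2168101",  "G", "T")
  ), class = "snp_panel")
}

panel_rsids <- function(panel) vapply(panel, `[[`, character(1), "rsid")

#' Construct a cohort
#'
#' A cohort bundles a SNP panel with a subject table holding case/control
#' status, covariates and per-SNP variant-allele doses (0/1/2, `NA` when
#' the genotype is missing).
#'
#' @param panel A `snp_panel` (list of [snp_def()]).
#' @param subjects A data.frame with columns `subject_id`, `status`
#'   (`"case"`/`"control"`), `age_months`, `sex` (`"female"`/`"male"`),
#'   `site`, and one integer dose column per panel rsID.
#' @return An object of class `cohort`.
#' @export
new_cohort <- function(panel, subjects) {
  rsids <- panel_rsids(panel)
  need <- c("subject_id", "status", "age_months", "sex", "site", rsids)
  miss <- setdiff(need, names(subjects))
  if (length(miss)) stop("subjects table lacks columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(subjects$subject_id))
    stop("duplicate subject_id: ",
         subjects$subject_id[duplicated(subjects$subject_id)][1])
  if (!all(subjects$status %in% c("case", "control")))
    stop("status must be 'case' or 'control'")
  if (!all(subjects$sex %in% c("female", "male")))
    stop("sex must be 'female' or 'male'")
  if (any(subjects$age_months < 0, na.rm = TRUE))
    stop("age_months must be non-negative")
  ok_site <- c("adrenal", "retroperitoneal", "mediastinum", "other",
               "not_applicable")
  if (!all(subjects$site %in% ok_site))
    stop("invalid site value")
  if (any(subjects$site[subjects$status == "control"] != "not_applicable"))
    stop("controls must have site = not_applicable")
  for (r in rsids) {
    d <- subjects[[r]]
    if (!all(is.na(d) | d %in% 0:2))
      stop("doses for ", r, " must be in {0,1,2} or NA")
    subjects[[r]] <- as.integer(d)
  }
  structure(list(panel = panel, subjects = subjects), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  s <- x$subjects
  cat(sprintf("<cohort> %d subjects (%d cases / %d controls), %d SNPs\n",
              nrow(s), sum(s$status == "case"), sum(s$status == "control"),
              length(x$panel)))
  invisible(x)
}

# genotype string ("AG", "GA", "./.") -> dose relative to a snp_def
genotype_to_dose <- function(g, snp) {
  if (g == "./.") return(NA_integer_)
  alleles <- strsplit(g, "")[[1]]
  if (length(alleles) != 2L ||
      !all(alleles %in% c(snp$common_allele, snp$variant_allele)))
    stop("unknown allele in genotype '", g, "' for ", snp$rsid)
  sum(alleles == snp$variant_allele)
}

dose_to_genotype <- function(d, snp) {
  if (is.na(d)) return("./.")
  paste0(c(rep(snp$common_allele, 2L - d), rep(snp$variant_allele, d)),
         collapse = "")
}

#' Read a cohort from a TSV file
#'
#' The file has a header `subject_id status age_months sex site <rsid...>`
#' with genotypes as two-letter allele strings (allele order irrelevant,
#' `"AG"` is the same as `"GA"`) or `"./."` for missing; `sex` is `F`/`M`
#' and `site` is `NA` for controls.
#'
#' @param path Path to the TSV file.
#' @param panel SNP panel; defaults to [study_panel()].
#' @return A [new_cohort()] object.
#' @export
read_cohort <- function(path, panel = study_panel()) {
  raw <- utils::read.delim(path, colClasses = "character",
                           check.names = FALSE, na.strings = NULL)
  rsids <- panel_rsids(panel)
  need <- c("subject_id", "status", "age_months", "sex", "site", rsids)
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("cohort file lacks columns: ",
                         paste(miss, collapse = ", "))
  age <- suppressWarnings(as.numeric(raw$age_months))
  bad <- which(is.na(age) | age < 0)
  if (length(bad)) stop("malformed age_months in row ", bad[1])
  if (!all(raw$sex %in% c("F", "M")))
    stop("malformed sex in row ", which(!raw$sex %in% c("F", "M"))[1])
  subjects <- data.frame(
    subject_id = raw$subject_id,
    status     = raw$status,
    age_months = age,
    sex        = ifelse(raw$sex == "F", "female", "male"),
    site       = ifelse(raw$site == "NA", "not_applicable", raw$site),
    stringsAsFactors = FALSE)
  for (k in seq_along(panel)) {
    snp <- panel[[k]]
    subjects[[snp$rsid]] <- vapply(seq_len(nrow(raw)), function(i) {
      tryCatch(genotype_to_dose(raw[[snp$rsid]][i], snp),
               error = function(e) stop("row ", i, ", column ", snp$rsid,
                                        ": ", conditionMessage(e),
                                        call. = FALSE))
    }, integer(1))
  }
  new_cohort(panel, subjects)
}

#' Write a cohort to a TSV file
#'
#' Inverse of [read_cohort()]; doses are rendered as normalized genotype
#' strings (common allele first), so read-write-read is idempotent.
#'
#' @param cohort A `cohort`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  s <- cohort$subjects
  out <- data.frame(
    subject_id = s$subject_id,
    status     = s$status,
    age_months = s$age_months,
    sex        = ifelse(s$sex == "female", "F", "M"),
    site       = ifelse(s$site == "not_applicable", "NA", s$site),
    stringsAsFactors = FALSE)
  for (snp in cohort$panel)
    out[[snp$rsid]] <- vapply(s[[snp$rsid]], dose_to_genotype, character(1),
                              snp = snp)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Genotype count table for one SNP
#'
#' The 3x2 genotype-by-status count atom of a single-locus association
#' analysis: dose 0/1/2 counts among cases and among controls.
#'
#' @param rsid SNP identifier.
#' @param case_counts,control_counts Integer triples `(n0, n1, n2)`.
#' @param n_missing_case,n_missing_control Subjects excluded for missing
#'   genotype.
#' @return An object of class `genotype_counts`.
#' @export
genotype_counts <- function(rsid, case_counts, control_counts,
                            n_missing_case = 0L, n_missing_control = 0L) {
  stopifnot(length(case_counts) == 3L, length(control_counts) == 3L,
            all(case_counts >= 0), all(control_counts >= 0))
  structure(list(rsid = rsid,
                 case = as.integer(case_counts),
                 control = as.integer(control_counts),
                 n_missing_case = as.integer(n_missing_case),
                 n_missing_control = as.integer(n_missing_control)),
            class = "genotype_counts")
}

#' Tabulate genotype doses by case/control status
#'
#' @param cohort A `cohort`.
#' @param rsid A panel rsID.
#' @return A [genotype_counts()] object; missing genotypes are excluded
#'   from the triples and reported in the missing tallies.
#' @export
tabulate_genotypes <- function(cohort, rsid) {
  if (!rsid %in% panel_rsids(cohort$panel))
    stop("rsid ", rsid, " not in panel")
  s <- cohort$subjects
  d <- s[[rsid]]
  cnt <- function(status) tabulate(d[s$status == status] + 1L, nbins = 3L)
  genotype_counts(rsid,
                  cnt("case"), cnt("control"),
                  sum(s$status == "case" & is.na(d)),
                  sum(s$status == "control" & is.na(d)))
}

#' Validate a cohort, returning structured findings
#'
#' Reporting-only checks: empty case or control group (error findings),
#' monomorphic SNPs and all-missing SNPs (warnings). A well-formed cohort
#' yields zero rows.
#'
#' @param cohort A `cohort`.
#' @return A data.frame with columns `level` (`"error"`/`"warning"`),
#'   `code` and `message`.
#' @export
validate_cohort <- function(cohort) {
  s <- cohort$subjects
  findings <- list()
  add <- function(level, code, message)
    findings[[length(findings) + 1L]] <<- data.frame(
      level = level, code = code, message = message,
      stringsAsFactors = FALSE)
  if (!any(s$status == "case"))
    add("error", "empty_group", "cohort contains no cases")
  if (!any(s$status == "control"))
    add("error", "empty_group", "cohort contains no controls")
  for (snp in cohort$panel) {
    d <- s[[snp$rsid]]
    if (all(is.na(d))) {
      add("warning", "all_missing",
          paste0(snp$rsid, ": all genotypes missing"))
    } else if (length(unique(d[!is.na(d)])) == 1L) {
      add("warning", "monomorphic",
          paste0(snp$rsid, ": monomorphic (all non-missing dose ",
                 unique(d[!is.na(d)]), ")"))
    }
  }
  if (length(findings)) do.call(rbind, findings)
  else data.frame(level = character(), code = character(),
                  message = character(), stringsAsFactors = FALSE)
}

#' Read an aggregate genotype count table
#'
#' Columns `rsid genotype n_case n_control` with `genotype` the variant
#' dose 0/1/2; returns one [genotype_counts()] per SNP, in file order.
#'
#' @param path Path to the TSV.
#' @return Named list of `genotype_counts`.
#' @export
read_genotype_counts <- function(path) {
  tab <- utils::read.delim(path)
  stopifnot(all(c("rsid", "genotype", "n_case", "n_control") %in% names(tab)))
  out <- list()
  for (r in unique(tab$rsid)) {
    sub <- tab[tab$rsid == r, ]
    cc <- mc <- integer(3)
    cc[sub$genotype + 1L] <- sub$n_case
    mc[sub$genotype + 1L] <- sub$n_control
    out[[r]] <- genotype_counts(r, cc, mc)
  }
  out
}

extdata <- function(file) {
  path <- system.file("extdata", file, package = "ccsnp", mustWork = TRUE)
  path
}

#' Published study count tables
#'
#' Accessors for the aggregate tables of the LMO1 neuroblastoma
#' case-control study shipped with the package: per-SNP genotype counts
#' (313 cases / 762 controls), combined protective-genotype score counts,
#' FPRP inputs for the significant findings (ORs, CIs, p-values and the
#' published power column), and five-locus haplotype counts (626 case /
#' 1524 control chromosomes).
#'
#' @return `study_genotype_counts()`: a named list of [genotype_counts()];
#'   the others: data.frames.
#' @export
study_genotype_counts <- function() read_genotype_counts(
  extdata("lmo1_genotype_counts.tsv"))

#' @rdname study_genotype_counts
#' @export
study_combined_counts <- function() utils::read.delim(
  extdata("lmo1_combined_counts.tsv"))

#' @rdname study_genotype_counts
#' @export
study_fprp_inputs <- function() utils::read.delim(
  extdata("lmo1_fprp_inputs.tsv"))

#' @rdname study_genotype_counts
#' @export
study_haplotype_counts <- function() utils::read.delim(
  extdata("lmo1_haplotype_counts.tsv"))
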