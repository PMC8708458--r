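# Cohort layer: eligibility filtering, baseline-characteristic summaries
# with between-group tests, and the sensitivity-analysis subset reruns.

#' Apply the study eligibility criteria
#'
#' Excludes subjects with a COPD or lung-cancer diagnosis, smokers or
#' ex-smokers with >= 10 pack-years (inclusive), and current users of
#' antibiotics for acute respiratory symptoms. One reason is logged per
#' excluded subject (the first matching criterion).
#'
#' @param records cohort data.frame with fields `subject_id`, `copd_dx`,
#'   `lung_cancer_dx`, `smoking_status`, `pack_years`,
#'   `current_antibiotics`.
#' @return list with `eligible` (retained rows) and `exclusions`
#'   (data.frame `subject_id`, `reason`).
#' @export
applyEligibility <- function(records) {
  required <- c("subject_id", "copd_dx", "lung_cancer_dx", "smoking_status",
                "pack_years", "current_antibiotics")
  miss <- setdiff(required, names(records))
  if (length(miss)) stop("missing required field(s): ",
                         paste(miss, collapse = ", "))
  for (f in required) {
    bad <- which(is.na(records[[f]]))
    if (length(bad)) stop("missing value in field '", f, "' at row ", bad[1])
  }
  reason <- rep(NA_character_, nrow(records))
  hit <- records$copd_dx | records$lung_cancer_dx
  reason[hit] <- "COPD and/or lung cancer diagnosis"
  smokeHeavy <- records$smoking_status %in% c("ex", "current") &
    records$pack_years >= 10
  reason[is.na(reason) & smokeHeavy] <- ">= 10 pack-years smoking history"
  reason[is.na(reason) & records$current_antibiotics] <-
    "current antibiotic use for acute respiratory symptoms"
  keep <- is.na(reason)
  list(eligible = records[keep, , drop = FALSE],
       exclusions = data.frame(subject_id = records$subject_id[!keep],
                               reason = reason[!keep],
                               stringsAsFactors = FALSE))
}

#' Summary-type dictionary for the baseline table
#'
#' Maps each baseline variable to its summary and test type, mirroring
#' which rows of the emulated study's baseline tables show mean (SD)
#' (t-test), median (IQR) (Wilcoxon rank-sum) or n (%) (Pearson's
#' chi-squared). Selection is dictionary-driven rather than
#' normality-tested per run, for reproducibility.
#'
#' @return data.frame with columns `variable`, `type`
#'   (`mean_sd` / `median_iqr` / `n_pct` / `categorical`).
#' @export
baselineDictionary <- function() {
  data.frame(
    variable = c("age", "sex_male", "bmi", "smoking_status", "pack_years",
                 "recent_antibiotics", "fev1_pct", "fev1_fvc_pct",
                 "blood_eos", "blood_neut", "feno", "acq", "allergy",
                 "ics_maintenance"),
    type = c("mean_sd", "n_pct", "mean_sd", "categorical", "median_iqr",
             "n_pct", "mean_sd", "mean_sd",
             "median_iqr", "median_iqr", "median_iqr", "mean_sd", "n_pct",
             "n_pct"),
    stringsAsFactors = FALSE
  )
}

.fmtMeanSD <- function(x) sprintf("%.1f (%.1f)", mean(x), sd(x))
.fmtMedianIQR <- function(x) {
  q <- quantile(x, c(0.25, 0.5, 0.75), type = 7)  # linear interpolation
  sprintf("%.1f (%.1f-%.1f)", q[2], q[1], q[3])
}
.fmtNPct <- function(x) sprintf("%d (%.1f)", sum(x), 100 * mean(x))

#' Baseline-characteristics table by exacerbation group
#'
#' Per variable: mean (SD) for approximately normal continuous variables,
#' median (IQR, linear-interpolation quartiles) for skewed ones, n (%) for
#' binary/categorical ones, with the variable-to-summary mapping taken from
#' [baselineDictionary()]. Group-comparison p-values from
#' [compareGroups()] are attached.
#'
#' @param records cohort data.frame including the `exacerbation` label.
#' @param dictionary summary-type dictionary (default
#'   [baselineDictionary()]); variables absent from `records` are skipped.
#' @return data.frame with one row per variable (categorical levels
#'   expanded): `variable`, `overall`, `exacerbation`, `no_exacerbation`,
#'   `test`, `p`.
#' @export
summarizeBaseline <- function(records, dictionary = baselineDictionary()) {
  if (!nrow(records)) stop("empty cohort")
  if (!"exacerbation" %in% names(records)) stop("missing 'exacerbation' label")
  g1 <- records$exacerbation == 1
  if (!any(g1) || all(g1)) stop("both exacerbation groups must be non-empty")
  dictionary <- dictionary[dictionary$variable %in% names(records), ]
  rows <- list()
  for (i in seq_len(nrow(dictionary))) {
    v <- dictionary$variable[i]
    ty <- dictionary$type[i]
    x <- records[[v]]
    cmp <- compareGroups(records, v, dictionary)
    fmt <- switch(ty, mean_sd = .fmtMeanSD, median_iqr = .fmtMedianIQR,
                  n_pct = .fmtNPct, categorical = NULL)
    if (ty == "categorical") {
      lv <- unique(x)
      for (l in sort(lv)) {
        rows[[length(rows) + 1L]] <- data.frame(
          variable = paste0(v, ":", l),
          overall = .fmtNPct(x == l),
          exacerbation = .fmtNPct(x[g1] == l),
          no_exacerbation = .fmtNPct(x[!g1] == l),
          test = cmp$test, p = cmp$p, stringsAsFactors = FALSE)
      }
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, overall = fmt(x), exacerbation = fmt(x[g1]),
        no_exacerbation = fmt(x[!g1]), test = cmp$test, p = cmp$p,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Between-group test for one baseline variable
#'
#' Pooled-variance independent t-test for mean (SD) variables, Wilcoxon
#' rank-sum for median (IQR) variables, Pearson's chi-squared (without
#' continuity correction by default) for binary/categorical variables; the
#' selection comes from the same dictionary as [summarizeBaseline()].
#' Identical values in both groups degenerate to p = 1. A chi-squared
#' validity warning (expected cell count < 5) is attached as attribute
#' `warning`.
#'
#' @param records cohort data.frame including `exacerbation`.
#' @param variable variable name.
#' @param dictionary summary-type dictionary.
#' @param yates apply Yates continuity correction to chi-squared tests.
#' @return list with `test`, `statistic`, `p` (and possibly attribute
#'   `warning`).
#' @export
compareGroups <- function(records, variable,
                          dictionary = baselineDictionary(),
                          yates = FALSE) {
  if (!variable %in% names(records)) stop("variable not found: ", variable)
  ty <- dictionary$type[dictionary$variable == variable]
  if (!length(ty)) stop("variable not in the summary dictionary: ", variable)
  x <- records[[variable]]
  g <- factor(records$exacerbation, levels = c(0, 1))
  if (ty %in% c("n_pct", "categorical")) {
    tab <- table(x, g)
    if (nrow(tab) < 2L)
      return(list(test = "chi-squared", statistic = 0, p = 1))
    ct <- suppressWarnings(chisq.test(tab, correct = yates))
    out <- list(test = "chi-squared", statistic = unname(ct$statistic),
                p = ct$p.value)
    if (any(ct$expected < 5))
      attr(out, "warning") <- "expected cell count < 5; chi-squared approximation questionable"
    return(out)
  }
  x0 <- x[g == 0]; x1 <- x[g == 1]
  if (sd(x) == 0)
    return(list(test = if (ty == "mean_sd") "t-test" else "rank-sum",
                statistic = 0, p = 1))
  if (ty == "mean_sd") {
    tt <- t.test(x1, x0, var.equal = TRUE)
    list(test = "t-test", statistic = unname(tt$statistic), p = tt$p.value)
  } else {
    wt <- suppressWarnings(wilcox.test(x1, x0, exact = FALSE, correct = FALSE))
    list(test = "rank-sum", statistic = unname(wt$statistic), p = wt$p.value)
  }
}

#' The printed baseline counts of the emulated study
#'
#' Group-level counts transcribed from the published baseline tables of the
#' study this package emulates, shipped as plain text in
#' `inst/extdata/baseline_counts.tsv`. These serve as worked-example inputs:
#' prevalences, subgroup percentages and sensitivity-subset sizes are
#' recomputed from them.
#'
#' @return data.frame with one row per (dataset, group): `n` and counts of
#'   recent antibiotic use, smoking status, maintenance ICS, allergy and
#'   male sex, plus the percentages as printed.
#' @export
referenceBaselineCounts <- function() {
  read.delim(system.file("extdata", "baseline_counts.tsv",
                         package = "breathprint"),
             stringsAsFactors = FALSE)
}

#' Expand the printed baseline counts into a subject-level cohort table
#'
#' Deterministically expands [referenceBaselineCounts()] into one row per
#' subject with the flags assigned marginally (the first k subjects of each
#' group carry each flag; joint flag structure is not published and is not
#' needed for marginal arithmetic).
#'
#' @param counts a counts table as returned by [referenceBaselineCounts()].
#' @return cohort data.frame with `subject_id`, `split`, `exacerbation`,
#'   `recent_antibiotics`, `smoking_status`, `ics_maintenance`.
#' @export
buildReferenceCohort <- function(counts = referenceBaselineCounts()) {
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    r <- counts[i, ]
    n <- r$n
    smoking <- rep(c("never", "ex", "current"),
                   c(r$smoking_never, r$smoking_ex, r$smoking_current))
    # one printed smoking row sums to n - 1 (missing value in the source
    # table); pad with the modal category, which leaves the current-smoker
    # count — the only one entering subset arithmetic — untouched
    if (length(smoking) < n)
      smoking <- c(smoking, rep("never", n - length(smoking)))
    data.frame(
      split = if (r$dataset == "training") "train" else "validation",
      exacerbation = as.integer(r$group == "exacerbation"),
      recent_antibiotics = seq_len(n) <= r$recent_antibiotics,
      smoking_status = smoking,
      ics_maintenance = seq_len(n) <= r$ics,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- cbind(subject_id = sprintf("R%04d", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Consistency check of printed counts against printed percentages
#'
#' Recomputes each percentage from its count and group size and flags cells
#' where the printed percentage disagrees by more than rounding (0.05
#' points). The emulated study's tables contain one such arithmetic
#' inconsistency (the maintenance-ICS percentage of the training
#' no-exacerbation group), which this check surfaces rather than silently
#' reproducing.
#'
#' @param counts a counts table as returned by [referenceBaselineCounts()].
#' @return data.frame of flagged cells: `dataset`, `group`, `variable`,
#'   `count`, `printed_pct`, `recomputed_pct`.
#' @export
checkBaselineConsistency <- function(counts = referenceBaselineCounts()) {
  pctVars <- c(recent_antibiotics = "recent_antibiotics_pct",
               ics = "ics_pct", allergy = "allergy_pct", male = "male_pct")
  flagged <- list()
  for (i in seq_len(nrow(counts))) {
    r <- counts[i, ]
    for (v in names(pctVars)) {
      printed <- r[[pctVars[[v]]]]
      if (is.na(printed)) next
      recomputed <- round(100 * r[[v]] / r$n, 1)
      if (abs(recomputed - printed) > 0.05)
        flagged[[length(flagged) + 1L]] <- data.frame(
          dataset = r$dataset, group = r$group, variable = v,
          count = r[[v]], printed_pct = printed,
          recomputed_pct = recomputed, stringsAsFactors = FALSE)
    }
  }
  if (!length(flagged))
    return(data.frame(dataset = character(0), group = character(0),
                      variable = character(0), count = integer(0),
                      printed_pct = numeric(0), recomputed_pct = numeric(0)))
  do.call(rbind, flagged)
}

#' Sensitivity-analysis subset rules
#'
#' Pure row filters on the cohort covariates: drop recent antibiotic users,
#' drop current smokers, or keep only maintenance-ICS users.
#'
#' @param name one of `"no_recent_antibiotics"`, `"no_current_smokers"`,
#'   `"ics_only"`.
#' @return a predicate `function(colData) -> logical` selecting the rows to
#'   keep.
#' @export
subsetRule <- function(name = c("no_recent_antibiotics",
                                "no_current_smokers", "ics_only")) {
  name <- match.arg(name)
  switch(name,
    no_recent_antibiotics = function(cd) !as.logical(cd$recent_antibiotics),
    no_current_smokers = function(cd) cd$smoking_status != "current",
    ics_only = function(cd) as.logical(cd$ics_maintenance)
  )
}

#' Sensitivity-analysis reruns on cohort subsets
#'
#' For each named rule, filters the feature set's subjects in place
#' (keeping the original train/validation membership; no re-split) and
#' reruns [runDiscriminantPipeline()] on the subset. Errors if a subset
#' loses a class in either part, naming the rule.
#'
#' @param fs a [BreathFeatureSet-class] whose `colData` carries `split` and
#'   the filter covariates.
#' @param rules character vector of [subsetRule()] names.
#' @param config a [pipelineConfig()] list.
#' @return named list, one element per rule: `n`, `nTrain`, `nValidation`
#'   and the [DiscriminantPipeline-class] `result`.
#' @export
sensitivitySubsets <- function(fs, rules = c("no_recent_antibiotics",
                                             "no_current_smokers",
                                             "ics_only"),
                               config = pipelineConfig()) {
  stopifnot(is(fs, "BreathFeatureSet"))
  cd <- SummarizedExperiment::colData(fs)
  if (!"split" %in% names(cd))
    stop("feature set must carry the original split membership")
  out <- list()
  for (rule in rules) {
    keep <- subsetRule(rule)(cd)
    sub <- fs[, keep]
    scd <- SummarizedExperiment::colData(sub)
    for (part in c("train", "validation")) {
      lab <- scd$exacerbation[scd$split == part]
      if (length(unique(lab)) < 2L)
        stop("subset '", rule, "' loses a class in the ", part, " part")
    }
    out[[rule]] <- list(n = ncol(sub),
                        nTrain = sum(scd$split == "train"),
                        nValidation = sum(scd$split == "validation"),
                        result = runDiscriminantPipeline(sub, config))
  }
  out
}
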