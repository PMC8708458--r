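# Cohort layer: eligibility screening, baseline summaries with
# between-group tests, printed-count arithmetic and sensitivity subsets.

mkRecords <- function(n = 6) {
  data.frame(
    subject_id = sprintf("P%02d", seq_len(n)),
    copd_dx = FALSE, lung_cancer_dx = FALSE,
    smoking_status = "never", pack_years = 0,
    current_antibiotics = FALSE, stringsAsFactors = FALSE
  )
}

test_that("eligibility applies the exclusion criteria with inclusive boundaries", {
  r <- mkRecords(5)
  r$smoking_status[2:3] <- "ex"
  r$pack_years[2] <- 12     # excluded: >= 10 inclusive
  r$pack_years[3] <- 9.9    # retained: strictly below
  r$copd_dx[4] <- TRUE
  r$current_antibiotics[5] <- TRUE
  out <- applyEligibility(r)
  expect_identical(out$eligible$subject_id, c("P01", "P03"))
  expect_identical(nrow(out$exclusions) + nrow(out$eligible), nrow(r))
  expect_match(out$exclusions$reason[out$exclusions$subject_id == "P02"],
               "pack-years")
  expect_match(out$exclusions$reason[out$exclusions$subject_id == "P04"],
               "COPD")
  expect_match(out$exclusions$reason[out$exclusions$subject_id == "P05"],
               "antibiotic")

  # boundary: pack_years exactly 10
  r10 <- mkRecords(1); r10$smoking_status <- "current"; r10$pack_years <- 10
  expect_identical(nrow(applyEligibility(r10)$eligible), 0L)

  expect_error(applyEligibility(r[, -3]), "missing required")
  rna <- mkRecords(2); rna$pack_years[2] <- NA
  expect_error(applyEligibility(rna), "pack_years.*row 2")
})

test_that("eligibility filtering is idempotent", {
  r <- mkRecords(10)
  r$smoking_status[1:4] <- "ex"; r$pack_years[1:4] <- c(5, 15, 10, 2)
  once <- applyEligibility(r)$eligible
  twice <- applyEligibility(once)$eligible
  expect_identical(once, twice)
})

test_that("baseline summaries reproduce the printed arithmetic", {
  co <- data.frame(
    exacerbation = rep(c(1, 0), c(41, 211)),
    recent_antibiotics = c(rep(TRUE, 17), rep(FALSE, 24),
                           rep(TRUE, 6), rep(FALSE, 205))
  )
  tab <- summarizeBaseline(co)
  ab <- tab[tab$variable == "recent_antibiotics", ]
  expect_identical(ab$exacerbation, "17 (41.5)")
  expect_identical(ab$no_exacerbation, "6 (2.8)")
  expect_identical(ab$overall, "23 (9.1)")
  expect_identical(sprintf("%.1f", 100 * 41 / 252), "16.3")

  q <- quantile(c(1, 2, 3, 4, 100), c(0.25, 0.5, 0.75), type = 7)
  expect_identical(unname(q), c(2, 3, 4))
})

test_that("between-group tests match hand-computed oracles", {
  dict <- data.frame(variable = c("v", "w", "b"),
                     type = c("mean_sd", "median_iqr", "n_pct"))
  co <- data.frame(exacerbation = rep(c(1, 0), each = 3),
                   v = c(1, 2, 3, 4, 5, 6), w = c(1, 2, 3, 4, 5, 6),
                   b = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
  # pooled t: mean diff -3, sp = 1, se = sqrt(2/3)
  tt <- compareGroups(co, "v", dict)
  expect_identical(tt$test, "t-test")
  expect_equal(tt$statistic, -3 / sqrt(2 / 3), tolerance = 1e-12)

  # identical values in both groups: degenerate p = 1
  same <- data.frame(exacerbation = rep(c(1, 0), each = 3), v = rep(2, 6))
  expect_identical(compareGroups(same, "v", dict)$p, 1)

  # 2x2 chi-squared (no continuity correction) against the closed form
  co2 <- data.frame(
    exacerbation = rep(c(1, 0), c(41, 211)),
    b = c(rep(TRUE, 17), rep(FALSE, 24), rep(TRUE, 6), rep(FALSE, 205)))
  ct <- compareGroups(co2, "b", dict)
  a <- 205; b <- 6; cc <- 24; d <- 17; n <- a + b + cc + d
  oracle <- n * (a * d - b * cc)^2 /
    ((a + b) * (cc + d) * (a + cc) * (b + d))
  expect_equal(ct$statistic, oracle, tolerance = 1e-6)
})

test_that("printed counts reproduce the study's prevalences and subset sizes", {
  counts <- referenceBaselineCounts()
  co <- buildReferenceCohort(counts)
  expect_identical(nrow(co), 361L)
  train <- co[co$split == "train", ]
  expect_identical(nrow(train), 252L)
  expect_identical(sum(train$exacerbation), 41L)
  expect_equal(round(100 * mean(train$exacerbation), 1), 16.3)
  val <- co[co$split == "validation", ]
  expect_equal(round(100 * mean(val$exacerbation), 1), 10.1)

  expect_identical(sum(!co$recent_antibiotics), 333L)
  expect_identical(sum(co$smoking_status != "current"), 338L)
  expect_identical(sum(co$ics_maintenance), 308L)
})

test_that("the consistency check flags the inconsistent printed ICS cell", {
  flagged <- checkBaselineConsistency()
  bad <- flagged[flagged$variable == "ics" &
                   flagged$group == "no_exacerbation" &
                   flagged$dataset == "training", ]
  expect_identical(nrow(bad), 1L)
  expect_identical(bad$printed_pct, 70.1)
  expect_equal(bad$recomputed_pct, 83.4)
  # the arithmetic used downstream always comes from the counts
  expect_false("recent_antibiotics" %in%
                 flagged$variable[flagged$dataset == "training"])
})

test_that("sensitivity subsets keep the split membership and report sizes", {
  d <- drawFeatures(140, 0.3, 1, seed = 70, nValidation = 70,
                    prevalenceValidation = 0.3)
  co <- d$cohort
  fs <- makeFeatureSet(as.matrix(d$x), co$exacerbation, split = co$split,
                       covars = co[c("recent_antibiotics", "smoking_status",
                                     "ics_maintenance")])
  cfg <- testConfig()
  out <- sensitivitySubsets(fs, config = cfg)
  expect_identical(names(out),
                   c("no_recent_antibiotics", "no_current_smokers",
                     "ics_only"))
  expect_identical(out$no_recent_antibiotics$n,
                   sum(!co$recent_antibiotics))
  expect_identical(out$no_current_smokers$n,
                   sum(co$smoking_status != "current"))
  expect_identical(out$ics_only$n, sum(co$ics_maintenance))
  # membership preserved: subset training count equals the filtered count
  expect_identical(out$ics_only$nTrain,
                   sum(co$ics_maintenance & co$split == "train"))
  # filters are pure and idempotent
  cd <- SummarizedExperiment::colData(fs)
  keep <- subsetRule("no_current_smokers")(cd)
  expect_identical(keep, subsetRule("no_current_smokers")(cd[, , drop = FALSE]))

  # a subset that loses a class errors naming the rule
  co2 <- co
  co2$ics_maintenance <- !(co2$exacerbation == 1)  # ICS-only drops all cases
  fs2 <- makeFeatureSet(as.matrix(d$x), co2$exacerbation,
                        split = co2$split,
                        covars = co2[c("recent_antibiotics",
                                       "smoking_status", "ics_maintenance")])
  expect_error(sensitivitySubsets(fs2, "ics_only", cfg), "ics_only")
})
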