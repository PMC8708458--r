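# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: AUC by exhaustive pair counting, least squares
# by the normal equations, spectra by FFT.

# concordance probability by brute force over all case-control pairs
aucPairCount <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# least-squares line via the normal equations
lsLineOracle <- function(t, x) {
  X <- cbind(1, t)
  drop(X %*% solve(crossprod(X), crossprod(X, x)))
}

# a minimal valid frame: one compound signal replicated over the 7 sensors
makeFrame <- function(breathSeries, ambientSeries = NULL, fs = 10,
                      tidal = 4, insp = 3, expd = 10) {
  n <- length(breathSeries)
  t <- (seq_len(n) - 1) / fs
  ends <- cumsum(c(rep(tidal, 5), insp, 5, expd))
  phases <- data.frame(
    phase = c(rep("tidal", 5), "inspiration", "breath_hold", "expiration"),
    t_start = c(0, ends[-8]), t_end = ends)
  if (is.null(ambientSeries)) ambientSeries <- numeric(n)
  SensorFrame("T001", t,
              matrix(breathSeries, n, 7), matrix(ambientSeries, n, 7),
              phases)
}

# feature set built directly from a feature matrix + labels (+ optional split)
makeFeatureSet <- function(x, labels, split = NULL, covars = NULL) {
  ids <- sprintf("S%04d", seq_len(nrow(x)))
  rownames(x) <- ids
  colnames(x) <- breathFeatureNames()
  cohort <- data.frame(subject_id = ids, exacerbation = as.integer(labels),
                       stringsAsFactors = FALSE)
  if (!is.null(split)) cohort$split <- split
  if (!is.null(covars)) cohort <- cbind(cohort, covars)
  assembleFeatureSet(x, cohort)
}

# generative feature draw bypassing traces, for discriminant-level tests
drawFeatures <- function(n, prevalence, delta, seed,
                         nValidation = 0, prevalenceValidation = 0.5) {
  spec <- cohortSpec(nTrain = n, nValidation = nValidation,
                     prevalenceTrain = prevalence,
                     prevalenceValidation = prevalenceValidation,
                     classSeparation = delta, seed = seed)
  sim <- simulateCohort(spec, maneuverProfile(), traces = FALSE)
  list(x = sim$featureTruth, labels = sim$cohort$exacerbation,
       split = sim$cohort$split, cohort = sim$cohort)
}

# fast test configuration (bootstrap kept light)
testConfig <- function(...) {
  pipelineConfig(nBootstrap = 200, notchFrequencies = 2.5, ...)
}
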