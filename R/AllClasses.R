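#' @import methods
#' @importFrom stats approx cor median pnorm prcomp qnorm quantile rbinom rlnorm
#'   rnorm runif sd var chisq.test t.test wilcox.test setNames predict
#'   plnorm qlnorm
#' @importFrom utils head read.delim write.table
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames colData
#' @importFrom S4Vectors DataFrame metadata
NULL

VALID_PHASES <- c("tidal", "inspiration", "breath_hold", "expiration")

setOldClass(c("PipelineConfig", "list"))

#' SensorFrame: one subject's raw or conditioned eNose maneuver
#'
#' Container for a single breath maneuver recorded by a SpiroNose-type
#' electronic nose: a shared, uniformly sampled time axis, seven
#' breath-channel and seven ambient-channel sensor series, and the phase
#' annotation of the maneuver (five tidal breaths, one full inspiration, a
#' 5 s breath hold, a slow maximal expiration).
#'
#' @slot subjectID single character identifier.
#' @slot time numeric vector of sample times in seconds, uniformly spaced.
#' @slot breath numeric matrix, one column per breath-channel sensor (7).
#' @slot ambient numeric matrix, one column per ambient-channel sensor (7).
#' @slot phases data.frame with columns `phase`, `t_start`, `t_end`;
#'   ordered, non-overlapping, phases drawn from
#'   tidal/inspiration/breath_hold/expiration.
#' @slot metadata list of provenance (generator truth, conditioning flags,
#'   chosen ambient lags, ...).
#'
#' @export
setClass("SensorFrame",
  representation(
    subjectID = "character",
    time = "numeric",
    breath = "matrix",
    ambient = "matrix",
    phases = "data.frame",
    metadata = "list"
  )
)

setValidity("SensorFrame", function(object) {
  msg <- character(0)
  n <- length(object@time)
  if (length(object@subjectID) != 1L) msg <- c(msg, "subjectID must be length 1")
  if (n < 2L) msg <- c(msg, "time axis needs at least 2 samples")
  dt <- diff(object@time)
  if (n >= 2L && (any(dt <= 0) || diff(range(dt)) > 1e-8 * mean(dt)))
    msg <- c(msg, "time axis must be strictly increasing and uniformly sampled")
  if (ncol(object@breath) != 7L) msg <- c(msg, "exactly 7 breath channels required")
  if (ncol(object@ambient) != 7L) msg <- c(msg, "exactly 7 ambient channels required")
  if (nrow(object@breath) != n || nrow(object@ambient) != n)
    msg <- c(msg, "breath/ambient rows must match the time axis")
  ph <- object@phases
  if (!all(c("phase", "t_start", "t_end") %in% names(ph))) {
    msg <- c(msg, "phases needs columns phase, t_start, t_end")
  } else {
    if (!all(ph$phase %in% VALID_PHASES))
      msg <- c(msg, paste0("unknown phase name(s): ",
                           paste(setdiff(ph$phase, VALID_PHASES), collapse = ", ")))
    if (any(ph$t_end <= ph$t_start))
      msg <- c(msg, "phase durations must be strictly positive")
    if (nrow(ph) > 1L && any(ph$t_start[-1] < ph$t_end[-nrow(ph)] - 1e-9))
      msg <- c(msg, "phases must be ordered and non-overlapping")
    if (!"breath_hold" %in% ph$phase)
      msg <- c(msg, "maneuver must contain a breath_hold phase")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SensorFrame
#'
#' @param subjectID subject identifier.
#' @param time numeric time axis (seconds), uniformly sampled.
#' @param breath,ambient numeric matrices with 7 columns each.
#' @param phases data.frame (`phase`, `t_start`, `t_end`).
#' @param metadata optional provenance list.
#' @return A [SensorFrame-class] object.
#' @export
SensorFrame <- function(subjectID, time, breath, ambient, phases,
                        metadata = list()) {
  breath <- as.matrix(breath)
  ambient <- as.matrix(ambient)
  if (is.null(colnames(breath))) colnames(breath) <- paste0("s", seq_len(ncol(breath)))
  if (is.null(colnames(ambient))) colnames(ambient) <- paste0("s", seq_len(ncol(ambient)))
  new("SensorFrame", subjectID = as.character(subjectID), time = as.numeric(time),
      breath = breath, ambient = ambient,
      phases = as.data.frame(phases), metadata = metadata)
}

#' ManeuverProfile: parameters of a simulated breath maneuver
#'
#' Describes the generative shape of one SpiroNose maneuver: sampling rate,
#' the phase schedule (five tidal cycles, inspiration, 5 s breath hold,
#' expiration), per-sensor clean response amplitudes, the breath-hold trough
#' depth as a fraction of the peak, ambient baseline level, linear drift,
#' white-noise level, injected resonance sinusoids, and the shared ambient
#' contaminant (amplitude and lag).
#'
#' @slot samplingRate samples per second.
#' @slot phaseSchedule data.frame (`phase`, `duration`) in maneuver order.
#' @slot amplitude numeric(7), clean expiration-peak conductance per sensor.
#' @slot troughDepth breath-hold trough as a fraction of the peak (0, 1].
#' @slot ambientLevel constant ambient-channel baseline.
#' @slot driftSlope additive linear drift, units/second.
#' @slot noiseSD white Gaussian noise standard deviation.
#' @slot resonance data.frame (`frequency`, `amplitude`) of injected
#'   resonance sinusoids (Hz).
#' @slot contaminantAmplitude amplitude of the shared ambient contaminant.
#' @slot contaminantLag lag (s) of the contaminant copy seen by the ambient
#'   channels relative to the breath channels.
#'
#' @export
setClass("ManeuverProfile",
  representation(
    samplingRate = "numeric",
    phaseSchedule = "data.frame",
    amplitude = "numeric",
    troughDepth = "numeric",
    ambientLevel = "numeric",
    driftSlope = "numeric",
    noiseSD = "numeric",
    resonance = "data.frame",
    contaminantAmplitude = "numeric",
    contaminantLag = "numeric"
  )
)

setValidity("ManeuverProfile", function(object) {
  msg <- character(0)
  if (object@samplingRate <= 0) msg <- c(msg, "samplingRate must be positive")
  sched <- object@phaseSchedule
  if (!all(c("phase", "duration") %in% names(sched))) {
    msg <- c(msg, "phaseSchedule needs columns phase, duration")
  } else {
    if (any(sched$duration <= 0)) msg <- c(msg, "phase durations must be positive")
    expected <- c(rep("tidal", 5), "inspiration", "breath_hold", "expiration")
    if (!identical(as.character(sched$phase), expected))
      msg <- c(msg, "phaseSchedule must be 5 tidal cycles, inspiration, breath_hold, expiration")
    if ("breath_hold" %in% sched$phase &&
        abs(sched$duration[sched$phase == "breath_hold"] - 5) > 1e-9)
      msg <- c(msg, "breath_hold duration must be 5 s")
  }
  if (length(object@amplitude) != 7L || any(object@amplitude <= 0))
    msg <- c(msg, "amplitude must be 7 positive values")
  if (object@troughDepth <= 0 || object@troughDepth > 1)
    msg <- c(msg, "troughDepth must be in (0, 1]")
  if (object@noiseSD < 0) msg <- c(msg, "noiseSD must be >= 0")
  if (nrow(object@resonance) &&
      any(object@resonance$frequency * 2 >= object@samplingRate))
    msg <- c(msg, "samplingRate must exceed twice the highest resonance frequency")
  if (length(msg)) msg else TRUE
})

#' CohortSpec: parameters of a simulated study cohort
#'
#' @slot nTrain,nValidation subject counts in the two parts (validation may
#'   be 0 for a single-part cohort).
#' @slot prevalenceTrain,prevalenceValidation class-1 (recent exacerbation)
#'   prevalence in each part.
#' @slot classSeparation Mahalanobis distance between the two class means in
#'   the 13-dimensional feature space.
#' @slot seed integer RNG seed.
#' @slot covariates named list of class-conditional covariate parameters
#'   (see [defaultCovariateFrequencies()]).
#'
#' @export
setClass("CohortSpec",
  representation(
    nTrain = "integer",
    nValidation = "integer",
    prevalenceTrain = "numeric",
    prevalenceValidation = "numeric",
    classSeparation = "numeric",
    seed = "integer",
    covariates = "list"
  )
)

setValidity("CohortSpec", function(object) {
  msg <- character(0)
  if (object@nTrain < 2L) msg <- c(msg, "nTrain must be >= 2")
  if (object@nValidation < 0L) msg <- c(msg, "nValidation must be >= 0")
  if (object@prevalenceTrain <= 0 || object@prevalenceTrain >= 1)
    msg <- c(msg, "prevalenceTrain must lie strictly in (0, 1)")
  if (object@nValidation > 0L &&
      (object@prevalenceValidation <= 0 || object@prevalenceValidation >= 1))
    msg <- c(msg, "prevalenceValidation must lie strictly in (0, 1)")
  if (object@classSeparation < 0) msg <- c(msg, "classSeparation must be >= 0")
  if (length(msg)) msg else TRUE
})

#' BreathFeatureSet: the 13-variable breathprint matrix with clinical data
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding the
#' 13 x n feature matrix (assay `"features"`: six sensor peaks normalized to
#' sensor 2 plus seven peak/breath-hold-trough ratios) with the clinical
#' covariates, the binary recent-exacerbation label and, once split, the
#' train/validation membership in `colData`.
#'
#' @export
setClass("BreathFeatureSet", contains = "SummarizedExperiment")

setValidity("BreathFeatureSet", function(object) {
  msg <- character(0)
  if (!"features" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'features' is required")
  if (nrow(object) != 13L)
    msg <- c(msg, "a breathprint has exactly 13 feature rows")
  if (!"exacerbation" %in% names(SummarizedExperiment::colData(object)))
    msg <- c(msg, "colData must contain the binary 'exacerbation' label")
  if (length(msg)) msg else TRUE
})

#' PCATransform: training-set standardization and rotation
#'
#' Correlation-scale principal-component transform fitted on the training
#' features only: per-feature means and standard deviations, the orthonormal
#' rotation (loadings), eigenvalues in descending order, and the indices of
#' components retained by the Kaiser criterion (eigenvalue >= 1).
#'
#' @slot means,sds numeric(13) training standardization parameters.
#' @slot rotation 13 x 13 orthonormal loading matrix, columns = components.
#' @slot eigenvalues numeric(13), descending, summing to 13.
#' @slot retained integer indices of Kaiser-retained components (a prefix).
#'
#' @export
setClass("PCATransform",
  representation(
    means = "numeric",
    sds = "numeric",
    rotation = "matrix",
    eigenvalues = "numeric",
    retained = "integer"
  )
)

setValidity("PCATransform", function(object) {
  msg <- character(0)
  p <- length(object@means)
  if (length(object@sds) != p || !all(dim(object@rotation) == p) ||
      length(object@eigenvalues) != p)
    msg <- c(msg, "inconsistent dimensions")
  g <- crossprod(object@rotation)
  if (max(abs(g - diag(p))) > 1e-8)
    msg <- c(msg, "rotation columns must be orthonormal")
  if (is.unsorted(rev(object@eigenvalues)))
    msg <- c(msg, "eigenvalues must be in descending order")
  if (abs(sum(object@eigenvalues) - p) > 1e-6)
    msg <- c(msg, sprintf("eigenvalues must sum to %d (correlation-scale PCA)", p))
  if (length(object@retained) == 0L ||
      !identical(object@retained, seq_along(object@retained)))
    msg <- c(msg, "retained must be a non-empty prefix of 1..p")
  if (length(msg)) msg else TRUE
})

#' LDAModel: two-class linear discriminant over retained components
#'
#' @slot direction unit-norm discriminant direction over the retained PCs,
#'   oriented so the exacerbation class has the higher mean score.
#' @slot threshold equal-prior decision boundary on the score scale
#'   (midpoint of the projected class means).
#' @slot classMeans 2 x k matrix of class mean vectors (rows: class 0, 1).
#' @slot priors class prior fractions, summing to 1.
#'
#' @export
setClass("LDAModel",
  representation(
    direction = "numeric",
    threshold = "numeric",
    classMeans = "matrix",
    priors = "numeric"
  )
)

setValidity("LDAModel", function(object) {
  msg <- character(0)
  if (abs(sqrt(sum(object@direction^2)) - 1) > 1e-8)
    msg <- c(msg, "direction must have unit norm")
  if (length(object@priors) != 2L || abs(sum(object@priors) - 1) > 1e-8 ||
      any(object@priors <= 0))
    msg <- c(msg, "priors must be two positive fractions summing to 1")
  if (length(msg)) msg else TRUE
})

#' DiscriminantResult: scores, ROC curve and AUC for one evaluation set
#'
#' @slot scores per-subject discriminant scores.
#' @slot labels binary labels (0/1) aligned with `scores`.
#' @slot roc data.frame (`fpr`, `tpr`, `threshold`) from (0,0) to (1,1).
#' @slot auc Mann-Whitney AUC (ties counted 1/2).
#' @slot aucCI percentile bootstrap interval, `c(low, high)` (NA if not run).
#' @slot nBootstrap bootstrap iteration count used for `aucCI`.
#'
#' @export
setClass("DiscriminantResult",
  representation(
    scores = "numeric",
    labels = "integer",
    roc = "data.frame",
    auc = "numeric",
    aucCI = "numeric",
    nBootstrap = "integer"
  )
)

setValidity("DiscriminantResult", function(object) {
  msg <- character(0)
  if (length(object@scores) != length(object@labels))
    msg <- c(msg, "scores and labels must align")
  if (!all(object@labels %in% c(0L, 1L)))
    msg <- c(msg, "labels must be 0/1")
  if (object@auc < 0 || object@auc > 1) msg <- c(msg, "auc must lie in [0, 1]")
  r <- object@roc
  if (nrow(r)) {
    if (any(abs(c(r$fpr[1], r$tpr[1])) > 1e-12) ||
        any(abs(c(r$fpr[nrow(r)], r$tpr[nrow(r)]) - 1) > 1e-12))
      msg <- c(msg, "roc must start at (0,0) and end at (1,1)")
    if (is.unsorted(r$fpr) || is.unsorted(r$tpr))
      msg <- c(msg, "roc must be monotone in both coordinates")
  }
  if (length(msg)) msg else TRUE
})

#' DiscriminantPipeline: the full result bundle of one pipeline run
#'
#' @slot training,validation [DiscriminantResult-class] for the
#'   resubstitution (training) and projected validation evaluations.
#' @slot loocv [DiscriminantResult-class] over the leave-one-out held-out
#'   scores of the training set.
#' @slot pca the training [PCATransform-class].
#' @slot lda the training [LDAModel-class].
#' @slot config resolved pipeline configuration (list).
#' @slot configHash short hash of the resolved configuration.
#'
#' @export
setClass("DiscriminantPipeline",
  representation(
    training = "DiscriminantResult",
    loocv = "DiscriminantResult",
    validation = "DiscriminantResult",
    pca = "PCATransform",
    lda = "LDAModel",
    config = "list",
    configHash = "character"
  )
)

setMethod("show", "SensorFrame", function(object) {
  cat("SensorFrame for subject", object@subjectID, "\n")
  cat(sprintf("  %d samples at %.3g Hz over %.1f s\n", length(object@time),
              1 / mean(diff(object@time)), max(object@time) - min(object@time)))
  cat("  7 breath + 7 ambient channels;",
      nrow(object@phases), "annotated phases\n")
})

setMethod("show", "ManeuverProfile", function(object) {
  cat("ManeuverProfile:", sum(object@phaseSchedule$duration), "s maneuver at",
      object@samplingRate, "samples/s\n")
  cat(sprintf("  trough depth %.2f, drift %.3g/s, noise sd %.3g, %d resonance component(s)\n",
              object@troughDepth, object@driftSlope, object@noiseSD,
              nrow(object@resonance)))
})

setMethod("show", "CohortSpec", function(object) {
  cat(sprintf("CohortSpec: %d training + %d validation subjects\n",
              object@nTrain, object@nValidation))
  cat(sprintf("  prevalence %.3f / %s, class separation (Mahalanobis) %.3f, seed %d\n",
              object@prevalenceTrain,
              ifelse(object@nValidation > 0,
                     sprintf("%.3f", object@prevalenceValidation), "-"),
              object@classSeparation, object@seed))
})

setMethod("show", "PCATransform", function(object) {
  cat("PCATransform (correlation scale) on", length(object@means), "features\n")
  cat("  eigenvalues:", paste(sprintf("%.2f", head(object@eigenvalues, 6)),
                              collapse = " "), "...\n")
  cat("  Kaiser-retained components:", length(object@retained), "\n")
})

setMethod("show", "LDAModel", function(object) {
  cat("LDAModel over", length(object@direction), "retained component(s)\n")
  cat(sprintf("  priors %.3f / %.3f, equal-prior threshold %.3f\n",
              object@priors[1], object@priors[2], object@threshold))
})

setMethod("show", "DiscriminantResult", function(object) {
  cat(sprintf("DiscriminantResult: n = %d (%d cases), AUC = %.3f",
              length(object@scores), sum(object@labels), object@auc))
  if (!anyNA(object@aucCI))
    cat(sprintf(" (95%%-CI %.3f-%.3f, %d bootstrap iterations)",
                object@aucCI[1], object@aucCI[2], object@nBootstrap))
  cat("\n")
})

setMethod("show", "DiscriminantPipeline", function(object) {
  cat("DiscriminantPipeline (config", object@configHash, ")\n")
  cat(sprintf("  retained components: %d\n", length(object@pca@retained)))
  fmt <- function(lbl, r) {
    ci <- if (anyNA(r@aucCI)) "" else
      sprintf(" (%.2f-%.2f)", r@aucCI[1], r@aucCI[2])
    cat(sprintf("  %-12s AUC %.3f%s  [n = %d]\n", lbl, r@auc, ci,
                length(r@scores)))
  }
  fmt("training", object@training)
  fmt("LOO-CV", object@loocv)
  fmt("validation", object@validation)
})
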