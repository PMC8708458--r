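# The statistical engine: standardize -> correlation-scale PCA with the
# Kaiser criterion -> two-class pooled-covariance LDA -> discriminant
# scores -> Mann-Whitney ROC/AUC, with leave-one-out cross-validation,
# stratified percentile-bootstrap confidence intervals, and projection of
# the held-out validation set through the training transform only.

#' Split a cohort into training and validation parts
#'
#' Simple random (by default unstratified) split at the stated fraction.
#' The training part gets `floor(n * trainFraction)` subjects. Errors if
#' either part would miss a class or be empty.
#'
#' @param fs a [BreathFeatureSet-class].
#' @param trainFraction fraction allocated to training (default 0.70).
#' @param seed integer seed making the split reproducible.
#' @param stratify if `TRUE`, split within each class at the same fraction.
#' @return the [BreathFeatureSet-class] with a `split` column
#'   (`"train"`/`"validation"`) added to `colData`.
#' @export
splitCohort <- function(fs, trainFraction = 0.70, seed = 1L,
                        stratify = FALSE) {
  stopifnot(is(fs, "BreathFeatureSet"))
  if (trainFraction <= 0 || trainFraction >= 1)
    stop("trainFraction must lie strictly in (0, 1)")
  n <- ncol(fs)
  labels <- exacerbationLabels(fs)
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  set.seed(as.integer(seed))
  if (stratify) {
    idxTrain <- unlist(lapply(unique(labels), function(l) {
      i <- which(labels == l)
      sample(i, floor(length(i) * trainFraction))
    }))
  } else {
    idxTrain <- sample.int(n, floor(n * trainFraction))
  }
  if (length(idxTrain) == 0L || length(idxTrain) == n)
    stop("split leaves an empty part; adjust trainFraction or n")
  split <- rep("validation", n)
  split[idxTrain] <- "train"
  for (part in c("train", "validation")) {
    lab <- labels[split == part]
    if (length(unique(lab)) < 2L)
      stop("class missing from the ", part,
           " part; try another seed or stratify = TRUE")
  }
  SummarizedExperiment::colData(fs)$split <- split
  fs
}

#' Kaiser-criterion component retention
#'
#' @param eigenvalues non-negative eigenvalues in descending order.
#' @param threshold retention threshold (inclusive), default 1.0.
#' @return integer indices of the components with eigenvalue >= threshold.
#'   Errors if no component qualifies.
#' @export
kaiserRetain <- function(eigenvalues, threshold = 1.0) {
  if (any(eigenvalues < 0) || is.unsorted(rev(eigenvalues)))
    stop("eigenvalues must be non-negative and in descending order")
  # small numerical slack: an exactly-unit eigenvalue may come back from
  # the eigendecomposition as 1 - epsilon and the threshold is inclusive
  idx <- which(eigenvalues >= threshold - 1e-9)
  if (!length(idx))
    stop("no eigenvalue reaches the retention threshold; model cannot be fit")
  seq_len(max(idx))
}

#' Fit the correlation-scale PCA transform on training features
#'
#' Z-scores every feature by its training mean and standard deviation, then
#' eigendecomposes the resulting correlation structure. Eigenvector signs
#' follow the convention that each component's largest-magnitude loading is
#' positive, making rotation matrices reproducible across runs.
#'
#' @param x numeric n x p matrix of training features (n > p, no constant
#'   column).
#' @param kaiserThreshold eigenvalue threshold for [kaiserRetain()].
#' @return a [PCATransform-class].
#' @export
fitPCA <- function(x, kaiserThreshold = 1.0) {
  x <- as.matrix(x)
  if (nrow(x) <= ncol(x))
    stop("need more observations than features (rank deficiency)")
  sds <- apply(x, 2, sd)
  if (any(sds == 0))
    stop("constant feature column(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  pc <- prcomp(x, center = TRUE, scale. = TRUE)
  rot <- pc$rotation
  for (j in seq_len(ncol(rot))) {
    k <- which.max(abs(rot[, j]))
    if (rot[k, j] < 0) rot[, j] <- -rot[, j]
  }
  ev <- pc$sdev^2
  new("PCATransform", means = pc$center, sds = pc$scale, rotation = rot,
      eigenvalues = ev, retained = kaiserRetain(ev, kaiserThreshold))
}

#' Project features onto the retained principal components
#'
#' Standardizes rows of `x` by the transform's (training) means and
#' standard deviations, rotates by the training rotation and restricts to
#' the Kaiser-retained components. No statistic of `x` itself is used.
#'
#' @param transform a [PCATransform-class].
#' @param x numeric matrix with the same feature columns as the training
#'   set.
#' @return n x k matrix of component scores.
#' @export
pcaScores <- function(transform, x) {
  x <- as.matrix(x)
  if (ncol(x) != length(transform@means))
    stop("feature column mismatch: expected ", length(transform@means),
         ", got ", ncol(x))
  if (!is.null(colnames(x)) && !is.null(names(transform@means)) &&
      !identical(colnames(x), names(transform@means)))
    stop("feature columns differ from training: expected [",
         paste(names(transform@means), collapse = ", "), "], got [",
         paste(colnames(x), collapse = ", "), "]")
  z <- sweep(sweep(x, 2, transform@means), 2, transform@sds, "/")
  z %*% transform@rotation[, transform@retained, drop = FALSE]
}

#' Fit a two-class pooled-covariance linear discriminant
#'
#' Fisher's LDA: the discriminant direction is `S_pooled^{-1} (mu1 - mu0)`,
#' normalized to unit length and oriented so the exacerbation class (label
#' 1) has the higher mean score.
#'
#' @param scores n x k matrix of (training) component scores.
#' @param labels binary 0/1 labels.
#' @return an [LDAModel-class].
#' @export
fitLDA <- function(scores, labels) {
  scores <- as.matrix(scores)
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be binary 0/1")
  n0 <- sum(labels == 0L); n1 <- sum(labels == 1L)
  if (n0 < 2L || n1 < 2L) stop("both classes need at least 2 observations")
  m0 <- colMeans(scores[labels == 0L, , drop = FALSE])
  m1 <- colMeans(scores[labels == 1L, , drop = FALSE])
  s0 <- var(scores[labels == 0L, , drop = FALSE])
  s1 <- var(scores[labels == 1L, , drop = FALSE])
  Sp <- ((n0 - 1) * s0 + (n1 - 1) * s1) / (n0 + n1 - 2)
  w <- tryCatch(solve(Sp, m1 - m0), error = function(e)
    stop("singular pooled covariance; retain fewer components"))
  nw <- sqrt(sum(w^2))
  if (nw == 0) stop("degenerate discriminant direction (equal class means)")
  w <- w / nw
  if (sum(w * (m1 - m0)) < 0) w <- -w
  new("LDAModel", direction = w,
      threshold = 0.5 * sum(w * (m0 + m1)),
      classMeans = rbind(`0` = m0, `1` = m1),
      priors = c(n0, n1) / (n0 + n1))
}

#' Discriminant scores under a fitted LDA model
#'
#' @param model an [LDAModel-class].
#' @param scores n x k matrix of component scores.
#' @return numeric vector of scalar discriminant scores.
#' @export
ldaScores <- function(model, scores) {
  scores <- as.matrix(scores)
  if (ncol(scores) != length(model@direction))
    stop("component count mismatch with the fitted direction")
  drop(scores %*% model@direction)
}

#' Mann-Whitney AUC
#'
#' The AUC as the concordance probability that a random case scores above a
#' random control, ties counted 1/2 (equivalently the normalized
#' Mann-Whitney U statistic).
#'
#' @param scores numeric scores.
#' @param labels binary 0/1 labels (both classes present).
#' @return AUC in `[0, 1]`.
#' @export
mannWhitneyAUC <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve and AUC
#'
#' Builds the empirical ROC curve with one vertex per distinct threshold
#' (thresholds swept from +Inf downwards; a subject is called positive when
#' its score is >= the threshold) and the Mann-Whitney AUC.
#'
#' @param scores numeric scores (higher = more case-like).
#' @param labels binary 0/1 labels.
#' @return list with `roc` (data.frame `fpr`, `tpr`, `threshold`, from
#'   (0,0) to (1,1)) and `auc`.
#' @export
rocAuc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  keep <- !duplicated(s, fromLast = TRUE)  # last index of each distinct score
  tp <- cumsum(l)[keep]; fp <- cumsum(1 - l)[keep]
  roc <- data.frame(fpr = c(0, fp / n0), tpr = c(0, tp / n1),
                    threshold = c(Inf, s[keep]))
  list(roc = roc, auc = mannWhitneyAUC(scores, labels))
}

.discriminantResult <- function(scores, labels, ci = c(NA_real_, NA_real_),
                                nBootstrap = 0L) {
  r <- rocAuc(scores, labels)
  new("DiscriminantResult", scores = as.numeric(scores),
      labels = as.integer(labels), roc = r$roc, auc = r$auc,
      aucCI = ci, nBootstrap = as.integer(nBootstrap))
}

#' Leave-one-out cross-validated discriminant scores
#'
#' Each subject is scored by a discriminant fitted without it. Under the
#' default scope (`"lda_only"`) the standardization/PCA transform is fitted
#' once on the full training set and only the LDA stage is refit per fold
#' (the usual `CV = TRUE` idiom); `"full_pipeline"` refits standardization
#' and PCA inside every fold as well.
#'
#' @param x n x 13 training feature matrix.
#' @param labels binary 0/1 labels (n >= 10, both classes with >= 2
#'   members so no fold loses a class).
#' @param kaiserThreshold eigenvalue retention threshold.
#' @param scope `"lda_only"` or `"full_pipeline"`.
#' @return numeric vector of held-out scores, one per subject.
#' @export
loocvScores <- function(x, labels, kaiserThreshold = 1.0,
                        scope = c("lda_only", "full_pipeline")) {
  scope <- match.arg(scope)
  x <- as.matrix(x)
  labels <- as.integer(labels)
  n <- nrow(x)
  if (n < 10L) stop("leave-one-out needs at least 10 subjects")
  if (min(table(factor(labels, c(0, 1)))) < 2L)
    stop("a fold would lose a class entirely; need >= 2 subjects per class")
  out <- numeric(n)
  if (scope == "lda_only") {
    pcs <- pcaScores(fitPCA(x, kaiserThreshold), x)
    for (i in seq_len(n)) {
      m <- fitLDA(pcs[-i, , drop = FALSE], labels[-i])
      out[i] <- ldaScores(m, pcs[i, , drop = FALSE])
    }
  } else {
    for (i in seq_len(n)) {
      tr <- fitPCA(x[-i, , drop = FALSE], kaiserThreshold)
      m <- fitLDA(pcaScores(tr, x[-i, , drop = FALSE]), labels[-i])
      out[i] <- ldaScores(m, pcaScores(tr, x[i, , drop = FALSE]))
    }
  }
  out
}

#' Leave-one-out cross-validated AUC
#'
#' @inheritParams loocvScores
#' @return AUC over the n held-out scores.
#' @export
loocvAuc <- function(x, labels, kaiserThreshold = 1.0,
                     scope = c("lda_only", "full_pipeline")) {
  mannWhitneyAUC(loocvScores(x, labels, kaiserThreshold, scope), labels)
}

#' Stratified percentile-bootstrap confidence interval for the AUC
#'
#' Resamples cases and controls separately with replacement (preserving
#' class sizes), recomputes the Mann-Whitney AUC per resample and returns
#' the percentile interval.
#'
#' @param scores numeric scores.
#' @param labels binary 0/1 labels (>= 2 per class).
#' @param nIter bootstrap iterations (>= 100; the study-scale default is
#'   10,000).
#' @param level confidence level (default 0.95).
#' @param seed integer seed making the interval reproducible.
#' @return numeric `c(low, high)`.
#' @export
bootstrapCI <- function(scores, labels, nIter = 10000, level = 0.95,
                        seed = 1L) {
  labels <- as.integer(labels)
  if (nIter < 100) stop("nIter must be at least 100")
  i0 <- which(labels == 0L); i1 <- which(labels == 1L)
  if (length(i0) < 2L || length(i1) < 2L)
    stop("each class needs at least 2 observations to resample")
  set.seed(as.integer(seed))
  aucs <- vapply(seq_len(nIter), function(b) {
    idx <- c(sample(i0, replace = TRUE), sample(i1, replace = TRUE))
    mannWhitneyAUC(scores[idx], labels[idx])
  }, numeric(1))
  unname(quantile(aucs, c((1 - level) / 2, (1 + level) / 2)))
}

#' Project a validation set through the training transform and model
#'
#' Validation rows are standardized by the training means/sds, rotated by
#' the training rotation, restricted to the retained components and scored
#' by the training LDA; nothing is refit and no validation statistic enters
#' the projection.
#'
#' @param x validation feature matrix (same 13 columns as training).
#' @param transform the training [PCATransform-class].
#' @param model the training [LDAModel-class].
#' @param labels validation 0/1 labels.
#' @return a [DiscriminantResult-class] (bootstrap CI not yet filled in).
#' @export
projectValidation <- function(x, transform, model, labels) {
  .discriminantResult(ldaScores(model, pcaScores(transform, x)), labels)
}

#' Run the full discriminant pipeline on a feature set
#'
#' Executes split (if not already present) -> correlation-scale PCA with
#' Kaiser retention -> LDA -> resubstitution ROC/AUC -> leave-one-out
#' cross-validated AUC -> stratified bootstrap CIs (training, LOO and
#' validation scores) -> projection of the validation part through the
#' training transform.
#'
#' @param fs a [BreathFeatureSet-class]; if `colData(fs)$split` exists it is
#'   honored (sensitivity reruns keep the original membership), otherwise
#'   [splitCohort()] is applied with the configured fraction and seed.
#' @param config a [pipelineConfig()] list.
#' @return a [DiscriminantPipeline-class].
#' @export
runDiscriminantPipeline <- function(fs, config = pipelineConfig()) {
  stopifnot(is(fs, "BreathFeatureSet"))
  cd <- SummarizedExperiment::colData(fs)
  if (!"split" %in% names(cd)) {
    fs <- splitCohort(fs, config$trainFraction, config$seeds$split,
                      stratify = isTRUE(config$stratifySplit))
    cd <- SummarizedExperiment::colData(fs)
  }
  x <- featureMatrix(fs)
  labels <- exacerbationLabels(fs)
  isTr <- cd$split == "train"
  if (!any(isTr) || !any(!isTr))
    stop("both a training and a validation part are required")
  xtr <- x[isTr, , drop = FALSE]; ytr <- labels[isTr]
  xva <- x[!isTr, , drop = FALSE]; yva <- labels[!isTr]

  pca <- fitPCA(xtr, config$kaiserThreshold)
  pcs <- pcaScores(pca, xtr)
  lda <- fitLDA(pcs, ytr)
  strain <- ldaScores(lda, pcs)
  sloo <- loocvScores(xtr, ytr, config$kaiserThreshold, config$loocvScope)

  bseed <- as.integer(config$seeds$bootstrap)
  training <- .discriminantResult(
    strain, ytr,
    ci = bootstrapCI(strain, ytr, config$nBootstrap, config$bootstrapLevel,
                     seed = bseed),
    nBootstrap = config$nBootstrap)
  loocv <- .discriminantResult(
    sloo, ytr,
    ci = bootstrapCI(sloo, ytr, config$nBootstrap, config$bootstrapLevel,
                     seed = bseed + 1L),
    nBootstrap = config$nBootstrap)
  validation <- projectValidation(xva, pca, lda, yva)
  validation@aucCI <- bootstrapCI(validation@scores, yva, config$nBootstrap,
                                  config$bootstrapLevel, seed = bseed + 2L)
  validation@nBootstrap <- as.integer(config$nBootstrap)

  new("DiscriminantPipeline", training = training, loocv = loocv,
      validation = validation, pca = pca, lda = lda, config = config,
      configHash = configHash(config))
}
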