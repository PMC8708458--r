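# The statistical engine: split, correlation-scale PCA with Kaiser
# retention, pooled-covariance LDA, Mann-Whitney ROC/AUC, LOO-CV,
# stratified bootstrap and validation projection — each against an
# independent oracle (pair counting, closed forms, MASS/pROC, explicit
# fold loops, explicit matrix arithmetic).

test_that("the 70/30 split has the expected sizes and is reproducible", {
  d <- drawFeatures(361, 0.15, 0, seed = 1)
  fs <- makeFeatureSet(d$x, d$labels)
  sp <- splitCohort(fs, 0.70, seed = 5)
  split <- SummarizedExperiment::colData(sp)$split
  expect_identical(sum(split == "train"), 252L)
  expect_identical(sum(split == "validation"), 109L)
  sp2 <- splitCohort(fs, 0.70, seed = 5)
  expect_identical(split, SummarizedExperiment::colData(sp2)$split)
  expect_false(identical(split,
                         SummarizedExperiment::colData(
                           splitCohort(fs, 0.70, seed = 6))$split))

  tiny <- makeFeatureSet(d$x[1:6, ], c(0, 1, 0, 1, 0, 1))
  expect_error(splitCohort(tiny, 0.99, seed = 1), "empty|class")
})

test_that("correlation-scale PCA satisfies its closed forms", {
  set.seed(10)
  x <- matrix(rnorm(4000 * 13), 4000, 13)
  colnames(x) <- breathFeatureNames()
  # independent features: all eigenvalues near 1, all retained
  p <- fitPCA(x)
  expect_equal(sum(eigenvalues(p)), 13, tolerance = 1e-6)
  expect_true(all(abs(eigenvalues(p) - 1) < 0.15))
  expect_lt(max(abs(crossprod(rotationMatrix(p)) - diag(13))), 1e-8)
  expect_lt(max(abs(tcrossprod(rotationMatrix(p)) - diag(13))), 1e-8)

  # 2-feature toy with exact sample correlation rho: eigenvalues 1 +/- rho
  rho <- 0.6
  set.seed(2)
  a <- scale(rnorm(500)); b <- scale(residuals(lm.fit(a, rnorm(500))))
  y <- cbind(drop(a), rho * drop(a) + sqrt(1 - rho^2) * drop(b))
  ev <- eigen(cor(y))$values
  expect_equal(ev, c(1 + rho, 1 - rho), tolerance = 1e-10)
  p2 <- prcomp(y, scale. = TRUE)
  expect_equal(sort(p2$sdev^2, decreasing = TRUE), c(1 + rho, 1 - rho),
               tolerance = 1e-10)

  # degenerate inputs
  xc <- x[1:100, ]; xc[, 4] <- 2
  expect_error(fitPCA(xc), "constant")
  expect_error(fitPCA(x[1:10, ]), "rank|observations")
})

test_that("Kaiser retention is inclusive at the threshold", {
  expect_identical(kaiserRetain(c(2.5, 1.2, 1.0, 0.3, 0.1)), 1:3)
  expect_identical(kaiserRetain(rep(1, 13)), 1:13)
  expect_error(kaiserRetain(c(0.9, 0.5)), "threshold")
  expect_error(kaiserRetain(c(0.5, 0.9)))
})

test_that("LDA recovers the Fisher direction and matches MASS", {
  # closed form: direction parallel to Sigma^-1 (mu1 - mu0). The latent
  # covariance is ill-conditioned (eigenvalues 3.43 .. 0.19), so the
  # sampling angle shrinks slowly; n is sized for a 2-degree bound.
  mod <- breathprint:::.latentModel()
  set.seed(3)
  n <- 300000; delta <- 3
  y <- rbinom(n, 1, 0.5)
  xl <- matrix(rnorm(n * 4), n, 4) %*% t(mod$loadings) +
    matrix(rnorm(n * 13, 0, mod$uniqueSD), n, 13) +
    outer(y, delta * mod$deltaUnit)
  m <- fitLDA(xl, y)
  wTrue <- solve(mod$Sigma, mod$deltaUnit)  # scale-free Fisher direction
  cosang <- sum(discriminantDirection(m) * wTrue) /
    sqrt(sum(wTrue^2))
  expect_gt(abs(cosang), cos(2 * pi / 180))

  d <- drawFeatures(2000, 0.5, 1.5, seed = 3)
  x <- as.matrix(d$x)
  m <- fitLDA(x, d$labels)
  ml <- MASS::lda(x, grouping = d$labels)
  wm <- ml$scaling[, 1]; wm <- wm / sqrt(sum(wm^2))
  expect_gt(abs(sum(discriminantDirection(m) * wm)), 1 - 1e-8)

  # 1-D symmetric classes: equal-prior threshold at 0
  set.seed(4)
  s1 <- matrix(c(rnorm(50, -1), rnorm(50, 1)), ncol = 1)
  m1 <- fitLDA(s1, rep(c(0, 1), each = 50))
  mu <- (mean(s1[1:50, ]) + mean(s1[51:100, ])) / 2
  expect_equal(m1@threshold, mu * m1@direction, tolerance = 1e-12)

  # duplicating every observation leaves the direction unchanged
  m2 <- fitLDA(rbind(x, x), c(d$labels, d$labels))
  expect_equal(discriminantDirection(m2), discriminantDirection(m),
               tolerance = 1e-9)
})

test_that("AUC equals exhaustive Mann-Whitney pair counting, including ties", {
  expect_identical(mannWhitneyAUC(c(1, 2), c(0, 1)), 1)
  expect_equal(mannWhitneyAUC(c(1, 2, 2, 3), c(0, 0, 1, 1)), 0.875)
  expect_equal(aucPairCount(c(1, 2, 2, 3), c(0, 0, 1, 1)), 0.875)
  set.seed(8)
  for (i in 1:20) {
    nn <- sample(10:200, 1)
    labels <- rbinom(nn, 1, 0.4)
    if (length(unique(labels)) < 2) next
    scores <- sample(round(rnorm(nn), sample(0:2, 1)))  # force ties
    expect_equal(mannWhitneyAUC(scores, labels),
                 aucPairCount(scores, labels))
    # label-swap symmetry
    expect_equal(mannWhitneyAUC(scores, 1 - labels),
                 1 - mannWhitneyAUC(scores, labels))
  }
  set.seed(9)
  scores <- rnorm(1000); labels <- rbinom(1000, 1, 0.5)
  expect_lt(abs(mannWhitneyAUC(scores, labels) - 0.5), 0.03)
  expect_error(mannWhitneyAUC(1:3, c(1, 1, 1)), "both classes")
})

test_that("the ROC curve is a valid staircase agreeing with pROC", {
  set.seed(12)
  scores <- round(rnorm(80), 1); labels <- rbinom(80, 1, 0.3)
  r <- rocAuc(scores, labels)
  expect_identical(r$roc$fpr[1], 0); expect_identical(r$roc$tpr[1], 0)
  expect_identical(r$roc$fpr[nrow(r$roc)], 1)
  expect_identical(r$roc$tpr[nrow(r$roc)], 1)
  expect_false(is.unsorted(r$roc$fpr)); expect_false(is.unsorted(r$roc$tpr))
  pr <- pROC::roc(labels, scores, direction = "<", quiet = TRUE)
  expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
  # trapezoid area under our own staircase equals the Mann-Whitney AUC
  area <- sum(diff(r$roc$fpr) * (head(r$roc$tpr, -1) + r$roc$tpr[-1]) / 2)
  expect_equal(area, r$auc, tolerance = 1e-12)
})

test_that("LOO-CV equals an explicit fold-by-fold oracle", {
  # 12-subject toy with hand-chosen 1-D scores
  x <- matrix(c(0.2, 1.4, -0.5, 2.1, 0.9, 1.1,
                -1.3, 0.4, 1.8, -0.2, 0.6, 2.4), ncol = 1)
  labels <- rep(c(0, 1), 6)

  pcs <- pcaScores(fitPCA(x), x)
  oracle <- vapply(1:12, function(i) {
    m <- fitLDA(pcs[-i, , drop = FALSE], labels[-i])
    ldaScores(m, pcs[i, , drop = FALSE])
  }, numeric(1))
  expect_identical(loocvScores(x, labels), oracle)
  expect_identical(loocvAuc(x, labels), mannWhitneyAUC(oracle, labels))

  # full-pipeline scope against its own explicit loop
  oracleFull <- vapply(1:12, function(i) {
    tr <- fitPCA(x[-i, , drop = FALSE])
    m <- fitLDA(pcaScores(tr, x[-i, , drop = FALSE]), labels[-i])
    ldaScores(m, pcaScores(tr, x[i, , drop = FALSE]))
  }, numeric(1))
  expect_identical(loocvScores(x, labels, scope = "full_pipeline"),
                   oracleFull)

  # widely separated classes: every held-out subject sorts correctly
  d <- drawFeatures(60, 0.5, 6, seed = 21)
  expect_identical(loocvAuc(as.matrix(d$x), d$labels), 1)

  expect_error(loocvScores(x[1:8, ], labels[1:8]), "at least 10")
  expect_error(loocvScores(x, c(1, rep(0, 11))), "class")
})

test_that("stratified bootstrap CIs are reproducible and match an independent oracle", {
  set.seed(30)
  scores <- c(rnorm(160), rnorm(40, 1.4))  # about AUC 0.84
  labels <- rep(c(0, 1), c(160, 40))

  expect_identical(bootstrapCI(scores, labels, 200, seed = 7),
                   bootstrapCI(scores, labels, 200, seed = 7))

  # oracle sharing the resample sequence, AUC by pair counting
  i0 <- which(labels == 0); i1 <- which(labels == 1)
  set.seed(99)
  oa <- vapply(1:200, function(b) {
    idx <- c(sample(i0, replace = TRUE), sample(i1, replace = TRUE))
    aucPairCount(scores[idx], labels[idx])
  }, numeric(1))
  oracle <- unname(quantile(oa, c(0.025, 0.975)))
  expect_equal(bootstrapCI(scores, labels, 200, seed = 99), oracle,
               tolerance = 1e-12)

  # perfectly separated scores: every resample has AUC 1
  ci <- bootstrapCI(c(1, 2, 3, 11, 12, 13), c(0, 0, 0, 1, 1, 1), 200,
                    seed = 1)
  expect_identical(ci, c(1, 1))

  # interval width sane and covering the large-sample AUC near 0.76
  delta <- separationForTargetAUC(0.76)
  set.seed(31)
  s2 <- c(rnorm(160), rnorm(40, delta)); l2 <- rep(c(0, 1), c(160, 40))
  ci2 <- bootstrapCI(s2, l2, 2000, seed = 2)
  expect_gt(diff(ci2), 0.05); expect_lt(diff(ci2), 0.25)
  expect_gt(0.76, ci2[1] - 0.05); expect_lt(0.76, ci2[2] + 0.05)

  expect_error(bootstrapCI(1:5, c(0, 0, 0, 0, 1), 200), "at least 2")
  expect_error(bootstrapCI(scores, labels, 50), "nIter")
})

test_that("validation projection uses training statistics only", {
  d <- drawFeatures(150, 0.3, 1, seed = 40)
  x <- as.matrix(d$x)
  pca <- fitPCA(x)
  lda <- fitLDA(pcaScores(pca, x), d$labels)

  # validation = copy of training: identical AUC by construction
  res <- projectValidation(x, pca, lda, d$labels)
  expect_identical(auc(res),
                   mannWhitneyAUC(ldaScores(lda, pcaScores(pca, x)),
                                  d$labels))

  # a row equal to the training means maps to the origin
  expect_equal(unname(pcaScores(pca, matrix(pca@means, 1))),
               matrix(0, 1, length(retainedComponents(pca))),
               tolerance = 1e-12)

  # explicit matrix-arithmetic oracle
  set.seed(41)
  xv <- matrix(rnorm(30 * 13, 1, 2), 30, 13,
               dimnames = list(NULL, colnames(x)))
  lv <- rbinom(30, 1, 0.5); lv[1:2] <- c(0, 1)
  res2 <- projectValidation(xv, pca, lda, lv)
  oracle <- (sweep(sweep(xv, 2, pca@means), 2, pca@sds, "/") %*%
               pca@rotation[, retainedComponents(pca)]) %*%
    discriminantDirection(lda)
  expect_lt(max(abs(discriminantScores(res2) - oracle)), 1e-10)

  # corrupting validation labels must not change the scores
  res3 <- projectValidation(xv, pca, lda, 1 - lv)
  expect_identical(discriminantScores(res3), discriminantScores(res2))

  expect_error(projectValidation(xv[, 1:12], pca, lda, lv), "mismatch")
})

test_that("AUCs are invariant to affine rescaling of any feature", {
  d <- drawFeatures(120, 0.3, 1.2, seed = 50, nValidation = 60)
  fs <- makeFeatureSet(as.matrix(d$x), d$labels, split = d$split)
  cfg <- testConfig()
  r1 <- runDiscriminantPipeline(fs, cfg)
  x2 <- as.matrix(d$x)
  x2[, 3] <- x2[, 3] * 40 - 7
  x2[, 9] <- x2[, 9] / 5 + 100
  r2 <- runDiscriminantPipeline(makeFeatureSet(x2, d$labels,
                                               split = d$split), cfg)
  expect_equal(auc(trainingResult(r1)), auc(trainingResult(r2)),
               tolerance = 1e-9)
  expect_equal(auc(loocvResult(r1)), auc(loocvResult(r2)), tolerance = 1e-9)
  expect_equal(auc(validationResult(r1)), auc(validationResult(r2)),
               tolerance = 1e-9)
})

test_that("the pipeline bundle is deterministic given config and seeds", {
  d <- drawFeatures(100, 0.3, 1, seed = 60, nValidation = 50)
  fs <- makeFeatureSet(as.matrix(d$x), d$labels, split = d$split)
  cfg <- testConfig()
  r1 <- runDiscriminantPipeline(fs, cfg)
  r2 <- runDiscriminantPipeline(fs, cfg)
  expect_identical(writeResultBundle(r1), writeResultBundle(r2))
  expect_identical(r1@configHash, r2@configHash)
  expect_s4_class(trainingResult(r1), "DiscriminantResult")
  expect_false(anyNA(aucCI(loocvResult(r1))))
})
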