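# Synthetic eNose maneuvers and cohorts.
#
# The generative core lives in feature space: per-subject 13-vectors are
# drawn from a 4-latent-factor Gaussian (mimicking the cross-reactive,
# multicollinear sensor responses), the exacerbation class receives a mean
# shift of a chosen Mahalanobis size, and raw sensor maneuvers are then
# back-solved so that noise-free conditioning + feature extraction recovers
# the drawn features exactly. This makes the optimal AUC of the simulated
# problem available in closed form: Phi(Delta / sqrt(2)).

#' Names of the 13 breathprint variables
#'
#' Six sensor peaks normalized to sensor 2 (`npk_s1`, `npk_s3`..`npk_s7`)
#' followed by seven per-sensor peak / breath-hold-trough ratios
#' (`pt_s1`..`pt_s7`).
#'
#' @return character(13).
#' @export
breathFeatureNames <- function() {
  c(paste0("npk_s", c(1L, 3:7)), paste0("pt_s", 1:7))
}

# harmonics (cycles over the full maneuver) of the shared ambient
# contaminant; high enough that the autocorrelation is sharply peaked (so
# cross-correlation alignment is well-posed) yet below the low-pass cutoff
CONTAMINANT_CYCLES <- c(10, 14, 17)
CONTAMINANT_WEIGHTS <- c(1, 0.8, 0.6)

#' Construct a ManeuverProfile
#'
#' Defaults describe a 38 s maneuver sampled at 10 samples/s: five 4 s tidal
#' cycles, a 3 s full inspiration, the 5 s breath hold and a 10 s slow
#' maximal expiration. The sampling rate and phase durations beyond the 5 s
#' hold are conventions of this generator (the maneuver protocol fixes only
#' the phase sequence and the hold length), chosen so that the whole
#' maneuver and its sub-Hz artifacts are comfortably resolved.
#'
#' @param samplingRate samples per second (> 0).
#' @param tidalDuration,inspirationDuration,expirationDuration phase
#'   durations in seconds (breath hold is fixed at 5 s).
#' @param amplitude numeric(7) clean expiration-peak amplitude per sensor
#'   (dimensionless conductance units); sensor 2 is the normalization
#'   reference and is given the largest, most stable response.
#' @param troughDepth breath-hold trough as a fraction of the peak.
#' @param ambientLevel constant baseline of the ambient channels.
#' @param driftSlope additive linear drift (units/s) on the breath channels.
#' @param noiseSD white Gaussian noise sd on all channels.
#' @param resonance data.frame (`frequency`, `amplitude`) of injected
#'   resonance sinusoids; default one component at 2.5 Hz.
#' @param contaminantAmplitude amplitude of the shared ambient contaminant
#'   (an integer-cycle cosine mixture, hence orthogonal to a linear trend).
#' @param contaminantLag lag (s) between the contaminant as seen by the
#'   breath channels and its copy on the ambient channels.
#' @return A [ManeuverProfile-class].
#' @export
maneuverProfile <- function(samplingRate = 10,
                            tidalDuration = 4,
                            inspirationDuration = 3,
                            expirationDuration = 10,
                            amplitude = c(1.6, 2.0, 1.2, 1.8, 1.4, 1.0, 1.5),
                            troughDepth = 0.5,
                            ambientLevel = 0.2,
                            driftSlope = 0.005,
                            noiseSD = 0.02,
                            resonance = data.frame(frequency = 2.5,
                                                   amplitude = 0.05),
                            contaminantAmplitude = 0.1,
                            contaminantLag = 0.5) {
  sched <- data.frame(
    phase = c(rep("tidal", 5), "inspiration", "breath_hold", "expiration"),
    duration = c(rep(tidalDuration, 5), inspirationDuration, 5,
                 expirationDuration),
    stringsAsFactors = FALSE
  )
  new("ManeuverProfile", samplingRate = samplingRate, phaseSchedule = sched,
      amplitude = amplitude, troughDepth = troughDepth,
      ambientLevel = ambientLevel, driftSlope = driftSlope, noiseSD = noiseSD,
      resonance = as.data.frame(resonance),
      contaminantAmplitude = contaminantAmplitude,
      contaminantLag = contaminantLag)
}

#' Construct a CohortSpec
#'
#' Defaults reproduce the study design emulated by this package: 252
#' training and 109 validation subjects with recent-exacerbation prevalences
#' 0.163 and 0.101, and a feature-space class separation calibrated to a
#' target AUC of 0.76.
#'
#' @param nTrain,nValidation subject counts (set `nValidation = 0` for a
#'   single-part cohort).
#' @param prevalenceTrain,prevalenceValidation class-1 prevalences.
#' @param classSeparation Mahalanobis distance between class means in the
#'   13-dimensional feature space.
#' @param seed integer RNG seed.
#' @param covariates class-conditional covariate parameters; see
#'   [defaultCovariateFrequencies()].
#' @return A [CohortSpec-class].
#' @export
cohortSpec <- function(nTrain = 252, nValidation = 109,
                       prevalenceTrain = 0.163, prevalenceValidation = 0.101,
                       classSeparation = separationForTargetAUC(0.76),
                       seed = 1L,
                       covariates = defaultCovariateFrequencies()) {
  new("CohortSpec", nTrain = as.integer(nTrain),
      nValidation = as.integer(nValidation),
      prevalenceTrain = prevalenceTrain,
      prevalenceValidation = if (nValidation > 0) prevalenceValidation else NA_real_,
      classSeparation = classSeparation, seed = as.integer(seed),
      covariates = covariates)
}

#' Mahalanobis separation achieving a target optimal AUC
#'
#' For two homoscedastic Gaussian classes whose means differ by Mahalanobis
#' distance Delta, the AUC of the optimal (Fisher) score is
#' Phi(Delta / sqrt(2)); this inverts that relation.
#'
#' @param targetAuc desired AUC in `[0.5, 1)`.
#' @return Delta = sqrt(2) * qnorm(targetAuc).
#' @seealso [theoreticalAUC()]
#' @export
separationForTargetAUC <- function(targetAuc) {
  if (!is.numeric(targetAuc) || targetAuc < 0.5 || targetAuc >= 1)
    stop("targetAuc must lie in [0.5, 1)")
  sqrt(2) * qnorm(targetAuc)
}

#' Optimal AUC of two homoscedastic Gaussian classes
#'
#' @param delta Mahalanobis distance between the class means.
#' @return Phi(delta / sqrt(2)).
#' @export
theoreticalAUC <- function(delta) pnorm(delta / sqrt(2))

# 4-latent-factor model for the 13 features (unit per-feature variance).
# Blocks of 4/3/3/3 features load one factor each with loading 0.9, so the
# population correlation matrix has exactly four eigenvalues >= 1
# (3.43, 2.62, 2.62, 2.62) and nine at 0.19.
.latentModel <- function() {
  blocks <- rep(1:4, times = c(4, 3, 3, 3))
  loading <- 0.9
  L <- matrix(0, 13, 4)
  L[cbind(seq_len(13), blocks)] <- loading
  uniqueSD <- sqrt(1 - loading^2)
  Sigma <- tcrossprod(L) + diag(uniqueSD^2, 13)
  eg <- eigen(Sigma, symmetric = TRUE)
  e1 <- eg$vectors[, 1]
  if (sum(e1) < 0) e1 <- -e1
  # a unit-Mahalanobis shift confined to the leading factor direction
  deltaUnit <- sqrt(eg$values[1]) * e1
  list(loadings = L, uniqueSD = uniqueSD, Sigma = Sigma,
       deltaUnit = deltaUnit, featureScale = 0.12)
}

# baseline (class-0, noiseless) feature means implied by a profile
.baselineFeatures <- function(profile) {
  amp <- profile@amplitude
  f <- c(amp[c(1L, 3:7)] / amp[2L], rep(1 / profile@troughDepth, 7))
  names(f) <- breathFeatureNames()
  f
}

# shared ambient contaminant, evaluated analytically at arbitrary times
.contaminant <- function(profile, t, lag = 0) {
  T <- sum(profile@phaseSchedule$duration)
  w <- 2 * pi * CONTAMINANT_CYCLES / T
  profile@contaminantAmplitude *
    drop(cos(outer(t - lag, w)) %*% CONTAMINANT_WEIGHTS)
}

# Clean maneuver shape templates. clean_s(t) = peak_s * P(t) + trough_s * Q(t),
# with P, Q made exactly orthogonal (in the discrete least-squares sense) to
# span{1, t, cos/sin at the contaminant harmonics} by a minimum-norm
# baseline offset confined to the tidal window. Whole-maneuver linear
# detrending is then a no-op on the clean component (conditioning preserves
# the generator's peak and trough levels), and the clean maneuver carries
# no energy at the contaminant frequencies (so cross-correlation alignment
# is driven by the contaminant alone).
.cleanTemplates <- function(profile) {
  sched <- profile@phaseSchedule
  T <- sum(sched$duration)
  dt <- 1 / profile@samplingRate
  t <- seq(0, T, by = dt)
  ends <- cumsum(sched$duration)
  starts <- c(0, ends[-length(ends)])
  tTid <- ends[5]
  iIns <- which(sched$phase == "inspiration")
  iHold <- which(sched$phase == "breath_hold")
  iExp <- which(sched$phase == "expiration")

  P <- numeric(length(t))
  Q <- numeric(length(t))
  # tidal oscillation under a smooth envelope vanishing at the window ends,
  # so the maneuver starts and ends near baseline
  inTid <- t < starts[iIns]
  P[inTid] <- 0.25 * sin(2 * pi * 5 * t[inTid] / tTid) *
    sin(pi * t[inTid] / tTid)^2
  inIns <- t >= starts[iIns] & t < starts[iHold]
  u <- (t[inIns] - starts[iIns]) / sched$duration[iIns]
  Q[inIns] <- (1 - cos(pi * u)) / 2
  inHold <- t >= starts[iHold] & t < starts[iExp]
  Q[inHold] <- 1
  # expiration: rise from the trough to the peak at mid-phase, then decay
  # to zero so the maneuver ends near baseline (keeps edge effects of the
  # zero-phase filtering and of the lag alignment negligible)
  inExp <- t >= starts[iExp]
  u <- pmin((t[inExp] - starts[iExp]) / sched$duration[iExp], 1)
  # raised-cosine rise and quarter-cosine decay: C1-smooth joins at the
  # breath-hold exit and at the landing, which keeps low-pass ringing in
  # the hold window negligible; zero tail after 80% of the phase
  rise <- u < 0.5
  decay <- u >= 0.5 & u < 0.8
  P[inExp][rise] <- 0.5 * (1 - cos(2 * pi * u[rise]))
  Q[inExp][rise] <- 1 - 0.5 * (1 - cos(2 * pi * u[rise]))
  P[inExp][decay] <- cos(pi * (u[decay] - 0.5) / 0.6)

  # the offset is supported on [2, tTid - 2] s with a smooth taper, so it
  # vanishes identically over the edge windows used for shift padding and
  # excluded from interior line fits downstream
  w <- 2 * pi * CONTAMINANT_CYCLES / T
  B <- cbind(1, t, cos(outer(t, w)), sin(outer(t, w)))
  taper <- numeric(length(t))
  inWin <- t >= 2 & t <= tTid - 2
  taper[inWin] <- sin(pi * (t[inWin] - 2) / (tTid - 4))^2
  G <- B * taper
  M <- crossprod(B, G)
  P <- P + drop(G %*% solve(M, -crossprod(B, P)))
  Q <- Q + drop(G %*% solve(M, -crossprod(B, Q)))

  phases <- data.frame(phase = as.character(sched$phase), t_start = starts,
                       t_end = ends, stringsAsFactors = FALSE)
  list(t = t, P = P, Q = Q, phases = phases, peakTime = starts[iExp] +
         sched$duration[iExp] / 2)
}

# peaks/troughs realizing a given 13-feature vector (sensor-2 peak is the
# anchor: its amplitude from the profile, all else back-solved)
.featuresToLandmarks <- function(profile, features) {
  npk <- features[1:6]
  pt <- features[7:13]
  if (any(npk <= 0)) stop("normalized peaks must stay positive")
  if (any(pt <= 0)) stop("peak/trough ratios must stay positive")
  peaks <- numeric(7)
  peaks[2] <- profile@amplitude[2]
  peaks[c(1L, 3:7)] <- npk * peaks[2]
  troughs <- peaks / pt
  list(peaks = peaks, troughs = troughs)
}

#' Simulate one breath maneuver
#'
#' Generates a [SensorFrame-class] containing seven breath and seven ambient
#' sensor series: a clean maneuver (tidal oscillations, inspiration descent,
#' breath-hold plateau, expiration peak) whose expiration peak and
#' breath-hold trough realize the profile's baseline features shifted by
#' `featureShift`, plus additive linear drift, injected resonance sinusoids,
#' a shared ambient contaminant and white Gaussian noise. The ambient
#' channels carry a constant baseline and a lagged copy of the contaminant.
#'
#' The clean component is identical across seeds; only the noise changes.
#' Generator truth (clean peaks/troughs and the realized feature vector) is
#' stored in the frame's metadata.
#'
#' @param profile a [ManeuverProfile-class].
#' @param featureShift numeric(13) mean shift added to the profile's
#'   baseline feature vector (class effect plus subject-level variation).
#' @param seed integer seed for the noise realization.
#' @param subjectID identifier for the frame.
#' @return A [SensorFrame-class].
#' @export
simulateManeuver <- function(profile, featureShift = rep(0, 13), seed = 1L,
                             subjectID = "S001") {
  stopifnot(is(profile, "ManeuverProfile"))
  validObject(profile)
  if (length(featureShift) != 13L)
    stop("featureShift must have length 13")
  tpl <- .cleanTemplates(profile)
  features <- .baselineFeatures(profile) + featureShift
  lm <- .featuresToLandmarks(profile, features)

  n <- length(tpl$t)
  clean <- outer(tpl$P, lm$peaks) + outer(tpl$Q, lm$troughs)
  drift <- profile@driftSlope * tpl$t
  res <- numeric(n)
  if (nrow(profile@resonance))
    for (i in seq_len(nrow(profile@resonance)))
      res <- res + profile@resonance$amplitude[i] *
        sin(2 * pi * profile@resonance$frequency[i] * tpl$t)
  contam <- .contaminant(profile, tpl$t)
  contamLagged <- .contaminant(profile, tpl$t, lag = profile@contaminantLag)

  set.seed(as.integer(seed))
  noiseB <- matrix(rnorm(n * 7, 0, profile@noiseSD), n, 7)
  noiseA <- matrix(rnorm(n * 7, 0, profile@noiseSD), n, 7)
  breath <- clean + drift + res + contam + noiseB
  ambient <- profile@ambientLevel + contamLagged + noiseA
  colnames(breath) <- colnames(ambient) <- paste0("s", 1:7)

  SensorFrame(subjectID, tpl$t, breath, ambient, tpl$phases,
              metadata = list(cleanPeaks = lm$peaks,
                              cleanTroughs = lm$troughs,
                              cleanPeakTime = tpl$peakTime,
                              features = features,
                              contaminantLag = profile@contaminantLag,
                              seed = as.integer(seed)))
}

#' Class-conditional covariate parameters emulating the study cohort
#'
#' Frequencies and distribution parameters (per class: no exacerbation /
#' exacerbation) approximating the pooled baseline tables of the emulated
#' study: antibiotic use for acute worsening, smoking status, maintenance
#' ICS, sex, allergy as Bernoulli frequencies; age/BMI/lung function/ACQ as
#' normals; pack-years, blood counts and FeNO as log-normals. Covariates are
#' generated independently of the breath features given class.
#'
#' @return named list of parameter lists.
#' @export
defaultCovariateFrequencies <- function() {
  list(
    recent_antibiotics = list(type = "bernoulli", p = c(0.026, 0.385)),
    smoking_status = list(type = "categorical",
                          levels = c("never", "ex", "current"),
                          p0 = c(0.718, 0.204, 0.078),
                          p1 = c(0.692, 0.308, 0.000)),
    ics_maintenance = list(type = "bernoulli", p = c(0.845, 0.904)),
    sex_male = list(type = "bernoulli", p = c(0.372, 0.269)),
    allergy = list(type = "bernoulli", p = c(0.706, 0.731)),
    age = list(type = "normal", mean = c(47.6, 52.2), sd = c(17.7, 16.3)),
    bmi = list(type = "normal", mean = c(27.7, 27.3), sd = c(6.5, 5.5)),
    fev1_pct = list(type = "normal", mean = c(87.3, 85.7), sd = c(20.7, 25.3)),
    fev1_fvc_pct = list(type = "normal", mean = c(86.6, 84.3),
                        sd = c(14.8, 17.4)),
    acq = list(type = "normal", mean = c(1.75, 1.9), sd = c(1.35, 1.35)),
    # truncated below the 10 pack-year eligibility cut: the emulated cohort
    # is the post-eligibility population whose printed medians these match
    pack_years = list(type = "lognormal", meanlog = log(c(5, 4.8)),
                      sdlog = c(1.03, 1.1), upper = 10),
    blood_eos = list(type = "lognormal", meanlog = log(c(0.21, 0.24)),
                     sdlog = c(1.14, 1.08)),
    blood_neut = list(type = "lognormal", meanlog = log(c(4.5, 5.5)),
                      sdlog = c(0.43, 0.41)),
    feno = list(type = "lognormal", meanlog = log(c(24, 29)),
                sdlog = c(0.93, 0.55))
  )
}

.drawCovariate <- function(par, label) {
  i <- label + 1L
  switch(par$type,
    bernoulli = rbinom(length(label), 1, par$p[i]) == 1,
    normal = pmax(rnorm(length(label), par$mean[i], par$sd[i]), 0),
    lognormal = {
      if (is.null(par$upper)) rlnorm(length(label), par$meanlog[i], par$sdlog[i])
      else {  # inverse-CDF draw truncated at the upper bound
        pmax <- plnorm(par$upper, par$meanlog[i], par$sdlog[i])
        qlnorm(runif(length(label), 0, pmax), par$meanlog[i], par$sdlog[i])
      }
    },
    categorical = {
      pm <- rbind(par$p0, par$p1)
      vapply(seq_along(label), function(j)
        sample(par$levels, 1, prob = pm[label[j] + 1L, ]), character(1))
    },
    stop("unknown covariate type: ", par$type)
  )
}

#' Simulate a full study cohort
#'
#' Draws exacerbation labels at the part-specific prevalences, per-subject
#' 13-feature vectors from the latent-factor Gaussian (class 1 shifted by a
#' Mahalanobis distance of `classSeparation` along the leading factor
#' direction), class-conditional clinical covariates, and (optionally) the
#' raw sensor maneuvers realizing those features.
#'
#' @param spec a [CohortSpec-class].
#' @param profile a [ManeuverProfile-class].
#' @param traces if `TRUE` (default), generate a [SensorFrame-class] per
#'   subject; if `FALSE`, return only the cohort table and the generative
#'   feature truth (fast path for large simulation studies).
#' @return list with elements `frames` (list of SensorFrame or `NULL`),
#'   `cohort` (data.frame: subject_id, split, exacerbation, covariates) and
#'   `featureTruth` (n x 13 matrix of generative feature vectors).
#' @export
simulateCohort <- function(spec, profile = maneuverProfile(), traces = TRUE) {
  stopifnot(is(spec, "CohortSpec"), is(profile, "ManeuverProfile"))
  validObject(spec)
  set.seed(spec@seed)
  n <- spec@nTrain + spec@nValidation
  split <- rep(c("train", "validation"), c(spec@nTrain, spec@nValidation))
  prev <- ifelse(split == "train", spec@prevalenceTrain,
                 spec@prevalenceValidation)
  label <- rbinom(n, 1, prev)
  for (part in unique(split)) {
    lab <- label[split == part]
    if (all(lab == 1L)) stop("no subjects in class 'no exacerbation' (", part,
                             " part); increase n or lower the prevalence")
    if (all(lab == 0L)) stop("no subjects in class 'exacerbation' (", part,
                             " part); increase n or raise the prevalence")
  }

  mod <- .latentModel()
  z <- matrix(rnorm(n * 4), n, 4)
  eps <- matrix(rnorm(n * 13, 0, mod$uniqueSD), n, 13)
  x <- z %*% t(mod$loadings) + eps +
    outer(label, spec@classSeparation * mod$deltaUnit)
  shift <- mod$featureScale * x
  features <- sweep(shift, 2, .baselineFeatures(profile), "+")
  colnames(features) <- breathFeatureNames()

  ids <- sprintf("S%04d", seq_len(n))
  rownames(features) <- ids
  cohort <- data.frame(subject_id = ids, split = split,
                       exacerbation = label, stringsAsFactors = FALSE)
  for (nm in names(spec@covariates))
    cohort[[nm]] <- .drawCovariate(spec@covariates[[nm]], label)
  if ("smoking_status" %in% names(cohort) && "pack_years" %in% names(cohort))
    cohort$pack_years[cohort$smoking_status == "never"] <- 0
  # eligibility-screened fields: present but always negative by construction
  cohort$copd_dx <- FALSE
  cohort$lung_cancer_dx <- FALSE
  cohort$current_antibiotics <- FALSE

  frames <- NULL
  if (traces) {
    subjSeeds <- sample.int(.Machine$integer.max - 1L, n)
    frames <- lapply(seq_len(n), function(i)
      simulateManeuver(profile, featureShift = shift[i, ],
                       seed = subjSeeds[i], subjectID = ids[i]))
    names(frames) <- ids
  }
  list(frames = frames, cohort = cohort, featureTruth = features)
}
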