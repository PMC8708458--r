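# Pipeline configuration: every default follows the emulated study design
# where it states one (70/30 split, Kaiser threshold 1.0, 10,000 bootstrap
# iterations); conditioning defaults are this package's documented
# conventions.

#' Build a pipeline configuration
#'
#' @param trainFraction training-part fraction of the split (default 0.70).
#' @param kaiserThreshold eigenvalue retention threshold (default 1.0,
#'   inclusive).
#' @param nBootstrap bootstrap iterations for AUC confidence intervals
#'   (default 10,000; simulation studies in the tests use 2,000).
#' @param bootstrapLevel confidence level (default 0.95).
#' @param lowpassCutoff,filterOrder zero-phase Butterworth low-pass
#'   settings (default 0.5 Hz, order 2).
#' @param notchFrequencies resonance notch center frequencies in Hz
#'   (default empty; set to the known eigenfrequencies of the device, or to
#'   the generator's resonance frequencies for synthetic data).
#' @param notchBandwidth notch stop-band width in Hz.
#' @param maxLag ambient cross-correlation search half-window in seconds.
#' @param alignHighpass high-pass cutoff (Hz) of the lag-alignment
#'   prefilter in [ambientCorrect()] (0 disables it).
#' @param loocvScope `"lda_only"` (default) or `"full_pipeline"`; see
#'   [loocvScores()].
#' @param stratifySplit stratify the split by class (default `FALSE`).
#' @param subsetRules sensitivity-analysis rules to run.
#' @param seeds named list of integer seeds (`split`, `simulation`,
#'   `bootstrap`).
#' @return a classed list (`PipelineConfig`).
#' @export
pipelineConfig <- function(trainFraction = 0.70,
                           kaiserThreshold = 1.0,
                           nBootstrap = 10000,
                           bootstrapLevel = 0.95,
                           lowpassCutoff = 0.5,
                           filterOrder = 2,
                           notchFrequencies = numeric(0),
                           notchBandwidth = 0.2,
                           maxLag = 2,
                           alignHighpass = 0.15,
                           loocvScope = c("lda_only", "full_pipeline"),
                           stratifySplit = FALSE,
                           subsetRules = c("no_recent_antibiotics",
                                           "no_current_smokers", "ics_only"),
                           seeds = list(split = 1L, simulation = 1L,
                                        bootstrap = 1L)) {
  loocvScope <- match.arg(loocvScope)
  stopifnot(trainFraction > 0, trainFraction < 1, kaiserThreshold > 0,
            nBootstrap >= 100, lowpassCutoff > 0, filterOrder >= 1,
            maxLag > 0)
  seeds <- lapply(seeds, as.integer)
  structure(list(trainFraction = trainFraction,
                 kaiserThreshold = kaiserThreshold,
                 nBootstrap = as.integer(nBootstrap),
                 bootstrapLevel = bootstrapLevel,
                 lowpassCutoff = lowpassCutoff,
                 filterOrder = as.integer(filterOrder),
                 notchFrequencies = notchFrequencies,
                 notchBandwidth = notchBandwidth,
                 maxLag = maxLag,
                 alignHighpass = alignHighpass,
                 loocvScope = loocvScope,
                 stratifySplit = stratifySplit,
                 subsetRules = subsetRules,
                 seeds = seeds),
            class = "PipelineConfig")
}

#' Short reproducibility hash of a resolved configuration
#'
#' Polynomial rolling hash (mod 2^31 - 1) of the deparsed configuration;
#' embedded in every result bundle so two runs can be checked for equal
#' settings at a glance.
#'
#' @param config a [pipelineConfig()] list.
#' @return 8-character hexadecimal string.
#' @export
configHash <- function(config) {
  bytes <- utf8ToInt(paste(deparse(unclass(config)), collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path file path.
#' @param config a [pipelineConfig()] list.
#' @return `readPipelineConfig` returns a [pipelineConfig()] list built
#'   from the file's fields (missing fields take their defaults);
#'   `writePipelineConfig` writes the resolved configuration and returns
#'   `path` invisibly.
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipelineConfig))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  do.call(pipelineConfig, vals)
}

#' @rdname readPipelineConfig
#' @export
writePipelineConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
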