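#' Accessors for breathprint S4 objects
#'
#' Slot access for [SensorFrame-class], [PCATransform-class],
#' [LDAModel-class], [DiscriminantResult-class] and
#' [DiscriminantPipeline-class] objects.
#'
#' @param object the object to access.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("subjectID", function(object) standardGeneric("subjectID"))
#' @rdname accessors
#' @export
setMethod("subjectID", "SensorFrame", function(object) object@subjectID)

#' @rdname accessors
#' @export
setGeneric("frameTime", function(object) standardGeneric("frameTime"))
#' @rdname accessors
#' @export
setMethod("frameTime", "SensorFrame", function(object) object@time)

#' @rdname accessors
#' @export
setGeneric("breathSignals", function(object) standardGeneric("breathSignals"))
#' @rdname accessors
#' @export
setMethod("breathSignals", "SensorFrame", function(object) object@breath)

#' @rdname accessors
#' @export
setGeneric("ambientSignals", function(object) standardGeneric("ambientSignals"))
#' @rdname accessors
#' @export
setMethod("ambientSignals", "SensorFrame", function(object) object@ambient)

#' @rdname accessors
#' @export
setGeneric("framePhases", function(object) standardGeneric("framePhases"))
#' @rdname accessors
#' @export
setMethod("framePhases", "SensorFrame", function(object) object@phases)

#' @rdname accessors
#' @export
setGeneric("frameMetadata", function(object) standardGeneric("frameMetadata"))
#' @rdname accessors
#' @export
setMethod("frameMetadata", "SensorFrame", function(object) object@metadata)

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setMethod("samplingRate", "SensorFrame", function(object)
  1 / mean(diff(object@time)))
#' @rdname accessors
#' @export
setMethod("samplingRate", "ManeuverProfile", function(object)
  object@samplingRate)

#' @rdname accessors
#' @export
setGeneric("eigenvalues", function(object) standardGeneric("eigenvalues"))
#' @rdname accessors
#' @export
setMethod("eigenvalues", "PCATransform", function(object) object@eigenvalues)

#' @rdname accessors
#' @export
setGeneric("retainedComponents", function(object)
  standardGeneric("retainedComponents"))
#' @rdname accessors
#' @export
setMethod("retainedComponents", "PCATransform", function(object)
  object@retained)
#' @rdname accessors
#' @export
setMethod("retainedComponents", "DiscriminantPipeline", function(object)
  object@pca@retained)

#' @rdname accessors
#' @export
setGeneric("rotationMatrix", function(object) standardGeneric("rotationMatrix"))
#' @rdname accessors
#' @export
setMethod("rotationMatrix", "PCATransform", function(object) object@rotation)

#' @rdname accessors
#' @export
setGeneric("discriminantDirection", function(object)
  standardGeneric("discriminantDirection"))
#' @rdname accessors
#' @export
setMethod("discriminantDirection", "LDAModel", function(object)
  object@direction)

#' @rdname accessors
#' @export
setGeneric("discriminantScores", function(object)
  standardGeneric("discriminantScores"))
#' @rdname accessors
#' @export
setMethod("discriminantScores", "DiscriminantResult", function(object)
  object@scores)

#' @rdname accessors
#' @export
setGeneric("auc", function(object) standardGeneric("auc"))
#' @rdname accessors
#' @export
setMethod("auc", "DiscriminantResult", function(object) object@auc)

#' @rdname accessors
#' @export
setGeneric("aucCI", function(object) standardGeneric("aucCI"))
#' @rdname accessors
#' @export
setMethod("aucCI", "DiscriminantResult", function(object) object@aucCI)

#' @rdname accessors
#' @export
setGeneric("rocCurve", function(object) standardGeneric("rocCurve"))
#' @rdname accessors
#' @export
setMethod("rocCurve", "DiscriminantResult", function(object) object@roc)

#' @rdname accessors
#' @export
setGeneric("trainingResult", function(object) standardGeneric("trainingResult"))
#' @rdname accessors
#' @export
setMethod("trainingResult", "DiscriminantPipeline", function(object)
  object@training)

#' @rdname accessors
#' @export
setGeneric("loocvResult", function(object) standardGeneric("loocvResult"))
#' @rdname accessors
#' @export
setMethod("loocvResult", "DiscriminantPipeline", function(object)
  object@loocv)

#' @rdname accessors
#' @export
setGeneric("validationResult", function(object)
  standardGeneric("validationResult"))
#' @rdname accessors
#' @export
setMethod("validationResult", "DiscriminantPipeline", function(object)
  object@validation)

#' @rdname accessors
#' @export
setGeneric("pcaTransform", function(object) standardGeneric("pcaTransform"))
#' @rdname accessors
#' @export
setMethod("pcaTransform", "DiscriminantPipeline", function(object) object@pca)

#' @rdname accessors
#' @export
setGeneric("ldaModel", function(object) standardGeneric("ldaModel"))
#' @rdname accessors
#' @export
setMethod("ldaModel", "DiscriminantPipeline", function(object) object@lda)

#' Feature matrix of a BreathFeatureSet (subjects x 13)
#'
#' @param object a [BreathFeatureSet-class].
#' @return numeric matrix, one row per subject, 13 feature columns.
#' @export
featureMatrix <- function(object) {
  stopifnot(is(object, "BreathFeatureSet"))
  t(SummarizedExperiment::assay(object, "features"))
}

#' Binary exacerbation labels of a BreathFeatureSet
#'
#' @param object a [BreathFeatureSet-class].
#' @return integer 0/1 vector.
#' @export
exacerbationLabels <- function(object) {
  as.integer(SummarizedExperiment::colData(object)$exacerbation)
}
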