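#' @importFrom methods setGeneric setMethod new validObject is slot
NULL

#' @rdname MsmsSpectrum-class
#' @param object,x an object.
#' @export
setGeneric("spectrumId", function(object) standardGeneric("spectrumId"))

#' @rdname MsmsSpectrum-class
#' @export
setGeneric("precursorMz", function(object) standardGeneric("precursorMz"))

#' @rdname MsmsSpectrum-class
#' @export
setGeneric("rtSeconds", function(object) standardGeneric("rtSeconds"))

#' @rdname MsmsSpectrum-class
#' @export
setGeneric("precursorIntensity", function(object) standardGeneric("precursorIntensity"))

#' @rdname MsmsSpectrum-class
#' @export
setGeneric("peakMatrix", function(object) standardGeneric("peakMatrix"))

#' @rdname SulfateExperiment-class
#' @param object an object.
#' @export
setGeneric("featureMz", function(object) standardGeneric("featureMz"))

#' @rdname SulfateExperiment-class
#' @export
setGeneric("featureRt", function(object) standardGeneric("featureRt"))

#' @rdname SulfateExperiment-class
#' @export
setGeneric("featureSnr", function(object) standardGeneric("featureSnr"))

#' @rdname SulfateExperiment-class
#' @export
setGeneric("sampleRole", function(object) standardGeneric("sampleRole"))

#' @rdname SulfateExperiment-class
#' @export
setGeneric("injectionOrder", function(object) standardGeneric("injectionOrder"))

#' @rdname SulfateClustering-class
#' @param object an object.
#' @export
setGeneric("clusterAssignment", function(object) standardGeneric("clusterAssignment"))

#' @rdname SulfateClustering-class
#' @export
setGeneric("sulfateFeatures", function(object) standardGeneric("sulfateFeatures"))
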