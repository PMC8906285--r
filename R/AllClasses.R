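#' MsmsSpectrum: one DDA product-ion scan
#'
#' Container for a single MS/MS spectrum: precursor m/z, retention time in
#' seconds, optional precursor intensity and the fragment peak list. Peaks
#' are stored as a two-column matrix (`mz`, `intensity`), sorted ascending
#' by m/z; zero-intensity peaks are dropped at construction.
#'
#' @slot spectrumId character scan identifier.
#' @slot precursorMz precursor m/z (> 0).
#' @slot rtSeconds retention time in seconds (>= 0).
#' @slot precursorIntensity precursor intensity (arbitrary counts, may be
#'   `NA` when the source file does not carry one).
#' @slot peaks numeric matrix with columns `mz` and `intensity`.
#'
#' @param spectrumId character scan identifier.
#' @param precursorMz precursor m/z.
#' @param rtSeconds retention time in seconds.
#' @param peaks two-column matrix or data.frame of (mz, intensity).
#' @param precursorIntensity optional precursor intensity.
#' @return `MsmsSpectrum()` returns a validated [MsmsSpectrum-class] object.
#' @examples
#' sp <- MsmsSpectrum("scan1", 367.1583, 520,
#'                    peaks = cbind(mz = c(96.9601, 79.9573),
#'                                  intensity = c(500, 150)))
#' peakMatrix(sp)
#' @aliases spectrumId precursorMz rtSeconds precursorIntensity peakMatrix
#' @export MsmsSpectrum
#' @exportClass MsmsSpectrum
setClass("MsmsSpectrum",
    representation(
        spectrumId = "character",
        precursorMz = "numeric",
        rtSeconds = "numeric",
        precursorIntensity = "numeric",
        peaks = "matrix"
    )
)

setValidity("MsmsSpectrum", function(object) {
    msg <- character(0)
    if (length(object@spectrumId) != 1L || is.na(object@spectrumId))
        msg <- c(msg, "spectrumId must be a single non-NA string")
    if (length(object@precursorMz) != 1L || !is.finite(object@precursorMz) ||
        object@precursorMz <= 0)
        msg <- c(msg, "precursorMz must be a single positive number")
    if (length(object@rtSeconds) != 1L || !is.finite(object@rtSeconds) ||
        object@rtSeconds < 0)
        msg <- c(msg, "rtSeconds must be a single non-negative number")
    pk <- object@peaks
    if (!is.numeric(pk) || ncol(pk) != 2L ||
        !identical(colnames(pk), c("mz", "intensity")))
        msg <- c(msg, "peaks must be a numeric matrix with columns mz, intensity")
    else if (nrow(pk) > 0L) {
        if (any(pk[, "mz"] <= 0))
            msg <- c(msg, "all peak m/z must be positive")
        if (any(pk[, "intensity"] <= 0))
            msg <- c(msg, "all peak intensities must be positive")
        if (is.unsorted(pk[, "mz"]))
            msg <- c(msg, "peaks must be sorted ascending by m/z")
    }
    if (length(msg)) msg else TRUE
})

MsmsSpectrum <- function(spectrumId, precursorMz, rtSeconds, peaks,
                         precursorIntensity = NA_real_) {
    pk <- as.matrix(peaks)
    if (ncol(pk) != 2L)
        stop("peaks must have two columns (mz, intensity)")
    colnames(pk) <- c("mz", "intensity")
    storage.mode(pk) <- "double"
    pk <- pk[pk[, "intensity"] > 0, , drop = FALSE]  # zero-intensity dropped
    pk <- pk[order(pk[, "mz"]), , drop = FALSE]
    new("MsmsSpectrum",
        spectrumId = as.character(spectrumId),
        precursorMz = as.numeric(precursorMz),
        rtSeconds = as.numeric(rtSeconds),
        precursorIntensity = as.numeric(precursorIntensity),
        peaks = pk)
}

#' @rdname MsmsSpectrum-class
setMethod("spectrumId", "MsmsSpectrum", function(object) object@spectrumId)
#' @rdname MsmsSpectrum-class
setMethod("precursorMz", "MsmsSpectrum", function(object) object@precursorMz)
#' @rdname MsmsSpectrum-class
setMethod("rtSeconds", "MsmsSpectrum", function(object) object@rtSeconds)
#' @rdname MsmsSpectrum-class
setMethod("precursorIntensity", "MsmsSpectrum",
          function(object) object@precursorIntensity)
#' @rdname MsmsSpectrum-class
setMethod("peakMatrix", "MsmsSpectrum", function(object) object@peaks)

setMethod("show", "MsmsSpectrum", function(object) {
    cat("MsmsSpectrum '", object@spectrumId, "': precursor m/z ",
        format(object@precursorMz, digits = 8), ", RT ",
        format(object@rtSeconds, digits = 6), " s, ",
        nrow(object@peaks), " peaks\n", sep = "")
})

#' SulfateExperiment: aligned LC-MS features with sample metadata
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding the
#' aligned feature table. The `"intensities"` assay carries one column per
#' sample; `rowData` carries `mz`, `rt_seconds`, `snr`, and (after spectrum
#' mapping) `has_msms` and `spectrum_id`; `colData` carries the sample
#' sheet columns `role` (`biological`, `pooled_qc` or `blank`), `group`
#' and `injection_order`.
#'
#' @slot .. see [SummarizedExperiment::SummarizedExperiment].
#' @param featureTable data.frame with columns `feature_id`, `mz`, `rt`
#'   (unit set by `rtUnit`), `snr`, then one intensity column per sample.
#' @param sampleSheet data.frame with columns `sample_id`, `role`,
#'   `group`, `injection_order`.
#' @param rtUnit unit of the feature-table `rt` column; `"minutes"`
#'   (default, converted to seconds on construction) or `"seconds"`.
#' @return `SulfateExperiment()` returns a validated
#'   [SulfateExperiment-class].
#' @aliases featureMz featureRt featureSnr sampleRole injectionOrder
#' @export SulfateExperiment
#' @exportClass SulfateExperiment
setClass("SulfateExperiment", contains = "SummarizedExperiment")

setValidity("SulfateExperiment", function(object) {
    msg <- character(0)
    rd <- SummarizedExperiment::rowData(object)
    cd <- SummarizedExperiment::colData(object)
    if (!all(c("mz", "rt_seconds", "snr") %in% colnames(rd)))
        msg <- c(msg, "rowData must contain mz, rt_seconds, snr")
    else {
        if (any(rd$mz <= 0)) msg <- c(msg, "feature mz must be positive")
        if (any(rd$snr < 0)) msg <- c(msg, "feature snr must be non-negative")
    }
    if (!all(c("role", "group", "injection_order") %in% colnames(cd)))
        msg <- c(msg, "colData must contain role, group, injection_order")
    else {
        if (!all(cd$role %in% c("biological", "pooled_qc", "blank")))
            msg <- c(msg, "role must be biological, pooled_qc or blank")
        if (anyDuplicated(cd$injection_order))
            msg <- c(msg, "injection_order values must be unique")
        if (any(cd$injection_order < 1))
            msg <- c(msg, "injection_order values must be positive")
    }
    if (ncol(object) < 1L)
        msg <- c(msg, "at least one sample column required")
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "feature ids must be unique")
    if (length(msg)) msg else TRUE
})

SulfateExperiment <- function(featureTable, sampleSheet,
                              rtUnit = c("minutes", "seconds")) {
    rtUnit <- match.arg(rtUnit)
    req <- c("feature_id", "mz", "rt", "snr")
    if (!all(req %in% colnames(featureTable)))
        stop("feature table must contain columns: ",
             paste(setdiff(req, colnames(featureTable)), collapse = ", "))
    sampleSheet <- validateSampleSheet(sampleSheet)
    missing <- setdiff(sampleSheet$sample_id, colnames(featureTable))
    if (length(missing) > 0L)
        stop("samples in sheet absent from feature table: ",
             paste(missing, collapse = ", "))
    if (anyDuplicated(featureTable$feature_id))
        stop("duplicate feature_id in feature table")
    mat <- as.matrix(featureTable[, sampleSheet$sample_id, drop = FALSE])
    storage.mode(mat) <- "double"
    mat[is.na(mat)] <- 0  # missing intensity cells mean "not detected"
    rownames(mat) <- featureTable$feature_id
    rtSec <- if (rtUnit == "minutes") featureTable$rt * 60 else featureTable$rt
    rd <- S4Vectors::DataFrame(
        mz = featureTable$mz,
        rt_seconds = rtSec,
        snr = featureTable$snr,
        has_msms = if ("has_msms" %in% colnames(featureTable))
            as.logical(featureTable$has_msms) else NA,
        spectrum_id = if ("spectrum_id" %in% colnames(featureTable))
            as.character(featureTable$spectrum_id) else NA_character_,
        row.names = featureTable$feature_id)
    cd <- S4Vectors::DataFrame(
        role = sampleSheet$role,
        group = sampleSheet$group,
        injection_order = as.integer(sampleSheet$injection_order),
        row.names = sampleSheet$sample_id)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(intensities = mat), rowData = rd, colData = cd)
    new("SulfateExperiment", se)
}

## Check the sample-sheet contract (used by both the constructor and IO).
validateSampleSheet <- function(sampleSheet) {
    req <- c("sample_id", "role", "group", "injection_order")
    if (!all(req %in% colnames(sampleSheet)))
        stop("sample sheet must contain columns: ",
             paste(setdiff(req, colnames(sampleSheet)), collapse = ", "))
    if (anyDuplicated(sampleSheet$sample_id))
        stop("duplicate sample_id in sample sheet")
    if (anyDuplicated(sampleSheet$injection_order))
        stop("injection_order values must be unique")
    if (!all(sampleSheet$role %in% c("biological", "pooled_qc", "blank")))
        stop("sample roles must be one of biological, pooled_qc, blank")
    as.data.frame(sampleSheet)
}

#' @rdname SulfateExperiment-class
setMethod("featureMz", "SulfateExperiment",
          function(object) stats::setNames(SummarizedExperiment::rowData(object)$mz,
                                           rownames(object)))
#' @rdname SulfateExperiment-class
setMethod("featureRt", "SulfateExperiment",
          function(object) stats::setNames(SummarizedExperiment::rowData(object)$rt_seconds,
                                           rownames(object)))
#' @rdname SulfateExperiment-class
setMethod("featureSnr", "SulfateExperiment",
          function(object) stats::setNames(SummarizedExperiment::rowData(object)$snr,
                                           rownames(object)))
#' @rdname SulfateExperiment-class
setMethod("sampleRole", "SulfateExperiment",
          function(object) stats::setNames(as.character(SummarizedExperiment::colData(object)$role),
                                           colnames(object)))
#' @rdname SulfateExperiment-class
setMethod("injectionOrder", "SulfateExperiment",
          function(object) stats::setNames(SummarizedExperiment::colData(object)$injection_order,
                                           colnames(object)))

setMethod("show", "SulfateExperiment", function(object) {
    methods::callNextMethod()
    roles <- table(SummarizedExperiment::colData(object)$role)
    cat("sample roles:", paste(names(roles), roles, sep = "=", collapse = " "), "\n")
})

#' SulfateClustering: two-group k-means result over the spectral parameters
#'
#' Result of k-means (k = 2) on the eight-parameter matrix (six diagnostic
#' fragment relative abundances, IR and MA). The cluster whose centroid has
#' the larger MA on the original percentage scale is labelled `sulfate`.
#'
#' @slot assignment named character vector, `"sulfate"` or
#'   `"non_sulfate"` per feature.
#' @slot centroids 2 x 8 centroid matrix in the scaled space, rows
#'   `sulfate` and `non_sulfate`.
#' @slot nSulfate,nNonSulfate feature counts per class.
#' @slot summaries data.frame of per-class median/mean/min/max of IR and MA
#'   (original percent scale).
#' @slot totWithinss best within-cluster sum of squares over the restarts.
#' @aliases clusterAssignment sulfateFeatures
#' @exportClass SulfateClustering
setClass("SulfateClustering",
    representation(
        assignment = "character",
        centroids = "matrix",
        nSulfate = "integer",
        nNonSulfate = "integer",
        summaries = "data.frame",
        totWithinss = "numeric"
    )
)

setValidity("SulfateClustering", function(object) {
    msg <- character(0)
    if (!all(object@assignment %in% c("sulfate", "non_sulfate")))
        msg <- c(msg, "assignment values must be sulfate or non_sulfate")
    if (is.null(names(object@assignment)))
        msg <- c(msg, "assignment must be named by feature id")
    if (object@nSulfate + object@nNonSulfate != length(object@assignment))
        msg <- c(msg, "class counts must sum to the number of clustered features")
    if (length(msg)) msg else TRUE
})

#' @rdname SulfateClustering-class
setMethod("clusterAssignment", "SulfateClustering",
          function(object) object@assignment)
#' @rdname SulfateClustering-class
setMethod("sulfateFeatures", "SulfateClustering",
          function(object) names(object@assignment)[object@assignment == "sulfate"])

setMethod("show", "SulfateClustering", function(object) {
    cat("SulfateClustering: ", length(object@assignment), " features -> ",
        object@nSulfate, " sulfate / ", object@nNonSulfate,
        " non-sulfate\n", sep = "")
    cat("total within-cluster SS:", format(object@totWithinss, digits = 6), "\n")
    print(object@summaries)
})
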