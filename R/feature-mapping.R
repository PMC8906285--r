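## Attaching DDA MS/MS spectra to aligned features and the feature-curation
## filters (no MS/MS, low S/N, too few samples, blank-derived).

#' Map MS/MS spectra onto aligned features
#'
#' A spectrum is a candidate for a feature when the precursor m/z is
#' within `mzTolPpm` of the feature m/z and the retention-time difference
#' is within `rtTolSeconds`. Candidates are assigned greedily in order of
#' increasing absolute RT difference (ties: higher precursor intensity,
#' then lexicographic spectrum id), and each spectrum serves at most one
#' feature, so the mapping is injective. Features left without a spectrum
#' get `has_msms = FALSE`.
#'
#' @param spectra list of [MsmsSpectrum-class] objects.
#' @param se a [SulfateExperiment-class].
#' @param mzTolPpm precursor mass tolerance in ppm (default 5).
#' @param rtTolSeconds retention-time tolerance in seconds (default 3).
#' @return `se` with `rowData` columns `spectrum_id` (NA when unmatched)
#'   and `has_msms` filled in.
#' @export
mapSpectraToFeatures <- function(spectra, se, mzTolPpm = 5, rtTolSeconds = 3) {
    stopifnot(is(se, "SulfateExperiment"), mzTolPpm > 0, rtTolSeconds > 0)
    fmz <- featureMz(se)
    frt <- featureRt(se)
    smz <- vapply(spectra, precursorMz, numeric(1))
    srt <- vapply(spectra, rtSeconds, numeric(1))
    sint <- vapply(spectra, precursorIntensity, numeric(1))
    sid <- vapply(spectra, spectrumId, character(1))
    if (anyDuplicated(sid))
        stop("duplicate spectrum ids")
    ## candidate pairs within both tolerances
    cand <- list()
    for (j in seq_along(spectra)) {
        ppm <- abs(ppmError(smz[j], fmz))
        dRt <- abs(srt[j] - frt)
        ok <- which(ppm <= mzTolPpm & dRt <= rtTolSeconds)
        if (length(ok) > 0L)
            cand[[length(cand) + 1L]] <- data.frame(
                feature = names(fmz)[ok], spectrum = j, dRt = dRt[ok],
                stringsAsFactors = FALSE)
    }
    assigned <- stats::setNames(rep(NA_character_, nrow(se)), rownames(se))
    if (length(cand) > 0L) {
        cand <- do.call(rbind, cand)
        intTie <- ifelse(is.na(sint[cand$spectrum]), -Inf, sint[cand$spectrum])
        cand <- cand[order(cand$dRt, -intTie, sid[cand$spectrum]), ]
        usedSpectrum <- logical(length(spectra))
        for (k in seq_len(nrow(cand))) {
            f <- cand$feature[k]; j <- cand$spectrum[k]
            if (is.na(assigned[[f]]) && !usedSpectrum[j]) {
                assigned[[f]] <- sid[j]
                usedSpectrum[j] <- TRUE
            }
        }
    }
    rd <- SummarizedExperiment::rowData(se)
    rd$spectrum_id <- unname(assigned)
    rd$has_msms <- unname(!is.na(assigned))
    SummarizedExperiment::rowData(se) <- rd
    se
}

#' Apply the feature-curation filters
#'
#' Keeps features that (i) carry an MS/MS spectrum, (ii) have
#' `snr >= minSnr`, and (iii) are detected (intensity > 0) in at least
#' `minSamplesDetected` samples. Removed features are reported with the
#' first failing reason, checked in the order `no_msms`, `low_snr`,
#' `too_few_samples`.
#'
#' @param se a [SulfateExperiment-class] with `has_msms` set by
#'   [mapSpectraToFeatures()].
#' @param minSnr minimum signal-to-noise ratio (default 3).
#' @param minSamplesDetected minimum number of samples with nonzero
#'   intensity (default 2).
#' @return List with `kept` (a filtered [SulfateExperiment-class]) and
#'   `removed` (data.frame `feature_id`, `reason`).
#' @export
filterFeatures <- function(se, minSnr = 3, minSamplesDetected = 2L) {
    stopifnot(is(se, "SulfateExperiment"))
    rd <- SummarizedExperiment::rowData(se)
    if (all(is.na(rd$has_msms)))
        stop("has_msms not set; run mapSpectraToFeatures() first")
    nDetected <- rowSums(SummarizedExperiment::assay(se, "intensities") > 0)
    reason <- rep(NA_character_, nrow(se))
    reason[nDetected < minSamplesDetected] <- "too_few_samples"
    reason[rd$snr < minSnr] <- "low_snr"
    reason[!rd$has_msms] <- "no_msms"  # assigned last = first in priority
    keep <- is.na(reason)
    list(kept = se[keep, ],
         removed = data.frame(feature_id = rownames(se)[!keep],
                              reason = reason[!keep],
                              stringsAsFactors = FALSE))
}

#' Remove features matching the most intense blank-derived ions
#'
#' Desk-side analogue of an acquisition-time static exclusion list: the
#' `topN` features most intense in blank samples define an exclusion
#' list, and any feature matching one of them in m/z (ppm tolerance) and
#' RT is removed.
#'
#' @param se a [SulfateExperiment-class] whose `colData` contains blank
#'   samples (`role == "blank"`); an error otherwise.
#' @param topN size of the exclusion list (default 1000); 0 disables
#'   exclusion.
#' @param mzTolPpm,rtTolSeconds matching tolerances (defaults 5 ppm, 3 s).
#' @return List with `kept` (filtered [SulfateExperiment-class]) and
#'   `removed` (data.frame `feature_id`, `reason = "blank_derived"`).
#' @export
blankExclusion <- function(se, topN = 1000L, mzTolPpm = 5, rtTolSeconds = 3) {
    stopifnot(is(se, "SulfateExperiment"))
    blanks <- colnames(se)[sampleRole(se) == "blank"]
    if (length(blanks) == 0L)
        stop("no blank samples in the experiment; blank exclusion needs role == 'blank'")
    if (topN == 0L)
        return(list(kept = se,
                    removed = data.frame(feature_id = character(0),
                                         reason = character(0))))
    blankInt <- SummarizedExperiment::assay(se, "intensities")[, blanks, drop = FALSE]
    maxBlank <- apply(blankInt, 1L, max)
    present <- which(maxBlank > 0)
    exclIdx <- present[order(-maxBlank[present])]
    exclIdx <- utils::head(exclIdx, topN)
    if (length(exclIdx) == 0L)
        return(list(kept = se,
                    removed = data.frame(feature_id = character(0),
                                         reason = character(0))))
    fmz <- featureMz(se); frt <- featureRt(se)
    drop <- logical(nrow(se))
    for (i in exclIdx) {
        hit <- abs(ppmError(fmz, fmz[i])) <= mzTolPpm &
            abs(frt - frt[i]) <= rtTolSeconds
        drop <- drop | hit
    }
    list(kept = se[!drop, ],
         removed = data.frame(feature_id = rownames(se)[drop],
                              reason = "blank_derived",
                              stringsAsFactors = FALSE))
}
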