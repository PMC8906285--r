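## MGF and delimited-table IO. The MGF dialect is the package's data
## contract: BEGIN IONS / END IONS blocks with TITLE, PEPMASS (m/z and
## optional intensity), RTINSECONDS, optional CHARGE, then "mz intensity"
## peak lines.

#' Read MS/MS spectra from a Mascot Generic Format file
#'
#' Each `BEGIN IONS`/`END IONS` block becomes one [MsmsSpectrum-class].
#' Peaks are re-sorted ascending by m/z and zero-intensity peaks dropped.
#' `PEPMASS` and `RTINSECONDS` are mandatory per block; a missing header
#' or an unparseable peak line raises an error naming the block or line.
#'
#' @param path path to an MGF file.
#' @return List of [MsmsSpectrum-class] objects.
#' @seealso [writeMgf()]
#' @export
readMgf <- function(path) {
    if (!file.exists(path))
        stop("MGF file not found: ", path)
    lines <- readLines(path)
    starts <- which(lines == "BEGIN IONS")
    ends <- which(lines == "END IONS")
    if (length(starts) != length(ends) || any(ends < starts))
        stop("malformed MGF: unbalanced BEGIN IONS/END IONS")
    spectra <- vector("list", length(starts))
    for (b in seq_along(starts)) {
        block <- lines[(starts[b] + 1L):(ends[b] - 1L)]
        lineNos <- (starts[b] + 1L):(ends[b] - 1L)
        isHeader <- grepl("^[A-Z][A-Z0-9]*=", block)
        headers <- block[isHeader]
        keys <- sub("=.*$", "", headers)
        vals <- sub("^[A-Z][A-Z0-9]*=", "", headers)
        names(vals) <- keys
        if (!"PEPMASS" %in% keys)
            stop("PEPMASS missing in MGF block ", b)
        if (!"RTINSECONDS" %in% keys)
            stop("RTINSECONDS missing in MGF block ", b)
        pep <- strsplit(trimws(vals[["PEPMASS"]]), "[ \t]+")[[1L]]
        precMz <- suppressWarnings(as.numeric(pep[1L]))
        if (is.na(precMz))
            stop("unparseable PEPMASS in MGF block ", b)
        precInt <- if (length(pep) >= 2L)
            suppressWarnings(as.numeric(pep[2L])) else NA_real_
        rt <- suppressWarnings(as.numeric(vals[["RTINSECONDS"]]))
        if (is.na(rt))
            stop("unparseable RTINSECONDS in MGF block ", b)
        title <- if ("TITLE" %in% keys) vals[["TITLE"]] else paste0("index_", b)
        peakLines <- block[!isHeader & nzchar(trimws(block))]
        peakLineNos <- lineNos[!isHeader & nzchar(trimws(block))]
        pk <- matrix(numeric(0), ncol = 2L)
        if (length(peakLines) > 0L) {
            fields <- strsplit(trimws(peakLines), "[ \t]+")
            bad <- which(vapply(fields, length, integer(1)) < 2L)
            if (length(bad) > 0L)
                stop("unparseable peak line ", peakLineNos[bad[1L]],
                     " in MGF file: '", peakLines[bad[1L]], "'")
            mzv <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 1L)))
            inv <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2L)))
            if (anyNA(mzv) || anyNA(inv)) {
                bad <- which(is.na(mzv) | is.na(inv))[1L]
                stop("unparseable peak line ", peakLineNos[bad],
                     " in MGF file: '", peakLines[bad], "'")
            }
            pk <- cbind(mzv, inv)
        }
        colnames(pk) <- c("mz", "intensity")
        spectra[[b]] <- MsmsSpectrum(title, precMz, rt, pk,
                                     precursorIntensity = precInt)
    }
    names(spectra) <- vapply(spectra, spectrumId, character(1))
    spectra
}

#' Write MS/MS spectra to a Mascot Generic Format file
#'
#' The output is re-readable by [readMgf()] with numeric agreement to at
#' least six significant digits. Charge is written as `1-` (negative-mode
#' convention).
#'
#' @param spectra list of [MsmsSpectrum-class] objects.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeMgf <- function(spectra, path) {
    con <- file(path, open = "wt")
    on.exit(close(con))
    for (sp in spectra) {
        stopifnot(is(sp, "MsmsSpectrum"))
        pk <- peakMatrix(sp)
        pep <- if (is.na(precursorIntensity(sp)))
            sprintf("%.6f", precursorMz(sp))
        else
            sprintf("%.6f %.6f", precursorMz(sp), precursorIntensity(sp))
        writeLines(c(
            "BEGIN IONS",
            paste0("TITLE=", spectrumId(sp)),
            paste0("PEPMASS=", pep),
            paste0("RTINSECONDS=", sprintf("%.4f", rtSeconds(sp))),
            "CHARGE=1-",
            if (nrow(pk) > 0L)
                sprintf("%.6f %.6f", pk[, "mz"], pk[, "intensity"]),
            "END IONS"), con)
    }
    invisible(path)
}

#' Read a sample sheet
#'
#' Delimited text (comma or tab autodetected) with columns `sample_id`,
#' `role` (`biological`, `pooled_qc`, `blank`), `group`,
#' `injection_order`.
#'
#' @param path path to the sample sheet.
#' @return A validated data.frame.
#' @export
readSampleSheet <- function(path) {
    if (!file.exists(path))
        stop("sample sheet not found: ", path)
    sheet <- utils::read.delim(path, sep = detectDelim(path),
                               stringsAsFactors = FALSE, check.names = FALSE)
    validateSampleSheet(sheet)
}

#' Read an aligned feature table into a SulfateExperiment
#'
#' Delimited text (comma or tab autodetected) with header columns
#' `feature_id`, `mz`, `rt`, `snr`, then one column per `sample_id` in the
#' sheet. Missing intensity cells are read as 0 (not detected). The `rt`
#' column is in minutes by default (chromatography convention) and is
#' converted to seconds internally.
#'
#' @param path path to the feature table.
#' @param sampleSheet data.frame as returned by [readSampleSheet()].
#' @param rtUnit `"minutes"` (default) or `"seconds"`.
#' @return A [SulfateExperiment-class].
#' @export
readFeatureTable <- function(path, sampleSheet, rtUnit = c("minutes", "seconds")) {
    if (!file.exists(path))
        stop("feature table not found: ", path)
    tab <- utils::read.delim(path, sep = detectDelim(path),
                             stringsAsFactors = FALSE, check.names = FALSE)
    SulfateExperiment(tab, sampleSheet, rtUnit = match.arg(rtUnit))
}

#' Write a SulfateExperiment back to a delimited feature table
#'
#' Inverse of [readFeatureTable()]; round-trips all fields.
#'
#' @param se a [SulfateExperiment-class].
#' @param path output path (written comma-separated).
#' @param rtUnit unit for the written `rt` column.
#' @param assayName which assay to write (default `"intensities"`).
#' @return Invisibly, `path`.
#' @export
writeFeatureTable <- function(se, path, rtUnit = c("minutes", "seconds"),
                              assayName = "intensities") {
    rtUnit <- match.arg(rtUnit)
    rd <- SummarizedExperiment::rowData(se)
    rt <- if (rtUnit == "minutes") rd$rt_seconds / 60 else rd$rt_seconds
    tab <- data.frame(feature_id = rownames(se), mz = rd$mz, rt = rt,
                      snr = rd$snr, check.names = FALSE)
    tab <- cbind(tab, as.data.frame(SummarizedExperiment::assay(se, assayName)))
    utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Write the sample sheet of a SulfateExperiment
#' @param se a [SulfateExperiment-class].
#' @param path output path (written comma-separated).
#' @return Invisibly, `path`.
#' @export
writeSampleSheet <- function(se, path) {
    cd <- SummarizedExperiment::colData(se)
    utils::write.csv(data.frame(sample_id = colnames(se), role = cd$role,
                                group = cd$group,
                                injection_order = cd$injection_order),
                     path, row.names = FALSE, quote = FALSE)
    invisible(path)
}
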