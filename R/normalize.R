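## Pooled-QC anchored LOWESS correction of injection-order signal drift.

#' LOWESS signal-drift normalization
#'
#' For every feature with at least `minQc` pooled-QC samples of nonzero
#' intensity, fits a locally weighted regression ([stats::lowess]) of QC
#' intensity against injection order (span `frac`), evaluates the fitted
#' drift curve at every sample's injection order (linear interpolation,
#' linear extrapolation beyond the first/last QC), and divides raw
#' intensities by the correction factor `fitted / median(QC intensity)`.
#' Corrected intensities are re-anchored so the per-feature QC median is
#' unchanged by normalization; zeros stay zero. Features with too few
#' usable QCs are passed through unchanged and flagged.
#'
#' @param se a [SulfateExperiment-class] with pooled-QC samples
#'   (`role == "pooled_qc"`); an error when there are none.
#' @param frac LOWESS span (default 0.7).
#' @param minQc minimum nonzero QC observations per feature (default 3).
#' @param assayName assay to correct (default `"intensities"`).
#' @return List of class `"NormalizationResult"`:
#'   \describe{
#'     \item{se}{the input with an added `"corrected"` assay.}
#'     \item{factors}{feature x sample matrix of correction factors
#'       (all > 0; 1 for passed-through features).}
#'     \item{qcRsd}{data.frame `feature_id`, `rsd_before`, `rsd_after`
#'       (percent relative SD over nonzero QCs), `flagged`.}
#'   }
#' @export
lowessNormalize <- function(se, frac = 0.7, minQc = 3L,
                            assayName = "intensities") {
    stopifnot(is(se, "SulfateExperiment"), frac > 0)
    roles <- sampleRole(se)
    qcCols <- which(roles == "pooled_qc")
    if (length(qcCols) == 0L)
        stop("no pooled QC samples: disable normalization or provide role == 'pooled_qc'")
    mat <- SummarizedExperiment::assay(se, assayName)
    ord <- injectionOrder(se)
    factors <- matrix(1, nrow(mat), ncol(mat), dimnames = dimnames(mat))
    flagged <- logical(nrow(mat))
    rsd <- function(x) if (length(x) >= 2L && mean(x) > 0)
        100 * stats::sd(x) / mean(x) else NA_real_
    rsdBefore <- rsdAfter <- rep(NA_real_, nrow(mat))
    corrected <- mat
    for (i in seq_len(nrow(mat))) {
        qcInt <- mat[i, qcCols]
        nz <- qcInt > 0
        rsdBefore[i] <- rsd(qcInt[nz])
        if (sum(nz) < minQc) {
            flagged[i] <- TRUE
            rsdAfter[i] <- rsdBefore[i]
            next
        }
        x <- ord[qcCols][nz]
        y <- qcInt[nz]
        o <- order(x)
        fit <- stats::lowess(x[o], y[o], f = frac)
        fitted <- interpLinearExtrap(fit$x, fit$y, ord)
        medQc <- stats::median(y)
        fac <- fitted / medQc
        fac[!is.finite(fac) | fac <= 0] <- 1  # guard degenerate fits
        corr <- mat[i, ] / fac
        ## re-anchor: per-feature QC median is invariant under correction
        medAfter <- stats::median(corr[qcCols][nz])
        if (is.finite(medAfter) && medAfter > 0) {
            scaleBack <- medQc / medAfter
            corr <- corr * scaleBack
            fac <- fac / scaleBack
        }
        corrected[i, ] <- corr
        factors[i, ] <- fac
        rsdAfter[i] <- rsd(corr[qcCols][nz])
    }
    SummarizedExperiment::assays(se)[["corrected"]] <- corrected
    out <- list(se = se, factors = factors,
                qcRsd = data.frame(feature_id = rownames(mat),
                                   rsd_before = rsdBefore,
                                   rsd_after = rsdAfter,
                                   flagged = flagged,
                                   stringsAsFactors = FALSE))
    class(out) <- "NormalizationResult"
    out
}

#' @export
print.NormalizationResult <- function(x, ...) {
    n <- nrow(x$qcRsd)
    ok <- !x$qcRsd$flagged
    cat("NormalizationResult:", n, "features,", sum(x$qcRsd$flagged),
        "passed through (too few QCs)\n")
    if (any(ok)) {
        cat(sprintf("median QC RSD before %.1f%% -> after %.1f%%\n",
                    stats::median(x$qcRsd$rsd_before[ok], na.rm = TRUE),
                    stats::median(x$qcRsd$rsd_after[ok], na.rm = TRUE)))
    }
    invisible(x)
}
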