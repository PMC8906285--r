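## Differential metabolite-level analysis: log2 preparation, moderated t
## with empirical-Bayes variance shrinkage, Benjamini-Hochberg adjustment
## and volcano classification.

#' Prepare a log2 intensity matrix
#'
#' Replaces zeros by half the smallest nonzero intensity of that feature
#' (half-minimum imputation), then takes log2. Features that are zero in
#' every sample are excluded and reported.
#'
#' @param mat numeric matrix of (normalized) intensities, features x
#'   samples.
#' @return List with `log2` (matrix) and `excluded` (character vector of
#'   all-zero feature ids).
#' @export
log2Prepare <- function(mat) {
    stopifnot(is.matrix(mat))
    allZero <- rowSums(mat > 0) == 0L
    excluded <- rownames(mat)[allZero] %||% character(0)
    m <- mat[!allZero, , drop = FALSE]
    for (i in seq_len(nrow(m))) {
        z <- m[i, ] == 0
        if (any(z))
            m[i, z] <- min(m[i, !z]) / 2
    }
    list(log2 = log2(m), excluded = excluded)
}

## Invert the trigamma function by Newton iteration (monotone decreasing
## on (0, Inf)); used by the moment estimator of the prior df.
trigammaInverse <- function(y) {
    vapply(y, function(yi) {
        if (!is.finite(yi) || yi <= 0)
            return(Inf)
        if (yi > 1e7)
            return(1 / sqrt(yi))
        x <- 0.5 + 1 / yi
        for (iter in 1:50) {
            tri <- trigamma(x)
            dif <- tri * (1 - tri / yi) / psigamma(x, deriv = 2L)
            x <- x + dif
            if (abs(dif) / x < 1e-10)
                break
        }
        x
    }, numeric(1))
}

#' Moderated two-group t-statistics with empirical-Bayes shrinkage
#'
#' Per feature, the log2 fold change is the mean difference
#' `treatment - reference` and the residual variance `s2` is pooled over
#' both groups with `d = n1 + n2 - 2` degrees of freedom. The prior
#' `(d0, s0^2)` is estimated by the closed-form method of moments on
#' `log(s2)` (mean and variance of the log-F distribution, trigamma
#' inversion); the posterior variance is
#' `(d0 s0^2 + d s2) / (d0 + d)`, and the moderated t uses `d0 + d`
#' degrees of freedom. With `priorDf = 0` the statistic reduces exactly
#' to the ordinary pooled two-sample t.
#'
#' @param log2Mat log2 intensity matrix, features x samples.
#' @param groups factor or character vector, one entry per column, with
#'   exactly two levels; the first level is the reference.
#' @param priorDf optional forced prior degrees of freedom (`NULL` =
#'   estimate; `0` = ordinary t; `Inf` = equal-variance limit).
#' @return data.frame `feature_id`, `log2_fc`, `t_mod`, `p_raw`,
#'   `df_total`, `s2`, `s2_post`, with attribute `ebayes` (list `d0`,
#'   `s0_sq`).
#' @export
fitModeratedT <- function(log2Mat, groups, priorDf = NULL) {
    stopifnot(is.matrix(log2Mat), length(groups) == ncol(log2Mat))
    groups <- factor(groups)
    if (nlevels(groups) != 2L)
        stop("exactly two groups required")
    n <- table(groups)
    if (any(n < 2L))
        stop("each group needs at least two samples")
    ref <- levels(groups)[1L]; trt <- levels(groups)[2L]
    m1 <- rowMeans(log2Mat[, groups == ref, drop = FALSE])
    m2 <- rowMeans(log2Mat[, groups == trt, drop = FALSE])
    v1 <- apply(log2Mat[, groups == ref, drop = FALSE], 1L, stats::var)
    v2 <- apply(log2Mat[, groups == trt, drop = FALSE], 1L, stats::var)
    n1 <- n[[ref]]; n2 <- n[[trt]]
    d <- n1 + n2 - 2L
    s2 <- ((n1 - 1L) * v1 + (n2 - 1L) * v2) / d
    lfc <- m2 - m1
    if (is.null(priorDf)) {
        pos <- s2 > 0
        if (sum(pos) < 2L)
            stop("too few positive residual variances to estimate the prior")
        z <- log(s2[pos])
        e <- z - digamma(d / 2) + log(d / 2)
        evar <- stats::var(e) - trigamma(d / 2)
        if (is.finite(evar) && evar > 0) {
            d0 <- 2 * trigammaInverse(evar)
            s0sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
        } else {
            d0 <- Inf
            s0sq <- exp(mean(e))
        }
    } else {
        stopifnot(priorDf >= 0)
        d0 <- priorDf
        s0sq <- if (d0 > 0) {
            pos <- s2 > 0
            z <- log(s2[pos])
            e <- z - digamma(d / 2) + log(d / 2)
            if (is.finite(d0)) exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
            else exp(mean(e))
        } else NA_real_
    }
    s2post <- if (d0 == 0) s2
        else if (is.infinite(d0)) rep(s0sq, length(s2))
        else (d0 * s0sq + d * s2) / (d0 + d)
    se <- sqrt(s2post * (1 / n1 + 1 / n2))
    tmod <- lfc / se
    dfTotal <- d0 + d
    p <- 2 * stats::pt(-abs(tmod), df = dfTotal)
    out <- data.frame(feature_id = rownames(log2Mat) %||%
                          as.character(seq_along(lfc)),
                      log2_fc = lfc, t_mod = tmod, p_raw = p,
                      df_total = dfTotal, s2 = s2, s2_post = s2post,
                      stringsAsFactors = FALSE, row.names = NULL)
    attr(out, "ebayes") <- list(d0 = d0, s0_sq = s0sq)
    out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin, validated wrapper around `stats::p.adjust(method = "BH")`.
#'
#' @param p vector of raw p-values in (0, 1\].
#' @return Adjusted p-values in the input order; elementwise
#'   `p_adj >= p_raw`.
#' @export
bhAdjust <- function(p) {
    if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
        stop("p-values must lie in (0, 1]")
    stats::p.adjust(p, method = "BH")
}

#' Volcano classification of differential results
#'
#' `grey` when not significant (`p_adj > alpha`); among significant
#' features, `red` when `|log2_fc| > log2FcRed` (default 3, i.e. a
#' fold change above 8) and `blue` otherwise.
#'
#' @param results data.frame with columns `log2_fc` and `p_adj`.
#' @param alpha adjusted-p significance threshold (default 0.01).
#' @param log2FcRed absolute log2 fold-change boundary for `red`
#'   (strictly greater than; default 3).
#' @return `results` with an added `volcano_class` column.
#' @export
volcanoClassify <- function(results, alpha = 0.01, log2FcRed = 3) {
    stopifnot(all(c("log2_fc", "p_adj") %in% colnames(results)))
    cls <- rep("grey", nrow(results))
    sig <- results$p_adj <= alpha
    cls[sig] <- ifelse(abs(results$log2_fc[sig]) > log2FcRed, "red", "blue")
    results$volcano_class <- cls
    results
}

#' Count up/down-regulated significant features
#'
#' @param results classified results from [volcanoClassify()].
#' @param classFilter which volcano classes count as significant
#'   (default `c("blue", "red")`).
#' @return Named integer vector `c(up =, down =)` by the sign of
#'   `log2_fc`.
#' @export
summarizeDirection <- function(results, classFilter = c("blue", "red")) {
    sig <- results[results$volcano_class %in% classFilter, , drop = FALSE]
    c(up = sum(sig$log2_fc > 0), down = sum(sig$log2_fc < 0))
}

#' Two-group differential analysis of a SulfateExperiment
#'
#' Convenience wrapper: extracts the biological samples of the two
#' requested groups from the corrected assay (falling back to raw
#' intensities when no normalization was run), prepares log2 values,
#' fits the moderated t, adjusts with Benjamini-Hochberg, and classifies
#' the volcano.
#'
#' @param se a [SulfateExperiment-class].
#' @param reference,treatment group labels in `colData(se)$group`; the
#'   log2 fold change is `treatment - reference`.
#' @param alpha,log2FcRed see [volcanoClassify()].
#' @param priorDf see [fitModeratedT()].
#' @return data.frame with `feature_id`, `mz`, `rt_seconds`, the
#'   moderated-t columns, `p_adj` and `volcano_class`; attribute
#'   `excluded` lists all-zero features.
#' @export
runDifferential <- function(se, reference, treatment, alpha = 0.01,
                            log2FcRed = 3, priorDf = NULL) {
    stopifnot(is(se, "SulfateExperiment"))
    cd <- SummarizedExperiment::colData(se)
    keep <- cd$role == "biological" & cd$group %in% c(reference, treatment)
    if (sum(cd$group[keep] == reference) < 2L ||
        sum(cd$group[keep] == treatment) < 2L)
        stop("need at least two biological replicates per group")
    assayName <- if ("corrected" %in%
                     names(SummarizedExperiment::assays(se))) "corrected"
                 else "intensities"
    mat <- SummarizedExperiment::assay(se, assayName)[, keep, drop = FALSE]
    prep <- log2Prepare(mat)
    groups <- factor(cd$group[keep], levels = c(reference, treatment))
    fit <- fitModeratedT(prep$log2, groups, priorDf = priorDf)
    fit$p_adj <- bhAdjust(fit$p_raw)
    fit <- volcanoClassify(fit, alpha = alpha, log2FcRed = log2FcRed)
    rd <- SummarizedExperiment::rowData(se)[fit$feature_id, ]
    out <- cbind(fit[, "feature_id", drop = FALSE],
                 data.frame(mz = rd$mz, rt_seconds = rd$rt_seconds),
                 fit[, setdiff(colnames(fit), "feature_id")])
    attr(out, "excluded") <- prep$excluded
    attr(out, "ebayes") <- attr(fit, "ebayes")
    out
}
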