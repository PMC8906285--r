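## Eight-parameter matrix, seeded k-means (k = 2) sulfate/non-sulfate
## classification, and sulfate speciation summaries.

.PARAM_COLUMNS <- c("SO3_radical_anion", "HSO3_anion", "SO4_radical_anion",
                    "HSO4_anion", "loss_SO3", "loss_H2SO4", "IR", "MA")

#' Build the eight-parameter clustering matrix
#'
#' One row per annotated feature; columns are the relative abundances of
#' the six diagnostic sulfate signals plus IR and MA, all on the 0-100
#' percent scale. Unmatched rules contribute 0.
#'
#' @param annotations annotation table from [annotateSpectra()] (with the
#'   default sulfate rules).
#' @return Numeric matrix, rownames = feature ids, 8 columns.
#' @export
buildParameterMatrix <- function(annotations) {
    if (anyDuplicated(annotations$feature_id))
        stop("duplicate feature ids in annotation table")
    missing <- setdiff(.PARAM_COLUMNS, colnames(annotations))
    if (length(missing) > 0L)
        stop("annotation table lacks parameter columns: ",
             paste(missing, collapse = ", "))
    m <- as.matrix(annotations[, .PARAM_COLUMNS])
    m[is.na(m)] <- 0
    rownames(m) <- annotations$feature_id
    if (any(m < 0) || any(m > 100))
        stop("parameter values must lie in [0, 100]")
    m
}

#' Z-score the columns of a parameter matrix
#'
#' Centers each column to mean 0 and scales to unit standard deviation
#' (n - 1 denominator, as in [base::scale]); constant columns map to all
#' zeros.
#'
#' @param m numeric matrix with at least two rows.
#' @return Scaled matrix of identical shape, with attributes
#'   `scaled:center` and `scaled:scale`.
#' @export
scaleColumns <- function(m) {
    stopifnot(is.matrix(m), nrow(m) >= 2L)
    s <- scale(m)
    const <- attr(s, "scaled:scale") == 0 | !is.finite(attr(s, "scaled:scale"))
    if (any(const))
        s[, const] <- 0
    s
}

## k-means++ initial centers: first uniform, next proportional to squared
## distance from the nearest chosen center.
.kmeansPlusPlusInit <- function(x, k) {
    n <- nrow(x)
    centers <- matrix(NA_real_, k, ncol(x))
    centers[1L, ] <- x[sample.int(n, 1L), ]
    d2 <- colSums((t(x) - centers[1L, ])^2)
    for (j in seq_len(k - 1L) + 1L) {
        if (all(d2 == 0))
            return(NULL)
        centers[j, ] <- x[sample.int(n, 1L, prob = d2), ]
        d2 <- pmin(d2, colSums((t(x) - centers[j, ])^2))
    }
    centers
}

#' Seeded two-cluster k-means over the spectral parameters
#'
#' Z-scores the parameter matrix ([scaleColumns()]), runs Lloyd's
#' algorithm ([stats::kmeans], Euclidean distance, k = 2) from
#' `nRestarts` k-means++ initializations drawn from a seeded RNG, keeps
#' the solution with the lowest within-cluster sum of squares, and labels
#' the cluster with the larger mean MA (original percent scale) as
#' `sulfate`.
#'
#' @param params eight-parameter matrix from [buildParameterMatrix()].
#' @param nRestarts number of k-means++ restarts (default 25).
#' @param seed integer RNG seed (restored after use).
#' @return A [SulfateClustering-class].
#' @export
kmeansSulfate <- function(params, nRestarts = 25L, seed = 1L) {
    stopifnot(is.matrix(params), nrow(params) >= 2L)
    scaled <- scaleColumns(params)
    if (nrow(unique(scaled)) < 2L)
        stop("all rows identical: no two-cluster partition exists")
    best <- NULL
    withSeed(seed, {
        for (r in seq_len(nRestarts)) {
            init <- .kmeansPlusPlusInit(scaled, 2L)
            if (is.null(init))
                next
            km <- tryCatch(
                stats::kmeans(scaled, centers = init, iter.max = 100L,
                              algorithm = "Lloyd"),
                error = function(e) NULL,
                warning = function(w) suppressWarnings(
                    stats::kmeans(scaled, centers = init, iter.max = 200L,
                                  algorithm = "Lloyd")))
            if (is.null(km))
                next
            if (is.null(best) || km$tot.withinss < best$tot.withinss)
                best <- km
        }
    })
    if (is.null(best))
        stop("k-means failed on all restarts")
    maMean <- tapply(params[, "MA"], best$cluster, mean)
    sulfateCluster <- as.integer(names(maMean)[which.max(maMean)])
    lab <- ifelse(best$cluster == sulfateCluster, "sulfate", "non_sulfate")
    names(lab) <- rownames(params)
    centroids <- best$centers[c(sulfateCluster, setdiff(1:2, sulfateCluster)), ,
                              drop = FALSE]
    rownames(centroids) <- c("sulfate", "non_sulfate")
    summ <- do.call(rbind, lapply(c("sulfate", "non_sulfate"), function(cl) {
        sub <- params[lab == cl, , drop = FALSE]
        data.frame(class = cl, n = nrow(sub),
                   IR_median = stats::median(sub[, "IR"]),
                   IR_mean = mean(sub[, "IR"]),
                   IR_min = min(sub[, "IR"]), IR_max = max(sub[, "IR"]),
                   MA_median = stats::median(sub[, "MA"]),
                   MA_mean = mean(sub[, "MA"]),
                   MA_min = min(sub[, "MA"]), MA_max = max(sub[, "MA"]),
                   stringsAsFactors = FALSE)
    }))
    new("SulfateClustering", assignment = lab, centroids = centroids,
        nSulfate = sum(lab == "sulfate"), nNonSulfate = sum(lab == "non_sulfate"),
        summaries = summ, totWithinss = best$tot.withinss)
}

#' Speciate sulfate features by their dominant diagnostic fragment
#'
#' @param annotations annotation table from [annotateSpectra()].
#' @param clustering a [SulfateClustering-class].
#' @return data.frame `species`, `n`, `percent` over the sulfate-class
#'   features (zero rows when there are none); percentages sum to 100 up
#'   to rounding.
#' @export
speciate <- function(annotations, clustering) {
    sulf <- sulfateFeatures(clustering)
    sub <- annotations[annotations$feature_id %in% sulf, , drop = FALSE]
    if (nrow(sub) == 0L)
        return(data.frame(species = character(0), n = integer(0),
                          percent = numeric(0)))
    dom <- ifelse(is.na(sub$dominant_species), "none", sub$dominant_species)
    tab <- sort(table(dom), decreasing = TRUE)
    data.frame(species = names(tab), n = as.integer(tab),
               percent = 100 * as.integer(tab) / nrow(sub),
               stringsAsFactors = FALSE, row.names = NULL)
}

#' Fraction of sulfate features with two or more diagnostic fragments
#'
#' Counts sulfate-class features whose spectra show at least two distinct
#' sulfate-derived signals above the relative-abundance threshold.
#'
#' @param annotations annotation table from [annotateSpectra()].
#' @param clustering a [SulfateClustering-class].
#' @param thresholdPct relative-abundance threshold in percent (default
#'   5).
#' @return Percentage in \[0, 100\] (`NaN` when there are no sulfate
#'   features).
#' @export
multiFragmentFraction <- function(annotations, clustering, thresholdPct = 5) {
    sulf <- sulfateFeatures(clustering)
    sub <- annotations[annotations$feature_id %in% sulf, , drop = FALSE]
    ruleCols <- intersect(.PARAM_COLUMNS[1:6], colnames(sub))
    nGe <- rowSums(as.matrix(sub[, ruleCols, drop = FALSE]) >= thresholdPct)
    100 * sum(nGe >= 2L) / nrow(sub)
}
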