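## Shared fixtures and independent oracles, all built in code.

## Random elemental formula over the supported elements.
randomFormula <- function() {
    elems <- c("C", "H", "N", "O", "P", "S")
    pick <- sample(elems, sample(1:4, 1))
    counts <- sample(1:30, length(pick), replace = TRUE)
    names(counts) <- pick
    paste0(vapply(names(counts), function(s)
        paste0(s, counts[[s]]), character(1)), collapse = "")
}

toySpectrum <- function(mz, intensity, precursor = 367.1583, rt = 100,
                        id = "sp1") {
    MsmsSpectrum(id, precursor, rt, cbind(mz = mz, intensity = intensity))
}

## Minimal SulfateExperiment builder.
toySe <- function(mz, rtSec, snr = rep(10, length(mz)), intensities = NULL,
                  roles = NULL, groups = NULL, ids = NULL) {
    n <- length(mz)
    if (is.null(intensities))
        intensities <- matrix(100, n, 2,
                              dimnames = list(NULL, c("A", "B")))
    samples <- colnames(intensities)
    if (is.null(roles))
        roles <- rep("biological", length(samples))
    if (is.null(groups))
        groups <- rep("g", length(samples))
    if (is.null(ids))
        ids <- sprintf("F%03d", seq_len(n))
    tab <- data.frame(feature_id = ids, mz = mz, rt = rtSec, snr = snr,
                      check.names = FALSE)
    tab <- cbind(tab, as.data.frame(intensities))
    sheet <- data.frame(sample_id = samples, role = roles, group = groups,
                        injection_order = seq_along(samples))
    SulfateExperiment(tab, sheet, rtUnit = "seconds")
}

## Brute-force Benjamini-Hochberg step-up, straight from the definition:
## p_adj(i) = min over j >= i (in sorted order) of min(1, m p_(j) / j).
bruteBH <- function(p) {
    m <- length(p)
    o <- order(p)
    ps <- p[o]
    adj <- numeric(m)
    for (i in seq_len(m)) {
        vals <- vapply(i:m, function(j) min(1, m * ps[j] / j), numeric(1))
        adj[i] <- min(vals)
    }
    out <- numeric(m)
    out[o] <- adj
    out
}

## Exhaustive best two-cluster partition by within-cluster sum of squares.
bruteBestBipartition <- function(x) {
    n <- nrow(x)
    stopifnot(n <= 12)
    best <- NULL
    for (code in 1:(2^(n - 1) - 1)) {  # fix row 1 in cluster 0 (symmetry)
        lab <- c(0L, as.integer(intToBits(code)[seq_len(n - 1)]))
        wcss <- 0
        for (cl in 0:1) {
            sub <- x[lab == cl, , drop = FALSE]
            cen <- colMeans(sub)
            wcss <- wcss + sum(sweep(sub, 2, cen)^2)
        }
        if (is.null(best) || wcss < best$wcss)
            best <- list(labels = lab, wcss = wcss)
    }
    best
}

## Ordinary pooled two-sample t per row (oracle for the priorDf = 0 limit).
pooledT <- function(mat, groups) {
    groups <- factor(groups)
    g1 <- levels(groups)[1]; g2 <- levels(groups)[2]
    x1 <- mat[, groups == g1, drop = FALSE]
    x2 <- mat[, groups == g2, drop = FALSE]
    n1 <- ncol(x1); n2 <- ncol(x2)
    v1 <- apply(x1, 1, var); v2 <- apply(x2, 1, var)
    s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    (rowMeans(x2) - rowMeans(x1)) / sqrt(s2 * (1 / n1 + 1 / n2))
}
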