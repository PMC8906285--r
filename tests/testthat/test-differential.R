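test_that("log2 preparation imputes half-minimum and drops all-zero rows", {
    mat <- rbind(F1 = c(8, 8, 8, 8), F2 = c(0, 4, 8, 8), F3 = c(0, 0, 0, 0))
    prep <- log2Prepare(mat)
    expect_equal(prep$excluded, "F3")
    expect_equal(unname(prep$log2["F1", 1]), 3)
    expect_equal(unname(prep$log2["F2", 1]), 1)  # half of min nonzero (4) -> 2
})

test_that("forcing the prior df to zero recovers the ordinary pooled t", {
    set.seed(71)
    mat <- matrix(rnorm(100 * 6), 100, 6,
                  dimnames = list(sprintf("F%03d", 1:100), NULL))
    groups <- rep(c("a", "b"), each = 3)
    fit <- fitModeratedT(mat, groups, priorDf = 0)
    expect_equal(fit$t_mod, unname(pooledT(mat, groups)), tolerance = 1e-12)
    expect_equal(fit$df_total, rep(4, 100))
    ## identical group means: zero fold change, p near 1
    mat2 <- matrix(rep(c(1, 2, 3), 4), nrow = 1)
    fit2 <- fitModeratedT(rbind(mat2, mat2 + 1), rep(c("a", "b"), each = 6),
                          priorDf = 0)
    expect_equal(fit2$log2_fc, c(0, 0))
    expect_equal(fit2$p_raw, c(1, 1), tolerance = 1e-9)
    expect_error(fitModeratedT(mat[, 1:3], c("a", "a", "b")), "at least two")
})

test_that("empirical-Bayes moderation matches the limma estimator", {
    set.seed(72)
    ## heteroscedastic features so the prior df is finite and informative
    sd <- sqrt(1 / rgamma(300, shape = 4, rate = 2))
    mat <- matrix(rnorm(300 * 8, sd = rep(sd, 8)), 300, 8,
                  dimnames = list(sprintf("F%03d", 1:300), NULL))
    groups <- factor(rep(c("a", "b"), each = 4))
    fit <- fitModeratedT(mat, groups)
    eb <- attr(fit, "ebayes")
    design <- stats::model.matrix(~groups)
    lfit <- limma::eBayes(limma::lmFit(mat, design))
    expect_equal(eb$d0, lfit$df.prior, tolerance = 0.02)
    expect_equal(eb$s0_sq, lfit$s2.prior, tolerance = 0.02)
    expect_equal(fit$t_mod, unname(lfit$t[, 2]), tolerance = 1e-6)
    expect_equal(fit$p_raw, unname(lfit$p.value[, 2]), tolerance = 1e-6)
})

test_that("BH adjustment equals the brute-force step-up definition", {
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
    expect_equal(bhAdjust(0.2), 0.2)
    set.seed(73)
    for (i in 1:50) {
        p <- runif(sample(1:20, 1))
        adj <- bhAdjust(p)
        expect_equal(adj, bruteBH(p), tolerance = 1e-12)
        expect_true(all(adj >= p))
        expect_true(all(adj <= 1))
    }
    expect_error(bhAdjust(c(0.1, 0)), "\\(0, 1\\]")
    expect_error(bhAdjust(c(0.1, 1.2)), "\\(0, 1\\]")
})

test_that("volcano classes follow the alpha and fold-change boundaries", {
    res <- data.frame(log2_fc = c(10, 1, 2, -5, 3),
                      p_adj = c(0.005, 0.5, 0.005, 0.001, 0.009))
    cls <- volcanoClassify(res)$volcano_class
    expect_equal(cls, c("red", "grey", "blue", "red", "blue"))
    ## boundary |lfc| = 3 is blue (red is strictly greater)
    expect_equal(volcanoClassify(data.frame(log2_fc = 3, p_adj = 0.005))$
                     volcano_class, "blue")
})

test_that("direction counts split significant features by sign", {
    res <- volcanoClassify(data.frame(
        log2_fc = c(rep(4, 5), rep(-4, 3), 2),
        p_adj = c(rep(0.001, 8), 0.5)))
    expect_equal(summarizeDirection(res), c(up = 5L, down = 3L))
    expect_equal(summarizeDirection(res[res$p_adj > 0.1, ]),
                 c(up = 0L, down = 0L))
})

test_that("runDifferential wires the assay, groups and annotations together", {
    set.seed(74)
    samples <- c("c1", "c2", "c3", "t1", "t2", "t3")
    ints <- matrix(2^rnorm(60 * 6, 10, 0.3), 60, 6,
                   dimnames = list(NULL, samples))
    ints[1:5, 4:6] <- ints[1:5, 4:6] * 2^6  # strong spike
    se <- toySe(mz = runif(60, 250, 600), rtSec = runif(60, 60, 1200),
                intensities = ints, roles = rep("biological", 6),
                groups = rep(c("ctrl", "trt"), each = 3))
    res <- runDifferential(se, "ctrl", "trt")
    expect_true(all(res$p_adj >= res$p_raw))
    expect_true(all(res$volcano_class[1:5] == "red"))
    expect_equal(res$feature_id, rownames(se))
})
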