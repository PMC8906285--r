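mkSpec <- function(id, mz, rt, int = 100) {
    MsmsSpectrum(id, mz, rt, cbind(mz = 100, intensity = 1),
                 precursorIntensity = int)
}

test_that("spectra map to features under the closest-RT rule", {
    se <- toySe(mz = c(300, 400), rtSec = c(100, 500))
    ## exact match assigned; 2nd feature has no candidate
    sp <- list(mkSpec("a", 300, 100))
    se1 <- mapSpectraToFeatures(sp, se)
    rd <- SummarizedExperiment::rowData(se1)
    expect_equal(rd$spectrum_id, c("a", NA))
    expect_equal(rd$has_msms, c(TRUE, FALSE))
    ## closer of two candidates wins
    sp <- list(mkSpec("far", 300, 102), mkSpec("near", 300, 101))
    rd <- SummarizedExperiment::rowData(mapSpectraToFeatures(sp, se))
    expect_equal(rd$spectrum_id[1], "near")
    ## outside the RT tolerance: unassigned
    sp <- list(mkSpec("a", 300, 104.1))
    rd <- SummarizedExperiment::rowData(mapSpectraToFeatures(sp, se,
                                                             rtTolSeconds = 3))
    expect_false(rd$has_msms[1])
    ## outside the ppm tolerance: unassigned
    sp <- list(mkSpec("a", 300 * (1 + 6e-6), 100))
    rd <- SummarizedExperiment::rowData(mapSpectraToFeatures(sp, se))
    expect_false(rd$has_msms[1])
})

test_that("mapping is injective and invariant to input order", {
    set.seed(41)
    n <- 40
    mz <- runif(n, 250, 600)
    rt <- runif(n, 60, 1200)
    se <- toySe(mz, rt)
    spectra <- lapply(seq_len(n), function(i)
        mkSpec(sprintf("s%02d", i), mz[i] * (1 + runif(1, -3e-6, 3e-6)),
               rt[i] + runif(1, -2, 2), int = runif(1, 1, 100)))
    rd <- SummarizedExperiment::rowData(mapSpectraToFeatures(spectra, se))
    ids <- rd$spectrum_id[!is.na(rd$spectrum_id)]
    expect_equal(anyDuplicated(ids), 0L)
    ## shuffling the spectrum list changes nothing
    rd2 <- SummarizedExperiment::rowData(
        mapSpectraToFeatures(sample(spectra), se))
    expect_equal(rd2$spectrum_id, rd$spectrum_id)
})

test_that("curation filters remove features with the first failing reason", {
    ints <- rbind(c(10, 10), c(10, 10), c(10, 0), c(10, 10))
    colnames(ints) <- c("A", "B")
    se <- toySe(mz = c(300, 310, 320, 330), rtSec = c(1, 2, 3, 4) * 100,
                snr = c(10, 2.9, 10, 10), intensities = ints)
    spectra <- list(mkSpec("s1", 300, 100), mkSpec("s2", 310, 200),
                    mkSpec("s3", 320, 300))  # 4th feature: no spectrum
    se <- mapSpectraToFeatures(spectra, se)
    fl <- filterFeatures(se)
    expect_equal(nrow(fl$kept), 1)
    expect_equal(fl$removed$reason[fl$removed$feature_id == "F002"], "low_snr")
    expect_equal(fl$removed$reason[fl$removed$feature_id == "F003"],
                 "too_few_samples")
    expect_equal(fl$removed$reason[fl$removed$feature_id == "F004"], "no_msms")
    ## idempotence
    fl2 <- filterFeatures(fl$kept)
    expect_equal(nrow(fl2$removed), 0)
    expect_equal(rownames(fl2$kept), rownames(fl$kept))
})

test_that("blank exclusion removes co-eluting blank-derived features", {
    n <- 20
    set.seed(42)
    mz <- seq(300, 500, length.out = n)
    rt <- seq(100, 1000, length.out = n)
    ints <- cbind(S1 = runif(n, 50, 100), Blank1 = 0)
    ints[1:3, "Blank1"] <- c(1000, 900, 800)  # blank contaminants
    se <- toySe(mz, rt, intensities = ints,
                roles = c("biological", "blank"),
                groups = c("ctrl", "blank"))
    bl <- blankExclusion(se, topN = 1000)
    expect_equal(nrow(bl$kept), 17)
    expect_setequal(bl$removed$feature_id, c("F001", "F002", "F003"))
    ## topN = 0 is the identity
    expect_equal(nrow(blankExclusion(se, topN = 0)$kept), n)
    ## no blank samples -> error
    se2 <- toySe(mz, rt, intensities = ints)
    expect_error(blankExclusion(se2), "blank")
})
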