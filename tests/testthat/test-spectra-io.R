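test_that("MGF round trip preserves randomized spectra", {
    set.seed(21)
    spectra <- lapply(1:5, function(i) {
        k <- sample(1:12, 1)
        MsmsSpectrum(paste0("scan", i), runif(1, 200, 600), runif(1, 60, 1200),
                     cbind(mz = runif(k, 50, 500),
                           intensity = runif(k, 1, 1e6)),
                     precursorIntensity = runif(1, 1e4, 1e7))
    })
    path <- withr::local_tempfile(fileext = ".mgf")
    writeMgf(spectra, path)
    back <- readMgf(path)
    expect_length(back, 5)
    for (i in 1:5) {
        expect_equal(spectrumId(back[[i]]), spectrumId(spectra[[i]]))
        expect_equal(precursorMz(back[[i]]), precursorMz(spectra[[i]]),
                     tolerance = 1e-6)
        expect_equal(rtSeconds(back[[i]]), rtSeconds(spectra[[i]]),
                     tolerance = 1e-4)
        expect_equal(peakMatrix(back[[i]]), peakMatrix(spectra[[i]]),
                     tolerance = 1e-6)
    }
    ## empty list gives an empty, readable file
    writeMgf(list(), path)
    expect_length(readMgf(path), 0)
})

test_that("spectrum construction sorts peaks and drops zero intensities", {
    sp <- toySpectrum(c(300, 100, 200), c(5, 10, 7))
    expect_equal(peakMatrix(sp)[, "mz"], c(100, 200, 300))
    path <- withr::local_tempfile(fileext = ".mgf")
    writeLines(c("BEGIN IONS", "TITLE=z", "PEPMASS=300.1", "RTINSECONDS=12",
                 "150.0 0", "120.5 33", "END IONS"), path)
    sp2 <- readMgf(path)[[1]]
    expect_equal(nrow(peakMatrix(sp2)), 1)  # zero-intensity peak dropped
    expect_equal(unname(peakMatrix(sp2)[1, "mz"]), 120.5)
})

test_that("malformed MGF blocks raise informative errors", {
    path <- withr::local_tempfile(fileext = ".mgf")
    writeLines(c("BEGIN IONS", "TITLE=a", "RTINSECONDS=5",
                 "100 1", "END IONS"), path)
    expect_error(readMgf(path), "PEPMASS missing")
    writeLines(c("BEGIN IONS", "TITLE=a", "PEPMASS=200.2",
                 "100 1", "END IONS"), path)
    expect_error(readMgf(path), "RTINSECONDS missing")
    writeLines(c("BEGIN IONS", "TITLE=a", "PEPMASS=200.2", "RTINSECONDS=5",
                 "100 1", "garbage_line", "END IONS"), path)
    expect_error(readMgf(path), "peak line 6")
})

test_that("feature table IO round-trips and applies the zero convention", {
    sheet <- data.frame(sample_id = c("S1", "QC1"),
                        role = c("biological", "pooled_qc"),
                        group = c("ctrl", "QC"), injection_order = 1:2)
    path <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("feature_id,mz,rt,snr,S1,QC1",
                 "F1,300.5,2.5,10,100,90",
                 "F2,400.1,5.0,8,,50",
                 "F3,250.2,7.1,4,20,30"), path)
    se <- readFeatureTable(path, sheet)
    expect_equal(dim(se), c(3L, 2L))
    expect_equal(unname(SummarizedExperiment::assay(se)["F2", "S1"]), 0)
    expect_equal(unname(featureRt(se)["F1"]), 150)  # minutes -> seconds
    out <- withr::local_tempfile(fileext = ".csv")
    writeFeatureTable(se, out)
    se2 <- readFeatureTable(out, sheet)
    expect_equal(SummarizedExperiment::assay(se2),
                 SummarizedExperiment::assay(se))
    expect_equal(featureRt(se2), featureRt(se))
    expect_equal(featureMz(se2), featureMz(se))
})

test_that("feature table and sample sheet contracts are enforced", {
    sheet <- data.frame(sample_id = c("S1", "QC3"),
                        role = c("biological", "pooled_qc"),
                        group = c("ctrl", "QC"), injection_order = 1:2)
    path <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("feature_id,mz,rt,snr,S1", "F1,300.5,2.5,10,100"), path)
    expect_error(readFeatureTable(path, sheet), "QC3")
    writeLines(c("feature_id,mz,rt,snr,S1,QC3",
                 "F1,300.5,2.5,10,100,1", "F1,301.5,2.6,10,100,1"), path)
    expect_error(readFeatureTable(path, sheet), "duplicate feature_id")
    badSheet <- sheet; badSheet$injection_order <- c(1, 1)
    expect_error(SulfateExperiment(
        data.frame(feature_id = "F1", mz = 1, rt = 1, snr = 1, S1 = 1, QC3 = 1),
        badSheet), "injection_order")
})
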