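test_that("default rule sets carry the expected signals and masses", {
    sr <- defaultSulfateRules()
    expect_equal(nrow(sr), 6)
    expect_equal(sum(sr$kind == "product_ion"), 4)
    expect_equal(round(sr$accurate_mass[sr$name == "HSO4_anion"], 4), 96.9601)
    ## electron-mass identity for the SO3 ion/loss pair
    expect_equal(sr$accurate_mass[sr$name == "SO3_radical_anion"] -
                     sr$accurate_mass[sr$name == "loss_SO3"],
                 0.00054858, tolerance = 1e-12)
    gr <- defaultGlucuronideRules()
    expect_equal(nrow(gr), 7)
    ## frozen from hand sums: C6H10O7 = 194.0427, [C2H3O3]- = 75.0088
    expect_equal(round(gr$accurate_mass[gr$formula == "C6H10O7"], 4), 194.0427)
    expect_equal(round(gr$accurate_mass[gr$name == "gluc_75"], 4), 75.0088)
    expect_error(fragmentRules("a", "product_ion", "sulfate", -1))
    expect_error(fragmentRules(c("a", "a"), "product_ion", "sulfate", c(1, 2)),
                 "unique")
})

test_that("product ions and neutral losses match as specified", {
    sp <- toySpectrum(96.9601, 500, precursor = 367.1583)
    m <- matchFragments(sp)
    expect_equal(m$name, "HSO4_anion")
    ## neutral loss: 367.1583 - 287.2015 = 79.9568
    sp <- toySpectrum(287.2015, 300, precursor = 367.1583)
    m <- matchFragments(sp)
    expect_equal(m$name, "loss_SO3")
    expect_lt(abs(m$mass_error), 0.010)
    sp <- toySpectrum(150.0, 100, precursor = 367.1583)
    expect_equal(nrow(matchFragments(sp)), 0)
    ## most intense of several in-window peaks is kept
    sp <- toySpectrum(c(96.9590, 96.9605), c(10, 90), precursor = 400)
    m <- matchFragments(sp)
    expect_equal(m$intensity, 90)
})

test_that("IR, MA, dominant species and the 5% count follow their definitions", {
    sp <- toySpectrum(c(96.9601, 79.9573, 150.0), c(50, 30, 20),
                      precursor = 367.1583)
    ann <- computeAnnotation(sp, matchFragments(sp))
    expect_equal(ann$IR, 80)   # 100 x (50 + 30) / 100
    expect_equal(ann$MA, 100)  # 100 x 50 / 50 (base peak is matched)
    expect_equal(ann$dominant_species, "HSO4_anion")
    expect_equal(ann$n_fragments_ge5pct, 2L)
    ## no matches
    sp0 <- toySpectrum(150, 10)
    ann0 <- computeAnnotation(sp0, matchFragments(sp0))
    expect_equal(c(ann0$IR, ann0$MA), c(0, 0))
    expect_true(is.na(ann0$dominant_species))
    ## single matched peak is the limiting case IR = MA = 100
    sp1 <- toySpectrum(96.9601, 42, precursor = 400)
    ann1 <- computeAnnotation(sp1, matchFragments(sp1))
    expect_equal(c(ann1$IR, ann1$MA), c(100, 100))
})

test_that("annotation statistics respect their invariants on random spectra", {
    set.seed(31)
    for (i in 1:40) {
        k <- sample(1:15, 1)
        sp <- toySpectrum(runif(k, 50, 500), runif(k, 1, 1000),
                          precursor = runif(1, 250, 600))
        m <- matchFragments(sp)
        ann <- computeAnnotation(sp, m)
        expect_gte(ann$IR, 0); expect_lte(ann$IR, 100)
        expect_gte(ann$MA, 0); expect_lte(ann$MA, 100)
        if (nrow(m) > 0) {
            expect_true(all(ann$MA >= m$relative_abundance))
            ## uniform intensity rescaling leaves the annotation unchanged
            pk <- peakMatrix(sp)
            sp2 <- MsmsSpectrum("s", precursorMz(sp), rtSeconds(sp),
                                cbind(mz = pk[, "mz"],
                                      intensity = pk[, "intensity"] * 37.5))
            ann2 <- computeAnnotation(sp2, matchFragments(sp2))
            expect_equal(ann2$IR, ann$IR, tolerance = 1e-9)
            expect_equal(ann2$MA, ann$MA, tolerance = 1e-9)
            ## deleting all non-matching peaks: IR -> 100, MA unchanged
            keep <- sort(unique(m$peak_index))
            sp3 <- MsmsSpectrum("s", precursorMz(sp), rtSeconds(sp),
                                pk[keep, , drop = FALSE])
            m3 <- matchFragments(sp3)
            ann3 <- computeAnnotation(sp3, m3)
            if (max(pk[keep, "intensity"]) == max(pk[, "intensity"]))
                expect_equal(ann3$MA, ann$MA, tolerance = 1e-9)
            expect_equal(ann3$IR, 100, tolerance = 1e-9)
        }
    }
})

test_that("glucuronide calls require two distinct transitions", {
    ## rule masses frozen from formula sums: [C6H7O6]- 175.0248,
    ## [C5H5O3]- 113.0244
    sp <- toySpectrum(c(113.0244, 175.0248), c(80, 100), precursor = 463.2)
    res <- isGlucuronide(sp)
    expect_true(res$is_glucuronide)
    expect_setequal(res$matched_rules, c("gluc_113", "gluc_175"))
    sp1 <- toySpectrum(175.0248, 100, precursor = 463.2)
    expect_false(isGlucuronide(sp1)$is_glucuronide)
    expect_false(isGlucuronide(toySpectrum(300, 1))$is_glucuronide)
})

test_that("annotateSpectra produces the parameter columns for every rule", {
    sp <- toySpectrum(c(96.9601, 79.9573, 150.0), c(50, 30, 20),
                      precursor = 367.1583)
    tab <- annotateSpectra(list(F1 = sp))
    expect_equal(tab$feature_id, "F1")
    expect_equal(tab$HSO4_anion, 100)
    expect_equal(tab$SO3_radical_anion, 60)
    expect_equal(tab$loss_SO3, 0)
    expect_equal(tab$IR, 80)
})
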