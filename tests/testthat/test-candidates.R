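test_that("multiset enumeration matches the stars-and-bars count", {
    cand <- enumerateCandidates("C19H28O2", "testosterone")
    expect_equal(attr(cand, "nEnumerated"), 20)  # 1 + 3 + 6 + 10
    ## parameterised: T transformation types, depth d
    for (case in list(c(T = 2, d = 2, n = 6), c(T = 1, d = 3, n = 4),
                      c(T = 3, d = 1, n = 4))) {
        tr <- defaultBiotransformations()[seq_len(case[["T"]]), ]
        cand <- enumerateCandidates("C19H28O2", maxDepth = case[["d"]],
                                    transformations = tr)
        expect_equal(attr(cand, "nEnumerated"), unname(case[["n"]]))
    }
    ## oxidation+reduction cancels: duplicates collapsed with both multisets
    cand <- enumerateCandidates("C19H28O2", "testosterone")
    expect_lt(nrow(cand), 20)
    parentRow <- cand[cand$formula == "C19H28O5S", ]
    expect_match(parentRow$transformations, ";")
})

test_that("the steroid sulfate series is reachable within 5 ppm", {
    cand <- enumerateCandidates("C19H28O2", "testosterone")
    ## printed observed masses of the identified/unidentified series
    lookup <- function(observed)
        min(abs(ppmError(observed, cand$theoretical_mz)))
    expect_lt(lookup(367.1583), 5)   # testosterone sulfate
    expect_lt(lookup(369.1739), 5)   # epiandrosterone sulfate (+H2)
    expect_lt(lookup(371.1895), 5)   # androstanediol sulfate (+2 H2)
    expect_lt(lookup(383.1537), 5)   # +O
    expect_lt(lookup(385.1690), 5)   # +O +H2
    expect_lt(lookup(387.1845), 5)   # +O +2 H2
    ## the specific multisets behind the three confirmed structures
    tsRow <- cand[cand$formula == "C19H28O5S", ]
    expect_lt(abs(ppmError(367.1583, tsRow$theoretical_mz)), 5)
    redRow <- cand[cand$formula == "C19H30O5S", ]
    expect_match(redRow$transformations, "reduction")
    expect_lt(abs(ppmError(369.1739, redRow$theoretical_mz)), 5)
    red2Row <- cand[cand$formula == "C19H32O5S", ]
    expect_lt(abs(ppmError(371.1895, red2Row$theoretical_mz)), 5)
})

test_that("candidate masses round-trip through the formula arithmetic", {
    cand <- enumerateCandidates("C19H28O2", conjugate = "glucuronide",
                                maxDepth = 2)
    recomputed <- vapply(cand$formula, deprotonatedMz, numeric(1))
    expect_equal(unname(recomputed), cand$theoretical_mz, tolerance = 1e-12)
    ## glucuronide conjugation adds C6H8O6
    parentRow <- cand[cand$n_transformations == 0, ]
    expect_equal(parentRow$formula, "C25H36O8")
})

test_that("feature matching honours the ppm tolerance monotonically", {
    cand <- enumerateCandidates("C19H28O2", "testosterone")
    feats <- data.frame(feature_id = c("A", "B"), mz = c(369.1739, 500.0))
    m5 <- matchCandidates(feats, cand, ppmTol = 5)
    expect_true("A" %in% m5$feature_id)
    expect_false("B" %in% m5$feature_id)
    expect_equal(nrow(matchCandidates(feats, cand, ppmTol = 0.1)), 0)
    m10 <- matchCandidates(feats, cand, ppmTol = 10)
    key <- function(m) paste(m$feature_id, m$formula)
    expect_true(all(key(m5) %in% key(m10)))  # widening never removes a match
    expect_equal(nrow(matchCandidates(feats, cand[0, ])), 0)
})

test_that("the upregulated screen applies the fold-change window and alpha", {
    matches <- data.frame(feature_id = c("A", "B", "C"),
                          observed_mz = c(367.158, 369.174, 371.19),
                          parent = "testosterone", transformations = "",
                          formula = "x", theoretical_mz = 1, ppm_error = 0)
    diff <- data.frame(feature_id = c("A", "B", "C"),
                       log2_fc = c(10, 3, 8), p_adj = c(2e-7, 1e-5, 0.5))
    sl <- screenUpregulated(matches, diff)
    expect_equal(sl$feature_id, "A")   # B fails fold change, C fails alpha
    expect_equal(nrow(screenUpregulated(matches, diff[0, ])), 0)
})
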