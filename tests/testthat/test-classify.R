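## Synthetic eight-column parameter matrices for clustering tests.
blobMatrix <- function(nSulf, nOther, seed = 1) {
    set.seed(seed)
    sulf <- cbind(matrix(pmax(0, rnorm(nSulf * 6, 20, 10)), nSulf, 6),
                  pmin(100, pmax(0, rnorm(nSulf, 50, 15))),
                  pmin(100, pmax(40, rnorm(nSulf, 95, 5))))
    oth <- cbind(matrix(pmax(0, rnorm(nOther * 6, 0.5, 0.5)), nOther, 6),
                 pmax(0, rnorm(nOther, 2, 1)),
                 pmax(0, rnorm(nOther, 5, 3)))
    m <- rbind(sulf, oth)
    colnames(m) <- c("SO3_radical_anion", "HSO3_anion", "SO4_radical_anion",
                     "HSO4_anion", "loss_SO3", "loss_H2SO4", "IR", "MA")
    rownames(m) <- sprintf("F%04d", seq_len(nrow(m)))
    m
}

mkClustering <- function(ids, labels) {
    methods::new("SulfateClustering",
                 assignment = stats::setNames(labels, ids),
                 centroids = matrix(0, 2, 8,
                                    dimnames = list(c("sulfate", "non_sulfate"),
                                                    NULL)),
                 nSulfate = sum(labels == "sulfate"),
                 nNonSulfate = sum(labels == "non_sulfate"),
                 summaries = data.frame(), totWithinss = 0)
}

test_that("parameter matrix mirrors the annotation table", {
    sp <- toySpectrum(c(96.9601, 79.9573, 150.0), c(50, 30, 20),
                      precursor = 367.1583)
    tab <- annotateSpectra(list(F1 = sp, F2 = toySpectrum(150, 10)))
    m <- buildParameterMatrix(tab)
    expect_equal(dim(m), c(2L, 8L))
    expect_equal(m["F1", c("HSO4_anion", "SO3_radical_anion", "IR", "MA")],
                 c(HSO4_anion = 100, SO3_radical_anion = 60, IR = 80, MA = 100))
    expect_equal(unname(m["F2", ]), rep(0, 8))
    tab2 <- rbind(tab, tab[1, ])
    expect_error(buildParameterMatrix(tab2), "duplicate")
})

test_that("column scaling uses the n-1 convention and zeroes constants", {
    m <- cbind(a = c(0, 10), b = c(5, 5))
    s <- scaleColumns(m)
    expect_equal(unname(s[, "a"]), c(-1, 1) / sqrt(2), tolerance = 1e-12)
    expect_equal(unname(s[, "b"]), c(0, 0))
    ## scaling a scaled non-constant matrix is the identity
    m2 <- matrix(rnorm(40), 10, 4)
    s1 <- scaleColumns(m2)
    s2 <- scaleColumns(unclass(s1))
    expect_equal(unname(s2[, ]), unname(s1[, ]), tolerance = 1e-12)
})

test_that("k-means recovers well-separated sulfate and non-sulfate blobs", {
    m <- blobMatrix(200, 200, seed = 51)
    cl <- kmeansSulfate(m, seed = 5)
    truth <- rep(c("sulfate", "non_sulfate"), each = 200)
    expect_gte(mean(clusterAssignment(cl)[rownames(m)] == truth), 0.99)
    ## the sulfate class has the larger MA and IR medians (the expected
    ## qualitative pattern)
    s <- cl@summaries
    expect_gt(s$MA_median[s$class == "sulfate"],
              s$MA_median[s$class == "non_sulfate"])
    expect_gt(s$IR_median[s$class == "sulfate"],
              s$IR_median[s$class == "non_sulfate"])
})

test_that("k-means equals the exhaustive best-WCSS bipartition on tiny inputs", {
    for (seed in c(61, 62, 63, 64)) {
        m <- blobMatrix(3, 3, seed = seed)
        cl <- kmeansSulfate(m, seed = seed)
        scaled <- scaleColumns(m)
        oracle <- bruteBestBipartition(unclass(scaled)[, , drop = FALSE])
        expect_equal(cl@totWithinss, oracle$wcss, tolerance = 1e-8)
        ## same partition (up to label swap)
        km <- clusterAssignment(cl) == "sulfate"
        br <- oracle$labels == 1
        expect_true(all(km == br) || all(km == !br))
    }
})

test_that("k-means is deterministic and rejects degenerate input", {
    m <- blobMatrix(10, 10, seed = 65)
    cl1 <- kmeansSulfate(m, seed = 9)
    cl2 <- kmeansSulfate(m, seed = 9)
    expect_equal(clusterAssignment(cl1), clusterAssignment(cl2))
    ## a duplicated row gets the same label as the original
    m2 <- rbind(m, dup = m[1, ])
    rownames(m2)[nrow(m2)] <- "dup"
    cl3 <- kmeansSulfate(m2, seed = 9)
    expect_equal(unname(clusterAssignment(cl3)["dup"]),
                 unname(clusterAssignment(cl3)[rownames(m)[1]]))
    ## identical rows cannot be partitioned
    same <- m[rep(1, 5), ]
    expect_error(kmeansSulfate(same, seed = 1), "identical")
})

test_that("speciation tabulates dominant species over sulfate features", {
    ids <- sprintf("F%02d", 1:12)
    ann <- data.frame(feature_id = ids,
                      dominant_species = c(rep("HSO4_anion", 6),
                                           rep("SO3_radical_anion", 3),
                                           rep("loss_SO3", 1), NA, NA),
                      stringsAsFactors = FALSE)
    cl <- mkClustering(ids, c(rep("sulfate", 10), rep("non_sulfate", 2)))
    tab <- speciate(ann, cl)
    expect_equal(tab$percent[tab$species == "HSO4_anion"], 60)
    expect_equal(sum(tab$percent), 100)
    ## zero sulfates -> empty table
    cl0 <- mkClustering(ids, rep("non_sulfate", 12))
    expect_equal(nrow(speciate(ann, cl0)), 0)
})

test_that("multi-fragment fraction counts rules above the threshold", {
    ids <- sprintf("F%02d", 1:10)
    ruleCols <- c("SO3_radical_anion", "HSO3_anion", "SO4_radical_anion",
                  "HSO4_anion", "loss_SO3", "loss_H2SO4")
    ann <- as.data.frame(matrix(0, 10, 6, dimnames = list(NULL, ruleCols)))
    ann$feature_id <- ids
    ann[1:7, c("SO3_radical_anion", "HSO4_anion")] <- 50  # 7 multi-fragment
    ann[8:10, "HSO4_anion"] <- 50
    cl <- mkClustering(ids, rep("sulfate", 10))
    expect_equal(multiFragmentFraction(ann, cl), 70)
    ## threshold 0 counts every matched rule
    ann[8, "SO3_radical_anion"] <- 0.5
    expect_equal(multiFragmentFraction(ann, cl, thresholdPct = 0.1), 80)
})
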