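## Seeded generator of synthetic DDA datasets with known ground truth:
## MGF spectra + aligned feature table + sample sheet. Sulfate spectra are
## built to hit exact IR/MA targets; non-sulfate spectra are guaranteed
## free of peaks inside the sulfate matching windows.

#' Synthetic-study configuration
#'
#' Defaults emulate the equine DDA study conditions: 28 percent sulfate
#' features, triplicate biological groups, pooled QCs dispersed through
#' the injection sequence, log-normal intensities with multiplicative
#' injection-order drift, and a spiked subset with log2 fold changes of
#' 4-10 (16- to 1024-fold).
#'
#' @param nFeatures number of aligned features (default 500).
#' @param fracSulfate,fracGlucuronide class fractions (exact counts, not
#'   Bernoulli); must sum to at most 1.
#' @param groups named integer vector of biological replicate counts per
#'   condition (exactly two conditions; each >= 2).
#' @param nQc number of pooled QC injections (>= 3 for LOWESS).
#' @param nBlank number of extraction blanks.
#' @param fracSpiked fraction of features spiked with a differential
#'   effect in the second (treatment) group.
#' @param spikeLog2fcRange range of |log2 fold change| for spiked
#'   features.
#' @param fracSpikedDown fraction of spiked features that are
#'   down-regulated (default 0.37, echoing the observed up/down split).
#' @param baseIntensityLogMean,baseIntensityLogSd natural-log mean/sd of
#'   per-feature base intensity.
#' @param driftSlopePerInjection multiplicative signal drift per
#'   injection (default 0.02, i.e. 2 percent).
#' @param noiseSdLog2 biological replicate noise SD on the log2 scale
#'   (default 0.5).
#' @param qcNoiseSdLog2 analytical noise SD for pooled QCs (default 0.1).
#' @param sulfateSpeciesMix named weights over the six sulfate rules for
#'   the dominant species (defaults echo the equine speciation: radical
#'   SO3 51 percent, SO3 loss 22 percent, HSO4 20 percent, ...).
#' @param minSulfateIR minimum IR (percent) built into sulfate spectra
#'   (default 5; IR targets are drawn uniformly between this and 97).
#' @param fracBlankContaminant fraction of features that are
#'   blank-derived contaminants.
#' @param fracNoMsms,fracLowSnr,fracFewSamples fractions of
#'   non-sulfate/non-glucuronide features carrying each curation defect.
#' @param seed integer RNG seed; everything is reproducible from it.
#' @return List of class `"SynthConfig"`.
#' @export
synthConfig <- function(nFeatures = 500L,
                        fracSulfate = 0.28,
                        fracGlucuronide = 0.05,
                        groups = c(control = 3L, treatment = 3L),
                        nQc = 6L,
                        nBlank = 2L,
                        fracSpiked = 0.05,
                        spikeLog2fcRange = c(4, 10),
                        fracSpikedDown = 0.37,
                        baseIntensityLogMean = log(1e6),
                        baseIntensityLogSd = 1,
                        driftSlopePerInjection = 0.02,
                        noiseSdLog2 = 0.5,
                        qcNoiseSdLog2 = 0.1,
                        sulfateSpeciesMix = c(SO3_radical_anion = 0.51,
                                              loss_SO3 = 0.22,
                                              HSO4_anion = 0.20,
                                              HSO3_anion = 0.05,
                                              SO4_radical_anion = 0.01,
                                              loss_H2SO4 = 0.01),
                        minSulfateIR = 5,
                        fracBlankContaminant = 0.02,
                        fracNoMsms = 0.03,
                        fracLowSnr = 0.03,
                        fracFewSamples = 0.02,
                        seed = 1L) {
    cfg <- as.list(environment())
    fr <- c(cfg$fracSulfate, cfg$fracGlucuronide, cfg$fracSpiked,
            cfg$fracBlankContaminant, cfg$fracNoMsms, cfg$fracLowSnr,
            cfg$fracFewSamples)
    if (any(fr < 0) || any(fr > 1))
        stop("fractions must lie in [0, 1]")
    if (cfg$fracSulfate + cfg$fracGlucuronide > 1)
        stop("fracSulfate + fracGlucuronide must not exceed 1")
    if (length(cfg$groups) != 2L || is.null(names(cfg$groups)))
        stop("groups must be a named vector of two replicate counts")
    if (any(cfg$groups < 2L))
        stop("each condition needs at least two replicates")
    if (abs(sum(cfg$sulfateSpeciesMix) - 1) > 1e-6)
        stop("sulfateSpeciesMix weights must sum to 1")
    if (!all(names(cfg$sulfateSpeciesMix) %in% defaultSulfateRules()$name))
        stop("sulfateSpeciesMix names must be sulfate rule names")
    if (diff(cfg$spikeLog2fcRange) < 0 || cfg$spikeLog2fcRange[1L] <= 0)
        stop("spikeLog2fcRange must be an increasing positive range")
    class(cfg) <- "SynthConfig"
    cfg
}

#' Study-scale default configuration
#'
#' Convenience wrapper returning [synthConfig()] defaults, whose class
#' proportions echo the equine study (28 percent sulfates, spike range
#' 16- to 1024-fold); `nFeatures = 500` keeps the default desk-scale,
#' with the full 3467-feature scale available by argument.
#'
#' @param nFeatures number of features (default 500).
#' @param ... overrides passed to [synthConfig()].
#' @return A `SynthConfig`.
#' @export
defaultPaperLikeConfig <- function(nFeatures = 500L, ...) {
    synthConfig(nFeatures = nFeatures, ...)
}

## Sample peak m/z values avoiding the diagnostic matching windows (both
## families), for ions directly and for the implied neutral loss.
.randomCleanMz <- function(n, precursor, ionMasses, lossMasses,
                           lo = 50, hi = NULL, margin = 0.03) {
    hi <- hi %||% (precursor - 5)
    out <- numeric(0)
    while (length(out) < n) {
        p <- stats::runif(n, lo, hi)
        bad <- vapply(p, function(x) {
            any(abs(x - ionMasses) <= margin) ||
                any(abs((precursor - x) - lossMasses) <= margin)
        }, logical(1))
        out <- c(out, p[!bad])
    }
    out[seq_len(n)]
}

## Distribute `total` over peaks each bounded by ~90 (relative scale).
.splitIntensity <- function(total, maxEach = 90) {
    if (total <= 0)
        return(numeric(0))
    k <- max(1L, ceiling(total / (maxEach * 0.66)))
    w <- stats::runif(k, 0.5, 1.5)
    vals <- total * w / sum(w)
    if (max(vals) > maxEach)  # rare: rebalance uniformly
        vals <- rep(total / k, k)
    vals
}

#' Generate a synthetic DDA study with ground truth
#'
#' Produces MS/MS spectra, an aligned feature table, a sample sheet and a
#' per-feature ground-truth table, all reproducible from the config seed:
#' \itemize{
#'   \item sulfate features' spectra contain their assigned dominant
#'     diagnostic signal (and possibly minor ones) with IR built to a
#'     target of at least `minSulfateIR` percent;
#'   \item non-sulfate spectra contain no peak within the sulfate
#'     matching windows (IR = MA = 0 by construction);
#'   \item glucuronide spectra carry at least two glucuronide
#'     transitions;
#'   \item intensities are log-normal with shared multiplicative
#'     injection-order drift; spiked features are multiplied by
#'     `2^true_log2fc` in the treatment group;
#'   \item class allocation uses exact counts, not Bernoulli draws.
#' }
#'
#' @param config a [synthConfig()].
#' @return List of class `"SynthStudy"`: `spectra` (named list of
#'   [MsmsSpectrum-class]), `se` (a [SulfateExperiment-class]),
#'   `featureTable`, `sampleSheet`, `truth` (data.frame with `class`,
#'   `dominant_species`, `spiked`, `true_log2fc`, `blank_contaminant`,
#'   `defect`), and `config`.
#' @export
generateSyntheticStudy <- function(config = synthConfig()) {
    stopifnot(inherits(config, "SynthConfig"))
    withSeed(config$seed, .generateStudy(config))
}

.generateStudy <- function(cfg) {
    n <- cfg$nFeatures
    sulfRules <- defaultSulfateRules()
    glucRules <- defaultGlucuronideRules()
    sulfIonMass <- sulfRules$accurate_mass[sulfRules$kind == "product_ion"]
    sulfLossMass <- sulfRules$accurate_mass[sulfRules$kind == "neutral_loss"]
    glucIonMass <- glucRules$accurate_mass[glucRules$kind == "product_ion"]
    glucLossMass <- glucRules$accurate_mass[glucRules$kind == "neutral_loss"]
    avoidIons <- c(sulfIonMass, glucIonMass)
    avoidLosses <- c(sulfLossMass, glucLossMass)

    ## -- class allocation (exact counts) ---------------------------------
    nSulf <- round(cfg$fracSulfate * n)
    nGluc <- round(cfg$fracGlucuronide * n)
    cls <- rep("other", n)
    cls[seq_len(nSulf)] <- "sulfate"
    if (nGluc > 0L)
        cls[nSulf + seq_len(nGluc)] <- "glucuronide"
    cls <- sample(cls)
    featureId <- sprintf("F%04d", seq_len(n))

    ## -- feature coordinates ---------------------------------------------
    mz <- stats::runif(n, 250, 600)
    rtSec <- stats::runif(n, 60, 1200)
    snr <- stats::runif(n, 5, 80)

    ## defects and contaminants live in the "other" class so the sulfate /
    ## glucuronide ground truth survives curation intact
    otherIdx <- which(cls == "other")
    nDefect <- c(no_msms = round(cfg$fracNoMsms * length(otherIdx)),
                 low_snr = round(cfg$fracLowSnr * length(otherIdx)),
                 too_few_samples = round(cfg$fracFewSamples * length(otherIdx)))
    defectPool <- sample(otherIdx)
    defect <- rep("none", n)
    k <- 0L
    for (d in names(nDefect)) {
        if (nDefect[[d]] > 0L) {
            defect[defectPool[k + seq_len(nDefect[[d]])]] <- d
            k <- k + nDefect[[d]]
        }
    }
    snr[defect == "low_snr"] <- stats::runif(sum(defect == "low_snr"), 0.5, 2.9)
    contamPool <- setdiff(otherIdx, which(defect != "none"))
    nContam <- min(round(cfg$fracBlankContaminant * n), length(contamPool))
    contaminant <- logical(n)
    contaminant[sample(contamPool, nContam)] <- TRUE

    ## -- spiking ----------------------------------------------------------
    spiked <- logical(n)
    spikePool <- which(defect == "none" & !contaminant)
    nSpiked <- min(round(cfg$fracSpiked * n), length(spikePool))
    spiked[sample(spikePool, nSpiked)] <- TRUE
    lfc <- numeric(n)
    sgn <- ifelse(stats::runif(nSpiked) < cfg$fracSpikedDown, -1, 1)
    lfc[spiked] <- sgn * stats::runif(nSpiked, cfg$spikeLog2fcRange[1L],
                                      cfg$spikeLog2fcRange[2L])

    ## -- sample sheet and injection sequence ------------------------------
    grpNames <- names(cfg$groups)
    bio <- unlist(lapply(grpNames, function(g)
        paste0(g, "_", seq_len(cfg$groups[[g]]))))
    bioGroup <- rep(grpNames, times = cfg$groups)
    names(bioGroup) <- bio
    qc <- if (cfg$nQc > 0L) paste0("QC_", seq_len(cfg$nQc)) else character(0)
    blanks <- if (cfg$nBlank > 0L) paste0("Blank_", seq_len(cfg$nBlank))
        else character(0)
    bioSeq <- sample(bio)  # biological samples run in random order
    seqIds <- blanks
    qi <- 0L
    for (i in seq_along(bioSeq)) {
        if (i %% 2L == 1L && qi < length(qc)) {
            qi <- qi + 1L
            seqIds <- c(seqIds, qc[qi])
        }
        seqIds <- c(seqIds, bioSeq[i])
    }
    if (qi < length(qc))
        seqIds <- c(seqIds, qc[(qi + 1L):length(qc)])
    sampleSheet <- data.frame(
        sample_id = seqIds,
        role = ifelse(seqIds %in% qc, "pooled_qc",
                      ifelse(seqIds %in% blanks, "blank", "biological")),
        group = ifelse(seqIds %in% bio, bioGroup[seqIds],
                       ifelse(seqIds %in% qc, "QC", "blank")),
        injection_order = seq_along(seqIds),
        stringsAsFactors = FALSE)

    ## -- intensity matrix --------------------------------------------------
    base <- exp(stats::rnorm(n, cfg$baseIntensityLogMean,
                             cfg$baseIntensityLogSd))
    ord <- stats::setNames(sampleSheet$injection_order, sampleSheet$sample_id)
    drift <- 1 + cfg$driftSlopePerInjection * ord
    intensities <- matrix(0, n, length(seqIds),
                          dimnames = list(featureId, seqIds))
    for (s in seqIds) {
        role <- sampleSheet$role[sampleSheet$sample_id == s]
        if (role == "blank") {
            intensities[contaminant, s] <- base[contaminant] * 3 * drift[[s]]
        } else {
            sd <- if (role == "pooled_qc") cfg$qcNoiseSdLog2 else cfg$noiseSdLog2
            v <- base * drift[[s]] * 2^stats::rnorm(n, 0, sd)
            if (role == "biological" &&
                bioGroup[[s]] == grpNames[2L])  # second condition is treated
                v <- v * 2^lfc
            intensities[, s] <- v
        }
    }
    few <- which(defect == "too_few_samples")
    if (length(few) > 0L) {
        keepCol <- sample(bio, 1L)
        intensities[few, ] <- 0
        intensities[few, keepCol] <- base[few]
    }

    ## -- spectra -----------------------------------------------------------
    dominant <- rep(NA_character_, n)
    spectra <- list()
    for (i in seq_len(n)) {
        if (defect[i] == "no_msms")
            next
        precursor <- mz[i] * (1 + stats::runif(1, -2e-6, 2e-6))
        peaks <- switch(cls[i],
            sulfate = {
                sp <- .sulfateSpectrumPeaks(precursor, cfg, sulfRules,
                                            avoidIons, avoidLosses)
                dominant[i] <- sp$dominant
                sp$peaks
            },
            glucuronide = .glucuronideSpectrumPeaks(mz, i, cfg, glucRules,
                                                    sulfIonMass, sulfLossMass,
                                                    avoidIons, avoidLosses),
            other = {
                k <- sample(5:10, 1L)
                cbind(mz = .randomCleanMz(k, precursor, avoidIons, avoidLosses),
                      intensity = stats::runif(k, 5, 100))
            })
        if (cls[i] == "glucuronide") {
            ## precursor may have been redrawn to keep windows clean
            precursor <- attr(peaks, "precursor")
            mz[i] <- precursor / (1 + stats::runif(1, -2e-6, 2e-6))
        }
        scaleAbs <- stats::runif(1, 20, 200)
        peaks[, "intensity"] <- peaks[, "intensity"] * scaleAbs
        spectra[[length(spectra) + 1L]] <- MsmsSpectrum(
            sprintf("S%04d", i), precursor,
            max(0, rtSec[i] + stats::runif(1, -1.5, 1.5)),
            peaks, precursorIntensity = max(intensities[i, ]))
    }
    names(spectra) <- vapply(spectra, spectrumId, character(1))

    featureTable <- data.frame(feature_id = featureId, mz = mz,
                               rt = rtSec / 60, snr = snr,
                               check.names = FALSE, stringsAsFactors = FALSE)
    featureTable <- cbind(featureTable, as.data.frame(intensities))
    truth <- data.frame(feature_id = featureId, class = cls,
                        dominant_species = dominant, spiked = spiked,
                        true_log2fc = lfc, blank_contaminant = contaminant,
                        defect = defect,
                        spectrum_id = ifelse(defect == "no_msms",
                                             NA_character_,
                                             sprintf("S%04d", seq_len(n))),
                        stringsAsFactors = FALSE)
    se <- SulfateExperiment(featureTable, sampleSheet, rtUnit = "minutes")
    out <- list(spectra = spectra, se = se, featureTable = featureTable,
                sampleSheet = sampleSheet, truth = truth, config = cfg)
    class(out) <- "SynthStudy"
    out
}

## Build sulfate peaks on a relative scale (base peak = 100) hitting exact
## IR and MA targets.
.sulfateSpectrumPeaks <- function(precursor, cfg, sulfRules,
                                  avoidIons, avoidLosses) {
    domRule <- sample(names(cfg$sulfateSpeciesMix), 1L,
                      prob = cfg$sulfateSpeciesMix)
    MA <- if (stats::runif(1) < 0.6) 100 else stats::runif(1, 40, 99.5)
    others <- setdiff(sulfRules$name, domRule)
    pick <- others[stats::runif(length(others)) < 0.35]
    otherRel <- stats::runif(length(pick), 2, 0.8 * MA)
    sumSulf <- MA + sum(otherRel)
    IRt <- stats::runif(1, cfg$minSulfateIR, 97)
    required <- sumSulf * (100 - IRt) / IRt
    if (MA < 100 && required < 105) {
        MA <- 100
        sumSulf <- MA + sum(otherRel)
        required <- sumSulf * (100 - IRt) / IRt
    }
    ruleMz <- function(rule) {
        row <- sulfRules[sulfRules$name == rule, ]
        if (row$kind == "product_ion")
            row$accurate_mass + stats::runif(1, -0.003, 0.003)
        else
            precursor - row$accurate_mass + stats::runif(1, -0.006, 0.006)
    }
    mzs <- vapply(c(domRule, pick), ruleMz, numeric(1))
    rels <- c(MA, otherRel)
    if (MA < 100) {
        rest <- .splitIntensity(required - 100)
        nd <- c(100, rest)
    } else {
        nd <- .splitIntensity(required)
    }
    if (length(nd) > 0L) {
        mzs <- c(mzs, .randomCleanMz(length(nd), precursor, avoidIons,
                                     avoidLosses))
        rels <- c(rels, nd)
    }
    pk <- cbind(mz = unname(mzs), intensity = rels)
    structure(list(peaks = pk, dominant = domRule))
}

## Glucuronide peaks: >= 2 transitions; precursor redrawn until no planned
## peak falls inside a sulfate matching window.
.glucuronideSpectrumPeaks <- function(mzVec, i, cfg, glucRules,
                                      sulfIonMass, sulfLossMass,
                                      avoidIons, avoidLosses) {
    for (attempt in 1:200) {
        precursor <- if (attempt == 1L) mzVec[i] else stats::runif(1, 250, 600)
        nTr <- sample(2:5, 1L)
        rules <- glucRules[sample(nrow(glucRules), nTr), ]
        peakMz <- ifelse(rules$kind == "product_ion",
                         rules$accurate_mass + stats::runif(nTr, -0.003, 0.003),
                         precursor - rules$accurate_mass +
                             stats::runif(nTr, -0.006, 0.006))
        cleanIon <- all(vapply(peakMz, function(x)
            all(abs(x - sulfIonMass) > 0.03), logical(1)))
        cleanLoss <- all(vapply(peakMz, function(x)
            all(abs((precursor - x) - sulfLossMass) > 0.03), logical(1)))
        if (cleanIon && cleanLoss && all(peakMz > 50))
            break
    }
    k <- sample(2:5, 1L)
    extraMz <- .randomCleanMz(k, precursor, avoidIons, avoidLosses)
    pk <- cbind(mz = c(peakMz, extraMz),
                intensity = c(stats::runif(nTr, 30, 100),
                              stats::runif(k, 5, 60)))
    attr(pk, "precursor") <- precursor
    pk
}

#' Write a synthetic study to disk
#'
#' Emits `spectra.mgf`, `features.csv`, `samples.csv` and `truth.csv` in
#' the exact dialects consumed by [readMgf()], [readFeatureTable()] and
#' [readSampleSheet()].
#'
#' @param study a `SynthStudy` from [generateSyntheticStudy()].
#' @param dir output directory (created when absent).
#' @return Invisibly, the vector of paths written.
#' @export
writeSyntheticStudy <- function(study, dir) {
    stopifnot(inherits(study, "SynthStudy"))
    if (!dir.exists(dir))
        dir.create(dir, recursive = TRUE)
    paths <- file.path(dir, c("spectra.mgf", "features.csv", "samples.csv",
                              "truth.csv"))
    writeMgf(study$spectra, paths[1L])
    utils::write.csv(study$featureTable, paths[2L], row.names = FALSE,
                     quote = FALSE)
    utils::write.csv(study$sampleSheet, paths[3L], row.names = FALSE,
                     quote = FALSE)
    utils::write.csv(study$truth, paths[4L], row.names = FALSE, quote = FALSE)
    invisible(paths)
}

#' @export
print.SynthStudy <- function(x, ...) {
    cat("SynthStudy:", nrow(x$truth), "features,", length(x$spectra),
        "spectra,", nrow(x$sampleSheet), "samples\n")
    print(table(x$truth$class))
    invisible(x)
}
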