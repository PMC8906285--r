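## End-to-end orchestration: mapping -> curation -> normalization ->
## annotation -> clustering -> differential analysis -> speciation.

.stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
        stop("[", name, "] ", conditionMessage(e), call. = FALSE))
}

#' Run the full sulfate-profiling workflow
#'
#' Chains the package stages on in-memory objects: spectrum-to-feature
#' mapping, blank exclusion (when blank samples are present), the
#' curation filters, pooled-QC LOWESS normalization, diagnostic-fragment
#' annotation, eight-parameter k-means classification, two-group
#' moderated-t differential analysis, and sulfate speciation.
#'
#' @param spectra list of [MsmsSpectrum-class] (e.g. from [readMgf()]).
#' @param se a [SulfateExperiment-class] (e.g. from [readFeatureTable()]).
#' @param reference,treatment biological group labels contrasted as
#'   `treatment - reference`.
#' @param mzTolPpm,rtTolSeconds mapping tolerances (defaults 5 ppm, 3 s).
#' @param minSnr,minSamplesDetected curation thresholds (defaults 3, 2).
#' @param blankTopN static-exclusion list size (default 1000; only used
#'   when blank samples exist).
#' @param normalize run LOWESS normalization (default TRUE; requires
#'   pooled QCs).
#' @param lowessFrac,minQc see [lowessNormalize()].
#' @param rules sulfate fragment rules (default [defaultSulfateRules()]).
#' @param ionTolDa,lossTolDa fragment tolerances (defaults 0.005, 0.010).
#' @param alpha,log2FcRed volcano thresholds (defaults 0.01, 3).
#' @param kmeansRestarts,seed clustering restarts and RNG seed.
#' @return List of class `"SulfateProfile"` with elements `se` (curated,
#'   normalized), `removed` (curation audit), `annotations`, `clustering`
#'   ([SulfateClustering-class]), `differential`, `speciation`,
#'   `multiFragmentPct`, `direction`, `normalization`, and `summary` (a
#'   plain list of headline counts and IR/MA statistics).
#' @export
profileSulfates <- function(spectra, se, reference, treatment,
                            mzTolPpm = 5, rtTolSeconds = 3,
                            minSnr = 3, minSamplesDetected = 2L,
                            blankTopN = 1000L, normalize = TRUE,
                            lowessFrac = 0.7, minQc = 3L,
                            rules = defaultSulfateRules(),
                            ionTolDa = 0.005, lossTolDa = 0.010,
                            alpha = 0.01, log2FcRed = 3,
                            kmeansRestarts = 25L, seed = 1L) {
    nInput <- nrow(se)
    se <- .stage("mapping",
                 mapSpectraToFeatures(spectra, se, mzTolPpm, rtTolSeconds))
    removed <- data.frame(feature_id = character(0), reason = character(0))
    if (any(sampleRole(se) == "blank") && blankTopN > 0L) {
        bl <- .stage("blank_exclusion",
                     blankExclusion(se, blankTopN, mzTolPpm, rtTolSeconds))
        se <- bl$kept
        removed <- rbind(removed, bl$removed)
    }
    fl <- .stage("filtering", filterFeatures(se, minSnr, minSamplesDetected))
    se <- fl$kept
    removed <- rbind(removed, fl$removed)
    norm <- NULL
    if (normalize) {
        norm <- .stage("normalization", lowessNormalize(se, lowessFrac, minQc))
        se <- norm$se
    }
    rd <- SummarizedExperiment::rowData(se)
    annotations <- .stage("annotation", {
        specIds <- rd$spectrum_id
        annotateSpectra(spectra[specIds], rules = rules,
                        featureIds = rownames(se),
                        ionTolDa = ionTolDa, lossTolDa = lossTolDa)
    })
    clustering <- .stage("clustering", {
        params <- buildParameterMatrix(annotations)
        kmeansSulfate(params, nRestarts = kmeansRestarts, seed = seed)
    })
    differential <- .stage("differential",
                           runDifferential(se, reference, treatment,
                                           alpha = alpha, log2FcRed = log2FcRed))
    spec <- .stage("speciation", speciate(annotations, clustering))
    multiPct <- multiFragmentFraction(annotations, clustering)
    sulfIds <- sulfateFeatures(clustering)
    diffSulf <- differential[differential$feature_id %in% sulfIds, ]
    direction <- summarizeDirection(diffSulf)
    summary <- list(
        n_features_input = nInput,
        n_features_kept = nrow(se),
        n_removed = nrow(removed),
        n_sulfate = clustering@nSulfate,
        n_non_sulfate = clustering@nNonSulfate,
        pct_sulfate = 100 * clustering@nSulfate / nrow(se),
        class_summaries = clustering@summaries,
        speciation = spec,
        multi_fragment_pct = multiPct,
        n_sulfate_significant = sum(diffSulf$volcano_class != "grey"),
        direction_up = unname(direction["up"]),
        direction_down = unname(direction["down"]))
    out <- list(se = se, removed = removed, annotations = annotations,
                clustering = clustering, differential = differential,
                speciation = spec, multiFragmentPct = multiPct,
                direction = direction, normalization = norm,
                summary = summary)
    class(out) <- "SulfateProfile"
    out
}

#' @export
print.SulfateProfile <- function(x, ...) {
    s <- x$summary
    cat("SulfateProfile:", s$n_features_input, "features ->",
        s$n_features_kept, "curated ->", s$n_sulfate, "sulfate /",
        s$n_non_sulfate, "non-sulfate\n")
    cat(sprintf("significantly changed sulfates: %d (%d up / %d down)\n",
                s$n_sulfate_significant, s$direction_up, s$direction_down))
    invisible(x)
}

#' Final curated feature list
#'
#' One row per curated feature with coordinates, sulfate class, dominant
#' species, the per-rule relative abundances, IR/MA and the differential
#' statistics — the workflow's headline output table.
#'
#' @param profile a `SulfateProfile` from [profileSulfates()].
#' @return data.frame.
#' @export
curatedTable <- function(profile) {
    stopifnot(inherits(profile, "SulfateProfile"))
    rd <- SummarizedExperiment::rowData(profile$se)
    base <- data.frame(feature_id = rownames(profile$se),
                       mz = rd$mz, rt_minutes = rd$rt_seconds / 60,
                       snr = rd$snr,
                       class = unname(clusterAssignment(profile$clustering)[
                           rownames(profile$se)]),
                       stringsAsFactors = FALSE)
    ann <- profile$annotations
    diff <- profile$differential[, c("feature_id", "log2_fc", "p_raw",
                                     "p_adj", "volcano_class")]
    out <- merge(base, ann, by = "feature_id", sort = FALSE)
    out <- merge(out, diff, by = "feature_id", all.x = TRUE, sort = FALSE)
    out[match(rownames(profile$se), out$feature_id), , drop = FALSE]
}

#' Write profile outputs to a directory
#'
#' Emits the curated feature list, the curation audit, the speciation
#' table and a JSON summary.
#'
#' @param profile a `SulfateProfile`.
#' @param dir output directory (created when absent).
#' @return Invisibly, the paths written.
#' @export
writeProfile <- function(profile, dir) {
    stopifnot(inherits(profile, "SulfateProfile"))
    if (!dir.exists(dir))
        dir.create(dir, recursive = TRUE)
    paths <- file.path(dir, c("curated_features.csv", "removed_features.csv",
                              "speciation.csv", "summary.json"))
    utils::write.csv(curatedTable(profile), paths[1L], row.names = FALSE)
    utils::write.csv(profile$removed, paths[2L], row.names = FALSE)
    utils::write.csv(profile$speciation, paths[3L], row.names = FALSE)
    summ <- profile$summary
    summ$class_summaries <- NULL  # nested data.frame; written in the CSVs
    jsonlite::write_json(summ, paths[4L], auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    invisible(paths)
}

#' Candidate search against profiled features
#'
#' Enumerates conjugated biotransformation products of one or more parent
#' compounds, matches them against the curated features by accurate mass,
#' and shortlists the significantly upregulated matches.
#'
#' @param profile a `SulfateProfile`.
#' @param parents data.frame with columns `name` and `formula` (e.g.
#'   `data.frame(name = "testosterone", formula = "C19H28O2")`).
#' @param transformations see [enumerateCandidates()].
#' @param maxDepth maximum number of transformations (default 3).
#' @param conjugate `"sulfate"` or `"glucuronide"`.
#' @param ppmTol accurate-mass tolerance (default 5 ppm).
#' @param minLog2fc,maxLog2fc,alpha see [screenUpregulated()].
#' @return List with `candidates`, `matches` and `shortlist` data.frames.
#' @export
runCandidateSearch <- function(profile, parents,
                               transformations = defaultBiotransformations(),
                               maxDepth = 3L, conjugate = "sulfate",
                               ppmTol = 5, minLog2fc = 4, maxLog2fc = 10,
                               alpha = 0.01) {
    stopifnot(inherits(profile, "SulfateProfile"),
              all(c("name", "formula") %in% colnames(parents)))
    candidates <- do.call(rbind, lapply(seq_len(nrow(parents)), function(i)
        enumerateCandidates(parents$formula[i], parents$name[i],
                            transformations, maxDepth, conjugate)))
    feats <- data.frame(feature_id = rownames(profile$se),
                        mz = unname(featureMz(profile$se)),
                        stringsAsFactors = FALSE)
    matches <- matchCandidates(feats, candidates, ppmTol)
    shortlist <- screenUpregulated(matches, profile$differential,
                                   minLog2fc, maxLog2fc, alpha)
    list(candidates = candidates, matches = matches, shortlist = shortlist)
}
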