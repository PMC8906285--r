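## Biotransformation-based candidate metabolite enumeration and
## accurate-mass matching.

#' Default phase-I biotransformation set
#'
#' Hydroxylation (+O), bond oxidation read as dehydrogenation (-H2) and
#' reduction (+H2). Together with sulfation these generate the saturated
#' and unsaturated steroid sulfate series (mass shifts of +-H2 and +O
#' around the sulfated parent).
#'
#' @return data.frame with columns `name`, `add`, `remove` (formula
#'   strings, possibly empty).
#' @export
defaultBiotransformations <- function() {
    data.frame(name = c("hydroxylation", "oxidation", "reduction"),
               add = c("O", "", "H2"),
               remove = c("", "H2", ""),
               stringsAsFactors = FALSE)
}

## All non-negative integer count vectors over `k` slots summing to <=
## maxDepth (multisets of transformations, sizes 0..maxDepth).
.enumerateMultisets <- function(k, maxDepth) {
    out <- list(integer(k))
    grow <- function(counts, startIdx, remaining) {
        if (remaining == 0L)
            return(invisible())
        for (i in startIdx:k) {
            nxt <- counts
            nxt[i] <- nxt[i] + 1L
            out[[length(out) + 1L]] <<- nxt
            grow(nxt, i, remaining - 1L)
        }
    }
    if (maxDepth > 0L && k > 0L)
        grow(integer(k), 1L, maxDepth)
    out
}

#' Enumerate conjugated candidate metabolites of a parent compound
#'
#' Applies every multiset of up to `maxDepth` biotransformations to the
#' parent formula (skipping applications that would drive an element
#' count negative), conjugates the result (sulfation adds SO3;
#' glucuronidation adds C6H8O6), and computes the theoretical `[M-H]-`
#' m/z. Candidates with identical final formulas are collapsed, with all
#' generating multisets recorded.
#'
#' @param parentFormula neutral formula of the parent (string or parsed),
#'   e.g. testosterone `"C19H28O2"`.
#' @param parentName label recorded in the output.
#' @param transformations data.frame as [defaultBiotransformations()].
#' @param maxDepth maximum multiset size (default 3).
#' @param conjugate `"sulfate"` (default) or `"glucuronide"`.
#' @param collapse collapse duplicates by final formula (default TRUE).
#' @return data.frame `parent`, `transformations` (multiset as
#'   `"a+b"`; alternatives separated by `";"` after collapsing; empty
#'   string for the unmodified parent), `n_transformations`, `formula`
#'   (Hill string of the conjugated neutral), `theoretical_mz`. Attribute
#'   `nEnumerated` holds the pre-collapse multiset count.
#' @examples
#' cand <- enumerateCandidates("C19H28O2", "testosterone")
#' subset(cand, n_transformations == 0)$theoretical_mz  # testosterone sulfate
#' @export
enumerateCandidates <- function(parentFormula, parentName = "parent",
                                transformations = defaultBiotransformations(),
                                maxDepth = 3L,
                                conjugate = c("sulfate", "glucuronide"),
                                collapse = TRUE) {
    conjugate <- match.arg(conjugate)
    parent <- asFormula(parentFormula)
    conjFormula <- if (conjugate == "sulfate") "SO3" else "C6H8O6"
    adds <- lapply(transformations$add, parseFormula)
    rems <- lapply(transformations$remove, parseFormula)
    multisets <- .enumerateMultisets(nrow(transformations), maxDepth)
    rows <- lapply(multisets, function(counts) {
        f <- parent
        for (i in seq_along(counts)) {
            if (counts[i] == 0L)
                next
            for (rep in seq_len(counts[i])) {
                f <- formulaAdd(f, adds[[i]])
                f <- tryCatch(formulaSubtract(f, rems[[i]]),
                              error = function(e) NULL)
                if (is.null(f))
                    return(NULL)
            }
        }
        f <- formulaAdd(f, conjFormula)
        label <- paste(rep(transformations$name, counts), collapse = "+")
        data.frame(parent = parentName, transformations = label,
                   n_transformations = sum(counts),
                   formula = formulaToString(f),
                   theoretical_mz = deprotonatedMz(f),
                   stringsAsFactors = FALSE)
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    out <- do.call(rbind, rows)
    nEnum <- nrow(out)
    if (collapse && nrow(out) > 0L) {
        out <- do.call(rbind, lapply(split(out, out$formula), function(g) {
            g <- g[order(g$n_transformations), , drop = FALSE]
            first <- g[1L, , drop = FALSE]
            first$transformations <- paste(g$transformations, collapse = ";")
            first
        }))
        out <- out[order(out$theoretical_mz), , drop = FALSE]
        rownames(out) <- NULL
    }
    attr(out, "nEnumerated") <- nEnum
    out
}

#' Match features to candidate metabolites by accurate mass
#'
#' Reports every (feature, candidate) pair whose observed m/z is within
#' `ppmTol` of the candidate's theoretical `[M-H]-` m/z. A feature may
#' match several candidates (isomers are indistinguishable by mass).
#'
#' @param features a [SulfateExperiment-class] or data.frame with columns
#'   `feature_id` and `mz`.
#' @param candidates data.frame from [enumerateCandidates()].
#' @param ppmTol mass tolerance in ppm (default 5).
#' @return data.frame `feature_id`, `observed_mz`, `parent`,
#'   `transformations`, `formula`, `theoretical_mz`, `ppm_error`.
#' @export
matchCandidates <- function(features, candidates, ppmTol = 5) {
    if (is(features, "SulfateExperiment"))
        features <- data.frame(feature_id = rownames(features),
                               mz = unname(featureMz(features)),
                               stringsAsFactors = FALSE)
    stopifnot(all(c("feature_id", "mz") %in% colnames(features)))
    empty <- data.frame(feature_id = character(0), observed_mz = numeric(0),
                        parent = character(0), transformations = character(0),
                        formula = character(0), theoretical_mz = numeric(0),
                        ppm_error = numeric(0), stringsAsFactors = FALSE)
    if (nrow(candidates) == 0L || nrow(features) == 0L)
        return(empty)
    rows <- lapply(seq_len(nrow(candidates)), function(i) {
        ppm <- ppmError(features$mz, candidates$theoretical_mz[i])
        hit <- which(abs(ppm) <= ppmTol)
        if (length(hit) == 0L)
            return(NULL)
        data.frame(feature_id = features$feature_id[hit],
                   observed_mz = features$mz[hit],
                   parent = candidates$parent[i],
                   transformations = candidates$transformations[i],
                   formula = candidates$formula[i],
                   theoretical_mz = candidates$theoretical_mz[i],
                   ppm_error = ppm[hit], stringsAsFactors = FALSE)
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (length(rows) == 0L) empty else {
        out <- do.call(rbind, rows)
        rownames(out) <- NULL
        out
    }
}

#' Shortlist candidate matches that are significantly upregulated
#'
#' Joins candidate matches with differential results and keeps matches
#' with `p_adj <= alpha` and `minLog2fc <= log2_fc <= maxLog2fc` (the
#' 16- to 1024-fold window of interest).
#'
#' @param matches data.frame from [matchCandidates()].
#' @param differential data.frame with `feature_id`, `log2_fc`, `p_adj`.
#' @param minLog2fc,maxLog2fc fold-change window on the log2 scale
#'   (defaults 4 and 10).
#' @param alpha adjusted-p threshold (default 0.01).
#' @return Filtered matches with `log2_fc` and `p_adj` columns appended.
#' @export
screenUpregulated <- function(matches, differential, minLog2fc = 4,
                              maxLog2fc = 10, alpha = 0.01) {
    joined <- merge(matches,
                    differential[, c("feature_id", "log2_fc", "p_adj")],
                    by = "feature_id")
    keep <- joined$p_adj <= alpha & joined$log2_fc >= minLog2fc &
        joined$log2_fc <= maxLog2fc
    out <- joined[keep, , drop = FALSE]
    rownames(out) <- NULL
    out
}
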