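## Diagnostic fragment rules and per-spectrum annotation statistics.
##
## A rule is either a product ion (matched against peak m/z) or a neutral
## loss (matched against precursor m/z minus peak m/z). Sulfate esters in
## negative mode give six characteristic signals; glucuronides give seven.

#' Fragment rule table constructor
#'
#' @param name rule names, unique within a family.
#' @param kind `"product_ion"` or `"neutral_loss"`.
#' @param family `"sulfate"` or `"glucuronide"`.
#' @param accurate_mass ion m/z for product ions, mass difference in Da
#'   for neutral losses; must be positive.
#' @param formula elemental formula string of the ion/neutral (metadata).
#' @return data.frame of class `"FragmentRules"`.
#' @export
fragmentRules <- function(name, kind, family, accurate_mass, formula = NA_character_) {
    stopifnot(all(kind %in% c("product_ion", "neutral_loss")),
              all(family %in% c("sulfate", "glucuronide")),
              all(accurate_mass > 0))
    df <- data.frame(name = name, kind = kind, family = family,
                     accurate_mass = accurate_mass, formula = formula,
                     stringsAsFactors = FALSE)
    for (fam in unique(df$family))
        if (anyDuplicated(df$name[df$family == fam]))
            stop("rule names must be unique within family '", fam, "'")
    class(df) <- c("FragmentRules", "data.frame")
    df
}

#' The six diagnostic sulfate-derived signals
#'
#' Four product ions (the radical anions of SO3 and SO4 plus HSO3- and
#' HSO4-) and two neutral losses (SO3, H2SO4), with accurate masses
#' computed from monoisotopic atomic masses ([ionMz()] includes one
#' electron mass for the singly charged anions). Rounded to 4 dp the
#' masses are 79.9574, 80.9652, 95.9523, 96.9601 (ions) and 79.9568,
#' 97.9674 (losses).
#'
#' @return A `FragmentRules` data.frame with six rows.
#' @export
defaultSulfateRules <- function() {
    fragmentRules(
        name = c("SO3_radical_anion", "HSO3_anion", "SO4_radical_anion",
                 "HSO4_anion", "loss_SO3", "loss_H2SO4"),
        kind = c(rep("product_ion", 4L), rep("neutral_loss", 2L)),
        family = "sulfate",
        accurate_mass = c(ionMz("SO3"), ionMz("HSO3"), ionMz("SO4"),
                          ionMz("HSO4"), monoisotopicMass("SO3"),
                          monoisotopicMass("H2SO4")),
        formula = c("SO3", "HSO3", "SO4", "HSO4", "SO3", "H2SO4"))
}

#' The seven diagnostic glucuronide transitions
#'
#' Neutral losses of glucuronic acid (C6H10O7, nominal 194 Da) and its
#' dehydrated form (C6H8O6, 176 Da), plus five product ions of the sugar
#' moiety: \[C6H7O6\]-, \[C6H5O5\]-, \[C5H5O3\]-, \[C4H5O2\]-,
#' \[C2H3O3\]-.
#'
#' @return A `FragmentRules` data.frame with seven rows.
#' @export
defaultGlucuronideRules <- function() {
    ions <- c(gluc_175 = "C6H7O6", gluc_157 = "C6H5O5", gluc_113 = "C5H5O3",
              gluc_85 = "C4H5O2", gluc_75 = "C2H3O3")
    fragmentRules(
        name = c("loss_glucuronic_acid", "loss_anhydroglucuronic_acid",
                 names(ions)),
        kind = c("neutral_loss", "neutral_loss", rep("product_ion", 5L)),
        family = "glucuronide",
        accurate_mass = c(monoisotopicMass("C6H10O7"),
                          monoisotopicMass("C6H8O6"),
                          vapply(ions, ionMz, numeric(1))),
        formula = c("C6H10O7", "C6H8O6", unname(ions)))
}

#' Match fragment rules against one spectrum
#'
#' A product-ion rule matches any peak with
#' `|peak mz - accurate_mass| <= ionTolDa`; a neutral-loss rule matches any
#' peak with `|(precursor mz - peak mz) - accurate_mass| <= lossTolDa`.
#' When several peaks satisfy one rule the most intense is kept; one peak
#' may satisfy several rules. The intensity credited to a neutral loss is
#' that of the product-ion peak implying the loss.
#'
#' The default tolerances are absolute mDa windows (5 mDa for product
#' ions, 10 mDa for losses): at m/z 80 a 5 ppm window would be 0.4 mDa,
#' far tighter than realistic fragment mass accuracy.
#'
#' @param spectrum an [MsmsSpectrum-class].
#' @param rules a `FragmentRules` table ([defaultSulfateRules()] or
#'   [defaultGlucuronideRules()]).
#' @param ionTolDa,lossTolDa absolute matching tolerances in Da.
#' @return data.frame with one row per matched rule: `name`, `kind`,
#'   `family`, `accurate_mass`, `peak_index`, `peak_mz`, `intensity`,
#'   `relative_abundance` (percent of spectrum base peak, in (0, 100\]),
#'   `mass_error` (Da, on the ion for product ions, on the loss for
#'   neutral losses). Zero rows when nothing matches.
#' @export
matchFragments <- function(spectrum, rules = defaultSulfateRules(),
                           ionTolDa = 0.005, lossTolDa = 0.010) {
    stopifnot(is(spectrum, "MsmsSpectrum"), ionTolDa > 0, lossTolDa > 0)
    pk <- peakMatrix(spectrum)
    empty <- data.frame(name = character(0), kind = character(0),
                        family = character(0), accurate_mass = numeric(0),
                        peak_index = integer(0), peak_mz = numeric(0),
                        intensity = numeric(0), relative_abundance = numeric(0),
                        mass_error = numeric(0), stringsAsFactors = FALSE)
    if (nrow(pk) == 0L)
        return(empty)
    base <- max(pk[, "intensity"])
    rows <- lapply(seq_len(nrow(rules)), function(i) {
        target <- rules$accurate_mass[i]
        err <- if (rules$kind[i] == "product_ion") {
            pk[, "mz"] - target
        } else {
            (precursorMz(spectrum) - pk[, "mz"]) - target
        }
        tol <- if (rules$kind[i] == "product_ion") ionTolDa else lossTolDa
        hit <- which(abs(err) <= tol)
        if (length(hit) == 0L)
            return(NULL)
        best <- hit[which.max(pk[hit, "intensity"])]
        data.frame(name = rules$name[i], kind = rules$kind[i],
                   family = rules$family[i], accurate_mass = target,
                   peak_index = best, peak_mz = pk[best, "mz"],
                   intensity = pk[best, "intensity"],
                   relative_abundance = min(100, 100 * (pk[best, "intensity"] / base)),
                   mass_error = err[best], stringsAsFactors = FALSE)
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (length(rows) == 0L) empty else do.call(rbind, rows)
}

#' Per-spectrum sulfate annotation statistics
#'
#' Computes the two spectral ratios used throughout the workflow:
#' \describe{
#'   \item{IR (intensity ratio)}{100 x (sum of intensities of the distinct
#'     peaks matched by any sulfate signal) / (sum of all peak
#'     intensities). A peak matching several rules is counted once, so
#'     0 <= IR <= 100.}
#'   \item{MA (maximum abundance)}{relative abundance (percent of base
#'     peak) of the most intense matched sulfate signal.}
#' }
#' The dominant species is the rule of the most intense match; ties break
#' product ions before neutral losses, then lower accurate mass.
#'
#' @param spectrum the [MsmsSpectrum-class] the matches came from.
#' @param matches data.frame from [matchFragments()] on `spectrum`.
#' @param featureId identifier recorded in the result (defaults to the
#'   spectrum id).
#' @param thresholdPct relative-abundance threshold (percent) for the
#'   multi-fragment count (default 5).
#' @return List of class `"SulfateAnnotation"`: `feature_id`, `matches`,
#'   `IR`, `MA`, `dominant_species` (`NA` when nothing matched),
#'   `n_fragments_ge5pct`, and `rule_abundance` (named vector of relative
#'   abundances, 0 for unmatched rules).
#' @export
computeAnnotation <- function(spectrum, matches,
                              featureId = spectrumId(spectrum),
                              thresholdPct = 5) {
    stopifnot(is(spectrum, "MsmsSpectrum"))
    pk <- peakMatrix(spectrum)
    total <- sum(pk[, "intensity"])
    ruleAb <- numeric(0)
    if (nrow(matches) > 0L)
        ruleAb <- stats::setNames(matches$relative_abundance, matches$name)
    if (nrow(matches) == 0L || total == 0) {
        ann <- list(feature_id = featureId, matches = matches, IR = 0, MA = 0,
                    dominant_species = NA_character_, n_fragments_ge5pct = 0L,
                    rule_abundance = ruleAb)
        class(ann) <- "SulfateAnnotation"
        return(ann)
    }
    matchedPeaks <- unique(matches$peak_index)
    IR <- 100 * sum(pk[matchedPeaks, "intensity"]) / total
    MA <- max(matches$relative_abundance)
    ord <- order(-matches$intensity,
                 matches$kind != "product_ion",  # FALSE (ions) sorts first
                 matches$accurate_mass)
    dominant <- matches$name[ord[1L]]
    ann <- list(feature_id = featureId, matches = matches,
                IR = min(IR, 100), MA = min(MA, 100),
                dominant_species = dominant,
                n_fragments_ge5pct = sum(matches$relative_abundance >= thresholdPct),
                rule_abundance = ruleAb)
    class(ann) <- "SulfateAnnotation"
    ann
}

#' @export
print.SulfateAnnotation <- function(x, ...) {
    cat("SulfateAnnotation '", x$feature_id, "': IR ",
        round(x$IR, 1), "%, MA ", round(x$MA, 1), "%, dominant ",
        if (is.na(x$dominant_species)) "none" else x$dominant_species,
        ", ", nrow(x$matches), " matched signal(s)\n", sep = "")
    invisible(x)
}

#' Annotate a list of spectra into a flat table
#'
#' Runs [matchFragments()] + [computeAnnotation()] per spectrum and
#' returns one row per spectrum with the per-rule relative abundances as
#' columns — the direct input of [buildParameterMatrix()].
#'
#' @param spectra list of [MsmsSpectrum-class]; `featureIds` defaults to
#'   the element names (or spectrum ids).
#' @param rules a `FragmentRules` table.
#' @param featureIds feature identifiers, parallel to `spectra`.
#' @param ionTolDa,lossTolDa matching tolerances in Da.
#' @param thresholdPct threshold for `n_fragments_ge5pct`.
#' @return data.frame: `feature_id`, one column per rule name (relative
#'   abundance, 0 when unmatched), `IR`, `MA`, `dominant_species`,
#'   `n_fragments_ge5pct`.
#' @export
annotateSpectra <- function(spectra, rules = defaultSulfateRules(),
                            featureIds = NULL, ionTolDa = 0.005,
                            lossTolDa = 0.010, thresholdPct = 5) {
    if (is.null(featureIds))
        featureIds <- names(spectra) %||%
            vapply(spectra, spectrumId, character(1))
    stopifnot(length(featureIds) == length(spectra))
    rows <- lapply(seq_along(spectra), function(i) {
        m <- matchFragments(spectra[[i]], rules, ionTolDa, lossTolDa)
        ann <- computeAnnotation(spectra[[i]], m, featureId = featureIds[i],
                                 thresholdPct = thresholdPct)
        ab <- stats::setNames(numeric(nrow(rules)), rules$name)
        ab[names(ann$rule_abundance)] <- ann$rule_abundance
        cbind(data.frame(feature_id = ann$feature_id, stringsAsFactors = FALSE),
              as.data.frame(as.list(ab), check.names = FALSE),
              data.frame(IR = ann$IR, MA = ann$MA,
                         dominant_species = if (is.na(ann$dominant_species))
                             NA_character_ else ann$dominant_species,
                         n_fragments_ge5pct = ann$n_fragments_ge5pct,
                         stringsAsFactors = FALSE))
    })
    do.call(rbind, rows)
}

#' Glucuronide screen for one spectrum
#'
#' A spectrum is called a glucuronide when at least `minRules` distinct
#' glucuronide transitions match.
#'
#' @param spectrum an [MsmsSpectrum-class].
#' @param rules glucuronide `FragmentRules` (default
#'   [defaultGlucuronideRules()]).
#' @param ionTolDa,lossTolDa matching tolerances in Da.
#' @param minRules minimum number of distinct matching transitions
#'   (default 2).
#' @return List with `is_glucuronide` (logical) and `matched_rules`
#'   (character vector of rule names).
#' @export
isGlucuronide <- function(spectrum, rules = defaultGlucuronideRules(),
                          ionTolDa = 0.005, lossTolDa = 0.010, minRules = 2L) {
    m <- matchFragments(spectrum, rules, ionTolDa, lossTolDa)
    list(is_glucuronide = length(unique(m$name)) >= minRules,
         matched_rules = unique(m$name))
}
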