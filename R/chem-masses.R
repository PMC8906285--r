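## Exact monoisotopic mass and ion m/z arithmetic. Every accurate-mass
## comparison in the package routes through these functions.

## Monoisotopic atomic masses (Da), CODATA/IUPAC. "O18" is the heavy-oxygen
## label used by the 18O-labelled sulfate internal standards.
.ATOMIC_MASSES <- c(
    C   = 12.0,
    H   = 1.00782503207,
    N   = 14.0030740048,
    O   = 15.9949146196,
    P   = 30.97376163,
    S   = 31.97207100,
    O18 = 17.9991610
)

## Electron rest mass (Da); one electron is added per negative charge.
.ELECTRON_MASS <- 0.00054858

#' Parse an elemental formula string
#'
#' Formulas are Hill-order strings over the supported elements C, H, N, O,
#' P, S with an optional bracketed isotope label for heavy oxygen, written
#' `[18O]`. Counts default to 1. Parsing is case-sensitive: `"co"` is an
#' error, not cobalt or carbon-oxygen.
#'
#' @param x a formula string such as `"C19H28O2"`, `"H2SO4"` or
#'   `"C19H27[18O]3O2S"`; the empty string is the empty formula.
#' @return Named integer vector of element counts (class
#'   `"ElementalFormula"`), possibly empty.
#' @examples
#' parseFormula("H2SO4")
#' parseFormula("[18O]3")
#' @export
parseFormula <- function(x) {
    stopifnot(is.character(x), length(x) == 1L, !is.na(x))
    counts <- integer(0)
    rest <- x
    while (nchar(rest) > 0L) {
        m <- regmatches(rest, regexec("^(\\[18O\\]|[A-Z][a-z]?)([0-9]*)", rest))[[1L]]
        if (length(m) == 0L || m[1L] == "")
            stop("unparseable formula near '", rest, "' in '", x, "'")
        sym <- if (m[2L] == "[18O]") "O18" else m[2L]
        if (!sym %in% names(.ATOMIC_MASSES))
            stop("unsupported element symbol '", m[2L], "' in formula '", x, "'")
        n <- if (m[3L] == "") 1L else as.integer(m[3L])
        counts[sym] <- (if (sym %in% names(counts)) counts[[sym]] else 0L) + n
        rest <- substr(rest, nchar(m[1L]) + 1L, nchar(rest))
    }
    asFormula(counts)
}

## Normalize a named count vector into a validated ElementalFormula.
asFormula <- function(x) {
    if (inherits(x, "ElementalFormula"))
        return(x)
    if (is.character(x))
        return(parseFormula(x))
    stopifnot(is.numeric(x))
    if (length(x) > 0L) {
        if (is.null(names(x)) || any(names(x) == ""))
            stop("formula counts must be named by element symbol")
        bad <- setdiff(names(x), names(.ATOMIC_MASSES))
        if (length(bad) > 0L)
            stop("unsupported element symbol '", bad[1L], "'")
        if (any(x < 0))
            stop("negative element count in formula")
        x <- x[x > 0]
    }
    storage.mode(x) <- "integer"
    structure(x, class = "ElementalFormula")
}

#' Add two elemental formulas element-wise
#' @param a,b formulas (strings or parsed).
#' @return An `ElementalFormula`.
#' @export
formulaAdd <- function(a, b) {
    a <- asFormula(a); b <- asFormula(b)
    syms <- union(names(a), names(b))
    out <- vapply(syms, function(s) {
        (if (s %in% names(a)) a[[s]] else 0L) + (if (s %in% names(b)) b[[s]] else 0L)
    }, integer(1))
    asFormula(out)
}

#' Subtract one elemental formula from another
#'
#' Errors if any element count would become negative.
#' @param a,b formulas (strings or parsed); result is `a - b`.
#' @return An `ElementalFormula`.
#' @export
formulaSubtract <- function(a, b) {
    a <- asFormula(a); b <- asFormula(b)
    syms <- union(names(a), names(b))
    out <- vapply(syms, function(s) {
        (if (s %in% names(a)) a[[s]] else 0L) - (if (s %in% names(b)) b[[s]] else 0L)
    }, integer(1))
    if (any(out < 0)) {
        bad <- syms[out < 0][1L]
        stop("formula subtraction yields negative count for element '", bad, "'")
    }
    asFormula(out)
}

#' Render a formula as a Hill-order string
#'
#' Carbon first, hydrogen second, remaining elements alphabetical; the
#' heavy-oxygen label prints as `[18O]`.
#' @param x a formula (string or parsed).
#' @return Single character string (empty formula renders as `""`).
#' @export
formulaToString <- function(x) {
    x <- asFormula(x)
    if (length(x) == 0L)
        return("")
    syms <- names(x)
    ord <- c(intersect(c("C", "H"), syms), sort(setdiff(syms, c("C", "H"))))
    paste0(vapply(ord, function(s) {
        lab <- if (s == "O18") "[18O]" else s
        n <- x[[s]]
        paste0(lab, if (n == 1L) "" else n)
    }, character(1)), collapse = "")
}

#' Monoisotopic mass of an elemental formula
#'
#' Sum of count times monoisotopic atomic mass over all elements.
#'
#' @param formula a formula string (e.g. `"SO3"`) or parsed
#'   `ElementalFormula`.
#' @return Mass in Da (0 for the empty formula).
#' @examples
#' round(monoisotopicMass("SO3"), 4)    # 79.9568, the SO3 neutral loss
#' round(monoisotopicMass("H2SO4"), 4)  # 97.9674
#' @export
monoisotopicMass <- function(formula) {
    f <- asFormula(formula)
    if (length(f) == 0L)
        return(0)
    sum(as.numeric(f) * .ATOMIC_MASSES[names(f)])
}

#' m/z of an ion
#'
#' `(monoisotopic mass + extra electrons x m_e) / |charge|`, with
#' `m_e = 0.00054858` Da. A singly charged anion (z = -1) therefore weighs
#' one electron mass more than its neutral composition; cations weigh less.
#'
#' @param formula atomic composition of the ion, including all hydrogens
#'   (string or parsed formula).
#' @param charge signed integer charge; negative for anions. Zero is an
#'   error.
#' @return m/z in Th.
#' @examples
#' round(ionMz("HSO4", -1), 4)  # 96.9601
#' @export
ionMz <- function(formula, charge = -1L) {
    stopifnot(is.numeric(charge), length(charge) == 1L)
    charge <- as.integer(charge)
    if (charge == 0L)
        stop("ion charge must be nonzero")
    extraElectrons <- -charge  # one electron gained per negative charge
    (monoisotopicMass(formula) + extraElectrons * .ELECTRON_MASS) / abs(charge)
}

#' m/z of the deprotonated molecular anion [M-H]-
#'
#' @param formula neutral molecular formula (string or parsed).
#' @return m/z of the `[M-H]-` ion.
#' @export
deprotonatedMz <- function(formula) {
    ionMz(formulaSubtract(formula, c(H = 1L)), charge = -1L)
}

#' Relative mass error in parts per million
#'
#' `1e6 * (observed - theoretical) / theoretical`; the sign is preserved.
#'
#' @param observed,theoretical m/z values; `theoretical` must be positive.
#' @return ppm error (vectorized).
#' @export
ppmError <- function(observed, theoretical) {
    if (any(theoretical <= 0))
        stop("theoretical m/z must be positive")
    1e6 * (observed - theoretical) / theoretical
}

#' @export
print.ElementalFormula <- function(x, ...) {
    cat("ElementalFormula:", if (length(x) == 0L) "(empty)" else formulaToString(x), "\n")
    invisible(x)
}
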