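#' Natural isotope abundance table
#'
#' IUPAC representative isotopic abundances for the elements of fatty-acid
#' methyl ester fragments. One row per isotope: the integer mass shift in Da
#' above the lightest isotope and its molar abundance. Users may supply
#' their own table (e.g. to drop the minor oxygen and hydrogen isotopes)
#' anywhere a \code{table} argument is accepted; abundances must sum to one
#' within each element.
#'
#' @return Data frame with columns \code{element}, \code{mass_shift},
#'   \code{abundance}.
#' @examples
#' defaultIsotopeTable()
#' @export
defaultIsotopeTable <- function() {
    data.frame(
        element    = c("C", "C", "H", "H", "O", "O", "O"),
        mass_shift = c(0L, 1L, 0L, 1L, 0L, 1L, 2L),
        abundance  = c(0.9893, 0.0107,
                       0.999885, 0.000115,
                       0.99757, 0.00038, 0.00205),
        stringsAsFactors = FALSE)
}

.checkIsotopeTable <- function(table) {
    stopifnot(all(c("element", "mass_shift", "abundance") %in% names(table)))
    if (any(table$mass_shift < 0) ||
        any(table$mass_shift != round(table$mass_shift)))
        stop("isotope mass shifts must be non-negative integers")
    tot <- tapply(table$abundance, table$element, sum)
    bad <- names(tot)[abs(tot - 1) > 1e-6]
    if (length(bad))
        stop("isotope abundances do not sum to 1 for element(s): ",
             paste(bad, collapse = ", "))
    invisible(table)
}

#' Parse a molecular formula into element counts
#'
#' @param formula A Hill-style formula such as \code{"C17H34O2"}.
#' @return Named integer vector of atom counts.
#' @examples
#' parseFormula("C17H34O2")
#' @export
parseFormula <- function(formula) {
    stopifnot(is.character(formula), length(formula) == 1L, nzchar(formula))
    m <- gregexpr("[A-Z][a-z]?[0-9]*", formula)[[1]]
    toks <- regmatches(formula, list(m))[[1]]
    if (!length(toks) || sum(attr(m, "match.length")) != nchar(formula))
        stop("cannot parse formula: ", formula)
    el <- sub("[0-9]*$", "", toks)
    n <- sub("^[A-Z][a-z]?", "", toks)
    n <- ifelse(n == "", 1L, as.integer(n))
    counts <- tapply(n, el, sum)
    out <- as.integer(counts)
    names(out) <- names(counts)
    if (any(out < 0) || sum(out) < 1L)
        stop("formula must contain at least one atom")
    out
}

## single-atom mass-shift distribution for one element, as a dense vector
.atomDist <- function(element, table) {
    rows <- table$element == element
    if (!any(rows))
        stop("element '", element, "' is not in the isotope table")
    shifts <- table$mass_shift[rows]
    v <- numeric(max(shifts) + 1L)
    v[shifts + 1L] <- table$abundance[rows]
    v
}

## linear convolution of two fraction vectors, truncated at shift K.
## Truncation is exact for entries <= K: discarded tail mass can only land
## beyond K in any further convolution.
.convTrunc <- function(a, b, K) {
    n <- min(length(a) + length(b) - 1L, K + 1L)
    out <- numeric(n)
    for (i in seq_along(a)) {
        if (a[i] == 0) next
        jmax <- min(length(b), n - i + 1L)
        if (jmax < 1L) break
        idx <- i:(i + jmax - 1L)
        out[idx] <- out[idx] + a[i] * b[seq_len(jmax)]
    }
    out
}

## natural-abundance fraction vector (unnormalized, truncated at K)
.naturalVec <- function(counts, table, K) {
    out <- 1
    for (el in names(counts)) {
        n <- counts[[el]]
        if (n == 0L) next
        d <- .atomDist(el, table)
        ## binary exponentiation of the per-atom polynomial
        base <- d
        acc <- NULL
        while (n > 0L) {
            if (n %% 2L == 1L)
                acc <- if (is.null(acc)) base else .convTrunc(acc, base, K)
            n <- n %/% 2L
            if (n > 0L) base <- .convTrunc(base, base, K)
        }
        out <- .convTrunc(out, acc, K)
    }
    length(out) <- K + 1L
    out[is.na(out)] <- 0
    out
}

#' Theoretical natural-abundance MID of an unlabeled molecule
#'
#' Convolves the per-atom isotope-shift distributions of every atom in the
#' fragment, truncates the result at mass shift \code{K} and renormalizes.
#' This is the spectrum a purely unlabeled analyte presents, and the
#' generating vector of the natural-abundance correction.
#'
#' @param composition A formula string (e.g. \code{"C17H34O2"}) or a named
#'   integer vector of atom counts.
#' @param K Highest mass shift retained (cluster length is \code{K + 1}).
#' @param table Isotope table, see \code{\link{defaultIsotopeTable}}.
#' @return A \linkS4class{MassIsotopomerDistribution}.
#' @examples
#' naturalMID("C17H34O2", K = 5)
#' @export
naturalMID <- function(composition, K = 5L, table = defaultIsotopeTable()) {
    stopifnot(K >= 2L)
    .checkIsotopeTable(table)
    counts <- if (is.character(composition)) parseFormula(composition)
              else composition
    MID(.naturalVec(counts, table, as.integer(K)), normalize = TRUE)
}

#' Convolve two mass isotopomer distributions
#'
#' Discrete convolution of two MIDs (the spectrum of a molecule whose mass
#' shift is the sum of two independent contributions), truncated at
#' \code{K} and renormalized. Commutative and, up to truncation,
#' associative.
#'
#' @param a,b MIDs (or bare fraction vectors).
#' @param K Highest retained shift; defaults to the longer input's K.
#' @return A \linkS4class{MassIsotopomerDistribution}.
#' @export
convolveMID <- function(a, b, K = NULL) {
    fa <- midFractions(a); fb <- midFractions(b)
    if (is.null(K)) K <- max(length(fa), length(fb)) - 1L
    v <- .convTrunc(fa, fb, as.integer(K))
    length(v) <- K + 1L
    v[is.na(v)] <- 0
    MID(v, normalize = TRUE)
}

#' Natural-abundance correction matrix
#'
#' Lower-triangular \code{(K+1) x (K+1)} matrix whose column \code{j} is the
#' natural-abundance MID of the fragment shifted up by \code{j} and
#' truncated at \code{K}. Multiplying it by a tracer-only MID gives the
#' observed (uncorrected) cluster, so the observed spectrum is corrected by
#' solving the triangular system.
#'
#' @inheritParams naturalMID
#' @return Numeric matrix.
#' @export
correctionMatrix <- function(composition, K = 5L,
                             table = defaultIsotopeTable()) {
    nat <- midFractions(naturalMID(composition, K, table))
    n <- K + 1L
    M <- matrix(0, n, n)
    for (j in seq_len(n))
        M[j:n, j] <- nat[seq_len(n - j + 1L)]
    M
}

#' Correct a raw ion cluster for natural isotope abundance
#'
#' Normalizes the raw SIM intensities to molar fractions and removes the
#' contribution of naturally occurring heavy isotopes (including the
#' derivatizing agent's atoms, which are part of the fragment composition)
#' by solving the exact triangular system of \code{\link{correctionMatrix}}.
#' Small negative components produced by detector noise are clipped to zero
#' and the result renormalized. An unlabeled sample returns a delta at m0.
#'
#' @param intensities Non-negative intensities at contiguous shifts
#'   0, 1, ..., K.
#' @inheritParams naturalMID
#' @param table Isotope table.
#' @return A \linkS4class{MassIsotopomerDistribution} of tracer-only
#'   fractions.
#' @examples
#' nat <- midFractions(naturalMID("C17H34O2", K = 5))
#' correctMID(nat * 1e6, "C17H34O2")  # unlabeled: delta at m0
#' @export
correctMID <- function(intensities, composition,
                       table = defaultIsotopeTable()) {
    y <- as.numeric(intensities)
    if (anyNA(y) || any(y < 0))
        stop("intensities must be non-negative and free of NA")
    tot <- sum(y)
    if (tot <= 0)
        stop("total cluster intensity must be positive")
    K <- length(y) - 1L
    if (K < 2L)
        stop("a cluster needs at least three monitored shifts")
    M <- correctionMatrix(composition, K, table)
    if (M[1L, 1L] <= .Machine$double.eps * 10)
        stop("correction system is singular: natural m0 fraction is ~0")
    x <- forwardsolve(M, y / tot)
    x[x < 0] <- 0
    if (sum(x) <= 0)
        stop("correction produced an all-zero distribution")
    MID(x, normalize = TRUE)
}

#' Default fatty-acid definitions
#'
#' Chemical and tracer constants for the analytes monitored by the
#' pipeline: the methyl-ester fragment composition behind each monitored
#' m/z cluster, the number of hydrogen positions that take up deuterium
#' from body water during de novo synthesis (N; 21 for palmitate, with the
#' stearate and oleate values shipped as editable assumptions), and the
#' number of acetyl units polymerised into the chain (8 for palmitate, 9
#' for the C18 acids). Analytes without a monitored cluster (profile-only
#' species and the heptadecanoate-d3 internal standard) carry NA constants.
#'
#' @return Data frame with columns \code{name}, \code{formula},
#'   \code{base_mz}, \code{n_d_sites}, \code{n_acetyl}, \code{traced}.
#' @export
fattyAcidDefinitions <- function() {
    data.frame(
        name = c("palmitate", "stearate", "oleate",
                 "palmitoleate", "vaccenate", "heptadecanoate_d3"),
        formula = c("C17H34O2", "C19H38O2", "C18H32O", NA, NA, NA),
        base_mz = c(270L, 298L, 264L, NA, NA, NA),
        n_d_sites = c(21L, 24L, 24L, NA, NA, NA),
        n_acetyl = c(8L, 9L, 9L, NA, NA, NA),
        traced = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
        stringsAsFactors = FALSE)
}
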