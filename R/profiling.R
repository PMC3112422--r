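#' Fatty-acid profile as percent of palmitate
#'
#' Expresses each analyte's GC peak area as a percentage of the palmitate
#' area in the same sample, palmitate set to 100. Invariant to uniform
#' scaling of the areas.
#'
#' @param areas Named numeric vector of integrated peak areas; must contain
#'   a \code{palmitate} entry with positive area.
#' @param reference Name of the reference analyte.
#' @return Named numeric vector of percentages.
#' @examples
#' profilePercent(c(palmitate = 200, oleate = 150))
#' @export
profilePercent <- function(areas, reference = "palmitate") {
    stopifnot(is.numeric(areas), !is.null(names(areas)))
    if (!reference %in% names(areas))
        stop("reference analyte '", reference, "' missing from areas")
    ref <- areas[[reference]]
    if (!is.finite(ref) || ref <= 0)
        stop("reference analyte area must be positive")
    100 * areas / ref
}

#' Desaturation indices and the stearate/palmitate ratio
#'
#' Monounsaturated-to-saturated peak-area ratios used as a proxy for SCD1
#' activity — palmitoleate/palmitate (16:1/16:0), oleate/stearate
#' (18:1n-9/18:0) and vaccenate/stearate (18:1n-7/18:0) — together with the
#' stearate/palmitate ratio tracking stearate production (elongation plus
#' de novo) against palmitate. Raw integrated areas are used, uncorrected
#' for isotopes. A zero denominator yields NA for that ratio with a
#' warning.
#'
#' @param areas Named numeric vector of peak areas including
#'   \code{palmitate}, \code{palmitoleate}, \code{stearate}, \code{oleate},
#'   \code{vaccenate}.
#' @return Named numeric vector: \code{palmitoleate_palmitate},
#'   \code{oleate_stearate}, \code{vaccenate_stearate},
#'   \code{stearate_palmitate}.
#' @export
desaturationIndices <- function(areas) {
    stopifnot(is.numeric(areas), !is.null(names(areas)))
    pairs <- rbind(
        c("palmitoleate", "palmitate"),
        c("oleate", "stearate"),
        c("vaccenate", "stearate"),
        c("stearate", "palmitate"))
    out <- apply(pairs, 1L, function(pr) {
        if (!all(pr %in% names(areas))) return(NA_real_)
        den <- areas[[pr[2L]]]
        if (!is.finite(den) || den <= 0) {
            warning("zero denominator for ", pr[1L], "/", pr[2L])
            return(NA_real_)
        }
        areas[[pr[1L]]] / den
    })
    names(out) <- paste(pairs[, 1L], pairs[, 2L], sep = "_")
    out
}

#' Internal-standard absolute quantification
#'
#' Converts GC peak areas to micrograms of analyte per mg of tissue using
#' a known quantity of heptadecanoate-d3 spiked before saponification:
#' \code{quantity_i = isQuantityUg * (area_i / isArea) * rf_i /
#' tissueMassMg}. Detector response factors default to 1 for all FAMEs.
#'
#' @param areas Named numeric vector of analyte peak areas.
#' @param isArea Internal-standard peak area (> 0).
#' @param isQuantityUg Spiked internal-standard quantity, micrograms.
#' @param tissueMassMg Tissue mass, mg (> 0).
#' @param responseFactors Optional named vector of per-analyte response
#'   factors; analytes not named get 1.
#' @return Named numeric vector, micrograms per mg tissue.
#' @examples
#' quantifyFattyAcids(c(palmitate = 20), isArea = 10,
#'                    isQuantityUg = 10, tissueMassMg = 30)
#' @export
quantifyFattyAcids <- function(areas, isArea, isQuantityUg, tissueMassMg,
                               responseFactors = NULL) {
    stopifnot(is.numeric(areas), all(areas >= 0))
    if (!is.finite(isArea) || isArea <= 0)
        stop("internal-standard area must be positive")
    if (isQuantityUg <= 0) stop("internal-standard quantity must be positive")
    if (tissueMassMg <= 0) stop("tissue mass must be positive")
    rf <- rep(1, length(areas))
    if (!is.null(responseFactors)) {
        hit <- names(areas) %in% names(responseFactors)
        rf[hit] <- responseFactors[names(areas)[hit]]
    }
    isQuantityUg * (areas / isArea) * rf / tissueMassMg
}

#' Relative expression fold change by the delta-delta-Ct method
#'
#' Fold change of a target gene in group b relative to group a, each
#' normalized to a reference gene, assuming amplification efficiency
#' exactly 2: \eqn{2^{-\Delta\Delta Ct}} with
#' \eqn{\Delta\Delta Ct = (Ct^{tgt}_b - Ct^{ref}_b) -
#' (Ct^{tgt}_a - Ct^{ref}_a)}. Mean Ct values per group are the usual
#' inputs.
#'
#' @param ctTargetA,ctRefA Target and reference-gene Ct in the baseline
#'   group.
#' @param ctTargetB,ctRefB Target and reference-gene Ct in the comparison
#'   group.
#' @return Fold change (group b vs group a).
#' @examples
#' ddCtFoldChange(25, 12, 24.2776, 12)  # ~1.65
#' @export
ddCtFoldChange <- function(ctTargetA, ctRefA, ctTargetB, ctRefB) {
    cts <- c(ctTargetA, ctRefA, ctTargetB, ctRefB)
    if (any(!is.finite(cts)) || any(cts <= 0))
        stop("Ct values must be positive")
    ddct <- (ctTargetB - ctRefB) - (ctTargetA - ctRefA)
    2^(-ddct)
}
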