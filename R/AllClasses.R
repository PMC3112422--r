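#' @import methods
NULL

#' Mass isotopomer distribution (MID)
#'
#' Molar fractions of an ion cluster at integer mass shifts m0, m1, ...
#' above the monoisotopic peak. Fractions are non-negative and sum to one.
#'
#' @slot fractions Numeric vector of molar fractions, element \code{i}
#'   corresponding to mass shift \code{i - 1} Da.
#' @exportClass MassIsotopomerDistribution
setClass("MassIsotopomerDistribution",
    representation(fractions = "numeric"),
    validity = function(object) {
        f <- object@fractions
        if (length(f) < 3L)
            return("an MID needs at least three mass shifts (m0..m2)")
        if (anyNA(f))
            return("fractions must not contain NA")
        if (any(f < 0))
            return("fractions must be non-negative")
        if (abs(sum(f) - 1) > 1e-9)
            return("fractions must sum to 1 within 1e-9")
        TRUE
    })

#' Construct a mass isotopomer distribution
#'
#' @param fractions Numeric vector of molar fractions for shifts m0, m1, ...
#'   (length at least 3).
#' @param normalize If \code{TRUE}, divide by the total before validating;
#'   use for raw non-negative weights.
#' @return A \linkS4class{MassIsotopomerDistribution}.
#' @examples
#' MID(c(0.9, 0.08, 0.02))
#' @export
MID <- function(fractions, normalize = FALSE) {
    fractions <- as.numeric(fractions)
    if (normalize) {
        s <- sum(fractions)
        if (!is.finite(s) || s <= 0)
            stop("cannot normalize: total is not positive")
        fractions <- fractions / s
    }
    new("MassIsotopomerDistribution", fractions = fractions)
}

#' @describeIn MID Accessor for the molar-fraction vector.
#' @param x A \code{MassIsotopomerDistribution}.
#' @export
midFractions <- function(x) {
    if (is(x, "MassIsotopomerDistribution")) x@fractions else as.numeric(x)
}

setMethod("show", "MassIsotopomerDistribution", function(object) {
    f <- object@fractions
    cat("MassIsotopomerDistribution (K =", length(f) - 1L, ")\n")
    names(f) <- paste0("m", seq_along(f) - 1L)
    print(round(f, 6))
})

setMethod("length", "MassIsotopomerDistribution", function(x)
    length(x@fractions))

#' Two-group synthetic study design
#'
#' Declarative description of a simulated labeling study: groups, sample
#' sizes, tracer, per-(tissue, analyte, group) ground truth for fractional
#' synthesis and precursor enrichment, tissue composition, qPCR effects and
#' the noise model. Built by \code{\link{defaultStudyDesign}} or directly.
#'
#' @slot groups Character vector of two group labels; the first is the
#'   reference (control) group.
#' @slot nPerGroup Integer, animals (or cultures) per group.
#' @slot tracer \code{"deuterium"} or \code{"c13"}.
#' @slot labelingDays Length of the labeling window in days.
#' @slot analytes Data frame of fatty-acid definitions
#'   (see \code{\link{fattyAcidDefinitions}}).
#' @slot truth Data frame with columns \code{tissue}, \code{analyte},
#'   \code{group}, \code{fns} (fraction), \code{fns_sd} (between-animal SD),
#'   \code{precursor} (p or g), \code{precursor_sd}.
#' @slot composition Data frame with columns \code{tissue}, \code{analyte},
#'   \code{group}, \code{amount_ug_per_mg}.
#' @slot ct Data frame with columns \code{tissue}, \code{group},
#'   \code{dct_mean} (target Ct minus reference Ct), \code{ct_ref_mean},
#'   \code{ct_sd}.
#' @slot noise List: \code{depth} (expected total ion counts per cluster;
#'   \code{Inf} for noiseless), \code{areaCV} (log-normal CV of peak areas),
#'   \code{tissueMassMg}, \code{isQuantityUg}.
#' @exportClass StudyDesign
setClass("StudyDesign",
    representation(groups = "character", nPerGroup = "integer",
        tracer = "character", labelingDays = "numeric",
        analytes = "data.frame", truth = "data.frame",
        composition = "data.frame", ct = "data.frame", noise = "list"),
    validity = function(object) {
        if (length(object@groups) != 2L || anyDuplicated(object@groups))
            return("exactly two distinct group labels are required")
        if (object@nPerGroup < 2L)
            return("at least 2 samples per group are required")
        if (!object@tracer %in% c("deuterium", "c13"))
            return("tracer must be 'deuterium' or 'c13'")
        if (object@labelingDays <= 0)
            return("labelingDays must be positive")
        tr <- object@truth
        need <- c("tissue", "analyte", "group", "fns", "fns_sd",
                  "precursor", "precursor_sd")
        if (!all(need %in% names(tr)))
            return(paste("truth must have columns:",
                         paste(need, collapse = ", ")))
        if (any(tr$fns < 0 | tr$fns > 1))
            return("truth fns must lie in [0, 1]")
        if (any(tr$precursor <= 0 | tr$precursor >= 1))
            return("truth precursor enrichment must lie in (0, 1)")
        TRUE
    })

setMethod("show", "StudyDesign", function(object) {
    cat("StudyDesign:", object@tracer, "tracer,",
        paste(object@groups, collapse = " vs "),
        sprintf("(n = %d/group)\n", object@nPerGroup))
    cat("  tissues: ", paste(unique(object@truth$tissue), collapse = ", "),
        "\n  analytes:", paste(unique(object@truth$analyte), collapse = ", "),
        "\n  labeling:", object@labelingDays, "days; cluster depth",
        object@noise$depth, "counts\n")
})

#' A simulated study bundle
#'
#' Container for one realisation of a \linkS4class{StudyDesign}: raw SIM
#' cluster intensities, GC peak areas, the sample manifest, qPCR Ct values
#' and the ground-truth table used to score recovery. All components are
#' plain data frames; \code{\link{writeStudy}} serialises them to CSV.
#'
#' @slot clusters Data frame: \code{sample}, \code{tissue}, \code{analyte},
#'   \code{shift}, \code{intensity}.
#' @slot areas Data frame: \code{sample}, \code{tissue}, \code{analyte},
#'   \code{area} (includes the internal-standard rows).
#' @slot manifest Data frame: \code{sample}, \code{group}, \code{tissue},
#'   \code{tracer}, \code{tissue_mass_mg}, \code{is_quantity_ug},
#'   \code{labeling_days}.
#' @slot ct Data frame: \code{sample}, \code{group}, \code{tissue},
#'   \code{target_ct}, \code{reference_ct}.
#' @slot truth Data frame of per-sample ground truth.
#' @slot seed The integer seed the realisation was drawn with.
#' @exportClass SyntheticStudy
setClass("SyntheticStudy",
    representation(clusters = "data.frame", areas = "data.frame",
        manifest = "data.frame", ct = "data.frame", truth = "data.frame",
        seed = "integer"),
    validity = function(object) {
        if (nrow(object@manifest) == 0L)
            return("manifest must not be empty")
        if (any(object@clusters$intensity < 0))
            return("cluster intensities must be non-negative")
        TRUE
    })

setMethod("show", "SyntheticStudy", function(object) {
    cat("SyntheticStudy:", nrow(object@manifest), "samples,",
        length(unique(object@clusters$analyte)), "traced analytes,",
        "seed", object@seed, "\n")
})

#' @describeIn SyntheticStudy-class Accessors for the study components.
#' @param x A \code{SyntheticStudy}.
#' @export
studyClusters <- function(x) x@clusters
#' @describeIn SyntheticStudy-class Peak-area table.
#' @export
studyAreas <- function(x) x@areas
#' @describeIn SyntheticStudy-class Sample manifest.
#' @export
studyManifest <- function(x) x@manifest
#' @describeIn SyntheticStudy-class qPCR Ct table.
#' @export
studyCt <- function(x) x@ct
#' @describeIn SyntheticStudy-class Ground-truth table.
#' @export
studyTruth <- function(x) x@truth
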