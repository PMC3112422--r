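#' Simulate one raw SIM ion cluster
#'
#' Forward model for a labeled fatty-acid cluster: the tracer-only MID
#' (deuterium: an unlabeled fraction plus Binomial(N, p) labeling;
#' 13C: the MIDA polymerisation model) is convolved with the fragment's
#' natural-abundance spectrum, scaled to the expected total ion count and
#' Poisson-sampled. With \code{depth = Inf} the noiseless expected
#' intensities are returned.
#'
#' @param f Fraction of newly synthesised molecules.
#' @param precursor Body-water deuterium enrichment p (deuterium) or
#'   acetyl-CoA M+2 enrichment g (c13).
#' @param definition One row of \code{\link{fattyAcidDefinitions}} (needs
#'   \code{formula} and \code{n_d_sites} or \code{n_acetyl}).
#' @param tracer \code{"deuterium"} or \code{"c13"}.
#' @param depth Expected total counts in the cluster (Poisson noise), or
#'   \code{Inf} for noiseless.
#' @param K Highest monitored mass shift. Default: \code{min(N, 12)} for
#'   deuterium, \code{2 * n_acetyl} for c13 (full tracer support).
#' @param table Isotope table.
#' @return Numeric intensity vector for shifts 0..K.
#' @export
simulateCluster <- function(f, precursor, definition,
                            tracer = c("deuterium", "c13"),
                            depth = 1e6, K = NULL,
                            table = defaultIsotopeTable()) {
    tracer <- match.arg(tracer)
    stopifnot(f >= 0, f <= 1, precursor >= 0, precursor < 1)
    if (tracer == "deuterium") {
        N <- definition$n_d_sites
        if (is.null(K)) K <- min(N, 12L)
        tr <- numeric(K + 1L)
        kk <- 0:min(N, K)
        tr[kk + 1L] <- f * stats::dbinom(kk, N, precursor)
        tr[1L] <- tr[1L] + (1 - f)
    } else {
        n <- definition$n_acetyl
        if (is.null(K)) K <- 2L * n
        tr <- midFractions(midaForward(f, precursor, n, K))
    }
    nat <- .naturalVec(parseFormula(definition$formula), table, K)
    mu <- .convTrunc(tr, nat, K)
    length(mu) <- K + 1L
    mu[is.na(mu)] <- 0
    mu <- mu / sum(mu)
    if (is.infinite(depth)) mu else as.numeric(stats::rpois(K + 1L, mu * depth))
}

## Table-derived defaults for the two study arms. The deuterium arm mirrors
## the p21 subcutaneous-fat in vivo measurements; the c13 arm mirrors the
## primary adipocyte cultures. Between-animal SDs are SE * sqrt(n) of the
## printed group summaries (Control n = 5, FR n = 6 in vivo; 8 cultures).
.deuteriumTruth <- function() {
    sdC <- sqrt(5); sdF <- sqrt(6)
    data.frame(
        tissue = "SC_fat",
        analyte = rep(c("palmitate", "stearate", "oleate"), each = 2L),
        group = rep(c("Control", "FR"), 3L),
        fns = c(0.400, 0.435, 0.225, 0.241, 0.178, 0.176),
        fns_sd = c(0.014 * sdC, 0.011 * sdF, 0.011 * sdC, 0.010 * sdF,
                   0.010 * sdC, 0.012 * sdF),
        precursor = 0.03,
        precursor_sd = 0.001,
        stringsAsFactors = FALSE)
}

.c13Truth <- function() {
    sd8 <- sqrt(8)
    data.frame(
        tissue = "adipocyte_culture",
        analyte = rep(c("palmitate", "stearate", "oleate"), each = 2L),
        group = rep(c("Control", "FR"), 3L),
        fns = c(0.254, 0.310, 0.079, 0.092, 0.015, 0.017),
        fns_sd = c(0.004, 0.001, 0.002, 0.001, 0.001, 0.001) * sd8,
        precursor = rep(c(0.118, 0.133), 3L),
        precursor_sd = 0.001 * sd8,
        stringsAsFactors = FALSE)
}

## Tissue composition (ug fatty acid per mg SC fat). Palmitate content is
## anchored to the printed synthesis rate (rate * days / FNS); the other
## species follow the printed area-ratio chain so that the generated
## desaturation indices match the group summaries exactly.
.scFatComposition <- function() {
    palmC <- 3.19 * 14 / 0.400
    palmF <- 3.85 * 14 / 0.435
    steaC <- 0.27 * palmC
    steaF <- 0.25 * palmF
    data.frame(
        tissue = "SC_fat",
        analyte = rep(c("palmitate", "stearate", "oleate",
                        "palmitoleate", "vaccenate"), each = 2L),
        group = rep(c("Control", "FR"), 5L),
        amount_ug_per_mg = c(palmC, palmF, steaC, steaF,
                             3.23 * steaC, 3.51 * steaF,
                             0.041 * palmC, 0.046 * palmF,
                             0.29 * steaC, 0.31 * steaF),
        stringsAsFactors = FALSE)
}

.scd1Ct <- function() {
    data.frame(
        tissue = c("SC_fat", "SC_fat", "liver", "liver"),
        group = c("Control", "FR", "Control", "FR"),
        dct_mean = c(8, 8 - log2(1.65), 9, 9 - log2(0.28)),
        ct_ref_mean = 12,
        ct_sd = 0.15,
        stringsAsFactors = FALSE)
}

#' Default study designs parameterised from the programmed-obesity model
#'
#' Two ready-made two-group designs. \code{tracer = "deuterium"}: nursing
#' offspring labeled 14 days via ~3\% body-water deuterium, subcutaneous
#' fat analysed for palmitate/stearate/oleate FNS, composition and SCD1
#' expression. \code{tracer = "c13"}: primary adipocyte cultures on 50\%
#' [U-13C]glucose medium for 24 h, analysed by MIDA. Group means are the
#' published control vs food-restricted (FR) values; between-animal SDs
#' derive from the published SEs.
#'
#' @param tracer Which arm to build.
#' @param nPerGroup Animals (or cultures) per group.
#' @param depth Expected total ion counts per SIM cluster (\code{Inf} for
#'   noiseless).
#' @param areaCV Log-normal coefficient of variation of peak areas.
#' @return A \linkS4class{StudyDesign}.
#' @examples
#' defaultStudyDesign("deuterium", nPerGroup = 6L)
#' @export
defaultStudyDesign <- function(tracer = c("deuterium", "c13"),
                               nPerGroup = 6L, depth = 1e6,
                               areaCV = 0.05) {
    tracer <- match.arg(tracer)
    if (tracer == "deuterium") {
        truth <- .deuteriumTruth(); comp <- .scFatComposition()
        ct <- .scd1Ct(); days <- 14
    } else {
        truth <- .c13Truth()
        comp <- data.frame(tissue = character(), analyte = character(),
                           group = character(), amount_ug_per_mg = numeric())
        ct <- data.frame(tissue = character(), group = character(),
                         dct_mean = numeric(), ct_ref_mean = numeric(),
                         ct_sd = numeric())
        days <- 1
    }
    new("StudyDesign", groups = c("Control", "FR"),
        nPerGroup = as.integer(nPerGroup), tracer = tracer,
        labelingDays = days, analytes = fattyAcidDefinitions(),
        truth = truth, composition = comp, ct = ct,
        noise = list(depth = depth, areaCV = areaCV,
                     tissueMassMg = 30, isQuantityUg = 50))
}

.truncNorm <- function(n, mean, sd, lo, hi) {
    pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)
}

#' Simulate a complete two-group labeling study
#'
#' Draws per-animal ground truth (Gaussian on FNS and precursor
#' enrichment, truncated to valid ranges; log-normal on composition),
#' generates raw SIM clusters through the forward isotope model with
#' Poisson counting noise, GC peak areas with multiplicative noise, a
#' sample manifest and qPCR Ct values, and keeps the drawn truth for
#' scoring recovery. Fully deterministic for a given seed.
#'
#' @param design A \linkS4class{StudyDesign}.
#' @param seed Integer seed.
#' @return A \linkS4class{SyntheticStudy}.
#' @examples
#' study <- simulateStudy(defaultStudyDesign("deuterium"), seed = 1)
#' @export
simulateStudy <- function(design, seed = 1L) {
    stopifnot(is(design, "StudyDesign"))
    validObject(design)
    set.seed(as.integer(seed))
    groups <- rep(design@groups, each = design@nPerGroup)
    samples <- sprintf("%s_%02d", groups,
                       rep(seq_len(design@nPerGroup), 2L))
    noise <- design@noise
    defs <- design@analytes
    tracer <- design@tracer
    tissues <- unique(design@truth$tissue)

    manifest <- data.frame(sample = samples, group = groups,
        tissue = tissues[1L], tracer = tracer,
        tissue_mass_mg = noise$tissueMassMg,
        is_quantity_ug = noise$isQuantityUg,
        labeling_days = design@labelingDays,
        stringsAsFactors = FALSE)

    ## per-sample precursor enrichment (body water p / acetyl-CoA g is a
    ## property of the animal or culture, shared across analytes)
    precRow <- design@truth[design@truth$analyte == design@truth$analyte[1L], ]
    prec <- numeric(length(samples))
    for (g in design@groups) {
        r <- precRow[precRow$group == g, ][1L, ]
        sel <- groups == g
        prec[sel] <- .truncNorm(sum(sel), r$precursor, r$precursor_sd,
                                1e-4, 0.499)
    }

    clusters <- list(); truth <- list()
    tracedAn <- unique(design@truth$analyte)
    for (an in tracedAn) {
        def <- defs[defs$name == an, ]
        if (nrow(def) != 1L || !isTRUE(def$traced))
            stop("no traced definition for analyte '", an, "'")
        for (g in design@groups) {
            tr <- design@truth[design@truth$analyte == an &
                               design@truth$group == g, ]
            sel <- which(groups == g)
            fI <- .truncNorm(length(sel), tr$fns, tr$fns_sd, 1e-4, 0.999)
            for (j in seq_along(sel)) {
                i <- sel[j]
                y <- simulateCluster(fI[j], prec[i], def, tracer,
                                     depth = noise$depth)
                clusters[[length(clusters) + 1L]] <- data.frame(
                    sample = samples[i], tissue = tr$tissue, analyte = an,
                    shift = seq_along(y) - 1L, intensity = y,
                    stringsAsFactors = FALSE)
                truth[[length(truth) + 1L]] <- data.frame(
                    sample = samples[i], group = groups[i],
                    tissue = tr$tissue, analyte = an, fns_true = fI[j],
                    precursor_true = prec[i], stringsAsFactors = FALSE)
            }
        }
    }
    clusters <- do.call(rbind, clusters)
    truth <- do.call(rbind, truth)

    ## GC peak areas: proportional to tissue content, log-normal noise,
    ## plus the internal-standard rows
    areas <- NULL
    if (nrow(design@composition)) {
        sdlog <- sqrt(log(1 + noise$areaCV^2))
        scale <- 100  # arbitrary detector counts per ug
        rows <- list()
        amt <- numeric(nrow(truth)); names(amt) <- paste(truth$sample,
                                                         truth$analyte)
        for (i in seq_along(samples)) {
            comp <- design@composition[design@composition$group == groups[i], ]
            eps <- if (noise$areaCV > 0)
                exp(stats::rnorm(nrow(comp), 0, sdlog)) else rep(1, nrow(comp))
            amount <- comp$amount_ug_per_mg * eps
            rows[[i]] <- data.frame(sample = samples[i],
                tissue = comp$tissue, analyte = comp$analyte,
                area = amount * noise$tissueMassMg * scale,
                stringsAsFactors = FALSE)
            key <- paste(samples[i], comp$analyte)
            amt[match(key, names(amt), nomatch = 0L)] <-
                amount[key %in% names(amt)]
            isEps <- if (noise$areaCV > 0) exp(stats::rnorm(1, 0, sdlog)) else 1
            rows[[i]] <- rbind(rows[[i]], data.frame(sample = samples[i],
                tissue = comp$tissue[1L], analyte = "heptadecanoate_d3",
                area = noise$isQuantityUg * scale * isEps,
                stringsAsFactors = FALSE))
        }
        areas <- do.call(rbind, rows)
        truth$amount_true <- amt
    }
    if (is.null(areas))
        areas <- data.frame(sample = character(), tissue = character(),
                            analyte = character(), area = numeric())

    ## qPCR Ct values
    ct <- NULL
    if (nrow(design@ct)) {
        rows <- list()
        for (k in seq_len(nrow(design@ct))) {
            d <- design@ct[k, ]
            sel <- which(groups == d$group)
            ref <- stats::rnorm(length(sel), d$ct_ref_mean, d$ct_sd)
            tgt <- ref + stats::rnorm(length(sel), d$dct_mean, d$ct_sd)
            rows[[k]] <- data.frame(sample = samples[sel], group = d$group,
                tissue = d$tissue, target_ct = tgt, reference_ct = ref,
                stringsAsFactors = FALSE)
        }
        ct <- do.call(rbind, rows)
    }
    if (is.null(ct))
        ct <- data.frame(sample = character(), group = character(),
                         tissue = character(), target_ct = numeric(),
                         reference_ct = numeric())

    rownames(clusters) <- rownames(truth) <- rownames(areas) <-
        rownames(ct) <- NULL
    new("SyntheticStudy", clusters = clusters, areas = areas,
        manifest = manifest, ct = ct, truth = truth,
        seed = as.integer(seed))
}

#' Write a synthetic study to CSV files
#'
#' Serialises the five component tables (\code{clusters.csv},
#' \code{areas.csv}, \code{manifest.csv}, \code{ct.csv}, \code{truth.csv})
#' into a directory, creating it if needed.
#'
#' @param study A \linkS4class{SyntheticStudy}.
#' @param dir Output directory.
#' @return \code{dir}, invisibly.
#' @export
writeStudy <- function(study, dir) {
    stopifnot(is(study, "SyntheticStudy"))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    parts <- list(clusters = study@clusters, areas = study@areas,
                  manifest = study@manifest, ct = study@ct,
                  truth = study@truth)
    for (nm in names(parts))
        utils::write.csv(parts[[nm]], file.path(dir, paste0(nm, ".csv")),
                         row.names = FALSE)
    invisible(dir)
}

#' Read a study directory written by \code{\link{writeStudy}}
#'
#' @param dir Directory containing the study CSV files; \code{truth.csv}
#'   and \code{ct.csv} are optional.
#' @return A \linkS4class{SyntheticStudy}.
#' @export
readStudy <- function(dir) {
    rd <- function(nm, required = TRUE) {
        p <- file.path(dir, paste0(nm, ".csv"))
        if (!file.exists(p)) {
            if (required) stop("missing input file: ", p)
            return(NULL)
        }
        utils::read.csv(p, stringsAsFactors = FALSE)
    }
    clusters <- rd("clusters"); manifest <- rd("manifest")
    areas <- rd("areas", required = FALSE)
    ct <- rd("ct", required = FALSE)
    truth <- rd("truth", required = FALSE)
    if (is.null(areas))
        areas <- data.frame(sample = character(), tissue = character(),
                            analyte = character(), area = numeric())
    if (is.null(ct))
        ct <- data.frame(sample = character(), group = character(),
                         tissue = character(), target_ct = numeric(),
                         reference_ct = numeric())
    if (is.null(truth)) truth <- data.frame()
    new("SyntheticStudy", clusters = clusters, areas = areas,
        manifest = manifest, ct = ct, truth = truth, seed = NA_integer_)
}
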