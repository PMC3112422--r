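#' Two-group summary with unpaired t-test
#'
#' Per-group mean, standard error and n, plus a two-sided unpaired t-test
#' between the two groups. The pooled-variance (Student) test is the
#' default, matching the convention of reporting mean +/- SE with an
#' unqualified unpaired t-test; Welch's test is available by flag. A group
#' with fewer than two values yields a summary without a test, flagged
#' \code{"insufficient n"}. Significance markers: \code{**} p < 0.01,
#' \code{*} p < 0.05, \code{¥} 0.05 <= p < 0.10 (strong trend).
#'
#' @param values Numeric vector of per-sample values.
#' @param groups Factor or character vector of group labels, two levels.
#' @param refLevel Optional reference (first) group label.
#' @param welch Use Welch's unequal-variance t-test instead of pooled.
#' @return One-row data frame: \code{group1}, \code{mean1}, \code{se1},
#'   \code{n1}, \code{group2}, \code{mean2}, \code{se2}, \code{n2},
#'   \code{t}, \code{df}, \code{p}, \code{signif}, \code{flag}.
#' @examples
#' summarizeGroups(c(1, 2, 3, 4, 5, 6), rep(c("Control", "FR"), each = 3))
#' @export
summarizeGroups <- function(values, groups, refLevel = NULL, welch = FALSE) {
    keep <- is.finite(values)
    values <- values[keep]; groups <- as.character(groups)[keep]
    lev <- unique(groups)
    if (length(lev) != 2L)
        stop("exactly two groups are required, got: ",
             paste(lev, collapse = ", "))
    if (!is.null(refLevel)) {
        if (!refLevel %in% lev) stop("refLevel not among group labels")
        lev <- c(refLevel, setdiff(lev, refLevel))
    }
    v1 <- values[groups == lev[1L]]; v2 <- values[groups == lev[2L]]
    se <- function(x) if (length(x) > 1L) stats::sd(x) / sqrt(length(x))
                      else NA_real_
    out <- data.frame(group1 = lev[1L], mean1 = mean(v1), se1 = se(v1),
        n1 = length(v1), group2 = lev[2L], mean2 = mean(v2), se2 = se(v2),
        n2 = length(v2), t = NA_real_, df = NA_real_, p = NA_real_,
        signif = "", flag = NA_character_, stringsAsFactors = FALSE)
    if (length(v1) < 2L || length(v2) < 2L) {
        out$flag <- "insufficient n"
        return(out)
    }
    if (stats::sd(v1) == 0 && stats::sd(v2) == 0) {
        ## degenerate: no within-group variance
        d <- mean(v2) - mean(v1)
        out$t <- if (d == 0) 0 else sign(d) * Inf
        out$df <- length(v1) + length(v2) - 2L
        out$p <- if (d == 0) 1 else 0
    } else {
        tt <- stats::t.test(v2, v1, var.equal = !welch)
        out$t <- unname(tt$statistic)
        out$df <- unname(tt$parameter)
        out$p <- tt$p.value
    }
    out$signif <- if (out$p < 0.01) "**" else if (out$p < 0.05) "*"
                  else if (out$p < 0.10) "¥" else ""
    out
}

.requireCols <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss))
        stop(what, " is missing column(s): ", paste(miss, collapse = ", "))
}

.validateStudy <- function(study) {
    man <- study@manifest
    if (nrow(man) == 0L) stop("manifest is empty: nothing to analyse")
    .requireCols(man, c("sample", "group", "tracer"), "manifest")
    cl <- study@clusters
    .requireCols(cl, c("sample", "analyte", "shift", "intensity"),
                 "clusters table")
    if (any(cl$intensity < 0))
        stop("clusters table contains negative intensities (sample ",
             cl$sample[which(cl$intensity < 0)[1L]], ")")
    bad <- setdiff(unique(cl$sample), man$sample)
    if (length(bad))
        stop("clusters reference samples absent from the manifest: ",
             paste(bad, collapse = ", "))
    split_key <- paste(cl$sample, cl$analyte)
    for (k in unique(split_key)) {
        s <- sort(cl$shift[split_key == k])
        if (s[1L] != 0L || any(diff(s) != 1L))
            stop("cluster shifts not contiguous from 0 for ", k)
    }
    invisible(TRUE)
}

## estimate enrichment for every (sample, analyte) cluster of one study
.analyseClusters <- function(study, defs, pFromReference = TRUE) {
    man <- study@manifest
    cl <- study@clusters
    tracer <- man$tracer[1L]
    out <- list()
    for (smp in man$sample) {
        grp <- man$group[man$sample == smp][1L]
        sub <- cl[cl$sample == smp, ]
        mids <- list()
        for (an in unique(sub$analyte)) {
            d <- sub[sub$analyte == an, ]
            d <- d[order(d$shift), ]
            def <- defs[defs$name == an, ]
            if (nrow(def) != 1L || is.na(def$formula))
                stop("no fragment definition for analyte '", an, "'")
            mids[[an]] <- correctMID(d$intensity, def$formula)
        }
        ## deuterium: body-water p estimated once per sample from the
        ## reference analyte (palmitate, the strongest signal)
        pShared <- NULL
        if (tracer == "deuterium" && pFromReference &&
            "palmitate" %in% names(mids)) {
            Np <- defs$n_d_sites[defs$name == "palmitate"]
            pShared <- waterEnrichmentFromRatio(mids$palmitate, Np)$p
        }
        for (an in names(mids)) {
            def <- defs[defs$name == an, ]
            mid <- mids[[an]]
            if (tracer == "deuterium") {
                p <- if (is.null(pShared))
                    waterEnrichmentFromRatio(mid, def$n_d_sites)$p
                else pShared
                fr <- fnsDeuterium(mid, p, def$n_d_sites)
                row <- data.frame(sample = smp, group = grp, analyte = an,
                    precursor = p, me = fr$me, fns = fr$fns,
                    stringsAsFactors = FALSE)
            } else {
                pair <- if (an == "stearate") "m6/m4" else "m4/m2"
                g <- acetylEnrichment(mid, def$n_acetyl, pair)$g
                fr <- fnsMIDA(mid, g, def$n_acetyl)
                row <- data.frame(sample = smp, group = grp, analyte = an,
                    precursor = g, me = molarEnrichment(mid), fns = fr$fns,
                    stringsAsFactors = FALSE)
            }
            out[[length(out) + 1L]] <- row
        }
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

## per-sample profile metrics from the peak-area table
.analyseAreas <- function(study) {
    ar <- study@areas
    if (nrow(ar) == 0L) return(NULL)
    man <- study@manifest
    out <- list()
    for (smp in unique(ar$sample)) {
        sub <- ar[ar$sample == smp, ]
        a <- stats::setNames(sub$area, sub$analyte)
        m <- man[man$sample == smp, ][1L, ]
        idx <- desaturationIndices(a)
        fa <- a[names(a) != "heptadecanoate_d3"]
        ug <- if ("heptadecanoate_d3" %in% names(a))
            quantifyFattyAcids(fa, a[["heptadecanoate_d3"]],
                               m$is_quantity_ug, m$tissue_mass_mg)
        else rep(NA_real_, length(fa))
        pct <- profilePercent(fa)
        out[[smp]] <- data.frame(sample = smp, group = m$group,
            analyte = names(fa), area = unname(fa),
            percent_of_palmitate = unname(pct),
            amount_ug_per_mg = unname(ug),
            palmitoleate_palmitate = idx[["palmitoleate_palmitate"]],
            oleate_stearate = idx[["oleate_stearate"]],
            vaccenate_stearate = idx[["vaccenate_stearate"]],
            stearate_palmitate = idx[["stearate_palmitate"]],
            stringsAsFactors = FALSE)
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

.mdTable <- function(df) {
    hdr <- paste0("| ", paste(names(df), collapse = " | "), " |")
    sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
    fmt <- vapply(seq_len(nrow(df)), function(i) {
        cells <- vapply(df[i, ], function(x)
            if (is.numeric(x)) formatC(x, digits = 4, format = "fg")
            else as.character(x), character(1))
        paste0("| ", paste(cells, collapse = " | "), " |")
    }, character(1))
    c(hdr, sep, fmt)
}

#' Run the full analysis pipeline on a study
#'
#' End-to-end orchestration: input validation, natural-abundance
#' correction of every cluster, tracer-appropriate enrichment estimation
#' (deuterium FNS or 13C MIDA), internal-standard quantification, fatty
#' acid profile and desaturation indices, synthesis rates, SCD1
#' delta-delta-Ct fold change, and two-group summaries with unpaired
#' t-tests for every metric. The summary layout mirrors the group-mean +/-
#' SE tables of the underlying study design.
#'
#' @param study A \linkS4class{SyntheticStudy} or a directory of study
#'   CSVs (see \code{\link{writeStudy}}).
#' @param outDir Optional directory; when given, per-stage CSVs
#'   (\code{enrichment.csv}, \code{profile.csv}, \code{folds.csv},
#'   \code{summary.csv}) and a Markdown report (\code{report.md}) are
#'   written there.
#' @param defs Fatty-acid definitions table.
#' @param welch Use Welch's t-test instead of pooled-variance.
#' @param bhAdjust Add a Benjamini-Hochberg adjusted p-value column
#'   (off by default).
#' @return List: \code{enrichment} (per-sample estimates), \code{profile}
#'   (per-sample areas/indices/amounts), \code{rates} (per-sample
#'   synthesis rates), \code{folds} (expression fold changes),
#'   \code{summary} (group statistics per metric).
#' @export
runPipeline <- function(study, outDir = NULL,
                        defs = fattyAcidDefinitions(), welch = FALSE,
                        bhAdjust = FALSE) {
    if (is.character(study)) study <- readStudy(study)
    stopifnot(is(study, "SyntheticStudy"))
    .validateStudy(study)
    man <- study@manifest

    enr <- .analyseClusters(study, defs)
    prof <- .analyseAreas(study)

    ## synthesis rates need both FNS and ug/mg
    rates <- NULL
    if (!is.null(prof) && man$tracer[1L] == "deuterium" &&
        "labeling_days" %in% names(man)) {
        m <- merge(enr, prof[, c("sample", "analyte", "amount_ug_per_mg")],
                   by = c("sample", "analyte"))
        m <- merge(m, man[, c("sample", "labeling_days")], by = "sample")
        m$rate_ug_per_mg_day <- synthesisRate(m$amount_ug_per_mg, m$fns,
                                              m$labeling_days)
        rates <- m[order(m$analyte, m$sample),
                   c("sample", "group", "analyte", "amount_ug_per_mg",
                     "fns", "rate_ug_per_mg_day")]
        rownames(rates) <- NULL
    }

    ## qPCR: per-sample delta Ct, group fold change
    folds <- NULL
    ctTab <- study@ct
    if (nrow(ctTab)) {
        ctTab$dct <- ctTab$target_ct - ctTab$reference_ct
        rows <- list()
        for (tis in unique(ctTab$tissue)) {
            sub <- ctTab[ctTab$tissue == tis, ]
            s <- summarizeGroups(sub$dct, sub$group, refLevel = "Control")
            rows[[tis]] <- data.frame(tissue = tis,
                fold_change = 2^(-(s$mean2 - s$mean1)),
                t = s$t, p = s$p, signif = s$signif,
                stringsAsFactors = FALSE)
        }
        folds <- do.call(rbind, rows)
        rownames(folds) <- NULL
    }

    ## group summaries for every metric
    sm <- list()
    addSummary <- function(label, values, groups) {
        if (length(unique(groups[is.finite(values)])) != 2L) return()
        s <- summarizeGroups(values, groups, refLevel = "Control")
        sm[[length(sm) + 1L]] <<- cbind(metric = label, s,
                                        stringsAsFactors = FALSE)
    }
    for (an in unique(enr$analyte)) {
        e <- enr[enr$analyte == an, ]
        addSummary(paste0("FNS ", an, " (%)"), 100 * e$fns, e$group)
    }
    addSummary("precursor enrichment",
               enr$precursor[enr$analyte == enr$analyte[1L]],
               enr$group[enr$analyte == enr$analyte[1L]])
    if (!is.null(prof)) {
        one <- prof[!duplicated(prof$sample), ]
        for (ix in c("palmitoleate_palmitate", "oleate_stearate",
                     "vaccenate_stearate", "stearate_palmitate"))
            addSummary(paste0("index ", sub("_", "/", ix)), one[[ix]],
                       one$group)
        for (an in unique(prof$analyte)) {
            pa <- prof[prof$analyte == an, ]
            if (all(is.finite(pa$amount_ug_per_mg)))
                addSummary(paste0(an, " (ug/mg)"), pa$amount_ug_per_mg,
                           pa$group)
        }
    }
    if (!is.null(rates))
        for (an in unique(rates$analyte)) {
            r <- rates[rates$analyte == an, ]
            addSummary(paste0("rate ", an, " (ug/mg/day)"),
                       r$rate_ug_per_mg_day, r$group)
        }
    summary <- do.call(rbind, sm)
    rownames(summary) <- NULL
    if (bhAdjust) summary$p_bh <- stats::p.adjust(summary$p, "BH")

    res <- list(enrichment = enr, profile = prof, rates = rates,
                folds = folds, summary = summary)

    if (!is.null(outDir)) {
        dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
        utils::write.csv(enr, file.path(outDir, "enrichment.csv"),
                         row.names = FALSE)
        if (!is.null(prof))
            utils::write.csv(prof, file.path(outDir, "profile.csv"),
                             row.names = FALSE)
        if (!is.null(rates))
            utils::write.csv(rates, file.path(outDir, "rates.csv"),
                             row.names = FALSE)
        if (!is.null(folds))
            utils::write.csv(folds, file.path(outDir, "folds.csv"),
                             row.names = FALSE)
        utils::write.csv(summary, file.path(outDir, "summary.csv"),
                         row.names = FALSE)
        md <- c("# Study report", "",
                sprintf("Samples: %d (%s), tracer: %s", nrow(man),
                        paste(table(man$group), collapse = " + "),
                        man$tracer[1L]), "",
                "## Group summaries", "", .mdTable(summary))
        if (!is.null(folds))
            md <- c(md, "", "## SCD1 expression fold change (FR/Control)",
                    "", .mdTable(folds))
        writeLines(md, file.path(outDir, "report.md"))
    }
    res
}
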