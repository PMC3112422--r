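test_that("profile percent normalizes to palmitate = 100", {
    p <- profilePercent(c(palmitate = 200, oleate = 150))
    expect_equal(unname(p), c(100, 75))
    same <- c(palmitate = 3, stearate = 3, oleate = 3)
    expect_equal(unname(profilePercent(same)), c(100, 100, 100))
    # scale invariance
    a <- c(palmitate = 120, stearate = 40, oleate = 90)
    expect_equal(profilePercent(a * 7.3), profilePercent(a))
    expect_error(profilePercent(c(stearate = 10)), "missing")
    expect_error(profilePercent(c(palmitate = 0, oleate = 2)), "positive")
})

test_that("desaturation indices are the named area ratios", {
    a <- c(palmitate = 100, palmitoleate = 4.1, stearate = 50,
           oleate = 100, vaccenate = 8)
    idx <- desaturationIndices(a)
    expect_equal(idx[["oleate_stearate"]], 2.0)
    expect_equal(idx[["palmitoleate_palmitate"]], 0.041)
    expect_equal(idx[["vaccenate_stearate"]], 0.16)
    expect_equal(idx[["stearate_palmitate"]], 0.5)
    allEq <- c(palmitate = 5, palmitoleate = 5, stearate = 5,
               oleate = 5, vaccenate = 5)
    expect_true(all(desaturationIndices(allEq) == 1))
    # scale invariance
    expect_equal(desaturationIndices(a * 0.01), idx)
    # zero denominator: NA with warning, other ratios intact
    a2 <- a; a2[["stearate"]] <- 0
    # both stearate ratios warn
    expect_warning(expect_warning(desaturationIndices(a2),
                                  "zero denominator"), "zero denominator")
    idx2 <- suppressWarnings(desaturationIndices(a2))
    expect_true(is.na(idx2[["oleate_stearate"]]))
    expect_equal(idx2[["palmitoleate_palmitate"]], 0.041)
})

test_that("generator defaults reproduce the control-group indices", {
    # noiseless areas from the default design carry the configured ratios
    des <- defaultStudyDesign("deuterium", depth = Inf, areaCV = 0)
    st <- simulateStudy(des, seed = 3)
    ar <- studyAreas(st)
    smp <- ar[ar$sample == "Control_01", ]
    idx <- desaturationIndices(setNames(smp$area, smp$analyte))
    expect_equal(idx[["palmitoleate_palmitate"]], 0.041, tolerance = 1e-6)
    expect_equal(idx[["oleate_stearate"]], 3.23, tolerance = 1e-6)
    expect_equal(idx[["vaccenate_stearate"]], 0.29, tolerance = 1e-6)
    expect_equal(idx[["stearate_palmitate"]], 0.27, tolerance = 1e-6)
})

test_that("internal-standard quantification follows the area ratio", {
    q <- quantifyFattyAcids(c(palmitate = 20), isArea = 10,
                            isQuantityUg = 10, tissueMassMg = 30)
    expect_equal(unname(q), 10 * 2 / 30, tolerance = 1e-12)
    expect_equal(unname(quantifyFattyAcids(c(oleate = 0), 10, 10, 30)), 0)
    # per-analyte response factors scale the result
    q2 <- quantifyFattyAcids(c(palmitate = 20), 10, 10, 30,
                             responseFactors = c(palmitate = 1.1))
    expect_equal(unname(q2), unname(q) * 1.1)
    expect_error(quantifyFattyAcids(c(palmitate = 1), 0, 10, 30),
                 "standard area")
    expect_error(quantifyFattyAcids(c(palmitate = 1), 10, 10, 0), "mass")
})

test_that("quantification recovers generator-truth tissue content", {
    set.seed(55)
    des <- defaultStudyDesign("deuterium", depth = Inf, areaCV = 0.05)
    st <- simulateStudy(des, seed = 55)
    ar <- studyAreas(st); man <- studyManifest(st); tru <- studyTruth(st)
    smp <- ar[ar$sample == "FR_03", ]
    a <- setNames(smp$area, smp$analyte)
    m <- man[man$sample == "FR_03", ]
    ug <- quantifyFattyAcids(a[names(a) != "heptadecanoate_d3"],
                             a[["heptadecanoate_d3"]],
                             m$is_quantity_ug, m$tissue_mass_mg)
    want <- tru$amount_true[tru$sample == "FR_03" &
                            tru$analyte == "palmitate"]
    # one replicate at 5% area CV on analyte and IS: within ~3 sigma
    expect_equal(unname(ug[["palmitate"]]), want, tolerance = 0.25)
})

test_that("ddCt fold change is 2^-ddCt with exact antisymmetry", {
    expect_equal(ddCtFoldChange(25, 12, 25, 12), 1.0)
    expect_equal(ddCtFoldChange(25, 12, 25 - 0.7224, 12), 1.65,
                 tolerance = 1e-4)
    expect_equal(ddCtFoldChange(25, 12, 25 + 1.8365, 12), 0.28,
                 tolerance = 1e-4)
    # fold(a -> b) * fold(b -> a) = 1
    expect_equal(ddCtFoldChange(24, 11, 26.3, 12.1) *
                 ddCtFoldChange(26.3, 12.1, 24, 11), 1, tolerance = 1e-12)
    expect_error(ddCtFoldChange(-1, 12, 25, 12), "positive")
})
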