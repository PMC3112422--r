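test_that("molar enrichment is the mean mass shift", {
    expect_equal(molarEnrichment(c(1, 0, 0)), 0)
    expect_equal(molarEnrichment(c(0, 0, 1)), 2)
    # 40% newly made at p = 0.03, N = 21: ME = 0.4 * 21 * 0.03
    f <- 0.4
    mix <- f * dbinom(0:21, 21, 0.03)
    mix[1] <- mix[1] + (1 - f)
    expect_equal(molarEnrichment(mix), 0.4 * 21 * 0.03, tolerance = 1e-12)
})

test_that("water enrichment inverts the binomial m2/m1 ratio", {
    # labeled-only binomial spectrum: r = (N-1)/2 * p/(1-p)
    for (case in list(c(21, 0.03), c(11, 0.05))) {
        N <- case[1]; p <- case[2]
        for (f in c(0.2, 1)) {  # invariant to unlabeled dilution
            mix <- f * dbinom(0:N, N, p)
            mix[1] <- mix[1] + (1 - f)
            est <- waterEnrichmentFromRatio(mix, N)
            expect_equal(est$ratio, (N - 1) / 2 * p / (1 - p),
                         tolerance = 1e-9)
            expect_equal(est$p, p, tolerance = 1e-9)
        }
    }
})

test_that("water enrichment edge cases behave", {
    expect_equal(waterEnrichmentFromRatio(c(0.5, 0.5, 0, 0), 21)$p, 0)
    expect_error(waterEnrichmentFromRatio(c(1, 0, 0), 21), "m1 fraction")
    # implausibly heavy labeling is flagged, not rejected
    heavy <- dbinom(0:11, 11, 0.7)
    est <- waterEnrichmentFromRatio(heavy, 11)
    expect_false(is.na(est$flag))
})

test_that("FNS follows the printed formula and clips noise", {
    mix <- 0.4 * dbinom(0:21, 21, 0.03)
    mix[1] <- mix[1] + 0.6
    r <- fnsDeuterium(mix, p = 0.03, N = 21)
    expect_equal(r$me, 0.252, tolerance = 1e-9)
    expect_equal(r$fns, 0.400, tolerance = 1e-9)
    expect_equal(fnsDeuterium(c(1, 0, 0), 0.03, 21)$fns, 0)
    expect_error(fnsDeuterium(mix, 0, 21), "in \\(0, 1\\)")
    # marginally > 1 from noise: clipped with warning, raw value kept
    hot <- dbinom(0:21, 21, 0.031)
    expect_warning(r2 <- fnsDeuterium(hot, p = 0.03, N = 21), "clipped")
    expect_equal(r2$fns, 1)
    expect_gt(r2$fns_raw, 1)
})

test_that("FNS is strictly increasing in molar enrichment", {
    p <- 0.03; N <- 21
    fs <- seq(0.05, 0.95, by = 0.1)
    fns <- vapply(fs, function(f) {
        mix <- f * dbinom(0:N, N, p); mix[1] <- mix[1] + (1 - f)
        fnsDeuterium(mix, p, N)$fns
    }, numeric(1))
    expect_true(all(diff(fns) > 0))
})

test_that("synthesis rate arithmetic and guards", {
    expect_equal(synthesisRate(1.0, 0.5, 14), 0.0357, tolerance = 1e-3)
    expect_equal(synthesisRate(5, 0, 14), 0)
    # the in-vivo operating point: ~112 ug/mg palmitate, FNS 0.40, 14 d
    expect_equal(synthesisRate(112, 0.40, 14), 3.2, tolerance = 1e-9)
    expect_error(synthesisRate(1, 0.5, 0), "positive")
})

test_that("simulate -> correct -> estimate recovers p and FNS noiselessly", {
    defs <- fattyAcidDefinitions()
    for (p in c(0.01, 0.03, 0.05)) {
        for (N in c(11, 21, 27)) {
            for (f in c(0.05, 0.4, 0.9)) {
                def <- defs[1, ]; def$n_d_sites <- N
                y <- simulateCluster(f, p, def, "deuterium", depth = Inf,
                                     K = N)
                mid <- correctMID(y, def$formula)
                est <- waterEnrichmentFromRatio(mid, N)
                expect_equal(est$p, p, tolerance = 1e-6)
                expect_equal(fnsDeuterium(mid, est$p, N)$fns, f,
                             tolerance = 1e-6)
            }
        }
    }
})

test_that("ratio inversion agrees with a grid-search binomial fit", {
    def <- fattyAcidDefinitions()[1, ]
    for (p in c(0.01, 0.05)) {
        for (f in c(0.1, 0.8)) {
            y <- simulateCluster(f, p, def, "deuterium", depth = Inf, K = 21)
            mid <- midFractions(correctMID(y, def$formula))
            fit <- oracleFitDeuterium(mid, 21)
            est <- waterEnrichmentFromRatio(mid, 21)
            expect_equal(est$p, fit$p, tolerance = 1e-6)
            expect_equal(fnsDeuterium(mid, est$p, 21)$fns, fit$f,
                         tolerance = 1e-6)
        }
    }
})

test_that("noisy FNS estimates are accurate at realistic count depth", {
    set.seed(101)
    def <- fattyAcidDefinitions()[1, ]
    errs <- replicate(50, {
        y <- simulateCluster(0.4, 0.03, def, "deuterium", depth = 1e6)
        mid <- correctMID(y, def$formula)
        est <- waterEnrichmentFromRatio(mid, 21)
        abs(fnsDeuterium(mid, est$p, 21)$fns - 0.4)
    })
    expect_lt(mean(errs), 0.01)
})
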