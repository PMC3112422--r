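test_that("MID construction enforces validity", {
    expect_s4_class(MID(c(0.7, 0.2, 0.1)), "MassIsotopomerDistribution")
    expect_error(MID(c(0.5, 0.5)), "at least three")
    expect_error(MID(c(0.7, 0.2, 0.2)), "sum to 1")
    expect_error(MID(c(1.1, -0.05, -0.05)), "non-negative")
    expect_equal(midFractions(MID(c(2, 1, 1), normalize = TRUE)),
                 c(0.5, 0.25, 0.25))
})

test_that("formula parsing handles counts, implicit 1s and bad input", {
    expect_equal(parseFormula("C17H34O2"), c(C = 17L, H = 34L, O = 2L))
    expect_equal(parseFormula("CH4"), c(C = 1L, H = 4L))
    expect_error(parseFormula("C17H34O2x"), "cannot parse")
    expect_error(parseFormula(""), "nzchar")
})

test_that("natural MID of a single-isotope element is a delta at m0", {
    tab <- data.frame(element = "X", mass_shift = 0L, abundance = 1)
    f <- midFractions(naturalMID(c(X = 5L), K = 4, table = tab))
    expect_equal(f, c(1, 0, 0, 0, 0))
})

test_that("natural MID matches hand expansion for two carbons", {
    f <- midFractions(naturalMID(c(C = 2L), K = 2))
    # (0.9893 + 0.0107 x)^2: m1/m0 = 2 * 0.0107/0.9893
    expect_equal(f[2] / f[1], 2 * 0.0107 / 0.9893, tolerance = 1e-12)
    expect_equal(f[3] / f[1], (0.0107 / 0.9893)^2, tolerance = 1e-12)
})

test_that("natural MID matches the enumeration oracle for FAME fragments", {
    for (frag in list(c(17, 34, 2), c(19, 38, 2), c(18, 32, 1))) {
        comp <- c(C = frag[1], H = frag[2], O = frag[3])
        got <- midFractions(naturalMID(comp, K = 6))
        want <- oracleNaturalMID(frag[1], frag[2], frag[3], K = 6)
        expect_equal(got, want, tolerance = 1e-12)
    }
})

test_that("convolution has a delta identity and adds shifts", {
    X <- MID(c(0.5, 0.3, 0.15, 0.05))
    d0 <- MID(c(1, 0, 0, 0))
    expect_equal(midFractions(convolveMID(d0, X)), midFractions(X))
    d1 <- c(0, 1, 0, 0, 0, 0); d2 <- c(0, 0, 1, 0, 0, 0)
    expect_equal(which.max(midFractions(convolveMID(d1, d2))), 4L)  # m3
})

test_that("convolution of natural MIDs composes like atom counts", {
    # C2 (x) C3 = C5 as polynomial multiplication would give
    K <- 6
    c2 <- naturalMID(c(C = 2L), K)
    c3 <- naturalMID(c(C = 3L), K)
    c5 <- naturalMID(c(C = 5L), K)
    expect_equal(midFractions(convolveMID(c2, c3, K)), midFractions(c5),
                 tolerance = 1e-12)
})

test_that("convolution is commutative and associative", {
    set.seed(42)
    for (rep in 1:20) {
        a <- randomMID(6); b <- randomMID(6); c <- randomMID(6)
        ab <- convolveMID(a, b, 12)
        expect_equal(midFractions(ab), midFractions(convolveMID(b, a, 12)),
                     tolerance = 1e-12)
        expect_equal(
            midFractions(convolveMID(ab, c, 12)),
            midFractions(convolveMID(a, convolveMID(b, c, 12), 12)),
            tolerance = 1e-12)
    }
})

test_that("correction matrix is lower triangular with natural MID columns", {
    K <- 5
    M <- correctionMatrix("C17H34O2", K)
    nat <- midFractions(naturalMID("C17H34O2", K))
    expect_equal(M[, 1], nat)
    expect_true(all(M[upper.tri(M)] == 0))
    # column 3 = natural MID shifted by 2
    expect_equal(M[, 3], c(0, 0, nat[1:(K - 1)]))
    # M %*% delta(m2) reproduces the shifted natural spectrum
    d2 <- c(0, 0, 1, 0, 0, 0)
    expect_equal(as.numeric(M %*% d2), c(0, 0, nat[1:(K - 1)]))
})

test_that("correction matrix is the identity under a single-isotope table", {
    tab <- data.frame(element = c("C", "H", "O"), mass_shift = 0L,
                      abundance = 1)
    M <- correctionMatrix("C17H34O2", 4, table = tab)
    expect_equal(M, diag(5))
})

test_that("correcting an unlabeled spectrum returns a delta at m0", {
    nat <- midFractions(naturalMID("C19H38O2", K = 6))
    out <- midFractions(correctMID(nat * 3.7e5, "C19H38O2"))
    expect_equal(out, c(1, rep(0, 6)), tolerance = 1e-9)
})

test_that("correction round-trips arbitrary tracer MIDs exactly", {
    set.seed(7)
    for (comp in c("C17H34O2", "C19H38O2", "C18H32O")) {
        for (rep in 1:10) {
            K <- sample(4:10, 1)
            X <- randomMID(K)
            nat <- naturalMID(comp, K)
            obs <- midFractions(convolveMID(nat, X, K))
            back <- midFractions(correctMID(obs * 1e6, comp))
            expect_lt(max(abs(back - midFractions(X))), 1e-9)
        }
    }
})

test_that("correction rejects degenerate input", {
    expect_error(correctMID(c(0, 0, 0, 0), "C17H34O2"), "positive")
    expect_error(correctMID(c(-1, 2, 1), "C17H34O2"), "non-negative")
    expect_error(correctMID(c(5, 3), "C17H34O2"), "at least three")
    expect_error(naturalMID(c(Zz = 2L), 4), "not in the isotope table")
})

test_that("every returned MID is a valid distribution", {
    set.seed(11)
    for (rep in 1:25) {
        K <- sample(3:9, 1)
        X <- randomMID(K)
        nat <- naturalMID("C17H34O2", K)
        for (m in list(nat, convolveMID(nat, X, K),
                       correctMID(midFractions(convolveMID(nat, X, K)) * 1e5,
                                  "C17H34O2"))) {
            f <- midFractions(m)
            expect_true(all(f >= 0))
            expect_equal(sum(f), 1, tolerance = 1e-9)
        }
    }
})
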