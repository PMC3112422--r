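# Independent oracles used to check the package's estimators.
# These deliberately avoid the package's convolution/inversion code paths:
# the natural-abundance oracle enumerates heavy-isotope placements
# explicitly, and the mixture fits are brute-force grid searches over the
# binomial forward model.

# Natural-abundance MID of a C/H/O fragment by explicit enumeration of
# (n 13C, n 2H, n 17O, n 18O) placements contributing to each mass shift.
oracleNaturalMID <- function(nC, nH, nO, K,
                             aC = 0.0107, aH = 0.000115,
                             aO17 = 0.00038, aO18 = 0.00205) {
    pO <- function(k17, k18) {
        if (k17 + k18 > nO) return(0)
        stats::dmultinom(c(nO - k17 - k18, k17, k18),
                         prob = c(1 - aO17 - aO18, aO17, aO18))
    }
    f <- numeric(K + 1)
    for (s in 0:K) {
        tot <- 0
        for (i in 0:min(s, nC)) {
            for (j in 0:min(s - i, nH)) {
                for (k17 in 0:(s - i - j)) {
                    rem <- s - i - j - k17
                    if (rem %% 2 != 0) next
                    k18 <- rem / 2
                    tot <- tot + stats::dbinom(i, nC, aC) *
                        stats::dbinom(j, nH, aH) * pO(k17, k18)
                }
            }
        }
        f[s + 1] <- tot
    }
    f / sum(f)
}

# Brute-force fit of the deuterium mixture model: coarse grid over p with
# the labeled fraction profiled by least squares on shifts >= 1, refined
# by golden-section optimisation. Returns list(p, f).
oracleFitDeuterium <- function(fractions, N) {
    x <- fractions[-1]
    sse <- function(p) {
        b <- stats::dbinom(seq_along(x), N, p)
        fhat <- sum(b * x) / sum(b * b)
        sum((x - fhat * b)^2)
    }
    grid <- seq(1e-4, 0.4999, length.out = 2000)
    vals <- vapply(grid, sse, numeric(1))
    i <- which.min(vals)
    lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
    p <- stats::optimize(sse, c(lo, hi), tol = 1e-12)$minimum
    b <- stats::dbinom(seq_along(x), N, p)
    f <- sum(b * x) / sum(b * b)
    list(p = p, f = f)
}

# Same idea for the 13C MIDA model: grid over acetyl M+2 enrichment g,
# labeled fraction profiled on the even shifts >= 2.
oracleFitMIDA <- function(fractions, nUnits) {
    K <- length(fractions) - 1
    units <- seq_len(min(nUnits, K %/% 2))
    x <- fractions[2 * units + 1]
    sse <- function(g) {
        b <- stats::dbinom(units, nUnits, g)
        fhat <- sum(b * x) / sum(b * b)
        sum((x - fhat * b)^2)
    }
    grid <- seq(1e-4, 0.9, length.out = 2000)
    vals <- vapply(grid, sse, numeric(1))
    i <- which.min(vals)
    lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
    g <- stats::optimize(sse, c(lo, hi), tol = 1e-12)$minimum
    b <- stats::dbinom(units, nUnits, g)
    f <- sum(b * x) / sum(b * b)
    list(g = g, f = f)
}

# Random valid MID for property tests.
randomMID <- function(K) {
    f <- stats::rexp(K + 1)
    MID(f / sum(f))
}
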