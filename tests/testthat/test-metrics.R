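test_that("Dice score matches its closed form", {
    a <- matrix(0, 20, 20); a[3:12, 3:12] <- 1
    expect_equal(diceScore(a, a), 100)
    b <- matrix(0, 20, 20); b[15:18, 15:18] <- 1
    expect_equal(diceScore(a, b), 0)
    ## two 10x10 squares overlapping in a 5x10 strip
    c1 <- matrix(0, 30, 30); c1[1:10, 1:10] <- 1
    c2 <- matrix(0, 30, 30); c2[6:15, 1:10] <- 1
    expect_equal(diceScore(c1, c2), 50)
    expect_equal(diceScore(c2, c1), 50)                  # symmetry
    expect_equal(diceScore(matrix(0, 5, 5), matrix(0, 5, 5)), 100)
    expect_error(diceScore(a, matrix(0, 5, 5)), "shape")
    ## translation invariance
    d1 <- matrix(0, 30, 30); d1[4:9, 4:9] <- 1
    d2 <- matrix(0, 30, 30); d2[6:11, 8:13] <- 1
    s1 <- matrix(0, 30, 30); s1[14:19, 14:19] <- 1
    s2 <- matrix(0, 30, 30); s2[16:21, 18:23] <- 1
    expect_equal(diceScore(d1, d2), diceScore(s1, s2))
})

test_that("Hausdorff distance equals the brute-force oracle", {
    a <- matrix(0, 20, 20); a[5:10, 5:10] <- 1
    expect_equal(hausdorffDistance(a, a), 0)
    p1 <- matrix(0, 16, 16); p1[1, 1] <- 1
    p2 <- matrix(0, 16, 16); p2[4, 5] <- 1        # offset (3, 4)
    expect_equal(hausdorffDistance(p1, p2), 5)
    expect_equal(hausdorffDistance(p2, p1), 5)    # symmetry
    ## square vs Chebyshev-dilated square
    sq <- matrix(0, 30, 30); sq[10:19, 10:19] <- 1
    dil <- matrix(0, 30, 30); dil[7:22, 7:22] <- 1
    expect_equal(hausdorffDistance(sq, dil), bruteHausdorff(sq, dil))
    ## random masks
    set.seed(19)
    for (i in 1:10) {
        m1 <- matrix(rbinom(400, 1, 0.15), 20, 20)
        m2 <- matrix(rbinom(400, 1, 0.15), 20, 20)
        if (sum(m1) == 0 || sum(m2) == 0) next
        expect_equal(hausdorffDistance(m1, m2), bruteHausdorff(m1, m2))
    }
    expect_error(hausdorffDistance(sq, matrix(0, 30, 30)), "empty")
})

test_that("diameters recover disc and ellipse extents", {
    dm <- discMask(81, c(40, 40), 30)
    d <- diametersOfMask(dm, spacing = 1)
    expect_lt(abs(d@a - 60), 1)
    expect_lt(abs(d@b - 60), 1)
    ## axis-aligned ellipse, semi-axes 40 and 20
    yy <- matrix(0:99, 100, 100); xx <- t(yy)
    el <- 1 * ((xx - 50)^2 / 40^2 + (yy - 50)^2 / 20^2 <= 1)
    de <- diametersOfMask(el, spacing = 1)
    expect_lt(abs(de@a - 80), 1)
    expect_lt(abs(de@b - 40), 1)
    ## brute-force check of a over all boundary pixel pairs
    fg <- which(el == 1, arr.ind = TRUE)
    hull <- fg[grDevices::chull(fg[, 2], fg[, 1]), ]
    expect_equal(de@a, max(stats::dist(hull[, 2:1])))
    ## mm conversion
    expect_equal(diametersOfMask(el, spacing = 0.5)@a, de@a * 0.5)
})

test_that("diameter a is invariant under 90-degree rotation", {
    set.seed(4)
    m <- discMask(61, c(30, 26), 14)
    m[20:26, 40:52] <- 1
    d1 <- diametersOfMask(m, spacing = 1)
    d2 <- diametersOfMask(t(m)[ncol(m):1, ], spacing = 1)  # rotate 90
    expect_equal(d1@a, d2@a)
})

test_that("single-pixel mask has one-pixel extent and perpendicular segments", {
    m <- matrix(0, 16, 16); m[8, 8] <- 1
    d <- diametersOfMask(m, spacing = 0.3)
    expect_equal(d@a, 0.3)
    expect_equal(d@b, 0.3)
    dm <- diametersOfMask(discMask(81, c(40, 40), 25), spacing = 1)
    va <- dm@endpointsA[2, ] - dm@endpointsA[1, ]
    vb <- dm@endpointsB[2, ] - dm@endpointsB[1, ]
    expect_lt(abs(sum(va * vb)) / sqrt(sum(va^2) * sum(vb^2)), 1e-6)
    expect_error(diametersOfMask(matrix(0, 16, 16)), "empty")
})

test_that("ICC is 1 for perfect agreement and ~0 for pure offset", {
    x <- c(80, 85, 90, 95, 70)
    expect_equal(iccAbsoluteAgreement(x, x), 1)
    ## large constant offset, tiny case variance: absolute agreement ~ 0
    y <- c(50, 50.1, 49.9, 50.05, 49.95)
    expect_lt(abs(iccAbsoluteAgreement(y, y + 40)), 0.05)
    ## zero rater variance, positive case variance: analytic limit 1
    expect_equal(iccAbsoluteAgreement(c(1, 2, 3, 4), c(1, 2, 3, 4)), 1)
    expect_error(iccAbsoluteAgreement(1:4, 1:5), "equal length")
    ## hand-evaluated closed form on a constructed 5-case table
    r1 <- c(84, 70, 91, 60, 77); r2 <- c(80, 75, 88, 66, 79)
    n <- 5; k <- 2; xm <- cbind(r1, r2); grand <- mean(xm)
    MSR <- k * sum((rowMeans(xm) - grand)^2) / (n - 1)
    MSC <- n * sum((colMeans(xm) - grand)^2) / (k - 1)
    MSE <- (sum((xm - grand)^2) - (n - 1) * MSR / k * k -
            (k - 1) * MSC / n * n) / ((n - 1) * (k - 1))
    want <- (MSR - MSE) / (MSR + (k - 1) * MSE + k / n * (MSC - MSE))
    expect_equal(iccAbsoluteAgreement(r1, r2), want)
})

test_that("bootstrap median CI is deterministic and contains the median", {
    ci <- bootstrapMedianCI(rep(5, 20), nBoot = 200, seed = 3)
    expect_equal(unname(ci), c(5, 5, 5))
    ci2 <- bootstrapMedianCI(1:101, nBoot = 500, seed = 7)
    expect_equal(ci2[["median"]], 51)
    expect_lte(ci2[["lo"]], 51)
    expect_gte(ci2[["hi"]], 51)
    expect_identical(bootstrapMedianCI(1:101, nBoot = 500, seed = 7), ci2)
    expect_false(identical(
        bootstrapMedianCI(1:101, nBoot = 500, seed = 8)[["lo"]],
        NULL))
})
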