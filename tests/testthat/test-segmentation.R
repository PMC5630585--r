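test_that("noiseless disc phantom segments with high Dice", {
    img <- discImage(101, radius = 30)
    truth <- discMask(101, c(50, 50), 30)
    res <- segmentLesion(img, c(50, 50))
    expect_gt(diceScore(lesionMask(res), truth) / 100, 0.95)
    ## off-center seed: star-shape tolerance
    res2 <- segmentLesion(img, c(55, 50))
    expect_gt(diceScore(lesionMask(res2), truth) / 100, 0.90)
})

test_that("dragging the seed across the lesion keeps Dice high", {
    img <- discImage(101, radius = 30)
    truth <- discMask(101, c(50, 50), 30)
    for (dx in c(-8, 0, 8)) for (dy in c(-8, 0, 8)) {
        res <- segmentLesion(img, c(50 + dx, 50 + dy),
                             params = graphParams(nRays = 30, nNodes = 30))
        expect_gt(diceScore(lesionMask(res), truth) / 100, 0.9)
    }
})

test_that("uniform image degenerates to a constant-radius contour", {
    ## no gradient anywhere: all capacities are zero, the tie-break picks a
    ## single feasible radius for every ray; documented degenerate output
    img <- ultrasoundImage(matrix(77, 64, 64))
    res <- segmentLesion(img, c(32, 32),
                         params = graphParams(nRays = 16, nNodes = 10))
    r <- sqrt(rowSums(sweep(contourPolygon(res), 2, c(32, 32))^2))
    expect_lt(diff(range(r)), 1e-9)
    expect_identical(length(unique(cutIndices(res))), 1L)
})

test_that("a helper seed pins its ray exactly", {
    img <- randomNoiseImage(101, seed = 31)
    p <- graphParams(nRays = 12, nNodes = 20, maxRadius = 40)
    g <- buildRadialGraph(img, c(50, 50), p)
    ## helper straight up at radius 30 -> ray 0, node index 15 (1-based)
    g2 <- applyHelperConstraints(g, list(c(50, 20)))
    expect_identical(g2@pins[1], 15L)
    expect_identical(cutIndices(solveMinCut(g2))[1], 14L)
    ## helper beyond maxRadius errors
    expect_error(applyHelperConstraints(g, list(c(50, 5))), "maxRadius")
    ## two helpers on the same ray: last wins with a warning
    expect_warning(
        g3 <- applyHelperConstraints(g, list(c(50, 20), c(50, 30))),
        "last one wins")
    expect_identical(g3@pins[1], 10L)
})

test_that("helper with deltaR = 0 pins the entire contour radius", {
    img <- randomNoiseImage(101, seed = 13)
    p <- graphParams(nRays = 10, nNodes = 20, maxRadius = 40, deltaR = 0)
    g <- applyHelperConstraints(buildRadialGraph(img, c(50, 50), p),
                                list(c(50, 20))) # index 15
    ci <- cutIndices(solveMinCut(g))
    expect_true(all(ci == 14L))
})

test_that("helper on the boundary never hurts a noisy disc by much", {
    set.seed(55)
    for (i in 1:5) {
        px <- pmax(pmin(discImage(101, radius = 28)@pixels +
                        matrix(round(rnorm(101 * 101, 0, 12)), 101, 101),
                        255), 0)
        img <- ultrasoundImage(px)
        truth <- discMask(101, c(50, 50), 28)
        p <- graphParams(nRays = 24, nNodes = 24, maxRadius = 42)
        before <- diceScore(lesionMask(segmentLesion(img, c(50, 50),
                                                     params = p)), truth)
        after <- diceScore(lesionMask(segmentLesion(img, c(50, 50),
            helpers = list(c(50, 50 - 28)), params = p)), truth)
        expect_gte(after, before - 1)
    }
})

test_that("resegment is referentially transparent", {
    img <- discImage(101, radius = 25)
    res <- segmentLesion(img, c(50, 50),
                         params = graphParams(nRays = 16, nNodes = 16))
    same <- resegment(res)
    expect_identical(cutIndices(same), cutIndices(res))
    expect_identical(contourPolygon(same), contourPolygon(res))
    ## moving the seed and adding a helper equals a fresh call
    moved <- resegment(res, newSeed = c(48, 52),
                       addHelpers = list(c(50, 25)))
    fresh <- segmentLesion(img, c(48, 52), helpers = list(c(50, 25)),
                           params = res@params)
    expect_identical(cutIndices(moved), cutIndices(fresh))
    expect_identical(pixelMatrix(lesionMask(moved)),
                     pixelMatrix(lesionMask(fresh)))
})

test_that("polygon rasterization follows the pixel-center even-odd rule", {
    sq <- cbind(c(10, 10, 20, 20), c(10, 20, 20, 10))
    m <- rasterizeContour(sq, c(32, 32))
    expect_equal(sum(pixelMatrix(m)), 100)      # a 10 x 10 block of centers
    expect_true(all(pixelMatrix(m)[11:20, 11:20] == 1))
    ## regular 60-gon of radius 30: area within 2% of pi r^2
    th <- 2 * pi * (0:59) / 60
    poly <- cbind(40 + 30 * cos(th), 40 + 30 * sin(th))
    a <- sum(pixelMatrix(rasterizeContour(poly, c(81, 81))))
    expect_lt(abs(a - pi * 900) / (pi * 900), 0.02)
    ## polygon fully outside the image: empty mask
    tri <- cbind(c(-30, -20, -25), c(-30, -30, -20))
    expect_equal(sum(pixelMatrix(rasterizeContour(tri, c(32, 32)))), 0)
    expect_error(rasterizeContour(cbind(1:2, 1:2), c(32, 32)), "degenerate")
})

test_that("mask and contour are mutually consistent and star-shaped", {
    img <- discImage(101, radius = 30)
    res <- segmentLesion(img, c(52, 49))
    ctr <- contourPolygon(res)
    redone <- rasterizeContour(ctr, dim(pixelMatrix(img)))
    expect_equal(diceScore(lesionMask(res), redone), 100)
    ## star shape: sampled points on every seed-to-vertex segment stay inside
    seed <- res@seed
    for (k in seq(1, nrow(ctr), by = 7)) {
        tt <- seq(0.02, 0.98, length.out = 15)
        xs <- seed[1] + tt * (ctr[k, 1] - seed[1])
        ys <- seed[2] + tt * (ctr[k, 2] - seed[2])
        expect_true(all(starcut:::.pointInPolygon(xs, ys,
                                                  ctr[, 1], ctr[, 2])))
    }
})

test_that("seeds outside the image are rejected", {
    img <- discImage(64, radius = 15)
    expect_error(segmentLesion(img, c(-1, 10)), "outside")
    expect_error(segmentLesion(img, c(10, 100)), "outside")
})
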