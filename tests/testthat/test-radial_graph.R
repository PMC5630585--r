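test_that("ray sampling follows the clockwise-from-up convention", {
    img <- ultrasoundImage(matrix(42, 101, 101))
    g <- sampleRays(img, c(50, 50),
                    graphParams(nRays = 4, nNodes = 2, maxRadius = 10,
                                avgWindow = 1))
    ## ray 0 up, ray 1 right, ray 2 down, ray 3 left; radii 5 and 10
    expect_equal(g@nodeX, matrix(c(50, 50, 55, 60, 50, 50, 45, 40),
                                 4, 2, byrow = TRUE))
    expect_equal(g@nodeY, matrix(c(45, 40, 50, 50, 55, 60, 50, 50),
                                 4, 2, byrow = TRUE))
    expect_true(all(g@grays == 42))
})

test_that("gray sampling is bilinear with border clamping", {
    px <- matrix(10, 16, 16)
    px[, 12:16] <- 20          # columns x >= 11 are 20
    expect_equal(starcut:::.bilinear(px, 10.5, 5), 15)
    expect_equal(starcut:::.bilinear(px, 10.25, 5), 12.5)
    ## outside positions clamp to the border pixel
    expect_equal(starcut:::.bilinear(px, -3, 5), 10)
    expect_equal(starcut:::.bilinear(px, 40, 5), 20)
})

test_that("seed-average gray handles windows and border clipping", {
    expect_equal(averageSeedGray(ultrasoundImage(matrix(30, 32, 32)),
                                 c(16, 16), 7), 30)
    px <- matrix(0, 16, 16)
    px[8:10, 8:10] <- matrix(0:8, 3, 3, byrow = TRUE)   # values 0..8
    img <- ultrasoundImage(px)
    expect_equal(averageSeedGray(img, c(8, 8), 3), 4)
    ## corner seed, 5x5 window clips to the in-bounds 3x3 region
    set.seed(2)
    px2 <- matrix(sample(0:255, 256, replace = TRUE), 16, 16)
    img2 <- ultrasoundImage(px2)
    expect_equal(averageSeedGray(img2, c(0, 0), 5), mean(px2[1:3, 1:3]))
})

test_that("terminal weights implement the sign-based binding rule", {
    ## constant ray at m: all capacities zero, ends bound source/sink
    tw <- terminalWeights(c(20, 20, 20, 20), m = 20)
    expect_identical(tw$side[1, ], c(0L, 1L, 1L, 1L))
    expect_true(all(tw$cap == 0))
    ## step profile
    tw <- terminalWeights(c(20, 20, 120, 120), m = 20)
    expect_identical(tw$side[1, ], c(0L, 1L, 1L, 1L))
    expect_equal(tw$cap[1, ], c(0, 0, 100, 100))
    ## decreasing profile toward m = 0: interior negative difference -> source
    tw <- terminalWeights(c(10, 5, 0), m = 0)
    expect_identical(tw$side[1, ], c(0L, 0L, 1L))
    expect_equal(tw$cap[1, ], c(10, 5, 0))
})

test_that("graph edge counts match the construction", {
    img <- randomNoiseImage(64, seed = 8)
    K <- 6; N <- 7
    g <- buildRadialGraph(img, c(30, 30),
                          graphParams(nRays = K, nNodes = N, maxRadius = 20))
    ge <- starcut:::.graphEdges(g)
    caps <- ge$caps
    expect_equal(nrow(ge$edges), K * (N - 1) + 2 * K * N + K * N)
    expect_equal(sum(caps == ge$INF), K * (N - 1) + 2 * K * N)
    expect_equal(sum(caps < ge$INF), K * N)
})

test_that("deltaR = 0 collapses the cut to a single radius", {
    for (s in 1:3) {
        img <- randomNoiseImage(64, seed = s)
        g <- buildRadialGraph(img, c(31, 33),
                              graphParams(nRays = 5, nNodes = 8,
                                          maxRadius = 24, deltaR = 0))
        ci <- cutIndices(solveMinCut(g))
        expect_identical(length(unique(ci)), 1L)
    }
})

test_that("every returned cut satisfies the circular smoothness constraint", {
    set.seed(40)
    for (i in 1:25) {
        dr <- sample(0:3, 1)
        img <- randomNoiseImage(48, seed = 100 + i)
        g <- buildRadialGraph(img, c(23, 24),
                              graphParams(nRays = sample(4:10, 1),
                                          nNodes = sample(5:12, 1),
                                          maxRadius = 20, deltaR = dr))
        expect_true(cutFeasible(solveMinCut(g), dr))
    }
})

test_that("solver flow matches the DP oracle on random instances", {
    set.seed(17)
    for (i in 1:40) {
        g <- randomGraphInstance(sample(3:8, 1), sample(3:12, 1),
                                 sample(0:3, 1))
        expect_identical(flowValue(solveMinCut(g)), flowValue(oracleMinCut(g)))
    }
})

test_that("oracle handles the unconstrained and single-ray limits", {
    ## single ray: exhaustive minimum over cut positions
    side <- matrix(c(0L, 1L, 0L, 1L, 1L), 1, 5)
    cap <- matrix(c(4, 7, 2, 1, 9), 1, 5)
    g1 <- newRadialGraph(side, cap, deltaR = 2)
    cost <- vapply(1:5, function(c)
        sum(cap[side == 1L & col(cap) <= c]) +
        sum(cap[side == 0L & col(cap) > c]), numeric(1))
    o <- oracleMinCut(g1)
    expect_equal(flowValue(o), min(cost))
    ## deltaR >= N: constraint vacuous, per-ray independent argmin
    set.seed(9)
    g <- randomGraphInstance(4, 6, deltaR = 6)
    perRay <- vapply(1:4, function(k) {
        cst <- vapply(1:6, function(c)
            sum(g@termCap[k, g@termSide[k, ] == 1L & 1:6 <= c]) +
            sum(g@termCap[k, g@termSide[k, ] == 0L & 1:6 > c]), numeric(1))
        min(cst)
    }, numeric(1))
    expect_equal(flowValue(oracleMinCut(g)), sum(perRay))
    expect_equal(flowValue(solveMinCut(g)), sum(perRay))
})

test_that("optimal flow is monotone non-increasing in deltaR", {
    set.seed(23)
    for (i in 1:10) {
        side <- matrix(sample(0:1, 5 * 8, replace = TRUE), 5, 8)
        side[, 1] <- 0L; side[, 8] <- 1L
        cap <- matrix(sample(0:50, 5 * 8, replace = TRUE), 5, 8)
        flows <- vapply(0:3, function(dr)
            flowValue(solveMinCut(newRadialGraph(side, cap, dr))),
            numeric(1))
        expect_true(all(diff(flows) <= 1e-9))
    }
})

test_that("the cut is deterministic for identical inputs", {
    img <- randomNoiseImage(64, seed = 77)
    p <- graphParams(nRays = 16, nNodes = 12, maxRadius = 25)
    g <- buildRadialGraph(img, c(32, 30), p)
    c1 <- solveMinCut(g); c2 <- solveMinCut(g)
    expect_identical(cutIndices(c1), cutIndices(c2))
    expect_identical(flowValue(c1), flowValue(c2))
})

test_that("noiseless disc: cut radius within one node spacing of the edge", {
    r <- 30
    img <- discImage(101, radius = r)
    p <- graphParams(nRays = 24, nNodes = 40, maxRadius = 45)
    g <- buildRadialGraph(img, c(50, 50), p)
    cut <- solveMinCut(g)
    radii <- (cutIndices(cut) + 1) * 45 / 40
    spacing <- 45 / 40
    ## one node spacing, plus the sqrt(2)/2-px half-width of the bilinear
    ## sampling support (a node is exactly lesion-gray only when its whole
    ## 2x2 pixel neighborhood is inside the disc)
    expect_true(all(abs(radii - r) <= spacing + sqrt(2)))
})

test_that("graph edge dump writes one line per edge", {
    g <- randomGraphInstance(3, 4, 1)
    f <- tempfile(fileext = ".txt")
    dumpGraphEdges(g, f)
    df <- read.csv(f, header = FALSE)
    expect_identical(nrow(df), 3L * 3L + 2L * 12L + 12L)
})
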