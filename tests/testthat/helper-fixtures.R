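## fixture builders shared across the test files; everything is generated
## in code at test time

## hypoechoic disc on a bright background, seed-friendly
discImage <- function(size = 101, center = c((size - 1) / 2, (size - 1) / 2),
                      radius = 30, inside = 20, outside = 120) {
    yy <- matrix(0:(size - 1), size, size)
    xx <- t(yy)
    px <- matrix(outside, size, size)
    px[(xx - center[1])^2 + (yy - center[2])^2 <= radius^2] <- inside
    ultrasoundImage(px)
}

## analytic disc mask (pixel centers at integer coordinates)
discMask <- function(size, center, radius) {
    yy <- matrix(0:(size - 1), size, size)
    xx <- t(yy)
    m <- matrix(0, size, size)
    m[(xx - center[1])^2 + (yy - center[2])^2 <= radius^2] <- 1
    m
}

randomNoiseImage <- function(size = 64, seed = 1, maxGray = 255) {
    set.seed(seed)
    ultrasoundImage(matrix(sample(0:maxGray, size * size, replace = TRUE),
                           size, size))
}

## O(n^2) brute-force symmetric Hausdorff distance oracle
bruteHausdorff <- function(a, b) {
    fa <- which(a == 1, arr.ind = TRUE)
    fb <- which(b == 1, arr.ind = TRUE)
    d2 <- outer(fa[, 1], fb[, 1], "-")^2 + outer(fa[, 2], fb[, 2], "-")^2
    sqrt(max(apply(d2, 1, min), apply(d2, 2, min)))
}

## circular smoothness predicate for a cut
cutFeasible <- function(cut, deltaR) {
    ci <- cutIndices(cut)
    all(abs(diff(c(ci, ci[1]))) <= deltaR)
}

## random radial graph with integer capacities (first node source-bound,
## last sink-bound, interior random), for solver/oracle cross-checks
randomGraphInstance <- function(K, N, deltaR, capMax = 50) {
    side <- matrix(sample(0:1, K * N, replace = TRUE), K, N)
    side[, 1] <- 0L
    side[, N] <- 1L
    storage.mode(side) <- "integer"
    cap <- matrix(sample(0:capMax, K * N, replace = TRUE), K, N)
    newRadialGraph(side, cap, deltaR)
}

## ---------------------------------------------------------------------------
## minimal explicit-VR little-endian DICOM writer (test fixture only)
## ---------------------------------------------------------------------------

.raw16 <- function(x) as.raw(c(x %% 256, x %/% 256))
.raw32 <- function(x) as.raw(c(x %% 256, (x %/% 256) %% 256,
                               (x %/% 65536) %% 256,
                               (x %/% 16777216) %% 256))

.dcmElem <- function(group, elem, vr, value) {
    if (length(value) %% 2 == 1)
        value <- c(value, as.raw(if (vr %in% c("UI", "OB")) 0L else 0x20))
    hdr <- c(.raw16(group), .raw16(elem), charToRaw(vr))
    if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN"))
        c(hdr, as.raw(c(0, 0)), .raw32(length(value)), value)
    else c(hdr, .raw16(length(value)), value)
}

writeMiniDicom <- function(path, pixels, spacing = c(0.2, 0.2), bits = 8,
                           nFrames = NULL) {
    stopifnot(bits %in% c(8, 16))
    body <- c(
        .dcmElem(0x0002, 0x0010, "UI", charToRaw("1.2.840.10008.1.2.1")),
        .dcmElem(0x0028, 0x0010, "US", .raw16(nrow(pixels))),
        .dcmElem(0x0028, 0x0011, "US", .raw16(ncol(pixels))),
        .dcmElem(0x0028, 0x0030, "DS",
                 charToRaw(paste(format(spacing), collapse = "\\"))),
        .dcmElem(0x0028, 0x0100, "US", .raw16(bits)))
    if (!is.null(nFrames))
        body <- c(body, .dcmElem(0x0028, 0x0008, "IS",
                                 charToRaw(as.character(nFrames))))
    vals <- as.integer(t(pixels))               # row-major
    pd <- if (bits == 8) as.raw(vals) else
        as.raw(as.vector(rbind(vals %% 256L, vals %/% 256L)))
    body <- c(body, .dcmElem(0x7FE0, 0x0010, if (bits == 8) "OB" else "OW",
                             pd))
    writeBin(c(raw(128), charToRaw("DICM"), body), path)
    invisible(path)
}
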