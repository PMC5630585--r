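## agreement and size measures: DSC, Hausdorff, diameters, ICC, bootstrap CI

.maskPixels <- function(m) if (is(m, "BinaryMask")) m@pixels else m

#' Dice similarity score
#'
#' \code{100 * 2 |A & B| / (|A| + |B|)} in percent; 100 when both masks are
#' empty (perfect agreement on the empty segmentation).
#'
#' @param maskA,maskB \linkS4class{BinaryMask} objects (or plain 0/1
#'   matrices) of identical shape
#' @return the Dice score in percent, in [0, 100]
#' @examples
#' a <- matrix(0, 16, 16); a[4:13, 4:8] <- 1
#' b <- matrix(0, 16, 16); b[4:13, 4:13] <- 1
#' diceScore(a, b)
#' @export
diceScore <- function(maskA, maskB) {
    a <- .maskPixels(maskA); b <- .maskPixels(maskB)
    if (!identical(dim(a), dim(b)))
        stop("masks must have identical shape")
    sa <- sum(a); sb <- sum(b)
    if (sa + sb == 0) return(100)
    100 * 2 * sum(a * b) / (sa + sb)
}

#' Symmetric Hausdorff distance between two masks
#'
#' The greatest of all Euclidean distances from a foreground pixel center in
#' one mask to the closest foreground pixel center in the other,
#' symmetrized: \code{max(h(A, B), h(B, A))}.  Computed over all foreground
#' pixels (not only boundary pixels), which gives the identical value for
#' the symmetric distance, via exact Euclidean distance transforms.
#'
#' @param maskA,maskB nonempty \linkS4class{BinaryMask} objects (or 0/1
#'   matrices) of identical shape
#' @return the Hausdorff distance in pixels
#' @export
hausdorffDistance <- function(maskA, maskB) {
    a <- .maskPixels(maskA); b <- .maskPixels(maskB)
    if (!identical(dim(a), dim(b)))
        stop("masks must have identical shape")
    if (sum(a) == 0 || sum(b) == 0)
        stop("Hausdorff distance is undefined for an empty mask")
    dToB <- EBImage::distmap(1 - b)   # distance to nearest foreground of B
    dToA <- EBImage::distmap(1 - a)
    max(max(dToB[a == 1]), max(dToA[b == 1]))
}

#' Perpendicular diameters of a mask
#'
#' The largest diameter \code{a} is the maximal Euclidean distance between
#' two foreground pixel centers (computed on the convex hull).  Diameter
#' \code{b} is the maximal foreground chord measured along the direction
#' perpendicular to \code{a} (the longest extent of the foreground within
#' any 1-px-wide band parallel to that perpendicular axis), mirroring a
#' caliper measurement at 90 degrees.  With
#' \code{projection = TRUE}, \code{b} is instead the width of the projection
#' of the whole foreground onto the perpendicular axis.  A single-pixel mask
#' is defined to have \code{a = b = spacing} (one pixel extent).
#'
#' @param mask a nonempty \linkS4class{BinaryMask} (or 0/1 matrix)
#' @param spacing mm per pixel; defaults to the mask's own spacing
#' @param projection measure \code{b} as projection width instead of the
#'   maximal perpendicular chord
#' @return a \linkS4class{DiameterPair} (diameters in mm)
#' @export
diametersOfMask <- function(mask, spacing = NULL, projection = FALSE) {
    p <- .maskPixels(mask)
    if (is.null(spacing))
        spacing <- if (is(mask, "BinaryMask")) mask@spacing else 1
    fg <- which(p == 1, arr.ind = TRUE)
    if (nrow(fg) == 0) stop("diameters are undefined for an empty mask")
    pts <- cbind(x = fg[, 2] - 1, y = fg[, 1] - 1)
    if (nrow(fg) == 1) {
        ea <- rbind(pts[1, ], pts[1, ] + c(1, 0))
        eb <- rbind(pts[1, ], pts[1, ] + c(0, 1))
        return(new("DiameterPair", a = spacing, b = spacing,
                   endpointsA = ea, endpointsB = eb))
    }
    hull <- pts[grDevices::chull(pts[, 1], pts[, 2]), , drop = FALSE]
    if (nrow(hull) == 1) hull <- pts[!duplicated(pts), , drop = FALSE]
    dm <- as.matrix(stats::dist(hull))
    ij <- which(dm == max(dm), arr.ind = TRUE)[1, ]
    aPx <- max(dm)
    pA <- hull[ij[1], ]; pB <- hull[ij[2], ]
    if (aPx == 0) {                       # collinear duplicates guard
        aPx <- 1; pB <- pA + c(1, 0)
    }
    u <- (pB - pA) / sqrt(sum((pB - pA)^2))   # direction of a
    v <- c(-u[2], u[1])                       # perpendicular direction
    pu <- pts %*% u
    pv <- pts %*% v
    bins <- round(pu)
    ext <- tapply(pv, bins, function(z) max(z) - min(z))
    bPx <- max(ext)
    if (projection) bPx <- max(pv) - min(pv)
    bPx <- max(bPx, 1)                        # at least one pixel extent
    aPx <- max(aPx, bPx)                      # numeric guard: a >= b
    if (projection) {
        ib <- c(which.min(pv), which.max(pv))
        mid <- mean(pu[ib])
        ebU <- c(mid, mid); ebV <- pv[ib]
    } else {
        bb <- names(ext)[which.max(ext)]
        selB <- which(bins == as.numeric(bb))
        ebU <- rep(mean(range(pu[selB])) * 0 + as.numeric(bb), 2)
        ebV <- range(pv[selB])
    }
    ep <- function(uc, vc) pA * 0 + uc * u + vc * v
    eb <- rbind(ep(ebU[1], ebV[1]), ep(ebU[2], ebV[2]))
    new("DiameterPair", a = aPx * spacing, b = bPx * spacing,
        endpointsA = rbind(pA, pB), endpointsB = eb)
}

#' @rdname accessors
#' @param spacing mm per pixel
#' @export
setMethod("lesionDiameters", "BinaryMask",
          function(object, spacing = NULL, ...)
              diametersOfMask(object, spacing = spacing, ...))

#' Intraclass correlation coefficient (two-way, absolute agreement, single)
#'
#' ICC(A,1): the two-way random-effects, absolute-agreement,
#' single-measurement intraclass correlation of a cases x raters table,
#' computed from the standard mean-square decomposition
#' \code{(MSR - MSE) / (MSR + (k - 1) MSE + k/n (MSC - MSE))}.  Absolute
#' agreement penalizes systematic rater offsets, which is the appropriate
#' choice for inter-operator variability of segmentation scores.
#'
#' @param rater1,rater2 paired numeric score vectors (one entry per case)
#' @return the ICC, in [-1, 1]
#' @examples
#' iccAbsoluteAgreement(c(80, 85, 90, 95), c(81, 84, 91, 94))
#' @export
iccAbsoluteAgreement <- function(rater1, rater2) {
    if (length(rater1) != length(rater2))
        stop("rater score vectors must have equal length")
    n <- length(rater1)
    if (n < 2) stop("need at least 2 paired cases")
    x <- cbind(rater1, rater2)
    k <- 2
    grand <- mean(x)
    MSR <- k * sum((rowMeans(x) - grand)^2) / (n - 1)
    MSC <- n * sum((colMeans(x) - grand)^2) / (k - 1)
    SSE <- sum((x - outer(rowMeans(x), rep(1, k)) -
                outer(rep(1, n), colMeans(x)) + grand)^2)
    MSE <- SSE / ((n - 1) * (k - 1))
    denom <- MSR + (k - 1) * MSE + k / n * (MSC - MSE)
    if (denom == 0) return(1)       # zero variance everywhere: agreement
    (MSR - MSE) / denom
}

## run code with a private, restored RNG state
.withSeed <- function(seed, expr) {
    hadSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (hadSeed) old <- get(".Random.seed", envir = globalenv())
    on.exit(if (hadSeed) assign(".Random.seed", old, envir = globalenv())
            else if (exists(".Random.seed", envir = globalenv(),
                            inherits = FALSE))
                rm(".Random.seed", envir = globalenv()))
    set.seed(seed)
    expr
}

#' Percentile-bootstrap 95\% confidence interval of the median
#'
#' @param values nonempty numeric vector
#' @param nBoot number of bootstrap resamples (>= 100)
#' @param seed RNG seed making the interval deterministic
#' @return named numeric vector \code{(median, lo, hi)}
#' @examples
#' bootstrapMedianCI(1:101, nBoot = 500, seed = 7)
#' @export
bootstrapMedianCI <- function(values, nBoot = 2000, seed = 1) {
    stopifnot(length(values) >= 1, nBoot >= 100)
    meds <- .withSeed(seed, {
        vapply(seq_len(nBoot), function(i)
            stats::median(sample(values, replace = TRUE)), numeric(1))
    })
    qs <- stats::quantile(meds, c(0.025, 0.975), names = FALSE, type = 7)
    c(median = stats::median(values), lo = qs[1], hi = qs[2])
}
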