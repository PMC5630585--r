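#' @import methods
NULL

## ---------------------------------------------------------------------------
## UltrasoundImage
## ---------------------------------------------------------------------------

#' 2-D grayscale ultrasound image
#'
#' Container for a single B-mode ultrasound frame (or any 2-D grayscale
#' raster): an integer-valued gray-level matrix together with the isotropic
#' pixel spacing in mm per pixel.  The coordinate convention used throughout
#' the package is 0-based, \code{x} = column, \code{y} = row, origin at the
#' top-left corner; the matrix is indexed \code{pixels[y + 1, x + 1]}.
#'
#' @slot pixels numeric matrix of gray levels, rows are image rows (y)
#' @slot spacing isotropic pixel spacing, mm per pixel
#' @slot maxGray maximal representable gray value (255 for 8-bit input,
#'   65535 for 16-bit)
#' @slot sourceId free-text provenance tag (file name, phantom id, ...)
#' @export
setClass("UltrasoundImage",
    representation(pixels = "matrix", spacing = "numeric",
                   maxGray = "numeric", sourceId = "character"),
    prototype(spacing = 1, maxGray = 255, sourceId = ""))

setValidity("UltrasoundImage", function(object) {
    p <- object@pixels
    if (nrow(p) < 16L || ncol(p) < 16L)
        return("image must be at least 16 x 16 pixels")
    if (anyNA(p)) return("gray values must not contain NA")
    if (min(p) < 0 || max(p) > object@maxGray)
        return(sprintf("gray values must lie in [0, %d]", object@maxGray))
    if (length(object@spacing) != 1L || !is.finite(object@spacing) ||
        object@spacing <= 0)
        return("spacing must be a single positive number")
    TRUE
})

#' Create an UltrasoundImage
#'
#' @param pixels numeric matrix of gray levels (rows = y, columns = x)
#' @param spacing pixel spacing in mm per pixel (isotropic), default 1
#' @param maxGray maximal gray value, default 255
#' @param sourceId free-text identifier
#' @return an \linkS4class{UltrasoundImage}
#' @examples
#' img <- ultrasoundImage(matrix(7, 16, 16))
#' pixelSpacing(img)
#' @export
ultrasoundImage <- function(pixels, spacing = 1, maxGray = 255,
                            sourceId = "") {
    new("UltrasoundImage", pixels = pixels, spacing = spacing,
        maxGray = maxGray, sourceId = sourceId)
}

#' @rdname accessors
#' @export
setMethod("pixelMatrix", "UltrasoundImage", function(object, ...) object@pixels)

#' @rdname accessors
#' @export
setMethod("pixelSpacing", "UltrasoundImage", function(object, ...) object@spacing)

setMethod("show", "UltrasoundImage", function(object) {
    cat(sprintf("UltrasoundImage %d x %d px, %.4g mm/px, gray [%g, %g]%s\n",
                ncol(object@pixels), nrow(object@pixels), object@spacing,
                min(object@pixels), max(object@pixels),
                if (nzchar(object@sourceId))
                    paste0(" <", object@sourceId, ">") else ""))
})

#' @rdname accessors
#' @export
setMethod("dim", "UltrasoundImage", function(x) dim(x@pixels))

## ---------------------------------------------------------------------------
## BinaryMask
## ---------------------------------------------------------------------------

#' Binary segmentation mask
#'
#' Rasterized segmentation area with the same shape and spacing as its parent
#' image; pixel values are strictly 0 or 1.
#'
#' @slot pixels 0/1 matrix
#' @slot spacing mm per pixel
#' @export
setClass("BinaryMask",
    representation(pixels = "matrix", spacing = "numeric"),
    prototype(spacing = 1))

setValidity("BinaryMask", function(object) {
    p <- object@pixels
    if (anyNA(p) || !all(p %in% c(0, 1)))
        return("mask values must be 0 or 1")
    if (object@spacing <= 0) return("spacing must be positive")
    TRUE
})

#' Create a BinaryMask
#'
#' @param pixels 0/1 matrix (rows = y, columns = x)
#' @param spacing pixel spacing in mm per pixel
#' @return a \linkS4class{BinaryMask}
#' @export
binaryMask <- function(pixels, spacing = 1) {
    storage.mode(pixels) <- "double"
    new("BinaryMask", pixels = pixels, spacing = spacing)
}

#' @rdname accessors
#' @export
setMethod("pixelMatrix", "BinaryMask", function(object, ...) object@pixels)

#' @rdname accessors
#' @export
setMethod("pixelSpacing", "BinaryMask", function(object, ...) object@spacing)

#' @rdname accessors
#' @export
setMethod("dim", "BinaryMask", function(x) dim(x@pixels))

setMethod("show", "BinaryMask", function(object) {
    cat(sprintf("BinaryMask %d x %d px, %d foreground px (%.1f%%)\n",
                ncol(object@pixels), nrow(object@pixels),
                sum(object@pixels),
                100 * mean(object@pixels)))
})

## ---------------------------------------------------------------------------
## GraphParams
## ---------------------------------------------------------------------------

#' Radial graph parameters
#'
#' Tunable parameters of the circular graph template: the number of rays
#' \code{nRays}, nodes per ray \code{nNodes}, outermost node distance
#' \code{maxRadius} (pixels; \code{NA} picks
#' \code{min(border distance, 0.45 * min(height, width))} at build time),
#' the smoothness parameter \code{deltaR} bounding how many radial steps the
#' cut may move between adjacent rays, and the side length \code{avgWindow}
#' of the square window used to average the gray value around the seed.
#'
#' @slot nRays integer, number of radial rays (>= 3)
#' @slot nNodes integer, nodes per ray (>= 2)
#' @slot maxRadius numeric, outermost node radius in pixels, or NA for auto
#' @slot deltaR non-negative integer smoothness constraint
#' @slot avgWindow odd integer window side for the seed average
#' @export
setClass("GraphParams",
    representation(nRays = "integer", nNodes = "integer",
                   maxRadius = "numeric", deltaR = "integer",
                   avgWindow = "integer"))

setValidity("GraphParams", function(object) {
    if (object@nRays < 3L) return("nRays must be >= 3")
    if (object@nNodes < 2L) return("nNodes must be >= 2")
    if (!is.na(object@maxRadius) && object@maxRadius < object@nNodes)
        return("maxRadius must be >= nNodes (at least 1 px node spacing)")
    if (object@deltaR < 0L) return("deltaR must be >= 0")
    if (object@avgWindow < 1L || object@avgWindow %% 2L == 0L)
        return("avgWindow must be odd and >= 1")
    TRUE
})

#' Create a GraphParams object
#'
#' @param nRays number of rays, default 60
#' @param nNodes nodes per ray, default 40
#' @param maxRadius outermost node radius in pixels; \code{NA} (default)
#'   derives it from the image/seed geometry at build time
#' @param deltaR smoothness parameter, default 2
#' @param avgWindow seed-average window side in pixels (odd), default 9
#' @return a \linkS4class{GraphParams}
#' @examples
#' graphParams(deltaR = 0)
#' @export
graphParams <- function(nRays = 60, nNodes = 40, maxRadius = NA_real_,
                        deltaR = 2, avgWindow = 9) {
    new("GraphParams", nRays = as.integer(nRays), nNodes = as.integer(nNodes),
        maxRadius = as.numeric(maxRadius), deltaR = as.integer(deltaR),
        avgWindow = as.integer(avgWindow))
}

setMethod("show", "GraphParams", function(object) {
    cat(sprintf(
        "GraphParams: K=%d rays, N=%d nodes/ray, maxRadius=%s px, deltaR=%d, avgWindow=%d\n",
        object@nRays, object@nNodes,
        if (is.na(object@maxRadius)) "auto" else format(object@maxRadius),
        object@deltaR, object@avgWindow))
})

## ---------------------------------------------------------------------------
## RadialGraph
## ---------------------------------------------------------------------------

#' Radial-ray graph around a seed point
#'
#' Graph template of \code{K x N} nodes sampled along radial rays around the
#' seed, with two virtual terminals (source and sink).  Terminal edges carry
#' the finite capacities derived from the gray-value profile; intra-ray and
#' inter-ray edges are infinity-weighted and are materialized only when the
#' cut is solved.  Helper-seed constraints are recorded per ray in
#' \code{pins} (1-based node index, \code{NA} = unconstrained).
#'
#' @slot nodeX,nodeY K x N matrices of node coordinates (pixels, 0-based)
#' @slot grays K x N matrix of bilinearly sampled gray values
#' @slot termSide K x N integer matrix: 0 = bound to source, 1 = to sink
#' @slot termCap K x N matrix of non-negative terminal capacities
#' @slot deltaR integer smoothness parameter
#' @slot seed numeric length-2 (x, y) seed position
#' @slot avgGray mean gray value around the seed
#' @slot maxRadius outermost node radius (pixels)
#' @slot pins integer vector of length K of pinned node indices (1-based, NA
#'   where no helper constrains the ray)
#' @export
setClass("RadialGraph",
    representation(nodeX = "matrix", nodeY = "matrix", grays = "matrix",
                   termSide = "matrix", termCap = "matrix",
                   deltaR = "integer", seed = "numeric", avgGray = "numeric",
                   maxRadius = "numeric", pins = "integer"))

setValidity("RadialGraph", function(object) {
    K <- nrow(object@grays); N <- ncol(object@grays)
    if (K < 1L || N < 2L) return("graph needs >= 1 ray and >= 2 nodes/ray")
    for (s in c("nodeX", "nodeY", "termSide", "termCap"))
        if (!identical(dim(slot(object, s)), c(K, N)))
            return(sprintf("slot %s must be a %d x %d matrix", s, K, N))
    if (!all(object@termSide %in% c(0L, 1L)))
        return("termSide entries must be 0 (source) or 1 (sink)")
    if (any(object@termCap < 0)) return("terminal capacities must be >= 0")
    if (object@deltaR < 0L) return("deltaR must be >= 0")
    if (length(object@pins) != K) return("pins must have one entry per ray")
    ok <- is.na(object@pins) | (object@pins >= 1L & object@pins <= N)
    if (!all(ok)) return("pins must be NA or in [1, N]")
    TRUE
})

setMethod("show", "RadialGraph", function(object) {
    K <- nrow(object@grays); N <- ncol(object@grays)
    cat(sprintf(
        "RadialGraph: K=%d rays x N=%d nodes, deltaR=%d, seed=(%g, %g), m=%.2f, maxRadius=%.1f px, %d pinned ray(s)\n",
        K, N, object@deltaR, object@seed[1], object@seed[2], object@avgGray,
        object@maxRadius, sum(!is.na(object@pins))))
})

## ---------------------------------------------------------------------------
## CutResult
## ---------------------------------------------------------------------------

#' Minimum s-t cut of a radial graph
#'
#' Per-ray cut indices (0-based: \code{cutIndex[k]} is the outermost node of
#' ray \code{k} kept on the source/foreground side) and the total severed
#' capacity of the minimum cut.
#'
#' @slot cutIndex integer vector of length K, values in [0, N - 1]
#' @slot flowValue total capacity of the minimum cut (= max-flow value)
#' @export
setClass("CutResult",
    representation(cutIndex = "integer", flowValue = "numeric"))

setValidity("CutResult", function(object) {
    if (any(object@cutIndex < 0L)) return("cut indices must be >= 0")
    if (!is.finite(object@flowValue) || object@flowValue < 0)
        return("flowValue must be finite and >= 0")
    TRUE
})

#' @rdname accessors
#' @export
setMethod("cutIndices", "CutResult", function(object, ...) object@cutIndex)

#' @rdname accessors
#' @export
setMethod("flowValue", "CutResult", function(object, ...) object@flowValue)

setMethod("show", "CutResult", function(object) {
    cat(sprintf("CutResult: K=%d rays, cut indices in [%d, %d], flow=%.6g\n",
                length(object@cutIndex), min(object@cutIndex),
                max(object@cutIndex), object@flowValue))
})

## ---------------------------------------------------------------------------
## DiameterPair
## ---------------------------------------------------------------------------

#' Perpendicular lesion diameters
#'
#' Largest diameter \code{a} and the largest extent \code{b} measured along
#' the direction perpendicular to \code{a}, both in millimeters, with segment
#' endpoints in pixel coordinates.
#'
#' @slot a,b diameters in mm, \code{a >= b > 0}
#' @slot endpointsA,endpointsB 2 x 2 matrices of segment endpoints, rows are
#'   points, columns (x, y) in pixels
#' @export
setClass("DiameterPair",
    representation(a = "numeric", b = "numeric",
                   endpointsA = "matrix", endpointsB = "matrix"))

setValidity("DiameterPair", function(object) {
    if (object@b <= 0 || object@a < object@b)
        return("diameters must satisfy a >= b > 0")
    da <- object@endpointsA[2, ] - object@endpointsA[1, ]
    db <- object@endpointsB[2, ] - object@endpointsB[1, ]
    na <- sqrt(sum(da^2)); nb <- sqrt(sum(db^2))
    if (na > 0 && nb > 0 && abs(sum(da * db)) / (na * nb) > 1e-6)
        return("diameter segments must be perpendicular")
    TRUE
})

setMethod("show", "DiameterPair", function(object) {
    cat(sprintf("DiameterPair: a=%.2f mm, b=%.2f mm\n", object@a, object@b))
})

## ---------------------------------------------------------------------------
## SegmentationResult
## ---------------------------------------------------------------------------

#' Result of a seed-based segmentation
#'
#' Closed star-shaped contour (one sub-pixel vertex per ray), the rasterized
#' binary mask, the underlying cut, the automatically measured perpendicular
#' diameters in millimeters, and the full inputs (image, seed, helper seeds,
#' parameters) so the segmentation can be re-run with modified seeds.
#'
#' @slot contour K x 2 matrix of (x, y) contour vertices
#' @slot mask \linkS4class{BinaryMask} rasterized from the contour
#' @slot cut \linkS4class{CutResult}
#' @slot diameters \linkS4class{DiameterPair} in mm
#' @slot params \linkS4class{GraphParams} actually used (maxRadius resolved)
#' @slot seed numeric (x, y) primary seed
#' @slot helpers list of numeric (x, y) helper seeds
#' @slot image the segmented \linkS4class{UltrasoundImage}
#' @export
setClass("SegmentationResult",
    representation(contour = "matrix", mask = "BinaryMask",
                   cut = "CutResult", diameters = "DiameterPair",
                   params = "GraphParams", seed = "numeric",
                   helpers = "list", image = "UltrasoundImage"))

#' @rdname accessors
#' @export
setMethod("contourPolygon", "SegmentationResult",
          function(object, ...) object@contour)

#' @rdname accessors
#' @export
setMethod("lesionMask", "SegmentationResult", function(object, ...) object@mask)

#' @rdname accessors
#' @export
setMethod("lesionDiameters", "SegmentationResult",
          function(object, ...) object@diameters)

#' @rdname accessors
#' @export
setMethod("cutIndices", "SegmentationResult",
          function(object, ...) object@cut@cutIndex)

#' @rdname accessors
#' @export
setMethod("flowValue", "SegmentationResult",
          function(object, ...) object@cut@flowValue)

setMethod("show", "SegmentationResult", function(object) {
    cat(sprintf(
        "SegmentationResult: seed=(%g, %g), %d helper(s), %d-vertex contour, area %d px, a=%.1f mm, b=%.1f mm, flow=%.4g\n",
        object@seed[1], object@seed[2], length(object@helpers),
        nrow(object@contour), sum(object@mask@pixels),
        object@diameters@a, object@diameters@b, object@cut@flowValue))
})

## ---------------------------------------------------------------------------
## PhantomSpec / PhantomCase
## ---------------------------------------------------------------------------

#' Parametric description of a synthetic speckle phantom
#'
#' Describes one synthetic B-mode-like image: a star-shaped hypoechoic lesion
#' (echogenicity \code{lesionGain} < 1 relative to the background) with an
#' optional echo-poor halo ring, embedded in multi-look gamma speckle,
#' blurred by a Gaussian point-spread function and log-compressed to 8 bit.
#' The lesion boundary radius is
#' \code{r(theta) = baseRadius * (1 + sum(amp * sin(freq * theta + phase)))},
#' which is star-shaped by construction.
#'
#' @slot imageSize integer, side length of the square image (pixels)
#' @slot spacing mm per pixel
#' @slot center numeric (x, y) lesion center
#' @slot baseRadius base lesion radius in pixels
#' @slot harmonics numeric matrix with columns \code{amp}, \code{freq},
#'   \code{phase} (possibly 0 rows); amplitudes are fractions of baseRadius
#' @slot lesionGain lesion/background echogenicity ratio in (0, 1)
#' @slot haloWidth halo ring width in pixels (0 = no halo)
#' @slot haloGain halo echogenicity in (0, 1]
#' @slot psfSigma Gaussian PSF sigma in pixels (0 = no blur)
#' @slot speckleLooks integer L >= 1, number of speckle looks
#' @slot rngSeed integer seed making the phantom deterministic
#' @export
setClass("PhantomSpec",
    representation(imageSize = "integer", spacing = "numeric",
                   center = "numeric", baseRadius = "numeric",
                   harmonics = "matrix", lesionGain = "numeric",
                   haloWidth = "numeric", haloGain = "numeric",
                   psfSigma = "numeric", speckleLooks = "integer",
                   rngSeed = "integer"))

setValidity("PhantomSpec", function(object) {
    if (object@imageSize < 16L) return("imageSize must be >= 16")
    if (object@spacing <= 0) return("spacing must be positive")
    if (object@baseRadius <= 0) return("baseRadius must be positive")
    if (object@lesionGain <= 0 || object@lesionGain >= 1)
        return("lesionGain must lie in (0, 1): the lesion is hypoechoic")
    if (object@haloGain <= 0 || object@haloGain > 1)
        return("haloGain must lie in (0, 1]")
    if (object@haloWidth < 0) return("haloWidth must be >= 0")
    if (object@speckleLooks < 1L) return("speckleLooks must be >= 1")
    if (nrow(object@harmonics) > 0) {
        if (ncol(object@harmonics) != 3L)
            return("harmonics needs columns amp, freq, phase")
        if (any(object@harmonics[, 1] < 0) ||
            any(object@harmonics[, 1] > 0.25))
            return("harmonic amplitudes must lie in [0, 0.25]")
        if (sum(object@harmonics[, 1]) >= 1)
            return("summed harmonic amplitudes must stay below 1 (radius > 0)")
    }
    TRUE
})

#' Create a PhantomSpec
#'
#' @param imageSize square image side in pixels
#' @param spacing mm per pixel
#' @param center numeric (x, y) lesion center; default image center
#' @param baseRadius base lesion radius in pixels
#' @param harmonics matrix with columns (amp, freq, phase); default none
#' @param lesionGain lesion echogenicity relative to background, default 0.25
#' @param haloWidth halo ring width in px, default 0
#' @param haloGain halo echogenicity, default 0.6
#' @param psfSigma PSF sigma in px, default 1.5
#' @param speckleLooks number of speckle looks L, default 16
#' @param rngSeed integer RNG seed, default 1
#' @return a \linkS4class{PhantomSpec}
#' @export
phantomSpec <- function(imageSize, baseRadius, spacing = 1, center = NULL,
                        harmonics = matrix(numeric(0), 0, 3),
                        lesionGain = 0.25, haloWidth = 0, haloGain = 0.6,
                        psfSigma = 1.5, speckleLooks = 16, rngSeed = 1) {
    if (is.null(center))
        center <- c((imageSize - 1) / 2, (imageSize - 1) / 2)
    harmonics <- as.matrix(harmonics)
    if (ncol(harmonics) == 0L) harmonics <- matrix(numeric(0), 0, 3)
    colnames(harmonics) <- c("amp", "freq", "phase")
    new("PhantomSpec", imageSize = as.integer(imageSize), spacing = spacing,
        center = as.numeric(center), baseRadius = baseRadius,
        harmonics = harmonics, lesionGain = lesionGain,
        haloWidth = haloWidth, haloGain = haloGain, psfSigma = psfSigma,
        speckleLooks = as.integer(speckleLooks),
        rngSeed = as.integer(rngSeed))
}

setMethod("show", "PhantomSpec", function(object) {
    cat(sprintf(
        "PhantomSpec: %d px image, r=%.1f px (%d harmonic(s)), gain=%.2f, halo %s, L=%d, psf=%.1f px, seed=%d\n",
        object@imageSize, object@baseRadius, nrow(object@harmonics),
        object@lesionGain,
        if (object@haloWidth > 0)
            sprintf("%.1f px @ %.2f", object@haloWidth, object@haloGain)
        else "none",
        object@speckleLooks, object@psfSigma, object@rngSeed))
})

#' Synthetic phantom with ground truth
#'
#' A generated phantom image together with its ground-truth contour and
#' rasterized truth mask, plus the pre-log-compression intensity field
#' (useful for checking first- and second-order speckle statistics).
#'
#' @slot image \linkS4class{UltrasoundImage}
#' @slot truthMask \linkS4class{BinaryMask}
#' @slot truthContour polygon matrix (x, y) of the true lesion boundary
#' @slot spec the generating \linkS4class{PhantomSpec}
#' @slot preLog matrix of post-PSF, pre-log-compression intensities
#' @export
setClass("PhantomCase",
    representation(image = "UltrasoundImage", truthMask = "BinaryMask",
                   truthContour = "matrix", spec = "PhantomSpec",
                   preLog = "matrix"))

#' @rdname accessors
#' @export
setMethod("truthMask", "PhantomCase", function(object, ...) object@truthMask)

#' @rdname accessors
#' @export
setMethod("truthContour", "PhantomCase",
          function(object, ...) object@truthContour)

setMethod("show", "PhantomCase", function(object) {
    cat("PhantomCase\n  ")
    show(object@image)
    cat("  ")
    show(object@spec)
})

## ---------------------------------------------------------------------------
## EvalSummary
## ---------------------------------------------------------------------------

#' Summary of a phantom-suite evaluation
#'
#' Per-case agreement scores of the segmentation pipeline against ground
#' truth, with medians, percentile-bootstrap 95\% confidence intervals of the
#' medians, and the fraction of cases counted as satisfied under the
#' DSC >= 70\% proxy.
#'
#' @slot perCase data.frame with one row per case (dsc_pct, hd_px,
#'   d_a_diff_mm, d_b_diff_mm, n_helpers, flow, diam_px, ...)
#' @slot medians named numeric vector of medians
#' @slot ci named list of length-2 numeric vectors (lower, upper)
#' @slot satisfiedRate fraction of cases with DSC >= 70\%
#' @slot kMax maximal number of auto-placed helper seeds per case
#' @slot masterSeed suite master seed
#' @export
setClass("EvalSummary",
    representation(perCase = "data.frame", medians = "numeric", ci = "list",
                   satisfiedRate = "numeric", kMax = "integer",
                   masterSeed = "integer"))

setValidity("EvalSummary", function(object) {
    pc <- object@perCase
    for (nm in intersect(names(object@medians), colnames(pc))) {
        v <- pc[[nm]]
        if (length(v) && (object@medians[[nm]] < min(v) ||
                          object@medians[[nm]] > max(v)))
            return(sprintf("median of %s outside per-case range", nm))
    }
    TRUE
})

setMethod("show", "EvalSummary", function(object) {
    cat(sprintf(
        "EvalSummary: %d cases, kMax=%d, masterSeed=%d\n",
        nrow(object@perCase), object@kMax, object@masterSeed))
    cat(sprintf("  median DSC  %.1f %% (95%% CI %.1f-%.1f)\n",
                object@medians[["dsc_pct"]],
                object@ci[["dsc_pct"]][1], object@ci[["dsc_pct"]][2]))
    cat(sprintf("  median HD   %.1f px (95%% CI %.1f-%.1f)\n",
                object@medians[["hd_px"]],
                object@ci[["hd_px"]][1], object@ci[["hd_px"]][2]))
    cat(sprintf("  median |da| %.2f mm, median |db| %.2f mm\n",
                object@medians[["d_a_diff_mm"]],
                object@medians[["d_b_diff_mm"]]))
    cat(sprintf("  satisfied (DSC >= 70%%): %.0f %%\n",
                100 * object@satisfiedRate))
})
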