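## synthetic B-mode speckle phantoms with known ground truth

## boundary radius r(theta) of a spec, theta measured clockwise from "up"
.phantomRadius <- function(spec, theta) {
    r <- rep(spec@baseRadius, length(theta))
    if (nrow(spec@harmonics) > 0)
        for (j in seq_len(nrow(spec@harmonics)))
            r <- r + spec@baseRadius * spec@harmonics[j, 1] *
                sin(spec@harmonics[j, 2] * theta + spec@harmonics[j, 3])
    r
}

## ground-truth polygon (x, y) of the lesion boundary
.phantomContour <- function(spec, nVertices = 360) {
    theta <- 2 * pi * (seq_len(nVertices) - 1) / nVertices
    r <- .phantomRadius(spec, theta)
    cbind(x = spec@center[1] + sin(theta) * r,
          y = spec@center[2] - cos(theta) * r)
}

## log-compression constants: alpha sets the dynamic-range compression,
## iRef the intensity mapped to full white (a high multiple of the
## unit-mean background speckle intensity)
.LOG_ALPHA <- 20
.LOG_IREF <- 6

.logCompress <- function(intensity) {
    g <- 255 * log1p(.LOG_ALPHA * intensity) / log1p(.LOG_ALPHA * .LOG_IREF)
    pmin(pmax(round(g), 0), 255)
}

#' Generate a synthetic speckle phantom
#'
#' Renders one B-mode-like image from its parametric description: an
#' echogenicity map (background 1.0, echo-poor halo ring
#' \code{haloGain}, hypoechoic lesion \code{lesionGain}, boundary radius
#' \code{r(theta) = baseRadius * (1 + sum amp sin(freq theta + phase))}) is
#' multiplied by an L-look intensity speckle field (the average of L squared
#' independent zero-mean complex Gaussian fields, i.e. unit-mean
#' gamma-distributed intensities with shape L), blurred by a Gaussian
#' point-spread function and log-compressed to 8 bit.  Deterministic given
#' \code{rngSeed}.
#'
#' The ground-truth mask contains the lesion only; the halo ring is outside
#' the truth by default (the "thin halo" reading).  Set
#' \code{haloInTruth = TRUE} to include the halo ring in the truth mask, the
#' alternative clinical reading in which the echo-poor rim belongs to the
#' lesion.
#'
#' @param spec a \linkS4class{PhantomSpec}
#' @param haloInTruth include the halo ring in the ground-truth mask
#' @return a \linkS4class{PhantomCase}
#' @examples
#' pc <- generatePhantom(phantomSpec(imageSize = 96, baseRadius = 25))
#' pc
#' @export
generatePhantom <- function(spec, haloInTruth = FALSE) {
    validObject(spec)
    n <- spec@imageSize
    theta <- 2 * pi * (0:719) / 720
    if (min(.phantomRadius(spec, theta)) <= 0)
        stop("invalid phantom spec: boundary radius is not positive ",
             "everywhere")
    xx <- matrix(0:(n - 1), n, n, byrow = TRUE)   # x = column, 0-based
    yy <- matrix(0:(n - 1), n, n)                 # y = row
    dx <- xx - spec@center[1]; dy <- yy - spec@center[2]
    rr <- sqrt(dx^2 + dy^2)
    ang <- atan2(dx, -dy) %% (2 * pi)             # clockwise from "up"
    rb <- matrix(.phantomRadius(spec, as.vector(ang)), n, n)
    echo <- matrix(1, n, n)
    inLesion <- rr <= rb
    inHalo <- !inLesion & rr <= rb + spec@haloWidth
    echo[inHalo] <- spec@haloGain
    echo[inLesion] <- spec@lesionGain
    speckle <- .withSeed(spec@rngSeed, {
        matrix(stats::rgamma(n * n, shape = spec@speckleLooks,
                             rate = spec@speckleLooks), n, n)
    })
    intensity <- echo * speckle
    if (spec@psfSigma > 0)
        intensity <- as.matrix(EBImage::gblur(intensity, spec@psfSigma))
    gray <- .logCompress(intensity)
    img <- ultrasoundImage(gray, spacing = spec@spacing,
                           sourceId = sprintf("phantom-seed%d", spec@rngSeed))
    thetaC <- 2 * pi * (0:359) / 360
    rC <- .phantomRadius(spec, thetaC) +
        if (haloInTruth) spec@haloWidth else 0
    ctr <- cbind(x = spec@center[1] + sin(thetaC) * rC,
                 y = spec@center[2] - cos(thetaC) * rC)
    mask <- rasterizeContour(ctr, c(n, n), spacing = spec@spacing)
    new("PhantomCase", image = img, truthMask = mask, truthContour = ctr,
        spec = spec, preLog = intensity)
}

## deterministic per-case sub-seeds below 2^31
.subSeeds <- function(masterSeed, n) {
    .withSeed(masterSeed, sample.int(.Machine$integer.max - 1L, n))
}

## map a physical diameter (mm) monotonically to a rendered pixel diameter
## in [30, 250] px, emulating the clinical zoom that keeps lesions at a
## comparable on-screen size
.diameterToPixels <- function(dMm, dRange = c(6, 115), pxRange = c(30, 250)) {
    f <- log(dMm / dRange[1]) / log(dRange[2] / dRange[1])
    pxRange[1] + f * (pxRange[2] - pxRange[1])
}

#' Generate a deterministic suite of phantom cases
#'
#' Draws \code{nCases} phantom specifications from documented distributions
#' and renders them.  Maximal lesion diameters are drawn from a log-normal
#' distribution calibrated to the clinical size distribution of liver
#' metastases (median 20 mm, quartiles near 14 and 27 mm), truncated to
#' \code{diameterRange} (default 6-115 mm); each
#' case is rendered at a zoom that maps its diameter monotonically into
#' 30-250 px, and the mm/px spacing is set accordingly.  Boundary harmonics
#' (one low- and one higher-frequency component with modest amplitudes),
#' lesion gain (uniform 0.1-0.35), and an echo-poor halo in 30\% of the
#' cases (gain 0.45-0.7, width 2-6 px) model roundish hypoechoic lesions of
#' varying irregularity.  Speckle looks (L = 16) and PSF sigma (1.5 px) are
#' fixed.  The suite is bit-identical for a fixed \code{masterSeed}.
#'
#' @param nCases number of cases (>= 1)
#' @param masterSeed integer seed; every case seed derives from it
#' @param diameterRange numeric (min, max) maximal diameter range in mm
#' @param render generate the images (\code{TRUE}) or return the
#'   \linkS4class{PhantomSpec} list only (\code{FALSE}, cheap; useful for
#'   checking sampler statistics)
#' @param haloInTruth passed to \code{\link{generatePhantom}}
#' @return a list of \linkS4class{PhantomCase} (or \linkS4class{PhantomSpec}
#'   when \code{render = FALSE}); the sampled maximal diameters in mm are
#'   attached as attribute \code{"diametersMm"}
#' @export
generateSuite <- function(nCases, masterSeed = 42, diameterRange = c(6, 115),
                          render = TRUE, haloInTruth = FALSE) {
    stopifnot(nCases >= 1)
    seeds <- .subSeeds(masterSeed, nCases + 1L)
    pars <- .withSeed(seeds[nCases + 1L], {
        ## maximal diameters: log-normal calibrated to the clinical size
        ## distribution (median 20 mm, quartiles ~14 and ~27 mm), truncated
        ## to diameterRange by inverse-CDF sampling
        mlog <- log(20); slog <- log(27 / 20) / stats::qnorm(0.75)
        pr <- stats::plnorm(diameterRange, mlog, slog)
        dMm <- stats::qlnorm(stats::runif(nCases, pr[1], pr[2]), mlog, slog)
        list(dMm = dMm,
             amp1 = stats::runif(nCases, 0.03, 0.12),
             freq1 = sample(2:4, nCases, replace = TRUE),
             amp2 = stats::runif(nCases, 0.01, 0.05),
             freq2 = sample(4:6, nCases, replace = TRUE),
             ph1 = stats::runif(nCases, 0, 2 * pi),
             ph2 = stats::runif(nCases, 0, 2 * pi),
             gain = stats::runif(nCases, 0.10, 0.35),
             halo = stats::runif(nCases) < 0.30,
             haloGain = stats::runif(nCases, 0.45, 0.70),
             haloWidth = stats::runif(nCases, 2, 6),
             jx = stats::runif(nCases, -3, 3),
             jy = stats::runif(nCases, -3, 3))
    })
    out <- vector("list", nCases)
    for (i in seq_len(nCases)) {
        dPx <- .diameterToPixels(pars$dMm[i], diameterRange)
        spacing <- pars$dMm[i] / dPx
        size <- max(96L, as.integer(ceiling(1.75 * dPx)))
        ## the sampled dMm is the *maximal* diameter; the base radius is
        ## shrunk by the harmonic amplitude so max r(theta) matches dPx/2
        ampSum <- pars$amp1[i] + pars$amp2[i]
        base <- (dPx / 2) / (1 + ampSum)
        harm <- rbind(c(pars$amp1[i], pars$freq1[i], pars$ph1[i]),
                      c(pars$amp2[i], pars$freq2[i], pars$ph2[i]))
        spec <- phantomSpec(
            imageSize = size, spacing = spacing,
            center = c((size - 1) / 2 + pars$jx[i],
                       (size - 1) / 2 + pars$jy[i]),
            baseRadius = base, harmonics = harm,
            lesionGain = pars$gain[i],
            haloWidth = if (pars$halo[i]) pars$haloWidth[i] else 0,
            haloGain = pars$haloGain[i],
            psfSigma = 1.5, speckleLooks = 16, rngSeed = seeds[i])
        out[[i]] <- if (render) generatePhantom(spec, haloInTruth)
                    else spec
    }
    attr(out, "diametersMm") <- pars$dMm
    out
}
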