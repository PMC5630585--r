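## batch evaluation harness: centroid seed + auto-boundary helper policy

## centroid of a binary mask, (x, y) 0-based
.maskCentroid <- function(mask) {
    fg <- which(.maskPixels(mask) == 1, arr.ind = TRUE)
    c(mean(fg[, 2]) - 1, mean(fg[, 1]) - 1)
}

## distance from `seed` to the truth boundary along each of K ray
## directions, by marching along the ray in 0.5 px steps and keeping the
## outermost point inside the truth polygon
.truthRadii <- function(truthCtr, seed, K, maxRadius) {
    dirs <- .rayDirections(K)
    rs <- seq(0.5, maxRadius, by = 0.5)
    vapply(seq_len(K), function(k) {
        xs <- seed[1] + dirs[k, "dx"] * rs
        ys <- seed[2] + dirs[k, "dy"] * rs
        ins <- .pointInPolygon(xs, ys, truthCtr[, 1], truthCtr[, 2])
        if (!any(ins)) NA_real_ else rs[max(which(ins))]
    }, numeric(1))
}

## cyclic ray distance on K rays
.rayDist <- function(k1, k2, K) {
    d <- abs(k1 - k2)
    pmin(d, K - d)
}

#' Segment one phantom case with the auto-boundary helper policy
#'
#' Emulates an examiner's refinement loop on a case with known ground
#' truth: the primary seed is placed at the truth-mask centroid and the
#' radial cut is solved; then, up to \code{kMax} times, a helper seed is
#' placed on the true boundary at the ray of maximal current radial error
#' and the cut is re-solved.  Candidate rays that are already pinned, whose
#' truth boundary lies beyond \code{maxRadius}, or whose pin would be
#' jointly infeasible with existing pins under the \code{deltaR} constraint
#' are skipped.  Refinement stops early when the maximal radial error drops
#' below one node spacing.
#'
#' @param case a \linkS4class{PhantomCase}
#' @param kMax maximal number of helper seeds (0 = none)
#' @param params a \linkS4class{GraphParams}
#' @return list with the final \linkS4class{SegmentationResult}
#'   (\code{$result}), the helper seeds used (\code{$helpers}) and the seed
#'   (\code{$seed})
#' @export
segmentPhantomCase <- function(case, kMax = 4, params = graphParams()) {
    stopifnot(is(case, "PhantomCase"), kMax >= 0)
    seed <- round(.maskCentroid(case@truthMask))
    res <- segmentLesion(case@image, seed, params = params)
    if (kMax > 0) {
        K <- params@nRays; N <- params@nNodes
        graph0 <- buildRadialGraph(case@image, seed, params)  # for geometry
        mr <- graph0@maxRadius
        spacing <- mr / N
        rTruth <- .truthRadii(case@truthContour, seed, K, mr)
        iTruth <- pmin(pmax(round(rTruth * N / mr), 1L), N)
        dirs <- .rayDirections(K)
        pinned <- rep(NA_integer_, K)
        helpers <- list()
        for (h in seq_len(kMax)) {
            rAlg <- .cutRadii(res@cut, mr, N)
            err <- abs(rAlg - rTruth)
            err[is.na(err)] <- -Inf
            err[!is.na(pinned)] <- -Inf
            ## pick the worst ray whose pin stays jointly feasible with the
            ## existing pins under the deltaR constraint
            kSel <- NA_integer_
            for (k in order(err, decreasing = TRUE)) {
                if (!is.finite(err[k])) break
                others <- which(!is.na(pinned))
                okPin <- all(abs(iTruth[k] - pinned[others]) <=
                             params@deltaR * .rayDist(k, others, K))
                if (okPin) { kSel <- k; break }
            }
            k <- kSel
            if (is.na(k) || err[k] < spacing) break
            helper <- c(seed[1] + dirs[k, "dx"] * rTruth[k],
                        seed[2] + dirs[k, "dy"] * rTruth[k])
            pinned[k] <- iTruth[k]
            helpers <- c(helpers, list(helper))
            res <- segmentLesion(case@image, seed, helpers = helpers,
                                 params = params)
        }
    }
    list(result = res, helpers = res@helpers, seed = seed)
}

#' Evaluate the segmentation pipeline on a phantom suite
#'
#' Generates (or accepts) a deterministic phantom suite, segments every case
#' with the centroid seed and the auto-boundary helper policy of
#' \code{\link{segmentPhantomCase}}, and summarizes the agreement with the
#' ground truth: per-case Dice score (percent), symmetric Hausdorff
#' distance (pixels), absolute diameter differences (mm), plus medians with
#' percentile-bootstrap 95\% confidence intervals and the fraction of cases
#' satisfied under the DSC >= 70\% proxy.
#'
#' @param nCases number of phantom cases, default 105
#' @param masterSeed suite master seed, default 42
#' @param kMax maximal helper seeds per case, default 4
#' @param params a \linkS4class{GraphParams}
#' @param suite optional pre-generated list of \linkS4class{PhantomCase};
#'   when supplied, \code{nCases}/\code{masterSeed} only label the summary
#' @param nBoot bootstrap resamples for the median CIs
#' @param verbose print per-case progress lines
#' @return an \linkS4class{EvalSummary}
#' @export
evaluateSuite <- function(nCases = 105, masterSeed = 42, kMax = 4,
                          params = graphParams(), suite = NULL,
                          nBoot = 1000, verbose = FALSE) {
    if (is.null(suite))
        suite <- generateSuite(nCases, masterSeed = masterSeed)
    n <- length(suite)
    rows <- vector("list", n)
    for (i in seq_len(n)) {
        t0 <- proc.time()[["elapsed"]]
        case <- suite[[i]]
        seg <- segmentPhantomCase(case, kMax = kMax, params = params)
        res <- seg$result
        dsc <- diceScore(res@mask, case@truthMask)
        hd <- hausdorffDistance(res@mask, case@truthMask)
        dTruth <- diametersOfMask(case@truthMask, case@spec@spacing)
        rows[[i]] <- data.frame(
            case = i,
            dsc_pct = dsc,
            hd_px = hd,
            d_a_diff_mm = abs(res@diameters@a - dTruth@a),
            d_b_diff_mm = abs(res@diameters@b - dTruth@b),
            n_helpers = length(seg$helpers),
            flow = res@cut@flowValue,
            diam_truth_px = dTruth@a / case@spec@spacing,
            seconds = proc.time()[["elapsed"]] - t0)
        if (verbose)
            message(sprintf(
                "case %3d: DSC %5.1f %%, HD %5.1f px, %d helper(s), %.2f s",
                i, dsc, hd, length(seg$helpers), rows[[i]]$seconds))
    }
    perCase <- do.call(rbind, rows)
    medCols <- c("dsc_pct", "hd_px", "d_a_diff_mm", "d_b_diff_mm")
    medians <- vapply(perCase[medCols], stats::median, numeric(1))
    ci <- lapply(seq_along(medCols), function(j)
        unname(bootstrapMedianCI(perCase[[medCols[j]]], nBoot = nBoot,
                                 seed = masterSeed + j)[2:3]))
    names(ci) <- medCols
    new("EvalSummary", perCase = perCase, medians = medians, ci = ci,
        satisfiedRate = mean(perCase$dsc_pct >= 70),
        kMax = as.integer(kMax), masterSeed = as.integer(masterSeed))
}

#' Write an evaluation summary to CSV and JSON
#'
#' Writes the per-case table as CSV and the medians, confidence intervals
#' and satisfied rate as JSON next to it.
#'
#' @param summary an \linkS4class{EvalSummary}
#' @param dir output directory (created if missing)
#' @param prefix file-name prefix
#' @return invisibly, the two file paths
#' @export
writeEvalSummary <- function(summary, dir, prefix = "evaluation") {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    csv <- file.path(dir, paste0(prefix, "_per_case.csv"))
    js <- file.path(dir, paste0(prefix, "_summary.json"))
    utils::write.csv(summary@perCase, csv, row.names = FALSE)
    jsonlite::write_json(
        list(n_cases = nrow(summary@perCase),
             k_max = summary@kMax,
             master_seed = summary@masterSeed,
             medians = as.list(summary@medians),
             ci95 = summary@ci,
             satisfied_rate = summary@satisfiedRate,
             icc_variant = "two-way random, absolute agreement, single"),
        js, auto_unbox = TRUE, digits = NA)
    invisible(c(csv, js))
}
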