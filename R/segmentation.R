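## seed + helper seeds -> closed star-shaped contour and mask

## map a helper position to its nearest ray (1-based) and node index
## (1-based) of a radial graph
.helperToNode <- function(graph, helper) {
    K <- nrow(graph@grays); N <- ncol(graph@grays)
    d <- helper - graph@seed
    r <- sqrt(sum(d^2))
    if (r > graph@maxRadius)
        stop("helper seed (", paste(helper, collapse = ", "),
             ") is farther from the seed than maxRadius = ",
             format(graph@maxRadius), " px")
    if (r == 0)
        stop("helper seed must be distinct from the primary seed")
    theta <- atan2(d[1], -d[2]) %% (2 * pi)   # clockwise from "up"
    k <- (round(theta / (2 * pi / K)) %% K) + 1L
    i <- min(max(round(r * N / graph@maxRadius), 1L), N)
    c(ray = as.integer(k), index = as.integer(i))
}

#' Apply helper-seed constraints to a radial graph
#'
#' Each helper seed is mapped to its nearest ray \code{k} and radial node
#' index \code{i}; the cut on that ray is then forced to \code{c_k = i} by
#' infinity-capacity terminal edges (nodes at or inside \code{i} to the
#' source, nodes beyond \code{i} to the sink).  Neighboring rays adjust
#' through the \code{deltaR} smoothness constraint.  If two helpers map to
#' the same ray with different indices, the last one wins with a warning.
#'
#' @param graph a \linkS4class{RadialGraph}
#' @param helpers list of numeric (x, y) helper positions (pixels)
#' @return the graph with updated \code{pins}
#' @export
applyHelperConstraints <- function(graph, helpers) {
    for (h in helpers) {
        ki <- .helperToNode(graph, h)
        old <- graph@pins[ki["ray"]]
        if (!is.na(old) && old != ki["index"])
            warning("two helper seeds map to ray ", ki["ray"] - 1L,
                    " with different indices; the last one wins")
        graph@pins[ki["ray"]] <- ki["index"]
    }
    graph
}

## contour vertex radius per ray: midpoint between the last foreground node
## and the first background node; at c = N - 1 the vertex sits at maxRadius
.cutRadii <- function(cut, maxRadius, N) {
    pmin(cut@cutIndex + 1.5, N) * maxRadius / N
}

.contourFromCut <- function(graph, cut) {
    K <- nrow(graph@grays); N <- ncol(graph@grays)
    r <- .cutRadii(cut, graph@maxRadius, N)
    dirs <- .rayDirections(K)
    cbind(x = graph@seed[1] + dirs[, "dx"] * r,
          y = graph@seed[2] + dirs[, "dy"] * r)
}

## even-odd point-in-polygon test for pixel centers at integer coordinates;
## half-open edge rule: a point exactly on a left/top edge is inside, on a
## right/bottom edge outside (resolves boundary centers deterministically)
.pointInPolygon <- function(x, y, polyx, polyy) {
    n <- length(polyx)
    x2 <- c(polyx[-1], polyx[1]); y2 <- c(polyy[-1], polyy[1])
    inside <- logical(length(x))
    for (e in seq_len(n)) {
        ylo <- min(polyy[e], y2[e]); yhi <- max(polyy[e], y2[e])
        if (ylo == yhi) next
        sel <- ylo <= y & y < yhi
        if (!any(sel)) next
        xint <- polyx[e] + (y[sel] - polyy[e]) * (x2[e] - polyx[e]) /
            (y2[e] - polyy[e])
        inside[sel] <- xor(inside[sel], x[sel] < xint)
    }
    inside
}

#' Rasterize a closed polygon to a binary mask
#'
#' A pixel (integer coordinates, 0-based) is foreground iff its center lies
#' inside the polygon under the even-odd rule; centers exactly on an edge
#' are resolved by a half-open (top-left in, bottom-right out) rule so the
#' rasterization is deterministic.
#'
#' @param polygon matrix with columns (x, y) of polygon vertices (closed
#'   implicitly: the last vertex connects back to the first)
#' @param dim integer (rows, cols) = (height, width) of the target raster
#' @param spacing mm per pixel recorded on the mask
#' @return a \linkS4class{BinaryMask}
#' @examples
#' sq <- cbind(c(10, 10, 20, 20), c(10, 20, 20, 10))
#' sum(pixelMatrix(rasterizeContour(sq, c(32, 32))))  # 100 pixels
#' @export
rasterizeContour <- function(polygon, dim, spacing = 1) {
    polygon <- as.matrix(polygon)
    if (nrow(polygon) < 3L) stop("degenerate polygon: need >= 3 vertices")
    H <- dim[1]; W <- dim[2]
    m <- matrix(0, H, W)
    px <- polygon[, 1]; py <- polygon[, 2]
    ylo <- max(0L, ceiling(min(py))); yhi <- min(H - 1L, floor(max(py)))
    xlo <- max(0L, ceiling(min(px))); xhi <- min(W - 1L, floor(max(px)))
    if (yhi >= ylo && xhi >= xlo) {
        xs <- xlo:xhi
        x2 <- c(px[-1], px[1]); y2 <- c(py[-1], py[1])
        for (y in ylo:yhi) {
            sel <- pmin(py, y2) <= y & y < pmax(py, y2)
            if (!any(sel)) next
            xint <- px[sel] + (y - py[sel]) * (x2[sel] - px[sel]) /
                (y2[sel] - py[sel])
            xis <- sort(xint)
            cnt <- length(xis) - findInterval(xs, xis)
            m[y + 1L, xs[cnt %% 2L == 1L] + 1L] <- 1
        }
    }
    binaryMask(m, spacing = spacing)
}

#' Segment a lesion from a seed point
#'
#' End-to-end interactive segmentation step: builds the radial graph around
#' the seed, applies helper-seed constraints, solves the minimum s-t cut,
#' converts the per-ray cut indices to a closed star-shaped contour (one
#' sub-pixel vertex per ray at the midpoint between the last foreground and
#' first background node), rasterizes it to a binary mask and measures the
#' perpendicular diameters in millimeters.
#'
#' The function is pure: identical inputs give identical results, so an
#' interactive session (dragging the seed, adding helpers) is emulated by
#' repeated calls (see \code{\link{resegment}}).
#'
#' @param image an \linkS4class{UltrasoundImage}
#' @param seed numeric (x, y) seed inside the lesion
#' @param helpers list of numeric (x, y) helper seeds on the lesion border
#' @param params a \linkS4class{GraphParams}
#' @return a \linkS4class{SegmentationResult}
#' @examples
#' px <- matrix(120, 96, 96)
#' yy <- matrix(0:95, 96, 96); xx <- t(yy)
#' px[(xx - 48)^2 + (yy - 48)^2 <= 30^2] <- 20   # hypoechoic disc
#' res <- segmentLesion(ultrasoundImage(px), seed = c(48, 48))
#' res
#' @export
segmentLesion <- function(image, seed, helpers = list(),
                          params = graphParams()) {
    graph <- buildRadialGraph(image, seed, params)
    if (length(helpers)) graph <- applyHelperConstraints(graph, helpers)
    cut <- solveMinCut(graph)
    contour <- .contourFromCut(graph, cut)
    mask <- rasterizeContour(contour, dim(image@pixels),
                             spacing = image@spacing)
    dia <- diametersOfMask(mask, image@spacing)
    new("SegmentationResult", contour = contour, mask = mask, cut = cut,
        diameters = dia, params = params, seed = as.numeric(seed),
        helpers = helpers, image = image)
}

#' Re-run a segmentation with a moved seed or extra helper seeds
#'
#' Emulates the interactive refinement loop (dragging the seed inside the
#' lesion, adding helper seeds on its border).  The call is referentially
#' transparent: it is exactly equivalent to a fresh \code{segmentLesion}
#' with the new seed and the union of the accumulated helper seeds.
#'
#' @param previous a \linkS4class{SegmentationResult}
#' @param newSeed optional numeric (x, y) replacement for the primary seed
#' @param addHelpers list of additional helper seeds
#' @return a new \linkS4class{SegmentationResult}
#' @export
resegment <- function(previous, newSeed = NULL, addHelpers = list()) {
    stopifnot(is(previous, "SegmentationResult"))
    seed <- if (is.null(newSeed)) previous@seed else as.numeric(newSeed)
    segmentLesion(previous@image, seed,
                  helpers = c(previous@helpers, addHelpers),
                  params = previous@params)
}
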