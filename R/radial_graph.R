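## radial-ray graph construction and the s-t minimum cut

## direction of ray k (0-based) of K rays: angles 2*pi*k/K measured clockwise
## on screen (y grows downward) starting from "up" (0, -1)
.rayDirections <- function(K) {
    theta <- 2 * pi * (seq_len(K) - 1L) / K
    cbind(dx = sin(theta), dy = -cos(theta))
}

## bilinear interpolation at sub-pixel (x, y), 0-based; out-of-image
## positions clamp to the border pixel
.bilinear <- function(pixels, x, y) {
    H <- nrow(pixels); W <- ncol(pixels)
    x <- pmin(pmax(x, 0), W - 1)
    y <- pmin(pmax(y, 0), H - 1)
    x0 <- floor(x); y0 <- floor(y)
    x1 <- pmin(x0 + 1, W - 1); y1 <- pmin(y0 + 1, H - 1)
    fx <- x - x0; fy <- y - y0
    p00 <- pixels[cbind(y0 + 1, x0 + 1)]
    p10 <- pixels[cbind(y0 + 1, x1 + 1)]
    p01 <- pixels[cbind(y1 + 1, x0 + 1)]
    p11 <- pixels[cbind(y1 + 1, x1 + 1)]
    (1 - fy) * ((1 - fx) * p00 + fx * p10) +
        fy * ((1 - fx) * p01 + fx * p11)
}

.resolveMaxRadius <- function(image, seed, params) {
    if (!is.na(params@maxRadius)) return(params@maxRadius)
    H <- nrow(image@pixels); W <- ncol(image@pixels)
    border <- min(seed[1], W - 1 - seed[1], seed[2], H - 1 - seed[2])
    max(min(border, 0.45 * min(H, W)), params@nNodes)
}

.checkSeedInside <- function(image, seed) {
    H <- nrow(image@pixels); W <- ncol(image@pixels)
    if (length(seed) != 2L || anyNA(seed) ||
        seed[1] < 0 || seed[1] > W - 1 || seed[2] < 0 || seed[2] > H - 1)
        stop("seed point (", paste(seed, collapse = ", "),
             ") is outside the image")
}

#' Sample gray values along radial rays
#'
#' Places \code{K x N} nodes around the seed: node \code{(k, i)} (both
#' 0-based) lies at radius \code{(i + 1) * maxRadius / N} along ray
#' \code{k}, whose angle is \code{2 * pi * k / K} measured clockwise on
#' screen starting from "up".  Gray values are sampled by bilinear
#' interpolation; positions outside the image clamp to the border pixel.
#' Terminal capacities are left empty (zero): use
#' \code{\link{buildRadialGraph}} for the full graph.
#'
#' @param image an \linkS4class{UltrasoundImage}
#' @param seed numeric (x, y) seed position, 0-based pixels, strictly inside
#' @param params a \linkS4class{GraphParams}
#' @return a \linkS4class{RadialGraph} with node positions and grays only
#' @export
sampleRays <- function(image, seed, params = graphParams()) {
    .checkSeedInside(image, seed)
    K <- params@nRays; N <- params@nNodes
    mr <- .resolveMaxRadius(image, seed, params)
    dirs <- .rayDirections(K)
    radii <- seq_len(N) * mr / N
    nodeX <- seed[1] + outer(dirs[, "dx"], radii)     # K x N
    nodeY <- seed[2] + outer(dirs[, "dy"], radii)
    grays <- matrix(.bilinear(image@pixels, as.vector(nodeX),
                              as.vector(nodeY)), K, N)
    new("RadialGraph", nodeX = nodeX, nodeY = nodeY, grays = grays,
        termSide = matrix(1L, K, N), termCap = matrix(0, K, N),
        deltaR = params@deltaR, seed = as.numeric(seed),
        avgGray = NA_real_, maxRadius = mr, pins = rep(NA_integer_, K))
}

#' Average gray value around the seed point
#'
#' Arithmetic mean of the \code{window x window} square of pixels centered
#' at the (rounded) seed, clipped to the image bounds.
#'
#' @param image an \linkS4class{UltrasoundImage}
#' @param seed numeric (x, y), inside the image
#' @param window odd window side length in pixels
#' @return the mean gray value
#' @export
averageSeedGray <- function(image, seed, window = 9) {
    .checkSeedInside(image, seed)
    h <- (window - 1) / 2
    H <- nrow(image@pixels); W <- ncol(image@pixels)
    cx <- round(seed[1]); cy <- round(seed[2])
    xs <- max(0, cx - h):min(W - 1, cx + h)
    ys <- max(0, cy - h):min(H - 1, cy + h)
    mean(image@pixels[ys + 1, xs + 1])
}

#' Terminal edge weights from a gray-value profile
#'
#' Implements the terminal binding rule of the radial graph.  With
#' \code{a_i = |g_i - m|} (node 0 innermost): node 0 is bound to the source
#' with capacity \code{a_0}, node \code{N-1} to the sink with capacity
#' \code{a_{N-1}}, and each interior node \code{i} with capacity
#' \code{|a_i - a_{i-1}|} to the source when \code{a_i - a_{i-1} < 0} and to
#' the sink otherwise (a zero difference ties to the sink).
#'
#' @param grays numeric matrix (rays x nodes) or vector of sampled grays
#' @param m the reference (seed-average) gray value
#' @return list with integer matrix \code{side} (0 = source, 1 = sink) and
#'   numeric matrix \code{cap} of the same shape as \code{grays}
#' @examples
#' terminalWeights(c(20, 20, 120, 120), m = 20)
#' @export
terminalWeights <- function(grays, m) {
    if (is.null(dim(grays))) grays <- matrix(grays, nrow = 1)
    N <- ncol(grays)
    stopifnot(N >= 2)
    a <- abs(grays - m)
    side <- matrix(1L, nrow(grays), N)
    cap <- matrix(0, nrow(grays), N)
    side[, 1] <- 0L
    cap[, 1] <- a[, 1]
    cap[, N] <- a[, N]
    if (N > 2) {
        d <- a[, 2:(N - 1), drop = FALSE] - a[, 1:(N - 2), drop = FALSE]
        side[, 2:(N - 1)] <- ifelse(d < 0, 0L, 1L)
        cap[, 2:(N - 1)] <- abs(d)
    }
    list(side = side, cap = cap)
}

#' Build the full radial graph around a seed
#'
#' Samples the rays, computes the seed-average gray value and attaches the
#' terminal capacities of \code{\link{terminalWeights}}.  The
#' infinity-weighted intra-edges (outward to inward along each ray) and
#' inter-edges (to radial index \code{max(0, i - deltaR)} on both adjacent
#' rays, wrapping around) are implied by the stored geometry and
#' materialized by \code{\link{solveMinCut}}; they guarantee that every
#' finite-capacity cut is star-shaped and satisfies the circular smoothness
#' constraint \code{|c_k - c_{k+1}| <= deltaR}.
#'
#' @inheritParams sampleRays
#' @return a \linkS4class{RadialGraph}
#' @examples
#' img <- ultrasoundImage(matrix(100, 64, 64))
#' g <- buildRadialGraph(img, c(32, 32), graphParams(nRays = 8, nNodes = 10))
#' g
#' @export
buildRadialGraph <- function(image, seed, params = graphParams()) {
    g <- sampleRays(image, seed, params)
    m <- averageSeedGray(image, seed, params@avgWindow)
    tw <- terminalWeights(g@grays, m)
    g@termSide <- tw$side
    g@termCap <- tw$cap
    g@avgGray <- m
    g
}

#' Construct a radial graph from explicit terminal weights
#'
#' Programmatic constructor used for testing and experimentation: builds a
#' \linkS4class{RadialGraph} directly from terminal sides and capacities,
#' with dummy node geometry.
#'
#' @param side integer matrix (rays x nodes), 0 = source, 1 = sink
#' @param cap non-negative capacity matrix of the same shape
#' @param deltaR smoothness parameter
#' @return a \linkS4class{RadialGraph}
#' @export
newRadialGraph <- function(side, cap, deltaR = 2) {
    side <- as.matrix(side); storage.mode(side) <- "integer"
    cap <- as.matrix(cap)
    K <- nrow(cap); N <- ncol(cap)
    radii <- seq_len(N)
    dirs <- .rayDirections(K)
    new("RadialGraph",
        nodeX = outer(dirs[, "dx"], radii), nodeY = outer(dirs[, "dy"], radii),
        grays = cap, termSide = side, termCap = cap,
        deltaR = as.integer(deltaR), seed = c(0, 0), avgGray = NA_real_,
        maxRadius = as.numeric(N), pins = rep(NA_integer_, K))
}

## edge list of the full directed graph; node ids: (k - 1) * N + i for
## 1-based ray k and node i, source = K * N + 1, sink = K * N + 2
.graphEdges <- function(graph) {
    K <- nrow(graph@termCap); N <- ncol(graph@termCap)
    INF <- sum(graph@termCap) + 1
    id <- function(k, i) (k - 1L) * N + i
    ks <- rep(seq_len(K), each = N - 1L)
    is <- rep(2:N, times = K)
    intra <- cbind(id(ks, is), id(ks, is - 1L))
    ka <- rep(seq_len(K), each = N)
    ia <- rep(seq_len(N), times = K)
    tgt <- pmax(1L, ia - graph@deltaR)
    inter <- NULL
    if (K >= 2L) {
        nxt <- ka %% K + 1L
        prv <- (ka - 2L) %% K + 1L
        inter <- rbind(cbind(id(ka, ia), id(nxt, tgt)),
                       cbind(id(ka, ia), id(prv, tgt)))
    }
    s <- K * N + 1L; t <- K * N + 2L
    sideV <- as.vector(t(graph@termSide))   # ordered by id
    capV <- as.vector(t(graph@termCap))
    allIds <- seq_len(K * N)
    term <- rbind(cbind(s, allIds[sideV == 0L]),
                  cbind(allIds[sideV == 1L], t))
    termCapV <- c(capV[sideV == 0L], capV[sideV == 1L])
    pinFrom <- pinTo <- integer(0)
    if (any(!is.na(graph@pins))) {
        for (k in which(!is.na(graph@pins))) {
            p <- graph@pins[k]
            pinFrom <- c(pinFrom, rep(s, p), id(k, seq_len(N - p) + p))
            pinTo <- c(pinTo, id(k, seq_len(p)), rep(t, N - p))
        }
    }
    edges <- rbind(intra, inter, term, cbind(pinFrom, pinTo))
    caps <- c(rep(INF, nrow(intra) + if (is.null(inter)) 0L else nrow(inter)),
              termCapV, rep(INF, length(pinFrom)))
    list(edges = edges, caps = caps, s = s, t = t, K = K, N = N, INF = INF)
}

#' Solve the minimum s-t cut of a radial graph
#'
#' Computes the globally optimal minimum s-t cut (by max-flow) of the radial
#' graph, including any helper-seed pin constraints, and converts it to
#' per-ray cut indices.  When several minimum cuts exist the unique
#' *outermost* one is returned (the maximal source side, obtained by
#' residual-graph reachability), which makes the result deterministic.
#'
#' @param graph a \linkS4class{RadialGraph}
#' @return a \linkS4class{CutResult}
#' @export
solveMinCut <- function(graph) {
    ge <- .graphEdges(graph)
    g <- igraph::graph_from_edgelist(ge$edges, directed = TRUE)
    if (igraph::vcount(g) < ge$K * ge$N + 2L)
        g <- igraph::add_vertices(g, ge$K * ge$N + 2L - igraph::vcount(g))
    mf <- igraph::max_flow(g, ge$s, ge$t, capacity = ge$caps)
    if (mf$value >= ge$INF - 1e-9)
        stop("no finite-capacity cut: helper-seed constraints are jointly ",
             "infeasible under deltaR = ", graph@deltaR)
    ## maximal source side: complement of the set of vertices that can still
    ## reach t in the residual graph
    flow <- mf$flow
    tol <- 1e-9 * max(1, max(ge$caps[is.finite(ge$caps)]))
    fwd <- ge$caps - flow > tol          # residual forward arcs
    bwd <- flow > tol                    # residual backward arcs
    resEdges <- rbind(ge$edges[fwd, , drop = FALSE],
                      ge$edges[bwd, c(2, 1), drop = FALSE])
    gr <- igraph::graph_from_edgelist(resEdges, directed = TRUE)
    if (igraph::vcount(gr) < ge$K * ge$N + 2L)
        gr <- igraph::add_vertices(gr, ge$K * ge$N + 2L - igraph::vcount(gr))
    reachT <- as.integer(igraph::subcomponent(gr, ge$t, mode = "in"))
    inS <- rep(TRUE, ge$K * ge$N + 2L)
    inS[reachT] <- FALSE
    nodeS <- matrix(inS[seq_len(ge$K * ge$N)], nrow = ge$K, ncol = ge$N,
                    byrow = TRUE)
    cutIdx <- apply(nodeS, 1, function(row) {
        w <- which(row)
        if (length(w)) max(w) else 1L    # innermost node is always foreground
    })
    new("CutResult", cutIndex = as.integer(cutIdx) - 1L,
        flowValue = mf$value)
}

#' Exact minimum cut by dynamic programming (independent oracle)
#'
#' Independent reference solver: enumerates the cut index of the first ray
#' and runs a dynamic program over the remaining rays on the cycle, subject
#' to the circular constraint \code{|c_k - c_{k+1}| <= deltaR}; the per-ray
#' cost of cutting at index \code{c} is the summed capacity of the terminal
#' edges severed there.  Intended for small instances only.
#'
#' @param graph a \linkS4class{RadialGraph}
#' @param maxCells guard on \code{K * N^2}; larger instances raise an error
#' @return a \linkS4class{CutResult}
#' @export
oracleMinCut <- function(graph) {
    K <- nrow(graph@termCap); N <- ncol(graph@termCap)
    if (K * N^2 > 2e6)
        stop("instance too large for the dynamic-programming oracle")
    dr <- graph@deltaR
    ## per-ray cost of a cut at (1-based) index c: sink capacities of nodes
    ## <= c plus source capacities of nodes > c
    cost <- matrix(0, K, N)
    for (k in seq_len(K)) {
        sink <- graph@termCap[k, ] * (graph@termSide[k, ] == 1L)
        src <- graph@termCap[k, ] * (graph@termSide[k, ] == 0L)
        cost[k, ] <- cumsum(sink) + rev(cumsum(rev(src))) - src
        if (!is.na(graph@pins[k])) {
            masked <- rep(Inf, N)
            masked[graph@pins[k]] <- cost[k, graph@pins[k]]
            cost[k, ] <- masked
        }
    }
    if (K == 1L) {
        best <- which.min(cost[1, ])
        return(new("CutResult", cutIndex = best - 1L,
                   flowValue = cost[1, best]))
    }
    window <- function(v, c) {          # min of v over |j - c| <= dr, argmin
        lo <- max(1L, c - dr); hi <- min(N, c + dr)
        j <- lo:hi
        jm <- j[which.min(v[j])]
        c(v[jm], jm)
    }
    bestVal <- Inf; bestIdx <- NULL
    firstRange <- if (!is.na(graph@pins[1])) graph@pins[1] else seq_len(N)
    for (c1 in firstRange) {
        if (!is.finite(cost[1, c1])) next
        dp <- rep(Inf, N); arg <- matrix(NA_integer_, K, N)
        dp[c1] <- cost[1, c1]
        dpPrev <- dp
        for (k in 2:K) {
            dpNew <- rep(Inf, N)
            for (c in seq_len(N)) {
                if (!is.finite(cost[k, c])) next
                w <- window(dpPrev, c)
                if (is.finite(w[1])) {
                    dpNew[c] <- w[1] + cost[k, c]
                    arg[k, c] <- w[2]
                }
            }
            dpPrev <- dpNew
        }
        feas <- which(abs(seq_len(N) - c1) <= dr & is.finite(dpPrev))
        if (!length(feas)) next
        cK <- feas[which.min(dpPrev[feas])]
        if (dpPrev[cK] < bestVal - 1e-12) {
            bestVal <- dpPrev[cK]
            idx <- integer(K); idx[K] <- cK
            for (k in K:2) idx[k - 1L] <- arg[k, idx[k]]
            bestIdx <- idx
        }
    }
    if (is.null(bestIdx))
        stop("no feasible cut: pin constraints are jointly infeasible")
    new("CutResult", cutIndex = as.integer(bestIdx) - 1L,
        flowValue = bestVal)
}

#' Dump the graph as an edge-list text file
#'
#' Debug helper: writes every directed edge as
#' \code{from_id,to_id,capacity}, with node ids \code{(k-1)*N + i}
#' (1-based), source \code{K*N + 1} and sink \code{K*N + 2}.
#'
#' @param graph a \linkS4class{RadialGraph}
#' @param path output text file
#' @return invisibly, the path
#' @export
dumpGraphEdges <- function(graph, path) {
    ge <- .graphEdges(graph)
    utils::write.table(data.frame(from = ge$edges[, 1], to = ge$edges[, 2],
                                  capacity = ge$caps),
                       path, sep = ",", row.names = FALSE, col.names = FALSE)
    invisible(path)
}
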