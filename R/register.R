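# Cycle-to-cycle alignment and tile stitching in a per-section frame.
# Coarse alignment is frequency-based (normalized cross-power spectrum of
# images or rasterized dot clouds); refinement is gated nearest-neighbour
# pairing with least-squares affine/projective fits. No non-linear
# transformations are applied.

#' Apply and compose planar transforms
#'
#' Transforms map source (x, y) row vectors into the reference frame via
#' the homogeneous matrix. `composeTransforms(a, b)` returns the
#' transform equivalent to applying `a` first, then `b`.
#'
#' @param transform a \linkS4class{Transform2D}.
#' @param xy n x 2 matrix or data.frame of coordinates.
#' @param a,b transforms to compose (a first).
#' @return `applyTransform`: n x 2 matrix; `composeTransforms`,
#'   `invertTransform`: a \linkS4class{Transform2D}.
#' @export
applyTransform <- function(transform, xy) {
    xy <- as.matrix(xy)
    h <- cbind(xy[, 1], xy[, 2], 1) %*% transform@matrix
    h[, 1:2, drop = FALSE] / h[, 3]
}

#' @rdname applyTransform
#' @export
composeTransforms <- function(a, b) {
    kinds <- c(a@kind, b@kind)
    kind <- if ("projective" %in% kinds) "projective"
            else if ("affine" %in% kinds) "affine" else "translation"
    transform2d(a@matrix %*% b@matrix, kind = kind,
                rmsResidual = max(a@rmsResidual, b@rmsResidual),
                nSupport = min(a@nSupport, b@nSupport),
                lowConfidence = a@lowConfidence || b@lowConfidence)
}

#' @rdname applyTransform
#' @export
invertTransform <- function(transform) {
    transform2d(solve(transform@matrix), kind = transform@kind,
                rmsResidual = transform@rmsResidual,
                nSupport = transform@nSupport,
                lowConfidence = transform@lowConfidence)
}

.translationTransform <- function(dx, dy, rms = 0, n = 0, low = FALSE) {
    m <- diag(3)
    m[3, 1] <- dx
    m[3, 2] <- dy
    transform2d(m, kind = "translation", rmsResidual = rms, nSupport = n,
                lowConfidence = low)
}

# 2-D phase correlation surface of two equal-size matrices
.phaseCorrSurface <- function(a, b) {
    fa <- stats::fft(a)
    fb <- stats::fft(b)
    cp <- fa * Conj(fb)
    mag <- Mod(cp)
    mag[mag < 1e-12] <- 1e-12
    Re(stats::fft(cp / mag, inverse = TRUE)) / length(a)
}

#' Pre-alignment by phase correlation
#'
#' Estimates the translation between two images (or two rasterized dot
#' tables) as the peak of the normalized cross-power spectrum, refined to
#' subpixel precision by parabolic interpolation around the peak. A weak
#' correlation peak flags the transform as low-confidence.
#'
#' @param a,b numeric matrices (same size), or data.frames with x/y
#'   columns which are rasterized with [rasterizeDots()] on a common
#'   grid.
#' @param binSize raster bin size in pixels when a/b are dot tables.
#' @param minPeak confidence floor on the normalized peak height.
#' @return a translation \linkS4class{Transform2D} such that applying it
#'   to `a` coordinates aligns them with `b`.
#' @export
prealignTranslation <- function(a, b, binSize = 1, minPeak = 0.1) {
    if (is.data.frame(a) || is.data.frame(b)) {
        rng <- list(
            x = range(c(a$x, b$x)) + c(-2, 2) * binSize,
            y = range(c(a$y, b$y)) + c(-2, 2) * binSize)
        a <- rasterizeDots(a, binSize, rng)
        b <- rasterizeDots(b, binSize, rng)
    } else {
        binSize <- 1
    }
    stopifnot(all(dim(a) == dim(b)))
    surf <- .phaseCorrSurface(b, a)  # peak at (dy, dx) of a -> b
    peak <- which(surf == max(surf), arr.ind = TRUE)[1, , drop = TRUE]
    ny <- nrow(surf); nx <- ncol(surf)
    wrap <- function(i, n) ifelse(i - 1 > n / 2, i - 1 - n, i - 1)
    dy <- wrap(peak[1], ny)
    dx <- wrap(peak[2], nx)
    # parabolic subpixel refinement with wrapped neighbours
    at <- function(i, j) surf[(i - 1) %% ny + 1, (j - 1) %% nx + 1]
    denY <- at(peak[1] - 1, peak[2]) - 2 * at(peak[1], peak[2]) +
            at(peak[1] + 1, peak[2])
    if (is.finite(denY) && denY < 0)
        dy <- dy + 0.5 * (at(peak[1] - 1, peak[2]) -
                          at(peak[1] + 1, peak[2])) / denY
    denX <- at(peak[1], peak[2] - 1) - 2 * at(peak[1], peak[2]) +
            at(peak[1], peak[2] + 1)
    if (is.finite(denX) && denX < 0)
        dx <- dx + 0.5 * (at(peak[1], peak[2] - 1) -
                          at(peak[1], peak[2] + 1)) / denX
    low <- max(surf) < minPeak
    .translationTransform(dx * binSize, dy * binSize, n = 0, low = low)
}

#' Rasterize a dot table
#'
#' @param dots data.frame with x, y columns (pixels).
#' @param binSize bin edge length in pixels.
#' @param rng optional list(x=, y=) of ranges defining the grid.
#' @return a count matrix (rows = y bins, cols = x bins).
#' @export
rasterizeDots <- function(dots, binSize = 1, rng = NULL) {
    if (is.null(rng))
        rng <- list(x = range(dots$x), y = range(dots$y))
    bx <- seq(floor(rng$x[1] / binSize) * binSize,
              ceiling((rng$x[2] + binSize) / binSize) * binSize, by = binSize)
    by <- seq(floor(rng$y[1] / binSize) * binSize,
              ceiling((rng$y[2] + binSize) / binSize) * binSize, by = binSize)
    ix <- findInterval(dots$x, bx, rightmost.closed = TRUE)
    iy <- findInterval(dots$y, by, rightmost.closed = TRUE)
    m <- matrix(0, length(by) - 1, length(bx) - 1)
    ok <- ix >= 1 & ix < length(bx) & iy >= 1 & iy < length(by)
    if (any(ok)) {
        tab <- table(factor(iy[ok], levels = seq_len(nrow(m))),
                     factor(ix[ok], levels = seq_len(ncol(m))))
        m <- m + unclass(tab)
    }
    m
}

# least-squares affine fit src -> ref (n x 2 each); returns 3x3
.fitAffine <- function(src, ref) {
    A <- cbind(src, 1)
    px <- stats::lm.fit(A, ref[, 1])$coefficients
    py <- stats::lm.fit(A, ref[, 2])$coefficients
    m <- diag(3)
    m[, 1] <- c(px[1], px[2], px[3])
    m[, 2] <- c(py[1], py[2], py[3])
    m[, 3] <- c(0, 0, 1)
    m
}

# projective fit via normalized DLT
.fitProjective <- function(src, ref) {
    n <- nrow(src)
    A <- matrix(0, 2 * n, 9)
    for (i in seq_len(n)) {
        x <- src[i, 1]; y <- src[i, 2]
        u <- ref[i, 1]; v <- ref[i, 2]
        A[2 * i - 1, ] <- c(x, y, 1, 0, 0, 0, -u * x, -u * y, -u)
        A[2 * i, ]     <- c(0, 0, 0, x, y, 1, -v * x, -v * y, -v)
    }
    h <- svd(A, nu = 0)$v[, 9]
    H <- matrix(h, 3, 3, byrow = TRUE)  # row-vector convention transpose
    m <- t(H)
    m / m[3, 3]
}

#' Register two point clouds
#'
#' Frequency-based coarse alignment (phase correlation of 1-px rasters)
#' followed by iterated gated nearest-neighbour pairing and least-squares
#' affine (or projective) refinement, until the rms residual changes by
#' less than `tol` or `maxIter` iterations.
#'
#' @param src,ref data.frames with x, y columns (pixels).
#' @param kind "affine" (default), "projective", or "translation".
#'   Projective fits additionally require `nSupport >= projectiveMin`.
#' @param gate nearest-neighbour pairing gate in pixels.
#' @param minPoints minimum points per cloud.
#' @param minPairs minimum gated pairs needed for a model fit.
#' @param tol rms convergence tolerance in pixels.
#' @param maxIter iteration cap.
#' @param binSize raster bin size for the coarse stage.
#' @param projectiveMin support needed before a projective model is used.
#' @return a \linkS4class{Transform2D} mapping src into the ref frame.
#' @export
registerPointClouds <- function(src, ref, kind = c("affine", "projective",
                                                   "translation"),
                                gate = 5, minPoints = 10, minPairs = 4,
                                tol = 0.01, maxIter = 20, binSize = 1,
                                projectiveMin = 50) {
    kind <- match.arg(kind)
    if (nrow(src) < minPoints || nrow(ref) < minPoints)
        stop(sprintf("need >= %d points per cloud (got %d, %d)",
                     minPoints, nrow(src), nrow(ref)))
    tr <- prealignTranslation(src, ref, binSize = binSize)
    m <- tr@matrix
    srcXY <- as.matrix(src[, c("x", "y")])
    refXY <- as.matrix(ref[, c("x", "y")])
    rmsPrev <- Inf
    rms <- Inf
    nSupport <- 0L
    for (it in seq_len(maxIter)) {
        cur <- cbind(srcXY, 1) %*% m
        cur <- cur[, 1:2, drop = FALSE] / cur[, 3]
        d <- crossDist(cur, refXY)
        j <- max.col(-d, ties.method = "first")
        dd <- d[cbind(seq_along(j), j)]
        ok <- dd <= gate
        if (sum(ok) < minPairs) {
            if (it == 1)
                stop(sprintf("insufficient pairs after gating (n_support=%d)",
                             sum(ok)))
            break
        }
        pairsSrc <- srcXY[ok, , drop = FALSE]
        pairsRef <- refXY[j[ok], , drop = FALSE]
        nSupport <- sum(ok)
        useProjective <- kind == "projective" && nSupport >= projectiveMin
        m <- if (kind == "translation") {
            dm <- diag(3)
            dm[3, 1:2] <- colMeans(pairsRef) - colMeans(pairsSrc)
            dm
        } else if (useProjective) {
            .fitProjective(pairsSrc, pairsRef)
        } else {
            .fitAffine(pairsSrc, pairsRef)
        }
        fit <- cbind(pairsSrc, 1) %*% m
        fit <- fit[, 1:2, drop = FALSE] / fit[, 3]
        rms <- sqrt(mean(rowSums((fit - pairsRef)^2)))
        if (abs(rmsPrev - rms) < tol) break
        rmsPrev <- rms
    }
    transform2d(m,
                kind = if (kind == "projective" && nSupport >= projectiveMin)
                           "projective" else kind,
                rmsResidual = rms, nSupport = nSupport,
                lowConfidence = tr@lowConfidence)
}

#' Align sequencing cycles to a reference cycle
#'
#' Registers each cycle's dot cloud to its neighbour toward the reference
#' cycle (mid-sequencing by default) and composes the per-step transforms
#' into a transform chain into the reference frame. A cycle that cannot
#' be registered (too few dots or no gated pairs) keeps its pre-alignment
#' (identity) transform, flagged low-confidence.
#'
#' @param dotsByCycle named list of dot tables (x, y), names = cycle ids
#'   or in cycle order.
#' @param reference index of the reference cycle (default the middle).
#' @param ... passed to [registerPointClouds()].
#' @return list of \linkS4class{Transform2D}, one per cycle, mapping that
#'   cycle's coordinates into the reference frame.
#' @export
alignCyclesToReference <- function(dotsByCycle, reference = NULL, ...) {
    n <- length(dotsByCycle)
    if (is.null(reference)) reference <- ceiling(n / 2)
    stopifnot(reference >= 1, reference <= n)
    step <- vector("list", n)
    step[[reference]] <- transform2d()
    out <- vector("list", n)
    out[[reference]] <- transform2d()
    for (c0 in setdiff(seq_len(n), reference)) {
        nb <- c0 + sign(reference - c0)  # neighbour toward the reference
        t0 <- tryCatch(
            registerPointClouds(dotsByCycle[[c0]], dotsByCycle[[nb]], ...),
            error = function(e) transform2d(lowConfidence = TRUE))
        step[[c0]] <- t0
    }
    for (c0 in order(abs(seq_len(n) - reference))) {
        if (c0 == reference) next
        if (step[[c0]]@lowConfidence && step[[c0]]@nSupport == 0L) {
            # registration failed outright: keep the pre-alignment
            # (identity in the pre-aligned frame), flagged
            out[[c0]] <- step[[c0]]
            next
        }
        nb <- c0 + sign(reference - c0)
        out[[c0]] <- composeTransforms(step[[c0]], out[[nb]])
    }
    names(out) <- names(dotsByCycle)
    out
}

#' Stitch tiles into a section frame
#'
#' Places tiles into a global section frame starting from nominal imaging
#' offsets, merging tiles in descending rolony-count order: each new tile
#' is registered (translation refinement) against the union of dots from
#' already-placed tiles, so tiles with few rolonies are stitched to tiles
#' with many. Overlap duplicates are retained (deduplicated later
#' per-barcode downstream). A tile without placed content to register
#' against keeps its nominal offset and starts a new component, with a
#' warning.
#'
#' @param dotsByTile named list of per-tile dot tables (x, y in tile
#'   pixels).
#' @param layout data.frame with tile, offsetX, offsetY (nominal tile
#'   origins in section-frame pixels).
#' @param gate pairing gate for the refinement (px).
#' @param overlapMargin how far (px) beyond a tile's bounds placed dots
#'   are considered overlap context.
#' @return list with `dots` (section-frame table with tile column) and
#'   `transforms` (per-tile \linkS4class{Transform2D}).
#' @export
stitchTiles <- function(dotsByTile, layout, gate = 5, overlapMargin = 0) {
    tiles <- names(dotsByTile)
    stopifnot(!is.null(tiles), all(tiles %in% as.character(layout$tile)))
    counts <- vapply(dotsByTile, nrow, integer(1))
    ord <- tiles[order(-counts)]
    placed <- NULL
    transforms <- stats::setNames(vector("list", length(tiles)), tiles)
    for (tl in ord) {
        li <- layout[as.character(layout$tile) == tl, ]
        nominal <- dotsByTile[[tl]]
        nominal$x <- nominal$x + li$offsetX
        nominal$y <- nominal$y + li$offsetY
        tr <- .translationTransform(li$offsetX, li$offsetY)
        if (!is.null(placed) && nrow(nominal) >= 3) {
            near <- placed[placed$x >= min(nominal$x) - gate - overlapMargin &
                           placed$x <= max(nominal$x) + gate + overlapMargin &
                           placed$y >= min(nominal$y) - gate - overlapMargin &
                           placed$y <= max(nominal$y) + gate + overlapMargin, ]
            if (nrow(near) >= 3) {
                ref <- tryCatch(
                    registerPointClouds(nominal, near, kind = "translation",
                                        gate = gate, minPoints = 3,
                                        minPairs = 3),
                    error = function(e) NULL)
                if (!is.null(ref) && !ref@lowConfidence) {
                    adj <- applyTransform(ref, nominal[, c("x", "y")])
                    nominal$x <- adj[, 1]
                    nominal$y <- adj[, 2]
                    tr <- composeTransforms(tr, ref)
                }
            } else {
                warning(sprintf("tile %s has no placed overlap; using nominal offset",
                                tl))
            }
        }
        nominal$tile <- tl
        placed <- rbind(placed, nominal)
        transforms[[tl]] <- tr
    }
    rownames(placed) <- NULL
    list(dots = placed, transforms = transforms)
}

#' Apply a sampled displacement field to points
#'
#' Thin applicator for externally fitted non-rigid corrections (e.g.
#' section-to-volume registration): bilinearly interpolates a vector
#' field sampled on a regular grid and adds it to the coordinates.
#'
#' @param points data.frame or matrix with x, y (same units as the grid).
#' @param grid list with `x`, `y` (ascending sample coordinates), `dx`,
#'   `dy` (matrices, rows = y samples, cols = x samples).
#' @return displaced n x 2 matrix.
#' @export
applyDisplacementField <- function(points, grid) {
    pts <- as.matrix(points[, c("x", "y")])
    interp <- function(m, px, py) {
        ix <- findInterval(px, grid$x, all.inside = TRUE)
        iy <- findInterval(py, grid$y, all.inside = TRUE)
        fx <- (px - grid$x[ix]) / diff(grid$x)[ix]
        fy <- (py - grid$y[iy]) / diff(grid$y)[iy]
        fx <- pmin(pmax(fx, 0), 1)
        fy <- pmin(pmax(fy, 0), 1)
        m[cbind(iy, ix)] * (1 - fx) * (1 - fy) +
            m[cbind(iy, ix + 1)] * fx * (1 - fy) +
            m[cbind(iy + 1, ix)] * (1 - fx) * fy +
            m[cbind(iy + 1, ix + 1)] * fx * fy
    }
    cbind(x = pts[, 1] + interp(grid$dx, pts[, 1], pts[, 2]),
          y = pts[, 2] + interp(grid$dy, pts[, 1], pts[, 2]))
}
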