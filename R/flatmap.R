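# Cortical flatmap construction from a labeled volume: outer/inner
# boundary extraction, column lines from each outer boundary voxel to its
# nearest inner boundary voxel, per-voxel depth%, and a mid-cortical
# reference plate flattened into AP/ML coordinates by cumulative geodesic
# distance from median reference contours. Hemispheres are processed
# independently.

# voxel index matrix (n x 3) -> micrometre centre coordinates
.voxelCenters <- function(idx, voxelSize) {
    (idx - 0.5) * voxelSize
}

# n x 3 index matrix of voxels where mask is TRUE
.maskWhich <- function(mask) {
    which(mask, arr.ind = TRUE)
}

# shift a logical 3-D array by one voxel along axis (filling FALSE)
.shift3 <- function(a, axis, by) {
    d <- dim(a)
    out <- array(FALSE, d)
    src <- lapply(d, seq_len)
    dst <- src
    if (by > 0) { src[[axis]] <- 1:(d[axis] - 1); dst[[axis]] <- 2:d[axis] }
    else { src[[axis]] <- 2:d[axis]; dst[[axis]] <- 1:(d[axis] - 1) }
    out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
    out
}

#' Extract outer and inner cortical boundaries
#'
#' The outer boundary is the set of cortical voxels with a 6-neighbour
#' carrying the outside label (or lying on the volume edge facing
#' outside); the inner boundary is the set with a 6-neighbour carrying
#' an interior label.
#'
#' @param vol an \linkS4class{AnnotationVolume}.
#' @return list with `outer` and `inner` (n x 3 voxel index matrices) and
#'   `cortexMask` (logical array).
#' @export
extractBoundaries <- function(vol) {
    lab <- vol@labels
    cortex <- array(lab %in% vol@cortexLabels, dim(lab))
    if (!any(cortex)) stop("no voxels carry a cortex label")
    outside <- array(lab %in% vol@outsideLabel, dim(lab))
    interior <- array(lab %in% vol@interiorLabels, dim(lab))
    if (!any(interior)) stop("no voxels carry an interior label")
    nearOutside <- array(FALSE, dim(lab))
    nearInterior <- array(FALSE, dim(lab))
    for (axis in 1:3) for (by in c(-1, 1)) {
        nearOutside <- nearOutside | .shift3(outside, axis, by)
        nearInterior <- nearInterior | .shift3(interior, axis, by)
    }
    outer <- cortex & nearOutside
    inner <- cortex & nearInterior
    if (!any(outer) || !any(inner))
        stop("cortex labels do not form a shell between outside and interior")
    if (any(outer & inner))
        warning("one-voxel-thick shell: some voxels are both outer and inner")
    list(outer = .maskWhich(outer), inner = .maskWhich(inner),
         cortexMask = cortex)
}

#' Compute cortical columns and per-voxel depth
#'
#' Draws a column line from each outer boundary voxel to its closest
#' inner boundary voxel, assigns every cortical voxel to its nearest
#' column (point-to-segment distance) and computes depth as the
#' fractional arc position along that column, in percent (0 at the outer
#' boundary, 100 at the inner).
#'
#' @param vol an \linkS4class{AnnotationVolume}.
#' @param boundaries optional output of [extractBoundaries()].
#' @return list with `columns` (data.frame: outer/inner voxel indices,
#'   micrometre endpoints, length, hemisphere), `depth` (array, percent,
#'   NA outside cortex) and `columnIndex` (array of assigned column ids).
#' @export
computeColumns <- function(vol, boundaries = extractBoundaries(vol)) {
    vs <- vol@voxelSize
    O <- .voxelCenters(boundaries$outer, vs)
    I <- .voxelCenters(boundaries$inner, vs)
    # nearest inner voxel per outer voxel, chunked
    nO <- nrow(O)
    nearest <- integer(nO)
    step <- max(1L, floor(2e7 / nrow(I)))
    for (s in seq(1, nO, by = step)) {
        e <- min(nO, s + step - 1)
        d <- crossDist(O[s:e, , drop = FALSE], I)
        nearest[s:e] <- max.col(-d, ties.method = "first")
    }
    Iend <- I[nearest, , drop = FALSE]
    U <- Iend - O
    L <- sqrt(rowSums(U^2))
    L[L == 0] <- 1e-9
    U <- U / L
    hem <- if (length(vol@hemisphere))
        vol@hemisphere[boundaries$outer] else rep(2L, nO)
    columns <- data.frame(
        oi = boundaries$outer[, 1], oj = boundaries$outer[, 2],
        ok = boundaries$outer[, 3],
        ox = O[, 1], oy = O[, 2], oz = O[, 3],
        ix = Iend[, 1], iy = Iend[, 2], iz = Iend[, 3],
        length = L, hemisphere = hem)
    # assign every cortical voxel to its nearest column segment
    Vidx <- .maskWhich(boundaries$cortexMask)
    V <- .voxelCenters(Vidx, vs)
    nV <- nrow(V)
    bestD <- rep(Inf, nV)
    bestT <- rep(NA_real_, nV)
    bestJ <- rep(NA_integer_, nV)
    OU <- rowSums(O * U)      # per column
    O2 <- rowSums(O^2)
    vChunk <- 20000L
    cChunk <- 200L
    for (vs0 in seq(1, nV, by = vChunk)) {
        ve <- min(nV, vs0 + vChunk - 1)
        Vc <- V[vs0:ve, , drop = FALSE]
        V2 <- rowSums(Vc^2)
        for (cs in seq(1, nO, by = cChunk)) {
            ce <- min(nO, cs + cChunk - 1)
            jj <- cs:ce
            A <- tcrossprod(Vc, U[jj, , drop = FALSE])   # V.U
            tpar <- sweep(A, 2, OU[jj], "-")
            tpar <- sweep(tpar, 2, L[jj], "/")
            tpar[tpar < 0] <- 0
            tpar[tpar > 1] <- 1
            VO <- tcrossprod(Vc, O[jj, , drop = FALSE])  # V.O
            tL <- sweep(tpar, 2, L[jj], "*")
            # |V - (O + tL U)|^2
            d2 <- V2 - 2 * (VO + tL * A) +
                  outer(rep(1, nrow(Vc)), O2[jj]) +
                  2 * tL * outer(rep(1, nrow(Vc)), OU[jj]) + tL^2
            d2[d2 < 0] <- 0
            mj <- max.col(-d2, ties.method = "first")
            md <- d2[cbind(seq_len(nrow(d2)), mj)]
            upd <- md < bestD[vs0:ve]
            if (any(upd)) {
                gi <- (vs0:ve)[upd]
                bestD[gi] <- md[upd]
                bestJ[gi] <- jj[mj[upd]]
                bestT[gi] <- tpar[cbind(which(upd), mj[upd])]
            }
        }
    }
    depth <- array(NA_real_, dim(vol@labels))
    colIdx <- array(NA_integer_, dim(vol@labels))
    depth[Vidx] <- bestT * 100
    colIdx[Vidx] <- bestJ
    list(columns = columns, depth = depth, columnIndex = colIdx)
}

# pairs of rows of P within radius r, via grid binning; returns 2-col
# index matrix
.radiusPairs <- function(P, r) {
    key <- paste(floor(P[, 1] / r), floor(P[, 2] / r), floor(P[, 3] / r))
    bins <- split(seq_len(nrow(P)), key)
    kx <- floor(P[, 1] / r); ky <- floor(P[, 2] / r); kz <- floor(P[, 3] / r)
    out <- list()
    for (i in seq_len(nrow(P))) {
        js <- integer(0)
        for (ox in -1:1) for (oy in -1:1) for (oz in -1:1) {
            b <- bins[[paste(kx[i] + ox, ky[i] + oy, kz[i] + oz)]]
            if (!is.null(b)) js <- c(js, b)
        }
        js <- js[js > i]
        if (!length(js)) next
        d <- sqrt((P[js, 1] - P[i, 1])^2 + (P[js, 2] - P[i, 2])^2 +
                  (P[js, 3] - P[i, 3])^2)
        ok <- d <= r
        if (any(ok))
            out[[length(out) + 1L]] <- cbind(i, js[ok], d[ok])
    }
    if (!length(out)) return(matrix(numeric(0), 0, 3))
    do.call(rbind, out)
}

# signed geodesic coordinate on one hemisphere's plate point set:
# distance to the median contour of `score`, signed by side. `apValues`
# (when given) adds the AP-deviation penalty to edge weights.
.plateAxis <- function(P, score, edges, penalty = 0, apValues = NULL,
                       voxelSize = 25, mode = c("penalized", "iso")) {
    mode <- match.arg(mode)
    med <- stats::median(score)
    refSet <- which(abs(score - med) <= voxelSize * 0.75)
    if (!length(refSet)) refSet <- which.min(abs(score - med))
    w <- edges[, 3]
    if (!is.null(apValues)) {
        dap <- abs(apValues[edges[, 1]] - apValues[edges[, 2]])
        if (mode == "penalized") w <- w + penalty * dap
        else {
            keep <- dap <= voxelSize
            edges <- edges[keep, , drop = FALSE]
            w <- w[keep]
        }
    }
    g <- igraph::graph_from_edgelist(
        cbind(edges[, 1], edges[, 2]), directed = FALSE)
    g <- igraph::add_vertices(g, max(0, nrow(P) - igraph::vcount(g)))
    dmat <- igraph::distances(g, v = refSet, weights = w)
    geo <- apply(dmat, 2, min)
    sign(score - med) * geo
}

#' Build the flatmap lookup table
#'
#' Flattens the cortex: the reference plate is the set of column
#' intersections at `plateDepth` (default the mid-cortical plate, 50%
#' depth). Per hemisphere, principal component analysis of the plate
#' defines the 1st axis as AP and the 2nd as ML (an explicit `axes`
#' basis can override the PCA for volumes whose principal axes do not
#' align with anatomy). The AP value of a column is its cumulative
#' geodesic distance (signed) to the contour of median AP score on the
#' plate adjacency graph; the ML value is the distance to the median-ML
#' contour along paths penalized for AP change (`mode = "penalized"`) or
#' restricted to iso-AP steps (`mode = "iso"`). Values are smoothed with
#' an averaging filter over plate neighbours and the per-hemisphere
#' minimum of each axis is shifted to 1. Every cortical voxel inherits
#' its column's plate values; depth comes from [computeColumns()].
#'
#' @param vol an \linkS4class{AnnotationVolume}.
#' @param cols optional output of [computeColumns()].
#' @param plateDepth reference plate depth fraction.
#' @param axes optional 2 x 3 matrix (rows: AP direction, ML direction)
#'   replacing the PCA basis.
#' @param mode ML geodesic mode.
#' @param penalty AP-deviation penalty weight for `mode = "penalized"`.
#' @param edgeRadius plate adjacency radius in voxel units (2.9 covers a
#'   5 x 5 neighbourhood and keeps the metrication error of the geodesic
#'   small).
#' @param smoothPasses averaging-filter passes over plate neighbours.
#' @param fillRadiusUm edge-fill radius for interpolation support (um).
#' @return a \linkS4class{FlatmapLUT}.
#' @export
buildReferenceAxes <- function(vol, cols = computeColumns(vol),
                               plateDepth = 0.5, axes = NULL,
                               mode = c("penalized", "iso"), penalty = 5,
                               edgeRadius = 2.9, smoothPasses = 1,
                               fillRadiusUm = 50) {
    mode <- match.arg(mode)
    cb <- cols$columns
    P <- cbind(cb$ox, cb$oy, cb$oz) +
         plateDepth * cb$length * (cbind(cb$ix, cb$iy, cb$iz) -
                                   cbind(cb$ox, cb$oy, cb$oz)) /
         cbind(cb$length, cb$length, cb$length)
    apVal <- rep(NA_real_, nrow(P))
    mlVal <- rep(NA_real_, nrow(P))
    for (h in unique(cb$hemisphere)) {
        sel <- which(cb$hemisphere == h)
        Ph <- P[sel, , drop = FALSE]
        if (nrow(Ph) < 3) stop("degenerate reference plate (< 3 points)")
        if (is.null(axes)) {
            pc <- stats::prcomp(Ph, center = TRUE, scale. = FALSE)
            a1 <- pc$rotation[, 1]; a2 <- pc$rotation[, 2]
        } else {
            a1 <- axes[1, ] / sqrt(sum(axes[1, ]^2))
            a2 <- axes[2, ] / sqrt(sum(axes[2, ]^2))
        }
        # fix signs deterministically: largest-magnitude loading positive
        if (a1[which.max(abs(a1))] < 0) a1 <- -a1
        if (a2[which.max(abs(a2))] < 0) a2 <- -a2
        ctr <- colMeans(Ph)
        s1 <- as.numeric((Ph - matrix(ctr, nrow(Ph), 3, TRUE)) %*% a1)
        s2 <- as.numeric((Ph - matrix(ctr, nrow(Ph), 3, TRUE)) %*% a2)
        edges <- .radiusPairs(Ph, edgeRadius * vol@voxelSize)
        ap <- .plateAxis(Ph, s1, edges, voxelSize = vol@voxelSize)
        ml <- .plateAxis(Ph, s2, edges, penalty = penalty, apValues = ap,
                         voxelSize = vol@voxelSize, mode = mode)
        if (smoothPasses > 0 && nrow(edges)) {
            adj <- split(c(edges[, 2], edges[, 1]),
                         c(edges[, 1], edges[, 2]))
            for (p in seq_len(smoothPasses)) {
                apS <- ap; mlS <- ml
                for (i in seq_along(ap)) {
                    nb <- adj[[as.character(i)]]
                    apS[i] <- mean(c(ap[i], ap[nb]))
                    mlS[i] <- mean(c(ml[i], ml[nb]))
                }
                ap <- apS; ml <- mlS
            }
        }
        ap <- ap - min(ap[is.finite(ap)]) + 1
        ml <- ml - min(ml[is.finite(ml)]) + 1
        apVal[sel] <- ap
        mlVal[sel] <- ml
    }
    dims <- dim(vol@labels)
    mlArr <- array(NA_real_, dims)
    apArr <- array(NA_real_, dims)
    inCortex <- !is.na(cols$columnIndex)
    mlArr[inCortex] <- mlVal[cols$columnIndex[inCortex]]
    apArr[inCortex] <- apVal[cols$columnIndex[inCortex]]
    fillR <- max(1L, round(fillRadiusUm / vol@voxelSize))
    lutNew <- new("FlatmapLUT", ml = mlArr, ap = apArr, depth = cols$depth,
                  mlFill = .edgeFill(mlArr, fillR),
                  apFill = .edgeFill(apArr, fillR),
                  depthFill = .edgeFill(cols$depth, fillR),
                  voxelSize = vol@voxelSize, plateDepth = plateDepth)
    lutNew
}

# non-zero (non-NA) average fill: NA voxels within `r` voxels of valid
# values receive the mean of the valid values in their (2r+1)^3
# neighbourhood; valid voxels are untouched.
.edgeFill <- function(arr, r) {
    d <- dim(arr)
    val <- !is.na(arr)
    sums <- array(0, d)
    cnts <- array(0, d)
    a0 <- arr
    a0[!val] <- 0
    offs <- expand.grid(ox = -r:r, oy = -r:r, oz = -r:r)
    for (i in seq_len(nrow(offs))) {
        ox <- offs$ox[i]; oy <- offs$oy[i]; oz <- offs$oz[i]
        sx <- max(1, 1 - ox):min(d[1], d[1] - ox)
        sy <- max(1, 1 - oy):min(d[2], d[2] - oy)
        sz <- max(1, 1 - oz):min(d[3], d[3] - oz)
        sums[sx + ox, sy + oy, sz + oz] <-
            sums[sx + ox, sy + oy, sz + oz] + a0[sx, sy, sz]
        cnts[sx + ox, sy + oy, sz + oz] <-
            cnts[sx + ox, sy + oy, sz + oz] + val[sx, sy, sz]
    }
    out <- arr
    fill <- !val & cnts > 0
    out[fill] <- sums[fill] / cnts[fill]
    out
}

#' Convert points to flatmap coordinates
#'
#' Trilinearly interpolates the lookup table at each point; values near
#' the cortical edge are backed by the non-zero average fill. Points
#' outside the (filled) cortex return NA.
#'
#' @param points data.frame or matrix with x, y, z in micrometres.
#' @param lut a \linkS4class{FlatmapLUT}.
#' @return data.frame with ml, ap, depth per point (NA outside cortex).
#' @export
toFlatCoords <- function(points, lut) {
    pts <- as.matrix(points[, c("x", "y", "z")])
    vs <- lut@voxelSize
    ci <- pts / vs + 0.5  # continuous voxel index (centre of voxel 1 -> 1)
    d <- dim(lut@depth)
    interp <- function(arr) {
        vapply(seq_len(nrow(ci)), function(i) {
            p <- ci[i, ]
            i0 <- floor(p)
            f <- p - i0
            tot <- 0; wsum <- 0
            for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
                ii <- i0 + c(dx, dy, dz)
                if (any(ii < 1) || any(ii > d)) next
                v <- arr[ii[1], ii[2], ii[3]]
                if (is.na(v)) next
                w <- prod(ifelse(c(dx, dy, dz) == 1, f, 1 - f))
                tot <- tot + w * v
                wsum <- wsum + w
            }
            if (wsum <= 0) NA_real_ else tot / wsum
        }, numeric(1))
    }
    data.frame(ml = interp(lut@mlFill), ap = interp(lut@apFill),
               depth = interp(lut@depthFill))
}
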