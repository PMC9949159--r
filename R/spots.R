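# Rolony spot detection in 4-channel sequencing stacks: fixed-pattern
# noise removal by floor-subtracted projection, z-score channel intensity
# correction anchored on local maxima, and local-maximum calling with the
# four acceptance criteria (z-adjacency, channel dominance, intensity
# ratio < 0.95, intensity threshold) plus subpixel localization.

#' Floor-subtracted maximum projection
#'
#' For every pixel and channel, the maximum over z minus the 3rd-smallest
#' value over z, clipped at zero. Pixels without a rolony have a
#' discontinuous z-profile, so this suppresses fixed-pattern and tissue
#' background while preserving blob peaks.
#'
#' @param stack an \linkS4class{ImageStack} with at least 3 z-planes.
#' @return numeric array dim c(ny, nx, 4).
#' @export
floorSubtractedProjection <- function(stack) {
    d <- dim(stack@intensities)
    if (d[3] < 3) stop("floor subtraction needs at least 3 z-planes")
    out <- array(0, dim = c(d[1], d[2], 4))
    for (ch in 1:4) {
        m <- matrix(stack@intensities[, , , ch], nrow = d[1] * d[2])
        mx <- do.call(pmax, as.data.frame(m))
        third <- apply(m, 1, function(v) sort(v, partial = 3)[3])
        out[, , ch] <- matrix(pmax(mx - third, 0), d[1], d[2])
    }
    out
}

# raw local maxima of one 2-D image within a circular neighbourhood of
# the given diameter; ties resolved by (y, x) lexicographic order (only
# the first pixel of a plateau is kept). Returns 0-based integer coords.
.localMaxima <- function(img, diameter = 5) {
    r <- floor(diameter / 2)
    ny <- nrow(img); nx <- ncol(img)
    offs <- expand.grid(dy = -r:r, dx = -r:r)
    offs <- offs[offs$dy^2 + offs$dx^2 <= r^2 &
                 !(offs$dy == 0 & offs$dx == 0), ]
    isMax <- matrix(TRUE, ny, nx)
    for (i in seq_len(nrow(offs))) {
        dy <- offs$dy[i]; dx <- offs$dx[i]
        sh <- matrix(-Inf, ny, nx)
        ys <- max(1, 1 + dy):min(ny, ny + dy)
        xs <- max(1, 1 + dx):min(nx, nx + dx)
        sh[ys - dy, xs - dx] <- img[ys, xs]
        # strict where the neighbour precedes us lexicographically,
        # non-strict otherwise: deterministic plateau tie-break
        if (dy < 0 || (dy == 0 && dx < 0)) {
            isMax <- isMax & (img > sh)
        } else {
            isMax <- isMax & (img >= sh)
        }
    }
    w <- which(isMax & img > -Inf, arr.ind = TRUE)
    data.frame(y = w[, 1] - 1L, x = w[, 2] - 1L,
               intensity = img[w])
}

#' Correct channel intensities using local maxima
#'
#' Standardizes each channel so that channels with different gains and
#' decay are comparable: corrected = (I - background median) /
#' SD(local-maxima intensities). The background median anchors zero at
#' the signal floor and the maxima SD equalizes the spread of true-dot
#' intensities across channels, so the detection threshold can be read as
#' "maxima-SDs above background". Optionally estimates and inverts a
#' linear bleed-through mixing matrix from maxima whose second-highest /
#' highest channel ratio is below `purity`.
#'
#' @param images ny x nx x 4 array (e.g. from
#'   [floorSubtractedProjection()]).
#' @param minMaxima minimum local maxima per channel required; below this
#'   the channel falls back to identity correction with a warning.
#' @param unmix estimate and apply linear bleed-through unmixing.
#' @param purity ratio2nd ceiling for a maximum to count as spectrally
#'   pure when estimating bleed-through.
#' @param diameter local-maximum neighbourhood diameter (px).
#' @return list with `corrected` (ny x nx x 4), and a `report`
#'   data.frame (channel, nMaxima, background, scale, fallback) plus the
#'   `bleed` matrix when unmixing was applied.
#' @export
correctChannelIntensities <- function(images, minMaxima = 50,
                                      unmix = FALSE, purity = 0.5,
                                      diameter = 5) {
    stopifnot(length(dim(images)) == 3, dim(images)[3] == 4)
    maxima <- lapply(1:4, function(ch) {
        mx <- .localMaxima(images[, , ch], diameter)
        # drop background plateaus: a sampled maximum must rise above
        # the channel's signal floor
        mx[mx$intensity > stats::median(images[, , ch]), , drop = FALSE]
    })
    bleed <- diag(4)
    if (unmix) {
        # per channel, gather pure maxima and the cross-channel response
        for (ch in 1:4) {
            mx <- maxima[[ch]]
            if (!nrow(mx)) next
            px <- cbind(mx$y + 1L, mx$x + 1L)
            vals <- sapply(1:4, function(oc)
                images[cbind(px, rep(oc, nrow(px)))])
            if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1)
            top <- vals[, ch]
            ratio2 <- apply(vals, 1, function(v) {
                s <- sort(v, decreasing = TRUE)
                if (s[1] <= 0) 1 else s[2] / s[1]
            })
            pure <- ratio2 < purity & top > 0 &
                    apply(vals, 1, which.max) == ch
            if (sum(pure) >= 3) {
                for (oc in setdiff(1:4, ch))
                    bleed[oc, ch] <- stats::median(vals[pure, oc] /
                                                   vals[pure, ch])
            }
        }
        inv <- solve(bleed)
        flat <- matrix(images, ncol = 4)
        flat <- flat %*% t(inv)
        images <- array(flat, dim = dim(images))
    }
    corrected <- images
    report <- data.frame(channel = 1:4, nMaxima = 0L, background = 0,
                         scale = 1, fallback = FALSE)
    for (ch in 1:4) {
        mx <- maxima[[ch]]
        report$nMaxima[ch] <- nrow(mx)
        if (nrow(mx) < minMaxima || stats::sd(mx$intensity) < 1e-12 ||
            is.na(stats::sd(mx$intensity))) {
            report$fallback[ch] <- TRUE
            warning(sprintf(
                "channel %d: %d local maxima (< %d); identity correction",
                ch, nrow(mx), minMaxima))
            next
        }
        bg <- stats::median(images[, , ch])
        sc <- stats::sd(mx$intensity)
        corrected[, , ch] <- (images[, , ch] - bg) / sc
        report$background[ch] <- bg
        report$scale[ch] <- sc
    }
    out <- list(corrected = corrected, report = report)
    if (unmix) out$bleed <- bleed
    out
}

# parabolic (quadratic) subpixel refinement along one axis
.subpixelOffset <- function(im1, i0, ip1) {
    den <- im1 - 2 * i0 + ip1
    if (!is.finite(den) || den >= 0) return(0)
    off <- 0.5 * (im1 - ip1) / den
    max(-0.5, min(0.5, off))
}

#' Detect rolony dots in a sequencing stack
#'
#' Identifies local maxima within a circular neighbourhood (default
#' 5-pixel diameter) on the floor-subtracted, intensity-corrected channel
#' projections and accepts a maximum as a dot when (1) in the z-stack the
#' plane of highest intensity neighbours the plane of 2nd or 3rd highest
#' intensity, (2) its channel has the highest intensity at that pixel
#' both before and after correction, (3) the second-highest / highest
#' channel ratio is strictly below `ratioMax`, and (4) the corrected
#' intensity passes `threshold`. Positions are refined to subpixel
#' precision by quadratic interpolation of the 3x3 neighbourhood.
#'
#' @param stack an \linkS4class{ImageStack}.
#' @param threshold corrected-intensity threshold (maxima-SDs above
#'   background; default 3).
#' @param ratioMax strict upper bound on 2nd max / 1st max channel
#'   intensity (default 0.95).
#' @param diameter local-maximum suppression diameter in pixels.
#' @param bothAdjacent require the plane of 1st max to be adjacent to the
#'   planes of both the 2nd and 3rd max (default: 2nd or 3rd).
#' @param correct apply [correctChannelIntensities()] (with its fallback
#'   to identity when maxima are scarce).
#' @param minMaxima,unmix passed to the intensity correction.
#' @return data.frame of dot calls: x, y (0-based subpixel), channel,
#'   intensity (corrected), ratio2nd, cycle, tile.
#' @export
detectDots <- function(stack, threshold = 3, ratioMax = 0.95,
                       diameter = 5, bothAdjacent = FALSE, correct = TRUE,
                       minMaxima = 50, unmix = FALSE) {
    raw <- floorSubtractedProjection(stack)
    if (correct) {
        corr <- suppressWarnings(
            correctChannelIntensities(raw, minMaxima = minMaxima,
                                      unmix = unmix, diameter = diameter))
        cimg <- corr$corrected
    } else {
        cimg <- raw
    }
    nz <- dim(stack@intensities)[3]
    out <- list()
    for (ch in 1:4) {
        mx <- .localMaxima(cimg[, , ch], diameter)
        if (!nrow(mx)) next
        keep <- logical(nrow(mx))
        xs <- numeric(nrow(mx)); ys <- numeric(nrow(mx))
        ratio <- numeric(nrow(mx))
        for (i in seq_len(nrow(mx))) {
            yi <- mx$y[i] + 1L; xi <- mx$x[i] + 1L
            # (1) z-profile: plane of 1st max adjacent to 2nd (or 3rd)
            zprof <- stack@intensities[yi, xi, , ch]
            o <- order(zprof, decreasing = TRUE)
            adj2 <- abs(o[1] - o[2]) == 1
            adj3 <- nz >= 3 && abs(o[1] - o[3]) == 1
            okZ <- if (bothAdjacent) adj2 && adj3 else adj2 || adj3
            if (!okZ) next
            # (2) channel dominance before and after correction
            rawV <- raw[yi, xi, ]
            corV <- cimg[yi, xi, ]
            if (which.max(rawV) != ch || which.max(corV) != ch) next
            # (3) intensity ratio, on non-negative corrected values
            v <- pmax(corV, 0)
            s <- sort(v, decreasing = TRUE)
            ratio[i] <- if (s[1] <= 0) 1 else s[2] / s[1]
            if (!(ratio[i] < ratioMax)) next
            # (4) threshold
            if (cimg[yi, xi, ch] < threshold) next
            keep[i] <- TRUE
            img <- cimg[, , ch]
            dx <- if (xi > 1 && xi < ncol(img))
                .subpixelOffset(img[yi, xi - 1], img[yi, xi], img[yi, xi + 1])
                else 0
            dy <- if (yi > 1 && yi < nrow(img))
                .subpixelOffset(img[yi - 1, xi], img[yi, xi], img[yi + 1, xi])
                else 0
            xs[i] <- mx$x[i] + dx
            ys[i] <- mx$y[i] + dy
        }
        if (any(keep))
            out[[ch]] <- data.frame(
                x = xs[keep], y = ys[keep], channel = ch,
                intensity = mx$intensity[keep], ratio2nd = ratio[keep],
                cycle = stack@cycleId, tile = stack@tileId)
    }
    if (!length(out))
        return(data.frame(x = numeric(0), y = numeric(0),
                          channel = integer(0), intensity = numeric(0),
                          ratio2nd = numeric(0), cycle = integer(0),
                          tile = integer(0)))
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}
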