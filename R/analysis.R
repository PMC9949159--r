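# Single-neuron projection statistics: laminar depth profiles and their
# permutation-KS comparison, bootstrap group percentages, soma-depth
# grouping, focal projection distance with its subsampling error curve,
# simulated retrograde tracing, and connect-the-dots reconstruction.

#' Laminar depth profile
#'
#' Depth histogram (normalized frequency) and CDF on a percent-depth
#' grid.
#'
#' @param depths rolony depths in percent (0-100).
#' @param binWidth 1 or 5 (percent).
#' @param region optional region label carried through.
#' @return list with `breaks`, `freq` (sums to 1 when n > 0), `cdf`
#'   (nondecreasing, ends at 1), `n`, `region`.
#' @export
laminarProfile <- function(depths, binWidth = 1, region = NA_character_) {
    breaks <- seq(0, 100, by = binWidth)
    h <- graphics::hist(pmin(pmax(depths, 0), 100), breaks = breaks,
                        plot = FALSE)
    n <- length(depths)
    freq <- if (n > 0) h$counts / n else h$counts * 0
    list(breaks = breaks, freq = freq, cdf = cumsum(freq), n = n,
         region = region)
}

# KS distance between two depth samples on the percent grid
.ksOnGrid <- function(a, b, binWidth = 1) {
    pa <- laminarProfile(a, binWidth)$cdf
    pb <- laminarProfile(b, binWidth)$cdf
    max(abs(pa - pb))
}

#' Permutation Kolmogorov-Smirnov comparison of two laminar patterns
#'
#' The KS distance is the maximum absolute difference between the two
#' depth CDFs on a 1% grid. Its p-value is the fraction of label
#' shuffles (rolony depths randomly reassigned between the two regions,
#' preserving group sizes) whose KS distance is at least the observed
#' one. Patterns are classified as different when p <= `alpha`.
#'
#' @param depthsA,depthsB depth samples (percent) from two regions of
#'   one cell.
#' @param nShuffles number of shuffles (default 1000).
#' @param binWidth CDF grid (percent).
#' @param alpha classification threshold.
#' @param seed RNG seed for the shuffles (seed per cell id keeps results
#'   reproducible).
#' @param plusOne use the (k+1)/(n+1) small-sample correction instead of
#'   the plain fraction.
#' @return list with `ks`, `p`, `different`; all NA when either sample
#'   is empty.
#' @export
ksPermutation <- function(depthsA, depthsB, nShuffles = 1000,
                          binWidth = 1, alpha = 0.05, seed = 1,
                          plusOne = FALSE) {
    nA <- length(depthsA); nB <- length(depthsB)
    if (nA == 0 || nB == 0)
        return(list(ks = NA_real_, p = NA_real_, different = NA))
    obs <- .ksOnGrid(depthsA, depthsB, binWidth)
    pool <- c(depthsA, depthsB)
    nbin <- 100 / binWidth
    binIdx <- pmin(pmax(ceiling(pool / binWidth), 1), nbin)
    n <- nA + nB
    allCounts <- tabulate(binIdx, nbins = nbin)
    count <- withSeed(seed, {
        hits <- 0L
        for (s in seq_len(nShuffles)) {
            ia <- sample.int(n, nA)
            ca <- tabulate(binIdx[ia], nbins = nbin)
            cb <- allCounts - ca
            ks <- max(abs(cumsum(ca) / nA - cumsum(cb) / nB))
            if (ks >= obs - 1e-12) hits <- hits + 1L
        }
        hits
    })
    p <- if (plusOne) (count + 1) / (nShuffles + 1) else count / nShuffles
    list(ks = obs, p = p, different = p <= alpha)
}

#' Percentage of cells with different laminar patterns, with bootstrap CI
#'
#' For each group, the percentage of cells classified as different
#' (p <= alpha) and its percentile bootstrap confidence interval (2.5
#' and 97.5%). Two groups are called significantly different when their
#' intervals do not overlap.
#'
#' @param pvalues list of numeric vectors (per-cell p-values), one per
#'   group.
#' @param alpha classification threshold.
#' @param nBoot bootstrap iterations (default 2000).
#' @param seed RNG seed.
#' @return data.frame with group, n, percent, lower, upper.
#' @export
fractionDifferent <- function(pvalues, alpha = 0.05, nBoot = 2000,
                              seed = 1) {
    if (is.null(names(pvalues)))
        names(pvalues) <- seq_along(pvalues)
    rows <- lapply(names(pvalues), function(g) {
        p <- pvalues[[g]]
        n <- length(p)
        if (n == 0)
            return(data.frame(group = g, n = 0L, percent = NA_real_,
                              lower = NA_real_, upper = NA_real_))
        pct <- mean(p <= alpha) * 100
        if (n == 1) {
            warning("single cell in group ", g, "; degenerate interval")
            return(data.frame(group = g, n = 1L, percent = pct,
                              lower = pct, upper = pct))
        }
        boot <- withSeed(seed + match(g, names(pvalues)), {
            vapply(seq_len(nBoot), function(i)
                mean(sample(p, n, replace = TRUE) <= alpha) * 100,
                numeric(1))
        })
        ci <- stats::quantile(boot, c(0.025, 0.975), names = FALSE)
        data.frame(group = g, n = n, percent = pct, lower = ci[1],
                   upper = ci[2])
    })
    do.call(rbind, rows)
}

#' Soma depth groups
#'
#' Upper (<= 35% depth), middle (35-60%] and deep (> 60%); cells without
#' a known soma are excluded (NA).
#'
#' @param depths soma depths in percent; NA = unknown.
#' @param bounds the two group boundaries.
#' @return factor with levels upper, middle, deep (NA when no soma).
#' @export
somaDepthGroups <- function(depths, bounds = c(35, 60)) {
    out <- rep(NA_character_, length(depths))
    ok <- !is.na(depths)
    out[ok & depths <= bounds[1]] <- "upper"
    out[ok & depths > bounds[1] & depths <= bounds[2]] <- "middle"
    out[ok & depths > bounds[2]] <- "deep"
    factor(out, levels = c("upper", "middle", "deep"))
}

#' Prepare cortical rolonies for laminar analysis
#'
#' Drops rolonies deeper than `maxDepth` percent (fiber-tract
#' proximity), rolonies within the injection exclusion disk on the
#' ML-AP plate (radius = the 95th percentile of soma distances to the
#' injection center, the median soma location), and optionally the
#' mirrored contralateral disk (local-exclusion control).
#'
#' @param rolonies data.frame with ml, ap, depth columns (flatmap
#'   coordinates).
#' @param somaML,somaAP soma locations defining the injection disk; NULL
#'   disables the disk exclusion.
#' @param maxDepth depth cut in percent.
#' @param mirrorML function mapping an ML value to its mirrored
#'   contralateral value, or NULL to skip the control exclusion.
#' @param radius optional fixed disk radius overriding the percentile
#'   rule.
#' @return list with `rolonies` (kept rows), `center` (ML, AP),
#'   `radius`.
#' @export
corticalRolonyPrep <- function(rolonies, somaML = NULL, somaAP = NULL,
                               maxDepth = 95, mirrorML = NULL,
                               radius = NULL) {
    keep <- is.na(rolonies$depth) | rolonies$depth <= maxDepth
    keep[is.na(keep)] <- FALSE
    center <- c(ml = NA_real_, ap = NA_real_)
    if (!is.null(somaML) && length(somaML)) {
        center <- c(ml = stats::median(somaML), ap = stats::median(somaAP))
        if (is.null(radius)) {
            d <- sqrt((somaML - center[1])^2 + (somaAP - center[2])^2)
            radius <- stats::quantile(d, 0.95, names = FALSE)
        }
        inDisk <- sqrt((rolonies$ml - center[1])^2 +
                       (rolonies$ap - center[2])^2) < radius
        keep <- keep & !inDisk
        if (!is.null(mirrorML)) {
            inMirror <- sqrt((rolonies$ml - mirrorML(center[1]))^2 +
                             (rolonies$ap - center[2])^2) < radius
            keep <- keep & !inMirror
        }
    }
    list(rolonies = rolonies[keep, , drop = FALSE], center = center,
         radius = if (is.null(radius)) NA_real_ else radius)
}

#' Focal projection distance
#'
#' For each rolony, the mean of its shortest `fraction` of pairwise
#' distances to the cell's other rolonies on the ML-AP plate
#' (ceil(fraction * (n - 1)) distances, self excluded); the cell value
#' is the mean over rolonies. Cells with fewer than `minN` rolonies are
#' excluded (NA): below that, the subsampling error of the statistic is
#' substantial.
#'
#' @param ml,ap rolony coordinates on the flat plate.
#' @param fraction fraction of shortest distances kept (default 0.33).
#' @param minN minimum rolony count (default 55).
#' @return the cell's focal projection distance, or NA when n < minN.
#' @export
focalDistance <- function(ml, ap, fraction = 0.33, minN = 55) {
    n <- length(ml)
    if (n < minN) return(NA_real_)
    if (n < 2) return(0)
    xy <- cbind(ml, ap)
    d <- as.matrix(stats::dist(xy))
    m <- ceiling(fraction * (n - 1))
    perRolony <- vapply(seq_len(n), function(i) {
        di <- sort(d[i, -i], partial = m)[seq_len(m)]
        mean(di)
    }, numeric(1))
    mean(perRolony)
}

#' Subsampling error curve of the focal projection distance
#'
#' For each subsample size, draws `reps` random subsamples, computes the
#' focal distance of each, and reports the median relative error
#' |d_sample - d_truth| / d_truth * 100 against the full-sample value.
#' Sizes larger than n are skipped.
#'
#' @param ml,ap rolony coordinates.
#' @param sizes subsample sizes.
#' @param reps random subsamples per size (default 100).
#' @param fraction focal-distance fraction.
#' @param seed RNG seed.
#' @return data.frame with size and medianError (percent).
#' @export
subsamplingErrorCurve <- function(ml, ap, sizes, reps = 100,
                                  fraction = 0.33, seed = 1) {
    n <- length(ml)
    truth <- focalDistance(ml, ap, fraction, minN = 0)
    sizes <- sizes[sizes <= n]
    rows <- withSeed(seed, {
        lapply(sizes, function(s) {
            errs <- vapply(seq_len(reps), function(r) {
                idx <- sample.int(n, s)
                est <- focalDistance(ml[idx], ap[idx], fraction, minN = 0)
                abs(est - truth) / truth * 100
            }, numeric(1))
            data.frame(size = s, medianError = stats::median(errs))
        })
    })
    do.call(rbind, rows)
}

#' Simulated retrograde tracing
#'
#' Selects the cells that would be labeled by a tracer injection of
#' radius `radius` at `center` on the flatmap: a positive cell (1) is
#' from the IT class, (2) has at least `minPatch` rolonies within the
#' patch and (3) has a soma location. For a contralateral patch, a
#' positive cell projects specifically when its patch / contralateral
#' cortex count ratio is at least `specificity`.
#'
#' @param cells data.frame with barcode, class (CF/ITi/ITc), hasSoma
#'   (logical) and contraCount (rolony count in contralateral cortex).
#' @param rolonies data.frame with barcode, ml, ap.
#' @param center length-2 (ml, ap) patch center.
#' @param radius patch radius (micrometre-scale flatmap units).
#' @param minPatch minimum rolonies within the patch.
#' @param specificity patch/contra ratio for the specificity flag.
#' @return data.frame of positive cells with patchCount and specific.
#' @export
simulatedRetrograde <- function(cells, rolonies, center, radius = 300,
                                minPatch = 10, specificity = 0.75) {
    d <- sqrt((rolonies$ml - center[1])^2 + (rolonies$ap - center[2])^2)
    inPatch <- rolonies[d <= radius, , drop = FALSE]
    patchCount <- table(inPatch$barcode)
    cells$patchCount <- as.integer(patchCount[cells$barcode])
    cells$patchCount[is.na(cells$patchCount)] <- 0L
    pos <- cells$class %in% c("ITi", "ITc") &
           cells$patchCount >= minPatch & cells$hasSoma
    out <- cells[pos, , drop = FALSE]
    out$specific <- out$contraCount > 0 &
        out$patchCount / pmax(out$contraCount, 1L) >= specificity
    out
}

#' Connect-the-dots reconstruction of one cell
#'
#' Connects each data point (rolonies and soma) to its closest
#' neighbour to form clusters, then repeatedly connects the two closest
#' clusters via their closest point pair, until all clusters are
#' connected or no linking pair remains within `maxEdge` micrometres
#' (clusters farther apart stay separate components).
#'
#' @param points n x 3 matrix or data.frame (x, y, z micrometres).
#' @param maxEdge maximum link length.
#' @return data.frame of edges (from, to, dist; row indices into
#'   `points`).
#' @export
reconstructCell <- function(points, maxEdge = 1000) {
    pts <- as.matrix(points)
    n <- nrow(pts)
    empty <- data.frame(from = integer(0), to = integer(0),
                        dist = numeric(0))
    if (n < 2) return(empty)
    d <- as.matrix(stats::dist(pts))
    diag(d) <- Inf
    edges <- list()
    comp <- seq_len(n)
    link <- function(i, j) {
        edges[[length(edges) + 1L]] <<- c(i, j, d[i, j])
        ci <- comp[i]; cj <- comp[j]
        comp[comp == cj] <<- ci
    }
    # step 1: each point to its nearest neighbour
    for (i in seq_len(n)) {
        j <- which.min(d[i, ])
        if (d[i, j] > maxEdge) next
        if (comp[i] == comp[j]) next
        link(i, j)
    }
    # step 2: merge closest clusters via their closest point pair
    repeat {
        comps <- unique(comp)
        if (length(comps) < 2) break
        best <- c(NA, NA, Inf)
        for (a in seq_along(comps)) {
            ia <- which(comp == comps[a])
            for (b in seq_len(a - 1)) {
                ib <- which(comp == comps[b])
                sub <- d[ia, ib, drop = FALSE]
                w <- which.min(sub)
                dv <- sub[w]
                if (dv < best[3]) {
                    ri <- (w - 1) %% length(ia) + 1
                    rj <- (w - 1) %/% length(ia) + 1
                    best <- c(ia[ri], ib[rj], dv)
                }
            }
        }
        if (!is.finite(best[3]) || best[3] > maxEdge) break
        link(best[1], best[2])
    }
    if (!length(edges)) return(empty)
    m <- do.call(rbind, edges)
    data.frame(from = as.integer(pmin(m[, 1], m[, 2])),
               to = as.integer(pmax(m[, 1], m[, 2])), dist = m[, 3])
}
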