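# Rolony base-calling: dots are chained across sequencing cycles by
# gated one-to-one greedy matching (cycle intervals 1-3), chains are
# assembled into barcode reads with N-filled gaps and conflict forking,
# and somata are base-called per pixel with phasing correction.

#' Chain dots across sequencing cycles
#'
#' For every target cycle t and interval d in 1..`lookback`, one-to-one
#' matches dots of cycle t to the closest available dots of cycle t-d
#' within `gate` pixels. Matching is greedy over candidate pairs in
#' ascending distance order (ties broken by dot id), and no dot
#' participates twice within the same cycle-pair matching.
#'
#' @param dots data.frame with dotId, cycle, x, y (one aligned frame).
#' @param gate matching gate in pixels (a pair farther than this is never
#'   matched).
#' @param lookback maximum cycle interval bridged.
#' @return data.frame of matches: cycleFrom, cycleTo, interval, dotFrom,
#'   dotTo, dist.
#' @export
chainDots <- function(dots, gate = 5, lookback = 3) {
    cycles <- sort(unique(dots$cycle))
    byCycle <- split(seq_len(nrow(dots)), dots$cycle)
    xs <- dots$x; ys <- dots$y; ids <- dots$dotId
    from <- list(); to <- list(); dist <- list()
    meta <- list()
    k <- 0L
    for (t in cycles) {
        for (d in seq_len(lookback)) {
            if (!((t - d) %in% cycles)) next
            ia <- byCycle[[as.character(t - d)]]
            ib <- byCycle[[as.character(t)]]
            m <- .greedyPairs(xs[ia], ys[ia], ids[ia],
                              xs[ib], ys[ib], ids[ib], gate)
            if (length(m$from)) {
                k <- k + 1L
                from[[k]] <- m$from; to[[k]] <- m$to; dist[[k]] <- m$dist
                meta[[k]] <- c(t - d, t, d, length(m$from))
            }
        }
    }
    if (!k)
        return(data.frame(cycleFrom = integer(0), cycleTo = integer(0),
                          interval = integer(0), dotFrom = integer(0),
                          dotTo = integer(0), dist = numeric(0)))
    mm <- do.call(rbind, meta)
    data.frame(cycleFrom = rep(mm[, 1], mm[, 4]),
               cycleTo = rep(mm[, 2], mm[, 4]),
               interval = rep(mm[, 3], mm[, 4]),
               dotFrom = unlist(from), dotTo = unlist(to),
               dist = unlist(dist))
}

# one-to-one greedy matching between two dot sets by ascending pair
# distance within the gate; deterministic tie-break by (dist, fromId,
# toId). Candidate pairs are found with coarse spatial binning so dense
# sections stay tractable.
.greedyPairs <- function(ax, ay, aid, bx, by, bid, gate) {
    nA <- length(ax); nB <- length(bx)
    none <- list(from = integer(0), to = integer(0), dist = numeric(0))
    if (!nA || !nB) return(none)
    x0 <- min(ax, bx); y0 <- min(ay, by)
    gxa <- floor((ax - x0) / gate) + 2L
    gya <- floor((ay - y0) / gate) + 2L
    gxb <- floor((bx - x0) / gate) + 2L
    gyb <- floor((by - y0) / gate) + 2L
    K <- max(gxa, gxb) + 2L
    binsB <- split(seq_len(nB), gyb * K + gxb)
    ci <- vector("list", nA); cj <- vector("list", nA); cd <- vector("list", nA)
    for (i in seq_len(nA)) {
        js <- integer(0)
        base <- gya[i] * K + gxa[i]
        for (oy in c(-K, 0L, K)) for (ox in -1:1) {
            jj <- binsB[[as.character(base + oy + ox)]]
            if (!is.null(jj)) js <- c(js, jj)
        }
        if (!length(js)) next
        dd <- sqrt((bx[js] - ax[i])^2 + (by[js] - ay[i])^2)
        ok <- dd <= gate
        if (any(ok)) {
            ci[[i]] <- rep.int(i, sum(ok)); cj[[i]] <- js[ok]
            cd[[i]] <- dd[ok]
        }
    }
    ci <- unlist(ci); cj <- unlist(cj); cd <- unlist(cd)
    if (!length(ci)) return(none)
    o <- order(cd, aid[ci], bid[cj])
    ci <- ci[o]; cj <- cj[o]; cd <- cd[o]
    usedA <- logical(nA); usedB <- logical(nB)
    keep <- logical(length(ci))
    for (r in seq_along(ci)) {
        if (!usedA[ci[r]] && !usedB[cj[r]]) {
            usedA[ci[r]] <- TRUE; usedB[cj[r]] <- TRUE; keep[r] <- TRUE
        }
    }
    list(from = aid[ci[keep]], to = bid[cj[keep]], dist = cd[keep])
}

#' Assemble rolony reads from cycle-interval matches
#'
#' Merges matches sequentially by target cycle, interval ascending (3-4,
#' 2-4, 1-4, 4-5, 3-5, 2-5, ...). A match extends the chain containing
#' its earlier dot; cycles skipped by an interval > 1 are filled with N.
#' When a match disagrees with an existing chain entry, the chain's
#' prefix is duplicated to include the new match (both forks are
#' retained; they are condensed after codebook matching). A chain that
#' forks more than `maxForks` times is dropped. Reads with more than
#' `maxNRun` continuous non-base-called nucleotides are discarded.
#'
#' @param matches output of [chainDots()].
#' @param dots the dot table used for chaining (dotId, cycle, x, y,
#'   channel, and optionally section).
#' @param nCycles total number of sequencing cycles.
#' @param referenceCycle cycle whose dot supplies the read position when
#'   present (default the middle cycle); otherwise the chain centroid.
#' @param maxNRun longest tolerated N run.
#' @param maxForks fork cap per original chain.
#' @return list with `reads` (readId, barcode, x, y, section, nCalled,
#'   maxNRun) and `dotMap` (list of per-read integer vectors, dotId per
#'   cycle, NA where non-base-called).
#' @export
assembleSequences <- function(matches, dots, nCycles,
                              referenceCycle = ceiling(nCycles / 2),
                              maxNRun = 3, maxForks = 4) {
    maxId <- max(dots$dotId)
    chanOf <- integer(maxId); chanOf[dots$dotId] <- dots$channel
    xOfV <- numeric(maxId); xOfV[dots$dotId] <- dots$x
    yOfV <- numeric(maxId); yOfV[dots$dotId] <- dots$y
    hasSection <- "section" %in% names(dots)
    secOfV <- integer(maxId)
    if (hasSection) secOfV[dots$dotId] <- dots$section
    nChainCap <- 256L
    chainMat <- matrix(NA_integer_, nChainCap, nCycles)
    nChains <- 0L
    roots <- integer(0)       # root chain id per chain
    forkCount <- integer(0)   # forks per root
    member <- vector("list", maxId)  # dotId -> chain ids (a dot lives in
                                     # exactly one cycle)
    growIfNeeded <- function() {
        if (nChains >= nrow(chainMat)) {
            m2 <- matrix(NA_integer_, nrow(chainMat) * 2L, nCycles)
            m2[seq_len(nChains), ] <- chainMat[seq_len(nChains), ]
            chainMat <<- m2
        }
    }
    if (nrow(matches)) {
        matches <- matches[order(matches$cycleTo, matches$interval,
                                 matches$dist), ]
        mFrom <- matches$dotFrom; mTo <- matches$dotTo
        mCa <- matches$cycleFrom; mCb <- matches$cycleTo
        for (r in seq_len(nrow(matches))) {
            a <- mFrom[r]; b <- mTo[r]
            ca <- mCa[r]; cb <- mCb[r]
            inA <- member[[a]]
            if (is.null(inA)) {
                # new chain seeded by this pair
                growIfNeeded()
                nChains <- nChains + 1L
                chainMat[nChains, ca] <- a
                chainMat[nChains, cb] <- b
                roots[nChains] <- nChains
                forkCount[nChains] <- 0L
                member[[a]] <- c(member[[a]], nChains)
                member[[b]] <- c(member[[b]], nChains)
                next
            }
            for (idx in inA) {
                cur <- chainMat[idx, cb]
                if (is.na(cur)) {
                    chainMat[idx, cb] <- b
                    member[[b]] <- c(member[[b]], idx)
                } else if (cur != b) {
                    rt <- roots[idx]
                    forkCount[rt] <- forkCount[rt] + 1L
                    if (forkCount[rt] > maxForks) next
                    # duplicate the prefix up to the earlier cycle, then
                    # the new match (gap cycles stay N)
                    growIfNeeded()
                    nChains <- nChains + 1L
                    chainMat[nChains, seq_len(ca)] <-
                        chainMat[idx, seq_len(ca)]
                    chainMat[nChains, cb] <- b
                    roots[nChains] <- rt
                    forkCount[nChains] <- 0L
                    for (cy in which(!is.na(chainMat[nChains, ])))
                        member[[chainMat[nChains, cy]]] <-
                            c(member[[chainMat[nChains, cy]]], nChains)
                }
            }
        }
    }
    chains <- lapply(seq_len(nChains), function(i) chainMat[i, ])
    if (!length(chains))
        return(list(reads = data.frame(readId = integer(0),
                                       barcode = character(0),
                                       x = numeric(0), y = numeric(0),
                                       section = integer(0),
                                       nCalled = integer(0),
                                       maxNRun = integer(0)),
                    dotMap = list()))
    overLimit <- which(vapply(seq_along(chains),
                              function(i) forkCount[roots[i]] > maxForks,
                              logical(1)))
    if (length(overLimit)) {
        dropRoots <- unique(roots[overLimit])
        keepIdx <- which(!(roots %in% dropRoots))
        message(sprintf("dropped %d chains from %d over-forked roots",
                        sum(roots %in% dropRoots), length(dropRoots)))
    } else keepIdx <- seq_along(chains)
    rows <- list(); dotMap <- list()
    for (i in keepIdx) {
        ch <- chains[[i]]
        called <- !is.na(ch)
        bc <- rep("N", nCycles)
        bc[called] <- channelToNt(chanOf[ch[called]])
        bcs <- paste0(bc, collapse = "")
        runN <- maxRunLength(bcs)
        if (runN > maxNRun) next
        ref <- ch[referenceCycle]
        if (!is.na(ref)) {
            px <- xOfV[ref]; py <- yOfV[ref]
        } else {
            ids <- ch[called]
            px <- mean(xOfV[ids]); py <- mean(yOfV[ids])
        }
        sec <- if (hasSection)
            as.integer(stats::median(secOfV[ch[called]]))
            else NA_integer_
        rows[[length(rows) + 1L]] <- data.frame(
            barcode = bcs, x = px, y = py, section = sec,
            nCalled = sum(called), maxNRun = runN)
        dotMap[[length(dotMap) + 1L]] <- ch
    }
    if (!length(rows))
        return(list(reads = data.frame(readId = integer(0),
                                       barcode = character(0),
                                       x = numeric(0), y = numeric(0),
                                       section = integer(0),
                                       nCalled = integer(0),
                                       maxNRun = integer(0)),
                    dotMap = list()))
    reads <- do.call(rbind, rows)
    reads$readId <- seq_len(nrow(reads))
    rownames(reads) <- NULL
    list(reads = reads[, c("readId", "barcode", "x", "y", "section",
                           "nCalled", "maxNRun")],
         dotMap = dotMap)
}

#' Chain and assemble reads section by section
#'
#' Convenience wrapper running [chainDots()] and [assembleSequences()]
#' independently within each section of an aligned dot table (rolonies
#' never chain across sections) and concatenating the reads.
#'
#' @param dots aligned dot table (dotId, cycle, section, x, y, channel).
#' @param nCycles number of sequencing cycles.
#' @param gate,lookback passed to [chainDots()].
#' @param ... passed to [assembleSequences()].
#' @return list with `reads` (re-numbered readIds) and `dotMap`.
#' @export
assembleBySection <- function(dots, nCycles, gate = 5, lookback = 3, ...) {
    reads <- list(); dotMap <- list()
    for (sec in sort(unique(dots$section))) {
        ds <- dots[dots$section == sec, , drop = FALSE]
        m <- chainDots(ds, gate = gate, lookback = lookback)
        asm <- assembleSequences(m, ds, nCycles = nCycles, ...)
        if (nrow(asm$reads)) {
            reads[[length(reads) + 1L]] <- asm$reads
            dotMap <- c(dotMap, asm$dotMap)
        }
    }
    if (!length(reads))
        return(list(reads = data.frame(readId = integer(0),
                                       barcode = character(0),
                                       x = numeric(0), y = numeric(0),
                                       section = integer(0),
                                       nCalled = integer(0),
                                       maxNRun = integer(0)),
                    dotMap = list()))
    out <- do.call(rbind, reads)
    out$readId <- seq_len(nrow(out))
    rownames(out) <- NULL
    list(reads = out, dotMap = dotMap)
}

#' Exclude reads close to somata
#'
#' Removes a read when, in more than `minCycles` sequencing cycles, at
#' least `minPixels` soma pixels lie within `radiusUm` of its position
#' (high signal density around somata makes base-calling unreliable).
#'
#' @param reads read table (x, y in pixels; section).
#' @param somaPixels data.frame of soma pixels: x, y (pixels), section,
#'   cycle. NULL or empty keeps everything (with a warning for NULL).
#' @param radiusUm exclusion radius in micrometres.
#' @param minPixels soma-pixel count threshold per cycle.
#' @param minCycles a read is removed only when strictly more than this
#'   many cycles exceed `minPixels`.
#' @param pixelSize micrometres per pixel.
#' @return the filtered read table.
#' @export
excludePerisomatic <- function(reads, somaPixels, radiusUm = 20,
                               minPixels = 35, minCycles = 2,
                               pixelSize = 0.55) {
    if (is.null(somaPixels)) {
        warning("no soma pixel map; perisomatic exclusion skipped")
        return(reads)
    }
    if (!nrow(somaPixels) || !nrow(reads)) return(reads)
    rad <- radiusUm / pixelSize
    drop <- logical(nrow(reads))
    for (i in seq_len(nrow(reads))) {
        sp <- somaPixels
        if (!is.na(reads$section[i]) && "section" %in% names(sp))
            sp <- sp[sp$section == reads$section[i], ]
        if (!nrow(sp)) next
        d <- sqrt((sp$x - reads$x[i])^2 + (sp$y - reads$y[i])^2)
        nearby <- sp[d <= rad, ]
        if (!nrow(nearby)) next
        perCycle <- table(nearby$cycle)
        drop[i] <- sum(perCycle >= minPixels) > minCycles
    }
    reads[!drop, , drop = FALSE]
}

#' Base-call soma pixels with phasing correction
#'
#' Somata are base-called per pixel rather than per local maximum. To
#' correct carry-over (phasing) of the previous cycle's signal, each
#' cycle's channel intensities are reduced by the previous cycle's: 50%
#' of the previous intensity for the channel that was the previous
#' argmax, 100% for the other channels, clipped at zero. The call is the
#' argmax of the corrected channels; an all-zero pixel calls N.
#'
#' @param intensities numeric array, dim c(nPixels, nCycles, 4).
#' @param phasingMax fraction subtracted for the previous argmax channel.
#' @param phasingOther fraction subtracted for the remaining channels.
#' @return list with `barcodes` (character, one per pixel) and
#'   `corrected` (the corrected intensity array).
#' @export
basecallSoma <- function(intensities, phasingMax = 0.5, phasingOther = 1) {
    stopifnot(length(dim(intensities)) == 3, dim(intensities)[3] == 4)
    np <- dim(intensities)[1]; nc <- dim(intensities)[2]
    corrected <- intensities
    calls <- matrix("N", np, nc)
    for (cy in seq_len(nc)) {
        cur <- intensities[, cy, , drop = FALSE]
        dim(cur) <- c(np, 4)
        if (cy > 1) {
            prev <- intensities[, cy - 1, , drop = FALSE]
            dim(prev) <- c(np, 4)
            prevPos <- rowSums(prev) > 0
            prevArgmax <- max.col(prev, ties.method = "first")
            fac <- matrix(phasingOther, np, 4)
            fac[cbind(which(prevPos), prevArgmax[prevPos])] <- phasingMax
            cur <- pmax(cur - fac * prev, 0)
        }
        corrected[, cy, ] <- cur
        pos <- rowSums(cur) > 0
        am <- max.col(cur, ties.method = "first")
        calls[pos, cy] <- NT_LETTERS[am[pos]]
    }
    list(barcodes = apply(calls, 1, paste0, collapse = ""),
         corrected = corrected)
}
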