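# Shared fixtures, built in code at test time.

# Half-cylindrical cortical shell: cortex (label 1) between radii rIn and
# rOut, interior core (label 2), non-cortical tissue (label 3) below the
# cut plane so the cut face is not a cortical boundary, empty space
# (label 0) outside. Cylinder axis along z.
makeHalfCylinder <- function(rIn = 8, rOut = 20, nz = 10, voxelSize = 25) {
    nx <- 2 * rOut + 8
    ny <- rOut + 6
    cx <- nx / 2
    cy <- 1
    lab <- array(0L, c(nx, ny, nz))
    for (i in seq_len(nx)) for (j in seq_len(ny)) {
        rho <- sqrt((i - 0.5 - cx)^2 + (j - 0.5 - cy)^2)
        up <- (j - 0.5) >= cy + 1
        l <- if (rho > rOut) 0L else if (!up) 3L
             else if (rho <= rIn) 2L else 1L
        lab[i, j, ] <- l
    }
    list(vol = annotationVolume(lab, voxelSize = voxelSize),
         cx = cx, cy = cy, rIn = rIn, rOut = rOut, nz = nz,
         voxelSize = voxelSize)
}

# Flat cortical slab: cortex rows jTop..jTop+thick-1 (outer side at low
# y), interior below, space above.
makeSlab <- function(nx = 20, thick = 8, nz = 6, voxelSize = 25,
                     hemisphereSplit = NULL) {
    ny <- thick + 6
    jTop <- 3
    lab <- array(0L, c(nx, ny, nz))
    lab[, jTop:(jTop + thick - 1), ] <- 1L
    lab[, (jTop + thick):ny, ] <- 2L
    hemi <- NULL
    if (!is.null(hemisphereSplit)) {
        hemi <- array(2L, dim(lab))
        hemi[seq_len(hemisphereSplit), , ] <- 1L
    }
    list(vol = annotationVolume(lab, voxelSize = voxelSize,
                                hemisphere = hemi),
         jTop = jTop, thick = thick, nx = nx, ny = ny, nz = nz,
         voxelSize = voxelSize)
}

# dots for a single rolony observed across cycles at one position
chainFixture <- function(positions, channels, cycles = seq_along(channels),
                         startId = 1L) {
    data.frame(dotId = startId + seq_along(cycles) - 1L,
               cycle = cycles, section = 1L,
               x = positions[, 1], y = positions[, 2],
               channel = channels)
}

# brute-force strict-lookup Hamming oracle: enumerate every
# substitution of the N positions in both strings independently; the
# distance is 0 when some substitution matches exactly, otherwise the
# worst case over substitutions (an uncertain position counts as a
# mismatch as soon as any true mismatch exists).
strictHammingOracle <- function(a, b) {
    av <- strsplit(a, "")[[1]]
    bv <- strsplit(b, "")[[1]]
    slots <- rbind(
        if (any(av == "N")) cbind(which(av == "N"), 1),
        if (any(bv == "N")) cbind(which(bv == "N"), 2))
    if (is.null(slots) || !nrow(slots)) return(sum(av != bv))
    letters4 <- c("G", "T", "A", "C")
    subs <- expand.grid(rep(list(letters4), nrow(slots)),
                        stringsAsFactors = FALSE)
    dists <- apply(subs, 1, function(ch) {
        a2 <- av; b2 <- bv
        for (s in seq_len(nrow(slots))) {
            if (slots[s, 2] == 1) a2[slots[s, 1]] <- ch[s]
            else b2[slots[s, 1]] <- ch[s]
        }
        sum(a2 != b2)
    })
    if (min(dists) == 0) return(0L)
    # worst case with both-N positions counted once
    doubleCalled <- sum(av != bv & av != "N" & bv != "N")
    eitherN <- sum(av == "N" | bv == "N")
    as.integer(doubleCalled + eitherN)
}

# random barcode of length n over the 4 letters
randomBarcode <- function(n = 17) {
    paste0(sample(c("G", "T", "A", "C"), n, replace = TRUE), collapse = "")
}
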