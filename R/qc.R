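# Barcode and rolony quality-control filters: error-prone barcode
# exclusion, count gates, secondary-infection screening, overlap
# deduplication, soma identification, floating-rolony detection and
# non-neural cell exclusion. Rolony tables carry micrometre coordinates
# (x, y tangential within a section; section index along the cutting
# axis) plus barcode, region and field-of-origin columns.

#' Default per-region minimum rolony counts
#'
#' Post-registration minimums below which a region's count is zeroed: 5
#' for ipsilateral/contralateral cortex and thalamus, 3 for striatum and
#' midbrain. Regions not used as projection targets (injection site,
#' fiber tract) carry no minimum and never satisfy the target gate.
#'
#' @return named numeric vector of minimum counts per region.
#' @export
defaultRegionMinimums <- function() {
    c(AudI = Inf, Fiber = Inf, VisI = 5, CtxC = 5, Thal = 5, Str = 3,
      Midbrain = 3)
}

#' Region count matrix
#'
#' @param rolonies rolony table with barcode and region columns.
#' @param regionMinimums named vector naming the known regions; counts
#'   below a region's minimum are zeroed (`Inf` always zeroes).
#' @return integer matrix, rows = barcodes, cols = regions (gated
#'   counts), with attribute `raw` holding the ungated counts.
#' @export
regionCounts <- function(rolonies, regionMinimums = defaultRegionMinimums()) {
    unknown <- setdiff(unique(rolonies$region), names(regionMinimums))
    if (length(unknown))
        stop("unknown region label(s): ", paste(unknown, collapse = ", "))
    tab <- table(rolonies$barcode,
                 factor(rolonies$region, levels = names(regionMinimums)))
    raw <- matrix(as.integer(tab), nrow = nrow(tab),
                  dimnames = dimnames(tab))
    gated <- raw
    for (r in colnames(gated)) {
        below <- gated[, r] < regionMinimums[[r]]
        gated[below, r] <- 0L
    }
    attr(gated, "raw") <- raw
    gated
}

#' Filter error-prone barcodes
#'
#' Applies, in order: (1) exclude barcodes with more than `maxRun`
#' continuous identical nucleotides; (2) exclude barcodes with more than
#' `maxChannelPair` called nucleotides in channels 1/2 (G/T) or channels
#' 3/4 (A/C); (3) exclude barcodes with more rolonies at 1 or 2
#' mismatches than at 0 mismatches.
#'
#' @param codebook a \linkS4class{Codebook}.
#' @param matchDistances optional data.frame with columns entry and
#'   distance (one row per matched read, e.g. from [matchToCodebook()]);
#'   required for rule 3, which is skipped with a warning otherwise.
#' @param maxRun rule-1 run limit (exclude when strictly greater).
#' @param maxChannelPair rule-2 per-channel-pair limit (exclude when
#'   strictly greater).
#' @return list with `codebook` (filtered) and `report` (data.frame
#'   rule, removed).
#' @export
filterErrorProne <- function(codebook, matchDistances = NULL, maxRun = 6,
                             maxChannelPair = 14) {
    ent <- entries(codebook)
    removed <- integer(3)
    keep1 <- maxIdenticalRun(ent$barcode) <= maxRun
    removed[1] <- sum(!keep1)
    ent <- ent[keep1, , drop = FALSE]
    inPair <- function(bc) {
        ch <- strsplit(bc, "", fixed = TRUE)[[1]]
        c(sum(ch %in% c("G", "T")), sum(ch %in% c("A", "C")))
    }
    pairCounts <- t(vapply(ent$barcode, inPair, numeric(2)))
    keep2 <- pairCounts[, 1] <= maxChannelPair &
             pairCounts[, 2] <= maxChannelPair
    removed[2] <- sum(!keep2)
    ent <- ent[keep2, , drop = FALSE]
    if (is.null(matchDistances)) {
        if (nrow(ent)) warning("no match distances; mismatch-ratio rule skipped")
        keep3 <- rep(TRUE, nrow(ent))
    } else {
        keep3 <- vapply(ent$barcode, function(bc) {
            d <- matchDistances$distance[matchDistances$entry == bc]
            sum(d %in% 1:2) <= sum(d == 0)
        }, logical(1))
    }
    removed[3] <- sum(!keep3)
    ent <- ent[keep3, , drop = FALSE]
    rownames(ent) <- NULL
    list(codebook = new("Codebook", entries = ent,
                        fixedPositions = codebook@fixedPositions,
                        variableLength = codebook@variableLength),
         report = data.frame(
             rule = c("identical-run", "channel-pair", "mismatch-ratio"),
             removed = removed))
}

#' Apply barcode count gates
#'
#' A barcoded cell is kept iff (1) it has at least `minTargetCount`
#' rolonies in at least one target region after the per-region minimums
#' zero sub-threshold counts, (2) its axonal rolony count lies in
#' [`minAxonal`, `maxAxonal`], and (3) its somal barcode pixel count is
#' at most `maxSomal`.
#'
#' @param rolonies axonal rolony table (barcode, region, ...).
#' @param somaCounts optional named vector of somal barcode pixel counts
#'   (missing barcodes count 0).
#' @param regionMinimums named per-region minimums (see
#'   [defaultRegionMinimums()]).
#' @param targetRegions regions eligible for gate 1 (default: those with
#'   finite minimums).
#' @param minTargetCount,minAxonal,maxAxonal,maxSomal gate thresholds.
#' @return list with `kept` (barcodes passing), `counts` (gated region
#'   count matrix) and `report`.
#' @export
applyCountGates <- function(rolonies, somaCounts = NULL,
                            regionMinimums = defaultRegionMinimums(),
                            targetRegions = NULL, minTargetCount = 10,
                            minAxonal = 3, maxAxonal = 1000,
                            maxSomal = 7000) {
    counts <- regionCounts(rolonies, regionMinimums)
    if (is.null(targetRegions))
        targetRegions <- names(regionMinimums)[is.finite(regionMinimums)]
    bcs <- rownames(counts)
    axonal <- as.integer(table(rolonies$barcode)[bcs])
    g1 <- apply(counts[, targetRegions, drop = FALSE] >= minTargetCount,
                1, any)
    g2 <- axonal >= minAxonal & axonal <= maxAxonal
    soma <- if (is.null(somaCounts)) rep(0, length(bcs))
            else ifelse(is.na(somaCounts[bcs]), 0, somaCounts[bcs])
    g3 <- soma <= maxSomal
    keep <- g1 & g2 & g3
    list(kept = bcs[keep], counts = counts,
         report = data.frame(gate = c("target-region", "axonal-count",
                                      "somal-count"),
                             failed = c(sum(!g1), sum(!g2), sum(!g3))))
}

#' Exclude barcodes near secondary-infection contaminants
#'
#' Removes any barcode within `radius` Hamming distance (permissive
#' convention, fixed positions excluded) of a known contaminant barcode.
#'
#' @param barcodesToCheck character vector of cell barcodes.
#' @param contaminants character vector of contaminant barcodes.
#' @param radius Hamming radius (default 4).
#' @param fixedPositions positions excluded from the distance.
#' @return logical vector, TRUE = keep.
#' @export
excludeSecondary <- function(barcodesToCheck, contaminants, radius = 4,
                             fixedPositions = c(9L, 10L)) {
    if (!length(contaminants)) return(rep(TRUE, length(barcodesToCheck)))
    vapply(barcodesToCheck, function(bc) {
        all(hammingDistance(bc, contaminants, "permissive",
                            exclude = fixedPositions) > radius)
    }, logical(1), USE.NAMES = FALSE)
}

#' Deduplicate rolonies across overlapping imaging fields
#'
#' In regions imaged by overlapping fields, keeps only one copy per
#' barcode among same-barcode rolonies recorded in different fields
#' within `range` micrometres of each other (same-field neighbours are
#' genuine distinct rolonies and are kept).
#'
#' @param rolonies rolony table with barcode, x, y, section, field.
#' @param range exclusion range in micrometres (strictly-less-than).
#' @return deduplicated rolony table.
#' @export
dedupOverlap <- function(rolonies, range = 25) {
    if (!nrow(rolonies)) return(rolonies)
    keep <- rep(TRUE, nrow(rolonies))
    for (bc in unique(rolonies$barcode)) {
        idx <- which(rolonies$barcode == bc)
        if (length(idx) < 2) next
        kept <- integer(0)
        for (i in idx) {
            dup <- FALSE
            for (j in kept) {
                if (rolonies$field[i] != rolonies$field[j] &&
                    rolonies$section[i] == rolonies$section[j]) {
                    d <- sqrt((rolonies$x[i] - rolonies$x[j])^2 +
                              (rolonies$y[i] - rolonies$y[j])^2)
                    if (d < range) { dup <- TRUE; break }
                }
            }
            if (dup) keep[i] <- FALSE else kept <- c(kept, i)
        }
    }
    rolonies[keep, , drop = FALSE]
}

#' Identify a barcode's soma location
#'
#' The soma section is the section with the highest summed soma-pixel
#' intensity; within it the brightest pixel gives the location. The soma
#' is valid only with at least `minCounts` same-barcode soma pixels
#' within `radius` micrometres of that location on the soma section.
#'
#' @param somaPixels soma pixels of one barcode: x, y (micrometres),
#'   section, intensity.
#' @param minCounts minimum barcode counts within the radius.
#' @param radius validation radius in micrometres.
#' @return list(x, y, section) or NULL when no valid soma.
#' @export
identifySoma <- function(somaPixels, minCounts = 80, radius = 100) {
    if (is.null(somaPixels) || !nrow(somaPixels)) return(NULL)
    sums <- tapply(somaPixels$intensity, somaPixels$section, sum)
    sec <- as.integer(names(sums)[which.max(sums)])
    onSec <- somaPixels[somaPixels$section == sec, ]
    best <- onSec[which.max(onSec$intensity), ]
    d <- sqrt((onSec$x - best$x)^2 + (onSec$y - best$y)^2)
    if (sum(d <= radius) < minCounts) return(NULL)
    list(x = best$x, y = best$y, section = sec)
}

#' Detect a floating-rolony section
#'
#' For barcodes without a known soma, finds the section where rolonies
#' floated off the soma and settled: candidate rolonies are those with
#' no same-barcode neighbour within `neighborRadius` (tangential) on any
#' section more than one away; a section qualifies when its candidates
#' form at least `minClusters` single-linkage clusters separated by more
#' than `clusterGap`; among qualifying sections the one with the widest
#' tangential coverage (bounding-box diagonal) is returned.
#'
#' @param rolonies one barcode's rolonies (x, y, section) restricted to
#'   the scanned regions (by default AudI, Thal, VisI).
#' @param regions regions searched for floaters.
#' @param neighborRadius tangential isolation radius, micrometres.
#' @param minClusters minimum spread-out clusters on a section.
#' @param clusterGap single-linkage cut, micrometres.
#' @return the flagged section index, or NA when none qualifies.
#' @export
detectFloatingSections <- function(rolonies,
                                   regions = c("AudI", "Thal", "VisI"),
                                   neighborRadius = 140, minClusters = 3,
                                   clusterGap = 50) {
    if (!is.null(rolonies$region))
        rolonies <- rolonies[rolonies$region %in% regions, , drop = FALSE]
    n <- nrow(rolonies)
    if (n < minClusters) return(NA_integer_)
    isCand <- logical(n)
    for (i in seq_len(n)) {
        far <- abs(rolonies$section - rolonies$section[i]) > 1
        if (!any(far)) { isCand[i] <- TRUE; next }
        d <- sqrt((rolonies$x[far] - rolonies$x[i])^2 +
                  (rolonies$y[far] - rolonies$y[i])^2)
        isCand[i] <- all(d >= neighborRadius)
    }
    cand <- rolonies[isCand, , drop = FALSE]
    if (!nrow(cand)) return(NA_integer_)
    best <- NA_integer_
    bestCover <- -Inf
    for (sec in unique(cand$section)) {
        cs <- cand[cand$section == sec, , drop = FALSE]
        if (nrow(cs) < minClusters) next
        cl <- singleLinkageClusters(cs[, c("x", "y")], clusterGap)
        if (length(unique(cl)) < minClusters) next
        cover <- sqrt(diff(range(cs$x))^2 + diff(range(cs$y))^2)
        if (cover > bestCover) { bestCover <- cover; best <- sec }
    }
    as.integer(best)
}

#' Exclude floating rolonies around an anchor section
#'
#' Removes rolonies in the scanned regions within `window` sections of
#' the anchor (the soma section when known, otherwise the flagged
#' floating-rolony section).
#'
#' @param rolonies one barcode's rolony table.
#' @param anchorSection soma or flagged section (NA = identity).
#' @param window sections on each side (2 by default, 3 optionally).
#' @param regions regions subject to the exclusion.
#' @return filtered rolony table.
#' @export
excludeFloating <- function(rolonies, anchorSection, window = 2,
                            regions = c("AudI", "Thal", "VisI")) {
    if (is.na(anchorSection) || is.null(anchorSection)) return(rolonies)
    drop <- rolonies$region %in% regions &
            abs(rolonies$section - anchorSection) <= window
    rolonies[!drop, , drop = FALSE]
}

#' Exclude non-neural cells
#'
#' Keeps a cell only when it has at least `minCount` axonal rolonies at
#' `minDistance` micrometres or more from its anchor (the soma when
#' known, otherwise the centroid of its axonal rolonies); non-neural
#' cells do not have long projections.
#'
#' @param rolonies one barcode's axonal rolonies (x, y, z micrometres).
#' @param soma optional list/row with x, y, z.
#' @param minCount,minDistance thresholds.
#' @return TRUE to keep the cell.
#' @export
excludeNonNeural <- function(rolonies, soma = NULL, minCount = 3,
                             minDistance = 200) {
    if (!nrow(rolonies)) return(FALSE)
    anchor <- if (!is.null(soma)) c(soma$x, soma$y, soma$z)
              else colMeans(rolonies[, c("x", "y", "z")])
    d <- sqrt((rolonies$x - anchor[1])^2 + (rolonies$y - anchor[2])^2 +
              (rolonies$z - anchor[3])^2)
    sum(d >= minDistance) >= minCount
}

#' Run the QC filter chain with a stage ledger
#'
#' Applies the barcode-level filters in the pipeline's order — count
#' gates, secondary-infection exclusion, per-barcode overlap
#' deduplication, floating-rolony exclusion, non-neural exclusion — and
#' records a telescoping ledger (input = kept + removed at each stage).
#'
#' @param rolonies axonal rolony table (barcode, x, y, z, section,
#'   region, field).
#' @param somata named list of soma locations (list(x, y, z, section))
#'   per barcode; barcodes absent use the floating-section detector.
#' @param contaminants contaminant barcode list.
#' @param somaCounts named somal pixel counts per barcode.
#' @param regionMinimums named per-region minimums.
#' @param floatingWindow sections excluded on each side of the anchor.
#' @return list with `cells` (kept barcodes), `rolonies` (filtered
#'   table) and `ledger` (stage, input, kept, removed).
#' @export
runQcChain <- function(rolonies, somata = list(), contaminants = character(0),
                       somaCounts = NULL,
                       regionMinimums = defaultRegionMinimums(),
                       floatingWindow = 2) {
    ledger <- data.frame(stage = character(0), input = integer(0),
                         kept = integer(0), removed = integer(0))
    note <- function(stage, input, kept) {
        ledger <<- rbind(ledger, data.frame(
            stage = stage, input = input, kept = kept,
            removed = input - kept))
    }
    cells <- unique(rolonies$barcode)
    gates <- applyCountGates(rolonies, somaCounts, regionMinimums)
    note("count-gates", length(cells), length(gates$kept))
    cells <- gates$kept
    keepSec <- excludeSecondary(cells, contaminants)
    note("secondary-infection", length(cells), sum(keepSec))
    cells <- cells[keepSec]
    rol <- rolonies[rolonies$barcode %in% cells, , drop = FALSE]
    n0 <- nrow(rol)
    rol <- dedupOverlap(rol)
    note("overlap-dedup", n0, nrow(rol))
    n0 <- nrow(rol)
    parts <- lapply(cells, function(bc) {
        rb <- rol[rol$barcode == bc, , drop = FALSE]
        anchor <- if (!is.null(somata[[bc]])) somata[[bc]]$section
                  else detectFloatingSections(rb)
        excludeFloating(rb, anchor, window = floatingWindow)
    })
    rol <- do.call(rbind, parts)
    note("floating-rolonies", n0, nrow(rol))
    keepNeural <- vapply(cells, function(bc) {
        excludeNonNeural(rol[rol$barcode == bc, , drop = FALSE],
                         soma = somata[[bc]])
    }, logical(1))
    note("non-neural", length(cells), sum(keepNeural))
    cells <- cells[keepNeural]
    rol <- rol[rol$barcode %in% cells, , drop = FALSE]
    rownames(rol) <- NULL
    list(cells = cells, rolonies = rol, ledger = ledger)
}
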