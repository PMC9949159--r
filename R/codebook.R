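# Codebook construction and Hamming-distance matching. Two conventions
# are used at different stages: the permissive convention (N matches all
# four nucleotides; the fixed library positions are excluded) for
# codebook separation and contaminant screening, and the strict lookup
# convention (an N counts as a mismatch as soon as any true mismatch is
# present; all positions included) for matching reads to the codebook.

#' Hamming distance under the pipeline's conventions
#'
#' Under `"permissive"`, N matches any nucleotide and the positions in
#' `exclude` are skipped; the distance is the number of included
#' positions where both strings are called and differ. Under `"strict"`
#' (the lookup convention), with m the number of mismatches at included
#' doubly-called positions and k the number of included positions where
#' either string is N, the distance is 0 when m = 0 and m + k otherwise
#' (a position where both strings have N counts once).
#'
#' @param a,b barcode strings of equal length (alphabet G, T, A, C, N).
#'   `b` may be a vector; the result is vectorized over it.
#' @param convention "permissive" or "strict".
#' @param exclude 1-based positions skipped from the calculation
#'   (typically the fixed library positions; use `integer()` to include
#'   all positions, as codebook lookup does).
#' @return integer vector of distances.
#' @export
hammingDistance <- function(a, b, convention = c("permissive", "strict"),
                            exclude = c(9L, 10L)) {
    convention <- match.arg(convention)
    if (any(nchar(b) != nchar(a))) stop("barcode lengths differ")
    av <- strsplit(a, "", fixed = TRUE)[[1]]
    bm <- barcodeMatrix(b)
    keep <- setdiff(seq_along(av), exclude)
    am <- matrix(av[keep], nrow = nrow(bm), ncol = length(keep),
                 byrow = TRUE)
    bm <- bm[, keep, drop = FALSE]
    anyN <- am == "N" | bm == "N"
    mism <- am != bm & !anyN
    m <- rowSums(mism)
    if (convention == "permissive") return(as.integer(m))
    k <- rowSums(anyN)
    as.integer(ifelse(m == 0, 0L, m + k))
}

# composition limits used by codebook acceptance:
# (a) < maxSame identical called nucleotides (counted over called
#     positions including the fixed ones),
# (b) >= minCalled of the variable positions base-called,
# (c) N-run <= maxNRun.
.passesComposition <- function(bc, fixedPositions, maxSame = 14,
                               minCalled = 13, maxNRun = 3) {
    ch <- strsplit(bc, "", fixed = TRUE)[[1]]
    counts <- table(ch[ch != "N"])
    if (length(counts) && max(counts) >= maxSame) return(FALSE)
    varPos <- setdiff(seq_along(ch), fixedPositions)
    if (sum(ch[varPos] != "N") < minCalled) return(FALSE)
    if (maxRunLength(bc) > maxNRun) return(FALSE)
    TRUE
}

#' Build the codebook of true barcodes
#'
#' Aggregates reads by barcode identity, collapses partially called
#' variants by permissive-N consensus clustering (candidates agreeing at
#' every doubly-called position merge under the strongest anchor, whose
#' N positions are resolved by the support-weighted majority of the
#' absorbed reads), then accepts candidates greedily in descending
#' support order under the codebook assumptions: a true barcode is seen in at
#' least `minSupport` rolonies, has a higher count than its erroneous
#' versions, passes the composition limits (< `maxSame` identical
#' nucleotides; at least `minCalled` of the variable positions called;
#' N-run at most `maxNRun`), and no two accepted barcodes lie within
#' Hamming distance 1 of each other (permissive convention, fixed
#' positions excluded). The support of a candidate rejected as a
#' 1-neighbour is attributed to its accepted neighbour.
#'
#' @param reads character vector of barcodes, or a read table with a
#'   `barcode` column.
#' @param fixedPositions fixed library positions excluded from the
#'   separation distance.
#' @param minSupport minimum rolony count.
#' @param maxSame,minCalled,maxNRun composition limits.
#' @return a \linkS4class{Codebook}.
#' @export
buildCodebook <- function(reads, fixedPositions = c(9L, 10L),
                          minSupport = 3, maxSame = 14, minCalled = 13,
                          maxNRun = 3) {
    bcs <- if (is.data.frame(reads)) reads$barcode else reads
    if (!length(bcs))
        return(new("Codebook",
                   entries = data.frame(barcode = character(0),
                                        support = integer(0),
                                        attributed = integer(0)),
                   fixedPositions = as.integer(fixedPositions),
                   variableLength = 0L))
    L <- nchar(bcs[1])
    tab <- table(bcs)
    cand <- data.frame(barcode = names(tab), support = as.integer(tab),
                       stringsAsFactors = FALSE)
    # permissive-N consensus clustering: candidates that agree at every
    # doubly-called position collapse under the strongest anchor, whose
    # non-base-called positions are then resolved by the support-weighted
    # majority of the absorbed reads (partially called reads must not
    # splinter a true barcode's support, nor drift onto an erroneous
    # fully-called variant)
    nCalled <- nchar(cand$barcode) -
        vapply(strsplit(cand$barcode, "", fixed = TRUE),
               function(ch) sum(ch == "N"), integer(1))
    ord <- order(-cand$support, -nCalled, cand$barcode)
    cand <- cand[ord, , drop = FALSE]
    absorbed <- logical(nrow(cand))
    outBc <- character(0)
    outSup <- integer(0)
    for (i in seq_len(nrow(cand))) {
        if (absorbed[i]) next
        free <- which(!absorbed)
        free <- free[free >= i]
        d0 <- free[hammingDistance(cand$barcode[i], cand$barcode[free],
                                   "permissive", exclude = integer(0)) == 0]
        absorbed[d0] <- TRUE
        members <- barcodeMatrix(cand$barcode[d0])
        w <- cand$support[d0]
        consensus <- vapply(seq_len(L), function(p) {
            votes <- tapply(w, members[, p], sum)
            votes <- votes[names(votes) != "N"]
            if (!length(votes)) return("N")
            names(votes)[order(-votes, names(votes))][1]
        }, character(1))
        outBc <- c(outBc, paste0(consensus, collapse = ""))
        outSup <- c(outSup, sum(w))
    }
    sup <- tapply(outSup, outBc, sum)  # clusters may share a consensus
    cand <- data.frame(barcode = names(sup), support = as.integer(sup),
                       stringsAsFactors = FALSE)
    cand <- cand[order(-cand$support, cand$barcode), ]
    accepted <- character(0)
    support <- integer(0)
    attributed <- integer(0)
    rejectedNear <- list()
    for (i in seq_len(nrow(cand))) {
        bc <- cand$barcode[i]
        s <- cand$support[i]
        near <- if (length(accepted))
            which(hammingDistance(bc, accepted, "permissive",
                                  exclude = fixedPositions) <= 1)
            else integer(0)
        if (length(near)) {
            # erroneous version of an already-accepted (higher-count)
            # barcode: attribute its support to the nearest neighbour
            j <- near[1]
            support[j] <- support[j] + s
            attributed[j] <- attributed[j] + s
            next
        }
        if (s < minSupport) next
        if (!.passesComposition(bc, fixedPositions, maxSame, minCalled,
                                maxNRun)) next
        accepted <- c(accepted, bc)
        support <- c(support, s)
        attributed <- c(attributed, 0L)
    }
    new("Codebook",
        entries = data.frame(barcode = accepted, support = support,
                             attributed = attributed,
                             stringsAsFactors = FALSE),
        fixedPositions = as.integer(fixedPositions),
        variableLength = as.integer(L - length(fixedPositions)))
}

#' Match barcodes to the codebook
#'
#' Looks each query up under the strict convention with all positions
#' included. A query is `matched` to the nearest entry when that entry is
#' unique at distance <= `maxDistance`, `ambiguous` (and discarded
#' downstream) when two or more entries tie at the minimum distance, and
#' `unmatched` otherwise.
#'
#' @param queries character vector of barcodes, or a table with a
#'   `barcode` column.
#' @param codebook a \linkS4class{Codebook}.
#' @param maxDistance match cut-off (default 2).
#' @return data.frame with query, entry (NA unless matched), distance,
#'   verdict.
#' @export
matchToCodebook <- function(queries, codebook, maxDistance = 2) {
    q <- if (is.data.frame(queries)) queries$barcode else queries
    ents <- barcodes(codebook)
    out <- data.frame(query = q, entry = NA_character_,
                      distance = NA_integer_,
                      verdict = "unmatched", stringsAsFactors = FALSE)
    if (!length(ents) || !length(q)) return(out)
    uq <- unique(q)
    res <- lapply(uq, function(b) {
        d <- hammingDistance(b, ents, "strict", exclude = integer(0))
        dm <- min(d)
        if (dm > maxDistance) return(list(NA_character_, NA_integer_,
                                          "unmatched"))
        hits <- which(d == dm)
        if (length(hits) > 1) return(list(NA_character_, as.integer(dm),
                                          "ambiguous"))
        list(ents[hits], as.integer(dm), "matched")
    })
    names(res) <- uq
    for (i in seq_along(q)) {
        r <- res[[q[i]]]
        out$entry[i] <- r[[1]]
        out$distance[i] <- r[[2]]
        out$verdict[i] <- r[[3]]
    }
    out
}

#' Condense matched reads sharing rolonies
#'
#' Axonal barcode correction after lookup: (1) a dot claimed by reads
#' matched to more than one codebook barcode is blanked to N in all
#' claimants; (2) reads violating the length and N-interval limits after
#' blanking are excluded; (3) within a matched barcode, reads whose dot
#' sets overlap at Jaccard >= `jaccard` are condensed into the read with
#' the most base-called digits.
#'
#' @param assembled output of [assembleSequences()] (reads + dotMap).
#' @param matches output of [matchToCodebook()] aligned to the reads
#'   (row i describes read i).
#' @param maxNRun longest tolerated N run after blanking.
#' @param minCalledTotal minimum called positions after blanking.
#' @param jaccard dot-set similarity above which reads collapse.
#' @return list with `reads`, `dotMap`, `entry` (matched barcode per
#'   surviving read).
#' @export
condenseReads <- function(assembled, matches, maxNRun = 3,
                          minCalledTotal = 13, jaccard = 0.8) {
    reads <- assembled$reads
    dotMap <- assembled$dotMap
    stopifnot(nrow(reads) == nrow(matches))
    keep <- matches$verdict == "matched"
    reads <- reads[keep, , drop = FALSE]
    dotMap <- dotMap[keep]
    entry <- matches$entry[keep]
    if (!nrow(reads))
        return(list(reads = reads, dotMap = dotMap, entry = entry))
    # (1) blank dots claimed by more than one matched barcode
    claims <- list()
    for (i in seq_along(dotMap)) {
        ids <- dotMap[[i]]
        for (cy in which(!is.na(ids))) {
            k <- as.character(ids[cy])
            claims[[k]] <- unique(c(claims[[k]], entry[i]))
        }
    }
    shared <- names(claims)[vapply(claims, length, integer(1)) > 1]
    sharedIds <- as.integer(shared)
    bcm <- barcodeMatrix(reads$barcode)
    for (i in seq_along(dotMap)) {
        hit <- which(dotMap[[i]] %in% sharedIds)
        if (length(hit)) {
            dotMap[[i]][hit] <- NA_integer_
            bcm[i, hit] <- "N"
        }
    }
    reads$barcode <- matrixToBarcode(bcm)
    reads$nCalled <- rowSums(bcm != "N")
    reads$maxNRun <- maxRunLength(reads$barcode)
    # (2) re-apply length and interval limits
    ok <- reads$maxNRun <= maxNRun & reads$nCalled >= minCalledTotal
    reads <- reads[ok, , drop = FALSE]
    dotMap <- dotMap[ok]
    entry <- entry[ok]
    # (3) condense similar dot sets within a matched barcode
    keepRow <- rep(TRUE, nrow(reads))
    for (e in unique(entry)) {
        idx <- which(entry == e)
        if (length(idx) < 2) next
        idx <- idx[order(-reads$nCalled[idx], reads$readId[idx])]
        kept <- integer(0)
        for (i in idx) {
            di <- dotMap[[i]][!is.na(dotMap[[i]])]
            dup <- FALSE
            for (j in kept) {
                dj <- dotMap[[j]][!is.na(dotMap[[j]])]
                inter <- length(intersect(di, dj))
                uni <- length(union(di, dj))
                if (uni > 0 && inter / uni >= jaccard) { dup <- TRUE; break }
            }
            if (dup) keepRow[i] <- FALSE else kept <- c(kept, i)
        }
    }
    list(reads = reads[keepRow, , drop = FALSE],
         dotMap = dotMap[keepRow], entry = entry[keepRow])
}
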