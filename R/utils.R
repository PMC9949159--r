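# Shared helpers: nucleotide/channel coding, barcode matrices, tie-aware
# modes, run lengths. Channel order follows the imaging convention
# (channel 1..4 = G, T, A, C).

NT_LETTERS <- c("G", "T", "A", "C")

#' Convert between channels and nucleotides
#'
#' Sequencing channels 1..4 image G, T, A and C respectively; channel 0 /
#' `NA` encodes a non-base-called position (N).
#'
#' @param channel integer vector in 0..4 (0 or NA = N).
#' @param nt character vector over G, T, A, C, N.
#' @return `channelToNt` returns letters; `ntToChannel` returns integers
#'   (NA for N).
#' @export
channelToNt <- function(channel) {
    out <- rep("N", length(channel))
    ok <- !is.na(channel) & channel >= 1 & channel <= 4
    out[ok] <- NT_LETTERS[channel[ok]]
    out
}

#' @rdname channelToNt
#' @export
ntToChannel <- function(nt) {
    match(nt, NT_LETTERS)
}

# barcode strings <-> character matrix (rows = barcodes)
barcodeMatrix <- function(x) {
    if (!length(x)) return(matrix(character(0), nrow = 0, ncol = 0))
    n <- unique(nchar(x))
    if (length(n) != 1) stop("barcodes must have equal length")
    matrix(unlist(strsplit(x, "", fixed = TRUE), use.names = FALSE),
           nrow = length(x), byrow = TRUE)
}

matrixToBarcode <- function(m) {
    if (!nrow(m)) return(character(0))
    apply(m, 1, paste0, collapse = "")
}

# longest run of a letter (default N) in a barcode string
maxRunLength <- function(x, letter = "N") {
    vapply(strsplit(x, "", fixed = TRUE), function(ch) {
        r <- rle(ch == letter)
        w <- r$lengths[r$values]
        if (length(w)) max(w) else 0L
    }, integer(1))
}

# longest run of any identical called nucleotide (N breaks runs)
maxIdenticalRun <- function(x) {
    vapply(strsplit(x, "", fixed = TRUE), function(ch) {
        r <- rle(ch)
        w <- r$lengths[r$values != "N"]
        if (length(w)) max(w) else 0L
    }, integer(1))
}

# mode of a character vector with deterministic ties:
# prefer `previous` when it ties for the max; otherwise `tiebreak` if that
# ties; otherwise first in sort order.
modeLabel <- function(x, previous = NA_character_,
                      tiebreak = NA_character_) {
    x <- x[!is.na(x)]
    if (!length(x)) return(NA_character_)
    tab <- table(x)
    top <- names(tab)[tab == max(tab)]
    if (length(top) == 1L) return(top)
    if (!is.na(previous) && previous %in% top) return(previous)
    if (!is.na(tiebreak) && tiebreak %in% top) return(tiebreak)
    sort(top)[1L]
}

# pairwise Euclidean distances between rows of two coordinate matrices
crossDist <- function(a, b) {
    a <- as.matrix(a); b <- as.matrix(b)
    d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
    sqrt(pmax(d2, 0))
}

# indices of the k nearest rows of `pts` for each row of `query`
# (excluding identical index when self = TRUE). Brute force; the point
# sets used here are a few thousand at most.
knnIndex <- function(query, pts, k, self = FALSE) {
    d <- crossDist(query, pts)
    if (self) d[cbind(seq_len(nrow(d)), seq_len(nrow(d)))] <- Inf
    t(apply(d, 1, function(r) order(r)[seq_len(min(k, length(r)))]))
}

# single-linkage clusters with a distance cut, on a coordinate matrix
singleLinkageClusters <- function(xy, cut) {
    n <- nrow(xy)
    if (n == 0) return(integer(0))
    if (n == 1) return(1L)
    hc <- stats::hclust(stats::dist(xy), method = "single")
    stats::cutree(hc, h = cut)
}

# seeded RNG scope: evaluates expr with a local seed, restoring the
# caller's RNG state afterwards
withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
        on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
    eval.parent(substitute(expr))
}
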