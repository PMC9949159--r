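# Projection-based cell typing: the corticofugal / intratelencephalic
# split from subcortical projection counts, the ET/CT split by iterative
# k-nearest-neighbour label propagation seeded from the fiber-zone
# bundle geometry, and the ITi/ITc split by contralateral projections.

#' Default fiber region of interest
#'
#' Axis-aligned box (micrometres) in the striatal-thalamic fiber zone
#' where CT and ET axon bundles separate dorsoventrally; the top (lower
#' y) half seeds CT, the bottom half ET.
#'
#' @return list with xmin/xmax, ymin/ymax, zmin/zmax.
#' @export
fiberROI <- function() {
    list(xmin = 8250, xmax = 9000, ymin = 3500, ymax = 5000,
         zmin = 6750, zmax = 7500)
}

#' Classify corticofugal vs intratelencephalic cells
#'
#' CF cells project to the thalamus or the midbrain (superior
#' colliculus) at or above the per-region minimum counts; the remaining
#' cells are IT, split into ITc (at least `itcMin` rolonies in the
#' contralateral cortex) and ITi.
#'
#' @param counts gated region count matrix from [regionCounts()] (rows =
#'   barcodes).
#' @param thalRegion,midbrainRegion,contraRegion column names.
#' @param itcMin contralateral count for ITc.
#' @return character vector of labels (CF, ITc, ITi) named by barcode.
#' @export
classifyCfIt <- function(counts, thalRegion = "Thal",
                         midbrainRegion = "Midbrain",
                         contraRegion = "CtxC", itcMin = 5) {
    cf <- counts[, thalRegion] > 0 | counts[, midbrainRegion] > 0
    itc <- !cf & counts[, contraRegion] >= itcMin
    out <- ifelse(cf, "CF", ifelse(itc, "ITc", "ITi"))
    stats::setNames(out, rownames(counts))
}

#' Seed ET/CT labels in the fiber region of interest
#'
#' Labels the rolonies inside the ROI by the median split of their
#' y-coordinate: the top half (smaller y, dorsal bundle) is CT, the
#' bottom half ET. Rolonies outside the ROI are unlabeled.
#'
#' @param rolonies rolony table with barcode, x, y, z (micrometres).
#' @param roi list from [fiberROI()].
#' @return data.frame of the ROI rolonies with a `label` column.
#' @export
seedEtct <- function(rolonies, roi = fiberROI()) {
    inRoi <- rolonies$x >= roi$xmin & rolonies$x <= roi$xmax &
             rolonies$y >= roi$ymin & rolonies$y <= roi$ymax &
             rolonies$z >= roi$zmin & rolonies$z <= roi$zmax
    sel <- rolonies[inRoi, , drop = FALSE]
    if (!nrow(sel)) {
        warning("no rolonies in the fiber ROI; empty seed")
        sel$label <- character(0)
        return(sel)
    }
    if (nrow(sel) == 1) warning("single rolony in the fiber ROI")
    med <- stats::median(sel$y)
    sel$label <- ifelse(sel$y <= med, "CT", "ET")
    sel
}

#' Iterative kNN label propagation over ROI rolonies
#'
#' Alternates (a) assigning each rolony the most frequent label among
#' its `k` nearest neighbours (3-D Euclidean distance in registered
#' micrometres) and (b) assigning each barcoded cell the most frequent
#' label of its rolonies, with rolonies inheriting the cell label, until
#' no label changes or `maxIter` iterations. Ties keep the previous
#' label, falling back to CT.
#'
#' @param seeded output of [seedEtct()] (rolonies with barcode, x, y, z,
#'   label).
#' @param k neighbourhood size.
#' @param maxIter iteration cap.
#' @return list with `rolonies` (labels after convergence), `cells`
#'   (label per barcode: mode of its ROI rolonies), `iterations`,
#'   `converged`.
#' @export
iterateKnn <- function(seeded, k = 10, maxIter = 100) {
    n <- nrow(seeded)
    if (!n)
        return(list(rolonies = seeded, cells = character(0),
                    iterations = 0L, converged = TRUE))
    pts <- as.matrix(seeded[, c("x", "y", "z")])
    nn <- knnIndex(pts, pts, k, self = TRUE)
    lab <- seeded$label
    converged <- FALSE
    it <- 0L
    cellOf <- seeded$barcode
    while (it < maxIter) {
        it <- it + 1L
        prev <- lab
        # (a) rolony <- mode of kNN labels
        lab <- vapply(seq_len(n), function(i)
            modeLabel(prev[nn[i, ]], previous = prev[i], tiebreak = "CT"),
            character(1))
        # (b) cell <- mode of its rolonies; rolonies inherit
        cellLab <- vapply(split(seq_len(n), cellOf), function(ix)
            modeLabel(lab[ix], tiebreak = "CT"), character(1))
        lab <- unname(cellLab[cellOf])
        if (identical(lab, prev)) { converged <- TRUE; break }
    }
    if (!converged)
        message("iterateKnn: reached the ", maxIter, "-iteration cap")
    seeded$label <- lab
    cells <- vapply(split(lab, cellOf), function(x)
        modeLabel(x, tiebreak = "CT"), character(1))
    list(rolonies = seeded, cells = cells, iterations = it,
         converged = converged)
}

#' Finalize ET/CT labels from thalamic rolonies
#'
#' One propagation pass: every thalamic rolony takes the most frequent
#' label of its `k` nearest labeled rolonies (from the converged ROI
#' labeling), and each cell's type is the most frequent label of its
#' thalamic rolonies. Cells without thalamic rolonies are unassigned.
#'
#' @param thalRolonies thalamic rolony table (barcode, x, y, z).
#' @param labeled converged ROI rolonies (x, y, z, label) from
#'   [iterateKnn()].
#' @param k neighbourhood size.
#' @return list with `rolonies` (thalamic, labeled) and `cells` (label
#'   per barcode; "unassigned" when no thalamic rolonies).
#' @export
finalizeEtct <- function(thalRolonies, labeled, k = 10) {
    if (!nrow(thalRolonies))
        return(list(rolonies = thalRolonies, cells = character(0)))
    if (!nrow(labeled)) stop("no labeled rolonies to propagate from")
    nn <- knnIndex(as.matrix(thalRolonies[, c("x", "y", "z")]),
                   as.matrix(labeled[, c("x", "y", "z")]), k)
    thalRolonies$label <- vapply(seq_len(nrow(thalRolonies)), function(i)
        modeLabel(labeled$label[nn[i, ]], tiebreak = "CT"), character(1))
    cells <- vapply(split(thalRolonies$label, thalRolonies$barcode),
                    function(x) modeLabel(x, tiebreak = "CT"), character(1))
    list(rolonies = thalRolonies, cells = cells)
}
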