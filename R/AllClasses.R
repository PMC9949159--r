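#' Simulation configuration
#'
#' Holds the acquisition constants and noise parameters used by the
#' synthetic data generator: 17-cycle sequencing of 17-nt barcodes with
#' fixed nucleotides at positions 9 and 10, 0.55 um pixels and 20 um
#' sections, plus per-cycle dropout, per-base substitution, positional
#' jitter, floating-rolony and secondary-infection contamination, and the
#' mixture over the four projection classes (CT, ET, ITi, ITc).
#'
#' @slot nNeurons number of barcoded neurons to simulate.
#' @slot barcodeLength barcode length in nucleotides.
#' @slot fixedPositions 1-based positions held constant across the library.
#' @slot fixedLetters letters at the fixed positions (recycled).
#' @slot nCycles number of sequencing cycles imaged.
#' @slot nRolonies axonal rolonies emitted per neuron.
#' @slot pixelSize micrometres per pixel.
#' @slot sectionThickness section thickness in micrometres.
#' @slot dropoutRate probability a rolony yields no dot in a given cycle.
#' @slot substitutionRate probability a base-call reports the wrong channel.
#' @slot jitterSD positional jitter SD per cycle, in pixels.
#' @slot nFloatingPerSoma floating rolonies planted per soma-bearing barcode.
#' @slot floatingRadius tangential scatter radius of floaters, micrometres.
#' @slot nSecondaryBarcodes contaminant barcodes from secondary infection.
#' @slot classMixture named proportions over c(CT, ET, ITi, ITc), sum 1.
#' @slot seed integer seed driving all randomness.
#' @export
setClass("SimConfig", representation(
    nNeurons = "integer", barcodeLength = "integer",
    fixedPositions = "integer", fixedLetters = "character",
    nCycles = "integer", nRolonies = "integer",
    pixelSize = "numeric", sectionThickness = "numeric",
    dropoutRate = "numeric", substitutionRate = "numeric",
    jitterSD = "numeric", nFloatingPerSoma = "integer",
    floatingRadius = "numeric", nSecondaryBarcodes = "integer",
    classMixture = "numeric", seed = "integer"))

setValidity("SimConfig", function(object) {
    msg <- character()
    pr <- c(object@dropoutRate, object@substitutionRate)
    if (any(pr < 0 | pr > 1)) msg <- c(msg, "rates must lie in [0, 1]")
    if (abs(sum(object@classMixture) - 1) > 1e-8)
        msg <- c(msg, "classMixture must sum to 1")
    if (!identical(sort(names(object@classMixture)),
                   sort(c("CT", "ET", "ITi", "ITc"))))
        msg <- c(msg, "classMixture must be named CT, ET, ITi, ITc")
    if (length(object@fixedPositions) &&
        object@barcodeLength <= max(object@fixedPositions))
        msg <- c(msg, "barcodeLength must exceed max(fixedPositions)")
    if (object@nNeurons < 0L) msg <- c(msg, "nNeurons must be >= 0")
    if (object@jitterSD < 0) msg <- c(msg, "jitterSD must be >= 0")
    if (length(msg)) msg else TRUE
})

#' @describeIn SimConfig constructor with the package's study-condition
#'   defaults.
#' @param nNeurons,barcodeLength,fixedPositions,fixedLetters,nCycles Passed
#'   to the corresponding slots.
#' @param nRolonies,pixelSize,sectionThickness,dropoutRate,substitutionRate
#'   Passed to the corresponding slots.
#' @param jitterSD,nFloatingPerSoma,floatingRadius,nSecondaryBarcodes Passed
#'   to the corresponding slots.
#' @param classMixture,seed Passed to the corresponding slots.
#' @export
simConfig <- function(nNeurons = 100, barcodeLength = 17,
                      fixedPositions = c(9, 10), fixedLetters = "G",
                      nCycles = 17, nRolonies = 30,
                      pixelSize = 0.55, sectionThickness = 20,
                      dropoutRate = 0.05, substitutionRate = 0.005,
                      jitterSD = 0.5, nFloatingPerSoma = 2,
                      floatingRadius = 500, nSecondaryBarcodes = 2,
                      classMixture = c(CT = 0.15, ET = 0.10,
                                       ITi = 0.45, ITc = 0.30),
                      seed = 1) {
    new("SimConfig",
        nNeurons = as.integer(nNeurons),
        barcodeLength = as.integer(barcodeLength),
        fixedPositions = as.integer(fixedPositions),
        fixedLetters = rep_len(fixedLetters, length(fixedPositions)),
        nCycles = as.integer(nCycles), nRolonies = as.integer(nRolonies),
        pixelSize = pixelSize, sectionThickness = sectionThickness,
        dropoutRate = dropoutRate, substitutionRate = substitutionRate,
        jitterSD = jitterSD, nFloatingPerSoma = as.integer(nFloatingPerSoma),
        floatingRadius = floatingRadius,
        nSecondaryBarcodes = as.integer(nSecondaryBarcodes),
        classMixture = classMixture, seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
    cat("SimConfig:", object@nNeurons, "neurons,",
        object@nCycles, "cycles,", object@barcodeLength, "nt barcodes\n")
    cat("  fixed positions:",
        paste0(object@fixedPositions, "=", object@fixedLetters,
               collapse = " "), "\n")
    cat("  dropout", object@dropoutRate, "| substitution",
        object@substitutionRate, "| jitter", object@jitterSD, "px\n")
    cat("  mixture:", paste(names(object@classMixture),
        object@classMixture, sep = "=", collapse = " "), "\n")
})

#' Four-channel sequencing image stack
#'
#' One imaged tile in one sequencing cycle: a y * x * z * 4 intensity
#' array (one channel per nucleotide) with its physical calibration.
#'
#' @slot intensities numeric array, dim c(ny, nx, nz, 4), non-negative.
#' @slot pixelSize micrometres per pixel.
#' @slot zStep micrometres between z planes.
#' @slot tileId,cycleId identifiers.
#' @export
setClass("ImageStack", representation(
    intensities = "array", pixelSize = "numeric", zStep = "numeric",
    tileId = "integer", cycleId = "integer"))

setValidity("ImageStack", function(object) {
    d <- dim(object@intensities)
    if (length(d) != 4 || d[4] != 4)
        return("intensities must be a ny x nx x nz x 4 array")
    if (any(object@intensities < 0))
        return("intensities must be non-negative")
    TRUE
})

#' @describeIn ImageStack constructor.
#' @param intensities,pixelSize,zStep,tileId,cycleId see slots.
#' @export
imageStack <- function(intensities, pixelSize = 0.55, zStep = 3,
                       tileId = 1, cycleId = 1) {
    new("ImageStack", intensities = intensities, pixelSize = pixelSize,
        zStep = zStep, tileId = as.integer(tileId),
        cycleId = as.integer(cycleId))
}

setMethod("show", "ImageStack", function(object) {
    d <- dim(object@intensities)
    cat(sprintf("ImageStack tile %d cycle %d: %d x %d px, %d z-planes, 4 channels (%.2f um/px)\n",
                object@tileId, object@cycleId, d[1], d[2], d[3],
                object@pixelSize))
})

#' @rdname pixelSize
#' @export
setMethod("pixelSize", "ImageStack", function(x) x@pixelSize)

#' Planar transform between point clouds or images
#'
#' @slot kind one of "translation", "affine", "projective".
#' @slot matrix 3x3 homogeneous matrix mapping source (x, y, 1) row vectors
#'   onto the reference frame.
#' @slot rmsResidual root-mean-square residual of the supporting pairs (px).
#' @slot nSupport number of matched point pairs supporting the fit.
#' @slot lowConfidence flag set when the estimate could not be trusted
#'   (weak correlation peak or too few pairs).
#' @export
setClass("Transform2D", representation(
    kind = "character", matrix = "matrix", rmsResidual = "numeric",
    nSupport = "integer", lowConfidence = "logical"))

setValidity("Transform2D", function(object) {
    if (!all(dim(object@matrix) == c(3, 3))) return("matrix must be 3x3")
    if (!is.finite(det(object@matrix)) || abs(det(object@matrix)) < 1e-12)
        return("matrix must be invertible")
    if (object@rmsResidual < 0) return("rmsResidual must be >= 0")
    TRUE
})

#' @describeIn Transform2D constructor.
#' @param kind,matrix,rmsResidual,nSupport,lowConfidence see slots.
#' @export
transform2d <- function(matrix = diag(3), kind = "translation",
                        rmsResidual = 0, nSupport = 0,
                        lowConfidence = FALSE) {
    new("Transform2D", kind = kind, matrix = matrix,
        rmsResidual = rmsResidual, nSupport = as.integer(nSupport),
        lowConfidence = lowConfidence)
}

setMethod("show", "Transform2D", function(object) {
    cat(sprintf("Transform2D (%s): rms %.4g px, n = %d%s\n", object@kind,
                object@rmsResidual, object@nSupport,
                if (object@lowConfidence) " [low confidence]" else ""))
    print(signif(object@matrix, 6))
})

#' @rdname transformMatrix
#' @export
setMethod("transformMatrix", "Transform2D", function(x) x@matrix)

#' Codebook of inferred true barcodes
#'
#' The set of barcodes accepted as real under the count, composition and
#' Hamming-separation rules, with per-barcode rolony support.
#'
#' @slot entries data.frame with columns `barcode`, `support` (rolony
#'   count including support attributed from rejected 1-neighbours) and
#'   `attributed` (support inherited from rejected near-neighbours).
#' @slot fixedPositions positions excluded from the default Hamming
#'   convention.
#' @slot variableLength number of variable (non-fixed) positions.
#' @export
setClass("Codebook", representation(
    entries = "data.frame", fixedPositions = "integer",
    variableLength = "integer"))

setValidity("Codebook", function(object) {
    if (!all(c("barcode", "support") %in% names(object@entries)))
        return("entries needs columns barcode, support")
    TRUE
})

#' @describeIn Codebook number of accepted barcodes.
#' @param x a Codebook.
#' @export
setMethod("length", "Codebook", function(x) nrow(x@entries))

#' @rdname entries
#' @export
setMethod("entries", "Codebook", function(x) x@entries)

#' @rdname entries
#' @export
setMethod("barcodes", "Codebook", function(x) x@entries$barcode)

#' @rdname entries
#' @export
setMethod("supportCounts", "Codebook", function(x) {
    stats::setNames(x@entries$support, x@entries$barcode)
})

setMethod("show", "Codebook", function(object) {
    cat(sprintf("Codebook: %d barcodes (%d variable nt, fixed at %s)\n",
                nrow(object@entries), object@variableLength,
                paste(object@fixedPositions, collapse = ",")))
    if (nrow(object@entries))
        cat("  support:", paste(stats::quantile(object@entries$support,
            c(0, .5, 1)), collapse = "/"), "(min/median/max)\n")
})

#' Labeled annotation volume
#'
#' A 3-D voxel grid of region/layer labels from which the cortical flatmap
#' is built. Label 0 marks space outside the tissue; `cortexLabels` mark
#' the cortical shell and `interiorLabels` the tissue beneath it, so that
#' outer and inner cortical boundaries can be recovered.
#'
#' @slot labels integer 3-D array (x, y, z order).
#' @slot voxelSize micrometres per voxel edge (default 25).
#' @slot cortexLabels labels forming the cortical shell.
#' @slot interiorLabels labels of tissue interior to the shell.
#' @slot outsideLabel label of space outside the tissue.
#' @slot hemisphere integer array matching `labels` (1 = left, 2 = right),
#'   or a zero-length array meaning everything is one (right) hemisphere.
#' @export
setClass("AnnotationVolume", representation(
    labels = "array", voxelSize = "numeric", cortexLabels = "integer",
    interiorLabels = "integer", outsideLabel = "integer",
    hemisphere = "array"))

setValidity("AnnotationVolume", function(object) {
    if (length(dim(object@labels)) != 3) return("labels must be 3-D")
    if (length(object@hemisphere) &&
        !identical(dim(object@hemisphere), dim(object@labels)))
        return("hemisphere must match labels dimensions")
    TRUE
})

#' @describeIn AnnotationVolume constructor.
#' @param labels,voxelSize,cortexLabels,interiorLabels,outsideLabel,hemisphere
#'   see slots.
#' @export
annotationVolume <- function(labels, voxelSize = 25, cortexLabels = 1L,
                             interiorLabels = 2L, outsideLabel = 0L,
                             hemisphere = NULL) {
    if (is.null(hemisphere)) hemisphere <- array(integer(0), dim = c(0, 0, 0))
    new("AnnotationVolume", labels = labels, voxelSize = voxelSize,
        cortexLabels = as.integer(cortexLabels),
        interiorLabels = as.integer(interiorLabels),
        outsideLabel = as.integer(outsideLabel), hemisphere = hemisphere)
}

setMethod("show", "AnnotationVolume", function(object) {
    cat("AnnotationVolume:", paste(dim(object@labels), collapse = " x "),
        "voxels at", object@voxelSize, "um\n")
})

#' Cortical flatmap lookup table
#'
#' Voxel-indexed lookup from 3-D volume coordinates to flattened cortical
#' coordinates: ML and AP (micrometre-scale distances on the mid-cortical
#' reference plate, per-hemisphere minimum shifted to 1) and depth as a
#' percentage of the local column length (0 at the pial surface, 100 at
#' the inner boundary).
#'
#' @slot ml,ap,depth numeric 3-D arrays (NA outside cortex).
#' @slot mlFill,apFill,depthFill edge-filled copies used for
#'   interpolation near the cortical border.
#' @slot voxelSize micrometres per voxel.
#' @slot plateDepth reference plate depth fraction (default 0.5).
#' @export
setClass("FlatmapLUT", representation(
    ml = "array", ap = "array", depth = "array",
    mlFill = "array", apFill = "array", depthFill = "array",
    voxelSize = "numeric", plateDepth = "numeric"))

setValidity("FlatmapLUT", function(object) {
    d <- object@depth[!is.na(object@depth)]
    if (length(d) && (min(d) < -1e-9 || max(d) > 100 + 1e-9))
        return("depth must lie in [0, 100]")
    TRUE
})

setMethod("show", "FlatmapLUT", function(object) {
    n <- sum(!is.na(object@depth))
    cat("FlatmapLUT:", n, "cortical voxels at", object@voxelSize,
        "um; reference plate at", object@plateDepth * 100, "% depth\n")
})

#' @rdname pixelSize
#' @export
setMethod("pixelSize", "AnnotationVolume", function(x) x@voxelSize)
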