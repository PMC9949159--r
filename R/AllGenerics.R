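#' Codebook entry table
#'
#' @param x a \linkS4class{Codebook}.
#' @return For `entries`, a `data.frame` with columns `barcode` and
#'   `support`; for `barcodes`, a character vector; for `supportCounts`, an
#'   integer vector named by barcode.
#' @export
setGeneric("entries", function(x) standardGeneric("entries"))

#' @rdname entries
#' @export
setGeneric("barcodes", function(x) standardGeneric("barcodes"))

#' @rdname entries
#' @export
setGeneric("supportCounts", function(x) standardGeneric("supportCounts"))

#' Pixel size accessor
#'
#' @param x an object with a physical pixel or voxel size.
#' @return Size in micrometres.
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' Transform matrix accessor
#'
#' @param x a \linkS4class{Transform2D}.
#' @return The 3x3 homogeneous transform matrix.
#' @export
setGeneric("transformMatrix", function(x) standardGeneric("transformMatrix"))
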