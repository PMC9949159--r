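# Plain-text serialization: TSV tables with documented headers, a
# key-value config format, row-major transform chains, and (optional)
# multi-page TIFF export of rendered stacks via the tiff package.

#' Read and write dot / read / rolony tables as TSV
#'
#' @param x a data.frame.
#' @param path file path.
#' @return `readTable` returns a data.frame.
#' @export
writeTable <- function(x, path) {
    utils::write.table(x, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname writeTable
#' @export
readTable <- function(path) {
    utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write and read a codebook as TSV
#'
#' @param codebook a \linkS4class{Codebook}.
#' @param path file path.
#' @return `readCodebook` returns a \linkS4class{Codebook}.
#' @export
writeCodebook <- function(codebook, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# fixedPositions=%s variableLength=%d",
                       paste(codebook@fixedPositions, collapse = ","),
                       codebook@variableLength), con)
    utils::write.table(entries(codebook), con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname writeCodebook
#' @export
readCodebook <- function(path) {
    hdr <- readLines(path, n = 1)
    fx <- sub(".*fixedPositions=([0-9,]*).*", "\\1", hdr)
    vl <- as.integer(sub(".*variableLength=([0-9]+).*", "\\1", hdr))
    ent <- utils::read.delim(path, skip = 1, stringsAsFactors = FALSE)
    if (!"attributed" %in% names(ent)) ent$attributed <- 0L
    new("Codebook", entries = ent,
        fixedPositions = as.integer(strsplit(fx, ",")[[1]]),
        variableLength = vl)
}

#' Write and read a simulation config as key-value text
#'
#' @param cfg a \linkS4class{SimConfig}.
#' @param path file path.
#' @return `readSimConfig` returns a \linkS4class{SimConfig}.
#' @export
writeSimConfig <- function(cfg, path) {
    sl <- methods::slotNames("SimConfig")
    lines <- vapply(sl, function(s) {
        v <- methods::slot(cfg, s)
        if (s == "classMixture")
            paste0(s, " = ", paste(names(v), v, sep = ":", collapse = ","))
        else paste0(s, " = ", paste(v, collapse = ","))
    }, character(1))
    writeLines(lines, path)
    invisible(path)
}

#' @rdname writeSimConfig
#' @export
readSimConfig <- function(path) {
    lines <- readLines(path)
    kv <- strsplit(lines, " = ", fixed = TRUE)
    vals <- stats::setNames(lapply(kv, `[`, 2), vapply(kv, `[`, "", 1))
    mix <- strsplit(strsplit(vals$classMixture, ",")[[1]], ":")
    mixture <- stats::setNames(as.numeric(vapply(mix, `[`, "", 2)),
                               vapply(mix, `[`, "", 1))
    num <- function(k) as.numeric(strsplit(vals[[k]], ",")[[1]])
    chr <- function(k) strsplit(vals[[k]], ",")[[1]]
    simConfig(nNeurons = num("nNeurons"),
              barcodeLength = num("barcodeLength"),
              fixedPositions = num("fixedPositions"),
              fixedLetters = chr("fixedLetters"),
              nCycles = num("nCycles"), nRolonies = num("nRolonies"),
              pixelSize = num("pixelSize"),
              sectionThickness = num("sectionThickness"),
              dropoutRate = num("dropoutRate"),
              substitutionRate = num("substitutionRate"),
              jitterSD = num("jitterSD"),
              nFloatingPerSoma = num("nFloatingPerSoma"),
              floatingRadius = num("floatingRadius"),
              nSecondaryBarcodes = num("nSecondaryBarcodes"),
              classMixture = mixture, seed = num("seed"))
}

#' Serialize a transform chain as structured text
#'
#' One block per transform: a header line (name, kind, rms, nSupport,
#' lowConfidence) and the 3x3 matrix row-major on the next line.
#'
#' @param transforms named list of \linkS4class{Transform2D}.
#' @param path file path.
#' @return `readTransforms` returns the named list.
#' @export
writeTransforms <- function(transforms, path) {
    con <- file(path, "w")
    on.exit(close(con))
    for (nm in names(transforms)) {
        tr <- transforms[[nm]]
        writeLines(sprintf("%s\t%s\t%.6g\t%d\t%d", nm, tr@kind,
                           tr@rmsResidual, tr@nSupport,
                           as.integer(tr@lowConfidence)), con)
        writeLines(paste(signif(as.vector(t(tr@matrix)), 12),
                         collapse = "\t"), con)
    }
    invisible(path)
}

#' @rdname writeTransforms
#' @export
readTransforms <- function(path) {
    lines <- readLines(path)
    out <- list()
    for (i in seq(1, length(lines), by = 2)) {
        hdr <- strsplit(lines[i], "\t")[[1]]
        m <- matrix(as.numeric(strsplit(lines[i + 1], "\t")[[1]]), 3, 3,
                    byrow = TRUE)
        out[[hdr[1]]] <- transform2d(
            m, kind = hdr[2], rmsResidual = as.numeric(hdr[3]),
            nSupport = as.integer(hdr[4]),
            lowConfidence = as.logical(as.integer(hdr[5])))
    }
    out
}

#' Export an image stack as multi-page TIFF
#'
#' One file per channel, one page per z-plane; requires the tiff
#' package.
#'
#' @param stack an \linkS4class{ImageStack}.
#' @param prefix output path prefix; files are
#'   `<prefix>_ch<channel>.tif`.
#' @param scale intensities are divided by this before writing (TIFF
#'   stores [0, 1]).
#' @return the written paths, invisibly.
#' @export
writeStackTIFF <- function(stack, prefix, scale = 4095) {
    if (!requireNamespace("tiff", quietly = TRUE))
        stop("the tiff package is required for TIFF export")
    d <- dim(stack@intensities)
    paths <- character(4)
    for (ch in 1:4) {
        pages <- lapply(seq_len(d[3]), function(z)
            pmin(stack@intensities[, , z, ch] / scale, 1))
        paths[ch] <- sprintf("%s_ch%d.tif", prefix, ch)
        tiff::writeTIFF(pages, paths[ch], bits.per.sample = 16)
    }
    invisible(paths)
}
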