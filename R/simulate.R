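# Ground-truthed synthetic data: barcoded projection neurons of four
# classes (CT, ET, ITi, ITc) emitting rolonies along class-specific
# trajectories, observed over multi-cycle 4-channel sequencing with
# dropout, substitution, jitter, floating rolonies and secondary-infection
# contaminants. Coordinates are micrometres, right-handed: x = mediolateral,
# y = depth from the pial side (increasing ventrally), z = anteroposterior.
# Sections are 1-based indices along z.

#' Synthetic brain region geometry
#'
#' Axis-aligned boxes (micrometres) for the simulated injection site
#' (AudI), cortical targets (VisI, CtxC), thalamus, striatum, midbrain and
#' the striatal-thalamic fiber zone used for ET/CT trajectory splitting.
#' The fiber box matches the cell-typing region of interest
#' (x 8250-9000, y 3500-5000, z 6750-7500).
#'
#' @return data.frame with columns region, xmin, xmax, ymin, ymax, zmin,
#'   zmax.
#' @export
regionBoxes <- function() {
    data.frame(
        region = c("AudI", "VisI", "CtxC", "Thal", "Str", "Midbrain",
                   "Fiber"),
        xmin = c(8000, 7800, 1400, 6200, 6800, 5200, 8250),
        xmax = c(10000, 9800, 3400, 8200, 8800, 6800, 9000),
        ymin = c(1000, 800, 800, 3200, 2600, 1400, 3500),
        ymax = c(3000, 2800, 3000, 5600, 4200, 3000, 5000),
        zmin = c(4400, 6400, 4400, 6600, 5000, 9000, 6750),
        zmax = c(5600, 7600, 6400, 8400, 6400, 10200, 7500),
        stringsAsFactors = FALSE)
}

# unseeded barcode draw; uniform over the variable positions, constants at
# the fixed positions
.drawBarcodes <- function(n, cfg) {
    if (n == 0) return(character(0))
    L <- cfg@barcodeLength
    m <- matrix(sample(NT_LETTERS, n * L, replace = TRUE), nrow = n)
    if (length(cfg@fixedPositions))
        m[, cfg@fixedPositions] <- matrix(rep(cfg@fixedLetters, each = n),
                                          nrow = n)
    matrixToBarcode(m)
}

#' Generate a barcode library
#'
#' Draws `n` barcodes of length `cfg@barcodeLength` uniformly at random
#' over the variable positions; the fixed positions carry the configured
#' constant letters in every barcode. Reproducible from `cfg@seed`.
#'
#' @param n number of barcodes.
#' @param cfg a \linkS4class{SimConfig}.
#' @return character vector of `n` barcode strings.
#' @export
generateBarcodeLibrary <- function(n, cfg = simConfig()) {
    stopifnot(n >= 0)
    withSeed(cfg@seed, .drawBarcodes(n, cfg))
}

# per-class rolony allocation over targets (fractions of cfg@nRolonies)
.classTargets <- list(
    CT  = c(Fiber = 0.25, Thal = 0.55, Str = 0.20),
    ET  = c(Fiber = 0.25, Thal = 0.40, Midbrain = 0.15, Str = 0.20),
    ITi = c(VisI = 0.65, Str = 0.35),
    ITc = c(VisI = 0.40, CtxC = 0.35, Str = 0.25))

# fiber-bundle depth (y) means: CT takes the dorsal (upper) half of the
# fiber zone, ET the ventral half; SD 150 um gives the bundles a ~10%
# spatial overlap at the median split
.fiberY <- c(CT = 4000, ET = 4500)
.fiberYSD <- 150

.truncNorm <- function(n, mean, sd, lo, hi) {
    pmin(hi, pmax(lo, stats::rnorm(n, mean, sd)))
}

# cortical rolony depth profile given the soma depth group
.corticalDepth <- function(n, somaDepth) {
    if (somaDepth <= 35) {
        .truncNorm(n, 25, 10, 0, 100)
    } else if (somaDepth <= 60) {
        .truncNorm(n, 32, 12, 0, 100)
    } else {
        deep <- stats::runif(n) < 0.8
        d <- numeric(n)
        d[deep] <- .truncNorm(sum(deep), 72, 10, 0, 100)
        d[!deep] <- .truncNorm(sum(!deep), 30, 10, 0, 100)
        d
    }
}

.sampleTargetCloud <- function(n, region, boxes, spreadSD, depths = NULL) {
    b <- boxes[boxes$region == region, ]
    if (region == "Fiber") stop("fiber clouds are sampled separately")
    cx <- stats::runif(1, b$xmin + spreadSD, b$xmax - spreadSD)
    cz0 <- b$zmin
    x <- .truncNorm(n, cx, spreadSD, b$xmin, b$xmax)
    z <- stats::runif(n, b$zmin, b$zmax)
    if (!is.null(depths)) {
        y <- b$ymin + depths / 100 * (b$ymax - b$ymin)
    } else {
        cy <- stats::runif(1, b$ymin + spreadSD, b$ymax - spreadSD)
        y <- .truncNorm(n, cy, spreadSD, b$ymin, b$ymax)
    }
    data.frame(x = x, y = y, z = z, region = region,
               depthPct = if (is.null(depths)) NA_real_ else depths)
}

#' Simulate ground-truth barcoded neurons
#'
#' Draws neurons from the configured class mixture and gives each a
#' barcode, a soma in the injection site with a class-typical laminar
#' depth (CT peaked at 90%, ET at 60%, IT spread across layers), and a
#' class-consistent rolony cloud: CT/ET clouds pass through the dorsal or
#' ventral stratum of the fiber zone and terminate in distinct thalamic
#' strata; IT clouds terminate in cortex with soma-depth-dependent laminar
#' profiles and focal (upper somata) or diffuse (deep somata) tangential
#' spread; ITc additionally sends at least 5 rolonies to contralateral
#' cortex. Floating rolonies are planted on the soma section +/- 1 with
#' broad tangential scatter, and `nSecondaryBarcodes` contaminant barcodes
#' are emitted as compact glial-like clusters in target regions.
#'
#' @param cfg a \linkS4class{SimConfig}.
#' @return list with elements `neurons` (one row per neuron: id, barcode,
#'   cellClass, somaX/Y/Z, somaDepth, somaSection, trajectoryTag),
#'   `rolonies` (one row per ground-truth rolony: rolonyId, neuronId,
#'   barcode, x, y, z, section, region, depthPct, kind in
#'   axonal/floating/secondary) and `config`.
#' @export
simulateNeurons <- function(cfg = simConfig()) {
    boxes <- regionBoxes()
    withSeed(cfg@seed, {
        n <- cfg@nNeurons
        classes <- sample(names(cfg@classMixture), n, replace = TRUE,
                          prob = cfg@classMixture)
        bcs <- .drawBarcodes(n, cfg)
        aud <- boxes[boxes$region == "AudI", ]
        somaDepth <- numeric(n)
        somaDepth[classes == "CT"] <- .truncNorm(sum(classes == "CT"), 90, 4, 1, 99)
        somaDepth[classes == "ET"] <- .truncNorm(sum(classes == "ET"), 60, 5, 1, 99)
        it <- classes %in% c("ITi", "ITc")
        somaDepth[it] <- stats::runif(sum(it), 15, 85)
        somaX <- stats::runif(n, aud$xmin + 100, aud$xmax - 100)
        somaZ <- stats::runif(n, aud$zmin + 50, aud$zmax - 50)
        somaY <- aud$ymin + somaDepth / 100 * (aud$ymax - aud$ymin)
        neurons <- data.frame(
            id = seq_len(n), barcode = bcs, cellClass = classes,
            somaX = somaX, somaY = somaY, somaZ = somaZ,
            somaDepth = somaDepth,
            somaSection = as.integer(floor(somaZ / cfg@sectionThickness)) + 1L,
            trajectoryTag = c(CT = "dorsal", ET = "ventral", ITi = "none",
                              ITc = "none")[classes],
            stringsAsFactors = FALSE)

        rol <- vector("list", n)
        fib <- boxes[boxes$region == "Fiber", ]
        for (i in seq_len(n)) {
            cls <- classes[i]
            alloc <- .classTargets[[cls]]
            cnt <- floor(alloc * cfg@nRolonies)
            rem <- cfg@nRolonies - sum(cnt)
            if (rem > 0) cnt[seq_len(rem)] <- cnt[seq_len(rem)] + 1L
            if (cls == "ITc")  # class invariant: >= 5 contralateral
                cnt["CtxC"] <- max(cnt["CtxC"], min(5L, cfg@nRolonies))
            spreadSD <- if (somaDepth[i] <= 60) 60 else 250
            parts <- lapply(names(cnt), function(tg) {
                k <- cnt[[tg]]
                if (k == 0) return(NULL)
                if (tg == "Fiber") {
                    data.frame(
                        x = stats::runif(k, fib$xmin, fib$xmax),
                        y = .truncNorm(k, .fiberY[[cls]], .fiberYSD,
                                       fib$ymin, fib$ymax),
                        z = stats::runif(k, fib$zmin, fib$zmax),
                        region = "Fiber", depthPct = NA_real_)
                } else if (tg == "Thal") {
                    # the two classes terminate in distinct thalamic
                    # strata, each continuous with its own fiber bundle
                    # (CT dorsal, ET ventral)
                    b <- boxes[boxes$region == "Thal", ]
                    ylo <- if (cls == "CT") b$ymin else 4400
                    yhi <- if (cls == "CT") 4400 else b$ymax
                    d <- .sampleTargetCloud(k, "Thal", boxes, 120)
                    d$y <- stats::runif(k, ylo, yhi)
                    d
                } else if (tg %in% c("VisI", "CtxC")) {
                    .sampleTargetCloud(k, tg, boxes, spreadSD,
                                       depths = .corticalDepth(k, somaDepth[i]))
                } else {
                    .sampleTargetCloud(k, tg, boxes, 120)
                }
            })
            ri <- do.call(rbind, parts)
            ri$neuronId <- i
            ri$kind <- "axonal"
            # floating rolonies: soma section +/- 1, broad tangential scatter
            if (cfg@nFloatingPerSoma > 0) {
                k <- cfg@nFloatingPerSoma
                ang <- stats::runif(k, 0, 2 * pi)
                rad <- cfg@floatingRadius * sqrt(stats::runif(k))
                fz <- (neurons$somaSection[i] - 1L +
                       sample(c(-1L, 0L, 1L), k, replace = TRUE,
                              prob = c(0.2, 0.6, 0.2)) - 0.5)
                fl <- data.frame(
                    x = somaX[i] + rad * cos(ang),
                    y = somaY[i] + rad * sin(ang),
                    z = pmax(0, fz * cfg@sectionThickness + cfg@sectionThickness / 2),
                    region = "AudI", depthPct = NA_real_,
                    neuronId = i, kind = "floating")
                ri <- rbind(ri, fl)
            }
            rol[[i]] <- ri
        }
        rolonies <- do.call(rbind, rol)
        # secondary-infection contaminants: compact clusters, own barcodes
        if (cfg@nSecondaryBarcodes > 0) {
            sbc <- .drawBarcodes(cfg@nSecondaryBarcodes, cfg)
            sec <- lapply(seq_len(cfg@nSecondaryBarcodes), function(j) {
                tg <- sample(c("Thal", "VisI", "CtxC"), 1)
                b <- boxes[boxes$region == tg, ]
                cx <- stats::runif(1, b$xmin + 50, b$xmax - 50)
                cy <- stats::runif(1, b$ymin + 50, b$ymax - 50)
                cz <- stats::runif(1, b$zmin + 20, b$zmax - 20)
                k <- 15L
                data.frame(
                    x = stats::rnorm(k, cx, 20), y = stats::rnorm(k, cy, 20),
                    z = cz + stats::runif(k, -5, 5),
                    region = tg, depthPct = NA_real_,
                    neuronId = n + j, kind = "secondary")
            })
            sec <- do.call(rbind, sec)
            rolonies <- rbind(rolonies, sec)
            neurons <- rbind(neurons, data.frame(
                id = n + seq_len(cfg@nSecondaryBarcodes), barcode = sbc,
                cellClass = "secondary", somaX = NA_real_, somaY = NA_real_,
                somaZ = NA_real_, somaDepth = NA_real_,
                somaSection = NA_integer_, trajectoryTag = "none"))
        }
        rolonies$rolonyId <- seq_len(nrow(rolonies))
        rolonies$barcode <- neurons$barcode[rolonies$neuronId]
        rolonies$section <- as.integer(floor(rolonies$z / cfg@sectionThickness)) + 1L
        rownames(rolonies) <- NULL
        list(neurons = neurons,
             rolonies = rolonies[, c("rolonyId", "neuronId", "barcode",
                                     "x", "y", "z", "section", "region",
                                     "depthPct", "kind")],
             config = cfg)
    })
}

#' Emit per-cycle dot observations from ground-truth neurons
#'
#' Images every ground-truth rolony over `cfg@nCycles` sequencing cycles:
#' each rolony yields at most one dot per cycle, missing with probability
#' `dropoutRate`; the observed channel equals the barcode letter of that
#' cycle except with probability `substitutionRate` (uniform over the
#' other three channels); positions are jittered by `jitterSD` pixels per
#' axis per cycle. Dot coordinates are section-frame pixels
#' (micrometres / `pixelSize`); one tile per section.
#'
#' @param sim output of [simulateNeurons()].
#' @param cfg a \linkS4class{SimConfig}; defaults to `sim$config`.
#' @return list with `dots` (dotId, cycle, section, tile, x, y, channel,
#'   intensity, plus ground-truth linkage columns rolonyId, neuronId,
#'   kind — linkage is for auditing only, never used by the pipeline) and
#'   `truth` (the `sim` input).
#' @export
emitDotObservations <- function(sim, cfg = sim$config) {
    rol <- sim$rolonies
    withSeed(cfg@seed + 1L, {
        nC <- cfg@nCycles
        nR <- nrow(rol)
        bm <- barcodeMatrix(rol$barcode)
        keep <- matrix(stats::runif(nR * nC) >= cfg@dropoutRate, nR, nC)
        out <- vector("list", nC)
        for (cy in seq_len(nC)) {
            idx <- which(keep[, cy])
            if (!length(idx)) { out[[cy]] <- NULL; next }
            ch <- ntToChannel(bm[idx, cy])
            sub <- stats::runif(length(idx)) < cfg@substitutionRate
            if (any(sub)) {
                shift <- sample(1:3, sum(sub), replace = TRUE)
                ch[sub] <- ((ch[sub] - 1L + shift) %% 4L) + 1L
            }
            out[[cy]] <- data.frame(
                cycle = cy,
                section = rol$section[idx],
                tile = rol$section[idx],
                x = rol$x[idx] / cfg@pixelSize +
                    stats::rnorm(length(idx), 0, cfg@jitterSD),
                y = rol$y[idx] / cfg@pixelSize +
                    stats::rnorm(length(idx), 0, cfg@jitterSD),
                channel = ch,
                intensity = stats::rnorm(length(idx), 100, 10),
                rolonyId = rol$rolonyId[idx],
                neuronId = rol$neuronId[idx],
                kind = rol$kind[idx])
        }
        dots <- do.call(rbind, out)
        dots$dotId <- seq_len(nrow(dots))
        rownames(dots) <- NULL
        list(dots = dots[, c("dotId", "cycle", "section", "tile", "x", "y",
                             "channel", "intensity", "rolonyId", "neuronId",
                             "kind")],
             truth = sim)
    })
}

#' Render dots into a four-channel image stack
#'
#' Renders each dot as a Gaussian blob (3-7 px diameter at threshold)
#' whose z-profile peaks on a contiguous slab of planes, with optional
#' additive noise, linear channel bleed-through, uneven illumination, and
#' phasing carry-over from a previous cycle's stack.
#'
#' @param dots data.frame with columns x, y (0-based pixels, subpixel
#'   allowed), channel (1..4), intensity, and optionally zPeak (1-based
#'   peak plane).
#' @param nx,ny,nz image dimensions (pixels / planes); nz >= 3.
#' @param sigma blob SD in pixels.
#' @param zSigma blob SD across planes.
#' @param noiseSD additive Gaussian noise SD (clipped at 0).
#' @param bleedThrough fraction of each blob leaking into the other three
#'   channels.
#' @param illumination optional ny x nx multiplicative field.
#' @param previous optional \linkS4class{ImageStack} of the previous
#'   cycle; `phasing` of its signal is carried over additively.
#' @param phasing carry-over fraction.
#' @param pixelSize,zStep,tileId,cycleId stack calibration.
#' @param seed seed for the noise draw.
#' @return an \linkS4class{ImageStack}.
#' @export
renderImageStack <- function(dots, nx, ny, nz = 5, sigma = 0.9,
                             zSigma = 0.8, noiseSD = 0, bleedThrough = 0,
                             illumination = NULL, previous = NULL,
                             phasing = 0, pixelSize = 0.55, zStep = 3,
                             tileId = 1, cycleId = 1, seed = 1) {
    stopifnot(nz >= 3)
    arr <- array(0, dim = c(ny, nx, nz, 4))
    if (nrow(dots)) {
        if (is.null(dots$zPeak))
            dots$zPeak <- withSeed(seed + 1L,
                sample(2:(nz - 1), nrow(dots), replace = TRUE))
        for (i in seq_len(nrow(dots))) {
            x0 <- dots$x[i]; y0 <- dots$y[i]
            xs <- max(0, floor(x0 - 4)):min(nx - 1, ceiling(x0 + 4))
            ys <- max(0, floor(y0 - 4)):min(ny - 1, ceiling(y0 + 4))
            if (!length(xs) || !length(ys)) next
            gx <- exp(-((xs - x0)^2) / (2 * sigma^2))
            gy <- exp(-((ys - y0)^2) / (2 * sigma^2))
            blob <- dots$intensity[i] * outer(gy, gx)
            gz <- exp(-((seq_len(nz) - dots$zPeak[i])^2) / (2 * zSigma^2))
            ch <- dots$channel[i]
            for (z in seq_len(nz)) {
                add <- blob * gz[z]
                arr[ys + 1, xs + 1, z, ch] <- arr[ys + 1, xs + 1, z, ch] + add
                if (bleedThrough > 0) {
                    for (oc in setdiff(1:4, ch))
                        arr[ys + 1, xs + 1, z, oc] <-
                            arr[ys + 1, xs + 1, z, oc] + bleedThrough * add
                }
            }
        }
    }
    if (!is.null(illumination))
        arr <- arr * array(rep(illumination, nz * 4), dim = dim(arr))
    if (!is.null(previous) && phasing > 0)
        arr <- arr + phasing * previous@intensities
    if (noiseSD > 0)
        arr <- arr + withSeed(seed, array(stats::rnorm(length(arr), 0, noiseSD),
                                          dim = dim(arr)))
    arr[arr < 0] <- 0
    imageStack(arr, pixelSize = pixelSize, zStep = zStep,
               tileId = tileId, cycleId = cycleId)
}
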