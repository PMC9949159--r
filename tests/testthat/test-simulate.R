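test_that("barcode library: empty case, determinism, fixed positions", {
    cfg <- simConfig(seed = 42)
    expect_identical(generateBarcodeLibrary(0, cfg), character(0))
    b1 <- generateBarcodeLibrary(2, cfg)
    b2 <- generateBarcodeLibrary(2, cfg)
    expect_identical(b1, b2)
    lib <- generateBarcodeLibrary(50, cfg)
    expect_true(all(nchar(lib) == 17))
    expect_true(all(substr(lib, 9, 10) == "GG"))
})

test_that("one-Hamming-neighbour rate matches the closed form", {
    n <- 10000L
    cfg <- simConfig(seed = 99)
    lib <- generateBarcodeLibrary(n, cfg)
    varPart <- paste0(substr(lib, 1, 8), substr(lib, 11, 17))  # 15 variable nt
    counts <- table(varPart)
    seen <- new.env(parent = emptyenv())
    for (b in names(counts)) assign(b, counts[[b]], envir = seen)
    letters4 <- c("G", "T", "A", "C")
    hasNeighbour <- vapply(varPart, function(b) {
        if (get(b, envir = seen) > 1) return(TRUE)  # exact duplicate
        ch <- strsplit(b, "")[[1]]
        for (p in 1:15) for (l in setdiff(letters4, ch[p])) {
            nb <- ch; nb[p] <- l
            if (exists(paste0(nb, collapse = ""), envir = seen,
                       inherits = FALSE)) return(TRUE)
        }
        FALSE
    }, logical(1), USE.NAMES = FALSE)
    pNeighbour <- 1 - (1 - 46 / 4^15)^(n - 1)
    expected <- n * pNeighbour
    # Poisson-scale tolerance: 3 standard errors of the expected count
    expect_lt(abs(sum(hasNeighbour) - expected), 3 * sqrt(expected) + 1)
})

test_that("degenerate mixture yields pure ITi with no contralateral rolonies", {
    cfg <- simConfig(nNeurons = 30,
                     classMixture = c(CT = 0, ET = 0, ITi = 1, ITc = 0),
                     nSecondaryBarcodes = 0, seed = 3)
    sim <- simulateNeurons(cfg)
    expect_true(all(sim$neurons$cellClass == "ITi"))
    expect_false(any(sim$rolonies$region == "CtxC"))
    expect_true(all(sim$rolonies$region %in% regionBoxes()$region))
})

test_that("class counts follow the configured mixture binomially", {
    cfg <- simConfig(nNeurons = 200,
                     classMixture = c(CT = 0.5, ET = 0.5, ITi = 0, ITc = 0),
                     nSecondaryBarcodes = 0, seed = 5)
    sim <- simulateNeurons(cfg)
    nCT <- sum(sim$neurons$cellClass == "CT")
    bounds <- qbinom(c(0.005, 0.995), 200, 0.5)
    expect_gte(nCT, bounds[1])
    expect_lte(nCT, bounds[2])
    expect_true(all(sim$neurons$trajectoryTag[sim$neurons$cellClass == "CT"]
                    == "dorsal"))
    expect_true(all(sim$neurons$trajectoryTag[sim$neurons$cellClass == "ET"]
                    == "ventral"))
})

test_that("class invariants: ITc contralateral minimum, CT/ET target strata", {
    cfg <- simConfig(nNeurons = 60, nSecondaryBarcodes = 0, seed = 8)
    sim <- simulateNeurons(cfg)
    for (i in sim$neurons$id[sim$neurons$cellClass == "ITc"]) {
        ri <- sim$rolonies[sim$rolonies$neuronId == i, ]
        expect_gte(sum(ri$region == "CtxC"), 5)
    }
    for (i in sim$neurons$id[sim$neurons$cellClass == "ITi"]) {
        ri <- sim$rolonies[sim$rolonies$neuronId == i, ]
        expect_equal(sum(ri$region == "CtxC"), 0)
    }
    ct <- sim$neurons$id[sim$neurons$cellClass == "CT"]
    et <- sim$neurons$id[sim$neurons$cellClass == "ET"]
    rolCT <- sim$rolonies[sim$rolonies$neuronId %in% ct &
                          sim$rolonies$region == "Fiber", ]
    rolET <- sim$rolonies[sim$rolonies$neuronId %in% et &
                          sim$rolonies$region == "Fiber", ]
    expect_lt(mean(rolCT$y), mean(rolET$y))  # CT dorsal, ET ventral
})

test_that("noiseless emission reproduces barcodes exactly at true positions", {
    cfg <- simConfig(nNeurons = 5, dropoutRate = 0, substitutionRate = 0,
                     jitterSD = 0, nFloatingPerSoma = 0,
                     nSecondaryBarcodes = 0, seed = 10)
    sim <- simulateNeurons(cfg)
    obs <- emitDotObservations(sim, cfg)
    expect_equal(nrow(obs$dots), nrow(sim$rolonies) * cfg@nCycles)
    one <- obs$dots[obs$dots$rolonyId == sim$rolonies$rolonyId[1], ]
    one <- one[order(one$cycle), ]
    expect_identical(paste0(channelToNt(one$channel), collapse = ""),
                     sim$rolonies$barcode[1])
    expect_equal(one$x, rep(sim$rolonies$x[1] / cfg@pixelSize, 17))
})

test_that("dropout removes the expected number of cycles per rolony", {
    cfg <- simConfig(nNeurons = 40, dropoutRate = 0.1, substitutionRate = 0,
                     jitterSD = 0, nFloatingPerSoma = 0,
                     nSecondaryBarcodes = 0, seed = 12)
    sim <- simulateNeurons(cfg)
    obs <- emitDotObservations(sim, cfg)
    nR <- nrow(sim$rolonies)
    missingPerRolony <- cfg@nCycles - as.integer(table(
        factor(obs$dots$rolonyId, levels = sim$rolonies$rolonyId)))
    se <- sqrt(17 * 0.1 * 0.9 / nR)
    expect_lt(abs(mean(missingPerRolony) - 1.7), 3 * se)
})

test_that("floating rolonies are flagged per soma-bearing barcode, on soma +/- 1", {
    cfg <- simConfig(nNeurons = 10, nFloatingPerSoma = 5,
                     nSecondaryBarcodes = 0, seed = 14)
    sim <- simulateNeurons(cfg)
    fl <- sim$rolonies[sim$rolonies$kind == "floating", ]
    perNeuron <- table(factor(fl$neuronId, levels = sim$neurons$id))
    expect_true(all(perNeuron == 5))
    off <- fl$section - sim$neurons$somaSection[fl$neuronId]
    expect_true(all(abs(off) <= 1))
})

test_that("ground-truth linkage is total and seed-deterministic", {
    cfg <- simConfig(nNeurons = 15, nSecondaryBarcodes = 2, seed = 17)
    s1 <- simulateNeurons(cfg)
    s2 <- simulateNeurons(cfg)
    expect_identical(s1, s2)
    obs1 <- emitDotObservations(s1, cfg)
    obs2 <- emitDotObservations(s2, cfg)
    expect_identical(obs1$dots, obs2$dots)
    expect_true(all(obs1$dots$rolonyId %in% s1$rolonies$rolonyId))
    expect_true(all(obs1$dots$neuronId %in% s1$neurons$id))
    expect_true(all(s1$rolonies$kind %in% c("axonal", "floating",
                                            "secondary")))
})

test_that("rendering: delta response, empty stack, bleed-through fraction", {
    empty <- renderImageStack(data.frame(x = numeric(0), y = numeric(0),
                                         channel = integer(0),
                                         intensity = numeric(0)),
                              nx = 20, ny = 20, nz = 4)
    expect_true(all(empty@intensities == 0))
    one <- data.frame(x = 7, y = 11, channel = 2, intensity = 100,
                      zPeak = 2)
    st <- renderImageStack(one, nx = 20, ny = 20, nz = 4)
    proj <- apply(st@intensities[, , , 2], c(1, 2), max)
    pk <- which(proj == max(proj), arr.ind = TRUE)
    expect_equal(unname(pk[1, ]), c(12, 8))  # 0-based (7, 11) -> [12, 8]
    stB <- renderImageStack(one, nx = 20, ny = 20, nz = 4,
                            bleedThrough = 0.1)
    onPeak <- max(stB@intensities[, , , 2])
    offPeak <- max(stB@intensities[, , , 1])
    expect_equal(offPeak / onPeak, 0.1, tolerance = 1e-6)
})

test_that("config round-trips through the key-value format and validates", {
    cfg <- simConfig(nNeurons = 7, dropoutRate = 0.2, seed = 123)
    path <- withr::local_tempfile(fileext = ".cfg")
    writeSimConfig(cfg, path)
    back <- readSimConfig(path)
    expect_equal(back, cfg)
    expect_error(simConfig(dropoutRate = 1.5), "rates")
    expect_error(simConfig(classMixture = c(CT = 1, ET = 1, ITi = 0,
                                            ITc = 0)), "sum")
    expect_error(simConfig(barcodeLength = 9), "exceed")
})
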