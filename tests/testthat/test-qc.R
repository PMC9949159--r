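mkCodebook <- function(bcs, support = NULL) {
    if (is.null(support)) support <- rep(5L, length(bcs))
    new("Codebook",
        entries = data.frame(barcode = bcs, support = support,
                             attributed = 0L),
        fixedPositions = c(9L, 10L), variableLength = 15L)
}

test_that("error-prone barcode rules fire in order and are reported", {
    run7 <- "GGGGGGGTACGTACGTA"            # 7 identical in a row
    chPair <- "GTGTGTGTGGTGTGTTG"          # 17 calls in channels G/T
    okbc <- "GTACGTACGGTACGTAC"
    mism <- "CATGCATGGGATGCATG"            # more 1-2-mismatch than exact
    cb <- mkCodebook(c(run7, chPair, okbc, mism))
    md <- data.frame(entry = c(rep(okbc, 5), rep(mism, 7)),
                     distance = c(rep(0L, 5), 0L, 0L, rep(1L, 3),
                                  rep(2L, 2)))
    out <- filterErrorProne(cb, md)
    expect_identical(barcodes(out$codebook), okbc)
    expect_equal(out$report$removed, c(1L, 1L, 1L))
    # boundary: exactly 6-run and exactly 14 in a channel pair are kept
    run6 <- "GGGGGGTACGTACGTAC"
    pair14 <- "GTGTGTGTGGTGTGAAC"  # exactly 14 G/T calls
    out2 <- filterErrorProne(mkCodebook(c(run6, pair14)),
                             data.frame(entry = character(0),
                                        distance = integer(0)))
    expect_equal(length(out2$codebook), 2)
    # rule 3: 5 exact vs 6 one-mismatch reads -> removed
    out3 <- filterErrorProne(mkCodebook(okbc),
                             data.frame(entry = rep(okbc, 11),
                                        distance = c(rep(0L, 5),
                                                     rep(1L, 6))))
    expect_equal(length(out3$codebook), 0)
})

test_that("count gates enforce target, axonal and somal limits", {
    mkRol <- function(bc, region, n)
        data.frame(barcode = bc, region = region)[rep(1, n), ]
    rol <- rbind(mkRol("A", "VisI", 12),
                 mkRol("B", "VisI", 9),             # max region count 9
                 mkRol("C", "VisI", 12))
    gates <- applyCountGates(rol, somaCounts = c(A = 100, C = 8000))
    expect_true("A" %in% gates$kept)      # 12 in one region, soma 100
    expect_false("B" %in% gates$kept)     # below the 10-rolony target gate
    expect_false("C" %in% gates$kept)     # soma counts above 7000
    # axonal ceiling
    rolBig <- mkRol("D", "VisI", 1200)
    expect_false("D" %in% applyCountGates(rolBig)$kept)
    # sub-minimum region counts are zeroed (4 < the thalamic minimum 5)
    rolMin <- rbind(mkRol("E", "Thal", 4), mkRol("E", "VisI", 10))
    g <- applyCountGates(rolMin)
    expect_equal(unname(g$counts["E", "Thal"]), 0L)
    expect_equal(unname(g$counts["E", "VisI"]), 10L)
    expect_error(applyCountGates(data.frame(barcode = "X",
                                            region = "Nowhere")),
                 "unknown region")
})

test_that("secondary-infection screen excludes Hamming-4 neighbourhoods", {
    bc <- "GTACGTACGGTACGTAC"
    cont <- bc
    expect_false(excludeSecondary(bc, cont))
    # distance 4 (excluded positions skipped): removed
    d4 <- bc
    substr(d4, 1, 4) <- "CATG"
    expect_equal(hammingDistance(d4, bc, "permissive"), 4L)
    expect_false(excludeSecondary(d4, cont))
    # distance 5: kept
    d5 <- d4
    substr(d5, 5, 5) <- "C"
    expect_equal(hammingDistance(d5, bc, "permissive"), 5L)
    expect_true(excludeSecondary(d5, cont))
    expect_true(all(excludeSecondary(c(bc, d4, d5), character(0))))
})

test_that("overlap deduplication keeps one copy across fields, same field kept", {
    rol <- data.frame(barcode = "A", section = 1L,
                      x = c(0, 10, 300, 0), y = 0,
                      field = c(1, 2, 2, 1))
    out <- dedupOverlap(rol)
    # the 10-um cross-field pair collapses to one; 300-um copy and the
    # same-field duplicate stay
    expect_equal(nrow(out), 3)
    expect_equal(sum(out$field == 1), 2)
    # 30 um apart: outside the exclusion range
    rol2 <- data.frame(barcode = "A", section = 1L, x = c(0, 30), y = 0,
                       field = c(1, 2))
    expect_equal(nrow(dedupOverlap(rol2)), 2)
    # idempotence
    expect_identical(dedupOverlap(out), out)
})

test_that("soma identification needs 80 counts within 100 um", {
    set.seed(61)
    mkPixels <- function(n, sec = 3L, bright = 500)
        data.frame(x = rnorm(n, 1000, 20), y = rnorm(n, 2000, 20),
                   section = sec,
                   intensity = c(bright, runif(n - 1, 50, 100)))
    soma <- identifySoma(mkPixels(120))
    expect_equal(soma$section, 3L)
    expect_lt(abs(soma$x - 1000), 100)
    expect_null(identifySoma(mkPixels(79)))
    expect_null(identifySoma(NULL))
    # the section with the highest summed intensity wins
    two <- rbind(mkPixels(100, sec = 3L), mkPixels(100, sec = 7L,
                                                   bright = 5000))
    expect_equal(identifySoma(two)$section, 7L)
})

test_that("floating-section detector finds planted disks, spares axons", {
    set.seed(62)
    # planted floater disk: 12 spread-out rolonies on one section, far
    # from the axon; axon = compact column through sections 10-20
    axon <- data.frame(x = rnorm(40, 5000, 40), y = rnorm(40, 3000, 40),
                       section = rep(10:19, each = 4), region = "Thal")
    floaters <- data.frame(x = runif(12, 8000, 9000),
                           y = runif(12, 2000, 3000),
                           section = 4L, region = "AudI")
    expect_equal(detectFloatingSections(rbind(axon, floaters)), 4L)
    # continuous axon only: nothing flagged
    expect_true(is.na(detectFloatingSections(axon)))
    # two isolated rolonies only: below the 3-cluster floor
    two <- data.frame(x = c(0, 500), y = c(0, 500), section = 1L,
                      region = "AudI")
    expect_true(is.na(detectFloatingSections(two)))
    # regions outside the scan list are ignored
    elsewhere <- floaters
    elsewhere$region <- "Str"
    expect_true(is.na(detectFloatingSections(rbind(axon[0, ], elsewhere))))
})

test_that("floating exclusion removes the window around the anchor only", {
    rol <- data.frame(barcode = "A",
                      x = 0, y = 0,
                      section = c(10, 11, 12, 15, 10),
                      region = c("AudI", "Thal", "VisI", "AudI", "Str"))
    out <- excludeFloating(rol, anchorSection = 10, window = 2)
    # sections 10-12 in scanned regions removed; section 15 kept;
    # non-listed region (Str) kept even on the anchor section
    expect_equal(nrow(out), 2)
    expect_setequal(out$section, c(15, 10))
    expect_true("Str" %in% out$region)
    # no anchor: identity; idempotence
    expect_identical(excludeFloating(rol, NA), rol)
    expect_identical(excludeFloating(out, 10, window = 2), out)
})

test_that("non-neural exclusion requires 3 rolonies at 200 um", {
    compact <- data.frame(x = runif(20, 0, 150), y = 0, z = 0)
    expect_false(excludeNonNeural(compact))
    spread <- rbind(compact,
                    data.frame(x = c(400, 420, 440), y = 0, z = 0))
    anchor <- list(x = 0, y = 0, z = 0)
    expect_true(excludeNonNeural(spread, soma = anchor))
    two <- rbind(compact[1:5, ], data.frame(x = c(400, 420), y = 0, z = 0))
    expect_false(excludeNonNeural(two, soma = anchor))
})

test_that("the QC chain ledger telescopes at every stage", {
    cfg <- simConfig(nNeurons = 25, nFloatingPerSoma = 12,
                     nSecondaryBarcodes = 2, seed = 63)
    sim <- simulateNeurons(cfg)
    rol <- sim$rolonies
    rol$field <- rol$section
    rol <- rol[, c("barcode", "x", "y", "z", "section", "region", "field")]
    somata <- split(sim$neurons, sim$neurons$id)
    somata <- stats::setNames(
        lapply(somata, function(nr)
            if (is.na(nr$somaSection)) NULL
            else list(x = nr$somaX, y = nr$somaY, z = nr$somaZ,
                      section = nr$somaSection)),
        sim$neurons$barcode)
    contaminants <- sim$neurons$barcode[sim$neurons$cellClass == "secondary"]
    out <- runQcChain(rol, somata = somata, contaminants = contaminants)
    lg <- out$ledger
    expect_true(all(lg$input == lg$kept + lg$removed))
    expect_true(all(lg$removed >= 0))
    # secondary-infection barcodes are gone
    expect_false(any(contaminants %in% out$cells))
    # floating rolonies near somata were excluded
    expect_gt(lg$removed[lg$stage == "floating-rolonies"], 0)
})
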