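test_that("Hamming conventions: N handling, exclusions, strict lookup", {
    a <- "GTACGTACGGTACGTAC"
    expect_equal(hammingDistance(a, a), 0L)
    expect_equal(hammingDistance(a, a, "strict", exclude = integer()), 0L)
    # one N, rest equal: a match under both conventions
    aN <- sub("^G", "N", a)
    expect_equal(hammingDistance(aN, a, "strict", exclude = integer()), 0L)
    expect_equal(hammingDistance(aN, a, "permissive"), 0L)
    # one N plus one true mismatch: strict counts the N too
    aNm <- aN
    substr(aNm, 3, 3) <- "G"  # position 3 was A
    expect_equal(hammingDistance(aNm, a, "strict", exclude = integer()), 2L)
    # excluded fixed positions are skipped under the permissive convention
    aF <- a
    substr(aF, 9, 10) <- "TT"
    expect_equal(hammingDistance(aF, a, "permissive", exclude = c(9, 10)),
                 0L)
    expect_equal(hammingDistance(aF, a, "permissive", exclude = integer()),
                 2L)
    expect_error(hammingDistance("GTA", "GTAC"), "lengths")
})

test_that("strict lookup distance equals the N-substitution enumeration oracle", {
    set.seed(51)
    letters5 <- c("G", "T", "A", "C", "N")
    for (rep in 1:40) {
        n <- 8
        a <- paste0(sample(letters5, n, TRUE, prob = c(rep(0.22, 4), 0.12)),
                    collapse = "")
        b <- paste0(sample(letters5, n, TRUE, prob = c(rep(0.22, 4), 0.12)),
                    collapse = "")
        expect_equal(
            hammingDistance(a, b, "strict", exclude = integer()),
            strictHammingOracle(a, b),
            info = paste(a, b))
    }
})

test_that("permissive distance is a metric on N-free strings", {
    set.seed(52)
    for (rep in 1:30) {
        x <- randomBarcode(12); y <- randomBarcode(12); z <- randomBarcode(12)
        dxy <- hammingDistance(x, y, exclude = integer())
        dyx <- hammingDistance(y, x, exclude = integer())
        dxz <- hammingDistance(x, z, exclude = integer())
        dzy <- hammingDistance(z, y, exclude = integer())
        expect_identical(dxy, dyx)
        expect_lte(dxy, dxz + dzy)
        expect_identical(hammingDistance(x, x, exclude = integer()), 0L)
    }
})

test_that("codebook acceptance rules: support, error attribution, separation", {
    x <- "GTACGTACGGTACGTAC"
    xErr <- x
    substr(xErr, 3, 3) <- "G"
    # 5 copies of X + 1 one-mismatch copy: X accepted with support 6
    cb <- buildCodebook(c(rep(x, 5), xErr))
    expect_identical(barcodes(cb), x)
    expect_equal(unname(supportCounts(cb)), 6L)
    expect_equal(entries(cb)$attributed, 1L)
    # 2 copies only: below the 3-rolony floor
    y <- "TACGTACGGGACGTACG"
    expect_equal(length(buildCodebook(rep(y, 2))), 0)
    # composition limits: nucleotide monoculture and too few called positions
    mono <- "GGGGGGGTGGGGGGGGT"   # 15 G (>= 14 identical)
    expect_equal(length(buildCodebook(rep(mono, 5))), 0)
    manyN <- "GTNCGNACGGTNCGTAC"  # only 12 of 15 variable nt called
    expect_equal(length(buildCodebook(rep(manyN, 5))), 0)
    # empty input
    expect_equal(length(buildCodebook(character(0))), 0)
})

test_that("greedy codebook equals exhaustive rule evaluation on small read sets", {
    set.seed(53)
    for (rep in 1:5) {
        truth <- replicate(12, {
            b <- randomBarcode(17); substr(b, 9, 10) <- "GG"; b
        })
        reads <- unlist(lapply(truth, function(b) {
            k <- sample(3:8, 1)
            out <- rep(b, k)
            # sprinkle 1-mismatch errors
            nerr <- sample(0:2, 1)
            for (e in seq_len(nerr)) {
                p <- sample(setdiff(1:17, 9:10), 1)
                bad <- out[1]
                substr(bad, p, p) <- sample(setdiff(c("G","T","A","C"),
                                            substr(b, p, p)), 1)
                out <- c(out, bad)
            }
            out
        }))
        cb <- buildCodebook(reads)
        # independent oracle: direct quadratic evaluation of the rules
        tab <- sort(table(reads), decreasing = TRUE)
        cand <- names(tab)
        accepted <- character(0)
        for (b in cand) {
            nearAcc <- any(vapply(accepted, function(a)
                hammingDistance(b, a, "permissive", exclude = c(9, 10)) <= 1,
                logical(1)))
            if (nearAcc) next
            if (tab[[b]] < 3) next
            ch <- strsplit(b, "")[[1]]
            if (max(table(ch[ch != "N"])) >= 14) next
            if (sum(ch[-c(9, 10)] != "N") < 13) next
            accepted <- c(accepted, b)
        }
        expect_setequal(barcodes(cb), accepted)
        expect_setequal(barcodes(cb), truth[tab[truth] >= 3])
    }
})

test_that("reads with N collapse into their unique fully-called barcode", {
    x <- "GTACGTACGGTACGTAC"
    xN <- sub("^G", "N", x)
    cb <- buildCodebook(c(rep(x, 2), rep(xN, 2)))
    expect_identical(barcodes(cb), x)
    expect_equal(unname(supportCounts(cb)), 4L)
})

test_that("codebook matching: unique within distance 2, ambiguity discarded", {
    e1 <- "GTACGTACGGTACGTAC"
    e2 <- "CATGCATGGGATGCATG"
    cb <- buildCodebook(c(rep(e1, 3), rep(e2, 3)))
    expect_equal(length(cb), 2)
    m0 <- matchToCodebook(e1, cb)
    expect_identical(m0$verdict, "matched")
    expect_equal(m0$distance, 0L)
    # distance exactly 2 from one entry
    q2 <- e1
    substr(q2, 1, 1) <- "A"; substr(q2, 3, 3) <- "T"
    m2 <- matchToCodebook(q2, cb)
    expect_identical(m2$verdict, "matched")
    expect_identical(m2$entry, e1)
    expect_equal(m2$distance, 2L)
    # distance 3: unmatched
    q3 <- q2
    substr(q3, 5, 5) <- "A"
    expect_identical(matchToCodebook(q3, cb)$verdict, "unmatched")
    # equidistant from two entries at the minimum: ambiguous, discarded
    eA <- "GGGGGGGGGGGGGGGGG"
    eB <- "GGGGGGGGGGGGGTTTT"
    cb2 <- new("Codebook",
               entries = data.frame(barcode = c(eA, eB),
                                    support = c(5L, 5L),
                                    attributed = c(0L, 0L)),
               fixedPositions = c(9L, 10L), variableLength = 15L)
    qT <- "GGGGGGGGGGGGGGGTT"  # 2 mismatches to each
    expect_equal(hammingDistance(qT, c(eA, eB), "strict",
                                 exclude = integer()), c(2L, 2L))
    expect_identical(matchToCodebook(qT, cb2)$verdict, "ambiguous")
})

test_that("matching recall and precision on a simulated library", {
    set.seed(54)
    truth <- replicate(50, {
        b <- randomBarcode(17); substr(b, 9, 10) <- "GG"; b
    })
    reads <- unlist(lapply(truth, function(b) {
        vapply(1:10, function(i) {
            ch <- strsplit(b, "")[[1]]
            err <- runif(17) < 0.01
            ch[err] <- vapply(ch[err], function(l)
                sample(setdiff(c("G","T","A","C"), l), 1), "")
            paste0(ch, collapse = "")
        }, "")
    }))
    cb <- buildCodebook(reads)
    expect_equal(sort(barcodes(cb)), sort(truth))  # recall & precision 1
    m <- matchToCodebook(reads, cb)
    truthOfRead <- rep(truth, each = 10)
    matched <- m$verdict == "matched"
    expect_gte(mean(matched), 0.99)
    expect_equal(mean(m$entry[matched] != truthOfRead[matched]), 0)
})

test_that("condensation blanks shared dots and collapses similar reads", {
    e1 <- "GTACGTACGGTACGTAC"
    nC <- 17
    mkRead <- function(id, barcode, dotIds) {
        list(reads = data.frame(readId = id, barcode = barcode, x = 0,
                                y = 0, section = 1L,
                                nCalled = sum(strsplit(barcode, "")[[1]] != "N"),
                                maxNRun = maxN(barcode)),
             dotMap = list(dotIds))
    }
    maxN <- function(b) {
        r <- rle(strsplit(b, "")[[1]] == "N")
        w <- r$lengths[r$values]
        if (length(w)) max(w) else 0L
    }
    # two forked reads sharing 16/17 dots -> the more-called one survives
    bcFull <- e1
    bcN <- sub("C$", "N", e1)
    dots1 <- 1:17
    dots2 <- c(1:16, NA)
    asm <- list(reads = rbind(mkRead(1, bcFull, dots1)$reads,
                              mkRead(2, bcN, dots2)$reads),
                dotMap = list(dots1, dots2))
    matches <- data.frame(query = c(bcFull, bcN), entry = e1,
                          distance = c(0L, 0L), verdict = "matched")
    out <- condenseReads(asm, matches)
    expect_equal(nrow(out$reads), 1)
    expect_identical(out$reads$barcode, bcFull)
    # disjoint reads are untouched
    asm2 <- list(reads = rbind(mkRead(1, bcFull, 1:17)$reads,
                               mkRead(2, bcFull, 18:34)$reads),
                 dotMap = list(1:17, 18:34))
    out2 <- condenseReads(asm2, matches[c(1, 1), ])
    expect_equal(nrow(out2$reads), 2)
    # a dot claimed by two different matched barcodes is blanked in both;
    # a read whose N-run then exceeds 3 is excluded
    e2 <- "CATGCATGGGATGCATG"
    shared <- 5:8  # four consecutive cycles share dots across barcodes
    dmA <- 1:17; dmB <- c(101:104, 5:8, 109:117)
    asm3 <- list(reads = rbind(mkRead(1, e1, dmA)$reads,
                               mkRead(2, e2, dmB)$reads),
                 dotMap = list(dmA, dmB))
    matches3 <- data.frame(query = c(e1, e2), entry = c(e1, e2),
                           distance = 0L, verdict = "matched")
    out3 <- condenseReads(asm3, matches3)
    expect_equal(nrow(out3$reads), 0)  # both fall to an N-run of 4
})
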