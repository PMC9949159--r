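test_that("laminar profiles normalize and accumulate correctly", {
    p <- laminarProfile(c(10, 10, 50, 90), binWidth = 1)
    expect_equal(sum(p$freq), 1)
    expect_equal(p$cdf[length(p$cdf)], 1)
    expect_true(all(diff(p$cdf) >= 0))
    expect_equal(p$n, 4)
    p5 <- laminarProfile(numeric(0), binWidth = 5)
    expect_equal(sum(p5$freq), 0)
    expect_equal(length(p5$freq), 20)
})

test_that("KS permutation: identity, separation, empty samples", {
    a <- c(10, 20, 30, 40, 50)
    same <- ksPermutation(a, a, nShuffles = 200, seed = 1)
    expect_equal(same$ks, 0)
    expect_equal(same$p, 1)
    expect_false(same$different)
    # disjoint supports with n = 100 each: decisively different
    set.seed(81)
    lo <- runif(100, 0, 50)
    hi <- runif(100, 50, 100)
    sep <- ksPermutation(lo, hi, nShuffles = 1000, seed = 2)
    expect_lte(sep$p, 0.001)
    expect_true(sep$different)
    # empty sample: undefined marker
    none <- ksPermutation(numeric(0), hi)
    expect_true(is.na(none$ks) && is.na(none$p))
    # determinism via the per-cell seed
    r1 <- ksPermutation(lo, hi[1:40], nShuffles = 100, seed = 7)
    r2 <- ksPermutation(lo, hi[1:40], nShuffles = 100, seed = 7)
    expect_identical(r1, r2)
})

test_that("group percentages with bootstrap confidence intervals", {
    all01 <- fractionDifferent(list(g1 = rep(0.01, 30)))
    expect_equal(all01$percent, 100)
    set.seed(82)
    half <- fractionDifferent(list(g = c(rep(0.01, 50), rep(0.5, 50))),
                              nBoot = 500)
    expect_equal(half$percent, 50)
    expect_lt(half$lower, 50)
    expect_gt(half$upper, 50)
    expect_warning(one <- fractionDifferent(list(g = 0.2)), "single")
    expect_equal(one$lower, one$percent)
})

test_that("soma depth groups use the 35/60 boundaries and drop unknowns", {
    g <- somaDepthGroups(c(35, 35.1, 60, 60.1, 10, NA))
    expect_identical(as.character(g),
                     c("upper", "middle", "middle", "deep", "upper", NA))
})

test_that("cortical rolony prep: depth cut and injection disk", {
    rol <- data.frame(ml = c(0, 0, 300, 5000), ap = c(0, 0, 0, 0),
                      depth = c(50, 96, 50, 50))
    somaML <- rnorm(50, 0, 50)
    somaAP <- rnorm(50, 0, 50)
    prep <- corticalRolonyPrep(rol, somaML, somaAP)
    # depth > 95 dropped; rolonies inside the 95th-percentile disk dropped
    expect_false(any(prep$rolonies$depth > 95))
    expect_true(5000 %in% prep$rolonies$ml)
    expect_false(0 %in% prep$rolonies$ml)
    # mirrored control removes the contralateral disk too
    rolM <- data.frame(ml = c(-prep$center["ml"] * 0 - 10, 5000),
                       ap = c(0, 0), depth = c(50, 50))
    prepM <- corticalRolonyPrep(rolM, somaML, somaAP,
                                mirrorML = function(ml) -ml)
    expect_equal(nrow(prepM$rolonies), 1)
    # no soma information: only the depth rule applies
    prep0 <- corticalRolonyPrep(rol)
    expect_equal(nrow(prep0$rolonies), 3)
})

test_that("focal distance equals the brute-force oracle and orders spreads", {
    set.seed(83)
    # exact equality against direct enumeration on a unit-spaced line
    ml <- seq_len(60); ap <- rep(0, 60)
    m <- ceiling(0.33 * 59)
    oracle <- mean(vapply(1:60, function(i) {
        d <- abs(ml[-i] - ml[i])
        mean(sort(d)[seq_len(m)])
    }, numeric(1)))
    expect_equal(focalDistance(ml, ap), oracle)
    # all points identical -> 0
    expect_equal(focalDistance(rep(1, 60), rep(2, 60)), 0)
    # under the minimum rolony count -> excluded marker
    expect_true(is.na(focalDistance(1:54, 1:54)))
    # a tight disk scores lower than a dispersed cloud of the same size
    tight <- focalDistance(rnorm(80, 0, 50), rnorm(80, 0, 50))
    loose <- focalDistance(rnorm(80, 0, 500), rnorm(80, 0, 500))
    expect_lt(tight, loose)
})

test_that("subsampling error: zero at full size, reproducible, shrinking", {
    set.seed(84)
    ml <- rnorm(120, 0, 200); ap <- rnorm(120, 0, 200)
    err <- subsamplingErrorCurve(ml, ap, sizes = c(15, 60, 120, 200),
                                 reps = 30, seed = 5)
    expect_equal(nrow(err), 3)          # size 200 > n is skipped
    expect_equal(err$medianError[err$size == 120], 0)
    expect_gt(err$medianError[err$size == 15],
              err$medianError[err$size == 60])
    err2 <- subsamplingErrorCurve(ml, ap, sizes = c(15, 60, 120, 200),
                                  reps = 30, seed = 5)
    expect_identical(err, err2)
    # median over several cells is nonincreasing with size
    meds <- sapply(1:6, function(cell) {
        x <- rnorm(100, 0, 300); y <- rnorm(100, 0, 300)
        subsamplingErrorCurve(x, y, sizes = c(20, 50, 90), reps = 25,
                              seed = cell)$medianError
    })
    expect_true(all(diff(apply(meds, 1, median)) <= 0))
})

test_that("simulated retrograde tracing applies all three criteria", {
    cells <- data.frame(barcode = c("it", "cf", "nosoma", "few", "spec"),
                        class = c("ITc", "CF", "ITi", "ITc", "ITc"),
                        hasSoma = c(TRUE, TRUE, FALSE, TRUE, TRUE),
                        contraCount = c(16, 0, 0, 0, 12))
    rolonies <- data.frame(
        barcode = c(rep("it", 12), rep("cf", 12), rep("nosoma", 12),
                    rep("few", 9), rep("spec", 12)),
        ml = 0, ap = 0)
    pos <- simulatedRetrograde(cells, rolonies, center = c(0, 0))
    expect_setequal(pos$barcode, c("it", "spec"))
    # specificity: patch / contralateral count ratio >= 0.75
    expect_identical(pos$specific[pos$barcode == "it"], TRUE)   # 12/16
    expect_identical(pos$specific[pos$barcode == "spec"], TRUE) # 12/12
    cells$contraCount[cells$barcode == "it"] <- 17              # 12/17 < .75
    pos2 <- simulatedRetrograde(cells, rolonies, center = c(0, 0))
    expect_identical(pos2$specific[pos2$barcode == "it"], FALSE)
    # shrinking the radius never adds positives
    rolFar <- rolonies
    rolFar$ml <- rep(c(0, 250), length.out = nrow(rolFar))
    p300 <- simulatedRetrograde(cells, rolFar, center = c(0, 0),
                                radius = 300)
    p100 <- simulatedRetrograde(cells, rolFar, center = c(0, 0),
                                radius = 100)
    expect_true(all(p100$barcode %in% p300$barcode))
})

test_that("reconstruction links points into capped spanning trees", {
    # two points 500 um apart: one edge
    e <- reconstructCell(cbind(c(0, 500), 0, 0))
    expect_equal(nrow(e), 1)
    expect_equal(e$dist, 500)
    # two clusters 1200 um apart stay separate components
    pts <- rbind(cbind(runif(5, 0, 50), 0, 0),
                 cbind(runif(5, 1250, 1300), 0, 0))
    e2 <- reconstructCell(pts)
    g <- igraph::graph_from_edgelist(as.matrix(e2[, 1:2]),
                                     directed = FALSE)
    g <- igraph::add_vertices(g, 10 - igraph::vcount(g))
    expect_equal(igraph::components(g)$no, 2)
    expect_true(all(e2$dist <= 1000))
    # the edge set is a spanning forest whose weight matches the MST
    set.seed(85)
    pts3 <- cbind(runif(40, 0, 800), runif(40, 0, 800), runif(40, 0, 200))
    e3 <- reconstructCell(pts3)
    g3 <- igraph::graph_from_edgelist(as.matrix(e3[, 1:2]),
                                      directed = FALSE)
    expect_equal(igraph::components(g3)$no, 1)
    expect_equal(nrow(e3), 39)  # acyclic spanning tree
    d <- as.matrix(dist(pts3))
    gFull <- igraph::graph_from_adjacency_matrix(d, mode = "undirected",
                                                 weighted = TRUE)
    mstLen <- sum(igraph::E(igraph::mst(gFull))$weight)
    expect_gte(sum(e3$dist) + 1e-9, mstLen)
    # collinear points: reconstruction equals the MST exactly
    line <- cbind(sort(runif(20, 0, 900)), 0, 0)
    eL <- reconstructCell(line)
    expect_equal(sum(eL$dist), max(line[, 1]) - min(line[, 1]))
})
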