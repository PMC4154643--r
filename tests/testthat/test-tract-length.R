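test_that("truncated-exponential estimate matches quadrature", {
    set.seed(61)
    for (i in 1:100) {
        a <- runif(1, 1, 2000)
        b <- a + runif(1, 1, 3000)
        p <- runif(1, 0.99, 0.9995)
        expect_lt(abs(estimateTractLength(a, b, p) -
                      truncExpMeanQuad(a, b, p)) / truncExpMeanQuad(a, b, p),
                  1e-6)
    }
})

test_that("estimator limits: degenerate bounds and the uniform limit", {
    expect_equal(estimateTractLength(500, 500), 500)
    expect_lt(abs(estimateTractLength(100, 300, p = 0.9999999) - 200), 0.01)
    expect_error(estimateTractLength(300, 100), "a <= b")
    # estimates always lie within the bounds and increase with p
    set.seed(62)
    for (i in 1:20) {
        a <- runif(1, 1, 500); b <- a + runif(1, 1, 2000)
        ps <- seq(0.99, 0.999, by = 0.001)
        ests <- vapply(ps, function(p) estimateTractLength(a, b, p),
                       numeric(1))
        expect_true(all(ests >= a & ests <= b))
        expect_true(all(diff(ests) > 0))
    }
})

test_that("continuous closed form agrees with the discrete geometric sum", {
    p <- 0.99717
    for (ab in list(c(100, 1000), c(1, 50), c(353, 2000))) {
        k <- ab[1]:ab[2]
        w <- p^k
        discrete <- sum(k * w) / sum(w)
        expect_lt(abs(estimateTractLength(ab[1], ab[2], p) - discrete), 1)
    }
})

test_that("trans tracts split at the phase-switch midpoint", {
    map <- tinySnpMap(c(-200, 0, 150, 300, 350, 600, 900, 1100))
    # run 1: markers 0..300 (top donor); run 2: 350..900 (bottom donor)
    obs <- manualObservation(markers(map)$position,
                             top = c("P1", "P2", "P2", "P2", "P1", "P1",
                                     "P1", "P1"),
                             bottom = c("P1", "P1", "P1", "P1", "P2", "P2",
                                        "P2", "P1"))
    tract <- findHdnaTracts(callMarkerStates(obs), map)[[1]]
    expect_equal(classifyCisTrans(tract), "trans")
    bounds <- splitTransTract(tract, map)
    expect_equal(nrow(bounds), 2L)
    expect_equal(bounds$a, c(300, 550))
    # inner boundary at (300 + 350)/2 = 325; outer at excluded flanks
    expect_equal(bounds$b, c(325 - (-200), 1100 - 325))
    # single-marker second run: a = footprint
    obs2 <- manualObservation(markers(map)$position,
                              top = c("P1", "P2", "P2", "P2", "P1", "P1",
                                      "P1", "P1"),
                              bottom = c("P1", "P1", "P1", "P1", "P2", "P1",
                                         "P1", "P1"))
    tract2 <- findHdnaTracts(callMarkerStates(obs2), map)[[1]]
    b2 <- splitTransTract(tract2, map)
    expect_equal(b2$a[2], 1)
    # cis tracts cannot be split
    cis <- manualObservation(markers(map)$position,
                             top = c("P1", "P2", "P2", "P1", "P1", "P1",
                                     "P1", "P1"),
                             bottom = rep("P1", 8))
    expect_error(splitTransTract(
        findHdnaTracts(callMarkerStates(cis), map)[[1]], map), "trans")
})

test_that("length summaries: mean, SEM, and the geometric sanity check", {
    s <- summarizeLengths(c(100, 300))
    expect_equal(s$mean, 200)
    expect_equal(s$sem, 100)
    s1 <- summarizeLengths(42)
    expect_equal(s1$n, 1)
    expect_true(is.na(s1$sem))
    expect_error(summarizeLengths(numeric(0)), "no estimates")
    set.seed(63)
    p <- 0.99717
    lens <- 1 + rgeom(1000, prob = 1 - p)
    ests <- estimateTractLength(lens, lens, p = p)
    se <- sd(ests) / sqrt(length(ests))
    expect_lt(abs(mean(ests) - 1 / (1 - p)), 3 * se)
})

test_that("censoring through a marker map recovers the conditional mean", {
    # Tracts start at 0 and extend right a geometric number of bases; a
    # marker map censors the length into inclusion/exclusion bounds.  The
    # mean estimate over detected tracts should match the true conditional
    # mean from brute-force enumeration.
    p <- 0.995
    markersAt <- c(50, 150, 300, 600, 1200)
    leftExcl <- -50
    boundsOf <- function(len) {
        cov <- markersAt[markersAt < len]
        if (length(cov) == 0L)
            return(NULL)
        nxt <- c(markersAt[markersAt >= len], 2400)[1]
        a <- if (length(cov) == 1L) 1 else max(cov) - min(cov)
        c(a, nxt - leftExcl)
    }
    kmax <- 4000
    k <- 1:kmax
    w <- p^k
    detected <- k > 50
    trueCondMean <- sum(k[detected] * w[detected]) / sum(w[detected])
    set.seed(64)
    lens <- 1 + rgeom(3000, prob = 1 - p)
    ests <- numeric(0)
    for (len in lens) {
        b <- boundsOf(len)
        if (!is.null(b))
            ests <- c(ests, estimateTractLength(b[1], b[2], p = p))
    }
    se <- sd(ests) / sqrt(length(ests))
    # estimator bias from coarse censoring is tolerated up to 3 SE + 10%
    expect_lt(abs(mean(ests) - trueCondMean),
              3 * se + 0.1 * trueCondMean)
})
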