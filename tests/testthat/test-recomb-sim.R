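map <- rosyMarkerMap()

test_that("DSB resection/synthesis lengths are geometric with 1 bp minimum", {
    cfg0 <- modelConfig(pResect = 0, pSynth = 0)
    set.seed(1)
    d <- sampleDSB(map, cfg0)
    expect_equal(d$resectLeft, 1L)
    expect_equal(d$resectRight, 1L)
    expect_equal(d$synthLeft, 1L)
    expect_equal(d$synthRight, 1L)

    set.seed(42)
    d1 <- sampleDSB(map, modelConfig())
    set.seed(42)
    d2 <- sampleDSB(map, modelConfig())
    expect_identical(d1, d2)

    p <- 0.99
    cfg <- modelConfig(pResect = p, pSynth = p)
    set.seed(5)
    draws <- vapply(seq_len(5000), function(i)
        sampleDSB(map, cfg)$resectLeft, numeric(1))
    se <- sd(draws) / sqrt(length(draws))
    expect_lt(abs(mean(draws) - 1 / (1 - p)), 3 * se)
})

test_that("DSB positions fall in the gene region by default", {
    set.seed(8)
    cfg <- modelConfig()
    pos <- vapply(seq_len(200), function(i)
        sampleDSB(map, cfg)$position, numeric(1))
    gr <- geneRegion(map)
    expect_true(all(pos >= gr[1] & pos < gr[2]))
})

test_that("SDSA products are NCOs with one-sided hDNA and a nick", {
    set.seed(10)
    for (i in 1:50) {
        dsb <- sampleDSB(map, modelConfig())
        prod <- makeSdsaNCO(dsb, donor = "P2", map)
        expect_true(validObject(prod))
        tr <- truthInfo(prod)
        expect_equal(tr$label, "NCO")
        h <- hdnaIntervals(prod)
        expect_lte(nrow(h), 1L)
        if (nrow(h) == 1L) {
            if (tr$side == "right")
                expect_gte(h$start, dsb$position)
            else
                expect_lte(h$end, dsb$position)
        }
        strand <- if (tr$side == "right") "top" else "bottom"
        expect_gte(length(nicks(prod)[[strand]]), 1L)
    }
    # degenerate synthesis: product identical to the recipient parent
    dsb <- structure(list(position = 1000, resectLeft = 1, resectRight = 1,
                          synthLeft = 1, synthRight = 1), class = "DSBEvent")
    dsb$synthRight <- 0
    prod <- makeSdsaNCO(dsb, donor = "P2", map, side = "right")
    expect_equal(nrow(hdnaIntervals(prod)), 0L)
})

test_that("two-end engagement gives trans-hDNA NCOs or conversion-free COs", {
    set.seed(11)
    cfgNCO <- modelConfig(engagementCOProb = 0)
    cfgCO <- modelConfig(engagementCOProb = 1)
    for (i in 1:40) {
        dsb <- sampleDSB(map, cfgNCO)
        nco <- makeTwoEndEngagement(dsb, map, cfgNCO)
        expect_equal(truthInfo(nco)$label, "NCO")
        expect_gte(length(nicks(nco)$top), 1L)
        expect_gte(length(nicks(nco)$bottom), 1L)
        het <- hetMarkersOf(nco, map)
        if (any(het < dsb$position) && any(het >= dsb$position)) {
            an <- analyzeRecombinant(observeRecombinant(nco, map), map)
            expect_equal(an$tracts[[1]]$cisTrans, "trans")
        }
        co <- makeTwoEndEngagement(sampleDSB(map, cfgCO), map, cfgCO)
        expect_equal(truthInfo(co)$label, "CO")
        an <- analyzeRecombinant(observeRecombinant(co, map), map)
        for (tr in an$tracts)
            expect_false(any(tr$outcomes == "converted"))
    }
})

test_that("dHJ resolution orientation bias controls conversion tracts", {
    set.seed(12)
    cfg1 <- modelConfig(resolutionBias = 1)
    conv <- vapply(seq_len(200), function(i)
        truthInfo(makeDhjResolution(sampleDSB(map, cfg1), map,
                                    cfg1))$conversion, logical(1))
    expect_equal(sum(conv), 0L)

    cfg5 <- modelConfig(resolutionBias = 0.5)
    conv <- vapply(seq_len(2000), function(i)
        truthInfo(makeDhjResolution(sampleDSB(map, cfg5), map,
                                    cfg5))$conversion, logical(1))
    se <- sqrt(0.25 / length(conv))
    expect_lt(abs(mean(conv) - 0.5), 3 * se)
    # resolution always yields crossovers
    expect_true(all(vapply(seq_len(50), function(i)
        truthInfo(makeDhjResolution(sampleDSB(map, cfg5), map,
                                    cfg5))$label, character(1)) == "CO"))
})

test_that("dHJ dissolution gives nick-free trans NCOs", {
    set.seed(13)
    for (i in 1:40) {
        dsb <- sampleDSB(map, modelConfig())
        prod <- makeDhjDissolutionNCO(dsb, map)
        expect_equal(length(nicks(prod)$top) + length(nicks(prod)$bottom), 0L)
        expect_equal(truthInfo(prod)$label, "NCO")
        het <- hetMarkersOf(prod, map)
        if (any(het < dsb$position) && any(het >= dsb$position)) {
            an <- analyzeRecombinant(observeRecombinant(prod, map), map)
            expect_equal(an$tracts[[1]]$cisTrans, "trans")
        }
    }
})

test_that("gap repair converts fully with no hDNA inside the gap", {
    # gap [1250, 2155) spans exactly four markers: 1300, 1620, 1900, 2150
    dsb <- structure(list(position = 1700, resectLeft = 450,
                          resectRight = 455, synthLeft = 1, synthRight = 1),
                     class = "DSBEvent")
    prod <- makeGapRepairNCO(dsb, map)
    expect_equal(nrow(hdnaIntervals(prod)), 0L)
    states <- callMarkerStates(observeRecombinant(prod, map))
    expect_equal(sum(states$state == "homoduplex_P2"), 4L)
    expect_equal(sum(states$state == "heteroduplex"), 0L)
    expect_true(all(states$position[states$state == "homoduplex_P2"] %in%
                    c(1300, 1620, 1900, 2150)))
    # gap spanning no markers: indistinguishable from the recipient parent
    dsb0 <- structure(list(position = 2550, resectLeft = 20,
                           resectRight = 20, synthLeft = 1, synthRight = 1),
                      class = "DSBEvent")
    prod0 <- makeGapRepairNCO(dsb0, map)
    st0 <- callMarkerStates(observeRecombinant(prod0, map))
    expect_true(all(st0$state == "homoduplex_P1"))
})

test_that("simulateMeiosis respects weights, n and the seed", {
    cfg <- modelConfig(weights = c(sdsa = 1), seed = 99)
    prods <- simulateMeiosis(map, cfg, 100)
    expect_length(prods, 100)
    expect_true(all(vapply(prods, function(p) truthInfo(p)$model,
                           character(1)) == "sdsa"))
    expect_length(simulateMeiosis(map, cfg, 0), 0)
    mix <- modelConfig(weights = c(sdsa = 0.5, dhj_dissolution = 0.5),
                       seed = 7)
    a <- simulateMeiosis(map, mix, 20)
    b <- simulateMeiosis(map, mix, 20)
    expect_identical(lapply(a, strandSegments), lapply(b, strandSegments))
    expect_identical(lapply(a, nicks), lapply(b, nicks))
    expect_error(modelConfig(weights = c(sdsa = 0.5)), "sum to 1")
    expect_error(modelConfig(weights = c(nonsense = 1)), "named")
})

test_that("strands always tile the locus with one parental origin apiece", {
    cfg <- modelConfig(weights = c(sdsa = 0.2, two_ended_sdsa = 0.1,
                                   two_end_engagement = 0.3,
                                   dhj_resolution = 0.2,
                                   dhj_dissolution = 0.1, gap_repair = 0.1),
                       seed = 21)
    prods <- simulateMeiosis(map, cfg, 60)
    for (p in prods) {
        expect_true(validObject(p))
        for (strand in c("top", "bottom")) {
            segs <- strandSegments(p, strand)
            expect_equal(segs$start[1], locusBounds(map)[1])
            expect_equal(segs$end[nrow(segs)], locusBounds(map)[2])
            if (nrow(segs) > 1)
                expect_equal(segs$start[-1], segs$end[-nrow(segs)])
        }
    }
})
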