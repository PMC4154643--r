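test_that("marker states derive from strand call agreement", {
    obs <- manualObservation(c(10, 20, 30),
                             top = c("P1", "P2", "P2"),
                             bottom = c("P2", "P2", "P1"))
    st <- callMarkerStates(obs)
    expect_equal(st$state,
                 c("heteroduplex", "homoduplex_P2", "heteroduplex"))
    allP1 <- manualObservation(c(1, 2), c("P1", "P1"), c("P1", "P1"))
    expect_length(findHdnaTracts(callMarkerStates(allP1),
                                 tinySnpMap(c(1, 2))), 0L)
})

test_that("crossover classification reads the flanking phase", {
    co <- manualObservation(c(0, 100, 200),
                            c("P1", "P1", "P2"), c("P1", "P2", "P2"))
    expect_equal(classifyCrossover(callMarkerStates(co)), "CO")
    nco <- manualObservation(c(0, 100, 200),
                             c("P1", "P2", "P1"), c("P1", "P1", "P1"))
    expect_equal(classifyCrossover(callMarkerStates(nco)), "NCO")
    bad <- manualObservation(c(0, 100), c("P1", "P2"), c("P1", "P1"))
    expect_error(classifyCrossover(callMarkerStates(bad)), "heteroduplex")
})

test_that("tract reconstruction finds maximal non-background runs", {
    map <- tinySnpMap(seq(100, 1000, by = 100))
    top <- rep("P1", 10); top[3:6] <- "P2"
    obs <- manualObservation(markers(map)$position, top, rep("P1", 10))
    tracts <- findHdnaTracts(callMarkerStates(obs), map)
    expect_length(tracts, 1)
    expect_equal(tracts[[1]]$positions, c(300, 400, 500, 600))
    expect_equal(tracts[[1]]$spanMin, 300)
    expect_equal(tracts[[1]]$spanMax, 500)          # 700 - 200
    expect_equal(tracts[[1]]$displayStart, 250)     # halfway 200..300
    expect_equal(tracts[[1]]$displayEnd, 650)       # halfway 600..700

    # single-marker tract: spanMin = footprint, spanMax = flanking gap
    top1 <- rep("P1", 10); top1[4] <- "P2"
    tr1 <- findHdnaTracts(callMarkerStates(
        manualObservation(markers(map)$position, top1, rep("P1", 10))), map)
    expect_length(tr1, 1)
    expect_equal(tr1[[1]]$spanMin, 1)
    expect_equal(tr1[[1]]$spanMax, 200)

    # no non-background markers: no tracts
    none <- manualObservation(markers(map)$position, rep("P1", 10),
                              rep("P1", 10))
    expect_length(findHdnaTracts(callMarkerStates(none), map), 0)
})

test_that("marker outcomes score conversion, restoration and hDNA", {
    map <- tinySnpMap(seq(100, 700, by = 100))
    # het, converted, het inside a P1 background
    obs <- manualObservation(markers(map)$position,
                             top = c("P1", "P1", "P2", "P2", "P2", "P1",
                                     "P1"),
                             bottom = c("P1", "P1", "P2", "P1", "P2", "P1",
                                        "P1"))
    tracts <- findHdnaTracts(callMarkerStates(obs), map)
    expect_length(tracts, 1)
    expect_equal(scoreMarkerOutcomes(tracts[[1]]),
                 c("converted", "unrepaired", "converted"))
    # a background homoduplex marker between tract markers is a restoration
    obs2 <- manualObservation(markers(map)$position,
                              top = c("P1", "P2", "P1", "P2", "P1", "P1",
                                      "P1"),
                              bottom = rep("P1", 7))
    tracts2 <- findHdnaTracts(callMarkerStates(obs2), map)
    expect_length(tracts2, 1)
    out2 <- scoreMarkerOutcomes(tracts2[[1]])
    expect_equal(out2, c("unrepaired", "restored", "unrepaired"))
    expect_true(isPatchy(out2))
})

test_that("cis/trans classification uses strand-phase runs only", {
    map <- tinySnpMap(seq(100, 600, by = 100))
    trans <- manualObservation(markers(map)$position,
                               top = c("P1", "P1", "P1", "P2", "P2", "P1"),
                               bottom = c("P1", "P2", "P2", "P1", "P1",
                                          "P1"))
    tr <- findHdnaTracts(callMarkerStates(trans), map)
    expect_equal(classifyCisTrans(tr[[1]]), "trans")
    cis <- manualObservation(markers(map)$position,
                             top = c("P1", "P2", "P2", "P2", "P1", "P1"),
                             bottom = rep("P1", 6))
    expect_equal(classifyCisTrans(
        findHdnaTracts(callMarkerStates(cis), map)[[1]]), "cis")
    single <- manualObservation(markers(map)$position,
                                top = c("P1", "P2", "P1", "P1", "P1", "P1"),
                                bottom = rep("P1", 6))
    expect_equal(classifyCisTrans(
        findHdnaTracts(callMarkerStates(single), map)[[1]]),
        "undetermined")
})

test_that("patchiness flags mixed repair within a tract", {
    expect_true(isPatchy(c("unrepaired", "restored", "unrepaired")))
    expect_true(isPatchy(c("converted", "restored")))
    expect_false(isPatchy(c("unrepaired", "unrepaired")))
    expect_false(isPatchy(c("converted", "converted", "converted")))
    expect_false(isPatchy("converted"))
})

test_that("co-repair pair classification follows the counting rule", {
    out <- c("converted", "converted", "unrepaired", "unrepaired",
             "restored")
    pairs <- coRepairPairs(out, c(0, 10, 40, 80, 400))
    expect_equal(pairs$class,
                 c("co_repaired", "not_co_repaired", "excluded",
                   "not_co_repaired"))
    expect_equal(nrow(pairs), length(out) - 1L)
    # partition property
    expect_equal(sum(pairs$class == "co_repaired") +
                 sum(pairs$class == "not_co_repaired") +
                 sum(pairs$class == "excluded"), nrow(pairs))
})

test_that("distance binning matches the published-table shape", {
    pairs <- data.frame(distance = c(10, 10, 300),
                        class = c("co_repaired", "co_repaired",
                                  "not_co_repaired"))
    tab <- binPairsByDistance(pairs, edges = 21)
    expect_equal(tab$co_repaired, c(2L, 0L))
    expect_equal(tab$not_co_repaired, c(0L, 1L))
    empty <- binPairsByDistance(data.frame(distance = numeric(0),
                                           class = character(0)))
    expect_equal(empty$total, c(0L, 0L))
    # engineered counts reproduce the printed percentages
    eng <- data.frame(
        distance = c(rep(10, 42), rep(100, 111)),
        class = c(rep("co_repaired", 40), rep("not_co_repaired", 2),
                  rep("co_repaired", 40), rep("not_co_repaired", 71)))
    tab <- binPairsByDistance(eng, edges = 21)
    expect_equal(round(tab$pct_co_repaired), c(95, 36))
})

test_that("mismatch spectrum reports ambiguous pairs and loops", {
    map <- tinySnpMap(100)   # alleles A/G
    mt <- data.frame(position = 100, outcome = "unrepaired",
                     top = "P1", bottom = "P2", trans = FALSE)
    sp <- mismatchSpectrum(mt, map)
    # A/G SNP in unknown phase: both A:C and G:T at weight 1/2
    expect_setequal(sp$type, c("A:C", "G:T"))
    expect_equal(sp$unrepaired[sp$type == "A:C"], 0.5)
    expect_equal(sum(sp$unrepaired), 1)
    expect_equal(sum(sp$repaired), 0)
    # known phase in a trans tract: the observed pairing only, weight 1
    mtT <- data.frame(position = 100, outcome = "unrepaired",
                      top = "P1", bottom = "P2", trans = TRUE)
    specT <- mismatchSpectrum(mtT, map)
    # top carries A, bottom strand base is complement(G) = C
    expect_equal(specT$type, "A:C")
    expect_equal(specT$unrepaired, 1)
    # indel marker: loop of footprint size
    rosy <- rosyMarkerMap()
    mt2 <- data.frame(position = 2700, outcome = "unrepaired",
                      top = "P1", bottom = "P2", trans = FALSE)
    expect_equal(mismatchSpectrum(mt2, rosy)$type, "loop4")
    # empty input
    expect_equal(nrow(mismatchSpectrum(mt[0, ], map)), 0L)
})

test_that("analysis round-trips simulator ground truth", {
    map <- rosyMarkerMap()
    cfg <- modelConfig(weights = c(sdsa = 0.3, two_end_engagement = 0.3,
                                   dhj_resolution = 0.2,
                                   dhj_dissolution = 0.2), seed = 51)
    prods <- simulateMeiosis(map, cfg, 150)
    for (p in prods) {
        an <- analyzeRecombinant(observeRecombinant(p, map), map)
        expect_equal(an$label, truthInfo(p)$label)
        model <- truthInfo(p)$model
        labels <- vapply(an$tracts, `[[`, character(1), "cisTrans")
        if (model == "sdsa")
            expect_false(any(labels == "trans"))
        if (model %in% c("dhj_dissolution", "two_end_engagement") &&
            truthInfo(p)$label == "NCO") {
            x <- truthInfo(p)$dsb$position
            het <- hetMarkersOf(p, map)
            if (any(het < x) && any(het >= x))
                expect_equal(labels, "trans")
        }
    }
})
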