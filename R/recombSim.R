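#' Simulator configuration
#'
#' Parameters of the strand-level recombination simulator.  Resection and
#' repair-synthesis tract lengths are geometric: starting from a 1 bp minimum,
#' each tract extends one additional base with the per-bp continuation
#' probability, independently on the two sides of the break.  The default
#' continuation probability of 0.99717 (mean tract scale about 353 bp per
#' side) matches the prior used by the tract-length estimator.
#'
#' @param weights named numeric vector of model mixture weights over
#'   \code{c("sdsa", "two_ended_sdsa", "two_end_engagement",
#'   "dhj_resolution", "dhj_dissolution", "gap_repair")}; must sum to 1.
#' @param pResect,pSynth per-bp continuation probabilities in [0, 1) for
#'   resection and synthesis tracts.  Scalars are applied to both sides;
#'   length-2 vectors give independent left/right parameters.
#' @param resolutionBias probability that a double Holliday junction is
#'   resolved in the orientation yielding a single hDNA tract (no adjacent
#'   full-conversion tract); 1 - bias gives the conversion-bearing
#'   orientation.  The classical unbiased model is 0.5.
#' @param engagementCOProb probability that a two-end engagement intermediate
#'   is nicked into a crossover rather than disassembled into a noncrossover.
#' @param recipient which parent carries the broken (recipient) chromatid.
#' @param dsbRegion interval over which DSB positions are drawn uniformly;
#'   \code{NULL} means the gene region of the map (see \code{\link{geneRegion}}).
#' @param seed optional integer seed applied by \code{\link{simulateMeiosis}}.
#' @return A list of class \code{"ModelConfig"}.
#' @examples
#' modelConfig(weights = c(two_end_engagement = 1))
#' @export
modelConfig <- function(weights = c(two_end_engagement = 1),
                        pResect = 0.99717, pSynth = 0.99717,
                        resolutionBias = 0.5, engagementCOProb = 0.5,
                        recipient = c("P1", "P2"), dsbRegion = NULL,
                        seed = NULL) {
    recipient <- match.arg(recipient)
    known <- c("sdsa", "two_ended_sdsa", "two_end_engagement",
               "dhj_resolution", "dhj_dissolution", "gap_repair")
    if (is.null(names(weights)) || !all(names(weights) %in% known))
        stop("weights must be named with models among: ",
             paste(known, collapse = ", "))
    if (any(weights < 0) || abs(sum(weights) - 1) > 1e-8)
        stop("model weights must be non-negative and sum to 1")
    probs <- c(pResect, pSynth, resolutionBias, engagementCOProb)
    if (any(probs < 0) || any(probs > 1))
        stop("probabilities must lie in [0, 1]")
    if (any(c(pResect, pSynth) >= 1))
        stop("continuation probabilities must be < 1")
    structure(list(weights = weights,
                   pResect = rep(pResect, length.out = 2L),
                   pSynth = rep(pSynth, length.out = 2L),
                   resolutionBias = resolutionBias,
                   engagementCOProb = engagementCOProb,
                   recipient = recipient, dsbRegion = dsbRegion,
                   seed = seed),
              class = "ModelConfig")
}

# Geometric tract length with 1 bp minimum and continuation probability p.
.rtract <- function(n, p) 1L + stats::rgeom(n, prob = 1 - p)

#' Sample a double-strand break event
#'
#' The break position is uniform over the configured DSB region (by default
#' the gene region of the map; breaks are thought to occur throughout the
#' gene rather than at a hotspot).  Resection and synthesis tract lengths on
#' each side are geometric with the configured per-bp continuation
#' probabilities, with a 1 bp minimum.
#'
#' @param map A \linkS4class{MarkerMap}.
#' @param config A \code{\link{modelConfig}}.
#' @return list of class \code{"DSBEvent"} with fields \code{position},
#'   \code{resectLeft}, \code{resectRight}, \code{synthLeft},
#'   \code{synthRight}.
#' @examples
#' set.seed(1)
#' sampleDSB(rosyMarkerMap(), modelConfig())
#' @export
sampleDSB <- function(map, config) {
    region <- config$dsbRegion
    if (is.null(region))
        region <- geneRegion(map)
    pos <- floor(stats::runif(1, region[1], region[2]))
    structure(list(position = pos,
                   resectLeft = .rtract(1, config$pResect[1]),
                   resectRight = .rtract(1, config$pResect[2]),
                   synthLeft = .rtract(1, config$pSynth[1]),
                   synthRight = .rtract(1, config$pSynth[2])),
              class = "DSBEvent")
}

# Fresh recipient-parent duplex spanning the locus bounds.
.newDuplex <- function(map, recipient) {
    b <- locusBounds(map)
    list(top = .newStrand(b, recipient), bottom = .newStrand(b, recipient),
         bounds = b)
}

.clip <- function(x, bounds) pmin(pmax(x, bounds[1]), bounds[2])

.duplex <- function(d, nicksTop, nicksBottom, truth) {
    new("RecombinantDuplex", top = .mergeSegments(d$top),
        bottom = .mergeSegments(d$bottom),
        nicks = list(top = sort(unique(nicksTop)),
                     bottom = sort(unique(nicksBottom))),
        truth = truth, locusBounds = d$bounds)
}

#' Synthesis-dependent strand annealing (one-ended SDSA) noncrossover
#'
#' One 3' end invades the homologous donor, is extended by synthesis, and
#' re-anneals to the other break end.  The product is always a noncrossover
#' with a single hDNA tract (newly synthesized donor sequence opposite the
#' recipient strand) confined to one side of the break, and carries a nick on
#' the repaired strand at the unligated junction.
#'
#' @param dsb A \code{\link{sampleDSB}} event.
#' @param donor the donor parent, \code{"P1"} or \code{"P2"}.
#' @param map A \linkS4class{MarkerMap}.
#' @param side invading side, \code{"left"}, \code{"right"}, or
#'   \code{"random"}.  The hDNA tract lies on the invading side of the break.
#' @return A \linkS4class{RecombinantDuplex} with \code{truth$label == "NCO"}.
#' @export
makeSdsaNCO <- function(dsb, donor, map, side = c("random", "left", "right")) {
    side <- match.arg(side)
    if (side == "random")
        side <- sample(c("left", "right"), 1L)
    recipient <- .otherParent(donor)
    d <- .newDuplex(map, recipient)
    x <- dsb$position
    nt <- numeric(0); nb <- numeric(0)
    if (side == "right") {
        s <- .clip(x + dsb$synthRight, d$bounds)
        d$top <- .rewriteInterval(d$top, .clip(x, d$bounds), s, donor)
        nt <- s
    } else {
        s <- .clip(x - dsb$synthLeft, d$bounds)
        d$bottom <- .rewriteInterval(d$bottom, s, .clip(x, d$bounds), donor)
        nb <- s
    }
    .duplex(d, nt, nb,
            list(model = "sdsa", dsb = dsb, label = "NCO", side = side,
                 donor = donor, conversion = FALSE))
}

#' Two-end engagement intermediate: crossover or noncrossover
#'
#' Both resected break ends engage the same homologous chromatid and are
#' extended by synthesis, producing an intermediate with unligated (nicked)
#' junctions.  With probability \code{engagementCOProb} the intermediate is
#' nicked by a nuclease across from the existing nicks, yielding a crossover
#' whose recovered chromatid carries a single hDNA tract spanning the break
#' and no full-conversion tract.  Otherwise a helicase disassembles the
#' intermediate, yielding a noncrossover with trans hDNA (donor sequence on
#' the top strand right of the break and on the bottom strand left of it) and
#' at least one nick per strand.
#'
#' @inheritParams makeSdsaNCO
#' @param config A \code{\link{modelConfig}}; uses \code{engagementCOProb}
#'   and \code{recipient}.
#' @param modelName internal; label recorded in \code{truth$model}.
#' @return A \linkS4class{RecombinantDuplex}.
#' @export
makeTwoEndEngagement <- function(dsb, map, config,
                                 modelName = "two_end_engagement") {
    recipient <- config$recipient
    donor <- .otherParent(recipient)
    d <- .newDuplex(map, recipient)
    x <- dsb$position
    a <- .clip(x - dsb$synthLeft, d$bounds)
    b <- .clip(x + dsb$synthRight, d$bounds)
    isCO <- modelName == "two_end_engagement" &&
        stats::runif(1) < config$engagementCOProb
    if (isCO) {
        # Nicked into a crossover: hDNA [a, b) on the top strand, flanks
        # exchange phase at the tract, no conversion tract.
        d$top <- .rewriteInterval(d$top, a, d$bounds[2], donor)
        d$bottom <- .rewriteInterval(d$bottom, b, d$bounds[2], donor)
        return(.duplex(d, a, b,
                       list(model = modelName, dsb = dsb, label = "CO",
                            donor = donor, conversion = FALSE)))
    }
    # Disassembled into a noncrossover with trans hDNA.
    d$top <- .rewriteInterval(d$top, .clip(x, d$bounds), b, donor)
    d$bottom <- .rewriteInterval(d$bottom, a, .clip(x, d$bounds), donor)
    .duplex(d, b, a,
            list(model = modelName, dsb = dsb, label = "NCO",
                 donor = donor, conversion = FALSE))
}

#' Two-ended SDSA noncrossover
#'
#' Both ends undergo strand exchange and synthesis, then dissociate and
#' anneal.  Observationally equivalent to the noncrossover branch of
#' \code{\link{makeTwoEndEngagement}} (trans hDNA, nicks present); the two
#' mechanisms cannot be distinguished from recovered products.
#'
#' @inheritParams makeTwoEndEngagement
#' @return A \linkS4class{RecombinantDuplex} with \code{truth$label == "NCO"}.
#' @export
makeTwoEndedSdsaNCO <- function(dsb, map, config) {
    makeTwoEndEngagement(dsb, map, config, modelName = "two_ended_sdsa")
}

#' Double Holliday junction resolution crossover
#'
#' Cleaving different strands at the two junctions yields a crossover.  One
#' orientation (probability \code{resolutionBias}) gives a product with a
#' single hDNA tract; the other gives a product with a full gene-conversion
#' tract (both strands donor) adjacent to the hDNA tract.  Cleavage points
#' leave nicks.
#'
#' @inheritParams makeTwoEndEngagement
#' @return A \linkS4class{RecombinantDuplex} with \code{truth$label == "CO"}
#'   and \code{truth$conversion} indicating the orientation.
#' @export
makeDhjResolution <- function(dsb, map, config) {
    recipient <- config$recipient
    donor <- .otherParent(recipient)
    d <- .newDuplex(map, recipient)
    x <- .clip(dsb$position, d$bounds)
    a <- .clip(dsb$position - dsb$synthLeft, d$bounds)
    b <- .clip(dsb$position + dsb$synthRight, d$bounds)
    open <- stats::runif(1) < config$resolutionBias
    if (open) {
        # Single hDNA tract [x, b) on the invading-side synthesis.
        d$top <- .rewriteInterval(d$top, x, d$bounds[2], donor)
        d$bottom <- .rewriteInterval(d$bottom, b, d$bounds[2], donor)
        nt <- x; nb <- b
    } else {
        # Full conversion on [a, x) adjacent to hDNA on [x, b).
        d$top <- .rewriteInterval(d$top, a, d$bounds[2], donor)
        d$bottom <- .rewriteInterval(d$bottom, a, x, donor)
        d$bottom <- .rewriteInterval(d$bottom, b, d$bounds[2], donor)
        nt <- a; nb <- c(x, b)
    }
    .duplex(d, nt, nb,
            list(model = "dhj_resolution", dsb = dsb, label = "CO",
                 donor = donor, conversion = !open))
}

#' Double Holliday junction dissolution noncrossover
#'
#' The two junctions converge by combined helicase/topoisomerase action,
#' unwinding the intermediate without cleavage.  The product is a
#' noncrossover with trans hDNA (donor on opposite strands on the two sides
#' of the break) and, distinctively, no nicks: dissolution leaves no entry
#' points for nick-directed mismatch repair.
#'
#' @inheritParams makeTwoEndEngagement
#' @param recipient recipient parent (broken chromatid).
#' @return A \linkS4class{RecombinantDuplex} with empty nick lists.
#' @export
makeDhjDissolutionNCO <- function(dsb, map, recipient = "P1") {
    donor <- .otherParent(recipient)
    d <- .newDuplex(map, recipient)
    x <- .clip(dsb$position, d$bounds)
    a <- .clip(dsb$position - dsb$synthLeft, d$bounds)
    b <- .clip(dsb$position + dsb$synthRight, d$bounds)
    d$top <- .rewriteInterval(d$top, x, b, donor)
    d$bottom <- .rewriteInterval(d$bottom, a, x, donor)
    .duplex(d, numeric(0), numeric(0),
            list(model = "dhj_dissolution", dsb = dsb, label = "NCO",
                 donor = donor, conversion = FALSE))
}

#' Double-strand gap repair noncrossover
#'
#' The break is enlarged to a gap before repair; synthesis across the gap
#' using the homolog necessarily copies the donor on both strands, producing
#' a tract of full gene conversion with no hDNA inside it.  The resection
#' fields of the DSB event give the gap extent on each side.
#'
#' @inheritParams makeDhjDissolutionNCO
#' @return A \linkS4class{RecombinantDuplex} with \code{truth$label == "NCO"}
#'   and a single full-conversion tract.
#' @export
makeGapRepairNCO <- function(dsb, map, recipient = "P1") {
    donor <- .otherParent(recipient)
    d <- .newDuplex(map, recipient)
    a <- .clip(dsb$position - dsb$resectLeft, d$bounds)
    b <- .clip(dsb$position + dsb$resectRight, d$bounds)
    d$top <- .rewriteInterval(d$top, a, b, donor)
    d$bottom <- .rewriteInterval(d$bottom, a, b, donor)
    .duplex(d, b, a,
            list(model = "gap_repair", dsb = dsb, label = "NCO",
                 donor = donor, conversion = TRUE))
}

#' Simulate recombinant duplex chromatids
#'
#' Draws \code{n} independent repair events: for each, a model is chosen
#' according to the mixture weights, a DSB is sampled, and the corresponding
#' product constructor is applied.  Only the recovered chromatid is
#' simulated.  Reproducible under \code{config$seed}.
#'
#' @param map A \linkS4class{MarkerMap}.
#' @param config A \code{\link{modelConfig}}.
#' @param n number of meioses (products) to simulate.
#' @return list of \linkS4class{RecombinantDuplex}, each with an
#'   \code{eventId} in its truth metadata.
#' @examples
#' prods <- simulateMeiosis(rosyMarkerMap(),
#'                          modelConfig(weights = c(sdsa = 1), seed = 1),
#'                          n = 3)
#' length(prods)
#' @export
simulateMeiosis <- function(map, config, n) {
    if (!inherits(config, "ModelConfig"))
        stop("config must come from modelConfig()")
    if (!is.null(config$seed))
        set.seed(config$seed)
    if (n == 0L)
        return(list())
    modelNames <- names(config$weights)
    picks <- sample(modelNames, n, replace = TRUE, prob = config$weights)
    donor <- .otherParent(config$recipient)
    out <- vector("list", n)
    for (i in seq_len(n)) {
        dsb <- sampleDSB(map, config)
        prod <- switch(picks[i],
            sdsa = makeSdsaNCO(dsb, donor, map),
            two_ended_sdsa = makeTwoEndedSdsaNCO(dsb, map, config),
            two_end_engagement = makeTwoEndEngagement(dsb, map, config),
            dhj_resolution = makeDhjResolution(dsb, map, config),
            dhj_dissolution = makeDhjDissolutionNCO(dsb, map,
                                                    config$recipient),
            gap_repair = makeGapRepairNCO(dsb, map, config$recipient))
        prod@truth$eventId <- sprintf("ev%05d", i)
        out[[i]] <- prod
    }
    out
}

#' hDNA intervals of a duplex
#'
#' Maximal intervals where the two strands carry different parental origins.
#'
#' @param duplex A \linkS4class{RecombinantDuplex}.
#' @return \code{data.frame} with columns \code{start}, \code{end}
#'   (half-open).
#' @export
hdnaIntervals <- function(duplex) {
    .hdnaIntervals(duplex@top, duplex@bottom)
}
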