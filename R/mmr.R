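#' Short-patch mismatch repair parameters
#'
#' The short-patch pathway is modeled on nucleotide excision repair: each
#' repair event excises a patch extending 22-24 nt to the 5' side and 5-6 nt
#' to the 3' side of the lesion on the excised strand (window arms are drawn
#' uniformly from those ranges per event), and resynthesizes it from the
#' intact template strand.  Mismatches within one patch are therefore
#' repaired in the same direction (co-repaired), while mismatches farther
#' apart than one patch are repaired independently.
#'
#' @param repairProb probability \code{r} that an unrepaired mismatch
#'   triggers an excision event (default 0.82, the overall per-marker repair
#'   frequency observed in canonical-MMR mutants).
#' @param strandBias probability that the top strand is the excised strand
#'   (default 0.5: unbiased, so conversion and restoration are equally
#'   likely at an isolated mismatch).
#' @param window5 integer candidate arm lengths 5' of the lesion (nt).
#' @param window3 integer candidate arm lengths 3' of the lesion (nt).
#' @return list of class \code{"ShortPatchParams"}.
#' @examples
#' shortPatchParams()
#' @export
shortPatchParams <- function(repairProb = 0.82, strandBias = 0.5,
                             window5 = 22:24, window3 = 5:6) {
    if (repairProb < 0 || repairProb > 1 || strandBias < 0 || strandBias > 1)
        stop("repairProb and strandBias must lie in [0, 1]")
    if (any(window5 < 1) || any(window3 < 1))
        stop("window arms must be positive")
    structure(list(repairProb = repairProb, strandBias = strandBias,
                   window5 = as.integer(window5),
                   window3 = as.integer(window3)),
              class = "ShortPatchParams")
}

#' Canonical (long-patch, nick-directed) mismatch repair
#'
#' Canonical MMR is stimulated by the nicks left after repair synthesis and
#' excises long tracts, so all mismatches within one contiguous hDNA region
#' are repaired in the same direction.  For each maximal hDNA region carrying
#' at least one nick within the region or at its boundary, the nicked strand
#' (nearest nick decides; ties broken at random) is excised and rewritten
#' from the other strand across the whole region.  Regions without any nick
#' are left intact -- in particular, dissolution products, which lack nicks,
#' pass through unchanged.
#'
#' @param duplex A \linkS4class{RecombinantDuplex}.
#' @return The repaired \linkS4class{RecombinantDuplex}.
#' @export
applyCanonicalMMR <- function(duplex) {
    h <- .hdnaIntervals(duplex@top, duplex@bottom)
    if (nrow(h) == 0L)
        return(duplex)
    top <- duplex@top
    bottom <- duplex@bottom
    for (i in seq_len(nrow(h))) {
        s <- h$start[i]; e <- h$end[i]
        nt <- duplex@nicks$top
        nb <- duplex@nicks$bottom
        cand <- data.frame(
            pos = c(nt, nb),
            strand = c(rep("top", length(nt)), rep("bottom", length(nb))),
            stringsAsFactors = FALSE)
        cand <- cand[cand$pos >= s & cand$pos <= e, , drop = FALSE]
        if (nrow(cand) == 0L)
            next
        d <- pmin(abs(cand$pos - s), abs(cand$pos - e),
                  ifelse(cand$pos >= s & cand$pos <= e, 0, Inf))
        best <- which(d == min(d))
        if (length(best) > 1L)
            best <- sample(best, 1L)
        if (cand$strand[best] == "top")
            top <- .copyInterval(top, bottom, s, e)
        else
            bottom <- .copyInterval(bottom, top, s, e)
    }
    duplex@top <- .mergeSegments(top)
    duplex@bottom <- .mergeSegments(bottom)
    duplex
}

# Marker positions of `map` currently in hDNA (strand origins differ).
.hetMarkerPositions <- function(top, bottom, map) {
    pos <- markers(map)$position
    if (length(pos) == 0L)
        return(integer(0))
    pos[.parentAt(top, pos) != .parentAt(bottom, pos)]
}

#' Short-patch (NER-window) mismatch repair
#'
#' Mismatched markers are visited in random order.  Each still-unrepaired
#' mismatch triggers an excision event with probability \code{repairProb}:
#' the excised strand is chosen by \code{strandBias}, window arms are drawn,
#' and the patch is resynthesized from the template strand.  Window placement
#' is processive: the patch is positioned to also cover any still-unrepaired
#' mismatches within \code{w5 + w3} bp of the triggering lesion, which are
#' thereby co-repaired in the same direction.  Mismatches farther apart than
#' one patch are repaired in independent events, so their repair directions
#' are independent.
#'
#' @param duplex A \linkS4class{RecombinantDuplex}.
#' @param map A \linkS4class{MarkerMap}; mismatches arise at its markers.
#' @param params A \code{\link{shortPatchParams}}.
#' @return The repaired \linkS4class{RecombinantDuplex}.
#' @export
applyShortPatchMMR <- function(duplex, map, params = shortPatchParams()) {
    top <- duplex@top
    bottom <- duplex@bottom
    mk <- markers(map)
    het <- .hetMarkerPositions(top, bottom, map)
    if (length(het) == 0L)
        return(duplex)
    for (m in het[sample.int(length(het))]) {
        # Skip sites already co-repaired by an earlier patch.
        if (.parentAt(top, m) == .parentAt(bottom, m))
            next
        if (stats::runif(1) > params$repairProb)
            next
        exciseTop <- stats::runif(1) < params$strandBias
        w5 <- sample(params$window5, 1L)
        w3 <- sample(params$window3, 1L)
        reach <- w5 + w3
        cur <- .hetMarkerPositions(top, bottom, map)
        targets <- cur[abs(cur - m) <= reach]
        foot <- mk$footprint[match(max(targets), mk$position)]
        s <- min(targets)
        e <- max(targets) + foot
        if (exciseTop)
            top <- .copyInterval(top, bottom, s, e)
        else
            bottom <- .copyInterval(bottom, top, s, e)
    }
    duplex@top <- .mergeSegments(top)
    duplex@bottom <- .mergeSegments(bottom)
    duplex
}

#' Simulate co-repair of a marker pair under short-patch MMR
#'
#' Monte Carlo harness for the co-repair statistics: builds \code{n}
#' independent two-marker heteroduplexes with the markers \code{distance} bp
#' apart, applies short-patch repair to each, scores the two markers against
#' the recipient background (heteroduplex = unrepaired; donor homoduplex =
#' converted; recipient homoduplex = restored), and classifies the pair.
#'
#' @param n number of simulated pairs.
#' @param distance marker distance in bp.
#' @param params A \code{\link{shortPatchParams}}.
#' @return named integer vector with counts \code{co_repaired},
#'   \code{not_co_repaired}, \code{excluded}.
#' @examples
#' set.seed(1)
#' simulateCoRepairPairs(200, distance = 10,
#'                       params = shortPatchParams(repairProb = 1))
#' @export
simulateCoRepairPairs <- function(n, distance,
                                  params = shortPatchParams()) {
    pos <- c(0L, as.integer(distance))
    mk <- data.frame(position = pos, kind = "snp", footprint = 1L,
                     allele_p1 = "A", allele_p2 = "G",
                     is_selection_site = FALSE, stringsAsFactors = FALSE)
    map <- markerMap(mk, locusBounds = c(-100, distance + 100))
    base <- .newDuplex(map, "P1")
    counts <- c(co_repaired = 0L, not_co_repaired = 0L, excluded = 0L)
    for (i in seq_len(n)) {
        d <- base
        d$top <- .rewriteInterval(d$top, -50, distance + 50, "P2")
        dup <- .duplex(d, numeric(0), numeric(0), list(label = NULL))
        rep <- applyShortPatchMMR(dup, map, params)
        outc <- vapply(pos, function(p) {
            tp <- .parentAt(rep@top, p); bp <- .parentAt(rep@bottom, p)
            if (tp != bp) "unrepaired"
            else if (tp == "P1") "restored" else "converted"
        }, character(1))
        cls <- coRepairPairs(outc, pos)$class
        counts[cls] <- counts[cls] + 1L
    }
    counts
}

#' Apply a mismatch-repair genotype
#'
#' \code{wild_type}: canonical nick-directed MMR first, then short-patch
#' repair of any leftovers.  \code{Msh6} (canonical MMR lost): short-patch
#' only.  \code{Xpc_Msh6} (both pathways lost): no repair, up to an optional
#' residual per-mismatch repair probability (default 0).
#'
#' @param duplex A \linkS4class{RecombinantDuplex}.
#' @param genotype one of \code{"wild_type"}, \code{"Msh6"},
#'   \code{"Xpc_Msh6"}.
#' @param map A \linkS4class{MarkerMap}.
#' @param params A \code{\link{shortPatchParams}}.
#' @param residualProb residual repair probability under \code{Xpc_Msh6}.
#' @return The repaired \linkS4class{RecombinantDuplex}.
#' @export
applyGenotype <- function(duplex, genotype = c("Xpc_Msh6", "Msh6",
                                               "wild_type"),
                          map, params = shortPatchParams(),
                          residualProb = 0) {
    genotype <- match.arg(genotype)
    switch(genotype,
        wild_type = applyShortPatchMMR(applyCanonicalMMR(duplex), map,
                                       params),
        Msh6 = applyShortPatchMMR(duplex, map, params),
        Xpc_Msh6 = {
            if (residualProb > 0) {
                p <- params
                p$repairProb <- residualProb
                applyShortPatchMMR(duplex, map, p)
            } else duplex
        })
}
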