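#' Per-marker duplex states
#'
#' Derives the duplex state at each observed marker from the two strand
#' calls: heteroduplex when the calls differ, otherwise homoduplex for the
#' shared parent.
#'
#' @param obs An \linkS4class{ObservedRecombinant}.
#' @return \code{data.frame} with columns \code{position}, \code{top},
#'   \code{bottom}, \code{state} in
#'   \code{c("homoduplex_P1", "homoduplex_P2", "heteroduplex")}.
#' @export
callMarkerStates <- function(obs) {
    calls <- markerCalls(obs)
    state <- ifelse(calls$top != calls$bottom, "heteroduplex",
                    paste0("homoduplex_", calls$top))
    cbind(calls, state = state, stringsAsFactors = FALSE)
}

.stateParent <- function(state) sub("homoduplex_", "", state)

#' Crossover / noncrossover classification from flanking phase
#'
#' A recombinant is a crossover when the two ends of the locus carry
#' different homoduplex parental phase, as read from the outermost markers.
#' Both outermost markers must be homoduplex (the flanks must resolve);
#' otherwise classification fails with an error.
#'
#' @param states marker-state table from \code{\link{callMarkerStates}}.
#' @return \code{"CO"} or \code{"NCO"}.
#' @export
classifyCrossover <- function(states) {
    if (nrow(states) < 2L)
        stop("need at least two markers to classify a recombinant")
    ends <- states$state[c(1L, nrow(states))]
    if (any(ends == "heteroduplex"))
        stop("outermost marker is heteroduplex; flanking phase unresolved")
    if (.stateParent(ends[1L]) != .stateParent(ends[2L])) "CO" else "NCO"
}

# Internal tract assembly.  Returns a list of TractCall lists.
.buildTract <- function(states, idx, map, bgLeft, bgRight) {
    pos <- states$position
    mk <- markers(map)
    b <- c(min(idx), max(idx))
    included <- pos[idx]
    leftExcl <- if (b[1] > 1L) pos[b[1] - 1L] else NA_real_
    rightExcl <- if (b[2] < length(pos)) pos[b[2] + 1L] else NA_real_
    footLast <- mk$footprint[match(included[length(included)], mk$position)]
    footLast <- ifelse(is.na(footLast), 1L, footLast)
    spanMin <- if (length(included) == 1L) footLast
               else max(included) - min(included)
    lo <- if (is.na(leftExcl)) locusBounds(map)[1] else leftExcl
    hi <- if (is.na(rightExcl)) locusBounds(map)[2] else rightExcl
    hetIdx <- idx[states$state[idx] == "heteroduplex"]
    structure(list(
        markerIdx = idx,
        positions = included,
        states = states$state[idx],
        hetPositions = pos[hetIdx],
        hetTopCall = states$top[hetIdx],
        spanMin = spanMin,
        spanMax = hi - lo,
        leftExcl = lo,
        rightExcl = hi,
        displayStart = (lo + min(included)) / 2,
        displayEnd = (max(included) + hi) / 2,
        backgroundLeft = bgLeft,
        backgroundRight = bgRight), class = "TractCall")
}

#' Reconstruct hDNA / conversion tracts from marker states
#'
#' Tracts are maximal runs of non-background markers (heteroduplex, or
#' homoduplex for the non-background parent, i.e. converted) bounded by
#' background homoduplex markers.  For noncrossovers the background is the
#' shared parental phase of the two locus ends; runs separated by at most
#' \code{maxGapMarkers} interior background markers are merged into one
#' tract, so that restorations flanked by tract markers remain inside the
#' tract (restorations at tract edges are invisible, as in the real assay).
#' For crossovers the single tract spans from the first marker inconsistent
#' with the left flank to the last marker inconsistent with the right flank.
#'
#' Each tract records a minimum span (outermost included markers; the marker
#' footprint for single-marker tracts), a maximum span (nearest excluded
#' flanking markers, or the locus bounds at the map edge), and display
#' bounds at the halfway points between the last included and first excluded
#' markers.
#'
#' @param states marker-state table from \code{\link{callMarkerStates}}.
#' @param map A \linkS4class{MarkerMap}.
#' @param maxGapMarkers merge non-background runs separated by at most this
#'   many background markers (noncrossovers only).
#' @return list of \code{"TractCall"} objects (possibly empty).
#' @export
findHdnaTracts <- function(states, map, maxGapMarkers = 1L) {
    n <- nrow(states)
    if (n == 0L)
        return(list())
    st <- states$state
    hom <- st != "heteroduplex"
    if (!any(hom))
        stop("no homoduplex markers; cannot determine background phase")
    bl <- .stateParent(st[which(hom)[1L]])
    br <- .stateParent(st[rev(which(hom))[1L]])
    if (bl == br) {
        nonbg <- st != paste0("homoduplex_", bl)
        if (!any(nonbg))
            return(list())
        idx <- which(nonbg)
        # Merge runs separated by <= maxGapMarkers background markers.
        grp <- cumsum(c(1L, diff(idx) > maxGapMarkers + 1L))
        unname(lapply(split(idx, grp), function(run) {
            full <- seq(min(run), max(run))
            .buildTract(states, full, map, bl, br)
        }))
    } else {
        L0 <- which(st != paste0("homoduplex_", bl))[1L]
        R0 <- rev(which(st != paste0("homoduplex_", br)))[1L]
        if (is.na(L0) || is.na(R0) || L0 > R0)
            return(list())
        list(.buildTract(states, seq(L0, R0), map, bl, br))
    }
}

#' Per-marker repair outcomes within a tract
#'
#' Heteroduplex markers are unrepaired; homoduplex markers for the
#' non-background parent are converted; homoduplex markers matching the
#' background that lie inside the tract are restored.  When the two flanks
#' disagree (crossover tracts), each marker is scored against the flank of
#' its nearer tract edge.
#'
#' @param tract a \code{"TractCall"} from \code{\link{findHdnaTracts}}.
#' @return character vector of \code{c("converted", "restored",
#'   "unrepaired")}, one per tract marker.
#' @export
scoreMarkerOutcomes <- function(tract) {
    k <- length(tract$states)
    bg <- if (tract$backgroundLeft == tract$backgroundRight)
        rep(tract$backgroundLeft, k)
    else ifelse(seq_len(k) - 1 <= k - seq_len(k),
                tract$backgroundLeft, tract$backgroundRight)
    out <- character(k)
    for (i in seq_len(k)) {
        s <- tract$states[i]
        out[i] <- if (s == "heteroduplex") "unrepaired"
                  else if (.stateParent(s) == bg[i]) "restored"
                  else "converted"
    }
    out
}

#' cis / trans classification of a tract's hDNA
#'
#' In a cis tract all heteroduplex markers carry the donor allele on the same
#' strand; in a trans tract two adjacent maximal runs carry it on opposite
#' strands (the signature of both break ends having been engaged and
#' extended).  Classification uses strand-phase switches only -- never an
#' assumed break position.  Tracts with fewer than two heteroduplex markers
#' are undetermined and are excluded from trans/cis tallies.
#'
#' @param tract a \code{"TractCall"} from \code{\link{findHdnaTracts}}.
#' @return \code{"cis"}, \code{"trans"} or \code{"undetermined"}.
#' @export
classifyCisTrans <- function(tract) {
    phase <- tract$hetTopCall
    if (length(phase) < 2L)
        return("undetermined")
    if (length(rle(phase)$lengths) >= 2L) "trans" else "cis"
}

#' Is a tract patchy?
#'
#' A tract is patchy when it mixes repaired (converted or restored) markers
#' with unrepaired heteroduplex markers, or converted with restored markers
#' -- the signature of independent short-patch repair events within one
#' tract.
#'
#' @param outcomes character vector from \code{\link{scoreMarkerOutcomes}}.
#' @return logical scalar (\code{FALSE} for tracts with fewer than two
#'   markers).
#' @export
isPatchy <- function(outcomes) {
    if (length(outcomes) < 2L)
        return(FALSE)
    rep_ <- outcomes %in% c("converted", "restored")
    (any(rep_) && any(outcomes == "unrepaired")) ||
        (any(outcomes == "converted") && any(outcomes == "restored"))
}

#' Co-repair classification of adjacent marker pairs
#'
#' Each pair of adjacent markers in a tract is co-repaired when both are
#' converted or both restored; not co-repaired when one is converted and one
#' restored, or one repaired and one unrepaired; pairs in which both are
#' unrepaired are not counted (excluded).
#'
#' @param outcomes character vector from \code{\link{scoreMarkerOutcomes}}.
#' @param positions marker positions (same length as \code{outcomes}).
#' @return \code{data.frame} with columns \code{position1}, \code{position2},
#'   \code{distance}, \code{class} in
#'   \code{c("co_repaired", "not_co_repaired", "excluded")}.
#' @export
coRepairPairs <- function(outcomes, positions) {
    k <- length(outcomes)
    if (k < 2L)
        return(data.frame(position1 = numeric(0), position2 = numeric(0),
                          distance = numeric(0), class = character(0)))
    o1 <- outcomes[-k]; o2 <- outcomes[-1L]
    cls <- ifelse(o1 == "unrepaired" & o2 == "unrepaired", "excluded",
           ifelse(o1 == o2 & o1 != "unrepaired", "co_repaired",
                  "not_co_repaired"))
    data.frame(position1 = positions[-k], position2 = positions[-1L],
               distance = diff(positions), class = cls,
               stringsAsFactors = FALSE)
}

#' Bin co-repair pairs by marker distance
#'
#' Counts co-repaired and not-co-repaired pairs per distance bin; excluded
#' (both-unrepaired) pairs are dropped.  The default single edge at 21 bp
#' separates pairs within short-patch co-excision range from distant pairs;
#' a distance equal to an edge falls in the upper bin.
#'
#' @param pairs \code{data.frame} from \code{\link{coRepairPairs}} (rows from
#'   several tracts may be concatenated).
#' @param edges increasing numeric bin edges.
#' @return \code{data.frame} with columns \code{bin}, \code{co_repaired},
#'   \code{not_co_repaired}, \code{total}, \code{pct_co_repaired}.
#' @examples
#' pairs <- data.frame(distance = c(10, 10, 300),
#'                     class = c("co_repaired", "co_repaired",
#'                               "not_co_repaired"))
#' binPairsByDistance(pairs)
#' @export
binPairsByDistance <- function(pairs, edges = 21) {
    breaks <- c(-Inf, edges, Inf)
    labs <- character(length(breaks) - 1L)
    labs[1L] <- paste0("<", edges[1L])
    if (length(edges) > 1L)
        labs[2:(length(labs) - 1L)] <-
            paste0(edges[-length(edges)], "-", edges[-1L])
    labs[length(labs)] <- paste0(">=", edges[length(edges)])
    counted <- pairs[pairs$class != "excluded", , drop = FALSE]
    bin <- cut(counted$distance, breaks = breaks, right = FALSE,
               labels = labs)
    co <- tapply(counted$class == "co_repaired", bin, sum, default = 0L)
    nc <- tapply(counted$class == "not_co_repaired", bin, sum, default = 0L)
    out <- data.frame(bin = labs, co_repaired = as.integer(co),
                      not_co_repaired = as.integer(nc))
    out$total <- out$co_repaired + out$not_co_repaired
    out$pct_co_repaired <- ifelse(out$total > 0,
                                  100 * out$co_repaired / out$total, NA_real_)
    rownames(out) <- NULL
    out
}

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

.mismatchTypes <- function(a1, a2) {
    # The two possible base-base mismatches for a SNP with alleles a1/a2,
    # depending on which allele sat on which strand of the heteroduplex.
    t1 <- paste(sort(c(a1, .COMPLEMENT[[a2]])), collapse = ":")
    t2 <- paste(sort(c(a2, .COMPLEMENT[[a1]])), collapse = ":")
    c(t1, t2)
}

#' Mismatch-type spectrum of tract markers
#'
#' Tallies repaired (converted or restored) versus unrepaired tract markers
#' by mismatch type.  For SNPs, which of the two possible mismatches sat in
#' the heteroduplex of the intermediate depends on which strand carried the
#' donor allele; when that phase is not inferable both possible types are
#' reported with weight 1/2 each.  For heteroduplex markers in trans tracts
#' the phase is known and the observed pairing is reported with weight 1.
#' Indel markers are reported as loops of their footprint size.
#'
#' @param markerTable \code{data.frame} with columns \code{position},
#'   \code{outcome}, \code{top}, \code{bottom} and \code{trans} (logical:
#'   marker belongs to a trans tract), e.g. the \code{markerTable} component
#'   of \code{\link{analyzeRecombinant}} output (rows from several events may
#'   be concatenated).
#' @param map A \linkS4class{MarkerMap}.
#' @return \code{data.frame} with columns \code{type}, \code{repaired},
#'   \code{unrepaired} (weighted counts).
#' @export
mismatchSpectrum <- function(markerTable, map) {
    mk <- markers(map)
    rows <- list()
    for (i in seq_len(nrow(markerTable))) {
        r <- markerTable[i, ]
        j <- match(r$position, mk$position)
        if (is.na(j))
            next
        repaired <- r$outcome %in% c("converted", "restored")
        if (mk$kind[j] == "indel") {
            types <- paste0("loop", mk$footprint[j])
            w <- 1
        } else if (!repaired && isTRUE(r$trans)) {
            topBase <- if (r$top == "P1") mk$allele_p1[j] else mk$allele_p2[j]
            botBase <- if (r$bottom == "P1") mk$allele_p1[j]
                       else mk$allele_p2[j]
            types <- paste(sort(c(topBase, .COMPLEMENT[[botBase]])),
                           collapse = ":")
            w <- 1
        } else {
            types <- .mismatchTypes(mk$allele_p1[j], mk$allele_p2[j])
            w <- 0.5
        }
        for (tp in types)
            rows[[length(rows) + 1L]] <-
                data.frame(type = tp,
                           repaired = if (repaired) w else 0,
                           unrepaired = if (repaired) 0 else w,
                           stringsAsFactors = FALSE)
    }
    if (length(rows) == 0L)
        return(data.frame(type = character(0), repaired = numeric(0),
                          unrepaired = numeric(0)))
    tab <- do.call(rbind, rows)
    out <- aggregate(cbind(repaired, unrepaired) ~ type, data = tab, FUN = sum)
    out[order(out$type), , drop = FALSE]
}

#' Full per-recombinant tract analysis
#'
#' Runs the whole analysis layer on one observed recombinant: marker states,
#' crossover classification, tract reconstruction, per-marker outcomes,
#' cis/trans and patchiness labels, adjacent-pair co-repair classes, and
#' tract-length bounds and estimates (trans tracts are split into their two
#' halves, each treated as an independent tract).
#'
#' @param obs An \linkS4class{ObservedRecombinant}.
#' @param map A \linkS4class{MarkerMap}.
#' @param p per-base tract-extension probability for length estimation.
#' @param maxGapMarkers passed to \code{\link{findHdnaTracts}}.
#' @return list with components \code{eventId}, \code{label} ("CO"/"NCO", or
#'   \code{NA} if the flanks do not resolve), \code{tracts} (annotated
#'   \code{TractCall} list, each gaining \code{outcomes}, \code{cisTrans},
#'   \code{patchy}), \code{markerTable}, \code{pairs}, and \code{estimates}
#'   (one row per tract or trans half: \code{a}, \code{b}, \code{estimate}).
#' @examples
#' set.seed(7)
#' map <- rosyMarkerMap()
#' prod <- simulateMeiosis(map, modelConfig(weights = c(sdsa = 1)), 1)[[1]]
#' analyzeRecombinant(observeRecombinant(prod, map), map)$label
#' @export
analyzeRecombinant <- function(obs, map, p = 0.99717, maxGapMarkers = 1L) {
    states <- callMarkerStates(obs)
    label <- tryCatch(classifyCrossover(states), error = function(e) NA)
    tracts <- findHdnaTracts(states, map, maxGapMarkers = maxGapMarkers)
    markerRows <- list()
    pairRows <- list()
    estRows <- list()
    for (ti in seq_along(tracts)) {
        tr <- tracts[[ti]]
        tr$outcomes <- scoreMarkerOutcomes(tr)
        tr$cisTrans <- classifyCisTrans(tr)
        tr$patchy <- isPatchy(tr$outcomes)
        tracts[[ti]] <- tr
        sel <- tr$markerIdx
        markerRows[[ti]] <- data.frame(
            eventId = obs@eventId, tract = ti,
            position = tr$positions, state = tr$states,
            outcome = tr$outcomes,
            top = states$top[sel], bottom = states$bottom[sel],
            trans = tr$cisTrans == "trans", stringsAsFactors = FALSE)
        pr <- coRepairPairs(tr$outcomes, tr$positions)
        if (nrow(pr) > 0L) {
            pr$eventId <- obs@eventId
            pr$tract <- ti
            pairRows[[length(pairRows) + 1L]] <- pr
        }
        bounds <- if (tr$cisTrans == "trans")
            splitTransTract(tr, map)
        else
            data.frame(a = tr$spanMin, b = tr$spanMax)
        bounds$estimate <- estimateTractLength(bounds$a, bounds$b, p = p)
        bounds$eventId <- obs@eventId
        bounds$tract <- ti
        bounds$half <- seq_len(nrow(bounds))
        estRows[[length(estRows) + 1L]] <- bounds
    }
    emptyPairs <- data.frame(position1 = numeric(0), position2 = numeric(0),
                             distance = numeric(0), class = character(0),
                             eventId = character(0), tract = integer(0))
    list(eventId = obs@eventId, label = label, tracts = tracts,
         markerTable = do.call(rbind, markerRows),
         pairs = if (length(pairRows)) do.call(rbind, pairRows)
                 else emptyPairs,
         estimates = if (length(estRows)) do.call(rbind, estRows)
                     else data.frame(a = numeric(0), b = numeric(0),
                                     estimate = numeric(0)))
}
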