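#' Purine-selection survival of a recombinant
#'
#' Dietary purine kills larvae without a functional copy of the gene.  After
#' replication, each strand of the recovered duplex founds its own cell
#' lineage, and the gene product acts non-cell-autonomously, so a mosaic
#' animal survives whenever at least one single strand carries the wild-type
#' allele at \emph{both} selection sites.  The wild-type allele at each site
#' is the one carried by the parent that is not mutant there (the two
#' mutations lie on opposite parents).
#'
#' @param duplex A \linkS4class{RecombinantDuplex}.
#' @param map A \linkS4class{MarkerMap} with its two selection sites.
#' @return logical scalar.
#' @examples
#' set.seed(2)
#' map <- rosyMarkerMap()
#' cfg <- modelConfig(weights = c(two_end_engagement = 1))
#' prods <- simulateMeiosis(map, cfg, 5)
#' vapply(prods, survivesPurine, logical(1), map = map)
#' @export
survivesPurine <- function(duplex, map) {
    ss <- selectionSites(map)
    if (nrow(ss) != 2L)
        stop("map has no selection sites; selection is undefined")
    wt <- .otherParent(ss$mutant_parent)
    for (strand in c("top", "bottom")) {
        segs <- slot(duplex, strand)
        if (all(.parentAt(segs, ss$position) == wt))
            return(TRUE)
    }
    FALSE
}

#' Observe a recombinant at the sequencing level
#'
#' Per-strand parental calls at each marker of the map, excluding any markers
#' listed in the coverage mask.  Sequencing is modeled error-free: the calls
#' equal the duplex's strand origins at every reported marker.
#'
#' @param duplex A \linkS4class{RecombinantDuplex}.
#' @param map A \linkS4class{MarkerMap}.
#' @param coverageMask integer vector of marker positions to drop (default
#'   none).
#' @return An \linkS4class{ObservedRecombinant}; its \code{survived} flag is
#'   filled in from \code{\link{survivesPurine}}.
#' @export
observeRecombinant <- function(duplex, map, coverageMask = integer(0)) {
    pos <- markers(map)$position
    pos <- pos[!pos %in% coverageMask]
    calls <- data.frame(position = pos,
                        top = .parentAt(duplex@top, pos),
                        bottom = .parentAt(duplex@bottom, pos),
                        stringsAsFactors = FALSE)
    surv <- if (nrow(selectionSites(map)) == 2L)
        survivesPurine(duplex, map) else NA
    new("ObservedRecombinant", calls = calls,
        eventId = duplex@truth$eventId %||% "event",
        survived = surv)
}

#' Read and write observed-recombinant tables
#'
#' TSV with header and columns \code{event_id}, \code{position}, \code{top},
#' \code{bottom}; one file may hold many events.  Strand calls are parent
#' labels "P1"/"P2".
#'
#' @param path file path.
#' @return \code{readObservedTable} returns a list of
#'   \linkS4class{ObservedRecombinant}; \code{writeObservedTable} invisibly
#'   returns \code{path}.
#' @export
readObservedTable <- function(path) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("event_id", "position", "top", "bottom")
    miss <- setdiff(need, names(tab))
    if (length(miss) > 0L)
        stop("observed table is missing columns: ",
             paste(miss, collapse = ", "))
    lapply(split(tab, tab$event_id), function(ev) {
        ev <- ev[order(ev$position), , drop = FALSE]
        surv <- if (is.null(ev$survived)) NA else as.logical(ev$survived[1L])
        new("ObservedRecombinant",
            calls = data.frame(position = ev$position, top = ev$top,
                               bottom = ev$bottom, stringsAsFactors = FALSE),
            eventId = as.character(ev$event_id[1L]),
            survived = surv)
    })
}

#' @param observations list of \linkS4class{ObservedRecombinant}.
#' @rdname readObservedTable
#' @export
writeObservedTable <- function(observations, path) {
    rows <- lapply(observations, function(obs) {
        calls <- markerCalls(obs)
        if (nrow(calls) == 0L)
            return(NULL)
        data.frame(event_id = obs@eventId, position = calls$position,
                   top = calls$top, bottom = calls$bottom,
                   survived = obs@survived, stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
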