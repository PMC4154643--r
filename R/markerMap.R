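#' Construct a MarkerMap
#'
#' @param markers \code{data.frame} with columns \code{position}, \code{kind},
#'   \code{footprint}, \code{allele_p1}, \code{allele_p2} and (optionally)
#'   \code{is_selection_site}; may have zero rows.
#' @param selectionSites \code{data.frame} with columns \code{position} and
#'   \code{mutant_parent}, exactly two rows.  If \code{NULL}, the rows of
#'   \code{markers} flagged \code{is_selection_site} are used, with the
#'   convention that the left site is mutant on \code{"P2"} and the right on
#'   \code{"P1"} (the rosy arrangement: the recipient parent carries the
#'   downstream mutation).
#' @param locusBounds half-open interval \code{[L, R)}; defaults to a tight
#'   interval around all markers and selection sites.
#' @return A \linkS4class{MarkerMap}.
#' @examples
#' m <- data.frame(position = c(-468L, 0L, 100L, 3312L), kind = "snp",
#'                 footprint = 1L, allele_p1 = c("G", "A", "C", "T"),
#'                 allele_p2 = c("A", "G", "T", "C"),
#'                 is_selection_site = c(TRUE, FALSE, FALSE, TRUE))
#' markerMap(m)
#' @export
markerMap <- function(markers, selectionSites = NULL, locusBounds = NULL) {
    if (is.null(markers$is_selection_site))
        markers$is_selection_site <- FALSE
    markers$position <- as.integer(markers$position)
    markers$footprint <- as.integer(markers$footprint)
    markers <- markers[order(markers$position), , drop = FALSE]
    rownames(markers) <- NULL
    if (is.null(selectionSites)) {
        sel <- markers$position[markers$is_selection_site]
        if (!length(sel) %in% c(0L, 2L))
            stop("need exactly two selection sites (flag is_selection_site)")
        selectionSites <- data.frame(
            position = sort(sel),
            mutant_parent = if (length(sel)) c("P2", "P1") else character(0),
            stringsAsFactors = FALSE)
    }
    selectionSites$position <- as.integer(selectionSites$position)
    if (is.null(locusBounds)) {
        allPos <- c(markers$position, selectionSites$position)
        if (length(allPos) == 0L)
            stop("locusBounds must be given for a map with no markers")
        lo <- min(allPos)
        hi <- max(c(markers$position + markers$footprint,
                    selectionSites$position + 1L))
        locusBounds <- c(lo - 1L, hi + 1L)
    }
    new("MarkerMap", markers = markers, selectionSites = selectionSites,
        locusBounds = as.numeric(locusBounds))
}

#' Read and write marker-map tables
#'
#' The on-disk format is a UTF-8 TSV with a header row and columns
#' \code{position}, \code{kind}, \code{footprint}, \code{allele_p1},
#' \code{allele_p2}, \code{is_selection_site}, plus optional columns
#' \code{mutant_parent} (for selection-site rows), \code{bounds_lo} and
#' \code{bounds_hi} (locus bounds, repeated on every row).  Positions are
#' integer base pairs relative to the locus anchor and may be negative.
#'
#' @param path file path of the TSV.
#' @return \code{readMarkerTable} returns a \linkS4class{MarkerMap};
#'   \code{writeMarkerTable} invisibly returns \code{path}.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeMarkerTable(rosyMarkerMap(), tf)
#' identical(markers(readMarkerTable(tf)), markers(rosyMarkerMap()))
#' @export
readMarkerTable <- function(path) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("position", "kind", "footprint", "allele_p1", "allele_p2")
    miss <- setdiff(need, names(tab))
    if (length(miss) > 0L)
        stop("marker table is missing columns: ", paste(miss, collapse = ", "))
    if (anyDuplicated(tab$position))
        stop("marker table has duplicate positions")
    if (is.unsorted(tab$position, strictly = TRUE))
        stop("marker table positions must be strictly increasing")
    if (is.null(tab$is_selection_site))
        tab$is_selection_site <- FALSE
    sel <- NULL
    if (!is.null(tab$mutant_parent)) {
        ss <- tab[tab$is_selection_site, , drop = FALSE]
        sel <- data.frame(position = ss$position,
                          mutant_parent = ss$mutant_parent,
                          stringsAsFactors = FALSE)
    }
    bounds <- NULL
    if (all(c("bounds_lo", "bounds_hi") %in% names(tab)) && nrow(tab) > 0L)
        bounds <- c(tab$bounds_lo[1L], tab$bounds_hi[1L])
    cols <- c(need, "is_selection_site")
    markerMap(tab[, cols], selectionSites = sel, locusBounds = bounds)
}

#' @param map A \linkS4class{MarkerMap}.
#' @rdname readMarkerTable
#' @export
writeMarkerTable <- function(map, path) {
    tab <- markers(map)
    ss <- selectionSites(map)
    tab$mutant_parent <- ss$mutant_parent[match(tab$position, ss$position)]
    tab$mutant_parent[is.na(tab$mutant_parent)] <- ""
    tab$bounds_lo <- locusBounds(map)[1]
    tab$bounds_hi <- locusBounds(map)[2]
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Distances between consecutive markers
#'
#' One row per consecutive marker pair, with the distance between their
#' \code{position} fields.  Pairs closer than the short-patch excision window
#' (under 21 bp in the original assay) are candidates for co-excision in a
#' single repair event.
#'
#' @param map A \linkS4class{MarkerMap}.
#' @return \code{data.frame} with columns \code{position1}, \code{position2},
#'   \code{distance}; zero rows when the map has fewer than two markers.
#' @examples
#' head(adjacentDistances(rosyMarkerMap()))
#' @export
adjacentDistances <- function(map) {
    pos <- markers(map)$position
    if (length(pos) < 2L)
        return(data.frame(position1 = integer(0), position2 = integer(0),
                          distance = integer(0)))
    data.frame(position1 = pos[-length(pos)], position2 = pos[-1L],
               distance = diff(pos))
}

#' Packaged synthetic marker map of the rosy locus
#'
#' A deterministic fixture map emulating the marker spacing of the assayed
#' locus: two selection sites at -468 and +3312 (coordinates relative to an
#' EcoRI-site anchor; the left site is mutant on P2, the right on P1), a
#' handful of marker pairs closer than 21 bp (within short-patch co-excision
#' range), mostly SNPs with two small indels, and two distal flank markers
#' several kilobases outside the gene region that report the parental phase of
#' the chromosome ends (standing in for the recessive flanking markers of the
#' genetic assay).  The published supplementary marker list is not
#' redistributed; positions here are synthetic but match the described
#' spacing statistics.
#'
#' @param flankOffset distance (bp) of the two phase-reporting flank markers
#'   beyond the gene-region markers.
#' @return A \linkS4class{MarkerMap}.
#' @examples
#' rosyMarkerMap()
#' @export
rosyMarkerMap <- function(flankOffset = 5000L) {
    pos <- c(-950L, -800L, -720L, -706L, -600L, -468L, -455L, -310L, -302L,
             -150L, 20L, 180L, 195L, 420L, 700L, 710L, 980L, 1300L, 1620L,
             1900L, 2150L, 2160L, 2400L, 2700L, 3000L, 3150L, 3312L, 3460L,
             3700L, 4100L)
    n <- length(pos)
    kind <- rep("snp", n)
    foot <- rep(1L, n)
    kind[pos %in% c(-600L, 2700L)] <- "indel"
    foot[pos == -600L] <- 2L
    foot[pos == 2700L] <- 4L
    base1 <- rep(c("A", "C", "G", "T"), length.out = n)
    base2 <- rep(c("G", "T", "A", "C"), length.out = n)
    a1 <- base1
    a2 <- base2
    a1[pos == -600L] <- "CAT"
    a2[pos == -600L] <- "C"
    a1[pos == 2700L] <- "G"
    a2[pos == 2700L] <- "GTTAA"
    sel <- pos %in% c(-468L, 3312L)
    gene <- data.frame(position = pos, kind = kind, footprint = foot,
                       allele_p1 = a1, allele_p2 = a2,
                       is_selection_site = sel, stringsAsFactors = FALSE)
    flank <- data.frame(
        position = c(min(pos) - flankOffset, max(pos) + flankOffset),
        kind = "snp", footprint = 1L,
        allele_p1 = c("T", "A"), allele_p2 = c("C", "G"),
        is_selection_site = FALSE, stringsAsFactors = FALSE)
    all <- rbind(flank[1L, ], gene, flank[2L, ])
    markerMap(all,
              locusBounds = c(min(all$position) - 200L,
                              max(all$position) + 200L))
}

#' Gene-region interval of a marker map
#'
#' The interval spanned by the non-flank markers (those within the selection
#' sites' neighbourhood) over which double-strand breaks are drawn by default.
#' Defined as the span of all markers excluding the outermost one on each
#' side, padded by \code{pad} bp, and clipped to the locus bounds.
#'
#' @param map A \linkS4class{MarkerMap}.
#' @param pad padding in bp on each side.
#' @return numeric length 2.
#' @export
geneRegion <- function(map, pad = 300L) {
    pos <- markers(map)$position
    if (length(pos) <= 2L)
        return(locusBounds(map))
    inner <- pos[-c(1L, length(pos))]
    lo <- max(locusBounds(map)[1], min(inner) - pad)
    hi <- min(locusBounds(map)[2], max(inner) + pad)
    c(lo, hi)
}
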