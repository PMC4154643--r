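#' @import methods
NULL

#' Accessor generics for hdnaTracts classes
#'
#' Small accessor generics used across the package: \code{markers} returns the
#' marker table of a \linkS4class{MarkerMap}, \code{selectionSites} its
#' selection-site table, \code{locusBounds} the half-open locus interval,
#' \code{strandSegments} the parental-origin segments of one strand of a
#' \linkS4class{RecombinantDuplex}, \code{nicks} its per-strand nick positions,
#' \code{truthInfo} its ground-truth metadata, and \code{markerCalls} the
#' per-marker strand calls of an \linkS4class{ObservedRecombinant}.
#'
#' @param x A \linkS4class{MarkerMap}, \linkS4class{RecombinantDuplex} or
#'   \linkS4class{ObservedRecombinant}, as appropriate.
#' @param strand For \code{strandSegments}, \code{"top"} or \code{"bottom"}.
#' @return A \code{data.frame} (\code{markers}, \code{selectionSites},
#'   \code{strandSegments}, \code{markerCalls}), a numeric vector of length 2
#'   (\code{locusBounds}), a named list of numeric vectors (\code{nicks}), or a
#'   list (\code{truthInfo}).
#' @name accessors
#' @aliases markers selectionSites locusBounds strandSegments nicks truthInfo
#'   markerCalls
NULL

#' @rdname accessors
#' @export
setGeneric("markers", function(x) standardGeneric("markers"))

#' @rdname accessors
#' @export
setGeneric("selectionSites", function(x) standardGeneric("selectionSites"))

#' @rdname accessors
#' @export
setGeneric("locusBounds", function(x) standardGeneric("locusBounds"))

#' @rdname accessors
#' @export
setGeneric("strandSegments", function(x, strand = c("top", "bottom"))
    standardGeneric("strandSegments"))

#' @rdname accessors
#' @export
setGeneric("nicks", function(x) standardGeneric("nicks"))

#' @rdname accessors
#' @export
setGeneric("truthInfo", function(x) standardGeneric("truthInfo"))

#' @rdname accessors
#' @export
setGeneric("markerCalls", function(x) standardGeneric("markerCalls"))
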