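#' @include AllGenerics.R segments.R
NULL

#' MarkerMap: polymorphic markers of an assayed locus
#'
#' Ordered polymorphic sites (SNPs and small indels) along a locus, in integer
#' base pairs relative to an anchor position (coordinates may be negative),
#' together with the two selection-site positions used to recover wild-type
#' recombinants.  Selection sites are themselves polymorphisms and also appear
#' as rows of the marker table, flagged by \code{is_selection_site}.
#'
#' @slot markers \code{data.frame} with columns \code{position} (integer bp,
#'   strictly increasing), \code{kind} (\code{"snp"} or \code{"indel"}),
#'   \code{footprint} (bp, 1 for SNPs, indel length otherwise),
#'   \code{allele_p1}, \code{allele_p2} (short nucleotide strings, distinct),
#'   and \code{is_selection_site} (logical).
#' @slot selectionSites \code{data.frame} with columns \code{position} and
#'   \code{mutant_parent} ("P1"/"P2"), one row per selection site; the
#'   wild-type allele at a site is carried by the other parent.
#' @slot locusBounds numeric length 2; half-open interval \code{[L, R)}
#'   containing all markers and selection sites.
#' @name MarkerMap-class
#' @aliases MarkerMap-class
#' @exportClass MarkerMap
setClass("MarkerMap",
    representation(markers = "data.frame",
                   selectionSites = "data.frame",
                   locusBounds = "numeric"))

setValidity("MarkerMap", function(object) {
    m <- object@markers
    need <- c("position", "kind", "footprint", "allele_p1", "allele_p2",
              "is_selection_site")
    if (!all(need %in% names(m)))
        return(paste("marker table must have columns:",
                     paste(need, collapse = ", ")))
    if (length(object@locusBounds) != 2 ||
        object@locusBounds[1] >= object@locusBounds[2])
        return("locusBounds must be an increasing length-2 numeric")
    if (nrow(m) > 0L) {
        if (is.unsorted(m$position, strictly = TRUE))
            return("marker positions must be strictly increasing")
        if (any(m$allele_p1 == m$allele_p2))
            return("allele_p1 and allele_p2 must differ at every marker")
        if (!all(m$kind %in% c("snp", "indel")))
            return("marker kind must be 'snp' or 'indel'")
        if (any((m$footprint == 1L) != (m$kind == "snp")))
            return("footprint must be 1 exactly for SNP markers")
        if (any(m$footprint < 1L))
            return("footprint must be >= 1")
        if (any(m$position < object@locusBounds[1]) ||
            any(m$position + m$footprint > object@locusBounds[2]))
            return("all markers must lie within locusBounds")
    }
    ss <- object@selectionSites
    if (!all(c("position", "mutant_parent") %in% names(ss)))
        return("selectionSites must have columns position, mutant_parent")
    if (!nrow(ss) %in% c(0L, 2L))
        return("selection requires exactly two selection sites (or none)")
    if (!all(ss$mutant_parent %in% .PARENTS))
        return("selection-site mutant_parent must be 'P1' or 'P2'")
    if (any(ss$position < object@locusBounds[1]) ||
        any(ss$position >= object@locusBounds[2]))
        return("selection sites must lie within locusBounds")
    TRUE
})

#' RecombinantDuplex: one recovered recombinant chromatid, strand by strand
#'
#' The product of a simulated meiotic double-strand-break repair event.  Each
#' strand of the duplex is a mosaic of parental-origin segments tiling the
#' locus bounds; nick positions record unligated junctions left by repair
#' synthesis.  Heteroduplex DNA (hDNA) is the set of positions where the two
#' strands carry different parental origins.
#'
#' @slot top,bottom \code{data.frame} of strand segments with columns
#'   \code{start}, \code{end}, \code{parent}; half-open intervals tiling the
#'   locus bounds.
#' @slot nicks named list with numeric components \code{top} and
#'   \code{bottom}: nick positions on each strand.
#' @slot truth list of ground-truth event metadata: at least \code{model},
#'   \code{label} ("CO"/"NCO"), and the generating \code{dsb} event.
#' @slot locusBounds numeric length 2, as in \linkS4class{MarkerMap}.
#' @name RecombinantDuplex-class
#' @aliases RecombinantDuplex-class
#' @exportClass RecombinantDuplex
setClass("RecombinantDuplex",
    representation(top = "data.frame", bottom = "data.frame",
                   nicks = "list", truth = "list", locusBounds = "numeric"))

setValidity("RecombinantDuplex", function(object) {
    for (strand in c("top", "bottom")) {
        ok <- .checkTiling(slot(object, strand), object@locusBounds)
        if (!isTRUE(ok))
            return(paste0(strand, " strand: ", ok))
    }
    if (!all(c("top", "bottom") %in% names(object@nicks)))
        return("nicks must be a list with components 'top' and 'bottom'")
    lab <- object@truth$label
    if (!is.null(lab)) {
        if (!lab %in% c("CO", "NCO"))
            return("truth$label must be 'CO' or 'NCO'")
        # The CO label must agree with the duplex phase at the locus ends,
        # whenever both ends are homoduplex.
        L <- object@locusBounds[1]
        R <- object@locusBounds[2] - 1
        tl <- .parentAt(object@top, L); bl <- .parentAt(object@bottom, L)
        tr <- .parentAt(object@top, R); br <- .parentAt(object@bottom, R)
        if (tl == bl && tr == br) {
            isCO <- tl != tr
            if (isCO != (lab == "CO"))
                return("truth$label disagrees with end-phase of the duplex")
        }
    }
    TRUE
})

#' ObservedRecombinant: sequencing-level view of a recombinant
#'
#' Per-strand parental allele calls at each (unmasked) marker of a
#' \linkS4class{MarkerMap}, as obtained from bulk plus clone sequencing of a
#' recovered recombinant.  Sequencing is modeled error-free; missing markers
#' arise only through an explicit coverage mask.
#'
#' @slot calls \code{data.frame} with columns \code{position}, \code{top},
#'   \code{bottom}; strand calls are parent labels "P1"/"P2".
#' @slot eventId character scalar.
#' @slot survived logical scalar: did the chromatid pass purine selection.
#' @name ObservedRecombinant-class
#' @aliases ObservedRecombinant-class
#' @exportClass ObservedRecombinant
setClass("ObservedRecombinant",
    representation(calls = "data.frame", eventId = "character",
                   survived = "logical"))

setValidity("ObservedRecombinant", function(object) {
    need <- c("position", "top", "bottom")
    if (!all(need %in% names(object@calls)))
        return("calls must have columns position, top, bottom")
    if (nrow(object@calls) > 0L) {
        if (is.unsorted(object@calls$position, strictly = TRUE))
            return("call positions must be strictly increasing")
        if (!all(c(object@calls$top, object@calls$bottom) %in% .PARENTS))
            return("strand calls must be 'P1' or 'P2'")
    }
    TRUE
})

#' @rdname accessors
#' @export
setMethod("markers", "MarkerMap", function(x) x@markers)

#' @rdname accessors
#' @export
setMethod("selectionSites", "MarkerMap", function(x) x@selectionSites)

#' @rdname accessors
#' @export
setMethod("locusBounds", "MarkerMap", function(x) x@locusBounds)

#' @rdname accessors
#' @export
setMethod("locusBounds", "RecombinantDuplex", function(x) x@locusBounds)

#' @rdname accessors
#' @export
setMethod("strandSegments", "RecombinantDuplex",
    function(x, strand = c("top", "bottom")) {
        strand <- match.arg(strand)
        slot(x, strand)
    })

#' @rdname accessors
#' @export
setMethod("nicks", "RecombinantDuplex", function(x) x@nicks)

#' @rdname accessors
#' @export
setMethod("truthInfo", "RecombinantDuplex", function(x) x@truth)

#' @rdname accessors
#' @export
setMethod("markerCalls", "ObservedRecombinant", function(x) x@calls)

setMethod("show", "MarkerMap", function(object) {
    m <- object@markers
    cat("MarkerMap with", nrow(m), "markers on [",
        object@locusBounds[1], ",", object@locusBounds[2], ")\n")
    cat("  kinds:", sum(m$kind == "snp"), "snp,",
        sum(m$kind == "indel"), "indel\n")
    ss <- object@selectionSites
    cat("  selection sites:",
        paste(sprintf("%d (mutant on %s)", ss$position, ss$mutant_parent),
              collapse = ", "), "\n")
})

setMethod("show", "RecombinantDuplex", function(object) {
    tr <- object@truth
    cat("RecombinantDuplex (", tr$model %||% "?", ", ",
        tr$label %||% "?", ")\n", sep = "")
    h <- .hdnaIntervals(object@top, object@bottom)
    cat("  hDNA intervals:", nrow(h),
        "| nicks: top", length(object@nicks$top),
        ", bottom", length(object@nicks$bottom), "\n")
})

setMethod("show", "ObservedRecombinant", function(object) {
    cat("ObservedRecombinant", object@eventId, "with",
        nrow(object@calls), "marker calls; survived =",
        object@survived, "\n")
})

`%||%` <- function(a, b) if (is.null(a)) b else a
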