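# Internal strand-segment machinery.
#
# A strand is a mosaic of parental-origin segments stored as a data.frame with
# columns start, end, parent ("P1"/"P2").  Intervals are half-open [start, end)
# in integer base pairs and must tile the locus bounds without gaps or
# overlaps.  All simulator and repair operations reduce to interval rewrites
# on these tables.

.PARENTS <- c("P1", "P2")

.otherParent <- function(parent) ifelse(parent == "P1", "P2", "P1")

.newStrand <- function(bounds, parent) {
    data.frame(start = bounds[1], end = bounds[2], parent = parent,
               stringsAsFactors = FALSE)
}

# Coalesce adjacent segments with the same parent; drop empty segments.
.mergeSegments <- function(segs) {
    segs <- segs[segs$end > segs$start, , drop = FALSE]
    segs <- segs[order(segs$start), , drop = FALSE]
    if (nrow(segs) <= 1L) {
        rownames(segs) <- NULL
        return(segs)
    }
    keep <- c(TRUE, segs$parent[-1L] != segs$parent[-nrow(segs)])
    grp <- cumsum(keep)
    out <- data.frame(
        start = tapply(segs$start, grp, min),
        end = tapply(segs$end, grp, max),
        parent = segs$parent[keep],
        stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
}

# Parental origin of a strand at each of the given positions.
.parentAt <- function(segs, pos) {
    idx <- findInterval(pos, segs$start)
    bad <- idx < 1L | pos >= segs$end[pmax(idx, 1L)]
    if (any(bad))
        stop("position outside strand segments")
    segs$parent[idx]
}

# Rewrite [s, e) to a single parent.
.rewriteInterval <- function(segs, s, e, parent) {
    if (e <= s)
        return(segs)
    left <- segs
    left$end <- pmin(left$end, s)
    right <- segs
    right$start <- pmax(right$start, e)
    mid <- data.frame(start = s, end = e, parent = parent,
                      stringsAsFactors = FALSE)
    .mergeSegments(rbind(left, mid, right))
}

# Rewrite [s, e) of `dst` so that it copies the parental origin of `src`
# position-by-position (excision of dst, resynthesis from the src template).
.copyInterval <- function(dst, src, s, e) {
    if (e <= s)
        return(dst)
    for (i in seq_len(nrow(src))) {
        os <- max(src$start[i], s)
        oe <- min(src$end[i], e)
        if (oe > os)
            dst <- .rewriteInterval(dst, os, oe, src$parent[i])
    }
    dst
}

# Maximal intervals where the two strands carry different parental origins.
.hdnaIntervals <- function(top, bottom) {
    bp <- sort(unique(c(top$start, top$end, bottom$start, bottom$end)))
    s <- bp[-length(bp)]
    e <- bp[-1L]
    diff <- .parentAt(top, s) != .parentAt(bottom, s)
    if (!any(diff))
        return(data.frame(start = numeric(0), end = numeric(0)))
    segs <- data.frame(start = s[diff], end = e[diff], parent = "x",
                       stringsAsFactors = FALSE)
    .mergeSegments(segs)[, c("start", "end")]
}

.checkTiling <- function(segs, bounds) {
    if (nrow(segs) == 0L)
        return("strand has no segments")
    segs <- segs[order(segs$start), , drop = FALSE]
    if (segs$start[1L] != bounds[1] || segs$end[nrow(segs)] != bounds[2])
        return("strand segments do not span the locus bounds")
    if (any(segs$end <= segs$start))
        return("strand segment with non-positive width")
    if (nrow(segs) > 1L &&
        any(segs$start[-1L] != segs$end[-nrow(segs)]))
        return("strand segments leave gaps or overlap")
    if (!all(segs$parent %in% .PARENTS))
        return("strand parent labels must be 'P1' or 'P2'")
    TRUE
}
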