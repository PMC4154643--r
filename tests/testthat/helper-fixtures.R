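# Shared fixtures and independent oracles, built in code.

# A minimal SNP-only map without selection sites.
tinySnpMap <- function(positions, bounds = NULL) {
    n <- length(positions)
    mk <- data.frame(position = as.integer(positions), kind = "snp",
                     footprint = 1L,
                     allele_p1 = rep(c("A", "C"), length.out = n),
                     allele_p2 = rep(c("G", "T"), length.out = n),
                     is_selection_site = FALSE, stringsAsFactors = FALSE)
    if (is.null(bounds))
        bounds <- c(min(positions) - 100L, max(positions) + 100L)
    markerMap(mk, locusBounds = bounds)
}

# A small map with the two selection sites, suitable for selection tests.
selTestMap <- function() {
    pos <- c(-900L, -468L, -200L, 400L, 1500L, 2600L, 3312L, 3900L)
    mk <- data.frame(position = pos, kind = "snp", footprint = 1L,
                     allele_p1 = rep(c("A", "C"), 4),
                     allele_p2 = rep(c("G", "T"), 4),
                     is_selection_site = pos %in% c(-468L, 3312L),
                     stringsAsFactors = FALSE)
    markerMap(mk, locusBounds = c(-1200, 4200))
}

# Build strand segments tiling `bounds` that carry `donor` on the given
# intervals (list of c(start, end)) and `recipient` elsewhere.  Independent
# of the package's interval machinery.
segsFromIntervals <- function(bounds, donorIvs, recipient = "P1",
                              donor = "P2") {
    bp <- sort(unique(c(bounds, unlist(donorIvs))))
    bp <- bp[bp >= bounds[1] & bp <= bounds[2]]
    starts <- bp[-length(bp)]
    ends <- bp[-1L]
    par <- vapply(starts, function(s) {
        inside <- any(vapply(donorIvs, function(iv)
            s >= iv[1] && s < iv[2], logical(1)))
        if (inside) donor else recipient
    }, character(1))
    data.frame(start = starts, end = ends, parent = par,
               stringsAsFactors = FALSE)
}

# Hand-built duplex from donor-carrying intervals per strand.
manualDuplex <- function(map, topIvs = list(), bottomIvs = list(),
                         nicksTop = numeric(0), nicksBottom = numeric(0),
                         recipient = "P1", label = NULL,
                         truth = list()) {
    b <- locusBounds(map)
    donor <- if (recipient == "P1") "P2" else "P1"
    truth$label <- label
    new("RecombinantDuplex",
        top = segsFromIntervals(b, topIvs, recipient, donor),
        bottom = segsFromIntervals(b, bottomIvs, recipient, donor),
        nicks = list(top = nicksTop, bottom = nicksBottom),
        truth = truth, locusBounds = b)
}

# Observation straight from hand-written strand calls.
manualObservation <- function(positions, top, bottom, eventId = "ev") {
    new("ObservedRecombinant",
        calls = data.frame(position = positions, top = top, bottom = bottom,
                           stringsAsFactors = FALSE),
        eventId = eventId, survived = NA)
}

# Independent quadrature oracle for the truncated-exponential expectation.
truncExpMeanQuad <- function(a, b, p) {
    lambda <- -log(p)
    dens <- function(x) exp(-lambda * x)
    z <- stats::integrate(dens, a, b, rel.tol = 1e-12)$value
    m <- stats::integrate(function(x) x * dens(x), a, b,
                          rel.tol = 1e-12)$value
    m / z
}

# Marker-level heteroduplex positions of a duplex (independent of the
# package's interval set computation).
hetMarkersOf <- function(duplex, map) {
    obs <- observeRecombinant(duplex, map)
    calls <- markerCalls(obs)
    calls$position[calls$top != calls$bottom]
}
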