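#' Tract bounds
#'
#' Inclusion/exclusion bounds of a tract: a minimum length \code{a} from the
#' outermost included markers and a maximum length \code{b} from the nearest
#' non-included markers.
#'
#' @param a minimum length (bp), > 0.
#' @param b maximum length (bp), >= a.
#' @return \code{data.frame} with columns \code{a}, \code{b}.
#' @export
tractBounds <- function(a, b) {
    if (any(a <= 0))
        stop("minimum tract length a must be positive")
    if (any(a > b))
        stop("tract bounds must satisfy a <= b")
    data.frame(a = a, b = b)
}

#' Truncated-exponential tract-length estimate
#'
#' Gene-conversion tract lengths are modeled as exponential with per-base
#' extension probability \code{p} (rate \code{lambda = -log(p)}; mean
#' \code{1/lambda}, about 353 bp at the default \code{p}).  A tract observed
#' to include markers spanning \code{a} bp but not the flanking markers
#' \code{b} bp apart has a length in \code{[a, b]}; the estimate returned is
#' the conditional expectation of the exponential truncated to that
#' interval,
#' \deqn{E[L] = 1/\lambda +
#'   \frac{a e^{-\lambda a} - b e^{-\lambda b}}
#'        {e^{-\lambda a} - e^{-\lambda b}},}
#' computed in a numerically stable form.  Degenerate bounds (\code{a == b})
#' return \code{a}; in the \code{p -> 1} limit the truncated density becomes
#' uniform and the estimate tends to the interval midpoint.
#'
#' @param a,b tract bounds in bp (vectors recycle).
#' @param p per-base extension probability in (0, 1); default 0.99717.
#' @return numeric vector of length estimates, always within \code{[a, b]}.
#' @examples
#' estimateTractLength(100, 1000)
#' estimateTractLength(100, 300, p = 0.9999999) # ~ midpoint
#' @export
estimateTractLength <- function(a, b, p = 0.99717) {
    if (any(p <= 0) || any(p >= 1))
        stop("p must lie strictly between 0 and 1")
    if (any(a > b))
        stop("tract bounds must satisfy a <= b")
    if (any(a < 0))
        stop("tract bounds must be non-negative")
    lambda <- -log(p)
    d <- b - a
    # E = 1/lambda + (a - b exp(-lambda d)) / (1 - exp(-lambda d))
    num <- a - b * exp(-lambda * d)
    den <- -expm1(-lambda * d)
    est <- 1 / lambda + num / den
    mid <- (a + b) / 2
    small <- lambda * d < 1e-9
    est[small] <- mid[small]
    est[d == 0] <- a[d == 0]
    est
}

#' Split a trans tract into its two halves
#'
#' Each strand-phase run of a trans tract is treated as an independent tract
#' (each half has the same predicted origin as a single cis tract).  The
#' inner boundary between adjacent runs is placed at the halfway point
#' between their facing heteroduplex markers; the outer boundaries are the
#' tract's excluded flanking markers.  The minimum length of a half is the
#' span of its run's markers (the marker footprint for single-marker runs).
#'
#' @param tract an annotated \code{"TractCall"} with \code{cisTrans ==
#'   "trans"} (see \code{\link{analyzeRecombinant}}), or any tract from
#'   \code{\link{findHdnaTracts}} whose \code{\link{classifyCisTrans}} is
#'   trans.
#' @param map A \linkS4class{MarkerMap} (for marker footprints).
#' @return \code{data.frame} of bounds with columns \code{a}, \code{b}, one
#'   row per phase run (two for a typical trans tract).
#' @export
splitTransTract <- function(tract, map) {
    if (classifyCisTrans(tract) != "trans")
        stop("splitTransTract requires a trans tract")
    phase <- tract$hetTopCall
    pos <- tract$hetPositions
    runs <- rle(phase)
    ends <- cumsum(runs$lengths)
    starts <- c(1L, ends[-length(ends)] + 1L)
    mk <- markers(map)
    nRuns <- length(ends)
    mids <- (pos[ends[-nRuns]] + pos[starts[-1L]]) / 2
    a <- b <- numeric(nRuns)
    for (k in seq_len(nRuns)) {
        rp <- pos[starts[k]:ends[k]]
        if (length(rp) == 1L) {
            foot <- mk$footprint[match(rp, mk$position)]
            a[k] <- ifelse(is.na(foot), 1L, foot)
        } else {
            a[k] <- max(rp) - min(rp)
        }
        lo <- if (k == 1L) tract$leftExcl else mids[k - 1L]
        hi <- if (k == nRuns) tract$rightExcl else mids[k]
        b[k] <- hi - lo
    }
    tractBounds(a, b)
}

#' Summarize tract-length estimates
#'
#' @param estimates numeric vector of tract-length estimates (bp).
#' @param semSingle value returned as the SEM when only one estimate is
#'   given (\code{NA} by default; some workflows prefer 0).
#' @return list with \code{n}, \code{mean}, \code{sem}.
#' @examples
#' summarizeLengths(c(100, 300))
#' @export
summarizeLengths <- function(estimates, semSingle = NA_real_) {
    n <- length(estimates)
    if (n == 0L)
        stop("no estimates to summarize")
    list(n = n, mean = mean(estimates),
         sem = if (n == 1L) semSingle else stats::sd(estimates) / sqrt(n))
}
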