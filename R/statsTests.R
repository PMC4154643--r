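#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value by direct enumeration of the hypergeometric
#' distribution over all tables with the observed margins: the p-value is
#' the sum of the probabilities of all tables whose probability does not
#' exceed that of the observed table, with a relative tie tolerance of 1e-7
#' (tie handling changes the two-sided p on degenerate tables, so the
#' tolerance is fixed and documented).
#'
#' @param table 2x2 matrix (or object coercible to one) of non-negative
#'   integer counts; rows are groups, columns outcomes.
#' @return p-value in (0, 1].
#' @examples
#' fisherExactTwoSided(matrix(c(40, 40, 2, 71), nrow = 2))
#' @export
fisherExactTwoSided <- function(table) {
    tab <- as.matrix(table)
    if (!all(dim(tab) == c(2L, 2L)))
        stop("need a 2x2 table")
    if (any(tab < 0) || any(tab != round(tab)))
        stop("counts must be non-negative integers")
    m <- sum(tab[1L, ])          # row 1 total
    n <- sum(tab[2L, ])          # row 2 total
    k <- sum(tab[, 1L])          # column 1 total
    if (m + n == 0L)
        stop("table has no observations")
    support <- max(0L, k - n):min(k, m)
    probs <- stats::dhyper(support, m, n, k)
    pObs <- stats::dhyper(tab[1L, 1L], m, n, k)
    p <- sum(probs[probs <= pObs * (1 + 1e-7)])
    min(p, 1)
}

#' Probability of zero successes in n binomial trials
#'
#' The closed form \code{(1 - q)^n}: the probability of recovering zero of
#' \code{n} expected detections when each is detected independently with
#' probability \code{q}.
#'
#' @param n number of trials (>= 0).
#' @param q per-trial success probability in [0, 1].
#' @return probability.
#' @examples
#' binomialZeroProbability(5, 0.5)
#' @export
binomialZeroProbability <- function(n, q) {
    if (n < 0 || q < 0 || q > 1)
        stop("need n >= 0 and q in [0, 1]")
    (1 - q)^n
}

#' Compare two sets of tract lengths
#'
#' Default tests: two-sided Welch (unequal-variance) t for unpaired groups,
#' two-sided paired t for paired groups (e.g. the short and long halves of
#' trans tracts, which come from the same event).  A seeded permutation
#' alternative is provided for both modes: group labels are shuffled
#' (unpaired) or within-pair signs flipped (paired) and the absolute mean
#' difference is compared to its permutation distribution.
#'
#' @param groupA,groupB numeric vectors of tract lengths (bp); paired mode
#'   requires equal lengths.
#' @param mode \code{"unpaired"} or \code{"paired"}.
#' @param method \code{"t"} or \code{"permutation"}.
#' @param nPerm number of label shuffles for the permutation test.
#' @return list with \code{p}, \code{statistic} (t statistic or observed
#'   mean difference), \code{method}, \code{mode}.
#' @examples
#' set.seed(1)
#' compareTractLengths(rnorm(20, 700, 100), rnorm(20, 720, 100))$p
#' @export
compareTractLengths <- function(groupA, groupB,
                                mode = c("unpaired", "paired"),
                                method = c("t", "permutation"),
                                nPerm = 10000L) {
    mode <- match.arg(mode)
    method <- match.arg(method)
    if (length(groupA) < 2L || length(groupB) < 2L)
        stop("need at least two values per group")
    if (mode == "paired" && length(groupA) != length(groupB))
        stop("paired mode requires equal-length groups")
    if (method == "t") {
        ht <- tryCatch(
            stats::t.test(groupA, groupB, paired = mode == "paired",
                          var.equal = FALSE),
            error = function(e) NULL)
        if (is.null(ht) || is.nan(ht$p.value)) {
            # degenerate (essentially constant) data: decide on the means
            p <- if (isTRUE(all.equal(mean(groupA), mean(groupB)))) 1 else 0
            return(list(p = p, statistic = NA_real_, method = "t",
                        mode = mode))
        }
        return(list(p = ht$p.value, statistic = unname(ht$statistic),
                    method = "t", mode = mode))
    }
    if (mode == "unpaired") {
        pooled <- c(groupA, groupB)
        nA <- length(groupA)
        obs <- abs(mean(groupA) - mean(groupB))
        perm <- replicate(nPerm, {
            idx <- sample(length(pooled), nA)
            abs(mean(pooled[idx]) - mean(pooled[-idx]))
        })
    } else {
        diffs <- groupA - groupB
        obs <- abs(mean(diffs))
        perm <- replicate(nPerm, {
            signs <- sample(c(-1, 1), length(diffs), replace = TRUE)
            abs(mean(signs * diffs))
        })
    }
    p <- (1 + sum(perm >= obs)) / (nPerm + 1)
    list(p = p, statistic = obs, method = "permutation", mode = mode)
}
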