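#' Moment summary of a quantitative phenotype
#'
#' Computes n, mean, standard deviation, the adjusted Fisher-Pearson sample
#' skewness and the small-sample-corrected excess kurtosis (the conventions
#' used by SPSS), and flags the distribution as approximately normal when
#' both |skewness| < 1 and |kurtosis| < 1 -- the moment criterion commonly
#' used to justify treating an F2 trait as quantitative.
#'
#' Skewness: `g1 * sqrt(n (n-1)) / (n-2)` with `g1 = m3 / m2^(3/2)` from
#' central moments. Excess kurtosis:
#' `n (n+1) / ((n-1)(n-2)(n-3)) * sum(((x - mean)/s)^4) - 3 (n-1)^2 / ((n-2)(n-3))`
#' with `s` the sample standard deviation.
#'
#' @param heights numeric vector (cm), length >= 3 (>= 4 for kurtosis), all
#'   finite, non-degenerate.
#' @return one-row `data.frame`: `n`, `mean`, `sd`, `skewness`, `kurtosis`,
#'   `normalFlag`.
#' @examples
#' summarizePhenotypes(c(10, 12, 11, 14, 13, 12, 15, 11))
#' @export
summarizePhenotypes <- function(heights) {
    x <- as.numeric(heights)
    if (length(x) < 3L) stop("need at least 3 phenotype values")
    if (any(!is.finite(x))) stop("phenotype values must be finite")
    n <- length(x)
    s <- sd(x)
    if (s == 0) stop("zero phenotype variance")
    xc <- x - mean(x)
    m2 <- mean(xc^2)
    m3 <- mean(xc^3)
    g1 <- m3 / m2^1.5
    skew <- g1 * sqrt(n * (n - 1)) / (n - 2)
    kurt <- if (n >= 4L)
        n * (n + 1) / ((n - 1) * (n - 2) * (n - 3)) * sum((xc / s)^4) -
            3 * (n - 1)^2 / ((n - 2) * (n - 3))
    else NA_real_
    data.frame(n = n, mean = mean(x), sd = s,
               skewness = skew, kurtosis = kurt,
               normalFlag = isTRUE(abs(skew) < 1 && abs(kurt) < 1))
}

#' Select the two extreme phenotype bulks
#'
#' Returns the `k` lowest and `k` highest individuals. Ties at a bulk
#' boundary are broken by ascending id, so the lower id enters the bulk;
#' the rule is deterministic and symmetric (negating all heights swaps the
#' two bulks exactly).
#'
#' @param heights numeric vector.
#' @param ids ids parallel to `heights`; defaults to `names(heights)` or
#'   `seq_along(heights)`.
#' @param k bulk size; `2 k <= length(heights)` required.
#' @return list with character/integer vectors `low` and `high` (each of
#'   length `k`, disjoint), ordered by extremity.
#' @export
selectBulks <- function(heights, ids = NULL, k) {
    if (is.null(ids)) ids <- names(heights)
    if (is.null(ids)) ids <- seq_along(heights)
    if (length(ids) != length(heights)) stop("ids must parallel heights")
    if (anyDuplicated(ids)) stop("ids must be unique")
    n <- length(heights)
    if (2L * k > n) stop("2 * k exceeds the number of individuals")
    oLow <- order(heights, ids)
    oHigh <- order(-heights, ids)
    low <- ids[oLow[seq_len(k)]]
    high <- ids[oHigh[seq_len(k)]]
    if (length(intersect(low, high)))
        stop("bulks overlap: tied heights span both selection boundaries")
    list(low = low, high = high)
}
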