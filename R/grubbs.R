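#' Grubbs critical value
#'
#' Closed-form critical value of Grubbs' outlier test from the
#' t-distribution:
#' \deqn{G_{crit} = \frac{n-1}{\sqrt{n}}
#'   \sqrt{\frac{t^2}{n - 2 + t^2}}}
#' with \eqn{t} the upper \eqn{\alpha/n} (one-sided) or \eqn{\alpha/(2n)}
#' (two-sided) quantile of the t-distribution on \eqn{n-2} degrees of
#' freedom.
#'
#' @param n Sample size (>= 3).
#' @param alpha Significance level.
#' @param side `"one_sided_max"` or `"two_sided"`.
#' @return The critical value.
#' @export
grubbsCritical <- function(n, alpha = 0.05,
                           side = c("one_sided_max", "two_sided")) {
    side <- match.arg(side)
    if (n < 3) stop("Grubbs test requires n >= 3")
    p <- if (side == "one_sided_max") alpha / n else alpha / (2 * n)
    t <- qt(p, df = n - 2, lower.tail = FALSE)
    ((n - 1) / sqrt(n)) * sqrt(t^2 / (n - 2 + t^2))
}

#' Repeated Grubbs outlier test
#'
#' Iteratively applies Grubbs' test: compute
#' \eqn{G = (x_{extreme} - \bar{x}) / s}; if \eqn{G} exceeds the critical
#' value at `alpha` for the current sample size, remove that value, record
#' it, and repeat on the remainder.  Removal stops at the first
#' non-significant test or when fewer than 3 values remain.  A zero-variance
#' sample yields no outliers.  The test is invariant under affine
#' transformations of the input, so the base of any preceding log
#' transform is immaterial.
#'
#' @param values Numeric vector (length >= 3, finite).
#' @param alpha Significance level (default 0.05).
#' @param side `"one_sided_max"` tests only the maximum (appropriate when
#'   degradation can only inflate the score); `"two_sided"` tests the most
#'   extreme deviation on either side.
#' @return A [GrubbsResult-class].
#' @examples
#' grubbsRepeated(c(rep(1, 9), 10))
#' @importFrom stats sd
#' @export
grubbsRepeated <- function(values, alpha = 0.05,
                           side = c("one_sided_max", "two_sided")) {
    side <- match.arg(side)
    if (length(values) < 3) stop("Grubbs test requires n >= 3")
    if (any(!is.finite(values))) stop("values must be finite")
    remaining <- seq_along(values)
    outliers <- integer()
    gs <- numeric(); crits <- numeric()
    repeat {
        x <- values[remaining]
        n <- length(x)
        if (n < 3) break
        s <- sd(x)
        if (s == 0) break
        m <- mean(x)
        if (side == "one_sided_max") {
            i <- which.max(x)
            G <- (x[i] - m) / s
        } else {
            i <- which.max(abs(x - m))
            G <- abs(x[i] - m) / s
        }
        crit <- grubbsCritical(n, alpha, side)
        if (G > crit) {
            outliers <- c(outliers, remaining[i])
            gs <- c(gs, G); crits <- c(crits, crit)
            remaining <- remaining[-i]
        } else break
    }
    new("GrubbsResult", values = as.numeric(values),
        outlierIndices = outliers, gStatistics = gs,
        criticalValues = crits, alpha = alpha, side = side)
}
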