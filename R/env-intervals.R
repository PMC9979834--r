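#' Paired-difference credible interval for an environmental variable
#'
#' Central 95% (by default) credible interval for the mean difference between
#' paired measurements (deep minus shallow, one pair per week). Under
#' independent identically normal differences and the noninformative uniform
#' prior on the mean and log standard deviation, this central credible
#' interval coincides with the classical one-sample t-interval:
#' mean +/- t_{(1+level)/2, n-1} s / sqrt(n). Pairs with a missing member are
#' dropped listwise.
#'
#' @param deep,shallow equal-length numeric vectors (NA allowed).
#' @param level credible level (default 0.95).
#' @param variable name used in printing.
#' @return object of class `paired_ci`: list with `variable`, `n`, `mean`,
#'   `lower`, `upper`, `level`, `differences`, `degenerate`.
#' @export
paired_credible_interval <- function(deep, shallow, level = 0.95,
                                     variable = "difference") {
  if (length(deep) != length(shallow)) stop("vectors must have equal length")
  ok <- is.finite(deep) & is.finite(shallow)
  d <- deep[ok] - shallow[ok]
  n <- length(d)
  if (n < 2L) stop("need at least 2 complete pairs")
  m <- mean(d)
  s <- sd(d)
  degenerate <- s == 0
  half <- if (degenerate) 0 else qt((1 + level) / 2, n - 1L) * s / sqrt(n)
  structure(list(variable = variable, n = n, mean = m,
                 lower = m - half, upper = m + half, level = level,
                 differences = d, degenerate = degenerate),
            class = "paired_ci")
}

#' @export
print.paired_ci <- function(x, digits = 3, ...) {
  cat(sprintf("%s: mean difference %.*f, central %d%% credible interval [%.*f, %.*f] (n = %d pairs)%s\n",
              x$variable, digits, x$mean, round(100 * x$level),
              digits, x$lower, digits, x$upper, x$n,
              if (x$degenerate) " [degenerate: zero variance]" else ""))
  invisible(x)
}

#' QQ-plot points against the standard normal
#'
#' Order statistics paired with standard-normal quantiles at plotting
#' positions (i - 0.5)/n, for checking approximate normality of paired
#' differences.
#'
#' @param x numeric vector, length >= 3.
#' @return data.frame with columns `theoretical`, `sample`.
#' @export
qq_points <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3L) stop("need at least 3 values")
  data.frame(theoretical = qnorm((seq_len(n) - 0.5) / n), sample = sort(x))
}

#' Depth-difference credible intervals for all environmental variables
#'
#' Pairs the two depths within each week and returns one row per variable.
#'
#' @param env data.frame with columns week, depth, dissolved_oxygen,
#'   temperature, salinity (or an `experiment_table`).
#' @param level credible level.
#' @return data.frame: variable, n, mean, lower, upper.
#' @export
env_intervals <- function(env, level = 0.95) {
  if (inherits(env, "experiment_table")) env <- env$env
  depths <- sort(unique(env$depth))
  if (length(depths) != 2L) stop("expected exactly two depths")
  vars <- intersect(c("dissolved_oxygen", "temperature", "salinity"), names(env))
  rows <- lapply(vars, function(v) {
    deep <- env[env$depth == depths[2], ]
    shal <- env[env$depth == depths[1], ]
    m <- match(shal$week, deep$week)
    ci <- paired_credible_interval(deep[[v]][m], shal[[v]], level, variable = v)
    data.frame(variable = v, n = ci$n, mean = ci$mean,
               lower = ci$lower, upper = ci$upper)
  })
  do.call(rbind, rows)
}
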