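#' @useDynLib rhabdom, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm rpois rgamma runif qlnorm plnorm fft sd median
#'   quantile lm coef pnorm convolve dnorm var
#' @importFrom utils head tail write.csv
#' @importFrom graphics hist
NULL

# trapezoidal integral on an (x, y) grid
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

# centred moving-average smoothing (width in samples, forced odd)
moving_average <- function(x, width) {
  width <- max(1L, as.integer(width))
  if (width %% 2L == 0L) width <- width + 1L
  if (width == 1L) return(x)
  k <- rep(1 / width, width)
  n <- length(x)
  xs <- stats::filter(c(rep(x[1], width), x, rep(x[n], width)), k, sides = 2)
  as.numeric(xs[(width + 1):(width + n)])
}

# deterministic per-trial child seeds from one master seed
child_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  set.seed(seed)
  as.list(sample.int(.Machine$integer.max - 1L, n))
}

maybe_set_seed <- function(seed) {
  if (!is.null(seed)) set.seed(seed)
  invisible(seed)
}

# mean of a log-normal truncated to [lo, hi]
truncated_lognormal_mean <- function(meanlog, sdlog, lo, hi) {
  plo <- plnorm(lo, meanlog, sdlog)
  phi <- plnorm(hi, meanlog, sdlog)
  f <- function(x) x * stats::dlnorm(x, meanlog, sdlog) / (phi - plo)
  stats::integrate(f, lo, hi)$value
}

`%||%` <- function(a, b) if (is.null(a)) b else a
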