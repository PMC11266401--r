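#' Piecewise-exponential survival tools
#'
#' Mortality in the synthetic world is piecewise-exponential with hazard
#' change-points at 90, 182 and 1095 days after the index date, the simplest
#' family that reproduces three printed cumulative-mortality values (3, 6 and
#' 36 months) while keeping the characteristic early-mortality shape of a
#' newly diagnosed severe disease.
#'
#' `pexp_hazards` converts cumulative mortality at the piece ends into the
#' constant hazard of each piece (the last, open-ended piece reuses the final
#' hazard).  `pexp_cdf` is the analytic distribution function, `pexp_surv`
#' its complement, `pexp_rand` an inverse-CDF sampler, and `pexp_integral`
#' the analytic integral of the survival function over an interval (expected
#' alive-days, used to calibrate visit rates).
#'
#' @param cum_mortality cumulative mortality at the end of each finite piece,
#'   non-decreasing values in `[0, 1)`.
#' @param breaks upper bounds (days) of the finite hazard pieces.
#' @param hazards vector of `length(breaks) + 1` piecewise hazards per day.
#' @param t time in days (vectorised).
#' @param n number of draws.
#' @param lower truncation bound: draws are conditional on surviving past
#'   `lower` days (0 for unconditional draws).
#' @param a,b interval bounds in days, `a <= b`.
#' @return Hazards, probabilities, random times (possibly `Inf` when all
#'   hazards are zero), or the integral of S(t) over `[a, b]`.
#' @examples
#' h <- pexp_hazards(c(0.084, 0.121, 0.188))
#' pexp_cdf(182, h)  # 0.121
#' @export
pexp_hazards <- function(cum_mortality, breaks = c(90, 182, 1095)) {
  stopifnot(length(cum_mortality) == length(breaks))
  if (any(cum_mortality < 0 | cum_mortality >= 1)) {
    stop("cumulative mortality must lie in [0, 1)", call. = FALSE)
  }
  if (is.unsorted(cum_mortality)) {
    stop("cumulative mortality must be non-decreasing", call. = FALSE)
  }
  logS <- log(1 - cum_mortality)
  widths <- diff(c(0, breaks))
  h <- -diff(c(0, logS)) / widths
  c(h, h[length(h)])
}

#' @rdname pexp_hazards
#' @export
pexp_cdf <- function(t, hazards, breaks = c(90, 182, 1095)) {
  1 - pexp_surv(t, hazards, breaks)
}

#' @rdname pexp_hazards
#' @export
pexp_surv <- function(t, hazards, breaks = c(90, 182, 1095)) {
  if (any(hazards < 0)) stop("hazards must be >= 0", call. = FALSE)
  stopifnot(length(hazards) == length(breaks) + 1L)
  lo <- c(0, breaks)
  hi <- c(breaks, Inf)
  H <- vapply(t, function(tt) {
    sum(hazards * pmax(0, pmin(tt, hi) - lo))
  }, numeric(1))
  exp(-H)
}

#' @rdname pexp_hazards
#' @export
pexp_rand <- function(n, hazards, breaks = c(90, 182, 1095), lower = 0) {
  if (any(hazards < 0)) stop("hazards must be >= 0", call. = FALSE)
  stopifnot(length(hazards) == length(breaks) + 1L)
  # invert S(t) = exp(-H(t)); H is piecewise linear in t
  lo <- c(0, breaks)
  Hlo <- cumsum(c(0, hazards[-length(hazards)] * diff(c(0, breaks))))
  H0 <- if (lower > 0) -log(pexp_surv(lower, hazards, breaks)) else 0
  u <- runif(n)
  target <- H0 - log1p(-u)          # conditional on T > lower
  idx <- findInterval(target, Hlo)  # piece containing the target cum. hazard
  t <- rep(Inf, n)
  pos <- hazards[idx] > 0
  t[pos] <- lo[idx[pos]] + (target[pos] - Hlo[idx[pos]]) / hazards[idx[pos]]
  # target can exceed total hazard of finite pieces only when tail hazard is 0
  t
}

#' @rdname pexp_hazards
#' @export
pexp_integral <- function(a, b, hazards, breaks = c(90, 182, 1095)) {
  stopifnot(a <= b, length(hazards) == length(breaks) + 1L)
  lo <- c(0, breaks)
  hi <- c(breaks, Inf)
  total <- 0
  for (j in seq_along(hazards)) {
    l <- max(a, lo[j]); u <- min(b, hi[j])
    if (u <= l) next
    Sl <- pexp_surv(l, hazards, breaks)
    total <- total + if (hazards[j] > 0) {
      Sl * (1 - exp(-hazards[j] * (u - l))) / hazards[j]
    } else {
      Sl * (u - l)
    }
  }
  total
}
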