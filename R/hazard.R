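#' Cumulative transition hazard from residency durations
#'
#' The instantaneous rate r(t) of leaving a location after t seconds of
#' residency satisfies the identity
#' \eqn{\int_0^t r = -\ln(1 - \int_0^t p)}, where p is the density of
#' residency durations. This returns the cumulative hazard
#' R(t) = -ln(1 - F(t)) on a grid, with F the product-limit (Kaplan-Meier)
#' estimate so that the final, right-censored residency of a session is used
#' rather than discarded.
#'
#' @param durations Numeric vector of residency durations, or a data.frame
#'   with columns `duration` and `censored` as returned by
#'   [residency_durations()].
#' @param grid Numeric vector of time points (seconds).
#' @return A data.frame `t`, `R` (nondecreasing). Grid points beyond the last
#'   observed duration where the survival estimate hits 0 are clipped to the
#'   largest finite value, with a warning.
#' @export
cumulative_hazard <- function(durations, grid) {
  if (is.data.frame(durations)) {
    dur <- durations$duration
    event <- !durations$censored
  } else {
    dur <- as.numeric(durations)
    event <- rep(TRUE, length(dur))
  }
  zero <- dur <= 0
  if (any(zero & event)) stop("durations must be > 0", call. = FALSE)
  # a censored residency of zero length carries no information
  dur <- dur[!zero]; event <- event[!zero]
  if (!any(event)) stop("need at least one uncensored duration", call. = FALSE)
  fit <- survival::survfit(survival::Surv(dur, event) ~ 1)
  sf <- stats::stepfun(fit$time, c(1, fit$surv))
  S <- sf(grid)
  R <- -log(S)
  if (any(!is.finite(R))) {
    warning("survival estimate reaches 0 on the grid; ",
            "cumulative hazard clipped", call. = FALSE)
    # cap at the resolution limit of a sample of this size
    mx <- suppressWarnings(max(R[is.finite(R)], 0))
    R[!is.finite(R)] <- max(mx, log(2 * length(dur)))
  }
  data.frame(t = grid, R = R)
}

#' Instantaneous transition rate by smoothed differentiation
#'
#' Smooths a cumulative hazard with a fixed-bandwidth gaussian kernel and
#' differentiates numerically; the result is clipped at 0.
#'
#' @param R A data.frame `t`, `R` from [cumulative_hazard()].
#' @param bandwidth Kernel bandwidth in seconds (default 5).
#' @return A data.frame `t`, `rate`.
#' @export
instantaneous_rate <- function(R, bandwidth = 5) {
  if (bandwidth <= 0) stop("bandwidth must be > 0", call. = FALSE)
  if (!nrow(R)) return(data.frame(t = numeric(0), rate = numeric(0)))
  if (nrow(R) < 3L) return(data.frame(t = R$t, rate = rep(NA_real_, nrow(R))))
  if (any(diff(R$R) < -1e-9)) stop("R must be nondecreasing", call. = FALSE)
  ks <- stats::ksmooth(R$t, R$R, kernel = "normal", bandwidth = bandwidth,
                       x.points = R$t)
  Rs <- ks$y
  n <- length(Rs)
  rate <- numeric(n)
  rate[2:(n - 1L)] <- (Rs[3:n] - Rs[1:(n - 2L)]) / (R$t[3:n] - R$t[1:(n - 2L)])
  rate[1L] <- (Rs[2L] - Rs[1L]) / (R$t[2L] - R$t[1L])
  rate[n] <- (Rs[n] - Rs[n - 1L]) / (R$t[n] - R$t[n - 1L])
  data.frame(t = R$t, rate = pmax(rate, 0))
}
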