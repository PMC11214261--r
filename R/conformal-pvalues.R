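#' Conformal p-value calculators
#'
#' The standard conformal p-value ranks the test nonconformity against the
#' calibration list with the test instance included:
#' \deqn{p = |\{j = 1..n+1 : \alpha_j \ge \alpha_{n+1}\}| / (n+1).}
#' The smoothed variant splits ties with a factor \eqn{\tau \in [0,1]}
#' (\eqn{\tau = 1} recovers the standard value); on exchangeable data the
#' smoothed p-value of the true label is uniform on (0,1). The linearly
#' interpolated variant passes a piecewise-linear, monotone non-increasing
#' function through the knots \eqn{(\alpha_{(k)}, p_{std}(\alpha_{(k)}))},
#' clamped at 1 below the smallest calibration value and at
#' \eqn{1/(n+1)} above the largest, which smooths the staircase a small
#' calibration set produces.
#'
#' @param calibration numeric vector of calibration nonconformity values
#'   (any order; sorted internally).
#' @param alpha test nonconformity value(s); vectorized.
#' @return numeric p-value(s) in (0, 1].
#' @examples
#' pValueStandard(c(1, 2, 3, 4, 5), 3.5)       # 0.5
#' pValueSmoothed(c(1, 2, 3), 2, tau = 0.5)    # 0.5
#' pValueInterpolated(c(1, 2, 3, 4, 5), 2.5)   # 0.75
#' @export
pValueStandard <- function(calibration, alpha) {
  n <- length(calibration)
  if (n < 1L) .stopf("empty calibration set")
  s <- sort(calibration)
  nLess <- findInterval(alpha, s, left.open = TRUE)
  (n - nLess + 1) / (n + 1)
}

#' @rdname pValueStandard
#' @param tau tie-splitting factor in [0,1]; scalar or one value per alpha.
#' @export
pValueSmoothed <- function(calibration, alpha, tau) {
  n <- length(calibration)
  if (n < 1L) .stopf("empty calibration set")
  if (any(tau < 0 | tau > 1)) .stopf("tau must lie in [0,1]")
  s <- sort(calibration)
  nLE <- findInterval(alpha, s)
  nLess <- findInterval(alpha, s, left.open = TRUE)
  nGreater <- n - nLE
  nEqual <- nLE - nLess + 1  # calibration ties plus the test instance
  (nGreater + tau * nEqual) / (n + 1)
}

#' @rdname pValueStandard
#' @export
pValueInterpolated <- function(calibration, alpha) {
  n <- length(calibration)
  if (n < 1L) .stopf("empty calibration set")
  s <- sort(calibration)
  knots <- unique(s)
  pk <- pValueStandard(s, knots)
  out <- numeric(length(alpha))
  below <- alpha <= knots[1]
  above <- alpha > knots[length(knots)]
  mid <- !below & !above
  out[below] <- 1
  out[above] <- 1 / (n + 1)
  if (any(mid)) {
    if (length(knots) == 1L) out[mid] <- pk  # unreachable: mid empty then
    else out[mid] <- stats::approx(knots, pk, xout = alpha[mid],
                                   method = "linear", ties = "ordered")$y
  }
  out
}

#' P-value calculator configuration
#'
#' @param mode "standard", "smoothed" or "linear-interpolated".
#' @param tau smoothing factor in [0,1], or "random" to draw one value per
#'   (test object, class) from the seeded RNG.
#' @param seed seed for random tau draws.
#' @return a list of class \code{"PValueConfig"}.
#' @export
pValueConfig <- function(mode = c("standard", "smoothed", "linear-interpolated"),
                         tau = "random", seed = 1L) {
  mode <- match.arg(mode)
  if (!identical(tau, "random")) {
    tau <- as.numeric(tau)
    if (is.na(tau) || tau < 0 || tau > 1) .stopf("tau must be in [0,1] or 'random'")
  }
  structure(list(mode = mode, tau = tau, seed = as.integer(seed)),
            class = "PValueConfig")
}

# Dispatch one calculator over a vector of test alphas. `tauDraws` supplies
# the per-(object, class) uniforms in smoothed/random mode.
.computePValues <- function(calibration, alpha, pconfig, tauDraws = NULL) {
  switch(pconfig$mode,
    standard = pValueStandard(calibration, alpha),
    `linear-interpolated` = pValueInterpolated(calibration, alpha),
    smoothed = {
      tau <- if (identical(pconfig$tau, "random")) tauDraws else pconfig$tau
      pValueSmoothed(calibration, alpha, tau)
    })
}
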