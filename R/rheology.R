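#' Stress-relaxation trace
#'
#' @param time_s Strictly increasing times in seconds, first >= 0.
#' @param stress_Pa Shear stress in Pa.
#' @param strain_pct Imposed strain in percent (metadata; the deployed
#'   protocol holds 15%).
#' @return data.frame of class \code{relax_trace}.
#' @export
relax_trace <- function(time_s, stress_Pa, strain_pct = 15) {
  stopifnot(length(time_s) == length(stress_Pa))
  if (length(time_s) < 10L)
    stop("stress-relaxation trace needs at least 10 samples", call. = FALSE)
  if (time_s[1] < 0) stop("time must start at >= 0 s", call. = FALSE)
  if (any(diff(time_s) <= 0))
    stop("time stamps must be strictly increasing (trace rejected, not sorted)",
         call. = FALSE)
  structure(data.frame(time_s = time_s, stress_Pa = stress_Pa),
            strain_pct = strain_pct,
            class = c("relax_trace", "data.frame"))
}

#' Oscillatory trace (temperature sweep, time sweep or strain cycling)
#'
#' @param abscissa Numeric axis: temperature (deg C), time (s) or cycle index.
#' @param g_prime,g_double_prime Storage and loss moduli in Pa.
#' @param kind One of \code{"temperature"}, \code{"time"}, \code{"cycle"}.
#' @param cycle Optional integer cycle labels (strain cycling).
#' @param period Optional period labels, \code{"h"} (healing) /
#'   \code{"b"} (breaking).
#' @return data.frame of class \code{oscillatory_trace}.
#' @export
oscillatory_trace <- function(abscissa, g_prime, g_double_prime,
                              kind = c("temperature", "time", "cycle"),
                              cycle = NULL, period = NULL) {
  kind <- match.arg(kind)
  stopifnot(length(abscissa) == length(g_prime),
            length(abscissa) == length(g_double_prime))
  if (any(g_prime < 0) || any(g_double_prime < 0))
    stop("moduli must be non-negative", call. = FALSE)
  df <- data.frame(abscissa = abscissa, Gp_Pa = g_prime,
                   Gpp_Pa = g_double_prime)
  if (!is.null(cycle)) df$cycle <- as.integer(cycle)
  if (!is.null(period)) df$period <- as.character(period)
  structure(df, kind = kind, class = c("oscillatory_trace", "data.frame"))
}

#' Stress-relaxation time by the 1/e rule (simple Maxwell model)
#'
#' \eqn{\sigma_0} is the stress at the earliest sample; the relaxation time
#' \eqn{\tau} is the first time at which the stress crosses
#' \eqn{\sigma_0 / e}. On noisy traces a raw sample-to-sample crossing is
#' biased early, so the crossing is located by a local log-linear
#' regression over the samples within \eqn{\pm 40\%} (in log stress) of the
#' 1/e level; on a noiseless exponential this is exact, and when fewer
#' than three samples fall in the window the crossing falls back to linear
#' interpolation between the bracketing samples.
#'
#' @param trace A \code{relax_trace}.
#' @return Object of class \code{maxwell_fit} with \code{sigma0},
#'   \code{tau}, \code{method = "one_over_e"}, \code{rmse} (against the
#'   implied single exponential).
#' @examples
#' tr <- relax_trace(seq(0, 60, by = 0.5), 5 * exp(-seq(0, 60, by = 0.5) / 10))
#' coef(relaxation_time_1e(tr))["tau"]  # 10
#' @export
relaxation_time_1e <- function(trace) {
  t <- trace$time_s; s <- trace$stress_Pa
  sigma0 <- s[1]
  if (!is.finite(sigma0) || sigma0 <= 0)
    stop("sigma0 (earliest stress sample) must be positive", call. = FALSE)
  target <- sigma0 / exp(1)
  below <- which(s <= target)
  if (!length(below)) {
    stop(sprintf("trace has not relaxed to sigma0/e within %g s (tau > %g s)",
                 t[length(t)], t[length(t)]), call. = FALSE)
  }
  j <- below[1]
  tau <- NA_real_
  W <- which(s > 0 & abs(log(s / target)) <= 0.4)
  if (length(W) >= 3L) {
    fw <- stats::lm.fit(cbind(1, t[W]), log(s[W]))
    if (is.finite(fw$coefficients[2]) && fw$coefficients[2] < 0)
      tau <- unname((log(target) - fw$coefficients[1]) / fw$coefficients[2])
  }
  if (!is.finite(tau) || tau < 0) {
    tau <- if (j == 1L) t[1] else {
      t[j - 1] + (target - s[j - 1]) * (t[j] - t[j - 1]) / (s[j] - s[j - 1])
    }
  }
  new_maxwell_fit(sigma0, tau, "one_over_e", trace)
}

#' Least-squares Maxwell fit of a stress-relaxation trace
#'
#' Fits \eqn{\ln\sigma = \ln\sigma_0 - t/\tau} by ordinary least squares
#' when all stresses are positive; otherwise falls back to a nonlinear
#' least-squares fit of \eqn{\sigma = \sigma_0 e^{-t/\tau}}. The RMSE (in
#' Pa, against the fitted exponential) flags departures from
#' single-exponential behaviour.
#'
#' @param trace A \code{relax_trace}.
#' @return Object of class \code{maxwell_fit} (method
#'   \code{"least_squares"}).
#' @export
fit_maxwell <- function(trace) {
  t <- trace$time_s; s <- trace$stress_Pa
  if (stats::var(s) == 0)
    stop("degenerate trace: stress has zero variance", call. = FALSE)
  if (all(s > 0)) {
    fit <- stats::lm(log(s) ~ t)
    slope <- stats::coef(fit)[2]
    if (slope >= 0)
      stop("stress does not decay; no Maxwell relaxation time", call. = FALSE)
    tau <- -1 / slope
    sigma0 <- exp(stats::coef(fit)[1])
  } else {
    start <- list(sigma0 = max(s), tau = max(t[2], diff(range(t)) / 3))
    fit <- stats::nls(s ~ sigma0 * exp(-t / tau), start = start,
                      control = stats::nls.control(warnOnly = TRUE))
    cf <- stats::coef(fit)
    sigma0 <- cf[["sigma0"]]; tau <- cf[["tau"]]
    if (tau <= 0) stop("nonlinear fit returned non-positive tau", call. = FALSE)
  }
  new_maxwell_fit(unname(sigma0), unname(tau), "least_squares", trace)
}

new_maxwell_fit <- function(sigma0, tau, method, trace) {
  pred <- sigma0 * exp(-trace$time_s / tau)
  structure(list(sigma0 = sigma0, tau = tau, method = method,
                 rmse = sqrt(mean((trace$stress_Pa - pred)^2)),
                 trace = trace),
            class = "maxwell_fit")
}

#' @export
print.maxwell_fit <- function(x, ...) {
  cat(sprintf("Maxwell fit (%s): tau = %.4g s, sigma0 = %.4g Pa, rmse = %.3g Pa\n",
              x$method, x$tau, x$sigma0, x$rmse))
  invisible(x)
}

#' @export
coef.maxwell_fit <- function(object, ...) {
  c(sigma0 = object$sigma0, tau = object$tau)
}

#' @export
predict.maxwell_fit <- function(object, time_s = object$trace$time_s, ...) {
  object$sigma0 * exp(-time_s / object$tau)
}

#' @export
residuals.maxwell_fit <- function(object, ...) {
  object$trace$stress_Pa - predict(object)
}

#' @export
plot.maxwell_fit <- function(x, ...) {
  graphics::plot(x$trace$time_s, x$trace$stress_Pa, xlab = "time (s)",
                 ylab = "stress (Pa)", main = sprintf("Maxwell fit (%s)", x$method),
                 ...)
  graphics::lines(x$trace$time_s, predict(x), col = 2, lwd = 2)
  graphics::abline(h = x$sigma0 / exp(1), lty = 3)
  invisible(x)
}

#' Viscoelastic phase angle
#'
#' \eqn{\delta = \mathrm{atan2}(G'', G')} in degrees, in [0, 90]:
#' ~0 degrees for an elastic solid, approaching 90 for a viscous liquid.
#'
#' @param g_prime,g_double_prime Moduli in Pa (>= 0, not both zero);
#'   vectorized.
#' @return Phase angle(s) in degrees.
#' @export
phase_angle <- function(g_prime, g_double_prime) {
  if (any(g_prime < 0) || any(g_double_prime < 0))
    stop("moduli must be non-negative", call. = FALSE)
  if (any(g_prime == 0 & g_double_prime == 0))
    stop("phase angle undefined when both moduli are zero", call. = FALSE)
  atan2(g_double_prime, g_prime) * 180 / pi
}

#' Gel melting point from a temperature sweep
#'
#' The gel point is taken as the first G' = G'' crossover (phase angle
#' 45 degrees) in sweep order, linearly interpolated in
#' \eqn{(T, G' - G'')}. All crossovers are listed when several exist.
#'
#' @param sweep An \code{oscillatory_trace} over temperature.
#' @return List: \code{melting_point_C}, \code{direction}
#'   (\code{"heating"}/\code{"cooling"}), \code{all_crossovers_C}.
#' @export
gel_melting_point <- function(sweep) {
  T_ <- sweep$abscissa
  d <- sweep$Gp_Pa - sweep$Gpp_Pa
  n <- length(d)
  # sign changes between consecutive samples, plus exact touches, in sweep order
  hits <- numeric(0)
  for (i in seq_len(n - 1L)) {
    if (d[i] == 0) hits <- c(hits, T_[i])
    else if (d[i] * d[i + 1] < 0)
      hits <- c(hits, T_[i] - d[i] * (T_[i + 1] - T_[i]) / (d[i + 1] - d[i]))
  }
  if (d[n] == 0) hits <- c(hits, T_[n])
  if (!length(hits)) {
    stop(sprintf("no G'/G'' crossover in sweep (phase angle %.1f deg at end of range)",
                 phase_angle(sweep$Gp_Pa[n], sweep$Gpp_Pa[n])),
         call. = FALSE)
  }
  list(melting_point_C = hits[1],
       direction = if (T_[n] >= T_[1]) "heating" else "cooling",
       all_crossovers_C = hits)
}

#' Self-healing recovery ratio from strain cycling
#'
#' Compares the storage-modulus plateau of the last healing period with the
#' first: \eqn{100 \times \bar{G}'_{last} / \bar{G}'_{first}}, each
#' averaged over the final \code{window} fraction of its healing period
#' (default last 50%, where the plateau has stabilized).
#'
#' @param cycles An \code{oscillatory_trace} with \code{cycle} and
#'   \code{period} (\code{"h"}/\code{"b"}) labels.
#' @param window Final fraction of each healing period to average.
#' @return Recovery in percent.
#' @export
recovery_ratio <- function(cycles, window = 0.5) {
  if (is.null(cycles$cycle) || is.null(cycles$period))
    stop("trace lacks cycle/period labels", call. = FALSE)
  stopifnot(window > 0, window <= 1)
  h <- cycles[cycles$period == "h", ]
  ids <- sort(unique(h$cycle))
  if (length(ids) < 2L)
    stop("need at least 2 labelled healing periods", call. = FALSE)
  plateau <- function(cyc) {
    seg <- h[h$cycle == cyc, ]
    n <- nrow(seg)
    keep <- seq.int(max(1L, n - ceiling(window * n) + 1L), n)
    mean(seg$Gp_Pa[keep])
  }
  100 * plateau(ids[length(ids)]) / plateau(ids[1])
}

#' Crosslinking efficiency as a function of temperature
#'
#' Applies the affine-network inversion pointwise along a temperature sweep
#' of G': the temperature enters both the measured modulus and the
#' \eqn{k_B T} denominator.
#'
#' @param sweep An \code{oscillatory_trace} over temperature (deg C).
#' @param p A \code{polymer_spec}.
#' @param model Passed to \code{\link{theoretical_max_modulus}}.
#' @return data.frame: \code{temp_C}, \code{g_prime_Pa}, \code{g_max_Pa},
#'   \code{efficiency}.
#' @export
efficiency_vs_temperature <- function(sweep, p, model = c("affine", "phantom")) {
  model <- match.arg(model)
  T_K <- sweep$abscissa + 273.15
  g_max <- vapply(T_K, function(tk) theoretical_max_modulus(p, tk, model),
                  numeric(1))
  data.frame(temp_C = sweep$abscissa, g_prime_Pa = sweep$Gp_Pa,
             g_max_Pa = g_max, efficiency = sweep$Gp_Pa / g_max)
}
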