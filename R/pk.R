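#' Pharmacokinetic parameters of the microdose delivery
#'
#' @param c_inc Blood nicotine increment per puff, ng/mL (> 0).
#' @param elimination_rate First-order elimination rate, 1/s. The default 0
#'   treats delivery as linear in time with no within-session clearance; a
#'   positive rate supports adaptation to shorter-half-life compounds.
#' @return A `pk_params` object.
#' @export
pk_params <- function(c_inc = 0.6, elimination_rate = 0) {
  stopifnot(c_inc > 0, elimination_rate >= 0)
  structure(list(c_inc = c_inc, elimination_rate = elimination_rate),
            class = "pk_params")
}

#' Simulate the blood nicotine concentration under a puff schedule
#'
#' With zero elimination, concentration is a step function:
#' `c(t) = c_inc * #(puffs with onset <= t)`. With elimination rate `k > 0`
#' each puff contributes `c_inc * exp(-k * (t - onset))`.
#'
#' @param schedule A `puff_schedule`.
#' @param pk A [pk_params()].
#' @param dt Sampling interval of the output grid, seconds (> 0).
#' @return A `concentration_trace`: list with `t` (0 to session length by
#'   `dt`) and `c` (ng/mL).
#' @export
simulate_concentration <- function(schedule, pk = pk_params(), dt = 1) {
  stopifnot(inherits(schedule, "puff_schedule"), inherits(pk, "pk_params"),
            dt > 0)
  t <- seq(0, schedule$session_length, by = dt)
  k <- pk$elimination_rate
  c <- numeric(length(t))
  for (on in schedule$puff_onsets) {
    idx <- t >= on
    c[idx] <- c[idx] + if (k > 0) pk$c_inc * exp(-k * (t[idx] - on)) else pk$c_inc
  }
  structure(list(t = t, c = c), class = "concentration_trace")
}

#' @export
print.concentration_trace <- function(x, ...) {
  cat(sprintf("<concentration_trace: %d samples, final %.2f ng/mL>\n",
              length(x$t), x$c[length(x$c)]))
  invisible(x)
}

#' Write a concentration trace as two-column TSV (t, c)
#' @param trace A `concentration_trace`.
#' @param path TSV path.
#' @return The path, invisibly.
#' @export
write_concentration_tsv <- function(trace, path) {
  write.table(data.frame(t = trace$t, c = trace$c), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Fit the exponential craving model to a trace
#'
#' Nonlinear least squares of `rating(t) = A + B * exp(-(t - t0)/tau)` on the
#' samples at `t >= t0`. Initialisation: `A0` is the mean of the last 10% of
#' samples, `B0` the mean of the first 10% minus `A0`, `tau0` one third of the
#' fitted span; bounds constrain `tau` to (1 s, 10 * span) and `B >= 0`.
#' Samples sitting on the scale bounds (0 or `scale_max`) are censored and
#' excluded, with a message reporting the count. The fit is deterministic.
#'
#' @param trace A `craving_trace`.
#' @param t0 Start of the fitted span, seconds (usually the first puff onset).
#' @return A `craving_fit`: `A`, `B`, `tau`, standard errors `se_A`, `se_B`,
#'   `se_tau`, `n_excluded`, and slots `c0` / `tau_puffs` filled by
#'   [decay_concentration()] / [decay_in_puffs()].
#' @export
fit_craving_model <- function(trace, t0 = trace$t[1]) {
  stopifnot(inherits(trace, "craving_trace"))
  if (t0 < trace$t[1] || t0 > trace$t[length(trace$t)])
    stop("t0 must lie inside the trace")
  keep <- trace$t >= t0
  tt <- trace$t[keep] - t0
  y <- trace$rating[keep]
  clipped <- y <= 0 | y >= trace$scale_max
  if (any(clipped)) {
    message(sum(clipped), " clipped sample(s) excluded from the craving fit")
    tt <- tt[!clipped]; y <- y[!clipped]
  }
  if (length(y) < 4) stop("fewer than 4 usable samples; cannot fit")
  span <- max(tt) - min(tt)
  if (stats::sd(y) < 1e-12) {
    # flat trace: amplitude indistinguishable from zero, tau unidentifiable
    warning("trace is constant; returning B = 0 with tau fixed at its start value")
    return(structure(list(A = mean(y), B = 0, tau = max(span / 3, 1.5),
                          se_A = 0, se_B = NA_real_, se_tau = NA_real_,
                          n_excluded = sum(clipped),
                          c0 = NA_real_, tau_puffs = NA_real_),
                     class = "craving_fit"))
  }
  A0 <- mean(y[tt >= stats::quantile(tt, 0.9)])
  B0 <- max(mean(y[tt <= stats::quantile(tt, 0.1)]) - A0, 0)
  tau0 <- max(span / 3, 1.5)
  start <- c(A = A0, B = B0, tau = tau0)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A + B * exp(-tt / tau),
                      start = as.list(start),
                      lower = c(A = -Inf, B = 0, tau = 1),
                      upper = c(A = Inf, B = Inf, tau = 10 * span),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stop("craving fit did not converge (start A=", signif(A0, 4), ", B=",
           signif(B0, 4), ", tau=", signif(tau0, 4), "): ",
           conditionMessage(e)))
  est <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) setNames(rep(NA_real_, 3), names(est)))
  if (3 * est[["tau"]] > span)
    warning("trace covers less than 3 fitted decay times; tau is weakly ",
            "constrained")
  structure(list(A = est[["A"]], B = est[["B"]], tau = est[["tau"]],
                 se_A = se[["A"]], se_B = se[["B"]], se_tau = se[["tau"]],
                 n_excluded = sum(clipped),
                 c0 = NA_real_, tau_puffs = NA_real_),
            class = "craving_fit")
}

#' Construct a craving fit from known parameters
#'
#' Convenience constructor used when the model parameters come from an
#' external report rather than a fitted trace.
#'
#' @param A,B,tau Model parameters (`tau > 0`, `B >= 0`).
#' @return A `craving_fit` with missing standard errors.
#' @export
craving_fit <- function(A, B, tau) {
  stopifnot(tau > 0, B >= 0)
  structure(list(A = A, B = B, tau = tau,
                 se_A = NA_real_, se_B = NA_real_, se_tau = NA_real_,
                 n_excluded = 0L, c0 = NA_real_, tau_puffs = NA_real_),
            class = "craving_fit")
}

#' @export
print.craving_fit <- function(x, ...) {
  cat(sprintf("<craving_fit: A = %.3g +/- %.2g, B = %.3g +/- %.2g, tau = %.4g +/- %.2g s>\n",
              x$A, x$se_A, x$B, x$se_B, x$tau, x$se_tau))
  if (!is.na(x$c0))
    cat(sprintf("  decay concentration %.2f ng/mL%s\n", round(x$c0, 2),
                if (!is.na(x$tau_puffs))
                  sprintf(" (%.1f puffs)", round(x$tau_puffs, 1)) else ""))
  invisible(x)
}

check_fixed_interval <- function(schedule) {
  if (!inherits(schedule, "puff_schedule") ||
      schedule$mode != "fixed_interval")
    stop("conversion to concentration units requires a fixed-interval ",
         "schedule (ad-libitum spacing is not constant)")
}

#' Decay concentration of the craving-concentration exponential
#'
#' Under a fixed-interval protocol concentration grows linearly in time
#' (`c_inc` per `iti` seconds), so the temporal decay constant `tau` maps to
#' a concentration decay constant `c0 = c_inc * tau / iti`: craving follows
#' `A + B * exp(-c / c0)` in concentration units. The result is also stored
#' into the returned fit's `c0` slot (the fit is returned as attribute
#' `"fit"`).
#'
#' @param fit A `craving_fit`.
#' @param schedule A fixed-interval `puff_schedule`.
#' @param pk A [pk_params()].
#' @return The decay concentration in ng/mL, with the updated fit attached as
#'   attribute `fit`.
#' @examples
#' f <- craving_fit(A = 4.2, B = 3.2, tau = 310)
#' s <- generate_puff_schedule(iti = 120, n_puffs = 20)
#' decay_concentration(f, s)  # 0.6 * 310 / 120 = 1.55 ng/mL
#' @export
decay_concentration <- function(fit, schedule, pk = pk_params()) {
  stopifnot(inherits(fit, "craving_fit"), inherits(pk, "pk_params"))
  check_fixed_interval(schedule)
  c0 <- pk$c_inc * fit$tau / schedule$iti
  fit$c0 <- c0
  structure(c0, fit = fit)
}

#' Decay time expressed in puffs
#'
#' `tau / iti`: how many inter-puff intervals one craving decay time spans.
#' Reported to one decimal; the unrounded value is retained in attribute
#' `"unrounded"` and in the updated fit (attribute `"fit"`).
#'
#' @inheritParams decay_concentration
#' @return The decay time in puffs, rounded to one decimal.
#' @export
decay_in_puffs <- function(fit, schedule) {
  stopifnot(inherits(fit, "craving_fit"))
  check_fixed_interval(schedule)
  raw <- fit$tau / schedule$iti
  fit$tau_puffs <- raw
  structure(round(raw, 1), unrounded = raw, fit = fit)
}

#' Delivery efficiency of a puff
#'
#' Fraction of the nebulized dose that reaches the blood: the per-puff blood
#' increment times the distribution volume, over the nebulized mass. The
#' distribution volume is a configuration constant, not an estimate; its
#' default makes a 0.6 ng/mL increment from a 0.1 mg puff come out near 3.4%.
#'
#' @param pk A [pk_params()] (uses `c_inc`, ng/mL).
#' @param dose_per_puff Nebulized dose, mg.
#' @param blood_volume Distribution volume, litres (> 0).
#' @return Efficiency as a fraction in `[0, 1]` (no rounding).
#' @export
delivery_efficiency <- function(pk = pk_params(),
                                dose_per_puff = puff_dose_mg(),
                                blood_volume = 5.6) {
  stopifnot(inherits(pk, "pk_params"), blood_volume > 0, dose_per_puff > 0)
  # ng delivered to blood = c_inc [ng/mL] * volume [mL]; dose mg -> ng
  (pk$c_inc * blood_volume * 1000) / (dose_per_puff * 1e6)
}

#' Craving as a function of blood nicotine concentration
#'
#' Returns the callable `c -> A + B * exp(-c / c0)`; requires `fit$c0` to
#' have been derived (see [decay_concentration()]).
#'
#' @param fit A `craving_fit` with `c0` set.
#' @return A function of concentration (ng/mL).
#' @export
craving_vs_concentration <- function(fit) {
  stopifnot(inherits(fit, "craving_fit"))
  if (is.na(fit$c0))
    stop("fit$c0 is unset; derive it with decay_concentration() first")
  A <- fit$A; B <- fit$B; c0 <- fit$c0
  function(c) A + B * exp(-c / c0)
}

#' Craving-model parameter recovery experiment
#'
#' Simulates `n_sim` craving traces from known parameters under a
#' fixed-interval schedule, adds Gaussian noise, refits each with
#' [fit_craving_model()], and summarises the recovered parameters. Used to
#' check that the fitting procedure recovers the generating values within
#' their reported uncertainty.
#'
#' @param n_sim Number of simulated traces.
#' @param A,B,tau Generating parameters.
#' @param noise_sd Noise SD per 1 Hz sample.
#' @param iti,n_puffs,baseline_length Fixed-interval protocol.
#' @param post_t0 Length of the fitted span after the first puff, seconds.
#' @param scale_max Rating scale ceiling.
#' @param seed Base seed; trace `i` uses `seed + i`.
#' @return List with vectors `A_hat`, `B_hat`, `tau_hat` and medians
#'   `median_A`, `median_B`, `median_tau`.
#' @export
recovery_experiment <- function(n_sim = 100, A = 4.2, B = 3.2, tau = 310,
                                noise_sd = 0.3, iti = 120, n_puffs = 20,
                                baseline_length = 300, post_t0 = 2400,
                                scale_max = 10, seed = 1L) {
  schedule <- generate_puff_schedule(
    "fixed_interval", iti = iti, n_puffs = n_puffs,
    baseline_length = baseline_length,
    session_length = baseline_length + post_t0)
  fits <- lapply(seq_len(n_sim), function(i) {
    trace <- generate_craving_trace(schedule, A = A, B = B, tau = tau,
                                    noise_sd = noise_sd,
                                    scale_max = scale_max, seed = seed + i)
    fit_craving_model(trace, t0 = schedule$puff_onsets[1])
  })
  A_hat <- vapply(fits, `[[`, numeric(1), "A")
  B_hat <- vapply(fits, `[[`, numeric(1), "B")
  tau_hat <- vapply(fits, `[[`, numeric(1), "tau")
  list(A_hat = A_hat, B_hat = B_hat, tau_hat = tau_hat,
       median_A = median(A_hat), median_B = median(B_hat),
       median_tau = median(tau_hat))
}
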