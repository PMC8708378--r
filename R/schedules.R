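#' Default labels for the 23 addiction-circuit regions
#'
#' The driver-node analysis operates on 23 regions of the prefrontal-limbic
#' reward circuit. The exact atlas is user-supplied in practice; this default
#' list names the anterior cingulate cortex plus eleven bilateral structures
#' commonly implicated in nicotine addiction, and is used by the synthetic
#' generator.
#'
#' @return Character vector of length 23.
#' @export
addiction_regions <- function() {
  bilat <- c("Nucleus Accumbens", "Amygdala", "Hippocampus", "Caudate",
             "Putamen", "Pallidum", "Insula", "Thalamus",
             "Orbitofrontal Cortex", "Dorsolateral Prefrontal Cortex",
             "Ventral Tegmental Area")
  c("Anterior Cingulate Cortex",
    as.vector(rbind(paste0(bilat, " (Left)"), paste0(bilat, " (Right)"))))
}

#' Nicotine content of one nebulized puff
#'
#' One puff dispenses a fixed volume of stock nicotine solution; the default
#' arguments describe a 10 uL puff of a 3 mg / 300 uL nasal-spray stock,
#' i.e. 0.1 mg nicotine per puff (one cigarette equals ten puffs).
#'
#' @param volume_ul Dispensed volume per puff in microlitres.
#' @param stock_mg Nicotine mass in the loaded stock, mg.
#' @param stock_volume_ul Volume of the loaded stock, microlitres.
#' @return Dose per puff in mg nicotine.
#' @export
puff_dose_mg <- function(volume_ul = 10, stock_mg = 3, stock_volume_ul = 300) {
  stopifnot(volume_ul > 0, stock_mg > 0, stock_volume_ul > 0)
  stock_mg * volume_ul / stock_volume_ul
}

new_puff_schedule <- function(mode, puff_onsets, dose_per_puff, iti,
                              session_length, baseline_length) {
  sched <- structure(
    list(mode = mode, puff_onsets = puff_onsets,
         dose_per_puff = dose_per_puff, iti = iti,
         session_length = session_length, baseline_length = baseline_length),
    class = "puff_schedule")
  validate_puff_schedule(sched)
}

validate_puff_schedule <- function(sched) {
  on <- sched$puff_onsets
  if (sched$dose_per_puff <= 0) stop("dose_per_puff must be > 0")
  if (length(on) && any(diff(on) <= 0)) stop("puff onsets must be strictly increasing")
  if (length(on) && on[1] < sched$baseline_length)
    stop("first puff onset ", on[1], " s precedes the end of baseline (",
         sched$baseline_length, " s)")
  bad <- which(on > sched$session_length)
  if (length(bad))
    stop("puff onset ", on[bad[1]], " s exceeds session_length ",
         sched$session_length, " s")
  if (sched$mode == "ad_libitum") {
    if (length(on) > 20) stop("ad-libitum schedules are capped at 20 puffs")
    if (length(on) > 1 && any(diff(on) < 120))
      stop("ad-libitum puffs must be at least 120 s apart")
  }
  sched
}

#' Generate a puff delivery schedule
#'
#' Fixed-interval schedules place `n_puffs` onsets at
#' `baseline_length + k * iti`, `k = 0, ..., n_puffs - 1`, emulating the
#' 2-minute (20 puffs) and 4-minute (10 puffs) protocols. `mode =
#' "ad_libitum"` delegates to [generate_adlib_behavior()] with its default
#' craving model.
#'
#' @param mode `"fixed_interval"` or `"ad_libitum"`.
#' @param iti Inter-trial interval in seconds (fixed mode).
#' @param n_puffs Number of puffs (>= 1).
#' @param dose_per_puff mg nicotine per puff; default [puff_dose_mg()].
#' @param baseline_length Pre-dosing baseline in seconds.
#' @param session_length Total session length in seconds.
#' @param seed Integer seed (used by the ad-libitum generator).
#' @return A `puff_schedule` object.
#' @examples
#' generate_puff_schedule(iti = 120, n_puffs = 20)$puff_onsets
#' @export
generate_puff_schedule <- function(mode = c("fixed_interval", "ad_libitum"),
                                   iti = 120, n_puffs = 20,
                                   dose_per_puff = puff_dose_mg(),
                                   baseline_length = 300,
                                   session_length = 3600, seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "ad_libitum")
    return(generate_adlib_behavior(session_length = session_length,
                                   max_puffs = n_puffs,
                                   dose_per_puff = dose_per_puff,
                                   baseline_length = baseline_length,
                                   seed = seed))
  stopifnot(n_puffs >= 1)
  if (n_puffs > 1 && (!is.numeric(iti) || iti <= 0))
    stop("fixed_interval mode requires iti > 0")
  onsets <- baseline_length + (seq_len(n_puffs) - 1) * iti
  new_puff_schedule("fixed_interval", onsets, dose_per_puff, iti,
                    session_length, baseline_length)
}

#' @export
print.puff_schedule <- function(x, ...) {
  cat(sprintf("<puff_schedule: %s, %d puffs, dose %.3g mg, session %g s>\n",
              x$mode, length(x$puff_onsets), x$dose_per_puff,
              x$session_length))
  invisible(x)
}

#' Simulate ad-libitum self-administration from the craving model
#'
#' A behavioural model of the self-administration protocol: craving follows
#' `A + B * exp(-c_eff / c0)` where the effective concentration `c_eff` jumps
#' by `c_inc` at each puff and relaxes with time constant `tau` between puffs,
#' so craving is knocked down along the fitted concentration-craving curve
#' after every puff and recovers towards `A + B` as the effect washes out.
#' The subject requests a puff at the first second at which craving reaches
#' `threshold` and the refractory period has elapsed; the first puff is
#' delivered at the end of the baseline. The model is deterministic; `seed`
#' is accepted for interface uniformity with the other generators.
#'
#' @param A,B,tau Craving-model parameters (asymptote, amplitude, decay s).
#' @param c_inc Blood concentration increment per puff, ng/mL.
#' @param threshold Craving level triggering a request; must lie in (A, A+B).
#' @param refractory Minimum spacing between puffs, seconds.
#' @param session_length Session length, seconds.
#' @param max_puffs Hard cap on puffs (protocol ceiling 20).
#' @param dose_per_puff mg nicotine per puff.
#' @param baseline_length Seconds before the first (free) puff.
#' @param seed Integer seed (unused by the deterministic core).
#' @return A `puff_schedule` with `mode = "ad_libitum"`.
#' @export
generate_adlib_behavior <- function(A = 4.2, B = 3.2, tau = 310,
                                    c_inc = 0.6, threshold = 6.5,
                                    refractory = 120,
                                    session_length = 2400, max_puffs = 20,
                                    dose_per_puff = puff_dose_mg(),
                                    baseline_length = 0, seed = 1L) {
  stopifnot(tau > 0, refractory > 0, c_inc > 0)
  if (threshold <= A || threshold >= A + B)
    stop("threshold must lie strictly between A and A + B")
  c0 <- c_inc * tau / refractory
  onsets <- baseline_length
  c_eff <- c_inc
  t_last <- baseline_length
  t <- baseline_length + 1
  while (t <= session_length && length(onsets) < max_puffs) {
    craving <- A + B * exp(-c_eff * exp(-(t - t_last) / tau) / c0)
    if (t - t_last >= refractory && craving >= threshold) {
      c_eff <- c_eff * exp(-(t - t_last) / tau) + c_inc
      t_last <- t
      onsets <- c(onsets, t)
    }
    t <- t + 1
  }
  new_puff_schedule("ad_libitum", onsets, dose_per_puff, NA_real_,
                    session_length, baseline_length)
}

#' Generate a 1 Hz craving trace from a puff schedule
#'
#' Before the first puff the subject is in withdrawal and craving sits at the
#' model ceiling `A + B`; from the first puff onward craving relaxes as
#' `A + B * exp(-(t - t0)/tau)`. Gaussian noise is added per sample and the
#' result clipped to `[0, scale_max]`.
#'
#' @param schedule A `puff_schedule`; its first onset sets `t0`.
#' @param A,B,tau Craving-model parameters.
#' @param noise_sd Gaussian noise SD (>= 0).
#' @param scale_max Upper bound of the rating scale.
#' @param seed Integer seed; identical seeds give identical traces.
#' @return A `craving_trace`: list with `t` (0, 1, ..., session_length - 1),
#'   `rating`, `scale_max`.
#' @export
generate_craving_trace <- function(schedule, A = 4.2, B = 3.2, tau = 310,
                                   noise_sd = 0, scale_max = 10, seed = 1L) {
  stopifnot(inherits(schedule, "puff_schedule"), tau > 0, noise_sd >= 0)
  t0 <- schedule$puff_onsets[1]
  t <- seq(0, schedule$session_length - 1)
  mu <- ifelse(t < t0, A + B, A + B * exp(-(t - t0) / tau))
  eps <- if (noise_sd > 0) {
    set.seed(as.integer(seed))
    rnorm(length(t), 0, noise_sd)
  } else 0
  rating <- pmin(pmax(mu + eps, 0), scale_max)
  structure(list(t = t, rating = rating, scale_max = scale_max),
            class = "craving_trace")
}

#' @export
print.craving_trace <- function(x, ...) {
  cat(sprintf("<craving_trace: %d samples at 1 Hz, scale 0-%g, mean %.2f>\n",
              length(x$t), x$scale_max, mean(x$rating)))
  invisible(x)
}

#' Write / read an events table (BIDS-style TSV)
#'
#' Columns `onset`, `duration`, `trial_type` with onsets in seconds to three
#' decimals; one `baseline` row followed by one `puff` row per delivery (each
#' puff nebulizes over 3 s).
#'
#' @param schedule A `puff_schedule`.
#' @param path Output TSV path.
#' @return `write_events_tsv`: the path, invisibly. `read_events_tsv`: a
#'   data.frame with the three columns.
#' @export
write_events_tsv <- function(schedule, path) {
  ev <- data.frame(
    onset = sprintf("%.3f", c(0, schedule$puff_onsets)),
    duration = sprintf("%.3f", c(schedule$baseline_length,
                                 rep(3, length(schedule$puff_onsets)))),
    trial_type = c("baseline", rep("puff", length(schedule$puff_onsets))),
    stringsAsFactors = FALSE)
  write.table(ev, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  ev <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("onset", "duration", "trial_type")
  if (!all(need %in% names(ev)))
    stop("events file must have columns onset, duration, trial_type")
  ev$onset <- as.numeric(ev$onset)
  ev$duration <- as.numeric(ev$duration)
  ev
}

#' Puff onsets recorded in an events table
#' @param events Events data.frame from [read_events_tsv()].
#' @return Numeric vector of puff onset times, seconds.
#' @export
puff_onsets_from_events <- function(events) {
  as.numeric(events$onset[events$trial_type == "puff"])
}

#' Write / read a craving trace as two-column TSV (t, rating)
#' @param trace A `craving_trace`.
#' @param path TSV path.
#' @param scale_max Scale ceiling assumed when reading.
#' @return The path invisibly, or the reconstructed `craving_trace`.
#' @export
write_craving_tsv <- function(trace, path) {
  write.table(data.frame(t = trace$t, rating = trace$rating), path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_craving_tsv
#' @export
read_craving_tsv <- function(path, scale_max = 10) {
  d <- read.delim(path)
  if (!all(c("t", "rating") %in% names(d)))
    stop("craving trace file must have columns t, rating")
  dt <- diff(d$t)
  if (length(dt) && any(abs(dt - 1) > 1e-9))
    stop("craving trace must be sampled on a uniform 1 s grid")
  structure(list(t = d$t, rating = d$rating, scale_max = scale_max),
            class = "craving_trace")
}
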