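run_config_defaults <- function() {
  list(
    # acquisition / windowing
    tr = 0.802, window_length_trs = 38L, n_windows = 10L,
    # state analysis
    threshold = 0.65, strength_mode = "signed", linkage = "average",
    k = "auto",
    # protocol
    iti = 240, n_puffs = 10L, baseline_length = 305, session_length = 2700,
    dose_per_puff = 0.1, max_puffs = 20L,
    # pharmacokinetics / craving model
    c_inc = 0.6, blood_volume = 5.6,
    A = 4.2, B = 3.2, tau = 310, noise_sd = 0.3, scale_max = 10,
    # planted structure (simulation only)
    n_states = 3L, module_size = 7L, hub = "Anterior Cingulate Cortex",
    within_edge_r = 0.8, background_r = 0.1,
    # control analysis
    top_k = 2L, candidate_policy = "union", neighborhood = "open",
    # run control
    seed = 1L, simulate = TRUE, subject = "sim01",
    roi_path = NULL, events_path = NULL, craving_path = NULL, out_dir = NULL)
}

#' Build and validate a run configuration
#'
#' Either pass overrides directly or point `file` at a flat YAML file.
#' Defaults mirror the fixed-interval imaging protocol: TR 0.802 s, 38-TR
#' windows, 10 windows per condition, binarization threshold 0.65, ITI 240 s,
#' 0.1 mg per puff. Unknown keys are rejected.
#'
#' @param ... Named overrides of the defaults.
#' @param file Optional YAML file of overrides (applied before `...`).
#' @return A validated `run_config` list.
#' @export
run_config <- function(..., file = NULL) {
  cfg <- run_config_defaults()
  override <- list()
  if (!is.null(file)) override <- yaml::read_yaml(file)
  override <- utils::modifyList(override, list(...))
  unknown <- setdiff(names(override), names(cfg))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(cfg, override, keep.null = TRUE)

  num_pos <- c("tr", "threshold", "iti", "session_length", "dose_per_puff",
               "c_inc", "blood_volume", "tau", "scale_max")
  for (key in num_pos)
    if (!is.numeric(cfg[[key]]) || cfg[[key]] <= 0)
      stop("config key '", key, "' must be a positive number")
  if (cfg$noise_sd < 0) stop("config key 'noise_sd' must be >= 0")
  if (cfg$baseline_length < 0) stop("config key 'baseline_length' must be >= 0")
  for (key in c("window_length_trs", "n_windows", "n_puffs", "top_k",
                "max_puffs", "n_states", "module_size", "seed"))
    if (!is.numeric(cfg[[key]]) || cfg[[key]] < 1)
      stop("config key '", key, "' must be a positive integer")
  if (!cfg$strength_mode %in% c("signed", "absolute"))
    stop("config key 'strength_mode' must be 'signed' or 'absolute'")
  if (!cfg$candidate_policy %in% c("union", "first"))
    stop("config key 'candidate_policy' must be 'union' or 'first'")
  if (!cfg$neighborhood %in% c("open", "closed"))
    stop("config key 'neighborhood' must be 'open' or 'closed'")
  if (!identical(cfg$k, "auto") &&
      (!is.numeric(cfg$k) || cfg$k < 1))
    stop("config key 'k' must be 'auto' or a positive integer")
  if (!is.logical(cfg$simulate))
    stop("config key 'simulate' must be TRUE or FALSE")
  if (!cfg$simulate &&
      (is.null(cfg$roi_path) || is.null(cfg$events_path)))
    stop("without simulate = TRUE, roi_path and events_path are required")
  structure(cfg, class = "run_config")
}

# Small rolling hash for the provenance block (config fingerprinting only).
config_hash <- function(cfg) {
  s <- paste(deparse(cfg[order(names(cfg))]), collapse = "")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

# Stitch a full-session ROI series: abstinence windows tile the baseline,
# satiety windows sit 38 TRs after each puff, and the remaining TRs carry
# background-only correlation. A single seed drives the whole stream.
simulate_session_series <- function(plan, schedule, tr, window_length_trs,
                                    n_windows, seed) {
  total_trs <- as.integer(ceiling(schedule$session_length / tr))
  tr_state <- integer(total_trs)             # 0 = background
  abst <- rep(plan$window_assignment[seq_len(n_windows)],
              each = window_length_trs)
  if (length(abst) > floor(schedule$puff_onsets[1] / tr))
    stop("baseline too short for ", n_windows, " abstinence windows")
  tr_state[seq_along(abst)] <- abst
  sat_starts <- floor(schedule$puff_onsets[seq_len(n_windows)] / tr) +
    window_length_trs
  if (max(sat_starts) + window_length_trs > total_trs)
    stop("session too short for the last satiety window")
  sat_assign <- plan$window_assignment[seq_len(n_windows)]
  for (i in seq_len(n_windows))
    tr_state[(sat_starts[i] + 1L):(sat_starts[i] + window_length_trs)] <-
      sat_assign[i]

  lds <- lapply(plan$states, state_loadings,
                within_edge_r = plan$within_edge_r,
                background_r = plan$background_r,
                threshold = plan$threshold)
  bg <- state_loadings(matrix(0L, plan$n_regions, plan$n_regions),
                       plan$within_edge_r, plan$background_r)
  runs <- rle(tr_state)
  set.seed(as.integer(seed))
  blocks <- mapply(function(s, len) {
    sample_block(if (s == 0L) bg else lds[[s]], len)
  }, runs$values, runs$lengths, SIMPLIFY = FALSE)
  X <- do.call(cbind, blocks)
  rownames(X) <- plan$region_labels
  new_roi_timeseries(X, tr, plan$region_labels,
                     window_assignment = plan$window_assignment)
}

#' Simulate one subject's inputs
#'
#' Produces the puff schedule, noisy craving trace, full-session ROI series
#' with planted states, and the state plan, all driven by `config$seed`.
#'
#' @param config A [run_config()].
#' @return List with `schedule`, `trace`, `ts`, `plan`.
#' @export
simulate_subject <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  schedule <- generate_puff_schedule(
    "fixed_interval", iti = config$iti, n_puffs = config$n_puffs,
    dose_per_puff = config$dose_per_puff,
    baseline_length = config$baseline_length,
    session_length = config$session_length)
  trace <- generate_craving_trace(
    schedule, A = config$A, B = config$B, tau = config$tau,
    noise_sd = config$noise_sd, scale_max = config$scale_max,
    seed = config$seed)
  plan <- state_plan(
    n_regions = 23, n_states = config$n_states, hub = config$hub,
    module_size = config$module_size, n_windows = config$n_windows,
    within_edge_r = config$within_edge_r,
    background_r = config$background_r, threshold = config$threshold)
  ts <- simulate_session_series(plan, schedule, config$tr,
                                config$window_length_trs, config$n_windows,
                                seed = config$seed + 1L)
  list(schedule = schedule, trace = trace, ts = ts, plan = plan)
}

#' Run the full per-subject analysis
#'
#' Stages, in order, for both conditions: craving-model fit with derived
#' pharmacokinetic constants; window extraction; windowed connectivity,
#' nodal strength and window similarity; state clustering; state averaging
#' and binarization; minimum-dominating-set driver accounting and target
#' selection. Identical config and seed give identical results.
#'
#' @param config A [run_config()]. With `simulate = TRUE` inputs are
#'   generated by [simulate_subject()]; otherwise `roi_path`, `events_path`
#'   and optionally `craving_path` are read.
#' @return A `subject_result`: list with `craving`, per-condition `states`
#'   and `drivers`, `targets`, and a `provenance` block. When
#'   `config$out_dir` is set, result files are written there.
#' @export
run_subject <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  if (config$simulate) {
    inputs <- simulate_subject(config)
    schedule <- inputs$schedule; trace <- inputs$trace; ts <- inputs$ts
  } else {
    ts <- read_roi_tsv(config$roi_path, tr = config$tr)
    events <- read_events_tsv(config$events_path)
    onsets <- puff_onsets_from_events(events)
    iti <- if (length(onsets) > 1) diff(onsets)[1] else config$iti
    fixed <- length(onsets) < 2 ||
      all(abs(diff(onsets) - iti) < 1e-6)
    schedule <- new_puff_schedule(
      if (fixed) "fixed_interval" else "ad_libitum", onsets,
      config$dose_per_puff, if (fixed) iti else NA_real_,
      config$session_length, min(onsets))
    trace <- if (!is.null(config$craving_path))
      read_craving_tsv(config$craving_path, scale_max = config$scale_max)
  }

  pk <- pk_params(c_inc = config$c_inc)
  craving <- NULL
  if (!is.null(trace)) {
    fit <- fit_craving_model(trace, t0 = schedule$puff_onsets[1])
    if (schedule$mode == "fixed_interval") {
      c0 <- decay_concentration(fit, schedule, pk)
      fit <- attr(c0, "fit")
      tp <- decay_in_puffs(fit, schedule)
      fit <- attr(tp, "fit")
    }
    craving <- list(
      fit = fit,
      decay_concentration_ng_ml = if (!is.na(fit$c0)) round(fit$c0, 2),
      decay_in_puffs = if (!is.na(fit$tau_puffs)) round(fit$tau_puffs, 1),
      delivery_efficiency = delivery_efficiency(
        pk, dose_per_puff = config$dose_per_puff,
        blood_volume = config$blood_volume))
  }

  conditions <- list()
  for (cond in c("abstinence", "satiety")) {
    cw <- extract_condition_windows(ts, schedule, cond,
                                    n_windows = config$n_windows,
                                    window_length_trs = config$window_length_trs)
    st <- condition_states(cw, threshold = config$threshold,
                           strength_mode = config$strength_mode,
                           linkage = config$linkage, k = config$k)
    drv <- driver_report(st$state_graphs, labels = ts$region_labels,
                         policy = config$candidate_policy,
                         neighborhood = config$neighborhood)
    conditions[[cond]] <- list(states = st, drivers = drv,
                               targets = select_targets(drv, config$top_k))
  }

  res <- structure(list(
    subject = config$subject,
    craving = craving,
    conditions = conditions,
    provenance = list(config = unclass(config),
                      config_hash = config_hash(unclass(config)),
                      seed = config$seed,
                      package_version = as.character(packageVersion("nicodyn")))),
    class = "subject_result")
  if (!is.null(config$out_dir)) write_subject_result(res, config$out_dir)
  res
}

#' @export
print.subject_result <- function(x, ...) {
  cat(sprintf("<subject_result: %s>\n", x$subject))
  if (!is.null(x$craving)) print(x$craving$fit)
  for (cond in names(x$conditions)) {
    tg <- x$conditions[[cond]]$targets
    cat(sprintf("  %s targets: %s\n", cond,
                if (nrow(tg)) paste(sprintf("%s (%.2f%%)", tg$label,
                                            tg$controlled_pct),
                                    collapse = ", ")
                else "(no common driver)"))
  }
  invisible(x)
}

#' Write a subject result to a directory
#'
#' `summary.json` holds the craving fit, derived constants, state
#' assignments, driver percentages, targets and provenance; per-state
#' connectivity matrices and binarized graphs are written as labeled TSV.
#'
#' @param res A `subject_result`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_subject_result <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  summ <- list(subject = res$subject, provenance = res$provenance)
  if (!is.null(res$craving)) {
    f <- res$craving$fit
    summ$craving <- list(
      A = f$A, B = f$B, tau = f$tau,
      se_A = f$se_A, se_B = f$se_B, se_tau = f$se_tau,
      decay_concentration_ng_ml = res$craving$decay_concentration_ng_ml,
      decay_in_puffs = res$craving$decay_in_puffs,
      delivery_efficiency = res$craving$delivery_efficiency)
  }
  for (cond in names(res$conditions)) {
    cnd <- res$conditions[[cond]]
    summ[[cond]] <- list(
      state_assignment = cnd$states$assignment,
      common_drivers = cnd$drivers$labels[cnd$drivers$common_drivers],
      controlled_pct = round(unname(cnd$drivers$controlled_pct), 2),
      targets = cnd$targets$label,
      target_pct = round(cnd$targets$controlled_pct, 2))
    for (sn in names(cnd$states$state_matrices)) {
      write_matrix_tsv(round(cnd$states$state_matrices[[sn]], 6),
                       file.path(dir, paste0(cond, "_", sn, "_connectivity.tsv")))
      write_matrix_tsv(cnd$states$state_graphs[[sn]],
                       file.path(dir, paste0(cond, "_", sn, "_graph.tsv")))
    }
    write.table(data.frame(window = seq_along(cnd$states$assignment),
                           state = cnd$states$assignment),
                file.path(dir, paste0(cond, "_states.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(summ, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Tabulate driver results across subjects
#'
#' One row per (subject, condition, common driver) with the controlled-node
#' percentage; drivers are the top-`top_k` targets of each condition, so a
#' driver absent from a condition's common set contributes no row there.
#'
#' @param results List of `subject_result` objects (or a single one).
#' @param top_k Targets per condition to list (default 2).
#' @return Data frame with `subject`, `condition`, `driver`,
#'   `controlled_pct`.
#' @export
report_table <- function(results, top_k = 2) {
  if (inherits(results, "subject_result")) results <- list(results)
  stopifnot(length(results) >= 1)
  rows <- list()
  for (res in results) {
    for (cond in names(res$conditions)) {
      tg <- res$conditions[[cond]]$targets
      tg <- head(tg, top_k)
      if (nrow(tg))
        rows[[length(rows) + 1L]] <- data.frame(
          subject = res$subject, condition = cond, driver = tg$label,
          controlled_pct = tg$controlled_pct, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(subject = character(0), condition = character(0),
                      driver = character(0), controlled_pct = numeric(0)))
  do.call(rbind, rows)
}

#' Format the driver table as text
#'
#' @param results List of `subject_result` objects.
#' @param top_k Targets per condition.
#' @return Character vector of report lines (two-decimal percentages);
#'   conditions without a common driver get an explanatory note.
#' @export
format_report <- function(results, top_k = 2) {
  if (inherits(results, "subject_result")) results <- list(results)
  lines <- sprintf("%-10s %-12s %-35s %s", "Subject", "Condition",
                   "Driver Nodes", "Controllable Nodes (% of Total)")
  for (res in results) {
    for (cond in names(res$conditions)) {
      tg <- head(res$conditions[[cond]]$targets, top_k)
      if (!nrow(tg)) {
        lines <- c(lines, sprintf("%-10s %-12s %s", res$subject, cond,
                                  "(no common driver across states)"))
      } else {
        for (i in seq_len(nrow(tg)))
          lines <- c(lines, sprintf("%-10s %-12s %-35s %.2f%%",
                                    if (i == 1) res$subject else "",
                                    if (i == 1) cond else "",
                                    tg$label[i], tg$controlled_pct[i]))
      }
    }
  }
  lines
}
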