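#' Plan the planted state structure of a synthetic ROI series
#'
#' A `state_plan` specifies a small number of brain-connectivity states as
#' 0/1 adjacency matrices over `n_regions` regions, a designated hub (driver)
#' region per state, an assignment of analysis windows to states, and the
#' target correlations: `within_edge_r` for connected pairs and
#' `background_r` for unconnected pairs.
#'
#' By default each state is a clique on the hub plus a state-specific,
#' disjoint set of `module_size - 1` leaf regions, with the hub shared across
#' all states. Cliques (rather than bare stars) are used because a star whose
#' spokes correlate at `within_edge_r` forces leaf-leaf correlations of at
#' least `within_edge_r^2`, which for the default 0.8 sits at the 0.65
#' binarization threshold and would make the planted adjacency unrecoverable
#' in principle.
#'
#' @param n_regions Number of regions (default 23).
#' @param n_states Number of planted states.
#' @param hub Index or label of the shared hub region.
#' @param module_size Clique size per state (hub + leaves).
#' @param n_windows Number of analysis windows to assign.
#' @param within_edge_r Target correlation of connected pairs.
#' @param background_r Target correlation of unconnected pairs.
#' @param threshold Binarization threshold the structure must straddle.
#' @param region_labels Region names (length `n_regions`).
#' @param states Optional list of adjacency matrices overriding the default
#'   construction (symmetric 0/1, zero diagonal).
#' @param driver_labels Optional per-state hub indices/labels (with `states`).
#' @param window_assignment Optional integer vector of state indices per
#'   window; defaults to states recycled over windows.
#' @return A `state_plan` object.
#' @export
state_plan <- function(n_regions = 23, n_states = 3, hub = 1,
                       module_size = 7, n_windows = 10,
                       within_edge_r = 0.8, background_r = 0.1,
                       threshold = 0.65,
                       region_labels = addiction_regions(),
                       states = NULL, driver_labels = NULL,
                       window_assignment = NULL) {
  stopifnot(n_regions >= 2, length(region_labels) == n_regions)
  if (!(within_edge_r > threshold && threshold > background_r))
    stop("need within_edge_r > threshold > background_r for recoverable structure")
  if (is.character(hub)) hub <- match(hub, region_labels)
  stopifnot(!is.na(hub), hub >= 1, hub <= n_regions)

  if (is.null(states)) {
    stopifnot(module_size >= 2,
              (module_size - 1) * n_states <= n_regions - 1)
    leaves_pool <- setdiff(seq_len(n_regions), hub)
    states <- vector("list", n_states)
    for (s in seq_len(n_states)) {
      members <- c(hub, leaves_pool[seq_len(module_size - 1) +
                                      (s - 1) * (module_size - 1)])
      A <- matrix(0L, n_regions, n_regions)
      A[members, members] <- 1L
      diag(A) <- 0L
      states[[s]] <- A
    }
    driver_labels <- rep(hub, n_states)
  } else {
    n_states <- length(states)
    if (is.null(driver_labels)) driver_labels <- rep(hub, n_states)
    if (is.character(driver_labels))
      driver_labels <- match(driver_labels, region_labels)
    stopifnot(length(driver_labels) == n_states)
    for (A in states) {
      stopifnot(is.matrix(A), nrow(A) == n_regions, ncol(A) == n_regions,
                all(A %in% c(0, 1)), all(A == t(A)), all(diag(A) == 0))
    }
  }
  for (s in seq_along(states)) {
    cand <- driver_candidates(list(minimum_dominating_sets(states[[s]])))[[1]]
    if (!(driver_labels[s] %in% cand))
      stop("planted hub of state ", s,
           " does not belong to any minimum dominating set of its adjacency")
  }
  if (is.null(window_assignment))
    window_assignment <- rep(seq_len(n_states), length.out = n_windows)
  stopifnot(all(window_assignment %in% seq_len(n_states)))
  structure(list(n_regions = n_regions, states = states,
                 driver_labels = driver_labels,
                 window_assignment = as.integer(window_assignment),
                 within_edge_r = within_edge_r,
                 background_r = background_r, threshold = threshold,
                 region_labels = region_labels),
            class = "state_plan")
}

#' @export
print.state_plan <- function(x, ...) {
  cat(sprintf(
    "<state_plan: %d regions, %d states, hubs {%s}, r_edge %.2f, r_bg %.2f>\n",
    x$n_regions, length(x$states),
    paste(x$region_labels[x$driver_labels], collapse = ", "),
    x$within_edge_r, x$background_r))
  invisible(x)
}

# Factor loadings realizing a planted adjacency: one latent factor per maximal
# clique (loading sqrt((r_w - bg)/k_i) for a node in k_i cliques) plus one
# global factor at sqrt(bg). For states that are unions of node-disjoint
# cliques the implied correlation is exactly r_w on edges and bg off edges;
# overlapping cliques attenuate edge correlations (warned). Residual variances
# stay positive for r_w < 1, guaranteeing a positive definite covariance.
state_loadings <- function(A, within_edge_r, background_r, threshold = NULL) {
  n <- nrow(A)
  delta <- within_edge_r - background_r
  cliques <- list()
  if (any(A > 0)) {
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
    cliques <- lapply(igraph::max_cliques(g, min = 2), as.integer)
  }
  L <- matrix(0, n, length(cliques) + 1L)
  if (length(cliques)) {
    k <- tabulate(unlist(cliques), nbins = n)
    for (ci in seq_along(cliques)) {
      m <- cliques[[ci]]
      L[m, ci] <- sqrt(delta / k[m])
    }
  }
  L[, ncol(L)] <- sqrt(background_r)
  resid <- 1 - rowSums(L^2)
  stopifnot(all(resid > 0))        # PD guard; holds whenever within_edge_r < 1
  if (!is.null(threshold) && length(cliques)) {
    R <- L %*% t(L)
    low <- which(A == 1 & R < threshold, arr.ind = TRUE)
    if (nrow(low))
      warning("overlapping cliques attenuate ", nrow(low) / 2,
              " edge correlation(s) below the binarization threshold")
  }
  list(L = L, resid_sd = sqrt(resid))
}

# One multivariate-normal block of `n_t` samples with the given loadings.
sample_block <- function(ld, n_t) {
  nf <- ncol(ld$L)
  n <- nrow(ld$L)
  F <- matrix(rnorm(nf * n_t), nf, n_t)
  ld$L %*% F + ld$resid_sd * matrix(rnorm(n * n_t), n, n_t)
}

#' Generate a multi-state ROI time series with planted hub structure
#'
#' Each window draws `window_length_trs` samples from a zero-mean
#' multivariate normal whose covariance realizes the window's planted
#' adjacency through a clique-factor construction: every maximal clique of
#' the adjacency shares a latent factor and all regions share one weak global
#' factor, calibrated so connected pairs correlate at `within_edge_r` and
#' unconnected pairs at `background_r` in expectation. The covariance is
#' positive definite by construction (positive residual variances).
#'
#' @param plan A [state_plan()].
#' @param window_length_trs Samples per window (>= 2).
#' @param tr_seconds Repetition time attached to the output, seconds.
#' @param seed Integer seed; identical seeds give identical output.
#' @return A `roi_timeseries`: list with `data` (`n_regions` x
#'   `n_windows * window_length_trs` matrix), `tr`, `region_labels`, and the
#'   ground truth `window_assignment`.
#' @export
generate_roi_timeseries <- function(plan, window_length_trs = 38,
                                    tr_seconds = 0.802, seed = 1L) {
  stopifnot(inherits(plan, "state_plan"), window_length_trs >= 2)
  lds <- lapply(plan$states, state_loadings,
                within_edge_r = plan$within_edge_r,
                background_r = plan$background_r,
                threshold = plan$threshold)
  set.seed(as.integer(seed))
  blocks <- lapply(plan$window_assignment, function(s)
    sample_block(lds[[s]], window_length_trs))
  X <- do.call(cbind, blocks)
  rownames(X) <- plan$region_labels
  new_roi_timeseries(X, tr_seconds, plan$region_labels,
                     window_assignment = plan$window_assignment)
}

new_roi_timeseries <- function(data, tr, region_labels,
                               window_assignment = NULL) {
  stopifnot(is.matrix(data), nrow(data) >= 2, tr > 0,
            !anyNA(data), length(region_labels) == nrow(data))
  structure(list(data = data, tr = tr, region_labels = region_labels,
                 window_assignment = window_assignment),
            class = "roi_timeseries")
}

#' @export
print.roi_timeseries <- function(x, ...) {
  cat(sprintf("<roi_timeseries: %d regions x %d TRs, TR = %g s>\n",
              nrow(x$data), ncol(x$data), x$tr))
  invisible(x)
}

#' Write / read an ROI time series as TSV
#'
#' First column `region` holds the label; remaining columns are TR samples.
#'
#' @param ts A `roi_timeseries`.
#' @param path TSV path.
#' @param tr Repetition time attached when reading, seconds.
#' @return The path invisibly, or the reconstructed `roi_timeseries`.
#' @export
write_roi_tsv <- function(ts, path) {
  d <- data.frame(region = ts$region_labels, ts$data, check.names = FALSE)
  colnames(d) <- c("region", sprintf("tr%04d", seq_len(ncol(ts$data)) - 1L))
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_roi_tsv
#' @export
read_roi_tsv <- function(path, tr = 0.802) {
  d <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(d)[1] != "region") stop("first column of an ROI TSV must be 'region'")
  X <- as.matrix(d[, -1, drop = FALSE])
  mode(X) <- "numeric"
  rownames(X) <- d$region
  new_roi_timeseries(X, tr, d$region)
}

#' Write the ground-truth sidecar of a synthetic subject
#'
#' Flat key-value text (one `key<TAB>value` pair per line) recording the
#' planted hubs, the window-state assignment, and the correlation targets, so
#' external harnesses can score recovery without parsing R objects.
#'
#' @param plan A [state_plan()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_ground_truth <- function(plan, path) {
  lines <- c(
    paste0("n_regions\t", plan$n_regions),
    paste0("n_states\t", length(plan$states)),
    paste0("within_edge_r\t", plan$within_edge_r),
    paste0("background_r\t", plan$background_r),
    paste0("hub_labels\t",
           paste(plan$region_labels[plan$driver_labels], collapse = ";")),
    paste0("window_assignment\t",
           paste(plan$window_assignment, collapse = ";")))
  writeLines(lines, path)
  invisible(path)
}
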