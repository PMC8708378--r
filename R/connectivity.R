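#' Extract abstinence or satiety analysis windows from an ROI series
#'
#' Abstinence windows tile the start of the series: the first
#' `n_windows * window_length_trs` TRs are split into contiguous,
#' non-overlapping windows, all acquired before the first puff. Satiety
#' windows follow the puffs: each window starts `window_length_trs` TRs
#' (about 30.5 s at TR = 0.802 s) after a puff onset, with onsets floored to
#' the TR grid.
#'
#' @param ts A `roi_timeseries`.
#' @param events Events data.frame (`onset`, `duration`, `trial_type`) or a
#'   `puff_schedule`.
#' @param condition `"abstinence"` or `"satiety"`.
#' @param n_windows Number of windows (default 10).
#' @param window_length_trs Window length in TRs (default 38).
#' @return A `condition_windows`: list with `condition`, `windows` (list of
#'   region x TR matrices), `window_length_trs`, `start_trs` (0-based).
#' @export
extract_condition_windows <- function(ts, events,
                                      condition = c("abstinence", "satiety"),
                                      n_windows = 10,
                                      window_length_trs = 38) {
  condition <- match.arg(condition)
  stopifnot(inherits(ts, "roi_timeseries"), n_windows >= 1,
            window_length_trs >= 2)
  onsets <- if (inherits(events, "puff_schedule")) events$puff_onsets
            else puff_onsets_from_events(events)
  n_tr <- ncol(ts$data)
  if (condition == "abstinence") {
    need <- n_windows * window_length_trs
    avail <- if (length(onsets)) floor(onsets[1] / ts$tr) else n_tr
    if (avail < need)
      stop("abstinence needs ", need, " pre-puff TRs but only ", avail,
           " are available (short by ", need - avail, ")")
    starts <- (seq_len(n_windows) - 1L) * window_length_trs
  } else {
    if (length(onsets) < n_windows)
      stop("satiety needs one puff per window: ", n_windows,
           " windows requested but only ", length(onsets), " puffs")
    starts <- floor(onsets[seq_len(n_windows)] / ts$tr) + window_length_trs
    if (any(diff(starts) < window_length_trs))
      stop("satiety windows overlap; inter-puff interval too short for ",
           window_length_trs, "-TR windows")
    if (max(starts) + window_length_trs > n_tr)
      stop("satiety window starting at TR ", max(starts), " needs ",
           window_length_trs, " TRs but the series ends at TR ", n_tr - 1)
  }
  windows <- lapply(starts, function(s)
    ts$data[, (s + 1L):(s + window_length_trs), drop = FALSE])
  structure(list(condition = condition, windows = windows,
                 window_length_trs = window_length_trs,
                 start_trs = as.integer(starts),
                 region_labels = ts$region_labels),
            class = "condition_windows")
}

#' Pairwise Pearson connectivity of one window
#'
#' @param window Regions x TRs matrix (>= 3 time points, no constant region).
#' @return Symmetric correlation matrix with unit diagonal, carrying the
#'   region labels as dimnames.
#' @export
window_connectivity <- function(window) {
  stopifnot(is.matrix(window), ncol(window) >= 3)
  sds <- apply(window, 1, stats::sd)
  if (any(sds == 0)) {
    bad <- rownames(window)[sds == 0]
    if (is.null(bad)) bad <- which(sds == 0)
    stop("zero-variance region in window: ", paste(bad, collapse = ", "))
  }
  cor(t(window))
}

#' Nodal connectivity strength of each region
#'
#' Row sums of the connectivity matrix excluding the diagonal; `mode =
#' "absolute"` sums `|r|` instead of signed correlations.
#'
#' @param conn Connectivity matrix.
#' @param mode `"signed"` (default) or `"absolute"`.
#' @return Named numeric vector of strengths.
#' @export
nodal_strength <- function(conn, mode = c("signed", "absolute")) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(conn), nrow(conn) == ncol(conn))
  v <- if (mode == "absolute") abs(conn) else conn
  rowSums(v) - diag(v)
}

#' Strength profile of a set of windows
#'
#' @param cw A `condition_windows` or a list of windows.
#' @param mode Passed to [nodal_strength()].
#' @return Windows x regions matrix of nodal strengths (a `strength_profile`).
#' @export
strength_profile <- function(cw, mode = c("signed", "absolute")) {
  mode <- match.arg(mode)
  windows <- if (inherits(cw, "condition_windows")) cw$windows else cw
  P <- t(vapply(windows, function(w) nodal_strength(window_connectivity(w), mode),
                numeric(nrow(windows[[1]]))))
  rownames(P) <- paste0("window", seq_len(nrow(P)))
  P
}

#' Inter-window similarity of strength profiles
#'
#' Pearson correlation of nodal-strength vectors between every pair of
#' windows, computed across regions; 10 windows yield the 10 x 10 similarity
#' matrix that is subsequently clustered into brain-connectivity states.
#'
#' @param profile Windows x regions strength matrix.
#' @return A `window_similarity`: list with `values` (windows x windows
#'   correlation matrix) and `state_assignment` (filled by
#'   [cluster_states()]).
#' @export
window_similarity <- function(profile) {
  stopifnot(is.matrix(profile), nrow(profile) >= 2)
  sds <- apply(profile, 1, stats::sd)
  if (any(sds == 0))
    stop("constant strength vector in window ", which(sds == 0)[1],
         "; similarity undefined")
  structure(list(values = cor(t(profile)), state_assignment = NULL),
            class = "window_similarity")
}

#' Cluster windows into brain-connectivity states
#'
#' Agglomerative hierarchical clustering on the distance `1 - similarity`.
#' With `k = "auto"` the number of states is chosen in 2..5 by maximal mean
#' silhouette width (ties to the smaller k). State labels are renumbered in
#' order of first occurrence, so the assignment is deterministic and
#' equivariant under window permutation.
#'
#' @param sim A `window_similarity` (or plain similarity matrix).
#' @param linkage Linkage method for [stats::hclust()] (default "average").
#' @param k `"auto"` or a fixed integer number of states.
#' @return Integer vector of state labels, one per window.
#' @export
cluster_states <- function(sim, linkage = "average", k = "auto") {
  S <- if (inherits(sim, "window_similarity")) sim$values else sim
  stopifnot(is.matrix(S), nrow(S) == ncol(S))
  n <- nrow(S)
  if (!identical(k, "auto")) {
    k <- as.integer(k)
    if (k > n) stop("k = ", k, " exceeds the number of windows (", n, ")")
    if (k == 1) return(rep(1L, n))
  }
  d <- as.dist(1 - S)
  hc <- hclust(d, method = linkage)
  if (identical(k, "auto")) {
    ks <- seq(2L, min(5L, n - 1L))
    sil <- vapply(ks, function(kk) {
      lab <- cutree(hc, kk)
      mean(cluster::silhouette(lab, d)[, "sil_width"])
    }, numeric(1))
    k <- ks[which.max(sil)]
  }
  lab <- cutree(hc, k)
  relabel_by_first_occurrence(lab)
}

relabel_by_first_occurrence <- function(lab) {
  first <- !duplicated(lab)
  map <- match(lab, lab[first])
  as.integer(map)
}

#' Per-state average connectivity
#'
#' The connectivity matrices of a state's member windows are averaged
#' entrywise after Fisher z-transform and transformed back (variance
#' stabilised averaging); the diagonal is forced to 1. A singleton state
#' returns its window's matrix unchanged.
#'
#' @param conns List of connectivity matrices, one per window.
#' @param assignment Integer state label per window.
#' @return Named list of per-state connectivity matrices.
#' @export
state_connectivity <- function(conns, assignment) {
  stopifnot(length(conns) == length(assignment))
  states <- sort(unique(assignment))
  out <- lapply(states, function(s) {
    members <- conns[assignment == s]
    if (!length(members)) stop("state ", s, " has no member windows")
    if (length(members) == 1) return(members[[1]])
    zs <- lapply(members, function(m) atanh(pmin(pmax(m, -1 + 1e-15), 1 - 1e-15)))
    avg <- tanh(Reduce(`+`, zs) / length(zs))
    diag(avg) <- 1
    dimnames(avg) <- dimnames(members[[1]])
    avg
  })
  names(out) <- paste0("state", states)
  out
}

#' Binarize a state connectivity matrix into an adjacency
#'
#' Edge `(i, j)` is present iff the (signed, by default) correlation is at
#' least `threshold`; the comparison is inclusive and the diagonal is zeroed.
#'
#' @param conn Connectivity matrix.
#' @param threshold Binarization threshold (default 0.65).
#' @param mode `"signed"` compares raw correlations; `"absolute"` compares
#'   `|r|`.
#' @return 0/1 integer adjacency matrix with zero diagonal.
#' @export
binarize_state <- function(conn, threshold = 0.65,
                           mode = c("signed", "absolute")) {
  mode <- match.arg(mode)
  v <- if (mode == "absolute") abs(conn) else conn
  A <- (v >= threshold) * 1L
  diag(A) <- 0L
  storage.mode(A) <- "integer"
  A
}

#' Full state analysis of one condition
#'
#' Convenience wrapper chaining [strength_profile()], [window_similarity()],
#' [cluster_states()], [state_connectivity()] and [binarize_state()].
#'
#' @param cw A `condition_windows`.
#' @param threshold Binarization threshold.
#' @param strength_mode Passed to [nodal_strength()].
#' @param linkage,k Passed to [cluster_states()].
#' @return List with `assignment`, `similarity`, `state_matrices`,
#'   `state_graphs`.
#' @export
condition_states <- function(cw, threshold = 0.65,
                             strength_mode = "signed",
                             linkage = "average", k = "auto") {
  conns <- lapply(cw$windows, window_connectivity)
  prof <- strength_profile(cw, mode = strength_mode)
  sim <- window_similarity(prof)
  assignment <- cluster_states(sim, linkage = linkage, k = k)
  sim$state_assignment <- assignment
  mats <- state_connectivity(conns, assignment)
  graphs <- lapply(mats, binarize_state, threshold = threshold)
  list(assignment = assignment, similarity = sim,
       state_matrices = mats, state_graphs = graphs)
}

#' Write a labeled square matrix as TSV
#' @param m Matrix with region dimnames.
#' @param path TSV path.
#' @return The path, invisibly.
#' @export
write_matrix_tsv <- function(m, path) {
  d <- data.frame(region = rownames(m), m, check.names = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a labeled square matrix from TSV
#' @param path TSV path written by [write_matrix_tsv()].
#' @return Matrix with dimnames.
#' @export
read_matrix_tsv <- function(path) {
  d <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  X <- as.matrix(d[, -1, drop = FALSE])
  mode(X) <- "numeric"
  rownames(X) <- d[[1]]
  X
}
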