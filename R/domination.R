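# Bitmask helpers for graphs on <= 30 nodes (bits 0..29 of an R integer).

bitmask_of <- function(idx) {
  m <- 0L
  for (i in idx) m <- bitwOr(m, bitwShiftL(1L, i - 1L))
  m
}

popcount <- function(x) {
  cnt <- integer(length(x))
  while (any(x != 0L)) {
    cnt <- cnt + bitwAnd(x, 1L)
    x <- bitwShiftR(x, 1L)
  }
  cnt
}

mask_members <- function(mask, n) {
  which(bitwAnd(mask, bitwShiftL(1L, seq_len(n) - 1L)) != 0L)
}

check_adjacency <- function(graph) {
  stopifnot(is.matrix(graph), nrow(graph) == ncol(graph))
  if (!all(graph %in% c(0, 1))) stop("adjacency must be 0/1")
  if (!all(graph == t(graph))) stop("adjacency must be symmetric")
  if (any(diag(graph) != 0)) stop("adjacency must have zero diagonal")
  graph
}

# Closed neighborhood masks N[i] = {i} union neighbors(i).
closed_neighborhoods <- function(graph) {
  n <- nrow(graph)
  vapply(seq_len(n), function(i)
    bitmask_of(c(i, which(graph[i, ] != 0))), integer(1))
}

#' Is a node set dominating?
#'
#' A set dominates the graph when every node either belongs to the set or is
#' adjacent to a member (closed-neighborhood domination; isolated nodes can
#' only be dominated by themselves).
#'
#' @param graph 0/1 symmetric adjacency matrix with zero diagonal.
#' @param node_set Integer node indices (or labels matching dimnames).
#' @return TRUE or FALSE.
#' @export
is_dominating <- function(graph, node_set) {
  graph <- check_adjacency(graph)
  n <- nrow(graph)
  if (is.character(node_set)) node_set <- match(node_set, rownames(graph))
  stopifnot(!anyNA(node_set), all(node_set >= 1), all(node_set <= n))
  if (!length(node_set)) return(n == 0L)
  Nc <- closed_neighborhoods(graph)
  covered <- Reduce(bitwOr, Nc[node_set], 0L)
  covered == bitmask_of(seq_len(n))
}

#' Greedy dominating set
#'
#' Standard greedy maximum-coverage heuristic: repeatedly add the node whose
#' closed neighborhood covers the most still-undominated nodes (ties to the
#' lowest index). The result is dominating but not necessarily minimum; its
#' size is within a factor H(Delta + 1) of the optimum.
#'
#' @param graph 0/1 symmetric adjacency matrix with zero diagonal.
#' @return Sorted integer vector of node indices.
#' @export
greedy_dominating_set <- function(graph) {
  graph <- check_adjacency(graph)
  n <- nrow(graph)
  if (n == 0L) return(integer(0))
  Nc <- closed_neighborhoods(graph)
  full <- bitmask_of(seq_len(n))
  dominated <- 0L
  chosen <- integer(0)
  while (dominated != full) {
    gain <- popcount(bitwAnd(Nc, bitwNot(dominated)))
    v <- which.max(gain)
    chosen <- c(chosen, v)
    dominated <- bitwOr(dominated, Nc[v])
  }
  sort(chosen)
}

#' Enumerate all minimum dominating sets
#'
#' Exact branch-and-bound over bitmask neighborhoods: the search always
#' branches on an undominated node with the fewest admissible dominators
#' (every dominating set must contain one of them), uses a greedy upper
#' bound, prunes with the covering lower bound
#' `ceil(#undominated / max coverage)`, and excludes earlier branch choices
#' so each set is produced exactly once. All dominating sets of minimum
#' cardinality are returned in lexicographic order.
#'
#' @param graph 0/1 symmetric adjacency matrix with zero diagonal, at most 30
#'   nodes (beyond that use [greedy_dominating_set()]).
#' @return List of sorted integer vectors, lexicographically ordered; the
#'   domination number is attached as attribute `"gamma"`.
#' @examples
#' p4 <- matrix(0, 4, 4); p4[cbind(1:3, 2:4)] <- 1; p4 <- p4 + t(p4)
#' minimum_dominating_sets(p4)
#' @export
minimum_dominating_sets <- function(graph) {
  graph <- check_adjacency(graph)
  n <- nrow(graph)
  if (n > 30)
    stop("exact enumeration is limited to 30 nodes; use ",
         "greedy_dominating_set() for larger graphs")
  if (n == 0L) return(structure(list(integer(0)), gamma = 0L))
  Nc <- closed_neighborhoods(graph)
  full <- bitmask_of(seq_len(n))
  bitv <- bitwShiftL(1L, seq_len(n) - 1L)

  env <- new.env(parent = emptyenv())
  env$best <- length(greedy_dominating_set(graph))
  env$sols <- list()

  recurse <- function(chosen, dominated, excluded) {
    len <- length(chosen)
    if (dominated == full) {
      if (len < env$best) {
        env$best <- len
        env$sols <- list(sort(chosen))
      } else if (len == env$best) {
        env$sols[[length(env$sols) + 1L]] <- sort(chosen)
      }
      return(invisible())
    }
    undom <- bitwAnd(full, bitwNot(dominated))
    allowed <- bitwNot(excluded)
    cover <- popcount(bitwAnd(Nc, undom))
    cover[bitwAnd(bitv, allowed) == 0L] <- 0L
    maxcov <- max(cover)
    if (maxcov == 0L) return(invisible())
    if (len + ceiling(popcount(undom) / maxcov) > env$best) return(invisible())
    # branch vertex: undominated node with fewest admissible dominators
    undom_idx <- mask_members(undom, n)
    n_cand <- vapply(undom_idx, function(u)
      popcount(bitwAnd(Nc[u], allowed)), integer(1))
    if (any(n_cand == 0L)) return(invisible())
    u <- undom_idx[which.min(n_cand)]
    cands <- mask_members(bitwAnd(Nc[u], allowed), n)
    excl <- excluded
    for (w in cands) {
      recurse(c(chosen, w), bitwOr(dominated, Nc[w]), bitwOr(excl, bitv[w]))
      excl <- bitwOr(excl, bitv[w])
    }
    invisible()
  }
  recurse(integer(0), 0L, 0L)
  sols <- env$sols
  keys <- vapply(sols, function(s)
    paste(sprintf("%02d", s), collapse = ","), character(1))
  structure(sols[order(keys)], gamma = env$best)
}

#' Per-state driver candidates
#'
#' Minimum dominating sets are generally non-unique; a node is a driver
#' candidate for a state if it appears in at least one of the state's
#' minimum dominating sets. `policy = "first"` instead takes the single
#' lexicographically first set.
#'
#' @param per_state_mds List (one element per state) of MDS lists as returned
#'   by [minimum_dominating_sets()].
#' @param policy `"union"` (default) or `"first"`.
#' @return List of sorted integer vectors, one per state.
#' @export
driver_candidates <- function(per_state_mds, policy = c("union", "first")) {
  policy <- match.arg(policy)
  lapply(per_state_mds, function(mds) {
    if (!length(mds)) stop("state has no minimum dominating set listed")
    if (policy == "first") sort(mds[[1]]) else sort(unique(unlist(mds)))
  })
}

#' Drivers common to every brain-connectivity state
#'
#' Intersection of the per-state candidate sets. An empty intersection is
#' returned as an empty set with a warning (some subject/condition pairs have
#' a single common driver or none beyond it).
#'
#' @param candidates List of per-state candidate node vectors.
#' @return Sorted integer vector (possibly empty).
#' @export
common_drivers <- function(candidates) {
  stopifnot(length(candidates) >= 1)
  common <- Reduce(intersect, candidates)
  if (!length(common))
    warning("no driver node is common to all brain-connectivity states")
  sort(common)
}

#' Percentage of nodes controlled by a driver
#'
#' Mean over states of the driver's neighborhood size divided by the number
#' of regions, times 100. The default counts the open neighborhood (slave
#' nodes only, driver excluded); `neighborhood = "closed"` includes the
#' driver itself.
#'
#' @param driver Node index (or label).
#' @param graphs List of 0/1 adjacency matrices (one per state).
#' @param neighborhood `"open"` (default) or `"closed"`.
#' @return Percentage in `[0, 100]` (full precision; format with two decimals
#'   for reporting).
#' @export
controlled_percentage <- function(driver, graphs,
                                  neighborhood = c("open", "closed")) {
  neighborhood <- match.arg(neighborhood)
  stopifnot(length(graphs) >= 1)
  if (is.character(driver)) driver <- match(driver, rownames(graphs[[1]]))
  sizes <- vapply(graphs, function(g) {
    check_adjacency(g)
    stopifnot(driver >= 1, driver <= nrow(g))
    sum(g[driver, ]) + (neighborhood == "closed")
  }, numeric(1))
  100 * mean(sizes) / nrow(graphs[[1]])
}

#' Driver-node report for one condition
#'
#' Runs the full minimum-dominating-set accounting over the binarized state
#' graphs: per-state MDS enumeration, per-state candidate union, common
#' drivers across states, and controlled-node percentages.
#'
#' @param graphs Named list of 0/1 state adjacency matrices.
#' @param labels Region labels (defaults to the graphs' dimnames).
#' @param policy Candidate policy, see [driver_candidates()].
#' @param neighborhood See [controlled_percentage()].
#' @return A `driver_report`: list with `per_state_mds`, `candidates`,
#'   `common_drivers`, `controlled_pct` (named, percent), `labels`.
#' @export
driver_report <- function(graphs, labels = rownames(graphs[[1]]),
                          policy = "union", neighborhood = "open") {
  stopifnot(length(graphs) >= 1)
  if (is.null(labels)) labels <- as.character(seq_len(nrow(graphs[[1]])))
  per_state_mds <- lapply(graphs, minimum_dominating_sets)
  cands <- driver_candidates(per_state_mds, policy = policy)
  common <- suppressWarnings(common_drivers(cands))
  pct <- vapply(common, controlled_percentage, numeric(1),
                graphs = graphs, neighborhood = neighborhood)
  names(pct) <- labels[common]
  structure(list(per_state_mds = per_state_mds, candidates = cands,
                 common_drivers = common, controlled_pct = pct,
                 labels = labels),
            class = "driver_report")
}

#' @export
print.driver_report <- function(x, ...) {
  cat(sprintf("<driver_report: %d states, %d common driver(s)>\n",
              length(x$per_state_mds), length(x$common_drivers)))
  tg <- select_targets(x, top_k = length(x$common_drivers))
  for (i in seq_len(nrow(tg)))
    cat(sprintf("  %s: %.2f%%\n", tg$label[i], tg$controlled_pct[i]))
  invisible(x)
}

#' Select the top neuromodulation targets
#'
#' Common drivers ranked by controlled percentage (descending, ties broken
#' lexicographically by label); the first `top_k` are the proposed
#' neuromodulation target sites. Fewer rows are returned when fewer common
#' drivers exist.
#'
#' @param report A [driver_report()].
#' @param top_k Number of targets (default 2).
#' @return Data frame with columns `node`, `label`, `controlled_pct`.
#' @export
select_targets <- function(report, top_k = 2) {
  stopifnot(inherits(report, "driver_report"))
  nodes <- report$common_drivers
  if (!length(nodes))
    return(data.frame(node = integer(0), label = character(0),
                      controlled_pct = numeric(0)))
  labs <- report$labels[nodes]
  pct <- unname(report$controlled_pct)
  ord <- order(-pct, labs)
  take <- head(ord, top_k)
  data.frame(node = nodes[take], label = labs[take],
             controlled_pct = pct[take], row.names = NULL)
}
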