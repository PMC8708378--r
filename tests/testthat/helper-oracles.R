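# Independent oracles and small fixture builders used across the suite.

# Exhaustive minimum-dominating-set search over all 2^n subsets. Written
# independently of the package's branch-and-bound enumerator so it can serve
# as its oracle on small graphs.
brute_force_mds <- function(adj) {
  n <- nrow(adj)
  nbr <- lapply(seq_len(n), function(i) c(i, which(adj[i, ] != 0)))
  best_size <- n + 1L
  sols <- list()
  for (code in 0:(2^n - 1)) {
    members <- which(bitwAnd(code, 2^(seq_len(n) - 1)) != 0)
    if (length(members) > best_size) next
    covered <- unique(unlist(nbr[members]))
    if (length(covered) == n) {
      if (length(members) < best_size) {
        best_size <- length(members)
        sols <- list(members)
      } else {
        sols[[length(sols) + 1L]] <- members
      }
    }
  }
  keys <- vapply(sols, function(s) paste(sprintf("%02d", s), collapse = ","),
                 character(1))
  structure(sols[order(keys)], gamma = best_size)
}

random_graph <- function(n, p, seed) {
  set.seed(seed)
  A <- matrix(0L, n, n)
  up <- upper.tri(A)
  A[up] <- as.integer(stats::runif(sum(up)) < p)
  A + t(A)
}

path_graph <- function(n) {
  A <- matrix(0L, n, n)
  if (n > 1) A[cbind(seq_len(n - 1), seq_len(n - 1) + 1L)] <- 1L
  A + t(A)
}

star_graph <- function(n) {
  A <- matrix(0L, n, n)
  A[1, -1] <- 1L
  A + t(A)
}

complete_graph <- function(n) {
  A <- matrix(1L, n, n)
  diag(A) <- 0L
  A
}

# Adjusted Rand index between two partitions (contingency-table form).
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- si * sj / n2
  if (abs((si + sj) / 2 - expected) < 1e-12) return(1)
  (sij - expected) / ((si + sj) / 2 - expected)
}

# Windows of a generated series, cut on the generator's own grid.
cut_windows <- function(ts, window_length_trs = 38) {
  n_w <- ncol(ts$data) %/% window_length_trs
  lapply(seq_len(n_w) - 1L, function(i)
    ts$data[, i * window_length_trs + seq_len(window_length_trs)])
}
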