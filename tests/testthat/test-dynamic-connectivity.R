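sim_subject_fixture <- function(seed = 1) {
  cfg <- run_config(seed = seed)
  simulate_subject(cfg)
}

test_that("abstinence windows tile the pre-puff baseline", {
  inp <- sim_subject_fixture(seed = 2)
  cw <- extract_condition_windows(inp$ts, inp$schedule, "abstinence")
  expect_length(cw$windows, 10)
  expect_true(all(vapply(cw$windows, ncol, integer(1)) == 38))
  expect_equal(cw$start_trs, seq(0, 9) * 38)
  expect_identical(cw$windows[[1]], inp$ts$data[, 1:38])

  # all 380 abstinence TRs precede the first puff
  expect_lte(380, floor(inp$schedule$puff_onsets[1] / inp$ts$tr))
})

test_that("satiety windows start 38 TRs after each puff and never overlap", {
  inp <- sim_subject_fixture(seed = 2)
  cw <- extract_condition_windows(inp$ts, inp$schedule, "satiety")
  expect_length(cw$windows, 10)
  expected_starts <- floor(inp$schedule$puff_onsets / inp$ts$tr) + 38
  expect_equal(cw$start_trs, as.integer(expected_starts))
  expect_true(all(diff(cw$start_trs) >= 38))
})

test_that("window extraction reports shortfalls and overlaps", {
  inp <- sim_subject_fixture(seed = 2)
  short <- inp$ts
  expect_error(
    extract_condition_windows(short, inp$schedule, "abstinence",
                              n_windows = 20),
    "short by")
  tight <- generate_puff_schedule(iti = 30, n_puffs = 10,
                                  baseline_length = 305,
                                  session_length = 2700)
  expect_error(extract_condition_windows(inp$ts, tight, "satiety"), "overlap")
  expect_error(
    extract_condition_windows(inp$ts, inp$schedule, "satiety", n_windows = 12),
    "12 windows")

  # degenerate single window equals the input slice
  one <- extract_condition_windows(inp$ts, inp$schedule, "abstinence",
                                   n_windows = 1, window_length_trs = 38)
  expect_identical(one$windows[[1]], inp$ts$data[, 1:38])
})

test_that("window connectivity is plain Pearson correlation", {
  set.seed(5)
  w <- matrix(rnorm(15), 3, 5,
              dimnames = list(c("a", "b", "c"), NULL))
  cm <- window_connectivity(w)
  # direct formula, computed independently
  pear <- function(x, y) {
    xm <- x - mean(x); ym <- y - mean(y)
    sum(xm * ym) / sqrt(sum(xm^2) * sum(ym^2))
  }
  for (i in 1:3) for (j in 1:3)
    expect_equal(cm[i, j], pear(w[i, ], w[j, ]), tolerance = 1e-12)
  expect_equal(diag(cm), c(a = 1, b = 1, c = 1))
  expect_equal(cm, t(cm))

  dup <- rbind(w, d = w["a", ])
  expect_equal(window_connectivity(dup)["a", "d"], 1)
  neg <- rbind(w, d = -w["a", ])
  expect_equal(window_connectivity(neg)["a", "d"], -1)

  w0 <- rbind(w, flat = rep(1, 5))
  expect_error(window_connectivity(w0), "flat")
})

test_that("nodal strength sums off-diagonal weights", {
  expect_equal(nodal_strength(diag(5)), rep(0, 5))
  m <- matrix(0.5, 23, 23); diag(m) <- 1
  expect_equal(nodal_strength(m), rep(11, 23))
  set.seed(1)
  pos <- abs(matrix(rnorm(36), 6, 6)); pos <- (pos + t(pos)) / 2; diag(pos) <- 1
  expect_equal(nodal_strength(pos, "signed"), nodal_strength(pos, "absolute"))
  mixed <- pos; mixed[1, 2] <- mixed[2, 1] <- -0.4
  expect_gt(nodal_strength(mixed, "absolute")[1], nodal_strength(mixed)[1])
})

test_that("window similarity is the 10 x 10 strength correlation", {
  inp <- sim_subject_fixture(seed = 3)
  cw <- extract_condition_windows(inp$ts, inp$schedule, "abstinence")
  prof <- strength_profile(cw)
  expect_equal(dim(prof), c(10, 23))
  sim <- window_similarity(prof)
  expect_equal(dim(sim$values), c(10, 10))
  expect_equal(sim$values, t(sim$values))
  expect_equal(diag(sim$values), setNames(rep(1, 10), rownames(prof)))

  # identical windows correlate at exactly 1
  two <- window_similarity(rbind(prof[1, ], prof[1, ]))
  expect_equal(two$values[1, 2], 1)

  # orthogonalized strength vectors correlate near 0
  x <- prof[1, ] - mean(prof[1, ])
  y <- prof[2, ] - mean(prof[2, ])
  y <- y - sum(x * y) / sum(x * x) * x
  orth <- window_similarity(rbind(w1 = x, w2 = y))
  expect_equal(orth$values[1, 2], 0, tolerance = 1e-12)

  expect_error(window_similarity(rbind(prof[1, ], rep(2, 23))), "constant")
})

test_that("clustering recovers a planted two-block similarity exactly", {
  S <- matrix(0, 10, 10)
  blocks <- rep(1:2, each = 5)
  S[outer(blocks, blocks, "==")] <- 0.9
  diag(S) <- 1
  lab <- cluster_states(S)
  expect_equal(lab, rep(1:2, each = 5))

  expect_equal(cluster_states(S, k = 1), rep(1L, 10))
  expect_error(cluster_states(S, k = 11), "exceeds")

  # permuting the windows permutes the labels consistently
  perm <- c(3, 8, 1, 9, 5, 2, 10, 4, 6, 7)
  lab_p <- cluster_states(S[perm, perm])
  expect_equal(adjusted_rand(lab_p, blocks[perm]), 1)
})

test_that("state averaging is the Fisher-z mean with unit diagonal", {
  m1 <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  m2 <- matrix(c(1, 0.9, 0.9, 1), 2, 2)
  avg <- state_connectivity(list(m1, m2), c(1, 1))$state1
  expect_equal(avg[1, 2], tanh(mean(atanh(c(0.5, 0.9)))), tolerance = 1e-12)
  expect_equal(avg[1, 2], 0.7658, tolerance = 1e-3)
  expect_gt(avg[1, 2], mean(c(0.5, 0.9)))   # not the arithmetic 0.70

  # singleton state passes through, identical matrices average to themselves
  out <- state_connectivity(list(m1, m2, m2), c(1, 2, 2))
  expect_identical(out$state1, m1)
  expect_equal(out$state2, m2, tolerance = 1e-12)
})

test_that("binarization is an inclusive threshold on signed correlations", {
  m <- matrix(0.64, 4, 4); diag(m) <- 1
  expect_true(all(binarize_state(m) == 0))
  m65 <- matrix(0.65, 4, 4); diag(m65) <- 1
  A <- binarize_state(m65)
  expect_true(all(A[upper.tri(A)] == 1) && all(diag(A) == 0))

  mixed <- matrix(c(1, 0.7, -0.8, 0.7, 1, 0.1, -0.8, 0.1, 1), 3, 3)
  expect_equal(binarize_state(mixed),
               matrix(as.integer(mixed >= 0.65 & diag(3) == 0), 3, 3))
  expect_equal(binarize_state(mixed, mode = "absolute")[1, 3], 1L)
})

test_that("region relabeling permutes the whole pipeline consistently", {
  plan <- state_plan(n_windows = 6)
  ts <- generate_roi_timeseries(plan, seed = 17)
  perm <- sample(seq_len(23))
  ts_p <- ts
  ts_p$data <- ts$data[perm, ]
  ts_p$region_labels <- ts$region_labels[perm]

  w <- cut_windows(ts)[[1]]
  w_p <- cut_windows(ts_p)[[1]]
  cm <- window_connectivity(w)
  cm_p <- window_connectivity(w_p)
  expect_equal(cm_p, cm[perm, perm], tolerance = 1e-12)
  expect_equal(nodal_strength(cm_p), nodal_strength(cm)[perm],
               tolerance = 1e-12)
  expect_equal(binarize_state(cm_p), binarize_state(cm)[perm, perm])
})

test_that("planted states are recovered from generator output", {
  plan <- state_plan()    # 3 states, 10 windows, r_edge 0.8, r_bg 0.1
  ok_part <- 0; ok_adj <- 0
  n_seed <- 50
  single <- state_plan(n_states = 1, n_windows = 10)
  for (seed in seq_len(n_seed)) {
    ts <- generate_roi_timeseries(plan, seed = seed)
    conns <- lapply(cut_windows(ts), window_connectivity)
    prof <- strength_profile(cut_windows(ts))
    lab <- cluster_states(window_similarity(prof))
    if (adjusted_rand(lab, plan$window_assignment) == 1)
      ok_part <- ok_part + 1

    ts1 <- generate_roi_timeseries(single, seed = seed + 1000)
    conns1 <- lapply(cut_windows(ts1), window_connectivity)
    avg <- state_connectivity(conns1, rep(1L, 10))$state1
    if (identical(unname(binarize_state(avg)), unname(single$states[[1]])))
      ok_adj <- ok_adj + 1
  }
  expect_gte(ok_part, 0.9 * n_seed)
  expect_gte(ok_adj, 0.9 * n_seed)
})

test_that("matrix TSV round trip preserves labels and values", {
  dir <- withr::local_tempdir()
  m <- matrix(rnorm(9), 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  write_matrix_tsv(m, file.path(dir, "m.tsv"))
  back <- read_matrix_tsv(file.path(dir, "m.tsv"))
  expect_equal(back, m, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(rownames(back), rownames(m))
})
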