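# Markov-chain generator: kernels, fragmentation arithmetic, determinism.

test_that("effective transition matrix blends dwell and switch", {
  p0 <- test_profile(f = 0)
  expect_equal(unname(effective_transition_matrix(p0, 2)), diag(7))
  p1 <- test_profile(f = 1)
  T1 <- effective_transition_matrix(p1, 2)
  expect_equal(unname(diag(T1)), rep(0, 7))
  expect_equal(unname(T1), unname(p1$switch_kernel))
  # uniform kernel, f = 0.4: diagonal 0.6, off-diagonals 0.4/6
  K <- matrix(1 / 6, 7, 7); diag(K) <- 0
  pu <- phase_profile(rep(1 / 7, 7), fragmentation = 0.4, switch_kernel = K)
  Tu <- effective_transition_matrix(pu, 2)
  expect_equal(unname(diag(Tu)), rep(0.6, 7))
  expect_equal(unname(Tu[1, 2]), 0.4 / 6)
  expect_equal(rowSums(Tu), rep(1, 7), ignore_attr = TRUE)
})

test_that("day drift shifts fragmentation linearly with clamping", {
  p <- test_profile(f = 0.4, drift = -0.05)
  expect_equal(effective_fragmentation(p, 2), 0.4)
  expect_equal(effective_fragmentation(p, 5), 0.4 - 0.05 * 3)
  pc <- test_profile(f = 0.1, drift = -0.05)
  expect_equal(effective_fragmentation(pc, 9), 0)  # clamped at 0
})

test_that("degenerate fragmentation gives constant / always-switching runs", {
  set.seed(9)
  s0 <- simulate_session(test_profile(f = 0), 2)
  expect_length(s0, 25)
  expect_length(unique(s0), 1)
  s1 <- simulate_session(test_profile(f = 1), 2)
  expect_true(all(s1[-1] != s1[-25]))
})

test_that("expected transition count is 24 * f_d (Monte Carlo)", {
  prof <- test_profile(f = 0.4, drift = -0.02)
  for (ppd in c(2L, 6L)) {
    set.seed(100 + ppd)
    counts <- replicate(4000, transition_count(simulate_session(prof, ppd)))
    f_d <- effective_fragmentation(prof, ppd)
    expect_equal(mean(counts), 24 * f_d, tolerance = 0.05 / (24 * f_d))
  }
})

test_that("simulated datasets are deterministic and dam-stable", {
  cfg <- sim_config(n_dams_per_group = 3, seed = 77)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(obs_rows(d1), obs_rows(d2))
  expect_equal(nrow(session_info <- unique(d1[, c("dam_id", "ppd", "period")])),
               3 * 2 * 8 * 3)
  # adding dams never reshuffles existing dams' sequences
  d4 <- simulate_dataset(sim_config(n_dams_per_group = 4, seed = 77))
  keep <- d4$dam_id %in% unique(d1$dam_id)
  expect_identical(obs_rows(d4[keep, ]), obs_rows(d1))
  # and the caller's RNG stream is untouched
  set.seed(5); before <- runif(1)
  set.seed(5); invisible(simulate_dataset(cfg)); after <- runif(1)
  expect_identical(before, after)
})

test_that("default full-size config yields 432 sessions", {
  d <- simulate_dataset(sim_config(seed = 1))
  expect_equal(nrow(unique(d[, c("dam_id", "ppd", "period")])), 432)
  expect_equal(length(unique(d$dam_id)), 18)
})

test_that("switch-kernel parameter recovery from simulated transitions", {
  prof <- test_profile(f = 0.5)
  set.seed(314)
  n_sessions <- 4000
  from <- integer(0); to <- integer(0)
  codes <- behavior_codes()
  for (i in seq_len(n_sessions)) {
    s <- match(simulate_session(prof, 2), codes)
    sw <- which(s[-1] != s[-25])
    from <- c(from, s[sw]); to <- c(to, s[sw + 1])
  }
  expect_gt(length(from), 4e4)
  Khat <- matrix(0, 7, 7)
  for (i in 1:7) {
    sel <- from == i
    if (any(sel)) Khat[i, ] <- tabulate(to[sel], 7) / sum(sel)
  }
  expect_lt(max(abs(Khat - prof$switch_kernel)), 0.02)
})

test_that("long-chain occupancy approaches the stationary distribution", {
  prof <- test_profile(f = 0.45)
  T <- effective_transition_matrix(prof, 2)
  ev <- eigen(t(T))
  stat <- Re(ev$vectors[, which.min(abs(ev$values - 1))])
  stat <- stat / sum(stat)
  set.seed(2718)
  chain <- ethonet:::simulate_chain(prof, 2, 1e5)
  occ <- as.numeric(table(factor(chain, levels = behavior_codes()))) / 1e5
  expect_lt(sum(abs(occ - stat)) / 2, 0.02)  # total variation
})

test_that("LBN preset exceeds CTRL in mean dark-phase transitions", {
  # >= 200 simulated dams per group, accumulated over small datasets
  dark_means <- sapply(0:9, function(k) {
    d <- simulate_dataset(sim_config(n_dams_per_group = 10, seed = 600 + k))
    rt <- response_table(d, "transitions", "DARK")
    tapply(rt$value, rt$group, mean)
  })
  expect_true(all(dark_means["LBN", ] > dark_means["CTRL", ]))
})

test_that("profile and config validation rejects malformed inputs", {
  expect_error(phase_profile(rep(0.2, 7), 0.5), "summing to 1")
  expect_error(phase_profile(rep(1 / 7, 7), 1.5), "must be in")
  K <- matrix(1 / 6, 7, 7)  # non-zero diagonal
  expect_error(phase_profile(rep(1 / 7, 7), 0.5, switch_kernel = K),
               "zero diagonal")
  expect_error(sim_config(profiles = default_profiles()[1:3]),
               "must contain")
})

test_that("config file round trip reproduces the default presets", {
  path <- system.file("extdata", "default_config.yaml", package = "ethonet")
  expect_true(nzchar(path))
  cfg <- read_sim_config(path)
  ref <- default_profiles()
  for (k in names(ref)) {
    expect_equal(cfg$profiles[[k]]$initial_dist, ref[[k]]$initial_dist)
    expect_equal(cfg$profiles[[k]]$fragmentation, ref[[k]]$fragmentation)
    expect_equal(cfg$profiles[[k]]$switch_kernel, ref[[k]]$switch_kernel)
  }
  expect_equal(cfg$n_dams_per_group, 9L)
})
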