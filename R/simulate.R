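# Seeded Markov-chain generator of scan-sampled observation datasets.
#
# Behavior sequences are simulated as discrete-time Markov chains over the
# 7-code ethogram. Fragmentation is factored out of the transition kernel: at
# each 3-min step the dam switches state with probability f (the fragmentation
# parameter) and, conditional on switching, draws the destination from a
# zero-diagonal row-stochastic switch kernel. "More fragmented, same
# repertoire" is thus a one-parameter manipulation. A per-day additive drift
# on f emulates the decline of transition counts across postpartum days.

#' Define a phase profile for the behavior simulator
#'
#' A phase profile fully specifies the generating chain for one (group,
#' period-class) combination: the distribution of the first scan sample, the
#' switch kernel, the per-slot switch probability `fragmentation`, and its
#' additive per-day drift. The effective fragmentation on postpartum day `d`
#' is `clamp(fragmentation + day_drift * (d - 2), 0, 1)`.
#'
#' @param initial_dist Probability vector over the 7 behavior codes (in
#'   [behavior_codes()] order); must sum to 1.
#' @param fragmentation Per-slot switch probability `f` in `[0, 1]`.
#' @param day_drift Additive change to `f` per postpartum day (day 2 is the
#'   reference); negative values make behavior less fragmented over days.
#' @param switch_kernel Optional 7x7 row-stochastic matrix with zero diagonal:
#'   the distribution of the next state given that a switch occurs. Defaults
#'   to resampling from `initial_dist` conditioned on leaving the current
#'   state, i.e. `K[i, j] = p[j] / (1 - p[i])` for `j != i`.
#' @return An object of class `phase_profile`.
#' @export
#' @examples
#' p <- phase_profile(rep(1 / 7, 7), fragmentation = 0.4)
#' effective_transition_matrix(p, ppd = 2)[1, 1]  # 0.6
phase_profile <- function(initial_dist, fragmentation, day_drift = 0,
                          switch_kernel = NULL) {
  p <- as.numeric(initial_dist)
  if (length(p) != 7 || any(p < 0) || abs(sum(p) - 1) > 1e-8)
    stop("`initial_dist` must be 7 non-negative probabilities summing to 1")
  names(p) <- .CODES
  if (is.null(switch_kernel)) {
    if (any(p >= 1)) stop("default switch kernel needs all initial_dist < 1")
    switch_kernel <- outer(1 / (1 - p), p)
    diag(switch_kernel) <- 0
  }
  K <- as.matrix(switch_kernel)
  if (!all(dim(K) == c(7, 7)) || any(K < 0) || any(abs(diag(K)) > 0) ||
      any(abs(rowSums(K) - 1) > 1e-8))
    stop("`switch_kernel` must be 7x7 row-stochastic with zero diagonal")
  dimnames(K) <- list(.CODES, .CODES)
  if (!is.numeric(fragmentation) || fragmentation < 0 || fragmentation > 1)
    stop("`fragmentation` must be in [0, 1]")
  structure(list(initial_dist = p, switch_kernel = K,
                 fragmentation = fragmentation, day_drift = day_drift),
            class = "phase_profile")
}

#' @export
print.phase_profile <- function(x, ...) {
  cat("Phase profile: f =", x$fragmentation, "drift/day =", x$day_drift, "\n")
  cat("  initial distribution:\n")
  print(round(x$initial_dist, 3))
  invisible(x)
}

#' Effective fragmentation on a given postpartum day
#'
#' @param profile A [phase_profile()].
#' @param ppd Postpartum day (2--9).
#' @return `clamp(f + day_drift * (ppd - 2), 0, 1)`.
#' @export
effective_fragmentation <- function(profile, ppd) {
  min(max(profile$fragmentation + profile$day_drift * (ppd - .PPD_MIN), 0), 1)
}

#' One-step transition matrix of the generating chain
#'
#' Combines dwell and switch: `T = (1 - f_d) * I + f_d * K`, where `f_d` is
#' the day-effective fragmentation and `K` the switch kernel. Rows sum to 1.
#'
#' @inheritParams effective_fragmentation
#' @return A 7x7 row-stochastic matrix.
#' @export
effective_transition_matrix <- function(profile, ppd) {
  f <- effective_fragmentation(profile, ppd)
  (1 - f) * diag(7) + f * profile$switch_kernel
}

# Simulate a chain of `n` codes from the current RNG state.
simulate_chain <- function(profile, ppd, n) {
  f <- effective_fragmentation(profile, ppd)
  K <- profile$switch_kernel
  cur <- sample.int(7L, 1L, prob = profile$initial_dist)
  out <- rep(cur, n)
  if (n > 1) {
    switches <- which(stats::runif(n - 1) < f)
    for (t in switches) {
      cur <- sample.int(7L, 1L, prob = K[cur, ])
      out[(t + 1):n] <- cur
    }
  }
  .CODES[out]
}

#' Simulate one 25-slot observation session
#'
#' Slot 0 is drawn from the profile's initial distribution and each following
#' slot from the day-effective transition matrix row of the current state.
#' Draws come from R's current RNG stream; use `set.seed()` (or
#' [simulate_dataset()], which manages per-dam streams) for reproducibility.
#'
#' @inheritParams effective_fragmentation
#' @return Character vector of 25 behavior codes.
#' @export
#' @examples
#' set.seed(1)
#' simulate_session(default_profiles()[["CTRL.LIGHT"]], ppd = 2)
simulate_session <- function(profile, ppd) {
  simulate_chain(profile, ppd, .N_SLOTS)
}

#' Default simulation presets
#'
#' Phase profiles for the four (group, period-class) combinations, chosen to
#' emulate the qualitative group effects reported for the limited bedding and
#' nesting (LBN) paradigm: high crouch nursing elevated in LBN dams in both
#' phases, supine nursing suppressed in the LBN light phase, dark-phase
#' fragmentation elevated in LBN dams, and transitions declining across
#' postpartum days (negative `day_drift`). The numeric values are tuning
#' choices of this package (no quantitative dwell-time data exist to fit);
#' see the package vignette.
#'
#' @return Named list of four [phase_profile()] objects with keys
#'   `CTRL.LIGHT`, `CTRL.DARK`, `LBN.LIGHT`, `LBN.DARK`.
#' @export
default_profiles <- function() {
  #           HG    LW   SUP    L   HG/L   DN   OFF
  list(
    CTRL.LIGHT = phase_profile(
      c(0.40, 0.12, 0.08, 0.03, 0.09, 0.13, 0.15),
      fragmentation = 0.35, day_drift = -0.015),
    CTRL.DARK = phase_profile(
      c(0.15, 0.07, 0.04, 0.02, 0.04, 0.23, 0.45),
      fragmentation = 0.30, day_drift = -0.015),
    LBN.LIGHT = phase_profile(
      c(0.55, 0.10, 0.03, 0.03, 0.10, 0.09, 0.10),
      fragmentation = 0.35, day_drift = -0.015),
    LBN.DARK = phase_profile(
      c(0.32, 0.08, 0.04, 0.02, 0.06, 0.23, 0.25),
      fragmentation = 0.45, day_drift = -0.015))
}

#' Simulation configuration
#'
#' @param n_dams_per_group Number of dams per housing group (default 9, the
#'   study design emulated by the defaults).
#' @param profiles Named list of four [phase_profile()]s with keys
#'   `CTRL.LIGHT`, `CTRL.DARK`, `LBN.LIGHT`, `LBN.DARK`; `AM` and `PM`
#'   sessions use the `LIGHT` profile (the two light periods are treated as
#'   exchangeable), `DARK` sessions the `DARK` profile.
#' @param ppd_range Integer range of postpartum days, default `c(2, 9)`.
#' @param seed Integer seed governing the whole dataset.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_dams_per_group = 9, profiles = default_profiles(),
                       ppd_range = c(2L, 9L), seed = 1L) {
  keys <- c("CTRL.LIGHT", "CTRL.DARK", "LBN.LIGHT", "LBN.DARK")
  if (!all(keys %in% names(profiles)))
    stop("`profiles` must contain all of: ", paste(keys, collapse = ", "))
  for (k in keys)
    if (!inherits(profiles[[k]], "phase_profile"))
      stop("profile '", k, "' is not a phase_profile")
  ppd_range <- as.integer(ppd_range)
  if (ppd_range[1] < .PPD_MIN || ppd_range[2] > .PPD_MAX ||
      ppd_range[1] > ppd_range[2])
    stop("`ppd_range` must lie within [", .PPD_MIN, ", ", .PPD_MAX, "]")
  if (n_dams_per_group < 1) stop("need at least 1 dam per group")
  structure(list(n_dams_per_group = as.integer(n_dams_per_group),
                 profiles = profiles[keys], ppd_range = ppd_range,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Deterministic per-dam sub-seed. Fixed per-group offsets mean adding dams
# (or changing the other group's size) never reshuffles existing dams.
dam_seed <- function(seed, group, dam_index) {
  base <- if (group == "CTRL") 0 else 1e5
  as.integer((as.double(seed) %% 1000003) * 2011 + base + dam_index * 97) %%
    2147483647L
}

#' Simulate a full observation dataset
#'
#' Simulates `n_dams_per_group` dams per group over the configured postpartum
#' days, three sessions per day (`AM` and `PM` from the group's `LIGHT`
#' profile, `DARK` from its `DARK` profile). Each dam draws from its own
#' seeded stream derived from the global seed, so the dataset is fully
#' deterministic given `config$seed` and adding dams leaves existing dams'
#' sequences unchanged. The caller's RNG state is preserved.
#'
#' @param config A [sim_config()].
#' @return A [beh_dataset] with seed and config recorded in its metadata.
#' @export
#' @examples
#' d <- simulate_dataset(sim_config(n_dams_per_group = 2, seed = 42))
#' print(d)
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  ppds <- seq(config$ppd_range[1], config$ppd_range[2])
  n_per_dam <- length(ppds) * length(.PERIODS) * .N_SLOTS
  rows_code <- list()
  info <- list()
  for (g in .GROUPS) {
    light <- config$profiles[[paste0(g, ".LIGHT")]]
    dark <- config$profiles[[paste0(g, ".DARK")]]
    for (i in seq_len(config$n_dams_per_group)) {
      id <- sprintf("%s%02d", if (g == "CTRL") "C" else "L", i)
      set.seed(dam_seed(config$seed, g, i))
      codes <- character(n_per_dam)
      pos <- 0L
      for (ppd in ppds) {
        for (period in .PERIODS) {
          prof <- if (period == "DARK") dark else light
          codes[pos + seq_len(.N_SLOTS)] <- simulate_chain(prof, ppd, .N_SLOTS)
          pos <- pos + .N_SLOTS
        }
      }
      rows_code[[id]] <- codes
      info[[id]] <- list(group = g, id = id)
    }
  }
  ids <- names(rows_code)
  n_dams <- length(ids)
  df <- data.frame(
    dam_id = rep(ids, each = n_per_dam),
    group = rep(vapply(info, function(x) x$group, ""), each = n_per_dam),
    ppd = rep(rep(ppds, each = length(.PERIODS) * .N_SLOTS), times = n_dams),
    period = rep(rep(.PERIODS, each = .N_SLOTS),
                 times = n_dams * length(ppds)),
    slot = rep(seq_len(.N_SLOTS) - 1L,
               times = n_dams * length(ppds) * length(.PERIODS)),
    code = unlist(rows_code, use.names = FALSE),
    aux = "",
    stringsAsFactors = FALSE)
  structure(df,
            metadata = list(seed = config$seed, config = config,
                            source = "simulate_dataset"),
            class = c("beh_dataset", "data.frame"))
}
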