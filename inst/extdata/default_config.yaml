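# Default simulation configuration for ethonet.
#
# One phase profile per (group, period class). AM and PM sessions share the
# LIGHT profile (the two light observation periods are treated as
# exchangeable); DARK sessions use the DARK profile.
#
# initial_dist: probabilities of the first scan sample over the 7 codes, in
#   the order HG, LW, SUP, L, HG/L, DN, OFF.
# fragmentation: per-3-min-slot probability of switching behavior (f). The
#   fragmentation values below are tuning choices: no quantitative dwell-time
#   data exist to fit them, so they were picked once to give realistic session
#   statistics and the qualitative group contrasts of the limited bedding and
#   nesting paradigm (elevated high crouch in LBN, elevated dark-phase
#   switching in LBN, switching declining over days).
# day_drift: additive change of f per postpartum day (day 2 = reference).
# switch_kernel (optional): 7 rows of 7 giving the destination distribution
#   when a switch occurs; zero diagonal, rows sum to 1. When omitted, the
#   destination is resampled from initial_dist conditioned on change.

seed: 1
n_dams_per_group: 9
ppd_range: [2, 9]
profiles:
  CTRL.LIGHT:
    initial_dist: [0.40, 0.12, 0.08, 0.03, 0.09, 0.13, 0.15]
    fragmentation: 0.35
    day_drift: -0.015
  CTRL.DARK:
    initial_dist: [0.15, 0.07, 0.04, 0.02, 0.04, 0.23, 0.45]
    fragmentation: 0.30
    day_drift: -0.015
  LBN.LIGHT:
    initial_dist: [0.55, 0.10, 0.03, 0.03, 0.10, 0.09, 0.10]
    fragmentation: 0.35
    day_drift: -0.015
  LBN.DARK:
    initial_dist: [0.32, 0.08, 0.04, 0.02, 0.06, 0.23, 0.25]
    fragmentation: 0.45
    day_drift: -0.015
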