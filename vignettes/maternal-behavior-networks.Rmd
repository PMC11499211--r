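---
title: "Transition-network analysis of maternal care: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transition-network analysis of maternal care: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ethonet)
```

## The problem

Rodent dams housed with limited bedding and nesting material (LBN) provide
*fragmented* maternal care: they switch between discrete behaviors — nursing
postures, licking, being in or off the nest — more often than control dams,
reducing the predictability of the sensory input their pups receive.
Traditional analyses count how often each behavior occurs and how often the
dam switches at all. `ethonet` adds the *sequence* dimension: which behavior
leads to which, how central each behavior is in the dam's switching
repertoire, and how that structure evolves across postpartum days (PPD) and
between light and dark phases.

The observation protocol it models is instantaneous scan sampling: the dam's
ongoing behavior is recorded every 3 minutes over a 72-minute period
(25 samples per period), three periods per day (two light-phase, one
dark-phase; 75 samples per 24 h), from PPD 2 to PPD 9, for two groups
(control and LBN) of 9 dams each.

## The ethogram and the data model

Seven mutually exclusive states are scored: high crouch nursing (`HG`), low
crouch nursing (`LW`), supine nursing (`SUP`), licking/grooming alone (`L`),
high crouch while licking (`HG/L`), dam in nest not nursing (`DN`), and dam
off nest (`OFF`). `HG/L` is a first-class code, not a flag pair: licking
essentially always co-occurs with high crouch, so the combination is its own
behavioral state and its own network node. Licking *alone* is scored (it
appears in frequency analyses) but is not a network node. Event-type
behaviors that can co-occur with any state (nest building, pup retrieval,
self-grooming, pups off nest) ride on a slot as auxiliary annotations; they
are countable responses for the ANOVA layer but never enter transition
counting, since the network describes transitions between the dam's
exclusive states.

Datasets are long tables, one row per scan sample, with sessions of exactly
25 slots (0-based) per (dam, day, period); `beh_dataset()` validates all of
this and errors name the offending row.

## Transition networks

Within one session, every adjacent pair of samples with differing codes is a
directed transition. Two statistics must be distinguished:

* the **transition count** over the raw 7-code sequence
  (`transition_count(scope = "all")`) — this is the classical fragmentation
  statistic computed *before* any network abstraction, and it is what the
  ANOVA layer analyzes;
* the **network transition matrix** (`transition_matrix()`), a 6×6
  zero-diagonal count matrix over the node codes, computed *after* removing
  `L` slots.

Two `L`-removal policies are implemented because the choice is genuinely
open: `bridge` (default) deletes `L` slots so their neighbors become
adjacent, preserving sequence continuity; `drop` discards any pair touching
an `L` slot, never inventing an adjacency that was not observed. On data
where `L` is rare (the empirical situation that motivates excluding it) the
two agree almost everywhere. The policy is recorded in every network's
context and in the pipeline run log. Transitions are never counted across
period boundaries — hours of unobserved behavior separate the periods.

Per dam and day, the light phase is represented by the element-wise *mean*
of the two light-period matrices and occurrence vectors (the two light
periods are statistically indistinguishable and treated as exchangeable);
the dark phase by the single dark session. Group networks
(`build_group_network()`) are element-wise means over dams, so the total
edge weight equals the group-mean per-dam transition count between nodes — a
conservation identity the tests exploit.

## Centrality

In-strength and out-strength are column and row sums of the weight matrix:
how strongly a behavior is entered from, and leads into, the rest of the
repertoire. Betweenness uses the classical fractional shortest-path count
(Brandes accumulation, endpoints excluded, unnormalized): node *v* receives
\(\sum_{s \ne t \ne v} \sigma_{st}(v)/\sigma_{st}\).

Betweenness has a genuinely open modeling choice on weighted digraphs.
The default `binary` mode places a unit-length edge wherever weight is
positive — the textbook count-of-shortest-paths definition, with no
weight-to-distance conversion. The `weighted` mode uses edge length
1/weight, so frequently used transitions are "shorter". Both are exposed,
the mode is recorded in output metadata, and neither is asserted to be the
single correct choice. Zero-weight edges are absent in both modes (no
epsilon flooring). Ties in path length are detected with a relative
tolerance of 1e-10; with continuous weights exact ties are essentially
confined to the binary mode, where lengths are integers and the comparison
is exact at that tolerance.

Centrality profiles are z-standardized *within one network* — across its 6
nodes, per (group, phase, day) — so day-by-day trajectories of different
networks share a common scale. The population SD (divide by *n*) is used; a
constant profile (SD 0) maps to all zeros rather than NaN. Raw betweenness
is reported unnormalized since the z-score removes scale anyway.

## Group statistics

`response_table()` extracts one value per (dam, day): an occurrence count,
an auxiliary-event count, or the raw transition count; light-phase values
are AM/PM means. `mixed_anova()` is the classical univariate split-plot
decomposition for the balanced two-group repeated-measures design: housing
is tested against subjects-within-groups, day and day×housing against
day-by-subjects-within-groups. With 2 groups × 9 dams × 8 days this yields
df (1, 16) and (7, 112). No sphericity correction is applied by default —
the uncorrected df are the ones this design reports — but a
Greenhouse–Geisser option (`gg = TRUE`) is available. Unbalanced inputs are
rejected with the missing cells named rather than approximated: the
closed-form decomposition is exact only for balanced data, and the emulated
design is balanced. Degenerate inputs (all responses equal) report F = 0,
p = 1 by convention instead of 0/0.

Šídák post hoc comparisons contrast the two groups within each day:
\(p_{adj} = 1 - (1 - p_{raw})^m\) with the family size *m* defaulting to the
number of days (8). The t statistics use Winer's pooled error — the
subjects-within plus day-by-subjects sums of squares over their pooled df —
which is the appropriate error for a between-group contrast at a fixed
within-subject level and the one mainstream commercial packages use for this
family. This family definition is an interpretive choice and is documented
as such.

## The synthetic generator

No raw observation data are distributable, so the generator is a
first-class, tested module that emulates the study conditions. Each (group,
period-class) has a `phase_profile()`: an initial distribution over the 7
codes, a zero-diagonal switch kernel, a fragmentation parameter *f* (the
per-slot switch probability), and a per-day drift on *f*. The one-step
chain is \(T = (1-f_d) I + f_d K\), so the expected per-session transition
count is exactly \(24 f_d\) — a closed form the tests check by Monte Carlo.
Factoring *f* out of the kernel makes "more fragmented, same repertoire" a
one-parameter manipulation, mirroring how fragmentation is defined as
transition frequency.

The default switch kernel resamples the destination from the initial
distribution conditioned on leaving the current state
(\(K_{ij} = p_j/(1-p_i)\)); its stationary occupancy is proportional to
\(p_i(1-p_i)\), which preserves the intended dominance ordering of every
preset. The default presets encode the qualitative effect pattern of the
LBN paradigm as sign constraints:

| profile | shape | f | drift/day |
|---|---|---|---|
| CTRL light | HG-dominant | 0.35 | −0.015 |
| CTRL dark | OFF-dominant | 0.30 | −0.015 |
| LBN light | HG boosted, SUP suppressed | 0.35 | −0.015 |
| LBN dark | HG boosted | **0.45** | −0.015 |

The *f* and drift values are tuning choices — no quantitative dwell-time
data exist to fit them — picked once for realism (≈6–10 transitions per
25-sample dark session, declining across days) and labeled as such in the
shipped config file. The elevated LBN dark-phase *f* reproduces the
direction of the dark-phase fragmentation effect; its magnitude is a preset
choice, not an empirical claim. AM and PM share one light profile. Each dam
draws from its own seed derived from the global seed with fixed per-group
offsets, so adding dams never reshuffles existing dams' sequences, and the
caller's RNG state is left untouched.

What the generator does *not* emulate: dwell-time distributions beyond
geometric (no semi-Markov structure), pup-state feedback, litter-size
effects, time-of-day structure within a period, auxiliary events, and
between-dam heterogeneity (all dams in a group share one profile — the
generator is, by design, the null model of its own group label). Passing
tests therefore demonstrate correctness of the *machinery* and calibration
under Markovian data, not that real maternal behavior is Markovian.

## Numerical and design choices

* Fragmentation is clamped to [0, 1] after drift; f = 0 and f = 1 are valid
  degenerate chains (constant and always-switching).
* The ANOVA decomposition is validated two ways: the sums of squares add up
  to the total within 1e-9 relative, and F/p match `aov()` with an
  `Error(dam)` stratum to 1e-10 on random designs.
* Betweenness is validated against exhaustive simple-path enumeration on
  all 4,096 directed 4-node graphs and random weighted 6-node graphs (both
  modes, 1e-9), and against igraph on random digraphs.
* Pipeline outputs are TSV-first, written atomically (write-then-rename),
  and byte-identical under a fixed config and seed; plots are optional
  derivatives. Heat maps export the raw 6×6 weight matrix; the rendered
  PNG uses a white-to-red scale (lowest to highest weight) that is
  mimicked, not bit-asserted.
* Statistical calibration is checked by simulation: with both groups
  generated from the control profiles, the housing effect rejects at
  close to the nominal 5% level over 2,000 replicate experiments; under the
  default presets the dark-phase transition ANOVA detects the housing
  effect with power above 0.8. Heavier Monte-Carlo settings (replicates,
  chain lengths, session counts: 2,000 experiments, 1e5-step chains, 4e4
  sessions) are sized to keep the full suite in the low minutes while
  leaving comfortable statistical margins.

## A worked example

```{r example, eval = FALSE}
cfg <- sim_config(n_dams_per_group = 9, seed = 1)
d <- simulate_dataset(cfg)

net <- build_group_network(d, "LBN", "DARK", ppd = 2)
print(net)
head(centrality_table(net), 6)

rt <- response_table(d, "transitions", "DARK")
mixed_anova(rt)
sidak_posthoc(rt)

run_pipeline("lbn_run", dataset = d)          # full TSV export
```

From the shell, the same pipeline is:

```sh
Rscript inst/exec/ethonet run --seed 1 --out lbn_run --no-plots
```

## Limitations

The package analyzes the *average* network per group; it does not model
between-dam variation in network structure (per-dam networks are available
via `phase_aggregate()`, but no inferential machinery is attached to them).
The ANOVA layer is balanced-only by design. Only first-order (lag-1)
transitions are considered; no temporal-motif or multilayer analysis.
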