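# From code sequences to transition counts, occurrence counts, per-dam
# transition matrices and group-averaged behavior networks.

# Apply the licking-exclusion policy to a raw code sequence and return the
# retained adjacent (from, to) pairs. bridge: L slots are removed and their
# neighbors become adjacent; drop: any adjacent pair touching an L slot is
# discarded. Transitions are only ever counted within one period.
node_pairs <- function(codes, l_policy = c("bridge", "drop")) {
  l_policy <- match.arg(l_policy)
  if (l_policy == "bridge") {
    x <- codes[codes != "L"]
    if (length(x) < 2) return(list(from = character(), to = character()))
    list(from = x[-length(x)], to = x[-1])
  } else {
    n <- length(codes)
    if (n < 2) return(list(from = character(), to = character()))
    a <- codes[-n]
    b <- codes[-1]
    keep <- a != "L" & b != "L"
    list(from = a[keep], to = b[keep])
  }
}

#' Count behavioral transitions in a session
#'
#' A transition is an adjacent pair of scan samples with differing codes. With
#' `scope = "all"` (the default, the statistic used for the per-period
#' transition-frequency analysis) the raw 7-code sequence is compared
#' directly; with `scope = "network"` the licking-exclusion policy is applied
#' first, so the count equals the off-diagonal sum of [transition_matrix()].
#'
#' @param codes Character vector of behavior codes (one session: 25 slots).
#' @param scope `"all"` or `"network"`.
#' @param l_policy Licking-exclusion policy for `scope = "network"`; see
#'   [transition_matrix()].
#' @return Integer count in `[0, length(codes) - 1]`.
#' @export
#' @examples
#' transition_count(c("HG", "HG", "LW", "HG"))  # 2
transition_count <- function(codes, scope = c("all", "network"),
                             l_policy = c("bridge", "drop")) {
  scope <- match.arg(scope)
  if (length(codes) == 0) stop("empty code sequence")
  if (scope == "all") {
    if (length(codes) < 2) return(0L)
    return(sum(codes[-1] != codes[-length(codes)]))
  }
  p <- node_pairs(codes, match.arg(l_policy))
  sum(p$from != p$to)
}

#' Per-code occurrence counts of a session
#'
#' @param codes Character vector of behavior codes.
#' @return Named integer vector over the 7 codes, summing to `length(codes)`
#'   (25 for a full session).
#' @export
occurrence_counts <- function(codes) {
  if (length(codes) == 0) stop("empty code sequence")
  counts <- table(factor(codes, levels = .CODES))
  stats::setNames(as.integer(counts), .CODES)
}

#' Transition matrix of a code sequence
#'
#' Counts directed switches between the 6 network nodes. Licking-alone (`L`)
#' slots are excluded first under one of two policies: `bridge` (default)
#' removes `L` slots so their neighbors become adjacent before pair counting;
#' `drop` discards any adjacent pair touching an `L` slot. Each remaining
#' adjacent unequal pair (a, b) increments `weights[a, b]`; equal pairs
#' contribute nothing (no self-links: the diagonal is structurally zero).
#'
#' @inheritParams transition_count
#' @param l_policy `"bridge"` or `"drop"`.
#' @return 6x6 non-negative integer matrix with zero diagonal, rows/cols in
#'   [network_nodes()] order.
#' @export
#' @examples
#' transition_matrix(c("HG", "L", "LW"))                    # one HG -> LW
#' transition_matrix(c("HG", "L", "LW"), l_policy = "drop") # all zero
transition_matrix <- function(codes, l_policy = c("bridge", "drop")) {
  if (length(codes) == 0) stop("empty code sequence")
  p <- node_pairs(codes, match.arg(l_policy))
  keep <- p$from != p$to
  m <- table(factor(p$from[keep], levels = .NODES),
             factor(p$to[keep], levels = .NODES))
  m <- matrix(as.numeric(m), 6, 6, dimnames = list(.NODES, .NODES))
  m
}

# Per-session values needed downstream, computed in bulk: transition matrix,
# node occurrences (6 nodes), full occurrences (7 codes), transition counts.
session_values <- function(dataset, l_policy = "bridge") {
  sm <- session_matrix(dataset)
  n <- ncol(sm$codes)
  mats <- vector("list", n)
  occ <- matrix(0, n, 7, dimnames = list(NULL, .CODES))
  for (i in seq_len(n)) {
    mats[[i]] <- transition_matrix(sm$codes[, i], l_policy = l_policy)
    occ[i, ] <- occurrence_counts(sm$codes[, i])
  }
  trans_all <- colSums(sm$codes[-1, , drop = FALSE] !=
                         sm$codes[-.N_SLOTS, , drop = FALSE])
  list(info = sm$info, matrices = mats, occurrences = occ,
       transitions = trans_all)
}

#' Aggregate one dam's day into light- and dark-phase matrices
#'
#' The light phase is represented by the element-wise mean of the `AM` and
#' `PM` transition matrices and occurrence vectors; the dark phase by the
#' single `DARK` session's values. Transitions are never counted across
#' period boundaries.
#'
#' @param dataset A [beh_dataset].
#' @param dam_id Dam identifier.
#' @param ppd Postpartum day.
#' @param l_policy Licking-exclusion policy, see [transition_matrix()].
#' @return List with elements `LIGHT` and `DARK`, each a list holding
#'   `weights` (6x6 matrix), `node_sizes` (occurrences of the 6 node codes)
#'   and `occurrences` (all 7 codes, sums to 25).
#' @export
phase_aggregate <- function(dataset, dam_id, ppd,
                            l_policy = c("bridge", "drop")) {
  l_policy <- match.arg(l_policy)
  per <- list()
  for (period in .PERIODS) {
    codes <- session_codes(dataset, dam_id, ppd, period)
    if (is.null(codes))
      stop("missing session for dam ", dam_id, ", ppd ", ppd,
           ", period ", period)
    per[[period]] <- list(weights = transition_matrix(codes, l_policy),
                          occurrences = occurrence_counts(codes))
  }
  light_w <- (per$AM$weights + per$PM$weights) / 2
  light_o <- (per$AM$occurrences + per$PM$occurrences) / 2
  list(
    LIGHT = list(weights = light_w, node_sizes = light_o[.NODES],
                 occurrences = light_o),
    DARK = list(weights = per$DARK$weights,
                node_sizes = per$DARK$occurrences[.NODES],
                occurrences = per$DARK$occurrences))
}

#' Build a group-averaged behavior network
#'
#' Edge weights and node sizes are element-wise means over dams of the
#' per-dam phase-aggregated transition matrices and node occurrence counts
#' (light phase: mean of the two light periods; dark phase: the dark period).
#' Node size is the mean number of scan samples in which the behavior
#' occurred per period; edge weights may be fractional.
#'
#' @param dataset A [beh_dataset].
#' @param group `"CTRL"` or `"LBN"`.
#' @param phase `"LIGHT"` or `"DARK"`.
#' @param ppd Postpartum day.
#' @param l_policy Licking-exclusion policy, see [transition_matrix()].
#' @return An object of class `beh_network`: list with `nodes`, `node_sizes`,
#'   `weights` (6x6, zero diagonal) and `context` (group, phase, ppd, n_dams,
#'   l_policy).
#' @export
#' @examples
#' d <- simulate_dataset(sim_config(n_dams_per_group = 3, seed = 7))
#' net <- build_group_network(d, "LBN", "DARK", ppd = 2)
#' print(net)
build_group_network <- function(dataset, group, phase = c("LIGHT", "DARK"),
                                ppd, l_policy = c("bridge", "drop")) {
  phase <- match.arg(phase)
  l_policy <- match.arg(l_policy)
  if (!group %in% .GROUPS) stop("unknown group '", group, "'")
  info <- session_info(dataset)
  need <- if (phase == "LIGHT") c("AM", "PM") else "DARK"
  dams <- unique(info$dam_id[info$group == group])
  qual <- dams[vapply(dams, function(d) {
    have <- info$period[info$dam_id == d & info$ppd == ppd]
    all(need %in% have)
  }, logical(1))]
  if (length(qual) == 0)
    stop("no dams in group ", group, " with complete ", phase,
         " sessions on ppd ", ppd)
  w <- matrix(0, 6, 6, dimnames = list(.NODES, .NODES))
  sizes <- stats::setNames(numeric(6), .NODES)
  for (d in qual) {
    per <- lapply(need, function(period) {
      codes <- session_codes(dataset, d, ppd, period)
      list(w = transition_matrix(codes, l_policy),
           o = occurrence_counts(codes)[.NODES])
    })
    w <- w + Reduce(`+`, lapply(per, `[[`, "w")) / length(per)
    sizes <- sizes + Reduce(`+`, lapply(per, `[[`, "o")) / length(per)
  }
  structure(list(nodes = .NODES,
                 node_sizes = sizes / length(qual),
                 weights = w / length(qual),
                 context = list(group = group, phase = phase, ppd = ppd,
                                n_dams = length(qual), l_policy = l_policy)),
            class = "beh_network")
}

#' @export
print.beh_network <- function(x, ...) {
  ctx <- x$context
  cat(sprintf("Behavior transition network: %s, %s phase, PPD %d (%d dams)\n",
              ctx$group, ctx$phase, ctx$ppd, ctx$n_dams))
  cat("  total edge weight:", round(sum(x$weights), 3), "\n")
  cat("  node sizes (mean events/period):\n")
  print(round(x$node_sizes, 2))
  invisible(x)
}
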