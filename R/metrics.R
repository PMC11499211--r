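# Centrality measures on directed weighted behavior networks.
#
# In-strength and out-strength are column and row sums of the weight matrix.
# Betweenness uses the classical fractional shortest-path count (Brandes
# accumulation): for each ordered pair (s, t) the node v != s, t receives
# sigma_st(v) / sigma_st, where sigma_st counts shortest directed s->t paths.
# In binary mode (default) an edge exists iff its weight is positive and has
# unit length; in weighted mode edge length is 1/weight, so heavier edges are
# shorter. Pairs with no connecting path contribute nothing.

as_weight_matrix <- function(net) {
  if (inherits(net, "beh_network")) return(net$weights)
  m <- as.matrix(net)
  if (nrow(m) != ncol(m)) stop("weight matrix must be square")
  if (any(m < 0)) stop("weights must be non-negative")
  m
}

metric_names <- function(m) {
  if (!is.null(rownames(m))) rownames(m) else paste0("V", seq_len(nrow(m)))
}

#' In-strength of each node
#'
#' Total weight of incoming links, `sum_u w[u, v]`: how strongly a behavioral
#' component is reached from other components.
#'
#' @param net A `beh_network` or a non-negative square weight matrix.
#' @return Named numeric vector, one value per node.
#' @export
in_strength <- function(net) {
  m <- as_weight_matrix(net)
  stats::setNames(colSums(m), metric_names(m))
}

#' Out-strength of each node
#'
#' Total weight of outgoing links, `sum_v w[u, v]`: how strongly a behavioral
#' component leads into other components.
#'
#' @inheritParams in_strength
#' @return Named numeric vector, one value per node.
#' @export
out_strength <- function(net) {
  m <- as_weight_matrix(net)
  stats::setNames(rowSums(m), metric_names(m))
}

#' Betweenness centrality
#'
#' Fractional count of shortest directed paths through each node (Brandes /
#' Freeman convention, endpoints excluded, unnormalized). `mode = "binary"`
#' (default) treats every positive-weight edge as present with unit length;
#' `mode = "weighted"` uses length `1/weight`. Zero-weight edges are absent
#' in both modes.
#'
#' @inheritParams in_strength
#' @param mode `"binary"` or `"weighted"`.
#' @return Named numeric vector, one value per node; bounded by
#'   `(n - 1) * (n - 2)`.
#' @export
#' @examples
#' m <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' m["A", "B"] <- 1; m["B", "C"] <- 1
#' betweenness(m)  # B lies on the single A->C shortest path
betweenness <- function(net, mode = c("binary", "weighted")) {
  mode <- match.arg(mode)
  w <- as_weight_matrix(net)
  n <- nrow(w)
  adj <- w > 0
  len <- if (mode == "binary") ifelse(adj, 1, Inf) else ifelse(adj, 1 / w, Inf)
  bc <- numeric(n)
  for (s in seq_len(n)) {
    # Dijkstra with shortest-path counting
    dist <- rep(Inf, n)
    dist[s] <- 0
    sigma <- numeric(n)
    sigma[s] <- 1
    preds <- vector("list", n)
    done <- logical(n)
    order_done <- integer(0)
    repeat {
      cand <- which(!done & is.finite(dist))
      if (length(cand) == 0) break
      u <- cand[which.min(dist[cand])]
      done[u] <- TRUE
      order_done <- c(order_done, u)
      for (v in which(adj[u, ] & !done)) {
        alt <- dist[u] + len[u, v]
        tol <- 1e-10 * max(1, abs(alt))
        if (alt < dist[v] - tol) {
          dist[v] <- alt
          sigma[v] <- sigma[u]
          preds[[v]] <- u
        } else if (abs(alt - dist[v]) <= tol) {
          sigma[v] <- sigma[v] + sigma[u]
          preds[[v]] <- c(preds[[v]], u)
        }
      }
    }
    delta <- numeric(n)
    for (u in rev(order_done)) {
      for (p in preds[[u]])
        delta[p] <- delta[p] + sigma[p] / sigma[u] * (1 + delta[u])
      if (u != s) bc[u] <- bc[u] + delta[u]
    }
  }
  stats::setNames(bc, metric_names(w))
}

#' z-standardize a vector of node values
#'
#' Centers and scales by the population standard deviation across the nodes
#' of one network (the convention used when centrality profiles of different
#' days are plotted on a common z scale). A constant vector (SD 0) maps to
#' all zeros.
#'
#' @param values Numeric vector of at least 2 node values.
#' @return Numeric vector with mean 0 and population SD 1 (or all zeros).
#' @export
#' @examples
#' zscore(c(1, 2, 3))  # -1.2247, 0, 1.2247
zscore <- function(values) {
  if (length(values) < 2) stop("need at least 2 values to standardize")
  m <- mean(values)
  s <- sqrt(mean((values - m)^2))
  if (s < 1e-12) return(stats::setNames(rep(0, length(values)), names(values)))
  (values - m) / s
}

#' Centrality table of a behavior network
#'
#' Raw and z-standardized in-strength, out-strength and betweenness for every
#' node, in long format.
#'
#' @param net A `beh_network`.
#' @param betweenness_mode Passed to [betweenness()].
#' @return Data frame with columns `group`, `phase`, `ppd`, `code`, `metric`,
#'   `raw`, `z` (18 rows: 6 nodes x 3 metrics).
#' @export
centrality_table <- function(net, betweenness_mode = c("binary", "weighted")) {
  stopifnot(inherits(net, "beh_network"))
  betweenness_mode <- match.arg(betweenness_mode)
  ctx <- net$context
  vals <- list(in_strength = in_strength(net),
               out_strength = out_strength(net),
               betweenness = betweenness(net, mode = betweenness_mode))
  out <- do.call(rbind, lapply(names(vals), function(metric) {
    v <- vals[[metric]]
    data.frame(group = ctx$group, phase = ctx$phase, ppd = ctx$ppd,
               code = names(v), metric = metric,
               raw = unname(v), z = unname(zscore(v)),
               stringsAsFactors = FALSE)
  }))
  attr(out, "betweenness_mode") <- betweenness_mode
  rownames(out) <- NULL
  out
}
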