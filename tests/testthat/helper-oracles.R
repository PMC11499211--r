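# Independent oracles and small generators used across the suite.

# --- exhaustive betweenness oracle ------------------------------------------
# Enumerates every simple directed path between each ordered node pair,
# identifies the shortest ones by total length, and credits intermediate
# nodes fractionally. Deliberately brute force and independent of the
# Dijkstra/Brandes implementation under test.

enum_simple_paths <- function(adj, s, t) {
  n <- nrow(adj)
  paths <- list()
  walk <- function(path) {
    u <- path[length(path)]
    if (u == t) {
      paths[[length(paths) + 1]] <<- path
      return()
    }
    for (v in which(adj[u, ])) if (!v %in% path) walk(c(path, v))
  }
  walk(s)
  paths
}

enum_betweenness <- function(w, mode = "binary") {
  n <- nrow(w)
  adj <- w > 0
  len <- if (mode == "binary") ifelse(adj, 1, Inf) else ifelse(adj, 1 / w, Inf)
  bc <- numeric(n)
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s == t) next
    paths <- enum_simple_paths(adj, s, t)
    if (length(paths) == 0) next
    plen <- vapply(paths, function(p) {
      sum(len[cbind(p[-length(p)], p[-1])])
    }, numeric(1))
    dmin <- min(plen)
    shortest <- paths[plen <= dmin + 1e-10 * max(1, dmin)]
    sigma <- length(shortest)
    for (p in shortest) {
      inner <- p[-c(1, length(p))]
      bc[inner] <- bc[inner] + 1 / sigma
    }
  }
  bc
}

random_weight_matrix <- function(n = 6, density = 0.5) {
  w <- matrix(0, n, n)
  edges <- which(matrix(stats::runif(n * n) < density, n, n) & !diag(n) > 0)
  w[edges] <- stats::runif(length(edges), 0.2, 5)
  w
}

# --- split-plot ANOVA cross-check via stats::aov ----------------------------

aov_mixed_oracle <- function(rt) {
  x <- as.data.frame(rt)
  x$group <- factor(x$group)
  x$ppd <- factor(x$ppd)
  x$dam_id <- factor(x$dam_id)
  fit <- stats::aov(value ~ group * ppd + Error(dam_id), data = x)
  sm <- summary(fit)
  b <- sm[["Error: dam_id"]][[1]]
  w <- sm[["Error: Within"]][[1]]
  clean <- function(tab) {
    rn <- trimws(rownames(tab))
    stats::setNames(
      lapply(seq_len(nrow(tab)), function(i)
        list(df = tab[i, "Df"], ss = tab[i, "Sum Sq"],
             F = tab[i, "F value"], p = tab[i, "Pr(>F)"])), rn)
  }
  list(between = clean(b), within = clean(w))
}

# --- dataset fixtures -------------------------------------------------------

# Observation rows only, shorn of class/metadata/rownames, for comparing
# datasets regardless of provenance.
obs_rows <- function(d) {
  x <- as.data.frame(d)
  attr(x, "metadata") <- NULL
  class(x) <- "data.frame"
  rownames(x) <- NULL
  x
}

# Hand-built dataset: n_dams per group x days x all three periods, codes
# supplied by `code_fun(group, dam, ppd, period)` returning 25 codes.
make_dataset <- function(n_dams = 2, ppds = 2:3,
                         code_fun = function(g, d, p, per) rep("HG", 25)) {
  rows <- list()
  for (g in c("CTRL", "LBN")) for (i in seq_len(n_dams)) {
    id <- sprintf("%s%02d", substr(g, 1, 1), i)
    for (ppd in ppds) for (per in c("AM", "PM", "DARK")) {
      rows[[paste(id, ppd, per)]] <- data.frame(
        dam_id = id, group = g, ppd = ppd, period = per, slot = 0:24,
        code = code_fun(g, i, ppd, per), aux = "",
        stringsAsFactors = FALSE)
    }
  }
  beh_dataset(do.call(rbind, rows))
}

random_codes <- function(n = 25) sample(behavior_codes(), n, replace = TRUE)

# a small profile with a distinctive, hand-specified switch kernel
test_profile <- function(f = 0.5, drift = 0) {
  p <- c(0.30, 0.15, 0.10, 0.05, 0.10, 0.15, 0.15)
  phase_profile(p, fragmentation = f, day_drift = drift)
}
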