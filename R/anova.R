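# Frequency-level group statistics: response tables, two-way mixed
# (split-plot) repeated-measures ANOVA, Sidak post hoc comparisons, and
# mean +/- SEM summaries.

#' Build a per-dam response table
#'
#' Extracts one value per (dam, postpartum day) for a chosen response and
#' phase. Light-phase values are the mean of the two light-period sessions;
#' dark-phase values come from the single dark session. The table must be
#' complete and balanced (every dam observed on every day), as required by
#' the repeated-measures decomposition.
#'
#' @param dataset A [beh_dataset].
#' @param response `"transitions"` (per-session transition count over the raw
#'   7-code sequence), one of [behavior_codes()] (per-session occurrence
#'   count), or one of [aux_codes()] (per-session count of slots annotated
#'   with that auxiliary event).
#' @param phase `"LIGHT"` or `"DARK"`.
#' @return An object of class `beh_response`: data frame with columns
#'   `dam_id`, `group`, `ppd`, `value`.
#' @export
#' @examples
#' d <- simulate_dataset(sim_config(n_dams_per_group = 3, seed = 1))
#' rt <- response_table(d, "transitions", "DARK")
#' summary(rt)
response_table <- function(dataset, response = "transitions",
                           phase = c("LIGHT", "DARK")) {
  phase <- match.arg(phase)
  x <- as.data.frame(dataset)
  if (nrow(x) == 0) stop("empty dataset")
  info <- session_info(dataset)
  sm <- session_matrix(dataset)
  if (identical(response, "transitions")) {
    v <- colSums(sm$codes[-1, , drop = FALSE] !=
                   sm$codes[-.N_SLOTS, , drop = FALSE])
  } else if (response %in% .CODES) {
    v <- colSums(sm$codes == response)
  } else if (response %in% .AUX) {
    aux <- matrix(x$aux, nrow = .N_SLOTS)
    v <- colSums(matrix(vapply(
      strsplit(aux, ";", fixed = TRUE),
      function(tok) response %in% tok, logical(1)), nrow = .N_SLOTS))
  } else {
    stop("unknown response '", response, "'")
  }
  info$value <- as.numeric(v)

  need <- if (phase == "LIGHT") c("AM", "PM") else "DARK"
  dams <- unique(info[, c("dam_id", "group")])
  ppds <- sort(unique(info$ppd))
  cells <- expand.grid(dam_id = dams$dam_id, ppd = ppds,
                       period = need, stringsAsFactors = FALSE)
  have <- paste(info$dam_id, info$ppd, info$period)
  missing <- cells[!paste(cells$dam_id, cells$ppd, cells$period) %in% have, ]
  if (nrow(missing) > 0)
    stop("unbalanced data; missing cell(s): ",
         paste(sprintf("(dam %s, ppd %d, %s)", missing$dam_id, missing$ppd,
                       missing$period)[seq_len(min(5, nrow(missing)))],
               collapse = ", "))

  sub <- info[info$period %in% need, ]
  agg <- stats::aggregate(value ~ dam_id + group + ppd, data = sub, FUN = mean)
  agg <- agg[order(agg$dam_id, agg$ppd), c("dam_id", "group", "ppd", "value")]
  rownames(agg) <- NULL
  structure(agg, response = response, phase = phase,
            class = c("beh_response", "data.frame"))
}

#' Mean and SEM per group and day
#'
#' @param object A `beh_response`.
#' @param ... Unused.
#' @return Data frame with columns `group`, `ppd`, `n`, `mean`, `sem`
#'   (SEM = sample SD / sqrt(n); requires at least 2 dams per group).
#' @export
summary.beh_response <- function(object, ...) {
  x <- as.data.frame(object)
  out <- do.call(rbind, lapply(split(x, list(x$group, x$ppd), drop = TRUE),
    function(cell) {
      n <- nrow(cell)
      if (n < 2) stop("need at least 2 dams per group for SEM")
      data.frame(group = cell$group[1], ppd = cell$ppd[1], n = n,
                 mean = mean(cell$value),
                 sem = stats::sd(cell$value) / sqrt(n),
                 stringsAsFactors = FALSE)
    }))
  out <- out[order(out$group, out$ppd), ]
  rownames(out) <- NULL
  out
}

#' @export
print.beh_response <- function(x, ...) {
  cat("Response table:", attr(x, "response"), "|", attr(x, "phase"),
      "phase |", length(unique(x$dam_id)), "dams x",
      length(unique(x$ppd)), "days\n")
  print(as.data.frame(utils::head(x, 8)))
  if (nrow(x) > 8) cat("  ...", nrow(x) - 8, "more rows\n")
  invisible(x)
}

#' Two-way mixed repeated-measures ANOVA
#'
#' Classical univariate split-plot decomposition for a balanced design with
#' one between-subjects factor (housing group) and one within-subjects factor
#' (postpartum day), subjects (dams) nested in groups. The housing effect is
#' tested against subjects-within-groups; day and the interaction against
#' day-by-subjects-within-groups. With `g` groups of `n` dams over `d` days
#' the degrees of freedom are `(g-1, g(n-1))` for housing and
#' `(d-1, (d-1)g(n-1))` for day and interaction. No sphericity correction is
#' applied by default (set `gg = TRUE` for Greenhouse--Geisser-adjusted
#' day/interaction p-values).
#'
#' Degenerate inputs: if an effect and its error sum of squares are both zero
#' (e.g. all responses equal), F is reported as 0 with p = 1 by convention;
#' a zero error SS with a positive effect SS yields F = Inf, p = 0.
#'
#' @param table A `beh_response` from [response_table()]; must be balanced
#'   with equal group sizes and at least 2 dams per group.
#' @param gg Apply the Greenhouse--Geisser sphericity correction to the
#'   within-subject tests (default `FALSE`; the classical uncorrected df are
#'   reported either way).
#' @return An object of class `beh_anova` with a per-effect table (`F`,
#'   `df1`, `df2`, `p`) and the full sums-of-squares decomposition.
#' @export
#' @examples
#' d <- simulate_dataset(sim_config(n_dams_per_group = 3, seed = 1))
#' mixed_anova(response_table(d, "transitions", "DARK"))
mixed_anova <- function(table, gg = FALSE) {
  x <- as.data.frame(table)
  stopifnot(all(c("dam_id", "group", "ppd", "value") %in% names(x)))
  dams <- unique(x[, c("dam_id", "group")])
  groups <- sort(unique(dams$group))
  g <- length(groups)
  if (g < 2) stop("need at least 2 groups")
  sizes <- base::table(dams$group)
  if (length(unique(as.integer(sizes))) != 1)
    stop("unbalanced design: unequal group sizes (",
         paste(sizes, collapse = " vs "), ")")
  n <- as.integer(sizes[1])
  if (n < 2) stop("need at least 2 dams per group")
  ppds <- sort(unique(x$ppd))
  d <- length(ppds)
  if (d < 2) stop("need at least 2 within-subject levels")
  cnt <- base::table(x$dam_id, x$ppd)
  if (any(cnt != 1))
    stop("unbalanced design: each dam needs exactly one value per day")

  # response matrix, dams in rows, days in columns
  Y <- matrix(NA_real_, g * n, d,
              dimnames = list(dams$dam_id[order(dams$group, dams$dam_id)],
                              ppds))
  for (i in seq_len(nrow(x)))
    Y[x$dam_id[i], as.character(x$ppd[i])] <- x$value[i]
  dam_group <- dams$group[match(rownames(Y), dams$dam_id)]

  gm <- mean(Y)
  subj_means <- rowMeans(Y)
  day_means <- colMeans(Y)
  grp_means <- tapply(subj_means, dam_group, mean)[groups]
  cell_means <- apply(Y, 2, function(col) tapply(col, dam_group, mean))
  # cell_means: g x d (groups x days)

  ss_total <- sum((Y - gm)^2)
  ss_housing <- n * d * sum((grp_means - gm)^2)
  ss_subj <- d * sum((subj_means - grp_means[match(dam_group, groups)])^2)
  ss_day <- g * n * sum((day_means - gm)^2)
  ss_int <- n * sum((cell_means -
                       outer(grp_means, rep(1, d)) -
                       outer(rep(1, g), day_means) + gm)^2)
  ss_err <- ss_total - ss_housing - ss_subj - ss_day - ss_int
  ss_err <- max(ss_err, 0)

  df_h <- g - 1
  df_s <- g * (n - 1)
  df_d <- d - 1
  df_i <- (g - 1) * (d - 1)
  df_e <- (d - 1) * g * (n - 1)

  f_of <- function(ss_eff, df_eff, ss_er, df_er) {
    tol <- 1e-12 * max(1, ss_total)
    ms_eff <- ss_eff / df_eff
    ms_er <- ss_er / df_er
    if (ms_er <= tol) {
      if (ms_eff <= tol) return(c(F = 0, p = 1))  # degenerate: flat data
      return(c(F = Inf, p = 0))
    }
    f <- ms_eff / ms_er
    c(F = f, p = stats::pf(f, df_eff, df_er, lower.tail = FALSE))
  }
  fh <- f_of(ss_housing, df_h, ss_subj, df_s)
  fd <- f_of(ss_day, df_d, ss_err, df_e)
  fi <- f_of(ss_int, df_i, ss_err, df_e)

  eps <- NA_real_
  if (gg) {
    # Greenhouse-Geisser epsilon from the pooled within-group covariance
    resid <- Y - cell_means[match(dam_group, groups), , drop = FALSE]
    S <- crossprod(resid) / (g * (n - 1))
    Sc <- S - outer(rowMeans(S), rep(1, d)) -
      outer(rep(1, d), colMeans(S)) + mean(S)
    eps <- sum(diag(Sc))^2 / ((d - 1) * sum(Sc^2))
    eps <- min(max(eps, 1 / (d - 1)), 1)
    fd["p"] <- stats::pf(fd["F"], eps * df_d, eps * df_e, lower.tail = FALSE)
    fi["p"] <- stats::pf(fi["F"], eps * df_i, eps * df_e, lower.tail = FALSE)
  }

  tab <- data.frame(
    effect = c("day", "housing", "day:housing"),
    df1 = c(df_d, df_h, df_i),
    df2 = c(df_e, df_s, df_e),
    F = c(fd["F"], fh["F"], fi["F"]),
    p = c(fd["p"], fh["p"], fi["p"]),
    stringsAsFactors = FALSE)
  structure(list(
    table = tab,
    ss = c(housing = ss_housing, subjects_within = ss_subj, day = ss_day,
           interaction = ss_int, error = ss_err, total = ss_total),
    df = c(housing = df_h, subjects_within = df_s, day = df_d,
           interaction = df_i, error = df_e),
    design = list(groups = groups, n_per_group = n, days = ppds),
    gg_epsilon = eps,
    response = attr(table, "response"),
    phase = attr(table, "phase")),
    class = "beh_anova")
}

#' @export
print.beh_anova <- function(x, ...) {
  cat("Two-way mixed RM ANOVA",
      if (!is.null(x$response))
        paste0("(", x$response, ", ", x$phase, " phase)"), "\n")
  cat(sprintf("  %d groups x %d dams x %d days\n",
              length(x$design$groups), x$design$n_per_group,
              length(x$design$days)))
  tab <- x$table
  for (i in seq_len(nrow(tab)))
    cat(sprintf("  %-12s F(%d, %d) = %.4g, p = %.4g%s\n", tab$effect[i],
                tab$df1[i], tab$df2[i], tab$F[i], tab$p[i],
                if (is.finite(tab$p[i]) && tab$p[i] < 0.05) " *" else ""))
  if (!is.na(x$gg_epsilon))
    cat(sprintf("  (Greenhouse-Geisser epsilon = %.3f applied to",
                x$gg_epsilon), "within-subject p-values)\n")
  invisible(x)
}

#' @export
summary.beh_anova <- function(object, ...) {
  print(object)
  cat("  sums of squares:\n")
  print(round(object$ss, 4))
  invisible(object)
}

#' Sidak-adjusted per-day group comparisons
#'
#' Compares the two housing groups within each postpartum day with t
#' statistics built on the pooled error (subjects-within-groups plus
#' day-by-subjects error, Winer's pooled error for between-group comparisons
#' at a fixed within-subject level). Raw p-values are Sidak-adjusted,
#' `p_adj = 1 - (1 - p_raw)^m`; the family size `m` defaults to the number
#' of days compared.
#'
#' @param table A `beh_response`.
#' @param anova Optional `beh_anova` fitted on `table` (refit if omitted).
#' @param m Family size for the Sidak adjustment; default: number of days.
#' @return Data frame with one row per day: group means, difference
#'   (second group minus first, alphabetically), `t`, `df`, `p_raw`, `p_adj`.
#' @export
sidak_posthoc <- function(table, anova = NULL, m = NULL) {
  if (is.null(anova)) anova <- mixed_anova(table)
  x <- as.data.frame(table)
  groups <- anova$design$groups
  n <- anova$design$n_per_group
  ppds <- anova$design$days
  if (is.null(m)) m <- length(ppds)
  ms_pool <- (anova$ss[["subjects_within"]] + anova$ss[["error"]]) /
    (anova$df[["subjects_within"]] + anova$df[["error"]])
  df_pool <- anova$df[["subjects_within"]] + anova$df[["error"]]
  out <- do.call(rbind, lapply(ppds, function(day) {
    m1 <- mean(x$value[x$ppd == day & x$group == groups[1]])
    m2 <- mean(x$value[x$ppd == day & x$group == groups[2]])
    diff <- m2 - m1
    se <- sqrt(2 * ms_pool / n)
    t <- if (se > 0) diff / se else if (abs(diff) > 0) Inf * sign(diff) else 0
    p_raw <- if (se > 0) 2 * stats::pt(-abs(t), df_pool) else
      as.numeric(abs(diff) == 0)
    data.frame(ppd = day, mean_1 = m1, mean_2 = m2, diff = diff,
               t = t, df = df_pool, p_raw = p_raw,
               p_adj = 1 - (1 - p_raw)^m, stringsAsFactors = FALSE)
  }))
  names(out)[2:3] <- paste0("mean_", groups)
  attr(out, "m") <- m
  out
}
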