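# Response tables, mixed RM ANOVA, Sidak post hoc, mean +/- SEM summaries.

test_that("light-phase responses average the two light periods", {
  # AM: 10 HG slots, PM: 14 HG slots
  am <- c(rep("HG", 10), rep("OFF", 15))
  pm <- c(rep("HG", 14), rep("OFF", 11))
  d <- make_dataset(n_dams = 2, ppds = 2:3, code_fun = function(g, i, ppd, per)
    switch(per, AM = am, PM = pm, DARK = rep("DN", 25)))
  rt <- response_table(d, "HG", "LIGHT")
  expect_true(all(rt$value == 12))
  expect_true(all(response_table(d, "HG", "DARK")$value == 0))
  expect_true(all(response_table(d, "DN", "DARK")$value == 25))
  # transitions response equals per-session transition counts (LIGHT mean)
  rt_t <- response_table(d, "transitions", "LIGHT")
  expect_true(all(rt_t$value ==
                    (transition_count(am) + transition_count(pm)) / 2))
})

test_that("all-HG dataset gives constant 25 for HG and 0 elsewhere", {
  d <- make_dataset(n_dams = 2, ppds = 2:3)
  expect_true(all(response_table(d, "HG", "LIGHT")$value == 25))
  expect_true(all(response_table(d, "LW", "LIGHT")$value == 0))
  expect_true(all(response_table(d, "transitions", "DARK")$value == 0))
})

test_that("auxiliary events are countable responses", {
  x <- as.data.frame(make_dataset(n_dams = 2, ppds = 2:3))
  sel <- x$dam_id == "C01" & x$ppd == 2 & x$period == "DARK" & x$slot < 3
  x$aux[sel] <- "NEST_BUILD"
  x$aux[sel][1] <- "NEST_BUILD;SELF_GROOM"
  d <- beh_dataset(x)
  rt <- response_table(d, "NEST_BUILD", "DARK")
  expect_equal(rt$value[rt$dam_id == "C01" & rt$ppd == 2], 3)
  expect_equal(sum(rt$value), 3)
  rt2 <- response_table(d, "SELF_GROOM", "DARK")
  expect_equal(sum(rt2$value), 1)
})

test_that("unbalanced data is rejected with the missing cells named", {
  d <- make_dataset(n_dams = 2, ppds = 2:4)
  drop <- !(d$dam_id == "L01" & d$ppd == 3 & d$period == "PM")
  d2 <- beh_dataset(as.data.frame(d)[drop, ])
  expect_error(response_table(d2, "HG", "LIGHT"), "dam L01, ppd 3, PM")
  expect_silent(rt <- response_table(d2, "HG", "DARK"))  # dark unaffected
})

test_that("mixed ANOVA df follow the split-plot design", {
  d <- simulate_dataset(sim_config(n_dams_per_group = 9, seed = 4))
  a <- mixed_anova(response_table(d, "transitions", "DARK"))
  tab <- a$table
  expect_equal(tab[tab$effect == "housing", c("df1", "df2")],
               data.frame(df1 = 1, df2 = 16), ignore_attr = TRUE)
  expect_equal(tab[tab$effect == "day", c("df1", "df2")],
               data.frame(df1 = 7, df2 = 112), ignore_attr = TRUE)
  expect_equal(tab[tab$effect == "day:housing", c("df1", "df2")],
               data.frame(df1 = 7, df2 = 112), ignore_attr = TRUE)
})

test_that("sums of squares decompose exactly and match aov", {
  set.seed(61)
  for (i in 1:60) {
    # 2 groups x 3 dams x 4 days with random responses
    dams <- data.frame(dam_id = c("C1", "C2", "C3", "L1", "L2", "L3"),
                       group = rep(c("CTRL", "LBN"), each = 3))
    rt <- do.call(rbind, lapply(2:5, function(day)
      transform(dams, ppd = day, value = rnorm(6, mean = day))))
    class(rt) <- c("beh_response", "data.frame")
    a <- mixed_anova(rt)
    expect_equal(sum(a$ss[c("housing", "subjects_within", "day",
                            "interaction", "error")]),
                 a$ss[["total"]], tolerance = 1e-9)
    orc <- aov_mixed_oracle(rt)
    expect_equal(a$table$F[a$table$effect == "housing"],
                 orc$between$group$F, tolerance = 1e-10)
    expect_equal(a$table$p[a$table$effect == "housing"],
                 orc$between$group$p, tolerance = 1e-10)
    expect_equal(a$table$F[a$table$effect == "day"],
                 orc$within$ppd$F, tolerance = 1e-10)
    expect_equal(a$table$F[a$table$effect == "day:housing"],
                 orc$within$`group:ppd`$F, tolerance = 1e-10)
    expect_equal(a$table$p[a$table$effect == "day:housing"],
                 orc$within$`group:ppd`$p, tolerance = 1e-10)
    expect_equal(a$ss[["subjects_within"]], orc$between$Residuals$ss,
                 tolerance = 1e-10)
    expect_equal(a$ss[["error"]], orc$within$Residuals$ss, tolerance = 1e-10)
  }
})

test_that("flat responses give F = 0, p = 1 by convention", {
  d <- make_dataset(n_dams = 3, ppds = 2:5)
  a <- mixed_anova(response_table(d, "HG", "LIGHT"))  # constant 25
  expect_equal(a$table$F, rep(0, 3))
  expect_equal(a$table$p, rep(1, 3))
})

test_that("ANOVA rejects unbalanced or degenerate designs", {
  d <- make_dataset(n_dams = 3, ppds = 2:4)
  rt <- response_table(d, "HG", "DARK")
  expect_error(mixed_anova(rt[rt$dam_id != "C01", ]), "unequal group sizes")
  expect_error(mixed_anova(rt[!(rt$dam_id == "C01" & rt$ppd == 2), ]),
               "exactly one value per day")
  one_dam <- rt[rt$dam_id %in% c("C01", "L01", "L02"), ]
  expect_error(mixed_anova(one_dam), "unequal group sizes")
})

test_that("Greenhouse-Geisser option keeps F and shifts only p", {
  set.seed(71)
  d <- simulate_dataset(sim_config(n_dams_per_group = 5, seed = 71))
  rt <- response_table(d, "transitions", "LIGHT")
  a0 <- mixed_anova(rt)
  a1 <- mixed_anova(rt, gg = TRUE)
  expect_equal(a1$table$F, a0$table$F)
  expect_equal(a1$table$p[a1$table$effect == "housing"],
               a0$table$p[a0$table$effect == "housing"])
  d_levels <- length(unique(rt$ppd))
  expect_gte(a1$gg_epsilon, 1 / (d_levels - 1))
  expect_lte(a1$gg_epsilon, 1)
  expect_gte(a1$table$p[a1$table$effect == "day"],
             a0$table$p[a0$table$effect == "day"])
})

test_that("Sidak adjustment is bounded, monotone, identity at m = 1", {
  d <- simulate_dataset(sim_config(n_dams_per_group = 4, seed = 81))
  rt <- response_table(d, "transitions", "DARK")
  ph <- sidak_posthoc(rt)
  expect_equal(nrow(ph), 8)
  expect_equal(attr(ph, "m"), 8)
  expect_true(all(ph$p_adj >= ph$p_raw - 1e-12))
  expect_true(all(ph$p_adj >= 0 & ph$p_adj <= 1))
  ph1 <- sidak_posthoc(rt, m = 1)
  expect_equal(ph1$p_adj, ph1$p_raw)
  # monotone in p_raw over a grid, and exact at the bounds
  grid <- seq(0, 1, by = 0.01)
  adj <- 1 - (1 - grid)^8
  expect_true(all(diff(adj) >= 0))
  expect_equal(adj[c(1, length(adj))], c(0, 1))
})

test_that("summary reports textbook mean and SEM per group and day", {
  dams <- data.frame(dam_id = c("C1", "C2", "L1", "L2"),
                     group = rep(c("CTRL", "LBN"), each = 2))
  rt <- transform(dams, ppd = 2, value = c(2, 4, 5, 5))
  class(rt) <- c("beh_response", "data.frame")
  s <- summary(rt)
  expect_equal(s$mean[s$group == "CTRL"], 3)
  expect_equal(s$sem[s$group == "CTRL"], 1)  # sd(c(2,4))/sqrt(2) = 1
  expect_equal(s$sem[s$group == "LBN"], 0)
  set.seed(91)
  for (i in 1:50) {
    v <- rnorm(6)
    rt2 <- data.frame(dam_id = paste0("C", 1:6), group = "CTRL", ppd = 2,
                      value = v)
    class(rt2) <- c("beh_response", "data.frame")
    s2 <- summary(rt2)
    expect_equal(s2$mean, mean(v))
    expect_equal(s2$sem, sd(v) / sqrt(6))
  }
})
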