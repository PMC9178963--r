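test_that("Kruskal-Wallis H matches hand computation and the stats oracle", {
  g <- list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(7, 8, 9))
  kw <- kruskal_wallis(g)
  expect_equal(kw$statistic, 7.2)
  expect_equal(kw$df, 2)

  # all observations identical: tie-correction convention H = 0, p = 1
  const <- kruskal_wallis(list(x = rep(4, 5), y = rep(4, 6)))
  expect_equal(const$statistic, 0)
  expect_equal(const$p_value, 1)

  # independent oracle with ties
  set.seed(31)
  for (i in 1:20) {
    gr <- list(a = round(rnorm(7), 1), b = round(rnorm(9), 1),
               c = round(rnorm(5), 1))
    ours <- kruskal_wallis(gr)
    ref <- stats::kruskal.test(gr)
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ours$p_value, unname(ref$p.value), tolerance = 1e-12)
  }
})

test_that("Kruskal-Wallis H is invariant under monotone transformation", {
  set.seed(32)
  g <- list(a = rnorm(8), b = rnorm(8, 1), c = rnorm(8, 2))  # no ties a.s.
  h1 <- kruskal_wallis(g)$statistic
  h2 <- kruskal_wallis(lapply(g, exp))$statistic
  h3 <- kruskal_wallis(lapply(g, function(v) v^3))$statistic
  expect_equal(h1, h2, tolerance = 1e-12)
  expect_equal(h1, h3, tolerance = 1e-12)
})

test_that("Kruskal-Wallis detects a 2-pooled-SD shift at large n", {
  set.seed(33)
  hits <- 0
  for (i in 1:200) {
    g <- list(a = rnorm(30), b = rnorm(30, 2))
    if (kruskal_wallis(g)$p_value < 0.05) hits <- hits + 1
  }
  expect_gte(hits / 200, 0.95)
})

test_that("Dunn's z values match the brute-force oracle", {
  g <- list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(7, 8, 9))
  ours <- dunn_posthoc(g)
  ref <- dunn_oracle(g)
  expect_equal(ours$z, ref$z, tolerance = 1e-12)

  set.seed(34)
  for (i in 1:10) {
    gr <- list(a = round(rnorm(6), 1), b = round(rnorm(8), 1),
               c = round(rnorm(7), 1), d = round(rnorm(5), 1))
    ours <- dunn_posthoc(gr)
    ref <- dunn_oracle(gr)
    expect_equal(nrow(ours), 6)  # k(k-1)/2 for k = 4
    expect_equal(ours$z, ref$z, tolerance = 1e-12)
  }

  ident <- dunn_posthoc(list(a = rep(2, 4), b = rep(2, 4)))
  expect_equal(ident$z, 0)
  expect_equal(ident$p_unadjusted, 1)
})

test_that("Dunn's z is antisymmetric under group relabelling", {
  set.seed(35)
  g <- list(a = rnorm(6), b = rnorm(6), c = rnorm(6))
  fwd <- dunn_posthoc(g)
  rev <- dunn_posthoc(g[c("c", "b", "a")])
  z_ab <- fwd$z[fwd$group_i == "a" & fwd$group_j == "b"]
  z_ba <- rev$z[rev$group_i == "b" & rev$group_j == "a"]
  expect_equal(z_ab, -z_ba, tolerance = 1e-12)

  adj <- dunn_posthoc(g, adjustment = "bonferroni")
  expect_true(all(adj$p_adjusted >= adj$p_unadjusted))
})

test_that("one-way ANOVA matches hand decomposition and stats oracle", {
  a <- one_way_anova(list(x = c(1, 2, 3), y = c(2, 3, 4)))
  expect_equal(a$statistic, 1.5)  # SSB = 1.5, SSW = 4, df (1, 4)
  expect_equal(unname(a$ss["between"]), 1.5)
  expect_equal(unname(a$ss["within"]), 4)

  const <- one_way_anova(list(x = rep(2, 3), y = rep(2, 3)))
  expect_equal(const$statistic, 0)
  expect_equal(const$p_value, 1)

  sep <- one_way_anova(list(x = rep(1, 3), y = rep(2, 3)))
  expect_true(is.infinite(sep$statistic))
  expect_equal(sep$p_value, 0)

  set.seed(36)
  for (i in 1:10) {
    gr <- list(a = rnorm(8), b = rnorm(8, 0.5), c = rnorm(8, 1))
    ours <- one_way_anova(gr)
    df <- data.frame(v = unlist(gr), g = rep(names(gr), each = 8))
    ref <- summary(stats::aov(v ~ g, df))[[1]]
    expect_equal(ours$statistic, ref[["F value"]][1], tolerance = 1e-10)
    expect_equal(ours$p_value, ref[["Pr(>F)"]][1], tolerance = 1e-10)
    # decomposition: SSB + SSW = SST
    sst <- sum((df$v - mean(df$v))^2)
    expect_equal(unname(ours$ss["between"] + ours$ss["within"]), sst,
                 tolerance = 1e-12)
  }
})

test_that("the log-linear RMR model recovers exact generating coefficients", {
  # one watershed, no noise
  t1 <- seq(8, 22, length.out = 12)
  d1 <- data.frame(rmr = exp(0.08 * t1 - 0.5), temp_c = t1, watershed = "A")
  f1 <- fit_rmr_model(d1)
  expect_equal(f1$slope_per_c, 0.08, tolerance = 1e-10)
  expect_equal(unname(f1$intercepts["A"]), -0.5, tolerance = 1e-10)

  # two watersheds, common slope, intercepts differing by 0.2
  d2 <- rbind(d1, data.frame(rmr = exp(0.08 * t1 - 0.3), temp_c = t1,
                             watershed = "B"))
  f2 <- fit_rmr_model(d2)
  expect_equal(f2$slope_per_c, 0.08, tolerance = 1e-10)
  expect_equal(unname(f2$intercepts["B"] - f2$intercepts["A"]), 0.2,
               tolerance = 1e-10)
  expect_equal(f2$residual_sd, 0, tolerance = 1e-8)

  expect_warning(
    f3 <- fit_rmr_model(rbind(d2, data.frame(rmr = -1, temp_c = 10,
                                             watershed = "A"))),
    "non-positive")
  expect_equal(f3$n, 24)
})

test_that("fixed-effects slope survives per-fish random intercepts", {
  set.seed(37)
  hits <- 0
  for (rep in 1:50) {
    rows <- NULL
    for (w in c("A", "B", "C", "D")) {
      w_int <- runif(1, -0.6, -0.4)
      for (f in 1:24) {
        fish_eff <- rnorm(1, 0, 0.1)
        t <- runif(4, 8, 22)
        rows <- rbind(rows, data.frame(
          rmr = exp(0.08 * t + w_int + fish_eff + rnorm(4, 0, 0.02)),
          temp_c = t, watershed = w))
      }
    }
    est <- fit_rmr_model(rows)$slope_per_c
    if (abs(est - 0.08) / 0.08 <= 0.1) hits <- hits + 1
  }
  expect_gte(hits / 50, 0.90)
})
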