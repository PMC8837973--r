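test_that("percent change and fold ratio reproduce the printed contrasts", {
  # liver D9-PC 1145 -> 647 nmol and lung 112 -> 58 nmol
  expect_equal(round(percent_change(1145, 647)), -43)
  expect_equal(round(percent_change(112, 58)), -48)
  expect_equal(percent_change(5, 5), 0)
  expect_error(percent_change(0, 5), "pool_t1")

  # lung vs cerebellum SPH pools; cerebrum vs liver PC-precursor pools
  expect_equal(round(fold_ratio(1.0, 0.35), 1), 2.9)
  expect_equal(round(fold_ratio(621, 293), 1), 2.1)
  expect_equal(round(fold_ratio(533, 293), 1), 1.8)
  expect_equal(fold_ratio(7, 7), 1)
  expect_error(fold_ratio(1, 0), "denominator")

  # consistency: fold = 1 + pct/100 on random pairs
  set.seed(3)
  a <- runif(20, 1, 100)
  b <- runif(20, 1, 100)
  expect_equal(fold_ratio(b, a), 1 + percent_change(a, b) / 100)
})

test_that("subgroup profiles normalize and converge to equilibrium", {
  amounts <- tibble::tibble(
    acyl_group = c("C18:2", "C20:4", "C22:6"),
    amount_nmol = c(4, 4, 4)
  )
  prof <- subgroup_profile(amounts)
  expect_equal(prof$fraction, rep(1 / 3, 3))

  eq <- tibble::tibble(
    acyl_group = c("C18:2", "C20:4", "C22:6"),
    fraction = c(0.2, 0.5, 0.3)
  )
  expect_equal(
    unique(profile_distance(eq, eq)$total_abs_deviation), 0
  )

  # exponential relaxation toward equilibrium: distance decreases in time
  start <- c(0.7, 0.2, 0.1)
  times <- c(1.5, 6, 24)
  traj <- purrr::map_dfr(times, function(t) {
    f <- eq$fraction + (start - eq$fraction) * exp(-0.15 * t)
    tibble::tibble(time_h = t, acyl_group = eq$acyl_group, fraction = f)
  })
  dist <- profile_distance(traj, eq, by = "time_h") %>%
    dplyr::distinct(time_h, total_abs_deviation) %>%
    dplyr::arrange(time_h)
  expect_true(all(diff(dist$total_abs_deviation) < 0))
})

test_that("group comparisons: t test, Tukey and Bonferroni behave", {
  # identical groups: p = 1
  same <- tibble::tibble(value = rep(c(1, 2, 3), 2),
    group = rep(c("a", "b"), each = 3)
  )
  res_same <- compare_groups(same)
  expect_equal(res_same$p_value, 1)

  # two-group raw mode agrees with the Welch t test
  set.seed(5)
  d <- tibble::tibble(
    value = c(rnorm(8, 10), rnorm(8, 12)),
    group = rep(c("a", "b"), each = 8)
  )
  res <- compare_groups(d)
  oracle <- t.test(value ~ group, data = d)
  expect_equal(res$p_value, oracle$p.value)

  # summary-statistics mode: reported betaine liver vs lung contrast
  summ <- tibble::tibble(
    group = c("liver", "lung"), mean = c(1631, 29), se = c(125, 2), n = 27
  )
  res_summ <- compare_groups(summ)
  expect_lt(res_summ$p_value, 0.001)
  expect_equal(res_summ$method, "welch_t_summary")

  # n < 2 in any group errors
  expect_error(
    compare_groups(tibble::tibble(value = c(1, 2, 3), group = c("a", "a", "b"))),
    "n >= 2"
  )

  # Bonferroni across families: monotone nondecreasing, capped at 1
  r1 <- compare_groups(d, n_families = 1)
  r5 <- compare_groups(d, n_families = 5)
  expect_true(all(r5$p_adj >= r1$p_adj))
  expect_true(all(r5$p_adj <= 1))
  expect_equal(r5$p_adj, pmin(1, r1$p_value * 5))
})

test_that("Tukey p-values agree with a permutation studentized-range oracle", {
  set.seed(17)
  g <- rep(c("a", "b", "c"), each = 6)
  x <- rnorm(18, mean = c(rep(0, 6), rep(1.0, 6), rep(0.3, 6)))
  d <- tibble::tibble(value = x, group = g)
  res <- compare_groups(d)

  # permutation distribution of the maximum studentized range statistic
  q_stat <- function(vals, grp) {
    m <- tapply(vals, grp, mean)
    n <- tapply(vals, grp, length)
    fit <- aov(vals ~ grp)
    mse <- sum(fit$residuals^2) / fit$df.residual
    outer(m, m, function(a, b) abs(a - b)) / sqrt(mse / n[1])
  }
  obs <- q_stat(d$value, factor(d$group))
  B <- 1500
  exceed <- matrix(0, 3, 3)
  for (b in seq_len(B)) {
    qp <- q_stat(d$value, factor(sample(d$group)))
    qmax <- max(qp)
    exceed <- exceed + (qmax >= obs)
  }
  p_perm <- exceed / B
  for (cmp in res$comparison) {
    pair <- strsplit(cmp, " - ")[[1]]
    expect_lt(
      abs(res$p_value[res$comparison == cmp] - p_perm[pair[1], pair[2]]),
      0.1
    )
  }
})

test_that("normality screen passes normal, flags heavy-tailed, guards n", {
  set.seed(23)
  expect_true(normality_screen(rnorm(300))$pass)
  expect_false(normality_screen(rlnorm(300, sdlog = 1))$pass)
  small <- normality_screen(rnorm(5))
  expect_true(is.na(small$pass))
  expect_equal(small$flag, "insufficient_n")
})
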