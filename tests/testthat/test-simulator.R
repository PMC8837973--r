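test_that("network construction validates its edge table", {
  expect_error(
    tracer_network(tibble::tibble(
      process = "p", from = "a", to = "b", yield = 1, rate = -1
    )),
    ">= 0"
  )
  expect_error(
    tracer_network(tibble::tibble(
      process = c("p", "p"), from = c("a", "c"), to = "b",
      yield = 1, rate = 1
    )),
    "single from"
  )
})

test_that("a frozen network keeps the dose at the injection site", {
  rates <- default_rates()
  rates[] <- 0
  net <- default_network(rates)
  tr <- simulate_tracer(net, 100, c(1.5, 6, 24))
  at_site <- dplyr::filter(tr, compartment == "peritoneum.choline.D9")
  expect_equal(at_site$amount_nmol, rep(100, 3), tolerance = 1e-9)
})

test_that("two-compartment transfer matches the closed form", {
  net <- two_compartment_network(k = log(2))
  tr <- simulate_tracer(net, 100, times = c(1, 2, 3))
  a <- dplyr::filter(tr, compartment == "peritoneum.choline.D9")
  expect_equal(a$amount_nmol, 100 * 2^-(1:3), tolerance = 1e-7)
  b <- dplyr::filter(tr, compartment == "plasma.choline.D9")
  expect_equal(b$amount_nmol, 100 * (1 - 2^-(1:3)), tolerance = 1e-7)
})

test_that("the closed system conserves methyl-weighted label", {
  net <- closed_network(default_network())
  times <- c(0.5, 1.5, 3, 6, 12, 24, 48)
  tr <- simulate_tracer(net, 100, times)
  totals <- tr %>%
    tidyr::pivot_wider(
      id_cols = "time", names_from = "compartment",
      values_from = "amount_nmol"
    )
  for (i in seq_along(times)) {
    state <- unlist(totals[i, -1])
    expect_equal(methyl_weighted_total(state), 100, tolerance = 1e-8)
  }
})

test_that("solver trajectories match the matrix-exponential solution", {
  net <- default_network()
  A <- rate_matrix(net)
  x0 <- setNames(numeric(ncol(A)), colnames(A))
  x0["peritoneum.choline.D9"] <- 100
  for (t in c(1.5, 6, 24)) {
    oracle <- as.numeric(Matrix::expm(A * t) %*% x0)
    names(oracle) <- colnames(A)
    tr <- simulate_tracer(net, 100, times = t)
    sim <- setNames(tr$amount_nmol, tr$compartment)[names(oracle)]
    denom <- pmax(oracle, 1e-6)
    expect_lt(max(abs(sim - oracle) / denom), 1e-6)
  }

  # and on a small arbitrary network
  edges <- tibble::tibble(
    process = c("p1", "p2", "p3"),
    from = c("liver.PC.D9", "plasma.PC.D9", "liver.PC.D9"),
    to = c("plasma.PC.D9", "lung.PC.D9", "sink"),
    yield = 1,
    rate = c(0.3, 0.12, 0.05)
  )
  net2 <- tracer_network(edges)
  A2 <- rate_matrix(net2)
  y0 <- setNames(c(50, 0, 0, 0), colnames(A2))
  y0["liver.PC.D9"] <- 50
  tr2 <- simulate_tracer(net2, times = 7, x0 = c("liver.PC.D9" = 50))
  oracle2 <- as.numeric(Matrix::expm(A2 * 7) %*% y0)
  names(oracle2) <- colnames(A2)
  sim2 <- setNames(tr2$amount_nmol, tr2$compartment)[names(oracle2)]
  expect_equal(unname(sim2), unname(oracle2), tolerance = 1e-6)
})

test_that("default kinetics reproduce the study's qualitative patterns", {
  tr <- simulate_tracer(default_network(), 100, c(1.5, 6, 24))
  get <- function(comp) {
    d <- dplyr::filter(tr, compartment == comp) %>% dplyr::arrange(time)
    d$amount_nmol
  }
  total_of <- function(spec, lab) {
    tr %>%
      dplyr::filter(
        species %in% spec, label == lab,
        !organ %in% c("peritoneum", "sink")
      ) %>%
      dplyr::group_by(time) %>%
      dplyr::summarise(x = sum(amount_nmol)) %>%
      dplyr::arrange(time) %>%
      dplyr::pull(x)
  }

  # PC precursors fall > 7-fold from 1.5 h to 6 h
  prec <- total_of(c("choline", "phosphocholine", "CDPcholine"), "D9")
  expect_gt(prec[1] / prec[2], 7)

  # liver D9-PC peaks by 1.5 h and declines thereafter
  liver <- get("liver.PC.D9")
  expect_gt(liver[1], liver[2])
  expect_gt(liver[2], liver[3])

  # lung D9-PC dips at 6 h, then rises again (plasma-supplied accretion)
  lung <- get("lung.PC.D9")
  expect_gt(lung[1], lung[2])
  expect_gt(lung[3], lung[2])

  # brain D9-PC is nondecreasing over the whole time course
  for (comp in c("cerebrum.PC.D9", "cerebellum.PC.D9")) {
    x <- get(comp)
    expect_true(all(diff(x) > -1e-9), info = comp)
  }

  # surfactant (LLF) D9-PC increases monotonically
  llf <- get("LLF.PC.D9")
  expect_true(all(diff(llf) > 0))

  # D3-PC rises monotonically and stays below 3% of the dose
  d3 <- total_of("PC", "D3") / 3 # methyl-corrected
  expect_true(all(diff(d3) > 0))
  expect_lt(max(d3), 3)

  # precursor compartments empty out at long times
  late <- simulate_tracer(default_network(), 100, 200)
  prec_late <- late %>%
    dplyr::filter(
      species %in% c("choline", "phosphocholine", "CDPcholine", "betaine"),
      !organ %in% c("sink")
    )
  expect_lt(sum(prec_late$amount_nmol), 0.05)
})

test_that("study sampling is seed-deterministic and noise-free exact", {
  s1 <- sample_study(simulation_config(n_per_timepoint = 2, seed = 99))
  s2 <- sample_study(simulation_config(n_per_timepoint = 2, seed = 99))
  expect_identical(s1$measurements, s2$measurements)
  expect_identical(s1$truth, s2$truth)
  s3 <- sample_study(simulation_config(n_per_timepoint = 2, seed = 100))
  expect_false(identical(s1$measurements, s3$measurements))

  # with all noise off, the quantification chain inverts the forward model
  st <- small_noisefree_study()
  q <- quantify_measurements(st$measurements)
  cmp <- dplyr::inner_join(
    dplyr::select(st$truth, animal_id, matrix, analyte,
      truth = amount_nmol
    ),
    dplyr::select(q, animal_id, matrix, analyte, est = amount_nmol),
    by = c("animal_id", "matrix", "analyte")
  )
  expect_equal(nrow(cmp), nrow(st$truth))
  expect_equal(cmp$est, cmp$truth, tolerance = 1e-9)
})

test_that("transfer-rate fitting recovers known rates", {
  # pure transfer source -> target, source decaying first order
  k <- 0.2
  times <- c(1.5, 6, 24)
  source <- 100 * exp(-k * times)
  target <- 100 * (1 - exp(-k * times))
  fit <- fit_transfer_rate(times, source, target)
  expect_equal(fit$k, k, tolerance = 1e-6)
  expect_lt(fit$rss, 1e-10)

  # flat target: no transfer
  flat <- fit_transfer_rate(times, source, rep(5, 3))
  expect_equal(flat$k, 0, tolerance = 1e-12)

  expect_error(fit_transfer_rate(c(1, 2), c(1, 2), c(1, 2)), "3 time points")

  # broom-style accessors
  td <- generics::tidy(fit)
  expect_equal(td$estimate, fit$k)
  gl <- generics::glance(fit)
  expect_equal(gl$n_times, 3)
})

test_that("noisy transfer-rate estimates have small median bias", {
  k <- 0.2
  times <- c(1.5, 6, 24)
  source <- 100 * exp(-k * times)
  target <- 100 * (1 - exp(-k * times))
  set.seed(314)
  sdlog <- sqrt(log(1 + 0.1^2))
  ks <- replicate(200, {
    s <- source * rlnorm(3, -sdlog^2 / 2, sdlog)
    tg <- target * rlnorm(3, -sdlog^2 / 2, sdlog)
    fit_transfer_rate(times, s, tg)$k
  })
  expect_lt(abs(median(ks) / k - 1), 0.05)
})
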