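test_that("plasma volume follows the blood-volume model", {
  # direct arithmetic oracle: 28.2 * 0.125 * 0.6 / 1.025 * 1000
  expect_equal(estimate_plasma_volume(28.2), 28.2 * 0.125 * 0.6 / 1.025 * 1000,
    tolerance = 1e-12
  )
  expect_equal(round(estimate_plasma_volume(28.2), 1), 2063.4)

  # hematocrit 1 leaves no plasma
  m <- plasma_volume_model(hematocrit = 1)
  expect_equal(estimate_plasma_volume(28.2, m), 0)

  # consistency with the reported plasma compartment mass (2151 mg):
  # model volume within 5% of mass / density
  expect_lt(
    abs(estimate_plasma_volume(28.2) - 2151 / 1.025) / (2151 / 1.025),
    0.05
  )

  expect_error(estimate_plasma_volume(0), "body_weight_g")
  expect_error(plasma_volume_model(plasma_density = 1.5), "plasma_density")
})

test_that("pool computation is a unit-consistent product", {
  expect_equal(compute_pool(0, 500), 0)
  expect_equal(compute_pool(10, 282), 2820)
  # plasma choline-phospholipid: concentration x plasma volume in umol range
  conc <- 5.5e3 / (2151 / 1.025) # nmol/uL from the reported pool and volume
  expect_equal(round(conc, 1), 2.6)
  expect_equal(compute_pool(2.62, 2098.5), 5498.07)
  # nmol -> umol conversion scales the result by exactly 1e3
  expect_equal(
    compute_pool(2.62, 2098.5) / compute_pool(2.62e-3, 2098.5), 1e3
  )
})

test_that("totals across matrices equal brute-force sums", {
  set.seed(7)
  tbl <- tidyr::expand_grid(
    animal_id = c("r1", "r2"),
    matrix = c("liver", "plasma", "lung"),
    analyte = c("PC16:0/16:0", "choline")
  )
  tbl$amount_nmol <- runif(nrow(tbl), 0, 100)
  tot <- aggregate_totals(tbl)
  # independent summation oracle via base tapply
  oracle <- tapply(
    tbl$amount_nmol, list(tbl$animal_id, tbl$analyte), sum
  )
  for (i in seq_len(nrow(tot))) {
    expect_equal(
      tot$amount_nmol[i], oracle[tot$animal_id[i], tot$analyte[i]],
      ignore_attr = TRUE
    )
  }
  single <- dplyr::filter(tbl, matrix == "liver")
  expect_equal(
    aggregate_totals(single)$amount_nmol,
    single$amount_nmol[order(single$animal_id, single$analyte)]
  )
})

test_that("reported lipid totals are per-column sums within rounding", {
  ref <- reference_pools()
  pc <- dplyr::filter(ref, panel == "lipid", analyte == "PC")
  expect_equal(sum(pc$mean), 55.1) # printed total is 55.2 +/- 3.7
  expect_lt(abs(sum(pc$mean) - 55.2), 0.15)
  cpl <- dplyr::filter(ref, panel == "lipid", analyte == "choline_phospholipids")
  expect_lt(abs(sum(cpl$mean) - 61.3), 0.05)
})

test_that("descriptive fractions reproduce the printed percentages", {
  d <- descriptive_fractions()
  get <- function(org, col) d[[col]][d$organ == org]

  expect_equal(round(get("liver", "pct_body_mass"), 1), 2.9)
  expect_equal(round(get("liver", "pct_choline_pl"), 1), 8.1)
  expect_equal(round(get("cerebrum", "pct_body_mass"), 1), 3.1)
  expect_equal(round(get("cerebrum", "pct_choline_pl"), 1), 7.1)
  expect_equal(round(get("lung", "pct_body_mass"), 2), 1.00)
  expect_equal(round(get("lung", "pct_choline_pl"), 1), 2.4)
  expect_equal(round(get("cerebellum", "pct_body_mass"), 1), 1.0)
  expect_equal(round(get("cerebellum", "pct_choline_pl"), 1), 2.1)
  expect_equal(round(get("all_organs_plasma", "pct_body_mass"), 1), 15.6)
  expect_equal(round(get("investigated_total", "pct_choline_pl"), 1), 21.7)

  # fractions of the exhaustive weight partition stay below 100%
  per_organ <- d$pct_body_mass[!is.na(d$pct_body_mass) &
    d$organ != "all_organs_plasma"]
  expect_lt(sum(per_organ), 100)
})

test_that("pool_fractions is scale-invariant and guards its domain", {
  expect_equal(pool_fractions(0, 282), 0)
  expect_equal(pool_fractions(61.3, 282), pool_fractions(61300, 282000))
  expect_equal(round(pool_fractions(61.3, 282), 1), 21.7)
  expect_error(pool_fractions(1, 0), "reference")
})

test_that("pool_table attaches compartment sizes and concentrations", {
  animals <- tibble::tibble(
    animal_id = "r1", body_weight_g = 28.2, time_point_h = 1.5,
    liver_mg = 830, lung_mg = 282, cerebrum_mg = 880, cerebellum_mg = 270
  )
  pools <- tibble::tibble(
    animal_id = "r1",
    matrix = c("liver", "plasma", "LLF"),
    analyte = "PC16:0/16:0",
    amount_nmol = c(8300, 2063.4, 10)
  )
  pt <- pool_table(pools, animals)
  expect_equal(pt$compartment_size[pt$matrix == "liver"], 830)
  expect_equal(
    pt$compartment_size[pt$matrix == "plasma"],
    estimate_plasma_volume(28.2)
  )
  expect_equal(pt$concentration[pt$matrix == "liver"], 10)
  # LLF pools are total recovered amounts, no size normalization
  expect_true(is.na(pt$compartment_size[pt$matrix == "LLF"]))
  expect_equal(pt$time_point_h, rep(1.5, 3))
})
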