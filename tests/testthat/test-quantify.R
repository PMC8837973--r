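test_that("13C correction matrix has the M+2 binomial structure", {
  panel <- pc_panel()

  # zero natural abundance: identity
  cm0 <- build_c13_matrix(panel, p13 = 0)
  expect_equal(unname(cm0$C), diag(3))

  # two carbons at p = 0.5: off-diagonal term choose(2,2) * 0.25
  small <- panel[1:2, ]
  small$n_carbons <- 2
  cm <- build_c13_matrix(small, p13 = 0.5)
  expect_equal(cm$C["PC34:1", "PC34:2"], 0.25)
  expect_equal(diag(cm$C), c("PC34:2" = 1, "PC34:1" = 1))

  # PC 34:2 -> PC 34:1 channel with n = 42 at natural abundance, checked
  # against an independent per-atom convolution of isotopologue probabilities
  cm42 <- build_c13_matrix(panel, p13 = 0.0107)
  oracle <- convolve_isotope_prob(42, 0.0107, 2)
  expect_equal(cm42$C["PC34:1", "PC34:2"], oracle, tolerance = 1e-12)
  # non-neighbours do not spill
  expect_equal(cm42$C["PC36:4", "PC34:2"], 0)

  # two species closer than the tolerance cannot be assigned
  clash <- panel
  clash$precursor_mz[2] <- clash$precursor_mz[1] + 0.2
  expect_error(build_c13_matrix(clash), "ambiguous")
})

test_that("isotope correction inverts forward spillover exactly", {
  panel <- pc_panel()
  cm <- build_c13_matrix(panel, p13 = 0.0107)

  # identity behaviour
  expect_equal(
    as.numeric(apply_isotope_correction(c(5, 7, 9), build_c13_matrix(
      panel,
      p13 = 0
    ))),
    c(5, 7, 9),
    ignore_attr = TRUE
  )
  expect_equal(
    as.numeric(apply_isotope_correction(c(0, 0, 0), cm)),
    c(0, 0, 0),
    ignore_attr = TRUE
  )

  # round-trip property on random panels and counts
  set.seed(11)
  for (i in 1:25) {
    n_sp <- sample(2:6, 1)
    sp <- tibble::tibble(
      name = paste0("S", seq_len(n_sp)),
      precursor_mz = 700 + seq_len(n_sp) * 2, # adjacent M+2 chain
      n_carbons = sample(30:48, n_sp, replace = TRUE)
    )
    cmi <- build_c13_matrix(sp, p13 = runif(1, 0.005, 0.02))
    x <- runif(n_sp, 0, 1e6)
    raw <- forward_isotopologue_spillover(x, cmi)
    back <- apply_isotope_correction(raw, cmi)
    expect_equal(as.numeric(back), x, tolerance = 1e-9, ignore_attr = TRUE)
  }

  # negative solutions clip to zero with a warning
  raw <- c(10, 0, 0) # channel 2 sees spillover but records nothing
  expect_warning(
    out <- apply_isotope_correction(c(10, 0.0001, 5), cm, quiet = FALSE),
    "clipped"
  )
  expect_true(all(out >= 0))

  singular <- structure(
    list(species = c("a", "b"), C = matrix(1, 2, 2)),
    class = "correction_matrix"
  )
  expect_error(apply_isotope_correction(c(1, 1), singular), "singular")
})

test_that("internal-standard quantification follows the ratio formula", {
  expect_equal(quantify_by_internal_standard(1000, 1000, 10), 10)
  expect_equal(quantify_by_internal_standard(2000, 1000, 10), 20)
  # response factor divides, post-spike dilution multiplies
  expect_equal(quantify_by_internal_standard(1000, 1000, 10, response = 2), 5)
  expect_equal(
    quantify_by_internal_standard(1000, 1000, 10,
      dilution_factor = 157, convention = "post_spike"
    ),
    1570
  )
  # pre-spike convention: dilution cancels in the ratio
  expect_equal(
    quantify_by_internal_standard(1000, 1000, 10, dilution_factor = 157),
    10
  )
  # linearity in the analyte count
  counts <- runif(10, 1, 1e5)
  expect_equal(
    quantify_by_internal_standard(3 * counts, 1e4, 10),
    3 * quantify_by_internal_standard(counts, 1e4, 10)
  )
  expect_error(
    quantify_by_internal_standard(100, 0, 10,
      sample = "r1 liver", is_name = "D4-choline"
    ),
    "D4-choline.*r1 liver"
  )
})

test_that("species grouping sums by registry acyl tag with coverage", {
  reg <- default_registry()
  # one species per subgroup with amounts 1..5: groups pass through
  sp <- c(
    "PC16:0/16:0", "PC16:0/18:1", "PC16:0/18:2",
    "PC16:0/20:4", "PC16:0/22:6"
  )
  amounts <- tibble::tibble(analyte = sp, amount_nmol = 1:5)
  out <- group_species(amounts, reg)
  expect_equal(
    out$amount_nmol[match(
      c("sat", "C18:1", "C18:2", "C20:4", "C22:6"), out$acyl_group
    )],
    c(1, 2, 3, 4, 5)
  )
  expect_equal(out$coverage, rep(1, 5))

  # constructed 50/10/10/20/10 split over a two-species-per-group panel
  amounts2 <- tibble::tibble(
    analyte = c(
      "PC16:0/16:0", "PC16:0/18:1", "PC18:0/18:1", "PC16:0/18:2",
      "PC16:0/20:4", "PC18:0/20:4", "PC16:0/22:6"
    ),
    amount_nmol = c(50, 6, 4, 10, 12, 8, 10)
  )
  out2 <- group_species(amounts2, reg)
  expect_equal(
    out2$fraction[match(
      c("sat", "C18:1", "C18:2", "C20:4", "C22:6"), out2$acyl_group
    )],
    c(0.5, 0.1, 0.1, 0.2, 0.1)
  )

  # species without a subgroup stay in the class total but not the groups
  with_na <- dplyr::bind_rows(
    amounts,
    tibble::tibble(analyte = "SPH16:0", amount_nmol = 5)
  )
  expect_warning(out3 <- group_species(with_na, reg), "excluded")
  expect_equal(unique(out3$class_total_nmol), 20)
  expect_equal(unique(out3$coverage), 15 / 20)
})

test_that("table-level quantification is linear in analyte counts", {
  study <- small_noisefree_study()
  meas <- study$measurements
  reg <- default_registry()
  is_names <- registry_internal_standards(reg)
  scaled <- meas
  idx <- !scaled$analyte %in% is_names
  scaled$ion_count[idx] <- scaled$ion_count[idx] * 3

  q1 <- quantify_measurements(meas, reg)
  q3 <- quantify_measurements(scaled, reg)
  joined <- dplyr::inner_join(
    q1, q3,
    by = c("animal_id", "matrix", "analyte"), suffix = c("", "_scaled")
  )
  expect_equal(joined$amount_nmol_scaled, joined$amount_nmol * 3,
    tolerance = 1e-9
  )
})
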