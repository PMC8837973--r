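#' Chain-length ionization response model
#'
#' Electrospray response of phospholipid species varies with total acyl chain
#' length. The model is affine in the carbon count and normalized to 1.0 at
#' the class internal standard: response = 1 + slope * (n_carbons -
#' reference_carbons). The default slope of 0 applies no correction; supply a
#' calibrated slope (per carbon) when a calibration table is available.
#'
#' @param slope Response change per acyl carbon relative to the reference.
#' @param reference_carbons Carbon count of the reference (internal standard)
#'   species at which the response is 1.0.
#' @return An object of class `response_model`.
#' @export
response_model <- function(slope = 0, reference_carbons = 48) {
  structure(
    list(slope = slope, reference_carbons = reference_carbons),
    class = "response_model"
  )
}

#' Predicted ionization response for a carbon count
#'
#' @param model A [response_model()].
#' @param n_carbons Vector of molecule carbon counts.
#' @return Positive response factors (errors if the model predicts a
#'   non-positive response anywhere on the requested range).
#' @export
predict_response <- function(model, n_carbons) {
  r <- 1 + model$slope * (n_carbons - model$reference_carbons)
  if (any(r <= 0)) {
    abort("response model predicts non-positive response over carbon range")
  }
  r
}

#' Build a natural-abundance 13C correction matrix
#'
#' Within a panel of same-class species sharing a diagnostic product ion,
#' a species acquired at precursor m/z M contributes its M+2 isotopologue
#' (two 13C atoms) to the SRM channel of a species 2 Da heavier - the
#' dominant spillover in phospholipid SRM panels, where species differing by
#' one double bond differ by 2 Da. Entry `C[i, j]` is the probability that a
#' molecule of species j is recorded in channel i:
#' unity on the diagonal, and for `mz[i] - mz[j] = 2` (within `tol`) the
#' binomial probability of exactly two 13C among `n_carbons[j]` atoms,
#' `choose(n, 2) p13^2 (1 - p13)^(n - 2)`.
#'
#' @param species Registry subset: one row per panel species, with columns
#'   `name`, `precursor_mz`, `n_carbons` (all same class/product ion).
#' @param p13 Natural 13C abundance (default 0.0107).
#' @param tol m/z tolerance for the +2 Da match (Da).
#' @return A `correction_matrix` object: species names (ascending precursor
#'   m/z) and the square spillover matrix.
#' @export
build_c13_matrix <- function(species, p13 = 0.0107, tol = 0.6) {
  if (p13 < 0 || p13 > 0.5) {
    abort("p13 must be a small natural-abundance probability")
  }
  sp <- as_tibble(species) %>% arrange(.data$precursor_mz)
  n <- nrow(sp)
  mz <- sp$precursor_mz
  if (n > 1) {
    gaps <- diff(mz)
    if (any(gaps < tol)) {
      abort(paste0(
        "ambiguous m/z assignment: species closer than the tolerance: ",
        paste(sp$name[which(gaps < tol)], sp$name[which(gaps < tol) + 1],
          sep = " / ", collapse = "; "
        )
      ))
    }
  }
  C <- diag(1, n)
  if (n > 1) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i != j && abs((mz[i] - mz[j]) - 2) <= tol) {
          nc <- sp$n_carbons[j]
          C[i, j] <- choose(nc, 2) * p13^2 * (1 - p13)^(nc - 2)
        }
      }
    }
  }
  dimnames(C) <- list(sp$name, sp$name)
  structure(list(species = sp$name, C = C), class = "correction_matrix")
}

#' Remove 13C isotopologue spillover from raw SRM counts
#'
#' Solves `C x = raw` for the spillover-free counts `x`. Small negative
#' solutions (noise at low abundance) are clipped to zero and flagged.
#'
#' @param raw_counts Numeric vector (or species x sample matrix) of raw ion
#'   counts aligned to `correction$species`.
#' @param correction A `correction_matrix` from [build_c13_matrix()].
#' @param quiet Suppress the clipping warning.
#' @return Corrected counts with the same shape as `raw_counts`; attribute
#'   `clipped` marks entries clipped to zero.
#' @export
apply_isotope_correction <- function(raw_counts, correction, quiet = FALSE) {
  C <- correction$C
  x <- if (is.matrix(raw_counts)) raw_counts else matrix(raw_counts, ncol = 1)
  if (nrow(x) != nrow(C)) {
    abort("raw counts are not aligned to the correction matrix species order")
  }
  if (abs(det(C)) < .Machine$double.eps) {
    abort("correction matrix is singular")
  }
  sol <- solve(C, x)
  clipped <- sol < 0
  if (any(clipped)) {
    sol[clipped] <- 0
    if (!quiet) {
      warn(paste0(
        sum(clipped),
        " corrected count(s) were negative and were clipped to zero"
      ))
    }
  }
  out <- if (is.matrix(raw_counts)) sol else drop(sol)
  attr(out, "clipped") <- if (is.matrix(raw_counts)) clipped else drop(clipped)
  out
}

#' Quantify an analyte against its internal standard
#'
#' amount = (corrected_count / is_count) * is_amount / response *
#' dilution_term. With the default `convention = "pre_spike"` the internal
#' standard is added to the primary extract before dilution, the analyte:IS
#' count ratio is dilution-invariant and the dilution factor does not enter
#' the amount. Under `"post_spike"` the IS amount refers to the diluted
#' working solution and the extract amount is the ratio scaled up by
#' `dilution_factor` (applied once, at extract level).
#'
#' @param corrected_count Spillover-corrected analyte counts (au).
#' @param is_count Corrected internal-standard counts in the same run (au).
#' @param is_amount Amount of internal standard added (nmol).
#' @param response Relative ionization response of the analyte (1 = same as
#'   IS), see [predict_response()].
#' @param dilution_factor Extract dilution factor (>= 1).
#' @param convention `"pre_spike"` (default) or `"post_spike"`, see above.
#' @param sample,is_name Optional identifiers used in error messages.
#' @return Amounts in the extract (nmol), vectorized over inputs.
#' @export
quantify_by_internal_standard <- function(corrected_count, is_count, is_amount,
                                          response = 1, dilution_factor = 1,
                                          convention = c(
                                            "pre_spike", "post_spike"
                                          ),
                                          sample = NULL, is_name = NULL) {
  convention <- match.arg(convention)
  bad <- !is.finite(is_count) | is_count <= 0
  if (any(bad)) {
    where <- if (!is.null(sample)) {
      paste0(" (sample ", paste(unique(sample[bad]), collapse = ", "), ")")
    } else {
      paste0(" (position ", paste(which(bad), collapse = ", "), ")")
    }
    is_lab <- if (!is.null(is_name)) {
      paste0(" for internal standard ", paste(unique(is_name[bad]),
        collapse = ", "
      ))
    } else {
      ""
    }
    abort(paste0("internal-standard count is zero or invalid", is_lab, where))
  }
  dil <- if (convention == "post_spike") dilution_factor else 1
  (corrected_count / is_count) * is_amount / response * dil
}

#' Group PC/PE species amounts into acyl subgroups
#'
#' Species are grouped by their registry `acyl_group` tag: two saturated
#' residues (sat), or one oleic (C18:1), linoleic (C18:2), arachidonic
#' (C20:4) or docosahexaenoic (C22:6) residue. Species tagged `n/a` are
#' excluded from the subgroup sums (with a warning) but retained in the class
#' total used for the coverage fraction.
#'
#' @param amounts Tibble with columns `analyte` and `amount_nmol`, plus any
#'   grouping columns named in `by` (e.g. animal, matrix, time).
#' @param registry Registry tibble supplying `acyl_group` per analyte.
#' @param by Character vector of extra grouping columns present in `amounts`.
#' @return A tibble with one row per group x acyl subgroup: `amount_nmol`,
#'   the class total `class_total_nmol`, the subgroup `fraction` of the
#'   class total, and `coverage` (grouped fraction of the class total).
#' @export
group_species <- function(amounts, registry, by = character()) {
  tbl <- as_tibble(amounts) %>%
    left_join(select(registry, "name", "acyl_group"),
      by = c(analyte = "name")
    )
  if (any(is.na(tbl$acyl_group))) {
    abort(paste0(
      "analyte(s) not in registry: ",
      paste(unique(tbl$analyte[is.na(tbl$acyl_group)]), collapse = ", ")
    ))
  }
  if (any(tbl$acyl_group == "n/a")) {
    warn(paste0(
      "species without an acyl subgroup excluded from subgroup sums: ",
      paste(unique(tbl$analyte[tbl$acyl_group == "n/a"]), collapse = ", ")
    ))
  }
  totals <- tbl %>%
    group_by(across(all_of(by))) %>%
    summarise(class_total_nmol = sum(.data$amount_nmol), .groups = "drop")
  grouped <- tbl %>%
    filter(.data$acyl_group != "n/a") %>%
    group_by(across(all_of(c(by, "acyl_group")))) %>%
    summarise(amount_nmol = sum(.data$amount_nmol), .groups = "drop")
  joined <- if (length(by)) {
    left_join(grouped, totals, by = by)
  } else {
    mutate(grouped, class_total_nmol = totals$class_total_nmol)
  }
  joined %>%
    group_by(across(all_of(by))) %>%
    mutate(
      fraction = if_else(.data$class_total_nmol > 0,
        .data$amount_nmol / .data$class_total_nmol, 0
      ),
      coverage = if_else(.data$class_total_nmol > 0,
        sum(.data$amount_nmol) / .data$class_total_nmol, NA_real_
      )
    ) %>%
    ungroup()
}

#' Default internal-standard amounts per extract
#'
#' Amounts (nmol) of the internal standards added to each extract:
#' D4-choline chloride for the water-soluble panel, PC20:0/20:0 for
#' choline-containing lipids and PE14:0/14:0 for the PE panel.
#'
#' @return Named numeric vector of nmol amounts.
#' @export
default_is_amounts <- function() {
  c("D4-choline" = 50, "PC20:0/20:0" = 500, "PE14:0/14:0" = 200)
}

#' Quantify a full measurement table
#'
#' Runs the complete per-extract quantification chain on a long measurement
#' table: panel-wise 13C spillover correction (panels are same-class species
#' sharing a diagnostic product ion), chain-length response factors,
#' internal-standard ratio quantification, and scaling from the analysed
#' extract to the whole compartment via `injected_fraction`.
#'
#' @param measurements Measurement tibble (see [read_measurements()]).
#' @param registry Registry tibble (default [default_registry()]).
#' @param p13 Natural 13C abundance.
#' @param response A [response_model()].
#' @param is_amounts Named vector of internal-standard amounts (nmol) per
#'   extract, see [default_is_amounts()].
#' @param convention Dilution convention, see
#'   [quantify_by_internal_standard()].
#' @param quiet Suppress clipping warnings.
#' @return A pool tibble: `animal_id`, `matrix`, `analyte`, `class`,
#'   `label_state`, `acyl_group`, `n_labeled_methyls`, `amount_nmol`
#'   (whole compartment) and `clipped`.
#' @export
quantify_measurements <- function(measurements, registry = default_registry(),
                                  p13 = 0.0107,
                                  response = response_model(),
                                  is_amounts = default_is_amounts(),
                                  convention = "pre_spike",
                                  quiet = TRUE) {
  meas <- validate_measurements(measurements, registry)
  reg <- registry %>% mutate(panel = panel_key(registry))

  meas <- meas %>%
    mutate(sample = paste(.data$animal_id, .data$matrix, sep = "\r")) %>%
    left_join(
      select(
        reg, "name", "class", "label_state", "acyl_group",
        "n_labeled_methyls", "internal_standard", "n_carbons", "panel"
      ),
      by = c(analyte = "name")
    )

  # spillover correction, one small solve per panel over all samples at once
  corrected <- meas %>%
    tidyr::nest(data = -"panel") %>%
    mutate(data = purrr::map2(.data$panel, .data$data, function(p, d) {
      sp <- reg %>% filter(.data$panel == p)
      cm <- build_c13_matrix(sp, p13 = p13)
      wide <- tidyr::pivot_wider(
        select(d, "sample", "analyte", "ion_count"),
        names_from = "sample", values_from = "ion_count",
        values_fill = 0, values_fn = sum
      )
      raw <- matrix(0, nrow = length(cm$species), ncol = ncol(wide) - 1,
        dimnames = list(cm$species, names(wide)[-1])
      )
      raw[wide$analyte, ] <- as.matrix(wide[, -1])
      corr <- apply_isotope_correction(raw, cm, quiet = quiet)
      clip <- attr(corr, "clipped")
      tibble(
        sample = rep(colnames(raw), each = nrow(raw)),
        analyte = rep(rownames(raw), times = ncol(raw)),
        corrected_count = as.vector(corr),
        clipped = as.vector(clip)
      ) %>%
        semi_join(d, by = c("sample", "analyte"))
    })) %>%
    tidyr::unnest("data") %>%
    select(-"panel")

  meas <- meas %>%
    left_join(corrected, by = c("sample", "analyte"))

  # corrected counts of each sample's internal standards
  is_counts <- meas %>%
    filter(.data$analyte %in% registry_internal_standards(reg)) %>%
    select("sample",
      internal_standard = "analyte", is_count = "corrected_count"
    )

  quant <- meas %>%
    filter(!.data$analyte %in% registry_internal_standards(reg)) %>%
    left_join(is_counts, by = c("sample", "internal_standard"))
  if (any(is.na(quant$is_count))) {
    miss <- quant %>% filter(is.na(.data$is_count))
    abort(paste0(
      "no internal-standard measurement for ",
      paste(unique(paste0(miss$internal_standard, " in ", miss$animal_id,
        "/", miss$matrix
      )), collapse = ", ")
    ))
  }
  unknown_is_amount <- setdiff(unique(quant$internal_standard),
    names(is_amounts)
  )
  if (length(unknown_is_amount) > 0) {
    abort(paste0(
      "no is_amounts entry for internal standard: ",
      paste(unknown_is_amount, collapse = ", ")
    ))
  }

  quant %>%
    mutate(
      response = predict_response(response, .data$n_carbons),
      amount_extract = quantify_by_internal_standard(
        .data$corrected_count, .data$is_count,
        unname(is_amounts[.data$internal_standard]),
        response = .data$response,
        dilution_factor = .data$dilution_factor,
        convention = convention,
        sample = paste(.data$animal_id, .data$matrix),
        is_name = .data$internal_standard
      ),
      amount_nmol = .data$amount_extract / .data$injected_fraction
    ) %>%
    select(
      "animal_id", "matrix", "analyte", "class", "label_state",
      "acyl_group", "n_labeled_methyls", "amount_nmol", "clipped"
    )
}

# panel key: class + product ion (rounded); same-panel species share the
# spillover correction
panel_key <- function(registry) {
  paste(registry$class, round(registry$product_mz), sep = ":")
}
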