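#' Plasma volume model
#'
#' Plasma volume is estimated from body weight via blood volume (a fixed
#' fraction of body weight), hematocrit and plasma density:
#' volume (uL) = body_weight (g) * blood_fraction * (1 - hematocrit) /
#' plasma_density * 1000.
#'
#' @param blood_fraction Blood volume as fraction of body weight
#'   (default 0.125).
#' @param hematocrit Hematocrit fraction (default 0.40).
#' @param plasma_density Plasma density in g/mL (default 1.025).
#' @return An object of class `plasma_volume_model`.
#' @export
plasma_volume_model <- function(blood_fraction = 0.125, hematocrit = 0.40,
                                plasma_density = 1.025) {
  if (blood_fraction <= 0 || blood_fraction >= 1) {
    abort("blood_fraction must be in (0, 1)")
  }
  if (hematocrit < 0 || hematocrit > 1) {
    abort("hematocrit must be in [0, 1]")
  }
  if (plasma_density < 1.0 || plasma_density > 1.1) {
    abort("plasma_density must be in [1.0, 1.1] g/mL")
  }
  structure(
    list(
      blood_fraction = blood_fraction, hematocrit = hematocrit,
      plasma_density = plasma_density
    ),
    class = "plasma_volume_model"
  )
}

#' Estimate total plasma volume from body weight
#'
#' @param body_weight_g Body weight(s) in g.
#' @param model A [plasma_volume_model()].
#' @return Plasma volume(s) in uL.
#' @export
#' @examples
#' estimate_plasma_volume(28.2) # 2063.4 uL
estimate_plasma_volume <- function(body_weight_g,
                                   model = plasma_volume_model()) {
  if (any(body_weight_g <= 0)) {
    abort("body_weight_g must be > 0")
  }
  body_weight_g * model$blood_fraction * (1 - model$hematocrit) /
    model$plasma_density * 1000
}

#' Whole-compartment pool from concentration and compartment size
#'
#' The pool size is the product of a concentration (nmol per mg tissue, or
#' nmol per uL plasma) and the compartment size (organ wet weight in mg, or
#' plasma volume in uL). LLF pools are the total recovered lavage amount and
#' need no size normalization.
#'
#' @param concentration Concentration(s), nmol/mg or nmol/uL.
#' @param compartment_size Compartment size(s), mg or uL (matching units).
#' @return Pool size(s) in nmol.
#' @export
compute_pool <- function(concentration, compartment_size) {
  if (any(concentration < 0) || any(compartment_size < 0)) {
    abort("concentration and compartment_size must be >= 0")
  }
  concentration * compartment_size
}

#' Per-analyte totals across compartments
#'
#' Sums pool amounts over all matrices, preserving any further grouping
#' columns (animal, label state, time point).
#'
#' @param pools Pool tibble with `matrix`, `analyte` and `amount_nmol`.
#' @param by Extra grouping columns to preserve (default: `animal_id` and any
#'   of `label_state`, `class` present).
#' @return Tibble of per-analyte totals (`amount_nmol` summed over matrices).
#' @export
aggregate_totals <- function(pools, by = NULL) {
  tbl <- as_tibble(pools)
  if (is.null(by)) {
    by <- intersect(c("animal_id", "label_state", "class"), names(tbl))
  }
  tbl %>%
    group_by(across(all_of(c(by, "analyte")))) %>%
    summarise(amount_nmol = sum(.data$amount_nmol), .groups = "drop")
}

#' Pool as a percentage of a reference pool
#'
#' @param pool Pool size(s); any unit, as long as it matches `reference`.
#' @param reference Reference pool (> 0), same unit as `pool`.
#' @return Percentages, 100 * pool / reference.
#' @export
#' @examples
#' pool_fractions(831, 28200) # liver, % of body mass
pool_fractions <- function(pool, reference) {
  if (any(reference <= 0)) {
    abort("reference must be > 0")
  }
  100 * pool / reference
}

#' Estimated whole-body choline-phospholipid pool
#'
#' The whole-body reference pool is 10 umol choline-containing phospholipid
#' per g body weight.
#'
#' @param body_weight_g Body weight in g.
#' @param umol_per_g Reference density (default 10 umol/g).
#' @return Whole-body pool in nmol.
#' @export
whole_body_choline_pl <- function(body_weight_g, umol_per_g = 10) {
  body_weight_g * umol_per_g * 1000
}

#' Attach whole-compartment sizes and concentrations to a pool table
#'
#' Joins animal metadata onto quantified pools, adds the compartment size
#' (organ wet weight in mg; model-derived plasma volume in uL; none for LLF)
#' and the derived concentration (nmol/mg tissue or nmol/uL plasma).
#'
#' @param pools Quantified pool tibble (see [quantify_measurements()]).
#' @param animals Animal metadata tibble (see [read_animals()]).
#' @param volume_model A [plasma_volume_model()].
#' @return The pool tibble with `time_point_h`, `compartment_size` and
#'   `concentration` columns.
#' @export
pool_table <- function(pools, animals, volume_model = plasma_volume_model()) {
  pools <- validate_pools(pools)
  animals <- validate_animals(animals)
  sizes <- animals %>%
    mutate(plasma_uL = estimate_plasma_volume(
      .data$body_weight_g, volume_model
    )) %>%
    select(
      "animal_id", "time_point_h", "body_weight_g",
      liver = "liver_mg", lung = "lung_mg", cerebrum = "cerebrum_mg",
      cerebellum = "cerebellum_mg", plasma = "plasma_uL"
    ) %>%
    tidyr::pivot_longer(
      c("liver", "lung", "cerebrum", "cerebellum", "plasma"),
      names_to = "matrix", values_to = "compartment_size"
    )
  pools %>%
    left_join(sizes,
      by = c("animal_id", "matrix")
    ) %>%
    left_join(
      distinct(
        select(animals, "animal_id",
          time_point_h2 = "time_point_h", body_weight_g2 = "body_weight_g"
        )
      ),
      by = "animal_id"
    ) %>%
    mutate(
      time_point_h = dplyr::coalesce(.data$time_point_h, .data$time_point_h2),
      body_weight_g = dplyr::coalesce(.data$body_weight_g, .data$body_weight_g2),
      concentration = .data$amount_nmol / .data$compartment_size
    ) %>%
    select(-"time_point_h2", -"body_weight_g2")
}

#' Packaged reference pool summary
#'
#' Organ wet weights and endogenous pool sizes (means +/- SE over 27 animals)
#' of choline, its water-soluble metabolites and choline-containing
#' phospholipids in liver, plasma, lung, lung lavage fluid, cerebrum and
#' cerebellum of 14-day-old rats. The plasma "weight" row is the plasma
#' compartment mass in mg (volume x density). Amount units are as printed:
#' nmol for the water-soluble panel, umol for the lipid panel.
#'
#' @return A tibble with columns `panel`, `organ`, `analyte`, `mean`, `se`,
#'   `unit`.
#' @export
reference_pools <- function() {
  readr::read_csv(
    system.file("extdata", "reference_pools.csv",
      package = "cholinetrace", mustWork = TRUE
    ),
    show_col_types = FALSE, progress = FALSE
  )
}

#' Packaged reference label-fraction time course
#'
#' Fractions of the administered D9-choline dose (methyl-corrected, % of
#' dose, means +/- SE of 8-10 animals) recovered in the summed study organs
#' and plasma as water-soluble D9-derived metabolites, D9-labeled
#' phospholipids and D3-labeled phospholipids at 1.5, 6 and 24 h.
#'
#' @return A tibble with columns `time_h`, `category`, `mean_pct`, `se_pct`.
#' @export
reference_label_fractions <- function() {
  readr::read_csv(
    system.file("extdata", "reference_label_fractions.csv",
      package = "cholinetrace", mustWork = TRUE
    ),
    show_col_types = FALSE, progress = FALSE
  )
}

#' Study-level descriptive constants
#'
#' Mean body weight (28.2 g), number of animals (27 with complete data; 29
#' injected), sacrifice times (1.5, 6, 24 h) and the whole-body
#' choline-phospholipid reference density (10 umol/g) used by the
#' descriptive-fraction reports.
#'
#' @return A named list.
#' @export
study_constants <- function() {
  list(
    body_weight_g = 28.2,
    body_weight_se_g = 0.4,
    n_animals = 27,
    time_points_h = c(1.5, 6, 24),
    whole_body_umol_per_g = 10,
    dose_mg_per_kg = 50
  )
}

#' Descriptive organ fractions from the packaged reference pools
#'
#' Recomputes, from the packaged reference summary, each organ's share of
#' body mass and of total investigated choline-phospholipids, the summed
#' organ+plasma share of body weight, and the investigated share of the
#' estimated whole-body choline-phospholipid pool (10 umol/g).
#'
#' @param pools Reference pool tibble (default [reference_pools()]).
#' @param body_weight_g Body weight used as denominator (default 28.2 g).
#' @return A tibble with `organ`, `pct_body_mass`, `pct_choline_pl`, plus
#'   attributes-free summary rows `all_organs_plasma` (% body weight) and
#'   `investigated_total` (% of the whole-body 10 umol/g estimate) in the
#'   columns `pct_body_mass` and `pct_choline_pl` respectively.
#' @export
descriptive_fractions <- function(pools = reference_pools(),
                                  body_weight_g = study_constants()$body_weight_g) {
  body_mg <- body_weight_g * 1000
  whole_body_umol <- whole_body_choline_pl(body_weight_g) / 1000

  weights <- pools %>%
    filter(.data$panel == "weights") %>%
    select("organ", weight_mg = "mean")
  lipids <- pools %>%
    filter(.data$panel == "lipid", .data$analyte == "choline_phospholipids") %>%
    select("organ", pl_umol = "mean")
  total_pl <- sum(lipids$pl_umol)

  per_organ <- weights %>%
    left_join(lipids, by = "organ") %>%
    mutate(
      pct_body_mass = pool_fractions(.data$weight_mg, body_mg),
      pct_choline_pl = pool_fractions(.data$pl_umol, whole_body_umol)
    ) %>%
    select("organ", "pct_body_mass", "pct_choline_pl")

  bind_rows(
    per_organ,
    tibble(
      organ = "all_organs_plasma",
      pct_body_mass = pool_fractions(sum(weights$weight_mg), body_mg),
      pct_choline_pl = NA_real_
    ),
    tibble(
      organ = "investigated_total",
      pct_body_mass = NA_real_,
      pct_choline_pl = pool_fractions(total_pl, whole_body_umol)
    )
  )
}
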