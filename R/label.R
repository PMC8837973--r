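#' Dose specification for D9-choline chloride
#'
#' The tracer is injected intraperitoneally at `dose_mg_per_kg` of D9-choline
#' chloride. The molar dose per gram body weight is derived from the molar
#' mass of the chloride salt (choline chloride 139.62 g/mol plus nine
#' deuterium mass excesses of 1.00628 g/mol each, i.e. 148.68 g/mol), giving
#' approximately 336 nmol per g body weight at the default 50 mg/kg.
#'
#' @param dose_mg_per_kg Injected dose (mg salt per kg body weight).
#' @param compound_mw Molar mass of the injected compound (g/mol).
#' @return An object of class `dose_spec` with the derived `nmol_per_g`.
#' @export
dose_spec <- function(dose_mg_per_kg = 50, compound_mw = 148.68) {
  if (dose_mg_per_kg <= 0 || compound_mw <= 0) {
    abort("dose and molar mass must be > 0")
  }
  structure(
    list(
      dose_mg_per_kg = dose_mg_per_kg,
      compound_mw = compound_mw,
      nmol_per_g = dose_mg_per_kg / compound_mw * 1000
    ),
    class = "dose_spec"
  )
}

#' Administered tracer dose for an animal
#'
#' @param body_weight_g Body weight(s) in g (> 0).
#' @param spec A [dose_spec()].
#' @return Dose(s) in nmol.
#' @export
#' @examples
#' compute_dose(1) # ~336 nmol
#' compute_dose(28.2) # ~9483 nmol
compute_dose <- function(body_weight_g, spec = dose_spec()) {
  if (any(!is.finite(body_weight_g)) || any(body_weight_g <= 0)) {
    abort("body_weight_g must be > 0")
  }
  body_weight_g * spec$nmol_per_g
}

#' Methyl-corrected fraction of the administered label
#'
#' Deuterated pools are expressed as the percentage of administered
#' D9-choline they account for, corrected for the number of deuterated
#' methyl groups per molecule: D9 species carry all three labeled methyls of
#' one tracer molecule, D6-DMG carries two, and D3 species (D3-methionine,
#' D3-choline, D3-PC, ...) carry one, so their absolute amounts are weighted
#' by n/3.
#'
#' @param pool_nmol Deuterated pool size(s), nmol.
#' @param n_labeled_methyls Deuterated methyl count(s), in 1, 2 or 3.
#' @param dose_nmol Administered dose, nmol (> 0).
#' @return Percent of administered label: 100 * pool * (n/3) / dose.
#' @export
methyl_corrected_fraction <- function(pool_nmol, n_labeled_methyls,
                                      dose_nmol) {
  if (any(dose_nmol <= 0)) {
    abort("dose_nmol must be > 0")
  }
  if (any(!n_labeled_methyls %in% c(1, 2, 3))) {
    abort("n_labeled_methyls must be 1, 2 or 3 for deuterated species")
  }
  100 * pool_nmol * (n_labeled_methyls / 3) / dose_nmol
}

#' Deuterium enrichment of a metabolite pool
#'
#' @param labeled_nmol Labeled amount(s), nmol.
#' @param unlabeled_nmol Unlabeled amount(s), nmol.
#' @return Percent enrichment, 100 * labeled / (labeled + unlabeled).
#' @export
enrichment <- function(labeled_nmol, unlabeled_nmol) {
  total <- labeled_nmol + unlabeled_nmol
  if (any(total <= 0)) {
    abort("labeled + unlabeled must be > 0")
  }
  100 * labeled_nmol / total
}

#' Label balance at one time point
#'
#' Sums the percent-of-dose categories observed at each time point and
#' reports the unobserved residual (label in excretion, carcass, intestine
#' and other unmeasured compartments). The residual is reported, never
#' imputed to any compartment.
#'
#' @param fractions Tibble with `percent_of_dose` and optionally `time_h`;
#'   rows are label categories at a time point.
#' @return Tibble with `time_h` (if present), `recovered_pct` and
#'   `residual_pct`.
#' @export
#' @examples
#' label_balance(tibble::tibble(
#'   time_h = 1.5,
#'   category = c("water_soluble", "D9_PL", "D3_PL"),
#'   percent_of_dose = c(11.8, 15.3, 0.8)
#' ))
label_balance <- function(fractions) {
  tbl <- as_tibble(fractions)
  if (nrow(tbl) == 0) {
    return(tibble(recovered_pct = 0, residual_pct = 100))
  }
  if (!"percent_of_dose" %in% names(tbl)) {
    abort("fractions must have a percent_of_dose column")
  }
  by <- intersect("time_h", names(tbl))
  tbl %>%
    group_by(across(all_of(by))) %>%
    summarise(
      recovered_pct = sum(.data$percent_of_dose),
      residual_pct = 100 - sum(.data$percent_of_dose),
      .groups = "drop"
    )
}

#' Dose-fraction table from deuterated pools
#'
#' Converts deuterated whole-compartment pools into methyl-corrected percent
#' of each animal's administered dose, then summarises per time point and
#' category (water-soluble D9-derived metabolites, D9-labeled phospholipids,
#' D3-labeled phospholipids).
#'
#' @param pools Pool tibble with `animal_id`, `class`, `label_state`,
#'   `n_labeled_methyls`, `amount_nmol` and `time_point_h`.
#' @param animals Animal metadata (for body weight and dose).
#' @param spec A [dose_spec()].
#' @return Tibble with `time_h`, `category`, `n`, `percent_of_dose` (mean)
#'   and `se`.
#' @export
label_fraction_table <- function(pools, animals, spec = dose_spec()) {
  animals <- validate_animals(animals)
  doses <- animals %>%
    mutate(dose_nmol = compute_dose(.data$body_weight_g, spec)) %>%
    select("animal_id", "time_point_h", "dose_nmol")
  labeled <- as_tibble(pools) %>%
    filter(.data$label_state %in% c("D9", "D6", "D3")) %>%
    left_join(doses, by = intersect(
      c("animal_id", "time_point_h"), names(pools)
    )) %>%
    mutate(
      category = case_when(
        .data$class == "water_soluble" ~ "water_soluble_D9_derived",
        .data$label_state == "D3" ~ "D3_phospholipid",
        TRUE ~ "D9_phospholipid"
      ),
      pct = methyl_corrected_fraction(
        .data$amount_nmol, .data$n_labeled_methyls, .data$dose_nmol
      )
    )
  labeled %>%
    group_by(.data$animal_id, time_h = .data$time_point_h, .data$category) %>%
    summarise(pct = sum(.data$pct), .groups = "drop") %>%
    group_by(.data$time_h, .data$category) %>%
    summarise(
      n = dplyr::n(),
      percent_of_dose = mean(.data$pct),
      se = sd(.data$pct) / sqrt(dplyr::n()),
      .groups = "drop"
    )
}
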