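#' Simulation configuration for a synthetic tracer study
#'
#' Defaults emulate the study design: 3 sacrifice times (1.5, 6, 24 h) with
#' 9 animals each, 14-day-old rats of 28.2 g mean body weight (SD 2.1 g),
#' organ wet weights drawn from the reference means with SDs derived from
#' the reported standard errors (N = 27), a 50 mg/kg D9-choline chloride
#' dose, multiplicative lognormal biological (per-animal) and measurement
#' (per-observation) noise, and a fixed seed.
#'
#' @param n_per_timepoint Animals per sacrifice time.
#' @param time_points_h Sacrifice times (h).
#' @param body_weight_mean_g,body_weight_sd_g Body-weight distribution (g).
#' @param cv_animal Biological (animal-level) coefficient of variation of
#'   labeled pools.
#' @param cv_measurement Per-observation measurement coefficient of
#'   variation of ion counts.
#' @param dose A [dose_spec()].
#' @param seed Random seed; the seed fully determines the sampled study.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_per_timepoint = 9,
                              time_points_h = c(1.5, 6, 24),
                              body_weight_mean_g = 28.2,
                              body_weight_sd_g = 2.1,
                              cv_animal = 0.15,
                              cv_measurement = 0.15,
                              dose = dose_spec(),
                              seed = 20220720) {
  structure(
    list(
      n_per_timepoint = n_per_timepoint,
      time_points_h = time_points_h,
      body_weight_mean_g = body_weight_mean_g,
      body_weight_sd_g = body_weight_sd_g,
      organ_weights = tibble(
        organ = c("liver", "lung", "cerebrum", "cerebellum"),
        mean_mg = c(831, 282, 881, 268),
        sd_mg = c(21, 4, 37, 14) * sqrt(27)
      ),
      cv_animal = cv_animal,
      cv_measurement = cv_measurement,
      dose = dose,
      seed = seed
    ),
    class = "simulation_config"
  )
}

#' PC acyl-subgroup composition model
#'
#' Equilibrium (endogenous) PC subgroup fractions per organ, the hepatic
#' de-novo synthesis split of newly made (deuterated) PC, and the
#' organ-specific remodeling rate (per h) with which the deuterated profile
#' relaxes toward the organ's equilibrium profile. Newly synthesized PC is
#' enriched in linoleoyl (C18:2) species; lung surfactant-type PC is
#' saturated-rich and remodels quickly; brain remodels over about a day.
#'
#' @return A list with `equilibrium` (tibble organ x acyl_group x fraction),
#'   `synthesis` (named fractions) and `remodel_rate` (named, per h).
#' @export
pc_subgroup_model <- function() {
  groups <- c("sat", "C18:1", "C18:2", "C20:4", "C22:6")
  eq <- tibble(
    organ = rep(c(
      "liver", "plasma", "lung", "LLF", "cerebrum", "cerebellum"
    ), each = 5),
    acyl_group = rep(groups, times = 6),
    fraction = c(
      0.25, 0.20, 0.25, 0.22, 0.08, # liver
      0.20, 0.15, 0.35, 0.22, 0.08, # plasma
      0.50, 0.20, 0.119, 0.160, 0.021, # lung
      0.50, 0.20, 0.119, 0.160, 0.021, # LLF (surfactant, lung-like)
      0.45, 0.267, 0.065, 0.171, 0.047, # cerebrum
      0.45, 0.292, 0.065, 0.141, 0.052 # cerebellum
    )
  )
  list(
    equilibrium = eq,
    synthesis = setNames(c(0.22, 0.22, 0.40, 0.12, 0.04), groups),
    remodel_rate = c(
      liver = 0.08, plasma = 0.03, lung = 3, LLF = 3,
      cerebrum = 0.12, cerebellum = 0.12
    )
  )
}

# deuterated-PC subgroup fractions at time t for one organ
d9_subgroup_fractions <- function(organ, time_h, model = pc_subgroup_model()) {
  eq <- model$equilibrium %>% filter(.data$organ == !!organ)
  r <- model$remodel_rate[[organ]]
  f <- eq$fraction + (model$synthesis[eq$acyl_group] - eq$fraction) *
    exp(-r * time_h)
  setNames(f / sum(f), eq$acyl_group)
}

# species making up each acyl subgroup, with within-subgroup weights
pc_species_weights <- function() {
  tibble(
    species_suffix = c(
      "PC16:0/16:0",
      "PC16:0/18:1", "PC18:0/18:1",
      "PC16:0/18:2", "PC18:0/18:2",
      "PC16:0/20:4", "PC18:0/20:4",
      "PC16:0/22:6", "PC18:0/22:6"
    ),
    acyl_group = c(
      "sat", "C18:1", "C18:1", "C18:2", "C18:2",
      "C20:4", "C20:4", "C22:6", "C22:6"
    ),
    weight = c(1, 0.6, 0.4, 0.6, 0.4, 0.6, 0.4, 0.6, 0.4)
  )
}

# map network compartments to registry analytes (non-PC species)
.species_analyte <- c(
  "choline.D9" = "D9-choline",
  "phosphocholine.D9" = "D9-phosphocholine",
  "GPC.D9" = "D9-GPC",
  "betaine.D9" = "D9-betaine",
  "DMG.D6" = "D6-DMG",
  "methionine.D3" = "D3-methionine",
  "choline.D3" = "D3-choline",
  "lysoPC.D9" = "D9-lysoPC16:0",
  "SPH.D9" = "D9-SPH16:0"
)

#' Sample a complete synthetic tracer study
#'
#' Draws per-animal metadata, evaluates the deterministic network
#' trajectories at each animal's sacrifice time, splits PC into acyl-defined
#' species via the subgroup composition model, adds endogenous (unlabeled)
#' pools held at the reference steady state, applies lognormal animal-level
#' noise, and synthesizes raw SRM ion counts by the forward model of the
#' quantification chain (internal-standard ratios, response factors, 13C
#' isotopologue spillover, dilution and injected-fraction bookkeeping) so
#' that quantification of the sampled counts recovers the ground-truth pools
#' up to measurement noise.
#'
#' @param config A [simulation_config()].
#' @param network A [tracer_network()]; default [default_network()].
#' @param registry Registry tibble.
#' @param trajectories Optional precomputed output of [simulate_tracer()]
#'   with `dose_nmol = 100` at the config's time points (they are
#'   deterministic, so replicated sampling runs can share one simulation).
#' @return A list with `animals` (metadata tibble), `truth` (ground-truth
#'   pool tibble, before measurement noise) and `measurements` (raw ion
#'   count tibble ready for [quantify_measurements()]).
#' @export
sample_study <- function(config = simulation_config(),
                         network = default_network(),
                         registry = default_registry(),
                         trajectories = NULL) {
  set.seed(config$seed)
  n_total <- config$n_per_timepoint * length(config$time_points_h)

  animals <- tibble(
    animal_id = sprintf("rat%02d", seq_len(n_total)),
    time_point_h = rep(config$time_points_h, each = config$n_per_timepoint),
    body_weight_g = pmax(
      rnorm(n_total, config$body_weight_mean_g, config$body_weight_sd_g),
      0.5 * config$body_weight_mean_g
    ),
    dose_mg_per_kg = config$dose$dose_mg_per_kg
  )
  for (i in seq_len(nrow(config$organ_weights))) {
    ow <- config$organ_weights[i, ]
    animals[[paste0(ow$organ, "_mg")]] <- pmax(
      rnorm(n_total, ow$mean_mg, ow$sd_mg), 0.3 * ow$mean_mg
    )
  }
  animals$dose_nmol <- compute_dose(animals$body_weight_g, config$dose)

  # deterministic trajectories, percent-of-dose units
  if (is.null(trajectories)) {
    trajectories <- simulate_tracer(network,
      dose_nmol = 100, times = config$time_points_h
    )
  }
  if (!all(config$time_points_h %in% trajectories$time)) {
    abort("trajectories do not cover the config time points")
  }
  traj <- trajectories %>%
    filter(!.data$organ %in% c("peritoneum", "sink"))

  truth <- build_truth_pools(animals, traj, config, registry)
  measurements <- synthesize_measurements(truth, animals, registry, config)

  list(animals = animals, truth = truth, measurements = measurements)
}

# ground-truth per-animal pools: labeled (trajectory-derived, species-split)
# plus endogenous pools held at the reference steady state
build_truth_pools <- function(animals, traj, config, registry) {
  model <- pc_subgroup_model()
  spw <- pc_species_weights()
  reg_info <- select(
    registry, analyte = "name", "class", "label_state",
    "acyl_group", "n_labeled_methyls"
  )

  labeled <- animals %>%
    select("animal_id", "time_point_h", "dose_nmol") %>%
    inner_join(traj, by = c(time_point_h = "time"),
      relationship = "many-to-many"
    ) %>%
    mutate(amount_nmol = .data$amount_nmol * .data$dose_nmol / 100)

  # PC compartments: split into acyl species with time/organ-dependent mix
  pc <- labeled %>%
    filter(.data$species == "PC") %>%
    mutate(frac_key = paste(.data$organ, .data$time_point_h))
  frac_tbl <- pc %>%
    distinct(.data$organ, .data$time_point_h) %>%
    purrr::pmap_dfr(function(organ, time_point_h) {
      f <- d9_subgroup_fractions(organ, time_point_h, model)
      tibble(
        organ = organ, time_point_h = time_point_h,
        acyl_group = names(f), group_fraction = unname(f)
      )
    })
  pc_species <- pc %>%
    left_join(frac_tbl, by = c("organ", "time_point_h"),
      relationship = "many-to-many"
    ) %>%
    left_join(spw, by = "acyl_group", relationship = "many-to-many") %>%
    mutate(
      analyte = paste0(
        if_else(.data$label == "D9", "D9-", "D3-"), .data$species_suffix
      ),
      amount_nmol = .data$amount_nmol * .data$group_fraction * .data$weight
    ) %>%
    select(
      "animal_id", "time_point_h", matrix = "organ", "analyte", "amount_nmol"
    )

  non_pc <- labeled %>%
    filter(.data$species != "PC", .data$species != "CDPcholine") %>%
    mutate(analyte = unname(
      .species_analyte[paste(.data$species, .data$label, sep = ".")]
    )) %>%
    filter(!is.na(.data$analyte)) %>%
    select(
      "animal_id", "time_point_h", matrix = "organ", "analyte", "amount_nmol"
    )

  endo <- build_endogenous_pools(animals, model, spw)

  pools <- bind_rows(pc_species, non_pc, endo) %>%
    left_join(reg_info, by = "analyte")
  # LLF is not analysed for water-soluble components
  pools <- pools %>%
    filter(!(.data$matrix == "LLF" & .data$class == "water_soluble"))

  # animal-level biological noise (mean-one lognormal per animal x analyte)
  if (config$cv_animal > 0) {
    sdlog <- sqrt(log(1 + config$cv_animal^2))
    pools$amount_nmol <- pools$amount_nmol *
      rlnorm(nrow(pools), -sdlog^2 / 2, sdlog)
  }
  pools
}

# endogenous pools at reference steady state, scaled by organ size
build_endogenous_pools <- function(animals, model, spw) {
  ref <- reference_pools()
  ws_keep <- c(
    "choline", "phosphocholine", "GPC", "betaine", "DMG", "methionine"
  )
  mean_size <- c(
    liver = 831, plasma = 2151, lung = 282,
    LLF = 1, cerebrum = 881, cerebellum = 268
  )

  sizes <- animals %>%
    mutate(
      plasma = estimate_plasma_volume(.data$body_weight_g) * 1.025,
      LLF = 1
    ) %>%
    select("animal_id",
      liver = "liver_mg", lung = "lung_mg",
      cerebrum = "cerebrum_mg", cerebellum = "cerebellum_mg",
      "plasma", "LLF"
    ) %>%
    tidyr::pivot_longer(-"animal_id",
      names_to = "matrix", values_to = "size"
    ) %>%
    mutate(scale = .data$size / unname(mean_size[.data$matrix]))

  ws <- ref %>%
    filter(.data$panel == "water_soluble", .data$analyte %in% ws_keep) %>%
    select(matrix = "organ", "analyte", base_nmol = "mean")

  lipid <- ref %>%
    filter(
      .data$panel == "lipid",
      .data$analyte %in% c("PC", "lysoPC", "SPH")
    ) %>%
    mutate(base_nmol = .data$mean * 1000) %>%
    select(matrix = "organ", "analyte", "base_nmol")

  # endogenous PC split by the organ's equilibrium composition
  lipid_pc <- lipid %>%
    filter(.data$analyte == "PC") %>%
    left_join(model$equilibrium,
      by = c(matrix = "organ"), relationship = "many-to-many"
    ) %>%
    left_join(spw, by = "acyl_group", relationship = "many-to-many") %>%
    mutate(
      analyte = .data$species_suffix,
      base_nmol = .data$base_nmol * .data$fraction * .data$weight
    ) %>%
    select("matrix", "analyte", "base_nmol")
  lipid_other <- lipid %>%
    filter(.data$analyte != "PC") %>%
    mutate(analyte = paste0(.data$analyte, "16:0")) %>%
    select("matrix", "analyte", "base_nmol")

  base <- bind_rows(ws, lipid_pc, lipid_other)
  animals %>%
    select("animal_id", "time_point_h") %>%
    inner_join(
      left_join(base, sizes, by = "matrix", relationship = "many-to-many"),
      by = "animal_id"
    ) %>%
    mutate(amount_nmol = .data$base_nmol * .data$scale) %>%
    select(
      "animal_id", "time_point_h", "matrix", "analyte", "amount_nmol"
    )
}

# forward model: ground-truth pools -> raw SRM ion counts
synthesize_measurements <- function(truth, animals, registry, config,
                                    response = response_model(),
                                    is_amounts = default_is_amounts(),
                                    is_count_base = c(
                                      "D4-choline" = 5e5,
                                      "PC20:0/20:0" = 1e6,
                                      "PE14:0/14:0" = 8e5
                                    )) {
  reg <- registry %>% mutate(panel = panel_key(registry))
  plasma_vol <- setNames(
    estimate_plasma_volume(animals$body_weight_g), animals$animal_id
  )

  meas <- truth %>%
    left_join(
      select(reg, analyte = "name", "n_carbons", "internal_standard",
        reg_class = "class"
      ),
      by = "analyte"
    ) %>%
    mutate(
      injected_fraction = dplyr::case_when(
        .data$matrix == "plasma" ~ 50 / unname(plasma_vol[.data$animal_id]),
        TRUE ~ 1
      ),
      dilution_factor = dplyr::case_when(
        .data$reg_class == "water_soluble" & .data$matrix == "liver" ~ 110,
        .data$reg_class == "water_soluble" ~ 7.5,
        TRUE ~ 157
      ),
      amount_extract = .data$amount_nmol * .data$injected_fraction,
      resp = predict_response(response, .data$n_carbons),
      corrected_count = .data$amount_extract * .data$resp /
        unname(is_amounts[.data$internal_standard]) *
        unname(is_count_base[.data$internal_standard])
    ) %>%
    select(
      "animal_id", "matrix", "analyte", "corrected_count",
      "dilution_factor", "injected_fraction"
    )

  # internal-standard rows for every sampled extract
  is_rows <- meas %>%
    left_join(select(reg, analyte = "name", "internal_standard"),
      by = "analyte"
    ) %>%
    distinct(
      .data$animal_id, .data$matrix, analyte = .data$internal_standard,
      .data$dilution_factor
    ) %>%
    mutate(
      corrected_count = unname(is_count_base[.data$analyte]),
      injected_fraction = 1
    )

  counts <- bind_rows(meas, is_rows) %>%
    mutate(sample = paste(.data$animal_id, .data$matrix, sep = "\r")) %>%
    left_join(select(reg, analyte = "name", "panel"), by = "analyte")

  # forward 13C spillover, panel by panel
  raw <- counts %>%
    tidyr::nest(data = -"panel") %>%
    mutate(data = purrr::map2(.data$panel, .data$data, function(p, d) {
      sp <- reg %>% filter(.data$panel == p)
      cm <- build_c13_matrix(sp)
      wide <- tidyr::pivot_wider(
        select(d, "sample", "analyte", "corrected_count"),
        names_from = "sample", values_from = "corrected_count",
        values_fill = 0, values_fn = sum
      )
      X <- matrix(0, nrow = length(cm$species), ncol = ncol(wide) - 1,
        dimnames = list(cm$species, names(wide)[-1])
      )
      X[wide$analyte, ] <- as.matrix(wide[, -1])
      R <- forward_isotopologue_spillover(X, cm)
      tibble(
        sample = rep(colnames(R), each = nrow(R)),
        analyte = rep(rownames(R), times = ncol(R)),
        ion_count = as.vector(R)
      ) %>%
        semi_join(d, by = c("sample", "analyte"))
    })) %>%
    tidyr::unnest("data") %>%
    select(-"panel")

  out <- counts %>%
    select(-"corrected_count") %>%
    left_join(raw, by = c("sample", "analyte")) %>%
    select(
      "animal_id", "matrix", "analyte", "ion_count",
      "dilution_factor", "injected_fraction"
    )

  if (config$cv_measurement > 0) {
    sdlog <- sqrt(log(1 + config$cv_measurement^2))
    out$ion_count <- out$ion_count *
      rlnorm(nrow(out), -sdlog^2 / 2, sdlog)
  }
  out
}

#' Forward 13C isotopologue spillover
#'
#' Applies the spillover matrix in the forward direction (`C %*% x`):
#' synthesizes the raw counts that a spillover-free count vector would
#' produce. [apply_isotope_correction()] is its exact inverse.
#'
#' @param counts Numeric vector or species x sample matrix aligned to
#'   `correction$species`.
#' @param correction A `correction_matrix` from [build_c13_matrix()].
#' @return Raw counts, same shape as `counts`.
#' @export
forward_isotopologue_spillover <- function(counts, correction) {
  C <- correction$C
  if (is.matrix(counts)) {
    out <- C %*% counts
    dimnames(out) <- dimnames(counts)
    out
  } else {
    drop(C %*% matrix(counts, ncol = 1))
  }
}
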