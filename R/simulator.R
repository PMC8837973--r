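#' Construct a first-order tracer network
#'
#' A tracer network is a set of compartments named `organ.species.label`
#' (plus the absorbing `sink`) connected by first-order processes. Each
#' process consumes its `from` compartment at rate `rate` (per h) and
#' delivers `yield` molecules to each `to` compartment; a process listed with
#' several product rows (same `process` id) models a molecular split, e.g.
#' demethylation of D9-betaine yielding D6-dimethylglycine plus a D3-methyl
#' that enters D3-methionine, conserving methyl-weighted label (3 = 2 + 1).
#'
#' @param edges Tibble with columns `process`, `from`, `to`, `yield`, `rate`.
#' @return An object of class `tracer_network`.
#' @export
tracer_network <- function(edges) {
  edges <- as_tibble(edges)
  required <- c("process", "from", "to", "yield", "rate")
  miss <- setdiff(required, names(edges))
  if (length(miss) > 0) {
    abort(paste0("edges missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (any(edges$rate < 0)) {
    abort("rate constants must be >= 0")
  }
  if (any(edges$yield <= 0)) {
    abort("yields must be > 0")
  }
  rate_per_process <- edges %>%
    distinct(.data$process, .data$from, .data$rate)
  if (any(duplicated(rate_per_process$process))) {
    abort("a process must have a single from-compartment and rate")
  }
  comp <- sort(unique(c(edges$from, edges$to)))
  structure(
    list(edges = edges, compartments = comp),
    class = "tracer_network"
  )
}

#' @export
print.tracer_network <- function(x, ...) {
  cat(
    "<tracer_network> ", length(x$compartments), " compartments, ",
    length(unique(x$edges$process)), " processes\n",
    sep = ""
  )
  invisible(x)
}

#' Closed-system variant of a network
#'
#' Removes every process that delivers to the `sink` compartment (excretion,
#' carcass uptake, further demethylation). The remaining system conserves
#' methyl-weighted label exactly, which the simulator tests exploit.
#'
#' @param network A [tracer_network()].
#' @return A `tracer_network` without sink processes.
#' @export
closed_network <- function(network) {
  sink_processes <- unique(network$edges$process[network$edges$to == "sink"])
  tracer_network(filter(
    network$edges, !.data$process %in% sink_processes
  ))
}

#' First-order rate matrix of a network
#'
#' Builds the matrix A of the linear system dx/dt = A x over the network's
#' compartments.
#'
#' @param network A [tracer_network()].
#' @return A square matrix with compartment dimnames.
#' @export
rate_matrix <- function(network) {
  comp <- network$compartments
  n <- length(comp)
  A <- matrix(0, n, n, dimnames = list(comp, comp))
  consumption <- distinct(network$edges, .data$process, .data$from, .data$rate)
  for (i in seq_len(nrow(consumption))) {
    f <- consumption$from[i]
    A[f, f] <- A[f, f] - consumption$rate[i]
  }
  for (i in seq_len(nrow(network$edges))) {
    e <- network$edges[i, ]
    A[e$to, e$from] <- A[e$to, e$from] + e$rate * e$yield
  }
  A
}

# parse organ/species/label out of compartment names
parse_compartments <- function(comp) {
  parts <- strsplit(comp, ".", fixed = TRUE)
  tibble(
    compartment = comp,
    organ = purrr::map_chr(parts, ~ .x[1]),
    species = purrr::map_chr(parts, ~ if (length(.x) > 1) .x[2] else NA_character_),
    label = purrr::map_chr(parts, ~ if (length(.x) > 2) .x[3] else NA_character_)
  )
}

#' Methyl-weighted label content of a state
#'
#' Weights each compartment by its deuterated-methyl count over 3 (D9 = 1,
#' D6 = 2/3, D3 = 1/3), the bookkeeping that makes total label comparable to
#' the administered D9 dose. The sink (unknown label mixture) is excluded;
#' use [closed_network()] when testing conservation.
#'
#' @param state Named state vector (nmol per compartment).
#' @return Total methyl-weighted label (nmol D9-choline equivalents).
#' @export
methyl_weighted_total <- function(state) {
  info <- parse_compartments(names(state))
  w <- dplyr::case_match(info$label,
    "D9" ~ 1, "D6" ~ 2 / 3, "D3" ~ 1 / 3, .default = 0
  )
  sum(state * w)
}

#' Simulate tracer kinetics on a network
#'
#' Integrates the linear first-order system dx/dt = A x with the dose placed
#' in the peritoneal choline compartment (intraperitoneal injection), using
#' a stiff ODE solver. Tiny negative excursions from the integrator are
#' clamped to zero.
#'
#' @param network A [tracer_network()].
#' @param dose_nmol Administered dose (nmol); ignored when `x0` is given.
#' @param times Output times (h); 0 is added automatically.
#' @param x0 Optional named initial-state vector overriding the default.
#' @param rtol,atol Solver tolerances.
#' @return A tibble of class `tracer_trajectories`: `time`, `compartment`,
#'   `organ`, `species`, `label`, `amount_nmol`.
#' @export
simulate_tracer <- function(network, dose_nmol = 100, times = c(1.5, 6, 24),
                            x0 = NULL, rtol = 1e-10, atol = 1e-12) {
  A <- rate_matrix(network)
  comp <- colnames(A)
  state <- setNames(numeric(length(comp)), comp)
  if (is.null(x0)) {
    if (!"peritoneum.choline.D9" %in% comp) {
      abort("network lacks the peritoneum.choline.D9 dose compartment")
    }
    state["peritoneum.choline.D9"] <- dose_nmol
  } else {
    unknown <- setdiff(names(x0), comp)
    if (length(unknown) > 0) {
      abort(paste0(
        "x0 names not in network: ", paste(unknown, collapse = ", ")
      ))
    }
    state[names(x0)] <- x0
  }
  tt <- sort(unique(c(0, times)))
  sol <- deSolve::ode(
    y = state, times = tt,
    func = function(t, y, parms) list(parms %*% y),
    parms = A, method = "lsoda", rtol = rtol, atol = atol
  )
  if (attr(sol, "istate")[1] < 0) {
    abort("ODE integration failed; check rate constants for stiffness")
  }
  out <- as_tibble(as.data.frame(sol)) %>%
    filter(.data$time %in% times) %>%
    tidyr::pivot_longer(-"time",
      names_to = "compartment", values_to = "amount_nmol"
    ) %>%
    mutate(amount_nmol = pmax(.data$amount_nmol, 0)) %>%
    left_join(parse_compartments(comp), by = "compartment")
  class(out) <- c("tracer_trajectories", class(out))
  out
}

#' Default rate constants of the packaged choline network
#'
#' First-order rate constants (per h) of the packaged neonatal choline
#' tracer network. The values were calibrated by the package authors so that
#' the deterministic trajectories reproduce the study-level label kinetics:
#' the methyl-corrected dose fractions of water-soluble D9 metabolites,
#' D9-phospholipids (anchored at 15.3% at 1.5 h) and D3-phospholipids at
#' 1.5/6/24 h, and the qualitative organ patterns (hepatic and pulmonary
#' D9-PC peak at 1.5 h and fall to 6 h, pulmonary and brain D9-PC accretion
#' from 6 to 24 h, monotone surfactant (LLF) D9-PC increase, >7-fold fall of
#' D9-PC precursors from 1.5 to 6 h, monotone sub-3%-of-dose D3-PC). They
#' are not fitted to per-animal data (none are deposited) and carry no
#' per-organ quantitative claim beyond those constraints.
#'
#' @return Named numeric vector of rate constants (per h).
#' @export
default_rates <- function() {
  c(
    k_abs = 30,
    k_cho_up_liver = 0.9799, k_cho_up_lung = 0.06811,
    k_cho_up_cerebrum = 0.004807, k_cho_up_cerebellum = 0.002112,
    k_cho_clear = 2.179, k_cho_efflux = 0.003388,
    k_ck_liver = 1.8, k_ck_lung = 30,
    k_ck_cerebrum = 30, k_ck_cerebellum = 20.13,
    k_chdh = 2.298,
    k_cct = 30, k_cpt = 20,
    k_bet_efflux = 0.7245, k_bet_uptake = 0.0003016, k_bet_clear = 1.469,
    k_bhmt = 0.3115,
    k_dmg_efflux = 14.04, k_dmg_clear = 30, k_dmg_deg = 30,
    k_met_use = 0.001407, k_pemt = 3.953,
    k_pla = 0.08446, k_lyso_deacyl = 0.5884, k_lyso_efflux = 0.0001,
    k_lyso_clear = 24.2, k_gpc = 0.4553,
    k_vldl = 0.02094, k_bile = 0.0001,
    k_pc_up_liver = 0.02861, k_pc_up_lung = 0.5294,
    k_pc_up_cerebrum = 0.01485, k_pc_up_cerebellum = 0.006523,
    k_abca1 = 0.8534, k_surf = 0.003743,
    k_sms_liver = 0.01259, k_sms_lung = 0.0002084,
    k_sms_cerebrum = 0.0001, k_sms_cerebellum = 0.0001465,
    k_d3_hyd = 0.0001, k_cho3_clear = 0.0001
  )
}

#' Packaged neonatal choline tracer network
#'
#' Builds the packaged network topology: intraperitoneal absorption, plasma
#' choline distribution to liver, lung, cerebrum and cerebellum (plus
#' clearance to unobserved compartments), the CDP-choline pathway
#' (choline -> phosphocholine -> CDP-choline -> PC) in each tissue, hepatic
#' choline oxidation to betaine and its demethylation (D6-DMG + D3-methyl to
#' D3-methionine), the PEMT route to D3-PC, PC catabolism and recycling
#' (lyso-PC, GPC), hepatic VLDL and pulmonary ABCA1 secretion of PC into
#' plasma, plasma PC uptake by the organs, apical secretion into bile (sink)
#' and surfactant (LLF), and PC-to-sphingomyelin phosphocholine transfer.
#'
#' @param rates Named vector of rate constants, see [default_rates()].
#' @return A [tracer_network()].
#' @export
default_network <- function(rates = default_rates()) {
  k <- function(name) {
    if (!name %in% names(rates)) {
      abort(paste0("missing rate constant: ", name))
    }
    unname(rates[name])
  }
  organs <- c("liver", "lung", "cerebrum", "cerebellum")
  e <- list()
  add <- function(process, from, to, rate, yield = 1) {
    e[[length(e) + 1]] <<- tibble(
      process = process, from = from, to = to, yield = yield, rate = rate
    )
  }

  add("abs", "peritoneum.choline.D9", "plasma.choline.D9", k("k_abs"))
  for (o in organs) {
    add(
      paste0("cho_up_", o), "plasma.choline.D9",
      paste0(o, ".choline.D9"), k(paste0("k_cho_up_", o))
    )
    add(
      paste0("ck_", o), paste0(o, ".choline.D9"),
      paste0(o, ".phosphocholine.D9"), k(paste0("k_ck_", o))
    )
    add(
      paste0("cct_", o), paste0(o, ".phosphocholine.D9"),
      paste0(o, ".CDPcholine.D9"), k("k_cct")
    )
    add(
      paste0("cpt_", o), paste0(o, ".CDPcholine.D9"),
      paste0(o, ".PC.D9"), k("k_cpt")
    )
    add(
      paste0("sms_", o), paste0(o, ".PC.D9"),
      paste0(o, ".SPH.D9"), k(paste0("k_sms_", o))
    )
  }
  add("cho_clear", "plasma.choline.D9", "sink", k("k_cho_clear"))
  add("cho_efflux", "liver.choline.D9", "plasma.choline.D9", k("k_cho_efflux"))

  # betaine arm: oxidation, exchange, demethylation with D3-methyl handoff
  add("chdh", "liver.choline.D9", "liver.betaine.D9", k("k_chdh"))
  add("bet_efflux", "liver.betaine.D9", "plasma.betaine.D9", k("k_bet_efflux"))
  add("bet_uptake", "plasma.betaine.D9", "liver.betaine.D9", k("k_bet_uptake"))
  add("bet_clear", "plasma.betaine.D9", "sink", k("k_bet_clear"))
  add("bhmt", "liver.betaine.D9", "liver.DMG.D6", k("k_bhmt"))
  add("bhmt", "liver.betaine.D9", "liver.methionine.D3", k("k_bhmt"))
  add("dmg_efflux", "liver.DMG.D6", "plasma.DMG.D6", k("k_dmg_efflux"))
  add("dmg_clear", "plasma.DMG.D6", "sink", k("k_dmg_clear"))
  add("dmg_deg", "liver.DMG.D6", "sink", k("k_dmg_deg"))
  add("met_use", "liver.methionine.D3", "sink", k("k_met_use"))
  add("pemt", "liver.methionine.D3", "liver.PC.D3", k("k_pemt"))

  # PC catabolism and recycling in the liver
  add("pla", "liver.PC.D9", "liver.lysoPC.D9", k("k_pla"))
  add("lyso_deacyl", "liver.lysoPC.D9", "liver.GPC.D9", k("k_lyso_deacyl"))
  add("lyso_efflux", "liver.lysoPC.D9", "plasma.lysoPC.D9", k("k_lyso_efflux"))
  add("lyso_clear", "plasma.lysoPC.D9", "sink", k("k_lyso_clear"))
  add("gpc", "liver.GPC.D9", "liver.choline.D9", k("k_gpc"))

  # inter-organ PC trafficking
  add("vldl", "liver.PC.D9", "plasma.PC.D9", k("k_vldl"))
  add("bile", "liver.PC.D9", "sink", k("k_bile"))
  for (o in organs) {
    add(
      paste0("pc_up_", o), "plasma.PC.D9",
      paste0(o, ".PC.D9"), k(paste0("k_pc_up_", o))
    )
  }
  add("abca1", "lung.PC.D9", "plasma.PC.D9", k("k_abca1"))
  add("surf", "lung.PC.D9", "LLF.PC.D9", k("k_surf"))

  # D3-PC mirror (PEMT product) trafficking
  add("vldl_d3", "liver.PC.D3", "plasma.PC.D3", k("k_vldl"))
  add("bile_d3", "liver.PC.D3", "sink", k("k_bile"))
  for (o in c("lung", "cerebrum", "cerebellum")) {
    add(
      paste0("pc3_up_", o), "plasma.PC.D3",
      paste0(o, ".PC.D3"), k(paste0("k_pc_up_", o))
    )
  }
  add("d3_hyd", "liver.PC.D3", "plasma.choline.D3", k("k_d3_hyd"))
  add("cho3_clear", "plasma.choline.D3", "sink", k("k_cho3_clear"))

  tracer_network(bind_rows(e))
}

#' Least-squares estimate of a single first-order transfer rate
#'
#' Estimates the rate constant k of a transfer source -> target from pool
#' time courses of the two compartments, by least squares on
#' target(t_i) = target(t_1) + k * integral of source. The source is
#' interpolated log-linearly between observations (exact for first-order
#' decay), falling back to linear interpolation where values are
#' non-positive.
#'
#' @param times Observation times (h), at least 3.
#' @param source Source-compartment pools at `times`.
#' @param target Target-compartment pools at `times`.
#' @return An object of class `transfer_fit` with elements `k`, `fitted`,
#'   `residuals`, `times`, `rss`.
#' @export
fit_transfer_rate <- function(times, source, target) {
  if (length(times) < 3) {
    abort("at least 3 time points are required")
  }
  ord <- order(times)
  times <- times[ord]
  source <- source[ord]
  target <- target[ord]
  # cumulative integral of the source, log-linear within intervals
  seg <- numeric(length(times) - 1)
  for (i in seq_along(seg)) {
    a <- source[i]
    b <- source[i + 1]
    dt <- times[i + 1] - times[i]
    seg[i] <- if (a > 0 && b > 0 && abs(log(b / a)) > 1e-12) {
      (b - a) / log(b / a) * dt
    } else {
      (a + b) / 2 * dt
    }
  }
  z <- c(0, cumsum(seg))
  y <- target - target[1]
  k <- if (sum(z^2) > 0) sum(z * y) / sum(z^2) else 0
  fitted <- target[1] + k * z
  structure(
    list(
      k = k, fitted = fitted, residuals = target - fitted,
      times = times, rss = sum((target - fitted)^2)
    ),
    class = "transfer_fit"
  )
}

#' @export
print.transfer_fit <- function(x, ...) {
  cat("<transfer_fit> k =", format(x$k, digits = 6), "per h, rss =",
    format(x$rss, digits = 4), "\n"
  )
  invisible(x)
}
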