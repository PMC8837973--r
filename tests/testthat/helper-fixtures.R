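# shared fixtures built in code

suppressMessages(library(dplyr))

# minimal two-analyte registry (analyte + its internal standard)
tiny_registry <- function() {
  tibble::tibble(
    name = c("choline", "D4-choline"),
    class = "water_soluble",
    label_state = c("unlabeled", "D4_IS"),
    precursor_mz = c(104, 108),
    product_mz = c(60, 60),
    n_carbons = 5,
    n_labeled_methyls = 0,
    internal_standard = c("D4-choline", NA),
    acyl_group = "n/a"
  )
}

# a PC-like species panel with one M+2 (double-bond) neighbour pair
pc_panel <- function(n_carbons = c(42, 42, 44)) {
  tibble::tibble(
    name = c("PC34:2", "PC34:1", "PC36:4"),
    class = "PC",
    label_state = "unlabeled",
    precursor_mz = c(758.6, 760.6, 782.6),
    product_mz = 184.1,
    n_carbons = n_carbons,
    n_labeled_methyls = 0,
    internal_standard = "PC34:2",
    acyl_group = c("C18:2", "C18:1", "C20:4")
  )
}

# simple one-edge network A -> B
two_compartment_network <- function(k = log(2)) {
  tracer_network(tibble::tibble(
    process = "transfer",
    from = "peritoneum.choline.D9",
    to = "plasma.choline.D9",
    yield = 1,
    rate = k
  ))
}

# independent convolution oracle: P(exactly m heavy atoms among n), built by
# convolving per-atom distributions rather than using the binomial density
convolve_isotope_prob <- function(n, p, m) {
  dist <- 1
  for (i in seq_len(n)) {
    dist <- convolve(c(dist, 0), rev(c(1 - p, p)), type = "open")
  }
  dist[m + 1]
}

# small noise-free synthetic study shared across tests
small_noisefree_study <- function(n = 2, seed = 42) {
  sample_study(simulation_config(
    n_per_timepoint = n, cv_animal = 0, cv_measurement = 0, seed = seed
  ))
}
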