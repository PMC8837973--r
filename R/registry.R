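#' Load an SRM analyte/transition registry
#'
#' The registry declares every analyte the pipeline knows about: its lipid or
#' water-soluble class, deuterium label state, SRM transition (precursor and
#' product m/z), carbon count (for natural-abundance \eqn{^{13}}C correction),
#' number of trideuteromethyl groups (for dose accounting), internal-standard
#' link, and PC/PE acyl subgroup tag.
#'
#' Accepted formats are delimited text (`.csv`/`.tsv`, header row with the
#' columns of [default_registry()]) and YAML (`.yaml`/`.yml`, one mapping per
#' analyte with the same field names).
#'
#' @param path Path to a registry file.
#' @return A validated tibble with one row per SRM transition and columns
#'   `name`, `class`, `label_state`, `precursor_mz`, `product_mz`,
#'   `n_carbons`, `n_labeled_methyls`, `internal_standard`, `acyl_group`.
#' @seealso [default_registry()]
#' @export
#' @examples
#' reg <- default_registry()
#' dplyr::filter(reg, name %in% c("choline", "D9-choline"))
load_registry <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("registry file not found: ", path))
  }
  ext <- tolower(tools::file_ext(path))
  reg <- switch(ext,
    yaml = ,
    yml = {
      recs <- yaml::read_yaml(path)
      purrr::map_dfr(recs, function(r) {
        r$internal_standard <- r$internal_standard %||% NA_character_
        as_tibble(r)
      })
    },
    csv = readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
    tsv = readr::read_tsv(path, show_col_types = FALSE, progress = FALSE),
    abort(paste0("unsupported registry format: .", ext))
  )
  validate_registry(reg)
}

#' Packaged default registry
#'
#' Returns the registry shipped with the package: the 17 water-soluble SRM
#' transitions of the assay (choline 104->60, D3-choline 107->63, D4-choline
#' 108->60 and 108->61, D9-choline 113->69, betaine 118->59, D9-betaine
#' 127->68, phosphocholine 184->86, D9-phosphocholine 193->95, DMG 104->58,
#' D6-DMG 110->64, GPC 258->104, D9-GPC 267->113, methionine 150->61,
#' D3-methionine 153->64, carnitine 162->60, D3-carnitine 165->63) plus
#' endogenous, D9- and D3-labeled PC, lyso-PC and SPH species and a small PE
#' panel. Diagnostic product ions are m/z 184 (endogenous choline lipids),
#' 193 (D9) and 187 (D3); PE uses neutral loss of 141.
#'
#' @return A validated registry tibble (see [load_registry()]).
#' @export
default_registry <- function() {
  load_registry(system.file("extdata", "srm_registry.csv",
    package = "cholinetrace", mustWork = TRUE
  ))
}

#' Validate an analyte registry
#'
#' Checks column presence and types, uniqueness of analyte names, allowed
#' class/label/acyl vocabularies, the label-state/methyl-count correspondence
#' (3 for D9, 2 for D6, 1 for D3, 0 otherwise), transition sanity
#' (precursor > product > 0), and that every non-internal-standard analyte
#' maps to exactly one registered internal standard.
#'
#' @param reg A data frame with the registry columns.
#' @return The registry as a tibble, invisibly usable downstream.
#' @export
validate_registry <- function(reg) {
  required <- c(
    "name", "class", "label_state", "precursor_mz", "product_mz",
    "n_carbons", "n_labeled_methyls", "internal_standard", "acyl_group"
  )
  missing_cols <- setdiff(required, names(reg))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "registry is missing column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  reg <- as_tibble(reg)[required]
  reg$internal_standard <- as.character(reg$internal_standard)
  reg$internal_standard[!is.na(reg$internal_standard) &
    reg$internal_standard == ""] <- NA_character_

  dup <- reg$name[duplicated(reg$name)]
  if (length(dup) > 0) {
    abort(paste0(
      "duplicate analyte name(s) in registry: ",
      paste(unique(dup), collapse = ", ")
    ))
  }
  bad_class <- setdiff(unique(reg$class), .analyte_classes)
  if (length(bad_class) > 0) {
    abort(paste0("unknown analyte class: ", paste(bad_class, collapse = ", ")))
  }
  bad_label <- setdiff(unique(reg$label_state), .label_states)
  if (length(bad_label) > 0) {
    abort(paste0("unknown label state: ", paste(bad_label, collapse = ", ")))
  }
  bad_acyl <- setdiff(unique(reg$acyl_group), .acyl_groups)
  if (length(bad_acyl) > 0) {
    abort(paste0("unknown acyl group: ", paste(bad_acyl, collapse = ", ")))
  }

  expected <- unname(.label_methyls[reg$label_state])
  off <- reg$name[reg$n_labeled_methyls != expected]
  if (length(off) > 0) {
    abort(paste0(
      "label state and n_labeled_methyls disagree for: ",
      paste(off, collapse = ", "),
      " (D9 carries 3, D6 carries 2, D3 carries 1 deuterated methyl)"
    ))
  }

  bad_mz <- reg$name[!(reg$precursor_mz > reg$product_mz & reg$product_mz > 0)]
  if (length(bad_mz) > 0) {
    abort(paste0(
      "transition must satisfy precursor_mz > product_mz > 0 for: ",
      paste(bad_mz, collapse = ", ")
    ))
  }
  if (any(reg$n_carbons < 1)) {
    abort("n_carbons must be a positive count")
  }

  is_names <- registry_internal_standards(reg)
  need_is <- !(reg$name %in% is_names)
  no_link <- reg$name[need_is & is.na(reg$internal_standard)]
  if (length(no_link) > 0) {
    abort(paste0(
      "analyte(s) without an internal-standard link: ",
      paste(no_link, collapse = ", ")
    ))
  }
  unknown_is <- setdiff(
    reg$internal_standard[!is.na(reg$internal_standard)], reg$name
  )
  if (length(unknown_is) > 0) {
    abort(paste0(
      "internal standard(s) not present in registry: ",
      paste(unknown_is, collapse = ", ")
    ))
  }
  reg
}

#' Internal-standard analytes of a registry
#'
#' An analyte acts as an internal standard if it is referenced by another
#' analyte's `internal_standard` field or carries the `D4_IS` label state.
#'
#' @param reg A registry tibble.
#' @return Character vector of internal-standard analyte names.
#' @export
registry_internal_standards <- function(reg) {
  union(
    unique(reg$internal_standard[!is.na(reg$internal_standard)]),
    reg$name[reg$label_state == "D4_IS"]
  )
}
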