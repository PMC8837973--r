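#' Read a long-format SRM measurement table
#'
#' Expected columns: `animal_id`, `matrix` (one of liver, plasma, lung, LLF,
#' cerebrum, cerebellum), `analyte`, `ion_count` (arbitrary units, >= 0),
#' `dilution_factor` (>= 1) and `injected_fraction` (fraction of the whole
#' compartment represented by the analysed extract, in (0, 1]; 1 when the
#' extract covers the whole organ). Missing `dilution_factor` or
#' `injected_fraction` columns default to 1.
#'
#' @param path Delimited text file (`.csv` or `.tsv`) with a header row.
#' @param registry Optional registry tibble; when supplied, analyte names are
#'   checked against it and water-soluble analytes are rejected in lung lavage
#'   fluid (LLF), which the assay does not analyse for water-soluble
#'   components.
#' @return A validated measurement tibble.
#' @export
read_measurements <- function(path, registry = NULL) {
  tbl <- read_delimited(path, "measurement table")
  validate_measurements(tbl, registry)
}

#' Validate a measurement table
#'
#' @param measurements A data frame of SRM measurements (see
#'   [read_measurements()] for the column contract).
#' @inheritParams read_measurements
#' @return The measurement tibble with defaulted columns filled in.
#' @export
validate_measurements <- function(measurements, registry = NULL) {
  tbl <- as_tibble(measurements)
  if (nrow(tbl) == 0) {
    abort("measurement table is empty")
  }
  required <- c("animal_id", "matrix", "analyte", "ion_count")
  miss <- setdiff(required, names(tbl))
  if (length(miss) > 0) {
    abort(paste0(
      "measurement table is missing column(s): ", paste(miss, collapse = ", ")
    ))
  }
  if (!"dilution_factor" %in% names(tbl)) tbl$dilution_factor <- 1
  if (!"injected_fraction" %in% names(tbl)) tbl$injected_fraction <- 1

  fail_rows(tbl, !tbl$matrix %in% .matrices, "unknown matrix/organ name")
  fail_rows(
    tbl, !is.finite(tbl$ion_count) | tbl$ion_count < 0,
    "negative or non-finite ion_count"
  )
  fail_rows(
    tbl, !is.finite(tbl$dilution_factor) | tbl$dilution_factor < 1,
    "dilution_factor must be >= 1"
  )
  fail_rows(
    tbl,
    !is.finite(tbl$injected_fraction) | tbl$injected_fraction <= 0 |
      tbl$injected_fraction > 1,
    "injected_fraction must be in (0, 1]"
  )

  if (!is.null(registry)) {
    unknown <- setdiff(unique(tbl$analyte), registry$name)
    if (length(unknown) > 0) {
      abort(paste0(
        "analyte(s) not in registry: ", paste(unknown, collapse = ", ")
      ))
    }
    cls <- setNames(registry$class, registry$name)
    fail_rows(
      tbl, tbl$matrix == "LLF" & cls[tbl$analyte] == "water_soluble",
      "water-soluble analytes are not measured in LLF"
    )
  }
  tbl
}

#' Read an animal metadata table
#'
#' Expected columns: `animal_id`, `body_weight_g`, `time_point_h`, organ wet
#' weights `liver_mg`, `lung_mg`, `cerebrum_mg`, `cerebellum_mg`, and
#' optionally `dose_mg_per_kg` (default 50) and `sex`.
#'
#' @param path Delimited text file (`.csv` or `.tsv`) with a header row.
#' @return A validated tibble, one row per animal.
#' @export
read_animals <- function(path) {
  tbl <- read_delimited(path, "animal table")
  validate_animals(tbl)
}

#' Validate an animal metadata table
#'
#' @param animals A data frame of animal records (see [read_animals()]).
#' @return The validated tibble with `dose_mg_per_kg` defaulted to 50.
#' @export
validate_animals <- function(animals) {
  tbl <- as_tibble(animals)
  if (nrow(tbl) == 0) {
    abort("animal table is empty")
  }
  organ_cols <- c("liver_mg", "lung_mg", "cerebrum_mg", "cerebellum_mg")
  required <- c("animal_id", "body_weight_g", "time_point_h", organ_cols)
  miss <- setdiff(required, names(tbl))
  if (length(miss) > 0) {
    abort(paste0(
      "animal table is missing column(s): ", paste(miss, collapse = ", ")
    ))
  }
  if (!"dose_mg_per_kg" %in% names(tbl)) tbl$dose_mg_per_kg <- 50
  dup <- tbl$animal_id[duplicated(tbl$animal_id)]
  if (length(dup) > 0) {
    abort(paste0(
      "duplicate animal_id: ", paste(unique(dup), collapse = ", ")
    ))
  }
  fail_rows(
    tbl, !is.finite(tbl$body_weight_g) | tbl$body_weight_g <= 0,
    "body_weight_g must be > 0"
  )
  fail_rows(
    tbl, !is.finite(tbl$time_point_h) | tbl$time_point_h <= 0,
    "time_point_h must be > 0"
  )
  for (oc in organ_cols) {
    fail_rows(
      tbl, !is.finite(tbl[[oc]]) | tbl[[oc]] <= 0,
      paste0(oc, " must be > 0")
    )
  }
  fail_rows(
    tbl, !is.finite(tbl$dose_mg_per_kg) | tbl$dose_mg_per_kg <= 0,
    "dose_mg_per_kg must be > 0"
  )
  tbl
}

#' Write and read whole-compartment pool tables
#'
#' Pool tables are long tables of absolute amounts (nmol) per animal,
#' compartment and analyte; extra annotation columns (label state, class,
#' concentration) round-trip unchanged. Values are written at full precision
#' so a write-then-read cycle reproduces them exactly.
#'
#' @param pools A pool tibble with at least `animal_id`, `matrix`, `analyte`,
#'   `amount_nmol`.
#' @param path Output/input CSV path.
#' @return `write_pool_table()` returns `path` invisibly; `read_pool_table()`
#'   returns the validated pool tibble.
#' @export
write_pool_table <- function(pools, path) {
  pools <- validate_pools(pools)
  readr::write_csv(pools, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_pool_table
#' @export
read_pool_table <- function(path) {
  validate_pools(read_delimited(path, "pool table"))
}

#' Validate a pool table
#'
#' @param pools A data frame with `animal_id`, `matrix`, `analyte`,
#'   `amount_nmol` (>= 0) columns.
#' @return The validated tibble.
#' @export
validate_pools <- function(pools) {
  tbl <- as_tibble(pools)
  if (nrow(tbl) == 0) {
    abort("pool table is empty")
  }
  required <- c("animal_id", "matrix", "analyte", "amount_nmol")
  miss <- setdiff(required, names(tbl))
  if (length(miss) > 0) {
    abort(paste0(
      "pool table is missing column(s): ", paste(miss, collapse = ", ")
    ))
  }
  fail_rows(tbl, !tbl$matrix %in% .matrices, "unknown matrix/organ name")
  fail_rows(
    tbl, !is.finite(tbl$amount_nmol) | tbl$amount_nmol < 0,
    "amount_nmol must be >= 0"
  )
  tbl
}

# shared delimited reader: csv/tsv by extension, empty-file guard
read_delimited <- function(path, what) {
  if (!file.exists(path)) {
    abort(paste0(what, " file not found: ", path))
  }
  ext <- tolower(tools::file_ext(path))
  reader <- switch(ext,
    tsv = readr::read_tsv,
    readr::read_csv
  )
  tbl <- suppressWarnings(
    reader(path, show_col_types = FALSE, progress = FALSE)
  )
  if (nrow(tbl) == 0) {
    abort(paste0(what, " is empty: ", path))
  }
  tbl
}

# abort with offending row numbers when `bad` has any TRUE
fail_rows <- function(tbl, bad, msg) {
  bad[is.na(bad)] <- TRUE
  if (any(bad)) {
    rows <- which(bad)
    shown <- paste(head(rows, 10), collapse = ", ")
    if (length(rows) > 10) shown <- paste0(shown, ", ...")
    abort(paste0(msg, " (row ", shown, ")"))
  }
  invisible(tbl)
}
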