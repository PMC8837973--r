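#' @importFrom generics tidy glance
NULL

#' Tidy a transfer-rate fit
#'
#' @param x A `transfer_fit` from [fit_transfer_rate()].
#' @param ... Unused.
#' @return One-row tibble with `term`, `estimate`.
#' @export
tidy.transfer_fit <- function(x, ...) {
  tibble(term = "k_per_h", estimate = x$k)
}

#' One-line summary of a transfer-rate fit
#'
#' @param x A `transfer_fit`.
#' @param ... Unused.
#' @return One-row tibble with `k`, `rss`, `n_times`.
#' @export
glance.transfer_fit <- function(x, ...) {
  tibble(k = x$k, rss = x$rss, n_times = length(x$times))
}

#' Tidy a group comparison
#'
#' @param x A `group_comparison` from [compare_groups()].
#' @param ... Unused.
#' @return The pairwise comparison tibble.
#' @export
tidy.group_comparison <- function(x, ...) {
  as_tibble(unclass(x))
}

#' One-line summary of a group comparison
#'
#' @param x A `group_comparison`.
#' @param ... Unused.
#' @return One-row tibble with comparison counts and the family multiplier.
#' @export
glance.group_comparison <- function(x, ...) {
  tibble(
    n_comparisons = nrow(x),
    n_significant = sum(x$significant),
    n_families = attr(x, "n_families"),
    method = x$method[1]
  )
}

#' @export
generics::tidy

#' @export
generics::glance
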