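#' Percent change between two time points
#'
#' @param pool_t1 Pool at the earlier time (> 0).
#' @param pool_t2 Pool at the later time.
#' @return Percent change, 100 * (pool_t2 - pool_t1) / pool_t1.
#' @export
#' @examples
#' percent_change(1145, 647) # liver D9-PC, 1.5 h -> 6 h
percent_change <- function(pool_t1, pool_t2) {
  if (any(pool_t1 <= 0)) {
    abort("pool_t1 must be > 0")
  }
  100 * (pool_t2 - pool_t1) / pool_t1
}

#' Fold ratio between two pools
#'
#' @param a Numerator pool(s).
#' @param b Denominator pool(s) (> 0).
#' @return a / b.
#' @export
fold_ratio <- function(a, b) {
  if (any(b <= 0)) {
    abort("denominator must be > 0")
  }
  a / b
}

#' Acyl-subgroup composition profile
#'
#' Normalizes subgroup amounts (typically the polyunsaturated PC subgroups
#' C18:2, C20:4 and C22:6) to fractions of their total, per grouping unit.
#'
#' @param amounts Tibble with `acyl_group` and `amount_nmol`, plus optional
#'   grouping columns in `by`.
#' @param by Extra grouping columns.
#' @return Tibble with a `fraction` column per subgroup (fractions sum to 1
#'   within each group).
#' @export
subgroup_profile <- function(amounts, by = character()) {
  as_tibble(amounts) %>%
    group_by(across(all_of(c(by, "acyl_group")))) %>%
    summarise(amount_nmol = sum(.data$amount_nmol), .groups = "drop_last") %>%
    mutate(fraction = .data$amount_nmol / sum(.data$amount_nmol)) %>%
    ungroup()
}

#' Deviation of an observed profile from an equilibrium profile
#'
#' Compares subgroup fractions of a (typically D9-labeled) PC profile against
#' an equilibrium reference (the unlabeled PC composition pooled over all
#' animals). Reports per-subgroup deviations and the total absolute
#' deviation; a trajectory converging to equilibrium has a decreasing total
#' deviation over time.
#'
#' @param observed Tibble with `acyl_group` and `fraction` (see
#'   [subgroup_profile()]), plus optional grouping columns in `by`.
#' @param equilibrium Tibble with `acyl_group` and `fraction`.
#' @param by Extra grouping columns in `observed` (e.g. `time_h`).
#' @return Tibble with per-subgroup `deviation`
#'   (observed - equilibrium) and the per-group `total_abs_deviation`.
#' @export
profile_distance <- function(observed, equilibrium, by = character()) {
  eq <- as_tibble(equilibrium) %>%
    select("acyl_group", eq_fraction = "fraction")
  as_tibble(observed) %>%
    left_join(eq, by = "acyl_group") %>%
    mutate(deviation = .data$fraction - .data$eq_fraction) %>%
    group_by(across(all_of(by))) %>%
    mutate(total_abs_deviation = sum(abs(.data$deviation))) %>%
    ungroup()
}

#' Group comparisons with Tukey range test and Bonferroni family correction
#'
#' Two groups are compared with a two-tailed t test; three or more with
#' Tukey's honestly-significant-difference range test. The resulting
#' p-values are additionally multiplied by the number of analyte families
#' tested (`n_families`, Bonferroni across families; capped at 1), reported
#' alongside the raw within-family p-value. Significance threshold is 0.05.
#'
#' Two input modes are supported: raw per-animal values (a data frame with
#' `value` and `group` columns) or printed summary statistics (a data frame
#' with `group`, `mean`, `se`, `n`), for which pairwise Welch t tests with
#' SE-based degrees of freedom are used (flagged approximate).
#'
#' @param data Data frame in raw or summary form (see above).
#' @param n_families Number of analyte families tested (Bonferroni
#'   multiplier across families).
#' @return An object of class `group_comparison`: a tibble of pairwise
#'   comparisons with `estimate`, `statistic`, `df`, `p_value` (within
#'   family), `p_adj` (across families), `significant` and `method`.
#' @export
compare_groups <- function(data, n_families = 1) {
  tbl <- as_tibble(data)
  summary_mode <- all(c("group", "mean", "se", "n") %in% names(tbl)) &&
    !"value" %in% names(tbl)
  if (summary_mode) {
    if (any(tbl$n < 2)) {
      abort("each group needs n >= 2")
    }
    pairs <- utils::combn(seq_len(nrow(tbl)), 2, simplify = FALSE)
    res <- purrr::map_dfr(pairs, function(ij) {
      a <- tbl[ij[1], ]
      b <- tbl[ij[2], ]
      se2 <- a$se^2 + b$se^2
      tstat <- (a$mean - b$mean) / sqrt(se2)
      df <- se2^2 / (a$se^4 / (a$n - 1) + b$se^4 / (b$n - 1))
      tibble(
        comparison = paste(a$group, b$group, sep = " - "),
        estimate = a$mean - b$mean,
        statistic = tstat,
        df = df,
        p_value = 2 * pt(-abs(tstat), df),
        method = "welch_t_summary"
      )
    })
  } else {
    if (!all(c("value", "group") %in% names(tbl))) {
      abort(
        "data must have value+group columns (raw) or group+mean+se+n (summary)"
      )
    }
    tbl$group <- factor(tbl$group)
    sizes <- table(tbl$group)
    if (any(sizes < 2)) {
      abort("each group needs n >= 2")
    }
    if (nlevels(tbl$group) < 2) {
      abort("at least two groups are required")
    }
    if (nlevels(tbl$group) == 2) {
      lv <- levels(tbl$group)
      x <- tbl$value[tbl$group == lv[1]]
      y <- tbl$value[tbl$group == lv[2]]
      if (sd(x) == 0 && sd(y) == 0 && mean(x) == mean(y)) {
        res <- tibble(
          comparison = paste(lv[1], lv[2], sep = " - "),
          estimate = 0, statistic = 0, df = length(x) + length(y) - 2,
          p_value = 1, method = "t_test"
        )
      } else {
        tt <- t.test(x, y)
        res <- tibble(
          comparison = paste(lv[1], lv[2], sep = " - "),
          estimate = mean(x) - mean(y),
          statistic = unname(tt$statistic),
          df = unname(tt$parameter),
          p_value = tt$p.value,
          method = "t_test"
        )
      }
    } else {
      fit <- aov(value ~ group, data = tbl)
      tk <- TukeyHSD(fit)$group
      res <- tibble(
        comparison = gsub("-", " - ", rownames(tk), fixed = TRUE),
        estimate = tk[, "diff"],
        statistic = NA_real_,
        df = stats::df.residual(fit),
        p_value = tk[, "p adj"],
        method = "tukey_hsd"
      )
    }
  }
  res <- res %>%
    mutate(
      p_adj = pmin(1, .data$p_value * n_families),
      significant = .data$p_adj < 0.05
    )
  structure(res, class = c("group_comparison", class(res)),
    n_families = n_families
  )
}

#' Normality screen based on sample skewness and kurtosis
#'
#' Advisory omnibus screen: the Jarque-Bera statistic
#' JB = n/6 (S^2 + (K - 3)^2 / 4) is referred to a chi-squared distribution
#' with 2 degrees of freedom. Samples with n < 8 are flagged as having
#' insufficient n for a meaningful moment-based screen. The screen is
#' advisory only and gates no downstream analysis.
#'
#' @param x Numeric vector.
#' @param alpha Significance level (default 0.05).
#' @return A one-row tibble: `n`, `skewness`, `excess_kurtosis`,
#'   `statistic`, `p_value`, `pass` (NA when insufficient n) and `flag`.
#' @export
normality_screen <- function(x, alpha = 0.05) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8) {
    return(tibble(
      n = n, skewness = NA_real_, excess_kurtosis = NA_real_,
      statistic = NA_real_, p_value = NA_real_, pass = NA,
      flag = "insufficient_n"
    ))
  }
  m <- mean(x)
  s2 <- mean((x - m)^2)
  skew <- mean((x - m)^3) / s2^1.5
  kurt <- mean((x - m)^4) / s2^2
  jb <- n / 6 * (skew^2 + (kurt - 3)^2 / 4)
  p <- pchisq(jb, df = 2, lower.tail = FALSE)
  tibble(
    n = n, skewness = skew, excess_kurtosis = kurt - 3,
    statistic = jb, p_value = p, pass = p >= alpha, flag = "ok"
  )
}
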