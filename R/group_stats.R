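#' Wilcoxon signed-rank test for paired hippocampal measurements
#'
#' Two-sided paired test of left vs right (or ipsilateral vs contralateral)
#' hippocampal values. Zero differences are dropped before ranking (the
#' classical convention; `zero_method = "pratt"` keeps them in the ranking and
#' drops their ranks afterwards). The null distribution is exact when the
#' number of non-zero differences is at most 12 and their absolute values are
#' tie-free; otherwise a normal approximation with continuity correction is
#' used.
#'
#' @param paired_a,paired_b numeric vectors of equal length.
#' @param zero_method `"wilcox"` (drop zero differences) or `"pratt"`.
#' @param exact_max largest n for which the exact null is used.
#'
#' @return Tibble with `statistic` (V, sum of positive-difference ranks),
#'   `p_value`, `n` (differences used) and `method`.
#' @export
wilcoxon_signed_rank <- function(paired_a, paired_b,
                                 zero_method = c("wilcox", "pratt"),
                                 exact_max = 12) {
  zero_method <- match.arg(zero_method)
  if (length(paired_a) != length(paired_b)) abort("Paired vectors differ in length.")
  d <- as.numeric(paired_a) - as.numeric(paired_b)
  if (all(d == 0)) abort("All paired differences are zero: no information.")

  if (zero_method == "wilcox") {
    d <- d[d != 0]
    n <- length(d)
    exact <- n <= exact_max && !any(duplicated(abs(d)))
    ht <- suppressWarnings(wilcox.test(d, mu = 0, exact = exact, correct = TRUE))
    tibble::tibble(
      statistic = unname(ht$statistic), p_value = ht$p.value, n = n,
      method = if (exact) "exact" else "normal approximation"
    )
  } else {
    # Pratt: rank |d| including zeros, then discard the zero ranks.
    n <- length(d)
    r <- rank(abs(d))
    v <- sum(r[d > 0])
    nz <- d != 0
    ev <- sum(r[nz]) / 2
    varv <- sum(r[nz]^2) / 4
    z <- (v - ev) / sqrt(varv)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    tibble::tibble(statistic = v, p_value = p, n = sum(nz),
                   method = "pratt normal approximation")
  }
}

#' Mann-Whitney U test for two independent groups
#'
#' Two-sided rank-sum comparison, exact when the combined sample size is at
#' most `exact_max` and the data are tie-free, otherwise a normal
#' approximation with tie and continuity correction. The returned statistic
#' is U, the number of (a, b) pairs with `a > b` (ties one-half), so
#' `U / (n_a * n_b)` is the AUC of group membership against the value.
#'
#' @param group_a,group_b numeric vectors, both non-empty.
#' @param exact_max largest combined n for which the exact null is used.
#'
#' @return Tibble with `statistic` (U), `p_value`, `n_a`, `n_b`, `method`.
#' @export
mann_whitney_u <- function(group_a, group_b, exact_max = 12) {
  if (length(group_a) == 0L || length(group_b) == 0L) {
    abort("Both groups must be non-empty.")
  }
  n_a <- length(group_a)
  n_b <- length(group_b)
  exact <- (n_a + n_b) <= exact_max && !any(duplicated(c(group_a, group_b)))
  ht <- suppressWarnings(
    wilcox.test(group_a, group_b, exact = exact, correct = TRUE)
  )
  tibble::tibble(
    statistic = unname(ht$statistic), p_value = ht$p.value,
    n_a = n_a, n_b = n_b,
    method = if (exact) "exact" else "normal approximation"
  )
}

#' Left-vs-right hippocampal comparisons per group
#'
#' Runs the paired Wilcoxon signed-rank test of left vs right hippocampal
#' values within every group of a measures table, for the raw and z-scored
#' T2 and SUVR measurements. Alpha is 0.05 two-sided and no multiplicity
#' correction is applied.
#'
#' @param measures tibble from the pipeline (or [derive_asymmetry()]): needs
#'   `group` plus the `t2_*`, `suvr_*`, `z_*` hemisphere columns.
#'
#' @return Tibble with one row per group x measure: `group`, `measure`,
#'   `statistic`, `p_value`, `n`, `significant`.
#' @export
compare_hemispheres_by_group <- function(measures) {
  pairs <- tibble::tribble(
    ~measure, ~left, ~right,
    "t2", "t2_left", "t2_right",
    "suvr", "suvr_left", "suvr_right",
    "z_t2", "z_t2_left", "z_t2_right",
    "z_suvr", "z_suvr_left", "z_suvr_right"
  )
  pairs <- dplyr::filter(pairs, .data$left %in% names(measures) &
                           .data$right %in% names(measures))
  out <- purrr::map_dfr(split(measures, measures$group), function(g) {
    purrr::pmap_dfr(pairs, function(measure, left, right) {
      res <- tryCatch(
        wilcoxon_signed_rank(g[[left]], g[[right]]),
        error = function(e) tibble::tibble(
          statistic = NA_real_, p_value = NA_real_,
          n = nrow(g), method = "failed"
        )
      )
      dplyr::mutate(res, group = g$group[1], measure = measure, .before = 1)
    })
  })
  dplyr::mutate(out, significant = !is.na(.data$p_value) & .data$p_value < 0.05)
}

#' Asymmetry-index bar plot with control reference bands
#'
#' Per-patient bar plot of the two asymmetry indices, subjects ordered by
#' increasing SUVR asymmetry, with horizontal lines marking the central 95%
#' reference interval of the healthy-control asymmetries.
#'
#' @param measures patient measures tibble with `subject_id`, `group`,
#'   `ai_t2`, `ai_suvr`.
#' @param control_intervals optional named list with tibble entries `ai_t2`
#'   and `ai_suvr` from [control_reference_interval()].
#' @return A ggplot.
#' @export
plot_asymmetry_indices <- function(measures, control_intervals = NULL) {
  ord <- dplyr::arrange(measures, .data$ai_suvr)
  ord$subject_id <- factor(ord$subject_id, levels = ord$subject_id)
  long <- tidyr::pivot_longer(
    ord[c("subject_id", "group", "ai_t2", "ai_suvr")],
    c("ai_t2", "ai_suvr"),
    names_to = "modality", values_to = "ai"
  )
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$subject_id, .data$ai,
                                          fill = .data$group)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~modality, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "Asymmetry index (left - right, z-units)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, size = 6))
  if (!is.null(control_intervals)) {
    bands <- purrr::imap_dfr(control_intervals, function(iv, nm) {
      dplyr::mutate(iv, modality = nm)
    })
    bands <- tidyr::pivot_longer(bands[c("modality", "low", "high")],
                                 c("low", "high"), values_to = "bound")
    p <- p + ggplot2::geom_hline(
      data = bands, ggplot2::aes(yintercept = .data$bound),
      linetype = "dotted", colour = "grey30"
    )
  }
  p
}
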