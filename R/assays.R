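#' Transwell chemotaxis: percent migrated cells
#'
#' The transwell readout: `(number of cells in the bottom chamber / number
#' of cells seeded in the upper chamber) x 100`.
#'
#' Flow-cytometric counting at constant flow acquires only part of the
#' resuspension volume (commonly 150 of 200 µl); `volume_scale` rescales the
#' migrated count accordingly before the formula. It defaults to 1 (no
#' correction), since published percentages are routinely computed on the
#' acquired counts directly; pass `200/150` to extrapolate to the full
#' volume.
#'
#' @param n_migrated cells counted in the bottom chamber.
#' @param n_seeded cells seeded in the upper chamber (> 0).
#' @param volume_scale multiplicative correction applied to `n_migrated`
#'   (default 1).
#' @return percentage of seeded cells that migrated.
#' @examples
#' percent_migrated(25000, 100000)  # 25
#' @export
percent_migrated <- function(n_migrated, n_seeded, volume_scale = 1) {
  if (!is.numeric(n_seeded) || length(n_seeded) != 1L || !is.finite(n_seeded) ||
      n_seeded <= 0) {
    stop_usage("`n_seeded` must be a single positive count.")
  }
  if (!is.numeric(n_migrated) || length(n_migrated) != 1L ||
      !is.finite(n_migrated) || n_migrated < 0) {
    stop_usage("`n_migrated` must be a single non-negative count.")
  }
  if (volume_scale <= 0) stop_usage("`volume_scale` must be > 0.")
  eff <- n_migrated * volume_scale
  if (eff > n_seeded) {
    warn("migrated count exceeds seeded count; counting at constant flow can overcount.")
  }
  100 * eff / n_seeded
}

#' Chemotaxis fold change versus the untreated condition
#'
#' Ratio of the treated migration percentage to the untreated (spontaneous
#' migration) percentage.
#'
#' @param percent_treated,percent_untreated migration percentages; the
#'   untreated baseline must be > 0.
#' @return dimensionless fold change.
#' @examples
#' fold_change(20, 10)  # 2
#' @export
fold_change <- function(percent_treated, percent_untreated) {
  if (!is.numeric(percent_untreated) || length(percent_untreated) != 1L ||
      !is.finite(percent_untreated) || percent_untreated <= 0) {
    stop_undefined("untreated migration is zero or invalid; fold change is undefined.")
  }
  if (!is.numeric(percent_treated) || length(percent_treated) != 1L ||
      !is.finite(percent_treated) || percent_treated < 0) {
    stop_usage("`percent_treated` must be a single non-negative percentage.")
  }
  percent_treated / percent_untreated
}

#' Full chemotaxis result for one condition
#'
#' @inheritParams percent_migrated
#' @param percent_untreated optional untreated baseline percentage for the
#'   fold change.
#' @return one-row tibble: `n_seeded`, `n_migrated`, `percent_migrated`,
#'   `fold_change` (`NA` when no baseline is given).
#' @export
chemotaxis_result <- function(n_migrated, n_seeded, percent_untreated = NULL,
                              volume_scale = 1) {
  pm <- percent_migrated(n_migrated, n_seeded, volume_scale)
  fc <- if (is.null(percent_untreated)) NA_real_ else
    fold_change(pm, percent_untreated)
  tibble(n_seeded = n_seeded, n_migrated = n_migrated,
         percent_migrated = pm, fold_change = fc)
}
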