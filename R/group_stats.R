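#' Compare a metric between groups
#'
#' Statistical comparison of per-track metric values between groups, using
#' the tests standard in intravital imaging figure legends: Kruskal-Wallis
#' (omnibus over all groups), Welch's unequal-variance t-test, Mann-Whitney
#' (Wilcoxon rank-sum), or a seeded two-sample permutation test on the
#' difference of means. Pairwise tests are run for every pair of groups;
#' Kruskal-Wallis is a single omnibus test. No multiple-testing adjustment
#' is applied by default (single pairwise tests per panel being the field's
#' convention); Holm adjustment is available.
#'
#' If all values across all groups are identical the test is degenerate: a
#' warning is raised and p = 1 is reported.
#'
#' @param values_by_group named list mapping group label to a numeric vector
#'   of metric values (each group needs >= 2 finite values).
#' @param test `"kruskal_wallis"`, `"welch_t"`, `"mann_whitney"` or
#'   `"permutation"`.
#' @param adjustment `"none"` (default) or `"holm"`, applied across the
#'   pairwise p-values returned by one call.
#' @param n_perm number of resamples for the permutation test (>= 10000).
#' @param seed RNG seed for the permutation test.
#' @param metric optional metric name carried into the output.
#' @return tibble with one row per comparison: `metric`, `group1`, `group2`
#'   (`NA` for the omnibus test), `test`, `statistic`, `p_value`,
#'   `p_adjusted`, `n1`, `n2`, `adjustment`.
#' @examples
#' compare_groups(list(vehicle = c(5.1, 6.2, 4.8), treated = c(2.1, 2.4, 2.0)),
#'                test = "welch_t")
#' @export
compare_groups <- function(values_by_group,
                           test = c("kruskal_wallis", "welch_t",
                                    "mann_whitney", "permutation"),
                           adjustment = c("none", "holm"),
                           n_perm = 10000, seed = 1L, metric = NA_character_) {
  test <- match.arg(test)
  adjustment <- match.arg(adjustment)
  if (!is.list(values_by_group) || length(values_by_group) < 2 ||
      is.null(names(values_by_group)) || any(!nzchar(names(values_by_group)))) {
    stop_usage("`values_by_group` must be a named list with >= 2 groups.")
  }
  vals <- lapply(values_by_group, function(v) as.numeric(v[is.finite(v)]))
  short <- names(vals)[vapply(vals, length, integer(1)) < 2]
  if (length(short) > 0) {
    stop_usage(sprintf("group(s) with fewer than 2 finite values: %s",
                       paste(short, collapse = ", ")))
  }
  degenerate <- length(unique(unlist(vals))) == 1L
  if (degenerate) {
    warn("all values are identical across groups; test is degenerate (p = 1).")
  }

  if (test == "kruskal_wallis") {
    if (degenerate) {
      res <- tibble(metric = metric, group1 = NA_character_,
                    group2 = NA_character_, test = test, statistic = 0,
                    p_value = 1, n1 = sum(lengths(vals)), n2 = NA_real_)
    } else {
      kw <- stats::kruskal.test(vals)
      res <- tibble(metric = metric, group1 = NA_character_,
                    group2 = NA_character_, test = test,
                    statistic = unname(kw$statistic), p_value = kw$p.value,
                    n1 = sum(lengths(vals)), n2 = NA_real_)
    }
  } else {
    # order of input groups must not matter: iterate pairs in sorted label order
    labs <- sort(names(vals))
    pairs <- utils::combn(labs, 2, simplify = FALSE)
    res <- dplyr::bind_rows(lapply(pairs, function(pr) {
      a <- vals[[pr[1]]]
      b <- vals[[pr[2]]]
      pair_degen <- length(unique(c(a, b))) == 1L
      if (pair_degen) {
        stat <- 0
        p <- 1
        if (!degenerate) {
          warn(sprintf("values identical within pair %s vs %s; p = 1.",
                       pr[1], pr[2]))
        }
      } else if (test == "welch_t") {
        tt <- stats::t.test(a, b, var.equal = FALSE)
        stat <- unname(tt$statistic)
        p <- tt$p.value
      } else if (test == "mann_whitney") {
        wt <- stats::wilcox.test(a, b, exact = FALSE)
        stat <- unname(wt$statistic)
        p <- wt$p.value
      } else {
        pt <- permutation_test(a, b, n_perm = n_perm, seed = seed)
        stat <- pt$statistic
        p <- pt$p_value
      }
      tibble(metric = metric, group1 = pr[1], group2 = pr[2], test = test,
             statistic = stat, p_value = p,
             n1 = length(a), n2 = length(b))
    }))
  }
  res$p_adjusted <- if (adjustment == "holm") {
    stats::p.adjust(res$p_value, method = "holm")
  } else {
    res$p_value
  }
  res$adjustment <- adjustment
  res
}

#' Two-sample permutation test on the difference of means
#'
#' Monte-Carlo permutation test: group labels are reshuffled `n_perm` times
#' under a private seeded RNG stream and the two-sided p-value is
#' `(1 + #{|diff*| >= |diff|}) / (n_perm + 1)`.
#'
#' @param a,b numeric vectors.
#' @param n_perm number of resamples (>= 10000 enforced).
#' @param seed RNG seed.
#' @return list with `statistic` (observed mean difference) and `p_value`.
#' @export
permutation_test <- function(a, b, n_perm = 10000, seed = 1L) {
  if (n_perm < 10000) stop_usage("`n_perm` must be >= 10000.")
  a <- a[is.finite(a)]
  b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2) {
    stop_usage("both samples need >= 2 finite values.")
  }
  obs <- mean(a) - mean(b)
  pooled <- c(a, b)
  na <- length(a)
  with_private_seed(seed, {
    exceed <- 0L
    n <- length(pooled)
    for (i in seq_len(n_perm)) {
      idx <- sample.int(n, na)
      d <- mean(pooled[idx]) - mean(pooled[-idx])
      if (abs(d) >= abs(obs) - 1e-12) exceed <- exceed + 1L
    }
    list(statistic = obs, p_value = (1 + exceed) / (n_perm + 1))
  })
}

#' Origin-translated track data for flower plots
#'
#' Translates every T cell track so its first position is exactly (0, 0)
#' and discards z, producing the data behind a "flower plot" — all tracks
#' radiating from a common origin so that dispersion (displacement) can be
#' compared between groups at a glance.
#'
#' @param movie an [movie()].
#' @param min_frames keep tracks with at least this many positions
#'   (default 2).
#' @return tibble: `track_id`, `frame` (1-based within track), `dx`, `dy`.
#' @examples
#' m <- simulate_tracks(preset_config("vehicle_early", seed = 1))$movie
#' fp <- flower_plot_data(m)
#' head(fp)
#' @export
flower_plot_data <- function(movie, min_frames = 2) {
  stopifnot(inherits(movie, "ivm_movie"))
  trs <- movie_tracks(movie, labels = T_CELL_LABELS)
  trs <- trs[vapply(trs, nrow, integer(1)) >= min_frames]
  if (length(trs) == 0) stop_usage("no T cell track with enough positions.")
  dplyr::bind_rows(lapply(trs, function(tr) {
    tibble(track_id = attr(tr, "track_id"), frame = seq_len(nrow(tr)),
           dx = tr$x - tr$x[1], dy = tr$y - tr$y[1])
  }))
}
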