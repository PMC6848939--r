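#' Bhattacharyya distance between two Gaussian summaries
#'
#' Closed-form Bhattacharyya distance between two normal distributions
#' summarized by mean and standard deviation:
#' \deqn{D_B = \tfrac14 \ln\!\Big(\tfrac14\big(\tfrac{\sigma_p^2}{\sigma_m^2}
#' + \tfrac{\sigma_m^2}{\sigma_p^2} + 2\big)\Big) +
#' \tfrac14 \frac{(\mu_p - \mu_m)^2}{\sigma_p^2 + \sigma_m^2}}
#' (natural logarithm). It is zero iff the distributions are identical,
#' symmetric in its arguments, and invariant to a common affine
#' rescaling of both inputs — so it does not depend on measurement
#' units. It is the evaluation metric of choice here because predicted
#' samples (every canopy pixel) and manual samples (a few dozen
#' harvested plugs) have incomparable sizes: comparing distributions is
#' more appropriate than pairing values.
#'
#' @param p,m Either [gaussian_summary()] objects, or numeric means
#'   (in which case `sigma_p`, `sigma_m` supply the standard
#'   deviations; all vectorized).
#' @param sigma_p,sigma_m Standard deviations when `p`, `m` are numeric.
#' @return The distance(s), dimensionless, `>= 0`.
#' @export
#' @examples
#' bhattacharyya_distance(0, 2, sigma_p = 1, sigma_m = 1)  # 0.5
bhattacharyya_distance <- function(p, m, sigma_p = NULL, sigma_m = NULL) {
  if (inherits(p, "gaussian_summary")) { sigma_p <- p$sigma; p <- p$mu }
  if (inherits(m, "gaussian_summary")) { sigma_m <- m$sigma; m <- m$mu }
  if (is.null(sigma_p) || is.null(sigma_m)) {
    stop("standard deviations are required", call. = FALSE)
  }
  if (any(sigma_p <= 0) || any(sigma_m <= 0)) {
    stop("zero or negative variance: Bhattacharyya distance undefined",
         call. = FALSE)
  }
  vp <- sigma_p^2; vm <- sigma_m^2
  0.25 * log(0.25 * (vp / vm + vm / vp + 2)) +
    0.25 * (p - m)^2 / (vp + vm)
}

#' Compare predicted and manually measured trait distributions
#'
#' For every (rack, day) present on either side, summarizes the
#' predicted and measured values as Gaussians and computes the
#' Bhattacharyya distance between them. A (rack, day) with only one
#' side present is reported with `NA` distance (absent, not zero).
#'
#' @param predicted,measured Data frames with columns `rack_id`, `das`
#'   and the trait column named by `feature`.
#' @param feature Name of the trait column (e.g. `"height_mm"`).
#' @return A `comparison_report` tibble: `rack_id`, `das`, `feature`,
#'   `mu_pred`, `sd_pred`, `n_pred`, `mu_meas`, `sd_meas`, `n_meas`,
#'   `DB`. The attribute `"rationale"` records why distributions (not
#'   paired values) are compared.
#' @export
compare_to_ground_truth <- function(predicted, measured, feature) {
  for (d in list(predicted, measured)) {
    stopifnot(all(c("rack_id", "das", feature) %in% names(d)))
  }
  if (nrow(predicted) == 0L || nrow(measured) == 0L) {
    stop("both predicted and measured records must be non-empty",
         call. = FALSE)
  }
  side_summary <- function(d, suffix) {
    d |>
      dplyr::group_by(.data$rack_id, .data$das) |>
      dplyr::summarise(mu = mean(.data[[feature]]),
                       sd = stats::sd(.data[[feature]]),
                       n = dplyr::n(), .groups = "drop") |>
      dplyr::rename_with(\(x) paste0(x, suffix), c("mu", "sd", "n"))
  }
  out <- dplyr::full_join(side_summary(predicted, "_pred"),
                          side_summary(measured, "_meas"),
                          by = c("rack_id", "das"))
  valid <- !is.na(out$mu_pred) & !is.na(out$mu_meas) &
    !is.na(out$sd_pred) & !is.na(out$sd_meas) &
    out$sd_pred > 0 & out$sd_meas > 0
  out$feature <- feature
  out$DB <- NA_real_
  out$DB[valid] <- bhattacharyya_distance(
    out$mu_pred[valid], out$mu_meas[valid],
    out$sd_pred[valid], out$sd_meas[valid])
  out <- out |>
    dplyr::arrange(.data$rack_id, .data$das) |>
    dplyr::relocate("feature", .after = "das")
  attr(out, "rationale") <- paste(
    "Predicted samples (all canopy pixels) and manual samples (a few",
    "harvested plugs per day) have incomparable sizes; a distance",
    "between probability distributions is therefore compared instead",
    "of paired values.")
  class(out) <- c("comparison_report", class(out))
  out
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report> feature '%s', %d (rack, DAS) cells\n",
              x$feature[1], nrow(x)))
  NextMethod()
}

#' Write a comparison report as CSV
#'
#' @param report A [compare_to_ground_truth()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_comparison_csv <- function(report, path) {
  utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  invisible(path)
}

#' Read manual ground-truth measurements
#'
#' The manual protocol records, per harvested plug: the plant height,
#' the weight of all its leaves, the leaf count and the plug weight.
#'
#' @param path CSV with columns `rack_id`, `das`, `plug_id`,
#'   `height_mm`, `leaves_weight_g`, `n_leaves`, `plug_weight_g`.
#' @return A tibble.
#' @export
read_manual_measurements <- function(path) {
  d <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  need <- c("rack_id", "das", "plug_id", "height_mm", "leaves_weight_g",
            "n_leaves", "plug_weight_g")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop("manual measurements CSV missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  d
}

#' Density-class discrimination summary
#'
#' Descriptive comparison of the two planting densities across the
#' three phenotype features (height, leaf area, leaf weight): per-class
#' marginal histograms, all pairwise feature scatter tables, and a
#' per-feature class-separation statistic (standardized mean
#' difference, |mean high - mean low| / pooled SD).
#'
#' @param records Data frame with columns `density_class` (`"high"` /
#'   `"low"`), `height_mm`, `leaf_area_mm2`, `leaf_weight_g` (plus any
#'   metadata).
#' @param bins Histogram bin count, default 20.
#' @return List with `separation` (tibble: feature, mean/sd per class,
#'   `smd`), `histograms` (tibble: feature, density_class, bin
#'   midpoints, counts) and `pairs` (tibble of the three feature pairs
#'   in long form, ready for scatter plotting).
#' @export
density_discrimination_summary <- function(records, bins = 20L) {
  feats <- c("height_mm", "leaf_area_mm2", "leaf_weight_g")
  stopifnot(all(c("density_class", feats) %in% names(records)))
  cls <- unique(records$density_class)
  if (length(cls) < 2L) {
    stop("both density classes must be present", call. = FALSE)
  }
  long <- records |>
    tidyr::pivot_longer(dplyr::all_of(feats), names_to = "feature",
                        values_to = "value") |>
    dplyr::filter(is.finite(.data$value))
  separation <- long |>
    dplyr::group_by(.data$feature, .data$density_class) |>
    dplyr::summarise(mu = mean(.data$value), sd = stats::sd(.data$value),
                     n = dplyr::n(), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "density_class",
                       values_from = c("mu", "sd", "n")) |>
    dplyr::mutate(
      pooled_sd = sqrt(((.data$n_high - 1) * .data$sd_high^2 +
                          (.data$n_low - 1) * .data$sd_low^2) /
                         pmax(.data$n_high + .data$n_low - 2, 1)),
      smd = abs(.data$mu_high - .data$mu_low) / .data$pooled_sd)
  histograms <- long |>
    dplyr::group_by(.data$feature) |>
    dplyr::group_modify(function(d, key) {
      br <- seq(min(d$value), max(d$value), length.out = bins + 1L)
      if (br[1] == br[length(br)]) br <- br[1] + c(-0.5, 0.5)
      d |>
        dplyr::group_by(.data$density_class) |>
        dplyr::group_modify(function(dd, k2) {
          h <- graphics::hist(dd$value, breaks = br, plot = FALSE)
          tibble::tibble(mid = h$mids, count = h$counts)
        }) |>
        dplyr::ungroup()
    }) |>
    dplyr::ungroup()
  combos <- utils::combn(feats, 2)
  pairs <- purrr::map_dfr(seq_len(ncol(combos)), function(i) {
    tibble::tibble(
      feature_x = combos[1, i], feature_y = combos[2, i],
      x = records[[combos[1, i]]], y = records[[combos[2, i]]],
      density_class = records$density_class)
  })
  list(separation = separation, histograms = histograms, pairs = pairs)
}
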