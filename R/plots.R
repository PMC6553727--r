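#' Bland-Altman plot of one method against CHM
#'
#' Scatter of paired difference vs paired mean with a solid bias line and
#' dashed 95% limits-of-agreement lines.
#'
#' @param data Flat cohort table with `post_*` columns.
#' @param method Method name (without the `post_` prefix).
#' @param reference Reference name (default `"CHM"`).
#' @param loa_multiplier LOA multiplier (default 1.96).
#'
#' @return A ggplot object.
#' @export
plot_bland_altman <- function(data, method, reference = "CHM",
                              loa_multiplier = 1.96) {
  xcol <- paste0("post_", method)
  ycol <- paste0("post_", reference)
  for (cl in c(xcol, ycol)) {
    if (!cl %in% names(data)) {
      abort(sprintf("cohort table is missing column(s): %s", cl),
            class = "keratrace_missing_column")
    }
  }
  x <- data[[xcol]]
  y <- data[[ycol]]
  ba <- bland_altman(x, y, loa_multiplier)
  df <- tibble::tibble(avg = (x + y) / 2, diff = x - y)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$avg, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = ba$bias, linetype = "solid") +
    ggplot2::geom_hline(yintercept = c(ba$loa_low, ba$loa_high),
                        linetype = "dashed") +
    ggplot2::labs(
      x = sprintf("Mean of %s and %s (D)", method, reference),
      y = sprintf("%s - %s (D)", method, reference),
      title = sprintf("%s vs %s: bias %.2f D, 95%% LOA (%.2f, %.2f) D",
                      method, reference, ba$bias, ba$loa_low, ba$loa_high)) +
    ggplot2::theme_minimal()
}

#' Bland-Altman panel for a report
#'
#' One Bland-Altman facet per method, drawn from the cohort table the
#' report was built on.
#'
#' @param object A `keratrace_report`.
#' @param data The flat cohort table the report was built from.
#' @param methods Which methods to show (default: all non-CHM rows).
#' @param ... Unused.
#'
#' @return A ggplot object.
#' @method autoplot keratrace_report
#' @export
autoplot.keratrace_report <- function(object, data, methods = NULL, ...) {
  methods <- methods %||% setdiff(object$table2$method, "CHM")
  chm_v <- data$post_CHM
  df <- purrr::map_dfr(methods, function(nm) {
    v <- data[[paste0("post_", nm)]]
    tibble::tibble(method = nm, avg = (v + chm_v) / 2, diff = v - chm_v)
  })
  lines <- object$table2[object$table2$method %in% methods, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$avg, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::geom_hline(data = lines,
                        ggplot2::aes(yintercept = .data$bias), linetype = "solid") +
    ggplot2::geom_hline(data = lines,
                        ggplot2::aes(yintercept = .data$loa_low), linetype = "dashed") +
    ggplot2::geom_hline(data = lines,
                        ggplot2::aes(yintercept = .data$loa_high), linetype = "dashed") +
    ggplot2::facet_wrap(~method, scales = "free") +
    ggplot2::labs(x = "Mean of method and CHM (D)", y = "Method - CHM (D)") +
    ggplot2::theme_minimal()
}

#' Radial power profile of a power map
#'
#' Meridian-averaged ray-traced power as a function of radius, a quick
#' visual check of the center-to-periphery power distribution.
#'
#' @param object A `power_map`.
#' @param ... Unused.
#'
#' @return A ggplot object.
#' @method autoplot power_map
#' @export
autoplot.power_map <- function(object, ...) {
  prof <- dplyr::summarise(dplyr::group_by(tibble::as_tibble(object), .data$r_mm),
                           power_D = mean(.data$power_D, na.rm = TRUE),
                           .groups = "drop")
  ggplot2::ggplot(prof, ggplot2::aes(x = .data$r_mm, y = .data$power_D)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Radius from center (mm)",
                  y = "Meridian-mean ray-traced power (D)") +
    ggplot2::theme_minimal()
}
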