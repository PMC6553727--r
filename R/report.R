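default_table2_methods <- function() {
  c("Km", "TNP", "EKR_4.0", "EKR_4.5",
    as.vector(outer(
      c("TCRP_pupil_zone", "TCRP_pupil_ring", "TCRP_apex_zone", "TCRP_apex_ring"),
      c(2, 4, 6), paste, sep = "_")),
    "K_Haigis", "K_Shammas")
}

#' Method-vs-CHM agreement report for a cohort
#'
#' Builds the two summary analyses of the pipeline from a flat cohort
#' table (see [cohort_to_table()]):
#'
#' * `table2`: one row per keratometric method — cohort mean and SD, bias
#'   against CHM, Bonferroni-adjusted paired p, 95% limits of agreement
#'   and Pearson correlation with CHM.  The CHM row itself is included
#'   with empty comparison columns; the two additive modified TCRP
#'   variants are appended.
#' * `table1`: TCRP mean +/- SD for the four centration/geometry variants
#'   at every diameter, with a per-diameter repeated-measures omnibus F
#'   and p across the four variants.
#'
#' Degenerate correlations (zero variance in a method after exact
#' equality) are reported as NA with `degenerate = TRUE`, never as 1.
#'
#' @param tbl Flat cohort table with `post_*` keratometry columns.
#' @param methods Table-2 method names (without the `post_` prefix);
#'   default: Km, TNP, EKR 4.0/4.5, the four TCRP variants at 2/4/6 mm,
#'   K_Haigis, K_Shammas.
#' @param diameters Table-1 diameters (default 1:8).
#' @param loa_multiplier LOA multiplier (default 1.96).
#'
#' @return An object of class `keratrace_report`: list with `table2`,
#'   `table1`, `metadata` (n, seed, config hash, Bonferroni family size
#'   m, alpha).
#' @export
#'
#' @examples
#' \donttest{
#' cohort <- generate_cohort(cohort_config(n = 10, seed = 3))
#' rep <- build_report(cohort_to_table(cohort))
#' tidy(rep)
#' }
build_report <- function(tbl, methods = default_table2_methods(),
                         diameters = 1:8, loa_multiplier = 1.96) {
  mods <- c("modTCRP_pupil_zone_4", "modTCRP_apex_zone_4")
  need <- paste0("post_", c("CHM", methods, mods))
  missing_cols <- setdiff(need, names(tbl))
  if (length(missing_cols) > 0) {
    abort(sprintf("cohort table is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "keratrace_missing_column")
  }
  chm_v <- tbl$post_CHM
  all_methods <- c(methods, mods)
  m_family <- length(all_methods)

  # omnibus RM-ANOVA and Bonferroni-adjusted paired contrasts vs CHM
  mat <- as.matrix(tbl[, paste0("post_", c("CHM", all_methods))])
  colnames(mat) <- c("CHM", all_methods)
  rm_res <- repeated_measures_compare(mat, reference = "CHM")

  row_for <- function(name) {
    if (name == "CHM") {
      return(tibble::tibble(
        method = "CHM", mean = mean(chm_v), sd = sd(chm_v),
        bias = NA_real_, sd_diff = NA_real_, p_adjusted = NA_real_,
        loa_low = NA_real_, loa_high = NA_real_,
        pearson_r = NA_real_, pearson_p = NA_real_, degenerate = FALSE))
    }
    v <- tbl[[paste0("post_", name)]]
    ba <- bland_altman(v, chm_v, loa_multiplier)
    degen <- sd(v) == 0 || sd(chm_v) == 0 || sd(v - chm_v) == 0
    pr <- if (degen) tibble::tibble(r = NA_real_, p = NA_real_) else pearson(v, chm_v)
    padj <- rm_res$pairwise$p_adjusted[rm_res$pairwise$method == name]
    tibble::tibble(
      method = name, mean = mean(v), sd = sd(v),
      bias = ba$bias, sd_diff = ba$sd_diff, p_adjusted = padj,
      loa_low = ba$loa_low, loa_high = ba$loa_high,
      pearson_r = pr$r, pearson_p = pr$p, degenerate = degen)
  }
  table2 <- purrr::map_dfr(c("CHM", all_methods), row_for)

  # Table-1 analog: four TCRP variants by diameter
  variants <- c("TCRP_pupil_zone", "TCRP_pupil_ring",
                "TCRP_apex_zone", "TCRP_apex_ring")
  table1 <- purrr::map_dfr(diameters, function(d) {
    cols <- paste0("post_", variants, "_", d)
    cols <- cols[cols %in% names(tbl)]
    sub <- as.matrix(tbl[, cols])
    colnames(sub) <- sub("^post_", "", cols)
    omni <- if (ncol(sub) >= 2 && !anyNA(sub)) {
      repeated_measures_compare(sub, reference = colnames(sub)[1])
    } else list(F = NA_real_, p = NA_real_)
    tibble::tibble(
      diameter_mm = d,
      variant = colnames(sub),
      mean = colMeans(sub),
      sd = apply(sub, 2, sd),
      F_omnibus = omni$F, p_omnibus = omni$p)
  })

  cfg <- attr(tbl, "cohort_config")
  metadata <- list(
    n = nrow(tbl),
    seed = attr(tbl, "seed"),
    config_hash = rlang::hash(cfg),
    bonferroni_m = m_family,
    loa_multiplier = loa_multiplier,
    alpha = 0.05,
    omnibus_F = rm_res$F, omnibus_p = rm_res$p)

  structure(list(table2 = table2, table1 = table1, metadata = metadata),
            class = "keratrace_report")
}

#' @export
print.keratrace_report <- function(x, ...) {
  cat(sprintf("<keratrace_report> n = %s eyes, %d methods vs CHM (Bonferroni m = %d)\n",
              x$metadata$n, nrow(x$table2) - 1, x$metadata$bonferroni_m))
  cat(sprintf("omnibus RM-ANOVA: F = %.3f, p = %.3g\n",
              x$metadata$omnibus_F, x$metadata$omnibus_p))
  print(x$table2, n = nrow(x$table2))
  invisible(x)
}

#' Tidy a keratrace report
#'
#' @param x A `keratrace_report`.
#' @param table Which block: `"table2"` (method-vs-CHM agreement, default)
#'   or `"table1"` (TCRP by diameter).
#' @param ... Unused.
#'
#' @return A tibble.
#' @method tidy keratrace_report
#' @export
tidy.keratrace_report <- function(x, table = c("table2", "table1"), ...) {
  switch(match.arg(table), table2 = x$table2, table1 = x$table1)
}

#' One-row summary of a keratrace report
#'
#' @param x A `keratrace_report`.
#' @param ... Unused.
#'
#' @return A one-row tibble with cohort size, seed, omnibus test and the
#'   best-agreeing method (narrowest LOA width).
#' @method glance keratrace_report
#' @export
glance.keratrace_report <- function(x, ...) {
  t2 <- x$table2[!is.na(x$table2$bias), ]
  widths <- t2$loa_high - t2$loa_low
  tibble::tibble(
    n = x$metadata$n,
    seed = x$metadata$seed %||% NA_integer_,
    bonferroni_m = x$metadata$bonferroni_m,
    omnibus_F = x$metadata$omnibus_F,
    omnibus_p = x$metadata$omnibus_p,
    best_method = t2$method[which.min(widths)],
    best_loa_width = min(widths))
}
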