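# smallest p value reported for degenerate (zero-variance) paired contrasts
P_EPS <- 1e-15

#' Bland-Altman agreement statistics
#'
#' Bias (mean of x - y), sample SD of the paired differences (n - 1
#' denominator) and the 95% limits of agreement bias +/- 1.96 * SD.
#'
#' @param x,y Paired measurements, diopters (equal length >= 2, no NA).
#' @param loa_multiplier LOA multiplier (default 1.96).
#'
#' @return A one-row tibble: `bias`, `sd_diff`, `loa_low`, `loa_high`.
#' @export
#'
#' @examples
#' bland_altman(c(37.5, 38.0, 38.5), c(37.0, 37.0, 37.0))
bland_altman <- function(x, y, loa_multiplier = 1.96) {
  if (length(x) != length(y)) {
    abort("x and y must have equal length", class = "keratrace_domain_error")
  }
  if (length(x) < 2) abort("need n >= 2 pairs", class = "keratrace_domain_error")
  if (anyNA(x) || anyNA(y)) {
    abort("missing pairs are not allowed", class = "keratrace_domain_error")
  }
  d <- x - y
  bias <- mean(d)
  s <- sd(d)
  tibble::tibble(bias = bias, sd_diff = s,
                 loa_low = bias - loa_multiplier * s,
                 loa_high = bias + loa_multiplier * s)
}

#' Pearson correlation with two-sided p value
#'
#' @param x,y Numeric vectors, equal length >= 3, both with nonzero
#'   variance.
#'
#' @return A one-row tibble: `r`, `p`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    abort("need equal-length vectors with n >= 3", class = "keratrace_domain_error")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    abort("zero variance: correlation undefined", class = "keratrace_zero_variance")
  }
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  tibble::tibble(r = unname(ct$estimate), p = ct$p.value)
}

#' Repeated-measures comparison of methods against a reference
#'
#' Within-subject one-way repeated-measures ANOVA over the method columns
#' (omnibus F and p), plus pairwise paired t tests of every non-reference
#' method against the reference column, Bonferroni-multiplied by the
#' number of pairwise tests and capped at 1.  A degenerate paired
#' contrast (zero SD of differences, nonzero mean) is reported with the
#' documented epsilon floor `1e-15`; zero mean with zero SD gives p = 1.
#'
#' @param mat Numeric matrix or data frame, eyes x methods, complete,
#'   with column names; >= 3 eyes and >= 2 methods.
#' @param reference Name of the reference column (default `"CHM"` if
#'   present, else the first column).
#'
#' @return A list: `F`, `p` (omnibus), and `pairwise`, a tibble with
#'   `method`, `mean_diff`, `p_raw`, `p_adjusted`, and attribute `m`
#'   (the Bonferroni family size).
#' @export
repeated_measures_compare <- function(mat, reference = NULL) {
  mat <- as.matrix(mat)
  if (is.null(colnames(mat))) colnames(mat) <- paste0("m", seq_len(ncol(mat)))
  if (ncol(mat) < 2 || nrow(mat) < 3) {
    abort("need >= 2 methods and >= 3 eyes", class = "keratrace_domain_error")
  }
  if (anyNA(mat)) abort("incomplete matrix", class = "keratrace_domain_error")
  reference <- reference %||%
    (if ("CHM" %in% colnames(mat)) "CHM" else colnames(mat)[1])
  if (!reference %in% colnames(mat)) {
    abort(sprintf("reference column '%s' not found", reference),
          class = "keratrace_domain_error")
  }

  long <- data.frame(
    subject = factor(rep(seq_len(nrow(mat)), ncol(mat))),
    method = factor(rep(colnames(mat), each = nrow(mat)),
                    levels = colnames(mat)),
    value = as.vector(mat))
  # within-subject one-way RM-ANOVA: subject as the error stratum;
  # a zero between-method sum of squares short-circuits to F = 0 so the
  # identical-columns case is not left to floating-point noise in aov
  grand <- mean(mat)
  ss_method <- nrow(mat) * sum((colMeans(mat) - grand)^2)
  ss_total <- sum((mat - grand)^2)
  if (ss_method <= 1e-12 * max(1, ss_total)) {
    Fval <- 0; pval <- 1
  } else {
    fit <- aov(value ~ method + Error(subject), data = long)
    tab <- summary(fit)[["Error: Within"]][[1]]
    i <- which(trimws(rownames(tab)) == "method")
    Fval <- tab[i, "F value"]
    pval <- tab[i, "Pr(>F)"]
    if (is.na(Fval)) { Fval <- 0; pval <- 1 }
  }

  others <- setdiff(colnames(mat), reference)
  m <- length(others)
  pw <- purrr::map_dfr(others, function(nm) {
    d <- mat[, nm] - mat[, reference]
    if (sd(d) < .Machine$double.eps) {
      p_raw <- if (abs(mean(d)) < .Machine$double.eps) 1 else P_EPS
    } else {
      p_raw <- t.test(mat[, nm], mat[, reference], paired = TRUE)$p.value
      p_raw <- max(p_raw, P_EPS)
    }
    tibble::tibble(method = nm, mean_diff = mean(d), p_raw = p_raw,
                   p_adjusted = min(1, p_raw * m))
  })
  attr(pw, "m") <- m
  list(F = unname(Fval), p = unname(pval), pairwise = pw)
}

#' Shapiro-Wilk normality annotation
#'
#' @param values Numeric vector, 3 <= n <= 5000, nonzero variance.
#'
#' @return A one-row tibble: `W`, `p`.
#' @export
normality_check <- function(values) {
  n <- length(values)
  if (n < 3 || n > 5000) {
    abort("Shapiro-Wilk requires 3 <= n <= 5000", class = "keratrace_domain_error")
  }
  if (sd(values) == 0) {
    abort("zero variance: normality test undefined",
          class = "keratrace_zero_variance")
  }
  sw <- shapiro.test(values)
  tibble::tibble(W = unname(sw$statistic), p = sw$p.value)
}
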