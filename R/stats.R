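#' Interpretation band for a correlation coefficient
#'
#' Evans' (1996) descriptive bands on |rho|: <0.20 very weak, 0.20-0.39
#' weak, 0.40-0.59 moderate, 0.60-0.79 strong, >= 0.80 very strong.
#'
#' @param rho correlation coefficient.
#' @return character band label.
#' @export
correlation_band <- function(rho) {
  cut(abs(rho), breaks = c(-Inf, 0.2, 0.4, 0.6, 0.8, Inf), right = FALSE,
      labels = c("very weak", "weak", "moderate", "strong",
                 "very strong")) |> as.character()
}

#' Spearman rank correlation with significance
#'
#' rho is the Pearson correlation of average ranks (ties get average
#' ranks). The two-sided p-value uses the t approximation
#' `t = rho * sqrt((n-2)/(1-rho^2))` by default; for n <= 8 an exact
#' permutation p-value (all n! permutations) is available.
#'
#' @param x,y equal-length numeric vectors, n >= 4, finite values.
#' @param method `"t_approx"` (default) or `"exact_permutation"`
#'   (n <= 8 only).
#' @return object of class `correlation_result`: `rho`, `p_value`, `n`,
#'   `method`, `band`.
#' @export
spearman <- function(x, y, method = c("t_approx", "exact_permutation")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 4) stop("need n >= 4", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("values must be finite", call. = FALSE)
  if (diff(range(x)) == 0 || diff(range(y)) == 0)
    stop("undefined correlation: constant series", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (method == "exact_permutation") {
    if (n > 8) stop("exact permutation limited to n <= 8", call. = FALSE)
    perms <- e1071::permutations(n)
    rhos <- apply(perms, 1, function(p) stats::cor(rx, ry[p]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
  }
  structure(list(rho = rho, p_value = p, n = n, method = method,
                 band = correlation_band(rho)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> rho = %.4f (%s), p = %.4g, n = %d (%s)\n",
              x$rho, x$band, x$p_value, x$n, x$method))
  invisible(x)
}

# Two-way crossed ANOVA mean squares for a complete subjects x raters
# matrix: rows (subjects), columns (raters), residual.
icc_mean_squares <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sse <- sum((m - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  list(MSR = ssr / (n - 1), MSC = ssc / (k - 1),
       MSE = sse / ((n - 1) * (k - 1)), n = n, k = k)
}

#' Two-way mixed-effects absolute-agreement ICC
#'
#' ICC(A,1) (single measurement) and ICC(A,k) (mean of k ratings) under
#' the two-way mixed-effects model with absolute agreement, estimated
#' from the two-way ANOVA decomposition (MSR between subjects, MSC
#' between raters, MSE residual):
#' \deqn{ICC(A,1) = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE)/n)}
#' \deqn{ICC(A,k) = (MSR - MSE) / (MSR + (MSC - MSE)/n)}
#' 95% confidence intervals follow the F-distribution method of McGraw &
#' Wong, with the average-measures bounds obtained from the
#' single-measure bounds via the Spearman-Brown step-up.
#'
#' @param data complete numeric matrix, subjects in rows (n >= 3),
#'   raters in columns (k >= 2).
#' @param form `"A1_single"` or `"Ak_average"`.
#' @param conf confidence level (default 0.95).
#' @return object of class `icc_result`: `icc`, `ci_low`, `ci_high`,
#'   `form`, `n_subjects`, `k_raters`, `MSR`, `MSC`, `MSE`.
#' @export
icc_two_way_mixed_absolute <- function(data,
                                       form = c("A1_single", "Ak_average"),
                                       conf = 0.95) {
  form <- match.arg(form)
  m <- as.matrix(data)
  if (any(is.na(m))) stop("missing cells not allowed", call. = FALSE)
  n <- nrow(m); k <- ncol(m)
  if (n < 3 || k < 2) stop("need >= 3 subjects and >= 2 raters",
                           call. = FALSE)
  ms <- icc_mean_squares(m)
  MSR <- ms$MSR; MSC <- ms$MSC; MSE <- ms$MSE
  if (MSR < .Machine$double.eps)
    warning("zero between-subject variance: ICC degenerate",
            call. = FALSE)
  denom1 <- MSR + (k - 1) * MSE + k * (MSC - MSE) / n
  icc1 <- (MSR - MSE) / denom1
  icck <- (MSR - MSE) / (MSR + (MSC - MSE) / n)

  alpha <- 1 - conf
  fj <- MSC / MSE
  a_ <- k * icc1 / (n * (1 - icc1))
  b_ <- 1 + k * icc1 * (n - 1) / (n * (1 - icc1))
  v_num <- (a_ * fj + b_)^2
  v_den <- a_^2 * fj^2 / (k - 1) + b_^2 / (n - 1)
  v <- v_num / v_den
  f_u <- stats::qf(1 - alpha / 2, n - 1, v)
  f_l <- stats::qf(1 - alpha / 2, v, n - 1)
  lo1 <- n * (MSR - f_u * MSE) /
    (f_u * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
  hi1 <- n * (f_l * MSR - MSE) /
    (k * MSC + (k * n - k - n) * MSE + n * f_l * MSR)
  if (form == "A1_single") {
    icc <- icc1; lo <- lo1; hi <- hi1
  } else {
    icc <- icck
    lo <- lo1 * k / (1 + (k - 1) * lo1)
    hi <- hi1 * k / (1 + (k - 1) * hi1)
  }
  structure(list(icc = icc, ci_low = lo, ci_high = hi, form = form,
                 n_subjects = n, k_raters = k,
                 MSR = MSR, MSC = MSC, MSE = MSE, conf = conf),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("<icc_result %s> ICC = %.3f, %g%% CI [%.3f, %.3f] (n=%d, k=%d)\n",
              x$form, x$icc, 100 * x$conf, x$ci_low, x$ci_high,
              x$n_subjects, x$k_raters))
  invisible(x)
}

#' Correlation panel: BMD category volumes vs days and deformation
#'
#' Spearman correlation of every BMD category's volume series against
#' days after surgery and, when a deformation series is supplied, against
#' Xd, Yd and Zd. Results are flagged significant at p < 0.05 with no
#' multiplicity adjustment (set `adjust = "BH"` for Benjamini-Hochberg).
#' Constant category columns are flagged undefined and excluded from the
#' very-strong count.
#'
#' @param volume_table a `bmd_volume_table` (needs `days` and `cat*`
#'   columns).
#' @param series optional `deformation_series` with matching scan keys.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return object of class `correlation_panel`: data.frame `panel`
#'   (category, against, rho, p_value, band, significant, defined) and
#'   `n_very_strong_vs_days` (count of categories with rho > 0.8 vs
#'   days).
#' @export
correlation_panel <- function(volume_table, series = NULL,
                              adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  cats <- grep("^cat\\d+$", names(volume_table), value = TRUE)
  against <- list(days = volume_table$days)
  if (!is.null(series)) {
    st <- series$table
    key <- match(volume_table$days, st$days)
    if (any(is.na(key)))
      stop("scan key mismatch between volume table and deformation series",
           call. = FALSE)
    against$Xd <- st$Xd[key]
    against$Yd <- st$Yd[key]
    against$Zd <- st$Zd[key]
  }
  rows <- list()
  for (a in names(against)) for (cc in cats) {
    v <- volume_table[[cc]]
    ok <- diff(range(v)) > 0
    if (ok) {
      r <- spearman(against[[a]], v)
      rows[[length(rows) + 1]] <- data.frame(
        category = as.integer(sub("cat", "", cc)), against = a,
        rho = r$rho, p_value = r$p_value, band = r$band, defined = TRUE)
    } else {
      rows[[length(rows) + 1]] <- data.frame(
        category = as.integer(sub("cat", "", cc)), against = a,
        rho = NA_real_, p_value = NA_real_, band = NA_character_,
        defined = FALSE)
    }
  }
  panel <- do.call(rbind, rows)
  if (adjust == "BH")
    panel$p_value <- stats::ave(panel$p_value, panel$against,
                                FUN = function(p) stats::p.adjust(p, "BH"))
  panel$significant <- !is.na(panel$p_value) & panel$p_value < 0.05
  vd <- panel[panel$against == "days" & panel$defined, ]
  structure(list(panel = panel,
                 n_very_strong_vs_days =
                   sum(vd$rho > 0.8 & vd$significant)),
            class = "correlation_panel")
}

#' @export
print.correlation_panel <- function(x, ...) {
  cat(sprintf(
    "<correlation_panel> %d tests; %d categories very strong vs days\n",
    nrow(x$panel), x$n_very_strong_vs_days))
  print(x$panel, digits = 3)
  invisible(x)
}
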