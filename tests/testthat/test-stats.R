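# explicit sum-of-squares ANOVA oracle for the ICC estimators
icc_oracle <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  SSR <- k * sum((rowMeans(m) - grand)^2)
  SSC <- n * sum((colMeans(m) - grand)^2)
  SST <- sum((m - grand)^2)
  SSE <- SST - SSR - SSC
  MSR <- SSR / (n - 1); MSC <- SSC / (k - 1)
  MSE <- SSE / ((n - 1) * (k - 1))
  list(A1 = (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n),
       Ak = (MSR - MSE) / (MSR + (MSC - MSE) / n),
       MSR = MSR, MSC = MSC, MSE = MSE)
}

test_that("monotone series give rho of +1 and -1", {
  x <- c(1, 4, 9, 16, 25, 36)
  up <- spearman(x, exp(x / 10))
  expect_equal(up$rho, 1)
  expect_identical(up$band, "very strong")
  down <- spearman(x, -x^3)
  expect_equal(down$rho, -1)
})

test_that("spearman is invariant under strictly monotone transforms", {
  set.seed(41)
  x <- rnorm(12); y <- rnorm(12)
  base <- spearman(x, y)
  expect_equal(spearman(exp(x), y)$rho, base$rho, tolerance = 1e-12)
  expect_equal(spearman(x, y^3 + 5 * y)$rho, base$rho, tolerance = 1e-12)
  expect_equal(spearman(x, exp(y))$p_value, base$p_value,
               tolerance = 1e-12)
})

test_that("spearman handles ties with average ranks, matching cor.test", {
  x <- c(1, 2, 2, 3, 4, 5, 5, 6)
  y <- c(2, 1, 4, 3, 6, 5, 8, 7)
  r <- spearman(x, y)
  ref <- suppressWarnings(cor.test(x, y, method = "spearman"))
  expect_equal(r$rho, unname(ref$estimate), tolerance = 1e-12)
})

test_that("degenerate spearman inputs error", {
  expect_error(spearman(1:3, 1:3), "n >= 4")
  expect_error(spearman(rep(1, 5), 1:5), "constant")
  expect_error(spearman(1:5, c(1, 2, NA, 4, 5)), "finite")
})

test_that("exact permutation p agrees with the t approximation for n <= 8", {
  set.seed(43)
  for (i in 1:5) {
    x <- rnorm(7); y <- 0.8 * x + rnorm(7, 0, 0.6)
    ex <- spearman(x, y, method = "exact_permutation")
    tt <- spearman(x, y, method = "t_approx")
    expect_equal(ex$rho, tt$rho, tolerance = 1e-12)
    expect_lt(abs(ex$p_value - tt$p_value), 0.12)
    # exact p is a valid permutation tail probability
    expect_gte(ex$p_value, 1 / factorial(7))
    expect_lte(ex$p_value, 1)
  }
  expect_error(spearman(rnorm(9), rnorm(9), method = "exact_permutation"),
               "n <= 8")
})

test_that("exact permutation p matches full enumeration on a tiny case", {
  x <- c(3, 1, 4, 2, 5)
  y <- c(2, 1, 5, 3, 4)
  ex <- spearman(x, y, method = "exact_permutation")
  # independent enumeration with a different mechanism
  perms <- as.matrix(expand.grid(rep(list(1:5), 5)))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 5), ]
  rhos <- apply(perms, 1, function(p) cor(rank(x), rank(y)[p]))
  expect_equal(ex$p_value,
               mean(abs(rhos) >= abs(cor(rank(x), rank(y))) - 1e-12),
               tolerance = 1e-12)
})

test_that("ICC matches the brute-force ANOVA oracle on a hand matrix", {
  m <- matrix(c(9, 2, 5, 8,
                6, 1, 3, 2,
                8, 4, 6, 8,
                7, 1, 2, 6,
                10, 5, 6, 9), nrow = 5, byrow = TRUE)[, c(1, 2, 4)]
  o <- icc_oracle(m)
  a1 <- icc_two_way_mixed_absolute(m, "A1_single")
  ak <- icc_two_way_mixed_absolute(m, "Ak_average")
  expect_equal(a1$icc, o$A1, tolerance = 1e-9)
  expect_equal(ak$icc, o$Ak, tolerance = 1e-9)
  expect_equal(a1$MSR, o$MSR, tolerance = 1e-9)
  expect_equal(a1$MSE, o$MSE, tolerance = 1e-9)
  expect_lte(a1$ci_low, a1$icc)
  expect_gte(a1$ci_high, a1$icc)
})

test_that("ICC matches the oracle on random small matrices (property)", {
  set.seed(44)
  for (i in 1:20) {
    n <- sample(4:8, 1)
    m <- matrix(rnorm(n * 3, sd = 2) + rep(rnorm(n, sd = 3), 3), n, 3)
    o <- icc_oracle(m)
    a1 <- icc_two_way_mixed_absolute(m, "A1_single")
    ak <- icc_two_way_mixed_absolute(m, "Ak_average")
    expect_equal(a1$icc, o$A1, tolerance = 1e-9)
    expect_equal(ak$icc, o$Ak, tolerance = 1e-9)
    if (a1$icc > 0) expect_gte(ak$icc, a1$icc - 1e-12)
  }
})

test_that("identical raters give ICC 1 with zero residual", {
  v <- c(3, 7, 1, 9, 5)
  m <- cbind(v, v, v)
  r <- icc_two_way_mixed_absolute(m, "A1_single")
  expect_equal(r$icc, 1)
  expect_equal(r$MSE, 0)
})

test_that("ICC recovers a known reliability of 0.8 at n = 200", {
  set.seed(45)
  n <- 200; k <- 3
  subj <- rnorm(n, sd = sqrt(0.8))
  m <- matrix(rep(subj, k), n, k) + matrix(rnorm(n * k, sd = sqrt(0.2)),
                                           n, k)
  r <- icc_two_way_mixed_absolute(m, "A1_single")
  expect_equal(r$icc, 0.8, tolerance = 0.05)
  expect_lt(r$ci_low, r$icc)
  expect_gt(r$ci_high, r$icc)
})

test_that("ICC input validation", {
  m <- matrix(rnorm(9), 3, 3)
  m[1, 1] <- NA
  expect_error(icc_two_way_mixed_absolute(m), "missing cells")
  expect_error(icc_two_way_mixed_absolute(matrix(rnorm(4), 2, 2)),
               ">= 3 subjects")
  flat <- matrix(rep(c(1, 2, 3), each = 4), 4, 3)
  expect_warning(icc_two_way_mixed_absolute(flat), "degenerate")
})

test_that("correlation panel over the shipped longitudinal table", {
  vt <- followup_bmd_volumes()
  panel <- correlation_panel(vt)
  vs_days <- panel$panel[panel$panel$against == "days", ]
  expect_equal(nrow(vs_days), 10)
  expect_equal(panel$n_very_strong_vs_days, 6)
  top <- vs_days$rho[vs_days$category == 10]
  expect_gt(top, 0.800)
  expect_equal(top, 0.9247, tolerance = 1e-3)
  # oracle: Pearson on average ranks, independent of spearman()
  oracle <- cor(rank(vt$days), rank(vt$cat10))
  expect_equal(top, oracle, tolerance = 1e-12)
})

test_that("constant category columns are flagged undefined, not counted", {
  vt <- followup_bmd_volumes()
  vt$cat1 <- 1.5
  panel <- correlation_panel(vt)
  row <- panel$panel[panel$panel$category == 1 &
                       panel$panel$against == "days", ]
  expect_false(row$defined)
  expect_true(is.na(row$rho))
  expect_equal(panel$n_very_strong_vs_days, 6)
})

test_that("panel joins a deformation series and flags significance", {
  vt <- followup_bmd_volumes()
  set.seed(46)
  recs <- lapply(seq_len(nrow(vt)), function(i)
    measure_deformation(c(rnorm(1), rnorm(1), 54 - 0.005 * vt$days[i] +
                            rnorm(1, 0, 0.5)),
                        c(0, 0, 0), scan_id = vt$scan_id[i],
                        days_after_surgery = vt$days[i]))
  series <- build_series(recs)
  panel <- correlation_panel(vt, series)
  expect_setequal(unique(panel$panel$against),
                  c("days", "Xd", "Yd", "Zd"))
  expect_equal(nrow(panel$panel), 40)
  # BH adjustment only raises p-values
  raw <- panel$panel$p_value
  adj <- correlation_panel(vt, series, adjust = "BH")$panel$p_value
  expect_true(all(adj >= raw - 1e-12, na.rm = TRUE))
})

test_that("evans bands split at 0.2/0.4/0.6/0.8", {
  expect_identical(correlation_band(c(0.1, -0.25, 0.45, -0.7, 0.95)),
                   c("very weak", "weak", "moderate", "strong",
                     "very strong"))
})
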