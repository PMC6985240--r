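test_that("noise-free 4PL parameters are recovered to high precision", {
  doses <- 10^seq(-4, 0, length.out = 8)
  y <- 0 + (1 - 0) / (1 + (doses / 0.02)^1)
  fit <- fit_4pl(doses, y)
  expect_equal(fit$ic50, 0.02, tolerance = 1e-6)
  expect_equal(fit$hill, 1, tolerance = 1e-6)
  expect_equal(fit$top, 1, tolerance = 1e-6)
  expect_equal(fit$bottom, 0, tolerance = 1e-6)
  expect_false(fit$no_dose_effect)
})

test_that("seeded noisy 4PL recovers IC50 within 10% across magnitudes", {
  # truths spanning realistic single-agent IC50 magnitudes (3e-4 .. 60)
  for (truth_ic50 in c(0.000322, 0.0216, 1, 63.4)) {
    set.seed(1000 + round(log10(truth_ic50) * 10))
    doses <- rep(truth_ic50 * 10^seq(-2.1, 2.1, length.out = 8), each = 3)
    y <- 1 / (1 + (doses / truth_ic50)^1.3) + rnorm(length(doses), 0, 0.03)
    fit <- fit_4pl(doses, y)
    expect_lt(abs(fit$ic50 - truth_ic50) / truth_ic50, 0.10,
              label = sprintf("ic50 truth %g", truth_ic50))
  }
})

test_that("flat data is flagged as having no dose effect", {
  doses <- 10^seq(-3, 1, length.out = 8)
  fit <- fit_4pl(doses, rep(0.98, 8))
  expect_true(fit$no_dose_effect)
  expect_true(is.na(fit$ic50))
  expect_error(predict(fit, 1), class = "qpop_validation_error")
})

test_that("4PL fit is equivariant under dose-unit rescaling", {
  set.seed(4)
  doses <- rep(10^seq(-3, 1, length.out = 8), each = 2)
  y <- 1 / (1 + (doses / 0.05)^2) + rnorm(length(doses), 0, 0.01)
  f1 <- fit_4pl(doses, y)
  f2 <- fit_4pl(doses * 1000, y) # uM -> nM
  expect_equal(f2$ic50 / f1$ic50, 1000, tolerance = 1e-4)
  expect_equal(f2$hill, f1$hill, tolerance = 1e-4)
})

test_that("fit_4pl validates its inputs", {
  expect_error(fit_4pl(c(1, 2, 3, 4), c(1, 1, 1, 1)),
               regexp = "5 distinct", class = "qpop_validation_error")
  expect_error(fit_4pl(c(-1, 1, 2, 3, 4), rep(1, 5)),
               class = "qpop_validation_error")
})

test_that("median-effect fit is exact on exact median-effect data", {
  # (Dm = 1, m = 1): fa at D = Dm is exactly 0.5
  D <- c(0.1, 0.3, 1, 3, 10)
  fa <- (D / 1)^1 / (1 + (D / 1)^1)
  fit <- fit_median_effect(D, fa)
  expect_equal(fit$Dm, 1, tolerance = 1e-12)
  expect_equal(fit$m, 1, tolerance = 1e-12)
  expect_equal(dose_at_fa(fit, 0.5), fit$Dm)

  # (Dm = 0.5, m = 2) at 6 doses, against a hand-rolled regression oracle
  D <- 0.5 * 2^seq(-2.5, 2.5, 1)
  fa <- (D / 0.5)^2 / (1 + (D / 0.5)^2)
  x <- log(D); y <- log(fa / (1 - fa))
  m_oracle <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  Dm_oracle <- exp(-(mean(y) - m_oracle * mean(x)) / m_oracle)
  fit2 <- fit_median_effect(D, fa)
  expect_equal(fit2$m, m_oracle, tolerance = 1e-12)
  expect_equal(fit2$Dm, Dm_oracle, tolerance = 1e-12)
  expect_equal(fit2$m, 2, tolerance = 1e-10)
  expect_equal(fit2$r, 1, tolerance = 1e-12)
})

test_that("median-effect fit excludes boundary points and errors when empty", {
  D <- c(0.1, 1, 10, 100)
  expect_warning(fit_median_effect(D, c(0.2, 0.5, 0.8, 1.0)), "excluding")
  expect_error(
    suppressWarnings(fit_median_effect(D, rep(0.999999999, 4) + 1e-9)),
    class = "qpop_validation_error"
  )
})

test_that("sham self-combination has CI = 1 at every effect level", {
  # one agent 'combined with itself': doses d and D-d of the same drug,
  # identical single-agent fits -> Loewe additivity identity
  D <- 2^seq(-3, 3)
  fa <- (D / 1.5)^1.7 / (1 + (D / 1.5)^1.7)
  me <- fit_median_effect(D, fa)
  split <- 0.3
  ci <- combination_index(list(me, me),
                          cbind(split * D, (1 - split) * D), fa)
  expect_true(all(abs(ci$CI - 1) <= 1e-9))
  expect_true(all(ci$verdict == "additive"))
})

test_that("the generated Loewe alpha is recovered as the CI, noise-free", {
  for (alpha in c(0.5, 1, 2)) {
    truth <- hill_combo_truth(c(0.02, 0.0005), hills = c(1, 1.5),
                              loewe_alpha = alpha, noise_sd = 0)
    sim <- simulate_combo_series(truth, n_points = 9)
    fits <- lapply(names(sim$singles), function(nm) {
      df <- sim$singles[[nm]]
      fit_median_effect(df$dose, fa_from_viability(df$response), label = nm)
    })
    ci <- combination_index(fits, as.matrix(sim$combo[, 1:2]),
                            fa_from_viability(sim$combo$response))
    interior <- ci$fa > 0.01 & ci$fa < 0.99
    expect_true(all(abs(ci$CI[interior] - alpha) < 1e-6),
                label = sprintf("alpha = %g", alpha))
    if (alpha == 0.5) expect_true(all(ci$verdict[interior] == "synergy"))
    if (alpha == 2) expect_true(all(ci$verdict[interior] == "antagonism"))
  }
})

test_that("CI is monotone in the generator's interaction parameter", {
  mean_ci <- vapply(c(0.4, 0.8, 1.2, 2), function(alpha) {
    truth <- hill_combo_truth(c(0.02, 0.0005), loewe_alpha = alpha, noise_sd = 0)
    sim <- simulate_combo_series(truth, n_points = 7)
    fits <- lapply(names(sim$singles), function(nm) {
      df <- sim$singles[[nm]]
      fit_median_effect(df$dose, fa_from_viability(df$response), label = nm)
    })
    ci <- combination_index(fits, as.matrix(sim$combo[, 1:2]),
                            fa_from_viability(sim$combo$response))
    mean(ci$CI[ci$fa > 0.1 & ci$fa < 0.9])
  }, numeric(1))
  expect_true(all(diff(mean_ci) > 0))
})

test_that("a left-shifted combination curve yields CI < 1 at all tested fa", {
  # fixture shaped like a clinical follow-up synergy experiment: IC50s at
  # realistic magnitudes and a synergistic combination (curve shifted left
  # relative to both singles) -> CI < 1 across effect levels
  truth <- hill_combo_truth(c(0.0216, 0.000322), hills = c(1.2, 1),
                            labels = c("bortezomib", "panobinostat"),
                            loewe_alpha = 0.4, noise_sd = 0)
  sim <- simulate_combo_series(truth, n_points = 8)
  fits <- lapply(names(sim$singles), function(nm) {
    df <- sim$singles[[nm]]
    fit_median_effect(df$dose, fa_from_viability(df$response), label = nm)
  })
  ci <- combination_index(fits, as.matrix(sim$combo[, 1:2]),
                          fa_from_viability(sim$combo$response))
  keep <- ci$fa > 0.01 & ci$fa < 0.99
  expect_true(all(ci$CI[keep] < 1))
})

test_that("CI points at fa = 0 or 1 are skipped with a warning", {
  D <- 2^seq(-3, 3)
  fa <- (D / 1)^1 / (1 + D)
  me <- fit_median_effect(D, fa)
  expect_warning(
    ci <- combination_index(list(me, me), cbind(D / 2, D / 2), c(fa[-7], 1)),
    "skipping"
  )
  expect_equal(nrow(ci), 6)
})

test_that("response surface maps behave like the quadratic they sample", {
  p <- tiny_panel(3)
  # only b_12 < 0: minimum at the high-high corner
  s <- surface_truth(p, beta0 = 1, beta_int = c(-0.2, 0, 0), noise_sd = 0)$surface
  rsm <- response_surface_map(s, c("druga", "drugb"), resolution = 11)
  best <- which(rsm$viability == min(rsm$viability), arr.ind = TRUE)
  expect_equal(unname(best[1, ]), c(11, 11))

  # additive surface: zero cross second-difference everywhere on the grid
  s2 <- surface_truth(p, beta0 = 1, beta_lin = c(-0.3, -0.2, 0),
                      beta_quad = c(0.05, 0.02, 0), noise_sd = 0)$surface
  g <- response_surface_map(s2, c("druga", "drugb"), resolution = 6)$viability
  cross_dd <- g[-1, -1] - g[-1, -6] - g[-6, -1] + g[-6, -6]
  expect_true(all(abs(cross_dd) < 1e-12))

  # resolution 2: exactly the four corners
  r2 <- response_surface_map(s, c("druga", "drugb"), resolution = 2)
  expect_equal(dim(r2$viability), c(2, 2))
  expect_equal(r2$x, c(0, 2))

  expect_error(response_surface_map(s, c("druga", "nope")),
               class = "qpop_validation_error")
  expect_error(response_surface_map(s, c("druga", "drugb"), resolution = 1),
               class = "qpop_validation_error")
})

test_that("measured two-drug grids are bilinearly interpolated", {
  g <- expand.grid(dose_a = c(0, 1, 2), dose_b = c(0, 1, 2))
  g$response <- 1 - 0.2 * g$dose_a - 0.1 * g$dose_b # bilinear in each cell
  rsm <- response_surface_map(g, c("A", "B"), resolution = 5)
  expect_equal(
    rsm$grid$viability,
    1 - 0.2 * rsm$grid$dose_a - 0.1 * rsm$grid$dose_b,
    tolerance = 1e-12
  )
})
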