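test_that("mean residue ellipticity follows the conversion formula", {
  expect_equal(mean_residue_ellipticity(20, mre_params(1000, 11, 1, 0.1)),
               2000)
  # linear in theta, inverse-linear in c and pl
  set.seed(51)
  for (i in 1:20) {
    p <- mre_params(mw = runif(1, 500, 5000),
                    n_residues = sample(2:60, 1),
                    conc_mg_ml = runif(1, 0.1, 2),
                    pathlength_cm = runif(1, 0.05, 1))
    th <- runif(1, -50, 50)
    base <- mean_residue_ellipticity(th, p)
    expect_equal(mean_residue_ellipticity(2 * th, p), 2 * base)
    p2 <- mre_params(p$mw, p$n_residues, 2 * p$conc_mg_ml, p$pathlength_cm)
    expect_equal(mean_residue_ellipticity(th, p2), base / 2)
    p3 <- mre_params(p$mw, p$n_residues, p$conc_mg_ml, 2 * p$pathlength_cm)
    expect_equal(mean_residue_ellipticity(th, p3), base / 2)
  }
  expect_error(mre_params(1000, 1, 1, 0.1), "n_residues >= 2")
})

test_that("cd_features computes subtraction, 222/208 ratio, and melt curve", {
  w <- seq(190, 260, by = 1)
  s5 <- cd_spectrum(w, -100 - (w - 215)^2 / 10, temperature_c = 5)
  s75 <- cd_spectrum(w, -50 - (w - 215)^2 / 20, temperature_c = 75)
  feats <- cd_features(list(s75, s5))  # order by temperature internally
  expect_equal(feats$subtraction$delta, s5$mre - s75$mre)
  expect_equal(feats$melt$normalized[1], 1.0)

  # identical spectra -> all-zero subtraction
  feats0 <- cd_features(list(s5, cd_spectrum(w, s5$ellipticity_mdeg, 75)))
  expect_true(all(feats0$subtraction$delta == 0))

  # the printed arithmetic example: -30000 / -25000 at 222/208
  flat <- function(temp, v222, v208) {
    e <- rep(-1000, length(w)); e[w == 222] <- v222; e[w == 208] <- v208
    cd_spectrum(w, e, temp)
  }
  f <- cd_features(list(flat(5, -30000, -25000), flat(75, -1000, -1000)))
  expect_equal(unname(f$ratio_222_208[1]), 1.2)

  expect_error(cd_features(list(s5, cd_spectrum(w + 0.5, s5$mre, 75))),
               "common wavelength grid")
  coarse <- seq(190, 260, by = 5)  # no grid point within 1 nm of 208
  expect_error(
    cd_features(list(cd_spectrum(coarse, coarse * 0 - 1, 5),
                     cd_spectrum(coarse, coarse * 0 - 2, 75))),
    "within 1 nm")
})

test_that("FRAP double normalization sets pre-bleach to 1 and cancels drift", {
  g <- gen_frap_trace(noise_sd = 0)
  norm <- frap_normalize(g$trace)
  pre <- seq_len(g$trace$n_prebleach)
  expect_equal(mean(norm$normalized[pre]), 1)

  # shared multiplicative decay cancels exactly
  gd <- gen_frap_trace(noise_sd = 0, shared_decay_tau = 200)
  norm_d <- frap_normalize(gd$trace)
  expect_equal(norm_d$normalized, norm$normalized, tolerance = 1e-12)
  fit <- frap_normalize_fit(g$trace)
  fit_d <- frap_normalize_fit(gd$trace)
  expect_equal(fit_d$plateau, fit$plateau, tolerance = 1e-6)
})

test_that("noiseless FRAP fit recovers the programmed half-time and mobile fraction", {
  g <- gen_frap_trace(tau_s = 24.28, f0 = 0.1, plateau = 0.802,
                      noise_sd = 0)
  fit <- frap_normalize_fit(g$trace)
  expect_equal(fit$t_half_s, 16.83, tolerance = 0.01)
  expect_equal(fit$mobile_fraction, 0.78, tolerance = 0.01)
  expect_lt(fit$residual_rms, 1e-6)
  expect_length(fit$flags, 0L)
})

test_that("a non-recovering trace is flagged", {
  n <- 60
  t <- seq(0, by = 1, length.out = n)
  bleached <- c(rep(100, 3), 100 * (0.5 - 0.002 * seq_len(n - 3)))
  fit <- frap_normalize_fit(frap_trace(t, bleached,
                                       cbind(rep(90, n), rep(110, n))))
  expect_true("no_recovery" %in% fit$flags)
})

test_that("luciferase normalization fixes the control mean at exactly 1", {
  set.seed(61)
  for (i in 1:10) {
    n <- sample(8:24, 1)
    groups <- sample(c("control", "treated"), n, replace = TRUE,
                     prob = c(0.5, 0.5))
    groups[1:2] <- c("control", "treated")
    renilla <- rlnorm(n, log(1e5), 0.3)
    firefly <- ifelse(groups == "treated", 0.7, 1) * renilla *
      rlnorm(n, 0, 0.05)
    out <- luciferase_normalize(firefly, renilla, groups)
    expect_equal(mean(out[groups == "control"]), 1, tolerance = 1e-12)
    # scale invariance
    out2 <- luciferase_normalize(2 * firefly, 2 * renilla, groups)
    expect_equal(out2, out, tolerance = 1e-12)
  }
  expect_error(luciferase_normalize(c(1, 1), c(1, 0), c("control", "t")),
               "well 2")
  expect_error(luciferase_normalize(c(1, 1), c(1, 1), c("a", "b"),
                                    control_group = "control"), "empty")
})

test_that("treated wells at a programmed fraction of control recover it", {
  # construction embedding the reported repression value 0.79
  renilla <- rep(1e5, 8)
  firefly <- c(rep(2e5, 4), rep(2e5 * 0.79, 4))
  groups <- rep(c("control", "treated"), each = 4)
  out <- luciferase_normalize(firefly, renilla, groups)
  expect_equal(unique(out[groups == "treated"]), 0.79, tolerance = 1e-12)
})

test_that("condensate areas normalize relative to cell area and control", {
  expect_equal(condensate_relative_area(10, 100)$relative, 0.10)
  out <- condensate_relative_area(0.05 * 200, 200, control_mean = 0.20)
  expect_equal(out$normalized, 0.25)
  # pair constructed with normalized treated value 0.24 vs control 1
  ctrl <- condensate_relative_area(30, 100, control_mean = 0.30)
  trt <- condensate_relative_area(0.24 * 0.30 * 100, 100,
                                  control_mean = 0.30)
  expect_equal(ctrl$normalized, 1)
  expect_equal(trt$normalized, 0.24)
  expect_error(condensate_relative_area(1, 0), "positive")
})

test_that("cochlear landmark ratios are distance ratios", {
  lm <- data.frame(
    label = rep(c("cochlear_width", "cochlear_height",
                  "basicranium_width"), each = 2),
    x = c(0, 1, 0, 0, 0, 4), y = c(0, 0, 0, 1, 0, 0),
    z = c(0, 0, 0, 0, 0, 0))
  r <- cochlear_ratios(lm)
  expect_equal(r$cw_over_bw, 0.25)
  expect_equal(r$height_over_width, 1.0)
  expect_error(cochlear_ratios(lm[-1, ]), "exactly twice")
  lm0 <- lm; lm0[lm0$label == "basicranium_width", c("x", "y", "z")] <- 0
  expect_error(cochlear_ratios(lm0), "zero denominator")
})

test_that("a synthetic chiropteran landmark panel stays in the plausible CW/BW envelope", {
  set.seed(62)
  ratios <- replicate(16, {
    cw <- runif(1, 0.13, 0.37)  # programmed CW/BW inside the reported range
    bw <- runif(1, 5, 12)
    theta <- runif(1, 0, pi)
    lm <- data.frame(
      label = rep(c("cochlear_width", "cochlear_height",
                    "basicranium_width"), each = 2),
      x = c(0, cw * bw * cos(theta), 0, 0, 0, bw),
      y = c(0, cw * bw * sin(theta), 0, cw * bw * 0.8, 0, 0),
      z = 0)
    cochlear_ratios(lm)$cw_over_bw
  })
  expect_true(all(ratios >= 0.13 & ratios <= 0.37))
})
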