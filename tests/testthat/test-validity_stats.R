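fake_fit <- function(trend = c("rising", "flat"), converged = TRUE,
                     n = 40) {
  # an intake_lmm with an exactly known trend statistic: |residual|
  # increasing in fitted gives Spearman rho 1; constant |residual| is the
  # degenerate case reported as 0
  trend <- match.arg(trend)
  structure(list(converged = converged,
                 fitted = seq_len(n),
                 residuals = if (trend == "rising") seq_len(n) else rep(2, n),
                 weights = rep(1, n),
                 period_means = c(ivfr1 = 0, recall = 0, ivfr2 = 0),
                 vcov = diag(3)),
            class = "intake_lmm")
}

test_that("Bland-Altman bias, limits and trend screen", {
  r <- bland_altman(c(10, 20, 30), c(8, 16, 24))
  expect_equal(r$bias, 4)
  expect_equal(r$spearman_rho, 1)
  expect_equal(r$loa_low, 4 - 1.96 * sd(c(2, 4, 6)))
  expect_equal(r$loa_high, 4 + 1.96 * sd(c(2, 4, 6)))

  # identical pairs: degenerate, rho reported as 0 with a flag
  r0 <- bland_altman(c(5, 6, 7, 8), c(5, 6, 7, 8))
  expect_equal(r0$bias, 0)
  expect_equal(c(r0$loa_low, r0$loa_high), c(0, 0))
  expect_true(r0$rho_degenerate)
  expect_equal(r0$spearman_rho, 0)

  # constant difference: sd(diff) = 0, flagged
  rc <- bland_altman(c(10, 20, 30), c(5, 15, 25))
  expect_equal(rc$bias, 5)
  expect_true(rc$rho_degenerate)

  expect_error(bland_altman(c(1, 2), c(1, 2)), "at least 3")
})

test_that("unweighted marginal means equal grand means on balanced data", {
  long <- balanced_long()
  fit <- fit_lmm(long)
  expect_true(fit$converged)
  grand <- tapply(long$value, long$period, mean)
  expect_equal(fit$period_means[names(grand)], c(grand), tolerance = 1e-6)
})

test_that("constant data collapses to zero variance components", {
  long <- balanced_long()
  long$value <- 42
  fit <- fit_lmm(long)
  expect_equal(unname(fit$period_means), rep(42, 3), tolerance = 1e-8)
  expect_lt(fit$var_participant, 1e-6)
})

test_that("rescaling all weights leaves the fit unchanged", {
  long <- balanced_long(seed = 7)
  w <- runif(nrow(long), 0.5, 2)
  f1 <- fit_lmm(long, w)
  f2 <- fit_lmm(long, w * 1234.5)
  expect_equal(f1$period_means, f2$period_means, tolerance = 1e-8)
  expect_equal(f1$vcov, f2$vcov, tolerance = 1e-8)
})

test_that("mixed model recovers the participant variance component", {
  # single-observation-per-cell data: participant variance is identified,
  # cell and residual variance only jointly
  errs <- replicate(100, {
    cfg <- sim_config(nutrient_panel = "energy", n_households = 150,
                      withdrawal_rate = 0,
                      residual_sd = list(energy = c(150, 0)),
                      seed = sample.int(2^30, 1))
    gl <- generate_long(cfg)
    long <- data.frame(participant_id = gl$period_means$participant_id,
                       period = gl$period_means$period,
                       value = gl$period_means$energy)
    fit <- fit_lmm(long)
    abs(sqrt(fit$var_participant) - 100) / 100
  })
  expect_lt(median(errs), 0.2)
})

test_that("variance-function regression recovers noiseless coefficients", {
  set.seed(19)
  fitted <- runif(200, 500, 2500)
  resid <- (2 + 0.1 * fitted) * sample(c(-1, 1), 200, replace = TRUE)
  vf <- fit_sd_function(resid, fitted, "linear")
  expect_equal(vf$coefficients[1], 2, tolerance = 1e-8)
  expect_equal(vf$coefficients[2], 0.1, tolerance = 1e-8)
  # cubic recovery on noiseless cubic data
  co <- c(5, 0.02, 3e-6, 1e-9)
  resid3 <- (co[1] + co[2] * fitted + co[3] * fitted^2 + co[4] * fitted^3) *
    sample(c(-1, 1), 200, replace = TRUE)
  vf3 <- fit_sd_function(resid3, fitted, "cubic")
  expect_equal(vf3$coefficients, co, tolerance = 1e-6)
})

test_that("homoscedastic residuals give a slope within 2 SE of zero", {
  set.seed(29)
  fitted <- runif(300, 500, 2500)
  resid <- rnorm(300, 0, 100)
  vf <- fit_sd_function(resid, fitted, "linear")
  se <- summary(lm(abs(resid) ~ fitted))$coefficients["fitted", "Std. Error"]
  expect_lt(abs(vf$coefficients[2]), 2 * se)
})

test_that("degenerate constant fitted values yield a constant SD function", {
  vf <- fit_sd_function(rnorm(50), rep(7, 50), "linear")
  expect_equal(vf$kind, "none")
  w <- weights_from(vf, rep(7, 10))
  expect_equal(length(unique(w)), 1)
})

test_that("weights are inverse squared SD with a floor", {
  vf <- structure(list(kind = "linear", coefficients = c(2, 0),
                       floor = 0.5), class = "variance_function")
  expect_equal(as.numeric(weights_from(vf, c(1, 10))), c(0.25, 0.25))
  vf2 <- structure(list(kind = "linear", coefficients = c(-5, 0.001),
                        floor = 0.5), class = "variance_function")
  # fitted SD would be negative -> floored -> weight 1/0.5^2
  expect_equal(as.numeric(weights_from(vf2, 100))[1], 4)
  # monotone SD -> antitone weights
  vf3 <- structure(list(kind = "linear", coefficients = c(1, 0.1),
                        floor = 0.1), class = "variance_function")
  w <- weights_from(vf3, c(10, 20, 30))
  expect_true(all(diff(w) < 0))
})

test_that("model selection minimizes the standardized-residual trend", {
  cands <- structure(list(M0 = fake_fit("rising"), M1 = fake_fit("flat"),
                          M2 = fake_fit("rising"), M3 = fake_fit("rising")),
                     class = "candidate_fits")
  sel <- select_model(cands)
  expect_equal(sel$label, "M1")
  expect_length(sel$trend_stats, 4)
  expect_equal(unname(sel$trend_stats[["M0"]]), 1)
  expect_equal(unname(sel$trend_stats[["M1"]]), 0)

  # only M0 converged -> forced fallback, annotated
  cands2 <- structure(list(M0 = fake_fit("rising"),
                           M1 = fake_fit("flat", converged = FALSE),
                           M2 = fake_fit("flat", converged = FALSE),
                           M3 = fake_fit("flat", converged = FALSE)),
                      class = "candidate_fits")
  sel2 <- select_model(cands2)
  expect_equal(sel2$label, "M0")
  expect_match(sel2$note, "no weighting was used")

  # exact tie between M1 and M2 -> fewer weighting iterations win
  cands3 <- structure(list(M0 = fake_fit("rising"), M1 = fake_fit("flat"),
                           M2 = fake_fit("flat"), M3 = fake_fit("rising")),
                      class = "candidate_fits")
  expect_equal(select_model(cands3)$label, "M1")
})

test_that("pairwise effects difference the marginal means with Wald CIs", {
  fit <- structure(list(converged = TRUE,
                        period_means = c(ivfr1 = 1400, recall = 1700,
                                         ivfr2 = 1420),
                        vcov = diag(c(4, 4, 4))),
                   class = "intake_lmm")
  dimnames(fit$vcov) <- list(names(fit$period_means),
                             names(fit$period_means))
  eff <- pairwise_effects(fit)
  expect_equal(eff$estimate, c(-300, -280, -20))
  se <- sqrt(8)
  expect_equal(eff$ci_low, eff$estimate - qnorm(0.975) * se)
  expect_equal(eff$ci_high, eff$estimate + qnorm(0.975) * se)
  expect_true(eff$p_omnibus[1] < 1e-10)
  expect_equal(length(unique(eff$p_omnibus)), 1)
})

test_that("the full per-role report is shaped like the summary tables", {
  cfg <- sim_config(n_households = 25, withdrawal_rate = 0.2, seed = 77)
  gr <- generate_records(cfg)
  daily <- compute_daily_intakes(gr$records, toy_fcd(), toy_retention(),
                                 toy_reference_portions())
  incl <- inclusion_filter(gr$records)
  pm <- period_means(daily)
  pm <- pm[pm$participant_id %in% incl$included & pm$n_days >= 2, ]
  rep_ <- run_validity_analysis(pm, nutrient_panel = c("energy", "protein"))
  expect_s3_class(rep_, "validity_report")
  expect_equal(nrow(rep_$summary), 4)  # 2 roles x 2 nutrients
  expect_setequal(unique(rep_$summary$role), c("mother", "child"))
  mrow <- rep_$summary[rep_$summary$role == "mother" &
                         rep_$summary$nutrient == "energy", ]
  expect_true(is.finite(mrow$mean_ivfr1) && is.finite(mrow$p_value))
  # generating bias: test-method energy below recall, periods similar
  expect_lt(mrow$diff_ivfr1_recall, 0)
  expect_lt(mrow$diff_ivfr2_recall, 0)
  expect_lt(abs(mrow$diff_ivfr1_ivfr2),
            abs(mrow$diff_ivfr1_recall))
})

test_that("an all-zero nutrient is reported as degenerate, not fatal", {
  pm <- data.frame(participant_id = rep(sprintf("P%02d", 1:10), each = 3),
                   role = "mother",
                   period = rep(c("ivfr1", "recall", "ivfr2"), 10),
                   energy = rnorm(30, 1500, 100), zeronut = 0)
  rep_ <- run_validity_analysis(pm, nutrient_panel = c("energy", "zeronut"),
                                roles = "mother")
  zrow <- rep_$summary[rep_$summary$nutrient == "zeronut", ]
  expect_match(zrow$note, "degenerate")
  erow <- rep_$summary[rep_$summary$nutrient == "energy", ]
  expect_true(is.finite(erow$p_value))
})
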