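#' Bland-Altman agreement between two methods
#'
#' Bias (mean difference), 95% limits of agreement (bias +/- 1.96 SD of
#' the differences), and the Spearman correlation of the differences
#' against the pair means, used to screen for a trend in the bias over
#' the intake range before the mixed-model comparison.
#'
#' @param a,b Paired measurements from the two methods (equal length,
#'   at least 3 complete pairs).
#' @return An object of class `bland_altman`: `bias`, `loa_low`,
#'   `loa_high`, `spearman_rho`, `rho_degenerate` (TRUE when the
#'   correlation is undefined, e.g. constant differences; rho is then
#'   reported as 0), `n_pairs`.
#' @export
bland_altman <- function(a, b) {
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 3) stop("Bland-Altman requires at least 3 complete pairs")
  d <- a - b
  m <- (a + b) / 2
  bias <- mean(d)
  s <- stats::sd(d)
  rho <- suppressWarnings(stats::cor(d, m, method = "spearman"))
  degenerate <- !is.finite(rho)
  structure(
    list(bias = bias, loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
         spearman_rho = if (degenerate) 0 else rho,
         rho_degenerate = degenerate, n_pairs = length(a)),
    class = "bland_altman"
  )
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman (n = %d): bias %.3g, LoA [%.3g, %.3g], Spearman rho (diff vs mean) %.3f%s\n",
              x$n_pairs, x$bias, x$loa_low, x$loa_high, x$spearman_rho,
              if (x$rho_degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Bland-Altman plot
#'
#' @param x A [bland_altman()] result, or `a`,`b` vectors via `...`.
#' @param a,b Paired measurements (used to draw the points).
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the `bland_altman` result.
#' @export
plot_bland_altman <- function(a, b, ...) {
  ba <- bland_altman(a, b)
  d <- a - b
  m <- (a + b) / 2
  graphics::plot(m, d, xlab = "Mean of methods", ylab = "Difference",
                 ...)
  graphics::abline(h = c(ba$bias, ba$loa_low, ba$loa_high),
                   lty = c(1, 2, 2))
  invisible(ba)
}

#' Fit the three-period linear mixed model
#'
#' `value ~ 0 + period` with two random intercepts -- one per participant
#' and one per recording period nested within participant -- fitted by
#' REML. Optional per-row weights scale the residual variance by
#' `1/weight` (weights are normalised to mean 1 first, so any positive
#' rescaling of the weights leaves the fit unchanged). The fixed-effect
#' estimates are the (weighted) marginal means per period.
#'
#' With one observation per (participant, period) cell the nested
#' intercept and the residual are confounded; the fixed effects and
#' their covariance remain well defined, and lme4 resolves the variance
#' split at a boundary if need be (a boundary fit still counts as
#' converged). Diagnostic fitted values and residuals are therefore
#' defined at cell level: fitted = fixed effect + participant intercept,
#' residual = observation - fitted, so the residual carries the full
#' within-participant cell deviation the variance-function weighting
#' needs to see.
#'
#' @param data Long data frame with `participant_id`, `period` (levels
#'   among `ivfr1`, `recall`, `ivfr2`) and `value`.
#' @param weights Optional positive per-row weights.
#' @return An object of class `intake_lmm`: `period_means` (named),
#'   `vcov` (their covariance), `var_participant`, `var_period_within`,
#'   `sigma2`, `weights`, `fitted`, `residuals`, `std_residuals`,
#'   `converged`, `weighting` (provenance label), `data`.
#' @export
fit_lmm <- function(data, weights = NULL) {
  stopifnot(all(c("participant_id", "period", "value") %in% names(data)))
  d <- data.frame(
    pid = factor(data$participant_id),
    period = factor(data$period, levels = PERIODS),
    value = as.numeric(data$value)
  )
  d$period <- droplevels(d$period)
  w_label <- if (is.null(weights)) "none"
             else attr(weights, "label") %||% "custom"
  if (is.null(weights)) {
    w <- rep(1, nrow(d))
  } else {
    if (length(weights) != nrow(d) || any(!is.finite(weights)) ||
        any(weights <= 0)) {
      stop("weights must be positive, finite and one per row")
    }
    # normalize to mean 1 and round to 12 significant digits: the rounded
    # vector is invariant under any positive rescaling of the weights, so
    # rescaled weights give a bit-identical fit
    w <- signif(weights / mean(weights), 12)
  }
  d$w <- w
  fit <- tryCatch(
    lme4::lmer(value ~ 0 + period + (1 | pid) + (1 | pid:period),
               data = d, weights = w, REML = TRUE,
               control = lme4::lmerControl(
                 calc.derivs = FALSE,
                 check.conv.singular = "ignore",
                 check.nobs.vs.nlev = "ignore",
                 check.nobs.vs.rankZ = "ignore",
                 check.nobs.vs.nRE = "ignore",
                 optCtrl = list(xtol_abs = 1e-10, ftol_abs = 1e-10))),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    return(structure(list(converged = FALSE,
                          error = conditionMessage(fit),
                          weighting = w_label, data = d),
                     class = "intake_lmm"))
  }
  conv_code <- fit@optinfo$conv$opt
  converged <- is.null(conv_code) || conv_code == 0
  beta <- lme4::fixef(fit)
  lev <- levels(d$period)
  names(beta) <- sub("^period", "", names(beta))
  beta <- beta[lev]
  V <- as.matrix(stats::vcov(fit))
  dimnames(V) <- list(lev, lev)
  re <- lme4::ranef(fit)
  u_pid <- setNames(re$pid[, 1], rownames(re$pid))
  fitted_cell <- beta[as.character(d$period)] +
    u_pid[as.character(d$pid)]
  resid_cell <- d$value - fitted_cell
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_pid <- vc$vcov[vc$grp == "pid"]
  var_cell <- vc$vcov[vc$grp == "pid:period"]
  sigma2 <- stats::sigma(fit)^2
  # cell-level SD implied by this fit's weighting, used to standardize
  sd_row <- sqrt(pmax(var_cell + sigma2 / w, 1e-12))
  structure(
    list(period_means = beta, vcov = V,
         var_participant = var_pid, var_period_within = var_cell,
         sigma2 = sigma2, weights = w,
         fitted = unname(fitted_cell), residuals = unname(resid_cell),
         std_residuals = unname(resid_cell / sd_row),
         converged = converged, weighting = w_label,
         n_participants = nlevels(d$pid), data = d),
    class = "intake_lmm"
  )
}

#' @export
print.intake_lmm <- function(x, ...) {
  if (!isTRUE(x$converged)) {
    cat("Linear mixed model: NOT converged",
        if (!is.null(x$error)) paste0(" (", x$error, ")"), "\n")
    return(invisible(x))
  }
  cat("Three-period linear mixed model (REML), weighting:", x$weighting, "\n")
  cat("Marginal means:\n")
  print(round(x$period_means, 3))
  cat(sprintf("Variance components: participant %.4g, period-within-participant %.4g, residual scale %.4g\n",
              x$var_participant, x$var_period_within, x$sigma2))
  invisible(x)
}

#' Fit a residual-SD variance function
#'
#' Ordinary least squares of the absolute residuals on the predicted
#' values -- linear (`|r| ~ 1 + pred`) or cubic (`|r| ~ 1 + pred + pred^2
#' + pred^3`). The fitted line estimates the residual SD as a function of
#' the predicted value. A positive floor (the larger of the 10th
#' percentile of the absolute residuals and a small constant) guards the
#' downstream weights against non-positive fitted SDs. Constant
#' predicted values are a degenerate design: the function kind is then
#' `"none"` and the SD is constant.
#'
#' @param residuals Model residuals.
#' @param fitted Predicted values, same length.
#' @param kind `"linear"` or `"cubic"`.
#' @return An object of class `variance_function`: `kind`,
#'   `coefficients`, `floor`.
#' @export
fit_sd_function <- function(residuals, fitted, kind = c("linear", "cubic")) {
  kind <- match.arg(kind)
  stopifnot(length(residuals) == length(fitted))
  if (length(residuals) < 10) {
    stop("variance-function regression requires at least 10 rows")
  }
  a <- abs(residuals)
  floor_val <- max(stats::quantile(a, 0.1, names = FALSE), 1e-6)
  if (stats::sd(fitted) < 1e-10) {
    return(structure(list(kind = "none",
                          coefficients = c(sd = stats::sd(residuals)),
                          floor = floor_val),
                     class = "variance_function"))
  }
  co <- if (kind == "linear") {
    stats::coef(stats::lm(a ~ fitted))
  } else {
    stats::coef(stats::lm(a ~ fitted + I(fitted^2) + I(fitted^3)))
  }
  structure(list(kind = kind, coefficients = unname(co), floor = floor_val),
            class = "variance_function")
}

#' Evaluate a variance function
#'
#' @param varfun A [fit_sd_function()] result.
#' @param fitted Predicted values.
#' @return SD at each predicted value, floored at `varfun$floor`.
#' @export
sd_at <- function(varfun, fitted) {
  stopifnot(inherits(varfun, "variance_function"))
  co <- varfun$coefficients
  s <- switch(varfun$kind,
    none = rep(co[1], length(fitted)),
    linear = co[1] + co[2] * fitted,
    cubic = co[1] + co[2] * fitted + co[3] * fitted^2 + co[4] * fitted^3
  )
  pmax(s, varfun$floor)
}

#' Weights from a variance function
#'
#' `weight_i = 1 / SD(pred_i)^2`; the SD floor guarantees finite,
#' positive weights.
#'
#' @param varfun A [fit_sd_function()] result.
#' @param fitted Predicted values.
#' @param label Provenance label attached to the weights.
#' @return Numeric weight vector.
#' @export
weights_from <- function(varfun, fitted, label = NULL) {
  w <- 1 / sd_at(varfun, fitted)^2
  attr(w, "label") <- label %||% paste0("1/SD^2, ", varfun$kind)
  w
}

#' Fit the four candidate weighted mixed models
#'
#' The iterative weighting procedure:
#' \describe{
#'   \item{M0}{unweighted fit;}
#'   \item{M1}{weighted by a linear SD function of M0's absolute
#'     residuals against its predicted values;}
#'   \item{M2}{second iteration -- weighted by a linear SD function of
#'     M1's residuals;}
#'   \item{M3}{second iteration -- weighted by a cubic SD function of
#'     M1's residuals.}
#' }
#' Candidates that fail to fit are flagged not-converged and are skipped
#' by [select_model()].
#'
#' @param data Long data frame for [fit_lmm()].
#' @return A named list of four `intake_lmm` objects (class
#'   `candidate_fits`).
#' @export
iterative_weighting <- function(data) {
  m0 <- fit_lmm(data)
  m0$weighting <- "none"
  failed <- function(label) {
    structure(list(converged = FALSE, weighting = label), class = "intake_lmm")
  }
  if (!isTRUE(m0$converged)) {
    out <- list(M0 = m0, M1 = failed("linear (iter 1)"),
                M2 = failed("linear (iter 2)"), M3 = failed("cubic (iter 2)"))
    return(structure(out, class = "candidate_fits"))
  }
  m1 <- tryCatch({
    f1 <- fit_sd_function(m0$residuals, m0$fitted, "linear")
    w1 <- weights_from(f1, m0$fitted, label = "linear (iter 1)")
    fit <- fit_lmm(data, w1)
    fit$varfun <- f1
    fit
  }, error = function(e) failed("linear (iter 1)"))
  if (isTRUE(m1$converged)) {
    m2 <- tryCatch({
      f2 <- fit_sd_function(m1$residuals, m1$fitted, "linear")
      fit <- fit_lmm(data, weights_from(f2, m1$fitted,
                                        label = "linear (iter 2)"))
      fit$varfun <- f2
      fit
    }, error = function(e) failed("linear (iter 2)"))
    m3 <- tryCatch({
      f3 <- fit_sd_function(m1$residuals, m1$fitted, "cubic")
      fit <- fit_lmm(data, weights_from(f3, m1$fitted,
                                        label = "cubic (iter 2)"))
      fit$varfun <- f3
      fit
    }, error = function(e) failed("cubic (iter 2)"))
  } else {
    m2 <- failed("linear (iter 2)")
    m3 <- failed("cubic (iter 2)")
  }
  structure(list(M0 = m0, M1 = m1, M2 = m2, M3 = m3),
            class = "candidate_fits")
}

# Quantitative proxy for examining standardized-residual plots: the
# absolute Spearman correlation between |standardized residual| and the
# fitted value. A suitable weighting function leaves no such trend.
trend_statistic <- function(fit) {
  if (!isTRUE(fit$converged)) return(NA_real_)
  z <- abs(fit$residuals * sqrt(fit$weights))
  rho <- suppressWarnings(stats::cor(z, fit$fitted, method = "spearman"))
  if (!is.finite(rho)) 0 else abs(rho)
}

#' Choose the most suitable weighting among the four candidates
#'
#' Picks the converged candidate whose standardized residuals show the
#' least trend against the fitted values (smallest absolute Spearman
#' correlation between |standardized residual| and fitted value). Exact
#' ties go to the candidate with fewer weighting iterations and then the
#' lower polynomial order (M0 < M1 < M2 < M3). If every weighted
#' candidate failed, the unweighted model is used and the result is
#' annotated that no weighting was used.
#'
#' @param candidates A [iterative_weighting()] result.
#' @return A list with `fit` (the chosen `intake_lmm`), `label`,
#'   `trend_stats` (named, one per candidate), and `note`.
#' @export
select_model <- function(candidates) {
  stopifnot(inherits(candidates, "candidate_fits"))
  stats_ <- vapply(candidates, trend_statistic, 0)
  ok <- !is.na(stats_)
  if (!any(ok)) stop("no candidate model converged")
  idx <- which(ok)[which.min(stats_[ok])]
  label <- names(candidates)[idx]
  note <- if (label == "M0") {
    if (sum(ok) == 1) "no weighting was used (weighted fits unavailable)"
    else "no weighting was used"
  } else {
    paste("weighted:", candidates[[idx]]$weighting)
  }
  list(fit = candidates[[idx]], label = label, trend_stats = stats_,
       note = note)
}

#' Pairwise differences of the weighted marginal means
#'
#' All three pairwise differences of the period marginal means from the
#' final model -- test period 1 minus recall, test period 2 minus recall,
#' and test period 1 minus test period 2 -- with 95% Wald confidence
#' intervals from the fixed-effect covariance, plus a single omnibus
#' Wald chi-square p-value for the recording-period effect attached to
#' every pair.
#'
#' @param fit A converged `intake_lmm`.
#' @param conf_level Confidence level (default 0.95).
#' @return Data frame with `pair`, `estimate`, `ci_low`, `ci_high`,
#'   `p_omnibus`.
#' @export
pairwise_effects <- function(fit, conf_level = 0.95) {
  stopifnot(inherits(fit, "intake_lmm"), isTRUE(fit$converged))
  mu <- fit$period_means
  V <- fit$vcov
  lev <- names(mu)
  pair_defs <- list(
    c("ivfr1", "recall"), c("ivfr2", "recall"), c("ivfr1", "ivfr2")
  )
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  rows <- list()
  for (pd in pair_defs) {
    if (!all(pd %in% lev)) next
    est <- mu[[pd[1]]] - mu[[pd[2]]]
    se <- sqrt(V[pd[1], pd[1]] + V[pd[2], pd[2]] - 2 * V[pd[1], pd[2]])
    rows[[length(rows) + 1L]] <- data.frame(
      pair = paste(pd[1], "-", pd[2]),
      estimate = est, ci_low = est - z * se, ci_high = est + z * se,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  # omnibus Wald test of any difference among the period means
  if (length(lev) >= 2) {
    C <- matrix(0, nrow = length(lev) - 1, ncol = length(lev),
                dimnames = list(NULL, lev))
    for (i in seq_len(length(lev) - 1)) {
      C[i, i] <- 1
      C[i, i + 1] <- -1
    }
    delta <- C %*% mu
    W <- drop(t(delta) %*% solve(C %*% V %*% t(C)) %*% delta)
    p <- stats::pchisq(W, df = nrow(C), lower.tail = FALSE)
  } else {
    p <- NA_real_
  }
  out$p_omnibus <- p
  rownames(out) <- NULL
  out
}

#' Full two-method validity analysis
#'
#' Orchestrates the statistical comparison separately for each role and
#' nutrient: Bland-Altman screens for each method pair, the four-model
#' iterative weighting procedure, selection of the most suitable
#' weighting, and the pairwise differences of the weighted marginal
#' means. Nutrients are analysed in isolation: one nutrient's failure is
#' reported in its row and never aborts the others.
#'
#' @param period_intakes Per-period intakes from [period_means()], after
#'   the inclusion filter has been applied (participants with fewer than
#'   2 periods present are dropped here as a safety net).
#' @param nutrient_panel Named list `role -> nutrient vector`, or a
#'   single vector used for every role. Defaults to the columns present.
#' @param roles Roles to analyse.
#' @return An object of class `validity_report`: `summary` (one row per
#'   role x nutrient, shaped like a per-period summary table with effect
#'   columns) and `details` (per role/nutrient: Bland-Altman results,
#'   candidate trend statistics, the selected fit, effects).
#' @export
run_validity_analysis <- function(period_intakes, nutrient_panel = NULL,
                                  roles = c("mother", "child")) {
  stopifnot(all(c("participant_id", "role", "period") %in%
                  names(period_intakes)))
  all_nut <- setdiff(names(period_intakes),
                     c("participant_id", "household_id", "role", "site",
                       "period", "n_days"))
  panel_for <- function(role) {
    if (is.null(nutrient_panel)) return(all_nut)
    if (is.list(nutrient_panel)) {
      return(intersect(nutrient_panel[[role]], all_nut))
    }
    intersect(nutrient_panel, all_nut)
  }
  summary_rows <- list()
  details <- list()
  for (role in roles) {
    sub <- period_intakes[period_intakes$role == role, , drop = FALSE]
    if (!nrow(sub)) next
    keep <- names(which(table(sub$participant_id) >= 2))
    sub <- sub[sub$participant_id %in% keep, , drop = FALSE]
    for (nut in panel_for(role)) {
      res <- tryCatch(
        analyse_one(sub, role, nut),
        error = function(e) {
          list(summary = data.frame(role = role, nutrient = nut,
                                    note = conditionMessage(e),
                                    stringsAsFactors = FALSE),
               detail = list(error = conditionMessage(e)))
        }
      )
      summary_rows[[paste(role, nut)]] <- res$summary
      details[[paste(role, nut, sep = ".")]] <- res$detail
    }
  }
  all_cols <- unique(unlist(lapply(summary_rows, names)))
  summary_rows <- lapply(summary_rows, function(r) {
    r[setdiff(all_cols, names(r))] <- NA
    r[all_cols]
  })
  structure(
    list(summary = do.call(rbind, summary_rows), details = details),
    class = "validity_report"
  )
}

analyse_one <- function(sub, role, nut) {
  long <- data.frame(participant_id = sub$participant_id,
                     period = sub$period, value = sub[[nut]],
                     stringsAsFactors = FALSE)
  unadj <- lapply(PERIODS, function(p) {
    v <- long$value[long$period == p]
    c(mean = mean(v), sd = stats::sd(v), n = length(v))
  })
  names(unadj) <- PERIODS
  if (stats::sd(long$value) < 1e-12) {
    return(list(
      summary = data.frame(role = role, nutrient = nut,
                           note = "degenerate: no variation in intakes",
                           stringsAsFactors = FALSE),
      detail = list(degenerate = TRUE, unadjusted = unadj)
    ))
  }
  # Bland-Altman screen per method pair, on participants with both periods
  wide <- stats::reshape(long, idvar = "participant_id",
                         timevar = "period", direction = "wide")
  ba <- list()
  for (pd in list(c("ivfr1", "recall"), c("ivfr2", "recall"),
                  c("ivfr1", "ivfr2"))) {
    va <- wide[[paste0("value.", pd[1])]]
    vb <- wide[[paste0("value.", pd[2])]]
    if (is.null(va) || is.null(vb)) next
    ok <- is.finite(va) & is.finite(vb)
    if (sum(ok) >= 3) {
      ba[[paste(pd, collapse = "_vs_")]] <- bland_altman(va[ok], vb[ok])
    }
  }
  candidates <- iterative_weighting(long)
  sel <- select_model(candidates)
  eff <- pairwise_effects(sel$fit)
  row <- data.frame(role = role, nutrient = nut, stringsAsFactors = FALSE)
  for (p in PERIODS) {
    row[[paste0("mean_", p)]] <- unadj[[p]][["mean"]]
    row[[paste0("sd_", p)]] <- unadj[[p]][["sd"]]
  }
  row$p_value <- eff$p_omnibus[1]
  key <- c("ivfr1 - recall" = "ivfr1_recall",
           "ivfr2 - recall" = "ivfr2_recall",
           "ivfr1 - ivfr2" = "ivfr1_ivfr2")
  for (i in seq_len(nrow(eff))) {
    k <- key[[eff$pair[i]]]
    row[[paste0("diff_", k)]] <- eff$estimate[i]
    row[[paste0("lo_", k)]] <- eff$ci_low[i]
    row[[paste0("hi_", k)]] <- eff$ci_high[i]
  }
  row$model <- sel$label
  row$note <- sel$note
  list(summary = row,
       detail = list(bland_altman = ba, trend_stats = sel$trend_stats,
                     selected = sel$label, fit = sel$fit, effects = eff,
                     unadjusted = unadj))
}

#' @export
print.validity_report <- function(x, digits = 3, ...) {
  cat("Two-method validity analysis\n")
  s <- x$summary
  num <- vapply(s, is.numeric, TRUE)
  s[num] <- lapply(s[num], function(v) signif(v, digits))
  print(s, row.names = FALSE)
  invisible(x)
}
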