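#' Bundled illustrative food-composition fixtures
#'
#' Small synthetic tables shipped with the package: a toy food
#' composition table of common Cambodian-style foods with plausible (not
#' authoritative) per-100 g values, an illustrative cooking
#' retention-factor table, and a reference-portion table. Real analyses
#' should supply their own tables via [load_fcd()] and friends.
#'
#' @param nutrient_panel Panel for the toy table.
#' @return `toy_fcd()` an `fcd`; `toy_retention()` a `retention_table`;
#'   `toy_reference_portions()` a `reference_portions` table.
#' @export
toy_fcd <- function(nutrient_panel = default_nutrient_panel("mother")) {
  load_fcd(
    system.file("extdata", "toy_fcd.csv", package = "sharedplate"),
    nutrient_panel = nutrient_panel,
    measures_path = system.file("extdata", "toy_measures.csv",
                                package = "sharedplate")
  )
}

#' @rdname toy_fcd
#' @export
toy_retention <- function() {
  load_retention(system.file("extdata", "toy_retention.csv",
                             package = "sharedplate"))
}

#' @rdname toy_fcd
#' @export
toy_reference_portions <- function() {
  load_reference_portions(system.file("extdata", "toy_reference_portions.csv",
                                      package = "sharedplate"))
}

#' Simulation configuration
#'
#' Ground truth and design parameters for the synthetic two-method
#' study. Defaults emulate the mother-like study conditions: 148
#' households over 3 sites, 3 recording periods of 3 nonconsecutive days
#' (one weekend day each), a 28% household withdrawal rate, a systematic
#' between-method energy bias of roughly -300 kcal (test method minus
#' 24-h recall; about -150 kcal for the child preset), between-participant
#' and period-within-participant random variation, and a residual SD that
#' grows linearly with the predicted intake so the variance-function
#' weighting machinery has something to find.
#'
#' @param role Preset: `"mother"` or `"child"`.
#' @param n_households Number of households.
#' @param site_proportions Named 3-vector over rural/semirural/urban,
#'   summing to 1.
#' @param withdrawal_rate Probability that a household withdraws after
#'   the first recording period.
#' @param days_per_period Recorded days per period (2 or 3).
#' @param nutrient_panel Nutrients to simulate.
#' @param true_period_means Named list `period -> named nutrient vector`
#'   of true mean daily intakes.
#' @param sd_participant Named vector of between-participant SDs.
#' @param sd_period_within Named vector of period-within-participant SDs.
#' @param residual_sd Named list `nutrient -> coefficients` of the
#'   residual SD function of the predicted value: length 2 for linear
#'   `c0 + c1*pred`, length 4 for cubic.
#' @param shared_plate_rate Probability that a main dish is a shared
#'   plate.
#' @param recipe_rate Probability that a main dish is a home recipe.
#' @param seed Integer seed; all stochastic draws flow from one stream.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(role = c("mother", "child"),
                       n_households = 148,
                       site_proportions = c(rural = 1/3, semirural = 1/3,
                                            urban = 1/3),
                       withdrawal_rate = 0.28,
                       days_per_period = 3,
                       nutrient_panel = c("energy", "protein"),
                       true_period_means = NULL,
                       sd_participant = NULL,
                       sd_period_within = NULL,
                       residual_sd = NULL,
                       shared_plate_rate = 0.5,
                       recipe_rate = 0.35,
                       seed = 1L) {
  role <- match.arg(role)
  if (is.null(true_period_means)) {
    true_period_means <- if (role == "mother") {
      list(ivfr1 = c(energy = 1400, protein = 60),
           recall = c(energy = 1700, protein = 67),
           ivfr2 = c(energy = 1420, protein = 64))
    } else {
      list(ivfr1 = c(energy = 620, protein = 26),
           recall = c(energy = 790, protein = 25.5),
           ivfr2 = c(energy = 650, protein = 26.5))
    }
    true_period_means <- lapply(true_period_means, function(v) v[nutrient_panel])
  }
  if (is.null(sd_participant)) {
    sd_participant <- if (role == "mother") c(energy = 100, protein = 8)
                      else c(energy = 60, protein = 5)
    sd_participant <- sd_participant[nutrient_panel]
  }
  if (is.null(sd_period_within)) {
    sd_period_within <- if (role == "mother") c(energy = 50, protein = 4)
                        else c(energy = 30, protein = 2.5)
    sd_period_within <- sd_period_within[nutrient_panel]
  }
  if (is.null(residual_sd)) {
    residual_sd <- if (role == "mother") {
      list(energy = c(50, 0.1), protein = c(4, 0.05))
    } else {
      list(energy = c(30, 0.1), protein = c(2.5, 0.05))
    }
    residual_sd <- residual_sd[nutrient_panel]
  }
  cfg <- structure(
    list(role = role, n_households = n_households,
         site_proportions = site_proportions,
         withdrawal_rate = withdrawal_rate,
         days_per_period = days_per_period,
         nutrient_panel = nutrient_panel,
         true_period_means = true_period_means,
         sd_participant = sd_participant,
         sd_period_within = sd_period_within,
         residual_sd = residual_sd,
         shared_plate_rate = shared_plate_rate,
         recipe_rate = recipe_rate,
         seed = as.integer(seed)),
    class = "sim_config"
  )
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(
    cfg$n_households >= 0,
    abs(sum(cfg$site_proportions) - 1) < 1e-8,
    cfg$withdrawal_rate >= 0, cfg$withdrawal_rate <= 1,
    cfg$shared_plate_rate >= 0, cfg$shared_plate_rate <= 1,
    cfg$recipe_rate >= 0, cfg$recipe_rate <= 1,
    cfg$days_per_period %in% 2:3,
    all(vapply(cfg$true_period_means, length, 0L) ==
          length(cfg$nutrient_panel)),
    all(cfg$sd_participant >= 0), all(cfg$sd_period_within >= 0)
  )
  for (nm in cfg$nutrient_panel) {
    co <- cfg$residual_sd[[nm]]
    if (is.null(co) || !length(co) %in% c(2L, 4L)) {
      stop("residual_sd coefficients for '", nm,
           "' must have length 2 (linear) or 4 (cubic)")
    }
    if (co[1] <= 0) stop("residual_sd intercept must be > 0 for '", nm, "'")
    # expected truncation-at-zero rate under a normal approximation; the
    # generator clamps negative draws at 0 and this should stay rare
    for (p in names(cfg$true_period_means)) {
      mu <- cfg$true_period_means[[p]][[nm]]
      sd_tot <- sqrt(cfg$sd_participant[[nm]]^2 +
                     cfg$sd_period_within[[nm]]^2 +
                     eval_sd_poly(co, mu)^2)
      if (stats::pnorm(0, mean = mu, sd = sd_tot) > 0.01) {
        warning(sprintf(
          "config implies > 1%% of simulated %s intakes truncated at 0 (period %s)",
          nm, p), call. = FALSE)
      }
    }
  }
  invisible(cfg)
}

eval_sd_poly <- function(co, pred) {
  s <- co[1] + co[2] * pred
  if (length(co) == 4) s <- s + co[3] * pred^2 + co[4] * pred^3
  pmax(s, 1e-8)
}

#' Generate a long-format synthetic nutrient dataset
#'
#' Draws directly from the analysis model: for participant i, period j,
#' day k, `y_ijk = mu_period(j) + a_i + b_ij + e_ijk` with
#' `a_i ~ N(0, sd_participant^2)`, `b_ij ~ N(0, sd_period_within^2)` and
#' `e_ijk ~ N(0, SD(mu_j + a_i + b_ij)^2)` where `SD()` is the
#' configured residual SD function of the predicted value. Negative
#' draws are truncated at 0 and counted. Withdrawn households retain only
#' their first recording period. Deterministic given the config seed.
#'
#' @param config A [sim_config()].
#' @return A list with `daily` (one row per participant-period-day),
#'   `period_means` (one row per participant-period; the mixed-model
#'   observation unit), and `truth` (the generating parameters plus the
#'   truncation count).
#' @export
generate_long <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_households
  panel <- config$nutrient_panel
  pids <- sprintf("P%04d", seq_len(n))
  withdrawn <- stats::runif(n) < config$withdrawal_rate
  n_days <- config$days_per_period
  rows <- vector("list", n)
  truncated <- 0L
  for (i in seq_len(n)) {
    periods <- if (withdrawn[i]) PERIODS[1] else PERIODS
    a <- vapply(panel, function(nm)
      stats::rnorm(1, 0, config$sd_participant[[nm]]), 0)
    prows <- list()
    for (p in periods) {
      b <- vapply(panel, function(nm)
        stats::rnorm(1, 0, config$sd_period_within[[nm]]), 0)
      for (k in seq_len(n_days)) {
        y <- vapply(panel, function(nm) {
          mu <- config$true_period_means[[p]][[nm]]
          pred <- mu + a[[nm]] + b[[nm]]
          s <- eval_sd_poly(config$residual_sd[[nm]], pred)
          pred + stats::rnorm(1, 0, s)
        }, 0)
        neg <- y < 0
        truncated <- truncated + sum(neg)
        y[neg] <- 0
        row <- data.frame(participant_id = pids[i], period = p,
                          day_index = k, stringsAsFactors = FALSE)
        row[panel] <- as.list(y)
        prows[[length(prows) + 1L]] <- row
      }
    }
    rows[[i]] <- do.call(rbind, prows)
  }
  if (length(rows)) {
    daily <- do.call(rbind, rows)
    pm <- stats::aggregate(daily[panel],
                           by = daily[c("participant_id", "period")],
                           FUN = mean)
    pm <- pm[order(pm$participant_id, match(pm$period, PERIODS)), ]
    rownames(pm) <- NULL
  } else {
    daily <- data.frame(participant_id = character(0),
                        period = character(0), day_index = integer(0))
    daily[panel] <- lapply(panel, function(x) numeric(0))
    pm <- daily[setdiff(names(daily), "day_index")]
  }
  list(
    daily = daily,
    period_means = pm,
    truth = list(config = config, n_truncated = truncated,
                 n_withdrawn = sum(withdrawn))
  )
}

# Per-role, per-period portion scale factors encoding the between-method
# bias: test-method portions are systematically smaller than recall-period
# portions in the same proportion as the default true period means.
period_scale_factors <- function() {
  list(
    mother = c(ivfr1 = 1400 / 1700, recall = 1, ivfr2 = 1420 / 1700),
    child = c(ivfr1 = 620 / 790, recall = 1, ivfr2 = 650 / 790)
  )
}

rlnorm1 <- function(sdlog) stats::rlnorm(1, meanlog = -sdlog^2 / 2, sdlog = sdlog)

# encode grams as an analyst-estimate set whose deterministic resolution
# equals `target` exactly
make_estimate_set <- function(target, discordant = FALSE) {
  if (discordant) {
    list(estimates = list(
      list(analyst_id = "A1", grams = target * 1.35),
      list(analyst_id = "A2", grams = target * 0.65)
    ), third = target)
  } else {
    d <- stats::runif(1, 0.01, 0.12)
    a <- target * (1 + d)
    b <- target * (1 - d)
    list(estimates = list(
      list(analyst_id = "A1", grams = a),
      list(analyst_id = "A2", grams = b)
    ))
  }
}

resolved_grams <- function(amount) {
  if (is.numeric(amount)) return(amount)
  g <- vapply(amount$estimates, function(e) e$grams, 0)
  if (length(g) == 1) return(g)
  rel <- abs(g[1] - g[2]) / mean(g[1:2])
  if (rel <= 0.25) mean(g[1:2]) else amount$third
}

#' Generate a complete synthetic study record set with embedded truth
#'
#' Emulates the study structure: mother-and-child households across 3
#' sites; 3 recording periods (test method, 24-h recall, test method
#' repeat) of nonconsecutive days including one weekend day; a supervised
#' training day (flagged, never analysed); own-plate and shared-plate
#' servings; home recipes reused across the household's occasions;
#' analyst estimate sets (concordant pairs and discordant pairs settled
#' by a third analyst); leftovers; occasional fully unconsumed servings;
#' and household withdrawal after the first period. Portion sizes carry
#' per-role period scale factors, so the between-method bias propagates
#' through the records themselves.
#'
#' Every serving resolves deterministically, and the generator computes
#' each participant-day nutrient total analytically with the same
#' resolution, retention, leftover and even-split rules the engine
#' implements, returning them as the embedded ground truth.
#'
#' @param config A [sim_config()]; `n_households`, `site_proportions`,
#'   `withdrawal_rate`, `shared_plate_rate`, `recipe_rate` and `seed`
#'   drive the record structure.
#' @param fcd Food composition table (default [toy_fcd()]).
#' @param rf Retention table (default [toy_retention()]).
#' @return A list with `records` (a validated `intake_recordset`),
#'   `truth` (data frame of exact participant-day nutrient totals) and
#'   `config`.
#' @export
generate_records <- function(config = sim_config(), fcd = NULL, rf = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(fcd)) fcd <- toy_fcd()
  if (is.null(rf)) rf <- toy_retention()
  set.seed(config$seed)
  panel <- fcd$panel
  scales <- period_scale_factors()
  sites <- sample(names(config$site_proportions), config$n_households,
                  replace = TRUE, prob = config$site_proportions)
  households <- vector("list", config$n_households)
  truth_rows <- list()

  for (h in seq_len(config$n_households)) {
    hid <- sprintf("H%03d", h)
    mother_id <- paste0(hid, "_M")
    child_id <- paste0(hid, "_C")
    jitter <- function(x) x * rlnorm1(0.1)
    recipes <- list(
      list(recipe_id = paste0(hid, "_soup"),
           ingredients = list(
             list(food_id = "fish_freshwater", grams = jitter(250),
                  cooking_method = "boiled"),
             list(food_id = "morning_glory", grams = jitter(150),
                  cooking_method = "boiled"),
             list(food_id = "fish_sauce", grams = jitter(30),
                  cooking_method = "boiled"),
             list(food_id = "water", grams = jitter(600),
                  cooking_method = "boiled")
           )),
      list(recipe_id = paste0(hid, "_fry"),
           ingredients = list(
             list(food_id = "pork_lean", grams = jitter(200),
                  cooking_method = "fried"),
             list(food_id = "morning_glory", grams = jitter(120),
                  cooking_method = "fried"),
             list(food_id = "oil_vegetable", grams = jitter(20),
                  cooking_method = "fried")
           ),
           final_weight = NULL)
    )
    # analytic per-100 g profiles for the truth computation
    rprof <- lapply(recipes, function(r) {
      tot <- setNames(numeric(length(panel)), panel)
      w <- 0
      for (ing in r$ingredients) {
        keep <- retention_lookup(rf, panel, ing$cooking_method)
        tot <- tot + ing$grams / 100 * fcd$nutrients[ing$food_id, ] * keep
        w <- w + ing$grams
      }
      tot * 100 / (r$final_weight %||% w)
    })
    names(rprof) <- vapply(recipes, `[[`, "", "recipe_id")

    withdrawn <- stats::runif(1) < config$withdrawal_rate
    periods <- if (withdrawn) PERIODS[1] else PERIODS
    m_mult <- rlnorm1(0.15)
    c_mult <- rlnorm1(0.15)
    days <- list()
    # supervised practice day before the first period
    days[[1]] <- list(
      period = "ivfr1", day_index = 1L, is_weekend = FALSE, training = TRUE,
      occasions = list(list(
        occasion_id = paste0(hid, "_training_o1"),
        servings = list(list(
          serving_type = "own", item_kind = "food", item_ref = "rice_cooked",
          served = 200, leftover = 0,
          consumption_status = "eaten_completely",
          eaters = list(participant_ids = list(mother_id),
                        n_nonparticipant_adults = 0L,
                        n_nonparticipant_children = 0L)
        ))
      ))
    )
    for (p in periods) {
      weekend_day <- sample(config$days_per_period, 1)
      p_mult_m <- rlnorm1(0.08)
      p_mult_c <- rlnorm1(0.08)
      for (k in seq_len(config$days_per_period)) {
        day_mult <- rlnorm1(0.08)
        child_absent <- stats::runif(1) < 0.05
        occasions <- list()
        day_truth <- matrix(0, nrow = 2, ncol = length(panel),
                            dimnames = list(c(mother_id, child_id), panel))
        present <- c(FALSE, FALSE)
        names(present) <- c(mother_id, child_id)
        add_serving <- function(serving, resolved_served, resolved_leftover) {
          status <- serving$consumption_status
          consumed <- if (status == "eaten_completely") resolved_served
                      else if (status == "not_consumed") 0
                      else max(resolved_served - resolved_leftover, 0)
          pids <- as.character(unlist(serving$eaters$participant_ids))
          present[pids] <<- TRUE
          if (consumed > 0) {
            prof <- if ((serving$item_kind %||% "food") == "recipe") {
              rprof[[serving$item_ref]]
            } else {
              fcd$nutrients[serving$item_ref, ]
            }
            n_eaters <- length(pids) +
              serving$eaters$n_nonparticipant_adults +
              serving$eaters$n_nonparticipant_children
            amt <- if (serving$serving_type == "shared") consumed / n_eaters
                   else consumed
            for (pid in pids) {
              day_truth[pid, ] <<- day_truth[pid, ] + amt / 100 * prof
            }
          }
          serving
        }
        own_serving <- function(pid, item, grams, kind = "food") {
          g <- grams
          u <- stats::runif(1)
          served <- if (u < 0.30) make_estimate_set(g)
                    else if (u < 0.35) make_estimate_set(g, discordant = TRUE)
                    else g
          served_res <- resolved_grams(served)
          u2 <- stats::runif(1)
          if (u2 < 0.03) {
            status <- "not_consumed"; leftover <- served_res; left_res <- served_res
          } else if (u2 < 0.28) {
            status <- "partial"
            left_res <- served_res * stats::runif(1, 0.05, 0.3)
            leftover <- left_res
          } else {
            status <- "eaten_completely"; leftover <- 0; left_res <- 0
          }
          add_serving(list(
            serving_type = "own", item_kind = kind, item_ref = item,
            served = served, leftover = leftover,
            consumption_status = status,
            eaters = list(participant_ids = list(pid),
                          n_nonparticipant_adults = 0L,
                          n_nonparticipant_children = 0L)
          ), served_res, left_res)
        }
        role_scale <- function(role) {
          mult <- if (role == "mother") m_mult * p_mult_m else c_mult * p_mult_c
          mult * day_mult * scales[[role]][[p]]
        }
        for (meal in c("breakfast", "lunch", "dinner")) {
          servings <- list()
          # staple rice, own plate
          servings[[length(servings) + 1L]] <-
            own_serving(mother_id, "rice_cooked",
                        220 * role_scale("mother") * rlnorm1(0.15))
          if (!child_absent) {
            servings[[length(servings) + 1L]] <-
              own_serving(child_id, "rice_cooked",
                          90 * role_scale("child") * rlnorm1(0.15))
          }
          # main dish: shared plate or individual own plates
          is_recipe <- stats::runif(1) < config$recipe_rate
          item_kind <- if (is_recipe) "recipe" else "food"
          item_ref <- if (is_recipe) {
            sample(names(rprof), 1)
          } else {
            sample(c("fish_freshwater", "chicken", "egg_chicken",
                     "noodles_rice"), 1)
          }
          if (stats::runif(1) < config$shared_plate_rate) {
            child_in <- !child_absent && stats::runif(1) < 0.8
            pids <- c(mother_id, if (child_in) child_id)
            n_adults <- sample(0:2, 1)
            n_child <- sample(0:1, 1)
            g <- 350 * role_scale("mother") * rlnorm1(0.2) *
              (1 + n_adults + n_child)
            served_res <- g
            u2 <- stats::runif(1)
            if (u2 < 0.25) {
              status <- "partial"
              left_res <- g * stats::runif(1, 0.05, 0.25)
            } else {
              status <- "eaten_completely"; left_res <- 0
            }
            servings[[length(servings) + 1L]] <- add_serving(list(
              serving_type = "shared", item_kind = item_kind,
              item_ref = item_ref, served = g, leftover = left_res,
              consumption_status = status,
              eaters = list(participant_ids = as.list(pids),
                            n_nonparticipant_adults = n_adults,
                            n_nonparticipant_children = n_child)
            ), served_res, left_res)
          } else {
            servings[[length(servings) + 1L]] <-
              own_serving(mother_id, item_ref,
                          150 * role_scale("mother") * rlnorm1(0.2),
                          kind = item_kind)
            if (!child_absent && stats::runif(1) < 0.7) {
              servings[[length(servings) + 1L]] <-
                own_serving(child_id, "egg_chicken",
                            50 * role_scale("child") * rlnorm1(0.2))
            }
          }
          # fruit sometimes
          if (stats::runif(1) < 0.4) {
            servings[[length(servings) + 1L]] <-
              own_serving(mother_id, sample(c("banana", "mango_ripe"), 1),
                          100 * role_scale("mother") * rlnorm1(0.2))
          }
          occasions[[length(occasions) + 1L]] <- list(
            occasion_id = sprintf("%s_%s_d%d_%s", hid, p, k, meal),
            servings = servings
          )
        }
        days[[length(days) + 1L]] <- list(
          period = p, day_index = as.integer(k),
          is_weekend = k == weekend_day, training = FALSE,
          occasions = occasions
        )
        for (pid in c(mother_id, child_id)[present]) {
          row <- data.frame(participant_id = pid, household_id = hid,
                            role = if (pid == mother_id) "mother" else "child",
                            site = sites[h], period = p,
                            day_index = as.integer(k),
                            stringsAsFactors = FALSE)
          row[panel] <- as.list(day_truth[pid, ])
          truth_rows[[length(truth_rows) + 1L]] <- row
        }
      }
    }
    households[[h]] <- list(
      household_id = hid, site = sites[h],
      participants = list(
        list(participant_id = mother_id, role = "mother"),
        list(participant_id = child_id, role = "child")
      ),
      recipes = recipes,
      days = days
    )
  }
  truth <- if (length(truth_rows)) {
    do.call(rbind, truth_rows)
  } else {
    e <- data.frame(participant_id = character(0),
                    household_id = character(0), role = character(0),
                    site = character(0), period = character(0),
                    day_index = integer(0))
    e[panel] <- lapply(panel, function(x) numeric(0))
    e
  }
  records <- validate_records(list(households = households))
  list(records = records, truth = truth, config = config)
}
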