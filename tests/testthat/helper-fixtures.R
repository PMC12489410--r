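# Builders for tiny in-code fixtures shared across the test files.

tiny_fcd_csv <- function(dir = tempdir()) {
  path <- file.path(dir, paste0("fcd-", as.integer(runif(1, 1, 1e8)), ".csv"))
  writeLines(c(
    "food_id,name,group,energy,protein,thiamine",
    "rice_raw,\"Rice, raw\",Cereals,350,7,0.4",
    "water,Water,Beverages,0,0,0",
    "fish,Fish,Fish,105,18.5,0.08"
  ), path)
  path
}

tiny_fcd <- function(panel = c("energy", "protein", "thiamine")) {
  load_fcd(tiny_fcd_csv(), nutrient_panel = panel)
}

tiny_retention_csv <- function(dir = tempdir()) {
  path <- file.path(dir, paste0("rf-", as.integer(runif(1, 1, 1e8)), ".csv"))
  writeLines(c(
    "nutrient,cooking_method,factor",
    "thiamine,boiled,0.5"
  ), path)
  path
}

tiny_retention <- function() load_retention(tiny_retention_csv())

# -- record-set builders ------------------------------------------------

own_serving <- function(pid, item, served, leftover = 0,
                        status = "partial", kind = "food") {
  list(serving_type = "own", item_kind = kind, item_ref = item,
       served = served, leftover = leftover, consumption_status = status,
       eaters = list(participant_ids = list(pid),
                     n_nonparticipant_adults = 0L,
                     n_nonparticipant_children = 0L))
}

shared_serving <- function(pids, item, served, n_adults = 0L,
                           n_children = 0L, leftover = 0,
                           status = "partial", kind = "food") {
  list(serving_type = "shared", item_kind = kind, item_ref = item,
       served = served, leftover = leftover, consumption_status = status,
       eaters = list(participant_ids = as.list(pids),
                     n_nonparticipant_adults = n_adults,
                     n_nonparticipant_children = n_children))
}

rec_day <- function(period, day_index, servings, training = FALSE,
                    is_weekend = FALSE) {
  list(period = period, day_index = day_index, is_weekend = is_weekend,
       training = training,
       occasions = list(list(occasion_id = paste0(period, "_d", day_index),
                             servings = servings)))
}

rec_household <- function(id, days = list(), recipes = list(),
                          site = "rural", with_child = TRUE) {
  parts <- list(list(participant_id = paste0(id, "_M"), role = "mother"))
  if (with_child) {
    parts <- c(parts, list(list(participant_id = paste0(id, "_C"),
                                role = "child")))
  }
  list(household_id = id, site = site, participants = parts,
       recipes = recipes, days = days)
}

record_set <- function(...) validate_records(list(households = list(...)))

# complete balanced three-period long data with participant intercepts
balanced_long <- function(n = 30, seed = 101, mu = c(ivfr1 = 1400,
                                                     recall = 1700,
                                                     ivfr2 = 1420),
                          sd_p = 100, sd_e = 80) {
  set.seed(seed)
  a <- rnorm(n, 0, sd_p)
  do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(participant_id = sprintf("P%03d", i), period = names(mu),
               value = unname(mu) + a[i] + rnorm(3, 0, sd_e))
  }))
}

# long energy dataset drawn from the analysis model, plus the truth
sim_energy_long <- function(seed, n = 150, mu = c(1400, 1700, 1420),
                            resid = c(50, 0.1)) {
  cfg <- sim_config(
    nutrient_panel = "energy", n_households = n, withdrawal_rate = 0,
    true_period_means = list(ivfr1 = c(energy = mu[1]),
                             recall = c(energy = mu[2]),
                             ivfr2 = c(energy = mu[3])),
    sd_participant = c(energy = 100), sd_period_within = c(energy = 50),
    residual_sd = list(energy = resid), seed = seed)
  gl <- generate_long(cfg)
  data.frame(participant_id = gl$period_means$participant_id,
             period = gl$period_means$period,
             value = gl$period_means$energy)
}

# a household whose mother records `days_per_period` plain rice days in
# the given periods (used by inclusion-filter tests)
simple_days <- function(pid, periods_days) {
  days <- list()
  for (p in names(periods_days)) {
    for (k in seq_len(periods_days[[p]])) {
      days[[length(days) + 1L]] <-
        rec_day(p, k, list(own_serving(pid, "rice_raw", 100,
                                       status = "eaten_completely")))
    }
  }
  days
}
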