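est_set <- function(...) {
  g <- c(...)
  list(estimates = lapply(seq_along(g), function(i)
    list(analyst_id = paste0("A", i), grams = g[i])))
}

test_that("dual-analyst reconciliation follows the 25% rule", {
  expect_equal(reconcile_portion(est_set(100, 110)), 105)
  expect_equal(reconcile_portion(est_set(80, 80)), 80)
  expect_equal(reconcile_portion(est_set(120)), 120)
  # discordant pair with a third-analyst decision
  e <- est_set(100, 150)
  e$third <- 120
  expect_equal(reconcile_portion(e), 120)
  # discordant, no third analyst -> unresolved
  expect_true(is.na(reconcile_portion(est_set(100, 150))))
  # exactly at the threshold counts as concordant
  e2 <- est_set(100, 100 * 13 / 11)  # rel diff = 2/12 ... scaled: check below
  expect_equal(reconcile_portion(est_set(87.5, 112.5)),
               100)  # rel diff exactly 0.25
  expect_error(reconcile_portion(list(estimates = list())), "zero")
})

test_that("portion imputation walks the hierarchy and records the level", {
  portions <- data.frame(
    item_ref = c("rice", "rice", "rice", "rice", "rice"),
    context_id = c("P1", "P1", "P1", "P2", "P3"),
    role = c("mother", "mother", "mother", "mother", "mother"),
    grams = c(150, 200, 250, 100, 300)
  )
  # level 1: same participant's own resolved portions
  r1 <- impute_portion("rice", "P1", "mother", portions)
  expect_equal(r1$grams, 200)
  expect_equal(r1$level, 1L)
  # level 2: same participant type
  r2 <- impute_portion("rice", "P9", "mother", portions)
  expect_equal(r2$grams, 200)  # median of 150,200,250,100,300
  expect_equal(r2$level, 2L)
  # level 2 with only two donors averages them
  two <- portions[4:5, ]
  expect_equal(impute_portion("rice", "P9", "mother", two)$grams, 200)
  # single resolved portion
  one <- data.frame(item_ref = "fish", context_id = "P1", role = "child",
                    grams = 120)
  expect_equal(impute_portion("fish", "P1", "child", one)$grams, 120)
  # level 3: reference table
  refs <- toy_reference_portions()
  r3 <- impute_portion("rice_cooked", "P9", "mother",
                       portions[0, ], fallback = refs)
  expect_equal(r3$grams, 250)
  expect_equal(r3$level, 3L)
  # nothing anywhere -> error naming the item
  expect_error(impute_portion("durian", "P9", "mother", portions[0, ]),
               "durian")
})

test_that("recipe profiles apply retention at ingredient level and divide by prepared weight", {
  fcd <- tiny_fcd()
  rf <- tiny_retention()
  # single ingredient, no losses, no final weight -> identity
  r_id <- list(recipe_id = "r", ingredients = list(
    list(food_id = "fish", grams = 250, cooking_method = "steamed")))
  expect_equal(recipe_profile(r_id, fcd, rf),
               fcd_profile(fcd, "fish"))
  # unknown ingredient
  r_bad <- list(recipe_id = "r", ingredients = list(
    list(food_id = "durian", grams = 10)))
  expect_error(recipe_profile(r_bad, fcd, rf), "durian")
})

test_that("consumed amount honours the consumption status", {
  expect_equal(consumed_amount(400, 100, "partial"), 300)
  expect_equal(consumed_amount(250, 0, "eaten_completely"), 250)
  expect_equal(consumed_amount(250, 250, "not_consumed"), 0)
})

test_that("shared-plate apportioning is even and conserves mass", {
  sole <- apportion_shared(240, list(participant_ids = "M",
                                     n_nonparticipant_adults = 0,
                                     n_nonparticipant_children = 0))
  expect_equal(unname(sole), 240)
  both <- apportion_shared(400, list(participant_ids = c("M", "C"),
                                     n_nonparticipant_adults = 2,
                                     n_nonparticipant_children = 0))
  expect_equal(unname(both), c(100, 100))
  # property: assigned + discarded = consumed, exactly, over random rosters
  set.seed(31)
  for (i in 1:100) {
    n_p <- sample(0:2, 1)
    n_a <- sample(0:3, 1)
    n_c <- sample(0:3, 1)
    if (n_p + n_a + n_c == 0) n_a <- 1
    total <- runif(1, 0, 1000)
    roster <- list(participant_ids = if (n_p) paste0("P", seq_len(n_p))
                                     else character(0),
                   n_nonparticipant_adults = n_a,
                   n_nonparticipant_children = n_c)
    shares <- apportion_shared(total, roster)
    discarded <- total / (n_p + n_a + n_c) * (n_a + n_c)
    expect_equal(sum(shares) + discarded, total, tolerance = 1e-12)
  }
})

engine_fixture <- function(servings, recipes = list()) {
  rs <- record_set(rec_household("H1", days = list(
    rec_day("ivfr1", 1, servings)), recipes = recipes))
  compute_daily_intakes(rs, tiny_fcd(), tiny_retention())
}

test_that("daily intakes compose scaling, apportioning and summation", {
  # 200 g of a 350 kcal/100 g food, own plate
  d1 <- engine_fixture(list(own_serving("H1_M", "rice_raw", 200,
                                        status = "eaten_completely")))
  expect_equal(d1$energy[d1$participant_id == "H1_M"], 700)

  # plus a 300 g shared dish (3 eaters) of a 100 kcal/100 g item
  d2 <- engine_fixture(list(
    own_serving("H1_M", "rice_raw", 200, status = "eaten_completely"),
    shared_serving("H1_M", "fish", 300, n_adults = 2L,
                   status = "eaten_completely")))
  expect_equal(d2$energy[d2$participant_id == "H1_M"], 700 + 105)

  # an all-unconsumed day yields a zero vector, not a missing row
  d3 <- engine_fixture(list(own_serving("H1_M", "rice_raw", 200,
                                        leftover = 200,
                                        status = "not_consumed")))
  expect_equal(d3$energy[d3$participant_id == "H1_M"], 0)
  expect_equal(d3$protein[d3$participant_id == "H1_M"], 0)
})

test_that("engine matches a spreadsheet-style hand calculation", {
  # fixture: mother eats 150 g rice_raw (analyst pair 140/160 -> 150),
  # shares a 3-eater 300 g fish dish with 60 g leftover (-> 80 g share),
  # child has 50 g fish own plate, half left over.
  servings <- list(
    own_serving("H1_M", "rice_raw", est_set(140, 160),
                status = "eaten_completely"),
    shared_serving(c("H1_M", "H1_C"), "fish", 300, n_adults = 1L,
                   leftover = 60, status = "partial"),
    own_serving("H1_C", "fish", 50, leftover = 25, status = "partial")
  )
  d <- engine_fixture(servings)
  # hand calculation:
  # mother: 150/100*350 + 80/100*105 = 525 + 84 = 609 kcal
  # child:  80/100*105 + 25/100*105 = 84 + 26.25 = 110.25 kcal
  m <- d[d$participant_id == "H1_M", ]
  c_ <- d[d$participant_id == "H1_C", ]
  expect_equal(m$energy, 609, tolerance = 1e-9)
  expect_equal(c_$energy, 110.25, tolerance = 1e-9)
  expect_equal(m$protein, 150 / 100 * 7 + 80 / 100 * 18.5, tolerance = 1e-9)
})

test_that("unresolved portions are imputed from the participant's own median", {
  servings <- list(
    own_serving("H1_M", "rice_raw", 150, status = "eaten_completely"),
    own_serving("H1_M", "rice_raw", 250, status = "eaten_completely"),
    own_serving("H1_M", "rice_raw", est_set(100, 160),  # discordant, no 3rd
                status = "eaten_completely")
  )
  d <- engine_fixture(servings)
  # imputed serving = median(150, 250) = 200 -> total 600 g rice
  expect_equal(d$energy[d$participant_id == "H1_M"], 600 / 100 * 350)
})

test_that("daily totals scale linearly and ignore serving order", {
  servings <- list(
    own_serving("H1_M", "rice_raw", 180, leftover = 30),
    shared_serving(c("H1_M", "H1_C"), "fish", 320, n_adults = 1L,
                   leftover = 20),
    own_serving("H1_C", "rice_raw", 60, status = "eaten_completely")
  )
  base <- engine_fixture(servings)
  doubled <- lapply(servings, function(s) {
    s$served <- s$served * 2
    s$leftover <- s$leftover * 2
    s
  })
  d2 <- engine_fixture(doubled)
  nut <- c("energy", "protein", "thiamine")
  expect_equal(as.matrix(d2[nut]), 2 * as.matrix(base[nut]),
               tolerance = 1e-12, ignore_attr = TRUE)
  shuffled <- engine_fixture(servings[c(3, 1, 2)])
  shuffled <- shuffled[match(base$participant_id, shuffled$participant_id), ]
  expect_equal(as.matrix(shuffled[nut]), as.matrix(base[nut]),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("period means average 2-3 days and flag single-day periods", {
  daily <- data.frame(
    participant_id = "P1", household_id = "H1", role = "mother",
    site = "rural",
    period = c("ivfr1", "ivfr1", "recall", "recall", "recall", "ivfr2"),
    day_index = c(1, 2, 1, 2, 3, 1),
    energy = c(600, 900, 600, 900, 900, 1000)
  )
  pm <- period_means(daily)
  expect_equal(pm$energy[pm$period == "ivfr1"], 750)
  expect_equal(pm$energy[pm$period == "recall"], 800)
  expect_equal(pm$energy[pm$period == "ivfr2"], 1000)
  expect_equal(pm$n_days[pm$period == "ivfr2"], 1)  # below-minimum flag
})
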