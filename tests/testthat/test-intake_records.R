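test_that("a minimal one-household fixture parses with 2 participants", {
  rs <- record_set(rec_household("H1", days = simple_days(
    "H1_M", list(ivfr1 = 3, recall = 3, ivfr2 = 3))))
  expect_s3_class(rs, "intake_recordset")
  pt <- participants_table(rs)
  expect_equal(nrow(pt), 2)
  expect_setequal(pt$role, c("mother", "child"))
})

test_that("JSON read/write round trip preserves grams exactly", {
  g <- 123.456789012345  # value with a long binary expansion
  rs <- record_set(rec_household("H1", days = list(
    rec_day("ivfr1", 1, list(own_serving("H1_M", "rice_raw", g,
                                         leftover = g / 7))))))
  path <- tempfile(fileext = ".json")
  write_records(rs, path)
  rs2 <- read_records(path)
  s <- rs2$households[[1]]$days[[1]]$occasions[[1]]$servings[[1]]
  expect_identical(s$served, g)
  expect_identical(s$leftover, g / 7)
})

test_that("structural invariants are enforced with a path to the offender", {
  # own-plate serving listing two participants
  bad <- list(households = list(rec_household("H1", days = list(
    rec_day("ivfr1", 1, list(
      shared_serving(c("H1_M", "H1_C"), "rice_raw", 100)))))))
  bad$households[[1]]$days[[1]]$occasions[[1]]$servings[[1]]$serving_type <- "own"
  expect_error(validate_records(bad), "exactly one participating eater")

  # leftover exceeding served
  expect_error(
    record_set(rec_household("H1", days = list(
      rec_day("ivfr1", 1, list(own_serving("H1_M", "rice_raw", 100,
                                           leftover = 120)))))),
    "leftover \\(120 g\\) exceeds served \\(100 g\\)"
  )

  # two mothers in one household
  bad2 <- list(households = list(rec_household("H1")))
  bad2$households[[1]]$participants[[2]]$role <- "mother"
  expect_error(validate_records(bad2), "exactly one mother")

  # unknown participant in a roster, with JSON-path in the message
  bad3 <- list(households = list(rec_household("H1", days = list(
    rec_day("ivfr1", 1, list(own_serving("NOBODY", "rice_raw", 100)))))))
  err <- tryCatch(validate_records(bad3), error = conditionMessage)
  expect_match(err, "/households/1/days/1/occasions/1/servings/1")

  # empty eating occasion
  bad4 <- list(households = list(rec_household("H1", days = list(
    list(period = "ivfr1", day_index = 1, training = FALSE,
         occasions = list(list(occasion_id = "o1", servings = list())))))))
  expect_error(validate_records(bad4), ">= 1 serving")
})

test_that("inclusion filter applies the 2-of-3-periods, 2-3-days rule", {
  hh <- function(id, spec) {
    rec_household(id, days = simple_days(paste0(id, "_M"), spec),
                  with_child = FALSE)
  }
  rs <- record_set(
    hh("A", list(ivfr1 = 3, recall = 3)),           # two full periods: in
    hh("B", list(ivfr1 = 1, recall = 3, ivfr2 = 1)) # one qualifying: out
  )
  res <- inclusion_filter(rs)
  expect_true("A_M" %in% res$included)
  expect_false("B_M" %in% res$included)
  expect_match(res$report$reason[res$report$participant_id == "B_M"],
               "only 1 period")
})

test_that("a child with complete periods but no servings at all is excluded", {
  days <- simple_days("H1_M", list(ivfr1 = 3, recall = 3, ivfr2 = 3))
  rs <- record_set(rec_household("H1", days = days))
  res <- inclusion_filter(rs)
  expect_true("H1_M" %in% res$included)
  expect_false("H1_C" %in% res$included)
  expect_equal(res$report$reason[res$report$participant_id == "H1_C"],
               "no intake data")
})

test_that("days of only unconsumed servings do not count as recorded days", {
  days <- lapply(1:3, function(k) {
    rec_day("ivfr1", k, list(own_serving("H1_M", "rice_raw", 100,
                                         leftover = 100,
                                         status = "not_consumed")))
  })
  days <- c(days, simple_days("H1_M", list(recall = 3, ivfr2 = 1)))
  rs <- record_set(rec_household("H1", days = days, with_child = FALSE))
  res <- inclusion_filter(rs)
  expect_false("H1_M" %in% res$included)
})

test_that("training days never count toward inclusion", {
  days <- c(
    list(rec_day("ivfr1", 1,
                 list(own_serving("H1_M", "rice_raw", 100,
                                  status = "eaten_completely")),
                 training = TRUE)),
    simple_days("H1_M", list(ivfr1 = 1, recall = 3))
  )
  rs <- record_set(rec_household("H1", days = days, with_child = FALSE))
  res <- inclusion_filter(rs)
  # ivfr1 has only 1 real day -> only recall qualifies -> excluded
  expect_false("H1_M" %in% res$included)
})

test_that("inclusion filter is idempotent and order-independent", {
  set.seed(5)
  cfg <- sim_config(n_households = 8, seed = 21)
  rs <- generate_records(cfg)$records
  res1 <- inclusion_filter(rs)
  res2 <- inclusion_filter(rs)
  expect_identical(res1$included, res2$included)
  rs_rev <- validate_records(list(households = rev(rs$households)))
  res3 <- inclusion_filter(rs_rev)
  expect_setequal(res1$included, res3$included)
})

test_that("flat CSV export has one row per participant-day-serving", {
  rs <- record_set(rec_household("H1", days = list(
    rec_day("ivfr1", 1, list(
      own_serving("H1_M", "rice_raw", 100),
      shared_serving(c("H1_M", "H1_C"), "fish", 300, n_adults = 1L))))))
  path <- tempfile(fileext = ".csv")
  records_to_csv(rs, path)
  flat <- read.csv(path)
  expect_equal(nrow(flat), 3)  # own(M) + shared(M) + shared(C)
  expect_equal(sum(flat$serving_type == "shared"), 2)
  expect_equal(unique(flat$n_eaters[flat$serving_type == "shared"]), 3)
})
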