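PERIODS <- c("ivfr1", "recall", "ivfr2")
SITES <- c("rural", "semirural", "urban")
ROLES <- c("mother", "child")
STATUSES <- c("eaten_completely", "not_consumed", "partial")

`%||%` <- function(a, b) if (is.null(a)) b else a

fail_at <- function(path, msg) {
  stop(sprintf("record validation error at %s: %s", path, msg), call. = FALSE)
}

is_amount <- function(x) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 0
}

is_estimate_set <- function(x) {
  is.list(x) && !is.null(x$estimates)
}

validate_amount <- function(x, path, allow_zero = TRUE) {
  if (is_amount(x)) {
    if (!allow_zero && x <= 0) fail_at(path, "amount must be > 0")
    return(invisible(TRUE))
  }
  if (is_estimate_set(x)) {
    ests <- x$estimates
    if (!length(ests) || length(ests) > 3) {
      fail_at(path, "estimate set must contain 1-3 analyst estimates")
    }
    for (i in seq_along(ests)) {
      e <- ests[[i]]
      g <- e$grams
      if (!is_amount(g) || g <= 0) {
        fail_at(paste0(path, "/estimates/", i), "estimate grams must be > 0")
      }
    }
    if (!is.null(x$third) && (!is_amount(x$third) || x$third <= 0)) {
      fail_at(paste0(path, "/third"), "third-analyst grams must be > 0")
    }
    return(invisible(TRUE))
  }
  fail_at(path, "amount must be non-negative grams or an analyst estimate set")
}

validate_serving <- function(s, path, participant_ids, recipe_ids) {
  if (is.null(s$serving_type) || !s$serving_type %in% c("own", "shared")) {
    fail_at(paste0(path, "/serving_type"), "must be 'own' or 'shared'")
  }
  kind <- s$item_kind %||% "food"
  if (!kind %in% c("food", "recipe")) {
    fail_at(paste0(path, "/item_kind"), "must be 'food' or 'recipe'")
  }
  if (is.null(s$item_ref) || !nzchar(s$item_ref)) {
    fail_at(paste0(path, "/item_ref"), "missing item reference")
  }
  if (kind == "recipe" && !s$item_ref %in% recipe_ids) {
    fail_at(paste0(path, "/item_ref"),
            sprintf("recipe '%s' not defined for this household", s$item_ref))
  }
  status <- s$consumption_status %||% "partial"
  if (!status %in% STATUSES) {
    fail_at(paste0(path, "/consumption_status"),
            paste("must be one of", paste(STATUSES, collapse = ", ")))
  }
  validate_amount(s$served, paste0(path, "/served"))
  leftover <- s$leftover %||% 0
  validate_amount(leftover, paste0(path, "/leftover"))
  if (is_amount(s$served) && is_amount(leftover)) {
    if (leftover > s$served + 1e-9) {
      fail_at(paste0(path, "/leftover"),
              sprintf("leftover (%g g) exceeds served (%g g)",
                      leftover, s$served))
    }
    if (status == "eaten_completely" && leftover > 0) {
      fail_at(paste0(path, "/leftover"),
              "status eaten_completely requires zero leftover")
    }
    if (status == "not_consumed" && abs(leftover - s$served) > 1e-9 &&
        leftover != 0) {
      fail_at(paste0(path, "/leftover"),
              "status not_consumed requires leftover equal to served")
    }
  }
  eaters <- s$eaters
  if (is.null(eaters)) fail_at(paste0(path, "/eaters"), "missing eater roster")
  pids <- unlist(eaters$participant_ids) %||% character(0)
  pids <- as.character(pids)
  n_adults <- eaters$n_nonparticipant_adults %||% 0
  n_children <- eaters$n_nonparticipant_children %||% 0
  if (!is_amount(n_adults) || !is_amount(n_children) ||
      n_adults != round(n_adults) || n_children != round(n_children)) {
    fail_at(paste0(path, "/eaters"),
            "nonparticipant counts must be non-negative integers")
  }
  unknown <- setdiff(pids, participant_ids)
  if (length(unknown)) {
    fail_at(paste0(path, "/eaters/participant_ids"),
            paste("unknown participant:", paste(unknown, collapse = ", ")))
  }
  if (anyDuplicated(pids)) {
    fail_at(paste0(path, "/eaters/participant_ids"), "duplicated participant")
  }
  total <- length(pids) + n_adults + n_children
  if (total < 1) {
    fail_at(paste0(path, "/eaters"), "total eater count must be >= 1")
  }
  if (s$serving_type == "own" &&
      (length(pids) != 1 || n_adults + n_children != 0)) {
    fail_at(paste0(path, "/eaters"),
            "own-plate serving must list exactly one participating eater")
  }
  invisible(TRUE)
}

validate_household <- function(hh, path) {
  if (is.null(hh$household_id) || !nzchar(hh$household_id)) {
    fail_at(paste0(path, "/household_id"), "missing household id")
  }
  if (is.null(hh$site) || !hh$site %in% SITES) {
    fail_at(paste0(path, "/site"),
            paste("must be one of", paste(SITES, collapse = ", ")))
  }
  parts <- hh$participants
  if (!length(parts)) fail_at(paste0(path, "/participants"), "no participants")
  roles <- vapply(parts, function(p) p$role %||% "", "")
  if (!all(roles %in% ROLES)) {
    fail_at(paste0(path, "/participants"), "roles must be 'mother' or 'child'")
  }
  if (sum(roles == "mother") != 1) {
    fail_at(paste0(path, "/participants"),
            "a household must have exactly one mother")
  }
  if (sum(roles == "child") > 1) {
    fail_at(paste0(path, "/participants"),
            "a household may have at most one child")
  }
  pids <- vapply(parts, function(p) as.character(p$participant_id %||% ""), "")
  if (any(!nzchar(pids)) || anyDuplicated(pids)) {
    fail_at(paste0(path, "/participants"), "participant ids missing or duplicated")
  }
  recipe_ids <- character(0)
  for (i in seq_along(hh$recipes %||% list())) {
    r <- hh$recipes[[i]]
    rpath <- paste0(path, "/recipes/", i)
    if (is.null(r$recipe_id) || !nzchar(r$recipe_id)) {
      fail_at(rpath, "missing recipe id")
    }
    if (!length(r$ingredients)) fail_at(rpath, "recipe must have >= 1 ingredient")
    for (j in seq_along(r$ingredients)) {
      ing <- r$ingredients[[j]]
      if (is.null(ing$food_id) || !nzchar(ing$food_id)) {
        fail_at(paste0(rpath, "/ingredients/", j), "missing food_id")
      }
      if (!is_amount(ing$grams) || ing$grams <= 0) {
        fail_at(paste0(rpath, "/ingredients/", j),
                "ingredient grams must be > 0")
      }
    }
    if (!is.null(r$final_weight) &&
        (!is_amount(r$final_weight) || r$final_weight <= 0)) {
      fail_at(paste0(rpath, "/final_weight"), "final weight must be > 0")
    }
    recipe_ids <- c(recipe_ids, r$recipe_id)
  }
  if (anyDuplicated(recipe_ids)) {
    fail_at(paste0(path, "/recipes"), "duplicate recipe_id within household")
  }
  seen_day <- character(0)
  for (i in seq_along(hh$days %||% list())) {
    d <- hh$days[[i]]
    dpath <- paste0(path, "/days/", i)
    if (is.null(d$period) || !d$period %in% PERIODS) {
      fail_at(paste0(dpath, "/period"),
              paste("must be one of", paste(PERIODS, collapse = ", ")))
    }
    if (is.null(d$day_index) || !is_amount(d$day_index) ||
        !(d$day_index %in% 1:3)) {
      fail_at(paste0(dpath, "/day_index"), "must be 1, 2 or 3")
    }
    training <- isTRUE(d$training)
    if (!training) {
      key <- paste(d$period, d$day_index)
      if (key %in% seen_day) {
        fail_at(paste0(dpath, "/day_index"),
                sprintf("duplicate day_index %d in period %s",
                        d$day_index, d$period))
      }
      seen_day <- c(seen_day, key)
    }
    occs <- d$occasions %||% list()
    for (j in seq_along(occs)) {
      occ <- occs[[j]]
      opath <- paste0(dpath, "/occasions/", j)
      if (!length(occ$servings)) {
        fail_at(opath, "eating occasion must have >= 1 serving")
      }
      for (k in seq_along(occ$servings)) {
        validate_serving(occ$servings[[k]], paste0(opath, "/servings/", k),
                         pids, recipe_ids)
      }
    }
  }
  invisible(pids)
}

#' Validate a raw record hierarchy
#'
#' Checks every structural invariant of the record model (roles per
#' household, own-plate rosters, leftover vs served, estimate sets, recipe
#' references, day uniqueness) and returns a classed record set. Error
#' messages carry a JSON-style path to the offending node.
#'
#' @param x A list shaped like the documented record schema (see
#'   `system.file("schema", "records.schema.json", package = "sharedplate")`).
#' @return An object of class `intake_recordset`.
#' @export
validate_records <- function(x) {
  if (is.null(x$households)) fail_at("/households", "missing")
  all_pids <- character(0)
  hh_ids <- character(0)
  for (i in seq_along(x$households)) {
    pids <- validate_household(x$households[[i]], paste0("/households/", i))
    if (any(pids %in% all_pids)) {
      fail_at(paste0("/households/", i),
              "participant id reused across households")
    }
    all_pids <- c(all_pids, pids)
    hh_ids <- c(hh_ids, x$households[[i]]$household_id)
  }
  if (anyDuplicated(hh_ids)) fail_at("/households", "duplicate household_id")
  structure(x, class = "intake_recordset")
}

#' Read an intake record set from JSON
#'
#' @param path Path to a records JSON document.
#' @return A validated `intake_recordset`.
#' @export
read_records <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  validate_records(x)
}

#' Write an intake record set to JSON
#'
#' Numeric grams are written at full double precision so a
#' read/write/read round trip preserves every value exactly.
#'
#' @param records An `intake_recordset`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  stopifnot(inherits(records, "intake_recordset"))
  x <- unclass(records)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' @export
print.intake_recordset <- function(x, ...) {
  pt <- participants_table(x)
  cat(sprintf("Intake record set: %d households, %d participants (%d mothers, %d children)\n",
              length(x$households), nrow(pt),
              sum(pt$role == "mother"), sum(pt$role == "child")))
  invisible(x)
}

#' Participant roster of a record set
#'
#' @param records An `intake_recordset`.
#' @return Data frame with `participant_id`, `household_id`, `role`, `site`.
#' @export
participants_table <- function(records) {
  rows <- lapply(records$households, function(hh) {
    data.frame(
      participant_id = vapply(hh$participants,
                              function(p) as.character(p$participant_id), ""),
      household_id = hh$household_id,
      role = vapply(hh$participants, function(p) p$role, ""),
      site = hh$site,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Flat CSV export of a record set
#'
#' One row per (participant, day, serving), with resolved-or-raw amounts
#' left as-is (estimate sets are summarised by their analyst count).
#'
#' @param records An `intake_recordset`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
records_to_csv <- function(records, path) {
  rows <- list()
  for (hh in records$households) {
    for (d in hh$days %||% list()) {
      for (occ in d$occasions %||% list()) {
        for (s in occ$servings) {
          pids <- as.character(unlist(s$eaters$participant_ids))
          served <- if (is_amount(s$served)) s$served else NA_real_
          leftover <- if (is_amount(s$leftover %||% 0)) (s$leftover %||% 0) else NA_real_
          n_est <- if (is_estimate_set(s$served)) length(s$served$estimates) else 0L
          for (pid in pids) {
            rows[[length(rows) + 1L]] <- data.frame(
              participant_id = pid, household_id = hh$household_id,
              period = d$period, day_index = d$day_index,
              training = isTRUE(d$training),
              occasion_id = occ$occasion_id %||% NA_character_,
              serving_type = s$serving_type, item_kind = s$item_kind %||% "food",
              item_ref = s$item_ref, served_g = served, leftover_g = leftover,
              n_analyst_estimates = n_est,
              consumption_status = s$consumption_status %||% "partial",
              n_eaters = length(pids) +
                (s$eaters$n_nonparticipant_adults %||% 0) +
                (s$eaters$n_nonparticipant_children %||% 0),
              stringsAsFactors = FALSE
            )
          }
        }
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame()
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

# Days of intake data per participant per period: a day counts iff the
# participant appears in >= 1 serving whose status is not 'not_consumed'
# and the day is not the supervised training day.
count_recording_days <- function(records) {
  pt <- participants_table(records)
  counts <- matrix(0L, nrow = nrow(pt), ncol = length(PERIODS),
                   dimnames = list(pt$participant_id, PERIODS))
  for (hh in records$households) {
    for (d in hh$days %||% list()) {
      if (isTRUE(d$training)) next
      with_data <- character(0)
      for (occ in d$occasions %||% list()) {
        for (s in occ$servings) {
          if ((s$consumption_status %||% "partial") == "not_consumed") next
          with_data <- union(with_data,
                             as.character(unlist(s$eaters$participant_ids)))
        }
      }
      if (length(with_data)) {
        counts[with_data, d$period] <- counts[with_data, d$period] + 1L
      }
    }
  }
  counts
}

#' Analysis inclusion filter
#'
#' A participant enters the analysis if they have at least 2 of the 3
#' recording periods with 2 or 3 recorded days of food and beverage
#' intake data each. A day counts as recorded when the participant ate
#' from at least one serving that was not entirely unconsumed; children
#' with no intake data at all are therefore excluded by the same rule.
#'
#' @param records An `intake_recordset`.
#' @return A list with `included` (character vector of participant ids)
#'   and `report` (data frame with per-period day counts and the reason
#'   for each decision).
#' @export
inclusion_filter <- function(records) {
  pt <- participants_table(records)
  counts <- count_recording_days(records)
  qualifying <- counts >= 2 & counts <= 3
  n_periods <- rowSums(qualifying)
  included <- pt$participant_id[n_periods >= 2]
  reason <- ifelse(
    n_periods >= 2, "included",
    ifelse(rowSums(counts) == 0, "no intake data",
           sprintf("only %d period(s) with 2-3 recorded days", n_periods))
  )
  report <- data.frame(
    participant_id = pt$participant_id, role = pt$role,
    days_ivfr1 = counts[, "ivfr1"], days_recall = counts[, "recall"],
    days_ivfr2 = counts[, "ivfr2"],
    n_qualifying_periods = n_periods,
    included = n_periods >= 2, reason = reason,
    stringsAsFactors = FALSE
  )
  list(included = included, report = report)
}
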