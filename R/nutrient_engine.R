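#' Reconcile dual-analyst portion estimates
#'
#' Two blinded analysts estimate a portion independently. If the two
#' estimates agree to within the tolerance (relative difference
#' `|a - b| / mean(a, b)` of at most `threshold`, default 25%), the
#' reconciled portion is their arithmetic mean. If they disagree by more
#' than the tolerance and a third analyst reviewed the record, the third
#' analyst's value is final. With no third review the portion is
#' unresolved (`NA`) and falls through to median-portion imputation.
#'
#' @param est An analyst estimate set: a list with `estimates` (a list of
#'   `list(analyst_id =, grams =)`, 1 or 2 entries) and optionally
#'   `third` (grams decided by the reviewing analyst). A bare numeric is
#'   returned as-is.
#' @param threshold Relative-difference tolerance (default 0.25).
#' @return Grams, or `NA_real_` when unresolved.
#' @export
#' @examples
#' reconcile_portion(list(estimates = list(
#'   list(analyst_id = "A1", grams = 100),
#'   list(analyst_id = "A2", grams = 110))))  # 105
reconcile_portion <- function(est, threshold = 0.25) {
  if (is.numeric(est)) return(as.numeric(est))
  ests <- est$estimates
  if (!length(ests)) stop("estimate set with zero analyst estimates")
  g <- vapply(ests, function(e) as.numeric(e$grams), 0)
  if (length(g) == 1) return(g)
  a <- g[1]; b <- g[2]
  rel <- abs(a - b) / mean(c(a, b))
  if (rel <= threshold) return(mean(c(a, b)))
  third <- est$third
  if (is.null(third) && length(g) >= 3) third <- g[3]
  if (!is.null(third)) return(as.numeric(third))
  NA_real_
}

#' Impute an unresolved portion
#'
#' Hierarchy used when no quantity could be resolved for a serving:
#' \enumerate{
#'   \item median of the resolved portions of the same item in the same
#'     context (the same participant for own-plate servings, the same
#'     household's shared servings for shared plates);
#'   \item median of all resolved portions of the item among participants
#'     of the same type (mother or child);
#'   \item the reference-portion table default.
#' }
#' Only portions resolved directly (never themselves imputed) feed the
#' medians, so imputation cannot feed back into itself.
#'
#' @param item_ref Food or recipe identifier.
#' @param context_id Participant id (own plate) or household id (shared).
#' @param role `"mother"`, `"child"` or `"shared"`.
#' @param portions Data frame of resolved portions with columns
#'   `item_ref`, `context_id`, `role`, `grams`.
#' @param fallback A `reference_portions` table or `NULL`.
#' @return A list with `grams` and `level` (1, 2 or 3).
#' @export
impute_portion <- function(item_ref, context_id, role, portions,
                           fallback = NULL) {
  if (!is.null(portions) && nrow(portions)) {
    same_ctx <- portions$grams[portions$item_ref == item_ref &
                               portions$context_id == context_id]
    if (length(same_ctx)) {
      return(list(grams = stats::median(same_ctx), level = 1L))
    }
    same_role <- portions$grams[portions$item_ref == item_ref &
                                portions$role == role]
    if (length(same_role)) {
      return(list(grams = stats::median(same_role), level = 2L))
    }
  }
  ref <- reference_default(fallback, item_ref)
  if (!is.na(ref)) return(list(grams = ref, level = 3L))
  stop(sprintf("no portion data available to impute item '%s'", item_ref))
}

#' Per-100 g nutrient profile of a home recipe
#'
#' For each nutrient the recipe total is the sum over ingredients of
#' `grams/100 * per-100 g value * retention factor(nutrient, cooking
#' method)`. The per-100 g profile divides by the prepared weight `W`:
#' the recorded final weight when available, otherwise the sum of raw
#' ingredient weights.
#'
#' @param recipe A recipe record: `list(recipe_id =, ingredients = list(
#'   list(food_id =, grams =, cooking_method =)), final_weight = NULL)`.
#' @param fcd An `fcd` object.
#' @param rf A `retention_table` or `NULL` (no losses).
#' @return Named numeric per-100 g profile over the table's panel.
#' @export
recipe_profile <- function(recipe, fcd, rf = NULL) {
  if (!length(recipe$ingredients)) {
    stop("recipe '", recipe$recipe_id %||% "?", "' has no ingredients")
  }
  total <- setNames(numeric(length(fcd$panel)), fcd$panel)
  raw_mass <- 0
  for (ing in recipe$ingredients) {
    prof <- fcd_profile(fcd, ing$food_id)
    keep <- retention_lookup(rf, fcd$panel, ing$cooking_method %||% NA)
    total <- total + ing$grams / 100 * prof * keep
    raw_mass <- raw_mass + ing$grams
  }
  w <- recipe$final_weight %||% raw_mass
  total * 100 / w
}

#' Amount of a serving actually consumed
#'
#' @param served Served grams.
#' @param leftover Leftover grams.
#' @param status Consumption status: `eaten_completely` forces the full
#'   served amount, `not_consumed` forces zero, `partial` subtracts the
#'   leftover.
#' @return Consumed grams (never negative).
#' @export
consumed_amount <- function(served, leftover,
                            status = c("partial", "eaten_completely",
                                       "not_consumed")) {
  status <- match.arg(status)
  switch(status,
    eaten_completely = served,
    not_consumed = 0,
    partial = max(served - leftover, 0)
  )
}

#' Apportion a shared serving evenly among its eaters
#'
#' The consumed total is split evenly over everyone who ate from the
#' serving -- participating or not, adult or child -- and each listed
#' participant is assigned one share; nonparticipants' shares are
#' discarded. A serving shared by one participating adult and two
#' nonparticipating adults therefore assigns one third of the consumed
#' total to the participant.
#'
#' @param consumed_total Consumed grams of the shared serving.
#' @param roster Eater roster: `list(participant_ids =,
#'   n_nonparticipant_adults =, n_nonparticipant_children =)`.
#' @return Named numeric vector of grams, one entry per listed
#'   participant.
#' @export
#' @examples
#' apportion_shared(300, list(participant_ids = "M1",
#'                            n_nonparticipant_adults = 2,
#'                            n_nonparticipant_children = 0))  # 100
apportion_shared <- function(consumed_total, roster) {
  pids <- as.character(unlist(roster$participant_ids))
  n_total <- length(pids) + (roster$n_nonparticipant_adults %||% 0) +
    (roster$n_nonparticipant_children %||% 0)
  if (n_total < 1) stop("eater roster must total >= 1")
  share <- consumed_total / n_total
  setNames(rep(share, length(pids)), pids)
}

resolve_serving_amounts <- function(s, threshold) {
  served <- reconcile_portion(s$served, threshold)
  leftover_raw <- s$leftover %||% 0
  status <- s$consumption_status %||% "partial"
  leftover <- if (status == "eaten_completely") {
    0
  } else if (status == "not_consumed") {
    served
  } else {
    reconcile_portion(leftover_raw, threshold)
  }
  list(served = served, leftover = leftover, status = status)
}

serving_context <- function(s, hh) {
  if (s$serving_type == "own") {
    list(context_id = as.character(unlist(s$eaters$participant_ids))[1],
         role = NA_character_)  # role filled by caller
  } else {
    list(context_id = hh$household_id, role = "shared")
  }
}

#' Compute per-participant daily nutrient intakes
#'
#' The composition of the whole intake-processing workflow: analyst
#' estimates are reconciled, still-unresolved portions imputed from
#' median portions, home-recipe profiles built once per household and
#' reused across that household's occasions, leftovers subtracted,
#' shared servings apportioned evenly across eaters, and consumed grams
#' converted to nutrients through per-100 g profiles. Voice addenda for
#' forgotten foods are ordinary own-plate servings in the record model.
#' The supervised training day is always dropped.
#'
#' @param records A validated `intake_recordset`.
#' @param fcd An `fcd` object covering every food referenced.
#' @param rf Optional `retention_table` for recipe cooking losses.
#' @param fallback Optional `reference_portions` table for last-resort
#'   imputation.
#' @param threshold Analyst reconciliation tolerance (default 0.25).
#' @return A data frame with one row per participant-day: columns
#'   `participant_id`, `household_id`, `role`, `site`, `period`,
#'   `day_index`, then one column per panel nutrient (absolute amounts
#'   for the day). Attribute `imputation_log` records which hierarchy
#'   level resolved each imputed serving.
#' @export
compute_daily_intakes <- function(records, fcd, rf = NULL, fallback = NULL,
                                  threshold = 0.25) {
  stopifnot(inherits(records, "intake_recordset"), inherits(fcd, "fcd"))
  pt <- participants_table(records)
  role_of <- setNames(pt$role, pt$participant_id)
  panel <- fcd$panel

  # Pass 1: resolve amounts; collect directly resolved portions for the
  # imputation medians (own servings keyed by participant, shared by
  # household).
  resolved <- list()
  portion_rows <- list()
  for (hi in seq_along(records$households)) {
    hh <- records$households[[hi]]
    for (di in seq_along(hh$days %||% list())) {
      d <- hh$days[[di]]
      if (isTRUE(d$training)) next
      for (oi in seq_along(d$occasions %||% list())) {
        occ <- d$occasions[[oi]]
        for (si in seq_along(occ$servings)) {
          s <- occ$servings[[si]]
          key <- paste(hi, di, oi, si, sep = "/")
          amounts <- resolve_serving_amounts(s, threshold)
          resolved[[key]] <- amounts
          if (!is.na(amounts$served)) {
            ctx <- serving_context(s, hh)
            role <- if (s$serving_type == "own") {
              role_of[[ctx$context_id]]
            } else "shared"
            portion_rows[[length(portion_rows) + 1L]] <- data.frame(
              item_ref = s$item_ref, context_id = ctx$context_id,
              role = role, grams = amounts$served,
              stringsAsFactors = FALSE
            )
          }
        }
      }
    }
  }
  portions <- if (length(portion_rows)) {
    do.call(rbind, portion_rows)
  } else {
    data.frame(item_ref = character(0), context_id = character(0),
               role = character(0), grams = numeric(0))
  }

  # Recipe profiles, built once per household and reused.
  recipe_profiles <- list()
  for (hh in records$households) {
    for (r in hh$recipes %||% list()) {
      recipe_profiles[[paste(hh$household_id, r$recipe_id)]] <-
        recipe_profile(r, fcd, rf)
    }
  }

  imputation_log <- list()
  day_rows <- list()
  for (hi in seq_along(records$households)) {
    hh <- records$households[[hi]]
    hh_pids <- vapply(hh$participants, function(p) as.character(p$participant_id), "")
    for (di in seq_along(hh$days %||% list())) {
      d <- hh$days[[di]]
      if (isTRUE(d$training)) next
      totals <- matrix(0, nrow = length(hh_pids), ncol = length(panel),
                       dimnames = list(hh_pids, panel))
      present <- setNames(rep(FALSE, length(hh_pids)), hh_pids)
      for (oi in seq_along(d$occasions %||% list())) {
        occ <- d$occasions[[oi]]
        for (si in seq_along(occ$servings)) {
          s <- occ$servings[[si]]
          spath <- sprintf("households/%d/days/%d/occasions/%d/servings/%d",
                           hi, di, oi, si)
          pids <- as.character(unlist(s$eaters$participant_ids))
          present[pids] <- TRUE
          amounts <- resolved[[paste(hi, di, oi, si, sep = "/")]]
          served <- amounts$served
          leftover <- amounts$leftover
          if (is.na(served)) {
            ctx <- serving_context(s, hh)
            role <- if (s$serving_type == "own") role_of[[ctx$context_id]] else "shared"
            imp <- tryCatch(
              impute_portion(s$item_ref, ctx$context_id, role, portions,
                             fallback),
              error = function(e) stop(conditionMessage(e), " [at ", spath, "]",
                                       call. = FALSE)
            )
            served <- imp$grams
            imputation_log[[length(imputation_log) + 1L]] <- data.frame(
              path = spath, item_ref = s$item_ref, field = "served",
              level = imp$level, grams = served, stringsAsFactors = FALSE
            )
          }
          if (is.na(leftover)) {
            # an unresolved leftover estimate: impute like a portion, but
            # never beyond what was served
            ctx <- serving_context(s, hh)
            role <- if (s$serving_type == "own") role_of[[ctx$context_id]] else "shared"
            imp <- tryCatch(
              impute_portion(s$item_ref, ctx$context_id, role, portions,
                             fallback),
              error = function(e) stop(conditionMessage(e), " [at ", spath, "]",
                                       call. = FALSE)
            )
            leftover <- min(imp$grams, served)
            imputation_log[[length(imputation_log) + 1L]] <- data.frame(
              path = spath, item_ref = s$item_ref, field = "leftover",
              level = imp$level, grams = leftover, stringsAsFactors = FALSE
            )
          }
          if (leftover > served + 1e-9) {
            stop(sprintf("leftover (%g g) exceeds served (%g g) [at %s]",
                         leftover, served, spath), call. = FALSE)
          }
          consumed <- consumed_amount(served, min(leftover, served),
                                      amounts$status)
          if (consumed <= 0) next
          prof <- if ((s$item_kind %||% "food") == "recipe") {
            recipe_profiles[[paste(hh$household_id, s$item_ref)]]
          } else {
            tryCatch(fcd_profile(fcd, s$item_ref),
                     error = function(e) stop(conditionMessage(e), " [at ",
                                              spath, "]", call. = FALSE))
          }
          if (s$serving_type == "shared") {
            shares <- apportion_shared(consumed, s$eaters)
            for (pid in names(shares)) {
              totals[pid, ] <- totals[pid, ] + shares[[pid]] / 100 * prof
            }
          } else {
            pid <- pids[1]
            totals[pid, ] <- totals[pid, ] + consumed / 100 * prof
          }
        }
      }
      for (pid in hh_pids[present]) {
        row <- data.frame(
          participant_id = pid, household_id = hh$household_id,
          role = role_of[[pid]], site = hh$site,
          period = d$period, day_index = d$day_index,
          stringsAsFactors = FALSE
        )
        row[panel] <- as.list(totals[pid, ])
        day_rows[[length(day_rows) + 1L]] <- row
      }
    }
  }
  out <- if (length(day_rows)) {
    do.call(rbind, day_rows)
  } else {
    empty <- data.frame(participant_id = character(0),
                        household_id = character(0), role = character(0),
                        site = character(0), period = character(0),
                        day_index = integer(0))
    empty[panel] <- lapply(panel, function(x) numeric(0))
    empty
  }
  rownames(out) <- NULL
  attr(out, "imputation_log") <- if (length(imputation_log)) {
    do.call(rbind, imputation_log)
  } else NULL
  out
}

#' Average daily intakes into per-period intakes
#'
#' The arithmetic mean of each participant's recorded days within each
#' recording period: the observation unit of the mixed-model analysis.
#' Periods with fewer than 2 recorded days are kept but flagged
#' (`n_days`), so the inclusion filter can act on them.
#'
#' @param daily Output of [compute_daily_intakes()].
#' @return Data frame with one row per (participant, period): id
#'   columns, `n_days`, then panel nutrient means.
#' @export
period_means <- function(daily) {
  id_cols <- c("participant_id", "household_id", "role", "site", "period")
  nut_cols <- setdiff(names(daily), c(id_cols, "day_index"))
  if (!nrow(daily)) {
    out <- daily[, id_cols, drop = FALSE]
    out$n_days <- integer(0)
    out[nut_cols] <- daily[nut_cols]
    return(out)
  }
  agg <- stats::aggregate(daily[nut_cols],
                          by = daily[id_cols], FUN = mean)
  n <- stats::aggregate(list(n_days = daily$day_index),
                        by = daily[id_cols], FUN = length)
  out <- merge(n, agg, by = id_cols, sort = TRUE)
  rownames(out) <- NULL
  out
}
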