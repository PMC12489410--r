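#' Default nutrient panels
#'
#' The adult (mother) panel covers 20 nutrients; the child panel is the
#' same set without alcohol (19 nutrients). Energy is in kcal; protein,
#' fat, carbohydrate, fiber and alcohol in g; vitamins and minerals in mg
#' or ug as conventional for each nutrient (vitamin A as retinol
#' equivalents, folate as dietary folate equivalents).
#'
#' @param role `"mother"` or `"child"`.
#' @return Character vector of nutrient names.
#' @export
#' @examples
#' default_nutrient_panel("mother")
default_nutrient_panel <- function(role = c("mother", "child")) {
  role <- match.arg(role)
  panel <- c(
    "energy", "protein", "fat", "carbohydrate", "fiber", "alcohol",
    "vitamin_a_re", "thiamine", "riboflavin", "niacin", "vitamin_b6",
    "vitamin_b12", "vitamin_c", "dfe", "calcium", "phosphorus",
    "sodium", "potassium", "iron", "zinc"
  )
  if (role == "child") panel <- setdiff(panel, "alcohol")
  panel
}

#' Load a food composition table
#'
#' Reads a per-100 g food composition CSV (`food_id,name,group` plus one
#' column per nutrient) and, optionally, a companion household-measure CSV
#' (`food_id,measure_label,grams`). Foods missing a panel nutrient column
#' get 0 for that nutrient, with one warning per nutrient counting the
#' affected foods; the table remains usable and auditable.
#'
#' @param path Path to the food composition CSV.
#' @param nutrient_panel Character vector of nutrient names required for
#'   the run (see [default_nutrient_panel()]).
#' @param measures_path Optional path to the household-measure CSV.
#' @return An object of class `fcd` with elements `foods` (data frame),
#'   `nutrients` (numeric matrix, foods x panel, rownames = food ids),
#'   `measures` (data frame or NULL) and `panel`.
#' @export
load_fcd <- function(path, nutrient_panel = default_nutrient_panel("mother"),
                     measures_path = NULL) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("food_id", "name", "group")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    stop("food composition CSV is missing column(s): ",
         paste(miss, collapse = ", "))
  }
  raw$food_id <- as.character(raw$food_id)
  dup <- unique(raw$food_id[duplicated(raw$food_id)])
  if (length(dup)) {
    stop("duplicate food_id in food composition table: ",
         paste(dup, collapse = ", "))
  }
  nut <- matrix(0, nrow = nrow(raw), ncol = length(nutrient_panel),
                dimnames = list(raw$food_id, nutrient_panel))
  for (nm in nutrient_panel) {
    if (!nm %in% names(raw)) {
      warning(sprintf(
        "nutrient '%s' missing from food composition table; set to 0 for %d food(s)",
        nm, nrow(raw)), call. = FALSE)
      next
    }
    v <- suppressWarnings(as.numeric(raw[[nm]]))
    na <- is.na(v) & !is.na(raw[[nm]]) & raw[[nm]] != ""
    if (any(na)) {
      stop(sprintf("non-numeric value for nutrient '%s' at food_id %s",
                   nm, raw$food_id[which(na)[1]]))
    }
    blank <- is.na(v)
    if (any(blank)) {
      warning(sprintf(
        "nutrient '%s' missing from food composition table; set to 0 for %d food(s)",
        nm, sum(blank)), call. = FALSE)
      v[blank] <- 0
    }
    if (any(v < 0)) {
      bad <- which(v < 0)[1]
      stop(sprintf("negative value for nutrient '%s' at food_id %s",
                   nm, raw$food_id[bad]))
    }
    if (any(!is.finite(v))) {
      stop(sprintf("non-finite value for nutrient '%s'", nm))
    }
    nut[, nm] <- v
  }
  measures <- NULL
  if (!is.null(measures_path)) {
    measures <- utils::read.csv(measures_path, stringsAsFactors = FALSE)
    need_m <- c("food_id", "measure_label", "grams")
    if (!all(need_m %in% names(measures))) {
      stop("measures CSV must have columns food_id, measure_label, grams")
    }
    measures$food_id <- as.character(measures$food_id)
    if (any(!is.finite(measures$grams)) || any(measures$grams <= 0)) {
      stop("all measure weights must be finite and > 0")
    }
    unknown <- setdiff(measures$food_id, raw$food_id)
    if (length(unknown)) {
      stop("measures reference unknown food_id: ",
           paste(unknown, collapse = ", "))
    }
    key <- paste(measures$food_id, measures$measure_label)
    if (anyDuplicated(key)) {
      stop("duplicate (food_id, measure_label) in measures CSV")
    }
  }
  structure(
    list(foods = raw[, need], nutrients = nut, measures = measures,
         panel = nutrient_panel),
    class = "fcd"
  )
}

#' @export
print.fcd <- function(x, ...) {
  cat(sprintf("Food composition table: %d foods, %d-nutrient panel\n",
              nrow(x$foods), length(x$panel)))
  cat("Panel:", paste(x$panel, collapse = ", "), "\n")
  if (!is.null(x$measures)) {
    cat(sprintf("Household measures: %d entries\n", nrow(x$measures)))
  }
  invisible(x)
}

#' Write a food composition table
#'
#' Inverse of [load_fcd()]. Numeric values are written with 17 significant
#' digits so a load/write/load round trip reproduces every value exactly.
#'
#' @param fcd An `fcd` object.
#' @param path Output CSV path.
#' @param measures_path Optional path for the measures CSV.
#' @return `path`, invisibly.
#' @export
write_fcd <- function(fcd, path, measures_path = NULL) {
  stopifnot(inherits(fcd, "fcd"))
  out <- fcd$foods
  for (nm in fcd$panel) {
    out[[nm]] <- sprintf("%.17g", fcd$nutrients[, nm])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  if (!is.null(measures_path) && !is.null(fcd$measures)) {
    m <- fcd$measures
    m$grams <- sprintf("%.17g", m$grams)
    utils::write.csv(m, measures_path, row.names = FALSE, quote = TRUE)
  }
  invisible(path)
}

#' Per-100 g nutrient profile of a food
#'
#' @param fcd An `fcd` object.
#' @param food_id Food identifier.
#' @return Named numeric vector over the table's nutrient panel.
#' @export
fcd_profile <- function(fcd, food_id) {
  stopifnot(inherits(fcd, "fcd"))
  if (!food_id %in% rownames(fcd$nutrients)) {
    stop("unknown food_id: ", food_id)
  }
  fcd$nutrients[food_id, ]
}

#' Load a cooking retention-factor table
#'
#' CSV columns `nutrient,cooking_method,factor`, one row per pair. Factors
#' are the fraction of the nutrient retained after the cooking method and
#' must lie in \[0, 1\]; out-of-range factors are a load-time error, so
#' lookups never fail.
#'
#' @param path Path to the retention CSV.
#' @return An object of class `retention_table`.
#' @export
load_retention <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("nutrient", "cooking_method", "factor")
  if (!all(need %in% names(raw))) {
    stop("retention CSV must have columns nutrient, cooking_method, factor")
  }
  raw$factor <- as.numeric(raw$factor)
  bad <- !is.finite(raw$factor) | raw$factor < 0 | raw$factor > 1
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf("retention factor out of [0, 1] for (%s, %s): %s",
                 raw$nutrient[i], raw$cooking_method[i],
                 format(raw$factor[i])))
  }
  key <- paste(raw$nutrient, raw$cooking_method)
  if (anyDuplicated(key)) {
    stop("duplicate (nutrient, cooking_method) in retention CSV")
  }
  structure(list(factors = raw), class = "retention_table")
}

#' Retention-factor lookup
#'
#' Total over its domain: an absent (nutrient, cooking method) pair -- or a
#' `NULL` table, or a missing cooking method -- returns 1 (no loss).
#'
#' @param table A `retention_table` or `NULL`.
#' @param nutrient Character vector of nutrient names.
#' @param method Single cooking-method name (or `NA`/`NULL`).
#' @return Numeric vector of factors in \[0, 1\], one per nutrient.
#' @export
#' @examples
#' retention_lookup(NULL, "thiamine", "boiled")  # 1
retention_lookup <- function(table, nutrient, method) {
  out <- rep(1, length(nutrient))
  names(out) <- nutrient
  if (is.null(table) || is.null(method) || is.na(method)) return(out)
  f <- table$factors
  hit <- f[f$cooking_method == method, , drop = FALSE]
  if (nrow(hit)) {
    m <- match(nutrient, hit$nutrient)
    out[!is.na(m)] <- hit$factor[m[!is.na(m)]]
  }
  out
}

#' Load a reference-portion table
#'
#' Fallback portion weights used at the last level of the imputation
#' hierarchy when no observed portion of a food is available. CSV columns
#' `food_id,portion_label,grams`; labels must be unique per food and
#' weights positive.
#'
#' @param path Path to the CSV.
#' @return An object of class `reference_portions`.
#' @export
load_reference_portions <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("food_id", "portion_label", "grams")
  if (!all(need %in% names(raw))) {
    stop("reference portion CSV must have columns food_id, portion_label, grams")
  }
  raw$food_id <- as.character(raw$food_id)
  raw$grams <- as.numeric(raw$grams)
  if (any(!is.finite(raw$grams)) || any(raw$grams <= 0)) {
    stop("all reference portion weights must be finite and > 0")
  }
  if (anyDuplicated(paste(raw$food_id, raw$portion_label))) {
    stop("duplicate (food_id, portion_label) in reference portion CSV")
  }
  structure(list(entries = raw), class = "reference_portions")
}

#' Default reference portion of a food
#'
#' The median over the food's listed portion weights, or `NA` if the food
#' has no entry.
#'
#' @param refs A `reference_portions` object or `NULL`.
#' @param food_id Food identifier.
#' @return Grams (length-1 numeric), possibly `NA`.
#' @export
reference_default <- function(refs, food_id) {
  if (is.null(refs)) return(NA_real_)
  g <- refs$entries$grams[refs$entries$food_id == food_id]
  if (!length(g)) return(NA_real_)
  stats::median(g)
}
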