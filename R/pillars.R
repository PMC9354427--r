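#' @keywords internal
"_PACKAGE"

# Ordinal category labels used throughout the survey schema.
# Comparisons are always on category order, never on midpoints.
FV_LEVELS  <- c("0", "1-2", "3-4", "5+")
SED_LEVELS <- c("0h", "1-2h", "3-4h", "5+h")
PILLAR_VARS <- c("sleep_met", "fv_met", "sedentary_met", "mvpa_met",
                 "nonsmoking_met")

#' Body mass index from US-customary height and weight
#'
#' BMI (kg/m^2) from self-reported height in inches and weight in pounds,
#' using the conventional conversion `703 * weight / height^2`. Missing or
#' non-positive inputs yield `NA` rather than an error.
#'
#' @param height_in Height in inches (> 0).
#' @param weight_lb Weight in pounds (> 0).
#' @return Numeric vector of BMI values (kg/m^2), `NA` where undefined.
#' @examples
#' compute_bmi(65, 150)  # 24.96
#' @export
compute_bmi <- function(height_in, weight_lb) {
  bad <- is.na(height_in) | is.na(weight_lb) | height_in <= 0 | weight_lb <= 0
  out <- 703 * weight_lb / height_in^2
  out[bad] <- NA_real_
  out
}

#' Code the sleep pillar
#'
#' Met when reported average nightly sleep reaches the standard: 8 hours for
#' the main analysis, 7 hours for the sensitivity setting.
#'
#' @param sleep_hours Average sleep per night, hours.
#' @param standard `"8h"` (default) or `"7h"`.
#' @return Logical vector (`TRUE` = met, `NA` = missing).
#' @export
code_sleep <- function(sleep_hours, standard = c("8h", "7h")) {
  standard <- match.arg(standard)
  cut <- if (standard == "8h") 8 else 7
  neg <- !is.na(sleep_hours) & sleep_hours < 0
  if (any(neg)) {
    warning(sum(neg), " negative sleep duration(s) set to missing")
    sleep_hours[neg] <- NA_real_
  }
  sleep_hours >= cut
}

fv_ord <- function(x) {
  if (is.factor(x)) x <- as.character(x)
  match(x, FV_LEVELS)
}

#' Code the fruit-and-vegetable pillar
#'
#' The default ("literal") rule reproduces the published clause list: met when
#' fruits are at least "3-4" servings with vegetables at least "1-2", or
#' vegetables are "5+" with fruits at least "1-2". With `symmetric_fv = TRUE`
#' the mirrored clause (vegetables "3-4" with fruits at least "1-2") also
#' counts as met, symmetrizing the rule in fruits vs vegetables.
#'
#' @param fruit_cat,veg_cat Ordinal servings/day categories, one of
#'   `"0"`, `"1-2"`, `"3-4"`, `"5+"`.
#' @param symmetric_fv Logical; enable the symmetric variant.
#' @return Logical vector (`NA` when either category is missing).
#' @export
code_fruit_veg <- function(fruit_cat, veg_cat, symmetric_fv = FALSE) {
  f <- fv_ord(fruit_cat)
  v <- fv_ord(veg_cat)
  met <- (f >= 3 & v >= 2) | (v == 4 & f >= 2)
  if (symmetric_fv) met <- met | (v == 3 & f >= 2)
  met[is.na(f) | is.na(v)] <- NA
  met
}

#' Weekly moderate-to-vigorous physical activity minutes
#'
#' Days of vigorous activity count 20 minutes per bout-day and days of
#' moderate activity 30 minutes, summed to minutes per week.
#'
#' @param vigorous_days,moderate_days Days per week, integers 0-7.
#' @return Minutes/week of MVPA; `NA` where either input is missing.
#' @export
compute_mvpa_minutes <- function(vigorous_days, moderate_days) {
  20 * vigorous_days + 30 * moderate_days
}

#' Code the physical-activity pillar
#'
#' Met when weekly MVPA minutes reach 150.
#' @param mvpa_minutes Minutes/week (see [compute_mvpa_minutes()]).
#' @return Logical vector.
#' @export
code_mvpa <- function(mvpa_minutes) mvpa_minutes >= 150

#' Code the sedentary-time pillar
#'
#' Met for the "0h" and "1-2h" daily sitting/screen-time categories; not met
#' for "3-4h" and "5+h".
#' @param sedentary_cat Ordinal category, one of `"0h"`, `"1-2h"`, `"3-4h"`,
#'   `"5+h"`.
#' @return Logical vector.
#' @export
code_sedentary <- function(sedentary_cat) {
  if (is.factor(sedentary_cat)) sedentary_cat <- as.character(sedentary_cat)
  s <- match(sedentary_cat, SED_LEVELS)
  s <= 2
}

#' Code the non-smoking pillar
#'
#' Met for participants not currently smoking.
#' @param current_smoker Logical (or 0/1).
#' @return Logical vector.
#' @export
code_smoking <- function(current_smoker) {
  !as.logical(current_smoker)
}

#' Pillar count from the five indicators
#'
#' Sum of pillar indicators met. The count is `NA` whenever any indicator is
#' missing: a count built from partial data would be a lower bound rather than
#' a sum, so partial profiles do not contribute a count.
#'
#' @param ... Either five logical vectors (in any order) or a single
#'   data.frame/matrix with five indicator columns.
#' @return Integer vector with values 0-5 or `NA`.
#' @export
count_pillars <- function(...) {
  args <- list(...)
  m <- if (length(args) == 1L && (is.data.frame(args[[1]]) || is.matrix(args[[1]])))
    as.matrix(args[[1]]) else do.call(cbind, args)
  storage.mode(m) <- "logical"
  out <- as.integer(rowSums(m))
  out[rowSums(is.na(m)) > 0] <- NA_integer_
  out
}

#' Code a raw twin-registry survey table
#'
#' Applies all five pillar coding rules, the pillar count, and the outcome
#' transforms (BMI from height/weight with its natural log; PHQ-2 total from
#' the two items with its square root) to a long-format table of one row per
#' twin. Recoding an already-coded table simply recomputes the same columns,
#' so the operation is idempotent.
#'
#' @param data Data frame with the raw survey columns (`sleep_duration`,
#'   `fruit_cat`, `veg_cat`, `sedentary_cat`, `vigorous_days`,
#'   `moderate_days`, `current_smoker`, `phq_item1`, `phq_item2`, `height`,
#'   `weight`, plus identifiers).
#' @param sleep_standard `"8h"` (default) or `"7h"`.
#' @param symmetric_fv Logical; see [code_fruit_veg()].
#' @return The input with appended columns `sleep_met`, `fv_met`,
#'   `sedentary_met`, `mvpa_met`, `nonsmoking_met`, `mvpa_minutes`,
#'   `n_pillars`, `bmi`, `log_bmi`, `phq_total`, `sqrt_phq`.
#' @export
code_pillars <- function(data, sleep_standard = c("8h", "7h"),
                         symmetric_fv = FALSE) {
  sleep_standard <- match.arg(sleep_standard)
  data$sleep_met      <- code_sleep(data$sleep_duration, sleep_standard)
  data$fv_met         <- code_fruit_veg(data$fruit_cat, data$veg_cat,
                                        symmetric_fv)
  data$sedentary_met  <- code_sedentary(data$sedentary_cat)
  data$mvpa_minutes   <- compute_mvpa_minutes(data$vigorous_days,
                                              data$moderate_days)
  data$mvpa_met       <- code_mvpa(data$mvpa_minutes)
  data$nonsmoking_met <- code_smoking(data$current_smoker)
  data$n_pillars      <- count_pillars(data[PILLAR_VARS])
  data$bmi            <- compute_bmi(data$height, data$weight)
  data$log_bmi        <- log(data$bmi)
  data$phq_total      <- data$phq_item1 + data$phq_item2
  data$sqrt_phq       <- sqrt(data$phq_total)
  attr(data, "sleep_standard") <- sleep_standard
  data
}

#' Pillar count over a named subset of pillars
#'
#' Counts met indicators over a subset such as the two most important pillars
#' for an outcome. Missing on any member of the subset gives `NA`.
#'
#' @param data Coded data (see [code_pillars()]).
#' @param pillars Character vector of indicator column names, or one of the
#'   presets `"all"`, `"bmi_top2"` (MVPA + sedentary), `"phq_top2"`
#'   (sedentary + smoking).
#' @return Integer count vector.
#' @export
pillar_count <- function(data, pillars = "all") {
  cols <- resolve_pillars(pillars)
  count_pillars(data[cols])
}

resolve_pillars <- function(pillars) {
  if (length(pillars) == 1L && pillars %in% c("all", "bmi_top2", "phq_top2")) {
    pillars <- switch(pillars,
      all      = PILLAR_VARS,
      bmi_top2 = c("mvpa_met", "sedentary_met"),
      phq_top2 = c("sedentary_met", "nonsmoking_met"))
  }
  stopifnot(all(pillars %in% PILLAR_VARS), length(pillars) >= 1L)
  pillars
}
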