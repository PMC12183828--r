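#' FFQ frequency categories
#'
#' The eight predefined consumption-frequency response categories, in
#' increasing order.
#'
#' @return Ordered character vector of length 8.
#' @export
ffq_frequency_levels <- function() {
  c("never/seldom", "1-3 times per month", "1-2 times per week",
    "3-4 times per week", "5-6 times per week", "once a day",
    "2 times a day", ">=3 times per day")
}

# Category midpoints in servings/day. Month taken as 30.4 days; weekly
# categories use the interval midpoint, the open top category its floor.
ffq_midpoints <- function() {
  c("never/seldom" = 0,
    "1-3 times per month" = 2 / 30.4,
    "1-2 times per week" = 1.5 / 7,
    "3-4 times per week" = 3.5 / 7,
    "5-6 times per week" = 5.5 / 7,
    "once a day" = 1,
    "2 times a day" = 2,
    ">=3 times per day" = 3)
}

#' Convert FFQ frequency categories to servings/day
#'
#' Maps each categorical frequency response to a daily serving estimate:
#' the category's midpoint frequency times a portion multiplier. The mapping
#' is monotone in category order.
#'
#' @param category Character vector of categories from
#'   [ffq_frequency_levels()].
#' @param portion_multiplier Positive scalar scaling all categories
#'   (e.g. age-specific portion size).
#' @return Numeric vector of servings/day.
#' @export
frequency_to_servings <- function(category, portion_multiplier = 1) {
  if (!is.numeric(portion_multiplier) || portion_multiplier <= 0)
    stop("portion_multiplier must be positive", call. = FALSE)
  mid <- ffq_midpoints()
  unknown <- setdiff(unique(category), names(mid))
  if (length(unknown))
    stop("unknown frequency category: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  unname(mid[category] * portion_multiplier)
}

#' Read an FFQ item to food-group mapping
#'
#' @param file YAML file mapping item names to food-group names.
#' @return Named character vector (item -> group).
#' @export
read_food_group_mapping <- function(file) {
  mapping <- unlist(yaml::read_yaml(file))
  if (anyDuplicated(names(mapping)))
    stop("each FFQ item must map to exactly one group", call. = FALSE)
  mapping
}

#' Aggregate FFQ item intakes into food groups
#'
#' Group intake is the sum of member items' servings/day; aggregation is
#' invariant to item order.
#'
#' @param item_intakes Named numeric vector of item servings/day.
#' @param mapping Named character vector (item -> group), e.g. from
#'   [read_food_group_mapping()].
#' @param unit "servings/day" or "servings/week" (the latter multiplies
#'   by 7).
#' @return Named numeric vector over all groups appearing in `mapping`
#'   (groups with no consumed items are 0).
#' @export
aggregate_food_groups <- function(item_intakes, mapping,
                                  unit = c("servings/day", "servings/week")) {
  unit <- match.arg(unit)
  groups <- unique(unname(mapping))
  out <- stats::setNames(numeric(length(groups)), groups)
  if (length(item_intakes)) {
    unmapped <- setdiff(names(item_intakes), names(mapping))
    if (length(unmapped))
      stop("unmapped FFQ item: ", paste(unmapped, collapse = ", "),
           call. = FALSE)
    sums <- tapply(item_intakes, mapping[names(item_intakes)], sum)
    out[names(sums)] <- sums
  }
  if (unit == "servings/week") out <- out * 7
  out
}

#' Apply the cohort exclusion rules
#'
#' Removes participants in the order the rules are stated: hsCRP above
#' 20 mg/L, missing IL-6, missing TNF-R1/TNF-R2, missing education, then
#' implausible energy intake (more than 3 SD from the mean of log energy,
#' mean and SD computed once on the input cohort). Each removal is logged
#' with a reason code; a participant can carry several reasons.
#'
#' @param cohort Cohort data.frame with hscrp, il6, tnfr1, tnfr2, education
#'   and energy columns.
#' @return list(cohort = retained rows, log = data.frame(id, reason)).
#' @export
apply_exclusions <- function(cohort) {
  if (nrow(cohort) == 0) stop("empty cohort", call. = FALSE)
  needed <- c("hscrp", "il6", "tnfr1", "tnfr2", "education", "energy")
  miss <- setdiff(needed, names(cohort))
  if (length(miss))
    stop("cohort lacks columns: ", paste(miss, collapse = ", "), call. = FALSE)

  log_energy <- log(cohort$energy)
  e_mean <- mean(log_energy, na.rm = TRUE)
  e_sd <- stats::sd(log_energy, na.rm = TRUE)

  reasons <- list(
    `hsCRP>20` = !is.na(cohort$hscrp) & cohort$hscrp > 20,
    `missing IL-6` = is.na(cohort$il6),
    `missing TNF-R1/R2` = is.na(cohort$tnfr1) | is.na(cohort$tnfr2),
    `missing education` = is.na(cohort$education),
    `implausible energy` = is.na(log_energy) |
      abs(log_energy - e_mean) > 3 * e_sd
  )
  flagged <- Reduce(`|`, reasons)
  log <- do.call(rbind, lapply(names(reasons), function(r) {
    idx <- which(reasons[[r]])
    if (!length(idx)) return(NULL)
    data.frame(id = cohort$id[idx], reason = r, stringsAsFactors = FALSE)
  }))
  if (is.null(log))
    log <- data.frame(id = character(), reason = character(),
                      stringsAsFactors = FALSE)
  kept <- cohort[!flagged, , drop = FALSE]
  attr(kept, "foods") <- attr(cohort, "foods")
  list(cohort = kept, log = log)
}

#' Write an exclusion log as TSV
#'
#' @param log data.frame(id, reason) from [apply_exclusions()].
#' @param file Output path.
#' @export
write_exclusion_log <- function(log, file) {
  utils::write.table(log, file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Add the log2 hsCRP column
#'
#' hsCRP is measured in mg/L and analysed on the log2 scale; the Olink
#' markers are already log2 NPX and pass through unchanged. The original
#' hsCRP column is retained for threshold-based filters.
#'
#' @param cohort Cohort data.frame with positive `hscrp`.
#' @return Cohort with an added `log2_hscrp` column.
#' @export
transform_biomarkers <- function(cohort) {
  if (any(cohort$hscrp <= 0, na.rm = TRUE))
    stop("non-positive hsCRP concentration", call. = FALSE)
  cohort$log2_hscrp <- log2(cohort$hscrp)
  cohort
}

#' Random half-split into Discovery and Replication groups
#'
#' Disjoint, exhaustive, deterministic for a given seed. With odd n the
#' Discovery group receives the extra participant.
#'
#' @param cohort Cohort data.frame, n >= 2.
#' @param seed Integer seed for the random assignment.
#' @return list(discovery, replication).
#' @export
split_cohort <- function(cohort, seed = 1L) {
  n <- nrow(cohort)
  if (n < 2) stop("need at least 2 participants to split", call. = FALSE)
  idx <- with_local_seed(seed, sample.int(n))
  n_disc <- ceiling(n / 2)
  disc <- cohort[sort(idx[seq_len(n_disc)]), , drop = FALSE]
  repl <- cohort[sort(idx[-seq_len(n_disc)]), , drop = FALSE]
  attr(disc, "foods") <- attr(cohort, "foods")
  attr(repl, "foods") <- attr(cohort, "foods")
  list(discovery = disc, replication = repl)
}
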