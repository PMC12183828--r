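#' Score one food component
#'
#' Tertile points for an intake against a component criterion. For an
#' anti-inflammatory food: 0 points below the lower cut-off, 0.5 in the
#' closed middle interval \[lo, hi\], 1 above hi; for a zero-anchored
#' criterion the bottom class is exactly zero consumption and the middle is
#' (0, hi]. Pro-inflammatory foods score the mirror image (1 at the bottom,
#' 0 at the top). The olive/canola component uses a 0-4 usage count with the
#' same zero-anchored classes (0 / 1 / more than 1).
#'
#' @param intake Numeric vector of intakes in the criterion's unit.
#' @param criterion One row of an index definition's `criteria` (list or
#'   single-row data.frame with direction, unit, lo, hi, zero_anchored).
#' @return Numeric vector of points in {0, 0.5, 1}.
#' @export
score_component <- function(intake, criterion) {
  criterion <- as.list(criterion)
  if (anyNA(intake)) stop("missing intake", call. = FALSE)
  if (any(intake < 0)) stop("negative intake", call. = FALSE)
  if (identical(criterion$unit, "usage-count") &&
      any(intake != round(intake) | intake > 4))
    stop("usage-count intake must be an integer 0-4", call. = FALSE)
  anti_points <- if (isTRUE(criterion$zero_anchored)) {
    ifelse(intake == 0, 0, ifelse(intake <= criterion$hi, 0.5, 1))
  } else {
    ifelse(intake < criterion$lo, 0,
           ifelse(intake <= criterion$hi, 0.5, 1))
  }
  if (criterion$direction == "pro") 1 - anti_points else anti_points
}

# conversion factor from `from` unit into `to` unit
unit_factor <- function(from, to) {
  if (from == to) return(1)
  if (from == "servings/day" && to == "servings/week") return(7)
  if (from == "servings/week" && to == "servings/day") return(1 / 7)
  stop("cannot convert intake unit '", from, "' to '", to, "'",
       call. = FALSE)
}

#' Score one participant's diet
#'
#' @param intakes Named numeric vector of food intakes.
#' @param definition An `index_definition`.
#' @param missing_policy "error" (default) stops on a food absent from
#'   `intakes`; "zero" scores it as zero intake and lists it in the result.
#' @param units Named character vector giving the unit of each entry of
#'   `intakes`; defaults to servings/day (usage-count for a usage-count
#'   criterion). Conversion is silent only between servings/day and
#'   servings/week.
#' @return list of class `score_result`: `points` (named, per food),
#'   `total`, `missing` (foods scored as zero under the "zero" policy).
#' @export
score_participant <- function(intakes, definition,
                              missing_policy = c("error", "zero"),
                              units = NULL) {
  stopifnot(inherits(definition, "index_definition"))
  missing_policy <- match.arg(missing_policy)
  cr <- definition$criteria
  points <- stats::setNames(numeric(nrow(cr)), cr$food)
  missing <- character()
  for (i in seq_len(nrow(cr))) {
    food <- cr$food[i]
    if (!food %in% names(intakes)) {
      if (missing_policy == "error")
        stop("no intake for component: ", food, call. = FALSE)
      missing <- c(missing, food)
      points[food] <- score_component(0, cr[i, ])
      next
    }
    from <- if (!is.null(units) && food %in% names(units)) units[[food]]
            else if (cr$unit[i] == "usage-count") "usage-count"
            else "servings/day"
    x <- intakes[[food]] * unit_factor(from, cr$unit[i])
    points[food] <- score_component(x, cr[i, ])
  }
  structure(list(points = points, total = sum(points), missing = missing),
            class = "score_result")
}

#' @export
print.score_result <- function(x, ...) {
  cat(sprintf("eADI score: %.1f (of %d components", x$total, length(x$points)))
  if (length(x$missing))
    cat(sprintf("; %d scored as zero intake", length(x$missing)))
  cat(")\n")
  invisible(x)
}

#' Score a whole cohort
#'
#' Vectorized scoring of every participant's intake columns against an
#' index definition. Cohort intake columns are assumed to be in
#' servings/day (usage-count columns for usage-count criteria) unless
#' `units` says otherwise.
#'
#' @param cohort data.frame with one column per component food.
#' @param definition An `index_definition`.
#' @param units Optional named character vector of column units.
#' @return Numeric vector of total scores (one per row), with the per-food
#'   points matrix attached as attribute `points`.
#' @export
score_cohort <- function(cohort, definition, units = NULL) {
  stopifnot(inherits(definition, "index_definition"))
  cr <- definition$criteria
  absent <- setdiff(cr$food, names(cohort))
  if (length(absent))
    stop("cohort lacks intake columns: ", paste(absent, collapse = ", "),
         call. = FALSE)
  pts <- sapply(seq_len(nrow(cr)), function(i) {
    food <- cr$food[i]
    from <- if (!is.null(units) && food %in% names(units)) units[[food]]
            else if (cr$unit[i] == "usage-count") "usage-count"
            else "servings/day"
    score_component(cohort[[food]] * unit_factor(from, cr$unit[i]), cr[i, ])
  })
  pts <- matrix(pts, ncol = nrow(cr), dimnames = list(NULL, cr$food))
  total <- rowSums(pts)
  attr(total, "points") <- pts
  total
}
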