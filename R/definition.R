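#' Tertile cut-offs for a food's consumption
#'
#' lo and hi are the 1/3 and 2/3 empirical quantiles (type-1, inverse CDF).
#' When at least a third of the sample reports zero consumption the usual
#' tertiles collapse onto zero, so a zero-anchored criterion is emitted
#' instead: bottom class {0}, middle (0, hi], top (hi, Inf). If the zero
#' mass also swallows the 2/3 quantile, hi is taken as the upper tertile
#' bound of the positive intakes. A constant vector yields a degenerate,
#' unusable criterion.
#'
#' @param values Non-negative consumption values, length >= 3.
#' @return list(lo, hi, zero_anchored, degenerate).
#' @export
derive_tertile_cutoffs <- function(values) {
  if (length(values) < 3) stop("need at least 3 values", call. = FALSE)
  if (anyNA(values) || any(values < 0))
    stop("values must be non-negative and complete", call. = FALSE)
  if (length(unique(values)) == 1L)
    return(list(lo = NA_real_, hi = NA_real_, zero_anchored = FALSE,
                degenerate = TRUE))
  q <- stats::quantile(values, c(1, 2) / 3, type = 1, names = FALSE)
  if (mean(values == 0) >= 1 / 3) {
    hi <- q[2]
    if (hi <= 0)
      hi <- stats::quantile(values[values > 0], 2 / 3, type = 1, names = FALSE)
    return(list(lo = 0, hi = hi, zero_anchored = TRUE, degenerate = FALSE))
  }
  list(lo = q[1], hi = q[2], zero_anchored = FALSE, degenerate = FALSE)
}

#' Build an index definition from a selection decision and cut-offs
#'
#' @param decision A `selection_decision` from [collect_features()].
#' @param cutoffs Named list (food -> list(lo, hi, zero_anchored,
#'   degenerate)) covering every selected food, e.g. from
#'   [derive_tertile_cutoffs()] per food.
#' @param name Index name.
#' @param units Optional named character of per-food units; defaults to
#'   servings/day (usage-count for olive_canola_oil).
#' @param provenance Free-text provenance note.
#' @return Object of class `index_definition`.
#' @export
build_index_definition <- function(decision, cutoffs, name = "eADI",
                                   units = NULL, provenance = "derived") {
  stopifnot(inherits(decision, "selection_decision"))
  sel <- decision[decision$selected, , drop = FALSE]
  if (nrow(sel) == 0) stop("empty selection: no foods to score", call. = FALSE)
  missing <- setdiff(sel$food, names(cutoffs))
  if (length(missing))
    stop("no cut-offs for selected foods: ",
         paste(missing, collapse = ", "), call. = FALSE)
  criteria <- do.call(rbind, lapply(seq_len(nrow(sel)), function(i) {
    food <- sel$food[i]
    ct <- cutoffs[[food]]
    if (isTRUE(ct$degenerate))
      stop("degenerate tertile criterion for selected food: ", food,
           call. = FALSE)
    unit <- if (!is.null(units) && food %in% names(units)) units[[food]]
            else if (food == "olive_canola_oil") "usage-count"
            else "servings/day"
    data.frame(food = food, direction = sel$direction[i], unit = unit,
               lo = ct$lo, hi = ct$hi, zero_anchored = isTRUE(ct$zero_anchored),
               stringsAsFactors = FALSE)
  }))
  new_index_definition(name, criteria, provenance)
}

new_index_definition <- function(name, criteria, provenance = "") {
  stopifnot(is.data.frame(criteria), nrow(criteria) >= 1)
  if (anyDuplicated(criteria$food))
    stop("food names in an index definition must be unique", call. = FALSE)
  if (any(criteria$lo > criteria$hi))
    stop("criterion lower cut-off exceeds upper cut-off", call. = FALSE)
  if (!all(criteria$direction %in% c("anti", "pro")))
    stop("direction must be 'anti' or 'pro'", call. = FALSE)
  rownames(criteria) <- NULL
  structure(list(name = name, criteria = criteria, provenance = provenance),
            class = "index_definition")
}

#' @export
print.index_definition <- function(x, ...) {
  cr <- x$criteria
  cat(sprintf("Index definition '%s': %d components (%d anti, %d pro)\n",
              x$name, nrow(cr), sum(cr$direction == "anti"),
              sum(cr$direction == "pro")))
  print(cr, row.names = FALSE)
  invisible(x)
}

#' Serialize an index definition to JSON
#'
#' @param definition An `index_definition`.
#' @param file Output path.
#' @export
write_index_definition <- function(definition, file) {
  stopifnot(inherits(definition, "index_definition"))
  jsonlite::write_json(
    list(name = definition$name, provenance = definition$provenance,
         criteria = definition$criteria),
    file, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(file)
}

#' Read an index definition from JSON
#'
#' @param file Path written by [write_index_definition()] or a packaged
#'   definition file.
#' @return An `index_definition`.
#' @export
read_index_definition <- function(file) {
  obj <- jsonlite::read_json(file, simplifyVector = TRUE)
  criteria <- as.data.frame(obj$criteria, stringsAsFactors = FALSE)
  criteria$lo <- as.numeric(criteria$lo)
  criteria$hi <- as.numeric(criteria$hi)
  criteria$zero_anchored <- as.logical(criteria$zero_anchored)
  new_index_definition(obj$name, criteria, obj$provenance %||% "")
}

#' Load a packaged canonical index definition
#'
#' "eADI-17" is the full 17-component index (11 anti-inflammatory, 6
#' pro-inflammatory food groups) with its published consumption-tertile
#' cut-offs; "eADI-15" is its adaptation to FFQ instruments lacking the
#' seeds and legumes questions, retaining the remaining 15 criteria with
#' unchanged cut-offs.
#'
#' @param name "eADI-17" or "eADI-15".
#' @return An `index_definition`.
#' @export
load_canonical_definition <- function(name = c("eADI-17", "eADI-15")) {
  if (!is.character(name) || length(name) != 1 ||
      !name %in% c("eADI-17", "eADI-15"))
    stop("unknown index definition: ", paste(name, collapse = ","),
         " (available: eADI-17, eADI-15)", call. = FALSE)
  file <- system.file("extdata",
                      paste0(tolower(sub("-", "", name)), ".json"),
                      package = "eadi", mustWork = TRUE)
  read_index_definition(file)
}

#' Adapt an index definition by omitting foods
#'
#' Removes the named components, leaving the remaining criteria unchanged.
#'
#' @param definition An `index_definition`.
#' @param omit Character vector of food names to drop (may be empty).
#' @return An `index_definition`; the name is annotated when foods are
#'   dropped.
#' @export
adapt_definition <- function(definition, omit) {
  stopifnot(inherits(definition, "index_definition"))
  if (length(omit) == 0) return(definition)
  unknown <- setdiff(omit, definition$criteria$food)
  if (length(unknown))
    stop("foods not in definition: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  criteria <- definition$criteria[!definition$criteria$food %in% omit, ,
                                  drop = FALSE]
  if (nrow(criteria) == 0) stop("adaptation removes every component",
                                call. = FALSE)
  new_index_definition(
    paste0(definition$name, " (without ", paste(omit, collapse = ", "), ")"),
    criteria,
    paste0(definition$provenance, "; adapted by omitting ",
           paste(omit, collapse = ", ")))
}
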