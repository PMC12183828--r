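#' Develop an index on a discovery cohort
#'
#' Runs the full development procedure on a prepared discovery cohort:
#' per-fold compound-indicator fitting and L1-penalized food selection,
#' the cross-fold stability filter, direction assignment, and tertile
#' cut-off derivation on the discovery intakes; the result bundles the
#' emitted index definition with the selection diagnostics.
#'
#' @param discovery Discovery-group cohort (post exclusions).
#' @param foods Candidate food columns; defaults to the cohort's `foods`
#'   attribute.
#' @param k Fold count.
#' @param lambda L1 penalty (see [fold_lasso_selection()]).
#' @param min_nonzero Stability threshold (non-zero in at least this many
#'   folds).
#' @param seed Seed for the fold assignment.
#' @param name Stem for the definition name; the component count is
#'   appended (e.g. "eADI-17").
#' @return list of class `eadi_development`: `definition`, `selection`
#'   (the per-food decision), `folds` (the `fold_selection`), `indicator`
#'   (compound indicator fitted on the full discovery group).
#' @export
develop_index <- function(discovery, foods = NULL, k = 10L, lambda = 0.07,
                          min_nonzero = 9L, seed = 1L, name = "eADI") {
  foods <- foods %||% attr(discovery, "foods") %||%
    intersect(candidate_foods(), names(discovery))
  folds <- fold_lasso_selection(discovery, foods, k = k, lambda = lambda,
                                seed = seed)
  decision <- collect_features(folds, min_nonzero = min_nonzero)
  selected <- decision$food[decision$selected]
  if (length(selected) == 0)
    stop("no foods passed the stability filter; lower lambda or min_nonzero",
         call. = FALSE)
  cutoffs <- lapply(stats::setNames(selected, selected), function(food)
    derive_tertile_cutoffs(discovery[[food]]))
  definition <- build_index_definition(
    decision, cutoffs, name = paste0(name, "-", length(selected)),
    provenance = sprintf(
      "derived: k=%d folds, lambda=%g, stability >= %d/%d, n=%d",
      k, lambda, min_nonzero, k, nrow(discovery)))
  indicator <- fit_compound_indicator(biomarker_matrix(discovery))
  structure(list(definition = definition, selection = decision,
                 folds = folds, indicator = indicator),
            class = "eadi_development")
}

#' @export
print.eadi_development <- function(x, ...) {
  sel <- x$selection[x$selection$selected, ]
  cat(sprintf(
    "Index development: %d/%d foods selected (%d anti, %d pro)\n",
    nrow(sel), nrow(x$selection), sum(sel$direction == "anti"),
    sum(sel$direction == "pro")))
  cat(sprintf("  PC1 variance share: %.1f%%\n",
              100 * x$indicator$variance_explained[1]))
  print(x$definition)
  invisible(x)
}
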