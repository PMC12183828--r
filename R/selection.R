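#' Biomarker matrix on the log2 scale
#'
#' @param cohort Cohort data.frame; uses `log2_hscrp` if present, otherwise
#'   log2-transforms `hscrp`.
#' @return n x 4 matrix (log2_hscrp, il6, tnfr1, tnfr2).
#' @export
biomarker_matrix <- function(cohort) {
  log2_hscrp <- if ("log2_hscrp" %in% names(cohort)) cohort$log2_hscrp
                else log2(cohort$hscrp)
  cbind(log2_hscrp = log2_hscrp, il6 = cohort$il6,
        tnfr1 = cohort$tnfr1, tnfr2 = cohort$tnfr2)
}

#' Random balanced fold assignment
#'
#' @param n Number of observations.
#' @param k Number of folds, 2 <= k <= n.
#' @param seed Integer seed.
#' @return Integer vector of fold labels 1..k; fold sizes differ by at
#'   most 1.
#' @export
make_folds <- function(n, k = 10L, seed = 1L) {
  if (k < 2) stop("k must be at least 2", call. = FALSE)
  if (k > n) stop("more folds than observations", call. = FALSE)
  with_local_seed(seed, sample(rep_len(seq_len(k), n)))
}

# L1-penalized least squares with objective
#   (1/(2n)) * ||y - b0 - X beta||^2 + lambda * ||beta||_1
# X is expected pre-standardized; the intercept is unpenalized. lambda = 0
# reduces to OLS and is solved by the normal equations directly.
lasso_coefficients <- function(x, y, lambda) {
  if (lambda < 0) stop("lambda must be non-negative", call. = FALSE)
  if (lambda == 0) {
    xc <- cbind(1, x)
    beta <- solve(crossprod(xc), crossprod(xc, y))
    return(stats::setNames(drop(beta)[-1], colnames(x)))
  }
  fit <- glmnet::glmnet(x, y, family = "gaussian", alpha = 1,
                        lambda = lambda, standardize = FALSE,
                        intercept = TRUE, thresh = 1e-10)
  beta <- drop(as.matrix(fit$beta))
  stats::setNames(beta, colnames(x))
}

#' Per-fold Lasso coefficients for food selection
#'
#' Runs the filtering procedure fold by fold: for each of k random folds of
#' the discovery cohort, a training set (by default the complement of the
#' held-out fold) is used to (1) fit the compound inflammation indicator on
#' its standardized biomarkers and (2) regress the PC1 scores on the
#' standardized food intakes with an L1 penalty, recording the coefficient
#' of every food in every fold.
#'
#' @param discovery Discovery-group cohort (post exclusions), with intake
#'   and biomarker columns.
#' @param foods Food column names; defaults to the cohort's `foods`
#'   attribute or the candidate pool.
#' @param k Fold count (default 10).
#' @param lambda L1 penalty under the (1/(2n)) least-squares convention.
#' @param seed Seed for the fold assignment.
#' @param train_on "complement" (default) fits on the k-1 folds excluding
#'   the held-out fold; "fold" fits on the fold itself.
#' @return Object of class `fold_selection`: `coefficients` (food x fold),
#'   `nonzero_count`, `mean_coef`, `sd_coef`, `folds`, `lambda`, `k`.
#' @export
fold_lasso_selection <- function(discovery, foods = NULL, k = 10L,
                                 lambda = 0.07, seed = 1L,
                                 train_on = c("complement", "fold")) {
  train_on <- match.arg(train_on)
  foods <- foods %||% attr(discovery, "foods") %||%
    intersect(candidate_foods(), names(discovery))
  x_all <- intake_matrix(discovery, foods)
  if (anyNA(x_all)) stop("missing food intakes", call. = FALSE)
  bm <- biomarker_matrix(discovery)
  if (anyNA(bm)) stop("missing biomarker values", call. = FALSE)
  folds <- make_folds(nrow(discovery), k, seed)

  coefs <- matrix(0, length(foods), k,
                  dimnames = list(foods, paste0("fold", seq_len(k))))
  for (f in seq_len(k)) {
    idx <- if (train_on == "complement") which(folds != f) else which(folds == f)
    indicator <- fit_compound_indicator(bm[idx, , drop = FALSE])
    x <- x_all[idx, , drop = FALSE]
    sds <- apply(x, 2, stats::sd)
    zv <- sds == 0
    if (any(zv))
      warning("zero-variance food in fold ", f, " training set: ",
              paste(foods[zv], collapse = ", "), "; coefficient fixed at 0",
              call. = FALSE)
    xs <- scale(x[, !zv, drop = FALSE])
    beta <- lasso_coefficients(xs, indicator$scores, lambda)
    coefs[names(beta), f] <- beta
  }
  out <- list(
    coefficients = coefs,
    nonzero_count = rowSums(coefs != 0),
    mean_coef = rowMeans(coefs),
    sd_coef = apply(coefs, 1, stats::sd),
    folds = folds,
    lambda = lambda,
    k = as.integer(k),
    train_on = train_on
  )
  class(out) <- "fold_selection"
  out
}

#' @export
print.fold_selection <- function(x, ...) {
  cat(sprintf("Per-fold Lasso selection: %d foods, k = %d, lambda = %g\n",
              nrow(x$coefficients), x$k, x$lambda))
  cat(sprintf("  foods non-zero in >= %d folds: %d\n",
              x$k - 1L, sum(x$nonzero_count >= x$k - 1L)))
  invisible(x)
}

#' Write per-fold coefficients as TSV
#'
#' Long format (food, fold, coefficient), one row per food x fold.
#'
#' @param result A `fold_selection`.
#' @param file Output path.
#' @export
write_fold_coefficients <- function(result, file) {
  long <- data.frame(
    food = rep(rownames(result$coefficients), result$k),
    fold = rep(seq_len(result$k), each = nrow(result$coefficients)),
    coefficient = as.vector(result$coefficients)
  )
  utils::write.table(long, file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Collect stable features across folds
#'
#' A food is selected when its Lasso coefficient is non-zero in at least
#' `min_nonzero` of the k folds. The direction comes from the sign of the
#' mean coefficient across folds: negative means anti-inflammatory,
#' positive pro-inflammatory. Foods whose non-zero fold coefficients
#' disagree in sign with the mean are flagged as sign-inconsistent (the
#' mean sign still classifies them).
#'
#' @param result A `fold_selection`.
#' @param min_nonzero Stability threshold (default 9 of 10 folds).
#' @return data.frame of class `selection_decision`: food, nonzero_count,
#'   mean_coef, sd_coef, selected, direction, sign_consistent.
#' @export
collect_features <- function(result, min_nonzero = 9L) {
  stopifnot(inherits(result, "fold_selection"))
  selected <- result$nonzero_count >= min_nonzero
  direction <- ifelse(selected,
                      ifelse(result$mean_coef < 0, "anti", "pro"),
                      NA_character_)
  consistent <- apply(result$coefficients, 1, function(b) {
    nz <- b[b != 0]
    length(nz) == 0 || all(sign(nz) == sign(mean(b)))
  })
  out <- data.frame(
    food = rownames(result$coefficients),
    nonzero_count = unname(result$nonzero_count),
    mean_coef = unname(result$mean_coef),
    sd_coef = unname(result$sd_coef),
    selected = unname(selected),
    direction = unname(direction),
    sign_consistent = unname(consistent),
    stringsAsFactors = FALSE
  )
  class(out) <- c("selection_decision", "data.frame")
  out
}
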