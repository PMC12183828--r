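#' Fit the compound inflammation indicator
#'
#' Standardizes the four biomarkers (mean 0, SD 1) and extracts principal
#' components of their correlation structure. The first component is the
#' compound inflammation indicator; its sign is fixed so that it loads
#' positively on the biomarkers (all four, whenever the loading signs
#' allow). The second component is retained for inspection but plays no
#' role in feature selection because it does not correlate consistently
#' with all four markers.
#'
#' @param biomarkers Numeric matrix or data.frame, n x 4, complete.
#' @return Object of class `compound_indicator`: `loadings` (4 x 2,
#'   unit-norm columns), `variance_explained` (fractions for PC1, PC2),
#'   `scores` (PC1 score per participant), `scores_pc2`, `center`, `scale`.
#' @export
fit_compound_indicator <- function(biomarkers) {
  x <- as.matrix(biomarkers)
  if (nrow(x) < 5) stop("need at least 5 observations", call. = FALSE)
  if (anyNA(x)) stop("biomarker matrix contains missing values", call. = FALSE)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance biomarker column: ",
         paste(colnames(x)[sds == 0], collapse = ", "), call. = FALSE)
  pca <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  # sign convention: the indicator points towards higher inflammation
  for (comp in 1:2) {
    if (sum(pca$rotation[, comp]) < 0) {
      pca$rotation[, comp] <- -pca$rotation[, comp]
      pca$x[, comp] <- -pca$x[, comp]
    }
  }
  ve <- pca$sdev^2 / sum(pca$sdev^2)
  out <- list(
    loadings = pca$rotation[, 1:2, drop = FALSE],
    variance_explained = ve[1:2],
    scores = unname(pca$x[, 1]),
    scores_pc2 = unname(pca$x[, 2]),
    center = pca$center,
    scale = pca$scale
  )
  class(out) <- "compound_indicator"
  out
}

#' @export
print.compound_indicator <- function(x, ...) {
  cat("Compound inflammation indicator (PC1 of 4 standardized biomarkers)\n")
  cat(sprintf("  variance explained: PC1 %.1f%%, PC2 %.1f%%\n",
              100 * x$variance_explained[1], 100 * x$variance_explained[2]))
  cat("  PC1 loadings:\n")
  print(round(x$loadings[, 1], 3))
  invisible(x)
}

#' Score new participants on a fitted compound indicator
#'
#' @param object A `compound_indicator`.
#' @param newdata n x 4 biomarker matrix on the same scale as the training
#'   data.
#' @param ... Unused.
#' @return Numeric vector of PC1 scores.
#' @export
predict.compound_indicator <- function(object, newdata, ...) {
  x <- scale(as.matrix(newdata), center = object$center, scale = object$scale)
  drop(x %*% object$loadings[, 1])
}
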