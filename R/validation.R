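#' Published eADI-17 category breaks
#'
#' The five score intervals used to categorize eADI-17. Because scores move
#' in half-point steps, the gaps between printed intervals are unreachable
#' and the intervals are exhaustive over observed scores.
#'
#' @return list of c(lower, upper) interval bounds.
#' @export
eadi_category_breaks <- function() {
  list(c(2, 6), c(6.5, 8), c(8.5, 9.5), c(10, 12), c(12.5, 16))
}

interval_labels <- function(breaks) {
  vapply(breaks, function(b) paste0(format(b[1]), "-", format(b[2])),
         character(1))
}

#' Categorize eADI scores
#'
#' Assigns each score to exactly one closed interval. With `extend = TRUE`
#' the first and last intervals are opened downwards/upwards so scores
#' outside the printed range (attainable on other cohorts) still
#' categorize; otherwise an out-of-range score is an error.
#'
#' @param scores Numeric eADI scores.
#' @param breaks list of c(lower, upper) intervals, ordered, from
#'   [eadi_category_breaks()] by default.
#' @param extend Clamp the outer intervals to cover the whole line.
#' @return factor with one level per interval, labelled "lo-hi".
#' @export
categorize_eadi <- function(scores, breaks = eadi_category_breaks(),
                            extend = FALSE) {
  lower <- vapply(breaks, `[`, numeric(1), 1)
  upper <- vapply(breaks, `[`, numeric(1), 2)
  if (is.unsorted(lower) || any(upper < lower) ||
      any(lower[-1] <= upper[-length(upper)]))
    stop("breaks must be ordered, non-overlapping intervals", call. = FALSE)
  labels <- interval_labels(breaks)
  if (extend) {
    lower[1] <- -Inf
    upper[length(upper)] <- Inf
  }
  idx <- rep(NA_integer_, length(scores))
  for (i in seq_along(breaks))
    idx[scores >= lower[i] & scores <= upper[i]] <- i
  if (anyNA(idx[!is.na(scores)]))
    stop("score outside all category intervals: ",
         paste(unique(scores[is.na(idx) & !is.na(scores)]), collapse = ", "),
         call. = FALSE)
  factor(labels[idx], levels = labels)
}

#' Spearman correlation table
#'
#' Rank correlations of the total index score and each component's intake
#' with the score itself, the compound inflammation indicator, and the four
#' biomarkers (hsCRP on the log2 scale) -- rank correlations are invariant
#' to the monotone log2 transform.
#'
#' @param data Cohort data.frame containing the component intake columns
#'   and biomarkers.
#' @param scores Numeric vector of total index scores (aligned with rows).
#' @param components Character vector of component intake columns; default
#'   none (score row only).
#' @param indicator Optional numeric vector of compound-indicator scores.
#' @return data.frame, one row per variable ("eADI" first, then
#'   components), columns eadi, indicator (if given), hscrp, il6, tnfr1,
#'   tnfr2. Constant columns yield NA with a warning.
#' @export
spearman_table <- function(data, scores, components = character(),
                           indicator = NULL) {
  if (length(scores) != nrow(data))
    stop("scores and data are not aligned", call. = FALSE)
  if (nrow(data) < 3) stop("need at least 3 rows", call. = FALSE)
  bm <- biomarker_matrix(data)
  targets <- cbind(eadi = scores,
                   if (!is.null(indicator)) cbind(indicator = indicator),
                   hscrp = bm[, "log2_hscrp"], il6 = bm[, "il6"],
                   tnfr1 = bm[, "tnfr1"], tnfr2 = bm[, "tnfr2"])
  vars <- cbind(eADI = scores, intake_matrix(data, components))
  const <- apply(vars, 2, function(v) stats::sd(v, na.rm = TRUE) == 0)
  if (any(const))
    warning("constant column(s), Spearman undefined: ",
            paste(colnames(vars)[const], collapse = ", "), call. = FALSE)
  rs <- suppressWarnings(
    stats::cor(vars, targets, method = "spearman", use = "pairwise"))
  rs[const, ] <- NA_real_
  as.data.frame(rs)
}

factor_with_missing <- function(x, levels, label = "missing") {
  f <- factor(x, levels = levels)
  if (anyNA(f)) {
    f <- factor(x, levels = c(levels, label))
    f[is.na(f)] <- label
  }
  f
}

# quintile factor computed on the analysis data; ties fall to the lower
# quintile (left-open intervals)
quintile_factor <- function(x, label = "missing") {
  br <- unique(stats::quantile(x, 1:4 / 5, type = 1, na.rm = TRUE))
  g <- findInterval(x, br, left.open = TRUE) + 1L
  factor_with_missing(paste0("Q", g), paste0("Q", 1:(length(br) + 1L)), label)
}

#' Coded covariate frame for the adjusted models
#'
#' Applies the standard covariate codings: age continuous; education
#' 3-level; walking/cycling 4-level; smoking 3-level; NSAID/statin/
#' cortisone use binary; antibiotic use 4-level; sleep 2-level; BMI in the
#' four conventional categories; sagittal measure and energy intake in
#' quintiles computed on the supplied data (ties to the lower quintile);
#' Charlson comorbidity index continuous by default or in categories
#' 0/1/2/3+. Missing walking/cycling, smoking, sleep, BMI and sagittal
#' values become explicit "missing" indicator categories.
#'
#' @param data Cohort data.frame.
#' @param cci_coding "continuous" (default) or "categorical".
#' @return data.frame of coded covariates, row-aligned with `data`.
#' @export
covariate_model_frame <- function(data,
                                  cci_coding = c("continuous", "categorical")) {
  cci_coding <- match.arg(cci_coding)
  bmi_cat <- cut(data$bmi, c(-Inf, 18.5, 25, 30, Inf), right = FALSE,
                 labels = c("<18.5", "18.5-24.9", "25-29.9", ">=30"))
  out <- data.frame(
    age = data$age,
    education = factor(data$education,
                       levels = c("primary", "high school", "university")),
    walking_cycling = factor_with_missing(
      data$walking_cycling, c("<20", "20-40", "40-60", ">60")),
    smoking = factor_with_missing(data$smoking,
                                  c("never", "former", "current")),
    nsaid_use = data$nsaid_use,
    statin_use = data$statin_use,
    cortisone_use = data$cortisone_use,
    antibiotic_use = factor(data$antibiotic_use,
                            levels = c("no", "<3 months", "3-6 months",
                                       "6-12 months")),
    sleep = factor_with_missing(data$sleep, c("<=7", ">7")),
    bmi = factor_with_missing(as.character(bmi_cat),
                              c("<18.5", "18.5-24.9", "25-29.9", ">=30")),
    sagittal = quintile_factor(data$sagittal),
    energy = quintile_factor(data$energy)
  )
  out$cci <- if (cci_coding == "continuous") data$cci else
    cut(data$cci, c(-Inf, 0, 1, 2, Inf),
        labels = c("0", "1", "2", ">=3"))
  out
}

# Factors that are constant in the analysis set (typical when stratifying
# by a covariate) carry no information and are absorbed by the intercept;
# they are dropped rather than breaking the contrast coding.
fit_lm_checked <- function(y, design) {
  design <- droplevels(design)
  keep <- vapply(design, function(col) {
    if (is.factor(col)) nlevels(col) >= 2 else stats::sd(col) > 0
  }, logical(1))
  df <- cbind(data.frame(.y = y), design[, keep, drop = FALSE])
  fit <- stats::lm(.y ~ ., data = df)
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("collinear covariate coding; undetermined terms: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  fit
}

#' Multivariable relative-concentration model
#'
#' Ordinary least squares of a log2-scale biomarker on eADI score
#' categories (lowest category as reference) with the standard covariate
#' adjustment. Coefficients and Wald 95% confidence intervals are reported
#' on the log2 scale and back-transformed (2^beta) to relative
#' concentrations versus the reference category. The trend p-value comes
#' from a matched model with the score entered as a continuous covariate,
#' which also supplies the per-point and per-2-SD estimates.
#'
#' @param data Analysis cohort (one of the split groups, or the combined
#'   cohort), with biomarker and covariate columns.
#' @param scores Numeric eADI scores aligned with `data` rows.
#' @param outcome One of "log2_hscrp", "il6", "tnfr1", "tnfr2".
#' @param breaks Category intervals (default [eadi_category_breaks()]).
#' @param adjust Include the covariate set (TRUE) or fit crude (FALSE).
#' @param cci_coding Passed to [covariate_model_frame()].
#' @param sd2 The score increment representing 2 SD; default twice the SD
#'   of `scores` in `data`. Use [per_2sd_estimate()] to rescale to an
#'   external (e.g. Discovery-group) SD.
#' @param conf_level Confidence level for Wald intervals.
#' @param extend_breaks Open the outer intervals so any attainable score
#'   categorizes (default TRUE).
#' @return Object of class `eadi_regression` with elements `categories`
#'   (data.frame: category, n, beta, se, ci_lo, ci_hi, rel_conc, rel_lo,
#'   rel_hi), `per_point`, `per_2sd`, `p_trend`, `sd2`, `n`, `outcome`.
#' @export
fit_relative_concentration_model <- function(data, scores,
                                             outcome = "log2_hscrp",
                                             breaks = eadi_category_breaks(),
                                             adjust = TRUE,
                                             cci_coding = "continuous",
                                             sd2 = NULL,
                                             conf_level = 0.95,
                                             extend_breaks = TRUE) {
  outcome <- match.arg(outcome, c("log2_hscrp", "il6", "tnfr1", "tnfr2"))
  y <- biomarker_matrix(data)[, outcome]
  cat_f <- categorize_eadi(scores, breaks, extend = extend_breaks)
  counts <- table(cat_f)
  if (any(counts == 0))
    stop("empty eADI category: ",
         paste(names(counts)[counts == 0], collapse = ", "), call. = FALSE)
  design <- data.frame(.eadi_cat = cat_f)
  if (adjust) design <- cbind(design, covariate_model_frame(data, cci_coding))
  fit <- fit_lm_checked(y, design)

  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  cf <- summary(fit)$coefficients
  cat_terms <- paste0(".eadi_cat", levels(cat_f)[-1])
  beta <- c(0, cf[cat_terms, "Estimate"])
  se <- c(NA, cf[cat_terms, "Std. Error"])
  categories <- data.frame(
    category = levels(cat_f), n = as.integer(counts),
    beta = beta, se = se,
    ci_lo = beta - z * se, ci_hi = beta + z * se,
    rel_conc = 2^beta, rel_lo = 2^(beta - z * se), rel_hi = 2^(beta + z * se),
    stringsAsFactors = FALSE
  )
  categories[1, c("rel_lo", "rel_hi")] <- NA  # reference: 1.00 (Ref.)
  categories$rel_conc[1] <- 1

  design_c <- design
  design_c$.eadi_cat <- NULL
  design_c <- cbind(data.frame(.eadi = scores), design_c)
  fit_c <- fit_lm_checked(y, design_c)
  cfc <- summary(fit_c)$coefficients[".eadi", ]
  per_point <- c(beta = unname(cfc["Estimate"]), se = unname(cfc["Std. Error"]),
                 ci_lo = unname(cfc["Estimate"] - z * cfc["Std. Error"]),
                 ci_hi = unname(cfc["Estimate"] + z * cfc["Std. Error"]))
  p_trend <- unname(cfc["Pr(>|t|)"])

  if (is.null(sd2)) sd2 <- 2 * stats::sd(scores)
  out <- structure(list(
    outcome = outcome, categories = categories,
    per_point = per_point,
    per_2sd = scale_per_increment(per_point, sd2),
    p_trend = p_trend, sd2 = sd2, n = length(y),
    adjust = adjust, breaks = breaks
  ), class = "eadi_regression")
  out
}

scale_per_increment <- function(per_point, increment) {
  if (is.null(increment) || is.na(increment) || increment <= 0)
    stop("score SD increment must be positive", call. = FALSE)
  b <- per_point[c("beta", "ci_lo", "ci_hi")] * increment
  c(beta = unname(b["beta"]), ci_lo = unname(b["ci_lo"]),
    ci_hi = unname(b["ci_hi"]),
    rel_conc = unname(2^b["beta"]), rel_lo = unname(2^b["ci_lo"]),
    rel_hi = unname(2^b["ci_hi"]), increment = increment)
}

#' Per-2-SD estimate with an external SD source
#'
#' Rescales a fitted model's continuous (per-point) estimate to a
#' 2-SD score increment, e.g. the Discovery group's 2 x SD (4.5 points).
#' Confidence limits scale linearly on the log2 scale; the back-transform
#' is applied after scaling.
#'
#' @param fit An `eadi_regression`.
#' @param sd_source Either a numeric vector of scores whose SD defines the
#'   increment, or a single number taken directly as the 2-SD increment.
#' @return Named vector: beta, ci_lo, ci_hi (log2 scale), rel_conc,
#'   rel_lo, rel_hi, increment.
#' @export
per_2sd_estimate <- function(fit, sd_source) {
  stopifnot(inherits(fit, "eadi_regression"))
  increment <- if (length(sd_source) > 1) 2 * stats::sd(sd_source)
               else as.numeric(sd_source)
  scale_per_increment(fit$per_point, increment)
}

#' @export
print.eadi_regression <- function(x, ...) {
  cat(sprintf("Relative %s by eADI category (n = %d, %s)\n",
              sub("log2_", "", x$outcome), x$n,
              if (x$adjust) "multivariable-adjusted" else "crude"))
  tab <- x$categories
  tab[, c("beta", "se", "ci_lo", "ci_hi", "rel_conc", "rel_lo", "rel_hi")] <-
    round(tab[, c("beta", "se", "ci_lo", "ci_hi", "rel_conc", "rel_lo",
                  "rel_hi")], 3)
  print(tab, row.names = FALSE)
  cat(sprintf("per %.2f-point (2 SD): %.2f (%.2f-%.2f);  p-trend = %.3g\n",
              x$sd2, x$per_2sd["rel_conc"], x$per_2sd["rel_lo"],
              x$per_2sd["rel_hi"], x$p_trend))
  invisible(x)
}

#' Results table in the published layout
#'
#' @param fit An `eadi_regression`.
#' @return data.frame with one row per category plus a per-2SD row.
#' @export
regression_table <- function(fit) {
  stopifnot(inherits(fit, "eadi_regression"))
  cats <- fit$categories
  rbind(
    data.frame(term = cats$category, n = cats$n, beta_log2 = cats$beta,
               ci_lo = cats$ci_lo, ci_hi = cats$ci_hi,
               rel_conc = cats$rel_conc, rel_lo = cats$rel_lo,
               rel_hi = cats$rel_hi, p_trend = NA_real_),
    data.frame(term = sprintf("per %.2f-point (2 SD)", fit$sd2),
               n = fit$n, beta_log2 = fit$per_2sd[["beta"]],
               ci_lo = fit$per_2sd[["ci_lo"]], ci_hi = fit$per_2sd[["ci_hi"]],
               rel_conc = fit$per_2sd[["rel_conc"]],
               rel_lo = fit$per_2sd[["rel_lo"]],
               rel_hi = fit$per_2sd[["rel_hi"]], p_trend = fit$p_trend)
  )
}

#' Stratified subgroup analyses
#'
#' Refits the adjusted relative-concentration model within each stratum.
#' Strata may be given as a factor aligned with rows or as a named list of
#' logical row filters (strata from thresholds, e.g. hsCRP < 3 mg/L, may
#' overlap). Rows with a missing stratifier are logged and dropped. When
#' the top score category in a stratum holds fewer than `min_category_n`
#' participants it is merged into the neighbouring category and the trend
#' test is restricted to scores below the merged interval; empty or
#' unfittable strata are skipped with a log entry.
#'
#' @param data Analysis cohort.
#' @param scores eADI scores aligned with `data`.
#' @param strata Factor or named list of logical vectors.
#' @param outcome,breaks,cci_coding,sd2 Passed to
#'   [fit_relative_concentration_model()]; `sd2` defaults to twice the SD
#'   of `scores` over all of `data` so strata share the same increment.
#' @param min_category_n Floor below which the top category is merged.
#' @return list(results = named list of `eadi_regression`, log =
#'   data.frame(stratum, note)).
#' @export
subgroup_analysis <- function(data, scores, strata,
                              outcome = "log2_hscrp",
                              breaks = eadi_category_breaks(),
                              cci_coding = "continuous",
                              sd2 = NULL, min_category_n = 10L) {
  if (is.list(strata)) {
    filters <- strata
  } else {
    f <- as.factor(strata)
    n_missing <- sum(is.na(f))
    filters <- lapply(stats::setNames(levels(f), levels(f)),
                      function(l) !is.na(f) & f == l)
    attr(filters, "n_missing") <- n_missing
  }
  if (is.null(sd2)) sd2 <- 2 * stats::sd(scores)
  results <- list()
  log <- data.frame(stratum = character(), note = character(),
                    stringsAsFactors = FALSE)
  note <- function(stratum, msg)
    log <<- rbind(log, data.frame(stratum = stratum, note = msg))
  nm <- attr(filters, "n_missing")
  if (!is.null(nm) && nm > 0)
    note("(all)", sprintf("%d rows with missing stratifier dropped", nm))

  for (s in names(filters)) {
    keep <- filters[[s]]
    if (!any(keep)) { note(s, "empty stratum, skipped"); next }
    d <- data[keep, , drop = FALSE]
    sc <- scores[keep]
    br <- breaks
    trend_keep <- rep(TRUE, nrow(d))
    cat_f <- categorize_eadi(sc, br, extend = TRUE)
    counts <- table(cat_f)
    while (length(br) > 2 && counts[length(counts)] < min_category_n) {
      top <- br[[length(br)]]
      br[[length(br) - 1]][2] <- top[2]
      br[[length(br)]] <- NULL
      trend_keep <- sc < top[1]
      cat_f <- categorize_eadi(sc, br, extend = TRUE)
      counts <- table(cat_f)
      note(s, sprintf(
        "sparse top category merged; trend restricted to scores < %g", top[1]))
    }
    fit <- tryCatch(
      fit_relative_concentration_model(d, sc, outcome = outcome, breaks = br,
                                       cci_coding = cci_coding, sd2 = sd2),
      error = function(e) { note(s, paste("not fitted:", conditionMessage(e)))
                            NULL })
    if (is.null(fit)) next
    if (!all(trend_keep)) {
      trend_fit <- tryCatch(
        fit_relative_concentration_model(
          d[trend_keep, , drop = FALSE], sc[trend_keep], outcome = outcome,
          breaks = br[-length(br)], cci_coding = cci_coding, sd2 = sd2),
        error = function(e) NULL)
      if (!is.null(trend_fit)) fit$p_trend <- trend_fit$p_trend
    }
    results[[s]] <- fit
  }
  list(results = results, log = log)
}

#' hsCRP inclusion-threshold strata
#'
#' Named logical filters keeping participants below successive hsCRP
#' concentration thresholds (mg/L); these strata are nested, not disjoint.
#'
#' @param data Cohort with an `hscrp` column.
#' @param thresholds Upper hsCRP limits.
#' @return Named list of logical vectors.
#' @export
hscrp_threshold_strata <- function(data, thresholds = c(15, 10, 5, 3)) {
  stats::setNames(
    lapply(thresholds, function(t) !is.na(data$hscrp) & data$hscrp < t),
    paste0("<", thresholds, " mg/L"))
}

#' Write regression results as TSV
#'
#' One file mirroring the published table layout: category, log2-scale
#' beta and CI, relative concentration and CI, p-trend.
#'
#' @param fits Named list of `eadi_regression` (or a single fit).
#' @param file Output path.
#' @export
write_regression_results <- function(fits, file) {
  if (inherits(fits, "eadi_regression")) fits <- list(result = fits)
  tab <- do.call(rbind, lapply(names(fits), function(nm) {
    cbind(analysis = nm, regression_table(fits[[nm]]))
  }))
  utils::write.table(tab, file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}
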