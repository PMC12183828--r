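test_that("Spearman correlations match hand-computed rank values", {
  co <- make_scored_cohort(seed = 21, n = 300)
  tab <- spearman_table(co, co$eadi, components = c("vegetables", "nuts"))
  expect_equal(tab["eADI", "eadi"], 1)  # monotone transform of itself
  expect_equal(unname(stats::cor(-co$eadi, co$eadi, method = "spearman")),
               -1)
  # rank-formula oracle: ranks of y = (5,6,7,8,7) are (1,2,3.5,5,3.5)
  x <- 1:5; y <- c(5, 6, 7, 8, 7)
  rx <- x; ry <- c(1, 2, 3.5, 5, 3.5)
  oracle <- sum((rx - 3) * (ry - 3)) /
    sqrt(sum((rx - 3)^2) * sum((ry - 3)^2))
  expect_equal(unname(stats::cor(x, y, method = "spearman")), oracle)
  d <- co[1:5, ]; d$il6 <- y
  t2 <- spearman_table(d, x)
  expect_equal(t2["eADI", "il6"], oracle)
  # constant component flagged as NA with a warning
  co$tea <- 1
  expect_warning(t3 <- spearman_table(co, co$eadi, components = "tea"),
                 "constant")
  expect_true(all(is.na(t3["tea", ])))
})

test_that("score categories follow the published intervals exhaustively", {
  expect_equal(as.character(categorize_eadi(6)), "2-6")
  expect_equal(as.character(categorize_eadi(6.5)), "6.5-8")
  expect_equal(as.character(categorize_eadi(16)), "12.5-16")
  grid <- seq(2, 16, by = 0.5)
  cats <- categorize_eadi(grid)
  expect_false(anyNA(cats))  # exhaustive over attainable scores
  expect_equal(nlevels(cats), 5)
  expect_error(categorize_eadi(1), "outside")
  expect_equal(as.character(categorize_eadi(c(0, 17), extend = TRUE)),
               c("2-6", "12.5-16"))
})

test_that("reference category is 1.00 and betas back-transform as 2^beta", {
  co <- make_scored_cohort(seed = 22)
  fit <- fit_relative_concentration_model(co, co$eadi)
  expect_equal(fit$categories$rel_conc[1], 1)
  expect_true(all(is.na(fit$categories[1, c("rel_lo", "rel_hi")])))
  expect_equal(fit$categories$rel_conc[-1], 2^fit$categories$beta[-1])
  expect_equal(2^-0.19, 0.8766, tolerance = 1e-4)
  # point estimates sit inside their intervals
  with(fit$categories[-1, ], {
    expect_true(all(ci_lo <= beta & beta <= ci_hi))
    expect_true(all(rel_lo <= rel_conc & rel_conc <= rel_hi))
  })
  expect_equal(sum(fit$categories$n), nrow(co))
})

test_that("crude two-category fit equals the difference in outcome means", {
  co <- make_scored_cohort(seed = 23, n = 800)
  breaks <- list(c(0, 8), c(8.5, 17))
  fit <- fit_relative_concentration_model(co, co$eadi, breaks = breaks,
                                          adjust = FALSE)
  cat_f <- categorize_eadi(co$eadi, breaks)
  y <- co$log2_hscrp
  expect_equal(fit$categories$beta[2],
               mean(y[cat_f == "8.5-17"]) - mean(y[cat_f == "0-8"]),
               tolerance = 1e-10)
})

test_that("per-2SD estimates scale the per-point fit linearly", {
  co <- make_scored_cohort(seed = 24)
  fit <- fit_relative_concentration_model(co, co$eadi)
  p45 <- per_2sd_estimate(fit, 4.5)
  expect_equal(unname(p45["beta"]), unname(fit$per_point["beta"] * 4.5))
  # CI width scales by exactly the increment on the log2 scale
  expect_equal(unname(p45["ci_hi"] - p45["ci_lo"]),
               unname((fit$per_point["ci_hi"] - fit$per_point["ci_lo"]) * 4.5))
  # increments from an SD source vector
  p2 <- per_2sd_estimate(fit, co$eadi)
  expect_equal(unname(p2["increment"]), 2 * stats::sd(co$eadi))
  # zero slope back-transforms to relative concentration 1
  fit0 <- fit
  fit0$per_point[c("beta", "ci_lo", "ci_hi")] <- 0
  expect_equal(unname(per_2sd_estimate(fit0, 4.5)["rel_conc"]), 1)
  expect_error(per_2sd_estimate(fit, 0), "positive")
})

test_that("adjustment for confounders moves the crude estimate", {
  co <- make_scored_cohort(seed = 25, n = 2500)
  crude <- fit_relative_concentration_model(co, co$eadi, adjust = FALSE)
  adj <- fit_relative_concentration_model(co, co$eadi)
  # smoking/BMI confounding is planted, so the two differ detectably
  expect_gt(abs(crude$per_point["beta"] - adj$per_point["beta"]), 1e-4)
})

test_that("missing covariates enter as explicit indicator categories", {
  cfg <- generator_config(2000, seed = 26,
                          missingness = list(smoking = 0.06, sleep = 0.05,
                                             bmi = 0.02))
  co <- transform_biomarkers(generate_cohort(cfg))
  co$eadi <- as.numeric(score_cohort(co, load_canonical_definition("eADI-17")))
  mf <- covariate_model_frame(co)
  expect_true("missing" %in% levels(mf$smoking))
  expect_false(anyNA(mf$smoking))
  fit <- fit_relative_concentration_model(co, co$eadi)
  expect_equal(fit$n, nrow(co))  # nobody dropped
})

test_that("CCI coding switch changes the design but keeps the default", {
  co <- make_scored_cohort(seed = 27, n = 600)
  mf_cont <- covariate_model_frame(co)
  mf_cat <- covariate_model_frame(co, cci_coding = "categorical")
  expect_true(is.numeric(mf_cont$cci))
  expect_s3_class(mf_cat$cci, "factor")
  expect_equal(levels(mf_cat$cci), c("0", "1", "2", ">=3"))
  fit <- fit_relative_concentration_model(co, co$eadi,
                                          cci_coding = "categorical")
  expect_s3_class(fit, "eadi_regression")
})

test_that("subgroup strata are filtered, logged and skip empty cells", {
  co <- make_scored_cohort(seed = 28, n = 2000)
  strata <- hscrp_threshold_strata(co, c(15, 3))
  out <- subgroup_analysis(co, co$eadi, strata)
  expect_equal(out$results[["<3 mg/L"]]$n, sum(co$hscrp < 3))
  empty <- list("none" = rep(FALSE, nrow(co)))
  out2 <- subgroup_analysis(co, co$eadi, empty)
  expect_length(out2$results, 0)
  expect_match(out2$log$note, "empty stratum")
  # factor stratifier with missing values logs the dropped rows
  f <- co$smoking; f[1:10] <- NA
  out3 <- subgroup_analysis(co, co$eadi, f)
  expect_true(any(grepl("missing stratifier", out3$log$note)))
  expect_setequal(names(out3$results), c("never", "former", "current"))
})

test_that("stratum estimates agree with the pooled estimate on average", {
  diffs <- sapply(1:20, function(s) {
    co <- make_scored_cohort(seed = 100 + s, n = 1200)
    pooled <- fit_relative_concentration_model(co, co$eadi)
    strata <- list(A = co$id %in% co$id[seq(1, nrow(co), 2)],
                   B = co$id %in% co$id[seq(2, nrow(co), 2)])
    out <- subgroup_analysis(co, co$eadi, strata, min_category_n = 1)
    mean(sapply(out$results, function(r) r$per_point["beta"])) -
      pooled$per_point["beta"]
  })
  # no exposure-by-stratum interaction is planted: mean difference ~ 0
  expect_lt(abs(mean(diffs)), 3 * stats::sd(diffs) / sqrt(length(diffs)) +
              1e-3)
})

test_that("sparse top categories are merged and the trend range restricted", {
  co <- make_scored_cohort(seed = 29, n = 1500)
  keep <- co$eadi <= 12 | seq_len(nrow(co)) %in%
    head(which(co$eadi > 12), 3)
  d <- co[keep, ]
  out <- subgroup_analysis(d, d$eadi, list(all = rep(TRUE, nrow(d))),
                           min_category_n = 10)
  expect_true(any(grepl("merged", out$log$note)))
  fit <- out$results$all
  expect_lt(nrow(fit$categories), 5)
})

test_that("regression results export in the published table layout", {
  co <- make_scored_cohort(seed = 30, n = 800)
  fit <- fit_relative_concentration_model(co, co$eadi)
  file <- file.path(withr::local_tempdir(), "table.tsv")
  write_regression_results(list(hsCRP = fit), file)
  back <- utils::read.delim(file)
  expect_equal(nrow(back), 6)  # 5 categories + per-2SD row
  expect_equal(back$rel_conc[1], 1)
  expect_equal(back$p_trend[6], fit$p_trend, tolerance = 1e-10)
})
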