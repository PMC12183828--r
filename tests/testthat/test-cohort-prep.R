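test_that("frequency categories convert to servings/day by fixed midpoints", {
  expect_equal(frequency_to_servings("never/seldom"), 0)
  expect_equal(frequency_to_servings("once a day"), 1)
  expect_equal(frequency_to_servings("1-3 times per month"), 2 / 30.4)
  expect_equal(frequency_to_servings("2 times a day", 0.5), 1)

  daily <- frequency_to_servings(ffq_frequency_levels())
  expect_true(all(diff(daily) > 0))  # monotone in category order
  expect_error(frequency_to_servings("twice a fortnight"), "unknown")
  expect_error(frequency_to_servings("once a day", -1), "positive")
})

test_that("item aggregation is additive, permutation-invariant, unit-aware", {
  mapping <- c("wholegrain bread" = "wholegrains", rice = "wholegrains",
               lettuce = "vegetables")
  items <- c("wholegrain bread" = 2.0, rice = 0.5)
  agg <- aggregate_food_groups(items, mapping)
  expect_equal(agg[["wholegrains"]], 2.5)
  expect_equal(agg[["vegetables"]], 0)
  expect_equal(aggregate_food_groups(rev(items), mapping), agg)
  expect_equal(aggregate_food_groups(c(lettuce = 0.5), mapping,
                                     unit = "servings/week")[["vegetables"]],
               3.5)
  expect_true(all(aggregate_food_groups(stats::setNames(numeric(0),
                                                        character(0)),
                                        mapping) == 0))
  expect_error(aggregate_food_groups(c(pizza = 1), mapping), "unmapped")
})

test_that("packaged demo FFQ mapping loads and aggregates", {
  mapping <- read_food_group_mapping(
    system.file("extdata", "ffq-item-mapping-demo.yaml", package = "eadi"))
  expect_true(all(mapping %in% candidate_foods()))
  agg <- aggregate_food_groups(c(macaroni = 1, rice = 0.5, tomato = 2),
                               mapping)
  expect_equal(agg[["wholegrains"]], 1.5)
})

test_that("exclusion rules keep hsCRP <= 20 and plausible energy", {
  co <- generate_cohort(generator_config(n_participants = 200, seed = 5))
  co$hscrp <- pmin(co$hscrp, 10)
  co$hscrp[1] <- 25       # above threshold
  co$hscrp[2] <- 20.0     # boundary: retained
  co$il6[3] <- NA
  co$tnfr2[4] <- NA
  co$education[5] <- NA
  # 5 SD out so the outlier still exceeds 3 SD of the moments it inflates
  log_e <- log(co$energy)
  co$energy[6] <- exp(mean(log_e) + 5 * stats::sd(log_e))

  res <- apply_exclusions(co)
  expect_false("P00001" %in% res$cohort$id)
  expect_true("P00002" %in% res$cohort$id)
  expect_setequal(res$log$reason[res$log$id == "P00001"], "hsCRP>20")
  expect_setequal(res$log$reason[res$log$id == "P00003"], "missing IL-6")
  expect_setequal(res$log$reason[res$log$id == "P00004"],
                  "missing TNF-R1/R2")
  expect_setequal(res$log$reason[res$log$id == "P00005"],
                  "missing education")
  expect_true("implausible energy" %in% res$log$reason[res$log$id == "P00006"])
  # reasons are logged in the narrative order
  expect_equal(unique(res$log$reason),
               c("hsCRP>20", "missing IL-6", "missing TNF-R1/R2",
                 "missing education", "implausible energy"))
  # removals reconcile: flagged ids = input - output
  expect_equal(length(unique(res$log$id)), nrow(co) - nrow(res$cohort))
  expect_error(apply_exclusions(co[0, ]), "empty")
})

test_that("energy rule uses the pre-exclusion cohort's log-scale moments", {
  co <- generate_cohort(generator_config(n_participants = 200, seed = 6))
  co$hscrp <- pmin(co$hscrp, 10)
  log_e <- log(co$energy)
  z <- (log_e - mean(log_e)) / stats::sd(log_e)
  res <- apply_exclusions(co)
  expect_setequal(res$log$id[res$log$reason == "implausible energy"],
                  co$id[abs(z) > 3])
})

test_that("log2 transform adds a column and round-trips", {
  co <- data.frame(hscrp = c(4, 1, 0.5))
  out <- transform_biomarkers(co)
  expect_equal(out$log2_hscrp, c(2, 0, -1))
  expect_equal(out$hscrp, co$hscrp)  # original retained
  x <- stats::runif(1000, 0.01, 30)
  expect_equal(2^(transform_biomarkers(data.frame(hscrp = x))$log2_hscrp), x)
  expect_error(transform_biomarkers(data.frame(hscrp = -1)), "positive")
})

test_that("half-split is disjoint, exhaustive, deterministic, odd-n aware", {
  co <- generate_cohort(generator_config(n_participants = 100, seed = 7))
  sp <- split_cohort(co, seed = 11)
  expect_equal(nrow(sp$discovery), 50)
  expect_equal(nrow(sp$replication), 50)
  expect_length(intersect(sp$discovery$id, sp$replication$id), 0)
  expect_setequal(c(sp$discovery$id, sp$replication$id), co$id)
  sp2 <- split_cohort(co, seed = 11)
  expect_identical(sp2$discovery$id, sp$discovery$id)

  odd <- split_cohort(co[1:5, ], seed = 1)
  expect_equal(nrow(odd$discovery), 3)  # discovery takes the extra row
  expect_equal(nrow(odd$replication), 2)
  expect_error(split_cohort(co[1, , drop = FALSE]), "at least 2")
})
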