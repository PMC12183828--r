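test_that("component points reproduce the published scoring examples", {
  d17 <- load_canonical_definition("eADI-17")
  cr <- function(food) d17$criteria[d17$criteria$food == food, ]
  expect_equal(score_component(5.4, cr("wholegrains")), 1)
  expect_equal(score_component(3.0, cr("vegetables")), 0.5)
  expect_equal(score_component(1.0, cr("milk_3pct")), 0)
  expect_equal(score_component(0, cr("soft_drinks")), 1)
  # boundary semantics: closed middle interval, zero-anchored bottom = {0}
  expect_equal(score_component(c(2.4, 2.5, 4.0, 4.1), cr("wholegrains")),
               c(0, 0.5, 0.5, 1))
  expect_equal(score_component(c(0, 0.05, 1.0, 1.1), cr("nuts")),
               c(0, 0.5, 0.5, 1))
  # olive/canola usage count: 0 / 1 / more than 1
  expect_equal(score_component(0:4, cr("olive_canola_oil")),
               c(0, 0.5, 1, 1, 1))
  expect_error(score_component(-1, cr("vegetables")), "negative")
  expect_error(score_component(2.5, cr("olive_canola_oil")), "integer")
})

test_that("profile totals hit the forced values: 6.0, 17.0, 8.5", {
  d17 <- load_canonical_definition("eADI-17")
  units <- criterion_units(d17)
  zero <- stats::setNames(numeric(17), d17$criteria$food)
  expect_equal(score_participant(zero, d17, units = units)$total, 6.0)

  best <- stats::setNames(
    ifelse(d17$criteria$direction == "anti", d17$criteria$hi + 1, 0),
    d17$criteria$food)
  expect_equal(score_participant(best, d17, units = units)$total, 17.0)

  middle <- stats::setNames(
    ifelse(d17$criteria$zero_anchored, d17$criteria$hi, d17$criteria$lo),
    d17$criteria$food)
  expect_equal(score_participant(middle, d17, units = units)$total,
               17 * 0.5)
})

test_that("vectorized cohort scoring equals brute-force row scoring", {
  d17 <- load_canonical_definition("eADI-17")
  profiles <- random_profiles(d17, 1000, seed = 42)
  units <- criterion_units(d17)
  vec <- score_cohort(profiles, d17, units = units)
  brute <- vapply(seq_len(nrow(profiles)), function(i)
    brute_force_score(profiles[i, ], d17), numeric(1))
  expect_equal(as.numeric(vec), brute)
  # totals are always half-integers within range
  expect_true(all(vec * 2 == round(vec * 2)))
  expect_true(all(vec >= 0 & vec <= 17))
})

test_that("anti intake never lowers and pro intake never raises the score", {
  d17 <- load_canonical_definition("eADI-17")
  units <- criterion_units(d17)
  profiles <- random_profiles(d17, 200, seed = 7)
  base <- score_cohort(profiles, d17, units = units)
  for (food in c("vegetables", "nuts", "olive_canola_oil")) {
    up <- profiles
    up[[food]] <- pmin(up[[food]] + 1, if (food == "olive_canola_oil") 4
                       else Inf)
    expect_true(all(score_cohort(up, d17, units = units) >= base))
  }
  for (food in c("soft_drinks", "processed_meat")) {
    up <- profiles
    up[[food]] <- up[[food]] + 1
    expect_true(all(score_cohort(up, d17, units = units) <= base))
  }
})

test_that("flipping a criterion's direction mirrors its points", {
  d17 <- load_canonical_definition("eADI-17")
  x <- c(0, 0.1, 0.5, 1, 2, 3, 5)
  for (i in seq_len(nrow(d17$criteria))) {
    cr <- d17$criteria[i, ]
    xi <- if (cr$unit == "usage-count") 0:4 else x
    flipped <- cr
    flipped$direction <- if (cr$direction == "anti") "pro" else "anti"
    expect_equal(score_component(xi, flipped), 1 - score_component(xi, cr))
  }
})

test_that("daily intakes are converted to weekly criteria", {
  d17 <- load_canonical_definition("eADI-17")
  # 0.5 servings/day = 3.5/week: above the chicken hi cut-off of 0.5/week
  intakes <- stats::setNames(numeric(17), d17$criteria$food)
  intakes["chicken"] <- 0.5
  res <- score_participant(intakes, d17)
  expect_equal(unname(res$points["chicken"]), 1)
  # identical profile declared weekly scores the middle class
  res_wk <- score_participant(intakes, d17,
                              units = c(chicken = "servings/week"))
  expect_equal(unname(res_wk$points["chicken"]), 0.5)
  expect_error(
    score_participant(intakes, d17, units = c(chicken = "usage-count")),
    "cannot convert")
})

test_that("missing components follow the declared policy", {
  d17 <- load_canonical_definition("eADI-17")
  partial <- stats::setNames(numeric(16), setdiff(d17$criteria$food, "wine"))
  expect_error(score_participant(partial, d17), "wine")
  res <- score_participant(partial, d17, missing_policy = "zero")
  expect_equal(res$missing, "wine")
  expect_equal(unname(res$points["wine"]), 0)
})
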