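#' Candidate food-group pool
#'
#' The 33 FFQ-derived food groups that enter index development. Seventeen of
#' them carry planted inflammatory effects in the default synthetic generator
#' (11 anti-inflammatory, 6 pro-inflammatory); the remaining 16 are null
#' groups with no effect on the latent inflammation factor.
#'
#' @return Character vector of 33 food-group names.
#' @export
candidate_foods <- function() {
  c(anti_foods(), pro_foods(), null_foods())
}

anti_foods <- function() {
  c("vegetables", "olive_canola_oil", "nuts", "seeds", "legumes", "wine",
    "muesli", "chicken", "eggs", "wholegrains", "coffee")
}

pro_foods <- function() {
  c("soft_drinks", "sugar_honey", "milk_3pct", "boiled_potatoes",
    "processed_meat", "other_processed_foods")
}

null_foods <- function() {
  c("fish", "fruits", "berries", "cheese", "fermented_milk", "butter",
    "margarine", "tea", "beer", "spirits", "white_bread", "red_meat",
    "low_fat_milk", "root_vegetables", "crispbread", "porridge")
}
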