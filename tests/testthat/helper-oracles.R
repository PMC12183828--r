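# Brute-force row scorer: literal if-chains over the tertile classes,
# independent of score_component / score_cohort. Intakes are taken to be in
# each criterion's own unit.
brute_force_score <- function(intake_row, definition) {
  total <- 0
  for (i in seq_len(nrow(definition$criteria))) {
    cr <- definition$criteria[i, ]
    x <- intake_row[[cr$food]]
    if (isTRUE(cr$zero_anchored)) {
      anti <- if (x == 0) 0 else if (x <= cr$hi) 0.5 else 1
    } else {
      anti <- if (x < cr$lo) 0 else if (x <= cr$hi) 0.5 else 1
    }
    total <- total + if (cr$direction == "pro") 1 - anti else anti
  }
  total
}

# units vector declaring intakes already on each criterion's scale
criterion_units <- function(definition) {
  stats::setNames(definition$criteria$unit, definition$criteria$food)
}

# random intake profiles spanning all tertile classes of a definition
random_profiles <- function(definition, n, seed) {
  cr <- definition$criteria
  eadi:::with_local_seed(seed, {
    cols <- lapply(seq_len(nrow(cr)), function(i) {
      if (cr$unit[i] == "usage-count") sample(0:4, n, replace = TRUE)
      else round(stats::runif(n, 0, 2 * cr$hi[i] + 1), 2) *
        stats::rbinom(n, 1, 0.8)
    })
    names(cols) <- cr$food
    as.data.frame(cols)
  })
}

# small default cohort reused by validation tests
make_scored_cohort <- function(seed, n = 1500) {
  co <- generate_cohort(generator_config(n_participants = n, seed = seed))
  co <- transform_biomarkers(co)
  def <- load_canonical_definition("eADI-17")
  co$eadi <- as.numeric(score_cohort(co, def))
  co
}
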