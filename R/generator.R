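#' Default planted food effects
#'
#' Signed effect of one standard deviation of food intake on the latent
#' inflammation factor, in log2-biomarker units (before biomarker loadings).
#' Negative values mark anti-inflammatory foods, positive pro-inflammatory,
#' zero null. Defaults plant 11 anti, 6 pro and 16 null groups with
#' magnitudes graded like the correlation ordering seen for empirically
#' selected foods (vegetables/nuts/wine strongest, wholegrains/eggs weakest).
#'
#' @return Named numeric vector over [candidate_foods()].
#' @export
default_food_effects <- function() {
  eff <- stats::setNames(numeric(length(candidate_foods())), candidate_foods())
  eff[c("vegetables", "nuts", "wine")] <- -0.16
  eff[c("olive_canola_oil")] <- -0.14
  eff[c("seeds", "legumes", "muesli")] <- -0.13
  eff[c("chicken", "coffee")] <- -0.12
  eff[c("eggs", "wholegrains")] <- -0.11
  eff[c("soft_drinks")] <- 0.13
  eff[c("sugar_honey", "milk_3pct", "processed_meat")] <- 0.12
  eff[c("boiled_potatoes", "other_processed_foods")] <- 0.11
  eff
}

#' Default per-food intake model
#'
#' Zero-inflated log-normal intake parameters in servings/day: probability of
#' zero consumption, median among consumers, and log-scale SD. Parameters are
#' set so the consumption-tertile patterns resemble an elderly Swedish FFQ
#' cohort, including foods with more than two thirds of zero intake (seeds)
#' that exercise the zero-anchored tertile rule. The olive/canola component
#' is a 0-4 usage count (cooking/dressing x two oils) rather than a
#' servings amount and is modelled as an ordinal variable.
#'
#' @return data.frame with columns food, p_zero, median, sdlog.
#' @export
default_intake_model <- function() {
  m <- data.frame(
    food = candidate_foods(),
    p_zero = 0.05, median = 0.5, sdlog = 0.8,
    stringsAsFactors = FALSE
  )
  rownames(m) <- m$food
  set_row <- function(food, p, med, sd) {
    m[food, c("p_zero", "median", "sdlog")] <<- list(p, med, sd)
  }
  set_row("vegetables", 0.01, 3.0, 0.50)
  set_row("olive_canola_oil", NA, NA, NA)  # ordinal 0-4, see generate_cohort
  set_row("nuts", 0.33, 0.07, 1.00)
  set_row("seeds", 0.72, 0.07, 1.20)
  set_row("legumes", 0.52, 0.07, 0.90)
  set_row("wine", 0.25, 0.10, 1.00)
  set_row("muesli", 0.57, 0.20, 1.00)
  set_row("chicken", 0.09, 0.07, 0.80)
  set_row("eggs", 0.05, 0.21, 0.70)
  set_row("wholegrains", 0.02, 3.1, 0.55)
  set_row("coffee", 0.05, 2.0, 0.50)
  set_row("soft_drinks", 0.60, 0.04, 1.00)
  set_row("sugar_honey", 0.52, 0.35, 1.10)
  set_row("milk_3pct", 0.80, 0.30, 1.00)
  set_row("boiled_potatoes", 0.05, 0.60, 0.60)
  set_row("processed_meat", 0.03, 1.10, 0.60)
  set_row("other_processed_foods", 0.02, 2.00, 0.50)
  set_row("fish", 0.04, 0.50, 0.70)
  set_row("fruits", 0.03, 1.50, 0.60)
  set_row("berries", 0.30, 0.20, 0.90)
  set_row("cheese", 0.05, 1.00, 0.70)
  set_row("fermented_milk", 0.25, 0.70, 0.80)
  set_row("butter", 0.35, 0.60, 0.90)
  set_row("margarine", 0.30, 0.80, 0.90)
  set_row("tea", 0.40, 0.50, 1.00)
  set_row("beer", 0.35, 0.20, 1.10)
  set_row("spirits", 0.55, 0.05, 1.10)
  set_row("white_bread", 0.20, 0.80, 0.80)
  set_row("red_meat", 0.05, 0.60, 0.60)
  set_row("low_fat_milk", 0.45, 0.80, 1.00)
  set_row("root_vegetables", 0.10, 0.40, 0.70)
  set_row("crispbread", 0.15, 1.00, 0.80)
  set_row("porridge", 0.40, 0.40, 0.90)
  m
}

#' Default covariate effects
#'
#' Effects of covariates on the latent inflammation factor (log2-biomarker
#' units) and on the diet-quality propensity that shifts planted food
#' intakes. Smoking and BMI act on both pathways, so crude and
#' covariate-adjusted diet-biomarker estimates differ (confounding).
#'
#' @return list with components `inflammation` and `diet`.
#' @export
default_covariate_effects <- function() {
  list(
    inflammation = c(age_z = 0.20, smoking_current = 0.35,
                     smoking_former = 0.10, bmi_z = 0.30, cci = 0.08),
    diet = c(smoking_current = -0.50, smoking_former = -0.15,
             bmi_z = -0.30, education_university = 0.30)
  )
}

#' Synthetic cohort generator configuration
#'
#' Bundles every knob of the synthetic-cohort generator: sample size, seed,
#' planted signed food effects, intake distributions, biomarker loadings on
#' the shared latent inflammation factor, residual noise, covariate effects
#' and optional missingness rates. The seed fully determines the output.
#'
#' @param n_participants Number of men to simulate.
#' @param seed Integer seed; all randomness derives from it.
#' @param food_effects Named numeric vector over the candidate foods; sign
#'   encodes the planted role (negative = anti-inflammatory).
#' @param intake_model data.frame as [default_intake_model()].
#' @param biomarker_loadings Positive loadings of hsCRP, IL-6, TNF-R1 and
#'   TNF-R2 (log2 scale) on the latent inflammation factor.
#' @param noise_sd Per-biomarker residual SD on the log2 scale.
#' @param covariate_effects list as [default_covariate_effects()].
#' @param latent_sd SD of the residual part of the latent inflammation
#'   factor, beyond food and covariate contributions.
#' @param missingness Optional named rates in \[0,1\] for columns
#'   walking_cycling, smoking, sleep, bmi, sagittal, il6, tnfr, education;
#'   `NULL` generates complete data.
#' @return An object of class `eadi_config`.
#' @export
generator_config <- function(n_participants = 4432L,
                             seed = 1L,
                             food_effects = default_food_effects(),
                             intake_model = default_intake_model(),
                             biomarker_loadings = c(hscrp = 0.80, il6 = 0.95,
                                                    tnfr1 = 1.20, tnfr2 = 1.10),
                             noise_sd = c(hscrp = 1.80, il6 = 1.65,
                                          tnfr1 = 1.30, tnfr2 = 1.42),
                             covariate_effects = default_covariate_effects(),
                             latent_sd = 1,
                             missingness = NULL) {
  if (length(n_participants) != 1L || is.na(n_participants) || n_participants < 1)
    stop("n_participants must be a positive count", call. = FALSE)
  foods <- intake_model$food
  if (anyDuplicated(foods)) stop("duplicate foods in intake_model", call. = FALSE)
  unknown <- setdiff(names(food_effects), foods)
  if (length(unknown))
    stop("unknown food in food_effects: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  eff <- stats::setNames(numeric(length(foods)), foods)
  eff[names(food_effects)] <- food_effects
  if (length(biomarker_loadings) != 4L || any(biomarker_loadings <= 0))
    stop("biomarker_loadings must be 4 positive values", call. = FALSE)
  pz <- intake_model$p_zero
  if (any(pz < 0 | pz > 1, na.rm = TRUE))
    stop("zero-inflation probabilities must lie in [0,1]", call. = FALSE)
  if (any(noise_sd <= 0) || latent_sd <= 0)
    stop("noise SDs must be positive", call. = FALSE)
  cfg <- list(
    n_participants = as.integer(n_participants),
    seed = as.integer(seed),
    foods = foods,
    food_effects = eff,
    intake_model = intake_model,
    biomarker_loadings = biomarker_loadings,
    noise_sd = noise_sd,
    covariate_effects = covariate_effects,
    latent_sd = latent_sd,
    missingness = missingness
  )
  class(cfg) <- "eadi_config"
  cfg
}

#' @export
print.eadi_config <- function(x, ...) {
  truth <- planted_truth(x)
  cat("Synthetic cohort generator configuration\n")
  cat("  participants:", x$n_participants, " seed:", x$seed, "\n")
  cat("  foods:", length(x$foods),
      sprintf("(%d anti, %d pro, %d null)\n",
              sum(truth == "anti"), sum(truth == "pro"), sum(truth == "null")))
  invisible(x)
}

#' Planted ground-truth food roles
#'
#' @param config An `eadi_config`.
#' @return Named character vector over foods with values "anti", "pro",
#'   "null", from the sign of the planted effect.
#' @export
planted_truth <- function(config) {
  stopifnot(inherits(config, "eadi_config"))
  eff <- config$food_effects
  role <- ifelse(eff < 0, "anti", ifelse(eff > 0, "pro", "null"))
  stats::setNames(role, names(eff))
}

# Run expr under a local RNG stream without disturbing the caller's RNG state.
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Generate a synthetic cohort
#'
#' Simulates a cohort with the structure the index-development pipeline
#' assumes: 33 zero-inflated skewed food-group intakes, four positively
#' inter-correlated inflammatory biomarkers whose shared latent factor is
#' weakly driven by the planted foods and by covariates, plus the full
#' covariate set used in the adjusted models. Smoking and BMI confound the
#' diet-inflammation association by also shifting a diet-quality propensity
#' that moves planted intakes. hsCRP is emitted on the natural mg/L scale
#' (its latent value is log2) so the downstream log2 transform and the
#' hsCRP > 20 exclusion apply; the Olink markers are emitted as log2 NPX.
#'
#' @param config An `eadi_config`.
#' @return data.frame of class `eadi_cohort`: id, covariates, biomarkers and
#'   one intake column per food (servings/day; olive/canola as a 0-4 usage
#'   count). The latent inflammation factor is attached as attribute
#'   `latent` for generator diagnostics.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "eadi_config"))
  n <- config$n_participants
  with_local_seed(config$seed, {
    age <- pmin(pmax(round(stats::rnorm(n, 74, 6)), 63), 94)
    education <- sample(c("primary", "high school", "university"), n,
                        replace = TRUE, prob = c(0.45, 0.30, 0.25))
    walking_cycling <- sample(c("<20", "20-40", "40-60", ">60"), n,
                              replace = TRUE, prob = c(0.25, 0.35, 0.20, 0.20))
    smoking <- sample(c("never", "former", "current"), n,
                      replace = TRUE, prob = c(0.42, 0.48, 0.10))
    nsaid_use <- stats::rbinom(n, 1, 0.15)
    statin_use <- stats::rbinom(n, 1, 0.30)
    cortisone_use <- stats::rbinom(n, 1, 0.08)
    antibiotic_use <- sample(c("no", "<3 months", "3-6 months", "6-12 months"),
                             n, replace = TRUE, prob = c(0.75, 0.10, 0.08, 0.07))
    sleep <- sample(c("<=7", ">7"), n, replace = TRUE, prob = c(0.60, 0.40))
    bmi <- stats::rlnorm(n, log(26), 0.13)
    sagittal <- pmax(10 + 0.45 * bmi + stats::rnorm(n, 0, 1.5), 12)
    cci <- stats::rpois(n, 0.8)
    energy <- stats::rlnorm(n, log(2500), 0.25)

    age_z <- as.numeric(scale(age))
    bmi_z <- as.numeric(scale(bmi))
    ce <- config$covariate_effects

    # diet-quality propensity: higher = healthier diet pattern
    diet_q <- stats::rnorm(n) +
      ce$diet["smoking_current"] * (smoking == "current") +
      ce$diet["smoking_former"] * (smoking == "former") +
      ce$diet["bmi_z"] * bmi_z +
      ce$diet["education_university"] * (education == "university")

    eff <- config$food_effects
    role_dir <- sign(eff) * -1  # anti foods rise with diet quality, pro fall
    im <- config$intake_model
    intakes <- matrix(0, n, length(config$foods),
                      dimnames = list(NULL, config$foods))
    for (j in seq_along(config$foods)) {
      food <- config$foods[j]
      d <- role_dir[food]
      if (food == "olive_canola_oil") {
        # ordinal 0-4 usage count via thresholds on a shifted latent normal
        v <- 0.30 * d * diet_q + stats::rnorm(n)
        cuts <- stats::qnorm(cumsum(c(0.26, 0.29, 0.25, 0.12)))
        intakes[, j] <- findInterval(v, cuts)
        next
      }
      p_nonzero <- stats::plogis(stats::qlogis(1 - im$p_zero[j]) +
                                   0.35 * d * diet_q)
      consume <- stats::rbinom(n, 1, p_nonzero)
      amount <- exp(log(im$median[j]) + 0.15 * d * diet_q +
                      im$sdlog[j] * stats::rnorm(n))
      intakes[, j] <- consume * amount
    }

    z <- scale(intakes)
    z[, attr(z, "scaled:scale") == 0] <- 0

    latent <- drop(z %*% eff) +
      ce$inflammation["age_z"] * age_z +
      ce$inflammation["smoking_current"] * (smoking == "current") +
      ce$inflammation["smoking_former"] * (smoking == "former") +
      ce$inflammation["bmi_z"] * bmi_z +
      ce$inflammation["cci"] * cci +
      stats::rnorm(n, 0, config$latent_sd)

    a <- config$biomarker_loadings
    s <- config$noise_sd
    baseline <- c(hscrp = 0.6, il6 = 2.5, tnfr1 = 5.5, tnfr2 = 6.0)
    log2_markers <- sapply(1:4, function(k) {
      baseline[k] + a[k] * latent + stats::rnorm(n, 0, s[k])
    })

    cohort <- data.frame(
      id = sprintf("P%05d", seq_len(n)),
      age = age, education = education, walking_cycling = walking_cycling,
      smoking = smoking, nsaid_use = nsaid_use, statin_use = statin_use,
      cortisone_use = cortisone_use, antibiotic_use = antibiotic_use,
      sleep = sleep, bmi = bmi, sagittal = sagittal, cci = cci,
      energy = energy,
      hscrp = 2^log2_markers[, 1],
      il6 = log2_markers[, 2],
      tnfr1 = log2_markers[, 3],
      tnfr2 = log2_markers[, 4],
      stringsAsFactors = FALSE
    )
    cohort <- cbind(cohort, as.data.frame(intakes))

    mr <- config$missingness
    if (!is.null(mr)) {
      inject <- function(col, rate) {
        if (is.null(rate) || rate <= 0) return()
        idx <- which(stats::runif(n) < rate)
        cohort[idx, col] <<- NA
      }
      inject("walking_cycling", mr[["walking_cycling"]])
      inject("smoking", mr[["smoking"]])
      inject("sleep", mr[["sleep"]])
      inject("bmi", mr[["bmi"]])
      inject("sagittal", mr[["sagittal"]])
      inject("il6", mr[["il6"]])
      if (!is.null(mr[["tnfr"]]) && mr[["tnfr"]] > 0) {
        idx <- which(stats::runif(n) < mr[["tnfr"]])
        cohort[idx, c("tnfr1", "tnfr2")] <- NA
      }
      inject("education", mr[["education"]])
    }

    attr(cohort, "latent") <- latent
    attr(cohort, "foods") <- config$foods
    class(cohort) <- c("eadi_cohort", "data.frame")
    cohort
  })
}

#' Food intake columns of a cohort
#'
#' @param cohort A cohort data.frame from [generate_cohort()] or read from
#'   file with a `foods` attribute; otherwise `foods` must be given.
#' @param foods Optional explicit food column names.
#' @return Numeric matrix of intakes (participants x foods).
#' @export
intake_matrix <- function(cohort, foods = NULL) {
  foods <- foods %||% attr(cohort, "foods") %||%
    intersect(candidate_foods(), names(cohort))
  missing <- setdiff(foods, names(cohort))
  if (length(missing))
    stop("intake columns absent from cohort: ",
         paste(missing, collapse = ", "), call. = FALSE)
  as.matrix(cohort[, foods, drop = FALSE])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a cohort to CSV with a column dictionary
#'
#' Writes the cohort as plain CSV plus a JSON sidecar describing each column
#' (role, unit) and, when a config is supplied, the planted ground-truth
#' roles as JSON.
#'
#' @param cohort Cohort data.frame.
#' @param file CSV path; the sidecar is written as `<file>.dict.json`.
#' @param config Optional `eadi_config`; writes `<file>.truth.json`.
#' @return `file`, invisibly.
#' @export
write_cohort <- function(cohort, file, config = NULL) {
  utils::write.csv(as.data.frame(cohort), file, row.names = FALSE)
  foods <- attr(cohort, "foods") %||% intersect(candidate_foods(), names(cohort))
  dict <- lapply(names(cohort), function(col) {
    if (col %in% foods) {
      unit <- if (col == "olive_canola_oil") "usage-count (0-4)" else "servings/day"
      list(role = "food_group_intake", unit = unit)
    } else if (col == "hscrp") {
      list(role = "biomarker", unit = "mg/L")
    } else if (col %in% c("il6", "tnfr1", "tnfr2")) {
      list(role = "biomarker", unit = "log2 NPX")
    } else {
      list(role = "covariate", unit = switch(col,
        age = "years", bmi = "kg/m2", sagittal = "cm",
        energy = "kcal/day", cci = "score", "categorical/flag"))
    }
  })
  names(dict) <- names(cohort)
  jsonlite::write_json(dict, paste0(file, ".dict.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(config)) {
    jsonlite::write_json(as.list(planted_truth(config)),
                         paste0(file, ".truth.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(file)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param file CSV path.
#' @return Cohort data.frame with the `foods` attribute restored from the
#'   sidecar when present.
#' @export
read_cohort <- function(file) {
  cohort <- utils::read.csv(file, stringsAsFactors = FALSE)
  dict_file <- paste0(file, ".dict.json")
  if (file.exists(dict_file)) {
    dict <- jsonlite::read_json(dict_file)
    foods <- names(dict)[vapply(dict, function(d)
      identical(d$role, "food_group_intake"), logical(1))]
    attr(cohort, "foods") <- foods
  }
  class(cohort) <- c("eadi_cohort", "data.frame")
  cohort
}
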