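#' Patient profile
#'
#' The per-patient evidence used to personalize every service:
#' demographics, ADRD stage, comorbidities, and the hard and soft food
#' constraints. Allergies and religious constraints may name either food
#' ids or food classes; class-level entries exclude every food subsumed
#' by that class.
#'
#' @param age Age in years (> 0).
#' @param sex `"male"` or `"female"`.
#' @param adrd_stage `"early"`, `"middle"`, or `"late"`.
#' @param comorbidities Character vector of condition identifiers (e.g.
#'   `"type2_diabetes"`).
#' @param allergies,dislikes,preferences,religious_constraints Character
#'   vectors of food/class identifiers.
#' @param eer Estimated Energy Requirement in kcal/day, if known;
#'   otherwise derived on demand via [estimate_eer()].
#' @param meals_per_day Positive integer, default 3.
#' @param weight_kg,height_m Optional anthropometrics for the EER
#'   equations; sex-specific reference values are used when absent.
#' @param id Optional identifier used by profile files.
#' @return A `patient_profile` object.
#' @export
patient_profile <- function(age, sex, adrd_stage = "early",
                            comorbidities = character(),
                            allergies = character(), dislikes = character(),
                            preferences = character(),
                            religious_constraints = character(),
                            eer = NULL, meals_per_day = 3,
                            weight_kg = NULL, height_m = NULL, id = NULL) {
  if (!is_num(age) || age <= 0) {
    da_abort("patient age must be > 0", "dietassist_validation_error")
  }
  sex <- match.arg(sex, c("male", "female"))
  adrd_stage <- match.arg(adrd_stage, c("early", "middle", "late"))
  if (!is_count(meals_per_day, min = 1)) {
    da_abort("meals_per_day must be a positive integer", "dietassist_validation_error")
  }
  if (!is.null(eer) && (!is_num(eer) || eer <= 0)) {
    da_abort("eer, if given, must be > 0", "dietassist_validation_error")
  }
  structure(
    list(id = id, age = as.numeric(age), sex = sex, adrd_stage = adrd_stage,
         comorbidities = sort(unique(as.character(comorbidities))),
         allergies = sort(unique(as.character(allergies))),
         dislikes = sort(unique(as.character(dislikes))),
         preferences = sort(unique(as.character(preferences))),
         religious_constraints = sort(unique(as.character(religious_constraints))),
         eer = eer, meals_per_day = as.integer(meals_per_day),
         weight_kg = weight_kg, height_m = height_m),
    class = "patient_profile"
  )
}

#' Caregiver profile
#'
#' Captures the caregiver-side constraints that shape recommendations:
#' available cooking time, per-meal budget, and the education tier that
#' selects how technical generated responses are.
#'
#' @param time_limit Minutes available for cooking (> 0).
#' @param budget Currency units available per meal (> 0).
#' @param education_level `"basic"`, `"standard"`, or `"advanced"`.
#' @param id Optional identifier used by profile files.
#' @return A `caregiver_profile` object.
#' @export
caregiver_profile <- function(time_limit, budget,
                              education_level = "standard", id = NULL) {
  if (!is_num(time_limit) || time_limit <= 0) {
    da_abort("caregiver time_limit must be > 0", "dietassist_validation_error")
  }
  if (!is_num(budget) || budget <= 0) {
    da_abort("caregiver budget must be > 0", "dietassist_validation_error")
  }
  education_level <- match.arg(education_level, c("basic", "standard", "advanced"))
  structure(
    list(id = id, time_limit = as.numeric(time_limit),
         budget = as.numeric(budget), education_level = education_level),
    class = "caregiver_profile"
  )
}

has_diabetes <- function(patient) {
  any(grepl("diabet", patient$comorbidities, ignore.case = TRUE))
}

#' Estimated Energy Requirement (EER)
#'
#' Returns the profile's stored EER when present; otherwise computes the
#' Institute of Medicine adult EER equations at a "low active" physical
#' activity level:
#' \deqn{EER_{male} = 662 - 9.53\,age + PA (15.91\,wt + 539.6\,ht)}
#' \deqn{EER_{female} = 354 - 6.91\,age + PA (9.36\,wt + 726\,ht)}
#' with weight in kg, height in m, and PA = 1.11 (men) / 1.12 (women).
#' Missing anthropometrics fall back to reference values (77 kg / 1.76 m
#' for men, 64 kg / 1.62 m for women).
#'
#' @param patient A [patient_profile()].
#' @return EER in kcal/day.
#' @export
estimate_eer <- function(patient) {
  if (!is.null(patient$eer)) return(as.numeric(patient$eer))
  male <- patient$sex == "male"
  wt <- patient$weight_kg %||% if (male) 77 else 64
  ht <- patient$height_m %||% if (male) 1.76 else 1.62
  if (male) {
    662 - 9.53 * patient$age + 1.11 * (15.91 * wt + 539.6 * ht)
  } else {
    354 - 6.91 * patient$age + 1.12 * (9.36 * wt + 726 * ht)
  }
}
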