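# Analysis-view schema of a head-and-neck tumor registry cohort:
# 38 pre-treatment attributes (demography, history, preliminary diagnoses)
# and 6 therapy-decision labels. The categorical cardinalities are a fixed
# fixture chosen so the one-hot encoded dimension is exactly 160.

DECISION_NAMES <- c("therapy_intention", "operation", "radiation",
                    "local_chemotherapy", "systemic_chemotherapy",
                    "other_therapy")

#' Default cohort schema
#'
#' The fixture schema of the synthetic registry cohort: 8 numeric
#' pre-treatment attributes (age, height, weight, amount of alcohol, pack
#' years, tumor number, tumor size, duration of precancerous lesions) and 30
#' categorical ones (staging classifications, clinical state, risk factors,
#' comorbidities, ...) whose cardinalities sum to 152, so that one-hot
#' expansion plus the numeric pass-throughs yields exactly 160 encoded
#' features. The six decision attributes are the therapy intention (encoded
#' positive = curative) and whether an operation, radiation therapy, local
#' chemotherapy, systemic chemotherapy, or other therapy was carried out.
#'
#' @return object of class `cohort_schema` with fields `attributes`
#'   (data.frame: name, kind, cardinality), `levels` (named list of category
#'   sets), `decisions`, `encoded_dimension`.
#' @examples
#' s <- default_schema()
#' nrow(s$attributes)   # 38
#' s$encoded_dimension  # 160
#' @export
default_schema <- function() {
  numeric_attrs <- c("age", "height", "weight", "amount_of_alcohol",
                     "pack_years", "tumor_number", "tumor_size",
                     "duration_precancerous_lesions")
  categorical <- c(
    sex = 3, t_classification = 8, n_classification = 8,
    m_classification = 4, clinical_state = 8, grading = 5, tumor_type = 8,
    reason_for_visit = 12, familial_tumor_predisposition = 2,
    inflammatory_response = 5, degree_of_dysplasia = 5,
    existing_precancerous_lesions = 2, heavy_heart_disease = 2,
    restricted_lung_function = 2, hpv_status = 4, smoking_status = 5,
    alcohol_abuse = 4, diabetes = 3, hypertension = 3,
    renal_insufficiency = 3, liver_disease = 3, immunosuppression = 3,
    prior_radiation = 3, prior_tumor_surgery = 3, dental_status = 5,
    nutritional_status = 5, ecog_status = 7, asa_classification = 6,
    tumor_localization = 14, diagnosis_admission_status = 7
  )
  attributes <- rbind(
    data.frame(name = numeric_attrs, kind = "numeric",
               cardinality = NA_integer_, stringsAsFactors = FALSE),
    data.frame(name = names(categorical), kind = "categorical",
               cardinality = as.integer(categorical), stringsAsFactors = FALSE)
  )
  levels <- lapply(categorical, function(k) paste0("l", seq_len(k)))
  structure(
    list(attributes = attributes,
         levels = levels,
         decisions = DECISION_NAMES,
         encoded_dimension = as.integer(length(numeric_attrs) + sum(categorical))),
    class = "cohort_schema"
  )
}

#' @export
print.cohort_schema <- function(x, ...) {
  cat(sprintf("cohort schema: %d pre-treatment attributes (%d numeric, %d categorical), %d decisions, encoded dimension %d\n",
              nrow(x$attributes), sum(x$attributes$kind == "numeric"),
              sum(x$attributes$kind == "categorical"),
              length(x$decisions), x$encoded_dimension))
  invisible(x)
}
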