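# Shared fixtures: a small hand-specified nomogram and cohort builders.
# All built in code; nothing here depends on the shipped default table.

test_nomogram <- function() {
  nomogram(
    variables = list(
      age = list(type = "continuous", breakpoints = c(40, 60, 80),
                 points = c(0, 10, 20)),
      heart_rate = list(type = "continuous", breakpoints = c(50, 100),
                        points = c(0, 15)),
      systolic_bp = list(type = "continuous", breakpoints = c(80, 120, 160),
                         points = c(30, 15, 0)),
      creatinine = list(type = "continuous", breakpoints = c(50, 100, 200),
                        points = c(0, 5, 10)),
      diuretic_in_hospital = list(type = "binary", points = 20),
      cardiac_arrest = list(type = "binary", points = 25),
      st_deviation = list(type = "binary", points = 10),
      elevated_markers = list(type = "binary", points = 12)
    ),
    score_to_risk = data.frame(score = c(0, 40, 80, 120, 160),
                               risk = c(0.005, 0.02, 0.08, 0.25, 0.60)),
    name = "test-nomogram"
  )
}

# minimal complete record, overridable field by field
make_record <- function(id = "p1", ...) {
  rec <- list(
    patient_id = id, age = 65, heart_rate = 75, systolic_bp = 130,
    creatinine = 90, diuretic_in_hospital = FALSE, cardiac_arrest = FALSE,
    st_deviation = TRUE, elevated_markers = TRUE, oad_indicator = FALSE,
    smoking = "never", diagnosis = "NSTEMI", diabetes = FALSE,
    admission_year = 2010L, died_6m = FALSE
  )
  over <- list(...)
  rec[names(over)] <- over
  as.data.frame(rec, stringsAsFactors = FALSE)
}

make_cohort <- function(...) {
  recs <- list(...)
  do.call(rbind, recs)
}

small_synthetic_cohort <- function(n = 2000, seed = 11, ...) {
  generate_cohort(generator_config(n = n, seed = seed, ...))
}
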