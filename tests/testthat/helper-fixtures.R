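# Small hand-built fixtures used across test files.

make_visit <- function(date, department = "radiologie",
                       procedure = "mammographie", ...) {
  visit_event(date = date, department = department, procedure = procedure,
              ...)
}

# A patient with three visits spanning the history window.
make_record <- function(patient_id = "T001",
                        diagnosis_date = as.Date("2016-03-01"),
                        surgery_date = as.Date("2016-04-01"),
                        dfs_event = FALSE, followup_days = 1500,
                        visits = NULL, ...) {
  if (is.null(visits)) {
    visits <- list(
      make_visit(diagnosis_date - 10),
      make_visit(surgery_date, department = "chirurgie",
                 procedure = "tumorectomie", tumor_size_cm = 2.0),
      make_visit(surgery_date + 40, department = "oncologie medicale",
                 procedure = "seance chimiotherapie")
    )
  }
  patient_record(
    patient_id = patient_id, birth_date = as.Date("1960-01-01"),
    diagnosis_date = diagnosis_date, surgery_date = surgery_date,
    visits = visits, molecular_subtype = "Luminal", tumor_grade = 2,
    n_nodes = 1, tnm_stage = "T1", tumor_size_cm = 2.0,
    dfs_event = dfs_event, followup_days = followup_days, ...
  )
}

# A visit carrying every one of the 17 tokenizable features (all five
# markers measured and all five deltas non-zero given prev_bio below).
make_full_visit <- function(date = as.Date("2016-04-10")) {
  visit_event(
    date = date, department = "oncologie medicale",
    procedure = "seance chimiotherapie", therapy = "chimiotherapie",
    subtherapy = "taxane",
    bio_values = list(MONO = 0.6, LEUK = 12, LYMP = 2, PN = 3,
                      `CA15-3` = 45),
    tumor_size_cm = 2.5
  )
}

full_visit_context <- function() {
  # previous values chosen so every marker delta is at least 5 units,
  # hence non-zero after the divide-by-ten discretization
  list(
    marker_specs = default_marker_specs(),
    prev_bio = list(MONO = 6, LEUK = 5, LYMP = 9, PN = 10,
                    `CA15-3` = 10),
    birth_date = as.Date("1960-01-01"),
    subtype = "Luminal",
    dnpi_group = "GPG"
  )
}

# Cached small labelled cohort shared by the model-level tests.
small_cohort_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      co <- generate_cohort(sim_config(n_patients = 120, seed = 2024))
      cache <<- apply_cohort_filters(co)$kept
    }
    cache
  }
})

# Tiny encoder configuration used wherever a model must actually train.
tiny_encoder_config <- function(seed = 1, epochs = 2, max_len = 48) {
  encoder_config(n_layers = 2, n_heads = 2, hidden = 16, intermediate = 24,
                 max_len = max_len, learning_rate = 1e-3, batch_size = 16,
                 epochs = epochs, seed = seed)
}
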