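#' Configuration of the synthetic EHR cohort generator
#'
#' Defines the study conditions the generator emulates: cohort size, the
#' ~6.2% three-year event prevalence of the modelled breast-cancer
#' population, visit intensity, department/procedure vocabularies with
#' joint (co-occurring) draws, therapy vocabularies, marker baselines and
#' missingness, planted prognostic effect sizes (log-odds scale), an
#' independent censoring distribution, and the report template bank with
#' relapse-linked signal phrases.
#'
#' @param n_patients Number of patients to generate.
#' @param prevalence Target three-year event prevalence (default 0.062).
#' @param visits_per_month Mean visit intensity over the history window.
#' @param effects Named list of planted log-odds effect sizes:
#'   `npi` (per NPI unit), `tnbc` (TNBC vs other subtypes),
#'   `ca153_abnormal` (any abnormal CA 15-3 measurement). Set all to zero
#'   for a null cohort.
#' @param marker_missingness Named numeric vector of per-marker missing
#'   probabilities (given the biology panel was sampled at the visit).
#' @param p_bio_panel Probability a visit carries a biology panel.
#' @param p_abnormal Probability a measured marker value falls outside
#'   its normal range.
#' @param censor_range Two-element day range of the independent uniform
#'   censoring distribution.
#' @param horizon_days Event-dichotomization horizon (default 1095).
#' @param report_length_mean,report_length_sd Mean and sd of the report
#'   word count (default mean 159 words).
#' @param signal_phrases Character vector of multi-word (3--9 word)
#'   phrases injected into reports of event-bound patients.
#' @param p_signal_event,p_signal_noevent Injection probability per
#'   report for patients with/without an event.
#' @param seed Mandatory integer seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_patients = 500,
                       prevalence = 0.062,
                       visits_per_month = 1.0,
                       effects = list(npi = 0.9, tnbc = 1.0,
                                      ca153_abnormal = 0.8),
                       marker_missingness = c(MONO = 0.10, LEUK = 0.05,
                                              LYMP = 0.10, PN = 0.08,
                                              `CA15-3` = 0.25),
                       p_bio_panel = 0.6,
                       p_abnormal = 0.15,
                       censor_range = c(400, 2600),
                       horizon_days = 1095,
                       report_length_mean = 159,
                       report_length_sd = 30,
                       signal_phrases = default_signal_phrases(),
                       p_signal_event = 0.8,
                       p_signal_noevent = 0.05,
                       seed = NULL) {
  if (is.null(seed)) stop_input("sim_config requires an explicit seed")
  if (!is_scalar_number(prevalence) || prevalence <= 0 || prevalence >= 1) {
    stop_input("prevalence must lie in (0, 1)")
  }
  if (visits_per_month < 0 || p_bio_panel < 0 || p_abnormal < 0 ||
      any(unlist(marker_missingness) < 0)) {
    stop_input("rates must be non-negative")
  }
  structure(
    list(n_patients = n_patients, prevalence = prevalence,
         visits_per_month = visits_per_month, effects = effects,
         marker_missingness = marker_missingness, p_bio_panel = p_bio_panel,
         p_abnormal = p_abnormal, censor_range = censor_range,
         horizon_days = horizon_days,
         report_length_mean = report_length_mean,
         report_length_sd = report_length_sd,
         signal_phrases = signal_phrases,
         p_signal_event = p_signal_event,
         p_signal_noevent = p_signal_noevent,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Default relapse-linked signal phrases
#'
#' Multi-word pseudo-clinical phrases (3--9 words each) planted in the
#' reports of event-bound patients, giving the frequent-sequence miner a
#' recoverable target.
#' @return Character vector of phrases.
#' @export
default_signal_phrases <- function() {
  c("progression tumorale suspecte avec adenopathie axillaire persistante",
    "masse residuelle palpable du lit operatoire")
}

# Department -> procedure co-occurrence structure: procedures are (mostly)
# department-specific so the MLM has recoverable context.
sim_departments <- function() {
  list(
    radiologie = c("mammographie", "echographie mammaire", "irm mammaire"),
    `oncologie medicale` = c("consultation oncologie", "seance chimiotherapie"),
    chirurgie = c("tumorectomie", "mastectomie", "consultation chirurgie"),
    radiotherapie = c("seance radiotherapie", "simulation radiotherapie"),
    laboratoire = c("bilan sanguin", "dosage marqueurs"),
    `consultation pluridisciplinaire` = c("reunion rcp", "consultation suivi")
  )
}

sim_therapies <- function() {
  list(
    chimiotherapie = c("anthracycline", "taxane"),
    hormonotherapie = c("tamoxifene", "inhibiteur aromatase"),
    radiotherapie = c("rt externe"),
    `therapie ciblee` = c("trastuzumab")
  )
}

# One visit of the adjuvant care pathway. Visits follow the standard
# phase structure (screening/workup -> surgery -> chemotherapy cycles ->
# radiotherapy -> surveillance), so departments, procedures and
# therapies co-occur within visits and cluster in time, as in routine
# oncology care.
sim_pathway_visit <- function(kind, date, config, specs, chemo_molecule,
                              hormono) {
  depts <- sim_departments()
  plan <- switch(kind,
    screening = list(dept = "radiologie", therapy = NA, p_bio = 0.1),
    workup = list(dept = sample(c("radiologie", "laboratoire",
                                  "consultation pluridisciplinaire"), 1,
                                prob = c(0.5, 0.3, 0.2)),
                  therapy = NA, p_bio = 0.4),
    surgery = list(dept = "chirurgie", therapy = "chirurgie", p_bio = 0.5),
    chemo = list(dept = "oncologie medicale", therapy = "chimiotherapie",
                 p_bio = 0.9),
    radio = list(dept = "radiotherapie", therapy = "radiotherapie",
                 p_bio = 0.1),
    surveillance = list(dept = sample(c("consultation pluridisciplinaire",
                                        "laboratoire"), 1),
                        therapy = if (hormono) "hormonotherapie" else NA,
                        p_bio = 0.5)
  )
  # occasional off-pathway visit keeps the structure noisy but learnable
  dept <- if (stats::runif(1) < 0.85) plan$dept else sample(names(depts), 1)
  proc <- if (kind == "surgery" && dept == "chirurgie") {
    sample(c("tumorectomie", "mastectomie"), 1)
  } else if (kind == "chemo" && dept == "oncologie medicale") {
    "seance chimiotherapie"
  } else {
    sample(depts[[dept]], 1)
  }
  therapy <- plan$therapy
  subtherapy <- if (is.na(therapy)) NA else switch(therapy,
    chimiotherapie = chemo_molecule,
    chirurgie = proc,
    radiotherapie = "rt externe",
    hormonotherapie = sample(sim_therapies()$hormonotherapie, 1)
  )
  bio <- NULL
  if (stats::runif(1) < plan$p_bio * config$p_bio_panel / 0.6) {
    bio <- list()
    for (m in names(specs)) {
      if (stats::runif(1) < config$marker_missingness[[m]]) next
      s <- specs[[m]]
      mid <- (s$normal_low + s$normal_high) / 2
      sdv <- (s$normal_high - s$normal_low) / 6
      val <- if (stats::runif(1) < config$p_abnormal) {
        s$normal_high + abs(stats::rnorm(1, 2 * sdv, sdv))
      } else {
        min(s$normal_high, max(s$normal_low, stats::rnorm(1, mid, sdv)))
      }
      bio[[m]] <- round(val, 2)
    }
    if (length(bio) == 0L) bio <- NULL
  }
  list(date = date, department = dept, procedure = proc, therapy = therapy,
       subtherapy = subtherapy, bio = bio)
}

#' Generate a synthetic patient cohort
#'
#' Draws static clinical features, a chronological visit process with
#' jointly sampled department/procedure pairs, biological marker panels
#' with configured missingness, and a survival outcome: event times are
#' exponential with rate scaled by a centred logistic linear predictor on
#' (NPI, TNBC subtype, abnormal CA 15-3), then dichotomized at the
#' three-year horizon; censoring is drawn independently of covariates.
#' Fully reproducible given `config$seed`.
#'
#' @param config A [sim_config()].
#' @param reports If `TRUE` (default) attach free-text reports via
#'   [generate_reports()].
#' @return List of [patient_record()]s.
#' @examples
#' cohort <- generate_cohort(sim_config(n_patients = 20, seed = 1))
#' length(cohort)
#' @export
generate_cohort <- function(config, reports = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n <- config$n_patients
    depts <- sim_departments()
    thers <- sim_therapies()
    specs <- default_marker_specs()

    raw <- vector("list", n)
    eta <- numeric(n)
    for (i in seq_len(n)) {
      age_dx <- min(85, max(25, stats::rnorm(1, 55, 10)))
      diagnosis <- as.Date("2015-01-01") + stats::runif(1, 0, 1460)
      surgery <- diagnosis + round(stats::runif(1, 20, 60))
      birth <- diagnosis - round(age_dx * 365.25)
      subtype <- sample(molecular_subtypes(), 1,
                        prob = c(0.70, 0.12, 0.08, 0.10))
      grade <- sample(1:3, 1, prob = c(0.25, 0.45, 0.30))
      n_nodes <- if (stats::runif(1) < 0.6) 0L else 1L + stats::rpois(1, 1.5)
      size <- round(stats::rgamma(1, shape = 4, rate = 1.8), 1)
      tnm <- if (size <= 2) "T1" else if (size <= 5) "T2" else "T3"

      # Adjuvant care pathway: screening/workup, surgery, chemotherapy
      # cycles, optional radiotherapy, surveillance. The intensity knob
      # scales the number of visits in each phase.
      k <- config$visits_per_month
      chemo_molecule <- sample(thers$chimiotherapie, 1)
      hormono <- subtype %in% c("Luminal", "HER2+/RH+") && stats::runif(1) < 0.8
      plan <- list()
      if (stats::runif(1) < 0.7) {
        plan[[length(plan) + 1L]] <-
          list(kind = "screening", date = diagnosis - round(stats::runif(1, 40, 110)))
      }
      for (j in seq_len(max(2L, stats::rpois(1, 3 * k)))) {
        plan[[length(plan) + 1L]] <-
          list(kind = "workup",
               date = diagnosis + round(stats::runif(1, 0, max(
                 1, as.numeric(surgery - diagnosis) - 2))))
      }
      plan[[length(plan) + 1L]] <- list(kind = "surgery", date = surgery)
      n_cycles <- max(3L, stats::rpois(1, 5 * k))
      chemo_start <- surgery + round(stats::runif(1, 20, 40))
      for (j in seq_len(n_cycles)) {
        plan[[length(plan) + 1L]] <-
          list(kind = "chemo",
               date = chemo_start + 21 * (j - 1) + sample(-2:2, 1))
      }
      rt_start <- chemo_start + 21 * n_cycles + round(stats::runif(1, 10, 25))
      if (stats::runif(1) < 0.7) {
        for (j in seq_len(max(2L, stats::rpois(1, 4 * k)))) {
          plan[[length(plan) + 1L]] <-
            list(kind = "radio", date = rt_start + round(stats::runif(1, 0, 40)))
        }
      }
      for (j in seq_len(max(1L, stats::rpois(1, 2 * k)))) {
        plan[[length(plan) + 1L]] <-
          list(kind = "surveillance",
               date = rt_start + 45 + round(stats::runif(1, 0, 120)))
      }
      plan <- plan[order(vapply(plan, function(p) as.numeric(p$date),
                                numeric(1)))]
      visits <- vector("list", length(plan))
      any_abn_ca <- FALSE
      for (v in seq_along(plan)) {
        pv <- sim_pathway_visit(plan[[v]]$kind, plan[[v]]$date, config,
                                specs, chemo_molecule, hormono)
        if (!is.null(pv$bio[["CA15-3"]]) &&
            pv$bio[["CA15-3"]] > specs[["CA15-3"]]$normal_high) {
          any_abn_ca <- TRUE
        }
        size_here <- NA
        if (v == 1L) size_here <- size
        if (plan[[v]]$kind == "surgery") {
          size_here <- max(0.1, round(size + stats::rnorm(1, 0, 0.3), 1))
        }
        visits[[v]] <- visit_event(
          date = pv$date, department = pv$department,
          procedure = pv$procedure, therapy = pv$therapy,
          subtherapy = pv$subtherapy, bio_values = pv$bio,
          tumor_size_cm = size_here
        )
      }
      npi <- compute_npi(size, grade, n_nodes)$npi
      eta[i] <- config$effects$npi * npi +
        config$effects$tnbc * (subtype == "TNBC") +
        config$effects$ca153_abnormal * any_abn_ca
      raw[[i]] <- list(
        patient_id = sprintf("P%05d", i), birth_date = birth,
        diagnosis_date = diagnosis, surgery_date = surgery,
        visits = visits, molecular_subtype = subtype, tumor_grade = grade,
        n_nodes = n_nodes, tnm_stage = tnm, tumor_size_cm = size
      )
    }

    # Centre the linear predictor so the baseline exponential rate hits the
    # target prevalence at the horizon when all effects are zero.
    eta <- eta - mean(eta)
    rate0 <- -log(1 - config$prevalence) / config$horizon_days
    records <- vector("list", n)
    for (i in seq_len(n)) {
      t_event <- stats::rexp(1, rate = rate0 * exp(eta[i]))
      t_cens <- stats::runif(1, config$censor_range[1], config$censor_range[2])
      event <- t_event <= t_cens
      followup <- round(min(t_event, t_cens))
      r <- raw[[i]]
      # Static missingness, applied after the outcome draw so the planted
      # signal reflects the true (not observed) covariates.
      if (stats::runif(1) < 0.08) r$tumor_size_cm <- NA
      if (stats::runif(1) < 0.05) r$tumor_grade <- NA
      if (stats::runif(1) < 0.05) r$n_nodes <- NA
      if (stats::runif(1) < 0.03) r$molecular_subtype <- NA
      records[[i]] <- patient_record(
        patient_id = r$patient_id, birth_date = r$birth_date,
        diagnosis_date = r$diagnosis_date, surgery_date = r$surgery_date,
        visits = r$visits, molecular_subtype = r$molecular_subtype,
        tumor_grade = r$tumor_grade, n_nodes = r$n_nodes,
        tnm_stage = r$tnm_stage, tumor_size_cm = r$tumor_size_cm,
        dfs_event = event, followup_days = followup
      )
    }
    if (reports) {
      records <- lapply(records, generate_reports, config = config)
    }
    records
  })
}

# Filler vocabulary for pseudo-clinical report text.
sim_report_vocab <- function() {
  c("examen", "clinique", "sein", "droit", "gauche", "sans", "anomalie",
    "lesion", "nodule", "axillaire", "bilan", "biologique", "normal",
    "patiente", "suivie", "pour", "carcinome", "canalaire", "infiltrant",
    "traitement", "adjuvant", "en", "cours", "tolerance", "correcte",
    "controle", "prevu", "dans", "trois", "mois", "aspect", "cicatriciel",
    "stable", "pas", "de", "signe", "evolutif", "surveillance",
    "marqueurs", "dosage", "resultat", "attente", "protocole", "standard")
}

#' Attach templated free-text reports to a patient's visits
#'
#' Each visit receives a pseudo-clinical report opening with its
#' department and procedure, followed by filler sentences drawn from a
#' fixed vocabulary up to the configured word count. Patients whose event
#' occurs within the horizon receive a configured signal phrase in each
#' report with probability `p_signal_event` (`p_signal_noevent`
#' otherwise), emulating discriminative text.
#'
#' @param record A [patient_record()] from [generate_cohort()].
#' @param config The [sim_config()] used for generation.
#' @return The record with `report_text` filled on every visit.
#' @export
generate_reports <- function(record, config) {
  vocab <- sim_report_vocab()
  is_event <- isTRUE(record$dfs_event) &&
    record$followup_days <= config$horizon_days
  p_signal <- if (is_event) config$p_signal_event else config$p_signal_noevent
  record$visits <- lapply(record$visits, function(visit) {
    n_words <- max(10, round(stats::rnorm(1, config$report_length_mean,
                                          config$report_length_sd)))
    header <- c(visit$department, visit$procedure)
    body <- sample(vocab, max(0, n_words - length(header)), replace = TRUE)
    words <- c(header, body)
    if (length(config$signal_phrases) > 0 && stats::runif(1) < p_signal) {
      phrase <- sample(config$signal_phrases, 1)
      pos <- sample.int(length(words), 1)
      words <- append(words, strsplit(phrase, " ")[[1]], after = pos)
    }
    visit$report_text <- paste(words, collapse = " ")
    visit
  })
  record
}
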