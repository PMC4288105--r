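# ---- Cohort specification --------------------------------------------------

#' Specify a synthetic EHR cohort
#'
#' Describes the statistical structure of a synthetic cohort: size,
#' seed, comorbidity prevalences, and the mix of medication scenarios.
#' Each patient realises exactly one scenario:
#'
#' * `naive` — no neuropathic-pain (NP) drugs at all;
#' * `first_line_only` — one or two current first-line drugs, never a
#'   current line-2/3 order;
#' * `first_plus_second` — a current first-line drug plus a current
#'   opioid or tramadol (the borderline case that triggers the scope
#'   warning);
#' * `third_line` — a current third-line drug, half the time alongside
#'   a first-line drug;
#' * `past_only` — no current NP drug, but one or two NP orders that
#'   ended within the five-year lookback.
#'
#' Default prevalences and weights are chosen as plausible for an older
#' primary-care population with chronic pain; they are configuration, to
#' be varied per study.
#'
#' @param n Number of patients.
#' @param seed Integer seed; the whole cohort is a deterministic
#'   function of the spec.
#' @param prevalence Named probabilities per comorbidity (names must
#'   match the comorbidity map).
#' @param scenario_weights Named probabilities per scenario, summing
#'   to 1.
#' @param age_range Two integers, inclusive.
#' @param as_of Reference date for all relative dates.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n, seed,
                        prevalence = c(heart_disease = 0.25, depression = 0.30,
                                       diabetes = 0.25, renal_disease = 0.10,
                                       seizure_disorder = 0.05, glaucoma = 0.08),
                        scenario_weights = c(naive = 0.25, first_line_only = 0.35,
                                             first_plus_second = 0.15,
                                             third_line = 0.10, past_only = 0.15),
                        age_range = c(35L, 90L),
                        as_of = as.Date("2014-06-01")) {
  problems <- character(0)
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 0 || n != floor(n))
    problems <- c(problems, "n: must be a non-negative integer")
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    problems <- c(problems, "seed: must be an integer")
  if (is.null(names(prevalence)) || any(prevalence < 0 | prevalence > 1))
    problems <- c(problems, "prevalence: named probabilities in [0,1]")
  known <- c("naive", "first_line_only", "first_plus_second", "third_line",
             "past_only")
  if (is.null(names(scenario_weights)) ||
      !all(names(scenario_weights) %in% known))
    problems <- c(problems,
                  paste0("scenario_weights: names must be among ",
                         paste(known, collapse = ", ")))
  else if (any(scenario_weights < 0) ||
           abs(sum(scenario_weights) - 1) > 1e-9)
    problems <- c(problems, "scenario_weights: must be >= 0 and sum to 1")
  if (length(age_range) != 2L || age_range[1] > age_range[2])
    problems <- c(problems, "age_range: must be c(lo, hi) with lo <= hi")
  if (length(problems))
    stop("invalid cohort spec:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 prevalence = prevalence, scenario_weights = scenario_weights,
                 age_range = as.integer(age_range), as_of = as.Date(as_of)),
            class = "cohort_spec")
}

# per-patient substream seed derived by counter, so insertion order and
# cohort size never change any other patient's records
patient_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + i * 16807) %% 2147483647)
}

.decoy_icd9 <- c("401.9", "272.4", "465.9", "724.2", "530.81", "780.52")
.decoy_drugs <- c("lisinopril", "metformin", "atorvastatin", "omeprazole")

.dose_text <- c(amitriptyline = "25 mg PO qhs", nortriptyline = "25 mg PO qhs",
                duloxetine = "60 mg PO daily", venlafaxine = "75 mg PO daily",
                gabapentin = "300 mg PO tid", pregabalin = "75 mg PO bid",
                morphine = "15 mg PO q12h", oxycodone = "5 mg PO q6h prn",
                hydrocodone = "5 mg PO q6h prn", methadone = "5 mg PO bid",
                tramadol = "50 mg PO q6h prn",
                carbamazepine = "200 mg PO bid", lamotrigine = "100 mg PO bid",
                topiramate = "50 mg PO bid", "valproic acid" = "250 mg PO bid",
                bupropion = "150 mg PO daily", citalopram = "20 mg PO daily",
                paroxetine = "20 mg PO daily")

dose_for <- function(drug) {
  d <- unname(.dose_text[drug])
  ifelse(is.na(d), paste(drug, "dose per pharmacy"), d)
}

#' Generate a synthetic EHR cohort
#'
#' Produces the three EHR tables the extraction layer consumes.  For a
#' fixed spec (including seed) the output is bit-for-bit reproducible,
#' and each patient's records depend only on the seed and the patient's
#' index.  Diagnosis codes are drawn from the comorbidity map's
#' prefixes (extended with a random decimal), plus decoy codes that map
#' to no comorbidity — roughly a fifth of diagnosis records — to
#' exercise the negative path of prefix matching.  All generated
#' records satisfy the extractor's record-level validation.
#'
#' @param spec A [cohort_spec()].
#' @param comorbidity_map A [read_comorbidity_map()]; prevalences with
#'   no matching comorbidity are an error.
#' @param taxonomy A [read_taxonomy()].
#' @return List of data frames `patients` (`patient_id`, `name`, `age`,
#'   `sex`, `scenario`), `diagnoses`, `orders`.
#' @export
generate_cohort <- function(spec,
                            comorbidity_map = read_comorbidity_map(),
                            taxonomy = read_taxonomy()) {
  stopifnot(inherits(spec, "cohort_spec"))
  bad <- setdiff(names(spec$prevalence), names(comorbidity_map))
  if (length(bad))
    stop("prevalence for unknown comorbidity: ", paste(bad, collapse = ", "),
         call. = FALSE)
  as_of <- spec$as_of
  line1 <- taxonomy$drug[taxonomy$line == 1L]
  line2 <- taxonomy$drug[taxonomy$line == 2L]
  line3 <- taxonomy$drug[taxonomy$line == 3L]

  pat_rows <- vector("list", spec$n)
  dx_rows <- vector("list", spec$n)
  od_rows <- vector("list", spec$n)

  for (i in seq_len(spec$n)) {
    set.seed(patient_seed(spec$seed, i))
    id <- sprintf("P%05d", i)
    age <- sample(seq(spec$age_range[1], spec$age_range[2]), 1L)
    sex <- sample(c("M", "F"), 1L, prob = c(0.9, 0.1))  # VA-like population
    scenario <- sample(names(spec$scenario_weights), 1L,
                       prob = spec$scenario_weights)

    # -- diagnoses: comorbidities by prevalence, then ~20% decoys
    dx <- list()
    for (cm in names(spec$prevalence)) {
      if (stats::runif(1) < spec$prevalence[[cm]]) {
        k <- sample(1:2, 1L)
        pref <- sample(comorbidity_map[[cm]], k, replace = TRUE)
        ext <- sample(0:9, k, replace = TRUE)
        code <- ifelse(stats::runif(k) < 0.6,
                       ifelse(grepl("\\.", pref), paste0(pref, ext),
                              paste0(pref, ".", ext)),
                       pref)
        dx[[length(dx) + 1L]] <- data.frame(
          patient_id = id, icd9 = code,
          date = as_of - sample(30:2000, k, replace = TRUE),
          stringsAsFactors = FALSE)
      }
    }
    n_comorbid_dx <- if (length(dx)) sum(vapply(dx, nrow, integer(1))) else 0L
    n_decoy <- round(n_comorbid_dx / 4)
    if (n_decoy > 0L)
      dx[[length(dx) + 1L]] <- data.frame(
        patient_id = id,
        icd9 = sample(.decoy_icd9, n_decoy, replace = TRUE),
        date = as_of - sample(30:2000, n_decoy, replace = TRUE),
        stringsAsFactors = FALSE)
    dx_rows[[i]] <- if (length(dx)) do.call(rbind, dx) else NULL

    # -- medication orders per scenario
    active_order <- function(drug) {
      start <- as_of - sample(30:365, 1L)
      open <- stats::runif(1) < 0.7
      data.frame(patient_id = id, drug = drug, dose = dose_for(drug),
                 start_date = start,
                 end_date = if (open) as.Date(NA) else as_of + sample(10:180, 1L),
                 status = "active", stringsAsFactors = FALSE)
    }
    past_order <- function(drug, years_back_max = 4.5) {
      end <- as_of - sample(30:floor(365 * years_back_max), 1L)
      data.frame(patient_id = id, drug = drug, dose = dose_for(drug),
                 start_date = end - sample(60:365, 1L), end_date = end,
                 status = sample(c("discontinued", "expired"), 1L),
                 stringsAsFactors = FALSE)
    }
    ancient_order <- function(drug) {  # ends outside the lookback window
      end <- add_years(as_of, -5L) - sample(30:700, 1L)
      data.frame(patient_id = id, drug = drug, dose = dose_for(drug),
                 start_date = end - sample(60:365, 1L), end_date = end,
                 status = "discontinued", stringsAsFactors = FALSE)
    }

    od <- list()
    if (stats::runif(1) < 0.5)   # unrelated, non-taxonomy medication
      od[[length(od) + 1L]] <- active_order(sample(.decoy_drugs, 1L))
    if (scenario == "first_line_only") {
      for (d in sample(line1, sample(1:2, 1L)))
        od[[length(od) + 1L]] <- active_order(d)
      if (stats::runif(1) < 0.3)
        od[[length(od) + 1L]] <- past_order(sample(line1, 1L))
      if (stats::runif(1) < 0.2)
        od[[length(od) + 1L]] <- ancient_order(sample(line1, 1L))
    } else if (scenario == "first_plus_second") {
      od[[length(od) + 1L]] <- active_order(sample(line1, 1L))
      od[[length(od) + 1L]] <- active_order(sample(line2, 1L))
    } else if (scenario == "third_line") {
      od[[length(od) + 1L]] <- active_order(sample(line3, 1L))
      if (stats::runif(1) < 0.5)
        od[[length(od) + 1L]] <- active_order(sample(line1, 1L))
    } else if (scenario == "past_only") {
      for (d in sample(taxonomy$drug, sample(1:2, 1L)))
        od[[length(od) + 1L]] <- past_order(d)
    }
    od_rows[[i]] <- if (length(od)) do.call(rbind, od) else NULL

    pat_rows[[i]] <- data.frame(patient_id = id,
                                name = sprintf("ZZTEST,PATIENT %05d", i),
                                age = age, sex = sex, scenario = scenario,
                                stringsAsFactors = FALSE)
  }

  empty_dx <- data.frame(patient_id = character(0), icd9 = character(0),
                         date = as.Date(character(0)), stringsAsFactors = FALSE)
  empty_od <- data.frame(patient_id = character(0), drug = character(0),
                         dose = character(0), start_date = as.Date(character(0)),
                         end_date = as.Date(character(0)), status = character(0),
                         stringsAsFactors = FALSE)
  empty_pat <- data.frame(patient_id = character(0), name = character(0),
                          age = integer(0), sex = character(0),
                          scenario = character(0), stringsAsFactors = FALSE)
  list(patients = if (spec$n) do.call(rbind, pat_rows) else empty_pat,
       diagnoses = if (any(!vapply(dx_rows, is.null, logical(1))))
         do.call(rbind, dx_rows[!vapply(dx_rows, is.null, logical(1))])
       else empty_dx,
       orders = if (any(!vapply(od_rows, is.null, logical(1))))
         do.call(rbind, od_rows[!vapply(od_rows, is.null, logical(1))])
       else empty_od)
}

#' Write a cohort to CSV files with a manifest
#'
#' Writes `patients.csv`, `diagnoses.csv`, `medication_orders.csv` and a
#' `manifest.yaml` recording the spec, its seed, and a content hash so a
#' run can be traced back to its generating spec.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @param spec The generating [cohort_spec()] (recorded in the
#'   manifest).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, spec = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$patients, file.path(dir, "patients.csv"),
                   row.names = FALSE)
  dx <- cohort$diagnoses; dx$date <- format(dx$date)
  utils::write.csv(dx, file.path(dir, "diagnoses.csv"), row.names = FALSE)
  od <- cohort$orders
  od$start_date <- format(od$start_date)
  od$end_date <- ifelse(is.na(od$end_date), "", format(od$end_date))
  utils::write.csv(od, file.path(dir, "medication_orders.csv"),
                   row.names = FALSE)
  manifest <- list(
    seed = if (!is.null(spec)) spec$seed else NA,
    n = nrow(cohort$patients),
    spec_hash = fnv1a(jsonlite::toJSON(unclass(spec), auto_unbox = TRUE,
                                       null = "null")),
    tables = list(patients = nrow(cohort$patients),
                  diagnoses = nrow(cohort$diagnoses),
                  medication_orders = nrow(cohort$orders)))
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Directory containing the three CSVs.
#' @return List of data frames `patients`, `diagnoses`, `orders`.
#' @export
read_cohort <- function(dir) {
  pats <- utils::read.csv(file.path(dir, "patients.csv"),
                          stringsAsFactors = FALSE,
                          colClasses = c(patient_id = "character"))
  dx <- utils::read.csv(file.path(dir, "diagnoses.csv"),
                        stringsAsFactors = FALSE,
                        colClasses = c(patient_id = "character",
                                       icd9 = "character"))
  dx$date <- as.Date(dx$date)
  od <- utils::read.csv(file.path(dir, "medication_orders.csv"),
                        stringsAsFactors = FALSE,
                        colClasses = c(patient_id = "character"))
  od$start_date <- as.Date(od$start_date)
  od$end_date <- as.Date(ifelse(od$end_date == "", NA, od$end_date))
  list(patients = pats, diagnoses = dx, orders = od)
}

# 32-bit FNV-1a over a string; cheap content fingerprint for manifests
fnv1a <- function(x) {
  bytes <- utf8ToInt(as.character(x))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b %% 256))
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# ---- Hand-authored demo patients -------------------------------------------

#' Single-patient demonstration fixtures
#'
#' Returns a hand-authored one-patient EHR fixture for documentation and
#' golden tests.  Available scenarios: `"tca_depression"` (on
#' amitriptyline with a depression ICD9 code — the worked example of
#' the conditional-comment machinery), `"naive"`, `"first_line_only"`,
#' `"first_plus_second"` (gabapentin plus oxycodone — triggers the
#' scope warning), `"third_line"` (citalopram), and `"past_only"`.
#'
#' @param name Scenario name.
#' @return List: `patients`, `diagnoses`, `orders`, `as_of`, `scenario`.
#'   Unknown names raise an error listing the available scenarios.
#' @export
demo_patient <- function(name) {
  as_of <- as.Date("2014-06-01")
  fixtures <- list(
    tca_depression = list(
      patients = data.frame(patient_id = "DEMO1", name = "ZZTEST,DEMO TCA",
                            age = 67L, sex = "M", scenario = "tca_depression",
                            stringsAsFactors = FALSE),
      diagnoses = data.frame(patient_id = "DEMO1",
                             icd9 = c("311", "401.9"),
                             date = as_of - c(200L, 400L),
                             stringsAsFactors = FALSE),
      orders = data.frame(patient_id = "DEMO1", drug = "Amitriptyline HCl",
                          dose = dose_for("amitriptyline"),
                          start_date = as_of - 90L, end_date = as.Date(NA),
                          status = "active", stringsAsFactors = FALSE)),
    naive = list(
      patients = data.frame(patient_id = "DEMO2", name = "ZZTEST,DEMO NAIVE",
                            age = 54L, sex = "F", scenario = "naive",
                            stringsAsFactors = FALSE),
      diagnoses = data.frame(patient_id = "DEMO2", icd9 = "724.2",
                             date = as_of - 300L, stringsAsFactors = FALSE),
      orders = data.frame(patient_id = character(0), drug = character(0),
                          dose = character(0),
                          start_date = as.Date(character(0)),
                          end_date = as.Date(character(0)),
                          status = character(0), stringsAsFactors = FALSE)),
    first_line_only = list(
      patients = data.frame(patient_id = "DEMO3", name = "ZZTEST,DEMO FIRSTLINE",
                            age = 61L, sex = "M", scenario = "first_line_only",
                            stringsAsFactors = FALSE),
      diagnoses = data.frame(patient_id = "DEMO3", icd9 = "250.02",
                             date = as_of - 500L, stringsAsFactors = FALSE),
      orders = data.frame(patient_id = "DEMO3", drug = "Gabapentin",
                          dose = dose_for("gabapentin"),
                          start_date = as_of - 120L, end_date = as.Date(NA),
                          status = "active", stringsAsFactors = FALSE)),
    first_plus_second = list(
      patients = data.frame(patient_id = "DEMO4", name = "ZZTEST,DEMO SCOPE",
                            age = 58L, sex = "M", scenario = "first_plus_second",
                            stringsAsFactors = FALSE),
      diagnoses = data.frame(patient_id = "DEMO4", icd9 = "250.02",
                             date = as_of - 700L, stringsAsFactors = FALSE),
      orders = data.frame(patient_id = "DEMO4",
                          drug = c("Gabapentin", "Oxycodone"),
                          dose = dose_for(c("gabapentin", "oxycodone")),
                          start_date = as_of - c(120L, 45L),
                          end_date = as.Date(c(NA, NA)),
                          status = "active", stringsAsFactors = FALSE)),
    third_line = list(
      patients = data.frame(patient_id = "DEMO5", name = "ZZTEST,DEMO THIRDLINE",
                            age = 49L, sex = "F", scenario = "third_line",
                            stringsAsFactors = FALSE),
      diagnoses = data.frame(patient_id = "DEMO5", icd9 = "296.22",
                             date = as_of - 250L, stringsAsFactors = FALSE),
      orders = data.frame(patient_id = "DEMO5", drug = "Citalopram",
                          dose = dose_for("citalopram"),
                          start_date = as_of - 200L, end_date = as.Date(NA),
                          status = "active", stringsAsFactors = FALSE)),
    past_only = list(
      patients = data.frame(patient_id = "DEMO6", name = "ZZTEST,DEMO PAST",
                            age = 72L, sex = "M", scenario = "past_only",
                            stringsAsFactors = FALSE),
      diagnoses = data.frame(patient_id = "DEMO6", icd9 = "365.11",
                             date = as_of - 800L, stringsAsFactors = FALSE),
      orders = data.frame(patient_id = "DEMO6", drug = "Nortriptyline",
                          dose = dose_for("nortriptyline"),
                          start_date = as_of - 900L, end_date = as_of - 600L,
                          status = "discontinued", stringsAsFactors = FALSE)))
  if (!name %in% names(fixtures))
    stop("unknown demo scenario '", name, "'; available: ",
         paste(names(fixtures), collapse = ", "), call. = FALSE)
  c(fixtures[[name]], list(as_of = as_of, scenario = name))
}
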