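tax <- read_taxonomy()
cmap <- read_comorbidity_map()
AS_OF <- as.Date("2014-06-01")

mk_dx <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(patient_id = r[[1]], icd9 = r[[2]], date = as.Date(r[[3]]),
               stringsAsFactors = FALSE)))
}

mk_order <- function(id, drug, start, end = NA, status = "active",
                     dose = "dose") {
  data.frame(patient_id = id, drug = drug, dose = dose,
             start_date = as.Date(start), end_date = as.Date(end),
             status = status, stringsAsFactors = FALSE)
}

empty_orders <- mk_order("x", "none", "2000-01-01")[0, ]

test_that("ICD9 prefix matching respects dot boundaries", {
  expect_true(icd9_matches("311", "311"))
  expect_true(icd9_matches("311.0", "311"))
  expect_false(icd9_matches("3110", "311"))
  expect_true(icd9_matches("296.22", "296.2"))
  expect_false(icd9_matches("296.32", "296.2"))
  expect_true(all(icd9_matches(c("250.02", "250"), "250")))
  expect_false(icd9_matches("2500", "250"))
})

test_that("comorbidity flags are set from matching diagnosis codes", {
  dx <- mk_dx(list("p1", "414.01", "2013-01-01"),  # heart disease
              list("p2", "724.2", "2013-01-01"))   # decoy: no comorbidity
  st <- build_staging(dx, empty_orders, tax, cmap, AS_OF)
  r1 <- staging_record(st, "p1", now = AS_OF)
  expect_true(r1$flags[["heart_disease"]])
  expect_false(any(r1$flags[names(r1$flags) != "heart_disease"]))
  r2 <- staging_record(st, "p2", now = AS_OF)
  expect_false(any(r2$flags))

  # packed bitset keys bit i to comorbidity i in map order
  expect_identical(r1$bits, as.integer(2^(match("heart_disease", names(cmap)) - 1L)))
  expect_identical(r2$bits, 0L)
})

test_that("patients appear in staging iff they have any record", {
  dx <- mk_dx(list("p1", "311", "2013-01-01"))
  od <- mk_order("p2", "gabapentin", "2014-01-01")
  st <- build_staging(dx, od, tax, cmap, AS_OF)
  expect_setequal(st$flags$patient_id, c("p1", "p2"))
  # absent patient: empty record, all-false flags
  r <- staging_record(st, "p99", now = AS_OF)
  expect_false(any(r$flags))
  expect_identical(nrow(r$past_meds), 0L)
})

test_that("the five-year lookback is a closed interval on the order span", {
  boundary <- add_years(AS_OF, -5L)
  mk_st <- function(end) {
    od <- mk_order("p1", "gabapentin", as.Date(end) - 100, end,
                   status = "discontinued")
    build_staging(mk_dx(list("p1", "724.2", "2009-01-01")), od, tax, cmap, AS_OF)
  }
  # ends exactly 5 years before as_of: included
  inc <- staging_record(mk_st(boundary), "p1", now = AS_OF)
  expect_identical(inc$past_meds$drug, "gabapentin")
  # one day earlier: excluded
  exc <- staging_record(mk_st(boundary - 1L), "p1", now = AS_OF)
  expect_identical(nrow(exc$past_meds), 0L)
  # ended 4 years before: included; 6 years before: excluded
  expect_identical(nrow(staging_record(mk_st(add_years(AS_OF, -4L)), "p1",
                                       now = AS_OF)$past_meds), 1L)
  expect_identical(nrow(staging_record(mk_st(add_years(AS_OF, -6L)), "p1",
                                       now = AS_OF)$past_meds), 0L)
})

test_that("malformed records are rejected individually and counted", {
  dx <- mk_dx(list("p1", "311", "2013-01-01"),
              list("p1", "", "2013-01-01"),          # empty code
              list("p1", "414", "2099-01-01"))       # future date
  od <- rbind(mk_order("p1", "gabapentin", "2014-01-01"),
              mk_order("p1", "tramadol", "2014-03-01", "2014-01-01"))  # end < start
  expect_message(st <- build_staging(dx, od, tax, cmap, AS_OF), "rejected")
  expect_identical(unname(st$rejected), c(2L, 1L))
  r <- staging_record(st, "p1", now = AS_OF)
  expect_true(r$flags[["depression"]])
  expect_false(r$flags[["heart_disease"]])   # the matching row was rejected
  expect_identical(r$past_meds$drug, "gabapentin")
})

test_that("current medications require active status and a covering span", {
  od <- rbind(
    mk_order("p1", "Amitriptyline HCl", "2014-01-01"),                 # open, active
    mk_order("p1", "Gabapentin", "2014-01-01", "2014-07-01"),          # covers as_of
    mk_order("p1", "Pregabalin", "2014-01-01", "2014-05-01"),          # ended before
    mk_order("p1", "Duloxetine", "2014-07-01"),                        # starts after
    mk_order("p1", "Tramadol", "2014-01-01", status = "discontinued"), # not active
    mk_order("p1", "Lisinopril", "2014-01-01"))                        # not NP
  cur <- current_np_meds(od, tax, AS_OF)
  expect_setequal(cur$drug, c("amitriptyline", "gabapentin"))
  expect_identical(cur$class[cur$drug == "amitriptyline"], "TCA")
  expect_identical(cur$line[cur$drug == "gabapentin"], 1L)
  # an order ending exactly at as_of is still current
  od2 <- mk_order("p1", "gabapentin", "2014-01-01", AS_OF)
  expect_identical(current_np_meds(od2, tax, AS_OF)$drug, "gabapentin")
  # empty order table
  expect_identical(nrow(current_np_meds(empty_orders, tax, AS_OF)), 0L)
})

test_that("drug name normalisation is case-insensitive and strips salts", {
  expect_identical(normalize_drug("  Amitriptyline HCl "), "amitriptyline")
  expect_identical(normalize_drug("NORTRIPTYLINE hydrochloride"), "nortriptyline")
  expect_identical(normalize_drug("Valproic  Acid"), "valproic acid")
  expect_identical(normalize_drug("Venlafaxine ER"), "venlafaxine")
})

test_that("facts publish <drug>_tx and <comorbidity>_hx with extracted provenance", {
  dx <- mk_dx(list("p1", "311.0", "2013-06-01"))
  od <- mk_order("p1", "Amitriptyline", "2014-01-01")
  st <- build_staging(dx, od, tax, cmap, AS_OF)
  rec <- staging_record(st, "p1", now = AS_OF)
  cur <- current_np_meds(od, tax, AS_OF)
  cfg <- read_kb_config(system.file("extdata", "kb_config.yaml",
                                    package = "neurocds"))
  facts <- facts_from_ehr(rec, cur, cfg$inputs, age = 67, sex = "M")
  expect_true(facts$values[["amitriptyline_tx"]])
  expect_true(facts$values[["depression_hx"]])
  others <- setdiff(names(facts$values), c("amitriptyline_tx", "depression_hx"))
  expect_false(any(facts$values[others]))
  expect_true(all(facts$provenance == "extracted"))
  expect_setequal(names(facts$values), cfg$inputs)

  # nortriptyline only
  od2 <- mk_order("p1", "Nortriptyline", "2014-01-01")
  f2 <- facts_from_ehr(rec, current_np_meds(od2, tax, AS_OF), cfg$inputs)
  expect_true(f2$values[["nortriptyline_tx"]])
  expect_false(f2$values[["amitriptyline_tx"]])

  # empty record and meds: all false
  f3 <- facts_from_ehr(staging_record(st, "none", now = AS_OF),
                       current_np_meds(empty_orders, tax, AS_OF), cfg$inputs)
  expect_false(any(f3$values))

  # name collision with a derived variable is refused
  expect_error(facts_from_ehr(rec, cur, cfg$inputs,
                              derived_vars = "amitriptyline_tx"),
               "collide")
})

test_that("regimen classification flags treatment lines from current drugs", {
  od <- rbind(mk_order("p1", "Gabapentin", "2014-01-01"),
              mk_order("p1", "Oxycodone", "2014-02-01"))
  reg <- classify_regimen(current_np_meds(od, tax, AS_OF))
  expect_true(reg$first_line_present)
  expect_true(reg$second_line_present)
  expect_false(reg$third_line_present)
  expect_identical(reg$by_line$line2, "oxycodone")

  only1 <- classify_regimen(current_np_meds(
    mk_order("p1", "Gabapentin", "2014-01-01"), tax, AS_OF))
  expect_true(only1$first_line_present)
  expect_false(only1$second_line_present || only1$third_line_present)

  only3 <- classify_regimen(current_np_meds(
    mk_order("p1", "Citalopram", "2014-01-01"), tax, AS_OF))
  expect_true(only3$third_line_present)
  expect_false(only3$first_line_present || only3$second_line_present)
})

test_that("staging round-trips through the CSV bundle and is byte-deterministic", {
  set.seed(11)
  coh <- generate_cohort(cohort_spec(n = 30, seed = 11), cmap, tax)
  st <- build_staging(coh$diagnoses, coh$orders, tax, cmap, AS_OF)
  d1 <- file.path(tempdir(), "stage1"); d2 <- file.path(tempdir(), "stage2")
  write_staging(st, d1)
  write_staging(build_staging(coh$diagnoses, coh$orders, tax, cmap, AS_OF), d2)
  for (f in c("flags.csv", "past_meds.csv", "meta.yaml"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  rt <- read_staging(d1)
  expect_identical(rt$flags$patient_id, st$flags$patient_id)
  expect_identical(rt$past_meds$drug, st$past_meds$drug)
  expect_identical(rt$as_of, st$as_of)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("stale staging stores trigger a staleness warning", {
  st <- build_staging(mk_dx(list("p1", "311", "2013-01-01")), empty_orders,
                      tax, cmap, AS_OF)
  expect_warning(staging_record(st, "p1", now = AS_OF + 3L), "stale")
  expect_silent(staging_record(st, "p1", now = AS_OF))
})

test_that("staging-backed queries equal direct full-table scans", {
  # staging is a cache: every flag and med list must equal the same
  # query computed straight from the raw tables
  set.seed(21)
  coh <- generate_cohort(cohort_spec(n = 120, seed = 21), cmap, tax)
  st <- build_staging(coh$diagnoses, coh$orders, tax, cmap, AS_OF)
  lb <- add_years(AS_OF, -5L)
  for (pid in coh$patients$patient_id) {
    rec <- staging_record(st, pid, now = AS_OF)
    dx <- coh$diagnoses[coh$diagnoses$patient_id == pid, , drop = FALSE]
    od <- coh$orders[coh$orders$patient_id == pid, , drop = FALSE]
    for (cm in names(cmap))
      expect_identical(rec$flags[[cm]], any(icd9_matches(dx$icd9, cmap[[cm]])),
                       info = paste(pid, cm))
    norm <- normalize_drug(od$drug, attr(tax, "salts"))
    in_win <- norm %in% tax$drug & od$start_date <= AS_OF &
      (is.na(od$end_date) | od$end_date >= lb)
    expect_setequal(rec$past_meds$drug, unique(norm[in_win]))
  }
})
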