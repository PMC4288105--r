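# ---- Drug taxonomy and comorbidity map -------------------------------------

#' Neuropathic-pain drug taxonomy
#'
#' Loads the drug taxonomy mapping normalised drug names to a
#' pharmacologic class and a treatment line: tier 1 (first line) are the
#' TCAs, SNRIs and gabapentinoids; tier 2 is opioids and tramadol; tier
#' 3 the other anticonvulsants/antidepressants sometimes used for
#' neuropathic pain (carbamazepine, lamotrigine, topiramate, valproic
#' acid, bupropion, citalopram, paroxetine).  The mapping ships as an
#' editable YAML file, so formulary changes are configuration, not code.
#'
#' @param path YAML file; defaults to the taxonomy bundled with the
#'   package.
#' @return Object of class `drug_taxonomy`: a data frame (`drug`,
#'   `class`, `line`) plus a `salts` attribute listing the suffixes
#'   stripped during name normalisation.
#' @export
read_taxonomy <- function(path = system.file("extdata", "taxonomy.yaml",
                                             package = "neurocds")) {
  cfg <- yaml::read_yaml(path)
  rows <- lapply(names(cfg$drugs), function(d) {
    e <- cfg$drugs[[d]]
    data.frame(drug = d, class = e$class, line = as.integer(e$line),
               stringsAsFactors = FALSE)
  })
  tx <- do.call(rbind, rows)
  valid_class <- c("TCA", "SNRI", "gabapentinoid", "opioid", "tramadol",
                   "third_line_other")
  if (!all(tx$class %in% valid_class))
    stop("unknown drug class in taxonomy: ",
         paste(setdiff(tx$class, valid_class), collapse = ", "), call. = FALSE)
  if (!all(tx$line %in% 1:3))
    stop("treatment line must be 1, 2 or 3", call. = FALSE)
  structure(tx, class = c("drug_taxonomy", "data.frame"),
            salts = as.character(unlist(cfg$salts)))
}

#' Normalise a drug name
#'
#' Lowercases, trims, collapses internal whitespace, and strips trailing
#' salt/formulation suffixes (e.g. "Amitriptyline HCl" ->
#' "amitriptyline") so order rows match taxonomy keys
#' case-insensitively.
#'
#' @param x Character vector of drug names as written in orders.
#' @param salts Suffix tokens to strip; defaults to the taxonomy's list.
#' @return Character vector of normalised names.
#' @export
normalize_drug <- function(x, salts = c("hydrochloride", "hcl", "sodium",
                                        "tartrate", "sulfate", "er", "xr",
                                        "sr", "cr")) {
  x <- tolower(trimws(x))
  x <- gsub("[[:space:]]+", " ", x)
  if (length(salts)) {
    pat <- paste0(" (", paste(salts, collapse = "|"), ")$")
    repeat {
      y <- sub(pat, "", x)
      if (identical(y, x)) break
      x <- y
    }
  }
  x
}

#' Comorbidity-to-ICD9 mapping
#'
#' Loads the mapping from comorbidity names (depression, heart disease,
#' ...) to sets of ICD9 code prefixes.  The shipped mapping is a
#' clinically plausible editable config; its order fixes the bit
#' position of each comorbidity in staging records.  Prefixes must not
#' overlap across comorbidities.
#'
#' @param path YAML file; defaults to the mapping bundled with the
#'   package.
#' @return Named list of character prefix vectors, class
#'   `comorbidity_map`.
#' @export
read_comorbidity_map <- function(path = system.file("extdata", "comorbidities.yaml",
                                                    package = "neurocds")) {
  cfg <- yaml::read_yaml(path)
  cmap <- lapply(cfg, function(p) as.character(unlist(p)))
  all_pref <- unlist(cmap, use.names = FALSE)
  for (i in seq_along(all_pref)) {
    for (j in seq_along(all_pref)) {
      if (i != j && startsWith(all_pref[j], all_pref[i]) &&
          !same_comorbidity(cmap, all_pref[i], all_pref[j]))
        stop("overlapping ICD9 prefixes across comorbidities: '",
             all_pref[i], "' and '", all_pref[j], "'", call. = FALSE)
    }
  }
  structure(cmap, class = "comorbidity_map")
}

same_comorbidity <- function(cmap, a, b) {
  any(vapply(cmap, function(p) a %in% p && b %in% p, logical(1)))
}

#' Match ICD9 codes against a prefix set
#'
#' A dotted code matches a prefix when it equals the prefix or extends
#' it at a dot boundary: prefix `"311"` matches `"311"` and `"311.0"`
#' but not `"3110"`; prefix `"296.2"` matches `"296.2"` and `"296.22"`.
#'
#' @param codes Character vector of dotted ICD9 codes.
#' @param prefixes Character vector of prefixes.
#' @return Logical vector parallel to `codes`.
#' @export
icd9_matches <- function(codes, prefixes) {
  hit <- rep(FALSE, length(codes))
  for (p in prefixes) {
    if (grepl(".", p, fixed = TRUE)) {
      hit <- hit | codes == p | startsWith(codes, p)
    } else {
      hit <- hit | codes == p | startsWith(codes, paste0(p, "."))
    }
  }
  hit
}

# calendar-aware year shift; clamps Feb 29 to Feb 28
add_years <- function(date, k) {
  lt <- as.POSIXlt(date)
  lt$year <- lt$year + k
  out <- as.Date(lt)
  bad <- is.na(out)
  if (any(bad)) {
    lt2 <- as.POSIXlt(date[bad])
    lt2$year <- lt2$year + k
    lt2$mday <- 28L
    out[bad] <- as.Date(lt2)
  }
  out
}

# ---- Staging build ---------------------------------------------------------

#' Build the condensed staging store
#'
#' Condenses full diagnosis and medication-order tables into a small,
#' query-fast store — the batch nightly-extract design: one record per
#' patient appearing in either table, carrying (1) a fixed-width bitset
#' of comorbidity flags, one bit per comorbidity in map order, set iff
#' some diagnosis code matches one of that comorbidity's ICD9 prefixes,
#' and (2) the patient's neuropathic-pain medication history over the
#' five-year lookback window.  An order contributes to the history when
#' its active span overlaps the closed interval
#' `[as_of - 5 years, as_of]`; an order ending exactly five years before
#' `as_of` is therefore included.
#'
#' Records with unparseable dates, diagnosis dates after `as_of`, empty
#' codes, or negative order intervals are rejected at the record level:
#' the build continues, rejects are logged via `message()`, and totals
#' are kept on the store.
#'
#' @param diagnoses Data frame: `patient_id`, `icd9`, `date`.
#' @param orders Data frame: `patient_id`, `drug`, `dose`, `start_date`,
#'   `end_date` (NA = open), `status`
#'   (`active`/`discontinued`/`expired`).
#' @param taxonomy A [read_taxonomy()] object.
#' @param comorbidity_map A [read_comorbidity_map()] object.
#' @param as_of The extraction date (`Date` or parseable string).
#' @param build_date Date stamped on the store; defaults to `as_of` so
#'   rebuilds from identical inputs are byte-identical.
#' @return Object of class `staging_store`: `flags` (data frame,
#'   `patient_id` + one logical column per comorbidity + packed integer
#'   `bits`), `past_meds` (`patient_id`, `drug`, `class`, `last_date`),
#'   `comorbidities`, `as_of`, `build_date`, `rejected` counts.
#' @seealso [staging_record()], [write_staging()]
#' @export
build_staging <- function(diagnoses, orders, taxonomy, comorbidity_map,
                          as_of, build_date = as_of) {
  as_of <- as.Date(as_of)
  build_date <- as.Date(build_date)
  cn <- names(comorbidity_map)

  # -- record-level validation
  dx <- diagnoses
  dx$date <- as.Date(dx$date)
  bad_dx <- is.na(dx$date) | is.na(dx$icd9) | !nzchar(dx$icd9) | dx$date > as_of
  if (any(bad_dx))
    message(sum(bad_dx), " diagnosis record(s) rejected (bad date/code)")
  dx <- dx[!bad_dx, , drop = FALSE]

  od <- orders
  od$start_date <- as.Date(od$start_date)
  od$end_date <- as.Date(od$end_date)
  bad_od <- is.na(od$start_date) |
    (!is.na(od$end_date) & od$end_date < od$start_date)
  if (any(bad_od))
    message(sum(bad_od), " medication order(s) rejected (bad/negative interval)")
  od <- od[!bad_od, , drop = FALSE]

  ids <- sort(unique(c(dx$patient_id, od$patient_id)))

  # -- comorbidity bitflags
  flags <- data.frame(patient_id = ids, stringsAsFactors = FALSE)
  for (cm in cn) {
    hit_ids <- unique(dx$patient_id[icd9_matches(dx$icd9, comorbidity_map[[cm]])])
    flags[[cm]] <- flags$patient_id %in% hit_ids
  }
  flags$bits <- comorbidity_bits(flags, cn)

  # -- past NP meds in the 5-year lookback
  lb_start <- add_years(as_of, -5L)
  od$norm <- normalize_drug(od$drug, attr(taxonomy, "salts"))
  np <- od[od$norm %in% taxonomy$drug, , drop = FALSE]
  in_window <- np$start_date <= as_of &
    (is.na(np$end_date) | np$end_date >= lb_start)
  np <- np[in_window, , drop = FALSE]
  if (nrow(np)) {
    np$last_date <- pmin(ifelse(is.na(np$end_date), as_of, np$end_date),
                         as.numeric(as_of))
    np$last_date <- as.Date(np$last_date, origin = "1970-01-01")
    agg <- stats::aggregate(last_date ~ patient_id + norm, data = np, FUN = max)
    names(agg)[names(agg) == "norm"] <- "drug"
    agg$class <- taxonomy$class[match(agg$drug, taxonomy$drug)]
    past <- agg[order(agg$patient_id, agg$drug),
                c("patient_id", "drug", "class", "last_date")]
    rownames(past) <- NULL
  } else {
    past <- data.frame(patient_id = character(0), drug = character(0),
                       class = character(0), last_date = as.Date(character(0)),
                       stringsAsFactors = FALSE)
  }

  structure(list(flags = flags, past_meds = past, comorbidities = cn,
                 as_of = as_of, build_date = build_date,
                 rejected = c(diagnoses = sum(bad_dx), orders = sum(bad_od))),
            class = "staging_store")
}

#' Pack comorbidity flag columns into an integer bitset
#'
#' Bit `i` (least significant first) corresponds to comorbidity `i` in
#' map order.
#'
#' @param flags Data frame with one logical column per comorbidity.
#' @param comorbidities Comorbidity names in map order.
#' @return Integer vector of packed flags.
#' @export
comorbidity_bits <- function(flags, comorbidities) {
  bits <- integer(nrow(flags))
  for (k in seq_along(comorbidities))
    bits <- bits + as.integer(flags[[comorbidities[k]]]) * 2L^(k - 1L)
  as.integer(bits)
}

#' @export
print.staging_store <- function(x, ...) {
  cat(sprintf("<staging_store: %d patient(s), %d comorbidity flag(s), %d past-med row(s); as of %s>\n",
              nrow(x$flags), length(x$comorbidities), nrow(x$past_meds),
              format(x$as_of)))
  invisible(x)
}

#' Fetch one patient's staging record
#'
#' @param store A [build_staging()] store.
#' @param patient_id Patient identifier.
#' @param now Date used for the staleness check.
#' @param max_age_hours Warn when the store's build date is older than
#'   this (default 36 h — staging is meant to be rebuilt nightly).
#' @return List: `patient_id`, named logical `flags`, `bits`,
#'   `past_meds` data frame.  A patient absent from staging yields
#'   all-false flags and an empty history.
#' @export
staging_record <- function(store, patient_id, now = Sys.Date(),
                           max_age_hours = 36) {
  stopifnot(inherits(store, "staging_store"))
  age_h <- as.numeric(difftime(as.Date(now), store$build_date, units = "hours"))
  if (age_h > max_age_hours)
    warning(sprintf("staging store is stale: built %s (%.0f h ago)",
                    format(store$build_date), age_h), call. = FALSE)
  i <- match(patient_id, store$flags$patient_id)
  if (is.na(i)) {
    fl <- stats::setNames(rep(FALSE, length(store$comorbidities)),
                          store$comorbidities)
    pm <- store$past_meds[0, , drop = FALSE]
    bits <- 0L
  } else {
    fl <- vapply(store$comorbidities, function(cm) store$flags[[cm]][i],
                 logical(1))
    pm <- store$past_meds[store$past_meds$patient_id == patient_id, ,
                          drop = FALSE]
    rownames(pm) <- NULL
    bits <- store$flags$bits[i]
  }
  list(patient_id = patient_id, flags = fl, bits = bits, past_meds = pm)
}

#' Write / read a staging store as a plain-text bundle
#'
#' The store is written as `flags.csv`, `past_meds.csv` and `meta.yaml`
#' in a directory; rows are written in sorted order so identical inputs
#' produce byte-identical bundles.
#'
#' @param store A `staging_store`.
#' @param dir Directory (created if needed).
#' @return `write_staging()` returns `dir` invisibly; `read_staging()`
#'   returns the reconstructed `staging_store`.
#' @export
write_staging <- function(store, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(store$flags, file.path(dir, "flags.csv"), row.names = FALSE)
  pm <- store$past_meds
  pm$last_date <- format(pm$last_date)
  utils::write.csv(pm, file.path(dir, "past_meds.csv"), row.names = FALSE)
  meta <- list(comorbidities = as.list(store$comorbidities),
               as_of = format(store$as_of),
               build_date = format(store$build_date),
               rejected = as.list(store$rejected))
  yaml::write_yaml(meta, file.path(dir, "meta.yaml"))
  invisible(dir)
}

#' @rdname write_staging
#' @export
read_staging <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "meta.yaml"))
  flags <- utils::read.csv(file.path(dir, "flags.csv"),
                           stringsAsFactors = FALSE)
  pm <- utils::read.csv(file.path(dir, "past_meds.csv"),
                        stringsAsFactors = FALSE,
                        colClasses = c(patient_id = "character"))
  pm$last_date <- as.Date(pm$last_date)
  flags$patient_id <- as.character(flags$patient_id)
  structure(list(flags = flags, past_meds = pm,
                 comorbidities = as.character(unlist(meta$comorbidities)),
                 as_of = as.Date(meta$as_of),
                 build_date = as.Date(meta$build_date),
                 rejected = unlist(meta$rejected)),
            class = "staging_store")
}

# ---- Live queries ----------------------------------------------------------

#' Current neuropathic-pain medications
#'
#' Extracts the orders active at `as_of` — status `active`, started on
#' or before `as_of`, and either open-ended or ending on/after `as_of`
#' (a discontinued order is never current even if its span covers
#' `as_of`) — and intersects them with the taxonomy.  Drug-name matching
#' is case-insensitive after normalisation; non-taxonomy drugs are
#' silently ignored.
#'
#' @inheritParams build_staging
#' @return Data frame: `drug` (normalised), `class`, `line`, `dose`.
#' @export
current_np_meds <- function(orders, taxonomy, as_of) {
  as_of <- as.Date(as_of)
  od <- orders
  od$start_date <- as.Date(od$start_date)
  od$end_date <- as.Date(od$end_date)
  cur <- od$status == "active" & od$start_date <= as_of &
    (is.na(od$end_date) | od$end_date >= as_of)
  cur[is.na(cur)] <- FALSE
  od <- od[cur, , drop = FALSE]
  od$norm <- normalize_drug(od$drug, attr(taxonomy, "salts"))
  od <- od[od$norm %in% taxonomy$drug, , drop = FALSE]
  od <- od[!duplicated(od$norm), , drop = FALSE]
  out <- data.frame(drug = od$norm,
                    class = taxonomy$class[match(od$norm, taxonomy$drug)],
                    line = taxonomy$line[match(od$norm, taxonomy$drug)],
                    dose = if (nrow(od)) as.character(od$dose) else character(0),
                    stringsAsFactors = FALSE)
  out <- out[order(out$line, out$drug), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Publish engine input facts from the EHR layers
#'
#' Turns one patient's staging record and current-medication list into
#' the boolean fact set the rules engine consumes: `<drug>_tx` is true
#' for each current neuropathic-pain drug, `<comorbidity>_hx` is true
#' for each set staging flag, and every other declared input is false.
#' All published facts carry provenance `"extracted"`.  Drug names are
#' made identifier-safe (spaces to underscores: `valproic_acid_tx`).
#'
#' @param record A [staging_record()].
#' @param current_meds A [current_np_meds()] data frame.
#' @param declared_inputs The knowledge base's declared input variables.
#' @param derived_vars Derived (rule-target) variable names; publishing
#'   a fact whose name collides with one is refused, keeping the DSL
#'   namespace sound.
#' @param age,sex Demographics carried into the fact set.
#' @return A [fact_set()].
#' @export
facts_from_ehr <- function(record, current_meds, declared_inputs,
                           derived_vars = character(),
                           age = NA_real_, sex = NA_character_) {
  drug_facts <- if (nrow(current_meds)) paste0(fact_name(current_meds$drug), "_tx")
                else character(0)
  hx_on <- names(record$flags)[record$flags]
  hx_facts <- if (length(hx_on)) paste0(hx_on, "_hx") else character(0)
  truthy <- c(drug_facts, hx_facts)
  clash <- intersect(truthy, derived_vars)
  if (length(clash))
    stop("extracted fact(s) collide with derived knowledge-base variable(s): ",
         paste(sQuote(clash), collapse = ", "), call. = FALSE)
  all_names <- union(declared_inputs, truthy)
  vals <- stats::setNames(all_names %in% truthy, all_names)
  fact_set(vals, "extracted", age = age, sex = sex)
}

fact_name <- function(x) gsub("[^A-Za-z0-9_]", "_", x)

#' Classify the patient's treatment regimen by line
#'
#' Summarises which treatment lines are represented among the current
#' medications.  A patient on a second- or third-line drug is outside a
#' first-line-only advisory's scope, which drives the scope-warning
#' text in the report.
#'
#' @param current_meds A [current_np_meds()] data frame.
#' @param past_meds Optional past-medication data frame (carried through
#'   for reporting).
#' @return Object of class `regimen_summary`: logical
#'   `first_line_present`, `second_line_present`, `third_line_present`;
#'   `by_line`, a list of current-drug vectors per line; `current`,
#'   `past` the input tables.
#' @export
classify_regimen <- function(current_meds, past_meds = NULL) {
  by_line <- lapply(1:3, function(l) current_meds$drug[current_meds$line == l])
  names(by_line) <- c("line1", "line2", "line3")
  structure(list(first_line_present = length(by_line$line1) > 0L,
                 second_line_present = length(by_line$line2) > 0L,
                 third_line_present = length(by_line$line3) > 0L,
                 by_line = by_line,
                 current = current_meds,
                 past = past_meds),
            class = "regimen_summary")
}

#' @export
print.regimen_summary <- function(x, ...) {
  cat(sprintf("<regimen_summary: line1=%s line2=%s line3=%s>\n",
              x$first_line_present, x$second_line_present, x$third_line_present))
  invisible(x)
}
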