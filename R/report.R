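# ---- Fixed texts and layout ------------------------------------------------

#' Scope-warning text for patients on advanced regimens
#'
#' The explanatory text shown when a patient is currently receiving a
#' second- or third-line neuropathic-pain drug, clarifying that the
#' advisory covers first-line pharmacologic management only and that
#' such drugs may be prescribed for reasons other than neuropathic
#' pain.
#'
#' @return A single string.
#' @export
np_scope_warning_text <- function() {
  paste0(
    "This system is designed ONLY for first-line pharmacologic management ",
    "of neuropathic pain (NP). Some patients receive second- or third-line ",
    "NP drugs for other reasons (not for NP), in which case the comments ",
    "below may still be relevant. If this patient is receiving a ",
    "second-line drug (eg, an opioid or tramadol) or a third-line drug ",
    "(eg, carbamazepine, lamotrigine, topiramate, valproic acid, ",
    "bupropion, citalopram, or paroxetine) for NP, and you have concerns ",
    "about NP management, please consider referral to neurology.")
}

#' Report layout: how locations map to report sections
#'
#' The layout names the location that feeds the Comments/Recommendations
#' section and, for each remaining location, the outline category (drug
#' class or auxiliary box) whose expandable panel it fills.  Loaded from
#' YAML so the knowledge base and the screen layout can evolve together.
#'
#' @param path YAML file; defaults to the layout bundled with the
#'   package.
#' @return List with `recommendations` (a location id) and `outline`
#'   (named list: category label -> location id).
#' @export
read_layout <- function(path = system.file("extdata", "layout.yaml",
                                           package = "neurocds")) {
  cfg <- yaml::read_yaml(path)
  list(recommendations = cfg$recommendations,
       outline = lapply(cfg$outline, as.character))
}

#' Link registry for the report footer
#'
#' @param path YAML file of `label: target` pairs; defaults to the
#'   registry bundled with the package.  Targets are symbolic keys — the
#'   static pages themselves are deployment assets, not package code.
#' @return Data frame with columns `label`, `target`.
#' @export
read_links <- function(path = system.file("extdata", "links.yaml",
                                          package = "neurocds")) {
  cfg <- yaml::read_yaml(path)
  data.frame(label = names(cfg), target = as.character(unlist(cfg)),
             stringsAsFactors = FALSE, row.names = NULL)
}

# ---- Assembly --------------------------------------------------------------

#' Assemble the sectioned patient report
#'
#' Builds the single-screen advisory: header with demographics and
#' comorbidity checkboxes (distinguishing chart-extracted values from
#' clinician overrides), current and past neuropathic-pain medications,
#' the ordered Comments/Recommendations, the per-category outline
#' panels, the scope warning (present iff the current regimen includes
#' a second- or third-line drug), and reference links.  Pure function
#' of its inputs.
#'
#' @param demographics List or one-row data frame with `name`, `age`,
#'   `sex`.
#' @param facts The evaluated [fact_set()] (from the evaluation result).
#' @param regimen A [classify_regimen()] summary.
#' @param result The [evaluate()] result the facts came from.
#' @param links A [read_links()] data frame.
#' @param layout A [read_layout()] layout.  Placements to a location
#'   absent from the layout are refused by name, catching drift between
#'   knowledge base and screen.
#' @return Object of class `np_report`.
#' @export
assemble_report <- function(demographics, facts, regimen, result,
                            links = read_links(), layout = read_layout()) {
  known_locs <- c(layout$recommendations,
                  unlist(layout$outline, use.names = FALSE))
  placed_locs <- names(result$placements)[vapply(result$placements, nrow,
                                                 integer(1)) > 0L]
  orphan <- setdiff(placed_locs, known_locs)
  if (length(orphan))
    stop("placement(s) to location(s) absent from the report layout: ",
         paste(sQuote(orphan), collapse = ", "), call. = FALSE)

  hx <- grep("_hx$", names(facts$values), value = TRUE)
  checkboxes <- data.frame(
    comorbidity = sub("_hx$", "", hx),
    checked = unname(facts$values[hx]),
    provenance = unname(facts$provenance[hx]),
    stringsAsFactors = FALSE)

  cur <- regimen$current
  cur$note_key <- if (nrow(cur)) paste0(cur$class, "_side_effects")
                  else character(0)
  past <- regimen$past
  if (!is.null(past) && nrow(past)) {
    past <- past[!(past$drug %in% cur$drug), , drop = FALSE]
    past <- past[order(past$drug), c("drug", "class", "last_date")]
    rownames(past) <- NULL
  } else {
    past <- data.frame(drug = character(0), class = character(0),
                       last_date = as.Date(character(0)),
                       stringsAsFactors = FALSE)
  }

  get_loc <- function(loc) {
    p <- result$placements[[loc]]
    if (is.null(p)) empty_placements(loc)[[1]] else p
  }
  outline <- lapply(layout$outline, get_loc)

  structure(list(
    header = list(name = demographics$name, age = demographics$age,
                  sex = demographics$sex, checkboxes = checkboxes),
    current_meds = cur,
    past_meds = past,
    recommendations = get_loc(layout$recommendations),
    outline = outline,
    scope_warning = if (regimen$second_line_present ||
                        regimen$third_line_present) np_scope_warning_text()
                    else NULL,
    links = links), class = "np_report")
}

#' @export
print.np_report <- function(x, ...) {
  cat(render_report(x, "text"))
  invisible(x)
}

# ---- Rendering -------------------------------------------------------------

#' Render a report
#'
#' Renders the assembled report in one of three formats that carry
#' identical texts in identical order: `"json"` (machine-readable),
#' `"html"` (single static page; each outline category is one
#' expandable `<details>` element standing in for a hover box), or
#' `"text"` (plain text for a terminal).  Output contains no
#' timestamps, so rendering the same report twice is byte-identical.
#'
#' @param report An [assemble_report()] object.
#' @param format One of `"json"`, `"html"`, `"text"`.
#' @return A single string (the document).
#' @export
render_report <- function(report, format = c("json", "html", "text")) {
  if (!format[1] %in% c("json", "html", "text"))
    stop("unknown format '", format[1], "'; supported: json, html, text",
         call. = FALSE)
  switch(format[1],
         json = render_json(report),
         html = render_html(report),
         text = render_text(report))
}

report_to_list <- function(r) {
  plc <- function(df) {
    if (!nrow(df)) return(list())
    lapply(seq_len(nrow(df)), function(i)
      list(comment = df$comment[i], order = df$order[i], text = df$text[i]))
  }
  list(
    header = list(name = r$header$name, age = r$header$age, sex = r$header$sex,
                  checkboxes = r$header$checkboxes),
    current_meds = r$current_meds,
    past_meds = transform(r$past_meds, last_date = format(last_date)),
    scope_warning = r$scope_warning,
    recommendations = plc(r$recommendations),
    outline = lapply(r$outline, plc),
    links = r$links)
}

render_json <- function(r) {
  paste0(jsonlite::toJSON(report_to_list(r), pretty = TRUE, auto_unbox = TRUE,
                          null = "null", dataframe = "rows", digits = NA),
         "\n")
}

render_text <- function(r) {
  out <- character(0)
  push <- function(...) out <<- c(out, paste0(...))
  rule <- function() push(strrep("-", 72))
  push(sprintf("Patient: %s   Age: %s   Sex: %s",
               r$header$name, r$header$age, r$header$sex))
  cb <- r$header$checkboxes
  if (nrow(cb)) {
    push("Comorbidities:")
    for (i in seq_len(nrow(cb)))
      push(sprintf("  [%s] %s (%s)", if (cb$checked[i]) "x" else " ",
                   cb$comorbidity[i], cb$provenance[i]))
  }
  rule()
  push("Current NP medications:")
  if (nrow(r$current_meds)) {
    for (i in seq_len(nrow(r$current_meds)))
      push(sprintf("  %s (%s, line %d) - %s", r$current_meds$drug[i],
                   r$current_meds$class[i], r$current_meds$line[i],
                   r$current_meds$dose[i]))
  } else push("  (none)")
  push("Past NP medications (5-year lookback):")
  if (nrow(r$past_meds)) {
    for (i in seq_len(nrow(r$past_meds)))
      push(sprintf("  %s (%s) - last %s", r$past_meds$drug[i],
                   r$past_meds$class[i], format(r$past_meds$last_date[i])))
  } else push("  (none)")
  if (!is.null(r$scope_warning)) {
    rule()
    push("SCOPE NOTE:")
    push(r$scope_warning)
  }
  rule()
  push("Comments/Recommendations:")
  if (nrow(r$recommendations)) {
    for (i in seq_len(nrow(r$recommendations)))
      push(sprintf("  %d. %s", i, r$recommendations$text[i]))
  } else push("  (none)")
  rule()
  push("Treatment outline:")
  for (cat in names(r$outline)) {
    push(sprintf("* %s", cat))
    p <- r$outline[[cat]]
    for (i in seq_len(nrow(p))) push(sprintf("    - %s", p$text[i]))
  }
  if (nrow(r$links)) {
    rule()
    push("Links:")
    for (i in seq_len(nrow(r$links)))
      push(sprintf("  %s -> %s", r$links$label[i], r$links$target[i]))
  }
  paste0(paste(out, collapse = "\n"), "\n")
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

render_html <- function(r) {
  out <- character(0)
  push <- function(...) out <<- c(out, paste0(...))
  push("<!DOCTYPE html>")
  push("<html><head><meta charset=\"utf-8\">")
  push("<title>Neuropathic pain advisory</title>")
  push("<style>body{font-family:sans-serif;max-width:60em;margin:1em auto}",
       "details{border:1px solid #999;margin:.3em 0;padding:.3em}",
       ".warn{border:2px solid #a00;padding:.5em}",
       ".prov-override{font-style:italic}</style></head><body>")
  push(sprintf("<h1>%s</h1>", html_escape(r$header$name)))
  push(sprintf("<p>Age: %s &mdash; Sex: %s</p>",
               html_escape(as.character(r$header$age)),
               html_escape(as.character(r$header$sex))))
  cb <- r$header$checkboxes
  if (nrow(cb)) {
    push("<h2>Comorbidities</h2><ul>")
    for (i in seq_len(nrow(cb)))
      push(sprintf("<li class=\"prov-%s\">[%s] %s (%s)</li>",
                   cb$provenance[i], if (cb$checked[i]) "x" else "&nbsp;",
                   html_escape(cb$comorbidity[i]), cb$provenance[i]))
    push("</ul>")
  }
  push("<h2>Current NP medications</h2>")
  if (nrow(r$current_meds)) {
    push("<ul>")
    for (i in seq_len(nrow(r$current_meds)))
      push(sprintf("<li>%s (%s, line %d) &mdash; %s</li>",
                   html_escape(r$current_meds$drug[i]),
                   html_escape(r$current_meds$class[i]),
                   r$current_meds$line[i],
                   html_escape(r$current_meds$dose[i])))
    push("</ul>")
  } else push("<p>(none)</p>")
  push("<h2>Past NP medications (5-year lookback)</h2>")
  if (nrow(r$past_meds)) {
    push("<ul>")
    for (i in seq_len(nrow(r$past_meds)))
      push(sprintf("<li>%s (%s) &mdash; last %s</li>",
                   html_escape(r$past_meds$drug[i]),
                   html_escape(r$past_meds$class[i]),
                   format(r$past_meds$last_date[i])))
    push("</ul>")
  } else push("<p>(none)</p>")
  if (!is.null(r$scope_warning))
    push(sprintf("<div class=\"warn\">%s</div>", html_escape(r$scope_warning)))
  push("<h2>Comments/Recommendations</h2>")
  if (nrow(r$recommendations)) {
    push("<ol>")
    for (i in seq_len(nrow(r$recommendations)))
      push(sprintf("<li>%s</li>", html_escape(r$recommendations$text[i])))
    push("</ol>")
  } else push("<p>(none)</p>")
  push("<h2>Treatment outline</h2>")
  for (cat in names(r$outline)) {
    push(sprintf("<details><summary>%s</summary>",
                 html_escape(gsub("_", " ", cat))))
    p <- r$outline[[cat]]
    if (nrow(p)) {
      push("<ul>")
      for (i in seq_len(nrow(p)))
        push(sprintf("<li>%s</li>", html_escape(p$text[i])))
      push("</ul>")
    } else push("<p>(no patient-specific comments)</p>")
    push("</details>")
  }
  if (nrow(r$links)) {
    push("<h2>Links</h2><ul>")
    for (i in seq_len(nrow(r$links)))
      push(sprintf("<li><a href=\"#%s\">%s</a></li>",
                   html_escape(r$links$target[i]),
                   html_escape(r$links$label[i])))
    push("</ul>")
  }
  push("</body></html>")
  paste0(paste(out, collapse = "\n"), "\n")
}

# ---- End-to-end pipeline ---------------------------------------------------

#' Run the full advisory pipeline for one patient
#'
#' Convenience wrapper tying the modules together: stages the EHR
#' tables, extracts the patient's facts, applies clinician overrides,
#' evaluates the compiled knowledge base, and assembles the report.
#'
#' @param kb A parsed [knowledge_base()] (with inputs and locations
#'   attached).
#' @param ehr List with `patients`, `diagnoses`, `orders` data frames
#'   (e.g. from [read_cohort()] or [demo_patient()]).
#' @param patient_id Which patient to report on.
#' @param as_of Extraction date.
#' @param overrides Named logical vector of checkbox overrides, e.g.
#'   `c(depression_hx = TRUE)`.
#' @param taxonomy,comorbidity_map,links,layout Configuration objects;
#'   package defaults when omitted.
#' @param staging Optional pre-built [build_staging()] store (rebuilt
#'   from `ehr` when `NULL`).
#' @return List: `report` ([assemble_report()]), `result`
#'   ([evaluate()]), `facts`, `regimen`.
#' @export
cds_run <- function(kb, ehr, patient_id, as_of, overrides = NULL,
                    taxonomy = read_taxonomy(),
                    comorbidity_map = read_comorbidity_map(),
                    links = read_links(), layout = read_layout(),
                    staging = NULL) {
  as_of <- as.Date(as_of)
  if (is.null(staging))
    staging <- build_staging(ehr$diagnoses, ehr$orders, taxonomy,
                             comorbidity_map, as_of)
  rec <- staging_record(staging, patient_id, now = as_of)
  pat_orders <- ehr$orders[ehr$orders$patient_id == patient_id, , drop = FALSE]
  cur <- current_np_meds(pat_orders, taxonomy, as_of)
  plan <- compile_kb(kb)
  facts <- facts_from_ehr(rec, cur, plan$inputs, plan$targets,
                          age = demo_field(ehr$patients, patient_id, "age"),
                          sex = demo_field(ehr$patients, patient_id, "sex"))
  result <- evaluate(plan, facts)
  if (!is.null(overrides)) {
    for (v in names(overrides))
      result <- override_fact(plan, result$facts, v, overrides[[v]])
  }
  regimen <- classify_regimen(cur, rec$past_meds)
  demo <- list(name = demo_field(ehr$patients, patient_id, "name"),
               age = demo_field(ehr$patients, patient_id, "age"),
               sex = demo_field(ehr$patients, patient_id, "sex"))
  report <- assemble_report(demo, result$facts, regimen, result,
                            links = links, layout = layout)
  list(report = report, result = result, facts = facts, regimen = regimen)
}

demo_field <- function(patients, id, field) {
  i <- match(id, patients$patient_id)
  if (is.na(i)) NA else patients[[field]][i]
}
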