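# ---- Fact sets -------------------------------------------------------------

#' Construct a patient fact set
#'
#' A fact set holds the boolean variables the engine evaluates against —
#' medication facts (`<drug>_tx`), comorbidity facts (`<comorbidity>_hx`)
#' — each with a provenance, plus basic demographics.  Provenance is
#' `"extracted"` for values the EHR condensation layer set,
#' `"override"` for values a clinician changed by hand, and `"derived"`
#' for rule targets computed by the engine.
#'
#' @param values Named logical vector of input facts.
#' @param provenance Either a single provenance applied to all values or
#'   a character vector parallel to `values`.
#' @param age Age in years (may be `NA`).
#' @param sex Coded sex, e.g. `"M"`/`"F"` (may be `NA`).
#' @return An object of class `fact_set`.
#' @export
fact_set <- function(values = logical(0), provenance = "extracted",
                     age = NA_real_, sex = NA_character_) {
  values <- stats::setNames(as.logical(values), names(values))
  if (length(values) && is.null(names(values)))
    stop("values must be named", call. = FALSE)
  if (anyNA(values)) stop("fact values must be TRUE or FALSE", call. = FALSE)
  if (length(provenance) == 1L) provenance <- rep(provenance, length(values))
  stopifnot(length(provenance) == length(values),
            all(provenance %in% c("extracted", "override", "derived")))
  structure(list(values = values,
                 provenance = stats::setNames(provenance, names(values)),
                 age = as.numeric(age), sex = as.character(sex)),
            class = "fact_set")
}

#' @export
print.fact_set <- function(x, ...) {
  cat(sprintf("<fact_set: %d fact(s); age=%s sex=%s>\n", length(x$values),
              format(x$age), x$sex))
  if (length(x$values)) {
    df <- data.frame(fact = names(x$values), value = unname(x$values),
                     provenance = unname(x$provenance))
    print(df, row.names = FALSE)
  }
  invisible(x)
}

#' @export
as.data.frame.fact_set <- function(x, ...) {
  data.frame(fact = names(x$values), value = unname(x$values),
             provenance = unname(x$provenance), stringsAsFactors = FALSE)
}

# ---- Evaluation ------------------------------------------------------------

#' Evaluate a compiled plan against a fact set
#'
#' Runs the rule steps once, in declaration order (assignments are
#' literals; a later rule may overwrite an earlier target — last write
#' wins), then checks every comment route against the post-rule
#' bindings.  Rule targets are initialised to `FALSE` before the pass,
#' so a rule whose condition is false leaves its target false, exactly
#' as default-initialised booleans behave in generated straight-line
#' code.  A declared input missing from `facts` defaults to `FALSE`
#' with a warning (absence of evidence in the chart reads as absent).
#'
#' @param plan An [compile_kb()] plan.
#' @param facts A [fact_set()] covering the declared inputs.
#' @return An object of class `evaluation_result`: `facts`, the final
#'   fact set (inputs plus derived values), and `placements`, a named
#'   list over every registered location, each a data frame of placed
#'   comments (`comment`, `order`, `text`) sorted ascending by `order`
#'   with ties broken by declaration order; a comment appears at most
#'   once per location.
#' @examples
#' kb <- parse_kb(
#'   "if (amitriptyline_tx || nortriptyline_tx) tca_tx = true;",
#'   inputs = c("amitriptyline_tx", "nortriptyline_tx"))
#' res <- evaluate(compile_kb(kb),
#'                 fact_set(c(amitriptyline_tx = TRUE, nortriptyline_tx = FALSE)))
#' res$facts$values[["tca_tx"]]
#' @export
evaluate <- function(plan, facts) {
  stopifnot(inherits(plan, "evaluation_plan"), inherits(facts, "fact_set"))
  env <- new.env(parent = baseenv())

  missing_inputs <- setdiff(plan$inputs, names(facts$values))
  if (length(missing_inputs))
    warning("input(s) ", paste(sQuote(missing_inputs), collapse = ", "),
            " have no binding; defaulting to FALSE", call. = FALSE)
  for (v in plan$inputs) assign(v, FALSE, envir = env)
  for (v in names(facts$values)) assign(v, facts$values[[v]], envir = env)
  for (v in plan$targets) assign(v, FALSE, envir = env)

  eval_cond <- function(cond) {
    tryCatch(eval(cond, env),
             error = function(e) {
               m <- regmatches(conditionMessage(e),
                               regexec("object '([^']+)' not found", conditionMessage(e)))[[1]]
               if (length(m) == 2L)
                 stop("evaluation error: variable '", m[2],
                      "' has no binding and no default", call. = FALSE)
               stop(e)
             })
  }

  for (s in plan$steps) {
    if (isTRUE(eval_cond(s$cond))) {
      for (v in names(s$assignments)) assign(v, s$assignments[[v]], envir = env)
    }
  }

  fired <- Filter(function(r) isTRUE(eval_cond(r$cond)), plan$routes)
  placements <- empty_placements(plan$locations)
  if (length(fired)) {
    df <- data.frame(
      comment = vapply(fired, `[[`, character(1), "comment"),
      location = vapply(fired, `[[`, character(1), "location"),
      order = vapply(fired, `[[`, integer(1), "order"),
      text = vapply(fired, `[[`, character(1), "text"),
      decl = vapply(fired, `[[`, integer(1), "decl"),
      stringsAsFactors = FALSE)
    for (loc in unique(df$location)) {
      sub <- df[df$location == loc, , drop = FALSE]
      sub <- sub[order(sub$order, sub$decl), , drop = FALSE]
      sub <- sub[!duplicated(sub$comment), , drop = FALSE]   # once per location
      rownames(sub) <- NULL
      placements[[loc]] <- sub[, c("comment", "order", "text")]
    }
  }

  out_names <- c(plan$inputs, plan$targets)
  vals <- vapply(out_names, function(v) get(v, envir = env), logical(1))
  prov <- c(ifelse(plan$inputs %in% names(facts$provenance),
                   facts$provenance[plan$inputs], "extracted"),
            rep("derived", length(plan$targets)))
  final <- fact_set(stats::setNames(vals, out_names), prov,
                    age = facts$age, sex = facts$sex)
  structure(list(facts = final, placements = placements),
            class = "evaluation_result")
}

empty_placements <- function(locations) {
  stats::setNames(
    rep(list(data.frame(comment = character(0), order = integer(0),
                        text = character(0), stringsAsFactors = FALSE)),
        length(locations)),
    locations)
}

#' @export
print.evaluation_result <- function(x, ...) {
  n_placed <- sum(vapply(x$placements, nrow, integer(1)))
  cat(sprintf("<evaluation_result: %d fact(s), %d placed comment(s) across %d location(s)>\n",
              length(x$facts$values), n_placed, length(x$placements)))
  invisible(x)
}

#' Re-evaluate with one fact overridden
#'
#' Models the clinician checking or unchecking a comorbidity checkbox:
#' the variable takes the new value with provenance `"override"` and the
#' whole plan is re-run (a full re-run is well under the interactive
#' latency budget at knowledge-base scale).  The original fact set is
#' not modified.
#'
#' @param plan An [compile_kb()] plan.
#' @param facts The current [fact_set()].
#' @param var A declared input variable.
#' @param value New logical value.
#' @return The fresh [evaluate()] result.
#' @export
override_fact <- function(plan, facts, var, value) {
  stopifnot(is.character(var), length(var) == 1L,
            is.logical(value), length(value) == 1L, !is.na(value))
  if (!(var %in% plan$inputs)) {
    if (var %in% plan$targets)
      stop("cannot override '", var, "': it is derived by rule ",
           plan$rule_owner[[var]], call. = FALSE)
    stop("cannot override '", var, "': not a declared input", call. = FALSE)
  }
  new_values <- facts$values
  new_prov <- facts$provenance
  new_values[[var]] <- value
  new_prov[[var]] <- "override"
  evaluate(plan, fact_set(new_values, new_prov, age = facts$age, sex = facts$sex))
}

# ---- Reference interpreter (test oracle) -----------------------------------

#' Reference evaluation by direct AST interpretation
#'
#' Interprets the knowledge base directly — no compilation step, a
#' recursive walk over each condition tree, and an independently coded
#' placement sort — so it can serve as an oracle for
#' `evaluate(compile_kb(kb), ...)`.  Intended for exhaustive
#' truth-table checks over all `2^n` input assignments (keep `n <= 16`).
#'
#' @param kb A [knowledge_base()].
#' @param inputs Named logical vector assigning every declared input.
#' @param declared_inputs,locations Overrides for `kb$inputs` /
#'   `kb$locations`.
#' @return An `evaluation_result`, comparable to [evaluate()]'s.
#' @export
truth_table_reference <- function(kb, inputs, declared_inputs = kb$inputs,
                                  locations = kb$locations) {
  if (length(declared_inputs) > 16L)
    stop("reference interpreter is limited to 16 inputs", call. = FALSE)
  binding <- as.list(stats::setNames(rep(FALSE, length(declared_inputs)),
                                     declared_inputs))
  for (v in names(inputs)) binding[[v]] <- inputs[[v]]
  for (v in kb_targets(kb)) binding[[v]] <- FALSE

  interp <- function(e) {
    if (inherits(e, "kb_var")) {
      if (is.null(binding[[e$name]]))
        stop("evaluation error: variable '", e$name,
             "' has no binding and no default", call. = FALSE)
      binding[[e$name]]
    } else if (inherits(e, "kb_not")) {
      !interp(e$operand)
    } else if (inherits(e, "kb_and")) {
      all(vapply(e$operands, interp, logical(1)))
    } else {
      any(vapply(e$operands, interp, logical(1)))
    }
  }

  for (r in kb$rules) {
    if (interp(r$condition))
      for (v in names(r$assignments)) binding[[v]] <- r$assignments[[v]]
  }

  placements <- empty_placements(locations)
  decl <- 0L
  placed <- list()
  for (cm in kb$comments) {
    for (r in cm$routes) {
      decl <- decl + 1L
      if (interp(r$condition))
        placed[[length(placed) + 1L]] <-
          list(comment = cm$name, location = r$location,
               order = r$order, text = cm$text, decl = decl)
    }
  }
  if (length(placed)) {
    # independent sort: decorate with a single sortable key
    key <- vapply(placed, function(p) p$order * 1e6 + p$decl, numeric(1))
    placed <- placed[sort.int(key, index.return = TRUE)$ix]
    for (p in placed) {
      cur <- placements[[p$location]]
      if (!(p$comment %in% cur$comment))
        placements[[p$location]] <- rbind(
          cur, data.frame(comment = p$comment, order = p$order, text = p$text,
                          stringsAsFactors = FALSE))
    }
    placements <- lapply(placements, function(d) { rownames(d) <- NULL; d })
  }

  out_names <- c(declared_inputs, kb_targets(kb))
  vals <- vapply(out_names, function(v) binding[[v]], logical(1))
  prov <- c(rep("extracted", length(declared_inputs)),
            rep("derived", length(kb_targets(kb))))
  structure(list(facts = fact_set(stats::setNames(vals, out_names), prov),
                 placements = placements),
            class = "evaluation_result")
}
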