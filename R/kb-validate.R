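# ---- Static validation -----------------------------------------------------

new_diagnostic <- function(severity, code, message, file = "<kb>",
                           line = NA_integer_, col = NA_integer_) {
  data.frame(file = file, line = line, col = col, severity = severity,
             code = code, message = message, stringsAsFactors = FALSE)
}

#' Validate a knowledge base before compilation
#'
#' Checks the static soundness conditions the engine relies on and
#' returns them as a diagnostics table rather than raising errors, so a
#' knowledge-base author sees every problem at once.  Checks:
#'
#' * `undefined_variable` (error) — a referenced variable is neither a
#'   declared input nor assigned by any rule;
#' * `input_assigned` (error) — a declared input is also a rule target;
#' * `use_before_assignment` (error) — a rule condition reads a derived
#'   variable that no earlier rule assigns (rules run once, in
#'   declaration order, so the read would see the default);
#' * `unknown_location` (error) — a route names a location absent from
#'   the registry;
#' * `unreachable_route` (warning) — a route condition references a
#'   variable nothing can set, so the route can never fire as intended;
#' * `duplicate_comment` (error) — two comments share a name (also caught
#'   at parse time; re-checked for programmatically built KBs).
#'
#' @param kb A [knowledge_base()].
#' @param declared_inputs Declared input variables; defaults to
#'   `kb$inputs`.
#' @param locations Location registry; defaults to `kb$locations`.
#' @return A data frame of diagnostics (columns `file`, `line`, `col`,
#'   `severity`, `code`, `message`); zero rows iff the KB is runnable.
#' @seealso [format_diagnostics()], [compile_kb()]
#' @export
validate_kb <- function(kb, declared_inputs = kb$inputs,
                        locations = kb$locations) {
  file <- attr(kb, "file") %||% "<kb>"
  srcpos <- attr(kb, "srcpos")
  item_pos <- function(idx) {
    if (!is.null(srcpos) && idx <= nrow(srcpos)) srcpos[idx, ] else c(NA_integer_, NA_integer_)
  }
  diags <- list()
  add <- function(severity, code, message, idx = NA_integer_) {
    p <- if (is.na(idx)) c(NA_integer_, NA_integer_) else item_pos(idx)
    diags[[length(diags) + 1L]] <<-
      new_diagnostic(severity, code, message, file, p[1], p[2])
  }

  targets <- kb_targets(kb)
  known <- union(declared_inputs, targets)

  # inputs may not be assigned
  for (v in intersect(declared_inputs, targets))
    add("error", "input_assigned",
        sprintf("declared input '%s' is assigned by a rule", v))

  # undefined variables, anywhere; report at the first referencing item
  item_refs <- lapply(kb$items, function(it) {
    if (inherits(it, "kb_rule")) expr_vars(it$condition)
    else unlist(lapply(it$routes, function(r) expr_vars(r$condition)),
                use.names = FALSE)
  })
  for (v in setdiff(kb_referenced(kb), known)) {
    first <- which(vapply(item_refs, function(r) v %in% r, logical(1)))[1]
    add("error", "undefined_variable",
        sprintf("variable '%s' is referenced but is neither a declared input nor assigned by any rule", v),
        idx = if (length(first)) first else NA_integer_)
  }

  # use-before-assignment in rule conditions (single forward pass)
  assigned_so_far <- character(0)
  rule_idx <- 0L
  for (k in seq_along(kb$items)) {
    it <- kb$items[[k]]
    if (!inherits(it, "kb_rule")) next
    rule_idx <- rule_idx + 1L
    for (v in expr_vars(it$condition)) {
      if (!(v %in% declared_inputs) && (v %in% targets) &&
          !(v %in% assigned_so_far))
        add("error", "use_before_assignment",
            sprintf("rule %d reads '%s' before any rule assigns it", rule_idx, v),
            idx = k)
    }
    assigned_so_far <- union(assigned_so_far, names(it$assignments))
  }

  # comment checks
  seen_names <- character(0)
  for (k in seq_along(kb$items)) {
    it <- kb$items[[k]]
    if (!inherits(it, "kb_comment")) next
    if (it$name %in% seen_names)
      add("error", "duplicate_comment",
          sprintf("duplicate comment name '%s'", it$name), idx = k)
    seen_names <- c(seen_names, it$name)
    for (j in seq_along(it$routes)) {
      r <- it$routes[[j]]
      if (!(r$location %in% locations))
        add("error", "unknown_location",
            sprintf("comment '%s' routes to unknown location '%s'",
                    it$name, r$location), idx = k)
      bad <- setdiff(expr_vars(r$condition), known)
      if (length(bad))
        add("warning", "unreachable_route",
            sprintf("comment '%s' route %d can never fire: variable(s) %s cannot be set",
                    it$name, j, paste(sQuote(bad), collapse = ", ")), idx = k)
    }
  }

  if (!length(diags))
    return(new_diagnostic(character(0), character(0), character(0),
                          character(0), integer(0), integer(0)))
  do.call(rbind, diags)
}

#' Format diagnostics as compiler-style lines
#'
#' @param diags Data frame returned by [validate_kb()].
#' @return Character vector, one `file:line:col: severity: message` line
#'   per diagnostic (`line`/`col` omitted when unknown).
#' @export
format_diagnostics <- function(diags) {
  if (!nrow(diags)) return(character(0))
  pos <- ifelse(is.na(diags$line), "",
                sprintf("%d:%d:", diags$line, ifelse(is.na(diags$col), 1L, diags$col)))
  sprintf("%s:%s %s: %s", diags$file, pos, diags$severity, diags$message)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- Compilation -----------------------------------------------------------

#' Compile a knowledge base to an evaluation plan
#'
#' Lowers every rule condition and comment-route condition to a host
#' (R) expression once, so that repeated per-patient evaluation pays no
#' tree-walking cost — the moral equivalent of the original design of
#' translating the knowledge base into compiled web-server code.  The
#' plan is immutable and deterministic: compiling the same knowledge
#' base twice yields byte-identical serialisations ([plan_serialize()]).
#'
#' Compilation refuses if [validate_kb()] reports any error-severity
#' diagnostic; the error carries the full diagnostics table.
#'
#' @param kb A [knowledge_base()].
#' @param declared_inputs,locations Overrides for `kb$inputs` /
#'   `kb$locations`.
#' @return An object of class `evaluation_plan` with rule steps in
#'   declaration order followed by comment-route checks.
#' @seealso [evaluate()], [truth_table_reference()]
#' @export
compile_kb <- function(kb, declared_inputs = kb$inputs,
                       locations = kb$locations) {
  diags <- validate_kb(kb, declared_inputs, locations)
  if (any(diags$severity == "error")) {
    msg <- paste(c("knowledge base has blocking diagnostics:",
                   format_diagnostics(diags[diags$severity == "error", ])),
                 collapse = "\n  ")
    cond <- structure(class = c("kb_compile_error", "error", "condition"),
                      list(message = msg, call = NULL, diagnostics = diags))
    stop(cond)
  }

  steps <- lapply(kb$rules, function(r) {
    list(cond = expr_to_lang(r$condition), assignments = r$assignments)
  })
  decl <- 0L
  routes <- list()
  for (cm in kb$comments) {
    for (r in cm$routes) {
      decl <- decl + 1L
      routes[[decl]] <- list(comment = cm$name, cond = expr_to_lang(r$condition),
                             location = r$location, order = r$order,
                             text = cm$text, decl = decl)
    }
  }

  structure(list(steps = steps, routes = routes,
                 inputs = declared_inputs,
                 targets = kb_targets(kb),
                 locations = locations,
                 rule_owner = rule_owner_table(kb)),
            class = "evaluation_plan")
}

# map derived variable -> index of first rule assigning it (for messages)
rule_owner_table <- function(kb) {
  own <- integer(0)
  for (k in seq_along(kb$rules)) {
    for (v in names(kb$rules[[k]]$assignments))
      if (!(v %in% names(own))) own[v] <- k
  }
  own
}

#' Serialise an evaluation plan deterministically
#'
#' @param plan An `evaluation_plan`.
#' @return A single string; identical knowledge bases compile to
#'   byte-identical serialisations.
#' @export
plan_serialize <- function(plan) {
  step_lines <- vapply(seq_along(plan$steps), function(k) {
    s <- plan$steps[[k]]
    sprintf("step %d: if %s then %s", k,
            paste(deparse(s$cond), collapse = " "),
            paste(sprintf("%s=%s", names(s$assignments),
                          tolower(as.character(s$assignments))), collapse = ","))
  }, character(1))
  route_lines <- vapply(plan$routes, function(r) {
    sprintf("route %d: %s -> %s@%d if %s", r$decl, r$comment, r$location,
            r$order, paste(deparse(r$cond), collapse = " "))
  }, character(1))
  paste(c(sprintf("inputs: %s", paste(plan$inputs, collapse = ",")),
          sprintf("locations: %s", paste(plan$locations, collapse = ",")),
          step_lines, route_lines), collapse = "\n")
}

#' @export
print.evaluation_plan <- function(x, ...) {
  cat(sprintf("<evaluation_plan: %d rule step(s), %d comment route(s)>\n",
              length(x$steps), length(x$routes)))
  invisible(x)
}
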