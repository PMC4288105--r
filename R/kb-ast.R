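# ---- Boolean expression AST ------------------------------------------------
#
# Expressions are plain lists tagged with S3 classes so that identical()
# gives structural equality.  And/Or are n-ary (>= 2 operands); the parser
# flattens chains at the same precedence level, so an And operand is never
# itself an And unless the source parenthesised it.

#' Boolean expression constructors
#'
#' Build the abstract syntax tree used by the knowledge-base language:
#' variable references, negation, and n-ary conjunction/disjunction.
#' These are exported so that knowledge bases can be constructed
#' programmatically as well as parsed from source.
#'
#' @param name Identifier (`[A-Za-z_][A-Za-z0-9_]*`), compared
#'   case-sensitively.
#' @param operand,... Sub-expressions.
#' @return An object of class `kb_expr`.
#' @examples
#' e <- kb_or(kb_var("amitriptyline_tx"), kb_var("nortriptyline_tx"))
#' expr_vars(e)
#' expr_deparse(e)
#' @name kb_expr
NULL

#' @rdname kb_expr
#' @export
kb_var <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!grepl("^[A-Za-z_][A-Za-z0-9_]*$", name))
    stop("invalid identifier: '", name, "'", call. = FALSE)
  structure(list(name = name), class = c("kb_var", "kb_expr"))
}

#' @rdname kb_expr
#' @export
kb_not <- function(operand) {
  stopifnot(inherits(operand, "kb_expr"))
  structure(list(operand = operand), class = c("kb_not", "kb_expr"))
}

#' @rdname kb_expr
#' @export
kb_and <- function(...) {
  ops <- list(...)
  if (length(ops) == 1L && is.list(ops[[1]]) && !inherits(ops[[1]], "kb_expr"))
    ops <- ops[[1]]
  if (length(ops) < 2L) stop("kb_and() needs at least two operands", call. = FALSE)
  stopifnot(all(vapply(ops, inherits, logical(1), "kb_expr")))
  structure(list(operands = ops), class = c("kb_and", "kb_expr"))
}

#' @rdname kb_expr
#' @export
kb_or <- function(...) {
  ops <- list(...)
  if (length(ops) == 1L && is.list(ops[[1]]) && !inherits(ops[[1]], "kb_expr"))
    ops <- ops[[1]]
  if (length(ops) < 2L) stop("kb_or() needs at least two operands", call. = FALSE)
  stopifnot(all(vapply(ops, inherits, logical(1), "kb_expr")))
  structure(list(operands = ops), class = c("kb_or", "kb_expr"))
}

#' Variables referenced by an expression
#'
#' @param expr A `kb_expr`.
#' @return Character vector of distinct identifiers, in first-use order.
#' @export
expr_vars <- function(expr) {
  out <- character(0)
  walk <- function(e) {
    if (inherits(e, "kb_var")) {
      out[[length(out) + 1L]] <<- e$name
    } else if (inherits(e, "kb_not")) {
      walk(e$operand)
    } else {
      for (op in e$operands) walk(op)
    }
  }
  walk(expr)
  unique(out)
}

# Precedence levels: or = 1, and = 2, not = 3, var = 4.
expr_prec <- function(e) {
  if (inherits(e, "kb_var")) 4L
  else if (inherits(e, "kb_not")) 3L
  else if (inherits(e, "kb_and")) 2L
  else 1L
}

#' Deparse an expression to knowledge-base source syntax
#'
#' Produces the canonical surface form (`||` for or, `&` for and, `!` for
#' not) with the minimal parentheses needed so that re-parsing the output
#' reconstructs the identical tree.
#'
#' @param expr A `kb_expr`.
#' @return A single string.
#' @export
expr_deparse <- function(expr) {
  wrap <- function(e, parent_prec) {
    s <- expr_deparse(e)
    # parenthesise when the child binds no tighter than its context,
    # otherwise n-ary flattening on re-parse would change the tree shape
    if (expr_prec(e) <= parent_prec) paste0("(", s, ")") else s
  }
  if (inherits(expr, "kb_var")) {
    expr$name
  } else if (inherits(expr, "kb_not")) {
    paste0("!", wrap(expr$operand, 3L))
  } else if (inherits(expr, "kb_and")) {
    paste(vapply(expr$operands, wrap, character(1), 2L), collapse = " & ")
  } else {
    paste(vapply(expr$operands, wrap, character(1), 1L), collapse = " || ")
  }
}

# Convert to an R language object using the vectorised operators `&`, `|`,
# `!`.  Compiled plans evaluate these directly in an environment.
expr_to_lang <- function(expr) {
  if (inherits(expr, "kb_var")) {
    as.name(expr$name)
  } else if (inherits(expr, "kb_not")) {
    call("!", expr_to_lang(expr$operand))
  } else {
    op <- if (inherits(expr, "kb_and")) "&" else "|"
    Reduce(function(a, b) call(op, a, b), lapply(expr$operands, expr_to_lang))
  }
}

#' @export
print.kb_expr <- function(x, ...) {
  cat(expr_deparse(x), "\n")
  invisible(x)
}

# ---- Rules, comments, knowledge base ---------------------------------------

#' Construct a derivation rule
#'
#' A rule guards one or more boolean-literal assignments behind a
#' condition: when the condition evaluates true, each target variable is
#' set to its literal.  Targets default to `FALSE` before any rule runs,
#' mirroring straight-line generated code with default-initialised
#' booleans.
#'
#' @param condition A `kb_expr`.
#' @param assignments Named logical vector: `c(tca_tx = TRUE)`.
#' @return An object of class `kb_rule`.
#' @export
kb_rule <- function(condition, assignments) {
  stopifnot(inherits(condition, "kb_expr"), is.logical(assignments),
            length(assignments) >= 1L, !is.null(names(assignments)))
  if (anyDuplicated(names(assignments)))
    stop("rule repeats a target variable", call. = FALSE)
  structure(list(condition = condition, assignments = assignments),
            class = "kb_rule")
}

#' Construct a conditional comment
#'
#' A comment carries one text string and one or more routes; each route
#' pairs a condition with a placement (location identifier plus a sort
#' order).  The same comment may be routed to several interface locations
#' under different conditions.
#'
#' @param name Comment identifier, unique within a knowledge base.
#' @param routes List of routes from [kb_route()].
#' @param text The comment text shown to the clinician.
#' @return An object of class `kb_comment`.
#' @export
kb_comment <- function(name, routes, text) {
  stopifnot(is.character(name), length(name) == 1L,
            is.list(routes), length(routes) >= 1L,
            is.character(text), length(text) == 1L)
  stopifnot(all(vapply(routes, inherits, logical(1), "kb_route")))
  structure(list(name = name, routes = routes, text = text),
            class = "kb_comment")
}

#' @rdname kb_comment
#' @param condition A `kb_expr` guarding the placement.
#' @param location Identifier of a registered report location.
#' @param order Non-negative integer sort key within the location.
#' @export
kb_route <- function(condition, location, order) {
  stopifnot(inherits(condition, "kb_expr"),
            is.character(location), length(location) == 1L)
  order <- as.integer(order)
  stopifnot(length(order) == 1L, !is.na(order), order >= 0L)
  structure(list(condition = condition, location = location, order = order),
            class = "kb_route")
}

#' Construct a knowledge base
#'
#' @param items List of [kb_rule()] and [kb_comment()] objects in
#'   declaration order.
#' @param inputs Character vector of declared input variables (facts the
#'   extraction layer publishes; rules may not assign them).
#' @param locations Ordered character vector: the registry of report
#'   locations comments may route to.
#' @return An object of class `knowledge_base` with components `items`
#'   (declaration order), `rules`, `comments`, `inputs`, `locations`.
#' @export
knowledge_base <- function(items = list(), inputs = character(),
                           locations = character()) {
  ok <- vapply(items, function(x) inherits(x, "kb_rule") || inherits(x, "kb_comment"),
               logical(1))
  if (length(items) && !all(ok))
    stop("items must be kb_rule or kb_comment objects", call. = FALSE)
  is_rule <- vapply(items, inherits, logical(1), "kb_rule")
  structure(list(items = items,
                 rules = items[is_rule],
                 comments = items[!is_rule],
                 inputs = unique(as.character(inputs)),
                 locations = unique(as.character(locations))),
            class = "knowledge_base")
}

# All rule-target names, in assignment order.
kb_targets <- function(kb) {
  unique(unlist(lapply(kb$rules, function(r) names(r$assignments)), use.names = FALSE))
}

# Every variable referenced anywhere in the KB.
kb_referenced <- function(kb) {
  refs <- lapply(kb$items, function(it) {
    if (inherits(it, "kb_rule")) expr_vars(it$condition)
    else unlist(lapply(it$routes, function(r) expr_vars(r$condition)), use.names = FALSE)
  })
  unique(unlist(refs, use.names = FALSE))
}

#' Structural equality of knowledge bases
#'
#' Compares declarations, inputs, and the location registry; ignores
#' source positions and file names, so a parsed knowledge base and the
#' re-parse of its pretty-printed form compare equal.
#'
#' @param a,b `knowledge_base` objects.
#' @return `TRUE` or `FALSE`.
#' @export
kb_identical <- function(a, b) {
  identical(a$items, b$items) &&
    identical(a$inputs, b$inputs) &&
    identical(a$locations, b$locations)
}

#' @export
print.knowledge_base <- function(x, ...) {
  cat(sprintf("<knowledge_base: %d rule(s), %d comment(s), %d input(s), %d location(s)>\n",
              length(x$rules), length(x$comments),
              length(x$inputs), length(x$locations)))
  invisible(x)
}
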