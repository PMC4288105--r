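# ---- Lexer -----------------------------------------------------------------
#
# One master regex tokenises the whole document; any character the regex
# cannot account for is a lexical error reported with line:col.  Strings
# are double-quoted, may span lines, and escape an embedded quote as \".

.kb_token_re <- paste0(
  "(?s)",
  "(?<COMMENT>#[^\n]*)",
  "|(?<STRING>\"(?:\\\\.|[^\"\\\\])*\")",
  "|(?<IDENT>[A-Za-z_][A-Za-z0-9_]*)",
  "|(?<INT>[0-9]+)",
  "|(?<OP>\\|\\||&&|[|&!(){};=:])",
  "|(?<WS>[ \t\r\n]+)"
)

kb_error <- function(msg, line, col, file = "<kb>",
                     class = "kb_syntax_error") {
  cond <- structure(
    class = c(class, "kb_parse_error", "error", "condition"),
    list(message = sprintf("%s:%d:%d: error: %s", file, line, col, msg),
         call = NULL, line = line, col = col, file = file))
  stop(cond)
}

kb_tokenize <- function(source, file = "<kb>") {
  if (length(source) != 1L || !is.character(source))
    stop("source must be a single string", call. = FALSE)
  nl <- c(0L, gregexpr("\n", source, fixed = TRUE)[[1]])
  if (length(nl) == 2L && nl[2] == -1L) nl <- 0L
  pos_line <- function(p) findInterval(p, nl + 1L)
  pos_col <- function(p) p - nl[pos_line(p)]

  if (!nchar(source))
    return(data.frame(type = character(0), value = character(0),
                      line = integer(0), col = integer(0),
                      stringsAsFactors = FALSE))
  m <- gregexpr(.kb_token_re, source, perl = TRUE)[[1]]
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  if (starts[1] == -1L) { starts <- integer(0); lens <- integer(0) }

  # any gap between consecutive matches is an illegal character
  covered <- integer(0)
  expect_next <- 1L
  for (i in seq_along(starts)) {
    if (starts[i] != expect_next) {
      p <- expect_next
      ch <- substr(source, p, p)
      if (ch == "\"")
        kb_error("unterminated Text string", pos_line(p), pos_col(p), file,
                 class = "kb_unterminated_string_error")
      kb_error(sprintf("unexpected character '%s'", ch),
               pos_line(p), pos_col(p), file)
    }
    expect_next <- starts[i] + lens[i]
  }
  if (expect_next <= nchar(source)) {
    p <- expect_next
    ch <- substr(source, p, p)
    if (ch == "\"")
      kb_error("unterminated Text string", pos_line(p), pos_col(p), file,
               class = "kb_unterminated_string_error")
    kb_error(sprintf("unexpected character '%s'", ch),
             pos_line(p), pos_col(p), file)
  }

  vals <- substring(source, starts, starts + lens - 1L)
  type <- character(length(vals))
  cs <- attr(m, "capture.start")
  if (length(vals)) {
    for (nm in colnames(cs)) type[cs[, nm] > 0L] <- nm
  }
  keep <- !(type %in% c("WS", "COMMENT"))
  data.frame(type = type[keep], value = vals[keep],
             line = pos_line(starts[keep]), col = pos_col(starts[keep]),
             stringsAsFactors = FALSE)
}

# decode a STRING token's source form into its value
kb_unquote <- function(s) {
  body <- substr(s, 2L, nchar(s) - 1L)
  body <- gsub("\\\\(.)", "\\1", body)
  body
}

kb_quote <- function(s) {
  paste0("\"", gsub("([\"\\\\])", "\\\\\\1", s), "\"")
}

# ---- Recursive-descent parser ----------------------------------------------

#' Parse knowledge-base source text
#'
#' Parses the knowledge-base language: C-like derivation rules
#' (`if (<expr>) <var> = true|false; ...`) and conditional-comment blocks
#' (`Comment <name> { Condition: <expr>; Where: <loc> (order: <n>); ...
#' Text: "..." }`).  Both `||`/`|` parse as or and `&&`/`&` as and; `!` is
#' not; precedence is not > and > or; `#` starts a line comment.
#' Declaration order is preserved, and the pretty-printed form
#' ([kb_deparse()]) re-parses to a structurally identical knowledge base.
#'
#' @param source Knowledge-base source as a single string (or a character
#'   vector of lines, which is joined with newlines).
#' @param file Name used in diagnostics.
#' @param inputs,locations Optional declared-input set and location
#'   registry to attach (both usually come from a config file; see
#'   [read_kb_config()]).
#' @return A [knowledge_base()] object.  Parse failures signal a
#'   condition of class `kb_parse_error` whose message carries
#'   `file:line:col`; duplicate comment names signal
#'   `kb_duplicate_comment_error`, unterminated strings
#'   `kb_unterminated_string_error`.
#' @examples
#' kb <- parse_kb("if (amitriptyline_tx || nortriptyline_tx) tca_tx = true;")
#' kb$rules[[1]]$assignments
#' @seealso [kb_deparse()], [validate_kb()], [compile_kb()]
#' @export
parse_kb <- function(source, file = "<kb>", inputs = character(),
                     locations = character()) {
  if (length(source) > 1L) source <- paste(source, collapse = "\n")
  toks <- kb_tokenize(source, file)
  n <- nrow(toks)
  i <- 1L

  peek <- function() if (i <= n) toks[i, ] else NULL
  at_end <- function() i > n
  err <- function(msg, tok = peek(), class = "kb_syntax_error") {
    if (is.null(tok))
      kb_error(paste0(msg, " (at end of input)"),
               if (n) toks$line[n] else 1L, if (n) toks$col[n] else 1L,
               file, class)
    kb_error(sprintf("%s; offending token '%s'", msg, tok$value),
             tok$line, tok$col, file, class)
  }
  advance <- function() { t <- toks[i, ]; i <<- i + 1L; t }
  expect <- function(value, what = sprintf("expected '%s'", value)) {
    t <- peek()
    if (is.null(t) || t$value != value) err(what, t)
    advance()
  }
  expect_ident <- function(what = "expected identifier") {
    t <- peek()
    if (is.null(t) || t$type != "IDENT") err(what, t)
    advance()$value
  }

  parse_primary <- function() {
    t <- peek()
    if (is.null(t)) err("expected expression")
    if (t$value == "(") {
      advance()
      e <- parse_or()
      expect(")")
      return(e)
    }
    if (t$type == "IDENT") {
      if (t$value %in% c("true", "false"))
        err("boolean literals are not allowed inside conditions", t)
      return(kb_var(advance()$value))
    }
    err("expected expression", t)
  }
  parse_unary <- function() {
    t <- peek()
    if (!is.null(t) && t$value == "!") {
      advance()
      return(kb_not(parse_unary()))
    }
    parse_primary()
  }
  parse_and <- function() {
    ops <- list(parse_unary())
    while (!at_end() && peek()$value %in% c("&&", "&")) {
      advance()
      ops[[length(ops) + 1L]] <- parse_unary()
    }
    if (length(ops) == 1L) ops[[1]] else kb_and(ops)
  }
  parse_or <- function() {
    ops <- list(parse_and())
    while (!at_end() && peek()$value %in% c("||", "|")) {
      advance()
      ops[[length(ops) + 1L]] <- parse_and()
    }
    if (length(ops) == 1L) ops[[1]] else kb_or(ops)
  }

  parse_bool_literal <- function() {
    t <- peek()
    if (is.null(t) || !(t$value %in% c("true", "false")))
      err("expected 'true' or 'false'", t)
    advance()$value == "true"
  }

  parse_rule <- function() {
    start <- peek()
    expect("if")
    expect("(")
    cond <- parse_or()
    expect(")")
    targets <- character(0)
    values <- logical(0)
    repeat {
      t <- peek()
      if (is.null(t) || t$type != "IDENT" ||
          t$value %in% c("if", "Comment") ||
          (i + 1L <= n && toks$value[i + 1L] != "=")) break
      tgt <- expect_ident()
      expect("=")
      val <- parse_bool_literal()
      expect(";")
      if (tgt %in% targets)
        err(sprintf("target '%s' repeated within one rule", tgt), start)
      targets <- c(targets, tgt)
      values <- c(values, val)
    }
    if (!length(targets)) err("rule needs at least one assignment", peek())
    list(item = kb_rule(cond, stats::setNames(values, targets)),
         line = start$line, col = start$col)
  }

  parse_comment <- function() {
    start <- peek()
    expect("Comment")
    name <- expect_ident("expected comment name")
    expect("{")
    routes <- list()
    text <- NULL
    repeat {
      t <- peek()
      if (is.null(t)) err("unterminated Comment block (expected '}')", t)
      if (t$value == "Condition") {
        advance()
        expect(":")
        cond <- parse_or()
        expect(";")
        expect("Where", "expected 'Where' after Condition")
        expect(":")
        loc <- expect_ident("expected location identifier")
        expect("(")
        expect("order", "expected 'order'")
        expect(":")
        ot <- peek()
        if (is.null(ot) || ot$type != "INT") err("expected integer order", ot)
        ord <- as.integer(advance()$value)
        expect(")")
        expect(";")
        routes[[length(routes) + 1L]] <- kb_route(cond, loc, ord)
      } else if (t$value == "Text") {
        advance()
        expect(":")
        st <- peek()
        if (is.null(st) || st$type != "STRING") err("expected quoted Text string", st)
        text <- kb_unquote(advance()$value)
        expect("}")
        break
      } else {
        err("expected 'Condition:' or 'Text:' inside Comment block", t)
      }
    }
    if (!length(routes)) err("Comment needs at least one Condition/Where route", start)
    if (is.null(text)) err("Comment needs a Text clause", start)
    list(item = kb_comment(name, routes, text),
         line = start$line, col = start$col)
  }

  items <- list()
  pos <- list()
  comment_names <- character(0)
  while (!at_end()) {
    t <- peek()
    if (t$value == "if") {
      parsed <- parse_rule()
    } else if (t$value == "Comment") {
      parsed <- parse_comment()
      nm <- parsed$item$name
      if (nm %in% comment_names)
        kb_error(sprintf("duplicate comment name '%s'", nm),
                 t$line, t$col, file, class = "kb_duplicate_comment_error")
      comment_names <- c(comment_names, nm)
    } else {
      err("expected 'if' rule or 'Comment' block at top level", t)
    }
    items[[length(items) + 1L]] <- parsed$item
    pos[[length(pos) + 1L]] <- c(parsed$line, parsed$col)
  }

  kb <- knowledge_base(items, inputs = inputs, locations = locations)
  attr(kb, "srcpos") <- do.call(rbind, pos)
  attr(kb, "file") <- file
  kb
}

#' @rdname parse_kb
#' @param path Path to a `.kb` source file (UTF-8).
#' @export
parse_kb_file <- function(path, inputs = character(), locations = character()) {
  src <- paste(readLines(path, warn = FALSE, encoding = "UTF-8"), collapse = "\n")
  parse_kb(src, file = basename(path), inputs = inputs, locations = locations)
}

# ---- Pretty printer --------------------------------------------------------

#' Pretty-print a knowledge base to source text
#'
#' Writes the canonical surface form of every declaration in declaration
#' order.  `parse_kb(kb_deparse(kb))` reconstructs a structurally
#' identical knowledge base (the round-trip property).
#'
#' @param kb A [knowledge_base()].
#' @return A single string of knowledge-base source.
#' @export
kb_deparse <- function(kb) {
  fmt_item <- function(it) {
    if (inherits(it, "kb_rule")) {
      asg <- paste(sprintf("%s = %s;", names(it$assignments),
                           ifelse(it$assignments, "true", "false")),
                   collapse = " ")
      sprintf("if (%s) %s", expr_deparse(it$condition), asg)
    } else {
      routes <- vapply(it$routes, function(r) {
        sprintf("  Condition: %s; Where: %s (order: %d);",
                expr_deparse(r$condition), r$location, r$order)
      }, character(1))
      paste0("Comment ", it$name, " {\n",
             paste(routes, collapse = "\n"), "\n",
             "  Text: ", kb_quote(it$text), "\n}")
    }
  }
  paste(vapply(kb$items, fmt_item, character(1)), collapse = "\n\n")
}

# ---- Config ----------------------------------------------------------------

#' Read a knowledge-base configuration file
#'
#' The configuration is a YAML document with two keys: `inputs`, the
#' declared input variables the extraction layer publishes, and
#' `locations`, the ordered registry of report locations.  The DSL file
#' itself carries no declarations; attaching them here keeps the
#' knowledge base editable without touching extraction code.
#'
#' @param path Path to a YAML file.
#' @return List with character vectors `inputs` and `locations`.
#' @export
read_kb_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$inputs) || is.null(cfg$locations))
    stop("KB config must define 'inputs' and 'locations'", call. = FALSE)
  list(inputs = as.character(unlist(cfg$inputs)),
       locations = as.character(unlist(cfg$locations)))
}
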