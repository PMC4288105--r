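test_that("the printed rule and comment examples parse to the expected trees", {
  kb <- box_kb()
  expect_length(kb$rules, 1L)
  expect_length(kb$comments, 1L)

  r <- kb$rules[[1]]
  expect_identical(r$condition,
                   kb_or(kb_var("amitriptyline_tx"), kb_var("nortriptyline_tx")))
  expect_identical(r$assignments, c(tca_tx = TRUE))

  cm <- kb$comments[[1]]
  expect_identical(cm$name, "TCA_depression")
  expect_length(cm$routes, 2L)
  expect_identical(cm$routes[[1]]$condition,
                   kb_and(kb_var("tca_tx"), kb_var("depression_hx")))
  expect_identical(cm$routes[[1]]$location, "Recommendations")
  expect_identical(cm$routes[[1]]$order, 7L)
  expect_identical(cm$routes[[2]]$condition, kb_var("depression_hx"))
  expect_identical(cm$routes[[2]]$location, "TCA_comments")
  expect_identical(cm$routes[[2]]$order, 5L)
  expect_match(cm$text, "^The presence of depression is not required")
})

test_that("an empty document yields an empty knowledge base", {
  kb <- parse_kb("")
  expect_length(kb$rules, 0L)
  expect_length(kb$comments, 0L)
  kb2 <- parse_kb("# only a comment line\n")
  expect_length(kb2$items, 0L)
})

test_that("operator aliases, precedence and grouping parse correctly", {
  e1 <- parse_kb("if (a || b) t = true;")$rules[[1]]$condition
  e2 <- parse_kb("if (a | b) t = true;")$rules[[1]]$condition
  expect_identical(e1, e2)
  e3 <- parse_kb("if (a && b) t = true;")$rules[[1]]$condition
  e4 <- parse_kb("if (a & b) t = true;")$rules[[1]]$condition
  expect_identical(e3, e4)

  # not > and > or
  e <- parse_kb("if (!a & b || c) t = true;")$rules[[1]]$condition
  expect_identical(e, kb_or(kb_and(kb_not(kb_var("a")), kb_var("b")),
                            kb_var("c")))
  # parentheses regroup
  eg <- parse_kb("if (!a & (b || c)) t = true;")$rules[[1]]$condition
  expect_identical(eg, kb_and(kb_not(kb_var("a")),
                              kb_or(kb_var("b"), kb_var("c"))))
  # n-ary chains flatten at one level
  en <- parse_kb("if (a || b || c) t = true;")$rules[[1]]$condition
  expect_length(en$operands, 3L)
})

test_that("multi-assignment rules and multi-line strings parse", {
  kb <- parse_kb("if (a) x = true; y = false;")
  expect_identical(kb$rules[[1]]$assignments, c(x = TRUE, y = FALSE))

  src <- "Comment C { Condition: a; Where: L (order: 0);\n  Text: \"line one\nand a \\\"quoted\\\" bit\" }"
  cm <- parse_kb(src)$comments[[1]]
  expect_identical(cm$text, "line one\nand a \"quoted\" bit")
})

test_that("syntax errors carry line and column and the offending token", {
  err <- tryCatch(parse_kb("if (a ||) t = true;"), condition = identity)
  expect_s3_class(err, "kb_parse_error")
  expect_match(conditionMessage(err), "<kb>:1:9")
  expect_match(conditionMessage(err), "offending token '\\)'")

  err2 <- tryCatch(parse_kb("if (a)\n  t = maybe;"), condition = identity)
  expect_match(conditionMessage(err2), ":2:")
})

test_that("duplicate comment names and unterminated strings are named diagnostics", {
  src <- paste("Comment C { Condition: a; Where: L (order: 1); Text: \"x\" }",
               "Comment C { Condition: b; Where: L (order: 2); Text: \"y\" }",
               sep = "\n")
  expect_error(parse_kb(src), class = "kb_duplicate_comment_error")
  expect_error(parse_kb("Comment C { Condition: a; Where: L (order: 1); Text: \"never ends }"),
               class = "kb_unterminated_string_error")
})

test_that("parse -> pretty-print -> parse round-trips random knowledge bases", {
  set.seed(101)
  for (i in 1:40) {
    kb <- random_kb(n_inputs = sample(1:6, 1L), n_rules = sample(0:20, 1L),
                    n_comments = sample(0:20, 1L))
    kb2 <- parse_kb(kb_deparse(kb), inputs = kb$inputs,
                    locations = kb$locations)
    expect_true(kb_identical(kb, kb2),
                info = paste("round-trip failed for generated KB", i))
  }
})

test_that("validate_kb flags undefined variables, bad locations and unsound order", {
  cfg_loc <- c("Recommendations", "TCA_comments")

  # runnable KB -> empty diagnostics
  expect_identical(nrow(validate_kb(box_kb())), 0L)

  # rule reads an unassignable variable
  kb <- parse_kb("if (tca_tx) x = true;", inputs = character(0),
                 locations = cfg_loc)
  d <- validate_kb(kb)
  expect_identical(d$code, "undefined_variable")
  expect_match(d$message, "'tca_tx'")

  # oracle: set difference of referenced vs (inputs union assigned)
  expect_identical(setdiff(kb_referenced(kb),
                           union(kb$inputs, names(kb$rules[[1]]$assignments))),
                   "tca_tx")

  # unknown location (registry membership is the oracle)
  kb2 <- parse_kb(box_kb_source(),
                  inputs = c("amitriptyline_tx", "nortriptyline_tx",
                             "depression_hx"),
                  locations = "TCA_comments")
  d2 <- validate_kb(kb2)
  expect_identical(d2$code[d2$severity == "error"], "unknown_location")
  expect_match(d2$message[d2$severity == "error"], "'Recommendations'")
  expect_false("Recommendations" %in% kb2$locations)

  # use before assignment
  kb3 <- parse_kb("if (late) a = true;\nif (a) late = true;",
                  inputs = character(0), locations = cfg_loc)
  expect_true("use_before_assignment" %in% validate_kb(kb3)$code)

  # input also assigned
  kb4 <- parse_kb("if (a) b = true;", inputs = c("a", "b"),
                  locations = cfg_loc)
  expect_true("input_assigned" %in% validate_kb(kb4)$code)

  # unreachable route warning names the comment
  kb5 <- parse_kb("Comment C { Condition: ghost; Where: TCA_comments (order: 1); Text: \"t\" }",
                  inputs = character(0), locations = cfg_loc)
  d5 <- validate_kb(kb5)
  expect_true("unreachable_route" %in% d5$code)
  expect_identical(d5$severity[d5$code == "unreachable_route"], "warning")
})

test_that("diagnostics format as file:line:col: severity: message lines", {
  kb <- parse_kb("if (ghost) x = true;", file = "demo.kb")
  lines <- format_diagnostics(validate_kb(kb))
  expect_match(lines, "^demo\\.kb:1:1: error: ", all = TRUE)
})

test_that("compilation preserves step counts, is deterministic, and refuses broken KBs", {
  plan <- compile_kb(box_kb())
  expect_length(plan$steps, 1L)

  set.seed(7)
  kb <- random_kb(n_inputs = 3L, n_rules = 3L, n_comments = 2L)
  plan2 <- compile_kb(kb)
  expect_length(plan2$steps, 3L)
  n_routes <- sum(vapply(kb$comments, function(cm) length(cm$routes), integer(1)))
  expect_length(plan2$routes, n_routes)

  # deterministic: byte-identical serialization on recompilation
  expect_identical(plan_serialize(compile_kb(kb)), plan_serialize(compile_kb(kb)))

  broken <- parse_kb("if (ghost) x = true;")
  err <- tryCatch(compile_kb(broken), condition = identity)
  expect_s3_class(err, "kb_compile_error")
  expect_true("undefined_variable" %in% err$diagnostics$code)
})
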