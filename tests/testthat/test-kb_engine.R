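test_that("the TCA worked example routes the comment as printed", {
  plan <- compile_kb(box_kb())

  # on amitriptyline with depression: derived TCA treatment, comment in
  # both Recommendations (order 7) and the TCA hover box (order 5)
  res <- evaluate(plan, box_facts(ami = TRUE, dep = TRUE))
  expect_true(res$facts$values[["tca_tx"]])
  expect_identical(res$facts$provenance[["tca_tx"]], "derived")
  expect_identical(res$placements$Recommendations$comment, "TCA_depression")
  expect_identical(res$placements$Recommendations$order, 7L)
  expect_identical(res$placements$TCA_comments$comment, "TCA_depression")
  expect_identical(res$placements$TCA_comments$order, 5L)

  # depression without TCA treatment: hover box only
  res2 <- evaluate(plan, box_facts(dep = TRUE))
  expect_false(res2$facts$values[["tca_tx"]])
  expect_identical(nrow(res2$placements$Recommendations), 0L)
  expect_identical(res2$placements$TCA_comments$comment, "TCA_depression")

  # all inputs false: nothing derived, nothing placed
  res3 <- evaluate(plan, box_facts())
  expect_false(any(res3$facts$values[["tca_tx"]]))
  expect_identical(sum(vapply(res3$placements, nrow, integer(1))), 0L)
})

test_that("the derivation rule covers all four input assignments", {
  plan <- compile_kb(box_kb())
  for (ami in c(FALSE, TRUE)) for (nor in c(FALSE, TRUE)) {
    res <- evaluate(plan, box_facts(ami = ami, nor = nor))
    expect_identical(res$facts$values[["tca_tx"]], ami || nor)
  }
  # reference interpreter agrees on the single-drug case
  ref <- truth_table_reference(box_kb(),
                               c(amitriptyline_tx = FALSE,
                                 nortriptyline_tx = TRUE,
                                 depression_hx = FALSE))
  expect_true(ref$facts$values[["tca_tx"]])
})

test_that("missing inputs default to FALSE with a warning; unknown vars error", {
  plan <- compile_kb(box_kb())
  expect_warning(res <- evaluate(plan, fact_set(c(depression_hx = TRUE))),
                 "defaulting to FALSE")
  expect_false(res$facts$values[["amitriptyline_tx"]])

  kb <- knowledge_base(list(kb_rule(kb_var("phantom"), c(x = TRUE))),
                       inputs = character(0), locations = character(0))
  plan2 <- structure(list(steps = list(list(cond = quote(phantom),
                                            assignments = c(x = TRUE))),
                          routes = list(), inputs = character(0),
                          targets = "x", locations = character(0),
                          rule_owner = c(x = 1L)),
                     class = "evaluation_plan")
  expect_error(evaluate(plan2, fact_set()),
               "variable 'phantom' has no binding and no default")
})

test_that("overriding a checkbox re-evaluates and leaves the original facts alone", {
  plan <- compile_kb(box_kb())
  facts <- box_facts(ami = TRUE, dep = FALSE)
  base <- evaluate(plan, facts)
  expect_identical(nrow(base$placements$Recommendations), 0L)

  # checking the depression box adds the recommendation
  over <- override_fact(plan, facts, "depression_hx", TRUE)
  expect_identical(over$placements$Recommendations$comment, "TCA_depression")
  expect_identical(over$facts$provenance[["depression_hx"]], "override")
  expect_false(facts$values[["depression_hx"]])   # input unchanged

  # no-op override reproduces the prior placements and values
  same <- override_fact(plan, facts, "depression_hx", FALSE)
  expect_identical(same$placements, base$placements)
  expect_identical(same$facts$values, base$facts$values)

  # toggling there and back reproduces the original evaluation
  back <- override_fact(plan, over$facts, "depression_hx", FALSE)
  expect_identical(back$placements, base$placements)
  expect_identical(back$facts$values, base$facts$values)

  # derived variables are refused by the rule that owns them
  expect_error(override_fact(plan, facts, "tca_tx", TRUE),
               "derived by rule 1")
})

test_that("compiled evaluation matches the reference interpreter exhaustively", {
  set.seed(202)
  for (i in 1:25) {
    kb <- random_kb(n_inputs = sample(1:5, 1L), n_rules = sample(0:8, 1L),
                    n_comments = sample(0:5, 1L))
    expect_identical(count_disagreements(kb), 0L,
                     info = paste("disagreement in generated KB", i))
  }
})

test_that("a comment whose conditions are all false changes nothing", {
  set.seed(303)
  kb <- random_kb(n_inputs = 3L, n_rules = 2L, n_comments = 2L)
  dead_cond <- kb_and(kb_var("in1"), kb_not(kb_var("in1")))  # contradiction
  dead <- kb_comment("Dead", list(kb_route(dead_cond, "loc1", 0L)), "never")
  kb2 <- knowledge_base(c(kb$items, list(dead)), kb$inputs, kb$locations)
  p1 <- compile_kb(kb)
  p2 <- compile_kb(kb2)
  for (asg in all_assignments(kb$inputs)) {
    r1 <- evaluate(p1, fact_set(asg))
    r2 <- evaluate(p2, fact_set(asg))
    expect_identical(r1$placements, r2$placements)
    expect_identical(r1$facts$values, r2$facts$values)
  }
})

test_that("placements are sorted by order with declaration-order ties, once per location", {
  src <- paste(
    "Comment A { Condition: x; Where: L (order: 5); Text: \"a\" }",
    "Comment B { Condition: x; Where: L (order: 2); Text: \"b\" }",
    "Comment C { Condition: x; Where: L (order: 5); Text: \"c\" }",
    # two true routes of one comment to the same location: placed once,
    # at the earlier sort position
    "Comment D { Condition: x; Where: L (order: 9); Condition: x; Where: L (order: 1); Text: \"d\" }",
    sep = "\n")
  kb <- parse_kb(src, inputs = "x", locations = "L")
  res <- evaluate(compile_kb(kb), fact_set(c(x = TRUE)))
  placed <- res$placements$L
  expect_identical(placed$comment, c("D", "B", "A", "C"))
  expect_true(all(diff(placed$order) >= 0))
  expect_identical(anyDuplicated(placed$comment), 0L)

  # property: non-decreasing order in every location of random KBs
  set.seed(404)
  for (i in 1:10) {
    kb <- random_kb(n_inputs = 3L, n_rules = 3L, n_comments = 5L)
    plan <- compile_kb(kb)
    for (asg in all_assignments(kb$inputs)) {
      for (loc in names(evaluate(plan, fact_set(asg))$placements)) {
        p <- evaluate(plan, fact_set(asg))$placements[[loc]]
        expect_true(all(diff(p$order) >= 0))
        expect_identical(anyDuplicated(p$comment), 0L)
      }
    }
  }
})

test_that("a knowledge base without comments yields empty placements everywhere", {
  kb <- parse_kb("if (a) t = true;", inputs = "a", locations = c("L1", "L2"))
  res <- evaluate(compile_kb(kb), fact_set(c(a = TRUE)))
  expect_named(res$placements, c("L1", "L2"))
  expect_identical(vapply(res$placements, nrow, integer(1)),
                   c(L1 = 0L, L2 = 0L))
})

test_that("later rules overwrite earlier targets deterministically", {
  src <- "if (a) t = true;\nif (b) t = false;"
  kb <- parse_kb(src, inputs = c("a", "b"), locations = character(0))
  plan <- compile_kb(kb)
  expect_true(evaluate(plan, fact_set(c(a = TRUE, b = FALSE)))$facts$values[["t"]])
  expect_false(evaluate(plan, fact_set(c(a = TRUE, b = TRUE)))$facts$values[["t"]])
})
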