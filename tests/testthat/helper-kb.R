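# Random knowledge-base generator and equivalence helpers shared by the
# property-style tests and the acceptance suite.

random_expr <- function(vars, depth = 2L) {
  if (depth <= 0L || stats::runif(1) < 0.4)
    return(kb_var(sample(vars, 1L)))
  k <- sample(3L, 1L)
  if (k == 1L) {
    kb_not(random_expr(vars, depth - 1L))
  } else {
    ops <- lapply(seq_len(sample(2:3, 1L)), function(i)
      random_expr(vars, depth - 1L))
    if (k == 2L) kb_and(ops) else kb_or(ops)
  }
}

# A runnable random KB: rule conditions only read inputs and
# previously-assigned targets (no use-before-assignment); comments may
# read anything; locations drawn from a small registry.
random_kb <- function(n_inputs = sample(1:4, 1L),
                      n_rules = sample(0:6, 1L),
                      n_comments = sample(0:4, 1L),
                      n_locations = 3L) {
  inputs <- paste0("in", seq_len(n_inputs))
  locs <- paste0("loc", seq_len(n_locations))
  targets <- character(0)
  items <- list()
  for (r in seq_len(n_rules)) {
    avail <- c(inputs, targets)
    cond <- random_expr(avail, sample(1:3, 1L))
    tgts <- paste0("d", r)
    if (length(targets) && stats::runif(1) < 0.3)
      tgts <- c(tgts, sample(targets, 1L))     # re-assign: last write wins
    vals <- sample(c(TRUE, FALSE), length(tgts), replace = TRUE)
    items[[length(items) + 1L]] <- kb_rule(cond, stats::setNames(vals, tgts))
    targets <- union(targets, tgts)
  }
  all_vars <- c(inputs, targets)
  for (ci in seq_len(n_comments)) {
    routes <- lapply(seq_len(sample(1:3, 1L)), function(j)
      kb_route(random_expr(all_vars, sample(1:2, 1L)),
               sample(locs, 1L), sample(0:9, 1L)))
    items[[length(items) + 1L]] <- kb_comment(paste0("C", ci), routes,
                                              paste0("comment text ", ci))
  }
  knowledge_base(items, inputs = inputs, locations = locs)
}

# All 2^n assignments of the given inputs, as a list of named logical
# vectors.
all_assignments <- function(inputs) {
  n <- length(inputs)
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  lapply(seq_len(nrow(grid)), function(i)
    stats::setNames(as.logical(grid[i, ]), inputs))
}

results_agree <- function(a, b) {
  identical(a$facts$values[sort(names(a$facts$values))],
            b$facts$values[sort(names(b$facts$values))]) &&
    identical(a$placements, b$placements)
}

# Exhaustive compiled-vs-reference check for one KB; returns the number
# of disagreeing assignments.
count_disagreements <- function(kb) {
  plan <- compile_kb(kb)
  sum(!vapply(all_assignments(kb$inputs), function(asg) {
    results_agree(evaluate(plan, fact_set(asg)),
                  truth_table_reference(kb, asg))
  }, logical(1)))
}

box_kb_source <- function() {
  paste(
    "if (amitriptyline_tx || nortriptyline_tx) tca_tx = true;",
    "Comment TCA_depression {",
    "  Condition: tca_tx & depression_hx; Where: Recommendations (order: 7);",
    "  Condition: depression_hx; Where: TCA_comments (order: 5);",
    "  Text: \"The presence of depression is not required for the analgesic effects of TCAs, although they may be particularly useful in patients with inadequately treated depression.\"",
    "}", sep = "\n")
}

box_kb <- function() {
  parse_kb(box_kb_source(),
           inputs = c("amitriptyline_tx", "nortriptyline_tx", "depression_hx"),
           locations = c("Recommendations", "TCA_comments"))
}

box_facts <- function(ami = FALSE, nor = FALSE, dep = FALSE) {
  fact_set(c(amitriptyline_tx = ami, nortriptyline_tx = nor,
             depression_hx = dep))
}
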