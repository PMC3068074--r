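test_that("the packaged guideline fixture loads and validates", {
  g <- load_guideline(system.file("extdata", "guideline_prostate.yaml",
                                  package = "psakit"))
  kinds <- vapply(g$nodes, `[[`, character(1), "kind")
  expect_gte(sum(kinds == "decision"), 3)
  expect_true(g$entry %in% names(g$nodes))
  expect_gte(length(g$edges), length(g$nodes) - 1)
})

test_that("a two-node linear graph loads with one edge", {
  g <- load_guideline(guideline_yaml("
entry: a
facts: {psa: numeric}
nodes:
  - {id: a, label: A, kind: decision, predicate: true}
  - {id: b, label: B, kind: therapy, predicate: 'psa > 1'}
edges:
  - {from: a, to: b}
"))
  expect_length(g$edges, 1)
  expect_length(g$nodes, 2)
})

test_that("load-time validation rejects broken graphs", {
  expect_error(load_guideline(guideline_yaml("
entry: a
facts: {}
nodes:
  - {id: a, label: A, kind: decision}
edges:
  - {from: a, to: ghost}
")), "missing node", class = "psakit_data_error")

  expect_error(load_guideline(guideline_yaml("
entry: a
facts: {}
nodes:
  - {id: a, label: A, kind: decision}
  - {id: b, label: B, kind: decision}
edges:
  - {from: a, to: b}
  - {from: b, to: a}
")), "cycle", class = "psakit_data_error")

  expect_error(load_guideline(guideline_yaml("
entry: a
facts: {psa: numeric}
nodes:
  - {id: a, label: A, kind: decision, predicate: 'ghost_fact > 1'}
edges: []
")), "undeclared fact", class = "psakit_data_error")

  expect_error(load_guideline(guideline_yaml("
entry: a
facts: {psa: numeric}
nodes:
  - {id: a, label: A, kind: decision, predicate: 'system(\"date\")'}
edges: []
")), "disallowed", class = "psakit_data_error")

  expect_error(load_guideline(guideline_yaml("
entry: a
facts: {}
nodes:
  - {id: a, label: A, kind: decision}
  - {id: a, label: A2, kind: therapy}
edges: []
")), "duplicate", class = "psakit_data_error")
})

test_that("evaluation highlights the satisfied branch", {
  g <- toy_branch_graph()

  hi <- evaluate_guideline(g, list(psa = 82.35))
  expect_identical(hi$highlighted, c("entry", "therapyA"))
  expect_true("therapyB" %in% hi$unmet)

  lo <- evaluate_guideline(g, list(psa = 5))
  expect_identical(lo$highlighted, c("entry", "therapyB"))

  # unknown facts never highlight, but are recorded as unmet
  unk <- evaluate_guideline(g, list())
  expect_identical(unk$highlighted, "entry")
  expect_setequal(unk$unmet, c("therapyA", "therapyB"))
})

test_that("edge predicates gate traversal under three-valued logic", {
  g <- load_guideline(guideline_yaml("
entry: a
facts: {symptomatic: logical, psa: numeric}
nodes:
  - {id: a, label: A, kind: decision}
  - {id: b, label: B, kind: therapy}
edges:
  - {from: a, to: b, predicate: 'symptomatic == FALSE && psa > 2'}
"))
  expect_identical(
    evaluate_guideline(g, list(symptomatic = FALSE, psa = 5))$highlighted,
    c("a", "b"))
  # unknown symptomatic stops highlighting
  expect_identical(evaluate_guideline(g, list(psa = 5))$highlighted, "a")
  # but a FALSE conjunct decides regardless of the unknown (Kleene logic)
  expect_identical(
    evaluate_guideline(g, list(psa = 1))$highlighted, "a")
  expect_true("b" %in% evaluate_guideline(g, list(psa = 1))$unmet)
})

test_that("identical graphs and facts yield identical traces", {
  g <- load_guideline(system.file("extdata", "guideline_prostate.yaml",
                                  package = "psakit"))
  facts <- list(psa = 82.35, t_category = "T2c", gleason_sum = 7,
                life_expectancy_years = 15,
                lymph_node_involvement_pct = 38, symptomatic = FALSE)
  expect_identical(evaluate_guideline(g, facts), evaluate_guideline(g, facts))
})

test_that("adding facts never removes highlighted nodes", {
  g <- load_guideline(system.file("extdata", "guideline_prostate.yaml",
                                  package = "psakit"))
  full <- list(psa = 8, t_category = "T1c", gleason_sum = 6,
               life_expectancy_years = 15,
               lymph_node_involvement_pct = 5, symptomatic = FALSE)
  for (k in seq_along(full)) {
    partial <- full[seq_len(k)]
    h_partial <- evaluate_guideline(g, partial)$highlighted
    h_full <- evaluate_guideline(g, full)$highlighted
    expect_true(all(h_partial %in% h_full),
                label = sprintf("facts 1..%d monotone", k))
  }
})

test_that("highlighted sets form connected paths on random DAGs", {
  set.seed(99)
  for (rep in 1:25) {
    n <- sample(4:9, 1)
    ids <- paste0("n", seq_len(n))
    edges <- list()
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (runif(1) < 0.4) {
        edges[[length(edges) + 1]] <- list(from = ids[i], to = ids[j])
      }
    }
    thresholds <- round(runif(n, 0, 10), 1)
    node_lines <- sprintf(
      "  - {id: %s, label: %s, kind: decision, predicate: '%s'}",
      ids, ids,
      c("true", sprintf("x %s %s", sample(c("<", ">", "<=", ">="),
                                          n - 1, TRUE), thresholds[-1])))
    edge_lines <- vapply(edges, function(e) {
      sprintf("  - {from: %s, to: %s}", e$from, e$to)
    }, character(1))
    g <- load_guideline(guideline_yaml(c(
      "entry: n1", "facts: {x: numeric}", "nodes:", node_lines,
      "edges:", edge_lines)))
    facts <- if (runif(1) < 0.2) list() else list(x = runif(1, 0, 10))
    tr <- evaluate_guideline(g, facts)

    expect_true(all(tr$highlighted %in% tr$visited))
    expect_setequal(tr$unmet, setdiff(tr$visited, tr$highlighted))
    # connectivity: each highlighted node is the entry or has a
    # highlighted parent
    for (id in tr$highlighted) {
      if (id == "n1") next
      parents <- vapply(Filter(function(e) e$to == id, edges),
                        `[[`, character(1), "from")
      expect_true(any(parents %in% tr$highlighted),
                  label = sprintf("connected %s (rep %d)", id, rep))
    }
  }
})

test_that("traces render as text paths and styled dot documents", {
  g <- toy_branch_graph()
  tr <- evaluate_guideline(g, list(psa = 30))

  txt <- render_trace(g, tr, "text")
  expect_length(txt, 2)
  expect_match(txt[1], "^entry")
  expect_match(txt[2], "therapyA")

  dot <- render_trace(g, tr, "dot")
  expect_identical(sum(grepl("fillcolor", dot)), length(tr$highlighted))
  expect_match(dot[1], "^digraph")

  single <- load_guideline(guideline_yaml(
    c("entry: only", "facts: {}", "nodes:",
      "  - {id: only, label: Only, kind: terminal}", "edges: []")))
  tr1 <- evaluate_guideline(single, list())
  expect_length(render_trace(single, tr1, "text"), 1)

  # trace/graph mismatch
  expect_error(render_trace(single, tr, "text"), class = "psakit_data_error")
})
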