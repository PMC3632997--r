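joinable <- c("unset", "up", "down", "ambiguous")

test_that("the sign join is an idempotent commutative associative lattice", {
  expect_identical(combine_signs("up", "unset"), "up")
  expect_identical(combine_signs("up", "down"), "ambiguous")
  for (a in joinable) {
    for (b in joinable) {
      ab <- combine_signs(a, b)
      expect_identical(ab, combine_signs(b, a))       # commutative
      expect_identical(combine_signs(a, a), a)        # idempotent
      for (d in joinable) {
        expect_identical(combine_signs(ab, d),
                         combine_signs(a, combine_signs(b, d)))  # associative
      }
    }
  }
  expect_error(combine_signs("clamped", "up"), "clamped")
})

test_that("propagation follows edge signs, flips on -1 and blurs on 0", {
  g <- graph_from_edges(data.frame(from = "A", to = "F", sign = -1,
                                   provenance = "x",
                                   stringsAsFactors = FALSE))
  res <- propagate(g, list(list(node = "A", direction = "up")))
  expect_identical(res$states[["F"]], "down")

  g0 <- graph_from_edges(data.frame(from = "A", to = "F", sign = 0,
                                    provenance = "x",
                                    stringsAsFactors = FALSE))
  expect_identical(propagate(g0, c(A = "up"))$states[["F"]], "ambiguous")

  # clamped nodes absorb and transmit nothing
  g2 <- graph_from_edges(data.frame(from = c("A", "B"), to = c("B", "C"),
                                    sign = c(1, 1), provenance = "x",
                                    stringsAsFactors = FALSE))
  res2 <- propagate(g2, list(list(node = "A", direction = "up"),
                             list(node = "B", direction = "clamp")))
  expect_identical(res2$states[["B"]], "clamped")
  expect_identical(res2$states[["C"]], "unset")

  expect_error(propagate(g2, c(Z = "up")), "unknown node")
  expect_error(propagate(g2, c(A = "clamp")), "non-clamp")
})

test_that("a glucose increment propagates down the whole glycolytic chain", {
  m <- make_glycolysis_toy()
  spec <- attr(m, "fixture_spec")
  map <- infer_from_reactions(m)
  g <- to_signed_graph(map)
  glu <- entity_id_for_variable(map, m, "glucose")
  res <- propagate(g, list(list(node = glu, direction = "up")))
  for (sp in spec$chain) {
    eid <- entity_id_for_variable(map, m, sp)
    expect_identical(res$states[[eid]], "up", label = paste(sp, "state"))
  }
  for (i in seq_len(spec$n_reactions)) {
    expect_identical(res$states[[paste0("flow_R", i)]], "up")
  }
  # the enzymes are off the propagation path
  expect_identical(res$states[[entity_id_for_variable(map, m, "HK")]],
                   "unset")
  expect_identical(res$states[[entity_id_for_variable(map, m, "citrate")]],
                   "unset")
})

test_that("propagation equals the per-path sign join on random acyclic graphs", {
  brute_force_state <- function(g, from, node) {
    if (node == from) return("up")
    paths <- find_paths(g, from, node, max_len = nrow(g$nodes))
    if (length(paths) == 0L) return("unset")
    states <- vapply(paths, function(p) {
      if (is.na(p$sign)) "ambiguous" else if (p$sign > 0) "up" else "down"
    }, character(1))
    Reduce(combine_signs, states, accumulate = FALSE)
  }
  for (seed in 301:330) {
    m <- make_random_network(5, 5, p_modifier = 0.3, seed = seed)
    map <- infer_from_reactions(m)
    g <- to_signed_graph(map)
    from <- sort(g$nodes$id[g$nodes$kind == "entity"])[[1L]]
    res <- propagate(g, list(list(node = from, direction = "up")))
    for (node in g$nodes$id) {
      expect_identical(res$states[[node]], brute_force_state(g, from, node),
                       label = paste("seed", seed, "node", node))
    }
  }
})

test_that("propagation terminates within the lattice bound on cyclic graphs", {
  for (seed in 401:415) {
    m <- make_random_network(5, 7, p_modifier = 0.2, seed = seed,
                             acyclic = FALSE)
    map <- infer_from_reactions(m)
    g <- to_signed_graph(map, include_depletion = TRUE)
    from <- sort(g$nodes$id[g$nodes$kind == "entity"])[[1L]]
    res <- propagate(g, list(list(node = from, direction = "up")))
    expect_lte(res$iterations, 2L * nrow(g$nodes))
  }
})

test_that("adding a perturbation never lowers any node on the lattice", {
  rank <- c(unset = 0, up = 1, down = 1, ambiguous = 2, clamped = 0)
  for (seed in 501:510) {
    m <- make_random_network(6, 6, p_modifier = 0.3, seed = seed)
    map <- infer_from_reactions(m)
    g <- to_signed_graph(map)
    ents <- sort(g$nodes$id[g$nodes$kind == "entity"])
    r1 <- propagate(g, list(list(node = ents[[1L]], direction = "up")))
    r2 <- propagate(g, list(list(node = ents[[1L]], direction = "up"),
                            list(node = ents[[2L]], direction = "down")))
    for (node in g$nodes$id) {
      expect_gte(rank[[r2$states[[node]]]], rank[[r1$states[[node]]]])
    }
  }
})

test_that("path enumeration matches exhaustive search and composes signs", {
  # disconnected nodes yield no paths
  g <- graph_from_edges(data.frame(from = "A", to = "B", sign = 1,
                                   provenance = "x",
                                   stringsAsFactors = FALSE))
  gd <- g
  gd$nodes <- rbind(gd$nodes, data.frame(id = "Z", kind = "entity"))
  expect_length(find_paths(gd, "A", "Z"), 0L)

  # one path with signs (+1, -1) composes to -1
  g2 <- graph_from_edges(data.frame(from = c("A", "B"), to = c("B", "C"),
                                    sign = c(1, -1), provenance = "x",
                                    stringsAsFactors = FALSE))
  r <- find_paths(g2, "A", "C")
  expect_length(r, 1L)
  expect_identical(r[[1]]$sign, -1)
  expect_identical(r[[1]]$path, c("A", "B", "C"))

  # random graphs against igraph's independent enumeration
  for (seed in 601:610) {
    m <- make_random_network(5, 6, p_modifier = 0.2, seed = seed,
                             acyclic = FALSE)
    map <- infer_from_reactions(m)
    g3 <- to_signed_graph(map, include_depletion = TRUE)
    ids <- sort(g3$nodes$id)
    from <- ids[[1L]]; to <- ids[[length(ids)]]
    mine <- find_paths(g3, from, to, max_len = nrow(g3$nodes))
    ig <- physiomapr:::signed_graph_as_igraph(g3)
    ref <- igraph::all_simple_paths(ig, from, to, mode = "out")
    mine_keys <- sort(vapply(mine, function(p) paste(p$path, collapse = ">"),
                             character(1)))
    ref_keys <- sort(vapply(ref, function(p) {
      paste(igraph::as_ids(p), collapse = ">")
    }, character(1)))
    expect_identical(unique(mine_keys), unique(ref_keys),
                     label = paste("paths, seed", seed))
  }
})

test_that("loop polarity equals the parity of negative edges, exhaustively", {
  expect_length(detect_feedback_loops(
    to_signed_graph(infer_from_reactions(make_glycolysis_toy()))), 0L)

  for (len in 2:4) {
    ids <- LETTERS[seq_len(len)]
    combos <- expand.grid(rep(list(c(1, -1)), len))
    for (ci in seq_len(nrow(combos))) {
      signs <- as.numeric(combos[ci, ])
      g <- graph_from_edges(data.frame(
        from = ids, to = c(ids[-1], ids[1]), sign = signs,
        provenance = "x", stringsAsFactors = FALSE))
      loops <- detect_feedback_loops(g)
      expect_length(loops, 1L)
      expected <- if (sum(signs == -1) %% 2 == 0) "positive" else "negative"
      expect_identical(loops[[1]]$polarity, expected,
                       label = paste("cycle length", len, "signs",
                                     paste(signs, collapse = ",")))
      expect_identical(loops[[1]]$nodes[[1]], "A")  # canonical rotation
    }
  }

  # a zero-sign edge makes the loop indeterminate
  g0 <- graph_from_edges(data.frame(from = c("A", "B"), to = c("B", "A"),
                                    sign = c(1, 0), provenance = "x",
                                    stringsAsFactors = FALSE))
  expect_identical(detect_feedback_loops(g0)[[1]]$polarity, "indeterminate")
})
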