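mk_model <- function(edges, nodes = NULL) {
  nodes <- nodes %||% unique(c(edges$from, edges$to))
  structure(list(nodes = nodes,
                 parents = setNames(lapply(nodes, function(v)
                   edges$from[edges$to == v]), nodes),
                 edges = edges), class = "bn_model")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("Markov neighborhood extraction by undirected BFS", {
  star <- mk_model(data.frame(from = "hub", to = paste0("leaf", 1:5),
                              strength = 1:5))
  mn <- extract_mn(star, "hub", 1)
  expect_setequal(mn$members, paste0("leaf", 1:5))

  iso <- mk_model(data.frame(from = "a", to = "b", strength = 1),
                  nodes = c("a", "b", "lone"))
  expect_length(extract_mn(iso, "lone", 1)$members, 0)

  # path a - b - center - c - d at radius 2
  path <- mk_model(data.frame(from = c("a", "b", "center", "c"),
                              to = c("b", "center", "c", "d"),
                              strength = rep(1, 4)))
  expect_setequal(extract_mn(path, "center", 2)$members,
                  c("a", "b", "c", "d"))
  expect_setequal(extract_mn(path, "center", 1)$members, c("b", "c"))
  expect_error(extract_mn(path, "zzz"), "unknown center")
})

test_that("radius-1 neighborhood equals the undirected adjacency", {
  set.seed(41)
  for (rep in 1:5) {
    nodes <- paste0("v", 1:8)
    # random DAG via random order
    ord <- sample(nodes)
    pairs <- t(combn(8, 2))
    keep <- runif(nrow(pairs)) < 0.3
    edges <- data.frame(from = ord[pairs[keep, 1]], to = ord[pairs[keep, 2]],
                        strength = runif(sum(keep)))
    model <- mk_model(edges, nodes)
    center <- sample(nodes, 1)
    adj <- unique(c(edges$to[edges$from == center],
                    edges$from[edges$to == center]))
    expect_setequal(extract_mn(model, center, 1)$members, adj)
  }
})

test_that("KS statistic and p-value behave at the boundaries", {
  x <- c(1.2, 3.4, 2.2, 5.0)
  r <- ks_two_sample(x, x)
  expect_equal(r$D, 0)
  expect_equal(r$p, 1)
  expect_equal(ks_two_sample(c(1, 2, 3), c(4, 5, 6))$D, 1)
  expect_error(ks_two_sample(numeric(0), x), "at least 2")
})

test_that("KS D equals the brute-force ECDF sweep and the stats oracle", {
  set.seed(42)
  for (rep in 1:10) {
    x0 <- rnorm(20); x1 <- rnorm(20, 0.4)
    r <- ks_two_sample(x0, x1)
    expect_equal(r$D, ks_D_oracle(x0, x1))
    expect_equal(r$D,
                 unname(suppressWarnings(stats::ks.test(x0, x1)$statistic)))
  }
})

test_that("two-sided Fisher p matches enumeration and is symmetric", {
  expect_equal(fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2)), 1.0)
  t2 <- matrix(c(3, 1, 1, 3), 2, byrow = TRUE)
  expect_equal(fisher_exact_2x2(t2), fisher_oracle(3, 1, 1, 3))
  expect_equal(fisher_exact_2x2(t2), 0.485714285714, tolerance = 1e-9)
  # transposition and row/column swaps leave p unchanged
  set.seed(43)
  for (rep in 1:20) {
    tb <- matrix(rpois(4, 5), 2)
    p <- fisher_exact_2x2(tb)
    expect_equal(fisher_exact_2x2(t(tb)), p)
    expect_equal(fisher_exact_2x2(tb[2:1, ]), p)
    expect_equal(fisher_exact_2x2(tb[, 2:1]), p)
  }
  expect_warning(p0 <- fisher_exact_2x2(matrix(c(0, 0, 3, 4), 2,
                                               byrow = TRUE)), "margin")
  expect_equal(p0, 1)
})

test_that("posthoc_table tests each member with the right test", {
  ds <- tiny_dataset(g = 8, n = 200, delta = 3, seed = 44)
  members <- c("g1_M", "g2_E", "g3_S", "g4_M", "g5_E", "g6_S", "g7_M")
  edges <- data.frame(from = members, to = "outcome",
                      strength = c(9, 5, 4, 3, 2.5, 2, 1))
  model <- mk_model(edges)
  mn <- extract_mn(model, "outcome", 1)
  rep <- posthoc_table(ds, mn, alpha = 0.05, min_count = 5)

  expect_equal(nrow(rep), 7)                       # one row per member
  expect_true(all(diff(rep$edge_strength) <= 0))   # sorted by strength
  expect_equal(rep$test[rep$modality == "S"][1], "fisher_exact")
  expect_equal(rep$test[rep$modality == "M"][1], "ks_two_sample")
  # g1_M carries a 3-SD shift: overwhelmingly significant
  expect_true(rep$significant[rep$variable == "g1_M"])
  expect_true(all(rep$p_value > 0 & rep$p_value <= 1))
  # significance never co-occurs with exclusion
  expect_false(any(rep$significant & rep$excluded))
})

test_that("low-mutation-count S rows are excluded regardless of p", {
  ds <- tiny_dataset(g = 3, n = 200, seed = 45)
  ds$S["g2", ] <- 0
  ds$S["g2", c(1, 3, 5)] <- 1   # 2 + 1 mutated across the groups
  model <- mk_model(data.frame(from = "g2_S", to = "outcome", strength = 2))
  rep <- posthoc_table(ds, extract_mn(model, "outcome", 1), min_count = 5)
  expect_true(rep$excluded[rep$variable == "g2_S"])
  expect_false(rep$significant[rep$variable == "g2_S"])
  expect_match(rep$exclusion_reason[rep$variable == "g2_S"], "low mutation")
})
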