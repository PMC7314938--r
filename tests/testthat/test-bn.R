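dd_from <- function(mat, card = NULL) {
  card <- card %||% setNames(apply(mat, 1, function(r) max(r) + 1L),
                             rownames(mat))
  discretized_dataset(mat, card)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("BDeu family score matches the Beta-function closed form", {
  # binary child, no parents, counts (3, 1), ess = 1:
  # log[ B(0.5 + 3, 0.5 + 1) / B(0.5, 0.5) ]
  dat <- matrix(c(0L, 0L, 0L, 1L), 1, dimnames = list("x", NULL))
  dd <- dd_from(dat, c(x = 2L))
  expected <- lbeta(3.5, 1.5) - lbeta(0.5, 0.5)
  expect_equal(family_score(dd, "x", cfg = score_config(ess = 1)), expected)

  # row order of the data never matters
  set.seed(31)
  mat <- rbind(x = rbinom(50, 1, 0.4), y = rbinom(50, 2, 0.5))
  dd2 <- dd_from(mat)
  perm <- sample(50)
  dd3 <- dd_from(mat[, perm])
  cfg <- score_config()
  expect_equal(family_score(dd2, "x", "y", cfg),
               family_score(dd3, "x", "y", cfg))

  expect_error(family_score(dd2, "x", "nope", cfg), "unknown")
  expect_error(family_score(dd2, "x", "x", cfg), "own parent")
})

test_that("sparse candidates pick the strongest pairwise partners", {
  set.seed(32)
  x <- rbinom(400, 1, 0.5)
  mat <- rbind(X = x, Y = x, Z = rbinom(400, 1, 0.5))
  dd <- dd_from(mat)
  cand <- sparse_candidates(dd, m = 1)
  expect_equal(cand$X[1], "Y")
  expect_equal(cand$Y[1], "X")
  # m >= p - 1 gives full candidate sets
  cand_full <- sparse_candidates(dd, m = 2)
  expect_setequal(cand_full$Z, c("X", "Y"))
  # symmetric closure: candidacy is mutual
  for (v in names(cand))
    for (u in cand[[v]]) expect_true(v %in% cand[[u]])
})

test_that("independent variables learn an empty graph", {
  set.seed(33)
  mat <- rbind(A = rbinom(2000, 1, 0.5), B = rbinom(2000, 1, 0.3),
               C = rbinom(2000, 1, 0.7))
  model <- learn_structure(dd_from(mat), score_config(seed = 1))
  expect_equal(nrow(model$edges), 0)
})

test_that("score trace is monotone, graph acyclic, score decomposable", {
  dd <- xor_fixture(n = 500, seed = 2)
  cfg <- score_config(seed = 3)
  model <- learn_structure(dd, cfg)
  for (tr in model$traces) expect_true(all(diff(tr) > 0 | length(tr) == 1))
  expect_silent(mmibn:::topo_sort(model$parents))
  expect_equal(network_score(model, dd, cfg), model$log_score)
})

test_that("edge strengths are family-score differences in log10", {
  set.seed(34)
  x <- rbinom(100, 1, 0.5)
  mat <- rbind(X = x, Y = x)  # deterministic copy
  dd <- dd_from(mat)
  cfg <- score_config(seed = 1)
  model <- learn_structure(dd, cfg)
  expect_equal(nrow(model$edges), 1)
  s <- model$edges$strength[1]
  expect_gt(s, 5)
  to <- model$edges$to[1]; from <- model$edges$from[1]
  expect_equal(s, (family_score(dd, to, from, cfg) -
                     family_score(dd, to, character(0), cfg)) / log(10))
  expect_error(edge_strength(model, dd, "nope", to, cfg), "not in model")
})

test_that("DOT export is well-formed and round-trips", {
  set.seed(35)
  mat <- rbind(A = rbinom(200, 1, 0.5), B = rbinom(200, 1, 0.5))
  empty_model <- learn_structure(dd_from(mat), score_config(seed = 1))
  dot <- export_dot(empty_model)
  parsed <- parse_dot(dot)
  expect_setequal(parsed$nodes, c("A", "B"))
  expect_equal(nrow(parsed$edges), 0)

  model <- structure(list(
    nodes = c("A", "B"),
    parents = list(A = character(0), B = "A"),
    edges = data.frame(from = "A", to = "B", strength = 14.131)),
    class = "bn_model")
  dot2 <- export_dot(model)
  expect_match(dot2, "label=\"14.13\"", fixed = TRUE)
  parsed2 <- parse_dot(dot2)
  expect_equal(parsed2$edges$from, "A")
  expect_equal(parsed2$edges$label, 14.13)
})
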