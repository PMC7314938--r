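test_that("mixed_mi tracks the closed-form Gaussian MI", {
  # bivariate normal: I = -0.5 * log(1 - rho^2); modest n here, the
  # tight-tolerance check at n = 5000 lives in the acceptance suite
  set.seed(11)
  n <- 2000; rho <- 0.6
  x <- rnorm(n); y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
  est <- mixed_mi(x, y, discrete_x = FALSE, discrete_y = FALSE)
  expect_lt(abs(est - (-0.5 * log(1 - rho^2))), 0.05)
})

test_that("mixed_mi agrees with plug-in MI for purely discrete data", {
  set.seed(12)
  for (rep in 1:3) {
    n <- 1000
    x <- sample(0:2, n, replace = TRUE)
    y <- ifelse(runif(n) < 0.6, x %% 2, rbinom(n, 1, 0.5))
    est <- mixed_mi(x, y, discrete_x = TRUE)
    expect_lt(abs(est - plugin_mi(x, y)), 0.05)
  }
  # identity case: balanced binary X = y approaches ln 2
  yb <- rep(0:1, 500)
  expect_lt(abs(mixed_mi(yb, yb, discrete_x = TRUE) - log(2)), 0.05)
})

test_that("mixed_mi is deterministic and invariant to order and affine maps", {
  set.seed(13)
  n <- 300
  X <- cbind(rbinom(n, 1, 0.2), rnorm(n), rnorm(n, 5, 3))
  y <- rbinom(n, 1, 0.5)
  flags <- c(TRUE, FALSE, FALSE)
  v <- mixed_mi(X, y, flags)
  expect_identical(v, mixed_mi(X, y, flags))
  perm <- sample(n)
  expect_equal(mixed_mi(X[perm, ], y[perm], flags), v)
  # affine rescaling of a continuous column is absorbed by standardization
  X2 <- X; X2[, 3] <- 7 * X2[, 3] - 100
  expect_equal(mixed_mi(X2, y, flags), v)

  # zero-variance continuous column: warning, treated as constant
  X3 <- X; X3[, 2] <- 1
  expect_warning(v3 <- mixed_mi(X3, y, flags), "zero variance")
  expect_true(is.finite(v3))

  expect_error(mixed_mi(X[1:10, ], y[1:10], flags, mmi_config(k = 10)),
               "k.*smaller")
})

test_that("rank_genes puts a planted gene first and respects gene order", {
  top_rank <- vapply(1:10, function(s) {
    ds <- tiny_dataset(g = 10, n = 300, delta = 2, seed = s)
    tab <- rank_genes(ds)
    which(tab$gene == "g1")
  }, numeric(1))
  expect_gte(sum(top_rank == 1), 6)  # majority of 10 seeds

  ds <- tiny_dataset(g = 6, n = 120, delta = 1, seed = 3)
  tab <- rank_genes(ds)
  dsr <- ds
  rev_idx <- rev(seq_along(ds$genes))
  dsr$genes <- ds$genes[rev_idx]
  dsr$S <- ds$S[rev_idx, ]; dsr$E <- ds$E[rev_idx, ]; dsr$M <- ds$M[rev_idx, ]
  tabr <- rank_genes(dsr)
  expect_equal(tabr[order(tabr$gene), c("gene", "mmi")],
               tab[order(tab$gene), c("gene", "mmi")],
               ignore_attr = TRUE)

  # rank/cdf invariants
  expect_equal(sort(tab$rank), seq_len(nrow(tab)))
  expect_true(all(diff(tab$mmi) <= 0))
  expect_true(all(tab$cdf > 0 & tab$cdf <= 1))
})

test_that("CDF-quantile selection count and boundary-tie handling", {
  tab <- rank_table(paste0("g", 1:1000), seq(1000, 1) / 1000)
  expect_length(select_top_cdf(tab, 0.995)$selected_genes, 5)

  # boundary ties are all included
  scores <- c(10, 9, 8, 8, 8, seq(7, 1, length.out = 95))
  tabt <- rank_table(paste0("g", seq_along(scores)), scores)
  sel <- select_top_cdf(tabt, 0.96)  # m = 4 -> boundary score 8, three ties
  expect_length(sel$selected_genes, 5)

  expect_error(select_top_cdf(tab, 1.2), "q must")
  expect_error(select_top_cdf(tab, 0), "q must")
})

test_that("threshold selection is strict", {
  tab <- rank_table(c("a", "b", "c"), c(0.10, 0.08, 0.01))
  expect_equal(select_by_threshold(tab, 0.08)$selected_genes, "a")
  expect_length(select_by_threshold(tab, max(tab$mmi))$selected_genes, 0)
  expect_setequal(select_by_threshold(tab, -Inf)$selected_genes,
                  c("a", "b", "c"))
})

test_that("jaccard_curve stabilizes at 1 for well-separated planted signal", {
  ds <- tiny_dataset(g = 30, n = 500, delta = 3, seed = 5)
  jc <- jaccard_curve(ds, k_range = 10:14, q = 0.99)  # top-1 selection
  expect_equal(jc$k, 10:13)
  expect_true(all(jc$jaccard >= 0 & jc$jaccard <= 1))
  # delta = 3 SD separates the planted gene at every k: selections agree
  expect_true(all(jc$jaccard == 1))
})
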