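# fixtures and independent oracles, built in code at test time

make_mm <- function(vals, genes, samples, modality = "E") {
  modality_matrix(matrix(vals, length(genes), length(samples),
                         dimnames = list(genes, samples)), modality)
}

# a tiny aligned dataset: g genes, n samples, planted M shift in gene 1
tiny_dataset <- function(g = 4, n = 60, delta = 0, seed = 1) {
  set.seed(seed)
  genes <- paste0("g", seq_len(g))
  samples <- paste0("p", seq_len(n))
  y <- rep(c(0L, 1L), length.out = n)
  M <- matrix(rnorm(g * n), g, n, dimnames = list(genes, samples))
  M[1, ] <- M[1, ] + delta * y
  assemble_dataset(
    make_mm(rbinom(g * n, 1, 0.2), genes, samples, "S"),
    make_mm(rnorm(g * n), genes, samples, "E"),
    modality_matrix(M, "M"),
    setNames(y, samples))
}

clinical_df <- function(...) {
  rows <- list(...)
  data.frame(sample_id = vapply(rows, `[[`, "", 1),
             tumor_status = vapply(rows, `[[`, "", 2),
             vital_status = vapply(rows, `[[`, "", 3),
             survival_days = suppressWarnings(as.numeric(
               vapply(rows, function(r) as.character(r[[4]]), ""))),
             stringsAsFactors = FALSE)
}

# plug-in discrete MI oracle on the contingency table (nats)
plugin_mi <- function(x, y) {
  tab <- table(x, y) / length(x)
  px <- rowSums(tab); py <- colSums(tab)
  e <- outer(px, py)
  pos <- tab > 0
  sum(tab[pos] * log(tab[pos] / e[pos]))
}

# exhaustive DAG enumeration oracle for 3-variable problems:
# every combination of parent sets (4^3 = 64), acyclic ones kept
brute_force_best_score <- function(dd, cfg) {
  vars <- dd$variables
  stopifnot(length(vars) == 3)
  subsets <- function(v) {
    others <- setdiff(vars, v)
    list(character(0), others[1], others[2], others)
  }
  best <- -Inf
  n_dags <- 0
  for (p1 in subsets(vars[1])) for (p2 in subsets(vars[2]))
    for (p3 in subsets(vars[3])) {
      parents <- setNames(list(p1, p2, p3), vars)
      ok <- tryCatch({ mmibn:::topo_sort(parents); TRUE },
                     error = function(e) FALSE)
      if (!ok) next
      n_dags <- n_dags + 1
      sc <- sum(vapply(vars, function(v)
        family_score(dd, v, parents[[v]], cfg), numeric(1)))
      if (sc > best) best <- sc
    }
  list(best = best, n_dags = n_dags)
}

# two-sided Fisher oracle: explicit enumeration with lchoose (no dhyper)
fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  if (r1 == 0 || c1 == 0 || r1 == n || c1 == n) return(1)
  lp <- function(x) lchoose(c1, x) + lchoose(n - c1, r1 - x) - lchoose(n, r1)
  xs <- max(0, r1 + c1 - n):min(r1, c1)
  lps <- vapply(xs, lp, numeric(1))
  sum(exp(lps[lps <= lp(a) + 1e-7]))
}

# brute-force KS D oracle: direct ECDF gap sweep over every sample point
ks_D_oracle <- function(x0, x1) {
  pts <- c(x0, x1)
  max(vapply(pts, function(t)
    abs(mean(x0 <= t) - mean(x1 <= t)), numeric(1)))
}

# XOR collider fixture: biased parents keep the v-structure identifiable
# (fair coins would make all three variables pairwise independent)
xor_fixture <- function(n = 2000, seed = 1, noise = 0.05) {
  cpds <- list(
    X = list(levels = 2, table = c(0.7, 0.3)),
    Y = list(levels = 2, table = c(0.6, 0.4)),
    Z = list(levels = 2, parents = c("X", "Y"),
             table = matrix(c(1 - noise, noise,
                              noise, 1 - noise,
                              noise, 1 - noise,
                              1 - noise, noise), 4, 2, byrow = TRUE)))
  generate_bn_fixture(data.frame(from = c("X", "Y"), to = c("Z", "Z")),
                      cpds, n, seed)
}

chain_fixture <- function(n = 2000, seed = 1) {
  strong <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2, byrow = TRUE)
  cpds <- list(
    X = list(levels = 2, table = c(0.5, 0.5)),
    Y = list(levels = 2, parents = "X", table = strong),
    Z = list(levels = 2, parents = "Y", table = strong))
  generate_bn_fixture(data.frame(from = c("X", "Y"), to = c("Y", "Z")),
                      cpds, n, seed)
}

skeleton_of <- function(model) {
  e <- model$edges
  if (!nrow(e)) return(character(0))
  sort(paste(pmin(e$from, e$to), pmax(e$from, e$to), sep = "--"))
}
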