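#' Specification of a synthetic multimodal cohort
#'
#' Describes a cohort of `n_samples` patients and `n_genes` genes with a
#' binary outcome. Null genes carry standard-normal E and M values
#' independent of the outcome and a sparse Bernoulli S indicator. The first
#' `n_planted` genes carry a planted association through one or more
#' modalities: a mean shift `delta_E` / `delta_M` of the continuous
#' component in outcome class 1, and/or an odds-ratio `gamma_S` on the
#' mutation probability. Optional `inter_gene_edges` induce correlated
#' components through shared latent factors.
#'
#' Continuous components are standard normal rather than, say, beta-shaped
#' methylation fractions: both the MMI estimator and equal-frequency
#' binning are rank-based, so the marginal shape is immaterial to every
#' downstream stage.
#'
#' @param n_samples,n_genes cohort dimensions.
#' @param n_planted number of genes carrying signal (first `n_planted`
#'   gene IDs).
#' @param delta_E,delta_M class-1 mean shifts in SD units (default 0 / 1).
#' @param gamma_S odds ratio on mutation probability in class 1 (default 1).
#' @param s_prevalence null mutation rate (default 0.05, sparse somatic
#'   calls).
#' @param outcome_balance class-1 fraction (default 0.5).
#' @param inter_gene_edges optional data.frame `source`, `target`,
#'   `strength` naming `<gene>_<S|E|M>` components to couple.
#' @param seed RNG seed.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_samples, n_genes, n_planted = 0L,
                           delta_E = 0, delta_M = 1, gamma_S = 1,
                           s_prevalence = 0.05, outcome_balance = 0.5,
                           inter_gene_edges = NULL, seed = 1L) {
  if (n_planted > n_genes) stopf("n_planted exceeds n_genes")
  if (s_prevalence <= 0 || s_prevalence >= 1 ||
      outcome_balance <= 0 || outcome_balance >= 1)
    stopf("rates must lie in (0, 1)")
  if (delta_E < 0 || delta_M < 0) stopf("shifts must be nonnegative")
  if (gamma_S <= 0) stopf("gamma_S must be positive")
  structure(list(n_samples = as.integer(n_samples),
                 n_genes = as.integer(n_genes),
                 n_planted = as.integer(n_planted),
                 delta_E = delta_E, delta_M = delta_M, gamma_S = gamma_S,
                 s_prevalence = s_prevalence,
                 outcome_balance = outcome_balance,
                 inter_gene_edges = inter_gene_edges,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Cohort-scale preset emulating a lower-grade-glioma tumor-status analysis
#'
#' 273 samples by 4782 genes with 5 planted genes, matching the shape of a
#' real cohort-scale run.
#'
#' @param seed RNG seed.
#' @param n_planted planted genes (default 5).
#' @export
lgg_like_spec <- function(seed = 1L, n_planted = 5L) {
  synthetic_spec(n_samples = 273L, n_genes = 4782L, n_planted = n_planted,
                 delta_M = 1, seed = seed)
}

#' Generate a synthetic multi-omics dataset with known ground truth
#'
#' @param spec a [synthetic_spec()].
#' @return list with `dataset` (a `multiomics_dataset`) and `truth` (the
#'   planted genes, their effects, and any induced component couplings).
#'   Fully reproducible from `spec$seed`.
#' @export
generate_multiomics <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)

  n <- spec$n_samples; G <- spec$n_genes; P <- spec$n_planted
  genes <- sprintf("G%04d", seq_len(G))
  samples <- sprintf("P%04d", seq_len(n))
  y <- rbinom(n, 1, spec$outcome_balance)
  # guarantee both classes (tiny cohorts could degenerate)
  if (length(unique(y)) < 2L) y[1:2] <- c(0L, 1L)

  E <- matrix(rnorm(G * n), G, n, dimnames = list(genes, samples))
  M <- matrix(rnorm(G * n), G, n, dimnames = list(genes, samples))
  p_s <- matrix(spec$s_prevalence, G, n)
  if (P > 0) {
    idx <- seq_len(P)
    E[idx, ] <- E[idx, , drop = FALSE] +
      spec$delta_E * matrix(y, P, n, byrow = TRUE)
    M[idx, ] <- M[idx, , drop = FALSE] +
      spec$delta_M * matrix(y, P, n, byrow = TRUE)
    p_s[idx, ] <- plogis(qlogis(spec$s_prevalence) +
                           log(spec$gamma_S) * matrix(y, P, n, byrow = TRUE))
  }
  S <- matrix(rbinom(G * n, 1, as.vector(p_s)), G, n,
              dimnames = list(genes, samples))

  if (!is.null(spec$inter_gene_edges)) {
    ie <- spec$inter_gene_edges
    pick <- function(id) {
      g <- sub("_(S|E|M)$", "", id)
      m <- sub("^.*_(S|E|M)$", "\\1", id)
      if (!g %in% genes || !m %in% c("S", "E", "M"))
        stopf("bad component id '%s' in inter_gene_edges", id)
      list(g = g, m = m)
    }
    for (i in seq_len(nrow(ie))) {
      z <- rnorm(n)            # shared latent factor
      w <- ie$strength[i]
      for (id in c(ie$source[i], ie$target[i])) {
        cp <- pick(id)
        if (cp$m == "S") {
          pr <- plogis(qlogis(spec$s_prevalence) + w * z)
          S[cp$g, ] <- rbinom(n, 1, pr)
        } else {
          mat <- get(cp$m)
          mat[cp$g, ] <- mat[cp$g, ] + w * z
          assign(cp$m, mat)
        }
      }
    }
  }

  ds <- assemble_dataset(modality_matrix(S, "S"), modality_matrix(E, "E"),
                         modality_matrix(M, "M"),
                         setNames(as.integer(y), samples))
  truth <- list(planted_genes = genes[seq_len(P)],
                effects = list(delta_E = spec$delta_E,
                               delta_M = spec$delta_M,
                               gamma_S = spec$gamma_S),
                inter_gene_edges = spec$inter_gene_edges,
                seed = spec$seed)
  list(dataset = ds, truth = truth)
}

#' Sample a discrete dataset from a known Bayesian network
#'
#' Ancestral sampling of `n` records from a DAG with explicit conditional
#' probability tables; used to build fixtures with known structure.
#'
#' @param dag data.frame with columns `from`, `to` (edge list; may have
#'   zero rows).
#' @param cpds named list, one entry per variable: `list(levels = r,
#'   parents = chr, table = matrix)` where `table` has one row per parent
#'   configuration (mixed-radix order, first parent fastest) and one
#'   column per level; rows must sum to 1.
#' @param n number of records.
#' @param seed RNG seed.
#' @return a `discretized_dataset`.
#' @export
generate_bn_fixture <- function(dag, cpds, n, seed = 1L) {
  vars <- names(cpds)
  parents <- setNames(lapply(cpds, function(x) x$parents %||% character(0)),
                      vars)
  for (i in seq_len(nrow(dag)))
    if (!(dag$from[i] %in% parents[[dag$to[i]]]))
      stopf("dag edge %s -> %s has no matching cpd parent",
            dag$from[i], dag$to[i])
  ord <- topo_sort(parents)   # errors on cycles

  for (v in vars) {
    tab <- cpds[[v]]$table
    if (is.null(dim(tab))) tab <- matrix(tab, nrow = 1)
    if (any(abs(rowSums(tab) - 1) > 1e-8))
      stopf("cpd rows for '%s' must sum to 1", v)
    cpds[[v]]$table <- tab
  }

  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  data <- matrix(0L, length(vars), n,
                 dimnames = list(vars, sprintf("r%05d", seq_len(n))))
  card <- setNames(vapply(cpds, function(x) as.integer(x$levels), integer(1)),
                   vars)
  for (v in ord) {
    pa <- parents[[v]]
    tab <- cpds[[v]]$table
    if (!length(pa)) {
      cfg <- rep(1L, n)
    } else {
      cfg <- rep(1L, n); stride <- 1L
      for (p in pa) {
        cfg <- cfg + data[p, ] * stride
        stride <- stride * card[[p]]
      }
    }
    u <- runif(n)
    cum <- t(apply(tab, 1, cumsum))
    data[v, ] <- vapply(seq_len(n), function(i)
      sum(u[i] > cum[cfg[i], ]), numeric(1))
  }
  discretized_dataset(data, card)
}
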