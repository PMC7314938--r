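#' Configuration for BN structure learning
#'
#' @param ess equivalent sample size of the BDeu prior (default 1.0).
#' @param max_parents parent-set size cap (default 4).
#' @param candidates_per_node number of highest-MI partners kept as
#'   candidate neighbours per node before search (default 10).
#' @param restarts number of seeded hill-climbing restarts; the first starts
#'   from the empty graph, the rest from random candidate-pair DAGs
#'   (default 5).
#' @param seed RNG seed making the search deterministic.
#' @return a `score_config` list.
#' @export
score_config <- function(ess = 1.0, max_parents = 4L,
                         candidates_per_node = 10L, restarts = 5L,
                         seed = 1L) {
  if (ess <= 0) stopf("ess must be positive")
  max_parents <- as.integer(max_parents)
  candidates_per_node <- as.integer(candidates_per_node)
  if (candidates_per_node < max_parents)
    stopf("candidates_per_node must be >= max_parents")
  structure(list(ess = ess, max_parents = max_parents,
                 candidates_per_node = candidates_per_node,
                 restarts = as.integer(restarts), seed = as.integer(seed)),
            class = "score_config")
}

#' BDeu family log-score
#'
#' Log marginal likelihood of `child` given a parent set under a uniform-
#' mass Dirichlet prior with equivalent sample size `cfg$ess`: with `q`
#' parent configurations and `r` child levels, cell priors are
#' `ess / (q * r)` and configuration priors `ess / q`. Parent
#' configurations absent from the data contribute zero. Deterministic and
#' row-order invariant.
#'
#' @param dd a `discretized_dataset`.
#' @param child variable name.
#' @param parents character vector of parent variable names (may be empty).
#' @param cfg a [score_config()].
#' @return the family log-score (natural log).
#' @export
family_score <- function(dd, child, parents = character(0),
                         cfg = score_config()) {
  unknown <- setdiff(c(child, parents), dd$variables)
  if (length(unknown))
    stopf("unknown variable(s): %s", paste(unknown, collapse = ", "))
  if (child %in% parents) stopf("child cannot be its own parent")
  if (length(parents) > cfg$max_parents)
    stopf("parent set exceeds max_parents = %d", cfg$max_parents)
  bdeu_family(dd$data, dd$cardinality, child, parents, cfg$ess)
}

# internal fast path: counts by mixed-radix parent-config index
bdeu_family <- function(data, card, child, parents, ess) {
  r <- card[[child]]
  cv <- data[child, ]
  if (length(parents)) {
    q <- prod(card[parents])
    pidx <- rep(0L, ncol(data))
    stride <- 1L
    for (p in parents) {
      pidx <- pidx + data[p, ] * stride
      stride <- stride * card[[p]]
    }
  } else {
    q <- 1L
    pidx <- rep(0L, ncol(data))
  }
  njk <- tabulate(1L + pidx + q * cv, nbins = q * r)
  nj <- .rowSums(njk, q, r)   # njk laid out config-major within level blocks
  a_jk <- ess / (q * r)
  a_j <- ess / q
  occupied <- nj > 0
  sum(lgamma(a_j) - lgamma(a_j + nj[occupied])) +
    sum(lgamma(a_jk + njk[njk > 0]) - lgamma(a_jk))
}

#' Total decomposable score of a network
#'
#' Sum of [family_score()] over all nodes given the model's parent sets.
#'
#' @param model a `bn_model`.
#' @param dd the `discretized_dataset` the model was learned from.
#' @param cfg a [score_config()].
#' @export
network_score <- function(model, dd, cfg = score_config()) {
  sum(vapply(model$nodes, function(v)
    family_score(dd, v, model$parents[[v]], cfg), numeric(1)))
}
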