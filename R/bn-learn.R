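#' Sparse candidate neighbour sets
#'
#' For each variable, keeps the `m` other variables with the highest
#' pairwise plug-in mutual information on the discrete data, then applies
#' the symmetric closure (if a is a candidate of b, b is a candidate of a)
#' so that edge moves are well-defined. Search is later restricted to these
#' pairs.
#'
#' @param dd a `discretized_dataset`.
#' @param m candidates per node.
#' @return named list of character vectors.
#' @export
sparse_candidates <- function(dd, m = 10L) {
  m <- as.integer(m)
  if (m < 1L) stopf("m must be >= 1")
  vars <- dd$variables
  p <- length(vars)
  mi <- matrix(0, p, p, dimnames = list(vars, vars))
  n <- ncol(dd$data)
  for (i in seq_len(p - 1L)) {
    xi <- dd$data[i, ]
    ri <- dd$cardinality[[i]]
    for (j in (i + 1L):p) {
      tab <- tabulate(1L + xi + ri * dd$data[j, ],
                      nbins = ri * dd$cardinality[[j]]) / n
      px <- .rowSums(tab, ri, dd$cardinality[[j]])
      py <- .colSums(tab, ri, dd$cardinality[[j]])
      e <- outer(px, py)
      pos <- tab > 0
      mi[i, j] <- mi[j, i] <- sum(tab[pos] * log(tab[pos] / e[pos]))
    }
  }
  cand <- lapply(seq_len(p), function(i) {
    ord <- order(mi[i, -i], decreasing = TRUE)
    vars[-i][ord][seq_len(min(m, p - 1L))]
  })
  names(cand) <- vars
  # symmetric closure
  for (v in vars)
    for (u in cand[[v]])
      if (!(v %in% cand[[u]])) cand[[u]] <- c(cand[[u]], v)
  cand
}

# DAG helpers on a parents-list representation -------------------------------

has_path <- function(parents, from, to) {
  # TRUE if a directed path from -> ... -> to exists (children direction)
  if (from == to) return(TRUE)
  children <- names(parents)[vapply(parents, function(p) from %in% p, logical(1))]
  seen <- character(0)
  stack <- children
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    if (v == to) return(TRUE)
    if (v %in% seen) next
    seen <- c(seen, v)
    kids <- names(parents)[vapply(parents, function(p) v %in% p, logical(1))]
    stack <- c(stack, setdiff(kids, seen))
  }
  FALSE
}

topo_sort <- function(parents) {
  nodes <- names(parents)
  indeg <- vapply(parents, length, integer(1))
  order <- character(0)
  avail <- nodes[indeg == 0L]
  pa <- parents
  while (length(avail)) {
    v <- avail[[1]]
    avail <- avail[-1]
    order <- c(order, v)
    for (w in nodes)
      if (v %in% pa[[w]]) {
        pa[[w]] <- setdiff(pa[[w]], v)
        if (!length(pa[[w]])) avail <- c(avail, w)
      }
  }
  if (length(order) != length(parents)) stopf("graph contains a cycle")
  order
}

edges_df <- function(parents) {
  from <- character(0); to <- character(0)
  for (v in names(parents))
    if (length(parents[[v]])) {
      from <- c(from, parents[[v]])
      to <- c(to, rep(v, length(parents[[v]])))
    }
  data.frame(from = from, to = to, stringsAsFactors = FALSE)
}

# one steepest-ascent hill climb from a given starting parents list
hill_climb <- function(dd, cand, cfg, parents, fam_cache) {
  eps <- 1e-9
  vars <- dd$variables
  fam <- function(child, pa) {
    key <- paste(child, paste(sort(pa), collapse = ","), sep = "|")
    val <- fam_cache[[key]]
    if (is.null(val)) {
      val <- bdeu_family(dd$data, dd$cardinality, child, pa, cfg$ess)
      fam_cache[[key]] <- val
    }
    val
  }
  score_of <- function(v) fam(v, parents[[v]])
  node_score <- setNames(vapply(vars, score_of, numeric(1)), vars)
  trace <- sum(node_score)

  # ordered candidate pairs (u, v), u != v, within the symmetric closure
  pairs <- do.call(rbind, lapply(vars, function(v)
    if (length(cand[[v]])) cbind(cand[[v]], v) else NULL))

  repeat {
    best <- list(delta = eps)
    for (r in sample.int(nrow(pairs))) {
      u <- pairs[r, 1]; v <- pairs[r, 2]
      pa_v <- parents[[v]]
      if (u %in% pa_v) {
        # delete u -> v
        d <- fam(v, setdiff(pa_v, u)) - node_score[[v]]
        if (d > best$delta) best <- list(delta = d, op = "delete", u = u, v = v)
        # reverse u -> v  (becomes v -> u)
        if (length(parents[[u]]) < cfg$max_parents) {
          parents[[v]] <- setdiff(pa_v, u)
          ok <- !has_path(parents, u, v)
          parents[[v]] <- pa_v
          if (ok) {
            d <- (fam(v, setdiff(pa_v, u)) - node_score[[v]]) +
              (fam(u, c(parents[[u]], v)) - node_score[[u]])
            if (d > best$delta)
              best <- list(delta = d, op = "reverse", u = u, v = v)
          }
        }
      } else if (!(v %in% parents[[u]])) {
        # add u -> v
        if (length(pa_v) < cfg$max_parents && !has_path(parents, v, u)) {
          d <- fam(v, c(pa_v, u)) - node_score[[v]]
          if (d > best$delta) best <- list(delta = d, op = "add", u = u, v = v)
        }
      }
    }
    if (is.null(best$op)) break
    u <- best$u; v <- best$v
    if (best$op == "add") {
      parents[[v]] <- c(parents[[v]], u)
    } else if (best$op == "delete") {
      parents[[v]] <- setdiff(parents[[v]], u)
    } else {
      parents[[v]] <- setdiff(parents[[v]], u)
      parents[[u]] <- c(parents[[u]], v)
      node_score[[u]] <- fam(u, parents[[u]])
    }
    node_score[[v]] <- fam(v, parents[[v]])
    trace <- c(trace, sum(node_score))
  }
  list(parents = parents, score = sum(node_score), trace = trace)
}

#' Learn a Bayesian network structure
#'
#' Greedy steepest-ascent search over edge additions, deletions and
#' reversals, restricted to the sparse candidate pairs and `max_parents`,
#' under the BDeu score, with acyclicity maintained at every move. The
#' search runs `cfg$restarts` times - first from the empty graph, then from
#' random candidate-pair DAG seeds - and returns the best-scoring result.
#' Deterministic given `cfg$seed`.
#'
#' @param dd a `discretized_dataset` with at least 2 variables and 10
#'   samples.
#' @param cfg a [score_config()].
#' @return a `bn_model`: list with `nodes`, `parents` (named list),
#'   `edges` (data.frame `from`, `to`, `strength` in log10), `log_score`,
#'   `traces` (per-restart monotone score traces), `config`.
#' @export
learn_structure <- function(dd, cfg = score_config()) {
  stopifnot(inherits(dd, "discretized_dataset"))
  if (length(dd$variables) < 2L) stopf("need at least 2 variables")
  if (ncol(dd$data) < 10L) stopf("need at least 10 samples")
  vars <- dd$variables
  cand <- sparse_candidates(dd, cfg$candidates_per_node)
  fam_cache <- new.env(parent = emptyenv())

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(cfg$seed)

  empty <- setNames(lapply(vars, function(v) character(0)), vars)
  best <- NULL
  traces <- list()
  for (r in seq_len(max(1L, cfg$restarts))) {
    start <- empty
    if (r > 1L) {
      # random DAG seed: random order, candidate pairs added with prob 0.25
      ord <- sample(vars)
      pos <- setNames(seq_along(ord), ord)
      for (v in vars) {
        ups <- cand[[v]][pos[cand[[v]]] < pos[[v]]]
        ups <- ups[runif(length(ups)) < 0.25]
        start[[v]] <- head(ups, cfg$max_parents)
      }
    }
    res <- hill_climb(dd, cand, cfg, start, fam_cache)
    traces[[r]] <- res$trace
    if (is.null(best) || res$score > best$score) best <- res
  }

  model <- structure(
    list(nodes = vars, parents = best$parents, edges = edges_df(best$parents),
         log_score = best$score, traces = traces, config = cfg),
    class = "bn_model")
  model$edges$strength <- vapply(seq_len(nrow(model$edges)), function(i)
    edge_strength(model, dd, model$edges$from[i], model$edges$to[i], cfg),
    numeric(1))
  model
}

#' Edge strength as a log10 Bayes factor
#'
#' Score ratio between the learned model and the same model with one edge
#' deleted; by decomposability this is the child's family-score difference,
#' reported in log10 units (larger means stronger dependence).
#'
#' @param model a `bn_model`.
#' @param dd the `discretized_dataset` used for learning.
#' @param from,to edge endpoints (`from -> to` must be in the model).
#' @param cfg a [score_config()].
#' @export
edge_strength <- function(model, dd, from, to, cfg = score_config()) {
  if (!(from %in% model$parents[[to]]))
    stopf("edge %s -> %s not in model", from, to)
  (family_score(dd, to, model$parents[[to]], cfg) -
     family_score(dd, to, setdiff(model$parents[[to]], from), cfg)) / log(10)
}

#' @export
print.bn_model <- function(x, ...) {
  cat(sprintf("<bn_model: %d nodes, %d edges, log-score %.2f>\n",
              length(x$nodes), nrow(x$edges), x$log_score))
  invisible(x)
}
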