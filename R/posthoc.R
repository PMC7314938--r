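#' Markov neighborhood of a node
#'
#' Nodes within `radius` undirected steps of `center` (direction ignored),
#' with the induced edges and their strengths. Radius 1 is the usual
#' surrogate for the Markov blanket; radius 2 covers cases where one
#' degree of separation does not encapsulate the variable of interest.
#'
#' @param model a `bn_model`.
#' @param center variable name (typically the clinical outcome node).
#' @param radius 1 or 2.
#' @return a `markov_neighborhood`: list with `center`, `radius`,
#'   `members`, `induced_edges`.
#' @export
extract_mn <- function(model, center, radius = 1L) {
  if (!(center %in% model$nodes)) stopf("unknown center '%s'", center)
  radius <- as.integer(radius)
  if (!radius %in% c(1L, 2L)) stopf("radius must be 1 or 2")
  edges <- model$edges
  frontier <- center
  members <- character(0)
  for (step in seq_len(radius)) {
    nb <- c(edges$to[edges$from %in% frontier],
            edges$from[edges$to %in% frontier])
    frontier <- setdiff(unique(nb), c(members, center))
    members <- union(members, frontier)
  }
  keep <- edges$from %in% c(center, members) & edges$to %in% c(center, members)
  structure(list(center = center, radius = radius, members = members,
                 induced_edges = edges[keep, , drop = FALSE]),
            class = "markov_neighborhood")
}

#' @export
print.markov_neighborhood <- function(x, ...) {
  cat(sprintf("<markov_neighborhood of '%s' (radius %d): %d members>\n",
              x$center, x$radius, length(x$members)))
  invisible(x)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the supremum gap between the two empirical CDFs; the p-value comes
#' from the asymptotic Kolmogorov distribution evaluated at the effective
#' sample size `n0 * n1 / (n0 + n1)` (with the standard small-sample
#' continuity adjustment). Suitable for group sizes in the tens to
#' hundreds; no exact small-sample p is computed.
#'
#' @param x0,x1 numeric vectors (length >= 2 each).
#' @return list with `D` and `p`.
#' @export
ks_two_sample <- function(x0, x1) {
  n0 <- length(x0); n1 <- length(x1)
  if (n0 < 2L || n1 < 2L) stopf("both groups need at least 2 observations")
  if (anyNA(x0) || anyNA(x1)) stopf("missing values")
  pts <- c(x0, x1)
  D <- max(abs(ecdf(x0)(pts) - ecdf(x1)(pts)))
  ne <- n0 * n1 / (n0 + n1)
  lambda <- (sqrt(ne) + 0.12 + 0.11 / sqrt(ne)) * D
  j <- seq_len(101)
  p <- 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * lambda^2))
  list(D = D, p = min(max(p, 0), 1))
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact two-sided p: the sum of hypergeometric probabilities, over all
#' tables with the observed margins, of tables no more probable than the
#' observed one. A zero margin gives p = 1 with a warning.
#'
#' @param tab 2x2 matrix of nonnegative integer counts.
#' @return the two-sided p-value.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == 2L) || any(tab < 0) || any(tab != round(tab)))
    stopf("tab must be a 2x2 matrix of nonnegative integers")
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  if (r1 == 0 || c1 == 0 || r1 == n || c1 == n) {
    warnf("degenerate margin; p = 1")
    return(1)
  }
  lo <- max(0, r1 + c1 - n); hi <- min(r1, c1)
  xs <- lo:hi
  pr <- dhyper(xs, c1, n - c1, r1)
  # relative tolerance guards against ties broken by floating-point noise
  sum(pr[pr <= pr[xs == a] * (1 + 1e-7)])
}

#' Post-hoc statistics for a Markov neighborhood
#'
#' The Table-1-style report: every molecular member of the neighborhood is
#' tested for a marginal difference between the two outcome groups - a
#' two-sample KS test on the continuous E/M values, a two-sided Fisher
#' exact test on the binary S indicator. S rows whose mutated-sample count
#' is below `min_count` in both outcome groups are flagged excluded (too
#' few mutations for the test to mean anything), mirroring the low-count
#' exclusion rule. Rows are ordered by descending edge strength; a
#' Benjamini-Hochberg column is included for transparency although the
#' significance flag uses the unadjusted p.
#'
#' @param ds the `multiomics_dataset` holding the original (continuous)
#'   values.
#' @param mn a `markov_neighborhood` whose members are `<gene>_<S|E|M>`
#'   variables.
#' @param alpha significance level (default 0.05).
#' @param min_count low-count exclusion threshold for S rows (default 5).
#' @return a `posthoc_report` data.frame with columns `variable`, `gene`,
#'   `modality`, `edge_strength`, `test`, `p_value`, `p_adjusted`,
#'   `p_display`, `significant`, `excluded`, `exclusion_reason`.
#' @export
posthoc_table <- function(ds, mn, alpha = 0.05, min_count = 5L) {
  stopifnot(inherits(ds, "multiomics_dataset"),
            inherits(mn, "markov_neighborhood"))
  members <- setdiff(mn$members, ds$outcome_name)
  mol <- grepl("_(S|E|M)$", members)
  if (!all(mol))
    stopf("members not of the form <gene>_<S|E|M>: %s",
          paste(members[!mol], collapse = ", "))
  gene <- sub("_(S|E|M)$", "", members)
  modality <- sub("^.*_(S|E|M)$", "\\1", members)
  missing <- !mapply(function(g, m) g %in% rownames(ds[[m]]), gene, modality)
  if (any(missing))
    stopf("genes absent from dataset: %s",
          paste(unique(gene[missing]), collapse = ", "))

  # strength of the edge linking the member to the neighborhood
  e <- mn$induced_edges
  strength <- vapply(members, function(v) {
    s <- e$strength[(e$from == v & e$to == mn$center) |
                      (e$to == v & e$from == mn$center)]
    if (!length(s)) s <- e$strength[e$from == v | e$to == v]
    if (length(s)) max(s) else NA_real_
  }, numeric(1))

  y <- ds$outcome
  rows <- lapply(seq_along(members), function(i) {
    g <- gene[i]; m <- modality[i]
    if (m == "S") {
      s <- ds$S[g, ]
      tab <- matrix(c(sum(s == 1 & y == 1), sum(s == 1 & y == 0),
                      sum(s == 0 & y == 1), sum(s == 0 & y == 0)),
                    2, byrow = TRUE)
      p <- withCallingHandlers(fisher_exact_2x2(tab),
                               warning = function(w) invokeRestart("muffleWarning"))
      low <- tab[1, 1] < min_count && tab[1, 2] < min_count
      data.frame(variable = members[i], gene = g, modality = m,
                 edge_strength = strength[i], test = "fisher_exact",
                 p_value = p, excluded = low,
                 exclusion_reason = if (low) "low mutation count in both groups"
                                    else NA_character_,
                 stringsAsFactors = FALSE)
    } else {
      ks <- ks_two_sample(ds[[m]][g, y == 0], ds[[m]][g, y == 1])
      data.frame(variable = members[i], gene = g, modality = m,
                 edge_strength = strength[i], test = "ks_two_sample",
                 p_value = ks$p, excluded = FALSE,
                 exclusion_reason = NA_character_,
                 stringsAsFactors = FALSE)
    }
  })
  rep <- do.call(rbind, rows)
  rep <- rep[order(-rep$edge_strength), , drop = FALSE]
  rep$p_adjusted <- stats::p.adjust(rep$p_value, method = "BH")
  rep$p_display <- ifelse(rep$p_value >= 0.995, "~1.0",
                          formatC(rep$p_value, format = "g", digits = 4))
  rep$significant <- rep$p_value < alpha & !rep$excluded
  rownames(rep) <- NULL
  rep <- rep[, c("variable", "gene", "modality", "edge_strength", "test",
                 "p_value", "p_adjusted", "p_display", "significant",
                 "excluded", "exclusion_reason")]
  class(rep) <- c("posthoc_report", "data.frame")
  rep
}

#' Write a post-hoc report as TSV
#' @param rep a `posthoc_report`.
#' @param path output path.
#' @export
write_posthoc <- function(rep, path) {
  data.table::fwrite(as.data.frame(rep), path, sep = "\t")
  invisible(path)
}
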