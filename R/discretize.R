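#' Maximum-entropy (equal-frequency) discretization
#'
#' Bins a continuous vector into `bins` classes at empirical quantile
#' boundaries, the split that maximizes the marginal entropy of the binned
#' variable. Boundaries sit at the `ceiling(n * i / bins)`-th order
#' statistics; a value equal to a boundary falls in the lower bin, so the
#' label is a function of the value alone and tied values always share a
#' label (ties may unbalance the bins, which is reported as a warning).
#'
#' @param x numeric vector (length >= bins).
#' @param bins number of bins (default 3).
#' @return list with `labels` (integers `0 .. bins-1`) and `edges` (the
#'   `bins - 1` interior boundaries).
#' @examples
#' me_discretize(1:9)$labels   # occupancies 3/3/3
#' @export
me_discretize <- function(x, bins = 3L) {
  bins <- as.integer(bins)
  n <- length(x)
  if (n < bins) stopf("need at least %d values for %d bins", bins, bins)
  if (anyNA(x) || any(!is.finite(x))) stopf("non-finite values")
  if (max(x) == min(x)) stopf("constant vector cannot be discretized")
  xs <- sort(x)
  edges <- xs[ceiling(n * seq_len(bins - 1L) / bins)]
  labels <- rowSums(outer(x, edges, ">"))
  occ <- tabulate(labels + 1L, nbins = bins)
  if (max(occ) - min(occ) > 1L)
    warnf("ties unbalance the bins (occupancies %s)",
          paste(occ, collapse = "/"))
  list(labels = as.integer(labels), edges = edges)
}

#' Expand selected genes into discrete S/E/M nodes
#'
#' Each selected gene contributes three variables named `<gene>_S`,
#' `<gene>_E`, `<gene>_M`: the binary S indicator passes through and the
#' continuous E and M components are binned by [me_discretize()] into three
#' levels. The binary outcome is appended as the final variable, so the
#' result has `3 * |selected| + 1` variables.
#'
#' @param ds a `multiomics_dataset`.
#' @param selected character vector of genes (subset of `ds$genes`), e.g.
#'   `selection_result$selected_genes`.
#' @param bins bins for the continuous components (default 3).
#' @return a `discretized_dataset`: list with `variables`, `cardinality`
#'   (named integer vector), `data` (variable x sample integer matrix,
#'   values in `0 .. cardinality-1`), `bin_edges`, `outcome_name`.
#' @export
discretize_dataset <- function(ds, selected, bins = 3L) {
  stopifnot(inherits(ds, "multiomics_dataset"))
  if (inherits(selected, "selection_result"))
    selected <- selected$selected_genes
  bad <- setdiff(selected, ds$genes)
  if (length(bad))
    stopf("selected genes not in dataset: %s", paste(bad, collapse = ", "))
  if (!length(selected)) stopf("empty selection")

  nvar <- 3L * length(selected) + 1L
  vars <- character(nvar)
  card <- integer(nvar)
  dat <- matrix(0L, nvar, length(ds$samples))
  edges <- list()
  i <- 0L
  for (g in selected) {
    for (comp in c("S", "E", "M")) {
      i <- i + 1L
      vars[i] <- paste0(g, "_", comp)
      if (comp == "S") {
        dat[i, ] <- as.integer(ds$S[g, ])
        card[i] <- 2L
      } else {
        d <- tryCatch(me_discretize(ds[[comp]][g, ], bins),
                      error = function(e)
                        stopf("%s_%s: %s", g, comp, conditionMessage(e)))
        dat[i, ] <- d$labels
        card[i] <- bins
        edges[[vars[i]]] <- d$edges
      }
    }
  }
  i <- i + 1L
  vars[i] <- ds$outcome_name
  dat[i, ] <- as.integer(ds$outcome)
  card[i] <- 2L
  rownames(dat) <- vars
  colnames(dat) <- ds$samples
  structure(list(variables = vars, cardinality = setNames(card, vars),
                 data = dat, bin_edges = edges,
                 outcome_name = ds$outcome_name),
            class = "discretized_dataset")
}

#' Construct a discretized dataset from an integer matrix
#'
#' Low-level constructor used by the network fixtures: `data` is a
#' variable-by-sample integer matrix with values in `0 .. cardinality-1`.
#'
#' @param data integer matrix with variable rownames.
#' @param cardinality named integer vector of level counts.
#' @param outcome_name optional name of the outcome variable.
#' @export
discretized_dataset <- function(data, cardinality, outcome_name = NULL) {
  stopifnot(is.matrix(data), !is.null(rownames(data)))
  storage.mode(data) <- "integer"
  vars <- rownames(data)
  cardinality <- cardinality[vars]
  if (anyNA(cardinality)) stopf("cardinality must cover every variable")
  for (v in vars)
    if (any(data[v, ] < 0L | data[v, ] >= cardinality[v]))
      stopf("variable '%s' has values outside 0..%d", v, cardinality[v] - 1L)
  structure(list(variables = vars, cardinality = cardinality, data = data,
                 bin_edges = list(), outcome_name = outcome_name),
            class = "discretized_dataset")
}

#' @export
print.discretized_dataset <- function(x, ...) {
  cat(sprintf("<discretized_dataset: %d variables x %d samples>\n",
              nrow(x$data), ncol(x$data)))
  invisible(x)
}

#' Read a discretized dataset written by [write_discretized()]
#' @param path TSV path (the `<path>.json` sidecar must sit next to it).
#' @export
read_discretized <- function(path) {
  dt <- data.table::fread(path, header = TRUE, colClasses = list(character = 1))
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  dat <- as.matrix(dt[, -1, drop = FALSE])
  rownames(dat) <- dt[[1]]
  discretized_dataset(dat, unlist(side$cardinality),
                      outcome_name = side$outcome)
}

#' Write a discretized dataset (TSV + JSON bin-edge sidecar)
#' @param dd a `discretized_dataset`.
#' @param path output TSV path; the sidecar is written at `<path>.json`.
#' @export
write_discretized <- function(dd, path) {
  dt <- data.table::data.table(variable = dd$variables)
  dt <- cbind(dt, data.table::as.data.table(dd$data))
  data.table::fwrite(dt, path, sep = "\t")
  jsonlite::write_json(
    list(cardinality = as.list(dd$cardinality),
         bin_edges = dd$bin_edges,
         outcome = dd$outcome_name),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
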