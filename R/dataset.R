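#' Assemble an aligned multi-omics dataset
#'
#' Restricts the three modality matrices and the outcome to their common
#' genes and samples, enforcing identical orderings. Genes with any
#' non-finite value in a continuous modality are dropped (complete-case per
#' gene); the assembly log records every dropped gene and sample.
#'
#' @param S,E,M [modality_matrix()] objects of the matching modalities.
#' @param outcome an `outcome_vector` (see [encode_tumor_status()],
#'   [dichotomize_survival()]).
#' @return a `multiomics_dataset`: list with `genes`, `samples`, `S`, `E`,
#'   `M` (aligned matrices), `outcome` (0/1 integer vector named by sample)
#'   `outcome_name`, and `log`.
#' @export
assemble_dataset <- function(S, E, M, outcome) {
  mods <- list(S = S, E = E, M = M)
  for (nm in names(mods)) {
    if (!inherits(mods[[nm]], "modality_matrix") || modality(mods[[nm]]) != nm)
      stopf("argument %s must be a modality_matrix of modality %s", nm, nm)
    if (!nrow(mods[[nm]]) || !ncol(mods[[nm]])) stopf("%s matrix is empty", nm)
  }
  if (inherits(outcome, "outcome_vector")) {
    olabels <- setNames(outcome$labels, outcome$sample_ids)
    oname <- outcome$name
  } else {
    if (is.null(names(outcome))) stopf("outcome must be named by sample ID")
    olabels <- outcome
    oname <- "outcome"
  }
  genes <- Reduce(intersect, lapply(mods, rownames))
  samples <- Reduce(intersect, c(lapply(mods, colnames), list(names(olabels))))
  if (!length(genes)) stopf("no genes shared by the three modalities")
  if (!length(samples)) stopf("no samples shared by modalities and outcome")

  sub <- lapply(mods, function(m) unclass(m)[genes, samples, drop = FALSE])
  ok <- is.finite(sub$E) & is.finite(sub$M) & is.finite(sub$S)
  keep_gene <- rowSums(!ok) == 0L
  dropped_genes <- genes[!keep_gene]
  genes <- genes[keep_gene]
  if (!length(genes)) stopf("no complete-case genes left after assembly")
  sub <- lapply(sub, function(m) m[genes, , drop = FALSE])

  y <- as.integer(olabels[samples])
  if (length(unique(y)) < 2L)
    stopf("outcome has a single class after sample intersection")
  if (min(table(y)) < 2L)
    stopf("fewer than 2 samples in one outcome class")

  all_genes <- unique(c(unlist(lapply(mods, rownames))))
  all_samples <- unique(c(unlist(lapply(mods, colnames)), names(olabels)))
  structure(
    list(genes = genes, samples = samples,
         S = sub$S, E = sub$E, M = sub$M,
         outcome = setNames(y, samples), outcome_name = oname,
         log = list(
           n_genes = length(genes), n_samples = length(samples),
           dropped_genes = sort(setdiff(all_genes, genes)),
           dropped_samples = sort(setdiff(all_samples, samples)),
           incomplete_genes = dropped_genes)),
    class = "multiomics_dataset")
}

#' @export
print.multiomics_dataset <- function(x, ...) {
  cat(sprintf(
    "<multiomics_dataset: %d genes x %d samples, outcome '%s' (%d/%d)>\n",
    length(x$genes), length(x$samples), x$outcome_name,
    sum(x$outcome == 1L), sum(x$outcome == 0L)))
  invisible(x)
}

#' Re-wrap an assembled dataset's matrices as modality matrices
#' @noRd
dataset_modality <- function(ds, which = c("S", "E", "M")) {
  which <- match.arg(which)
  modality_matrix(ds[[which]], which)
}
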