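#' Modality matrix (gene x sample) for one molecular data type
#'
#' A `modality_matrix` is a numeric gene-by-sample matrix tagged with its
#' modality: `"S"` (binary somatic-mutation indicator), `"E"` (continuous
#' mRNA expression) or `"M"` (continuous promoter methylation). Gene and
#' sample identifiers must be unique; `S` entries are restricted to 0/1 and
#' `E`/`M` entries must be finite.
#'
#' @param values numeric matrix with gene rownames and sample colnames.
#' @param modality one of `"S"`, `"E"`, `"M"`.
#' @return a `modality_matrix` object (a validated matrix with a `modality`
#'   attribute).
#' @examples
#' m <- modality_matrix(matrix(rnorm(6), 3, 2,
#'   dimnames = list(c("g1", "g2", "g3"), c("p1", "p2"))), "E")
#' modality(m)
#' @export
modality_matrix <- function(values, modality = c("S", "E", "M")) {
  modality <- match.arg(modality)
  if (!is.matrix(values) || !is.numeric(values))
    stopf("values must be a numeric matrix")
  genes <- rownames(values)
  samples <- colnames(values)
  if (is.null(genes) || is.null(samples))
    stopf("values must carry gene rownames and sample colnames")
  dup_g <- unique(genes[duplicated(genes)])
  if (length(dup_g))
    stopf("duplicate gene IDs: %s", paste(dup_g, collapse = ", "))
  dup_s <- unique(samples[duplicated(samples)])
  if (length(dup_s))
    stopf("duplicate sample IDs: %s", paste(dup_s, collapse = ", "))
  if (anyNA(values) || any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    stopf("non-finite value at gene '%s', sample '%s'",
          genes[bad[1]], samples[bad[2]])
  }
  if (modality == "S") {
    # any nonzero call collapses to presence
    values[] <- as.numeric(values != 0)
  }
  structure(values, modality = modality, class = c("modality_matrix", "matrix"))
}

#' @rdname modality_matrix
#' @param x a `modality_matrix`.
#' @export
modality <- function(x) attr(x, "modality")

#' @export
print.modality_matrix <- function(x, ...) {
  cat(sprintf("<modality_matrix %s: %d genes x %d samples>\n",
              modality(x), nrow(x), ncol(x)))
  print(utils::head(unclass(x)[, seq_len(min(ncol(x), 6)), drop = FALSE], 4))
  invisible(x)
}

#' Read a delimited gene-by-sample matrix
#'
#' Expects a header row of sample IDs and a first column of gene IDs;
#' TSV or CSV is auto-detected. Non-numeric cells and duplicated IDs are
#' hard errors with coordinates.
#'
#' @param path file path.
#' @inheritParams modality_matrix
#' @return a [modality_matrix()].
#' @export
read_modality <- function(path, modality = c("S", "E", "M")) {
  modality <- match.arg(modality)
  dt <- data.table::fread(path, header = TRUE, colClasses = list(character = 1))
  if (ncol(dt) < 2) stopf("'%s': no sample columns", path)
  genes <- dt[[1]]
  vals <- as.matrix(dt[, -1, drop = FALSE])
  if (is.character(vals)) {
    num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals)))
    bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
    if (nrow(bad))
      stopf("'%s': non-numeric cell at gene '%s', sample '%s' (value '%s')",
            path, genes[bad[1, 1]], colnames(dt)[-1][bad[1, 2]],
            vals[bad[1, 1], bad[1, 2]])
    vals <- num
  }
  storage.mode(vals) <- "double"
  rownames(vals) <- genes
  colnames(vals) <- colnames(dt)[-1]
  modality_matrix(vals, modality)
}

#' Write a modality matrix as TSV
#'
#' Round-trips with [read_modality()] to full printed precision.
#'
#' @param x a `modality_matrix`.
#' @param path output path.
#' @export
write_modality <- function(x, path) {
  dt <- data.table::data.table(gene = rownames(x))
  dt <- cbind(dt, data.table::as.data.table(unclass(x)))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Binarize somatic mutation calls
#'
#' Collapses a per-call table into the binary S matrix: `S[g, s] = 1` iff
#' sample `s` carries at least one non-synonymous call in gene `g`.
#' Synonymous-only calls and absent pairs yield 0.
#'
#' @param calls data.frame with columns `sample_id`, `gene_id`,
#'   `nonsynonymous` (logical).
#' @param genes,samples gene and sample universes for the output matrix.
#' @return a [modality_matrix()] of modality `"S"`.
#' @export
binarize_somatic <- function(calls, genes, samples) {
  need <- c("sample_id", "gene_id", "nonsynonymous")
  if (!all(need %in% names(calls)))
    stopf("calls must have columns %s", paste(need, collapse = ", "))
  vals <- matrix(0, length(genes), length(samples),
                 dimnames = list(genes, samples))
  keep <- calls$nonsynonymous &
    calls$gene_id %in% genes & calls$sample_id %in% samples
  if (any(keep))
    vals[cbind(match(calls$gene_id[keep], genes),
               match(calls$sample_id[keep], samples))] <- 1
  modality_matrix(vals, "S")
}
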