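#' Read a clinical table
#'
#' Delimited text with columns `sample_id`, `tumor_status`, `vital_status`,
#' `survival_days`. Missing survival days may be empty or NA.
#'
#' @param path file path.
#' @return data.frame of clinical records.
#' @export
read_clinical <- function(path) {
  dt <- data.table::fread(path, header = TRUE,
                          colClasses = list(character = 1:3))
  need <- c("sample_id", "tumor_status", "vital_status", "survival_days")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stopf("clinical table '%s' lacks columns: %s", path,
          paste(miss, collapse = ", "))
  out <- as.data.frame(dt[, need, with = FALSE])
  out$survival_days <- suppressWarnings(as.numeric(out$survival_days))
  if (any(out$sample_id == "" | is.na(out$sample_id)))
    stopf("clinical table has empty sample IDs")
  out
}

new_outcome_vector <- function(name, sample_ids, labels, excluded) {
  stopifnot(all(labels %in% c(0L, 1L)))
  if (length(intersect(sample_ids, excluded$sample_id)))
    stopf("internal: sample both labeled and excluded")
  degenerate <- length(unique(labels)) < 2L
  structure(
    list(name = name, sample_ids = sample_ids,
         labels = as.integer(labels),
         excluded = excluded, degenerate = degenerate),
    class = "outcome_vector")
}

#' @export
print.outcome_vector <- function(x, ...) {
  cat(sprintf("<outcome_vector '%s': %d labeled (%d/%d), %d excluded%s>\n",
              x$name, length(x$labels), sum(x$labels == 1L),
              sum(x$labels == 0L), nrow(x$excluded),
              if (x$degenerate) ", DEGENERATE" else ""))
  invisible(x)
}

norm_label <- function(x) gsub("[^a-z]", "", tolower(x))

#' Dichotomize survival at a fixed cutoff
#'
#' Encodes the two-year survival outcome: patients who died before
#' `cutoff_days` are high-risk (label 1); anyone, dead or living, with
#' follow-up of at least `cutoff_days` is low-risk (label 0). Patients
#' recorded living with follow-up shorter than the cutoff carry no label
#' ("insufficient follow-up"); missing status or days excludes the record
#' ("no survival status").
#'
#' @param records clinical data.frame as from [read_clinical()].
#' @param cutoff_days dichotomy point in days; default 730 (two years).
#' @return an `outcome_vector` named `"survival2y"`.
#' @export
dichotomize_survival <- function(records, cutoff_days = 730) {
  if (!nrow(records)) stopf("no clinical records")
  days <- records$survival_days
  if (any(days < 0, na.rm = TRUE)) stopf("negative survival days")
  vital <- norm_label(records$vital_status)
  dead <- vital %in% c("dead", "deceased")
  living <- vital %in% c("alive", "living")
  lab <- rep(NA_integer_, nrow(records))
  reason <- rep(NA_character_, nrow(records))
  known <- (dead | living) & !is.na(days)
  reason[!known] <- "no survival status"
  lab[known & days >= cutoff_days] <- 0L
  lab[known & dead & days < cutoff_days] <- 1L
  short_living <- known & living & days < cutoff_days
  reason[short_living] <- "insufficient follow-up"
  keep <- !is.na(lab)
  new_outcome_vector(
    "survival2y",
    sample_ids = records$sample_id[keep],
    labels = lab[keep],
    excluded = data.frame(sample_id = records$sample_id[!keep],
                          reason = reason[!keep],
                          stringsAsFactors = FALSE))
}

#' Encode tumor status as a binary outcome
#'
#' Case- and punctuation-insensitive match: "with tumor" maps to 1,
#' "tumor free"/"tumor-free" to 0; anything else (empty, "unknown", ...)
#' excludes the record.
#'
#' @inheritParams dichotomize_survival
#' @return an `outcome_vector` named `"tumor_status"`.
#' @export
encode_tumor_status <- function(records) {
  if (!nrow(records)) stopf("no clinical records")
  st <- norm_label(records$tumor_status)
  lab <- rep(NA_integer_, nrow(records))
  lab[st == "withtumor"] <- 1L
  lab[st == "tumorfree"] <- 0L
  keep <- !is.na(lab)
  new_outcome_vector(
    "tumor_status",
    sample_ids = records$sample_id[keep],
    labels = lab[keep],
    excluded = data.frame(
      sample_id = records$sample_id[!keep],
      reason = rep("ambiguous or missing tumor status", sum(!keep)),
      stringsAsFactors = FALSE))
}
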