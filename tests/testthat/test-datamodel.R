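test_that("modality matrices round-trip through TSV and enforce invariants", {
  m <- make_mm(c(0.123456789, -2.5, 3.14159, 1e-8, 42, 0), paste0("g", 1:3),
               c("s1", "s2"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_modality(m, path)
  back <- read_modality(path, "E")
  expect_equal(unclass(back), unclass(m))

  # S entries normalize to presence/absence
  s <- make_mm(c(0, 2, 5, 1), c("a", "b"), c("s1", "s2"), "S")
  expect_true(all(unclass(s) %in% c(0, 1)))
  expect_equal(unclass(s)["b", "s1"], 1)

  # duplicate gene IDs are a hard error naming the gene
  bad <- matrix(1:4, 2, 2, dimnames = list(c("TP53", "TP53"), c("s1", "s2")))
  expect_error(modality_matrix(bad, "E"), "TP53")

  # non-numeric cell errors with coordinates
  pnum <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1\ts2", "g1\t1.5\toops", "g2\t2\t3"), pnum)
  expect_error(read_modality(pnum, "E"), "g1.*s2|s2.*g1")
})

test_that("binarize_somatic applies the >=1 non-synonymous rule", {
  calls <- data.frame(
    sample_id = c("P1", "P1", "P1", "P2", "P2"),
    gene_id = c("KRAS", "KRAS", "KRAS", "KRAS", "TP53"),
    nonsynonymous = c(TRUE, TRUE, TRUE, FALSE, TRUE))
  S <- binarize_somatic(calls, genes = c("KRAS", "TP53"),
                        samples = c("P1", "P2"))
  expect_equal(unclass(S)["KRAS", "P1"], 1)   # 3 calls -> 1
  expect_equal(unclass(S)["KRAS", "P2"], 0)   # synonymous-only -> 0
  expect_equal(unclass(S)["TP53", "P2"], 1)
  empty <- binarize_somatic(calls[0, ], c("a", "b"), c("P1", "P2"))
  expect_true(all(unclass(empty) == 0))
})

test_that("survival dichotomy at 730 days with exclusion rules", {
  recs <- clinical_df(
    list("P1", "", "dead", "500"),     # died early -> high risk
    list("P2", "", "living", "600"),   # insufficient follow-up
    list("P3", "", "dead", "900"),     # low risk
    list("P4", "", "living", "900"),   # low risk
    list("P5", "", "", "100"),         # no status
    list("P6", "", "dead", NA))        # no days
  ov <- dichotomize_survival(recs)
  expect_equal(setNames(ov$labels, ov$sample_ids),
               c(P1 = 1L, P3 = 0L, P4 = 0L))
  expect_setequal(ov$excluded$sample_id, c("P2", "P5", "P6"))
  expect_match(ov$excluded$reason[ov$excluded$sample_id == "P2"],
               "insufficient follow-up")
  # conservation: every record is labeled or excluded
  expect_equal(length(ov$labels) + nrow(ov$excluded), nrow(recs))
  expect_error(dichotomize_survival(
    clinical_df(list("P1", "", "dead", "-5"))), "negative")
})

test_that("tumor status encoding is case/punctuation insensitive", {
  recs <- clinical_df(
    list("P1", "WITH TUMOR", "", ""), list("P2", "TUMOR FREE", "", ""),
    list("P3", "tumor-free", "", ""), list("P4", "unknown", "", ""),
    list("P5", "", "", ""))
  ov <- encode_tumor_status(recs)
  expect_equal(setNames(ov$labels, ov$sample_ids),
               c(P1 = 1L, P2 = 0L, P3 = 0L))
  expect_setequal(ov$excluded$sample_id, c("P4", "P5"))
  expect_equal(length(ov$labels) + nrow(ov$excluded), nrow(recs))
})

test_that("assemble_dataset intersects genes/samples and is idempotent", {
  mk <- function(genes, samples, mod)
    make_mm(seq_len(length(genes) * length(samples)), genes, samples, mod)
  samples <- paste0("P", 1:8)
  y <- setNames(rep(c(0L, 1L), 4), samples)
  S <- mk(c("a", "b", "c"), samples, "S")
  E <- mk(c("b", "c", "d"), samples, "E")
  M <- mk(c("b", "c"), samples, "M")
  ds <- assemble_dataset(S, E, M, y)
  expect_equal(ds$genes, c("b", "c"))

  # excluded outcome sample disappears everywhere
  y2 <- y[setdiff(samples, "P3")]
  ds2 <- assemble_dataset(S, E, M, y2)
  expect_false("P3" %in% ds2$samples)
  expect_false("P3" %in% colnames(ds2$S))

  # disjoint sample universes
  Sx <- mk(c("b", "c"), paste0("Q", 1:4), "S")
  expect_error(assemble_dataset(Sx, E, M, y), "sample")

  # idempotence: assembling the assembled parts changes nothing
  ds3 <- assemble_dataset(
    modality_matrix(ds$S, "S"), modality_matrix(ds$E, "E"),
    modality_matrix(ds$M, "M"), ds$outcome)
  expect_equal(ds3$genes, ds$genes)
  expect_equal(ds3$samples, ds$samples)
  expect_equal(ds3$S, ds$S)
  expect_equal(ds3$outcome, ds$outcome)

  # single-class outcome after intersection
  yc <- setNames(rep(0L, 8), samples)
  expect_error(assemble_dataset(S, E, M, yc), "single class")
})
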