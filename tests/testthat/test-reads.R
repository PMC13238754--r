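test_that("translation recovers the wild type and rejects by rule", {
  wt_read <- variant_read("WT")
  res <- translate_read(wt_read, default_cfg)
  expect_equal(res$status, "ok")
  expect_equal(res$protein, BPTI_WT)

  coding <- protein_to_dna(BPTI_WT)
  bad_base <- coding; substr(bad_base, 30L, 30L) <- "N"
  stopc <- coding; substr(stopc, 10L, 12L) <- "TAA"
  reads <- c(
    strrep("AC", 100L),                      # primer absent anywhere
    paste0("TAGC", substr(coding, 1L, 120L)), # 120 < 162 nt
    paste0("TAGC", bad_base),
    paste0("TAGC", stopc))
  res <- translate_read(reads, default_cfg)
  expect_equal(res$status,
               c("no_primer", "too_short", "invalid_base", "invalid_protein"))
  expect_true(all(is.na(res$protein)))
})

test_that("the primer is found anywhere and trailing bases are ignored", {
  coding <- protein_to_dna(BPTI_WT)
  # leading junk (no TAGC inside) and 30 trailing bases
  read <- paste0("CCCCCAACC", "TAGC", coding, strrep("G", 30L))
  res <- translate_read(read, default_cfg)
  expect_equal(res$status, "ok")
  expect_equal(res$protein, BPTI_WT)
})

test_that("classification confines substitutions to the mutable positions", {
  cl <- classify_variant(BPTI_WT, default_cfg)
  expect_equal(cl$status, "ok")
  expect_equal(cl$variant_id, "WT")
  expect_equal(cl$n_sub, 0L)

  single <- variant_protein("K15Y", default_cfg)
  expect_equal(classify_variant(single, default_cfg)$variant_id, "K15Y")

  off <- strsplit(BPTI_WT, "")[[1]]
  off[20L] <- "A"   # position 20 is outside the 12 mutable positions
  cl <- classify_variant(paste(off, collapse = ""), default_cfg)
  expect_equal(cl$status, "off_target_mutation")

  triple <- strsplit(BPTI_WT, "")[[1]]
  triple[c(11L, 15L, 39L)] <- c("A", "Y", "A")
  cl <- classify_variant(paste(triple, collapse = ""), default_cfg)
  expect_equal(cl$status, "higher_order")

  expect_error(classify_variant("SHORT", default_cfg), "length")
})

test_that("counting aggregates at the protein level and tallies rejections", {
  # two DNA encodings of the same protein must collapse to one genotype
  coding <- protein_to_dna(BPTI_WT)
  synonym <- coding
  substr(synonym, 1L, 3L) <- "AGA"  # CGT -> AGA, both Arg
  reads <- list(
    PRESORT = c(paste0("TAGC", coding), paste0("TAGC", synonym),
                variant_read("K15Y")),
    LO = c(variant_read("WT"), variant_read("K15Y")))
  tbl <- count_variants(reads, default_cfg)
  pre <- tbl$counts[tbl$counts$gate == "PRESORT", ]
  expect_equal(pre$count[pre$variant_id == "WT"], 2L)

  # 10 reads, 3 failing different filters: accepted counts sum to 7
  reads10 <- list(
    PRESORT = c(rep(variant_read("WT"), 4L),
                rep(variant_read("T11A"), 3L),
                strrep("AC", 100L),
                paste0("TAGC", substr(coding, 1L, 90L)),
                paste0("TAGC", sub("T", "Z", coding))),
    HI = rep(variant_read("WT"), 5L))
  tbl <- count_variants(reads10, default_cfg)
  expect_equal(sum(tbl$counts$count[tbl$counts$gate == "PRESORT"]), 7L)
  rej <- tbl$rejected[tbl$rejected$gate == "PRESORT", ]
  expect_equal(sum(rej$n), 3L)

  expect_error(count_variants(list(PRESORT = variant_read("WT")),
                              default_cfg), "selection gate")
  expect_error(
    count_variants(list(PRESORT = variant_read("WT"),
                        LO = strrep("AC", 100L)), default_cfg),
    "no valid reads")
})

test_that("enrichment follows the frequency/NF/ER arithmetic exactly", {
  reads <- reads_from_counts(list(
    PRESORT = c(WT = 25L, K15Y = 25L),
    HI = c(WT = 10L, K15Y = 40L)))
  enr <- compute_enrichment(count_variants(reads, default_cfg))
  v <- enr[enr$variant_id == "K15Y" & enr$gate == "HI", ]
  expect_equal(v$f, 0.8)
  expect_equal(v$nf, 4)
  expect_equal(v$er, 4)
  expect_equal(v$log2_er, 2)
  wt <- enr[enr$variant_id == "WT", ]
  expect_equal(wt$er, rep(1, nrow(wt)))
  expect_equal(wt$log2_er, rep(0, nrow(wt)))
})

test_that("variants absent from the pre-sort library are unscoreable", {
  reads <- reads_from_counts(list(
    PRESORT = c(WT = 10L, T11A = 5L),
    LO = c(WT = 5L, T11A = 3L, K15Y = 7L)))  # K15Y unseen pre-sort
  enr <- compute_enrichment(count_variants(reads, default_cfg))
  expect_false("K15Y" %in% enr$variant_id)
  # frequencies still computed over the full gate totals
  expect_equal(enr$f[enr$variant_id == "WT" & enr$gate == "LO"], 5 / 15)
})

test_that("a missing wild type makes the normalization fail loudly", {
  reads <- reads_from_counts(list(
    PRESORT = c(WT = 10L, T11A = 5L),
    LO = c(T11A = 3L, K15Y = 7L)))
  expect_error(compute_enrichment(count_variants(reads, default_cfg)),
               "absent from gate")
  reads <- reads_from_counts(list(
    PRESORT = c(T11A = 5L),
    LO = c(WT = 3L, T11A = 7L)))
  expect_error(compute_enrichment(count_variants(reads, default_cfg)),
               "absent from PRESORT")
})

test_that("per-gate frequencies sum to one over recorded variants", {
  set.seed(11)
  ids <- c("WT", "K15Y", "T11A", "R39A", "K15Y_R39A")
  mk <- function() setNames(sample(5:30, length(ids)), ids)
  reads <- reads_from_counts(list(PRESORT = mk(), HI = mk(), LO = mk()))
  enr <- compute_enrichment(count_variants(reads, default_cfg))
  for (g in c("HI", "LO")) {
    expect_equal(sum(enr$f[enr$gate == g]), 1)
  }
})

test_that("enrichment matches the brute-force recount oracle", {
  set.seed(4)
  ids <- c("WT", "K15Y", "G12D", "T11A_V34P")
  mk <- function() setNames(sample(2:6, length(ids)), ids)
  reads <- reads_from_counts(list(PRESORT = mk(), HI = mk(), SL = mk()))
  # sprinkle corrupt reads into each fraction
  reads <- lapply(reads, function(r) {
    sample(c(r, strrep("AC", 100L),
             paste0("TAGC", substr(protein_to_dna(BPTI_WT), 1L, 60L))))
  })
  expect_true(sum(lengths(reads)) <= 100L)
  got <- compute_enrichment(count_variants(reads, default_cfg))
  want <- oracle_enrichment(reads, default_cfg)
  key_g <- paste(got$variant_id, got$gate)
  key_w <- paste(want$variant_id, want$gate)
  expect_setequal(key_g, key_w)
  i <- match(key_g, key_w)
  expect_equal(got$count, want$count[i])
  expect_equal(got$f, want$f[i])
  expect_equal(got$nf, want$nf[i])
  expect_equal(got$er, want$er[i])
})

test_that("filtering is order-independent: rule order never changes the accepted set", {
  coding <- protein_to_dna(BPTI_WT)
  mixed <- c(variant_read("WT"), variant_read("K15Y"),
             variant_read("K15Y_R39A"),
             strrep("AC", 100L),
             paste0("TAGC", substr(coding, 1L, 100L)),
             paste0("TAGC", sub("G", "N", coding)))
  orders <- list(
    c("no_primer", "too_short", "invalid_base", "invalid_protein",
      "off_target", "higher_order"),
    c("higher_order", "off_target", "invalid_protein", "invalid_base",
      "too_short", "no_primer"),
    c("invalid_base", "no_primer", "higher_order", "too_short",
      "invalid_protein", "off_target"))
  accepted <- lapply(orders, function(o) {
    vapply(mixed, function(r) {
      cl <- oracle_classify_read(r, default_cfg, rule_order = o)
      if (cl$ok) cl$variant_id else NA_character_
    }, character(1), USE.NAMES = FALSE)
  })
  expect_identical(accepted[[1L]], accepted[[2L]])
  expect_identical(accepted[[1L]], accepted[[3L]])
  # and the pipeline agrees with the rule-set semantics
  tr <- translate_read(mixed, default_cfg)
  pipe <- rep(NA_character_, length(mixed))
  ok <- tr$status == "ok"
  cl <- classify_variant(tr$protein[ok], default_cfg)
  pipe[ok][cl$status == "ok"] <- cl$variant_id[cl$status == "ok"]
  expect_identical(pipe, accepted[[1L]])
})

test_that("reads files round-trip in FASTQ and plain-line form", {
  reads <- c(variant_read("WT"), variant_read("K15Y"), strrep("AC", 10L))
  tmp <- withr::local_tempdir()
  fq <- file.path(tmp, "r.fastq")
  writeLines(paste0("@r", seq_along(reads), "\n", reads, "\n+\n",
                    vapply(nchar(reads), function(n) strrep("I", n),
                           character(1))), fq)
  expect_identical(read_reads_file(fq), reads)
  txt <- file.path(tmp, "r.txt")
  writeLines(reads, txt)
  expect_identical(read_reads_file(txt), reads)
})
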