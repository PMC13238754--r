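# shared fixtures: read builders and an independent brute-force enrichment
# oracle (naive per-read loops, own codon lookup, no shared code path with
# the package implementation beyond the reference configuration)

default_cfg <- reference_config()

# DNA read for a variant id: primer + fixed-codon coding sequence
variant_read <- function(id, cfg = default_cfg) {
  paste0(cfg$primer, protein_to_dna(variant_protein(id, cfg)))
}

# read sets realising exact per-variant counts: list(gate = c(WT = 10, ...))
reads_from_counts <- function(counts_by_gate, cfg = default_cfg) {
  lapply(counts_by_gate, function(cnt) {
    unlist(lapply(names(cnt), function(id) {
      rep(variant_read(id, cfg), cnt[[id]])
    }))
  })
}

# independent per-codon translation table (standard genetic code)
oracle_codon_to_aa <- local({
  tab <- Biostrings::GENETIC_CODE
  function(codon) unname(tab[codon])
})

# classify a single read by evaluating every filter rule independently, in
# the given rule order; returns the variant id or the first failing reason
oracle_classify_read <- function(read, cfg,
                                 rule_order = c("no_primer", "too_short",
                                                "invalid_base",
                                                "invalid_protein",
                                                "off_target", "higher_order")) {
  chars <- strsplit(read, "")[[1]]
  np <- nchar(cfg$primer)
  primer_at <- NA_integer_
  for (i in seq_len(max(0L, length(chars) - np + 1L))) {
    if (paste(chars[i:(i + np - 1L)], collapse = "") == cfg$primer) {
      primer_at <- i
      break
    }
  }
  coding <- if (!is.na(primer_at)) {
    chars[(primer_at + np):min(length(chars),
                               primer_at + np + cfg$min_coding_length_nt - 1L)]
  } else character()
  protein <- NULL
  fails <- list(
    no_primer = is.na(primer_at),
    too_short = !is.na(primer_at) &&
      length(coding) < cfg$min_coding_length_nt,
    invalid_base = length(coding) == cfg$min_coding_length_nt &&
      !all(coding %in% c("A", "C", "G", "T")))
  if (!fails$no_primer && !fails$too_short && !fails$invalid_base) {
    aa <- vapply(seq(1L, cfg$min_coding_length_nt, by = 3L), function(k) {
      oracle_codon_to_aa(paste(coding[k:(k + 2L)], collapse = ""))
    }, character(1))
    fails$invalid_protein <- any(aa == "*")
    if (!fails$invalid_protein) {
      protein <- aa
      d <- which(aa != cfg$wt_residues)
      fails$off_target <- length(setdiff(d, cfg$mutable_positions)) > 0L
      fails$higher_order <- !fails$off_target && length(d) > 2L
    }
  }
  for (r in rule_order) {
    if (isTRUE(fails[[r]])) return(list(ok = FALSE, reason = r))
  }
  d <- which(protein != cfg$wt_residues)
  id <- if (length(d) == 0L) "WT" else {
    paste(paste0(cfg$wt_residues[d], d, protein[d]), collapse = "_")
  }
  list(ok = TRUE, variant_id = id)
}

# naive recount + Eq 1-3 arithmetic over raw reads
oracle_enrichment <- function(reads_by_gate, cfg = default_cfg) {
  counts <- lapply(reads_by_gate, function(reads) {
    acc <- list()
    for (r in reads) {
      cl <- oracle_classify_read(r, cfg)
      if (cl$ok) acc[[cl$variant_id]] <- (acc[[cl$variant_id]] %||% 0L) + 1L
    }
    unlist(acc)
  })
  pre <- counts$PRESORT
  f_pre <- pre / sum(pre)
  nf_pre <- f_pre / f_pre[["WT"]]
  out <- list()
  for (g in setdiff(names(counts), "PRESORT")) {
    cg <- counts[[g]]
    f <- cg / sum(cg)
    nf <- f / f[["WT"]]
    for (v in names(cg)) {
      if (!v %in% names(nf_pre)) next
      out[[length(out) + 1L]] <- data.frame(
        variant_id = v, gate = g, count = as.integer(cg[[v]]),
        f = f[[v]], nf = nf[[v]], er = nf[[v]] / nf_pre[[v]])
    }
  }
  do.call(rbind, out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
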