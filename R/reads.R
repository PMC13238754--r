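## Read translation, filtering, counting, and enrichment ratios.
##
## Filtering rules: a read is kept only if it contains the primer, carries a
## full-length coding region after it, uses only A/C/G/T in that region,
## translates without a stop codon, and encodes a protein whose differences
## from the wild type are confined to the mutable positions with at most two
## substitutions. Rejections are tallied per rule, never raised as errors.

REJECT_REASONS <- c("no_primer", "too_short", "invalid_base",
                    "invalid_protein", "off_target_mutation", "higher_order")

#' Translate raw DNA reads into interface protein sequences
#'
#' Locates the primer anywhere in the read (first occurrence), reads the
#' following `min_coding_length_nt` nucleotides in frame, and translates
#' them. Reads failing a rule are returned with a reason code instead of a
#' protein; rejections are data, not exceptions.
#'
#' @param reads Character vector of raw reads.
#' @param cfg A [reference_config()].
#' @return A data.frame with one row per read: `status` (`"ok"` or a reason
#'   among `no_primer`, `too_short`, `invalid_base`, `invalid_protein`) and
#'   `protein` (`NA` unless ok).
#' @export
translate_read <- function(reads, cfg) {
  n <- length(reads)
  status <- rep("ok", n)
  protein <- rep(NA_character_, n)
  loc <- regexpr(cfg$primer, reads, fixed = TRUE)
  status[loc < 0L] <- "no_primer"
  start <- as.integer(loc) + nchar(cfg$primer)
  avail <- nchar(reads) - start + 1L
  short <- status == "ok" & avail < cfg$min_coding_length_nt
  status[short] <- "too_short"
  idx <- which(status == "ok")
  if (length(idx)) {
    coding <- substr(reads[idx], start[idx],
                     start[idx] + cfg$min_coding_length_nt - 1L)
    bad <- grepl("[^ACGT]", coding)
    status[idx[bad]] <- "invalid_base"
    idx <- idx[!bad]; coding <- coding[!bad]
    if (length(idx)) {
      aa <- as.character(Biostrings::translate(Biostrings::DNAStringSet(coding)))
      stopc <- grepl("*", aa, fixed = TRUE)
      status[idx[stopc]] <- "invalid_protein"
      protein[idx[!stopc]] <- aa[!stopc]
    }
  }
  data.frame(status = status, protein = protein, stringsAsFactors = FALSE)
}

#' Classify proteins as library genotypes
#'
#' Compares each protein to the wild type and restricts differences to the
#' mutable positions. Differences elsewhere reject the read
#' (`off_target_mutation`); more than two substitutions at allowed positions
#' are tallied as `higher_order` and excluded from analysis (the library is
#' single/double by construction).
#'
#' @param proteins Character vector of full-length protein sequences.
#' @param cfg A [reference_config()].
#' @return A data.frame with columns `protein`, `status` (`"ok"`,
#'   `"off_target_mutation"` or `"higher_order"`), `variant_id` (`NA` unless
#'   ok) and `n_sub`.
#' @export
classify_variant <- function(proteins, cfg) {
  len <- nchar(cfg$wt_protein)
  if (any(nchar(proteins) != len)) {
    stop("all proteins must have length ", len)
  }
  n <- length(proteins)
  if (n == 0L) {
    return(data.frame(protein = character(), status = character(),
                      variant_id = character(), n_sub = integer(),
                      stringsAsFactors = FALSE))
  }
  m <- matrix(unlist(strsplit(proteins, ""), use.names = FALSE),
              nrow = n, byrow = TRUE)
  diff <- sweep(m, 2L, cfg$wt_residues, FUN = "!=")
  off <- rowSums(diff[, -cfg$mutable_positions, drop = FALSE]) > 0L
  nsub <- rowSums(diff[, cfg$mutable_positions, drop = FALSE])
  status <- rep("ok", n)
  status[nsub > 2L] <- "higher_order"
  status[off] <- "off_target_mutation"
  vid <- rep(NA_character_, n)
  ok <- which(status == "ok")
  for (i in ok) {
    p <- cfg$mutable_positions[diff[i, cfg$mutable_positions]]
    vid[i] <- if (length(p) == 0L) "WT" else variant_id(p, m[i, p], cfg)
  }
  data.frame(protein = proteins, status = status, variant_id = vid,
             n_sub = as.integer(nsub), stringsAsFactors = FALSE)
}

#' Count variants per gate from raw reads
#'
#' Runs the full filter cascade on every gate's reads, aggregates counts at
#' the protein-genotype level (synonymous DNA variants collapse), and logs
#' per-rule rejection tallies.
#'
#' @param reads_by_gate Named list of character vectors of raw reads; must
#'   contain `"PRESORT"` and at least one selection gate among
#'   `r paste(GATES, collapse = ", ")`.
#' @param cfg A [reference_config()].
#' @return An object of class `gate_count_table`: list with `counts`
#'   (data.frame `variant_id`, `gate`, `count`), `rejected` (data.frame
#'   `gate`, `reason`, `n`), `n_reads` (named total input reads) and `cfg`.
#' @export
count_variants <- function(reads_by_gate, cfg) {
  gates <- names(reads_by_gate)
  if (is.null(gates) || !(PRESORT %in% gates)) {
    stop("reads_by_gate must be a named list containing PRESORT")
  }
  if (!any(gates %in% GATES)) {
    stop("reads_by_gate must contain at least one selection gate")
  }
  bad <- setdiff(gates, c(GATES, PRESORT))
  if (length(bad)) stop("unknown gate label(s): ", paste(bad, collapse = ", "))
  counts <- list(); rejected <- list()
  for (g in gates) {
    reads <- reads_by_gate[[g]]
    if (length(reads) == 0L) stop("gate ", g, " has no reads")
    tr <- translate_read(reads, cfg)
    # classify unique proteins once, then map back through the count table
    prot_counts <- table(tr$protein[tr$status == "ok"])
    rej <- table(factor(tr$status[tr$status != "ok"], levels = REJECT_REASONS))
    if (length(prot_counts)) {
      cl <- classify_variant(names(prot_counts), cfg)
      for (r in c("off_target_mutation", "higher_order")) {
        rej[r] <- rej[r] + sum(prot_counts[cl$status == r])
      }
      keep <- cl$status == "ok"
      if (any(keep)) {
        cnt <- tapply(as.integer(prot_counts[keep]), cl$variant_id[keep], sum)
        counts[[g]] <- data.frame(variant_id = names(cnt), gate = g,
                                  count = as.integer(cnt),
                                  stringsAsFactors = FALSE)
      }
    }
    if (is.null(counts[[g]])) stop("gate ", g, " has no valid reads")
    rejected[[g]] <- data.frame(gate = g, reason = REJECT_REASONS,
                                n = as.integer(rej[REJECT_REASONS]),
                                stringsAsFactors = FALSE)
  }
  structure(
    list(counts = do.call(rbind, c(counts, list(make.row.names = FALSE))),
         rejected = do.call(rbind, c(rejected, list(make.row.names = FALSE))),
         n_reads = vapply(reads_by_gate, length, integer(1)),
         cfg = cfg),
    class = "gate_count_table")
}

#' @export
print.gate_count_table <- function(x, ...) {
  cat("Gate count table:",
      length(unique(x$counts$variant_id)), "genotypes over",
      length(unique(x$counts$gate)), "fractions\n")
  tot <- tapply(x$counts$count, x$counts$gate, sum)
  rej <- tapply(x$rejected$n, x$rejected$gate, sum)
  print(data.frame(gate = names(tot), accepted_reads = as.integer(tot),
                   rejected_reads = as.integer(rej[names(tot)])))
  invisible(x)
}

#' Per-variant frequencies, normalized frequencies and enrichment ratios
#'
#' For every variant observed in both the pre-sort library and a selection
#' gate, computes the frequency `f` (count over the gate's accepted reads),
#' the wild-type-normalized frequency `nf = f / f_WT`, the enrichment ratio
#' `er = nf_gate / nf_presort`, and `log2_er`. No pseudocounts: variants
#' absent from the pre-sort library or from a gate get no record for that
#' gate. The wild type must be observed in the pre-sort library and in every
#' selection gate (the normalizing denominators), else an error is raised.
#'
#' @param tbl A [count_variants()] result.
#' @return A data.frame of class `enrichment_table` with columns
#'   `variant_id`, `n_sub`, `pos1`, `aa1`, `pos2`, `aa2`, `gate`, `count`,
#'   `f`, `nf`, `er`, `log2_er`; the wild-type row in every gate has
#'   `er = 1`, `log2_er = 0` exactly.
#' @export
compute_enrichment <- function(tbl) {
  stopifnot(inherits(tbl, "gate_count_table"))
  cn <- tbl$counts
  gates <- intersect(GATES, unique(cn$gate))
  pre <- cn[cn$gate == PRESORT, ]
  if (!nrow(pre)) stop("no PRESORT counts")
  tot_pre <- sum(pre$count)
  f_pre <- stats::setNames(pre$count / tot_pre, pre$variant_id)
  if (is.na(f_pre["WT"]) || f_pre["WT"] <= 0) {
    stop("wild type absent from PRESORT: normalized frequencies undefined")
  }
  nf_pre <- f_pre / f_pre[["WT"]]
  out <- lapply(gates, function(g) {
    gc <- cn[cn$gate == g, ]
    tot <- sum(gc$count)
    f <- gc$count / tot
    wt_i <- match("WT", gc$variant_id)
    if (is.na(wt_i)) stop("wild type absent from gate ", g)
    nf <- f / f[wt_i]
    keep <- gc$variant_id %in% names(nf_pre)
    gc <- gc[keep, ]; f <- f[keep]; nf <- nf[keep]
    er <- nf / nf_pre[gc$variant_id]
    data.frame(variant_id = gc$variant_id, gate = g, count = gc$count,
               f = f, nf = nf, er = as.numeric(er),
               log2_er = log2(as.numeric(er)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  geno <- parse_variants(out$variant_id)
  out <- cbind(geno[, c("variant_id", "n_sub", "pos1", "aa1", "pos2", "aa2")],
               out[, c("gate", "count", "f", "nf", "er", "log2_er")])
  class(out) <- c("enrichment_table", "data.frame")
  attr(out, "cfg") <- tbl$cfg
  out
}

#' Pivot an enrichment table to one row per variant
#'
#' @param enr An [compute_enrichment()] result.
#' @param value Column to pivot (default `"log2_er"`).
#' @return A numeric matrix, rows named by variant, one column per gate
#'   present; `NA` where a variant has no record in a gate.
#' @export
enrichment_wide <- function(enr, value = "log2_er") {
  gates <- intersect(GATES, unique(enr$gate))
  ids <- unique(enr$variant_id)
  m <- matrix(NA_real_, length(ids), length(gates),
              dimnames = list(ids, gates))
  m[cbind(match(enr$variant_id, ids), match(enr$gate, gates))] <- enr[[value]]
  m
}

#' Library coverage per gate
#'
#' Observed single- and double-mutant genotypes per fraction against the
#' theoretical universe, as counts and percentages.
#'
#' @param tbl A [count_variants()] result.
#' @return A data.frame with one row per fraction: `gate`,
#'   `singles_observed`, `singles_pct`, `doubles_observed`, `doubles_pct`.
#' @export
coverage_summary <- function(tbl) {
  stopifnot(inherits(tbl, "gate_count_table"))
  cfg <- tbl$cfg
  p <- length(cfg$mutable_positions)
  n_singles <- 19L * p
  n_doubles <- as.integer(19L * 19L * choose(p, 2L))
  geno <- parse_variants(tbl$counts$variant_id)
  ns <- geno$n_sub[match(tbl$counts$variant_id, geno$variant_id)]
  gates <- unique(tbl$counts$gate)
  do.call(rbind, lapply(gates, function(g) {
    sel <- tbl$counts$gate == g
    s <- length(unique(tbl$counts$variant_id[sel & ns == 1L]))
    d <- length(unique(tbl$counts$variant_id[sel & ns == 2L]))
    data.frame(gate = g, singles_observed = s,
               singles_pct = coverage_percent(s, n_singles),
               doubles_observed = d,
               doubles_pct = coverage_percent(d, n_doubles),
               stringsAsFactors = FALSE)
  }))
}

## ---- file input / output -------------------------------------------------

#' Read sequencing reads from FASTQ or plain text
#'
#' FASTQ qualities are ignored. Plain-text input is one read per line.
#' Parsing is deliberately tolerant: reads containing arbitrary characters
#' must flow through so the filter rules can reject them.
#'
#' @param path File path; format auto-detected from the first character
#'   (`@` means FASTQ) unless `format` is given.
#' @param format `"auto"`, `"fastq"` or `"lines"`.
#' @return Character vector of reads.
#' @export
read_reads_file <- function(path, format = c("auto", "fastq", "lines")) {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(character())
  if (format == "auto") {
    format <- if (startsWith(lines[1L], "@")) "fastq" else "lines"
  }
  if (format == "fastq") {
    if (length(lines) %% 4L != 0L) stop("malformed FASTQ: ", path)
    lines[seq(2L, length(lines), by = 4L)]
  } else {
    lines
  }
}

#' Write an enrichment table and rejection summary as TSV
#'
#' @param enr An [compute_enrichment()] result.
#' @param tbl The matching [count_variants()] result (for rejections), or
#'   `NULL` to skip the summary.
#' @param path Output TSV path; the rejection summary goes to
#'   `<path base>_rejections.tsv`.
#' @return Invisibly, the paths written.
#' @export
write_enrichment_tsv <- function(enr, tbl = NULL, path) {
  utils::write.table(enr, path, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- path
  if (!is.null(tbl)) {
    rp <- sub("\\.tsv$", "", path)
    rp <- paste0(rp, "_rejections.tsv")
    utils::write.table(tbl$rejected, rp, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, rp)
  }
  invisible(paths)
}
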