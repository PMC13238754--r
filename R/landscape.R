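## Assembly of the single/double-mutant affinity landscape, double-mutant
## cycle epistasis with ensemble uncertainty, and positional summaries.

#' Double-mutant cycle epistasis
#'
#' `epsilon = ddg_i + ddg_j - ddg_ij`: positive epistasis means the double
#' mutant binds more tightly than the additive expectation of its two
#' singles; all three values must come from the same seed (or the same
#' aggregation level).
#'
#' @param ddg_i,ddg_j Single-mutant ddG_bind values (kcal/mol).
#' @param ddg_ij Double-mutant ddG_bind value.
#' @return Epistasis (kcal/mol); vectorized.
#' @examples
#' epistasis(-2.382, -1.042, -1.681) # -1.743
#' @export
epistasis <- function(ddg_i, ddg_j, ddg_ij) {
  ddg_i + ddg_j - ddg_ij
}

#' Build the affinity and epistasis landscape
#'
#' Runs each ensemble member independently through the whole prediction
#' pipeline: per seed, predict the four gate log2 enrichment ratios for
#' every variant, apply the calibration, anchor to the wild type, and
#' compute per-double epistasis from that same seed's single-mutant values;
#' means and standard deviations are then taken across seeds. The wild type
#' and any missing component singles are added to the requested variant set
#' automatically (they are needed for anchoring and for epistasis).
#'
#' @param ensembles Named list of [train_gate_ensemble()] results, one per
#'   gate in `r paste(GATES, collapse = ", ")`, all with the same ensemble
#'   size.
#' @param coeffs A `calibration`.
#' @param variants Character vector of variant ids to score (defaults to
#'   the full 24,055-genotype universe).
#' @param provider The `embedding_provider` used at training time.
#' @param cfg A [reference_config()].
#' @return data.frame of class `landscape_table`: `variant_id`, `n_sub`,
#'   `pos1`, `aa1`, `pos2`, `aa2`, `ddg_mean`, `ddg_sd`, `epsilon_mean`,
#'   `epsilon_sd` (epistasis defined only for doubles). The wild-type row
#'   has `ddg_mean = 0`, `ddg_sd = 0` exactly.
#' @export
build_landscape <- function(ensembles, coeffs, variants = NULL, provider,
                            cfg) {
  stopifnot(identical(sort(names(ensembles)), sort(GATES)))
  n_seeds <- unique(vapply(ensembles, function(e) e$cfg$n_seeds, integer(1)))
  if (length(n_seeds) != 1L) {
    stop("all four gate ensembles must share the same number of seeds")
  }
  if (is.null(variants)) variants <- enumerate_variant_space(cfg)$variant_id
  geno <- parse_variants(variants)
  dbl <- geno$variant_id[geno$n_sub == 2L]
  need <- "WT"
  if (length(dbl)) need <- c(need, as.vector(component_singles(dbl)))
  ids <- union(variants, need)
  feats <- build_feature_matrix(ids, provider, cfg)
  # member predictions per gate: list of (n_variants x n_seeds) matrices
  member_preds <- lapply(ensembles, function(e) {
    predict_ensemble(e, feats)$members
  })
  ddg <- matrix(NA_real_, length(ids), n_seeds,
                dimnames = list(ids, NULL))
  for (s in seq_len(n_seeds)) {
    log2er <- vapply(CALIBRATION_GATES,
                     function(g) member_preds[[g]][, s],
                     numeric(length(ids)))
    ddg[, s] <- apply_calibration(coeffs, log2er)
  }
  ddg <- normalize_to_wt(ddg)
  eps <- matrix(NA_real_, length(ids), n_seeds, dimnames = list(ids, NULL))
  if (length(dbl)) {
    comp <- component_singles(dbl)
    eps[dbl, ] <- epistasis(ddg[comp[, 1L], , drop = FALSE],
                            ddg[comp[, 2L], , drop = FALSE],
                            ddg[dbl, , drop = FALSE])
  }
  row_sd <- function(m) {
    if (ncol(m) == 1L) rep(0, nrow(m)) else apply(m, 1L, stats::sd)
  }
  out <- data.frame(
    parse_variants(ids)[, c("variant_id", "n_sub", "pos1", "aa1",
                            "pos2", "aa2")],
    ddg_mean = rowMeans(ddg), ddg_sd = row_sd(ddg),
    epsilon_mean = rowMeans(eps), epsilon_sd = NA_real_,
    stringsAsFactors = FALSE)
  out$epsilon_sd[out$n_sub == 2L] <- row_sd(eps[out$n_sub == 2L, ,
                                                drop = FALSE])
  out <- out[match(union(variants, setdiff(ids, variants)),
                   out$variant_id), ]
  rownames(out) <- NULL
  class(out) <- c("landscape_table", "data.frame")
  attr(out, "n_seeds") <- n_seeds
  out
}

#' Positional pair averages of affinity and epistasis
#'
#' Means over all substitution combinations at each pair of mutated
#' positions (361 combinations per pair at full coverage; 66 pairs for the
#' 12-position library); symmetric in the pair labelling.
#'
#' @param entries A [build_landscape()] result (or any data.frame with
#'   `n_sub`, `pos1`, `pos2`, `ddg_mean`, `epsilon_mean`).
#' @return data.frame `pos_i`, `pos_j` (pos_i < pos_j), `n`, `mean_ddg`,
#'   `mean_epsilon`.
#' @export
pair_averages <- function(entries) {
  d <- entries[entries$n_sub == 2L, ]
  if (!nrow(d)) stop("no double mutants in the landscape")
  key <- paste(pmin(d$pos1, d$pos2), pmax(d$pos1, d$pos2), sep = ":")
  agg <- function(v) tapply(v, key, mean)
  ddg <- agg(d$ddg_mean); eps <- agg(d$epsilon_mean)
  n <- tapply(rep(1L, nrow(d)), key, sum)
  pp <- do.call(rbind, strsplit(names(ddg), ":", fixed = TRUE))
  out <- data.frame(pos_i = as.integer(pp[, 1L]),
                    pos_j = as.integer(pp[, 2L]),
                    n = as.integer(n), mean_ddg = as.numeric(ddg),
                    mean_epsilon = as.numeric(eps))
  out[order(out$pos_i, out$pos_j), ]
}

#' Symmetric position-pair matrix from pair averages
#'
#' @param pa A [pair_averages()] result.
#' @param value `"mean_ddg"` or `"mean_epsilon"`.
#' @return A symmetric matrix over the positions present (diagonal `NA`),
#'   ready for heatmap display.
#' @export
pair_matrix <- function(pa, value = c("mean_epsilon", "mean_ddg")) {
  value <- match.arg(value)
  pos <- sort(unique(c(pa$pos_i, pa$pos_j)))
  m <- matrix(NA_real_, length(pos), length(pos),
              dimnames = list(pos, pos))
  i <- match(pa$pos_i, pos); j <- match(pa$pos_j, pos)
  m[cbind(i, j)] <- pa[[value]]
  m[cbind(j, i)] <- pa[[value]]
  m
}

#' Per-position, per-gate mutation frequencies
#'
#' For each mutable position and each selection gate, the fraction of that
#' gate's accepted variant reads carrying a mutation at the position
#' (double mutants count toward both of their positions). Mirrors the
#' positional gate-occupancy summary used to identify hotspots: positions
#' whose mutations are over-represented in the low-affinity gate.
#'
#' @param tbl A [count_variants()] result.
#' @return data.frame `gate`, `position`, `frequency` in `[0, 1]`.
#' @export
gate_position_frequency <- function(tbl) {
  stopifnot(inherits(tbl, "gate_count_table"))
  cfg <- tbl$cfg
  cn <- tbl$counts
  geno <- parse_variants(unique(cn$variant_id))
  i <- match(cn$variant_id, geno$variant_id)
  gates <- unique(cn$gate)
  out <- do.call(rbind, lapply(gates, function(g) {
    sel <- cn$gate == g
    tot <- sum(cn$count[sel])
    freq <- vapply(cfg$mutable_positions, function(p) {
      hit <- sel & (!is.na(geno$pos1[i]) & geno$pos1[i] == p |
                    !is.na(geno$pos2[i]) & geno$pos2[i] == p)
      sum(cn$count[hit]) / tot
    }, numeric(1))
    data.frame(gate = g, position = cfg$mutable_positions, frequency = freq,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Write landscape tables as TSV
#'
#' @param entries A [build_landscape()] result.
#' @param path Output TSV; pair averages go to `<base>_pairs.tsv`.
#' @return Invisibly, the paths written.
#' @export
write_landscape_tsv <- function(entries, path) {
  utils::write.table(entries, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  pp <- paste0(sub("\\.tsv$", "", path), "_pairs.tsv")
  if (any(entries$n_sub == 2L)) {
    utils::write.table(pair_averages(entries), pp, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(c(path, pp))
  } else invisible(path)
}
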