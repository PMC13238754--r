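## Data-partitioning schemes, performance metrics, leakage control, and the
## additive-baseline comparison for double mutants.

#' Pearson correlation and RMSE between predictions and observations
#'
#' @param predicted,observed Numeric vectors of equal length (n >= 3); an
#'   error is raised if either has zero variance (r undefined).
#' @return data.frame `pearson_r`, `rmse`, `n`.
#' @export
pearson_rmse <- function(predicted, observed) {
  stopifnot(length(predicted) == length(observed))
  if (length(predicted) < 3L) stop("need at least 3 paired values")
  if (stats::sd(predicted) == 0 || stats::sd(observed) == 0) {
    stop("zero variance: Pearson correlation undefined")
  }
  data.frame(pearson_r = stats::cor(predicted, observed),
             rmse = sqrt(mean((predicted - observed)^2)),
             n = length(predicted))
}

## canonical deterministic variant ordering used for tie-breaking
canonical_order <- function(ids) {
  p <- parse_variants(ids)
  order(p$n_sub, p$pos1, p$aa1, p$pos2, p$aa2, na.last = FALSE,
        method = "radix")
}

#' Read-depth-ranked train/validation/test split
#'
#' Variants are ranked by total read count (pre-sort + the given gate),
#' descending: the top `fractions[1]` become the test set (the most
#' reliable enrichment measurements), the next `fractions[2]` the
#' validation set, the rest the training set. Ties are broken by canonical
#' variant order, so the split is deterministic.
#'
#' @param tbl A [count_variants()] result.
#' @param gate A selection gate.
#' @param fractions Numeric `(test, val)`, each in (0,1), summing to < 1.
#' @return List of character vectors `train`, `val`, `test` (disjoint,
#'   jointly all variants with counts in both fractions).
#' @export
split_by_read_count <- function(tbl, gate, fractions = c(0.1, 0.1)) {
  stopifnot(inherits(tbl, "gate_count_table"), gate %in% GATES,
            length(fractions) == 2L, all(fractions > 0),
            all(fractions < 1), sum(fractions) < 1)
  cn <- tbl$counts
  g <- cn[cn$gate == gate, ]
  if (!nrow(g)) stop("no counts for gate ", gate)
  pre <- cn[cn$gate == PRESORT, ]
  ids <- intersect(g$variant_id, pre$variant_id)
  if (!length(ids)) stop("no variants shared between ", gate, " and PRESORT")
  # rank descending by total depth with canonical order as tiebreak
  key <- data.frame(id = ids, total = g$count[match(ids, g$variant_id)] +
                      pre$count[match(ids, pre$variant_id)])
  key <- key[canonical_order(key$id), ]
  key <- key[order(-key$total), ]
  n <- nrow(key)
  n_test <- round(fractions[1L] * n)
  n_val <- round(fractions[2L] * n)
  list(test = key$id[seq_len(n_test)],
       val = key$id[n_test + seq_len(n_val)],
       train = key$id[-seq_len(n_test + n_val)])
}

#' Position-wise holdout split
#'
#' Strict mode: every variant carrying a substitution at the target
#' position (through either of a double's two substitutions) goes to the
#' test set; the training set provably contains none. Inclusion mode: only
#' a fraction (default 10%) of the position-touching variants is reserved
#' for testing, and the remainder joins the training set, quantifying the
#' value of same-position training examples.
#'
#' @param ids Character vector of variant ids to split.
#' @param target_position A mutable position.
#' @param include_mode `FALSE` (strict, default) or `TRUE` (inclusion).
#' @param test_fraction Fraction of position-touching variants tested in
#'   inclusion mode.
#' @param seed Seed for the inclusion-mode subsample.
#' @param cfg A [reference_config()].
#' @return List of character vectors `train`, `test`.
#' @export
split_position_holdout <- function(ids, target_position, include_mode = FALSE,
                                   test_fraction = 0.1, seed = 1L,
                                   cfg = reference_config()) {
  if (!target_position %in% cfg$mutable_positions) {
    stop("target_position must be one of the mutable positions")
  }
  p <- parse_variants(ids)
  touch <- (!is.na(p$pos1) & p$pos1 == target_position) |
    (!is.na(p$pos2) & p$pos2 == target_position)
  if (!any(touch)) stop("no variants touch position ", target_position)
  if (!include_mode) {
    return(list(train = ids[!touch], test = ids[touch]))
  }
  held <- ids[touch][canonical_order(ids[touch])]
  n_test <- max(1L, round(test_fraction * length(held)))
  test <- with_seed(derive_seed(seed, "position_holdout"), {
    sample(held, n_test)
  })
  list(train = c(ids[!touch], setdiff(held, test)), test = test)
}

#' Remove measured variants from a training table
#'
#' Leakage control for literature validation and calibration: variants with
#' experimental measurements (and, optionally, the component singles of
#' measured doubles) are excluded from every gate's training data before
#' the ensembles are trained.
#'
#' @param enr An [compute_enrichment()] result.
#' @param measured Character vector of measured variant ids.
#' @param with_singles Also exclude the component singles of measured
#'   doubles (required for the additive-baseline comparison).
#' @return The filtered enrichment table, with attribute `excluded`.
#' @export
exclude_from_training <- function(enr, measured, with_singles = FALSE) {
  excl <- measured
  if (with_singles) {
    p <- parse_variants(measured)
    dbl <- measured[p$n_sub == 2L]
    if (length(dbl)) excl <- union(excl, as.vector(component_singles(dbl)))
  }
  out <- enr[!enr$variant_id %in% excl, ]
  attr(out, "excluded") <- excl
  attr(out, "cfg") <- attr(enr, "cfg")
  class(out) <- class(enr)
  out
}

#' Exhaustive-subset comparison of direct versus additive predictions
#'
#' For n measured double mutants, the additive prediction of each double is
#' the sum of its two singles' predicted ddG values. Pearson correlation
#' with the measurements is evaluated for the direct and the additive
#' predictor over every subset of sizes n-2, n-1 and n (exhaustive, not
#' sampled: 45 + 10 + 1 = 56 subsets for n = 10), reporting mean and SD
#' across subsets.
#'
#' @param double_ids Character vector of measured double mutants (n >= 4).
#' @param direct Named numeric: directly predicted ddG per double.
#' @param singles Named numeric: predicted ddG of every needed single.
#' @param measured Named numeric: experimental ddG per double.
#' @param exclusions_applied Flag recorded in the output asserting that the
#'   doubles and their component singles were excluded from training.
#' @return List with `direct` and `additive` (each mean, sd, n_subsets) and
#'   `per_double` (data.frame of the three predictions per double).
#' @export
additive_baseline_comparison <- function(double_ids, direct, singles,
                                         measured,
                                         exclusions_applied = NA) {
  n <- length(double_ids)
  if (n < 4L) stop("need at least 4 measured double mutants")
  comp <- component_singles(double_ids)
  if (!all(comp %in% names(singles))) {
    stop("missing single-mutant predictions for some doubles")
  }
  additive <- singles[comp[, 1L]] + singles[comp[, 2L]]
  direct <- direct[double_ids]; measured <- measured[double_ids]
  if (anyNA(direct) || anyNA(measured)) stop("missing predictions/measurements")
  subset_r <- function(pred) {
    unlist(lapply((n - 2L):n, function(k) {
      utils::combn(n, k, function(i) stats::cor(pred[i], measured[i]))
    }))
  }
  rd <- subset_r(as.numeric(direct))
  ra <- subset_r(as.numeric(additive))
  list(direct = list(mean_r = mean(rd), sd_r = stats::sd(rd),
                     n_subsets = length(rd)),
       additive = list(mean_r = mean(ra), sd_r = stats::sd(ra),
                       n_subsets = length(ra)),
       per_double = data.frame(variant_id = double_ids,
                               direct = as.numeric(direct),
                               additive = as.numeric(additive),
                               measured = as.numeric(measured)),
       exclusions_applied = exclusions_applied)
}

#' Validate predictions against literature measurements
#'
#' Computes, for variants with experimental ddG_bind values, the Pearson
#' correlation of each gate's ensemble-mean log2 ER prediction with the
#' measurements, and of the combined (calibrated, WT-anchored) ddG
#' prediction. Measured variants must have been excluded from training
#' (see [exclude_from_training()]).
#'
#' @param ensembles Named list of the four gate ensembles.
#' @param coeffs A `calibration`.
#' @param measurements data.frame with `variant_id`, `ddg_exp`.
#' @param provider The `embedding_provider` used at training time.
#' @param cfg A [reference_config()].
#' @return List with `per_gate` (data.frame `gate`, `pearson_r`, `abs_r`,
#'   `n`) and `combined` (a [pearson_rmse()] report for the calibrated
#'   ddG).
#' @export
literature_validation <- function(ensembles, coeffs, measurements, provider,
                                  cfg) {
  p <- parse_variants(measurements$variant_id)
  ok <- (is.na(p$pos1) | p$pos1 %in% cfg$mutable_positions) &
    (is.na(p$pos2) | p$pos2 %in% cfg$mutable_positions)
  if (!all(ok)) {
    stop("measurement variant(s) outside the library positions: ",
         paste(measurements$variant_id[!ok], collapse = ", "))
  }
  land <- build_landscape(ensembles, coeffs,
                          variants = measurements$variant_id,
                          provider = provider, cfg = cfg)
  feats <- build_feature_matrix(measurements$variant_id, provider, cfg)
  per_gate <- do.call(rbind, lapply(GATES, function(g) {
    pred <- predict_ensemble(ensembles[[g]], feats)$mean
    r <- stats::cor(pred, measurements$ddg_exp)
    data.frame(gate = g, pearson_r = r, abs_r = abs(r),
               n = length(pred), stringsAsFactors = FALSE)
  }))
  ddg <- land$ddg_mean[match(measurements$variant_id, land$variant_id)]
  list(per_gate = per_gate,
       combined = pearson_rmse(ddg, measurements$ddg_exp))
}
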