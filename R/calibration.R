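## Linear calibration from the four gate log2 enrichment ratios to the
## binding free-energy change, ddG_bind (kcal/mol).

## Gate order of the coefficient vector throughout this module.
CALIBRATION_GATES <- c("HI", "SL", "WT_GATE", "LO")

#' Published calibration coefficients
#'
#' The linear map fitted on 27 literature-measured single mutants of the
#' BPTI-chymotrypsin complex:
#' `ddG = -0.397 log2ER_HI - 0.348 log2ER_SL + 0.184 log2ER_WT
#'        + 0.597 log2ER_LO - 0.560`.
#' Ships as a named preset for users without their own calibration data.
#'
#' @return Object of class `calibration`: named numeric
#'   `(HI, SL, WT_GATE, LO, bias)`.
#' @export
calibration_preset <- function() {
  structure(c(HI = -0.397, SL = -0.348, WT_GATE = 0.184, LO = 0.597,
              bias = -0.560),
            class = "calibration", source = "published_preset")
}

## coerce gate predictions into an n x 4 matrix in CALIBRATION_GATES order
as_gate_matrix <- function(log2er) {
  if (is.null(dim(log2er))) log2er <- matrix(log2er, nrow = 1L,
                                             dimnames = list(NULL,
                                                             names(log2er)))
  log2er <- as.matrix(log2er)
  if (is.null(colnames(log2er))) {
    if (ncol(log2er) != 4L) stop("expected 4 gate columns")
    colnames(log2er) <- CALIBRATION_GATES
  }
  missing <- setdiff(CALIBRATION_GATES, colnames(log2er))
  if (length(missing)) {
    stop("missing gate value(s): ", paste(missing, collapse = ", "))
  }
  m <- log2er[, CALIBRATION_GATES, drop = FALSE]
  if (anyNA(m)) stop("missing gate value(s): NA in log2 ER input")
  m
}

#' Fit the gate-to-ddG calibration by ordinary least squares
#'
#' Regresses experimental ddG_bind measurements on the four predicted log2
#' enrichment ratios plus an intercept, minimizing mean squared error.
#'
#' @param log2er Matrix (one row per measured variant) with columns
#'   `HI`, `SL`, `WT_GATE`, `LO` of model-predicted log2 ER values.
#' @param ddg_exp Numeric vector of experimental ddG_bind values
#'   (kcal/mol), same length as `nrow(log2er)`; at least 5 (one per
#'   unknown).
#' @return Object of class `calibration` with `fit` attributes
#'   (`r_squared`, `n`).
#' @export
fit_calibration <- function(log2er, ddg_exp) {
  x <- as_gate_matrix(log2er)
  if (nrow(x) != length(ddg_exp)) stop("row/measurement count mismatch")
  if (length(ddg_exp) < 5L) {
    stop("at least 5 measurements are needed to fit 4 weights + bias")
  }
  design <- cbind(x, bias = 1)
  fit <- stats::lm.fit(design, ddg_exp)
  if (fit$rank < ncol(design)) {
    stop("rank-deficient design: the gate log2 ER values are collinear; ",
         "provide more or more varied measurements")
  }
  co <- fit$coefficients[c(CALIBRATION_GATES, "bias")]
  res <- ddg_exp - design %*% co
  structure(stats::setNames(as.numeric(co), c(CALIBRATION_GATES, "bias")),
            class = "calibration", source = "fitted",
            fit = list(n = length(ddg_exp),
                       r_squared = 1 - sum(res^2) /
                         sum((ddg_exp - mean(ddg_exp))^2)))
}

#' Apply a calibration to gate log2 enrichment ratios
#'
#' @param coeffs A `calibration` ([calibration_preset()] or
#'   [fit_calibration()]).
#' @param log2er Named numeric of length 4, or a matrix with gate columns.
#' @return Numeric ddG_bind values (kcal/mol), one per input row.
#' @export
apply_calibration <- function(coeffs, log2er) {
  stopifnot(inherits(coeffs, "calibration"), all(is.finite(coeffs)))
  x <- as_gate_matrix(log2er)
  as.numeric(x %*% coeffs[CALIBRATION_GATES] + coeffs[["bias"]])
}

#' @export
print.calibration <- function(x, ...) {
  cat("ddG_bind calibration (", attr(x, "source"), "):\n  ", sep = "")
  cat(sprintf("%+.3f log2ER_%s", as.numeric(x[CALIBRATION_GATES]),
              c("HI", "SL", "WT", "LO")), sprintf("%+.3f", x[["bias"]]),
      sep = " ")
  cat("\n")
  invisible(x)
}

#' Anchor predicted ddG values to the wild type
#'
#' Subtracts each seed's predicted wild-type value from all of that seed's
#' predictions, so the wild type is exactly 0 for every seed and variant
#' rank order within a seed is preserved.
#'
#' @param ddg Numeric matrix, variants x seeds, with a row named `"WT"`
#'   (or a vector with a `"WT"` element).
#' @return Same shape, wild-type row identically 0.
#' @export
normalize_to_wt <- function(ddg) {
  vec <- is.null(dim(ddg))
  m <- if (vec) matrix(ddg, ncol = 1L, dimnames = list(names(ddg))) else ddg
  wt <- match("WT", rownames(m))
  if (is.na(wt)) stop("no wild-type ('WT') row to normalize against")
  out <- sweep(m, 2L, m[wt, ], "-")
  if (vec) out[, 1L] else out
}

#' Read a literature measurement table
#'
#' TSV with columns `variant_id` (notation `K15Y` / `K15Y_R39A`), `ddg_exp`
#' and optionally `source`; variants must lie within the library positions.
#'
#' @param path TSV file path.
#' @param cfg A [reference_config()].
#' @return data.frame with parsed genotype columns.
#' @export
read_literature_table <- function(path, cfg) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("variant_id", "ddg_exp") %in% names(x))) {
    stop("literature table needs columns variant_id and ddg_exp")
  }
  p <- parse_variants(x$variant_id)
  ok <- is.na(p$pos1) | p$pos1 %in% cfg$mutable_positions
  ok <- ok & (is.na(p$pos2) | p$pos2 %in% cfg$mutable_positions)
  if (!all(ok)) {
    stop("measurement variant(s) outside the library positions: ",
         paste(x$variant_id[!ok], collapse = ", "))
  }
  cbind(x, p[, c("n_sub", "pos1", "aa1", "pos2", "aa2")])
}
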