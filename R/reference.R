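#' @keywords internal
"_PACKAGE"

#' The 20 standard amino acids, alphabetical
#'
#' Fixed alphabetical ordering used everywhere a one-hot block or an
#' amino-acid index is needed; any fixed order would do, this one is chosen
#' once for determinism.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' BPTI reference sequence, residues 1-54
#'
#' Mature bovine pancreatic trypsin inhibitor chain (UniProt P00974),
#' truncated to the 54 N-terminal residues covered by the sequencing
#' amplicon.
#' @export
BPTI_WT <- "RPDFCLEPPYTGPCKARIIRYFYNAKAGLCQTFVYGGCRAKRNNFKSAEDCMRT"

#' The 12 mutable interface positions of the BPTI library
#' @export
BPTI_POSITIONS <- c(11L, 12L, 13L, 15L, 16L, 17L, 18L, 34L, 35L, 36L, 37L, 39L)

#' Reference configuration for a mutational library
#'
#' Bundles the wild-type protein sequence, the set of mutable residue
#' positions, the primer marking the start of the coding region in a raw
#' read, and the minimum coding length. Defaults describe the
#' BPTI-chymotrypsin interface library: residues 1-54 of BPTI with 12
#' mutable interface positions.
#'
#' @param wt_protein Wild-type amino-acid sequence (single string).
#' @param mutable_positions Integer vector of 1-based residue positions at
#'   which substitutions are allowed. Must be distinct, sorted, within the
#'   protein.
#' @param primer DNA string marking the start of the coding region.
#' @param min_coding_length_nt Minimum coding-region length in nucleotides;
#'   defaults to three times the protein length.
#' @return An object of class `reference_config`.
#' @examples
#' cfg <- reference_config()
#' cfg$mutable_positions
#' @export
reference_config <- function(wt_protein = BPTI_WT,
                             mutable_positions = BPTI_POSITIONS,
                             primer = "TAGC",
                             min_coding_length_nt = 3L * nchar(wt_protein)) {
  stopifnot(is.character(wt_protein), length(wt_protein) == 1L)
  n <- nchar(wt_protein)
  aa <- strsplit(wt_protein, "")[[1]]
  if (!all(aa %in% AA_ALPHABET)) {
    stop("wt_protein contains non-standard amino-acid letters")
  }
  mutable_positions <- as.integer(mutable_positions)
  if (anyDuplicated(mutable_positions) ||
      is.unsorted(mutable_positions, strictly = TRUE) ||
      any(mutable_positions < 1L) || any(mutable_positions > n)) {
    stop("mutable_positions must be distinct, strictly sorted, and within [1, ",
         n, "]")
  }
  if (!grepl("^[ACGT]+$", primer)) stop("primer must be a DNA string (ACGT)")
  structure(
    list(wt_protein = wt_protein,
         wt_residues = aa,
         mutable_positions = mutable_positions,
         primer = primer,
         min_coding_length_nt = as.integer(min_coding_length_nt)),
    class = "reference_config")
}

#' @export
print.reference_config <- function(x, ...) {
  cat("Reference configuration\n")
  cat("  protein length :", nchar(x$wt_protein), "residues\n")
  cat("  mutable positions:", paste(x$mutable_positions, collapse = ", "), "\n")
  cat("  primer:", x$primer, " min coding length:",
      x$min_coding_length_nt, "nt\n")
  invisible(x)
}

#' Gate identifiers
#'
#' The four affinity selection gates (high affinity, wild-type-like,
#' slightly lower than wild type, low affinity) plus the pre-sort library.
#' `PRESORT` is never a selection gate; `WT_GATE` names the wild-type-like
#' gate, distinct from the wild-type *variant*.
#' @export
GATES <- c("HI", "WT_GATE", "SL", "LO")

#' @rdname GATES
#' @export
PRESORT <- "PRESORT"

## ---- variant identifiers -------------------------------------------------
## A variant is named "WT", "K15Y" or "K15Y_R39A": wild-type residue,
## 1-based position, substituting residue, substitutions sorted by position.

#' Build canonical variant identifiers
#'
#' @param positions Integer vector (length 0, 1 or 2) of residue positions.
#' @param aas Character vector of substituting amino acids, same length.
#' @param cfg A [reference_config()].
#' @return A single variant id string such as `"WT"`, `"K15Y"` or
#'   `"K15Y_R39A"`.
#' @export
variant_id <- function(positions, aas, cfg) {
  if (length(positions) == 0L) return("WT")
  stopifnot(length(positions) == length(aas))
  o <- order(positions)
  positions <- positions[o]; aas <- aas[o]
  if (anyDuplicated(positions)) stop("duplicate positions in one genotype")
  wt <- cfg$wt_residues[positions]
  if (any(wt == aas)) stop("substitution equal to the wild-type residue")
  paste(paste0(wt, positions, aas), collapse = "_")
}

#' Parse variant identifiers into positions and amino acids
#'
#' @param ids Character vector of variant ids (`"WT"`, `"K15Y"`,
#'   `"K15Y_R39A"`).
#' @return A data.frame with columns `variant_id`, `n_sub`, `pos1`, `aa1`,
#'   `pos2`, `aa2` (`NA` where absent).
#' @export
parse_variants <- function(ids) {
  if (length(ids) == 0L) {
    return(data.frame(variant_id = character(), n_sub = integer(),
                      pos1 = integer(), aa1 = character(),
                      pos2 = integer(), aa2 = character(),
                      stringsAsFactors = FALSE))
  }
  out <- data.frame(variant_id = ids, n_sub = 0L,
                    pos1 = NA_integer_, aa1 = NA_character_,
                    pos2 = NA_integer_, aa2 = NA_character_,
                    stringsAsFactors = FALSE)
  nonwt <- ids != "WT"
  if (!any(nonwt)) return(out)
  parts <- strsplit(ids[nonwt], "_", fixed = TRUE)
  ns <- lengths(parts)
  if (any(ns > 2L)) stop("variant ids with more than two substitutions")
  pos <- function(tok) as.integer(sub("^[A-Z]([0-9]+)[A-Z]$", "\\1", tok))
  sub_aa <- function(tok) sub("^[A-Z][0-9]+([A-Z])$", "\\1", tok)
  first <- vapply(parts, `[`, character(1), 1L)
  out$n_sub[nonwt] <- as.integer(ns)
  out$pos1[nonwt] <- pos(first)
  out$aa1[nonwt] <- sub_aa(first)
  two <- nonwt
  two[nonwt] <- ns == 2L
  if (any(two)) {
    second <- vapply(parts[ns == 2L], `[`, character(1), 2L)
    out$pos2[two] <- pos(second)
    out$aa2[two] <- sub_aa(second)
  }
  out
}

#' Reconstruct full-length mutant protein sequences
#'
#' @param ids Character vector of variant ids.
#' @param cfg A [reference_config()].
#' @return Character vector of protein sequences.
#' @export
variant_protein <- function(ids, cfg) {
  p <- parse_variants(ids)
  vapply(seq_along(ids), function(i) {
    aa <- cfg$wt_residues
    if (p$n_sub[i] >= 1L) aa[p$pos1[i]] <- p$aa1[i]
    if (p$n_sub[i] == 2L) aa[p$pos2[i]] <- p$aa2[i]
    paste(aa, collapse = "")
  }, character(1))
}

#' Enumerate the complete variant universe
#'
#' All genotypes with zero, one or two substitutions at the mutable
#' positions: the wild type, 19 substitutions x P positions singles, and
#' 19 x 19 x choose(P, 2) doubles. For the 12-position BPTI library this is
#' 1 + 228 + 23,826 = 24,055 genotypes.
#'
#' @param cfg A [reference_config()].
#' @param max_order 1 to stop at singles, 2 (default) for singles + doubles.
#' @return A data.frame in canonical order (WT, then singles by position and
#'   amino acid, then doubles) with columns `variant_id`, `n_sub`, `pos1`,
#'   `aa1`, `pos2`, `aa2`.
#' @export
enumerate_variant_space <- function(cfg, max_order = 2L) {
  pos <- cfg$mutable_positions
  singles <- do.call(rbind, lapply(pos, function(p) {
    wt <- cfg$wt_residues[p]
    aas <- setdiff(AA_ALPHABET, wt)
    data.frame(n_sub = 1L, pos1 = p, aa1 = aas,
               pos2 = NA_integer_, aa2 = NA_character_,
               stringsAsFactors = FALSE)
  }))
  rows <- list(
    data.frame(n_sub = 0L, pos1 = NA_integer_, aa1 = NA_character_,
               pos2 = NA_integer_, aa2 = NA_character_,
               stringsAsFactors = FALSE),
    singles)
  if (max_order >= 2L && length(pos) >= 2L) {
    pairs <- utils::combn(pos, 2L)
    doubles <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
      p1 <- pairs[1L, k]; p2 <- pairs[2L, k]
      a1 <- setdiff(AA_ALPHABET, cfg$wt_residues[p1])
      a2 <- setdiff(AA_ALPHABET, cfg$wt_residues[p2])
      g <- expand.grid(aa2 = a2, aa1 = a1, stringsAsFactors = FALSE)
      data.frame(n_sub = 2L, pos1 = p1, aa1 = g$aa1,
                 pos2 = p2, aa2 = g$aa2, stringsAsFactors = FALSE)
    }))
    rows <- c(rows, list(doubles))
  }
  out <- do.call(rbind, rows)
  wt1 <- cfg$wt_residues[out$pos1]
  wt2 <- cfg$wt_residues[out$pos2]
  out$variant_id <- ifelse(
    out$n_sub == 0L, "WT",
    ifelse(out$n_sub == 1L,
           paste0(wt1, out$pos1, out$aa1),
           paste0(wt1, out$pos1, out$aa1, "_", wt2, out$pos2, out$aa2)))
  rownames(out) <- NULL
  out[, c("variant_id", "n_sub", "pos1", "aa1", "pos2", "aa2")]
}

#' Ids of the two component singles of a double mutant
#'
#' @param ids Character vector of double-mutant variant ids.
#' @return A two-column character matrix (`single1`, `single2`).
#' @export
component_singles <- function(ids) {
  parts <- strsplit(ids, "_", fixed = TRUE)
  if (any(lengths(parts) != 2L)) stop("all ids must be double mutants")
  cbind(single1 = vapply(parts, `[`, character(1), 1L),
        single2 = vapply(parts, `[`, character(1), 2L))
}

#' Observed-versus-possible coverage percentages
#'
#' @param observed Integer vector of observed variant counts.
#' @param possible Matching vector of theoretical library sizes.
#' @return Numeric vector of percentages (0-100).
#' @examples
#' coverage_percent(213, 228) # 93.4
#' @export
coverage_percent <- function(observed, possible) {
  stopifnot(all(observed >= 0), all(possible > 0), all(observed <= possible))
  100 * observed / possible
}

## Deterministic seed derivation: one master seed fans out to per-stage
## seeds via a polynomial string hash, kept below 2^31.
#' Derive a stage seed from a master seed and a label
#'
#' @param seed Master integer seed.
#' @param label Character label of the consuming stage.
#' @return An integer seed in [1, 2^31 - 2].
#' @export
derive_seed <- function(seed, label) {
  h <- as.double(seed %% 2147483647L)
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h %% 2147483646) + 1L
}
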