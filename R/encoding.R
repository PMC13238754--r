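## Model input representation: one-hot over the mutable positions
## concatenated with a per-variant embedding averaged over those positions.

#' One-hot encode a variant over the mutable positions
#'
#' One 20-way block per mutable position, blocks ordered by position,
#' amino acids ordered alphabetically ([AA_ALPHABET]). Every block encodes
#' the variant's actual residue, so the wild type is representable (one hot
#' entry per position, P ones in total; 12 x 20 = 240 features for the
#' default library).
#'
#' @param ids Character vector of variant ids.
#' @param cfg A [reference_config()].
#' @return Numeric matrix `length(ids)` x `20 * P` with named columns
#'   `pos<p>_<aa>`.
#' @export
onehot_encode <- function(ids, cfg) {
  pos <- cfg$mutable_positions
  p <- length(pos)
  cols <- paste0("pos", rep(pos, each = 20L), "_", rep(AA_ALPHABET, p))
  if (length(ids) == 0L) {
    return(matrix(0, 0L, 20L * p, dimnames = list(NULL, cols)))
  }
  geno <- parse_variants(ids)
  # start from the wild-type residue in every block, then apply substitutions
  res <- matrix(rep(cfg$wt_residues[pos], each = length(ids)),
                nrow = length(ids))
  s1 <- which(geno$n_sub >= 1L)
  res[cbind(s1, match(geno$pos1[s1], pos))] <- geno$aa1[s1]
  s2 <- which(geno$n_sub == 2L)
  res[cbind(s2, match(geno$pos2[s2], pos))] <- geno$aa2[s2]
  m <- matrix(0, nrow = length(ids), ncol = 20L * p,
              dimnames = list(ids, cols))
  for (j in seq_len(p)) {
    m[cbind(seq_along(ids), (j - 1L) * 20L + match(res[, j], AA_ALPHABET))] <- 1
  }
  m
}

#' Deterministic hash-based embedding provider
#'
#' A stand-in protein embedding: every (residue identity, sequence position)
#' pair maps to a fixed pseudo-random D-vector drawn from a seeded stream,
#' so identical sequences always yield identical embedding matrices and no
#' model download is needed. Unlike a real protein language model the stub
#' is context-free: a residue's vector does not depend on its neighbours.
#' Real pretrained embeddings can be plugged in through the same interface
#' (a function from a protein sequence to an L x D matrix).
#'
#' @param dim Embedding dimension D (0 allowed: features reduce to the
#'   one-hot block).
#' @param max_len Maximum sequence length supported.
#' @param seed Integer seed of the hash stream.
#' @return Object of class `embedding_provider`: list with `name`, `dim`,
#'   `deterministic` and `embed(sequence)`.
#' @export
hash_embedding_provider <- function(dim = 64L, max_len = 54L, seed = 1L) {
  dim <- as.integer(dim)
  stopifnot(dim >= 0L, max_len >= 1L)
  # precompute the (aa, position) -> vector table once
  tab <- array(0, dim = c(20L, max_len, max(dim, 1L)))
  if (dim > 0L) {
    for (a in 1:20) {
      for (i in seq_len(max_len)) {
        with_seed(derive_seed(seed, paste0("emb:", AA_ALPHABET[a], ":", i)), {
          tab[a, i, ] <- stats::rnorm(dim)
        })
      }
    }
  }
  structure(
    list(name = sprintf("hash%d", dim), dim = dim, deterministic = TRUE,
         embed = function(sequence) {
           aa <- strsplit(sequence, "")[[1]]
           if (length(aa) > max_len) stop("sequence longer than max_len")
           if (dim == 0L) return(matrix(0, length(aa), 0L))
           idx <- match(aa, AA_ALPHABET)
           if (anyNA(idx)) stop("non-standard residue in sequence")
           t(vapply(seq_along(aa), function(i) tab[idx[i], i, ],
                    numeric(dim)))
         }),
    class = "embedding_provider")
}

#' Constant embedding provider (testing aid)
#'
#' Every residue maps to the same fixed row vector.
#' @param row Numeric vector; the per-residue embedding.
#' @return An `embedding_provider`.
#' @export
constant_embedding_provider <- function(row) {
  structure(
    list(name = "constant", dim = length(row), deterministic = TRUE,
         embed = function(sequence) {
           matrix(rep(row, each = nchar(sequence)), nrow = nchar(sequence))
         }),
    class = "embedding_provider")
}

#' Embed variants by averaging over the mutable positions
#'
#' Reconstructs each full-length mutant sequence, obtains per-residue
#' embeddings from the provider, and averages the rows at the mutable
#' positions.
#'
#' @param ids Character vector of variant ids.
#' @param provider An `embedding_provider`.
#' @param cfg A [reference_config()].
#' @return Numeric matrix `length(ids)` x D.
#' @export
embed_variant <- function(ids, provider, cfg) {
  stopifnot(inherits(provider, "embedding_provider"))
  if (provider$dim == 0L) {
    return(matrix(0, length(ids), 0L, dimnames = list(ids, NULL)))
  }
  seqs <- variant_protein(ids, cfg)
  out <- t(vapply(seqs, function(s) {
    e <- tryCatch(provider$embed(s),
                  error = function(err) stop("embedding provider '",
                                             provider$name, "' failed: ",
                                             conditionMessage(err)))
    colMeans(e[cfg$mutable_positions, , drop = FALSE])
  }, numeric(provider$dim)))
  rownames(out) <- ids
  colnames(out) <- paste0("emb", seq_len(provider$dim))
  out
}

#' Build the combined feature matrix
#'
#' Flattened one-hot encoding concatenated with the averaged embedding:
#' `20 * P + D` columns (240 + D for the default library). Row order is
#' preserved; construction is pure, so repeated calls are bit-identical.
#'
#' @param ids Character vector of variant ids.
#' @param provider An `embedding_provider`.
#' @param cfg A [reference_config()].
#' @return Numeric matrix with attribute `embed_cols` (the column indices of
#'   the embedding block, used for standardization at training time).
#' @export
build_feature_matrix <- function(ids, provider, cfg) {
  oh <- onehot_encode(ids, cfg)
  if (length(ids) == 0L) {
    m <- cbind(oh, matrix(0, 0L, provider$dim))
  } else {
    m <- cbind(oh, embed_variant(ids, provider, cfg))
  }
  attr(m, "embed_cols") <- if (provider$dim > 0L) {
    ncol(oh) + seq_len(provider$dim)
  } else integer()
  m
}
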