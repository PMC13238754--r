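## Synthetic sort-seq generator: a planted additive + sparse-epistasis
## affinity landscape, Gaussian-kernel gate occupancy, multinomial read
## sampling, and injected corrupt reads exercising every filter rule.

## One fixed codon per amino acid; the filter pipeline only needs
## protein-level fidelity, so synonymous diversity is not simulated.
CODON_TABLE <- c(A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT",
                 G = "GGT", H = "CAT", I = "ATT", K = "AAA", L = "CTG",
                 M = "ATG", N = "AAT", P = "CCG", Q = "CAA", R = "CGT",
                 S = "TCT", T = "ACT", V = "GTT", W = "TGG", Y = "TAT")

## run code under a temporary RNG state so generators do not clobber the
## caller's random stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Encode proteins as coding DNA
#'
#' @param proteins Character vector of protein sequences.
#' @return Character vector of coding DNA (no primer).
#' @export
protein_to_dna <- function(proteins) {
  vapply(strsplit(proteins, ""), function(aa) {
    paste(CODON_TABLE[aa], collapse = "")
  }, character(1))
}

#' Plant a ground-truth affinity landscape
#'
#' Samples an additive per-substitution effect for every single mutant and a
#' sparse pairwise epistasis term for a configurable fraction of doubles.
#' The double-mutant truth follows the double-mutant-cycle convention
#' `ddg_ij = e_i + e_j - epsilon_ij`, so `epsilon = e_i + e_j - ddg_ij`
#' recovers the planted term; the wild type is 0 by definition.
#'
#' @param cfg A [reference_config()].
#' @param single_mean,single_sd Normal distribution of single-substitution
#'   effects (kcal/mol); the positive default mean reflects that most
#'   interface mutations are deleterious.
#' @param epistasis_fraction Fraction of double mutants with nonzero
#'   planted epistasis.
#' @param epistasis_sd SD of the nonzero epistasis terms (kcal/mol).
#' @param seed Integer seed; the same seed reproduces the landscape
#'   bit-exactly.
#' @return Object of class `planted_landscape`: list with `universe` (the
#'   full variant table plus `ddg_true`, `eps_true`), `single_effects`
#'   (named vector) and `params`.
#' @export
plant_landscape <- function(cfg, single_mean = 0.5, single_sd = 1.2,
                            epistasis_fraction = 0.15, epistasis_sd = 1.0,
                            seed = 1L) {
  stopifnot(epistasis_fraction >= 0, epistasis_fraction <= 1,
            single_sd >= 0, epistasis_sd >= 0)
  uni <- enumerate_variant_space(cfg)
  with_seed(derive_seed(seed, "plant_landscape"), {
    is_s <- uni$n_sub == 1L
    is_d <- uni$n_sub == 2L
    e <- stats::setNames(stats::rnorm(sum(is_s), single_mean, single_sd),
                         uni$variant_id[is_s])
    eps <- numeric(sum(is_d))
    if (epistasis_fraction > 0 && sum(is_d) > 0) {
      hot <- sample(sum(is_d), round(epistasis_fraction * sum(is_d)))
      eps[hot] <- stats::rnorm(length(hot), 0, epistasis_sd)
    }
    uni$ddg_true <- 0
    uni$eps_true <- NA_real_
    uni$ddg_true[is_s] <- as.numeric(e)
    if (sum(is_d)) {
      comp <- component_singles(uni$variant_id[is_d])
      uni$ddg_true[is_d] <- e[comp[, 1L]] + e[comp[, 2L]] - eps
      uni$eps_true[is_d] <- eps
    }
    structure(
      list(universe = uni, single_effects = e, cfg = cfg,
           params = list(single_mean = single_mean, single_sd = single_sd,
                         epistasis_fraction = epistasis_fraction,
                         epistasis_sd = epistasis_sd, seed = seed)),
      class = "planted_landscape")
  })
}

#' Look up planted ground truth for variants
#'
#' @param landscape A [plant_landscape()] result.
#' @param ids Variant ids.
#' @return data.frame with `variant_id`, `ddg_true`, `eps_true`.
#' @export
true_values <- function(landscape, ids) {
  i <- match(ids, landscape$universe$variant_id)
  if (anyNA(i)) stop("unknown variant id(s)")
  landscape$universe[i, c("variant_id", "ddg_true", "eps_true")]
}

#' Gaussian gate-occupancy model
#'
#' Stand-in for the experimental FACS windows: a cell carrying a variant
#' with true binding change x (plus Gaussian cell-to-cell noise) falls into
#' gate g with probability proportional to a Gaussian kernel centred at the
#' gate's position on the ddG axis. Gate centres must be ordered
#' HI < WT_GATE < SL < LO (lower ddG = tighter binding = higher affinity).
#'
#' @param gate_centers Named numeric of length 4 (HI, WT_GATE, SL, LO).
#' @param bandwidth Kernel SD (kcal/mol).
#' @param cell_noise_sd SD of the per-variant measurement noise added to
#'   the true ddG before gating (kcal/mol).
#' @return Object of class `gate_binning`.
#' @export
gate_binning_model <- function(gate_centers = c(HI = -1.5, WT_GATE = 0,
                                                SL = 1.5, LO = 3),
                               bandwidth = 1.2, cell_noise_sd = 0.2) {
  stopifnot(identical(names(gate_centers), GATES), bandwidth > 0,
            cell_noise_sd >= 0)
  if (is.unsorted(gate_centers, strictly = TRUE)) {
    stop("gate_centers must satisfy HI < WT_GATE < SL < LO")
  }
  structure(list(gate_centers = gate_centers, bandwidth = bandwidth,
                 cell_noise_sd = cell_noise_sd), class = "gate_binning")
}

#' Per-variant gate probabilities
#'
#' @param binning A [gate_binning_model()].
#' @param x Numeric vector of (noisy) ddG values.
#' @return Matrix `length(x)` x 4, rows summing to 1.
#' @export
gate_probabilities <- function(binning, x) {
  k <- vapply(binning$gate_centers, function(c0) {
    exp(-((x - c0)^2) / (2 * binning$bandwidth^2))
  }, numeric(length(x)))
  k <- matrix(k, nrow = length(x), dimnames = list(NULL, GATES))
  k / rowSums(k)
}

#' Simulation configuration for the synthetic sorter
#'
#' @param n_variants Number of library variants sampled (wild type and all
#'   singles first, then random doubles).
#' @param presort_reads Sequencing depth of the pre-sort library.
#' @param reads_per_gate Depth per selection gate; scalar or named vector
#'   over `GATES`. A gate with 0 reads yields an empty read set and is
#'   flagged.
#' @param abundance_meanlog,abundance_sdlog Log-normal pre-sort abundance
#'   distribution.
#' @param corrupted_read_fraction Fraction of each fraction's reads replaced
#'   by corrupt reads (no primer / too short / invalid base / off-target
#'   mutation, in equal parts).
#' @param seed Integer master seed; fixes the output bit-exactly.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_variants = 2000L, presort_reads = 100000L,
                              reads_per_gate = 50000L,
                              abundance_meanlog = 0,
                              abundance_sdlog = 0.7,
                              corrupted_read_fraction = 0.05, seed = 1L) {
  if (length(reads_per_gate) == 1L) {
    reads_per_gate <- stats::setNames(rep(reads_per_gate, 4L), GATES)
  }
  stopifnot(identical(sort(names(reads_per_gate)), sort(GATES)),
            n_variants >= 1L, presort_reads > 0L, all(reads_per_gate >= 0L),
            corrupted_read_fraction >= 0, corrupted_read_fraction < 1)
  structure(list(n_variants = as.integer(n_variants),
                 presort_reads = as.integer(presort_reads),
                 reads_per_gate = reads_per_gate[GATES],
                 abundance_meanlog = abundance_meanlog,
                 abundance_sdlog = abundance_sdlog,
                 corrupted_read_fraction = corrupted_read_fraction,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

## corrupt read constructors, one per filter rule
corrupt_reads <- function(n, cfg) {
  if (n == 0L) return(character())
  wt_coding <- protein_to_dna(cfg$wt_protein)
  off_prot <- cfg$wt_residues
  off_pos <- setdiff(seq_along(off_prot), cfg$mutable_positions)
  off_pos <- if (20L %in% off_pos) 20L else off_pos[1L]
  off_prot[off_pos] <- setdiff(AA_ALPHABET, off_prot[off_pos])[1L]
  bad_base <- wt_coding
  substr(bad_base, 10L, 10L) <- "N"
  kinds <- c(
    no_primer = strrep("AC", nchar(wt_coding) %/% 2L + 2L),
    too_short = paste0(cfg$primer, substr(wt_coding, 1L, 120L)),
    invalid_base = paste0(cfg$primer, bad_base),
    off_target = paste0(cfg$primer, protein_to_dna(paste(off_prot, collapse = ""))))
  unname(kinds[(seq_len(n) - 1L) %% 4L + 1L])
}

#' Simulate a sorted-library sequencing experiment
#'
#' Samples a variant library from the planted landscape, draws log-normal
#' pre-sort abundances, assigns cells to gates with Gaussian-kernel
#' probabilities evaluated at the true ddG plus noise, samples reads
#' multinomially per fraction at the configured depth, encodes genotypes as
#' primer-prefixed DNA, and injects corrupt reads at the configured
#' fraction.
#'
#' @param landscape A [plant_landscape()] result.
#' @param binning A [gate_binning_model()].
#' @param simcfg A [simulation_config()].
#' @return Object of class `sortseq_sim`: list with `reads` (named list of
#'   character vectors, `PRESORT` plus the four gates), `truth` (data.frame
#'   `variant_id`, `ddg_true`, `eps_true` for the sampled library),
#'   `empty_gates` (gates simulated at zero depth) and the configs.
#' @export
simulate_sort <- function(landscape, binning, simcfg) {
  stopifnot(inherits(landscape, "planted_landscape"),
            inherits(binning, "gate_binning"),
            inherits(simcfg, "simulation_config"))
  cfg <- landscape$cfg
  uni <- landscape$universe
  with_seed(derive_seed(simcfg$seed, "simulate_sort"), {
    base_ids <- uni$variant_id[uni$n_sub <= 1L]
    dbl_ids <- uni$variant_id[uni$n_sub == 2L]
    n <- simcfg$n_variants
    ids <- if (n <= length(base_ids)) {
      c("WT", sample(setdiff(base_ids, "WT"), n - 1L))
    } else {
      c(base_ids, sample(dbl_ids, min(n - length(base_ids), length(dbl_ids))))
    }
    tv <- true_values(landscape, ids)
    abundance <- stats::rlnorm(length(ids), simcfg$abundance_meanlog,
                               simcfg$abundance_sdlog)
    x <- tv$ddg_true + stats::rnorm(length(ids), 0, binning$cell_noise_sd)
    p_gate <- gate_probabilities(binning, x)
    dna <- paste0(cfg$primer, protein_to_dna(variant_protein(ids, cfg)))

    draw_fraction <- function(depth, weights) {
      if (depth == 0L) return(character())
      n_bad <- round(depth * simcfg$corrupted_read_fraction)
      cnt <- stats::rmultinom(1L, depth - n_bad, weights)[, 1L]
      reads <- c(rep(dna, cnt), corrupt_reads(n_bad, cfg))
      sample(reads)
    }
    reads <- c(
      list(PRESORT = draw_fraction(simcfg$presort_reads, abundance)),
      stats::setNames(lapply(GATES, function(g) {
        draw_fraction(simcfg$reads_per_gate[[g]], abundance * p_gate[, g])
      }), GATES))
    structure(
      list(reads = reads, truth = tv,
           empty_gates = GATES[simcfg$reads_per_gate == 0L],
           abundance = stats::setNames(abundance, ids),
           landscape_params = landscape$params, binning = binning,
           simcfg = simcfg, cfg = cfg),
      class = "sortseq_sim")
  })
}

#' Synthetic literature-style calibration table
#'
#' Emulates a curated set of experimentally measured binding free-energy
#' changes: planted truth plus Gaussian measurement noise for a sample of
#' single and double mutants.
#'
#' @param landscape A [plant_landscape()] result.
#' @param n_singles,n_doubles Numbers of single-/double-mutant rows.
#' @param noise_sd Measurement noise SD (kcal/mol).
#' @param seed Integer seed.
#' @param pool Optional character vector restricting the variants that can
#'   be drawn (e.g. to library members actually observed).
#' @return data.frame `variant_id`, `n_sub`, `ddg_exp`, `source`.
#' @export
emit_literature_table <- function(landscape, n_singles = 27L, n_doubles = 10L,
                                  noise_sd = 0.1, seed = 1L, pool = NULL) {
  uni <- landscape$universe
  if (!is.null(pool)) uni <- uni[uni$variant_id %in% pool, ]
  singles <- uni$variant_id[uni$n_sub == 1L]
  doubles <- uni$variant_id[uni$n_sub == 2L]
  if (n_singles > length(singles) || n_doubles > length(doubles)) {
    stop("requested more measurements than available variants")
  }
  with_seed(derive_seed(seed, "emit_literature_table"), {
    ids <- c(sample(singles, n_singles), sample(doubles, n_doubles))
    tv <- true_values(landscape, ids)
    data.frame(variant_id = ids,
               n_sub = ifelse(seq_along(ids) <= n_singles, 1L, 2L),
               ddg_exp = tv$ddg_true + stats::rnorm(length(ids), 0, noise_sd),
               source = "synthetic_literature", stringsAsFactors = FALSE)
  })
}

#' Write simulated reads and ground truth to disk
#'
#' @param sim A [simulate_sort()] result.
#' @param dir Output directory (created if missing).
#' @param format `"fastq"` (dummy qualities) or `"lines"`.
#' @return Invisibly, a named vector of written file paths.
#' @export
write_sim_reads <- function(sim, dir, format = c("fastq", "lines")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (format == "fastq") ".fastq" else ".txt"
  paths <- c()
  for (g in names(sim$reads)) {
    p <- file.path(dir, paste0(tolower(g), ext))
    reads <- sim$reads[[g]]
    if (format == "fastq" && length(reads)) {
      qual <- vapply(nchar(reads), function(n) strrep("I", n), character(1))
      writeLines(paste0("@read", seq_along(reads), "\n", reads, "\n+\n", qual), p)
    } else {
      writeLines(reads, p)
    }
    paths[g] <- p
  }
  tp <- file.path(dir, "ground_truth.tsv")
  utils::write.table(sim$truth, tp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths["truth"] <- tp
  invisible(paths)
}
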