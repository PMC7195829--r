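## Approximate background amino-acid frequencies of SwissProt, PSI-BLAST
## residue order. Used as the sampling distribution for synthetic sequences.
AA_BACKGROUND <- c(A = 0.083, R = 0.055, N = 0.041, D = 0.055, C = 0.014,
                   Q = 0.039, E = 0.068, G = 0.071, H = 0.023, I = 0.060,
                   L = 0.097, K = 0.058, M = 0.024, F = 0.039, P = 0.047,
                   S = 0.066, T = 0.053, W = 0.011, Y = 0.029, V = 0.069)

#' Synthetic-dataset configuration
#'
#' Defines the class-dependent signal structure of generated data: which
#' fraction of catalog domains a protein carries, how strongly positives are
#' enriched in a chosen residue set, and how strongly designated PSSM columns
#' of positives are shifted toward conservation.
#'
#' Defaults emulate an ECM-versus-intracellular screen at the 1:21 class
#' imbalance of a realistic training corpus: positives are multidomain
#' (almost every positive carries at least one catalog domain), negatives
#' rarely carry one, positives are enriched in Gly/Pro/Cys (collagen-like
#' composition) and carry elevated conservation on four designated PSSM
#' columns.
#'
#' @param n_pos,n_neg Class sizes.
#' @param seq_len_range Inclusive (min, max) sequence length; min >= 4
#'   (PSSM-descriptor precondition).
#' @param p_domain_pos,p_domain_neg Per-domain assignment probability for
#'   positives / negatives.
#' @param composition_shift Total probability mass moved onto
#'   `enriched_residues` when sampling positive-class residues.
#' @param pssm_signal Mean offset added to the designated `signal_columns`
#'   of positive-class PSSM scores.
#' @param signal_columns Indices (1..20, PSI-BLAST order) of the designated
#'   conserved columns.
#' @param enriched_residues Residues enriched in positives.
#' @param p_x Per-residue probability of an unknown residue `X`.
#' @param seed Master seed; generation is fully deterministic given it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_pos = 100L, n_neg = 2100L,
                       seq_len_range = c(50L, 300L),
                       p_domain_pos = 0.10, p_domain_neg = 0.005,
                       composition_shift = 0.15, pssm_signal = 2,
                       signal_columns = 1:4,
                       enriched_residues = c("G", "P", "C"),
                       p_x = 0.002, seed = 1L) {
  stopifnot(n_pos >= 1L, n_neg >= 1L,
            length(seq_len_range) == 2L, seq_len_range[1] >= 4L,
            seq_len_range[1] <= seq_len_range[2],
            p_domain_pos >= 0, p_domain_pos <= 1,
            p_domain_neg >= 0, p_domain_neg <= 1,
            composition_shift >= 0, pssm_signal >= 0,
            all(signal_columns %in% 1:20),
            all(enriched_residues %in% PSSM_RESIDUES))
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 seq_len_range = as.integer(seq_len_range),
                 p_domain_pos = p_domain_pos, p_domain_neg = p_domain_neg,
                 composition_shift = composition_shift,
                 pssm_signal = pssm_signal,
                 signal_columns = as.integer(signal_columns),
                 enriched_residues = enriched_residues,
                 p_x = p_x, seed = as.integer(seed)),
            class = "sim_config")
}

## One synthetic protein record (sequence, domain set, PSSM matrix).
## Assumes the RNG state is already seeded by the caller.
sim_record <- function(id, positive, config, catalog) {
  L <- sample(seq(config$seq_len_range[1], config$seq_len_range[2]), 1L)
  p <- AA_BACKGROUND
  if (positive && config$composition_shift > 0) {
    enr <- config$enriched_residues
    p[enr] <- p[enr] + config$composition_shift / length(enr)
    p <- p / sum(p)
  }
  chars <- sample(names(p), L, replace = TRUE, prob = p)
  if (config$p_x > 0) {
    xmask <- stats::runif(L) < config$p_x
    chars[xmask] <- "X"
  }
  p_dom <- if (positive) config$p_domain_pos else config$p_domain_neg
  domains <- catalog[stats::runif(length(catalog)) < p_dom]
  scores <- matrix(stats::rnorm(L * 20L, mean = 0, sd = 3), nrow = L)
  if (positive && config$pssm_signal > 0) {
    scores[, config$signal_columns] <-
      scores[, config$signal_columns] + config$pssm_signal
  }
  scores <- pmin(pmax(round(scores), -10L), 10L)
  list(id = id, sequence = paste(chars, collapse = ""),
       domains = domains,
       pssm = pssm(scores, protein_id = id, residues = chars),
       label = if (positive) "ECM" else "nonECM")
}

sim_records <- function(config, catalog) {
  withr::with_seed(config$seed, {
    c(lapply(seq_len(config$n_pos), function(i) {
        sim_record(sprintf("ECM%05d", i), TRUE, config, catalog)
      }),
      lapply(seq_len(config$n_neg), function(i) {
        sim_record(sprintf("NEC%05d", i), FALSE, config, catalog)
      }))
  })
}

#' Render a PSSM as PSI-BLAST ASCII text
#'
#' Emits the `-out_ascii_pssm` layout this package's reader consumes: two
#' header lines, the 20-residue column header, one row per position with the
#' position index, query residue, 20 integer scores and trailing
#' weighted-percentage columns (zeros), and a blank footer line.
#'
#' @param pssm A `pssm` object.
#' @return Character vector of file lines.
#' @export
format_pssm <- function(pssm) {
  res <- attr(pssm, "residues")
  if (is.null(res)) res <- rep("A", nrow(pssm))
  header <- paste0("          ",
                   paste(sprintf("%4s", c(PSSM_RESIDUES, PSSM_RESIDUES)),
                         collapse = ""))
  rows <- vapply(seq_len(nrow(pssm)), function(i) {
    paste0(sprintf("%5d %s  ", i, res[i]),
           paste(sprintf("%4d", pssm[i, ]), collapse = ""),
           "  ",
           paste(sprintf("%4d", rep(0L, 20L)), collapse = ""))
  }, character(1))
  c("", "Last position-specific scoring matrix computed", header, rows, "")
}

#' Generate a synthetic PSSM for one sequence
#'
#' Integer scores are drawn from a discretized normal (sd 3) clipped to
#' [-10, 10], the typical PSI-BLAST log-odds range; when `signal > 0` the
#' designated columns receive that mean offset (emulating class-specific
#' conservation). Uses the current RNG state.
#'
#' @param sequence Amino-acid sequence (length >= 4).
#' @param config A [sim_config()] (provides clip range/columns).
#' @param signal Mean offset applied to `config$signal_columns`.
#' @param protein_id Identifier stamped on the matrix.
#' @return Character vector of ASCII PSSM file lines.
#' @export
generate_pssm <- function(sequence, config = sim_config(), signal = 0,
                          protein_id = "query") {
  L <- nchar(sequence)
  if (L < 4L) stop("sequence too short for a PSSM descriptor (need length >= 4)")
  scores <- matrix(stats::rnorm(L * 20L, mean = 0, sd = 3), nrow = L)
  if (signal > 0) {
    scores[, config$signal_columns] <- scores[, config$signal_columns] + signal
  }
  scores <- pmin(pmax(round(scores), -10L), 10L)
  format_pssm(pssm(scores, protein_id = protein_id,
                   residues = strsplit(sequence, "")[[1]]))
}

#' Generate a complete synthetic dataset on disk
#'
#' Writes `sequences.fasta`, `annotations.tsv`, `labels.tsv`, one ASCII PSSM
#' per protein under `pssm/`, and `truth.json` recording every generator
#' parameter and the per-protein ground truth. Byte-identical for identical
#' configurations (including the seed).
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @param catalog Domain catalog used for assignment.
#' @return Named list of the written paths, invisibly.
#' @export
generate_dataset <- function(config, out_dir,
                             catalog = default_domain_catalog()) {
  dir.create(file.path(out_dir, "pssm"), recursive = TRUE, showWarnings = FALSE)
  recs <- sim_records(config, catalog)
  proteins <- data.frame(id = vapply(recs, `[[`, "", "id"),
                         sequence = vapply(recs, `[[`, "", "sequence"),
                         stringsAsFactors = FALSE)
  paths <- list(fasta = file.path(out_dir, "sequences.fasta"),
                annotations = file.path(out_dir, "annotations.tsv"),
                labels = file.path(out_dir, "labels.tsv"),
                pssm_dir = file.path(out_dir, "pssm"),
                truth = file.path(out_dir, "truth.json"))
  write_fasta(proteins, paths$fasta)
  ann <- do.call(rbind, lapply(recs, function(r) {
    if (length(r$domains) == 0L) return(NULL)
    data.frame(protein_id = r$id, accession = r$domains,
               stringsAsFactors = FALSE)
  }))
  if (is.null(ann)) {
    ann <- data.frame(protein_id = character(0), accession = character(0))
  }
  utils::write.table(ann, paths$annotations, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  labels <- data.frame(id = proteins$id,
                       label = vapply(recs, `[[`, "", "label"))
  utils::write.table(labels, paths$labels, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  for (r in recs) {
    writeLines(format_pssm(r$pssm),
               file.path(paths$pssm_dir, paste0(r$id, ".pssm")))
  }
  truth <- list(config = unclass(config),
                proteins = lapply(recs, function(r) {
                  list(id = r$id, label = r$label, length = nchar(r$sequence),
                       domains = as.list(r$domains))
                }))
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(paths)
}

#' Generate a labeled feature matrix in memory
#'
#' Runs the same generator as [generate_dataset()] but skips the file round
#' trip and returns extracted features directly — the fast path for
#' simulation studies and tests.
#'
#' @param config A [sim_config()].
#' @param catalog Domain catalog.
#' @param table Physicochemical property table.
#' @return List with `x` (n x 167 feature matrix), `y` (factor
#'   `nonECM`/`ECM`) and `ids`.
#' @export
simulate_labeled_features <- function(config,
                                      catalog = default_domain_catalog(),
                                      table = default_aaindex_table()) {
  recs <- sim_records(config, catalog)
  annotations <- lapply(recs, `[[`, "domains")
  names(annotations) <- vapply(recs, `[[`, "", "id")
  rows <- lapply(recs, function(r) {
    extract_features(list(id = r$id, sequence = r$sequence),
                     annotations, r$pssm, catalog, table)
  })
  x <- do.call(rbind, rows)
  rownames(x) <- names(annotations)
  list(x = x,
       y = factor(vapply(recs, `[[`, "", "label"),
                  levels = c("nonECM", "ECM")),
       ids = names(annotations))
}
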