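#' Read protein sequences from a FASTA file
#'
#' Records are validated against the 20 canonical one-letter amino-acid codes
#' plus `X` (unknown residue). The record identifier is the first
#' whitespace-delimited token after `>`; multi-line sequences are concatenated
#' and upper-cased.
#'
#' @param path Path to a FASTA file.
#' @return A data.frame with columns `id`, `sequence` and `length`, one row
#'   per record.
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no records in FASTA file: ", path)
  ids <- vapply(strsplit(names(set), "[[:space:]]+"), `[`, "", 1L)
  if (anyNA(ids) || any(!nzchar(ids))) stop("FASTA record with empty identifier")
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA identifier: ", ids[duplicated(ids)][1L])
  }
  seqs <- toupper(as.character(set))
  seqs <- gsub("[[:space:]]", "", seqs)
  for (i in seq_along(seqs)) {
    bad <- setdiff(unique(strsplit(seqs[i], "")[[1]]), SEQ_ALPHABET)
    if (length(bad)) {
      stop(sprintf("record '%s' contains invalid residue character '%s'",
                   ids[i], bad[1L]))
    }
    if (!nzchar(seqs[i])) stop(sprintf("record '%s' has an empty sequence", ids[i]))
  }
  data.frame(id = ids, sequence = unname(seqs), length = nchar(seqs),
             stringsAsFactors = FALSE)
}

#' Write protein sequences to a FASTA file
#'
#' @param proteins A data.frame with columns `id` and `sequence`
#'   (as returned by [read_fasta()]).
#' @param path Output path.
#' @param width Line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path, width = 60L) {
  set <- Biostrings::BStringSet(proteins$sequence)
  names(set) <- proteins$id
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a PSI-BLAST ASCII position-specific scoring matrix
#'
#' Parses the `-out_ascii_pssm` dialect: header lines, then one row per
#' sequence position carrying the position index, the query residue and 20
#' integer log-odds scores (any trailing weighted-percentage columns are
#' ignored).
#'
#' @param path Path to an ASCII PSSM file.
#' @param expected_length Optional integer; if given, the parsed matrix must
#'   have exactly this many rows.
#' @param protein_id Identifier attached to the matrix (defaults to the file
#'   base name without extension).
#' @return An object of class `pssm`: an L x 20 integer matrix with the
#'   residues of the PSI-BLAST column order as column names, the query
#'   residues as a `residues` attribute and `protein_id` attribute.
#' @export
read_pssm <- function(path, expected_length = NULL, protein_id = NULL) {
  stopifnot(file.exists(path))
  if (is.null(protein_id)) {
    protein_id <- sub("\\.[^.]*$", "", basename(path))
  }
  lines <- readLines(path, warn = FALSE)
  header_at <- NA_integer_
  for (i in seq_along(lines)) {
    tok <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    if (length(tok) >= 20L && identical(tok[1:20], PSSM_RESIDUES)) {
      header_at <- i
      break
    }
  }
  if (is.na(header_at)) {
    stop("missing PSSM header (residue column line) in ", path)
  }
  scores <- list()
  residues <- character()
  row_re <- "^[[:space:]]*[0-9]+[[:space:]]+[A-Za-z]"
  i <- header_at + 1L
  while (i <= length(lines)) {
    line <- lines[i]
    if (!grepl(row_re, line)) break
    tok <- strsplit(trimws(line), "[[:space:]]+")[[1]]
    if (length(tok) < 22L) {
      stop(sprintf("PSSM row %d of '%s' has fewer than 20 scores",
                   length(scores) + 1L, path))
    }
    vals <- suppressWarnings(as.integer(tok[3:22]))
    if (anyNA(vals)) {
      stop(sprintf("PSSM row %d of '%s' has non-integer scores",
                   length(scores) + 1L, path))
    }
    scores[[length(scores) + 1L]] <- vals
    residues <- c(residues, toupper(tok[2L]))
    i <- i + 1L
  }
  if (length(scores) == 0L) stop("no score rows found in ", path)
  mat <- do.call(rbind, scores)
  colnames(mat) <- PSSM_RESIDUES
  if (!is.null(expected_length) && nrow(mat) != expected_length) {
    stop(sprintf("PSSM '%s' has %d rows but the sequence has length %d",
                 protein_id, nrow(mat), expected_length))
  }
  pssm(mat, protein_id = protein_id, residues = residues)
}

#' Construct a PSSM object
#'
#' @param scores Integer L x 20 matrix of substitution scores.
#' @param protein_id Identifier of the corresponding protein.
#' @param residues Optional character vector of the L query residues.
#' @return An object of class `pssm`.
#' @export
pssm <- function(scores, protein_id = "", residues = NULL) {
  scores <- as.matrix(scores)
  if (ncol(scores) != 20L) stop("a PSSM must have exactly 20 columns")
  if (any(scores != round(scores))) stop("PSSM entries must be integers")
  storage.mode(scores) <- "integer"
  colnames(scores) <- PSSM_RESIDUES
  attr(scores, "protein_id") <- protein_id
  attr(scores, "residues") <- residues
  class(scores) <- c("pssm", class(scores))
  scores
}

#' Read a domain catalog
#'
#' Tab-separated file with a header; the first column holds domain accession
#' strings (the catalog order is the feature order of the domain block).
#'
#' @param path Path to a TSV file.
#' @return Character vector of accessions, order preserved.
#' @export
read_domain_catalog <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  acc <- trimws(as.character(tab[[1L]]))
  if (anyDuplicated(acc)) {
    stop("duplicate accession in domain catalog: ", acc[duplicated(acc)][1L])
  }
  if (length(acc) == 0L) stop("empty domain catalog: ", path)
  acc
}

#' Read a protein-to-domain annotation map
#'
#' Tab-separated `(protein_id, accession)` pairs with a header row. Proteins
#' absent from the file have the empty domain set. Accessions are compared
#' case-sensitively after whitespace trimming.
#'
#' @param path Path to a TSV file.
#' @return A named list mapping protein id to a character vector of unique
#'   accessions.
#' @export
read_domain_annotations <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("annotation file needs (protein_id, accession) columns")
  ids <- trimws(as.character(tab[[1L]]))
  acc <- trimws(as.character(tab[[2L]]))
  lapply(split(acc, ids), unique)
}

#' Domain set of one protein
#'
#' @param annotations A map from [read_domain_annotations()].
#' @param protein_id Protein identifier.
#' @return Character vector of accessions (empty if unannotated).
#' @export
domain_set <- function(annotations, protein_id) {
  a <- annotations[[protein_id]]
  if (is.null(a)) character(0) else a
}

#' Read a physicochemical amino-acid index table
#'
#' Tab-separated file with a header: first column the property name, then one
#' column per residue letter. Every property must define a value for all 20
#' canonical residues.
#'
#' @param path Path to a TSV file.
#' @return Numeric matrix, one row per property (rownames = property names),
#'   columns the 20 residues in PSI-BLAST order.
#' @export
read_aaindex_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  props <- trimws(as.character(tab[[1L]]))
  missing_res <- setdiff(PSSM_RESIDUES, colnames(tab))
  if (length(missing_res)) {
    stop("AAIndex table lacks residue column(s): ",
         paste(missing_res, collapse = ", "))
  }
  mat <- as.matrix(tab[, PSSM_RESIDUES, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- props
  for (p in seq_len(nrow(mat))) {
    if (anyNA(mat[p, ])) {
      res <- PSSM_RESIDUES[which(is.na(mat[p, ]))][1L]
      stop(sprintf("property '%s' is missing a value for residue '%s'",
                   props[p], res))
    }
  }
  mat
}

#' Read a labeled training dataset
#'
#' Tab-separated mirror of a (UniprotID, Class, FastaSequence) table. Class
#' tokens must be `ECM` or `nonECM`.
#'
#' @param path Path to a TSV file.
#' @return A data.frame with columns `id`, `label` (factor, levels
#'   `nonECM`, `ECM`) and `sequence`.
#' @export
read_labeled_dataset <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(tab) < 3L) stop("labeled dataset needs (id, label, sequence) columns")
  lab <- trimws(as.character(tab[[2L]]))
  bad <- setdiff(unique(lab), c("ECM", "nonECM"))
  if (length(bad)) stop("unknown class label token: ", bad[1L])
  out <- data.frame(id = trimws(as.character(tab[[1L]])),
                    label = factor(lab, levels = c("nonECM", "ECM")),
                    sequence = toupper(trimws(as.character(tab[[3L]]))),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$id)) {
    stop("duplicate protein id in dataset: ", out$id[duplicated(out$id)][1L])
  }
  out
}

#' Packaged domain catalog
#'
#' Loads the synthetic 63-accession ECM domain catalog shipped with the
#' package (a stand-in with the shape of the curated ECM inclusion/exclusion
#' domain list; accessions use the reserved `IPRX` prefix so they cannot be
#' mistaken for real InterPro identifiers).
#'
#' @return Character vector of 63 accessions.
#' @export
default_domain_catalog <- function() {
  read_domain_catalog(system.file("extdata", "ecm_domain_catalog_synthetic.tsv",
                                  package = "ecmscout", mustWork = TRUE))
}

#' Packaged physicochemical property table
#'
#' Loads the 24-property amino-acid index table shipped with the package:
#' Kyte-Doolittle hydropathy and residue mass plus 22 synthetic indices of
#' realistic scale (a stand-in with the shape of the 24-index selection used
#' for ECM prediction).
#'
#' @return 24 x 20 numeric matrix.
#' @export
default_aaindex_table <- function() {
  read_aaindex_table(system.file("extdata", "aaindex_properties_synthetic.tsv",
                                 package = "ecmscout", mustWork = TRUE))
}

#' Save a trained under-sampling ensemble
#'
#' The archive is self-describing: it records a format-version stamp, the
#' feature subset, the number of base learners, the seed and the base-learner
#' parameters, so that a reloaded model reproduces predictions bitwise.
#'
#' @param model An `ecm_ensemble` from [train_ensemble()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "ecm_ensemble"))
  saveRDS(list(format = MODEL_FORMAT_VERSION, model = model), path)
  invisible(path)
}

#' Load a trained under-sampling ensemble
#'
#' @param path Path written by [save_model()].
#' @return The `ecm_ensemble` object.
#' @export
load_model <- function(path) {
  obj <- tryCatch(suppressWarnings(readRDS(path)), error = function(e) {
    stop("cannot read model archive '", path, "': ", conditionMessage(e))
  })
  if (!is.list(obj) || !identical(obj$format, MODEL_FORMAT_VERSION)) {
    stop("model archive '", path, "' has an unsupported format stamp; refusing to load")
  }
  obj$model
}
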