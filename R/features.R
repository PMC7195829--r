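#' Binary ECM-domain feature block
#'
#' One indicator per catalog domain. Under the default `as_printed` polarity a
#' domain that IS annotated on the protein scores 0 and an absent domain
#' scores 1 (the original scoring convention); `presence` inverts the
#' encoding (1 = present). Tree ensembles are invariant to the polarity of a
#' binary feature, so the choice does not affect classification.
#'
#' @param protein_id Protein identifier (a protein absent from the annotation
#'   map has the empty domain set).
#' @param annotations Map from [read_domain_annotations()].
#' @param catalog Accession vector from [read_domain_catalog()]; output order
#'   follows catalog order.
#' @param polarity `"as_printed"` (default) or `"presence"`.
#' @return Named numeric vector of 0/1 values, one per catalog accession.
#' @export
domain_features <- function(protein_id, annotations, catalog,
                            polarity = c("as_printed", "presence")) {
  polarity <- match.arg(polarity)
  stopifnot(length(catalog) >= 1L)
  a <- domain_set(annotations, protein_id)
  present <- as.numeric(catalog %in% a)
  x <- if (polarity == "presence") present else 1 - present
  names(x) <- catalog
  x
}

#' Mean physicochemical property features
#'
#' For each property of the index table, the mean index value over the
#' residues of the sequence. Unknown residues (`X`) carry no index value and
#' are skipped, with the effective length reduced accordingly.
#'
#' @param sequence Amino-acid sequence string.
#' @param table Property matrix from [read_aaindex_table()].
#' @return Named numeric vector, one mean per property.
#' @export
physchem_features <- function(sequence, table) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  if (length(chars) < 1L) stop("empty sequence")
  bad <- setdiff(unique(chars), SEQ_ALPHABET)
  if (length(bad)) stop("invalid residue character '", bad[1L], "'")
  chars <- chars[chars != "X"]
  if (length(chars) == 0L) {
    stop("sequence consists entirely of unknown residues (X); ",
         "physicochemical means are undefined")
  }
  idx <- match(chars, colnames(table))
  rowMeans(table[, idx, drop = FALSE])
}

#' Standardize a PSSM to (0, 1)
#'
#' Elementwise logistic squashing `f(E) = 1 / (1 + exp(-E))`. Strict
#' positivity of the output is required by the grey model's cumulative sum.
#' Matrices with fewer than 4 rows are rejected because the GM(2,1) fit needs
#' at least 3 usable difference rows.
#'
#' @param pssm A `pssm` object (or plain L x 20 matrix).
#' @return L x 20 numeric matrix with entries strictly inside (0, 1).
#' @export
standardize_pssm <- function(pssm) {
  m <- unclass(pssm)
  attributes(m)[setdiff(names(attributes(m)), c("dim", "dimnames"))] <- NULL
  if (nrow(m) < 4L) {
    stop("protein too short for the PSSM descriptor: need length >= 4, got ",
         nrow(m))
  }
  stats::plogis(m)
}

#' Fit a GM(2,1) grey model to one series
#'
#' Second-order grey model of a short positive series `x0`:
#' the accumulated series is `x1(k) = sum(x0[1:k])`, the first difference is
#' `a(k) = x0(k) - x0(k-1)` and the background value is
#' `z1(k) = (x1(k) + x1(k-1)) / 2`. The coefficients solve the least-squares
#' system with rows `[-x0(k), -z1(k), 1]` against `a(k)` for `k = 2..L`,
#' using the minimum-norm pseudo-inverse so that degenerate (for example
#' constant) columns yield the zero solution instead of failing.
#'
#' @param column Numeric vector of length >= 4, all entries > 0.
#' @return Named numeric vector `c(a1, a2, b)`.
#' @export
fit_gm21 <- function(column) {
  x0 <- as.numeric(column)
  if (length(x0) < 4L) stop("GM(2,1) needs at least 4 points")
  if (any(x0 <= 0)) stop("GM(2,1) requires strictly positive input")
  L <- length(x0)
  x1 <- cumsum(x0)
  a <- diff(x0)
  z1 <- (x1[-1L] + x1[-L]) / 2
  B <- cbind(-x0[-1L], -z1, 1)
  theta <- as.numeric(MASS::ginv(B) %*% a)
  names(theta) <- c("a1", "a2", "b")
  theta
}

#' 80-dimensional PSSM descriptor
#'
#' Concatenates (i) the 20 column means of the standardized matrix and
#' (ii) the GM(2,1) coefficient triple `(a1, a2, b)` fitted to each
#' standardized column, in PSI-BLAST residue order: 20 + 60 = 80 values.
#'
#' @param pssm A `pssm` object (L >= 4).
#' @return Named numeric vector of length 80.
#' @export
pssm_features <- function(pssm) {
  s <- standardize_pssm(pssm)
  means <- colMeans(s)
  names(means) <- sprintf("pssm_mean_%02d", seq_len(20L))
  gm <- vapply(seq_len(20L), function(j) fit_gm21(s[, j]), numeric(3))
  gm_vec <- as.numeric(gm)  # column-major: (a1, a2, b) per residue column
  names(gm_vec) <- as.vector(vapply(
    seq_len(20L),
    function(j) sprintf(c("gm_a1_%02d", "gm_a2_%02d", "gm_b_%02d"), j),
    character(3)))
  c(means, gm_vec)
}

#' Full feature-name vector
#'
#' The fixed global feature order: 63 catalog accessions, then the 24
#' property names, then the 80 PSSM descriptor names.
#'
#' @param catalog Domain catalog.
#' @param table Property table.
#' @return Character vector of length `length(catalog) + nrow(table) + 80`.
#' @export
feature_names <- function(catalog = default_domain_catalog(),
                          table = default_aaindex_table()) {
  gm_names <- as.vector(vapply(
    seq_len(20L),
    function(j) sprintf(c("gm_a1_%02d", "gm_a2_%02d", "gm_b_%02d"), j),
    character(3)))
  c(catalog, rownames(table), sprintf("pssm_mean_%02d", 1:20), gm_names)
}

#' Assemble the full feature vector of one protein
#'
#' Concatenation of the domain block, the physicochemical block and the PSSM
#' descriptor (63 + 24 + 80 = 167 values with the packaged fixtures), in the
#' fixed global order of [feature_names()].
#'
#' @param protein One-row data.frame (or list) with `id` and `sequence`.
#' @param annotations Domain annotation map.
#' @param pssm A `pssm` whose row count equals the sequence length.
#' @param catalog Domain catalog.
#' @param table Property table.
#' @param polarity Domain-block polarity, see [domain_features()].
#' @return Named numeric vector.
#' @export
extract_features <- function(protein, annotations, pssm,
                             catalog = default_domain_catalog(),
                             table = default_aaindex_table(),
                             polarity = "as_printed") {
  if (nrow(pssm) != nchar(protein$sequence)) {
    stop(sprintf("PSSM of '%s' has %d rows but the sequence has length %d",
                 protein$id, nrow(pssm), nchar(protein$sequence)))
  }
  v <- c(domain_features(protein$id, annotations, catalog, polarity),
         physchem_features(protein$sequence, table),
         pssm_features(pssm))
  if (!all(is.finite(v))) stop("non-finite feature value for '", protein$id, "'")
  v
}

#' Feature matrix for a set of proteins
#'
#' @param proteins Data.frame from [read_fasta()] (columns `id`, `sequence`).
#' @param annotations Domain annotation map.
#' @param pssms Named list of `pssm` objects keyed by protein id, or a
#'   directory containing `<id>.pssm` files.
#' @param catalog,table,polarity Passed to [extract_features()].
#' @return Numeric matrix, one row per protein (rownames = protein ids),
#'   columns in [feature_names()] order.
#' @export
extract_feature_matrix <- function(proteins, annotations, pssms,
                                   catalog = default_domain_catalog(),
                                   table = default_aaindex_table(),
                                   polarity = "as_printed") {
  get_pssm <- function(id, len) {
    if (is.character(pssms)) {
      read_pssm(file.path(pssms, paste0(id, ".pssm")),
                expected_length = len, protein_id = id)
    } else {
      p <- pssms[[id]]
      if (is.null(p)) stop("no PSSM available for protein '", id, "'")
      p
    }
  }
  rows <- lapply(seq_len(nrow(proteins)), function(i) {
    pr <- proteins[i, , drop = FALSE]
    extract_features(pr, annotations,
                     get_pssm(pr$id, nchar(pr$sequence)),
                     catalog, table, polarity)
  })
  x <- do.call(rbind, rows)
  rownames(x) <- proteins$id
  x
}
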