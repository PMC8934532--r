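# The codon alignment container: a taxa x codon-column character matrix over
# sense codons plus the two missing-data states "---" (gap) and "NNN"
# (ambiguous).  In-frame stop codons are not representable; they must be
# converted upstream (see mask_internal_stops()).

GAP_STATE <- "---"
AMBIG_STATE <- "NNN"

#' Construct a codon alignment
#'
#' @param x Either a character matrix of 3-letter codon states (rows =
#'   taxa, must have row names) or a named character vector of aligned
#'   nucleotide sequences of equal length divisible by 3.
#' @param code_id Genetic code id (see [codon_table()]); used to validate
#'   that no in-frame stop codon appears as a state.
#' @return An object of class `codon_alignment`: a character matrix with one
#'   column per codon, entries among the sense codons, `"---"` (gap) and
#'   `"NNN"` (ambiguous).
#' @export
codon_alignment <- function(x, code_id = "1") {
  tab <- codon_table(code_id)
  if (is.character(x) && !is.matrix(x)) {
    if (is.null(names(x)) || anyDuplicated(names(x))) {
      stop("sequences must have unique names")
    }
    len <- unique(nchar(x))
    if (length(len) != 1) stop("aligned sequences must have equal length")
    if (len %% 3 != 0) stop("alignment length ", len, " is not divisible by 3")
    m <- matrix("", nrow = length(x), ncol = len / 3, dimnames = list(names(x), NULL))
    for (i in seq_along(x)) {
      m[i, ] <- substring(toupper(x[[i]]), seq(1, len, 3), seq(3, len, 3))
    }
    x <- m
  }
  if (!is.matrix(x) || !is.character(x)) stop("'x' must be a character matrix or named sequences")
  if (is.null(rownames(x)) || anyDuplicated(rownames(x))) stop("taxa must be unique row names")
  x[] <- toupper(x)
  x[grepl("-", x, fixed = TRUE)] <- GAP_STATE
  known <- x %in% tab$codons | x == GAP_STATE
  if (any(x[!known] %in% tab$stops)) {
    stop("in-frame stop codon present; convert stops with mask_internal_stops() first")
  }
  x[!known] <- AMBIG_STATE
  structure(x, class = "codon_alignment", code_id = code_id)
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("codon_alignment:", nrow(x), "taxa x", ncol(x), "codon columns\n")
  invisible(x)
}

#' Number of codon columns in a codon alignment
#' @param aln A `codon_alignment`.
#' @return Integer column count.
#' @export
ncodons <- function(aln) ncol(aln)

# integer encoding for the likelihood engine: 0-based sense-codon index,
# n (= number of sense codons) for gap/ambiguous.
aln_state_int <- function(aln, tab = codon_table(attr(aln, "code_id") %||% "1")) {
  idx <- codon_index(unclass(aln), tab)
  m <- matrix(as.integer(ifelse(is.na(idx), tab$n, idx - 1L)),
              nrow = nrow(aln), dimnames = dimnames(aln))
  m
}

# site-pattern compression: unique columns and their multiplicities
aln_patterns <- function(int_mat) {
  key <- apply(int_mat, 2, paste, collapse = ",")
  ux <- !duplicated(key)
  list(tips = int_mat[, ux, drop = FALSE],
       weights = as.numeric(table(key)[key[ux]]))
}

# per-column amino-acid translation; NA where gapped/ambiguous
aln_aa_matrix <- function(aln, tab = codon_table(attr(aln, "code_id") %||% "1")) {
  idx <- codon_index(unclass(aln), tab)
  matrix(tab$aa[idx], nrow = nrow(aln), dimnames = dimnames(aln))
}

#' Write a codon alignment to FASTA
#'
#' @param aln A `codon_alignment`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_codon_fasta <- function(aln, path) {
  seqs <- apply(unclass(aln), 1, paste, collapse = "")
  writeLines(paste0(">", rownames(aln), "\n", seqs), path)
  invisible(path)
}

#' Read a codon alignment from FASTA
#'
#' @param path FASTA file of aligned, equal-length nucleotide sequences.
#' @param code_id Genetic code id.
#' @return A `codon_alignment`.
#' @export
read_codon_fasta <- function(path, code_id = "1") {
  recs <- read_fasta(path)
  seqs <- stats::setNames(recs$residues, recs$id)
  codon_alignment(seqs, code_id = code_id)
}

#' Write a codon alignment in sequential PHYLIP-like layout
#'
#' A header line with the taxon count and column count (in codons) followed
#' by one `name  sequence` line per taxon, the interchange layout used for
#' codon-model tools.
#'
#' @param aln A `codon_alignment`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_codon_phylip <- function(aln, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(nrow(aln), ncol(aln)), con)
  seqs <- apply(unclass(aln), 1, paste, collapse = "")
  writeLines(paste0(format(rownames(aln), width = max(nchar(rownames(aln))) + 2),
                    seqs), con)
  invisible(path)
}
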