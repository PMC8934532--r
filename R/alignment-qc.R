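# Building codon alignments from protein alignments + CDS, and the masking,
# trimming and length rules applied before selection testing.
#
# The edge-trimming and masking rules formalize a manual review process:
# alignment edges are kept only from the first completely conserved
# amino-acid triplet inward, gapped regions and runs of substitutions
# unique to one taxon are deleted between their nearest flanking conserved
# columns, and short alignments are discarded.  Every deletion is recorded
# in a mask log so the filtering is auditable.

#' Convert in-frame stop codons to ambiguity characters
#'
#' A single terminal stop codon is removed; every remaining in-frame stop
#' is replaced by `"NNN"`.  Protein-coding gene models occasionally contain
#' stops (annotation error or read-through), and aligners treat stop
#' characters inconsistently, so the conversion keeps protein/nucleotide
#' correspondence intact.
#'
#' @param cds Nucleotide sequence string, length divisible by 3.
#' @param code_id Genetic code id.
#' @return The converted sequence string.
#' @export
mask_internal_stops <- function(cds, code_id = "1") {
  cds <- toupper(gsub("\\s", "", cds))
  if (nchar(cds) %% 3 != 0) {
    stop("frame error: CDS length ", nchar(cds), " not divisible by 3")
  }
  tab <- codon_table(code_id)
  codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  n <- length(codons)
  if (n > 0 && codons[n] %in% tab$stops) codons <- codons[-n]
  codons[codons %in% tab$stops] <- AMBIG_STATE
  paste(codons, collapse = "")
}

#' Back-translate a protein alignment onto coding sequences
#'
#' Maps each aligned amino-acid column onto one codon column: protein gaps
#' become codon gaps, protein `X` or any codon containing `N` becomes the
#' ambiguous state, and every clean codon is checked to translate to its
#' aligned amino acid.
#'
#' @param protein_alignment Named character vector of aligned amino-acid
#'   sequences (or a data frame from [read_fasta()]).
#' @param cds Named character vector of unaligned coding sequences, one per
#'   taxon; a single terminal stop is stripped and internal stops converted
#'   via [mask_internal_stops()].
#' @param code_id Genetic code id.
#' @return A [codon_alignment()].
#' @export
backtranslate_alignment <- function(protein_alignment, cds, code_id = "1") {
  if (is.data.frame(protein_alignment)) {
    protein_alignment <- stats::setNames(protein_alignment$residues,
                                         protein_alignment$id)
  }
  tab <- codon_table(code_id)
  gc <- Biostrings::getGeneticCode(as.character(code_id))
  taxa <- names(protein_alignment)
  if (!all(taxa %in% names(cds))) {
    stop("missing CDS for taxa: ",
         paste(setdiff(taxa, names(cds)), collapse = ", "))
  }
  plen <- unique(nchar(protein_alignment))
  if (length(plen) != 1) stop("protein alignment rows differ in length")
  out <- matrix(GAP_STATE, length(taxa), plen, dimnames = list(taxa, NULL))
  for (tx in taxa) {
    aa <- strsplit(toupper(protein_alignment[[tx]]), "")[[1]]
    nt <- mask_internal_stops(cds[[tx]], code_id)
    n_res <- sum(aa != "-")
    if (nchar(nt) != 3 * n_res) {
      stop("correspondence error for taxon ", tx, ": ungapped protein length ",
           n_res, " x 3 != CDS length ", nchar(nt))
    }
    codons <- substring(nt, seq(1, nchar(nt), 3), seq(3, nchar(nt), 3))
    j <- 0L
    for (col in seq_len(plen)) {
      if (aa[col] == "-") next
      j <- j + 1L
      cod <- codons[j]
      if (aa[col] == "X" || grepl("[^ACGT]", cod)) {
        out[tx, col] <- AMBIG_STATE
        next
      }
      if (is.na(gc[cod]) || gc[cod] != aa[col]) {
        stop("correspondence error for taxon ", tx, " at column ", col,
             ": codon ", cod, " does not translate to ", aa[col])
      }
      out[tx, col] <- cod
    }
  }
  codon_alignment(out, code_id = code_id)
}

# conserved column: all taxa hold clean sense codons translating to the
# same amino acid
conserved_columns <- function(aln, tab = codon_table(attr(aln, "code_id") %||% "1")) {
  aa <- aln_aa_matrix(aln, tab)
  apply(aa, 2, function(col) !anyNA(col) && length(unique(col)) == 1L)
}

subset_columns <- function(aln, idx) {
  out <- unclass(aln)[, idx, drop = FALSE]
  structure(out, class = "codon_alignment", code_id = attr(aln, "code_id"))
}

#' Trim alignment edges to the outermost conserved triplets
#'
#' Alignment edges are error-prone (missed exons, wrong termini), so
#' columns are dropped from each end until the first run of three
#' consecutive conserved columns; the conserved triplets themselves are
#' retained.  If no conserved triplet exists anywhere the result has zero
#' columns and carries attribute `no_conserved_triplet = TRUE`.
#'
#' @param aln A [codon_alignment()].
#' @return The trimmed alignment.
#' @export
trim_to_conserved_edges <- function(aln) {
  if (ncol(aln) == 0) {
    attr(aln, "no_conserved_triplet") <- TRUE
    return(aln)
  }
  cons <- conserved_columns(aln)
  n <- length(cons)
  trip_start <- if (n >= 3) {
    which(cons[1:(n - 2)] & cons[2:(n - 1)] & cons[3:n])
  } else integer(0)
  if (length(trip_start) == 0) {
    out <- subset_columns(aln, integer(0))
    attr(out, "no_conserved_triplet") <- TRUE
    return(out)
  }
  from <- min(trip_start)
  to <- max(trip_start) + 2L
  subset_columns(aln, from:to)
}

#' Mask parameters for suspect-region deletion
#'
#' @param unique_run_min Minimum length (codons, >= 2) of a taxon-unique
#'   substitution run that triggers masking; default 3.
#' @return A list of class `mask_params`.
#' @export
mask_params <- function(unique_run_min = 3) {
  if (unique_run_min < 2) stop("unique_run_min must be >= 2")
  structure(list(unique_run_min = unique_run_min), class = "mask_params")
}

# maximal runs of TRUE in a logical vector -> matrix of (start, end)
logical_runs <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

#' Delete gapped and taxon-unique suspect regions
#'
#' Two deterministic rules emulate manual alignment review.  R1: any
#' maximal run of columns containing at least one gap is deleted, together
#' with every column between its nearest flanking conserved columns
#' (exclusive of the conserved columns themselves).  R2: any run of at
#' least `unique_run_min` consecutive columns in which exactly one taxon
#' (the same taxon throughout the run) differs from an otherwise identical
#' amino-acid consensus is deleted in the same way; such runs are more
#' parsimoniously explained by errors in that sequence's gene model than by
#' repeated substitution.
#'
#' @param aln A trimmed [codon_alignment()].
#' @param params A [mask_params()] list.
#' @return List with `alignment` (masked) and `log`, a data frame with one
#'   row per deleted interval (`rule`, `start_col`, `end_col`, in input
#'   column coordinates).
#' @export
mask_suspect_regions <- function(aln, params = mask_params()) {
  nc <- ncol(aln)
  log0 <- data.frame(rule = character(), start_col = integer(),
                     end_col = integer(), stringsAsFactors = FALSE)
  if (nc == 0) return(list(alignment = aln, log = log0))
  cons <- conserved_columns(aln)
  states <- unclass(aln)
  aa <- aln_aa_matrix(aln)

  expand_to_conserved <- function(start, end) {
    prev <- which(cons[seq_len(start - 1)])
    nxt <- which(cons) ; nxt <- nxt[nxt > end]
    c(if (length(prev)) max(prev) + 1L else 1L,
      if (length(nxt)) min(nxt) - 1L else nc)
  }

  intervals <- list()
  # R1: gap runs
  has_gap <- apply(states == GAP_STATE, 2, any)
  for (k in seq_len(nrow(logical_runs(has_gap)))) {
    run <- logical_runs(has_gap)[k, ]
    iv <- expand_to_conserved(run[["start"]], run[["end"]])
    intervals[[length(intervals) + 1L]] <-
      data.frame(rule = "R1", start_col = iv[1], end_col = iv[2])
  }
  # R2: taxon-unique substitution runs
  odd_taxon <- apply(aa, 2, function(col) {
    if (anyNA(col)) return(NA_integer_)
    tb <- table(col)
    if (length(tb) != 2L || min(tb) != 1L || max(tb) < 2L) return(NA_integer_)
    which(col == names(tb)[tb == 1L])[1]
  })
  if (nc > 0) {
    r <- rle(ifelse(is.na(odd_taxon), 0L, odd_taxon))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values > 0L & r$lengths >= params$unique_run_min
    for (k in which(keep)) {
      iv <- expand_to_conserved(starts[k], ends[k])
      intervals[[length(intervals) + 1L]] <-
        data.frame(rule = "R2", start_col = iv[1], end_col = iv[2])
    }
  }
  if (length(intervals) == 0) return(list(alignment = aln, log = log0))
  log <- do.call(rbind, intervals)
  drop <- unique(unlist(mapply(seq, log$start_col, log$end_col, SIMPLIFY = FALSE)))
  out <- subset_columns(aln, setdiff(seq_len(nc), drop))
  list(alignment = out, log = log)
}

#' Minimum-length filter for trimmed alignments
#'
#' @param aln A trimmed [codon_alignment()].
#' @param min_codons Minimum column count (default 100); alignments below
#'   it are too short for stable rate estimation.
#' @return `TRUE` (pass) or `FALSE` (fail).
#' @export
filter_min_length <- function(aln, min_codons = 100) {
  ncol(aln) >= min_codons
}

#' Per-column conservation score
#'
#' Fraction of taxa matching the column's majority amino acid (gaps and
#' ambiguity count as mismatches); exported so users can apply an external
#' alignment-consistency gate of their choice.
#'
#' @param aln A [codon_alignment()].
#' @return Numeric vector, one score in `[0, 1]` per column.
#' @export
conservation_score <- function(aln) {
  aa <- aln_aa_matrix(aln)
  apply(aa, 2, function(col) {
    col <- col[!is.na(col)]
    if (length(col) == 0) return(0)
    max(table(col)) / nrow(aln)
  })
}
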