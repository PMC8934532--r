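# Internal codon bookkeeping shared by the rate matrix, the likelihood engine
# and the simulator.  All state indexing in the package refers to the sense
# codons of a genetic code in the fixed order defined here.

.codon_cache <- new.env(parent = emptyenv())

#' @useDynLib omegascreen, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Sense-codon table for a genetic code
#'
#' Returns the bookkeeping used throughout the package for a given genetic
#' code: the sense codons (stop codons excluded) in a fixed order, their
#' amino-acid translations, and which single-nucleotide changes are
#' transitions or synonymous.
#'
#' @param code_id Genetic code identifier understood by
#'   [Biostrings::getGeneticCode()]; `"1"` (default) is the standard code.
#' @return A list with elements `codons` (character vector of sense codons),
#'   `aa` (amino acid per sense codon), `stops` (stop codons), and `n`
#'   (number of sense codons; 61 for the standard code).
#' @export
codon_table <- function(code_id = "1") {
  key <- as.character(code_id)
  if (!is.null(.codon_cache[[key]])) {
    return(.codon_cache[[key]])
  }
  gc <- Biostrings::getGeneticCode(key)
  codons <- names(gc)
  sense <- codons[gc != "*"]
  tab <- list(
    codons = sense,
    aa = unname(gc[sense]),
    stops = codons[gc == "*"],
    n = length(sense)
  )
  # Pairwise single-step structure: for every ordered codon pair differing at
  # exactly one position, record whether the change is a transition and
  # whether it is synonymous.  Stored as dense n x n integer matrices:
  # step[i, j] = 0 (not single-step), 1 transversion, 2 transition;
  # syn[i, j] = 1 if translation is unchanged.
  n <- tab$n
  split_nt <- do.call(rbind, strsplit(sense, ""))
  is_transition <- function(a, b) {
    (a == "A" & b == "G") | (a == "G" & b == "A") |
      (a == "C" & b == "T") | (a == "T" & b == "C")
  }
  step <- matrix(0L, n, n)
  syn <- matrix(0L, n, n)
  for (pos in 1:3) {
    same_other <- outer(split_nt[, -pos][, 1], split_nt[, -pos][, 1], "==") &
      outer(split_nt[, -pos][, 2], split_nt[, -pos][, 2], "==")
    diff_here <- outer(split_nt[, pos], split_nt[, pos], "!=")
    single <- same_other & diff_here
    ti <- outer(split_nt[, pos], split_nt[, pos], is_transition)
    step[single] <- ifelse(ti[single], 2L, 1L)
  }
  syn[step > 0L] <- as.integer(outer(tab$aa, tab$aa, "==")[step > 0L])
  diag(step) <- 0L
  tab$step <- step
  tab$syn <- syn
  tab$nt <- split_nt
  .codon_cache[[key]] <- tab
  tab
}

# Map codon strings to 1-based sense-codon indices; NA for anything that is
# not an unambiguous sense codon (gaps, Ns, stops).
codon_index <- function(codons, tab = codon_table()) {
  match(toupper(codons), tab$codons)
}

#' Empirical F3x4 codon frequencies
#'
#' Estimates equilibrium codon frequencies from a codon alignment by the
#' F3x4 method: nucleotide frequencies are tabulated separately at each
#' codon position over all unambiguous sense codons, and the frequency of a
#' codon is the product of its three positional nucleotide frequencies,
#' renormalised over sense codons.
#'
#' @param aln A [codon_alignment] object.
#' @param tab Codon table, see [codon_table()].
#' @param floor Minimum codon frequency before renormalisation; guards the
#'   reversible-matrix machinery against zero frequencies in short
#'   alignments.
#' @return Numeric vector of frequencies over sense codons, summing to 1.
#' @export
codon_freq_f3x4 <- function(aln, tab = codon_table(attr(aln, "code_id") %||% "1"),
                            floor = 1e-6) {
  states <- unclass(aln)
  idx <- codon_index(states, tab)
  idx <- idx[!is.na(idx)]
  if (length(idx) == 0) {
    return(rep(1 / tab$n, tab$n))
  }
  pos_freq <- matrix(0, 4, 3, dimnames = list(c("T", "C", "A", "G"), NULL))
  for (pos in 1:3) {
    cnt <- table(factor(tab$nt[idx, pos], levels = rownames(pos_freq)))
    pos_freq[, pos] <- (cnt + 1) / sum(cnt + 4)  # +1 pseudocount per base
  }
  pi <- pos_freq[tab$nt[, 1], 1] * pos_freq[tab$nt[, 2], 2] * pos_freq[tab$nt[, 3], 3]
  pi <- pmax(pi / sum(pi), floor)
  pi / sum(pi)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Self-consistent F3x4 codon frequencies
#'
#' The fixed point of the F3x4 construction: codon frequencies whose own
#' positional nucleotide marginals reproduce them as a product.  Used as
#' the simulator's default equilibrium distribution, so that data generated
#' under it are correctly described by the F3x4 frequencies estimated
#' during fitting.
#'
#' @param code_id Genetic code id.
#' @param max_iter,tol Fixed-point iteration controls.
#' @return Frequency vector over sense codons.
#' @export
codon_freq_f3x4_stationary <- function(code_id = "1", max_iter = 100, tol = 1e-12) {
  tab <- codon_table(code_id)
  pi <- rep(1 / tab$n, tab$n)
  nts <- c("T", "C", "A", "G")
  for (i in seq_len(max_iter)) {
    q <- vapply(1:3, function(pos) {
      vapply(nts, function(b) sum(pi[tab$nt[, pos] == b]), numeric(1))
    }, numeric(4))
    new <- q[match(tab$nt[, 1], nts), 1] * q[match(tab$nt[, 2], nts), 2] *
      q[match(tab$nt[, 3], nts), 3]
    new <- new / sum(new)
    if (max(abs(new - pi)) < tol) return(new)
    pi <- new
  }
  pi
}
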