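# The foreground-branch likelihood-ratio test and the orthogroup screen.

#' Branch likelihood-ratio test for positive selection
#'
#' Tests whether the site-class omega2 on the foreground branch exceeds 1.
#' The null model is the foreground-labeled site-class model with omega2
#' fixed at 1; the alternative frees omega2 in `[1, 999]`.  Twice the
#' log-likelihood difference (negative values clamped to 0) is referred to
#' the upper tail of a chi-squared distribution with one degree of freedom.
#' A test is `accepted` when the p-value is below `alpha`, the omega2
#' estimate is at least 1, and the fitted tree length does not exceed
#' `tree_length_max` (long trees flag alignment error).
#'
#' @param aln A [codon_alignment()].
#' @param tree Unrooted `ape::phylo` with exactly one foreground branch.
#' @param alpha Significance level (default 0.001).
#' @param tree_length_max Maximum acceptable tree length in substitutions
#'   per codon (default 10).
#' @param include_m1 Also fit the two-class M1 model and report its
#'   log-likelihood as a convergence diagnostic (never used as the test
#'   null); off by default because it roughly doubles the cost.
#' @param null_dist `"chisq1"` (default) refers the statistic to a plain
#'   chi-squared with df = 1; `"mixture"` uses the more conservative 50:50
#'   boundary mixture of a point mass at zero and chi-squared df = 1.
#' @param pi,n_starts,seed,control Passed to [fit_model()].
#' @return An object of class `lrt_result`: `lnL_null`, `lnL_alt`,
#'   `statistic`, `df`, `p_value`, `omega2_hat`, `p2_hat`, `tree_length`,
#'   `accepted`, plus the two fits and optional `lnL_m1`.
#' @export
branch_lrt <- function(aln, tree, alpha = 0.001, tree_length_max = 10,
                       include_m1 = FALSE, null_dist = c("chisq1", "mixture"),
                       pi = NULL, n_starts = 3, seed = NULL, control = list()) {
  null_dist <- match.arg(null_dist)
  if (length(foreground_edges(tree)) != 1L) {
    stop("branch_lrt needs exactly one foreground branch; see set_foreground()")
  }
  alt <- fit_model(aln, tree, model = "M2_branch", pi = pi,
                   n_starts = n_starts, seed = seed, control = control)
  # warm-start the null from the alternative solution
  null_init <- alt$params
  null <- fit_model(aln, alt$tree, model = "M2_branch", fix_omega2 = 1,
                    params_init = null_init, pi = pi, n_starts = 1,
                    control = control)
  statistic <- max(0, 2 * (alt$lnL - null$lnL))
  p <- chi2_sf(statistic, df = 1)
  if (null_dist == "mixture") {
    p <- if (statistic == 0) 1 else 0.5 * p
  }
  p2 <- 1 - alt$params$p0 - alt$params$p1
  res <- list(
    lnL_null = null$lnL, lnL_alt = alt$lnL,
    statistic = statistic, df = 1L, p_value = p,
    omega2_hat = alt$params$omega2, p2_hat = p2,
    tree_length = alt$tree_length,
    accepted = (p < alpha) && (alt$params$omega2 >= 1) &&
      (alt$tree_length <= tree_length_max),
    alpha = alpha, tree_length_max = tree_length_max,
    fit_alt = alt, fit_null = null
  )
  if (include_m1) {
    m1 <- fit_model(aln, alt$tree, model = "M1",
                    params_init = alt$params, pi = pi, n_starts = 1,
                    control = control)
    res$lnL_m1 <- m1$lnL
  }
  structure(res, class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat("branch LRT: 2*dlnL =", signif(x$statistic, 6),
      " p =", format(x$p_value, digits = 4), "(df = 1)\n")
  cat("  omega2 =", signif(x$omega2_hat, 5), " p2 =", signif(x$p2_hat, 4),
      " tree length =", signif(x$tree_length, 5), "\n")
  cat("  accepted:", x$accepted, "\n")
  invisible(x)
}

# one tabular row per LRT result (Supp-1-style layout)
lrt_row <- function(og, lr, stage = "tested") {
  data.frame(
    orthogroup = og,
    n_codons = lr$fit_alt$n_codons,
    lnL_m1 = if (is.null(lr$lnL_m1)) NA_real_ else lr$lnL_m1,
    lnL_null = lr$lnL_null, lnL_alt = lr$lnL_alt,
    statistic = lr$statistic, p_value = lr$p_value,
    omega2_hat = lr$omega2_hat, p2_hat = lr$p2_hat,
    tree_length = lr$tree_length,
    stage = stage, accepted = lr$accepted,
    stringsAsFactors = FALSE
  )
}

#' Screen a batch of orthogroup alignments for positive selection
#'
#' Applies, per orthogroup: alignment quality control (edge trimming and
#' the minimum-length rule), the branch likelihood-ratio test, the
#' tree-length exclusion, and the acceptance rules.  Per-orthogroup
#' failures are logged and skipped, never fatal.
#'
#' @param alignments Named list of [codon_alignment()] objects (or a
#'   directory of FASTA files, read with [read_codon_fasta()]).
#' @param tree Unrooted species tree with one foreground branch; its
#'   branch lengths are starting values only.
#' @param config List of settings overriding the defaults: `alpha` (0.001),
#'   `tree_length_max` (10), `min_codons` (100), `trim` (TRUE, apply
#'   [trim_to_conserved_edges()]), `mask` (FALSE, apply
#'   [mask_suspect_regions()]), `include_m1` (FALSE), `n_starts` (1),
#'   `seed`, `control` (optimizer control for [fit_model()]).
#' @param verbose Log stagewise counts with `message()`.
#' @return A data frame report (one row per orthogroup: log-likelihoods,
#'   statistic, p-value, omega2 and p2 estimates, tree length, stage flag,
#'   acceptance) with attribute `counts`, a named vector of stagewise
#'   totals.
#' @export
screen_orthogroups <- function(alignments, tree, config = list(), verbose = TRUE) {
  cfg <- utils::modifyList(list(
    alpha = 0.001, tree_length_max = 10, min_codons = 100,
    trim = TRUE, mask = FALSE, include_m1 = FALSE,
    n_starts = 1, seed = NULL, control = list()
  ), config)
  if (is.character(alignments) && length(alignments) == 1L && dir.exists(alignments)) {
    files <- list.files(alignments, pattern = "\\.(fa|fna|fasta)$", full.names = TRUE)
    alignments <- stats::setNames(lapply(files, read_codon_fasta),
                                  sub("\\.(fa|fna|fasta)$", "", basename(files)))
  }
  n_in <- length(alignments)
  rows <- list()
  counts <- c(input = n_in, qc_fail = 0L, error = 0L, tested = 0L,
              tree_length_excluded = 0L, significant = 0L, accepted = 0L)
  empty_row <- function(og, stage, ncod = NA_integer_) {
    data.frame(orthogroup = og, n_codons = ncod, lnL_m1 = NA_real_,
               lnL_null = NA_real_, lnL_alt = NA_real_, statistic = NA_real_,
               p_value = NA_real_, omega2_hat = NA_real_, p2_hat = NA_real_,
               tree_length = NA_real_, stage = stage, accepted = FALSE,
               stringsAsFactors = FALSE)
  }
  screen_one <- function(og, aln) {
    if (cfg$trim) {
      aln <- trim_to_conserved_edges(aln)
      if (isTRUE(attr(aln, "no_conserved_triplet"))) {
        return(list(row = empty_row(og, "qc_no_conserved_triplet", 0L),
                    stage = "qc_fail"))
      }
    }
    if (cfg$mask) aln <- mask_suspect_regions(aln)$alignment
    if (!filter_min_length(aln, cfg$min_codons)) {
      return(list(row = empty_row(og, "qc_too_short", ncodons(aln)),
                  stage = "qc_fail"))
    }
    lr <- branch_lrt(aln, tree, alpha = cfg$alpha,
                     tree_length_max = cfg$tree_length_max,
                     include_m1 = cfg$include_m1,
                     n_starts = cfg$n_starts, seed = cfg$seed,
                     control = cfg$control)
    stage <- if (lr$tree_length > cfg$tree_length_max) "tree_length" else "tested"
    list(row = lrt_row(og, lr, stage), stage = stage, lr = lr)
  }
  for (og in names(alignments)) {
    res <- tryCatch(screen_one(og, alignments[[og]]), error = function(e) {
      if (verbose) message("orthogroup ", og, " failed: ", conditionMessage(e))
      list(row = empty_row(og, "error"), stage = "error")
    })
    rows[[og]] <- res$row
    if (res$stage == "qc_fail") {
      counts["qc_fail"] <- counts["qc_fail"] + 1L
    } else if (res$stage == "error") {
      counts["error"] <- counts["error"] + 1L
    } else {
      counts["tested"] <- counts["tested"] + 1L
      if (res$stage == "tree_length") {
        counts["tree_length_excluded"] <- counts["tree_length_excluded"] + 1L
      }
      if (res$lr$p_value < cfg$alpha) counts["significant"] <- counts["significant"] + 1L
      if (res$lr$accepted) counts["accepted"] <- counts["accepted"] + 1L
    }
  }
  report <- if (length(rows) > 0) do.call(rbind, rows) else empty_row(character(0), character(0))
  rownames(report) <- NULL
  if (verbose) {
    message("screen: ", counts["input"], " in, ", counts["tested"], " tested, ",
            counts["significant"], " significant (alpha = ", cfg$alpha, "), ",
            counts["tree_length_excluded"], " tree-length excluded, ",
            counts["accepted"], " accepted")
  }
  attr(report, "counts") <- counts
  report
}
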