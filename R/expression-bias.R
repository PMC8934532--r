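# Tissue-expression bias of selected vs non-selected genes: per-gene max
# normalization, removal of highly correlated tissues (so multiple-test
# corrections are not inflated by near-duplicate tissues), peak-tissue
# enrichment, and per-tissue mean comparisons.

#' Normalize each gene's expression to its maximum
#'
#' Every non-all-zero gene row is divided by its row maximum, so values are
#' relative expression in `[0, 1]` with the peak tissue at exactly 1.
#' All-zero rows are kept as zeros and flagged (attribute `no_expression`),
#' and are excluded from peak assignment and mean tests downstream.
#'
#' @param m Nonnegative gene x tissue matrix.
#' @return The normalized matrix with attributes `normalized = TRUE` and
#'   `no_expression` (logical per gene).
#' @export
normalize_to_max <- function(m) {
  if (any(m < 0)) stop("expression values must be nonnegative")
  mx <- apply(m, 1, max)
  zero <- mx == 0
  out <- m / ifelse(zero, 1, mx)
  attr(out, "normalized") <- TRUE
  attr(out, "no_expression") <- zero
  out
}

#' Remove one tissue of each highly correlated pair
#'
#' Computes all pairwise Pearson correlations between tissues (across
#' genes), then walks the offending pairs (correlation above
#' `r_threshold`) in descending order; for each pair whose members are both still retained, one member is
#' removed uniformly at random.  Afterwards no retained pair exceeds the
#' threshold.  The removal log makes every choice auditable and the seed
#' makes runs reproducible.
#'
#' @param m Normalized gene x tissue matrix (see [normalize_to_max()]).
#' @param r_threshold Correlation threshold (default 0.90).
#' @param seed Optional integer seed for the uniform member choice.
#' @return List with `retained` (tissue names), `removed`, and `log` (data
#'   frame: `removed`, `kept`, `r` per removal).
#' @export
decorrelate_tissues <- function(m, r_threshold = 0.90, seed = NULL) {
  if (ncol(m) < 2) stop("need at least 2 tissues")
  if (!is.null(seed)) set.seed(seed)
  tissues <- colnames(m)
  zerovar <- apply(m, 2, stats::var) == 0
  if (any(zerovar)) {
    warning("tissue(s) with zero variance excluded from correlation: ",
            paste(tissues[zerovar], collapse = ", "))
  }
  usable <- tissues[!zerovar]
  cm <- stats::cor(m[, usable, drop = FALSE])
  pairs <- which(upper.tri(cm) & cm > r_threshold, arr.ind = TRUE)
  log <- data.frame(removed = character(), kept = character(), r = numeric(),
                    stringsAsFactors = FALSE)
  retained <- tissues
  if (nrow(pairs) > 0) {
    ord <- order(-cm[pairs])
    for (k in ord) {
      a <- usable[pairs[k, 1]]; b <- usable[pairs[k, 2]]
      if (!(a %in% retained) || !(b %in% retained)) next
      drop <- if (stats::runif(1) < 0.5) a else b
      retained <- setdiff(retained, drop)
      log <- rbind(log, data.frame(removed = drop, kept = setdiff(c(a, b), drop),
                                   r = cm[pairs[k, 1], pairs[k, 2]],
                                   stringsAsFactors = FALSE))
    }
  }
  list(retained = retained, removed = setdiff(tissues, retained), log = log)
}

#' Peak tissue per gene
#'
#' The tissue of maximum relative expression per gene; ties are broken by
#' the first tissue in the matrix column order.  Genes flagged
#' `no_expression` are excluded.
#'
#' @param m Normalized gene x tissue matrix, restricted to retained
#'   tissues.
#' @return Named character vector mapping gene id to peak tissue.
#' @export
peak_tissue <- function(m) {
  zero <- attr(m, "no_expression") %||% (apply(m, 1, max) == 0)
  mm <- m[!zero, , drop = FALSE]
  stats::setNames(colnames(m)[apply(mm, 1, which.max)], rownames(mm))
}

#' Peak-tissue enrichment test
#'
#' For a focal tissue, builds the 2x2 table {selected, not selected} x
#' {peak in focal tissue, peak elsewhere} (all other tissues pooled into a
#' single bin) and applies the two-sided Fisher exact test.  When `focal`
#' is `NULL` the test is run for every tissue with BH adjustment across
#' tissues.
#'
#' @param peaks Named peak-tissue vector from [peak_tissue()].
#' @param selected Named logical vector (or character vector of selected
#'   gene ids) over the same genes.
#' @param focal Focal tissue name, or `NULL` for all tissues.
#' @param tissues Tissue universe (default: observed peak values).
#' @param removal_log Optional removal log from [decorrelate_tissues()],
#'   used to explain an error when the focal tissue was removed.
#' @return For one focal tissue: list with `table`, `p_value`.  For all:
#'   data frame `tissue`, `selected_peak`, `selected_other`,
#'   `background_peak`, `background_other`, `p_value`, `p_adjusted`.
#' @export
peak_enrichment_test <- function(peaks, selected, focal = NULL,
                                 tissues = sort(unique(peaks)),
                                 removal_log = NULL) {
  if (is.character(selected)) selected <- stats::setNames(
    names(peaks) %in% selected, names(peaks))
  sel <- selected[names(peaks)]
  one <- function(tis) {
    tab <- matrix(c(sum(sel & peaks == tis), sum(sel & peaks != tis),
                    sum(!sel & peaks == tis), sum(!sel & peaks != tis)),
                  2, 2, byrow = TRUE,
                  dimnames = list(c("selected", "not_selected"),
                                  c("peak_focal", "peak_elsewhere")))
    if (sum(sel) == 0) {
      warning("no selected genes with expression data: p = 1")
      return(list(table = tab, p_value = 1))
    }
    list(table = tab, p_value = fisher_exact(tab))
  }
  if (!is.null(focal)) {
    if (!focal %in% tissues) {
      hint <- ""
      if (!is.null(removal_log) && focal %in% removal_log$removed) {
        i <- match(focal, removal_log$removed)
        hint <- paste0(" (removed by decorrelation, r = ",
                       signif(removal_log$r[i], 3), " with ",
                       removal_log$kept[i], ")")
      }
      stop("focal tissue '", focal, "' is not retained", hint)
    }
    return(one(focal))
  }
  rows <- lapply(tissues, function(tis) {
    r <- one(tis)
    data.frame(tissue = tis,
               selected_peak = r$table[1, 1], selected_other = r$table[1, 2],
               background_peak = r$table[2, 1], background_other = r$table[2, 2],
               p_value = r$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- bh_adjust(out$p_value)
  out
}

#' Per-tissue mean-expression comparison of selected vs other genes
#'
#' Pooled-variance two-sided t-test of normalized expression per retained
#' tissue, BH-adjusted across tissues, sorted by t statistic descending
#' (so the most selected-biased tissue ranks first).
#'
#' @param m Normalized gene x tissue matrix restricted to retained
#'   tissues; rows flagged `no_expression` are dropped.
#' @param selected Named logical vector or character vector of selected
#'   gene ids.
#' @return Data frame: `tissue`, `mean_selected`, `mean_other`, `t`, `df`,
#'   `p_value`, `p_adjusted`, ordered by `t` descending.
#' @export
mean_expression_tests <- function(m, selected) {
  zero <- attr(m, "no_expression") %||% (apply(m, 1, max) == 0)
  mm <- m[!zero, , drop = FALSE]
  if (is.character(selected)) selected <- stats::setNames(
    rownames(m) %in% selected, rownames(m))
  sel <- selected[rownames(mm)]
  if (sum(sel) < 2 || sum(!sel) < 2) stop("need at least 2 genes per group")
  rows <- lapply(colnames(mm), function(tis) {
    tt <- two_sample_t(mm[sel, tis], mm[!sel, tis])
    data.frame(tissue = tis, mean_selected = tt$mean_x, mean_other = tt$mean_y,
               t = tt$t, df = tt$df, p_value = tt$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- bh_adjust(out$p_value)
  out <- out[order(-out$t), ]
  rownames(out) <- NULL
  out
}
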