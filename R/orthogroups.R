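# Orthogroup membership filtering: only "perfect" single-copy orthogroups
# (exactly one gene per species) or "near-perfect" ones (a single paralog
# pair in one species other than the focal lineage) are carried forward,
# because closely related paralogs can evolve non-independently and distort
# the background rate estimate.  Near-perfect groups are pruned of one
# paralog copy by a deterministic identity-based rule.

#' Construct an orthogroup record
#'
#' @param og_id Orthogroup identifier.
#' @param members Named list mapping species to character vectors of gene
#'   ids; every configured species must be a key (possibly empty).
#' @param species Ordered character vector of the configured species list;
#'   absent keys are filled with empty vectors.
#' @return A list of class `orthogroup_record` with an `unset`
#'   classification.
#' @export
orthogroup_record <- function(og_id, members, species = names(members)) {
  members <- members[intersect(names(members), species)]
  for (sp in setdiff(species, names(members))) members[[sp]] <- character(0)
  structure(list(og_id = og_id, members = members[species],
                 classification = "unset"),
            class = "orthogroup_record")
}

#' Classify an orthogroup by per-species gene counts
#'
#' `perfect` if every species has exactly one member; `near_perfect` if
#' exactly one species other than the focal one has exactly two members and
#' all others exactly one; `rejected` otherwise (any absence, any focal
#' duplication, more than two copies anywhere, or two or more duplicated
#' species).
#'
#' @param record An [orthogroup_record()].
#' @param species Ordered species list.
#' @param focal Focal species id; duplications here always reject.
#' @return The record with its `classification` field set.
#' @export
classify_orthogroup <- function(record, species, focal) {
  if (!focal %in% species) {
    stop("configuration error: focal species '", focal, "' not in species list")
  }
  counts <- vapply(species, function(sp) {
    m <- record$members[[sp]]
    if (is.null(m)) 0L else length(m)
  }, integer(1))
  record$classification <-
    if (all(counts == 1L)) {
      "perfect"
    } else {
      dup2 <- names(counts)[counts == 2L]
      if (all(counts %in% c(1L, 2L)) && length(dup2) == 1L && dup2 != focal) {
        "near_perfect"
      } else {
        "rejected"
      }
    }
  record
}

#' Prune the single allowed paralog from a near-perfect orthogroup
#'
#' Exactly one of the two duplicate copies is removed.  The retained copy
#' is the one with the higher mean pairwise identity to the single-copy
#' members; ties are broken by the longer protein, then by the
#' lexicographically smaller gene id.  The result classifies as perfect.
#'
#' @param record A `near_perfect` [orthogroup_record()].
#' @param protein_lengths Named numeric vector of protein lengths covering
#'   both duplicate gene ids.
#' @param pairwise_identity Named numeric vector of identity fractions with
#'   names `"geneA|geneB"` (order-insensitive lookup), or a function of two
#'   gene ids.
#' @return The pruned record (classification `perfect`), with attribute
#'   `pruned_gene_id` naming the removed copy.
#' @export
prune_paralog <- function(record, protein_lengths, pairwise_identity) {
  if (!identical(record$classification, "near_perfect")) {
    stop("prune_paralog requires a near_perfect record (got '",
         record$classification, "')")
  }
  counts <- vapply(record$members, length, integer(1))
  sp_dup <- names(counts)[counts == 2L]
  dups <- record$members[[sp_dup]]
  if (!all(dups %in% names(protein_lengths))) {
    stop("protein_lengths must cover both duplicates: ",
         paste(dups, collapse = ", "))
  }
  singles <- unlist(record$members[names(counts)[counts == 1L]], use.names = FALSE)
  ident <- if (is.function(pairwise_identity)) {
    pairwise_identity
  } else {
    function(a, b) {
      v <- pairwise_identity[paste(a, b, sep = "|")]
      if (is.na(v)) v <- pairwise_identity[paste(b, a, sep = "|")]
      unname(v)
    }
  }
  mean_ident <- vapply(dups, function(d) {
    mean(vapply(singles, function(s) ident(d, s), numeric(1)))
  }, numeric(1))
  # keep higher mean identity; tie -> longer protein -> smaller gene id
  ord <- order(-mean_ident, -protein_lengths[dups], dups)
  keep <- dups[ord[1]]
  drop <- setdiff(dups, keep)
  record$members[[sp_dup]] <- keep
  record$classification <- "perfect"
  attr(record, "pruned_gene_id") <- drop
  record
}

#' Read a long-format orthogroup membership table
#'
#' @param path TSV with columns `orthogroup_id`, `species`, `gene_id`.
#' @param species Ordered species list for the records.
#' @return Named list of [orthogroup_record()]s.
#' @export
read_orthogroups <- function(path, species) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("orthogroup_id", "species", "gene_id")
  if (!all(need %in% names(df))) {
    stop("orthogroup table needs columns: ", paste(need, collapse = ", "))
  }
  recs <- lapply(split(df, df$orthogroup_id), function(d) {
    orthogroup_record(d$orthogroup_id[1],
                      split(d$gene_id, factor(d$species, levels = species)),
                      species)
  })
  recs[order(names(recs))]
}

#' Classify a set of orthogroup records and log stagewise counts
#'
#' @param records List of [orthogroup_record()]s.
#' @param species Ordered species list.
#' @param focal Focal species id.
#' @param verbose Log counts in/out with `message()`.
#' @return A data frame with columns `orthogroup_id` and `classification`,
#'   with attribute `records` holding the classified records.
#' @export
classify_orthogroups <- function(records, species, focal, verbose = TRUE) {
  records <- lapply(records, classify_orthogroup, species = species, focal = focal)
  cls <- vapply(records, `[[`, character(1), "classification")
  if (verbose) {
    message("orthogroups: ", length(records), " in, ",
            sum(cls == "perfect"), " perfect, ",
            sum(cls == "near_perfect"), " near-perfect, ",
            sum(cls == "rejected"), " rejected")
  }
  out <- data.frame(orthogroup_id = vapply(records, `[[`, character(1), "og_id"),
                    classification = cls, stringsAsFactors = FALSE,
                    row.names = NULL)
  attr(out, "records") <- records
  out
}
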