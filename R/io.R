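# Readers and writers for the standard formats the pipeline touches:
# FASTA sequence sets, GFF3 gene models, Newick trees with a foreground tag,
# and tab-separated report tables.

#' Read a FASTA file
#'
#' @param path Path to a FASTA file.
#' @return A data frame with columns `id`, `description` and `residues`
#'   (uppercase, whitespace stripped), one row per record in file order.
#'   File order defines "first listed" semantics used downstream.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L) stop("FASTA format error at line 1: empty file: ", path)
  if (!startsWith(first, ">")) {
    stop("FASTA format error at line 1: expected '>' header in ", path)
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("FASTA format error: no records in ", path)
  headers <- names(set)
  id <- sub("\\s.*$", "", headers)
  if (any(id == "")) stop("FASTA format error: empty record id in ", path)
  if (anyDuplicated(id)) {
    stop("FASTA format error: duplicate record id '", id[duplicated(id)][1], "' in ", path)
  }
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  res <- toupper(gsub("\\s", "", as.character(set)))
  data.frame(id = id, description = desc, residues = unname(res),
             stringsAsFactors = FALSE)
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences, or a data frame as
#'   returned by [read_fasta()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.data.frame(seqs)) {
    hdr <- ifelse(nzchar(seqs$description),
                  paste(seqs$id, seqs$description), seqs$id)
    writeLines(paste0(">", hdr, "\n", seqs$residues), path)
  } else {
    writeLines(paste0(">", names(seqs), "\n", unname(seqs)), path)
  }
  invisible(path)
}

# -- GFF3 gene models --------------------------------------------------------

gff_attr <- function(attributes, key) {
  pat <- paste0("(^|;)\\s*", key, "=([^;]*)")
  m <- regexpr(pat, attributes, perl = TRUE)
  out <- rep(NA_character_, length(attributes))
  hit <- m != -1L
  out[hit] <- sub(pat, "\\2", regmatches(attributes, m), perl = TRUE)
  out
}

#' Read gene models from a GFF3 file
#'
#' Builds one locus per `gene` feature.  The locus span is the minimum start
#' and maximum end over the gene and all its descendant features.  The exon
#' count is the number of `exon` features of the first mRNA in file order
#' (its `CDS` features if it has no exons); for genes without an mRNA the
#' gene's direct exon (or CDS) children are counted.  The midpoint is
#' `floor((start + end) / 2)` and is strand-independent.
#'
#' @param path Path to a GFF3 file.
#' @return A data frame of loci with columns `gene_id`, `scaffold`, `start`,
#'   `end`, `strand`, `exon_count`, `midpoint`, `selected` (initialised
#'   `FALSE`).
#' @export
read_gff_gene_models <- function(path) {
  gff <- ape::read.gff(path, GFF3 = TRUE)
  gff$ID <- gff_attr(gff$attributes, "ID")
  gff$Parent <- gff_attr(gff$attributes, "Parent")
  genes <- gff[gff$type == "gene", , drop = FALSE]
  if (nrow(genes) == 0L) {
    warning("no gene features in ", path)
    return(empty_gene_loci())
  }
  known <- gff$ID[!is.na(gff$ID)]
  parents <- unlist(strsplit(gff$Parent[!is.na(gff$Parent)], ","))
  missing_parent <- setdiff(parents, known)
  if (length(missing_parent) > 0L) {
    stop("GFF consistency error: feature(s) reference missing parent '",
         missing_parent[1], "'")
  }
  out <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    gid <- if (!is.na(g$ID)) g$ID else paste0("gene_", i)
    mrna <- gff[!is.na(gff$Parent) & gff$Parent == g$ID &
                  gff$type %in% c("mRNA", "transcript"), , drop = FALSE]
    if (nrow(mrna) > 0L) {
      first <- mrna$ID[1]  # first listed isoform
      kids <- gff[!is.na(gff$Parent) & gff$Parent %in% mrna$ID, , drop = FALSE]
      ex <- sum(kids$type == "exon" & kids$Parent == first)
      if (ex == 0L) ex <- sum(kids$type == "CDS" & kids$Parent == first)
      span_feats <- rbind(g[, c("start", "end")], mrna[, c("start", "end")],
                          kids[, c("start", "end")])
    } else {
      kids <- gff[!is.na(gff$Parent) & gff$Parent == g$ID, , drop = FALSE]
      ex <- sum(kids$type == "exon")
      if (ex == 0L) ex <- sum(kids$type == "CDS")
      span_feats <- rbind(g[, c("start", "end")], kids[, c("start", "end")])
    }
    data.frame(gene_id = gid, scaffold = as.character(g$seqid),
               start = min(span_feats$start), end = max(span_feats$end),
               strand = as.character(g$strand), exon_count = max(ex, 1L),
               stringsAsFactors = FALSE)
  })
  loci <- do.call(rbind, out)
  gene_loci(loci)
}

#' Construct a validated table of gene loci
#'
#' @param df Data frame with columns `gene_id`, `scaffold`, `start`, `end`,
#'   `strand`, `exon_count`, optionally `selected`.
#' @return The validated data frame with `midpoint` and `selected` columns.
#' @export
gene_loci <- function(df) {
  need <- c("gene_id", "scaffold", "start", "end", "strand", "exon_count")
  if (!all(need %in% names(df))) {
    stop("gene loci need columns: ", paste(need, collapse = ", "))
  }
  if (any(df$start > df$end)) stop("locus with start > end")
  if (any(df$exon_count < 1)) stop("exon_count must be >= 1")
  df$midpoint <- floor((df$start + df$end) / 2)
  if (is.null(df$selected)) df$selected <- rep(FALSE, nrow(df))
  rownames(df) <- NULL
  df
}

empty_gene_loci <- function() {
  gene_loci(data.frame(gene_id = character(), scaffold = character(),
                       start = integer(), end = integer(),
                       strand = character(), exon_count = integer(),
                       stringsAsFactors = FALSE))
}

# -- Newick trees ------------------------------------------------------------

#' Read a Newick tree, unrooting and extracting the foreground tag
#'
#' Rooted input (a bifurcation at the root) is unrooted by collapsing the
#' root into a trifurcation; the two root-adjacent branch lengths are summed
#' onto the merged branch.  A `#1` suffix on a tip or internal node label
#' marks the branch leading to that node as the foreground branch of
#' branch-specific selection models.
#'
#' @param path Path to a Newick file (or a Newick string via `text`).
#' @param text Newick string, used instead of `path` when given.
#' @return An `ape::phylo` tree, unrooted, with attribute
#'   `foreground_edges` (integer edge indices, possibly empty) and attribute
#'   `lengths_to_estimate = TRUE` when the input had no branch lengths.
#' @export
read_newick <- function(path, text = NULL) {
  tr <- if (is.null(text)) ape::read.tree(path) else ape::read.tree(text = text)
  if (is.null(tr)) stop("could not parse Newick input")
  fg_tag <- "#\\d+$"
  fg_tips <- grepl(fg_tag, tr$tip.label)
  tr$tip.label <- sub(fg_tag, "", tr$tip.label)
  fg_nodes_lab <- logical(0)
  if (!is.null(tr$node.label)) {
    fg_nodes_lab <- grepl(fg_tag, tr$node.label)
    tr$node.label <- sub(fg_tag, "", tr$node.label)
  }
  if (anyDuplicated(tr$tip.label)) {
    stop("duplicate leaf label: ", tr$tip.label[duplicated(tr$tip.label)][1])
  }
  fg_tip_labels <- tr$tip.label[fg_tips]
  fg_clades <- lapply(which(fg_nodes_lab), function(i) {
    node <- ape::Ntip(tr) + i
    tr$tip.label[unlist(tip_descendants(tr, node))]
  })
  no_lengths <- is.null(tr$edge.length)
  # a 2-taxon tree has no root/unroot distinction ape can collapse
  if (ape::is.rooted(tr) && length(tr$tip.label) > 2) tr <- ape::unroot(tr)
  fg_edges <- integer(0)
  for (lab in fg_tip_labels) {
    fg_edges <- c(fg_edges, which(tr$edge[, 2] == match(lab, tr$tip.label)))
  }
  for (tips in fg_clades) {
    node <- ape::getMRCA(tr, tips)
    if (!is.null(node)) fg_edges <- c(fg_edges, which(tr$edge[, 2] == node))
  }
  attr(tr, "foreground_edges") <- sort(unique(fg_edges))
  if (no_lengths) attr(tr, "lengths_to_estimate") <- TRUE
  tr
}

# tip indices descending from an internal node (small helper; trees here are
# tiny so a simple recursion is fine)
tip_descendants <- function(tr, node) {
  ntip <- ape::Ntip(tr)
  kids <- tr$edge[tr$edge[, 1] == node, 2]
  unlist(lapply(kids, function(k) {
    if (k <= ntip) k else phangorn_free_descendants(tr, k)
  }))
}

#' Mark the foreground branch of a tree
#'
#' @param tree An `ape::phylo` tree.
#' @param tips Character vector of tip labels: the foreground branch is the
#'   terminal branch when one tip is given, otherwise the branch subtending
#'   the most recent common ancestor of the tips.
#' @return The tree with attribute `foreground_edges` set.
#' @export
set_foreground <- function(tree, tips) {
  missing <- setdiff(tips, tree$tip.label)
  if (length(missing) > 0) stop("tip(s) not in tree: ", paste(missing, collapse = ", "))
  node <- if (length(tips) == 1L) {
    match(tips, tree$tip.label)
  } else {
    ape::getMRCA(tree, tips)
  }
  edge <- which(tree$edge[, 2] == node)
  if (length(edge) != 1L) stop("no branch subtends the requested foreground node")
  attr(tree, "foreground_edges") <- edge
  tree
}

#' @rdname set_foreground
#' @return `foreground_edges()` returns the integer edge indices currently
#'   marked as foreground (possibly empty).
#' @export
foreground_edges <- function(tree) {
  fe <- attr(tree, "foreground_edges")
  if (is.null(fe)) integer(0) else fe
}

# -- report tables -----------------------------------------------------------

#' Write a tabular result set as TSV
#'
#' Tab-separated with a header row; numeric values are rendered with full
#' precision (at least 15 significant digits) so that re-reading reproduces
#' them within float round-trip.
#'
#' @param results A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path) {
  if (is.null(results)) stop("'results' must not be NULL")
  num <- vapply(results, is.numeric, logical(1))
  out <- results
  out[num] <- lapply(results[num], function(x) format(x, digits = 15, trim = TRUE))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a TSV report written by [write_report()]
#'
#' @param path Path to the TSV file.
#' @return A data frame.
#' @export
read_report <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}

#' Read a scaffold-length table
#'
#' @param path TSV with columns `scaffold` and `length`.
#' @return Named numeric vector of scaffold lengths.
#' @export
read_scaffold_lengths <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("scaffold", "length") %in% names(df))) {
    stop("scaffold length table needs columns 'scaffold' and 'length'")
  }
  stats::setNames(as.numeric(df$length), df$scaffold)
}

#' Read a gene x tissue expression table
#'
#' @param path TSV whose first column holds gene ids and whose remaining
#'   columns (named by tissue) hold nonnegative expression values.
#' @return Numeric matrix, genes in rows, tissues in columns.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  if (any(m < 0, na.rm = TRUE)) stop("negative expression values")
  m
}
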