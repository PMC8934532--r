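# Synthetic data generators: codon alignments evolved under the site-class
# models, gene landscapes on multi-scaffold genomes, and expression
# matrices with correlated tissue pairs.  The generators exist so that
# every pipeline stage is testable without external data; they share the
# rate-matrix machinery with the likelihood engine, so simulated branch
# lengths are in the same substitutions-per-codon units the fits report.

#' Default 8-taxon species tree fixture
#'
#' An unrooted 8-leaf tree with one designated foreground terminal branch
#' (`"focal"`), mirroring a small multispecies comparative design with two
#' major subclades.  Branch lengths total about one expected substitution
#' per codon, typical of single-copy orthogroups among confamilial and
#' subordinal relatives.
#'
#' @return An `ape::phylo` with attribute `foreground_edges` on the
#'   `"focal"` terminal branch.
#' @export
default_species_tree <- function() {
  txt <- paste0("((focal:0.06,bg1:0.06):0.04,(bg2:0.08,bg3:0.08):0.05,",
                "((bg4:0.09,bg5:0.09):0.06,(bg6:0.10,bg7:0.10):0.06):0.08);")
  tr <- read_newick(text = txt)
  set_foreground(tr, "focal")
}

#' Simulate a codon alignment under a site-class model
#'
#' Each site is assigned to a class by `(p0, p1, p2)`; a root codon is drawn
#' from `pi` at an internal node and states evolve along each branch under
#' the class- and branch-appropriate transition matrix.  Class-2 sites use
#' `omega2` on the foreground branch(es) only when `foreground_active` is
#' `TRUE`; otherwise (and on background branches always) they evolve
#' neutrally.  No indels are simulated.
#'
#' @param tree Unrooted `ape::phylo` with branch lengths in substitutions
#'   per codon and (optionally) a foreground branch.
#' @param params Model parameters (`kappa`, `p0`, `p1`, `omega0`,
#'   `omega2`).
#' @param n_codons Number of codon sites, >= 1.
#' @param foreground_active Apply `omega2` on foreground branches?
#' @param pi Codon frequencies (default the self-consistent F3x4
#'   distribution, [codon_freq_f3x4_stationary()]).
#' @param seed Optional integer seed.
#' @param code_id Genetic code id.
#' @return A [codon_alignment()] with attribute `site_class` (integer 0/1/2
#'   true class per site).
#' @export
simulate_codon_alignment <- function(tree, params, n_codons,
                                     foreground_active = TRUE, pi = NULL,
                                     seed = NULL, code_id = "1") {
  if (!is.null(seed)) set.seed(seed)
  if (n_codons < 1) stop("n_codons must be >= 1")
  validate_params(params, "M2_branch")
  tab <- codon_table(code_id)
  if (is.null(pi)) pi <- codon_freq_f3x4_stationary(code_id)
  cls <- model_classes(params, "M2_branch")
  po <- ape::reorder.phylo(tree, "postorder")
  perm <- match(paste(po$edge[, 1], po$edge[, 2]),
                paste(tree$edge[, 1], tree$edge[, 2]))
  fg_po <- which(perm %in% foreground_edges(tree))
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  root <- ntip + 1L

  site_class <- sample.int(3L, n_codons, replace = TRUE, prob = cls$p) - 1L
  states <- matrix(0L, nnode, n_codons)
  states[root, ] <- sample.int(tab$n, n_codons, replace = TRUE, prob = pi)

  omegas <- sort(unique(c(cls$omega, 1)))
  eigs <- lapply(omegas, function(w) {
    q <- build_rate_matrix(params$kappa, w, pi, rate_scale = 1, tab = tab)
    rate_eigen(q, pi)
  })
  rates <- vapply(omegas, function(w) unscaled_mean_rate(params$kappa, w, pi, tab),
                  numeric(1))
  # preorder: parents before children
  for (e in rev(seq_len(nrow(po$edge)))) {
    par <- po$edge[e, 1]; ch <- po$edge[e, 2]
    class_omega <- cls$omega
    if (!(e %in% fg_po) || !foreground_active) class_omega[3] <- 1
    edge_rate <- sum(cls$p * rates[match(class_omega, omegas)])
    s <- po$edge.length[e] / edge_rate
    for (c in 1:3) {
      idx <- which(site_class == c - 1L)
      if (length(idx) == 0) next
      eg <- eigs[[match(class_omega[c], omegas)]]
      P <- eg$U %*% (exp(eg$lambda * s) * eg$W)
      P[P < 0] <- 0
      for (st in unique(states[par, idx])) {
        sub <- idx[states[par, idx] == st]
        states[ch, sub] <- sample.int(tab$n, length(sub), replace = TRUE,
                                      prob = P[st, ])
      }
    }
  }
  m <- matrix(tab$codons[states[seq_len(ntip), , drop = FALSE]], nrow = ntip,
              dimnames = list(tree$tip.label, NULL))
  aln <- codon_alignment(m, code_id = code_id)
  attr(aln, "site_class") <- site_class
  aln
}

#' Simulate a batch of orthogroup alignments with a truth table
#'
#' Emits `n_null` alignments simulated without foreground selection and
#' `n_selected` with it, plus a truth table consumable by
#' [screen_orthogroups()].
#'
#' @param n_null,n_selected Nonnegative counts of null and selected
#'   orthogroups.
#' @param tree Species tree with foreground branch (default
#'   [default_species_tree()]).
#' @param params Model parameters used for every orthogroup.
#' @param n_codons Codon columns per alignment.
#' @param seed Integer seed.
#' @param dir Optional directory: when given, writes one FASTA per
#'   orthogroup and a `truth.tsv`.
#' @return List with `alignments` (named list) and `truth` (data frame with
#'   columns `orthogroup`, `foreground_active`, `omega2`, `p2`).
#' @export
simulate_orthogroup_batch <- function(n_null, n_selected,
                                      tree = default_species_tree(),
                                      params = list(kappa = 2, p0 = 0.5,
                                                    p1 = 0.3, omega0 = 0.1,
                                                    omega2 = 8),
                                      n_codons = 600, seed = NULL, dir = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- n_null + n_selected
  ogs <- sprintf("OG%05d", seq_len(max(n, 0)))
  active <- c(rep(FALSE, n_null), rep(TRUE, n_selected))
  alignments <- stats::setNames(vector("list", n), ogs)
  for (i in seq_len(n)) {
    alignments[[i]] <- simulate_codon_alignment(tree, params, n_codons,
                                                foreground_active = active[i])
  }
  truth <- data.frame(
    orthogroup = ogs, foreground_active = active,
    omega2 = ifelse(active, params$omega2, 1),
    p2 = rep(1 - params$p0 - params$p1, n),
    stringsAsFactors = FALSE
  )
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (og in ogs) write_codon_fasta(alignments[[og]], file.path(dir, paste0(og, ".fna")))
    write_report(truth, file.path(dir, "truth.tsv"))
  }
  list(alignments = alignments, truth = truth)
}

#' Simulate a gene landscape on a multi-scaffold genome
#'
#' Gene midpoints are placed uniformly, scaffolds chosen with probability
#' proportional to length, and expanded to short non-overlapping spans.
#' Selected flags are i.i.d. at `selected_fraction`, except for planted
#' clusters, which add `n_selected` selected genes within a stated span.
#'
#' @param scaffold_lengths Named numeric vector of scaffold lengths (bases).
#' @param n_genes Number of background genes.
#' @param selected_fraction Probability a background gene is selected.
#' @param planted_clusters Optional data frame with columns `scaffold`,
#'   `center`, `span`, `n_selected`; each row plants that many additional
#'   selected genes uniformly within `center +/- span/2`.
#' @param single_exon_fraction Fraction of genes drawn single-exon.
#' @param seed Integer seed.
#' @return List with `loci` (a [gene_loci()] data frame) and
#'   `scaffold_lengths`.
#' @export
simulate_landscape <- function(scaffold_lengths, n_genes,
                               selected_fraction = 0.016,
                               planted_clusters = NULL,
                               single_exon_fraction = 0.1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(names(scaffold_lengths))) {
    names(scaffold_lengths) <- sprintf("scaffold_%03d", seq_along(scaffold_lengths))
  }
  if (selected_fraction < 0 || selected_fraction > 1 ||
      single_exon_fraction < 0 || single_exon_fraction > 1) {
    stop("fractions must lie in [0, 1]")
  }
  scafs <- sample(names(scaffold_lengths), n_genes, replace = TRUE,
                  prob = scaffold_lengths)
  mids <- floor(stats::runif(n_genes, 1, scaffold_lengths[scafs] + 1))
  sel <- stats::runif(n_genes) < selected_fraction
  if (!is.null(planted_clusters)) {
    for (i in seq_len(nrow(planted_clusters))) {
      pc <- planted_clusters[i, ]
      len <- scaffold_lengths[[pc$scaffold]]
      if (is.null(len) || is.na(len)) stop("planted cluster on unknown scaffold ", pc$scaffold)
      lo <- pc$center - pc$span / 2; hi <- pc$center + pc$span / 2
      if (lo < 1 || hi > len) stop("planted cluster does not fit within scaffold ", pc$scaffold)
      if (pc$n_selected > pc$span / 100) stop("infeasible cluster: too many genes for span")
      mids <- c(mids, floor(stats::runif(pc$n_selected, lo, hi)))
      scafs <- c(scafs, rep(pc$scaffold, pc$n_selected))
      sel <- c(sel, rep(TRUE, pc$n_selected))
    }
  }
  n <- length(mids)
  exons <- ifelse(stats::runif(n) < single_exon_fraction, 1L,
                  1L + stats::rpois(n, 6))
  exons[exons < 1L] <- 1L
  # expand midpoints to short non-overlapping spans
  ord <- order(scafs, mids)
  half <- rep(500, n)
  for (sc in unique(scafs)) {
    i <- ord[scafs[ord] == sc]
    if (length(i) > 1) {
      gap <- diff(mids[i])
      half[i] <- pmax(1, pmin(500, floor(c(gap, Inf) / 2), floor(c(Inf, gap) / 2)))
    }
    half[i] <- pmin(half[i], mids[i] - 1, scaffold_lengths[[sc]] - mids[i])
    half[i] <- pmax(half[i], 0)
  }
  loci <- gene_loci(data.frame(
    gene_id = sprintf("gene_%05d", seq_len(n)),
    scaffold = scafs, start = mids - half, end = mids + half,
    strand = sample(c("+", "-"), n, replace = TRUE),
    exon_count = exons, selected = sel, stringsAsFactors = FALSE
  ))
  list(loci = loci, scaffold_lengths = scaffold_lengths)
}

#' Simulate a gene x tissue expression matrix
#'
#' Base values are i.i.d. log-normal.  Each correlated pair is built by
#' duplicating one tissue column plus small noise (correlation above 0.95).
#' An optional planted bias adds `shift` to the focal tissue for a fraction
#' of selected genes, before normalization.
#'
#' @param n_genes Number of genes.
#' @param tissues Character vector of tissue names (>= 2).
#' @param n_selected Number of genes flagged as selected (drawn at random).
#' @param correlated_pairs List of length-2 character vectors naming tissue
#'   pairs to make near-duplicates; the second member of each pair is
#'   overwritten by a noisy copy of the first.
#' @param bias Optional list `list(tissue =, shift =, fraction =)`: a shift
#'   added to the focal tissue for that fraction of selected genes.
#' @param seed Integer seed.
#' @return List with `matrix` (genes x tissues, raw nonnegative values) and
#'   `selected` (logical vector).
#' @export
simulate_expression <- function(n_genes, tissues, n_selected = 0,
                                correlated_pairs = list(), bias = NULL,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (length(tissues) < 2) stop("need at least 2 tissues")
  if (!is.null(bias) && bias$shift < 0) stop("bias shift must be >= 0")
  m <- matrix(stats::rlnorm(n_genes * length(tissues), 0, 1),
              n_genes, length(tissues),
              dimnames = list(sprintf("gene_%05d", seq_len(n_genes)), tissues))
  for (pr in correlated_pairs) {
    a <- pr[[1]]; b <- pr[[2]]
    m[, b] <- m[, a] * exp(stats::rnorm(n_genes, 0, 0.05))
  }
  selected <- rep(FALSE, n_genes)
  selected[sample.int(n_genes, min(n_selected, n_genes))] <- TRUE
  if (!is.null(bias)) {
    hit <- which(selected)
    hit <- hit[stats::runif(length(hit)) < bias$fraction]
    m[hit, bias$tissue] <- m[hit, bias$tissue] + bias$shift
  }
  list(matrix = m, selected = selected)
}
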