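# Conservation prioritization: neighbour-joining trees from genetic
# distances, the unrooted-tree Shapley value, and the consensus ranking
# against c-RONA.

#' Neighbour-joining tree from a genetic distance matrix
#'
#' Saitou-Nei agglomeration (via ape) on a symmetric distance matrix;
#' negative branch lengths are clamped to zero.
#'
#' @param dist an `fst_matrix`, or a symmetric numeric matrix with
#'   population dimnames.
#' @return An unrooted `phylo` tree.
#' @export
nj_tree <- function(dist) {
  D <- if (inherits(dist, "fst_matrix")) dist$fst else as.matrix(dist)
  if (anyNA(D)) stopf("distance matrix contains NA")
  if (nrow(D) < 3) stopf("need at least 3 populations")
  if (max(abs(D - t(D))) > 1e-12) stopf("distance matrix must be symmetric")
  tr <- ape::nj(stats::as.dist(D))
  tr$edge.length <- pmax(tr$edge.length, 0)
  tr
}

#' Shapley value of each leaf on an unrooted tree
#'
#' Closed-form split decomposition: each edge of weight `w` splitting the
#' `n` leaves into sides A and B contributes `w |B| / (n |A|)` to every leaf
#' in A. The scores satisfy the efficiency axiom: they sum to the total
#' tree length.
#'
#' @param tree a `phylo` object with edge lengths.
#' @return Object of class `shapley_scores`: data.frame `scores`
#'   (pop, sv), `total_length`.
#' @export
shapley <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  n <- length(tree$tip.label)
  if (n < 2) stopf("need at least 2 leaves")
  if (is.null(tree$edge.length)) stopf("tree has no edge lengths")
  nnode <- max(tree$edge)
  below <- matrix(FALSE, nnode, n)   # leaves below each node (child side)
  below[cbind(seq_len(n), seq_len(n))] <- TRUE
  # postorder: children are complete before their parent edge is visited
  for (e in ape::postorder(tree)) {
    par <- tree$edge[e, 1]; chl <- tree$edge[e, 2]
    below[par, ] <- below[par, ] | below[chl, ]
  }
  sv <- numeric(n)
  for (e in seq_len(nrow(tree$edge))) {
    w <- tree$edge.length[e]
    A <- below[tree$edge[e, 2], ]   # side below the edge
    nA <- sum(A); nB <- n - nA
    if (nA == 0 || nB == 0) next    # root edge artefact: no split
    sv[A] <- sv[A] + w * nB / (n * nA)
    sv[!A] <- sv[!A] + w * nA / (n * nB)
  }
  structure(list(scores = data.frame(pop = tree$tip.label, sv = sv,
                                     stringsAsFactors = FALSE),
                 total_length = sum(tree$edge.length)),
            class = "shapley_scores")
}

#' @exportS3Method base::print
print.shapley_scores <- function(x, ...) {
  cat(sprintf("<shapley_scores> %d pops, total diversity %.4f\n",
              nrow(x$scores), x$total_length))
  invisible(x)
}

#' Shapley index from allele counts on a locus subset
#'
#' Pipeline composition: pairwise WC84 FST on the subset, negative entries
#' floored at zero, neighbour joining, then the split-based Shapley value.
#'
#' @param counts a [genotype_counts] object.
#' @param loci locus id subset (e.g. the neutral or the adaptive set).
#' @param label subset label recorded on the result.
#' @return A `shapley_scores` object with a `label` element.
#' @export
shapley_index <- function(counts, loci, label = "all") {
  if (!length(loci)) stopf("empty locus subset")
  fm <- fst_matrix(counts, loci = loci, n_perm = 0, subset_label = label)
  D <- pmax(fm$fst, 0)
  sv <- shapley(nj_tree(D))
  sv$label <- label
  sv
}

#' Consensus ranking of low maladaptation and high adaptive diversity
#'
#' Populations are ranked by the mean of (rank of ascending c-RONA, rank of
#' descending adaptive Shapley value); ties get average ranks. Rank 1 is
#' the highest conservation priority: locally adapted and carrying much
#' adaptive diversity.
#'
#' @param mean_c_rona named numeric vector of combined c-RONA per population.
#' @param shapley_adaptive a `shapley_scores` object on the adaptive subset.
#' @return data.frame: pop, c_rona_rank, sv_rank, consensus_rank, ordered by
#'   consensus.
#' @export
consensus_rank <- function(mean_c_rona, shapley_adaptive) {
  sv <- shapley_adaptive$scores
  pops <- sv$pop
  if (!all(pops %in% names(mean_c_rona)))
    stopf("c-RONA values missing for: %s",
          paste(setdiff(pops, names(mean_c_rona)), collapse = ", "))
  cr <- mean_c_rona[pops]
  r1 <- rank(cr)          # low c-RONA first
  r2 <- rank(-sv$sv)      # high adaptive SV first
  cons <- rank((r1 + r2) / 2)
  out <- data.frame(pop = pops, c_rona_rank = r1, sv_rank = r2,
                    consensus_rank = cons, stringsAsFactors = FALSE)
  out[order(out$consensus_rank), ]
}
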