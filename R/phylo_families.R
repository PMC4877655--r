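#' Pairwise protein distances from a multiple alignment
#'
#' p-distance (mismatches over compared columns, where both rows are non-gap)
#' or its Poisson correction `-ln(1 - p)`. `X` residues count as mismatches
#' against everything, including `X`. Pairs whose non-gap overlap is below
#' `min_overlap` columns raise an error naming the pair.
#'
#' @param alignment A [multiple_alignment()].
#' @param model `"p"` or `"poisson"`.
#' @param min_overlap Minimum number of jointly non-gap columns per pair.
#' @param max_dist Cap for the Poisson distance as `p` approaches 1.
#' @return A labeled symmetric distance matrix (see [distance_matrix()]).
#' @export
protein_distance <- function(alignment, model = c("p", "poisson"),
                             min_overlap = 30L, max_dist = 10) {
  model <- match.arg(model)
  m <- aln_matrix(alignment)
  n <- nrow(m)
  if (n < 2L) stop("need at least 2 rows")
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  gap <- m == "-"
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- !gap[i, ] & !gap[j, ]
      if (sum(ok) < min_overlap) {
        stop("non-gap overlap below ", min_overlap, " columns for pair '",
             rownames(m)[i], "' / '", rownames(m)[j], "'")
      }
      a <- m[i, ok]; b <- m[j, ok]
      p <- mean(a != b | a == "X" | b == "X")
      v <- if (model == "p") p else {
        if (p >= 1 - 1e-12) max_dist else min(-log(1 - p), max_dist)
      }
      d[i, j] <- d[j, i] <- v
    }
  }
  distance_matrix(d)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (via [ape::nj()]) with negative branch lengths
#' clamped to zero and the deficit moved to the sister branch, so leaf-to-leaf
#' path lengths through the parent are preserved. Exact on additive matrices.
#'
#' @param d Labeled symmetric distance matrix.
#' @return An unrooted `ape::phylo` tree with the input labels as leaves.
#' @export
nj_tree <- function(d) {
  d <- distance_matrix(d)
  if (nrow(d) < 3L) stop("need at least 3 labels")
  tr <- ape::nj(stats::as.dist(d))
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    parent <- tr$edge[e, 1L]
    sisters <- which(tr$edge[, 1L] == parent)
    sisters <- setdiff(sisters, e)
    if (length(sisters) > 0L) {
      tr$edge.length[sisters[1L]] <- tr$edge.length[sisters[1L]] +
        tr$edge.length[e]
    }
    tr$edge.length[e] <- 0
  }
  tr
}

#' Assign family labels to tree leaves by reference-anchored clades
#'
#' The tree is midpoint rooted; each non-reference leaf receives the family of
#' the smallest clade that contains it together with reference exemplars of
#' exactly one family. Leaves whose smallest reference-containing clade mixes
#' families are `UNASSIGNED`. Reference leaves always map to their own family.
#'
#' @param tree An `ape::phylo` tree.
#' @param references Named character vector: leaf id -> family label.
#' @return Named character vector over all leaves with family labels.
#' @export
assign_families <- function(tree, references) {
  stopifnot(inherits(tree, "phylo"), length(references) >= 2L)
  if (length(unique(references)) < 2L) stop("need references from >= 2 families")
  missing_ref <- setdiff(names(references), tree$tip.label)
  if (length(missing_ref) > 0L) {
    stop("reference leaf missing from tree: ",
         paste(missing_ref, collapse = ", "))
  }
  rooted <- phangorn::midpoint(tree)
  ntip <- length(rooted$tip.label)
  parent <- integer(ntip + rooted$Nnode)
  parent[rooted$edge[, 2L]] <- rooted$edge[, 1L]
  # descendant tips per node
  tips_below <- phangorn::Descendants(rooted, (ntip + 1L):(ntip + rooted$Nnode),
                                      type = "tips")
  ref_idx <- match(names(references), rooted$tip.label)
  fam_of_tip <- rep(NA_character_, ntip)
  fam_of_tip[ref_idx] <- unname(references)

  out <- stats::setNames(rep("UNASSIGNED", ntip), rooted$tip.label)
  out[names(references)] <- unname(references)
  root <- ntip + 1L
  for (leaf in setdiff(seq_len(ntip), ref_idx)) {
    node <- parent[leaf]
    repeat {
      fams <- unique(fam_of_tip[tips_below[[node - ntip]]])
      fams <- fams[!is.na(fams)]
      if (length(fams) >= 1L) {
        if (length(fams) == 1L) out[rooted$tip.label[leaf]] <- fams
        break
      }
      if (node == root) break
      node <- parent[node]
    }
  }
  out[tree$tip.label]
}
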