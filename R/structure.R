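#' Allele-sharing pairwise distance matrix
#'
#' \code{d(i, j) = 1 - sum(2 - |g_i - g_k|) / (2 m_ij)} over the
#' pairwise-complete sites \code{m_ij}: one minus the mean fraction of
#' alleles identical by state between two unphased diploid genotypes.
#'
#' @param panel a \code{genotype_panel} with >= 2 samples
#' @return object of class \code{allele_sharing_dist}: list with
#'   \code{ids}, symmetric \code{d} matrix in \code{[0, 1]} with zero
#'   diagonal, and \code{n_sites} matrix of pairwise-complete site counts
#' @export
pairwise_distance <- function(panel) {
  ns <- n_samples(panel)
  if (ns < 2) stop("pairwise_distance needs >= 2 samples")
  G <- panel$geno
  D <- matrix(0, ns, ns, dimnames = list(panel$samples, panel$samples))
  M <- matrix(0L, ns, ns, dimnames = dimnames(D))
  diag(M) <- as.integer(colSums(!is.na(G)))
  for (i in seq_len(ns - 1)) {
    gi <- G[, i]
    for (j in (i + 1):ns) {
      ok <- !is.na(gi) & !is.na(G[, j])
      m <- sum(ok)
      if (m == 0)
        stop("no pairwise-complete sites for pair ",
             panel$samples[i], " / ", panel$samples[j])
      shared <- sum(2 - abs(gi[ok] - G[ok, j]))
      D[i, j] <- D[j, i] <- 1 - shared / (2 * m)
      M[i, j] <- M[j, i] <- m
    }
  }
  structure(list(ids = panel$samples, d = D, n_sites = M),
            class = "allele_sharing_dist")
}

#' @exportS3Method base::print
print.allele_sharing_dist <- function(x, ...) {
  cat(sprintf("allele_sharing_dist: %d samples, mean distance %.4f\n",
              length(x$ids), mean(x$d[upper.tri(x$d)])))
  invisible(x)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Validates the matrix (symmetric, non-negative, zero diagonal), runs
#' Saitou-Nei neighbor joining and clamps any negative branch length to
#' zero (logged). The returned \code{phylo} object serializes to Newick via
#' \code{ape::write.tree}.
#'
#' @param d an \code{allele_sharing_dist}, \code{dist} or square numeric
#'   matrix with at least 3 taxa
#' @return an unrooted \code{ape::phylo} tree
#' @export
nj_tree <- function(d) {
  if (inherits(d, "allele_sharing_dist")) d <- d$d
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) != ncol(d)) stop("d must be square")
  if (nrow(d) < 3) stop("nj_tree needs >= 3 taxa")
  if (any(d < 0)) stop("negative distances in input")
  if (max(abs(d - t(d))) > 1e-12) stop("distance matrix is not symmetric")
  tr <- ape::nj(d)
  neg <- tr$edge.length < 0
  if (any(neg)) {
    .ps_msg("nj_tree: clamped %d negative branch length(s) to 0", sum(neg))
    tr$edge.length[neg] <- 0
  }
  tr
}

#' Genetic relationship matrix
#'
#' Single-component GRM over polymorphic sites:
#' \code{G_ij = mean_k (x_ik - 2 p_k)(x_jk - 2 p_k) / (2 p_k (1 - p_k))},
#' with allele frequencies taken over called alleles, missing dosages
#' mean-imputed to \code{2 p_k}, and monomorphic sites excluded.
#'
#' @param panel a \code{genotype_panel}
#' @return object of class \code{grm_matrix}: list with \code{ids},
#'   symmetric \code{g} matrix, and \code{m} (number of SNPs used)
#' @export
grm <- function(panel) {
  st_all <- rowSums(!is.na(panel$geno))
  p <- ifelse(st_all > 0, rowSums(panel$geno, na.rm = TRUE) / (2 * st_all), NA)
  poly <- which(!is.na(p) & p > 0 & p < 1)
  if (!length(poly)) stop("grm: no polymorphic sites")
  X <- panel$geno[poly, , drop = FALSE]
  pk <- p[poly]
  mu <- 2 * pk
  X <- X - mu                     # recycles by column: rows are sites
  X[is.na(X)] <- 0                # mean imputation after centering
  W <- X / sqrt(2 * pk * (1 - pk))
  G <- crossprod(W) / length(poly)
  dimnames(G) <- list(panel$samples, panel$samples)
  structure(list(ids = panel$samples, g = G, m = length(poly)),
            class = "grm_matrix")
}

#' @exportS3Method base::print
print.grm_matrix <- function(x, ...) {
  cat(sprintf("grm_matrix: %d samples from %d SNPs, mean diagonal %.3f\n",
              length(x$ids), x$m, mean(diag(x$g))))
  invisible(x)
}

#' Principal components of a GRM
#'
#' Top-k eigenpairs in descending eigenvalue order. Each eigenvector's sign
#' is fixed by making its largest-magnitude loading positive, so results
#' are deterministic across LAPACK builds.
#'
#' @param g a \code{grm_matrix} or symmetric numeric matrix
#' @param k number of components (default 3); must not exceed the sample
#'   count
#' @return list with \code{values} (length k), \code{vectors} (samples x
#'   k, unit columns) and \code{all_values} (the full spectrum)
#' @export
grm_pca <- function(g, k = 3) {
  ids <- NULL
  if (inherits(g, "grm_matrix")) { ids <- g$ids; g <- g$g }
  if (k > nrow(g)) stop("k exceeds sample count")
  e <- eigen(g, symmetric = TRUE)
  V <- e$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  rownames(V) <- ids
  list(values = e$values[seq_len(k)], vectors = V, all_values = e$values)
}

#' Rand index of two partitions
#'
#' Fraction of sample pairs on which two labelings agree (same/different
#' cluster); 1 means identical partitions.
#'
#' @param x,y equal-length label vectors
#' @return numeric scalar in \code{[0, 1]}
#' @export
rand_index <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 2) return(1)
  sx <- outer(x, x, "==")[upper.tri(diag(n))]
  sy <- outer(y, y, "==")[upper.tri(diag(n))]
  mean(sx == sy)
}

#' Best bipartition agreement between a tree and group labels
#'
#' For every internal edge of an unrooted tree, the tips split into two
#' sides; returns the maximum Rand index between any such split and the
#' supplied group labels. 1.0 means some edge separates the groups
#' perfectly.
#'
#' @param tree an \code{ape::phylo}
#' @param groups named vector of group labels (names = tip labels)
#' @return maximum Rand index over internal edges
#' @export
tree_split_agreement <- function(tree, groups) {
  labs <- as.character(groups[tree$tip.label])
  if (anyNA(labs)) stop("groups must cover every tip label")
  ntip <- length(tree$tip.label)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  tips_below <- function(node) {
    if (node <= ntip) return(node)
    unlist(lapply(kids[[as.character(node)]], tips_below))
  }
  internal <- tree$edge[tree$edge[, 2] > ntip, 2]
  if (!length(internal)) return(rand_index(labs, labs))
  best <- 0
  for (nd in internal) {
    side <- seq_len(ntip) %in% tips_below(nd)
    best <- max(best, rand_index(side, labs == labs[1]))
  }
  best
}
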