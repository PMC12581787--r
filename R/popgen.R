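# Population characterization from panel genotypes: p-distance, neighbor-
# joining trees, PCA, nucleotide diversity and Weir-Cockerham FST.

# shared machinery: pairwise sum of |g_i - g_j| and co-observation counts via
# indicator-matrix products (fast, handles missing data pairwise-complete)
pairwise_geno_stats <- function(G) {
  A0 <- (!is.na(G) & G == 0) * 1
  A1 <- (!is.na(G) & G == 1) * 1
  A2 <- (!is.na(G) & G == 2) * 1
  obs <- A0 + A1 + A2
  sum_absdiff <- A0 %*% t(A1) + A1 %*% t(A0) + A1 %*% t(A2) + A2 %*% t(A1) +
    2 * (A0 %*% t(A2) + A2 %*% t(A0))
  list(sum_absdiff = sum_absdiff, n_co = obs %*% t(obs))
}

#' Pairwise p-distance between samples
#'
#' Mean per-site allele-sharing dissimilarity over co-observed sites:
#' `d(i,j) = sum |g_i - g_j| / (2 * n_co)`. Identical samples give 0; opposite
#' homozygotes at every site give 1.
#'
#' @param G genotype matrix (samples x SNPs) or a [variant_table()].
#' @return symmetric distance matrix with sample IDs.
#' @export
p_distance <- function(G) {
  if (inherits(G, "variant_table")) G <- genotypes(G)
  if (nrow(G) < 2) stop("need at least two samples")
  st <- pairwise_geno_stats(G)
  if (any(st$n_co[upper.tri(st$n_co)] == 0))
    stop("sample pair with zero co-observed sites")
  D <- st$sum_absdiff / (2 * st$n_co)
  diag(D) <- 0
  dimnames(D) <- list(rownames(G), rownames(G))
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration with deterministic tie-breaking (the
#' lexicographically lowest index pair among minimal Q values). Negative
#' branch lengths are clamped to zero with the deficit moved to the sister
#' branch.
#'
#' @param D symmetric distance matrix with row/column names (n >= 3).
#' @return an \pkg{ape} `phylo` tree (unrooted).
#' @export
nj_tree <- function(D) {
  D <- as.matrix(D)
  if (!isSymmetric(unname(D), tol = 1e-8)) stop("distance matrix not symmetric")
  n <- nrow(D)
  if (n < 3) stop("need at least three taxa")
  labels <- rownames(D)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  n_tip <- n
  # node bookkeeping: active entries carry their tree-node id
  node_id <- seq_len(n_tip)
  next_internal <- n_tip + 1L
  edges <- matrix(0L, 0, 2)
  lens <- numeric(0)
  add_edge <- function(parent, child, len) {
    edges <<- rbind(edges, c(parent, child))
    lens <<- c(lens, len)
  }
  while (nrow(D) > 2) {
    r <- nrow(D)
    rs <- rowSums(D)
    Q <- (r - 2) * D - outer(rs, rs, "+")
    diag(Q) <- Inf
    # lowest (i, j) with i < j among minimal Q
    minQ <- min(Q)
    cand <- which(Q <= minQ + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    i <- cand[1, 1]; j <- cand[1, 2]
    bi <- D[i, j] / 2 + (rs[i] - rs[j]) / (2 * (r - 2))
    bj <- D[i, j] - bi
    if (bi < 0) { bj <- bj + bi; bi <- 0 }
    if (bj < 0) { bi <- bi + bj; bj <- 0 }
    new_node <- next_internal
    next_internal <- next_internal + 1L
    add_edge(new_node, node_id[i], bi)
    add_edge(new_node, node_id[j], bj)
    d_new <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], d_new[keep]),
               c(d_new[keep], 0))
    node_id <- c(node_id[keep], new_node)
  }
  add_edge(node_id[2], node_id[1], max(D[1, 2], 0))
  # ape phylo: internal nodes numbered n_tip+1.., root = the last created node
  n_internal <- next_internal - n_tip - 1L
  # re-root bookkeeping: ape requires edges parent > n_tip; our last join made
  # node_id[2] the parent of node_id[1]; if node_id[2] is a tip (n_tip == 3
  # star handled above by internal node), swap
  if (node_id[2] <= n_tip && node_id[1] > n_tip) {
    edges[nrow(edges), ] <- c(node_id[1], node_id[2])
  }
  # renumber internal nodes so the root (final internal) is n_tip + 1
  internal_ids <- sort(unique(edges[edges > n_tip]))
  remap <- seq_along(internal_ids) + n_tip
  names(remap) <- rev(internal_ids)  # final join becomes the root
  relabel <- function(v) ifelse(v > n_tip, remap[as.character(v)], v)
  edges2 <- cbind(relabel(edges[, 1]), relabel(edges[, 2]))
  tr <- list(edge = edges2, edge.length = lens, tip.label = labels,
             Nnode = length(internal_ids))
  class(tr) <- "phylo"
  tr <- ape::collapse.singles(tr)
  stats::reorder(tr)
}

#' PCA of genotype dosages
#'
#' Columns are mean-imputed and centered; coordinates come from the singular
#' value decomposition. The sign convention fixes the largest-|loading| entry
#' of each component positive.
#'
#' @param G genotype matrix (samples x SNPs) or a [variant_table()].
#' @param n_components number of components to return.
#' @return list with `scores` (n x k), `explained` (variance fractions),
#'   `sdev`.
#' @export
pca_genotypes <- function(G, n_components = 3) {
  if (inherits(G, "variant_table")) G <- genotypes(G)
  if (any(colMeans(is.na(G)) == 1)) stop("all-missing SNP column")
  X <- impute_mean(G)
  X <- scale(X, center = TRUE, scale = FALSE)
  stopifnot(n_components < min(dim(X)))
  pc <- prcomp(X, center = FALSE, rank. = n_components)
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  scores <- sweep(pc$x, 2, flip, "*")
  rownames(scores) <- rownames(G)
  list(scores = scores,
       explained = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(n_components)],
       sdev = pc$sdev)
}

#' Per-group nucleotide diversity
#'
#' Average over sites of the unbiased per-site expected heterozygosity
#' `2 p q n / (n - 1)`, where n is the group's non-missing allele count at the
#' site.
#'
#' @param G genotype matrix or [variant_table()].
#' @param groups factor/vector of group labels per sample.
#' @return named numeric vector of per-group pi.
#' @export
nucleotide_diversity <- function(G, groups) {
  if (inherits(G, "variant_table")) G <- genotypes(G)
  groups <- as.factor(groups)
  vapply(levels(groups), function(g) {
    sub <- G[groups == g, , drop = FALSE]
    if (nrow(sub) < 2) stop("group ", g, " has fewer than 2 samples")
    n_al <- 2 * colSums(!is.na(sub))
    p <- colSums(sub, na.rm = TRUE) / n_al
    ok <- n_al > 1
    mean((2 * p * (1 - p) * n_al / (n_al - 1))[ok])
  }, 0)
}

# Weir-Cockerham theta for one pair of groups, ratio-of-sums over sites
wc_theta_pair <- function(G1, G2) {
  r <- 2
  n1 <- colSums(!is.na(G1)); n2 <- colSums(!is.na(G2))
  ok <- n1 >= 2 & n2 >= 2
  n1 <- n1[ok]; n2 <- n2[ok]
  G1 <- G1[, ok, drop = FALSE]; G2 <- G2[, ok, drop = FALSE]
  p1 <- colSums(G1, na.rm = TRUE) / (2 * n1)
  p2 <- colSums(G2, na.rm = TRUE) / (2 * n2)
  h1 <- colSums(G1 == 1, na.rm = TRUE) / n1
  h2 <- colSums(G2 == 1, na.rm = TRUE) / n2
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  poly <- pbar > 0 & pbar < 1
  if (!any(poly)) return(NA_real_)
  sum(a[poly]) / sum((a + b + cc)[poly])
}

#' Pairwise Weir-Cockerham FST between groups
#'
#' Variance-component estimator (two populations per comparison), combined
#' across sites as a ratio of sums. Negative estimates are reported as-is;
#' comparisons monomorphic at every site return NA.
#'
#' @param G genotype matrix or [variant_table()].
#' @param groups group labels per sample (each group needs >= 2 samples).
#' @return symmetric matrix of pairwise FST (diagonal NA).
#' @export
fst_weir_cockerham <- function(G, groups) {
  if (inherits(G, "variant_table")) G <- genotypes(G)
  groups <- as.factor(groups)
  lv <- levels(groups)
  if (any(table(groups) < 2)) stop("each group needs at least 2 samples")
  out <- matrix(NA_real_, length(lv), length(lv), dimnames = list(lv, lv))
  for (i in seq_along(lv)) for (j in seq_along(lv)) {
    if (j <= i) next
    th <- wc_theta_pair(G[groups == lv[i], , drop = FALSE],
                        G[groups == lv[j], , drop = FALSE])
    out[i, j] <- out[j, i] <- th
  }
  out
}

#' Diversity summary (pi and pairwise FST)
#' @param G genotype matrix or [variant_table()].
#' @param groups group labels per sample.
#' @return list with `pi` and `fst` (class `diversity_stats`).
#' @export
diversity_stats <- function(G, groups) {
  structure(list(pi = nucleotide_diversity(G, groups),
                 fst = fst_weir_cockerham(G, groups)),
            class = "diversity_stats")
}

#' @export
print.diversity_stats <- function(x, ...) {
  cat("per-group nucleotide diversity (pi):\n")
  print(round(x$pi, 4))
  cat("pairwise Weir-Cockerham FST:\n")
  print(round(x$fst, 4))
  invisible(x)
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Site-resampling bootstrap: SNP columns are resampled with replacement,
#' the p-distance/NJ pipeline re-run, and each internal edge of the reference
#' tree scored by the fraction of replicates containing its bipartition.
#'
#' @param G genotype matrix or [variant_table()].
#' @param n_boot replicates (default 100).
#' @param seed RNG seed.
#' @return list with `tree` (the reference NJ tree) and `support` (per
#'   internal node, fraction of replicates).
#' @export
nj_bootstrap <- function(G, n_boot = 100, seed = 1) {
  if (inherits(G, "variant_table")) G <- genotypes(G)
  set.seed(seed)
  ref <- nj_tree(p_distance(G))
  reps <- vector("list", n_boot)
  for (b in seq_len(n_boot)) {
    cols <- sample.int(ncol(G), replace = TRUE)
    reps[[b]] <- nj_tree(p_distance(G[, cols, drop = FALSE]))
  }
  pp <- ape::prop.clades(ref, reps, rooted = FALSE)
  list(tree = ref, support = pp / n_boot)
}
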