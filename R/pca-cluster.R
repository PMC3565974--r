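# Correlation-matrix PCA and Ward agglomerative clustering, the
# classification layer applied to cohort scores.

#' Principal component analysis on the correlation matrix
#'
#' Columns are centered and reduced (mean 0, SD 1, denominator n - 1), the
#' correlation matrix is eigendecomposed, and scores are the standardized
#' data projected on the loadings. Sign convention: the largest-magnitude
#' loading of each component is positive. Eigenvalues sum to the number of
#' variables.
#'
#' @param X Numeric matrix or data.frame (samples x variables), >= 3 rows,
#'   no constant column.
#' @return An object of class `pca_result`: list with `loadings`
#'   (variables x components), `scores`, `eigenvalues`,
#'   `cumulative_variability`, `center`, `scale`.
#' @examples
#' run_pca(matrix(rnorm(60), 10, 6))
#' @export
run_pca <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 3) stop("need at least 3 samples")
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("constant column(s): ", paste(colnames(X)[sds == 0], collapse = ", "))
  Z <- scale(X, center = TRUE, scale = TRUE)
  R <- stats::cor(X)
  ed <- eigen(R, symmetric = TRUE)
  load <- ed$vectors
  # deterministic sign: largest |loading| positive per component
  for (j in seq_len(ncol(load))) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) load[, j] <- -load[, j]
  }
  dimnames(load) <- list(colnames(X), paste0("F", seq_len(ncol(load))))
  scores <- Z %*% load
  structure(list(loadings = load,
                 scores = scores,
                 eigenvalues = ed$values,
                 cumulative_variability = cumsum(ed$values) / ncol(X),
                 center = attr(Z, "scaled:center"),
                 scale = attr(Z, "scaled:scale")),
            class = "pca_result")
}

#' Correlation-circle coordinates
#'
#' Coordinates of each variable on the first components: loading times the
#' square root of the eigenvalue, i.e. the correlation between the variable
#' and the component scores. All points lie inside the unit disk.
#'
#' @param pca A `pca_result`.
#' @param components Which components (default first two).
#' @return Matrix (variables x components) of coordinates.
#' @export
correlation_circle <- function(pca, components = 1:2) {
  if (max(components) > ncol(pca$loadings)) stop("component out of range")
  sweep(pca$loadings[, components, drop = FALSE], 2,
        sqrt(pmax(pca$eigenvalues[components], 0)), `*`)
}

#' Ward agglomerative clustering
#'
#' Agglomerative hierarchical clustering with the Ward criterion: each merge
#' joins the pair of clusters whose fusion minimally increases the total
#' within-cluster sum of squared Euclidean distances to centroids. Merge
#' heights are those increments, so they sum to the total sum of squares
#' about the grand centroid. Ties are broken by lowest node index. The
#' dissimilarity update is the Lance-Williams recurrence on ESS increments.
#'
#' @param X Numeric matrix (samples x coordinates), e.g. the first three
#'   PCA score columns.
#' @return An object of class `ward_tree`: list with `merge` (n-1 x 2,
#'   negative = leaf, positive = prior merge, hclust convention), `height`
#'   (ESS increments), `labels`, `order`.
#' @examples
#' ward_cluster(cbind(c(0, 1, 10)))
#' @export
ward_cluster <- function(X) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2) stop("need at least 2 samples")
  labels <- rownames(X)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  # ESS increment between singletons: d^2 / 2
  D <- as.matrix(stats::dist(X))^2 / 2
  diag(D) <- Inf
  size <- rep(1L, n)
  active <- rep(TRUE, n)
  node_id <- -seq_len(n)            # hclust convention
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  for (s in seq_len(n - 1)) {
    idx <- which(active)
    sub <- D[idx, idx, drop = FALSE]
    m <- which(sub == min(sub), arr.ind = TRUE)
    # lowest-index tie-break on the original slot indices
    m <- m[order(pmin(idx[m[, 1]], idx[m[, 2]]),
                 pmax(idx[m[, 1]], idx[m[, 2]])), , drop = FALSE]
    i <- idx[min(m[1, ])]; j <- idx[max(m[1, ])]
    height[s] <- D[i, j]
    a <- node_id[i]; b <- node_id[j]
    merge[s, ] <- if (a < b) c(a, b) else c(b, a)
    ni <- size[i]; nj <- size[j]
    # Lance-Williams (Ward) update into slot i
    for (k in which(active)) {
      if (k == i || k == j) next
      nk <- size[k]
      D[i, k] <- D[k, i] <-
        ((ni + nk) * D[i, k] + (nj + nk) * D[j, k] - nk * D[i, j]) /
          (ni + nj + nk)
    }
    size[i] <- ni + nj
    active[j] <- FALSE
    node_id[i] <- s
  }
  structure(list(merge = merge, height = height, labels = labels,
                 order = tree_order(merge, n)),
            class = "ward_tree")
}

# leaf order for plotting / hclust compatibility
tree_order <- function(merge, n) {
  expand <- function(node) {
    if (node < 0) return(-node)
    c(expand(merge[node, 1]), expand(merge[node, 2]))
  }
  expand(n - 1)
}

#' Convert a Ward tree to an `hclust` object
#' @param tree A `ward_tree`.
#' @return An object of class `hclust`.
#' @export
as_hclust <- function(tree) {
  structure(list(merge = tree$merge, height = tree$height,
                 order = tree$order, labels = tree$labels,
                 method = "ward", call = match.call(),
                 dist.method = "euclidean"),
            class = "hclust")
}

#' Write a dendrogram as Newick
#'
#' Branch lengths are derived from the merge heights via [ape::as.phylo()].
#'
#' @param tree A `ward_tree`.
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_dendrogram_newick <- function(tree, file) {
  phy <- ape::as.phylo(as_hclust(tree))
  ape::write.tree(phy, file = file)
  invisible(file)
}

#' Cut a dendrogram at its natural division
#'
#' Formalises the visual rule of comparing each link's height with the links
#' below: over the last `n_last` merges, the cut is placed where the ratio
#' `height_i / height_{i-1}` is maximal, giving k clusters. The full ratio
#' table is returned so the choice can be inspected or overridden.
#'
#' @param tree A `ward_tree`.
#' @param n_last How many of the top merges to scan (default 10).
#' @return list with `k`, `assignments` (integer vector named by labels),
#'   `ratios` (data.frame: merge index, height, ratio, k_if_cut),
#'   `all_equal` flag.
#' @export
natural_division <- function(tree, n_last = 10) {
  h <- tree$height
  n <- length(h) + 1
  if (n < 3) stop("need at least 3 leaves")
  if (max(h) - min(h) < 1e-12 * max(h, 1)) {
    return(list(k = 1L,
                assignments = stats::setNames(rep(1L, n), tree$labels),
                ratios = NULL, all_equal = TRUE))
  }
  i_last <- seq(max(2, n - n_last), n - 1)
  ratios <- h[i_last] / h[i_last - 1]
  tbl <- data.frame(merge = i_last, height = h[i_last], ratio = ratios,
                    k_if_cut = n - i_last + 1)
  best <- i_last[which.max(ratios)]
  k <- n - best + 1
  assignments <- stats::cutree(as_hclust(tree), k = k)
  list(k = as.integer(k),
       assignments = stats::setNames(assignments, tree$labels),
       ratios = tbl, all_equal = FALSE)
}
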