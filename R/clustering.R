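## UPGMA agglomeration on Euclidean distances and the Mojena stopping rule
## that turns the dendrogram into a flat group assignment (G1..Gg).

#' Pairwise Euclidean distances between sample feature vectors
#'
#' @param features Either a numeric matrix with samples as named rows, a
#'   named list of equal-length numeric vectors, or a named numeric vector
#'   (treated as a one-dimensional feature, e.g. the normalized diversity
#'   index per sample).
#' @return A symmetric numeric matrix with zero diagonal and sample ids as
#'   dimnames.
#' @export
euclidean_distances <- function(features) {
  if (is.numeric(features) && is.null(dim(features))) {
    if (is.null(names(features))) {
      stop("a feature vector must carry sample names", call. = FALSE)
    }
    mat <- matrix(features, ncol = 1, dimnames = list(names(features), NULL))
  } else if (is.list(features) && !is.data.frame(features)) {
    lens <- lengths(features)
    if (length(unique(lens)) != 1L) {
      stop("ragged feature vectors: dimensions ",
           paste(unique(lens), collapse = ", "), call. = FALSE)
    }
    mat <- do.call(rbind, features)
    rownames(mat) <- names(features)
  } else {
    mat <- as.matrix(features)
  }
  if (is.null(rownames(mat))) {
    stop("features must be named by sample", call. = FALSE)
  }
  storage.mode(mat) <- "double"
  if (any(!is.finite(mat))) {
    stop("features contain non-finite values", call. = FALSE)
  }
  d <- as.matrix(stats::dist(mat, method = "euclidean"))
  diag(d) <- 0
  d
}

check_distance_matrix <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) {
    stop("distance matrix must be square", call. = FALSE)
  }
  if (nrow(d) < 2L) {
    stop("clustering needs at least 2 samples", call. = FALSE)
  }
  if (any(is.na(d)) || any(!is.finite(d))) {
    stop("distance matrix contains NA/NaN/Inf", call. = FALSE)
  }
  if (max(abs(d - t(d))) > 1e-12) {
    stop("distance matrix is not symmetric", call. = FALSE)
  }
  if (any(abs(diag(d)) > 0)) {
    stop("distance matrix diagonal must be zero", call. = FALSE)
  }
  if (is.null(rownames(d))) {
    rownames(d) <- colnames(d) <- paste0("S", seq_len(nrow(d)))
  }
  d
}

#' UPGMA hierarchical clustering
#'
#' Agglomerates samples under unweighted pair-group average linkage: the
#' closest pair of clusters is merged at a fusion height equal to their
#' current average-linkage distance, and the merged cluster's distance to
#' any other cluster `K` is the size-weighted mean
#' `(|A| d(A,K) + |B| d(B,K)) / (|A| + |B|)`.  Fusion heights are
#' non-decreasing.  When several pairs are tied at the minimal distance the
#' pair whose smallest original leaf indices come first lexicographically
#' is merged, making the result deterministic.
#'
#' @param dm A symmetric distance matrix with zero diagonal (e.g. from
#'   [euclidean_distances()]).
#' @return An object of class `upgma_dendrogram`: a list with `merge`
#'   (hclust-style merge matrix: negative entries are leaves, positive
#'   entries earlier merges), `height` (fusion heights, one per merge),
#'   `size` (number of leaves in each merged cluster), `order` (leaf
#'   ordering for display), and `labels`.
#' @export
upgma <- function(dm) {
  dm <- check_distance_matrix(dm)
  n <- nrow(dm)
  labels <- rownames(dm)
  d <- dm
  ## active[[i]]: id is -leaf or +merge index; rep is the smallest original
  ## leaf index, used for deterministic tie-breaking
  active <- lapply(seq_len(n), function(i)
    list(id = -i, size = 1L, rep = i, members = i))
  merge <- matrix(0L, nrow = n - 1L, ncol = 2L)
  height <- numeric(n - 1L)
  size <- integer(n - 1L)
  children <- vector("list", n - 1L)

  for (step in seq_len(n - 1L)) {
    m <- length(active)
    best <- NULL
    for (i in seq_len(m - 1L)) {
      for (j in seq((i + 1L), m)) {
        dij <- d[i, j]
        pair_rep <- sort(c(active[[i]]$rep, active[[j]]$rep))
        if (is.null(best) || dij < best$d ||
            (dij == best$d &&
             (pair_rep[1L] < best$rep[1L] ||
              (pair_rep[1L] == best$rep[1L] && pair_rep[2L] < best$rep[2L])))) {
          best <- list(i = i, j = j, d = dij, rep = pair_rep)
        }
      }
    }
    a <- active[[best$i]]; b <- active[[best$j]]
    ## order within the merge row: leaves before merges, then by index
    ids <- c(a$id, b$id)
    merge[step, ] <- ids[order(ids >= 0, abs(ids))]
    height[step] <- best$d
    size[step] <- a$size + b$size
    children[[step]] <- list(a = a$id, b = b$id)

    new_cl <- list(id = step, size = a$size + b$size,
                   rep = min(a$rep, b$rep), members = c(a$members, b$members))
    keep <- setdiff(seq_len(m), c(best$i, best$j))
    if (length(keep) > 0L) {
      dnew <- (a$size * d[best$i, keep] + b$size * d[best$j, keep]) /
        (a$size + b$size)
      d <- d[keep, keep, drop = FALSE]
      d <- rbind(cbind(d, dnew), c(dnew, 0))
    } else {
      d <- matrix(0, 1, 1)
    }
    active <- c(active[keep], list(new_cl))
  }

  structure(
    list(merge = merge, height = height, size = size,
         order = dendro_leaf_order(merge, n), labels = labels, n = n),
    class = "upgma_dendrogram")
}

## Depth-first leaf order from an hclust-style merge matrix.
dendro_leaf_order <- function(merge, n) {
  expand <- function(node) {
    if (node < 0L) return(-node)
    c(expand(merge[node, 1L]), expand(merge[node, 2L]))
  }
  expand(n - 1L)
}

#' @export
print.upgma_dendrogram <- function(x, ...) {
  cat("<upgma_dendrogram>", x$n, "leaves,", length(x$height), "merges,",
      "heights in [", format(min(x$height), digits = 4), ",",
      format(max(x$height), digits = 4), "]\n")
  invisible(x)
}

#' Convert a UPGMA dendrogram to an hclust object
#'
#' @param x An `upgma_dendrogram`.
#' @param ... Unused.
#' @return A [stats::hclust] object (method `"average"`).
#' @export
as.hclust.upgma_dendrogram <- function(x, ...) {
  structure(
    list(merge = x$merge, height = x$height, order = x$order,
         labels = x$labels, method = "average",
         call = match.call(), dist.method = "euclidean"),
    class = "hclust")
}

#' Cut a dendrogram with the Mojena stopping rule
#'
#' Computes the threshold `theta = mean(h) + k * sd(h)` over the fusion
#' heights `h` (sample standard deviation; defined as 0 when only one
#' height exists) and scans merges in order: the first merge whose height
#' strictly exceeds `theta` stops the agglomeration, and the partition
#' immediately before it is returned.  With `j*` the index of that merge
#' among `n - 1` merges, the number of groups is `n - j* + 1`; if no height
#' exceeds `theta` all samples form a single group.  Groups are labelled
#' `G1..Gg` by the order in which each group's first leaf appears in the
#' dendrogram leaf order.
#'
#' @param dendro An [upgma()] dendrogram.
#' @param k Mojena constant (default 1.25).
#' @return An object of class `mojena_cut`: a list with `k`, `alpha_mean`,
#'   `alpha_sd`, `theta`, `cut_index` (`NA` when no height exceeds
#'   `theta`), `n_groups`, and `assignment`, a data frame with columns
#'   `sample_id` and `group` ordered by dendrogram leaf order.
#' @export
mojena_cut <- function(dendro, k = 1.25) {
  stopifnot(inherits(dendro, "upgma_dendrogram"))
  if (k <= 0) stop("k must be positive", call. = FALSE)
  h <- dendro$height
  n <- dendro$n
  alpha_mean <- mean(h)
  alpha_sd <- if (length(h) >= 2L) stats::sd(h) else 0
  theta <- alpha_mean + k * alpha_sd
  exceed <- which(h > theta)
  if (length(exceed) == 0L) {
    cut_index <- NA_integer_
    n_groups <- 1L
  } else {
    cut_index <- exceed[1L]
    n_groups <- n - cut_index + 1L
  }

  ## membership after applying the merges below the cut
  n_applied <- n - n_groups
  comp <- -seq_len(n)               # leaf i starts in its own component
  node_comp <- integer(length(h))   # component id holding each merge node
  for (j in seq_len(n_applied)) {
    ab <- dendro$merge[j, ]
    ca <- if (ab[1L] < 0L) ab[1L] else node_comp[ab[1L]]
    cb <- if (ab[2L] < 0L) ab[2L] else node_comp[ab[2L]]
    comp[comp == cb] <- ca
    node_comp[j] <- ca
    node_comp[node_comp == cb] <- ca
  }
  ## label groups G1..Gg by first appearance along the leaf order
  comp_by_order <- comp[dendro$order]
  first_seen <- unique(comp_by_order)
  group_of_comp <- stats::setNames(paste0("G", seq_along(first_seen)),
                                   as.character(first_seen))
  assignment <- data.frame(
    sample_id = dendro$labels[dendro$order],
    group = unname(group_of_comp[as.character(comp_by_order)]),
    stringsAsFactors = FALSE)

  structure(
    list(k = k, alpha_mean = alpha_mean, alpha_sd = alpha_sd,
         theta = theta, cut_index = cut_index, n_groups = n_groups,
         assignment = assignment),
    class = "mojena_cut")
}

#' @export
print.mojena_cut <- function(x, ...) {
  cat("<mojena_cut> k =", x$k, " theta =", format(x$theta, digits = 6),
      "->", x$n_groups, "group(s)\n")
  invisible(x)
}

#' Cophenetic distances of a dendrogram
#'
#' The cophenetic distance between two leaves is the fusion height of the
#' lowest dendrogram node joining them.  For a UPGMA tree the result is
#' ultrametric.
#'
#' @param dendro An [upgma()] dendrogram.
#' @return A symmetric matrix with zero diagonal and the leaf labels as
#'   dimnames.
#' @export
cophenetic_distances <- function(dendro) {
  stopifnot(inherits(dendro, "upgma_dendrogram"))
  n <- dendro$n
  coph <- matrix(0, n, n, dimnames = list(dendro$labels, dendro$labels))
  members <- vector("list", n - 1L)
  for (j in seq_along(dendro$height)) {
    ab <- dendro$merge[j, ]
    left <- if (ab[1L] < 0L) -ab[1L] else members[[ab[1L]]]
    right <- if (ab[2L] < 0L) -ab[2L] else members[[ab[2L]]]
    coph[left, right] <- dendro$height[j]
    coph[right, left] <- dendro$height[j]
    members[[j]] <- c(left, right)
  }
  coph
}

#' Export a dendrogram as a rooted ultrametric Newick string
#'
#' Branch lengths place every leaf at depth `height/2` below each ancestor
#' node, so leaf-to-leaf path lengths equal the cophenetic distances.
#'
#' @param dendro An [upgma()] dendrogram.
#' @param digits Significant digits for branch lengths (default 10).
#' @return A single Newick string terminated by `;`.
#' @export
to_newick <- function(dendro, digits = 10) {
  stopifnot(inherits(dendro, "upgma_dendrogram"))
  phy <- ape::as.phylo(as.hclust.upgma_dendrogram(dendro))
  ape::write.tree(phy, digits = digits)
}
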