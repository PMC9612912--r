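# Pathway similarity analysis: weighted-average Hausdorff distances,
# agglomerative clustering of the precomputed distance matrix, and ligand
# occupancy density grids per cluster.
#
# The weighted-average Hausdorff distance between paths A and B is
#   dH_wavg(A,B) = 1/2 [ dH_sum(A|B)/|A| + dH_sum(B|A)/|B| ],
# where dH_sum(A|B) = sum_{a in A} min_{b in B} d(a,b) and |A|, |B| are
# frame counts, so longer paths get no extra weight. It is symmetric,
# non-negative and zero for identical point sets, but the triangle
# inequality is NOT guaranteed; it is a similarity score, not a metric.

.as_path_matrix <- function(p) {
  if (inherits(p, "lp_pathway")) p <- p$trace
  m <- matrix(as.numeric(p), ncol = 3)
  if (nrow(m) == 0) stop("empty path")
  m
}

#' One-sided summed Hausdorff distance
#'
#' `sum over a in A of min over b in B of d(a, b)` (Angstrom).
#' @param A,B paths: `n x 3` matrices or `lp_pathway` objects
#' @return numeric (Angstrom)
#' @export
hausdorff_sum <- function(A, B) {
  A <- .as_path_matrix(A); B <- .as_path_matrix(B)
  d2 <- .cross_dist2(A, B)
  sum(sqrt(apply(d2, 1, min)))
}

#' Weighted-average Hausdorff distance between two paths
#'
#' @inheritParams hausdorff_sum
#' @return numeric (Angstrom); symmetric in its arguments
#' @export
wavg_hausdorff <- function(A, B) {
  A <- .as_path_matrix(A); B <- .as_path_matrix(B)
  d2 <- .cross_dist2(A, B)
  0.5 * (sum(sqrt(apply(d2, 1, min))) / nrow(A) +
         sum(sqrt(apply(d2, 2, min))) / nrow(B))
}

#' Pairwise weighted-average Hausdorff distance matrix
#'
#' @param paths list of paths (`n x 3` matrices or `lp_pathway`s)
#' @param ids optional path identifiers (default `path_1..n` or pathway
#'   chain ids)
#' @return object of class `lp_distmat`: list with `path_ids` and the
#'   symmetric zero-diagonal `values` matrix
#' @export
path_distance_matrix <- function(paths, ids = NULL) {
  n <- length(paths)
  if (n < 2) stop("need at least two paths")
  mats <- lapply(paths, .as_path_matrix)
  if (is.null(ids)) ids <- paste0("path_", seq_len(n) - 1L)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      m[i, j] <- m[j, i] <- wavg_hausdorff(mats[[i]], mats[[j]])
    }
  }
  structure(list(path_ids = ids, values = m), class = "lp_distmat")
}

#' Hierarchical clustering of a path distance matrix
#'
#' Agglomerative clustering on the precomputed weighted-average Hausdorff
#' distances. Ward (minimum variance, `ward.D2`) is the default linkage; it
#' formally presumes Euclidean geometry, which the Hausdorff matrix does
#' not guarantee — complete linkage is offered as the conservative
#' alternative. The dendrogram is always available via the returned
#' `hclust` object and [dendrogram_json()].
#'
#' @param distmat an `lp_distmat` (or symmetric matrix)
#' @param linkage "ward" (ward.D2) or "complete"
#' @param k number of clusters to cut (default 4), or NULL
#' @param h cut height (used when `k` is NULL)
#' @return object of class `lp_clusters`: list with `labels` (named integer
#'   cluster ids), `hclust`, `linkage`, `cut_spec`
#' @export
cluster_paths <- function(distmat, linkage = c("ward", "complete"), k = 4,
                          h = NULL) {
  linkage <- match.arg(linkage)
  m <- if (inherits(distmat, "lp_distmat")) distmat$values else as.matrix(distmat)
  if (!is.null(k) && k > nrow(m))
    stop("cut count (", k, ") exceeds number of paths (", nrow(m), ")")
  method <- if (linkage == "ward") "ward.D2" else "complete"
  hc <- stats::hclust(stats::as.dist(m), method = method)
  labels <- if (!is.null(k)) stats::cutree(hc, k = k) else stats::cutree(hc, h = h)
  structure(list(labels = labels, hclust = hc, linkage = linkage,
                 cut_spec = if (!is.null(k)) list(k = k) else list(h = h)),
            class = "lp_clusters")
}

#' @export
print.lp_clusters <- function(x, ...) {
  cat(sprintf("<lp_clusters> %d paths, %d clusters (%s linkage)\n",
              length(x$labels), length(unique(x$labels)), x$linkage))
  print(table(cluster = x$labels))
  invisible(x)
}

#' Dendrogram merge list as JSON-ready structure
#'
#' @param clusters an `lp_clusters`
#' @return list with `merge` (pairs, hclust convention), `height`, `order`,
#'   `labels`; serialize with `jsonlite::toJSON`
#' @export
dendrogram_json <- function(clusters) {
  hc <- clusters$hclust
  list(merge = unclass(hc$merge), height = hc$height, order = hc$order,
       labels = hc$labels, linkage = clusters$linkage)
}

#' Ligand occupancy density grid
#'
#' Bins path trace points onto a regular 3D grid; one call per cluster
#' produces the per-cluster density overlays.
#'
#' @param paths list of paths (matrices or `lp_pathway`s)
#' @param spacing voxel edge length (Angstrom), > 0
#' @param origin optional grid origin; default snaps to `spacing` multiples
#'   below the data minimum
#' @param dims optional voxel counts per axis
#' @return object of class `lp_grid`: `origin`, `spacing`, `counts`
#'   (3D array); `sum(counts)` equals the number of trace points
#' @export
occupancy_density <- function(paths, spacing = 1, origin = NULL, dims = NULL) {
  if (spacing <= 0) stop("spacing must be positive")
  pts <- do.call(rbind, lapply(paths, .as_path_matrix))
  if (is.null(origin))
    origin <- floor(apply(pts, 2, min) / spacing) * spacing
  idx <- floor(sweep(pts, 2, origin) / spacing) + 1L
  if (is.null(dims)) dims <- apply(idx, 2, max)
  if (any(idx < 1L) || any(sweep(idx, 2, dims) > 0L))
    stop("points fall outside the requested grid")
  counts <- array(0, dim = dims)
  lin <- (idx[, 3] - 1L) * dims[1] * dims[2] + (idx[, 2] - 1L) * dims[1] + idx[, 1]
  tab <- table(lin)
  counts[as.integer(names(tab))] <- as.integer(tab)
  structure(list(origin = origin, spacing = spacing, counts = counts),
            class = "lp_grid")
}

#' Adjusted Rand index between two partitions
#'
#' Used to score recovery of planted pathway families; 1 means identical
#' partitions up to label permutation.
#' @param a,b integer/character label vectors of equal length
#' @return numeric between -1 and 1
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
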