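# Hierarchical density-based clustering with automatic cluster-count
# selection: mutual-reachability distances, single-linkage hierarchy,
# condensed tree with a minimum cluster size, and excess-of-mass cluster
# extraction. Points falling outside every selected cluster are noise (0).

#' Density-based clusterer factory
#'
#' Returns a clustering function suitable for [fit_topic_model()]. The
#' algorithm follows the hierarchical density-clustering approach used by
#' cluster-based topic models: pairwise distances are smoothed into
#' mutual-reachability distances via each point's core distance (distance to
#' its `min_samples`-th neighbour), a single-linkage hierarchy is built, the
#' dendrogram is condensed so that only components of at least
#' `min_cluster_size` points count as clusters, and the flat clustering is
#' chosen by excess-of-mass stability. The number of clusters emerges from
#' the data; low-density points are labelled noise (`0`).
#'
#' @param min_cluster_size smallest admissible cluster (>= 2).
#' @param min_samples neighbourhood size for core distances; defaults to
#'   `min_cluster_size`.
#' @param allow_single_cluster if `TRUE` (default) the hierarchy root may be
#'   selected, so a corpus forming one dense blob yields one cluster rather
#'   than all-noise.
#' @return `function(points_matrix) -> integer labels` (0 = noise).
#' @export
density_clusterer <- function(min_cluster_size = 15L, min_samples = NULL,
                              allow_single_cluster = TRUE) {
  min_cluster_size <- as.integer(min_cluster_size)
  if (is.na(min_cluster_size) || min_cluster_size < 2L) {
    stop("min_cluster_size must be >= 2", call. = FALSE)
  }
  if (is.null(min_samples)) min_samples <- min_cluster_size
  min_samples <- as.integer(min_samples)
  function(points) {
    density_cluster_labels(points, min_cluster_size, min_samples,
                           allow_single_cluster)
  }
}

density_cluster_labels <- function(points, min_cluster_size, min_samples,
                                   allow_single_cluster = TRUE) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < min_cluster_size) {
    return(integer(n)) # too few points for any cluster: all noise
  }
  dm <- as.matrix(stats::dist(points))
  k <- min(min_samples, n - 1L)
  core <- vapply(seq_len(n), function(i) sort(dm[i, -i])[k], numeric(1))
  mreach <- pmax(dm, outer(core, core, pmax))
  diag(mreach) <- 0
  if (max(mreach) < 1e-12) {
    # all points coincide: one dense blob
    return(if (allow_single_cluster) rep(1L, n) else integer(n))
  }
  hc <- stats::hclust(stats::as.dist(mreach), method = "single")
  labels_from_hierarchy(hc, n, min_cluster_size, allow_single_cluster)
}

# Flat labels from a single-linkage hierarchy via condensed-tree stability.
labels_from_hierarchy <- function(hc, n, m, allow_single_cluster) {
  heights <- pmax(hc$height, 1e-12)
  lambdas <- 1 / heights
  # leaves under each internal node, and subtree sizes
  members <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    kids <- hc$merge[i, ]
    members[[i]] <- c(if (kids[1] < 0) -kids[1] else members[[kids[1]]],
                      if (kids[2] < 0) -kids[2] else members[[kids[2]]])
  }
  sub_size <- function(node) if (node < 0) 1L else length(members[[node]])
  sub_points <- function(node) if (node < 0) -node else members[[node]]

  # condensed tree: clusters are born at splits where both sides have >= m
  # points; smaller side-branches fall out of the running cluster
  birth <- numeric(0)      # lambda at which each cluster appears
  stability <- numeric(0)  # sum over points of (lambda_fall - lambda_birth)
  parent <- integer(0)     # parent cluster id (0 for root)
  kids_of <- list()
  pt_cluster <- integer(n) # condensed-tree parent cluster of each point
  pt_lambda <- numeric(n)

  new_cluster <- function(b, par) {
    birth <<- c(birth, b)
    stability <<- c(stability, 0)
    parent <<- c(parent, par)
    kids_of[[length(birth)]] <<- integer(0)
    if (par > 0) kids_of[[par]] <<- c(kids_of[[par]], length(birth))
    length(birth)
  }
  drop_points <- function(pts, cid, lam) {
    stability[cid] <<- stability[cid] + length(pts) * (lam - birth[cid])
    pt_cluster[pts] <<- cid
    pt_lambda[pts] <<- lam
  }

  root <- new_cluster(0, 0L)
  stack <- list(list(node = n - 1L, cid = root))
  while (length(stack) > 0) {
    task <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    node <- task$node
    cid <- task$cid
    if (node < 0) { # a single point handed a cluster of its own cannot split
      drop_points(-node, cid, Inf)
      next
    }
    lam <- lambdas[node]
    kids <- hc$merge[node, ]
    sa <- sub_size(kids[1])
    sb <- sub_size(kids[2])
    if (sa >= m && sb >= m) {
      # true split: parent ends here, two clusters are born
      stability[cid] <- stability[cid] +
        (sa + sb) * (lam - birth[cid])
      ca <- new_cluster(lam, cid)
      cb <- new_cluster(lam, cid)
      stack[[length(stack) + 1L]] <- list(node = kids[1], cid = ca)
      stack[[length(stack) + 1L]] <- list(node = kids[2], cid = cb)
    } else if (sa >= m) {
      drop_points(sub_points(kids[2]), cid, lam)
      stack[[length(stack) + 1L]] <- list(node = kids[1], cid = cid)
    } else if (sb >= m) {
      drop_points(sub_points(kids[1]), cid, lam)
      stack[[length(stack) + 1L]] <- list(node = kids[2], cid = cid)
    } else {
      # both sides below the minimum size: the cluster dissolves here
      drop_points(c(sub_points(kids[1]), sub_points(kids[2])), cid, lam)
    }
  }

  n_clusters <- length(birth)
  # excess-of-mass selection, children before parents
  selected <- logical(n_clusters)
  subtree_stab <- numeric(n_clusters)
  for (cid in rev(seq_len(n_clusters))) {
    ch <- kids_of[[cid]]
    if (length(ch) == 0) {
      selected[cid] <- TRUE
      subtree_stab[cid] <- stability[cid]
    } else {
      cs <- sum(subtree_stab[ch])
      take_self <- stability[cid] >= cs &&
        (cid != root || allow_single_cluster)
      if (cid == root && length(kids_of[[root]]) > 0 &&
          !allow_single_cluster) {
        take_self <- FALSE
      }
      if (take_self) {
        selected[cid] <- TRUE
        subtree_stab[cid] <- stability[cid]
      } else {
        subtree_stab[cid] <- cs
      }
    }
  }
  if (!allow_single_cluster && n_clusters == 1L) selected[root] <- FALSE
  # a selected ancestor silences all its descendants
  final_sel <- logical(n_clusters)
  queue <- root
  while (length(queue) > 0) {
    cid <- queue[1]
    queue <- queue[-1]
    if (selected[cid]) {
      final_sel[cid] <- TRUE
    } else {
      queue <- c(queue, kids_of[[cid]])
    }
  }
  # label each point by the selected cluster on its root path, if any
  sel_label <- integer(n_clusters)
  sel_label[final_sel] <- seq_len(sum(final_sel))
  labels <- integer(n)
  for (p in seq_len(n)) {
    cid <- pt_cluster[p]
    while (cid > 0 && !final_sel[cid]) cid <- parent[cid]
    labels[p] <- if (cid > 0) sel_label[cid] else 0L
  }
  labels
}
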