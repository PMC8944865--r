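#' Column-standardize an index table
#'
#' Standardizes every numeric index column to mean 0, SD 1 (n-1
#' denominator). Zero-variance columns are set to 0 with a warning. The
#' column centres and scales are kept as attributes so the transform can be
#' inverted.
#'
#' @param table Index table: a data frame with an optional `subject_id`
#'   column plus numeric index columns.
#' @return A tibble of class `z_matrix` with the same columns; attributes
#'   `center`, `scale`, `index_names`.
#' @export
zscore_indexes <- function(table) {
  idx_cols <- index_columns(table)
  X <- as.matrix(table[, idx_cols])
  if (any(!is.finite(X))) stop("non-finite values in index table")
  if (nrow(X) < 2) stop("need at least 2 subjects")
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  zero <- scl == 0
  if (any(zero)) {
    warning("zero-variance column(s) set to 0: ",
            paste(idx_cols[zero], collapse = ", "))
    scl[zero] <- 1
  }
  Z <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  out <- table
  out[, idx_cols] <- tibble::as_tibble(Z)
  attr(out, "center") <- ctr
  attr(out, "scale") <- scl
  attr(out, "index_names") <- idx_cols
  class(out) <- c("z_matrix", class(tibble::tibble()))
  out
}

#' Invert a z-score transform
#' @param z A `z_matrix`.
#' @return The original-scale tibble.
#' @export
unzscore <- function(z) {
  idx_cols <- attr(z, "index_names")
  X <- as.matrix(z[, idx_cols])
  X <- sweep(sweep(X, 2, attr(z, "scale"), "*"), 2, attr(z, "center"), "+")
  out <- as.data.frame(z)
  out[, idx_cols] <- X
  tibble::as_tibble(out)
}

index_columns <- function(table) {
  setdiff(names(table)[vapply(table, is.numeric, logical(1))],
          c("subject_id", "day_index"))
}

#' Low-dimensional embedding of standardized indexes
#'
#' Embeds subjects into `out_dim` dimensions. UMAP is the default;
#' `"pca"`, `"tsne"` and `"pca_umap"` (PCA to 10 components, then UMAP)
#' are selectable for comparison. Deterministic for a fixed seed.
#'
#' @param z A `z_matrix` (or plain numeric data frame).
#' @param method One of `"umap"`, `"pca"`, `"tsne"`, `"pca_umap"`.
#' @param out_dim Embedding dimension (default 3).
#' @param seed Integer seed.
#' @param n_neighbors,min_dist UMAP parameters.
#' @return Tibble with columns `e1..e<out_dim>` (plus `subject_id` when
#'   present in the input).
#' @export
embed_indexes <- function(z, method = c("umap", "pca", "tsne", "pca_umap"),
                          out_dim = 3, seed = 1, n_neighbors = 50,
                          min_dist = 0.0) {
  method <- match.arg(method)
  X <- as.matrix(z[, index_columns(z)])
  n <- nrow(X)
  if (n < out_dim + 1) stop("need more subjects than embedding dimensions")
  req_dim <- out_dim
  out_dim <- min(out_dim, ncol(X)) # never embed into more dims than inputs
  E <- with_seed(seed, switch(
    method,
    pca = {
      p <- stats::prcomp(X, center = TRUE, scale. = FALSE)
      p$x[, seq_len(min(out_dim, ncol(p$x))), drop = FALSE]
    },
    umap = run_umap(X, out_dim, n_neighbors, min_dist, seed),
    tsne = {
      perp <- max(2, min(30, floor((n - 1) / 3)))
      Rtsne::Rtsne(X, dims = out_dim, perplexity = perp,
                   check_duplicates = FALSE, pca = TRUE,
                   num_threads = 1)$Y
    },
    pca_umap = {
      p <- stats::prcomp(X, center = TRUE, scale. = FALSE)
      Xp <- p$x[, seq_len(min(10, ncol(p$x))), drop = FALSE]
      run_umap(Xp, out_dim, n_neighbors, min_dist, seed)
    }
  ))
  if (ncol(E) < req_dim) { # degenerate input: pad constant axes
    E <- cbind(E, matrix(0, n, req_dim - ncol(E)))
  }
  colnames(E) <- paste0("e", seq_len(req_dim))
  out <- tibble::as_tibble(E)
  if ("subject_id" %in% names(z)) {
    out <- tibble::add_column(out, subject_id = z$subject_id, .before = 1)
  }
  out
}

run_umap <- function(X, out_dim, n_neighbors, min_dist, seed) {
  nb <- min(n_neighbors, nrow(X) - 1)
  uwot::umap(X, n_components = out_dim, n_neighbors = nb,
             min_dist = min_dist, n_threads = 1, n_sgd_threads = 0,
             seed = seed)
}

#' DBSCAN density clustering
#'
#' Standard DBSCAN on the embedding coordinates: points with at least
#' `min_samples` neighbours within `eps` (themselves included) are core
#' points; clusters are the connected components of core points plus their
#' border points; everything else is noise, labelled -1.
#'
#' @param embedding Data frame with embedding columns `e1..ek` (or any
#'   all-numeric data frame/matrix).
#' @param eps Neighbourhood radius; `NULL` picks five times the median
#'   `min_samples`-nearest-neighbour distance. This adapts to the embedding
#'   scale and errs on the generous side: too large an eps merely merges
#'   everything into one cluster (a conservative outcome for the divisive
#'   tree), while too small an eps would shatter genuine clusters.
#' @param min_samples Core-point neighbourhood size.
#' @return Integer labels, one per point; clusters numbered 1, 2, ... in
#'   order of first appearance, noise = -1.
#' @export
density_cluster <- function(embedding, eps = NULL, min_samples = 20) {
  ecols <- grep("^e[0-9]+$", colnames(embedding), value = TRUE)
  X <- if (length(ecols) > 0) {
    as.matrix(as.data.frame(embedding)[, ecols, drop = FALSE])
  } else {
    as.matrix(embedding)
  }
  n <- nrow(X)
  D <- as.matrix(stats::dist(X))
  if (is.null(eps)) {
    k <- min(min_samples, n - 1)
    knn_d <- apply(D, 1, function(r) sort(r)[k + 1])
    eps <- 5 * stats::median(knn_d)
    if (eps == 0) eps <- .Machine$double.eps
  }
  if (eps <= 0) stop("eps must be positive")
  nb <- lapply(seq_len(n), function(i) which(D[i, ] <= eps))
  core <- vapply(nb, length, integer(1)) >= min_samples
  labels <- rep(-1L, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || labels[i] != -1L) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- nb[[i]]
    while (length(queue) > 0) {
      j <- queue[1]
      queue <- queue[-1]
      if (labels[j] == -1L) {
        labels[j] <- cl
        if (core[j]) queue <- c(queue, nb[[j]][labels[nb[[j]]] == -1L])
      }
    }
  }
  labels
}

#' Divisive embedding+density clustering
#'
#' The whole cohort forms the root. At each node the members' raw indexes
#' are re-standardized, embedded, and density-clustered; the split is
#' accepted only when at least two children reach `min_child_size` members
#' (smaller children are folded into the largest accepted sibling so the
#' children partition the node). Accepted children recurse until
#' `max_depth`. DBSCAN noise at a node is recorded and excluded from its
#' subtree.
#'
#' @param table Index table (with `subject_id` and numeric index columns).
#' @param max_depth Maximum number of split rounds.
#' @param min_child_size Minimum accepted child size (also the DBSCAN
#'   `min_samples`).
#' @param seed Integer seed for the embeddings.
#' @param method Embedding method, see [embed_indexes].
#' @param eps DBSCAN radius (`NULL` = kNN heuristic per node).
#' @param n_neighbors,min_dist UMAP parameters.
#' @return An object of class `cluster_tree`: list with the nested `root`
#'   node (`members`, `depth`, `noise`, `children`, `leaf_label`) and a
#'   tibble `assignments` (`subject_id`, `label`; noise at any node is
#'   labelled `"noise"`).
#' @export
divisive_cluster <- function(table, max_depth = 3, min_child_size = 20,
                             seed = 1, method = "umap", eps = NULL,
                             n_neighbors = 50, min_dist = 0.0) {
  ids <- if ("subject_id" %in% names(table)) {
    table$subject_id
  } else {
    sprintf("s%04d", seq_len(nrow(table)))
  }
  idx_cols <- index_columns(table)
  leaf_counter <- new.env(parent = emptyenv())
  leaf_counter$n <- 0L
  noise_ids <- character()

  grow <- function(member_idx, depth, path) {
    node <- list(members = ids[member_idx], depth = depth, noise = character(),
                 children = list(), leaf_label = NA_character_)
    accept <- FALSE
    if (depth < max_depth && length(member_idx) >= 2 * min_child_size) {
      sub <- table[member_idx, idx_cols, drop = FALSE]
      if (sum(apply(sub, 2, stats::sd) > 0) >= 1) {
        z <- suppressWarnings(zscore_indexes(sub))
        emb <- embed_indexes(z, method = method, seed = seed + depth,
                             n_neighbors = n_neighbors, min_dist = min_dist)
        labs <- density_cluster(emb, eps = eps, min_samples = min_child_size)
        sizes <- table(labs[labs != -1L])
        big <- as.integer(names(sizes)[sizes >= min_child_size])
        if (length(big) >= 2) {
          accept <- TRUE
          largest <- big[which.max(sizes[as.character(big)])]
          labs[labs != -1L & !labs %in% big] <- largest
          node$noise <- ids[member_idx[labs == -1L]]
          noise_ids <<- c(noise_ids, node$noise)
          for (ci in seq_along(big)) {
            child_idx <- member_idx[labs == big[ci]]
            node$children[[ci]] <- grow(child_idx, depth + 1,
                                        c(path, ci))
          }
        }
      }
    }
    if (!accept) {
      leaf_counter$n <- leaf_counter$n + 1L
      node$leaf_label <- paste(path, collapse = ".")
      if (node$leaf_label == "") node$leaf_label <- "1"
    }
    node
  }

  root <- grow(seq_len(nrow(table)), 0L, integer())
  leaves <- collect_leaves(root)
  assign_tbl <- purrr::map(leaves, function(l) {
    tibble::tibble(subject_id = l$members, label = l$leaf_label)
  }) |> purrr::list_rbind()
  if (length(noise_ids) > 0) {
    assign_tbl <- dplyr::bind_rows(
      assign_tbl, tibble::tibble(subject_id = noise_ids, label = "noise")
    )
  }
  assign_tbl <- assign_tbl[match(ids, assign_tbl$subject_id), ]
  structure(
    list(root = root, assignments = assign_tbl, max_depth = max_depth,
         min_child_size = min_child_size),
    class = "cluster_tree"
  )
}

collect_leaves <- function(node) {
  if (length(node$children) == 0) return(list(node))
  purrr::list_flatten(purrr::map(node$children, collect_leaves))
}

tree_depth <- function(node) {
  if (length(node$children) == 0) return(node$depth)
  max(purrr::map_dbl(node$children, tree_depth))
}

#' @export
tidy.cluster_tree <- function(x, ...) {
  leaves <- collect_leaves(x$root)
  purrr::map(leaves, function(l) {
    tibble::tibble(label = l$leaf_label, size = length(l$members),
                   depth = l$depth)
  }) |> purrr::list_rbind()
}

#' @export
glance.cluster_tree <- function(x, ...) {
  leaves <- collect_leaves(x$root)
  tibble::tibble(
    n_leaves = length(leaves),
    depth = tree_depth(x$root),
    n_noise = sum(x$assignments$label == "noise", na.rm = TRUE)
  )
}

#' Ward regrouping of divisive leaves within first-layer clusters
#'
#' Leaf clusters are summarised by their mean z-score profiles and
#' agglomerated with Ward's method, independently inside each first-layer
#' cluster so the first-layer relationship is preserved. Final groups are
#' relabelled hierarchically (`"2a"`, `"2b"`, ...).
#'
#' @param tree A `cluster_tree`.
#' @param z The cohort `z_matrix` aligned with the tree's subjects.
#' @param n_groups Target group count per first-layer cluster: a single
#'   integer applied to every first-layer cluster (capped at its leaf
#'   count), or a named vector keyed by first-layer label.
#' @return Tibble `subject_id`, `label` (regrouped), `leaf_label`.
#' @export
ward_regroup <- function(tree, z, n_groups = 2) {
  leaves <- collect_leaves(tree$root)
  if (length(leaves) == 0) stop("tree has no leaves")
  idx_cols <- attr(z, "index_names") %||% index_columns(z)
  ids <- z$subject_id
  Z <- as.matrix(z[, idx_cols])

  first_layer <- function(lbl) strsplit(lbl, ".", fixed = TRUE)[[1]][1]
  leaf_tbl <- tibble::tibble(
    leaf = purrr::map_chr(leaves, "leaf_label"),
    first = purrr::map_chr(purrr::map_chr(leaves, "leaf_label"), first_layer),
    members = purrr::map(leaves, "members")
  )

  out <- purrr::map(split(seq_len(nrow(leaf_tbl)), leaf_tbl$first),
                    function(rows) {
    fl <- leaf_tbl$first[rows[1]]
    k <- if (length(n_groups) > 1) {
      as.integer(n_groups[[fl]] %||% 1L)
    } else {
      as.integer(n_groups)
    }
    k <- max(1L, min(k, length(rows)))
    prof <- t(vapply(rows, function(r) {
      colMeans(Z[match(leaf_tbl$members[[r]], ids), , drop = FALSE])
    }, numeric(ncol(Z))))
    grp <- if (length(rows) == 1 || k == 1) {
      rep(1L, length(rows))
    } else {
      hc <- stats::hclust(stats::dist(prof), method = "ward.D2")
      stats::cutree(hc, k = k)
    }
    n_grp <- length(unique(grp))
    suffix <- if (n_grp == 1) "" else letters[seq_len(n_grp)]
    purrr::map(seq_along(rows), function(j) {
      tibble::tibble(
        subject_id = leaf_tbl$members[[rows[j]]],
        label = paste0(fl, suffix[grp[j]]),
        leaf_label = leaf_tbl$leaf[rows[j]]
      )
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
  out[order(match(out$subject_id, ids)), ]
}

#' Flag percentile outliers on selected indexes
#'
#' A subject is an outlier when any of the named indexes falls at or below
#' its `pct`-th percentile or at or beyond its `(100 - pct)`-th percentile
#' (linear-interpolation percentiles, boundaries inclusive). The default
#' 2.28 corresponds to two SDs under normality.
#'
#' @param table Index table.
#' @param indexes Character vector of index column names (default: the six
#'   indexes used for the outlier branch).
#' @param pct Tail percentile in (0, 50).
#' @return Logical vector, TRUE = outlier.
#' @export
select_outliers <- function(table,
                            indexes = c("wt_long_mn", "st_long_sd",
                                        "st_short_mn", "sleep_percentage_mn",
                                        "phase_mn", "period"),
                            pct = 2.28) {
  if (pct <= 0 || pct >= 50) stop("pct must be in (0, 50)")
  missing_idx <- setdiff(indexes, names(table))
  if (length(missing_idx) > 0) {
    stop("unknown index name(s): ", paste(missing_idx, collapse = ", "))
  }
  flagged <- rep(FALSE, nrow(table))
  for (nm in indexes) {
    x <- table[[nm]]
    qs <- stats::quantile(x, c(pct / 100, 1 - pct / 100), type = 7,
                          names = FALSE)
    flagged <- flagged | x <= qs[1] | x >= qs[2]
  }
  flagged
}

#' Cluster the outlier subset
#'
#' Re-standardizes the flagged subjects' indexes, embeds and
#' density-clusters them, independent of the main tree.
#'
#' @param table Index table restricted to the outlier subjects.
#' @param seed,method,eps,min_samples,n_neighbors,min_dist See
#'   [divisive_cluster] / [density_cluster].
#' @return Integer cluster labels (noise = -1).
#' @export
outlier_cluster <- function(table, seed = 1, method = "umap", eps = NULL,
                            min_samples = 20, n_neighbors = 50,
                            min_dist = 0.0) {
  if (nrow(table) == 0) stop("empty outlier subset")
  if (nrow(table) < min_samples) {
    stop("outlier subset smaller than min_samples")
  }
  z <- suppressWarnings(zscore_indexes(table))
  emb <- embed_indexes(z, method = method, seed = seed,
                       n_neighbors = n_neighbors, min_dist = min_dist)
  density_cluster(emb, eps = eps, min_samples = min_samples)
}

#' Per-cluster z-score profiles
#'
#' @param labels Cluster labels (character or integer; `"noise"`/-1
#'   excluded).
#' @param z The cohort `z_matrix`.
#' @return Tibble of class `cluster_profiles`: one row per cluster with
#'   `cluster`, `size`, `representative` (subject closest to the centroid,
#'   ties to the lowest id) and the mean z-score of every index.
#' @export
cluster_profiles <- function(labels, z) {
  idx_cols <- attr(z, "index_names") %||% index_columns(z)
  ids <- if ("subject_id" %in% names(z)) {
    z$subject_id
  } else {
    sprintf("s%04d", seq_len(nrow(z)))
  }
  Z <- as.matrix(z[, idx_cols])
  keep <- !labels %in% c("noise", -1L, NA)
  out <- purrr::map(sort(unique(labels[keep])), function(cl) {
    rows <- which(labels == cl)
    ctr <- colMeans(Z[rows, , drop = FALSE])
    d <- sqrt(rowSums(sweep(Z[rows, , drop = FALSE], 2, ctr)^2))
    rep_id <- ids[rows][order(d, ids[rows])][1]
    tibble::as_tibble(c(
      list(cluster = as.character(cl), size = length(rows),
           representative = rep_id),
      as.list(ctr)
    ))
  }) |> purrr::list_rbind()
  class(out) <- c("cluster_profiles", class(tibble::tibble()))
  out
}

#' @export
autoplot.cluster_profiles <- function(object, ...) {
  idx_cols <- setdiff(names(object), c("cluster", "size", "representative"))
  df <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("cluster", idx_cols)],
    -"cluster", names_to = "index", values_to = "z"
  )
  df$index <- factor(df$index, levels = idx_cols)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$index, y = .data$cluster,
                                   fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white",
                                  high = "firebrick") +
    ggplot2::labs(x = NULL, y = "cluster", fill = "mean z") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Scatter plot of an embedding with cluster labels
#'
#' @param embedding Tibble from [embed_indexes].
#' @param labels Cluster labels aligned with the embedding rows.
#' @param dims Which two embedding axes to draw.
#' @return A ggplot.
#' @export
plot_landscape <- function(embedding, labels, dims = c("e1", "e2")) {
  df <- tibble::tibble(x = embedding[[dims[1]]], y = embedding[[dims[2]]],
                       cluster = as.character(labels))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$cluster)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.8) +
    ggplot2::labs(x = dims[1], y = dims[2], colour = "cluster") +
    ggplot2::theme_minimal()
}

#' Adjusted Rand index against ground-truth labels
#'
#' Noise points (label `"noise"` or -1) in either partition are excluded
#' pairwise before computing the standard ARI.
#'
#' @param labels,truth_labels Aligned label vectors.
#' @return The adjusted Rand index.
#' @export
evaluate_recovery <- function(labels, truth_labels) {
  keep <- !labels %in% c("noise", -1L, NA) &
    !truth_labels %in% c("noise", -1L, NA)
  if (!any(keep)) stop("no non-noise pairs to compare")
  mclust::adjustedRandIndex(labels[keep], truth_labels[keep])
}
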