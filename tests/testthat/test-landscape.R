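test_that("z-scoring uses the n-1 convention and inverts exactly", {
  tbl <- tibble::tibble(subject_id = c("a", "b"), v = c(0, 2))
  z <- zscore_indexes(tbl)
  expect_equal(z$v, c(-1, 1) / sqrt(2), tolerance = 1e-12)

  tbl2 <- tibble::tibble(subject_id = c("a", "b", "c"),
                         v = c(1, 2, 4), w = c(5, 5, 5))
  expect_warning(z2 <- zscore_indexes(tbl2), "zero-variance")
  expect_true(all(z2$w == 0))
  expect_equal(mean(z2$v), 0, tolerance = 1e-12)
  expect_equal(sd(z2$v), 1, tolerance = 1e-12)

  back <- unzscore(suppressWarnings(zscore_indexes(tbl2)))
  expect_equal(back$v, tbl2$v, tolerance = 1e-9)
  expect_equal(back$w, tbl2$w, tolerance = 1e-9)

  expect_error(zscore_indexes(tibble::tibble(v = c(1, NA))), "non-finite")
  expect_error(zscore_indexes(tibble::tibble(v = 1)), "2 subjects")
})

test_that("PCA embedding of 3-D data preserves distances; seeds fix output", {
  set.seed(24)
  X <- tibble::tibble(a = rnorm(100), b = rnorm(100), c = rnorm(100))
  e <- embed_indexes(X, method = "pca", out_dim = 3)
  d0 <- dist(as.matrix(X))
  d1 <- dist(as.matrix(e))
  expect_equal(as.numeric(d1), as.numeric(d0), tolerance = 1e-6)

  # well-separated blobs stay separated under UMAP
  blob <- rbind(matrix(rnorm(150 * 5), 150),
                matrix(rnorm(150 * 5, mean = 20), 150))
  tblb <- tibble::as_tibble(as.data.frame(blob))
  e2 <- embed_indexes(tblb, method = "umap", seed = 7)
  m <- as.matrix(e2)
  within <- c(dist(m[1:150, ]), dist(m[151:300, ]))
  between <- sqrt(rowSums((m[1:150, ] - m[151:300, ])^2))
  expect_gt(min(between), quantile(within, 0.95))

  e3 <- embed_indexes(tblb, method = "umap", seed = 7)
  expect_identical(e2, e3)
  expect_error(embed_indexes(tblb, method = "sammon"), "arg")
})

test_that("DBSCAN implements core/border/noise semantics", {
  set.seed(25)
  blobs <- rbind(matrix(rnorm(60, sd = 0.1), ncol = 3),
                 matrix(rnorm(60, mean = 10, sd = 0.1), ncol = 3))
  colnames(blobs) <- paste0("e", 1:3)
  lab <- density_cluster(tibble::as_tibble(blobs), eps = 1, min_samples = 5)
  expect_equal(length(unique(lab)), 2)
  expect_false(any(lab == -1))
  expect_equal(length(unique(lab[1:20])), 1)
  expect_equal(length(unique(lab[21:40])), 1)

  # isolated point is noise
  pts <- rbind(matrix(rnorm(40, sd = 0.1), ncol = 2),
               c(50, 50))
  colnames(pts) <- c("e1", "e2")
  lab2 <- density_cluster(tibble::as_tibble(pts), eps = 1, min_samples = 2)
  expect_equal(lab2[21], -1L)

  # identical points form one cluster
  same <- matrix(1, nrow = 25, ncol = 2,
                 dimnames = list(NULL, c("e1", "e2")))
  lab3 <- density_cluster(tibble::as_tibble(same), eps = 0.5,
                          min_samples = 20)
  expect_true(all(lab3 == 1L))
  expect_error(density_cluster(tibble::as_tibble(same), eps = -1), "eps")
})

test_that("divisive clustering recovers planted blobs and obeys stop rules", {
  set.seed(26)
  centers <- rbind(c(0, 0, 0, 0), c(12, 0, 0, 0), c(0, 12, 0, 0),
                   c(12, 12, 12, 0))
  X <- do.call(rbind, lapply(1:4, function(k) {
    sweep(matrix(rnorm(200 * 4), 200), 2, centers[k, ], "+")
  }))
  tbl <- tibble::as_tibble(as.data.frame(X))
  tbl$subject_id <- sprintf("s%04d", 1:800)
  truth <- rep(1:4, each = 200)

  tree <- divisive_cluster(tbl, seed = 3)
  g <- glance(tree)
  expect_gte(g$n_leaves, 4)
  expect_lte(g$depth, 3)
  ari <- evaluate_recovery(tree$assignments$label, truth)
  expect_gte(ari, 0.8)

  # children partition parents; noise disjoint from descendants
  check_node <- function(node) {
    if (length(node$children) > 0) {
      kids <- unlist(lapply(node$children, function(ch) ch$members))
      expect_setequal(c(kids, node$noise), node$members)
      expect_equal(anyDuplicated(kids), 0)
      expect_length(intersect(node$noise, kids), 0)
      lapply(node$children, check_node)
    }
    invisible(NULL)
  }
  check_node(tree$root)

  # a homogeneous cloud is never split
  set.seed(27)
  cloud <- tibble::as_tibble(as.data.frame(matrix(rnorm(500 * 4), 500)))
  tree2 <- divisive_cluster(cloud, seed = 4)
  expect_equal(glance(tree2)$n_leaves, 1)

  # nodes below 2 * min_child_size are leaves by construction
  small <- tibble::as_tibble(as.data.frame(matrix(rnorm(19 * 4), 19)))
  tree3 <- divisive_cluster(small, seed = 5)
  expect_equal(glance(tree3)$n_leaves, 1)
  expect_length(tree3$root$children, 0)
})

test_that("Ward regrouping stays within first-layer clusters", {
  # two leaves with identical mean profiles merge at target 1
  mk_leaf <- function(lbl, members, depth) {
    list(members = members, depth = depth, noise = character(),
         children = list(), leaf_label = lbl)
  }
  ids <- sprintf("s%02d", 1:8)
  root <- list(
    members = ids, depth = 0L, noise = character(), leaf_label = NA_character_,
    children = list(
      list(members = ids[1:4], depth = 1L, noise = character(),
           leaf_label = NA_character_,
           children = list(mk_leaf("1.1", ids[1:2], 2L),
                           mk_leaf("1.2", ids[3:4], 2L))),
      mk_leaf("2", ids[5:8], 1L)
    )
  )
  tree <- structure(list(root = root,
                         assignments = tibble::tibble(subject_id = ids,
                                                      label = "x")),
                    class = "cluster_tree")
  tblz <- tibble::tibble(subject_id = ids,
                         a = c(1, 1, 1, 1, 9, 9, 9, 9),
                         b = c(0, 0, 0, 0, 4, 4, 4, 4))
  z <- zscore_indexes(tblz)
  out1 <- ward_regroup(tree, z, n_groups = 1)
  expect_equal(unique(out1$label[1:4]), "1")
  expect_equal(unique(out1$label[5:8]), "2")
  # different first-layer clusters are never merged even with target 1
  expect_length(unique(out1$label), 2)

  out2 <- ward_regroup(tree, z, n_groups = 2)
  expect_setequal(unique(out2$label[1:4]), c("1a", "1b"))
  expect_equal(unique(out2$label[5:8]), "2")
})

test_that("Ward merge order matches the hand-computed criterion sequence", {
  # profiles A=(0,0), B=(0,1), C=(4,0), D=(10,0):
  # Ward merges (A,B) first (d2 = 0.5), then (AB,C) (d2 = 10.83 < 18 = CD)
  prof <- matrix(c(0, 0, 0, 1, 4, 0, 10, 0), ncol = 2, byrow = TRUE)
  hc <- hclust(dist(prof), method = "ward.D2")
  expect_equal(sort(hc$merge[1, ]), c(-2, -1)) # A with B
  expect_equal(sort(hc$merge[2, ]), c(-3, 1)) # then C joins {A,B}
  expect_equal(sort(hc$merge[3, ]), c(-4, 2)) # D last
})

test_that("percentile outliers flag both tails inclusively", {
  tbl <- tibble::tibble(v = as.numeric(1:10000))
  mask <- select_outliers(tbl, indexes = "v", pct = 2.28)
  # brute-force rank count with the same interpolated quantiles
  qs <- quantile(tbl$v, c(0.0228, 1 - 0.0228), type = 7, names = FALSE)
  expect_equal(sum(mask), sum(tbl$v <= qs[1]) + sum(tbl$v >= qs[2]))
  expect_equal(sum(mask), 456) # 228 per tail on 10000 distinct values

  # union over indexes is idempotent: extremes in 2 indexes flag once
  tbl2 <- tibble::tibble(a = c(100, 2:99), b = c(100, 2:99))
  m2 <- select_outliers(tbl2, indexes = c("a", "b"), pct = 5)
  expect_equal(sum(m2), sum(select_outliers(tbl2, indexes = "a", pct = 5)))

  # pct near 50 flags everyone (distinct values)
  m3 <- select_outliers(tibble::tibble(v = as.numeric(1:10)),
                        indexes = "v", pct = 49.99)
  expect_true(all(m3))

  expect_error(select_outliers(tbl, indexes = "nope"), "unknown index")
  expect_error(select_outliers(tbl, indexes = "v", pct = 0), "pct")
})

test_that("outlier re-clustering separates planted extreme archetypes", {
  set.seed(28)
  n <- 400
  tbl <- tibble::tibble(
    subject_id = sprintf("s%04d", 1:n),
    a = rnorm(n), b = rnorm(n)
  )
  tbl$a[1:30] <- tbl$a[1:30] + 15 # extreme group 1
  tbl$b[31:60] <- tbl$b[31:60] - 15 # extreme group 2
  mask <- select_outliers(tbl, indexes = c("a", "b"), pct = 8)
  expect_true(all(mask[1:60]))
  lab <- outlier_cluster(tbl[mask, ], seed = 2, min_samples = 10)
  core <- lab[1:60]
  expect_equal(length(unique(core[core != -1])), 2)
  expect_equal(length(unique(core[1:30][core[1:30] != -1])), 1)

  # identical rows collapse to one cluster
  same <- tibble::tibble(subject_id = sprintf("s%02d", 1:25),
                         a = rep(1, 25), b = rep(2, 25))
  lab2 <- outlier_cluster(same, seed = 1, method = "pca", min_samples = 20)
  expect_true(all(lab2 == 1L))

  expect_error(outlier_cluster(same[0, ]), "empty")
  expect_error(outlier_cluster(same[1:5, ], min_samples = 20),
               "min_samples")
})

test_that("cluster profiles summarise sizes, centroids and representatives", {
  tbl <- tibble::tibble(subject_id = sprintf("s%02d", 1:6),
                        a = c(0, 1, 2, 10, 11, 12), b = rep(0, 6))
  z <- suppressWarnings(zscore_indexes(tbl))
  labels <- c(1, 1, 1, 2, 2, 2)
  prof <- cluster_profiles(labels, z)
  expect_equal(prof$size, c(3, 3))
  expect_equal(sum(prof$size), 6)
  expect_equal(prof$representative, c("s02", "s05")) # middle of each blob

  # single cluster: profile is the column means of Z, i.e. ~0
  prof1 <- cluster_profiles(rep(1, 6), z)
  expect_equal(prof1$a, 0, tolerance = 1e-12)

  # singleton cluster equals its own row
  prof2 <- cluster_profiles(c(1, 2, 2, 2, 2, 2), z)
  expect_equal(prof2$a[1], z$a[1])

  # noise is excluded from sizes
  prof3 <- cluster_profiles(c("noise", 1, 1, 2, 2, 2), z)
  expect_equal(sum(prof3$size), 5)
})

test_that("ARI matches the brute-force contingency formula", {
  expect_equal(evaluate_recovery(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(evaluate_recovery(1:4, rep(1, 4)), 0)
  a <- c(1, 1, 2, 2, 3, 3)
  b <- c(1, 2, 2, 2, 3, 1)
  expect_equal(evaluate_recovery(a, b), oracle_ari(a, b), tolerance = 1e-12)
  # noise excluded pairwise
  expect_equal(evaluate_recovery(c(1, 1, 2, 2, "noise"),
                                 c(1, 1, 2, 2, 1)), 1)
  expect_error(evaluate_recovery(rep("noise", 3), rep(1, 3)), "non-noise")
})

test_that("landscape plots build without error", {
  set.seed(29)
  tbl <- tibble::tibble(subject_id = sprintf("s%02d", 1:30),
                        a = rnorm(30), b = rnorm(30), c = rnorm(30))
  z <- zscore_indexes(tbl)
  emb <- embed_indexes(z, method = "pca", seed = 1)
  labs <- density_cluster(emb, eps = 5, min_samples = 3)
  p1 <- plot_landscape(emb, labs)
  p2 <- autoplot(cluster_profiles(labs, z))
  p3 <- autoplot(sw_series(rep(c("S", "W"), each = 120)))
  expect_s3_class(p1, "ggplot")
  expect_s3_class(p2, "ggplot")
  expect_s3_class(p3, "ggplot")
})
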