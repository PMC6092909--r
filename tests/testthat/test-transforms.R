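test_that("aggregate_columns applies null-skipping statistics", {
  tab <- make_column_table(rep("chr1", 3), c(0, 10, 20), c(1, 11, 21),
                           values = list(v1 = c(1, NA, NA),
                                         v2 = c(3, 5, NA)))
  out <- aggregate_columns(tab, c("v1", "v2"), "mean", "m")
  expect_equal(out$values$m, c(2, 5, NA))       # skip nulls; all-null -> null
  expect_length(out$values, 3L)                 # inputs retained

  expect_equal(aggregate_columns(tab, c("v1", "v2"), "sum", "s")$values$s,
               c(4, 5, NA))
  expect_equal(aggregate_columns(tab, c("v1", "v2"), "min", "lo")$values$lo,
               c(1, 5, NA))
  expect_error(aggregate_columns(tab, "nope", "mean", "x"), "nope")
  expect_error(aggregate_columns(tab, "v1", "mean", "v2"), "exists")

  # single-column mean is the identity on that column
  id <- aggregate_columns(tab, "v2", "mean", "copy")
  expect_equal(id$values$copy, tab$values$v2)
})

test_that("aggregated group difference recovers the fixture effect", {
  cfg <- fixture_config(seed = 21, n_features = 200, n_samples = 20,
                        group_effect = 2)
  ex <- make_expression(cfg)
  ctrl <- names(ex$table$values)[ex$group == "control"]
  case <- names(ex$table$values)[ex$group == "case"]
  tab <- aggregate_columns(ex$table, ctrl, "mean", "ctrl_mean")
  tab <- aggregate_columns(tab, case, "mean", "case_mean")
  diff <- tab$values$case_mean - tab$values$ctrl_mean
  # brute-force per-row check
  brute <- vapply(seq_len(ct_nrow(tab)), function(i) {
    mean(vapply(case, function(s) tab$values[[s]][i], 0)) -
      mean(vapply(ctrl, function(s) tab$values[[s]][i], 0))
  }, 0)
  expect_equal(diff, brute, tolerance = 1e-12)
  # parameter recovery: mean difference approximates the true shift
  se <- sd(diff) / sqrt(length(diff))
  expect_lt(abs(mean(diff) - cfg$group_effect), 4 * se + 0.05)
})

test_that("pairwise_distances metrics and degenerate inputs", {
  m <- rbind(a = c(0, 0), b = c(3, 4))
  d <- pairwise_distances(m, "euclidean")
  expect_equal(d["a", "b"], 5)                  # 3-4-5 triangle
  expect_equal(diag(d), c(a = 0, b = 0))

  same <- rbind(x = c(1, 2, 3), y = c(1, 2, 3))
  expect_equal(pairwise_distances(same, "euclidean")["x", "y"], 0)

  expect_equal(pairwise_distances(m, "manhattan")["a", "b"], 7)
  expect_error(pairwise_distances(rbind(c(1, 1), c(1, 2)),
                                  "one_minus_pearson"), "constant")
  expect_error(pairwise_distances(m[1, , drop = FALSE]), "2 rows")

  # random matrix vs brute-force double loop
  set.seed(33)
  r <- matrix(rnorm(100), 20, 5)
  d2 <- pairwise_distances(r, "euclidean")
  for (i in 1:20) for (j in 1:20) {
    expect_equal(d2[i, j], sqrt(sum((r[i, ] - r[j, ])^2)), tolerance = 1e-12)
  }
  d3 <- pairwise_distances(r, "one_minus_pearson")
  expect_equal(d3[2, 9], 1 - cor(r[2, ], r[9, ]), tolerance = 1e-12)

  # missing entries are mean-imputed per column before distances
  rm <- r
  rm[1, 2] <- NA
  imp <- r
  imp[1, 2] <- mean(rm[, 2], na.rm = TRUE)
  expect_equal(pairwise_distances(rm, "euclidean"),
               pairwise_distances(imp, "euclidean"))
})

test_that("hierarchical_cluster forced small cases", {
  d2 <- matrix(c(0, 3.5, 3.5, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  for (link in c("single", "complete", "average")) {
    dd <- hierarchical_cluster(d2, link)
    expect_equal(dd$height, 3.5)               # 2 items merge at exactly d
    expect_setequal(dd$leaf_order, c("a", "b"))
  }
  d3 <- matrix(c(0, 1, 10, 1, 0, 10, 10, 10, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  dd3 <- hierarchical_cluster(d3, "single")
  expect_equal(dd3$height, c(1, 10))           # (A,B) first, then C
  expect_equal(hierarchical_cluster(d3, "complete")$height, c(1, 10))
  expect_error(hierarchical_cluster(matrix(0, 1, 1)), "2 items")
})

test_that("merge heights match the naive O(n^3) reference for all linkages", {
  set.seed(55)
  for (rep in 1:10) {
    m <- matrix(rnorm(8 * 5), 8, 5,
                dimnames = list(paste0("s", 1:8), NULL))
    d <- pairwise_distances(m, "euclidean")
    for (link in c("single", "complete", "average")) {
      dd <- hierarchical_cluster(d, link)
      expect_equal(sort(dd$height), oracle_hclust_heights(d, link),
                   tolerance = 1e-10)
      # heights non-decreasing along the merge sequence for these linkages
      expect_true(all(diff(dd$height) >= -1e-12))
      # leaf order is a permutation of the labels consistent with the tree
      expect_setequal(dd$leaf_order, rownames(d))
    }
  }
})

test_that("single-linkage heights equal sorted MST edge weights", {
  set.seed(66)
  for (rep in 1:5) {
    m <- matrix(rnorm(60), 10, 6, dimnames = list(paste0("x", 1:10), NULL))
    d <- pairwise_distances(m, "euclidean")
    dd <- hierarchical_cluster(d, "single")
    expect_equal(sort(dd$height), oracle_mst_weights(d), tolerance = 1e-10)
  }
})

test_that("heights are invariant to input permutation", {
  set.seed(88)
  m <- matrix(rnorm(7 * 4), 7, 4, dimnames = list(letters[1:7], NULL))
  d <- pairwise_distances(m, "euclidean")
  for (link in c("single", "complete", "average")) {
    base <- hierarchical_cluster(d, link)
    for (rep in 1:3) {
      p <- sample(7)
      dp <- d[p, p]
      perm <- hierarchical_cluster(dp, link)
      expect_equal(sort(perm$height), sort(base$height), tolerance = 1e-12)
    }
  }
})

test_that("tie-breaking is deterministic by lexicographic label pair", {
  # equilateral: all distances equal, so the first merge must be (a, b)
  d <- matrix(1, 3, 3, dimnames = list(c("c", "a", "b"), c("c", "a", "b")))
  diag(d) <- 0
  dd <- hierarchical_cluster(d, "complete")
  first <- sort(dd$labels[-dd$merge[1, ]])
  expect_equal(first, c("a", "b"))
  expect_equal(dd$leaf_order[1], "a")
})

test_that("newick serialization preserves merge heights as path lengths", {
  set.seed(99)
  m <- matrix(rnorm(24), 6, 4, dimnames = list(paste0("L", 1:6), NULL))
  d <- pairwise_distances(m, "euclidean")
  dd <- hierarchical_cluster(d, "average")
  nwk <- dendrogram_to_newick(dd)
  expect_match(nwk, ";$")
  tree_labels <- regmatches(nwk, gregexpr("L[0-9]+", nwk))[[1]]
  expect_setequal(tree_labels, dd$labels)
  # leaf depth (sum of branch lengths root->leaf) equals the root height
  depths <- numeric()
  # parse-free check: root height is max height; every leaf is at depth root_h
  # verified structurally through the JSON serialization instead
  js <- jsonlite::fromJSON(dendrogram_to_json(dd), simplifyVector = FALSE)
  expect_equal(js$height, max(dd$height))
  leaf_depth <- function(node) {
    if (!is.null(node$label)) return(0)
    kids <- node$children
    unlist(lapply(kids, function(k) {
      (node$height - k$height) + leaf_depth(k)
    }))
  }
  expect_equal(unique(round(leaf_depth(js) - 0, 10)),
               round(max(dd$height), 10))
})
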