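test_that("library-size normalisation rescales to target and log-transforms", {
  counts <- rbind(s1 = c(1, 1, 2), s2 = c(10, 0, 10))
  colnames(counts) <- c("gA", "gB", "gC")
  e <- normalize_counts(toy_expression(counts), target_sum = 1e4)
  ln <- as.matrix(e$layers$lognorm)
  expect_equal(unname(ln["s1", ]), log1p(c(2500, 2500, 5000)))
  expect_equal(unname(ln["s2", ]), log1p(c(5000, 0, 5000)))
  # raw counts preserved
  expect_equal(as.matrix(e$counts)["s1", "gC"], 2)
  # scaled totals hit the target for every spot
  expect_equal(unname(rowSums(expm1(ln))), rep(1e4, 2), tolerance = 1e-6)
})

test_that("all-zero genes stay zero and zero-count spots are dropped with a warning", {
  counts <- rbind(s1 = c(5, 0), s2 = c(0, 0))
  colnames(counts) <- c("gA", "gB")
  expect_warning(e <- normalize_counts(toy_expression(counts)), "zero-count")
  expect_equal(rownames(e$counts), "s1")
  expect_equal(unname(as.matrix(e$layers$lognorm)[, "gB"]), 0)
})

make_blobs <- function(n_per = 50, gap = 30, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per * 10), n_per),
             matrix(rnorm(n_per * 10, mean = gap / sqrt(10)), n_per))
  rownames(X) <- sprintf("s%03d", seq_len(2 * n_per))
  X
}

test_that("two well-separated blobs cluster into two groups with high silhouette", {
  X <- make_blobs()
  cl <- cluster_spots(X, n_pcs = 5, n_neighbors = 10, resolution = 0.5, seed = 3)
  expect_equal(cl$n_clusters, 2)
  expect_gt(cl$silhouette, 0.5)
  truth <- rep(1:2, each = 50)
  expect_equal(v_measure_compare(cl$labels, truth), 1)
  # independent silhouette check in the same PC space
  pcs <- stats::prcomp(X, rank. = 5)$x
  sw <- cluster::silhouette(as.integer(cl$labels), dist(pcs))
  expect_equal(cl$silhouette, mean(sw[, "sil_width"]), tolerance = 1e-10)
})

test_that("degenerate clustering reports the -1 silhouette sentinel", {
  set.seed(4)
  X <- matrix(rnorm(60 * 5), 60)
  rownames(X) <- sprintf("s%02d", 1:60)
  cl <- cluster_spots(X, n_pcs = 3, n_neighbors = 10, resolution = 1e-4, seed = 1)
  expect_equal(cl$n_clusters, 1)
  expect_equal(cl$silhouette, -1)
  expect_error(cluster_spots(X[1:5, ], n_pcs = 2, n_neighbors = 10, seed = 1),
               "more spots")
})

test_that("clustering is deterministic given the seed and permutation-equivariant", {
  X <- make_blobs(n_per = 40, gap = 20, seed = 7)
  a <- cluster_spots(X, 5, 8, 0.5, seed = 11)
  b <- cluster_spots(X, 5, 8, 0.5, seed = 11)
  expect_identical(a$labels, b$labels)
  perm <- sample(nrow(X))
  cp <- cluster_spots(X[perm, ], 5, 8, 0.5, seed = 11)
  # same partition up to label renaming
  expect_equal(v_measure_compare(cp$labels, a$labels[perm]), 1)
})

test_that("grid search maximises silhouette and keeps an audit table", {
  X <- make_blobs(seed = 5)
  single <- grid_search_clustering(X, n_pcs_grid = 5, n_neighbors_grid = 10,
                                   resolution_grid = 0.5, seed = 2)
  direct <- cluster_spots(X, 5, 10, 0.5, seed = 2)
  expect_identical(single$labels, direct$labels)
  expect_equal(single$silhouette, direct$silhouette)

  gs <- grid_search_clustering(X, n_pcs_grid = c(3, 5),
                               n_neighbors_grid = c(5, 10),
                               resolution_grid = c(0.1, 0.5), seed = 2)
  expect_false(gs$degenerate)
  expect_equal(length(unique(gs$labels)), 2)
  expect_equal(nrow(gs$table), 8)
  expect_equal(max(gs$table$silhouette[gs$table$n_clusters > 1]), gs$silhouette)
})

test_that("imputation: none is the identity, constant genes are fixed points, diffusion fills dropout zeros", {
  net <- make_toy_network()
  ds <- simulate_spatial_counts(net, grid = c(10, 10), dropout = 0.3, seed = 9)
  e <- normalize_counts(ds$expr)
  e0 <- impute_expression(e, "none")
  expect_equal(as.matrix(e0$layers$imputed), as.matrix(e0$layers$lognorm))

  # constant-expression gene survives smoothing unchanged
  cc <- matrix(rpois(50 * 6, 20), 50, dimnames = list(sprintf("s%02d", 1:50),
                                                      sprintf("g%d", 1:6)))
  ec <- toy_expression(cc)
  ec$layers$lognorm <- Matrix::Matrix(cbind(as.matrix(normalize_counts(ec)$layers$lognorm)[, 1:5],
                                            gconst = rep(2, 50)), sparse = FALSE)
  colnames(ec$layers$lognorm) <- c(sprintf("g%d", 1:5), "gconst")
  em <- impute_expression(ec, "magic")
  expect_equal(as.numeric(em$layers$imputed[, "gconst"]), rep(2, 50), tolerance = 1e-8)

  # dropout recovery on synthetic data
  zfrac_before <- mean(as.matrix(e$layers$lognorm) == 0)
  em2 <- impute_expression(e, "magic")
  zfrac_after <- mean(as.matrix(em2$layers$imputed) < 1e-9)
  expect_lt(zfrac_after, zfrac_before)

  expect_error(impute_expression(e, "unknown_method"), "unknown imputation")
  # pluggable denoiser function
  ef <- impute_expression(e, function(x) x * 2)
  expect_equal(as.matrix(ef$layers$imputed), 2 * as.matrix(e$layers$lognorm))
})

test_that("binning sums counts, conserves totals and applies the majority rule", {
  # 4x4 grid of unit-spaced spots, factor 4 -> a single bin of 16 spots
  counts <- matrix(rpois(16 * 5, 5), 16,
                   dimnames = list(sprintf("s%02d", 1:16), sprintf("g%d", 1:5)))
  coords <- expand.grid(x = 1:4, y = 1:4)
  e <- expression_matrix(counts, data.frame(spot = rownames(counts), coords),
                         annotation = setNames(c(rep("Tumor", 9), rep("Stroma", 7)),
                                               rownames(counts)))
  b <- bin_spots(e, factor = 4)
  expect_equal(nrow(b$counts), 1)
  expect_equal(unname(colSums(as.matrix(e$counts))),
               unname(as.matrix(b$counts)[1, ]))
  # 9/16 Tumor > 0.5 -> Tumor
  expect_equal(unname(b$annotation), "Tumor")

  # exactly half does not exceed the majority threshold -> Interface
  e2 <- e
  e2$annotation <- setNames(c(rep("Tumor", 8), rep("Stroma", 8)), rownames(counts))
  expect_equal(unname(bin_spots(e2, 4)$annotation), "Interface")

  # factor 1 is the identity on counts
  b1 <- bin_spots(e, factor = 1)
  expect_equal(unname(as.matrix(b1$counts)[order(b1$coords$y, b1$coords$x), ]),
               unname(as.matrix(e$counts)[order(e$coords$y, e$coords$x), ]))

  # min_genes filter
  sparse_counts <- counts
  sparse_counts[1:8, ] <- 0
  e3 <- expression_matrix(sparse_counts, data.frame(spot = rownames(counts), coords))
  expect_equal(nrow(bin_spots(e3, 2, min_genes = 6)$counts) <
               nrow(bin_spots(e3, 2, min_genes = 0)$counts), TRUE)

  # irregular coordinates rejected
  e_bad <- e
  e_bad$coords$x[2] <- 1.37
  expect_error(bin_spots(e_bad, 2), "regular grid")
})

test_that("MTX round-trip through the reader preserves counts and metadata", {
  net <- make_toy_network()
  ds <- simulate_spatial_counts(net, grid = c(4, 4), seed = 2)
  dir <- withr::local_tempdir()
  Matrix::writeMM(Matrix::t(ds$expr$counts), file.path(dir, "m.mtx"))
  writeLines(colnames(ds$expr$counts), file.path(dir, "genes.tsv"))
  writeLines(rownames(ds$expr$counts), file.path(dir, "barcodes.tsv"))
  write.table(ds$expr$coords, file.path(dir, "coords.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  write.csv(data.frame(spot = names(ds$regions), label = unname(ds$regions)),
            file.path(dir, "ann.csv"), row.names = FALSE)
  got <- read_expression_mtx(file.path(dir, "m.mtx"), file.path(dir, "genes.tsv"),
                             file.path(dir, "barcodes.tsv"), file.path(dir, "coords.tsv"),
                             file.path(dir, "ann.csv"))
  expect_equal(as.matrix(got$counts), as.matrix(ds$expr$counts))
  expect_equal(got$annotation, ds$expr$annotation)
})

test_that("QC cluster filtering is opt-in and removes low-complexity clusters", {
  counts <- rbind(matrix(rpois(10 * 20, 20), 10),
                  matrix(rpois(5 * 20, 0.2), 5))
  dimnames(counts) <- list(sprintf("s%02d", 1:15), sprintf("g%02d", 1:20))
  e <- toy_expression(counts)
  labels <- c(rep("good", 10), rep("poor", 5))
  # nothing removed by default
  expect_equal(nrow(filter_low_quality_clusters(e, labels)$counts), 15)
  kept <- filter_low_quality_clusters(e, labels, min_genes = 5)
  expect_equal(nrow(kept$counts), 10)
  expect_setequal(rownames(kept$counts), sprintf("s%02d", 1:10))
})
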