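#' Construct a spatial expression container
#'
#' Holds a spot x gene raw count matrix together with spatial coordinates and
#' optional per-spot annotation, plus derived layers (`lognorm`, `imputed`)
#' filled in by [normalize_counts()] and [impute_expression()]. All layers
#' share the same spot and gene ordering.
#'
#' @param counts spot x gene matrix of non-negative integer counts; rownames
#'   are spot ids, colnames gene ids. Sparse (`dgCMatrix`) or dense.
#' @param coords data.frame with columns `spot`, `x`, `y` (micrometres or
#'   grid units); one row per spot, coordinates unique.
#' @param annotation optional named character vector (names = spot ids) of
#'   region labels, e.g. Tumor/Stroma/Interface.
#' @return an object of class `st_expression`.
#' @export
expression_matrix <- function(counts, coords, annotation = NULL) {
  counts <- as(as(Matrix::Matrix(counts, sparse = TRUE), "generalMatrix"), "CsparseMatrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry spot rownames and gene colnames")
  if (any(counts@x < 0)) stop("counts must be non-negative")
  stopifnot(is.data.frame(coords), all(c("spot", "x", "y") %in% names(coords)))
  coords <- coords[match(rownames(counts), coords$spot), , drop = FALSE]
  if (any(is.na(coords$spot))) stop("every spot needs coordinates")
  if (anyDuplicated(coords[, c("x", "y")])) stop("spot coordinates must be unique")
  if (!is.null(annotation)) {
    annotation <- annotation[rownames(counts)]
    if (any(is.na(annotation))) stop("annotation missing for some spots")
  }
  obj <- list(counts = counts, layers = list(), coords = coords,
              annotation = annotation, cluster = NULL)
  class(obj) <- "st_expression"
  obj
}

#' @export
print.st_expression <- function(x, ...) {
  cat(sprintf("st_expression: %d spots x %d genes; layers: %s%s\n",
              nrow(x$counts), ncol(x$counts),
              if (length(x$layers)) paste(names(x$layers), collapse = ", ") else "<none>",
              if (is.null(x$annotation)) "" else "; annotated"))
  invisible(x)
}

#' Read a spot x gene matrix from MatrixMarket + TSV sidecars
#'
#' Reads the common sparse-export layout: an `.mtx` count matrix (genes x
#' barcodes, as written by 10x-style pipelines, transposed on read), a gene
#' TSV (first column = gene id), a barcode TSV (first column = spot id), a
#' coordinate TSV with columns `spot`, `x`, `y`, and an optional annotation
#' CSV with columns `spot`, `label`.
#'
#' @param mtx,genes,barcodes,coords,annotation file paths (annotation may be
#'   `NULL`).
#' @return an [expression_matrix()].
#' @export
read_expression_mtx <- function(mtx, genes, barcodes, coords, annotation = NULL) {
  m <- Matrix::readMM(mtx)
  gene_ids <- utils::read.delim(genes, header = FALSE)[[1]]
  spot_ids <- utils::read.delim(barcodes, header = FALSE)[[1]]
  if (nrow(m) != length(gene_ids) || ncol(m) != length(spot_ids))
    stop("MTX dimensions do not match gene/barcode files")
  m <- Matrix::t(m)
  dimnames(m) <- list(spot_ids, gene_ids)
  xy <- utils::read.delim(coords)
  ann <- NULL
  if (!is.null(annotation)) {
    a <- utils::read.csv(annotation)
    ann <- stats::setNames(as.character(a$label), a$spot)
  }
  expression_matrix(m, xy, ann)
}

#' Library-size normalisation and log transform
#'
#' Rescales each spot's counts to a common total (`target_sum`) and applies
#' `log1p`, the standard library-size normalisation of droplet and spatial
#' transcriptomics. The raw counts layer is preserved; spots with zero total
#' count are dropped with a warning rather than erroring.
#'
#' @param expr an [expression_matrix()].
#' @param target_sum per-spot total after rescaling (default `1e4`).
#' @return `expr` with a `lognorm` layer.
#' @export
normalize_counts <- function(expr, target_sum = 1e4) {
  stopifnot(inherits(expr, "st_expression"))
  if (!is.numeric(target_sum) || target_sum <= 0) stop("target_sum must be positive")
  totals <- Matrix::rowSums(expr$counts)
  if (any(totals == 0)) {
    drop <- rownames(expr$counts)[totals == 0]
    warning(sprintf("dropping %d zero-count spot(s): %s", length(drop),
                    paste(utils::head(drop, 5), collapse = ", ")))
    expr <- subset_spots(expr, totals > 0)
    totals <- totals[totals > 0]
  }
  scaled <- Matrix::Diagonal(x = target_sum / totals) %*% expr$counts
  lognorm <- scaled
  lognorm@x <- log1p(lognorm@x)
  dimnames(lognorm) <- dimnames(expr$counts)
  expr$layers$lognorm <- as(lognorm, "CsparseMatrix")
  expr
}

subset_spots <- function(expr, keep) {
  expr$counts <- expr$counts[keep, , drop = FALSE]
  expr$layers <- lapply(expr$layers, function(l) l[keep, , drop = FALSE])
  expr$coords <- expr$coords[keep, , drop = FALSE]
  if (!is.null(expr$annotation)) expr$annotation <- expr$annotation[keep]
  if (!is.null(expr$cluster)) expr$cluster <- expr$cluster[keep]
  expr
}

get_layer <- function(expr, layer = c("auto", "lognorm", "imputed", "counts")) {
  layer <- match.arg(layer)
  if (layer == "counts") return(expr$counts)
  if (layer == "auto")
    layer <- if (!is.null(expr$layers$imputed)) "imputed" else "lognorm"
  out <- expr$layers[[layer]]
  if (is.null(out)) stop("layer '", layer, "' not present; run normalize_counts() first")
  out
}

#' Denoise the expression layer
#'
#' Pluggable dropout-denoising step. `method = "none"` is the identity on
#' the `lognorm` layer. `method = "magic"` applies Markov-affinity diffusion:
#' an adaptive Gaussian kernel on the kNN graph in PCA space is symmetrised,
#' row-normalised into a transition matrix and raised to `t_steps` powers;
#' expression is smoothed by this operator. Defaults follow the published
#' defaults of the diffusion approach (`knn = 5`, `decay = 1`, `t_steps = 3`).
#' A user function (signature `function(matrix) -> matrix`) can be supplied
#' to plug in an external denoiser.
#'
#' @param expr an [expression_matrix()] with a `lognorm` layer.
#' @param method `"none"`, `"magic"`, or a function.
#' @param npca PCs used for the affinity graph (default 20, capped at data size).
#' @param knn,decay,t_steps diffusion-kernel parameters.
#' @return `expr` with an `imputed` layer.
#' @export
impute_expression <- function(expr, method = "none", npca = 20, knn = 5,
                              decay = 1, t_steps = 3) {
  stopifnot(inherits(expr, "st_expression"))
  X <- get_layer(expr, "lognorm")
  if (is.function(method)) {
    expr$layers$imputed <- method(X)
    return(expr)
  }
  if (!is.character(method) || !(method %in% c("none", "magic")))
    stop("unknown imputation method; use \"none\", \"magic\", or a function")
  if (method == "none") {
    expr$layers$imputed <- X
    return(expr)
  }
  Xd <- as.matrix(X)
  n <- nrow(Xd)
  npca <- min(npca, n - 1L, ncol(Xd))
  pcs <- stats::prcomp(Xd, rank. = npca, center = TRUE, scale. = FALSE)$x
  D <- as.matrix(stats::dist(pcs))
  knn <- min(knn, n - 1L)
  kmax <- min(3L * knn, n - 1L)  # kernel support truncated to 3*knn neighbours
  sigma <- numeric(n)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    d <- D[i, ]
    ord <- order(d)
    nb <- ord[ord != i][seq_len(kmax)]
    sigma_i <- d[nb[knn]]
    if (sigma_i == 0 || !is.finite(sigma_i)) sigma_i <- 1e-12
    sigma[i] <- sigma_i
    A[i, nb] <- exp(-(d[nb] / sigma_i)^decay)
    A[i, i] <- 1
  }
  A <- (A + t(A)) / 2
  M <- A / rowSums(A)
  Mt <- M
  if (t_steps > 1) for (i in seq_len(t_steps - 1L)) Mt <- Mt %*% M
  out <- Mt %*% Xd
  dimnames(out) <- dimnames(Xd)
  expr$layers$imputed <- Matrix::Matrix(out, sparse = FALSE)
  expr
}

#' Aggregate grid spots into larger bins
#'
#' Sums raw counts within `factor` x `factor` windows of a regular spot grid
#' (e.g. factor 4 turns 8 um spots into 32 um bins of 16 spots). Bins with
#' fewer than `min_genes` detected genes are removed. When annotation is
#' present, a bin inherits the majority label if its proportion exceeds
#' `annotation_majority`, and is labelled `"Interface"` otherwise. Derived
#' layers are discarded: binning operates on raw counts and precedes
#' normalisation.
#'
#' @param expr an [expression_matrix()] with spots on a regular grid.
#' @param factor integer >= 1 window size in grid steps; 1 is the identity.
#' @param min_genes minimum detected genes per retained bin (default 0).
#' @param annotation_majority proportion a label must exceed to be inherited
#'   (default 0.5).
#' @return a new [expression_matrix()] of bins.
#' @export
bin_spots <- function(expr, factor, min_genes = 0, annotation_majority = 0.5) {
  stopifnot(inherits(expr, "st_expression"))
  if (factor < 1 || factor != round(factor)) stop("factor must be a positive integer")
  xs <- expr$coords$x; ys <- expr$coords$y
  step <- function(v) {
    u <- sort(unique(v))
    if (length(u) == 1) return(1)
    d <- diff(u)
    s <- min(d)
    if (any(abs(d / s - round(d / s)) > 1e-6))
      stop("coordinates do not lie on a regular grid")
    s
  }
  sx <- step(xs); sy <- step(ys)
  bx <- floor((xs - min(xs)) / (sx * factor) + 1e-9)
  by <- floor((ys - min(ys)) / (sy * factor) + 1e-9)
  bin <- paste0("bin_", bx, "_", by)
  ubin <- unique(bin)
  G <- Matrix::sparseMatrix(i = match(bin, ubin), j = seq_along(bin), x = 1,
                            dims = c(length(ubin), length(bin)))
  counts <- as(G %*% expr$counts, "CsparseMatrix")
  rownames(counts) <- ubin
  colnames(counts) <- colnames(expr$counts)
  coords <- data.frame(spot = ubin,
                       x = as.vector(G %*% xs) / Matrix::rowSums(G),
                       y = as.vector(G %*% ys) / Matrix::rowSums(G))
  ann <- NULL
  if (!is.null(expr$annotation)) {
    ann <- vapply(ubin, function(bb) {
      lab <- expr$annotation[bin == bb]
      tt <- table(lab) / length(lab)
      if (max(tt) > annotation_majority) names(tt)[which.max(tt)] else "Interface"
    }, character(1))
  }
  out <- expression_matrix(counts, coords, ann)
  detected <- Matrix::rowSums(out$counts > 0)
  if (any(detected < min_genes)) out <- subset_spots(out, detected >= min_genes)
  out
}

#' Optional QC removal of low-quality clusters
#'
#' Removes spots belonging to clusters whose median detected-gene count falls
#' below `min_genes` or whose median total count falls below `min_counts`.
#' Both thresholds default to `NULL` (nothing removed): there is no universal
#' numeric rule, so the filter is explicit and opt-in.
#'
#' @param expr an [expression_matrix()].
#' @param labels cluster labels, one per spot.
#' @param min_genes,min_counts thresholds on per-cluster medians; `NULL`
#'   disables the corresponding check.
#' @return the filtered [expression_matrix()].
#' @export
filter_low_quality_clusters <- function(expr, labels, min_genes = NULL, min_counts = NULL) {
  stopifnot(inherits(expr, "st_expression"), length(labels) == nrow(expr$counts))
  if (is.null(min_genes) && is.null(min_counts)) return(expr)
  detected <- Matrix::rowSums(expr$counts > 0)
  totals <- Matrix::rowSums(expr$counts)
  bad <- character(0)
  for (cl in unique(labels)) {
    idx <- labels == cl
    if (!is.null(min_genes) && stats::median(detected[idx]) < min_genes) bad <- c(bad, cl)
    else if (!is.null(min_counts) && stats::median(totals[idx]) < min_counts) bad <- c(bad, cl)
  }
  if (length(bad)) expr <- subset_spots(expr, !(labels %in% bad))
  expr
}

#' Cluster spots with Leiden on a kNN graph in PCA space
#'
#' The feature matrix (an expression layer, or any spot x feature matrix such
#' as a RAS or FES layer) is reduced by PCA; an undirected union kNN graph is
#' built from Euclidean distances in PC space and partitioned with the Leiden
#' algorithm. The mean silhouette width, computed in the same PC space, is
#' returned as the clustering quality; a single-cluster (degenerate) result
#' gets the sentinel value -1, since the silhouette is undefined there.
#'
#' @param x an [expression_matrix()] or a numeric spot x feature matrix.
#' @param n_pcs number of principal components (>= 2; capped at data size).
#' @param n_neighbors kNN graph degree (>= 2).
#' @param resolution Leiden resolution parameter.
#' @param seed integer seed; results are deterministic given the seed.
#' @param layer layer to use when `x` is an `st_expression`.
#' @return list with `labels` (integer vector, named by spot), `silhouette`,
#'   `n_clusters`, and the parameters used.
#' @export
cluster_spots <- function(x, n_pcs = 30, n_neighbors = 10, resolution = 1,
                          seed = 0, layer = "auto") {
  X <- if (inherits(x, "st_expression")) as.matrix(get_layer(x, layer)) else as.matrix(x)
  n <- nrow(X)
  if (n_pcs < 2) stop("n_pcs must be >= 2")
  if (n_neighbors < 2) stop("n_neighbors must be >= 2")
  if (n < n_neighbors + 1) stop("need more spots than n_neighbors")
  n_pcs_eff <- min(n_pcs, n - 1L, ncol(X))
  set.seed(seed)
  pcs <- stats::prcomp(X, rank. = n_pcs_eff, center = TRUE, scale. = FALSE)$x
  D <- as.matrix(stats::dist(pcs))
  diag(D) <- Inf
  nn <- t(apply(D, 1, function(d) order(d)[seq_len(n_neighbors)]))
  edges <- cbind(rep(seq_len(n), each = n_neighbors), as.vector(t(nn)))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::simplify(g)
  comm <- igraph::cluster_leiden(g, objective_function = "modularity",
                                 resolution = resolution, n_iterations = 3)
  labels <- igraph::membership(comm)
  labels <- stats::setNames(as.integer(labels), rownames(X))
  k <- length(unique(labels))
  sil <- if (k < 2) -1 else {
    sw <- cluster::silhouette(as.integer(labels), stats::dist(pcs))
    mean(sw[, "sil_width"])
  }
  list(labels = labels, silhouette = sil, n_clusters = k,
       n_pcs = n_pcs, n_neighbors = n_neighbors, resolution = resolution,
       seed = seed)
}

#' Silhouette-driven grid search over clustering parameters
#'
#' Runs [cluster_spots()] over a grid of PC counts, neighbourhood sizes and
#' Leiden resolutions and returns the combination maximising the silhouette.
#' Degenerate (single-cluster) combinations carry the -1 sentinel and are
#' never selected unless every combination is degenerate, in which case the
#' degenerate labelling is returned with `degenerate = TRUE`. Ties are broken
#' lexicographically by (fewer PCs, fewer neighbours, lower resolution). The
#' full search table is returned for audit.
#'
#' @param x as in [cluster_spots()].
#' @param n_pcs_grid,n_neighbors_grid,resolution_grid nonempty numeric grids.
#' @param seed integer seed applied to every combination.
#' @param layer layer to use when `x` is an `st_expression`.
#' @return list with `labels`, `silhouette`, `params`, `table`, `degenerate`.
#' @export
grid_search_clustering <- function(x, n_pcs_grid = c(15, 30, 50),
                                   n_neighbors_grid = c(10, 15, 30),
                                   resolution_grid = c(0.1, 0.25, 0.5, 1.0),
                                   seed = 0, layer = "auto") {
  if (!length(n_pcs_grid) || !length(n_neighbors_grid) || !length(resolution_grid))
    stop("all parameter grids must be nonempty")
  grid <- expand.grid(n_pcs = sort(n_pcs_grid), n_neighbors = sort(n_neighbors_grid),
                      resolution = sort(resolution_grid))
  runs <- vector("list", nrow(grid))
  tab <- grid
  tab$silhouette <- NA_real_
  tab$n_clusters <- NA_integer_
  for (i in seq_len(nrow(grid))) {
    runs[[i]] <- cluster_spots(x, grid$n_pcs[i], grid$n_neighbors[i],
                               grid$resolution[i], seed = seed, layer = layer)
    tab$silhouette[i] <- runs[[i]]$silhouette
    tab$n_clusters[i] <- runs[[i]]$n_clusters
  }
  valid <- tab$n_clusters > 1
  pool <- if (any(valid)) which(valid) else seq_len(nrow(tab))
  ord <- pool[order(-tab$silhouette[pool], tab$n_pcs[pool],
                    tab$n_neighbors[pool], tab$resolution[pool])]
  best <- ord[1]
  list(labels = runs[[best]]$labels,
       silhouette = tab$silhouette[best],
       params = as.list(grid[best, ]),
       table = tab,
       degenerate = !any(valid))
}
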