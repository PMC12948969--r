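#' V-measure between two clusterings
#'
#' Entropy-based agreement score: the harmonic mean (beta = 1) of
#' homogeneity `1 - H(ref|labels)/H(ref)` and completeness
#' `1 - H(labels|ref)/H(labels)`, computed from the label contingency
#' table. Symmetric at beta = 1 and invariant under label permutation;
#' 1 for identical partitions, 0 when one side is a single cluster against
#' a multi-class reference.
#'
#' @param labels_a candidate clustering (vector, any label type).
#' @param labels_ref reference clustering over the same spots.
#' @return a number in `[0, 1]`.
#' @export
v_measure_compare <- function(labels_a, labels_ref) {
  if (length(labels_a) != length(labels_ref))
    stop("clusterings must cover the same spots")
  if (!is.null(names(labels_a)) && !is.null(names(labels_ref))) {
    if (!setequal(names(labels_a), names(labels_ref)))
      stop("clusterings must cover the same spots")
    labels_ref <- labels_ref[names(labels_a)]
  }
  ct <- table(labels_ref, labels_a)
  n <- sum(ct)
  H <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  h_ref <- H(rowSums(ct) / n)
  h_lab <- H(colSums(ct) / n)
  # conditional entropies from joint counts
  cond <- function(tab) {        # H(rows | cols)
    tot <- colSums(tab)
    s <- 0
    for (j in seq_len(ncol(tab))) {
      if (tot[j] == 0) next
      p <- tab[, j] / n
      p <- p[p > 0]
      s <- s - sum(p * log(p / (tot[j] / n)))
    }
    s
  }
  h_ref_given <- cond(ct)
  h_lab_given <- cond(t(ct))
  hom <- if (h_ref == 0) 1 else 1 - h_ref_given / h_ref
  com <- if (h_lab == 0) 1 else 1 - h_lab_given / h_lab
  if (hom + com == 0) return(0)
  2 * hom * com / (hom + com)
}

#' Compare per-sample V-measures between two methods
#'
#' One-sided Mann-Whitney U test of the hypothesis that method 1's
#' per-sample V-measures are stochastically greater than method 2's.
#' All-tied inputs are reported with the p = 0.5 convention and flagged.
#'
#' @param v1,v2 numeric vectors of per-sample V-measures (>= 3 each).
#' @return list with `p_value`, `statistic`, `flagged`.
#' @export
compare_layers <- function(v1, v2) {
  if (length(v1) < 3 || length(v2) < 3)
    stop("need at least 3 samples per method")
  if (length(unique(c(v1, v2))) == 1)
    return(list(p_value = 0.5, statistic = NA_real_, flagged = TRUE))
  wt <- suppressWarnings(stats::wilcox.test(v1, v2, alternative = "greater"))
  list(p_value = wt$p.value, statistic = unname(wt$statistic), flagged = FALSE)
}

#' Contrast one score between two annotated regions
#'
#' Percent variation of the group means,
#' `100 * (mean_A - mean_B) / |mean_B|` (B is the reference group), with a
#' Welch two-sided t-test and significance stars at 0.05 / 0.01 / 0.001.
#' When `|mean_B|` falls below `1e-6 * max|values|` the ratio is numerically
#' meaningless and the result is flagged `unstable`.
#'
#' @param values per-spot scores (e.g. one reaction's FES column).
#' @param groups per-spot labels aligned with `values`.
#' @param group_a,group_b the two labels to contrast; `group_b` is the
#'   reference.
#' @return list with `percent_variation`, `p_value`, `stars`, `mean_a`,
#'   `mean_b`, `unstable`.
#' @export
region_contrast <- function(values, groups, group_a, group_b) {
  xa <- values[groups == group_a]
  xb <- values[groups == group_b]
  if (length(xa) < 2 || length(xb) < 2)
    stop("each group needs at least 2 spots")
  ma <- mean(xa); mb <- mean(xb)
  eps <- 1e-6 * max(abs(values), 1e-300)
  unstable <- abs(mb) < eps
  pct <- if (mb == 0) NA_real_ else 100 * (ma - mb) / abs(mb)
  p <- if (stats::sd(xa) == 0 && stats::sd(xb) == 0) {
    if (ma == mb) 1 else 0
  } else stats::t.test(xa, xb)$p.value
  stars <- if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else "ns"
  list(percent_variation = pct, p_value = p, stars = stars,
       mean_a = ma, mean_b = mb, unstable = unstable)
}

# fold change as a relative difference of group means, with a guarded
# denominator (the paper's maps threshold |FC| at 0.05 i.e. 5%)
fold_change_guarded <- function(ma, mb, scale) {
  eps <- 1e-6 * max(scale, 1e-300)
  denom <- max(abs(mb), eps)
  list(fc = (ma - mb) / denom, unstable = abs(mb) < eps)
}

#' Differential RAS/FES map between two regions
#'
#' Per reaction: a two-sample Kolmogorov-Smirnov test between the two
#' groups' score distributions, and the fold change (relative difference of
#' group means, reference = group B). A reaction is classed directionally
#' regulated (`up_in_A` / `up_in_B`) only if `p < alpha` *and*
#' `|fold change| > fc_threshold`; constant-zero reactions are
#' `not_significant` by convention. No multiple-testing correction is
#' applied by default (`adjust = "BH"` enables Benjamini-Hochberg).
#'
#' @param mat a `ras_matrix`, `fes_matrix` or plain spot x reaction matrix.
#' @param groups per-spot labels.
#' @param group_a,group_b labels to contrast (B = reference).
#' @param alpha significance level (default 0.05).
#' @param fc_threshold fold-change threshold (default 0.05, i.e. 5%).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return data.frame with columns `reaction`, `p_value`, `fold_change`,
#'   `mean_a`, `mean_b`, `class`, `unstable`.
#' @export
differential_map <- function(mat, groups, group_a, group_b, alpha = 0.05,
                             fc_threshold = 0.05, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (inherits(mat, "ras_matrix")) {
    X <- mat$scores[, mat$defined, drop = FALSE]
  } else if (inherits(mat, "fes_matrix")) {
    X <- mat$scores
  } else X <- as.matrix(mat)
  ia <- groups == group_a; ib <- groups == group_b
  if (!any(ia) || !any(ib)) stop("both groups must be nonempty")
  res <- lapply(colnames(X), function(rid) {
    xa <- X[ia, rid]; xb <- X[ib, rid]
    if (all(xa == 0) && all(xb == 0))
      return(data.frame(reaction = rid, p_value = 1, fold_change = 0,
                        mean_a = 0, mean_b = 0, class = "not_significant",
                        unstable = FALSE))
    p <- suppressWarnings(stats::ks.test(xa, xb)$p.value)
    fc <- fold_change_guarded(mean(xa), mean(xb), max(abs(X[, rid])))
    data.frame(reaction = rid, p_value = p, fold_change = fc$fc,
               mean_a = mean(xa), mean_b = mean(xb), class = NA_character_,
               unstable = fc$unstable)
  })
  out <- do.call(rbind, res)
  if (adjust == "BH") out$p_value <- stats::p.adjust(out$p_value, "BH")
  miss <- is.na(out$class)
  out$class[miss] <- ifelse(out$p_value[miss] < alpha & out$fold_change[miss] > fc_threshold,
                            "up_in_A",
                     ifelse(out$p_value[miss] < alpha & out$fold_change[miss] < -fc_threshold,
                            "up_in_B", "not_significant"))
  rownames(out) <- NULL
  out
}

#' RAS-FES concordance
#'
#' Restricts to reactions passing `p < alpha` and `|fold change| > fc` in
#' *both* differential maps, and returns the percentage of those whose fold
#' changes agree in sign. With an empty passing set the concordance is
#' undefined and `NA` is returned (with a message).
#'
#' @param ras_diff,fes_diff data.frames from [differential_map()] over a
#'   shared reaction universe.
#' @param alpha significance level (default 0.05).
#' @param fc fold-change threshold (default 0.2).
#' @return a percentage in `[0, 100]`, or `NA` if no reaction passes. The
#'   number of passing reactions is attached as attribute `"n"`.
#' @export
concordance <- function(ras_diff, fes_diff, alpha = 0.05, fc = 0.2) {
  mg <- merge(ras_diff, fes_diff, by = "reaction", suffixes = c("_ras", "_fes"))
  if (nrow(mg) == 0) stop("no shared reactions between the two maps")
  pass <- mg$p_value_ras < alpha & abs(mg$fold_change_ras) > fc &
          mg$p_value_fes < alpha & abs(mg$fold_change_fes) > fc
  if (!any(pass)) {
    message("concordance undefined: no reaction passes both filters")
    return(structure(NA_real_, n = 0L))
  }
  agree <- sign(mg$fold_change_ras[pass]) == sign(mg$fold_change_fes[pass])
  structure(100 * mean(agree), n = sum(pass))
}

#' Built-in marker gene panels
#'
#' `vascularization`: six endothelial markers (PECAM1/CD31, ESAM, CD34,
#' TEK/TIE2, VCAN, CDH5/VE-cadherin). `proliferation`: four canonical
#' cell-cycle markers (MCM7, MCM3, PCNA, MKI67), deliberately not metabolic
#' genes so the score is independent of the flux layer it is correlated
#' with.
#'
#' @return named list of character vectors.
#' @export
marker_panels <- function() {
  list(vascularization = c("PECAM1", "ESAM", "CD34", "TEK", "VCAN", "CDH5"),
       proliferation = c("MCM7", "MCM3", "PCNA", "MKI67"))
}

#' Per-spot marker score
#'
#' Mean normalized expression of the panel genes present in the matrix;
#' genes missing from the data reduce the denominator (the mean is over
#' present genes only). Errors if no panel gene is measured.
#'
#' @param expr an [expression_matrix()] with a `lognorm` layer.
#' @param panel a character vector of gene ids, or the name of a built-in
#'   panel (see [marker_panels()]).
#' @param layer expression layer (default `"lognorm"`).
#' @return named numeric vector, one score per spot.
#' @export
marker_score <- function(expr, panel, layer = "lognorm") {
  stopifnot(inherits(expr, "st_expression"))
  if (is.character(panel) && length(panel) == 1 && panel %in% names(marker_panels()))
    panel <- marker_panels()[[panel]]
  X <- get_layer(expr, layer)
  present <- intersect(panel, colnames(X))
  if (length(present) == 0) stop("no panel gene present in the expression matrix")
  if (length(present) < length(panel))
    message(sprintf("marker_score: %d/%d panel genes present",
                    length(present), length(panel)))
  stats::setNames(Matrix::rowSums(X[, present, drop = FALSE]) / length(present),
                  rownames(X))
}

#' Spearman correlation between two per-spot scores
#'
#' Spearman rho with a 95% confidence interval via the Fisher
#' z-transformation (Bonett-Wright standard error
#' `sqrt((1 + rho^2/2) / (n - 3))`). Constant input gives an undefined rho,
#' returned as `NA` with `defined = FALSE`.
#'
#' @param score_a,score_b paired per-spot values (>= 10 pairs).
#' @return list with `rho`, `ci` (length 2), `n`, `defined`.
#' @export
score_correlation <- function(score_a, score_b) {
  keep <- is.finite(score_a) & is.finite(score_b)
  a <- score_a[keep]; b <- score_b[keep]
  n <- length(a)
  if (n < 10) stop("need at least 10 paired spots")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    return(list(rho = NA_real_, ci = c(NA_real_, NA_real_), n = n, defined = FALSE))
  rho <- stats::cor(a, b, method = "spearman")
  z <- atanh(min(max(rho, -1 + 1e-12), 1 - 1e-12))
  se <- sqrt((1 + rho^2 / 2) / (n - 3))
  ci <- tanh(z + c(-1, 1) * stats::qnorm(0.975) * se)
  list(rho = rho, ci = ci, n = n, defined = TRUE)
}

#' Inverse-variance meta-analytic mean of Spearman correlations
#'
#' Fixed-effect combination on the Fisher-z scale of per-sample rho values
#' (e.g. biomass-FES vs proliferation score across samples), weighting each
#' by the inverse of its z-scale variance `(1 + rho^2/2)/(n - 3)`.
#'
#' @param rhos per-sample Spearman correlations.
#' @param ns per-sample spot counts.
#' @return list with `rho`, `ci` (95%), `k` samples combined.
#' @export
meta_spearman <- function(rhos, ns) {
  stopifnot(length(rhos) == length(ns), length(rhos) >= 1)
  z <- atanh(pmin(pmax(rhos, -1 + 1e-12), 1 - 1e-12))
  w <- (ns - 3) / (1 + rhos^2 / 2)
  zbar <- sum(w * z) / sum(w)
  se <- sqrt(1 / sum(w))
  list(rho = tanh(zbar),
       ci = tanh(zbar + c(-1, 1) * stats::qnorm(0.975) * se),
       k = length(rhos))
}

#' Pathway-level activity scores
#'
#' Expression variant: per spot, the mean normalized expression of a gene
#' set. Flux variant: per spot, the mean of |FES| over a reaction set.
#' Pathways with an empty intersection with the data are skipped with a
#' warning.
#'
#' @param x an [expression_matrix()] (gene variant) or a `fes_matrix` /
#'   spot x reaction matrix (flux variant).
#' @param sets named list of gene or reaction id vectors.
#' @param layer expression layer for the gene variant.
#' @return spot x pathway numeric matrix.
#' @export
pathway_score <- function(x, sets, layer = "lognorm") {
  stopifnot(is.list(sets), length(sets) > 0, !is.null(names(sets)))
  if (inherits(x, "st_expression")) {
    X <- as.matrix(get_layer(x, layer))
    absolute <- FALSE
  } else if (inherits(x, "fes_matrix")) {
    X <- x$scores
    absolute <- TRUE
  } else {
    X <- as.matrix(x)
    absolute <- TRUE
  }
  cols <- list()
  for (nm in names(sets)) {
    hit <- intersect(sets[[nm]], colnames(X))
    if (length(hit) == 0) {
      warning("pathway '", nm, "' has no member in the data; skipped")
      next
    }
    V <- X[, hit, drop = FALSE]
    if (absolute) V <- abs(V)
    cols[[nm]] <- rowMeans(V)
  }
  if (length(cols) == 0) stop("no pathway overlaps the data")
  do.call(cbind, cols)
}
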