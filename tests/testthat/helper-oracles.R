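# Independent oracles used to cross-check the LP core and the statistics.
# These deliberately avoid the package's own code paths: FVA/pFBA are checked
# against exhaustive vertex enumeration, the V-measure against a direct
# mutual-information formulation.

# All vertices of {v : S v = b, lb <= v <= ub}: pick n - m variables to pin
# at a bound (every combination, both bounds), solve the square system for
# the rest, keep solutions inside the box.
enumerate_vertices <- function(S, lb, ub, b = rep(0, nrow(S)), tol = 1e-9) {
  S <- as.matrix(S)
  m <- nrow(S); n <- ncol(S)
  qrS <- qr(S)
  rk <- qrS$rank
  nfree <- n - rk
  verts <- list()
  add_vertex <- function(v) {
    if (all(v >= lb - 1e-7) && all(v <= ub + 1e-7))
      verts[[length(verts) + 1L]] <<- pmin(pmax(v, lb), ub)
  }
  if (nfree == 0) {
    v <- tryCatch(qr.solve(S, b), error = function(e) NULL)
    if (!is.null(v) && max(abs(S %*% v - b)) < 1e-7) add_vertex(v)
  } else {
    combos <- utils::combn(n, nfree)
    for (ci in seq_len(ncol(combos))) {
      pinned <- combos[, ci]
      basis <- setdiff(seq_len(n), pinned)
      B <- S[, basis, drop = FALSE]
      if (qr(B)$rank < rk) next
      for (mask in 0:(2^nfree - 1)) {
        at_ub <- as.logical(bitwAnd(mask, 2^(seq_len(nfree) - 1)))
        vp <- ifelse(at_ub, ub[pinned], lb[pinned])
        rhs <- b - S[, pinned, drop = FALSE] %*% vp
        xB <- tryCatch(qr.solve(B, rhs), error = function(e) NULL)
        if (is.null(xB)) next
        v <- numeric(n)
        v[pinned] <- vp
        v[basis] <- xB
        if (max(abs(S %*% v - b)) < 1e-6) add_vertex(v)
      }
    }
  }
  if (length(verts) == 0) return(NULL)
  unique(do.call(rbind, verts))
}

# FVA by enumeration: the optimum of a bounded LP over a polytope is attained
# at a vertex.
brute_fva <- function(S, lb, ub) {
  V <- enumerate_vertices(S, lb, ub)
  if (is.null(V)) stop("empty polytope")
  cbind(min = apply(V, 2, min), max = apply(V, 2, max))
}

# pFBA by enumeration: biomass optimum over vertices, then the L1 minimum
# over the optimal-biomass slice. sum|v| is convex piecewise-linear, so its
# minimum need not sit at a slice vertex; within each sign orthant it is
# linear, so we enumerate the slice restricted to every orthant (bound
# clipping only) and take the overall best vertex.
brute_pfba <- function(S, lb, ub, bio_idx) {
  V <- enumerate_vertices(S, lb, ub)
  if (is.null(V)) stop("empty polytope")
  bstar <- max(V[, bio_idx])
  n <- ncol(S)
  Sfix <- rbind(as.matrix(S), as.numeric(seq_len(n) == bio_idx))
  bfix <- c(rep(0, nrow(S)), bstar)
  best <- Inf
  for (mask in 0:(2^n - 1)) {
    nonneg <- as.logical(bitwAnd(mask, 2^(seq_len(n) - 1)))
    lo <- ifelse(nonneg, pmax(lb, 0), lb)
    hi <- ifelse(nonneg, ub, pmin(ub, 0))
    if (any(lo > hi)) next
    Vo <- enumerate_vertices(Sfix, lo, hi, b = bfix)
    if (!is.null(Vo)) best <- min(best, min(rowSums(abs(Vo))))
  }
  list(objective = bstar, total_abs = best)
}

# Random small network for oracle comparisons: sparse-ish integer
# stoichiometry, bounds straddling zero so the polytope is nonempty.
random_small_network <- function(seed) {
  set.seed(seed)
  m <- sample(2:4, 1)
  n <- m + sample(1:2, 1)
  repeat {
    S <- matrix(sample(c(-2, -1, 0, 0, 1, 1, 2), m * n, replace = TRUE), m, n)
    if (all(colSums(S != 0) >= 1)) break
  }
  lb <- round(runif(n, -10, 0), 1)
  ub <- round(runif(n, 0, 10), 1)
  list(S = S, lb = lb, ub = ub)
}

# V-measure via the mutual-information identity (independent of the
# conditional-entropy formulation in the package).
oracle_v_measure <- function(a, ref) {
  ct <- table(ref, a)
  n <- sum(ct)
  pr <- rowSums(ct) / n
  pc <- colSums(ct) / n
  H <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  mi <- 0
  for (i in seq_len(nrow(ct))) for (j in seq_len(ncol(ct))) {
    pij <- ct[i, j] / n
    if (pij > 0) mi <- mi + pij * log(pij / (pr[i] * pc[j]))
  }
  hr <- H(pr); hc <- H(pc)
  hom <- if (hr == 0) 1 else mi / hr
  com <- if (hc == 0) 1 else mi / hc
  unname(if (hom + com == 0) 0 else 2 * hom * com / (hom + com))
}

# Random GPR tree of bounded depth over a gene pool.
random_gpr_tree <- function(depth, genes) {
  if (depth == 0 || runif(1) < 0.35)
    return(structure(list(op = "gene", gene = sample(genes, 1)), class = "gpr_rule"))
  op <- sample(c("and", "or"), 1)
  k <- sample(2:3, 1)
  args <- lapply(seq_len(k), function(i) unclass(random_gpr_tree(depth - 1, genes)))
  # flatten like the parser does so serialisation round-trips exactly
  flat <- list()
  for (a in args) {
    if (!is.null(a$op) && a$op == op) flat <- c(flat, a$args) else flat <- c(flat, list(a))
  }
  structure(list(op = op, args = flat), class = "gpr_rule")
}

# Toy expression container on a small grid, for preprocessing tests.
toy_expression <- function(counts, annotation = NULL) {
  n <- nrow(counts)
  side <- ceiling(sqrt(n))
  coords <- data.frame(spot = rownames(counts),
                       x = rep(seq_len(side), length.out = n),
                       y = rep(seq_len(side), each = side)[seq_len(n)])
  expression_matrix(counts, coords, annotation)
}

# A 1-D sampling polytope: a single exchange column, flux in [0, 5].
one_dim_network <- function() {
  metabolic_network(mets = "A", rxns = "R",
                    S = matrix(0, 1, 1), lb = 0, ub = 5,
                    exchanges = "R")
}
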