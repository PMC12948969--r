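#' Solve a single flux-balance LP
#'
#' Optimises a linear objective over the steady-state polytope
#' `{v : S v = 0, lb <= v <= ub}` with the package's bounded-variable
#' simplex. Used directly for FBA and internally by the samplers.
#'
#' @param network a [metabolic_network()].
#' @param objective named numeric objective coefficients, or a single
#'   reaction id (coefficient 1).
#' @param maximize direction (default `TRUE`).
#' @param lb,ub optional named bound overrides (e.g. one spot's row of
#'   [spot_bounds()]).
#' @return list with `objective`, `flux` (named vector) and `status`
#'   (0 = optimal).
#' @export
solve_fba <- function(network, objective = network$biomass, maximize = TRUE,
                      lb = NULL, ub = NULL) {
  stopifnot(inherits(network, "metabolic_network"))
  lo <- network$lb; hi <- network$ub
  if (!is.null(lb)) lo[names(lb)] <- lb
  if (!is.null(ub)) hi[names(ub)] <- ub
  cc <- stats::setNames(rep(0, length(network$rxns)), network$rxns)
  if (is.character(objective)) {
    if (is.na(objective) || !(objective %in% network$rxns))
      stop("objective reaction not found")
    cc[[objective]] <- 1
  } else cc[names(objective)] <- objective
  r <- cpp_lp(as.matrix(network$S), rep(0, length(network$mets)),
              unname(lo), unname(hi), unname(cc), maximize)
  if (r$status == 1) stop("FBA problem is infeasible")
  list(objective = r$objective,
       flux = stats::setNames(r$solution, network$rxns),
       status = r$status)
}

#' Corner-based vertex sampling (CB3) of a spot's flux polytope
#'
#' Samples vertices of the spot-constrained steady-state polytope by
#' repeatedly optimising random linear objectives: at each iteration weights
#' are drawn uniformly from \eqn{[-1, 1]} per reaction, rescaled by the
#' reaction's FVA magnitude (`max(|F^u|, |F^l|)`; reactions with zero range
#' get weight 0, as a blocked reaction cannot steer the objective), the
#' sense (maximise/minimise) is drawn with probability 1/2, and the LP is
#' solved to a vertex. Sampling is deterministic given `seed`; consecutive
#' solves warm-start from the previous optimal basis.
#'
#' @param network a [metabolic_network()].
#' @param bounds a [spot_bounds()] object.
#' @param spot spot id (row of `bounds`).
#' @param n_samples number of random objectives (paper-scale default 10000).
#' @param seed integer seed.
#' @param ranges the [run_fva()] result used for weight rescaling.
#' @return an object of class `flux_sample_set`: list with `spot`, `samples`
#'   (successful-sample x reaction matrix), `weights`, `senses`,
#'   `objectives`, `n_requested`, `n_failed`, `seed`.
#' @export
sample_cb3 <- function(network, bounds, spot, n_samples = 10000, seed = 0,
                       ranges = NULL) {
  stopifnot(inherits(network, "metabolic_network"), inherits(bounds, "spot_bounds"))
  if (n_samples < 1) stop("n_samples must be >= 1")
  if (!(spot %in% bounds$spots)) stop("unknown spot: ", spot)
  if (is.null(ranges)) ranges <- run_fva(network)
  rxns <- network$rxns
  stopifnot(identical(bounds$reactions, rxns), identical(ranges$reaction, rxns))
  lo <- bounds$L[spot, ]; hi <- bounds$U[spot, ]
  S <- as.matrix(network$S)
  if (!cpp_feasible(S, rep(0, nrow(S)), unname(lo), unname(hi)))
    stop("flux polytope of spot '", spot, "' is infeasible")
  normalizer <- pmax(abs(ranges$max), abs(ranges$min))
  scale <- ifelse(normalizer > 0, 1 / normalizer, 0)
  set.seed(seed)
  W <- matrix(stats::runif(n_samples * length(rxns), -1, 1), n_samples, length(rxns))
  W <- sweep(W, 2, scale, `*`)
  senses <- stats::runif(n_samples) < 0.5
  res <- cpp_sample_vertices(S, rep(0, nrow(S)), unname(lo), unname(hi),
                             W, as.integer(senses))
  ok <- res$status == 0
  n_failed <- sum(!ok)
  if (n_failed > 0)
    message(sprintf("spot %s: %d/%d sampling LP(s) failed and were skipped",
                    spot, n_failed, n_samples))
  samples <- res$samples[ok, , drop = FALSE]
  colnames(samples) <- rxns
  out <- list(spot = spot, samples = samples, weights = W, senses = senses,
              objectives = res$objectives[ok], n_requested = n_samples,
              n_failed = n_failed, seed = seed)
  class(out) <- "flux_sample_set"
  out
}

#' Parsimonious FBA for one spot
#'
#' Two-step LP: first maximise the biomass flux over the spot's polytope;
#' then, holding biomass at its optimum, minimise the total absolute flux
#' \eqn{\sum_j |v_j|}. The L1 step uses the standard linear reformulation
#' with auxiliary magnitude variables `t_j >= |v_j|`. Among alternative
#' L1-optimal solutions any optimum is accepted.
#'
#' @param network a [metabolic_network()] with a biomass reaction.
#' @param bounds optional [spot_bounds()]; with `spot`, selects the row.
#'   Omitting both runs pFBA on the network's default bounds.
#' @param spot spot id.
#' @return an object of class `flux_vector`: list with `flux` (named
#'   vector), `objective` (biomass optimum), `total_abs_flux`.
#' @export
run_pfba <- function(network, bounds = NULL, spot = NULL) {
  stopifnot(inherits(network, "metabolic_network"))
  if (is.na(network$biomass)) stop("network has no biomass reaction")
  rxns <- network$rxns
  if (!is.null(bounds)) {
    stopifnot(inherits(bounds, "spot_bounds"), !is.null(spot))
    lo <- bounds$L[spot, ]; hi <- bounds$U[spot, ]
  } else {
    lo <- network$lb; hi <- network$ub
  }
  S <- as.matrix(network$S)
  m <- nrow(S); r <- ncol(S)
  bio <- match(network$biomass, rxns)

  s1 <- cpp_lp(S, rep(0, m), unname(lo), unname(hi),
               replace(rep(0, r), bio, 1), TRUE)
  if (s1$status != 0) stop("pFBA step 1 infeasible or failed")
  bstar <- s1$objective

  # step 2: min sum(t), with t_j >= |v_j| via slack rows
  #   [ S  0  0  0 ] [v]   = 0
  #   [ I -I  I  0 ] [t]   = 0   (s1 = t - v >= 0)
  #   [-I -I  0  I ] [s1]  = 0   (s2 = t + v >= 0)
  tmax <- pmax(abs(lo), abs(hi))
  A <- rbind(cbind(S, matrix(0, m, 3 * r)),
             cbind(diag(r), -diag(r), diag(r), matrix(0, r, r)),
             cbind(-diag(r), -diag(r), matrix(0, r, r), diag(r)))
  lo2 <- unname(lo); hi2 <- unname(hi)
  eps <- 1e-9 * max(1, abs(bstar))
  lo2[bio] <- max(lo2[bio], bstar - eps)
  hi2[bio] <- min(hi2[bio], max(bstar, lo2[bio]))
  lb_all <- c(lo2, rep(0, r), rep(0, r), rep(0, r))
  ub_all <- c(hi2, unname(tmax), unname(2 * tmax), unname(2 * tmax))
  cc <- c(rep(0, r), rep(1, r), rep(0, 2 * r))
  s2 <- cpp_lp(A, rep(0, m + 2 * r), lb_all, ub_all, cc, FALSE)
  if (s2$status != 0) stop("pFBA step 2 failed (status ", s2$status, ")")
  v <- stats::setNames(s2$solution[seq_len(r)], rxns)
  out <- list(flux = v, objective = bstar, total_abs_flux = sum(abs(v)),
              spot = spot)
  class(out) <- "flux_vector"
  out
}
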