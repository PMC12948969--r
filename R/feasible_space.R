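#' Flux variability analysis
#'
#' For each reaction solves the two linear programs
#' \deqn{\max/\min\; v_j \quad \mathrm{s.t.}\; S v = 0,\; v_L \le v \le v_U,}
#' i.e. the attainable flux range over the steady-state polytope under the
#' model's (typically open-medium) bounds, with no objective-fraction
#' constraint: the feasible space is delimited without imposing any
#' optimisation objective. Extremes are clipped to the default bounds to
#' suppress solver round-off.
#'
#' @param network a [metabolic_network()], normally after
#'   [apply_open_medium()].
#' @param reactions reaction ids to analyse (default: all).
#' @return a data.frame of class `feasible_range` with columns `reaction`,
#'   `min` (\eqn{F^l}), `max` (\eqn{F^u}).
#' @export
run_fva <- function(network, reactions = NULL) {
  stopifnot(inherits(network, "metabolic_network"))
  if (is.null(reactions)) reactions <- network$rxns
  idx <- match(reactions, network$rxns)
  if (any(is.na(idx))) stop("unknown reaction id(s)")
  S <- as.matrix(network$S)
  res <- cpp_fva(S, rep(0, nrow(S)), unname(network$lb), unname(network$ub),
                 as.integer(idx))
  if (any(res$status == 1)) stop("model is infeasible under the current bounds")
  if (any(res$status > 1))
    stop("FVA failed for reaction(s): ",
         paste(reactions[res$status > 1], collapse = ", "))
  lo <- pmax(res$ranges[, 1], network$lb[idx])
  hi <- pmin(res$ranges[, 2], network$ub[idx])
  bad <- lo > hi  # pure round-off: collapse to midpoint ordering
  if (any(bad)) { m <- (lo[bad] + hi[bad]) / 2; lo[bad] <- m; hi[bad] <- m }
  out <- data.frame(reaction = reactions, min = unname(lo), max = unname(hi),
                    stringsAsFactors = FALSE)
  class(out) <- c("feasible_range", "data.frame")
  out
}

#' Spot-relative flux bounds from RAS ratios
#'
#' Scales the global FVA range of each reaction by the spot's share of the
#' maximal activity score:
#' \deqn{U_j^s = F_j^u \cdot RAS_j^s / \max_s RAS_j^s, \qquad
#'       L_j^s = F_j^l \cdot RAS_j^s / \max_s RAS_j^s.}
#' Only ratios enter, so the scores' absolute scale is irrelevant. Reactions
#' with undefined RAS (no GPR, or nothing measurable) keep the full FVA range
#' in every spot, as do defined reactions whose score is zero everywhere
#' (a uniformly silent column carries no relative information). A spot with
#' zero score on an expressed reaction gets `(0, 0)`: the reaction is closed
#' there.
#'
#' @param ranges a `feasible_range` from [run_fva()].
#' @param ras a `ras_matrix` from [compute_ras_matrix()] on the same
#'   reaction universe.
#' @return an object of class `spot_bounds`: list with spot x reaction
#'   matrices `L` and `U`, plus `spots` and `reactions`.
#' @export
spot_bounds <- function(ranges, ras) {
  stopifnot(inherits(ranges, "feasible_range"), inherits(ras, "ras_matrix"))
  if (!all(ranges$reaction %in% ras$reactions))
    stop("ranges and RAS must share the reaction universe")
  rxns <- ranges$reaction
  spots <- ras$spots
  Fl <- stats::setNames(ranges$min, rxns)
  Fu <- stats::setNames(ranges$max, rxns)
  L <- matrix(rep(Fl, each = length(spots)), length(spots), length(rxns),
              dimnames = list(spots, rxns))
  U <- matrix(rep(Fu, each = length(spots)), length(spots), length(rxns),
              dimnames = list(spots, rxns))
  for (rid in rxns[ras$defined[rxns]]) {
    col <- ras$scores[, rid]
    if (any(col < 0, na.rm = TRUE)) stop("negative RAS for reaction ", rid)
    mx <- max(col)
    if (!is.finite(mx) || mx == 0) next  # no relative information
    ratio <- col / mx
    L[, rid] <- Fl[[rid]] * ratio
    U[, rid] <- Fu[[rid]] * ratio
  }
  out <- list(L = L, U = U, spots = spots, reactions = rxns)
  class(out) <- "spot_bounds"
  out
}
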