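#' Normalise a flux by the matching FVA extreme
#'
#' Maps a raw flux to a score in \eqn{[-1, 1]}: positive fluxes are divided
#' by \eqn{|F^u|}, negative fluxes by \eqn{|F^l|}, zero maps to zero. The
#' division is by the magnitude of the extreme, so the score always carries
#' the sign of the flux (a negative exchange flux — consumption — stays
#' negative). If the extreme of the matching sign is zero the flux lies
#' outside the feasible sign region (solver noise); the score is 0 with a
#' warning. Results are clipped to \eqn{[-1, 1]}.
#'
#' @param value numeric vector of raw fluxes.
#' @param fmin,fmax FVA extremes \eqn{F^l \le F^u}, recycled along `value`.
#' @return numeric vector of scores in `[-1, 1]`.
#' @export
normalize_flux <- function(value, fmin, fmax) {
  if (any(fmin > fmax)) stop("fmin must not exceed fmax")
  n <- length(value)
  fmin <- rep_len(fmin, n); fmax <- rep_len(fmax, n)
  # snap solver noise to zero before dispatching on sign
  value[abs(value) < 1e-9 * pmax(1, pmax(abs(fmin), abs(fmax)))] <- 0
  out <- numeric(n)
  pos <- value > 0; neg <- value < 0
  badp <- pos & fmax == 0
  badn <- neg & fmin == 0
  if (any(badp | badn))
    warning(sprintf("%d flux value(s) outside the feasible sign region set to 0",
                    sum(badp | badn)))
  ok <- pos & !badp
  out[ok] <- value[ok] / abs(fmax[ok])
  ok <- neg & !badn
  out[ok] <- value[ok] / abs(fmin[ok])
  pmin(pmax(out, -1), 1)
}

#' Flux enrichment scores from a CB3 sample set
#'
#' Collapses one spot's vertex samples into a per-reaction Flux Enrichment
#' Score: the centroid (mean of the sampled fluxes — itself a feasible flux
#' distribution, by convexity) normalised by the signed FVA extreme via
#' [normalize_flux()]. A confidence interval for the centroid is computed on
#' the raw flux scale (normal approximation of the mean,
#' `centroid +/- z * sd/sqrt(n)`; or bootstrap percentiles with
#' `ci_method = "bootstrap"`) and then normalised the same way; bounds are
#' ordered so `ci_low <= fes <= ci_high`.
#'
#' @param samples a `flux_sample_set` from [sample_cb3()] with >= 2
#'   successful samples.
#' @param ranges the [run_fva()] result.
#' @param ci_level confidence level (default 0.99).
#' @param ci_method `"normal"` (default) or `"bootstrap"`.
#' @param boot_n bootstrap replicates when `ci_method = "bootstrap"`.
#' @return list with named vectors `fes`, `ci_low`, `ci_high`, plus
#'   `provenance = "cb3"` and `n_samples`.
#' @export
compute_fes <- function(samples, ranges, ci_level = 0.99,
                        ci_method = c("normal", "bootstrap"), boot_n = 500) {
  stopifnot(inherits(samples, "flux_sample_set"))
  ci_method <- match.arg(ci_method)
  X <- samples$samples
  n <- nrow(X)
  if (n < 2) stop("need at least 2 successful samples to compute a FES")
  rxns <- colnames(X)
  stopifnot(identical(ranges$reaction, rxns))
  centroid <- colMeans(X)
  if (ci_method == "normal") {
    se <- apply(X, 2, stats::sd) / sqrt(n)
    z <- stats::qnorm((1 + ci_level) / 2)
    lo_raw <- centroid - z * se
    hi_raw <- centroid + z * se
  } else {
    qs <- apply(replicate(boot_n, colMeans(X[sample.int(n, n, replace = TRUE), , drop = FALSE])),
                1, stats::quantile, probs = c((1 - ci_level) / 2, (1 + ci_level) / 2))
    lo_raw <- qs[1, ]; hi_raw <- qs[2, ]
  }
  fes <- normalize_flux(centroid, ranges$min, ranges$max)
  lo <- normalize_flux(lo_raw, ranges$min, ranges$max)
  hi <- normalize_flux(hi_raw, ranges$min, ranges$max)
  ci_low <- pmin(lo, hi, fes)
  ci_high <- pmax(lo, hi, fes)
  list(fes = stats::setNames(fes, rxns),
       ci_low = stats::setNames(ci_low, rxns),
       ci_high = stats::setNames(ci_high, rxns),
       provenance = "cb3", n_samples = n)
}

#' Flux enrichment scores from a pFBA flux vector
#'
#' Applies the same [normalize_flux()] normalisation to the unique pFBA
#' solution; the "interval" is degenerate (`ci_low = fes = ci_high`).
#'
#' @param flux a `flux_vector` from [run_pfba()].
#' @param ranges the [run_fva()] result.
#' @return list like [compute_fes()] with `provenance = "pfba"`.
#' @export
fes_from_pfba <- function(flux, ranges) {
  stopifnot(inherits(flux, "flux_vector"))
  rxns <- names(flux$flux)
  stopifnot(identical(ranges$reaction, rxns))
  fes <- stats::setNames(normalize_flux(flux$flux, ranges$min, ranges$max), rxns)
  list(fes = fes, ci_low = fes, ci_high = fes,
       provenance = "pfba", n_samples = 1L)
}

# Assemble per-spot FES rows into a spot x reaction matrix object.
fes_matrix <- function(rows, spots, provenance) {
  rxns <- names(rows[[1]]$fes)
  mk <- function(field) {
    m <- do.call(rbind, lapply(rows, `[[`, field))
    dimnames(m) <- list(spots, rxns)
    m
  }
  out <- list(scores = mk("fes"), ci_low = mk("ci_low"), ci_high = mk("ci_high"),
              provenance = provenance,
              n_samples = vapply(rows, `[[`, numeric(1), "n_samples"),
              spots = spots, reactions = rxns)
  class(out) <- "fes_matrix"
  out
}

#' @export
print.fes_matrix <- function(x, ...) {
  cat(sprintf("fes_matrix [%s]: %d spots x %d reactions, scores in [%.3f, %.3f]\n",
              x$provenance, length(x$spots), length(x$reactions),
              min(x$scores), max(x$scores)))
  invisible(x)
}
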