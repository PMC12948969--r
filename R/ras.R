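#' Reaction activity scores from GPR evaluation
#'
#' Evaluates every reaction's GPR rule on the chosen expression layer,
#' producing a spot x reaction matrix of non-negative activity scores
#' (AND -> min over genes, OR -> sum; see [evaluate_gpr()]). Reactions
#' without a GPR, or whose genes are entirely absent from the expression
#' matrix, are *undefined* (`NA` columns with `defined = FALSE`) — a state
#' deliberately distinct from a zero score, because downstream constraint
#' building leaves undefined reactions unconstrained while a zero score
#' blocks the reaction in that spot.
#'
#' Model genes that are measured enter the rule with their expression value;
#' unmeasured genes are pruned from the rule (an OR loses a summand, an AND
#' loses an argument) rather than being treated as zero, which would block
#' every complex containing an unmeasured gene on a technicality. Pruned
#' reactions are reported via the `partial` field.
#'
#' @param expr an [expression_matrix()] with a normalized (and optionally
#'   imputed) layer.
#' @param network a [metabolic_network()] with a nonempty GPR map.
#' @param layer `"auto"` (imputed if present, else lognorm), `"lognorm"` or
#'   `"imputed"`.
#' @param alias optional named character vector mapping model gene ids to
#'   expression-matrix gene ids, for transcriptomes in a different identifier
#'   namespace.
#' @return an object of class `ras_matrix`: list with `scores` (spot x
#'   reaction matrix, `NA` columns where undefined), `defined` (named
#'   logical), `partial` (reactions evaluated with pruned genes), `spots`,
#'   `reactions`.
#' @export
compute_ras_matrix <- function(expr, network, layer = "auto", alias = NULL) {
  stopifnot(inherits(expr, "st_expression"), inherits(network, "metabolic_network"))
  if (length(network$gpr) == 0) stop("network has no GPR rules")
  X <- get_layer(expr, layer)
  gene_ids <- colnames(X)
  if (!is.null(alias)) {
    hit <- alias[names(alias) %in% network$genes & alias %in% gene_ids]
    gene_ids[match(hit, gene_ids)] <- names(hit)
  }
  measured <- intersect(network$genes, gene_ids)
  if (length(measured) == 0)
    stop("no model gene found in the expression matrix; check the gene id namespace (an alias table may be needed)")
  cols <- lapply(measured, function(g) as.numeric(X[, match(g, gene_ids)]))
  names(cols) <- measured

  nspot <- nrow(X)
  scores <- matrix(NA_real_, nspot, length(network$rxns),
                   dimnames = list(rownames(X), network$rxns))
  defined <- stats::setNames(rep(FALSE, length(network$rxns)), network$rxns)
  partial <- character(0)
  for (rid in names(network$gpr)) {
    rule <- network$gpr[[rid]]
    v <- gpr_evaluate_columns(rule, cols)
    if (is.null(v)) next
    scores[, rid] <- v
    defined[rid] <- TRUE
    if (!all(gpr_genes(rule) %in% measured)) partial <- c(partial, rid)
  }
  if (length(partial))
    message(sprintf("RAS: %d reaction(s) evaluated with unmeasured genes pruned from their GPR", length(partial)))
  out <- list(scores = scores, defined = defined, partial = partial,
              spots = rownames(X), reactions = network$rxns)
  class(out) <- "ras_matrix"
  out
}

#' @export
print.ras_matrix <- function(x, ...) {
  cat(sprintf("ras_matrix: %d spots x %d reactions (%d defined, %d undefined)\n",
              length(x$spots), length(x$reactions), sum(x$defined), sum(!x$defined)))
  invisible(x)
}
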