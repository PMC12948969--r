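#' Construct a constraint-based metabolic network
#'
#' Container for the stoichiometric model used by every downstream stage:
#' sparse stoichiometric matrix `S` (metabolites x reactions), default flux
#' bounds, GPR rules, exchange-reaction set and the biomass pseudo-reaction.
#'
#' @param mets character vector of metabolite ids (length m).
#' @param rxns character vector of reaction ids (length r).
#' @param S stoichiometric matrix, m x r, coercible to `dgCMatrix`.
#' @param lb,ub numeric default lower/upper flux bounds, length r, `lb <= ub`,
#'   finite.
#' @param gpr named list of `gpr_rule` trees (or rule strings, parsed on the
#'   fly); names must be reaction ids. Reactions without a GPR are simply
#'   absent from this map.
#' @param exchanges character vector of exchange (boundary) reaction ids.
#' @param biomass id of the biomass pseudo-reaction, or `NA`.
#' @param reversible logical length r; defaults to `lb < 0`.
#' @param subsystem optional named character vector, reaction id -> subsystem.
#' @param met_elements optional named numeric vector of per-metabolite carbon
#'   counts used by mass-balance checks on toy models.
#' @return an object of class `metabolic_network`.
#' @export
metabolic_network <- function(mets, rxns, S, lb, ub, gpr = list(),
                              exchanges = character(0), biomass = NA_character_,
                              reversible = NULL, subsystem = NULL,
                              met_elements = NULL) {
  S <- as(as(Matrix::Matrix(S, sparse = TRUE), "generalMatrix"), "CsparseMatrix")
  m <- length(mets); r <- length(rxns)
  if (nrow(S) != m || ncol(S) != r)
    stop("S must be length(mets) x length(rxns)")
  if (anyDuplicated(mets) || anyDuplicated(rxns))
    stop("metabolite and reaction ids must be unique")
  if (length(lb) != r || length(ub) != r)
    stop("bounds must have one entry per reaction")
  if (any(!is.finite(lb)) || any(!is.finite(ub)))
    stop("all default bounds must be finite")
  if (any(lb > ub)) stop("lower bounds must not exceed upper bounds")
  gpr <- lapply(gpr, function(g) if (is.character(g)) parse_gpr(g) else g)
  if (length(gpr) && !all(names(gpr) %in% rxns))
    stop("GPR map keys must be reaction ids")
  if (!all(exchanges %in% rxns)) stop("exchange ids must be reaction ids")
  if (!is.na(biomass) && !(biomass %in% rxns))
    stop("biomass id not found among reaction ids")
  if (is.null(reversible)) reversible <- lb < 0
  # structural sanity: non-exchange, non-biomass columns must touch >= 1 metabolite
  nz <- Matrix::colSums(S != 0)
  pseudo <- rxns %in% c(exchanges, biomass)
  if (any(nz == 0 & !pseudo))
    stop("empty stoichiometric column(s): ", paste(rxns[nz == 0 & !pseudo], collapse = ", "))
  dimnames(S) <- list(mets, rxns)
  net <- list(mets = mets, rxns = rxns, S = S,
              lb = stats::setNames(as.numeric(lb), rxns),
              ub = stats::setNames(as.numeric(ub), rxns),
              gpr = gpr, exchanges = exchanges, biomass = biomass,
              reversible = stats::setNames(as.logical(reversible), rxns),
              subsystem = subsystem, met_elements = met_elements,
              genes = unique(unlist(lapply(gpr, gpr_genes), use.names = FALSE)))
  class(net) <- "metabolic_network"
  net
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat(sprintf("metabolic_network: %d metabolites, %d reactions, %d genes, %d GPR-bearing reactions\n",
              length(x$mets), length(x$rxns), length(x$genes), length(x$gpr)))
  cat(sprintf("  exchanges: %d; biomass: %s\n", length(x$exchanges),
              ifelse(is.na(x$biomass), "<none>", x$biomass)))
  invisible(x)
}

sbml_ns <- c(
  l3 = "http://www.sbml.org/sbml/level3/version1/core",
  l2 = "http://www.sbml.org/sbml/level2",
  fbc = "http://www.sbml.org/sbml/level3/version1/fbc/version2"
)

#' Load a metabolic model from SBML
#'
#' Reads SBML Level 3 with fbc-v2 flux bounds and gene-product associations
#' (the format of current genome-scale and core reconstructions), or SBML
#' Level 2 with `LOWER_BOUND`/`UPPER_BOUND` kinetic-law parameters and
#' `GENE_ASSOCIATION:` notes. Exchange reactions are recognised as reactions
#' with reactants only or products only (after dropping boundary-condition
#' species); the biomass reaction is taken from the active fbc objective
#' when present, otherwise from an id/name match on "biomass".
#'
#' @param path path to an SBML `.xml` file.
#' @param gene_id one of `"label"` (default, use the fbc gene-product label,
#'   typically the gene symbol) or `"id"` (use the raw fbc id).
#' @return a [metabolic_network()].
#' @export
load_model <- function(path, gene_id = c("label", "id")) {
  gene_id <- match.arg(gene_id)
  if (!file.exists(path)) stop("cannot read SBML file: ", path)
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stop("cannot parse SBML file '", path, "': ", conditionMessage(e)))
  root <- xml2::xml_ns_strip(xml2::read_xml(path))  # strip ns for core elements
  model <- xml2::xml_find_first(root, ".//model")
  if (is.na(xml2::xml_name(model))) stop("no <model> element in ", path)

  sp_nodes <- xml2::xml_find_all(model, ".//listOfSpecies/species")
  sp_id <- xml2::xml_attr(sp_nodes, "id")
  sp_boundary <- xml2::xml_attr(sp_nodes, "boundaryCondition") %in% "true"
  keep_sp <- !sp_boundary
  mets <- sp_id[keep_sp]

  # fbc gene products: id -> chosen identifier (local-name() because fbc
  # elements keep their prefix after namespace stripping)
  gp_nodes <- xml2::xml_find_all(
    model, ".//*[local-name()='listOfGeneProducts']/*[local-name()='geneProduct']")
  gp_id <- xml2::xml_attr(gp_nodes, "id")
  gp_label <- xml2::xml_attr(gp_nodes, "label")
  gp_map <- stats::setNames(
    if (gene_id == "label") ifelse(is.na(gp_label), gp_id, gp_label) else gp_id,
    gp_id)

  # global parameters (fbc bound values)
  par_nodes <- xml2::xml_find_all(model, ".//listOfParameters/parameter")
  par_val <- stats::setNames(as.numeric(xml2::xml_attr(par_nodes, "value")),
                             xml2::xml_attr(par_nodes, "id"))

  rx_nodes <- xml2::xml_find_all(model, ".//listOfReactions/reaction")
  if (length(rx_nodes) == 0) stop("no reactions in ", path)
  rxns <- xml2::xml_attr(rx_nodes, "id")
  rev_attr <- xml2::xml_attr(rx_nodes, "reversible")
  reversible <- is.na(rev_attr) | rev_attr == "true"

  ii <- integer(0); jj <- integer(0); vv <- numeric(0)
  lb <- numeric(length(rxns)); ub <- numeric(length(rxns))
  gpr <- list(); exchanges <- character(0); subsystem <- character(0)
  met_index <- stats::setNames(seq_along(mets), mets)

  for (k in seq_along(rx_nodes)) {
    rn <- rx_nodes[[k]]
    add_side <- function(xpath, sign) {
      refs <- xml2::xml_find_all(rn, xpath)
      sp <- xml2::xml_attr(refs, "species")
      st <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
      st[is.na(st)] <- 1
      keep <- sp %in% mets
      if (any(keep)) {
        ii <<- c(ii, met_index[sp[keep]])
        jj <<- c(jj, rep.int(k, sum(keep)))
        vv <<- c(vv, sign * st[keep])
      }
      sum(keep)
    }
    nreac <- add_side("./listOfReactants/speciesReference", -1)
    nprod <- add_side("./listOfProducts/speciesReference", +1)
    if (nreac == 0L || nprod == 0L) exchanges <- c(exchanges, rxns[k])

    # bounds: fbc attributes, else kineticLaw parameters (Level 2)
    lbp <- xml2::xml_attr(rn, "lowerFluxBound")
    ubp <- xml2::xml_attr(rn, "upperFluxBound")
    if (!is.na(lbp) && !is.na(ubp)) {
      if (!(lbp %in% names(par_val)) || !(ubp %in% names(par_val)))
        stop("reaction ", rxns[k], ": flux-bound parameter not found")
      lb[k] <- par_val[[lbp]]; ub[k] <- par_val[[ubp]]
    } else {
      kl <- xml2::xml_find_all(rn, ".//kineticLaw//parameter")
      kid <- xml2::xml_attr(kl, "id")
      kval <- as.numeric(xml2::xml_attr(kl, "value"))
      lo <- kval[kid == "LOWER_BOUND"]; hi <- kval[kid == "UPPER_BOUND"]
      if (length(lo) != 1 || length(hi) != 1 || is.na(lo) || is.na(hi))
        stop("reaction ", rxns[k], ": no flux bounds found (fbc or kineticLaw)")
      lb[k] <- lo; ub[k] <- hi
    }

    # GPR: fbc association tree, else GENE_ASSOCIATION note
    assoc <- xml2::xml_find_first(rn, "./*[local-name()='geneProductAssociation']")
    rule <- NULL
    if (!is.na(xml2::xml_name(assoc))) {
      rule <- sbml_assoc_tree(xml2::xml_child(assoc), gp_map, rxns[k])
    } else {
      notes <- xml2::xml_text(xml2::xml_find_first(rn, "./notes"))
      if (!is.na(notes)) {
        ga <- regmatches(notes, regexpr("GENE_ASSOCIATION:[^\n<]*", notes))
        if (length(ga) == 1) {
          txt <- trimws(sub("GENE_ASSOCIATION:", "", ga))
          if (nzchar(txt))
            rule <- tryCatch(parse_gpr(txt), error = function(e)
              stop("reaction ", rxns[k], ": malformed GPR: ", conditionMessage(e)))
        }
      }
    }
    if (!is.null(rule)) gpr[[rxns[k]]] <- rule
  }

  # biomass: active fbc objective, else name match
  biomass <- NA_character_
  obj <- xml2::xml_find_first(model, ".//*[local-name()='fluxObjective']")
  if (!is.na(xml2::xml_name(obj))) {
    cand <- xml2::xml_attr(obj, "reaction")
    if (!is.na(cand) && cand %in% rxns) biomass <- cand
  }
  if (is.na(biomass)) {
    hit <- grep("biomass", rxns, ignore.case = TRUE, value = TRUE)
    if (length(hit)) biomass <- hit[[1]]
  }

  # boundary pseudo-reactions are one-sided; among them, medium exchanges
  # follow the EX_ naming convention where the model uses it (demand/sink
  # and biomass columns are one-sided too but are not exchanges)
  exchanges <- setdiff(exchanges, biomass)
  ex_named <- exchanges[startsWith(exchanges, "EX_")]
  if (length(ex_named)) exchanges <- ex_named

  # clamp infinite bounds from the file is NOT done: spec requires explicit
  # bounds; INF here means the file declared them so, reject for the LP core
  if (any(!is.finite(lb)) || any(!is.finite(ub)))
    stop("model declares non-finite flux bounds; spfba requires finite bounds")

  S <- Matrix::sparseMatrix(i = ii, j = jj, x = vv,
                            dims = c(length(mets), length(rxns)))
  metabolic_network(mets, rxns, S, lb, ub, gpr = gpr, exchanges = exchanges,
                    biomass = biomass, reversible = reversible)
}

# fbc:geneProductAssociation subtree -> gpr_rule
sbml_assoc_tree <- function(node, gp_map, rxn) {
  if (is.na(xml2::xml_name(node)))
    stop("reaction ", rxn, ": empty geneProductAssociation")
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    ref <- xml2::xml_attr(node, "geneProduct")
    g <- if (ref %in% names(gp_map)) gp_map[[ref]] else ref
    return(structure(list(op = "gene", gene = g), class = "gpr_rule"))
  }
  if (nm %in% c("and", "or")) {
    kids <- xml2::xml_children(node)
    args <- lapply(seq_along(kids), function(i)
      unclass(sbml_assoc_tree(kids[[i]], gp_map, rxn)))
    if (length(args) == 0) stop("reaction ", rxn, ": empty ", nm, " in GPR")
    return(structure(gpr_node(nm, args), class = "gpr_rule"))
  }
  stop("reaction ", rxn, ": malformed GPR element <", nm, ">")
}

#' Write a metabolic network as SBML Level 3 + fbc v2
#'
#' Round-trip companion of [load_model()]; used by the synthetic-data
#' generator to export the toy model.
#'
#' @param network a [metabolic_network()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(network, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  genes <- network$genes
  bnd_vals <- sort(unique(c(network$lb, network$ub)))
  bid <- function(v) sprintf("bnd_%d", match(v, bnd_vals))

  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w('<?xml version="1.0" encoding="UTF-8"?>')
  w('<sbml xmlns="', sbml_ns[["l3"]], '" xmlns:fbc="', sbml_ns[["fbc"]],
    '" level="3" version="1" fbc:required="false">')
  w('  <model id="model" fbc:strict="true">')
  w('    <listOfParameters>')
  for (v in bnd_vals)
    w('      <parameter id="', bid(v), '" value="',
      format(v, digits = 17, scientific = FALSE, trim = TRUE),
      '" constant="true"/>')
  w('    </listOfParameters>')
  w('    <listOfCompartments><compartment id="c" constant="true"/></listOfCompartments>')
  w('    <listOfSpecies>')
  for (mm in network$mets)
    w('      <species id="', esc(mm), '" compartment="c" hasOnlySubstanceUnits="false"',
      ' boundaryCondition="false" constant="false"/>')
  w('    </listOfSpecies>')
  if (length(genes)) {
    w('    <fbc:listOfGeneProducts>')
    for (g in genes)
      w('      <fbc:geneProduct fbc:id="G_', esc(gsub("[^A-Za-z0-9_]", "_", g)),
        '" fbc:label="', esc(g), '"/>')
    w('    </fbc:listOfGeneProducts>')
  }
  gid <- function(g) paste0("G_", gsub("[^A-Za-z0-9_]", "_", g))
  assoc_xml <- function(node, ind) {
    pad <- strrep(" ", ind)
    if (node$op == "gene")
      return(paste0(pad, '<fbc:geneProductRef fbc:geneProduct="', gid(node$gene), '"/>'))
    inner <- vapply(node$args, assoc_xml, character(1), ind = ind + 2)
    paste0(pad, "<fbc:", node$op, ">\n", paste(inner, collapse = "\n"),
           "\n", pad, "</fbc:", node$op, ">")
  }
  w('    <listOfReactions>')
  for (k in seq_along(network$rxns)) {
    rid <- network$rxns[k]
    col <- network$S[, k]
    nzi <- which(col != 0)
    w('      <reaction id="', esc(rid), '" reversible="',
      tolower(network$reversible[[rid]]), '" fast="false" fbc:lowerFluxBound="',
      bid(network$lb[[rid]]), '" fbc:upperFluxBound="', bid(network$ub[[rid]]), '">')
    reac <- nzi[col[nzi] < 0]; prod <- nzi[col[nzi] > 0]
    if (length(reac)) {
      w('        <listOfReactants>')
      for (i in reac)
        w('          <speciesReference species="', esc(network$mets[i]),
          '" stoichiometry="', format(-col[i], digits = 17), '" constant="true"/>')
      w('        </listOfReactants>')
    }
    if (length(prod)) {
      w('        <listOfProducts>')
      for (i in prod)
        w('          <speciesReference species="', esc(network$mets[i]),
          '" stoichiometry="', format(col[i], digits = 17), '" constant="true"/>')
      w('        </listOfProducts>')
    }
    if (rid %in% names(network$gpr)) {
      w('        <fbc:geneProductAssociation>')
      w(assoc_xml(unclass(network$gpr[[rid]]), 10))
      w('        </fbc:geneProductAssociation>')
    }
    w('      </reaction>')
  }
  w('    </listOfReactions>')
  if (!is.na(network$biomass)) {
    w('    <fbc:listOfObjectives fbc:activeObjective="obj">')
    w('      <fbc:objective fbc:id="obj" fbc:type="maximize">')
    w('        <fbc:listOfFluxObjectives>')
    w('          <fbc:fluxObjective fbc:reaction="', esc(network$biomass),
      '" fbc:coefficient="1"/>')
    w('        </fbc:listOfFluxObjectives>')
    w('      </fbc:objective>')
    w('    </fbc:listOfObjectives>')
  }
  w('  </model>')
  w('</sbml>')
  invisible(path)
}

#' Open-medium boundary configuration
#'
#' Makes every exogenous metabolite abundantly available by widening the
#' exchange-reaction bounds to the stated magnitude. Reversible exchanges
#' get `(-bound, +bound)`; exchanges the model curates as irreversible keep
#' their blocked direction and only the permitted one is widened. Intake
#' flux is negative by convention (metabolite consumption), secretion
#' positive. Internal reaction bounds are untouched. Idempotent for a fixed
#' `bound`.
#'
#' @param network a [metabolic_network()].
#' @param bound positive magnitude of availability; 1000 mimics an
#'   effectively unlimited rich medium at the scale of core models.
#' @return the modified network.
#' @export
apply_open_medium <- function(network, bound = 1000) {
  stopifnot(inherits(network, "metabolic_network"))
  if (!is.numeric(bound) || length(bound) != 1 || !is.finite(bound) || bound <= 0)
    stop("bound must be a positive finite number")
  if (length(network$exchanges) == 0)
    stop("network has no exchange reactions")
  for (rid in network$exchanges) {
    rev <- network$reversible[[rid]]
    if (!rev && network$ub[[rid]] <= 0) {      # irreversible uptake-only
      network$lb[[rid]] <- -bound
    } else if (!rev && network$lb[[rid]] >= 0) {  # irreversible secretion-only
      network$ub[[rid]] <- bound
    } else {
      network$lb[[rid]] <- -bound
      network$ub[[rid]] <- bound
    }
  }
  network
}
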