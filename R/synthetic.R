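#' Toy central-carbon metabolic network
#'
#' A 21-reaction miniature of the glucose/lactate/glutamine/oxygen core of
#' central carbon metabolism, built for end-to-end testing of the spatial
#' flux pipeline without external model files. It contains glucose exchange
#' and uptake, a lumped glycolysis to pyruvate (GPR-bearing), lactate
#' dehydrogenase and a reversible lactate exchange, mitochondrial pyruvate
#' transport, PDH, a lumped TCA cycle, oxygen exchange plus an
#' ATP-producing respiration lump, glutamine/glutamate exchanges, an ATP
#' maintenance drain, and a biomass pseudo-reaction (no GPR) consuming ATP
#' and glutamate (growth is precursor-limited; the maintenance drain
#' dominates the ATP budget). Internal carbon-carrying reactions are carbon
#' balanced (per-metabolite carbon counts ship in `met_elements`); the
#' network admits both a pure-fermentation vertex (glucose in, lactate out,
#' no oxygen) and a pure-respiration vertex (glucose in, CO2 out, no
#' lactate), and blocking oxygen forces lactate secretion for any positive
#' biomass flux.
#'
#' Exchange fluxes are negative on uptake, positive on secretion. Default
#' bounds are pre-medium (glucose/oxygen/glutamine uptake capped at 10);
#' apply [apply_open_medium()] before flux calculations.
#'
#' @return a [metabolic_network()].
#' @export
make_toy_network <- function() {
  mets <- c("glc_e", "glc_c", "pyr_c", "pyr_m", "lac_c", "lac_e", "accoa_m",
            "co2_c", "co2_e", "o2_e", "o2_c", "nadh_m", "atp_c",
            "gln_e", "gln_c", "glu_c", "glu_e")
  carbon <- stats::setNames(
    c(6, 6, 3, 3, 3, 3, 2, 1, 1, 0, 0, 0, 0, 5, 5, 5, 5), mets)

  rx <- list(
    #            id        stoich (named),                          lb,    ub,   rev,  gpr
    list("EX_glc",  c(glc_e = -1),                                  -10,    0, FALSE, NA),
    list("EX_lac",  c(lac_e = -1),                                  -10,   10, TRUE,  NA),
    list("EX_o2",   c(o2_e = -1),                                   -10,    0, FALSE, NA),
    list("EX_co2",  c(co2_e = -1),                                    0,   10, FALSE, NA),
    list("EX_gln",  c(gln_e = -1),                                  -10,    0, FALSE, NA),
    list("EX_glu",  c(glu_e = -1),                                    0,   10, FALSE, NA),
    list("GLCt",    c(glc_e = -1, glc_c = 1),                          0, 1000, FALSE, "SLC2A1"),
    list("GLYC",    c(glc_c = -1, pyr_c = 2, atp_c = 2),               0, 1000, FALSE, "HK2 and PFKL and PKM"),
    list("LDH",     c(pyr_c = -1, lac_c = 1),                      -1000, 1000, TRUE,  "LDHA or LDHB"),
    list("LACt",    c(lac_c = -1, lac_e = 1),                      -1000, 1000, TRUE,  "SLC16A1 or SLC16A3"),
    list("PYRtm",   c(pyr_c = -1, pyr_m = 1),                          0, 1000, FALSE, "MPC1 and MPC2"),
    list("PDH",     c(pyr_m = -1, accoa_m = 1, co2_c = 1),             0, 1000, FALSE, "PDHA1 and PDHB"),
    list("TCA",     c(accoa_m = -1, co2_c = 2, nadh_m = 4),            0, 1000, FALSE, "CS and SDHA"),
    list("RESP",    c(nadh_m = -1, o2_c = -0.5, atp_c = 2.5),          0, 1000, FALSE, "NDUFS1 and COX4I1"),
    list("O2t",     c(o2_e = -1, o2_c = 1),                            0, 1000, FALSE, NA),
    list("CO2t",    c(co2_c = -1, co2_e = 1),                          0, 1000, FALSE, NA),
    list("GLNt",    c(gln_e = -1, gln_c = 1),                          0, 1000, FALSE, "SLC1A5"),
    list("GLS",     c(gln_c = -1, glu_c = 1),                          0, 1000, FALSE, "GLS"),
    list("GLUt",    c(glu_c = -1, glu_e = 1),                          0, 1000, FALSE, "SLC1A3"),
    list("ATPM",    c(atp_c = -1),                                     0, 3000, FALSE, NA),
    list("BIOMASS", c(atp_c = -0.5, glu_c = -1),                       0, 1000, FALSE, NA)
  )
  rxns <- vapply(rx, `[[`, character(1), 1)
  S <- matrix(0, length(mets), length(rxns), dimnames = list(mets, rxns))
  for (k in seq_along(rx)) S[names(rx[[k]][[2]]), k] <- rx[[k]][[2]]
  gpr <- lapply(rx, `[[`, 6)
  names(gpr) <- rxns
  gpr <- gpr[!is.na(gpr)]
  subsystem <- stats::setNames(c(
    rep("exchange", 6), "glycolysis", "glycolysis", "glycolysis", "glycolysis",
    "tca_oxphos", "tca_oxphos", "tca_oxphos", "tca_oxphos",
    "transport", "transport", "glutaminolysis", "glutaminolysis",
    "glutaminolysis", "maintenance", "biomass"), rxns)
  metabolic_network(
    mets, rxns, S,
    lb = vapply(rx, `[[`, numeric(1), 3),
    ub = vapply(rx, `[[`, numeric(1), 4),
    gpr = gpr,
    exchanges = rxns[startsWith(rxns, "EX_")],
    biomass = "BIOMASS",
    reversible = vapply(rx, `[[`, logical(1), 5),
    subsystem = subsystem,
    met_elements = carbon)
}

# Gene sets characterising the two pure metabolic regimes of the toy model.
# The fermentative (tumor) profile includes glutaminolysis: proliferating
# tumor cells are classically glutamine-addicted, and glutamate feeds the
# biomass pseudo-reaction.
toy_regime_genes <- function() {
  list(fermentative = c("SLC2A1", "HK2", "PFKL", "PKM", "LDHA", "LDHB",
                        "SLC16A1", "SLC16A3", "SLC1A5", "GLS"),
       oxidative = c("MPC1", "MPC2", "PDHA1", "PDHB", "CS", "SDHA",
                     "NDUFS1", "COX4I1"),
       pdh = c("PDHA1", "PDHB"))
}

#' Simulate spatially structured synthetic counts
#'
#' Generates a rectangular spot grid split into three contiguous vertical
#' bands — `tumor_core`, `tumor_interface`, `stroma` — each assigned a
#' metabolic regime. Per-gene baseline means are log-normal; in each region
#' the genes of the regime-characteristic reactions are scaled by `effect`
#' (fermentative: glycolysis + LDH + lactate transport up, PDH down;
#' oxidative: PDH + TCA + respiration up; hybrid: both sets scaled by
#' `sqrt(effect)`). Proliferation markers (MCM7, MCM3, PCNA, MKI67) are
#' enriched in the tumor core and vascular markers (PECAM1, ESAM, CD34,
#' TEK, VCAN, CDH5) in the stroma, so the built-in panels of
#' [marker_panels()] work on synthetic data unmodified. Counts are drawn
#' negative-binomially around the region-scaled means with per-spot
#' log-normal library-size factors, then thinned by Bernoulli dropout.
#' Regeneration with the same seed is bitwise identical.
#'
#' @param network the toy [make_toy_network()] (or any network whose GPR
#'   genes should be simulated).
#' @param grid `c(rows, cols)` spot grid (default `c(20, 20)`).
#' @param regimes named character vector region -> regime; the default maps
#'   tumor_core to fermentative, tumor_interface to hybrid, stroma to
#'   oxidative.
#' @param effect regime effect size (fold change on characteristic genes),
#'   must be >= 1; default 4.
#' @param dropout Bernoulli dropout probability in `[0, 1)`; default 0.3.
#' @param seed integer seed.
#' @param base_mean median baseline counts per gene before scaling
#'   (default 30, giving library sizes in the low thousands, the scale of
#'   real spot transcriptomes).
#' @param nb_size negative-binomial dispersion parameter (default 10).
#' @param n_housekeeping additional unstructured background genes
#'   (default 60).
#' @param n_program genes per region-identity program (default 40). Real
#'   annotated regions (tumor, interface, stroma) differ across broad
#'   transcriptional programs, not only metabolic genes; each region gets a
#'   dedicated gene set scaled by `effect` there, so expression-space
#'   neighbourhoods behave like real data.
#' @return an object of class `synthetic_dataset`: list with `network`,
#'   `expr` (an [expression_matrix()] whose annotation holds the
#'   ground-truth regions), `regions`, `regimes`, `params`.
#' @export
simulate_spatial_counts <- function(network, grid = c(20, 20),
                                    regimes = c(tumor_core = "fermentative",
                                                tumor_interface = "hybrid",
                                                stroma = "oxidative"),
                                    effect = 4, dropout = 0.3, seed = 0,
                                    base_mean = 30, nb_size = 10,
                                    n_housekeeping = 60, n_program = 40) {
  stopifnot(inherits(network, "metabolic_network"))
  if (effect < 1) stop("effect must be >= 1")
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  if (!all(c("tumor_core", "tumor_interface", "stroma") %in% names(regimes)))
    stop("regimes must cover tumor_core, tumor_interface and stroma")
  set.seed(seed)
  nr <- grid[1]; nc <- grid[2]
  coords <- expand.grid(x = seq_len(nc), y = seq_len(nr))
  spots <- sprintf("spot_%03d_%03d", coords$y, coords$x)
  # contiguous vertical bands
  c1 <- ceiling(nc / 3); c2 <- ceiling(2 * nc / 3)
  region <- ifelse(coords$x <= c1, "tumor_core",
                   ifelse(coords$x <= c2, "tumor_interface", "stroma"))
  names(region) <- spots

  markers <- marker_panels()
  programs <- list(tumor_core = sprintf("PRGT%02d", seq_len(n_program)),
                   tumor_interface = sprintf("PRGI%02d", seq_len(n_program)),
                   stroma = sprintf("PRGS%02d", seq_len(n_program)))
  genes <- c(network$genes, unlist(markers, use.names = FALSE),
             unlist(programs, use.names = FALSE),
             sprintf("HKG%02d", seq_len(n_housekeeping)))
  base <- stats::setNames(stats::rlnorm(length(genes), log(base_mean), 0.8), genes)

  sets <- toy_regime_genes()
  mult <- matrix(1, 3, length(genes),
                 dimnames = list(c("fermentative", "hybrid", "oxidative"), genes))
  mult["fermentative", intersect(sets$fermentative, genes)] <- effect
  mult["fermentative", intersect(sets$pdh, genes)] <- 1 / effect
  mult["oxidative", intersect(sets$oxidative, genes)] <- effect
  mult["hybrid", intersect(c(sets$fermentative, sets$oxidative), genes)] <- sqrt(effect)
  # markers: proliferation tracks the tumor core, vasculature the stroma
  pm <- intersect(markers$proliferation, genes)
  vm <- intersect(markers$vascularization, genes)
  marker_mult <- rbind(fermentative = stats::setNames(rep(1, length(genes)), genes),
                       hybrid = stats::setNames(rep(1, length(genes)), genes),
                       oxidative = stats::setNames(rep(1, length(genes)), genes))
  marker_mult["fermentative", pm] <- effect
  marker_mult["hybrid", pm] <- sqrt(effect)
  marker_mult["oxidative", vm] <- effect
  marker_mult["hybrid", vm] <- sqrt(effect)

  prog_mult <- matrix(1, 3, length(genes),
                      dimnames = list(names(programs), genes))
  for (rg in names(programs)) prog_mult[rg, programs[[rg]]] <- effect
  # tumor tissue shows globally enhanced metabolic transcription on top of
  # its regime-specific structure; sqrt(effect) keeps the regime signal
  # dominant while giving tumor regions the growth capacity real tumors show
  prog_mult["tumor_core", network$genes] <-
    prog_mult["tumor_core", network$genes] * sqrt(effect)
  prog_mult["tumor_interface", network$genes] <-
    prog_mult["tumor_interface", network$genes] * effect^0.25

  lib <- stats::rlnorm(length(spots), 0, 0.3)
  # per-spot growth-activity factor: proliferating spots coordinately
  # upregulate metabolic machinery and replication markers, coupling the
  # proliferation score to metabolic capacity within regions as well
  growth <- stats::rlnorm(length(spots), 0, 0.4)
  grown_genes <- c(network$genes, pm)
  counts <- matrix(0L, length(spots), length(genes), dimnames = list(spots, genes))
  for (s in seq_along(spots)) {
    rg <- region[s]
    regime <- regimes[[rg]]
    mu <- base * mult[regime, ] * marker_mult[regime, ] * prog_mult[rg, ] * lib[s]
    mu[grown_genes] <- mu[grown_genes] * growth[s]
    counts[s, ] <- stats::rnbinom(length(genes), size = nb_size, mu = mu)
  }
  if (dropout > 0) {
    keep <- matrix(stats::rbinom(length(counts), 1, 1 - dropout),
                   nrow(counts), ncol(counts))
    counts <- counts * keep
  }
  expr <- expression_matrix(counts, data.frame(spot = spots, x = coords$x, y = coords$y),
                            annotation = region)
  out <- list(network = network, expr = expr, regions = region,
              regimes = regimes,
              params = list(grid = grid, effect = effect, dropout = dropout,
                            seed = seed, base_mean = base_mean,
                            nb_size = nb_size, n_housekeeping = n_housekeeping,
                            n_program = n_program))
  class(out) <- "synthetic_dataset"
  out
}
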