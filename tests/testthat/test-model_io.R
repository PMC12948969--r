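test_that("GPR parsing honours precedence, parentheses and n-ary flattening", {
  t1 <- parse_gpr("g1 and g2 or g3")
  expect_equal(t1$op, "or")
  expect_equal(t1$args[[1]]$op, "and")
  expect_equal(vapply(t1$args[[1]]$args, `[[`, character(1), "gene"), c("g1", "g2"))
  expect_equal(t1$args[[2]]$gene, "g3")

  t2 <- parse_gpr("g1 and (g2 or g3)")
  expect_equal(t2$op, "and")
  expect_equal(t2$args[[1]]$gene, "g1")
  expect_equal(t2$args[[2]]$op, "or")

  # case-insensitive operators, case-preserving gene ids
  t3 <- parse_gpr("GeneA AND geneB Or gC")
  expect_equal(t3$op, "or")
  expect_equal(gpr_genes(t3), c("GeneA", "geneB", "gC"))

  # n-ary flattening
  t4 <- parse_gpr("a and b and c")
  expect_equal(t4$op, "and")
  expect_length(t4$args, 3)
})

test_that("malformed GPR strings give positioned parse errors", {
  expect_error(parse_gpr("(g1"), "unbalanced")
  expect_error(parse_gpr("g1 and"), "position")
  expect_error(parse_gpr("and g1"), "position")
  expect_error(parse_gpr(""), "non-empty")
  expect_error(parse_gpr("g1 or or g2"), "position")
})

test_that("serialise-then-parse is the identity on random GPR trees", {
  genes <- c("a1", "b2", "c3", "d4", "e5", "f6")
  set.seed(42)
  for (i in 1:40) {
    tr <- random_gpr_tree(depth = sample(1:5, 1), genes = genes)
    rt <- parse_gpr(gpr_to_string(tr))
    expect_equal(unclass(rt), unclass(tr))
  }
})

test_that("SBML write/load round-trips the toy network exactly", {
  net <- make_toy_network()
  path <- withr::local_tempfile(fileext = ".xml")
  write_model(net, path)
  net2 <- load_model(path)
  expect_equal(net2$mets, net$mets)
  expect_equal(net2$rxns, net$rxns)
  expect_equal(as.matrix(net2$S), as.matrix(net$S))
  expect_equal(net2$lb, net$lb)
  expect_equal(net2$ub, net$ub)
  expect_setequal(net2$exchanges, net$exchanges)
  expect_equal(net2$biomass, net$biomass)
  expect_equal(sort(names(net2$gpr)), sort(names(net$gpr)))
  for (rid in names(net$gpr))
    expect_equal(unclass(net2$gpr[[rid]]), unclass(net$gpr[[rid]]),
                 info = rid)
  # second round-trip is stable
  path2 <- withr::local_tempfile(fileext = ".xml")
  write_model(net2, path2)
  expect_equal(as.matrix(load_model(path2)$S), as.matrix(net$S))
})

test_that("a minimal one-reaction SBML file loads with the stated composition", {
  net <- metabolic_network(mets = c("A", "B"), rxns = "R1",
                           S = matrix(c(-1, 1), 2, 1),
                           lb = 0, ub = 10,
                           gpr = list(R1 = "g1"),
                           exchanges = character(0), biomass = NA)
  path <- withr::local_tempfile(fileext = ".xml")
  write_model(net, path)
  got <- load_model(path)
  expect_equal(length(got$rxns), 1L)
  expect_equal(length(got$mets), 2L)
  expect_length(got$gpr, 1L)
  expect_equal(gpr_to_string(got$gpr$R1), "g1")

  # nested GPR with explicit precedence
  net$gpr <- list(R1 = parse_gpr("(g1 and g2) or g3"))
  write_model(net, path)
  tr <- load_model(path)$gpr$R1
  expect_equal(tr$op, "or")
  expect_equal(tr$args[[1]]$op, "and")
})

test_that("SBML Level 2 models load via kineticLaw bounds and notes GPRs", {
  l2 <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level2" level="2" version="4">',
    '<model id="m"><listOfCompartments><compartment id="c"/></listOfCompartments>',
    '<listOfSpecies>',
    '<species id="A" compartment="c"/><species id="B" compartment="c"/>',
    '</listOfSpecies>',
    '<listOfReactions>',
    '<reaction id="R1" reversible="false">',
    '<notes><body xmlns="http://www.w3.org/1999/xhtml">',
    '<p>GENE_ASSOCIATION: gX and gY</p></body></notes>',
    '<listOfReactants><speciesReference species="A" stoichiometry="1"/></listOfReactants>',
    '<listOfProducts><speciesReference species="B" stoichiometry="2"/></listOfProducts>',
    '<kineticLaw><math/><listOfParameters>',
    '<parameter id="LOWER_BOUND" value="0"/><parameter id="UPPER_BOUND" value="25"/>',
    '</listOfParameters></kineticLaw>',
    '</reaction></listOfReactions></model></sbml>')
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(l2, path)
  net <- load_model(path)
  expect_equal(unname(net$lb), 0)
  expect_equal(unname(net$ub), 25)
  expect_equal(as.vector(net$S), c(-1, 2))
  expect_equal(gpr_to_string(net$gpr$R1), "gX and gY")
})

test_that("load errors are specific: missing file, missing bounds", {
  expect_error(load_model(file.path(tempdir(), "nope.xml")), "cannot read")
  broken <- c(
    '<?xml version="1.0"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level2" level="2" version="4">',
    '<model id="m"><listOfSpecies><species id="A" compartment="c"/></listOfSpecies>',
    '<listOfReactions><reaction id="R1">',
    '<listOfReactants><speciesReference species="A"/></listOfReactants>',
    '</reaction></listOfReactions></model></sbml>')
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(broken, path)
  expect_error(load_model(path), "bounds")
})

test_that("open medium widens exchanges per reversibility and leaves the rest", {
  net <- make_toy_network()
  open <- apply_open_medium(net, 1000)
  # irreversible uptake-only glucose: (-10, 0) -> (-1000, 0)
  expect_equal(unname(open$lb[["EX_glc"]]), -1000)
  expect_equal(unname(open$ub[["EX_glc"]]), 0)
  # reversible lactate exchange: full (-1000, 1000)
  expect_equal(unname(open$lb[["EX_lac"]]), -1000)
  expect_equal(unname(open$ub[["EX_lac"]]), 1000)
  # irreversible secretion-only CO2: (0, 1000)
  expect_equal(unname(open$lb[["EX_co2"]]), 0)
  expect_equal(unname(open$ub[["EX_co2"]]), 1000)
  # internal reactions untouched
  internals <- setdiff(net$rxns, net$exchanges)
  expect_equal(open$lb[internals], net$lb[internals])
  expect_equal(open$ub[internals], net$ub[internals])
  # idempotent
  open2 <- apply_open_medium(open, 1000)
  expect_identical(open2$lb, open$lb)
  expect_identical(open2$ub, open$ub)
  expect_error(apply_open_medium(net, 0), "positive")
  expect_error(apply_open_medium(net, -5), "positive")
})

test_that("network constructor enforces its invariants", {
  S <- matrix(c(-1, 1), 2, 1)
  expect_error(metabolic_network(c("A", "B"), "R", S, lb = 5, ub = 1),
               "lower bounds")
  expect_error(metabolic_network(c("A", "B"), "R", S, lb = -Inf, ub = 1),
               "finite")
  expect_error(metabolic_network(c("A", "B"), "R", S, lb = 0, ub = 1,
                                 biomass = "nope"), "biomass")
  expect_error(metabolic_network(c("A", "B"), "R", S, lb = 0, ub = 1,
                                 gpr = list(other = "g1")), "GPR map")
  # empty internal column rejected, empty exchange column allowed
  S0 <- matrix(0, 2, 1)
  expect_error(metabolic_network(c("A", "B"), "R", S0, lb = 0, ub = 1),
               "empty stoichiometric")
  expect_silent(metabolic_network(c("A", "B"), "R", S0, lb = 0, ub = 1,
                                  exchanges = "R"))
})
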