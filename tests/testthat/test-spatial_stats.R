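test_that("V-measure: perfect agreement, degenerate cases, oracle value, symmetry", {
  expect_equal(v_measure_compare(c(1, 1, 2, 2), c("a", "a", "b", "b")), 1)
  expect_equal(v_measure_compare(rep(1, 6), c(1, 1, 2, 2, 3, 3)), 0)
  a <- c("a", "a", "b", "b", "b", "c")
  r <- c(1, 1, 2, 2, 3, 3)
  expect_equal(v_measure_compare(a, r), oracle_v_measure(a, r), tolerance = 1e-12)
  # symmetry at beta = 1 and invariance under label renaming
  expect_equal(v_measure_compare(a, r), v_measure_compare(r, a))
  a2 <- c("z", "z", "q", "q", "q", "m")
  expect_equal(v_measure_compare(a2, r), v_measure_compare(a, r))
  set.seed(3)
  for (i in 1:10) {
    x <- sample(1:3, 30, replace = TRUE)
    y <- sample(1:4, 30, replace = TRUE)
    expect_equal(v_measure_compare(x, y), oracle_v_measure(x, y), tolerance = 1e-12)
    expect_equal(v_measure_compare(x, y), v_measure_compare(y, x), tolerance = 1e-12)
  }
  expect_error(v_measure_compare(1:3, 1:4), "same spots")
})

test_that("layer comparison is a one-sided Mann-Whitney with the tie convention", {
  # complete separation, untied: exact one-sided p = 1/choose(6,3)
  out <- compare_layers(c(0.9, 0.92, 0.91), c(0.1, 0.12, 0.11))
  expect_equal(out$p_value, 1 / choose(6, 3), tolerance = 1e-9)
  expect_false(out$flagged)
  # within-group ties fall back to the normal approximation, still < 0.05
  expect_lt(compare_layers(c(0.9, 0.9, 0.9), c(0.1, 0.1, 0.1))$p_value, 0.05)
  same <- compare_layers(c(0.3, 0.5, 0.4), c(0.3, 0.5, 0.4))
  expect_gte(same$p_value, 0.5)
  tied <- compare_layers(rep(0.4, 3), rep(0.4, 4))
  expect_equal(tied$p_value, 0.5)
  expect_true(tied$flagged)
  expect_error(compare_layers(c(1, 2), c(1, 2, 3)), "at least 3")
})

test_that("region contrast: percent variation, Welch test, stars, antisymmetry", {
  set.seed(21)
  vals <- c(rnorm(50, 2, 0.1), rnorm(50, 1, 0.1))
  grp <- rep(c("A", "B"), each = 50)
  rc <- region_contrast(vals, grp, "A", "B")
  expect_equal(rc$percent_variation, 100 * (mean(vals[1:50]) - mean(vals[51:100])) /
                 abs(mean(vals[51:100])))
  expect_lt(abs(rc$percent_variation - 100), 10)
  expect_equal(rc$stars, "***")

  ident <- region_contrast(c(1, 2, 3, 1, 2, 3), rep(c("A", "B"), each = 3), "A", "B")
  expect_equal(ident$percent_variation, 0)
  expect_gt(ident$p_value, 0.9)

  # swapping groups: x -> -x / (1 + x/100) * 100
  fwd <- region_contrast(vals, grp, "A", "B")$percent_variation
  rev <- region_contrast(vals, grp, "B", "A")$percent_variation
  expect_equal(rev, -fwd / (1 + fwd / 100), tolerance = 1e-9)

  # power: 2-sigma shift at n = 100/group is highly significant across seeds
  for (s in 1:3) {
    set.seed(s)
    x <- c(rnorm(100, 0, 1), rnorm(100, 2, 1))
    expect_lt(region_contrast(x, rep(c("A", "B"), each = 100), "A", "B")$p_value,
              0.001)
  }
  expect_error(region_contrast(c(1, 2), c("A", "B"), "A", "B"), "at least 2")
})

test_that("differential maps classify by KS significance AND fold-change threshold", {
  set.seed(6)
  n <- 40
  groups <- rep(c("A", "B"), each = n)
  mat <- cbind(
    same  = rnorm(2 * n, 1, 0.2),
    up_a  = c(rnorm(n, 2, 0.2), rnorm(n, 1, 0.2)),
    up_b  = c(rnorm(n, 0.5, 0.1), rnorm(n, 1.5, 0.1)),
    small = c(rnorm(n, 1.00, 0.001), rnorm(n, 1.02, 0.001)),  # significant, tiny FC
    zero  = rep(0, 2 * n))
  rownames(mat) <- sprintf("s%02d", seq_len(2 * n))
  dm <- differential_map(mat, groups, "A", "B")
  cls <- setNames(dm$class, dm$reaction)
  expect_equal(unname(cls["same"]), "not_significant")
  expect_equal(unname(cls["up_a"]), "up_in_A")
  expect_equal(unname(cls["up_b"]), "up_in_B")
  # p < alpha but |FC| < 5%: direction must NOT be called
  expect_lt(dm$p_value[dm$reaction == "small"], 0.05)
  expect_equal(unname(cls["small"]), "not_significant")
  expect_equal(unname(cls["zero"]), "not_significant")

  # disjoint support: KS statistic 1, minimal attainable p
  dj <- differential_map(cbind(r = c(rep(0, n), rep(10, n)) + runif(2 * n, 0, 0.1)),
                         groups, "A", "B")
  expect_lt(dj$p_value, 1e-10)
  expect_equal(dj$class, "up_in_B")

  # spot-order permutation stability
  perm <- sample(2 * n)
  dmp <- differential_map(mat[perm, ], groups[perm], "A", "B")
  expect_equal(dmp[order(dmp$reaction), ], dm[order(dm$reaction), ],
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("concordance counts sign agreement among doubly-passing reactions", {
  d1 <- data.frame(reaction = c("r1", "r2", "r3", "r4"),
                   p_value = c(0.001, 0.001, 0.2, 0.001),
                   fold_change = c(0.5, -0.5, 0.9, 0.1))
  # identical layers: 100%
  expect_equal(as.numeric(concordance(d1, d1)), 100)
  # opposite signs everywhere: 0%
  d2 <- d1; d2$fold_change <- -d2$fold_change
  expect_equal(as.numeric(concordance(d1, d2)), 0)
  # r3 fails alpha, r4 fails FC: only r1, r2 count
  expect_equal(attr(concordance(d1, d1), "n"), 2L)
  # empty passing set: undefined
  d3 <- d1; d3$p_value <- 0.9
  expect_message(out <- concordance(d1, d3), "undefined")
  expect_true(is.na(out))
  # mixed agreement stays inside [0, 100]
  d4 <- d1; d4$fold_change[1] <- -0.4
  val <- as.numeric(concordance(d1, d4))
  expect_gte(val, 0); expect_lte(val, 100)
})

test_that("marker scores average the present panel genes", {
  counts <- rbind(s1 = c(MCM7 = 1, MCM3 = 2, PCNA = 3, MKI67 = 4, other = 9),
                  s2 = c(MCM7 = 0, MCM3 = 0, PCNA = 0, MKI67 = 0, other = 9))
  e <- normalize_counts(toy_expression(counts))
  e$layers$lognorm <- Matrix::Matrix(counts, sparse = FALSE)
  sc <- marker_score(e, "proliferation")
  expect_equal(unname(sc), c(2.5, 0))
  # missing genes shrink the denominator
  e2 <- e
  e2$layers$lognorm <- e$layers$lognorm[, c("MCM7", "MCM3", "other")]
  expect_message(sc2 <- marker_score(e2, "proliferation"), "2/4")
  expect_equal(unname(sc2[["s1"]]), 1.5)
  expect_error(marker_score(e2, c("NOPE1", "NOPE2")), "no panel gene")
  expect_setequal(marker_panels()$proliferation, c("MCM7", "MCM3", "PCNA", "MKI67"))
  expect_setequal(marker_panels()$vascularization,
                  c("PECAM1", "ESAM", "CD34", "TEK", "VCAN", "CDH5"))
})

test_that("Spearman correlation with Fisher-z CI behaves on known inputs", {
  expect_equal(score_correlation(1:20, 1:20)$rho, 1)
  expect_equal(score_correlation(1:20, 20:1)$rho, -1)
  const <- score_correlation(rep(1, 20), 1:20)
  expect_false(const$defined)
  expect_error(score_correlation(1:5, 1:5), "at least 10")

  # bivariate normal with known rank correlation ~ 0.5
  for (s in 1:3) {
    set.seed(s)
    r_pearson <- 2 * sin(0.5 * pi / 6) / 1  # Pearson giving Spearman 0.5
    r <- 2 * sin(0.5 * pi / 6)
    x <- rnorm(200)
    y <- r * x + sqrt(1 - r^2) * rnorm(200)
    est <- score_correlation(x, y)
    expect_true(est$ci[1] <= 0.5 && est$ci[2] >= 0.5 - 0.1)
    expect_lt(abs(est$rho - 0.5), 0.15)
  }

  meta <- meta_spearman(c(0.5, 0.5, 0.5), c(100, 200, 150))
  expect_equal(meta$rho, 0.5, tolerance = 1e-12)
  expect_true(meta$ci[1] < 0.5 && meta$ci[2] > 0.5)
})

test_that("pathway scores: |FES| means for reactions, plain means for genes", {
  fm <- structure(list(scores = cbind(r1 = c(-0.5, 0.1), r2 = c(0.5, 0.3)),
                       spots = c("s1", "s2"), reactions = c("r1", "r2"),
                       provenance = "cb3"), class = "fes_matrix")
  rownames(fm$scores) <- c("s1", "s2")
  ps <- pathway_score(fm, list(p1 = c("r1", "r2"), p2 = "r2"))
  expect_equal(unname(ps[, "p1"]), c(0.5, 0.2))
  expect_equal(unname(ps[, "p2"]), c(0.5, 0.3))

  counts <- rbind(s1 = c(g1 = 1, g2 = 2, g3 = 3), s2 = c(g1 = 2, g2 = 2, g3 = 2))
  e <- normalize_counts(toy_expression(counts))
  e$layers$lognorm <- Matrix::Matrix(counts, sparse = FALSE)
  pg <- pathway_score(e, list(panel = c("g1", "g2", "g3")))
  expect_equal(unname(pg[, "panel"]), c(2, 2))

  expect_warning(ps2 <- pathway_score(fm, list(ok = "r1", gone = "rX")), "skipped")
  expect_equal(colnames(ps2), "ok")
  expect_error(suppressWarnings(pathway_score(fm, list(gone = "rX"))), "no pathway")
})
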