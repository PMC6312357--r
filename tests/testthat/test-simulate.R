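test_that("panel generation is reproducible and seed-sensitive", {
  s <- panel_spec(n_a = 1, n_b = 1, n_c = 1, n_d = 1, n_e = 1)
  p1 <- gen_ecc_panel(s, seed = 7)
  p2 <- gen_ecc_panel(s, seed = 7)
  p3 <- gen_ecc_panel(s, seed = 8)
  expect_identical(p1$panel, p2$panel)
  expect_identical(p1$truth, p2$truth)
  expect_false(identical(p1$panel$residues, p3$panel$residues))
  # the global RNG stream is untouched
  set.seed(123); before <- runif(3)
  set.seed(123); invisible(gen_ecc_panel(s, seed = 1)); after <- runif(3)
  expect_identical(before, after)
})

test_that("every planted feature of a noise-free Group D ECC is recovered", {
  p <- gen_ecc_panel(panel_spec(n_a = 0, n_b = 0, n_c = 0, n_d = 1,
                                n_e = 0), seed = 15)
  ann <- annotate_ecc(p$panel)
  tr <- p$truth
  expect_equal(ann$edvid$start, tr$edvid_start)
  expect_equal(ann$polar_stretch$start, tr$polar_start)
  expect_equal(ann$preploop$vg, tr$vg)
  expect_equal(ann$ploop$start, tr$ploop_start)
  expect_equal(ann$charged$start, tr$charged_start)
  expect_equal(ann$charged$n_acidic, tr$n_acidic)
  expect_equal(ann$charged$n_basic, tr$n_basic)
  expect_equal(ann$cc_end, tr$cc_end)
  expect_equal(ann$ccvx$length, tr$ccvx_length)
  expect_equal(ann$ecc_boundary, tr$ecc_boundary)
})

test_that("noise obeys anchor protection and degrades classification", {
  spec <- panel_spec(n_a = 1, n_b = 1, n_c = 1, n_d = 1, n_e = 1,
                     epsilon = 0.2)
  p <- gen_ecc_panel(spec, seed = 4)
  # initiator Met always intact
  expect_true(all(substr(p$panel$residues, 1, 1) == "M"))
  # protected anchors intact: the planted EDVID still matches exactly
  d <- p$panel$residues[p$truth$group == "D"]
  expect_equal(substr(d, p$truth$edvid_start[p$truth$group == "D"],
                      p$truth$edvid_start[p$truth$group == "D"] + 4L),
               "EDVID")
  acc <- function(eps, seeds) {
    mean(vapply(seeds, function(s) {
      pp <- gen_ecc_panel(panel_spec(n_a = 1, n_b = 1, n_c = 1, n_d = 1,
                                     n_e = 1, epsilon = eps), seed = s)
      cl <- classify_panel(annotate_panel(pp$panel))
      mean(cl$group == pp$truth$group)
    }, numeric(1)))
  }
  seeds <- 1:20
  expect_equal(acc(0, seeds), 1)
  expect_lt(acc(0.35, seeds), 1)  # monotone degradation on average
})

test_that("Y2H screens recover planted densities under perfect replication", {
  ids <- paste0("E", 1:8)
  groups <- rep(c("B", "C"), each = 4)
  full <- gen_y2h_screen(ids, groups,
                         y2h_model(edge_p = 1, self_p = 1, fn = 0, fp = 0),
                         seed = 2)
  edges <- call_interactions(full$matings, min_support = 3)
  expect_equal(nrow(edges[edges$a != edges$b, ]), choose(8, 2))
  expect_equal(nrow(edges[edges$a == edges$b, ]), 8L)
  empty <- gen_y2h_screen(ids, groups,
                          y2h_model(edge_p = 0, self_p = 0, fp = 0),
                          seed = 2)
  expect_equal(nrow(call_interactions(empty$matings)), 0L)
})

test_that("F2 simulation honours the Haldane map function and F2 ratios", {
  # recombination fraction between adjacent markers 1 cM apart
  model <- qtl_model(n = 4000, n_chr = 1, markers_per_chr = 2,
                     spacing = 1, qtl_chr = 1, qtl_pos = 0, a = 0, d = 0)
  pop <- gen_f2_population(model, seed = 6)
  g <- matrix(match(pop$geno, c("AA", "AB", "BB")) - 2L,
              nrow = nrow(pop$geno))
  # per-gamete recombination events between the two markers: estimate via
  # genotype transitions; expected r = (1 - exp(-0.02)) / 2 ~ 0.0099
  r_expected <- (1 - exp(-2 * 1 / 100)) / 2
  # count half the mean absolute genotype difference (each meiosis
  # recombines independently in the two gametes)
  diffs <- mean(abs(g[, 1] - g[, 2])) / 2
  expect_lt(abs(diffs - r_expected), 3 * sqrt(r_expected / (2 * 4000)))
  # 1:2:1 genotype frequencies at a marker
  tab <- table(pop$geno[, 1]) / nrow(pop$geno)
  expect_lt(abs(tab[["AA"]] - 0.25), 0.03)
  expect_lt(abs(tab[["AB"]] - 0.50), 0.03)
  expect_lt(abs(tab[["BB"]] - 0.25), 0.03)
})

test_that("phenotypes land on the 1-5 scale with balanced quintiles", {
  pop <- gen_f2_population(qtl_model(), seed = 21)
  expect_true(all(pop$phenotype %in% 1:5))
  expect_equal(length(pop$phenotype), 75L)
  counts <- table(factor(pop$phenotype, levels = 1:5))
  expect_true(all(counts >= 10))  # empirical quintile cuts
  # truth carries the planted QTL
  expect_equal(pop$truth$qtl_chr, 3L)
  expect_equal(pop$truth$qtl_pos, 40)
})
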