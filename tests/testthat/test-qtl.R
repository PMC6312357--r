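test_that("a genotype-independent phenotype gives LOD 0 everywhere", {
  pop <- gen_f2_population(qtl_model(n = 30, a = 0, d = 0), seed = 3)
  pop$phenotype <- rep(2, 30)  # constant response
  sc <- marker_scan(pop)
  expect_true(all(sc$lod == 0))
  expect_true(all(sc$flag == "monomorphic"))
})

test_that("a perfect genotype-phenotype fit is capped and flagged", {
  geno <- matrix(rep(c("AA", "AB", "BB", "AA", "AB", "BB", "AA", "AB"), 2),
                 nrow = 8,
                 dimnames = list(NULL, c("m1", "m2")))
  map <- tibble::tibble(marker = c("m1", "m2"), chr = 1L, pos = c(0, 10))
  y <- c(AA = -1, AB = 0, BB = 1)[geno[, 1]]
  pop <- f2_population(geno, map, y)
  sc <- marker_scan(pop)
  expect_equal(sc$lod[1], ecc_defaults()$lod_max)
  expect_equal(sc$flag[1], "perfect_fit")
})

test_that("the scan LOD equals a hand regression on a small table", {
  geno <- matrix(c("AA", "AA", "AB", "AB", "BB", "BB"), ncol = 1,
                 dimnames = list(NULL, "m1"))
  map <- tibble::tibble(marker = "m1", chr = 1L, pos = 0)
  y <- c(1, 2, 3, 3, 4, 5)
  pop <- f2_population(geno, map, y)
  sc <- marker_scan(pop)
  # oracle: explicit additive + dominance regression
  x <- c(-1, -1, 0, 0, 1, 1)
  z <- c(0, 0, 1, 1, 0, 0)
  fit <- stats::lm(y ~ x + z)
  rss1 <- sum(stats::resid(fit)^2)
  rss0 <- sum((y - mean(y))^2)
  expect_equal(sc$lod[1], (6 / 2) * log10(rss0 / rss1), tolerance = 1e-10)
})

test_that("markers with fewer than two genotype classes are flagged", {
  geno <- matrix(c(rep("AA", 6), "AA", "AB", "BB", "AA", "AB", "BB"),
                 ncol = 2, dimnames = list(NULL, c("mono", "seg")))
  map <- tibble::tibble(marker = c("mono", "seg"), chr = 1L, pos = c(0, 10))
  pop <- f2_population(geno, map, c(1, 2, 3, 4, 5, 4))
  sc <- marker_scan(pop)
  expect_equal(sc$lod[1], 0)
  expect_equal(sc$flag[1], "monomorphic")
  expect_gt(sc$lod[2], 0)
})

test_that("missing genotypes are handled complete-case per marker", {
  pop <- gen_f2_population(qtl_model(n = 60, missing = 0.2), seed = 8)
  sc <- marker_scan(pop)
  expect_true(all(sc$n < 60))
  expect_true(all(sc$n == colSums(!is.na(pop$geno))))
  expect_true(all(is.finite(sc$lod)))
})

test_that("LOD is invariant to affine rescaling of the phenotype", {
  pop <- gen_f2_population(qtl_model(n = 50), seed = 12)
  sc1 <- marker_scan(pop)
  pop2 <- pop
  pop2$phenotype <- 3 + 7 * pop$phenotype
  sc2 <- marker_scan(pop2)
  expect_equal(sc1$lod, sc2$lod, tolerance = 1e-9)
})

test_that("permutation thresholds are seeded and monotone in alpha", {
  pop <- gen_f2_population(qtl_model(n = 40, a = 0, d = 0), seed = 2)
  t1 <- permutation_threshold(pop, n_perm = 150, seed = 9)
  t2 <- permutation_threshold(pop, n_perm = 150, seed = 9)
  expect_equal(as.numeric(t1), as.numeric(t2))
  expect_equal(attr(t1, "max_lods"), attr(t2, "max_lods"))
  t_strict <- permutation_threshold(pop, n_perm = 150, alpha = 0.01,
                                    seed = 9)
  t_loose <- permutation_threshold(pop, n_perm = 150, alpha = 0.2,
                                   seed = 9)
  expect_gte(as.numeric(t_strict), as.numeric(t1))
  expect_gte(as.numeric(t1), as.numeric(t_loose))
  expect_error(permutation_threshold(pop, n_perm = 50, seed = 1), ">= 100")
})

test_that("support intervals collapse to flanking markers on a spike", {
  scan <- tibble::tibble(
    marker = paste0("m", 1:7), chr = 1L,
    pos = seq(0, 60, by = 10),
    lod = c(0.2, 0.1, 0.3, 5, 0.2, 0.1, 0.2),
    n = 75L, flag = "")
  class(scan) <- c("ecc_scan", class(scan))
  iv <- lod_support_interval(scan, "m4", drop = 1.5)
  expect_equal(iv$start, 20)
  expect_equal(iv$end, 40)
  flat <- scan
  flat$lod <- rep(3, 7)
  iv2 <- lod_support_interval(flat, "m4", drop = 1.5)
  expect_equal(iv2$start, 0)
  expect_equal(iv2$end, 60)
})

test_that("scan_qtl finds the planted locus and tidies/plots", {
  pop <- gen_f2_population(qtl_model(a = 1.5, d = 0.75), seed = 30)
  fit <- scan_qtl(pop, n_perm = 150, seed = 31)
  expect_s3_class(fit, "ecc_qtl_fit")
  expect_gt(max(fit$scan$lod), fit$threshold)
  best <- fit$scan[which.max(fit$scan$lod), ]
  expect_equal(best$chr, 3L)
  expect_equal(nrow(tidy(fit)), 50L)
  expect_equal(glance(fit)$n_markers, 50L)
  expect_s3_class(autoplot(fit), "ggplot")
  # rank-based robustness scan agrees on the peak chromosome
  kw <- scan_qtl(pop, n_perm = 150, seed = 31, method = "kruskal")
  expect_equal(kw$scan$chr[which.max(kw$scan$lod)], 3L)
})

test_that("F2 populations round-trip through CSV files", {
  pop <- gen_f2_population(qtl_model(n = 20), seed = 14)
  gd <- withr::local_tempfile(fileext = ".csv")
  md <- withr::local_tempfile(fileext = ".csv")
  pd <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::as_tibble(cbind(id = seq_len(20),
                                           as.data.frame(pop$geno))), gd)
  readr::write_csv(pop$map, md)
  readr::write_csv(tibble::tibble(phenotype = pop$phenotype), pd)
  back <- read_f2_population(gd, md, pd)
  expect_equal(unname(back$geno), unname(pop$geno))
  expect_equal(back$phenotype, as.numeric(pop$phenotype))
  expect_equal(marker_scan(back)$lod, marker_scan(pop)$lod)
})

test_that("segregation chi-square matches hand computation", {
  r <- segregation_test(c(14, 16), c(1, 1))
  expect_equal(r$chi2, 1 / 15 + 1 / 15, tolerance = 1e-10)
  expect_equal(r$df, 1)
  expect_equal(segregation_test(c(15, 15), c(1, 1))$chi2, 0)
  expect_equal(segregation_test(c(30, 0), c(1, 1))$chi2, 30)
  r31 <- segregation_test(c(90, 30), c(3, 1))
  expect_equal(r31$chi2, 0)
  expect_error(segregation_test(c(0, 0), c(1, 1)), "Zero total")
  expect_error(segregation_test(c(5, 5), c(1, 1, 1)), "same length")
})
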