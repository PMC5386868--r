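# Genotype probabilities, Haley-Knott scans, permutation thresholds,
# cofactor scans.

test_that("probabilities are indicators at observed markers and Mendelian priors without data", {
  calls <- matrix(c("A", "B",
                    "H", NA,
                    NA, NA), nrow = 3, byrow = TRUE,
                  dimnames = list(paste0("s", 1:3), NULL))
  gm <- manual_geno_matrix(calls)
  map <- manual_map(c(0, 20))
  probs <- genotype_probabilities(gm, map, step_cM = 10, design = "F2")
  at0 <- which(probs$grid$cM == 0)
  expect_equal(probs$pAA[1, at0], 1) # observed A
  expect_equal(probs$pAB[2, at0], 1) # observed H
  expect_equal(c(probs$pAA[3, at0], probs$pAB[3, at0], probs$pBB[3, at0]),
               c(0.25, 0.5, 0.25)) # no data anywhere
})

test_that("the midpoint between AA and BB flanks is most likely heterozygous", {
  calls <- matrix(c("A", "B"), nrow = 1,
                  dimnames = list("s1", NULL))
  gm <- manual_geno_matrix(calls)
  map <- manual_map(c(0, 20))
  probs <- genotype_probabilities(gm, map, step_cM = 10, design = "F2")
  mid <- which(probs$grid$cM == 10)
  p <- c(probs$pAA[1, mid], probs$pAB[1, mid], probs$pBB[1, mid])
  expect_equal(which.max(p), 2L)
  expect_equal(sum(p), 1)
  expect_equal(p[1], p[3]) # symmetry
})

test_that("RIL probabilities put zero mass on heterozygotes", {
  calls <- matrix(c("A", "B", "A", NA), nrow = 2, byrow = TRUE,
                  dimnames = list(c("s1", "s2"), NULL))
  gm <- manual_geno_matrix(calls)
  map <- manual_map(c(0, 30), design = "RIL")
  probs <- genotype_probabilities(gm, map, step_cM = 5, design = "RIL")
  expect_true(all(probs$pAB == 0))
  expect_equal(probs$pAA + probs$pBB,
               matrix(1, 2, nrow(probs$grid)), ignore_attr = TRUE)
})

test_that("scan LOD at a fully observed marker equals the closed-form ANOVA value", {
  calls <- matrix(c("A", "A",
                    "A", "A",
                    "B", "B",
                    "B", "B"), nrow = 4, byrow = TRUE,
                  dimnames = list(paste0("s", 1:4), NULL))
  gm <- manual_geno_matrix(calls)
  map <- manual_map(c(0, 10))
  probs <- genotype_probabilities(gm, map, step_cM = 2, design = "F2")
  y <- c(s1 = 1, s2 = 2, s3 = 3, s4 = 4)
  scan <- scan_sim(probs, y)
  at0 <- which(probs$grid$cM == 0)
  # RSS0 = 5 (about the grand mean 2.5), RSS1 = 1 (group means 1.5, 3.5)
  expect_equal(scan$lod[at0], (4 / 2) * log10(5 / 1), tolerance = 1e-12)
})

test_that("scan LOD matches an independent lm-based computation everywhere", {
  set.seed(41)
  g <- test_genome()
  pop <- simulate_cross(sim_config("F2", n_individuals = 60), g)
  calls <- simulate_window_calls(pop, call_rate = 1, error_rate = 0,
                                 low_diversity_rate = 0)
  gm <- genotype_population(calls)
  map <- build_genetic_map(gm, "F2")
  probs <- genotype_probabilities(gm, map, 2, "F2")
  y <- rnorm(60) + 3 * (probs$pAB[, 5] + 2 * probs$pBB[, 5])
  names(y) <- probs$samples
  scan <- scan_sim(probs, y)
  for (j in c(1, 7, 20, nrow(probs$grid))) {
    a <- probs$pAB[, j] + 2 * probs$pBB[, j]
    d <- probs$pAB[, j]
    fit1 <- lm(y ~ a + d)
    fit0 <- lm(y ~ 1)
    lod <- (60 / 2) * log10(sum(resid(fit0)^2) / sum(resid(fit1)^2))
    expect_equal(scan$lod[j], lod, tolerance = 1e-9)
  }
})

test_that("scans are invariant under phenotype translation and positive scaling", {
  calls <- matrix(sample(c("A", "H", "B"), 40, TRUE), nrow = 10,
                  dimnames = list(paste0("s", 1:10), NULL))
  gm <- manual_geno_matrix(calls)
  map <- manual_map(c(0, 5, 12, 30))
  probs <- genotype_probabilities(gm, map, 2, "F2")
  set.seed(42)
  y <- setNames(rnorm(10), probs$samples)
  base <- scan_sim(probs, y)$lod
  expect_equal(scan_sim(probs, 100 + y)$lod, base, tolerance = 1e-9)
  expect_equal(scan_sim(probs, y * 7.3)$lod, base, tolerance = 1e-9)
})

test_that("degenerate phenotypes are handled: constant gives zero scan, perfect fit is capped", {
  calls <- matrix(c("A", "A", "B", "B"), ncol = 1,
                  dimnames = list(paste0("s", 1:4), NULL))
  gm <- manual_geno_matrix(calls)
  map <- manual_map(0)
  probs <- genotype_probabilities(gm, map, 2, "F2")
  expect_warning(sc <- scan_sim(probs, setNames(rep(1, 4), probs$samples)),
                 "zero phenotypic variance")
  expect_true(all(sc$lod == 0))
  # phenotype perfectly determined by genotype: RSS1 = 0, LOD capped
  perfect <- setNames(c(0, 0, 1, 1), probs$samples)
  expect_equal(scan_sim(probs, perfect)$lod[1], 300)
})

test_that("permutation thresholds are seeded, deterministic, and zero for constant phenotypes", {
  set.seed(43)
  calls <- matrix(sample(c("A", "H", "B"), 200, TRUE), nrow = 20,
                  dimnames = list(paste0("s", 1:20), NULL))
  gm <- manual_geno_matrix(calls)
  map <- manual_map(seq(0, 45, by = 5))
  probs <- genotype_probabilities(gm, map, 2, "F2")
  y <- setNames(rnorm(20), probs$samples)
  t1 <- permutation_threshold(probs, y, 0.05, 100, seed = 9)
  t2 <- permutation_threshold(probs, y, 0.05, 100, seed = 9)
  expect_identical(t1$value, t2$value)
  expect_equal(t1$value,
               unname(quantile(t1$max_lods, 0.95, type = 7)))
  suppressWarnings(
    tc <- permutation_threshold(probs, setNames(rep(2, 20), probs$samples),
                                0.05, 100, seed = 9))
  expect_equal(tc$value, 0)
  expect_error(permutation_threshold(probs, y, 0.05, 50), "n_perm")
})

test_that("the cofactor scan reduces to SIM without cofactors and under local exclusion", {
  set.seed(44)
  calls <- matrix(sample(c("A", "H", "B"), 300, TRUE), nrow = 30,
                  dimnames = list(paste0("s", 1:30), NULL))
  gm <- manual_geno_matrix(calls)
  map <- manual_map(seq(0, 45, by = 5))
  probs <- genotype_probabilities(gm, map, 2, "F2")
  y <- setNames(rnorm(30), probs$samples)
  sim <- scan_sim(probs, y)
  cof_none <- scan_cofactor(probs, y, NULL)
  expect_equal(cof_none$lod, sim$lod)
  # a cofactor at a test position is excluded within the 10 cM window,
  # so the scan equals SIM there
  cof <- scan_cofactor(probs, y, data.frame(chrom = "chr1", cM = 20),
                       exclusion_window_cM = 10)
  near <- which(probs$grid$cM > 10 & probs$grid$cM < 30)
  expect_equal(cof$lod[near], sim$lod[near], tolerance = 1e-9)
  far <- which(probs$grid$cM >= 40)
  expect_false(isTRUE(all.equal(cof$lod[far], sim$lod[far])))
})

test_that("fitting the other QTL as a cofactor raises the focal peak LOD", {
  set.seed(45)
  g <- test_genome(n_chrom = 4, length_bp = 1e6)
  wins <- 0
  for (rep in 1:30) {
    pop <- simulate_cross(sim_config("F2", n_individuals = 150), g)
    calls <- simulate_window_calls(pop, call_rate = 1, error_rate = 0,
                                   low_diversity_rate = 0)
    gm <- genotype_population(calls)
    map <- build_genetic_map(gm, "F2")
    probs <- genotype_probabilities(gm, map, 2, "F2")
    q1 <- which(probs$grid$chrom == "chr1")[3]
    q3 <- which(probs$grid$chrom == "chr3")[3]
    dose <- function(j) probs$pAB[, j] + 2 * probs$pBB[, j]
    y <- setNames(dose(q1) + dose(q3) + rnorm(150, 0, 1.2), probs$samples)
    sim <- scan_sim(probs, y)
    cof <- scan_cofactor(probs, y,
                         data.frame(chrom = "chr3",
                                    cM = probs$grid$cM[q3]))
    if (cof$lod[q1] >= sim$lod[q1]) wins <- wins + 1
  }
  expect_gte(wins, 24) # variance absorbed by the cofactor helps in ~90%
})

test_that("per-chromosome peaks and significance flags are extracted correctly", {
  sc <- structure(data.frame(chrom = rep(c("chr1", "chr2"), each = 3),
                             cM = rep(c(0, 5, 10), 2),
                             lod = c(1, 4, 2, 0.5, 0.2, 0.1)),
                  class = c("nor_scan", "data.frame"))
  thr <- structure(list(value = 3, alpha = 0.05), class = "nor_threshold")
  pk <- find_peaks(sc, thr)
  expect_equal(pk$cM, c(5, 0))
  expect_equal(pk$significant, c(TRUE, FALSE))
})
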