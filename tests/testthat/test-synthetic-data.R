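# Pedigree simulator: meiosis, crosses, and the observation models.

test_that("meiosis with a 0 cM map and no mutation transmits one parental haplotype intact", {
  set.seed(101)
  g <- test_genome(length_cM = 0)
  p1 <- founder_individual(g, 1L, c(NOR2 = 500, NOR4 = 300), "P1")
  p2 <- founder_individual(g, 2L, c(NOR2 = 2500, NOR4 = 300), "P2")
  f1 <- norinherit:::fertilize(meiosis(p1, g), meiosis(p2, g), g, "F1", 1L, "F1")
  for (k in 1:20) {
    gam <- meiosis(f1, g)
    for (cn in g$chromosomes$name) {
      al <- gam$alleles[[cn]]
      expect_true(all(al == al[1L])) # no crossover: single origin
    }
    # NOR copies travel with the chr2/chr4 allele at the top window
    expect_equal(gam$nor[["NOR2"]],
                 if (gam$alleles$chr2[1L] == 1L) 500 else 2500)
    expect_equal(gam$nor[["NOR4"]], 300)
  }
})

test_that("without mutation NOR copy number is conserved exactly through deep pedigrees", {
  set.seed(102)
  g <- test_genome()
  cfg <- sim_config("RIL", n_individuals = 15, n_generations = 9,
                    parental_copies = list(NOR2 = c(500, 2500),
                                           NOR4 = c(300, 300)))
  pop <- simulate_cross(cfg, g, mutation_model(0, 0))
  for (ind in pop$individuals) {
    expect_true(all(ind$nor$NOR2 %in% c(500, 2500)))
    expect_identical(ind$nor$NOR4, c(300, 300))
  }
  # MA lineages keep the founder copy number in every generation
  cfg_ma <- sim_config("MA", n_individuals = 5, n_generations = 8,
                       n_replicates = 2,
                       parental_copies = list(NOR2 = c(400), NOR4 = c(400)))
  ma <- simulate_cross(cfg_ma, g, mutation_model(0, 0))
  expect_true(all(vapply(ma$individuals, total_nor_copies, 0) == 1600))
})

test_that("mean transmitted NOR2 copies from a 500x2500 F1 match the analytic 1500", {
  set.seed(103)
  g <- test_genome()
  p1 <- founder_individual(g, 1L, c(NOR2 = 500, NOR4 = 300), "P1")
  p2 <- founder_individual(g, 2L, c(NOR2 = 2500, NOR4 = 300), "P2")
  f1 <- norinherit:::fertilize(meiosis(p1, g), meiosis(p2, g), g, "F1", 1L, "F1")
  n <- 10000
  copies <- vapply(seq_len(n), function(i) meiosis(f1, g)$nor[["NOR2"]], 0)
  se <- 1000 / sqrt(n) # sd of a 500/2500 coin flip is 1000
  expect_lt(abs(mean(copies) - 1500), 3 * se)
})

test_that("F2 single-window diplotype frequencies are 1:2:1", {
  set.seed(104)
  g <- test_genome(length_bp = 3e5) # 3 windows per chromosome
  cfg <- sim_config("F2", n_individuals = 10000)
  pop <- simulate_cross(cfg, g)
  dip <- vapply(pop$individuals,
                function(ind) true_diplotypes(ind, g)$diplotype[4L], 0L)
  counts <- tabulate(dip + 1L, 3L)
  expect_gt(stats::chisq.test(counts, p = c(1, 2, 1) / 4)$p.value, 0.01)
  # chr2 NOR diplotype matches the chr2 top-window diplotype by construction
  nor_dip <- vapply(pop$individuals,
                    function(ind) sum(ind$nor$NOR2 == 2500), 0L)
  top2 <- vapply(pop$individuals,
                 function(ind) true_diplotypes(ind, g)$diplotype[4L], 0L)
  expect_identical(nor_dip, top2)
})

test_that("RIL residual heterozygosity decays as 0.5^g", {
  set.seed(105)
  g <- test_genome()
  n <- 400
  cfg <- sim_config("RIL", n_individuals = n, n_generations = 9)
  pop <- simulate_cross(cfg, g)
  het_frac <- vapply(pop$individuals, function(ind)
    mean(true_diplotypes(ind, g)$diplotype == 1L), 0)
  expected <- 0.5^9
  se <- stats::sd(het_frac) / sqrt(n) # individuals are independent
  expect_lt(abs(mean(het_frac) - expected), 4 * se + 1e-4)
})

test_that("coverage simulation is deterministic at dispersion 0 and reproducible under a seed", {
  g <- test_genome()
  ind <- founder_individual(g, 1L, c(NOR2 = 1000, NOR4 = 500), "s1")
  # diploid total 3000, depth 1 -> mean18S 1500, baseline 1, exactly
  cov <- simulate_coverage(list(ind), depth_mean = 1, dispersion = 0)
  expect_equal(cov$mean18S, 1500)
  expect_equal(cov$meanBaseline, 1)
  set.seed(42); a <- simulate_coverage(list(ind), 20, 0.5)
  set.seed(42); b <- simulate_coverage(list(ind), 20, 0.5)
  expect_identical(a, b)
  expect_error(simulate_coverage(list(ind), 20, -1), "dispersion")
})

test_that("mean NGS depth ratio matches copies-per-haploid within 1% at depth 20", {
  set.seed(106)
  g <- test_genome()
  ind <- founder_individual(g, 1L, c(NOR2 = 1000, NOR4 = 500), "s1")
  reps <- simulate_coverage(rep(list(ind), 200), depth_mean = 20,
                            dispersion = 0.5)
  ratio <- reps$mean18S / reps$meanBaseline
  expect_lt(abs(mean(ratio) - 1500) / 1500, 0.01)
})

test_that("window call counts follow the diplotype-plus-error model", {
  set.seed(107)
  g <- test_genome(n_chrom = 4, length_bp = 2.5e7) # 1000 windows total
  ind <- founder_individual(g, 1L, c(NOR2 = 500, NOR4 = 300), "s1")
  # no error, true AA everywhere: every call maternal
  calls <- simulate_window_calls(list(ind), g, snp_density = 150,
                                 low_diversity_rate = 0, call_rate = 1,
                                 error_rate = 0)
  expect_true(all(calls$n_maternal == calls$n_called))
  expect_true(all(calls$n_het == 0L))
  # call_rate 0: nothing called
  none <- simulate_window_calls(list(ind), g, call_rate = 0)
  expect_true(all(none$n_called == 0L))
  # error 0.02: maternal fraction near 0.98 in AA windows
  err <- simulate_window_calls(list(ind), g, snp_density = 100,
                               low_diversity_rate = 0, call_rate = 1,
                               error_rate = 0.02)
  frac <- sum(err$n_maternal) / sum(err$n_called)
  expect_lt(abs(frac - 0.98), 0.005)
})

test_that("qPCR simulation recovers copy number and shared plate offsets cancel", {
  samples <- data.frame(sample_id = c("a", "b"), copies = c(512, 2048))
  set.seed(108)
  ct <- simulate_qpcr(samples, n_plates = 2, plate_offset_sd = 0,
                      target_offset_sd = 0, replicate_sd = 0)
  est <- qpcr_estimates(ct)
  expect_equal(est$value[est$sample_id == "a"], 512)
  expect_equal(est$value[est$sample_id == "b"], 2048)
  # a large shared plate offset leaves the delta-Ct estimate unchanged
  set.seed(108)
  ct_off <- simulate_qpcr(samples, n_plates = 2, plate_offset_sd = 3,
                          target_offset_sd = 0, replicate_sd = 0)
  est_off <- qpcr_estimates(ct_off)
  expect_equal(sort(est_off$value), sort(est$value))
})

test_that("target-specific plate offsets bias estimates and control standardization corrects them", {
  samples <- data.frame(sample_id = sprintf("s%02d", 1:12),
                        copies = round(seq(200, 2400, length.out = 12)))
  set.seed(109)
  ct <- simulate_qpcr(samples, n_plates = 3, plate_offset_sd = 0.3,
                      target_offset_sd = 0.5, replicate_sd = 0,
                      control_id = "ctrl", control_copies = 500)
  est <- qpcr_estimates(ct)
  raw <- est[est$sample_id != "ctrl", ]
  expect_gt(stats::sd(raw$value / samples$copies[match(raw$sample_id,
                                                       samples$sample_id)]),
            1e-6) # biased before correction
  std <- standardize_plates(est, "control", control_sample = "ctrl")
  cor_ratio <- std$value[std$sample_id != "ctrl"] /
    samples$copies[match(std$sample_id[std$sample_id != "ctrl"],
                         samples$sample_id)]
  expect_lt(diff(range(cor_ratio)), 1e-9) # exactly proportional after
})

test_that("a fixed master seed reproduces the population stream bit-identically", {
  g <- test_genome()
  cfg <- sim_config("F2", n_individuals = 10, seed = 31)
  t1 <- population_table(simulate_cross(cfg, g))
  t2 <- population_table(simulate_cross(cfg, g))
  expect_identical(t1, t2)
})

test_that("invalid simulator configurations are rejected", {
  expect_error(sim_config("F2", n_individuals = 0), "n_individuals")
  expect_error(sim_config("F2", call_rate = 1.2), "rates")
  expect_error(mutation_model(-0.1), "jump_probability")
  expect_error(genome_model(chromosomes = data.frame(
    name = "chr1", length_bp = 1e6, length_cM = -5)), "negative genetic")
})
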