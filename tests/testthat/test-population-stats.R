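test_that("mean mutation burden counts genes without calls as zero", {
  anc <- cogfp_ancestor()
  calls <- tibble::tibble(index = c(1, 1, 2, 2, 2, 2),
                          protein_position = c(10L, 20L, 30L, 40L, 50L, 60L),
                          ref_aa = "A", alt_aa = c("V", "V", "V", "V", "V", "A"),
                          synonymous = c(rep(FALSE, 5), TRUE))
  s <- population_sample(character(0), calls, n_genes = 2, ancestor = anc)
  expect_equal(mean_mutations(s), 2.5)                       # (2 + 3)/2
  expect_equal(mean_mutations(s, nonsyn_only = FALSE), 3)
  s4 <- population_sample(character(0), calls, n_genes = 5, ancestor = anc)
  expect_equal(mean_mutations(s4), 1)
  empty <- population_sample(character(0), calls[0, ], n_genes = 3)
  expect_equal(mean_mutations(empty), 0)
  expect_error(mean_mutations(population_sample(character(0), calls,
                                                n_genes = 0)), "empty")
  # engineered chromophore calls can be discounted
  eng <- tibble::tibble(index = 1,
                        protein_position = c(74L, 75L, 76L),
                        ref_aa = c("Q", "Y", "G"), alt_aa = c("A", "S", "A"),
                        synonymous = FALSE)
  se <- population_sample(character(0), eng, n_genes = 1, ancestor = anc)
  expect_equal(mean_mutations(se, exclude = c("Q74A", "Y75S", "G76A")), 0)
})

test_that("average pairwise distance equals the brute-force double sum", {
  s2 <- population_sample(c("MKTAY", "MQTAW"))
  expect_equal(avg_pairwise_distance(s2), 2)          # (2 + 2)/2
  ident <- population_sample(rep("MKTAY", 6))
  expect_equal(avg_pairwise_distance(ident), 0)
  set.seed(4)
  s4 <- population_sample(random_protein(7, 4))
  expect_equal(avg_pairwise_distance(s4), bf_avg_pairwise(s4$proteins))
  for (n in c(11, 50)) {
    sr <- population_sample(random_protein(12, n))
    expect_equal(avg_pairwise_distance(sr), bf_avg_pairwise(sr$proteins))
  }
  expect_error(avg_pairwise_distance(population_sample("MKTAY")), "at least 2")
})

test_that("pair-subsampled distance estimator is unbiased", {
  set.seed(9)
  sr <- population_sample(random_protein(15, 40))
  exact <- avg_pairwise_distance(sr)
  ests <- vapply(1:40, function(s)
    avg_pairwise_distance(sr, max_pairs = 100L, seed = s), numeric(1))
  expect_lt(abs(mean(ests) - exact), 0.1)
  expect_gt(stats::sd(ests), 0)   # genuinely subsampled
})

test_that("NG86 site counts match exhaustive 9-mutant enumeration", {
  phe <- count_sites(list(coding_dna = "TTT"))
  expect_equal(phe$S, 1 / 3)
  expect_equal(phe$N, 8 / 3)
  met <- count_sites(list(coding_dna = "ATG"))
  expect_equal(met$S, 0)
  expect_equal(met$N, 3)
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  for (codon in sense) {
    got <- count_sites(list(coding_dna = codon))
    want <- bf_ng86_codon(codon)
    expect_equal(got$N, unname(want["N"]), info = codon)
    expect_equal(got$S, unname(want["S"]), info = codon)
    expect_equal(got$N + got$S, 3, info = codon)   # conservation
  }
  anc <- cogfp_ancestor()
  s <- count_sites(anc)
  expect_equal(s$N + s$S, 3 * s$n_codons)
  expect_equal(s$n_codons, anc$n_codons - 1)  # terminal stop excluded
})

test_that("dN/dS follows the pooled-count formula", {
  anc <- cogfp_ancestor()
  sites <- count_sites(anc)
  # nonsyn/syn counts proportional to N/S give a ratio near 1 by construction
  k <- 10
  n_non <- round(k * sites$N / sites$S)
  calls <- tibble::tibble(protein_position = rep(10L, n_non + k),
                          ref_aa = "X", alt_aa = "Y",
                          synonymous = rep(c(FALSE, TRUE), c(n_non, k)))
  s <- population_sample(character(0), calls, n_genes = 5, ancestor = anc)
  expect_equal(dnds(s, sites), (n_non / sites$N) / (k / sites$S))
  # no synonymous mutations -> flagged infinite
  ns <- population_sample(character(0), calls[!calls$synonymous, ],
                          n_genes = 5, ancestor = anc)
  expect_warning(v <- dnds(ns, sites), "undefined")
  expect_true(is.infinite(v))
  expect_true(attr(v, "undefined"))
})

test_that("neutral evolution gives dN/dS of 1 and purifying selection less", {
  set.seed(12)
  anc <- cogfp_ancestor()
  neutral <- simulate_neutral_genes(anc, n = 3000, rounds = 5)
  v <- dnds(neutral)
  expect_lt(abs(v - 1), 0.08)
  # selected populations accumulate relatively fewer nonsynonymous calls
  cfg <- simulator_config(population_size = 3000, generations = 2,
                          survival_fractions = c(0.6, 0.05), seed = 13,
                          copy_mode = "single", sample_size = 300)
  ex <- run_experiment(cfg)
  tc <- ex$generations$g2$truth_calls
  active_ids <- ex$generations$g2$truth$index[
    ex$generations$g2$truth$copy == 1 &
      ex$generations$g2$truth$functional_state == "active"]
  sel <- population_sample(character(0),
                           tc[tc$copy == 1 & tc$index %in% active_ids, ],
                           n_genes = length(active_ids), ancestor = anc)
  expect_lt(dnds(sel), 1)
})

test_that("allele trajectories count per-copy carriers and combinations", {
  variants <- tibble::tibble(
    generation = 1L, replicate = 1L,
    read_id = c("a", "a", "b", "c"), copy = c(1L, 1L, 2L, 1L),
    protein_position = c(147L, 98L, 147L, 162L),
    ref_aa = c("G", "L", "G", "V"), alt_aa = c("S", "M", "S", "D"),
    synonymous = FALSE)
  totals <- tibble::tibble(generation = 1L, replicate = 1L, n_genes = 10L)
  tr <- allele_trajectories(variants, totals,
                            c("G147S", "L98M", "V162D", "G147S/L98M"))
  f <- function(m) tr$frequency[tr$mutation == m]
  expect_equal(f("G147S"), 0.2)
  expect_equal(f("L98M"), 0.1)
  expect_equal(f("G147S/L98M"), 0.1)       # both on copy 1 of read a
  expect_equal(f("V162D"), 0.1)
  # absent mutation -> zero everywhere; unknown label -> error
  expect_equal(allele_trajectories(variants, totals, "A4V")$frequency, 0)
  expect_error(allele_trajectories(variants, totals, "Z999Q"), "unknown")
  # combination frequency bounded by every component frequency
  expect_lte(f("G147S/L98M"), f("G147S"))
  expect_lte(f("G147S/L98M"), f("L98M"))
})

test_that("combination frequencies stay below components on simulated data", {
  set.seed(23)
  anc <- cogfp_ancestor()
  pop <- new_population(400, anc, "double")
  for (r in 1:3) pop <- mutagenize(pop, calibrate_nucleotide_rate(anc, 2), 0)
  tc <- truth_calls(pop)
  tc$read_id <- paste0("v", tc$index)
  tc$generation <- 1L; tc$replicate <- 1L
  totals <- tibble::tibble(generation = 1L, replicate = 1L, n_genes = 800L)
  singles <- unique(paste0(tc$ref_aa, tc$protein_position, tc$alt_aa))
  singles <- head(sort(singles), 20)
  tr <- allele_trajectories(tc, totals, singles)
  expect_true(all(tr$frequency >= 0 & tr$frequency <= 1))
  combo <- paste(singles[1], singles[2], sep = "/")
  trc <- allele_trajectories(tc, totals, c(singles[1:2], combo))
  expect_lte(trc$frequency[trc$mutation == combo],
             min(trc$frequency[trc$mutation != combo]))
})

test_that("gating reproduces the negative-control construction", {
  set.seed(14)
  nc <- tibble::tibble(green = rlnorm(20000, 0, 0.3),
                       blue = rlnorm(20000, 0, 0.3))
  g <- gate_and_summarize(nc, nc, quantile = 0.99)
  expect_lt(abs(g$fraction_fluorescent - 1), 0.3)  # ~100*(1-quantile)
  bright <- tibble::tibble(green = nc$green * 10, blue = nc$blue)
  gb <- gate_and_summarize(bright, nc, quantile = 0.999, channel = "green")
  expect_equal(gb$fraction_fluorescent, 100)
  expect_equal(gb$median_green, stats::median(bright$green))
  expect_error(gate_and_summarize(nc[0, ], nc), "empty")
  expect_error(gate_and_summarize(nc, nc, quantile = 1), "quantile")
})

test_that("robustness arithmetic for duplicated genes", {
  expect_equal(predicted_double_copy_loss(1)$percent, 0)
  expect_equal(predicted_double_copy_loss(0)$percent, 100)
  r <- predicted_double_copy_loss(0.26)
  expect_equal(r$percent, 54.76)
  expect_equal(r$display, 55)
  # complementarity: loss + survival of at least one copy = 100%
  for (p in seq(0, 1, by = 0.1))
    expect_equal(predicted_double_copy_loss(p)$percent +
                   100 * (1 - (1 - p)^2), 100)
  expect_equal(duplicate_hit_ratio(1), 1)
  expect_equal(duplicate_hit_ratio(0.5), 1.5)
  z <- duplicate_hit_ratio(0)
  expect_equal(as.numeric(z), 2)
  expect_true(attr(z, "limit"))
  expect_error(duplicate_hit_ratio(2), "p_mut")
})
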