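test_that("nucleotide-rate calibration matches single-codon enumeration", {
  # Met (ATG) has no synonymous single-nt neighbours: all 9 changes are
  # nonsynonymous (verified by bf_ng86_codon), so f_nonsyn = 1 and
  # mu = 1 / (3 * 1) = 1/3.
  expect_equal(unname(bf_ng86_codon("ATG")["S"]), 0)
  atg <- list(coding_dna = "ATG")
  expect_equal(calibrate_nucleotide_rate(atg, 1), 1 / 3)
  expect_equal(calibrate_nucleotide_rate(atg, 0), 0)
  expect_error(calibrate_nucleotide_rate(atg, -1), "non-negative")
})

test_that("calibrated rate yields the requested mean nonsynonymous load", {
  anc <- cogfp_ancestor()
  mu <- calibrate_nucleotide_rate(anc, 2)
  set.seed(101)
  pop <- new_population(20000, anc, "double")
  pop <- mutagenize(pop, mu, q = 0)
  m <- mean(c(pop$last_round$nonsyn1, pop$last_round$nonsyn2))
  expect_lt(abs(m - 2), 0.05)
})

test_that("mutagenize respects its contract", {
  anc <- cogfp_ancestor()
  set.seed(5)
  pop <- new_population(50, anc, "single")
  same <- mutagenize(pop, 0)
  expect_identical(same$dna1, pop$dna1)
  expect_identical(same$state2, pop$state2)
  # expected substitution count: binomial mean mu * L per copy
  set.seed(6)
  pop2 <- new_population(5000, anc, "double")
  pop2 <- mutagenize(pop2, 1e-3, q = 0)
  n_subs <- sum(pop2$dna1 != new_population(5000, anc, "double")$dna1)
  expect_lt(abs(n_subs / 5000 - 0.696), 0.03)
  # engineered-inactive copy mutates but never changes state
  set.seed(7)
  pop3 <- new_population(2000, anc, "single")
  pop3 <- mutagenize(pop3, calibrate_nucleotide_rate(anc, 2), q = 0.668)
  expect_true(all(pop3$state2 == "engineered_inactive"))
  expect_gt(sum(pop3$last_round$nonsyn2), 0)
  expect_error(mutagenize(pop, -0.1), "mu")
})

test_that("single-copy loss rate reproduces the robustness calibration", {
  # with q = 0.668 and ~Poisson(2) nonsynonymous substitutions per copy,
  # a single active copy loses fluorescence with prob 1 - exp(-2q) = 0.737
  anc <- cogfp_ancestor()
  mu <- calibrate_nucleotide_rate(anc, 2)
  set.seed(11)
  pop <- new_population(30000, anc, "single")
  pop <- mutagenize(pop, mu, q = 0.668)
  loss <- mean(pop$state1 != "active")
  expect_lt(abs(loss - (1 - exp(-2 * 0.668))), 0.01)
})

test_that("phenotype model is additive over induced active copies", {
  anc <- cogfp_ancestor()
  model <- phenotype_model()
  dbl <- new_population(3, anc, "double")
  sgl <- new_population(3, anc, "single")
  # negative control: autofluorescence only
  nc <- phenotype(dbl, model, induction = character(0), noise = FALSE)
  expect_equal(nc$green, rep(0.05, 3))
  expect_equal(nc$blue, rep(0.05, 3))
  # one active ancestral copy: base + autofluorescence
  one <- phenotype(dbl, model, induction = "copy1", noise = FALSE)
  expect_equal(one$green, rep(1.05, 3))
  # single-copy plasmid under full induction: copy 2 is engineered inactive
  s <- phenotype(sgl, model, noise = FALSE)
  expect_equal(s$green, rep(1.05, 3))
  # dosage: double-copy signal is twice the single-copy signal (before
  # autofluorescence), ratio (2.05)/(1.05)
  d <- phenotype(dbl, model, noise = FALSE)
  expect_equal(d$green / s$green, rep(2.05 / 1.05, 3))
  # key-mutation effects are multiplicative on the carrying copy
  mut <- new_population(1, anc, "double")
  x <- anc$coding_dna
  substr(x, 3 * 147 - 2, 3 * 147) <- "AGC"  # G147S
  mut$dna1 <- matrix(match(strsplit(x, "")[[1]], c("A", "C", "G", "T")),
                     nrow = 1)
  m <- phenotype(mut, model, induction = "copy1", noise = FALSE)
  expect_equal(m$green, 0.05 + 2)   # green x2
  expect_equal(m$blue, 0.05 + 0.5)  # blue x0.5
})

test_that("truncation selection keeps the top-ranked cells", {
  ev <- tibble::tibble(cell_id = 1:10, green = 1:10, blue = 10:1,
                       induction = "copy1+copy2")
  set.seed(1)
  expect_setequal(select_survivors(ev, "green", 0.2), c(9, 10))
  expect_setequal(select_survivors(ev, "blue", 0.2), c(1, 2))
  expect_setequal(select_survivors(ev, "green", 1), 1:10)
  # survivors' minimum selected-channel value >= (1 - fraction) quantile
  set.seed(2)
  ev2 <- tibble::tibble(green = rlnorm(500), blue = rlnorm(500))
  for (f in c(0.5, 0.1, 0.02)) {
    idx <- select_survivors(ev2, "green", f)
    expect_length(idx, round(f * 500))
    expect_gte(min(ev2$green[idx]),
               stats::quantile(ev2$green, 1 - f, names = FALSE))
  }
  # joint gate: survivors must be strong in their weaker channel
  idx <- select_survivors(ev2, "green_and_blue", 0.1)
  worst <- pmin(rank(ev2$green), rank(ev2$blue))
  expect_length(idx, 50)
  expect_gte(min(worst[idx]), sort(worst, decreasing = TRUE)[60])
  # counter-selection: survivors lie below the opposite channel's gate
  thr <- c(green = 1, blue = 1)
  idx <- select_survivors(ev2, "green_only", 0.05, thr)
  expect_true(all(ev2$blue[idx] <= 1))
  # no_selection is a seeded uniform sample
  set.seed(3); a <- select_survivors(ev2, "no_selection", 0.5)
  set.seed(3); b <- select_survivors(ev2, "no_selection", 0.5)
  expect_identical(a, b)
  expect_length(a, 250)
  expect_error(select_survivors(ev2[0, ], "green", 0.5), "empty")
  expect_error(select_survivors(ev2, "green", 0), "fraction")
})

test_that("re-cloning swaps promoters as a Bernoulli event", {
  anc <- cogfp_ancestor()
  pop <- new_population(10000, anc, "double")
  expect_identical(reclone(pop, 0)$promoter1, pop$promoter1)
  sw <- reclone(pop, 1)
  expect_true(all(sw$promoter1 == "Ptac"))
  expect_identical(reclone(sw, 1)$promoter1, pop$promoter1)  # involution
  set.seed(21)
  half <- reclone(pop, 0.5)
  expect_lt(abs(mean(half$promoter1 == "Ptac") - 0.5), 0.02)
})

test_that("run_experiment is deterministic and honours generations = 0", {
  cfg <- simulator_config(population_size = 300, generations = 2,
                          survival_fractions = c(0.6, 0.1), seed = 99,
                          sample_size = 20)
  a <- run_experiment(cfg)
  b <- run_experiment(cfg)
  expect_identical(as.character(a$generations$g1$reads),
                   as.character(b$generations$g1$reads))
  expect_identical(a$generations$g2$events, b$generations$g2$events)
  expect_identical(a$generations$g2$truth, b$generations$g2$truth)
  cfg0 <- simulator_config(population_size = 50, generations = 0,
                           survival_fractions = numeric(0), seed = 1,
                           sample_size = 10)
  z <- run_experiment(cfg0)
  expect_named(z$generations, "g0")
  anc <- cogfp_ancestor()
  expect_true(all(vapply(seq_len(10), function(i)
    grepl(anc$spacer, as.character(z$generations$g0$reads[i]), fixed = TRUE) ||
      grepl(revcomp(anc$spacer), as.character(z$generations$g0$reads[i]),
            fixed = TRUE), logical(1))))
  expect_equal(sum(z$generations$g0$truth$n_nonsyn[
    z$generations$g0$truth$copy == 1]), 0)
})

test_that("configuration validation catches inconsistent settings", {
  expect_error(simulator_config(generations = 3,
                                survival_fractions = c(0.5, 0.5)),
               "one entry per generation")
  expect_error(simulator_config(survival_fractions = c(0.6, 0, 1, 1, 1)),
               "fractions")
  expect_error(simulator_config(inactivation_prob = 1), "inactivation_prob")
  expect_error(phenotype_model(noise_cv = -1), "noise_cv")
})
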