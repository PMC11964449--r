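test_that("frequency filter is inclusive at the threshold", {
  traj <- tibble::tibble(
    regime = rep(c("blue_only", "green_only"), each = 9),
    replicate = rep(1:3, times = 6),
    generation = 5L,
    mutation = rep(rep(c("G147S", "V162D", "L98M"), each = 3), 2),
    frequency = c(0.05, 0.01, 0.0,   0.2, 0.0, 0.0,   0.01, 0.02, 0.049,
                  0.0,  0.0,  0.0,   0.0, 0.3, 0.0,   0.0,  0.0,  0.0))
  expect_setequal(frequency_filter(traj), c("G147S", "V162D"))
  expect_identical(frequency_filter(traj, min_freq = 0.25), "V162D")
  low <- traj; low$frequency <- low$frequency / 100
  expect_length(frequency_filter(low), 0)
  expect_error(frequency_filter(traj, final_generation = 7), "final")
})

test_that("binomial LRT matches a numeric likelihood-maximisation oracle", {
  # identical proportions: statistic 0, p = 1
  r0 <- lrt_binomial(10, 100, 20, 200)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
  r <- lrt_binomial(30, 100, 10, 100)
  expect_lt(abs(r$statistic - bf_lrt(30, 100, 10, 100)), 1e-6)
  set.seed(55)
  for (i in 1:10) {
    n1 <- sample(20:300, 1); n2 <- sample(20:300, 1)
    k1 <- sample(seq_len(n1 - 1), 1); k2 <- sample(seq_len(n2 - 1), 1)
    expect_lt(abs(lrt_binomial(k1, n1, k2, n2)$statistic -
                    bf_lrt(k1, n1, k2, n2)), 1e-6,
              label = sprintf("(%d/%d vs %d/%d)", k1, n1, k2, n2))
  }
  # zero-count groups use the 0*log(0) = 0 convention
  expect_equal(lrt_binomial(0, 50, 0, 60)$statistic, 0)
  expect_gt(lrt_binomial(0, 50, 30, 60)$statistic, 0)
  expect_error(lrt_binomial(5, 0, 1, 10), "positive")
  expect_error(lrt_binomial(11, 10, 1, 10), "counts")
})

test_that("LRT agrees with glm analysis of deviance and with Pearson chi-square", {
  cases <- list(c(30, 100, 10, 100), c(12, 80, 25, 90), c(40, 200, 70, 210))
  for (cs in cases) {
    k1 <- cs[1]; n1 <- cs[2]; k2 <- cs[3]; n2 <- cs[4]
    fit <- stats::glm(cbind(c(k1, k2), c(n1 - k1, n2 - k2)) ~ factor(c(1, 2)),
                      family = stats::binomial())
    dev <- stats::anova(fit, test = "LRT")
    mine <- lrt_binomial(k1, n1, k2, n2)
    expect_equal(mine$statistic, dev$Deviance[2], tolerance = 1e-8)
    expect_equal(mine$p_value, dev$`Pr(>Chi)`[2], tolerance = 1e-8)
    # asymptotic agreement with Pearson chi-square (expected counts >= 20)
    chi <- suppressWarnings(stats::chisq.test(
      matrix(c(k1, n1 - k1, k2, n2 - k2), 2, byrow = TRUE),
      correct = FALSE)$statistic)
    expect_lt(abs(mine$statistic - chi) / chi, 0.1)
  }
})

test_that("LRT is symmetric under group relabelling", {
  a <- lrt_binomial(30, 100, 10, 120)
  b <- lrt_binomial(10, 120, 30, 100)
  expect_equal(a$statistic, b$statistic)
  expect_equal(a$p_value, b$p_value)
})

test_that("null simulation keeps the type-I error near nominal", {
  set.seed(66)
  B <- 4000; n <- 200; p <- 0.3
  k1 <- stats::rbinom(B, n, p); k2 <- stats::rbinom(B, n, p)
  r <- lrt_binomial(k1, n, k2, n)
  expect_lt(abs(mean(r$p_value < 0.05) - 0.05), 0.012)
})

make_regime_tables <- function(freqs, n_per_rep, reps = 3, seed = 1) {
  # freqs: named per-mutation true frequencies; draws independent carriers
  set.seed(seed)
  rows <- list(); totals <- list()
  muts <- names(freqs)
  info <- parse_mutation_labels(muts)
  for (r in seq_len(reps)) {
    for (m in seq_along(muts)) {
      carriers <- which(stats::runif(n_per_rep) < freqs[m])
      if (length(carriers) > 0)
        rows[[length(rows) + 1]] <- tibble::tibble(
          generation = 5L, replicate = r,
          read_id = paste0("r", r, "_", carriers), copy = 1L,
          protein_position = info$pos[m], ref_aa = info$ref[m],
          alt_aa = info$alt[m], synonymous = FALSE)
    }
    totals[[r]] <- tibble::tibble(generation = 5L, replicate = r,
                                  n_genes = n_per_rep)
  }
  list(variants = dplyr::bind_rows(rows), totals = dplyr::bind_rows(totals))
}

test_that("enrichment scan recovers a planted signal and respects Bonferroni", {
  anc <- cogfp_ancestor()
  aa <- strsplit(anc$protein, "")[[1]]
  muts_at <- function(pos) paste0(aa[pos], pos, ifelse(aa[pos] == "A", "V", "A"))
  labels <- vapply(c(10, 20, 30, 40, 147), muts_at, character(1))
  # planted: the position-147 mutation much commoner under blue-only
  f_blue <- stats::setNames(c(0.10, 0.12, 0.08, 0.11, 0.40), labels)
  f_green <- stats::setNames(c(0.10, 0.12, 0.08, 0.11, 0.06), labels)
  b <- make_regime_tables(f_blue, 400, seed = 2)
  g <- make_regime_tables(f_green, 400, seed = 3)
  res <- enrichment_scan(b$variants, b$totals, g$variants, g$totals)
  planted <- labels[5]
  expect_identical(res$enriched_in[res$mutation == planted], "blue_only")
  expect_true(all(res$enriched_in[res$mutation != planted] == "none"))
  expect_true(all(res$p_adjusted >= res$p_value))
  expect_true(all(res$p_adjusted <= 1))
  expect_true(all(res$lrt_statistic >= 0))
  # Bonferroni monotone in p
  ord <- order(res$p_value)
  expect_true(all(diff(res$p_adjusted[ord]) >= -1e-12))
})

test_that("enrichment scan edge cases", {
  # all frequencies below the filter -> empty result
  f <- stats::setNames(c(0.01, 0.02), c("A10V", "A20V"))
  anc <- cogfp_ancestor()
  aa <- strsplit(anc$protein, "")[[1]]
  labels <- paste0(aa[c(10, 20)], c(10, 20), "V")
  f <- stats::setNames(c(0.01, 0.02), labels)
  b <- make_regime_tables(f, 300, seed = 4)
  g <- make_regime_tables(f, 300, seed = 5)
  res <- enrichment_scan(b$variants, b$totals, g$variants, g$totals)
  expect_equal(nrow(res), 0)
  # double-copy tables refused unless explicitly allowed
  expect_error(enrichment_scan(b$variants, b$totals, g$variants, g$totals,
                               copy_mode = "double"), "allow_double")
  expect_warning(
    enrichment_scan(b$variants, b$totals, g$variants, g$totals,
                    copy_mode = "double", allow_double = TRUE),
    "double-copy")
  # Bonferroni arithmetic: m tests at raw p = 0.01 with m = 10 cannot pass
  p_adj <- pmin(1, rep(0.01, 10) * 10)
  expect_true(all(p_adj >= 0.05))
})
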