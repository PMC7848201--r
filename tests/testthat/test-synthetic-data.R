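test_that("gen_design produces the stated layout deterministically", {
  cfg <- sim_config(seed = 1)
  d <- gen_design(cfg)
  expect_equal(nrow(d), 30L)
  expect_true(all(table(d$state) == 5L))
  expect_false(anyDuplicated(d$sample) > 0)
  # near-balanced sexes within each state
  sex_tab <- table(d$state, d$sex)
  expect_true(all(abs(sex_tab[, "F"] - sex_tab[, "M"]) <= 1))
  # determinism
  expect_identical(d, gen_design(sim_config(seed = 1)))
  expect_false(identical(d$sex, gen_design(sim_config(seed = 2))$sex))
  # smaller design
  expect_equal(nrow(gen_design(sim_config(n_per_state = 2))), 12L)
})

test_that("sim_config rejects invalid fields by name", {
  expect_error(sim_config(n_per_state = 1), "n_per_state")
  expect_error(sim_config(dispersion = 0), "dispersion")
  expect_error(sim_config(cluster_fractions = c(Winter_high = 1.2)),
               "cluster_fractions")
  expect_error(sim_config(cluster_fractions = c(NoSuchTemplate = 0.1)),
               "NoSuchTemplate")
})

test_that("gen_counts honors truth labels, fractions, and determinism", {
  s <- small_sim(seed = 4, n_genes = 500)
  expect_true(all(s$counts >= 0))
  expect_identical(sort(s$truth$gene), sort(rownames(s$counts)))
  expect_equal(sum(s$truth$template == "null"), 500 - 10 * round(0.06 * 500))
  s2 <- small_sim(seed = 4, n_genes = 500)
  expect_identical(s$counts, s2$counts)
  # amplitude 0 => all genes effectively null
  s0 <- small_sim(seed = 4, n_genes = 50, amplitude = 0)
  m <- state_means(transform_counts(s0$counts, s0$size_factors), s0$design)
  expect_lt(max(apply(m, 1, function(x) diff(range(x)))), 2)
})

test_that("planted template genes correlate with their template", {
  s <- small_sim(seed = 9, n_genes = 300)
  expr <- transform_counts(s$counts, size_factors(s$counts))
  m <- state_means(expr, s$design)
  tpl <- reference_templates()
  wh <- s$truth$gene[s$truth$template == "Winter_high"]
  r <- vapply(wh, function(g) {
    stats::cor(m[g, colnames(tpl)], tpl["Winter_high", ])
  }, numeric(1))
  expect_gt(mean(r > 0.8), 0.9)
})

test_that("NB moments hold for replicated null genes", {
  # one state, many replicates, null genes: var ~= mu + d mu^2
  cfg <- sim_config(seed = 2, n_per_state = 1000L, states = "SA",
                    n_genes = 20L,
                    cluster_fractions = setNames(numeric(0), character(0)),
                    sex_effect_sd = 0, libsize_factor_range = c(1, 1),
                    dispersion = 0.1, baseline_logmean_range = c(7, 7))
  d <- gen_design(cfg)
  sim <- gen_counts(d, cfg)
  mu <- rowMeans(sim$counts)
  v <- apply(sim$counts, 1, var)
  expected <- mu + 0.1 * mu^2
  expect_true(all(abs(v / expected - 1) < 0.35))
})

test_that("gen_lsv_counts plants PSI and conserves coverage", {
  cfg <- sim_config(seed = 5)
  d <- gen_design(cfg)
  lsv <- gen_lsv_counts(d, 30, coverage_mean = 200, config = cfg)
  # per-sample counts within an LSV sum to a (Poisson) total; just check
  # they are non-negative integers and truth covers every LSV exactly once
  expect_true(all(lsv$lsv_counts$count >= 0))
  expect_identical(sort(unique(lsv$lsv_counts$lsv_id)),
                   sort(lsv$truth$lsv_id))
  expect_false(anyDuplicated(lsv$truth$lsv_id) > 0)
  # planted dPSI by construction
  tr <- lsv$truth
  expect_true(all(tr$dpsi_max[tr$template == "cold_drop"] == 0.5))
  expect_true(all(tr$dpsi_max[tr$template == "null"] == 0))
  # degenerate coverage: emitted but all-zero
  lsv0 <- gen_lsv_counts(d, 3, coverage_mean = 0, config = cfg)
  expect_true(all(lsv0$lsv_counts$count == 0))
  # bad PSI template rejected
  bad <- list(x = list(psi = matrix(0.4, 2, 6,
                                    dimnames = list(NULL, cfg$states)),
                       retained_intron = NA, fraction = 1))
  expect_error(gen_lsv_counts(d, 3, bad, 100, cfg), "sum to 1")
})

test_that("gen_sequences plants pentamers, GC and motifs as stated", {
  g <- gen_sequences(5, 1000, planted = list(gc = 0.5, n_pentamers = 0),
                     seed = 3)
  expect_false(any(grepl("ATTTA", g$sequences, fixed = TRUE)))
  # GC within tolerance at length 1e4
  g2 <- gen_sequences(3, 10000, planted = list(gc = 0.5), seed = 3)
  expect_true(all(abs(gc_content(g2$sequences) - 0.5) < 0.02))
  g3 <- gen_sequences(2, 10000, planted = list(gc = 0.7), seed = 3)
  expect_true(all(abs(gc_content(g3$sequences) - 0.7) < 0.02))
  # planted pentamers found exactly (spacing 20 nt: isolated)
  g4 <- gen_sequences(4, 2000, planted = list(n_pentamers = 3), seed = 8)
  utr <- extract_region(g4$sequences, g4$regions, "3UTR")
  sc <- are_score(utr)
  expect_true(all(sc$n_pentamer == 3))
  # planted motif found at least the planted number of times
  g5 <- gen_sequences(3, 2000,
                      planted = list(motif = "TAGCTAG", n_motif = 3),
                      seed = 2)
  expect_true(all(motif_scan(g5$sequences, "TAGCTAG")$count >= 3))
  # region table covers the sequence without overlap
  r <- g5$regions[g5$regions$transcript == "tx001", ]
  expect_equal(sum(r$end - r$start + 1), 2000)
  # error on oversized planted element
  expect_error(gen_sequences(1, 3, planted = list(n_pentamers = 1)),
               "longer than sequence")
})
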