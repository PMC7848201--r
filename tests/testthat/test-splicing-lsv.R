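two_junction_lsv <- function(counts_by_state, retained = c(FALSE, FALSE),
                             lsv_id = "L1") {
  # counts_by_state: named list state -> c(j1, j2); one sample per state
  rows <- lapply(names(counts_by_state), function(st) {
    data.frame(lsv_id = lsv_id, gene_id = "g1",
               junction_id = c("j1", "j2"), is_retained_intron = retained,
               sample = paste0(st, "_1"), count = counts_by_state[[st]],
               stringsAsFactors = FALSE)
  })
  lsv <- do.call(rbind, rows)
  design <- data.frame(sample = paste0(names(counts_by_state), "_1"),
                       state = names(counts_by_state), sex = "F",
                       stringsAsFactors = FALSE)
  list(lsv = lsv, design = design)
}

test_that("Dirichlet posterior means match the closed form", {
  x <- two_junction_lsv(list(SA = c(100L, 0L)))
  psi <- estimate_psi(x$lsv, x$design, splice_config())
  expect_equal(unname(psi[["L1"]]$psi["j1", "SA"]), 100.5 / 101)
  expect_equal(unname(psi[["L1"]]$psi["j2", "SA"]), 0.5 / 101)
  # symmetric counts -> 0.5
  y <- two_junction_lsv(list(SA = c(50L, 50L)))
  psi_y <- estimate_psi(y$lsv, y$design, splice_config())
  expect_equal(unname(psi_y[["L1"]]$psi[, "SA"]), c(0.5, 0.5))
})

test_that("PSI means sum to 1 within every LSV-state", {
  cfg <- sim_config(seed = 15)
  d <- gen_design(cfg)
  lsv <- gen_lsv_counts(d, 25, coverage_mean = 50, config = cfg)
  psi <- estimate_psi(lsv$lsv_counts, d, splice_config(seed = 15))
  for (rec in psi) {
    expect_true(all(abs(colSums(rec$psi) - 1) < 1e-9))
  }
})

test_that("dpsi_test: antisymmetry, power, and tiny-count humility", {
  cfg <- splice_config(seed = 2, mc_samples = 4000)
  x <- two_junction_lsv(list(SA = c(90L, 10L), LT = c(30L, 70L)))
  psi <- estimate_psi(x$lsv, x$design, cfg)
  ab <- dpsi_test(psi[["L1"]], "SA", "LT", cfg)
  ba <- dpsi_test(psi[["L1"]], "LT", "SA", cfg)
  expect_equal(ab$per_junction$e_dpsi, -ba$per_junction$e_dpsi)
  expect_equal(ab$per_junction$e_dpsi[1],
               unname(psi[["L1"]]$psi["j1", "LT"] -
                        psi[["L1"]]$psi["j1", "SA"]))
  expect_true(ab$significant)
  # identical PSI, good coverage -> not significant
  z <- two_junction_lsv(list(SA = c(50L, 50L), LT = c(50L, 50L)))
  psz <- estimate_psi(z$lsv, z$design, cfg)
  expect_false(dpsi_test(psz[["L1"]], "SA", "LT", cfg)$significant)
  # 2 total reads: posterior too wide regardless of the gap
  tiny <- two_junction_lsv(list(SA = c(1L, 0L), LT = c(0L, 1L)))
  pst <- estimate_psi(tiny$lsv, tiny$design, cfg)
  expect_false(dpsi_test(pst[["L1"]], "SA", "LT", cfg)$significant)
  # all-zero state flagged uninformative
  zz <- two_junction_lsv(list(SA = c(0L, 0L), LT = c(10L, 10L)))
  psu <- estimate_psi(zz$lsv, zz$design, cfg)
  expect_false(psu[["L1"]]$informative["SA"])
  expect_false(dpsi_test(psu[["L1"]], "SA", "LT", cfg)$informative)
})

test_that("posterior width shrinks with coverage on average", {
  cfg <- splice_config(seed = 4, mc_samples = 2000)
  set.seed(4)
  widths <- vapply(c(10L, 100L, 1000L), function(cov) {
    x <- two_junction_lsv(list(SA = c(cov, cov)))
    rec <- estimate_psi(x$lsv, x$design, cfg)[["L1"]]
    draws <- torportx:::rdirichlet(2000, rec$alpha[, "SA"])
    diff(stats::quantile(draws[, 1], c(0.025, 0.975)))
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("dominant_junction follows reference PSI with stated tie-break", {
  cfg <- splice_config()
  x <- two_junction_lsv(list(SA = c(70L, 30L)))
  psi <- estimate_psi(x$lsv, x$design, cfg)
  expect_equal(as.character(dominant_junction(psi[["L1"]], cfg)), "j1")
  # exact tie -> smaller id, flagged
  y <- two_junction_lsv(list(SA = c(50L, 50L)))
  dj <- dominant_junction(estimate_psi(y$lsv, y$design, cfg)[["L1"]], cfg)
  expect_equal(as.character(dj), "j1")
  expect_true(attr(dj, "tie"))
  # retained intron can be dominant
  z <- two_junction_lsv(list(SA = c(80L, 20L)), retained = c(TRUE, FALSE))
  expect_equal(as.character(
    dominant_junction(estimate_psi(z$lsv, z$design, cfg)[["L1"]], cfg)), "j1")
})

test_that("classify_intron_retention orients by reference-state PSI", {
  cfg <- splice_config()
  a <- two_junction_lsv(list(SA = c(60L, 40L)), retained = c(TRUE, FALSE))
  ra <- estimate_psi(a$lsv, a$design, cfg)[["L1"]]
  expect_equal(as.character(classify_intron_retention(ra, cfg)),
               "retained-default")
  b <- two_junction_lsv(list(SA = c(20L, 80L)), retained = c(TRUE, FALSE))
  rb <- estimate_psi(b$lsv, b$design, cfg)[["L1"]]
  expect_equal(as.character(classify_intron_retention(rb, cfg)),
               "excised-default")
  d <- two_junction_lsv(list(SA = c(50L, 50L)), retained = c(TRUE, FALSE))
  rd <- estimate_psi(d$lsv, d$design, cfg)[["L1"]]
  cl <- classify_intron_retention(rd, cfg)
  expect_equal(as.character(cl), "retained-default")
  expect_true(attr(cl, "tie"))
})

test_that("dPSI pattern clustering orients to the reference and recovers", {
  cfg <- sim_config(seed = 33)
  d <- gen_design(cfg)
  scfg <- splice_config(seed = 33)
  lsv <- gen_lsv_counts(d, 60, coverage_mean = 100, config = cfg)
  psi <- estimate_psi(lsv$lsv_counts, d, scfg)
  sig <- dpsi_all_pairs(psi, scfg)
  sig_ids <- sig$lsv_id[sig$significant]
  cl <- cluster_dpsi_patterns(psi, sig_ids, config = scfg)
  # SA entry is exactly 0 for every profile
  expect_true(all(cl$profiles[, "SA"] == 0))
  # planted cold drops of the dominant junction land in a Cold_low cluster
  cold_ids <- lsv$truth$lsv_id[lsv$truth$template == "cold_drop"]
  dom <- cl$assignments[cl$assignments$unit %in%
                          paste0(cold_ids, ":dominant"), ]
  expect_gt(mean(grepl("^Cold_low", dom$cluster)), 0.9)
  # a flat (null) profile would be Unassigned
  flat_ids <- intersect(sig_ids, lsv$truth$lsv_id[lsv$truth$template == "null"])
  expect_length(flat_ids, 0L)
})

test_that("temperature gate and control-intron selection", {
  cfg <- sim_config(seed = 44)
  d <- gen_design(cfg)
  scfg <- splice_config(seed = 44)
  lsv <- gen_lsv_counts(d, 60, coverage_mean = 100, config = cfg)
  psi <- estimate_psi(lsv$lsv_counts, d, scfg)
  temp_dep <- temperature_dependent_irs(psi, scfg)
  tr <- lsv$truth
  planted_ir <- tr$lsv_id[tr$template == "ir_warm_default"]
  null_ir <- tr$lsv_id[tr$template == "ir_null"]
  expect_true(all(planted_ir %in% temp_dep))
  expect_false(any(null_ir %in% temp_dep))
  ctrl <- select_control_introns(psi, scfg, significant_ids = temp_dep)
  # controls are exactly the non-significant, non-overlapping introns
  expect_setequal(ctrl$name, null_ir)
  # a control overlapping a significant intron is excluded: clone coords
  rec <- psi[[null_ir[1]]]
  psi2 <- psi
  psi2[[null_ir[1]]]$junctions$start <-
    psi[[planted_ir[1]]]$junctions$start
  psi2[[null_ir[1]]]$junctions$end <- psi[[planted_ir[1]]]$junctions$end
  ctrl2 <- select_control_introns(psi2, scfg, significant_ids = temp_dep)
  expect_false(null_ir[1] %in% ctrl2$name)
})
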