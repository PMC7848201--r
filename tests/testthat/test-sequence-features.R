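test_that("gc_content handles case, N bases, and reverse complement", {
  expect_equal(unname(gc_content("GGCC")), 1.0)
  expect_equal(unname(gc_content("ATGC")), 0.5)
  expect_equal(unname(gc_content("ANT")), 0.0)
  expect_equal(unname(gc_content("atgc")), 0.5)
  expect_true(is.na(gc_content("NNN")))
  set.seed(7)
  s <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE),
             collapse = "")
  rc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s)))
  expect_equal(gc_content(s), gc_content(rc))
})

test_that("are_score: hand-enumerated cases, gates, and monotonicity", {
  pad <- function(core, len = 300) {
    filler <- paste(rep("GC", ceiling((len - nchar(core)) / 2)),
                    collapse = "")
    paste0(substr(filler, 1, len - nchar(core)), core)
  }
  # no pentamer -> 0, "no ARE"
  r0 <- are_score(c(a = pad("")))
  expect_equal(r0$score, 0)
  expect_equal(r0$class, "no ARE")
  # ATTTATTTA: two overlapping pentamers, start distance 4 -> clustered
  r1 <- are_score(c(a = pad("ATTTATTTA")))
  expect_equal(r1$n_pentamer, 2L)
  expect_equal(r1$n_cluster, 1L)
  expect_equal(r1$score, 2 + 1.5)
  # short UTR excluded regardless of content
  r2 <- are_score(c(a = strrep("ATTTA", 30)), are_config(min_utr_len = 200))
  expect_equal(are_score(c(a = substr(strrep("ATTTA", 30), 1, 150)))$class,
               "excluded")
  # +1 per isolated pentamer; cluster bonus exactly on adjacency
  iso1 <- pad(paste0("ATTTA", strrep("G", 20), "ATTTA"))
  iso2 <- pad(paste0("ATTTA", strrep("G", 20), "ATTTA",
                     strrep("G", 20), "ATTTA"))
  expect_equal(are_score(c(a = iso2))$score - are_score(c(a = iso1))$score, 1)
  adj <- pad(paste0("ATTTA", strrep("G", 9), "ATTTA"))   # gap 9 -> clustered
  far <- pad(paste0("ATTTA", strrep("G", 10), "ATTTA"))  # gap 10 -> not
  expect_equal(are_score(c(a = adj))$score - are_score(c(a = far))$score, 1.5)
  # high-ARE class at score >= 8
  many <- pad(strrep(paste0("ATTTA", strrep("G", 20)), 8), 400)
  expect_equal(are_score(c(a = many))$class, "high ARE")
  # invalid characters rejected
  expect_error(are_score(c(a = pad("ATTXA"))), "non-ACGTN")
})

test_that("motif_scan counts IUPAC matches with overlap", {
  expect_equal(motif_scan(c(s = "ATGATG"), "ATG")$count, 2L)
  expect_equal(motif_scan(c(s = "ACAT"), "AY")$count, 2L)
  expect_equal(motif_scan(c(s = "AAAA"), "AA")$count, 3L)  # overlapping
  expect_equal(motif_scan(c(s = strrep("ATG", 10)), "ATG")$density_per_kb,
               10 * 1000 / 30)
  expect_error(motif_scan(c(s = "ACGT"), "AXZ"), "IUPAC")
  expect_error(motif_scan(c(s = "ACGT"), ""), "empty")
})

test_that("Fisher p equals brute-force hypergeometric enumeration", {
  set.seed(11)
  for (i in 1:40) {
    a <- sample(0:12, 1); b <- sample(0:12, 1)
    c_ <- sample(0:12, 1); d <- sample(0:12, 1)
    if (a + b == 0 || c_ + d == 0 || a + c_ == 0 || b + d == 0) next
    expect_equal(torportx:::fisher_2x2(a, b, c_, d)$p,
                 fisher_oracle(a, b, c_, d), tolerance = 1e-9)
  }
})

test_that("kmer_enrichment finds the planted k-mer and is symmetric", {
  set.seed(5)
  rand_seq <- function(n, len) {
    vapply(seq_len(n), function(i) {
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
            collapse = "")
    }, character(1))
  }
  fg <- rand_seq(60, 50)
  bg <- rand_seq(60, 50)
  plant <- "GGGGCGC"
  fg[1:54] <- paste0(plant, substr(fg[1:54], 8, 50))   # 90% of foreground
  bg[1:6] <- paste0(plant, substr(bg[1:6], 8, 50))     # 10% of background
  res <- kmer_enrichment(fg, bg, k = 7)
  expect_equal(res$kmer[1], plant)
  # symmetry: swapping sets inverts the odds ratio ranking direction
  res_sw <- kmer_enrichment(bg, fg, k = 7)
  or1 <- res$odds_ratio[res$kmer == plant]
  or2 <- res_sw$odds_ratio[res_sw$kmer == plant]
  expect_gt(or1, 1)
  expect_lt(or2, 1)
  # identical sets -> no enrichment signal
  same <- kmer_enrichment(fg[1:20], fg[1:20], k = 3)
  expect_true(all(same$qvalue > 0.05))
  expect_true(all(abs(same$odds_ratio[is.finite(same$odds_ratio)] - 1) <
                    1e-6))
})

test_that("cluster_feature_fisher detects a seeded class skew", {
  set.seed(13)
  bg <- paste0("g", 1:400)
  # cluster A: 120 genes, 80% "no ARE"; background rate 50%
  clA <- bg[1:120]
  classes <- setNames(ifelse(seq_along(bg) <= 120,
                             ifelse(seq_len(400) <= 96, "no ARE", "high ARE"),
                             sample(c("no ARE", "high ARE"), 400,
                                    replace = TRUE)[seq_len(400)]), bg)
  classes[121:400] <- sample(c("no ARE", "high ARE"), 280, replace = TRUE)
  asg <- data.frame(unit = clA, cluster = "A", stringsAsFactors = FALSE)
  res <- cluster_feature_fisher(asg, classes, bg)
  row <- res[res$cluster == "A" & res$class == "no ARE", ]
  expect_lt(row$pvalue, 0.01)
  # table margins consistent
  expect_equal(row$in_cluster_in_class + row$in_cluster_other, 120)
  expect_equal(row$bg_in_class + row$bg_other, 280)
})

test_that("wilcoxon_compare matches the exact enumerated p", {
  expect_equal(wilcoxon_compare(c(1, 2, 3), c(4, 5, 6)), 0.1)
  expect_equal(wilcoxon_compare(1, 1), 1)
  expect_error(wilcoxon_compare(numeric(0), 1), "empty")
  # null simulation: roughly uniform p
  set.seed(3)
  p <- replicate(300, wilcoxon_compare(rnorm(12), rnorm(12)))
  expect_gt(suppressWarnings(ks.test(p, "punif")$p.value), 0.01)
})

test_that("go_enrichment ranks a fully recovered term first", {
  bg <- paste0("g", 1:200)
  gmt <- list(TERM_A = bg[1:20], TERM_B = bg[51:100], TERM_C = bg[101:120])
  res <- go_enrichment(bg[1:20], gmt, bg)
  expect_equal(res$term[1], "TERM_A")
  expect_lt(res$pvalue[1], 1e-10)
  # background changes margins deterministically
  res2 <- go_enrichment(bg[1:20], gmt, bg[1:100])
  rowA <- res2[res2$term == "TERM_A", ]
  expect_equal(rowA$set_in_term + rowA$bg_in_term, 20)
  expect_equal(rowA$set_in_term + rowA$set_out_term +
                 rowA$bg_in_term + rowA$bg_out_term, 100)
  expect_error(go_enrichment(c("zzz"), gmt, bg), "disjoint")
})

test_that("GMT round-trip via read_gmt", {
  tmp <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("T1\tdesc\tg1\tg2\tg3", "T2\tdesc\tg4"), tmp)
  g <- read_gmt(tmp)
  expect_equal(g, list(T1 = c("g1", "g2", "g3"), T2 = "g4"))
  writeLines("bad_line_only_two\tfields", tmp)
  expect_error(read_gmt(tmp), "malformed")
})
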