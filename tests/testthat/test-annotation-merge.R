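mini_set <- function() {
  rbind(
    tx_set("A", "GA", "chr1", "+", c(100, 300), c(200, 400)),
    tx_set("B", "GB", "chr1", "+", 200, 300),
    tx_set("C", "GC", "chr1", "-", c(100, 300), c(200, 400)),
    tx_set("D", "GD", "chr2", "+", 100, 200))
}

test_that("exon_overlap respects half-open intervals and strand", {
  s <- mini_set()
  expect_true(exon_overlap(s, "A", "A"))
  # [100,200) and [200,300) are adjacent, not overlapping
  expect_false(exon_overlap(s, "A", "B"))
  # same intervals, opposite strand
  expect_false(exon_overlap(s, "A", "C"))
  # different chrom
  expect_false(exon_overlap(s, "A", "D"))
})

test_that("reciprocal_overlap matches per-base set intersection", {
  s <- rbind(tx_set("X", "GX", "chr1", "+", 100, 200),
             tx_set("Y", "GY", "chr1", "+", 150, 250),
             tx_set("Z", "GZ", "chr1", "+", 500, 600))
  expect_equal(reciprocal_overlap(s, "X", "X"), 1.0)
  expect_equal(reciprocal_overlap(s, "X", "Y"), 0.5)
  expect_equal(reciprocal_overlap(s, "X", "Z"), 0.0)
  # oracle: per-base intersection on random multi-exon transcripts
  set.seed(42)
  for (i in 1:20) {
    st1 <- sort(sample(1:500, 2)) * c(1, 1)
    a <- tx_set("a", "ga", "chr1", "+",
                c(st1[1], st1[2] + 200), c(st1[1] + 100, st1[2] + 300))
    st2 <- sort(sample(1:500, 1))
    b <- tx_set("b", "gb", "chr1", "+", st2, st2 + sample(50:400, 1))
    s2 <- rbind(a, b)
    bases_a <- unlist(Map(seq, a$start, a$end - 1))
    bases_b <- unlist(Map(seq, b$start, b$end - 1))
    sh <- length(intersect(bases_a, bases_b))
    oracle <- min(sh / length(bases_a), sh / length(bases_b))
    expect_equal(reciprocal_overlap(s2, "a", "b"), oracle)
  }
})

test_that("supplement rules keep/drop as stated", {
  fx <- gen_annotation_fixture()
  m <- supplement_secondary(fx$primary, fx$secondary)
  kept <- tx_ids(m)
  expect_true(all(c("S1", "S2") %in% kept))   # no-overlap; short RO 0.40
  expect_false(any(c("S3", "S4", "S5") %in% kept))
  prov <- attr(m, "provenance")
  expect_match(prov[["S3"]][["reason"]], "reciprocal_overlap")
  expect_equal(prov[["S1"]][["reason"]], "no_exon_overlap")
  # duplicate ids across sources rejected
  expect_error(supplement_secondary(fx$primary, fx$primary), "duplicate")
})

test_that("integrate_novel is the identity on an empty incoming set", {
  fx <- gen_annotation_fixture()
  m <- supplement_secondary(fx$primary, fx$secondary)
  empty <- fx$novel[0, ]
  m2 <- integrate_novel(m, empty)
  expect_identical(m2[names(m)], m[names(m)])
})

test_that("splice-evidence reassignment, removal, and retention", {
  fx <- gen_annotation_fixture()
  m <- integrate_novel(supplement_secondary(fx$primary, fx$secondary),
                       fx$novel)
  m3 <- reassign_by_splice_evidence(m, fx$evidence)
  expect_equal(unique(m3$gene_id[m3$tx_id == "N3"]), "GP3")
  expect_false("N2" %in% tx_ids(m3))                  # intronic, no evidence
  expect_equal(unique(m3$gene_id[m3$tx_id == "N1"]), "GN1")  # intergenic
  prov <- attr(m3, "provenance")
  expect_equal(prov[["N2"]][["status"]], "removed")
  expect_equal(prov[["N3"]][["status"]], "reassigned")
})

test_that("merge provenance accounts for every incoming transcript", {
  fx <- gen_annotation_fixture()
  mg <- merge_annotations(fx$primary, fx$secondary, fx$novel, fx$evidence)
  prov <- attr(mg, "provenance")
  incoming <- c(tx_ids(fx$secondary), tx_ids(fx$novel))
  expect_true(all(incoming %in% names(prov)))
})

test_that("raising the reciprocal-overlap gate never drops kept transcripts", {
  fx <- gen_annotation_fixture()
  kept_low <- tx_ids(supplement_secondary(fx$primary, fx$secondary,
                                          merge_rules(reciprocal_overlap_max = 0.5)))
  kept_high <- tx_ids(supplement_secondary(fx$primary, fx$secondary,
                                           merge_rules(reciprocal_overlap_max = 0.99)))
  expect_true(all(kept_low %in% kept_high))
})

test_that("assign_symbols applies the suffix partition and tie-breaks", {
  hits <- data.frame(
    tx_id = c("t1", "t2", "t3", "t4", "t5", "t5"),
    subject = c("FOS", "FOS", "FOS", "JUN", "AAA", "BBB"),
    evalue = c(1e-30, 1e-30, 1e-30, 1e-5, 1e-40, 1e-40),
    identity = c(99, 99, 99, 99, 90, 90),
    coverage = c(0.95, 0.70, 0.30, 0.95, 0.95, 0.95),
    stringsAsFactors = FALSE)
  res <- assign_symbols(c("t1", "t2", "t3", "t4", "t5"), hits)
  expect_equal(res$symbol[res$tx_id == "t1"], "FOS")
  expect_equal(res$symbol[res$tx_id == "t2"], "FOS_like")
  expect_equal(res$symbol[res$tx_id == "t3"], "FOS_containing")
  expect_true(is.na(res$symbol[res$tx_id == "t4"]))  # e-value gate
  # e-value tie: equal coverage/identity -> lexicographic subject
  expect_equal(res$symbol[res$tx_id == "t5"], "AAA")
  # boundary conventions: 0.90 plain, 0.50 containing
  hb <- data.frame(tx_id = c("b1", "b2"), subject = "SYM",
                   evalue = 1e-30, identity = 99, coverage = c(0.90, 0.50))
  rb <- assign_symbols(c("b1", "b2"), hb)
  expect_equal(rb$symbol, c("SYM", "SYM_containing"))
  # fallback used only when primary has no qualifying hit
  hf <- data.frame(tx_id = "t4", subject = "SQ", evalue = 1e-25,
                   identity = 95, coverage = 0.95)
  rf <- assign_symbols("t4", hits, hf)
  expect_equal(rf$symbol, "SQ")
  expect_equal(rf$source, "fallback")
  # malformed rows rejected with row numbers
  badh <- data.frame(tx_id = "x", subject = "S", evalue = -1,
                     identity = 1, coverage = 0.5)
  expect_error(assign_symbols("x", badh), "row")
})

test_that("GTF round-trip preserves the transcript set", {
  fx <- gen_annotation_fixture()
  tmp <- withr::local_tempfile(fileext = ".gtf")
  write_transcripts_gtf(fx$primary, tmp)
  back <- read_transcripts_gtf(tmp, source = "primary")
  key <- function(s) {
    s <- s[order(s$tx_id, s$start),
           c("tx_id", "gene_id", "chrom", "strand", "start", "end")]
    rownames(s) <- NULL
    s
  }
  expect_equal(key(back), key(fx$primary))
})
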