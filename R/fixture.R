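#' Constructed annotation-merge fixture with a known answer
#'
#' Builds three small transcript sets (primary, secondary, novel), junction
#' evidence, and the hand-constructed expected merged annotation.  Every
#' merge rule is exercised at least once:
#'
#' * S1: secondary, zero exon overlap — kept.
#' * S2: short (800 nt) single-exon secondary inside a 2 kb primary exon,
#'   reciprocal overlap 0.40 — kept by the rescue rule.
#' * S3: short single-exon secondary with reciprocal overlap ~0.976 against
#'   P4 — rejected (>= 0.90).
#' * S4: multi-exon secondary overlapping primary exons — dropped.
#' * S5: 1.2 kb (not short) single-exon secondary inside a primary exon —
#'   dropped.
#' * N1: intergenic novel, no evidence — kept under its own gene id.
#' * N2: single-exon novel inside a primary intron, no evidence — removed.
#' * N3: novel inside the same intron but with a 3-read junction into the
#'   host gene's exon — gene id reassigned to the host gene.
#' * N4: multi-exon novel overlapping a primary exon — excluded at the
#'   integration stage.
#' * N5: novel antisense to primary exons — no same-strand overlap, kept.
#'
#' @param seed accepted for interface symmetry; the fixture is fully
#'   deterministic.
#' @return list with `primary`, `secondary`, `novel` (transcript sets),
#'   `evidence` (junction table) and `expected_merged` (the oracle).
#' @export
gen_annotation_fixture <- function(seed = 1L) {
  primary <- rbind(
    tx_set("P1", "GP1", "chr1", "+", c(1000, 3000), c(2000, 4000),
           source = "primary"),
    tx_set("P2", "GP2", "chr1", "+", 10000, 12000, source = "primary"),
    tx_set("P3", "GP3", "chr1", "+", c(20000, 25000), c(21000, 26000),
           source = "primary"),
    tx_set("P4", "GP4", "chr1", "+", 30000, 30820, source = "primary"))

  secondary <- rbind(
    tx_set("S1", "GS1", "chr1", "+", 5000, 5400, source = "secondary"),
    tx_set("S2", "GS2", "chr1", "+", 10100, 10900, source = "secondary"),
    tx_set("S3", "GS3", "chr1", "+", 30000, 30800, source = "secondary"),
    tx_set("S4", "GS4", "chr1", "+", c(1500, 3500), c(1600, 3600),
           source = "secondary"),
    tx_set("S5", "GS5", "chr1", "+", 10500, 11700, source = "secondary"))

  novel <- rbind(
    tx_set("N1", "GN1", "chr1", "+", c(40000, 41000), c(40500, 41500),
           source = "novel"),
    tx_set("N2", "GN2", "chr1", "+", 21500, 21800, source = "novel"),
    tx_set("N3", "GN3", "chr1", "+", 21900, 22300, source = "novel"),
    tx_set("N4", "GN4", "chr1", "+", c(3900, 4500), c(4100, 4600),
           source = "novel"),
    tx_set("N5", "GN5", "chr1", "-", c(1200, 3500), c(1300, 3700),
           source = "novel"))

  evidence <- data.frame(
    chrom = "chr1", strand = "+", donor = 22250L, acceptor = 25100L,
    count = 3L, stringsAsFactors = FALSE)

  expected <- rbind(
    primary,
    secondary[secondary$tx_id %in% c("S1", "S2"), ],
    novel[novel$tx_id %in% c("N1", "N5"), ],
    {
      n3 <- novel[novel$tx_id == "N3", ]
      n3$gene_id <- "GP3"
      n3
    })
  rownames(expected) <- NULL

  list(primary = primary, secondary = secondary, novel = novel,
       evidence = evidence, expected_merged = expected)
}

#' Run the full merge procedure on three annotation sources
#'
#' Convenience wrapper: [supplement_secondary()], then [integrate_novel()],
#' then [reassign_by_splice_evidence()].  Provenance logs of the three
#' stages are concatenated in `attr(, "provenance")`.
#'
#' @param primary,secondary,novel transcript sets.
#' @param evidence junction-evidence data.frame.
#' @param rules a [merge_rules()].
#' @return merged transcript set.
#' @export
merge_annotations <- function(primary, secondary, novel, evidence,
                              rules = merge_rules()) {
  m1 <- supplement_secondary(primary, secondary, rules)
  l1 <- attr(m1, "provenance")
  m2 <- integrate_novel(m1, novel, rules)
  l2 <- attr(m2, "provenance")
  m3 <- reassign_by_splice_evidence(m2, evidence, rules)
  l3 <- attr(m3, "provenance")
  attr(m3, "provenance") <- c(l1, l2, l3)
  m3
}
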