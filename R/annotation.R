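#' Merge rules for stepwise annotation integration
#'
#' @param short_tx_max_len maximum exonic length (nt) of a "short"
#'   single-exon transcript eligible for the reciprocal-overlap rescue.
#' @param reciprocal_overlap_max transcripts at or above this reciprocal
#'   overlap with an existing transcript are rejected by the rescue rule.
#' @param min_spliced_reads junction reads required to count as splice
#'   evidence.
#' @return object of class `merge_rules`.
#' @export
merge_rules <- function(short_tx_max_len = 1000L,
                        reciprocal_overlap_max = 0.90,
                        min_spliced_reads = 1L) {
  stopifnot(reciprocal_overlap_max > 0, reciprocal_overlap_max <= 1,
            min_spliced_reads >= 1L)
  structure(list(short_tx_max_len = short_tx_max_len,
                 reciprocal_overlap_max = reciprocal_overlap_max,
                 min_spliced_reads = as.integer(min_spliced_reads)),
            class = "merge_rules")
}

#' Symbol-assignment rules
#'
#' Alignment hits must reach `max_evalue`; the chosen hit's query coverage
#' decides the suffix: none at coverage >= `like_cov_high`, "_like" strictly
#' between the two bounds, "_containing" below or at `like_cov_low`
#' (boundary convention: exactly 0.90 is plain, exactly 0.50 is
#' "_containing").
#'
#' @param max_evalue e-value gate.
#' @param like_cov_low,like_cov_high coverage band boundaries.
#' @return object of class `symbol_rules`.
#' @export
symbol_rules <- function(max_evalue = 1e-20, like_cov_low = 0.50,
                         like_cov_high = 0.90) {
  stopifnot(like_cov_low > 0, like_cov_low < like_cov_high,
            like_cov_high <= 1)
  structure(list(max_evalue = max_evalue, like_cov_low = like_cov_low,
                 like_cov_high = like_cov_high), class = "symbol_rules")
}

#' Construct a transcript set
#'
#' A transcript set is a plain data.frame with one row per exon and columns
#' tx_id, gene_id, chrom, strand, start, end, source, symbol.  Coordinates
#' are 0-based half-open internally; GTF I/O converts to/from the 1-based
#' closed convention.  Exons of a transcript must be sorted,
#' non-overlapping and share chrom/strand.
#'
#' @param tx_id,gene_id,chrom,strand per-exon (recycled) identifiers.
#' @param start,end 0-based half-open exon intervals.
#' @param source provenance: "primary", "secondary" or "novel".
#' @param symbol optional assigned symbol.
#' @return validated transcript-set data.frame.
#' @export
tx_set <- function(tx_id, gene_id, chrom, strand, start, end,
                   source = "primary", symbol = NA_character_) {
  df <- data.frame(tx_id = tx_id, gene_id = gene_id, chrom = chrom,
                   strand = strand, start = as.integer(start),
                   end = as.integer(end), source = source, symbol = symbol,
                   stringsAsFactors = FALSE)
  validate_tx_set(df)
  df
}

validate_tx_set <- function(df) {
  if (any(df$start >= df$end)) stop("exon with start >= end")
  if (!all(df$strand %in% c("+", "-"))) stop("strand must be + or -")
  for (id in unique(df$tx_id)) {
    e <- df[df$tx_id == id, , drop = FALSE]
    if (length(unique(e$chrom)) != 1L || length(unique(e$strand)) != 1L) {
      stop("transcript ", id, " spans multiple chrom/strand")
    }
    e <- e[order(e$start), , drop = FALSE]
    if (nrow(e) > 1L && any(e$start[-1] < e$end[-nrow(e)])) {
      stop("transcript ", id, " has overlapping exons")
    }
  }
  invisible(TRUE)
}

# per-transcript exon table, sorted
tx_exons <- function(set, id) {
  e <- set[set$tx_id == id, , drop = FALSE]
  e[order(e$start), , drop = FALSE]
}

tx_ids <- function(set) unique(set$tx_id)

tx_exonic_length <- function(set, id) {
  e <- tx_exons(set, id)
  sum(e$end - e$start)
}

# shared exonic bases between two exon tables (same chrom/strand assumed
# checked by caller)
shared_exonic_bases <- function(ea, eb) {
  tot <- 0L
  for (i in seq_len(nrow(ea))) {
    ov <- pmin(ea$end[i], eb$end) - pmax(ea$start[i], eb$start)
    tot <- tot + sum(ov[ov > 0])
  }
  tot
}

#' Do two transcripts share exonic sequence?
#'
#' TRUE iff some exon of `a` shares at least one base with some exon of `b`
#' on the same chromosome and strand (half-open intervals: adjacent exons
#' do not overlap; opposite strands never overlap — the data are stranded).
#'
#' @param set transcript set containing both transcripts.
#' @param id_a,id_b transcript ids.
#' @return logical.
#' @export
exon_overlap <- function(set, id_a, id_b) {
  ea <- tx_exons(set, id_a)
  eb <- tx_exons(set, id_b)
  if (ea$chrom[1] != eb$chrom[1] || ea$strand[1] != eb$strand[1]) {
    return(FALSE)
  }
  shared_exonic_bases(ea, eb) > 0L
}

#' Reciprocal exonic overlap fraction
#'
#' min(shared exonic bases / exonic length of a, shared / exonic length of
#' b); 0 for different chrom or strand.
#'
#' @inheritParams exon_overlap
#' @return fraction in \[0, 1\].
#' @export
reciprocal_overlap <- function(set, id_a, id_b) {
  ea <- tx_exons(set, id_a)
  eb <- tx_exons(set, id_b)
  if (ea$chrom[1] != eb$chrom[1] || ea$strand[1] != eb$strand[1]) return(0)
  sh <- shared_exonic_bases(ea, eb)
  min(sh / sum(ea$end - ea$start), sh / sum(eb$end - eb$start))
}

# apply the supplement rules of one incoming set against a base set;
# returns list(kept_ids, log)
supplement_rule <- function(base, incoming, rules) {
  kept <- character(0)
  log <- list()
  base_ids <- tx_ids(base)
  for (id in tx_ids(incoming)) {
    e <- tx_exons(incoming, id)
    cand <- base_ids[base$chrom[match(base_ids, base$tx_id)] == e$chrom[1]]
    has_ov <- any(vapply(cand, function(b) {
      shared_strand_overlap(base, incoming, b, id)
    }, logical(1)))
    if (!has_ov) {
      kept <- c(kept, id)
      log[[id]] <- c(status = "kept", reason = "no_exon_overlap")
      next
    }
    len <- sum(e$end - e$start)
    if (nrow(e) == 1L && len < rules$short_tx_max_len) {
      ro <- max(vapply(cand, function(b) {
        cross_reciprocal_overlap(base, incoming, b, id)
      }, numeric(1)))
      if (ro < rules$reciprocal_overlap_max) {
        kept <- c(kept, id)
        log[[id]] <- c(status = "kept",
                       reason = sprintf("short_single_exon_ro_%.3f", ro))
        next
      }
      log[[id]] <- c(status = "dropped",
                     reason = sprintf("reciprocal_overlap_%.3f", ro))
      next
    }
    log[[id]] <- c(status = "dropped", reason = "exon_overlap")
  }
  list(kept = kept, log = log)
}

shared_strand_overlap <- function(set_a, set_b, id_a, id_b) {
  ea <- tx_exons(set_a, id_a)
  eb <- tx_exons(set_b, id_b)
  if (ea$chrom[1] != eb$chrom[1] || ea$strand[1] != eb$strand[1]) {
    return(FALSE)
  }
  shared_exonic_bases(ea, eb) > 0L
}

cross_reciprocal_overlap <- function(set_a, set_b, id_a, id_b) {
  ea <- tx_exons(set_a, id_a)
  eb <- tx_exons(set_b, id_b)
  if (ea$chrom[1] != eb$chrom[1] || ea$strand[1] != eb$strand[1]) return(0)
  sh <- shared_exonic_bases(ea, eb)
  min(sh / sum(ea$end - ea$start), sh / sum(eb$end - eb$start))
}

#' Supplement a primary annotation with a secondary one
#'
#' Keeps every primary transcript, plus secondary transcripts with no
#' exonic overlap with any primary transcript, plus short (<
#' `short_tx_max_len`) single-exon secondary transcripts whose maximum
#' reciprocal overlap with the primaries stays below
#' `reciprocal_overlap_max`.  The decision for every incoming transcript is
#' recorded in `attr(, "provenance")`.
#'
#' @param primary,secondary transcript sets (see [tx_set()]).
#' @param rules a [merge_rules()].
#' @return merged transcript set.
#' @export
supplement_secondary <- function(primary, secondary, rules = merge_rules()) {
  dup <- intersect(tx_ids(primary), tx_ids(secondary))
  if (length(dup) > 0L) {
    stop("duplicate tx_id across sources: ", paste(dup, collapse = ", "))
  }
  res <- supplement_rule(primary, secondary, rules)
  merged <- rbind(primary, secondary[secondary$tx_id %in% res$kept, ,
                                     drop = FALSE])
  attr(merged, "provenance") <- res$log
  merged
}

#' Integrate novel transcripts into a merged annotation
#'
#' Applies the same keep rules as [supplement_secondary()] with the novel
#' set as the incoming set against the current merged set.  Overlapping
#' multi-exon novel transcripts are excluded here; their relationship to
#' reference genes is resolved separately by
#' [reassign_by_splice_evidence()].
#'
#' @param merged current merged transcript set.
#' @param novel novel transcript set (source "novel").
#' @param rules a [merge_rules()].
#' @return extended merged set with provenance attribute.
#' @export
integrate_novel <- function(merged, novel, rules = merge_rules()) {
  dup <- intersect(tx_ids(merged), tx_ids(novel))
  if (length(dup) > 0L) {
    stop("duplicate tx_id across sources: ", paste(dup, collapse = ", "))
  }
  if (nrow(novel) == 0L) {
    attr(merged, "provenance") <- list()
    return(merged)
  }
  res <- supplement_rule(merged, novel, rules)
  out <- rbind(merged, novel[novel$tx_id %in% res$kept, , drop = FALSE])
  attr(out, "provenance") <- res$log
  out
}

# introns of a transcript as a data.frame of half-open intervals
tx_introns <- function(set, id) {
  e <- tx_exons(set, id)
  if (nrow(e) < 2L) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0)))
  }
  data.frame(chrom = e$chrom[1], start = e$end[-nrow(e)], end = e$start[-1],
             stringsAsFactors = FALSE)
}

#' Resolve novel transcripts by splice evidence
#'
#' For each novel transcript in the merged set: if a junction with at least
#' `min_spliced_reads` reads links one of its exons to an exon of a
#' reference (non-novel) transcript on the same strand, the novel
#' transcript inherits that reference gene's gene_id; otherwise, if its
#' full span lies within a single intron of any reference transcript
#' (either strand), it is removed; otherwise it is left unchanged.  A
#' junction linking two different reference genes is resolved toward the
#' gene with more evidence reads, ties to the lexicographically smaller
#' gene_id; every decision is logged.
#'
#' @param merged merged transcript set.
#' @param evidence data.frame of junctions: chrom, strand, donor, acceptor,
#'   count (donor < acceptor, genome coordinates).
#' @param rules a [merge_rules()].
#' @return updated transcript set with `attr(, "provenance")`.
#' @export
reassign_by_splice_evidence <- function(merged, evidence,
                                        rules = merge_rules()) {
  stopifnot(all(c("chrom", "strand", "donor", "acceptor", "count")
                %in% names(evidence)))
  if (any(evidence$donor >= evidence$acceptor)) {
    stop("junction with donor >= acceptor")
  }
  log <- list()
  novel_ids <- tx_ids(merged[merged$source == "novel", , drop = FALSE])
  ref <- merged[merged$source != "novel", , drop = FALSE]
  ref_ids <- tx_ids(ref)
  drop_ids <- character(0)

  in_exon <- function(exons, pos) {
    any(exons$start <= pos & pos < exons$end)
  }

  for (id in novel_ids) {
    e <- tx_exons(merged, id)
    ev <- evidence[evidence$chrom == e$chrom[1] &
                     evidence$strand == e$strand[1] &
                     evidence$count >= rules$min_spliced_reads, ,
                   drop = FALSE]
    linked <- list()  # gene_id -> total evidence count
    for (k in seq_len(nrow(ev))) {
      d <- ev$donor[k]; a <- ev$acceptor[k]
      ends_in_novel <- c(in_exon(e, d), in_exon(e, a))
      if (!xor(ends_in_novel[1], ends_in_novel[2])) next
      other <- if (ends_in_novel[1]) a else d
      for (rid in ref_ids) {
        re <- tx_exons(ref, rid)
        if (re$chrom[1] != e$chrom[1] || re$strand[1] != e$strand[1]) next
        if (in_exon(re, other)) {
          g <- ref$gene_id[match(rid, ref$tx_id)]
          linked[[g]] <- (linked[[g]] %||% 0) + ev$count[k]
        }
      }
    }
    if (length(linked) > 0L) {
      cnts <- unlist(linked)
      best <- names(cnts)[cnts == max(cnts)]
      g <- sort(best)[1]
      merged$gene_id[merged$tx_id == id] <- g
      log[[id]] <- c(status = "reassigned", reason = paste0("gene:", g),
                     tie = length(best) > 1L)
      next
    }
    span <- c(min(e$start), max(e$end))
    contained <- FALSE
    host <- NA_character_
    for (rid in ref_ids) {
      ri <- tx_introns(ref, rid)
      if (nrow(ri) == 0L || ri$chrom[1] != e$chrom[1]) next
      hit <- ri$start <= span[1] & span[2] <= ri$end
      if (any(hit)) {
        contained <- TRUE
        host <- rid
        break
      }
    }
    if (contained) {
      drop_ids <- c(drop_ids, id)
      log[[id]] <- c(status = "removed",
                     reason = paste0("within_intron_of:", host))
    } else {
      log[[id]] <- c(status = "kept", reason = "intergenic_no_evidence")
    }
  }
  out <- merged[!merged$tx_id %in% drop_ids, , drop = FALSE]
  attr(out, "provenance") <- log
  out
}

#' Assign gene symbols from homology hits with suffix rules
#'
#' Per transcript, hits passing the e-value gate are taken from the primary
#' hit table; if none qualify, from the fallback table.  The lowest-e-value
#' hit wins (ties: higher coverage, then higher identity, then
#' lexicographic subject).  The symbol is used unmodified at coverage >=
#' `like_cov_high`, suffixed "_like" strictly between the bounds, and
#' "_containing" at or below `like_cov_low`.  Transcripts with no
#' qualifying hit keep their original id (symbol NA).
#'
#' @param tx_ids character vector of query transcript ids.
#' @param hits_primary,hits_fallback data.frames: tx_id, subject, evalue,
#'   identity, coverage (coverage as fraction in \[0, 1\]).
#' @param rules a [symbol_rules()].
#' @return data.frame: tx_id, symbol (NA when unassigned), source
#'   ("primary", "fallback" or NA).
#' @export
assign_symbols <- function(tx_ids, hits_primary, hits_fallback = NULL,
                           rules = symbol_rules()) {
  check_hits <- function(h, label) {
    if (is.null(h)) {
      return(data.frame(tx_id = character(0), subject = character(0),
                        evalue = numeric(0), identity = numeric(0),
                        coverage = numeric(0)))
    }
    need <- c("tx_id", "subject", "evalue", "identity", "coverage")
    miss <- setdiff(need, names(h))
    if (length(miss) > 0L) {
      stop(label, " hits missing column(s): ", paste(miss, collapse = ", "))
    }
    bad <- which(h$evalue < 0 | h$coverage < 0 | h$coverage > 1)
    if (length(bad) > 0L) {
      stop("malformed ", label, " hit row(s): ",
           paste(bad, collapse = ", "))
    }
    h
  }
  hp <- check_hits(hits_primary, "primary")
  hf <- check_hits(hits_fallback, "fallback")

  pick <- function(h) {
    h <- h[order(h$evalue, -h$coverage, -h$identity, h$subject), ,
           drop = FALSE]
    h[1, , drop = FALSE]
  }
  rows <- lapply(tx_ids, function(id) {
    cand <- hp[hp$tx_id == id & hp$evalue <= rules$max_evalue, ,
               drop = FALSE]
    src <- "primary"
    if (nrow(cand) == 0L) {
      cand <- hf[hf$tx_id == id & hf$evalue <= rules$max_evalue, ,
                 drop = FALSE]
      src <- "fallback"
    }
    if (nrow(cand) == 0L) {
      return(data.frame(tx_id = id, symbol = NA_character_,
                        source = NA_character_, stringsAsFactors = FALSE))
    }
    best <- pick(cand)
    sym <- if (best$coverage >= rules$like_cov_high) {
      best$subject
    } else if (best$coverage > rules$like_cov_low) {
      paste0(best$subject, "_like")
    } else {
      paste0(best$subject, "_containing")
    }
    data.frame(tx_id = id, symbol = sym, source = src,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

## ---- GTF I/O ---------------------------------------------------------------

#' Read a transcript set from GTF/GFF
#'
#' Exon records are imported via rtracklayer and converted to the internal
#' 0-based half-open convention.
#'
#' @param path GTF/GFF file.
#' @param source provenance label to stamp on every transcript.
#' @return transcript-set data.frame.
#' @export
read_transcripts_gtf <- function(path, source = "primary") {
  gr <- rtracklayer::import(path)
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0L) stop("no exon records in ", path)
  sym <- if ("assigned_symbol" %in% names(S4Vectors::mcols(gr))) {
    gr$assigned_symbol
  } else {
    NA_character_
  }
  df <- data.frame(tx_id = gr$transcript_id, gene_id = gr$gene_id,
                   chrom = as.character(GenomicRanges::seqnames(gr)),
                   strand = as.character(GenomicRanges::strand(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr), source = source,
                   symbol = sym, stringsAsFactors = FALSE)
  validate_tx_set(df)
  df
}

#' Write a transcript set as GTF
#'
#' Emits exon records with gene_id, transcript_id, source_db and
#' assigned_symbol attributes; converts back to 1-based closed coordinates.
#'
#' @param set transcript set.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_transcripts_gtf <- function(set, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = set$chrom,
    ranges = IRanges::IRanges(start = set$start + 1L, end = set$end),
    strand = set$strand)
  gr$type <- "exon"
  gr$gene_id <- set$gene_id
  gr$transcript_id <- set$tx_id
  gr$source_db <- set$source
  gr$assigned_symbol <- set$symbol
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Read junction-evidence TSV (chrom, strand, donor, acceptor, count)
#' @param path file path.
#' @return data.frame.
#' @export
read_junction_evidence <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("chrom", "strand", "donor", "acceptor", "count")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("junction evidence missing column(s): ",
         paste(miss, collapse = ", "))
  }
  df
}

#' Read an outfmt-6-like alignment hit table
#'
#' Tab-separated with columns tx_id, subject, evalue, identity, coverage
#' (header optional if the six-column blast outfmt order qseqid, sseqid,
#' pident, evalue, qcovs is not used; here a named header is required).
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_alignment_hits <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("tx_id", "subject", "evalue", "identity", "coverage")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("alignment hits missing column(s): ", paste(miss, collapse = ", "))
  }
  df
}
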