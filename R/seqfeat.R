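#' ARE scoring configuration
#'
#' AU-rich-element scoring of 3'UTRs, a documented approximation of the
#' web-based scorer the field uses: P overlapping AUUUA pentamers plus a
#' clustering bonus for consecutive pentamers whose starts are within
#' pentamer length + `cluster_gap` of each other.  3'UTRs shorter than
#' `min_utr_len` are excluded, score 0 means "no ARE", and scores at or
#' above `high_score_min` form the "high ARE" class.
#'
#' @param min_utr_len minimum 3'UTR length scored (nt).
#' @param pentamer the element, DNA alphabet.
#' @param cluster_gap maximum start-to-start gap beyond the pentamer length
#'   for two occurrences to count as clustered.
#' @param cluster_bonus score added per clustered consecutive pair.
#' @param high_score_min threshold of the "high ARE" class.
#' @return object of class `are_config`.
#' @export
are_config <- function(min_utr_len = 200L, pentamer = "ATTTA",
                       cluster_gap = 9L, cluster_bonus = 1.5,
                       high_score_min = 8) {
  stopifnot(min_utr_len >= nchar(pentamer))
  structure(list(min_utr_len = as.integer(min_utr_len), pentamer = pentamer,
                 cluster_gap = as.integer(cluster_gap),
                 cluster_bonus = cluster_bonus,
                 high_score_min = high_score_min), class = "are_config")
}

#' GC content of sequences
#'
#' (G + C) / (A + C + G + T), case-insensitive, N excluded from the
#' denominator.  All-N (or empty) sequences give NA.
#'
#' @param seqs character vector (or DNAStringSet) of DNA sequences.
#' @return numeric vector of fractions.
#' @export
gc_content <- function(seqs) {
  if (methods::is(seqs, "XStringSet")) seqs <- as.character(seqs)
  x <- Biostrings::DNAStringSet(toupper(seqs))
  f <- Biostrings::letterFrequency(x, c("A", "C", "G", "T"))
  denom <- rowSums(f)
  out <- ifelse(denom > 0, (f[, "G"] + f[, "C"]) / denom, NA_real_)
  stats::setNames(out, names(seqs))
}

# all (possibly overlapping) start positions of a fixed pattern
overlapping_starts <- function(seq, pattern) {
  m <- Biostrings::matchPattern(pattern, Biostrings::DNAString(seq))
  Biostrings::start(m)
}

#' ARE score of 3'UTR sequences
#'
#' @param seqs named character vector of 3'UTR sequences.
#' @param config an [are_config()].
#' @return data.frame: id, length, n_pentamer, n_cluster, score (NA for
#'   excluded sequences), class ("excluded", "no ARE", "intermediate",
#'   "high ARE").
#' @export
are_score <- function(seqs, config = are_config()) {
  seqs <- stats::setNames(toupper(as.character(seqs)),
                          names(seqs) %||% paste0("seq", seq_along(seqs)))
  if (any(grepl("[^ACGTN]", seqs))) {
    stop("non-ACGTN character(s) in sequence(s): ",
         paste(names(seqs)[grepl("[^ACGTN]", seqs)], collapse = ", "))
  }
  plen <- nchar(config$pentamer)
  rows <- lapply(names(seqs), function(id) {
    s <- seqs[[id]]
    len <- nchar(s)
    if (len < config$min_utr_len) {
      return(data.frame(id = id, length = len, n_pentamer = NA_integer_,
                        n_cluster = NA_integer_, score = NA_real_,
                        class = "excluded", stringsAsFactors = FALSE))
    }
    st <- overlapping_starts(s, config$pentamer)
    p <- length(st)
    cl <- if (p >= 2L) sum(diff(st) <= plen + config$cluster_gap) else 0L
    sc <- p + config$cluster_bonus * cl
    cls <- if (sc == 0) "no ARE"
           else if (sc >= config$high_score_min) "high ARE"
           else "intermediate"
    data.frame(id = id, length = len, n_pentamer = p, n_cluster = cl,
               score = sc, class = cls, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Scan sequences for an IUPAC motif
#'
#' Counts possibly-overlapping matches of the motif (IUPAC ambiguity codes
#' allowed) on the given strand and reports per-kb densities.
#'
#' @param seqs named character vector of DNA sequences.
#' @param motif IUPAC motif string.
#' @return data.frame: id, length, count, density_per_kb.
#' @export
motif_scan <- function(seqs, motif) {
  if (is.null(motif) || nchar(motif) == 0L) stop("empty motif")
  motif <- toupper(motif)
  iupac <- names(Biostrings::IUPAC_CODE_MAP)
  bad <- setdiff(strsplit(motif, "")[[1]], iupac)
  if (length(bad) > 0L) {
    stop("invalid IUPAC code(s) in motif: ", paste(unique(bad), collapse = ""))
  }
  seqs <- stats::setNames(toupper(as.character(seqs)),
                          names(seqs) %||% paste0("seq", seq_along(seqs)))
  x <- Biostrings::DNAStringSet(seqs)
  cnt <- Biostrings::vcountPattern(motif, x, fixed = FALSE)
  len <- nchar(seqs)
  data.frame(id = names(seqs), length = len, count = cnt,
             density_per_kb = cnt * 1000 / len, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Extract annotated regions from sequences
#'
#' @param seqs named character vector of transcript sequences.
#' @param regions region table (transcript, region, start, end; 1-based
#'   closed).
#' @param region which region to extract ("5UTR", "CDS", "3UTR").
#' @return named character vector of region sequences.
#' @export
extract_region <- function(seqs, regions, region = "3UTR") {
  r <- regions[regions$region == region, , drop = FALSE]
  r <- r[r$transcript %in% names(seqs), , drop = FALSE]
  out <- vapply(seq_len(nrow(r)), function(i) {
    substr(seqs[[r$transcript[i]]], r$start[i], r$end[i])
  }, character(1))
  stats::setNames(out, r$transcript)
}

## ---- enrichment statistics -------------------------------------------------

# two-sided Fisher exact p for one 2x2 table; odds ratio is the
# Haldane-corrected sample OR (exactly 1 on proportional tables, exactly
# inverted when the two sets are swapped)
fisher_2x2 <- function(a, b, c, d) {
  m <- matrix(c(a, b, c, d), nrow = 2)
  ft <- stats::fisher.test(m)
  or <- ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
  list(p = ft$p.value, or = or)
}

#' k-mer presence/absence enrichment between two sequence sets
#'
#' For every k-mer present in either set, a 2x2 table of sequence-level
#' presence in foreground vs background is tested with the Fisher exact
#' test; p-values are BH-adjusted over all tested k-mers.
#'
#' @param foreground,background character vectors of DNA sequences.
#' @param k k-mer length, 1..12.
#' @return data.frame: kmer, fg_with, fg_without, bg_with, bg_without,
#'   odds_ratio, pvalue, qvalue; sorted by p.
#' @export
kmer_enrichment <- function(foreground, background, k) {
  stopifnot(k >= 1L, k <= 12L, length(foreground) > 0L,
            length(background) > 0L)
  kmer_sets <- function(seqs) {
    lapply(toupper(seqs), function(s) {
      n <- nchar(s)
      if (n < k) return(character(0))
      unique(substring(s, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L))
    })
  }
  fg <- kmer_sets(foreground)
  bg <- kmer_sets(background)
  all_k <- unique(c(unlist(fg), unlist(bg)))
  all_k <- all_k[!grepl("[^ACGT]", all_k)]
  fg_with <- vapply(all_k, function(km) {
    sum(vapply(fg, function(s) km %in% s, logical(1)))
  }, integer(1))
  bg_with <- vapply(all_k, function(km) {
    sum(vapply(bg, function(s) km %in% s, logical(1)))
  }, integer(1))
  nf <- length(fg); nb <- length(bg)
  res <- lapply(seq_along(all_k), function(i) {
    ft <- fisher_2x2(fg_with[i], nf - fg_with[i], bg_with[i],
                     nb - bg_with[i])
    data.frame(kmer = all_k[i], fg_with = fg_with[i],
               fg_without = nf - fg_with[i], bg_with = bg_with[i],
               bg_without = nb - bg_with[i], odds_ratio = ft$or,
               pvalue = ft$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(res, list(make.row.names = FALSE)))
  out$qvalue <- stats::p.adjust(out$pvalue, "BH")
  out[order(out$pvalue), , drop = FALSE]
}

#' Cluster-by-feature-class over-representation
#'
#' For each cluster and each feature class, tests whether class members are
#' over-represented among the cluster's genes relative to the background
#' set (Fisher exact, 2x2: in-cluster/not x in-class/not).
#'
#' @param assignments data.frame with columns unit, cluster (as from
#'   [assign_clusters()]).
#' @param feature_class named character vector: gene -> class label.
#' @param background character vector of background gene ids.
#' @return data.frame: cluster, class, in_cluster_in_class,
#'   in_cluster_other, bg_in_class, bg_other, odds_ratio, pvalue, qvalue.
#' @export
cluster_feature_fisher <- function(assignments, feature_class, background) {
  background <- unique(background)
  feature_class <- feature_class[names(feature_class) %in% background]
  clusters <- setdiff(unique(assignments$cluster), character(0))
  classes <- unique(feature_class)
  rows <- list()
  for (cl in clusters) {
    genes <- intersect(assignments$unit[assignments$cluster == cl],
                       background)
    if (length(genes) == 0L) next
    rest <- setdiff(background, genes)
    for (fc in classes) {
      in_class <- names(feature_class)[feature_class == fc]
      a <- length(intersect(genes, in_class))
      b <- length(genes) - a
      c_ <- length(intersect(rest, in_class))
      d <- length(rest) - c_
      ft <- fisher_2x2(a, b, c_, d)
      rows[[paste(cl, fc)]] <- data.frame(
        cluster = cl, class = fc, in_cluster_in_class = a,
        in_cluster_other = b, bg_in_class = c_, bg_other = d,
        odds_ratio = ft$or, pvalue = ft$p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out$qvalue <- stats::p.adjust(out$pvalue, "BH")
  out
}

#' Two-sided Wilcoxon rank-sum comparison
#'
#' Exact when both groups have at most 8 untied values, otherwise the
#' tie-corrected normal approximation.
#'
#' @param a,b numeric vectors.
#' @return two-sided p-value.
#' @export
wilcoxon_compare <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) stop("empty group")
  if (length(unique(c(a, b))) == 1L) return(1)  # no evidence either way
  ties <- any(duplicated(c(a, b)))
  exact <- !ties && min(length(a), length(b)) <= 8L
  stats::wilcox.test(a, b, exact = exact, correct = !exact)$p.value
}

#' Read a GMT gene-set collection
#'
#' @param path GMT file: term, description, then member genes, tab
#'   separated.
#' @return named list of character vectors (term -> genes).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3L) stop("malformed GMT line: ", substr(l, 1, 60))
    stats::setNames(list(unique(parts[-(1:2)])), parts[1])
  })
  do.call(c, sets)
}

#' Gene-set (GO term) over-representation by Fisher exact test
#'
#' The background is a required, explicit choice (e.g. all annotated
#' genes, or the pass-filter detected set); term memberships are clipped to
#' it before testing.
#'
#' @param genes character vector, the gene set of interest.
#' @param collections named list of term -> member genes (see
#'   [read_gmt()]).
#' @param background character vector of background genes.
#' @return data.frame: term, set_in_term, set_out_term, bg_in_term,
#'   bg_out_term, odds_ratio, pvalue, qvalue; sorted by p.
#' @export
go_enrichment <- function(genes, collections, background) {
  background <- unique(background)
  genes <- unique(intersect(genes, background))
  if (length(genes) == 0L) {
    stop("gene set is disjoint from the background")
  }
  rest <- setdiff(background, genes)
  rows <- lapply(names(collections), function(term) {
    members <- intersect(collections[[term]], background)
    a <- length(intersect(genes, members))
    b <- length(genes) - a
    c_ <- length(intersect(rest, members))
    d <- length(rest) - c_
    ft <- fisher_2x2(a, b, c_, d)
    data.frame(term = term, set_in_term = a, set_out_term = b,
               bg_in_term = c_, bg_out_term = d, odds_ratio = ft$or,
               pvalue = ft$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out$qvalue <- stats::p.adjust(out$pvalue, "BH")
  out[order(out$pvalue), , drop = FALSE]
}
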