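#' Simulation configuration for the synthetic hibernation dataset
#'
#' Bundles every knob of the synthetic-data generator.  Defaults encode the
#' study design being emulated: six physiological states with five
#' biological replicates each and a sex covariate.  Effect sizes and
#' dispersions are engineering choices (the emulated study reports none):
#' amplitude 2 on log2 scale (a 4-fold peak-to-trough change), NB dispersion
#' 0.05 (typical for bulk brain RNA-seq replicates), baseline log2 means in
#' [8, 12] so that simulated genes sit above the detection filter the way
#' pass-filter genes do.
#'
#' @param seed integer seed; the single RNG stream for a generator call.
#' @param n_per_state replicates per state (>= 2).
#' @param states ordered state labels.
#' @param n_genes number of genes to simulate.
#' @param cluster_fractions named fractions per template; remainder are
#'   null genes.  Names must match rownames of `templates`.
#' @param amplitude log2-units peak-to-trough effect added on top of
#'   baseline for template genes.
#' @param dispersion NB dispersion d, variance = mu + d * mu^2.
#' @param baseline_logmean_range interval for per-gene baseline log2 mean.
#' @param sex_effect_sd sd of the gene-specific log2 offset applied to males.
#' @param libsize_factor_range multiplicative library-size factor interval
#'   (factors drawn log-uniform).
#' @param templates template matrix, see [reference_templates()].
#' @return object of class `sim_config` (a list).
#' @export
sim_config <- function(seed = 1L,
                       n_per_state = 5L,
                       states = hibernation_states(),
                       n_genes = 1000L,
                       cluster_fractions = stats::setNames(
                         rep(0.06, 10), rownames(reference_templates())),
                       amplitude = 2,
                       dispersion = 0.05,
                       baseline_logmean_range = c(8, 12),
                       sex_effect_sd = 0.1,
                       libsize_factor_range = c(0.7, 1.4),
                       templates = reference_templates()) {
  cfg <- list(seed = as.integer(seed), n_per_state = as.integer(n_per_state),
              states = states, n_genes = as.integer(n_genes),
              cluster_fractions = cluster_fractions, amplitude = amplitude,
              dispersion = dispersion,
              baseline_logmean_range = baseline_logmean_range,
              sex_effect_sd = sex_effect_sd,
              libsize_factor_range = libsize_factor_range,
              templates = templates)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  fail <- function(field, why) {
    stop("invalid sim_config field '", field, "': ", why, call. = FALSE)
  }
  if (cfg$n_per_state < 2L) fail("n_per_state", "must be >= 2")
  if (anyDuplicated(cfg$states)) fail("states", "must be distinct")
  if (cfg$dispersion <= 0) fail("dispersion", "must be > 0")
  fr <- cfg$cluster_fractions
  if (length(fr) > 0L) {
    if (any(fr < 0) || any(fr > 1)) {
      fail("cluster_fractions", "fractions must be in [0, 1]")
    }
    if (sum(fr) > 1 + 1e-12) fail("cluster_fractions", "fractions sum > 1")
    unknown <- setdiff(names(fr), rownames(cfg$templates))
    if (length(unknown) > 0L) {
      fail("cluster_fractions",
           paste("unknown template name(s):", paste(unknown, collapse = ", ")))
    }
  }
  if (cfg$n_genes < 1L) fail("n_genes", "must be >= 1")
  if (diff(cfg$baseline_logmean_range) < 0) {
    fail("baseline_logmean_range", "must be an interval")
  }
  if (any(cfg$libsize_factor_range <= 0)) {
    fail("libsize_factor_range", "must be positive")
  }
  invisible(TRUE)
}

# run expr with a private RNG stream; global .Random.seed is restored
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(expr)
}

#' Generate a sample design table
#'
#' Emits one row per sample: `n_per_state` replicates of each state, with a
#' near-balanced, seed-deterministic sex assignment within each state.
#'
#' @param config a [sim_config()].
#' @param region region label recorded for every sample.
#' @return data.frame with columns sample, state, sex, region.
#' @export
gen_design <- function(config, region = "brain") {
  stopifnot(inherits(config, "sim_config"))
  with_local_seed(config$seed, {
    rows <- lapply(config$states, function(st) {
      n <- config$n_per_state
      sexes <- sample(rep_len(c("F", "M"), n))
      data.frame(sample = paste0(st, "_", seq_len(n)),
                 state = st, sex = sexes, region = region,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Generate a synthetic count matrix with known ground truth
#'
#' Gene i generated from template k has state log2 mean
#' `baseline_i + amplitude * template_k(state)`, plus a gene-specific sex
#' offset for males; counts are negative binomial around that mean after
#' scaling by the sample's library-size factor.  Genes not allocated to a
#' template are null (state-constant).
#'
#' @param design design table from [gen_design()].
#' @param config a [sim_config()].
#' @return list with `counts` (integer matrix genes x samples), `truth`
#'   (data.frame gene, template, amplitude, baseline) and `size_factors`
#'   (the true library-size factors).
#' @export
gen_counts <- function(design, config) {
  stopifnot(inherits(config, "sim_config"))
  check_states(design$state, config$states)
  tpl <- config$templates
  miss <- setdiff(config$states, colnames(tpl))
  if (length(miss) > 0L) {
    stop("templates missing state column(s): ", paste(miss, collapse = ", "))
  }

  n_genes <- config$n_genes
  fr <- config$cluster_fractions
  n_per_tpl <- if (length(fr) > 0L) round(fr * n_genes) else integer(0)
  labels <- c(rep(names(n_per_tpl), n_per_tpl),
              rep("null", n_genes - sum(n_per_tpl)))

  with_local_seed(config$seed + 1L, {
    baseline <- stats::runif(n_genes, config$baseline_logmean_range[1],
                             config$baseline_logmean_range[2])
    sex_off <- stats::rnorm(n_genes, 0, config$sex_effect_sd)
    lf <- exp(stats::runif(nrow(design),
                           log(config$libsize_factor_range[1]),
                           log(config$libsize_factor_range[2])))
    names(lf) <- design$sample

    # genes x samples matrix of log2 means
    tpl_val <- matrix(0, n_genes, nrow(design))
    is_tpl <- labels != "null"
    if (any(is_tpl)) {
      tpl_val[is_tpl, ] <- config$amplitude *
        tpl[labels[is_tpl], design$state, drop = FALSE]
    }
    log2mu <- baseline + tpl_val +
      outer(sex_off, as.numeric(design$sex == "M"))
    mu <- 2^log2mu * rep(lf, each = n_genes)

    counts <- matrix(
      stats::rnbinom(length(mu), mu = mu, size = 1 / config$dispersion),
      n_genes, nrow(design),
      dimnames = list(sprintf("gene%04d", seq_len(n_genes)), design$sample))

    truth <- data.frame(
      gene = rownames(counts), template = labels,
      amplitude = ifelse(is_tpl, config$amplitude, 0),
      baseline = baseline, stringsAsFactors = FALSE)
    list(counts = counts, truth = truth, size_factors = lf)
  })
}

#' Default planted PSI templates for the LSV simulator
#'
#' Each entry describes one class of local splicing variation: a junctions x
#' states PSI matrix (columns in canonical state order, each column summing
#' to 1), the index of the retained-intron junction (NA if none) and the
#' fraction of simulated LSVs drawn from the class.  The default set plants
#' one cold-responsive cassette-like LSV (summer-dominant junction drops by
#' 0.5 in LT/Ar), one warm-default retained intron, one state-constant
#' retained intron (a control candidate), and fills the remainder with
#' state-constant null LSVs.
#'
#' @param states ordered state labels.
#' @return named list of class descriptors.
#' @export
default_psi_templates <- function(states = hibernation_states()) {
  cold <- states %in% c("LT", "Ar")
  mk <- function(hot, coldv) {
    m <- matrix(rep(hot, length(states)), nrow = length(hot))
    m[, cold] <- coldv
    colnames(m) <- states
    m
  }
  list(
    cold_drop = list(psi = mk(c(0.9, 0.1), c(0.4, 0.6)),
                     retained_intron = NA_integer_, fraction = 0.2),
    ir_warm_default = list(psi = mk(c(0.8, 0.2), c(0.3, 0.7)),
                           retained_intron = 1L, fraction = 0.2),
    ir_null = list(psi = mk(c(0.6, 0.4), c(0.6, 0.4)),
                   retained_intron = 1L, fraction = 0.1)
  )
}

#' Generate synthetic LSV junction counts
#'
#' Per sample, a total coverage is drawn Poisson(`coverage_mean`) and split
#' across the LSV's junctions multinomially with the planted per-state PSI.
#' LSVs not allocated to a named class are null: a constant PSI vector drawn
#' once per LSV and shared by all states.  Retained-intron junctions are
#' given invented genomic coordinates so downstream control-intron selection
#' has something to intersect.
#'
#' @param design design table.
#' @param n_lsv number of LSVs.
#' @param psi_templates list as from [default_psi_templates()].
#' @param coverage_mean mean per-sample total junction coverage.
#' @param config a [sim_config()] (seed and states are used).
#' @return list with `lsv_counts` (long data.frame: lsv_id, gene_id,
#'   junction_id, is_retained_intron, chrom, start, end, strand, sample,
#'   count) and `truth` (lsv_id, template, max planted |dPSI| vs reference).
#' @export
gen_lsv_counts <- function(design, n_lsv, psi_templates = default_psi_templates(),
                           coverage_mean = 100, config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  states <- config$states
  for (nm in names(psi_templates)) {
    p <- psi_templates[[nm]]$psi
    if (any(abs(colSums(p) - 1) > 1e-8)) {
      stop("psi template '", nm, "': per-state PSI must sum to 1")
    }
  }
  fr <- vapply(psi_templates, function(x) x$fraction, numeric(1))
  if (sum(fr) > 1 + 1e-12) stop("psi template fractions sum > 1")
  n_per <- round(fr * n_lsv)
  labels <- c(rep(names(n_per), n_per), rep("null", n_lsv - sum(n_per)))

  with_local_seed(config$seed + 2L, {
    out <- vector("list", n_lsv)
    truth <- vector("list", n_lsv)
    for (i in seq_len(n_lsv)) {
      lab <- labels[i]
      if (lab == "null") {
        p1 <- stats::runif(1, 0.2, 0.8)
        psi <- matrix(rep(c(p1, 1 - p1), length(states)), nrow = 2,
                      dimnames = list(NULL, states))
        ri <- NA_integer_
      } else {
        psi <- psi_templates[[lab]]$psi[, states, drop = FALSE]
        ri <- psi_templates[[lab]]$retained_intron
      }
      nj <- nrow(psi)
      lsv_id <- sprintf("lsv%04d", i)
      # invented non-overlapping genomic placement, 10 kb per LSV
      base <- 10000L * i
      jstart <- base + 1000L * (seq_len(nj) - 1L)
      totals <- stats::rpois(nrow(design), coverage_mean)
      cnt <- matrix(0L, nj, nrow(design))
      for (s in seq_len(nrow(design))) {
        if (totals[s] > 0) {
          cnt[, s] <- stats::rmultinom(1, totals[s], psi[, design$state[s]])
        }
      }
      out[[i]] <- data.frame(
        lsv_id = lsv_id, gene_id = sprintf("g%04d", i),
        junction_id = rep(paste0("j", seq_len(nj)), nrow(design)),
        is_retained_intron = rep(seq_len(nj) == ri & !is.na(ri), nrow(design)),
        chrom = "chrS", start = rep(jstart, nrow(design)),
        end = rep(jstart + 500L, nrow(design)), strand = "+",
        sample = rep(design$sample, each = nj),
        count = as.integer(cnt), stringsAsFactors = FALSE)
      ref <- states[1]
      dpsi_max <- max(abs(psi - psi[, ref]))
      truth[[i]] <- data.frame(lsv_id = lsv_id, template = lab,
                               dpsi_max = dpsi_max,
                               retained_intron = ifelse(is.na(ri), NA, ri),
                               stringsAsFactors = FALSE)
    }
    list(lsv_counts = do.call(rbind, out), truth = do.call(rbind, truth))
  })
}

#' Generate synthetic sequences with planted features
#'
#' Sequences are DNA-alphabet with a controlled GC fraction.  The 3'UTR
#' (last `utr3_frac` of each sequence) carries a stated number of planted
#' AUUUA pentamers (DNA: ATTTA) at a controllable start-to-start spacing and
#' optional planted motif occurrences; the background is scrubbed so that a
#' sequence with zero planted pentamers contains no ATTTA at all.
#'
#' @param n number of sequences.
#' @param length sequence length (nt).
#' @param planted list with optional fields `gc` (target fraction, default
#'   0.5), `n_pentamers` (default 0), `pentamer_spacing` (start-to-start,
#'   default 20 nt = isolated), `motif` (character, planted verbatim),
#'   `n_motif` (default 0).
#' @param seed integer seed.
#' @param utr3_frac fraction of the sequence annotated as 3'UTR (the last
#'   part); the first 10% is 5'UTR, the remainder CDS.
#' @return list with `sequences` (named character vector), `regions`
#'   (data.frame transcript, region, start, end; 1-based closed) and
#'   `truth` (per-sequence planted feature counts).
#' @export
gen_sequences <- function(n, length, planted = list(), seed = 1L,
                          utr3_frac = 0.3) {
  gc <- planted$gc %||% 0.5
  n_pent <- planted$n_pentamers %||% 0L
  spacing <- planted$pentamer_spacing %||% 20L
  motif <- planted$motif
  n_motif <- planted$n_motif %||% 0L
  if (length < 1) stop("length must be >= 1")
  pent <- "ATTTA"
  if (n_pent > 0 && nchar(pent) > length) {
    stop("planted element longer than sequence")
  }
  if (!is.null(motif) && n_motif > 0 && nchar(motif) > length) {
    stop("planted element longer than sequence")
  }

  utr3_start <- floor(length * (1 - utr3_frac)) + 1L
  utr5_end <- max(1L, floor(length * 0.1))

  with_local_seed(seed, {
    seqs <- character(n)
    for (i in seq_len(n)) {
      s <- sample(c("A", "T", "G", "C"), length, replace = TRUE,
                  prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2))
      s <- scrub_pentamer(s, pent)
      # plant pentamers in the 3'UTR at fixed spacing
      if (n_pent > 0) {
        starts <- utr3_start + spacing * (seq_len(n_pent) - 1L)
        if (any(starts + nchar(pent) - 1L > length)) {
          stop("planted pentamers do not fit in the 3'UTR at this spacing")
        }
        for (st in starts) {
          s[st:(st + nchar(pent) - 1L)] <- strsplit(pent, "")[[1]]
        }
        # planting can create incidental boundary occurrences; scrub any
        # occurrence that is not one of the planted starts
        s <- scrub_pentamer(s, pent, keep_starts = starts)
      }
      if (!is.null(motif) && n_motif > 0) {
        mlen <- nchar(motif)
        mstarts <- utr5_end + 1L + (mlen + 3L) * (seq_len(n_motif) - 1L)
        if (any(mstarts + mlen - 1L > utr3_start - 1L)) {
          stop("planted motifs do not fit in the CDS")
        }
        for (st in mstarts) {
          s[st:(st + mlen - 1L)] <- strsplit(motif, "")[[1]]
        }
      }
      seqs[i] <- paste(s, collapse = "")
    }
    ids <- sprintf("tx%03d", seq_len(n))
    names(seqs) <- ids
    regions <- do.call(rbind, lapply(ids, function(id) {
      data.frame(transcript = id,
                 region = c("5UTR", "CDS", "3UTR"),
                 start = c(1L, utr5_end + 1L, utr3_start),
                 end = c(utr5_end, utr3_start - 1L, length),
                 stringsAsFactors = FALSE)
    }))
    truth <- data.frame(transcript = ids, gc_target = gc,
                        n_pentamers = n_pent, n_motif = n_motif,
                        stringsAsFactors = FALSE)
    list(sequences = seqs, regions = regions, truth = truth)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# replace occurrences of pentamer not anchored at keep_starts; mutates one
# base per stray occurrence (a base outside any kept span where possible)
scrub_pentamer <- function(chars, pent, keep_starts = integer(0)) {
  plen <- nchar(pent)
  keep_cover <- unlist(lapply(keep_starts, function(st) st:(st + plen - 1L)))
  repeat {
    seq_str <- paste(chars, collapse = "")
    hits <- gregexpr(pent, seq_str, fixed = TRUE)[[1]]
    hits <- hits[hits > 0]
    # overlapping occurrences: rescan from every position
    all_hits <- integer(0)
    pos <- 1L
    while (pos + plen - 1L <= length(chars)) {
      if (substr(seq_str, pos, pos + plen - 1L) == pent) {
        all_hits <- c(all_hits, pos)
      }
      pos <- pos + 1L
    }
    stray <- setdiff(all_hits, keep_starts)
    if (length(stray) == 0L) return(chars)
    st <- stray[1]
    span <- st:(st + plen - 1L)
    free <- setdiff(span, keep_cover)
    if (length(free) == 0L) return(chars)  # fully inside kept spans: leave
    i <- free[1]
    chars[i] <- if (chars[i] %in% c("A", "T")) "G" else "A"
  }
}

## ---- writers ---------------------------------------------------------------

#' Write a counts matrix as TSV (gene id column + one column per sample)
#' @param counts integer matrix.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(gene = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a counts TSV written by [write_counts()]
#' @param path input path.
#' @return integer matrix with gene rownames.
#' @export
read_counts <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty counts file: ", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  m
}

#' Write / read the sample design table (CSV)
#' @param design design data.frame.
#' @param path file path.
#' @return invisibly `path`, or the design data.frame.
#' @export
write_design <- function(design, path) {
  utils::write.csv(design, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample", "state", "sex")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("design file missing column(s): ", paste(miss, collapse = ", "))
  }
  df
}

#' Write / read LSV junction counts (long TSV)
#' @param lsv_counts long data.frame as produced by [gen_lsv_counts()].
#' @param path file path.
#' @return invisibly `path`, or the data.frame.
#' @export
write_lsv_counts <- function(lsv_counts, path) {
  utils::write.table(lsv_counts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_lsv_counts
#' @export
read_lsv_counts <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("lsv_id", "gene_id", "junction_id", "is_retained_intron",
            "sample", "count")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("LSV counts file missing column(s): ", paste(miss, collapse = ", "))
  }
  df
}

#' Write sequences as FASTA (via Biostrings)
#' @param sequences named character vector.
#' @param path file path.
#' @return invisibly, `path`.
#' @export
write_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sequences), path)
  invisible(path)
}

#' Read a FASTA file into a named character vector
#' @param path file path.
#' @return named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write a complete synthetic input bundle to a directory
#'
#' Emits counts.tsv, design.csv, truth_genes.tsv, lsv_counts.tsv,
#' truth_lsv.tsv and templates.tsv — everything [run_all()] consumes.
#'
#' @param dir output directory (created if needed).
#' @param config a [sim_config()].
#' @param n_lsv number of LSVs.
#' @param coverage_mean LSV coverage.
#' @param psi_templates planted PSI classes.
#' @return invisibly, the directory path.
#' @export
write_synthetic_bundle <- function(dir, config = sim_config(), n_lsv = 200L,
                                   coverage_mean = 100,
                                   psi_templates = default_psi_templates()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  design <- gen_design(config)
  sim <- gen_counts(design, config)
  lsv <- gen_lsv_counts(design, n_lsv, psi_templates, coverage_mean, config)
  write_design(design, file.path(dir, "design.csv"))
  write_counts(sim$counts, file.path(dir, "counts.tsv"))
  utils::write.table(sim$truth, file.path(dir, "truth_genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_lsv_counts(lsv$lsv_counts, file.path(dir, "lsv_counts.tsv"))
  utils::write.table(lsv$truth, file.path(dir, "truth_lsv.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_templates(config$templates, file.path(dir, "templates.tsv"))
  invisible(dir)
}
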