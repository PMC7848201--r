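#' Pipeline configuration
#'
#' Collects input paths, the global seed and every stage configuration.
#' Precedence for the command-line wrapper is CLI flag > config value >
#' stage default.
#'
#' @param counts,design,lsv_counts,templates input file paths (templates
#'   optional: NULL uses [reference_templates()]).
#' @param out_dir output directory.
#' @param seed global seed (propagated to the splicing Monte Carlo).
#' @param filter a [filter_rule()].
#' @param de a [de_config()].
#' @param cluster a [cluster_config()].
#' @param splice a [splice_config()]; its seed is overridden by `seed`.
#' @param graph transition graph.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(counts, design, lsv_counts = NULL,
                            templates = NULL, out_dir = "torportx_out",
                            seed = 1L, filter = filter_rule(),
                            de = de_config(), cluster = cluster_config(),
                            splice = splice_config(), graph = state_graph()) {
  structure(list(counts = counts, design = design, lsv_counts = lsv_counts,
                 templates = templates, out_dir = out_dir,
                 seed = as.integer(seed), filter = filter, de = de,
                 cluster = cluster, splice = splice, graph = graph),
            class = "pipeline_config")
}

#' Load and cross-validate pipeline inputs
#'
#' Hard errors on schema violations: samples in the counts matrix must
#' exactly match the design table; LSV samples must be a subset of design
#' samples.
#'
#' @param config a [pipeline_config()].
#' @return list: counts, design, lsv_counts (or NULL), templates,
#'   checksums (md5 per input file).
#' @export
load_inputs <- function(config) {
  for (f in c(config$counts, config$design, config$lsv_counts,
              config$templates)) {
    if (!is.null(f) && !file.exists(f)) stop("input file not found: ", f)
  }
  counts <- read_counts(config$counts)
  design <- read_design(config$design)
  miss <- setdiff(design$sample, colnames(counts))
  if (length(miss) > 0L) {
    stop("design sample(s) missing from counts: ",
         paste(miss, collapse = ", "))
  }
  extra <- setdiff(colnames(counts), design$sample)
  if (length(extra) > 0L) {
    stop("counts column(s) missing from design: ",
         paste(extra, collapse = ", "))
  }
  check_states(design$state)
  lsv <- NULL
  if (!is.null(config$lsv_counts)) {
    lsv <- read_lsv_counts(config$lsv_counts)
    bad <- setdiff(unique(lsv$sample), design$sample)
    if (length(bad) > 0L) {
      stop("LSV sample(s) missing from design: ", paste(bad, collapse = ", "))
    }
  }
  templates <- if (is.null(config$templates)) reference_templates()
               else read_templates(config$templates)
  files <- c(config$counts, config$design, config$lsv_counts,
             config$templates)
  list(counts = counts, design = design, lsv_counts = lsv,
       templates = templates,
       checksums = tools::md5sum(files[!vapply(files, is.null, logical(1))]))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Filter, differential expression (multi-state LRT plus the transition
#' pairwise tests), reference-pattern clustering of DE genes, and — if LSV
#' counts are supplied — PSI/dPSI estimation over all pairwise state
#' comparisons, dPSI pattern clustering, intron-retention classification
#' and control-intron selection.  All declared outputs plus a run manifest
#' (JSON, no timestamps so reruns are byte-identical) are written to
#' `config$out_dir`.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return invisibly, the manifest list.
#' @export
run_all <- function(config, quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  inputs <- load_inputs(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(name) file.path(config$out_dir, name)
  outputs <- character(0)
  warnings <- character(0)
  counts <- inputs$counts
  design <- inputs$design
  splice_cfg <- config$splice
  splice_cfg$seed <- config$seed

  say("normalizing and filtering ", nrow(counts), " genes, ",
      ncol(counts), " samples")
  sf <- size_factors(counts)
  expr <- transform_counts(counts, sf)
  pass <- filter_genes(expr, design, config$filter)
  outputs <- c(outputs, write_tsv(data.frame(gene = pass),
                                  out("pass_filter_genes.tsv")))
  if (length(pass) == 0L) stop("no gene passes the detection filter")

  cts_f <- counts[pass, , drop = FALSE]
  disp <- estimate_dispersions(cts_f, sf, design)

  say("LRT differential expression on ", length(pass), " pass-filter genes")
  lrt <- de_lrt(cts_f, design, config$de, factors = sf, dispersions = disp)
  outputs <- c(outputs, write_tsv(lrt, out("de_lrt.tsv")))
  if (any(!lrt$converged)) {
    warnings <- c(warnings, paste0(sum(!lrt$converged),
                                   " gene(s) failed to converge in the LRT"))
  }

  say("pairwise transition tests")
  pw <- list()
  for (i in seq_len(nrow(config$graph))) {
    a <- config$graph$from[i]; b <- config$graph$to[i]
    key <- paste0(a, "->", b)
    pw[[key]] <- pairwise_de(cts_f, design, a, b, config$de, factors = sf,
                             dispersions = disp)
    fn <- out(paste0("pairwise_", a, "_", b, ".tsv"))
    outputs <- c(outputs, write_tsv(pw[[key]], fn))
  }
  trans <- transition_summary(pw, config$graph, config$de)
  outputs <- c(outputs, write_tsv(trans$edges, out("transitions.tsv")))

  say("reference-pattern clustering of DE genes")
  de_genes <- lrt$gene[!is.na(lrt$padj) & lrt$padj <= config$de$lrt_alpha]
  cl <- NULL
  if (length(de_genes) > 0L) {
    means <- state_means(expr[de_genes, , drop = FALSE], design)
    cl <- assign_clusters(means, inputs$templates, config$cluster)
    outputs <- c(outputs, write_tsv(cl, out("clusters.tsv")))
  }

  splice_outputs <- NULL
  if (!is.null(inputs$lsv_counts)) {
    say("PSI estimation and dPSI tests")
    psi <- estimate_psi(inputs$lsv_counts, design, splice_cfg)
    sig <- dpsi_all_pairs(psi, splice_cfg)
    outputs <- c(outputs, write_tsv(sig, out("lsv_significance.tsv")))
    sig_ids <- sig$lsv_id[sig$significant]
    dcl <- cluster_dpsi_patterns(psi, sig_ids, inputs$templates, splice_cfg,
                                 config$cluster)
    if (!is.null(dcl$assignments)) {
      outputs <- c(outputs, write_tsv(dcl$assignments,
                                      out("lsv_clusters.tsv")))
    }
    ir_ids <- names(psi)[vapply(psi, function(r) {
      any(r$junctions$is_retained_intron)
    }, logical(1))]
    if (length(ir_ids) > 0L) {
      ir <- data.frame(
        lsv_id = ir_ids,
        orientation = vapply(ir_ids, function(id) {
          as.character(classify_intron_retention(psi[[id]], splice_cfg))
        }, character(1)), stringsAsFactors = FALSE)
      outputs <- c(outputs, write_tsv(ir, out("intron_retention.tsv")))
      ctrl <- select_control_introns(psi, splice_cfg)
      outputs <- c(outputs, write_tsv(ctrl, out("control_introns.bed")))
      if (length(attr(ctrl, "skipped")) > 0L) {
        warnings <- c(warnings,
                      paste0(length(attr(ctrl, "skipped")),
                             " retained intron(s) without coordinates skipped"))
      }
    }
    splice_outputs <- list(n_lsv = length(psi), n_significant = sum(sig$significant))
  }

  manifest <- list(
    package = "torportx",
    version = as.character(utils::packageVersion("torportx")),
    seed = config$seed,
    inputs = as.list(inputs$checksums),
    config = list(
      filter = unclass(config$filter), de = unclass(config$de),
      cluster = unclass(config$cluster), splice = unclass(splice_cfg)),
    stages = list(
      n_genes = nrow(counts), n_samples = ncol(counts),
      n_pass_filter = length(pass), n_de_lrt = length(de_genes),
      transitions = trans$total_de, splicing = splice_outputs),
    warnings = warnings,
    outputs = basename(outputs))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  say("done: ", length(outputs), " output file(s) + manifest in ",
      config$out_dir)
  invisible(manifest)
}
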