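#' Splicing analysis configuration
#'
#' @param delta minimum |dPSI| of interest.
#' @param prob_threshold posterior probability required to call an LSV
#'   significant (general rule: 0.999 probability of |dPSI| >= delta).
#' @param ir_prob_threshold relaxed probability used only by the
#'   temperature-dependence scan for retained introns.
#' @param reference_state orientation state (summer active); the dominant
#'   junction and dPSI-vs-reference profiles are defined against it.
#' @param prior Dirichlet prior pseudocount per junction (Jeffreys 1/2).
#' @param mc_samples Monte-Carlo draws for dPSI probabilities.
#' @param seed base seed for the (deterministic) Monte-Carlo draws.
#' @return object of class `splice_config`.
#' @export
splice_config <- function(delta = 0.2, prob_threshold = 0.999,
                          ir_prob_threshold = 0.90, reference_state = "SA",
                          prior = 0.5, mc_samples = 10000L, seed = 1L) {
  stopifnot(delta > 0, delta < 1, prob_threshold > 0, prob_threshold < 1,
            ir_prob_threshold > 0, ir_prob_threshold < 1, prior > 0,
            mc_samples >= 100L)
  structure(list(delta = delta, prob_threshold = prob_threshold,
                 ir_prob_threshold = ir_prob_threshold,
                 reference_state = reference_state, prior = prior,
                 mc_samples = as.integer(mc_samples), seed = as.integer(seed)),
            class = "splice_config")
}

#' Estimate per-state PSI for every LSV
#'
#' Replicate junction counts are pooled within each state and combined with
#' a symmetric Dirichlet prior; the posterior over junction proportions is
#' Dirichlet(prior + pooled counts) and PSI point estimates are its means,
#' which sum to 1 across the LSV's junctions by construction.  States with
#' zero pooled coverage are flagged uninformative and excluded from tests.
#'
#' @param lsv_counts long data.frame (lsv_id, gene_id, junction_id,
#'   is_retained_intron, sample, count; optional chrom/start/end/strand on
#'   retained-intron rows).
#' @param design design table mapping samples to states.
#' @param config a [splice_config()].
#' @return object of class `psi_set`: a named list of per-LSV records with
#'   elements `lsv_id`, `gene_id`, `junctions` (data.frame), `counts`
#'   (junctions x states pooled matrix), `alpha` (posterior Dirichlet
#'   parameters), `psi` (posterior means), `informative` (logical per
#'   state).
#' @export
estimate_psi <- function(lsv_counts, design, config = splice_config()) {
  stopifnot(all(lsv_counts$sample %in% design$sample))
  states <- intersect(hibernation_states(), unique(design$state))
  extra <- setdiff(unique(design$state), states)
  states <- c(states, extra)
  state_of <- stats::setNames(design$state, design$sample)
  lsv_counts$state <- state_of[lsv_counts$sample]

  recs <- lapply(split(lsv_counts, lsv_counts$lsv_id), function(df) {
    jinfo <- unique(df[, intersect(c("junction_id", "is_retained_intron",
                                     "chrom", "start", "end", "strand"),
                                   names(df))])
    jinfo <- jinfo[order(jinfo$junction_id), , drop = FALSE]
    if (nrow(jinfo) < 2L) {
      stop("LSV ", df$lsv_id[1], " has fewer than 2 junctions")
    }
    cnt <- matrix(0, nrow(jinfo), length(states),
                  dimnames = list(jinfo$junction_id, states))
    agg <- stats::aggregate(count ~ junction_id + state, df, sum)
    cnt[cbind(agg$junction_id, agg$state)] <- agg$count
    alpha <- cnt + config$prior
    psi <- sweep(alpha, 2L, colSums(alpha), "/")
    informative <- colSums(cnt) > 0
    list(lsv_id = df$lsv_id[1], gene_id = df$gene_id[1], junctions = jinfo,
         counts = cnt, alpha = alpha, psi = psi, informative = informative)
  })
  structure(recs, class = "psi_set", states = states)
}

# deterministic per-LSV seed derived from the config seed and the LSV id;
# kept below 2^31
lsv_seed <- function(config, lsv_id) {
  h <- sum(utf8ToInt(lsv_id) * seq_along(utf8ToInt(lsv_id)))
  (config$seed * 10007L + h) %% 2147483647L
}

rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(stats::rgamma(n * k, shape = alpha), ncol = k, byrow = TRUE)
  g / rowSums(g)
}

#' Posterior dPSI test between two states for one LSV
#'
#' Monte-Carlo draws from the two states' Dirichlet posteriors give, per
#' junction, E\[dPSI\] (state B minus state A) and the one-sided
#' probabilities P(dPSI >= delta) and P(dPSI <= -delta).  The LSV is
#' significant if the larger of the two one-sided probabilities reaches
#' `prob_threshold` for any junction.
#'
#' @param rec one element of a [estimate_psi()] `psi_set`.
#' @param stateA,stateB state labels (dPSI is B minus A).
#' @param config a [splice_config()].
#' @param prob_threshold override of `config$prob_threshold` (the intron
#'   retention scan uses the relaxed one).
#' @return list: `significant`, `per_junction` data.frame (junction_id,
#'   e_dpsi, p_ge, p_le), `informative`.
#' @export
dpsi_test <- function(rec, stateA, stateB, config = splice_config(),
                      prob_threshold = config$prob_threshold) {
  if (!all(c(stateA, stateB) %in% colnames(rec$alpha))) {
    stop("state not estimated for LSV ", rec$lsv_id)
  }
  if (!rec$informative[stateA] || !rec$informative[stateB]) {
    return(list(significant = FALSE, per_junction = NULL,
                informative = FALSE))
  }
  with_local_seed(lsv_seed(config, rec$lsv_id), {
    da <- rdirichlet(config$mc_samples, rec$alpha[, stateA])
    db <- rdirichlet(config$mc_samples, rec$alpha[, stateB])
    dpsi <- db - da
    per_j <- data.frame(
      junction_id = rownames(rec$alpha),
      e_dpsi = rec$psi[, stateB] - rec$psi[, stateA],
      p_ge = colMeans(dpsi >= config$delta),
      p_le = colMeans(dpsi <= -config$delta),
      stringsAsFactors = FALSE, row.names = NULL)
    sig <- max(pmax(per_j$p_ge, per_j$p_le)) >= prob_threshold
    list(significant = sig, per_junction = per_j, informative = TRUE)
  })
}

#' Run the dPSI test over all pairwise state comparisons
#'
#' An LSV is study-significant if significant in any pairwise state
#' comparison.
#'
#' @param psi a `psi_set`.
#' @param config a [splice_config()].
#' @param pairs optional 2-column matrix/data.frame of state pairs; default
#'   all unordered pairs of estimated states, dPSI oriented later minus
#'   earlier in canonical order.
#' @param prob_threshold threshold override, see [dpsi_test()].
#' @return data.frame: lsv_id, significant, best_prob, n_pairs_significant.
#' @export
dpsi_all_pairs <- function(psi, config = splice_config(), pairs = NULL,
                           prob_threshold = config$prob_threshold) {
  states <- attr(psi, "states")
  if (is.null(pairs)) {
    cmb <- utils::combn(states, 2L)
    pairs <- data.frame(a = cmb[1, ], b = cmb[2, ], stringsAsFactors = FALSE)
  }
  need <- unique(c(pairs$a, pairs$b))
  rows <- lapply(psi, function(rec) {
    # one set of posterior draws per informative state, reused across pairs;
    # seeded per LSV so results match repeated dpsi_test() runs in law
    draws <- with_local_seed(lsv_seed(config, rec$lsv_id), {
      lapply(stats::setNames(need, need), function(st) {
        if (!st %in% colnames(rec$alpha) || !rec$informative[st]) NULL
        else rdirichlet(config$mc_samples, rec$alpha[, st])
      })
    })
    best <- 0
    nsig <- 0L
    for (k in seq_len(nrow(pairs))) {
      da <- draws[[pairs$a[k]]]
      db <- draws[[pairs$b[k]]]
      if (is.null(da) || is.null(db)) next
      dpsi <- db - da
      p <- max(pmax(colMeans(dpsi >= config$delta),
                    colMeans(dpsi <= -config$delta)))
      best <- max(best, p)
      if (p >= prob_threshold) nsig <- nsig + 1L
    }
    data.frame(lsv_id = rec$lsv_id, significant = nsig > 0L,
               best_prob = best, n_pairs_significant = nsig,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Summer-dominant junction of an LSV
#'
#' The junction with the highest posterior-mean PSI in the reference
#' (summer-active) state; exact ties go to the lowest junction id, recorded
#' in `attr(, "tie")`.
#'
#' @param rec one `psi_set` element.
#' @param config a [splice_config()].
#' @return junction id (character).
#' @export
dominant_junction <- function(rec, config = splice_config()) {
  ref <- config$reference_state
  if (!ref %in% colnames(rec$psi) || !rec$informative[ref]) {
    stop("reference state ", ref, " uninformative for LSV ", rec$lsv_id)
  }
  p <- rec$psi[, ref]
  best <- which(p == max(p))
  j <- sort(rownames(rec$psi)[best])[1]
  structure(j, tie = length(best) > 1L)
}

#' Cluster dPSI-vs-reference patterns
#'
#' For each study-significant LSV, builds the state profile of expected
#' dPSI relative to the reference state for (a) the reference-dominant
#' junction and (b) the retained intron if present, then assigns both
#' profiles to the shared reference-pattern templates.  The reference
#' state's entry is 0 by construction; flat profiles end up Unassigned.
#'
#' @param psi a `psi_set`.
#' @param significant_ids lsv_ids to profile (the study-significant set).
#' @param templates templates matrix.
#' @param config a [splice_config()].
#' @param cluster_cfg a [cluster_config()].
#' @return list with `profiles` (units x states matrix of dPSI-vs-reference;
#'   unit names `<lsv>:dominant` / `<lsv>:retained`) and `assignments`
#'   (from [assign_clusters()]).
#' @export
cluster_dpsi_patterns <- function(psi, significant_ids,
                                  templates = reference_templates(),
                                  config = splice_config(),
                                  cluster_cfg = cluster_config()) {
  ref <- config$reference_state
  states <- attr(psi, "states")
  if (!ref %in% states) stop("reference state ", ref, " not estimated")
  prof <- list()
  for (id in significant_ids) {
    rec <- psi[[id]]
    if (is.null(rec)) stop("unknown LSV id: ", id)
    if (!rec$informative[ref]) stop("missing reference estimate for ", id)
    dom <- dominant_junction(rec, config)
    prof[[paste0(id, ":dominant")]] <- rec$psi[dom, ] - rec$psi[dom, ref]
    ri <- rec$junctions$junction_id[rec$junctions$is_retained_intron]
    if (length(ri) == 1L && ri != dom) {
      prof[[paste0(id, ":retained")]] <- rec$psi[ri, ] - rec$psi[ri, ref]
    }
  }
  if (length(prof) == 0L) {
    return(list(profiles = NULL, assignments = NULL))
  }
  profiles <- do.call(rbind, prof)
  colnames(profiles) <- states
  list(profiles = profiles,
       assignments = assign_clusters(profiles, templates, cluster_cfg))
}

#' Classify intron-retention orientation
#'
#' An LSV with a retained-intron junction is "retained-default" when that
#' junction has the maximal PSI in the reference (warm, summer-active)
#' state — intron retention is the default homeothermic configuration —
#' and "excised-default" otherwise.  Ties classify as retained-default and
#' are flagged.
#'
#' @param rec one `psi_set` element with a retained-intron junction.
#' @param config a [splice_config()].
#' @return character label with attribute `tie`.
#' @export
classify_intron_retention <- function(rec, config = splice_config()) {
  ri <- rec$junctions$junction_id[rec$junctions$is_retained_intron]
  if (length(ri) != 1L) {
    stop("LSV ", rec$lsv_id, " has no (single) retained-intron junction")
  }
  ref <- config$reference_state
  p <- rec$psi[, ref]
  mx <- max(p)
  tie <- sum(p == mx) > 1L && p[ri] == mx
  lab <- if (p[ri] >= mx) "retained-default" else "excised-default"
  structure(lab, tie = tie)
}

#' Temperature-dependence gate for retained introns
#'
#' A retained-intron LSV is temperature dependent if it passes the relaxed
#' probability rule (`ir_prob_threshold` of |dPSI| >= delta) in any
#' warm-versus-cold state comparison.
#'
#' @param psi a `psi_set`.
#' @param config a [splice_config()].
#' @param partition warm/cold partition, see [warm_cold_states()].
#' @return character vector of temperature-dependent lsv_ids.
#' @export
temperature_dependent_irs <- function(psi, config = splice_config(),
                                      partition = warm_cold_states()) {
  states <- attr(psi, "states")
  warm <- intersect(partition$warm, states)
  cold <- intersect(partition$cold, states)
  pairs <- expand.grid(a = warm, b = cold, stringsAsFactors = FALSE)
  ir_ids <- names(psi)[vapply(psi, function(r) {
    any(r$junctions$is_retained_intron)
  }, logical(1))]
  res <- dpsi_all_pairs(psi[ir_ids], config, pairs = pairs,
                        prob_threshold = config$ir_prob_threshold)
  if (is.null(res)) return(character(0))
  res$lsv_id[res$significant]
}

#' Select control retained introns
#'
#' Retained introns that fail the temperature-dependence gate and do not
#' genomically overlap any temperature-dependent retained intron; emitted
#' BED-like for external splice-site strength scoring.  Introns without
#' coordinates are skipped and listed in `attr(, "skipped")`.
#'
#' @param psi a `psi_set`.
#' @param config a [splice_config()].
#' @param significant_ids ids of temperature-dependent retained-intron
#'   LSVs; computed via [temperature_dependent_irs()] if NULL.
#' @return data.frame with BED-like columns chrom, start, end, name, score,
#'   strand (0-based half-open starts as in BED).
#' @export
select_control_introns <- function(psi, config = splice_config(),
                                   significant_ids = NULL) {
  if (is.null(significant_ids)) {
    significant_ids <- temperature_dependent_irs(psi, config)
  }
  get_ir_coord <- function(rec) {
    j <- rec$junctions[rec$junctions$is_retained_intron, , drop = FALSE]
    if (nrow(j) != 1L || !all(c("chrom", "start", "end") %in% names(j)) ||
        is.na(j$start)) {
      return(NULL)
    }
    data.frame(chrom = j$chrom, start = j$start, end = j$end,
               name = rec$lsv_id, score = 0,
               strand = if ("strand" %in% names(j)) j$strand else "*",
               stringsAsFactors = FALSE)
  }
  ir_ids <- names(psi)[vapply(psi, function(r) {
    any(r$junctions$is_retained_intron)
  }, logical(1))]
  skipped <- character(0)
  sig_coords <- list()
  cand <- list()
  for (id in ir_ids) {
    co <- get_ir_coord(psi[[id]])
    if (is.null(co)) {
      skipped <- c(skipped, id)
      next
    }
    if (id %in% significant_ids) sig_coords[[id]] <- co else cand[[id]] <- co
  }
  keep <- list()
  for (id in names(cand)) {
    co <- cand[[id]]
    overlaps <- any(vapply(sig_coords, function(s) {
      s$chrom == co$chrom && s$start < co$end && co$start < s$end
    }, logical(1)))
    if (!overlaps) keep[[id]] <- co
  }
  out <- if (length(keep) > 0L) {
    do.call(rbind, c(keep, list(make.row.names = FALSE)))
  } else {
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               name = character(0), score = numeric(0), strand = character(0))
  }
  attr(out, "skipped") <- skipped
  out
}
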