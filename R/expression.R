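#' Detection filter rule
#'
#' A gene is detected if its transformed expression reaches
#' `min_transform_value` (log2 scale) in at least `min_pass_fraction` of the
#' replicates of at least one physiological state.  The default (7 in at
#' least 4/5 individuals of at least one group) keeps genes with roughly
#' 127+ normalized counts in most replicates of some state.
#'
#' @param min_transform_value log2-scale detection threshold.
#' @param min_pass_fraction fraction of a group's replicates required.
#' @return object of class `filter_rule`.
#' @export
filter_rule <- function(min_transform_value = 7, min_pass_fraction = 4 / 5) {
  stopifnot(min_pass_fraction > 0, min_pass_fraction <= 1)
  structure(list(min_transform_value = min_transform_value,
                 min_pass_fraction = min_pass_fraction),
            class = "filter_rule")
}

#' Differential-expression configuration
#'
#' @param lrt_alpha BH-adjusted significance level for the multi-state LRT.
#' @param pairwise_alpha BH-adjusted level for pairwise transition tests.
#' @param shrinkage_sd prior sd (log2 units) of the Normal(0, sd^2) prior
#'   used for shrunken log2 fold-changes.
#' @return object of class `de_config`.
#' @export
de_config <- function(lrt_alpha = 0.001, pairwise_alpha = 0.001,
                      shrinkage_sd = 1.0) {
  stopifnot(lrt_alpha > 0, lrt_alpha < 1, pairwise_alpha > 0,
            pairwise_alpha < 1, shrinkage_sd > 0)
  structure(list(lrt_alpha = lrt_alpha, pairwise_alpha = pairwise_alpha,
                 shrinkage_sd = shrinkage_sd), class = "de_config")
}

#' Median-of-ratios size factors
#'
#' Per-sample normalization factors computed against a geometric-mean
#' pseudo-reference over genes with all-positive counts.  If no gene has
#' positive counts in every sample, falls back to total-count scaling
#' (factors normalized to geometric mean 1) with a warning.
#'
#' @param counts integer matrix, genes x samples.
#' @return numeric vector of positive factors, one per sample.
#' @export
size_factors <- function(counts) {
  if (any(colSums(counts) == 0)) {
    stop("sample(s) with all-zero counts: ",
         paste(colnames(counts)[colSums(counts) == 0], collapse = ", "))
  }
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos)) {
    warning("no gene with all-positive counts; using total-count scaling")
    tot <- colSums(counts)
    sf <- tot / exp(mean(log(tot)))
    return(stats::setNames(sf, colnames(counts)))
  }
  logref <- rowMeans(log(counts[pos, , drop = FALSE]))
  sf <- apply(counts[pos, , drop = FALSE], 2L, function(col) {
    exp(stats::median(log(col) - logref))
  })
  stats::setNames(sf, colnames(counts))
}

#' Log-scale transform of normalized counts
#'
#' `log2(count / factor + 1)`, a light-weight stand-in for a regularized
#' log transform: monotone in counts and equal to 7 at 127 normalized
#' counts, so the detection filter's threshold keeps its meaning.
#'
#' @param counts integer matrix.
#' @param factors size factors from [size_factors()].
#' @return numeric matrix, same dimensions.
#' @export
transform_counts <- function(counts, factors) {
  stopifnot(length(factors) == ncol(counts), all(factors > 0))
  log2(sweep(counts, 2L, factors, "/") + 1)
}

#' Apply the detection filter
#'
#' @param expr transformed matrix from [transform_counts()].
#' @param design design table (column `state`).
#' @param rule a [filter_rule()].
#' @return character vector of pass-filter gene ids.
#' @export
filter_genes <- function(expr, design, rule = filter_rule()) {
  stopifnot(inherits(rule, "filter_rule"),
            all(design$sample %in% colnames(expr)))
  groups <- split(design$sample, design$state)
  if (any(lengths(groups) < 1L)) stop("state group with no samples")
  pass <- rep(FALSE, nrow(expr))
  for (g in groups) {
    need <- ceiling(rule$min_pass_fraction * length(g))
    hits <- rowSums(expr[, g, drop = FALSE] >= rule$min_transform_value)
    pass <- pass | (hits >= need)
  }
  rownames(expr)[pass]
}

#' Method-of-moments NB dispersion estimates
#'
#' Per gene, the dispersion d in var = mu + d mu^2 is estimated from
#' within-state means and variances of normalized counts, pooled across
#' states with df weights, floored at 1e-8, then shrunk 50% toward the
#' mean dispersion across genes.  A deliberately simple stabilizer for
#' small-n designs; no empirical-Bayes machinery.  Grouping by state only
#' (not state x sex) keeps per-group df workable at n = 5; the sex term's
#' small variance is absorbed into the dispersion, a mildly conservative
#' choice for the state test.
#'
#' @param counts integer matrix.
#' @param factors size factors.
#' @param design design table (`state`, `sex`).
#' @return numeric vector of dispersions, one per gene.
#' @export
estimate_dispersions <- function(counts, factors, design) {
  norm <- sweep(counts, 2L, factors, "/")
  grp <- factor(design$state)
  idx <- split(seq_len(ncol(norm)), grp)
  idx <- idx[lengths(idx) >= 2L]
  num <- den <- rep(0, nrow(norm))
  for (cols in idx) {
    m <- rowMeans(norm[, cols, drop = FALSE])
    v <- apply(norm[, cols, drop = FALSE], 1L, stats::var)
    w <- length(cols) - 1L
    ok <- m > 0
    num[ok] <- num[ok] + w * (v[ok] - m[ok])
    den[ok] <- den[ok] + w * m[ok]^2
  }
  d <- ifelse(den > 0, num / den, 0)
  d <- pmax(d, 1e-8)
  d <- 0.5 * d + 0.5 * mean(d)
  stats::setNames(pmax(d, 1e-8), rownames(counts))
}

# fit one NB glm with fixed dispersion; returns the fit or NULL
fit_nb <- function(y, mm, disp, off) {
  fam <- MASS::negative.binomial(theta = 1 / disp)
  tryCatch(
    suppressWarnings(stats::glm.fit(mm, y, family = fam, offset = off)),
    error = function(e) NULL)
}

nb_loglik <- function(y, mu, disp) {
  sum(stats::dnbinom(y, mu = mu, size = 1 / disp, log = TRUE))
}

#' Multi-state differential expression by NB likelihood-ratio test
#'
#' Per gene, a negative-binomial GLM with log link is fitted with fixed
#' gene-wise dispersion (see [estimate_dispersions()]) under the full model
#' `~ state + sex` and the reduced model `~ sex`, both with the log size
#' factors as offset.  The LRT statistic is referred to a chi-squared
#' distribution with `n_states - 1` degrees of freedom and p-values are
#' BH-adjusted across tested genes.
#'
#' @param counts integer matrix (pass-filter genes only, typically).
#' @param design design table.
#' @param config a [de_config()].
#' @param factors size factors; computed from `counts` if NULL.
#' @param dispersions gene-wise dispersions; estimated if NULL.
#' @return data.frame: gene, stat, df, pvalue, padj, converged.
#' @export
de_lrt <- function(counts, design, config = de_config(), factors = NULL,
                   dispersions = NULL) {
  states <- unique(design$state)
  if (length(states) < 2L) stop("LRT needs >= 2 states (df would be 0)")
  if (is.null(factors)) factors <- size_factors(counts)
  if (is.null(dispersions)) {
    dispersions <- estimate_dispersions(counts, factors, design)
  }
  off <- log(factors)
  state_f <- factor(design$state, levels = intersect(hibernation_states(),
                                                     states))
  if (anyNA(state_f)) state_f <- factor(design$state)
  sex_f <- factor(design$sex)
  mm_full <- stats::model.matrix(~ state_f + sex_f)
  mm_red <- stats::model.matrix(~ sex_f)
  df <- length(states) - 1L

  res <- lapply(seq_len(nrow(counts)), function(i) {
    y <- counts[i, ]
    d <- dispersions[i]
    f1 <- fit_nb(y, mm_full, d, off)
    f0 <- fit_nb(y, mm_red, d, off)
    if (is.null(f1) || is.null(f0) || !f1$converged || !f0$converged) {
      return(c(stat = NA_real_, pvalue = NA_real_, converged = 0))
    }
    lr <- 2 * (nb_loglik(y, f1$fitted.values, d) -
                 nb_loglik(y, f0$fitted.values, d))
    lr <- max(lr, 0)
    c(stat = lr, pvalue = stats::pchisq(lr, df, lower.tail = FALSE),
      converged = 1)
  })
  res <- do.call(rbind, res)
  out <- data.frame(gene = rownames(counts), stat = res[, "stat"], df = df,
                    pvalue = res[, "pvalue"],
                    padj = stats::p.adjust(res[, "pvalue"], "BH"),
                    converged = res[, "converged"] == 1,
                    stringsAsFactors = FALSE, row.names = NULL)
  out
}

#' Pairwise differential expression between two states
#'
#' NB GLM with `~ state + sex` on the two states' samples; the state
#' coefficient gives log2FC of `stateB` over `stateA`.  A Wald test supplies
#' p-values, BH-adjusted within the pair.  The shrunken estimate is the
#' posterior mean under a Normal(0, shrinkage_sd^2) prior on log2FC with a
#' normal likelihood approximation: `raw * sd0^2 / (sd0^2 + se^2)`, so
#' shrinkage vanishes as the prior widens and |shrunken| <= |raw| always.
#'
#' @param counts integer matrix.
#' @param design design table.
#' @param stateA,stateB the two states; fold-changes are B over A.
#' @param config a [de_config()].
#' @param factors,dispersions as in [de_lrt()]; computed on the full data
#'   if NULL (recommended: pass the full-data estimates).
#' @return data.frame: gene, baseMean, log2FC, log2FC_shrunk, se, pvalue,
#'   qvalue.  Genes with all-zero counts in both states are excluded and
#'   recorded in `attr(, "excluded")`.
#' @export
pairwise_de <- function(counts, design, stateA, stateB, config = de_config(),
                        factors = NULL, dispersions = NULL) {
  check_states(c(stateA, stateB), unique(design$state))
  if (is.null(factors)) factors <- size_factors(counts)
  if (is.null(dispersions)) {
    dispersions <- estimate_dispersions(counts, factors, design)
  }
  sel <- design$state %in% c(stateA, stateB)
  dsub <- design[sel, , drop = FALSE]
  csub <- counts[, dsub$sample, drop = FALSE]
  fsub <- factors[dsub$sample]
  excluded <- rownames(csub)[rowSums(csub) == 0]
  keep <- rowSums(csub) > 0
  csub <- csub[keep, , drop = FALSE]

  off <- log(fsub)
  state_f <- factor(dsub$state, levels = c(stateA, stateB))
  sex_f <- factor(dsub$sex)
  mm <- if (nlevels(sex_f) > 1L) stats::model.matrix(~ state_f + sex_f)
        else stats::model.matrix(~ state_f)
  coef_idx <- 2L  # the stateB coefficient
  sd0 <- config$shrinkage_sd

  res <- lapply(seq_len(nrow(csub)), function(i) {
    y <- csub[i, ]
    d <- dispersions[rownames(csub)[i]]
    f <- fit_nb(y, mm, d, off)
    if (is.null(f) || !f$converged) {
      return(c(baseMean = mean(y / fsub), log2FC = NA, log2FC_shrunk = NA,
               se = NA, pvalue = NA))
    }
    b <- unname(f$coefficients[coef_idx])
    # covariance of coefficients from the IRLS weights
    xtwx <- crossprod(mm * sqrt(f$weights))
    se_nat <- tryCatch(sqrt(solve(xtwx)[coef_idx, coef_idx]),
                       error = function(e) NA_real_)
    l2fc <- b / log(2)
    se2 <- se_nat / log(2)
    shrunk <- if (is.na(se2)) NA_real_ else l2fc * sd0^2 / (sd0^2 + se2^2)
    p <- if (is.na(se2)) NA_real_ else
      2 * stats::pnorm(abs(b / se_nat), lower.tail = FALSE)
    c(baseMean = mean(y / fsub), log2FC = l2fc, log2FC_shrunk = shrunk,
      se = se2, pvalue = p)
  })
  res <- as.data.frame(do.call(rbind, res))
  out <- data.frame(gene = rownames(csub), res,
                    qvalue = stats::p.adjust(res$pvalue, "BH"),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "excluded") <- excluded
  attr(out, "comparison") <- c(stateA, stateB)
  out
}

#' Summarize DE around the circannual transition graph
#'
#' Counts, for each transition edge, the genes significantly increased and
#' decreased in the later state (q below `pairwise_alpha`), plus the union
#' of DE genes over all edges.
#'
#' @param pairwise named list of [pairwise_de()] results; names
#'   "from->to" for each edge of `graph`.
#' @param graph transition graph, see [state_graph()].
#' @param config a [de_config()].
#' @return list with `edges` (data.frame from, to, n_up, n_down) and
#'   `total_de` (count of distinct DE genes over all edges).
#' @export
transition_summary <- function(pairwise, graph = state_graph(),
                               config = de_config()) {
  keys <- paste0(graph$from, "->", graph$to)
  miss <- setdiff(keys, names(pairwise))
  if (length(miss) > 0L) {
    stop("missing pairwise result(s) for edge(s): ",
         paste(miss, collapse = ", "))
  }
  de_union <- character(0)
  rows <- lapply(seq_along(keys), function(i) {
    pw <- pairwise[[keys[i]]]
    sig <- !is.na(pw$qvalue) & pw$qvalue < config$pairwise_alpha
    de_union <<- union(de_union, pw$gene[sig])
    data.frame(from = graph$from[i], to = graph$to[i],
               n_up = sum(sig & pw$log2FC > 0),
               n_down = sum(sig & pw$log2FC < 0),
               stringsAsFactors = FALSE)
  })
  list(edges = do.call(rbind, rows), total_de = length(de_union),
       de_genes = sort(de_union))
}
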