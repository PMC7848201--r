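#' Clustering configuration
#'
#' @param r_min minimum Pearson correlation for assignment to a named
#'   cluster; profiles below it fall into `unassigned_label`.
#' @param unassigned_label label for unassignable profiles.
#' @return object of class `cluster_config`.
#' @export
cluster_config <- function(r_min = 0.8, unassigned_label = "Unassigned") {
  stopifnot(r_min > 0, r_min <= 1)
  structure(list(r_min = r_min, unassigned_label = unassigned_label),
            class = "cluster_config")
}

#' Per-state mean expression profiles
#'
#' Arithmetic mean of transformed values per state, columns in canonical
#' state order (restricted to states present in the design).
#'
#' @param expr transformed matrix, genes x samples.
#' @param design design table.
#' @return numeric matrix, genes x states.
#' @export
state_means <- function(expr, design) {
  stopifnot(all(design$sample %in% colnames(expr)))
  states <- intersect(hibernation_states(), unique(design$state))
  if (length(states) == 0L) states <- unique(design$state)
  extra <- setdiff(unique(design$state), states)
  states <- c(states, extra)
  m <- vapply(states, function(st) {
    cols <- design$sample[design$state == st]
    if (length(cols) == 0L) stop("state with no samples: ", st)
    rowMeans(expr[, cols, drop = FALSE])
  }, numeric(nrow(expr)))
  if (is.null(dim(m))) m <- matrix(m, nrow = 1,
                                   dimnames = list(rownames(expr), states))
  m
}

#' Pearson correlation of profiles against templates
#'
#' Rows with zero variance (flat profiles) get NA against every template:
#' Pearson correlation is undefined there and such units are never assigned
#' to a named cluster.
#'
#' @param means units x states matrix (or a single profile vector).
#' @param templates templates x states matrix; columns must cover the
#'   states of `means`.
#' @return units x templates matrix of correlations.
#' @export
correlate_templates <- function(means, templates = reference_templates()) {
  if (is.null(dim(means))) {
    means <- matrix(means, nrow = 1,
                    dimnames = list("profile", names(means)))
  }
  validate_templates(templates)
  if (!is.null(colnames(means))) {
    miss <- setdiff(colnames(means), colnames(templates))
    if (length(miss) > 0L) {
      stop("templates missing state(s): ", paste(miss, collapse = ", "))
    }
    templates <- templates[, colnames(means), drop = FALSE]
  }
  if (ncol(means) < 3L) stop("need >= 3 states for correlation")
  r <- suppressWarnings(stats::cor(t(means), t(templates)))
  flat <- apply(means, 1L, stats::var) == 0
  r[flat, ] <- NA_real_
  rownames(r) <- rownames(means)
  r
}

#' Assign profiles to reference-pattern clusters
#'
#' Each unit goes to the template with the highest Pearson correlation if
#' that correlation reaches `r_min`, otherwise to the Unassigned cluster.
#' Exact ties are broken by template order (first wins) and recorded in
#' `attr(, "ties")`.
#'
#' @param means units x states matrix of profiles.
#' @param templates templates matrix.
#' @param config a [cluster_config()].
#' @return data.frame: unit, cluster, r_best, r_runner_up.
#' @export
assign_clusters <- function(means, templates = reference_templates(),
                            config = cluster_config()) {
  r <- correlate_templates(means, templates)
  tie_units <- character(0)
  n <- nrow(r)
  cluster <- character(n)
  r_best <- r_runner <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    ri <- r[i, ]
    if (all(is.na(ri))) {
      cluster[i] <- config$unassigned_label
      next
    }
    ord <- order(ri, decreasing = TRUE, na.last = TRUE)
    best <- ord[1]
    r_best[i] <- ri[best]
    if (length(ri) > 1L) r_runner[i] <- ri[ord[2]]
    if (!is.na(r_runner[i]) && r_runner[i] == r_best[i]) {
      tie_units <- c(tie_units, rownames(r)[i])
    }
    cluster[i] <- if (r_best[i] >= config$r_min) {
      rownames(templates)[best]
    } else {
      config$unassigned_label
    }
  }
  out <- data.frame(unit = rownames(r), cluster = cluster, r_best = r_best,
                    r_runner_up = r_runner, stringsAsFactors = FALSE)
  attr(out, "ties") <- tie_units
  out
}
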