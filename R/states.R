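#' Canonical physiological state order and transition graph
#'
#' The six sampling states of the circannual hibernation cycle, in their
#' canonical order: SA (summer active), IBA (interbout arousal), Ent
#' (entrance into torpor), LT (late torpor), Ar (arousing), SpD (spring
#' dark).  All state-profile vectors in the package (templates, state
#' means, PSI profiles) follow this order.
#'
#' @return Character vector of the six state labels.
#' @export
hibernation_states <- function() {
  c("SA", "IBA", "Ent", "LT", "Ar", "SpD")
}

#' The circannual transition graph
#'
#' Ordered physiological transitions around the hibernation year.  Each row
#' is an edge `from -> to`; differential-expression transition summaries
#' count genes increased or decreased in the `to` state relative to `from`.
#'
#' @return data.frame with columns `from`, `to`.
#' @export
state_graph <- function() {
  data.frame(
    from = c("SpD", "SA", "IBA", "Ent", "LT", "Ar", "IBA"),
    to   = c("SA", "IBA", "Ent", "LT", "Ar", "IBA", "SpD"),
    stringsAsFactors = FALSE
  )
}

#' Warm and cold state partition
#'
#' Torpid states at low body temperature (LT, Ar) versus euthermic states
#' (SA, IBA, Ent, SpD).  Used for the temperature-dependence gate on
#' retained introns.
#'
#' @return list with character vectors `warm` and `cold`.
#' @export
warm_cold_states <- function() {
  list(warm = c("SA", "IBA", "SpD", "Ent"), cold = c("LT", "Ar"))
}

# internal: validate that a vector of labels is a subset of the canonical
# states, error naming the offender otherwise
check_states <- function(x, allowed = hibernation_states()) {
  bad <- setdiff(unique(x), allowed)
  if (length(bad) > 0L) {
    stop("unknown state label(s): ", paste(bad, collapse = ", "),
         " (expected among ", paste(allowed, collapse = ", "), ")",
         call. = FALSE)
  }
  invisible(TRUE)
}
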