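#' Canonical reference pattern templates
#'
#' The ten named state-profile templates used for reference-pattern
#' clustering, as relative levels over the canonical state order
#' (SA, IBA, Ent, LT, Ar, SpD).  Naming convention: `Winter_*` patterns
#' separate the heterothermic season from the two active states;
#' `IBA_high` marks the burst of transcripts in the interbout arousal;
#' `Cold_high_*` / `Cold_low_*` patterns are driven by body temperature,
#' with the `EH`/`EM`/`EL` suffix giving the relative abundance during
#' entrance into torpor (high, medium, low).
#'
#' Pattern assignment uses Pearson correlation, which is invariant to
#' positive affine transforms, so only the shape of each vector matters.
#' Templates are data, not code: any data.frame/matrix with one row per
#' template and one column per state can be supplied wherever templates are
#' accepted, e.g. via [read_templates()].
#'
#' @return Numeric matrix, 10 templates x 6 states, with dimnames.
#' @export
#' @examples
#' reference_templates()["Winter_high", ]
reference_templates <- function() {
  states <- hibernation_states()
  tpl <- rbind(
    Winter_high  = c(0, 1, 1,   1, 1, 0),
    Winter_low   = c(1, 0, 0,   0, 0, 1),
    IBA_high     = c(0, 1, 0,   0, 0, 0),
    IBA_low      = c(1, 0, 1,   1, 1, 1),
    Cold_high_EH = c(0, 0, 1,   1, 1, 0),
    Cold_high_EM = c(0, 0, 0.5, 1, 1, 0),
    Cold_high_EL = c(0, 0, 0,   1, 1, 0),
    Cold_low_EH  = c(1, 1, 1,   0, 0, 1),
    Cold_low_EM  = c(1, 1, 0.5, 0, 0, 1),
    Cold_low_EL  = c(1, 1, 0,   0, 0, 1)
  )
  colnames(tpl) <- states
  tpl
}

#' Read pattern templates from a delimited file
#'
#' Expects a header `name` column followed by one column per state, in any
#' order covering the canonical states.  Tab- or comma-separated (sniffed
#' from the first line).
#'
#' @param path file path.
#' @return numeric matrix, templates x states in canonical order.
#' @export
read_templates <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!"name" %in% names(df)) stop("template file needs a 'name' column")
  states <- hibernation_states()
  missing <- setdiff(states, names(df))
  if (length(missing) > 0L) {
    stop("template file missing state column(s): ",
         paste(missing, collapse = ", "))
  }
  m <- as.matrix(df[, states, drop = FALSE])
  rownames(m) <- df$name
  validate_templates(m)
  m
}

#' Write pattern templates to a TSV file
#' @param templates templates matrix as from [reference_templates()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_templates <- function(templates, path) {
  df <- data.frame(name = rownames(templates), templates,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_templates <- function(templates) {
  if (is.null(dim(templates)) || nrow(templates) < 1L) {
    stop("empty template set")
  }
  if (is.null(rownames(templates)) || anyDuplicated(rownames(templates))) {
    stop("templates need unique row names")
  }
  v <- apply(templates, 1L, stats::var)
  if (any(v <= 0)) {
    stop("constant template(s): ",
         paste(rownames(templates)[v <= 0], collapse = ", "))
  }
  invisible(TRUE)
}
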