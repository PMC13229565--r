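# Internal helpers shared across modules.

# Uppercase + trim; the canonical form for gene symbols and drug names.
toupper_trim <- function(x) toupper(trimws(as.character(x)))

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ps <- function(...) stop(..., call. = FALSE)
warn_ps <- function(...) warning(..., call. = FALSE)

is_drugbank_id <- function(x) grepl("^DB[0-9]{5}$", x)

# Read a tab/comma table skipping "#" comment lines; always character columns,
# validation and typing happen at the call site.
read_delim_table <- function(path, sep, header) {
  if (!file.exists(path)) stop_ps("file not found: ", path)
  utils::read.table(path,
    sep = sep, header = header, comment.char = "#",
    quote = "\"", colClasses = "character", stringsAsFactors = FALSE,
    check.names = FALSE, blank.lines.skip = TRUE, fill = FALSE,
    strip.white = TRUE, fileEncoding = "UTF-8"
  )
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate correction used by both the phenotype
#' association stage and the gene-set enrichment stage (one shared
#' implementation).  Input order is preserved; adjusted values are monotone
#' in the ranks and capped at 1.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of BH-adjusted p-values, same length and order.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.04, 0.05))
bh_adjust <- function(p) {
  if (!is.numeric(p)) stop_ps("p-values must be numeric")
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    stop_ps("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

# One-sided (enrichment) Fisher exact p for a 2x2 overlap table: the
# hypergeometric tail P(X >= overlap) with X ~ Hypergeom(N, K, n).
hypergeom_tail_p <- function(overlap, n_set, n_draw, n_universe) {
  stats::phyper(overlap - 1, n_set, n_universe - n_set, n_draw,
    lower.tail = FALSE
  )
}
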