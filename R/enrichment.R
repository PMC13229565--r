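# Local Fisher-exact gene-set enrichment with BH adjustment.  The
# background universe is the set of all network genes from the pathway
# stage (not the gene-set library's own universe); terms that do not
# intersect the background are skipped rather than tested.

#' Fisher-exact gene-set enrichment of a query gene list
#'
#' Per term, a one-sided Fisher exact test of the 2x2 table
#' (query & term, query & not term, not query & term, neither) within the
#' background, followed by Benjamini-Hochberg adjustment across all
#' tested terms.  Query genes outside the background are dropped with a
#' warning; terms with zero background overlap are skipped.
#'
#' @param query Character vector of genes of interest (e.g. a favorable
#'   gene selection).
#' @param background Character vector: the gene universe (all network
#'   genes).
#' @param sets A `gene_set_collection`.
#' @return An `enrichment_table` data frame ranked by adjusted p, then p,
#'   then term id: columns `term_id`, `term_name`, `n_overlap`,
#'   `overlap_genes` (list-column), `p_value`, `adjusted_p`, `rank`.
#' @export
fisher_enrichment <- function(query, background, sets) {
  stopifnot(inherits(sets, "gene_set_collection"))
  background <- unique(toupper_trim(background))
  if (!length(background)) stop_ps("empty background")
  query <- unique(toupper_trim(query))
  outside <- setdiff(query, background)
  if (length(outside)) {
    warn_ps(
      "dropping ", length(outside),
      " query gene(s) outside the background"
    )
    query <- intersect(query, background)
  }
  if (!length(query)) stop_ps("empty query after background filtering")
  n_u <- length(background)
  n_q <- length(query)
  rows <- lapply(names(sets$sets), function(id) {
    term <- intersect(sets$sets[[id]], background)
    if (!length(term)) {
      return(NULL)
    }
    ov <- intersect(query, term)
    data.frame(
      term_id = id,
      term_name = unname(sets$term_names[id]),
      n_overlap = length(ov),
      overlap_genes = I(list(sort(ov))),
      p_value = hypergeom_tail_p(length(ov), length(term), n_q, n_u),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out)) {
    out <- data.frame(
      term_id = character(), term_name = character(),
      n_overlap = integer(), overlap_genes = I(list()),
      p_value = numeric()
    )
  }
  out$adjusted_p <- bh_adjust(out$p_value)
  ord <- order(out$adjusted_p, out$p_value, out$term_id)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("enrichment_table", "data.frame")
  out
}

#' Keep the top-ranked enrichment terms
#'
#' @param table An `enrichment_table` (already ranked; ties resolved by
#'   term id).
#' @param k Number of terms to keep (default 10).
#' @return The first `min(k, nrow)` rows.
#' @export
top_terms <- function(table, k = 10L) {
  stopifnot(inherits(table, "enrichment_table"))
  if (k <= 0) stop_ps("k must be > 0")
  utils::head(table, k)
}

#' Write an enrichment table to TSV
#'
#' @param table An `enrichment_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_enrichment_table <- function(table, path) {
  out <- as.data.frame(table)
  out$overlap_genes <- vapply(
    table$overlap_genes, paste, "", collapse = ";"
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
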