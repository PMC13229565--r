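# Cross-screen consensus: harmonize coefficient signs into a shared
# favorable/unfavorable vocabulary, aggregate per-gene coefficient
# magnitudes across screens, and report genes and enrichment terms shared
# between screens.

#' Harmonize coefficient favorability across screens
#'
#' A gene is favorable in a screen when the sign of its coefficient
#' equals that screen's favorable sign (negative only for screens where a
#' decrease in the measured outcome is the desired effect); genes with a
#' zero coefficient are in neither list.
#'
#' @param coeff_tables Named list of per-screen `coefficient_table`s.
#' @param conventions Named numeric/integer vector of +1/-1 favorable
#'   signs; every name must match a screen in `coeff_tables` and every
#'   screen must be covered.
#' @return Named list per screen: `list(favorable = ..., unfavorable =
#'   ...)` sorted gene vectors.
#' @export
harmonize_favorability <- function(coeff_tables, conventions) {
  screens <- names(coeff_tables)
  unknown <- setdiff(names(conventions), screens)
  if (length(unknown)) {
    stop_ps(
      "conventions name unknown screen(s): ",
      paste(unknown, collapse = ", ")
    )
  }
  uncovered <- setdiff(screens, names(conventions))
  if (length(uncovered)) {
    stop_ps(
      "no favorable-sign convention for screen(s): ",
      paste(uncovered, collapse = ", ")
    )
  }
  if (!all(conventions %in% c(-1, 1))) {
    stop_ps("favorable signs must be +1 or -1")
  }
  out <- lapply(screens, function(s) {
    tb <- coeff_tables[[s]]
    fs <- conventions[[s]]
    list(
      favorable = sort(tb$gene[sign(tb$coefficient) == fs]),
      unfavorable = sort(tb$gene[sign(tb$coefficient) == -fs])
    )
  })
  stats::setNames(out, screens)
}

#' Aggregate per-screen coefficients for one gene
#'
#' The consensus score is the mean of the absolute per-screen
#' coefficients, rounded half-to-even to 4 decimals (the output precision
#' of the consensus tables).
#'
#' @param coefficients Numeric vector of the gene's coefficient in each
#'   compared screen.
#' @return The aggregate score (>= 0).
#' @export
#' @examples
#' aggregate_coefficient(c(-0.0228, 0.0012, 0.2249)) # 0.083
aggregate_coefficient <- function(coefficients) {
  if (!length(coefficients) || anyNA(coefficients)) {
    stop_ps("coefficients must be non-missing")
  }
  round(mean(abs(coefficients)), 4)
}

#' Build the cross-screen consensus table
#'
#' One row per gene present in every compared screen (genes missing from
#' any screen are excluded and logged, not zero-filled: absence from a
#' design matrix is lack of evidence).  Carries each screen's coefficient,
#' its favorability flag under the screen's sign convention, and the
#' aggregate mean-absolute score.
#'
#' @inheritParams harmonize_favorability
#' @return A `consensus_table` data frame sorted by decreasing
#'   `aggregate`, with one coefficient and one favorability flag column
#'   per screen.
#' @export
consensus_table <- function(coeff_tables, conventions) {
  if (length(coeff_tables) < 2L) stop_ps("need at least 2 screens")
  # validates conventions as a side effect
  harmonize_favorability(coeff_tables, conventions)
  screens <- names(coeff_tables)
  shared <- Reduce(intersect, lapply(coeff_tables, `[[`, "gene"))
  n_union <- length(unique(unlist(lapply(coeff_tables, `[[`, "gene"))))
  if (n_union > length(shared)) {
    message(
      n_union - length(shared),
      " gene(s) absent from at least one screen excluded from consensus"
    )
  }
  out <- data.frame(gene = sort(shared), stringsAsFactors = FALSE)
  for (s in screens) {
    tb <- coeff_tables[[s]]
    b <- tb$coefficient[match(out$gene, tb$gene)]
    out[[paste0("coef_", s)]] <- b
    out[[paste0("favorable_", s)]] <- sign(b) == conventions[[s]]
  }
  coef_cols <- paste0("coef_", screens)
  out$aggregate <- apply(
    as.matrix(out[, coef_cols, drop = FALSE]), 1, aggregate_coefficient
  )
  out <- out[order(-out$aggregate, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("consensus_table", "data.frame")
  out
}

#' Genes shared across screens by favorability
#'
#' Intersects the per-screen favorable lists (and, separately, the
#' unfavorable lists); optionally intersects the shared sets with a
#' reference gene set (e.g. the genes behind the pathway tool's
#' psychiatric predictions) and reports Venn region counts for the 2- or
#' 3-screen diagram of the favorable sets.
#'
#' @param favorability Named list per screen with `favorable` and
#'   `unfavorable` gene vectors ([harmonize_favorability()] output or
#'   `gene_selection`s).
#' @param reference Optional reference gene set.
#' @return A `shared_gene_report`: list with `favorable_shared`,
#'   `unfavorable_shared`, `reference_favorable`, `reference_unfavorable`,
#'   `counts` (named cardinalities), `venn` (per-direction region
#'   counts).
#' @export
shared_genes <- function(favorability, reference = NULL) {
  if (length(favorability) < 2L) stop_ps("need at least 2 screens")
  fav_sets <- lapply(favorability, `[[`, "favorable")
  unf_sets <- lapply(favorability, `[[`, "unfavorable")
  fav <- sort(Reduce(intersect, fav_sets))
  unf <- sort(Reduce(intersect, unf_sets))
  out <- list(
    favorable_shared = fav,
    unfavorable_shared = unf,
    reference_favorable = if (!is.null(reference)) {
      sort(intersect(fav, reference))
    },
    reference_unfavorable = if (!is.null(reference)) {
      sort(intersect(unf, reference))
    },
    counts = c(
      favorable = length(fav), unfavorable = length(unf),
      reference_favorable = if (!is.null(reference)) {
        length(intersect(fav, reference))
      } else {
        NA_integer_
      },
      reference_unfavorable = if (!is.null(reference)) {
        length(intersect(unf, reference))
      } else {
        NA_integer_
      }
    ),
    venn = list(
      favorable = venn_counts(fav_sets),
      unfavorable = venn_counts(unf_sets)
    )
  )
  structure(out, class = "shared_gene_report")
}

# Region counts for 2- or 3-set Venn diagrams; regions keyed by a
# membership mask like "110" in the order of the input sets.
venn_counts <- function(sets) {
  k <- length(sets)
  if (k > 3L) sets <- sets[1:3]
  k <- length(sets)
  all_genes <- unique(unlist(sets))
  if (!length(all_genes)) {
    masks <- apply(
      expand.grid(rep(list(0:1), k))[-1, , drop = FALSE], 1, paste,
      collapse = ""
    )
    return(stats::setNames(integer(length(masks)), masks))
  }
  member <- vapply(sets, function(s) all_genes %in% s, logical(length(all_genes)))
  member <- matrix(member, ncol = k)
  mask <- apply(member, 1, function(m) paste(as.integer(m), collapse = ""))
  grid <- expand.grid(rep(list(0:1), k))
  masks <- apply(grid[rowSums(grid) > 0, , drop = FALSE], 1, paste,
    collapse = ""
  )
  counts <- stats::setNames(integer(length(masks)), masks)
  tab <- table(mask)
  counts[names(tab)] <- as.integer(tab)
  counts
}

#' Enrichment terms shared across screens, by significance tier
#'
#' Assigns each term appearing in at least one screen's enrichment table
#' to nested tiers: significant (adjusted p <= alpha) in all screens,
#' significant in at least two, or simply present in at least two tables
#' regardless of significance.  A term absent from a screen's table is
#' non-significant there.
#'
#' @param tables Named list of per-screen `enrichment_table`s (all for the
#'   same direction, favorable or unfavorable).
#' @param alpha Significance level on the adjusted p (default 0.05).
#' @return A `shared_term_report` data frame: `term_id`, `term_name`, one
#'   `adjp_<screen>` column per screen, `n_present`, `n_significant`,
#'   `tier` (one of "all_significant", "ge2_significant",
#'   "shared_regardless", or NA for terms in only one table).
#' @export
shared_terms <- function(tables, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop_ps("alpha must be in (0, 1)")
  if (length(tables) < 2L) stop_ps("need at least 2 screens")
  screens <- names(tables)
  ids <- sort(unique(unlist(lapply(tables, `[[`, "term_id"))))
  nm <- character(length(ids))
  out <- data.frame(term_id = ids, stringsAsFactors = FALSE)
  present <- sig <- matrix(FALSE, length(ids), length(screens))
  for (j in seq_along(screens)) {
    tb <- tables[[j]]
    idx <- match(ids, tb$term_id)
    out[[paste0("adjp_", screens[j])]] <- tb$adjusted_p[idx]
    present[, j] <- !is.na(idx)
    sig[, j] <- !is.na(idx) & tb$adjusted_p[idx] <= alpha
    nm[present[, j]] <- tb$term_name[idx[present[, j]]]
  }
  out$term_name <- nm
  out$n_present <- rowSums(present)
  out$n_significant <- rowSums(sig)
  out$tier <- ifelse(
    out$n_significant == length(screens), "all_significant",
    ifelse(out$n_significant >= 2L, "ge2_significant",
      ifelse(out$n_present >= 2L, "shared_regardless", NA_character_)
    )
  )
  cols <- c(
    "term_id", "term_name", paste0("adjp_", screens),
    "n_present", "n_significant", "tier"
  )
  out <- out[, cols]
  class(out) <- c("shared_term_report", "data.frame")
  out
}
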