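#' Published per-screen coefficients for cross-screen consensus genes
#'
#' Ridge-regression coefficients, per screen, for network genes
#' prioritized as favorable or unfavorable across three psychiatric drug
#' screens — an in silico phagocytosis screen (where negative
#' coefficients are favorable), a zebrafish phenoscore screen, and a
#' clinical antidepressant efficacy screen — together with the published
#' consensus average (mean of the absolute per-screen coefficients,
#' rounded to 4 decimals).  Used as a worked example and as the
#' verification input for [aggregate_coefficient()].
#'
#' @return Data frame with columns `gene`, `direction`, `in_silico`,
#'   `zebrafish`, `clinical`, `reported_average`.
#' @export
#' @examples
#' tab <- shared_screen_coefficients()
#' aggregate_coefficient(unlist(tab[tab$gene == "ABCG2", 3:5]))
shared_screen_coefficients <- function() {
  path <- system.file("extdata", "shared_screen_coefficients.tsv",
    package = "pathscreen", mustWork = TRUE
  )
  tab <- utils::read.table(path,
    sep = "\t", header = TRUE, comment.char = "#",
    stringsAsFactors = FALSE
  )
  tab
}
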