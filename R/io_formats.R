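# Readers, writers and name normalization for every external table the
# pipeline touches.  All gene symbols and drug names are uppercased before
# any comparison; files are UTF-8, tab- or comma-separated, and lines
# starting with "#" are ignored.

new_interactome <- function(edges) {
  # edges: data.frame(gene_a, gene_b, evidence_score), already validated
  genes <- sort(unique(c(edges$gene_a, edges$gene_b)))
  idx_a <- match(edges$gene_a, genes)
  idx_b <- match(edges$gene_b, genes)
  n <- length(genes)
  # adjacency lists (integer neighbor index + edge score) for fast score
  # propagation; built once per interactome
  adj_idx <- vector("list", n)
  adj_score <- vector("list", n)
  src <- c(idx_a, idx_b)
  dst <- c(idx_b, idx_a)
  sc <- c(edges$evidence_score, edges$evidence_score)
  o <- order(src)
  src <- src[o]; dst <- dst[o]; sc <- sc[o]
  runs <- split(seq_along(src), src)
  for (k in names(runs)) {
    i <- as.integer(k)
    adj_idx[[i]] <- dst[runs[[k]]]
    adj_score[[i]] <- sc[runs[[k]]]
  }
  structure(
    list(
      genes = genes, edges = edges,
      adj_idx = adj_idx, adj_score = adj_score
    ),
    class = "interactome"
  )
}

validate_interactome_edges <- function(edges, lines = seq_len(nrow(edges))) {
  bad <- which(!is.finite(edges$evidence_score) |
    edges$evidence_score <= 0 | edges$evidence_score > 1)
  if (length(bad)) {
    stop_ps(
      "evidence score outside (0, 1] at line ", lines[bad[1]],
      " (score = ", edges$evidence_score[bad[1]], ")"
    )
  }
  loops <- which(edges$gene_a == edges$gene_b)
  if (length(loops)) {
    stop_ps(
      "self-loop edge ", edges$gene_a[loops[1]], "-",
      edges$gene_b[loops[1]], " at line ", lines[loops[1]]
    )
  }
  edges
}

# Collapse duplicate unordered pairs to the maximum evidence score.
collapse_duplicate_edges <- function(edges) {
  key <- ifelse(edges$gene_a <= edges$gene_b,
    paste(edges$gene_a, edges$gene_b, sep = "\r"),
    paste(edges$gene_b, edges$gene_a, sep = "\r")
  )
  if (!anyDuplicated(key)) return(edges)
  score <- tapply(edges$evidence_score, key, max)
  parts <- strsplit(names(score), "\r", fixed = TRUE)
  data.frame(
    gene_a = vapply(parts, `[`, "", 1L),
    gene_b = vapply(parts, `[`, "", 2L),
    evidence_score = as.numeric(score),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Build an interactome from an edge data frame
#'
#' @param edges Data frame with columns `gene_a`, `gene_b`,
#'   `evidence_score`.  Symbols are uppercased, duplicate unordered pairs
#'   collapse to the maximum score, self-loops and scores outside (0, 1]
#'   are errors.
#' @return An `interactome` object: the undirected evidence-scored
#'   protein-protein interaction graph that underlies all pathway
#'   prediction.
#' @export
as_interactome <- function(edges) {
  edges <- data.frame(
    gene_a = toupper_trim(edges$gene_a),
    gene_b = toupper_trim(edges$gene_b),
    evidence_score = as.numeric(edges$evidence_score),
    stringsAsFactors = FALSE
  )
  validate_interactome_edges(edges)
  new_interactome(collapse_duplicate_edges(edges))
}

#' Read an evidence-scored interactome from a TSV edge list
#'
#' Expects three tab-separated columns: gene A, gene B, evidence score in
#' (0, 1].  Gene symbols are uppercased; duplicate unordered pairs are
#' collapsed to their maximum score (the strongest published evidence
#' wins); self-loops and out-of-range scores abort with the offending line
#' number.
#'
#' @param path Path to the TSV file.
#' @param header Logical; does the file carry a header line?
#' @return An [as_interactome()] object.
#' @export
read_interactome <- function(path, header = FALSE) {
  tab <- read_delim_table(path, sep = "\t", header = header)
  if (ncol(tab) != 3L) {
    stop_ps("interactome TSV must have 3 columns, found ", ncol(tab))
  }
  score <- suppressWarnings(as.numeric(tab[[3L]]))
  if (anyNA(score)) {
    stop_ps(
      "non-numeric evidence score at line ",
      which(is.na(score))[1] + as.integer(header)
    )
  }
  edges <- data.frame(
    gene_a = toupper_trim(tab[[1L]]),
    gene_b = toupper_trim(tab[[2L]]),
    evidence_score = score, stringsAsFactors = FALSE
  )
  validate_interactome_edges(edges,
    lines = seq_len(nrow(edges)) + as.integer(header)
  )
  new_interactome(collapse_duplicate_edges(edges))
}

#' Write an interactome back to its TSV edge-list form
#'
#' @param x An `interactome`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_interactome <- function(x, path) {
  stopifnot(inherits(x, "interactome"))
  utils::write.table(x$edges, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' @export
print.interactome <- function(x, ...) {
  cat(
    "<interactome> ", length(x$genes), " genes, ", nrow(x$edges),
    " evidence-scored edges\n",
    sep = ""
  )
  invisible(x)
}

#' Read a drug-to-target map from a TSV file
#'
#' Expects columns drug_id, drug_name, target gene (one row per
#' drug-target pair).  Target lists are deduplicated and sorted; drug
#' names are uppercased into a lookup vocabulary.  Drug ids must look like
#' DrugBank accessions ("DB" + 5 digits).
#'
#' @param path Path to the TSV file.
#' @param header Logical; does the file carry a header line?
#' @return A `drug_target_map`: list with `targets` (named list,
#'   drug_id -> sorted gene vector) and `vocabulary` (named character,
#'   uppercase drug name -> drug_id).
#' @export
read_drug_targets <- function(path, header = FALSE) {
  tab <- read_delim_table(path, sep = "\t", header = header)
  if (ncol(tab) != 3L) {
    stop_ps("drug-target TSV must have 3 columns, found ", ncol(tab))
  }
  drug_target_map(
    drug_id = trimws(tab[[1L]]),
    drug_name = tab[[2L]],
    gene = tab[[3L]]
  )
}

#' Construct a drug-to-target map from vectors
#'
#' @param drug_id Character vector of DrugBank-style ids ("DB" + 5 digits).
#' @param drug_name Character vector of drug common names.
#' @param gene Character vector of target gene symbols.
#' @return A `drug_target_map` object.
#' @export
drug_target_map <- function(drug_id, drug_name, gene) {
  bad <- which(!is_drugbank_id(drug_id))
  if (length(bad)) {
    stop_ps("malformed drug id \"", drug_id[bad[1]], "\"")
  }
  gene <- toupper_trim(gene)
  all_ids <- unique(drug_id)
  keep <- nzchar(gene)
  if (!all(keep)) {
    drug_id <- drug_id[keep]; drug_name <- drug_name[keep]
    gene <- gene[keep]
  }
  targets <- lapply(split(gene, drug_id), function(g) sort(unique(g)))
  dropped <- setdiff(all_ids, names(targets)[lengths(targets) > 0L])
  if (length(dropped)) {
    warn_ps(
      "dropping ", length(dropped),
      " drug(s) with no targets after filtering: ",
      paste(utils::head(dropped, 5), collapse = ", ")
    )
  }
  targets <- targets[lengths(targets) > 0L]
  name_map <- unique(data.frame(
    name = toupper_trim(drug_name), id = drug_id,
    stringsAsFactors = FALSE
  ))
  name_map <- name_map[name_map$id %in% names(targets), , drop = FALSE]
  dup <- duplicated(name_map$name)
  if (any(dup)) {
    warn_ps(
      "duplicate drug name(s) in vocabulary kept first: ",
      paste(unique(name_map$name[dup]), collapse = ", ")
    )
    name_map <- name_map[!dup, , drop = FALSE]
  }
  vocabulary <- stats::setNames(name_map$id, name_map$name)
  structure(list(targets = targets, vocabulary = vocabulary),
    class = "drug_target_map"
  )
}

#' @export
print.drug_target_map <- function(x, ...) {
  cat(
    "<drug_target_map> ", length(x$targets), " drugs, ",
    length(unique(unlist(x$targets))), " distinct target genes\n",
    sep = ""
  )
  invisible(x)
}

default_psychiatric_labels <- function() {
  c(
    "schizophrenia", "paranoid schizophrenia", "bipolar disorder",
    "unipolar depression", "major depressive disorder"
  )
}

new_gene_sets <- function(sets, names, class, psychiatric_labels = NULL) {
  obj <- list(sets = sets, term_names = names)
  if (identical(class, "phenotype_catalog")) {
    obj$psychiatric_labels <- psychiatric_labels %||%
      default_psychiatric_labels()
  }
  structure(obj, class = class)
}

#' Read gene sets from a GMT file or a two-column label/gene TSV
#'
#' GMT lines are `term_id<TAB>description<TAB>gene...`; the TSV form is
#' `label<TAB>gene`, one row per pair (used for phenotype-to-gene
#' annotation catalogs).  Genes are uppercased; terms with zero genes are
#' dropped with a warning; duplicated term ids are an error.
#'
#' @param path Path to the file.
#' @param format `"gmt"` or `"tsv"`.
#' @param psychiatric_labels For `format = "tsv"`, the configured subset of
#'   labels treated as the tracked psychiatric conditions (defaults to the
#'   five conditions the pathway tool tracks: schizophrenia, paranoid
#'   schizophrenia, bipolar disorder, unipolar depression, major
#'   depressive disorder).
#' @return A `gene_set_collection` (GMT) or `phenotype_catalog` (TSV).
#' @export
read_gene_sets <- function(path, format = c("gmt", "tsv"),
                           psychiatric_labels = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_ps("file not found: ", path)
  if (format == "gmt") {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    ids <- vapply(parts, `[`, "", 1L)
    if (anyDuplicated(ids)) {
      stop_ps(
        "duplicate term id in GMT: ",
        ids[duplicated(ids)][1]
      )
    }
    descs <- vapply(parts, function(p) if (length(p) >= 2) p[2] else "", "")
    sets <- lapply(parts, function(p) {
      g <- toupper_trim(p[-(1:2)])
      sort(unique(g[nzchar(g)]))
    })
    names(sets) <- ids
    empty <- lengths(sets) == 0L
    if (any(empty)) {
      warn_ps(
        "dropping ", sum(empty), " GMT term(s) with zero genes: ",
        paste(ids[empty], collapse = ", ")
      )
    }
    new_gene_sets(sets[!empty], stats::setNames(descs, ids)[!empty],
      class = "gene_set_collection"
    )
  } else {
    tab <- read_delim_table(path, sep = "\t", header = FALSE)
    if (ncol(tab) != 2L) {
      stop_ps("phenotype TSV must have 2 columns, found ", ncol(tab))
    }
    phenotype_catalog(
      label = tab[[1L]], gene = tab[[2L]],
      psychiatric_labels = psychiatric_labels
    )
  }
}

#' Construct a phenotype-to-gene annotation catalog
#'
#' @param label Character vector of phenotype labels.
#' @param gene Character vector of annotated gene symbols (uppercased).
#' @param psychiatric_labels Optional label subset marking the tracked
#'   psychiatric conditions; defaults to the five tracked conditions.
#' @return A `phenotype_catalog` object.
#' @export
phenotype_catalog <- function(label, gene, psychiatric_labels = NULL) {
  label <- trimws(as.character(label))
  gene <- toupper_trim(gene)
  keep <- nzchar(gene) & nzchar(label)
  sets <- lapply(split(gene[keep], label[keep]), function(g) {
    sort(unique(g))
  })
  empty <- lengths(sets) == 0L
  if (any(empty)) {
    warn_ps("dropping ", sum(empty), " empty phenotype label(s)")
    sets <- sets[!empty]
  }
  new_gene_sets(sets, stats::setNames(names(sets), names(sets)),
    class = "phenotype_catalog", psychiatric_labels = psychiatric_labels
  )
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("<gene_set_collection> ", length(x$sets), " terms\n", sep = "")
  invisible(x)
}

#' @export
print.phenotype_catalog <- function(x, ...) {
  cat(
    "<phenotype_catalog> ", length(x$sets), " phenotypes (",
    sum(names(x$sets) %in% x$psychiatric_labels),
    " tracked psychiatric)\n",
    sep = ""
  )
  invisible(x)
}

#' Read a screen outcome table from CSV
#'
#' Expects a header `drug,outcome` (any column names accepted; the first
#' column is the drug identifier, the second the outcome).  Rows sharing a
#' drug identifier are collapsed to one row; under the default `max`
#' policy the largest outcome is retained (for drugs tested several times
#' the maximum reported score is kept).
#'
#' @param path Path to the CSV file.
#' @param outcome_type `"binary"` (values must be 0/1) or `"continuous"`
#'   (values must be finite).
#' @param favorable_sign +1 or -1: the sign of a regression coefficient
#'   deemed favorable for this screen (negative only for screens where a
#'   decrease in the measured outcome is the desired drug effect).
#' @param screen_name Label carried through downstream tables; defaults to
#'   the file name.
#' @param duplicate_policy `"max"` (default), `"min"`, or `"mean"`.
#' @return A `screen_table`: data frame with columns `drug_id`, `outcome`
#'   plus attributes `screen_name`, `outcome_type`, `favorable_sign`.
#' @export
read_screen_table <- function(path, outcome_type = c("continuous", "binary"),
                              favorable_sign = 1L,
                              screen_name = NULL,
                              duplicate_policy = c("max", "min", "mean")) {
  outcome_type <- match.arg(outcome_type)
  duplicate_policy <- match.arg(duplicate_policy)
  tab <- read_delim_table(path, sep = ",", header = TRUE)
  if (ncol(tab) < 2L) {
    stop_ps("screen CSV must have >= 2 columns (drug, outcome)")
  }
  screen_table(
    drug_id = tab[[1L]],
    outcome = tab[[2L]],
    outcome_type = outcome_type,
    favorable_sign = favorable_sign,
    screen_name = screen_name %||% sub("\\.[^.]*$", "", basename(path)),
    duplicate_policy = duplicate_policy
  )
}

#' Construct a screen outcome table
#'
#' @param drug_id Character vector of drug identifiers.
#' @param outcome Outcome values (numeric, or coercible).
#' @inheritParams read_screen_table
#' @return A `screen_table` data frame, one row per drug.
#' @export
screen_table <- function(drug_id, outcome,
                         outcome_type = c("continuous", "binary"),
                         favorable_sign = 1L, screen_name = "screen",
                         duplicate_policy = c("max", "min", "mean")) {
  outcome_type <- match.arg(outcome_type)
  duplicate_policy <- match.arg(duplicate_policy)
  if (!favorable_sign %in% c(-1L, 1L)) {
    stop_ps("favorable_sign must be +1 or -1")
  }
  drug_id <- trimws(as.character(drug_id))
  val <- suppressWarnings(as.numeric(outcome))
  if (anyNA(val)) {
    stop_ps("non-numeric outcome at row ", which(is.na(val))[1])
  }
  if (outcome_type == "binary" && !all(val %in% c(0, 1))) {
    stop_ps(
      "binary screen outcome outside {0, 1} at row ",
      which(!val %in% c(0, 1))[1]
    )
  }
  if (outcome_type == "continuous" && !all(is.finite(val))) {
    stop_ps("non-finite continuous outcome")
  }
  agg <- switch(duplicate_policy, max = max, min = min, mean = mean)
  collapsed <- tapply(val, drug_id, agg)
  out <- data.frame(
    drug_id = names(collapsed),
    outcome = as.numeric(collapsed),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out <- out[order(out$drug_id), , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
    screen_name = screen_name, outcome_type = outcome_type,
    favorable_sign = as.integer(favorable_sign),
    class = c("screen_table", "data.frame")
  )
}

#' Write a screen table back to CSV
#'
#' @param x A `screen_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_screen_table <- function(x, path) {
  stopifnot(inherits(x, "screen_table"))
  utils::write.table(
    data.frame(drug = x$drug_id, outcome = x$outcome),
    path,
    sep = ",", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Normalize drug names against the drug-target vocabulary
#'
#' Exact, case-insensitive lookup of common names; salt/formulation
#' variants absent from the vocabulary deliberately return no-match (NA)
#' rather than fuzzy-matching.  The per-file match rate is attached as an
#' attribute and reported via `message()`.
#'
#' @param raw_name Character vector of raw drug names.
#' @param vocabulary A `drug_target_map` (its `vocabulary` is used) or a
#'   named character vector mapping uppercase names to drug ids.
#' @param quiet Suppress the match-rate message.
#' @return Character vector of drug ids with NA for no-match, attribute
#'   `match_rate` = matched rows / total rows.
#' @export
normalize_drug_name <- function(raw_name, vocabulary, quiet = FALSE) {
  vocab <- if (inherits(vocabulary, "drug_target_map")) {
    vocabulary$vocabulary
  } else {
    vocabulary
  }
  key <- toupper_trim(raw_name)
  id <- unname(vocab[key])
  id[!nzchar(key)] <- NA_character_
  rate <- if (length(id)) mean(!is.na(id)) else NA_real_
  if (!quiet && length(id)) {
    message(
      "matched ", sum(!is.na(id)), "/", length(id),
      " drug names (", round(100 * rate, 1), "%)"
    )
  }
  structure(id, match_rate = rate)
}
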