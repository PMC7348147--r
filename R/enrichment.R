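#' Gene set collection
#'
#' @param sets named list of character vectors (gene sets); names unique.
#' @param universe character vector of background gene symbols; sets are
#'   restricted to it.
#' @param descriptions optional named character vector of set descriptions.
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, universe, descriptions = NULL) {
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("gene sets must have unique ids")
  universe <- unique(universe)
  sets <- lapply(sets, function(s) intersect(unique(s), universe))
  structure(list(sets = sets, universe = universe,
                 descriptions = descriptions),
            class = "gene_set_collection")
}

#' Read a GMT file
#'
#' One set per line: id, description, then member genes, tab-separated.
#'
#' @param path GMT file path.
#' @return list with `sets` (named list) and `descriptions`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[[`, "", 1)
  desc <- vapply(parts, function(p) if (length(p) >= 2) p[[2]] else "", "")
  sets <- lapply(parts, function(p) unique(p[-(1:2)][nzchar(p[-(1:2)])]))
  names(sets) <- ids
  list(sets = sets, descriptions = stats::setNames(desc, ids))
}

#' Write a GMT file
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional named descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  lines <- vapply(names(sets), function(id) {
    d <- if (!is.null(descriptions) && id %in% names(descriptions))
      descriptions[[id]] else "na"
    paste(c(id, d, sets[[id]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

## One-sided (over-representation) hypergeometric tail:
## p = P(X >= k) with X ~ Hypergeom(N, K, n). Identical to the one-sided
## Fisher exact test on the 2x2 table.
hyper_test <- function(k, K, n, N) {
  stopifnot(k <= min(K, n), K <= N, n <= N)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Gene set over-representation analysis
#'
#' For each set, a one-sided hypergeometric test of the overlap between
#' the query and the set against the collection universe. The universe is
#' the single largest silent driver of enrichment p-values; it is explicit
#' here and the query must be contained in it.
#'
#' @param query character vector of genes (must be within the universe).
#' @param collection a [gene_set_collection()].
#' @param correction `"bh"` (default) or `"bonferroni"`.
#' @return data.frame sorted by p: feature_id, k, K, n, N, odds_ratio,
#'   p_value, p_adjusted.
#' @export
gene_set_enrichment <- function(query, collection, correction = c("bh", "bonferroni")) {
  correction <- match.arg(correction)
  stopifnot(inherits(collection, "gene_set_collection"))
  query <- unique(query)
  offenders <- setdiff(query, collection$universe)
  if (length(offenders))
    stop("query genes outside the universe: ",
         paste(utils::head(offenders, 10), collapse = ", "))
  N <- length(collection$universe)
  n <- length(query)
  rows <- lapply(names(collection$sets), function(id) {
    set <- collection$sets[[id]]
    K <- length(set)
    k <- length(intersect(query, set))
    or <- (k * (N - K - n + k)) / max((K - k) * (n - k), .Machine$double.eps)
    data.frame(feature_id = id, k = k, K = K, n = n, N = N,
               odds_ratio = or, p_value = hyper_test(k, K, n, N),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$p_adjusted <- if (correction == "bh") bh_adjust(res$p_value)
                    else pmin(1, res$p_value * nrow(res))
  res[order(res$p_value), ]
}

#' Drug feature over-representation (classes, side effects, interactions)
#'
#' For each feature label, a one-sided Fisher exact test of the 2x2 table
#' hit-vs-non-hit x has-label-vs-not, BH-adjusted across labels by
#' default. `feature_kind = "interaction"` treats the boolean
#' interacts-with-query-drug flag as the single feature.
#'
#' @param hit_drugs character vector, the drugs retained by the screen.
#' @param all_drugs character vector, the background drug universe
#'   (`hit_drugs` must be a subset).
#' @param annotations data.frame with columns `drug`, and `class`,
#'   `side_effect` (possibly several rows per drug) and/or logical
#'   `ddi_flag`.
#' @param feature_kind `"class"`, `"side_effect"` or `"interaction"`.
#' @param correction `"bh"` (default) or `"bonferroni"`.
#' @return data.frame as [gene_set_enrichment()], one row per label.
#' @export
drug_feature_enrichment <- function(hit_drugs, all_drugs, annotations,
                                    feature_kind = c("class", "side_effect", "interaction"),
                                    correction = c("bh", "bonferroni")) {
  feature_kind <- match.arg(feature_kind)
  correction <- match.arg(correction)
  hit_drugs <- unique(hit_drugs)
  all_drugs <- unique(all_drugs)
  if (!length(hit_drugs)) stop("empty hit drug set")
  if (!all(hit_drugs %in% all_drugs)) stop("hit_drugs must be a subset of all_drugs")
  ann <- annotations[annotations$drug %in% all_drugs, , drop = FALSE]
  label_sets <- switch(feature_kind,
    class = split(ann$drug, ann$class),
    side_effect = split(ann$drug, ann$side_effect),
    interaction = list(interacts_with_query_drug =
                         unique(ann$drug[as.logical(ann$ddi_flag)])))
  label_sets <- lapply(label_sets, unique)
  label_sets <- label_sets[vapply(label_sets, length, 0L) > 0]
  if (!length(label_sets)) stop("no feature labels of kind '", feature_kind, "'")
  N <- length(all_drugs); n <- length(hit_drugs)
  rows <- lapply(names(label_sets), function(lab) {
    K <- length(label_sets[[lab]])
    k <- length(intersect(hit_drugs, label_sets[[lab]]))
    or <- (k * (N - K - n + k)) / max((K - k) * (n - k), .Machine$double.eps)
    data.frame(feature_id = lab, k = k, K = K, n = n, N = N,
               odds_ratio = or, p_value = hyper_test(k, K, n, N),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$p_adjusted <- if (correction == "bh") bh_adjust(res$p_value)
                    else pmin(1, res$p_value * nrow(res))
  res[order(res$p_value), ]
}

#' Map mouse genes to human orthologs
#'
#' One-to-many mappings are expanded, many-to-one deduplicated; genes
#' without a mapping are returned in the unmapped report, never silently
#' dropped.
#'
#' @param mouse_genes character vector of mouse gene symbols.
#' @param table data.frame with columns `mouse` and `human`.
#' @return list with `human` (unique mapped symbols) and `unmapped`.
#' @export
map_orthologs <- function(mouse_genes, table) {
  if (!nrow(table)) stop("empty ortholog table")
  if (!all(c("mouse", "human") %in% names(table)))
    stop("ortholog table needs columns 'mouse' and 'human'")
  mouse_genes <- unique(mouse_genes)
  hits <- table[table$mouse %in% mouse_genes, , drop = FALSE]
  list(human = unique(hits$human),
       unmapped = setdiff(mouse_genes, hits$mouse))
}
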