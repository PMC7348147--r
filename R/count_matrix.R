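#' Gene-by-sample count container
#'
#' Lightweight list-based container (in the style of `edgeR::DGEList`)
#' holding an integer count matrix together with per-sample annotations and
#' optional gene lengths (required only for FPKM normalization).
#'
#' @param counts integer matrix, genes in rows (rownames required), samples
#'   in columns (colnames required).
#' @param samples data.frame with one row per sample and columns
#'   `sample`, `tissue`, `group` (`"treated"` or `"control"`) and
#'   `replicate`.
#' @param gene_lengths optional named numeric vector of gene lengths in
#'   bases; names must cover the rownames of `counts`.
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, samples, gene_lengths = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene rownames and sample colnames")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  need <- c("sample", "tissue", "group", "replicate")
  miss <- setdiff(need, names(samples))
  if (length(miss)) stop("samples annotation missing columns: ", paste(miss, collapse = ", "))
  if (!setequal(samples$sample, colnames(counts)) || anyDuplicated(samples$sample))
    stop("every sample column must be annotated exactly once")
  samples <- samples[match(colnames(counts), samples$sample), , drop = FALSE]
  rownames(samples) <- samples$sample
  if (!all(samples$group %in% c("treated", "control")))
    stop("group must be 'treated' or 'control'")
  if (!is.null(gene_lengths)) {
    miss <- setdiff(rownames(counts), names(gene_lengths))
    if (length(miss))
      stop("gene_lengths missing for genes: ", paste(utils::head(miss, 5), collapse = ", "))
    gene_lengths <- gene_lengths[rownames(counts)]
    if (any(!is.finite(gene_lengths)) || any(gene_lengths <= 0))
      stop("gene_lengths must be positive")
  }
  structure(list(counts = counts, samples = samples, gene_lengths = gene_lengths),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples; %d tissue(s)\n",
              nrow(x$counts), ncol(x$counts), length(unique(x$samples$tissue))))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Subset a count matrix by samples
#' @param cm a [count_matrix()].
#' @param samples character vector of sample ids or logical/integer index.
#' @return a `count_matrix` restricted to those samples.
#' @export
subset_samples <- function(cm, samples) {
  if (is.character(samples)) samples <- match(samples, colnames(cm$counts))
  count_matrix(cm$counts[, samples, drop = FALSE],
               cm$samples[samples, , drop = FALSE],
               cm$gene_lengths)
}

#' Log2 fold-change signature container
#'
#' A signature is the per-gene array of log2 fold changes characterizing one
#' perturbation relative to its control, plus bookkeeping: tissue of origin,
#' free-text topic label, beneficial/deleterious polarity tag and the
#' platform the values were derived from.
#'
#' @param id signature identifier.
#' @param values named numeric vector, gene -> log2 fold change; names
#'   unique, values finite.
#' @param tissue tissue identifier (may be `NA`).
#' @param topic free-text topic label.
#' @param polarity one of `"beneficial"`, `"deleterious"`, `"neutral"`.
#' @param platform one of `"two_colour_paired"`, `"two_colour_reference"`,
#'   `"one_colour"`, `"rnaseq"`.
#' @return An object of class `signature_fc`.
#' @export
signature_fc <- function(id, values, tissue = NA_character_, topic = "",
                         polarity = c("neutral", "beneficial", "deleterious"),
                         platform = c("rnaseq", "one_colour",
                                      "two_colour_paired", "two_colour_reference")) {
  polarity <- match.arg(polarity)
  platform <- match.arg(platform)
  if (is.null(names(values)) || anyDuplicated(names(values)))
    stop("signature values need unique gene names")
  if (any(!is.finite(values))) stop("signature values must be finite")
  structure(list(id = id, tissue = tissue, topic = topic, polarity = polarity,
                 platform = platform, values = values),
            class = "signature_fc")
}

#' @export
print.signature_fc <- function(x, ...) {
  cat(sprintf("signature_fc '%s' [%s/%s, %s]: %d genes\n",
              x$id, x$tissue, x$topic, x$platform, length(x$values)))
  invisible(x)
}
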