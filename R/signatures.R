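#' Build a log2 fold-change signature from an expression table
#'
#' Platform-aware fold-change deduction:
#' * `two_colour_paired`: per-gene mean of the per-pair log2 case/control
#'   signal ratios (ratios are taken per matched column pair).
#' * `one_colour`, `two_colour_reference`: mean(log2 case) - mean(log2
#'   control); a universal-reference two-colour design is treated exactly
#'   as a one-colour array.
#' * `rnaseq`: same, with a +1 pseudocount before the log2 transform.
#'
#' Values are log2-transformed before fold-change calculation unless
#' `log2_transformed = TRUE` declares them already on the log2 scale.
#'
#' @param expr numeric matrix, genes x samples.
#' @param design platform type (see above).
#' @param case_ids,control_ids column ids; for the paired design the two
#'   vectors must have equal length and are matched positionally.
#' @param log2_transformed are the values already log2?
#' @param id,tissue,topic,polarity passed to [signature_fc()].
#' @return a [signature_fc()].
#' @export
build_signature <- function(expr, design = c("rnaseq", "one_colour",
                                             "two_colour_reference",
                                             "two_colour_paired"),
                            case_ids, control_ids, log2_transformed = FALSE,
                            id = "query", tissue = NA_character_, topic = "",
                            polarity = "neutral") {
  design <- match.arg(design)
  expr <- as.matrix(expr)
  stopifnot(length(case_ids) >= 1, length(control_ids) >= 1)
  if (design == "two_colour_paired" && length(case_ids) != length(control_ids))
    stop("paired design requires equal numbers of case and control columns")
  tf <- function(x, pseudo = 0) {
    if (log2_transformed) return(x)
    x <- x + pseudo
    bad <- which(x <= 0, arr.ind = TRUE)
    if (length(bad)) {
      g <- unique(rownames(expr)[bad[, 1]])
      stop("non-positive intensity requires log2 transform; offending gene(s): ",
           paste(utils::head(g, 5), collapse = ", "))
    }
    log2(x)
  }
  cs <- expr[, case_ids, drop = FALSE]
  ct <- expr[, control_ids, drop = FALSE]
  if (design == "two_colour_paired") {
    lfc <- rowMeans(tf(cs) - tf(ct))
  } else {
    pseudo <- if (design == "rnaseq") 1 else 0
    lfc <- rowMeans(tf(cs, pseudo)) - rowMeans(tf(ct, pseudo))
  }
  signature_fc(id, stats::setNames(unname(lfc), rownames(expr)),
               tissue = tissue, topic = topic, polarity = polarity,
               platform = design)
}

#' Treatment signature from a count matrix tissue
#'
#' Convenience wrapper: mean(log2(count+1)) of size-factor-normalized
#' counts, treated minus control, for one tissue.
#'
#' @param cm a [count_matrix()].
#' @param tissue tissue identifier.
#' @param id signature id (default `"<tissue>_treatment"`).
#' @return a [signature_fc()] with platform `"rnaseq"`.
#' @export
build_signature_from_counts <- function(cm, tissue,
                                        id = paste0(tissue, "_treatment")) {
  sel <- cm$samples$tissue == tissue
  if (!any(sel)) stop("unknown tissue: ", tissue)
  y <- cm$counts[, sel, drop = FALSE]
  sf <- size_factors(y)
  z <- sweep(y, 2, sf, "/")
  grp <- cm$samples$group[sel]
  build_signature(z, "rnaseq",
                  case_ids = which(grp == "treated"),
                  control_ids = which(grp == "control"),
                  id = id, tissue = tissue, topic = "treatment")
}

## Spearman correlation with a deterministic p-value policy: exact
## permutation p below 10 shared genes (full enumeration), large-sample t
## approximation otherwise. Average ranks for ties.
spearman_test <- function(x, y) {
  n <- length(x)
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    return(list(rho = NA_real_, p = NA_real_))
  rho <- stats::cor(rx, ry)
  if (n < 10) {
    perms <- permutations_of(n)
    rxs <- (rx - mean(rx)) / sqrt(sum((rx - mean(rx))^2))
    rys <- (ry - mean(ry)) / sqrt(sum((ry - mean(ry))^2))
    stat <- as.vector(matrix(rys[perms], nrow(perms), n) %*% rxs)
    p <- mean(abs(stat) >= abs(rho) - 1e-12)
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, 1e-12))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
  }
  list(rho = rho, p = min(1, p))
}

## all permutations of 1..n as an (n!)-row matrix; n <= 9 by construction
permutations_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  for (pos in seq_len(n)) {
    block <- (pos - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[block, pos] <- n
    out[block, -pos] <- sub
  }
  out
}

correlate_one <- function(query, ref) {
  shared <- intersect(names(query$values), names(ref$values))
  if (length(shared) < 3)
    return(data.frame(query_id = query$id, reference_id = ref$id,
                      scc = NA_real_, n_shared = length(shared),
                      p_value = NA_real_, testable = FALSE,
                      stringsAsFactors = FALSE))
  st <- spearman_test(query$values[shared], ref$values[shared])
  data.frame(query_id = query$id, reference_id = ref$id, scc = st$rho,
             n_shared = length(shared), p_value = st$p,
             testable = is.finite(st$rho), stringsAsFactors = FALSE)
}

#' Correlate a query signature against a reference compendium
#'
#' Spearman correlation on the genes shared between query and each
#' reference (references sharing fewer than 3 genes are reported as
#' untestable and excluded from the correction count). P-values are
#' Bonferroni-corrected over the testable references; BH-adjusted values
#' are emitted alongside since empirical compendia report both.
#'
#' @param query a [signature_fc()].
#' @param refs list of [signature_fc()].
#' @param alpha significance level applied to the adjusted p.
#' @param correction `"bonferroni"` (default) or `"bh"`: which adjusted
#'   column drives the `significant` flag.
#' @return data.frame with columns query_id, reference_id, topic, polarity,
#'   scc, n_shared, p_value, p_bonferroni, p_bh, significant, testable.
#' @export
correlate_signatures <- function(query, refs, alpha = 0.05,
                                 correction = c("bonferroni", "bh")) {
  correction <- match.arg(correction)
  stopifnot(length(refs) >= 1)
  res <- do.call(rbind, lapply(refs, function(r) correlate_one(query, r)))
  res$topic <- vapply(refs, function(r) r$topic, "")
  res$polarity <- vapply(refs, function(r) r$polarity, "")
  n_test <- sum(res$testable)
  res$p_bonferroni <- ifelse(res$testable, pmin(1, res$p_value * n_test), NA)
  res$p_bh <- NA_real_
  res$p_bh[res$testable] <- bh_adjust(res$p_value[res$testable])
  padj <- if (correction == "bonferroni") res$p_bonferroni else res$p_bh
  res$significant <- res$testable & !is.na(padj) & padj < alpha
  res[order(res$p_value), ]
}

#' Correlate against drug signatures, restricted to matching tissue
#'
#' Identical contract to [correlate_signatures()] but only tissue-matched
#' pairs are tested and the multiple-testing correction counts only those
#' tests.
#'
#' @param query a [signature_fc()] with a tissue label.
#' @param drug_sigs list of [signature_fc()] with tissue labels.
#' @inheritParams correlate_signatures
#' @return as [correlate_signatures()]; zero-row data.frame (with a
#'   warning) when no reference matches the query tissue.
#' @export
correlate_with_drug_signatures <- function(query, drug_sigs, alpha = 0.05,
                                           correction = c("bonferroni", "bh")) {
  correction <- match.arg(correction)
  matched <- Filter(function(s) identical(s$tissue, query$tissue), drug_sigs)
  if (!length(matched)) {
    warning("no drug signature matches tissue '", query$tissue, "'")
    return(data.frame(query_id = character(0), reference_id = character(0),
                      topic = character(0), polarity = character(0),
                      scc = numeric(0), n_shared = integer(0),
                      p_value = numeric(0), p_bonferroni = numeric(0),
                      p_bh = numeric(0), significant = logical(0),
                      testable = logical(0)))
  }
  correlate_signatures(query, matched, alpha = alpha, correction = correction)
}

#' Remove redundant reference signatures
#'
#' Within each topic, signatures whose pairwise SCC exceeds `scc_cutoff`
#' are linked; one representative per connected component is kept (the
#' signature with the most genes, ties broken by lexicographic id).
#' Cross-topic pairs are never pruned. Pairs sharing fewer than 3 genes
#' are not comparable and never linked.
#'
#' @param refs list of [signature_fc()].
#' @param scc_cutoff redundancy threshold on SCC (strictly greater links).
#' @return the surviving subset of `refs`, input order preserved.
#' @export
prune_redundant <- function(refs, scc_cutoff = 0.5) {
  if (length(refs) < 2) return(refs)
  ids <- vapply(refs, function(s) s$id, "")
  topics <- vapply(refs, function(s) s$topic, "")
  sizes <- vapply(refs, function(s) length(s$values), 0L)
  keep <- rep(TRUE, length(refs))
  for (tp in unique(topics)) {
    idx <- which(topics == tp)
    if (length(idx) < 2) next
    g <- igraph::make_empty_graph(length(idx), directed = FALSE)
    for (a in seq_along(idx)) for (b in seq_len(a - 1L)) {
      shared <- intersect(names(refs[[idx[a]]]$values), names(refs[[idx[b]]]$values))
      if (length(shared) < 3) next
      scc <- stats::cor(refs[[idx[a]]]$values[shared],
                        refs[[idx[b]]]$values[shared], method = "spearman")
      if (is.finite(scc) && scc > scc_cutoff)
        g <- igraph::add_edges(g, c(a, b))
    }
    comp <- igraph::components(g)$membership
    for (cmp in unique(comp)) {
      members <- idx[comp == cmp]
      if (length(members) < 2) next
      ord <- order(-sizes[members], ids[members])
      keep[members[-ord[1]]] <- FALSE
    }
  }
  refs[keep]
}

#' Polarity-aware summary of signature correlations
#'
#' Counts significant positive/negative correlations split by the
#' reference polarity tag (the content of a circular correlation plot).
#'
#' @param corr result of [correlate_signatures()].
#' @return nested list of counts by polarity and correlation sign.
#' @export
polarity_summary <- function(corr) {
  sig <- corr[corr$significant %in% TRUE, , drop = FALSE]
  out <- list()
  for (pol in unique(sig$polarity)) {
    s <- sig[sig$polarity == pol, , drop = FALSE]
    out[[pol]] <- list(positive = sum(s$scc > 0), negative = sum(s$scc < 0))
  }
  out
}
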