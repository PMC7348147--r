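#' FPKM normalization
#'
#' `FPKM(g,s) = counts(g,s) * 1e9 / (total_counts(s) * length(g))`:
#' fragments per kilobase of transcript per million mapped fragments.
#'
#' @param cm a [count_matrix()] with `gene_lengths` set.
#' @return numeric matrix of FPKM values with the same dimnames.
#' @export
fpkm_normalize <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  if (is.null(cm$gene_lengths)) {
    stop("gene lengths required for FPKM; missing for all genes")
  }
  totals <- colSums(cm$counts)
  if (any(totals <= 0))
    stop("zero-depth sample(s): ", paste(colnames(cm$counts)[totals <= 0], collapse = ", "))
  fpkm <- sweep(cm$counts, 1, as.numeric(cm$gene_lengths), "/")
  fpkm <- sweep(fpkm, 2, totals, "/") * 1e9
  fpkm
}

## DESeq-style median-of-ratios size factors; falls back to library-size
## ratios when no gene is expressed everywhere. Normalized to geometric
## mean 1 so normalized counts stay on the count scale.
size_factors <- function(counts) {
  loggeo <- rowMeans(log(counts))
  use <- is.finite(loggeo)
  if (any(use)) {
    sf <- apply(counts[use, , drop = FALSE], 2, function(cnt)
      stats::median(exp(log(cnt) - loggeo[use])))
  } else {
    sf <- colSums(counts)
  }
  if (any(!is.finite(sf)) || any(sf <= 0)) sf <- colSums(counts)
  sf / exp(mean(log(sf)))
}

## Common NB dispersion by Cox-Reid adjusted profile likelihood: the group
## means are profiled out (q = sum y / sum s, the MLE for equal size
## factors) and the likelihood is penalized by half the log Fisher
## information of the profiled means, which removes the downward bias of
## plain profile ML at 2-3 replicates per group.
common_dispersion_apl <- function(y, sf, grp) {
  lv <- unique(grp)
  apl <- function(phi) {
    size <- 1 / phi
    total <- 0
    for (g in lv) {
      j <- grp == g
      q <- rowSums(y[, j, drop = FALSE]) / sum(sf[j])
      keep <- q > 0
      if (!any(keep)) next
      mu <- outer(q[keep], sf[j])
      ll <- stats::dnbinom(y[keep, j, drop = FALSE], mu = mu, size = size, log = TRUE)
      info <- sweep(1 / (mu * (1 + phi * mu)), 2, sf[j]^2, "*")
      total <- total + sum(ll) - 0.5 * sum(log(rowSums(info)))
    }
    total
  }
  opt <- stats::optimize(function(lp) apl(exp(lp)), c(log(1e-6), log(4)),
                         maximum = TRUE, tol = 1e-4)
  exp(opt$maximum)
}

## Tagwise dispersion: per-gene method of moments
## (Var(y/s) within a group = q/s + phi q^2) shrunk toward the CR-APL
## common value with `prior_df` pseudo-degrees of freedom.
estimate_dispersion <- function(y, sf, grp, prior_df = 20) {
  lv <- unique(grp)
  z <- sweep(y, 2, sf, "/")
  num <- den <- matrix(0, nrow(y), 2)
  df_tot <- 0
  for (k in 1:2) {
    j <- grp == lv[k]
    nk <- sum(j)
    qk <- rowSums(y[, j, drop = FALSE]) / sum(sf[j])
    mk <- rowMeans(z[, j, drop = FALSE])
    vk <- rowSums((z[, j, drop = FALSE] - mk)^2) / (nk - 1)
    num[, k] <- (nk - 1) * (vk - qk * mean(1 / sf[j]))
    den[, k] <- (nk - 1) * qk^2
    df_tot <- df_tot + (nk - 1)
  }
  phi_raw <- rowSums(num) / pmax(rowSums(den), 1e-12)
  common <- max(common_dispersion_apl(y, sf, grp), 1e-6)
  ## shrink the (roughly unbiased, possibly negative) raw moment estimate
  ## toward the common value; clamp only the final estimate
  phi_raw[!is.finite(phi_raw)] <- common
  phi_tag <- (df_tot * phi_raw + prior_df * common) / (df_tot + prior_df)
  list(common = common, tagwise = pmax(phi_tag, 1e-8))
}

## Two-sided "double tail" exact NB test on group sums, conditioning on the
## total. Group sums are moment-matched to NB: mean q0*S_g, dispersion
## phi * sum(s_i^2)/S_g^2. Enumeration is windowed around the conditional
## mode for large totals; the window always contains the observed value.
## `midp` subtracts half the observed outcome's point probability (mid-p),
## removing the conservativeness that test discreteness causes at low
## counts; set FALSE for the classical double tail.
exact_nb_test <- function(sA, sB, SA, SB, sumA2, sumB2, phi, midp = TRUE) {
  t <- sA + sB
  if (t == 0) return(1)
  q0 <- t / (SA + SB)
  muA <- q0 * SA; muB <- q0 * SB
  sizeA <- 1 / max(phi * sumA2 / SA^2, 1e-12)
  sizeB <- 1 / max(phi * sumB2 / SB^2, 1e-12)
  m <- t * muA / (muA + muB)
  vA <- muA + muA^2 / sizeA; vB <- muB + muB^2 / sizeB
  sdc <- sqrt(vA * vB / (vA + vB))
  lo <- max(0, floor(min(m, sA) - 16 * sdc - 5))
  hi <- min(t, ceiling(max(m, sA) + 16 * sdc + 5))
  k <- lo:hi
  lp <- stats::dnbinom(k, mu = muA, size = sizeA, log = TRUE) +
    stats::dnbinom(t - k, mu = muB, size = sizeB, log = TRUE)
  lp <- lp - max(lp)
  pr <- exp(lp)
  pr <- pr / sum(pr)
  po <- pr[match(sA, k)]
  p <- sum(pr[pr <= po * (1 + 1e-10)])
  if (midp) p <- p - 0.5 * po
  min(1, max(p, .Machine$double.xmin))
}

#' Per-tissue differential expression by a negative-binomial exact test
#'
#' Treated-vs-control test within one tissue: library sizes are normalized
#' by median-of-ratios size factors, tagwise dispersions are estimated by
#' method of moments and shrunk toward the common dispersion
#' (`prior_df` pseudo-degrees of freedom), and each gene receives a
#' two-sided p-value from an exact conditional NB test on the group sums.
#' log2 fold changes use a 0.5 pseudocount on the normalized group means.
#' All-zero genes get `p = 1`, `log2fc = 0`.
#'
#' @param cm a [count_matrix()].
#' @param tissue tissue identifier present in the annotations.
#' @param alpha significance threshold for the up/down call (raw p; the
#'   relaxed hypothesis-generation default is 0.05).
#' @param prior_df shrinkage weight toward the common dispersion.
#' @param fdr if `TRUE`, call direction on BH-adjusted p instead of raw p.
#' @param midp if `TRUE` (default) use the mid-p variant of the double
#'   tail, which corrects the conservativeness of discrete exact tests at
#'   low counts; `FALSE` gives the classical double tail.
#' @return a `deg_table`: data.frame with columns `gene`, `log2fc`,
#'   `p_value`, `direction` (up/down/ns); attributes `tissue` and `alpha`.
#' @export
detect_degs <- function(cm, tissue, alpha = 0.05, prior_df = 20, fdr = FALSE,
                        midp = TRUE) {
  stopifnot(inherits(cm, "count_matrix"))
  sel <- cm$samples$tissue == tissue
  if (!any(sel)) stop("unknown tissue: ", tissue)
  y <- cm$counts[, sel, drop = FALSE]
  grp <- cm$samples$group[sel]
  if (sum(grp == "treated") < 2 || sum(grp == "control") < 2)
    stop("tissue '", tissue, "' needs >= 2 replicates in each group")
  sf <- size_factors(y)
  A <- grp == "treated"; B <- grp == "control"
  disp <- estimate_dispersion(y, sf, grp, prior_df)
  qA <- rowSums(y[, A, drop = FALSE]) / sum(sf[A])
  qB <- rowSums(y[, B, drop = FALSE]) / sum(sf[B])
  log2fc <- log2(qA + 0.5) - log2(qB + 0.5)
  sA <- rowSums(y[, A, drop = FALSE]); sB <- rowSums(y[, B, drop = FALSE])
  SA <- sum(sf[A]); SB <- sum(sf[B])
  sumA2 <- sum(sf[A]^2); sumB2 <- sum(sf[B]^2)
  p <- vapply(seq_len(nrow(y)), function(i)
    exact_nb_test(sA[i], sB[i], SA, SB, sumA2, sumB2, disp$tagwise[i],
                  midp = midp),
    numeric(1))
  zero <- sA + sB == 0
  p[zero] <- 1; log2fc[zero] <- 0
  p_call <- if (fdr) bh_adjust(p) else p
  direction <- ifelse(p_call < alpha & log2fc > 0, "up",
                      ifelse(p_call < alpha & log2fc < 0, "down", "ns"))
  out <- data.frame(gene = rownames(y), log2fc = unname(log2fc),
                    p_value = unname(p), direction = direction,
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(out, class = c("deg_table", "data.frame"),
            tissue = tissue, alpha = alpha, fdr = fdr,
            common_dispersion = disp$common)
}

deg_sets <- function(tab) {
  list(up = tab$gene[tab$direction == "up"],
       down = tab$gene[tab$direction == "down"],
       both = tab$gene[tab$direction != "ns"])
}

#' Summarize DEG tables across tissues
#'
#' Computes per-tissue up/down counts, the union of DEGs, the sharing
#' histogram (how many genes are DEGs in exactly k tissues), the tissue x
#' tissue cosine-similarity matrix on signed indicator vectors (+1 up, -1
#' down, 0 otherwise, over the DEG union) and a 3-way tissue module
#' assignment (`Mod_up`/`Mod_down`/`Mod_inbetween`) from average-linkage
#' clustering of `1 - cosine`, clusters labelled by their mean signed DEG
#' balance.
#'
#' @param tables list of `deg_table` objects with distinct tissues.
#' @return a `deg_summary` list.
#' @export
summarize_degs <- function(tables) {
  stopifnot(length(tables) >= 1)
  tissues <- vapply(tables, function(t) attr(t, "tissue"), "")
  if (anyDuplicated(tissues)) stop("duplicate tissue ids in DEG tables")
  per_tissue <- data.frame(
    tissue = tissues,
    n_up = vapply(tables, function(t) sum(t$direction == "up"), 0L),
    n_down = vapply(tables, function(t) sum(t$direction == "down"), 0L),
    stringsAsFactors = FALSE)
  union_genes <- sort(unique(unlist(lapply(tables, function(t)
    t$gene[t$direction != "ns"]))))
  X <- matrix(0, length(tissues), length(union_genes),
              dimnames = list(tissues, union_genes))
  for (i in seq_along(tables)) {
    t <- tables[[i]]
    X[i, t$gene[t$direction == "up"]] <- 1
    X[i, t$gene[t$direction == "down"]] <- -1
  }
  multiplicity <- colSums(X != 0)
  sharing <- if (length(union_genes)) table(factor(multiplicity,
                                                  levels = seq_along(tissues)))
             else table(factor(integer(0), levels = seq_along(tissues)))
  nrm <- sqrt(rowSums(X^2))
  cosine <- (X %*% t(X)) / outer(nrm, nrm)
  cosine[!is.finite(cosine)] <- 0
  diag(cosine) <- 1
  modules <- rep(NA_character_, length(tissues))
  names(modules) <- tissues
  if (length(tissues) >= 3) {
    hc <- stats::hclust(stats::as.dist(1 - cosine), method = "average")
    cl <- stats::cutree(hc, k = 3)
    balance <- (per_tissue$n_up - per_tissue$n_down) /
      pmax(per_tissue$n_up + per_tissue$n_down, 1)
    cl_bal <- tapply(balance, cl, mean)
    lab <- rep("Mod_inbetween", 3)
    lab[which.max(cl_bal)] <- "Mod_up"
    lab[setdiff(which.min(cl_bal), which.max(cl_bal))] <- "Mod_down"
    modules[] <- lab[cl]
  }
  structure(list(per_tissue = per_tissue,
                 n_total_degs = length(union_genes),
                 sharing = as.integer(sharing),
                 sharing_levels = seq_along(tissues),
                 cosine = cosine,
                 modules = modules),
            class = "deg_summary")
}

#' @export
print.deg_summary <- function(x, ...) {
  cat(sprintf("deg_summary: %d tissues, %d distinct DEGs\n",
              nrow(x$per_tissue), x$n_total_degs))
  print(x$per_tissue)
  invisible(x)
}

#' Hierarchical clustering and PCA of expression profiles
#'
#' Clusters samples on `log2(FPKM + 1)` restricted to `gene_subset`, with
#' correlation distance and average linkage, and computes PCA scores on the
#' same matrix centred per gene.
#'
#' @param fm numeric FPKM matrix (genes x samples).
#' @param gene_subset genes to use (default: all).
#' @param n_pcs number of principal components to return (>= 2).
#' @return list with `hclust` (a [stats::hclust] object over samples) and
#'   `pca` (list: `scores` samples x PCs, `sdev`, `prop_var`).
#' @export
cluster_profiles <- function(fm, gene_subset = NULL, n_pcs = 2) {
  if (!is.null(gene_subset)) {
    miss <- setdiff(gene_subset, rownames(fm))
    if (length(miss)) stop("gene_subset not in matrix: ", paste(utils::head(miss, 5), collapse = ", "))
    fm <- fm[gene_subset, , drop = FALSE]
  }
  if (nrow(fm) < 2 || ncol(fm) < 3) stop("need >= 2 genes and >= 3 samples")
  m <- log2(fm + 1)
  sds <- apply(m, 2, stats::sd)
  if (all(apply(m, 1, stats::sd) == 0) || any(sds == 0))
    stop("degenerate expression matrix: constant sample profile(s)")
  cc <- stats::cor(m)
  hc <- stats::hclust(stats::as.dist(1 - cc), method = "average")
  centred <- m - rowMeans(m)
  pc <- stats::prcomp(t(centred), center = FALSE, scale. = FALSE)
  k <- min(max(2, n_pcs), ncol(pc$x))
  var_tot <- sum(pc$sdev^2)
  list(hclust = hc,
       pca = list(scores = pc$x[, seq_len(k), drop = FALSE],
                  sdev = pc$sdev,
                  prop_var = pc$sdev^2 / var_tot))
}

#' Compare network centrality of DEG vs non-DEG nodes
#'
#' Computes PageRank (damping 0.85) and betweenness centrality for every
#' node of the signalling network and contrasts DEG nodes against the rest
#' by a two-sided Wilcoxon rank-sum test for each metric.
#'
#' @param net a [signaling_network()].
#' @param deg_genes character vector of gene symbols.
#' @return list with `node_metrics` (data.frame node/pagerank/betweenness/
#'   is_deg) and `tests` (data.frame metric/median_deg/median_other/
#'   p_value).
#' @export
compare_centrality <- function(net, deg_genes) {
  stopifnot(inherits(net, "signaling_network"))
  g <- net$graph
  nodes <- igraph::V(g)$name
  is_deg <- nodes %in% toupper(deg_genes)
  if (!any(is_deg)) stop("no DEG maps into the network")
  directed <- net$mode == "directed"
  pr <- igraph::page_rank(g, damping = 0.85)$vector
  btw <- igraph::betweenness(g, directed = directed)
  df <- data.frame(node = nodes, pagerank = unname(pr),
                   betweenness = unname(btw), is_deg = is_deg,
                   stringsAsFactors = FALSE)
  tst <- function(v) {
    w <- stats::wilcox.test(v[is_deg], v[!is_deg], exact = FALSE)
    c(median_deg = stats::median(v[is_deg]),
      median_other = stats::median(v[!is_deg]), p_value = w$p.value)
  }
  tests <- rbind(pagerank = tst(df$pagerank), betweenness = tst(df$betweenness))
  tests <- data.frame(metric = rownames(tests), tests, row.names = NULL)
  list(node_metrics = df, tests = tests)
}
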