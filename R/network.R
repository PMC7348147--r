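#' Directed signalling network container
#'
#' Wraps an igraph graph over human gene symbols. Symbols are
#' uppercase-normalized, self-loops dropped and duplicate edges merged at
#' construction. `mode` fixes the default distance semantics: with
#' `"undirected"` (default) edges are traversable both ways when measuring
#' proximity; `"directed"` follows edge direction.
#'
#' @param graph an igraph graph with vertex names.
#' @param mode `"undirected"` or `"directed"` distance mode.
#' @return An object of class `signaling_network`.
#' @export
signaling_network <- function(graph, mode = c("undirected", "directed")) {
  mode <- match.arg(mode)
  if (is.null(igraph::V(graph)$name)) stop("network vertices must be named")
  igraph::V(graph)$name <- toupper(igraph::V(graph)$name)
  graph <- igraph::simplify(graph, remove.multiple = TRUE, remove.loops = TRUE)
  structure(list(graph = graph, mode = mode), class = "signaling_network")
}

#' @export
print.signaling_network <- function(x, ...) {
  comp <- igraph::components(x$graph, mode = "weak")
  cat(sprintf("signaling_network: %d nodes, %d edges, largest component %d (%s distances)\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph),
              max(comp$csize), x$mode))
  invisible(x)
}

#' Load a signalling network from an edge-list TSV or GraphML file
#'
#' Edge-list files need columns `source` and `target` and may carry a
#' logical `directed` column; rows flagged `FALSE` contribute both
#' directions. Duplicated edges and self-loops are removed and symbols
#' uppercased; a load summary is messaged.
#'
#' @param path file path (`.graphml` dispatches on extension).
#' @param mode distance mode passed to [signaling_network()].
#' @return a [signaling_network()].
#' @export
load_network <- function(path, mode = c("undirected", "directed")) {
  mode <- match.arg(mode)
  if (!file.size(path) > 0) stop("empty network file: ", path)
  if (grepl("\\.graphml$", path, ignore.case = TRUE)) {
    g <- igraph::read_graph(path, format = "graphml")
    if (is.null(igraph::V(g)$name)) {
      nm_attr <- intersect(c("id", "label"), igraph::vertex_attr_names(g))
      if (length(nm_attr)) igraph::V(g)$name <- igraph::vertex_attr(g, nm_attr[1])
    }
  } else {
    df <- tryCatch(as.data.frame(data.table::fread(path, sep = "\t")),
                   error = function(e) stop("unknown network format in '", path,
                                            "': ", conditionMessage(e)))
    if (!all(c("source", "target") %in% names(df)))
      stop("unknown network format: expected columns source, target in ", path)
    el <- cbind(as.character(df$source), as.character(df$target))
    if ("directed" %in% names(df)) {
      undir <- !as.logical(df$directed)
      el <- rbind(el, el[undir, c(2, 1), drop = FALSE])
    }
    g <- igraph::graph_from_edgelist(el, directed = TRUE)
  }
  net <- signaling_network(g, mode)
  comp <- igraph::components(net$graph, mode = "weak")
  message(sprintf("loaded network: %d nodes, %d edges, largest component %d",
                  igraph::vcount(net$graph), igraph::ecount(net$graph),
                  max(comp$csize)))
  net
}

#' Write a network as an edge-list TSV
#' @param net a [signaling_network()].
#' @param path output path.
#' @export
write_network <- function(net, path) {
  el <- igraph::as_edgelist(net$graph)
  data.table::fwrite(data.frame(source = el[, 1], target = el[, 2],
                                directed = TRUE),
                     path, sep = "\t")
  invisible(path)
}

## penalty for unreachable pairs: diameter of the network under the given
## mode (longest finite shortest path) + 1, used identically in observed
## and null computations so comparisons stay fair
unreachable_penalty <- function(net, mode = net$mode) {
  igraph::diameter(net$graph, directed = mode == "directed",
                   unconnected = TRUE) + 1
}

## distance matrix from a gene set to all network nodes, with Inf replaced
## by the penalty (or kept Inf when unreachable = "drop")
deg_distance_matrix <- function(net, degs, mode = net$mode,
                                unreachable = c("penalty", "drop")) {
  unreachable <- match.arg(unreachable)
  D <- intersect(toupper(degs), igraph::V(net$graph)$name)
  if (!length(D)) stop("DEG set does not intersect the network")
  dm <- igraph::distances(net$graph, v = D, mode = if (mode == "directed") "out" else "all")
  if (unreachable == "penalty") dm[is.infinite(dm)] <- unreachable_penalty(net, mode)
  dm
}

row_min_over <- function(dm, cols) {
  do.call(pmin, lapply(cols, function(j) dm[, j]))
}

#' Drug-target network proximity dist(D,T)
#'
#' `dist(D,T) = (1/m) * sum_i min_j sp(D_i, T_j)`: the mean, over the
#' in-network DEGs `D_i`, of the shortest-path hop distance to the nearest
#' in-network drug target. Genes absent from the network are dropped (and
#' counted); a DEG unreachable from every target contributes the penalty
#' `diameter + 1` (or is excluded with `unreachable = "drop"`).
#'
#' @param net a [signaling_network()].
#' @param degs gene set D.
#' @param targets gene set T.
#' @param mode distance mode override.
#' @param unreachable `"penalty"` (default) or `"drop"`.
#' @return list with `dist`, `per_deg_min`, `n_deg_in_network`,
#'   `n_targets_in_network`.
#' @export
drug_deg_proximity <- function(net, degs, targets, mode = net$mode,
                               unreachable = c("penalty", "drop")) {
  unreachable <- match.arg(unreachable)
  nodes <- igraph::V(net$graph)$name
  D <- intersect(toupper(degs), nodes)
  Tn <- intersect(toupper(targets), nodes)
  if (!length(D)) stop("empty post-intersection DEG set (side D)")
  if (!length(Tn)) stop("empty post-intersection target set (side T)")
  dm <- deg_distance_matrix(net, D, mode, unreachable)
  mins <- row_min_over(dm, match(Tn, colnames(dm)))
  if (unreachable == "drop") {
    fin <- is.finite(mins)
    if (!any(fin)) stop("no DEG can reach any target under 'drop'")
    mins <- mins[fin]
  }
  list(dist = mean(mins), per_deg_min = mins,
       n_deg_in_network = length(D), n_targets_in_network = length(Tn))
}

#' Permutation test for drug-target proximity
#'
#' The observed `dist(D,T)` is compared against `n_perm` null distances
#' obtained by redrawing `|T|` false targets from the network (uniformly
#' over all nodes by default; `null_mode = "degree_matched"` redraws within
#' out-degree bins for sensitivity analysis). The empirical p uses the
#' add-one estimator `(1 + #[null <= observed]) / (n_perm + 1)`.
#'
#' @inheritParams drug_deg_proximity
#' @param n_perm number of null draws (>= 1).
#' @param seed integer seed (local to this test; global RNG untouched).
#' @param null_mode `"uniform"` or `"degree_matched"`.
#' @param dm optional precomputed [deg_distance_matrix()] for D (rows must
#'   be the in-network DEGs) to amortize across drugs.
#' @return a `proximity_result` list: observed_dist, null_dists,
#'   empirical_p, n_deg_in_network, n_targets_in_network.
#' @export
proximity_permutation_test <- function(net, degs, targets, n_perm = 1000,
                                       seed = 1, mode = net$mode,
                                       null_mode = c("uniform", "degree_matched"),
                                       unreachable = c("penalty", "drop"),
                                       dm = NULL) {
  null_mode <- match.arg(null_mode)
  unreachable <- match.arg(unreachable)
  stopifnot(n_perm >= 1)
  nodes <- igraph::V(net$graph)$name
  Tn <- intersect(toupper(targets), nodes)
  if (!length(Tn)) stop("empty post-intersection target set (side T)")
  if (length(Tn) >= length(nodes))
    stop("target set covers the whole network; null draws impossible")
  if (is.null(dm)) dm <- deg_distance_matrix(net, degs, mode, unreachable)
  score <- function(cols) {
    mins <- row_min_over(dm, cols)
    if (unreachable == "drop") mins <- mins[is.finite(mins)]
    mean(mins)
  }
  observed <- score(match(Tn, colnames(dm)))
  nT <- length(Tn)
  null_dists <- with_seed(seed, {
    if (null_mode == "uniform") {
      vapply(seq_len(n_perm), function(b) score(sample.int(ncol(dm), nT)),
             numeric(1))
    } else {
      deg_bin <- findInterval(igraph::degree(net$graph, mode = "all"),
                              stats::quantile(igraph::degree(net$graph, mode = "all"),
                                              probs = seq(0, 1, 0.1)),
                              rightmost.closed = TRUE)
      pools <- split(seq_len(ncol(dm)), deg_bin[match(colnames(dm), nodes)])
      tbin <- deg_bin[match(Tn, nodes)]
      vapply(seq_len(n_perm), function(b) {
        cols <- vapply(tbin, function(bn) {
          pool <- pools[[as.character(bn)]]
          pool[sample.int(length(pool), 1)]
        }, integer(1))
        score(cols)
      }, numeric(1))
    }
  })
  empirical_p <- (1 + sum(null_dists <= observed + 1e-12)) / (n_perm + 1)
  structure(list(observed_dist = observed, null_dists = null_dists,
                 empirical_p = empirical_p,
                 n_deg_in_network = nrow(dm), n_targets_in_network = nT),
            class = "proximity_result")
}

#' Six-combination proximity screen with consensus calls
#'
#' For every drug and tissue, the proximity permutation test is run for the
#' six combinations of DEG set kind (up, down, both) and target annotation
#' source; p-values are BH-adjusted across drugs within each
#' (tissue, kind, source) stratum, and a (drug, tissue) pair is retained by
#' the consensus rule iff at least one DEG kind is significant
#' (`fdr < fdr_threshold`) in each of the two sources.
#'
#' @param net a [signaling_network()].
#' @param deg_tables named list of `deg_table` objects (one per tissue) or
#'   of lists with `up`/`down`/`both` gene sets.
#' @param targets data.frame with columns `drug`, `target`, `source_db`
#'   (exactly two source labels, each with >= 1 drug).
#' @param n_perm permutations per test.
#' @param seed global seed; every (tissue, kind, source, drug) test derives
#'   its own stream.
#' @param fdr_threshold consensus significance level on BH-adjusted p.
#' @inheritParams drug_deg_proximity
#' @return list with `results` (data.frame drug/tissue/deg_set_kind/
#'   source_db/observed_dist/empirical_p/fdr/n_deg_in_network/
#'   n_targets_in_network) and `consensus` (data.frame drug/tissue/
#'   supported kinds per source/retained).
#' @export
run_proximity_screen <- function(net, deg_tables, targets, n_perm = 1000,
                                 seed = 1, fdr_threshold = 0.05,
                                 mode = net$mode,
                                 null_mode = c("uniform", "degree_matched"),
                                 unreachable = c("penalty", "drop")) {
  null_mode <- match.arg(null_mode)
  unreachable <- match.arg(unreachable)
  sources <- sort(unique(targets$source_db))
  if (length(sources) != 2)
    stop("exactly two target sources required, got: ", paste(sources, collapse = ", "))
  for (s in sources) if (!length(unique(targets$drug[targets$source_db == s])))
    stop("target source '", s, "' has zero drugs")
  tissues <- names(deg_tables)
  if (is.null(tissues)) stop("deg_tables must be a named list (tissue names)")
  rows <- list()
  for (tis in tissues) {
    tab <- deg_tables[[tis]]
    sets <- if (inherits(tab, "deg_table")) deg_sets(tab) else tab
    ## distance rows for the union once per tissue, subset per kind
    union_genes <- intersect(toupper(sets$both), igraph::V(net$graph)$name)
    if (!length(union_genes)) next
    dm_all <- deg_distance_matrix(net, union_genes, mode, unreachable)
    for (kind in c("up", "down", "both")) {
      D <- intersect(toupper(sets[[kind]]), rownames(dm_all))
      if (!length(D)) next
      dm <- dm_all[D, , drop = FALSE]
      for (src in sources) {
        tsrc <- targets[targets$source_db == src, , drop = FALSE]
        for (d in unique(tsrc$drug)) {
          tg <- tsrc$target[tsrc$drug == d]
          pr <- proximity_permutation_test(
            net, D, tg, n_perm = n_perm,
            seed = sub_seed(seed, tis, kind, src, d),
            mode = mode, null_mode = null_mode, unreachable = unreachable,
            dm = dm)
          rows[[length(rows) + 1L]] <- data.frame(
            drug = d, tissue = tis, deg_set_kind = kind, source_db = src,
            observed_dist = pr$observed_dist, empirical_p = pr$empirical_p,
            n_deg_in_network = pr$n_deg_in_network,
            n_targets_in_network = pr$n_targets_in_network,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  res <- do.call(rbind, rows)
  if (is.null(res)) stop("no testable (tissue, drug) combination")
  res$fdr <- NA_real_
  for (tis in unique(res$tissue)) for (kind in unique(res$deg_set_kind))
    for (src in sources) {
      j <- res$tissue == tis & res$deg_set_kind == kind & res$source_db == src
      if (any(j)) res$fdr[j] <- bh_adjust(res$empirical_p[j])
    }
  cons <- list()
  for (tis in unique(res$tissue)) for (d in unique(res$drug)) {
    sub <- res[res$tissue == tis & res$drug == d, , drop = FALSE]
    hit <- sub[sub$fdr < fdr_threshold, , drop = FALSE]
    k1 <- hit$deg_set_kind[hit$source_db == sources[1]]
    k2 <- hit$deg_set_kind[hit$source_db == sources[2]]
    cons[[length(cons) + 1L]] <- data.frame(
      drug = d, tissue = tis,
      kinds_source_1 = paste(sort(k1), collapse = ","),
      kinds_source_2 = paste(sort(k2), collapse = ","),
      retained = length(k1) > 0 && length(k2) > 0,
      stringsAsFactors = FALSE)
  }
  list(results = res, consensus = do.call(rbind, cons))
}
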