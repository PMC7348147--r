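## synthetic-data generator: every downstream stage is exercised against a
## world with known planted structure (DEGs, signature correlations, drugs
## whose targets sit close to DEGs in the network).

TISSUE_POOL <- c("aorta", "brown_adipose", "brain", "eye", "heart",
                 "liver", "kidney", "skeletal_muscle", "stomach", "testis")

#' Simulation configuration
#'
#' Declares the synthetic world: a multi-tissue treated-vs-control RNA-seq
#' experiment with negative-binomial counts and tissue-specific planted
#' DEGs, a reference signature compendium with planted Spearman correlations
#' to the treatment signature, and a scale-free signalling network with
#' drugs whose targets are planted at controlled hop distance from DEGs.
#'
#' Defaults mirror the design the pipeline targets: 10 tissues x 2 groups x
#' 3 biological replicates.
#'
#' @param n_tissues number of tissues (first `n_tissues` of the built-in
#'   pool, generic names beyond 10).
#' @param n_genes number of genes.
#' @param n_replicates biological replicates per group.
#' @param deg_fraction fraction of genes planted as DEGs in each tissue
#'   (half up, half down), in (0,1); 0 gives a pure null world.
#' @param lfc_magnitude absolute log2 fold change of planted DEGs.
#' @param nb_dispersion negative-binomial dispersion phi
#'   (variance = mu + phi mu^2).
#' @param libsize_range length-2 numeric, bounds for per-sample total counts
#'   (drawn log-uniform).
#' @param tissue_effect_sd per-gene tissue baseline effect, SD on the log2
#'   scale (drives the tissue-wise clustering structure of real data).
#' @param network_nodes number of network nodes (first `network_nodes`
#'   genes become node symbols; must not exceed `n_genes`).
#' @param network_attach_param preferential-attachment edges per new node.
#' @param n_drugs number of drugs (two annotation sources each).
#' @param targets_per_drug targets per drug per source.
#' @param planted_proximity_drugs data.frame with columns `drug`, `hop` and
#'   optionally `tissue` (defaults to the first tissue): drugs whose targets
#'   are drawn from nodes within `hop` of that tissue's in-network DEGs.
#' @param n_reference_signatures size of the reference compendium.
#' @param planted_correlations data.frame with columns `id`, `topic`, `scc`:
#'   reference signatures planted at a target Spearman correlation with the
#'   treatment signature.
#' @param seed global integer seed; all components derive independent
#'   streams from it.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_tissues = 10, n_genes = 5000, n_replicates = 3,
                              deg_fraction = 0.05, lfc_magnitude = 2,
                              nb_dispersion = 0.1,
                              libsize_range = c(2e5, 5e5),
                              tissue_effect_sd = 1,
                              network_nodes = 1000, network_attach_param = 3,
                              n_drugs = 20, targets_per_drug = 8,
                              planted_proximity_drugs = NULL,
                              n_reference_signatures = 100,
                              planted_correlations = NULL,
                              seed = 1) {
  cfg <- structure(as.list(environment()), class = "simulation_config")
  validate_simulation_config(cfg)
  cfg
}

validate_simulation_config <- function(cfg) {
  for (f in c("n_tissues", "n_genes", "n_replicates", "network_nodes",
              "network_attach_param", "n_drugs", "targets_per_drug",
              "n_reference_signatures")) {
    if (!is_count(cfg[[f]])) stop_config("field '%s' must be a positive integer", f)
  }
  if (!(cfg$deg_fraction >= 0 && cfg$deg_fraction < 1))
    stop_config("field 'deg_fraction' must be in [0,1)")
  if (cfg$lfc_magnitude < 0) stop_config("field 'lfc_magnitude' must be >= 0")
  if (cfg$nb_dispersion < 0) stop_config("field 'nb_dispersion' must be >= 0")
  if (length(cfg$libsize_range) != 2 || any(cfg$libsize_range <= 0) ||
      cfg$libsize_range[1] > cfg$libsize_range[2])
    stop_config("field 'libsize_range' must be increasing positive bounds")
  if (cfg$network_nodes > cfg$n_genes)
    stop_config("field 'network_nodes' must not exceed n_genes")
  if (cfg$n_replicates < 2)
    stop_config("field 'n_replicates' must be >= 2 for differential testing")
  pc <- cfg$planted_correlations
  if (!is.null(pc)) {
    if (!all(c("id", "topic", "scc") %in% names(pc)))
      stop_config("field 'planted_correlations' needs columns id, topic, scc")
    if (any(abs(pc$scc) > 1))
      stop_config("field 'planted_correlations' has |scc| > 1")
  }
  pp <- cfg$planted_proximity_drugs
  if (!is.null(pp)) {
    if (!all(c("drug", "hop") %in% names(pp)))
      stop_config("field 'planted_proximity_drugs' needs columns drug, hop")
    if (any(pp$hop < 0)) stop_config("field 'planted_proximity_drugs' has negative hop")
  }
  invisible(cfg)
}

sim_tissue_names <- function(n) {
  if (n <= length(TISSUE_POOL)) TISSUE_POOL[seq_len(n)]
  else c(TISSUE_POOL, sprintf("tissue%02d", seq_len(n - length(TISSUE_POOL))))
}

#' Simulate a multi-tissue count matrix with planted DEGs
#'
#' Counts are negative-binomial around per-gene baselines modulated by a
#' per-tissue gene effect; planted DEGs have their mean shifted by
#' `2^(+/- lfc_magnitude)` in the treated group of their tissue only.
#' Library sizes are drawn log-uniform in `libsize_range` and applied
#' multiplicatively.
#'
#' @param cfg a [simulation_config()].
#' @return list with elements `cm` (a [count_matrix()]) and `truth` (a
#'   `ground_truth` list: `planted_deg_sets` is tissue -> list(up, down)).
#' @export
simulate_counts <- function(cfg) {
  validate_simulation_config(cfg)
  tissues <- sim_tissue_names(cfg$n_tissues)
  genes <- sprintf("g%05d", seq_len(cfg$n_genes))
  with_seed(sub_seed(cfg$seed, "counts"), {
    base_mean <- pmax(exp(stats::rnorm(cfg$n_genes, log(60), 1.2)), 0.5)
    gene_lengths <- stats::setNames(
      round(exp(stats::runif(cfg$n_genes, log(500), log(10000)))), genes)
    ## per-tissue log2 baseline modulation (tissue identity signal)
    tis_eff <- matrix(stats::rnorm(cfg$n_genes * cfg$n_tissues, 0,
                                   cfg$tissue_effect_sd),
                      cfg$n_genes, cfg$n_tissues, dimnames = list(genes, tissues))
    n_deg <- round(cfg$deg_fraction * cfg$n_genes)
    planted <- list()
    for (t in tissues) {
      idx <- sample.int(cfg$n_genes, n_deg)
      n_up <- floor(n_deg / 2)
      planted[[t]] <- list(up = sort(genes[idx[seq_len(n_up)]]),
                           down = sort(genes[idx[setdiff(seq_len(n_deg), seq_len(n_up))]]))
    }
    n_samp <- cfg$n_tissues * 2 * cfg$n_replicates
    ann <- expand.grid(replicate = seq_len(cfg$n_replicates),
                       group = c("control", "treated"),
                       tissue = tissues, stringsAsFactors = FALSE)
    ann$sample <- sprintf("%s_%s_%d", ann$tissue, ann$group, ann$replicate)
    libsizes <- exp(stats::runif(n_samp, log(cfg$libsize_range[1]),
                                 log(cfg$libsize_range[2])))
    phi <- max(cfg$nb_dispersion, 1e-8)
    counts <- matrix(0L, cfg$n_genes, n_samp, dimnames = list(genes, ann$sample))
    for (j in seq_len(n_samp)) {
      mu <- base_mean * 2^tis_eff[, ann$tissue[j]]
      if (ann$group[j] == "treated") {
        pl <- planted[[ann$tissue[j]]]
        mu[pl$up] <- mu[pl$up] * 2^cfg$lfc_magnitude
        mu[pl$down] <- mu[pl$down] * 2^(-cfg$lfc_magnitude)
      }
      mu <- mu * (libsizes[j] / sum(mu))
      counts[, j] <- stats::rnbinom(cfg$n_genes, mu = mu, size = 1 / phi)
    }
    truth <- structure(list(planted_deg_sets = planted,
                            planted_signature_scc = NULL,
                            planted_proximal_drugs = character(0)),
                       class = "ground_truth")
    list(cm = count_matrix(counts, ann[, c("sample", "tissue", "group", "replicate")],
                           gene_lengths),
         truth = truth)
  })
}

#' Simulate a scale-free signalling network and drug target sets
#'
#' Builds a preferential-attachment graph over the first `network_nodes`
#' gene symbols, directs each edge from the lower- to the higher-index node
#' and reciprocates a random 10 percent. Drugs listed in
#' `cfg$planted_proximity_drugs` get targets sampled from nodes within the
#' stated hop distance (undirected) of the planted DEGs of their tissue;
#' all other drugs get uniformly random targets. Each drug is annotated in
#' both target sources (`source_A`, `source_B`) with independent draws.
#'
#' @param cfg a [simulation_config()].
#' @param truth `ground_truth` from [simulate_counts()].
#' @return list with `network` (a [signaling_network()]), `targets`
#'   (data.frame drug/target/source_db) and `truth` updated with
#'   `planted_proximal_drugs`.
#' @export
simulate_network_and_drugs <- function(cfg, truth) {
  validate_simulation_config(cfg)
  genes <- sprintf("g%05d", seq_len(cfg$n_genes))
  nodes <- toupper(genes[seq_len(cfg$network_nodes)])
  with_seed(sub_seed(cfg$seed, "network"), {
    g0 <- igraph::sample_pa(cfg$network_nodes, power = 1,
                            m = cfg$network_attach_param, directed = FALSE)
    el <- igraph::as_edgelist(g0, names = FALSE)
    lo <- pmin(el[, 1], el[, 2]); hi <- pmax(el[, 1], el[, 2])
    el_dir <- cbind(lo, hi)
    n_recip <- round(0.10 * nrow(el_dir))
    if (n_recip > 0) {
      ridx <- sample.int(nrow(el_dir), n_recip)
      el_dir <- rbind(el_dir, el_dir[ridx, c(2, 1), drop = FALSE])
    }
    g <- igraph::graph_from_edgelist(el_dir, directed = TRUE)
    igraph::V(g)$name <- nodes[seq_len(igraph::vcount(g))]
    net <- signaling_network(g, mode = "undirected")

    drugs <- sprintf("drug%02d", seq_len(cfg$n_drugs))
    pp <- cfg$planted_proximity_drugs
    planted_ids <- character(0)
    if (!is.null(pp) && nrow(pp)) {
      if (!all(pp$drug %in% drugs))
        stop_config("planted drug ids must be among drug01..drug%02d", cfg$n_drugs)
      planted_ids <- pp$drug
      if (is.null(pp$tissue)) pp$tissue <- sim_tissue_names(cfg$n_tissues)[1]
    }
    rows <- list()
    dmat_cache <- list()
    for (src in c("source_A", "source_B")) {
      for (i in seq_along(drugs)) {
        d <- drugs[i]
        if (d %in% planted_ids) {
          spec <- pp[pp$drug == d, , drop = FALSE][1, ]
          degs <- toupper(unlist(truth$planted_deg_sets[[spec$tissue]], use.names = FALSE))
          deg_in_net <- intersect(degs, igraph::V(net$graph)$name)
          if (!length(deg_in_net))
            stop_sim("no planted DEG of tissue '%s' maps into the network", spec$tissue)
          key <- spec$tissue
          if (is.null(dmat_cache[[key]]))
            dmat_cache[[key]] <- igraph::distances(net$graph, v = deg_in_net,
                                                   mode = "all")
          dmat <- dmat_cache[[key]]
          mind <- apply(dmat, 2, min)
          cand <- names(mind)[is.finite(mind) & mind <= spec$hop]
          if (length(cand) < cfg$targets_per_drug)
            stop_sim("hop distance %d yields only %d candidate targets (< %d) for drug '%s'",
                     spec$hop, length(cand), cfg$targets_per_drug, d)
          ## coverage-greedy choice: targets must spread over the DEG
          ## neighbourhood, not pile up next to one DEG, or the planted
          ## proximity signal dissolves into the mean
          tg <- character(0)
          cur <- rep(Inf, nrow(dmat))
          avail <- cand
          for (step in seq_len(cfg$targets_per_drug)) {
            sc <- vapply(avail, function(cnd) mean(pmin(cur, dmat[, cnd])), 0)
            best <- avail[sc <= min(sc) + 1e-9]
            pick <- best[sample.int(length(best), 1)]
            tg <- c(tg, pick)
            cur <- pmin(cur, dmat[, pick])
            avail <- setdiff(avail, pick)
          }
        } else {
          tg <- sample(igraph::V(net$graph)$name, cfg$targets_per_drug)
        }
        rows[[length(rows) + 1L]] <- data.frame(drug = d, target = tg,
                                                source_db = src,
                                                stringsAsFactors = FALSE)
      }
    }
    truth$planted_proximal_drugs <- planted_ids
    list(network = net, targets = do.call(rbind, rows), truth = truth)
  })
}

#' Simulate a reference signature compendium with planted correlations
#'
#' Planted signatures are generated by rank-blending: the treatment
#' signature's normal scores are mixed with Gaussian noise at the Pearson
#' level `2*sin(pi*scc/6)` that induces the target Spearman correlation;
#' the achieved SCC is verified by direct computation before emission
#' (re-drawn, deterministically under the seed, if off by more than 0.04).
#' Unplanted signatures are independent permutations of the treatment
#' values. Targets of exactly +1/-1 are emitted as exact monotone
#' transforms.
#'
#' @param cfg a [simulation_config()].
#' @param treatment_sig a [signature_fc()] to plant correlations against.
#' @return list of `signature_fc`, length `cfg$n_reference_signatures`.
#' @export
simulate_reference_signatures <- function(cfg, treatment_sig) {
  validate_simulation_config(cfg)
  if (!length(treatment_sig$values)) stop_config("treatment signature is empty")
  v <- treatment_sig$values
  ng <- length(v)
  pc <- cfg$planted_correlations
  if (!is.null(pc) && any(abs(pc$scc) > 1))
    stop_config("target SCC outside [-1,1]")
  n_planted <- if (is.null(pc)) 0L else nrow(pc)
  if (n_planted > cfg$n_reference_signatures)
    stop_config("more planted correlations than reference signatures")
  with_seed(sub_seed(cfg$seed, "refsigs"), {
    z <- stats::qnorm((rank(v, ties.method = "average") - 0.5) / ng)
    sigs <- vector("list", cfg$n_reference_signatures)
    topics <- sprintf("topic_%02d", 1:20)
    for (i in seq_len(cfg$n_reference_signatures)) {
      if (i <= n_planted) {
        target <- pc$scc[i]
        if (abs(target) >= 1) {
          vals <- sign(target) * z
        } else {
          rho_p <- 2 * sin(pi * target / 6)
          for (try in 1:50) {
            vals <- rho_p * z + sqrt(1 - rho_p^2) * stats::rnorm(ng)
            ach <- stats::cor(vals, v, method = "spearman")
            if (abs(ach - target) <= 0.04) break
          }
        }
        sig <- signature_fc(pc$id[i], stats::setNames(vals, names(v)),
                            tissue = treatment_sig$tissue, topic = pc$topic[i],
                            polarity = sample(c("beneficial", "deleterious"), 1),
                            platform = "one_colour")
      } else {
        sig <- signature_fc(sprintf("ref%03d", i),
                            stats::setNames(sample(unname(v)), names(v)),
                            tissue = treatment_sig$tissue,
                            topic = sample(topics, 1),
                            polarity = sample(c("beneficial", "deleterious", "neutral"), 1),
                            platform = sample(c("one_colour", "rnaseq",
                                                "two_colour_paired"), 1))
      }
      sigs[[i]] <- sig
    }
    sigs
  })
}

#' Write all simulated inputs to an output directory
#'
#' Emits the count matrix (TSV and MTX with gene/sample index files), the
#' sample annotation, gene lengths, the network (edge-list TSV and
#' GraphML), drug targets, the reference signature compendium and a
#' machine-readable ground-truth manifest (JSON).
#'
#' @param cfg a [simulation_config()].
#' @param outdir output directory (created if absent).
#' @return invisibly, a named list of the generated objects.
#' @export
simulate_world <- function(cfg, outdir = NULL) {
  sim <- simulate_counts(cfg)
  nd <- simulate_network_and_drugs(cfg, sim$truth)
  first_tissue <- sim_tissue_names(cfg$n_tissues)[1]
  tsig <- build_signature_from_counts(sim$cm, first_tissue)
  refs <- simulate_reference_signatures(cfg, tsig)
  world <- list(cm = sim$cm, truth = nd$truth, network = nd$network,
                targets = nd$targets, treatment_signature = tsig,
                reference_signatures = refs)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_count_matrix(sim$cm, outdir)
    write_network(nd$network, file.path(outdir, "network.tsv"))
    igraph::write_graph(nd$network$graph, file.path(outdir, "network.graphml"),
                        format = "graphml")
    data.table::fwrite(nd$targets, file.path(outdir, "drug_targets.tsv"), sep = "\t")
    write_signatures(c(list(tsig), refs), file.path(outdir, "signatures.tsv"))
    manifest <- list(
      config = cfg[setdiff(names(cfg), c("planted_proximity_drugs",
                                         "planted_correlations"))],
      planted_deg_sets = nd$truth$planted_deg_sets,
      planted_proximal_drugs = nd$truth$planted_proximal_drugs,
      planted_correlations = cfg$planted_correlations)
    jsonlite::write_json(manifest, file.path(outdir, "ground_truth.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(world)
}
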