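#' Pipeline configuration
#'
#' Collects input paths and tuning parameters for [run_pipeline()]. Paths
#' left `NULL` disable the corresponding stage. May also be loaded from a
#' JSON file with the same field names.
#'
#' @param counts_dir directory with the count matrix files (see
#'   [read_count_matrix()]); required.
#' @param signatures_file reference signature compendium TSV (optional).
#' @param network_file edge-list TSV or GraphML (optional).
#' @param targets_file drug target TSV (optional; requires network).
#' @param gmt_file gene sets in GMT format (optional).
#' @param drug_annotations_file drug class/side-effect/ddi TSV (optional).
#' @param ortholog_file mouse->human mapping TSV (optional).
#' @param outdir output directory.
#' @param alpha DEG significance threshold (raw p).
#' @param scc_cutoff redundancy-pruning SCC cutoff.
#' @param n_perm proximity permutations.
#' @param seed global seed.
#' @param distance_mode `"undirected"` or `"directed"`.
#' @param null_mode `"uniform"` or `"degree_matched"`.
#' @param fdr_threshold consensus FDR threshold.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(counts_dir, signatures_file = NULL,
                            network_file = NULL, targets_file = NULL,
                            gmt_file = NULL, drug_annotations_file = NULL,
                            ortholog_file = NULL,
                            outdir = "proxscreen_out", alpha = 0.05,
                            scc_cutoff = 0.5, n_perm = 1000, seed = 1,
                            distance_mode = c("undirected", "directed"),
                            null_mode = c("uniform", "degree_matched"),
                            fdr_threshold = 0.05) {
  distance_mode <- match.arg(distance_mode)
  null_mode <- match.arg(null_mode)
  stopifnot(alpha >= 0, alpha <= 1, scc_cutoff >= -1, scc_cutoff <= 1,
            n_perm >= 1, fdr_threshold > 0, fdr_threshold <= 1)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Load a pipeline configuration from JSON
#' @param path JSON file whose keys are [pipeline_config()] arguments.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  args <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, args)
}

validate_pipeline_config <- function(cfg) {
  paths <- c(counts = cfg$counts_dir, cfg$signatures_file, cfg$network_file,
             cfg$targets_file, cfg$gmt_file, cfg$drug_annotations_file,
             cfg$ortholog_file)
  missing <- paths[!vapply(paths, function(p) is.null(p) || file.exists(p), TRUE)]
  if (length(missing))
    stop("missing input(s): ", paste(unlist(missing), collapse = ", "))
  if (!is.null(cfg$targets_file) && is.null(cfg$network_file))
    stop("targets_file requires network_file")
  invisible(cfg)
}

#' Run the end-to-end screening pipeline
#'
#' Executes normalize -> per-tissue DEG calling -> DEG summary and sample
#' clustering -> per-tissue treatment signatures (+ compendium correlation
#' when a compendium is supplied) -> network drug-target proximity screen
#' with consensus calls (when network + targets are supplied) -> gene-set
#' and drug-feature enrichment (when those inputs are supplied). All stage
#' outputs are written under `cfg$outdir`; a run manifest (config snapshot,
#' input checksums, per-stage row counts and timings) is written as
#' `manifest.json`. Identical config + seed reproduces identical outputs.
#'
#' @param cfg a [pipeline_config()].
#' @return the manifest, invisibly; stage outputs on disk.
#' @export
run_pipeline <- function(cfg) {
  validate_pipeline_config(cfg)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config = cfg[!vapply(cfg, is.null, TRUE)],
                   version = as.character(utils::packageVersion("proxscreen")),
                   stages = list())
  input_files <- list.files(cfg$counts_dir, full.names = TRUE)
  for (f in c(cfg$signatures_file, cfg$network_file, cfg$targets_file,
              cfg$gmt_file, cfg$drug_annotations_file, cfg$ortholog_file))
    input_files <- c(input_files, f)
  manifest$input_checksums <- as.list(tools::md5sum(unlist(input_files)))
  stage <- function(name, code) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(code, error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA,
                           force = TRUE)
      stop("stage '", name, "' failed: ", conditionMessage(e))
    })
    manifest$stages[[name]] <<- list(
      status = "ok", rows = if (is.data.frame(out)) nrow(out) else NA,
      seconds = round(proc.time()[["elapsed"]] - t0, 3))
    out
  }

  cm <- stage("load_counts", read_count_matrix(cfg$counts_dir))
  fm <- stage("normalize", {
    f <- fpkm_normalize(cm)
    data.table::fwrite(data.table::data.table(gene = rownames(f), f),
                       file.path(cfg$outdir, "fpkm.tsv"), sep = "\t")
    f
  })
  tissues <- unique(cm$samples$tissue)
  deg_tables <- stage("deg", {
    tabs <- lapply(tissues, function(t) detect_degs(cm, t, alpha = cfg$alpha))
    names(tabs) <- tissues
    for (t in tissues)
      write_deg_table(tabs[[t]], file.path(cfg$outdir, paste0("deg_", t, ".tsv")))
    tabs
  })
  summ <- stage("summarize", {
    s <- summarize_degs(unname(deg_tables))
    write_deg_summary(s, file.path(cfg$outdir, "deg_summary.json"))
    s
  })
  stage("cluster", {
    union_degs <- unlist(lapply(deg_tables, function(t) t$gene[t$direction != "ns"]))
    subset <- if (length(unique(union_degs)) >= 2) unique(union_degs) else NULL
    cl <- cluster_profiles(fm, subset)
    write_dendrogram_newick(cl$hclust, file.path(cfg$outdir, "sample_dendrogram.nwk"))
    data.table::fwrite(data.table::data.table(sample = rownames(cl$pca$scores),
                                              cl$pca$scores),
                       file.path(cfg$outdir, "pca_scores.tsv"), sep = "\t")
    cl
  })
  sigs <- stage("signatures", {
    s <- lapply(tissues, function(t) build_signature_from_counts(cm, t))
    names(s) <- tissues
    write_signatures(unname(s), file.path(cfg$outdir, "treatment_signatures.tsv"))
    s
  })
  if (!is.null(cfg$signatures_file)) {
    stage("signature_correlation", {
      refs <- read_signatures(cfg$signatures_file)
      refs <- prune_redundant(refs, cfg$scc_cutoff)
      out <- do.call(rbind, lapply(tissues, function(t) {
        cc <- correlate_signatures(sigs[[t]], refs)
        cc$tissue <- t
        cc
      }))
      data.table::fwrite(out, file.path(cfg$outdir, "signature_correlations.tsv"),
                         sep = "\t")
      jsonlite::write_json(polarity_summary(out),
                           file.path(cfg$outdir, "polarity_summary.json"),
                           auto_unbox = TRUE, pretty = TRUE)
      out
    })
  }
  screen <- NULL
  if (!is.null(cfg$network_file) && !is.null(cfg$targets_file)) {
    screen <- stage("proximity", {
      net <- suppressMessages(load_network(cfg$network_file, cfg$distance_mode))
      targets <- read_drug_targets(cfg$targets_file)
      deg_for_net <- deg_tables
      if (!is.null(cfg$ortholog_file)) {
        ortho <- as.data.frame(data.table::fread(cfg$ortholog_file))
        deg_for_net <- lapply(deg_tables, function(tab) {
          s <- deg_sets(tab)
          lapply(s, function(g) map_orthologs(g, ortho)$human)
        })
      }
      any_deg <- any(vapply(deg_for_net, function(tab) {
        s <- if (inherits(tab, "deg_table")) deg_sets(tab) else tab
        length(s$both) > 0
      }, TRUE))
      if (!any_deg) {
        empty <- data.frame(drug = character(0), tissue = character(0),
                            deg_set_kind = character(0), source_db = character(0),
                            observed_dist = numeric(0), empirical_p = numeric(0),
                            n_deg_in_network = integer(0),
                            n_targets_in_network = integer(0), fdr = numeric(0))
        data.table::fwrite(empty, file.path(cfg$outdir, "proximity.tsv"), sep = "\t")
        data.table::fwrite(data.frame(drug = character(0), tissue = character(0),
                                      kinds_source_1 = character(0),
                                      kinds_source_2 = character(0),
                                      retained = logical(0)),
                           file.path(cfg$outdir, "consensus.tsv"), sep = "\t")
        empty
      } else {
        sc <- run_proximity_screen(net, deg_for_net, targets,
                                   n_perm = cfg$n_perm, seed = cfg$seed,
                                   fdr_threshold = cfg$fdr_threshold,
                                   mode = cfg$distance_mode,
                                   null_mode = cfg$null_mode)
        data.table::fwrite(sc$results, file.path(cfg$outdir, "proximity.tsv"), sep = "\t")
        data.table::fwrite(sc$consensus, file.path(cfg$outdir, "consensus.tsv"), sep = "\t")
        sc$results
      }
    })
  }
  if (!is.null(cfg$gmt_file)) {
    stage("gene_set_enrichment", {
      gmt <- read_gmt(cfg$gmt_file)
      query <- unique(unlist(lapply(deg_tables, function(t)
        t$gene[t$direction != "ns"])))
      universe <- rownames(cm$counts)
      coll <- gene_set_collection(gmt$sets, universe, gmt$descriptions)
      enr <- gene_set_enrichment(intersect(query, universe), coll)
      data.table::fwrite(enr, file.path(cfg$outdir, "gene_set_enrichment.tsv"),
                         sep = "\t")
      enr
    })
  }
  if (!is.null(cfg$drug_annotations_file) && !is.null(screen)) {
    stage("drug_enrichment", {
      ann <- as.data.frame(data.table::fread(cfg$drug_annotations_file))
      cons <- as.data.frame(data.table::fread(file.path(cfg$outdir, "consensus.tsv")))
      hits <- unique(cons$drug[cons$retained == TRUE])
      if (length(hits)) {
        enr <- do.call(rbind, lapply(intersect(c("class", "side_effect", "interaction"),
                                               c(names(ann), "interaction")), function(kind) {
          if (kind == "interaction" && !"ddi_flag" %in% names(ann)) return(NULL)
          out <- drug_feature_enrichment(hits, unique(ann$drug), ann, kind)
          out$feature_kind <- kind
          out
        }))
        data.table::fwrite(enr, file.path(cfg$outdir, "drug_enrichment.tsv"), sep = "\t")
        enr
      } else data.frame()
    })
  }
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA, force = TRUE)
  invisible(manifest)
}

#' One-command synthetic demonstration
#'
#' Simulates a compact world with planted structure, writes its inputs to
#' `<outdir>/inputs`, runs the full pipeline on them and returns the
#' manifest. Sized to finish in well under five minutes on one CPU.
#'
#' @param outdir output directory.
#' @param seed global seed.
#' @param n_perm proximity permutations (reduced default for the demo).
#' @return list with the manifest and the ground truth.
#' @export
demo_pipeline <- function(outdir = tempfile("proxscreen_demo"), seed = 1,
                          n_perm = 200) {
  cfg <- simulation_config(
    n_tissues = 3, n_genes = 1200, n_replicates = 3, deg_fraction = 0.05,
    lfc_magnitude = 2.5, nb_dispersion = 0.05, libsize_range = c(6e4, 1.2e5),
    network_nodes = 400, network_attach_param = 3, n_drugs = 12,
    targets_per_drug = 8,
    planted_proximity_drugs = data.frame(drug = c("drug01", "drug02"),
                                         hop = c(0L, 1L),
                                         tissue = "aorta"),
    n_reference_signatures = 30,
    planted_correlations = data.frame(
      id = c("planted_pos", "planted_neg"),
      topic = c("dietary_restriction", "disease_model"),
      scc = c(0.258, -0.2)),
    seed = seed)
  inputs <- file.path(outdir, "inputs")
  world <- simulate_world(cfg, inputs)
  pcfg <- pipeline_config(
    counts_dir = inputs,
    signatures_file = file.path(inputs, "signatures.tsv"),
    network_file = file.path(inputs, "network.tsv"),
    targets_file = file.path(inputs, "drug_targets.tsv"),
    outdir = file.path(outdir, "results"),
    n_perm = n_perm, seed = seed)
  manifest <- run_pipeline(pcfg)
  list(manifest = manifest, truth = world$truth, outdir = outdir)
}
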