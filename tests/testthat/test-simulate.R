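test_that("configuration errors name the offending field", {
  expect_error(simulation_config(deg_fraction = 1.2), "deg_fraction",
               class = "proxscreen_config_error")
  expect_error(simulation_config(n_genes = 0), "n_genes")
  expect_error(simulation_config(network_nodes = 10, n_genes = 5),
               "network_nodes")
  expect_error(simulation_config(planted_correlations =
    data.frame(id = "a", topic = "t", scc = 1.5)), "scc")
})

test_that("same config and seed give byte-identical outputs", {
  cfg <- simulation_config(n_tissues = 2, n_genes = 120, network_nodes = 60,
                           n_drugs = 4, targets_per_drug = 3, seed = 9)
  a <- simulate_counts(cfg)
  b <- simulate_counts(cfg)
  expect_identical(a$cm$counts, b$cm$counts)
  expect_identical(a$truth$planted_deg_sets, b$truth$planted_deg_sets)
  na <- simulate_network_and_drugs(cfg, a$truth)
  nb <- simulate_network_and_drugs(cfg, b$truth)
  expect_identical(igraph::as_edgelist(na$network$graph),
                   igraph::as_edgelist(nb$network$graph))
  expect_identical(na$targets, nb$targets)
})

test_that("components draw from independent streams of one global seed", {
  cfg1 <- simulation_config(n_tissues = 1, n_genes = 100, network_nodes = 50,
                            n_reference_signatures = 5, seed = 3)
  cfg2 <- simulation_config(n_tissues = 1, n_genes = 100, network_nodes = 50,
                            n_reference_signatures = 9, seed = 3)
  expect_identical(simulate_counts(cfg1)$cm$counts,
                   simulate_counts(cfg2)$cm$counts)
})

test_that("planted up/down sets are disjoint and live in the matrix", {
  sim <- toy_count_matrix(n_genes = 200, seed = 2, n_tissues = 2)
  for (t in names(sim$truth$planted_deg_sets)) {
    pl <- sim$truth$planted_deg_sets[[t]]
    expect_length(intersect(pl$up, pl$down), 0)
    expect_true(all(c(pl$up, pl$down) %in% rownames(sim$cm$counts)))
  }
})

test_that("deg_fraction = 0 gives a calibrated null world", {
  cfg <- simulation_config(n_tissues = 1, n_genes = 2000, deg_fraction = 0,
                           seed = 21)
  sim <- simulate_counts(cfg)
  expect_length(sim$truth$planted_deg_sets$aorta$up, 0)
  tab <- detect_degs(sim$cm, "aorta")
  frac <- mean(tab$p_value < 0.05)
  bound <- 2.576 * sqrt(0.05 * 0.95 / 2000)
  expect_gt(frac, 0.05 - bound)
  expect_lt(frac, 0.05 + bound)
})

test_that("strong planted DEGs are recovered with matching direction", {
  cfg <- simulation_config(n_tissues = 1, n_genes = 1000, deg_fraction = 0.05,
                           lfc_magnitude = 3, nb_dispersion = 0.02, seed = 8)
  sim <- simulate_counts(cfg)
  tab <- detect_degs(sim$cm, "aorta")
  pl <- sim$truth$planted_deg_sets$aorta
  up_dir <- tab$direction[match(pl$up, tab$gene)]
  down_dir <- tab$direction[match(pl$down, tab$gene)]
  expect_gte(mean(c(up_dir == "up", down_dir == "down")), 0.9)
  # recovered genes never carry the opposite direction
  expect_false(any(up_dir == "down"))
  expect_false(any(down_dir == "up"))
})

test_that("network generator contract: small graphs are connected and named", {
  cfg <- simulation_config(n_tissues = 1, n_genes = 50, network_nodes = 10,
                           network_attach_param = 2, n_drugs = 2,
                           targets_per_drug = 2, seed = 4)
  sim <- simulate_counts(cfg)
  nd <- simulate_network_and_drugs(cfg, sim$truth)
  g <- nd$network$graph
  expect_equal(igraph::vcount(g), 10)
  expect_equal(igraph::components(g, mode = "weak")$no, 1)
  expect_true(all(nd$targets$target %in% igraph::V(g)$name))
})

test_that("hop-0 planting makes targets a subset of DEGs (distance 0)", {
  cfg <- simulation_config(n_tissues = 1, n_genes = 300, network_nodes = 300,
                           deg_fraction = 0.2, n_drugs = 3,
                           targets_per_drug = 4,
                           planted_proximity_drugs =
                             data.frame(drug = "drug01", hop = 0L,
                                        tissue = "aorta"),
                           seed = 12)
  sim <- simulate_counts(cfg)
  nd <- simulate_network_and_drugs(cfg, sim$truth)
  planted <- toupper(unlist(sim$truth$planted_deg_sets$aorta))
  tg <- nd$targets$target[nd$targets$drug == "drug01"]
  expect_true(all(tg %in% planted))
  # every target sits at hop 0 from the DEG set
  pr <- drug_deg_proximity(nd$network, tg, planted)
  expect_equal(pr$dist, 0)
})

test_that("unreachable hop request is a simulation error", {
  cfg <- simulation_config(n_tissues = 1, n_genes = 300, network_nodes = 250,
                           deg_fraction = 0.01, n_drugs = 2,
                           targets_per_drug = 200,
                           planted_proximity_drugs =
                             data.frame(drug = "drug01", hop = 0L,
                                        tissue = "aorta"),
                           seed = 1)
  sim <- simulate_counts(cfg)
  expect_error(simulate_network_and_drugs(cfg, sim$truth),
               class = "proxscreen_sim_error")
})

test_that("planted signature SCCs are achieved within tolerance", {
  cfg <- simulation_config(n_tissues = 1, n_genes = 2000, seed = 5,
                           n_reference_signatures = 6,
                           planted_correlations = data.frame(
                             id = c("pos", "zero", "neg", "unit"),
                             topic = letters[1:4],
                             scc = c(0.4, 0, -0.6, 1)))
  sim <- simulate_counts(cfg)
  tsig <- build_signature_from_counts(sim$cm, "aorta")
  refs <- simulate_reference_signatures(cfg, tsig)
  ach <- vapply(refs[1:4], function(r) scc_oracle(r$values, tsig$values), 0)
  expect_lt(max(abs(ach - c(0.4, 0, -0.6, 1))), 0.05)
  # target 1 is an exact monotone transform
  expect_equal(ach[[4]], 1)
  # unplanted signatures are near-independent permutations
  ach0 <- vapply(refs[5:6], function(r) scc_oracle(r$values, tsig$values), 0)
  expect_lt(max(abs(ach0)), 0.1)
})

test_that("impossible target SCC is rejected", {
  cfg <- simulation_config(n_tissues = 1, n_genes = 100, network_nodes = 50,
                           seed = 1)
  cfg$planted_correlations <- data.frame(id = "x", topic = "t", scc = 2)
  sim <- toy_count_matrix(100, 1)
  tsig <- build_signature_from_counts(sim$cm, "aorta")
  expect_error(simulate_reference_signatures(cfg, tsig),
               class = "proxscreen_config_error")
})

test_that("simulate_world writes the documented file set", {
  cfg <- simulation_config(n_tissues = 1, n_genes = 80, network_nodes = 40,
                           n_drugs = 3, targets_per_drug = 3,
                           n_reference_signatures = 4, seed = 6)
  out <- tempfile("world")
  simulate_world(cfg, out)
  for (f in c("counts.tsv", "counts.mtx", "genes.txt", "samples.txt",
              "sample_annotations.tsv", "gene_lengths.tsv", "network.tsv",
              "network.graphml", "drug_targets.tsv", "signatures.tsv",
              "ground_truth.json"))
    expect_true(file.exists(file.path(out, f)), label = f)
  cm <- read_count_matrix(out)
  cm2 <- read_count_matrix(out, format = "mtx")
  expect_equal(cm$counts, cm2$counts)
})
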