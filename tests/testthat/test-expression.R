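test_that("FPKM matches the closed form and an independent recomputation", {
  # counts=10, length=1000 bp, total=1e6 -> FPKM 10
  counts <- matrix(c(10L, 999990L), 2, 1,
                   dimnames = list(c("g1", "g2"), "s1"))
  cm <- count_matrix(counts,
                     data.frame(sample = "s1", tissue = "t", group = "treated",
                                replicate = 1),
                     gene_lengths = c(g1 = 1000, g2 = 500))
  f <- fpkm_normalize(cm)
  expect_equal(f["g1", "s1"], 10)
  # zero count -> zero FPKM
  counts["g1", 1] <- 0L
  cm$counts <- counts
  expect_equal(fpkm_normalize(cm)["g1", "s1"], 0)

  # random 50 x 6 against a two-line oracle
  sim <- toy_count_matrix(50, seed = 31)
  f <- fpkm_normalize(sim$cm)
  oracle <- t(t(sim$cm$counts / as.numeric(sim$cm$gene_lengths)) /
                colSums(sim$cm$counts)) * 1e9
  expect_equal(f, oracle)
})

test_that("FPKM errors: missing lengths, zero-depth sample", {
  sim <- toy_count_matrix(10, seed = 1)
  cm <- sim$cm
  cm$gene_lengths <- NULL
  expect_error(fpkm_normalize(cm), "length")
  cm2 <- sim$cm
  cm2$counts[, 1] <- 0L
  expect_error(fpkm_normalize(cm2), "zero-depth")
})

test_that("FPKM invariants: zero iff zero, linear in a gene's counts", {
  sim <- toy_count_matrix(30, seed = 17)
  f <- fpkm_normalize(sim$cm)
  expect_identical(f == 0, sim$cm$counts == 0)
  # doubling one gene's counts at fixed totals doubles its FPKM
  cm2 <- sim$cm
  cm2$counts["g00003", ] <- 2L * cm2$counts["g00003", ]
  f2 <- sweep(cm2$counts, 1, as.numeric(cm2$gene_lengths), "/")
  f2 <- sweep(f2, 2, colSums(sim$cm$counts), "/") * 1e9  # totals held fixed
  expect_equal(f2["g00003", ], 2 * f["g00003", ])
})

test_that("identical treated/control columns give no DEGs", {
  set.seed(7)
  base <- matrix(rpois(60 * 3, 40), 60, 3)
  counts <- cbind(base, base)
  dimnames(counts) <- list(sprintf("g%02d", 1:60), paste0("s", 1:6))
  ann <- data.frame(sample = paste0("s", 1:6), tissue = "liver",
                    group = rep(c("treated", "control"), each = 3),
                    replicate = rep(1:3, 2))
  tab <- detect_degs(count_matrix(counts, ann), "liver", alpha = 0.999)
  expect_true(all(tab$log2fc == 0))
  expect_true(all(tab$direction == "ns"))
})

test_that("group-label swap flips log2fc and preserves p-values", {
  sim <- toy_count_matrix(120, seed = 13)
  t1 <- detect_degs(sim$cm, "aorta")
  cm2 <- sim$cm
  cm2$samples$group <- ifelse(cm2$samples$group == "treated",
                              "control", "treated")
  t2 <- detect_degs(cm2, "aorta")
  expect_equal(t1$log2fc, -t2$log2fc, tolerance = 1e-12)
  expect_equal(t1$p_value, t2$p_value, tolerance = 1e-12)
})

test_that("all-zero genes get p = 1 and log2fc = 0", {
  sim <- toy_count_matrix(40, seed = 3)
  cm <- sim$cm
  cm$counts[c("g00005", "g00009"), ] <- 0L
  tab <- detect_degs(cm, "aorta")
  expect_equal(tab$p_value[tab$gene %in% c("g00005", "g00009")], c(1, 1))
  expect_equal(tab$log2fc[tab$gene %in% c("g00005", "g00009")], c(0, 0))
})

test_that("detect_degs enforces the replicate precondition", {
  sim <- toy_count_matrix(20, seed = 2)
  cm <- subset_samples(sim$cm, c("aorta_control_1", "aorta_control_2",
                                 "aorta_control_3", "aorta_treated_1"))
  expect_error(detect_degs(cm, "aorta"), "replicates")
})

make_deg_table <- function(tissue, up = character(0), down = character(0),
                           universe = sprintf("G%d", 1:20)) {
  dir <- rep("ns", length(universe))
  dir[match(up, universe)] <- "up"
  dir[match(down, universe)] <- "down"
  structure(data.frame(gene = universe,
                       log2fc = (dir == "up") - (dir == "down"),
                       p_value = ifelse(dir == "ns", 0.5, 0.001),
                       direction = dir, stringsAsFactors = FALSE),
            class = c("deg_table", "data.frame"), tissue = tissue,
            alpha = 0.05)
}

test_that("summarize_degs matches exhaustive hand computation", {
  t1 <- make_deg_table("t1", up = c("G1", "G2"), down = "G3")
  t2 <- make_deg_table("t2", up = c("G1", "G2"), down = "G3")
  t3 <- make_deg_table("t3", up = "G3", down = c("G1", "G4"))
  s <- summarize_degs(list(t1, t2, t3))
  expect_equal(s$n_total_degs, 4)                 # G1 G2 G3 G4
  expect_equal(s$sharing, c(1L, 1L, 2L))          # G4:1, G2:2, G1,G3:3
  expect_equal(s$per_tissue$n_up, c(2L, 2L, 1L))
  expect_equal(s$per_tissue$n_down, c(1L, 1L, 2L))
  # identical signed vectors -> cosine 1
  expect_equal(s$cosine["t1", "t2"], 1)
  # hand computation for t1 vs t3: v1=(1,1,-1,0), v3=(-1,0,1,-1)
  expect_equal(s$cosine["t1", "t3"], -2 / (sqrt(3) * sqrt(3)))
  expect_true(isSymmetric(s$cosine))
  expect_equal(unname(diag(s$cosine)), rep(1, 3))
  # conservation: histogram total = union size
  expect_equal(sum(s$sharing), s$n_total_degs)
})

test_that("sign-flipped DEG vectors give cosine -1", {
  t1 <- make_deg_table("a", up = c("G1", "G5"), down = "G7")
  t2 <- make_deg_table("b", up = "G7", down = c("G1", "G5"))
  t3 <- make_deg_table("c", up = "G2")
  s <- summarize_degs(list(t1, t2, t3))
  expect_equal(s$cosine["a", "b"], -1)
  expect_equal(s$cosine["a", "c"], 0)
})

test_that("duplicate tissue ids are rejected", {
  t1 <- make_deg_table("x", up = "G1")
  expect_error(summarize_degs(list(t1, t1)), "duplicate")
})

test_that("tissue modules split by predominant DEG direction", {
  up1 <- make_deg_table("u1", up = c("G1", "G2", "G3"))
  up2 <- make_deg_table("u2", up = c("G1", "G2", "G4"))
  dn1 <- make_deg_table("d1", down = c("G1", "G2", "G3"))
  dn2 <- make_deg_table("d2", down = c("G1", "G2", "G4"))
  mid <- make_deg_table("m1", up = "G9", down = "G10")
  s <- summarize_degs(list(up1, up2, dn1, dn2, mid))
  expect_equal(unname(s$modules[c("u1", "u2")]), rep("Mod_up", 2))
  expect_equal(unname(s$modules[c("d1", "d2")]), rep("Mod_down", 2))
  expect_equal(unname(s$modules["m1"]), "Mod_inbetween")
})

test_that("duplicated samples merge first at zero height", {
  sim <- toy_count_matrix(40, seed = 23)
  f <- fpkm_normalize(sim$cm)
  f2 <- cbind(f, dup = f[, 1])
  colnames(f2)[ncol(f2)] <- "dup_of_1"
  cl <- cluster_profiles(f2)
  expect_equal(min(cl$hclust$height), 0)
  first_merge <- cl$hclust$merge[which.min(cl$hclust$height), ]
  merged <- cl$hclust$labels[-first_merge]
  expect_setequal(merged, c(colnames(f)[1], "dup_of_1"))
})

test_that("PCA scores match a brute-force eigendecomposition", {
  set.seed(11)
  m <- matrix(rexp(4 * 5, 0.1), 4, 5,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:5)))
  cl <- cluster_profiles(m, n_pcs = 3)
  lg <- log2(m + 1)
  x <- t(lg - rowMeans(lg))                    # samples x genes, centred
  cov <- crossprod(x) / 1                      # unnormalized; eigvecs same
  ev <- eigen(cov)
  for (j in 1:3) {
    ref <- as.vector(x %*% ev$vectors[, j])
    expect_equal(abs(stats::cor(cl$pca$scores[, j], ref)), 1,
                 tolerance = 1e-8)
  }
})

test_that("well-separated simulated tissues split on PC1", {
  sim <- toy_count_matrix(300, seed = 19, n_tissues = 2)
  f <- fpkm_normalize(sim$cm)
  cl <- cluster_profiles(f)
  tissue <- sim$cm$samples$tissue
  pc1 <- cl$pca$scores[, 1]
  # silhouette on one dimension, two groups
  sil <- vapply(seq_along(pc1), function(i) {
    own <- mean(abs(pc1[i] - pc1[tissue == tissue[i]][-
      which(which(tissue == tissue[i]) == i)]))
    oth <- mean(abs(pc1[i] - pc1[tissue != tissue[i]]))
    (oth - own) / max(own, oth)
  }, 0)
  expect_gt(mean(sil), 0.5)
})

test_that("constant matrix is flagged as degenerate", {
  m <- matrix(3, 5, 4, dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
  expect_error(cluster_profiles(m), "degenerate")
})

test_that("centrality: ring symmetry and path maximum", {
  ring <- ring_net(8)
  cc <- compare_centrality(ring, c("N1", "N2"))
  expect_equal(cc$node_metrics$pagerank, rep(1 / 8, 8), tolerance = 1e-6)
  expect_lt(diff(range(cc$node_metrics$betweenness)), 1e-9)

  pth <- path_net(3)  # A-B-C: B is the unique betweenness maximum
  cb <- compare_centrality(pth, "A")$node_metrics
  expect_equal(cb$node[which.max(cb$betweenness)], "B")
})

test_that("betweenness matches brute-force shortest-path enumeration", {
  net <- random_net(12, 0.3, seed = 44)
  g <- net$graph
  nodes <- igraph::V(g)$name
  # oracle: count geodesics through each interior node
  dist <- sapply(nodes, function(v) bfs_oracle(net, v))  # dist[to, from]
  paths_through <- stats::setNames(numeric(length(nodes)), nodes)
  n_geo <- function(s, t) {
    # number of shortest s->t paths by DP over BFS layers
    if (is.infinite(dist[t, s])) return(0)
    cnt <- stats::setNames(numeric(length(nodes)), nodes)
    cnt[s] <- 1
    ord <- nodes[order(dist[, s])]
    for (v in ord) {
      if (v == s || is.infinite(dist[v, s])) next
      pre <- nodes[dist[, s] == dist[v, s] - 1]
      pre <- pre[vapply(pre, function(p)
        v %in% names(igraph::neighbors(g, p, mode = "all")), TRUE)]
      cnt[v] <- sum(cnt[pre])
    }
    cnt[t]
  }
  btw_oracle <- stats::setNames(numeric(length(nodes)), nodes)
  for (s in nodes) for (t in nodes) {
    if (s >= t || is.infinite(dist[t, s])) next
    tot <- n_geo(s, t)
    for (v in setdiff(nodes, c(s, t))) {
      if (is.finite(dist[v, s]) && is.finite(dist[t, v]) &&
          dist[v, s] + dist[t, v] == dist[t, s]) {
        btw_oracle[v] <- btw_oracle[v] + n_geo(s, v) * n_geo(v, t) / tot
      }
    }
  }
  cc <- compare_centrality(net, nodes[1:3])
  expect_equal(stats::setNames(cc$node_metrics$betweenness,
                               cc$node_metrics$node),
               btw_oracle, tolerance = 1e-9)
})

test_that("compare_centrality requires a mapped DEG", {
  expect_error(compare_centrality(path_net(4), "ZZZ"), "no DEG")
})
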