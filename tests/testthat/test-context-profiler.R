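mk_genes <- function(n, genome_id = "g", labels = NULL) {
  tibble::tibble(
    gene_id = sprintf("%s_%02d", genome_id, seq_len(n)),
    genome_id = genome_id,
    start = as.integer((seq_len(n) - 1) * 100),
    end = as.integer((seq_len(n) - 1) * 100 + 90),
    strand = "+",
    product_label = if (is.null(labels)) rep("", n) else labels
  )
}

test_that("extract_neighborhood windows, truncation, and invariants", {
  genes <- mk_genes(30)
  nb <- extract_neighborhood(genes, "g_15", radius = 10)
  expect_equal(nrow(nb), 21L)
  expect_equal(nb$rel_pos, -10:10)
  expect_false(attr(nb, "truncated_left"))

  nb2 <- extract_neighborhood(mk_genes(5), "g_01", radius = 10)
  expect_equal(nb2$rel_pos, 0:4)   # truncated at the scaffold start
  expect_true(attr(nb2, "truncated_left"))
  expect_false(attr(nb2, "truncated_right") == FALSE)

  expect_error(extract_neighborhood(genes, "nope"), "not found")
  # |neighbors| <= 2 radius + 1, contiguous when untruncated
  for (r in c(1, 3, 7)) {
    nbr <- extract_neighborhood(genes, "g_15", radius = r)
    expect_lte(nrow(nbr), 2 * r + 1)
    expect_equal(nbr$rel_pos, min(nbr$rel_pos):max(nbr$rel_pos))
  }
})

test_that("reorientation makes mirrored genomes give identical profiles", {
  labels <- rep("hypothetical protein", 21)
  labels[11] <- "ribosomal protein S21"
  labels[14] <- "major capsid protein"
  labels[8] <- "terminase large subunit"
  genes <- mk_genes(21, "fwd", labels)
  L <- 2100L
  mirrored <- genes
  mirrored$genome_id <- "mir"
  mirrored$gene_id <- sub("fwd", "mir", rev(genes$gene_id))
  mirrored$start <- L - rev(genes$end)
  mirrored$end <- L - rev(genes$start)
  mirrored$strand <- "-"
  mirrored$product_label <- rev(genes$product_label)

  nb_f <- extract_neighborhood(genes, "fwd_11", reorient = TRUE)
  nb_m <- extract_neighborhood(mirrored, "mir_11", reorient = TRUE)
  expect_equal(nb_f$product_label[order(nb_f$rel_pos)],
               nb_m$product_label[order(nb_m$rel_pos)])
  expect_equal(nb_f$rel_pos[nb_f$product_label == "major capsid protein"],
               nb_m$rel_pos[nb_m$product_label == "major capsid protein"])
})

test_that("cluster_families groups identical, splits unrelated, is order-canonical", {
  withr::local_seed(5)
  aa <- function(n) paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                                 n, replace = TRUE), collapse = "")
  p_same <- aa(150)
  unrelated <- tibble::tibble(protein_id = c("u1", "u2"),
                              sequence = c(aa(200), aa(200)))
  fams_u <- cluster_families(unrelated)
  expect_equal(dplyr::n_distinct(tidy(fams_u)$family_id), 2L)

  twins <- tibble::tibble(protein_id = c("t1", "t2"),
                          sequence = c(p_same, p_same))
  fams_t <- cluster_families(twins)
  expect_equal(dplyr::n_distinct(tidy(fams_t)$family_id), 1L)

  # permutation invariance of the partition
  pool <- tibble::tibble(
    protein_id = sprintf("p%02d", 1:8),
    sequence = c(p_same, p_same, aa(180), aa(120), aa(120),
                 substr(p_same, 1, 140), aa(90), aa(250)))
  part <- function(x) {
    m <- tidy(x)
    unname(split(sort(m$protein_id), m$family_id[order(m$protein_id)]))
  }
  f1 <- cluster_families(pool)
  f2 <- cluster_families(pool[sample(nrow(pool)), ])
  expect_setequal(part(f1), part(f2))
  # every non-centroid member satisfies the identity/coverage contract
  m <- tidy(f1)
  nc <- m[!m$is_centroid, ]
  if (nrow(nc)) {
    expect_true(all(nc$identity >= 0.30))
    expect_true(all(nc$coverage_min >= 0.75))
  }
})

test_that("consensus_annotation implements the 5%-of-members rule with ties", {
  hits <- tibble::tibble(
    protein_id = c("m1", "m2", "m3"),
    label = c("A", "A", "B"),
    e_value = c(1e-10, 1e-8, 1e-9))
  members20 <- sprintf("m%d", 1:20)
  expect_equal(consensus_annotation(members20, hits), "A")  # 2/20 = 10% >= 5%
  members40 <- sprintf("m%d", 1:40)
  hits1 <- hits[3, ]
  expect_equal(consensus_annotation(members40, hits1), "hyp")  # 1/40 = 2.5%
  expect_equal(consensus_annotation(members20, hits[0, ]), "hyp")
  # tie on counts resolves lexicographically
  tie <- tibble::tibble(protein_id = c("m1", "m2"), label = c("B", "A"),
                        e_value = 1e-9)
  expect_equal(consensus_annotation(sprintf("m%d", 1:10), tie), "A")
  # hits at or above e_max are ignored
  weak <- tibble::tibble(protein_id = "m1", label = "A", e_value = 1e-5)
  expect_equal(consensus_annotation(sprintf("m%d", 1:2), weak), "hyp")
  expect_error(consensus_annotation("m1", tibble::tibble(
    protein_id = "m1", label = "A", e_value = 0)), "e_value")
})

test_that("consensus_annotation equals the brute-force rule on random tables", {
  withr::local_seed(6)
  for (i in 1:100) {
    n <- sample(1:40, 1)
    members <- sprintf("m%03d", seq_len(n))
    k <- sample(0:30, 1)
    hits <- tibble::tibble(
      protein_id = sample(sprintf("m%03d", 1:50), k, replace = TRUE),
      label = sample(LETTERS[1:5], k, replace = TRUE),
      e_value = 10^runif(k, -12, -2))
    expect_equal(consensus_annotation(members, hits),
                 oracle_consensus(members, hits))
  }
})

test_that("position_profile counts genomes, not genes, and validates input", {
  nb <- tibble::tibble(
    anchor_gene_id = rep(c("a1", "b1"), each = 3),
    genome_id = rep(c("gA", "gB"), each = 3),
    gene_id = c("a0", "a1", "a2", "b0", "b1", "b2"),
    rel_pos = rep(c(-1L, 0L, 1L), 2),
    same_strand_as_anchor = TRUE,
    product_label = "")
  asg <- tibble::tibble(gene_id = c("a0", "a1", "a2", "b0", "b1", "b2"),
                        family_id = c("f1", "f0", "f2", "f1", "f0", "f2"))
  prof <- position_profile(nb, asg)
  expect_equal(prof$counts$n_genomes[prof$counts$family_id == "f0"], 2L)
  expect_true(all(prof$counts$n_genomes <= 2))
  expect_equal(prof$distances$mean_abs_distance[
    prof$distances$family_id == "f1"], 1)
  expect_equal(glance(prof)$n_neighborhoods, 2L)

  expect_error(position_profile(nb, asg[-1, ]), "a0")
  empty <- position_profile(nb[0, ], asg)
  expect_equal(nrow(tidy(empty)), 0L)
})

test_that("presence/absence clustering: distances, size filter, shared core", {
  genomes <- make_genome(c("g1", "g2", "g3"),
                         c(strrep("A", 1000), strrep("A", 1000),
                           strrep("A", 50)))
  gf <- tibble::tibble(
    genome_id = c("g1", "g1", "g2", "g2", "g3"),
    family_id = c("f1", "f2", "f1", "f2", "f1"))
  pa <- presence_absence_clustering(genomes, gf, min_genome_bp = 100)
  expect_equal(rownames(pa$matrix), c("g1", "g2"))  # g3 filtered out
  expect_equal(as.numeric(pa$jaccard), 0)           # identical family sets
  expect_equal(pa$shared_family_count, 2L)
  expect_match(pa$newick, "g1")
  expect_error(presence_absence_clustering(genomes, gf,
                                           min_genome_bp = 2000), "fewer")
})

test_that("planted clades are recovered from presence/absence at ARI 1", {
  spec <- synth_spec(seed = 41, n_genomes = 6, n_clades = 3,
                     genome_length = 20000)
  sim <- simulate_phage_genomes(spec)
  prots <- tibble::tibble(protein_id = sim$genes$gene_id,
                          sequence = sim$genes$protein)
  fams <- cluster_families(prots)
  gf <- dplyr::left_join(tidy(fams),
                         sim$genes[, c("gene_id", "genome_id")],
                         by = c(protein_id = "gene_id"))
  pa <- presence_absence_clustering(sim$genomes, gf, min_genome_bp = 0)
  cl <- tidy(pa, k = 3)
  truth <- dplyr::distinct(sim$truth, genome_id, clade)
  m <- dplyr::left_join(cl, truth, by = "genome_id")
  expect_equal(adjusted_rand_index(m$cluster, m$clade), 1)
})
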