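spec_small <- function(seed = 1, ...) {
  synth_spec(seed = seed, n_genomes = 2L, n_clades = 1L,
             genome_length = 20000L, ...)
}

test_that("generators are byte-deterministic under a fixed seed", {
  spec <- spec_small(seed = 9)
  s1 <- simulate_phage_genomes(spec)
  s2 <- simulate_phage_genomes(spec)
  expect_identical(s1, s2)
  f1 <- withr::local_tempfile(fileext = ".fasta")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(s1$genomes, f1)
  write_fasta(s2$genomes, f2)
  expect_identical(readLines(f1), readLines(f2))
  h1 <- simulate_host_with_crispr(s1$genomes, 2, c(0L, 1L), spec)
  h2 <- simulate_host_with_crispr(s2$genomes, 2, c(0L, 1L), spec)
  expect_identical(h1, h2)
})

test_that("planted module: anchor on the reverse strand relative to its neighbors", {
  sim <- simulate_phage_genomes(spec_small(seed = 3))
  genes <- dplyr::left_join(sim$genes, sim$truth,
                            by = c("gene_id", "genome_id"))
  for (g in unique(genes$genome_id)) {
    gg <- genes[genes$genome_id == g, ]
    anchor <- gg[gg$role == "bS21", ]
    mcp <- gg[gg$role == "MCP", ]
    flank <- gg[gg$role %in% c("hyp_flank_up", "hyp_flank_down"), ]
    expect_equal(nrow(anchor), 1L)
    expect_true(all(anchor$strand != mcp$strand))
    expect_true(all(anchor$strand != flank$strand))
    # structural roles within 5 genes of the anchor
    struct <- gg[gg$role %in% c("TerL", "portal", "prohead_protease", "MCP"), ]
    expect_true(all(abs(struct$rel_pos) <= 5))
    expect_setequal(flank$rel_pos, c(-1L, 1L))
  }
})

test_that("clade siblings sit at the expected nucleotide identity", {
  # both siblings mutated independently from the founder at d per site:
  # E[identity] = (1-d)^2 + d^2/3 = 0.9601 at d = 0.02
  spec <- spec_small(seed = 11)
  base <- generate_phage_genome(spec)
  sib1 <- generate_phage_genome(spec_small(seed = 21), clade_seed = base,
                                genome_id = "sib1")
  sib2 <- generate_phage_genome(spec_small(seed = 22), clade_seed = base,
                                genome_id = "sib2")
  a <- strsplit(sib1$genome$sequence, "")[[1]]
  b <- strsplit(sib2$genome$sequence, "")[[1]]
  expect_equal(mean(a == b), (1 - 0.02)^2 + 0.02^2 / 3, tolerance = 0.01)
  # genes and ground truth stay locatable in the sibling
  expect_equal(sib1$genes$start, base$genes$start)
  expect_equal(sib1$truth$role, base$truth$role)
})

test_that("emitted FASTA/GFF/SAM are re-parseable with zero loss of linkage", {
  spec <- spec_small(seed = 5)
  sim <- simulate_phage_genomes(spec)
  dir <- withr::local_tempdir()
  write_fasta(sim$genomes, file.path(dir, "g.fasta"))
  write_gene_gff(sim$genes, file.path(dir, "g.gff3"))
  genomes <- read_genome_fasta(file.path(dir, "g.fasta"), circular = TRUE)
  expect_equal(genomes$sequence, sim$genomes$sequence)
  genes <- read_gene_gff(file.path(dir, "g.gff3"), genomes)
  expect_equal(genes$gene_id, sim$genes$gene_id)
  expect_equal(genes$start, sim$genes$start)
  expect_true(all(sim$truth$gene_id %in% genes$gene_id))
  aln <- simulate_alignments(sim$genomes[1, ], spec = spec)
  write_sam(aln, sim$genomes, file.path(dir, "a.sam"))
  back <- read_sam(file.path(dir, "a.sam"))
  expect_equal(sum(vapply(back$blocks, function(m) sum(m[, 2] - m[, 1]), 0)),
               sum(vapply(aln$blocks, function(m) sum(m[, 2] - m[, 1]), 0)))
})

test_that("planted spacers carry exactly the requested mismatch counts", {
  spec <- spec_small(seed = 13)
  sim <- simulate_phage_genomes(spec)
  host <- simulate_host_with_crispr(sim$genomes, 4, c(0L, 1L, 2L, 5L), spec)
  tr <- host$truth
  for (i in seq_len(nrow(tr))) {
    proto <- substr(sim$genomes$sequence[sim$genomes$genome_id == tr$phage_id[i]],
                    tr$phage_start[i] + 1, tr$phage_start[i] + tr$length[i])
    sp <- if (tr$strand[i] == "+") tr$sequence[i] else rev_comp(tr$sequence[i])
    expect_equal(phagecontext:::hamming(sp, proto), tr$mismatches[i])
  }
  # the array is present verbatim in the host sequence
  expect_equal(substr(host$host$sequence, tr$host_start[1] + 1,
                      tr$host_start[1] + tr$length[1]), tr$sequence[1])
})

test_that("DNA alignments: depth-20 breadth is near-complete, error 0 means 0 mismatches", {
  spec <- synth_spec(seed = 17, n_genomes = 1, n_clades = 1,
                     genome_length = 30000, depth = 20, error_rate = 0)
  sim <- simulate_phage_genomes(spec)
  aln <- simulate_alignments(sim$genomes[1, ], spec = spec)
  expect_true(all(aln$mismatches == 0))
  # coupon-collector style bound: P(any position uncovered) <= L * e^-depth
  cov <- genome_coverage(aln, sim$genomes[1, ], min_identity = 0)
  expect_gte(cov$breadth, 0.999)
  expect_equal(nrow(aln), spec$depth * 30000 / spec$read_length,
               tolerance = 0.1)
})

test_that("RNA alignments follow expression weights and stay inside genes", {
  spec <- synth_spec(seed = 19, n_genomes = 1, n_clades = 1,
                     genome_length = 25000, depth = 30)
  sim <- simulate_phage_genomes(spec)
  g <- sim$genomes[1, ]
  genes <- sim$genes
  # two same-length background genes, one upweighted 10x
  bg <- dplyr::inner_join(genes, sim$truth[, c("gene_id", "category")],
                          by = "gene_id")
  bg <- bg[bg$category %in% c("core_bg", "accessory", "singleton"), ]
  len <- bg$end - bg$start
  pick <- bg$gene_id[order(len)][1:2]
  w <- setNames(rep(1, nrow(genes)), genes$gene_id)
  w[pick[2]] <- 10
  len1 <- genes$end[genes$gene_id == pick[1]] - genes$start[genes$gene_id == pick[1]]
  len2 <- genes$end[genes$gene_id == pick[2]] - genes$start[genes$gene_id == pick[2]]
  aln <- simulate_alignments(g, genes, spec = spec, rna = TRUE, weights = w,
                             depth = 60)
  # reads wholly inside their source gene
  gene_ir <- IRanges::IRanges(genes$start + 1, genes$end)
  read_ir <- IRanges::IRanges(aln$target_start + 1,
                              aln$target_start + aln$read_length)
  ov <- IRanges::countOverlaps(read_ir, gene_ir, type = "within")
  expect_true(all(ov >= 1))
  # Poisson thinning: 10x weight ~ 10x reads per base, within 3 SD
  n1 <- sum(aln$target_start >= genes$start[genes$gene_id == pick[1]] &
              aln$target_start < genes$end[genes$gene_id == pick[1]])
  n2 <- sum(aln$target_start >= genes$start[genes$gene_id == pick[2]] &
              aln$target_start < genes$end[genes$gene_id == pick[2]])
  expected2 <- n1 * 10 * (len2 / len1)
  expect_lt(abs(n2 - expected2), 3 * sqrt(expected2) + 3 * sqrt(n1) * 10)
})

test_that("group-MSA generator plants exactly what it reports", {
  g <- simulate_group_msa(10, 12, 50, c(5L, 25L), aromatic_column = 40L,
                          seed = 23)
  m <- do.call(rbind, strsplit(g$msa$aligned, ""))
  expect_true(all(m[, 41] %in% c("Y", "H", "F")))
  expect_equal(unname(attr(table(m[, 41]), "dimnames")[[1]][
    which.max(table(m[, 41]))]), "Y")
  for (col in c(5L, 25L)) {
    pa <- m[g$msa$group == "phage", col + 1]
    ba <- m[g$msa$group == "bacterial", col + 1]
    modal <- function(x) names(sort(table(x), decreasing = TRUE))[1]
    expect_true(modal(pa) != modal(ba))
    expect_gte(mean(pa == modal(pa)), 0.9)
    expect_gte(mean(ba == modal(ba)), 0.9)
  }
  expect_error(simulate_group_msa(5, 5, 50, c(5L), aromatic_column = 5L,
                                  seed = 1), "overlap")
  expect_error(simulate_group_msa(5, 5, 50, c(60L), seed = 1), "within|\\[0")
})

test_that("realized GC and coding density track the spec targets", {
  for (s in c(31, 32)) {
    spec <- synth_spec(seed = s, n_genomes = 3, n_clades = 3,
                       genome_length = 25000)
    sim <- simulate_phage_genomes(spec)
    expect_true(all(abs(gc_content(sim$genomes$sequence) -
                          100 * spec$gc_target) <= 2))
    summ <- summarize_genomes(sim$genomes, sim$genes)
    expect_true(all(abs(summ$coding_density_percent -
                          100 * spec$coding_density_target) <= 3))
  }
})

test_that("generator input validation", {
  expect_error(synth_spec(seed = 1, gc_target = 1.2), "gc_target")
  expect_error(synth_spec(seed = 1, depth = 0), "depth")
  expect_error(synth_spec(), "seed")
  spec <- synth_spec(seed = 1, n_genomes = 1, n_clades = 1,
                     genome_length = 2000)
  expect_error(simulate_phage_genomes(spec), "too small")
  tiny <- make_genome("p", "ACGT")
  expect_error(simulate_host_with_crispr(tiny, 1, c(0L), spec_small()),
               "too short")
  expect_error(simulate_host_with_crispr(tiny, 2, c(0L), spec_small()),
               "n_spacers")
})
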