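test_that("genome_coverage definitions and the identity filter", {
  g <- make_genome("g", random_dna_str(1000, 0.5))
  one <- make_aln("g", 100, 100)
  cov <- genome_coverage(one, g)
  expect_equal(cov$breadth, 0.10)
  expect_equal(cov$coverage, 1.0)
  expect_false(cov$detected)

  # reads tiling 95% once -> breadth 0.95, detected
  tile <- make_aln("g", seq(0, 900, by = 100), c(rep(100, 9), 50))
  cov2 <- genome_coverage(tile, g)
  expect_equal(cov2$breadth, 0.95)
  expect_true(cov2$detected)

  # 5 mismatches over 100 bp is 95% identity: excluded at the 97% filter
  low <- make_aln("g", c(0, 200), c(100, 100), mismatches = c(5L, 0L))
  cov3 <- genome_coverage(low, g, min_identity = 0.97)
  expect_equal(cov3$n_reads_mapped, 1L)
  expect_equal(cov3$breadth, 0.10)

  # zero passing reads
  cov4 <- genome_coverage(low[0, ], g)
  expect_equal(cov4$breadth, 0)
  expect_equal(cov4$coverage, 0)
  expect_false(cov4$detected)
})

test_that("breadth equals the per-position boolean oracle; detection is monotone", {
  withr::local_seed(11)
  g <- make_genome("g", random_dna_str(2000, 0.5))
  prev_breadth <- 0
  aln_all <- make_aln("g", integer(0), integer(0))
  for (i in 1:10) {
    n <- sample(5:40, 1)
    starts <- sample(0:1900, n, replace = TRUE)
    lens <- pmin(sample(20:100, n, replace = TRUE), 2000 - starts)
    aln <- make_aln("g", starts, lens)
    cov <- genome_coverage(aln, g, min_identity = 0)
    expect_equal(cov$breadth, mean(oracle_position_flags(aln, 2000)))
    # nested alignment sets: breadth(A) <= breadth(A u B)
    aln_all <- dplyr::bind_rows(aln_all, aln)
    b <- genome_coverage(aln_all, g, min_identity = 0)$breadth
    expect_gte(b, prev_breadth)
    prev_breadth <- b
  }
})

test_that("gene NTL formula, gates, and invariances", {
  g <- make_genome("g", random_dna_str(1000, 0.5))
  genes <- tibble::tibble(gene_id = "gene1", genome_id = "g", start = 100L,
                          end = 200L, strand = "+")
  inside <- make_aln("g", rep(100, 10), rep(100, 10), is_rna = TRUE)
  outside <- make_aln("g", rep(500, 490), rep(100, 490), is_rna = TRUE)
  outside$read_id <- sprintf("o%04d", 1:490)
  aln <- dplyr::bind_rows(inside, outside)
  act <- gene_ntl(aln, genes, g)
  expect_equal(act$total_base_gene, 1000L)
  expect_equal(act$total_read_genome, 500L)
  expect_equal(act$ntl, 1000 / 100 / 500)  # = 0.02

  # duplication of every record leaves NTL unchanged
  act2 <- gene_ntl(dplyr::bind_rows(aln, aln), genes, g)
  expect_equal(act2$ntl, act$ntl)

  # adding reads outside the gene strictly decreases its NTL
  act3 <- gene_ntl(dplyr::bind_rows(aln, outside[1:10, ]), genes, g)
  expect_lt(act3$ntl, act$ntl)

  # below the 80% covered-fraction gate: NA
  partial <- make_aln("g", 100, 70, is_rna = TRUE)  # 70% of the gene
  act4 <- gene_ntl(dplyr::bind_rows(partial, outside), genes, g)
  expect_equal(act4$covered_fraction, 0.7)
  expect_true(is.na(act4$ntl))

  # no passing reads at all: warned, all NA
  expect_warning(act5 <- gene_ntl(aln[0, ], genes, g), "no passing")
  expect_true(is.na(act5$ntl))

  # reads only partially overlapping a gene contribute overlapping bases
  straddle <- make_aln("g", 150, 100, is_rna = TRUE)  # 50 bases inside
  act6 <- gene_ntl(dplyr::bind_rows(inside, straddle), genes, g)
  expect_equal(act6$total_base_gene, 1050L)
})

test_that("sum over genes of ntl*len*reads never exceeds mapped RNA bases", {
  withr::local_seed(12)
  g <- make_genome("g", random_dna_str(3000, 0.5))
  genes <- tibble::tibble(
    gene_id = sprintf("g%d", 1:5), genome_id = "g",
    start = as.integer(seq(0, 2400, by = 600)),
    end = as.integer(seq(0, 2400, by = 600) + 500), strand = "+")
  n <- 200
  starts <- sample(0:2900, n, replace = TRUE)
  lens <- pmin(100L, 3000L - starts)
  aln <- make_aln("g", starts, lens, is_rna = TRUE)
  act <- gene_ntl(aln, genes, g, min_covered = 0)
  lhs <- sum(act$ntl * act$length_gene * act$total_read_genome, na.rm = TRUE)
  total_bases <- sum(vapply(aln$blocks, function(m) sum(m[, 2] - m[, 1]), 0))
  expect_lte(lhs, total_bases + 1e-9)
})

test_that("percent of mapped RNA reads per genome", {
  aln <- make_aln("p1", rep(0, 50), rep(100, 50), is_rna = TRUE)
  out <- percent_rna_mapped(aln, 10000)
  expect_equal(out$percent_mapped, 0.5)
  expect_equal(nrow(percent_rna_mapped(aln[0, ], 10)), 0L)
  expect_error(percent_rna_mapped(aln, 0), "> 0")
  # two genomes sharing reads: each counts its own records
  shared <- dplyr::bind_rows(aln, dplyr::mutate(aln, target_id = "p2"))
  out2 <- percent_rna_mapped(shared, 10000)
  expect_equal(out2$percent_mapped, c(0.5, 0.5))
})

test_that("rpS3 profiling: dereplication, coverage definition, ratio recovery", {
  withr::local_seed(13)
  m1 <- random_dna_str(300, 0.5)
  markers <- tibble::tibble(
    marker_id = c("a", "b", "c"),
    sequence = c(m1, m1, random_dna_str(400, 0.5)),
    taxon = c("Flavobacteriia", "Flavobacteriia", "Cytophagia"))
  derep <- phagecontext:::dereplicate_markers(markers)
  expect_equal(sum(derep$marker_id == derep$representative_id), 2L)

  aln <- make_aln("a", c(0, 100), c(300, 300))
  prof <- rps3_profile(markers[c(1, 3), ], aln)
  expect_equal(prof$coverage[prof$taxon == "Flavobacteriia"], 2.0)

  expect_error(rps3_profile(markers[0, ], aln), "length filter|no marker")
  # markers under 300 nt are dropped
  short <- tibble::tibble(marker_id = "s", sequence = random_dna_str(200, 0.5),
                          taxon = "X")
  expect_error(rps3_profile(short, aln), "no marker")

  # planted 5:3:1 class abundances (30x mean depth) recovered within 20%
  taxa <- c("Flavobacteriia", "Cytophagia", "Saprospiria")
  weights <- c(5, 3, 1)
  depth <- 30 * weights / mean(weights)
  mk <- tibble::tibble(
    marker_id = sprintf("rp%d", 1:3),
    sequence = replicate(3, random_dna_str(1000, 0.45)),
    taxon = taxa)
  reads <- purrr::map_dfr(1:3, function(i) {
    n <- stats::rpois(1, depth[i] * 1000 / 150)
    starts <- sample(0:(1000 - 150), n, replace = TRUE)
    a <- make_aln(mk$marker_id[i], starts, rep(150, n))
    a$read_id <- sprintf("%s_%04d", mk$marker_id[i], seq_len(n))
    a
  })
  prof2 <- rps3_profile(mk, reads)
  got <- setNames(prof2$coverage, prof2$taxon)[taxa]
  ratio <- got / got[1] * 5
  expect_true(all(abs(ratio - weights) / weights <= 0.2))
})

test_that("per-position depth track matches a direct count", {
  g <- make_genome("g", random_dna_str(50, 0.5))
  aln <- make_aln("g", c(0, 10, 10), c(20, 20, 30))
  d <- position_depth(aln, g, min_identity = 0)
  expect_equal(nrow(d), 50L)
  expect_equal(d$depth[1], 1L)
  expect_equal(d$depth[11], 3L)
  expect_equal(d$depth[45], 0L)
})
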