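# Codon-level machinery. Random proteins are drawn by sampling non-stop
# codons from a GC-biased base distribution and translating, so that amino
# acid composition stays consistent with the genome's GC target and
# reverse-translation can hit that target (AT-rich codon usage is how real
# low-GC genomes look).

codon_usage_table <- function(gc) {
  code <- Biostrings::GENETIC_CODE
  codons <- names(code)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  base_mat <- do.call(rbind, strsplit(codons, ""))
  w <- p[base_mat[, 1]] * p[base_mat[, 2]] * p[base_mat[, 3]]
  tibble(codon = codons, aa = unname(code), weight = unname(w))
}

.codon_cache <- new.env(parent = emptyenv())

codon_usage <- function(gc) {
  key <- sprintf("%.6f", gc)
  if (is.null(.codon_cache[[key]])) .codon_cache[[key]] <- codon_usage_table(gc)
  .codon_cache[[key]]
}

# Expected GC fraction of a codon drawn from the non-stop codon distribution
# parameterised by base-level GC `g`.
expected_codon_gc <- function(g) {
  cu <- codon_usage_table(g)
  cu <- cu[cu$aa != "*", ]
  gc_n <- stringr::str_count(cu$codon, "[GC]")
  sum(cu$weight * gc_n / 3) / sum(cu$weight)
}

# Base-level GC to feed the codon sampler (and intergenic DNA) so that the
# realized genome GC, after stop-codon exclusion and whole-genome mutation at
# rate d (substitution to a uniform different base), centers on gc_target.
calibrate_codon_gc <- function(gc_target, d) {
  # invert the mutation drift: E[gc'] = gc0 (1 - 4d/3) + 2d/3
  gc0 <- (gc_target - 2 * d / 3) / (1 - 4 * d / 3)
  f <- function(g) expected_codon_gc(g) - gc0
  stats::uniroot(f, c(0.02, 0.98), tol = 1e-6)$root
}

random_protein <- function(n_aa, gc) {
  cu <- codon_usage(gc)
  cu <- cu[cu$aa != "*", ]
  idx <- sample.int(nrow(cu), n_aa, replace = TRUE, prob = cu$weight)
  paste(cu$aa[idx], collapse = "")
}

reverse_translate <- function(protein, gc) {
  cu <- codon_usage(gc)
  aa <- strsplit(paste0(protein, "*"), "")[[1]]
  codons <- vapply(aa, function(a) {
    ch <- cu[cu$aa == a, ]
    if (nrow(ch) == 0) abort(paste0("cannot reverse-translate residue ", a))
    ch$codon[sample.int(nrow(ch), 1, prob = ch$weight)]
  }, character(1), USE.NAMES = FALSE)
  paste(codons, collapse = "")
}

AA20 <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")

mutate_protein <- function(protein, rate) {
  if (rate <= 0) return(protein)
  chars <- strsplit(protein, "")[[1]]
  hit <- which(runif(length(chars)) < rate)
  if (length(hit)) {
    chars[hit] <- vapply(chars[hit], function(a) sample(setdiff(AA20, a), 1L),
                         character(1), USE.NAMES = FALSE)
  }
  paste(chars, collapse = "")
}

# The conserved module around the anchor: bS21 on the reverse strand between
# two hypothetical-protein families, with TerL/portal/prohead-protease/MCP
# within five genes on either side.
module_architecture <- function() {
  tibble(
    slot = c("mod_m5", "mod_m4", "mod_m3", "mod_m2", "mod_m1",
             "mod_0", "mod_p1", "mod_p2", "mod_p3", "mod_p4", "mod_p5"),
    role = c("TerL", "portal", "core_hyp", "prohead_protease", "hyp_flank_up",
             "bS21", "hyp_flank_down", "core_hyp", "MCP", "core_hyp",
             "core_hyp"),
    rel_pos = c(-5L, -4L, -3L, -2L, -1L, 0L, 1L, 2L, 3L, 4L, 5L),
    strand = c("+", "+", "+", "+", "+", "-", "+", "+", "+", "+", "+"),
    label = c("terminase large subunit", "portal vertex protein",
              "hypothetical protein", "prohead maturation protease",
              "hypothetical protein", "ribosomal protein S21",
              "hypothetical protein", "hypothetical protein",
              "major capsid protein", "hypothetical protein",
              "hypothetical protein"),
    aa_len = c(420L, 380L, 150L, 230L, 90L, 60L, 95L, 140L, 330L, 160L, 120L)
  )
}

# Layout shared by every genome of one simulation: gene order, lengths,
# strands, and the category of each slot (module / core / accessory /
# singleton). Gene coordinates are identical across genomes.
plan_layout <- function(spec) {
  arch <- module_architecture()
  L <- spec$genome_length
  target_coding <- round(L * spec$coding_density_target)
  module_dna <- sum(3L * (arch$aa_len + 1L))
  if (target_coding < module_dna + 600 || L < module_dna + 1200) {
    abort("genome_length too small to host the conserved module")
  }
  mean_aa <- max(60, spec$mean_gene_length / 3 - 1)
  bg_aa <- integer(0)
  coding <- module_dna
  while (coding < target_coding) {
    aa <- max(60L, round(rgamma(1, shape = 4, scale = mean_aa / 4)))
    bg_aa <- c(bg_aa, aa)
    coding <- coding + 3L * (aa + 1L)
  }
  # resize the last background gene so the realized coding length lands on
  # the target (subject to the 60 aa minimum)
  if (length(bg_aa) > 0) {
    need <- target_coding - (coding - 3L * (tail(bg_aa, 1) + 1L))
    bg_aa[length(bg_aa)] <- max(60L, round(need / 3) - 1L)
    coding <- target_coding - need + 3L * (tail(bg_aa, 1) + 1L)
  }
  n_bg <- length(bg_aa)
  n_core <- round(0.4 * n_bg)
  n_acc <- round(0.4 * n_bg)
  n_single <- n_bg - n_core - n_acc
  category <- sample(c(rep("core_bg", n_core), rep("accessory", n_acc),
                       rep("singleton", n_single)))
  half <- n_bg %/% 2
  layout <- bind_rows(
    tibble(slot = sprintf("bg_%03d", seq_len(half)),
           role = "background", rel_pos = NA_integer_,
           strand = sample(c("+", "-"), half, replace = TRUE),
           label = "hypothetical protein", aa_len = bg_aa[seq_len(half)],
           category = category[seq_len(half)]),
    mutate(arch, category = "module"),
    tibble(slot = sprintf("bg_%03d", seq(half + 1, length.out = n_bg - half)),
           role = "background", rel_pos = NA_integer_,
           strand = sample(c("+", "-"), n_bg - half, replace = TRUE),
           label = "hypothetical protein",
           aa_len = bg_aa[seq(half + 1, length.out = n_bg - half)],
           category = category[seq(half + 1, length.out = n_bg - half)])
  )
  layout$dna_len <- 3L * (layout$aa_len + 1L)
  gap_total <- L - sum(layout$dna_len)
  if (gap_total < nrow(layout) + 1L) {
    abort("coding_density_target leaves no room for intergenic gaps")
  }
  layout
}

# Assemble a genome sequence from per-slot coding sequences and gap lengths;
# returns list(sequence, start, end) with 0-based half-open gene coords.
assemble_genome <- function(cds, strand, gaps, gc) {
  n <- length(cds)
  gap_seqs <- vapply(gaps, random_dna, character(1), gc = gc)
  placed <- ifelse(strand == "+", cds, rev_comp(cds))
  pieces <- character(2 * n + 1)
  pieces[seq(1, 2 * n + 1, by = 2)] <- gap_seqs
  pieces[seq(2, 2 * n, by = 2)] <- placed
  widths <- nchar(pieces)
  offsets <- cumsum(c(0L, widths))
  starts <- offsets[seq(2, 2 * n, by = 2)]
  list(sequence = paste(pieces, collapse = ""),
       start = as.integer(starts),
       end = as.integer(starts + nchar(placed)))
}

extract_cds <- function(sequence, start, end, strand) {
  s <- substring(sequence, start + 1L, end)
  ifelse(strand == "+", s, rev_comp(s))
}

# Build the gene/truth tables for one genome given its sequence and layout.
genome_tables <- function(genome_id, sequence, layout, clade, spec) {
  cds <- extract_cds(sequence, layout$start, layout$end, layout$strand)
  prot <- translate_cds(cds)
  gene_id <- sprintf("%s_g%03d", genome_id, seq_len(nrow(layout)))
  wt <- spec$expression_profile
  role_wt <- ifelse(layout$role %in% names(wt), wt[layout$role], wt["background"])
  genes <- tibble(
    gene_id = gene_id, genome_id = genome_id,
    start = layout$start, end = layout$end, strand = layout$strand,
    product_label = layout$label, protein = prot
  )
  truth <- tibble(
    gene_id = gene_id, genome_id = genome_id, clade = clade,
    slot = layout$slot, role = layout$role, category = layout$category,
    rel_pos = layout$rel_pos, expression_weight = unname(role_wt)
  )
  list(genes = genes, truth = truth)
}

#' Simulate a set of clade-structured phage genomes
#'
#' Generates `n_genomes` circular phage genomes in `n_clades` clades, each
#' carrying the conserved anchor module (bS21 on the reverse strand flanked
#' by two hypothetical-protein families, with TerL, portal, prohead protease
#' and MCP within five genes). Clade founders derive their conserved-module
#' and shared-core proteins from common ancestral sequences (cross-clade
#' amino-acid identity >= ~80%), carry clade-specific accessory genes, and
#' each emitted genome is an independently mutated copy of its founder at
#' `within_clade_divergence` per site, with its own singleton genes.
#'
#' @param spec a [synth_spec()].
#' @return a list with elements `genomes` (genome table), `genes` (gene table
#'   with proteins), and `truth` (per-gene ground truth: clade, slot, role,
#'   category, relative position in the module, expression weight).
#' @export
simulate_phage_genomes <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  withr::with_seed(spec$seed, {
    layout <- plan_layout(spec)
    gc <- calibrate_codon_gc(spec$gc_target, spec$within_clade_divergence)
    # ancestral proteins for everything shared across clades
    ancestral <- setNames(
      vapply(layout$aa_len, random_protein, character(1), gc = gc),
      layout$slot)
    clade_of <- rep(seq_len(spec$n_clades), length.out = spec$n_genomes)
    genomes <- list(); genes <- list(); truth <- list()
    for (cl in seq_len(spec$n_clades)) {
      prot <- ancestral
      shared <- layout$category %in% c("module", "core_bg")
      prot[shared] <- vapply(ancestral[shared], mutate_protein, character(1),
                             rate = spec$clade_protein_divergence)
      acc <- layout$category == "accessory"
      prot[acc] <- vapply(layout$aa_len[acc], random_protein, character(1),
                          gc = gc)
      cds <- vapply(prot, reverse_translate, character(1), gc = gc)
      gaps <- as.integer(rmultinom(1, spec$genome_length - sum(layout$dna_len),
                                   rep(1, nrow(layout) + 1L)))
      founder <- assemble_genome(cds, layout$strand, gaps, gc)
      lay <- layout
      lay$start <- founder$start
      lay$end <- founder$end
      members <- which(clade_of == cl)
      for (m in members) {
        gid <- sprintf("phage_%02d", m)
        seq_m <- mutate_dna(founder$sequence, spec$within_clade_divergence)
        # fresh singleton genes per member (same slot lengths keep coords)
        for (j in which(lay$category == "singleton")) {
          p <- random_protein(lay$aa_len[j], gc)
          d <- reverse_translate(p, gc)
          piece <- if (lay$strand[j] == "+") d else rev_comp(d)
          substr(seq_m, lay$start[j] + 1L, lay$end[j]) <- piece
        }
        tabs <- genome_tables(gid, seq_m, lay, cl, spec)
        genomes[[gid]] <- tibble(genome_id = gid, sequence = seq_m,
                                 circular = TRUE,
                                 description = sprintf("synthetic phage clade %d", cl))
        genes[[gid]] <- tabs$genes
        truth[[gid]] <- tabs$truth
      }
    }
    list(genomes = arrange(bind_rows(genomes), .data$genome_id),
         genes = arrange(bind_rows(genes), .data$genome_id, .data$start),
         truth = arrange(bind_rows(truth), .data$genome_id, .data$gene_id))
  })
}

#' Generate one synthetic phage genome
#'
#' Single-genome form of [simulate_phage_genomes()]. With `clade_seed =
#' NULL` a fresh founder-derived genome is built; given a previous result,
#' the new genome is a substitution-only mutated copy of it at
#' `within_clade_divergence` (proteins re-derived by translation), emulating
#' a clade sibling.
#'
#' @param spec a [synth_spec()].
#' @param clade_seed `NULL`, or the list returned by a previous call.
#' @param genome_id identifier for the emitted genome.
#' @return a list with `genome` (one-row genome table), `genes`, `truth`.
#' @export
generate_phage_genome <- function(spec, clade_seed = NULL,
                                  genome_id = "phage_01") {
  stopifnot(inherits(spec, "synth_spec"))
  if (is.null(clade_seed)) {
    one <- synth_spec(seed = spec$seed, n_genomes = 1L,
                      genome_length = spec$genome_length,
                      gc_target = spec$gc_target,
                      mean_gene_length = spec$mean_gene_length,
                      coding_density_target = spec$coding_density_target,
                      n_clades = 1L,
                      within_clade_divergence = spec$within_clade_divergence,
                      clade_protein_divergence = spec$clade_protein_divergence,
                      expression_profile = spec$expression_profile,
                      read_length = spec$read_length, depth = spec$depth,
                      error_rate = spec$error_rate)
    sim <- simulate_phage_genomes(one)
    gid_new <- genome_id
    g <- sim$genomes[1, ]
    g$genome_id <- gid_new
    genes <- mutate(sim$genes, genome_id = gid_new,
                    gene_id = sub("^phage_01", gid_new, .data$gene_id))
    truth <- mutate(sim$truth, genome_id = gid_new,
                    gene_id = sub("^phage_01", gid_new, .data$gene_id))
    return(list(genome = g, genes = genes, truth = truth))
  }
  withr::with_seed(spec$seed + 77L, {
    base <- clade_seed
    seq_m <- mutate_dna(base$genome$sequence[1], spec$within_clade_divergence)
    genes <- base$genes
    genes$genome_id <- genome_id
    genes$gene_id <- sub(paste0("^", base$genome$genome_id[1]), genome_id,
                         genes$gene_id)
    genes$protein <- translate_cds(
      extract_cds(seq_m, genes$start, genes$end, genes$strand))
    truth <- base$truth
    truth$genome_id <- genome_id
    truth$gene_id <- genes$gene_id
    list(genome = tibble(genome_id = genome_id, sequence = seq_m,
                         circular = TRUE,
                         description = "synthetic phage (clade sibling)"),
         genes = genes, truth = truth)
  })
}
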