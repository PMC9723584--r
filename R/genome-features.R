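#' GC content of DNA sequences
#'
#' Percent `100 * (G + C) / (A + C + G + T)`; `N` positions are excluded from
#' the denominator. Vectorised over `seq`.
#'
#' @param seq character vector of DNA sequences.
#' @return numeric vector of GC percentages.
#' @export
#' @examples
#' gc_content(c("GGCC", "ATAT", "ACGTN"))
gc_content <- function(seq) {
  if (any(nchar(seq) == 0)) abort("empty sequence")
  gc <- stringr::str_count(seq, "[GC]")
  at <- stringr::str_count(seq, "[AT]")
  if (any(gc + at == 0)) abort("sequence has no unambiguous bases (all N)")
  100 * gc / (gc + at)
}

#' Coding density of a genome
#'
#' Percent of genome positions inside the union of gene intervals; positions
#' under overlapping genes are counted once.
#'
#' @param genes gene table for one genome (0-based half-open coordinates).
#' @param genome_length genome length in bp.
#' @return coding density as a percentage.
#' @export
coding_density <- function(genes, genome_length) {
  if (genome_length <= 0) abort("genome_length must be positive")
  if (nrow(genes) == 0) return(0)
  ir <- IRanges::reduce(IRanges::IRanges(genes$start + 1L, genes$end))
  100 * sum(IRanges::width(ir)) / genome_length
}

GENETIC_CODE_STOPS <- c("TAA", "TAG", "TGA")

# Translate an in-frame CDS (DNA, + strand coding sequence, length % 3 == 0).
# Internal stops become '*'; a trailing stop codon is dropped.
translate_cds <- function(dna) {
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAStringSet(dna), no.init.codon = TRUE))
  sub("\\*$", "", aa)
}

# Maximal ORFs in a single frame of one strand. `codons` is the codon vector,
# offsets are in codon units from the frame start. Returns codon-start/end
# (0-based, half-open in codon units, stop codon included in the span).
frame_orfs <- function(codons, min_aa) {
  is_stop <- codons %in% GENETIC_CODE_STOPS
  has_n <- grepl("N", codons, fixed = TRUE)
  # segment breaks at stops and at N-containing codons; only stop-terminated
  # segments can yield ORFs (an N terminates and voids the putative ORF)
  breaks <- which(is_stop | has_n)
  out <- list()
  seg_start <- 1L
  for (b in breaks) {
    if (is_stop[b]) {
      seg <- seq(seg_start, b - 1L)
      atg <- seg[codons[seg] == "ATG"]
      if (length(atg) && (b - atg[1]) >= min_aa) {
        out[[length(out) + 1L]] <- c(atg[1], b)
      }
    }
    seg_start <- b + 1L
  }
  out
}

#' Naive ORF finder
#'
#' Finds all maximal open reading frames (first ATG after the previous stop,
#' through the next in-frame stop) on both strands and all six frames, with a
#' protein length of at least `min_aa` codons (stop excluded). The scan is
#' linear even on circular genomes (no wrap-around ORFs). Codons containing
#' `N` terminate and void a putative ORF: N-runs mark scaffolding gaps, not
#' genes. Deliberately annotation-naive — real pipelines should supply GFF3.
#'
#' @param genome one-row genome table (or any row with `genome_id`,
#'   `sequence`).
#' @param min_aa minimum protein length in amino acids.
#' @return a gene table with `gene_id`, `genome_id`, `start`, `end` (0-based
#'   half-open, forward-strand coordinates, stop codon included), `strand`,
#'   `product_label` (empty) and `protein`.
#' @export
find_orfs <- function(genome, min_aa = 60L) {
  seq <- genome$sequence[1]
  gid <- genome$genome_id[1]
  L <- nchar(seq)
  found <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else rev_comp(seq)
    for (frame in 0:2) {
      n_codons <- (L - frame) %/% 3
      if (n_codons < min_aa + 1) next
      starts <- frame + 1L + 3L * (seq_len(n_codons) - 1L)
      codons <- substring(s, starts, starts + 2L)
      for (orf in frame_orfs(codons, min_aa)) {
        a <- frame + 3L * (orf[1] - 1L)       # 0-based on scanned strand
        b <- frame + 3L * orf[2]              # end incl. stop codon
        if (strand == "+") {
          fs <- a; fe <- b
        } else {
          fs <- L - b; fe <- L - a
        }
        found[[length(found) + 1L]] <- tibble(
          genome_id = gid, start = fs, end = fe, strand = strand,
          protein = translate_cds(substring(s, a + 1L, b))
        )
      }
    }
  }
  if (length(found) == 0) {
    return(tibble(gene_id = character(), genome_id = character(),
                  start = integer(), end = integer(), strand = character(),
                  product_label = character(), protein = character()))
  }
  bind_rows(found) %>%
    arrange(.data$start, .data$end, .data$strand) %>%
    mutate(gene_id = sprintf("%s_orf%04d", .data$genome_id, row_number()),
           product_label = "") %>%
    select("gene_id", "genome_id", "start", "end", "strand",
           "product_label", "protein")
}

#' Per-genome summary statistics
#'
#' Length, GC content, gene count and coding density for each genome, in the
#' style of the headline per-genome table of a curation study (genome length,
#' GC %, number of protein-coding genes, coding density %).
#'
#' @param genomes genome table.
#' @param genes gene table covering those genomes (may be empty).
#' @return a tibble with one row per genome: `genome_id`, `length_bp`,
#'   `gc_percent`, `n_genes`, `coding_density_percent`, `circular`.
#' @export
summarize_genomes <- function(genomes, genes) {
  check_genomes(genomes)
  genes <- check_genes(genes, genomes)
  purrr::map_dfr(seq_len(nrow(genomes)), function(i) {
    g <- genomes[i, ]
    gg <- filter(genes, .data$genome_id == g$genome_id)
    tibble(
      genome_id = g$genome_id,
      length_bp = nchar(g$sequence),
      gc_percent = gc_content(g$sequence),
      n_genes = nrow(gg),
      coding_density_percent = coding_density(gg, nchar(g$sequence)),
      circular = isTRUE(g$circular)
    )
  })
}
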