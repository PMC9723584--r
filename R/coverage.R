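# Alignment-derived detection, abundance and transcription. Interval algebra
# goes through IRanges; per-position brute-force oracles live in the tests.

# Alignment table -> IRanges of target blocks (1-based) for passing records.
blocks_to_iranges <- function(alignments) {
  if (nrow(alignments) == 0) return(IRanges::IRanges())
  mats <- alignments$blocks
  starts <- unlist(lapply(mats, function(m) m[, "start"]), use.names = FALSE)
  ends <- unlist(lapply(mats, function(m) m[, "end"]), use.names = FALSE)
  IRanges::IRanges(start = starts + 1L, end = ends)
}

filter_passing <- function(alignments, genome_id, min_identity) {
  filter(alignments,
         .data$target_id == genome_id,
         alignment_identity(.data$mismatches, .data$read_length) >=
           min_identity)
}

#' Genome detection and coverage from read alignments
#'
#' Applies the read-identity filter, then computes breadth (fraction of
#' genome positions covered by >= 1 read), coverage (total aligned bases of
#' passing reads divided by the covered genome length) and the detection
#' flag (breadth >= `min_breadth`, by default the 90%-at-97%-identity rule).
#'
#' @param alignments alignment table (DNA reads).
#' @param genome one-row genome table.
#' @param min_identity minimum read identity (`1 - mismatches/read_length`).
#' @param min_breadth detection threshold on breadth.
#' @param sample_id optional sample label carried into the output.
#' @return one-row tibble: `genome_id`, `sample_id`, `n_reads_mapped`,
#'   `breadth`, `coverage`, `detected`.
#' @export
genome_coverage <- function(alignments, genome, min_identity = 0.97,
                            min_breadth = 0.90, sample_id = NA_character_) {
  gid <- genome$genome_id[1]
  L <- nchar(genome$sequence[1])
  pass <- filter_passing(alignments, gid, min_identity)
  ir <- blocks_to_iranges(pass)
  covered <- sum(IRanges::width(IRanges::reduce(ir)))
  total_bases <- sum(IRanges::width(ir))
  breadth <- covered / L
  tibble(
    genome_id = gid, sample_id = sample_id,
    n_reads_mapped = nrow(pass),
    breadth = breadth,
    coverage = if (covered > 0) total_bases / covered else 0,
    detected = breadth >= min_breadth
  )
}

#' Per-gene normalised transcriptional level (NTL)
#'
#' For each gene, `ntl = total_base_gene / length_gene / total_read_genome`,
#' where `total_base_gene` is the RNA bases (aligned block overlap) falling
#' inside the gene, `length_gene` its nucleotide length, and
#' `total_read_genome` the number of identity-passing RNA reads mapped
#' anywhere on the genome. Genes with less than `min_covered` of their bases
#' covered by RNA get `ntl = NA`.
#'
#' @param alignments RNA alignment table.
#' @param genes gene table for this genome.
#' @param genome one-row genome table.
#' @param min_identity minimum read identity (default the 98% RNA filter).
#' @param min_covered minimum covered fraction of gene bases for NTL to be
#'   defined.
#' @return tibble with one row per gene: `gene_id`, `length_gene`,
#'   `total_base_gene`, `covered_fraction`, `total_read_genome`, `ntl`.
#' @export
gene_ntl <- function(alignments, genes, genome, min_identity = 0.98,
                     min_covered = 0.80) {
  gid <- genome$genome_id[1]
  genes <- check_genes(filter(genes, .data$genome_id == gid), genome)
  pass <- filter_passing(alignments, gid, min_identity)
  total_reads <- nrow(pass)
  if (total_reads == 0) {
    warn(paste0("no passing RNA reads on ", gid, "; all NTL undefined"))
  }
  ir <- blocks_to_iranges(pass)
  cov_ir <- IRanges::reduce(ir)
  out <- purrr::map_dfr(seq_len(nrow(genes)), function(i) {
    g <- IRanges::IRanges(genes$start[i] + 1L, genes$end[i])
    len <- genes$end[i] - genes$start[i]
    total_base <- sum(IRanges::width(IRanges::pintersect(
      IRanges::findOverlapPairs(ir, g))))
    covered <- sum(IRanges::width(IRanges::pintersect(
      IRanges::findOverlapPairs(cov_ir, g))))
    tibble(gene_id = genes$gene_id[i], length_gene = len,
           total_base_gene = total_base, covered_fraction = covered / len)
  })
  out %>%
    mutate(total_read_genome = total_reads,
           ntl = dplyr::if_else(
             .data$covered_fraction >= min_covered & total_reads > 0,
             .data$total_base_gene / .data$length_gene / total_reads,
             NA_real_))
}

#' Percentage of RNA reads mapped per genome
#'
#' @param alignments RNA alignment table (possibly spanning genomes).
#' @param total_rna_reads total RNA reads in the sample (mapped + unmapped).
#' @param min_identity minimum read identity.
#' @return tibble with `genome_id`, `n_reads_mapped`, `percent_mapped`.
#'   Multi-mapped reads count once per target genome (no deduplication).
#' @export
percent_rna_mapped <- function(alignments, total_rna_reads,
                               min_identity = 0.98) {
  if (total_rna_reads <= 0) abort("total_rna_reads must be > 0")
  pass <- filter(alignments,
                 alignment_identity(.data$mismatches, .data$read_length) >=
                   min_identity)
  if (nrow(pass) > 0 && total_rna_reads < nrow(distinct(pass, .data$read_id))) {
    abort("total_rna_reads is smaller than the number of distinct mapped reads")
  }
  pass %>%
    count(.data$target_id, name = "n_reads_mapped") %>%
    rename(genome_id = "target_id") %>%
    mutate(percent_mapped = 100 * .data$n_reads_mapped / total_rna_reads) %>%
    arrange(.data$genome_id)
}

#' Per-position read depth track
#'
#' Depth of identity-passing reads at every genome position, for plotting
#' co-transcription profiles. Exported as a plain table.
#'
#' @param alignments alignment table.
#' @param genome one-row genome table.
#' @param min_identity minimum read identity.
#' @return tibble with `position` (0-based) and `depth`, one row per genome
#'   position.
#' @export
position_depth <- function(alignments, genome, min_identity = 0.98) {
  gid <- genome$genome_id[1]
  L <- nchar(genome$sequence[1])
  pass <- filter_passing(alignments, gid, min_identity)
  ir <- blocks_to_iranges(pass)
  cov <- IRanges::coverage(ir, width = L)
  tibble(position = 0:(L - 1L), depth = as.integer(cov))
}

# Greedy nucleotide dereplication at `identity` with >= 0.5 mutual coverage,
# longest sequence first (representative).
dereplicate_markers <- function(markers, identity = 0.97, min_cov = 0.5) {
  ord <- order(-nchar(markers$sequence), markers$marker_id)
  markers <- markers[ord, ]
  reps <- integer(0)
  rep_of <- integer(nrow(markers))
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  for (i in seq_len(nrow(markers))) {
    assigned <- FALSE
    if (length(reps)) {
      aln <- Biostrings::pairwiseAlignment(
        pattern = Biostrings::DNAStringSet(markers$sequence[reps]),
        subject = Biostrings::DNAString(markers$sequence[i]),
        type = "local", substitutionMatrix = mat,
        gapOpening = 5, gapExtension = 2)
      aln_len <- nchar(as.character(Biostrings::pattern(aln)))
      idv <- Biostrings::nmatch(aln) / aln_len
      pw <- Biostrings::end(Biostrings::pattern(aln)) -
        Biostrings::start(Biostrings::pattern(aln)) + 1
      sw <- Biostrings::end(Biostrings::subject(aln)) -
        Biostrings::start(Biostrings::subject(aln)) + 1
      covp <- pw / nchar(markers$sequence[reps])
      covs <- sw / nchar(markers$sequence[i])
      ok <- which(idv >= identity & covp >= min_cov & covs >= min_cov)
      if (length(ok)) {
        rep_of[i] <- reps[ok[1]]
        assigned <- TRUE
      }
    }
    if (!assigned) {
      reps <- c(reps, i)
      rep_of[i] <- i
    }
  }
  markers$representative_id <- markers$marker_id[rep_of]
  markers
}

#' rpS3 marker-based community profile
#'
#' Markers shorter than `min_len_nt` are dropped; the rest are greedily
#' dereplicated at `dereplicate_identity` with >= 0.5 mutual coverage
#' (longest sequence becomes the representative, mirroring cd-hit-est with
#' -c 0.97 -aS 0.5 -aL 0.5). Reads passing the mismatch filter
#' (`mismatches / read_length <= max_mismatch_frac`) contribute their aligned
#' bases to their target representative; coverage is mapped bases divided by
#' representative length, summed per taxon.
#'
#' @param markers tibble with `marker_id`, `sequence` (nucleotide), `taxon`.
#' @param alignments alignment table whose `target_id`s are marker IDs.
#' @param dereplicate_identity nucleotide identity for dereplication.
#' @param min_len_nt minimum marker length retained.
#' @param max_mismatch_frac maximum mismatch fraction per read.
#' @return tibble with `taxon`, `coverage`, `n_markers`, sorted by
#'   descending coverage.
#' @export
rps3_profile <- function(markers, alignments, dereplicate_identity = 0.97,
                         min_len_nt = 300L, max_mismatch_frac = 0.03) {
  stopifnot(all(c("marker_id", "sequence", "taxon") %in% names(markers)))
  markers <- filter(markers, nchar(.data$sequence) >= min_len_nt)
  if (nrow(markers) == 0) abort("no marker passes the length filter")
  derep <- dereplicate_markers(markers, identity = dereplicate_identity)
  reps <- derep %>% filter(.data$marker_id == .data$representative_id)
  pass <- filter(alignments,
                 .data$mismatches / .data$read_length <= max_mismatch_frac)
  per_rep <- purrr::map_dfr(seq_len(nrow(reps)), function(i) {
    r <- reps[i, ]
    recs <- filter(pass, .data$target_id == r$marker_id)
    bases <- sum(IRanges::width(blocks_to_iranges(recs)))
    tibble(marker_id = r$marker_id, taxon = r$taxon,
           coverage = bases / nchar(r$sequence))
  })
  per_rep %>%
    group_by(.data$taxon) %>%
    summarise(coverage = sum(.data$coverage), n_markers = n(),
              .groups = "drop") %>%
    arrange(desc(.data$coverage), .data$taxon)
}
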