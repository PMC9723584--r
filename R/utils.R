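#' @keywords internal
"_PACKAGE"

#' @import tibble
#' @importFrom dplyr %>% arrange bind_rows count desc distinct filter group_by
#'   left_join mutate n n_distinct pull rename row_number select slice summarise
#'   ungroup first anti_join
#' @importFrom rlang .data abort warn
#' @importFrom stats rbinom rgamma rmultinom rpois runif setNames cor hclust
#'   as.dist cutree
#' @importFrom utils head tail
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' Vectorised over `x`. `N` is its own complement; case is preserved upward
#' (sequences are expected uppercase throughout the package).
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
#' @examples
#' rev_comp("ACGTN")
rev_comp <- function(x) {
  stringi::stri_reverse(chartr("ACGTN", "TGCAN", x))
}

# Hamming distance between two equal-length strings (byte-wise).
hamming <- function(a, b) {
  ra <- charToRaw(a)
  rb <- charToRaw(b)
  stopifnot(length(ra) == length(rb))
  sum(ra != rb)
}

# Random DNA string of length n at a target GC fraction.
random_dna <- function(n, gc = 0.5) {
  if (n <= 0) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

# Substitute each position independently with probability `rate` to a
# uniformly chosen different base. Substitution-only: length preserved.
mutate_dna <- function(seq, rate) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(chars)) < rate & chars %in% DNA_BASES)
  if (length(hit)) {
    chars[hit] <- vapply(chars[hit], function(b) {
      sample(setdiff(DNA_BASES, b), 1L)
    }, character(1), USE.NAMES = FALSE)
  }
  paste(chars, collapse = "")
}

# Validate a genome table (genome_id, sequence, circular, description).
check_genomes <- function(genomes) {
  need <- c("genome_id", "sequence")
  if (!is.data.frame(genomes) || !all(need %in% names(genomes))) {
    abort("`genomes` must be a data frame with columns genome_id and sequence")
  }
  if (anyDuplicated(genomes$genome_id)) {
    abort(paste0("duplicate genome_id: ",
                 genomes$genome_id[duplicated(genomes$genome_id)][1]))
  }
  invisible(genomes)
}

# Validate a gene table and return it sorted by (genome_id, start).
check_genes <- function(genes, genomes = NULL) {
  need <- c("gene_id", "genome_id", "start", "end", "strand")
  if (!is.data.frame(genes) || !all(need %in% names(genes))) {
    abort("`genes` must have columns gene_id, genome_id, start, end, strand")
  }
  if (any(!genes$strand %in% c("+", "-"))) {
    abort("gene strand must be '+' or '-'")
  }
  if (any(genes$start < 0 | genes$start >= genes$end)) {
    abort("gene coordinates must satisfy 0 <= start < end")
  }
  if (!is.null(genomes)) {
    len <- setNames(nchar(genomes$sequence), genomes$genome_id)
    bad <- is.na(len[genes$genome_id]) | genes$end > len[genes$genome_id]
    if (any(bad)) {
      abort(paste0("gene ", genes$gene_id[bad][1],
                   " extends beyond its genome (wrap-around genes are not supported)"))
    }
  }
  dplyr::arrange(genes, .data$genome_id, .data$start)
}

# Fraction identity implied by an edit count over the read length.
#' Alignment identity from mismatch count
#'
#' Identity is defined as `1 - mismatches / read_length`, matching the
#' convention that 3 mismatches on a 150 bp read is 98% similarity.
#'
#' @param mismatches integer vector of edit counts.
#' @param read_length integer vector of read lengths.
#' @return numeric vector of identities in `[0, 1]`.
#' @export
alignment_identity <- function(mismatches, read_length) {
  1 - mismatches / read_length
}
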