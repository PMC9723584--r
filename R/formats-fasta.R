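#' Read genome sequences from FASTA
#'
#' Reads a (multi-)FASTA of nucleotide sequences into a genome table.
#' Sequences are uppercased and `U` is normalised to `T`; the alphabet is
#' restricted to `A`, `C`, `G`, `T`, `N`.
#'
#' @param path path to a FASTA file.
#' @param circular logical, recycled across records; whether each genome is
#'   circular (FASTA carries no topology, so this is supplied by the caller).
#' @return a tibble with columns `genome_id`, `sequence`, `circular`,
#'   `description` (text after the first whitespace in the header, or `""`).
#' @export
read_genome_fasta <- function(path, circular = FALSE) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) abort(paste0("empty FASTA file: ", path))
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate FASTA ID: ", ids[duplicated(ids)][1]))
  }
  seqs <- chartr("U", "T", toupper(as.character(set)))
  if (any(nchar(seqs) == 0)) abort("FASTA contains an empty sequence")
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    abort(paste0("sequence ", ids[bad][1],
                 " contains characters outside {A,C,G,T,N}"))
  }
  tibble(
    genome_id = unname(ids),
    sequence = unname(seqs),
    circular = rep_len(circular, length(ids)),
    description = unname(desc)
  )
}

#' Read protein sequences from FASTA
#'
#' @param path path to an amino-acid FASTA file.
#' @return a tibble with columns `protein_id`, `sequence`.
#' @export
read_protein_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) abort(paste0("empty FASTA file: ", path))
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate FASTA ID: ", ids[duplicated(ids)][1]))
  }
  tibble(protein_id = unname(ids), sequence = toupper(as.character(set)))
}

#' Write sequences to FASTA
#'
#' Deterministic writer: records are emitted in table order, wrapped at
#' `width` characters.
#'
#' @param x a data frame holding sequences.
#' @param path output path.
#' @param id_col,seq_col names of the ID and sequence columns.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, id_col = "genome_id", seq_col = "sequence",
                        width = 70L) {
  set <- Biostrings::BStringSet(setNames(x[[seq_col]], x[[id_col]]))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read an aligned FASTA (MSA)
#'
#' All sequences must share one alignment length; gaps are `-`.
#'
#' @param path path to an aligned FASTA file.
#' @return a tibble with columns `sequence_id`, `aligned`.
#' @export
read_msa_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) abort(paste0("empty FASTA file: ", path))
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  if (length(unique(nchar(seqs))) != 1) {
    abort("aligned FASTA has sequences of unequal length")
  }
  tibble(sequence_id = unname(ids), aligned = unname(seqs))
}
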