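#' Simulate a host genome carrying a CRISPR array
#'
#' Builds a random host genome containing one CRISPR repeat-spacer array:
#' `n_spacers + 1` exact copies (>= 3) of a repeat of length 28-36 bp,
#' interleaved with spacers sampled as substrings of the supplied phage
#' genomes with exactly the requested number of substituted positions.
#' Spacer origins (phage, strand, position, mismatch count) are recorded as
#' ground truth, so downstream matching under the dual rule (>= 24 nt &
#' <= 1 mismatch, or >= 30 nt & <= 3 mismatches) can be scored exactly.
#'
#' @param phages genome table of target phages.
#' @param n_spacers number of planted spacers (`length(mismatch_counts)`).
#' @param mismatch_counts integer vector; exact substitutions applied to each
#'   planted spacer relative to its phage protospacer.
#' @param spec a [synth_spec()] (supplies the seed).
#' @param spacer_lengths optional integer vector of spacer lengths (default:
#'   sampled in 24-36 bp).
#' @param host_length host genome length in bp.
#' @param host_gc host GC fraction.
#' @param host_id identifier of the emitted host genome.
#' @return a list with `host` (one-row genome table) and `truth` (tibble:
#'   `spacer_id`, `sequence`, `length`, `phage_id`, `strand`, `phage_start`,
#'   `mismatches`, `host_start`; filler spacers added to reach the 3-repeat
#'   minimum have `phage_id = NA`).
#' @export
simulate_host_with_crispr <- function(phages, n_spacers, mismatch_counts, spec,
                                      spacer_lengths = NULL,
                                      host_length = 20000L, host_gc = 0.40,
                                      host_id = "host_01") {
  stopifnot(inherits(spec, "synth_spec"))
  check_genomes(phages)
  if (length(mismatch_counts) != n_spacers) {
    abort("n_spacers must equal length(mismatch_counts)")
  }
  if (any(mismatch_counts < 0)) abort("mismatch_counts must be >= 0")
  withr::with_seed(spec$seed + 1000000L, {
    if (is.null(spacer_lengths)) {
      spacer_lengths <- sample(24:36, n_spacers, replace = TRUE)
    }
    if (length(spacer_lengths) != n_spacers) {
      abort("spacer_lengths must have length n_spacers")
    }
    if (any(mismatch_counts > spacer_lengths)) {
      abort("cannot plant more mismatches than spacer positions")
    }
    repeat_len <- sample(28:36, 1)
    repeat_seq <- random_dna(repeat_len, 0.5)
    phage_idx <- rep(seq_len(nrow(phages)), length.out = max(n_spacers, 1L))
    truth <- purrr::map_dfr(seq_len(n_spacers), function(i) {
      ph <- phages[phage_idx[i], ]
      plen <- nchar(ph$sequence)
      slen <- spacer_lengths[i]
      if (plen < slen) {
        abort(paste0("phage ", ph$genome_id, " too short to sample a spacer"))
      }
      start <- sample.int(plen - slen + 1L, 1) - 1L
      proto <- substring(ph$sequence, start + 1L, start + slen)
      strand <- sample(c("+", "-"), 1)
      sp <- if (strand == "+") proto else rev_comp(proto)
      k <- mismatch_counts[i]
      if (k > 0) {
        pos <- sample.int(slen, k)
        chars <- strsplit(sp, "")[[1]]
        chars[pos] <- vapply(chars[pos], function(b) {
          sample(setdiff(DNA_BASES, b), 1L)
        }, character(1), USE.NAMES = FALSE)
        sp <- paste(chars, collapse = "")
      }
      tibble(spacer_id = sprintf("%s_sp%02d", host_id, i), sequence = sp,
             length = slen, phage_id = ph$genome_id, strand = strand,
             phage_start = start, mismatches = as.integer(k))
    })
    # an array needs >= 3 repeat copies, i.e. >= 2 spacers; pad with fillers
    n_fill <- max(0L, 2L - n_spacers)
    if (n_fill > 0) {
      fill <- tibble(
        spacer_id = sprintf("%s_fill%02d", host_id, seq_len(n_fill)),
        sequence = vapply(rep(32L, n_fill), random_dna, character(1),
                          gc = host_gc),
        length = 32L, phage_id = NA_character_, strand = NA_character_,
        phage_start = NA_integer_, mismatches = NA_integer_)
      truth <- bind_rows(truth, fill)
    }
    array_seq <- paste0(repeat_seq,
                        paste0(truth$sequence, repeat_seq, collapse = ""))
    backbone <- random_dna(host_length, host_gc)
    ins <- sample.int(host_length - 1L, 1)
    host_seq <- paste0(substring(backbone, 1, ins), array_seq,
                       substring(backbone, ins + 1L, host_length))
    starts <- ins + repeat_len +
      cumsum(c(0L, head(truth$length + repeat_len, -1L)))
    truth$host_start <- as.integer(starts)
    list(
      host = tibble(genome_id = host_id, sequence = host_seq,
                    circular = FALSE,
                    description = sprintf("synthetic CRISPR host (repeat %d bp)",
                                          repeat_len)),
      truth = truth
    )
  })
}
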