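#' Simulate read alignments against a genome
#'
#' Emulates the alignment records a read mapper would produce, without
#' simulating base-level sequences. In DNA mode, read start positions are
#' uniform over the genome (wrapping the circular origin yields a two-block
#' record). In RNA mode, each read falls wholly inside one gene, with genes
#' drawn with probability proportional to `weight x gene length`. The number
#' of reads is Poisson with mean `depth * genome_length / read_length`;
#' per-read mismatch counts are Binomial(`read_length`, `error_rate`).
#'
#' @param genome one-row genome table.
#' @param genes gene table for that genome (required in RNA mode).
#' @param spec a [synth_spec()]; supplies seed, read length, depth and error
#'   rate.
#' @param rna logical; RNA mode.
#' @param weights named numeric vector of per-gene expression weights
#'   (names are `gene_id`); defaults to 1 for every gene. Ignored in DNA
#'   mode.
#' @param depth optional override of `spec$depth`.
#' @return an alignment table (same shape as [read_sam()]).
#' @export
simulate_alignments <- function(genome, genes = NULL, spec, rna = FALSE,
                                weights = NULL, depth = NULL) {
  stopifnot(inherits(spec, "synth_spec"))
  depth <- if (is.null(depth)) spec$depth else depth
  if (depth <= 0) abort("depth must be > 0")
  gid <- genome$genome_id[1]
  L <- nchar(genome$sequence[1])
  rl <- spec$read_length
  circular <- isTRUE(genome$circular[1])
  withr::with_seed(spec$seed + if (rna) 3000000L else 2000000L, {
    n_reads <- rpois(1, depth * L / rl)
    if (n_reads == 0) {
      return(tibble(read_id = character(), target_id = character(),
                    target_start = integer(), read_length = integer(),
                    mismatches = integer(), is_rna = logical(),
                    blocks = list()))
    }
    if (rna) {
      if (is.null(genes) || nrow(genes) == 0) {
        abort("RNA mode requires a gene table")
      }
      genes <- filter(genes, .data$genome_id == gid,
                      .data$end - .data$start >= rl)
      if (nrow(genes) == 0) abort("no gene is long enough to host a read")
      w <- if (is.null(weights)) rep(1, nrow(genes)) else {
        miss <- setdiff(genes$gene_id, names(weights))
        if (length(miss)) {
          abort(paste0("weights missing for gene ", miss[1]))
        }
        unname(weights[genes$gene_id])
      }
      p <- w * (genes$end - genes$start)
      gi <- sample.int(nrow(genes), n_reads, replace = TRUE, prob = p)
      span <- genes$end[gi] - genes$start[gi] - rl
      starts <- genes$start[gi] +
        floor(runif(n_reads) * (span + 1))
      blocks <- purrr::map(starts, function(s) {
        cbind(start = as.integer(s), end = as.integer(s + rl))
      })
    } else {
      if (circular) {
        starts <- sample.int(L, n_reads, replace = TRUE) - 1L
        blocks <- purrr::map(starts, function(s) {
          if (s + rl <= L) {
            cbind(start = s, end = s + rl)
          } else {
            cbind(start = c(s, 0L), end = c(L, s + rl - L))
          }
        })
      } else {
        starts <- sample.int(L - rl + 1L, n_reads, replace = TRUE) - 1L
        blocks <- purrr::map(starts, function(s) cbind(start = s, end = s + rl))
      }
    }
    tibble(
      read_id = sprintf("%s_%s_r%06d", gid, if (rna) "rna" else "dna",
                        seq_len(n_reads)),
      target_id = gid,
      target_start = as.integer(starts),
      read_length = rl,
      mismatches = rbinom(n_reads, rl, spec$error_rate),
      is_rna = rna,
      blocks = blocks
    )
  })
}
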