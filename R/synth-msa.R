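#' Simulate a two-group protein alignment with planted divergence
#'
#' Builds a gapless amino-acid MSA of `n_phage` + `n_bact` sequences. At each
#' planted divergent column the two groups carry different modal residues,
#' each internally conserved at `group_conservation` (>= 0.9); at the
#' aromatic column every sequence carries one of Y/H/F with Y predominant
#' (as with the Tyr54-position check against a reference structure); all
#' other columns share one profile across groups.
#'
#' @param n_phage,n_bact group sizes.
#' @param length alignment length in columns.
#' @param divergent_columns integer vector of 0-based planted divergent
#'   columns.
#' @param aromatic_column 0-based column carrying the aromatic residue, or
#'   `NULL`.
#' @param seed integer seed.
#' @param group_conservation within-group modal-residue frequency at planted
#'   and background columns.
#' @param aromatic_probs named probabilities over `c(Y, H, F)`.
#' @return a list with `msa` (tibble: `sequence_id`, `group` in
#'   `c("phage", "bacterial")`, `aligned`) and `truth` (list with
#'   `divergent_columns`, `aromatic_column`, `aromatic_residues` per
#'   sequence).
#' @export
simulate_group_msa <- function(n_phage, n_bact, length, divergent_columns,
                               aromatic_column = NULL, seed,
                               group_conservation = 0.95,
                               aromatic_probs = c(Y = 0.85, H = 0.10, F = 0.05)) {
  if (group_conservation < 0.9) {
    abort("group_conservation must be >= 0.9 so planted columns stay callable")
  }
  cols <- divergent_columns
  if (any(cols < 0 | cols >= length)) {
    abort("divergent_columns must lie in [0, length)")
  }
  if (!is.null(aromatic_column)) {
    if (aromatic_column < 0 || aromatic_column >= length) {
      abort("aromatic_column must lie in [0, length)")
    }
    if (aromatic_column %in% cols) {
      abort("divergent and aromatic column lists overlap")
    }
  }
  if (anyDuplicated(cols)) abort("divergent_columns contains duplicates")
  n <- n_phage + n_bact
  withr::with_seed(seed, {
    mat <- matrix("", nrow = n, ncol = length)
    draw_col <- function(modal, n_seq) {
      noise <- runif(n_seq) >= group_conservation
      out <- rep(modal, n_seq)
      if (any(noise)) {
        out[noise] <- sample(setdiff(AA20, modal), sum(noise), replace = TRUE)
      }
      out
    }
    for (j in seq_len(length)) {
      j0 <- j - 1L
      if (j0 %in% cols) {
        pair <- sample(AA20, 2)
        mat[seq_len(n_phage), j] <- draw_col(pair[1], n_phage)
        mat[n_phage + seq_len(n_bact), j] <- draw_col(pair[2], n_bact)
      } else if (!is.null(aromatic_column) && j0 == aromatic_column) {
        mat[, j] <- sample(names(aromatic_probs), n, replace = TRUE,
                           prob = aromatic_probs)
      } else {
        mat[, j] <- draw_col(sample(AA20, 1), n)
      }
    }
    ids <- c(sprintf("phage_s%02d", seq_len(n_phage)),
             sprintf("bact_s%02d", seq_len(n_bact)))
    msa <- tibble(
      sequence_id = ids,
      group = c(rep("phage", n_phage), rep("bacterial", n_bact)),
      aligned = apply(mat, 1, paste, collapse = "")
    )
    truth <- list(
      divergent_columns = sort(cols),
      aromatic_column = aromatic_column,
      aromatic_residues = if (is.null(aromatic_column)) NULL else
        setNames(mat[, aromatic_column + 1L], ids)
    )
    list(msa = msa, truth = truth)
  })
}
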