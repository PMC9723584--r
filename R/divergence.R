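# Two-group MSA analysis: per-column conservation/divergence in the phage
# vs. bacterial protein sets, consensus sequences, the aromatic-position
# check, and alignment-column <-> reference-residue numbering.

msa_matrix <- function(msa) {
  stopifnot(all(c("sequence_id", "aligned") %in% names(msa)))
  if (length(unique(nchar(msa$aligned))) != 1) {
    abort("aligned sequences differ in length")
  }
  m <- do.call(rbind, strsplit(toupper(msa$aligned), ""))
  rownames(m) <- msa$sequence_id
  m
}

modal_residue <- function(col) {
  res <- col[col != "-"]
  if (length(res) == 0) {
    return(list(residue = NA_character_, freq = NA_real_))
  }
  tt <- table(res)
  top <- sort(names(tt)[tt == max(tt)])[1]   # lexicographic tie-break
  list(residue = top, freq = unname(max(tt)) / length(res))
}

#' Per-column two-group conservation and divergence statistics
#'
#' For every alignment column, the modal non-gap residue and its frequency
#' are computed within each group. A column is *divergent* when both groups
#' are internally conserved at `tau_group` or better but on different
#' residues; it is *conserved* when the pooled modal frequency reaches
#' `tau_cons`. Columns whose overall gap fraction exceeds `max_gap_frac` are
#' flagged uncallable (neither divergent nor conserved). This explicit
#' modal-frequency statistic stands in for external divergence scorers whose
#' internals are unpublished; thresholds are configurable.
#'
#' @param msa tibble with `sequence_id`, `group` (exactly two non-empty
#'   groups), `aligned`.
#' @param tau_group within-group modal frequency required to call divergence.
#' @param tau_cons pooled modal frequency required to call conservation.
#' @param max_gap_frac maximum gap fraction for a callable column.
#' @param ref_id optional reference `sequence_id`; adds `ref_position`
#'   (1-based residue numbers in the ungapped reference, `NA` at reference
#'   gaps).
#' @return tibble with one row per column: `column` (0-based), `gap_frac`,
#'   `callable`, `modal_residue_a`, `modal_freq_a`, `modal_residue_b`,
#'   `modal_freq_b` (groups in alphabetical order of their labels),
#'   `pooled_modal_freq`, `divergent`, `conserved`, and optionally
#'   `ref_position`.
#' @export
column_stats <- function(msa, tau_group = 0.7, tau_cons = 0.9,
                         max_gap_frac = 0.5, ref_id = NULL) {
  stopifnot("group" %in% names(msa))
  groups <- sort(unique(msa$group))
  if (length(groups) != 2) abort("exactly two groups are required")
  m <- msa_matrix(msa)
  ga <- msa$group == groups[1]
  gb <- msa$group == groups[2]
  if (!any(ga) || !any(gb)) abort("both groups must be non-empty")
  n_col <- ncol(m)
  out <- purrr::map_dfr(seq_len(n_col), function(j) {
    col <- m[, j]
    a <- modal_residue(col[ga])
    b <- modal_residue(col[gb])
    pooled <- modal_residue(col)
    gap_frac <- mean(col == "-")
    callable <- gap_frac <= max_gap_frac
    divergent <- callable && !is.na(a$residue) && !is.na(b$residue) &&
      a$freq >= tau_group && b$freq >= tau_group && a$residue != b$residue
    conserved <- callable && !is.na(pooled$residue) && pooled$freq >= tau_cons
    tibble(column = j - 1L, gap_frac = gap_frac, callable = callable,
           modal_residue_a = a$residue, modal_freq_a = a$freq,
           modal_residue_b = b$residue, modal_freq_b = b$freq,
           pooled_modal_freq = pooled$freq,
           divergent = divergent, conserved = conserved)
  })
  if (!is.null(ref_id)) {
    num <- map_reference_numbering(msa, ref_id)
    out <- left_join(out, num, by = "column")
  }
  attr(out, "groups") <- groups
  out
}

#' Consensus sequence of an aligned group
#'
#' Per column: the modal non-gap residue when its frequency among non-gap
#' residues reaches `threshold`, otherwise `x`; columns that are majority
#' gap (> 50%) emit `-`. Ties break alphabetically.
#'
#' @param aligned character vector of aligned sequences (one group).
#' @param threshold minimum modal frequency.
#' @return a single consensus string.
#' @export
consensus_sequence <- function(aligned, threshold = 0.5) {
  if (length(aligned) == 0) abort("empty group")
  m <- do.call(rbind, strsplit(toupper(aligned), ""))
  cons <- vapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    if (mean(col == "-") > 0.5) return("-")
    mr <- modal_residue(col)
    if (!is.na(mr$freq) && mr$freq >= threshold) mr$residue else "x"
  }, character(1))
  paste(cons, collapse = "")
}

#' Map alignment columns to reference residue numbers
#'
#' Bijection between non-gap columns of the designated reference sequence
#' and 1-based residue numbers `1..len(ungapped reference)`; gap columns map
#' to `NA`.
#'
#' @param msa tibble with `sequence_id`, `aligned`.
#' @param ref_id reference `sequence_id`.
#' @return tibble with `column` (0-based) and `ref_position`.
#' @export
map_reference_numbering <- function(msa, ref_id) {
  if (!ref_id %in% msa$sequence_id) {
    abort(paste0("reference sequence not found: ", ref_id))
  }
  ref <- strsplit(msa$aligned[msa$sequence_id == ref_id][1], "")[[1]]
  pos <- cumsum(ref != "-")
  tibble(column = seq_along(ref) - 1L,
         ref_position = ifelse(ref == "-", NA_integer_, pos))
}

#' Residues at a reference-numbered position, with aromatic check
#'
#' Finds the alignment column holding residue `ref_residue_number` of the
#' reference sequence (ungapped counting) and reports every sequence's
#' residue there plus membership in the aromatic set {F, Y, W, H} — the
#' Tyr54-style check. Gapped sequences report `-` and are not aromatic.
#'
#' @param msa tibble with `sequence_id`, `aligned` (and optionally `group`).
#' @param ref_id reference `sequence_id`.
#' @param ref_residue_number 1-based residue number in the reference.
#' @return tibble with `sequence_id` (and `group` if present), `residue`,
#'   `is_aromatic`; the alignment column is attached as attribute
#'   `"column"` (0-based).
#' @export
aromatic_check <- function(msa, ref_id, ref_residue_number) {
  num <- map_reference_numbering(msa, ref_id)
  hit <- num$column[!is.na(num$ref_position) &
                      num$ref_position == ref_residue_number]
  if (length(hit) == 0) {
    abort(paste0("residue ", ref_residue_number,
                 " is beyond the ungapped reference length"))
  }
  m <- msa_matrix(msa)
  res <- m[, hit + 1L]
  out <- tibble(sequence_id = msa$sequence_id, residue = unname(res),
                is_aromatic = res %in% c("F", "Y", "W", "H"))
  if ("group" %in% names(msa)) out$group <- msa$group
  attr(out, "column") <- hit
  out
}

#' Divergence track plot for a two-group alignment
#'
#' Pooled conservation per column with divergent columns highlighted.
#'
#' @param object a tibble from [column_stats()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
plot_column_stats <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$column,
                                       y = .data$pooled_modal_freq)) +
    ggplot2::geom_col(ggplot2::aes(fill = .data$divergent), width = 0.9) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70",
                                          `TRUE` = "firebrick"),
                               name = "divergent") +
    ggplot2::labs(x = "alignment column (0-based)",
                  y = "pooled modal frequency") +
    ggplot2::theme_minimal()
}
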