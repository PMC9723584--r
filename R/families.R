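#' Greedy centroid clustering of proteins into families
#'
#' Single-pass greedy clustering: proteins are sorted by length (descending,
#' ties by ID), and each joins the first existing centroid it reaches at
#' `identity_threshold` identity with an alignment covering at least
#' `coverage` of both sequences, otherwise it founds a new family. Identity
#' is matches / alignment length of a local BLOSUM62 alignment; coverage is
#' the aligned span over each sequence's length. The sort makes the
#' partition canonical: permuting the input never changes it.
#'
#' @param proteins tibble with columns `protein_id`, `sequence` (amino
#'   acids). Gene IDs double as protein IDs throughout the package.
#' @param identity_threshold minimum fractional identity to a centroid.
#' @param coverage minimum mutual alignment coverage (both sequences).
#' @return an object of class `protein_families`; its `members` element is a
#'   tibble with `protein_id`, `family_id`, `centroid_id`, `is_centroid`,
#'   `identity`, `coverage_min` (both `NA` for centroids themselves).
#' @export
cluster_families <- function(proteins, identity_threshold = 0.30,
                             coverage = 0.75) {
  stopifnot(all(c("protein_id", "sequence") %in% names(proteins)))
  if (any(nchar(proteins$sequence) == 0)) abort("empty protein sequence")
  if (anyDuplicated(proteins$protein_id)) abort("duplicate protein_id")
  ord <- order(-nchar(proteins$sequence), proteins$protein_id)
  proteins <- proteins[ord, ]
  n <- nrow(proteins)
  cent_idx <- integer(0)        # row indices of centroids, founding order
  fam <- integer(n)             # family index per row
  ident <- rep(NA_real_, n)
  covmin <- rep(NA_real_, n)
  seqs <- proteins$sequence
  lens <- nchar(seqs)
  for (i in seq_len(n)) {
    assigned <- FALSE
    if (length(cent_idx)) {
      # mutual coverage is impossible when lengths are too discrepant;
      # 0.8 slack leaves room for gapped spans
      cand <- cent_idx[pmin(lens[cent_idx], lens[i]) /
                         pmax(lens[cent_idx], lens[i]) >= coverage * 0.8]
      if (length(cand)) {
        aln <- Biostrings::pairwiseAlignment(
          pattern = Biostrings::AAStringSet(seqs[cand]),
          subject = Biostrings::AAString(seqs[i]),
          type = "local", substitutionMatrix = "BLOSUM62",
          gapOpening = 10, gapExtension = 0.5)
        aln_len <- nchar(as.character(Biostrings::pattern(aln)))
        idv <- Biostrings::nmatch(aln) / aln_len
        pw <- Biostrings::end(Biostrings::pattern(aln)) -
          Biostrings::start(Biostrings::pattern(aln)) + 1
        covp <- pw / lens[cand]
        sw <- Biostrings::end(Biostrings::subject(aln)) -
          Biostrings::start(Biostrings::subject(aln)) + 1
        covs <- sw / lens[i]
        ok <- which(idv >= identity_threshold & covp >= coverage &
                      covs >= coverage)
        if (length(ok)) {
          k <- ok[1]  # first centroid in founding order
          fam[i] <- match(cand[k], cent_idx)
          ident[i] <- idv[k]
          covmin[i] <- pmin(covp[k], covs[k])
          assigned <- TRUE
        }
      }
    }
    if (!assigned) {
      cent_idx <- c(cent_idx, i)
      fam[i] <- length(cent_idx)
    }
  }
  members <- tibble(
    protein_id = proteins$protein_id,
    family_id = sprintf("fam%03d", fam),
    centroid_id = proteins$protein_id[cent_idx[fam]],
    is_centroid = seq_len(n) %in% cent_idx,
    identity = ident,
    coverage_min = covmin
  ) %>% arrange(.data$family_id, desc(.data$is_centroid), .data$protein_id)
  structure(list(members = members,
                 identity_threshold = identity_threshold,
                 coverage = coverage),
            class = "protein_families")
}

#' @export
print.protein_families <- function(x, ...) {
  cat(sprintf("<protein_families> %d proteins in %d families (identity >= %.2f, coverage >= %.2f)\n",
              nrow(x$members), n_distinct(x$members$family_id),
              x$identity_threshold, x$coverage))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.protein_families <- function(x, ...) x$members

#' @export
glance.protein_families <- function(x, ...) {
  tibble(n_proteins = nrow(x$members),
         n_families = n_distinct(x$members$family_id),
         largest_family = max(table(x$members$family_id)),
         identity_threshold = x$identity_threshold,
         coverage = x$coverage)
}

#' Consensus annotation of one protein family
#'
#' Among hits with `e_value < e_max`, the label hitting the most distinct
#' member proteins wins, provided it hits at least `min_frac` of the family
#' (ties broken lexicographically by label); otherwise the family is
#' "hyp" (hypothetical).
#'
#' @param member_ids character vector of the family's protein IDs.
#' @param hits tibble with columns `protein_id`, `label`, `e_value`.
#' @param e_max e-value threshold (hits at or above it are ignored).
#' @param min_frac minimum fraction of members the winning label must hit.
#' @return a single label string.
#' @export
consensus_annotation <- function(member_ids, hits, e_max = 1e-5,
                                 min_frac = 0.05) {
  if (nrow(hits) > 0 && any(hits$e_value <= 0)) {
    abort("e_value must be > 0")
  }
  h <- hits %>%
    filter(.data$e_value < e_max, .data$protein_id %in% member_ids) %>%
    distinct(.data$protein_id, .data$label)
  if (nrow(h) == 0) return("hyp")
  tally <- h %>% count(.data$label) %>%
    arrange(desc(.data$n), .data$label)
  if (tally$n[1] >= min_frac * length(member_ids)) tally$label[1] else "hyp"
}

#' Consensus annotations for every family
#'
#' @param families a `protein_families` object (or its `members` tibble).
#' @param hits annotation-hit table (`protein_id`, `label`, `e_value`).
#' @inheritParams consensus_annotation
#' @return a tibble with `family_id`, `n_members`, `consensus_label`.
#' @export
annotate_families <- function(families, hits, e_max = 1e-5, min_frac = 0.05) {
  members <- if (inherits(families, "protein_families")) families$members
             else families
  members %>%
    group_by(.data$family_id) %>%
    summarise(n_members = n(),
              consensus_label = consensus_annotation(
                .data$protein_id, hits, e_max = e_max, min_frac = min_frac),
              .groups = "drop")
}
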