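#' Extract the gene neighborhood around an anchor gene
#'
#' Collects up to `radius` genes on each side of the anchor in scaffold
#' coordinate order and assigns each a relative position (anchor = 0,
#' negative before, positive after). Windows truncate at scaffold ends.
#' With `reorient = TRUE`, if the designated marker gene (matched against
#' `product_label`) lies at a negative position, all signs are flipped so
#' profiles from mirrored assemblies line up.
#'
#' @param genes gene table (one genome, or the anchor's genome is selected).
#' @param anchor_id `gene_id` of the anchor.
#' @param radius window half-width in genes.
#' @param reorient logical; flip signs when the marker sits upstream.
#' @param marker_label `product_label` of the orientation marker (default
#'   major capsid protein).
#' @return a tibble with columns `anchor_gene_id`, `genome_id`, `gene_id`,
#'   `rel_pos`, `same_strand_as_anchor`, `product_label`, plus attributes
#'   `truncated_left`/`truncated_right`.
#' @export
extract_neighborhood <- function(genes, anchor_id, radius = 10L,
                                 reorient = FALSE,
                                 marker_label = "major capsid protein") {
  if (!anchor_id %in% genes$gene_id) {
    abort(paste0("anchor gene not found: ", anchor_id))
  }
  g0 <- genes$genome_id[genes$gene_id == anchor_id][1]
  gg <- genes %>% filter(.data$genome_id == g0) %>% arrange(.data$start)
  i <- which(gg$gene_id == anchor_id)
  lo <- max(1L, i - radius)
  hi <- min(nrow(gg), i + radius)
  nb <- gg[lo:hi, ]
  rel <- (lo:hi) - i
  if (reorient) {
    marker_pos <- rel[nb$product_label == marker_label & rel != 0]
    if (length(marker_pos) && all(marker_pos < 0)) {
      rel <- -rel
      ord <- order(rel)
      nb <- nb[ord, ]
      rel <- rel[ord]
    }
  }
  out <- tibble(
    anchor_gene_id = anchor_id,
    genome_id = g0,
    gene_id = nb$gene_id,
    rel_pos = as.integer(rel),
    same_strand_as_anchor = nb$strand == gg$strand[i],
    product_label = if ("product_label" %in% names(nb)) nb$product_label else ""
  )
  attr(out, "truncated_left") <- (i - lo) < radius
  attr(out, "truncated_right") <- (hi - i) < radius
  out
}

#' Extract neighborhoods around every gene matching an anchor label
#'
#' Convenience wrapper: finds anchors by `product_label` across all genomes
#' and binds their neighborhoods. A genome with several anchors yields one
#' neighborhood per anchor.
#'
#' @param genes gene table across genomes.
#' @param anchor_label `product_label` identifying anchor genes.
#' @inheritParams extract_neighborhood
#' @return row-bound neighborhoods (see [extract_neighborhood()]).
#' @export
extract_neighborhoods <- function(genes, anchor_label = "ribosomal protein S21",
                                  radius = 10L, reorient = FALSE,
                                  marker_label = "major capsid protein") {
  anchors <- genes$gene_id[genes$product_label == anchor_label]
  if (length(anchors) == 0) {
    abort(paste0("no gene labelled '", anchor_label, "'"))
  }
  purrr::map_dfr(anchors, function(a) {
    extract_neighborhood(genes, a, radius = radius, reorient = reorient,
                         marker_label = marker_label)
  })
}
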