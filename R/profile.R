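#' Family-by-position occurrence profile
#'
#' Counts, for every (protein family, relative position) cell, the number of
#' distinct genomes whose anchor neighborhood places a member of that family
#' at that position — the quantity drawn as circle sizes in a
#' family-vs-position bubble plot. Also reports each family's mean absolute
#' distance to the anchor.
#'
#' @param neighborhoods row-bound neighborhood tibble from
#'   [extract_neighborhoods()].
#' @param assignment tibble mapping genes to families (`protein_id` or
#'   `gene_id` column plus `family_id`), e.g. `tidy(cluster_families(...))`.
#' @param labels optional tibble (`family_id`, `consensus_label`) from
#'   [annotate_families()], joined onto the output.
#' @return an object of class `position_profile` with elements `counts`
#'   (tibble: `family_id`, `rel_pos`, `n_genomes`, optionally
#'   `consensus_label`), `distances` (tibble: `family_id`,
#'   `mean_abs_distance`, `n_occurrences`) and `n_neighborhoods`.
#' @export
position_profile <- function(neighborhoods, assignment, labels = NULL) {
  if ("protein_id" %in% names(assignment) && !"gene_id" %in% names(assignment)) {
    assignment <- rename(assignment, gene_id = "protein_id")
  }
  if (nrow(neighborhoods) == 0) {
    out <- list(counts = tibble(family_id = character(), rel_pos = integer(),
                                n_genomes = integer()),
                distances = tibble(family_id = character(),
                                   mean_abs_distance = numeric(),
                                   n_occurrences = integer()),
                n_neighborhoods = 0L)
    return(structure(out, class = "position_profile"))
  }
  joined <- left_join(neighborhoods, select(assignment, "gene_id", "family_id"),
                      by = "gene_id")
  if (any(is.na(joined$family_id))) {
    abort(paste0("gene not assigned to any family: ",
                 joined$gene_id[is.na(joined$family_id)][1]))
  }
  counts <- joined %>%
    distinct(.data$family_id, .data$rel_pos, .data$genome_id) %>%
    count(.data$family_id, .data$rel_pos, name = "n_genomes") %>%
    arrange(.data$family_id, .data$rel_pos)
  distances <- joined %>%
    group_by(.data$family_id) %>%
    summarise(mean_abs_distance = mean(abs(.data$rel_pos)),
              n_occurrences = n(), .groups = "drop")
  if (!is.null(labels)) {
    counts <- left_join(counts, labels, by = "family_id")
    distances <- left_join(distances, labels, by = "family_id")
  }
  structure(list(
    counts = counts, distances = distances,
    n_neighborhoods = nrow(distinct(neighborhoods, .data$genome_id,
                                    .data$anchor_gene_id))
  ), class = "position_profile")
}

#' @export
print.position_profile <- function(x, ...) {
  cat(sprintf("<position_profile> %d neighborhoods, %d families\n",
              x$n_neighborhoods, n_distinct(x$counts$family_id)))
  invisible(x)
}

#' @export
tidy.position_profile <- function(x, ...) x$counts

#' @export
glance.position_profile <- function(x, ...) {
  tibble(n_neighborhoods = x$n_neighborhoods,
         n_families = n_distinct(x$counts$family_id),
         max_cell = if (nrow(x$counts)) max(x$counts$n_genomes) else 0L)
}

#' Bubble plot of a position profile
#'
#' Families on the y axis (most frequent on top, optionally only the top
#' `top_k`), relative position on the x axis, circle area proportional to
#' the number of genomes.
#'
#' @param object a `position_profile`.
#' @param top_k keep only the `top_k` most frequent families (`Inf` = all).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.position_profile <- function(object, top_k = 12, ...) {
  counts <- object$counts
  keep <- counts %>%
    group_by(.data$family_id) %>%
    summarise(total = sum(.data$n_genomes), .groups = "drop") %>%
    arrange(desc(.data$total), .data$family_id) %>%
    head(top_k)
  counts <- counts %>% filter(.data$family_id %in% keep$family_id)
  ylab <- if ("consensus_label" %in% names(counts)) {
    counts <- mutate(counts, family = paste0(.data$family_id, " (",
                                             .data$consensus_label, ")"))
    "family (consensus annotation)"
  } else {
    counts <- mutate(counts, family = .data$family_id)
    "family"
  }
  fam_order <- counts %>%
    group_by(.data$family) %>%
    summarise(total = sum(.data$n_genomes), .groups = "drop") %>%
    arrange(.data$total)
  counts$family <- factor(counts$family, levels = fam_order$family)
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$rel_pos, y = .data$family,
                                       size = .data$n_genomes)) +
    ggplot2::geom_point(alpha = 0.8, colour = "steelblue") +
    ggplot2::scale_size_area(max_size = 8) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = "position relative to anchor (0 = anchor)", y = ylab,
                  size = "genomes") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Cluster genomes by protein-family presence/absence
#'
#' Builds the binary genome-by-family matrix over genomes passing the size
#' filter, computes Jaccard distances, runs average-linkage hierarchical
#' clustering, and counts the families shared by every retained genome
#' (the shared core).
#'
#' @param genomes genome table (supplies lengths for the size filter).
#' @param gene_families tibble with columns `genome_id`, `family_id` (one
#'   row per gene; duplicates collapse).
#' @param min_genome_bp minimum genome size retained; the 100 kbp default
#'   restricts the comparison to large, near-complete genomes.
#' @return an object of class `pa_clustering` with elements `matrix` (binary,
#'   rows = genomes sorted by ID), `jaccard` (a `dist`), `hclust`, `newick`
#'   (average-linkage dendrogram as a newick string) and
#'   `shared_family_count`.
#' @export
presence_absence_clustering <- function(genomes, gene_families,
                                        min_genome_bp = 100000L) {
  check_genomes(genomes)
  stopifnot(all(c("genome_id", "family_id") %in% names(gene_families)))
  keep <- genomes$genome_id[nchar(genomes$sequence) >= min_genome_bp]
  gf <- gene_families %>%
    filter(.data$genome_id %in% keep) %>%
    distinct(.data$genome_id, .data$family_id)
  gids <- sort(unique(gf$genome_id))
  if (length(gids) < 2) {
    abort("fewer than 2 genomes pass the size filter")
  }
  fids <- sort(unique(gf$family_id))
  mat <- matrix(0L, nrow = length(gids), ncol = length(fids),
                dimnames = list(gids, fids))
  mat[cbind(match(gf$genome_id, gids), match(gf$family_id, fids))] <- 1L
  shared <- sum(colSums(mat) == nrow(mat))
  d <- stats::dist(mat, method = "binary")  # Jaccard distance on 0/1 rows
  hc <- hclust(d, method = "average")
  newick <- ape::write.tree(ape::as.phylo(hc))
  structure(list(matrix = mat, jaccard = d, hclust = hc, newick = newick,
                 shared_family_count = shared,
                 min_genome_bp = min_genome_bp),
            class = "pa_clustering")
}

#' @export
print.pa_clustering <- function(x, ...) {
  cat(sprintf("<pa_clustering> %d genomes x %d families; %d shared by all\n",
              nrow(x$matrix), ncol(x$matrix), x$shared_family_count))
  invisible(x)
}

#' @param k number of clusters to cut the dendrogram into.
#' @rdname presence_absence_clustering
#' @export
tidy.pa_clustering <- function(x, k = 2, ...) {
  cl <- cutree(x$hclust, k = k)
  tibble(genome_id = names(cl), cluster = unname(cl))
}

#' @export
glance.pa_clustering <- function(x, ...) {
  tibble(n_genomes = nrow(x$matrix), n_families = ncol(x$matrix),
         shared_family_count = x$shared_family_count,
         min_genome_bp = x$min_genome_bp)
}

#' @export
autoplot.pa_clustering <- function(object, ...) {
  ord <- object$hclust$labels[object$hclust$order]
  df <- as.data.frame(as.table(object$matrix))
  names(df) <- c("genome_id", "family_id", "present")
  df$genome_id <- factor(df$genome_id, levels = ord)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$family_id, y = .data$genome_id,
                                   fill = factor(.data$present))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(`0` = "grey95", `1` = "steelblue"),
                               name = "present") +
    ggplot2::labs(x = "protein family", y = "genome (dendrogram order)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}
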