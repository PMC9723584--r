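#' Read gene annotations from GFF3
#'
#' Consumes CDS features. GFF3 1-based inclusive coordinates are converted to
#' the package-internal 0-based half-open convention at this boundary. Genes
#' are returned sorted by (genome_id, start). Wrap-around genes (end beyond
#' the genome) are rejected: the coordinate convention on circular genomes is
#' undefined upstream and the generator never emits them.
#'
#' @param path path to a GFF3 file.
#' @param genomes optional genome table; when given, coordinates are checked
#'   against sequence lengths.
#' @return a tibble with columns `gene_id`, `genome_id`, `start`, `end`
#'   (0-based half-open), `strand`, `product_label`.
#' @export
read_gene_gff <- function(path, genomes = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble(gene_id = character(), genome_id = character(),
                  start = integer(), end = integer(), strand = character(),
                  product_label = character()))
  }
  fields <- stringr::str_split_fixed(lines, "\t", 9)
  if (ncol(fields) < 9) abort("malformed GFF3: fewer than 9 columns")
  keep <- fields[, 3] == "CDS"
  fields <- fields[keep, , drop = FALSE]
  start1 <- suppressWarnings(as.integer(fields[, 4]))
  end1 <- suppressWarnings(as.integer(fields[, 5]))
  strand <- fields[, 7]
  if (any(is.na(start1)) || any(is.na(end1))) {
    abort("malformed GFF3: non-integer coordinates")
  }
  if (any(!strand %in% c("+", "-"))) {
    abort(paste0("unknown strand character in GFF3: ",
                 strand[!strand %in% c("+", "-")][1]))
  }
  attr_field <- fields[, 9]
  get_attr <- function(key) {
    m <- stringr::str_match(attr_field, paste0("(?:^|;)", key, "=([^;]*)"))[, 2]
    ifelse(is.na(m), "", m)
  }
  ids <- get_attr("ID")
  if (any(ids == "")) abort("GFF3 CDS feature lacks an ID attribute")
  genes <- tibble(
    gene_id = ids,
    genome_id = fields[, 1],
    start = start1 - 1L,
    end = end1,
    strand = strand,
    product_label = get_attr("product")
  )
  check_genes(genes, genomes)
}

#' Write gene annotations to GFF3
#'
#' Internal 0-based half-open coordinates are converted back to GFF3 1-based
#' inclusive. Rows are written sorted by (genome_id, start); bytes are
#' deterministic.
#'
#' @param genes a gene table (`gene_id`, `genome_id`, `start`, `end`,
#'   `strand`, optionally `product_label`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_gff <- function(genes, path) {
  genes <- check_genes(genes)
  product <- if ("product_label" %in% names(genes)) genes$product_label else ""
  attrs <- paste0("ID=", genes$gene_id,
                  ifelse(product == "" | is.na(product), "",
                         paste0(";product=", product)))
  lines <- paste(genes$genome_id, "phagecontext", "CDS",
                 genes$start + 1L, genes$end, ".", genes$strand, "0",
                 attrs, sep = "\t")
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}
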