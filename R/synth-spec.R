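#' Synthetic-world specification
#'
#' Collects every tunable of the synthetic-data generators in one validated
#' object. Defaults emulate the statistical structure of curated freshwater
#' bS21-phage genomes at test scale: ~30 kb circular genomes (the real
#' genomes are ~300 kb; `genome_length = 300000` reproduces that scale), GC
#' around 32%, coding density ~93%, clades of related genomes, and an RNA
#' expression profile in which the anchor gene and core structural genes are
#' highly transcribed.
#'
#' @param seed integer seed; every generator derived from this spec is fully
#'   deterministic given the seed.
#' @param n_genomes number of phage genomes to simulate.
#' @param genome_length genome length in bp.
#' @param gc_target target GC fraction in (0, 1).
#' @param mean_gene_length mean gene length in bp.
#' @param coding_density_target target coding density fraction.
#' @param n_clades number of clades; genomes are distributed round-robin.
#' @param within_clade_divergence per-site substitution probability applied
#'   independently to each clade member relative to the clade founder; two
#'   members then share an expected nucleotide identity of
#'   `(1 - d)^2 + d^2 / 3`.
#' @param clade_protein_divergence per-residue substitution probability
#'   between the ancestral conserved-module proteins and each clade's copy
#'   (keeps cross-clade module proteins at >= 80% amino-acid identity).
#' @param expression_profile named numeric vector of relative expression
#'   weights per gene role; roles not listed fall back to `"background"`.
#' @param read_length simulated read length in bp.
#' @param depth mean sequencing depth (fold coverage).
#' @param error_rate per-base substitution error rate of simulated reads.
#' @return an object of class `synth_spec`.
#' @export
synth_spec <- function(seed,
                       n_genomes = 12L,
                       genome_length = 30000L,
                       gc_target = 0.32,
                       mean_gene_length = 900L,
                       coding_density_target = 0.93,
                       n_clades = 3L,
                       within_clade_divergence = 0.02,
                       clade_protein_divergence = 0.08,
                       expression_profile = c(
                         bS21 = 10, hyp_flank_up = 8, hyp_flank_down = 3,
                         MCP = 15, TerL = 5, portal = 5,
                         prohead_protease = 5, core_hyp = 2, background = 1),
                       read_length = 150L,
                       depth = 20,
                       error_rate = 0.005) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    abort("`seed` is mandatory and must be a single integer")
  }
  if (gc_target <= 0 || gc_target >= 1) abort("gc_target must be in (0, 1)")
  if (depth <= 0) abort("depth must be > 0")
  if (n_genomes < 1 || n_clades < 1 || n_clades > n_genomes) {
    abort("need n_genomes >= n_clades >= 1")
  }
  if (within_clade_divergence < 0 || within_clade_divergence > 0.5) {
    abort("within_clade_divergence must be in [0, 0.5]")
  }
  if (!"background" %in% names(expression_profile)) {
    expression_profile <- c(expression_profile, background = 1)
  }
  structure(list(
    seed = as.integer(seed), n_genomes = as.integer(n_genomes),
    genome_length = as.integer(genome_length), gc_target = gc_target,
    mean_gene_length = as.integer(mean_gene_length),
    coding_density_target = coding_density_target,
    n_clades = as.integer(n_clades),
    within_clade_divergence = within_clade_divergence,
    clade_protein_divergence = clade_protein_divergence,
    expression_profile = expression_profile,
    read_length = as.integer(read_length), depth = depth,
    error_rate = error_rate
  ), class = "synth_spec")
}

#' @export
print.synth_spec <- function(x, ...) {
  cat("<synth_spec>\n")
  cat(sprintf("  seed %d | %d genomes in %d clades | %d bp, GC %.2f, density %.2f\n",
              x$seed, x$n_genomes, x$n_clades, x$genome_length, x$gc_target,
              x$coding_density_target))
  cat(sprintf("  reads %d bp at %gx, error %g | within-clade divergence %g\n",
              x$read_length, x$depth, x$error_rate, x$within_clade_divergence))
  invisible(x)
}
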