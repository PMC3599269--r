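#' Pipeline configuration
#'
#' Bundle of the tunable constants used across the annotation pipeline.
#' Defaults follow the conventions of comparative annotation of a
#' pyrosequenced yeast assembly against a finished reference: boundary
#' corrections limited to a 9-codon displacement, variant integration
#' requiring 60% read support, ortholog rescue restricted to the ten
#' best-ranked hits per query, 100 samples of 50 proteins for phylogenetic
#' placement, terminal 10% chromosome deciles for subtelomere enrichment,
#' 1-kb coverage windows, a 500-bp contig floor, and a Bonferroni-corrected
#' alpha of 0.2 for phenotype contrasts.
#'
#' @param stop_window_codons Codon displacement searched for a missing stop.
#' @param start_window_codons Codon displacement searched for a missing start.
#' @param min_variant_support Minimum read-support fraction for a variant
#'   to be integrated during polishing.
#' @param min_homopolymer_run Minimum run length (bp) for a single-base run
#'   to count as a homopolymer.
#' @param rescue_max_rank Deepest hit rank considered during syntenic rescue.
#' @param sample_count Number of random gene sets for placement.
#' @param genes_per_sample Genes concatenated per placement sample.
#' @param decile_fraction Terminal chromosome fraction treated as subtelomeric.
#' @param coverage_window_bp Width of coverage windows in bp.
#' @param min_contig_len Contigs shorter than this are excluded from metrics.
#' @param alpha Significance level after Bonferroni correction.
#' @param rng_seed Integer seed recorded with every run.
#' @return A list of class `pipeline_config`.
#' @export
#' @examples
#' cfg <- pipeline_config(rng_seed = 1)
#' cfg$stop_window_codons
pipeline_config <- function(stop_window_codons = 9L,
                            start_window_codons = 9L,
                            min_variant_support = 0.6,
                            min_homopolymer_run = 3L,
                            rescue_max_rank = 10L,
                            sample_count = 100L,
                            genes_per_sample = 50L,
                            decile_fraction = 0.1,
                            coverage_window_bp = 1000L,
                            min_contig_len = 500L,
                            alpha = 0.2,
                            rng_seed = 1L) {
  cfg <- list(stop_window_codons = as.integer(stop_window_codons),
              start_window_codons = as.integer(start_window_codons),
              min_variant_support = min_variant_support,
              min_homopolymer_run = as.integer(min_homopolymer_run),
              rescue_max_rank = as.integer(rescue_max_rank),
              sample_count = as.integer(sample_count),
              genes_per_sample = as.integer(genes_per_sample),
              decile_fraction = decile_fraction,
              coverage_window_bp = as.integer(coverage_window_bp),
              min_contig_len = as.integer(min_contig_len),
              alpha = alpha,
              rng_seed = as.integer(rng_seed))
  counts <- c("stop_window_codons", "start_window_codons",
              "min_homopolymer_run", "rescue_max_rank", "sample_count",
              "genes_per_sample", "coverage_window_bp", "min_contig_len")
  for (f in counts)
    if (cfg[[f]] <= 0L) stop("config field '", f, "' must be positive")
  for (f in c("min_variant_support", "decile_fraction", "alpha"))
    if (cfg[[f]] <= 0 || cfg[[f]] > 1)
      stop("config field '", f, "' must lie in (0, 1]")
  structure(cfg, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("arborator pipeline configuration\n")
  for (f in names(x)) cat(sprintf("  %-22s %s\n", f, format(x[[f]])))
  invisible(x)
}
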