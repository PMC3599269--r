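#' Generate and write a complete synthetic study to a run directory
#'
#' Simulates an ancestor, evolves a descendant under `params`, builds a
#' noisy hit table, and writes FASTA + GFF3 for both genomes, the hit
#' table, a variant table restoring any planted assembly errors, and the
#' truth tables as JSON.
#'
#' @param dir Output directory (created if needed).
#' @param n_chrom,genes_per_chrom Ancestor dimensions.
#' @param params An [evolution_params()].
#' @param decoy_prob,score_jitter Hit-table noise (see
#'   [make_hit_table()]).
#' @param rng_seed Integer seed.
#' @return Invisibly, the in-memory objects (`ancestor`, `derived`,
#'   `hits`).
#' @export
write_synthetic_run <- function(dir, n_chrom = 2L, genes_per_chrom = 50L,
                                params = evolution_params(),
                                decoy_prob = 0.3, score_jitter = 0.02,
                                rng_seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  anc <- simulate_ancestor(n_chrom, genes_per_chrom, rng_seed = rng_seed)
  der <- evolve(anc$genome, anc[c("genes", "trnas")], params)
  hits <- make_hit_table(anc$genes, der$genes, der$truth,
                         decoy_prob = decoy_prob,
                         score_jitter = score_jitter,
                         rng_seed = rng_seed + 1L)
  write_fasta(anc$genome, file.path(dir, "ancestor.fa"))
  write_gff3(anc$genes, file.path(dir, "ancestor.gff3"), trnas = anc$trnas)
  write_fasta(der$genome, file.path(dir, "target.fa"))
  write_gff3(der$genes, file.path(dir, "target.gff3"), trnas = der$trnas)
  write_hits_tsv(hits, file.path(dir, "hits.tsv"))
  truth <- der$truth
  truth$params <- unclass(truth$params)
  jsonlite::write_json(
    list(pairs = as.list(truth$pairs), lost = truth$lost,
         hp_indels = truth$hp_indels,
         rearrangements = lapply(truth$rearrangements, function(ev) {
           ev$breakpoints <- as.data.frame(ev$breakpoints)
           ev
         }),
         params = truth$params),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(list(ancestor = anc, derived = der, hits = hits))
}
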