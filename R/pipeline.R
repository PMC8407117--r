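#' Run the full competition-GWAS pipeline on simulated data
#'
#' Chains every stage: genome/phenotype/nodule-count simulation, occupancy
#' phenotyping, k-mer GWAS with clonal structure correction, selection of the
#' best k-mers (those carried by exactly the top-competitor strains), nested
#' cross-validated prediction, and mapping of the best k-mers back to the
#' annotated genomes. The phenotype fed to the association is the mean
#' single-nodule occupancy estimated from the simulated plants, so sampling
#' noise propagates as it would from a real assay.
#'
#' @param cfg a [sim_config()].
#' @param mode occupancy mode passed to [mean_occupancy()].
#' @param top_n,alpha,model_seed tuning passed through to the stages.
#' @return list with `sim`, `counts`, `occupancy`, `phenotype`, `gwas`,
#'   `best` (the [select_best_kmers()] result for the true carrier set),
#'   `model`, `hits`, `hit_summary`, `regions`.
#' @export
run_competition_pipeline <- function(cfg = sim_config(),
                                     mode = "single",
                                     top_n = 1000L, alpha = 0.05,
                                     model_seed = cfg$seed) {
  sim <- simulate_genomes(cfg)
  sim <- simulate_phenotype(sim)
  counts <- simulate_nodule_counts(sim)
  occ <- mean_occupancy(counts, mode = mode)
  phenotype <- normalize_for_gwas(occ, unique(counts$competition_id)[1L])
  gwas <- kmer_gwas(sim, phenotype, k = cfg$k, alpha = alpha)
  carriers <- sim$truth$carrier_map[[cfg$causal_block_id]]
  best <- select_best_kmers(gwas$association, gwas$kmers,
                            carrier_set = carriers)
  model <- fit_kmer_model(gwas, top_n = top_n, seed = model_seed)
  hits <- locate_kmers(best$exact, sim)
  cls <- classify_hits(hits, sim$annotation)
  hs <- if (nrow(cls)) summarize_hits(cls, sim$annotation) else NULL
  regions <- carrier_exclusive_regions(cls, sim$annotation, carriers)
  list(sim = sim, counts = counts, occupancy = occ, phenotype = phenotype,
       gwas = gwas, best = best, model = model, hits = cls,
       hit_summary = hs, regions = regions)
}

#' Write pipeline outputs as plain-text artifacts
#'
#' Emits the association table (TSV), GSC weights (TSV), strain tree
#' (Newick), occupancy matrix (TSV), model report (JSON) and classified hits
#' (TSV) under one directory; byte-identical across runs for identical inputs.
#'
#' @param result output of [run_competition_pipeline()].
#' @param dir output directory.
#' @return invisibly, `dir`.
#' @export
write_pipeline_outputs <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(x, f) utils::write.table(
    x, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  assoc <- as.data.frame(result$gwas$association)
  assoc$t <- sprintf("%.10g", assoc$t)
  assoc$df <- sprintf("%.10g", assoc$df)
  assoc$p <- sprintf("%.10g", assoc$p)
  assoc$delta_mu <- sprintf("%.10g", assoc$delta_mu)
  tsv(assoc, "association.tsv")
  tsv(data.frame(strain = names(result$gwas$weights),
                 weight = sprintf("%.10g", result$gwas$weights)),
      "gsc_weights.tsv")
  ape::write.tree(as_phylo(result$gwas$tree), file.path(dir, "tree.nwk"))
  occ <- result$occupancy$values
  tsv(cbind(strain = rownames(occ),
            as.data.frame(apply(occ, 2L, sprintf, fmt = "%.10g"))),
      "occupancy.tsv")
  jsonlite::write_json(
    list(features = result$model$features,
         lambda = result$model$final$lambda,
         coefficients = as.list(result$model$final$coefficients),
         fold_metrics = result$model$fold_metrics,
         mean_metrics = as.list(result$model$mean_metrics)),
    file.path(dir, "model.json"), auto_unbox = TRUE, digits = 10)
  tsv(result$hits, "hits.tsv")
  tsv(result$regions, "regions.tsv")
  if (!is.null(result$hit_summary)) {
    rf <- result$hit_summary$replicon_fractions
    tsv(cbind(strain = rownames(rf), as.data.frame(round(rf, 10))),
        "replicon_fractions.tsv")
  }
  invisible(dir)
}

#' Write classified hits as a BED track
#'
#' Converts 1-based inclusive hit coordinates to BED's 0-based half-open
#' intervals at write time.
#'
#' @param hits output of [classify_hits()] or [locate_kmers()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_hits_bed <- function(hits, path) {
  k <- if (nrow(hits)) nchar(hits$kmer) else integer(0)
  bed <- data.frame(chrom = hits$replicon,
                    start = hits$position - 1L,
                    end = hits$position - 1L + k,
                    name = hits$kmer,
                    score = 0L,
                    strand = hits$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
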