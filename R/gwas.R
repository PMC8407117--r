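#' k-mer genome-wide association with clonal structure correction
#'
#' The package's central fit: counts canonical k-mers across strain genomes,
#' derives clonal population-structure weights (Jaccard distance on the full
#' k-mer profiles, UPGMA dendrogram, Gerstein-Sonnhammer-Chothia weights),
#' filters k-mers on presence/absence support, and tests each retained k-mer
#' against the continuous phenotype with the weighted Welch two-sample t-test,
#' keeping k-mers at p <= `alpha`.
#'
#' @param genomes named list (strain) of named character vectors
#'   (replicon -> sequence), a `rhizo_sim`, or a directory of FASTA files.
#' @param phenotype named numeric vector of occupancy fractions in \[0, 1\],
#'   one per strain (see [normalize_for_gwas()]).
#' @param k k-mer length.
#' @param min_present,min_absent support filter (see [filter_kmers()]).
#' @param alpha retention threshold on the per-k-mer p-value.
#' @param weights optional strain weights; by default computed from the data.
#' @param adjust multiple-testing adjustment passed to [run_association()].
#' @return an object of class `kmer_gwas`: list with `association`
#'   (the [run_association()] table), `kmers` (filtered `kmer_matrix`),
#'   `n_total` (k-mers before filtering), `distance`, `tree`, `weights`,
#'   `phenotype`, `k` and `call`.
#' @seealso [fit_kmer_model()] for the downstream predictive regression,
#'   [locate_kmers()] for mapping selected k-mers back to the genomes.
#' @examples
#' cfg <- sim_config(n_strains = 6,
#'                   replicon_lengths = c(chromosome = 4000, pSymA = 4000),
#'                   accessory_blocks = list(list(id = "block_A", length = 800,
#'                                                replicon = 2, carriers = 1:3)),
#'                   seed = 3)
#' sim <- simulate_phenotype(simulate_genomes(cfg), noise_sd = 0)
#' fit <- kmer_gwas(sim, sim$truth$true_phenotype)
#' fit
#' @export
kmer_gwas <- function(genomes, phenotype, k = 13L, min_present = 2L,
                      min_absent = 2L, alpha = 0.05, weights = NULL,
                      adjust = c("none", "BH")) {
  cl <- match.call()
  if (is.character(genomes) && length(genomes) == 1L && dir.exists(genomes))
    genomes <- read_genomes(genomes)
  km <- count_kmers(genomes, k = k)
  d <- kmer_distance(km)
  tree <- upgma(d)
  if (is.null(weights)) weights <- gsc_weights(tree)
  kf <- filter_kmers(km, min_present = min_present, min_absent = min_absent)
  assoc <- run_association(kf, phenotype, weights = weights, alpha = alpha,
                           adjust = match.arg(adjust))
  if (!is.null(names(phenotype))) phenotype <- phenotype[rownames(km$counts)]
  structure(list(
    association = assoc,
    kmers = kf,
    n_total = ncol(km$counts),
    distance = d,
    tree = tree,
    weights = weights,
    phenotype = phenotype,
    k = k,
    call = cl
  ), class = "kmer_gwas")
}

#' @export
print.kmer_gwas <- function(x, ...) {
  cat("k-mer GWAS (k = ", x$k, ")\n", sep = "")
  cat("  strains:           ", length(x$weights), "\n", sep = "")
  cat("  k-mers counted:    ", x$n_total, "\n", sep = "")
  cat("  k-mers tested:     ", attr(x$association, "n_tested"),
      " (after support filter)\n", sep = "")
  cat("  significant:       ", nrow(x$association), " at p <= ",
      attr(x$association, "alpha"), "\n", sep = "")
  pr <- attr(x$association, "p_range")
  if (!anyNA(pr))
    cat("  p-value range:     ", format(pr[2], digits = 3), " - ",
        format(pr[1], digits = 3), "\n", sep = "")
  invisible(x)
}

#' @export
summary.kmer_gwas <- function(object, n = 10L, ...) {
  print(object)
  cat("\nGSC strain weights:\n")
  print(round(object$weights, 3))
  cat("\ntop k-mers:\n")
  print.data.frame(utils::head(as.data.frame(object$association), n),
                   digits = 4)
  invisible(object)
}

#' Plot a k-mer GWAS fit
#'
#' Left: the UPGMA dendrogram of strains (clonal structure the weights
#' correct for). Right: the p-value spectrum of retained k-mers.
#'
#' @param x a `kmer_gwas`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.kmer_gwas <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  ape::plot.phylo(as_phylo(x$tree), main = "strain UPGMA tree", ...)
  if (nrow(x$association)) {
    graphics::plot(seq_len(nrow(x$association)), -log10(x$association$p),
                   xlab = "k-mer rank", ylab = "-log10 p",
                   main = "retained k-mers", pch = 20)
  } else {
    graphics::plot.new()
    graphics::title("no retained k-mers")
  }
  invisible(x)
}

#' Residuals of the single-feature group model per k-mer
#'
#' For the top k-mer (or a chosen one), returns phenotype residuals around the
#' weighted group means of carriers and non-carriers.
#'
#' @param object a `kmer_gwas`.
#' @param kmer k-mer string (default: the top-ranked one).
#' @param ... unused.
#' @export
residuals.kmer_gwas <- function(object, kmer = NULL, ...) {
  if (nrow(object$association) == 0L) stop("no retained k-mers",
                                           call. = FALSE)
  kmer <- kmer %||% object$association$kmer[1L]
  pres <- kmer_presence(object$kmers)[, kmer]
  w <- object$weights
  x <- object$phenotype
  mu1 <- sum(w[pres] * x[pres]) / sum(w[pres])
  mu0 <- sum(w[!pres] * x[!pres]) / sum(w[!pres])
  x - ifelse(pres, mu1, mu0)
}
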