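#' Per-plant nodule occupancy fractions
#'
#' Converts raw per-plant nodule counts into occupancy fractions: each colour
#' count divided by the plant's total nodule count. Plants with zero nodules
#' carry no occupancy information and are excluded with a warning.
#'
#' @param counts a nodule count data frame (see [read_nodule_counts()]).
#' @return the table with added columns `f_green`, `f_red`, `f_mixed`
#'   (summing to 1 per row); zero-total rows dropped.
#' @examples
#' x <- data.frame(competition_id = "c", strain_id = "s", plant_id = "p",
#'                 n_green = 6, n_red = 3, n_mixed = 1)
#' plant_occupancy(x)[, c("f_green", "f_red", "f_mixed")]
#' @export
plant_occupancy <- function(counts) {
  counts <- validate_nodule_counts(counts)
  total <- counts$n_green + counts$n_red + counts$n_mixed
  zero <- total == 0L
  if (any(zero)) {
    warning(sum(zero), " plant(s) with zero nodules excluded: ",
            paste(utils::head(paste(counts$strain_id[zero],
                                    counts$plant_id[zero]), 5L),
                  collapse = "; "), call. = FALSE)
    counts <- counts[!zero, , drop = FALSE]
    total <- total[!zero]
  }
  counts$f_green <- counts$n_green / total
  counts$f_red <- counts$n_red / total
  counts$f_mixed <- counts$n_mixed / total
  rownames(counts) <- NULL
  counts
}

#' Mean nodule occupancy per strain and competition
#'
#' Averages per-plant occupancy ratios over the replicate plants of each
#' (strain, competition) cell -- the mean of ratios, not the ratio of pooled
#' counts (a pooled estimator is available via `pooled = TRUE` for sensitivity
#' analysis). `mode = "single"` uses the green (tester-only) fraction;
#' `mode = "single_plus_mixed"` adds the mixed-nodule fraction.
#'
#' @param counts nodule count data frame.
#' @param mode `"single"` or `"single_plus_mixed"`.
#' @param pooled if `TRUE`, pool nodule counts across plants instead of
#'   averaging per-plant ratios.
#' @return an object of class `occupancy_matrix`: list with `values`
#'   (strain x competition matrix of fractions), `n_plants` (replicates per
#'   cell) and `mode`.
#' @export
mean_occupancy <- function(counts, mode = c("single", "single_plus_mixed"),
                           pooled = FALSE) {
  mode <- match.arg(mode)
  before <- unique(paste(counts$strain_id, counts$competition_id, sep = "\r"))
  occ <- plant_occupancy(counts)
  after <- unique(paste(occ$strain_id, occ$competition_id, sep = "\r"))
  lost <- setdiff(before, after)
  if (length(lost)) {
    parts <- strsplit(lost, "\r", fixed = TRUE)[[1L]]
    stop("all plants excluded for strain ", parts[1L], " in competition ",
         parts[2L], call. = FALSE)
  }
  strains <- sort(unique(occ$strain_id), method = "radix")
  comps <- sort(unique(occ$competition_id), method = "radix")
  val <- matrix(NA_real_, length(strains), length(comps),
                dimnames = list(strains, comps))
  npl <- matrix(0L, length(strains), length(comps),
                dimnames = list(strains, comps))
  si <- match(occ$strain_id, strains)
  ci <- match(occ$competition_id, comps)
  for (cell in split(seq_len(nrow(occ)), paste(si, ci))) {
    i <- si[cell[1L]]; j <- ci[cell[1L]]
    if (pooled) {
      g <- sum(occ$n_green[cell]); m <- sum(occ$n_mixed[cell])
      tot <- g + sum(occ$n_red[cell]) + m
      val[i, j] <- (g + if (mode == "single_plus_mixed") m else 0) / tot
    } else {
      f <- occ$f_green[cell] +
        if (mode == "single_plus_mixed") occ$f_mixed[cell] else 0
      val[i, j] <- mean(f)
    }
    npl[i, j] <- length(cell)
  }
  structure(list(values = val, n_plants = npl, mode = mode),
            class = "occupancy_matrix")
}

#' @export
print.occupancy_matrix <- function(x, ...) {
  cat("occupancy_matrix (mode =", x$mode, "):",
      nrow(x$values), "strains x", ncol(x$values), "competitions\n")
  print(round(x$values, 3), ...)
  invisible(x)
}

#' Phenotype vector for association analysis
#'
#' Extracts one competition column as a continuous phenotype in \[0, 1\].
#' Fraction-scale values pass through unchanged; a column on the percent scale
#' (any value > 1) is divided by 100; values above 100 are rejected.
#'
#' @param matrix an `occupancy_matrix` (or plain numeric matrix, strains in
#'   rows).
#' @param competition_id column to extract.
#' @return named numeric vector in \[0, 1\] with attribute `mode`.
#' @examples
#' m <- matrix(c(93.4, 50.5), 2, 1,
#'             dimnames = list(c("GR4", "HM006"), "vs_Rm1021"))
#' normalize_for_gwas(m, "vs_Rm1021")
#' @export
normalize_for_gwas <- function(matrix, competition_id = NULL) {
  mode <- if (inherits(matrix, "occupancy_matrix")) matrix$mode else NA
  vals <- if (inherits(matrix, "occupancy_matrix")) matrix$values else matrix
  competition_id <- competition_id %||% colnames(vals)[1L]
  if (!competition_id %in% colnames(vals))
    stop("competition '", competition_id, "' not found", call. = FALSE)
  x <- vals[, competition_id]
  if (any(x > 100))
    stop("input-scale error: occupancy values above 100", call. = FALSE)
  if (any(x > 1)) x <- x / 100
  if (!is.na(mode)) attr(x, "mode") <- mode
  x
}

#' Classify competitor strength from single nodule occupancy
#'
#' Good competitors occupy more than 60% of nodules, weak competitors fewer
#' than 20%, and values in \[0.20, 0.60\] (boundaries included) are medium.
#'
#' @param value numeric vector of occupancy fractions in \[0, 1\].
#' @return character vector in `{"good", "medium", "weak"}`.
#' @examples
#' classify_competitor(c(0.639, 0.60, 0.017))
#' @export
classify_competitor <- function(value) {
  if (any(value < 0 | value > 1))
    stop("occupancy fraction out of [0, 1]", call. = FALSE)
  ifelse(value > 0.60, "good", ifelse(value < 0.20, "weak", "medium"))
}

#' PCA of strains on competition mean occupancies
#'
#' Column-mean-centred principal component analysis via singular value
#' decomposition, without variable scaling. The sign of each component is
#' fixed so its largest-magnitude loading is positive.
#'
#' @param matrix an `occupancy_matrix` or plain numeric matrix (strains in
#'   rows, competitions in columns), no missing cells.
#' @return list with `scores` (strain x component), `loadings`
#'   (competition x component) and `explained_variance` (fractions; all zero
#'   when the matrix has no variance).
#' @export
pca_strains <- function(matrix) {
  vals <- if (inherits(matrix, "occupancy_matrix")) matrix$values else matrix
  if (nrow(vals) < 2L || ncol(vals) < 2L)
    stop("need at least 2 strains and 2 competitions", call. = FALSE)
  if (anyNA(vals))
    stop("missing cells: impute or drop incomplete strains before PCA",
         call. = FALSE)
  pc <- stats::prcomp(vals, center = TRUE, scale. = FALSE)
  scores <- pc$x
  loadings <- pc$rotation
  for (j in seq_len(ncol(loadings))) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  v <- pc$sdev^2
  ev <- if (sum(v) > 0) v / sum(v) else rep(0, length(v))
  list(scores = scores, loadings = loadings, explained_variance = ev)
}

#' Permutational multivariate analysis of variance on occupancy profiles
#'
#' Computes the pseudo-F statistic on Euclidean distances between strain
#' occupancy profiles, `F = (SS_between/(g-1)) / (SS_within/(n-g))`, and a
#' permutation p-value `p = (1 + #{F* >= F}) / (1 + n_perm)` over seeded
#' random relabelings. With more than two groups, pairwise tests with
#' Bonferroni correction are added.
#'
#' @param matrix an `occupancy_matrix` or numeric matrix (strains in rows).
#' @param groups named character/factor of group labels per strain, or an
#'   unnamed vector in row order.
#' @param n_perm number of label permutations.
#' @param seed integer seed for the permutations.
#' @param method distance metric passed to [stats::dist()].
#' @return list of class `permanova` with `F`, `p`, `n_perm`, `groups` and,
#'   for more than two groups, a `pairwise` data frame with Bonferroni-adjusted
#'   p-values.
#' @export
permanova <- function(matrix, groups, n_perm = 999L, seed = 1L,
                      method = "euclidean") {
  vals <- if (inherits(matrix, "occupancy_matrix")) matrix$values else matrix
  if (!is.null(names(groups))) {
    if (!all(rownames(vals) %in% names(groups)))
      stop("groups must cover every strain", call. = FALSE)
    groups <- groups[rownames(vals)]
  }
  groups <- as.character(groups)
  if (length(groups) != nrow(vals))
    stop("one group label per strain required", call. = FALSE)
  if (any(table(groups) < 2L))
    stop("every group needs at least 2 strains", call. = FALSE)
  d2 <- as.matrix(stats::dist(vals, method = method))^2
  res <- with_seed(seed, permanova_one(d2, groups, n_perm))
  out <- list(F = res$F, p = res$p, n_perm = n_perm, groups = groups,
              method = method)
  labs <- sort(unique(groups))
  if (length(labs) > 2L) {
    pairs <- utils::combn(labs, 2L)
    pw <- with_seed(seed + 1L, apply(pairs, 2L, function(pr) {
      idx <- groups %in% pr
      r <- permanova_one(d2[idx, idx, drop = FALSE], groups[idx], n_perm)
      c(F = r$F, p = r$p)
    }))
    out$pairwise <- data.frame(
      group1 = pairs[1L, ], group2 = pairs[2L, ],
      F = pw["F", ], p = pw["p", ],
      p_bonferroni = pmin(1, pw["p", ] * ncol(pairs))
    )
  }
  structure(out, class = "permanova")
}

# pseudo-F and permutation p for one labeling; RNG state is the caller's
permanova_one <- function(d2, groups, n_perm) {
  n <- nrow(d2)
  labs <- unique(groups)
  g <- length(labs)
  ss_within <- function(gr) {
    s <- 0
    for (l in labs) {
      idx <- which(gr == l)
      s <- s + sum(d2[idx, idx]) / (2 * length(idx))
    }
    s
  }
  ss_t <- sum(d2) / (2 * n)
  f_of <- function(gr) {
    sw <- ss_within(gr)
    ((ss_t - sw) / (g - 1)) / (sw / (n - g))
  }
  f_obs <- f_of(groups)
  if (n_perm < 1L) return(list(F = f_obs, p = 1))
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    if (f_of(sample(groups)) >= f_obs) exceed <- exceed + 1L
  }
  list(F = f_obs, p = (1 + exceed) / (1 + n_perm))
}

#' @export
print.permanova <- function(x, ...) {
  cat("PERMANOVA (", x$method, " distance): pseudo-F = ",
      format(x$F, digits = 4), ", p = ", format(x$p, digits = 4),
      " (", x$n_perm, " permutations)\n", sep = "")
  if (!is.null(x$pairwise)) {
    cat("pairwise (Bonferroni-corrected):\n")
    print(x$pairwise, digits = 4)
  }
  invisible(x)
}
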