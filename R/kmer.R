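#' Count canonical k-mers per strain genome
#'
#' Slides a window of length `k` over every replicon of every strain, maps
#' each window to its canonical form (lexicographic minimum of the window and
#' its reverse complement) and aggregates counts per strain. Windows
#' containing N are skipped; records shorter than `k` are skipped with a
#' warning; any other non-IUPAC character is an error naming the record and
#' offset.
#'
#' @param genomes named list (strain) of named character vectors
#'   (replicon id -> sequence), as from [read_genomes()] or a `rhizo_sim`.
#' @param k k-mer length (default 13).
#' @return an object of class `kmer_matrix`: list with `counts` (strain x
#'   k-mer integer matrix, k-mers as sorted canonical strings) and `k`.
#' @examples
#' m <- count_kmers(list(s1 = c(r1 = "ACGTACGTACGTA")), k = 13)
#' m$counts
#' @export
count_kmers <- function(genomes, k = 13L) {
  if (inherits(genomes, "rhizo_sim")) genomes <- genomes$genomes
  k <- as.integer(k)
  tabs <- vector("list", length(genomes))
  for (s in seq_along(genomes)) {
    reps <- genomes[[s]]
    wins <- vector("list", length(reps))
    for (r in seq_along(reps)) {
      seq <- toupper(reps[[r]])
      rec <- paste0(names(genomes)[s], "/",
                    names(reps)[r] %||% paste0("record", r))
      check_alphabet(seq, rec)
      if (nchar(seq) < k) {
        warning("record ", rec, " shorter than k; skipped", call. = FALSE)
        next
      }
      wins[[r]] <- seq_kmers(seq, k)
    }
    tabs[[s]] <- table(unlist(wins, use.names = FALSE))
  }
  all_k <- sort(unique(unlist(lapply(tabs, names), use.names = FALSE)),
                method = "radix")
  counts <- matrix(0L, length(genomes), length(all_k),
                   dimnames = list(names(genomes), all_k))
  for (s in seq_along(tabs)) {
    if (length(tabs[[s]]))
      counts[s, match(names(tabs[[s]]), all_k)] <- as.integer(tabs[[s]])
  }
  structure(list(counts = counts, k = k), class = "kmer_matrix")
}

#' @export
print.kmer_matrix <- function(x, ...) {
  cat("kmer_matrix: ", nrow(x$counts), " strains x ", ncol(x$counts),
      " canonical ", x$k, "-mers\n", sep = "")
  invisible(x)
}

#' Presence matrix of a k-mer count matrix
#'
#' @param x a `kmer_matrix`.
#' @return logical strain x k-mer matrix (`count >= 1`).
#' @export
kmer_presence <- function(x) {
  stopifnot(inherits(x, "kmer_matrix"))
  x$counts >= 1L
}

#' Filter k-mers on presence/absence support
#'
#' Retains a k-mer only if it is present in at least `min_present` strains
#' and absent from at least `min_absent` strains (the "min 2 / max 2"
#' default), discarding near-monomorphic k-mers that cannot support a
#' two-group test.
#'
#' @param x a `kmer_matrix`.
#' @param min_present,min_absent minimum strains with / without the k-mer.
#' @return the filtered `kmer_matrix`.
#' @export
filter_kmers <- function(x, min_present = 2L, min_absent = 2L) {
  stopifnot(inherits(x, "kmer_matrix"))
  pres <- colSums(x$counts >= 1L)
  keep <- pres >= min_present & (nrow(x$counts) - pres) >= min_absent
  x$counts <- x$counts[, keep, drop = FALSE]
  x
}

#' Jaccard distances between strain k-mer profiles
#'
#' `d(i, j) = 1 - |K_i intersect K_j| / |K_i union K_j|` on the presence sets
#' of the (unfiltered) k-mer matrix. This exact Jaccard distance on 13-mer
#' profiles is the desk-scale equivalent of the sketch-based genome distances
#' large-scale tools estimate.
#'
#' @param x a `kmer_matrix` or a logical strain x k-mer presence matrix.
#' @return symmetric distance matrix with zero diagonal, entries in \[0, 1\].
#' @export
kmer_distance <- function(x) {
  P <- if (inherits(x, "kmer_matrix")) kmer_presence(x) else (x >= 1L)
  storage.mode(P) <- "numeric"
  sizes <- rowSums(P)
  if (any(sizes == 0))
    stop("strain(s) with zero k-mers: ",
         paste(rownames(P)[sizes == 0], collapse = ", "), call. = FALSE)
  inter <- tcrossprod(P)
  un <- outer(sizes, sizes, "+") - inter
  d <- 1 - inter / un
  diag(d) <- 0
  d
}

#' UPGMA clustering of strains
#'
#' Average-linkage agglomeration of a distance matrix; the merge height is
#' half the average distance, so the tree is ultrametric. Ties are broken
#' deterministically: among equally close pairs the one whose clusters contain
#' the lowest original strain indices merges first.
#'
#' @param d symmetric distance matrix (or `dist`).
#' @return an object of class `strain_tree`: list with `merge` (hclust-style),
#'   `height` (node heights, i.e. distance/2), `labels` and `n`.
#' @examples
#' d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' upgma(d)$height
#' @export
upgma <- function(d) {
  D <- as.matrix(d)
  if (anyNA(D)) stop("NaN/NA in distance matrix", call. = FALSE)
  n <- nrow(D)
  if (n < 2L) stop("need at least two strains", call. = FALSE)
  labels <- rownames(D) %||% paste0("t", seq_len(n))
  code <- -seq_len(n)         # hclust convention: negatives are leaves
  rep_idx <- seq_len(n)       # smallest original leaf index per cluster
  size <- rep(1L, n)
  active <- seq_len(n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (m in seq_len(n - 1L)) {
    na <- length(active)
    best <- NULL
    for (a in seq_len(na - 1L)) for (b in (a + 1L):na) {
      i <- active[a]; j <- active[b]
      dij <- D[i, j]
      key <- sort(c(rep_idx[i], rep_idx[j]))
      if (is.null(best) || dij < best$d - 1e-15 ||
          (abs(dij - best$d) <= 1e-15 &&
           (key[1L] < best$key[1L] ||
            (key[1L] == best$key[1L] && key[2L] < best$key[2L])))) {
        best <- list(d = dij, i = i, j = j, key = key)
      }
    }
    i <- best$i; j <- best$j
    merge[m, ] <- sort(c(code[i], code[j]))
    height[m] <- best$d / 2
    # average-linkage update into slot i
    for (o in setdiff(active, c(i, j)))
      D[i, o] <- D[o, i] <- (size[i] * D[i, o] + size[j] * D[j, o]) /
        (size[i] + size[j])
    size[i] <- size[i] + size[j]
    rep_idx[i] <- min(rep_idx[i], rep_idx[j])
    code[i] <- m
    active <- setdiff(active, j)
  }
  structure(list(merge = merge, height = height, labels = labels, n = n),
            class = "strain_tree")
}

#' @export
print.strain_tree <- function(x, ...) {
  cat("UPGMA strain_tree with", x$n, "leaves; root height",
      format(max(x$height), digits = 4), "\n")
  invisible(x)
}

#' Convert a strain tree to an ape phylogeny
#'
#' @param tree a `strain_tree`.
#' @return an object of class `phylo` (rooted, ultrametric).
#' @export
as_phylo <- function(tree) {
  stopifnot(inherits(tree, "strain_tree"))
  n <- tree$n
  # phylo node numbering: leaves 1..n, root n+1; merge m maps to 2n - m so
  # the final merge (the root) gets number n + 1
  nnode <- n - 1L
  edges <- matrix(0L, 2L * nnode, 2L)
  lens <- numeric(2L * nnode)
  node_id <- function(m) 2L * n - m
  height_of <- function(code) if (code < 0L) 0 else tree$height[code]
  e <- 0L
  for (m in seq_len(nnode)) {
    parent <- node_id(m)
    for (child_code in tree$merge[m, ]) {
      child <- if (child_code < 0L) -child_code else node_id(child_code)
      e <- e + 1L
      edges[e, ] <- c(parent, child)
      lens[e] <- tree$height[m] - height_of(child_code)
    }
  }
  phy <- list(edge = edges, edge.length = lens, tip.label = tree$labels,
              Nnode = nnode)
  class(phy) <- "phylo"
  ape::reorder.phylo(phy, "cladewise")
}

#' Gerstein-Sonnhammer-Chothia strain weights
#'
#' Tree-derived sample weights for clonal population-structure correction:
#' traversing from the leaves to the root, the length of each edge is
#' distributed among the leaves below it in proportion to their accumulated
#' weights (equally when those are all zero, as for a clone pair at distance
#' zero). Near-identical genomes thus share weight that distinct genomes keep
#' to themselves. Weights are normalized to sum to the number of strains.
#'
#' @param tree a `strain_tree` from [upgma()].
#' @param normalize if `FALSE`, return the raw accumulated branch lengths.
#' @return named numeric vector of positive weights (summing to `n` when
#'   normalized).
#' @export
gsc_weights <- function(tree, normalize = TRUE) {
  stopifnot(inherits(tree, "strain_tree"))
  if (any(tree$height < -1e-12) || any(diff(tree$height) < -1e-9))
    stop("negative branch length", call. = FALSE)
  n <- tree$n
  w <- numeric(n)
  leaves <- c(as.list(seq_len(n)), vector("list", n - 1L))
  node_height <- c(rep(0, n), tree$height)
  for (m in seq_len(n - 1L)) {
    h <- tree$height[m]
    kids <- tree$merge[m, ]
    below <- integer(0L)
    for (child_code in kids) {
      idx <- if (child_code < 0L) -child_code else n + child_code
      lv <- leaves[[idx]]
      len <- h - node_height[idx]
      if (len > 0) {
        cw <- w[lv]
        w[lv] <- if (sum(cw) <= 0) w[lv] + len / length(lv)
                 else w[lv] + len * cw / sum(cw)
      }
      below <- c(below, lv)
    }
    leaves[[n + m]] <- below
  }
  names(w) <- tree$labels
  if (!normalize) return(w)
  if (sum(w) <= 0) return(stats::setNames(rep(1, n), tree$labels))
  w * n / sum(w)
}

#' Weighted Welch two-sample t-test
#'
#' Unequal-variance two-sample t-test with per-sample weights: for each group
#' the weighted mean, weighted variance and Kish effective sample size
#' `n_eff = (sum w)^2 / sum w^2` replace their unweighted counterparts, and
#' the degrees of freedom follow Welch-Satterthwaite on
#' `(s^2/n_eff, n_eff - 1)`. With all weights equal this reduces exactly to
#' the classic Welch test. The statistic is invariant to rescaling all
#' weights.
#'
#' @param x numeric phenotype vector.
#' @param present logical vector (or index vector) defining group 1; the rest
#'   of the samples form group 2.
#' @param weights positive weights, same length as `x` (default: equal).
#' @return list with `t`, `df`, `p` (two-sided), `mean_present`,
#'   `mean_absent`, `delta_mu`.
#' @examples
#' weighted_welch_test(c(0.1, 0.2, 0.3, 0.6, 0.7, 0.8),
#'                     present = c(rep(FALSE, 3), rep(TRUE, 3)))
#' @export
weighted_welch_test <- function(x, present, weights = NULL) {
  if (!is.logical(present)) {
    p <- rep(FALSE, length(x)); p[present] <- TRUE; present <- p
  }
  if (is.null(weights)) weights <- rep(1, length(x))
  stopifnot(length(present) == length(x), length(weights) == length(x),
            all(weights > 0))
  if (!any(present) || all(present))
    stop("both groups must be nonempty", call. = FALSE)
  P <- matrix(present, ncol = 1L)
  st <- welch_stats(P, x, weights)
  if (st$skip[1L])
    stop("effective sample size <= 1 in a group", call. = FALSE)
  list(t = st$t[1L], df = st$df[1L], p = st$p[1L],
       mean_present = st$mu1[1L], mean_absent = st$mu0[1L],
       delta_mu = st$delta[1L])
}

# Vectorized weighted Welch statistics over the columns of a logical
# presence matrix P (samples x k-mers). Returns one entry per column.
welch_stats <- function(P, x, w) {
  storage.mode(P) <- "numeric"
  Q <- 1 - P
  grp <- function(M) {
    W <- drop(crossprod(M, w))
    A <- drop(crossprod(M, w * x))
    Q2 <- drop(crossprod(M, w * x^2))
    W2 <- drop(crossprod(M, w^2))
    mu <- A / W
    S <- pmax(Q2 - mu^2 * W, 0)          # sum w (x - mu)^2, guarded
    neff <- W^2 / W2
    s2 <- S * neff / ((neff - 1) * W)
    list(mu = mu, s2 = s2, neff = neff)
  }
  g1 <- grp(P); g0 <- grp(Q)
  skip <- g1$neff <= 1 + 1e-12 | g0$neff <= 1 + 1e-12
  v1 <- g1$s2 / g1$neff
  v0 <- g0$s2 / g0$neff
  se2 <- v1 + v0
  delta <- g1$mu - g0$mu
  t <- delta / sqrt(se2)
  df <- se2^2 / (v1^2 / (g1$neff - 1) + v0^2 / (g0$neff - 1))
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  # zero variance in both groups: p = 1 for equal means, else underflow clamp
  degen <- !skip & se2 <= 0
  eq <- degen & abs(delta) < 1e-12
  ne <- degen & !eq
  t[eq] <- 0; df[eq] <- Inf; p[eq] <- 1
  t[ne] <- sign(delta[ne]) * Inf; df[ne] <- Inf
  p[ne] <- .Machine$double.xmin
  list(t = t, df = df, p = p, mu1 = g1$mu, mu0 = g0$mu, delta = delta,
       skip = skip)
}

#' Association test of every retained k-mer with the phenotype
#'
#' Tests each k-mer's presence/absence split of the strains against the
#' continuous phenotype with the weighted Welch two-sample t-test, discards
#' k-mers with p above `alpha` (no multiple-testing correction by default,
#' matching the raw p < 0.05 screening of k-mer association tools;
#' Benjamini-Hochberg adjustment is available via `adjust = "BH"`), and sorts
#' ascending by p with ties broken by |t| descending then k-mer string.
#'
#' @param x a filtered `kmer_matrix`.
#' @param phenotype named numeric vector in \[0, 1\], one value per strain.
#' @param weights strain weights, e.g. from [gsc_weights()] (default equal).
#' @param alpha retention threshold on the (possibly adjusted) p-value.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return data frame of class `association_table` with columns `kmer`, `t`,
#'   `df`, `p`, `n_present`, `n_absent`, `delta_mu`; attributes `n_tested`,
#'   `n_skipped`, `p_range`, `alpha`.
#' @export
run_association <- function(x, phenotype, weights = NULL, alpha = 0.05,
                            adjust = c("none", "BH")) {
  stopifnot(inherits(x, "kmer_matrix"))
  adjust <- match.arg(adjust)
  strains <- rownames(x$counts)
  if (!is.null(names(phenotype))) {
    if (!all(strains %in% names(phenotype)))
      stop("phenotype does not cover all strains", call. = FALSE)
    phenotype <- phenotype[strains]
  } else if (length(phenotype) != length(strains)) {
    stop("phenotype/strain mismatch", call. = FALSE)
  }
  if (is.null(weights)) weights <- rep(1, length(strains))
  if (!is.null(names(weights))) weights <- weights[strains]
  P <- kmer_presence(x)              # strains x kmers
  npres <- colSums(P)
  st <- welch_stats(P, as.numeric(phenotype), as.numeric(weights))
  if (any(st$skip))
    message(sum(st$skip), " k-mer(s) skipped (effective group size <= 1)")
  p_out <- if (adjust == "BH") stats::p.adjust(st$p, "BH") else st$p
  keep <- !st$skip & p_out <= alpha
  tab <- data.frame(
    kmer = colnames(P)[keep],
    t = st$t[keep], df = st$df[keep], p = st$p[keep],
    n_present = as.integer(npres[keep]),
    n_absent = as.integer(nrow(P) - npres[keep]),
    delta_mu = st$delta[keep],
    stringsAsFactors = FALSE
  )
  ord <- order(tab$p, -abs(tab$t), tab$kmer, method = "radix")
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "n_tested") <- ncol(P)
  attr(tab, "n_skipped") <- sum(st$skip)
  attr(tab, "p_range") <- if (nrow(tab)) range(tab$p) else c(NA_real_, NA_real_)
  attr(tab, "alpha") <- alpha
  class(tab) <- c("association_table", "data.frame")
  tab
}

#' @export
print.association_table <- function(x, ...) {
  cat("association_table: ", nrow(x), " k-mers retained of ",
      attr(x, "n_tested"), " tested (p <= ", attr(x, "alpha"), ")\n", sep = "")
  pr <- attr(x, "p_range")
  if (!anyNA(pr))
    cat("p-value range: ", format(pr[2], digits = 3), " - ",
        format(pr[1], digits = 3), "\n", sep = "")
  print.data.frame(utils::head(x, 10L), digits = 4)
  if (nrow(x) > 10L) cat("... (", nrow(x) - 10L, " more rows)\n", sep = "")
  invisible(x)
}

#' Select the best-scoring k-mers and their carrier strains
#'
#' Returns all k-mers at or below `p_cut` together with the set of strains
#' carrying each, and -- when a query carrier set is given -- the subset of
#' k-mers whose carrier set equals it exactly (the "k-mers present precisely
#' in the top competitors" selection).
#'
#' @param table an `association_table`.
#' @param x the `kmer_matrix` the table was computed from (for carrier sets).
#' @param p_cut p-value cutoff (default: keep all retained k-mers).
#' @param carrier_set optional character vector of strain ids.
#' @return list with `table` (selected rows plus a `carriers` column) and
#'   `exact` (k-mers whose carriers equal `carrier_set`, or `NULL`).
#' @export
select_best_kmers <- function(table, x, p_cut = 1, carrier_set = NULL) {
  stopifnot(inherits(table, "association_table"), inherits(x, "kmer_matrix"))
  sel <- table[table$p <= p_cut, , drop = FALSE]
  P <- kmer_presence(x)
  strains <- rownames(P)
  carriers <- vapply(sel$kmer, function(km) {
    paste(strains[P[, km]], collapse = ",")
  }, character(1L))
  sel$carriers <- unname(carriers)
  rownames(sel) <- NULL
  exact <- NULL
  if (!is.null(carrier_set)) {
    want <- paste(strains[strains %in% carrier_set], collapse = ",")
    exact <- sel$kmer[sel$carriers == want]
  }
  list(table = sel, exact = exact)
}
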