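test_that("single-window and reverse-complement counting", {
  m <- count_kmers(list(s1 = c(r1 = "ACGTACGTACGTA")), k = 13)
  expect_equal(ncol(m$counts), 1L)
  km <- colnames(m$counts)
  expect_true(km %in% c("ACGTACGTACGTA",
                        revcomp("ACGTACGTACGTA")))
  expect_equal(km, canonical_kmer("ACGTACGTACGTA"))
  a <- count_kmers(list(s = c(r = "AAAAAAAAAAAAA")), k = 13)
  b <- count_kmers(list(s = c(r = "TTTTTTTTTTTTT")), k = 13)
  expect_identical(colnames(a$counts), "AAAAAAAAAAAAA")
  expect_identical(colnames(a$counts), colnames(b$counts))
})

test_that("counter equals the brute-force enumeration oracle", {
  set.seed(101)
  for (i in 1:20) {
    seq <- rand_seq(300)
    m <- count_kmers(list(s = c(r = seq)), k = 13)
    oracle <- naive_kmer_count(seq, 13)
    expect_identical(colnames(m$counts), names(oracle))
    expect_identical(unname(m$counts[1, ]), unname(as.integer(oracle)))
  }
})

test_that("N windows are skipped, short records warn, bad characters error", {
  seq <- "ACGTACGTACGTNACGTACGTACGTACG"
  m <- count_kmers(list(s = c(r = seq)), k = 13)
  oracle <- naive_kmer_count(seq, 13)
  expect_identical(unname(m$counts[1, ]), unname(as.integer(oracle)))
  expect_warning(count_kmers(list(s = c(short = "ACGT", r = rand_seq(20))),
                             k = 13), "shorter than k")
  expect_error(count_kmers(list(s = c(r = "ACGTXACGTACGTACGT")), k = 13),
               "non-IUPAC.*offset 5")
})

test_that("support filter keeps k-mers present in >=2 and absent in >=2", {
  sets <- c(
    list(one = c("AAA", "CCC")),                        # AAA in 1 strain only
    lapply(stats::setNames(1:12, paste0("x", 1:12)),
           function(i) c("CCC", "GGG"))
  )
  sets$two <- c("AAA", "CCC", "TTT")
  m <- kmer_matrix_from_sets(sets, k = 3)               # 14 strains
  f <- filter_kmers(m)
  expect_true("AAA" %in% colnames(f$counts))            # present 2, absent 12
  expect_false("CCC" %in% colnames(f$counts))           # present in all
  expect_false("TTT" %in% colnames(f$counts))           # present in 1
  expect_true("GGG" %in% colnames(f$counts))            # absent in 2
  # brute force over every column
  pres <- colSums(m$counts >= 1)
  keep <- names(pres)[pres >= 2 & (nrow(m$counts) - pres) >= 2]
  expect_identical(colnames(f$counts), keep)
})

test_that("Jaccard distances: identity, disjoint and a hand case", {
  m <- kmer_matrix_from_sets(list(a = c("AAA", "CCC"), b = c("AAA", "CCC"),
                                  c = c("GGG", "TTT"), d = c("AAA", "GGG")),
                             k = 3)
  d <- kmer_distance(m)
  expect_equal(d["a", "b"], 0)
  expect_equal(d["a", "c"], 1)
  expect_equal(d["a", "d"], 1 - 1 / 3)
  expect_true(isSymmetric(d))
  expect_equal(diag(d), stats::setNames(rep(0, 4), letters[1:4]))
  m$counts["a", ] <- 0L
  expect_error(kmer_distance(m), "zero k-mers")
})

test_that("UPGMA reproduces hand computations and is ultrametric", {
  d2 <- matrix(c(0, 0.4, 0.4, 0), 2, 2, dimnames = list(c("A", "B"),
                                                        c("A", "B")))
  t2 <- upgma(d2)
  expect_equal(t2$height, 0.2)
  d3 <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
               dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  t3 <- upgma(d3)
  expect_equal(t3$height, c(1, 2))
  expect_identical(t3$merge[1, ], c(-2L, -1L))   # A and B first
  phy <- as_phylo(t3)
  expect_true(ape::is.ultrametric(phy, tol = 1e-9))
  expect_error(upgma(matrix(c(0, NA, NA, 0), 2)), "NA")
})

test_that("UPGMA matches average-linkage hclust on random distances", {
  set.seed(31)
  for (i in 1:5) {
    X <- matrix(rnorm(60), 10)
    rownames(X) <- paste0("s", 1:10)
    D <- as.matrix(dist(X))
    tr <- upgma(D)
    hc <- stats::hclust(as.dist(D), method = "average")
    expect_equal(sort(tr$height * 2), sort(hc$height), tolerance = 1e-12)
    expect_equal(
      ape::cophenetic.phylo(as_phylo(tr))[rownames(D), rownames(D)],
      as.matrix(stats::cophenetic(hc))[rownames(D), rownames(D)],
      tolerance = 1e-10)
  }
})

test_that("UPGMA ties break deterministically on lowest strain indices", {
  d <- matrix(1, 4, 4, dimnames = list(paste0("s", 1:4), paste0("s", 1:4)))
  diag(d) <- 0
  t1 <- upgma(d)
  t2 <- upgma(d)
  expect_identical(t1, t2)
  expect_identical(t1$merge[1, ], c(-2L, -1L))   # s1 with s2 first
  expect_equal(t1$height, rep(0.5, 3))           # all merges at d/2
})

test_that("GSC weights: clone pair shares weight, symmetric trees are flat", {
  d <- matrix(c(0, 0, 2, 0, 0, 2, 2, 2, 0), 3, 3,
              dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  w <- gsc_weights(upgma(d))
  expect_equal(unname(w), c(0.75, 0.75, 1.5))
  expect_equal(sum(w), 3)
  for (n in c(4L, 8L)) {
    wb <- gsc_weights(upgma(balanced_dist(n)))
    expect_equal(unname(wb), rep(1, n))
  }
  star <- matrix(2, 5, 5, dimnames = list(paste0("s", 1:5), paste0("s", 1:5)))
  diag(star) <- 0
  expect_equal(unname(gsc_weights(upgma(star))), rep(1, 5))
})

test_that("duplicating a leaf at distance zero halves its raw weight", {
  d <- balanced_dist(4)
  w0 <- gsc_weights(upgma(d), normalize = FALSE)
  # add a clone of t1 at distance 0
  d5 <- rbind(cbind(d, t1b = d[, "t1"]), t1b = c(d["t1", ], 0))
  d5["t1", "t1b"] <- d5["t1b", "t1"] <- 0
  w5 <- gsc_weights(upgma(d5), normalize = FALSE)
  expect_equal(w5[["t1"]], w0[["t1"]] / 2)
  expect_equal(w5[["t1b"]], w0[["t1"]] / 2)
  expect_equal(w5[["t3"]], w0[["t3"]])
  expect_equal(sum(gsc_weights(upgma(d5))), 5)
})

test_that("weighted Welch reduces to the classic Welch test at equal weights", {
  res <- weighted_welch_test(c(0.1, 0.2, 0.3, 0.6, 0.7, 0.8),
                             present = c(rep(FALSE, 3), rep(TRUE, 3)))
  ref <- stats::t.test(c(0.6, 0.7, 0.8), c(0.1, 0.2, 0.3))
  expect_lt(abs(res$t - unname(ref$statistic)), 1e-10)
  expect_lt(abs(res$df - unname(ref$parameter)), 1e-10)
  expect_lt(abs(res$p - ref$p.value), 1e-10)
  set.seed(77)
  for (i in 1:200) {
    n <- sample(6:14, 1)
    x <- rnorm(n)
    g <- rep(FALSE, n)
    g[sample(n, sample(2:(n - 2), 1))] <- TRUE
    res <- weighted_welch_test(x, g)
    ref <- stats::t.test(x[g], x[!g])
    expect_lt(abs(res$t - unname(ref$statistic)), 1e-10)
    expect_lt(abs(res$df - unname(ref$parameter)), 1e-10)
    expect_lt(abs(res$p - ref$p.value), 1e-10)
  }
})

test_that("weighted Welch edge cases: null, scale invariance, degeneracy", {
  x <- c(1, 3, 2, 2, 2)
  g <- c(TRUE, TRUE, FALSE, FALSE, FALSE)   # both group means are 2
  res <- weighted_welch_test(x, g)
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)
  w1 <- weighted_welch_test(x, g, weights = rep(1, 5))
  w2 <- weighted_welch_test(x, g, weights = rep(0.5, 5))
  expect_equal(w1[c("t", "df", "p")], w2[c("t", "df", "p")])
  # zero variance in both groups, unequal means: p clamps above zero
  res2 <- weighted_welch_test(c(1, 1, 2, 2), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(res2$p, .Machine$double.xmin)
  expect_error(weighted_welch_test(x, rep(TRUE, 5)), "nonempty")
})

test_that("association keeps p <= alpha sorted by p, |t|, k-mer", {
  cfg <- small_cfg(seed = 17)
  sim <- simulate_phenotype(simulate_genomes(cfg), noise_sd = 0)
  ph <- sim$truth$true_phenotype
  km <- filter_kmers(count_kmers(sim))
  assoc <- run_association(km, ph, alpha = 0.05)
  expect_true(all(assoc$p <= 0.05))
  expect_true(all(diff(assoc$p) >= 0))
  ties <- split(seq_len(nrow(assoc)), assoc$p)
  for (idx in ties) {
    dt <- diff(abs(assoc$t[idx]))          # NaN when both t are infinite
    expect_true(all(is.nan(dt) | dt <= 1e-12))
  }
  expect_equal(assoc$n_present + assoc$n_absent,
               rep(nrow(km$counts), nrow(assoc)))
  # noiseless planted signal: causal k-mers attain the minimum p
  top <- assoc$kmer[assoc$p == min(assoc$p)]
  expect_true(any(top %in% sim$truth$causal_kmers))
  # constant phenotype: nothing is significant
  flat <- run_association(km, stats::setNames(rep(0.5, 6), names(ph)))
  expect_equal(nrow(flat), 0L)
  expect_error(run_association(km, c(a = 0.2)), "cover")
})

test_that("null phenotype yields roughly nominal per-k-mer type-I error", {
  set.seed(55)
  n <- 13
  P <- matrix(runif(n * 4000) < 0.5, n, 4000,
              dimnames = list(sprintf("S%02d", 1:n), NULL))
  pres <- colSums(P)
  P <- P[, pres >= 2 & (n - pres) >= 2]
  colnames(P) <- paste0("K", seq_len(ncol(P)))
  m <- structure(list(counts = P + 0L, k = 13L), class = "kmer_matrix")
  x <- stats::setNames(rnorm(n), rownames(P))
  assoc <- run_association(m, x, alpha = 1)
  frac <- mean(assoc$p <= 0.05)
  expect_gt(frac, 0.02)
  expect_lt(frac, 0.09)
})

test_that("best k-mer selection by p cut-off and exact carrier set", {
  cfg <- small_cfg(seed = 19)
  sim <- simulate_phenotype(simulate_genomes(cfg), noise_sd = 0.05)
  km <- filter_kmers(count_kmers(sim))
  assoc <- run_association(km, sim$truth$true_phenotype)
  expect_equal(nrow(select_best_kmers(assoc, km, p_cut = 0)$table), 0L)
  expect_equal(nrow(select_best_kmers(assoc, km, p_cut = 1)$table),
               nrow(assoc))
  sel <- select_best_kmers(assoc, km,
                           carrier_set = sim$truth$carrier_map$block_A)
  expect_gt(length(sel$exact), 0L)
  expect_true(all(sel$exact %in% sim$truth$causal_kmers))
})

test_that("kmer_gwas assembles the stages coherently", {
  cfg <- small_cfg(seed = 23)
  sim <- simulate_phenotype(simulate_genomes(cfg), noise_sd = 0)
  fit <- kmer_gwas(sim, sim$truth$true_phenotype)
  expect_s3_class(fit, "kmer_gwas")
  expect_equal(sum(fit$weights), cfg$n_strains)
  expect_true(all(fit$weights > 0))
  expect_gt(nrow(fit$association), 0)
  expect_lte(attr(fit$association, "n_tested"), fit$n_total)
  expect_output(print(fit), "k-mer GWAS")
  r <- residuals(fit)
  expect_length(r, cfg$n_strains)
  expect_lt(max(abs(r)), 1e-12)   # noiseless two-group phenotype fits exactly
})
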