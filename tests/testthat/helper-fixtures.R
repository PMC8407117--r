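# Shared fixtures and independent oracles, all built in code.

# compact simulation: 6 strains, 2 replicons, one 800-bp block in 3 strains
small_cfg <- function(seed = 1L, ...) {
  sim_config(
    n_strains = 6L,
    replicon_lengths = c(chromosome = 4000L, pSymA = 3000L),
    accessory_blocks = list(
      list(id = "block_A", length = 800L, replicon = 2L, carriers = 1:3)
    ),
    seed = seed,
    ...
  )
}

rand_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# brute-force k-mer counting oracle: per-window reverse complement built
# character by character, canonicalized by direct string comparison
naive_kmer_count <- function(seq, k = 13L) {
  n <- nchar(seq)
  out <- character(0L)
  if (n >= k) for (i in 1:(n - k + 1L)) {
    w <- substr(seq, i, i + k - 1L)
    if (grepl("N", w, fixed = TRUE)) next
    chars <- strsplit(w, "", fixed = TRUE)[[1L]]
    rc <- paste(rev(chartr("ACGT", "TGCA", chars)), collapse = "")
    out <- c(out, if (w <= rc) w else rc)
  }
  table(out)
}

# brute-force occurrence scan of both strands of one sequence
naive_locate <- function(kmer, seq) {
  k <- nchar(kmer)
  rc <- paste(rev(chartr("ACGT", "TGCA",
                         strsplit(kmer, "", fixed = TRUE)[[1L]])),
              collapse = "")
  hits <- list()
  for (i in 1:(nchar(seq) - k + 1L)) {
    w <- substr(seq, i, i + k - 1L)
    if (w == kmer) hits[[length(hits) + 1L]] <- c(i, "+")
    if (w == rc) hits[[length(hits) + 1L]] <- c(i, "-")
  }
  hits
}

# raw kmer_matrix from a named list of per-strain k-mer presence sets
kmer_matrix_from_sets <- function(sets, k = 13L) {
  all_k <- sort(unique(unlist(sets)), method = "radix")
  counts <- matrix(0L, length(sets), length(all_k),
                   dimnames = list(names(sets), all_k))
  for (s in names(sets)) counts[s, match(sets[[s]], all_k)] <- 1L
  structure(list(counts = counts, k = k), class = "kmer_matrix")
}

# balanced binary ultrametric distance matrix on 2^h leaves: the merge at
# level l sits at height l, so d(i, j) = 2 * (highest differing bit of
# i-1 and j-1, 1-based)
balanced_dist <- function(n_leaves) {
  stopifnot(log2(n_leaves) %% 1 == 0)
  d <- matrix(0, n_leaves, n_leaves)
  for (i in 1:(n_leaves - 1L)) for (j in (i + 1L):n_leaves) {
    lvl <- floor(log2(bitwXor(i - 1L, j - 1L))) + 1L
    d[i, j] <- d[j, i] <- 2 * lvl
  }
  dimnames(d) <- list(paste0("t", 1:n_leaves), paste0("t", 1:n_leaves))
  d
}
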