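toy_annotation <- function(len = 20000L, genes = NULL) {
  genes <- genes %||% data.frame(
    strain = "s", replicon = "s_chromosome",
    start = 10000L, end = 10900L, strand = "+",
    locus_tag = "g1", cog_id = "COG0410", ortholog_group = "OG1",
    stringsAsFactors = FALSE)
  genome_annotation(genes,
                    data.frame(strain = unique(genes$strain),
                               replicon = unique(genes$replicon),
                               length = len,
                               role = role_from_replicon(
                                 unique(genes$replicon))[1],
                               stringsAsFactors = FALSE))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("planted k-mers are located at their positions on both strands", {
  set.seed(61)
  km <- "ACCGTTAGGCATA"
  left <- rand_seq(50)
  seq <- paste0(left, km, rand_seq(50))
  g <- list(s = c(s_chr = seq))
  hits <- locate_kmers(km, g)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$position, 51L)
  expect_equal(hits$strand, "+")
  # present only as reverse complement: found on the minus strand
  g2 <- list(s = c(s_chr = paste0(left, revcomp(km), rand_seq(50))))
  hits2 <- locate_kmers(km, g2)
  expect_equal(hits2$position, 51L)
  expect_equal(hits2$strand, "-")
})

test_that("occurrence search equals a brute-force scan of both strands", {
  set.seed(67)
  reps <- lapply(1:6, function(i) rand_seq(2000))
  names(reps) <- paste0("s_r", 1:6)
  g <- list(s = reps)
  kmers <- unique(c(
    vapply(1:20, function(i) {
      r <- sample(6, 1)
      pos <- sample(1988, 1)
      canonical_kmer(substr(reps[[r]], pos, pos + 12L))
    }, character(1)),
    replicate(10, canonical_kmer(rand_seq(13)))))
  got <- locate_kmers(kmers, g)
  want <- list()
  for (km in kmers) for (r in names(reps)) {
    for (h in naive_locate(km, reps[[r]]))
      want[[length(want) + 1L]] <- data.frame(
        kmer = km, replicon = r, position = as.integer(h[1]), strand = h[2])
  }
  want <- do.call(rbind, want)
  want <- want[order(want$replicon, want$position, want$kmer, want$strand), ]
  got2 <- got[order(got$replicon, got$position, got$kmer, got$strand),
              c("kmer", "replicon", "position", "strand")]
  rownames(want) <- rownames(got2) <- NULL
  expect_equal(got2, want)
})

test_that("regulatory window arithmetic at the 600-nt boundary", {
  ann <- toy_annotation()
  occ <- function(pos) data.frame(kmer = "ACGTACGTACGTA", strain = "s",
                                  replicon = "s_chromosome",
                                  position = pos, strand = "+")
  # match 9400..9412: inside the [9400, 9999] window, 588 nt from the start
  reg <- classify_hits(occ(9400L), ann)
  expect_equal(reg$context, "regulatory")
  expect_equal(reg$distance_to_start, 588L)
  # match 9387..9399: entirely before the window
  expect_equal(classify_hits(occ(9387L), ann)$context, "intergenic")
  # match inside the gene
  cds <- classify_hits(occ(10100L), ann)
  expect_equal(cds$context, "CDS")
  expect_equal(cds$locus_tag, "g1")
  # window start clips at the replicon edge
  ann2 <- toy_annotation(genes = data.frame(
    strain = "s", replicon = "s_chromosome", start = 200L, end = 900L,
    strand = "+", locus_tag = "g1", stringsAsFactors = FALSE))
  early <- classify_hits(occ(5L), ann2)
  expect_equal(early$context, "regulatory")
  expect_equal(early$distance_to_start, 183L)
})

test_that("minus-strand upstream windows sit after the gene end", {
  ann <- toy_annotation(genes = data.frame(
    strain = "s", replicon = "s_chromosome", start = 5000L, end = 5900L,
    strand = "-", locus_tag = "g1", stringsAsFactors = FALSE))
  occ <- function(pos) data.frame(kmer = "ACGTACGTACGTA", strain = "s",
                                  replicon = "s_chromosome",
                                  position = pos, strand = "+")
  reg <- classify_hits(occ(6200L), ann)
  expect_equal(reg$context, "regulatory")
  expect_equal(reg$distance_to_start, 300L)     # 6200 - 5900
  expect_equal(classify_hits(occ(6501L), ann)$context, "intergenic")
  expect_equal(classify_hits(occ(5890L), ann)$context, "CDS")
})

test_that("one occurrence can tag several genes, CDS beats regulatory", {
  genes <- data.frame(
    strain = "s", replicon = "s_chromosome",
    start = c(1000L, 1010L, 1300L), end = c(1005L, 1400L, 1600L),
    strand = "+", locus_tag = c("gA", "gB", "gC"),
    stringsAsFactors = FALSE)
  ann <- toy_annotation(genes = genes)
  occ <- data.frame(kmer = "ACGTACGTACGTA", strain = "s",
                    replicon = "s_chromosome", position = 998L, strand = "+")
  rows <- classify_hits(occ, ann)
  expect_setequal(rows$locus_tag, c("gA", "gB"))   # overlaps both CDS
  expect_true(all(rows$context == "CDS"))          # never regulatory for gC
})

test_that("classification is invariant to reverse-complementing the genome", {
  set.seed(71)
  L <- 3000L
  seq <- rand_seq(L)
  genes <- data.frame(strain = "s", replicon = "s_chr",
                      start = c(1000L, 2200L), end = c(1500L, 2600L),
                      strand = c("+", "-"), locus_tag = c("g1", "g2"),
                      stringsAsFactors = FALSE)
  ann <- genome_annotation(genes, data.frame(
    strain = "s", replicon = "s_chr", length = L, role = "chr"))
  kmers <- canonical_kmer(vapply(c(1100L, 950L, 2650L, 500L), function(p)
    substr(seq, p, p + 12L), character(1)))
  h1 <- classify_hits(locate_kmers(kmers, list(s = c(s_chr = seq))), ann)
  # reverse complement the record and flip the annotation coordinates
  seq_rc <- revcomp(seq)
  genes_rc <- transform(genes, start = L - end + 1L, end = L - start + 1L,
                        strand = ifelse(strand == "+", "-", "+"))
  ann_rc <- genome_annotation(genes_rc, data.frame(
    strain = "s", replicon = "s_chr", length = L, role = "chr"))
  h2 <- classify_hits(locate_kmers(kmers, list(s = c(s_chr = seq_rc))),
                      ann_rc)
  sig <- function(h) sort(paste(h$kmer, h$context, h$locus_tag))
  expect_identical(sig(h1), sig(h2))
})

test_that("hit summaries count distinct genes, roles and unannotated CDSs", {
  genes <- data.frame(
    strain = "s", replicon = c("s_pSymA", "s_pSymA", "s_chromosome"),
    start = c(100L, 400L, 100L), end = c(300L, 600L, 300L), strand = "+",
    locus_tag = c("gA", "gB", "gC"),
    cog_id = c("COG1", "COG1", NA), ortholog_group = c("OG1", "OG2", NA),
    stringsAsFactors = FALSE)
  reps <- data.frame(strain = "s",
                     replicon = c("s_pSymA", "s_chromosome"),
                     length = 1000L, role = c("pSymA", "chromosome"),
                     stringsAsFactors = FALSE)
  ann <- genome_annotation(genes, reps)
  hits <- data.frame(
    kmer = c("K1", "K1", "K2", "K3"), strain = "s",
    replicon = c("s_pSymA", "s_pSymA", "s_pSymA", "s_chromosome"),
    position = c(150L, 450L, 290L, 150L), strand = "+",
    context = "CDS", locus_tag = c("gA", "gB", "gA", "gC"),
    distance_to_start = NA_integer_, stringsAsFactors = FALSE)
  hs <- summarize_hits(hits, ann)
  expect_equal(nrow(hs$gene_hits), 3L)            # gA counted once
  expect_equal(unname(hs$cog_counts[, "COG1"]), 2L)
  expect_equal(unname(hs$unannotated["s"]), 1L)   # gC has no ortholog group
  expect_equal(unname(hs$replicon_fractions["s", "pSymA"]), 1)  # OG hits only
  gp <- matrix(1, 2, 3, dimnames = list(c("OG1", "OG2"), paste0("s", 1:3)))
  gp["OG2", 1] <- 0
  hs2 <- summarize_hits(hits, ann, gene_presence = gp)
  expect_true(hs2$core_flags[["OG1"]])
  expect_false(hs2$core_flags[["OG2"]])
})

test_that("carrier-exclusive regions recover the planted block only", {
  cfg <- small_cfg(seed = 37)
  sim <- simulate_phenotype(simulate_genomes(cfg), noise_sd = 0)
  fit <- kmer_gwas(sim, sim$truth$true_phenotype)
  carriers <- sim$truth$carrier_map$block_A
  best <- select_best_kmers(fit$association, fit$kmers,
                            carrier_set = carriers)
  hits <- classify_hits(locate_kmers(best$exact, sim), sim$annotation)
  reg <- carrier_exclusive_regions(hits, sim$annotation, carriers)
  expect_setequal(unique(reg$strain), carriers)
  expect_equal(nrow(reg), length(carriers))       # one region per carrier
  expect_true(all(grepl("OG_block_A", reg$ortholog_groups)))
  # scattered hits farther apart than the gap form separate regions;
  # a carrier set equal to all strains reports nothing
  far <- data.frame(kmer = "ACGTACGTACGTA", strain = "s",
                    replicon = "s_chromosome",
                    position = c(100L, 9000L), strand = "+")
  ann <- toy_annotation(genes = data.frame(
    strain = "s", replicon = "s_chromosome",
    start = c(50L, 8900L), end = c(200L, 9100L), strand = "+",
    locus_tag = c("g1", "g2"), ortholog_group = c("OGx", "OGy"),
    stringsAsFactors = FALSE))
  reg2 <- carrier_exclusive_regions(far, ann, carriers = "s", gap = 5000L)
  expect_equal(nrow(reg2), 2L)
  expect_equal(nrow(carrier_exclusive_regions(
    hits, sim$annotation, carriers = cfg$strain_ids)), 0L)
})
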