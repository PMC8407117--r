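#' Configuration for the competition-assay simulator
#'
#' Builds the parameter set used by [simulate_genomes()],
#' [simulate_phenotype()] and [simulate_nodule_counts()]. Defaults emulate the
#' study design the analysis assumes: 13 tester strains with three replicons
#' each (a chromosome and two megaplasmid-like replicons), a core genome shared
#' by all strains, accessory blocks private to strain subsets -- including one
#' causal block on the pSymA-like replicon carried by exactly the
#' high-competitiveness strains -- strain-level SNPs, a continuous competition
#' phenotype in \[0, 1\] driven by the causal block, and six plants per
#' competition. Replicon sizes are desk-scale stand-ins for the megabase-sized
#' rhizobial replicons; the causal block (2 kb) stands in for the
#' 26-kb accessory region tagged by the real association analysis.
#'
#' @param n_strains number of tester strains.
#' @param replicon_lengths named integer vector of backbone lengths in bp;
#'   names are the replicon roles (`chromosome`, `pSymA`, `pSymB`, ...).
#' @param core_fraction fraction of each backbone shared identically across
#'   strains (up to SNPs); the remaining tail is redrawn per strain.
#' @param accessory_blocks list of blocks, each a list with elements `id`,
#'   `length` (bp), `replicon` (index into `replicon_lengths`) and `carriers`
#'   (integer indices of carrier strains, a nonempty proper subset).
#' @param snp_rate substitution probability per core bp per strain.
#' @param causal_block_id id of the block that drives the phenotype.
#' @param phenotype_base baseline nodule occupancy of non-carriers.
#' @param beta phenotype effect of carrying the causal block
#'   (occupancy-fraction units).
#' @param noise_sd standard deviation of phenotype noise.
#' @param plants_per_competition replicate plants per competition.
#' @param nodules_per_plant_mean Poisson mean of nodules per plant
#'   (conditioned on at least one nodule).
#' @param p_mix probability that a nodule is co-colonized by both strains.
#' @param k k-mer length used downstream (lengths must be >= k).
#' @param seed integer seed; the whole simulation is reproducible from it.
#' @return an object of class `sim_config`.
#' @examples
#' cfg <- sim_config(seed = 7)
#' cfg$causal_block_id
#' @export
sim_config <- function(n_strains = 13L,
                       replicon_lengths = c(chromosome = 12000L,
                                            pSymA = 8000L,
                                            pSymB = 6000L),
                       core_fraction = 0.9,
                       accessory_blocks = NULL,
                       snp_rate = 0.003,
                       causal_block_id = "block_A",
                       phenotype_base = 0.25,
                       beta = 0.40,
                       noise_sd = 0.05,
                       plants_per_competition = 6L,
                       nodules_per_plant_mean = 15,
                       p_mix = 0.15,
                       k = 13L,
                       seed = 1L) {
  n_strains <- as.integer(n_strains)
  if (is.null(names(replicon_lengths)))
    names(replicon_lengths) <- paste0("replicon", seq_along(replicon_lengths))
  if (is.null(accessory_blocks)) {
    accessory_blocks <- list(
      list(id = "block_A", length = 2000L, replicon = 2L, carriers = 1:4),
      list(id = "block_B", length = 1500L, replicon = 2L, carriers = 5:9),
      list(id = "block_C", length = 1200L, replicon = 1L, carriers = 6:12)
    )
  }
  cfg <- structure(list(
    n_strains = n_strains,
    strain_ids = sprintf("S%02d", seq_len(n_strains)),
    replicon_lengths = as.integer(replicon_lengths),
    replicon_roles = names(replicon_lengths),
    core_fraction = core_fraction,
    accessory_blocks = accessory_blocks,
    snp_rate = snp_rate,
    causal_block_id = causal_block_id,
    phenotype_base = phenotype_base,
    beta = beta,
    noise_sd = noise_sd,
    plants_per_competition = as.integer(plants_per_competition),
    nodules_per_plant_mean = nodules_per_plant_mean,
    p_mix = p_mix,
    k = as.integer(k),
    seed = as.integer(seed)
  ), class = "sim_config")
  names(cfg$replicon_lengths) <- cfg$replicon_roles
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$core_fraction < 0 || cfg$core_fraction > 1)
    stop("core_fraction must be in [0, 1]", call. = FALSE)
  if (any(cfg$replicon_lengths < cfg$k))
    stop("all replicon lengths must be >= k (", cfg$k, ")", call. = FALSE)
  ids <- vapply(cfg$accessory_blocks, `[[`, character(1L), "id")
  if (anyDuplicated(ids)) stop("duplicate accessory block ids", call. = FALSE)
  if (length(cfg$accessory_blocks) > 0L &&
      !(cfg$causal_block_id %in% ids))
    stop("causal_block_id '", cfg$causal_block_id,
         "' does not name an accessory block", call. = FALSE)
  for (b in cfg$accessory_blocks) {
    if (length(b$carriers) < 1L || length(b$carriers) >= cfg$n_strains)
      stop("carrier set of block '", b$id,
           "' must be a nonempty proper subset of strains", call. = FALSE)
    if (b$length < cfg$k)
      stop("block '", b$id, "' shorter than k", call. = FALSE)
    if (b$length < 750L)
      stop("block '", b$id, "' too short (< 750 bp) to host an annotated ",
           "gene with a clear 600-nt upstream window", call. = FALSE)
    if (b$replicon < 1L || b$replicon > length(cfg$replicon_lengths))
      stop("block '", b$id, "' placed on unknown replicon", call. = FALSE)
  }
  # sizing: blocks must fit in the core part of their replicon
  core_len <- floor(cfg$core_fraction * cfg$replicon_lengths)
  for (r in seq_along(cfg$replicon_lengths)) {
    blen <- sum(vapply(cfg$accessory_blocks, function(b)
      if (b$replicon == r) b$length else 0L, numeric(1L)))
    if (blen > 0 && blen >= core_len[r])
      stop("sizing error: replicon ", cfg$replicon_roles[r],
           " is shorter than the sum of its placed blocks", call. = FALSE)
  }
  invisible(cfg)
}

# Pool of COG functional ids assigned to simulated genes (transport,
# cofactor biosynthesis, metabolism -- the functional classes the association
# analysis tends to flag in rhizobia).
.cog_pool <- c("COG0410", "COG0418", "COG0683", "COG1024", "COG1028",
               "COG1060", "COG1129", "COG1172", "COG1282", "COG1529",
               "COG1802", "COG2057", "COG2141", "COG2188", "COG3288")

# Backbone gene layout inside the core part of one replicon:
# 900-bp genes separated by 600-bp gaps, starting at position 601.
backbone_gene_starts <- function(core_len) {
  if (core_len < 1501L) return(integer(0L))
  seq.int(601L, core_len - 900L, by = 1500L)
}

#' Simulate strain genomes, annotations and planted truth
#'
#' Generates one multi-replicon genome per strain: a shared core backbone with
#' per-strain SNPs, a per-strain accessory tail (when `core_fraction < 1`),
#' and accessory blocks inserted at fixed backbone loci in carrier strains
#' only. Each block hosts at least one annotated gene with a clear 600-nt
#' upstream window, so downstream CDS and regulatory-window classification is
#' exercised. Background sequence is i.i.d. uniform over \{A,C,G,T\}.
#' Accidental occurrences of block k-mers elsewhere are handled in two ways:
#' collisions inside a strain's private sequence (its own SNP windows or
#' strain-specific tail) are repaired by resampling the private base, and
#' collisions in the shared core are excluded from the recorded truth set by
#' measurement -- so every k-mer in `truth$causal_kmers` is verified to occur
#' in all carriers and in no non-carrier. Replicons are emitted as linear
#' sequences; no k-mer spans a circular origin.
#'
#' @param cfg a [sim_config()] object.
#' @return an object of class `rhizo_sim`: a list with elements
#'   \describe{
#'     \item{genomes}{named list (strain) of named character vectors
#'       (replicon id -> sequence).}
#'     \item{annotation}{a `genome_annotation` object (gene and replicon
#'       tables; see [genome_annotation()]).}
#'     \item{truth}{planted truth: `causal_kmers` (canonical k-mers unique to
#'       the causal block), `block_kmers` (per block), `carrier_map`,
#'       `planted_genes`, `blocks`, and (after [simulate_phenotype()])
#'       `true_phenotype`.}
#'     \item{cfg}{the configuration.}
#'   }
#' @examples
#' cfg <- sim_config(n_strains = 5,
#'                   replicon_lengths = c(chromosome = 3000, pSymA = 3000),
#'                   accessory_blocks = list(list(id = "block_A", length = 800,
#'                                                replicon = 2, carriers = 1:2)),
#'                   seed = 1)
#' sim <- simulate_genomes(cfg)
#' names(sim$genomes)
#' @export
simulate_genomes <- function(cfg) {
  validate_sim_config(cfg)
  with_seed(cfg$seed, build_simulation(cfg))
}

build_simulation <- function(cfg) {
  k <- cfg$k
  n <- cfg$n_strains
  strains <- cfg$strain_ids
  roles <- cfg$replicon_roles
  lens <- cfg$replicon_lengths
  core_len <- as.integer(floor(cfg$core_fraction * lens))

  # ancestral backbones and backbone gene layout
  backbones <- lapply(lens, random_dna)
  bb_genes <- list()
  for (r in seq_along(lens)) {
    starts <- backbone_gene_starts(core_len[r])
    if (length(starts) == 0L) next
    bb_genes[[r]] <- data.frame(
      replicon_idx = r,
      start = starts,
      end = starts + 899L,
      strand = rep_len(c("+", "-"), length(starts)),
      ortholog_group = sprintf("OGcore_%s_%02d", roles[r], seq_along(starts)),
      cog_id = .cog_pool[(seq_along(starts) - 1L) %% length(.cog_pool) + 1L],
      stringsAsFactors = FALSE
    )
  }
  bb_genes <- do.call(rbind, bb_genes)

  # insertion loci: mid-gap positions between backbone genes, assigned to
  # blocks per replicon in declaration order
  blocks <- cfg$accessory_blocks
  gap_mid <- function(r) {
    starts <- backbone_gene_starts(core_len[r])
    mids <- starts + 1200L           # inside the gap after each gene
    mids <- mids[mids <= core_len[r] - 1L]
    if (length(mids) < 1L)
      stop("sizing error: replicon ", roles[r],
           " has no intergenic gap to host a block", call. = FALSE)
    mids
  }
  used <- integer(length(lens))
  for (i in seq_along(blocks)) {
    r <- blocks[[i]]$replicon
    mids <- gap_mid(r)
    used[r] <- used[r] + 1L
    if (used[r] > length(mids))
      stop("sizing error: more blocks than intergenic gaps on replicon ",
           roles[r], call. = FALSE)
    blocks[[i]]$insert_at <- mids[used[r]]
    blocks[[i]]$seq <- random_dna(blocks[[i]]$length)
  }
  # blocks must not share k-mers with one another (redraw later block)
  if (length(blocks) > 1L) {
    for (i in seq_along(blocks)[-1L]) {
      earlier <- unlist(lapply(blocks[seq_len(i - 1L)],
                               function(b) seq_kmers(b$seq, k)))
      for (tries in 1:50) {
        if (!any(seq_kmers(blocks[[i]]$seq, k) %in% earlier)) break
        blocks[[i]]$seq <- random_dna(blocks[[i]]$length)
      }
    }
  }

  # per-strain sequences: strain-specific tail, SNPs on core, block insertion
  genomes <- vector("list", n)
  names(genomes) <- strains
  shifts <- vector("list", n)  # per strain, per replicon: block table for coords
  snps <- replicate(n, vector("list", length(lens)), simplify = FALSE)
  for (s in seq_len(n)) {
    seqs <- character(length(lens))
    for (r in seq_along(lens)) {
      seq <- backbones[[r]]
      if (core_len[r] < lens[r]) {
        tail_len <- lens[r] - core_len[r]
        seq <- paste0(substr(seq, 1L, core_len[r]), random_dna(tail_len))
      }
      snp_pos <- integer(0L)
      if (cfg$snp_rate > 0 && core_len[r] > 0L) {
        snp_pos <- which(stats::runif(core_len[r]) < cfg$snp_rate)
        if (length(snp_pos)) {
          cur <- strsplit(substr(seq, 1L, core_len[r]), "",
                          fixed = TRUE)[[1L]][snp_pos]
          seq <- replace_bases(seq, snp_pos, substitute_bases(cur))
        }
      }
      snps[[s]][[r]] <- snp_pos
      seqs[r] <- seq
    }
    genomes[[s]] <- seqs
    shifts[[s]] <- lapply(seq_along(lens), function(r) {
      bs <- Filter(function(b) b$replicon == r && s %in% b$carriers, blocks)
      bs[order(vapply(bs, `[[`, numeric(1L), "insert_at"))]
    })
  }
  # insert blocks (descending position so earlier coordinates stay valid)
  for (s in seq_len(n)) {
    for (r in seq_along(lens)) {
      bs <- shifts[[s]][[r]]
      for (b in rev(bs)) {
        seq <- genomes[[s]][r]
        genomes[[s]][r] <- paste0(substr(seq, 1L, b$insert_at), b$seq,
                                  substr(seq, b$insert_at + 1L, nchar(seq)))
      }
    }
    names(genomes[[s]]) <- paste(strains[s], roles, sep = "_")
  }

  # coordinate bookkeeping: cumulative shift of an ancestral position
  shift_at <- function(s, r, pos) {
    bs <- shifts[[s]][[r]]
    if (length(bs) == 0L) return(0L)
    sum(vapply(bs, function(b)
      if (b$insert_at < pos) b$length else 0L, numeric(1L)))
  }

  # gene annotation per strain
  gene_rows <- list()
  gi <- 0L
  for (s in seq_len(n)) {
    cnt <- 0L
    if (!is.null(bb_genes)) for (j in seq_len(nrow(bb_genes))) {
      r <- bb_genes$replicon_idx[j]
      sh <- shift_at(s, r, bb_genes$start[j])
      cnt <- cnt + 1L
      gi <- gi + 1L
      gene_rows[[gi]] <- data.frame(
        strain = strains[s],
        replicon = paste(strains[s], roles[r], sep = "_"),
        start = bb_genes$start[j] + sh, end = bb_genes$end[j] + sh,
        strand = bb_genes$strand[j],
        locus_tag = sprintf("%s_%04d", strains[s], cnt),
        cog_id = bb_genes$cog_id[j],
        ortholog_group = bb_genes$ortholog_group[j],
        product = "core backbone protein",
        stringsAsFactors = FALSE
      )
    }
    for (b in blocks) {
      if (!(s %in% b$carriers)) next
      r <- b$replicon
      base <- b$insert_at + shift_at(s, r, b$insert_at + 1L) - b$length
      # block-local gene layout: gene 1 at [701, len-50] (clear 600-nt
      # upstream window inside the block), optional gene 2 on the minus strand
      g1 <- c(701L, min(b$length - 50L, 1600L))
      locs <- list(list(start = g1[1], end = g1[2], strand = "+", idx = 1L))
      if (b$length - 50L >= g1[2] + 250L)
        locs <- c(locs, list(list(start = g1[2] + 101L, end = b$length - 50L,
                                  strand = "-", idx = 2L)))
      for (g in locs) {
        cnt <- cnt + 1L
        gi <- gi + 1L
        gene_rows[[gi]] <- data.frame(
          strain = strains[s],
          replicon = paste(strains[s], roles[r], sep = "_"),
          start = base + g$start, end = base + g$end, strand = g$strand,
          locus_tag = sprintf("%s_%04d", strains[s], cnt),
          cog_id = .cog_pool[(g$idx + match(b$id, vapply(blocks, `[[`,
                    character(1L), "id"))) %% length(.cog_pool) + 1L],
          ortholog_group = sprintf("OG_%s_g%d", b$id, g$idx),
          product = "accessory block protein",
          stringsAsFactors = FALSE
        )
      }
    }
  }
  genes <- do.call(rbind, gene_rows)

  replicons <- do.call(rbind, lapply(seq_len(n), function(s) data.frame(
    strain = strains[s],
    replicon = paste(strains[s], roles, sep = "_"),
    length = nchar(genomes[[s]]),
    role = roles,
    stringsAsFactors = FALSE
  )))
  rownames(replicons) <- NULL

  # block intervals in final per-carrier coordinates, extended by k-1 so
  # insertion-junction k-mers count as block k-mers
  block_tbl <- list()
  for (b in blocks) {
    for (s in b$carriers) {
      base <- b$insert_at + shift_at(s, b$replicon, b$insert_at + 1L) - b$length
      block_tbl[[length(block_tbl) + 1L]] <- data.frame(
        block = b$id, strain = strains[s],
        replicon = paste(strains[s], roles[b$replicon], sep = "_"),
        start = base + 1L, end = base + b$length,
        stringsAsFactors = FALSE
      )
    }
  }
  block_tbl <- if (length(block_tbl)) do.call(rbind, block_tbl) else
    data.frame(block = character(0), strain = character(0),
               replicon = character(0), start = integer(0), end = integer(0))

  # private-sequence map in final coordinates: a strain's own SNP sites and
  # its strain-specific tail (positions no other strain shares)
  private <- lapply(seq_len(n), function(s) {
    out <- vector("list", length(lens))
    names(out) <- names(genomes[[s]])
    for (r in seq_along(lens)) {
      sp <- snps[[s]][[r]]
      sp_final <- if (length(sp)) sp + vapply(sp, function(p)
        shift_at(s, r, p), numeric(1L)) else integer(0L)
      carried <- sum(vapply(shifts[[s]][[r]], `[[`, numeric(1L), "length"))
      out[[r]] <- list(
        snp = as.integer(sp_final),
        tail_start = if (core_len[r] < lens[r])
          as.integer(core_len[r] + carried + 1L) else NA_integer_
      )
    }
    out
  })
  names(private) <- strains

  genomes <- repair_private_collisions(genomes, block_tbl, private, k)

  truth <- build_truth(genomes, block_tbl, blocks, strains, k, cfg)
  truth$planted_genes <- if (!is.null(genes))
    genes[grepl("^OG_block", genes$ortholog_group), , drop = FALSE] else NULL

  structure(list(
    genomes = genomes,
    annotation = genome_annotation(genes, replicons),
    truth = truth,
    cfg = cfg
  ), class = "rhizo_sim")
}

# Keep block k-mers out of the strains' PRIVATE sequence: when a block k-mer
# (junctions included) also occurs over a strain's own SNP site or inside its
# strain-specific tail, that private base is resampled. Collisions landing in
# the shared core are left alone -- the k-mer is then present in non-carriers
# as well, so it is removed from the planted-truth set by measurement and
# rejected by the support filter; it can never masquerade as carrier-exclusive.
repair_private_collisions <- function(genomes, block_tbl, private, k,
                                      max_iter = 25L) {
  if (nrow(block_tbl) == 0L) return(genomes)
  flank <- k - 1L
  block_kmer_set <- function() {
    unique(unlist(lapply(seq_len(nrow(block_tbl)), function(i) {
      seq <- genomes[[block_tbl$strain[i]]][[block_tbl$replicon[i]]]
      s <- max(1L, block_tbl$start[i] - flank)
      e <- min(nchar(seq), block_tbl$end[i] + flank)
      seq_kmers(substr(seq, s, e), k)
    })))
  }
  for (iter in seq_len(max_iter)) {
    B <- block_kmer_set()
    dirty <- FALSE
    for (s in names(genomes)) {
      for (rep_id in names(genomes[[s]])) {
        seq <- genomes[[s]][[rep_id]]
        wins <- seq_kmers(seq, k)
        hit <- which(wins %in% B)
        if (length(hit) == 0L) next
        bt <- block_tbl[block_tbl$strain == s & block_tbl$replicon == rep_id, ,
                        drop = FALSE]
        if (nrow(bt) > 0L) {
          inside <- rep(FALSE, length(hit))
          for (j in seq_len(nrow(bt))) {
            inside <- inside | (hit >= bt$start[j] - 2L * flank &
                                  hit <= bt$end[j] + flank)
          }
          hit <- hit[!inside]
        }
        if (length(hit) == 0L) next
        pv <- private[[s]][[rep_id]]
        pos <- integer(0L)
        for (h in hit) {
          in_win <- pv$snp[pv$snp >= h & pv$snp <= h + k - 1L]
          if (length(in_win)) pos <- c(pos, in_win[1L])
          else if (!is.na(pv$tail_start) && h + k - 1L >= pv$tail_start)
            pos <- c(pos, max(h, pv$tail_start))
        }
        if (length(pos) == 0L) next   # shared-core collisions stay
        dirty <- TRUE
        pos <- unique(pos)
        cur <- strsplit(seq, "", fixed = TRUE)[[1L]][pos]
        genomes[[s]][[rep_id]] <- replace_bases(seq, pos,
                                                substitute_bases(cur))
      }
    }
    if (!dirty) return(genomes)
  }
  genomes
}

build_truth <- function(genomes, block_tbl, blocks, strains, k, cfg) {
  flank <- k - 1L
  carrier_map <- lapply(blocks, function(b) strains[b$carriers])
  names(carrier_map) <- vapply(blocks, `[[`, character(1L), "id")
  strain_kmers <- lapply(genomes, function(reps)
    unique(unlist(lapply(reps, seq_kmers, k = k), use.names = FALSE)))
  block_kmers <- list()
  for (b in blocks) {
    carr <- strains[b$carriers]
    sets <- lapply(carr, function(s) {
      bt <- block_tbl[block_tbl$block == b$id & block_tbl$strain == s, ]
      seq <- genomes[[s]][[bt$replicon]]
      lo <- max(1L, bt$start - flank)
      hi <- min(nchar(seq), bt$end + flank)
      unique(seq_kmers(substr(seq, lo, hi), k))
    })
    cand <- Reduce(intersect, sets)
    non_carr <- setdiff(strains, carr)
    if (length(non_carr))
      cand <- cand[!cand %in% unique(unlist(strain_kmers[non_carr]))]
    block_kmers[[b$id]] <- sort(cand, method = "radix")
  }
  list(
    causal_kmers = block_kmers[[cfg$causal_block_id]] %||% character(0L),
    block_kmers = block_kmers,
    carrier_map = carrier_map,
    blocks = block_tbl,
    true_phenotype = NULL
  )
}

#' Simulate the competition phenotype
#'
#' Draws a per-strain nodule-occupancy phenotype:
#' `base + beta * carries_causal_block + Normal(0, noise_sd)`, clipped to
#' \[0, 1\]. The vector is stored in `sim$truth$true_phenotype`.
#'
#' @param sim a `rhizo_sim` object from [simulate_genomes()].
#' @param base,beta,noise_sd overrides of the corresponding `sim_config`
#'   fields.
#' @param seed integer seed (default derives from the simulation seed).
#' @return `sim`, with `truth$true_phenotype` filled (named numeric vector).
#' @export
simulate_phenotype <- function(sim, base = sim$cfg$phenotype_base,
                               beta = sim$cfg$beta,
                               noise_sd = sim$cfg$noise_sd,
                               seed = sim$cfg$seed + 1000003L) {
  stopifnot(inherits(sim, "rhizo_sim"))
  carriers <- sim$truth$carrier_map[[sim$cfg$causal_block_id]] %||% character(0L)
  strains <- sim$cfg$strain_ids
  ph <- with_seed(seed, {
    base + beta * (strains %in% carriers) +
      stats::rnorm(length(strains), 0, noise_sd)
  })
  ph <- pmin(1, pmax(0, ph))
  names(ph) <- strains
  sim$truth$true_phenotype <- ph
  sim
}

#' Simulate per-plant nodule count tables
#'
#' For each tester strain, draws `plants_per_competition` plants. Per plant the
#' nodule total is Poisson(`nodules_per_plant_mean`) conditioned on being at
#' least 1, and nodule colours are multinomial with
#' `p_green = phenotype * (1 - p_mix)`, `p_red = (1 - phenotype) * (1 - p_mix)`
#' and `p_mixed = p_mix`.
#'
#' @param phenotype a `rhizo_sim` with `truth$true_phenotype` set, or a named
#'   numeric vector of per-strain occupancies in \[0, 1\].
#' @param cfg a [sim_config()]; defaults to the simulation's own config.
#' @param competition_id label for this competition set.
#' @param p_mix probability of a mixed (co-colonized) nodule.
#' @param seed integer seed.
#' @return a data frame with columns `competition_id`, `strain_id`,
#'   `plant_id`, `n_green`, `n_red`, `n_mixed`.
#' @export
simulate_nodule_counts <- function(phenotype, cfg = NULL,
                                   competition_id = "vs_REF",
                                   p_mix = NULL, seed = NULL) {
  if (inherits(phenotype, "rhizo_sim")) {
    cfg <- cfg %||% phenotype$cfg
    phenotype <- phenotype$truth$true_phenotype
    if (is.null(phenotype))
      stop("run simulate_phenotype() first", call. = FALSE)
  }
  if (is.null(cfg)) stop("cfg required when phenotype is a plain vector",
                         call. = FALSE)
  stopifnot(all(phenotype >= 0 & phenotype <= 1))
  p_mix <- p_mix %||% cfg$p_mix
  seed <- seed %||% (cfg$seed + 2000003L)
  strains <- names(phenotype) %||% sprintf("S%02d", seq_along(phenotype))
  np <- cfg$plants_per_competition
  with_seed(seed, {
    rows <- vector("list", length(strains))
    for (i in seq_along(strains)) {
      tot <- stats::rpois(np, cfg$nodules_per_plant_mean)
      while (any(tot == 0L))
        tot[tot == 0L] <- stats::rpois(sum(tot == 0L),
                                       cfg$nodules_per_plant_mean)
      p <- c(phenotype[i] * (1 - p_mix), (1 - phenotype[i]) * (1 - p_mix),
             p_mix)
      cols <- vapply(tot, function(tt) stats::rmultinom(1L, tt, p)[, 1L],
                     numeric(3L))
      rows[[i]] <- data.frame(
        competition_id = competition_id,
        strain_id = strains[i],
        plant_id = sprintf("plant%02d", seq_len(np)),
        n_green = as.integer(cols[1L, ]),
        n_red = as.integer(cols[2L, ]),
        n_mixed = as.integer(cols[3L, ]),
        stringsAsFactors = FALSE
      )
    }
    do.call(rbind, rows)
  })
}
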