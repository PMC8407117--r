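#' Locate k-mers on strain genomes
#'
#' Exact-match search of each k-mer and its reverse complement over every
#' replicon of every strain. Every occurrence is reported with its position on
#' the forward coordinate system (1-based, leftmost base) and the matched
#' strand; overlapping occurrences are all reported.
#'
#' @param kmers character vector of (canonical) k-mers, all the same length.
#' @param genomes named list (strain) of named character vectors, or a
#'   `rhizo_sim`.
#' @return data frame with columns `kmer`, `strain`, `replicon`, `position`,
#'   `strand`.
#' @export
locate_kmers <- function(kmers, genomes) {
  if (inherits(genomes, "rhizo_sim")) genomes <- genomes$genomes
  kmers <- unique(kmers)
  if (length(kmers) == 0L)
    return(data.frame(kmer = character(0), strain = character(0),
                      replicon = character(0), position = integer(0),
                      strand = character(0)))
  pats <- Biostrings::DNAStringSet(kmers)
  pd_fwd <- Biostrings::PDict(pats)
  pd_rev <- Biostrings::PDict(Biostrings::reverseComplement(pats))
  rows <- list()
  for (s in names(genomes)) {
    for (rep_id in names(genomes[[s]])) {
      subj <- Biostrings::DNAString(genomes[[s]][[rep_id]])
      for (strand in c("+", "-")) {
        m <- Biostrings::matchPDict(if (strand == "+") pd_fwd else pd_rev,
                                    subj)
        st <- Biostrings::startIndex(m)
        hit <- which(lengths(st) > 0L)
        if (length(hit) == 0L) next
        rows[[length(rows) + 1L]] <- data.frame(
          kmer = rep(kmers[hit], lengths(st)[hit]),
          strain = s, replicon = rep_id,
          position = unlist(st[hit], use.names = FALSE),
          strand = strand,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(kmer = character(0), strain = character(0),
               replicon = character(0), position = integer(0),
               strand = character(0))
  out <- out[order(out$strain, out$replicon, out$position, out$kmer,
                   method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify k-mer occurrences against gene annotation
#'
#' Each occurrence is classified per gene: a `CDS` row for every gene whose
#' interval overlaps the match by at least one base (one k-mer may tag
#' multiple genes); if no gene overlaps, a `regulatory` row for every gene
#' whose strand-aware upstream window (600 nt before the CDS start, truncated
#' at replicon ends) overlaps the match, with `distance_to_start` the gap from
#' the match's nearest base to the CDS start; otherwise a single `intergenic`
#' row. CDS context takes precedence over regulatory at the same occurrence.
#'
#' @param occurrences output of [locate_kmers()].
#' @param annotation a [genome_annotation()].
#' @param upstream regulatory window size in nt (default 600).
#' @return data frame with columns of `occurrences` plus `context`
#'   (`CDS`/`regulatory`/`intergenic`), `locus_tag` (NA for intergenic) and
#'   `distance_to_start` (regulatory only, in \[1, upstream\]).
#' @export
classify_hits <- function(occurrences, annotation, upstream = 600L) {
  stopifnot(inherits(annotation, "genome_annotation"))
  genes <- annotation$genes
  reps <- annotation$replicons
  k <- nchar(occurrences$kmer[1L] %||% "")
  out <- vector("list", nrow(occurrences))
  for (i in seq_len(nrow(occurrences))) {
    occ <- occurrences[i, ]
    os <- occ$position
    oe <- occ$position + nchar(occ$kmer) - 1L
    g <- genes[genes$replicon == occ$replicon, , drop = FALSE]
    rlen <- reps$length[match(occ$replicon, reps$replicon)]
    cds <- g[g$start <= oe & g$end >= os, , drop = FALSE]
    if (nrow(cds) > 0L) {
      out[[i]] <- data.frame(occ, context = "CDS", locus_tag = cds$locus_tag,
                             distance_to_start = NA_integer_,
                             row.names = NULL, stringsAsFactors = FALSE)
      next
    }
    ws <- ifelse(g$strand == "+", pmax(1L, g$start - upstream), g$end + 1L)
    we <- ifelse(g$strand == "+", g$start - 1L,
                 pmin(rlen, g$end + upstream))
    reg <- which(ws <= oe & we >= os & we >= ws)
    if (length(reg) > 0L) {
      dist <- ifelse(g$strand[reg] == "+", g$start[reg] - oe, os - g$end[reg])
      out[[i]] <- data.frame(occ, context = "regulatory",
                             locus_tag = g$locus_tag[reg],
                             distance_to_start = as.integer(dist),
                             row.names = NULL, stringsAsFactors = FALSE)
      next
    }
    out[[i]] <- data.frame(occ, context = "intergenic",
                           locus_tag = NA_character_,
                           distance_to_start = NA_integer_,
                           row.names = NULL, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Summarize classified k-mer hits
#'
#' Per strain: counts of distinct tagged genes by COG category and by ortholog
#' group; genes without an ortholog annotation tallied as unannotated CDSs;
#' regulatory hits by target gene; and the fraction of ortholog-annotated gene
#' hits per replicon role. When a gene presence/absence table is supplied,
#' each tagged ortholog group is flagged core (present in all strains) or
#' accessory.
#'
#' @param hits output of [classify_hits()].
#' @param annotation a [genome_annotation()].
#' @param gene_presence optional binary matrix (ortholog group x strain).
#' @return an object of class `hit_summary`: list with `gene_hits` (distinct
#'   strain/gene CDS hits with annotation), `cog_counts` and
#'   `ortholog_counts` (strain x category matrices), `unannotated` (per-strain
#'   counts), `regulatory` (distinct strain/target-gene regulatory hits),
#'   `replicon_fractions` (strain x role, over ortholog-annotated gene hits)
#'   and optionally `core_flags`.
#' @export
summarize_hits <- function(hits, annotation, gene_presence = NULL) {
  stopifnot(inherits(annotation, "genome_annotation"))
  if (nrow(hits) == 0L) stop("no hits to summarize", call. = FALSE)
  genes <- annotation$genes
  reps <- annotation$replicons
  key <- paste(genes$strain, genes$locus_tag)

  cds <- hits[hits$context == "CDS", , drop = FALSE]
  cds <- cds[!duplicated(paste(cds$strain, cds$locus_tag)), , drop = FALSE]
  gi <- match(paste(cds$strain, cds$locus_tag), key)
  gene_hits <- data.frame(
    strain = cds$strain, locus_tag = cds$locus_tag,
    replicon = cds$replicon,
    role = reps$role[match(cds$replicon, reps$replicon)],
    cog_id = genes$cog_id[gi],
    ortholog_group = genes$ortholog_group[gi],
    stringsAsFactors = FALSE
  )
  strains <- sort(unique(c(hits$strain, reps$strain)), method = "radix")
  xtab <- function(val, keep) {
    v <- val[keep]
    s <- gene_hits$strain[keep]
    if (length(v) == 0L) return(matrix(0L, length(strains), 0L,
                                       dimnames = list(strains, NULL)))
    t3 <- table(factor(s, levels = strains), v)
    m <- matrix(as.integer(t3), nrow = length(strains),
                dimnames = dimnames(t3))
    m
  }
  has_og <- !is.na(gene_hits$ortholog_group)
  has_cog <- !is.na(gene_hits$cog_id)
  cog_counts <- xtab(gene_hits$cog_id, has_cog)
  ortholog_counts <- xtab(gene_hits$ortholog_group, has_og)
  unannotated <- vapply(strains, function(s)
    sum(gene_hits$strain == s & !has_og), integer(1L))

  roles <- sort(unique(reps$role), method = "radix")
  rf <- matrix(NA_real_, length(strains), length(roles),
               dimnames = list(strains, roles))
  for (s in strains) {
    sel <- gene_hits$strain == s & has_og
    if (!any(sel)) next
    tt <- table(factor(gene_hits$role[sel], levels = roles))
    rf[s, ] <- as.numeric(tt) / sum(tt)
  }

  regulatory <- hits[hits$context == "regulatory", , drop = FALSE]
  regulatory <- regulatory[!duplicated(paste(regulatory$strain,
                                             regulatory$locus_tag,
                                             regulatory$kmer)), , drop = FALSE]

  out <- list(gene_hits = gene_hits, cog_counts = cog_counts,
              ortholog_counts = ortholog_counts, unannotated = unannotated,
              regulatory = regulatory, replicon_fractions = rf)
  if (!is.null(gene_presence)) {
    ogs <- unique(gene_hits$ortholog_group[has_og])
    ogs <- ogs[ogs %in% rownames(gene_presence)]
    out$core_flags <- stats::setNames(
      rowSums(gene_presence[ogs, , drop = FALSE] >= 1) ==
        ncol(gene_presence),
      ogs)
  }
  structure(out, class = "hit_summary")
}

#' @export
print.hit_summary <- function(x, ...) {
  cat("hit_summary:", nrow(x$gene_hits), "distinct CDS hits,",
      nrow(x$regulatory), "regulatory hits\n")
  cat("replicon fractions of ortholog-gene hits:\n")
  print(round(x$replicon_fractions, 3))
  invisible(x)
}

#' Regions of clustered hits exclusive to a carrier set
#'
#' Clusters hit positions per strain and replicon into maximal regions with
#' inter-hit gaps of at most `gap` bp, attaches the ortholog groups of genes
#' overlapping each region, and reports the regions whose ortholog-group
#' content occurs (as a region) in exactly the given carrier strains and
#' nowhere else -- the accessory-region signature of a shared genetic
#' determinant.
#'
#' @param hits output of [classify_hits()] (or [locate_kmers()]).
#' @param annotation a [genome_annotation()].
#' @param carriers character vector of carrier strain ids.
#' @param gap maximum intra-region gap between consecutive hits (bp).
#' @return data frame of qualifying regions: `strain`, `replicon`, `start`,
#'   `end`, `n_hits`, `ortholog_groups` (comma-separated).
#' @export
carrier_exclusive_regions <- function(hits, annotation, carriers,
                                      gap = 5000L) {
  stopifnot(inherits(annotation, "genome_annotation"))
  genes <- annotation$genes
  k <- if (nrow(hits)) nchar(hits$kmer[1L]) else 0L
  regions <- list()
  for (s in unique(hits$strain)) for (r in unique(hits$replicon[
    hits$strain == s])) {
    pos <- sort(unique(hits$position[hits$strain == s & hits$replicon == r]))
    brk <- c(0L, which(diff(pos) > gap), length(pos))
    for (b in seq_len(length(brk) - 1L)) {
      p <- pos[(brk[b] + 1L):brk[b + 1L]]
      rs <- min(p); re <- max(p) + k - 1L
      g <- genes[genes$replicon == r & genes$start <= re & genes$end >= rs, ,
                 drop = FALSE]
      og <- sort(unique(stats::na.omit(g$ortholog_group)), method = "radix")
      regions[[length(regions) + 1L]] <- data.frame(
        strain = s, replicon = r, start = rs, end = re, n_hits = length(p),
        ortholog_groups = paste(og, collapse = ","),
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(regions) == 0L)
    return(data.frame(strain = character(0), replicon = character(0),
                      start = integer(0), end = integer(0),
                      n_hits = integer(0), ortholog_groups = character(0)))
  regions <- do.call(rbind, regions)
  carriers <- sort(carriers, method = "radix")
  keep <- vapply(seq_len(nrow(regions)), function(i) {
    sig <- regions$ortholog_groups[i]
    if (!nzchar(sig)) return(FALSE)
    have <- sort(unique(regions$strain[regions$ortholog_groups == sig]),
                 method = "radix")
    identical(have, carriers)
  }, logical(1L))
  out <- regions[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
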