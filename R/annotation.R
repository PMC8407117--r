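#' Genome annotation container
#'
#' Bundles the per-strain gene and replicon tables consumed by the mapping
#' stage. Coordinates are 1-based inclusive (GFF3 convention).
#'
#' @param genes data frame with columns `strain`, `replicon`, `start`, `end`,
#'   `strand` (`+`/`-`), `locus_tag`, and optional `cog_id`,
#'   `ortholog_group`, `product`.
#' @param replicons data frame with columns `strain`, `replicon`, `length`,
#'   `role` (one of `chromosome`, `pSymA`, `pSymB`, or another label).
#' @return an object of class `genome_annotation`.
#' @export
genome_annotation <- function(genes, replicons) {
  req <- c("strain", "replicon", "start", "end", "strand", "locus_tag")
  if (!all(req %in% names(genes)))
    stop("genes must have columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  for (col in c("cog_id", "ortholog_group", "product"))
    if (is.null(genes[[col]])) genes[[col]] <- NA_character_
  if (!all(c("strain", "replicon", "length", "role") %in% names(replicons)))
    stop("replicons must have columns strain, replicon, length, role",
         call. = FALSE)
  m <- match(genes$replicon, replicons$replicon)
  if (anyNA(m))
    stop("genes reference unknown replicons: ",
         paste(unique(genes$replicon[is.na(m)]), collapse = ", "),
         call. = FALSE)
  bad <- genes$start < 1L | genes$start > genes$end |
    genes$end > replicons$length[m]
  if (any(bad))
    stop("gene coordinates out of range for: ",
         paste(genes$locus_tag[bad], collapse = ", "), call. = FALSE)
  dup <- stats::aggregate(locus_tag ~ strain, genes,
                          function(x) anyDuplicated(x) > 0L)
  if (any(dup$locus_tag))
    stop("duplicate locus_tag within strain(s): ",
         paste(dup$strain[dup$locus_tag], collapse = ", "), call. = FALSE)
  rownames(genes) <- NULL
  rownames(replicons) <- NULL
  structure(list(genes = genes, replicons = replicons),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("genome_annotation:", nrow(x$genes), "genes on",
      nrow(x$replicons), "replicons across",
      length(unique(x$replicons$strain)), "strains\n")
  invisible(x)
}

# replicon role from the "<strain>_<role>" record id convention
role_from_replicon <- function(replicon_id) {
  sub("^[^_]*_", "", replicon_id)
}

#' Read strain genomes from FASTA files
#'
#' @param paths character vector of FASTA file paths (one file per strain) or
#'   a single directory containing `.fasta`/`.fa` files.
#' @return named list (strain = file base name) of named character vectors
#'   (record id -> uppercase sequence).
#' @export
read_genomes <- function(paths) {
  if (length(paths) == 1L && dir.exists(paths))
    paths <- list.files(paths, pattern = "\\.(fa|fasta)$", full.names = TRUE)
  out <- lapply(paths, function(p) {
    ss <- Biostrings::readDNAStringSet(p)
    seqs <- toupper(as.character(ss))
    names(seqs) <- sub("\\s.*$", "", names(ss))
    seqs
  })
  names(out) <- sub("\\.(fa|fasta)$", "", basename(paths))
  out
}

#' Write strain genomes as wrapped FASTA
#'
#' @param genomes named list (strain) of named character vectors
#'   (replicon id -> sequence).
#' @param dir output directory; one `<strain>.fasta` per strain, 80-column
#'   wrapped.
#' @return invisibly, the paths written.
#' @export
write_genomes <- function(genomes, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(genomes), function(s) {
    p <- file.path(dir, paste0(s, ".fasta"))
    ss <- Biostrings::DNAStringSet(genomes[[s]])
    Biostrings::writeXStringSet(ss, p, width = 80L)
    p
  }, character(1L))
  invisible(paths)
}

#' Write a genome annotation as GFF3
#'
#' One `##gff-version 3` file per strain with 1-based inclusive coordinates
#' and attributes `ID`, `locus_tag`, and (when present) `cog_id`,
#' `ortholog_group`, `product`.
#'
#' @param annotation a [genome_annotation()] object.
#' @param dir output directory; files are named `<strain>.gff3`.
#' @return invisibly, the paths written.
#' @export
write_gff3 <- function(annotation, dir) {
  stopifnot(inherits(annotation, "genome_annotation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  strains <- unique(annotation$replicons$strain)
  paths <- vapply(strains, function(s) {
    g <- annotation$genes[annotation$genes$strain == s, , drop = FALSE]
    r <- annotation$replicons[annotation$replicons$strain == s, , drop = FALSE]
    p <- file.path(dir, paste0(s, ".gff3"))
    attr_str <- function(nm, val) ifelse(is.na(val), "",
                                         paste0(";", nm, "=", val))
    lines <- c(
      "##gff-version 3",
      sprintf("##sequence-region %s 1 %d", r$replicon, r$length),
      if (nrow(g)) sprintf(
        "%s\trhizokmer\tgene\t%d\t%d\t.\t%s\t.\tID=%s;locus_tag=%s%s%s%s",
        g$replicon, g$start, g$end, g$strand, g$locus_tag, g$locus_tag,
        attr_str("cog_id", g$cog_id),
        attr_str("ortholog_group", g$ortholog_group),
        attr_str("product", gsub("[;=\t]", "_", g$product)))
    )
    writeLines(lines, p)
    p
  }, character(1L))
  invisible(paths)
}

#' Read genome annotations from GFF3 files
#'
#' @param paths GFF3 paths (one per strain; strain id taken from the file base
#'   name) or a directory of `.gff3`/`.gff` files.
#' @return a [genome_annotation()] object. Replicon roles are parsed from the
#'   `<strain>_<role>` record id convention.
#' @export
read_annotation <- function(paths) {
  if (length(paths) == 1L && dir.exists(paths))
    paths <- list.files(paths, pattern = "\\.gff3?$", full.names = TRUE)
  strains <- sub("\\.gff3?$", "", basename(paths))
  genes <- list(); reps <- list()
  for (i in seq_along(paths)) {
    gr <- rtracklayer::import(paths[i], format = "gff3")
    mc <- S4Vectors::mcols(gr)
    getcol <- function(nm) {
      v <- if (nm %in% names(mc)) as.character(mc[[nm]]) else
        rep(NA_character_, length(gr))
      v
    }
    genes[[i]] <- data.frame(
      strain = strains[i],
      replicon = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr),
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      locus_tag = getcol("locus_tag"),
      cog_id = getcol("cog_id"),
      ortholog_group = getcol("ortholog_group"),
      product = getcol("product"),
      stringsAsFactors = FALSE
    )
    hdr <- grep("^##sequence-region", readLines(paths[i], n = 200L),
                value = TRUE)
    parts <- strsplit(hdr, "\\s+")
    sl <- stats::setNames(vapply(parts, function(p) as.integer(p[4L]),
                                 integer(1L)),
                          vapply(parts, `[[`, character(1L), 2L))
    if (length(sl) == 0L) {   # fall back to feature extents
      ends <- tapply(GenomicRanges::end(gr),
                     as.character(GenomicRanges::seqnames(gr)), max)
      sl <- stats::setNames(as.integer(ends), names(ends))
    }
    reps[[i]] <- data.frame(
      strain = strains[i],
      replicon = names(sl),
      length = as.integer(sl),
      role = role_from_replicon(names(sl)),
      stringsAsFactors = FALSE
    )
  }
  genome_annotation(do.call(rbind, genes), do.call(rbind, reps))
}

#' Read and write per-plant nodule count tables
#'
#' Tab-separated with header
#' `competition_id strain_id plant_id n_green n_red n_mixed`.
#'
#' @param path file path.
#' @return `read_nodule_counts` returns the validated data frame.
#' @export
read_nodule_counts <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_nodule_counts(x)
}

#' @rdname read_nodule_counts
#' @param counts a nodule count data frame.
#' @export
write_nodule_counts <- function(counts, path) {
  validate_nodule_counts(counts)
  utils::write.table(counts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

validate_nodule_counts <- function(x) {
  req <- c("competition_id", "strain_id", "plant_id",
           "n_green", "n_red", "n_mixed")
  if (!all(req %in% names(x)))
    stop("nodule count table must have columns: ",
         paste(req, collapse = ", "), call. = FALSE)
  cts <- as.matrix(x[, c("n_green", "n_red", "n_mixed")])
  if (any(cts < 0) || any(cts != round(cts)))
    stop("nodule counts must be non-negative integers", call. = FALSE)
  key <- paste(x$competition_id, x$strain_id, x$plant_id)
  if (anyDuplicated(key))
    stop("(strain_id, plant_id) must be unique within a competition_id",
         call. = FALSE)
  x
}

#' Write a full simulated data set to disk
#'
#' Emits per-strain FASTA and GFF3, a replicon table, the planted-truth JSON
#' and (when supplied) the nodule count TSV.
#'
#' @param sim a `rhizo_sim` object.
#' @param dir output directory.
#' @param counts optional nodule count table to include.
#' @return invisibly, `dir`.
#' @export
write_simulation <- function(sim, dir, counts = NULL) {
  stopifnot(inherits(sim, "rhizo_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genomes(sim$genomes, dir)
  write_gff3(sim$annotation, dir)
  utils::write.table(sim$annotation$replicons, file.path(dir, "replicons.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- sim$truth
  jsonlite::write_json(
    list(causal_kmers = truth$causal_kmers,
         block_kmers = truth$block_kmers,
         carrier_map = truth$carrier_map,
         true_phenotype = as.list(truth$true_phenotype),
         blocks = truth$blocks),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(counts))
    write_nodule_counts(counts, file.path(dir, "nodule_counts.tsv"))
  invisible(dir)
}
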