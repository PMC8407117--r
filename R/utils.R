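# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG state
#'
#' Sets the seed, evaluates `code`, and restores the caller's RNG state so
#' seeded simulation helpers do not perturb the session stream.
#' @noRd
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

#' Reverse complement of DNA strings
#'
#' @param x character vector of sequences over A, C, G, T, N.
#' @return character vector of reverse complements.
#' @examples
#' revcomp("ACGTT")
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(comp, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

# Validate that a sequence only uses A/C/G/T/N; error names record and offset.
check_alphabet <- function(seq, record = "<sequence>") {
  bad <- regexpr("[^ACGTN]", seq)
  if (bad > 0L) {
    stop("non-IUPAC character '", substring(seq, bad, bad),
         "' in record ", record, " at offset ", bad, call. = FALSE)
  }
  invisible(TRUE)
}

#' Canonical k-mers of one sequence
#'
#' Slides a window of length `k` over `seq`; every window is collapsed to its
#' canonical form (lexicographic minimum of the window and its reverse
#' complement). Windows containing N are dropped.
#'
#' @param seq single character string over A, C, G, T, N (uppercase).
#' @param k window length (default 13).
#' @return character vector with one canonical k-mer per retained window,
#'   in positional order.
#' @examples
#' seq_kmers("ACGTACGTACGTA", k = 13)
#' @export
seq_kmers <- function(seq, k = 13L) {
  k <- as.integer(k)
  n <- nchar(seq)
  if (n < k) return(character(0L))
  starts <- seq_len(n - k + 1L)
  fwd <- substring(seq, starts, starts + k - 1L)
  rc <- revcomp(seq)
  # revcomp of seq[i .. i+k-1] sits at rc[n-k+2-i .. n+1-i]
  rev <- substring(rc, n - k + 2L - starts, n + 1L - starts)
  keep <- !grepl("N", fwd, fixed = TRUE)
  fwd <- fwd[keep]; rev <- rev[keep]
  ifelse(fwd <= rev, fwd, rev)
}

#' Canonical form of k-mer strings
#'
#' @param x character vector of k-mers.
#' @return canonical (strand-collapsed) form of each k-mer.
#' @export
canonical_kmer <- function(x) {
  rc <- revcomp(x)
  ifelse(x <= rc, x, rc)
}

# Random DNA string of length n drawn i.i.d. uniform over {A,C,G,T}.
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Replace the bases of `seq` at `pos` with `repl` (same length).
replace_bases <- function(seq, pos, repl) {
  s <- strsplit(seq, "", fixed = TRUE)[[1L]]
  s[pos] <- repl
  paste(s, collapse = "")
}

# Draw substitutions: for each position, a base different from the current one.
substitute_bases <- function(current) {
  bases <- c("A", "C", "G", "T")
  vapply(current, function(b) sample(setdiff(bases, b), 1L), character(1L),
         USE.NAMES = FALSE)
}
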