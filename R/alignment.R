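# Aligned sequence container, FASTA I/O, column cleaning, allele collapsing.

DNA_BASES <- c("A", "C", "G", "T")

#' Construct an alignment of equal-length nucleotide sequences
#'
#' The alignment is the unit all diversity measures consume: `n` sequences
#' (one per individual) of identical length. Sequences are uppercased;
#' identifiers must be unique.
#'
#' @param seqs Character vector of nucleotide sequences (equal lengths).
#' @param ids Optional character vector of unique identifiers; defaults to
#'   `seq_1 ... seq_n`.
#' @return An object of class `"alignment"` with fields `ids`, `seqs`,
#'   `n` (number of sequences) and `length` (sites per sequence).
#' @examples
#' alignment(c("AAA", "GGG", "TTT"))
#' @export
alignment <- function(seqs, ids = NULL) {
  if (length(seqs) < 1L) stop("alignment needs at least one sequence", call. = FALSE)
  seqs <- toupper(as.character(seqs))
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1L) {
    stop("all sequences in an alignment must have the same length", call. = FALSE)
  }
  if (is.null(ids)) ids <- paste0("seq_", seq_along(seqs))
  ids <- as.character(ids)
  if (length(ids) != length(seqs)) stop("ids and seqs lengths differ", call. = FALSE)
  if (anyDuplicated(ids)) stop("sequence identifiers must be unique", call. = FALSE)
  structure(
    list(ids = ids, seqs = unname(seqs), n = length(seqs), length = lens[1L]),
    class = "alignment"
  )
}

#' @export
print.alignment <- function(x, ...) {
  cat(sprintf("Alignment: %d sequences x %d sites\n", x$n, x$length))
  k <- min(x$n, 5L)
  for (i in seq_len(k)) {
    s <- x$seqs[i]
    if (nchar(s) > 60) s <- paste0(substr(s, 1, 57), "...")
    cat(sprintf("  %s  %s\n", x$ids[i], s))
  }
  if (x$n > k) cat(sprintf("  ... and %d more\n", x$n - k))
  invisible(x)
}

#' Read an aligned FASTA file
#'
#' Wraps [ape::read.FASTA()]; sequences are uppercased and must be of equal
#' length (the file must already be aligned).
#'
#' @param path Path to a FASTA file.
#' @return An [alignment()].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dna <- suppressWarnings(ape::read.FASTA(path))
  if (length(dna) == 0L) stop("no sequences found in ", path, call. = FALSE)
  seqs <- vapply(as.character(dna), paste, character(1), collapse = "")
  alignment(seqs, ids = names(dna))
}

#' Write an alignment to FASTA
#'
#' @param a An [alignment()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(a, path) {
  stopifnot(inherits(a, "alignment"))
  dna <- ape::as.DNAbin(strsplit(tolower(a$seqs), ""))
  names(dna) <- a$ids
  ape::write.FASTA(dna, path)
  invisible(path)
}

# alignment -> n x L character matrix
seq_char_matrix <- function(a) {
  matrix(unlist(strsplit(a$seqs, ""), use.names = FALSE),
         nrow = a$n, ncol = a$length, byrow = TRUE)
}

char_matrix_to_seqs <- function(m) {
  if (ncol(m) == 0L) return(rep("", nrow(m)))
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

#' Remove alignment columns containing gaps, unknown or ambiguous bases
#'
#' Every column holding any character outside `A, C, G, T` (gaps, `N`, IUPAC
#' ambiguity codes, ...) is deleted, so that downstream substitution rates
#' are defined on plain nucleotide states only. Row order and identifiers
#' are preserved.
#'
#' @param a An [alignment()].
#' @return A cleaned [alignment()]; a warning is emitted if every column was
#'   removed (the result then has length 0).
#' @export
remove_gap_unknown_columns <- function(a) {
  stopifnot(inherits(a, "alignment"))
  m <- seq_char_matrix(a)
  keep <- colSums(matrix(m %in% DNA_BASES, nrow = a$n)) == a$n
  if (!any(keep)) {
    warning("all columns contained gap/unknown characters; returning a length-0 alignment",
            call. = FALSE)
  }
  out <- alignment_allow_empty(char_matrix_to_seqs(m[, keep, drop = FALSE]), a$ids)
  copy_demes(out, a)
}

# like alignment() but tolerates length-0 sequences (post-cleaning edge case)
alignment_allow_empty <- function(seqs, ids) {
  structure(
    list(ids = as.character(ids), seqs = unname(as.character(seqs)),
         n = length(seqs), length = nchar(seqs[1L])),
    class = "alignment"
  )
}

# carry the per-sequence deme attribute (set by the simulator) across subsetting
copy_demes <- function(to, from) {
  if (!is.null(attr(from, "demes"))) attr(to, "demes") <- attr(from, "demes")
  to
}

is_clean <- function(a) {
  a$length == 0L || !grepl("[^ACGT]", paste(a$seqs, collapse = ""))
}

assert_clean <- function(a) {
  if (!is_clean(a)) {
    stop("alignment contains non-ACGT characters; apply remove_gap_unknown_columns() first",
         call. = FALSE)
  }
  invisible(a)
}

#' Subset an alignment by sequence index
#'
#' @param a An [alignment()].
#' @param idx Integer indices of the sequences to keep.
#' @return An [alignment()] with the selected sequences.
#' @export
subset_alignment <- function(a, idx) {
  stopifnot(inherits(a, "alignment"))
  out <- alignment_allow_empty(a$seqs[idx], a$ids[idx])
  d <- attr(a, "demes")
  if (!is.null(d)) attr(out, "demes") <- d[idx]
  out
}

#' Collapse an alignment into its distinct allele types
#'
#' Haplotype identity is exact string equality on the cleaned sequences.
#' Haplotypes are reported in order of first occurrence.
#'
#' @param a A cleaned [alignment()].
#' @return An object of class `"allele_set"` with fields `haplotypes`
#'   (distinct sequences), `counts`, `freqs` (counts/n), `m` (number of
#'   allele types), `n` (sample size) and `index` (haplotype id of each
#'   input sequence).
#' @export
collapse_alleles <- function(a) {
  stopifnot(inherits(a, "alignment"))
  assert_clean(a)
  haps <- unique(a$seqs)
  idx <- match(a$seqs, haps)
  counts <- tabulate(idx, nbins = length(haps))
  structure(
    list(haplotypes = haps, counts = counts, freqs = counts / a$n,
         m = length(haps), n = a$n, index = idx,
         length = a$length),
    class = "allele_set"
  )
}

#' @export
print.allele_set <- function(x, ...) {
  cat(sprintf("Allele set: m = %d types among n = %d sequences\n", x$m, x$n))
  invisible(x)
}
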