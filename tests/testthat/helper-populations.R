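# Shared fixture builders: everything is generated in code at test time.

# random cleaned alignment of n sequences x len sites
random_alignment <- function(n, len, ids = paste0("s", seq_len(n))) {
  seqs <- vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
  alignment(seqs, ids = ids)
}

# write an alignment (or raw lines) to a temporary FASTA file
write_temp_fasta <- function(x, wrap = FALSE) {
  path <- tempfile(fileext = ".fasta")
  if (inherits(x, "alignment")) {
    lines <- character(0)
    for (i in seq_len(x$n)) {
      s <- x$seqs[i]
      body <- if (wrap) {
        starts <- seq(1, nchar(s), by = 10)
        vapply(starts, function(j) substr(s, j, min(j + 9, nchar(s))), character(1))
      } else {
        s
      }
      lines <- c(lines, paste0(">", x$ids[i]), body)
    }
    writeLines(lines, path)
  } else {
    writeLines(x, path)
  }
  path
}

# the three-sequence toy population used in the worked examples
toy_three <- function() alignment(c("AAA", "GGG", "TTT"), ids = c("a", "b", "c"))

# brute-force nucleotide diversity: direct double sum over sequences
brute_pi <- function(a) {
  tot <- 0
  for (i in seq_len(a$n)) {
    for (j in seq_len(a$n)) {
      tot <- tot + pairwise_substitution_rate(a$seqs[i], a$seqs[j]) / a$n^2
    }
  }
  tot
}

# brute-force sigma: mean pairwise rate over ordered pairs of distinct alleles
brute_sigma <- function(a) {
  haps <- unique(a$seqs)
  m <- length(haps)
  if (m == 1) return(0)
  tot <- 0
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      if (i != j) tot <- tot + pairwise_substitution_rate(haps[i], haps[j])
    }
  }
  tot / (m * (m - 1))
}
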