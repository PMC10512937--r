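test_that("pairwise substitution rate is the per-site mismatch fraction", {
  expect_equal(pairwise_substitution_rate("AAA", "GGG"), 1)
  expect_equal(pairwise_substitution_rate("ACGT", "ACGT"), 0)
  expect_equal(pairwise_substitution_rate("AAT", "AAA"), 1 / 3)
  expect_equal(pairwise_substitution_rate("AAT", "AAA"),
               pairwise_substitution_rate("AAA", "AAT"))
  expect_error(pairwise_substitution_rate("AA", "AAA"), "equal length")
})

test_that("rate matrix agrees with scalar rates and an independent p-distance", {
  set.seed(31)
  a <- random_alignment(8, 60)
  r <- substitution_rate_matrix(a$seqs)
  expect_equal(diag(r), rep(0, 8))
  expect_equal(r, t(r))
  for (pair in list(c(1, 2), c(3, 7), c(5, 8))) {
    expect_equal(r[pair[1], pair[2]],
                 pairwise_substitution_rate(a$seqs[pair[1]], a$seqs[pair[2]]))
  }
  # independent route: ape's raw pairwise distance
  dna <- ape::as.DNAbin(strsplit(tolower(a$seqs), ""))
  ref <- as.matrix(ape::dist.dna(dna, model = "raw"))
  expect_equal(unname(r), unname(ref), tolerance = 1e-12)
})

test_that("expected heterozygosity follows 1 - sum(p^2) and its corrected form", {
  expect_equal(expected_heterozygosity(1), 0)
  expect_equal(expected_heterozygosity(c(0.5, 0.5)), 0.5)
  expect_equal(expected_heterozygosity(rep(0.2, 5)), 0.8)
  expect_error(expected_heterozygosity(c(-0.1, 1.1)), "non-negative")

  expect_equal(expected_heterozygosity_unbiased(1, 10), 0)
  expect_equal(expected_heterozygosity_unbiased(c(0.5, 0.5), 2), 2 / 3)
  # large-n limit recovers the uncorrected value
  expect_equal(expected_heterozygosity_unbiased(c(0.5, 0.5), 1e9), 0.5,
               tolerance = 1e-8)
  expect_error(expected_heterozygosity_unbiased(c(0.5, 0.5), 0), ">= 1")
})

test_that("nucleotide diversity matches the hand-enumerated double sum", {
  # monomorphic
  mono <- collapse_alleles(alignment(c("AAA", "AAA")))
  r0 <- substitution_rate_matrix(mono$haplotypes)
  expect_equal(nucleotide_diversity(mono$freqs, r0), 0)

  # two alleles at rate 1, equal frequencies
  expect_equal(nucleotide_diversity(c(0.5, 0.5), matrix(c(0, 1, 1, 0), 2)), 0.5)
  expect_equal(
    nucleotide_diversity(c(0.5, 0.5), matrix(c(0, 1, 1, 0), 2),
                         corrected = TRUE, n = 2),
    1
  )

  # {AAA, AAT, AAA}: direct hand enumeration gives 4/27 and 2/9
  a <- alignment(c("AAA", "AAT", "AAA"))
  al <- collapse_alleles(a)
  r <- substitution_rate_matrix(al$haplotypes)
  expect_equal(nucleotide_diversity(al$freqs, r), 4 / 27)
  expect_equal(nucleotide_diversity(al$freqs, r, corrected = TRUE, n = 3), 2 / 9)
  expect_error(nucleotide_diversity(1, matrix(0, 1, 1), corrected = TRUE, n = 1),
               "n >= 2")

  # random alignments agree with the brute-force double sum over sequences
  set.seed(7)
  for (i in 1:5) {
    b <- random_alignment(6, 12)
    al <- collapse_alleles(b)
    r <- substitution_rate_matrix(al$haplotypes)
    expect_equal(nucleotide_diversity(al$freqs, r), brute_pi(b), tolerance = 1e-12)
  }
})

test_that("Watterson's theta counts segregating sites over the harmonic number", {
  expect_equal(watterson_theta(alignment(c("AAAA", "AAAA"))), 0)

  # n = 2: harmonic number is 1, so theta equals K
  set.seed(5)
  a2 <- random_alignment(2, 1000)
  k <- segregating_sites(a2)
  expect_equal(watterson_theta(a2), k)
  expect_equal(watterson_theta(a2, per_site = TRUE), k / 1000)

  # n = 4, K = 11 -> 11 / (1 + 1/2 + 1/3) = 6
  a4 <- alignment(c(
    paste0(strrep("A", 11), "AAA"),
    paste0(strrep("C", 11), "AAA"),
    paste0(strrep("A", 11), "AAA"),
    paste0(strrep("A", 11), "AAA")
  ))
  expect_equal(segregating_sites(a4), 11L)
  expect_equal(watterson_theta(a4), 6)
  expect_error(watterson_theta(alignment("AAA")), "n >= 2")
})

test_that("sigma matches the worked examples and the brute-force form", {
  expect_equal(sigma_hat(toy_three()), 1)
  expect_equal(sigma_hat(alignment(c("AAA", "GGG", "TTT", "GGG"))), 1)
  expect_equal(sigma_hat(alignment(c("AAA", "AAA"))), 0)
  expect_equal(sigma_hat(alignment(c("AAA", "AAT"))), 1 / 3)

  set.seed(11)
  for (i in 1:5) {
    a <- random_alignment(7, 10)
    expect_equal(sigma_hat(a), brute_sigma(a), tolerance = 1e-12)
  }
})

test_that("sigma equals corrected nucleotide diversity when all sequences are distinct", {
  set.seed(19)
  for (i in 1:10) {
    a <- random_alignment(6, 25)
    al <- collapse_alleles(a)
    if (al$m < a$n) next
    d <- calc_diversity(a)
    expect_equal(d$sigma_hat, d$pi_tilde, tolerance = 1e-12)
  }
})

test_that("population sigma exceeds pi and converges to it for distinct equal-frequency alleles", {
  set.seed(23)
  for (N in c(4, 8, 16)) {
    a <- random_alignment(N, 200)
    al <- collapse_alleles(a)
    expect_identical(al$m, as.integer(N))  # collisions astronomically unlikely at 200 sites
    r <- substitution_rate_matrix(al$haplotypes)
    pi <- nucleotide_diversity(al$freqs, r)
    sg <- sigma_tilde(al, r)
    expect_equal(sg, pi * N / (N - 1), tolerance = 1e-12)
    expect_gt(sg, pi)
  }
})

test_that("the exhaustive subset oracle is monotone and anchored at its endpoints", {
  # worked toy: the maximising pair already attains 1, and stays at 1
  toy <- toy_three()
  expect_equal(sigma_n_oracle(toy, 2), 1)
  expect_equal(sigma_n_oracle(toy, 3), 1)

  # a duplicate allele leaves the size-2 maximum in place
  dup <- alignment(c("AAA", "AAA", "GGG"))
  expect_equal(sigma_n_oracle(dup, 2), 1)

  # n = N recovers the population statistic
  set.seed(3)
  pop <- random_alignment(7, 15)
  expect_equal(sigma_n_oracle(pop, 7), sigma_hat(pop), tolerance = 1e-12)

  # monotone non-increasing in n
  vals <- vapply(2:7, function(n) sigma_n_oracle(pop, n), numeric(1))
  expect_true(all(diff(vals) <= 1e-12))

  expect_error(sigma_n_oracle(pop, 1), "2 <= n")
  expect_error(sigma_n_oracle(pop, 4, cap = 3), "cap")
})

test_that("the diversity summary is consistent and invariant to reordering", {
  d <- calc_diversity(toy_three())
  expect_equal(d$sigma_hat, 1)
  expect_equal(d$pi_tilde, 1)
  expect_equal(d$He, 2 / 3)
  expect_equal(d$He_hat, 0.8)
  expect_equal(d$theta_w, 2)

  mono <- calc_diversity(alignment(c("AAAA", "AAAA", "AAAA")))
  for (f in c("He", "He_hat", "pi_hat", "pi_tilde", "theta_w", "sigma_hat")) {
    expect_equal(mono[[f]], 0)
  }

  da <- calc_diversity(alignment(c("AAA", "AAT", "AAA")))
  expect_equal(da$pi_tilde, 2 / 9)
  expect_equal(da$sigma_hat, 1 / 3)

  set.seed(13)
  a <- random_alignment(9, 40)
  perm <- sample(9)
  b <- subset_alignment(a, perm)
  d1 <- as.data.frame(calc_diversity(a))
  d2 <- as.data.frame(calc_diversity(b))
  expect_equal(d1, d2)
})
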