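# Tokenization schemes: canonicalization, vocabulary structure, hashing
# properties, encoding and padding.

test_that("revcomp is correct and involutive", {
  expect_equal(revcomp("ACGT"), "ACGT")
  expect_equal(revcomp("AAC"), "GTT")
  expect_equal(revcomp("ANT"), "ANT")
  expect_error(revcomp("ACX"), "outside")
  withr::with_seed(1, {
    s <- replicate(20, rand_dna(sample(1:30, 1)))
    expect_equal(revcomp(revcomp(s)), s)
  })
})

test_that("canonical form is the lexicographic minimum of both strands", {
  expect_equal(canonical_kmer("TTG"), "CAA")
  expect_equal(canonical_kmer("ACG"), "ACG")
  withr::with_seed(2, {
    s <- replicate(50, rand_dna(7))
    expect_equal(canonical_kmer(s), canonical_kmer(revcomp(s)))
    expect_true(all(canonical_kmer(s) <= s))
  })
})

test_that("vocabulary size matches the canonical closed forms up to k = 6", {
  expect_equal(build_vocab(1)$size, 5)   # {A, C} + 3 specials
  expect_equal(build_vocab(2)$size, 13)  # 10 canonical 2-mers
  expect_equal(build_vocab(3)$size, 35)  # 32 canonical 3-mers
  for (k in 1:6) {
    v <- build_vocab(k)
    expect_equal(v$size - 3, n_canonical_kmers(k))
    km <- all_kmers(k)
    ids <- vocab_id(v, km)
    # ids form exactly [3, size): a bijection onto the canonical classes
    expect_setequal(unique(ids), 3:(v$size - 1))
    # strand invariance for every k-mer
    expect_equal(ids, vocab_id(v, revcomp(km)))
    # lexicographic order of canonical k-mers matches id order
    can <- sort(unique(canonical_kmer(km)))
    expect_equal(vocab_id(v, can), 3:(v$size - 1))
  }
})

test_that("k-mer windows follow the stride-1 token count law", {
  expect_equal(kmer_tokens("ACGTA", 3), c("ACG", "CGT", "GTA"))
  expect_equal(length(kmer_tokens(rand_dna(150, seed = 1), 12)), 139)
  expect_equal(kmer_tokens("AC", 3), character(0))
  expect_equal(kmer_tokens("ACGTAC", 2, stride = 2), c("AC", "GT", "AC"))
  withr::with_seed(3, {
    for (i in 1:20) {
      L <- sample(5:60, 1); k <- sample(1:12, 1)
      n <- length(kmer_tokens(rand_dna(L), k))
      expect_equal(n, max(0, L - k + 1))
    }
  })
})

test_that("LSH buckets are strand-invariant, in range, and locality-preserving", {
  sc <- token_scheme("lsh", k = 15, b = 2^20, seed = 4)
  withr::with_seed(5, {
    km <- replicate(200, rand_dna(15))
    bk <- lsh_bucket(km, sc)
    expect_true(all(bk >= 0 & bk < 2^20))
    expect_equal(bk, lsh_bucket(revcomp(km), sc))
  })
  # changing only a non-sampled position cannot change the bucket
  off <- setdiff(seq_len(15), sc$lsh_pos)[1]
  base <- rep("A", 15) # canonical, and stays canonical after an A -> C edit
  other <- base
  other[off] <- "C"
  k1 <- paste(base, collapse = "")
  k2 <- paste(other, collapse = "")
  expect_false(k1 == k2)
  expect_equal(lsh_bucket(k1, sc), lsh_bucket(k2, sc))
})

test_that("hash-embedding indices are strand-invariant and well-spread", {
  sc <- token_scheme("hash", k = 13, b = 2^20, q = 6, seed = 6)
  withr::with_seed(7, km <- replicate(1e4, rand_dna(13)))
  hi <- hash_indices(km, sc)
  hi_rc <- hash_indices(revcomp(km), sc)
  expect_identical(hi, hi_rc)
  expect_true(all(hi$components >= 0 & hi$components < 2^20))
  expect_true(all(hi$importance >= 0 & hi$importance < sc$W))
  # q distinct seeds: component ids almost never all collide
  all_equal <- apply(hi$components, 1, function(r) length(unique(r)) == 1)
  expect_lt(mean(all_equal), 0.01)
  # deterministic across calls (and runs: seeds fix the hashes)
  expect_identical(hi, hash_indices(km, sc))
})

test_that("hash buckets are uniform by chi-square", {
  withr::with_seed(8, {
    cols <- replicate(15, sample(c("A", "C", "G", "T"), 1e6, replace = TRUE),
                      simplify = FALSE)
  })
  km <- do.call(paste0, cols)
  b <- 2^10
  h <- readformer:::cpp_murmur_mod(km, 12345L, b)
  tab <- tabulate(h + 1L, nbins = b)
  p <- stats::chisq.test(tab)$p.value
  expect_gt(p, 0.001)
})

test_that("encode_read maps windows to ids with UNK and CLS handling", {
  sc <- token_scheme("vocab", k = 3, seed = 1)
  ts <- encode_read(c(r1 = "ACGTA"), sc)
  expect_equal(ts$n, 3)
  expect_true(all(ts$ids >= 3))

  tsN <- encode_read(c(r1 = "ACNTA"), sc)
  expect_equal(tsN$ids, c(1L, 1L, 1L))   # every window contains N

  tsc <- encode_read(c(r1 = "ACGTA"), sc, with_cls = TRUE)
  expect_equal(tsc$ids[1], 2L)
  expect_equal(length(tsc$ids), 4)

  expect_error(encode_read(c(short = "AC"), sc), "short")

  # token multiset is strand-invariant under the vocab scheme
  withr::with_seed(9, {
    for (i in 1:10) {
      r <- rand_dna(30)
      a <- encode_read(c(x = r), sc)$ids
      b <- encode_read(c(x = revcomp(r)), sc)$ids
      expect_equal(sort(a), sort(b))
    }
  })
})

test_that("character tokenization keeps every base including N", {
  sc <- token_scheme("char", seed = 1)
  ts <- encode_read(c(r = "ACGTN"), sc)
  expect_equal(ts$ids, c(3L, 4L, 5L, 6L, 7L))
})

test_that("token streams are truncated at n_max with a log message", {
  sc <- token_scheme("vocab", k = 3, n_max = 5L, seed = 1)
  expect_message(ts <- encode_read(c(r = rand_dna(20, seed = 1)), sc),
                 "truncated")
  expect_equal(ts$n, 5)
})

test_that("pad_batch aligns streams and masks padding", {
  sc <- token_scheme("vocab", k = 3, seed = 1)
  s1 <- encode_read(c(a = "ACGTA"), sc)    # 3 tokens
  s2 <- encode_read(c(b = "ACGTACG"), sc)  # 5 tokens
  pb <- pad_batch(list(s1, s2))
  expect_equal(dim(pb$ids), c(2, 5))
  expect_equal(pb$mask[1, ], c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(rowSums(pb$mask), c(3, 5))
  expect_true(all(pb$ids[pb$mask] != 0))   # PAD never under a true mask
  expect_true(all(pb$ids[!pb$mask] == 0))

  same <- pad_batch(list(s1, s1))
  expect_true(all(same$mask))
})
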