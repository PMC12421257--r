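# brute-force canonical k-mer set of a sequence, as an oracle
r_kmer_set <- function(seq, k = 31L) {
  n <- nchar(seq)
  if (n < k) return(character())
  kms <- substring(seq, 1:(n - k + 1), k:n)
  kms <- kms[!grepl("N", kms)]
  unique(pmin(kms, vapply(kms, function(x) as.character(revcomp(x)),
                          character(1))))
}

test_that("index equivalence classes match brute-force k-mer set algebra", {
  a <- rand_dna(200, 11)
  b <- sub_at(a, 100L)  # one SNP
  fps <- list(build_fingerprint("m1", a, 1L), build_fingerprint("m2", b, 1L))
  idx <- build_index(fps)
  cls <- index_classes(idx)
  shared <- which(vapply(cls, function(x) setequal(x, c("m1", "m2")),
                         logical(1)))
  only1 <- which(vapply(cls, function(x) identical(x, "m1"), logical(1)))
  expect_equal(length(shared), 1)
  expect_equal(length(only1), 1)
  # member-specific k-mer counts around the SNP, against the set oracle
  ka <- r_kmer_set(a); kb <- r_kmer_set(b)
  info <- fingerquant:::cpp_index_info(idx$ptr)
  expect_equal(info$n_kmers, length(union(ka, kb)))
  # identical fingerprints: a single class containing both members
  fps2 <- list(build_fingerprint("m1", a, 1L), build_fingerprint("m2", a, 2L))
  cls2 <- index_classes(build_index(fps2))
  expect_equal(length(cls2), 1)
  expect_setequal(cls2[[1]], c("m1", "m2"))
  # single member: one class
  expect_equal(length(index_classes(build_index(fps[1]))), 1)
})

test_that("the spacer prevents k-mers across haplotype junctions", {
  a <- rand_dna(100, 13); b <- rand_dna(100, 14)
  fp <- build_fingerprint("m", c(a, b), c(1L, 1L))
  idx <- build_index(list(fp))
  info <- fingerquant:::cpp_index_info(idx$ptr)
  expect_equal(info$n_kmers, length(union(r_kmer_set(a), r_kmer_set(b))))
})

test_that("pseudoalignment distinguishes members through a discriminating SNP", {
  base <- rand_dna(300, 17)
  alt <- sub_at(base, 150L)
  fps <- list(build_fingerprint("X", base, 1L),
              build_fingerprint("Y", alt, 1L))
  idx <- build_index(fps)
  # read from the shared region: both members
  shared_read <- substr(base, 1, 100)
  cand <- pseudoalign(idx, shared_read)
  expect_setequal(idx$members[cand[[1]]], c("X", "Y"))
  # read covering the SNP: only the matching member
  snp_read <- substr(alt, 101, 200)
  cand2 <- pseudoalign(idx, snp_read)
  expect_equal(idx$members[cand2[[1]]], "Y")
  # exact substring of one member only
  cand3 <- pseudoalign(idx, substr(base, 120, 220))
  expect_equal(idx$members[cand3[[1]]], "X")
  # unindexed read
  expect_equal(length(pseudoalign(idx, rand_dna(100, 23))[[1]]), 0)
})

test_that("identity validation enforces the 0.95 floor", {
  ref <- rand_dna(400, 19)
  fps <- list(build_fingerprint("m", ref, 1L))
  idx <- build_index(fps)
  exact <- substr(ref, 51, 300)            # 250 bp
  mm10 <- sub_at(exact, seq(10L, 100L, by = 10L))   # 10 subs -> 0.96
  mm20 <- sub_at(exact, seq(10L, 200L, by = 10L))   # 20 subs -> 0.92
  cand <- list(1L, 1L, 1L)
  val <- validate_identity(idx, c(exact, mm10, mm20), candidates = cand)
  expect_equal(val$identity[[1]], 1.0)
  expect_equal(length(val$candidates[[1]]), 1)
  expect_equal(round(val$identity[[2]], 2), 0.96)
  expect_equal(length(val$candidates[[2]]), 1)
  expect_equal(length(val$candidates[[3]]), 0)  # 0.92 < 0.95 removed
})

test_that("EM reaches closed-form fixed points", {
  # 9 unique to X, 1 unique to Y, 10 shared: theta = (0.9, 0.1)
  asg <- c(replicate(9, 1L, simplify = FALSE), list(2L),
           replicate(10, c(1L, 2L), simplify = FALSE))
  em <- em_quantify(asg, 2)
  expect_equal(em$theta, c(0.9, 0.1), tolerance = 1e-6)
  expect_equal(em$raw_counts, c(18, 2), tolerance = 1e-5)
  # all shared, no unique evidence: symmetric split
  em2 <- em_quantify(replicate(8, c(1L, 2L), simplify = FALSE), 2)
  expect_equal(em2$raw_counts, c(4, 4))
  # all unique: tallies, 1-2 iterations
  em3 <- em_quantify(c(replicate(5, 1L, simplify = FALSE),
                       replicate(3, 2L, simplify = FALSE)), 2)
  expect_equal(em3$raw_counts, c(5, 3))
  # no assigned reads
  em0 <- em_quantify(list(integer(), integer()), 2)
  expect_equal(em0$mapping_rate, 0)
  expect_equal(em0$raw_counts, c(0, 0))
})

test_that("EM is monotone in log-likelihood and conserves reads", {
  withr::with_seed(31, {
    for (i in 1:10) {
      M <- sample(2:6, 1)
      n <- sample(20:100, 1)
      asg <- lapply(seq_len(n), function(j) {
        sort(sample(seq_len(M), sample(seq_len(M), 1)))
      })
      em <- em_quantify(asg, M)
      expect_true(all(diff(em$loglik_trace) >= -1e-9))
      expect_equal(sum(em$raw_counts), n, tolerance = 1e-6)
    }
  })
})

test_that("copy-number normalization divides then renormalizes", {
  expect_equal(copy_normalize(c(400, 100), c(4, 1)), c(0.5, 0.5))
  expect_equal(copy_normalize(c(30, 70), c(2, 2)), c(0.3, 0.7))
  expect_equal(copy_normalize(c(x = 50), c(x = 5)), c(x = 1))
  expect_error(copy_normalize(c(a = 10, b = 5), c(a = 2)),
               "no copy number.*b")
})

test_that("read trimming windows behave at the boundaries", {
  rd <- tibble::tibble(id = c("a", "b", "c"),
                       seq = c(rand_dna(250, 1), rand_dna(100, 2),
                               rand_dna(25, 3)),
                       qual = strrep("I", c(250, 100, 25)))
  out <- preprocess_reads(rd)
  expect_equal(out$id, c("a", "b"))
  expect_equal(nchar(out$seq), c(220L, 80L))  # [20,240) and clipped window
  expect_equal(nchar(out$qual), c(220L, 80L))
})

test_that("validated candidates equal the brute-force alignment oracle", {
  # small instance; the acceptance suite runs the full-size one
  withr::with_seed(41, {
    refs <- lapply(1:5, function(i) rand_dna(350, 100 + i))
    refs[[6]] <- refs[[1]]  # an exact duplicate reference
    fps <- lapply(seq_along(refs), function(i) {
      build_fingerprint(paste0("m", i), refs[[i]], 1L)
    })
    idx <- build_index(fps)
    reads <- vapply(1:60, function(j) {
      src <- sample(seq_along(refs), 1)
      start <- sample(1:(350 - 150), 1)
      r <- substr(refs[[src]], start, start + 149)
      fingerquant:::inject_errors(r, 0.005)
    }, character(1))
  })
  cand <- pseudoalign(idx, reads)
  val <- validate_identity(idx, reads, candidates = cand)
  om <- oracle_identity_matrix(reads, refs)
  for (j in seq_along(reads)) {
    expect_setequal(val$candidates[[j]], which(om[j, ] >= 0.95))
  }
})

test_that("quantify integrates trimming, validation, EM and normalization", {
  com <- simulate_community(n_members = 4, seed = 5)
  amps <- extract_amplicons(com$fingerprints, standard_primers("V3V4"))
  run <- simulate_amplicon_run(amps, com$abundances, n_reads = 4000, seed = 9)
  idx <- build_index(amps)
  q <- quantify(idx, run$reads1, run$reads2)
  expect_s3_class(tidy(q), "tbl_df")
  expect_equal(sum(q$table$norm_abundance), 1, tolerance = 1e-9)
  expect_gte(q$mapping_rate, 0.99)
  expect_true(all(q$table$confidence >= 0 & q$table$confidence <= 1,
                  na.rm = TRUE))
  truth <- com$abundances[q$table$member_id]
  expect_lt(max(abs(q$table$norm_abundance - truth)), 0.03)
  expect_equal(glance(q)$n_detected, 4)
})
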