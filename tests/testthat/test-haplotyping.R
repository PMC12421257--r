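test_that("Phred conversion follows 10^(-q/10)", {
  expect_equal(phred_to_error(30), 0.001)  # the MQ 30 <-> 0.1% error anchor
  expect_equal(phred_to_error(0), 1)
  expect_equal(phred_to_error(10), 0.1)
  expect_error(phred_to_error(-1), "non-negative")
})

locus_fx <- substr(fx_seed, 301, 900)  # 600 bp locus for read tests

mk_reads <- function(seqs, ids = sprintf("r%03d", seq_along(seqs)),
                     mate = NA_integer_) {
  tibble::tibble(id = ids, seq = seqs, qual = strrep("I", nchar(seqs)),
                 mate = mate)
}

test_that("recruitment keeps substring reads, drops random reads, keeps mates", {
  sub_read <- substr(locus_fx, 101, 250)
  rnd <- rand_dna(150, 77)
  rd <- mk_reads(c(sub_read, rnd), ids = c("a/1", "b/1"), mate = 1L)
  rec <- recruit_reads(rd, locus_fx)
  expect_equal(rec$id, "a/1")
  # the mate of a recruited read is included even without shared k-mers
  rd2 <- tibble::tibble(id = c("a/1", "a/2", "b/1"),
                        seq = c(sub_read, rnd, rand_dna(150, 78)),
                        qual = strrep("I", 150), mate = c(1L, 2L, 1L))
  rec2 <- recruit_reads(rd2, locus_fx)
  expect_setequal(rec2$id, c("a/1", "a/2"))
})

test_that("recruitment counts shared k-mers explicitly for diverged reads", {
  # a read from a 90% identical paralog: shared 21-mers decide
  paralog_read <- sub_at(substr(locus_fx, 101, 250),
                         seq(5L, 145L, by = 10L))  # 15 subs over 150 bp
  shared <- fingerquant:::cpp_shared_kmers(paralog_read, locus_fx, 21L)
  rec <- recruit_reads(mk_reads(paralog_read), locus_fx)
  expect_equal(nrow(rec), as.integer(shared >= 2))
})

test_that("alignment of exact and mismatched reads reports mq, identity and base calls", {
  exact <- substr(locus_fx, 151, 300)
  aln <- align_recruited(mk_reads(exact), locus_fx)
  expect_equal(aln$mq, 60)
  expect_equal(aln$identity, 1)
  expect_equal(aln$start, 150L)

  mm <- sub_at(exact, 49L)  # read offset 49 -> locus position 199
  aln2 <- align_recruited(mk_reads(mm), locus_fx)
  expect_equal(substr(aln2$proj, 50, 50), substr(mm, 50, 50))
  expect_lt(aln2$identity, 1)

  # reverse-complemented reads are re-oriented
  aln3 <- align_recruited(mk_reads(as.character(revcomp(exact))), locus_fx)
  expect_equal(aln3$start, 150L)
  expect_equal(aln3$strand, "-")
  expect_equal(aln3$identity, 1)
})

test_that("a read equally similar to a competitor locus gets mq 0", {
  exact <- substr(locus_fx, 151, 300)
  aln <- align_recruited(mk_reads(exact), locus_fx,
                         competitors = locus_fx)  # identical competitor
  expect_equal(aln$mq, 0)
  # a diverged competitor leaves mq high
  far <- sub_at(locus_fx, seq(10L, 590L, by = 10L))
  aln2 <- align_recruited(mk_reads(exact), locus_fx, competitors = far)
  expect_gte(aln2$mq, 30)
})

test_that("pileup conserves aligned bases", {
  withr::with_seed(5, {
    starts <- sample(0:(nchar(locus_fx) - 100), 200, replace = TRUE)
  })
  reads <- substring(locus_fx, starts + 1, starts + 100)
  aln <- align_recruited(mk_reads(reads), locus_fx)
  pile <- build_pileup(aln)
  expect_equal(sum(pile), sum(nchar(aln$proj)))
  expect_equal(nrow(pile), nchar(locus_fx))
})

test_that("variant calling applies depth, count and fraction thresholds", {
  L <- 60L
  ref <- rand_dna(L, 42)
  stopifnot(substr(ref, 31, 31) != "G")
  mk_pile <- function(ref_n, alt_n, pos, alt = "G") {
    pile <- matrix(0L, L, 10,
                   dimnames = list(NULL, c("A+", "C+", "G+", "T+", "del+",
                                           "A-", "C-", "G-", "T-", "del-")))
    refs <- strsplit(ref, "")[[1]]
    for (i in seq_len(L)) {
      pile[i, paste0(refs[i], "+")] <- 25L
      pile[i, paste0(refs[i], "-")] <- 25L
    }
    pile[pos, paste0(refs[pos], "+")] <- ceiling(ref_n / 2)
    pile[pos, paste0(refs[pos], "-")] <- floor(ref_n / 2)
    pile[pos, paste0(alt, "+")] <- ceiling(alt_n / 2)
    pile[pos, paste0(alt, "-")] <- floor(alt_n / 2)
    pile
  }
  # 25 ref / 25 alt, balanced strands: one call at af 0.5
  v <- call_variants(mk_pile(25, 25, 31L), ref)
  expect_equal(nrow(v), 1)
  expect_equal(v$pos, 30L)
  expect_equal(v$alt, "G")
  expect_equal(v$af, 0.5)
  # 49 ref / 1 alt: below count and fraction thresholds
  expect_equal(nrow(call_variants(mk_pile(49, 1, 31L), ref)), 0)
  # monomorphic pileup: no calls
  expect_equal(nrow(call_variants(mk_pile(50, 0, 31L), ref)), 0)
})

test_that("emitted calls from real alignments satisfy the MQ floor and carry annotations", {
  # two haplotypes of the locus differing at one site, 30 reads each
  alt_locus <- sub_at(locus_fx, 299L)
  withr::with_seed(11, starts <- sample(0:(nchar(locus_fx) - 120), 60,
                                        replace = TRUE))
  reads <- c(substring(locus_fx, starts[1:30] + 1, starts[1:30] + 120),
             substring(alt_locus, starts[31:60] + 1, starts[31:60] + 120))
  aln <- align_recruited(mk_reads(reads), locus_fx)
  pile <- build_pileup(aln)
  v <- call_variants(pile, locus_fx, aln)
  expect_equal(v$pos, 299L)
  expect_true(all(v$mean_mq >= 30))
  expect_true(all(v$mean_bq >= 20))
  expect_true(v$strand_bias_p > 0.01)  # no synthetic strand bias
})

test_that("two-haplotype phasing minimizes MEC (exhaustive oracle)", {
  # 10 x (ref,ref), 10 x (alt,alt), 1 x (ref,alt): MEC 1
  rm <- rbind(matrix(0L, 10, 2), matrix(1L, 10, 2), c(0L, 1L))
  rownames(rm) <- sprintf("r%02d", 1:21)
  v2 <- tibble::tibble(pos = c(10L, 20L), ref = "A", alt = "G")
  ph <- phase_two_haplotypes(v2, rm)
  expect_equal(ph$mec, 1)
  expect_true(setequal(list(ph$h1, ph$h2), list(c(0L, 0L), c(1L, 1L))))
  # perfectly linked variants: MEC 0
  rm0 <- rbind(matrix(0L, 8, 3), matrix(1L, 6, 3))
  ph0 <- phase_two_haplotypes(tibble::tibble(pos = c(1L, 2L, 3L)), rm0)
  expect_equal(ph0$mec, 0)
  expect_equal(ph0$fractions, c(8, 6) / 14, tolerance = 1e-9)
  # single variant: haplotypes differ only at that site
  ph1 <- phase_two_haplotypes(tibble::tibble(pos = 5L),
                              matrix(c(0L, 0L, 1L, 1L), 4, 1))
  expect_equal(sort(c(ph1$h1, ph1$h2)), c(0L, 1L))
})

test_that("phasing matches an independent exhaustive MEC search on random instances", {
  # independent oracle: enumerate every first-haplotype allele vector and
  # count flips directly, read by read
  oracle_mec <- function(rm) {
    v <- ncol(rm)
    best <- Inf
    for (code in 0:(2^v - 1)) {
      h <- as.integer(intToBits(code)[1:v])
      cost <- 0
      for (i in seq_len(nrow(rm))) {
        obs <- rm[i, ]
        ok <- !is.na(obs)
        m1 <- sum(obs[ok] != h[ok])
        m2 <- sum(obs[ok] != (1 - h)[ok])
        cost <- cost + min(m1, m2)
      }
      best <- min(best, cost)
    }
    best
  }
  withr::with_seed(202, {
    for (rep in 1:10) {
      v <- sample(2:5, 1)
      n <- sample(8:20, 1)
      truth <- sample(0:1, v, replace = TRUE)
      rm <- matrix(NA_integer_, n, v)
      for (i in seq_len(n)) {
        hap <- if (runif(1) < 0.5) truth else 1 - truth
        span <- sort(sample(seq_len(v), sample(1:v, 1)))
        rm[i, span] <- hap[span]
        if (runif(1) < 0.15) {  # an error flip
          j <- sample(span, 1)
          rm[i, j] <- 1 - rm[i, j]
        }
      }
      rm <- rm[rowSums(!is.na(rm)) > 0, , drop = FALSE]
      vars <- tibble::tibble(pos = seq_len(v))
      expect_equal(phase_two_haplotypes(vars, rm)$mec, oracle_mec(rm))
      # the restart heuristic reaches the same optimum on small instances
      expect_equal(phase_two_haplotypes(vars, rm, max_exact = 0L)$mec,
                   oracle_mec(rm))
    }
  })
})

test_that("haplotype assembly applies substitutions, deletions and insertions", {
  locus <- rand_dna(200, 9)
  # zero variants: the consensus alone
  h0 <- assemble_haplotypes(locus, tibble::tibble(pos = integer(),
                                                  ref = character(),
                                                  alt = character()),
                            list(h1 = integer(), h2 = NULL, fractions = 1))
  expect_equal(h0$seq, locus)
  # one SNP at position 100 (0-based)
  v1 <- tibble::tibble(pos = 100L, ref = substr(locus, 101, 101), alt = "T")
  stopifnot(v1$ref != "T")
  ph <- list(h1 = 1L, h2 = 0L, fractions = c(0.6, 0.4))
  h1 <- assemble_haplotypes(locus, v1, ph)
  expect_equal(nrow(h1), 2)
  d <- mapply(function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]),
              h1$seq[1], h1$seq[2])
  expect_equal(unname(d), 1)
  # a 3 bp deletion (three consecutive single-base deletion alleles)
  v3 <- tibble::tibble(pos = c(50L, 51L, 52L),
                       ref = substring(locus, 51:53, 51:53), alt = "-")
  ph3 <- list(h1 = c(1L, 1L, 1L), h2 = c(0L, 0L, 0L),
              fractions = c(0.5, 0.5))
  h3 <- assemble_haplotypes(locus, v3, ph3)
  expect_setequal(nchar(h3$seq), c(200L, 197L))
  # an insertion allele
  vi <- tibble::tibble(pos = 80L, ref = substr(locus, 81, 81), alt = "+ACG")
  hi <- assemble_haplotypes(locus, vi,
                            list(h1 = 1L, h2 = 0L, fractions = c(0.5, 0.5)))
  expect_setequal(nchar(hi$seq), c(200L, 203L))
})

test_that("both haplotypes are recovered exactly across simulated replicates", {
  # reduced-depth version of the recovery property (the acceptance suite
  # runs the full grid); d in {1,2,5} sites, 50x coverage, 0.1% error
  sdt <- seed_target(fx_seed)
  for (d in c(1L, 2L, 5L)) {
    ok <- 0L
    for (s in 1:8) {
      cfg <- sim_config(seed = 1000L * d + s, n_copies = 2L,
                        n_haplotypes = 2L, n_variant_sites = d)
      sim <- simulate_isolate(cfg, seed_marker = fx_seed)
      res <- fingerprint_genome(sim$assembly, sim$reads, sdt)
      ok <- ok + setequal(res$fingerprint$haplotypes$seq,
                          sim$truth$haplotypes$seq)
    }
    expect_gte(ok, 7L)
  }
})
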