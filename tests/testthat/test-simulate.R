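test_that("simulated isolates embed the configured copies and haplotypes", {
  cfg <- sim_config(seed = 3, n_copies = 4L, n_haplotypes = 2L,
                    n_variant_sites = 1L)
  sim <- simulate_isolate(cfg, seed_marker = fx_seed)
  expect_equal(nrow(sim$truth$loci), 4)
  expect_equal(nrow(sim$truth$haplotypes), 2)
  d <- mapply(function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]),
              sim$truth$haplotypes$seq[1], sim$truth$haplotypes$seq[2])
  expect_equal(unname(d), 1)
  # the embedded loci really carry the stated haplotypes
  g <- sim$assembly$seq
  for (i in seq_len(nrow(sim$truth$loci))) {
    lc <- sim$truth$loci[i, ]
    seg <- substr(g, lc$start + 1, lc$end)
    if (lc$strand == "-") seg <- as.character(revcomp(seg))
    expect_equal(seg, sim$truth$haplotypes$seq[lc$haplotype])
  }
  # read count follows coverage * genome / read_len
  expect_equal(nrow(sim$reads),
               round(cfg$coverage * cfg$genome_len / cfg$read_len))
})

test_that("the simulator is deterministic in its seed", {
  s1 <- simulate_isolate(sim_config(seed = 11), seed_marker = fx_seed)
  s2 <- simulate_isolate(sim_config(seed = 11), seed_marker = fx_seed)
  expect_identical(s1$assembly$seq, s2$assembly$seq)
  expect_identical(s1$reads$seq, s2$reads$seq)
  s3 <- simulate_isolate(sim_config(seed = 12), seed_marker = fx_seed)
  expect_false(identical(s1$assembly$seq, s3$assembly$seq))
})

test_that("amplicon runs weight members by abundance times copy number", {
  a <- rand_dna(300, 81); b <- rand_dna(300, 82)
  fps <- list(build_fingerprint("hi", a, 4L, region = "amp"),
              build_fingerprint("lo", b, 1L, region = "amp"))
  run <- simulate_amplicon_run(fps, c(hi = 0.5, lo = 0.5), n_reads = 6000,
                               read_len = 150, base_error = 0, seed = 2)
  expect_equal(unname(run$expected_read_share), c(0.8, 0.2))
  frac_hi <- mean(run$truth$member_id == "hi")
  expect_equal(frac_hi, 0.8, tolerance = 0.03)
  # error-free reads are exact substrings of the amplicons
  expect_true(all(vapply(seq_len(20), function(i) {
    grepl(run$reads1$seq[i], fps[[match(run$truth$member_id[i],
                                        c("hi", "lo"))]]$haplotypes$seq,
          fixed = TRUE)
  }, logical(1))))
  # mate 2 reads come from the other strand
  r2 <- run$reads2$seq[1]
  src <- fps[[match(run$truth$member_id[1], c("hi", "lo"))]]$haplotypes$seq
  expect_true(grepl(as.character(revcomp(r2)), src, fixed = TRUE))
  # zero reads: empty output
  r0 <- simulate_amplicon_run(fps, c(hi = 0.5, lo = 0.5), n_reads = 0)
  expect_equal(nrow(r0$reads1), 0)
})

test_that("a 20-member community with near-isogenic pairs is quantified faithfully", {
  com <- simulate_community(n_members = 20, seed = 17, n_isogenic_pairs = 3)
  amps <- extract_amplicons(com$fingerprints, standard_primers("V3V4"))
  run <- simulate_amplicon_run(amps, com$abundances, n_reads = 25000,
                               seed = 18)
  idx <- build_index(amps)
  q <- quantify(idx, run$reads1, run$reads2)
  truth <- com$abundances[q$table$member_id]
  expect_gte(stats::cor(q$table$norm_abundance, truth), 0.99)
  # every near-isogenic pair is resolved with the correct rank order
  for (i in seq_len(nrow(com$pairs))) {
    ea <- q$table$norm_abundance[q$table$member_id == com$pairs$a[i]]
    eb <- q$table$norm_abundance[q$table$member_id == com$pairs$b[i]]
    expect_gt(ea, 0); expect_gt(eb, 0)
    expect_equal(ea > eb,
                 com$abundances[[com$pairs$a[i]]] > com$abundances[[com$pairs$b[i]]])
  }
})

test_that("skipping copy-number normalization inflates the deviation score", {
  com <- simulate_community(n_members = 10, seed = 23)
  amps <- extract_amplicons(com$fingerprints, standard_primers("V3V4"))
  run <- simulate_amplicon_run(amps, com$abundances, n_reads = 15000,
                               seed = 24)
  idx <- build_index(amps)
  q <- quantify(idx, run$reads1, run$reads2)
  members <- q$table$member_id
  truthm <- matrix(com$abundances[members], ncol = 1,
                   dimnames = list(members, "s1"))
  withm <- matrix(q$table$norm_abundance, ncol = 1,
                  dimnames = list(members, "s1"))
  rawm <- matrix(q$table$raw_count / sum(q$table$raw_count), ncol = 1,
                 dimnames = list(members, "s1"))
  n_with <- attr(nrmse(harmonize(withm, truthm)), "mean_nrmse")
  n_without <- attr(nrmse(harmonize(rawm, truthm)), "mean_nrmse")
  expect_lt(n_with, n_without)
})
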