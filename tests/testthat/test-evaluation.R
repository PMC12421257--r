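test_that("threshold-1 clustering groups identical fingerprints exactly", {
  a <- rand_dna(150, 1); b <- sub_at(a, 70L)
  fps <- list(build_fingerprint("x", a, 2L),
              build_fingerprint("y", a, 2L),    # identical to x
              build_fingerprint("z", b, 2L),    # one SNP away
              build_fingerprint("w", a, 3L))    # same seq, different copies
  cl <- cluster_sequences(fps, threshold = 1)
  cid <- setNames(cl$cluster_id, cl$member_id)
  expect_equal(cid[["x"]], cid[["y"]])
  expect_false(cid[["x"]] == cid[["z"]])
  expect_false(cid[["x"]] == cid[["w"]])  # copies are part of the identity
  expect_equal(sort(as.vector(table(cl$cluster_id))), c(1, 1, 2))
})

test_that("threshold-1 clustering equals hash grouping on random fingerprints", {
  withr::with_seed(61, {
    pool <- lapply(1:12, function(i) rand_dna(120, 500 + i))
    fps <- lapply(1:40, function(i) {
      s <- sample(12, 1)
      build_fingerprint(sprintf("m%02d", i), pool[[s]],
                        sample(1:3, 1))
    })
  })
  cl <- cluster_sequences(fps, threshold = 1)
  # independent oracle: group by the literal (sequence, copies) string
  key <- vapply(fps, function(f) {
    paste(f$haplotypes$seq, f$haplotypes$copies, collapse = "#")
  }, character(1))
  oracle <- match(key, unique(key))
  expect_equal(length(unique(cl$cluster_id)), length(unique(oracle)))
  expect_true(all(tapply(oracle, cl$cluster_id,
                         function(x) length(unique(x))) == 1))
})

test_that("greedy sub-unit clustering joins near-identical members", {
  a <- rand_dna(300, 2)
  near <- sub_at(a, c(10L, 150L))          # 99.3% identical
  far <- rand_dna(300, 3)
  fps <- list(build_fingerprint("a", a, 1L),
              build_fingerprint("n", near, 1L),
              build_fingerprint("f", far, 1L))
  cl <- cluster_sequences(fps, threshold = 0.98)
  cid <- setNames(cl$cluster_id, cl$member_id)
  expect_equal(cid[["a"]], cid[["n"]])
  expect_false(cid[["a"]] == cid[["f"]])
  expect_equal(sum(cl$centroid), 2)
})

mk_tbl <- function(values, members, samples) {
  matrix(values, length(members), length(samples),
         dimnames = list(members, samples))
}

test_that("harmonization sums clusters, drops absences in both, renormalizes", {
  a <- mk_tbl(c(0.2, 0.1, 0.65, 0.05), c("x", "y", "z", "q"), "s1")
  m <- mk_tbl(c(0.3, 0.2, 0.5, 0.0), c("x", "y", "z", "q"), "s1")
  cl <- structure(tibble::tibble(member_id = c("x", "y", "z", "q"),
                                 cluster_id = c(1L, 1L, 2L, 3L),
                                 centroid = c(TRUE, FALSE, TRUE, TRUE)),
                  class = c("fq_clusters", class(tibble::tibble())))
  pair <- harmonize(a, m, clusters = cl, renormalize = FALSE)
  # cluster {x,y} sums to 0.3 in a before renormalization
  expect_equal(pair$a["cluster_1", "s1"], 0.3)
  # cluster q present in a (0.05) but 0 in m: removed from both
  expect_true(is.na(pair$a["cluster_3", "s1"]))
  expect_true(is.na(pair$m["cluster_3", "s1"]))
  pair2 <- harmonize(a, m, clusters = cl)
  expect_equal(sum(pair2$a[, "s1"], na.rm = TRUE), 1, tolerance = 1e-9)
  expect_equal(sum(pair2$m[, "s1"], na.rm = TRUE), 1, tolerance = 1e-9)
  # identical tables harmonize to a == m
  p3 <- harmonize(a, a)
  expect_equal(p3$a, p3$m)
  expect_error(harmonize(a, mk_tbl(1, "x", "other")), "same samples")
})

test_that("NRMSE matches the worked example and its properties", {
  expect_equal(nrmse(c(0.6, 0.4), c(0.5, 0.5)),
               (0.1 / 0.55 + 0.1 / 0.45) / 2, tolerance = 1e-12)
  expect_equal(round(nrmse(c(0.6, 0.4), c(0.5, 0.5)), 4), 0.202)
  expect_equal(nrmse(c(0.3, 0.7), c(0.3, 0.7)), 0)
  # symmetry and the per-taxon bound
  withr::with_seed(71, {
    for (i in 1:20) {
      k <- sample(2:8, 1)
      a <- stats::rexp(k); a <- a / sum(a)
      m <- stats::rexp(k); m <- m / sum(m)
      expect_equal(nrmse(a, m), nrmse(m, a))
      expect_lte(nrmse(a, m), 2)
      expect_gte(nrmse(a, m), 0)
      term <- abs(a - m) / ((a + m) / 2)
      expect_true(all(term <= 2))
    }
  })
})

test_that("NRMSE over a harmonized pair is reported per sample with its mean", {
  a <- mk_tbl(c(0.6, 0.4, 0.3, 0.7), c("x", "y"), c("s1", "s2"))
  m <- mk_tbl(c(0.5, 0.5, 0.3, 0.7), c("x", "y"), c("s1", "s2"))
  pair <- harmonize(a, m)
  out <- nrmse(pair)
  expect_equal(out$nrmse[out$sample == "s1"], 0.20202, tolerance = 1e-4)
  expect_equal(out$nrmse[out$sample == "s2"], 0)
  expect_equal(attr(out, "mean_nrmse"), mean(out$nrmse))
  expect_equal(out$K, c(2L, 2L))
})

test_that("presence metrics reproduce confusion-table arithmetic", {
  # 20 taxa engineered to give TP=8 FP=2 FN=1 TN=9
  members <- sprintf("t%02d", 1:20)
  pa <- c(rep(TRUE, 8), rep(TRUE, 2), rep(FALSE, 1), rep(FALSE, 9))
  pm <- c(rep(TRUE, 8), rep(FALSE, 2), rep(TRUE, 1), rep(FALSE, 9))
  av <- ifelse(pa, 0.08, 0.004)   # 0.004 < 0.5% threshold: absent
  mv <- ifelse(pm, 0.08, 0.004)
  a <- mk_tbl(av / sum(av) * 1, members, "s1"); a[] <- av
  m <- mk_tbl(mv, members, "s1")
  pair <- harmonize(a, m, drop_absent = FALSE, renormalize = FALSE)
  pmx <- presence_metrics(pair)
  expect_equal(pmx$TP, 8); expect_equal(pmx$FP, 2)
  expect_equal(pmx$FN, 1); expect_equal(pmx$TN, 9)
  expect_equal(pmx$accuracy, 0.85)
  expect_equal(pmx$precision, 0.8)
  expect_equal(pmx$recall, 8 / 9, tolerance = 1e-12)
  expect_equal(pmx$specificity, 9 / 11, tolerance = 1e-12)
})

test_that("presence threshold splits at 0.5% and degenerate ratios are NA", {
  a <- mk_tbl(c(0.006, 0.004, 0.99), c("x", "y", "z"), "s1")
  m <- mk_tbl(c(0.006, 0.004, 0.99), c("x", "y", "z"), "s1")
  pair <- harmonize(a, m, drop_absent = FALSE, renormalize = FALSE)
  pmx <- presence_metrics(pair)
  expect_equal(pmx$TP, 2)  # 0.006 and 0.99 present, 0.004 absent
  expect_equal(pmx$TN, 1)
  expect_equal(pmx$accuracy, 1)
  # all-absent truth: recall undefined, reported NA
  z <- mk_tbl(c(0.001, 0.002), c("x", "y"), "s1")
  pz <- harmonize(z, z, drop_absent = FALSE, renormalize = FALSE)
  mz <- presence_metrics(pz)
  expect_true(is.na(mz$recall))
  expect_true(is.na(mz$precision))
})

test_that("taxonomy collapse sums members and flags unmapped ones", {
  m <- mk_tbl(c(0.3, 0.2, 0.5), c("x", "y", "z"), "s1")
  map <- c(x = "gA", y = "gA", z = "gB")
  out <- collapse_taxonomy(m, map)
  expect_equal(out["gA", "s1"], 0.5)
  expect_equal(out["gB", "s1"], 0.5)
  expect_equal(collapse_taxonomy(m, c(x = "x", y = "y", z = "z"))[, ],
               m[, ])
  expect_error(collapse_taxonomy(m, map[1:2]), "without a taxonomy mapping: z")
})
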