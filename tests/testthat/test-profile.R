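test_that("profiles hold per-class frequencies and class priors", {
  d <- make_ds(c("AA", "AC", "CC", "GG"), c("F", "F", "F", "K"))
  pr <- build_profiles(d)
  kF <- match("F", class_alphabet())
  expect_equal(pr$q[2, 1, kF], 1 / 3)   # (2,A) in F
  expect_equal(pr$q[2, 2, kF], 2 / 3)   # (2,C) in F
  expect_equal(unname(pr$r[c("F", "K")]), c(0.75, 0.25))
  ## gapped column contributes no q mass
  d2 <- make_ds(c("A-", "AC"), c("F", "F"))
  pr2 <- build_profiles(d2)
  expect_equal(sum(pr2$q[2, , kF]), 0.5)
})

test_that("identity and hand log-odds hold under all four methods", {
  d <- make_ds(c("AA", "AC", "CA", "CC"), rep("F", 4))
  pr <- build_profiles(d)
  g <- make_ds("AC", "F", "q1")
  for (m in c("zero", "skip", "pseudo", "small"))
    expect_equal(score_profile(g, pr, pr, m), 0)

  ## qA = 0.5 vs qB = 0.25 for the single feature of a 1-tDNA genome
  dA <- make_ds(c("A", "A", "C", "C"), rep("F", 4), sprinzl = toy_map("1"))
  dB <- make_ds(c("A", "C", "C", "C"), rep("F", 4), sprinzl = toy_map("1"))
  pA <- build_profiles(dA)
  pB <- build_profiles(dB)
  g1 <- make_ds("A", "F", "q1", sprinzl = toy_map("1"))
  expect_equal(score_profile(g1, pA, pB, "zero"), 1)
  expect_equal(score_profile(g1, pA, pB, "skip"), 1)
  ## smoothing perturbs only slightly at these counts and keeps the sign
  expect_equal(score_profile(g1, pA, pB, "pseudo"),
               log2((2 + 1) / (4 + 4)) - log2((1 + 1) / (4 + 4)))
  expect_equal(score_profile(g1, pA, pB, "small"), 1)
})

test_that("antisymmetry under profile swap holds for all methods", {
  dA <- subset_genomes(random_ds(3), "g1")
  dB <- subset_genomes(random_ds(8), "g1")
  g <- subset_genomes(random_ds(13), "g1")
  pA <- build_profiles(dA)
  pB <- build_profiles(dB)
  for (m in c("zero", "skip", "pseudo", "small")) {
    s1 <- suppressWarnings(score_profile(g, pA, pB, m))
    s2 <- suppressWarnings(score_profile(g, pB, pA, m))
    expect_equal(s1, -s2, tolerance = 1e-12)
  }
})

test_that("pseudo and small converge to zero-method values", {
  dA <- make_ds(c("A", "A", "C", "C"), rep("F", 4), sprinzl = toy_map("1"))
  dB <- make_ds(c("A", "C", "C", "C"), rep("F", 4), sprinzl = toy_map("1"))
  pA <- build_profiles(dA)
  pB <- build_profiles(dB)
  g <- make_ds("A", "F", "q1", sprinzl = toy_map("1"))
  z <- score_profile(g, pA, pB, "zero")
  expect_equal(score_profile(g, pA, pB, "pseudo", pseudocount = 1e-6), z,
               tolerance = 1e-4)
  expect_equal(score_profile(g, pA, pB, "small", eps = 1e-9), z)
})

test_that("missing-data treatments separate as designed", {
  sp <- toy_map(as.character(1:6))
  ## A and B agree on columns 1-3 (positive sum toward A via column 1),
  ## B additionally shows states at columns 4-6 that A never shows
  dA <- make_ds(c("AAAAAA", "ACCCCC", "AAACCC", "ACACAC"), rep("F", 4),
                sprinzl = sp)
  dB <- make_ds(c("AAAGGG", "CCCGGG", "CACGGG", "CCAGGG"), rep("F", 4),
                sprinzl = sp)
  pA <- build_profiles(dA)
  pB <- build_profiles(dB)
  ## query carries B-only features (G at 4-6) plus scoreable features with
  ## a positive sum (A at 1 is 4/4 in A, 1/4 in B)
  g <- make_ds("AAAGGG", "F", "q1", sprinzl = sp)
  z <- score_profile(g, pA, pB, "zero")
  s <- score_profile(g, pA, pB, "skip")
  expect_lt(s, z)   # B-shared characters weigh more once dilution is gone

  ## novel features absent from both sets: near 0 under zero/skip and
  ## penalized symmetrically under pseudo/small (equal class counts)
  gq <- make_ds("TTTTTT", "F", "q1", sprinzl = sp)
  expect_equal(score_profile(gq, pA, pB, "zero"), 0)
  expect_equal(score_profile(gq, pA, pB, "skip"), 0)
  expect_lt(abs(score_profile(gq, pA, pB, "pseudo")), 1e-9)
  expect_lt(abs(score_profile(gq, pA, pB, "small")), 1e-9)
})

test_that("loocv_profile rebuilds profiles without the scored genome", {
  sp <- toy_map(c("1", "2"))
  dA <- make_ds(c("AG", "AG", "AC", "AC"), rep("F", 4),
                c("g1", "g1", "g2", "g2"), sprinzl = sp)
  dB <- make_ds(c("CG", "CG"), rep("F", 2), c("h1", "h2"), sprinzl = sp)
  res <- loocv_profile(dA, dB, method = "zero")
  pA <- build_profiles(dA)
  pB <- build_profiles(dB)
  full_g1 <- score_profile(subset_genomes(dA, "g1"), pA, pB, "zero")
  expect_false(isTRUE(all.equal(res$score[res$genome_id == "g1"],
                                full_g1)))
  q <- make_ds("AG", "F", "q1", sprinzl = sp)
  res_q <- loocv_profile(dA, dB, q, method = "zero")
  expect_equal(res_q$score[res_q$side == "query"],
               score_profile(q, pA, pB, "zero"))
  expect_error(loocv_profile(dA, dA), "both")
})

test_that("A+T convergence shifts zero-method scores toward the other set", {
  parts <- bench("parts")
  queries <- bench("queries")
  converged <- bench("converged")
  pA <- build_profiles(parts[["C1"]])
  pB <- build_profiles(parts[["C2"]])
  gids <- unique(queries$records$genome_id)
  before <- vapply(gids, function(g)
    score_profile(subset_genomes(queries, g), pA, pB, "zero"), 0)
  after <- vapply(gids, function(g)
    score_profile(subset_genomes(converged, g), pA, pB, "zero"), 0)
  ## paired comparison: every converged genome moves toward the A+T set
  expect_true(all(after < before))
  expect_gt(mean(before - after), 0)
})
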