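test_that("feature counting skips gaps, ambiguity codes and gapped pairs", {
  sp <- sprinzl_map(c("1", "2", "3"), data.frame(p5 = "1", p3 = "3"))
  d <- make_ds(c("AC-", "ANG"), c("F", "F"), sprinzl = sp)
  fc <- count_features(d)
  lab <- function(l, b) fc$single[match(l, sp$labels), match(b, c("A", "C", "G", "T"))]
  expect_equal(lab("1", "A"), 2)
  expect_equal(lab("2", "C"), 1)
  expect_equal(lab("2", "A"), 0)          # N yields nothing
  expect_equal(sum(fc$single[3, ]), 1)    # only the ungapped G
  ## pair (1,3): "AC-" gapped member -> no paired feature; "ANG" -> (A,G)
  expect_equal(sum(fc$pair), 1)
  expect_equal(fc$pair[1, (1 - 1) * 4 + 3], 1)

  d2 <- make_ds(c("AA", "AC"), c("F", "K"))
  fc2 <- count_features(d2)
  expect_equal(fc2$single[2, 1], 1)
  expect_equal(fc2$single_class[2, 1, match("F", class_alphabet())], 1)
  expect_equal(fc2$single_class[2, 1, match("K", class_alphabet())], 0)
})

test_that("feature_counts invariants hold on random data", {
  for (seed in 1:6) {
    d <- random_ds(seed)
    fc <- count_features(d)
    expect_equal(sum(fc$n_class), fc$n_total)
    expect_equal(rowSums(fc$single_class, dims = 2), fc$single)
    expect_true(all(fc$single <= fc$n_total))
    if (fc$use_pairs) {
      expect_equal(rowSums(fc$pair_class, dims = 2), fc$pair)
      expect_true(all(fc$pair <= fc$n_total))
    }
  }
  expect_error(count_features(make_ds(character(0), character(0),
                                      character(0), sprinzl = toy_map())),
               "empty")
})

test_that("background distribution is the empirical class frequency", {
  d <- make_ds(rep("ACG", 4), c("F", "F", "F", "K"))
  bg <- background_distribution(count_features(d))
  expect_equal(unname(bg[c("F", "K")]), c(0.75, 0.25))
  expect_equal(sum(bg), 1)
  d1 <- make_ds("ACG", "F")
  expect_equal(unname(background_distribution(count_features(d1))["F"]), 1)
})

test_that("feature information matches closed-form entropies", {
  ## uniform 2-class background, feature exclusive to F: 1 bit
  d <- make_ds(c(rep("A", 10), rep("C", 10)),
               c(rep("F", 10), rep("K", 10)),
               sprinzl = toy_map("1"))
  fc <- count_features(d)
  expect_equal(feature_information(fc, "1", "A", correction = "none"), 1)

  ## background {F:.75,K:.25}, posterior {.5,.5}: raw value is negative
  ## (0.8113 - 1) and clamps to 0
  d3 <- make_ds(c("A", rep("C", 5), "A", "C"),
                c(rep("F", 6), rep("K", 2)), sprinzl = toy_map("1"))
  fc3 <- count_features(d3)
  expect_equal(feature_information(fc3, "1", "A", correction = "none"), 0)

  ## n = 1 with MC correction: e(1) = H(bg), information saturates to 0
  d4 <- make_ds(c("A", "C", "G", "C"), c("F", "K", "F", "K"),
                sprinzl = toy_map("1"))
  fc4 <- count_features(d4)
  expect_equal(feature_information(fc4, "1", "G", correction = "mc",
                                   mc_reps = 200, seed = 3), 0)
  expect_error(feature_information(fc4, "1", "T"), "unseen")
})

test_that("logo heights follow the normalized-odds decomposition", {
  ## uniform background, exclusive feature -> all information on one class
  d <- make_ds(c(rep("AG", 10), rep("CG", 10)),
               c(rep("F", 10), rep("K", 10)),
               sprinzl = toy_map(c("1", "2")))
  lg <- function_logo(d, correction = "none")
  kF <- match("F", class_alphabet())
  kK <- match("K", class_alphabet())
  expect_equal(lg$single_heights[1, 1, kF], 1)
  expect_equal(lg$single_heights[1, 1, kK], 0)
  ## feature shared by all tDNAs: posterior equals background, info 0
  expect_equal(lg$single_info[2, 3], 0)
  expect_equal(sum(lg$single_heights[2, 3, ]), 0)

  ## background {F:.8,K:.2}: posterior {0,1} gives info H(bg) to class K
  d2 <- make_ds(c(rep("A", 8), rep("C", 2)),
                c(rep("F", 8), rep("K", 2)), sprinzl = toy_map("1"))
  lg2 <- function_logo(d2, correction = "none")
  expect_equal(lg2$single_info[1, 2],
               -(0.8 * log2(0.8) + 0.2 * log2(0.2)), tolerance = 1e-12)
  expect_equal(lg2$single_heights[1, 2, kK], lg2$single_info[1, 2])
  expect_equal(lg2$single_heights[1, 2, kF], 0)
})

test_that("logo equals the brute-force enumeration oracle", {
  for (seed in 1:8) {
    d <- random_ds(seed)
    lg <- function_logo(d, correction = "none")
    orc <- oracle_logo_heights(d)
    expect_equal(lg$single_heights, orc$single, tolerance = 1e-9)
    expect_equal(lg$single_info * (lg$single_n > 0), orc$single_info,
                 tolerance = 1e-9)
    if (lg$use_pairs)
      expect_equal(lg$pair_heights, orc$pair, tolerance = 1e-9)
  }
})

test_that("stack conservation: letter heights sum to corrected info", {
  for (seed in c(2, 5)) {
    d <- random_ds(seed)
    for (corr in c("none", "mc")) {
      lg <- function_logo(d, correction = corr, mc_reps = 200, seed = 7)
      expect_equal(rowSums(lg$single_heights, dims = 2),
                   lg$single_info * (lg$single_n > 0), tolerance = 1e-9)
      expect_true(all(lg$single_heights >= 0))
      kmax <- log2(sum(lg$background > 0))
      expect_true(all(lg$single_info <= kmax + 1e-9))
      if (lg$use_pairs)
        expect_equal(rowSums(lg$pair_heights, dims = 2),
                     lg$pair_info * (lg$pair_n > 0), tolerance = 1e-9)
    }
  }
})

test_that("reinforcing a class-exclusive feature never lowers its height", {
  ## background held fixed (balanced additions) with a shared correction
  ## cache: corrected height is monotone in the feature count
  base_F <- function(n_carrier) {
    make_ds(c(rep("A", n_carrier), rep("C", 30 - n_carrier), rep("G", 30)),
            c(rep("F", 30), rep("K", 30)), sprinzl = toy_map("1"))
  }
  kF <- match("F", class_alphabet())
  hts <- vapply(c(5, 10, 20, 30), function(nc) {
    lg <- function_logo(base_F(nc), correction = "mc", mc_reps = 500,
                        seed = 5)
    lg$single_heights[1, 1, kF]
  }, 0)
  expect_true(all(diff(hts) >= 0))
})

test_that("label shuffling drives mean corrected information near zero", {
  d <- bench("parts")[["C1"]]   # 880 tDNAs
  set.seed(99)
  d$records$cls <- sample(d$records$cls)
  lg <- function_logo(d, correction = "mc", mc_reps = 500, seed = 9)
  infos <- c(lg$single_info[lg$single_n > 0], lg$pair_info[lg$pair_n > 0])
  expect_lte(mean(infos), 0.05)
})

test_that("CIF extraction respects the height threshold", {
  d <- make_ds(c(rep("AG", 10), rep("CG", 10)),
               c(rep("F", 10), rep("K", 10)),
               sprinzl = toy_map(c("1", "2")))
  lg <- function_logo(d, correction = "none")
  all_pos <- extract_cifs(lg, 0)
  expect_true(all(all_pos$height > 0))
  expect_setequal(paste(all_pos$pos, all_pos$state, all_pos$cls)[
    all_pos$kind == "single"], c("1 A F", "1 C K"))
  half <- extract_cifs(lg, 0.5)
  expect_true(all(half$height >= 0.5))
  expect_equal(nrow(extract_cifs(lg, 10)), 0L)
  expect_error(extract_cifs(lg, -1))
})

test_that("permutation p-values behave under null and signal", {
  ## class-exclusive feature, n = 20, balanced two-class data
  d <- make_ds(c(rep("A", 20), rep("C", 20)),
               c(rep("F", 20), rep("K", 20)), sprinzl = toy_map("1"))
  p <- permutation_pvalue(d, "1", "A", "F", reps = 999, seed = 1)
  expect_lte(p, 0.01)
  expect_error(permutation_pvalue(d, "1", "A", "F", reps = 0), "reps")

  ## class-independent feature: p should look uniform (>= .05 mostly)
  ps <- vapply(1:10, function(s) {
    set.seed(s)
    dd <- make_ds(sample(c(rep("A", 20), rep("C", 20))),
                  c(rep("F", 20), rep("K", 20)), sprinzl = toy_map("1"))
    permutation_pvalue(dd, "1", "A", "F", reps = 199, seed = s)
  }, 0)
  expect_gte(mean(ps >= 0.05), 0.9)
})

test_that("logo tables export sorted and re-import identically", {
  d <- make_ds(c(rep("AG", 10), rep("CG", 10)),
               c(rep("F", 10), rep("K", 10)),
               sprinzl = toy_map(c("1", "2")))
  lg <- function_logo(d, correction = "none")
  f <- withr::local_tempfile()
  export_logo_table(lg, f)
  tab <- read_logo_table(f)
  expect_equal(nrow(tab), nrow(as.data.frame(lg)))
  df <- as.data.frame(lg)
  m <- merge(tab, df, by.x = c("position", "state", "class"),
             by.y = c("pos", "state", "cls"))
  expect_equal(m$height_bits, m$height, tolerance = 1e-9)
  ## empty logo -> header only
  export_logo_table(blank_logo(toy_map()), f)
  expect_equal(nrow(read_logo_table(f)), 0L)
  ## re-export of the import is byte-identical
  lines1 <- readLines(f)
  export_logo_table(blank_logo(toy_map()), f)
  expect_identical(readLines(f), lines1)
})

test_that("planted benchmark CIFs are recovered at 0.3 bits", {
  parts <- bench("parts")
  planted <- bench("gen")$planted
  lg <- function_logo(parts[["C3"]], seed = 1)
  cifs <- extract_cifs(lg, 0.3)
  got <- paste(cifs$pos, cifs$state, cifs$cls)
  want <- paste(planted$C3$pos, planted$C3$state, planted$C3$cls)
  expect_setequal(got[cifs$kind == "single"], want)
})
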