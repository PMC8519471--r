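test_that("toy partition engine agrees exactly with the enumeration oracle", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(10:20, 1)
    s <- random_dna(n)
    from <- sample(0:(n - 4), 1)
    to <- from + sample(2:3, 1)
    oracle <- toy_partition_oracle(s, c(from, to))
    p <- unpaired_probability(s, c(from, to), toy_cfg())
    expect_equal(p, oracle$p_unpaired, tolerance = 1e-12)
    expect_lte(oracle$z_unpaired, oracle$z)
    expect_gt(oracle$p_unpaired, 0)
  }
})

test_that("oracle structure count is reproduced by the uniform-weight recursion", {
  # second, independent route: the DP with Boltzmann weight 1 counts
  # structures, which must match the explicit enumeration
  set.seed(5)
  for (rep in 1:10) {
    s <- random_dna(sample(8:18, 1))
    o <- toy_partition_oracle(s)
    count_dp <- tirdesign:::toy_partition_cpp(
      tirdesign:::encode_seq(s), 1.0, 3L, 0L, 0L
    )
    expect_equal(o$n_structures, count_dp)
  }
})

test_that("a pair-free sequence has a single empty structure and p = 1", {
  o <- toy_partition_oracle("AAAAAAAA", c(2, 5))
  expect_identical(o$n_structures, 1L)
  expect_equal(o$p_unpaired, 1)
  expect_equal(o$mfe, 0)
})

test_that("GGGAAACCC enumeration matches the toy engine exactly", {
  o <- toy_partition_oracle("GGGAAACCC", c(3, 6))
  p <- unpaired_probability("GGGAAACCC", c(3, 6), toy_cfg())
  expect_equal(p, o$p_unpaired, tolerance = 1e-12)
  expect_gt(o$n_structures, 1)
  z_dp <- tirdesign:::toy_partition_cpp(
    tirdesign:::encode_seq("GGGAAACCC"),
    exp(1 / tirdesign:::rt_kcal(37)), 3L, 0L, 0L
  )
  expect_equal(o$z, z_dp, tolerance = 1e-12)
})

test_that("oracle refuses over-length input", {
  expect_error(toy_partition_oracle(random_dna(40)), class = "tir_validation_error")
})

test_that("unpaired probability shrinks as the interval widens", {
  set.seed(21)
  for (rep in 1:30) {
    s <- random_dna(30)
    p_narrow <- unpaired_probability(s, c(10, 14), toy_cfg())
    p_wide <- unpaired_probability(s, c(8, 18), toy_cfg())
    expect_lte(p_wide, p_narrow + 1e-12)
  }
})

test_that("opening energy is zero for poly-A and non-negative always", {
  cons <- coding_construct(strrep("A", 48), canonical = FALSE, id = "polyA")
  expect_equal(opening_energy(cons, region(1, 12), toy_cfg()), 0)
  set.seed(31)
  for (rep in 1:20) {
    cons <- random_construct(10, utr5_len = 12, seed = rep)
    oe <- opening_energy(cons, region(-6, 9), toy_cfg())
    expect_gte(oe, 0)
  }
})

test_that("opening energy is non-decreasing under region extension (toy engine)", {
  set.seed(41)
  for (rep in 1:20) {
    cons <- random_construct(12, utr5_len = 20, seed = 100 + rep)
    oe_small <- opening_energy(cons, region(-6, 12), toy_cfg())
    oe_large <- opening_energy(cons, region(-12, 18), toy_cfg())
    expect_gte(oe_large, oe_small - 1e-9)
  }
})

test_that("toy opening energy equals -RT log(p) from the oracle", {
  set.seed(51)
  rt <- tirdesign:::rt_kcal(37)
  for (rep in 1:10) {
    n <- 3 * sample(4:6, 1)
    cons <- coding_construct(random_dna(n), canonical = FALSE)
    reg <- region(2, min(8, n))
    o <- toy_partition_oracle(cons$cds, c(1, min(8, n)))
    expect_equal(
      opening_energy(cons, reg, toy_cfg()),
      -rt * log(o$p_unpaired),
      tolerance = 1e-9
    )
  }
})

test_that("scan profile cells equal independent direct calls", {
  cons <- demo_construct(n_codons = 12, utr5_len = 24)
  lengths <- c(6, 10, 14)
  ends <- c(-4, 6, 15)
  prof <- scan_profile(cons, lengths, ends, toy_cfg())
  expect_identical(nrow(prof), 9L)
  for (row in seq_len(nrow(prof))) {
    if (is.na(prof$opening_energy[row])) next
    reg <- endpos_len_to_region(prof$i[row], prof$l[row])
    expect_equal(
      prof$opening_energy[row],
      opening_energy(cons, reg, toy_cfg()),
      tolerance = 1e-9
    )
  }
})

test_that("scan profile marks cells beyond the available flank as undefined", {
  cons <- random_construct(10, utr5_len = 6, seed = 3)
  prof <- scan_profile(cons, lengths = c(10, 40), end_positions = c(6, 12), toy_cfg())
  # l = 40 ending at i = 6 needs 33 nt upstream flank; only 6 available
  bad <- prof[prof$l == 40 & prof$i == 6, ]
  expect_true(is.na(bad$opening_energy))
  good <- prof[prof$l == 10 & prof$i == 12, ]
  expect_false(is.na(good$opening_energy))
  expect_error(
    scan_profile(cons, integer(0), 1, toy_cfg()),
    class = "tir_validation_error"
  )
  expect_error(
    scan_profile(cons, lengths = 60, end_positions = 6, toy_cfg()),
    class = "tir_bounds_error"
  )
})

test_that("toy MFE equals the enumeration oracle optimum", {
  set.seed(61)
  for (rep in 1:10) {
    n <- 3 * sample(4:6, 1)
    s <- random_dna(n)
    cons <- coding_construct(s, canonical = FALSE)
    o <- toy_partition_oracle(s)
    expect_equal(mfe_region(cons, region(1, n), toy_cfg()), o$mfe)
  }
})

test_that("MFE of a local region ignores synonymous edits outside it", {
  cons <- random_construct(30, utr5_len = 30, seed = 77)
  codons <- tirdesign:::split_codons(cons$cds)
  # substitute codons 15..25, far beyond the -30:30 window (codon 10 ends it)
  for (i in 15:25) {
    alts <- synonymous_codons(codons[i])
    if (length(alts) > 1) codons[i] <- setdiff(alts, codons[i])[1]
  }
  mutant <- cons
  mutant$cds <- paste(codons, collapse = "")
  expect_false(identical(mutant$cds, cons$cds))
  expect_identical(
    mfe_region(cons, region(-30, 30), toy_cfg()),
    mfe_region(mutant, region(-30, 30), toy_cfg())
  )
})

test_that("engine swap preserves signs, bounds and grid geometry", {
  skip_if(!production_engine_available(), "ViennaRNA not on PATH")
  cons <- demo_construct(n_codons = 12, utr5_len = 24, seed = 5)
  for (cfg in list(toy_cfg(), fold_config("production"))) {
    oe <- opening_energy(cons, region(-12, 12), cfg)
    expect_gte(oe, 0)
    prof <- scan_profile(cons, c(6, 12), c(6, 12), cfg)
    expect_identical(dim(prof)[1], 4L)
    expect_true(all(prof$opening_energy >= 0, na.rm = TRUE))
  }
})

test_that("production engine opening energy is reproducible", {
  skip_if(!production_engine_available(), "ViennaRNA not on PATH")
  cons <- random_construct(40, utr5_len = 80, seed = 2024) # ~200 nt transcript
  cfg <- fold_config("production")
  a <- opening_energy(cons, region(-24, 24), cfg)
  b <- opening_energy(cons, region(-24, 24), cfg)
  expect_equal(a, b, tolerance = 1e-6)
  expect_gt(a, 0)
})
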