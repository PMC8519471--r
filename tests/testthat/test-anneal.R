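# Energy function used throughout: toy-engine opening energy of a region
# covered by the construct.
toy_energy <- function(reg = region(-12, 24)) {
  function(cons) opening_energy(cons, reg, toy_cfg())
}

test_that("replaceable positions exclude start and stop codons", {
  cons <- random_construct(20, utr5_len = 0, seed = 1)
  expect_identical(replaceable_positions(cons, 9), 2:10)
  expect_identical(replaceable_positions(cons, "full"), 2:19)
  short <- random_construct(5, utr5_len = 0, seed = 2)
  expect_identical(replaceable_positions(short, "full"), 2:4)
  expect_warning(
    pos <- replaceable_positions(random_construct(6, seed = 3), 9),
    "clipping"
  )
  expect_identical(pos, 2:5)
})

test_that("search-space count matches the three-synonyms-per-codon arithmetic", {
  # nine isoleucine codons: exactly 3 synonyms each -> 3^9 - 1 variants
  cons <- coding_construct(paste0("ATG", strrep("ATT", 9), "TAA"))
  expect_equal(count_search_space(cons, 9), 19682)
  # Met-Trp-Met + stop: nothing substitutable
  mw <- coding_construct("ATGTGGATGTAA")
  expect_equal(suppressWarnings(count_search_space(mw, 9)), 0)
  # two leucine codons: 6 x 6 - 1
  leu2 <- coding_construct("ATGCTGCTGTAA")
  expect_equal(suppressWarnings(count_search_space(leu2, 9)), 35)
})

test_that("move size follows the temperature schedule", {
  cons <- coding_construct(paste0("ATG", strrep("ATT", 9), "TAA"))
  codons <- tirdesign:::split_codons(cons$cds)
  pos <- replaceable_positions(cons, 9)
  set.seed(4)
  hot <- propose_move(codons, pos, temperature = 1, t0 = 1)
  expect_identical(sum(hot != codons), 9L) # drastic first move
  cold_changes <- replicate(20, {
    sum(propose_move(codons, pos, temperature = 1e-6, t0 = 1) != codons)
  })
  expect_true(all(cold_changes == 1)) # single-codon moves near T = 0
  # synonymy: protein conserved by every proposal
  for (rep in 1:20) {
    cand <- propose_move(codons, pos, runif(1), 1)
    expect_identical(
      tirdesign:::translate_cds(paste(cand, collapse = "")),
      tirdesign:::translate_cds(cons$cds)
    )
  }
  expect_error(
    propose_move(codons, integer(0), 1, 1),
    class = "tir_validation_error"
  )
})

test_that("Metropolis rule accepts improvements surely, worsenings per exp(-dE/T)", {
  set.seed(5)
  expect_true(metropolis_accept(1.0, 2.0, temperature = 0.5))
  # dE = T ln 2 -> acceptance probability exactly 1/2
  temp <- 0.8
  de <- temp * log(2)
  acc <- mean(replicate(10000, metropolis_accept(1 + de, 1, temp)))
  expect_equal(acc, 0.5, tolerance = 0.02)
  # a second point on the curve
  de2 <- temp * log(10)
  acc2 <- mean(replicate(10000, metropolis_accept(1 + de2, 1, temp)))
  expect_equal(acc2, 0.1, tolerance = 0.02)
  expect_error(metropolis_accept(1, 2, 0), class = "tir_validation_error")
})

test_that("motif filter screens both strands", {
  expect_false(motif_filter("AAAGGTCTCAAA", c(BsaI = "GGTCTC"))$pass)
  hit <- motif_filter("AAAGGTCTCAAA", c(BsaI = "GGTCTC"))$hits
  expect_identical(hit$position, 4L)
  # reverse complement of BsaI
  expect_false(motif_filter("AAAGAGACCAAA", c(BsaI = "GGTCTC"))$pass)
  expect_true(motif_filter("AAAGAGACCAAA", character(0))$pass)
})

test_that("annealing with no substitutable codons returns the input", {
  mw <- coding_construct("ATGTGGATGTGGTAA", utr5 = random_dna(12))
  cfg <- anneal_config(n_codons = 3, chains = 2, seed = 1, fold = toy_cfg())
  expect_warning(res <- anneal(mw, cfg, toy_energy(region(-12, 12))), "No substitutable")
  expect_identical(res$solutions$cds, mw$cds)
  expect_identical(res$solutions$n_substitutions, 0L)
})

test_that("annealing is deterministic for a fixed seed and respects best-so-far", {
  cons <- random_construct(12, utr5_len = 12, seed = 42)
  cfg <- anneal_config(
    n_codons = 4, chains = 2, max_iterations = 80, seed = 7, fold = toy_cfg()
  )
  fn <- toy_energy(region(-12, 15))
  r1 <- anneal(cons, cfg, fn)
  r2 <- anneal(cons, cfg, fn)
  expect_identical(r1$solutions, r2$solutions)
  expect_identical(r1$trajectory, r2$trajectory)
  expect_lte(r1$solutions$opening_energy[1], r1$input$opening_energy)
  # solutions conserve the protein and pass the motif filter
  for (s in r1$solutions$cds) {
    expect_identical(
      tirdesign:::translate_cds(s), tirdesign:::translate_cds(cons$cds)
    )
    expect_true(motif_filter(s, cfg$forbidden_motifs)$pass)
  }
})

test_that("annealing attains the exhaustive optimum on small instances", {
  hits <- 0
  runs <- 10
  for (s in seq_len(runs)) {
    cons <- random_construct(8, utr5_len = 12, seed = 300 + s)
    cfg <- anneal_config(
      n_codons = 4, chains = 4, max_iterations = 200, patience = 100,
      seed = s, fold = toy_cfg()
    )
    fn <- toy_energy(region(-12, 15))
    ex <- exhaustive_optimum(cons, cfg, fn)
    res <- anneal(cons, cfg, fn)
    expect_gte(res$solutions$opening_energy[1], ex$opening_energy - 1e-9)
    if (abs(res$solutions$opening_energy[1] - ex$opening_energy) < 1e-9) {
      hits <- hits + 1
    }
  }
  expect_gte(hits / runs, 0.9)
})

test_that("exhaustive enumeration honours its guard and motif filter", {
  cons <- coding_construct(paste0("ATG", strrep("ATT", 9), "TAA"))
  expect_error(
    exhaustive_optimum(cons, anneal_config(n_codons = 9), limit = 1000),
    class = "tir_validation_error"
  )
  leu2 <- coding_construct("ATGCTGCTGTAA", utr5 = random_dna(12))
  cfg <- anneal_config(n_codons = 2, fold = toy_cfg())
  ex <- exhaustive_optimum(leu2, cfg, toy_energy(region(-12, 12)))
  expect_identical(ex$n_enumerated, 36L)
  # oracle optimality: no variant beats it
  sets <- lapply(tirdesign:::split_codons(leu2$cds)[2:3], synonymous_codons)
  all_e <- apply(expand.grid(sets[[1]], sets[[2]]), 1, function(p) {
    v <- leu2
    v$cds <- paste0("ATG", p[1], p[2], "TAA")
    toy_energy(region(-12, 12))(v)
  })
  expect_equal(ex$opening_energy, min(all_e), tolerance = 1e-12)
})

test_that("nine-codon optimization approaches full-length optimization", {
  set.seed(99)
  n_fix <- 12
  e_input <- e_nine <- e_full <- e_rand <- numeric(n_fix)
  reg <- region(-12, 24)
  for (i in seq_len(n_fix)) {
    cons <- random_construct(16, utr5_len = 12, seed = 500 + i)
    fn <- toy_energy(reg)
    e_input[i] <- fn(cons)
    cfg9 <- anneal_config(
      n_codons = 9, chains = 2, max_iterations = 100, patience = 50,
      seed = i, fold = toy_cfg()
    )
    cfgf <- anneal_config(
      n_codons = "full", chains = 2, max_iterations = 100, patience = 50,
      seed = i, fold = toy_cfg()
    )
    e_nine[i] <- anneal(cons, cfg9, fn)$solutions$opening_energy[1]
    e_full[i] <- anneal(cons, cfgf, fn)$solutions$opening_energy[1]
    # purely random synonymous substitution of every replaceable codon
    codons <- tirdesign:::split_codons(cons$cds)
    pos <- replaceable_positions(cons, "full")
    for (p in pos) {
      syn <- synonymous_codons(codons[p])
      codons[p] <- sample(syn, 1)
    }
    rnd <- cons
    rnd$cds <- paste(codons, collapse = "")
    e_rand[i] <- fn(rnd)
  }
  dks <- ks_distance(e_nine, e_full)
  expect_lte(dks, 0.5)
  # optimization beats random substitution, which does not beat the input
  expect_lte(mean(e_nine), mean(e_rand))
  expect_lte(mean(e_rand), mean(e_input))
})
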