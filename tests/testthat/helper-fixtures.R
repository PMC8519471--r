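# Shared fixtures: everything is generated in code, nothing downloaded.

toy_cfg <- function(...) fold_config(engine = "toy", ...)

# Small canonical construct with enough 5' flank for the -24:24 region.
demo_construct <- function(n_codons = 12, utr5_len = 24, seed = 101) {
  random_construct(n_codons, utr5_len = utr5_len, seed = seed, id = "demo")
}

# Scripted interaction engine: dg_h derived deterministically from the
# ncRNA sequence so min-selection is testable without RNAup.
scripted_interaction <- function(energies) {
  i <- 0
  function(mrna, ncrna) {
    i <<- i + 1
    c(dg_u = 1.5, dg_h = energies[[i]])
  }
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Cache for expensive acceptance computations shared between criteria.
.acceptance_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.acceptance_cache[[key]])) {
    .acceptance_cache[[key]] <- force(expr)
  }
  .acceptance_cache[[key]]
}
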