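# Shared fixtures: independent oracles and small simulation configs.

# Independent Fisher oracle: full hypergeometric enumeration using
# exp(lchoose()) arithmetic (a different route than the implementation's
# dhyper), same two-sided tie rule.
oracle_fisher <- function(a, b, c, d) {
  m <- a + b
  n <- c + d
  k <- a + c
  support <- max(0, k - n):min(m, k)
  lp <- lchoose(m, support) + lchoose(n, k - support) - lchoose(m + n, k)
  probs <- exp(lp)
  p_obs <- exp(lchoose(m, a) + lchoose(n, c) - lchoose(m + n, k))
  min(sum(probs[probs <= p_obs * (1 + 1e-7)]), 1)
}

# A small, fast synthetic epigenome (400 kb, 66 TEs) for unit tests; the
# acceptance tests use the full default configuration.
small_sim_config <- function(...) {
  sim_config(
    genome_bp = 4e5,
    n_te = c(CMT = 24, DRM = 30, intermediate = 12),
    srna_depth = 1e5,
    chip_depth = 1e5,
    ...
  )
}

# Memoised default-scale simulations so acceptance tests that share a
# genome do not rebuild it.
.sim_cache <- new.env(parent = emptyenv())
cached_sim <- function(seed, cfg = sim_config()) {
  key <- paste0("s", seed)
  if (!exists(key, envir = .sim_cache)) {
    assign(key, build_genome(cfg, seed = seed), envir = .sim_cache)
  }
  get(key, envir = .sim_cache)
}

cached_small_sim <- function(seed = 99) {
  key <- paste0("small", seed)
  if (!exists(key, envir = .sim_cache)) {
    assign(key, build_genome(small_sim_config(), seed = seed),
           envir = .sim_cache)
  }
  get(key, envir = .sim_cache)
}

# Deterministic toy genome for context arithmetic tests: `blocks` copies of
# a 20-bp unit containing exactly one CG dinucleotide.
cg_block_genome <- function(blocks = 5) {
  unit <- "AACGTTAAATTTAAATTTAA"
  stopifnot(nchar(unit) == 20)
  setNames(paste(rep(unit, blocks), collapse = ""), "chr1")
}
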