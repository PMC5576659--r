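# Shared fixtures, built in code.

RES21 <- metseg_alphabet("residue21")

# small annotated chain with known binding sites
tiny_chain <- function(id = "ch1") {
  protein_chain(
    id = id,
    sequence = "MKCHDECAVLKRSTWYEFGH",
    binding_positions = c(3, 7, 15),
    ss = "CCHHHEECCCHHHEEECCCH",
    rsa = seq(0, 0.8, length.out = 20)
  )
}

# random equal-length segments over an alphabet, reproducibly
random_segments <- function(n, L, alphabet = RES21, seed = 1) {
  metseg:::with_seed(seed, {
    vapply(seq_len(n), function(i) {
      paste(sample(alphabet, L, replace = TRUE), collapse = "")
    }, "")
  })
}

# random nonempty count vector
random_counts <- function(dim, max_count = 100) {
  repeat {
    x <- sample.int(max_count + 1L, dim, replace = TRUE) - 1L
    if (sum(x) > 0) return(x)
  }
}

# the strong-signal world: whole binding window planted at theta
strong_signal_segments <- function(n_chains = 200, theta = 0.95, seed = 11,
                                   L = 7) {
  spec <- simulation_spec(
    n_chains = n_chains, seed = seed, theta = theta,
    flank_decay = 1, L = L
  )
  extract_segments_all(generate_dataset(spec)$chains, L)
}

fixture_dir <- function() {
  system.file("extdata", "synthetic_small", package = "metseg")
}
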