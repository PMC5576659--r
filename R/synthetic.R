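## Synthetic chains with planted binding microenvironments.  The generator
## emulates the statistical structure the method assumes: positional residue
## enrichment (C/H/D/E) inside binding windows, strongest at the center and
## decaying toward the flanks; distinct secondary-structure and solvent-
## accessibility distributions for binding vs non-binding residues (RSA
## multi-modal for binding residues).  It makes no attempt to simulate real
## structure, ligand geometry or inter-position correlation.

# UniProtKB/Swiss-Prot average amino-acid composition (percent), the
# background from which non-planted residues are drawn.
SWISSPROT_FREQ <- c(
  A = 8.25, C = 1.38, D = 5.46, E = 6.72, F = 3.86, G = 7.07, H = 2.27,
  I = 5.91, K = 5.80, L = 9.65, M = 2.41, N = 4.06, P = 4.74, Q = 3.93,
  R = 5.53, S = 6.64, T = 5.35, V = 6.86, W = 1.10, Y = 2.92
)

#' Specification of a synthetic binding-site dataset
#'
#' The stated world of the generator: `n_chains` chains of length
#' `chain_length`, an expected `site_density` binding sites per chain
#' (Poisson, truncated to capacity), and a planted binding window of length
#' `L` around each site in which the residue at offset `d` from the center
#' is drawn from the `preferred` set (uniformly) with probability
#' `theta * flank_decay^|d|` and from the `background` composition
#' otherwise.  Site centers keep `(L-1)/2` residues clear of the termini
#' and at least `min_separation` positions apart, so planted windows are
#' independent draws from the stated emission model.  Secondary structure
#' is drawn i.i.d. per residue from a per-class categorical over H/E/C;
#' RSA from per-class mixtures of truncated Gaussian bumps (binding modes
#' at 0.25/0.35/0.45; non-binding broader), rejected into
#' `[0, rsa_max = 0.85]` so the accessibility bins are exercised without
#' relying on the overflow clamp.
#'
#' @param n_chains number of chains.
#' @param chain_length residues per chain; a scalar or a `c(min,max)` range.
#' @param site_density expected binding sites per chain.
#' @param L planted (and default analysis) window length, odd.
#' @param theta preferred-residue weight at the binding center, in `[0,1]`.
#' @param flank_decay geometric decay of the enrichment with offset.
#' @param preferred preferred residue set at binding positions.
#' @param background named residue frequency vector (normalized internally).
#' @param ss_pos,ss_neg H/E/C probabilities for binding / non-binding
#'   residues.
#' @param rsa_pos,rsa_neg lists with `means`, `sd`, `weights` describing the
#'   RSA bump mixtures per class.
#' @param rsa_max upper truncation of generated RSA values.
#' @param min_separation minimum distance between site centers (default `L`).
#' @param annotate generate ss/rsa annotations (default `TRUE`).
#' @param seed master seed of the dataset.
#' @return object of class `simulation_spec`.
#' @export
simulation_spec <- function(n_chains = 50L, chain_length = 100L,
                            site_density = 2, L = 7L,
                            theta = 0.9, flank_decay = 0.6,
                            preferred = c("C", "H", "D", "E"),
                            background = SWISSPROT_FREQ,
                            ss_pos = c(H = 0.25, E = 0.15, C = 0.60),
                            ss_neg = c(H = 0.35, E = 0.25, C = 0.40),
                            rsa_pos = list(
                              means = c(0.25, 0.35, 0.45), sd = 0.06,
                              weights = c(1, 1, 1)
                            ),
                            rsa_neg = list(
                              means = c(0.15, 0.55), sd = 0.18,
                              weights = c(1, 1)
                            ),
                            rsa_max = 0.85, min_separation = NULL,
                            annotate = TRUE, seed = 0L) {
  L <- check_window(L)
  stopifnot(
    n_chains >= 1L, site_density >= 0,
    theta >= 0, theta <= 1, flank_decay >= 0, flank_decay <= 1,
    all(preferred %in% AA20),
    length(chain_length) %in% c(1L, 2L), all(chain_length >= L)
  )
  background <- background[AA20]
  if (anyNA(background) || any(background < 0)) {
    stop("background must be a named frequency vector over the 20 residues",
      call. = FALSE
    )
  }
  structure(
    list(
      n_chains = as.integer(n_chains), chain_length = as.integer(chain_length),
      site_density = site_density, L = L, theta = theta,
      flank_decay = flank_decay, preferred = preferred,
      background = background / sum(background),
      ss_pos = ss_pos / sum(ss_pos), ss_neg = ss_neg / sum(ss_neg),
      rsa_pos = rsa_pos, rsa_neg = rsa_neg, rsa_max = rsa_max,
      min_separation = as.integer(min_separation %||% L),
      annotate = isTRUE(annotate), seed = as.integer(seed)
    ),
    class = "simulation_spec"
  )
}

# per-offset probability of drawing from the preferred set
plant_weights <- function(spec) {
  k <- (spec$L - 1L) %/% 2L
  spec$theta * spec$flank_decay^abs(seq.int(-k, k))
}

#' Theoretical positive-segment emission probabilities
#'
#' The per-position residue distribution of a planted binding window under a
#' [simulation_spec()]: rows are window positions, columns the 21-letter
#' alphabet (padding letter `X` has probability 0 since sites keep clear of
#' the termini).
#'
#' @param spec a [simulation_spec()].
#' @return `L x 21` probability matrix.
#' @export
positive_truth_probs <- function(spec) {
  alphabet <- metseg_alphabet("residue21")
  th <- plant_weights(spec)
  out <- matrix(0, nrow = spec$L, ncol = length(alphabet),
    dimnames = list(NULL, alphabet)
  )
  for (i in seq_len(spec$L)) {
    p <- (1 - th[i]) * spec$background
    p[spec$preferred] <- p[spec$preferred] + th[i] / length(spec$preferred)
    out[i, AA20] <- p
  }
  out
}

sample_rsa <- function(n, model, rsa_max) {
  if (n == 0L) return(numeric())
  w <- model$weights / sum(model$weights)
  out <- numeric(n)
  todo <- seq_len(n)
  while (length(todo)) {
    comp <- sample.int(length(model$means), length(todo), replace = TRUE, prob = w)
    x <- stats::rnorm(length(todo), model$means[comp], model$sd)
    ok <- x >= 0 & x <= rsa_max
    out[todo[ok]] <- x[ok]
    todo <- todo[!ok]
  }
  out
}

sample_site_centers <- function(n_res, n_sites, k, min_sep) {
  lo <- k + 1L
  hi <- n_res - k
  if (hi < lo || n_sites == 0L) return(integer())
  centers <- integer()
  candidates <- seq.int(lo, hi)
  for (s in seq_len(n_sites)) {
    if (!length(candidates)) break
    c0 <- candidates[sample.int(length(candidates), 1L)]
    centers <- c(centers, c0)
    candidates <- candidates[abs(candidates - c0) >= min_sep]
  }
  sort(centers)
}

#' Generate a synthetic dataset
#'
#' Draws chains, plants binding windows and annotations according to the
#' spec, reproducibly from `spec$seed` (the global RNG state is left
#' untouched).  The returned ground truth carries the generating
#' distributions for parameter-recovery tests.
#'
#' @param spec a [simulation_spec()].
#' @return object of class `metseg_dataset`: `chains` (named list of
#'   [protein_chain()]), `truth` (`positive_probs`, per-class ss/rsa models,
#'   the spec).
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  k <- (spec$L - 1L) %/% 2L
  max_sites <- function(n_res) {
    floor((n_res - 2L * k - 1L) / spec$min_separation) + 1L
  }
  if (length(spec$chain_length) == 1L &&
    max_sites(spec$chain_length) < spec$site_density) {
    stop("site density exceeds chain capacity at this length/separation",
      call. = FALSE
    )
  }
  chains <- with_seed(spec$seed, {
    lapply(seq_len(spec$n_chains), function(ci) {
      n_res <- if (length(spec$chain_length) == 2L) {
        sample(seq.int(spec$chain_length[1L], spec$chain_length[2L]), 1L)
      } else {
        spec$chain_length
      }
      n_sites <- min(stats::rpois(1L, spec$site_density), max_sites(n_res))
      centers <- sample_site_centers(n_res, n_sites, k, spec$min_separation)
      seq_chars <- sample(AA20, n_res, replace = TRUE, prob = spec$background)
      th <- plant_weights(spec)
      for (c0 in centers) {
        for (i in seq_len(spec$L)) {
          if (stats::runif(1L) < th[i]) {
            seq_chars[c0 + i - 1L - k] <-
              spec$preferred[sample.int(length(spec$preferred), 1L)]
          }
        }
      }
      ss <- rsa <- NULL
      if (spec$annotate) {
        is_pos <- seq_len(n_res) %in% centers
        ss <- character(n_res)
        ss[is_pos] <- sample(names(spec$ss_pos), sum(is_pos),
          replace = TRUE, prob = spec$ss_pos
        )
        ss[!is_pos] <- sample(names(spec$ss_neg), sum(!is_pos),
          replace = TRUE, prob = spec$ss_neg
        )
        rsa <- numeric(n_res)
        rsa[is_pos] <- sample_rsa(sum(is_pos), spec$rsa_pos, spec$rsa_max)
        rsa[!is_pos] <- sample_rsa(sum(!is_pos), spec$rsa_neg, spec$rsa_max)
      }
      protein_chain(
        id = sprintf("syn%04d", ci),
        sequence = paste(seq_chars, collapse = ""),
        binding_positions = centers,
        ss = if (is.null(ss)) NULL else paste(ss, collapse = ""),
        rsa = rsa
      )
    })
  })
  names(chains) <- vapply(chains, function(ch) ch$id, "")
  structure(
    list(
      chains = chains,
      truth = list(
        positive_probs = positive_truth_probs(spec),
        ss_pos = spec$ss_pos, ss_neg = spec$ss_neg,
        rsa_pos = spec$rsa_pos, rsa_neg = spec$rsa_neg,
        spec = spec
      )
    ),
    class = "metseg_dataset"
  )
}

#' @export
print.metseg_dataset <- function(x, ...) {
  npos <- sum(vapply(x$chains, function(ch) length(ch$binding_positions), 0L))
  cat(
    "<metseg_dataset> ", length(x$chains), " chains, ", npos,
    " planted binding sites (seed ", x$truth$spec$seed, ")\n",
    sep = ""
  )
  invisible(x)
}

#' Residue windows centered on the binding positions of many chains
#'
#' @param chains list of [protein_chain()].
#' @param L odd window length.
#' @return character vector of positive residue segments.
#' @export
positive_segments <- function(chains, L) {
  L <- check_window(L)
  unlist(lapply(chains, function(ch) {
    if (!length(ch$binding_positions)) return(character())
    padded <- pad_sequence(ch$sequence, L)
    substring(padded, ch$binding_positions, ch$binding_positions + L - 1L)
  }), use.names = FALSE)
}

#' Parameter recovery of the planted emission matrix
#'
#' Builds the positive PWSM from the dataset's true positive segments and
#' compares the estimated per-position probabilities with the generating
#' distribution (adjusted by the same square-root pseudocount, so estimator
#' and target agree in the large-sample limit).
#'
#' @param dataset a [generate_dataset()] result.
#' @param L window length (default: the generating spec's `L`).
#' @return list with the fitted `pwsm`, `truth_adjusted` probabilities and
#'   `max_abs_dev`, the maximum absolute entry-wise deviation.
#' @export
recover_pwm <- function(dataset, L = NULL) {
  stopifnot(inherits(dataset, "metseg_dataset"))
  spec <- dataset$truth$spec
  L <- check_window(L %||% spec$L)
  segs <- positive_segments(dataset$chains, L)
  alphabet <- metseg_alphabet("residue21")
  m <- build_pwsm(segs, alphabet, "uniform")
  if (L == spec$L) {
    truth <- dataset$truth$positive_probs
  } else {
    spec2 <- spec
    spec2$L <- L
    truth <- positive_truth_probs(spec2)
  }
  N <- m$N
  A <- length(alphabet)
  truth_adj <- (N * truth + sqrt(N) / A) / (N + sqrt(N))
  list(
    pwsm = m, truth_adjusted = truth_adj,
    max_abs_dev = max(abs(m$probs - truth_adj))
  )
}

#' Write a synthetic dataset to the package's file dialects
#'
#' Emits `chains.fasta`, `sites.tsv`, `annotations.tsv` (when annotated)
#' and `truth.json` under `dir`; [read_chains()] reads them back.
#'
#' @param dataset a [generate_dataset()] result.
#' @param dir output directory.
#' @param ion ligand label for the sites file.
#' @return invisibly, the directory.
#' @export
write_dataset <- function(dataset, dir, ion = "ZN") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ann <- if (dataset$truth$spec$annotate) file.path(dir, "annotations.tsv")
  write_chains(
    dataset$chains,
    fasta = file.path(dir, "chains.fasta"),
    sites = file.path(dir, "sites.tsv"),
    annotations = ann, ion = ion
  )
  truth <- dataset$truth
  truth$spec <- unclass(truth$spec)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(dir)
}
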