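#' Protein chain with binding annotations
#'
#' Bundles a protein sequence with its set of metal-ion binding positions and
#' optional per-residue annotations: a secondary-structure string over
#' `{H,E,C}` and relative solvent accessibility values in `[0,1]`.  All
#' coordinates are 1-based and inclusive throughout the package.
#'
#' @param id chain identifier.
#' @param sequence residue string; non-standard letters are normalized to `X`
#'   (see [normalize_sequence()]).
#' @param binding_positions integer vector of 1-based binding residue
#'   positions (may be empty).
#' @param ss optional secondary-structure string over `{H,E,C}`, same length
#'   as `sequence`.
#' @param rsa optional numeric vector of relative solvent accessibilities in
#'   `[0,1]`, same length as `sequence`.
#' @return an object of class `protein_chain`.
#' @export
protein_chain <- function(id, sequence, binding_positions = integer(),
                          ss = NULL, rsa = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  sequence <- normalize_sequence(sequence)
  n <- nchar(sequence)
  if (n == 0L) stop("empty sequence for chain ", id, call. = FALSE)
  binding_positions <- sort(unique(as.integer(binding_positions)))
  if (length(binding_positions) &&
    (min(binding_positions) < 1L || max(binding_positions) > n)) {
    stop(
      "binding position outside [1, ", n, "] for chain ", id,
      call. = FALSE
    )
  }
  if (!is.null(ss)) {
    if (nchar(ss) != n) stop("ss length mismatch for chain ", id, call. = FALSE)
    if (!all(chars(ss) %in% c("H", "E", "C"))) {
      stop("ss letters must be in {H,E,C} for chain ", id, call. = FALSE)
    }
  }
  if (!is.null(rsa)) {
    rsa <- as.numeric(rsa)
    if (length(rsa) != n) stop("rsa length mismatch for chain ", id, call. = FALSE)
    if (any(!is.finite(rsa)) || any(rsa < 0)) {
      stop("rsa values must be finite and >= 0 for chain ", id, call. = FALSE)
    }
  }
  structure(
    list(
      id = id, sequence = sequence, binding_positions = binding_positions,
      ss = ss, rsa = rsa
    ),
    class = "protein_chain"
  )
}

#' @export
print.protein_chain <- function(x, ...) {
  cat(
    "<protein_chain> ", x$id, ": ", nchar(x$sequence), " aa, ",
    length(x$binding_positions), " binding site(s)",
    if (!is.null(x$ss)) ", ss" else "",
    if (!is.null(x$rsa)) ", rsa" else "", "\n",
    sep = ""
  )
  invisible(x)
}

#' Pad a sequence with terminal dummy residues
#'
#' Adds `(L-1)/2` copies of the dummy letter `X` at both termini so that a
#' window of odd length `L` can be centered on every residue of the original
#' sequence, including the first and last.
#'
#' @param seq residue string (any channel alphabet; the pad letter is always
#'   `X`).
#' @param L odd window length, `L >= 1`.
#' @return padded string of length `nchar(seq) + L - 1`.
#' @export
pad_sequence <- function(seq, L) {
  check_window(L, min = 1L)
  if (!is.character(seq) || length(seq) != 1L || !nzchar(seq)) {
    stop("seq must be a single non-empty string", call. = FALSE)
  }
  k <- (L - 1L) %/% 2L
  pad <- strrep("X", k)
  paste0(pad, seq, pad)
}

check_window <- function(L, min = 5L) {
  if (length(L) != 1L || !is.numeric(L) || is.na(L) || L != as.integer(L) ||
    L < min || L %% 2L == 0L) {
    stop("window length L must be an odd integer >= ", min, call. = FALSE)
  }
  invisible(as.integer(L))
}

#' Extract labeled sliding-window segments from a chain
#'
#' Slides a window of odd length `L` along the padded chain so that exactly
#' one segment is centered on each residue of the original sequence.  A
#' segment is labeled `positive` when its center residue is a binding
#' residue, `negative` otherwise.  Parallel channel strings are produced for
#' the hydropathy and charge recodings (always derivable from the residues)
#' and for secondary structure / solvent accessibility when the chain
#' carries those annotations; channel padding uses each alphabet's padding
#' letter.
#'
#' @param chain a [protein_chain()].
#' @param L odd window length `>= 5` (see [ion_window()] for per-ion
#'   defaults).
#' @return a `data.frame` of class `metseg_segments` with columns `chain_id`,
#'   `center`, `label`, `residues` and channel columns `hydro6`, `charge3`
#'   and, when annotated, `ss3`, `sa4`; attribute `L` records the window.
#' @export
extract_segments <- function(chain, L) {
  stopifnot(inherits(chain, "protein_chain"))
  L <- check_window(L)
  n <- nchar(chain$sequence)
  padded <- pad_sequence(chain$sequence, L)
  starts <- seq_len(n)
  res <- substring(padded, starts, starts + L - 1L)
  out <- data.frame(
    chain_id = rep(chain$id, n),
    center = starts,
    label = ifelse(starts %in% chain$binding_positions, "positive", "negative"),
    residues = res,
    hydro6 = substring(recode_hydro(padded), starts, starts + L - 1L),
    charge3 = substring(recode_charge(padded), starts, starts + L - 1L),
    stringsAsFactors = FALSE
  )
  if (!is.null(chain$ss)) {
    pss <- pad_sequence(chain$ss, L)
    out$ss3 <- substring(pss, starts, starts + L - 1L)
  }
  if (!is.null(chain$rsa)) {
    k <- (L - 1L) %/% 2L
    psa <- recode_sa(c(rep(NA_real_, k), chain$rsa, rep(NA_real_, k)))
    out$sa4 <- substring(psa, starts, starts + L - 1L)
  }
  class(out) <- c("metseg_segments", "data.frame")
  attr(out, "L") <- L
  out
}

#' Extract segments from many chains
#'
#' @param chains list of [protein_chain()] objects.
#' @inheritParams extract_segments
#' @return row-bound `metseg_segments` data frame.  Channel columns present
#'   only if every chain supports them.
#' @export
extract_segments_all <- function(chains, L) {
  parts <- lapply(chains, extract_segments, L = L)
  common <- Reduce(intersect, lapply(parts, names))
  out <- do.call(rbind, lapply(parts, function(p) p[common]))
  rownames(out) <- NULL
  class(out) <- c("metseg_segments", "data.frame")
  attr(out, "L") <- check_window(L)
  out
}

## ---- file formats -------------------------------------------------------

#' Read protein chains from FASTA plus annotation tables
#'
#' Sequences come from a standard (multi-record) FASTA file.  Binding
#' annotations come from a BioLiP-like tab-separated file with columns
#' `chain_id`, `ligand`, `positions`, where `positions` is a comma-separated
#' list of 1-based residue indices; several rows per chain (e.g. one per
#' bound ligand instance) are unioned.  An optional annotation TSV with
#' columns `chain_id`, `ss_string`, `rsa_csv` attaches secondary structure
#' and relative solvent accessibility.
#'
#' @param fasta path to the FASTA file.
#' @param sites optional path to the binding-site TSV.
#' @param annotations optional path to the SS/RSA annotation TSV.
#' @param ion optional ligand identifier; when given, only site rows whose
#'   `ligand` matches (case-insensitively) are used.
#' @return named list of [protein_chain()] objects.
#' @export
read_chains <- function(fasta, sites = NULL, annotations = NULL, ion = NULL) {
  seqs <- Biostrings::readAAStringSet(fasta)
  ids <- sub("\\s.*$", "", names(seqs))
  site_map <- list()
  if (!is.null(sites)) {
    st <- utils::read.table(sites,
      sep = "\t", header = TRUE, stringsAsFactors = FALSE,
      colClasses = "character", quote = ""
    )
    need <- c("chain_id", "ligand", "positions")
    if (!all(need %in% names(st))) {
      stop("sites file must have columns: ", paste(need, collapse = ", "),
        call. = FALSE
      )
    }
    if (!is.null(ion)) st <- st[tolower(st$ligand) == tolower(ion), , drop = FALSE]
    for (r in seq_len(nrow(st))) {
      cid <- st$chain_id[r]
      pos <- as.integer(strsplit(st$positions[r], ",", fixed = TRUE)[[1]])
      site_map[[cid]] <- union(site_map[[cid]], pos)
    }
  }
  ann_map <- list()
  if (!is.null(annotations)) {
    an <- utils::read.table(annotations,
      sep = "\t", header = TRUE, stringsAsFactors = FALSE,
      colClasses = "character", quote = ""
    )
    need <- c("chain_id", "ss_string", "rsa_csv")
    if (!all(need %in% names(an))) {
      stop("annotation file must have columns: ", paste(need, collapse = ", "),
        call. = FALSE
      )
    }
    for (r in seq_len(nrow(an))) {
      ann_map[[an$chain_id[r]]] <- list(
        ss = an$ss_string[r],
        rsa = as.numeric(strsplit(an$rsa_csv[r], ",", fixed = TRUE)[[1]])
      )
    }
  }
  chains <- lapply(seq_along(seqs), function(i) {
    cid <- ids[i]
    ann <- ann_map[[cid]]
    protein_chain(
      id = cid,
      sequence = as.character(seqs[[i]]),
      binding_positions = site_map[[cid]] %||% integer(),
      ss = ann$ss, rsa = ann$rsa
    )
  })
  names(chains) <- ids
  chains
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write protein chains to the package's file dialects
#'
#' Emits the FASTA, binding-site TSV and (when annotations are present)
#' SS/RSA annotation TSV that [read_chains()] reads back.
#'
#' @param chains named list of [protein_chain()] objects.
#' @param fasta,sites,annotations output paths (`annotations` may be `NULL`
#'   to skip).
#' @param ion ligand label written to the `ligand` column.
#' @return invisibly, the list of written paths.
#' @export
write_chains <- function(chains, fasta, sites, annotations = NULL, ion = "ZN") {
  seqs <- Biostrings::AAStringSet(vapply(chains, function(ch) ch$sequence, ""))
  names(seqs) <- vapply(chains, function(ch) ch$id, "")
  Biostrings::writeXStringSet(seqs, fasta, width = 70L)
  has_sites <- vapply(chains, function(ch) length(ch$binding_positions) > 0L, NA)
  st <- data.frame(
    chain_id = vapply(chains[has_sites], function(ch) ch$id, ""),
    ligand = ion,
    positions = vapply(
      chains[has_sites],
      function(ch) paste(ch$binding_positions, collapse = ","), ""
    ),
    stringsAsFactors = FALSE
  )
  utils::write.table(st, sites,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  paths <- c(fasta, sites)
  if (!is.null(annotations)) {
    has_ann <- vapply(chains, function(ch) !is.null(ch$ss) && !is.null(ch$rsa), NA)
    an <- data.frame(
      chain_id = vapply(chains[has_ann], function(ch) ch$id, ""),
      ss_string = vapply(chains[has_ann], function(ch) ch$ss, ""),
      rsa_csv = vapply(
        chains[has_ann],
        function(ch) paste(formatC(ch$rsa, digits = 4, format = "f"), collapse = ","), ""
      ),
      stringsAsFactors = FALSE
    )
    utils::write.table(an, annotations,
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    paths <- c(paths, annotations)
  }
  invisible(paths)
}

#' Write / read a segment table
#'
#' Plain TSV round-trip of a `metseg_segments` data frame (columns
#' `chain_id  center  label  residues  [channels...]`), used for debugging
#' and fixtures.
#'
#' @param segments a `metseg_segments` data frame.
#' @param path output (or input) file path.
#' @return `write_segments` returns `path` invisibly; `read_segments`
#'   returns the segment data frame with its `L` attribute restored.
#' @export
write_segments <- function(segments, path) {
  utils::write.table(as.data.frame(segments), path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_segments
#' @export
read_segments <- function(path) {
  out <- utils::read.table(path,
    sep = "\t", header = TRUE, stringsAsFactors = FALSE,
    colClasses = "character", quote = ""
  )
  out$center <- as.integer(out$center)
  class(out) <- c("metseg_segments", "data.frame")
  attr(out, "L") <- nchar(out$residues[1L])
  out
}

#' Per-ion default window lengths
#'
#' Optimal sliding-window lengths per metal ion, as selected by
#' cross-validated screening of `L` in 5..17: Zn 7, Cu 13, Fe2 9, Fe3 9,
#' Co 11, Mn 7, Ca 9, Mg 9, K 11, Na 9.
#'
#' @param ion ion label, case-insensitive; one of zn, cu, fe2, fe3, co, mn,
#'   ca, mg, k, na.
#' @return odd integer window length.
#' @export
ion_window <- function(ion) {
  tab <- c(
    zn = 7L, cu = 13L, fe2 = 9L, fe3 = 9L, co = 11L,
    mn = 7L, ca = 9L, mg = 9L, k = 11L, na = 9L
  )
  key <- tolower(ion)
  if (!key %in% names(tab)) {
    stop("unknown ion '", ion, "'; known: ", paste(names(tab), collapse = ", "),
      call. = FALSE
    )
  }
  tab[[key]]
}
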