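#' Channel alphabets
#'
#' Every feature channel of the pipeline lives on its own finite alphabet.
#' Terminal padding is an observed category of each alphabet (a dedicated
#' letter, `"X"`), not missing data, so padded window positions participate
#' in matrix estimation like any other letter.
#'
#' * `residue21`: the 20 standard amino acids plus the padding/catch-all `X`.
#' * `hydro6`: six hydropathy classes `1`-`6` (strongly hydrophilic,
#'   weakly hydrophilic, strongly hydrophobic, proline, glycine, cysteine)
#'   plus padding.
#' * `charge3`: polarization charge `p`/`n`/`u`
#'   (positive, negative, uncharged) plus padding.
#' * `ss3`: three-state secondary structure `H`/`E`/`C` plus padding.
#' * `sa4`: binned relative solvent accessibility `I`/`J`/`M`/`N`
#'   plus padding.
#'
#' @param name one of `"residue21"`, `"hydro6"`, `"charge3"`, `"ss3"`, `"sa4"`.
#' @return character vector of single letters; the padding letter is last and
#'   carried in attribute `"pad"`.
#' @export
metseg_alphabet <- function(name = c("residue21", "hydro6", "charge3", "ss3", "sa4")) {
  name <- match.arg(name)
  letters <- switch(name,
    residue21 = c(AA20, "X"),
    hydro6 = c("1", "2", "3", "4", "5", "6", "X"),
    charge3 = c("p", "n", "u", "X"),
    ss3 = c("H", "E", "C", "X"),
    sa4 = c("I", "J", "M", "N", "X")
  )
  structure(letters, pad = "X", name = name)
}

# the 20 standard residues, alphabetical one-letter codes
AA20 <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

# Hydrophilic-hydrophobic six-class grouping (side-chain hydropathy):
#   1 strongly hydrophilic  R D E N Q K H
#   2 weakly hydrophilic    L I V A M F
#   3 strongly hydrophobic  S T Y W
#   4 proline, 5 glycine, 6 cysteine
HYDRO6_MAP <- c(
  R = "1", D = "1", E = "1", N = "1", Q = "1", K = "1", H = "1",
  L = "2", I = "2", V = "2", A = "2", M = "2", F = "2",
  S = "3", T = "3", Y = "3", W = "3",
  P = "4", G = "5", C = "6", X = "X"
)

# Polarization charge: K R P positive, D E negative, rest uncharged
CHARGE3_MAP <- c(
  K = "p", R = "p", P = "p",
  D = "n", E = "n",
  N = "u", Q = "u", H = "u", L = "u", I = "u", V = "u", A = "u", M = "u",
  F = "u", S = "u", T = "u", Y = "u", W = "u", C = "u", G = "u", X = "X"
)

# split a string into single characters
chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

recode_via_map <- function(seq, map, what) {
  vapply(seq, function(s) {
    cc <- chars(s)
    out <- map[cc]
    if (anyNA(out)) {
      bad <- unique(cc[is.na(out)])
      stop("invalid residue letter(s) for ", what, " recoding: ",
        paste(bad, collapse = ", "),
        call. = FALSE
      )
    }
    paste(out, collapse = "")
  }, "", USE.NAMES = FALSE)
}

#' Recode residues into the six-class hydropathy alphabet
#'
#' Maps each residue of `seq` onto `hydro6` (see [metseg_alphabet()]):
#' strongly hydrophilic residues (R,D,E,N,Q,K,H) to class `1`, weakly
#' hydrophilic (L,I,V,A,M,F) to `2`, strongly hydrophobic (S,T,Y,W) to `3`,
#' P to `4`, G to `5`, C to `6`.  The padding letter `X` passes through.
#'
#' @param seq character vector of residue strings over the 21-letter alphabet.
#' @return character vector of recoded strings of equal lengths.
#' @export
recode_hydro <- function(seq) recode_via_map(seq, HYDRO6_MAP, "hydro6")

#' Recode residues into the three-class polarization-charge alphabet
#'
#' K, R and P map to `p` (positive), D and E to `n` (negative), the remaining
#' fifteen residues to `u` (uncharged); padding `X` passes through.
#'
#' @inheritParams recode_hydro
#' @return character vector of recoded strings.
#' @export
recode_charge <- function(seq) recode_via_map(seq, CHARGE3_MAP, "charge3")

#' Bin relative solvent accessibility into the four-letter SA alphabet
#'
#' Real-valued relative solvent accessibility (RSA, fraction of surface
#' exposed, in `[0,1]`) concentrates in four regimes which are encoded as
#' letters: `(0,0.2] -> I`, `(0.2,0.45] -> J`, `(0.45,0.6] -> M`,
#' `(0.6,0.85] -> N`.  Boundary policy: `x = 0` (fully buried) is assigned
#' to `I`; values above 0.85 are clamped to `N`.  `NA` encodes a padding
#' position and maps to the channel padding letter.
#'
#' @param rsa numeric vector of RSA values, all `>= 0` (NA allowed for
#'   padding positions).
#' @return single string over `{I,J,M,N,X}` of length `length(rsa)`.
#' @export
recode_sa <- function(rsa) {
  if (is.logical(rsa) && all(is.na(rsa))) rsa <- as.numeric(rsa)
  if (!is.numeric(rsa)) stop("rsa must be numeric", call. = FALSE)
  if (any(rsa < 0, na.rm = TRUE)) {
    stop("negative relative solvent accessibility", call. = FALSE)
  }
  out <- character(length(rsa))
  out[is.na(rsa)] <- "X"
  ok <- !is.na(rsa)
  x <- rsa[ok]
  out[ok] <- ifelse(x <= 0.2, "I",
    ifelse(x <= 0.45, "J",
      ifelse(x <= 0.6, "M", "N")
    )
  )
  paste(out, collapse = "")
}

#' Normalize a raw amino-acid sequence onto the 21-letter alphabet
#'
#' Upper-cases and replaces every non-standard letter (B, Z, U, O, J, `*`,
#' gaps, ...) with the catch-all `X`; the 20 standard residues and `X` are
#' kept as is.
#'
#' @param seq character vector of sequences.
#' @return character vector of normalized sequences.
#' @export
normalize_sequence <- function(seq) {
  vapply(seq, function(s) {
    cc <- chars(toupper(s))
    cc[!(cc %in% c(AA20, "X"))] <- "X"
    paste(cc, collapse = "")
  }, "", USE.NAMES = FALSE)
}
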