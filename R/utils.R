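# Shared small helpers: base encoding, clipping, seed discipline.

BASES <- c("A", "C", "G", "T")

#' Encode a nucleotide string as integer codes
#'
#' A=1, C=2, G=3, T=4; any other character (N, ambiguity codes) becomes `NA`.
#' Lowercase is accepted.
#'
#' @param seq single character string over the DNA alphabet.
#' @return integer vector of length `nchar(seq)`.
#' @keywords internal
seq_to_codes <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  raw <- as.integer(charToRaw(toupper(seq)))
  match(raw, as.integer(charToRaw("ACGT")))
}

#' @keywords internal
codes_to_seq <- function(codes) {
  out <- rep("N", length(codes))
  ok <- !is.na(codes)
  out[ok] <- BASES[codes[ok]]
  paste(out, collapse = "")
}

# complement code: A<->T (1<->4), C<->G (2<->3)
complement_codes <- function(codes) 5L - codes

clip01 <- function(x) pmin(1, pmax(0, x))

# Validate a 4-vector of strictly positive background probabilities; renormalize.
check_background <- function(background) {
  stopifnot(is.numeric(background), length(background) == 4L, all(background > 0))
  background <- background / sum(background)
  names(background) <- BASES
  background
}

# %||% for defaulting
`%||%` <- function(a, b) if (is.null(a)) b else a
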