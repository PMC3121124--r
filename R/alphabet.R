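#' The 21-letter amino-acid alphabet
#'
#' The symbol set used for all frequency counts: the 20 standard amino
#' acids plus the alignment gap character \code{"-"}, treated as a 21st
#' residue type so that gap co-occurrence contributes to the joint
#' frequencies exactly like any other symbol.
#'
#' @return Character vector of length 21; the gap is the last element.
#' @export
#' @examples
#' aa_alphabet()
aa_alphabet <- function() AA_SYMBOLS

AA_SYMBOLS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "-")

#' Integer index of the gap symbol in [aa_alphabet()]
#' @return The integer 21.
#' @export
aa_gap_index <- function() 21L

#' Encode aligned sequences as an integer matrix
#'
#' Each residue is mapped to its index in [aa_alphabet()].  Stockholm
#' conventions are normalized first: lowercase letters are uppercased and
#' \code{"."} becomes \code{"-"}.  Ambiguous or non-standard residue codes
#' (B, J, O, U, X, Z and anything else outside the alphabet) are mapped to
#' the gap symbol with a single warning, so the alphabet stays at exactly
#' 21 symbols.
#'
#' @param seqs Character vector of aligned sequences, all the same length.
#' @return Integer matrix with one row per sequence and one column per
#'   alignment position, values in 1..21.
#' @export
encode_residues <- function(seqs) {
  if (length(seqs) == 0L) stop("no sequences to encode")
  n_cols <- unique(nchar(seqs))
  if (length(n_cols) != 1L)
    stop("aligned sequences have differing lengths: ",
         paste(n_cols, collapse = ", "))
  if (n_cols < 1L) stop("alignment must have at least one column")
  chars <- matrix(unlist(strsplit(toupper(seqs), "", fixed = TRUE),
                         use.names = FALSE),
                  nrow = length(seqs), ncol = n_cols, byrow = TRUE)
  chars[chars == "."] <- "-"
  idx <- match(chars, AA_SYMBOLS)
  bad <- is.na(idx)
  if (any(bad)) {
    warning(sum(bad), " non-standard residue(s) (",
            paste(unique(chars[bad]), collapse = ", "),
            ") mapped to the gap symbol")
    idx[bad] <- aa_gap_index()
  }
  matrix(idx, nrow = length(seqs), ncol = n_cols)
}

decode_residues <- function(mat) {
  apply(mat, 1L, function(row) paste(AA_SYMBOLS[row], collapse = ""))
}
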