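# 20 proteinogenic residues; X is the catch-all 21st state used for any
# unknown or non-standard symbol.
AA20 <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")
AA21 <- c(AA20, "X")

#' Encode a protein string as integer states
#'
#' Maps the 20 standard residues to 1..20 and X (or any unrecognised symbol,
#' with a warning) to 21.
#'
#' @param x a single protein string.
#' @return integer vector of states in 1..21.
#' @keywords internal
aa_encode <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  chars <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  idx <- match(chars, AA21)
  if (anyNA(idx)) {
    bad <- unique(chars[is.na(idx)])
    warning("non-amino-acid symbol(s) ", paste(bad, collapse = ", "),
            " scored as X", call. = FALSE)
    idx[is.na(idx)] <- 21L
  }
  idx
}

#' Substitution matrices for protein alignment
#'
#' `"blosum62"` is the BLOSUM62 matrix shipped with Biostrings, restricted to
#' the 20 standard residues plus X. `"id"` is the identity matrix used by the
#' ClustalW-style aligner: match 1, mismatch 0 (X matches itself).
#'
#' @param name `"id"` or `"blosum62"`.
#' @return a 21 x 21 numeric matrix with dimnames over the residue alphabet.
#' @export
#' @examples
#' score_matrix("id")["A", "A"]
score_matrix <- function(name = c("id", "blosum62")) {
  name <- match.arg(name)
  if (name == "id") {
    S <- diag(1, 21L)
    dimnames(S) <- list(AA21, AA21)
    return(S)
  }
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  S <- e$BLOSUM62[AA21, AA21]
  storage.mode(S) <- "double"
  S
}
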