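#' Pairwise protein alignment with affine gap penalties
#'
#' Aligns two protein sequences by dynamic programming. `type = "global"` is a
#' Needleman-Wunsch alignment (the unit step of the progressive aligner);
#' `type = "local"` is Smith-Waterman, the primitive behind the homolog
#' search. A gap of length L costs `gap_open + L * gap_extend`. Traceback
#' ties are broken diagonal > vertical > horizontal, so results are
#' bit-stable.
#'
#' @param a,b protein strings (non-empty).
#' @param matrix substitution matrix: `"id"` (match 1 / mismatch 0, the
#'   ClustalW-style default) or `"blosum62"`; alternatively a 21 x 21 numeric
#'   matrix over the residue alphabet.
#' @param gap_open,gap_extend gap penalties (positive numbers; defaults are
#'   the ClustalW-style 8 / 0.1).
#' @param type `"global"` or `"local"`.
#' @return an object of class `pairwise_alignment`: a list with gapped
#'   strings `a` and `b`, the `score`, `identity` (matches / alignment
#'   columns), and for local alignments the 1-based `a_range` / `b_range` of
#'   the aligned segments.
#' @export
#' @examples
#' align_pair("ACDE", "ACDE")$score
#' align_pair("HEAGAWGHEE", "PAWHEAE", matrix = "blosum62",
#'            gap_open = 11, gap_extend = 1, type = "local")
align_pair <- function(a, b, matrix = "id", gap_open = 8, gap_extend = 0.1,
                       type = c("global", "local")) {
  type <- match.arg(type)
  if (!nzchar(a) || !nzchar(b)) {
    stop("align_pair() requires two non-empty sequences", call. = FALSE)
  }
  S <- if (is.character(matrix)) score_matrix(matrix) else matrix
  ea <- aa_encode(a)
  eb <- aa_encode(b)
  C <- S[ea, eb, drop = FALSE]
  res <- affine_align_cpp(C, gap_open, gap_extend, type == "local")
  pa <- res$a
  pb <- res$b
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  ga <- ifelse(pa == 0L, "-", ca[pmax(pa, 1L)])
  gb <- ifelse(pb == 0L, "-", cb[pmax(pb, 1L)])
  ncol_aln <- length(pa)
  matches <- sum(pa > 0L & pb > 0L & ga == gb)
  out <- list(
    a = paste(ga, collapse = ""),
    b = paste(gb, collapse = ""),
    score = res$score,
    identity = if (ncol_aln > 0) matches / ncol_aln else NA_real_,
    length = ncol_aln,
    type = type
  )
  if (type == "local") {
    out$a_range <- if (any(pa > 0L)) range(pa[pa > 0L]) else c(NA_integer_, NA_integer_)
    out$b_range <- if (any(pb > 0L)) range(pb[pb > 0L]) else c(NA_integer_, NA_integer_)
  }
  structure(out, class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("<pairwise_alignment> %s, score %.4g, identity %.3f\n",
              x$type, x$score, x$identity))
  cat(" ", x$a, "\n ", x$b, "\n")
  invisible(x)
}

#' Search an annotated proteome for homologs of query proteins
#'
#' Runs a Smith-Waterman local alignment (BLOSUM62, gap open 11, extend 1 by
#' default — the classic protein-search parameterisation) of every query
#' against every annotated protein, and keeps hits passing identity and
#' query-coverage thresholds.
#'
#' @param queries named character vector of query proteins (names become
#'   `query_id`), or an `AAStringSet`.
#' @param annotation a genome annotation tibble as returned by
#'   [read_annotation()] or [plant_genome()] (columns `locus_tag`,
#'   `replicon_id`, `start`, `end`, `strand`, `product`, `protein`).
#' @param min_identity,min_coverage acceptance thresholds in \[0, 1\].
#'   Defaults (0.25 / 0.5) are deliberately permissive, twilight-zone values.
#' @param gap_open,gap_extend,matrix alignment parameters.
#' @return a tibble with one row per accepted hit: `query_id`, `locus_tag`,
#'   `score`, `identity`, `query_coverage`, sorted by descending score. An
#'   empty proteome yields an empty tibble.
#' @export
find_homologs <- function(queries, annotation, min_identity = 0.25,
                          min_coverage = 0.5, gap_open = 11, gap_extend = 1,
                          matrix = "blosum62") {
  if (methods::is(queries, "AAStringSet")) {
    queries <- setNames(as.character(queries), names(queries))
  }
  if (length(queries) == 0L) stop("no query proteins supplied", call. = FALSE)
  if (is.null(names(queries)) || any(!nzchar(names(queries)))) {
    stop("queries must be named", call. = FALSE)
  }
  stopifnot(min_identity >= 0, min_identity <= 1,
            min_coverage >= 0, min_coverage <= 1)
  S <- if (is.character(matrix)) score_matrix(matrix) else matrix
  subjects <- annotation$protein
  if (length(subjects) == 0L) {
    return(tibble::tibble(query_id = character(), locus_tag = character(),
                          score = double(), identity = double(),
                          query_coverage = double()))
  }
  rows <- purrr::map_dfr(seq_along(queries), function(qi) {
    q <- queries[[qi]]
    eq <- aa_encode(q)
    purrr::map_dfr(seq_along(subjects), function(si) {
      es <- aa_encode(subjects[[si]])
      C <- S[eq, es, drop = FALSE]
      res <- affine_align_cpp(C, gap_open, gap_extend, TRUE)
      if (length(res$a) == 0L) return(NULL)
      pa <- res$a; pb <- res$b
      aligned <- pa > 0L & pb > 0L
      matches <- sum(aligned & eq[pmax(pa, 1L)] == es[pmax(pb, 1L)])
      tibble::tibble(
        query_id = names(queries)[qi],
        locus_tag = annotation$locus_tag[si],
        score = res$score,
        identity = matches / length(pa),
        query_coverage = sum(pa > 0L) / length(eq)
      )
    })
  })
  rows %>%
    dplyr::filter(.data$identity >= min_identity,
                  .data$query_coverage >= min_coverage) %>%
    dplyr::arrange(dplyr::desc(.data$score))
}
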