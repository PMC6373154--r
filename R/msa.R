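#' Construct a protein alignment tibble
#'
#' Alignments are plain tibbles with columns `label` and `sequence` (gapped,
#' equal-length strings) carrying class `protein_alignment`, so they pipe
#' through dplyr verbs unchanged.
#'
#' @param labels character vector of unique sequence ids.
#' @param rows gapped sequences, all the same length.
#' @return a `protein_alignment` tibble.
#' @export
protein_alignment <- function(labels, rows) {
  stopifnot(length(labels) == length(rows), !anyDuplicated(labels))
  widths <- nchar(rows)
  if (length(unique(widths)) > 1L) {
    stop("alignment rows differ in length", call. = FALSE)
  }
  out <- tibble::tibble(label = as.character(labels), sequence = rows)
  class(out) <- c("protein_alignment", class(out))
  out
}

#' @export
print.protein_alignment <- function(x, ...) {
  cat(sprintf("<protein_alignment> %d sequences x %d columns\n",
              nrow(x), alignment_length(x)))
  NextMethod()
}

#' Number of columns in an alignment
#' @param aln a `protein_alignment` (or any tibble with a `sequence` column).
#' @return integer column count.
#' @export
alignment_length <- function(aln) {
  if (nrow(aln) == 0L) return(0L)
  nchar(aln$sequence[[1]])
}

#' Alignment as a character matrix (rows = sequences, columns = sites)
#' @inheritParams alignment_length
#' @return character matrix with `label` rownames; gaps are `"-"`.
#' @export
alignment_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$sequence, "", fixed = TRUE))
  rownames(m) <- aln$label
  m
}

#' Remove gaps from alignment rows
#' @inheritParams alignment_length
#' @return named character vector of ungapped sequences.
#' @export
degap <- function(aln) {
  setNames(gsub("-", "", aln$sequence, fixed = TRUE), aln$label)
}

# Column residue-frequency profile: 21 x L, gap mass omitted (gaps dilute).
alignment_profile <- function(aln) {
  m <- alignment_matrix(aln)
  L <- ncol(m)
  prof <- matrix(0, nrow = 21L, ncol = L, dimnames = list(AA21, NULL))
  for (k in seq_len(21L)) {
    prof[k, ] <- colSums(m == AA21[k]) / nrow(m)
  }
  prof
}

# Merge two alignments along a pairwise path from affine_align_cpp().
merge_alignments <- function(aln_a, aln_b, pa, pb) {
  ma <- alignment_matrix(aln_a)
  mb <- alignment_matrix(aln_b)
  n_out <- length(pa)
  out_a <- matrix("-", nrow = nrow(ma), ncol = n_out)
  out_b <- matrix("-", nrow = nrow(mb), ncol = n_out)
  out_a[, pa > 0L] <- ma[, pa[pa > 0L], drop = FALSE]
  out_b[, pb > 0L] <- mb[, pb[pb > 0L], drop = FALSE]
  protein_alignment(c(rownames(ma), rownames(mb)),
                    c(apply(out_a, 1L, paste, collapse = ""),
                      apply(out_b, 1L, paste, collapse = "")))
}

# 3-mer distance: 1 - shared 3-mers / (min length - 2), where "shared" is the
# multiset intersection of 3-mer counts. Quick, deterministic guide distance.
kmer_distance <- function(seqs, k = 3L) {
  counts <- lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(table(character()))
    kmers <- substring(s, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
    table(kmers)
  })
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      shared_keys <- intersect(names(counts[[i]]), names(counts[[j]]))
      shared <- sum(pmin(counts[[i]][shared_keys], counts[[j]][shared_keys]))
      denom <- max(min(nchar(seqs[[i]]), nchar(seqs[[j]])) - k + 1L, 1L)
      d[i, j] <- d[j, i] <- 1 - shared / denom
    }
  }
  d
}

#' Progressive multiple alignment of protein sequences
#'
#' ClustalW-style progressive alignment: a quick 3-mer distance feeds a UPGMA
#' guide tree, and profiles are merged in guide-tree order with
#' average-of-pairs profile scoring under affine gap penalties. Defaults
#' mirror the classic identity-matrix parameterisation (match 1, mismatch 0,
#' gap open 8, gap extend 0.1).
#'
#' @param seqs named character vector of proteins, or a tibble with `label`
#'   and `sequence` columns (sequences ungapped).
#' @inheritParams align_pair
#' @return a [protein_alignment()] tibble; row order follows input order.
#' @export
progressive_align <- function(seqs, matrix = "id", gap_open = 8,
                              gap_extend = 0.1) {
  if (is.data.frame(seqs)) seqs <- setNames(seqs$sequence, seqs$label)
  if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
    stop("sequences must have unique names", call. = FALSE)
  }
  if (any(!nzchar(seqs))) stop("empty sequence in input", call. = FALSE)
  if (length(seqs) == 1L) {
    warning("single sequence: returned unchanged as a 1-row alignment",
            call. = FALSE)
    return(protein_alignment(names(seqs), unname(seqs)))
  }
  S <- if (is.character(matrix)) score_matrix(matrix) else matrix
  labels <- names(seqs)

  if (length(seqs) == 2L) {
    pw <- align_pair(seqs[[1]], seqs[[2]], matrix = S,
                     gap_open = gap_open, gap_extend = gap_extend)
    return(protein_alignment(labels, c(pw$a, pw$b)))
  }

  d <- kmer_distance(seqs)
  guide <- upgma_merge(d)
  # node alignments: negative index = tip, positive = merge-table row
  tip_aln <- lapply(seq_along(seqs),
                    function(i) protein_alignment(labels[i], unname(seqs[[i]])))
  node_aln <- vector("list", nrow(guide$merge))
  fetch <- function(id) if (id < 0L) tip_aln[[-id]] else node_aln[[id]]
  for (r in seq_len(nrow(guide$merge))) {
    left <- fetch(guide$merge[r, 1L])
    right <- fetch(guide$merge[r, 2L])
    pa_prof <- alignment_profile(left)
    pb_prof <- alignment_profile(right)
    C <- crossprod(pa_prof, S %*% pb_prof)
    path <- affine_align_cpp(C, gap_open, gap_extend, FALSE)
    node_aln[[r]] <- merge_alignments(left, right, path$a, path$b)
  }
  final <- node_aln[[nrow(guide$merge)]]
  final[match(labels, final$label), ]
}

#' Score an existing alignment under sum-of-pairs scoring
#'
#' Used for sanity checks (e.g. progressive output versus naive gap
#' stacking). Each pair of rows is scored column-wise with the substitution
#' matrix; per-row gap runs are charged `gap_open + L * gap_extend`
#' independently per pair.
#'
#' @inheritParams alignment_length
#' @inheritParams align_pair
#' @return total sum-of-pairs score (double).
#' @export
alignment_score <- function(aln, matrix = "id", gap_open = 8,
                            gap_extend = 0.1) {
  S <- if (is.character(matrix)) score_matrix(matrix) else matrix
  m <- alignment_matrix(aln)
  n <- nrow(m)
  total <- 0
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      ri <- m[i, ]; rj <- m[j, ]
      keep <- !(ri == "-" & rj == "-")
      ri <- ri[keep]; rj <- rj[keep]
      both <- ri != "-" & rj != "-"
      total <- total + sum(S[cbind(ri[both], rj[both])])
      gaps <- ri == "-" | rj == "-"
      runs <- rle(gaps)
      glen <- runs$lengths[runs$values]
      total <- total - sum(gap_open + glen * gap_extend)
    }
  }
  total
}

#' Concatenate two alignments row-wise by label pairing
#'
#' Builds the concatenated EtfA_EtfB-style alignment: for each pair, the
#' output row is the A row followed by the B row. Labels absent from the
#' pairing are dropped with a warning.
#'
#' @param aln_a,aln_b `protein_alignment` tibbles.
#' @param pairing named character vector mapping A labels to B labels, or a
#'   two-column data frame (`a`, `b`). Default pairs identical labels.
#' @return a `protein_alignment` with one row per pair, labelled by the A
#'   label, of width `length(A) + length(B)`.
#' @export
concatenate_alignments <- function(aln_a, aln_b, pairing = NULL) {
  if (is.null(pairing)) {
    common <- intersect(aln_a$label, aln_b$label)
    pairing <- setNames(common, common)
  }
  if (is.data.frame(pairing)) pairing <- setNames(pairing[[2]], pairing[[1]])
  if (anyDuplicated(names(pairing)) || anyDuplicated(pairing)) {
    stop("pairing must be one-to-one (a label appears twice)", call. = FALSE)
  }
  missing_a <- setdiff(names(pairing), aln_a$label)
  missing_b <- setdiff(unname(pairing), aln_b$label)
  if (length(missing_a) || length(missing_b)) {
    stop("pairing refers to unknown labels: ",
         paste(c(missing_a, missing_b), collapse = ", "), call. = FALSE)
  }
  dropped <- c(setdiff(aln_a$label, names(pairing)),
               setdiff(aln_b$label, unname(pairing)))
  if (length(dropped)) {
    warning("unpaired labels dropped: ", paste(dropped, collapse = ", "),
            call. = FALSE)
  }
  rows_a <- setNames(aln_a$sequence, aln_a$label)
  rows_b <- setNames(aln_b$sequence, aln_b$label)
  protein_alignment(names(pairing),
                    paste0(rows_a[names(pairing)], rows_b[unname(pairing)]))
}

#' Read/write aligned or unaligned FASTA
#'
#' Thin wrappers over Biostrings for the package's tibble conventions.
#'
#' @param path file path.
#' @return `read_fasta()`: a tibble with `label` and `sequence`.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  tibble::tibble(label = names(x), sequence = as.character(x))
}

#' @rdname read_fasta
#' @param x a tibble with `label`/`sequence` columns or a named character
#'   vector.
#' @export
write_fasta <- function(x, path) {
  if (is.data.frame(x)) x <- setNames(x$sequence, x$label)
  set <- Biostrings::AAStringSet(x)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
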