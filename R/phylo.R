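#' Jukes-Cantor distance generalised to 20 amino-acid states
#'
#' Converts an observed mismatch fraction p into an expected number of
#' substitutions per site under an equal-rates 20-state model:
#' d = -(19/20) * log(1 - (20/19) * p). Distances are capped at `cap` (with a
#' warning) when p approaches the saturation point 19/20.
#'
#' @param p mismatch fraction(s) in \[0, 1\].
#' @param cap value substituted for saturated pairs (default 10).
#' @return numeric vector of distances (substitutions/site).
#' @export
#' @examples
#' jc20_distance(0.10)
jc20_distance <- function(p, cap = 10) {
  stopifnot(all(p >= 0 & p <= 1))
  d <- numeric(length(p))
  sat <- p >= 19 / 20
  if (any(sat)) {
    warning("p >= 19/20 for ", sum(sat), " pair(s); distance capped at ", cap,
            call. = FALSE)
    d[sat] <- cap
  }
  d[!sat] <- -(19 / 20) * log(1 - (20 / 19) * p[!sat])
  pmin(d, cap)
}

#' Pairwise distance matrix from a protein alignment
#'
#' p-distances are mismatch fractions over comparable sites; `model = "jc20"`
#' applies the 20-state Jukes-Cantor correction via [jc20_distance()]. Gap
#' handling is pairwise deletion by default (sites where either row is
#' gapped are dropped per pair); `"complete"` drops every column containing
#' any gap before comparison.
#'
#' @param aln a [protein_alignment()] (>= 2 rows).
#' @param model `"jc20"` or `"p"`.
#' @param gap_handling `"pairwise"` or `"complete"` deletion.
#' @return symmetric numeric matrix with label dimnames, zero diagonal.
#' @export
distance_matrix <- function(aln, model = c("jc20", "p"),
                            gap_handling = c("pairwise", "complete")) {
  model <- match.arg(model)
  gap_handling <- match.arg(gap_handling)
  if (nrow(aln) < 2L) stop("need at least 2 sequences", call. = FALSE)
  m <- alignment_matrix(aln)
  if (gap_handling == "complete") {
    keep <- colSums(m == "-") == 0L
    m <- m[, keep, drop = FALSE]
  }
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  gap <- m == "-"
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      ok <- !gap[i, ] & !gap[j, ]
      if (!any(ok)) {
        stop("no comparable sites between ", rownames(m)[i], " and ",
             rownames(m)[j], call. = FALSE)
      }
      p <- mean(m[i, ok] != m[j, ok])
      d[i, j] <- d[j, i] <- if (model == "p") p else jc20_distance(p)
    }
  }
  d
}

# UPGMA merge loop with size-weighted average linkage. Ties are broken by the
# smallest (row, column) index pair in current label order, so output is
# deterministic. Returns an hclust-style merge table plus heights.
upgma_merge <- function(d) {
  n <- nrow(d)
  labels <- rownames(d)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  active <- seq_len(n)           # current cluster slots
  id <- -seq_len(n)              # hclust convention: negative = singleton
  size <- rep(1L, n)
  work <- d
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    k <- length(active)
    best <- c(NA_integer_, NA_integer_); best_d <- Inf
    for (i in seq_len(k - 1L)) {
      for (j in seq.int(i + 1L, k)) {
        if (work[i, j] < best_d - 1e-12) {
          best_d <- work[i, j]; best <- c(i, j)
        }
      }
    }
    i <- best[1L]; j <- best[2L]
    merge[step, ] <- c(id[i], id[j])
    height[step] <- best_d
    ni <- size[i]; nj <- size[j]
    new_row <- (ni * work[i, ] + nj * work[j, ]) / (ni + nj)
    keep <- setdiff(seq_len(k), c(i, j))
    work <- rbind(cbind(work[keep, keep, drop = FALSE], new_row[keep]),
                  c(new_row[keep], 0))
    id <- c(id[keep], step)
    size <- c(size[keep], ni + nj)
    active <- seq_len(k - 1L)
  }
  list(merge = merge, height = height, labels = labels)
}

#' UPGMA tree from a distance matrix
#'
#' Agglomerative size-weighted average-linkage clustering; each internal node
#' sits at half the merge distance, so the result is rooted and ultrametric.
#' Ties are broken by the smallest (row, column) index pair, making the
#' topology deterministic.
#'
#' @param d symmetric distance matrix with label dimnames (or a `dist`).
#' @return a rooted ultrametric `ape::phylo` tree.
#' @export
#' @examples
#' d <- matrix(c(0, .2, .6, .2, 0, .6, .6, .6, 0), 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' upgma(d)
upgma <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  if (nrow(d) == 1L) {
    tr <- list(edge = matrix(c(2L, 1L), 1L, 2L), edge.length = 0,
               tip.label = rownames(d), Nnode = 1L)
    class(tr) <- "phylo"
    return(tr)
  }
  mg <- upgma_merge(d)
  hc <- structure(list(merge = mg$merge, height = mg$height,
                       order = hclust_order(mg$merge), labels = mg$labels,
                       method = "upgma"),
                  class = "hclust")
  tr <- ape::as.phylo(hc)
  stats::reorder(tr, "cladewise")
}

# Leaf order for an hclust merge table (left-to-right traversal).
hclust_order <- function(merge) {
  walk <- function(id) {
    if (id < 0L) return(-id)
    c(walk(merge[id, 1L]), walk(merge[id, 2L]))
  }
  walk(nrow(merge))
}

#' Rooted clades (descendant tip sets) of a tree
#'
#' @param tree an `ape::phylo`.
#' @return named list: for each internal node (names are node numbers), the
#'   sorted tip labels below it.
#' @export
tree_clades <- function(tree) {
  n_tip <- length(tree$tip.label)
  pp <- ape::prop.part(tree)
  out <- lapply(pp, function(idx) sort(tree$tip.label[idx]))
  names(out) <- as.character(n_tip + seq_along(out))
  out
}

#' Bootstrap support for a UPGMA tree
#'
#' Builds the full-data tree, then resamples alignment columns with
#' replacement `replicates` times, rebuilds the tree per replicate, and
#' annotates each internal node of the full-data tree with the percentage of
#' replicate trees containing the identical rooted tip set. Replicate r
#' reseeds the generator at `seed + r`, so partial runs are reproducible.
#' Supports below `threshold` are kept but flagged.
#'
#' @inheritParams distance_matrix
#' @param replicates number of bootstrap replicates (>= 1).
#' @param seed integer seed.
#' @param threshold display/flag threshold in percent (default 30, annotated
#'   rather than collapsed).
#' @return an `ape::phylo` with class `etf_tree` prepended; `node.label`
#'   holds supports (root is `NA`), and attributes `support` (numeric, by
#'   node number) and `low_support` (node numbers under threshold) are set.
#' @export
bootstrap_support <- function(aln, model = "jc20", replicates = 100,
                              seed = 1, gap_handling = "pairwise",
                              threshold = 30) {
  stopifnot(replicates >= 1)
  L <- alignment_length(aln)
  if (L == 0L) stop("alignment has zero columns", call. = FALSE)
  m <- alignment_matrix(aln)
  full <- upgma(distance_matrix(aln, model = model,
                                gap_handling = gap_handling))
  clades <- tree_clades(full)
  keys <- vapply(clades, paste, "", collapse = "\r")
  counts <- setNames(numeric(length(keys)), keys)
  for (r in seq_len(replicates)) {
    set.seed(seed + r)
    cols <- sample.int(L, L, replace = TRUE)
    sub <- protein_alignment(rownames(m),
                             apply(m[, cols, drop = FALSE], 1L, paste,
                                   collapse = ""))
    rep_tree <- upgma(distance_matrix(sub, model = model,
                                      gap_handling = gap_handling))
    rep_keys <- vapply(tree_clades(rep_tree), paste, "", collapse = "\r")
    hit <- keys %in% rep_keys
    counts[hit] <- counts[hit] + 1
  }
  support <- 100 * counts / replicates
  names(support) <- names(clades)
  n_tip <- length(full$tip.label)
  support[as.character(n_tip + 1L)] <- NA_real_  # root: trivially present
  labels <- ifelse(is.na(support), "", formatC(support, format = "fg"))
  full$node.label <- labels[as.character(n_tip + seq_len(full$Nnode))]
  attr(full, "support") <- support
  attr(full, "low_support") <-
    as.integer(names(support)[!is.na(support) & support < threshold])
  attr(full, "replicates") <- replicates
  attr(full, "threshold") <- threshold
  class(full) <- c("etf_tree", class(full))
  full
}

#' Is a tip set a rooted clade, and with what support?
#'
#' @param tree an `ape::phylo`, typically from [bootstrap_support()].
#' @param tips character vector of tip labels.
#' @return a list with `present` (logical), `node` (node number or `NA`) and
#'   `support` (percentage, `NA` when absent or unannotated; the root is
#'   reported as `NA` by convention — it is trivially present in every
#'   replicate).
#' @export
clade_support <- function(tree, tips) {
  unknown <- setdiff(tips, tree$tip.label)
  if (length(unknown)) {
    stop("unknown tip(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (length(tips) == 1L) {
    return(list(present = TRUE, node = match(tips, tree$tip.label),
                support = NA_real_))
  }
  key <- paste(sort(tips), collapse = "\r")
  clades <- tree_clades(tree)
  keys <- vapply(clades, paste, "", collapse = "\r")
  hit <- match(key, keys)
  if (is.na(hit)) return(list(present = FALSE, node = NA_integer_,
                              support = NA_real_))
  node <- as.integer(names(clades)[hit])
  sup <- attr(tree, "support")
  support <- if (!is.null(sup)) unname(sup[as.character(node)]) else NA_real_
  list(present = TRUE, node = node, support = support)
}

#' @export
print.etf_tree <- function(x, ...) {
  cat(sprintf("<etf_tree> %d tips, %d bootstrap replicates (threshold %g%%)\n",
              length(x$tip.label), attr(x, "replicates") %||% NA,
              attr(x, "threshold") %||% NA))
  NextMethod()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
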