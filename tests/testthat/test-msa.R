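test_that("identical sequences align without gaps", {
  seqs <- setNames(rep("MKVLAQTT", 3), c("s1", "s2", "s3"))
  aln <- progressive_align(seqs)
  expect_equal(alignment_length(aln), 8L)
  expect_false(any(grepl("-", aln$sequence)))
  expect_equal(aln$label, names(seqs))
})

test_that("two-sequence progressive alignment reduces to align_pair", {
  set.seed(411)
  a <- random_protein(40)
  b <- random_protein(35)
  aln <- progressive_align(c(x = a, y = b))
  pw <- align_pair(a, b)
  expect_equal(aln$sequence, c(pw$a, pw$b))
})

test_that("single sequence is returned as a 1-row alignment with warning", {
  expect_warning(aln <- progressive_align(c(only = "MKV")), "single")
  expect_equal(nrow(aln), 1L)
  expect_equal(aln$sequence, "MKV")
})

test_that("de-gapping progressive output reproduces every input", {
  set.seed(412)
  base <- random_protein(80)
  mutate_del <- function(s) {
    ch <- strsplit(s, "")[[1]]
    pos <- sample(length(ch), 8)
    ch[pos] <- sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 8,
                      replace = TRUE)
    del_at <- sample(length(ch) - 6, 1)
    paste(ch[-(del_at:(del_at + sample(2:5, 1)))], collapse = "")
  }
  seqs <- c(a = base, b = mutate_del(base), c = mutate_del(base),
            d = mutate_del(base))
  aln <- progressive_align(seqs)
  expect_equal(degap(aln), seqs)
  expect_equal(length(unique(nchar(aln$sequence))), 1L)
})

test_that("progressive alignment beats naive all-gap stacking", {
  set.seed(413)
  base <- random_protein(60)
  seqs <- vapply(1:4, function(i) {
    ch <- strsplit(base, "")[[1]]
    pos <- sample(60, 6)
    ch[pos] <- sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 6,
                      replace = TRUE)
    paste(ch, collapse = "")
  }, "")
  names(seqs) <- paste0("s", 1:4)
  aln <- progressive_align(seqs)
  L <- nchar(seqs)
  offs <- c(0, cumsum(L))[1:4]
  stacked <- protein_alignment(names(seqs), vapply(1:4, function(i) {
    paste0(strrep("-", offs[i]), seqs[i], strrep("-", sum(L) - offs[i] - L[i]))
  }, ""))
  expect_gte(alignment_score(aln), alignment_score(stacked))
})

test_that("low-divergence generator families realign to the true columns", {
  tr <- simulate_tree(8, 0.15, 421)
  truth <- evolve_proteins(tr, 150, 422)
  aln <- progressive_align(degap(truth))
  # with no indels in the generator, every correctly aligned column maps the
  # same input position in all rows
  m <- alignment_matrix(aln)
  cum <- apply(m != "-", 1, cumsum)  # L x n: input position per output col
  good <- 0
  for (k in seq_len(ncol(m))) {
    if (all(m[, k] != "-") && length(unique(cum[k, ])) == 1L) good <- good + 1
  }
  expect_gte(good / 150, 0.9)
})

test_that("concatenation joins rows by pairing and drops unpaired labels", {
  a <- protein_alignment(c("s1", "s2"), c("ABCDE", "AB-DE"))
  b <- protein_alignment(c("s1", "s2", "s3"),
                         c("MKVLAQT", "MKVLAQT", "MKVLAQT"))
  expect_warning(cc <- concatenate_alignments(a, b), "s3")
  expect_equal(nrow(cc), 2L)
  expect_equal(alignment_length(cc), 12L)
  expect_equal(cc$sequence[1], "ABCDEMKVLAQT")
})

test_that("concatenating paired families gives additive column counts", {
  set.seed(414)
  labs <- paste0("sp", 1:18)
  a <- protein_alignment(labs, vapply(labs, function(x) random_protein(33), ""))
  b <- protein_alignment(labs, vapply(labs, function(x) random_protein(21), ""))
  cc <- concatenate_alignments(a, b)
  expect_equal(nrow(cc), 18L)
  expect_equal(alignment_length(cc), 54L)
})

test_that("a duplicated label in the pairing is an error", {
  a <- protein_alignment(c("s1", "s2"), c("AAA", "AAA"))
  b <- protein_alignment(c("t1", "t2"), c("CCC", "CCC"))
  expect_error(concatenate_alignments(a, b, c(s1 = "t1", s2 = "t1")),
               "one-to-one")
})
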