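# small synthetic annotation for classification-logic tests: genes laid out
# in order g01..gNN on one replicon, 1 kb apart
toy_annotation <- function(n, replicon = "rep1") {
  tibble::tibble(
    locus_tag = sprintf("g%02d", seq_len(n)),
    replicon_id = replicon,
    start = seq_len(n) * 1000L,
    end = seq_len(n) * 1000L + 600L,
    strand = rep(c("+", "-"), length.out = n),
    product = "cds",
    protein = strrep("M", 50)
  )
}

hit <- function(query_id, locus_tag) {
  tibble::tibble(query_id = query_id, locus_tag = locus_tag,
                 score = 100, identity = 0.9, query_coverage = 0.9)
}

no_hits <- hit(character(), character())

test_that("planted GenBank round-trips through the reader in start order", {
  g <- plant_genome(contexts = "GlcD", decoys = 6, seed = 501,
                    dir = tempfile())
  ann <- read_annotation(g$paths$genbank)
  ref <- g$annotation[order(g$annotation$start), ]
  expect_equal(nrow(ann), nrow(ref))
  expect_equal(ann$locus_tag, ref$locus_tag)
  expect_equal(ann$start, ref$start)
  expect_equal(ann$end, ref$end)
  expect_equal(ann$strand, ref$strand)
  expect_equal(ann$protein, ref$protein)
})

test_that("GFF3+FASTA and GenBank serialisations parse identically", {
  g <- plant_genome(contexts = c("acyl-CoA", "GlcD"), decoys = 8, seed = 502,
                    dir = tempfile())
  a_gbk <- read_annotation(g$paths$genbank)
  a_gff <- read_annotation(g$paths$gff3, fasta = g$paths$fasta)
  expect_equal(
    a_gbk[, c("locus_tag", "replicon_id", "start", "end", "strand",
              "protein")],
    a_gff[, c("locus_tag", "replicon_id", "start", "end", "strand",
              "protein")])
})

test_that("a record with start > end is a format error", {
  path <- tempfile(fileext = ".gbk")
  writeLines(c(
    "LOCUS       badrep               100 bp    DNA     linear BCT 01-JAN-2024",
    "FEATURES             Location/Qualifiers",
    "     source          1..100",
    "     CDS             90..10",
    '                     /locus_tag="bad1"',
    '                     /translation="MKV"',
    "ORIGIN",
    paste("        1", strrep("acgtacgtac ", 3)),
    "//"), path)
  expect_error(read_annotation(path), "start > end")
})

test_that("a planted diverged etfA copy is recovered at twilight thresholds", {
  g <- plant_genome(contexts = "unassigned", identity = 0.7, decoys = 6,
                    seed = 503)
  hits <- find_homologs(synthetic_queries()["etfA"], g$annotation,
                        min_identity = 0.25, min_coverage = 0.5)
  expect_true(g$truth$etfA_locus %in% hits$locus_tag)
  expect_gt(max(hits$identity), 0.6)
})

test_that("neighbourhood context classification follows the priority rules", {
  ann <- toy_annotation(12)
  etf <- dplyr::bind_rows(hit("etfA", "g05"), hit("etfB", "g06"))
  case <- function(markers) {
    detect_etf_clusters(ann, etf, markers)$context
  }
  expect_equal(case(no_hits), "unassigned")
  expect_equal(case(hit("GlcD", "g04")), "GlcD")
  expect_equal(case(dplyr::bind_rows(hit("GlcD", "g04"),
                                     hit("LldP", "g03"))), "LldP_GlcD")
  expect_equal(case(hit("LldP", "g03")), "unassigned")  # permease alone
  expect_equal(case(dplyr::bind_rows(hit("3-hydroxybutyryl-CoA", "g07"),
                                     hit("acyl-CoA", "g08"))),
               "3-hydroxybutyryl-CoA")
  expect_equal(case(hit("acyl-CoA", "g08")), "acyl-CoA")
  expect_equal(case(dplyr::bind_rows(hit("GlcD", "g04"),
                                     hit("3-hydroxybutyryl-CoA", "g07"))),
               "ambiguous")
  # marker outside the +-5 gene window is ignored
  expect_equal(case(hit("GlcD", "g12")), "unassigned")
})

test_that("etf pairing allows one intervening gene and reports unpaired hits", {
  ann <- toy_annotation(12)
  # one intervening gene: still a pair
  paired <- detect_etf_clusters(ann, dplyr::bind_rows(hit("etfA", "g03"),
                                                      hit("etfB", "g05")),
                                no_hits)
  expect_equal(nrow(paired), 1L)
  # two intervening genes: no pair, both reported unpaired
  lone <- detect_etf_clusters(ann, dplyr::bind_rows(hit("etfA", "g03"),
                                                    hit("etfB", "g07")),
                              no_hits)
  expect_equal(nrow(lone), 0L)
  expect_setequal(attr(lone, "unpaired")$locus_tag, c("g03", "g07"))
  # different replicons never pair
  ann2 <- dplyr::bind_rows(toy_annotation(3, "r1"), toy_annotation(3, "r2"))
  ann2$locus_tag <- sprintf("h%02d", 1:6)
  cross <- detect_etf_clusters(ann2, dplyr::bind_rows(hit("etfA", "h03"),
                                                      hit("etfB", "h04")),
                               no_hits)
  expect_equal(nrow(cross), 0L)
})

test_that("cluster calls are invariant under reverse-complement relabeling", {
  ann <- toy_annotation(12)
  L <- 14000L
  flipped <- ann
  flipped$strand <- ifelse(ann$strand == "+", "-", "+")
  flipped$start <- L - ann$end + 1L
  flipped$end <- L - ann$start + 1L
  flipped <- flipped[order(flipped$start), ]
  etf <- dplyr::bind_rows(hit("etfA", "g05"), hit("etfB", "g06"))
  mk <- dplyr::bind_rows(hit("LldP", "g03"), hit("GlcD", "g04"))
  fwd <- detect_etf_clusters(ann, etf, mk)
  rev <- detect_etf_clusters(flipped, etf, mk)
  expect_equal(fwd$context, rev$context)
  expect_setequal(c(fwd$etfA_locus, fwd$etfB_locus),
                  c(rev$etfA_locus, rev$etfB_locus))
})

test_that("the full pipeline recovers planted cluster counts and labels", {
  for (seed in c(511, 512, 513)) {
    contexts <- list(c("GlcD", "3-hydroxybutyryl-CoA", "LldP_GlcD"),
                     "acyl-CoA",
                     c("LldP_GlcD", "acyl-CoA"))[[(seed - 511) %% 3 + 1]]
    g <- plant_genome(contexts = contexts, identity = 0.7,
                      decoys = 6 * (length(contexts) + 1), seed = seed)
    etf_hits <- find_homologs(synthetic_queries(), g$annotation)
    mk_hits <- find_homologs(synthetic_markers(), g$annotation)
    cl <- detect_etf_clusters(g$annotation, etf_hits, mk_hits)
    expect_equal(nrow(cl), length(contexts), info = paste("seed", seed))
    truth_ctx <- g$truth$context[match(cl$etfA_locus, g$truth$etfA_locus)]
    expect_equal(cl$context, truth_ctx, info = paste("seed", seed))
  }
})

test_that("decoy-only genomes yield no clusters", {
  g <- plant_genome(contexts = character(), decoys = 8, seed = 520)
  etf_hits <- find_homologs(synthetic_queries(), g$annotation)
  cl <- detect_etf_clusters(g$annotation, etf_hits, no_hits)
  expect_equal(nrow(cl), 0L)
})
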