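# Seeded generators for every input the pipeline consumes: ultrametric
# trees, protein families evolved along them, annotated replicons with
# planted etf clusters, and fermentation tables derived from known fluxes.
# All are bit-reproducible given their seed.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  code
}

#' Simulate a rooted ultrametric tree
#'
#' Pure-birth (Yule) topology rescaled so every root-to-tip path equals
#' `height`.
#'
#' @param n_tips number of tips (>= 2).
#' @param height tree height in substitutions/site.
#' @param seed integer seed (mandatory; same seed, same Newick).
#' @return an ultrametric `ape::phylo` with tips `t1..tn`.
#' @export
simulate_tree <- function(n_tips, height, seed) {
  if (n_tips < 2) stop("n_tips must be >= 2", call. = FALSE)
  stopifnot(height > 0)
  tr <- with_seed(seed, ape::rphylo(n_tips, birth = 1, death = 0))
  depths <- ape::node.depth.edgelength(tr)
  tr$edge.length <- tr$edge.length * height / max(depths)
  tr$tip.label <- paste0("t", seq_len(n_tips))
  tr
}

#' Evolve protein sequences along a tree
#'
#' 20-state equal-rates substitution, site-independent: along a branch of
#' length d each site changes with probability (19/20)(1 - exp(-(20/19) d)),
#' and a changing site picks one of the other 19 residues uniformly. No
#' indels are introduced, so site k is homologous across all tips (the true
#' column map is the identity), which is what makes generator output usable
#' as alignment ground truth.
#'
#' @param tree an `ape::phylo` with branch lengths in substitutions/site.
#' @param length sequence length (>= 1).
#' @param seed integer seed.
#' @param root optional root protein string (random if omitted).
#' @return a [protein_alignment()] of the tip sequences (gap-free), with the
#'   root sequence in attribute `root`.
#' @export
evolve_proteins <- function(tree, length, seed, root = NULL) {
  if (length < 1) stop("length must be >= 1", call. = FALSE)
  with_seed(seed, {
    if (is.null(root)) {
      root <- paste(sample(AA20, length, replace = TRUE), collapse = "")
    }
    n_tip <- length(tree$tip.label)
    n_node <- n_tip + tree$Nnode
    seqs <- vector("list", n_node)
    root_node <- n_tip + 1L
    seqs[[root_node]] <- strsplit(root, "")[[1]]
    tr <- stats::reorder(tree, "cladewise")
    for (e in seq_len(nrow(tr$edge))) {
      parent <- tr$edge[e, 1L]; child <- tr$edge[e, 2L]
      d <- tr$edge.length[e]
      p_change <- (19 / 20) * (1 - exp(-(20 / 19) * d))
      s <- seqs[[parent]]
      hit <- runif(length(s)) < p_change
      if (any(hit)) {
        s[hit] <- vapply(s[hit], function(a) sample(setdiff(AA20, a), 1L), "")
      }
      seqs[[child]] <- s
    }
    tips <- vapply(seq_len(n_tip), function(i) paste(seqs[[i]], collapse = ""),
                   "")
    out <- protein_alignment(tree$tip.label, tips)
    attr(out, "root") <- root
    out
  })
}

#' Simulate two paralogous Etf subfamilies across a set of species
#'
#' Emulates the structure behind the reaction-specific clustering claim: one
#' species tree is simulated, duplicated into two paralog families (a
#' lactate-oxidation and a butyrate-formation context), and the two family
#' roots are joined so that the duplication predates speciation by
#' `inter_divergence` substitutions/site.
#'
#' @param n_species number of species (>= 2).
#' @param intra_height height of each family subtree (substitutions/site).
#' @param inter_divergence tip-to-tip divergence between families (must
#'   exceed `2 * intra_height`).
#' @param length protein length.
#' @param seed integer seed.
#' @return list with `tree` (2 x n_species tips named `sp<i>_lac` /
#'   `sp<i>_but`), `alignment` (gap-free tip sequences), and `labels`
#'   (tibble: tip, species, context).
#' @export
simulate_two_families <- function(n_species, intra_height = 0.15,
                                  inter_divergence = 0.9, length = 300,
                                  seed = 1) {
  if (inter_divergence <= 2 * intra_height) {
    stop("inter_divergence must exceed 2 * intra_height", call. = FALSE)
  }
  sp_tree <- simulate_tree(n_species, intra_height, seed)
  fam <- function(tag) {
    t2 <- sp_tree
    t2$tip.label <- paste0("sp", seq_len(n_species), "_", tag)
    t2
  }
  stem <- (inter_divergence - 2 * intra_height) / 2
  joined <- add_root_stems(fam("lac"), fam("but"), stem)
  aln <- evolve_proteins(joined, length, seed + 1000L)
  labels <- tibble::tibble(
    tip = joined$tip.label,
    species = sub("_(lac|but)$", "", joined$tip.label),
    context = ifelse(grepl("_lac$", joined$tip.label), "GlcD",
                     "3-hydroxybutyryl-CoA")
  )
  list(tree = joined, alignment = aln, labels = labels)
}

# Join two rooted trees under a new root with a stem branch of the given
# length above each.
add_root_stems <- function(a, b, stem) {
  na <- length(a$tip.label); nb <- length(b$tip.label)
  newick_a <- sub(";$", "", ape::write.tree(a))
  newick_b <- sub(";$", "", ape::write.tree(b))
  ape::read.tree(text = sprintf("(%s:%g,%s:%g);", newick_a, stem,
                                newick_b, stem))
}

# ---------------------------------------------------------------------------
# Planted genomes

# Deterministic synthetic reference proteins for the Etf subunits and the
# neighbourhood markers. Generated from a fixed internal seed so that
# queries and planted genes always refer to the same references; never taken
# from real accessions.
reference_proteins <- function() {
  lens <- c(etfA = 330L, etfB = 260L, GlcD = 460L, LldP = 420L,
            `3-hydroxybutyryl-CoA` = 280L, `acyl-CoA` = 380L)
  with_seed(987654L, {
    vapply(lens, function(L) paste(sample(AA20, L, replace = TRUE),
                                   collapse = ""), "")
  })
}

#' Synthetic Etf query proteins
#'
#' The two synthetic reference subunits used as homology-search queries
#' against planted genomes. Purely synthetic stand-ins (random-composition
#' proteins), not real sequences.
#'
#' @return named character vector (`etfA`, `etfB`).
#' @export
synthetic_queries <- function() reference_proteins()[c("etfA", "etfB")]

#' Synthetic neighbourhood marker proteins
#'
#' Synthetic stand-ins for the context markers: the GlcD-like FAD-binding
#' oxidoreductase, the l-lactate permease LldP, 3-hydroxybutyryl-CoA
#' dehydrogenase and acyl-CoA dehydrogenase.
#'
#' @return named character vector of four marker proteins.
#' @export
synthetic_markers <- function() {
  reference_proteins()[c("GlcD", "LldP", "3-hydroxybutyryl-CoA", "acyl-CoA")]
}

# Substitute residues to reach a target fractional identity to `seq`.
mutate_to_identity <- function(seq, identity) {
  chars <- strsplit(seq, "")[[1]]
  n_mut <- round((1 - identity) * length(chars))
  if (n_mut > 0) {
    pos <- sample(length(chars), n_mut)
    chars[pos] <- vapply(chars[pos],
                         function(a) sample(setdiff(AA20, a), 1L), "")
  }
  paste(chars, collapse = "")
}

# Back-translate a protein with uniformly random synonymous codons.
back_translate <- function(protein) {
  gc <- Biostrings::GENETIC_CODE
  by_aa <- split(names(gc), unname(gc))
  chars <- strsplit(protein, "")[[1]]
  codons <- vapply(chars, function(a) {
    opts <- by_aa[[a]]
    opts[sample.int(length(opts), 1L)]
  }, "")
  paste0(paste(codons, collapse = ""), "TAA")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Plant a synthetic replicon with etfA/etfB clusters
#'
#' Generates an annotated replicon containing one etfA/etfB pair per
#' requested context, with the appropriate marker genes in the immediate
#' neighbourhood, plus unrelated decoy genes, and (optionally) writes it as
#' a GenBank flat file and a GFF3 + FASTA pair sharing one internal model.
#' Planted Etf and marker genes are derived from the synthetic references at
#' the requested identity; decoys are fresh random proteins (background
#' identity to any reference is far below search thresholds).
#'
#' @param contexts character vector of context labels to plant, one cluster
#'   each, from `"GlcD"`, `"LldP_GlcD"`, `"3-hydroxybutyryl-CoA"`,
#'   `"acyl-CoA"`, `"unassigned"` (pair with no marker).
#' @param identity identity of planted genes to their reference (0, 1].
#' @param decoys number of decoy genes between/around clusters. Real etf
#'   clusters sit in separate genome regions, so the default gives each
#'   inter-cluster gap six decoys — beyond the default +-5-gene context
#'   window. Smaller values let neighbourhoods overlap.
#' @param spacing intergenic spacing range in bp (length-2 integer).
#' @param seed integer seed (mandatory).
#' @param dir if non-`NULL`, directory to write `genome.gbk`, `genome.gff3`,
#'   `genome.fasta` and `truth.tsv` into.
#' @return list with `annotation` (gene-record tibble), `sequences` (named
#'   DNA), `truth` (tibble: cluster, etfA_locus, etfB_locus, context), and
#'   `paths` (when written).
#' @export
plant_genome <- function(contexts = c("GlcD", "3-hydroxybutyryl-CoA",
                                      "LldP_GlcD"),
                         identity = 0.7, decoys = 24,
                         spacing = c(60L, 200L), seed, dir = NULL) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(identity > 0, identity <= 1)
  refs <- reference_proteins()
  with_seed(seed, {
    context_markers <- list(
      "GlcD" = "GlcD",
      "LldP_GlcD" = c("LldP", "GlcD"),
      "3-hydroxybutyryl-CoA" = c("3-hydroxybutyryl-CoA", "acyl-CoA"),
      "acyl-CoA" = "acyl-CoA",
      "unassigned" = character()
    )
    bad <- setdiff(contexts, names(context_markers))
    if (length(bad)) stop("unknown context(s): ", paste(bad, collapse = ", "),
                          call. = FALSE)
    # plan gene list: clusters interleaved with decoys
    genes <- list()  # list of (name_prefix, protein, is_cluster, cluster_id)
    add_gene <- function(prefix, protein, cluster = NA_integer_,
                         role = "decoy") {
      genes[[length(genes) + 1L]] <<- list(prefix = prefix, protein = protein,
                                           cluster = cluster, role = role)
    }
    n_ctx <- length(contexts)
    decoys_per_gap <- diff(floor(seq(0, decoys, length.out = n_ctx + 2L)))
    add_decoys <- function(k) {
      for (i in seq_len(k)) {
        add_gene("decoy", paste(sample(AA20, sample(150:350, 1L),
                                       replace = TRUE), collapse = ""))
      }
    }
    add_decoys(decoys_per_gap[1])
    for (ci in seq_along(contexts)) {
      ctx <- contexts[ci]
      for (mk in context_markers[[ctx]]) {
        add_gene(mk, mutate_to_identity(refs[[mk]], identity), ci, "marker")
      }
      add_gene("etfA", mutate_to_identity(refs[["etfA"]], identity), ci,
               "etfA")
      add_gene("etfB", mutate_to_identity(refs[["etfB"]], identity), ci,
               "etfB")
      add_decoys(decoys_per_gap[ci + 1L])
    }
    # lay genes along the replicon
    pos <- sample(spacing[1]:spacing[2], 1L)
    rows <- list()
    dna_parts <- list(random_dna(pos))
    for (gi in seq_along(genes)) {
      g <- genes[[gi]]
      cds <- back_translate(g$protein)
      strand <- sample(c("+", "-"), 1L)
      dna <- if (strand == "-") {
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
      } else {
        cds
      }
      start <- pos + 1L
      end <- pos + nchar(dna)
      rows[[gi]] <- tibble::tibble(
        locus_tag = sprintf("SYN_%04d", gi * 5L),
        replicon_id = "synrep1",
        start = start, end = end, strand = strand,
        product = sprintf("%s%s", g$prefix,
                          if (g$role == "decoy") " hypothetical protein"
                          else " synthetic reference homolog"),
        protein = g$protein,
        role = g$role, cluster = g$cluster
      )
      gap <- sample(spacing[1]:spacing[2], 1L)
      dna_parts[[length(dna_parts) + 1L]] <- dna
      dna_parts[[length(dna_parts) + 1L]] <- random_dna(gap)
      pos <- end + gap
    }
    ann_full <- dplyr::bind_rows(rows)
    sequences <- c(synrep1 = paste(unlist(dna_parts), collapse = ""))
    truth <- if (length(contexts)) {
      ann_full %>%
        dplyr::filter(.data$role %in% c("etfA", "etfB")) %>%
        dplyr::select("cluster", "role", "locus_tag") %>%
        tidyr::pivot_wider(names_from = "role", values_from = "locus_tag") %>%
        dplyr::mutate(context = contexts[.data$cluster]) %>%
        dplyr::rename(etfA_locus = "etfA", etfB_locus = "etfB")
    } else {
      tibble::tibble(cluster = integer(), etfA_locus = character(),
                     etfB_locus = character(), context = character())
    }
    annotation <- ann_full %>% dplyr::select(-"role", -"cluster")
    attr(annotation, "replicon_length") <-
      c(synrep1 = nchar(sequences[["synrep1"]]))
    out <- list(annotation = annotation, sequences = sequences, truth = truth)
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      paths <- list(
        genbank = file.path(dir, "genome.gbk"),
        gff3 = file.path(dir, "genome.gff3"),
        fasta = file.path(dir, "genome.fasta"),
        truth = file.path(dir, "truth.tsv")
      )
      write_genbank(annotation, sequences, paths$genbank)
      write_gff3(annotation, sequences, paths$gff3, paths$fasta)
      utils::write.table(truth, paths$truth, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      out$paths <- paths
    }
    out
  })
}

# ---------------------------------------------------------------------------
# Fermentation tables

#' Default starting medium for simulated fermentations
#'
#' Sodium lactate 7.41 g/L, sodium acetate 7 g/L, plus the yeast-extract
#' background butyrate (4.6 mM) and propionate (1 mM).
#'
#' @param registry metabolite registry.
#' @return named numeric vector of mM concentrations.
#' @export
default_medium <- function(registry = metabolite_registry()) {
  c(lactate = 7.41 / 112.06 * 1000,
    acetate = 7.00 / 82.03 * 1000,
    butyrate = 4.6,
    propionate = 1.0,
    ethanol = 0)
}

#' A flux vector with the published net proportions
#'
#' Returns the pathway flux (mmol basis) whose exchange footprint has the
#' canonical carbon proportions — per 200 mmol C of lactate: 100 acetate
#' consumed, 170 butyrate and 30 ethanol formed, the remainder to CO2 and
#' biomass — scaled so that `lactate_mmol` millimoles of lactate are
#' consumed.
#'
#' @param lactate_mmol lactate consumption in mmol (molecules, not carbon).
#' @return named numeric flux vector over [reaction_network()] reactions.
#' @export
example_flux <- function(lactate_mmol = 1) {
  base <- c(
    LDH_EtfAB = 200 / 3, PFOR = 200 / 3,
    thiolase = 42.5, HBD = 42.5, crotonase = 42.5, BCD_EtfAB = 42.5,
    PTB_BUK = 0, CoA_transferase = 42.5,
    acetate_kinase = 0, acetate_uptake = 7.5,
    ADHE = 15, hydrogenase = 55 / 3, Fd_NAD_oxidoreductase = 145 / 6,
    ATP_synthase = 145 / 6, ATP_hydrolysis = 0,
    biomass_sink = 50 / 3, biomass_e_uptake = 0, biomass_e_release = 0
  )
  base * lactate_mmol / (200 / 3)
}

#' Simulate a fermentation concentration table from a known flux
#'
#' Applies the network's exchange footprint S v to a starting medium and
#' emits a before/after concentration table in mM, with multiplicative
#' lognormal measurement noise of the given coefficient of variation on
#' every measured value.
#'
#' @param flux named flux vector (mmol per litre of culture).
#' @param network a [reaction_network()].
#' @param before named starting concentrations in mM (default
#'   [default_medium()]).
#' @param noise_cv coefficient of variation of measurement noise (>= 0).
#' @param seed integer seed.
#' @return a concentration table tibble (`metabolite`, `phase`, `value`,
#'   `unit = "mM"`, `form = "acid"`), with the noise-free truth in attribute
#'   `truth`.
#' @export
simulate_fermentation <- function(flux, network = reaction_network(),
                                  before = default_medium(),
                                  noise_cv = 0.05, seed = 1) {
  stopifnot(noise_cv >= 0)
  v <- setNames(rep(0, ncol(network$S)), colnames(network$S))
  v[names(flux)] <- flux
  net <- drop(network$S %*% v)
  measured <- names(before)
  after <- before + ifelse(measured %in% names(net), net[measured], 0)
  if (any(after < -1e-9)) {
    stop("flux drives concentration negative for: ",
         paste(measured[after < -1e-9], collapse = ", "), call. = FALSE)
  }
  after <- pmax(after, 0)
  truth <- tibble::tibble(metabolite = measured, before = unname(before),
                          after = unname(after),
                          net = unname(after - before))
  tab <- tibble::tibble(
    metabolite = rep(measured, 2L),
    phase = rep(c("before", "after"), each = length(measured)),
    value = c(unname(before), unname(after)),
    unit = "mM", form = "acid"
  )
  if (noise_cv > 0) {
    with_seed(seed, {
      sigma <- sqrt(log(1 + noise_cv^2))
      tab$value <- tab$value * exp(rnorm(nrow(tab), -sigma^2 / 2, sigma))
    })
  }
  attr(tab, "truth") <- truth
  tab
}
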