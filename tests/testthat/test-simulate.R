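test_that("simulated trees are ultrametric, sized, and seed-stable", {
  t2 <- simulate_tree(2, 0.7, 601)
  expect_equal(ape::cophenetic.phylo(t2)["t1", "t2"], 1.4)
  t16 <- simulate_tree(16, 0.5, 602)
  expect_true(ape::is.ultrametric(t16, tol = 1e-9))
  expect_equal(max(ape::node.depth.edgelength(t16)), 0.5)
  expect_identical(ape::write.tree(simulate_tree(9, 0.3, 603)),
                   ape::write.tree(simulate_tree(9, 0.3, 603)))
  expect_error(simulate_tree(1, 0.5, 604), "n_tips")
})

test_that("zero-length branches copy the parent sequence unchanged", {
  tr <- ape::read.tree(text = "(a:0,b:0.4);")
  aln <- evolve_proteins(tr, 60, 611)
  seqs <- setNames(aln$sequence, aln$label)
  expect_equal(seqs[["a"]], attr(aln, "root"))
})

test_that("empirical substitution fractions match the 20-state closed form", {
  d <- 0.5
  tr <- ape::read.tree(text = sprintf("(a:%g,b:0);", d))
  L <- 10000
  aln <- evolve_proteins(tr, L, 612)
  m <- alignment_matrix(aln)
  p_hat <- mean(m[1, ] != m[2, ])
  p_exp <- (19 / 20) * (1 - exp(-(20 / 19) * d))
  se <- sqrt(p_exp * (1 - p_exp) / L)
  expect_lt(abs(p_hat - p_exp), 3 * se)
})

test_that("two-family simulations order within/between distances correctly", {
  tf <- simulate_two_families(4, intra_height = 0.1, inter_divergence = 0.8,
                              length = 250, seed = 613)
  d <- distance_matrix(tf$alignment)
  fam <- ifelse(grepl("_lac$", rownames(d)), "lac", "but")
  within <- d[outer(fam, fam, "==") & upper.tri(d)]
  between <- d[outer(fam, fam, "!=") & upper.tri(d)]
  expect_lt(max(within), min(between))
})

test_that("planted genomes are self-consistent with their truth tables", {
  g <- plant_genome(contexts = c("GlcD", "acyl-CoA"), decoys = 12,
                    seed = 621, dir = tempfile())
  reread <- read_annotation(g$paths$genbank)
  expect_true(all(g$truth$etfA_locus %in% reread$locus_tag))
  expect_true(all(g$truth$etfB_locus %in% reread$locus_tag))
  truth_file <- utils::read.delim(g$paths$truth)
  expect_equal(truth_file$context, g$truth$context)
  # reproducibility
  g2 <- plant_genome(contexts = c("GlcD", "acyl-CoA"), decoys = 12,
                     seed = 621)
  expect_identical(g$sequences, g2$sequences)
  expect_identical(g$annotation$protein, g2$annotation$protein)
})

test_that("noise-free fermentation tables recover the generating net exactly", {
  net <- reaction_network()
  flux <- example_flux(60)
  tab <- simulate_fermentation(flux, noise_cv = 0, seed = 631)
  truth <- attr(tab, "truth")
  achieved <- drop(net$S[, names(flux)] %*% flux)
  for (met in c("lactate", "acetate", "butyrate", "ethanol")) {
    expect_equal(truth$net[truth$metabolite == met], achieved[[met]],
                 info = met)
  }
  cb <- carbon_balance(tab)
  reg <- metabolite_registry()
  for (met in c("lactate", "butyrate", "ethanol")) {
    nC <- reg$nC[reg$name == met]
    expect_equal(cb$fluxes$net[cb$fluxes$metabolite == met],
                 achieved[[met]] * nC, tolerance = 1e-9, info = met)
  }
})

test_that("zero flux leaves the medium unchanged", {
  tab <- simulate_fermentation(c(LDH_EtfAB = 0), noise_cv = 0, seed = 632)
  wide <- tidyr::pivot_wider(tab[, c("metabolite", "phase", "value")],
                             names_from = "phase", values_from = "value")
  expect_equal(wide$before, wide$after)
})

test_that("fluxes that overdraw the medium are rejected by name", {
  expect_error(simulate_fermentation(example_flux(500), noise_cv = 0,
                                     seed = 633),
               "lactate")
})

test_that("fermentation noise is seed-stable and lognormal-multiplicative", {
  t1 <- simulate_fermentation(example_flux(50), noise_cv = 0.05, seed = 640)
  t2 <- simulate_fermentation(example_flux(50), noise_cv = 0.05, seed = 640)
  expect_identical(t1$value, t2$value)
  t3 <- simulate_fermentation(example_flux(50), noise_cv = 0.05, seed = 641)
  expect_false(identical(t1$value, t3$value))
  expect_true(all(t1$value >= 0))
})
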