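# Synthetic genome generator: planted truth, determinism, evolution model.

test_that("truth table covers every generated gene exactly once", {
  spec <- synthetic_genome_spec(n_genomes = 4, n_core = 5,
                                n_dup_families = 2, n_accessory = 3,
                                protein_length = 70, rng_seed = 81)
  fx <- generate_genomes(spec)
  all_genes <- unlist(lapply(fx$genomes, function(g)
    qualified_id(g$genome_id, g$sequences$locus_id)))
  expect_setequal(fx$truth$qualified_id, all_genes)
  expect_identical(anyDuplicated(fx$truth$qualified_id), 0L)
  # per-genome composition: core everywhere; the host genome of each
  # duplicated family carries the extra copies
  core_per_genome <- table(fx$truth$genome_id[fx$truth$class == "CORE"])
  expect_true(all(core_per_genome == spec$n_core))
  dup_counts <- table(fx$truth$genome_id[fx$truth$class == "DUP"],
                      fx$truth$family[fx$truth$class == "DUP"])
  expect_true(all(colSums(dup_counts == 2) == 1))  # one host per family
  # accessory genes live in strict subsets
  acc <- table(fx$truth$family[fx$truth$class == "ACCESSORY"])
  expect_true(all(acc >= 1 & acc < spec$n_genomes))
})

test_that("generation is byte-deterministic in the seed, including written files", {
  spec <- synthetic_genome_spec(n_genomes = 3, n_core = 4,
                                n_dup_families = 1, n_accessory = 1,
                                protein_length = 60, rng_seed = 82)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_genomes(spec, out_dir = d1, format = "genbank")
  generate_genomes(spec, out_dir = d2, format = "genbank")
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6),
                     label = f)
  }
  # a different seed changes the content
  spec2 <- synthetic_genome_spec(n_genomes = 3, n_core = 4,
                                 n_dup_families = 1, n_accessory = 1,
                                 protein_length = 60, rng_seed = 83)
  fx1 <- generate_genomes(spec)
  fx2 <- generate_genomes(spec2)
  expect_false(identical(fx1$genomes$g01$sequences$protein,
                         fx2$genomes$g01$sequences$protein))
})

test_that("zero branch lengths give identical orthologues in every genome", {
  tr <- ape::rtree(4, tip.label = sprintf("g%02d", 1:4))
  tr$edge.length <- rep(0, nrow(tr$edge))
  spec <- synthetic_genome_spec(n_genomes = 4, n_core = 3,
                                n_dup_families = 0, n_accessory = 0,
                                protein_length = 60, tree = tr,
                                rng_seed = 84)
  fx <- generate_genomes(spec)
  for (fam in unique(fx$truth$family)) {
    rows <- fx$truth[fx$truth$family == fam, ]
    seqs <- mapply(function(g, l)
      fx$genomes[[g]]$sequences$protein[
        match(l, fx$genomes[[g]]$sequences$locus_id)],
      rows$genome_id, rows$locus_id)
    expect_length(unique(seqs), 1L)
  }
})

test_that("tip-to-tip mismatch matches the closed form of the substitution process", {
  # two tips joined by branches b1, b2: per-site mismatch probability is
  # (19/20) * (1 - prod((20*exp(-b) - 1)/19)) exactly under this process
  tr <- ape::read.tree(text = "(t1:0.15,t2:0.25);")
  aln <- simulate_alignment(tr, 10000, rng_seed = 85)
  rows <- strsplit(unname(aln$rows), "")
  p_obs <- mean(rows[[1]] != rows[[2]])
  alpha <- function(b) (20 * exp(-b) - 1) / 19
  p_exp <- (19 / 20) * (1 - alpha(0.15) * alpha(0.25))
  se <- sqrt(p_exp * (1 - p_exp) / 10000)
  expect_lt(abs(p_obs - p_exp), 3 * se)
})

test_that("NJ on a caterpillar-tree simulation recovers the topology", {
  tips <- paste0("t", 1:8)
  nwk <- "(((((((t1:.1,t2:.1):.3,t3:.1):.3,t4:.1):.3,t5:.1):.3,t6:.1):.3,t7:.1):.3,t8:.1);"
  truth <- ape::read.tree(text = nwk)
  aln <- simulate_alignment(truth, 2000, rng_seed = 86)
  rec <- build_tree(aln, method = "nj")
  expect_identical(robinson_foulds(rec, truth)$rf, 0L)
  expect_setequal(rec$tip.label, tips)
})

test_that("indel-enabled simulation still yields parseable, screenable genomes", {
  spec <- synthetic_genome_spec(n_genomes = 3, n_core = 3,
                                n_dup_families = 0, n_accessory = 0,
                                protein_length = 80, indel_rate = 0.02,
                                rng_seed = 87)
  fx <- generate_genomes(spec)
  lens <- unlist(lapply(fx$genomes, function(g) nchar(g$sequences$protein)))
  expect_false(all(lens == 80))  # indels actually happened
  dbs <- lapply(fx$genomes, build_database)
  sel <- select_loci(screen_loci(find_singletons(dbs$g01), fx$genomes, dbs))
  expect_length(sel$loci, 3L)
})

test_that("the unrelatedness self-test leaves no detectable cross-family similarity", {
  spec <- synthetic_genome_spec(n_genomes = 4, n_core = 8,
                                n_dup_families = 2, n_accessory = 2,
                                protein_length = 80, rng_seed = 88)
  fx <- generate_genomes(spec)
  fam <- setNames(fx$truth$family, fx$truth$qualified_id)
  dbs <- lapply(fx$genomes, build_database)
  for (g in names(fx$genomes)) {
    rec <- fx$genomes[[g]]
    for (i in seq_len(n_sequences(rec))) {
      q <- get_sequence(rec, rec$sequences$locus_id[i])
      for (g2 in names(dbs)) {
        h <- search_hits(q, dbs[[g2]])
        hit_fams <- fam[h$subject_id]
        expect_true(all(hit_fams == fam[[qualified_id(g, q$locus_id)]] |
                          h$evalue > 1e-3),
                    label = paste("no cross-family hit for", q$locus_id))
      }
    }
  }
})

test_that("invalid specifications are rejected up front", {
  expect_error(synthetic_genome_spec(n_genomes = 1), "n_genomes")
  expect_error(synthetic_genome_spec(divergence = 0), "divergence")
  expect_error(synthetic_genome_spec(tree = "newick"), "phylo")
  tr <- ape::rtree(3)
  expect_error(synthetic_genome_spec(n_genomes = 5, tree = tr), "tips")
  tr0 <- ape::rtree(5); tr0$edge.length <- NULL
  expect_error(synthetic_genome_spec(n_genomes = 5, tree = tr0),
               "branch lengths")
  expect_error(simulate_alignment(ape::rtree(4), 0), "positive")
})
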