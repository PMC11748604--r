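# Per-locus alignment and supermatrix concatenation.

test_that("internal aligner handles identity and single-gap cases", {
  a <- align_locus(c(g1 = "MKT", g2 = "MKT"), locus_id = "id")
  expect_identical(unname(a$rows), c("MKT", "MKT"))
  expect_identical(a$length, 3L)
  b <- align_locus(c(g1 = "MKT", g2 = "MT"), locus_id = "gap")
  expect_identical(b$length, 3L)
  expect_identical(gsub("-", "", b$rows[["g2"]]), "MT")
  expect_identical(b$rows[["g1"]], "MKT")
})

test_that("ungapping aligned rows always reproduces the inputs", {
  set.seed(51)
  for (rep in 1:6) {
    n <- sample(3:6, 1)
    base <- rand_protein(sample(60:120, 1))
    seqs <- setNames(vapply(seq_len(n), function(i) {
      s <- mutate_protein(base, runif(1, 0.05, 0.3))
      # random indel damage
      r <- strsplit(s, "")[[1]]
      drop <- sample(length(r), sample(0:5, 1))
      if (length(drop)) r <- r[-drop]
      paste(r, collapse = "")
    }, ""), sprintf("g%02d", seq_len(n)))
    a <- align_locus(seqs, locus_id = "x")
    expect_identical(gsub("-", "", a$rows[names(seqs)]), seqs)
    expect_length(unique(nchar(a$rows)), 1L)
  }
})

test_that("substitution-only fixtures align gap-free at the original length", {
  spec <- synthetic_genome_spec(n_genomes = 5, n_core = 3,
                                n_dup_families = 0, n_accessory = 0,
                                protein_length = 80, indel_rate = 0,
                                rng_seed = 52)
  fx <- generate_genomes(spec)
  prots <- vapply(fx$genomes, function(g) g$sequences$protein[1], "")
  a <- align_locus(prots, locus_id = "core_001")
  expect_identical(a$length, 80L)
  expect_false(any(grepl("-", a$rows, fixed = TRUE)))
})

test_that("align_locus rejects degenerate inputs", {
  expect_error(align_locus(c(g1 = "MKT"), locus_id = "solo"),
               "single-sequence.*solo")
  expect_error(align_locus(c("MKT", "MKT")), "names")
  expect_error(align_locus(setNames(c("MKT", "MR"), c("a", "a"))), "unique")
})

test_that("gather_locus labels records by genome and reports missing members", {
  spec <- synthetic_genome_spec(n_genomes = 4, n_core = 3,
                                n_dup_families = 0, n_accessory = 0,
                                protein_length = 60, rng_seed = 53)
  fx <- generate_genomes(spec)
  dbs <- lapply(fx$genomes, build_database)
  sel <- select_loci(screen_loci(find_singletons(dbs$g01), fx$genomes, dbs))
  locus <- sel$loci[1]
  seqs <- gather_locus(sel, locus, fx$genomes)
  expect_identical(names(seqs), sort(names(fx$genomes)))
  expect_error(gather_locus(sel, "g01|nope", fx$genomes), "not in selection")
  expect_error(gather_locus(sel, locus, fx$genomes["g01"]), "missing")
})

test_that("concatenation tiles partitions exactly and fills missing genomes with gaps", {
  a1 <- locus_alignment("L1", c(g1 = strrep("A", 10), g2 = strrep("C", 10),
                                g3 = strrep("D", 10), g4 = strrep("E", 10)))
  a2 <- locus_alignment("L2", c(g1 = strrep("K", 15), g2 = strrep("M", 15),
                                g3 = strrep("N", 15)))
  sm <- concatenate_alignments(list(a2, a1), c("g1", "g2", "g3", "g4"))
  expect_identical(sm$length, 25L)
  expect_identical(sm$partitions$locus_id, c("L1", "L2"))  # sorted
  expect_identical(sm$partitions$start, c(1L, 11L))
  expect_identical(sm$partitions$end, c(10L, 25L))
  expect_identical(sm$rows[["g4"]], paste0(strrep("E", 10), strrep("-", 15)))
  # single locus: supermatrix is that alignment
  sm1 <- concatenate_alignments(list(a1), names(a1$rows))
  expect_identical(sm1$rows, a1$rows)
  expect_identical(sm1$partitions$end, 10L)
  expect_error(concatenate_alignments(list(a1, a1), names(a1$rows)),
               "duplicate")
})

test_that("partition tiling and slice round-trip hold on pipeline-built supermatrices", {
  spec <- synthetic_genome_spec(n_genomes = 5, n_core = 4,
                                n_dup_families = 1, n_accessory = 2,
                                protein_length = 60, rng_seed = 54)
  fx <- generate_genomes(spec)
  dbs <- lapply(fx$genomes, build_database)
  pm <- screen_loci(find_singletons(dbs$g01), fx$genomes, dbs)
  # presence 60: accessory loci with partial presence can join, forcing
  # gap-filled rows
  sel <- select_loci(pm, presence_threshold = 60)
  alns <- lapply(sel$loci, function(l)
    align_locus(gather_locus(sel, l, fx$genomes), locus_id = l))
  sm <- concatenate_alignments(alns, names(fx$genomes))
  p <- sm$partitions
  expect_identical(p$start[1], 1L)
  expect_identical(p$end[nrow(p)], sm$length)
  if (nrow(p) > 1) expect_identical(p$start[-1], head(p$end, -1) + 1L)
  expect_identical(sm$length, sum(p$end - p$start + 1L))
  for (i in seq_len(nrow(p))) {
    locus <- p$locus_id[i]
    members <- sel$members[[locus]]
    for (g in names(sm$rows)) {
      slice <- substr(sm$rows[[g]], p$start[i], p$end[i])
      if (g %in% names(members)) {
        parts <- split_qualified_id(members[[g]])
        orig <- fx$genomes[[g]]$sequences$protein[
          match(parts$locus_id, fx$genomes[[g]]$sequences$locus_id)]
        expect_identical(gsub("-", "", slice), orig)
      } else {
        expect_identical(slice, strrep("-", p$end[i] - p$start[i] + 1L))
      }
    }
  }
})

test_that("supermatrix files are byte-stable across writes", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  a1 <- locus_alignment("L1", c(g1 = "MKT-A", g2 = "MKTCA"))
  a2 <- locus_alignment("L2", c(g1 = "WWWW", g2 = "WW-W"))
  sm <- concatenate_alignments(list(a1, a2), c("g1", "g2"))
  f1 <- write_supermatrix(sm, d1)
  f2 <- write_supermatrix(sm, d2)
  for (k in names(f1))
    expect_identical(readBin(f1[[k]], "raw", 1e5), readBin(f2[[k]], "raw", 1e5))
  expect_identical(readLines(f1[["partitions"]]),
                   c("PROT, L1 = 1-5", "PROT, L2 = 6-9"))
  expect_true(any(grepl("charset", readLines(f1[["nexus"]]))))
})

test_that("the mafft adapter satisfies the alignment contract", {
  set.seed(55)
  base <- rand_protein(90)
  seqs <- setNames(vapply(1:4, function(i) mutate_protein(base, 0.15), ""),
                   sprintf("g%02d", 1:4))
  a <- align_locus(seqs, aligner = "mafft", locus_id = "ext")
  expect_identical(sort(names(a$rows)), names(seqs))
  expect_identical(gsub("-", "", a$rows[names(seqs)]), seqs)
})
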