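# Singleton discovery, cross-genome screening and locus selection.

test_that("find_singletons matches hand-built cases", {
  set.seed(41)
  # all mutually unrelated -> everything is a singleton
  g <- genome_record("g", c("A", "B", "C"),
                     vapply(1:3, function(i) rand_protein(100), ""))
  expect_identical(find_singletons(build_database(g)),
                   c("g|A", "g|B", "g|C"))
  # an identical duplicate pair is excluded
  p <- rand_protein(100)
  g2 <- genome_record("g", c("A", "Adup", "B"), c(p, p, rand_protein(100)))
  expect_identical(find_singletons(build_database(g2)), "g|B")
})

test_that("find_singletons equals the exhaustive all-pairs oracle with planted duplicate pairs", {
  set.seed(42)
  for (rep in 1:5) {
    prots <- setNames(vapply(1:10, function(i) rand_protein(80), ""),
                      sprintf("L%02d", 1:10))
    prots[2] <- mutate_protein(prots[[1]], 0.05)   # pair 1
    prots[4] <- mutate_protein(prots[[3]], 0.05)   # pair 2
    db <- build_database(genome_record("g", names(prots), prots))
    mine <- sub("^g\\|", "", find_singletons(db))
    expect_identical(mine, oracle_singletons(prots))
  }
})

test_that("screen_loci classifies planted core, duplicated and accessory loci correctly", {
  spec <- synthetic_genome_spec(n_genomes = 4, n_core = 5,
                                n_dup_families = 2, n_accessory = 3,
                                protein_length = 70, rng_seed = 43)
  fx <- generate_genomes(spec)
  dbs <- lapply(fx$genomes, build_database)
  sing <- find_singletons(dbs$g01)
  pm <- screen_loci(sing, fx$genomes, dbs)
  cls <- setNames(fx$truth$class, fx$truth$qualified_id)
  fam <- setNames(fx$truth$family, fx$truth$qualified_id)
  for (locus in rownames(pm$status)) {
    row <- pm$status[locus, ]
    if (cls[[locus]] == "CORE") {
      expect_true(all(row == "S"), label = paste(locus, "all-SINGLETON"))
    } else if (cls[[locus]] == "DUP") {
      # singletons of a duplicated family exist only for families hosted
      # elsewhere; the host genome must show MULTI
      expect_true(any(row == "M"), label = paste(locus, "has MULTI"))
    } else {
      expect_true(any(row == "A"), label = paste(locus, "has ABSENT"))
      expect_false(any(row == "M"))
    }
  }
  # best_match recorded exactly where status is SINGLETON
  expect_identical(is.na(pm$best_match), pm$status != "S")
})

test_that("every selected locus is a reciprocal best hit in every member genome", {
  spec <- synthetic_genome_spec(n_genomes = 4, n_core = 4,
                                n_dup_families = 1, n_accessory = 1,
                                protein_length = 70, rng_seed = 44)
  fx <- generate_genomes(spec)
  dbs <- lapply(fx$genomes, build_database)
  pm <- screen_loci(find_singletons(dbs$g01), fx$genomes, dbs)
  sel <- select_loci(pm)
  for (locus in sel$loci) {
    for (g in names(sel$members[[locus]])) {
      subj <- sel$members[[locus]][[g]]
      parts <- split_qualified_id(subj)
      rev <- search_hits(get_sequence(fx$genomes[[parts$genome_id]],
                                      parts$locus_id), dbs$g01)
      expect_identical(rev$subject_id[1], locus)
    }
  }
})

test_that("screen_loci validates its configuration", {
  spec <- synthetic_genome_spec(n_genomes = 3, n_core = 3,
                                n_dup_families = 0, n_accessory = 0,
                                protein_length = 60, rng_seed = 45)
  fx <- generate_genomes(spec)
  dbs <- lapply(fx$genomes, build_database)
  sing <- find_singletons(dbs$g01)
  expect_error(screen_loci(sing, fx$genomes, dbs[c("g02", "g03")]),
               "seed genome")
  expect_error(screen_loci(character(0), fx$genomes, dbs), "no singletons")
  expect_error(screen_loci(c("g01|x", "g02|y"), fx$genomes, dbs),
               "one seed genome")
})

test_that("select_loci applies the ceil(presence) rule with ties toward inclusion", {
  gids <- sprintf("g%02d", 1:10)
  status <- matrix("S", 1, 10, dimnames = list("g01|L1", gids))
  status[, c("g09", "g10")] <- "A"   # SINGLETON in 8 of 10
  pm <- make_pm(status)
  expect_identical(select_loci(pm, presence_threshold = 80)$loci, "g01|L1")
  expect_error(select_loci(pm, presence_threshold = 90), "no loci")
})

test_that("a single MULTI cell disqualifies a locus at any presence threshold", {
  gids <- sprintf("g%02d", 1:5)
  status <- matrix("S", 2, 5, dimnames = list(c("g01|A", "g01|B"), gids))
  status["g01|B", "g03"] <- "M"
  pm <- make_pm(status)
  expect_identical(select_loci(pm, presence_threshold = 20)$loci, "g01|A")
})

test_that("maxloci truncates lexicographically, or by seeded sample when a seed is given", {
  gids <- c("g01", "g02", "g03")
  loci <- paste0("g01|L", sprintf("%02d", 1:8))
  status <- matrix("S", 8, 3, dimnames = list(loci, gids))
  pm <- make_pm(status)
  expect_identical(select_loci(pm)$loci, loci)
  expect_identical(select_loci(pm, maxloci = 3)$loci, loci[1:3])
  s1 <- select_loci(pm, maxloci = 4, rng_seed = 99)$loci
  s2 <- select_loci(pm, maxloci = 4, rng_seed = 99)$loci
  expect_identical(s1, s2)
  expect_identical(s1, sort(s1))  # ordering stays lexicographic
  expect_length(s1, 4L)
  # maxloci above availability is a no-op
  expect_length(select_loci(pm, maxloci = 100)$loci, 8L)
})

test_that("lowering the presence threshold never loses loci (monotonicity)", {
  set.seed(46)
  for (rep in 1:20) {
    ng <- sample(4:8, 1)
    nl <- sample(5:15, 1)
    status <- matrix(sample(c("S", "M", "A"), ng * nl, replace = TRUE,
                            prob = c(0.7, 0.1, 0.2)),
                     nl, ng,
                     dimnames = list(paste0("g01|L", sprintf("%02d", 1:nl)),
                                     sprintf("g%02d", seq_len(ng))))
    status[, 1] <- "S"
    pm <- make_pm(status)
    counts <- vapply(c(100, 80, 60, 40, 20), function(p) {
      tryCatch(length(select_loci(pm, presence_threshold = p)$loci),
               error = function(e) 0L)
    }, 0L)
    expect_true(all(diff(counts) >= 0))
  }
})

test_that("the presence matrix audit report is written and re-readable", {
  d <- withr::local_tempdir()
  gids <- c("g01", "g02")
  status <- matrix(c("S", "S", "M", "A"), 2, 2,
                   dimnames = list(c("g01|A", "g01|B"), gids))
  bm <- matrix(c("g01|A", "g01|B", NA, NA), 2, 2,
               dimnames = dimnames(status))
  pm <- make_pm(status, bm)
  p <- write_presence_matrix(pm, file.path(d, "pm.tsv"))
  tab <- read.delim(p, check.names = FALSE)
  expect_identical(tab$locus, c("g01|A", "g01|B"))
  expect_identical(tab$g01, c("S:g01|A", "S:g01|B"))
  expect_identical(tab$g02, c("M", "A"))
})
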