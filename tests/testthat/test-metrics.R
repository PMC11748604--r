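# Evaluation statistics: informative sites, support summaries, RF, NSUMRF.

test_that("count_informative_sites matches hand-counted and degenerate cases", {
  # columns: AAAA | CCTT | GGGC | TAAA -> only column 2 is informative
  aln <- locus_alignment("w", c(r1 = "ACGT", r2 = "ACGA",
                                r3 = "ATGA", r4 = "ATCA"))
  expect_identical(count_informative_sites(aln), 1L)
  expect_identical(count_informative_sites(
    locus_alignment("i", c(a = "MKT", b = "MKT", c = "MKT"))), 0L)
  # two rows can never produce an informative column
  set.seed(71)
  two <- c(a = rand_protein(200), b = rand_protein(200))
  expect_identical(count_informative_sites(locus_alignment("t", two)), 0L)
  # gaps and X are not states
  gx <- locus_alignment("g", c(a = "AX-", b = "AX-", c = "CXA", d = "CXA"))
  expect_identical(count_informative_sites(gx), 1L)
})

test_that("informative-site counts are column-additive over concatenation", {
  set.seed(72)
  for (rep in 1:5) {
    gids <- sprintf("g%02d", 1:5)
    alns <- lapply(1:3, function(k) {
      base <- rand_protein(40)
      locus_alignment(paste0("L", k),
                      setNames(vapply(gids, function(g)
                        mutate_protein(base, 0.3), ""), gids))
    })
    sm <- concatenate_alignments(alns, gids)
    expect_identical(count_informative_sites(sm),
                     sum(vapply(alns, count_informative_sites, 0L)))
  }
})

test_that("summarize_support computes mean and fraction-at-maximum, rescaling percent scales", {
  tr <- ape::read.tree(text = "((A:1,B:1)1.0:1,(C:1,D:1)1.0:1,(E:1,F:1)0.5:1);")
  s <- summarize_support(tr)
  expect_equal(s$mean_support, mean(c(1, 1, 0.5)))
  expect_equal(s$fraction_max, 100 * 2 / 3, tolerance = 1e-10)
  expect_identical(s$n_internal, 3L)
  pct <- ape::read.tree(text = "((A:1,B:1)100:1,(C:1,D:1)100:1,(E:1,F:1)50:1);")
  expect_equal(summarize_support(pct)$mean_support, mean(c(1, 1, 0.5)))
  expect_equal(summarize_support(pct)$fraction_max, 100 * 2 / 3,
               tolerance = 1e-10)
  all1 <- ape::read.tree(text = "((A:1,B:1)1.0:1,C:1,(D:1,E:1)1.0:1);")
  expect_equal(summarize_support(all1)$fraction_max, 100)
  bare <- ape::read.tree(text = "((A,B),C,(D,E));")
  expect_error(summarize_support(bare), "support")
})

test_that("summarize_support agrees with an independent re-parse of a fasttree newick", {
  set.seed(73)
  truth <- ape::rtree(10)
  truth$edge.length <- runif(nrow(truth$edge), 0.1, 0.4)
  aln <- simulate_alignment(truth, 600, rng_seed = 74)
  tr <- build_tree(aln, method = "fasttree")
  s <- summarize_support(tr)
  # independent recomputation straight from the newick text
  nwk <- ape::write.tree(tr)
  labs <- regmatches(nwk, gregexpr("\\)([0-9.]+)", nwk))[[1]]
  sup <- as.numeric(sub("^\\)", "", labs))
  expect_identical(s$n_internal, length(sup))
  expect_equal(s$mean_support, mean(sup), tolerance = 1e-9)
  expect_equal(s$fraction_max, 100 * mean(sup == 1), tolerance = 1e-9)
})

test_that("robinson_foulds matches the worked 5-taxon example and self-distance", {
  a <- ape::read.tree(text = "((A,B),C,(D,E));")
  b <- ape::read.tree(text = "((A,C),B,(D,E));")
  r <- robinson_foulds(a, b)
  expect_identical(r$rf, 2L)
  expect_identical(r$max_rf, 4L)
  expect_equal(r$normalized, 0.5)
  self <- robinson_foulds(a, a)
  expect_identical(self$rf, 0L)
  expect_equal(self$normalized, 0)
})

test_that("robinson_foulds equals brute-force enumeration and phangorn on random trees", {
  set.seed(75)
  for (rep in 1:40) {
    t1 <- ape::rtree(6)
    t2 <- ape::rtree(6)
    r <- robinson_foulds(t1, t2)
    expect_identical(r$rf, oracle_rf(t1, t2))
    expect_identical(r$rf,
                     as.integer(phangorn::RF.dist(ape::unroot(t1),
                                                  ape::unroot(t2))))
    expect_identical(r$rf %% 2L, 0L)
    expect_gte(r$normalized, 0)
    expect_lte(r$normalized, 1)
    # symmetry
    expect_identical(robinson_foulds(t2, t1)$rf, r$rf)
  }
})

test_that("robinson_foulds restricts to shared tips and enforces the minimum", {
  t1 <- ape::rtree(8)
  t2 <- ape::keep.tip(t1, t1$tip.label[1:5])
  r <- robinson_foulds(t1, t2)
  expect_identical(r$n_shared, 5L)
  expect_identical(r$rf, 0L)  # restriction of a tree to a subset agrees
  t3 <- ape::rtree(8)
  t3$tip.label <- paste0("other_", t3$tip.label)
  expect_error(robinson_foulds(t1, t3), "4 shared tips")
})

test_that("nsumrf spans its extremes and matches hand-enumerated fixtures", {
  a <- ape::read.tree(text = "((A,B),(C,D),(E,F));")
  expect_equal(nsumrf(list(a, a, a)), 0)
  # caterpillar vs a tree sharing no internal splits: normalized 1
  c1 <- ape::read.tree(text = "(((A,B),C),D,(E,F));")  # splits AB, ABC, EF
  c2 <- ape::read.tree(text = "(((A,F),C),D,(E,B));")
  r12 <- robinson_foulds(c1, c2)
  expect_equal(r12$normalized, 1)
  expect_equal(nsumrf(list(c1, c2, c2)), 1)
  # mixed set, hand-enumerated: c1 {AB, ABC, EF} vs a {AB, CD, EF} differ
  # in {ABC} and {CD} -> rf 2 of max 6
  r1a <- robinson_foulds(c1, a)
  expect_equal(r1a$normalized, 2 / 6)
  expect_equal(nsumrf(list(c1, a, c2)), mean(c(2 / 6, 1)))
  expect_equal(nsumrf(list(c1, a, c2), reference_index = 2),
               mean(c(r1a$normalized, robinson_foulds(a, c2)$normalized)))
  expect_error(nsumrf(list(a)), "at least 2")
})

test_that("the per-locus congruence report handles undefined comparisons", {
  d <- withr::local_tempdir()
  comb <- ape::rtree(6)
  lt <- list(`g01|L1` = comb,
             `g01|L2` = ape::keep.tip(comb, comb$tip.label[1:3]))
  out <- congruence_report(lt, comb, path = file.path(d, "c.tsv"))
  expect_identical(out$normalized[1], 0)
  expect_true(is.na(out$normalized[2]))
  tab <- read.delim(file.path(d, "c.tsv"))
  expect_identical(nrow(tab), 2L)
})
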