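# screen stage: singleton discovery in a seed genome, cross-genome
# presence screening, and locus selection.
#
# A singleton is a gene with no within-genome homologues: its only hit in
# its own genome's database is itself. A locus is selected for phylogenetic
# analysis only if it is a singleton in enough genomes (the presence
# threshold, default all) and is never multi-copy anywhere — a single MULTI
# cell disqualifies a locus outright, because paralogue contamination is
# exactly the failure mode this heuristic exists to avoid.

#' Find singletons within one genome
#'
#' @param db the genome's `protein_db`
#' @param max_evalue E-value cut-off for calling homology
#' @param backend `"internal"` (exact Smith-Waterman) or `"diamond"`
#'   (external binary, see [external_search()])
#' @param exe external search binary when `backend = "diamond"`
#' @return sorted character vector of qualified (`genome|locus`) ids whose
#'   within-genome hit count is exactly 1 (the self-hit)
#' @export
find_singletons <- function(db, max_evalue = 1e-3,
                            backend = c("internal", "diamond"),
                            exe = "diamond") {
  backend <- match.arg(backend)
  stopifnot(inherits(db, "protein_db"))
  if (length(db$entries) == 0) stop("empty database")
  keep <- vapply(names(db$entries), function(id) {
    q <- coding_sequence(db$genome_id, id, db$entries[[id]])
    n <- if (backend == "internal") count_hits(q, db, max_evalue)
         else nrow(external_search(q, db, max_evalue, exe = exe))
    n == 1L
  }, logical(1))
  sort(qualified_id(db$genome_id, names(db$entries)[keep]))
}

#' Screen seed-genome singletons across all genomes
#'
#' Each singleton is queried against every genome's database and classified
#' per genome by hit count: 0 = ABSENT, 1 = SINGLETON (best match recorded),
#' >= 2 = MULTI.
#'
#' @param singletons qualified ids from [find_singletons()] on the seed genome
#' @param genomes named list of [genome_record()]s (all genomes in the run)
#' @param dbs named list of `protein_db`s, one per genome
#' @param max_evalue E-value cut-off
#' @param backend,exe search backend, as in [find_singletons()]
#' @return an object of class `presence_matrix` with character matrices
#'   `status` (cells `"S"`, `"M"`, `"A"`; rows = loci, columns = genomes)
#'   and `best_match` (qualified subject id where status is `"S"`)
#' @export
screen_loci <- function(singletons, genomes, dbs, max_evalue = 1e-3,
                        backend = c("internal", "diamond"),
                        exe = "diamond") {
  backend <- match.arg(backend)
  if (length(singletons) == 0) stop("no singletons to screen")
  seed <- unique(split_qualified_id(singletons)$genome_id)
  if (length(seed) != 1)
    stop("singletons must all come from one seed genome")
  if (!seed %in% names(dbs))
    stop("seed genome '", seed, "' missing from databases")
  if (!setequal(names(genomes), names(dbs)))
    stop("genomes and databases name different genome sets")

  loci <- sort(singletons)
  gids <- sort(names(dbs))
  status <- matrix("A", nrow = length(loci), ncol = length(gids),
                   dimnames = list(loci, gids))
  best <- matrix(NA_character_, nrow = length(loci), ncol = length(gids),
                 dimnames = list(loci, gids))
  seed_genome <- genomes[[seed]]
  for (qid in loci) {
    lid <- split_qualified_id(qid)$locus_id
    query <- get_sequence(seed_genome, lid)
    for (g in gids) {
      r <- if (backend == "internal") .hit_counts(query, dbs[[g]], max_evalue)
           else {
             h <- external_search(query, dbs[[g]], max_evalue, exe = exe)
             list(count = nrow(h),
                  best = if (nrow(h) == 1L) h$subject_id else NA_character_)
           }
      status[qid, g] <- if (r$count == 0L) "A" else if (r$count == 1L) "S" else "M"
      if (r$count == 1L) best[qid, g] <- r$best
    }
  }
  if (!all(status[, seed] == "S"))
    stop("internal error: seed-genome singletons must be SINGLETON in the seed")
  structure(list(status = status, best_match = best, seed_genome = seed,
                 max_evalue = max_evalue),
            class = "presence_matrix")
}

#' @export
print.presence_matrix <- function(x, ...) {
  tab <- table(factor(x$status, levels = c("S", "M", "A")))
  cat("<presence_matrix> ", nrow(x$status), " loci x ", ncol(x$status),
      " genomes (seed: ", x$seed_genome, "); cells S/M/A = ",
      paste(tab, collapse = "/"), "\n", sep = "")
  invisible(x)
}

#' Select orthologous loci from a presence matrix
#'
#' Keeps loci with no MULTI cell anywhere and a SINGLETON count of at least
#' `ceiling(presence_threshold/100 * n_genomes)` (ties resolve toward
#' inclusion at exact equality). If more than `maxloci` survive, the first
#' `maxloci` in lexicographic order are taken, or a seeded uniform sample
#' when `rng_seed` is given; either way the returned loci are ordered
#' lexicographically, which fixes the ordering for all downstream stages.
#'
#' @param matrix a `presence_matrix`
#' @param presence_threshold percentage in (0, 100]; default 100 (all genomes)
#' @param maxloci positive integer cap, or `Inf` for unlimited
#' @param rng_seed optional integer; when set, the maxloci cut is a seeded
#'   uniform sample instead of the lexicographic head
#' @return an object of class `locus_selection`
#' @export
select_loci <- function(matrix, presence_threshold = 100, maxloci = Inf,
                        rng_seed = NULL) {
  stopifnot(inherits(matrix, "presence_matrix"),
            presence_threshold > 0, presence_threshold <= 100,
            maxloci >= 1)
  ng <- ncol(matrix$status)
  need <- ceiling(presence_threshold / 100 * ng)
  s_count <- rowSums(matrix$status == "S")
  has_multi <- rowSums(matrix$status == "M") > 0
  keep <- !has_multi & s_count >= need
  loci <- sort(rownames(matrix$status)[keep])
  if (length(loci) == 0)
    stop("no loci selected: try lowering presence_threshold (used ",
         presence_threshold, ") or a different seed genome")
  if (is.finite(maxloci) && length(loci) > maxloci) {
    loci <- if (is.null(rng_seed)) loci[seq_len(maxloci)]
            else sort(with_seed(rng_seed, sample(loci, maxloci)))
  }
  members <- lapply(loci, function(l) {
    g <- colnames(matrix$status)[matrix$status[l, ] == "S"]
    setNames(matrix$best_match[l, g], g)
  })
  names(members) <- loci
  structure(list(loci = loci, members = members,
                 presence_threshold = presence_threshold,
                 maxloci = maxloci, seed_genome = matrix$seed_genome),
            class = "locus_selection")
}

#' @export
print.locus_selection <- function(x, ...) {
  cat("<locus_selection> ", length(x$loci), " loci (seed: ", x$seed_genome,
      ", presence >= ", x$presence_threshold, "%)\n", sep = "")
  invisible(x)
}

#' Write the presence matrix audit report
#'
#' Tab-separated: rows = loci, columns = genomes, cells `S:<best match>`,
#' `M`, or `A`, so users can audit every locus's fate.
#'
#' @param matrix a `presence_matrix`
#' @param path output TSV path
#' @return `path`, invisibly
#' @export
write_presence_matrix <- function(matrix, path) {
  cells <- matrix$status
  s <- cells == "S"
  cells[s] <- paste0("S:", matrix$best_match[s])
  header <- paste(c("locus", colnames(cells)), collapse = "\t")
  body <- vapply(seq_len(nrow(cells)), function(i) {
    paste(c(rownames(cells)[i], cells[i, ]), collapse = "\t")
  }, "")
  write_lines_lf(c(header, body), path)
  invisible(path)
}
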