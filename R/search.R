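# search backend: per-genome protein databases and similarity search.
#
# The internal backend is an exact Smith-Waterman (BLOSUM62, affine gaps
# open 11 / extend 1) with Karlin-Altschul E-values using the BLAST gapped
# constants lambda = 0.267, K = 0.041 and a symmetric per-pair search space
# m x n (query length x subject length), so A-hits-B iff B-hits-A exactly.
# An external DIAMOND-style tool can be substituted behind the same contract.

.KA_LAMBDA <- 0.267
.KA_K <- 0.041

ka_evalue <- function(raw_score, m, n) {
  .KA_K * as.numeric(m) * as.numeric(n) * exp(-.KA_LAMBDA * raw_score)
}

ka_bitscore <- function(raw_score) {
  (.KA_LAMBDA * raw_score - log(.KA_K)) / log(2)
}

#' Construct a coding-sequence query
#'
#' @param genome_id,locus_id identifiers
#' @param protein amino-acid sequence
#' @return a `coding_sequence` list usable as a query in [search_hits()]
#' @export
coding_sequence <- function(genome_id, locus_id, protein) {
  structure(list(genome_id = genome_id, locus_id = locus_id,
                 protein = normalise_protein(protein, context = locus_id)),
            class = "coding_sequence")
}

#' Extract one coding sequence from a genome record
#' @param genome a [genome_record()]
#' @param locus_id bare locus id
#' @return a [coding_sequence()]
#' @export
get_sequence <- function(genome, locus_id) {
  i <- match(locus_id, genome$sequences$locus_id)
  if (is.na(i)) stop("locus '", locus_id, "' not found in genome '",
                     genome$genome_id, "'")
  coding_sequence(genome$genome_id, locus_id, genome$sequences$protein[i])
}

#' Build a per-genome protein database
#'
#' One database per genome; queries against it only ever see that genome's
#' proteins. When `dir` is given the database is persisted as a protein
#' FASTA so the checkpoint system can rebuild it byte-identically.
#'
#' @param genome a [genome_record()]
#' @param dir optional directory to persist the database in
#' @return an object of class `protein_db`
#' @export
build_database <- function(genome, dir = NULL) {
  if (n_sequences(genome) == 0) stop("cannot build a database from an empty genome")
  path <- NA_character_
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    path <- write_proteome_fasta(genome, dir)
  }
  structure(list(genome_id = genome$genome_id,
                 entries = setNames(genome$sequences$protein,
                                    genome$sequences$locus_id),
                 path = path),
            class = "protein_db")
}

#' Load a persisted protein database
#' @param path FASTA written by [build_database()]
#' @param genome_id genome label; defaults to file name without extension
#' @return a `protein_db`
#' @export
load_database <- function(path, genome_id = NULL) {
  build_database(read_proteome_fasta(path, genome_id))
}

#' @export
print.protein_db <- function(x, ...) {
  cat("<protein_db> ", x$genome_id, ": ", length(x$entries), " proteins\n",
      sep = "")
  invisible(x)
}

# Internal: raw scores / identities of one query against every db entry.
.sw_against_db <- function(protein, db, traceback) {
  .sw_batch(protein, unname(db$entries), blosum62(), 11L, 1L, traceback)
}

#' Search a query protein against a genome database
#'
#' Returns every subject whose local-alignment E-value is at or below
#' `max_evalue`, sorted by ascending E-value, then descending bit-score,
#' then subject id (a total, deterministic order). The self-hit (query
#' belongs to the database's genome) is always included even if its
#' E-value exceeds the threshold, so singleton logic is backend-independent.
#'
#' @param query a [coding_sequence()]
#' @param db a `protein_db` from [build_database()]
#' @param max_evalue E-value cut-off (> 0); default 1e-3
#' @return data.frame with columns query_id, subject_id (both qualified as
#'   `genome|locus`), score (bits), evalue, identity (fraction in \[0,1\])
#' @export
search_hits <- function(query, db, max_evalue = 1e-3) {
  stopifnot(inherits(db, "protein_db"), max_evalue > 0)
  if (!nzchar(query$protein)) stop("empty query protein")
  res <- .sw_against_db(query$protein, db, traceback = TRUE)
  m <- nchar(query$protein)
  n <- nchar(unname(db$entries))
  ev <- ka_evalue(res$score, m, n)
  keep <- ev <= max_evalue
  is_self <- db$genome_id == query$genome_id &
    names(db$entries) == query$locus_id
  keep[is_self] <- TRUE
  hits <- data.frame(
    query_id = qualified_id(query$genome_id, query$locus_id),
    subject_id = qualified_id(db$genome_id, names(db$entries)),
    score = ka_bitscore(res$score),
    evalue = ev,
    identity = res$identity,
    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  hits <- hits[order(hits$evalue, -hits$score, hits$subject_id,
                     method = "radix"), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Count hits of a query against a genome database
#'
#' Same hit/no-hit decision as [search_hits()] (self-hit guaranteed), but
#' skips alignment traceback, so it is the fast path used by screening.
#'
#' @inheritParams search_hits
#' @return non-negative integer
#' @export
count_hits <- function(query, db, max_evalue = 1e-3) {
  .hit_counts(query, db, max_evalue)$count
}

# Internal: count + (when exactly one hit) the subject's qualified id.
.hit_counts <- function(query, db, max_evalue) {
  stopifnot(inherits(db, "protein_db"), max_evalue > 0)
  res <- .sw_against_db(query$protein, db, traceback = FALSE)
  ev <- ka_evalue(res$score, nchar(query$protein),
                  nchar(unname(db$entries)))
  keep <- ev <= max_evalue
  is_self <- db$genome_id == query$genome_id &
    names(db$entries) == query$locus_id
  keep[is_self] <- TRUE
  idx <- which(keep)
  list(count = length(idx),
       best = if (length(idx) == 1L)
         qualified_id(db$genome_id, names(db$entries)[idx]) else NA_character_)
}

# ---- external (DIAMOND-style) adapter -----------------------------------

#' Parse tabular output of a DIAMOND/BLAST-style search
#'
#' Supports the standard 12-column blast tabular layout and the custom
#' 5-column layout `qseqid sseqid pident evalue bitscore`.
#'
#' @param lines character vector of tab-separated rows
#' @param query_genome,subject_genome genome ids used to qualify the bare
#'   sequence ids in the tabular output
#' @return data.frame in [search_hits()] layout
#' @export
parse_tabular_hits <- function(lines, query_genome, subject_genome) {
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0)
    return(data.frame(query_id = character(0), subject_id = character(0),
                      score = numeric(0), evalue = numeric(0),
                      identity = numeric(0), stringsAsFactors = FALSE))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- unique(lengths(fields))
  if (length(ncols) != 1 || !ncols %in% c(5L, 12L))
    stop("unrecognised tabular search output (expected 5 or 12 columns)")
  get <- function(i) vapply(fields, `[`, "", i)
  if (ncols == 5L) {
    out <- data.frame(query_id = get(1), subject_id = get(2),
                      score = as.numeric(get(5)),
                      evalue = as.numeric(get(4)),
                      identity = as.numeric(get(3)) / 100,
                      stringsAsFactors = FALSE)
  } else {
    out <- data.frame(query_id = get(1), subject_id = get(2),
                      score = as.numeric(get(12)),
                      evalue = as.numeric(get(11)),
                      identity = as.numeric(get(3)) / 100,
                      stringsAsFactors = FALSE)
  }
  out$query_id <- qualified_id(query_genome, out$query_id)
  out$subject_id <- qualified_id(subject_genome, out$subject_id)
  out[order(out$evalue, -out$score, out$subject_id, method = "radix"), ,
      drop = FALSE]
}

#' Search using an external DIAMOND-compatible binary
#'
#' Shells out with `makedb`-style database construction already done by the
#' caller (the persisted FASTA of [build_database()] serves as the subject
#' set via `blastp --db`-style invocation). Requires the binary on PATH;
#' errors otherwise — backend choice is always explicit, never auto-silent.
#'
#' @param query a [coding_sequence()]
#' @param db a `protein_db` persisted to disk
#' @param max_evalue E-value cut-off
#' @param exe binary name or path (e.g. `"diamond"`)
#' @return data.frame in [search_hits()] layout (self-hit enforced)
#' @export
external_search <- function(query, db, max_evalue = 1e-3, exe = "diamond") {
  if (Sys.which(exe) == "")
    stop("external search backend '", exe, "' not found on PATH")
  if (is.na(db$path)) stop("database for '", db$genome_id,
                           "' has not been persisted to disk")
  tmp <- tempfile(fileext = ".fasta")
  on.exit(unlink(c(tmp, paste0(tmp, ".dmnd"), paste0(tmp, ".tsv"))),
          add = TRUE)
  write_lines_lf(c(paste0(">", query$locus_id), query$protein), tmp)
  dmnd_db <- paste0(tmp, ".dmnd")
  r1 <- suppressWarnings(system2(exe, c("makedb", "--in", db$path, "-d", dmnd_db),
                                 stdout = TRUE, stderr = TRUE))
  if (!is.null(attr(r1, "status")))
    stop("external makedb failed: ", paste(r1, collapse = "\n"))
  out <- paste0(tmp, ".tsv")
  r2 <- suppressWarnings(system2(
    exe, c("blastp", "-q", tmp, "-d", dmnd_db, "-o", out,
           "-e", format(max_evalue), "--outfmt", "6",
           "qseqid", "sseqid", "pident", "evalue", "bitscore"),
    stdout = TRUE, stderr = TRUE))
  if (!is.null(attr(r2, "status")))
    stop("external blastp failed: ", paste(r2, collapse = "\n"))
  hits <- parse_tabular_hits(readLines(out, warn = FALSE),
                             query_genome = query$genome_id,
                             subject_genome = db$genome_id)
  hits$query_id <- qualified_id(query$genome_id, query$locus_id)
  self_id <- qualified_id(db$genome_id, query$locus_id)
  if (db$genome_id == query$genome_id &&
      query$locus_id %in% names(db$entries) &&
      !self_id %in% hits$subject_id) {
    hits <- rbind(data.frame(query_id = qualified_id(query$genome_id, query$locus_id),
                             subject_id = self_id, score = NA_real_,
                             evalue = 0, identity = 1,
                             stringsAsFactors = FALSE), hits)
  }
  rownames(hits) <- NULL
  hits
}
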