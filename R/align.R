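# align stage: per-locus sequence gathering, alignment, and supermatrix
# concatenation with a partition map.

#' Construct a locus alignment
#'
#' @param locus_id locus identifier
#' @param rows named character vector: genome_id -> aligned sequence
#'   (gaps as `-`), all the same length
#' @return an object of class `locus_alignment`
#' @export
locus_alignment <- function(locus_id, rows) {
  if (length(rows) == 0) stop("alignment has no rows")
  len <- unique(nchar(rows))
  if (length(len) != 1)
    stop("rows of locus '", locus_id, "' differ in length")
  if (len < 1) stop("zero-length alignment for locus '", locus_id, "'")
  structure(list(locus_id = locus_id, rows = rows, length = len),
            class = "locus_alignment")
}

#' @export
print.locus_alignment <- function(x, ...) {
  cat("<locus_alignment> ", x$locus_id, ": ", length(x$rows), " rows x ",
      x$length, " columns\n", sep = "")
  invisible(x)
}

#' Gather one selected locus across genomes
#'
#' One sequence per genome where the locus is a singleton, labelled by
#' genome id (tree tips are genomes, not locus tags).
#'
#' @param selection a `locus_selection` from [select_loci()]
#' @param locus qualified locus id present in the selection
#' @param genomes named list of [genome_record()]s
#' @return named character vector (genome_id -> protein), lexicographic
#'   genome order, with attribute `locus_id`
#' @export
gather_locus <- function(selection, locus, genomes) {
  if (!locus %in% selection$loci) stop("locus '", locus, "' not in selection")
  members <- selection$members[[locus]]
  gids <- sort(names(members))
  seqs <- vapply(gids, function(g) {
    subj <- split_qualified_id(members[[g]])
    rec <- genomes[[g]]
    if (is.null(rec))
      stop("genome '", g, "' (member of locus '", locus,
           "') missing from parsed genomes")
    i <- match(subj$locus_id, rec$sequences$locus_id)
    if (is.na(i))
      stop("sequence '", subj$locus_id, "' for locus '", locus,
           "' missing from genome '", g, "'")
    rec$sequences$protein[i]
  }, "")
  structure(seqs, locus_id = locus)
}

#' Align one locus
#'
#' The internal backend is a deterministic progressive alignment
#' (Needleman-Wunsch, BLOSUM62, gap open 10 / extend 1) over a guide order
#' fixed by lexicographic genome id — a binary-free fallback so the whole
#' pipeline runs without MUSCLE. External adapters support MUSCLE3
#' (`-in`/`-out`), MUSCLE5 (`-align`/`-output`) and MAFFT conventions.
#'
#' @param seqs named character vector (genome_id -> protein), >= 2 sequences
#' @param aligner `"internal"` (default), `"muscle"`, or `"mafft"`
#' @param locus_id label for the resulting alignment
#' @param exe external binary name/path (default: same as `aligner`)
#' @return a [locus_alignment()]
#' @export
align_locus <- function(seqs, aligner = c("internal", "muscle", "mafft"),
                        locus_id = attr(seqs, "locus_id"), exe = NULL) {
  aligner <- match.arg(aligner)
  if (length(seqs) < 2)
    stop("cannot align a single-sequence locus",
         if (!is.null(locus_id)) paste0(" ('", locus_id, "')"))
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("sequences must carry unique genome names")
  if (is.null(locus_id)) locus_id <- "locus"
  ord <- sort(names(seqs))
  if (aligner == "internal") {
    aligned <- .progressive_align(unname(seqs[ord]), blosum62(), 10, 1)
    rows <- setNames(aligned, ord)
  } else {
    rows <- run_external_aligner(seqs[ord], aligner, exe)
    rows <- rows[ord]
  }
  aln <- locus_alignment(locus_id, rows)
  degapped <- gsub("-", "", aln$rows, fixed = TRUE)
  bad <- names(which(degapped != seqs[names(aln$rows)]))
  if (length(bad) > 0)
    stop("aligner corrupted sequences for genome(s): ",
         paste(bad, collapse = ", "))
  aln
}

# MUSCLE3: muscle -in in.fa -out out.fa ; MUSCLE5: muscle -align in.fa
# -output out.fa ; MAFFT: mafft --auto --quiet in.fa > stdout.
run_external_aligner <- function(seqs, aligner, exe = NULL) {
  if (is.null(exe)) exe <- aligner
  if (Sys.which(exe) == "")
    stop("external aligner '", exe, "' not found on PATH")
  fin <- tempfile(fileext = ".fasta")
  fout <- tempfile(fileext = ".fasta")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  write_lines_lf(as.vector(rbind(paste0(">", names(seqs)), unname(seqs))), fin)
  if (aligner == "mafft") {
    ferr <- tempfile()
    on.exit(unlink(ferr), add = TRUE)
    out <- suppressWarnings(system2(exe, c("--auto", "--quiet", "--amino", fin),
                                    stdout = TRUE, stderr = ferr))
    if (!is.null(attr(out, "status")))
      stop("mafft failed: ",
           paste(readLines(ferr, warn = FALSE), collapse = "\n"))
    write_lines_lf(out, fout)
  } else {
    ver <- suppressWarnings(system2(exe, "-version", stdout = TRUE,
                                    stderr = TRUE))
    args <- if (any(grepl("3\\.[0-9]", ver)))
      c("-in", fin, "-out", fout) else c("-align", fin, "-output", fout)
    out <- suppressWarnings(system2(exe, args, stdout = TRUE, stderr = TRUE))
    if (!is.null(attr(out, "status")) || !file.exists(fout))
      stop("muscle failed: ", paste(out, collapse = "\n"))
  }
  aa <- Biostrings::readAAStringSet(fout)
  setNames(toupper(as.character(aa)),
           vapply(strsplit(names(aa), "\\s+"), `[`, "", 1L))
}

#' Concatenate per-locus alignments into a partitioned supermatrix
#'
#' Loci are concatenated in lexicographic locus order. A genome missing
#' from a locus (presence threshold below 100) receives a run of `-` of
#' that locus's aligned length. Partitions tile `[1, length]` exactly.
#'
#' @param alignments list of [locus_alignment()]s with unique locus ids
#' @param all_genomes character vector of genome ids forming the row set
#' @return an object of class `supermatrix`: `rows` (named character),
#'   `partitions` (data.frame locus_id/start/end, 1-based inclusive),
#'   `length`
#' @export
concatenate_alignments <- function(alignments, all_genomes) {
  if (length(alignments) == 0) stop("no alignments to concatenate")
  ids <- vapply(alignments, function(a) a$locus_id, "")
  if (anyDuplicated(ids))
    stop("duplicate locus ids: ", paste(unique(ids[duplicated(ids)]),
                                        collapse = ", "))
  alignments <- alignments[order(ids, method = "radix")]
  ids <- sort(ids, method = "radix")
  all_genomes <- sort(unique(all_genomes))
  lens <- vapply(alignments, function(a) a$length, 0L)
  ends <- cumsum(lens)
  starts <- c(1L, head(ends, -1L) + 1L)
  rows <- vapply(all_genomes, function(g) {
    paste(vapply(alignments, function(a) {
      if (g %in% names(a$rows)) a$rows[[g]] else strrep("-", a$length)
    }, ""), collapse = "")
  }, "")
  structure(list(rows = rows,
                 partitions = data.frame(locus_id = ids, start = starts,
                                         end = ends,
                                         stringsAsFactors = FALSE),
                 length = sum(lens)),
            class = "supermatrix")
}

#' @export
print.supermatrix <- function(x, ...) {
  cat("<supermatrix> ", length(x$rows), " genomes x ", x$length,
      " columns in ", nrow(x$partitions), " partitions\n", sep = "")
  invisible(x)
}

# FASTA text (60-column wrap) for a set of named rows.
.fasta_lines <- function(rows) {
  unlist(lapply(names(rows), function(id) {
    s <- rows[[id]]
    c(paste0(">", id),
      substring(s, seq(1L, nchar(s), 60L),
                pmin(seq(1L, nchar(s), 60L) + 59L, nchar(s))))
  }))
}

#' Write a locus alignment as FASTA
#' @param aln a [locus_alignment()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_alignment_fasta <- function(aln, path) {
  write_lines_lf(.fasta_lines(aln$rows), path)
  invisible(path)
}

#' Write a supermatrix and its partition files
#'
#' Emits the combined FASTA, a RAxML-style partition file
#' (`PROT, <locus> = <start>-<end>`) and a NEXUS sets block, all with
#' LF line endings so identical inputs give byte-identical files.
#'
#' @param sm a `supermatrix`
#' @param dir output directory (created if needed)
#' @return named character vector of the three written paths, invisibly
#' @export
write_supermatrix <- function(sm, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  combined <- file.path(dir, "combined.fasta")
  write_lines_lf(.fasta_lines(sm$rows), combined)
  raxml <- file.path(dir, "partitions.txt")
  write_lines_lf(sprintf("PROT, %s = %d-%d", sm$partitions$locus_id,
                         sm$partitions$start, sm$partitions$end), raxml)
  nexus <- file.path(dir, "partitions.nex")
  write_lines_lf(c("#NEXUS", "begin sets;",
                   sprintf("  charset %s = %d-%d;",
                           gsub("[^A-Za-z0-9_.|]", "_", sm$partitions$locus_id),
                           sm$partitions$start, sm$partitions$end),
                   "end;"), nexus)
  invisible(c(combined = combined, partitions = raxml, nexus = nexus))
}
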