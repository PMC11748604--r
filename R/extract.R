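# extract stage: GenBank flat-file parsing and per-genome protein FASTA I/O.
#
# One GenBank file = one genome (or other genetic element: plasmid, phage,
# gene cluster). Every CDS feature that yields both an identifier (the
# configurable `tag` qualifier, default locus_tag) and a protein (the
# /translation qualifier, or a conceptual translation of the spliced
# nucleotide span) becomes one coding sequence.

#' Construct a genome record
#'
#' Container for one parsed input file: an ordered collection of coding
#' sequences keyed by locus identifier.
#'
#' @param genome_id short label (derived from the file name for parsed input)
#' @param locus_id character vector of locus identifiers, unique within the genome
#' @param protein character vector of amino-acid sequences (one-letter codes)
#' @param source_tag qualifier name the identifiers came from
#' @param source_path originating file path, if any
#' @return an object of class `genome_record`
#' @export
genome_record <- function(genome_id, locus_id, protein,
                          source_tag = "locus_tag", source_path = NA_character_) {
  stopifnot(length(locus_id) == length(protein))
  if (anyDuplicated(locus_id))
    stop("duplicate locus ids in genome '", genome_id, "': ",
         paste(unique(locus_id[duplicated(locus_id)]), collapse = ", "))
  protein <- vapply(protein, normalise_protein, "", USE.NAMES = FALSE)
  if (any(!nzchar(protein))) stop("empty protein sequence in genome '", genome_id, "'")
  structure(list(
    genome_id = genome_id,
    sequences = data.frame(locus_id = as.character(locus_id),
                           protein = protein,
                           source_tag = rep_len(source_tag,
                                                length(locus_id)),
                           stringsAsFactors = FALSE),
    source_path = source_path
  ), class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat("<genome_record> ", x$genome_id, ": ", nrow(x$sequences),
      " coding sequences\n", sep = "")
  invisible(x)
}

#' Number of coding sequences in a genome record
#' @param x a `genome_record`
#' @return integer count
#' @export
n_sequences <- function(x) nrow(x$sequences)

# ---- GenBank location grammar -------------------------------------------
# span        := [<>]?start(..[<>]?end)?
# location    := span | complement(location) | join(location, ...) | order(...)
# complement(join(e1, e2)) extracts as revcomp(concat(e1, e2)), i.e. the
# spans are traversed in reverse order with each span complemented.
parse_gb_location <- function(loc) {
  loc <- gsub("[[:space:]<>]", "", loc)
  rec <- function(s) {
    if (grepl("^complement\\(", s)) {
      inner <- substr(s, 12L, nchar(s) - 1L)
      sp <- rec(inner)
      sp <- sp[rev(seq_len(nrow(sp))), , drop = FALSE]
      sp$complement <- !sp$complement
      return(sp)
    }
    if (grepl("^(join|order)\\(", s)) {
      inner <- sub("^(join|order)\\(", "", s)
      inner <- substr(inner, 1L, nchar(inner) - 1L)
      # split on top-level commas only
      depth <- 0L
      cuts <- integer(0)
      chars <- strsplit(inner, "")[[1]]
      for (i in seq_along(chars)) {
        if (chars[i] == "(") depth <- depth + 1L
        else if (chars[i] == ")") depth <- depth - 1L
        else if (chars[i] == "," && depth == 0L) cuts <- c(cuts, i)
      }
      starts <- c(1L, cuts + 1L)
      ends <- c(cuts - 1L, length(chars))
      parts <- mapply(function(a, b) paste(chars[a:b], collapse = ""),
                      starts, ends)
      return(do.call(rbind, lapply(parts, rec)))
    }
    m <- regmatches(s, regexec("^([0-9]+)(\\.\\.([0-9]+))?$", s))[[1]]
    if (length(m) == 0)
      stop("unsupported location: ", loc)
    start <- as.integer(m[2])
    end <- if (nzchar(m[4])) as.integer(m[4]) else start
    data.frame(start = start, end = end, complement = FALSE)
  }
  rec(loc)
}

# Parse the FEATURES block of one GenBank record into a list of
# list(key=, location=, qualifiers=list(name -> character)).
parse_gb_features <- function(lines) {
  feats <- list()
  cur <- NULL
  qual_name <- NULL
  flush <- function() if (!is.null(cur)) feats[[length(feats) + 1L]] <<- cur
  for (ln in lines) {
    if (grepl("^ {5}\\S", ln)) {  # new feature: key at column 6
      flush()
      key <- sub("^ {5}(\\S+).*$", "\\1", ln)
      loc <- sub("^ {5}\\S+\\s*", "", ln)
      cur <- list(key = key, location = loc, qualifiers = list())
      qual_name <- NULL
    } else if (grepl("^ {21}\\S", ln) || grepl("^\\s+/", ln)) {
      txt <- sub("^\\s+", "", ln)
      if (startsWith(txt, "/")) {
        eq <- regexpr("=", txt, fixed = TRUE)
        if (eq > 0) {
          qual_name <- substr(txt, 2L, eq - 1L)
          val <- substring(txt, eq + 1L)
          cur$qualifiers[[qual_name]] <-
            c(cur$qualifiers[[qual_name]], gsub("\"", "", val))
        } else {
          qual_name <- substring(txt, 2L)
          cur$qualifiers[[qual_name]] <- c(cur$qualifiers[[qual_name]], "")
        }
      } else if (is.null(qual_name)) {
        cur$location <- paste0(cur$location, txt)  # wrapped location
      } else {
        # continuation of a qualifier value; sequences concatenate directly
        n <- length(cur$qualifiers[[qual_name]])
        sep <- if (qual_name %in% c("translation")) "" else " "
        cur$qualifiers[[qual_name]][n] <-
          paste(cur$qualifiers[[qual_name]][n],
                gsub("\"", "", txt), sep = sep)
      }
    }
  }
  flush()
  feats
}

#' Parse a GenBank flat file into a genome record
#'
#' Extracts one coding sequence per CDS feature that carries the chosen
#' identifier qualifier and a protein. Proteins are taken from the
#' `/translation` qualifier when present; otherwise the feature's spliced
#' nucleotide span is translated conceptually with its `/transl_table`
#' (default 1), honouring strand and `join()`/`complement()` semantics.
#' CDS features without the chosen tag, with unusable spans (length not a
#' multiple of three), or duplicating an earlier locus id are skipped with a
#' warning; skip counts are kept on the returned record.
#'
#' @param path GenBank flat file (multi-record files are supported; features
#'   of all records are pooled into one genome)
#' @param tag qualifier supplying the locus identifier (default
#'   `"locus_tag"`; e.g. `"protein_id"` for RefSeq-style input)
#' @param quiet suppress warnings about skipped features
#' @return a [genome_record()] with attribute-like fields `n_cds` (CDS
#'   features seen) and `skipped` (named counts)
#' @export
parse_genbank <- function(path, tag = "locus_tag", quiet = FALSE) {
  if (!nzchar(tag)) stop("tag must be a non-empty qualifier name")
  if (!file.exists(path)) stop("GenBank file not found: ", path)
  lines <- tryCatch(readLines(path, warn = FALSE),
                    error = function(e) stop("cannot read GenBank file ", path,
                                             ": ", conditionMessage(e)))
  if (!any(startsWith(lines, "LOCUS")))
    stop("malformed GenBank file (no LOCUS line): ", path)
  genome_id <- tools::file_path_sans_ext(basename(path))

  # split into records on '//' terminators
  term <- which(trimws(lines) == "//")
  if (length(term) == 0) term <- length(lines)
  starts <- c(1L, head(term, -1L) + 1L)
  records <- mapply(function(a, b) lines[a:b], starts, term, SIMPLIFY = FALSE)

  loci <- character(0); prots <- character(0)
  n_cds <- 0L
  skipped <- c(no_tag = 0L, bad_span = 0L, duplicate = 0L, no_protein = 0L)

  for (rec in records) {
    fstart <- which(startsWith(rec, "FEATURES"))
    if (length(fstart) == 0) next
    fend <- which(grepl("^(ORIGIN|BASE COUNT|CONTIG)", rec))
    fend <- if (length(fend)) min(fend[fend > fstart[1]]) else length(rec)
    feats <- parse_gb_features(rec[(fstart[1] + 1L):(fend - 1L)])

    ostart <- which(startsWith(rec, "ORIGIN"))
    origin <- ""
    if (length(ostart)) {
      oseq <- rec[(ostart[1] + 1L):length(rec)]
      origin <- toupper(paste(gsub("[^A-Za-z]", "", oseq), collapse = ""))
    }

    for (f in feats) {
      if (f$key != "CDS") next
      n_cds <- n_cds + 1L
      id <- f$qualifiers[[tag]][1]
      if (is.null(id) || !nzchar(id)) {
        skipped["no_tag"] <- skipped["no_tag"] + 1L
        next
      }
      prot <- f$qualifiers[["translation"]][1]
      if (is.null(prot) || !nzchar(prot)) {
        prot <- tryCatch(
          conceptual_translation(f, origin),
          error = function(e) NA_character_)
        if (is.na(prot)) {
          skipped["bad_span"] <- skipped["bad_span"] + 1L
          if (!quiet) warning("skipping CDS '", id, "' in ", genome_id,
                              ": unusable span or no sequence", call. = FALSE)
          next
        }
      }
      prot <- tryCatch(normalise_protein(prot, context = id),
                       error = function(e) NA_character_)
      if (is.na(prot) || !nzchar(prot)) {
        skipped["no_protein"] <- skipped["no_protein"] + 1L
        next
      }
      if (id %in% loci) {
        skipped["duplicate"] <- skipped["duplicate"] + 1L
        if (!quiet) warning("duplicate locus id '", id, "' in ", genome_id,
                            "; keeping first occurrence", call. = FALSE)
        next
      }
      loci <- c(loci, id)
      prots <- c(prots, prot)
    }
  }

  if (!quiet && skipped["no_tag"] > 0)
    warning(skipped["no_tag"], " CDS feature(s) in ", genome_id,
            " lack the '", tag, "' qualifier and were skipped", call. = FALSE)
  if (length(loci) == 0)
    stop("no usable CDS features in ", path,
         " (identifier qualifier tried: '", tag, "')")

  g <- genome_record(genome_id, loci, prots, source_tag = tag,
                     source_path = path)
  g$n_cds <- n_cds
  g$skipped <- skipped
  g
}

# Conceptual translation of a CDS feature from its record's ORIGIN sequence.
conceptual_translation <- function(feature, origin) {
  if (!nzchar(origin)) stop("record has no ORIGIN sequence")
  spans <- parse_gb_location(feature$location)
  if (any(spans$end > nchar(origin)) || any(spans$start < 1))
    stop("location outside sequence")
  parts <- vapply(seq_len(nrow(spans)), function(i) {
    s <- substr(origin, spans$start[i], spans$end[i])
    if (spans$complement[i])
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    s
  }, "")
  nt <- paste(parts, collapse = "")
  if (nchar(nt) %% 3 != 0) stop("spliced span length not a multiple of 3")
  tbl <- feature$qualifiers[["transl_table"]][1]
  code <- Biostrings::getGeneticCode(if (is.null(tbl)) "1" else tbl)
  # literal codon-by-codon translation: initiator-codon remapping to M is
  # deliberately not applied (annotation-supplied /translation wins anyway)
  as.character(Biostrings::translate(Biostrings::DNAString(nt),
                                     genetic.code = code,
                                     no.init.codon = TRUE,
                                     if.fuzzy.codon = "X"))
}

#' Write a genome's proteome as FASTA
#'
#' One record per coding sequence, header = bare locus id, sequence wrapped
#' at 60 columns. Round-trips losslessly through [read_proteome_fasta()].
#'
#' @param genome a [genome_record()]
#' @param out_dir existing, writable directory
#' @return the written file path (`<out_dir>/<genome_id>.fasta`), invisibly
#' @export
write_proteome_fasta <- function(genome, out_dir) {
  if (!dir.exists(out_dir)) stop("not a directory: ", out_dir)
  if (n_sequences(genome) == 0) stop("genome '", genome$genome_id, "' is empty")
  path <- file.path(out_dir, paste0(genome$genome_id, ".fasta"))
  lines <- unlist(lapply(seq_len(n_sequences(genome)), function(i) {
    seq <- genome$sequences$protein[i]
    c(paste0(">", genome$sequences$locus_id[i]),
      substring(seq, seq(1L, nchar(seq), 60L),
                pmin(seq(1L, nchar(seq), 60L) + 59L, nchar(seq))))
  }))
  tryCatch(write_lines_lf(lines, path),
           error = function(e) stop("cannot write ", path, ": ",
                                    conditionMessage(e)))
  invisible(path)
}

#' Read a per-genome protein FASTA
#'
#' @param path FASTA file of amino-acid sequences
#' @param genome_id genome label; defaults to the file name without extension
#' @return a [genome_record()]; locus ids are the first whitespace-delimited
#'   header tokens
#' @export
read_proteome_fasta <- function(path, genome_id = NULL) {
  if (is.null(genome_id)) genome_id <- tools::file_path_sans_ext(basename(path))
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0) stop("no sequences in ", path)
  ids <- vapply(strsplit(names(aa), "\\s+"), `[`, "", 1L)
  if (anyDuplicated(ids))
    stop("duplicate identifiers in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  g <- genome_record(genome_id, ids, as.character(aa),
                     source_tag = "fasta", source_path = path)
  g
}
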