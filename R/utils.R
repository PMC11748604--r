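# Shared helpers: identifiers, alphabets, logging, seed scoping.

# IUPAC one-letter amino-acid alphabet accepted on ingestion; ambiguity codes
# B/Z and the rare U/O are remapped to X so every residue scores under
# BLOSUM62 without special-casing.
.AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
           "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
.AA_OK <- c(.AA20, "X", "*")

#' Qualified locus identifier
#'
#' Loci are keyed internally as `genome_id|locus_id` so identical locus tags
#' in different genomes can never collide; bare locus ids appear only in
#' display output and FASTA written per genome.
#' @param genome_id,locus_id character vectors
#' @return character vector of qualified ids
#' @export
qualified_id <- function(genome_id, locus_id) {
  # paste() promotes zero-length args to "", which would fabricate an id
  if (length(genome_id) == 0 || length(locus_id) == 0) return(character(0))
  paste(genome_id, locus_id, sep = "|")
}

#' Split a qualified locus identifier
#' @param qid character vector of `genome|locus` ids
#' @return data.frame with columns genome_id, locus_id
#' @export
split_qualified_id <- function(qid) {
  pos <- regexpr("|", qid, fixed = TRUE)
  if (any(pos < 0)) stop("not a qualified id (missing '|'): ", qid[pos < 0][1])
  data.frame(genome_id = substr(qid, 1L, pos - 1L),
             locus_id = substring(qid, pos + 1L),
             stringsAsFactors = FALSE)
}

st_log <- function(..., logfile = NULL, quiet = FALSE) {
  msg <- paste0(...)
  if (!quiet) message(msg)
  if (!is.null(logfile)) {
    cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " ", msg, "\n",
        sep = "", file = logfile, append = TRUE)
  }
  invisible(msg)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# seed = NULL leaves the RNG untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Normalise a protein string: uppercase, strip one trailing '*', remap
# non-standard residues, and validate the alphabet.
normalise_protein <- function(x, context = "") {
  x <- toupper(x)
  x <- sub("\\*$", "", x)
  x <- chartr("BZUO", "XXXX", x)
  bad <- setdiff(unique(strsplit(x, "")[[1]]), .AA_OK)
  if (length(bad) > 0) {
    stop("invalid amino-acid characters ", paste(bad, collapse = ""),
         if (nzchar(context)) paste0(" in ", context))
  }
  x
}

# writeLines with LF endings regardless of platform (byte-determinism).
write_lines_lf <- function(lines, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con = con, sep = "\n")
  invisible(path)
}
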