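# Shared fixtures and independent oracles.
#
# The Smith-Waterman oracle is Biostrings::pairwiseAlignment (independent C
# implementation); the Robinson-Foulds oracles are (a) a brute-force
# edge-removal/graph-component bipartition enumeration written here and
# (b) phangorn::RF.dist.

.aa20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
           "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

rand_protein <- function(n) paste(sample(.aa20, n, replace = TRUE),
                                  collapse = "")

mutate_protein <- function(p, frac) {
  r <- strsplit(p, "")[[1]]
  k <- max(1L, round(frac * length(r)))
  pos <- sample(length(r), k)
  r[pos] <- sample(.aa20, k, replace = TRUE)
  paste(r, collapse = "")
}

bs_blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

# Optimal local-alignment score via the independent Biostrings engine.
oracle_sw_score <- function(a, b) {
  Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
    substitutionMatrix = bs_blosum62, gapOpening = 11, gapExtension = 1,
    scoreOnly = TRUE)
}

oracle_evalue <- function(raw, m, n) 0.041 * m * n * exp(-0.267 * raw)

# Singleton calls from exhaustive all-pairs Smith-Waterman at the same
# Karlin-Altschul threshold; the self-pair never counts as a homologue.
oracle_singletons <- function(proteins, max_evalue = 1e-3) {
  n <- length(proteins)
  if (n == 1) return(sort(names(proteins)))
  pat <- Biostrings::AAStringSet(proteins)
  has_other <- rep(FALSE, n)
  for (j in seq_len(n)) {
    sc <- Biostrings::pairwiseAlignment(
      pat, Biostrings::AAString(proteins[[j]]), type = "local",
      substitutionMatrix = bs_blosum62, gapOpening = 11, gapExtension = 1,
      scoreOnly = TRUE)
    hit <- oracle_evalue(sc, nchar(proteins), nchar(proteins[[j]])) <= max_evalue
    hit[j] <- FALSE
    has_other[hit] <- TRUE
  }
  sort(names(proteins)[!has_other])
}

# Presence matrix built directly from a compact status specification.
make_pm <- function(status, best_match = NULL, seed_genome = colnames(status)[1]) {
  if (is.null(best_match)) {
    best_match <- matrix(NA_character_, nrow(status), ncol(status),
                         dimnames = dimnames(status))
    s <- status == "S"
    best_match[s] <- paste0(rep(colnames(status), each = nrow(status))[s],
                            "|x")
  }
  structure(list(status = status, best_match = best_match,
                 seed_genome = seed_genome, max_evalue = 1e-3),
            class = "presence_matrix")
}

# Non-trivial bipartitions by deleting each internal edge and collecting
# the tip set of the resulting component (graph traversal, no reuse of the
# package's postorder accumulation).
oracle_splits <- function(tree) {
  tree <- ape::unroot(tree)
  nt <- length(tree$tip.label)
  E <- tree$edge
  keys <- character(0)
  for (k in which(E[, 2] > nt)) {
    adj <- E[-k, , drop = FALSE]
    nodes <- E[k, 2]
    repeat {
      nb <- unique(c(adj[adj[, 1] %in% nodes, 2],
                     adj[adj[, 2] %in% nodes, 1]))
      new <- setdiff(nb, nodes)
      if (length(new) == 0) break
      nodes <- c(nodes, new)
    }
    side <- tree$tip.label[nodes[nodes <= nt]]
    if (length(side) < 2 || length(side) > nt - 2) next
    ref <- min(tree$tip.label)
    if (ref %in% side) side <- setdiff(tree$tip.label, side)
    keys <- c(keys, paste(sort(side), collapse = "|"))
  }
  unique(keys)
}

oracle_rf <- function(a, b) {
  sa <- oracle_splits(a)
  sb <- oracle_splits(b)
  length(setdiff(sa, sb)) + length(setdiff(sb, sa))
}

# A small literal GenBank file exercising strand, join() splicing,
# conceptual translation, a missing tag and a trailing stop. Returns the
# path and the expected parse result.
write_literal_genbank <- function(dir, name = "toy") {
  # layout: A1 plus strand 1..9 ("MK" + stop); A2 complement(11..19)
  #   ("MR" + stop, translation carries trailing *); P3 (no locus_tag)
  #   21..29; A4 join(31..36,38..43) with no /translation -> conceptual
  #   translation of ATGAAA + ACTTAA = "MKT" (stop stripped)
  seqs <- c("ATGAAATAA",                      # 1..9    A1 "MK"
            "T",
            as.character(Biostrings::reverseComplement(
              Biostrings::DNAString("ATGCGTTAA"))),  # 11..19 A2 "MR"
            "T",
            "ATGACTTAA",                      # 21..29  P3 "MT"
            "T",
            "ATGAAA", "G", "ACTTAA",          # 31..36, 38..43 A4 "MKT"
            "TTTTTTT")
  full <- paste(seqs, collapse = "")
  origin <- vapply(seq(1L, nchar(full), 60L), function(s) {
    chunk <- substr(full, s, min(s + 59L, nchar(full)))
    groups <- substring(chunk, seq(1L, nchar(chunk), 10L),
                        pmin(seq(1L, nchar(chunk), 10L) + 9L, nchar(chunk)))
    sprintf("%9d %s", s, tolower(paste(groups, collapse = " ")))
  }, "")
  lines <- c(
    sprintf("LOCUS       %-16s %d bp    DNA     linear   UNK 01-JAN-2026",
            name, nchar(full)),
    "DEFINITION  Literal test record.",
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", nchar(full)),
    "     CDS             1..9",
    "                     /locus_tag=\"A1\"",
    "                     /protein_id=\"P1\"",
    "                     /translation=\"MK\"",
    "     CDS             complement(11..19)",
    "                     /locus_tag=\"A2\"",
    "                     /protein_id=\"P2\"",
    "                     /translation=\"MR*\"",
    "     CDS             21..29",
    "                     /protein_id=\"P3\"",
    "                     /translation=\"MT\"",
    "     CDS             join(31..36,38..43)",
    "                     /locus_tag=\"A4\"",
    "                     /transl_table=11",
    "ORIGIN",
    origin,
    "//")
  path <- file.path(dir, paste0(name, ".gbk"))
  writeLines(lines, path)
  list(path = path,
       expected = data.frame(
         locus_id = c("A1", "A2", "A4"),
         protein = c("MK", "MR", "MKT"),
         stringsAsFactors = FALSE),
       n_cds = 4L)
}
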