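# Synthetic genome sets with planted orthologue structure and a known
# generating tree, so screening, alignment, tree inference and metrics are
# all testable without downloads. Deliberately simple evolution: uniform
# root sequences, Jukes-Cantor-style substitutions on the 20-letter
# alphabet, optional indels; no codon usage, synteny, or HGT.

#' Specify a synthetic genome set
#'
#' Defaults describe a small but structured world: 6 genomes, a planted
#' single-copy core of 15 genes, 3 paralogous families (duplicated in one
#' genome each), 5 accessory genes confined to strict genome subsets,
#' 120-residue proteins and a maximum pairwise divergence of 0.2
#' substitutions/site — the regime where the single-copy heuristic is
#' meant to operate.
#'
#' @param n_genomes number of genomes (>= 2; >= 4 for unrooted topologies)
#' @param n_core planted single-copy orthologues, one per genome each
#' @param n_dup_families gene families duplicated (copy number
#'   `dup_copies`) in at least one genome
#' @param n_accessory genes present in a strict subset of genomes
#' @param protein_length residues per simulated protein
#' @param tree optional `ape::phylo` generating topology with branch
#'   lengths (expected substitutions/site); a random topology is drawn
#'   from the seed when `NULL`
#' @param divergence target maximum pairwise path length (substitutions/
#'   site) used to scale a generated tree; ignored when `tree` is supplied
#' @param subst_rate_scale multiplier applied to all branch lengths
#' @param indel_rate per-site indel probability per branch (0 = none)
#' @param dup_copies copies per duplicated family in its host genome
#' @param dup_divergence substitution fraction between family copies
#'   (default 0.05 so copies remain mutual hits)
#' @param verify_unrelated run the oracle-search self-test: resample any
#'   family whose members show detectable similarity (E-value at or below
#'   `verify_evalue`) to another family, so the planted truth table is
#'   consistent with what a calibrated homology search can see (default
#'   `TRUE`; chance local alignments between "unrelated" random proteins
#'   would otherwise corrupt the truth at a rate of roughly
#'   `verify_evalue` per cross-family pair)
#' @param verify_evalue E-value cut-off used by the self-test (default
#'   1e-3, matching the search backend's default)
#' @param rng_seed integer; fully determines the output
#' @return validated spec object of class `synthetic_genome_spec`
#' @export
synthetic_genome_spec <- function(n_genomes = 6, n_core = 15,
                                  n_dup_families = 3, n_accessory = 5,
                                  protein_length = 120, tree = NULL,
                                  divergence = 0.2, subst_rate_scale = 1,
                                  indel_rate = 0, dup_copies = 2,
                                  dup_divergence = 0.05,
                                  verify_unrelated = TRUE,
                                  verify_evalue = 1e-3, rng_seed = 1) {
  stopifnot(n_genomes >= 2, n_core >= 0, n_dup_families >= 0,
            n_accessory >= 0, protein_length >= 10, divergence > 0,
            subst_rate_scale > 0, indel_rate >= 0, indel_rate < 1,
            dup_copies >= 2, dup_divergence >= 0, dup_divergence <= 1,
            is.logical(verify_unrelated), verify_evalue > 0)
  if (n_accessory > 0 && n_genomes < 2)
    stop("accessory genes need >= 2 genomes for a strict subset")
  if (!is.null(tree)) {
    if (!inherits(tree, "phylo")) stop("tree must be an ape::phylo")
    if (is.null(tree$edge.length)) stop("tree must carry branch lengths")
    if (length(tree$tip.label) != n_genomes)
      stop("tree has ", length(tree$tip.label), " tips but n_genomes = ",
           n_genomes)
  }
  structure(list(n_genomes = n_genomes, n_core = n_core,
                 n_dup_families = n_dup_families, n_accessory = n_accessory,
                 protein_length = protein_length, tree = tree,
                 divergence = divergence,
                 subst_rate_scale = subst_rate_scale,
                 indel_rate = indel_rate, dup_copies = dup_copies,
                 dup_divergence = dup_divergence,
                 verify_unrelated = verify_unrelated,
                 verify_evalue = verify_evalue,
                 rng_seed = as.integer(rng_seed)),
            class = "synthetic_genome_spec")
}

random_protein <- function(length) {
  paste(sample(.AA20, length, replace = TRUE), collapse = "")
}

# One branch of evolution on a residue vector: each site substitutes with
# probability 1 - exp(-bl) to a uniformly chosen *different* residue;
# optional indels (deletion / single-residue insertion, each indel_rate/2).
evolve_residues <- function(res, bl, indel_rate = 0) {
  n <- length(res)
  p <- 1 - exp(-bl)
  hit <- runif(n) < p
  if (any(hit)) {
    cur <- match(res[hit], .AA20)
    shift <- sample.int(19L, sum(hit), replace = TRUE)
    res[hit] <- .AA20[((cur - 1L + shift) %% 20L) + 1L]
  }
  if (indel_rate > 0 && n > 1) {
    del <- runif(n) < indel_rate / 2
    if (sum(!del) >= 2) res <- res[!del]
    insmask <- runif(length(res)) < indel_rate / 2
    if (any(insmask)) {
      pieces <- as.list(res)
      newres <- sample(.AA20, sum(insmask), replace = TRUE)
      pieces[insmask] <- Map(c, res[insmask], newres)
      res <- unlist(pieces, use.names = FALSE)
    }
  }
  res
}

# Evolve a root residue vector down a tree; returns list of tip residue
# vectors named by tip label. Preorder traversal so parents are done first.
evolve_along_tree <- function(tree, root_res, indel_rate = 0) {
  nt <- length(tree$tip.label)
  seqs <- vector("list", nt + tree$Nnode)
  seqs[[nt + 1L]] <- root_res
  tr <- ape::reorder.phylo(tree, "cladewise")
  for (k in seq_len(nrow(tr$edge))) {
    p <- tr$edge[k, 1]; ch <- tr$edge[k, 2]
    seqs[[ch]] <- evolve_residues(seqs[[p]], tr$edge.length[k], indel_rate)
  }
  setNames(seqs[seq_len(nt)], tree$tip.label)
}

# Mutate a fixed fraction of sites (used to diverge within-genome
# duplicate copies).
mutate_fraction <- function(res, fraction) {
  n <- length(res)
  k <- max(1L, round(fraction * n))
  pos <- sample.int(n, k)
  cur <- match(res[pos], .AA20)
  shift <- sample.int(19L, k, replace = TRUE)
  res[pos] <- .AA20[((cur - 1L + shift) %% 20L) + 1L]
  res
}

#' Generate a synthetic genome set with planted truth
#'
#' Core genes evolve from family root sequences along the generating tree
#' (single copy everywhere). Each duplicated family is present in all
#' genomes and carries extra within-genome copies (diverged by
#' `dup_divergence`) in one designated genome, making it MULTI there.
#' Accessory genes are random sequences shared identically by a strict
#' subset of genomes and drawn from an RNG stream downstream of the core
#' families, so they share no detectable similarity with them. Output is
#' fully determined by `rng_seed`.
#'
#' @param spec a [synthetic_genome_spec()]
#' @param out_dir optional directory; when given, genomes are written there
#'   in the requested `format` together with `truth.tsv`
#' @param format `"none"`, `"fasta"` (per-genome proteome FASTA), or
#'   `"genbank"` (minimal flat files via [write_genbank()])
#' @param translations include `/translation` qualifiers in GenBank output
#'   (set `FALSE` to exercise conceptual translation)
#' @return list with `genomes` (named list of [genome_record()]),
#'   `truth` (data.frame: genome_id, locus_id, qualified_id, class in
#'   CORE/DUP/ACCESSORY, family), `tree` (the scaled generating tree),
#'   and `spec`
#' @export
generate_genomes <- function(spec, out_dir = NULL,
                             format = c("none", "fasta", "genbank"),
                             translations = TRUE) {
  stopifnot(inherits(spec, "synthetic_genome_spec"))
  format <- match.arg(format)
  with_seed(spec$rng_seed, {
    n <- spec$n_genomes
    gids <- sprintf("g%02d", seq_len(n))
    tree <- spec$tree
    if (is.null(tree)) {
      tree <- ape::rtree(n, tip.label = gids)
      coph <- ape::cophenetic.phylo(tree)
      tree$edge.length <- tree$edge.length *
        (spec$divergence / max(coph))
    }
    tree$edge.length <- tree$edge.length * spec$subst_rate_scale

    # Families are generated as units so a family colliding with another
    # in the similarity self-test can be resampled wholesale. Each family
    # is a per-genome list of residue vectors (length > 1 in the host
    # genome of a duplicated family).
    gen_family <- function(kind, i) {
      root <- strsplit(random_protein(spec$protein_length), "")[[1]]
      if (kind == "CORE") {
        tips <- evolve_along_tree(tree, root, spec$indel_rate)
        members <- lapply(gids, function(g) list(tips[[g]]))
      } else if (kind == "DUP") {
        tips <- evolve_along_tree(tree, root, 0)
        host <- gids[((i - 1L) %% n) + 1L]
        members <- lapply(gids, function(g) {
          copies <- list(tips[[g]])
          if (g == host)
            for (k in seq_len(spec$dup_copies - 1L))
              copies <- c(copies,
                          list(mutate_fraction(tips[[g]],
                                               spec$dup_divergence)))
          copies
        })
      } else {
        res <- root
        size <- sample.int(n - 1L, 1L)
        subset <- sample(gids, size)
        members <- lapply(gids, function(g)
          if (g %in% subset) list(res) else list())
      }
      names(members) <- gids
      prefix <- c(CORE = "core", DUP = "dup", ACCESSORY = "acc")[[kind]]
      list(class = kind, family = sprintf("%s_%03d", prefix, i),
           members = members)
    }

    fams <- c(lapply(seq_len(spec$n_core), gen_family, kind = "CORE"),
              lapply(seq_len(spec$n_dup_families), gen_family, kind = "DUP"),
              lapply(seq_len(spec$n_accessory), gen_family,
                     kind = "ACCESSORY"))

    # Oracle-search self-test: no member of any family may be a similarity
    # hit of another family's member at verify_evalue. Offending families
    # (the later-generated one of each colliding pair) are resampled.
    if (isTRUE(spec$verify_unrelated) && length(fams) > 1) {
      for (round in seq_len(50L)) {
        seqs <- character(0); fidx <- integer(0)
        for (k in seq_along(fams))
          for (g in gids)
            for (res in fams[[k]]$members[[g]]) {
              seqs <- c(seqs, paste(res, collapse = ""))
              fidx <- c(fidx, k)
            }
        coll <- .collision_pairs(seqs, fidx, blosum62(), 11L, 1L,
                                 .KA_LAMBDA, .KA_K, spec$verify_evalue)
        if (nrow(coll) == 0) break
        resample <- sort(unique(pmax(fidx[coll[, 1]], fidx[coll[, 2]])))
        for (k in resample) {
          kind <- fams[[k]]$class
          i <- as.integer(sub("^.*_", "", fams[[k]]$family))
          fams[[k]] <- gen_family(kind, i)
        }
        if (round == 50L)
          stop("fixture self-test failed to converge; widen verify_evalue ",
               "or reduce family counts")
      }
    }

    genes <- setNames(rep(list(list()), n), gids)
    for (fam in fams) {
      for (g in gids) {
        for (res in fam$members[[g]]) {
          genes[[g]][[length(genes[[g]]) + 1L]] <-
            list(res = res, class = fam$class, family = fam$family)
        }
      }
    }

    genomes <- list()
    truth <- list()
    for (g in gids) {
      gl <- genes[[g]]
      if (length(gl) == 0) stop("genome '", g, "' has no genes; increase n_core")
      lids <- sprintf("%s_%04d", g, seq_along(gl))
      prots <- vapply(gl, function(x) paste(x$res, collapse = ""), "")
      genomes[[g]] <- genome_record(g, lids, prots)
      truth[[g]] <- data.frame(
        genome_id = g, locus_id = lids,
        qualified_id = qualified_id(g, lids),
        class = vapply(gl, `[[`, "", "class"),
        family = vapply(gl, `[[`, "", "family"),
        stringsAsFactors = FALSE)
    }
    truth <- do.call(rbind, truth)
    rownames(truth) <- NULL

    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      for (g in gids) {
        if (format == "fasta") write_proteome_fasta(genomes[[g]], out_dir)
        if (format == "genbank")
          write_genbank(genomes[[g]],
                        file.path(out_dir, paste0(g, ".gbk")),
                        translations = translations)
      }
      tl <- c("genome_id\tlocus_id\tqualified_id\tclass\tfamily",
              sprintf("%s\t%s\t%s\t%s\t%s", truth$genome_id, truth$locus_id,
                      truth$qualified_id, truth$class, truth$family))
      write_lines_lf(tl, file.path(out_dir, "truth.tsv"))
    }
    list(genomes = genomes, truth = truth, tree = tree, spec = spec)
  })
}

# Fixed reverse-translation codon per residue (standard code; X -> NNN).
.BACK_CODON <- c(A = "GCT", R = "CGT", N = "AAT", D = "GAT", C = "TGT",
                 Q = "CAA", E = "GAA", G = "GGT", H = "CAT", I = "ATT",
                 L = "CTG", K = "AAA", M = "ATG", F = "TTT", P = "CCT",
                 S = "TCT", T = "ACT", W = "TGG", Y = "TAT", V = "GTT",
                 X = "NNN")

revcomp_chr <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

#' Write a genome record as a minimal GenBank flat file
#'
#' Back-translates each protein with a fixed codon table, appends a stop
#' codon, and lays the genes on a synthetic contig separated by 30-bp
#' spacers. Strands alternate and every fourth CDS uses a two-span
#' `join()` location, so the emitted files exercise the parser's strand
#' and splicing logic. Round-trips through [parse_genbank()].
#'
#' @param genome a [genome_record()]
#' @param path output path
#' @param translations include `/translation` qualifiers (when `FALSE`,
#'   parsing relies on conceptual translation)
#' @param transl_table genetic code id written to `/transl_table`
#' @return `path`, invisibly
#' @export
write_genbank <- function(genome, path, translations = TRUE,
                          transl_table = 11) {
  n <- n_sequences(genome)
  spacer <- strrep("T", 30L)
  seq_parts <- character(0)
  feats <- character(0)
  pos <- 0L

  wrap_qual <- function(text) {
    # qualifier text wrapped at 58 chars, continuations at column 22
    starts <- seq(1L, nchar(text), 58L)
    pieces <- substring(text, starts, pmin(starts + 57L, nchar(text)))
    paste0(strrep(" ", 21L), pieces)
  }

  for (i in seq_len(n)) {
    prot <- genome$sequences$protein[i]
    lid <- genome$sequences$locus_id[i]
    nt <- paste0(paste(.BACK_CODON[strsplit(prot, "")[[1]]], collapse = ""),
                 "TAA")
    seq_parts <- c(seq_parts, spacer)
    pos <- pos + 30L
    start <- pos + 1L
    end <- pos + nchar(nt)
    minus <- i %% 2L == 0L
    seq_parts <- c(seq_parts, if (minus) revcomp_chr(nt) else nt)
    pos <- end
    span <- if (i %% 4L == 3L && nchar(nt) >= 6L) {
      mid <- start + 3L * (((end - start + 1L) %/% 3L) %/% 2L) - 1L
      sprintf("join(%d..%d,%d..%d)", start, mid, mid + 1L, end)
    } else sprintf("%d..%d", start, end)
    loc <- if (minus) paste0("complement(", span, ")") else span
    block <- c(sprintf("     CDS             %s", loc),
               wrap_qual(sprintf("/locus_tag=\"%s\"", lid)),
               wrap_qual(sprintf("/transl_table=%d", transl_table)))
    if (translations)
      block <- c(block, wrap_qual(sprintf("/translation=\"%s\"", prot)))
    feats <- c(feats, block)
  }
  full <- paste(seq_parts, collapse = "")
  total <- nchar(full)

  origin <- vapply(seq(1L, total, 60L), function(s) {
    chunk <- substr(full, s, min(s + 59L, total))
    groups <- substring(chunk, seq(1L, nchar(chunk), 10L),
                        pmin(seq(1L, nchar(chunk), 10L) + 9L, nchar(chunk)))
    sprintf("%9d %s", s, tolower(paste(groups, collapse = " ")))
  }, "")

  lines <- c(
    sprintf("LOCUS       %-16s %d bp    DNA     linear   UNK 01-JAN-2026",
            genome$genome_id, total),
    sprintf("DEFINITION  Synthetic genome %s.", genome$genome_id),
    sprintf("ACCESSION   %s", genome$genome_id),
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", total),
    feats,
    "ORIGIN",
    origin,
    "//")
  write_lines_lf(lines, path)
  invisible(path)
}

#' Simulate a gapless alignment on a tree
#'
#' Root sequence drawn uniformly from the 20-letter alphabet; per branch,
#' each site substitutes with probability `1 - exp(-branch_length)` to a
#' uniformly chosen different residue. No indels. Exactly under this
#' process, two tips joined by branches `b_1..b_k` differ per site with
#' probability `(19/20) * (1 - prod((20 * exp(-b_i) - 1) / 19))`, which
#' approaches the familiar `(19/20) * (1 - exp(-d * 20/19))` at path
#' distance `d` for short branches.
#'
#' @param tree `ape::phylo` with branch lengths
#' @param length number of columns (> 0)
#' @param rng_seed integer seed; fully determines the alignment
#' @return a [locus_alignment()] with one row per tip
#' @export
simulate_alignment <- function(tree, length, rng_seed = 1) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  if (length <= 0) stop("alignment length must be positive")
  with_seed(rng_seed, {
    root <- sample(.AA20, length, replace = TRUE)
    tips <- evolve_along_tree(tree, root, indel_rate = 0)
    locus_alignment("simulated",
                    vapply(tips, paste, "", collapse = ""))
  })
}
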