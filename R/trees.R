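# trees stage: phylogeny inference from the combined supermatrix and,
# optionally, from each per-locus alignment.
#
# The internal backend is neighbour-joining on Poisson-corrected pairwise
# distances — a deterministic, binary-free fallback suitable for testing
# and exploration. External maximum-likelihood tools (FastTree for fast
# runs and per-locus trees, IQ-TREE for a final combined tree) remain the
# recommended production path and are invoked through adapters.

# Rows of anything alignment-like.
alignment_rows <- function(x) {
  if (inherits(x, c("supermatrix", "locus_alignment"))) return(x$rows)
  if (is.character(x) && !is.null(names(x))) return(x)
  stop("expected a supermatrix, locus_alignment, or named character vector")
}

#' Poisson-corrected pairwise distances of aligned protein rows
#'
#' Per pair: p = mismatch fraction over columns where both rows are
#' ungapped; distance = -ln(1 - p). p is clamped at `p_max` (and pairs
#' with no comparable columns are assigned the ceiling) so the correction
#' stays finite.
#'
#' @param x alignment (supermatrix, locus_alignment, or named character)
#' @param p_max clamp on the observed mismatch fraction (default 0.95,
#'   i.e. a distance ceiling of -ln(0.05) ~ 3.0 substitutions/site)
#' @return symmetric numeric matrix with genome dimnames
#' @export
poisson_distances <- function(x, p_max = 0.95) {
  rows <- alignment_rows(x)
  if (length(rows) < 2) stop("need at least two rows")
  cnt <- .pairwise_mismatch(unname(rows))
  p <- ifelse(cnt$compared > 0, cnt$mismatch / cnt$compared, p_max)
  p <- pmin(p, p_max)
  d <- -log(1 - p)
  diag(d) <- 0
  dimnames(d) <- list(names(rows), names(rows))
  d
}

#' Infer a phylogenetic tree from an alignment
#'
#' @param alignment a `supermatrix`, [locus_alignment()], or named
#'   character vector of aligned rows (names become tip labels)
#' @param method `"nj"` (internal neighbour-joining, default),
#'   `"fasttree"`, or `"iqtree"` (external adapters; binary must be on
#'   PATH or given via `exe`)
#' @param out_file optional newick output path
#' @param exe external binary (defaults: `"fasttree"`, `"iqtree2"`)
#' @param partitions optional RAxML-style partition file path, passed to
#'   IQ-TREE as `-p`
#' @return an unrooted `ape::phylo` tree; external backends carry branch
#'   supports in `node.label`, the internal backend emits none rather than
#'   fabricating them
#' @export
build_tree <- function(alignment, method = c("nj", "fasttree", "iqtree"),
                       out_file = NULL, exe = NULL, partitions = NULL) {
  method <- match.arg(method)
  rows <- alignment_rows(alignment)
  if (length(rows) < 3)
    stop("need at least 3 taxa to build a tree (got ", length(rows), ")")
  allgap <- names(rows)[gsub("-", "", rows, fixed = TRUE) == ""]
  if (length(allgap) > 0)
    stop("all-gap alignment row(s) for genome(s): ",
         paste(allgap, collapse = ", "))
  rows <- rows[sort(names(rows))]

  tree <- switch(method,
    nj = {
      d <- poisson_distances(rows)
      tr <- ape::nj(d)
      tr$edge.length[tr$edge.length < 0] <- 0  # standard NJ clean-up
      ape::unroot(tr)
    },
    fasttree = run_fasttree(rows, exe %||% "fasttree"),
    iqtree = run_iqtree(rows, exe %||% "iqtree2", partitions))
  attr(tree, "source") <- method
  if (!is.null(out_file)) {
    dir.create(dirname(out_file), recursive = TRUE, showWarnings = FALSE)
    write_lines_lf(ape::write.tree(tree), out_file)
  }
  tree
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# FastTree convention: protein model by default, alignment file argument,
# newick on stdout (local SH-like supports on internal nodes).
run_fasttree <- function(rows, exe = "fasttree") {
  if (Sys.which(exe) == "")
    stop("external tree backend '", exe, "' not found on PATH")
  fin <- tempfile(fileext = ".fasta")
  on.exit(unlink(fin), add = TRUE)
  write_lines_lf(.fasta_lines(rows), fin)
  err <- tempfile()
  on.exit(unlink(err), add = TRUE)
  out <- suppressWarnings(system2(exe, c("-quiet", fin), stdout = TRUE,
                                  stderr = err))
  if (!is.null(attr(out, "status")))
    stop("fasttree failed: ",
         paste(readLines(err, warn = FALSE), collapse = "\n"))
  ape::unroot(ape::read.tree(text = paste(out, collapse = "")))
}

# IQ-TREE convention: -s alignment, optional -p partition file; tree is
# written to <prefix>.treefile. Model selection is delegated to the tool.
run_iqtree <- function(rows, exe = "iqtree2", partitions = NULL) {
  if (Sys.which(exe) == "")
    stop("external tree backend '", exe, "' not found on PATH")
  fin <- tempfile(fileext = ".fasta")
  prefix <- tempfile()
  on.exit(unlink(c(fin, paste0(prefix, c(".treefile", ".iqtree", ".log",
                                         ".ckp.gz", ".bionj", ".mldist")))),
          add = TRUE)
  write_lines_lf(.fasta_lines(rows), fin)
  args <- c("-s", fin, "--prefix", prefix, "-nt", "1", "--quiet")
  if (!is.null(partitions)) args <- c(args, "-p", partitions)
  out <- suppressWarnings(system2(exe, args, stdout = TRUE, stderr = TRUE))
  tf <- paste0(prefix, ".treefile")
  if (!is.null(attr(out, "status")) || !file.exists(tf))
    stop("iqtree failed: ", paste(out, collapse = "\n"))
  ape::unroot(ape::read.tree(tf))
}

#' Build one tree per selected locus
#'
#' Loci with fewer than 3 taxa are skipped with a warning; a failure on one
#' locus does not abort the rest.
#'
#' @param selection a `locus_selection` (defines the locus set)
#' @param alignments named list of [locus_alignment()]s keyed by locus id
#' @param method,exe as in [build_tree()]
#' @param out_dir optional directory for `<locus>.nwk` files (locus ids are
#'   sanitised for the file system)
#' @return named list of `phylo` trees (skipped/failed loci omitted)
#' @export
build_all_trees <- function(selection, alignments,
                            method = c("nj", "fasttree", "iqtree"),
                            out_dir = NULL, exe = NULL) {
  method <- match.arg(method)
  trees <- list()
  for (locus in selection$loci) {
    aln <- alignments[[locus]]
    if (is.null(aln)) {
      warning("no alignment for locus '", locus, "'; skipped", call. = FALSE)
      next
    }
    if (length(aln$rows) < 3) {
      warning("locus '", locus, "' has ", length(aln$rows),
              " taxa (< 3); skipped", call. = FALSE)
      next
    }
    out_file <- if (is.null(out_dir)) NULL else
      file.path(out_dir, paste0(gsub("[^A-Za-z0-9_.-]", "_", locus), ".nwk"))
    tr <- tryCatch(build_tree(aln, method = method, out_file = out_file,
                              exe = exe),
                   error = function(e) {
                     warning("tree for locus '", locus, "' failed: ",
                             conditionMessage(e), call. = FALSE)
                     NULL
                   })
    if (!is.null(tr)) trees[[locus]] <- tr
  }
  trees
}
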