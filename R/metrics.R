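# Evaluation statistics: parsimony-informative sites, branch-support
# summaries, Robinson-Foulds distances, and the normalised-sum congruence
# statistic over a set of trees.

#' Count parsimony-informative sites
#'
#' A column is parsimony-informative if it has at least two distinct
#' residue states each present in at least two rows. Gaps, `X`, `*` and
#' `?` never count as states. With only two rows no column can qualify.
#'
#' @param alignment `supermatrix`, [locus_alignment()], or named character
#' @return integer count of informative columns
#' @export
count_informative_sites <- function(alignment) {
  rows <- alignment_rows(alignment)
  mat <- do.call(rbind, strsplit(unname(rows), ""))
  mat[mat %in% c("-", "X", "*", "?")] <- NA_character_
  sum(vapply(seq_len(ncol(mat)), function(j) {
    tab <- tabulate(factor(mat[, j]))
    sum(tab >= 2L) >= 2L
  }, logical(1)))
}

#' Summarise branch supports of a tree
#'
#' Mean support and the percentage of internal edges at maximum support
#' (1.0), over exactly the internal edges that carry supports. Supports on
#' a 0-100 (percent bootstrap) scale are detected (any value > 1) and
#' rescaled to \[0, 1\].
#'
#' @param tree an `ape::phylo` with supports in `node.label`
#' @return list with `mean_support`, `fraction_max` (percent), `n_internal`
#' @export
summarize_support <- function(tree) {
  labs <- tree$node.label
  if (is.null(labs))
    stop("tree carries no branch supports; use a support-emitting backend ",
         "(e.g. fasttree)")
  labs <- labs[-1]  # drop the root/basal node: it subtends no internal edge
  sup <- suppressWarnings(as.numeric(labs))
  sup <- sup[!is.na(sup)]
  if (length(sup) == 0)
    stop("tree carries no numeric branch supports; use a support-emitting ",
         "backend (e.g. fasttree)")
  if (any(sup > 1)) sup <- sup / 100
  list(mean_support = mean(sup),
       fraction_max = 100 * mean(sup == 1),
       n_internal = length(sup))
}

# Non-trivial bipartitions of an unrooted tree as canonical string keys.
# Each internal edge splits the tips in two; the key is the sorted side not
# containing the lexicographically smallest tip label.
tree_bipartitions <- function(tree) {
  tree <- ape::unroot(tree)
  tips <- tree$tip.label
  nt <- length(tips)
  nn <- tree$Nnode
  desc <- vector("list", nt + nn)
  for (i in seq_len(nt)) desc[[i]] <- tips[i]
  po <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(po$edge))) {
    p <- po$edge[k, 1]; ch <- po$edge[k, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  ref <- min(tips)
  keys <- character(0)
  root <- nt + 1L
  for (v in seq.int(nt + 1L, nt + nn)) {
    if (v == root) next
    clade <- desc[[v]]
    if (length(clade) < 2L || length(clade) > nt - 2L) next
    side <- if (ref %in% clade) setdiff(tips, clade) else clade
    keys <- c(keys, paste(sort(side), collapse = "\r"))
  }
  unique(keys)
}

#' Robinson-Foulds distance between two trees
#'
#' Computed on the shared-tip restriction of both trees: the size of the
#' symmetric difference of their non-trivial bipartition sets. Maximum is
#' `2 * (n - 3)` for `n` shared tips.
#'
#' @param a,b `ape::phylo` trees with >= 4 shared tips
#' @return object of class `rf_result`: list with `rf` (even integer),
#'   `max_rf`, `normalized` (`rf / max_rf` in \[0, 1\]), `n_shared`
#' @export
robinson_foulds <- function(a, b) {
  shared <- intersect(a$tip.label, b$tip.label)
  if (length(shared) < 4)
    stop("Robinson-Foulds distance undefined: fewer than 4 shared tips (",
         length(shared), ")")
  ra <- ape::keep.tip(a, shared)
  rb <- ape::keep.tip(b, shared)
  sa <- tree_bipartitions(ra)
  sb <- tree_bipartitions(rb)
  rf <- length(setdiff(sa, sb)) + length(setdiff(sb, sa))
  max_rf <- 2L * (length(shared) - 3L)
  structure(list(rf = rf, max_rf = max_rf,
                 normalized = if (max_rf > 0) rf / max_rf else 0,
                 n_shared = length(shared)),
            class = "rf_result")
}

#' @export
print.rf_result <- function(x, ...) {
  cat("RF = ", x$rf, " / ", x$max_rf, " (normalized ",
      format(x$normalized, digits = 4), ", ", x$n_shared, " shared tips)\n",
      sep = "")
  invisible(x)
}

#' Normalised-sum Robinson-Foulds congruence (NSUMRF)
#'
#' Mean of the normalized RF distances from a reference tree to every
#' other tree in the set: 0 when all trees agree with the reference, 1
#' when the reference is maximally distant from each of them.
#'
#' @param trees list of `ape::phylo` trees (>= 2)
#' @param reference_index which tree is the reference (default 1)
#' @return numeric in \[0, 1\]
#' @export
nsumrf <- function(trees, reference_index = 1) {
  if (length(trees) < 2) stop("need at least 2 trees")
  stopifnot(reference_index >= 1, reference_index <= length(trees))
  ref <- trees[[reference_index]]
  others <- trees[-reference_index]
  mean(vapply(others, function(t) robinson_foulds(ref, t)$normalized,
              numeric(1)))
}

#' Per-locus congruence report against a combined tree
#'
#' Normalized RF of every per-locus tree versus the combined tree; loci
#' whose restriction leaves fewer than 4 shared tips get `NA`.
#'
#' @param locus_trees named list of per-locus `phylo` trees
#' @param combined_tree the combined-alignment tree
#' @param path optional TSV output path
#' @return data.frame with columns locus_id, rf, max_rf, normalized
#' @export
congruence_report <- function(locus_trees, combined_tree, path = NULL) {
  res <- lapply(names(locus_trees), function(l) {
    r <- tryCatch(robinson_foulds(locus_trees[[l]], combined_tree),
                  error = function(e) NULL)
    data.frame(locus_id = l,
               rf = if (is.null(r)) NA_integer_ else r$rf,
               max_rf = if (is.null(r)) NA_integer_ else r$max_rf,
               normalized = if (is.null(r)) NA_real_ else r$normalized,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (!is.null(path)) {
    lines <- c("locus_id\trf\tmax_rf\tnormalized",
               sprintf("%s\t%s\t%s\t%s", out$locus_id, out$rf, out$max_rf,
                       ifelse(is.na(out$normalized), "NA",
                              format(out$normalized, digits = 6))))
    write_lines_lf(lines, path)
  }
  out
}
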