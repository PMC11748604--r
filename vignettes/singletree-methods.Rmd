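---
title: "singletree: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{singletree: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the heuristic

Multi-locus (genome-scale) phylogenies need orthologous loci: genes related
by speciation, not duplication. Classical orthology inference — reciprocal
best hits plus clustering — is expensive and hard to tune. `singletree`
implements a strict single-copy heuristic instead: a gene is usable only if
it is a **singleton**, i.e. has no similarity hit other than itself, within
its own genome; and it is kept only if it is a singleton in (essentially)
*every* input genome. Under this rule every cross-genome match is
automatically a reciprocal best hit, so orthologue clustering is skipped
entirely. The price is that any gene with a paralogue anywhere is
discarded, which in gene-rich genomes throws away potentially informative
loci — a deliberate trade of sensitivity for speed and robustness against
paralogue contamination.

The pipeline has four stages, each exposed as ordinary functions and
orchestrated by `run_pipeline()`:

1. **extract** — parse GenBank flat files (or per-genome protein FASTA),
   one genome per file, into protein collections keyed by a configurable
   qualifier (`tag`, default `locus_tag`).
2. **screen** — find singletons in a seed genome, query each against every
   genome, and select loci by presence.
3. **align** — align each locus independently and concatenate into a
   partitioned supermatrix.
4. **trees** — infer the combined tree (and optionally one tree per locus
   for congruence assessment).

## Extraction choices

* Proteins come from `/translation` when present; otherwise the spliced
  nucleotide span (`join()`/`complement()` semantics) is translated with
  the feature's `/transl_table`. Translation is literal, codon by codon:
  initiator-codon remapping to M is *not* applied, because an annotated
  CDS normally carries `/translation` anyway and a literal translation
  keeps the conceptual path deterministic and testable.
* CDS features lacking the chosen tag are skipped and counted, not fatal;
  a file with zero usable CDS is an error naming the file and the tag.
* Duplicate locus ids keep the first occurrence (screening needs unique
  keys; later duplicates are almost always annotation artifacts). Loci are
  qualified internally as `genome|locus` so cross-genome id collisions are
  impossible; genome ids come from file names and must be unique.
* Non-standard residues (B, Z, U, O) map to X on ingestion so every
  sequence scores under BLOSUM62.

## The search backend and its statistics

The internal backend is an exact Smith–Waterman (BLOSUM62, affine gaps,
open 11 / extend 1 — a gap of length $L$ costs $11 + L$) with
Karlin–Altschul E-values

$$E = K \, m \, n \, e^{-\lambda S}, \qquad \lambda = 0.267,\; K = 0.041,$$

the standard gapped BLOSUM62/11/1 constants. The search space is the
*pair* space $m \times n$ (query length × subject length), not query ×
database size: this makes hits exactly symmetric (A hits B iff B hits A at
the same threshold), which the screening logic relies on. Consequences to
be aware of: E-values are a constant factor smaller than BLAST-style
database-scaled values, and at a fixed threshold $t$ the expected number
of chance hits grows with the number of *pairs* examined (about $t$ per
pair) rather than per query. The default threshold is `max_evalue = 1e-3`,
a conventional homologue-detection cut-off; only the hit/no-hit decision
feeds the pipeline, so exact agreement with DIAMOND is not required.

The self-hit is guaranteed by construction: if a query's own entry falls
over the threshold (very short proteins), it is re-inserted, so "hit count
== 1" always means "no homologue other than itself" regardless of backend.
An external DIAMOND-style backend can be substituted (`--backend diamond`);
it is never chosen silently, and its tabular output (5- or 12-column) is
parsed into the same hit records with the self-hit enforced.

## Screening rules

* **Seed genome**: lexicographically first genome id by default,
  overridable, or a seeded random choice — determinism first.
* **Presence**: a locus needs `ceiling(presence/100 * n_genomes)` SINGLETON
  cells (ties resolve toward inclusion at exact equality). Default 100.
* **MULTI disqualifies outright** even when `presence < 100`: a cell with
  two or more hits marks a paralogous family, which is precisely the
  contamination the method exists to avoid. Counting MULTI as merely absent
  would let family members back in through the presence loophole.
* **maxloci**: deterministic lexicographic truncation, or a seeded uniform
  sample; the selected set is always emitted in lexicographic order, which
  fixes concatenation order downstream.
* The full presence matrix is written as a TSV audit report
  (`S:<best match>` / `M` / `A`) so every locus's fate is inspectable.

## Alignment and the supermatrix

Each locus is aligned independently. The default aligner is an internal
deterministic progressive aligner (Needleman–Wunsch against the running
profile, BLOSUM62, gap open 10 / extend 1, guide order = lexicographic
genome id, fixed tie-breaks) so the whole pipeline — and its tests — run
without external binaries. MUSCLE3 (`-in/-out`), MUSCLE5
(`-align/-output`) and MAFFT adapters are provided for production use; the
aligned rows are verified to ungap back to the input sequences whichever
backend ran.

Concatenation is in lexicographic locus order (the original tool's order
is unstated; determinism required). A genome missing from a locus receives
a gap run of that locus's aligned length. Partitions tile `[1, length]`
exactly and are emitted both as RAxML-style lines
(`PROT, <locus> = <start>-<end>`) and as a NEXUS `sets` block. No trimming
or masking is applied. All writers emit LF line endings so identical
inputs give byte-identical files.

## Trees

The internal backend is neighbour-joining on Poisson-corrected distances:
for each pair, the mismatch fraction $p$ over columns where both rows are
ungapped, corrected as $d = -\ln(1-p)$, with $p$ clamped at 0.95 (distance
ceiling $-\ln 0.05 \approx 3.0$; pairs with no comparable columns get the
ceiling). Negative NJ branch lengths are clamped to zero. The internal
backend emits **no** branch supports rather than fabricating them.
External adapters follow FastTree conventions (alignment file in, newick
with local supports on stdout; recommended for exploration and per-locus
trees) and IQ-TREE conventions (`-s` alignment, optional `-p` partitions;
recommended for the final combined tree), with each tool's default model.

## Metrics

* **Parsimony-informative sites**: columns with ≥ 2 residue states each in
  ≥ 2 rows; gaps, `X`, `*`, `?` are never states.
* **Support summary**: mean and percent-at-maximum over exactly the
  internal edges carrying supports; 0–100-scale supports (any value > 1)
  are rescaled to [0, 1].
* **Robinson–Foulds**: symmetric difference of non-trivial bipartition
  sets on the shared-tip restriction; maximum $2(n-3)$; undefined below 4
  shared tips.
* **NSUMRF**: the congruence statistic is implemented as the *mean* of
  normalized pairwise RF distances from a reference tree to all others.
  The original publication names the statistic but never defines its
  normalization; a mean of normalized distances lies in [0, 1], consistent
  with the values the method's authors report, whereas a raw sum would
  not. This is a documented interpretation, not a claim about the original
  implementation.

## The synthetic-genome generator

`generate_genomes()` plants a known truth: a single-copy core (one
orthologue per genome, evolved from family roots along a known tree),
duplicated families (present everywhere, with extra ~5%-diverged copies in
one host genome each — enough divergence to be distinct, close enough to
stay mutual hits), and accessory genes (shared identically by a strict
subset of genomes). Substitutions follow a Jukes–Cantor-style process on
the 20-letter alphabet: per branch, each site substitutes with probability
$1 - e^{-b}$ to a uniformly chosen different residue; two tips joined by
branches $b_1 \ldots b_k$ then differ per site with probability exactly
$\tfrac{19}{20}\bigl(1 - \prod_i \tfrac{20 e^{-b_i} - 1}{19}\bigr)$, the
closed form the simulator tests pin down. Optional per-site indels
exercise the aligners. Defaults (6 genomes, 15 core, 3 duplicated
families, 5 accessory, 120 residues, maximum pairwise divergence 0.2
substitutions/site) describe the moderate-divergence regime in which the
single-copy heuristic is intended to operate.

**The unrelatedness self-test.** A planted truth table is only true if
"different families" are actually undetectable as homologues. Chance local
alignments between random proteins cross an E ≤ 1e-3 cut-off at a rate of
roughly the E-value per pair, and a realistic fixture exposes thousands of
cross-family pairs — so without intervention, about one "unrelated" pair
per generated genome set would be a genuine statistical homology hit and
the truth table would be wrong. The generator therefore scans all
cross-family pairs with the exact search backend and resamples the
later-generated family of any colliding pair until no detectable
cross-family similarity remains (`verify_unrelated = TRUE`,
`verify_evalue = 1e-3`). This is part of the generator's contract, not a
test-tuning device: it makes the planted labels mean what they claim.

What the generator does **not** emulate: codon usage, gene order and
synteny, horizontal transfer, pseudogenes, annotation errors beyond the
parser tests, and realistic residue composition (sequences are uniform
over the 20 residues, so BLOSUM62 E-values are, if anything, conservative
on real data). A green test establishes the machinery is correct on the
stated world; it does not certify accuracy on any particular real dataset.

## Checkpoints and determinism

Checkpoints are stage-level and content-hashed: a stage is skipped only if
it is marked done *and* every recorded output still has its recorded md5
(timestamps are never consulted, so copied or restored trees resume
correctly). Any change to the analysis parameters invalidates all
checkpoints. `stop_after=` ends a run after a chosen stage — the
mechanism used to test interruption/resume equivalence — and `resume_from()`
re-runs from a chosen stage after verifying prerequisites (extract and
databases may be rebuilt from the inputs, which is what makes
proteome-only input work; screen and align must genuinely be
checkpointed). With internal backends the pipeline is bytewise
deterministic: same inputs and parameters give byte-identical supermatrix,
partition and newick files. The `cpus` option is accepted for interface
compatibility; execution is serial and outputs never depend on it.

## Known limitations

* The singleton heuristic discards any locus with a paralogue in even one
  genome; on large genome sets the usable core can shrink to nothing —
  the method is not suited to tens of thousands of genomes.
* Incomplete assemblies can promote a duplicated gene to apparent
  singleton; quality-filter inputs first.
* The internal NJ backend is a fallback for testing and exploration;
  maximum-likelihood tools remain the recommended production path.
* E-values use the ungapped-approximation Karlin–Altschul constants with
  the gapped scoring system and no composition correction: fine for
  copy-number decisions, not a substitute for BLAST statistics.
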