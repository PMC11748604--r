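# Pipeline orchestration: extract -> databases -> screen -> align -> trees,
# with a content-hashed, stage-level checkpoint system. Checkpoints store
# md5 fingerprints of every stage output (not timestamps), so restarts are
# correct even after files are copied; any change to the analysis
# parameters invalidates all checkpoints.

.STAGES <- c("extract", "databases", "screen", "align", "trees")

.GENBANK_EXT <- c("gb", "gbk", "gbf", "gbff", "genbank")
.FASTA_EXT <- c("fa", "faa", "fasta")

hash_object <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeBin(serialize(x, NULL, version = 2), f)
  unname(tools::md5sum(f))
}

hash_files <- function(paths, root) {
  h <- tools::md5sum(paths)
  setNames(unname(h), sub(paste0("^", root, "/?"), "", paths))
}

cp_load <- function(output_dir) {
  path <- file.path(output_dir, "checkpoints.json")
  if (!file.exists(path))
    return(list(version = 1L, fingerprint = NULL, parameters = NULL,
                stages = list()))
  jsonlite::read_json(path, simplifyVector = FALSE)
}

cp_save <- function(state, output_dir) {
  jsonlite::write_json(state, file.path(output_dir, "checkpoints.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(state)
}

# A stage checkpoint is valid only if it is marked done and every recorded
# output still has its recorded content hash.
cp_valid <- function(state, stage, output_dir) {
  st <- state$stages[[stage]]
  if (is.null(st) || !isTRUE(st$done)) return(FALSE)
  files <- unlist(st$files)
  if (length(files) == 0) return(TRUE)
  paths <- file.path(output_dir, names(files))
  if (!all(file.exists(paths))) return(FALSE)
  all(unname(tools::md5sum(paths)) == unname(files))
}

list_genome_files <- function(input_dir, input_format) {
  all <- list.files(input_dir, full.names = TRUE)
  all <- all[!dir.exists(all)]
  ext <- tolower(tools::file_ext(all))
  gb <- all[ext %in% .GENBANK_EXT]
  fa <- all[ext %in% .FASTA_EXT]
  if (input_format == "auto")
    input_format <- if (length(gb) > 0) "genbank" else "fasta"
  files <- if (input_format == "genbank") gb else fa
  if (length(files) < 3)
    stop("need at least 3 parseable genome files in ", input_dir,
         " (found ", length(files), " ", input_format, " files)")
  ids <- tools::file_path_sans_ext(basename(files))
  if (anyDuplicated(ids))
    stop("genome id collision across input files: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  list(files = sort(files), format = input_format)
}

locus_file_name <- function(qid) {
  paste0(gsub("[^A-Za-z0-9_.-]", "_", split_qualified_id(qid)$locus_id),
         ".fasta")
}

#' Run the full pipeline
#'
#' Executes extract, databases, screen, align and trees over a directory of
#' annotated GenBank files (or per-genome protein FASTA files), honouring
#' stage checkpoints: completed stages whose outputs are intact are
#' skipped, so re-running after an interruption continues where the run
#' stopped and a re-run of a finished analysis is a no-op.
#'
#' @param input_dir directory with >= 3 genome files
#' @param output_dir run output directory (default
#'   `<input_dir>/singletree_out`)
#' @param tag GenBank qualifier supplying locus identifiers
#' @param presence presence threshold percentage in (0, 100]
#' @param maxloci cap on selected loci (`Inf` = unlimited)
#' @param seed_genome genome id whose singletons seed the screen
#'   (default: lexicographically first genome)
#' @param build_all also build one tree per locus and a congruence report
#' @param search_backend `"internal"` (exact Smith-Waterman) or
#'   `"diamond"` (external binary required)
#' @param aligner `"internal"`, `"muscle"`, or `"mafft"`
#' @param tree_method `"nj"`, `"fasttree"`, or `"iqtree"`
#' @param max_evalue homology E-value cut-off
#' @param rng_seed optional seed (used for seeded maxloci sampling and
#'   `seed_genome = "random"`)
#' @param cpus accepted for interface compatibility; stages execute
#'   serially and outputs never depend on this value
#' @param input_format `"auto"`, `"genbank"`, or `"fasta"` (proteome mode)
#' @param resume stage name: require all earlier stages checkpointed and
#'   re-run from this stage onward (see [resume_from()])
#' @param stop_after stage name: stop the run after this stage completes
#'   (checkpoints are kept, so a later run resumes)
#' @param quiet suppress progress messages (the run log is always written)
#' @return invisibly, a list with the run's `params`, `output_dir`, and
#'   paths of key outputs
#' @export
run_pipeline <- function(input_dir,
                         output_dir = file.path(input_dir, "singletree_out"),
                         tag = "locus_tag", presence = 100, maxloci = Inf,
                         seed_genome = NULL, build_all = FALSE,
                         search_backend = c("internal", "diamond"),
                         aligner = c("internal", "muscle", "mafft"),
                         tree_method = c("nj", "fasttree", "iqtree"),
                         max_evalue = 1e-3, rng_seed = NULL, cpus = 1L,
                         input_format = c("auto", "genbank", "fasta"),
                         resume = NULL, stop_after = NULL, quiet = TRUE) {
  search_backend <- match.arg(search_backend)
  aligner <- match.arg(aligner)
  tree_method <- match.arg(tree_method)
  input_format <- match.arg(input_format)
  if (!is.null(resume)) resume <- match.arg(resume, .STAGES)
  if (!is.null(stop_after)) stop_after <- match.arg(stop_after, .STAGES)
  if (!dir.exists(input_dir)) stop("input directory not found: ", input_dir)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  logfile <- file.path(output_dir, "run.log")

  # parameters that define the analysis (checkpoint-invalidating)
  params <- list(tag = tag, presence = presence,
                 maxloci = if (is.finite(maxloci)) maxloci else "unlimited",
                 seed_genome = seed_genome, build_all = build_all,
                 search_backend = search_backend, aligner = aligner,
                 tree_method = tree_method, max_evalue = max_evalue,
                 rng_seed = rng_seed, input_format = input_format)
  fp <- hash_object(params)

  state <- cp_load(output_dir)
  if (!identical(state$fingerprint, fp)) {
    if (!is.null(state$fingerprint))
      st_log("parameters changed; invalidating all checkpoints",
             logfile = logfile, quiet = quiet)
    state <- list(version = 1L, fingerprint = fp, parameters = params,
                  stages = list())
  }

  done <- vapply(.STAGES, cp_valid, logical(1), state = state,
                 output_dir = output_dir)
  run_stage <- !done
  if (!is.null(resume)) {
    idx <- match(resume, .STAGES)
    # extract/databases are rebuildable from the inputs; screen and align
    # must genuinely be checkpointed before a later resume.
    if (idx > 1) {
      need <- .STAGES[seq_len(idx - 1L)]
      hard <- setdiff(need, c("extract", "databases"))
      missing <- hard[!done[hard]]
      if (length(missing) > 0)
        stop("cannot resume from '", resume, "': prerequisite stage '",
             missing[1], "' is not checkpoint-complete")
    }
    run_stage[seq_len(length(.STAGES)) >= idx] <- TRUE
  }
  if (!is.null(stop_after))
    run_stage[seq_along(.STAGES) > match(stop_after, .STAGES)] <- FALSE

  for (p in names(params))
    st_log("param ", p, " = ",
           paste(format(params[[p]]), collapse = ","), logfile = logfile,
           quiet = TRUE)

  fasta_dir <- file.path(output_dir, "fasta")
  db_dir <- file.path(output_dir, "dmnd")
  screen_dir <- file.path(output_dir, "screen")
  align_dir <- file.path(output_dir, "aligns")
  tree_dir <- file.path(output_dir, "trees")

  genomes <- NULL
  dbs <- NULL
  selection <- NULL
  alignments <- NULL
  sm <- NULL

  load_genomes <- function() {
    files <- sort(list.files(fasta_dir, pattern = "\\.fasta$",
                             full.names = TRUE))
    if (length(files) == 0)
      stop("stage 'extract' produced no proteomes under ", fasta_dir)
    gs <- lapply(files, read_proteome_fasta)
    setNames(gs, vapply(gs, function(g) g$genome_id, ""))
  }

  finish_stage <- function(stage, files) {
    state$stages[[stage]] <<- list(done = TRUE,
                                   files = as.list(hash_files(files,
                                                              output_dir)))
    cp_save(state, output_dir)
    st_log("stage '", stage, "' complete (", length(files), " files)",
           logfile = logfile, quiet = quiet)
  }

  # ---- extract ----
  if (run_stage[["extract"]]) {
    inp <- list_genome_files(input_dir, input_format)
    st_log("extract: ", length(inp$files), " ", inp$format, " files",
           logfile = logfile, quiet = quiet)
    dir.create(fasta_dir, showWarnings = FALSE)
    genomes <- list()
    for (f in inp$files) {
      g <- if (inp$format == "genbank") parse_genbank(f, tag = tag,
                                                      quiet = quiet)
           else read_proteome_fasta(f)
      if (g$genome_id %in% names(genomes))
        stop("genome id collision: ", g$genome_id)
      genomes[[g$genome_id]] <- g
    }
    written <- vapply(genomes, write_proteome_fasta, "", out_dir = fasta_dir)
    finish_stage("extract", written)
  } else {
    st_log("stage 'extract' checkpointed; skipping", logfile = logfile,
           quiet = quiet)
  }
  if (any(run_stage[c("databases", "screen", "align", "trees")]) &&
      is.null(genomes))
    genomes <- load_genomes()

  # ---- databases ----
  if (run_stage[["databases"]]) {
    st_log("databases: building ", length(genomes), " protein databases",
           logfile = logfile, quiet = quiet)
    dbs <- lapply(genomes, build_database, dir = db_dir)
    finish_stage("databases",
                 vapply(dbs, function(d) d$path, ""))
  } else if (run_stage[["screen"]]) {
    dbs <- lapply(sort(list.files(db_dir, pattern = "\\.fasta$",
                                  full.names = TRUE)), load_database)
    dbs <- setNames(dbs, vapply(dbs, function(d) d$genome_id, ""))
  }

  # ---- screen ----
  selection_path <- file.path(screen_dir, "selection.json")
  if (run_stage[["screen"]]) {
    seed <- seed_genome
    if (is.null(seed)) seed <- sort(names(genomes))[1]
    else if (identical(seed, "random"))
      seed <- with_seed(rng_seed, sample(names(genomes), 1))
    if (!seed %in% names(genomes))
      stop("seed genome '", seed, "' is not among the inputs")
    st_log("screen: seed genome ", seed, ", max_evalue ", max_evalue,
           logfile = logfile, quiet = quiet)
    singletons <- find_singletons(dbs[[seed]], max_evalue = max_evalue,
                                  backend = search_backend)
    st_log("screen: ", length(singletons), " singletons in seed",
           logfile = logfile, quiet = quiet)
    pm <- screen_loci(singletons, genomes, dbs, max_evalue = max_evalue,
                      backend = search_backend)
    selection <- select_loci(pm, presence_threshold = presence,
                             maxloci = maxloci, rng_seed = rng_seed)
    st_log("screen: selected ", length(selection$loci), " loci (presence >= ",
           presence, "%)", logfile = logfile, quiet = quiet)
    dir.create(screen_dir, showWarnings = FALSE)
    pm_path <- file.path(screen_dir, "presence_matrix.tsv")
    write_presence_matrix(pm, pm_path)
    sel_path <- file.path(screen_dir, "selected_loci.txt")
    write_lines_lf(selection$loci, sel_path)
    jsonlite::write_json(
      list(loci = selection$loci,
           # as.list keeps the genome names as JSON object keys
           members = lapply(selection$members, as.list),
           presence_threshold = selection$presence_threshold,
           maxloci = if (is.finite(selection$maxloci)) selection$maxloci
                     else "unlimited",
           seed_genome = selection$seed_genome),
      selection_path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
    finish_stage("screen", c(pm_path, sel_path, selection_path))
  } else if (any(run_stage[c("align", "trees")])) {
    sj <- jsonlite::read_json(selection_path, simplifyVector = FALSE)
    selection <- structure(list(
      loci = unlist(sj$loci),
      members = lapply(sj$members, function(m)
        setNames(unlist(m), names(m))),
      presence_threshold = sj$presence_threshold,
      maxloci = if (identical(sj$maxloci, "unlimited")) Inf else sj$maxloci,
      seed_genome = sj$seed_genome), class = "locus_selection")
  }

  # ---- align ----
  index_path <- file.path(align_dir, "index.tsv")
  if (run_stage[["align"]]) {
    st_log("align: ", length(selection$loci), " loci with '", aligner,
           "' aligner", logfile = logfile, quiet = quiet)
    dir.create(align_dir, showWarnings = FALSE)
    unaln_dir <- file.path(align_dir, "unaligned")
    dir.create(unaln_dir, showWarnings = FALSE)
    alignments <- list()
    files <- character(0)
    for (locus in selection$loci) {
      seqs <- gather_locus(selection, locus, genomes)
      up <- file.path(unaln_dir, locus_file_name(locus))
      write_lines_lf(as.vector(rbind(paste0(">", names(seqs)),
                                     unname(seqs))), up)
      aln <- align_locus(seqs, aligner = aligner, locus_id = locus)
      ap <- file.path(align_dir, locus_file_name(locus))
      write_alignment_fasta(aln, ap)
      alignments[[locus]] <- aln
      files <- c(files, up, ap)
    }
    write_lines_lf(c("locus_id\tfile",
                     sprintf("%s\t%s", selection$loci,
                             vapply(selection$loci, locus_file_name, ""))),
                   index_path)
    sm <- concatenate_alignments(alignments, names(genomes))
    smf <- write_supermatrix(sm, align_dir)
    finish_stage("align", c(files, index_path, unname(smf)))
  } else if (run_stage[["trees"]]) {
    idx <- read.delim(index_path, stringsAsFactors = FALSE)
    alignments <- lapply(seq_len(nrow(idx)), function(i) {
      aa <- read_alignment_fasta(file.path(align_dir, idx$file[i]),
                                 idx$locus_id[i])
      aa
    })
    names(alignments) <- idx$locus_id
    sm <- read_supermatrix(align_dir)
  }

  # ---- trees ----
  if (run_stage[["trees"]]) {
    st_log("trees: combined tree via '", tree_method, "'",
           logfile = logfile, quiet = quiet)
    dir.create(tree_dir, showWarnings = FALSE)
    combined_path <- file.path(tree_dir, "combined.nwk")
    combined <- build_tree(sm, method = tree_method,
                           out_file = combined_path)
    files <- combined_path
    if (isTRUE(build_all)) {
      lt <- build_all_trees(selection, alignments, method = tree_method,
                            out_dir = tree_dir)
      files <- c(files,
                 file.path(tree_dir,
                           paste0(gsub("[^A-Za-z0-9_.-]", "_", names(lt)),
                                  ".nwk")))
      if (length(lt) > 0) {
        cr_path <- file.path(tree_dir, "congruence.tsv")
        congruence_report(lt, combined, path = cr_path)
        files <- c(files, cr_path)
      }
    }
    finish_stage("trees", files)
  }

  manifest <- list(layout_version = 1L,
                   directories = list(fasta = "fasta", databases = "dmnd",
                                      screen = "screen", align = "aligns",
                                      trees = "trees"),
                   parameters = params)
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  if (!is.null(stop_after)) {
    st_log("stopping after stage '", stop_after, "' as requested",
           logfile = logfile, quiet = quiet)
  }
  invisible(list(params = params, output_dir = output_dir,
                 combined_tree = file.path(tree_dir, "combined.nwk"),
                 supermatrix = file.path(align_dir, "combined.fasta"),
                 partitions = file.path(align_dir, "partitions.txt")))
}

#' Resume a pipeline run from a given stage
#'
#' All stages before `stage` must be checkpoint-complete with matching
#' parameters (extract and databases may instead be rebuilt from the
#' inputs — in proteome mode a directory of per-genome FASTA files
#' satisfies them); otherwise the first unsatisfied stage is named in the
#' error. Stages from `stage` onward are re-executed.
#'
#' @param stage one of extract, databases, screen, align, trees
#' @param input_dir,output_dir,... passed to [run_pipeline()]
#' @return see [run_pipeline()]
#' @export
resume_from <- function(stage, input_dir,
                        output_dir = file.path(input_dir, "singletree_out"),
                        ...) {
  run_pipeline(input_dir, output_dir, resume = stage, ...)
}

# Re-load alignment artifacts written by the align stage.
read_alignment_fasta <- function(path, locus_id) {
  aa <- Biostrings::readAAStringSet(path)
  locus_alignment(locus_id,
                  setNames(as.character(aa),
                           vapply(strsplit(names(aa), "\\s+"), `[`, "", 1L)))
}

read_supermatrix <- function(align_dir) {
  aa <- Biostrings::readAAStringSet(file.path(align_dir, "combined.fasta"))
  rows <- setNames(as.character(aa),
                   vapply(strsplit(names(aa), "\\s+"), `[`, "", 1L))
  pl <- readLines(file.path(align_dir, "partitions.txt"), warn = FALSE)
  m <- regmatches(pl, regexec("^PROT, (.+) = ([0-9]+)-([0-9]+)$", pl))
  parts <- data.frame(locus_id = vapply(m, `[`, "", 2L),
                      start = as.integer(vapply(m, `[`, "", 3L)),
                      end = as.integer(vapply(m, `[`, "", 4L)),
                      stringsAsFactors = FALSE)
  structure(list(rows = rows, partitions = parts,
                 length = unique(nchar(rows))),
            class = "supermatrix")
}

#' Run-time stage ordering of the pipeline
#' @return character vector of stage names in execution order
#' @export
pipeline_stages <- function() .STAGES
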