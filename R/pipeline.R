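# End-to-end orchestration: redundancy reduction, cross-family screen,
# chain verification, superfamily assignment, trees, profiles, strand
# counts and repeat scans, with TSV/Newick outputs and a run log.

#' Default pipeline configuration
#'
#' Defaults are the standard analysis settings: BLOSUM62 with gap
#' creation 8 / extension 2, 2000 shuffles, a 12 SD threshold over >= 60
#' residue segments, 85\% redundancy cutoff (70\% for plots/trees), 100
#' consensus replicates.
#'
#' @return named list of configuration values.
#' @export
defaultPipelineConfig <- function() {
  list(matrix = "BLOSUM62", gapOpen = 8L, gapExtend = 2L,
       shuffles = 2000L, sdThreshold = 12, minSeg = 60L,
       redundancyCutoff = 0.85, plotCutoff = 0.70,
       replicates = 100L, topK = 10L, seed = 1L)
}

#' Read a plain key-value configuration file
#'
#' Lines of the form \code{key = value}; \code{#} starts a comment.
#' Unknown keys error; missing keys take defaults.
#'
#' @param path config file path.
#' @return named list merged over \code{\link{defaultPipelineConfig}}.
#' @export
readPipelineConfig <- function(path) {
  cfg <- defaultPipelineConfig()
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(kv) != 2L)
      stop("malformed config line: ", ln, call. = FALSE)
    key <- trimws(kv[1L]); val <- trimws(kv[2L])
    if (!key %in% names(cfg))
      stop("unknown config key: ", key, call. = FALSE)
    cfg[[key]] <- if (key == "matrix") val else as.numeric(val)
  }
  for (k in c("gapOpen", "gapExtend", "shuffles", "minSeg", "replicates",
              "topK", "seed"))
    cfg[[k]] <- as.integer(cfg[[k]])
  cfg
}

#' Write a configuration file
#'
#' @param cfg configuration list.
#' @param path output path.
#' @export
writePipelineConfig <- function(cfg, path) {
  writeLines(sprintf("%s = %s", names(cfg),
                     vapply(cfg, as.character, character(1))), path)
  invisible(path)
}

.stage <- function(name, log, expr) {
  log(sprintf("[%s] start", name))
  res <- tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
  log(sprintf("[%s] done", name))
  res
}

#' Run the full family-analysis pipeline
#'
#' Executes, in order: redundancy reduction per family, the cross-family
#' homology screen (rapid local search, shuffle-score confirmation,
#' automatic transitive chains), superfamily assignment, protein- and
#' family-level score trees, per-family profiles and strand counts, and a
#' hairpin repeat scan of each family representative. All outputs are
#' written under \code{outdir} as TSV / Newick / FASTA text, together
#' with a run log recording the seeds and effective configuration; a
#' stage failure aborts with a stage-named error, retaining partial
#' outputs.
#'
#' @param inputs named list of family inputs: FASTA paths or
#'   \code{AAStringSet}s (>= 2 families).
#' @param config configuration list (see
#'   \code{\link{defaultPipelineConfig}}).
#' @param outdir output directory (created if needed).
#' @return invisibly, a list with the main results (reduced families,
#'   screen, superfamilies, trees, strand counts, repeat hits).
#' @export
runPipeline <- function(inputs, config = defaultPipelineConfig(),
                        outdir = "ompbarrel-out") {
  stopifnot(is.list(inputs), length(inputs) >= 2L, !is.null(names(inputs)))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  logPath <- file.path(outdir, "run.log")
  unlink(logPath)
  log <- function(msg) cat(format(Sys.time(), "%H:%M:%S "), msg, "\n",
                           sep = "", file = logPath, append = TRUE)
  log(sprintf("ompbarrel %s",
              as.character(utils::packageVersion("ompbarrel"))))
  writePipelineConfig(config, file.path(outdir, "effective-config.txt"))
  log(sprintf("master seed %d", config$seed))

  params <- alnParams(config$matrix, config$gapOpen, config$gapExtend)
  rule <- segmentRule(config$minSeg, config$sdThreshold)

  families <- .stage("read", log, {
    lapply(inputs, function(x)
      if (is.character(x) && length(x) == 1L && file.exists(x))
        readFastaSet(x) else makeSeqSet(as.character(x)))
  })

  reduced <- .stage("redundancy", log, {
    out <- lapply(names(families), function(f) {
      r <- reduceRedundancy(families[[f]], config$redundancyCutoff, params)
      writeClusterReport(r, file.path(outdir,
                                      sprintf("clusters_%s.tsv", f)))
      r
    })
    setNames(out, names(families))
  })

  screen <- .stage("screen", log, {
    sc <- screenFamilies(reduced, params, rule,
                         nShuffles = config$shuffles,
                         topK = config$topK, seed = config$seed)
    write.table(sc$tested, file.path(outdir, "screen_tested.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (length(sc$chains))
      writeChainReport(sc$chains, file.path(outdir, "chains.tsv"))
    sc
  })

  sfa <- .stage("superfamilies", log, {
    out <- buildSuperfamilies(screen$edges, names(reduced))
    memb <- data.frame(family = names(superfamilyOf(out)),
                       component = unname(superfamilyOf(out)),
                       status = unname(out@status))
    nsupp <- table(c(screen$edges$familyA, screen$edges$familyB))
    memb$n_supporting_edges <-
      as.integer(nsupp[memb$family])
    memb$n_supporting_edges[is.na(memb$n_supporting_edges)] <- 0L
    write.table(memb, file.path(outdir, "superfamilies.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    out
  })

  trees <- .stage("trees", log, {
    res <- list()
    pool <- do.call(c, lapply(unname(reduced), as.character))
    if (length(pool) >= 4L) {
      poolSet <- makeSeqSet(pool)
      res$protein <- consensusTree(poolSet, params,
                                   nReplicates = config$replicates,
                                   seed = deriveSeed(config$seed, 11L))
      ape::write.tree(res$protein,
                      file.path(outdir, "protein_tree.nwk"))
    }
    if (length(reduced) >= 3L) {
      res$family <- suppressWarnings(
        familyTree(reduced, params, nReplicates = config$replicates,
                   seed = deriveSeed(config$seed, 12L)))
      ape::write.tree(res$family, file.path(outdir, "family_tree.nwk"))
    }
    res
  })

  profiles <- .stage("profiles", log, {
    haveMafft <- Sys.which("mafft") != ""
    out <- list()
    for (f in names(reduced)) {
      fam <- reduced[[f]]
      aln <- if (length(fam) == 1L) fam
             else if (haveMafft) mafftAlign(fam) else NULL
      if (is.null(aln)) {
        log(sprintf("[profiles] mafft unavailable; skipping family %s", f))
        next
      }
      pr <- avehasProfile(aln)
      writeProfileTsv(pr, file.path(outdir, sprintf("profile_%s.tsv", f)))
      out[[f]] <- pr
    }
    out
  })

  strands <- .stage("strands", log, {
    ct <- countTmsByFamily(reduced)
    write.table(ct$summary, file.path(outdir, "strand_counts.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    topo <- lapply(reduced, function(fam)
      predictBetaTms(as.character(fam[[1L]])))
    writeStrandTsv(topo, file.path(outdir, "strand_intervals.tsv"))
    list(counts = ct, representative = topo)
  })

  repeats <- .stage("repeats", log, {
    out <- list()
    for (f in names(reduced)) {
      repSeq <- as.character(reduced[[f]][[1L]])
      topo <- strands$representative[[f]]
      hits <- hairpinRepeatScan(repSeq, topo,
                                nShuffles = config$shuffles,
                                seed = deriveSeed(config$seed, 20L))
      writeRepeatReport(hits, names(reduced[[f]])[1L],
                        file.path(outdir, sprintf("repeats_%s.tsv", f)))
      out[[f]] <- hits
    }
    out
  })

  log("pipeline complete")
  invisible(list(families = reduced, screen = screen, superfamilies = sfa,
                 trees = trees, profiles = profiles, strands = strands,
                 repeats = repeats, config = config, outdir = outdir))
}
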