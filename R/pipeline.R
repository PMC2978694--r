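# End-to-end orchestration: synthetic benchmark generation, per-class
# Gibbs scan, PWM refinement, degeneracy classification, code-table
# assembly and reporting, under one seeded configuration.

#' Pipeline configuration
#'
#' Collects every stage parameter of an end-to-end run. The seed is
#' mandatory and drives all stages deterministically.
#'
#' @param seed integer master seed.
#' @param code \code{\linkS4class{PlantedCode}} for synthetic runs.
#' @param tfsPerClass regulators per class (synthetic runs).
#' @param siteRate planted-site probability per region.
#' @param regionLen strict region length (bp).
#' @param background length-4 base probabilities.
#' @param restriction recognition-helix restriction string (columns
#'   17-20); \code{NULL} disables it.
#' @param gibbs named list of overrides for \code{\link{gibbsConfig}}.
#' @param pseudocount,nNull,alpha,maxIter,zMin refinement parameters
#'   (see \code{\link{refineSites}} and \code{\link{zscoreFilter}}).
#' @param alphaFdr FDR level of the degeneracy tests.
#' @return list of class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(seed,
                           code = plantedCode(c(GQ = "AC", HQ = "GG",
                                                KA = "TG", RS = "CA",
                                                TM = "TT", YQ = "TA")),
                           tfsPerClass = 8L, siteRate = 0.8,
                           regionLen = 150L, background = rep(0.25, 4),
                           restriction = "TVSR", gibbs = list(),
                           pseudocount = 1, nNull = 1e5, alpha = 1e-3,
                           maxIter = 50L, zMin = 4, alphaFdr = 0.05) {
  seed <- .checkSeed(seed)
  stopifnot(methods::is(code, "PlantedCode"))
  structure(list(seed = seed, code = code, tfsPerClass = tfsPerClass,
                 siteRate = siteRate, regionLen = regionLen,
                 background = background, restriction = restriction,
                 gibbs = gibbs, pseudocount = pseudocount, nNull = nNull,
                 alpha = alpha, maxIter = maxIter, zMin = zMin,
                 alphaFdr = alphaFdr),
            class = "PipelineConfig")
}

#' Run the full pipeline on a synthetic benchmark
#'
#' Generates a family and regions from the planted code, partitions the
#' domains into recognition classes, runs the palindromic Gibbs scan over
#' each class's strict regions, refines with iterative PWM scanning over
#' the extended regions, classifies degeneracies and assembles the
#' recognition-code table. All outputs are deterministic given the
#' configuration seed. When \code{outputDir} is given, site tables,
#' per-class motifs, the code table and a JSON summary are written there.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @param outputDir optional output directory (created if missing).
#' @return list with \code{family}, \code{regions}, \code{classes},
#'   \code{seedSites} (Gibbs survivors), \code{sites} (refined, in
#'   extended-region coordinates), \code{pwms} (per class),
#'   \code{codeTable}, \code{summary}, \code{mi} (mutual-information
#'   matrix domains x final sites) and \code{log} (per-stage timings and
#'   kept-site counts).
#' @export
runPipeline <- function(config, outputDir = NULL) {
  stopifnot(inherits(config, "PipelineConfig"))
  log <- list()
  tick <- function(stage, t0, info = "")
    sprintf("%s: %.2fs %s", stage, as.numeric(Sys.time()) - t0, info)

  t0 <- as.numeric(Sys.time())
  nClasses <- length(codeClasses(config$code))
  fam <- generateFamily(nClasses, config$tfsPerClass, config$code,
                        seed = .subSeed(config$seed, 1L))
  reg <- generateRegions(fam$classMap, config$code, config$siteRate,
                         config$regionLen, config$background,
                         seed = .subSeed(config$seed, 2L))
  log <- c(log, tick("simulate", t0,
                     sprintf("(%d TFs, %d planted sites)",
                             nrow(fam$classMap), nrow(reg$truth))))

  classes <- partitionClasses(fam$alignment, restrict = config$restriction)
  allSeed <- list(); allFinal <- list(); pwms <- list()
  for (cls in names(classes)) {
    members <- classes[[cls]]$members
    rids <- paste0(members, "_up")
    strict <- reg$strict[rids]
    extended <- reg$extended[rids]

    t0 <- as.numeric(Sys.time())
    gargs <- utils::modifyList(
      list(background = config$background,
           seed = .subSeed(config$seed, 100L + match(cls, names(classes)))),
      config$gibbs)
    cfg <- do.call(gibbsConfig, gargs)
    seeds <- gibbsSearch(strict, cfg)
    log <- c(log, tick(paste0("footprint[", cls, "]"), t0,
                       sprintf("(%d seed sites)", nrow(seeds))))
    if (nrow(seeds) == 0L) next
    allSeed[[cls]] <- seeds

    t0 <- as.numeric(Sys.time())
    ref <- refineSites(seeds, extended,
                       pseudocount = config$pseudocount,
                       background = config$background, palindromic = TRUE,
                       nNull = config$nNull, alpha = config$alpha,
                       maxIter = config$maxIter,
                       seed = .subSeed(config$seed,
                                       200L + match(cls, names(classes))))
    final <- zscoreFilter(ref$sites, config$zMin)
    log <- c(log, tick(paste0("refine[", cls, "]"), t0,
                       sprintf("(%d sites, %d iterations)",
                               nrow(final), ref$nIterations)))
    if (nrow(final)) {
      allFinal[[cls]] <- final
      pwms[[cls]] <- ref$pwm
    }
  }
  seedSites <- if (length(allSeed)) do.call(rbind, c(allSeed,
                                                     make.row.names = FALSE))
    else emptySiteTable()
  sites <- if (length(allFinal)) do.call(rbind, c(allFinal,
                                                  make.row.names = FALSE))
    else emptySiteTable()

  t0 <- as.numeric(Sys.time())
  codeTable <- assembleCodeTable(attr(classes, "classMap"), sites,
                                 backgroundDinuc =
                                   backgroundDinucleotides(config$background),
                                 alphaFdr = config$alphaFdr)
  summary <- summarizeCodeTable(codeTable)
  log <- c(log, tick("codetable", t0))

  mi <- NULL
  if (nrow(sites) >= 2L) {
    t0 <- as.numeric(Sys.time())
    # one site per regulator (best score) keeps the pairing univocal
    best <- sites[order(sites$tf_id, -sites$score), , drop = FALSE]
    best <- best[!duplicated(best$tf_id), , drop = FALSE]
    if (nrow(best) >= 2L)
      mi <- miMatrix(fam$alignment, best$sequence, best$tf_id)
    log <- c(log, tick("mi", t0))
  }

  out <- list(family = fam, regions = reg, classes = classes,
              seedSites = seedSites, sites = sites, pwms = pwms,
              codeTable = codeTable, summary = summary, mi = mi,
              log = unlist(log))
  if (!is.null(outputDir)) {
    dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
    writeSites(sites, file.path(outputDir, "sites.tsv"))
    writeSites(seedSites, file.path(outputDir, "seed_sites.tsv"))
    writeTruth(reg$truth, file.path(outputDir, "truth.tsv"))
    writeCodeTable(codeTable, file.path(outputDir, "code_table.tsv"))
    for (cls in names(pwms))
      writeMotif(pwms[[cls]], file.path(outputDir,
                                        paste0("motif_", cls, ".txt")),
                 name = cls)
    if (!is.null(mi))
      write.table(mi, file.path(outputDir, "mi_matrix.tsv"), sep = "\t",
                  quote = FALSE)
    jsonlite::write_json(as.list(summary),
                         file.path(outputDir, "summary.json"),
                         auto_unbox = TRUE)
    writeLines(out$log, file.path(outputDir, "run.log"))
  }
  invisible(out)
}

#' Compare recovered sites against planted truth
#'
#' Sensitivity is the fraction of planted sites recovered with a reported
#' start within \code{startTol} bp (same region); precision is the
#' fraction of reported sites matching a planted one under the same
#' criterion.
#'
#' @param found site table of recovered sites.
#' @param truth truth table from \code{\link{generateRegions}}.
#' @param startCol which truth start column matches the coordinate system
#'   of \code{found} (\code{"start"} for strict regions,
#'   \code{"start_extended"} for extended).
#' @param startTol tolerance in bp on the start coordinate.
#' @return named numeric vector: \code{sensitivity}, \code{precision},
#'   \code{n_planted}, \code{n_found}, \code{n_matched}.
#' @export
matchPlantedSites <- function(found, truth,
                              startCol = c("start_extended", "start"),
                              startTol = 1L) {
  startCol <- match.arg(startCol)
  nP <- nrow(truth); nF <- nrow(found)
  if (nP == 0L || nF == 0L)
    return(c(sensitivity = if (nP) 0 else NA_real_,
             precision = if (nF) 0 else NA_real_,
             n_planted = nP, n_found = nF, n_matched = 0))
  hitP <- logical(nP); hitF <- logical(nF)
  for (i in seq_len(nP)) {
    cand <- which(found$region_id == truth$region_id[i] &
                    abs(found$start - truth[[startCol]][i]) <= startTol)
    if (length(cand)) {
      hitP[i] <- TRUE
      hitF[cand] <- TRUE
    }
  }
  c(sensitivity = mean(hitP), precision = mean(hitF),
    n_planted = nP, n_found = nF, n_matched = sum(hitP))
}
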