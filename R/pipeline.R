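# End-to-end driver for the synthetic study: simulate two systems,
# build decoding/encoding manifolds, score tubularity, run the
# alignment battery, and write every artifact with logged seeds.

.PIPELINE_KEYS <- list(
  top        = c("seed", "output_dir", "ensemble", "population",
                 "population_b", "decoding", "encoding", "tubularity",
                 "alignment"),
  ensemble   = c("classes", "n_directions"),
  population = c("nPerClass", "nNonselective", "kappaRange", "gainRange",
                 "offClassGain", "profiles", "temporalFreq", "noiseModel",
                 "noiseScale", "nTimeBins", "binWidth", "sharedTuning",
                 "profilesByClass"),
  decoding   = c("n_dims", "grouping", "accuracy_scheme"),
  encoding   = c("rank", "n_dims", "k", "n_restarts"),
  tubularity = c("n_boot", "n_comparisons"),
  alignment  = c("cca_components", "cca_pca_dim", "lp_folds", "lp_ridge",
                 "dsa_rank", "dsa_restarts")
)

checkConfigKeys <- function(cfg, section) {
  allowed <- .PIPELINE_KEYS[[section]]
  bad <- setdiff(names(cfg), allowed)
  if (length(bad) > 0L)
    stop(sprintf("schema error: unknown key '%s' in section '%s'",
                 bad[1], section), call. = FALSE)
  invisible(TRUE)
}

#' Run the full synthetic-study pipeline from a YAML config
#'
#' Stages: simulate two populations on a shared stimulus ensemble, write
#' the response tensor (CSV bundle) and ground truth, build the decoding
#' manifold and trajectories (coordinates as CSV), classification
#' accuracy and selectivity indices, the encoding manifold and its
#' topology summary, tubularity scores with a bootstrap comparison
#' between the two systems, and the four-metric alignment report. Every
#' stage seed is derived deterministically from the single global
#' \code{seed} (global seed modulo 1e6, times 1000, plus a fixed
#' per-stage offset) and echoed to \code{run.log}; \code{manifest.json}
#' lists the artifacts of every completed stage, so a failed run still
#' documents what finished.
#'
#' @param configPath YAML file; unknown keys raise a schema error naming
#'   the key. All sections are optional (defaults are the study
#'   conditions).
#' @param outputDir overrides the config's \code{output_dir}.
#' @return the output directory, invisibly; side effect: artifacts.
#' @export
runPipeline <- function(configPath, outputDir = NULL) {
  cfg <- if (is.null(configPath)) list() else yaml::read_yaml(configPath)
  if (is.null(cfg)) cfg <- list()
  checkConfigKeys(cfg, "top")
  for (s in c("ensemble", "population", "population_b", "decoding",
              "encoding", "tubularity", "alignment"))
    if (!is.null(cfg[[s]]))
      checkConfigKeys(cfg[[s]],
                      if (s == "population_b") "population" else s)
  seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  out <- if (!is.null(outputDir)) outputDir
         else if (!is.null(cfg$output_dir)) cfg$output_dir
         else stop("schema error: missing key 'output_dir'", call. = FALSE)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)

  logFile <- file.path(out, "run.log")
  cat(sprintf("neurogeom pipeline | global seed %d\n", seed), file = logFile)
  logLine <- function(fmt, ...)
    cat(sprintf(paste0(fmt, "\n"), ...), file = logFile, append = TRUE)

  manifest <- list(global_seed = seed, stages = list())
  saveManifest <- function()
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  stage <- function(name, files) {
    manifest$stages[[name]] <<- list(status = "completed",
                                     files = as.list(files))
    saveManifest()
  }
  runStage <- function(name, code) {
    tryCatch(code, error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      saveManifest()
      stop(e)
    })
  }

  dcfg <- modifyList(list(n_dims = 3L, grouping = "class-direction",
                          accuracy_scheme = "nearest-centroid-loo"),
                     cfg$decoding %||% list())
  ecfg <- modifyList(list(rank = "auto", n_dims = 3L, k = 7L,
                          n_restarts = 3L), cfg$encoding %||% list())
  tcfg <- modifyList(list(n_boot = 500L, n_comparisons = 1L),
                     cfg$tubularity %||% list())
  acfg <- modifyList(list(cca_components = 5L, cca_pca_dim = 10L,
                          lp_folds = 5L, lp_ridge = 1e-3, dsa_rank = 5L,
                          dsa_restarts = 10L), cfg$alignment %||% list())

  # --- simulate ---------------------------------------------------------
  simA <- simB <- ens <- NULL
  runStage("simulate", {
    ens <- makeStimulusEnsemble(
      if (is.null(cfg$ensemble)) defaultEnsembleConfig()
      else list(classes = cfg$ensemble$classes %||%
                  defaultEnsembleConfig()$classes,
                nDirections = cfg$ensemble$n_directions %||% 8L))
    sA <- deriveSeed(seed, "simulate"); sB <- deriveSeed(seed, "simulate2")
    logLine("simulate: seedA=%d seedB=%d sequences=%d", sA, sB, length(ens))
    simA <- simulatePopulation(ens, cfg$population %||% list(), seed = sA)
    simB <- simulatePopulation(ens, cfg$population_b %||%
                                  (cfg$population %||% list()), seed = sB)
    writeResponseTensor(simA$tensor, file.path(out, "tensor_a"))
    writeResponseTensor(simB$tensor, file.path(out, "tensor_b"))
    write.csv(simA$groundTruth, file.path(out, "ground_truth_a.csv"),
              row.names = FALSE)
    write.csv(simB$groundTruth, file.path(out, "ground_truth_b.csv"),
              row.names = FALSE)
    stage("simulate", c("tensor_a", "tensor_b", "ground_truth_a.csv",
                        "ground_truth_b.csv"))
  })

  # --- decoding ---------------------------------------------------------
  trajA <- trajB <- NULL
  runStage("decoding", {
    mf <- buildDecodingManifold(simA$tensor, nDims = dcfg$n_dims,
                                grouping = dcfg$grouping)
    trajA <- buildDecodingTrajectories(simA$tensor, nDims = dcfg$n_dims,
                                        grouping = dcfg$grouping)
    trajB <- buildDecodingTrajectories(simB$tensor, nDims = dcfg$n_dims,
                                        grouping = dcfg$grouping)
    write.csv(cbind(pointLabels(mf), as.data.frame(coords(mf))),
              file.path(out, "decoding_manifold.csv"), row.names = FALSE)
    trLong <- trajectoryTable(trajA)
    write.csv(trLong, file.path(out, "decoding_trajectories.csv"),
              row.names = FALSE)
    acc <- classificationAccuracy(simA$tensor, scheme = dcfg$accuracy_scheme,
                                  grouping = dcfg$grouping,
                                  seed = deriveSeed(seed, "decoding"))
    sel <- selectivityIndices(simA$tensor)
    write.csv(sel, file.path(out, "selectivity.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(scheme = dcfg$accuracy_scheme, grouping = dcfg$grouping,
           n_points = nrow(coords(mf)),
           explained_variance = explainedVariance(mf), accuracy = acc),
      file.path(out, "decoding_report.json"), auto_unbox = TRUE,
      digits = NA, pretty = TRUE)
    logLine("decoding: %d points, accuracy=%.4f", nrow(coords(mf)), acc)
    stage("decoding", c("decoding_manifold.csv", "decoding_trajectories.csv",
                        "selectivity.csv", "decoding_report.json"))
  })

  # --- encoding ---------------------------------------------------------
  runStage("encoding", {
    es <- deriveSeed(seed, "encoding")
    em <- buildEncodingManifold(simA$tensor, rank = ecfg$rank,
                                nDims = ecfg$n_dims, k = ecfg$k,
                                nRestarts = ecfg$n_restarts, seed = es)
    gt <- simA$groundTruth
    lab <- gt$planted_class[match(neuronIds(em), gt$neuron_id)]
    ts <- topologyStats(em, labels = lab, seed = es)
    expo <- cbind(data.frame(neuron_id = neuronIds(em),
                             component = em@component),
                  as.data.frame(embedding(em)),
                  as.data.frame(neuronFactors(em)))
    write.csv(expo, file.path(out, "encoding_manifold.csv"),
              row.names = FALSE)
    jsonlite::write_json(
      list(rank = ncol(neuronFactors(em)), eigenvalues = em@eigenvalues,
           n_components = ts$nComponents, gap_ratio = ts$gapRatio,
           label_ari = ts$labelARI, k_chosen = ts$kChosen),
      file.path(out, "encoding_report.json"), auto_unbox = TRUE,
      digits = NA, pretty = TRUE)
    logLine("encoding: seed=%d rank=%d ARI=%.3f", es,
            ncol(neuronFactors(em)), ts$labelARI)
    stage("encoding", c("encoding_manifold.csv", "encoding_report.json"))
  })

  # --- tubularity -------------------------------------------------------
  runStage("tubularity", {
    tub <- tubularityScores(trajA)
    cmp <- compareScores(trajA, trajB, metric = "tight",
                         nBoot = tcfg$n_boot,
                         seed = deriveSeed(seed, "tubularity"),
                         nComparisons = tcfg$n_comparisons)
    jsonlite::write_json(
      list(s_tight = sTight(tub), s_cross = sCross(tub),
           per_class_tightness = as.list(tub@perClassTightness),
           per_time_tightness = tub@perTimeTightness,
           per_time_crossings = tub@perTimeCrossings,
           dims = tub@dims,
           comparison = list(metric = "tight", delta = cmp$delta,
                             p = cmp$p, p_bonferroni = cmp$pBonferroni,
                             n_boot = tcfg$n_boot)),
      file.path(out, "tubularity_report.json"), auto_unbox = TRUE,
      digits = NA, pretty = TRUE)
    logLine("tubularity: S_tight=%.4f S_cross=%.4f p=%.4f",
            sTight(tub), sCross(tub), cmp$p)
    stage("tubularity", "tubularity_report.json")
  })

  # --- alignment --------------------------------------------------------
  runStage("alignment", {
    XA <- conditionResponses(simA$tensor, grouping = dcfg$grouping)
    XB <- conditionResponses(simB$tensor, grouping = dcfg$grouping)
    alnRep <- alignmentReport(XA, XB, trajA, trajB,
                           config = list(ccaComponents = acfg$cca_components,
                                         ccaPcaDim = acfg$cca_pca_dim,
                                         lpFolds = acfg$lp_folds,
                                         lpRidge = acfg$lp_ridge,
                                         dsaRank = acfg$dsa_rank,
                                         dsaRestarts = acfg$dsa_restarts,
                                         seed = deriveSeed(seed, "alignment")))
    writeAlignmentReport(alnRep, file.path(out, "alignment_report.json"))
    logLine("alignment: mean=%.4f", meanScore(alnRep))
    stage("alignment", "alignment_report.json")
  })

  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Long-format table of a TrajectorySet (one row per trajectory x step).
trajectoryTable <- function(trajs) {
  tr <- trajectories(trajs)
  K <- dim(tr)[1]; T <- dim(tr)[2]; D <- dim(tr)[3]
  lab <- trajectoryLabels(trajs)
  coordsTab <- matrix(aperm(tr, c(2, 1, 3)), nrow = K * T, ncol = D)
  colnames(coordsTab) <- paste0("dim", seq_len(D))
  cbind(lab[rep(seq_len(K), each = T), , drop = FALSE],
        data.frame(time = rep(timeAxis(trajs), times = K)),
        as.data.frame(coordsTab))
}

#' Export PSTH grids for a set of neurons
#'
#' Writes one long-format CSV (neuron_id, base_class, variant_id,
#' direction, time_bin, activity) covering every (class, variant) grid
#' of the requested neurons, and optionally one grayscale raster PNG per
#' neuron (direction rows stacked over classes, brightness = activity).
#' Requesting zero neurons produces an empty CSV with a valid header.
#'
#' @param tensor a \linkS4class{ResponseTensor}.
#' @param ids neuron ids to export.
#' @param outPath CSV file path.
#' @param png also write \code{<outPath>_<neuron>.png} rasters.
#' @return \code{outPath}, invisibly.
#' @export
exportPsthFigureData <- function(tensor, ids, outPath, png = FALSE) {
  ids <- as.character(ids)
  unknown <- setdiff(ids, neuronIds(tensor))
  if (length(unknown) > 0L)
    stop(sprintf("lookup error: unknown neuron id(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  sq <- sequenceTable(ensemble(tensor))
  cv <- unique(sq[, c("base_class", "variant_id")])
  rows <- list()
  for (id in ids) {
    for (i in seq_len(nrow(cv))) {
      g <- psthGrid(tensor, id, cv$base_class[i], cv$variant_id[i])
      T <- ncol(g@matrix)
      rows[[length(rows) + 1L]] <- data.frame(
        neuron_id = id, base_class = cv$base_class[i],
        variant_id = cv$variant_id[i],
        direction = rep(g@directions, times = T),
        time_bin = rep(seq_len(T), each = length(g@directions)),
        activity = as.vector(g@matrix),
        stringsAsFactors = FALSE)
    }
  }
  empty <- data.frame(neuron_id = character(0), base_class = character(0),
                      variant_id = character(0), direction = numeric(0),
                      time_bin = integer(0), activity = numeric(0))
  tab <- if (length(rows) > 0L) do.call(rbind, rows) else empty
  write.csv(tab, outPath, row.names = FALSE)
  if (png && length(ids) > 0L) {
    for (id in ids) {
      sub <- tab[tab$neuron_id == id, ]
      T <- max(sub$time_bin)
      blocks <- lapply(seq_len(nrow(cv)), function(i) {
        s <- sub[sub$base_class == cv$base_class[i] &
                   sub$variant_id == cv$variant_id[i], ]
        matrix(s$activity, ncol = T)
      })
      img <- do.call(rbind, blocks)
      rng <- range(img)
      if (diff(rng) > 0) img <- (img - rng[1]) / diff(rng)
      f <- sprintf("%s_%s.png", sub("\\.csv$", "", outPath), id)
      grDevices::png(f, width = 40 * T, height = 8 * nrow(img))
      graphics::par(mar = c(0, 0, 0, 0))
      graphics::image(t(img[nrow(img):1, , drop = FALSE]),
                      col = gray(seq(0, 1, length.out = 256)),
                      axes = FALSE)
      grDevices::dev.off()
    }
  }
  invisible(outPath)
}
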