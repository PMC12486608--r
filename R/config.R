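#' Load and validate a pipeline configuration file
#'
#' The configuration is a single YAML file. Recognised keys (defaults
#' in parentheses): `contrasts` (CSV path), `brain_mask`, optional
#' `atlas` + `atlas_names` (text file, one network name per line),
#' optional `wm_mask` / `csf_mask`, `subjects` (list of
#' `{id, bold, motion}` entries), `tr` (override), `radius_mm` (4;
#' scalar or list), `q` (0.05), `tau` (0.5), `inclusive_tau` (false),
#' `alternative` ("greater"), `sig_threshold` (0.1),
#' `fd_threshold_mm` (0.5), `low_hz` (0.01), `high_hz` (0.1),
#' `fwhm_mm` (6), `global_signal` (true), `skip_preprocess` (false),
#' `max_trans_mm` (2), `max_rot_deg` (2), `out_dir` ("results").
#' Validation (path existence, threshold ranges) happens before any
#' compute.
#'
#' @param path YAML file path.
#' @return Validated configuration list.
#' @export
loadFCNMConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  defaults <- list(radius_mm = 4, q = 0.05, tau = 0.5,
                   inclusive_tau = FALSE, alternative = "greater",
                   sig_threshold = 0.1, fd_threshold_mm = 0.5,
                   low_hz = 0.01, high_hz = 0.1, fwhm_mm = 6,
                   global_signal = TRUE, skip_preprocess = FALSE,
                   max_trans_mm = 2, max_rot_deg = 2,
                   out_dir = "results", tr = NULL)
  for (k in names(defaults))
    if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  cfg$base <- dirname(normalizePath(path))
  validateFCNMConfig(cfg)
}

resolvePath <- function(p, base) {
  if (is.null(p)) return(NULL)
  if (file.exists(p)) return(normalizePath(p))
  cand <- file.path(base, p)
  if (file.exists(cand)) return(normalizePath(cand))
  stop("configured path does not exist: ", p)
}

validateFCNMConfig <- function(cfg) {
  for (k in c("contrasts", "brain_mask"))
    if (is.null(cfg[[k]])) stop("config is missing required key: ", k)
  cfg$contrasts <- resolvePath(cfg$contrasts, cfg$base)
  cfg$brain_mask <- resolvePath(cfg$brain_mask, cfg$base)
  for (k in c("atlas", "atlas_names", "wm_mask", "csf_mask"))
    cfg[[k]] <- resolvePath(cfg[[k]], cfg$base)
  if (!length(cfg$subjects)) stop("config lists no subjects")
  cfg$subjects <- lapply(cfg$subjects, function(s) {
    s$bold <- resolvePath(s$bold, cfg$base)
    s$motion <- resolvePath(s$motion, cfg$base)
    s
  })
  cfg$radius_mm <- as.numeric(unlist(cfg$radius_mm))
  if (any(cfg$radius_mm <= 0)) stop("radius_mm must be positive")
  if (cfg$q <= 0 || cfg$q >= 1) stop("q must lie in (0, 1)")
  if (cfg$tau <= 0 || cfg$tau > 1) stop("tau must lie in (0, 1]")
  if (!cfg$alternative %in% c("greater", "two.sided"))
    stop("alternative must be 'greater' or 'two.sided'")
  cfg
}

readAtlasFiles <- function(atlasPath, namesPath) {
  vol <- readVolume(atlasPath)
  labels <- array(as.integer(round(vol$values)), gridDim(vol$grid))
  K <- max(labels)
  nms <- if (!is.null(namesPath)) readLines(namesPath)
         else paste0("network_", seq_len(K))
  if (length(nms) < K)
    stop("atlas names file lists ", length(nms), " names for ", K,
         " labels")
  new("CanonicalAtlas", grid = vol$grid, labels = labels,
      networkNames = nms[seq_len(K)])
}

#' Execute a configured end-to-end run and write its artefacts
#'
#' Reads every input named in the configuration, executes [runFCNM()]
#' (optionally per subgroup), and writes NIfTI maps, CSV/JSON reports
#' and a run manifest under the output directory:
#' `<out>/<subgroup>/maps/` (per-contrast binary maps, probability map,
#' final network mask), `<out>/<subgroup>/reports/` (overlap ratios,
#' screening report, per-contrast inference sidecars, Dice table), and
#' `<out>/manifest.json` (configuration echo, package version, stage
#' counts, MD5 of every artefact). The pipeline is deterministic, so a
#' manifest identifies its outputs bit for bit.
#'
#' @param config path to a YAML configuration or a list from
#'   [loadFCNMConfig()].
#' @param outDir overrides the configured output directory.
#' @param subgroups criteria to run (default `"all"`).
#' @param verbose per-stage progress messages.
#' @return The manifest list, invisibly.
#' @export
runFCNMFromConfig <- function(config, outDir = NULL,
                              subgroups = "all", verbose = TRUE) {
  cfg <- if (is.character(config)) loadFCNMConfig(config) else config
  if (is.null(outDir)) outDir <- cfg$out_dir
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)

  contrasts <- readContrastTable(cfg$contrasts)
  bm <- readVolume(cfg$brain_mask)
  brain <- brainMask(bm$values > 0.5, bm$grid)
  atlas <- if (!is.null(cfg$atlas))
    readAtlasFiles(cfg$atlas, cfg$atlas_names)
  loadMask <- function(p) {
    if (is.null(p)) return(NULL)
    v <- readVolume(p); brainMask(v$values > 0.5, v$grid)
  }
  wm <- loadMask(cfg$wm_mask); csf <- loadMask(cfg$csf_mask)

  results <- runSubgroupSuite(
    contrasts, cfg$subjects, brain, criteria = subgroups,
    atlas = atlas, wm = wm, csf = csf,
    radiusMm = cfg$radius_mm, q = cfg$q, tau = cfg$tau,
    inclusiveTau = cfg$inclusive_tau, alternative = cfg$alternative,
    sigThreshold = cfg$sig_threshold,
    fdThresholdMm = cfg$fd_threshold_mm, lowHz = cfg$low_hz,
    highHz = cfg$high_hz, fwhmMm = cfg$fwhm_mm,
    globalSignal = cfg$global_signal,
    preprocess = !isTRUE(cfg$skip_preprocess),
    maxTransMm = cfg$max_trans_mm, maxRotDeg = cfg$max_rot_deg,
    trSeconds = cfg$tr, verbose = verbose)

  artefacts <- character()
  putVol <- function(x, path, grid = NULL) {
    writeVolume(x, path, grid = grid)
    artefacts <<- c(artefacts, path)
  }
  for (sg in names(results)) {
    res <- results[[sg]]
    mapsDir <- file.path(outDir, sg, "maps")
    repDir <- file.path(outDir, sg, "reports")
    dir.create(mapsDir, recursive = TRUE, showWarnings = FALSE)
    dir.create(repDir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(res$screening$report,
                     file.path(repDir, "screening.csv"),
                     row.names = FALSE)
    artefacts <- c(artefacts, file.path(repDir, "screening.csv"))
    for (r in names(res$byRadius)) {
      br <- res$byRadius[[r]]
      tag <- paste0("r", gsub("[.]", "p", r))
      for (gm in br$groupMaps) {
        putVol(gm, file.path(mapsDir, sprintf("%s_%s_binary.nii.gz",
                                              contrastId(gm), tag)))
        sidecar <- list(contrast = contrastId(gm),
                        n = as.integer(gm@dof + 1), dof = gm@dof,
                        q = gm@qLevel, p_threshold = gm@pThreshold,
                        n_rejected = sum(gm@binary))
        sp <- file.path(repDir, sprintf("%s_%s_inference.json",
                                        contrastId(gm), tag))
        jsonlite::write_json(sidecar, sp, auto_unbox = TRUE,
                             digits = NA)
        artefacts <- c(artefacts, sp)
      }
      putVol(br$probability,
             file.path(mapsDir, sprintf("probability_%s.nii.gz", tag)))
      putVol(br$networkMask,
             file.path(mapsDir, sprintf("network_mask_%s.nii.gz", tag)),
             grid = brain@grid)
      if (!is.null(br$overlap)) {
        op <- file.path(repDir, sprintf("overlap_%s.csv", tag))
        utils::write.csv(br$overlap, op, row.names = FALSE)
        jsonlite::write_json(br$overlap,
                             file.path(repDir,
                                       sprintf("overlap_%s.json", tag)),
                             digits = NA)
        artefacts <- c(artefacts, op,
                       file.path(repDir, sprintf("overlap_%s.json",
                                                 tag)))
      }
    }
    if (!is.null(res$diceTable)) {
      dp <- file.path(repDir, "radius_dice.csv")
      utils::write.csv(res$diceTable, dp, row.names = FALSE)
      artefacts <- c(artefacts, dp)
    }
  }

  cfgEcho <- cfg[setdiff(names(cfg), "base")]
  manifest <- list(
    package = "coordnet",
    version = as.character(utils::packageVersion("coordnet")),
    config = cfgEcho,
    configHash = digestList(cfgEcho),
    subgroups = lapply(results, function(res) list(
      contrasts = names(res$byRadius[[1]]$groupMaps),
      includedSubjects = res$includedSubjects,
      excludedSubjects = res$excludedSubjects,
      finalMaskVoxels = vapply(res$byRadius,
                               function(b) sum(b$networkMask),
                               numeric(1)))),
    artefacts = as.list(tools::md5sum(artefacts)))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

# order-stable MD5 of an R list via its canonical JSON serialisation
digestList <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA), tf)
  unname(tools::md5sum(tf))
}
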