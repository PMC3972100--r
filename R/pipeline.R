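## End-to-end orchestration: ingestion -> score injection/docking ->
## combined scoring -> classification -> site preference -> evaluation.

#' Assemble and validate a pipeline run configuration
#'
#' A run configuration is a named list (or a key-value text file with one
#' \code{key value} pair per line) with fields:
#' \describe{
#'   \item{scores}{path to a score table (required): ligand ids, optional
#'     logp / hsa_percent columns, and \code{<pdbid>:<site>} score columns.}
#'   \item{manifest}{optional ensemble manifest path; otherwise the
#'     ensemble is inferred from the score columns.}
#'   \item{model}{\code{"published"} (default) or a model file written by
#'     \code{\link{writeCombinedModel}}.}
#'   \item{site_threshold}{kcal/mol for \code{\link{sitePreference}}
#'     (default 2).}
#'   \item{weak_cutoff, binder_cutoff}{\%HSA class boundaries (25 / 80).}
#'   \item{seed}{integer, stamped into artifacts (default 1).}
#'   \item{out_dir}{output directory (required).}
#' }
#' Validation fails before any computation when a referenced path is
#' missing, and names the offending field.
#'
#' @param config named list or path to a key-value config file.
#' @return validated config list (class \code{hsaRunConfig}).
#' @export
readRunConfig <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config)
    lines <- readLines(config, warn = FALSE)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    kv <- strsplit(lines, "[ \t]+")
    config <- stats::setNames(
      lapply(kv, function(f) paste(f[-1], collapse = " ")),
      vapply(kv, `[`, "", 1))
  }
  stopifnot(is.list(config))
  defaults <- list(model = "published", site_threshold = 2,
                   weak_cutoff = 25, binder_cutoff = 80, seed = 1,
                   manifest = NULL)
  for (k in names(defaults))
    if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  for (k in c("site_threshold", "weak_cutoff", "binder_cutoff", "seed"))
    config[[k]] <- as.numeric(config[[k]])
  if (is.null(config$scores))
    stop("config validation failed: field 'scores' is required")
  if (!file.exists(config$scores))
    stop("config validation failed: field 'scores' points to a missing ",
         "file: ", config$scores)
  if (!is.null(config$manifest) && !file.exists(config$manifest))
    stop("config validation failed: field 'manifest' points to a missing ",
         "file: ", config$manifest)
  if (!identical(config$model, "published") && !file.exists(config$model))
    stop("config validation failed: field 'model' points to a missing ",
         "file: ", config$model)
  if (is.null(config$out_dir))
    stop("config validation failed: field 'out_dir' is required")
  class(config) <- "hsaRunConfig"
  config
}

.configHash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  fields <- config[sort(setdiff(names(config), character(0)))]
  writeLines(paste(names(fields),
                   vapply(fields, function(x) paste(format(x), collapse = " "),
                          character(1))), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full prediction pipeline
#'
#' Executes ingestion, score injection, ensemble aggregation, combined
#' scoring, binder classification, site preference, and (when observed
#' \%HSA values are present) ROC evaluation against the strict binder /
#' weak-binder labels. Every artifact is stamped with the config hash and
#' seed; rerunning with an identical config and injected scores reproduces
#' the prediction tables byte for byte. Per-ligand failures are logged and
#' summarized, never fatal; only configuration validation aborts a run.
#'
#' @param config a config list/path accepted by \code{\link{readRunConfig}}.
#' @return invisibly, a list with \code{predictions},
#'   \code{evaluation} (or NULL), and the artifact paths.
#' @export
runPredict <- function(config) {
  config <- readRunConfig(config)
  hash <- .configHash(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  logPath <- file.path(config$out_dir, "run.log")
  logCon <- file(logPath, "w")
  logmsg <- function(...) writeLines(paste0(...), logCon)
  on.exit(close(logCon))
  logmsg("# HSAbind run")
  logmsg("time: ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  logmsg("config_hash: ", hash)
  logmsg("seed: ", config$seed)

  ligands <- readLigands(config$scores, format = "score-table")
  logmsg("ligands: ", length(ligands))
  backend <- scoreTableBackend(config$scores)

  ## ensemble: explicit manifest, or inferred from the score columns
  header <- strsplit(readLines(config$scores, n = 1),
                     if (grepl("\t", readLines(config$scores, n = 1)))
                       "\t" else ",")[[1]]
  scoreCols <- grep("^[0-9][A-Za-z0-9]{3}:", header, value = TRUE)
  if (!is.null(config$manifest)) {
    ensemble <- buildEnsemble(config$manifest)
  } else {
    pdbs <- unique(vapply(strsplit(scoreCols, ":"), `[`, "", 1))
    known <- match(pdbs, .HSA_MANIFEST$pdb_id)
    ensemble <- buildEnsemble(data.frame(
      pdb_id = pdbs,
      resolution = ifelse(is.na(known), 2.5,
                          .HSA_MANIFEST$resolution[known])))
    logmsg("ensemble inferred from score columns: ",
           paste(pdbs, collapse = " "))
  }
  sites <- unique(vapply(strsplit(scoreCols, ":"), `[`, "", 2))
  pockets <- defaultSitePockets()[intersect(c("site_I", "site_II"), sites)]
  logmsg("applied defaults: site geometry (centroids in the 1N5U frame, ",
         "boxes 10/30 A); score convention kcal/mol, lower = better; ",
         "failed dockings excluded from aggregation")

  model <- if (identical(config$model, "published")) {
    logmsg("model: published coefficients 25.41 / -1.95 / 7.68")
    defaultCombinedModel()
  } else readCombinedModel(config$model)

  dex <- suppressMessages(dockLigands(ligands, ensemble, pockets, backend))
  ens <- suppressMessages(aggregateBest(dex))
  if (length(attr(ens, "unscored")))
    logmsg("ligands with zero ok docking results: ",
           paste(attr(ens, "unscored"), collapse = ", "))

  lp <- logP(ligands)[ens$ligand_id]
  ok <- is.finite(ens$best_overall) & is.finite(lp)
  score <- rep(NA_real_, nrow(ens))
  score[ok] <- combinedScore(model, ens$best_overall[ok], lp[ok])
  sp <- sitePreference(ens, threshold = config$site_threshold)
  pred <- data.frame(
    ligand_id = ens$ligand_id,
    xp_best = ens$best_overall,
    best_site_I = ens$best_site_I,
    best_site_II = ens$best_site_II,
    n_predictions = ens$n_predictions,
    logp = unname(lp),
    combined_score = score,
    predicted_hsa_percent = pmin(100, pmax(0, score)),
    delta_site = sp$delta,
    predicted_site = as.character(sp$predicted_site),
    stringsAsFactors = FALSE)

  obs <- hsaPercent(ligands)[pred$ligand_id]
  evalTab <- NULL
  if (any(is.finite(obs))) {
    pred$hsa_percent_obs <- unname(obs)
    cls <- rep(NA_character_, nrow(pred))
    fin <- is.finite(obs)
    cls[fin] <- as.character(suppressMessages(
      classifyBinder(obs[fin], config$weak_cutoff, config$binder_cutoff)))
    pred$class_obs <- cls
    strict <- fin & cls %in% c("weak", "binder") & ok
    if (sum(strict) >= 2 && length(unique(cls[strict])) == 2) {
      labels <- cls[strict] == "binder"
      evalTab <- evaluationReport(
        list(combined = pred$combined_score[strict],
             xp_only = -pred$xp_best[strict],
             logp_only = pred$logp[strict]),
        labels, setName = "strict")
      logmsg("evaluation on strict set: n_pos = ", sum(labels),
             ", n_neg = ", sum(!labels))
    } else logmsg("evaluation skipped: strict set lacks both classes")
  } else logmsg("no observed %HSA values; evaluation skipped")

  stamp <- sprintf("# config_hash=%s seed=%d", hash, as.integer(config$seed))
  predPath <- file.path(config$out_dir, "predictions.tsv")
  writeLines(stamp, predPath)
  suppressWarnings(utils::write.table(
    pred, predPath, sep = "\t", quote = FALSE,
    row.names = FALSE, append = TRUE))
  evalPath <- NULL
  if (!is.null(evalTab)) {
    evalPath <- file.path(config$out_dir, "evaluation.tsv")
    writeLines(stamp, evalPath)
    suppressWarnings(utils::write.table(
      evalTab, evalPath, sep = "\t", quote = FALSE,
      row.names = FALSE, append = TRUE))
  }
  logmsg("predictions: ", predPath)
  invisible(list(predictions = pred, evaluation = evalTab,
                 paths = c(predictions = predPath, evaluation = evalPath,
                           log = logPath),
                 config_hash = hash))
}
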