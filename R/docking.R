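## Pluggable docking backends and ensemble best-score aggregation.
##
## The score convention is fixed across the package: kcal/mol, more negative
## = more favorable. Docking against all ten ensemble structures and both
## xenobiotic sites yields 20 predictions per compound (the "20 site" model);
## the reduction keeps the per-site minima and the global minimum.

#' Score-table docking backend
#'
#' Replays precomputed docking scores (for example published Glide XP
#' scores) from a table instead of invoking an engine. Accepts either a long
#' table with columns \code{ligand_id}, \code{pdb_id}, \code{site},
#' \code{score}, or a wide table with a \code{ligand_id} column and score
#' columns named \code{<pdbid>:<site>} (the score-table exchange format; a
#' path to such a file is also accepted). Ligands absent from the table come
#' back with status \code{failed}, not an error.
#'
#' @param x data.frame or file path.
#' @return a backend object for \code{\link{dockLigands}}.
#' @export
scoreTableBackend <- function(x) {
  if (is.character(x) && length(x) == 1) {
    first <- readLines(x, n = 1)
    sep <- if (grepl("\t", first)) "\t" else ","
    x <- utils::read.table(x, header = TRUE, sep = sep, check.names = FALSE,
                           stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(x))
  if (all(c("ligand_id", "pdb_id", "site", "score") %in% colnames(x))) {
    long <- x[, c("ligand_id", "pdb_id", "site", "score")]
  } else if ("ligand_id" %in% colnames(x)) {
    scoreCols <- grep("^[0-9][A-Za-z0-9]{3}:", colnames(x), value = TRUE)
    if (!length(scoreCols))
      stop("no <pdbid>:<site> score columns found in score table")
    long <- do.call(rbind, lapply(scoreCols, function(cn) {
      ps <- strsplit(cn, ":", fixed = TRUE)[[1]]
      data.frame(ligand_id = x$ligand_id, pdb_id = ps[1], site = ps[2],
                 score = x[[cn]], stringsAsFactors = FALSE)
    }))
    long <- long[!is.na(long$score), ]
  } else stop("score table must carry a ligand_id column")
  key <- paste(long$ligand_id, long$pdb_id, long$site, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (ligand_id, pdb_id, site) entries in score table")
  lookup <- stats::setNames(long$score, key)
  structure(list(
    name = "score-table",
    dock = function(ligandId, pdbId, site, flexible = FALSE) {
      v <- lookup[paste(ligandId, pdbId, site, sep = "\r")]
      if (is.na(v)) list(score = NA_real_, status = "failed")
      else list(score = unname(v), status = "ok")
    }), class = "dockingBackend")
}

#' External-engine docking backend
#'
#' Adapter for an external docking engine invoked per (ligand, structure,
#' site) as a subprocess. The engine is expected to accept a receptor file,
#' a ligand structure, and grid-box geometry, and print the best pose score;
#' \code{parse} extracts that score from the captured output. A fixed seed
#' is passed so reruns agree. If the executable is not on the path, every
#' call returns status \code{failed} (and is logged) rather than raising.
#'
#' @param executable engine binary name or path.
#' @param argsFun function(receptorFile, ligandId, pocket, seed, flexible)
#'   returning the argument vector for one invocation.
#' @param parse function(characterOutput) returning the numeric score.
#' @param seed integer passed to \code{argsFun}; fixed by default for
#'   reproducibility.
#' @param flexibleResidues optional residue list forwarded to
#'   \code{argsFun} when flexible docking is requested (stands in for
#'   induced-fit side-chain optimization where the engine supports it).
#' @return a backend object for \code{\link{dockLigands}}.
#' @export
commandBackend <- function(executable, argsFun, parse = function(out)
  as.numeric(utils::tail(out, 1)), seed = 42L, flexibleResidues = NULL) {
  structure(list(
    name = paste0("engine:", executable),
    dock = function(ligandId, pdbId, site, flexible = FALSE,
                    receptorFile = NA, pocket = NULL) {
      if (!nzchar(Sys.which(executable)))
        return(list(score = NA_real_, status = "failed",
                    message = paste0("engine not available: ", executable)))
      out <- tryCatch(
        system2(executable,
                argsFun(receptorFile, ligandId, pocket, seed, flexible),
                stdout = TRUE, stderr = TRUE),
        warning = function(w) NULL, error = function(e) NULL)
      if (is.null(out) || !is.null(attr(out, "status")))
        return(list(score = NA_real_, status = "failed",
                    message = "engine exited with nonzero status"))
      sc <- suppressWarnings(parse(out))
      if (!length(sc) || !is.finite(sc))
        return(list(score = NA_real_, status = "failed",
                    message = "could not parse engine output"))
      list(score = sc, status = "ok")
    }), class = "dockingBackend")
}

#' Dock a ligand set against a receptor ensemble
#'
#' Runs the configured backend for every (ligand, structure, site)
#' combination and collects the results into a
#' \linkS4class{DockingExperiment}. Failures are recorded with status 0 and
#' an NA score; they never abort the run.
#'
#' @param ligands a \linkS4class{LigandSet}.
#' @param ensemble a \linkS4class{ReceptorEnsemble}.
#' @param pockets named list of \linkS4class{SitePocket} (default both
#'   xenobiotic sites).
#' @param backend a backend from \code{\link{scoreTableBackend}} or
#'   \code{\link{commandBackend}}.
#' @param flexible request receptor side-chain flexibility where the
#'   backend supports it.
#' @return a \linkS4class{DockingExperiment} (ligands x conditions).
#' @export
dockLigands <- function(ligands, ensemble, pockets = defaultSitePockets(),
                        backend, flexible = FALSE) {
  stopifnot(is(ligands, "LigandSet"), is(ensemble, "ReceptorEnsemble"),
            inherits(backend, "dockingBackend"))
  ids <- ligandIds(ligands)
  ent <- ensembleEntries(ensemble)
  conds <- expand.grid(pdb = ent$pdb_id, site = names(pockets),
                       stringsAsFactors = FALSE)
  score <- matrix(NA_real_, nrow = length(ids), ncol = nrow(conds),
                  dimnames = list(ids, paste(conds$pdb, conds$site,
                                             sep = ":")))
  status <- matrix(0L, nrow = length(ids), ncol = nrow(conds),
                   dimnames = dimnames(score))
  for (j in seq_len(nrow(conds))) {
    pk <- pockets[[conds$site[j]]]
    rf <- ent$file[match(conds$pdb[j], ent$pdb_id)]
    for (i in seq_along(ids)) {
      r <- backend$dock(ids[i], conds$pdb[j], conds$site[j],
                        flexible = flexible)
      if (identical(r$status, "ok")) {
        score[i, j] <- r$score
        status[i, j] <- 1L
      }
    }
  }
  nFail <- sum(status == 0L)
  if (nFail > 0)
    message(nFail, " of ", length(status),
            " docking attempts failed and are excluded from aggregation")
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(score = score, status = status),
    rowData = ligands@info,
    colData = DataFrame(
      pdb_id = conds$pdb, site = conds$site,
      fatty_acid_retained =
        ent$fatty_acid_retained[match(conds$pdb, ent$pdb_id)],
      row.names = colnames(score)))
  new("DockingExperiment", se)
}

#' Build a DockingExperiment directly from a long results table
#'
#' @param results data.frame with columns \code{ligand_id}, \code{pdb_id},
#'   \code{site}, \code{score} and optionally \code{status}
#'   (\code{ok}/\code{failed}).
#' @return a \linkS4class{DockingExperiment}.
#' @export
dockingExperimentFromTable <- function(results) {
  need <- c("ligand_id", "pdb_id", "site", "score")
  stopifnot(all(need %in% colnames(results)))
  if (nrow(results) == 0) stop("empty docking results")
  st <- if ("status" %in% colnames(results))
    as.integer(results$status == "ok") else
    as.integer(is.finite(results$score))
  key <- paste(results$ligand_id, results$pdb_id, results$site)
  if (anyDuplicated(key))
    stop("(ligand_id, pdb_id, site) must be unique per run")
  ids <- unique(results$ligand_id)
  cond <- unique(paste(results$pdb_id, results$site, sep = ":"))
  score <- matrix(NA_real_, length(ids), length(cond),
                  dimnames = list(ids, cond))
  status <- matrix(0L, length(ids), length(cond), dimnames = list(ids, cond))
  ij <- cbind(match(results$ligand_id, ids),
              match(paste(results$pdb_id, results$site, sep = ":"), cond))
  score[ij] <- ifelse(st == 1L, results$score, NA_real_)
  status[ij] <- st
  ps <- strsplit(cond, ":", fixed = TRUE)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(score = score, status = status),
    colData = DataFrame(pdb_id = vapply(ps, `[`, "", 1),
                        site = vapply(ps, `[`, "", 2),
                        fatty_acid_retained = FALSE,
                        row.names = cond))
  new("DockingExperiment", se)
}

#' Ensemble best-score aggregation
#'
#' Reduces the per-(structure, site) predictions of a
#' \linkS4class{DockingExperiment} to one row per ligand: the minimum (most
#' favorable) score over all contributing ok results, the per-site minima,
#' and the number of contributing predictions. Failed dockings never
#' contribute; ligands with zero ok results are reported with NA best scores
#' and listed in the \code{"unscored"} attribute. Docking ten structures
#' against both sites therefore gives \code{n_predictions = 20} when all
#' succeed.
#'
#' @param x a \linkS4class{DockingExperiment}.
#' @return \code{DataFrame} with columns \code{ligand_id},
#'   \code{best_overall}, \code{best_site_I}, \code{best_site_II},
#'   \code{n_predictions}.
#' @export
setMethod("aggregateBest", "DockingExperiment", function(x, ...) {
  sc <- SummarizedExperiment::assay(x, "score")
  st <- SummarizedExperiment::assay(x, "status")
  site <- SummarizedExperiment::colData(x)$site
  if (nrow(sc) == 0) stop("empty docking experiment")
  sc[st != 1L] <- NA_real_
  minOr <- function(v) if (all(is.na(v))) NA_real_ else min(v, na.rm = TRUE)
  bestI <- apply(sc[, site == "site_I", drop = FALSE], 1, minOr)
  bestII <- apply(sc[, site == "site_II", drop = FALSE], 1, minOr)
  out <- DataFrame(
    ligand_id = rownames(sc),
    best_overall = unname(apply(sc, 1, minOr)),
    best_site_I = unname(bestI),
    best_site_II = unname(bestII),
    n_predictions = as.integer(rowSums(st == 1L)))
  unscored <- out$ligand_id[out$n_predictions == 0L]
  if (length(unscored))
    message(length(unscored), " ligand(s) with zero ok results: ",
            paste(utils::head(unscored, 5), collapse = ", "))
  attr(out, "unscored") <- unscored
  out
})
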