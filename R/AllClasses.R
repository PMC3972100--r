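#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

#' LigandSet: a set of compounds with structures and descriptors
#'
#' Container for per-compound identity, parsed molecular graphs (when the
#' input format carried structures), the logP descriptor, curated \%HSA
#' evidence from one or more literature sources, and a free-text note for
#' racemic/enantiomer handling. Both members of an enantiomer pair are kept
#' as separate records.
#'
#' @slot info a \code{DataFrame} with columns \code{ligand_id},
#'   \code{smiles}, \code{logp}, \code{stereo_note}.
#' @slot hsaValues named list (per ligand) of data.frames with columns
#'   \code{value} (\%HSA in [0, 100]) and \code{source}.
#' @slot mols list of internal molecular graphs (or NULL where the record
#'   came from a score table).
#' @exportClass LigandSet
setClass("LigandSet",
  representation(info = "DataFrame", hsaValues = "list", mols = "list"),
  validity = function(object) {
    msg <- NULL
    ids <- object@info$ligand_id
    if (anyDuplicated(ids))
      msg <- c(msg, "duplicate ligand_id")
    if (length(object@mols) && length(object@mols) != length(ids))
      msg <- c(msg, "mols length disagrees with info")
    lp <- object@info$logp
    if (!is.null(lp) && any(!is.na(lp) & !is.finite(lp)))
      msg <- c(msg, "non-finite logp")
    for (h in object@hsaValues) {
      if (is.null(h)) next
      if (any(h$value < 0 | h$value > 100))
        msg <- c(msg, "hsa_percent value outside [0, 100]")
    }
    if (is.null(msg)) TRUE else msg
  })

#' SitePocket: binding-site geometry for grid docking
#'
#' Centroid and grid-box edge lengths of an HSA binding pocket, expressed in
#' the frame of the alignment-reference structure (1N5U). Defaults are the
#' site I (warfarin) and site II (indole/benzodiazepine) definitions used for
#' rigid-receptor grids: inner box 10 Angstrom, outer box 30 Angstrom.
#'
#' @slot siteName one of \code{site_I}, \code{site_II}, or a user-supplied
#'   \code{extra_*} pocket name.
#' @slot centroid numeric xyz, Angstrom.
#' @slot innerBox,outerBox grid edge lengths, Angstrom; inner <= outer.
#' @exportClass SitePocket
setClass("SitePocket",
  representation(siteName = "character", centroid = "numeric",
                 innerBox = "numeric", outerBox = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(object@centroid) != 3 || any(!is.finite(object@centroid)))
      msg <- c(msg, "centroid must be finite xyz")
    if (object@innerBox > object@outerBox)
      msg <- c(msg, "inner_box > outer_box")
    if (object@innerBox <= 0)
      msg <- c(msg, "box edges must be positive")
    if (!grepl("^(site_I|site_II|extra)", object@siteName))
      msg <- c(msg, paste0("unknown site name: ", object@siteName))
    if (is.null(msg)) TRUE else msg
  })

#' ReceptorEnsemble: the HSA crystal-structure ensemble
#'
#' The structures docked against, sorted by resolution (best first), each
#' with an optional PDB file path, the fatty-acid retention flag, and the
#' alignment reference in whose frame the site centroids are given.
#' Receptor preparation (protonation, side-chain placement, alignment to the
#' reference) is expected to have been done upstream.
#'
#' @slot entries \code{DataFrame} with columns \code{pdb_id}, \code{file},
#'   \code{resolution}, \code{fatty_acid_retained}, \code{alignment_reference}.
#' @exportClass ReceptorEnsemble
setClass("ReceptorEnsemble",
  representation(entries = "DataFrame"),
  validity = function(object) {
    e <- object@entries
    msg <- NULL
    need <- c("pdb_id", "file", "resolution", "fatty_acid_retained",
              "alignment_reference")
    if (!all(need %in% colnames(e)))
      msg <- c(msg, "missing manifest columns")
    else {
      if (nrow(e) == 0) msg <- c(msg, "empty ensemble")
      if (anyDuplicated(e$pdb_id)) msg <- c(msg, "duplicate pdb_id")
      if (any(!grepl("^[0-9][A-Za-z0-9]{3}$", e$pdb_id)))
        msg <- c(msg, "malformed pdb_id")
      if (any(!is.finite(e$resolution) | e$resolution <= 0))
        msg <- c(msg, "resolution must be > 0")
    }
    if (is.null(msg)) TRUE else msg
  })

#' DockingExperiment: per-(structure, site) docking scores for a ligand set
#'
#' A \code{SummarizedExperiment} with ligands as rows and (structure, site)
#' docking conditions as columns. Assay \code{score} holds scores in
#' kcal/mol (more negative = more favorable); assay \code{status} holds 1 for
#' ok and 0 for failed. Column data carries \code{pdb_id}, \code{site},
#' \code{fatty_acid_retained}; row data carries ligand descriptors.
#' @exportClass DockingExperiment
setClass("DockingExperiment", contains = "SummarizedExperiment",
  validity = function(object) {
    msg <- NULL
    if (!all(c("score", "status") %in%
             SummarizedExperiment::assayNames(object)))
      msg <- c(msg, "assays 'score' and 'status' required")
    else {
      sc <- SummarizedExperiment::assay(object, "score")
      st <- SummarizedExperiment::assay(object, "status")
      if (any(st == 1 & !is.finite(sc)))
        msg <- c(msg, "ok results must have finite scores")
    }
    if (!all(c("pdb_id", "site") %in%
             colnames(SummarizedExperiment::colData(object))))
      msg <- c(msg, "colData must carry pdb_id and site")
    if (is.null(msg)) TRUE else msg
  })

#' CombinedModel: the linear binding scorer
#'
#' The affine model \code{score = intercept + alpha * xp + beta * logp}
#' mapping the best ensemble docking score (kcal/mol) and logP to a
#' dimensionless binding score on the \%HSA scale (higher = stronger
#' predicted binding). The published coefficients are intercept 25.41,
#' alpha -1.95, beta 7.68 (see \code{\link{defaultCombinedModel}}).
#'
#' @slot intercept,alpha,beta finite model coefficients.
#' @slot fitMeta list of fit metadata (n, nBoot, seed, percentile
#'   confidence intervals) when the model came from \code{\link{fitCombined}}.
#' @exportClass CombinedModel
setClass("CombinedModel",
  representation(intercept = "numeric", alpha = "numeric", beta = "numeric",
                 fitMeta = "list"),
  validity = function(object) {
    co <- c(object@intercept, object@alpha, object@beta)
    if (length(co) != 3 || any(!is.finite(co)))
      return("coefficients must be three finite numbers")
    TRUE
  })

#' ROCResult: ranked-classification evaluation
#'
#' Receiver operating characteristic of a decision statistic against
#' binary labels. Points start at (0, 0), end at (1, 1); tied scores are
#' processed as a single threshold step (one diagonal segment). The area
#' under the curve is computed both by the trapezoid rule and by
#' concordant-pair counting (Mann-Whitney, ties at half credit); the two
#' must agree and \code{auc} stores the trapezoid value.
#'
#' @slot fpr,tpr curve coordinates.
#' @slot auc area under the curve in [0, 1].
#' @slot nPos,nNeg class counts.
#' @slot tprAtZeroFpr fraction of positives ranked above every negative
#'   (early enrichment at zero false-positive rate).
#' @exportClass ROCResult
setClass("ROCResult",
  representation(fpr = "numeric", tpr = "numeric", auc = "numeric",
                 nPos = "integer", nNeg = "integer",
                 tprAtZeroFpr = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(object@fpr) != length(object@tpr))
      msg <- c(msg, "fpr/tpr length mismatch")
    if (is.unsorted(object@fpr) || is.unsorted(object@tpr))
      msg <- c(msg, "curve must be non-decreasing")
    if (object@auc < 0 || object@auc > 1) msg <- c(msg, "auc outside [0, 1]")
    if (is.null(msg)) TRUE else msg
  })

## ---- show methods ---------------------------------------------------------

setMethod("show", "LigandSet", function(object) {
  cat("LigandSet with", nrow(object@info), "ligands\n")
  nMol <- sum(!vapply(object@mols, is.null, logical(1)))
  nLp <- sum(is.finite(object@info$logp))
  nH <- sum(vapply(object@hsaValues, function(x) !is.null(x) && nrow(x) > 0,
                   logical(1)))
  cat(" structures:", nMol, "| logP computed:", nLp,
      "| with %HSA evidence:", nH, "\n")
})

setMethod("show", "SitePocket", function(object) {
  cat(sprintf("SitePocket %s: centroid (%.2f, %.2f, %.2f) A, box %g/%g A\n",
              object@siteName, object@centroid[1], object@centroid[2],
              object@centroid[3], object@innerBox, object@outerBox))
})

setMethod("show", "ReceptorEnsemble", function(object) {
  e <- object@entries
  cat("ReceptorEnsemble with", nrow(e), "structures",
      sprintf("(%.2f-%.2f A)\n", min(e$resolution), max(e$resolution)))
  cat(" ", paste0(e$pdb_id, ifelse(e$fatty_acid_retained, "*", ""),
                  collapse = " "), "\n")
  if (any(e$fatty_acid_retained)) cat("  (* fatty acid retained)\n")
})

setMethod("show", "CombinedModel", function(object) {
  cat(sprintf(
    "CombinedModel: score = %.4g + (%.4g) * xp_score + (%.4g) * logP\n",
    object@intercept, object@alpha, object@beta))
  if (length(object@fitMeta))
    cat("  fitted: n =", object@fitMeta$n, ", bootstrap replicates =",
        object@fitMeta$nBoot, "\n")
})

setMethod("show", "ROCResult", function(object) {
  cat(sprintf("ROCResult: AUC = %.4f (%d pos / %d neg), TPR@FPR=0: %.4f\n",
              object@auc, object@nPos, object@nNeg, object@tprAtZeroFpr))
})
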