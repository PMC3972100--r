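## Ligand ingestion: SDF, SMILES lists, and precomputed score tables.

#' Read ligands from SDF, SMILES, or a score table
#'
#' Builds a \linkS4class{LigandSet} from one of the supported input formats.
#' Molecules that fail to parse or sanitize are reported via a warning and
#' skipped, never silently dropped. Enantiomer pairs present as separate
#' records are retained as separate records (compounds dosed as racemic
#' mixtures are commonly reported with a single \%HSA value; keep both
#' stereoisomers and tag them through \code{stereo_note}).
#'
#' Formats:
#' \describe{
#'   \item{sdf}{MDL SD file (V2000). Record names become ligand ids; formal
#'     charges are taken from \code{M  CHG} blocks.}
#'   \item{smiles}{one molecule per line, optionally followed by whitespace
#'     and an id. Requires the ChemmineOB package for structure conversion.}
#'   \item{score-table}{tab- or comma-delimited with header columns
#'     \code{ligand_id}, optionally \code{logp} (passed through untouched),
#'     \code{hsa_percent}, \code{source}, \code{stereo_note}, and any number
#'     of score columns named \code{<pdbid>:<site>} (consumed by
#'     \code{\link{scoreTableBackend}}).}
#' }
#'
#' @param path input file.
#' @param format one of \code{"auto"}, \code{"sdf"}, \code{"smiles"},
#'   \code{"score-table"}; \code{"auto"} guesses from the file extension.
#' @param seToS map selenium atoms to sulfur before descriptor calculation
#'   (off by default).
#' @return a \linkS4class{LigandSet}.
#' @examples
#' tbl <- system.file("extdata", "synthetic_scores.tsv", package = "HSAbind")
#' lig <- readLigands(tbl, format = "score-table")
#' lig
#' @export
readLigands <- function(path, format = c("auto", "sdf", "smiles",
                                         "score-table"), seToS = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, sdf = "sdf", mol = "sdf", smi = "smiles",
                     smiles = "smiles", tsv = "score-table",
                     csv = "score-table", txt = "score-table",
                     stop("cannot guess format from extension: ", ext))
  }
  switch(format,
         "sdf" = .readLigandsSDF(path, seToS = seToS),
         "smiles" = .readLigandsSMILES(path, seToS = seToS),
         "score-table" = .readLigandsTable(path))
}

.newLigandSet <- function(ids, smiles = NA_character_, logp = NA_real_,
                          stereo = NA_character_, hsaValues = NULL,
                          mols = NULL) {
  n <- length(ids)
  if (is.null(hsaValues)) hsaValues <- rep(list(NULL), n)
  if (is.null(mols)) mols <- rep(list(NULL), n)
  names(hsaValues) <- ids
  new("LigandSet",
      info = DataFrame(ligand_id = ids,
                       smiles = rep_len(smiles, n),
                       logp = rep_len(logp, n),
                       stereo_note = rep_len(stereo, n)),
      hsaValues = hsaValues, mols = mols)
}

## Formal charges per SDF record: ChemmineR keeps only the legacy atom-block
## charge column, so M CHG property lines are recovered from the raw text.
.sdfCharges <- function(path) {
  txt <- readLines(path, warn = FALSE)
  rec <- cumsum(c(1L, utils::head(txt, -1) == "$$$$"))
  lapply(split(txt, rec), function(r) {
    out <- integer(0)
    for (l in grep("^M  CHG", r, value = TRUE)) {
      f <- scan(text = sub("^M  CHG", "", l), quiet = TRUE)
      n <- f[1]
      if (length(f) >= 1 + 2 * n)
        for (k in seq_len(n)) out[as.character(f[2 * k])] <- f[2 * k + 1]
    }
    if (length(out)) out else NULL
  })
}

.readLigandsSDF <- function(path, seToS = FALSE) {
  sdfs <- tryCatch(suppressWarnings(ChemmineR::read.SDFset(path)),
                   error = function(e)
                     stop("zero parsable records in ", path, call. = FALSE))
  if (length(sdfs) == 0) stop("zero parsable records in ", path)
  ok <- ChemmineR::validSDF(sdfs)
  charges <- .sdfCharges(path)
  nSkip <- sum(!ok)
  if (nSkip > 0)
    warning(nSkip, " record(s) failed sanitization and were skipped")
  sdfs <- sdfs[ok]
  charges <- charges[ok]
  if (length(sdfs) == 0) stop("zero parsable records in ", path)
  ids <- vapply(seq_along(sdfs), function(i) {
    h <- ChemmineR::header(sdfs[[i]])[["Molecule_Name"]]
    if (is.null(h) || !nzchar(trimws(h))) paste0("mol", i) else trimws(h)
  }, character(1))
  if (anyDuplicated(ids)) stop("duplicate ligand_id in ", path, ": ",
                               paste(unique(ids[duplicated(ids)]),
                                     collapse = ", "))
  mols <- lapply(seq_along(sdfs), function(i)
    .molFromSDF(sdfs[[i]], charges = charges[[i]], seToS = seToS))
  ls <- .newLigandSet(ids, mols = mols)
  validObject(ls)
  ls
}

.readLigandsSMILES <- function(path, seToS = FALSE) {
  if (!requireNamespace("ChemmineOB", quietly = TRUE))
    stop("SMILES input requires the ChemmineOB package")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("zero parsable records in ", path)
  smi <- vapply(strsplit(trimws(lines), "[ \t]+"), `[`, character(1), 1)
  ids <- vapply(seq_along(lines), function(i) {
    f <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(f) > 1) f[2] else paste0("mol", i)
  }, character(1))
  if (anyDuplicated(ids)) stop("duplicate ligand_id in ", path)
  ## convert through a temporary SDF *file*: in-memory conversion drops the
  ## M CHG property block that carries formal charges
  tmpSmi <- tempfile(fileext = ".smi"); tmpSdf <- tempfile(fileext = ".sdf")
  on.exit(unlink(c(tmpSmi, tmpSdf)))
  writeLines(paste(smi, ids, sep = "\t"), tmpSmi)
  tryCatch(
    ChemmineOB::convertFormatFile("SMI", "SDF", tmpSmi, tmpSdf),
    error = function(e) stop("zero parsable records in ", path,
                             call. = FALSE))
  parsed <- tryCatch(.readLigandsSDF(tmpSdf, seToS = seToS),
                     error = function(e) NULL)
  parsedIds <- if (is.null(parsed)) character(0) else ligandIds(parsed)
  mols <- vector("list", length(smi))
  mols[ids %in% parsedIds] <-
    parsed@mols[match(ids[ids %in% parsedIds], parsedIds)]
  ## a line the converter rejects aborts the remainder of the batch, so
  ## retry unconverted lines one at a time
  for (i in which(vapply(mols, is.null, logical(1)))) {
    writeLines(paste(smi[i], ids[i], sep = "\t"), tmpSmi)
    one <- tryCatch({
      ChemmineOB::convertFormatFile("SMI", "SDF", tmpSmi, tmpSdf)
      .readLigandsSDF(tmpSdf, seToS = seToS)
    }, error = function(e) NULL)
    if (!is.null(one) && length(one) == 1) mols[[i]] <- one@mols[[1]]
  }
  bad <- vapply(mols, is.null, logical(1))
  if (any(bad))
    warning(sum(bad), " SMILES line(s) failed to parse and were skipped: ",
            paste(utils::head(ids[bad], 5), collapse = ", "))
  if (all(bad)) stop("zero parsable records in ", path)
  ids <- ids[!bad]; smi <- smi[!bad]; mols <- mols[!bad]
  ls <- .newLigandSet(ids, smiles = smi, mols = mols)
  validObject(ls)
  ls
}

.readLigandsTable <- function(path) {
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (!"ligand_id" %in% colnames(tab))
    stop("score table must have a ligand_id column")
  if (nrow(tab) == 0) stop("zero parsable records in ", path)
  ## one row per (ligand, source); collapse to one record per ligand
  ids <- unique(tab$ligand_id)
  getcol <- function(col, default) {
    if (col %in% colnames(tab)) tab[[col]] else rep(default, nrow(tab))
  }
  lp <- getcol("logp", NA_real_)
  st <- getcol("stereo_note", NA_character_)
  hp <- getcol("hsa_percent", NA_real_)
  src <- getcol("source", NA_character_)
  firstRow <- match(ids, tab$ligand_id)
  hsaValues <- lapply(ids, function(id) {
    rows <- which(tab$ligand_id == id & !is.na(hp))
    if (!length(rows)) return(NULL)
    data.frame(value = hp[rows],
               source = ifelse(is.na(src[rows]), "unspecified", src[rows]),
               stringsAsFactors = FALSE)
  })
  ls <- .newLigandSet(ids, logp = lp[firstRow], stereo = st[firstRow],
                      hsaValues = hsaValues)
  validObject(ls)
  ls
}

## ---- accessors ------------------------------------------------------------

#' Ligand identifiers
#' @param x a \linkS4class{LigandSet}.
#' @return character vector of ligand ids.
#' @export
setMethod("ligandIds", "LigandSet", function(x) x@info$ligand_id)

#' Get or set the logP descriptor
#' @param x a \linkS4class{LigandSet}.
#' @param value replacement numeric vector.
#' @return numeric vector named by ligand id.
#' @export
setMethod("logP", "LigandSet", function(x)
  stats::setNames(x@info$logp, x@info$ligand_id))

#' @rdname logP
#' @export
setMethod("logP<-", "LigandSet", function(x, value) {
  x@info$logp <- unname(value)
  validObject(x)
  x
})

#' Curated \%HSA evidence per ligand
#'
#' @param x a \linkS4class{LigandSet}.
#' @param collapse \code{"mean"} (default) averages over sources;
#'   \code{"none"} returns the long table of (ligand_id, value, source).
#' @return named numeric vector of mean \%HSA, or a data.frame.
#' @export
setMethod("hsaPercent", "LigandSet", function(x, collapse = c("mean", "none")) {
  collapse <- match.arg(collapse)
  if (collapse == "none") {
    rows <- lapply(names(x@hsaValues), function(id) {
      h <- x@hsaValues[[id]]
      if (is.null(h) || !nrow(h)) return(NULL)
      cbind(ligand_id = id, h)
    })
    return(do.call(rbind, rows))
  }
  vapply(x@hsaValues, function(h)
    if (is.null(h) || !nrow(h)) NA_real_ else mean(h$value), numeric(1))
})

setMethod("length", "LigandSet", function(x) nrow(x@info))

setMethod("[", "LigandSet", function(x, i, j, ..., drop = TRUE) {
  if (is.character(i)) i <- match(i, x@info$ligand_id)
  new("LigandSet", info = x@info[i, , drop = FALSE],
      hsaValues = x@hsaValues[i], mols = x@mols[i])
})

## ---- logP computation -----------------------------------------------------

#' Compute the atomic-contribution logP descriptor
#'
#' Fills the \code{logp} column of a \linkS4class{LigandSet} using the
#' Wildman-Crippen atomic-contribution method on each parsed structure.
#' Records whose logP was supplied by the input (score-table pass-through)
#' keep their value untouched unless \code{overwrite = TRUE}. The
#' calculation is a pure function of the molecular graph.
#'
#' @param x a \linkS4class{LigandSet}.
#' @param overwrite recompute even where a logP value is already present.
#' @return the updated \linkS4class{LigandSet}.
#' @export
setMethod("computeLogP", "LigandSet", function(x, overwrite = FALSE) {
  lp <- x@info$logp
  for (i in seq_len(nrow(x@info))) {
    if (!overwrite && is.finite(lp[i])) next
    m <- x@mols[[i]]
    if (is.null(m)) {
      if (!is.finite(lp[i]))
        warning("no structure and no logP for ", x@info$ligand_id[i])
      next
    }
    lp[i] <- .wcLogP(m)
  }
  x@info$logp <- lp
  validObject(x)
  x
})
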