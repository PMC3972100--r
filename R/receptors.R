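## HSA receptor ensemble and binding-site geometry.

## The ten best-resolution HSA crystal structures, resolutions in Angstrom.
## Centroids are expressed in the frame of the alignment reference 1N5U;
## structural superposition itself is an upstream preprocessing step.
.HSA_MANIFEST <- data.frame(
  pdb_id = c("1N5U", "3A73", "1E7A", "2BXH", "2BXP",
             "3JRY", "2BXA", "1E7B", "2XW0", "1HK4"),
  resolution = c(1.90, 2.19, 2.20, 2.25, 2.30, 2.30, 2.35, 2.38, 2.40, 2.40),
  stringsAsFactors = FALSE)

.ALIGN_REF <- "1N5U"

#' Default site I / site II pocket definitions
#'
#' Site I (warfarin site) centroid (30.5, 13.1, 9.7) Angstrom and site II
#' (indole/benzodiazepine site) centroid (10.25, 2.11, -13.75) Angstrom in
#' the 1N5U-aligned frame, with a 10 Angstrom inner and 30 Angstrom outer
#' grid box.
#'
#' @return list of two \linkS4class{SitePocket} objects.
#' @examples
#' defaultSitePockets()
#' @export
defaultSitePockets <- function() {
  list(site_I = new("SitePocket", siteName = "site_I",
                    centroid = c(30.5, 13.1, 9.7),
                    innerBox = 10, outerBox = 30),
       site_II = new("SitePocket", siteName = "site_II",
                     centroid = c(10.25, 2.11, -13.75),
                     innerBox = 10, outerBox = 30))
}

#' Load binding-site definitions from a key-value config
#'
#' The config is whitespace-delimited text, one line per field:
#' \preformatted{
#'   site_I  centroid   30.5 13.1 9.7
#'   site_I  inner_box  10
#'   site_II outer_box  30
#' }
#' Any field omitted for \code{site_I}/\code{site_II} falls back to the
#' defaults of \code{\link{defaultSitePockets}}; an empty config therefore
#' yields exactly the two default pockets. Additional pockets must be named
#' \code{extra_*} and must define their centroid. Lines starting with
#' \code{#} are ignored.
#'
#' @param path config file path, or \code{NULL} for pure defaults.
#' @return named list of \linkS4class{SitePocket}.
#' @export
loadSiteDefinitions <- function(path = NULL) {
  pockets <- defaultSitePockets()
  if (is.null(path)) return(pockets)
  if (!file.exists(path)) stop("site config not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  spec <- list()
  for (l in lines) {
    f <- strsplit(l, "[ \t]+")[[1]]
    if (length(f) < 3) stop("malformed site config line: ", l)
    site <- f[1]; key <- f[2]
    vals <- suppressWarnings(as.numeric(f[-(1:2)]))
    if (anyNA(vals)) stop("non-numeric coordinates in line: ", l)
    if (!grepl("^(site_I|site_II|extra)", site))
      stop("unknown site name: ", site)
    if (!key %in% c("centroid", "inner_box", "outer_box"))
      stop("unknown site field: ", key)
    spec[[site]][[key]] <- vals
  }
  for (site in names(spec)) {
    s <- spec[[site]]
    if (!is.null(s$centroid) && length(s$centroid) != 3)
      stop("centroid needs x y z: ", site)
    if (site %in% names(pockets)) {
      base <- pockets[[site]]
      cen <- if (is.null(s$centroid)) base@centroid else s$centroid
      ib <- if (is.null(s$inner_box)) base@innerBox else s$inner_box
      ob <- if (is.null(s$outer_box)) base@outerBox else s$outer_box
    } else {
      if (is.null(s$centroid))
        stop("extra pocket ", site, " must define its centroid")
      cen <- s$centroid
      ib <- if (is.null(s$inner_box)) 10 else s$inner_box
      ob <- if (is.null(s$outer_box)) 30 else s$outer_box
    }
    pockets[[site]] <- new("SitePocket", siteName = site, centroid = cen,
                           innerBox = ib, outerBox = ob)
  }
  if (isTRUE(all.equal(pockets$site_I@centroid, pockets$site_II@centroid)))
    stop("site_I and site_II centroids must be distinct")
  pockets
}

#' Serialize site definitions
#'
#' Writes the key-value format read by \code{\link{loadSiteDefinitions}};
#' the round trip is lossless.
#'
#' @param pockets named list of \linkS4class{SitePocket}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeSiteDefinitions <- function(pockets, path) {
  lines <- unlist(lapply(pockets, function(p) c(
    sprintf("%s centroid %.10g %.10g %.10g", p@siteName,
            p@centroid[1], p@centroid[2], p@centroid[3]),
    sprintf("%s inner_box %.10g", p@siteName, p@innerBox),
    sprintf("%s outer_box %.10g", p@siteName, p@outerBox))))
  writeLines(lines, path)
  invisible(path)
}

#' Build the HSA receptor ensemble
#'
#' Assembles a \linkS4class{ReceptorEnsemble} sorted by resolution (best
#' first). With no arguments the default ten-structure manifest is used
#' (1N5U 1.90 A through 1HK4 2.40 A). \code{reduced = TRUE} selects the
#' two-structure model: 2BXP for site I and 1N5U for site II, with the
#' myristic acid retained in site II of 1N5U (fatty-acid flag set) — the
#' configuration behind the best-performing combined model.
#'
#' @param entries optional data.frame with columns \code{pdb_id},
#'   \code{resolution}, and optionally \code{file},
#'   \code{fatty_acid_retained}; or a path to a delimited manifest with
#'   those columns.
#' @param reduced use the two-structure (2BXP site I / 1N5U site II + FA)
#'   model.
#' @param checkFiles verify that any non-NA receptor files exist.
#' @return a \linkS4class{ReceptorEnsemble}.
#' @examples
#' buildEnsemble()               # ten structures, 1N5U first
#' buildEnsemble(reduced = TRUE) # 2BXP + 1N5U with fatty acid
#' @export
buildEnsemble <- function(entries = NULL, reduced = FALSE,
                          checkFiles = FALSE) {
  if (is.character(entries) && length(entries) == 1) {
    first <- readLines(entries, n = 1)
    sep <- if (grepl("\t", first)) "\t" else ","
    entries <- utils::read.table(entries, header = TRUE, sep = sep,
                                 stringsAsFactors = FALSE)
  }
  if (is.null(entries)) {
    entries <- .HSA_MANIFEST
    entries$fatty_acid_retained <- FALSE
    if (reduced) {
      entries <- entries[entries$pdb_id %in% c("2BXP", "1N5U"), ]
      ## myristic acid retained in site II of 1N5U
      entries$fatty_acid_retained[entries$pdb_id == "1N5U"] <- TRUE
    }
  } else if (reduced) {
    entries <- entries[entries$pdb_id %in% c("2BXP", "1N5U"), ]
  }
  if (!is.data.frame(entries) || nrow(entries) == 0)
    stop("empty ensemble entry list")
  if (!all(c("pdb_id", "resolution") %in% colnames(entries)))
    stop("entries need pdb_id and resolution columns")
  if (!"file" %in% colnames(entries)) entries$file <- NA_character_
  entries$file <- as.character(entries$file)
  if (!"fatty_acid_retained" %in% colnames(entries))
    entries$fatty_acid_retained <- FALSE
  if (checkFiles) {
    bad <- !is.na(entries$file) & !file.exists(entries$file)
    if (any(bad))
      stop("unreadable receptor file(s): ",
           paste(entries$file[bad], collapse = ", "))
  }
  entries <- entries[order(entries$resolution, entries$pdb_id), ]
  obj <- new("ReceptorEnsemble", entries = DataFrame(
    pdb_id = entries$pdb_id,
    file = entries$file,
    resolution = entries$resolution,
    fatty_acid_retained = as.logical(entries$fatty_acid_retained),
    alignment_reference = .ALIGN_REF))
  validObject(obj)
  obj
}

#' Ensemble manifest accessor
#' @param x a \linkS4class{ReceptorEnsemble}.
#' @return the entry \code{DataFrame}.
#' @export
ensembleEntries <- function(x) {
  stopifnot(is(x, "ReceptorEnsemble"))
  x@entries
}

#' Write an ensemble manifest
#' @param x a \linkS4class{ReceptorEnsemble}.
#' @param path output path (tab-delimited).
#' @return \code{path}, invisibly.
#' @export
writeEnsembleManifest <- function(x, path) {
  utils::write.table(as.data.frame(x@entries), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
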