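# GC-map I/O, edge reversal, transition normalization and aggregation.
#
# File dialect: a dense numeric CSV/TSV matrix, optionally preceded by a
# header row of node labels.  Orientation: rows are source nodes, columns
# are target nodes (weights[i, j] = influence of i on j); use
# reverseEdges() after loading if a file was written the other way around.

#' Read a GC map from a dense CSV/TSV matrix file
#'
#' Reads an N x N nonnegative weight matrix.  Labels are taken from (in
#' order of precedence) `labelsPath` (a JSON array or newline-delimited
#' text file), a non-numeric header row detected in the matrix file, or the
#' defaults `"n0" ... "n{N-1}"`.
#'
#' @param path path to the matrix file.
#' @param labelsPath optional path to a label file (JSON list of strings or
#'   one label per line).
#' @param sep field separator; `","` (default) or `"\t"`.
#' @return a [GCMap-class]; rows of the file are source nodes.
#' @seealso [writeGCMap()], [reverseEdges()]
#' @export
readGCMap <- function(path, labelsPath = NULL, sep = ",") {
  if (!file.exists(path)) stopConfig("matrix file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stopData("empty matrix file: ", path)
  first <- strsplit(lines[[1L]], sep, fixed = TRUE)[[1L]]
  headerLabels <- NULL
  if (anyNA(suppressWarnings(as.numeric(first)))) {
    headerLabels <- trimws(first)
    lines <- lines[-1L]
  }
  rows <- lapply(strsplit(lines, sep, fixed = TRUE), function(x) {
    suppressWarnings(as.numeric(trimws(x)))
  })
  ncols <- lengths(rows)
  if (length(unique(ncols)) != 1L)
    stopData("ragged rows in matrix file: ", path)
  w <- do.call(rbind, rows)
  if (nrow(w) != ncol(w))
    stopData("matrix is not square (", nrow(w), " x ", ncol(w), "): ", path)
  if (anyNA(w)) stopData("non-numeric or NaN entries in matrix file: ", path)
  labels <- headerLabels
  if (!is.null(labelsPath)) labels <- readLabelSet(labelsPath)
  if (!is.null(labels) && length(labels) != nrow(w))
    stopData("label count (", length(labels),
             ") does not match matrix dimension (", nrow(w), ")")
  if (any(w < 0)) stopData("negative weights in matrix file: ", path)
  if (nrow(w) > 0 && any(diag(w) != 0))
    stopData("nonzero diagonal entries (self-edges) in matrix file: ", path)
  GCMap(w, labels = labels)
}

#' Write a GC map to a dense CSV/TSV matrix file
#'
#' Values are written with 17 significant digits so that a
#' read-write-read round trip reproduces the weights bit-exactly.  The
#' first row is a header of node labels.
#'
#' @param g a [GCMap-class].
#' @param path output path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
writeGCMap <- function(g, path, sep = ",") {
  stopifnot(is(g, "GCMap"))
  w <- gcWeights(g)
  body <- apply(w, 1L, function(r) {
    paste(formatC(r, format = "g", digits = 17), collapse = sep)
  })
  writeLines(c(paste(nodeLabels(g), collapse = sep), body), path)
  invisible(path)
}

#' Read a node label set (SOZ/RZ or node labels)
#'
#' Accepts either a JSON array of strings or a newline-delimited plain-text
#' file.
#'
#' @param path path to the label file.
#' @return character vector of labels.
#' @export
readLabelSet <- function(path) {
  if (!file.exists(path)) stopConfig("label file not found: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  if (grepl("^\\s*\\[", txt)) {
    as.character(jsonlite::fromJSON(txt))
  } else {
    labs <- trimws(strsplit(txt, "\n", fixed = TRUE)[[1L]])
    labs[nzchar(labs)]
  }
}

#' Reverse the edges of a GC map
#'
#' Transposes the weight matrix, so an edge describing how much activity at
#' node i causes activity at node j becomes an edge from j to i.  Rankings
#' on the reversed map send random walkers and centrality mass "uphill"
#' toward the generators of activity instead of its receivers.
#'
#' @param g a [GCMap-class].
#' @return the reversed [GCMap-class]; labels unchanged.
#' @export
#' @examples
#' g <- GCMap(rbind(c(0, 0.5), c(0.2, 0)))
#' gcWeights(reverseEdges(g))
reverseEdges <- function(g) {
  stopifnot(is(g, "GCMap"))
  GCMap(t(gcWeights(g)), labels = nodeLabels(g))
}

#' Row-normalize a GC map into walk transition probabilities
#'
#' Each row with positive total weight is divided by its sum so the outgoing
#' probabilities of every node add to one.  All-zero rows are left as zeros
#' and their indices recorded as dangling nodes; walks terminate there
#' (dangling rows are deliberately not patched with uniform probabilities).
#'
#' @param g a [GCMap-class].
#' @return a [TransitionModel-class].
#' @export
toTransition <- function(g) {
  stopifnot(is(g, "GCMap"))
  w <- gcWeights(g)
  rs <- rowSums(w)
  dangling <- which(rs == 0)
  p <- w
  pos <- rs > 0
  p[pos, ] <- w[pos, , drop = FALSE] / rs[pos]
  new("TransitionModel", probs = p, dangling = as.integer(dangling))
}

#' Aggregate several GC maps elementwise
#'
#' Combines per-segment maps of one patient into a single map by the
#' elementwise mean (default) or sum.  Note the alternative (often
#' preferable) policy of running a ranking algorithm on every segment and
#' averaging the per-node metrics is available through
#' [evaluatePatient()]'s `aggregate = "metrics"`.
#'
#' @param maps nonempty list of [GCMap-class] with identical labels.
#' @param method `"mean"` or `"sum"`.
#' @return the aggregated [GCMap-class].
#' @export
aggregateMaps <- function(maps, method = c("mean", "sum")) {
  method <- match.arg(method)
  if (length(maps) < 1L) stopConfig("'maps' must contain at least one GCMap")
  labs <- nodeLabels(maps[[1L]])
  for (m in maps) {
    if (!identical(nodeLabels(m), labs))
      stopData("cannot aggregate GCMaps with mismatching labels")
  }
  acc <- Reduce(`+`, lapply(maps, gcWeights))
  if (method == "mean") acc <- acc / length(maps)
  GCMap(acc, labels = labs)
}

#' Read a patient manifest into a PatientRecord
#'
#' The manifest is a JSON or YAML file with fields:
#' \describe{
#'   \item{segments}{list of paths to segment GC-matrix files (required).}
#'   \item{labels}{optional path to a node-label file applied to all
#'     segments.}
#'   \item{soz, rz}{label sets: either a path to a label file or an inline
#'     list of labels.  `rz` may be absent or empty.}
#' }
#' Relative paths are resolved against the manifest's directory.
#'
#' @param path path to the manifest file (`.json`, `.yaml` or `.yml`).
#' @return a [PatientRecord-class].
#' @export
readPatient <- function(path) {
  if (!file.exists(path)) stopConfig("manifest not found: ", path)
  man <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  if (is.null(man$segments) || !length(man$segments))
    stopConfig("manifest lists no segment files: ", path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  }
  labelsPath <- if (!is.null(man$labels)) resolve(man$labels) else NULL
  segs <- lapply(resolve(unlist(man$segments)), readGCMap,
                 labelsPath = labelsPath)
  readSet <- function(x) {
    if (is.null(x) || !length(x)) return(character())
    if (length(x) == 1L && file.exists(resolve(x))) return(readLabelSet(resolve(x)))
    as.character(x)
  }
  PatientRecord(segs, soz = readSet(man$soz), rz = readSet(man$rz))
}

#' Write a PatientRecord to a directory in the manifest dialect
#'
#' Writes one CSV per segment (`segment_001.csv`, ...), `soz.json`,
#' `rz.json` (if nonempty) and a `manifest.json` tying them together, so
#' the directory can be read back with [readPatient()].
#'
#' @param p a [PatientRecord-class].
#' @param dir output directory (created if missing).
#' @return the manifest path, invisibly.
#' @export
writePatient <- function(p, dir) {
  stopifnot(is(p, "PatientRecord"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  segs <- segments(p)
  segFiles <- sprintf("segment_%03d.csv", seq_along(segs))
  for (i in seq_along(segs)) writeGCMap(segs[[i]], file.path(dir, segFiles[i]))
  man <- list(segments = segFiles, soz = sozLabels(p))
  jsonlite::write_json(sozLabels(p), file.path(dir, "soz.json"))
  man$soz <- "soz.json"
  if (length(rzLabels(p))) {
    jsonlite::write_json(rzLabels(p), file.path(dir, "rz.json"))
    man$rz <- "rz.json"
  }
  manPath <- file.path(dir, "manifest.json")
  jsonlite::write_json(man, manPath, auto_unbox = TRUE)
  invisible(manPath)
}
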