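# Readers and writers for the plain-text formats the pipeline exchanges.
# Delimiters are sniffed between tab and comma, so .tsv/.csv content is
# interchangeable.

.sniffDelim <- function(path) {
  l1 <- readLines(path, n = 1)
  if (!length(l1)) stop("empty file: ", path)
  nt <- lengths(regmatches(l1, gregexpr("\t", l1)))
  nc <- lengths(regmatches(l1, gregexpr(",", l1)))
  if (nt >= nc) "\t" else ","
}

.readDelim <- function(path, rowIds = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- read.table(path, sep = .sniffDelim(path), header = TRUE,
                  check.names = FALSE, stringsAsFactors = FALSE,
                  comment.char = "", quote = "\"")
  if (rowIds) {
    ids <- trimws(as.character(d[[1]]))
    dup <- unique(ids[duplicated(ids)])
    if (length(dup))
      stop("duplicate id(s) in ", path, ": ", paste(dup, collapse = ", "))
    rownames(d) <- ids
    d <- d[, -1, drop = FALSE]
  }
  d
}

.numericMatrix <- function(d, path) {
  m <- as.matrix(d)
  if (!is.numeric(m)) {
    bad <- which(!vapply(d, is.numeric, logical(1)))
    stop("non-numeric column(s) in ", path, ": ",
         paste(names(d)[bad], collapse = ", "))
  }
  m
}

#' Read a component x sample peak-response table
#'
#' First column: component id; remaining columns: samples. Duplicate ids or
#' non-numeric cells are errors.
#'
#' @param path CSV or TSV file.
#' @return numeric matrix, components in rows.
#' @export
readPeakTable <- function(path) .numericMatrix(.readDelim(path), path)

#' Read a sample x indicator pharmacodynamic table
#'
#' First column: sample id; remaining columns: indicators.
#'
#' @param path CSV or TSV file.
#' @return numeric matrix, samples in rows.
#' @export
readEffectTable <- function(path) .numericMatrix(.readDelim(path), path)

#' Read a metabolite feature table with its sample-group map
#'
#' The feature table holds feature ids in the first column, optional
#' \code{mz}/\code{rt} columns, and sample intensity columns. The group map
#' is a two-column table (sample, group).
#'
#' @param path feature table CSV/TSV.
#' @param groupsPath sample-to-group map CSV/TSV.
#' @return a \linkS4class{MetabFeatureSet}.
#' @export
readFeatureTable <- function(path, groupsPath) {
  d <- .readDelim(path)
  mz <- if ("mz" %in% names(d)) as.numeric(d$mz) else NULL
  rt <- if ("rt" %in% names(d)) as.numeric(d$rt) else NULL
  d <- d[, setdiff(names(d), c("mz", "rt")), drop = FALSE]
  x <- .numericMatrix(d, path)
  g <- .readDelim(groupsPath, rowIds = FALSE)
  if (ncol(g) < 2) stop("group map needs columns sample, group")
  grp <- setNames(trimws(as.character(g[[2]])), trimws(as.character(g[[1]])))
  missing <- setdiff(colnames(x), names(grp))
  if (length(missing))
    stop("samples without group label: ", paste(missing, collapse = ", "))
  MetabFeatureSet(x, grp[colnames(x)], mz = mz, rt = rt)
}

#' Read a compound-target edge list
#'
#' Two id columns (from, to), optionally followed by kind columns; extra
#' columns are ignored.
#'
#' @param path TSV/CSV with a header row.
#' @return data.frame(from, to).
#' @export
readEdgeList <- function(path) {
  d <- .readDelim(path, rowIds = FALSE)
  if (ncol(d) < 2) stop("edge list needs two id columns")
  data.frame(from = trimws(as.character(d[[1]])),
             to = trimws(as.character(d[[2]])), stringsAsFactors = FALSE)
}

#' Read a one-id-per-line gene list
#'
#' @param path text file, one id per line; blank lines ignored.
#' @return character vector.
#' @export
readGeneList <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- trimws(readLines(path))
  x[nzchar(x)]
}

#' Read GMT-style pathway membership sets
#'
#' Tab-separated: name, description, member ids.
#'
#' @param path GMT file.
#' @return named list of member-id character vectors.
#' @export
readGmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("GMT line needs name, description, members: ", l)
    trimws(f[-(1:2)])
  })
  names(out) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  dup <- unique(names(out)[duplicated(names(out))])
  if (length(dup)) stop("duplicate pathway name(s): ", paste(dup, collapse = ", "))
  out
}

#' Read a glucose-tolerance subject panel
#'
#' @param subjectsPath CSV/TSV with columns subject, group, fbg, insulin.
#' @param curvesPath long-format CSV/TSV with columns subject, kind, time,
#'   glucose (optional; omit for a curve-free panel).
#' @return a \linkS4class{SubjectPanel}.
#' @export
readGlucosePanel <- function(subjectsPath, curvesPath = NULL) {
  s <- .readDelim(subjectsPath, rowIds = FALSE)
  need <- c("subject", "group", "fbg", "insulin")
  miss <- setdiff(need, names(s))
  if (length(miss)) stop("subjects table missing: ", paste(miss, collapse = ", "))
  dup <- unique(s$subject[duplicated(s$subject)])
  if (length(dup)) stop("duplicate subject id(s): ", paste(dup, collapse = ", "))
  cv <- if (is.null(curvesPath)) {
    data.frame(subject = character(), kind = character(), time = numeric(),
               glucose = numeric(), stringsAsFactors = FALSE)
  } else {
    d <- .readDelim(curvesPath, rowIds = FALSE)
    needc <- c("subject", "kind", "time", "glucose")
    missc <- setdiff(needc, names(d))
    if (length(missc)) stop("curves table missing: ", paste(missc, collapse = ", "))
    d[needc]
  }
  new("SubjectPanel", subjects = s[need], curves = cv)
}

#' Read an annotation candidate list
#'
#' @param path CSV/TSV with columns id, formula, adduct.
#' @return data.frame.
#' @export
readCandidates <- function(path) {
  d <- .readDelim(path, rowIds = FALSE)
  miss <- setdiff(c("id", "formula", "adduct"), names(d))
  if (length(miss)) stop("candidate list missing: ", paste(miss, collapse = ", "))
  d
}

#' Write a matrix or data.frame as TSV
#'
#' Matrices are written with their row ids in a leading column named
#' \code{id}, which is the layout the corresponding readers expect, so
#' every output round-trips.
#'
#' @param x matrix or data.frame.
#' @param path output file.
#' @param idColumn name of the leading id column for matrices.
#' @return \code{path}, invisibly.
#' @export
writeTsv <- function(x, path, idColumn = "id") {
  if (is.matrix(x)) {
    d <- data.frame(rownames(x), x, check.names = FALSE,
                    stringsAsFactors = FALSE)
    names(d)[1] <- idColumn
  } else d <- x
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
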