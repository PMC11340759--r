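# Readers/writers.  All tables are TSV with a header row, UTF-8, "." decimal;
# missing value token is "" or "NA".  Numbers are written at 12 significant
# digits so round-trips are lossless at that precision.

.num_fmt <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, format = "g", digits = 12))
}

.write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  for (cn in names(df)[num]) df[[cn]] <- .num_fmt(df[[cn]])
  con <- file(path, open = "wb")  # binary: byte-identical across platforms
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df))
    writeLines(do.call(paste, c(unname(as.list(df)), sep = "\t")), con)
  invisible(path)
}

.read_tsv <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             na.strings = c("NA", ""), check.names = FALSE,
             colClasses = NA, fileEncoding = "UTF-8")
}

#' Read a triad table from TSV
#'
#' Expects a header `sample_id  subject_id  role  substudy  donor_id`; roles
#' are taken from the file, never inferred from sample naming.
#'
#' @param path path to the TSV file.
#' @return a validated [triad_table()].
#' @export
read_triad_table <- function(path) {
  df <- .read_tsv(path)
  if (!is.null(df$donor_id)) df$donor_id[is.na(df$donor_id)] <- ""
  triad_table(df)
}

#' Write a triad table to TSV
#' @param tt a [triad_table()].
#' @param path output path.
#' @export
write_triad_table <- function(tt, path) {
  .write_tsv(as.data.frame(tt), path)
}

#' Read a per-SGB distance set
#'
#' In `matrix` mode the file is a square TSV of already-normalized pairwise
#' distances whose first column holds the row sample ids and whose header
#' holds the column ids.  In `newick` mode the file is a single tree whose
#' leaf names are sample ids; patristic distances (sums of branch lengths
#' along the connecting path) are computed for every leaf pair and divided by
#' the tree's total branch length, which is recorded as the normalizer.
#'
#' @param path file path.
#' @param mode `"matrix"` or `"newick"`.
#' @param sgb_id SGB identifier; defaults to the file name without extension.
#' @param marker_counts optional named per-sample marker counts.
#' @param tol symmetry tolerance for matrix mode.
#' @return a [distance_set()].
#' @export
read_distances <- function(path, mode = c("matrix", "newick"),
                           sgb_id = sub("\\.[^.]*$", "", basename(path)),
                           marker_counts = NULL, tol = 1e-9) {
  mode <- match.arg(mode)
  if (mode == "matrix") {
    df <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                     stringsAsFactors = FALSE)
    ids <- as.character(df[[1]])
    D <- as.matrix(df[, -1, drop = FALSE])
    rownames(D) <- ids
    if (!identical(ids, colnames(D)))
      stop("row and column sample ids disagree in ", path)
    distance_set(sgb_id, D, marker_counts = marker_counts,
                 normalizer = NA_real_, tol = tol)
  } else {
    tree <- ape::read.tree(path)
    if (is.null(tree)) stop("could not parse newick tree in ", path)
    if (anyDuplicated(tree$tip.label))
      stop("duplicate leaf names in tree ", path)
    total <- sum(tree$edge.length)
    if (!isTRUE(total > 0)) stop("tree has no positive branch length: ", path)
    D <- ape::cophenetic.phylo(tree) / total
    D <- D[tree$tip.label, tree$tip.label, drop = FALSE]
    distance_set(sgb_id, D, marker_counts = marker_counts, normalizer = total)
  }
}

#' Write a distance set as a square TSV matrix
#' @param ds a [distance_set()].
#' @param path output path.
#' @export
write_distances <- function(ds, path) {
  df <- data.frame(sample_id = ds$sample_ids, stringsAsFactors = FALSE,
                   check.names = FALSE)
  M <- ds$D
  for (j in seq_along(ds$sample_ids)) df[[ds$sample_ids[j]]] <- M[, j]
  .write_tsv(df, path)
}

#' Read an abundance table (samples x SGBs) from TSV
#' @param path file path; first column `sample_id`, remaining columns SGBs.
#' @return validated abundance matrix.
#' @export
read_abundance <- function(path) {
  df <- .read_tsv(path)
  A <- as.matrix(df[, -1, drop = FALSE])
  rownames(A) <- as.character(df[[1]])
  storage.mode(A) <- "double"
  abundance_table(A)
}

#' Write an abundance table to TSV
#' @param A abundance matrix (samples x SGBs).
#' @param path output path.
#' @export
write_abundance <- function(A, path) {
  df <- data.frame(sample_id = rownames(A), stringsAsFactors = FALSE,
                   check.names = FALSE)
  for (j in seq_len(ncol(A))) df[[colnames(A)[j]]] <- A[, j]
  .write_tsv(df, path)
}

#' Read a long clinical table from TSV
#' @param path file path.
#' @return validated clinical data.frame.
#' @export
read_clinical <- function(path) clinical_table(.read_tsv(path))

#' Write a clinical table to TSV
#' @param cl clinical data.frame.
#' @param path output path.
#' @export
write_clinical <- function(cl, path) .write_tsv(cl, path)

#' Read a metabolite table from TSV
#' @param path file path.
#' @return validated metabolite data.frame.
#' @export
read_metabolites <- function(path) metabolite_table(.read_tsv(path))

#' Write a metabolite table to TSV
#' @param mt metabolite data.frame.
#' @param path output path.
#' @export
write_metabolites <- function(mt, path) .write_tsv(mt, path)

#' Read a key=value configuration file
#'
#' One `key = value` pair per line; `#` starts a comment.  Values are parsed
#' as numbers when possible, as logicals for `true`/`false`, and
#' comma-separated values become vectors.
#'
#' @param path file path.
#' @return named list of settings.
#' @export
read_config <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq < 0) stop("malformed config line (no '='): ", ln)
    key <- trimws(substr(ln, 1, eq - 1))
    val <- trimws(substr(ln, eq + 1, nchar(ln)))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    parsed <- suppressWarnings(as.numeric(parts))
    if (!anyNA(parsed)) {
      out[[key]] <- parsed
    } else if (all(tolower(parts) %in% c("true", "false"))) {
      out[[key]] <- tolower(parts) == "true"
    } else {
      out[[key]] <- parts
    }
  }
  out
}
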