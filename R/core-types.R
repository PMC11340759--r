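#' Sample roles recognized in an FMT triad table
#' @keywords internal
.roles <- c("donor", "pre", "post")

#' Construct and validate a triad table
#'
#' A triad table maps every sample to a subject, a role within an FMT triad
#' (`donor`, `pre`, or `post`), a sub-study, and -- for recipient samples --
#' the sample id of the donor whose feces were infused.  One FMT triad is the
#' trio (donor sample, recipient pre-FMT sample, recipient post-FMT sample);
#' a donor may serve several recipients and therefore appear in several
#' triads.  Donor samples that no recipient references are allowed and act as
#' additional unrelated-only samples (e.g. baseline samples of an external
#' cohort used to enlarge the unrelated pair pool).
#'
#' @param records data.frame with columns `sample_id`, `subject_id`, `role`,
#'   `substudy`, `donor_id` (empty string for donor rows).
#' @return the validated data.frame with class `triad_table`.
#' @export
triad_table <- function(records) {
  needed <- c("sample_id", "subject_id", "role", "substudy", "donor_id")
  miss <- setdiff(needed, names(records))
  if (length(miss))
    stop("triad table is missing column(s): ", paste(miss, collapse = ", "))
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  for (cn in needed) records[[cn]] <- as.character(records[[cn]])
  records$donor_id[is.na(records$donor_id)] <- ""
  if (anyDuplicated(records$sample_id))
    stop("duplicate sample_id in triad table: ",
         paste(unique(records$sample_id[duplicated(records$sample_id)]),
               collapse = ", "))
  bad <- !records$role %in% .roles
  if (any(bad))
    stop("unknown role(s): ", paste(unique(records$role[bad]), collapse = ", "))
  donors <- records$sample_id[records$role == "donor"]
  rec <- records[records$role %in% c("pre", "post"), , drop = FALSE]
  orphan <- setdiff(rec$donor_id[rec$donor_id != ""], donors)
  if (length(orphan))
    stop("recipient rows reference donor sample(s) absent from the table: ",
         paste(orphan, collapse = ", "))
  if (any(rec$donor_id == ""))
    stop("recipient (pre/post) rows must name a donor_id")
  class(records) <- c("triad_table", "data.frame")
  records
}

#' Enumerate complete FMT triads from a triad table
#'
#' @param tt a [triad_table()].
#' @return data.frame with one row per triad: `subject_id`, `substudy`,
#'   `donor_sample`, `pre_sample`, `post_sample`.
#' @export
triads <- function(tt) {
  pre <- tt[tt$role == "pre", , drop = FALSE]
  post <- tt[tt$role == "post", , drop = FALSE]
  subjects <- intersect(pre$subject_id, post$subject_id)
  out <- lapply(subjects, function(s) {
    p <- pre[pre$subject_id == s, , drop = FALSE]
    q <- post[post$subject_id == s, , drop = FALSE]
    data.frame(subject_id = s, substudy = q$substudy[1],
               donor_sample = q$donor_id[1], pre_sample = p$sample_id[1],
               post_sample = q$sample_id[1], stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' @export
print.triad_table <- function(x, ...) {
  tr <- triads(x)
  cat(sprintf("triad_table: %d samples, %d triads, %d sub-studies\n",
              nrow(x), if (is.null(tr)) 0L else nrow(tr),
              length(unique(x$substudy))))
  invisible(x)
}

#' Construct a per-SGB distance set
#'
#' Holds the symmetric matrix of normalized phylogenetic distances between
#' the samples in which one species-level genome bin (SGB) was
#' strain-profiled, together with the per-sample marker counts used by the
#' profile quality filter.
#'
#' @param sgb_id character scalar.
#' @param D square numeric matrix with identical row and column names (the
#'   sample ids), zero diagonal, symmetric, finite, non-negative.
#' @param marker_counts optional named integer vector of per-sample marker
#'   counts; names must cover the samples of `D`.
#' @param normalizer the branch-length total used to normalize patristic
#'   distances, or `NA` when the matrix was supplied already normalized.
#' @param tol symmetry tolerance.
#' @return object of class `distance_set`.
#' @export
distance_set <- function(sgb_id, D, marker_counts = NULL, normalizer = NA_real_,
                         tol = 1e-9) {
  D <- as.matrix(D)
  ids <- rownames(D)
  if (is.null(ids) || is.null(colnames(D)) || !identical(ids, colnames(D)))
    stop("distance matrix must carry identical row and column sample ids")
  if (anyDuplicated(ids))
    stop("duplicate sample ids in distance matrix")
  if (any(!is.finite(D)))
    stop("non-finite distances")
  if (any(D < 0))
    stop("negative distances")
  if (max(abs(D - t(D))) > tol)
    stop(sprintf("distance matrix for %s asymmetric beyond tolerance %g",
                 sgb_id, tol))
  D <- (D + t(D)) / 2
  diag(D) <- 0
  if (!is.null(marker_counts)) {
    miss <- setdiff(ids, names(marker_counts))
    if (length(miss))
      stop("marker_counts missing for sample(s): ", paste(miss, collapse = ", "))
    marker_counts <- marker_counts[ids]
  }
  structure(list(sgb_id = as.character(sgb_id), sample_ids = ids, D = D,
                 marker_counts = marker_counts, normalizer = normalizer),
            class = "distance_set")
}

#' @export
print.distance_set <- function(x, ...) {
  cat(sprintf("distance_set %s: %d samples%s\n", x$sgb_id,
              length(x$sample_ids),
              if (is.na(x$normalizer)) "" else
                sprintf(", normalizer %.6g", x$normalizer)))
  invisible(x)
}

#' Validate a relative-abundance table
#'
#' @param A numeric matrix, samples in rows (rownames = sample ids), SGBs in
#'   columns; entries are relative-abundance fractions in `[0, 1]`.
#' @param tol tolerance on the per-sample sum exceeding 1.
#' @return the matrix, invisibly validated.
#' @export
abundance_table <- function(A, tol = 1e-6) {
  A <- as.matrix(A)
  if (is.null(rownames(A)) || is.null(colnames(A)))
    stop("abundance table needs sample rownames and SGB colnames")
  if (any(!is.finite(A)) || any(A < 0) || any(A > 1))
    stop("abundances must be finite fractions in [0, 1]")
  if (any(rowSums(A) > 1 + tol))
    stop("per-sample abundance sums exceed 1")
  A
}

#' Validate a long clinical table
#'
#' @param cl data.frame with columns `subject_id`, `parameter`,
#'   `time` (`pre`/`post`), `value`, `units`; missing values allowed.
#' @return the validated data.frame.
#' @export
clinical_table <- function(cl) {
  needed <- c("subject_id", "parameter", "time", "value", "units")
  miss <- setdiff(needed, names(cl))
  if (length(miss))
    stop("clinical table is missing column(s): ", paste(miss, collapse = ", "))
  if (!all(cl$time %in% c("pre", "post")))
    stop("clinical time must be 'pre' or 'post'")
  key <- paste(cl$subject_id, cl$parameter, cl$time)
  if (anyDuplicated(key))
    stop("duplicate (subject, parameter, time) rows in clinical table")
  cl$value <- as.numeric(cl$value)
  cl
}

#' Validate a metabolite table
#'
#' Wide table of metabolite intensities with identifying columns
#' `subject_id` and `time` followed by one numeric column per metabolite.
#' Missing cells are allowed before [preprocess_metabolites()].
#'
#' @param mt data.frame.
#' @return the validated data.frame.
#' @export
metabolite_table <- function(mt) {
  if (!all(c("subject_id", "time") %in% names(mt)))
    stop("metabolite table needs subject_id and time columns")
  if (!all(mt$time %in% c("pre", "post")))
    stop("metabolite time must be 'pre' or 'post'")
  met <- setdiff(names(mt), c("subject_id", "time"))
  for (m in met) mt[[m]] <- as.numeric(mt[[m]])
  if (any(vapply(mt[met], function(v) any(v < 0, na.rm = TRUE), logical(1))))
    stop("metabolite intensities must be non-negative")
  mt
}
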