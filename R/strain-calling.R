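# Per-SGB strain-identity thresholds and post-FMT strain origin assignment.
#
# A "strain" is defined operationally, per SGB, by a cutoff on the
# normalized phylogenetic distance between two samples' dominant strain
# profiles: pairs at or below the cutoff carry the same strain.  The cutoff
# is estimated by contrasting the distance distribution of related pairs
# (same-subject pre/post, and donor/post within a triad) with that of
# unrelated pairs (cross-subject pairs with no triad relation).

#' Apply the profile quality filter to a distance set
#'
#' Samples with fewer than `min_markers` markers are dropped from the SGB's
#' distance set (boundary inclusive: exactly `min_markers` is kept).  The
#' SGB is flagged as not passing when fewer than two samples remain.
#'
#' @param ds a [distance_set()].
#' @param min_markers minimum marker count per sample (default 20).
#' @return the filtered `distance_set`, with attribute `passed` (logical).
#' @export
filter_profiles <- function(ds, min_markers = 20L) {
  keep <- ds$sample_ids
  if (!is.null(ds$marker_counts))
    keep <- keep[ds$marker_counts >= min_markers]
  out <- distance_set(ds$sgb_id, ds$D[keep, keep, drop = FALSE],
                      marker_counts = if (is.null(ds$marker_counts)) NULL
                                      else ds$marker_counts[keep],
                      normalizer = ds$normalizer)
  attr(out, "passed") <- length(keep) >= 2L
  out
}

#' Marker prevalence filter
#'
#' Keeps markers present in at least `min_prevalence` of the samples
#' (boundary inclusive).  Operates on a logical samples x markers presence
#' matrix; marker-level filtering is an upstream profiling step, supplied
#' here for callers who carry marker presence data.
#'
#' @param presence logical matrix, samples in rows, markers in columns.
#' @param min_prevalence minimum fraction of samples (default 0.5).
#' @return character vector of retained marker names.
#' @export
filter_markers <- function(presence, min_prevalence = 0.5) {
  colnames(presence)[colMeans(presence) >= min_prevalence]
}

#' Label sample pairs as related or unrelated for one SGB
#'
#' Related pairs are the same-subject (pre, post) pairs and the same-triad
#' (donor, post) pairs; unrelated pairs are all remaining cross-subject
#' pairs, excluding the within-triad (donor, pre) pairs, which precede any
#' transplantation link and belong to neither class.  Pairs involving a
#' sample not profiled for the SGB are omitted.
#'
#' @param tt a [triad_table()].
#' @param ds a (filtered) [distance_set()].
#' @return data.frame with columns `sample_a`, `sample_b`, `label`
#'   (`related`/`unrelated`), `distance`; class `pair_labeling`.
#' @export
label_pairs <- function(tt, ds) {
  ids <- ds$sample_ids
  tr <- triads(tt)
  subj <- setNames(tt$subject_id, tt$sample_id)
  rel <- matrix(character(0), 0, 2)
  excl <- matrix(character(0), 0, 2)
  if (!is.null(tr)) for (k in seq_len(nrow(tr))) {
    po <- tr$post_sample[k]; pr <- tr$pre_sample[k]; dn <- tr$donor_sample[k]
    if (po %in% ids && pr %in% ids) rel <- rbind(rel, c(pr, po))
    if (po %in% ids && dn %in% ids) rel <- rbind(rel, c(dn, po))
    if (pr %in% ids && dn %in% ids) excl <- rbind(excl, c(dn, pr))
  }
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  all_pairs <- if (length(ids) >= 2) t(utils::combn(ids, 2)) else
    matrix(character(0), 0, 2)
  k_all <- key(all_pairs[, 1], all_pairs[, 2])
  k_rel <- if (nrow(rel)) key(rel[, 1], rel[, 2]) else character(0)
  k_exc <- if (nrow(excl)) key(excl[, 1], excl[, 2]) else character(0)
  same_subj <- subj[all_pairs[, 1]] == subj[all_pairs[, 2]]
  lab <- ifelse(k_all %in% k_rel, "related",
                ifelse(k_all %in% k_exc | same_subj, NA, "unrelated"))
  out <- data.frame(sample_a = all_pairs[, 1], sample_b = all_pairs[, 2],
                    label = lab, stringsAsFactors = FALSE)
  out <- out[!is.na(out$label), , drop = FALSE]
  out$distance <- ds$D[cbind(out$sample_a, out$sample_b)]
  rownames(out) <- NULL
  class(out) <- c("pair_labeling", "data.frame")
  out
}

#' Youden-optimal threshold between two distance distributions
#'
#' Scans every achievable classification: candidates are the sorted unique
#' observed distances, since under the inclusive sharing rule (`d <= t`)
#' any threshold between consecutive observed values classifies identically
#' to its left endpoint.  Sensitivity is the fraction of related pairs at or
#' below `t`, specificity the fraction of unrelated pairs above `t`;
#' Youden's J = sensitivity + specificity - 1.  Ties in J break toward the
#' smallest threshold.
#'
#' @param related,unrelated numeric distance vectors.
#' @return list with `threshold` and `j`.
#' @export
youden_threshold <- function(related, unrelated) {
  stopifnot(length(related) > 0, length(unrelated) > 0)
  cand <- sort(unique(c(related, unrelated)))
  sens <- vapply(cand, function(t) mean(related <= t), numeric(1))
  spec <- vapply(cand, function(t) mean(unrelated > t), numeric(1))
  j <- sens + spec - 1
  i <- which.max(j)            # first maximum = smallest threshold
  list(threshold = cand[i], j = j[i])
}

#' Estimate the strain-identity threshold for one SGB
#'
#' With at least `min_related` related pairs, the threshold is the more
#' conservative (smaller) of the Youden-optimal cutoff and the 5th
#' percentile of the unrelated distances; with fewer related pairs it is
#' the 3rd percentile of the unrelated distances.  Percentiles use linear
#' interpolation between order statistics (type 7).
#'
#' @param labeling a [label_pairs()] result, or a list with numeric elements
#'   `related` and `unrelated`.
#' @param min_related related-pair count at which the Youden/pct5 rule
#'   replaces the pct3 rule (default 50).
#' @return one-row data.frame: `threshold`, `rule` (`youden`/`pct5`/`pct3`),
#'   `n_related`, `n_unrelated`, `youden_j`, `estimable`.
#' @export
estimate_threshold <- function(labeling, min_related = 50L) {
  if (is.data.frame(labeling)) {
    related <- labeling$distance[labeling$label == "related"]
    unrelated <- labeling$distance[labeling$label == "unrelated"]
  } else {
    related <- labeling$related
    unrelated <- labeling$unrelated
  }
  n_rel <- length(related); n_unrel <- length(unrelated)
  if (n_unrel == 0)
    return(data.frame(threshold = NA_real_, rule = NA_character_,
                      n_related = n_rel, n_unrelated = 0L,
                      youden_j = NA_real_, estimable = FALSE,
                      stringsAsFactors = FALSE))
  if (n_rel >= min_related) {
    yd <- youden_threshold(related, unrelated)
    pct5 <- unname(quantile(unrelated, 0.05, type = 7))
    t <- min(yd$threshold, pct5)
    rule <- if (yd$threshold <= pct5) "youden" else "pct5"
    data.frame(threshold = t, rule = rule, n_related = n_rel,
               n_unrelated = n_unrel, youden_j = yd$j, estimable = TRUE,
               stringsAsFactors = FALSE)
  } else {
    data.frame(threshold = unname(quantile(unrelated, 0.03, type = 7)),
               rule = "pct3", n_related = n_rel, n_unrelated = n_unrel,
               youden_j = NA_real_, estimable = TRUE,
               stringsAsFactors = FALSE)
  }
}

#' Estimate strain-identity thresholds for every SGB of a cohort
#'
#' Applies the marker filter, labels pairs and estimates the per-SGB
#' threshold.
#'
#' @param tt a [triad_table()].
#' @param ds_list list of [distance_set()] objects.
#' @param min_markers per-sample marker minimum passed to
#'   [filter_profiles()].
#' @param min_related see [estimate_threshold()].
#' @return data.frame (`threshold_table`) with one row per SGB, adding
#'   `sgb_id` and `passed_filters` to the [estimate_threshold()] columns.
#' @export
estimate_thresholds <- function(tt, ds_list, min_markers = 20L,
                                min_related = 50L) {
  rows <- lapply(ds_list, function(ds) {
    f <- filter_profiles(ds, min_markers)
    if (!attr(f, "passed"))
      return(data.frame(sgb_id = ds$sgb_id, threshold = NA_real_,
                        rule = NA_character_, n_related = 0L,
                        n_unrelated = 0L, youden_j = NA_real_,
                        estimable = FALSE, passed_filters = FALSE,
                        stringsAsFactors = FALSE))
    est <- estimate_threshold(label_pairs(tt, f), min_related)
    cbind(data.frame(sgb_id = ds$sgb_id, stringsAsFactors = FALSE),
          est, passed_filters = TRUE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  class(out) <- c("threshold_table", "data.frame")
  out
}

#' Call strain sharing from a distance and a threshold
#'
#' Shared if and only if `d <= t` (inclusive boundary: ties at the threshold
#' count as shared).
#'
#' @param d numeric distance(s).
#' @param t threshold.
#' @return logical vector.
#' @export
call_sharing <- function(d, t) {
  if (is.na(t)) return(rep(NA, length(d)))
  d <= t
}

#' Assign the origin of a post-FMT strain within one triad
#'
#' A post-FMT strain shared only with the donor originates from the donor;
#' shared only with the recipient's pre-FMT sample, from the recipient;
#' shared with both, from the side with the lowest normalized distance.
#' When the SGB is absent pre-FMT but the post strain is shared with the
#' donor, the origin is `novel_donor` (engraftment into an empty niche).
#' Unshared strains are `retained_unshared`; when the SGB is present only
#' post-FMT the call is flagged `de_novo`.
#'
#' @param post_sample,pre_sample,donor_sample sample ids (pre/donor may be
#'   absent from the SGB's profile).
#' @param ds a filtered [distance_set()].
#' @param t strain-identity threshold for this SGB.
#' @return one-row data.frame: `post_sample`, `origin` in `{donor,
#'   recipient, novel_donor, retained_unshared, absent}`, `d_pre`, `d_donor`,
#'   `shared_with_donor`, `shared_with_pre`, `de_novo`.
#' @export
assign_origin <- function(post_sample, pre_sample, donor_sample, ds, t) {
  ids <- ds$sample_ids
  res <- function(origin, d_pre = NA_real_, d_donor = NA_real_,
                  sw_d = FALSE, sw_p = FALSE, de_novo = FALSE)
    data.frame(post_sample = post_sample, origin = origin, d_pre = d_pre,
               d_donor = d_donor, shared_with_donor = sw_d,
               shared_with_pre = sw_p, de_novo = de_novo,
               stringsAsFactors = FALSE)
  if (!post_sample %in% ids) return(res("absent"))
  has_pre <- pre_sample %in% ids
  has_don <- donor_sample %in% ids
  d_pre <- if (has_pre) ds$D[post_sample, pre_sample] else NA_real_
  d_don <- if (has_don) ds$D[post_sample, donor_sample] else NA_real_
  if (!has_pre && !has_don) return(res("retained_unshared", de_novo = TRUE))
  sw_p <- isTRUE(call_sharing(d_pre, t))
  sw_d <- isTRUE(call_sharing(d_don, t))
  origin <- if (sw_p && sw_d) {
    if (d_don < d_pre) "donor" else "recipient"   # lowest distance wins
  } else if (sw_d) {
    if (has_pre) "donor" else "novel_donor"
  } else if (sw_p) {
    "recipient"
  } else {
    "retained_unshared"
  }
  res(origin, d_pre, d_don, sw_d, sw_p)
}

#' Assign post-FMT strain origins for every SGB and triad
#'
#' @param tt a [triad_table()].
#' @param ds_list list of [distance_set()] objects (unfiltered; the marker
#'   filter is applied here).
#' @param thresholds a [estimate_thresholds()] table.
#' @param min_markers per-sample marker minimum.
#' @return data.frame of origin calls with `sgb_id`, `subject_id` plus the
#'   [assign_origin()] columns; class `origin_calls`.  Attribute `profiles`
#'   holds the filtered per-SGB sample lists used.
#' @export
call_origins <- function(tt, ds_list, thresholds, min_markers = 20L) {
  tr <- triads(tt)
  profiles <- list()
  rows <- lapply(ds_list, function(ds) {
    th <- thresholds[thresholds$sgb_id == ds$sgb_id, , drop = FALSE]
    if (nrow(th) != 1 || !isTRUE(th$estimable)) return(NULL)
    f <- filter_profiles(ds, min_markers)
    profiles[[ds$sgb_id]] <<- f$sample_ids
    out <- lapply(seq_len(nrow(tr)), function(k)
      assign_origin(tr$post_sample[k], tr$pre_sample[k], tr$donor_sample[k],
                    f, th$threshold))
    out <- do.call(rbind, out)
    cbind(data.frame(sgb_id = ds$sgb_id, subject_id = tr$subject_id,
                     stringsAsFactors = FALSE), out)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  class(out) <- c("origin_calls", "data.frame")
  attr(out, "profiles") <- profiles
  out
}

#' Build the binary engraftment matrix from origin calls
#'
#' Cell (SGB, recipient) is 1 when the post-FMT strain originates from the
#' donor (`donor` or `novel_donor`), 0 otherwise (including SGBs absent
#' post-FMT).
#'
#' @param origin_calls a [call_origins()] result.
#' @param sgb_ids,subjects optional row/column universes (default: those
#'   appearing in the calls).
#' @return integer matrix, SGBs x recipients.
#' @export
build_engraftment_matrix <- function(origin_calls,
                                     sgb_ids = unique(origin_calls$sgb_id),
                                     subjects = unique(origin_calls$subject_id)) {
  M <- matrix(0L, length(sgb_ids), length(subjects),
              dimnames = list(sgb_ids, subjects))
  hit <- origin_calls[origin_calls$origin %in% c("donor", "novel_donor"), ]
  if (nrow(hit)) M[cbind(hit$sgb_id, hit$subject_id)] <- 1L
  M
}
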