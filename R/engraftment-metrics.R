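# Cohort-level strain-sharing statistics, dissimilarity regression,
# engraftment-pattern classification and network export.

#' Bundle filtered distance sets with their thresholds
#'
#' Convenience container consumed by the sharing-rate, fraction and
#' dissimilarity functions: per estimable SGB it keeps the marker-filtered
#' distance matrix and the strain-identity threshold.
#'
#' @param tt a [triad_table()].
#' @param ds_list list of [distance_set()] objects.
#' @param thresholds an [estimate_thresholds()] table.
#' @param min_markers per-sample marker minimum.
#' @return object of class `strain_calls`.
#' @export
strain_calls <- function(tt, ds_list, thresholds, min_markers = 20L) {
  keep <- list()
  for (ds in ds_list) {
    th <- thresholds[thresholds$sgb_id == ds$sgb_id, , drop = FALSE]
    if (nrow(th) != 1 || !isTRUE(th$estimable)) next
    f <- filter_profiles(ds, min_markers)
    if (!attr(f, "passed")) next
    keep[[ds$sgb_id]] <- list(ids = f$sample_ids, D = f$D,
                              threshold = th$threshold)
  }
  structure(list(tt = tt, sgbs = keep), class = "strain_calls")
}

#' @export
print.strain_calls <- function(x, ...) {
  cat(sprintf("strain_calls: %d SGBs with thresholds, %d samples\n",
              length(x$sgbs), nrow(x$tt)))
  invisible(x)
}

#' Strain-sharing rate between sample pairs
#'
#' The sharing rate of a pair is the number of shared strains divided by
#' the number of SGBs strain-profiled in both samples.  Pairs with no SGB
#' profiled in common get a missing rate.
#'
#' @param calls a [strain_calls()] object.
#' @param pairs data.frame with columns `sample_a`, `sample_b`.
#' @return `pairs` extended with `n_shared`, `n_common`, `rate`.
#' @export
sharing_rates <- function(calls, pairs) {
  n <- nrow(pairs)
  n_shared <- n_common <- integer(n)
  for (s in calls$sgbs) {
    in_a <- pairs$sample_a %in% s$ids
    in_b <- pairs$sample_b %in% s$ids
    both <- in_a & in_b
    if (!any(both)) next
    n_common[both] <- n_common[both] + 1L
    d <- s$D[cbind(pairs$sample_a[both], pairs$sample_b[both])]
    n_shared[both] <- n_shared[both] + as.integer(d <= s$threshold)
  }
  pairs$n_shared <- n_shared
  pairs$n_common <- n_common
  pairs$rate <- ifelse(n_common > 0, n_shared / n_common, NA_real_)
  pairs
}

#' Strain-sharing rate for one sample pair
#' @param calls a [strain_calls()] object.
#' @param sample_a,sample_b sample ids.
#' @return one-row data.frame from [sharing_rates()].
#' @export
sharing_rate <- function(calls, sample_a, sample_b) {
  sharing_rates(calls, data.frame(sample_a = sample_a, sample_b = sample_b,
                                  stringsAsFactors = FALSE))
}

#' Post-FMT anchored sharing fractions per triad
#'
#' For every triad, the fraction of strains profiled in the post-FMT sample
#' that are shared with the donor (`f_donor`) and with the recipient's
#' pre-FMT sample (`f_pre`).  Both numerators divide by the count of SGBs
#' strain-profiled at post-FMT, so strains shared with both sides count in
#' each fraction and `f_donor + f_pre` may exceed 1.
#'
#' @param calls a [strain_calls()] object.
#' @return data.frame: `subject_id`, `substudy`, `n_post`, `f_donor`,
#'   `f_pre`.
#' @export
post_fractions <- function(calls) {
  tr <- triads(calls$tt)
  n_post <- sh_don <- sh_pre <- integer(nrow(tr))
  for (s in calls$sgbs) {
    po <- tr$post_sample %in% s$ids
    n_post[po] <- n_post[po] + 1L
    dn <- po & tr$donor_sample %in% s$ids
    if (any(dn)) {
      d <- s$D[cbind(tr$post_sample[dn], tr$donor_sample[dn])]
      sh_don[dn] <- sh_don[dn] + as.integer(d <= s$threshold)
    }
    pr <- po & tr$pre_sample %in% s$ids
    if (any(pr)) {
      d <- s$D[cbind(tr$post_sample[pr], tr$pre_sample[pr])]
      sh_pre[pr] <- sh_pre[pr] + as.integer(d <= s$threshold)
    }
  }
  data.frame(subject_id = tr$subject_id, substudy = tr$substudy,
             n_post = n_post,
             f_donor = ifelse(n_post > 0, sh_don / n_post, NA_real_),
             f_pre = ifelse(n_post > 0, sh_pre / n_post, NA_real_),
             stringsAsFactors = FALSE)
}

#' Dissimilarity regression of recipient samples on donors
#'
#' For every (recipient sample, donor sample) combination the dissimilarity
#' is `1 - n_shared / n_common`, where `n_common` (the maximum number of
#' shared strains) counts the SGBs strain-profiled in both samples.  An
#' ordinary least-squares model regresses the dissimilarity on the
#' recipient sample type (pre/post), whether the donor is the recipient's
#' true donor, and -- by default -- their interaction, whose coefficient
#' (`beta_donor_post`) measures the engraftment-attributable drop in
#' dissimilarity of post-FMT samples toward their own donor.
#'
#' @param calls a [strain_calls()] object.
#' @param scope `"substudy"` (donor combinations within the recipient's
#'   sub-study; the default) or `"all"`.
#' @param interaction include the donor x post interaction (default TRUE);
#'   `FALSE` fits main effects only.
#' @return list of class `dissimilarity_model`: `coefficients` data.frame
#'   (term, estimate, se, p), `beta_donor_post`, `fit` (the `lm`),
#'   `pairs` (the pair table used).
#' @export
fit_dissimilarity_model <- function(calls, scope = c("substudy", "all"),
                                    interaction = TRUE) {
  scope <- match.arg(scope)
  tt <- calls$tt
  tr <- triads(tt)
  don <- tt[tt$role == "donor", , drop = FALSE]
  rec <- rbind(
    data.frame(sample = tr$pre_sample, subject = tr$subject_id,
               substudy = tr$substudy, type = "pre",
               true_donor_sample = tr$donor_sample, stringsAsFactors = FALSE),
    data.frame(sample = tr$post_sample, subject = tr$subject_id,
               substudy = tr$substudy, type = "post",
               true_donor_sample = tr$donor_sample, stringsAsFactors = FALSE))
  don_df <- data.frame(donor_sample = don$sample_id,
                       donor_substudy = don$substudy, stringsAsFactors = FALSE)
  grid <- merge(rec, don_df, by = NULL)
  if (scope == "substudy")
    grid <- grid[grid$substudy == grid$donor_substudy, , drop = FALSE]
  sr <- sharing_rates(calls, data.frame(sample_a = grid$sample,
                                        sample_b = grid$donor_sample,
                                        stringsAsFactors = FALSE))
  grid$dissimilarity <- 1 - sr$rate
  grid$sample_type <- factor(grid$type, levels = c("pre", "post"))
  grid$true_donor <- grid$donor_sample == grid$true_donor_sample
  grid <- grid[!is.na(grid$dissimilarity), , drop = FALSE]
  form <- if (interaction) dissimilarity ~ sample_type * true_donor
          else dissimilarity ~ sample_type + true_donor
  X <- stats::model.matrix(form, grid)
  if (qr(X)$rank < ncol(X)) {
    ali <- colnames(X)[qr(X)$pivot[-seq_len(qr(X)$rank)]]
    stop("rank-deficient dissimilarity design; aliased column(s): ",
         paste(ali, collapse = ", "))
  }
  fit <- lm(form, data = grid)
  sm <- summary(fit)$coefficients
  co <- data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
                   p = sm[, 4], row.names = NULL, stringsAsFactors = FALSE)
  bdp <- if (interaction) co$estimate[co$term == "sample_typepost:true_donorTRUE"]
         else NA_real_
  structure(list(coefficients = co, beta_donor_post = bdp, fit = fit,
                 pairs = grid), class = "dissimilarity_model")
}

#' Paired pre/post abundance comparison for an engrafted SGB
#'
#' Two-sided paired Wilcoxon signed-rank test of post- versus pre-FMT
#' relative abundance among the subjects in which the SGB engrafted.  The
#' exact null distribution is used when there are no ties or zero
#' differences.
#'
#' @param pre,post paired abundance vectors.
#' @return list: `statistic`, `p.value`, `n` (complete pairs), `testable`.
#' @export
compare_abundance <- function(pre, post) {
  ok <- stats::complete.cases(pre, post)
  pre <- pre[ok]; post <- post[ok]
  n <- length(pre)
  if (n < 3)
    return(list(statistic = NA_real_, p.value = NA_real_, n = n,
                testable = FALSE))
  if (all(post == pre))          # no change anywhere: no evidence of a shift
    return(list(statistic = 0, p.value = 1, n = n, testable = TRUE))
  wt <- suppressWarnings(wilcox.test(post, pre, paired = TRUE,
                                     alternative = "two.sided"))
  list(statistic = unname(wt$statistic), p.value = wt$p.value, n = n,
       testable = TRUE)
}

#' Classify the engraftment pattern of each engrafted SGB
#'
#' Engraftment into a recipient lacking the SGB pre-FMT is `novel`; when
#' the SGB is present pre-FMT, engraftment with a significant paired
#' abundance increase across engrafted subjects is `expansion` (an enlarged
#' niche), otherwise `replacement` (strain turnover in a fixed niche).
#'
#' @param engraftment binary SGB x recipient matrix
#'   ([build_engraftment_matrix()]).
#' @param abundance abundance matrix (samples x SGBs).
#' @param tt a [triad_table()].
#' @param alpha significance level of the abundance-increase test.
#' @return data.frame: `sgb_id`, `subject_id`, `pattern`
#'   (`novel`/`replacement`/`expansion`/`missing`), `abundance_pre`,
#'   `abundance_post`, `p_increase`.
#' @export
classify_patterns <- function(engraftment, abundance, tt, alpha = 0.05) {
  tr <- triads(tt)
  rows <- list()
  for (sgb in rownames(engraftment)) {
    idx <- which(engraftment[sgb, ] == 1L)
    if (!length(idx)) next
    sub <- colnames(engraftment)[idx]
    k <- match(sub, tr$subject_id)
    a_pre <- if (sgb %in% colnames(abundance))
      abundance[tr$pre_sample[k], sgb] else rep(NA_real_, length(k))
    a_post <- if (sgb %in% colnames(abundance))
      abundance[tr$post_sample[k], sgb] else rep(NA_real_, length(k))
    present_pre <- !is.na(a_pre) & a_pre > 0
    cmp <- compare_abundance(a_pre[present_pre], a_post[present_pre])
    expanded <- isTRUE(cmp$testable) && !is.na(cmp$p.value) &&
      cmp$p.value < alpha &&
      median(a_post[present_pre] - a_pre[present_pre], na.rm = TRUE) > 0
    pattern <- ifelse(is.na(a_pre) | is.na(a_post), "missing",
                      ifelse(!present_pre, "novel",
                             if (expanded) "expansion" else "replacement"))
    rows[[sgb]] <- data.frame(sgb_id = sgb, subject_id = sub,
                              pattern = pattern, abundance_pre = a_pre,
                              abundance_post = a_post,
                              p_increase = cmp$p.value,
                              row.names = NULL, stringsAsFactors = FALSE)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Export a strain-sharing network with a reproducible layout
#'
#' Nodes are samples, edges connect pairs sharing at least one strain, edge
#' weights are the squared shared-strain counts, and coordinates come from
#' the Fruchterman-Reingold layout under a fixed seed.
#'
#' @param sharing a [sharing_rates()] table.
#' @param tt a [triad_table()] supplying node roles.
#' @param seed layout seed.
#' @return list: `nodes` (sample_id, role, x, y), `edges` (from, to,
#'   n_shared, weight).
#' @export
export_network <- function(sharing, tt, seed = 1L) {
  ed <- sharing[!is.na(sharing$n_shared) & sharing$n_shared > 0, , drop = FALSE]
  node_ids <- sort(unique(c(sharing$sample_a, sharing$sample_b)))
  if (!length(node_ids))
    return(list(nodes = data.frame(sample_id = character(0),
                                   role = character(0), x = numeric(0),
                                   y = numeric(0)),
                edges = data.frame(from = character(0), to = character(0),
                                   n_shared = integer(0),
                                   weight = numeric(0))))
  g <- igraph::graph_from_data_frame(
    data.frame(from = ed$sample_a, to = ed$sample_b,
               weight = as.numeric(ed$n_shared)^2, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = node_ids, stringsAsFactors = FALSE))
  set.seed(seed)
  xy <- igraph::layout_with_fr(g, weights = igraph::E(g)$weight)
  roles <- setNames(tt$role, tt$sample_id)
  list(nodes = data.frame(sample_id = node_ids,
                          role = unname(roles[node_ids]),
                          x = xy[, 1], y = xy[, 2], stringsAsFactors = FALSE),
       edges = data.frame(from = ed$sample_a, to = ed$sample_b,
                          n_shared = ed$n_shared,
                          weight = as.numeric(ed$n_shared)^2,
                          stringsAsFactors = FALSE))
}
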