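# Downstream statistics: metabolite preprocessing, mixed-effects engraftment
# tests with Satterthwaite degrees of freedom and FDR, Spearman links,
# Procrustes association, multilevel decomposition.

#' Preprocess a raw metabolite table
#'
#' Per metabolite: missing values are imputed with half the lowest observed
#' value (distinguishing below-detection-limit cells from the lowest
#' measurable intensity), then the column is divided by its median so the
#' per-metabolite median is exactly 1.  All-missing metabolites are dropped
#' with a warning.
#'
#' @param mt a [metabolite_table()] (or plain numeric matrix/data.frame of
#'   intensities; columns are metabolites).
#' @return the preprocessed table, same shape minus dropped columns.
#' @export
preprocess_metabolites <- function(mt) {
  id_cols <- intersect(c("subject_id", "time"), names(mt))
  met <- setdiff(names(as.data.frame(mt)), id_cols)
  mt <- as.data.frame(mt, stringsAsFactors = FALSE)
  drop <- character(0)
  for (m in met) {
    v <- as.numeric(mt[[m]])
    if (all(is.na(v))) { drop <- c(drop, m); next }
    v[is.na(v)] <- min(v, na.rm = TRUE) / 2
    med <- median(v)
    if (med == 0) { drop <- c(drop, m); next }
    mt[[m]] <- v / med
  }
  if (length(drop)) {
    warning("dropping metabolite(s) with no usable values: ",
            paste(drop, collapse = ", "))
    mt <- mt[, setdiff(names(mt), drop), drop = FALSE]
  }
  mt
}

#' Mixed-effects test of one engraftment/parameter combination
#'
#' Fits `value ~ engrafted * time + (1 | subject)` on the long pre/post
#' table: the engraftment indicator, time, and their interaction as fixed
#' effects and a per-subject random intercept.  The interaction coefficient
#' is the engraftment-attributable post-pre change, in the units of the
#' clinical parameter; its p-value uses Satterthwaite's degrees-of-freedom
#' approximation on the REML fit.
#'
#' @param data data.frame with columns `subject`, `time` (`pre`/`post`),
#'   `value`, `engrafted` (0/1); each engraftment group needs at least 2
#'   subjects.
#' @return one-row data.frame: `estimate` (interaction coefficient), `se`,
#'   `df` (Satterthwaite), `p`, `n_subjects`, `singular`.
#' @export
fit_engraftment_lmm <- function(data) {
  data <- data[!is.na(data$value), , drop = FALSE]
  data$time <- factor(data$time, levels = c("pre", "post"))
  grp <- tapply(data$subject, data$engrafted, function(s) length(unique(s)))
  if (length(grp) < 2 || any(grp < 2))
    stop("need at least 2 subjects per engraftment group")
  fit <- suppressMessages(suppressWarnings(
    lmerTest::lmer(value ~ engrafted * time + (1 | subject), data = data,
                   control = lme4::lmerControl(check.conv.singular = "ignore",
                                               check.conv.grad = "ignore",
                                               check.conv.hess = "ignore"))))
  sm <- suppressWarnings(summary(fit)$coefficients)
  row <- sm["engrafted:timepost", , drop = TRUE]
  data.frame(estimate = unname(row["Estimate"]),
             se = unname(row["Std. Error"]),
             df = unname(row["df"]), p = unname(row["Pr(>|t|)"]),
             n_subjects = length(unique(data$subject)),
             singular = lme4::isSingular(fit), stringsAsFactors = FALSE)
}

#' Mixed-effects tests across selected engraftment/outcome pairs
#'
#' Runs [fit_engraftment_lmm()] for each selected (SGB, parameter) pair and
#' adds Benjamini-Hochberg adjusted p-values across the tested set.
#'
#' @param pairs data.frame with columns `sgb_id` and `parameter`.
#' @param clinical a long [clinical_table()] (or any long table with
#'   `subject_id`, `parameter`, `time`, `value`).
#' @param engraftment binary SGB x subject matrix.
#' @return data.frame: `sgb_id`, `parameter`, `estimate`, `se`, `df`, `p`,
#'   `p_fdr`, `n_subjects`, `singular`.
#' @export
fit_engraftment_lmms <- function(pairs, clinical, engraftment) {
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    sgb <- pairs$sgb_id[i]; par <- pairs$parameter[i]
    cl <- clinical[clinical$parameter == par, , drop = FALSE]
    cl <- cl[cl$subject_id %in% colnames(engraftment), , drop = FALSE]
    d <- data.frame(subject = cl$subject_id, time = cl$time,
                    value = cl$value,
                    engrafted = engraftment[sgb, cl$subject_id],
                    stringsAsFactors = FALSE)
    res <- tryCatch(fit_engraftment_lmm(d), error = function(e)
      data.frame(estimate = NA_real_, se = NA_real_, df = NA_real_,
                 p = NA_real_, n_subjects = length(unique(d$subject)),
                 singular = NA, stringsAsFactors = FALSE))
    cbind(data.frame(sgb_id = sgb, parameter = par,
                     stringsAsFactors = FALSE), res)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out$p_fdr <- fdr_bh(out$p)
  out[, c("sgb_id", "parameter", "estimate", "se", "df", "p", "p_fdr",
          "n_subjects", "singular")]
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjustment; never smaller than the raw p-value and monotone in
#' the raw ranks.
#'
#' @param p numeric p-values in `[0, 1]` (`NA` allowed).
#' @return adjusted p-values.
#' @export
fdr_bh <- function(p) p.adjust(p, method = "BH")

#' Spearman correlation link between two paired variables
#'
#' Pairwise-complete Spearman correlation; p-values use the exact
#' permutation null for fewer than 10 pairs without ties and the
#' t-approximation otherwise.
#'
#' @param x,y numeric vectors.
#' @return data.frame: `rho`, `p`, `n`, `method`.
#' @export
spearman_link <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("need at least 4 paired observations")
  if (sd(x) == 0 || sd(y) == 0)
    return(data.frame(rho = NA_real_, p = NA_real_, n = n,
                      method = "undefined (constant input)",
                      stringsAsFactors = FALSE))
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  exact <- n < 10 && !ties
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = exact))
  data.frame(rho = unname(ct$estimate), p = ct$p.value, n = n,
             method = if (exact) "exact" else "t-approximation",
             stringsAsFactors = FALSE)
}

#' Procrustes permutation test between two subject configurations
#'
#' Each matrix is reduced to principal coordinates of its Euclidean
#' inter-subject distances, then the optimal translation/rotation/scaling
#' of `B` onto `A` is found and the concordance tested by random row
#' permutations of `B`.  `m2` is the symmetric normalized residual sum of
#' squares; the p-value is `(1 + #{permutations at least as concordant}) /
#' (1 + n_perm)`.
#'
#' @param A,B numeric matrices with matching subject rows (at least 4).
#' @param n_perm number of permutations (default 999).
#' @param seed optional seed for the permutations.
#' @param ndim number of principal coordinates kept (default 2).
#' @return list of class `procrustes_test`: `m2`, `p`, `correlation`
#'   (Procrustes correlation statistic), `n_perm`, `ndim`.
#' @export
procrustes_test <- function(A, B, n_perm = 999L, seed = NULL, ndim = 2L) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (nrow(A) != nrow(B)) stop("A and B must have matching subject rows")
  if (nrow(A) < 4) stop("need at least 4 subjects")
  reduce <- function(M, k) {
    k <- min(k, nrow(M) - 1, ncol(M))
    cmdscale(dist(M), k = k)
  }
  Ar <- reduce(A, ndim); Br <- reduce(B, ndim)
  if (!is.null(seed)) set.seed(seed)
  pt <- vegan::protest(Ar, Br, permutations = n_perm)
  structure(list(m2 = pt$ss, p = pt$signif, correlation = pt$t0,
                 n_perm = n_perm, ndim = ndim, protest = pt),
            class = "procrustes_test")
}

#' @export
print.procrustes_test <- function(x, ...) {
  cat(sprintf("Procrustes: m2 = %.4g, correlation = %.4g, p = %.4g (%d permutations)\n",
              x$m2, x$correlation, x$p, x$n_perm))
  invisible(x)
}

#' Split repeated measures into between- and within-subject parts
#'
#' The between-subject part replaces each observation by its subject's
#' mean; the within-subject part is the observation minus that mean, the
#' component carrying pre/post change.  The two parts reconstruct the
#' input exactly.  Subjects with a single observation get an all-zero
#' within row and are flagged.
#'
#' @param X numeric matrix, observations x features.
#' @param subject_ids subject of each row.
#' @return list: `between`, `within` (matrices shaped like `X`),
#'   `flagged` (subjects with a single observation).
#' @export
multilevel_split <- function(X, subject_ids) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(subject_ids))
  between <- apply(X, 2, function(v) ave(v, subject_ids, FUN = mean))
  within <- X - between
  counts <- table(subject_ids)
  list(between = between, within = within,
       flagged = names(counts)[counts == 1])
}

#' Post-pre delta matrix from a long clinical table
#'
#' @param clinical long [clinical_table()].
#' @param parameters optional parameter subset.
#' @return numeric matrix, subjects x parameters, of post minus pre values.
#' @export
clinical_deltas <- function(clinical, parameters = NULL) {
  if (is.null(parameters)) parameters <- unique(clinical$parameter)
  subjects <- unique(clinical$subject_id)
  M <- matrix(NA_real_, length(subjects), length(parameters),
              dimnames = list(subjects, parameters))
  for (p in parameters) {
    cl <- clinical[clinical$parameter == p, , drop = FALSE]
    pre <- setNames(cl$value[cl$time == "pre"], cl$subject_id[cl$time == "pre"])
    post <- setNames(cl$value[cl$time == "post"],
                     cl$subject_id[cl$time == "post"])
    common <- intersect(names(pre), names(post))
    M[common, p] <- post[common] - pre[common]
  }
  M
}

#' Post-pre delta matrix from a metabolite table
#'
#' @param mt a (preprocessed) [metabolite_table()].
#' @return numeric matrix, subjects x metabolites, of post minus pre values.
#' @export
metabolite_deltas <- function(mt) {
  met <- setdiff(names(mt), c("subject_id", "time"))
  pre <- mt[mt$time == "pre", , drop = FALSE]
  post <- mt[mt$time == "post", , drop = FALSE]
  common <- intersect(pre$subject_id, post$subject_id)
  M <- as.matrix(post[match(common, post$subject_id), met, drop = FALSE]) -
    as.matrix(pre[match(common, pre$subject_id), met, drop = FALSE])
  rownames(M) <- common
  M
}
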