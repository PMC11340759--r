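# Ridge-regularized canonical correlation analysis between binary
# engraftment profiles and baseline-corrected clinical deltas, with
# leave-one-out penalty tuning, correlation-circle coordinates and
# inner-product pair selection.

.inv_sqrt <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  vals <- pmax(e$values, .Machine$double.eps)
  e$vectors %*% (t(e$vectors) / sqrt(vals))
}

.standardize <- function(M, center = NULL, scale_ = NULL) {
  M <- as.matrix(M)
  if (is.null(center)) center <- colMeans(M)
  if (is.null(scale_)) scale_ <- apply(M, 2, sd)
  list(Z = sweep(sweep(M, 2, center, "-"), 2,
                 ifelse(scale_ > 0, scale_, 1), "/"),
       center = center, scale = scale_)
}

#' Fit a ridge-regularized canonical correlation model
#'
#' Columns of `X` and `Y` are centered and scaled; zero-variance columns are
#' dropped with a warning.  The canonical directions solve the generalized
#' eigenproblem of \eqn{(C_{xx}+\lambda_1 I)^{-1} C_{xy}
#' (C_{yy}+\lambda_2 I)^{-1} C_{yx}}, computed via the singular value
#' decomposition of the doubly-whitened cross-covariance; the canonical
#' correlations are the corresponding singular values (clamped to
#' \eqn{[0,1]}), non-increasing across components.  Canonical variates are
#' the standardized data times the loadings.
#'
#' @param X numeric matrix, subjects x features (e.g. binary engraftment).
#' @param Y numeric matrix, subjects x features (e.g. clinical deltas);
#'   rows with any missing value in `X` or `Y` are dropped (complete cases).
#' @param lambda1,lambda2 non-negative ridge penalties for `X` and `Y`.
#' @param ncomp number of components kept (default all available).
#' @return object of class `rcca`: `cor` (canonical correlations),
#'   `loadings_X`, `loadings_Y`, `variates_X`, `variates_Y`, `lambda1`,
#'   `lambda2`, standardization parameters and the standardized data.
#' @export
fit_rcc <- function(X, Y, lambda1 = 0, lambda2 = 0, ncomp = NULL) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (is.null(colnames(X))) colnames(X) <- paste0("X", seq_len(ncol(X)))
  if (is.null(colnames(Y))) colnames(Y) <- paste0("Y", seq_len(ncol(Y)))
  cc <- stats::complete.cases(X) & stats::complete.cases(Y)
  X <- X[cc, , drop = FALSE]; Y <- Y[cc, , drop = FALSE]
  n <- nrow(X)
  if (n < 3) stop("fewer than 3 complete subject rows")
  stopifnot(lambda1 >= 0, lambda2 >= 0)
  zv_x <- apply(X, 2, sd) == 0
  zv_y <- apply(Y, 2, sd) == 0
  if (any(zv_x)) {
    warning("dropping zero-variance X column(s): ",
            paste(colnames(X)[zv_x], collapse = ", "))
    X <- X[, !zv_x, drop = FALSE]
  }
  if (any(zv_y)) {
    warning("dropping zero-variance Y column(s): ",
            paste(colnames(Y)[zv_y], collapse = ", "))
    Y <- Y[, !zv_y, drop = FALSE]
  }
  sx <- .standardize(X); sy <- .standardize(Y)
  Cxx <- crossprod(sx$Z) / (n - 1) + lambda1 * diag(ncol(X))
  Cyy <- crossprod(sy$Z) / (n - 1) + lambda2 * diag(ncol(Y))
  Cxy <- crossprod(sx$Z, sy$Z) / (n - 1)
  Wx <- .inv_sqrt(Cxx); Wy <- .inv_sqrt(Cyy)
  sv <- svd(Wx %*% Cxy %*% Wy)
  kmax <- min(ncol(X), ncol(Y))
  if (is.null(ncomp)) ncomp <- kmax
  ncomp <- min(ncomp, kmax)
  lx <- Wx %*% sv$u[, seq_len(ncomp), drop = FALSE]
  ly <- Wy %*% sv$v[, seq_len(ncomp), drop = FALSE]
  rownames(lx) <- colnames(X); rownames(ly) <- colnames(Y)
  colnames(lx) <- colnames(ly) <- paste0("comp", seq_len(ncomp))
  structure(list(cor = pmin(pmax(sv$d[seq_len(ncomp)], 0), 1),
                 loadings_X = lx, loadings_Y = ly,
                 variates_X = sx$Z %*% lx, variates_Y = sy$Z %*% ly,
                 lambda1 = lambda1, lambda2 = lambda2,
                 center_X = sx$center, scale_X = sx$scale,
                 center_Y = sy$center, scale_Y = sy$scale,
                 Zx = sx$Z, Zy = sy$Z, n = n), class = "rcca")
}

#' @export
print.rcca <- function(x, ...) {
  cat(sprintf("rcca: %d subjects, %d x %d features, lambda = (%g, %g)\n",
              x$n, nrow(x$loadings_X), nrow(x$loadings_Y),
              x$lambda1, x$lambda2))
  cat("canonical correlations:", format(x$cor, digits = 4), "\n")
  invisible(x)
}

#' Default penalty grid: 21 log-spaced values in [1e-4, 1]
#' @return numeric vector.
#' @export
default_lambda_grid <- function() 10^seq(-4, 0, length.out = 21)

#' Tune the ridge penalties by leave-one-out cross-validation
#'
#' For each `(lambda1, lambda2)` grid point, each subject is left out once;
#' the model is fit on the remaining subjects, the held-out subject is
#' standardized with the training parameters and scored on the first pair
#' of canonical variates.  All held-out score pairs are pooled and their
#' Pearson correlation is the grid point's score; the grid point with the
#' largest pooled correlation wins, ties breaking toward larger penalties.
#'
#' @param X,Y data matrices as in [fit_rcc()].
#' @param grid1,grid2 candidate penalties (default [default_lambda_grid()]).
#' @return list: `lambda1`, `lambda2`, `score` (the winning pooled
#'   correlation), `scores` (matrix of pooled correlations,
#'   `grid1` x `grid2`).
#' @export
tune_rcc <- function(X, Y, grid1 = default_lambda_grid(),
                     grid2 = default_lambda_grid()) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (is.null(colnames(X))) colnames(X) <- paste0("X", seq_len(ncol(X)))
  if (is.null(colnames(Y))) colnames(Y) <- paste0("Y", seq_len(ncol(Y)))
  cc <- stats::complete.cases(X) & stats::complete.cases(Y)
  X <- X[cc, , drop = FALSE]; Y <- Y[cc, , drop = FALSE]
  n <- nrow(X)
  if (n < 4) stop("need at least 4 complete subjects to cross-validate")
  scores <- matrix(-Inf, length(grid1), length(grid2),
                   dimnames = list(format(grid1, digits = 4),
                                   format(grid2, digits = 4)))
  for (i in seq_along(grid1)) for (j in seq_along(grid2)) {
    ## reference fit on all subjects: fold loadings are sign-aligned to it
    ## (a joint sign flip of a fold's X and Y loadings leaves its model
    ## equivalent but stabilizes pooling across folds)
    ref <- tryCatch(
      suppressWarnings(fit_rcc(X, Y, grid1[i], grid2[j], ncomp = 1)),
      error = function(e) NULL)
    if (is.null(ref)) next
    u <- v <- numeric(n)
    ok <- TRUE
    for (k in seq_len(n)) {
      fit <- tryCatch(
        suppressWarnings(fit_rcc(X[-k, , drop = FALSE], Y[-k, , drop = FALSE],
                                 grid1[i], grid2[j], ncomp = 1)),
        error = function(e) NULL)
      if (is.null(fit)) { ok <- FALSE; break }
      flip <- sum(fit$loadings_X[, 1] *
                    ref$loadings_X[rownames(fit$loadings_X), 1])
      s <- if (flip < 0) -1 else 1
      zx <- (X[k, names(fit$center_X)] - fit$center_X) /
        ifelse(fit$scale_X > 0, fit$scale_X, 1)
      zy <- (Y[k, names(fit$center_Y)] - fit$center_Y) /
        ifelse(fit$scale_Y > 0, fit$scale_Y, 1)
      u[k] <- s * sum(zx * fit$loadings_X[, 1])
      v[k] <- s * sum(zy * fit$loadings_Y[, 1])
    }
    if (ok && sd(u) > 0 && sd(v) > 0)
      scores[i, j] <- cor(u, v)
  }
  best <- -Inf; bi <- bj <- 1L
  for (i in seq_along(grid1)) for (j in seq_along(grid2)) {
    if (scores[i, j] >= best) { best <- scores[i, j]; bi <- i; bj <- j }
  }
  list(lambda1 = grid1[bi], lambda2 = grid2[bj], score = best,
       scores = scores)
}

#' Correlation-circle coordinates of the original features
#'
#' Each feature's coordinates are its Pearson correlations with the first
#' two canonical variates of its own dataset; features whose distance from
#' the origin reaches `r_outer` sit in the outer ring and are considered
#' well represented.  Constant features get coordinates (0, 0).
#'
#' @param model a fitted [fit_rcc()] with at least 2 components.
#' @param r_outer outer-ring radius (default 0.5).
#' @return data.frame: `feature`, `dataset` (`X`/`Y`), `c1`, `c2`,
#'   `radius`, `outer`.
#' @export
circle_coords <- function(model, r_outer = 0.5) {
  stopifnot(inherits(model, "rcca"))
  if (ncol(model$variates_X) < 2)
    stop("need a model with at least 2 components")
  cc_of <- function(Z, V, dataset) {
    safe_cor <- function(z, v) if (sd(z) == 0 || sd(v) == 0) 0 else cor(z, v)
    c1 <- apply(Z, 2, safe_cor, v = V[, 1])
    c2 <- apply(Z, 2, safe_cor, v = V[, 2])
    data.frame(feature = colnames(Z), dataset = dataset, c1 = c1, c2 = c2,
               radius = sqrt(c1^2 + c2^2), row.names = NULL,
               stringsAsFactors = FALSE)
  }
  out <- rbind(cc_of(model$Zx, model$variates_X, "X"),
               cc_of(model$Zy, model$variates_Y, "Y"))
  out$outer <- out$radius >= r_outer
  out
}

#' Select candidate cross-dataset pairs by correlation-circle inner product
#'
#' Among outer-ring features only, every (X feature, Y feature) pair is
#' scored by the 2-D inner product of its circle coordinates,
#' \eqn{c_1^x c_1^y + c_2^x c_2^y} (the product of the two vectors' lengths
#' and the cosine of their angle); the `k` pairs with the largest absolute
#' inner products are returned, ranked.
#'
#' @param coords a [circle_coords()] table.
#' @param k number of pairs (default 10).
#' @return data.frame: `x_feature`, `y_feature`, `inner_product`, `rank`.
#' @export
select_pairs <- function(coords, k = 10L) {
  cx <- coords[coords$dataset == "X" & coords$outer, , drop = FALSE]
  cy <- coords[coords$dataset == "Y" & coords$outer, , drop = FALSE]
  if (!nrow(cx) || !nrow(cy)) {
    warning("no outer-ring features in one of the datasets; empty selection")
    return(data.frame(x_feature = character(0), y_feature = character(0),
                      inner_product = numeric(0), rank = integer(0),
                      stringsAsFactors = FALSE))
  }
  ip <- outer(seq_len(nrow(cx)), seq_len(nrow(cy)), function(i, j)
    cx$c1[i] * cy$c1[j] + cx$c2[i] * cy$c2[j])
  df <- data.frame(x_feature = cx$feature[row(ip)],
                   y_feature = cy$feature[col(ip)],
                   inner_product = as.vector(ip), stringsAsFactors = FALSE)
  df <- df[order(-abs(df$inner_product), df$x_feature, df$y_feature), ,
           drop = FALSE]
  df <- head(df, k)
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df
}
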