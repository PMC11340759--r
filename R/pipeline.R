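# File-based pipeline: simulate -> thresholds -> engraft -> metrics ->
# integrate -> linkstats.  Stages communicate only via files so any stage
# can be rerun in isolation; a JSON manifest records the effective
# configuration, seed and per-stage outputs, and a plain-text log records
# per-stage timing.

#' Default pipeline configuration
#'
#' Every parameter defaults to the package's documented convention:
#' inclusive sharing boundary, linear-interpolation percentiles, 50
#' related pairs for the Youden/pct5 rule, outer-ring radius 0.5, top-10
#' inner-product pairs, 21-point log-spaced penalty grid, BH FDR, 999
#' Procrustes permutations.
#'
#' @param seed master seed for simulation, layouts and permutation tests.
#' @param sim a [sim_config()]; defaults to the standard 29-triad cohort
#'   with this `seed`.
#' @return named list of class `run_config`.
#' @export
default_run_config <- function(seed = 1L, sim = sim_config(seed = seed)) {
  structure(list(
    seed = as.integer(seed),
    simulate = TRUE,
    sim = sim,
    data_dir = NULL,              # used when simulate = FALSE
    min_markers = 20L,
    min_related = 50L,
    dissimilarity_scope = "substudy",
    dissimilarity_interaction = TRUE,
    pattern_alpha = 0.05,
    rcca_top_sgb = 20L,
    complete_case_parameter = "diastolic_bp",
    lambda_grid1 = default_lambda_grid(),
    lambda_grid2 = default_lambda_grid(),
    r_outer = 0.5,
    k_pairs = 10L,
    metabolite_link_alpha = 0.05,
    n_perm = 999L,
    fdr_method = "BH"), class = "run_config")
}

.log_line <- function(con, ...) {
  if (!is.null(con)) writeLines(paste0(...), con)
}

#' Run the full engraftment-to-outcome pipeline
#'
#' Executes the six stages on a simulated or provided cohort, writing all
#' stage outputs under `out_dir` plus `manifest.json` (configuration hash,
#' seed, per-stage row counts and key statistics) and `pipeline.log`
#' (per-stage timing).  A failing stage leaves earlier outputs in place and
#' is marked in the manifest before the error is raised.
#'
#' @param config a [default_run_config()] list (entries may be overridden).
#' @param out_dir output directory.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_con <- file(file.path(out_dir, "pipeline.log"), open = "wt")
  on.exit(close(log_con))
  manifest <- list(seed = config$seed,
                   parameters = config[setdiff(names(config), c("sim"))],
                   stages = list(), counts = list(), statistics = list())
  manifest$parameters$sim <- config$sim[setdiff(names(config$sim),
                                                c("clinical_params"))]
  run_stage <- function(name, fun) {
    t0 <- Sys.time()
    res <- tryCatch(fun(), error = function(e) e)
    dt <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    if (inherits(res, "error")) {
      manifest$stages[[name]] <<- "failed"
      .log_line(log_con, sprintf("stage %-10s FAILED after %.2fs: %s",
                                 name, dt, conditionMessage(res)))
      .write_manifest(manifest, out_dir)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(res))
    }
    manifest$stages[[name]] <<- "ok"
    .log_line(log_con, sprintf("stage %-10s ok (%.2fs)", name, dt))
    res
  }

  ## 1. simulate ------------------------------------------------------------
  data_dir <- if (isTRUE(config$simulate)) file.path(out_dir, "data")
              else config$data_dir
  run_stage("simulate", function() {
    if (isTRUE(config$simulate)) {
      write_fixture(simulate_cohort(config$sim), data_dir)
    } else if (is.null(data_dir) || !dir.exists(data_dir)) {
      stop("simulate disabled and data_dir missing: ",
           if (is.null(data_dir)) "<unset>" else data_dir)
    }
    NULL
  })
  bundle <- read_fixture(data_dir)
  tt <- bundle$triads
  tr <- triads(tt)
  manifest$counts$n_samples <- nrow(tt)
  manifest$counts$n_triads <- nrow(tr)
  manifest$counts$n_substudies <- length(unique(tt$substudy))
  manifest$counts$n_sgb <- length(bundle$distances)

  ## 2. thresholds ----------------------------------------------------------
  thresholds <- run_stage("thresholds", function() {
    th <- estimate_thresholds(tt, bundle$distances,
                              min_markers = config$min_markers,
                              min_related = config$min_related)
    .write_tsv(th, file.path(out_dir, "thresholds.tsv"))
    th
  })
  manifest$counts$n_sgb_estimable <- sum(thresholds$estimable)

  ## 3. engraft -------------------------------------------------------------
  eng <- run_stage("engraft", function() {
    calls <- call_origins(tt, bundle$distances, thresholds,
                          min_markers = config$min_markers)
    .write_tsv(as.data.frame(calls), file.path(out_dir, "origins.tsv"))
    M <- build_engraftment_matrix(calls,
                                  sgb_ids = thresholds$sgb_id[thresholds$estimable],
                                  subjects = tr$subject_id)
    df <- data.frame(sgb_id = rownames(M), check.names = FALSE,
                     stringsAsFactors = FALSE)
    for (j in seq_len(ncol(M))) df[[colnames(M)[j]]] <- M[, j]
    .write_tsv(df, file.path(out_dir, "engraftment.tsv"))
    list(calls = calls, M = M)
  })
  manifest$counts$n_origin_calls <- nrow(eng$calls)
  manifest$counts$n_engraftment_events <- sum(eng$M)

  ## 4. metrics -------------------------------------------------------------
  met <- run_stage("metrics", function() {
    dir.create(file.path(out_dir, "metrics"), showWarnings = FALSE)
    calls <- strain_calls(tt, bundle$distances, thresholds,
                          min_markers = config$min_markers)
    fr <- post_fractions(calls)
    .write_tsv(fr, file.path(out_dir, "metrics", "post_fractions.tsv"))
    dm <- fit_dissimilarity_model(calls, scope = config$dissimilarity_scope,
                                  interaction = config$dissimilarity_interaction)
    .write_tsv(dm$coefficients,
               file.path(out_dir, "metrics", "dissimilarity_model.tsv"))
    pat <- classify_patterns(eng$M, bundle$abundance, tt,
                             alpha = config$pattern_alpha)
    .write_tsv(pat, file.path(out_dir, "metrics", "patterns.tsv"))
    for (st in unique(tt$substudy)) {
      ids <- tt$sample_id[tt$substudy == st]
      prs <- t(utils::combn(sort(ids), 2))
      sh <- sharing_rates(calls, data.frame(sample_a = prs[, 1],
                                            sample_b = prs[, 2],
                                            stringsAsFactors = FALSE))
      net <- export_network(sh, tt, seed = config$seed)
      .write_tsv(net$edges,
                 file.path(out_dir, "metrics",
                           paste0("network_edges_", st, ".tsv")))
      .write_tsv(net$nodes,
                 file.path(out_dir, "metrics",
                           paste0("network_nodes_", st, ".tsv")))
    }
    list(fractions = fr, dissimilarity = dm, patterns = pat)
  })
  manifest$statistics$mean_f_donor <- signif(mean(met$fractions$f_donor,
                                                  na.rm = TRUE), 8)
  manifest$statistics$mean_f_pre <- signif(mean(met$fractions$f_pre,
                                                na.rm = TRUE), 8)
  manifest$statistics$beta_donor_post <-
    signif(met$dissimilarity$beta_donor_post, 8)
  manifest$counts$n_pattern_calls <- nrow(met$patterns)

  ## 5. integrate -----------------------------------------------------------
  rc <- run_stage("integrate", function() {
    dir.create(file.path(out_dir, "rcca"), showWarnings = FALSE)
    top <- names(sort(rowSums(eng$M), decreasing = TRUE))
    top <- top[seq_len(min(config$rcca_top_sgb, length(top)))]
    X <- t(eng$M[top, , drop = FALSE])
    Y <- clinical_deltas(bundle$clinical)
    ## restrict to subjects complete for the designated parameter
    if (!is.null(config$complete_case_parameter)) {
      ok <- !is.na(Y[, config$complete_case_parameter])
      X <- X[ok, , drop = FALSE]; Y <- Y[ok, , drop = FALSE]
    }
    tune <- tune_rcc(X, Y, config$lambda_grid1, config$lambda_grid2)
    fit <- suppressWarnings(fit_rcc(X, Y, tune$lambda1, tune$lambda2))
    coords <- circle_coords(fit, r_outer = config$r_outer)
    sel <- select_pairs(coords, k = config$k_pairs)
    .write_tsv(coords, file.path(out_dir, "rcca", "circle_coords.tsv"))
    .write_tsv(sel, file.path(out_dir, "rcca", "selected_pairs.tsv"))
    lx <- data.frame(feature = rownames(fit$loadings_X), fit$loadings_X,
                     stringsAsFactors = FALSE)
    ly <- data.frame(feature = rownames(fit$loadings_Y), fit$loadings_Y,
                     stringsAsFactors = FALSE)
    .write_tsv(lx, file.path(out_dir, "rcca", "loadings_X.tsv"))
    .write_tsv(ly, file.path(out_dir, "rcca", "loadings_Y.tsv"))
    list(tune = tune, fit = fit, coords = coords, selected = sel,
         n_complete = nrow(X))
  })
  manifest$counts$n_complete_cases <- rc$n_complete
  manifest$statistics$lambda1 <- signif(rc$tune$lambda1, 8)
  manifest$statistics$lambda2 <- signif(rc$tune$lambda2, 8)
  manifest$statistics$first_canonical_cor <- signif(rc$fit$cor[1], 8)
  manifest$counts$n_selected_pairs <- nrow(rc$selected)

  ## 6. linkstats -----------------------------------------------------------
  ls_res <- run_stage("linkstats", function() {
    dir.create(file.path(out_dir, "stats"), showWarnings = FALSE)
    sel <- rc$selected
    lmm <- fit_engraftment_lmms(
      data.frame(sgb_id = sel$x_feature, parameter = sel$y_feature,
                 stringsAsFactors = FALSE),
      bundle$clinical, eng$M)
    .write_tsv(lmm, file.path(out_dir, "stats", "lmm.tsv"))
    mt <- suppressWarnings(preprocess_metabolites(bundle$metabolites))
    md <- metabolite_deltas(mt)
    ## metabolites related to the selected engrafted strains
    sgbs <- unique(sel$x_feature)
    met_long <- do.call(rbind, lapply(colnames(md), function(m)
      data.frame(subject_id = mt$subject_id, parameter = m, time = mt$time,
                 value = mt[[m]], stringsAsFactors = FALSE)))
    met_pairs <- expand.grid(sgb_id = sgbs, parameter = colnames(md),
                             stringsAsFactors = FALSE)
    met_lmm <- fit_engraftment_lmms(met_pairs, met_long, eng$M)
    .write_tsv(met_lmm, file.path(out_dir, "stats", "metabolite_lmm.tsv"))
    hits <- unique(met_lmm$parameter[!is.na(met_lmm$p) &
                                       met_lmm$p < config$metabolite_link_alpha])
    cl_params <- unique(sel$y_feature)
    Y <- clinical_deltas(bundle$clinical)
    sp <- do.call(rbind, lapply(hits, function(m) {
      do.call(rbind, lapply(cl_params, function(p) {
        common <- intersect(rownames(md), rownames(Y))
        r <- spearman_link(md[common, m], Y[common, p])
        cbind(data.frame(metabolite = m, parameter = p,
                         stringsAsFactors = FALSE), r)
      }))
    }))
    if (!is.null(sp))
      .write_tsv(sp, file.path(out_dir, "stats", "spearman_links.tsv"))
    ## global concordance: engraftment profile vs metabolite deltas
    common <- intersect(rownames(md), colnames(eng$M))
    pr <- procrustes_test(t(eng$M[, common, drop = FALSE]),
                          md[common, , drop = FALSE],
                          n_perm = config$n_perm, seed = config$seed)
    ml <- multilevel_split(as.matrix(mt[, colnames(md), drop = FALSE]),
                           mt$subject_id)
    pca <- prcomp(ml$within, center = FALSE, scale. = FALSE)
    jsonlite::write_json(
      list(procrustes = list(m2 = pr$m2, p = pr$p,
                             correlation = pr$correlation),
           within_pc1_var = unname(pca$sdev[1]^2 / sum(pca$sdev^2))),
      file.path(out_dir, "stats", "summary.json"),
      auto_unbox = TRUE, digits = NA)
    list(lmm = lmm, met_lmm = met_lmm, spearman = sp, procrustes = pr,
         within_pc1_var = unname(pca$sdev[1]^2 / sum(pca$sdev^2)))
  })
  best <- which.min(ls_res$lmm$p_fdr)
  if (length(best)) {
    manifest$statistics$top_lmm_sgb <- ls_res$lmm$sgb_id[best]
    manifest$statistics$top_lmm_parameter <- ls_res$lmm$parameter[best]
    manifest$statistics$top_lmm_estimate <- signif(ls_res$lmm$estimate[best], 8)
    manifest$statistics$top_lmm_p_fdr <- signif(ls_res$lmm$p_fdr[best], 8)
  }
  manifest$counts$n_metabolite_hits <-
    length(unique(ls_res$met_lmm$parameter[!is.na(ls_res$met_lmm$p) &
                     ls_res$met_lmm$p < config$metabolite_link_alpha]))
  manifest$statistics$procrustes_m2 <- signif(ls_res$procrustes$m2, 8)
  manifest$statistics$procrustes_p <- signif(ls_res$procrustes$p, 8)
  manifest$statistics$within_pc1_var <- signif(ls_res$within_pc1_var, 8)

  invisible(.write_manifest(manifest, out_dir))
}

.write_manifest <- function(manifest, out_dir) {
  cfg_json <- jsonlite::toJSON(manifest$parameters, auto_unbox = TRUE,
                               digits = NA)
  tmp <- tempfile(); writeLines(cfg_json, tmp)
  manifest$config_hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
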