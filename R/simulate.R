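# Synthetic FMT cohorts with known engraftment ground truth.
#
# The generator emulates the structure of a multi-sub-study FMT cohort:
# 29 triads over 3 sub-studies, donors reused round-robin across recipients,
# bimodal same-strain / different-strain distance distributions per SGB,
# a block of subjects with missing diastolic blood pressure, and planted
# engraftment -> metabolite -> clinical effects.

#' Simulation configuration for a synthetic FMT cohort
#'
#' Defaults describe the emulated study conditions: 29 FMT triads over 3
#' sub-studies with 8 donors assigned round-robin, 50 SGBs, same-strain
#' normalized distances centred at 0.01 and different-strain distances at
#' 0.20 (truncated normal at zero), a 30% per-SGB engraftment probability,
#' 10 subjects of the second sub-study missing diastolic blood pressure, and
#' a planted effect chain in which engraftment of the first SGBs lowers
#' diastolic blood pressure and an arginine-pathway-like plasma metabolite.
#'
#' @param n_triads number of FMT triads (recipients).
#' @param n_substudies number of sub-studies the triads are split over.
#' @param n_sgb number of SGBs simulated.
#' @param n_donors number of distinct donors, reused round-robin.
#' @param same_strain_dist `c(mu, sd)` of the same-strain (related) distance
#'   distribution, truncated at 0.
#' @param diff_strain_dist `c(mu, sd)` of the different-strain distribution.
#' @param engraft_prob per-SGB engraftment probability, recycled to `n_sgb`;
#'   the default is the long-tailed profile of [default_engraft_prob()], in
#'   which the effect-carrying strains are among the most engrafting.
#' @param p_donor_present probability a donor carries a given SGB.
#' @param p_pre_present probability a recipient carries the SGB pre-FMT.
#' @param effect_map data.frame with columns `sgb_id`, `target`, `type`
#'   (`"clinical"` or `"metabolite"`) and `delta`: the post-pre change added
#'   for subjects in which `sgb_id` engrafts.
#' @param missing_dbp_subjects number of subjects whose diastolic blood
#'   pressure values are set missing (drawn from the second sub-study first).
#' @param n_metabolites number of plasma metabolites.
#' @param metabolite_missing_rate fraction of each metabolite's lowest raw
#'   values censored to `NA` (below detection limit).
#' @param marker_count_range integer range per-sample marker counts are
#'   drawn from (uniform, inclusive).
#' @param clinical_params data.frame naming the simulated clinical
#'   parameters with their units, population mean/sd and the sd of the
#'   within-subject post-pre change noise.
#' @param seed integer seed fixing all randomness.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_triads = 29L, n_substudies = 3L, n_sgb = 50L,
                       n_donors = 8L,
                       same_strain_dist = c(mu = 0.01, sd = 0.004),
                       diff_strain_dist = c(mu = 0.20, sd = 0.06),
                       engraft_prob = default_engraft_prob(n_sgb),
                       p_donor_present = 0.8, p_pre_present = 0.7,
                       effect_map = default_effect_map(),
                       missing_dbp_subjects = 10L,
                       n_metabolites = 40L,
                       metabolite_missing_rate = 0.08,
                       marker_count_range = c(20L, 200L),
                       clinical_params = default_clinical_params(),
                       seed = 1L) {
  stopifnot(same_strain_dist[1] < diff_strain_dist[1],
            all(engraft_prob >= 0 & engraft_prob <= 1),
            p_donor_present >= 0, p_donor_present <= 1,
            p_pre_present >= 0, p_pre_present <= 1,
            n_triads >= 1, n_substudies >= 1, n_sgb >= 1, n_donors >= 1,
            missing_dbp_subjects <= n_triads)
  cfg <- list(n_triads = as.integer(n_triads),
              n_substudies = as.integer(n_substudies),
              n_sgb = as.integer(n_sgb), n_donors = as.integer(n_donors),
              same_strain_dist = unname(same_strain_dist),
              diff_strain_dist = unname(diff_strain_dist),
              engraft_prob = rep_len(engraft_prob, n_sgb),
              p_donor_present = p_donor_present,
              p_pre_present = p_pre_present,
              effect_map = effect_map,
              missing_dbp_subjects = as.integer(missing_dbp_subjects),
              n_metabolites = as.integer(n_metabolites),
              metabolite_missing_rate = metabolite_missing_rate,
              marker_count_range = as.integer(marker_count_range),
              clinical_params = clinical_params,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' Default clinical parameter panel for the generator
#'
#' A cardiometabolic panel typical of metabolic-syndrome FMT studies.
#' `change_sd` is the sd of the within-subject post-pre noise.
#' @return data.frame.
#' @export
default_clinical_params <- function() {
  data.frame(
    parameter = c("diastolic_bp", "systolic_bp", "fasting_glucose",
                  "rate_glucose_disappearance", "hdl", "triglycerides"),
    units = c("mmHg", "mmHg", "mmol/L", "mg/kg/min", "mmol/L", "mmol/L"),
    mean = c(88, 135, 6.0, 3.0, 1.1, 1.9),
    sd = c(8, 12, 0.8, 1.0, 0.25, 0.5),
    change_sd = c(5, 7, 0.4, 0.5, 0.1, 0.25),
    stringsAsFactors = FALSE)
}

#' Default per-SGB engraftment probabilities
#'
#' Engraftment frequencies across species are strongly long-tailed: a
#' handful of strains transfer in roughly half the recipients while most
#' transfer rarely.  The default profile puts the three effect-carrying
#' SGBs at 0.5 (the associated strains of the emulated study were among the
#' most transferred) and lets the remainder decay linearly to 0.05.
#'
#' @param n_sgb number of SGBs.
#' @return numeric vector of length `n_sgb`.
#' @export
default_engraft_prob <- function(n_sgb) {
  if (n_sgb <= 3) return(rep(0.5, n_sgb))
  c(rep(0.5, 3), seq(0.45, 0.05, length.out = n_sgb - 3))
}

#' Default planted effect map
#'
#' Engraftment of the first three SGBs lowers diastolic blood pressure;
#' the first two also lower metabolite `M01`, giving the chained
#' engraftment -> metabolite -> clinical signal the downstream statistics
#' are meant to recover.
#' @return data.frame with columns `sgb_id`, `target`, `type`, `delta`.
#' @export
default_effect_map <- function() {
  data.frame(
    sgb_id = c("SGB0001", "SGB0002", "SGB0003", "SGB0001", "SGB0002"),
    target = c("diastolic_bp", "diastolic_bp", "diastolic_bp", "M01", "M01"),
    type = c("clinical", "clinical", "clinical", "metabolite", "metabolite"),
    delta = c(-16.0, -19.5, -13.2, -0.5, -0.5),
    stringsAsFactors = FALSE)
}

.trunc_norm <- function(n, mu, sd) {
  if (sd <= 0) return(rep(mu, n))
  pmax(rnorm(n, mu, sd), 0)
}

.sgb_ids <- function(n) sprintf("SGB%04d", seq_len(n))

# deterministic per-SGB sub-seed so adding SGBs does not reshuffle earlier ones
.sub_seed <- function(seed, i) (as.integer(seed) %% 100003L) * 20011L + 7L * i

#' Simulate a complete synthetic FMT cohort
#'
#' Generates, for each SGB and triad, an engraftment indicator; engrafted
#' post-FMT strains sit at same-strain distance from their donor and
#' different-strain distance from the pre-FMT strain, and conversely for
#' retained strains.  All cross-subject pairs draw from the different-strain
#' distribution.  Clinical post values are pre values plus the planted
#' deltas of engrafted SGBs plus noise; metabolites analogously.  Designated
#' subjects get missing diastolic blood pressure.
#'
#' @param cfg a [sim_config()].
#' @return list with elements `triads` ([triad_table()]), `distances` (list
#'   of [distance_set()]), `abundance`, `clinical`, `metabolites`, `truth`
#'   (list with `engraftment` matrix, `origin` data.frame, `effects`), and
#'   `config`.
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  sgbs <- .sgb_ids(cfg$n_sgb)
  known <- c(cfg$clinical_params$parameter,
             sprintf("M%02d", seq_len(cfg$n_metabolites)))
  bad <- setdiff(cfg$effect_map$target, known)
  bad <- c(bad, setdiff(cfg$effect_map$sgb_id, sgbs))
  if (length(bad))
    stop("effect_map names unknown SGB/target: ", paste(bad, collapse = ", "))

  set.seed(cfg$seed)
  ## cohort structure -------------------------------------------------------
  subjects <- sprintf("R%02d", seq_len(cfg$n_triads))
  substudy <- sprintf("study%d", rep_len(seq_len(cfg$n_substudies),
                                         cfg$n_triads))
  substudy <- substudy[order(substudy)]           # contiguous blocks
  donors <- sprintf("D%02d", rep_len(seq_len(cfg$n_donors), cfg$n_triads))
  donor_samples <- paste0(donors, "_don")
  tt <- rbind(
    data.frame(sample_id = unique(donor_samples),
               subject_id = sub("_don$", "", unique(donor_samples)),
               role = "donor", substudy = substudy[match(unique(donor_samples),
                                                         donor_samples)],
               donor_id = "", stringsAsFactors = FALSE),
    data.frame(sample_id = paste0(subjects, "_pre"), subject_id = subjects,
               role = "pre", substudy = substudy, donor_id = donor_samples,
               stringsAsFactors = FALSE),
    data.frame(sample_id = paste0(subjects, "_post"), subject_id = subjects,
               role = "post", substudy = substudy, donor_id = donor_samples,
               stringsAsFactors = FALSE))
  tt <- triad_table(tt)
  tr <- triads(tt)

  ## subjects with missing diastolic blood pressure: second sub-study first
  ord <- order(match(substudy, sprintf("study%d",
                                       c(2L, setdiff(seq_len(cfg$n_substudies), 2L)))))
  miss_dbp <- subjects[ord][seq_len(cfg$missing_dbp_subjects)]

  ## per-SGB presence, engraftment, distances ------------------------------
  all_samples <- tt$sample_id
  n_tr <- nrow(tr)
  eng <- matrix(0L, cfg$n_sgb, n_tr, dimnames = list(sgbs, tr$subject_id))
  origin <- list()
  distances <- vector("list", cfg$n_sgb)
  names(distances) <- sgbs
  presence <- matrix(FALSE, cfg$n_sgb, length(all_samples),
                     dimnames = list(sgbs, all_samples))
  mu_s <- cfg$same_strain_dist[1]; sd_s <- cfg$same_strain_dist[2]
  mu_d <- cfg$diff_strain_dist[1]; sd_d <- cfg$diff_strain_dist[2]

  for (i in seq_len(cfg$n_sgb)) {
    set.seed(.sub_seed(cfg$seed, i))
    don_ids <- unique(tr$donor_sample)
    don_has <- setNames(rbinom(length(don_ids), 1, cfg$p_donor_present) == 1,
                        don_ids)
    pre_has <- rbinom(n_tr, 1, cfg$p_pre_present) == 1
    e <- rbinom(n_tr, 1, cfg$engraft_prob[i]) == 1 & don_has[tr$donor_sample]
    post_has <- e | pre_has
    eng[i, ] <- as.integer(e)
    org <- ifelse(!post_has, "absent",
                  ifelse(e & !pre_has, "novel_donor",
                         ifelse(e, "donor", "recipient")))
    origin[[i]] <- data.frame(sgb_id = sgbs[i], post_sample = tr$post_sample,
                              origin = org, stringsAsFactors = FALSE)
    samp <- c(don_ids[don_has], tr$pre_sample[pre_has],
              tr$post_sample[post_has])
    presence[i, samp] <- TRUE
    n_s <- length(samp)
    if (n_s < 2) { distances[[i]] <- NULL; next }
    D <- matrix(0, n_s, n_s, dimnames = list(samp, samp))
    low <- lower.tri(D)
    D[low] <- .trunc_norm(sum(low), mu_d, sd_d)
    D <- D + t(D)
    for (k in seq_len(n_tr)) {
      po <- tr$post_sample[k]; pr <- tr$pre_sample[k]
      dn <- tr$donor_sample[k]
      if (!po %in% samp) next
      if (e[k]) {
        D[po, dn] <- D[dn, po] <- .trunc_norm(1, mu_s, sd_s)
        if (pre_has[k]) D[po, pr] <- D[pr, po] <- .trunc_norm(1, mu_d, sd_d)
      } else if (pre_has[k]) {
        D[po, pr] <- D[pr, po] <- .trunc_norm(1, mu_s, sd_s)
        if (dn %in% samp) D[po, dn] <- D[dn, po] <- .trunc_norm(1, mu_d, sd_d)
      }
    }
    diag(D) <- 0
    mk <- setNames(sample(seq(cfg$marker_count_range[1],
                              cfg$marker_count_range[2]), n_s, replace = TRUE),
                   samp)
    distances[[i]] <- distance_set(sgbs[i], D, marker_counts = mk)
  }
  distances <- distances[!vapply(distances, is.null, logical(1))]

  ## abundances ------------------------------------------------------------
  set.seed(.sub_seed(cfg$seed, cfg$n_sgb + 1L))
  A <- matrix(0, length(all_samples), cfg$n_sgb,
              dimnames = list(all_samples, sgbs))
  for (s in all_samples) {
    pres <- presence[, s]
    if (!any(pres)) next
    w <- rgamma(sum(pres), shape = 0.8)
    A[s, pres] <- 0.95 * w / sum(w)
  }
  ## post abundances track pre for retained strains (small multiplicative
  ## drift) so paired tests see no systematic change unless planted
  for (k in seq_len(n_tr)) {
    pr <- tr$pre_sample[k]; po <- tr$post_sample[k]
    both <- presence[, pr] & presence[, po] & eng[, k] == 0L
    if (any(both)) {
      A[po, both] <- A[pr, both] * exp(rnorm(sum(both), 0, 0.15))
    }
    tot <- sum(A[po, ])
    if (tot > 0.95) A[po, ] <- A[po, ] * 0.95 / tot
  }
  A <- abundance_table(A)

  ## clinical --------------------------------------------------------------
  set.seed(.sub_seed(cfg$seed, cfg$n_sgb + 2L))
  cp <- cfg$clinical_params
  cl <- do.call(rbind, lapply(seq_len(nrow(cp)), function(j) {
    pre_v <- rnorm(n_tr, cp$mean[j], cp$sd[j])
    delta <- rep(0, n_tr)
    em <- cfg$effect_map[cfg$effect_map$type == "clinical" &
                           cfg$effect_map$target == cp$parameter[j], ,
                         drop = FALSE]
    for (r in seq_len(nrow(em)))
      delta <- delta + em$delta[r] * eng[em$sgb_id[r], ]
    post_v <- pre_v + delta + rnorm(n_tr, 0, cp$change_sd[j])
    if (cp$parameter[j] == "diastolic_bp") {
      pre_v[tr$subject_id %in% miss_dbp] <- NA
      post_v[tr$subject_id %in% miss_dbp] <- NA
    }
    data.frame(subject_id = rep(tr$subject_id, 2),
               parameter = cp$parameter[j],
               time = rep(c("pre", "post"), each = n_tr),
               value = c(pre_v, post_v), units = cp$units[j],
               stringsAsFactors = FALSE)
  }))
  cl <- clinical_table(cl)

  ## metabolites -----------------------------------------------------------
  set.seed(.sub_seed(cfg$seed, cfg$n_sgb + 3L))
  mets <- sprintf("M%02d", seq_len(cfg$n_metabolites))
  mt <- data.frame(subject_id = rep(tr$subject_id, 2),
                   time = rep(c("pre", "post"), each = n_tr),
                   stringsAsFactors = FALSE)
  for (m in mets) {
    scale_m <- exp(rnorm(1, 0, 0.5))
    pre_v <- scale_m * exp(rnorm(n_tr, 0, 0.4))
    delta <- rep(0, n_tr)
    em <- cfg$effect_map[cfg$effect_map$type == "metabolite" &
                           cfg$effect_map$target == m, , drop = FALSE]
    for (r in seq_len(nrow(em)))
      delta <- delta + em$delta[r] * scale_m * eng[em$sgb_id[r], ]
    post_v <- pmax(pre_v + delta + rnorm(n_tr, 0, 0.15 * scale_m), 0)
    v <- c(pre_v, post_v)
    if (cfg$metabolite_missing_rate > 0) {
      cut <- quantile(v, cfg$metabolite_missing_rate, type = 7)
      v[v < cut] <- NA
    }
    mt[[m]] <- v
  }
  mt <- metabolite_table(mt)

  list(triads = tt, distances = distances, abundance = A, clinical = cl,
       metabolites = mt,
       truth = list(engraftment = eng, origin = do.call(rbind, origin),
                    effects = cfg$effect_map, presence = presence),
       config = cfg)
}

#' Write a simulated cohort bundle to disk
#'
#' Writes every table in the package's TSV formats plus a JSON manifest
#' recording the configuration and seed.  Two runs with the same seed
#' produce byte-identical files.
#'
#' @param bundle result of [simulate_cohort()].
#' @param out_dir output directory (created if absent).
#' @return the manifest, invisibly; written to `manifest.json`.
#' @export
write_fixture <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "distances"), showWarnings = FALSE)
  write_triad_table(bundle$triads, file.path(out_dir, "triads.tsv"))
  write_abundance(bundle$abundance, file.path(out_dir, "abundance.tsv"))
  write_clinical(bundle$clinical, file.path(out_dir, "clinical.tsv"))
  write_metabolites(bundle$metabolites, file.path(out_dir, "metabolites.tsv"))
  mk <- list()
  for (ds in bundle$distances) {
    write_distances(ds, file.path(out_dir, "distances",
                                  paste0(ds$sgb_id, ".tsv")))
    mk[[ds$sgb_id]] <- data.frame(sgb_id = ds$sgb_id,
                                  sample_id = ds$sample_ids,
                                  n_markers = unname(ds$marker_counts),
                                  stringsAsFactors = FALSE)
  }
  .write_tsv(do.call(rbind, mk), file.path(out_dir, "marker_counts.tsv"))
  te <- bundle$truth$engraftment
  df <- data.frame(sgb_id = rownames(te), stringsAsFactors = FALSE,
                   check.names = FALSE)
  for (j in seq_len(ncol(te))) df[[colnames(te)[j]]] <- te[, j]
  .write_tsv(df, file.path(out_dir, "truth_engraftment.tsv"))
  .write_tsv(bundle$truth$origin, file.path(out_dir, "truth_origin.tsv"))
  cfg <- bundle$config
  manifest <- list(
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), c("clinical_params", "effect_map"))],
    effect_map = cfg$effect_map,
    files = c("triads.tsv", "abundance.tsv", "clinical.tsv",
              "metabolites.tsv", "marker_counts.tsv",
              "truth_engraftment.tsv", "truth_origin.tsv",
              file.path("distances",
                        paste0(vapply(bundle$distances, `[[`, "", "sgb_id"),
                               ".tsv"))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read back a fixture written by [write_fixture()]
#' @param dir fixture directory.
#' @return bundle list (without ground truth reconstruction of `presence`).
#' @export
read_fixture <- function(dir) {
  mk <- .read_tsv(file.path(dir, "marker_counts.tsv"))
  files <- list.files(file.path(dir, "distances"), pattern = "\\.tsv$",
                      full.names = TRUE)
  distances <- lapply(files, function(f) {
    sgb <- sub("\\.tsv$", "", basename(f))
    m <- mk[mk$sgb_id == sgb, ]
    read_distances(f, "matrix", sgb_id = sgb,
                   marker_counts = setNames(m$n_markers, m$sample_id))
  })
  names(distances) <- vapply(distances, `[[`, "", "sgb_id")
  te <- .read_tsv(file.path(dir, "truth_engraftment.tsv"))
  eng <- as.matrix(te[, -1, drop = FALSE]); rownames(eng) <- te$sgb_id
  list(triads = read_triad_table(file.path(dir, "triads.tsv")),
       distances = distances,
       abundance = read_abundance(file.path(dir, "abundance.tsv")),
       clinical = read_clinical(file.path(dir, "clinical.tsv")),
       metabolites = read_metabolites(file.path(dir, "metabolites.tsv")),
       truth = list(engraftment = eng,
                    origin = .read_tsv(file.path(dir, "truth_origin.tsv"))))
}
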