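make_calls <- function(bundle, min_related = 50L) {
  th <- estimate_thresholds(bundle$triads, bundle$distances,
                            min_related = min_related)
  strain_calls(bundle$triads, bundle$distances, th)
}

test_that("sharing rate is shared strains over SGBs profiled in common", {
  # 10 SGBs profiled in both samples, 5 shared
  tt <- toy_triads(1)
  ds_list <- lapply(1:10, function(i) {
    d_ab <- if (i <= 5) 0.01 else 0.5
    toy_distance_set(c("D1_don", "R1_pre", "R1_post"),
                     c(0.5, d_ab, 0.5), sgb_id = sprintf("g%02d", i))
  })
  th <- data.frame(sgb_id = sprintf("g%02d", 1:10), threshold = 0.1,
                   estimable = TRUE, stringsAsFactors = FALSE)
  calls <- strain_calls(tt, ds_list, th)
  r <- sharing_rate(calls, "D1_don", "R1_post")
  expect_equal(r$n_shared, 5L)
  expect_equal(r$n_common, 10L)
  expect_equal(r$rate, 0.5)
  # zero shared
  r0 <- sharing_rate(calls, "D1_don", "R1_pre")
  expect_equal(r0$rate, 0)
  # no SGB profiled in common -> missing
  calls2 <- strain_calls(tt, list(toy_distance_set(c("D1_don", "R1_pre"),
                                                   0.5, sgb_id = "g01")),
                         th)
  expect_true(is.na(sharing_rate(calls2, "D1_don", "R1_post")$rate))
})

test_that("sharing rates match a brute-force recount on simulated cohorts", {
  b <- simulate_cohort(sim_config(n_triads = 8, n_sgb = 12, seed = 31,
                                  missing_dbp_subjects = 0))
  calls <- make_calls(b)
  th <- estimate_thresholds(b$triads, b$distances)
  tr <- triads(b$triads)
  pairs <- data.frame(sample_a = tr$donor_sample, sample_b = tr$post_sample,
                      stringsAsFactors = FALSE)
  got <- sharing_rates(calls, pairs)
  for (k in seq_len(nrow(pairs))) {
    shared <- common <- 0
    for (ds in b$distances) {
      t <- th$threshold[th$sgb_id == ds$sgb_id]
      f <- filter_profiles(ds)
      if (!all(c(pairs$sample_a[k], pairs$sample_b[k]) %in% f$sample_ids))
        next
      common <- common + 1
      d <- f$D[pairs$sample_a[k], pairs$sample_b[k]]
      shared <- shared + (d <= t)
    }
    expect_equal(got$n_shared[k], shared)
    expect_equal(got$n_common[k], common)
  }
  # permutation invariance: swapping the pair orientation changes nothing
  rev <- sharing_rates(calls, data.frame(sample_a = pairs$sample_b,
                                         sample_b = pairs$sample_a,
                                         stringsAsFactors = FALSE))
  expect_equal(rev$rate, got$rate)
})

test_that("post-anchored fractions use the post-profiled denominator", {
  tt <- toy_triads(1)
  # 4 SGBs profiled at post; 1 shared with donor only, 3 with pre only
  ds_list <- lapply(1:4, function(i) {
    dd <- if (i == 1) 0.01 else 0.5       # donor-post
    dp <- if (i == 1) 0.5 else 0.01       # pre-post
    toy_distance_set(c("D1_don", "R1_pre", "R1_post"), c(0.5, dd, dp),
                     sgb_id = sprintf("g%d", i))
  })
  th <- data.frame(sgb_id = sprintf("g%d", 1:4), threshold = 0.1,
                   estimable = TRUE, stringsAsFactors = FALSE)
  fr <- post_fractions(strain_calls(tt, ds_list, th))
  expect_equal(fr$n_post, 4L)
  expect_equal(fr$f_donor, 0.25)
  expect_equal(fr$f_pre, 0.75)
})

test_that("f_donor and f_pre may jointly exceed 1 (both-shared strains)", {
  tt <- toy_triads(1)
  ds_list <- lapply(1:3, function(i)
    toy_distance_set(c("D1_don", "R1_pre", "R1_post"), c(0.5, 0.01, 0.01),
                     sgb_id = sprintf("g%d", i)))
  th <- data.frame(sgb_id = sprintf("g%d", 1:3), threshold = 0.1,
                   estimable = TRUE, stringsAsFactors = FALSE)
  fr <- post_fractions(strain_calls(tt, ds_list, th))
  expect_equal(fr$f_donor, 1)
  expect_equal(fr$f_pre, 1)
  expect_gt(fr$f_donor + fr$f_pre, 1)
})

test_that("post fractions match ground-truth tallies on separable cohorts", {
  b <- simulate_cohort(sim_config(n_triads = 8, n_sgb = 20,
                                  same_strain_dist = c(0.01, 0),
                                  diff_strain_dist = c(0.5, 0),
                                  missing_dbp_subjects = 0, seed = 13))
  # fixed threshold between the two (noise-free) distance modes
  th <- data.frame(sgb_id = vapply(b$distances, `[[`, "", "sgb_id"),
                   threshold = 0.1, estimable = TRUE, stringsAsFactors = FALSE)
  fr <- post_fractions(strain_calls(b$triads, b$distances, th))
  tr <- triads(b$triads)
  for (k in seq_len(nrow(tr))) {
    pres <- b$truth$presence[, tr$post_sample[k]]
    truth_eng <- b$truth$engraftment[, k] == 1L
    n_post <- sum(pres)
    # engrafted strains are shared with the donor; retained with pre
    expect_equal(fr$f_donor[k], sum(pres & truth_eng) / n_post)
    expect_equal(fr$f_pre[k],
                 sum(pres & !truth_eng &
                       b$truth$presence[, tr$pre_sample[k]]) / n_post)
  }
})

test_that("dissimilarity OLS recovers a planted noiseless donor-post effect", {
  # construct sharing so that true-donor/post pairs have dissimilarity
  # exactly 0.2 lower: 10 SGBs everywhere; baseline 5 shared (D=0.5),
  # true-donor post pairs 7 shared (D=0.3)
  tt <- toy_triads(3)
  ids <- tt$sample_id
  ds_list <- lapply(1:10, function(i) {
    n <- length(ids)
    D <- matrix(0.5, n, n, dimnames = list(ids, ids))
    diag(D) <- 0
    for (k in 1:3) {
      po <- sprintf("R%d_post", k); dn <- sprintf("D%d_don", k)
      d <- if (i <= 5) 0.01 else if (i <= 7) 0.02 else 0.5
      D[po, dn] <- D[dn, po] <- d
    }
    # all recipient-donor pre pairs and false-donor pairs share 5 of 10
    for (k in 1:3) for (j in 1:3) {
      pr <- sprintf("R%d_pre", k); dn <- sprintf("D%d_don", j)
      if (i <= 5) D[pr, dn] <- D[dn, pr] <- 0.01
      po <- sprintf("R%d_post", k)
      if (j != k && i <= 5) D[po, dn] <- D[dn, po] <- 0.01
    }
    distance_set(sprintf("g%02d", i), D)
  })
  th <- data.frame(sgb_id = sprintf("g%02d", 1:10), threshold = 0.1,
                   estimable = TRUE, stringsAsFactors = FALSE)
  calls <- strain_calls(tt, ds_list, th)
  # zero-residual design: lm warns that the fit is exact, which is the point
  m <- suppressWarnings(fit_dissimilarity_model(calls))
  expect_equal(m$beta_donor_post, -0.2, tolerance = 1e-10)
})

test_that("dissimilarity OLS equals the normal-equation oracle", {
  b <- simulate_cohort(sim_config(n_triads = 8, n_sgb = 12, seed = 17,
                                  missing_dbp_subjects = 0))
  m <- fit_dissimilarity_model(make_calls(b))
  g <- m$pairs
  X <- cbind(1, g$sample_type == "post", g$true_donor,
             (g$sample_type == "post") & g$true_donor)
  beta <- solve(t(X) %*% X, t(X) %*% g$dissimilarity)
  expect_equal(unname(m$coefficients$estimate), as.vector(beta),
               tolerance = 1e-10)

  # main-effects-only variant has no interaction coefficient
  m0 <- fit_dissimilarity_model(make_calls(b), interaction = FALSE)
  expect_true(is.na(m0$beta_donor_post))
  expect_equal(nrow(m0$coefficients), 3L)
})

test_that("pattern classification separates novel, replacement and expansion", {
  tt <- toy_triads(6)
  eng <- matrix(1L, 2, 6,
                dimnames = list(c("g1", "g2"), sprintf("R%d", 1:6)))
  A <- matrix(0, 18, 2, dimnames = list(tt$sample_id, c("g1", "g2")))
  # g1: absent pre for R1 (novel); stable for others (replacement)
  A[sprintf("R%d_pre", 2:6), "g1"] <- 0.02
  A[sprintf("R%d_post", 1:6), "g1"] <- 0.02
  # g2: doubles after FMT in every subject (expansion)
  A[sprintf("R%d_pre", 1:6), "g2"] <- seq(0.01, 0.06, by = 0.01)
  A[sprintf("R%d_post", 1:6), "g2"] <- 2 * seq(0.01, 0.06, by = 0.01)
  pat <- classify_patterns(eng, A, tt)
  p1 <- pat[pat$sgb_id == "g1", ]
  expect_equal(p1$pattern[p1$subject_id == "R1"], "novel")
  expect_true(all(p1$pattern[p1$subject_id != "R1"] == "replacement"))
  expect_true(all(pat$pattern[pat$sgb_id == "g2"] == "expansion"))
})

test_that("paired abundance comparison uses the exact signed-rank null", {
  pre <- c(0.01, 0.02, 0.03, 0.04, 0.05, 0.06)
  post <- pre + c(0.011, 0.012, 0.013, 0.014, 0.015, 0.016)
  r <- compare_abundance(pre, post)        # all increases, n = 6
  expect_equal(r$p.value, 0.03125)
  # identical vectors: no signal
  expect_equal(compare_abundance(pre, pre)$p.value, 1)
  # too few pairs
  expect_false(compare_abundance(c(1, 2), c(2, 3))$testable)
})

test_that("planted abundance shifts are detected with rising power", {
  pow <- vapply(c(1, 1.6), function(mult) {
    hits <- 0
    for (r in 1:60) {
      set.seed(4000 + r)
      pre <- rgamma(10, 2, 40)
      post <- pre * mult * exp(rnorm(10, 0, 0.2))
      hits <- hits + (compare_abundance(pre, post)$p.value < 0.05)
    }
    hits / 60
  }, numeric(1))
  expect_lt(pow[1], 0.2)       # null near nominal
  expect_gt(pow[2], pow[1])    # power grows with effect size
})

test_that("network export is deterministic and handles trivial graphs", {
  tt <- toy_triads(2)
  sh <- data.frame(sample_a = c("D1_don", "D1_don"),
                   sample_b = c("R1_post", "R2_post"),
                   n_shared = c(1L, 0L), stringsAsFactors = FALSE)
  net <- export_network(sh, tt, seed = 5)
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$edges$weight, 1)
  net2 <- export_network(sh, tt, seed = 5)
  expect_identical(net$nodes, net2$nodes)
  # edgeless graph
  sh$n_shared <- 0L
  net0 <- export_network(sh, tt, seed = 5)
  expect_equal(nrow(net0$edges), 0L)
  expect_equal(nrow(net0$nodes), 3L)
  # empty input
  empty <- export_network(sh[0, ], tt, seed = 5)
  expect_equal(nrow(empty$nodes), 0L)
})
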