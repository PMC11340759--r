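test_that("profile filter drops samples below 20 markers, boundary inclusive", {
  ids <- c("a", "b", "c")
  ds <- toy_distance_set(ids, c(0.1, 0.2, 0.3),
                         marker_counts = c(a = 19L, b = 20L, c = 150L))
  f <- filter_profiles(ds)
  expect_setequal(f$sample_ids, c("b", "c"))   # 19 removed, exactly 20 kept
  expect_true(attr(f, "passed"))

  f1 <- filter_profiles(toy_distance_set(ids, c(0.1, 0.2, 0.3),
                                         marker_counts = c(a = 5L, b = 8L,
                                                           c = 30L)))
  expect_false(attr(f1, "passed"))             # < 2 samples remain
})

test_that("marker prevalence filter keeps markers at exactly 50%", {
  P <- cbind(m1 = c(TRUE, TRUE, FALSE, FALSE),   # exactly 50%
             m2 = c(TRUE, FALSE, FALSE, FALSE),  # 25%
             m3 = rep(TRUE, 4))
  expect_setequal(filter_markers(P), c("m1", "m3"))
})

test_that("pair labeling matches the definition on constructed triads", {
  # 1 complete triad: exactly 2 related pairs (pre-post, donor-post)
  tt <- toy_triads(1)
  ds <- toy_distance_set(tt$sample_id, runif(3))
  lp <- label_pairs(tt, ds)
  expect_equal(sum(lp$label == "related"), 2L)
  # donor-pre excluded from both classes
  expect_equal(nrow(lp), 2L)

  # triad whose pre sample is not profiled: only the donor-post related pair
  ds2 <- toy_distance_set(c("D1_don", "R1_post"), 0.3)
  lp2 <- label_pairs(tt, ds2)
  expect_equal(lp2$label, "related")
  expect_setequal(c(lp2$sample_a, lp2$sample_b), c("D1_don", "R1_post"))
})

test_that("pair labeling agrees with brute-force enumeration", {
  set.seed(7)
  for (n in 2:4) for (shared in c(TRUE, FALSE)) {
    tt <- toy_triads(n, shared_donor = shared)
    ids <- tt$sample_id
    ds <- toy_distance_set(ids, runif(choose(length(ids), 2)))
    lp <- label_pairs(tt, ds)
    oracle <- enumerate_pairs(tt, ids)
    key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    got <- setNames(lp$label, key(lp$sample_a, lp$sample_b))
    want <- oracle[oracle$label != "excluded", ]
    expect_setequal(names(got), key(want$a, want$b))
    expect_identical(unname(got[key(want$a, want$b)]), want$label)
  }
  # frozen from the enumeration oracle: 2 disjoint triads over 6 samples
  tt2 <- toy_triads(2)
  lp2 <- label_pairs(tt2, toy_distance_set(tt2$sample_id, runif(15)))
  expect_equal(sum(lp2$label == "related"), 4L)
  expect_equal(sum(lp2$label == "unrelated"), 9L)
})

test_that("percentile thresholds follow linear interpolation", {
  # 100 unrelated distances 0.01..1.00, few related: pct3 rule
  est <- estimate_threshold(list(related = runif(10, 0, 0.005),
                                 unrelated = seq(0.01, 1, by = 0.01)))
  expect_equal(est$rule, "pct3")
  expect_equal(est$threshold, 0.0397)
})

test_that("Youden rule takes the conservative minimum and breaks ties low", {
  related <- seq(0.01, 0.1, length.out = 60)
  unrelated <- seq(0.5, 1, length.out = 80)
  est <- estimate_threshold(list(related = related, unrelated = unrelated))
  pct5 <- unname(quantile(unrelated, 0.05, type = 7))
  # J = 1 anywhere in [0.1, 0.5); smallest achieving candidate is 0.1
  expect_equal(youden_threshold(related, unrelated)$threshold, 0.1)
  expect_equal(est$threshold, min(0.1, pct5))
  expect_equal(est$rule, if (0.1 <= pct5) "youden" else "pct5")

  # identically distributed: no signal, pct5 governs
  set.seed(1)
  x <- rnorm(200, 0.3, 0.05)
  est2 <- estimate_threshold(list(related = x[1:100], unrelated = x[101:200]))
  yj <- youden_threshold(x[1:100], x[101:200])$j
  expect_lt(yj, 0.35)
  expect_equal(est2$rule, "pct5")
  expect_equal(est2$threshold, unname(quantile(x[101:200], 0.05, type = 7)))

  # zero unrelated pairs: not estimable
  est3 <- estimate_threshold(list(related = c(0.1, 0.2),
                                  unrelated = numeric(0)))
  expect_false(est3$estimable)
})

test_that("Youden agrees with an exhaustive midpoint scan", {
  set.seed(33)
  for (rep in 1:25) {
    related <- rnorm(30, 0.1, 0.05)
    unrelated <- rnorm(40, 0.25, 0.08)
    got <- youden_threshold(related, unrelated)
    pts <- sort(unique(c(related, unrelated)))
    mids <- c(pts[1] - 1e-6, (head(pts, -1) + pts[-1]) / 2, pts + 1e-12)
    j <- vapply(mids, function(t)
      mean(related <= t) + mean(unrelated > t) - 1, numeric(1))
    expect_equal(got$j, max(j), tolerance = 1e-12)
    # the returned threshold realizes the maximal classification
    expect_equal(mean(related <= got$threshold) +
                   mean(unrelated > got$threshold) - 1, max(j),
                 tolerance = 1e-12)
  }
})

test_that("sharing boundary is inclusive and monotone in the threshold", {
  expect_true(call_sharing(0, 0))
  expect_true(call_sharing(0.05, 0.05))
  expect_false(call_sharing(0.05 + 1e-9, 0.05))
  set.seed(2)
  d <- runif(200)
  ts <- sort(runif(20))
  n_shared <- vapply(ts, function(t) sum(call_sharing(d, t)), numeric(1))
  expect_true(all(diff(n_shared) >= 0))
})

test_that("origin assignment follows the lowest-distance tie-break", {
  ids <- c("D1_don", "R1_pre", "R1_post")
  t <- 0.05
  # shared only with pre
  ds <- toy_distance_set(ids, c(0.6, 0.6, 0.01))  # (don,pre), (don,post), (pre,post)
  oc <- assign_origin("R1_post", "R1_pre", "D1_don", ds, t)
  expect_equal(oc$origin, "recipient")
  # shared with both, donor closer -> donor
  ds2 <- toy_distance_set(ids, c(0.6, 0.02, 0.04))
  oc2 <- assign_origin("R1_post", "R1_pre", "D1_don", ds2, t)
  expect_equal(oc2$origin, "donor")
  expect_true(oc2$shared_with_pre && oc2$shared_with_donor)
  # shared with both, pre closer -> recipient
  ds3 <- toy_distance_set(ids, c(0.6, 0.04, 0.02))
  expect_equal(assign_origin("R1_post", "R1_pre", "D1_don", ds3, t)$origin,
               "recipient")
  # pre profile lacks the SGB, shared with donor -> novel engraftment
  ds4 <- toy_distance_set(c("D1_don", "R1_post"), 0.02)
  oc4 <- assign_origin("R1_post", "R1_pre", "D1_don", ds4, t)
  expect_equal(oc4$origin, "novel_donor")
  # shared with neither -> retained_unshared
  ds5 <- toy_distance_set(ids, c(0.6, 0.5, 0.4))
  expect_equal(assign_origin("R1_post", "R1_pre", "D1_don", ds5, t)$origin,
               "retained_unshared")
  # present only post-FMT -> de novo flag
  ds6 <- toy_distance_set(c("R1_post", "Z_other"), 0.3)
  oc6 <- assign_origin("R1_post", "R1_pre", "D1_don", ds6, t)
  expect_equal(oc6$origin, "retained_unshared")
  expect_true(oc6$de_novo)
  # absent post
  expect_equal(assign_origin("R1_post", "R1_pre", "D1_don",
                             toy_distance_set(c("D1_don", "R1_pre"), 0.6),
                             t)$origin, "absent")
})

test_that("engraftment matrix encodes donor origins only", {
  oc <- data.frame(sgb_id = c("g1", "g1", "g2", "g2"),
                   subject_id = c("R1", "R2", "R1", "R2"),
                   origin = c("donor", "recipient", "novel_donor", "absent"),
                   stringsAsFactors = FALSE)
  M <- build_engraftment_matrix(oc)
  expect_equal(M["g1", "R1"], 1L)
  expect_equal(M["g1", "R2"], 0L)
  expect_equal(M["g2", "R1"], 1L)
  expect_equal(M["g2", "R2"], 0L)
  oc$origin <- "recipient"
  expect_true(all(build_engraftment_matrix(oc) == 0L))
})

test_that("pct3 rule calibrates held-out false sharing near 3%", {
  set.seed(99)
  n_sgb <- 150
  false_share <- total <- 0
  for (i in seq_len(n_sgb)) {
    unrel <- pmax(rnorm(800, 0.2, 0.06), 0)
    est <- estimate_threshold(list(related = pmax(rnorm(10, 0.01, 0.004), 0),
                                   unrelated = unrel))
    held <- pmax(rnorm(50, 0.2, 0.06), 0)
    false_share <- false_share + sum(held <= est$threshold)
    total <- total + length(held)
  }
  expect_gt(false_share / total, 0.02)
  expect_lt(false_share / total, 0.045)
})

test_that("engraftment error rate rises as distributions merge", {
  err_at <- function(mu_s) {
    b <- simulate_cohort(sim_config(n_triads = 10, n_sgb = 15,
                                    same_strain_dist = c(mu_s, 0.03),
                                    diff_strain_dist = c(0.2, 0.03),
                                    missing_dbp_subjects = 0, seed = 77))
    th <- estimate_thresholds(b$triads, b$distances)
    oc <- call_origins(b$triads, b$distances, th)
    M <- build_engraftment_matrix(oc,
                                  sgb_ids = rownames(b$truth$engraftment),
                                  subjects = colnames(b$truth$engraftment))
    mean(M != b$truth$engraftment)
  }
  e1 <- err_at(0.01); e2 <- err_at(0.12); e3 <- err_at(0.19)
  expect_lte(e1, e2)
  expect_lte(e2, e3)
  expect_lt(e1, 0.02)
  expect_gt(e3, 0.05)
})
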