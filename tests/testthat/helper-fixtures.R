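# Small constructed fixtures shared across test files.

# one donor (D1), one recipient (R1) with pre and post samples
toy_triads <- function(n = 1L, shared_donor = FALSE) {
  rows <- lapply(seq_len(n), function(k) {
    don <- if (shared_donor) "D1_don" else sprintf("D%d_don", k)
    rbind(
      data.frame(sample_id = don, subject_id = sub("_don$", "", don),
                 role = "donor", substudy = "s1", donor_id = "",
                 stringsAsFactors = FALSE),
      data.frame(sample_id = sprintf("R%d_pre", k),
                 subject_id = sprintf("R%d", k), role = "pre",
                 substudy = "s1", donor_id = don, stringsAsFactors = FALSE),
      data.frame(sample_id = sprintf("R%d_post", k),
                 subject_id = sprintf("R%d", k), role = "post",
                 substudy = "s1", donor_id = don, stringsAsFactors = FALSE))
  })
  df <- unique(do.call(rbind, rows))
  rownames(df) <- NULL
  triad_table(df)
}

# symmetric distance matrix from the upper triangle given row-wise
toy_distance_set <- function(ids, upper, sgb_id = "SGB0001",
                             marker_counts = NULL) {
  n <- length(ids)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  D[upper.tri(D)] <- upper
  D <- D + t(D)
  distance_set(sgb_id, D, marker_counts = marker_counts)
}

# brute-force enumeration of the pair classification, independent of
# label_pairs(): related = same-subject pre/post + same-triad donor/post;
# excluded = within-triad donor/pre and same-subject pairs; rest unrelated
enumerate_pairs <- function(tt, ids) {
  tr <- triads(tt)
  subj <- setNames(tt$subject_id, tt$sample_id)
  out <- list()
  for (i in seq_along(ids)) for (j in seq_len(i - 1L)) {
    a <- ids[j]; b <- ids[i]
    lab <- "unrelated"
    for (k in seq_len(nrow(tr))) {
      po <- tr$post_sample[k]; pr <- tr$pre_sample[k]; dn <- tr$donor_sample[k]
      if (setequal(c(a, b), c(pr, po)) || setequal(c(a, b), c(dn, po)))
        lab <- "related"
      else if (setequal(c(a, b), c(dn, pr)) && lab != "related")
        lab <- "excluded"
    }
    if (lab == "unrelated" && subj[a] == subj[b]) lab <- "excluded"
    out[[length(out) + 1L]] <- data.frame(a = a, b = b, label = lab,
                                          stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
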