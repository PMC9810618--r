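mk_records <- function(keys, vaf, patient = "P1", timepoint = "pre",
                       depth = 100L) {
  parts <- strsplit(keys, ":")
  data.frame(
    patient = patient, timepoint = timepoint, gene = "G",
    chrom = vapply(parts, `[`, "", 1),
    pos = as.integer(vapply(parts, `[`, "", 2)),
    ref = vapply(parts, `[`, "", 3),
    alt = vapply(parts, `[`, "", 4),
    alt_reads = as.integer(round(vaf * depth)),
    depth = depth, vaf = vaf,
    nonsyn = TRUE, neoantigen = FALSE,
    stringsAsFactors = FALSE
  )
}

test_that("purity adjustment is the capped ratio, monotone, identity at purity 1", {
  expect_equal(adjust_vaf(0.25, 0.5), 0.5)
  expect_equal(adjust_vaf(0.4, 1.0), 0.4)
  expect_equal(adjust_vaf(0.8, 0.5), 1.0)
  expect_equal(adjust_vaf(0.25, 0.5, mode = "ccf"), 1.0)
  expect_equal(adjust_vaf(0.1, 0.8, mode = "ccf"), 0.25)
  v <- seq(0, 1, by = 0.05)
  a <- adjust_vaf(v, 0.4)
  expect_true(all(diff(a) >= 0))
  expect_true(all(a >= 0 & a <= 1))
  expect_error(adjust_vaf(0.2, 0), "purity")
})

test_that("call filters keep the VAF >= 0.02 boundary and log removals", {
  rec <- mk_records(c("1:100:A:T", "1:200:C:G", "1:300:G:A"),
                    vaf = c(0.019, 0.02, 0.30))
  out <- apply_call_filters(rec, quiet = TRUE)
  expect_equal(out$vaf, c(0.02, 0.30))
  expect_equal(attr(out, "n_removed"), 1L)
  # depth and alt-read thresholds
  rec2 <- mk_records("1:100:A:T", vaf = 0.3, depth = 5L)
  expect_equal(nrow(apply_call_filters(rec2, quiet = TRUE)), 0L)
  expect_equal(nrow(apply_call_filters(rec[0, ], quiet = TRUE)), 0L)
  expect_message(apply_call_filters(rec), "removed 1 of 3")
})

test_that("fate classes follow presence and the sign of adjusted VAF change", {
  pre <- mk_records(c("1:1:A:T", "1:2:A:T", "1:3:A:T", "1:4:A:T"),
                    vaf = c(0.20, 0.30, 0.30, 0.10))
  post <- mk_records(c("1:2:A:T", "1:3:A:T", "1:4:A:T", "1:5:A:T"),
                     vaf = c(0.40, 0.30, 0.05, 0.25), timepoint = "post")
  f <- classify_fates(pre, post, purity_pre = 1, purity_post = 1)
  fate <- setNames(as.character(f$fate), f$key)
  expect_equal(fate[["1:1:A:T"]], "lost")
  expect_equal(fate[["1:2:A:T"]], "increase")
  expect_equal(fate[["1:3:A:T"]], "stable")
  expect_equal(fate[["1:4:A:T"]], "decrease")
  expect_equal(fate[["1:5:A:T"]], "gain")
  # purity correction flips an apparent increase
  f2 <- classify_fates(pre, post, purity_pre = 0.4, purity_post = 1)
  fate2 <- setNames(as.character(f2$fate), f2$key)
  expect_equal(fate2[["1:2:A:T"]], "decrease")  # 0.30/0.4 = 0.75 > 0.40
  # tie tolerance turns small changes into stable (delta here is +0.10)
  f3 <- classify_fates(pre, post, 1, 1, tie_tol = 0.05)
  expect_equal(as.character(f3$fate[f3$key == "1:2:A:T"]), "increase")
  f4 <- classify_fates(pre, post, 1, 1, tie_tol = 0.15)
  expect_equal(as.character(f4$fate[f4$key == "1:2:A:T"]), "stable")
  expect_error(classify_fates(rbind(pre, pre[1, ]), post, 1, 1), "duplicate")
})

test_that("lost fraction is lost over pre-present, with explicit undefined case", {
  pre <- mk_records(sprintf("1:%d:A:T", 1:10), vaf = rep(0.3, 10))
  post <- mk_records(sprintf("1:%d:A:T", 4:10), vaf = rep(0.3, 7),
                     timepoint = "post")
  f <- classify_fates(pre, post, 1, 1)
  expect_equal(lost_fraction(f), 0.3)
  f_all_lost <- classify_fates(pre, post[0, ], 1, 1)
  expect_equal(lost_fraction(f_all_lost), 1.0)
  f_gain_only <- classify_fates(pre[0, ], post, 1, 1)
  expect_error(lost_fraction(f_gain_only), "undefined")
})

test_that("burden is count per megabase with TNB below TMB when neoantigens are nonsynonymous", {
  rec <- mk_records(sprintf("1:%d:A:T", 1:70), vaf = rep(0.3, 70))
  rec$neoantigen <- c(rep(TRUE, 10), rep(FALSE, 60))
  b <- compute_burden(rec, exome_mb = 35)
  expect_equal(b$tmb, 2.0)
  expect_equal(b$tnb, 10 / 35)
  expect_lte(b$tnb, b$tmb)
  b0 <- compute_burden(rec[0, ], exome_mb = 35)
  expect_equal(b0$tmb, 0)
  expect_equal(b0$tnb, 0)
  expect_error(compute_burden(rec, exome_mb = 0), "exome_mb")
})

test_that("dilution at m = 0 is an exact identity and deterministic given seed", {
  rec <- mk_records(sprintf("1:%d:A:T", 1:50),
                    vaf = runif(50, 0.02, 0.5))
  same <- purity_balance_dilution(rec, purity = 0.6, target_purity = 0.6,
                                  seed = 5)
  expect_identical(same$records, rec)
  expect_equal(same$m, 0)
  d1 <- purity_balance_dilution(rec, 0.6, 0.3, seed = 5)
  d2 <- purity_balance_dilution(rec, 0.6, 0.3, seed = 5)
  expect_identical(d1$records, d2$records)
  expect_equal(d1$m, 0.5)
  expect_error(purity_balance_dilution(rec, 0.4, 0.6, seed = 1), "dilution only")
})

test_that("subclone consistency compares signs, with absence coded as zero", {
  cl_up <- subclone_cluster("C1", 0.4, 0.8, "1:1:A:T")
  cl_down <- subclone_cluster("C2", 0.8, 0.2, "1:1:A:T")
  cl_gone <- subclone_cluster("C3", 0.8, 0.0, "1:1:A:T")
  up <- list(key = "1:1:A:T", adj_vaf_pre = 0.2, adj_vaf_post = 0.5)
  expect_true(clonal_consistency(up, cl_up))
  expect_false(clonal_consistency(up, cl_down))
  lost <- list(key = "1:1:A:T", adj_vaf_pre = 0.4, adj_vaf_post = NA_real_)
  expect_true(clonal_consistency(lost, cl_gone))
  expect_false(clonal_consistency(lost, cl_up))
  flat <- list(key = "1:1:A:T", adj_vaf_pre = 0.4, adj_vaf_post = 0.4)
  cl_flat <- subclone_cluster("C4", 0.5, 0.5, "1:1:A:T")
  expect_true(clonal_consistency(flat, cl_flat))
  # tolerance makes near-zero changes count as zero
  near <- list(key = "1:1:A:T", adj_vaf_pre = 0.40, adj_vaf_post = 0.41)
  expect_false(clonal_consistency(near, cl_flat))
  expect_true(clonal_consistency(near, cl_flat, tol = 0.05))
  expect_error(clonal_consistency(up, subclone_cluster("C5", 1, 1, "2:2:C:G")),
               "not assigned")
})

test_that("biomarker contingency reproduces quoted counts and handles degenerate margins", {
  # 4/5 responders mutated vs 0/14 non-responders mutated
  mutated <- c(rep(TRUE, 4), FALSE, rep(FALSE, 14))
  response <- c(rep(TRUE, 5), rep(FALSE, 14))
  bt <- biomarker_contingency(mutated, response)
  expect_equal(unname(bt$table), matrix(c(4, 1, 0, 14), nrow = 2, byrow = TRUE))
  expect_equal(bt$odds_ratio, Inf)
  expect_equal(bt$p_value, fisher.test(bt$table)$p.value)
  expect_false(bt$adjusted)
  # no association
  none <- biomarker_contingency(c(TRUE, TRUE, FALSE, FALSE),
                                c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(none$p_value, 1)
  expect_error(biomarker_contingency(c(TRUE, FALSE), c(TRUE, FALSE, TRUE)),
               "lengths differ")
})
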