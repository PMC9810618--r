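small_cfg <- function(...) {
  cohort_config(n_patients = 6, n_mutations = 30, repertoire_size = 100,
                n_genes = 30, tcr_reads = 1e4, ...)
}

test_that("identical config and seed give identical cohorts; truth respects frac_responders", {
  a <- generate_cohort(small_cfg(seed = 7))
  b <- generate_cohort(small_cfg(seed = 7))
  expect_identical(a$patients, b$patients)
  expect_identical(a$truth, b$truth)
  expect_identical(a$mutations, b$mutations)
  expect_identical(a$expression, b$expression)
  expect_identical(lapply(a$repertoires, lapply, as.data.frame),
                   lapply(b$repertoires, lapply, as.data.frame))
  c_ <- generate_cohort(small_cfg(seed = 8))
  expect_false(identical(a$patients, c_$patients))

  none <- generate_cohort(small_cfg(frac_responders = 0, seed = 3),
                          modules = "mutations")
  expect_false(any(none$truth$responder))

  expect_error(cohort_config(frac_responders = 1.5), "frac_responders",
               class = "neoresponse_config_error")
  expect_error(cohort_config(purity_range_pre = c(0, 0.5)),
               "purity_range_pre", class = "neoresponse_config_error")
  expect_error(cohort_config(repertoire_size = 20), "repertoire_size",
               class = "neoresponse_config_error")
})

test_that("written cohort tables are byte-identical across runs", {
  d1 <- file.path(tempdir(), "coh1"); d2 <- file.path(tempdir(), "coh2")
  write_cohort(generate_cohort(small_cfg(seed = 5)), d1)
  write_cohort(generate_cohort(small_cfg(seed = 5)), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("mutation pairs follow the prevalence x purity / 2 binomial model", {
  clusters <- list(
    subclone_cluster("C1", 1, 1, sprintf("m%03d", 1:500)),
    subclone_cluster("C2", 0.6, 0, sprintf("m%03d", 501:540))
  )
  pair <- generate_mutation_pair("P1", clusters, purity_pre = 1,
                                 purity_post = 1, depth_mean = 100, seed = 11)
  # eradicated subclone absent post-treatment
  gone <- pair$mutations$key[pair$mutations$cluster == "C2"]
  post_keys <- paste(pair$post$chrom, pair$post$pos, pair$post$ref,
                     pair$post$alt, sep = ":")
  expect_false(any(post_keys %in% gone))
  # clonal cluster at purity 1: expected VAF 0.5 within 3 SE at depth 100
  keep <- paste(pair$pre$chrom, pair$pre$pos, pair$pre$ref, pair$pre$alt,
                sep = ":") %in% pair$mutations$key[pair$mutations$cluster == "C1"]
  vafs <- pair$pre$vaf[keep]
  se <- sqrt(0.25 / 100) / sqrt(length(vafs))
  expect_lt(abs(mean(vafs) - 0.5), 3 * se)
  expect_true(all(pair$pre$alt_reads <= pair$pre$depth))
  expect_error(
    generate_mutation_pair("P1", clusters, 1, 1, depth_mean = 0, seed = 1),
    "depth_mean"
  )
})

test_that("static tumors produce gain/lost only at the filter-noise level", {
  clusters <- list(subclone_cluster("C1", 0.9, 0.9, sprintf("m%03d", 1:200)),
                   subclone_cluster("C2", 0.4, 0.4, sprintf("m%03d", 201:400)))
  frac <- vapply(1:5, function(s) {
    pair <- generate_mutation_pair("P1", clusters, 0.6, 0.6,
                                   depth_mean = 200, seed = s)
    pre <- apply_call_filters(pair$pre, quiet = TRUE)
    post <- apply_call_filters(pair$post, quiet = TRUE)
    f <- classify_fates(pre, post, 0.6, 0.6)
    mean(f$fate %in% c("gain", "lost"))
  }, numeric(1))
  expect_lt(mean(frac), 0.05)
})

test_that("repertoire pairs: deterministic core, expansion raises CE, heavy tails occupy the hyperexpanded class", {
  base <- generate_repertoire_pair("P1", 100, 1, expansion_factor = 1,
                                   seed = 4)
  expect_identical(as.data.frame(base$pre), as.data.frame(base$post))
  expect_equal(sum(base$pre$frequency), 1, tolerance = 1e-9)

  exp2 <- generate_repertoire_pair("P1", 100, 1, expansion_factor = 2,
                                   seed = 4)
  expect_gt(ce_score(exp2$pre, exp2$post), 0)

  heavy <- generate_repertoire_pair("P1", 50, 3, expansion_factor = 1,
                                    seed = 4)
  expect_gt(max(heavy$pre$frequency), 0.01)
  cls <- size_class_partition(heavy$pre)
  expect_gt(cls$counts[["hyperexpanded"]], 0)

  expect_error(generate_repertoire_pair("P1", 20, 1, 1, seed = 1),
               "repertoire_size")
})

test_that("turnover drags non-expanded repertoires' top clones down (negative CE)", {
  ce <- vapply(1:10, function(s) {
    rp <- generate_repertoire_pair("P1", 500, 1, expansion_factor = 1,
                                   seed = s, turnover = 0.05, n_reads = 1e5)
    ce_score(rp$pre, rp$post)
  }, numeric(1))
  expect_true(all(ce < 0))
})

test_that("expression generator shifts signature genes by the configured log2 effect", {
  samples <- data.frame(
    sample = sprintf("S%02d", 1:24),
    responder = rep(c(TRUE, FALSE), each = 12),
    timepoint = rep(c("pre", "post"), 12),
    stringsAsFactors = FALSE
  )
  sets <- list(sig = c("GZMA", "PRF1", "IFNG", "CD8A", "GZMB"))
  m0 <- generate_expression(50, samples, sets, signature_shift = 0, seed = 2)
  expect_true(all(m0 >= 0))
  s0 <- score_gene_set(m0, sets$sig)
  resp_post <- samples$responder & samples$timepoint == "post"
  base_mean <- mean(s0[!resp_post])
  se0 <- sd(s0) * sqrt(1 / sum(resp_post) + 1 / sum(!resp_post))
  expect_lt(abs(mean(s0[resp_post]) - base_mean), 3 * se0)

  m1 <- generate_expression(50, samples, sets, signature_shift = 1, seed = 2)
  s1 <- score_gene_set(m1, sets$sig)
  diff1 <- mean(s1[resp_post]) - mean(s1[!resp_post])
  se1 <- sd(s1[!resp_post]) * sqrt(1 / sum(resp_post) + 1 / sum(!resp_post))
  expect_lt(abs(diff1 - 1), 3 * se1 + 0.05)

  expect_error(generate_expression(3, samples, sets, 1, 1),
               class = "neoresponse_config_error")
})

test_that("per-patient substreams make cohort subsets reproducible", {
  big <- generate_cohort(small_cfg(seed = 9))
  small <- generate_cohort(small_cfg(seed = 9))
  # same patient id under the same cohort seed gives the same repertoire
  expect_identical(as.data.frame(big$repertoires[["P003"]]$pre),
                   as.data.frame(small$repertoires[["P003"]]$pre))
  expect_identical(
    big$mutations$pre[big$mutations$pre$patient == "P002", ],
    small$mutations$pre[small$mutations$pre$patient == "P002", ]
  )
})
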