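test_that("normalization recomputes frequencies, drops zeros, and is idempotent", {
  tab <- data.frame(
    cdr3aa = c("CASSA", "CASSB", "CASSC"),
    v_segment = "TRBV9", j_segment = "TRBJ1-1",
    count = c(3, 1, 0),
    stringsAsFactors = FALSE
  )
  out <- normalize_clonotypes(tab)
  expect_equal(nrow(out), 2)
  expect_equal(out$frequency, c(0.75, 0.25))
  expect_equal(sum(out$frequency), 1, tolerance = 1e-12)
  expect_identical(normalize_clonotypes(out)$frequency, out$frequency)
  # deterministic tie-break on equal frequency: lexicographic key
  tie <- normalize_clonotypes(data.frame(
    cdr3aa = c("CASSZ", "CASSA"), v_segment = "TRBV9",
    j_segment = "TRBJ1-1", count = c(5, 5), stringsAsFactors = FALSE
  ))
  expect_equal(tie$cdr3aa, c("CASSA", "CASSZ"))
  expect_error(normalize_clonotypes(transform(tab, count = 0)), "no positive")
  expect_error(normalize_clonotypes(transform(tab, count = c(-1, 1, 1))),
               "negative count")
  expect_error(normalize_clonotypes(tab[, -1]), "missing column")
})

test_that("CE score matches hand-enumerated toys in both top-k modes", {
  identical_tab <- toy_clonotypes(c(A = 0.7, B = 0.3))
  expect_equal(ce_score(identical_tab, identical_tab), 0)
  expect_equal(ce_score(identical_tab, identical_tab, mode = "per-sample"), 0)

  pre <- toy_clonotypes(c(A = 0.9, B = 0.1))
  post <- toy_clonotypes(c(A = 0.6, B = 0.4))
  expect_equal(ce_score(pre, post, k = 20), 0)               # (.6-.9)+(.4-.1)
  expect_equal(ce_score(pre, post, k = 20, mode = "per-sample"), 0)

  pre3 <- toy_clonotypes(c(A = 0.5, B = 0.3, C = 0.2))
  post3 <- toy_clonotypes(c(A = 0.8, B = 0.15, C = 0.05))
  expect_equal(ce_score(pre3, post3, k = 2), 0.15)           # set {A, B}
  expect_error(ce_score(pre3, post3, k = 0), "k")
})

test_that("CE score is antisymmetric and bounded on random repertoire pairs", {
  set.seed(23)
  for (i in 1:20) {
    n1 <- sample(5:40, 1); n2 <- sample(5:40, 1)
    shared <- sprintf("S%02d", 1:4)
    t1 <- toy_clonotypes(setNames(runif(n1), c(shared, sprintf("A%02d", 1:(n1 - 4)))))
    t2 <- toy_clonotypes(setNames(runif(n2), c(shared, sprintf("B%02d", 1:(n2 - 4)))))
    for (mode in c("pooled", "per-sample")) {
      s <- ce_score(t1, t2, k = 10, mode = mode)
      expect_lte(abs(s), 1)
      expect_equal(ce_score(t2, t1, k = 10, mode = mode), -s, tolerance = 1e-12)
    }
  }
})

test_that("size classes partition clonotypes at the resolved boundaries", {
  tab <- toy_clonotypes(c(H = 0.958550, L = 0.01, L2 = 0.002, M = 0.0005,
                          M2 = 0.001, S = 0.0001, S2 = 0.00005,
                          H2 = 0.0278))
  part <- size_class_partition(tab)
  cls <- setNames(as.character(part$assignment), tab$cdr3aa)
  expect_equal(cls[["H"]], "hyperexpanded")   # > 0.01
  expect_equal(cls[["H2"]], "hyperexpanded")
  expect_equal(cls[["L"]], "large")           # boundary 0.01 inclusive
  expect_equal(cls[["L2"]], "large")
  expect_equal(cls[["M"]], "medium")          # (1e-4, 1e-3]
  expect_equal(cls[["M2"]], "medium")         # boundary 1e-3 inclusive
  expect_equal(cls[["S"]], "small")           # boundary 1e-4 inclusive
  expect_equal(cls[["S2"]], "small")
  expect_equal(sum(part$mass), 1, tolerance = 1e-9)
  expect_false(anyNA(part$assignment))
  expect_equal(sum(part$counts), nrow(tab))
})

test_that("diversity metrics reproduce closed forms", {
  uniform <- toy_clonotypes(setNames(rep(0.01, 100), sprintf("U%03d", 1:100)))
  d <- diversity_metrics(uniform)
  expect_equal(d$richness, 100)
  expect_equal(d$evenness, 1.0, tolerance = 1e-12)
  expect_equal(d$d50, 50L)
  expect_equal(d$d50_pct, 50)

  single <- toy_clonotypes(c(A = 1))
  ds <- diversity_metrics(single)
  expect_equal(ds$shannon, 0)
  expect_equal(ds$richness, 1)
  expect_equal(ds$evenness, 0)
  expect_equal(ds$d50, 1L)

  skew <- toy_clonotypes(c(A = 0.5, B = 0.25, C = 0.25))
  dk <- diversity_metrics(skew)
  expect_equal(dk$shannon, 1.5 * log(2), tolerance = 1e-12)  # 1.0397 nats
  expect_equal(dk$d50, 1L)
})

test_that("V/J usage sums clonotype frequencies per segment", {
  tab <- normalize_clonotypes(data.frame(
    cdr3aa = c("CASSA", "CASSB", "CASSC", "CASSD"),
    v_segment = c("TRBV20-1", "TRBV20-1", "TRBV9", "TRBV9"),
    j_segment = c("TRBJ2-5", "TRBJ1-1", "TRBJ2-5", "TRBJ1-1"),
    count = c(30, 20, 30, 20),
    stringsAsFactors = FALSE
  ))
  u <- vj_usage(tab)
  expect_equal(sum(u$v), 1, tolerance = 1e-9)
  expect_equal(sum(u$j), 1, tolerance = 1e-9)
  expect_equal(unname(u$v["TRBV20-1"]), 0.5)
  expect_equal(unname(u$j["TRBJ2-5"]), 0.6)
  mono <- toy_clonotypes(c(A = 0.4, B = 0.6))
  expect_equal(unname(vj_usage(mono)$v), 1)
})

test_that("pairwise overlap counts shared keys symmetrically with richness diagonal", {
  a <- toy_clonotypes(setNames(runif(30) + 0.1, sprintf("A%02d", 1:30)))
  b <- toy_clonotypes(setNames(runif(30) + 0.1, sprintf("B%02d", 1:30)))
  m <- pairwise_overlap(list(x = a, y = b, z = a))
  expect_equal(unname(diag(m)), c(30L, 30L, 30L))
  expect_equal(m["x", "y"], 0L)
  expect_equal(m["x", "z"], 30L)
  expect_true(isSymmetric(m))
  expect_error(pairwise_overlap(list(a)), "at least 2")
})
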