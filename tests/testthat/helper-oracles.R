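# Independent brute-force oracles used to cross-check the package's
# statistical routes. These deliberately re-derive each quantity from first
# principles (enumeration / direct definitions) and never call the code
# paths they validate.

# Two-sided Fisher exact p by hypergeometric enumeration over all tables
# with the observed margins.
fisher_enum_p <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1]); n <- r1 + r2
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- choose(r1, support) * choose(r2, c1 - support) / choose(n, c1)
  p_obs <- probs[support == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Exact two-sided signed-rank p by enumeration of all 2^n sign assignments
# (requires no zero differences and no tied absolute values).
signed_rank_enum_p <- function(d) {
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  p <- 2 * min(mean(v_all <= v_obs), mean(v_all >= v_obs))
  min(1, p)
}

# Exact two-sided Spearman p by enumeration of all rank permutations
# (n <= 8, no ties), using the S = sum of squared rank differences
# statistic that the exact test is based on.
spearman_enum <- function(x, y) {
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  s_obs <- sum((rx - ry)^2)
  rho <- 1 - 6 * s_obs / (n * (n^2 - 1))
  perms <- permutations_of(n)
  s_all <- apply(perms, 1, function(p) sum((rx - ry[p])^2))
  p <- if (rho > 0) 2 * mean(s_all <= s_obs) else 2 * mean(s_all >= s_obs)
  list(rho = rho, p = min(1, p))
}

permutations_of <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- permutations_of(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

# Per-mutation reclassification oracle for fate calls: walks the union of
# keys one mutation at a time with plain if/else logic.
fate_oracle <- function(pre, post, purity_pre, purity_post, tie_tol = 0) {
  key_pre <- paste(pre$chrom, pre$pos, pre$ref, pre$alt, sep = ":")
  key_post <- paste(post$chrom, post$pos, post$ref, post$alt, sep = ":")
  keys <- union(key_pre, key_post)
  vapply(keys, function(k) {
    in_pre <- k %in% key_pre
    in_post <- k %in% key_post
    if (in_pre && !in_post) return("lost")
    if (!in_pre && in_post) return("gain")
    a <- min(1, pre$vaf[key_pre == k] / purity_pre)
    b <- min(1, post$vaf[key_post == k] / purity_post)
    if (abs(b - a) <= tie_tol) "stable" else if (b > a) "increase" else "decrease"
  }, character(1))
}

# Random MAF-like mutation table generator for oracle tests.
random_mutation_table <- function(n, patient = "PX", timepoint = "pre",
                                  pool_size = 60) {
  idx <- sample.int(pool_size, n)
  data.frame(
    patient = rep(patient, n), timepoint = rep(timepoint, n),
    gene = sprintf("G%02d", idx %% 20 + 1),
    chrom = as.character(idx %% 22 + 1),
    pos = idx * 1000L,
    ref = rep("A", n), alt = rep("T", n),
    alt_reads = pmin(sample(1:80, n, replace = TRUE), 100L),
    depth = rep(100L, n),
    vaf = rep(NA_real_, n),
    nonsyn = sample(c(TRUE, FALSE), n, replace = TRUE),
    neoantigen = rep(FALSE, n),
    stringsAsFactors = FALSE
  ) -> tab
  tab$vaf <- tab$alt_reads / tab$depth
  tab
}

# Minimal clonotype table from named frequencies (counts scaled by 1e6).
toy_clonotypes <- function(freqs) {
  normalize_clonotypes(data.frame(
    cdr3aa = names(freqs),
    v_segment = "TRBV20-1",
    j_segment = "TRBJ2-5",
    count = round(freqs * 1e6),
    stringsAsFactors = FALSE
  ))
}
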