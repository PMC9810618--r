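# TCR repertoire statistics: clonotype-table ingestion, clone-expansion
# score, frequency size classes, diversity indices, V/J usage, overlap.

clonotype_cols <- c("cdr3aa", "v_segment", "j_segment", "count", "frequency")

clonotype_key <- function(tab) {
  paste(tab$cdr3aa, tab$v_segment, tab$j_segment, sep = "|")
}

#' Normalize a clonotype table
#'
#' Recomputes frequencies as count / total, drops zero-count rows, and
#' orders rows by descending frequency with a deterministic lexicographic
#' tie-break on the clonotype key (CDR3aa, V, J). Idempotent.
#'
#' @param tab data frame with columns `cdr3aa`, `v_segment`, `j_segment`,
#'   `count`, and optionally `frequency` (recomputed regardless).
#' @return a `clonotype_table` data frame whose frequencies sum to 1.
#' @export
normalize_clonotypes <- function(tab) {
  missing <- setdiff(setdiff(clonotype_cols, "frequency"), names(tab))
  if (length(missing)) {
    stopf("clonotype table is missing column(s): %s",
          paste(missing, collapse = ", "))
  }
  if (any(tab$count < 0)) {
    stopf("negative count in clonotype table at row %d",
          which(tab$count < 0)[1])
  }
  tab <- tab[tab$count > 0, , drop = FALSE]
  total <- sum(as.numeric(tab$count))
  if (nrow(tab) == 0 || total == 0) {
    stopf("clonotype table has no positive counts")
  }
  key <- clonotype_key(tab)
  if (anyDuplicated(key)) {
    stopf("duplicate clonotype key: %s", key[duplicated(key)][1])
  }
  tab$frequency <- as.numeric(tab$count) / total
  ord <- order(-tab$frequency, clonotype_key(tab), method = "radix")
  out <- tab[ord, c(clonotype_cols, setdiff(names(tab), clonotype_cols)),
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("clonotype_table", "data.frame")
  out
}

#' Read a VDJtools-style clonotype table
#'
#' Reads a tab-separated clonotype table (columns `cdr3aa`, `v_segment`,
#' `j_segment`, `count`, `frequency`) and normalizes it with
#' [normalize_clonotypes()].
#'
#' @param path file path.
#' @return a `clonotype_table` data frame.
#' @export
read_clonotypes <- function(path) {
  if (!file.exists(path)) stopf("clonotype file not found: %s", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  normalize_clonotypes(tab)
}

check_normalized <- function(tab, name = "table") {
  if (!inherits(tab, "clonotype_table")) {
    stopf("`%s` must be a clonotype_table (see normalize_clonotypes())", name)
  }
  if (abs(sum(tab$frequency) - 1) > 1e-9) {
    stopf("`%s` frequencies do not sum to 1; re-run normalize_clonotypes()",
          name)
  }
  invisible(tab)
}

#' Clone-expansion (CE) score of a pre/post repertoire pair
#'
#' Summed change in frequency of the top-k (default 20) clonotypes from
#' pre- to post-treatment. A positive score indicates expansion of the
#' dominant clones after therapy.
#'
#' Two readings of "top-k" are supported. `"pooled"` (default) fixes one
#' clone set — the k clonotypes most frequent by the mean of their pre and
#' post frequencies — and sums `freq_post - freq_pre` over it, with a
#' clonotype absent from one sample contributing 0 on that side; this makes
#' the score antisymmetric (swapping pre and post negates it) and bounded in
#' \[-1, 1\]. `"per-sample"` subtracts the summed frequency of pre's own
#' top-k from that of post's own top-k.
#'
#' @param pre,post normalized `clonotype_table`s of the same patient.
#' @param k number of top clonotypes; default 20.
#' @param mode `"pooled"` or `"per-sample"`.
#' @return a single numeric score in \[-1, 1\].
#' @export
ce_score <- function(pre, post, k = 20, mode = c("pooled", "per-sample")) {
  mode <- match.arg(mode)
  check_normalized(pre, "pre")
  check_normalized(post, "post")
  if (!is.numeric(k) || length(k) != 1 || k < 1) {
    stopf("`k` must be a single number >= 1")
  }
  if (mode == "per-sample") {
    top_mass <- function(tab) sum(utils::head(tab$frequency, k))
    return(top_mass(post) - top_mass(pre))
  }
  keys <- union(clonotype_key(pre), clonotype_key(post))
  f_pre <- stats::setNames(rep(0, length(keys)), keys)
  f_post <- f_pre
  f_pre[clonotype_key(pre)] <- pre$frequency
  f_post[clonotype_key(post)] <- post$frequency
  pooled <- (f_pre + f_post) / 2
  ord <- order(-pooled, keys, method = "radix")
  top <- ord[seq_len(min(k, length(keys)))]
  sum(f_post[top] - f_pre[top])
}

#' Partition clonotypes into frequency size classes
#'
#' The four canonical clonotype size classes by frequency:
#' small (<= 1e-4), medium (> 1e-4 and <= 1e-3), large (> 1e-3 and <= 1e-2),
#' and hyperexpanded (> 1e-2). Every clonotype falls in exactly one class.
#'
#' @param tab a normalized `clonotype_table`.
#' @return list with `assignment` (factor per clonotype, ordered
#'   small < medium < large < hyperexpanded), `counts` (clonotypes per
#'   class) and `mass` (summed frequency per class; sums to 1).
#' @export
size_class_partition <- function(tab) {
  check_normalized(tab)
  breaks <- c(-Inf, 1e-4, 1e-3, 1e-2, Inf)
  labels <- c("small", "medium", "large", "hyperexpanded")
  cls <- cut(tab$frequency, breaks = breaks, labels = labels, right = TRUE)
  list(
    assignment = cls,
    counts = table(cls),
    mass = vapply(split(tab$frequency, cls), sum, numeric(1))
  )
}

#' Repertoire diversity metrics
#'
#' Richness (distinct clonotypes), Shannon entropy `H = -sum(f log f)` in
#' nats, Pielou evenness `H / log(richness)` (defined as 0 for a single
#' clone), and D50 — the smallest number of top clonotypes whose cumulative
#' frequency reaches 0.5, also expressed as a percentage of richness.
#'
#' @param tab a normalized `clonotype_table`.
#' @return data frame with `richness`, `shannon`, `evenness`, `d50`,
#'   `d50_pct`.
#' @export
diversity_metrics <- function(tab) {
  check_normalized(tab)
  f <- tab$frequency
  richness <- nrow(tab)
  shannon <- -sum(f * log(f))
  evenness <- if (richness > 1) shannon / log(richness) else 0
  d50 <- which(cumsum(sort(f, decreasing = TRUE)) >= 0.5)[1]
  data.frame(
    richness = richness,
    shannon = shannon,
    evenness = evenness,
    d50 = as.integer(d50),
    d50_pct = 100 * d50 / richness
  )
}

#' V- and J-segment usage
#'
#' Summed clonotype frequency per V segment and per J segment. Each usage
#' vector sums to 1 for a normalized table.
#'
#' @param tab a normalized `clonotype_table`.
#' @return list with named numeric vectors `v` and `j`, each sorted
#'   decreasing.
#' @export
vj_usage <- function(tab) {
  check_normalized(tab)
  usage <- function(seg) {
    u <- vapply(split(tab$frequency, seg), sum, numeric(1))
    u[order(-u, names(u), method = "radix")]
  }
  list(v = usage(tab$v_segment), j = usage(tab$j_segment))
}

#' Pairwise shared-clonotype counts
#'
#' Symmetric matrix of the number of clonotype keys (CDR3aa, V, J) shared
#' between every pair of repertoires; the diagonal is each repertoire's
#' richness.
#'
#' @param tables named list of normalized `clonotype_table`s (length >= 2).
#' @return integer matrix with the list names as dimnames.
#' @export
pairwise_overlap <- function(tables) {
  if (length(tables) < 2) stopf("need at least 2 clonotype tables")
  for (i in seq_along(tables)) check_normalized(tables[[i]])
  keys <- lapply(tables, clonotype_key)
  n <- length(tables)
  nm <- names(tables)
  if (is.null(nm)) nm <- paste0("S", seq_len(n))
  m <- matrix(0L, n, n, dimnames = list(nm, nm))
  for (i in seq_len(n)) {
    for (j in i:n) {
      m[i, j] <- m[j, i] <- length(intersect(keys[[i]], keys[[j]]))
    }
  }
  m
}
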