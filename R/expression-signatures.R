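# Immune gene-set signature scoring and group contrasts.

#' Default immune signature gene sets
#'
#' Small curated defaults for the immune axes commonly contrasted in
#' immunotherapy cohorts: cytolytic activity, interferon-gamma response,
#' T-cell exhaustion, and CD8 effector. These are editable conveniences,
#' not a published panel; supply your own sets (e.g. via
#' [read_gene_sets()]) for real analyses.
#'
#' @return named list of character vectors of gene symbols.
#' @export
default_immune_signatures <- function() {
  list(
    cytolytic = c("GZMA", "PRF1"),
    ifn_gamma = c("IFNG", "STAT1", "IDO1", "CXCL9", "CXCL10", "HLA-DRA"),
    t_exhaustion = c("PDCD1", "CTLA4", "LAG3", "HAVCR2", "TIGIT"),
    cd8_effector = c("CD8A", "CD8B", "GZMB", "EOMES", "TBX21")
  )
}

#' Read gene sets from a YAML file
#'
#' Expects a mapping of set name to a list of gene symbols.
#'
#' @param path YAML file path.
#' @return named list of character vectors.
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) stopf("gene-set file not found: %s", path)
  sets <- yaml::read_yaml(path)
  sets <- lapply(sets, as.character)
  if (is.null(names(sets)) || any(names(sets) == "")) {
    stopf("every gene set must be named")
  }
  for (nm in names(sets)) {
    if (length(sets[[nm]]) == 0) stopf("gene set '%s' is empty", nm)
    if (anyDuplicated(sets[[nm]])) stopf("gene set '%s' has duplicates", nm)
  }
  sets
}

#' Score one gene set across samples
#'
#' The signature score of a sample is the unweighted mean of
#' `log2(TPM + 1)` over the set genes present in the matrix — a simple,
#' transparent stand-in for weighted published scores. Optional per-gene
#' `weights` (named, matching set genes) turn it into a weighted mean.
#' Genes absent from the matrix are dropped with a warning; a set with no
#' gene in the matrix is an error.
#'
#' @param expr numeric gene-by-sample matrix of TPM values (rownames =
#'   gene symbols).
#' @param genes character vector of set genes.
#' @param name set label used in messages and output.
#' @param weights optional named numeric weights for the set genes.
#' @return named numeric vector of scores, one per sample (column).
#' @export
score_gene_set <- function(expr, genes, name = "signature", weights = NULL) {
  if (!is.matrix(expr) || is.null(rownames(expr))) {
    stopf("`expr` must be a matrix with gene rownames")
  }
  if (any(expr < 0)) stopf("`expr` must be non-negative TPM values")
  present <- intersect(genes, rownames(expr))
  if (length(present) == 0) {
    stopf("no gene of set '%s' is present in the expression matrix", name)
  }
  if (length(present) < length(genes)) {
    warning(sprintf("set '%s': %d of %d genes absent from the matrix",
                    name, length(genes) - length(present), length(genes)))
  }
  logx <- log2(expr[present, , drop = FALSE] + 1)
  if (is.null(weights)) {
    scores <- colMeans(logx)
  } else {
    w <- weights[present]
    if (anyNA(w)) stopf("`weights` must cover every present set gene")
    scores <- as.numeric(crossprod(w, logx)) / sum(w)
    names(scores) <- colnames(expr)
  }
  scores
}

#' Score several signatures at once
#'
#' @param expr gene-by-sample TPM matrix.
#' @param sets named list of gene vectors (default
#'   [default_immune_signatures()]).
#' @return data frame sample x signature of scores.
#' @export
score_signatures <- function(expr, sets = default_immune_signatures()) {
  out <- vapply(names(sets),
                function(nm) score_gene_set(expr, sets[[nm]], nm),
                numeric(ncol(expr)))
  out <- as.data.frame(out)
  out <- cbind(sample = colnames(expr), out)
  rownames(out) <- NULL
  out
}

#' Compare signature scores between two groups
#'
#' Two-sided Wilcoxon rank-sum test for independent groups, or signed-rank
#' test for paired samples (elements matched by position). The reported
#' effect is the difference of group medians (unpaired) or the median of
#' paired differences. P values are deliberately not adjusted for multiple
#' signatures; the output carries an `adjusted = FALSE` column as a
#' reminder.
#'
#' @param scores numeric vector, or a data frame / matrix with one column
#'   per signature (rows = samples).
#' @param groups two-level factor (or coercible) aligned with the rows of
#'   `scores`. For `paired = TRUE` the i-th sample of group 1 is matched
#'   with the i-th of group 2.
#' @param paired logical; default FALSE.
#' @return data frame with `signature`, `effect`, `p_value`, `adjusted`.
#' @export
compare_groups <- function(scores, groups, paired = FALSE) {
  if (is.numeric(scores) && is.null(dim(scores))) {
    scores <- data.frame(score = scores)
  }
  scores <- as.data.frame(scores)
  num_cols <- names(scores)[vapply(scores, is.numeric, logical(1))]
  if (length(num_cols) == 0) stopf("`scores` has no numeric columns")
  groups <- factor(groups)
  if (nlevels(groups) != 2) stopf("`groups` must have exactly 2 levels")
  if (length(groups) != nrow(scores)) {
    stopf("`groups` length (%d) does not match rows of `scores` (%d)",
          length(groups), nrow(scores))
  }
  n1 <- sum(groups == levels(groups)[1])
  n2 <- sum(groups == levels(groups)[2])
  if (min(n1, n2) < 2) stopf("each group needs at least 2 samples")
  if (paired && n1 != n2) stopf("paired comparison needs equal group sizes")

  one <- function(x) {
    a <- x[groups == levels(groups)[1]]
    b <- x[groups == levels(groups)[2]]
    if (paired) {
      d <- a - b
      if (all(d == 0)) return(c(effect = 0, p = 1))
      p <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE)$p.value)
      c(effect = stats::median(d), p = p)
    } else {
      if (length(unique(c(a, b))) == 1) return(c(effect = 0, p = 1))
      p <- suppressWarnings(stats::wilcox.test(a, b)$p.value)
      c(effect = stats::median(a) - stats::median(b), p = p)
    }
  }
  res <- t(vapply(scores[num_cols], one, numeric(2)))
  data.frame(
    signature = num_cols,
    effect = res[, "effect"],
    p_value = res[, "p"],
    adjusted = FALSE,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}
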