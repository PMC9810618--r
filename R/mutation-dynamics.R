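# Purity-corrected VAF dynamics: call filtering, mutation-fate
# classification, burden accounting, purity-balancing dilution, subclone
# consistency, and biomarker contingency tests.

mutation_key <- function(records) {
  paste(records$chrom, records$pos, records$ref, records$alt, sep = ":")
}

required_mutation_cols <- c("patient", "timepoint", "gene", "chrom", "pos",
                            "ref", "alt", "alt_reads", "depth", "vaf",
                            "nonsyn", "neoantigen")

check_mutation_records <- function(records, name = "records") {
  missing <- setdiff(required_mutation_cols, names(records))
  if (length(missing)) {
    stopf("`%s` is missing column(s): %s", name, paste(missing, collapse = ", "))
  }
  if (any(records$alt_reads > records$depth)) {
    stopf("`%s` has alt_reads > depth", name)
  }
  invisible(records)
}

#' Purity-adjusted variant allele fraction
#'
#' Rescales an observed VAF by tumor purity so that pre- and post-treatment
#' samples with different tumor content are comparable. Two conventions are
#' offered: `"vaf"` returns `min(1, vaf / purity)` (the observed fraction a
#' pure tumor would show under the simplest monotone correction) and `"ccf"`
#' returns `min(1, 2 * vaf / purity)` (cancer cell fraction under a
#' copy-neutral heterozygous diploid model). Fate classification depends only
#' on the sign of pre/post differences, which is invariant to the constant
#' factor between the two.
#'
#' @param vaf observed variant allele fraction(s) in \[0, 1\].
#' @param purity tumor purity in (0, 1\].
#' @param mode `"vaf"` (default) or `"ccf"`.
#' @return adjusted VAF(s), capped at 1.
#' @examples
#' adjust_vaf(0.25, 0.5)        # 0.5
#' adjust_vaf(0.25, 0.5, "ccf") # 1 (capped)
#' @export
adjust_vaf <- function(vaf, purity, mode = c("vaf", "ccf")) {
  mode <- match.arg(mode)
  check_number(vaf, "vaf", 0, 1)
  if (!is.numeric(purity) || any(purity <= 0) || any(purity > 1)) {
    stopf("`purity` must lie in (0, 1]")
  }
  factor <- if (mode == "ccf") 2 else 1
  pmin(1, factor * vaf / purity)
}

#' Filter somatic calls on VAF, depth and supporting reads
#'
#' Standard post-calling filter stack: retain calls with
#' `vaf >= min_vaf` (boundary inclusive), `depth >= min_depth`, and
#' `alt_reads >= min_alt`. The number of removed records is attached as
#' attribute `n_removed` and reported via `message()`.
#'
#' @param records mutation data frame (MAF-like columns; see
#'   [generate_cohort()] output).
#' @param min_vaf minimum variant allele fraction; default 0.02.
#' @param min_depth minimum total depth; default 10.
#' @param min_alt minimum alt-supporting reads; default 2.
#' @param quiet suppress the removal message.
#' @return the retained records, with attribute `n_removed`.
#' @export
apply_call_filters <- function(records, min_vaf = 0.02, min_depth = 10,
                               min_alt = 2, quiet = FALSE) {
  check_mutation_records(records)
  keep <- records$vaf >= min_vaf &
    records$depth >= min_depth &
    records$alt_reads >= min_alt
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(!keep)
  if (!quiet && nrow(records) > 0) {
    message(sprintf("apply_call_filters: removed %d of %d records",
                    sum(!keep), nrow(records)))
  }
  out
}

#' Classify mutation fates between paired pre/post samples
#'
#' Each mutation (keyed by chrom:pos:ref:alt) in the union of a patient's
#' pre- and post-treatment call sets is assigned one of five fates:
#' `lost` (present only pre-treatment), `gain` (present only
#' post-treatment), and for shared mutations `increase` / `decrease` /
#' `stable` by the sign of the purity-adjusted VAF change
#' (`stable` when the absolute change is within `tie_tol`).
#'
#' @param pre_records,post_records mutation data frames for one patient.
#' @param purity_pre,purity_post tumor purity of each sample, in (0, 1\].
#' @param tie_tol absolute adjusted-VAF change treated as no change;
#'   default 0.
#' @param mode purity-adjustment convention passed to [adjust_vaf()].
#' @return a `fate_table` data frame with columns `patient`, `key`, `gene`,
#'   `adj_vaf_pre`, `adj_vaf_post` (NA when absent) and `fate`.
#' @examples
#' pre <- data.frame(patient = "P1", timepoint = "pre", gene = "TP53",
#'                   chrom = "17", pos = 7577120, ref = "C", alt = "T",
#'                   alt_reads = 30, depth = 100, vaf = 0.3,
#'                   nonsyn = TRUE, neoantigen = FALSE)
#' post <- pre[0, ]
#' classify_fates(pre, post, 0.6, 0.5)  # single "lost" mutation
#' @export
classify_fates <- function(pre_records, post_records, purity_pre, purity_post,
                           tie_tol = 0, mode = c("vaf", "ccf")) {
  mode <- match.arg(mode)
  check_mutation_records(pre_records, "pre_records")
  check_mutation_records(post_records, "post_records")
  check_number(tie_tol, "tie_tol", 0, len = 1)

  key_pre <- mutation_key(pre_records)
  key_post <- mutation_key(post_records)
  if (anyDuplicated(key_pre)) {
    stopf("duplicate mutation key in pre_records: %s",
          key_pre[duplicated(key_pre)][1])
  }
  if (anyDuplicated(key_post)) {
    stopf("duplicate mutation key in post_records: %s",
          key_post[duplicated(key_post)][1])
  }

  keys <- union(key_pre, key_post)
  i_pre <- match(keys, key_pre)
  i_post <- match(keys, key_post)

  adj_pre <- rep(NA_real_, length(keys))
  adj_post <- rep(NA_real_, length(keys))
  adj_pre[!is.na(i_pre)] <-
    adjust_vaf(pre_records$vaf[i_pre[!is.na(i_pre)]], purity_pre, mode)
  adj_post[!is.na(i_post)] <-
    adjust_vaf(post_records$vaf[i_post[!is.na(i_post)]], purity_post, mode)

  fate <- character(length(keys))
  fate[!is.na(adj_pre) & is.na(adj_post)] <- "lost"
  fate[is.na(adj_pre) & !is.na(adj_post)] <- "gain"
  shared <- !is.na(adj_pre) & !is.na(adj_post)
  delta <- adj_post - adj_pre
  fate[shared & abs(delta) <= tie_tol] <- "stable"
  fate[shared & delta > tie_tol] <- "increase"
  fate[shared & delta < -tie_tol] <- "decrease"

  patient <- unique(c(pre_records$patient, post_records$patient))
  if (length(patient) > 1) {
    stopf("records span multiple patients: %s", paste(patient, collapse = ", "))
  }
  gene <- ifelse(is.na(i_pre), post_records$gene[i_post], pre_records$gene[i_pre])

  out <- data.frame(
    patient = if (length(patient)) patient else NA_character_,
    key = keys,
    gene = gene,
    adj_vaf_pre = adj_pre,
    adj_vaf_post = adj_post,
    fate = factor(fate, levels = c("gain", "lost", "increase", "decrease",
                                   "stable")),
    stringsAsFactors = FALSE
  )
  class(out) <- c("fate_table", "data.frame")
  out
}

#' Fraction of pre-treatment mutations lost after therapy
#'
#' The number of `lost` mutations divided by the number of mutations present
#' pre-treatment (lost + shared). Mutations gained post-treatment do not
#' enter the denominator.
#'
#' @param fates a `fate_table` from [classify_fates()].
#' @return fraction in \[0, 1\].
#' @export
lost_fraction <- function(fates) {
  if (!inherits(fates, "fate_table")) stopf("`fates` must be a fate_table")
  n_pre <- sum(fates$fate != "gain")
  if (n_pre == 0) stopf("no pre-treatment mutations: lost fraction undefined")
  sum(fates$fate == "lost") / n_pre
}

#' @export
plot.fate_table <- function(x, ...) {
  tab <- table(x$fate)
  graphics::barplot(tab / sum(tab), ylab = "fraction of mutations",
                    main = unique(x$patient)[1], ...)
  invisible(x)
}

#' Tumor mutational and neoantigen burden
#'
#' TMB is the number of nonsynonymous somatic mutations per megabase of the
#' captured exome; TNB the number of neoantigen-flagged mutations per
#' megabase. Records should already be filtered ([apply_call_filters()]).
#'
#' @param records mutation data frame for one sample.
#' @param exome_mb exome footprint in megabases (denominator); default 35.
#' @return data frame with `patient`, `timepoint`, `n_mutations`, `tmb`,
#'   `tnb`.
#' @export
compute_burden <- function(records, exome_mb = 35) {
  check_mutation_records(records)
  check_number(exome_mb, "exome_mb", len = 1)
  if (exome_mb <= 0) stopf("`exome_mb` must be > 0")
  data.frame(
    patient = if (nrow(records)) records$patient[1] else NA_character_,
    timepoint = if (nrow(records)) records$timepoint[1] else NA_character_,
    n_mutations = nrow(records),
    tmb = sum(records$nonsyn) / exome_mb,
    tnb = sum(records$neoantigen) / exome_mb,
    stringsAsFactors = FALSE
  )
}

#' Purity-balancing dilution of a high-purity sample
#'
#' When one sample of a pre/post pair has much higher tumor purity, its
#' apparent mutational burden is inflated relative to its partner. This
#' simulation blends the high-purity sample down to a target purity: with
#' mixing fraction `m = 1 - target_purity / purity`, each mutation's alt
#' count is redrawn as Binomial(depth, vaf * (1 - m)) — reads from the
#' matched normal replace a fraction m of tumor reads while total depth is
#' preserved. Standard call filters are then re-applied and burden
#' recomputed, so mutations diluted below the detection thresholds drop out
#' just as they would in re-called data.
#'
#' `target_purity` equal to the current purity (m = 0) is an exact identity:
#' the input records are returned unchanged.
#'
#' @param records unfiltered mutation data frame of the high-purity sample.
#' @param purity purity of that sample, in (0, 1\].
#' @param target_purity purity to dilute to; must not exceed `purity`.
#' @param seed integer seed for the binomial redraw.
#' @param exome_mb megabases for the burden denominator; default 35.
#' @param min_vaf,min_depth,min_alt filter thresholds re-applied after
#'   dilution (defaults as in [apply_call_filters()]).
#' @return list with `records` (diluted, unfiltered), `filtered` (after
#'   filters), `burden` (recomputed on the filtered set), and `m`.
#' @export
purity_balance_dilution <- function(records, purity, target_purity, seed,
                                    exome_mb = 35, min_vaf = 0.02,
                                    min_depth = 10, min_alt = 2) {
  check_mutation_records(records)
  if (purity <= 0 || purity > 1) stopf("`purity` must be in (0, 1]")
  if (target_purity > purity) {
    stopf("`target_purity` (%.3f) exceeds sample purity (%.3f): dilution only",
          target_purity, purity)
  }
  if (target_purity <= 0) stopf("`target_purity` must be > 0")
  m <- 1 - target_purity / purity

  diluted <- records
  if (m > 0 && nrow(records) > 0) {
    diluted$alt_reads <- with_seed(seed, {
      stats::rbinom(nrow(records), size = records$depth,
                    prob = pmin(1, records$vaf * (1 - m)))
    })
    diluted$vaf <- ifelse(diluted$depth > 0,
                          diluted$alt_reads / diluted$depth, 0)
  }
  filtered <- apply_call_filters(diluted, min_vaf = min_vaf,
                                 min_depth = min_depth, min_alt = min_alt,
                                 quiet = TRUE)
  list(
    records = diluted,
    filtered = filtered,
    burden = compute_burden(filtered, exome_mb = exome_mb),
    m = m
  )
}

#' Is a mutation's VAF change consistent with its subclone's dynamics?
#'
#' A mutation is consistent with its assigned subclone when the sign of its
#' purity-adjusted VAF change matches the sign of the cluster's cellular
#' prevalence change. Genes hosting consistent mutations are the "clonal
#' genes" of the tumor. Absence at a timepoint is coded as adjusted VAF 0,
#' so a mutation lost post-treatment agrees with a cluster eradicated
#' post-treatment (both signs negative, or zero-vs-zero when it was also
#' absent pre-treatment).
#'
#' @param fate one row of a `fate_table` (or a list with `key`,
#'   `adj_vaf_pre`, `adj_vaf_post`).
#' @param cluster a `subclone_cluster` (see [subclone_cluster()]).
#' @param tol absolute change below which a difference counts as zero;
#'   default 0.
#' @return logical.
#' @export
clonal_consistency <- function(fate, cluster, tol = 0) {
  if (!inherits(cluster, "subclone_cluster")) {
    stopf("`cluster` must be a subclone_cluster")
  }
  key <- as.character(fate$key)
  if (!key %in% cluster$member_mutations) {
    stopf("mutation %s is not assigned to cluster %s", key, cluster$cluster_id)
  }
  zero_sign <- function(x) {
    if (abs(x) <= tol) 0 else sign(x)
  }
  v_pre <- ifelse(is.na(fate$adj_vaf_pre), 0, fate$adj_vaf_pre)
  v_post <- ifelse(is.na(fate$adj_vaf_post), 0, fate$adj_vaf_post)
  d_vaf <- zero_sign(v_post - v_pre)
  d_prev <- zero_sign(cluster$prevalence_post - cluster$prevalence_pre)
  d_vaf == d_prev
}

#' Association between a biomarker and response: 2x2 exact test
#'
#' Cross-tabulates per-patient mutation (or other binary biomarker) status
#' against a binary response label and runs Fisher's exact test (two-sided).
#' Rows of the table are response yes/no, columns biomarker yes/no. The odds
#' ratio is the conditional MLE from the exact test and is `Inf` when a
#' margin cell is empty. P values are not adjusted for multiple testing;
#' screens over many genes must account for that downstream.
#'
#' @param mutated logical vector, one element per patient.
#' @param response logical vector aligned with `mutated`.
#' @param patient optional patient ids; must align when given.
#' @return list of class `biomarker_test`: `table`, `odds_ratio`, `p_value`,
#'   `adjusted` (always FALSE).
#' @export
biomarker_contingency <- function(mutated, response, patient = NULL) {
  if (length(mutated) != length(response)) {
    stopf("`mutated` and `response` lengths differ (%d vs %d)",
          length(mutated), length(response))
  }
  if (!is.null(patient) && length(patient) != length(mutated)) {
    stopf("`patient` labels do not align with the flag vectors")
  }
  mutated <- as.logical(mutated)
  response <- as.logical(response)
  if (anyNA(mutated) || anyNA(response)) stopf("flags must not contain NA")
  tab <- matrix(
    c(sum(response & mutated), sum(response & !mutated),
      sum(!response & mutated), sum(!response & !mutated)),
    nrow = 2, byrow = TRUE,
    dimnames = list(response = c("yes", "no"), biomarker = c("yes", "no"))
  )
  ft <- stats::fisher.test(tab)
  structure(
    list(table = tab,
         odds_ratio = unname(ft$estimate),
         p_value = ft$p.value,
         adjusted = FALSE),
    class = "biomarker_test"
  )
}

#' @export
print.biomarker_test <- function(x, ...) {
  cat("Biomarker vs response (Fisher's exact test, two-sided)\n")
  print(x$table)
  cat(sprintf("odds ratio = %s, p = %.4g (unadjusted)\n",
              format(x$odds_ratio, digits = 3), x$p_value))
  invisible(x)
}
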