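# Pipeline orchestration: run every analysis stage on a cohort directory
# and emit a deterministic report.

#' Spearman correlation of a per-patient statistic with regression
#'
#' Rank correlation (mid-ranks for ties) between a per-patient value (lost
#' mutation fraction, CE score, ...) and percent pathological regression,
#' with the two-sided p value. A constant input vector makes rho
#' undefined; this is signaled with a warning and NA results rather than
#' an error so cohort loops can continue.
#'
#' @param values numeric per-patient statistic.
#' @param regression numeric per-patient regression (same order).
#' @return list with `rho`, `p_value`, `n`.
#' @export
correlate_with_regression <- function(values, regression) {
  if (length(values) != length(regression)) {
    stopf("`values` and `regression` lengths differ")
  }
  keep <- !is.na(values) & !is.na(regression)
  values <- values[keep]
  regression <- regression[keep]
  if (length(values) < 3) stopf("need at least 3 complete pairs")
  if (length(unique(values)) == 1 || length(unique(regression)) == 1) {
    warning("constant input: Spearman rho undefined")
    return(list(rho = NA_real_, p_value = NA_real_, n = length(values)))
  }
  ct <- suppressWarnings(
    stats::cor.test(values, regression, method = "spearman")
  )
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(values))
}

pipeline_manifest <- function(input_dir, skip) {
  required <- c("patients.tsv")
  if (!"mutations" %in% skip) {
    required <- c(required, "mutations_pre.tsv", "mutations_post.tsv")
  }
  if (!"signatures" %in% skip) required <- c(required, "expression_tpm.tsv")
  absent <- required[!file.exists(file.path(input_dir, required))]
  if (length(absent)) {
    stopf("input directory is missing required table(s): %s",
          paste(absent, collapse = ", "),
          class = "neoresponse_manifest_error")
  }
  if (!"tcr" %in% skip) {
    if (length(Sys.glob(file.path(input_dir, "clonotypes_*_pre.tsv"))) == 0) {
      stopf("input directory has no clonotypes_<patient>_<timepoint>.tsv files",
            class = "neoresponse_manifest_error")
    }
  }
  invisible(TRUE)
}

read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

fmt <- function(x, d = 3) formatC(x, digits = d, format = "f")

#' Run the full analysis pipeline on a cohort directory
#'
#' Executes pathology -> mutation dynamics -> TCR -> signatures on the TSV
#' tables of a cohort directory (the layout written by [write_cohort()]),
#' writes every stage's output table plus a `report.md`, and returns the
#' stage results. The report text is deterministic given the same inputs,
#' seed and parameters (it embeds a fingerprint of both).
#'
#' @param input_dir directory with `patients.tsv`, `mutations_pre.tsv`,
#'   `mutations_post.tsv`, `clonotypes_<patient>_<timepoint>.tsv`,
#'   `expression_tpm.tsv` (stages present may be reduced via `skip`).
#' @param output_dir directory for outputs (created if needed).
#' @param conf confidence level for response rates; default 0.95.
#' @param seed integer seed for any stochastic stage.
#' @param skip character vector among `c("mutations", "tcr", "signatures")`
#'   naming stages to omit.
#' @param min_vaf,min_depth,min_alt somatic call filters.
#' @param ce_k,ce_mode clone-expansion score parameters (see [ce_score()]).
#' @return list of class `pipeline_run` with the stage outputs.
#' @export
run_pipeline <- function(input_dir, output_dir, conf = 0.95, seed = 1,
                         skip = character(), min_vaf = 0.02, min_depth = 10,
                         min_alt = 2, ce_k = 20, ce_mode = "pooled") {
  if (length(skip)) {
    skip <- match.arg(skip, c("mutations", "tcr", "signatures"),
                      several.ok = TRUE)
  }
  pipeline_manifest(input_dir, skip)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(x, name) {
    utils::write.table(x, file.path(output_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  report <- c("# Cohort analysis report", "")

  patients <- read_tsv(file.path(input_dir, "patients.tsv"))
  if (!"viable_pct" %in% names(patients)) {
    stopf("patients.tsv lacks a viable_pct column",
          class = "neoresponse_manifest_error")
  }

  # -- pathology ------------------------------------------------------
  calls <- classify_response(patients$viable_pct, patients$patient)
  rates <- response_rate_table(calls, conf = conf)
  wr(as.data.frame(rates), "response_rates.tsv")
  report <- c(report, "## Pathological response", "",
              sprintf("%d evaluable patients; %.0f%% Clopper-Pearson CIs.",
                      nrow(calls), 100 * conf), "",
              "| endpoint | events | rate | CI |",
              "|---|---|---|---|",
              sprintf("| %s | %d/%d | %.1f%% | %.1f-%.1f%% |",
                      rates$endpoint, rates$k, rates$n, rates$rate,
                      rates$ci_low, rates$ci_high),
              "")
  regression <- 100 - patients$viable_pct
  names(regression) <- patients$patient
  results <- list(calls = calls, rates = rates)

  # -- mutation dynamics ----------------------------------------------
  if (!"mutations" %in% skip) {
    pre_all <- read_tsv(file.path(input_dir, "mutations_pre.tsv"))
    post_all <- read_tsv(file.path(input_dir, "mutations_post.tsv"))
    fates_all <- list()
    burden_all <- list()
    lost <- stats::setNames(rep(NA_real_, nrow(patients)), patients$patient)
    for (i in seq_len(nrow(patients))) {
      pid <- patients$patient[i]
      pre <- apply_call_filters(pre_all[pre_all$patient == pid, , drop = FALSE],
                                min_vaf, min_depth, min_alt, quiet = TRUE)
      post <- apply_call_filters(post_all[post_all$patient == pid, , drop = FALSE],
                                 min_vaf, min_depth, min_alt, quiet = TRUE)
      exmb <- if ("exome_mb" %in% names(patients)) patients$exome_mb[i] else 35
      burden_all[[pid]] <- rbind(compute_burden(pre, exmb),
                                 compute_burden(post, exmb))
      if (nrow(pre) + nrow(post) == 0) next
      fates <- classify_fates(pre, post,
                              purity_pre = patients$purity_pre[i],
                              purity_post = patients$purity_post[i])
      fates_all[[pid]] <- fates
      if (sum(fates$fate != "gain") > 0) lost[pid] <- lost_fraction(fates)
    }
    fates_df <- do.call(rbind, unname(fates_all))
    wr(fates_df, "fates.tsv")
    burden_df <- do.call(rbind, unname(burden_all))
    burden_df <- burden_df[!is.na(burden_df$patient), , drop = FALSE]
    wr(burden_df, "burden.tsv")
    lf_cor <- correlate_with_regression(lost, regression)
    wr(data.frame(patient = names(lost), lost_fraction = lost,
                  regression_pct = regression),
       "lost_fraction.tsv")
    report <- c(report, "## Mutation dynamics", "",
                sprintf("Fates over %d mutations in %d patients (filters: VAF >= %s, depth >= %d, alt >= %d).",
                        nrow(fates_df), length(fates_all),
                        format(min_vaf), min_depth, min_alt),
                sprintf("Spearman rho(lost fraction, regression) = %s (p = %s, n = %d).",
                        fmt(lf_cor$rho), format(lf_cor$p_value, digits = 3),
                        lf_cor$n),
                "")
    results$fates <- fates_df
    results$burden <- burden_df
    results$lost_fraction <- lost
    results$lost_fraction_cor <- lf_cor
  }

  # -- TCR repertoire --------------------------------------------------
  if (!"tcr" %in% skip) {
    pre_files <- sort(Sys.glob(file.path(input_dir, "clonotypes_*_pre.tsv")))
    pids <- sub("^clonotypes_(.*)_pre\\.tsv$", "\\1", basename(pre_files))
    ce <- stats::setNames(rep(NA_real_, length(pids)), pids)
    metrics <- list()
    tables <- list()
    for (pid in pids) {
      pre <- read_clonotypes(file.path(input_dir,
                                       sprintf("clonotypes_%s_pre.tsv", pid)))
      post_path <- file.path(input_dir, sprintf("clonotypes_%s_post.tsv", pid))
      if (!file.exists(post_path)) next
      post <- read_clonotypes(post_path)
      ce[pid] <- ce_score(pre, post, k = ce_k, mode = ce_mode)
      tables[[paste0(pid, "_pre")]] <- pre
      tables[[paste0(pid, "_post")]] <- post
      metrics[[pid]] <- cbind(
        patient = pid, timepoint = c("pre", "post"),
        rbind(diversity_metrics(pre), diversity_metrics(post)),
        hyperexpanded_mass = c(size_class_partition(pre)$mass["hyperexpanded"],
                               size_class_partition(post)$mass["hyperexpanded"])
      )
    }
    metrics_df <- do.call(rbind, unname(metrics))
    wr(metrics_df, "tcr_metrics.tsv")
    ce_df <- data.frame(patient = names(ce), ce_score = ce,
                        regression_pct = regression[names(ce)])
    wr(ce_df, "ce_scores.tsv")
    if (length(tables) >= 2) {
      ov <- pairwise_overlap(tables)
      utils::write.table(ov, file.path(output_dir, "overlap_matrix.tsv"),
                         sep = "\t", quote = FALSE, row.names = TRUE,
                         col.names = NA)
    }
    ce_cor <- correlate_with_regression(ce, regression[names(ce)])
    report <- c(report, "## TCR repertoire", "",
                sprintf("CE scores (top-%d, %s mode) for %d patients; %d positive.",
                        ce_k, ce_mode, sum(!is.na(ce)),
                        sum(ce > 0, na.rm = TRUE)),
                sprintf("Spearman rho(CE score, regression) = %s (p = %s, n = %d).",
                        fmt(ce_cor$rho), format(ce_cor$p_value, digits = 3),
                        ce_cor$n),
                "")
    results$ce_scores <- ce_df
    results$tcr_metrics <- metrics_df
    results$ce_cor <- ce_cor
  }

  # -- expression signatures -------------------------------------------
  if (!"signatures" %in% skip) {
    em <- read_tsv(file.path(input_dir, "expression_tpm.tsv"))
    expr <- as.matrix(em[, -1, drop = FALSE])
    rownames(expr) <- em[[1]]
    sets_path <- file.path(input_dir, "gene_sets.yaml")
    sets <- if (file.exists(sets_path)) read_gene_sets(sets_path)
            else default_immune_signatures()
    scores <- score_signatures(expr, sets)
    wr(scores, "signature_scores.tsv")
    report <- c(report, "## Immune signatures", "",
                sprintf("Scored %d signatures over %d samples (mean log2(TPM+1)).",
                        length(sets), ncol(expr)), "")
    truth_path <- file.path(input_dir, "truth.tsv")
    if (file.exists(truth_path)) {
      truth <- read_tsv(truth_path)
      samp_patient <- sub("_(pre|post)$", "", scores$sample)
      samp_tp <- sub("^.*_(pre|post)$", "\\1", scores$sample)
      post_idx <- samp_tp == "post" & samp_patient %in% truth$patient
      grp <- truth$responder[match(samp_patient[post_idx], truth$patient)]
      if (length(unique(grp)) == 2 && min(table(grp)) >= 2) {
        contrasts <- compare_groups(
          scores[post_idx, setdiff(names(scores), "sample"), drop = FALSE],
          factor(ifelse(grp, "responder", "non_responder"),
                 levels = c("responder", "non_responder"))
        )
        wr(contrasts, "signature_contrasts.tsv")
        report <- c(report,
                    "Responder vs non-responder (post-treatment, rank-sum):", "",
                    sprintf("- %s: effect %s, p = %s",
                            contrasts$signature, fmt(contrasts$effect),
                            format(contrasts$p_value, digits = 3)),
                    "")
        results$signature_contrasts <- contrasts
      }
    }
    results$signature_scores <- scores
  }

  report <- c(report,
              "---",
              "P values are two-sided and unadjusted for multiple comparisons.",
              sprintf("Parameters: conf=%s seed=%d filters(vaf>=%s,depth>=%d,alt>=%d) ce(k=%d,%s).",
                      format(conf), seed, format(min_vaf), min_depth, min_alt,
                      ce_k, ce_mode),
              sprintf("Input fingerprint: %s",
                      text_fingerprint(c(
                        basename(sort(list.files(input_dir))),
                        readLines(file.path(input_dir, "patients.tsv"))
                      ))))
  writeLines(report, file.path(output_dir, "report.md"))
  results$report <- report
  class(results) <- "pipeline_run"
  invisible(results)
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("Pipeline run: %d stages completed\n",
              sum(c(TRUE, !is.null(x$fates), !is.null(x$ce_scores),
                    !is.null(x$signature_scores)))))
  print(x$rates)
  invisible(x)
}
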