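# Synthetic cohort generator: paired pre/post mutation tables from subclone
# prevalences with binomial read sampling, power-law TCR repertoires with
# responder-specific top-clone expansion, and expression matrices with
# group-shifted immune signatures.

# Fixed catalogues used by the generator. Gene symbols are frequently
# mutated gastric-cancer genes plus fillers; V/J labels follow TRB
# nomenclature.
.mutated_gene_catalogue <- c(
  "TTN", "TP53", "SPTA1", "MUC16", "LRP1B", "ARID1A", "KMT2D", "FAT4",
  "RREB1", "SSPO", "PIK3CA", "CDH1", "RHOA", "ERBB2", "ERBB3", "APC",
  "KRAS", "SMAD4", "CTNNB1", "FBXW7", "OBSCN", "CSMD3", "PCLO", "DNAH5",
  "RYR2", "ZFHX4", "FLG", "HMCN1", "SYNE1", "XIRP2"
)

.trbv_catalogue <- c(
  "TRBV2", "TRBV4-1", "TRBV5-1", "TRBV6-5", "TRBV7-9", "TRBV9",
  "TRBV11-2", "TRBV12-3", "TRBV15", "TRBV19", "TRBV20-1", "TRBV27",
  "TRBV28", "TRBV29-1", "TRBV30"
)
.trbj_catalogue <- c(
  "TRBJ1-1", "TRBJ1-2", "TRBJ1-5", "TRBJ2-1", "TRBJ2-2", "TRBJ2-3",
  "TRBJ2-5", "TRBJ2-7"
)

.aa_alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Configuration for the synthetic cohort generator
#'
#' Bundles and validates every generator parameter. Defaults emulate a
#' small neoadjuvant-immunotherapy trial: 19 evaluable patients of whom
#' about 42% respond (PPR+), WES at ~200x mean depth over a 35 Mb exome,
#' four tumor subclones, peripheral TCR repertoires of 2000 clonotypes
#' with a Zipf frequency profile, and a two-fold post-treatment expansion
#' of responders' dominant T-cell clones.
#'
#' @param n_patients number of patients.
#' @param frac_responders fraction of patients that are responders
#'   (truth label; responders emulate PPR+ patients).
#' @param regression_responder,regression_nonresponder length-2 Beta
#'   shape parameters for the pathological regression fraction in each
#'   group.
#' @param n_subclones subclone clusters per tumor.
#' @param n_mutations somatic mutations per tumor.
#' @param frac_nonsyn,frac_neoantigen fractions of mutations flagged
#'   nonsynonymous / neoantigenic (neoantigens are drawn from the
#'   nonsynonymous subset).
#' @param depth_mean mean sequencing depth (reads); per-site depths are
#'   Poisson around this.
#' @param purity_range_pre,purity_range_post tumor-purity sampling
#'   intervals in (0, 1].
#' @param exome_mb exome footprint in megabases (TMB denominator).
#' @param lost_subclone_prob_responder,lost_subclone_prob_nonresponder
#'   probability each subclone is eradicated post-treatment.
#' @param new_subclone_prob_responder,new_subclone_prob_nonresponder
#'   probability an emergent subclone (absent pre-treatment) arises.
#' @param repertoire_size distinct clonotypes per repertoire (>= 21).
#' @param zipf_exponent power-law exponent of clone frequencies.
#' @param expansion_factor_responder multiplier applied to responders'
#'   top-20 clone counts post-treatment.
#' @param turnover fraction of post-treatment repertoire read mass carried
#'   by novel clonotypes (repertoire turnover).
#' @param tcr_reads total reads per repertoire sample (multinomial
#'   resampling noise); NULL disables resampling.
#' @param n_genes expression genes (must cover the signature genes).
#' @param signature_shift additive log2 shift of signature genes in
#'   responder post-treatment samples.
#' @param seed integer RNG seed; identical config + seed gives
#'   byte-identical output tables.
#' @return validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 19,
                          frac_responders = 8 / 19,
                          regression_responder = c(8, 2),
                          regression_nonresponder = c(2, 6),
                          n_subclones = 4,
                          n_mutations = 80,
                          frac_nonsyn = 0.75,
                          frac_neoantigen = 0.15,
                          depth_mean = 200,
                          purity_range_pre = c(0.3, 0.8),
                          purity_range_post = c(0.15, 0.6),
                          exome_mb = 35,
                          lost_subclone_prob_responder = 0.6,
                          lost_subclone_prob_nonresponder = 0.15,
                          new_subclone_prob_responder = 0.05,
                          new_subclone_prob_nonresponder = 0.3,
                          repertoire_size = 2000,
                          zipf_exponent = 1,
                          expansion_factor_responder = 2,
                          turnover = 0.05,
                          tcr_reads = 1e5,
                          n_genes = 200,
                          signature_shift = 1,
                          seed = 1) {
  cfg <- list(
    n_patients = n_patients, frac_responders = frac_responders,
    regression_responder = regression_responder,
    regression_nonresponder = regression_nonresponder,
    n_subclones = n_subclones, n_mutations = n_mutations,
    frac_nonsyn = frac_nonsyn, frac_neoantigen = frac_neoantigen,
    depth_mean = depth_mean,
    purity_range_pre = purity_range_pre,
    purity_range_post = purity_range_post,
    exome_mb = exome_mb,
    lost_subclone_prob_responder = lost_subclone_prob_responder,
    lost_subclone_prob_nonresponder = lost_subclone_prob_nonresponder,
    new_subclone_prob_responder = new_subclone_prob_responder,
    new_subclone_prob_nonresponder = new_subclone_prob_nonresponder,
    repertoire_size = repertoire_size, zipf_exponent = zipf_exponent,
    expansion_factor_responder = expansion_factor_responder,
    turnover = turnover, tcr_reads = tcr_reads,
    n_genes = n_genes, signature_shift = signature_shift,
    seed = seed
  )
  validate_cohort_config(cfg)
  class(cfg) <- "cohort_config"
  cfg
}

validate_cohort_config <- function(cfg) {
  chk <- function(field, lower = -Inf, upper = Inf, len = 1) {
    x <- cfg[[field]]
    if (is.null(x) || !is.numeric(x) || length(x) != len ||
        anyNA(x) || any(x < lower) || any(x > upper)) {
      stopf("invalid configuration field `%s`", field,
            class = "neoresponse_config_error")
    }
  }
  chk("n_patients", lower = 1)
  chk("frac_responders", 0, 1)
  chk("regression_responder", lower = 1e-12, len = 2)
  chk("regression_nonresponder", lower = 1e-12, len = 2)
  chk("n_subclones", lower = 1)
  chk("n_mutations", lower = 1)
  chk("frac_nonsyn", 0, 1)
  chk("frac_neoantigen", 0, 1)
  chk("depth_mean", lower = 1)
  chk("purity_range_pre", lower = 1e-12, upper = 1, len = 2)
  chk("purity_range_post", lower = 1e-12, upper = 1, len = 2)
  chk("exome_mb", lower = 1e-12)
  chk("lost_subclone_prob_responder", 0, 1)
  chk("lost_subclone_prob_nonresponder", 0, 1)
  chk("new_subclone_prob_responder", 0, 1)
  chk("new_subclone_prob_nonresponder", 0, 1)
  chk("repertoire_size", lower = 21)
  chk("zipf_exponent", lower = 0)
  chk("expansion_factor_responder", lower = 0)
  chk("turnover", 0, 0.99)
  if (!is.null(cfg$tcr_reads)) chk("tcr_reads", lower = 1)
  chk("n_genes", lower = 1)
  chk("signature_shift")
  chk("seed")
  invisible(cfg)
}

#' Read a cohort configuration from YAML
#'
#' Fields mirror the arguments of [cohort_config()]; unknown fields are an
#' error, absent fields take the defaults.
#'
#' @param path YAML file.
#' @return `cohort_config`.
#' @export
read_cohort_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  values <- yaml::read_yaml(path)
  known <- names(formals(cohort_config))
  unknown <- setdiff(names(values), known)
  if (length(unknown)) {
    stopf("unknown configuration field `%s`", unknown[1],
          class = "neoresponse_config_error")
  }
  do.call(cohort_config, values)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  for (nm in names(x)) {
    cat(sprintf("  %-32s %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  }
  invisible(x)
}

#' Construct a subclone cluster
#'
#' A subclone is a set of mutations sharing cellular prevalence (the
#' fraction of tumor cells carrying them) before and after treatment.
#' Prevalence 0 post-treatment means the subclone was eradicated;
#' prevalence 0 pre-treatment an emergent subclone.
#'
#' @param cluster_id identifier.
#' @param prevalence_pre,prevalence_post cellular prevalence in \[0, 1\].
#' @param member_mutations character vector of mutation keys
#'   (chrom:pos:ref:alt) belonging to the cluster.
#' @return list of class `subclone_cluster`.
#' @export
subclone_cluster <- function(cluster_id, prevalence_pre, prevalence_post,
                             member_mutations) {
  check_number(prevalence_pre, "prevalence_pre", 0, 1, len = 1)
  check_number(prevalence_post, "prevalence_post", 0, 1, len = 1)
  structure(
    list(cluster_id = cluster_id,
         prevalence_pre = prevalence_pre,
         prevalence_post = prevalence_post,
         member_mutations = as.character(member_mutations)),
    class = "subclone_cluster"
  )
}

# Draw the invariant part of a mutation table (loci, genes, annotation
# flags) for one patient; cluster membership is appended by the caller.
draw_mutation_loci <- function(n, frac_nonsyn, frac_neoantigen) {
  chrom <- as.character(sample(1:22, n, replace = TRUE))
  pos <- sample.int(5e7, n)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  key <- paste(chrom, pos, ref, alt, sep = ":")
  dup <- duplicated(key)
  while (any(dup)) {
    pos[dup] <- sample.int(5e7, sum(dup))
    key <- paste(chrom, pos, ref, alt, sep = ":")
    dup <- duplicated(key)
  }
  nonsyn <- stats::runif(n) < frac_nonsyn
  neo <- nonsyn & stats::runif(n) < (frac_neoantigen / max(frac_nonsyn, 1e-12))
  data.frame(
    gene = sample(.mutated_gene_catalogue, n, replace = TRUE),
    chrom = chrom, pos = pos, ref = ref, alt = alt,
    nonsyn = nonsyn, neoantigen = neo,
    stringsAsFactors = FALSE
  )
}

#' Generate a paired pre/post mutation table from subclone prevalences
#'
#' Each mutation inherits its subclone's cellular prevalence; under a
#' copy-neutral heterozygous diploid model its true VAF at a timepoint is
#' `prevalence x purity / 2`. Observed alt-read counts are drawn
#' Binomial(depth, true VAF) with per-site Poisson depths around
#' `depth_mean`, and mutations with zero observed alt reads are absent
#' from that timepoint's table (so eradicated subclones vanish
#' post-treatment). Observed `vaf = alt_reads / depth`.
#'
#' @param patient patient id.
#' @param clusters list of [subclone_cluster()]s; their
#'   `member_mutations` jointly define the mutation set (keys
#'   chrom:pos:ref:alt). Loci/annotations for the keys are drawn here.
#' @param purity_pre,purity_post tumor purity of each sample, (0, 1].
#' @param depth_mean mean depth (>= 1).
#' @param seed integer seed.
#' @param frac_nonsyn,frac_neoantigen annotation-flag fractions.
#' @return list with data frames `pre` and `post` (MAF-like columns) and
#'   `mutations` (per-mutation truth: key, cluster, prevalences).
#' @export
generate_mutation_pair <- function(patient, clusters, purity_pre, purity_post,
                                   depth_mean, seed, frac_nonsyn = 0.75,
                                   frac_neoantigen = 0.15) {
  if (depth_mean < 1) stopf("`depth_mean` must be >= 1")
  if (purity_pre <= 0 || purity_pre > 1 || purity_post <= 0 || purity_post > 1) {
    stopf("purities must lie in (0, 1]")
  }
  for (cl in clusters) {
    if (!inherits(cl, "subclone_cluster")) {
      stopf("`clusters` must be a list of subclone_cluster objects")
    }
  }
  with_seed(seed, {
    member <- unlist(lapply(clusters, function(cl) {
      stats::setNames(rep(cl$cluster_id, length(cl$member_mutations)),
                      cl$member_mutations)
    }))
    if (anyDuplicated(names(member))) {
      stopf("mutation assigned to more than one cluster: %s",
            names(member)[duplicated(names(member))][1])
    }
    n <- length(member)
    loci <- draw_mutation_loci(n, frac_nonsyn, frac_neoantigen)
    prev <- do.call(rbind, lapply(clusters, function(cl) {
      data.frame(cluster = cl$cluster_id, pre = cl$prevalence_pre,
                 post = cl$prevalence_post, stringsAsFactors = FALSE)
    }))
    idx <- match(unname(member), prev$cluster)

    one_timepoint <- function(timepoint, prevalence, purity) {
      depth <- pmax(1L, stats::rpois(n, depth_mean))
      p_true <- prevalence * purity / 2
      alt <- stats::rbinom(n, depth, p_true)
      keep <- alt > 0
      out <- data.frame(
        patient = patient, timepoint = timepoint,
        gene = loci$gene, chrom = loci$chrom, pos = loci$pos,
        ref = loci$ref, alt = loci$alt,
        alt_reads = alt, depth = depth,
        vaf = alt / depth,
        nonsyn = loci$nonsyn, neoantigen = loci$neoantigen,
        stringsAsFactors = FALSE
      )[keep, , drop = FALSE]
      rownames(out) <- NULL
      out
    }
    list(
      pre = one_timepoint("pre", prev$pre[idx], purity_pre),
      post = one_timepoint("post", prev$post[idx], purity_post),
      mutations = data.frame(
        key = paste(loci$chrom, loci$pos, loci$ref, loci$alt, sep = ":"),
        cluster = unname(member),
        prevalence_pre = prev$pre[idx],
        prevalence_post = prev$post[idx],
        stringsAsFactors = FALSE
      )
    )
  })
}

#' Generate a paired pre/post TCR repertoire
#'
#' Pre-treatment clone counts follow a Zipf profile (`count_i` proportional
#' to `i^-zipf_exponent`). Post-treatment counts equal the pre counts with
#' the top-20 clones multiplied by `expansion_factor`, then renormalized.
#' Two optional realism layers, both off by default: `turnover` moves that
#' fraction of post-treatment read mass onto novel clonotypes (repertoire
#' turnover dilutes pre-existing clones), and `n_reads` resamples each
#' sample's counts Multinomial(n_reads, frequency) to add sampling noise.
#' With both off and `expansion_factor = 1` the pre and post tables are
#' identical.
#'
#' CDR3 amino-acid sequences are random 13-mers on a CASS...F scaffold,
#' with a subset drawn from a fixed public-clone catalogue so repertoires
#' of different patients share a small number of clonotypes; V/J labels
#' come from fixed TRBV/TRBJ catalogues.
#'
#' @param patient patient id.
#' @param repertoire_size distinct clonotypes (>= 21).
#' @param zipf_exponent power-law exponent (>= 0).
#' @param expansion_factor multiplier on the top-20 clone counts.
#' @param seed integer seed.
#' @param turnover fraction of post-treatment mass on novel clonotypes.
#' @param n_reads total reads per sample for multinomial resampling, or
#'   NULL for deterministic counts.
#' @param k_top number of top clones expanded; default 20.
#' @return list with `pre` and `post` `clonotype_table`s.
#' @export
generate_repertoire_pair <- function(patient, repertoire_size, zipf_exponent,
                                     expansion_factor, seed, turnover = 0,
                                     n_reads = NULL, k_top = 20) {
  if (repertoire_size < 21) {
    stopf("`repertoire_size` must be >= 21 (clone-expansion scoring needs a top-20)")
  }
  check_number(turnover, "turnover", 0, 0.99, len = 1)
  with_seed(seed, {
    n <- repertoire_size
    base <- (seq_len(n))^(-zipf_exponent)
    pre_counts <- pmax(1, round(1e5 * base / sum(base)))

    cdr3 <- draw_cdr3(n)
    v <- sample(.trbv_catalogue, n, replace = TRUE)
    j <- sample(.trbj_catalogue, n, replace = TRUE)
    key <- paste(cdr3, v, j, sep = "|")
    dup <- which(duplicated(key))
    if (length(dup)) cdr3[dup] <- paste0(cdr3[dup], "X", seq_along(dup))

    post_counts <- pre_counts
    top <- seq_len(min(k_top, n))
    post_counts[top] <- post_counts[top] * expansion_factor

    post_cdr3 <- cdr3; post_v <- v; post_j <- j
    if (turnover > 0) {
      # turnover mass is spread flat over many small novel clonotypes so the
      # novel clones dilute the existing repertoire without themselves
      # entering the top of the frequency ranking
      n_new <- max(1L, round(turnover * n))
      new_mass <- turnover / (1 - turnover) * sum(post_counts)
      new_counts <- pmax(1, rep(round(new_mass / n_new), n_new))
      new_cdr3 <- paste0(draw_cdr3(n_new), "N")
      post_cdr3 <- c(post_cdr3, new_cdr3)
      post_v <- c(post_v, sample(.trbv_catalogue, n_new, replace = TRUE))
      post_j <- c(post_j, sample(.trbj_catalogue, n_new, replace = TRUE))
      post_counts <- c(post_counts, new_counts)
    }

    if (!is.null(n_reads)) {
      pre_counts <- as.integer(stats::rmultinom(1, n_reads,
                                                pre_counts / sum(pre_counts)))
      post_counts <- as.integer(stats::rmultinom(1, n_reads,
                                                 post_counts / sum(post_counts)))
    }

    make_table <- function(cdr3, v, j, counts) {
      keep <- counts > 0
      normalize_clonotypes(data.frame(
        cdr3aa = cdr3[keep], v_segment = v[keep], j_segment = j[keep],
        count = counts[keep], frequency = NA_real_,
        stringsAsFactors = FALSE
      ))
    }
    list(
      pre = make_table(cdr3, v, j, pre_counts),
      post = make_table(post_cdr3, post_v, post_j, post_counts)
    )
  })
}

# Random CDR3 amino-acid 13-mers on a CASS...F scaffold; ~10% are taken
# from a fixed public-clone catalogue shared across patients.
draw_cdr3 <- function(n, public_frac = 0.1) {
  core <- matrix(sample(.aa_alphabet, n * 8, replace = TRUE), nrow = n)
  cdr3 <- paste0("CASS", apply(core, 1, paste0, collapse = ""), "F")
  n_pub <- min(length(public_clone_catalogue()), round(public_frac * n))
  if (n_pub > 0) {
    which_pub <- sample.int(n, n_pub)
    cdr3[which_pub] <- sample(public_clone_catalogue(), n_pub)
  }
  cdr3
}

public_clone_catalogue <- local({
  catalogue <- NULL
  function() {
    if (is.null(catalogue)) {
      catalogue <<- with_seed(20260922, {
        core <- matrix(sample(.aa_alphabet, 500 * 8, replace = TRUE), nrow = 500)
        unique(paste0("CASS", apply(core, 1, paste0, collapse = ""), "P"))
      })
    }
    catalogue
  }
})

#' Generate a TPM-like expression matrix with group-shifted signatures
#'
#' Log-normal baseline expression (log2 TPM ~ Normal per gene) with an
#' additive `signature_shift` (log2 units) applied to every signature gene
#' in responder post-treatment samples. Signature genes are given high
#' baselines (log2 mean 5-8) so `log2(TPM + 1)` scores track the shift
#' closely. All values are non-negative by construction.
#'
#' @param n_genes total genes; must be at least the number of distinct
#'   signature genes.
#' @param samples data frame with columns `sample`, `responder` (logical)
#'   and `timepoint` ("pre"/"post").
#' @param gene_sets named list of signature gene vectors; these genes
#'   become matrix rows. A set gene not in the generated matrix is a
#'   configuration error.
#' @param signature_shift additive log2 effect.
#' @param seed integer seed.
#' @return numeric `n_genes` x `nrow(samples)` matrix of TPM values.
#' @export
generate_expression <- function(n_genes, samples,
                                gene_sets = default_immune_signatures(),
                                signature_shift = 1, seed = 1) {
  needed <- c("sample", "responder", "timepoint")
  if (!all(needed %in% names(samples))) {
    stopf("`samples` must have columns: %s", paste(needed, collapse = ", "))
  }
  sig_genes <- unique(unlist(gene_sets))
  if (n_genes < length(sig_genes)) {
    stopf("`n_genes` (%d) is smaller than the %d distinct signature genes",
          n_genes, length(sig_genes), class = "neoresponse_config_error")
  }
  genes <- c(sig_genes,
             sprintf("GENE%04d", seq_len(n_genes - length(sig_genes))))
  unknown <- setdiff(sig_genes, genes)
  if (length(unknown)) {
    stopf("gene set references unknown gene `%s`", unknown[1],
          class = "neoresponse_config_error")
  }
  with_seed(seed, {
    mu <- c(stats::runif(length(sig_genes), 5, 8),
            stats::runif(n_genes - length(sig_genes), 0, 8))
    n_samp <- nrow(samples)
    z <- matrix(stats::rnorm(n_genes * n_samp, mean = mu, sd = 0.5),
                nrow = n_genes, ncol = n_samp,
                dimnames = list(genes, samples$sample))
    shifted_samples <- samples$responder & samples$timepoint == "post"
    if (any(shifted_samples) && signature_shift != 0) {
      z[sig_genes, shifted_samples] <- z[sig_genes, shifted_samples] +
        signature_shift
    }
    2^z
  })
}

#' Generate a complete synthetic cohort
#'
#' Runs the three generators over a patient roster drawn from the
#' configuration: responder labels and Beta-distributed pathological
#' regression, subclone clusters with responder-dependent eradication and
#' emergence, paired mutation tables, paired TCR repertoires (responders'
#' top clones expanded by `expansion_factor_responder`, everyone subject to
#' `turnover` and sampling noise), and an expression matrix with the
#' signature shift in responder post-treatment samples. Per-patient RNG
#' substreams are derived by stable hashing of the patient id, so any
#' subset of patients reproduces exactly.
#'
#' @param config a [cohort_config()].
#' @param modules character subset of `c("mutations", "tcr", "expression")`
#'   to generate; default all. Truth labels and pathology are always
#'   generated.
#' @return list of class `synthetic_cohort` with elements `config`,
#'   `patients` (per-sample metadata incl. viable_pct and purities),
#'   `truth` (responder flag, regression, true lost fraction, true CE
#'   direction), `mutations` (list with `pre`/`post` data frames over all
#'   patients), `clusters` (per-patient list of subclone_cluster),
#'   `repertoires` (per-patient list with `pre`/`post`), `expression`
#'   (matrix), `gene_sets`.
#' @export
generate_cohort <- function(config = cohort_config(),
                            modules = c("mutations", "tcr", "expression")) {
  validate_cohort_config(config)
  modules <- match.arg(modules, several.ok = TRUE)
  ids <- sprintf("P%03d", seq_len(config$n_patients))

  cohort_level <- with_seed(config$seed, {
    n_resp <- round(config$frac_responders * config$n_patients)
    responder <- rep(FALSE, config$n_patients)
    responder[sample.int(config$n_patients, n_resp)] <- TRUE
    shp_r <- config$regression_responder
    shp_n <- config$regression_nonresponder
    regression <- ifelse(
      responder,
      stats::rbeta(config$n_patients, shp_r[1], shp_r[2]),
      stats::rbeta(config$n_patients, shp_n[1], shp_n[2])
    )
    purity_pre <- stats::runif(config$n_patients,
                               config$purity_range_pre[1],
                               config$purity_range_pre[2])
    purity_post <- stats::runif(config$n_patients,
                                config$purity_range_post[1],
                                config$purity_range_post[2])
    msi_score <- stats::rexp(config$n_patients, 1 / 3)
    cps <- round(stats::rexp(config$n_patients, 1 / 5), 1)
    list(responder = responder, regression = regression,
         purity_pre = purity_pre, purity_post = purity_post,
         msi_score = msi_score, cps = cps)
  })

  truth <- data.frame(
    patient = ids,
    responder = cohort_level$responder,
    regression_pct = 100 * cohort_level$regression,
    true_lost_fraction = NA_real_,
    true_ce_direction = ifelse(cohort_level$responder &
                                 config$expansion_factor_responder > 1,
                               1L, -1L),
    stringsAsFactors = FALSE
  )

  patients <- data.frame(
    patient = ids,
    viable_pct = 100 - truth$regression_pct,
    purity_pre = cohort_level$purity_pre,
    purity_post = cohort_level$purity_post,
    msi_score = cohort_level$msi_score,
    msi_status = ifelse(cohort_level$msi_score > 10, "MSI-H", "MSS"),
    pdl1_cps = cohort_level$cps,
    exome_mb = config$exome_mb,
    stringsAsFactors = FALSE
  )

  clusters <- list()
  mut_pre <- list()
  mut_post <- list()
  repertoires <- list()

  for (i in seq_len(config$n_patients)) {
    pid <- ids[i]
    pseed <- derive_seed(config$seed, pid)
    resp <- cohort_level$responder[i]

    if ("mutations" %in% modules) {
      lost_p <- if (resp) config$lost_subclone_prob_responder
                else config$lost_subclone_prob_nonresponder
      new_p <- if (resp) config$new_subclone_prob_responder
               else config$new_subclone_prob_nonresponder
      cl <- with_seed(pseed, {
        n_cl <- config$n_subclones
        prev_pre <- c(1, stats::runif(n_cl - 1, 0.1, 0.9))[seq_len(n_cl)]
        eradicated <- stats::runif(n_cl) < lost_p
        prev_post <- ifelse(eradicated, 0,
                            pmin(1, prev_pre * stats::runif(n_cl, 0.5, 1.5)))
        emergent <- stats::runif(1) < new_p
        sizes <- as.vector(stats::rmultinom(
          1, config$n_mutations,
          rep(1, n_cl + emergent)
        ))
        prev_pre <- c(prev_pre, if (emergent) 0)
        prev_post <- c(prev_post, if (emergent) stats::runif(1, 0.2, 0.7))
        start <- cumsum(c(0, sizes))
        lapply(seq_along(sizes), function(k) {
          subclone_cluster(
            cluster_id = sprintf("%s_C%d", pid, k),
            prevalence_pre = prev_pre[k],
            prevalence_post = prev_post[k],
            member_mutations = sprintf("%s_M%03d", pid,
                                       seq_len(sizes[k]) + start[k])
          )
        })
      })
      pair <- generate_mutation_pair(
        pid, cl, cohort_level$purity_pre[i], cohort_level$purity_post[i],
        config$depth_mean, seed = derive_seed(pseed, "mut"),
        frac_nonsyn = config$frac_nonsyn,
        frac_neoantigen = config$frac_neoantigen
      )
      clusters[[pid]] <- relabel_clusters(cl, pair$mutations)
      mut_pre[[pid]] <- pair$pre
      mut_post[[pid]] <- pair$post
      pre_keys <- mutation_key(pair$pre)
      detected <- pair$mutations$key %in% pre_keys
      if (any(detected)) {
        truth$true_lost_fraction[i] <-
          mean(pair$mutations$prevalence_post[detected] == 0)
      }
    }

    if ("tcr" %in% modules) {
      repertoires[[pid]] <- generate_repertoire_pair(
        pid, config$repertoire_size, config$zipf_exponent,
        expansion_factor = if (resp) config$expansion_factor_responder else 1,
        seed = derive_seed(pseed, "tcr"),
        turnover = config$turnover,
        n_reads = config$tcr_reads
      )
    }
  }

  expression <- NULL
  if ("expression" %in% modules) {
    samples <- data.frame(
      sample = c(paste0(ids, "_pre"), paste0(ids, "_post")),
      patient = rep(ids, 2),
      responder = rep(cohort_level$responder, 2),
      timepoint = rep(c("pre", "post"), each = config$n_patients),
      stringsAsFactors = FALSE
    )
    expression <- generate_expression(
      config$n_genes, samples,
      gene_sets = default_immune_signatures(),
      signature_shift = config$signature_shift,
      seed = derive_seed(config$seed, "expr")
    )
  }

  structure(
    list(config = config, patients = patients, truth = truth,
         mutations = list(
           pre = if (length(mut_pre)) do.call(rbind, unname(mut_pre)),
           post = if (length(mut_post)) do.call(rbind, unname(mut_post))
         ),
         clusters = clusters, repertoires = repertoires,
         expression = expression,
         gene_sets = default_immune_signatures()),
    class = "synthetic_cohort"
  )
}

# Replace the provisional member ids of clusters with realized
# chrom:pos:ref:alt keys so downstream consistency checks can address
# mutations the way the tables do.
relabel_clusters <- function(clusters, mutations) {
  lapply(clusters, function(cl) {
    cl$member_mutations <- mutations$key[mutations$cluster == cl$cluster_id]
    cl
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d patients (%d responders), seed %d\n",
              nrow(x$patients), sum(x$truth$responder), x$config$seed))
  if (!is.null(x$mutations$pre)) {
    cat(sprintf("  mutations: %d pre, %d post\n",
                nrow(x$mutations$pre), nrow(x$mutations$post)))
  }
  if (length(x$repertoires)) {
    cat(sprintf("  repertoires: %d patients x pre/post\n",
                length(x$repertoires)))
  }
  if (!is.null(x$expression)) {
    cat(sprintf("  expression: %d genes x %d samples\n",
                nrow(x$expression), ncol(x$expression)))
  }
  invisible(x)
}

#' Write a synthetic cohort to a directory of TSV files
#'
#' Writes `patients.tsv`, `truth.tsv`, `mutations_pre.tsv`,
#' `mutations_post.tsv`, `clonotypes_<patient>_<timepoint>.tsv` and
#' `expression_tpm.tsv`. Output is plain text and byte-stable for a given
#' config and seed.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!inherits(cohort, "synthetic_cohort")) {
    stopf("`cohort` must be a synthetic_cohort")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(x, name, row_names = FALSE) {
    utils::write.table(x, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = row_names, col.names = TRUE)
  }
  wr(cohort$patients, "patients.tsv")
  wr(cohort$truth, "truth.tsv")
  if (!is.null(cohort$mutations$pre)) {
    wr(cohort$mutations$pre, "mutations_pre.tsv")
    wr(cohort$mutations$post, "mutations_post.tsv")
  }
  for (pid in names(cohort$repertoires)) {
    wr(cohort$repertoires[[pid]]$pre,
       sprintf("clonotypes_%s_pre.tsv", pid))
    wr(cohort$repertoires[[pid]]$post,
       sprintf("clonotypes_%s_post.tsv", pid))
  }
  if (!is.null(cohort$expression)) {
    em <- data.frame(gene = rownames(cohort$expression),
                     cohort$expression, check.names = FALSE)
    wr(em, "expression_tpm.tsv")
  }
  invisible(dir)
}
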