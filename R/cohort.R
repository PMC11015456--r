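#' Default actionable-variant spectrum
#'
#' Per-case probabilities of carrying each actionable driver, with ESCAT
#' actionability tiers and a flag for genes whose targeted therapy is
#' EMA-approved and reimbursed. The frequencies are literature-typical
#' values for non-squamous NSCLC (overall actionable fraction 48%,
#' consistent with the commonly cited 40-50%); they are assumptions, not
#' measured values, and are meant to be overridden when real frequencies
#' are available. Drivers are mutually exclusive by default (at most one
#' per case).
#'
#' @return Data frame with columns `gene`, `tier`, `freq`, `reimbursed`.
#' @export
default_variant_table <- function() {
  data.frame(
    gene = c("EGFR", "KRAS_G12C", "ALK", "MET_ex14", "BRAF_V600E",
             "ROS1", "RET", "ERBB2", "NTRK"),
    tier = c("I", "I", "I", "I", "I", "I", "I", "II", "I"),
    freq = c(0.160, 0.120, 0.060, 0.040, 0.025, 0.025, 0.020, 0.025,
             0.005),
    reimbursed = c(TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE,
                   FALSE),
    stringsAsFactors = FALSE
  )
}

#' Parameters of the synthetic cohort generator
#'
#' Defaults describe a one-year case series of 210 non-squamous NSCLC
#' samples: 78.1% advanced stage, 3.8% NGS retests, 10% orthogonal
#' confirmation (IHC used for 66% of confirmed cases, 86% when the gene
#' is ALK; real-time PCR for 38%, 75% when the gene is MET exon 14 -
#' methods drawn independently, "and/or", with at least one method per
#' confirmed case). Turnaround time (TAT) is gamma distributed in
#' working days: a base component with mean `tat_base_mean` for routine
#' cases, plus an extra gamma delay (mean `repeat_delay_mean`) for cases
#' flagged retest and/or orthogonal. With the defaults the overall TAT
#' mean is 9.44 + 0.1342 x 3.35 = 9.89 days and the repeat-excluded mean
#' is 9.44 days.
#'
#' @param n Number of cases, `>= 0` (default 210).
#' @param advanced_prob Probability of advanced stage (default 0.781).
#' @param variant_table Data frame as [default_variant_table()]; per-case
#'   frequencies must sum to at most 1.
#' @param retest_prob Probability of NGS reanalysis (default 0.038).
#' @param orthogonal_prob Probability of orthogonal confirmation
#'   (default 0.10).
#' @param orth_ihc_prob,orth_pcr_prob Method probabilities given
#'   confirmation (defaults 0.66 and 0.38).
#' @param orth_ihc_prob_alk,orth_pcr_prob_met Gene-conditional overrides
#'   (defaults 0.86 for ALK by IHC, 0.75 for MET exon 14 by PCR).
#' @param tat_base_mean,tat_shape Base TAT gamma mean (working days) and
#'   shape (defaults 9.44 and 12).
#' @param repeat_delay_mean,repeat_delay_shape Extra delay gamma mean and
#'   shape for retest/orthogonal cases (defaults 3.35 and 4).
#' @param seed Default random seed for [generate_cohort()] (optional
#'   here, but a seed must be available at generation time).
#' @return A validated `cohort_params` object.
#' @export
cohort_params <- function(n = 210L, advanced_prob = 0.781,
                          variant_table = default_variant_table(),
                          retest_prob = 0.038, orthogonal_prob = 0.10,
                          orth_ihc_prob = 0.66, orth_pcr_prob = 0.38,
                          orth_ihc_prob_alk = 0.86,
                          orth_pcr_prob_met = 0.75,
                          tat_base_mean = 9.44, tat_shape = 12,
                          repeat_delay_mean = 3.35,
                          repeat_delay_shape = 4, seed = NULL) {
  n <- as.integer(n)
  if (is.na(n) || n < 0L) stop("n must be an integer >= 0", call. = FALSE)
  probs <- c(advanced_prob = advanced_prob, retest_prob = retest_prob,
             orthogonal_prob = orthogonal_prob,
             orth_ihc_prob = orth_ihc_prob, orth_pcr_prob = orth_pcr_prob,
             orth_ihc_prob_alk = orth_ihc_prob_alk,
             orth_pcr_prob_met = orth_pcr_prob_met)
  bad <- probs < 0 | probs > 1 | !is.finite(probs)
  if (any(bad)) {
    stop("probabilities out of [0, 1]: ",
         paste(names(probs)[bad], collapse = ", "), call. = FALSE)
  }
  stopifnot(is.data.frame(variant_table),
            all(c("gene", "tier", "freq", "reimbursed") %in%
                  names(variant_table)))
  if (any(variant_table$freq < 0) || sum(variant_table$freq) > 1 + 1e-9) {
    stop("variant frequencies must be >= 0 and sum to at most 1",
         call. = FALSE)
  }
  stopifnot(tat_base_mean > 0, tat_shape > 0, repeat_delay_mean >= 0,
            repeat_delay_shape > 0)
  structure(list(n = n, advanced_prob = advanced_prob,
                 variant_table = variant_table, retest_prob = retest_prob,
                 orthogonal_prob = orthogonal_prob,
                 orth_ihc_prob = orth_ihc_prob,
                 orth_pcr_prob = orth_pcr_prob,
                 orth_ihc_prob_alk = orth_ihc_prob_alk,
                 orth_pcr_prob_met = orth_pcr_prob_met,
                 tat_base_mean = tat_base_mean, tat_shape = tat_shape,
                 repeat_delay_mean = repeat_delay_mean,
                 repeat_delay_shape = repeat_delay_shape, seed = seed),
            class = "cohort_params")
}

params_hash <- function(params) {
  f <- tempfile()
  on.exit(unlink(f))
  # canonical text serialization -> md5, independent of list attributes
  writeLines(utils::capture.output(utils::str(unclass(params),
                                              digits.d = 15)), f)
  unname(tools::md5sum(f))
}

#' Generate a seeded synthetic cohort
#'
#' Draws one row per case: stage, actionable variant (at most one driver
#' per case, reflecting the near mutual exclusivity of NSCLC drivers),
#' retest and orthogonal-confirmation events, TAT in working days, and a
#' therapy gene for advanced-stage cases whose driver has a reimbursed
#' targeted drug. Deterministic for a fixed seed; the caller's RNG state
#' is restored on exit. Seed and a parameter hash travel with the cohort
#' as attributes (and into the sidecar written by [write_cohort()]).
#'
#' @param params A [cohort_params()] object.
#' @param seed Integer seed; defaults to `params$seed`, and one of the
#'   two must be given.
#' @return A `synthetic_cohort` data frame with columns `case_id`,
#'   `stage`, `gene`, `escat_tier`, `retest`, `orth_ihc`, `orth_pcr`,
#'   `tat_days`, `therapy_gene`.
#' @export
generate_cohort <- function(params, seed = params$seed) {
  stopifnot(inherits(params, "cohort_params"))
  if (is.null(seed)) stop("a random seed is required", call. = FALSE)
  seed <- as.integer(seed)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)

  n <- params$n
  vt <- params$variant_table
  empty <- data.frame(case_id = character(0), stage = character(0),
                      gene = character(0), escat_tier = character(0),
                      retest = logical(0), orth_ihc = logical(0),
                      orth_pcr = logical(0), tat_days = numeric(0),
                      therapy_gene = character(0),
                      stringsAsFactors = FALSE)
  if (n == 0L) {
    return(structure(empty, seed = seed, params = params,
                     params_hash = params_hash(params),
                     class = c("synthetic_cohort", "data.frame")))
  }

  stage <- ifelse(stats::rbinom(n, 1L, params$advanced_prob) == 1L,
                  "advanced", "early")
  gene <- sample(c(vt$gene, "WT"), n, replace = TRUE,
                 prob = c(vt$freq, 1 - sum(vt$freq)))
  tier <- vt$tier[match(gene, vt$gene)]          # NA for WT

  retest <- stats::rbinom(n, 1L, params$retest_prob) == 1L
  confirmed <- stats::rbinom(n, 1L, params$orthogonal_prob) == 1L
  p_ihc <- ifelse(gene == "ALK", params$orth_ihc_prob_alk,
                  params$orth_ihc_prob)
  p_pcr <- ifelse(gene == "MET_ex14", params$orth_pcr_prob_met,
                  params$orth_pcr_prob)
  orth_ihc <- confirmed & stats::rbinom(n, 1L, p_ihc) == 1L
  orth_pcr <- confirmed & stats::rbinom(n, 1L, p_pcr) == 1L
  # "and/or": a confirmed case uses at least one method; when both
  # independent draws miss, fall back to the gene-favoured one (IHC,
  # PCR for MET exon 14)
  neither <- confirmed & !orth_ihc & !orth_pcr
  orth_ihc[neither & gene != "MET_ex14"] <- TRUE
  orth_pcr[neither & gene == "MET_ex14"] <- TRUE

  tat <- stats::rgamma(n, shape = params$tat_shape,
                       scale = params$tat_base_mean / params$tat_shape)
  flagged <- retest | confirmed
  if (any(flagged) && params$repeat_delay_mean > 0) {
    tat[flagged] <- tat[flagged] +
      stats::rgamma(sum(flagged), shape = params$repeat_delay_shape,
                    scale = params$repeat_delay_mean /
                      params$repeat_delay_shape)
  }

  reimb <- vt$gene[vt$reimbursed]
  therapy <- ifelse(stage == "advanced" & gene %in% reimb, gene,
                    NA_character_)

  cohort <- data.frame(
    case_id = sprintf("case_%04d", seq_len(n)), stage = stage,
    gene = gene, escat_tier = tier, retest = retest,
    orth_ihc = orth_ihc, orth_pcr = orth_pcr, tat_days = tat,
    therapy_gene = therapy, stringsAsFactors = FALSE)
  structure(cohort, seed = seed, params = params,
            params_hash = params_hash(params),
            class = c("synthetic_cohort", "data.frame"))
}

#' Summarize a cohort
#'
#' Counts by stage, gene and ESCAT tier, retest and orthogonal rates and
#' TAT statistics. With `exclude_repeats = TRUE` the TAT mean and median
#' drop cases flagged retest or orthogonal confirmation, isolating the
#' routine-workflow turnaround.
#'
#' @param cohort A non-empty `synthetic_cohort` (or compatible data
#'   frame).
#' @param exclude_repeats Drop retest/orthogonal cases from the TAT
#'   statistics?
#' @return A `cohort_summary` list.
#' @export
summarize_cohort <- function(cohort, exclude_repeats = FALSE) {
  stopifnot(is.data.frame(cohort))
  if (nrow(cohort) == 0L) stop("cannot summarize an empty cohort",
                               call. = FALSE)
  flagged <- cohort$retest | cohort$orth_ihc | cohort$orth_pcr
  tat <- if (exclude_repeats) cohort$tat_days[!flagged]
         else cohort$tat_days
  structure(list(
    n = nrow(cohort),
    n_advanced = sum(cohort$stage == "advanced"),
    advanced_fraction = mean(cohort$stage == "advanced"),
    gene_counts = table(cohort$gene),
    tier_counts = table(cohort$escat_tier, useNA = "ifany"),
    n_escat_i_ii = sum(cohort$escat_tier %in% c("I", "II"), na.rm = TRUE),
    n_reimbursed_eligible = sum(!is.na(cohort$therapy_gene)),
    retest_rate = mean(cohort$retest),
    orthogonal_rate = mean(cohort$orth_ihc | cohort$orth_pcr),
    tat_mean = mean(tat), tat_median = stats::median(tat),
    exclude_repeats = exclude_repeats
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort of %d cases: %d advanced (%.1f%%)\n", x$n,
              x$n_advanced, 100 * x$advanced_fraction))
  cat(sprintf("  ESCAT I-II variants: %d; reimbursed-therapy eligible: %d\n",
              x$n_escat_i_ii, x$n_reimbursed_eligible))
  cat(sprintf("  retest %.1f%%, orthogonal confirmation %.1f%%\n",
              100 * x$retest_rate, 100 * x$orthogonal_rate))
  cat(sprintf("  TAT mean %.2f, median %.2f working days%s\n", x$tat_mean,
              x$tat_median,
              if (x$exclude_repeats) " (repeats excluded)" else ""))
  invisible(x)
}

#' Write a cohort to CSV with a JSON provenance sidecar
#'
#' The CSV has one row per case; `<path>.json` records the seed and the
#' parameter hash so any run can be reproduced exactly.
#'
#' @param cohort A `synthetic_cohort`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  sidecar <- list(seed = attr(cohort, "seed"),
                  params_hash = attr(cohort, "params_hash"),
                  n = nrow(cohort))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a cohort CSV written by [write_cohort()]
#' @param path CSV path.
#' @return A data frame with the cohort columns.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$escat_tier <- as.character(df$escat_tier)
  df$therapy_gene <- as.character(df$therapy_gene)
  df
}
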