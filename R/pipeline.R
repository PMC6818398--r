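#' @importFrom jsonlite write_json
NULL

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

.pairedBy <- function(repertoires) {
  pats <- vapply(repertoires, patientId, character(1))
  tis <- vapply(repertoires, tissue, character(1))
  out <- lapply(unique(pats), function(p) {
    it <- which(pats == p & tis == "tumor")
    ino <- which(pats == p & tis == "normal")
    if (length(it) != 1L || length(ino) != 1L)
      stop("patient ", p, " does not have exactly one tumor and one ",
           "normal repertoire")
    list(tumor = repertoires[[it]], normal = repertoires[[ino]])
  })
  names(out) <- unique(pats)
  out
}

#' Run the full paired-repertoire comparison pipeline
#'
#' End-to-end orchestration: load (or accept) per-sample clonotype tables
#' and cohort metadata, compute per-sample metrics (reads, unique clones,
#' inverse Simpson DI, HEC rate, top-N cumulative frequency, frequency
#' spectrum, CDR3 peak length), within-patient tumor/normal overlap at nt
#' and aa resolution, V/J usage profiles with paired differential usage,
#' paired cohort tests on every per-sample quantity (both the Wilcoxon
#' signed-rank test and the Mann-Whitney U test are reported for each,
#' clearly labeled, since published repertoire studies have used either on
#' paired diversity values), clinical-covariate comparisons of tumor DI
#' (age at 60 years, TNM stage, differentiation), and a survival analysis
#' stratified at the median tumor DI (Kaplan-Meier + log-rank, overall and
#' disease-free when the metadata carries those fields). Every stage is a
#' pure function of inputs and parameters; rerunning the same inputs gives
#' identical outputs.
#'
#' @param input either a directory containing \code{<patient>_<tissue>.tsv}
#'   clonotype tables (plus optionally \code{metadata.tsv}), or a list of
#'   \linkS4class{Repertoire} objects.
#' @param metadata cohort metadata data.frame, or path to its TSV; may be
#'   omitted when \code{input} is a directory containing
#'   \code{metadata.tsv}.
#' @param outDir optional output directory: per-stage TSV reports, a
#'   \code{summary.json} with headline numbers, and a \code{run.log}.
#' @param keyLevel key level for per-sample metrics.
#' @param overlapLevels key levels for the overlap stage.
#' @param hecThresholdPercent,topN,spectrumEdges metric parameters.
#' @param usageWeighting \code{"reads"} or \code{"clones"}.
#' @param dialect clonotype-table dialect when reading from a directory.
#' @return (Invisibly) a list of all result tables: \code{metrics},
#'   \code{overlap}, \code{usage}, \code{differential_v},
#'   \code{differential_j}, \code{cohort}, \code{covariates},
#'   \code{survival}, \code{summary}.
#' @export
runPipeline <- function(input, metadata = NULL, outDir = NULL,
                        keyLevel = "nt+VJ",
                        overlapLevels = c("nt", "aa"),
                        hecThresholdPercent = 0.1, topN = 100,
                        spectrumEdges = c(1e-4, 1e-3, 1e-2, 0.1),
                        usageWeighting = "reads",
                        dialect = "native") {
  reps <- .stage("load", {
    if (is.character(input)) {
      files <- sort(list.files(input, pattern = "\\.tsv$", full.names = TRUE))
      files <- files[basename(files) != "metadata.tsv"]
      if (!length(files)) stop("no clonotype tables found in ", input)
      out <- lapply(files, readClonotypeTable, dialect = dialect)
      names(out) <- vapply(out, sampleId, character(1))
      out
    } else {
      stopifnot(is.list(input), all(vapply(input, is, logical(1),
                                           "Repertoire")))
      input
    }
  })
  md <- .stage("metadata", {
    if (is.character(metadata)) readMetadata(metadata)
    else if (is.data.frame(metadata)) metadata
    else if (is.character(input) &&
             file.exists(file.path(input, "metadata.tsv")))
      readMetadata(file.path(input, "metadata.tsv"))
    else NULL
  })
  pairs <- .stage("pairing", .pairedBy(reps))
  pids <- names(pairs)
  if (!is.null(md)) {
    missing <- setdiff(pids, md$patient_id)
    if (length(missing))
      stop("pipeline stage 'pairing' failed: patient ", missing[1L],
           " absent from metadata")
  }

  reps <- .stage("aggregate", lapply(reps, function(r)
    if (keyLevel != r@keyLevel) aggregateRepertoire(r, keyLevel) else r))

  metrics <- .stage("metrics", do.call(rbind, lapply(reps, sampleMetrics,
    hecThresholdPercent = hecThresholdPercent, topN = topN,
    binEdges = spectrumEdges)))
  rownames(metrics) <- NULL

  overlap <- .stage("overlap", do.call(rbind, lapply(pids, function(p) {
    do.call(rbind, lapply(overlapLevels, function(lvl)
      overlapRate(pairs[[p]]$tumor, pairs[[p]]$normal, level = lvl)))
  })))

  usageStage <- .stage("usage", {
    profs <- list()
    rows <- list()
    for (locus in c("V", "J")) {
      for (ti in c("tumor", "normal")) {
        profs[[locus]][[ti]] <- lapply(pairs, function(pr)
          usageProfile(pr[[ti]], locus = locus,
                       weighting = usageWeighting))
        for (p in pids) {
          pf <- profs[[locus]][[ti]][[p]]
          rows[[length(rows) + 1L]] <- data.frame(
            sample_id = sampleId(pairs[[p]][[ti]]), locus = locus,
            level = "segment", segment = names(pf),
            frequency = unname(pf), stringsAsFactors = FALSE)
        }
      }
    }
    list(table = do.call(rbind, rows), profiles = profs)
  })
  diffV <- .stage("differential_usage_v",
    differentialUsage(usageStage$profiles$V$tumor,
                      usageStage$profiles$V$normal))
  diffJ <- .stage("differential_usage_j",
    differentialUsage(usageStage$profiles$J$tumor,
                      usageStage$profiles$J$normal))

  cohort <- .stage("cohort_tests", {
    getMetric <- function(m, ti) vapply(pids, function(p) {
      s <- sampleId(pairs[[p]][[ti]])
      metrics$value[metrics$sample_id == s & metrics$metric == m]
    }, numeric(1))
    quantities <- c("total_reads", "n_unique", "inverse_simpson_di",
                    "hec_rate_pct", "topn_cumulative_pct")
    do.call(rbind, lapply(quantities, function(m) {
      tv <- getMetric(m, "tumor"); nv <- getMetric(m, "normal")
      # a quantity can be identical in every pair (e.g. fixed sequencing
      # depth in simulations); that is a degenerate, not an error, here
      w <- tryCatch(wilcoxonSignedRank(tv, nv)$p_two_tailed,
                    error = function(e) NA_real_)
      u <- mannWhitneyU(tv, nv)
      data.frame(quantity = m,
                 mean_tumor = mean(tv), sd_tumor = sd(tv),
                 mean_normal = mean(nv), sd_normal = sd(nv),
                 p_wilcoxon_signed_rank = w,
                 p_mann_whitney_u = u$p_two_tailed,
                 stringsAsFactors = FALSE)
    }))
  })

  diTumor <- vapply(pids, function(p)
    metrics$value[metrics$sample_id == sampleId(pairs[[p]]$tumor) &
                  metrics$metric == "inverse_simpson_di"], numeric(1))

  covariates <- .stage("covariates", {
    if (is.null(md)) NULL else {
      grps <- c("age", "tnm_stage", "differentiation")
      do.call(rbind, lapply(grps, function(g) {
        res <- tryCatch(compareByCovariate(diTumor, md, g),
                        error = function(e) NULL)
        if (is.null(res)) return(NULL)
        data.frame(grouping = g, test = res$test_name,
                   statistic = res$statistic, p = res$p_two_tailed,
                   groups = paste(sprintf("%s: %.1f +/- %.1f (n=%d)",
                                          res$summaries$group,
                                          res$summaries$mean,
                                          ifelse(is.na(res$summaries$sd), 0,
                                                 res$summaries$sd),
                                          res$summaries$n),
                                  collapse = "; "),
                   stringsAsFactors = FALSE)
      }))
    }
  })

  survivalRes <- .stage("survival", {
    if (is.null(md) || !all(c("os_time", "os_event") %in% names(md)))
      NULL
    else {
      idx <- match(pids, md$patient_id)
      out <- list()
      for (ep in c("os", "dfs")) {
        tc <- paste0(ep, "_time"); ec <- paste0(ep, "_event")
        if (all(c(tc, ec) %in% names(md)) && !anyNA(md[[tc]][idx])) {
          out[[ep]] <- tryCatch(
            diStratifiedSurvival(diTumor, md[[tc]][idx], md[[ec]][idx]),
            error = function(e) NULL)
        }
      }
      out
    }
  })

  summary <- list(
    n_patients = length(pids),
    key_level = keyLevel,
    mean_di_tumor = mean(cohort$mean_tumor[
      cohort$quantity == "inverse_simpson_di"]),
    mean_di_normal = mean(cohort$mean_normal[
      cohort$quantity == "inverse_simpson_di"]),
    mean_hec_rate_pct_tumor = cohort$mean_tumor[
      cohort$quantity == "hec_rate_pct"],
    mean_hec_rate_pct_normal = cohort$mean_normal[
      cohort$quantity == "hec_rate_pct"],
    mean_topn_cumulative_pct_tumor = cohort$mean_tumor[
      cohort$quantity == "topn_cumulative_pct"],
    mean_topn_cumulative_pct_normal = cohort$mean_normal[
      cohort$quantity == "topn_cumulative_pct"],
    mean_overlap_nt_tumor = mean(overlap$rate_tumor[
      overlap$key_level == "nt"]),
    mean_overlap_nt_normal = mean(overlap$rate_normal[
      overlap$key_level == "nt"]),
    mean_overlap_aa_tumor = mean(overlap$rate_tumor[
      overlap$key_level == "aa"]),
    mean_overlap_aa_normal = mean(overlap$rate_normal[
      overlap$key_level == "aa"]),
    p_di_wilcoxon = cohort$p_wilcoxon_signed_rank[
      cohort$quantity == "inverse_simpson_di"],
    p_di_mann_whitney = cohort$p_mann_whitney_u[
      cohort$quantity == "inverse_simpson_di"],
    p_hec_wilcoxon = cohort$p_wilcoxon_signed_rank[
      cohort$quantity == "hec_rate_pct"],
    significant_v_segments = diffV$segment[diffV$significant],
    p_logrank_os = if (!is.null(survivalRes$os))
      survivalRes$os$logrank$p_two_tailed else NA,
    p_logrank_dfs = if (!is.null(survivalRes$dfs))
      survivalRes$dfs$logrank$p_two_tailed else NA
  )

  result <- list(metrics = metrics, overlap = overlap,
                 usage = usageStage$table,
                 differential_v = diffV, differential_j = diffJ,
                 cohort = cohort, covariates = covariates,
                 survival = survivalRes, summary = summary)

  if (!is.null(outDir)) .stage("report", {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    wt <- function(df, name) if (!is.null(df))
      write.table(df, file.path(outDir, name), sep = "\t", quote = FALSE,
                  row.names = FALSE)
    wt(metrics, "metrics.tsv")
    wt(overlap, "overlap.tsv")
    wt(usageStage$table, "usage.tsv")
    wt(diffV, "differential_usage_V.tsv")
    wt(diffJ, "differential_usage_J.tsv")
    wt(cohort, "cohort_tests.tsv")
    wt(covariates, "covariates.tsv")
    if (!is.null(survivalRes)) for (ep in names(survivalRes)) {
      sr <- survivalRes[[ep]]
      if (is.null(sr)) next
      tab <- do.call(rbind, lapply(names(sr$km), function(g) {
        k <- sr$km[[g]]; k$group <- g; k
      }))
      wt(tab, paste0("survival_", ep, ".tsv"))
    }
    write_json(summary, file.path(outDir, "summary.json"),
               auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(c(
      paste0("TCRcompare ",
             as.character(utils::packageVersion("TCRcompare"))),
      paste0("run at: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
      paste0("patients: ", length(pids)),
      paste0("key_level: ", keyLevel),
      paste0("hec_threshold_percent: ", hecThresholdPercent),
      paste0("top_n: ", topN),
      paste0("spectrum_edges_percent: ",
             paste(spectrumEdges, collapse = ",")),
      paste0("usage_weighting: ", usageWeighting)
    ), file.path(outDir, "run.log"))
  })

  invisible(result)
}
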