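#' @import methods
NULL

.KEY_LEVELS <- c("nt+VJ" = 3L, "nt" = 2L, "aa" = 1L)

.keyColumns <- function(keyLevel) {
  switch(keyLevel,
    "nt+VJ" = c("cdr3_nt", "v_segment", "j_segment"),
    "nt"    = "cdr3_nt",
    "aa"    = "cdr3_aa",
    stop("unknown key level: ", keyLevel)
  )
}

#' Repertoire: one sample's clonotype collection
#'
#' An S4 container for the productive TCR-beta clonotypes of a single
#' tissue sample. Clonotypes are unique under the active key level:
#' \code{"nt+VJ"} (CDR3 nucleotide sequence plus V and J segment, the
#' finest level), \code{"nt"} (CDR3 nucleotide sequence) or \code{"aa"}
#' (CDR3 amino-acid sequence, the coarsest). Read counts proxy clone
#' sizes; \code{totalReads} always equals the sum of counts.
#'
#' @slot sampleId sample identifier.
#' @slot patientId patient identifier ("" if unknown).
#' @slot tissue tissue label, normally \code{"tumor"} or \code{"normal"}.
#' @slot keyLevel active aggregation level.
#' @slot clonotypes data.frame with columns \code{cdr3_nt}, \code{cdr3_aa},
#'   \code{v_segment}, \code{j_segment}, \code{count} (columns not defined
#'   at the active level hold \code{NA}).
#' @slot totalReads sum of clonotype counts.
#' @slot metadata free-form list (e.g., the rejected-row tally from
#'   \code{\link{readClonotypeTable}}).
#'
#' @seealso \code{\link{Repertoire}} (constructor),
#'   \code{\link{aggregateRepertoire}}, \code{\link{inverseSimpson}}
#' @export
setClass("Repertoire",
  representation(
    sampleId   = "character",
    patientId  = "character",
    tissue     = "character",
    keyLevel   = "character",
    clonotypes = "data.frame",
    totalReads = "numeric",
    metadata   = "list"
  )
)

setValidity("Repertoire", function(object) {
  msg <- character(0)
  df <- object@clonotypes
  lvl <- object@keyLevel
  if (length(lvl) != 1L || !lvl %in% names(.KEY_LEVELS))
    return(sprintf("keyLevel must be one of %s",
                   paste(names(.KEY_LEVELS), collapse = ", ")))
  need <- c(.keyColumns(lvl), "count")
  miss <- setdiff(need, names(df))
  if (length(miss))
    msg <- c(msg, paste("missing clonotype column(s):",
                        paste(miss, collapse = ", ")))
  if (!length(msg) && nrow(df)) {
    if (any(is.na(df$count)) || any(df$count < 1))
      msg <- c(msg, "all counts must be >= 1")
    keys <- do.call(paste, c(df[.keyColumns(lvl)], sep = "|"))
    if (anyDuplicated(keys))
      msg <- c(msg, "duplicate clonotype keys at the active key level")
    if ("cdr3_aa" %in% names(df)) {
      aa <- df$cdr3_aa
      if (any(grepl("*", aa[!is.na(aa)], fixed = TRUE)))
        msg <- c(msg, "cdr3_aa contains a stop symbol '*' (non-productive)")
      if ("cdr3_nt" %in% names(df)) {
        both <- !is.na(aa) & !is.na(df$cdr3_nt)
        if (any(nchar(df$cdr3_nt[both]) != 3L * nchar(aa[both])))
          msg <- c(msg, "cdr3_nt length must be 3 x cdr3_aa length")
      }
    }
  }
  if (!isTRUE(all.equal(object@totalReads, sum(df$count))) &&
      !(nrow(df) == 0L && object@totalReads == 0))
    msg <- c(msg, "totalReads must equal the sum of clonotype counts")
  if (length(msg)) msg else TRUE
})

#' Construct a Repertoire
#'
#' Builds a validated \linkS4class{Repertoire} from a clonotype
#' data.frame. Rows sharing the same key at \code{keyLevel} are merged by
#' summing their counts (upstream tools differ in how far they aggregate,
#' so duplicates are not treated as an error).
#'
#' @param clonotypes data.frame with (a subset of) columns \code{cdr3_nt},
#'   \code{cdr3_aa}, \code{v_segment}, \code{j_segment} and a \code{count}
#'   column of positive integers.
#' @param sampleId,patientId,tissue sample annotation strings.
#' @param keyLevel one of \code{"nt+VJ"}, \code{"nt"}, \code{"aa"}.
#' @param metadata optional list stored alongside the data.
#' @return A \linkS4class{Repertoire}.
#' @examples
#' df <- data.frame(cdr3_nt = c("TGTGCC", "TGTTTT"),
#'                  cdr3_aa = c("CA", "CF"),
#'                  v_segment = "TRBV20-1", j_segment = "TRBJ2-1",
#'                  count = c(5L, 3L))
#' rep <- Repertoire(df, sampleId = "S1", tissue = "tumor")
#' totalReads(rep)
#' @export
Repertoire <- function(clonotypes, sampleId = "sample",
                       patientId = "", tissue = NA_character_,
                       keyLevel = "nt+VJ", metadata = list()) {
  stopifnot(is.data.frame(clonotypes))
  for (col in c("cdr3_nt", "cdr3_aa", "v_segment", "j_segment"))
    if (!col %in% names(clonotypes)) clonotypes[[col]] <- NA_character_
  if (!"count" %in% names(clonotypes))
    stop("clonotypes must have a 'count' column")
  clonotypes <- clonotypes[c("cdr3_nt", "cdr3_aa", "v_segment",
                             "j_segment", "count")]
  clonotypes$count <- as.numeric(clonotypes$count)
  keys <- do.call(paste, c(clonotypes[.keyColumns(keyLevel)], sep = "|"))
  if (anyDuplicated(keys)) {
    cnt <- rowsum(clonotypes$count, keys, reorder = FALSE)
    first <- !duplicated(keys)
    clonotypes <- clonotypes[first, , drop = FALSE]
    clonotypes$count <- cnt[match(keys[first], rownames(cnt)), 1L]
  }
  rownames(clonotypes) <- NULL
  new("Repertoire", sampleId = as.character(sampleId),
      patientId = as.character(patientId), tissue = as.character(tissue),
      keyLevel = keyLevel, clonotypes = clonotypes,
      totalReads = sum(clonotypes$count), metadata = metadata)
}

setMethod("show", "Repertoire", function(object) {
  cat("Repertoire object\n",
      "  sample:  ", object@sampleId,
      if (nzchar(object@patientId))
        paste0(" (patient ", object@patientId, ", ", object@tissue, ")"),
      "\n",
      "  key level: ", object@keyLevel, "\n",
      "  unique clonotypes: ", nrow(object@clonotypes), "\n",
      "  total reads: ", format(object@totalReads, big.mark = ","), "\n",
      sep = "")
})

#' Synthetic paired-cohort configuration
#'
#' All knobs of the synthetic tumor/normal repertoire generator: cohort
#' size, per-tissue unique-clone pool sizes and sequencing depth, the
#' clone-abundance law and its per-tissue parameters, the fraction of the
#' normal-tissue clone pool shared with the matched tumor, V/J segment
#' usage profiles (with an optional tumor-specific fold change per V
#' segment), the CDR3 amino-acid length law, an age effect on tumor
#' diversity, and the survival model (exponential, hazard ratio for the
#' high-diversity group, independent exponential censoring).
#'
#' @seealso \code{\link{syntheticCohortConfig}},
#'   \code{\link{generatePairedCohort}}
#' @export
setClass("SyntheticCohortConfig",
  representation(
    nPatients          = "numeric",
    clonesTumor        = "numeric",
    clonesNormal       = "numeric",
    readsPerSample     = "numeric",
    abundanceLaw       = "character",
    tumorParam         = "numeric",
    normalParam        = "numeric",
    sharedFraction     = "numeric",
    vProfile           = "numeric",
    jProfile           = "numeric",
    vFoldTumor         = "numeric",
    cdr3LengthProbs    = "numeric",
    ageEffectOnDI      = "numeric",
    baselineHazard     = "numeric",
    hazardRatioHighDI  = "numeric",
    censoringRate      = "numeric",
    seed               = "numeric"
  )
)

setValidity("SyntheticCohortConfig", function(object) {
  msg <- character(0)
  pos <- c(nPatients = object@nPatients, clonesTumor = object@clonesTumor,
           clonesNormal = object@clonesNormal,
           readsPerSample = object@readsPerSample)
  if (any(pos < 1)) msg <- c(msg, "counts and depths must be positive")
  if (!object@abundanceLaw %in% c("zipf", "lognormal"))
    msg <- c(msg, "abundanceLaw must be 'zipf' or 'lognormal'")
  if (object@abundanceLaw == "zipf" &&
      (object@tumorParam < 0 || object@normalParam < 0))
    msg <- c(msg, "zipf exponents must be >= 0")
  if (object@sharedFraction < 0 || object@sharedFraction > 1)
    msg <- c(msg, "sharedFraction must lie in [0, 1]")
  for (nm in c("vProfile", "jProfile", "cdr3LengthProbs")) {
    p <- slot(object, nm)
    if (is.null(names(p)) || any(p < 0) ||
        abs(sum(p) - 1) > 1e-6)
      msg <- c(msg, paste(nm, "must be a named probability vector summing to 1"))
  }
  if (length(object@vFoldTumor) &&
      (is.null(names(object@vFoldTumor)) || any(object@vFoldTumor <= 0)))
    msg <- c(msg, "vFoldTumor must be a named vector of positive folds")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SyntheticCohortConfig", function(object) {
  cat("SyntheticCohortConfig\n",
      sprintf("  %d patients, %s/%s unique clones (tumor/normal), %s reads/sample\n",
              object@nPatients, format(object@clonesTumor, big.mark = ","),
              format(object@clonesNormal, big.mark = ","),
              format(object@readsPerSample, big.mark = ",")),
      sprintf("  abundance law: %s (tumor %.3g, normal %.3g), shared fraction %.2f\n",
              object@abundanceLaw, object@tumorParam, object@normalParam,
              object@sharedFraction),
      sprintf("  survival: baseline hazard %.3g/month, HR(high-DI) %.2f, censoring %.3g\n",
              object@baselineHazard, object@hazardRatioHighDI,
              object@censoringRate),
      sprintf("  seed: %d\n", as.integer(object@seed)), sep = "")
})
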