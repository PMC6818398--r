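#' @importFrom utils read.delim write.table
NULL

# Header maps for the supported clonotype-table dialects. Frequency columns
# present in vdjtools-style output are ignored and recomputed from counts, so
# upstream normalisation is never trusted.
.DIALECTS <- list(
  native   = c(cdr3_nt = "cdr3_nt", cdr3_aa = "cdr3_aa",
               v_segment = "v_segment", j_segment = "j_segment",
               count = "count"),
  vdjtools = c(cdr3_nt = "cdr3nt", cdr3_aa = "cdr3aa",
               v_segment = "v", j_segment = "j", count = "count"),
  airr     = c(cdr3_nt = "junction", cdr3_aa = "junction_aa",
               v_segment = "v_call", j_segment = "j_call",
               count = "duplicate_count")
)

.stripAllele <- function(x) sub("\\*.*$", "", x)

#' Read a clonotype table
#'
#' Reads a tab-separated clonotype table (one row per rearrangement:
#' CDR3 nucleotide and amino-acid sequence, V segment, J segment, read
#' count) into a validated \linkS4class{Repertoire} at the \code{"nt+VJ"}
#' key level. Three header dialects are recognised: \code{"native"}
#' (\code{cdr3_nt/cdr3_aa/v_segment/j_segment/count}), \code{"vdjtools"}
#' (\code{cdr3nt/cdr3aa/v/j/count}) and \code{"airr"}
#' (\code{junction/junction_aa/v_call/j_call/duplicate_count}).
#'
#' Rows are kept only if productive and well-formed: count >= 1, CDR3
#' nucleotide sequence over A/C/G/T with length three times the amino-acid
#' length, and no stop symbol \code{*} in the amino-acid sequence (an
#' in-frame premature stop marks a non-productive rearrangement). Failing
#' rows are dropped and tallied, never fatal, mirroring a productive-only
#' analysis. Allele suffixes (\code{*01}) on segment names are stripped;
#' duplicate keys are merged by summing counts.
#'
#' @param path path to a UTF-8, tab-separated file with a header row.
#' @param dialect one of \code{"native"}, \code{"vdjtools"}, \code{"airr"}.
#' @param sampleId,patientId,tissue sample annotation (default: file name
#'   stem, parsed as \code{<patient>_<tissue>} when it matches).
#' @return A \linkS4class{Repertoire}; \code{repMetadata(x)$rejectedRows}
#'   holds the number of dropped input rows and
#'   \code{repMetadata(x)$inputRows} the number read.
#' @seealso \code{\link{writeClonotypeTable}}, \code{\link{readMetadata}}
#' @export
readClonotypeTable <- function(path,
                               dialect = c("native", "vdjtools", "airr"),
                               sampleId = NULL, patientId = NULL,
                               tissue = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  map <- .DIALECTS[[dialect]]
  raw <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(unname(map), names(raw))
  if (length(miss))
    stop("clonotype table format error (dialect '", dialect,
         "'): missing column(s) ", paste(miss, collapse = ", "))
  df <- data.frame(
    cdr3_nt   = toupper(as.character(raw[[map[["cdr3_nt"]]]])),
    cdr3_aa   = toupper(as.character(raw[[map[["cdr3_aa"]]]])),
    v_segment = .stripAllele(as.character(raw[[map[["v_segment"]]]])),
    j_segment = .stripAllele(as.character(raw[[map[["j_segment"]]]])),
    count     = suppressWarnings(as.numeric(raw[[map[["count"]]]])),
    stringsAsFactors = FALSE
  )
  ok <- !is.na(df$count) & df$count >= 1 &
    !is.na(df$cdr3_nt) & grepl("^[ACGT]+$", df$cdr3_nt) &
    !is.na(df$cdr3_aa) & !grepl("*", df$cdr3_aa, fixed = TRUE) &
    nchar(df$cdr3_nt) == 3L * nchar(df$cdr3_aa)
  rejected <- sum(!ok)
  df <- df[ok, , drop = FALSE]
  if (!nrow(df))
    stop("empty repertoire: no row of ", path,
         " passed the productivity filters")
  stem <- sub("\\.[^.]*$", "", basename(path))
  if (is.null(sampleId)) sampleId <- stem
  if (grepl("_", stem) && (is.null(patientId) || is.null(tissue))) {
    parts <- strsplit(stem, "_", fixed = TRUE)[[1L]]
    if (is.null(patientId)) patientId <- parts[1L]
    if (is.null(tissue)) tissue <- parts[length(parts)]
  }
  Repertoire(df, sampleId = sampleId,
             patientId = if (is.null(patientId)) "" else patientId,
             tissue = if (is.null(tissue)) NA_character_ else tissue,
             keyLevel = "nt+VJ",
             metadata = list(rejectedRows = rejected,
                             inputRows = nrow(raw),
                             path = path, dialect = dialect))
}

#' Write a clonotype table
#'
#' Writes a \linkS4class{Repertoire} as a native-dialect TSV (including a
#' recomputed \code{freq} column). \code{readClonotypeTable} on the result
#' reproduces the keys, counts and totals exactly.
#'
#' @param x a \linkS4class{Repertoire}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeClonotypeTable <- function(x, path) {
  stopifnot(is(x, "Repertoire"))
  df <- x@clonotypes
  df$freq <- df$count / x@totalReads
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.DIFF_LEVELS <- c("L", "M", "H", "unknown")
.STAGE_LEVELS <- c("I", "II", "III")
.PATH_LEVELS <- c("ADC", "SCC", "SCLC")

#' Read a cohort metadata table
#'
#' Reads and validates the per-patient clinical table: columns
#' \code{patient_id}, \code{age}, \code{sex}, \code{path_type}
#' (ADC/SCC/SCLC), \code{differentiation} (L/M/H; \code{"-"}, \code{"–"}
#' or empty map to \code{"unknown"}), \code{tnm_stage} (I/II/III) and,
#' optionally, right-censored survival fields \code{os_time},
#' \code{os_event}, \code{dfs_time}, \code{dfs_event} (times in months,
#' events 0/1).
#'
#' @param path path to a tab-separated file, one row per patient.
#' @return A validated data.frame, one row per patient.
#' @export
readMetadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!nrow(df)) stop("metadata validation error: empty file ", path)
  need <- c("patient_id", "age", "sex", "path_type", "differentiation",
            "tnm_stage")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("metadata format error: missing column(s) ",
         paste(miss, collapse = ", "))
  df$patient_id <- as.character(df$patient_id)
  if (anyDuplicated(df$patient_id))
    stop("metadata validation error: duplicated patient_id")
  age <- suppressWarnings(as.numeric(df$age))
  bad <- which(is.na(age) | age <= 0)
  if (length(bad))
    stop("metadata validation error: non-numeric or non-positive age in row ",
         bad[1L])
  df$age <- age
  d <- as.character(df$differentiation)
  d[d %in% c("-", "–", "", NA)] <- "unknown"
  bad <- which(!d %in% .DIFF_LEVELS)
  if (length(bad))
    stop("metadata validation error: unknown differentiation code '",
         df$differentiation[bad[1L]], "' in row ", bad[1L])
  df$differentiation <- d
  st <- as.character(df$tnm_stage)
  bad <- which(!st %in% .STAGE_LEVELS)
  if (length(bad))
    stop("metadata validation error: unknown TNM stage '", st[bad[1L]],
         "' in row ", bad[1L])
  df$tnm_stage <- st
  bad <- which(!df$path_type %in% .PATH_LEVELS)
  if (length(bad))
    stop("metadata validation error: unknown pathological type '",
         df$path_type[bad[1L]], "' in row ", bad[1L])
  for (col in c("os_event", "dfs_event")) {
    if (col %in% names(df)) {
      v <- df[[col]][!is.na(df[[col]])]
      if (length(v) && !all(v %in% c(0, 1)))
        stop("metadata validation error: ", col, " must be 0/1")
    }
  }
  for (col in c("os_time", "dfs_time")) {
    if (col %in% names(df)) {
      v <- df[[col]][!is.na(df[[col]])]
      if (length(v) && any(v < 0))
        stop("metadata validation error: ", col, " must be >= 0")
    }
  }
  df
}
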