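#' Shared clonotypes between two repertoires
#'
#' Exact string-equality intersection of clonotype keys at the requested
#' resolution. Shared clones are CDR3 nucleotide (\code{"nt"}) or
#' amino-acid (\code{"aa"}) sequences present in both repertoires;
#' \code{"nt+VJ"} additionally requires identical V and J segments. Each
#' repertoire is re-aggregated to the requested level first, so amino-acid
#' sharing is never smaller than nucleotide sharing (translation is
#' many-to-one).
#'
#' @param a,b \linkS4class{Repertoire} objects, normally the paired tumor
#'   and normal samples of one patient.
#' @param level key level of the comparison; default \code{"nt"}.
#' @return Character vector of shared clone keys.
#' @export
sharedClones <- function(a, b, level = c("nt", "aa", "nt+VJ")) {
  level <- match.arg(level)
  intersect(clonotypeKeys(aggregateRepertoire(a, level)),
            clonotypeKeys(aggregateRepertoire(b, level)))
}

#' Within-patient tumor/normal overlap rate
#'
#' Percentage of each tissue's unique clonotypes that are also found in the
#' matched tissue: \eqn{100 |A \cap B| / |A|} for tissue A (per-tissue
#' denominator, so for a fixed intersection the tissue with more unique
#' clones gets the smaller rate).
#'
#' @param a,b paired \linkS4class{Repertoire} objects with distinct
#'   \code{tissue} labels, one \code{"tumor"} and one \code{"normal"}.
#' @param level key level of the comparison (\code{"nt"}, \code{"aa"} or
#'   \code{"nt+VJ"}).
#' @return One-row data.frame: \code{patient_id}, \code{key_level},
#'   \code{shared_count}, \code{rate_tumor}, \code{rate_normal} (percent).
#' @export
overlapRate <- function(a, b, level = c("nt", "aa", "nt+VJ")) {
  level <- match.arg(level)
  if (nUnique(a) == 0L || nUnique(b) == 0L)
    stop("undefined overlap rate: empty repertoire")
  tissues <- c(tissue(a), tissue(b))
  if (!setequal(tissues, c("tumor", "normal")))
    stop("overlapRate expects one 'tumor' and one 'normal' repertoire, got: ",
         paste(tissues, collapse = ", "))
  if (nzchar(patientId(a)) && nzchar(patientId(b)) &&
      patientId(a) != patientId(b))
    stop("repertoires belong to different patients: ",
         patientId(a), " vs ", patientId(b))
  aa_ <- aggregateRepertoire(a, level)
  bb <- aggregateRepertoire(b, level)
  shared <- length(intersect(clonotypeKeys(aa_), clonotypeKeys(bb)))
  rate <- function(r) 100 * shared / nUnique(r)
  tum <- if (tissue(a) == "tumor") aa_ else bb
  nor <- if (tissue(a) == "tumor") bb else aa_
  data.frame(patient_id = if (nzchar(patientId(a))) patientId(a)
                          else patientId(b),
             key_level = level,
             shared_count = shared,
             rate_tumor = rate(tum),
             rate_normal = rate(nor),
             stringsAsFactors = FALSE)
}
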