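#' @importFrom stats t.test p.adjust setNames sd median pnorm pchisq rnorm
#'   rexp rlnorm rmultinom runif
NULL

#' Collapse TRB segment names to gene families
#'
#' Maps TRBV/TRBJ segment names to their gene family: any allele suffix
#' (from \code{*}) is removed, then the name is truncated at the first
#' \code{-}. Names without a sub-family number are their own family, so
#' \code{"TRBV6-5"} gives \code{"TRBV6"} and \code{"TRBV18"} stays
#' \code{"TRBV18"}; the 13 TRBJ segments collapse to the two families
#' TRBJ1 and TRBJ2.
#'
#' @param x character vector of segment names beginning with TRBV or TRBJ.
#' @return Character vector of family names.
#' @export
mergeToFamily <- function(x) {
  bad <- !grepl("^TRB[VJ]", x)
  if (any(bad))
    stop("nomenclature error: not a TRBV/TRBJ name: ", x[bad][1L])
  sub("-.*$", "", sub("\\*.*$", "", x))
}

#' V or J segment usage profile
#'
#' Frequency of each V or J segment (or family) in one repertoire.
#' Read-weighted usage (the default) is the share of the repertoire's read
#' mass carried by clones using the segment; clone-weighted usage is the
#' share of unique clonotypes.
#'
#' @param x a \linkS4class{Repertoire} whose clonotypes carry segment calls
#'   (key level \code{"nt+VJ"}).
#' @param locus \code{"V"} or \code{"J"}.
#' @param level \code{"segment"} or \code{"family"}.
#' @param weighting \code{"reads"} or \code{"clones"}.
#' @return Named numeric vector of frequencies (sums to 1), sorted by
#'   segment name.
#' @export
usageProfile <- function(x, locus = c("V", "J"),
                         level = c("segment", "family"),
                         weighting = c("reads", "clones")) {
  locus <- match.arg(locus)
  level <- match.arg(level)
  weighting <- match.arg(weighting)
  seg <- x@clonotypes[[if (locus == "V") "v_segment" else "j_segment"]]
  if (!nUnique(x) || anyNA(seg))
    stop("segment calls missing: cannot compute ", locus, " usage")
  if (level == "family") seg <- mergeToFamily(seg)
  w <- if (weighting == "reads") x@clonotypes$count else rep(1, length(seg))
  tab <- rowsum(w, seg)
  out <- setNames(tab[, 1L] / sum(w), rownames(tab))
  out[order(names(out), method = "radix")]
}

#' Differential V/J usage between paired tissues
#'
#' Per-segment comparison of usage frequencies between paired tumor and
#' normal samples: a two-tailed paired t-test across patients, a fold
#' change defined as mean tumor frequency over mean normal frequency, and
#' a conjunction significance rule — a segment is flagged only when the
#' fold change exceeds \code{fcThreshold} (or falls below its reciprocal)
#' AND the p-value is below \code{alpha}. Segments absent from a sample
#' enter with frequency 0; a small pseudo-frequency floor keeps the fold
#' change finite when a mean is 0. No multiple-testing correction is
#' applied by default; \code{adjust = "BH"} switches the p gate to
#' Benjamini-Hochberg adjusted values.
#'
#' @param tumorProfiles,normalProfiles named lists (one element per
#'   patient, same patient names in both) of usage profiles as returned by
#'   \code{\link{usageProfile}}.
#' @param fcThreshold fold-change gate (default 1.5).
#' @param alpha p-value gate (default 0.05).
#' @param pseudo pseudo-frequency floor for the fold change.
#' @param adjust \code{"none"} (default) or \code{"BH"}.
#' @return data.frame per segment: \code{segment}, \code{mean_freq_tumor},
#'   \code{mean_freq_normal}, \code{fold_change}, \code{p_value},
#'   \code{p_adjusted}, \code{significant}; sorted by p-value.
#' @export
differentialUsage <- function(tumorProfiles, normalProfiles,
                              fcThreshold = 1.5, alpha = 0.05,
                              pseudo = 1e-6,
                              adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  pats <- names(tumorProfiles)
  if (is.null(pats) || !setequal(pats, names(normalProfiles)))
    stop("tumor and normal profiles must be named by the same patients")
  if (length(pats) < 2L)
    stop("insufficient data: differential usage needs >= 2 patient pairs")
  normalProfiles <- normalProfiles[pats]
  segs <- sort(unique(c(unlist(lapply(tumorProfiles, names)),
                        unlist(lapply(normalProfiles, names)))))
  fill <- function(p) {
    out <- setNames(numeric(length(segs)), segs)
    out[names(p)] <- p
    out
  }
  Tm <- vapply(tumorProfiles, fill, numeric(length(segs)))
  Nm <- vapply(normalProfiles, fill, numeric(length(segs)))
  res <- lapply(segs, function(s) {
    tv <- Tm[s, ]; nv <- Nm[s, ]
    d <- tv - nv
    p <- if (all(d == 0)) 1
         else if (sd(d) == 0) 0  # constant nonzero shift: t statistic infinite
         else t.test(tv, nv, paired = TRUE)$p.value
    mt <- mean(tv); mn <- mean(nv)
    fc <- max(mt, pseudo) / max(mn, pseudo)
    data.frame(segment = s, mean_freq_tumor = mt, mean_freq_normal = mn,
               fold_change = fc, p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adjusted <- p.adjust(out$p_value, method = if (adjust == "BH") "BH"
                                                  else "none")
  gate <- if (adjust == "BH") out$p_adjusted else out$p_value
  out$significant <- (out$fold_change > fcThreshold |
                      out$fold_change < 1 / fcThreshold) & gate < alpha
  out <- out[order(out$p_value, out$segment), , drop = FALSE]
  rownames(out) <- NULL
  out
}
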