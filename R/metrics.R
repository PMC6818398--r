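#' Clone frequencies
#'
#' Read frequencies of the clonotypes at the repertoire's active key level:
#' \eqn{p_i = c_i / \sum_j c_j}. Always sums to 1.
#'
#' @param x a \linkS4class{Repertoire} with at least one read.
#' @return Numeric vector of frequencies, in clonotype-table order.
#' @export
cloneFrequencies <- function(x) {
  stopifnot(is(x, "Repertoire"))
  if (nUnique(x) == 0L || totalReads(x) <= 0)
    stop("undefined frequency: empty repertoire")
  x@clonotypes$count / x@totalReads
}

#' Inverse Simpson diversity index
#'
#' The inverse Simpson diversity index \eqn{DI = 1 / \sum_i p_i^2}: the
#' effective number of equally abundant clones. \eqn{DI = 1} for a
#' monoclonal repertoire and \eqn{DI = N} exactly when all \eqn{N} clones
#' are equally frequent; high values indicate an even clone distribution,
#' low values clonal expansion. The plug-in estimate is used (no
#' rarefaction or bias correction).
#'
#' @param x a \linkS4class{Repertoire}.
#' @return A one-row data.frame with \code{inverse_simpson_di},
#'   \code{n_unique} and \code{key_level}.
#' @examples
#' rep <- Repertoire(data.frame(cdr3_nt = c("AAA", "CCC", "GGG"),
#'                              count = c(5, 3, 2)), keyLevel = "nt")
#' inverseSimpson(rep)$inverse_simpson_di  # 1 / 0.38
#' @export
inverseSimpson <- function(x) {
  p <- cloneFrequencies(x)
  data.frame(inverse_simpson_di = 1 / sum(p^2),
             n_unique = nUnique(x),
             key_level = keyLevel(x),
             stringsAsFactors = FALSE)
}

#' Highly-expanded-clone (HEC) rate
#'
#' Fraction of unique clonotypes whose read frequency strictly exceeds
#' \code{thresholdPercent} percent (default 0.1\%, the conventional HEC
#' cutoff). The denominator is the unique-clone count, not reads, so the
#' rate answers "what share of clones are expanded".
#'
#' @param x a \linkS4class{Repertoire}.
#' @param thresholdPercent frequency threshold in percent; must be >= 0.
#' @return Fraction in [0, 1].
#' @export
hecRate <- function(x, thresholdPercent = 0.1) {
  if (!is.numeric(thresholdPercent) || thresholdPercent < 0)
    stop("parameter error: thresholdPercent must be >= 0")
  p <- cloneFrequencies(x)
  sum(p * 100 > thresholdPercent) / length(p)
}

#' Clone-frequency spectrum
#'
#' Bins unique clonotypes by read frequency. With the default edges
#' (0.0001\%, 0.001\%, 0.01\%, 0.1\%) the bins are: at or below 0.0001\%,
#' three interior intervals, and strictly above 0.1\%. A clone exactly at
#' an edge falls in the lower bin, so the top-bin share equals
#' \code{\link{hecRate}} at the matching threshold.
#'
#' @param x a \linkS4class{Repertoire}.
#' @param binEdges strictly increasing frequency thresholds in percent.
#' @return data.frame with \code{bin} labels and \code{share}, the fraction
#'   of unique clones in each bin (sums to 1).
#' @export
frequencySpectrum <- function(x, binEdges = c(1e-4, 1e-3, 1e-2, 0.1)) {
  if (length(binEdges) < 1L || is.unsorted(binEdges, strictly = TRUE))
    stop("parameter error: binEdges must be strictly increasing")
  fpct <- cloneFrequencies(x) * 100
  idx <- findInterval(fpct, binEdges, left.open = TRUE) + 1L
  k <- length(binEdges)
  labels <- c(paste0("<=", binEdges[1L], "%"),
              if (k > 1L) paste0("(", binEdges[-k], "%,", binEdges[-1L], "%]"),
              paste0(">", binEdges[k], "%"))
  share <- tabulate(idx, nbins = k + 1L) / length(fpct)
  data.frame(bin = labels, share = share, stringsAsFactors = FALSE)
}

.topOrder <- function(x) {
  order(-x@clonotypes$count, clonotypeKeys(x), method = "radix")
}

#' Cumulative frequency of the top-N clones
#'
#' Sum of the read frequencies of the \code{n} most abundant clonotypes,
#' in percent. Ties are broken deterministically: count descending, then
#' clonotype key ascending. If \code{n} is at least the unique-clone count
#' the whole repertoire is covered and 100 is returned.
#'
#' @param x a \linkS4class{Repertoire}.
#' @param n number of top clones (default 100).
#' @return Percent in [0, 100].
#' @export
topNCumulativeFrequency <- function(x, n = 100) {
  if (!is.numeric(n) || n < 1) stop("parameter error: n must be >= 1")
  p <- cloneFrequencies(x)
  ord <- .topOrder(x)
  100 * sum(p[ord[seq_len(min(n, length(p)))]])
}

#' Table of the most abundant clones
#'
#' The top \code{n} clonotypes by read count with their frequencies, using
#' the same deterministic tie rule as \code{\link{topNCumulativeFrequency}}.
#'
#' @param x a \linkS4class{Repertoire}.
#' @param n number of clones to list (default 20).
#' @return data.frame with \code{key}, \code{count}, \code{frequency},
#'   frequencies non-increasing.
#' @export
topClonesTable <- function(x, n = 20) {
  if (!is.numeric(n) || n < 1) stop("parameter error: n must be >= 1")
  ord <- .topOrder(x)
  take <- ord[seq_len(min(n, nUnique(x)))]
  data.frame(key = clonotypeKeys(x)[take],
             count = x@clonotypes$count[take],
             frequency = cloneFrequencies(x)[take],
             stringsAsFactors = FALSE)
}

#' CDR3 amino-acid length distribution (spectratype)
#'
#' Share of the repertoire per CDR3 amino-acid length, weighted by unique
#' clones (default) or by reads. The peak (modal) length is attached as
#' attribute \code{"peak"}.
#'
#' @param x a \linkS4class{Repertoire} whose clonotypes carry amino-acid
#'   sequences.
#' @param weighting \code{"clones"} or \code{"reads"}.
#' @return data.frame with \code{length} and \code{share} (sums to 1);
#'   attribute \code{"peak"} holds the modal length.
#' @export
cdr3LengthDistribution <- function(x, weighting = c("clones", "reads")) {
  weighting <- match.arg(weighting)
  aa <- x@clonotypes$cdr3_aa
  if (!nUnique(x) || anyNA(aa))
    stop("amino-acid sequences missing: cannot compute length distribution")
  len <- nchar(aa)
  w <- if (weighting == "reads") x@clonotypes$count else rep(1, length(len))
  tab <- rowsum(w, len)
  out <- data.frame(length = as.integer(rownames(tab)),
                    share = tab[, 1L] / sum(w))
  rownames(out) <- NULL
  attr(out, "peak") <- out$length[which.max(out$share)]
  out
}

#' Per-sample metric table
#'
#' Computes the standard per-sample summary used by the pipeline: total
#' reads, unique clones at the active, nt and aa levels, inverse Simpson
#' DI, HEC rate (percent), top-N cumulative frequency (percent), spectrum
#' bin shares (percent of unique clones) and CDR3 peak length.
#'
#' @param x a \linkS4class{Repertoire}.
#' @param hecThresholdPercent HEC threshold in percent.
#' @param topN N for the cumulative-frequency statistic.
#' @param binEdges spectrum edges in percent.
#' @return Tidy data.frame: \code{sample_id}, \code{metric}, \code{value}.
#' @export
sampleMetrics <- function(x, hecThresholdPercent = 0.1, topN = 100,
                          binEdges = c(1e-4, 1e-3, 1e-2, 0.1)) {
  di <- inverseSimpson(x)
  spec <- frequencySpectrum(x, binEdges)
  hasAA <- !anyNA(x@clonotypes$cdr3_aa)
  nAt <- function(lvl) tryCatch(nUnique(aggregateRepertoire(x, lvl)),
                                error = function(e) NA_real_)
  vals <- c(
    total_reads = totalReads(x),
    n_unique = nUnique(x),
    n_unique_nt = nAt("nt"),
    n_unique_aa = nAt("aa"),
    inverse_simpson_di = di$inverse_simpson_di,
    hec_rate_pct = 100 * hecRate(x, hecThresholdPercent),
    topn_cumulative_pct = topNCumulativeFrequency(x, topN),
    if (hasAA) c(cdr3_peak_length =
                   attr(cdr3LengthDistribution(x), "peak")),
    stats::setNames(100 * spec$share, paste0("spectrum_", spec$bin))
  )
  data.frame(sample_id = sampleId(x), metric = names(vals),
             value = unname(vals), stringsAsFactors = FALSE)
}
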