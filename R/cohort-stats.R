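# Exact small-sample nonparametric tests, Kaplan-Meier and the log-rank
# test, implemented from their defining formulas so that every small-n
# p-value can be verified against brute-force enumeration.

# Null distribution of 2*W+ for the signed-rank statistic with integerised
# midranks w2 (counts over achievable sums; total mass 2^n).
.signedRankCounts <- function(w2) {
  f <- 1
  for (w in w2) {
    g <- numeric(length(f) + w)
    g[seq_along(f)] <- f
    g[w + seq_along(f)] <- g[w + seq_along(f)] + f
    f <- g
  }
  f  # f[s+1] = number of sign vectors with 2*W+ == s
}

#' Wilcoxon signed-rank test (two-tailed)
#'
#' Paired-sample signed-rank test. Zero differences are dropped (Wilcoxon's
#' convention), tied absolute differences receive midranks, and the
#' statistic is \eqn{W^+}, the rank sum of the positive differences. For
#' \code{n} effective pairs up to \code{exactMax} the two-tailed p-value is
#' exact, from full enumeration of the \eqn{2^n} sign assignments
#' (\eqn{p = \min(1, 2\min(P(W^+\le w), P(W^+\ge w)))}); beyond that a
#' normal approximation with tie correction and a continuity correction of
#' 1/2 is used.
#'
#' @param x numeric vector: first members of the pairs, or the differences
#'   themselves if \code{y} is \code{NULL}.
#' @param y optional numeric vector of second members.
#' @param exactMax largest effective n for which the exact null
#'   distribution is enumerated (default 25).
#' @return List with \code{test_name}, \code{n_effective},
#'   \code{statistic} (\eqn{W^+}), \code{p_two_tailed}, \code{method}.
#' @export
wilcoxonSignedRank <- function(x, y = NULL, exactMax = 25) {
  d <- if (is.null(y)) x else {
    stopifnot(length(x) == length(y))
    x - y
  }
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    stop("degenerate data: all paired differences are zero")
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= exactMax) {
    w2 <- as.integer(round(2 * r))
    f <- .signedRankCounts(w2)
    tot <- 2^n
    s <- as.integer(round(2 * W))
    pLe <- sum(f[seq_len(s + 1L)]) / tot
    pGe <- sum(f[(s + 1L):length(f)]) / tot
    p <- min(1, 2 * min(pLe, pGe))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal-approximation"
  }
  list(test_name = "wilcoxon_signed_rank", n_effective = n,
       statistic = W, p_two_tailed = p, method = method)
}

# Number of ways to choose m of the ranks 1..n with rank sum s, for all s
# (the Mann-Whitney null distribution); classic subset-sum DP.
.rankSumCounts <- function(n, m) {
  maxs <- sum((n - m + 1):n)
  f <- matrix(0, nrow = m + 1L, ncol = maxs + 1L)
  f[1L, 1L] <- 1
  for (i in seq_len(n)) {
    for (k in rev(seq_len(min(i, m)))) {
      shifted <- c(numeric(i), f[k, seq_len(maxs + 1L - i)])
      f[k + 1L, ] <- f[k + 1L, ] + shifted
    }
  }
  f[m + 1L, ]  # counts over rank sums 0..maxs (only >= m(m+1)/2 attainable)
}

#' Mann-Whitney U test (two-tailed)
#'
#' Rank-sum comparison of two independent groups. The statistic is
#' \eqn{U_A}, the number of (a, b) pairs with a ranked above b. When the
#' combined sample size is at most \code{exactMaxTotal} and there are no
#' ties, the two-tailed p-value is exact, from the full enumeration of the
#' \eqn{\binom{n_A+n_B}{n_A}} group labelings; otherwise a tie-corrected
#' normal approximation with a continuity correction of 1/2 is used.
#'
#' @param a,b numeric vectors (both non-empty).
#' @param exactMaxTotal largest combined sample size for the exact
#'   distribution (default 20).
#' @return List with \code{test_name}, \code{n_effective} (total n),
#'   \code{statistic} (\eqn{U_A}), \code{p_two_tailed}, \code{method}.
#' @export
mannWhitneyU <- function(a, b, exactMaxTotal = 20) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (!length(a) || !length(b))
    stop("both groups must be non-empty")
  nA <- length(a); nB <- length(b); N <- nA + nB
  r <- rank(c(a, b))
  U <- sum(r[seq_len(nA)]) - nA * (nA + 1) / 2
  ties <- anyDuplicated(c(a, b)) > 0L
  if (N <= exactMaxTotal && !ties) {
    f <- .rankSumCounts(N, nA)
    tot <- choose(N, nA)
    s <- as.integer(round(U + nA * (nA + 1) / 2))  # back to rank-sum scale
    pLe <- sum(f[seq_len(s + 1L)]) / tot
    pGe <- sum(f[(s + 1L):length(f)]) / tot
    p <- min(1, 2 * min(pLe, pGe))
    method <- "exact"
  } else {
    mu <- nA * nB / 2
    t_ <- table(r)
    sig2 <- nA * nB / 12 * ((N + 1) - sum(t_^3 - t_) / (N * (N - 1)))
    z <- if (sig2 == 0) 0 else (U - mu - sign(U - mu) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal-approximation"
  }
  list(test_name = "mann_whitney_u", n_effective = N,
       statistic = U, p_two_tailed = p, method = method)
}

#' Split values at the median
#'
#' Deterministic two-group split used for diversity stratification: values
#' at or below the median go to \code{"low"}, values above it to
#' \code{"high"} (for odd n the median observation itself is "low",
#' giving an 8/7 split for n = 15).
#'
#' @param values numeric vector (length >= 2), optionally named.
#' @return Character vector of \code{"low"}/\code{"high"} labels, named
#'   like \code{values}; attribute \code{"cutoff"} holds the median. A
#'   warning is raised if a group is empty (all values equal).
#' @export
medianSplit <- function(values) {
  stopifnot(length(values) >= 2L)
  m <- median(values)
  g <- ifelse(values <= m, "low", "high")
  names(g) <- names(values)
  if (length(unique(g)) < 2L)
    warning("degenerate median split: one group is empty")
  attr(g, "cutoff") <- m
  g
}

#' Kaplan-Meier product-limit estimator
#'
#' Survival curve for right-censored data: at each distinct event time
#' \eqn{t_j} with \eqn{d_j} events among \eqn{n_j} at risk, the survival
#' drops by the factor \eqn{1 - d_j/n_j}; censored subjects leave the risk
#' set after their time. With no censoring this reduces to the empirical
#' survival function.
#'
#' @param times non-negative follow-up times.
#' @param events 0/1 event indicators (1 = event, 0 = censored).
#' @return data.frame over distinct observed times: \code{time},
#'   \code{n_risk}, \code{n_event}, \code{n_censored}, \code{survival}
#'   (non-increasing, starting from 1).
#' @export
kaplanMeier <- function(times, events) {
  if (!length(times)) stop("empty survival input")
  stopifnot(length(times) == length(events), all(times >= 0),
            all(events %in% c(0, 1)))
  tt <- sort(unique(times))
  nRisk <- vapply(tt, function(t) sum(times >= t), numeric(1))
  nEvent <- vapply(tt, function(t) sum(times == t & events == 1), numeric(1))
  nCens <- vapply(tt, function(t) sum(times == t & events == 0), numeric(1))
  surv <- cumprod(1 - nEvent / nRisk)
  data.frame(time = tt, n_risk = nRisk, n_event = nEvent,
             n_censored = nCens, survival = surv)
}

#' Two-group log-rank test
#'
#' Standard (unweighted) log-rank test: at each distinct event time the
#' observed events in group A are compared with the expectation under the
#' hypergeometric null, and \eqn{\chi^2 = (\sum O_A - \sum E_A)^2 / \sum V}
#' is referred to a chi-square distribution with 1 df.
#'
#' @param times,events follow-up times and 0/1 event indicators.
#' @param group two-level grouping vector aligned with \code{times}.
#' @return List with \code{chisq}, \code{df}, \code{p_two_tailed},
#'   \code{observed} and \code{expected} (per group, in level order).
#' @export
logRankTest <- function(times, events, group) {
  stopifnot(length(times) == length(events),
            length(times) == length(group))
  g <- factor(group)
  if (nlevels(g) != 2L)
    stop("log-rank test requires exactly two groups")
  if (sum(events) == 0)
    stop("degenerate survival data: no events in either group")
  isA <- g == levels(g)[1L]
  evTimes <- sort(unique(times[events == 1]))
  O <- E <- V <- 0
  for (t in evTimes) {
    atRisk <- times >= t
    n <- sum(atRisk); n1 <- sum(atRisk & isA)
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & isA)
    O <- O + d1
    E <- E + n1 * d / n
    if (n > 1)
      V <- V + n1 * (n - n1) * d * (n - d) / (n^2 * (n - 1))
  }
  chisq <- if (V == 0) 0 else (O - E)^2 / V
  totE <- sum(events)
  list(chisq = chisq, df = 1L,
       p_two_tailed = pchisq(chisq, df = 1L, lower.tail = FALSE),
       observed = c(O, totE - O), expected = c(E, totE - E),
       groups = levels(g))
}

#' Compare a per-patient metric across clinical groups
#'
#' Groups a per-patient metric (e.g. tumor inverse Simpson DI) by a
#' clinical covariate and tests for a location difference: Mann-Whitney U
#' for two groups, Kruskal-Wallis for more. Built-in groupings: age
#' dichotomised at \code{ageCutoff} (default 60 years), TNM stage group
#' (I/II/III) and differentiation (L/M/H; patients with unknown
#' differentiation are excluded). Group summaries are reported as
#' mean and SD.
#'
#' @param values numeric metric named by \code{patient_id}.
#' @param metadata metadata data.frame from \code{\link{readMetadata}}.
#' @param grouping \code{"age"}, \code{"tnm_stage"},
#'   \code{"differentiation"}, or the name of any other metadata column
#'   (used as a factor).
#' @param ageCutoff age threshold in years for the age grouping.
#' @return List with \code{grouping}, \code{summaries} (data.frame of
#'   group, n, mean, sd), \code{test_name}, \code{statistic},
#'   \code{p_two_tailed}.
#' @export
compareByCovariate <- function(values, metadata, grouping = "age",
                               ageCutoff = 60) {
  stopifnot(!is.null(names(values)))
  md <- metadata[match(names(values), metadata$patient_id), , drop = FALSE]
  if (anyNA(md$patient_id))
    stop("metric patients missing from metadata: ",
         paste(setdiff(names(values), metadata$patient_id), collapse = ", "))
  fac <- switch(grouping,
    age = factor(ifelse(md$age <= ageCutoff,
                        paste0("<=", ageCutoff), paste0(">", ageCutoff)),
                 levels = c(paste0("<=", ageCutoff), paste0(">", ageCutoff))),
    tnm_stage = factor(md$tnm_stage, levels = .STAGE_LEVELS),
    differentiation = {
      f <- factor(md$differentiation, levels = c("L", "M", "H"))
      f  # unknown -> NA, dropped below
    },
    factor(md[[grouping]])
  )
  keep <- !is.na(fac) & !is.na(values)
  fac <- droplevels(fac[keep]); v <- values[keep]
  if (nlevels(fac) < 2L)
    stop("degenerate grouping: fewer than two non-empty groups for '",
         grouping, "'")
  summaries <- do.call(rbind, lapply(levels(fac), function(l) {
    vi <- v[fac == l]
    data.frame(group = l, n = length(vi), mean = mean(vi),
               sd = if (length(vi) > 1) sd(vi) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  if (nlevels(fac) == 2L) {
    tst <- mannWhitneyU(v[fac == levels(fac)[1L]], v[fac == levels(fac)[2L]])
    stat <- tst$statistic; p <- tst$p_two_tailed; nm <- tst$test_name
  } else {
    kw <- stats::kruskal.test(v, fac)
    stat <- unname(kw$statistic); p <- kw$p.value; nm <- "kruskal_wallis"
  }
  list(grouping = grouping, summaries = summaries, test_name = nm,
       statistic = stat, p_two_tailed = p)
}

#' Diversity-stratified survival analysis
#'
#' Splits patients into low/high groups at the median of a per-patient
#' metric (normally the tumor inverse Simpson DI) and compares survival
#' between the groups with Kaplan-Meier curves and the log-rank test.
#'
#' @param values per-patient metric named by \code{patient_id}.
#' @param times,events follow-up times (months) and 0/1 event indicators,
#'   aligned with \code{values}.
#' @return List with \code{groups} (the median split), \code{cutoff},
#'   \code{km} (named list of Kaplan-Meier curves per group) and
#'   \code{logrank} (see \code{\link{logRankTest}}).
#' @export
diStratifiedSurvival <- function(values, times, events) {
  g <- medianSplit(values)
  km <- lapply(split(seq_along(times), g), function(i)
    kaplanMeier(times[i], events[i]))
  lr <- logRankTest(times, events, g)
  list(groups = g, cutoff = attr(g, "cutoff"), km = km, logrank = lr)
}
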