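# Synthetic paired tumor/normal cohort generator. The defaults emulate the
# structure the downstream analysis assumes: heavy-tailed (Zipf) clone
# abundances with the tumor law flatter than the normal law (so tumor
# diversity is higher and normal tissue carries more highly expanded
# clones), partial clone sharing between the two tissues of a patient,
# CDR3 amino-acid lengths 8-23 peaking at 15, skewed V/J usage dominated
# by the segments most used in bulk TCR-beta data, and exponential
# survival with worse outcome in the high-diversity group.

# 46 functional TRBV segments (23 families) and the 13 TRBJ segments
# (2 families) of the human TCR-beta locus.
.TRBV_SEGMENTS <- c(
  "TRBV2", "TRBV3-1", "TRBV4-1", "TRBV4-2", "TRBV4-3",
  "TRBV5-1", "TRBV5-4", "TRBV5-5", "TRBV5-6", "TRBV5-8",
  "TRBV6-1", "TRBV6-2", "TRBV6-3", "TRBV6-4", "TRBV6-5", "TRBV6-6",
  "TRBV7-2", "TRBV7-3", "TRBV7-4", "TRBV7-6", "TRBV7-7", "TRBV7-8",
  "TRBV7-9", "TRBV9", "TRBV10-1", "TRBV10-2", "TRBV10-3",
  "TRBV11-1", "TRBV11-2", "TRBV11-3", "TRBV12-3", "TRBV12-4", "TRBV12-5",
  "TRBV13", "TRBV14", "TRBV15", "TRBV16", "TRBV18", "TRBV19",
  "TRBV20-1", "TRBV24-1", "TRBV25-1", "TRBV27", "TRBV28", "TRBV29-1",
  "TRBV30"
)

.TRBJ_SEGMENTS <- c(paste0("TRBJ1-", 1:6), paste0("TRBJ2-", 1:7))

.fillProfile <- function(segments, top, decay = 0.93) {
  rest <- setdiff(segments, names(top))
  w <- decay^seq_along(rest)
  p <- c(top, setNames(w / sum(w) * (1 - sum(top)), rest))
  p[segments] / sum(p)
}

#' Default V/J usage and CDR3 length profiles
#'
#' \code{defaultVProfile} covers the 46 functional TRBV segments
#' (23 families); the head of the distribution matches the segments most
#' used in bulk TCR-beta repertoires (TRBV11-2 15.25\%, TRBV29-1 10.08\%,
#' TRBV20-1 8.16\%, TRBV6-5 7.07\%, TRBV12-3 6.81\%), with the remaining
#' mass spread geometrically over the other segments.
#' \code{defaultJProfile} covers the 13 TRBJ segments (2 families) with
#' head TRBJ2-1 18.78\%, TRBJ2-7 17.58\%, TRBJ2-3 11.67\%, TRBJ2-5
#' 9.95\%. \code{defaultCdr3LengthProbs} is a discretised bell over
#' amino-acid lengths 8-23 with its mode at 15.
#'
#' @return Named probability vectors summing to 1.
#' @export
defaultVProfile <- function() {
  .fillProfile(.TRBV_SEGMENTS,
               c("TRBV11-2" = 0.1525, "TRBV29-1" = 0.1008,
                 "TRBV20-1" = 0.0816, "TRBV6-5" = 0.0707,
                 "TRBV12-3" = 0.0681))
}

#' @rdname defaultVProfile
#' @export
defaultJProfile <- function() {
  .fillProfile(.TRBJ_SEGMENTS,
               c("TRBJ2-1" = 0.1878, "TRBJ2-7" = 0.1758,
                 "TRBJ2-3" = 0.1167, "TRBJ2-5" = 0.0995))
}

#' @rdname defaultVProfile
#' @param peak modal CDR3 amino-acid length.
#' @param spread spread (in residues) of the bell around the peak.
#' @export
defaultCdr3LengthProbs <- function(peak = 15, spread = 2.2) {
  lens <- 8:23
  p <- stats::dnorm(lens, mean = peak, sd = spread)
  setNames(p / sum(p), lens)
}

#' Build a synthetic-cohort configuration
#'
#' Constructs a validated \linkS4class{SyntheticCohortConfig}. Defaults:
#' 15 patients with paired tumor/normal samples; 5e4 unique clones and 5e5
#' reads per sample (the analysed repertoires scaled down roughly tenfold);
#' Zipf clone abundances with exponent 1.05 in tumor and 1.25 in normal
#' tissue, so the tumor repertoire is flatter (higher diversity) and the
#' normal repertoire more expanded; 15\% of the normal clone pool shared
#' with the matched tumor; the default V/J and CDR3-length profiles; an
#' age effect adding 0.1 to the tumor Zipf exponent for patients over 60
#' (older = less diverse); exponential survival at 0.02 events/month with
#' hazard ratio 3 for the high-diversity group and exponential censoring
#' at 0.01/month.
#'
#' @param nPatients number of patients (each contributes a pair).
#' @param clonesTumor,clonesNormal unique clones in each tissue's pool.
#' @param readsPerSample sequencing depth per sample.
#' @param abundanceLaw \code{"zipf"} (probabilities proportional to
#'   rank^-alpha) or \code{"lognormal"} (sdlog parameter).
#' @param tumorParam,normalParam per-tissue law parameter (Zipf exponent
#'   >= 0, or lognormal sdlog > 0).
#' @param sharedFraction fraction of the normal pool also present in the
#'   matched tumor pool.
#' @param vProfile,jProfile named segment-probability vectors.
#' @param vFoldTumor named vector of per-V-segment fold changes applied to
#'   the tumor V profile (then renormalised); empty for none.
#' @param cdr3LengthProbs named probability vector over amino-acid lengths.
#' @param ageEffectOnDI added to the tumor law parameter for patients over
#'   60 years (positive = lower diversity in older patients).
#' @param baselineHazard,hazardRatioHighDI,censoringRate survival model
#'   (per month).
#' @param seed integer seed; identical config + seed gives byte-identical
#'   output tables.
#' @return A \linkS4class{SyntheticCohortConfig}.
#' @export
syntheticCohortConfig <- function(nPatients = 15,
                                  clonesTumor = 5e4,
                                  clonesNormal = 5e4,
                                  readsPerSample = 5e5,
                                  abundanceLaw = "zipf",
                                  tumorParam = 1.05,
                                  normalParam = 1.25,
                                  sharedFraction = 0.15,
                                  vProfile = defaultVProfile(),
                                  jProfile = defaultJProfile(),
                                  vFoldTumor = numeric(0),
                                  cdr3LengthProbs = defaultCdr3LengthProbs(),
                                  ageEffectOnDI = 0.1,
                                  baselineHazard = 0.02,
                                  hazardRatioHighDI = 3,
                                  censoringRate = 0.01,
                                  seed = 1) {
  new("SyntheticCohortConfig",
      nPatients = nPatients, clonesTumor = clonesTumor,
      clonesNormal = clonesNormal, readsPerSample = readsPerSample,
      abundanceLaw = abundanceLaw, tumorParam = tumorParam,
      normalParam = normalParam, sharedFraction = sharedFraction,
      vProfile = vProfile / sum(vProfile),
      jProfile = jProfile / sum(jProfile),
      vFoldTumor = vFoldTumor,
      cdr3LengthProbs = cdr3LengthProbs / sum(cdr3LengthProbs),
      ageEffectOnDI = ageEffectOnDI, baselineHazard = baselineHazard,
      hazardRatioHighDI = hazardRatioHighDI, censoringRate = censoringRate,
      seed = seed)
}

# Sense codons of the standard genetic code and their amino acids.
.senseCodons <- function() {
  gc <- Biostrings::GENETIC_CODE
  gc[gc != "*"]
}

#' Generate a pool of unique productive clonotypes
#'
#' Draws \code{n} distinct clonotypes: CDR3 amino-acid lengths from
#' \code{lengthProbs}, nucleotide sequences assembled codon-wise from the
#' 61 sense codons (so every sequence is in frame and stop-free by
#' construction), and V/J segments from the given profiles. Uses the
#' current RNG state; seed upstream for determinism.
#'
#' @param n number of clonotypes.
#' @param vProfile,jProfile named segment-probability vectors.
#' @param lengthProbs named probability vector over amino-acid lengths.
#' @return data.frame with \code{cdr3_nt}, \code{cdr3_aa},
#'   \code{v_segment}, \code{j_segment}; CDR3 nucleotide sequences are
#'   unique.
#' @export
generateClonePool <- function(n, vProfile = defaultVProfile(),
                              jProfile = defaultJProfile(),
                              lengthProbs = defaultCdr3LengthProbs()) {
  stopifnot(n >= 1)
  lens <- as.integer(names(lengthProbs))
  minLen <- min(lens[lengthProbs > 0])
  if (n > 0.5 * 61^minLen)
    stop("requested clone count exceeds the sequence-space bound")
  codons <- .senseCodons()
  aaOf <- unname(codons)
  ntOf <- names(codons)
  drawSeqs <- function(m) {
    L <- sample(lens, m, replace = TRUE, prob = lengthProbs)
    nt <- character(m); aa <- character(m)
    for (l in unique(L)) {
      i <- which(L == l)
      idx <- matrix(sample.int(length(codons), length(i) * l, replace = TRUE),
                    nrow = length(i))
      nt[i] <- do.call(paste0, lapply(seq_len(l), function(j) ntOf[idx[, j]]))
      aa[i] <- do.call(paste0, lapply(seq_len(l), function(j) aaOf[idx[, j]]))
    }
    list(nt = nt, aa = aa)
  }
  s <- drawSeqs(n)
  nt <- s$nt; aa <- s$aa
  iter <- 0L
  while (anyDuplicated(nt)) {          # collisions are vanishingly rare
    dup <- which(duplicated(nt))
    rs <- drawSeqs(length(dup))
    nt[dup] <- rs$nt; aa[dup] <- rs$aa
    iter <- iter + 1L
    if (iter > 100L)
      stop("could not generate ", n, " unique CDR3 sequences")
  }
  data.frame(cdr3_nt = nt, cdr3_aa = aa,
             v_segment = sample(names(vProfile), n, replace = TRUE,
                                prob = vProfile),
             j_segment = sample(names(jProfile), n, replace = TRUE,
                                prob = jProfile),
             stringsAsFactors = FALSE)
}

#' Assign heavy-tailed abundances to a clone pool
#'
#' Attaches clone-size probabilities to the pool (Zipf: rank^-alpha over a
#' random permutation of the clones, so which clones are big is random;
#' lognormal: i.i.d. lognormal weights) and draws read counts from a
#' multinomial at the configured depth. Clones receiving zero reads are
#' absent from the returned repertoire, as they would be from real data.
#'
#' @param pool clonotype data.frame from \code{\link{generateClonePool}}.
#' @param law \code{"zipf"} or \code{"lognormal"}.
#' @param param Zipf exponent (>= 0; 0 = uniform) or lognormal sdlog.
#' @param reads total reads to distribute (> 0).
#' @param sampleId,patientId,tissue annotation for the returned object.
#' @return A \linkS4class{Repertoire} at key level \code{"nt+VJ"}.
#' @export
assignAbundances <- function(pool, law = c("zipf", "lognormal"), param,
                             reads, sampleId = "synthetic",
                             patientId = "", tissue = NA_character_) {
  law <- match.arg(law)
  if (!is.numeric(reads) || reads < 1)
    stop("parameter error: reads must be positive")
  n <- nrow(pool)
  if (law == "zipf") {
    if (param < 0) stop("parameter error: zipf exponent must be >= 0")
    p <- seq_len(n)^(-param)
    p <- p[sample.int(n)]
  } else {
    if (param <= 0) stop("parameter error: lognormal sdlog must be > 0")
    p <- rlnorm(n, meanlog = 0, sdlog = param)
  }
  counts <- as.numeric(rmultinom(1L, size = reads, prob = p))
  keep <- counts > 0
  df <- pool[keep, , drop = FALSE]
  df$count <- counts[keep]
  Repertoire(df, sampleId = sampleId, patientId = patientId,
             tissue = tissue, keyLevel = "nt+VJ")
}

#' Generate a paired tumor/normal synthetic cohort
#'
#' Simulates the full study design: for each patient, a normal-tissue
#' clone pool, a tumor pool sharing \code{sharedFraction} of the normal
#' clones (abundances drawn independently in each tissue — sharing is
#' presence/absence only), per-tissue abundance laws (tumor flatter by
#' default, plus the age effect for patients over 60), clinical metadata
#' (age, sex, pathological type, differentiation, TNM stage group) and
#' exponential survival times whose hazard is tied to the patient's
#' tumor-diversity group (high DI = higher hazard). All randomness is
#' governed by \code{config@seed}: the same config gives byte-identical
#' tables.
#'
#' @param config a \linkS4class{SyntheticCohortConfig}.
#' @param outDir optional directory; when given, one clonotype TSV per
#'   sample (\code{<patient>_<tissue>.tsv}, native dialect) and a
#'   \code{metadata.tsv} are written there.
#' @return List with \code{repertoires} (named list of 2 x nPatients
#'   \linkS4class{Repertoire} objects), \code{metadata} (data.frame) and
#'   \code{config}.
#' @export
generatePairedCohort <- function(config = syntheticCohortConfig(),
                                 outDir = NULL) {
  stopifnot(is(config, "SyntheticCohortConfig"))
  validObject(config)
  set.seed(as.integer(config@seed))
  nP <- as.integer(config@nPatients)
  pids <- sprintf("P%02d", seq_len(nP))

  age <- pmin(pmax(round(rnorm(nP, mean = 60, sd = 13)), 30), 85)
  sex <- sample(c("Male", "Female"), nP, replace = TRUE, prob = c(2/3, 1/3))
  pathType <- sample(.PATH_LEVELS, nP, replace = TRUE,
                     prob = c(12, 2, 1) / 15)
  differentiation <- sample(.DIFF_LEVELS, nP, replace = TRUE,
                            prob = c(8, 4, 2, 1) / 15)
  tnm <- sample(.STAGE_LEVELS, nP, replace = TRUE, prob = c(8, 2, 5) / 15)

  vT <- config@vProfile
  if (length(config@vFoldTumor)) {
    miss <- setdiff(names(config@vFoldTumor), names(vT))
    if (length(miss))
      stop("vFoldTumor names not in vProfile: ", paste(miss, collapse = ", "))
    vT[names(config@vFoldTumor)] <-
      vT[names(config@vFoldTumor)] * config@vFoldTumor
    vT <- vT / sum(vT)
  }

  nShared <- round(config@sharedFraction * config@clonesNormal)
  nPrivate <- config@clonesTumor - nShared
  if (nPrivate < 0)
    stop("config error: sharedFraction * clonesNormal exceeds clonesTumor")

  reps <- list()
  for (i in seq_len(nP)) {
    normalPool <- generateClonePool(config@clonesNormal, config@vProfile,
                                    config@jProfile, config@cdr3LengthProbs)
    shared <- normalPool[sample.int(config@clonesNormal, nShared), ,
                         drop = FALSE]
    tumorPool <- shared
    if (nPrivate > 0) {
      priv <- generateClonePool(nPrivate, vT, config@jProfile,
                                config@cdr3LengthProbs)
      while (any(priv$cdr3_nt %in% normalPool$cdr3_nt)) {
        clash <- priv$cdr3_nt %in% normalPool$cdr3_nt
        priv[clash, ] <- generateClonePool(sum(clash), vT, config@jProfile,
                                           config@cdr3LengthProbs)
      }
      tumorPool <- rbind(shared, priv)
    }
    tumorParam_i <- config@tumorParam +
      if (age[i] > 60) config@ageEffectOnDI else 0
    reps[[paste0(pids[i], "_tumor")]] <-
      assignAbundances(tumorPool, config@abundanceLaw, tumorParam_i,
                       config@readsPerSample,
                       sampleId = paste0(pids[i], "_tumor"),
                       patientId = pids[i], tissue = "tumor")
    reps[[paste0(pids[i], "_normal")]] <-
      assignAbundances(normalPool, config@abundanceLaw, config@normalParam,
                       config@readsPerSample,
                       sampleId = paste0(pids[i], "_normal"),
                       patientId = pids[i], tissue = "normal")
  }

  diTumor <- vapply(pids, function(p)
    inverseSimpson(reps[[paste0(p, "_tumor")]])$inverse_simpson_di,
    numeric(1))
  grp <- if (nP >= 2) medianSplit(diTumor) else rep("low", nP)
  hazOS <- config@baselineHazard *
    ifelse(grp == "high", config@hazardRatioHighDI, 1)
  hazDFS <- 1.5 * hazOS  # progression precedes death on average
  drawSurv <- function(h) {
    tEvent <- rexp(nP, rate = h)
    tCens <- rexp(nP, rate = config@censoringRate)
    list(time = round(pmin(tEvent, tCens), 2),
         event = as.integer(tEvent <= tCens))
  }
  os <- drawSurv(hazOS)
  dfs <- drawSurv(hazDFS)

  metadata <- data.frame(
    patient_id = pids, age = age, sex = sex, path_type = pathType,
    differentiation = differentiation, tnm_stage = tnm,
    os_time = os$time, os_event = os$event,
    dfs_time = dfs$time, dfs_event = dfs$event,
    stringsAsFactors = FALSE
  )

  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(reps))
      writeClonotypeTable(reps[[nm]], file.path(outDir, paste0(nm, ".tsv")))
    write.table(metadata, file.path(outDir, "metadata.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  list(repertoires = reps, metadata = metadata, config = config)
}
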