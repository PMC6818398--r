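#' Repertoire accessors
#'
#' Accessor generics for \linkS4class{Repertoire} objects.
#'
#' @param x a \linkS4class{Repertoire}.
#' @return \code{sampleId}, \code{patientId}, \code{tissue} and
#'   \code{keyLevel} return length-one character vectors; \code{totalReads}
#'   and \code{nUnique} return numbers; \code{clonotypes} returns the
#'   clonotype data.frame; \code{clonotypeKeys} returns the character key of
#'   each clonotype at the active level; \code{repMetadata} returns the
#'   metadata list.
#' @name repertoire-accessors
#' @aliases sampleId patientId tissue keyLevel totalReads nUnique
#'   clonotypes clonotypeKeys repMetadata
NULL

#' @rdname repertoire-accessors
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))
#' @rdname repertoire-accessors
#' @export
setGeneric("patientId", function(x) standardGeneric("patientId"))
#' @rdname repertoire-accessors
#' @export
setGeneric("tissue", function(x) standardGeneric("tissue"))
#' @rdname repertoire-accessors
#' @export
setGeneric("keyLevel", function(x) standardGeneric("keyLevel"))
#' @rdname repertoire-accessors
#' @export
setGeneric("totalReads", function(x) standardGeneric("totalReads"))
#' @rdname repertoire-accessors
#' @export
setGeneric("nUnique", function(x) standardGeneric("nUnique"))
#' @rdname repertoire-accessors
#' @export
setGeneric("clonotypes", function(x) standardGeneric("clonotypes"))
#' @rdname repertoire-accessors
#' @export
setGeneric("clonotypeKeys", function(x) standardGeneric("clonotypeKeys"))
#' @rdname repertoire-accessors
#' @export
setGeneric("repMetadata", function(x) standardGeneric("repMetadata"))

#' @rdname repertoire-accessors
setMethod("sampleId", "Repertoire", function(x) x@sampleId)
#' @rdname repertoire-accessors
setMethod("patientId", "Repertoire", function(x) x@patientId)
#' @rdname repertoire-accessors
setMethod("tissue", "Repertoire", function(x) x@tissue)
#' @rdname repertoire-accessors
setMethod("keyLevel", "Repertoire", function(x) x@keyLevel)
#' @rdname repertoire-accessors
setMethod("totalReads", "Repertoire", function(x) x@totalReads)
#' @rdname repertoire-accessors
setMethod("nUnique", "Repertoire", function(x) nrow(x@clonotypes))
#' @rdname repertoire-accessors
setMethod("clonotypes", "Repertoire", function(x) x@clonotypes)
#' @rdname repertoire-accessors
setMethod("clonotypeKeys", "Repertoire", function(x)
  do.call(paste, c(x@clonotypes[.keyColumns(x@keyLevel)], sep = "|")))
#' @rdname repertoire-accessors
setMethod("repMetadata", "Repertoire", function(x) x@metadata)

#' Re-aggregate a repertoire to a coarser clonotype key
#'
#' Collapses clonotypes by summing counts under a coarser key. Levels are
#' ordered \code{"nt+VJ"} (finest) > \code{"nt"} > \code{"aa"} (coarsest;
#' CDR3 translation is many-to-one, so distinct nucleotide clones can merge).
#' Aggregating to the current level returns the object unchanged; requesting
#' a finer level (e.g. \code{"aa"} to \code{"nt"}) is an error because the
#' information is gone. Total reads are always preserved and the unique-clone
#' count can only decrease.
#'
#' @param x a \linkS4class{Repertoire}.
#' @param keyLevel target level, one of \code{"nt+VJ"}, \code{"nt"},
#'   \code{"aa"}.
#' @return A \linkS4class{Repertoire} at \code{keyLevel}. Columns no longer
#'   defined by the key (e.g. V/J after dropping them from the key) are set
#'   to \code{NA} unless they are constant within every merged group.
#' @export
setGeneric("aggregateRepertoire",
           function(x, keyLevel) standardGeneric("aggregateRepertoire"))

#' @rdname aggregateRepertoire
setMethod("aggregateRepertoire", "Repertoire", function(x, keyLevel) {
  keyLevel <- match.arg(keyLevel, names(.KEY_LEVELS))
  oldRank <- .KEY_LEVELS[[x@keyLevel]]
  newRank <- .KEY_LEVELS[[keyLevel]]
  if (newRank > oldRank)
    stop("invalid aggregation: cannot refine from '", x@keyLevel,
         "' to '", keyLevel, "'")
  if (newRank == oldRank) return(x)
  df <- x@clonotypes
  keyCols <- .keyColumns(keyLevel)
  if (anyNA(df[keyCols]))
    stop("cannot aggregate to '", keyLevel,
         "': key column(s) contain missing values")
  keys <- do.call(paste, c(df[keyCols], sep = "|"))
  first <- !duplicated(keys)
  cnt <- rowsum(df$count, keys, reorder = FALSE)
  out <- df[first, , drop = FALSE]
  out$count <- cnt[match(keys[first], rownames(cnt)), 1L]
  # columns outside the new key keep their value only if constant per group
  dropCols <- setdiff(c("cdr3_nt", "cdr3_aa", "v_segment", "j_segment"),
                      keyCols)
  for (col in dropCols) {
    nDistinct <- rowsum((!duplicated(paste(keys, df[[col]]))) + 0,
                        keys, reorder = FALSE)
    ambiguous <- rownames(nDistinct)[nDistinct[, 1L] > 1L]
    out[[col]][keys[first] %in% ambiguous] <- NA_character_
  }
  rownames(out) <- NULL
  new("Repertoire", sampleId = x@sampleId, patientId = x@patientId,
      tissue = x@tissue, keyLevel = keyLevel, clonotypes = out,
      totalReads = sum(out$count), metadata = x@metadata)
})
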