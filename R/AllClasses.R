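#' @import methods
NULL

#' CircularSequence: a circular DNA molecule with 1-based coordinates
#'
#' Thin container for a single (usually circular) DNA sequence. All
#' coordinates used throughout the package are 1-based and inclusive;
#' intervals on circular sequences may wrap the origin (start > end).
#'
#' @slot id single character identifier.
#' @slot sequence uppercase DNA string over A/C/G/T/N.
#' @slot circular logical; whether modular coordinate arithmetic applies.
#'
#' @seealso [circularSequence()], [seqLength()], [extractArc()]
#' @exportClass CircularSequence
setClass("CircularSequence",
  representation(id = "character", sequence = "character",
                 circular = "logical"))

setValidity("CircularSequence", function(object) {
  msg <- character()
  if (length(object@id) != 1L) msg <- c(msg, "'id' must be a single string")
  if (length(object@sequence) != 1L || nchar(object@sequence) < 1L)
    msg <- c(msg, "sequence must be a single non-empty string")
  if (length(object@circular) != 1L || is.na(object@circular))
    msg <- c(msg, "'circular' must be TRUE or FALSE")
  if (length(object@sequence) == 1L &&
      grepl("[^ACGTN]", object@sequence))
    msg <- c(msg, "sequence may only contain A, C, G, T, N")
  if (length(msg)) msg else TRUE
})

#' AnnotatedGenome: a sequence plus its features
#'
#' Couples a [CircularSequence] with a feature table. Features are rows
#' with columns \code{name}, \code{kind} (gene/exon/tRNA/rRNA/repeat),
#' \code{start}, \code{end} (1-based inclusive; start > end encodes a
#' feature wrapping the origin of a circular sequence), \code{strand}
#' ("+"/"-") and optional integer \code{exon_index}.
#'
#' @slot seq a [CircularSequence].
#' @slot features data.frame of features.
#' @exportClass AnnotatedGenome
setClass("AnnotatedGenome",
  representation(seq = "CircularSequence", features = "data.frame"))

.FEATURE_KINDS <- c("gene", "exon", "tRNA", "rRNA", "repeat")

setValidity("AnnotatedGenome", function(object) {
  ft <- object@features
  need <- c("name", "kind", "start", "end", "strand")
  if (!all(need %in% names(ft)))
    return(paste("features must have columns:", paste(need, collapse = ", ")))
  if (nrow(ft) == 0L) return(TRUE)
  N <- nchar(object@seq@sequence)
  msg <- character()
  if (!all(ft$kind %in% .FEATURE_KINDS))
    msg <- c(msg, "unknown feature kind")
  if (!all(ft$strand %in% c("+", "-")))
    msg <- c(msg, "strand must be '+' or '-'")
  if (any(ft$start < 1L | ft$start > N | ft$end < 1L | ft$end > N))
    msg <- c(msg, sprintf("feature coordinates outside [1, %d]", N))
  if (!object@seq@circular && any(ft$start > ft$end))
    msg <- c(msg, "start > end feature on a non-circular sequence")
  if (length(msg)) msg else TRUE
})

#' MoleculeState: a circular signed arrangement of segments and repeats
#'
#' The unit of recombination. A molecule is a cyclic ordered list of
#' signed units, each either a genome segment or one copy of a repeat
#' pair. Strand is +1/-1 relative to the master circle. Two states are
#' the same molecule iff their canonical keys (minimum over rotations and
#' over the whole-molecule flip) agree; see [canonicalKey()].
#'
#' @slot units data.frame with columns \code{type} ("segment"/"repeat"),
#'   \code{id}, \code{strand} (+1/-1).
#' @slot provenance character vector of recombination events applied.
#' @exportClass MoleculeState
setClass("MoleculeState",
  representation(units = "data.frame", provenance = "character"))

setValidity("MoleculeState", function(object) {
  u <- object@units
  if (!all(c("type", "id", "strand") %in% names(u)))
    return("units needs columns type, id, strand")
  if (nrow(u) == 0L) return("a molecule must contain at least one unit")
  msg <- character()
  if (!all(u$type %in% c("segment", "repeat")))
    msg <- c(msg, "unit type must be 'segment' or 'repeat'")
  if (!all(u$strand %in% c(1L, -1L)))
    msg <- c(msg, "unit strand must be +1 or -1")
  seg <- u$id[u$type == "segment"]
  if (anyDuplicated(seg))
    msg <- c(msg, "each segment label may appear at most once per circle")
  if (any(tabulate(factor(u$id[u$type == "repeat"])) > 2L))
    msg <- c(msg, "a repeat pair may appear at most twice")
  if (length(msg)) msg else TRUE
})

#' QuadripartiteMap: IRa/IRb/LSC/SSC intervals of a chloroplast genome
#'
#' Intervals are 1-based inclusive and may wrap the origin. The two IRs
#' are exact reverse complements; the invariant
#' 2 x IR + LSC + SSC = genome length always holds.
#'
#' @slot ira,irb,lsc,ssc integer vectors c(start, end).
#' @slot genomeLength integer genome size in bp.
#' @exportClass QuadripartiteMap
setClass("QuadripartiteMap",
  representation(ira = "integer", irb = "integer", lsc = "integer",
                 ssc = "integer", genomeLength = "integer"))

setValidity("QuadripartiteMap", function(object) {
  N <- object@genomeLength
  len <- function(iv) arcLength(iv[1], iv[2], N, "inclusive")
  tot <- len(object@ira) + len(object@irb) + len(object@lsc) + len(object@ssc)
  msg <- character()
  if (len(object@ira) != len(object@irb))
    msg <- c(msg, "IRa and IRb must have equal length")
  if (tot != N)
    msg <- c(msg, sprintf("regions tile %d bp, genome is %d bp", tot, N))
  if (len(object@lsc) < len(object@ssc))
    msg <- c(msg, "LSC must be at least as long as SSC")
  if (length(msg)) msg else TRUE
})
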