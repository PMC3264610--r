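#' Detect the quadripartite architecture of a chloroplast genome
#'
#' The longest palindromic maximal repeat pair of length >= `minIr`
#' defines IRa/IRb (the two copies are required to be exact reverse
#' complements; the detector reuses [findMaximalRepeats()]). The two
#' arcs between the IRs are assigned LSC (the longer) and SSC (the
#' shorter). IRa is the IR copy that immediately follows the LSC in
#' circular order, so the regions read LSC, IRa, SSC, IRb around the
#' circle.
#'
#' @param genome [CircularSequence-class] or [AnnotatedGenome-class].
#' @param minIr minimal IR length in bp (default 1000).
#' @return a [QuadripartiteMap-class], or `NULL` when no qualifying
#'   palindromic pair exists.
#' @examples
#' sim <- simulateQuadripartiteGenome(lsc = 8000, ir = 2000, ssc = 1500,
#'                                    seed = 7)
#' detectQuadripartite(sim$genome)
#' @export
detectQuadripartite <- function(genome, minIr = 1000L) {
  if (is(genome, "AnnotatedGenome")) genome <- genome@seq
  N <- seqLength(genome)
  reps <- suppressWarnings(
    findMaximalRepeats(genome, repeatConfig(min_length = minIr,
                                            orientations = "P")))
  if (nrow(reps) == 0L) return(NULL)
  top <- reps[reps$length == max(reps$length), , drop = FALSE]
  if (nrow(top) > 1L)
    stop("multiple palindromic pairs of equal maximal length (",
         top$length[1L], " bp); choose the IR pair manually")
  L <- top$length[1L]
  s1 <- top$start1[1L]; e1 <- .norm1(s1 + L - 1L, N)
  s2 <- top$start2[1L]; e2 <- .norm1(s2 + L - 1L, N)
  gapA <- c(.norm1(e1 + 1L, N), .norm1(s2 - 1L, N))   # between copy1, copy2
  gapB <- c(.norm1(e2 + 1L, N), .norm1(s1 - 1L, N))   # between copy2, copy1
  lenA <- arcLength(gapA[1], gapA[2], N, "inclusive")
  lenB <- arcLength(gapB[1], gapB[2], N, "inclusive")
  if (lenA >= lenB) {                     # gapA is LSC -> copy2 is IRa
    lsc <- gapA; ssc <- gapB; ira <- c(s2, e2); irb <- c(s1, e1)
  } else {
    lsc <- gapB; ssc <- gapA; ira <- c(s1, e1); irb <- c(s2, e2)
  }
  new("QuadripartiteMap", ira = as.integer(ira), irb = as.integer(irb),
      lsc = as.integer(lsc), ssc = as.integer(ssc),
      genomeLength = as.integer(N))
}

#' Region lengths and genome fractions of a quadripartite map
#'
#' @param map a [QuadripartiteMap-class].
#' @return data.frame with one row per region (LSC, IRa, SSC, IRb):
#'   start, end, length (bp) and fraction of the genome (a single IR
#'   copy counts its own length, so the printed "covering" percentage of
#'   one IR is `ir_length / N`).
#' @export
quadripartiteRegions <- function(map) {
  N <- map@genomeLength
  iv <- list(LSC = map@lsc, IRa = map@ira, SSC = map@ssc, IRb = map@irb)
  len <- vapply(iv, function(v) arcLength(v[1], v[2], N, "inclusive"), 0L)
  data.frame(region = names(iv),
             start = vapply(iv, `[`, 0L, 1),
             end = vapply(iv, `[`, 0L, 2),
             length = len,
             fraction = len / N,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @rdname quadripartiteRegions
#' @export
irLength <- function(map)
  arcLength(map@ira[1], map@ira[2], map@genomeLength, "inclusive")

#' @rdname quadripartiteRegions
#' @export
lscLength <- function(map)
  arcLength(map@lsc[1], map@lsc[2], map@genomeLength, "inclusive")

#' @rdname quadripartiteRegions
#' @export
sscLength <- function(map)
  arcLength(map@ssc[1], map@ssc[2], map@genomeLength, "inclusive")

#' Features at the four quadripartite junctions
#'
#' For each junction (LSC/IRa, IRa/SSC, SSC/IRb, IRb/LSC) reports the
#' features whose interval contains or abuts the junction, i.e.
#' overlaps the last base of the upstream region or the first base of
#' the downstream region. A feature that merely touches one of the two
#' flanking bases is reported as "abutting"; one that covers both is
#' "spanning".
#'
#' @param map a [QuadripartiteMap-class].
#' @param features feature data.frame (see [AnnotatedGenome-class]).
#' @return data.frame with columns `junction`, `name`, `kind`,
#'   `relation`.
#' @export
junctionFeatures <- function(map, features) {
  N <- map@genomeLength
  junctions <- list(
    "LSC/IRa" = c(map@lsc[2], map@ira[1]),
    "IRa/SSC" = c(map@ira[2], map@ssc[1]),
    "SSC/IRb" = c(map@ssc[2], map@irb[1]),
    "IRb/LSC" = c(map@irb[2], map@lsc[1]))
  contains <- function(s, e, p) ((p - s) %% N) <= ((e - s) %% N)
  out <- list()
  for (j in names(junctions)) {
    b <- junctions[[j]]
    for (i in seq_len(nrow(features))) {
      hitUp <- contains(features$start[i], features$end[i], b[1])
      hitDn <- contains(features$start[i], features$end[i], b[2])
      if (hitUp || hitDn)
        out[[length(out) + 1L]] <- data.frame(
          junction = j, name = features$name[i], kind = features$kind[i],
          relation = if (hitUp && hitDn) "spanning" else "abutting",
          stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(junction = character(), name = character(),
                      kind = character(), relation = character()))
  unique(do.call(rbind, out))
}
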