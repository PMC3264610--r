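#' Repeat search configuration
#'
#' @param min_length minimal repeat length in bp (default 50, the
#'   conventional cutoff for recombinationally relevant organellar
#'   repeats); must be >= 8.
#' @param orientations subset of c("F", "P"): F = forward/direct copies,
#'   P = palindromic (reverse-complement) copies.
#' @param max_pairs optional cap on the number of reported pairs (the
#'   longest are kept).
#' @param treat_circular search across the origin (default TRUE).
#' @return validated list of class "RepeatConfig".
#' @export
repeatConfig <- function(min_length = 50L, orientations = c("F", "P"),
                         max_pairs = NULL, treat_circular = TRUE) {
  min_length <- as.integer(min_length)
  if (is.na(min_length) || min_length < 8L)
    stop("min_length must be an integer >= 8")
  orientations <- match.arg(orientations, c("F", "P"), several.ok = TRUE)
  if (!is.null(max_pairs) && (max_pairs < 1L))
    stop("max_pairs must be >= 1")
  structure(list(min_length = min_length, orientations = orientations,
                 max_pairs = max_pairs,
                 treat_circular = isTRUE(treat_circular)),
            class = "RepeatConfig")
}

#' Find maximal exact repeat pairs on a (circular) genome
#'
#' Reports every maximal exact two-copy repeat of length >=
#' `config$min_length` in the requested orientations. \emph{Maximal}
#' means the match can be extended in neither direction without a
#' mismatch. On circular sequences matches may cross the origin. The
#' trivial whole-circle self-match and pairs whose two copies overlap
#' each other on the circle are excluded. Repeat families with more than
#' two copies are emitted as all their pairs.
#'
#' The search seeds on exact `min_length`-mers shared between the genome
#' (resp. its reverse complement for palindromic matches) and extends
#' each seed diagonal to maximality; correctness is defined against an
#' exhaustive diagonal-scan oracle in the test suite, not by the
#' implementation.
#'
#' @param genome [CircularSequence-class] or [AnnotatedGenome-class].
#' @param config a [repeatConfig()].
#' @return data.frame with columns `length`, `start1`, `start2`
#'   (1-based positions of the two copies, `start1 < start2`),
#'   `orientation` ("F"/"P") and `e_value`, sorted by decreasing length
#'   then `start1`. For orientation F the sequence at
#'   `start1..start1+L-1` equals the one at `start2..start2+L-1`; for P
#'   it equals its reverse complement (both read circularly). The
#'   E-value formula is recorded in `attr(, "evalue_formula")`.
#' @examples
#' sim <- simulateRepeatGenome(5000,
#'   data.frame(length = 300, start1 = 1000, start2 = 3000,
#'              orientation = "F"), seed = 1)
#' findMaximalRepeats(sim$genome, repeatConfig(min_length = 50))
#' @export
findMaximalRepeats <- function(genome, config = repeatConfig()) {
  if (is(genome, "AnnotatedGenome")) genome <- genome@seq
  s <- genome@sequence
  N <- nchar(s)
  k <- config$min_length
  empty <- data.frame(length = integer(), start1 = integer(),
                      start2 = integer(), orientation = character(),
                      e_value = numeric())
  if (N < 2L * k) {
    warning("genome shorter than 2 x min_length; no repeat can exist")
    return(empty)
  }
  circ <- config$treat_circular && genome@circular
  x <- strsplit(s, "")[[1]]
  xc <- chartr("ACGTN", "TGCAN", x)            # per-base complement
  # seeding on shorter exact words is sufficient: every maximal repeat of
  # length >= min_length contains an exact kseed-mer; filter on L after
  kseed <- min(k, 32L)
  res <- list()
  if ("F" %in% config$orientations)
    res$F <- .maximalForward(x, N, kseed, circ)
  if ("P" %in% config$orientations)
    res$P <- .maximalPalindromic(x, xc, N, kseed, circ)
  out <- do.call(rbind, res)
  if (!is.null(out)) out <- out[out$length >= k, , drop = FALSE]
  if (is.null(out) || nrow(out) == 0L) out <- empty
  else {
    out$e_value <- repeatEvalue(out$length, N,
                                length(config$orientations))
    out <- out[order(-out$length, out$start1, out$start2), , drop = FALSE]
    rownames(out) <- NULL
    if (!is.null(config$max_pairs) && nrow(out) > config$max_pairs)
      out <- out[seq_len(config$max_pairs), ]
  }
  attr(out, "evalue_formula") <-
    "E = orientations * N^2 * (1/4)^L (expected chance maximal pairs)"
  out
}

# positions are taken mod N onto 1..N
.norm1 <- function(p, N) ((p - 1L) %% N) + 1L

.kmerStarts <- function(s2, N, k, circ, N1) {
  # returns start positions (on the doubled string) of each k-mer window
  n <- if (circ) N else N - k + 1L
  if (n < 1L) return(integer(0))
  seq_len(n)
}

.maximalForward <- function(x, N, k, circ) {
  s2 <- if (circ) c(x, x) else x
  starts <- if (circ) seq_len(N) else seq_len(N - k + 1L)
  km <- vapply(starts, function(i) paste(s2[i:(i + k - 1L)], collapse = ""),
               "")
  grp <- split(starts, km)
  grp <- grp[lengths(grp) >= 2L]
  if (!length(grp)) return(NULL)
  seen <- new.env(hash = TRUE)
  found <- list()
  at <- function(i) if (circ) x[.norm1(i, N)] else
    if (i >= 1L && i <= N) x[i] else NA_character_
  for (pos in grp) {
    n <- length(pos)
    for (a in seq_len(n - 1L)) for (b in (a + 1L):n) {
      i <- pos[a]; j <- pos[b]
      o <- (j - i) %% N
      if (o == 0L) next                 # same circular position
      skey <- paste0("s", o, ".", .norm1(i, N))
      if (!is.null(seen[[skey]])) next
      # extend left
      L <- k; ii <- i
      while (L < N) {
        lb <- at(ii - 1L); rb <- at(ii - 1L + o)
        if (is.na(lb) || is.na(rb) || lb != rb || lb == "N") break
        ii <- ii - 1L; L <- L + 1L
      }
      # extend right
      while (L < N) {
        lb <- at(ii + L); rb <- at(ii + L + o)
        if (is.na(lb) || is.na(rb) || lb != rb || lb == "N") break
        L <- L + 1L
      }
      # mark all seed windows inside this run as handled on diagonal o
      for (t in 0:(L - k)) seen[[paste0("s", o, ".", .norm1(ii + t, N))]] <- TRUE
      if (L >= N) next                  # trivial whole-circle self-match
      a1 <- .norm1(ii, N); a2 <- .norm1(ii + o, N)
      gap1 <- (a2 - a1) %% N; gap2 <- (a1 - a2) %% N
      if (L > gap1 || L > gap2) next    # copies overlap each other
      p1 <- min(a1, a2); p2 <- max(a1, a2)
      fkey <- paste("F", L, p1, p2)
      if (is.null(seen[[fkey]])) {
        seen[[fkey]] <- TRUE
        found[[length(found) + 1L]] <- c(L, p1, p2)
      }
    }
  }
  .repeatDF(found, "F")
}

.maximalPalindromic <- function(x, xc, N, k, circ) {
  # seed: window i of x equals revcomp of window j of x
  # <=> forward match between x and rc(x); work via reversed complement
  rc <- rev(xc)                          # rc[i] = comp(x[N + 1 - i])
  s2 <- if (circ) c(x, x) else x
  r2 <- if (circ) c(rc, rc) else rc
  starts <- if (circ) seq_len(N) else seq_len(N - k + 1L)
  kmX <- vapply(starts, function(i) paste(s2[i:(i + k - 1L)], collapse = ""), "")
  kmR <- vapply(starts, function(i) paste(r2[i:(i + k - 1L)], collapse = ""), "")
  common <- intersect(kmX, kmR)
  if (!length(common)) return(NULL)
  gX <- split(starts, kmX)[common]
  gR <- split(starts, kmR)[common]
  seen <- new.env(hash = TRUE)
  found <- list()
  at <- function(i) if (circ) x[.norm1(i, N)] else
    if (i >= 1L && i <= N) x[i] else NA_character_
  cat_ <- function(i) if (circ) xc[.norm1(i, N)] else
    if (i >= 1L && i <= N) xc[i] else NA_character_
  for (w in seq_along(common)) {
    for (i in gX[[w]]) for (q in gR[[w]]) {
      # window q on rc maps to copy2 start j on x
      j <- N - q - k + 2L
      a1 <- .norm1(i, N); a2 <- .norm1(j, N)
      # anti-diagonal: a1 + (a2 + L - 1) is invariant under extension
      csum <- (a1 + a2 + k - 2L) %% N    # 0-based invariant
      skey <- paste0("c", csum, ".", a1)
      if (!is.null(seen[[skey]])) next
      L <- k; ii <- i; jj <- j           # copy1 start ii, copy2 start jj
      # extend copy1 left / copy2 right: x[ii-1] == comp(x[jj+L])
      while (L < N) {
        lb <- at(ii - 1L); rb <- cat_(jj + L)
        if (is.na(lb) || is.na(rb) || lb != rb || lb == "N") break
        ii <- ii - 1L; L <- L + 1L
      }
      # extend copy1 right / copy2 left: x[ii+L] == comp(x[jj-1])
      while (L < N) {
        lb <- at(ii + L); rb <- cat_(jj - 1L)
        if (is.na(lb) || is.na(rb) || lb != rb || lb == "N") break
        jj <- jj - 1L; L <- L + 1L
      }
      b1 <- .norm1(ii, N); b2 <- .norm1(jj, N)
      for (t in 0:(L - k)) {             # seeds of both roles are covered
        seen[[paste0("c", csum, ".", .norm1(ii + t, N))]] <- TRUE
        seen[[paste0("c", csum, ".", .norm1(jj + t, N))]] <- TRUE
      }
      if (L >= N) next
      gap1 <- (b2 - b1) %% N; gap2 <- (b1 - b2) %% N
      if (L > gap1 || L > gap2) next     # overlapping / self-palindrome
      p1 <- min(b1, b2); p2 <- max(b1, b2)
      fkey <- paste("P", L, p1, p2)
      if (is.null(seen[[fkey]])) {
        seen[[fkey]] <- TRUE
        found[[length(found) + 1L]] <- c(L, p1, p2)
      }
    }
  }
  .repeatDF(found, "P")
}

.repeatDF <- function(found, orientation) {
  if (!length(found)) return(NULL)
  m <- do.call(rbind, found)
  data.frame(length = as.integer(m[, 1]), start1 = as.integer(m[, 2]),
             start2 = as.integer(m[, 3]), orientation = orientation,
             e_value = NA_real_, stringsAsFactors = FALSE)
}

#' Expected number of chance maximal repeat pairs
#'
#' Simple closed-form expectation for a uniform random sequence of
#' length `N`: `E = orientations * N^2 * (1/4)^L`. This documents the
#' significance scale attached to reported pairs; repeat filtering uses
#' the length cutoff only, never the E-value, so downstream structural
#' results are insensitive to the formula.
#'
#' @param L repeat length (bp), vectorised.
#' @param N genome length (bp).
#' @param orientations number of searched orientation classes (1 or 2).
#' @return numeric expectation, monotonically decreasing in `L`.
#' @examples
#' repeatEvalue(1, 2, 1)    # 1
#' repeatEvalue(102, 5e5, 2) / repeatEvalue(101, 5e5, 2)  # 0.25
#' @export
repeatEvalue <- function(L, N, orientations = 2L) {
  stopifnot(all(L >= 1), all(N >= L))
  orientations * as.numeric(N)^2 * 0.25^L
}

#' Re-validate a repeat pair against the sequence
#'
#' Direct substring/reverse-complement comparison on the circular
#' sequence; used by tests and by [decomposeSegments()] input checks.
#'
#' @param genome [CircularSequence-class].
#' @param pairs data.frame with length/start1/start2/orientation.
#' @return logical vector, one per pair.
#' @export
validateRepeatPairs <- function(genome, pairs) {
  if (is(genome, "AnnotatedGenome")) genome <- genome@seq
  N <- seqLength(genome)
  vapply(seq_len(nrow(pairs)), function(i) {
    L <- pairs$length[i]
    e1 <- .norm1(pairs$start1[i] + L - 1L, N)
    e2 <- .norm1(pairs$start2[i] + L - 1L, N)
    c1 <- extractArc(genome, pairs$start1[i], e1)
    c2 <- extractArc(genome, pairs$start2[i], e2)
    if (pairs$orientation[i] == "F") c1 == c2 else c1 == revComp(c2)
  }, TRUE)
}
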