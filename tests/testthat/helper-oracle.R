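# Exhaustive diagonal-scan oracle for maximal exact repeat pairs on a
# circular sequence. Independent of the package's seeded finder: it
# enumerates every diagonal (forward) / anti-diagonal (palindromic),
# computes the full match vector, and reads maximal runs off rle().

.onorm <- function(p, N) ((p - 1L) %% N) + 1L

# maximal circular runs of TRUE in logical vector m (positions 1..N)
.circularRuns <- function(m) {
  N <- length(m)
  if (all(m)) return(NULL)                       # trivial full-circle match
  if (!any(m)) return(data.frame(start = integer(), len = integer()))
  r0 <- which(!m)[1L]
  rot <- c(r0:N, seq_len(r0 - 1L))               # rotate to start at FALSE
  rl <- rle(m[rot])
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths + 1L
  keep <- rl$values
  data.frame(start = .onorm(rot[starts[keep]], N), len = rl$lengths[keep])
}

oracleRepeats <- function(seq, minLen, orientations = c("F", "P")) {
  x <- strsplit(toupper(seq), "")[[1]]
  xc <- chartr("ACGT", "TGCA", x)
  N <- length(x)
  res <- list()
  addPair <- function(L, a1, a2, ori) {
    gap1 <- (a2 - a1) %% N; gap2 <- (a1 - a2) %% N
    if (L > gap1 || L > gap2) return()           # overlapping copies
    p1 <- min(a1, a2); p2 <- max(a1, a2)
    res[[paste(ori, L, p1, p2)]] <<- data.frame(
      length = L, start1 = p1, start2 = p2, orientation = ori,
      stringsAsFactors = FALSE)
  }
  if ("F" %in% orientations) {
    for (o in seq_len(N - 1L)) {
      m <- x == x[.onorm(seq_len(N) + o, N)]
      runs <- .circularRuns(m)
      if (is.null(runs)) next
      runs <- runs[runs$len >= minLen, , drop = FALSE]
      for (i in seq_len(nrow(runs)))
        addPair(runs$len[i], runs$start[i],
                .onorm(runs$start[i] + o, N), "F")
    }
  }
  if ("P" %in% orientations) {
    for (cs in seq_len(N)) {
      # position p pairs with cs - p (mod N): x[p] must equal comp there
      m <- x == xc[.onorm(cs - seq_len(N), N)]
      runs <- .circularRuns(m)
      if (is.null(runs)) next
      runs <- runs[runs$len >= minLen, , drop = FALSE]
      for (i in seq_len(nrow(runs))) {
        a1 <- runs$start[i]; L <- runs$len[i]
        a2 <- .onorm(cs - (a1 + L - 1L), N)      # partner of run end
        addPair(L, a1, a2, "P")
      }
    }
  }
  if (!length(res))
    return(data.frame(length = integer(), start1 = integer(),
                      start2 = integer(), orientation = character()))
  out <- do.call(rbind, res)
  out <- out[order(-out$length, out$start1, out$start2, out$orientation), ]
  rownames(out) <- NULL
  out
}

# comparable key sets for finder-vs-oracle equality
repeatKeys <- function(df) {
  if (nrow(df) == 0L) return(character())
  sort(paste(df$orientation, df$length, df$start1, df$start2))
}

# interval overlap in bases; scalar intervals only
.ovBases <- function(a1, a2, b1, b2) {
  stopifnot(length(a1) == 1L, length(b1) == 1L)
  as.numeric(max(0, min(a2, b2) - max(a1, b1) + 1))
}

# does any row of hits overlap the interval [s, e]?
.anyHitOverlaps <- function(hits, s, e) {
  nrow(hits) > 0L &&
    any(pmax(0, pmin(hits$mt_end, e) - pmax(hits$mt_start, s) + 1) > 0)
}
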