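#' Alignment thresholds for plastid-transfer detection
#'
#' Defaults follow the conventional homology thresholds for detecting
#' chloroplast-derived sequences in mitochondrial genomes: identity >=
#' 80\%, E-value <= 1e-5, length >= 50 bp, and (for age/tRNA
#' classification) query coverage >= 50\%.
#'
#' @param min_identity minimal alignment identity, fraction in (0, 1].
#' @param max_evalue maximal E-value.
#' @param min_length minimal aligned length in bp.
#' @param min_coverage minimal coverage of the query, fraction.
#' @return validated list of class "AlignmentParams".
#' @export
alignmentParams <- function(min_identity = 0.80, max_evalue = 1e-5,
                            min_length = 50L, min_coverage = 0.50) {
  if (!(min_identity > 0 && min_identity <= 1))
    stop("min_identity must be in (0, 1]")
  if (min_length < 1L) stop("min_length must be >= 1")
  if (!(min_coverage > 0 && min_coverage <= 1))
    stop("min_coverage must be in (0, 1]")
  if (max_evalue <= 0) stop("max_evalue must be positive")
  structure(list(min_identity = min_identity, max_evalue = max_evalue,
                 min_length = as.integer(min_length),
                 min_coverage = min_coverage),
            class = "AlignmentParams")
}

# Karlin-Altschul-style E-value for the built-in aligner. Parameters are
# fixed here (ungapped nucleotide defaults for match +2/mismatch -3) and
# reported in the hit table; thresholds on identity/length dominate in
# practice.
.KA_LAMBDA <- 0.625
.KA_K <- 0.41

.kaEvalue <- function(score, m, n) {
  .KA_K * as.numeric(m) * as.numeric(n) * exp(-.KA_LAMBDA * score)
}

# Seed-and-extend local search of `query` against `subject` (character
# strings). Seeds exact k-mers on both strands and clusters seeds per
# diagonal (substitution divergence keeps homologous seeds on one
# diagonal). Candidate clusters are screened by raw ungapped identity
# over a window extended `screen` bp beyond the cluster (chance seed
# clusters are diluted to background identity ~0.25; genuine homology
# stays high), then refined by local alignment (affine gaps) via
# Biostrings::pairwiseAlignment. Returns one row per refined candidate;
# threshold filtering and overlap merging are the caller's job.
.localAlignments <- function(query, subject, k = 8L, maxGap = 150L,
                             margin = 50L, screen = 40L,
                             screenId = 0.45, bothStrands = TRUE) {
  nq <- nchar(query); ns <- nchar(subject)
  if (nq < k || ns < k) return(.emptyAln())
  qk <- substring(query, 1:(nq - k + 1L), k:nq)
  qv <- strsplit(query, "")[[1]]
  strands <- if (bothStrands) c("+", "-") else "+"
  cand <- list()
  subjStr <- list("+" = subject)
  if (bothStrands) subjStr[["-"]] <- revComp(subject)
  for (strand in strands) {
    subj <- subjStr[[strand]]
    sk <- substring(subj, 1:(ns - k + 1L), k:ns)
    dtq <- data.table::data.table(kmer = qk, q = seq_along(qk))
    dts <- data.table::data.table(kmer = sk, s = seq_along(sk))
    hits <- dts[dtq, on = "kmer", allow.cartesian = TRUE, nomatch = NULL]
    if (nrow(hits) == 0L) next
    hits[, diag := q - s]
    data.table::setorder(hits, diag, q)
    hits[, brk := c(TRUE, diff(q) > maxGap), by = diag]
    hits[, cl := cumsum(brk)]
    cc <- hits[, .(q1 = min(q), q2 = max(q) + k - 1L,
                   s1 = min(s), s2 = max(s) + k - 1L,
                   nseeds = .N), by = .(diag, cl)]
    if (nrow(cc)) {
      sv <- strsplit(subj, "")[[1]]
      ok <- vapply(seq_len(nrow(cc)), function(i) {
        ext <- min(cc$q1[i] - 1L, cc$s1[i] - 1L, screen)
        a1 <- cc$q1[i] - ext; b1 <- cc$s1[i] - ext
        ext2 <- min(nq - cc$q2[i], ns - cc$s2[i], screen)
        a2 <- cc$q2[i] + ext2; b2 <- cc$s2[i] + ext2
        mean(qv[a1:a2] == sv[b1:b2]) >= screenId
      }, TRUE)
      cc <- cc[ok]
    }
    if (nrow(cc)) {
      cc[, strand := strand]
      cand[[strand]] <- cc
    }
  }
  if (!length(cand)) return(.emptyAln())
  cc <- data.table::rbindlist(cand)
  out <- vector("list", nrow(cc))
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 2,
                                                     mismatch = -3)
  for (i in seq_len(nrow(cc))) {
    qs <- max(1L, cc$q1[i] - margin); qe <- min(nq, cc$q2[i] + margin)
    ss <- max(1L, cc$s1[i] - margin); se <- min(ns, cc$s2[i] + margin)
    subj <- subjStr[[cc$strand[i]]]
    al <- Biostrings::pairwiseAlignment(
      substr(query, qs, qe), substr(subj, ss, se), type = "local",
      substitutionMatrix = submat, gapOpening = 5, gapExtension = 2)
    pr <- Biostrings::pattern(al); sr <- Biostrings::subject(al)
    if (nchar(as.character(pr)) == 0L) next
    tr <- .trimAlnEnds(as.character(pr), as.character(sr))
    if (is.null(tr)) next
    qA <- qs + Biostrings::start(pr@range) - 1L + tr$lq
    qB <- qs + Biostrings::end(pr@range) - 1L - tr$rq
    sA <- ss + Biostrings::start(sr@range) - 1L + tr$ls
    sB <- ss + Biostrings::end(sr@range) - 1L - tr$rs
    if (cc$strand[i] == "-") {             # map back to + coordinates
      tmp <- sA; sA <- ns - sB + 1L; sB <- ns - tmp + 1L
    }
    out[[i]] <- data.frame(
      q_start = qA, q_end = qB, s_start = sA, s_end = sB,
      strand = cc$strand[i], identity = tr$identity,
      aligned_length = tr$alen, score = tr$score,
      e_value = .kaEvalue(tr$score, nq, ns),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) .emptyAln() else res
}

# end-trimming of a gapped local alignment: noisy flank columns that a
# score-maximising alignment absorbs by luck are shaved off until each
# end opens with a dense match window (>= 5 matches in 8 columns), so
# reported boundaries track the homologous block
.trimAlnEnds <- function(pat, sub, win = 8L, minMatch = 5L) {
  p <- strsplit(pat, "")[[1]]; s <- strsplit(sub, "")[[1]]
  m <- p == s & p != "-"
  n <- length(m)
  a <- 1L; b <- n
  while (a <= b - win + 1L && sum(m[a:(a + win - 1L)]) < minMatch) a <- a + 1L
  while (b >= a + win - 1L && sum(m[(b - win + 1L):b]) < minMatch) b <- b - 1L
  if (b - a + 1L < win) return(NULL)
  pp <- p[a:b]; ss <- s[a:b]; mm <- m[a:b]
  nmatch <- sum(mm)
  nmis <- sum(pp != "-" & ss != "-" & !mm)
  gapRuns <- function(x) {
    r <- rle(x == "-")
    list(n = sum(r$values), tot = sum(r$lengths[r$values]))
  }
  gp <- gapRuns(pp); gs <- gapRuns(ss)
  score <- 2 * nmatch - 3 * nmis -
    (5 * (gp$n + gs$n) + 2 * (gp$tot + gs$tot))
  list(lq = sum(p[seq_len(a - 1L)] != "-"),
       rq = sum(p[seq(b + 1L, length.out = n - b)] != "-"),
       ls = sum(s[seq_len(a - 1L)] != "-"),
       rs = sum(s[seq(b + 1L, length.out = n - b)] != "-"),
       identity = nmatch / (b - a + 1L), alen = b - a + 1L,
       score = score)
}

.emptyAln <- function() {
  data.frame(q_start = integer(), q_end = integer(), s_start = integer(),
             s_end = integer(), strand = character(), identity = numeric(),
             aligned_length = integer(), score = numeric(),
             e_value = numeric())
}

#' Detect chloroplast-derived sequences (mtpt) in a mitochondrial genome
#'
#' Local alignments of the mt genome against the cp genome of the same
#' species, on both strands, filtered by the thresholds in `params`.
#' Overlapping mt-side hits are resolved to the highest-scoring
#' non-overlapping set (ties: longer, then leftmost). Per-hit GC is
#' computed on the mt-side sequence.
#'
#' @param mt,cp [AnnotatedGenome-class] (or [CircularSequence-class])
#'   mitochondrial and chloroplast genomes.
#' @param params an [alignmentParams()].
#' @return data.frame of insertion hits with columns `mt_start`,
#'   `mt_end`, `cp_start`, `cp_end`, `strand`, `identity`,
#'   `aligned_length`, `score`, `e_value`, `gc`, `age`, `cp_region`
#'   (the last two NA until [classifyAge()]/[regionOfOrigin()] run).
#' @export
findCpDerived <- function(mt, cp, params = alignmentParams()) {
  mtS <- if (is(mt, "AnnotatedGenome")) mt@seq else mt
  cpS <- if (is(cp, "AnnotatedGenome")) cp@seq else cp
  if (seqLength(mtS) < params$min_length ||
      seqLength(cpS) < params$min_length) {
    warning("genome shorter than min_length; no hits possible")
    return(.emptyHits())
  }
  aln <- .localAlignments(dnaSequence(mtS), dnaSequence(cpS))
  aln <- aln[aln$aligned_length >= params$min_length &
             aln$identity >= params$min_identity &
             aln$e_value <= params$max_evalue, , drop = FALSE]
  if (nrow(aln) == 0L) return(.emptyHits())
  aln <- .mergeMtHits(aln)
  data.frame(
    mt_start = aln$q_start, mt_end = aln$q_end,
    cp_start = aln$s_start, cp_end = aln$s_end, strand = aln$strand,
    identity = aln$identity, aligned_length = aln$aligned_length,
    score = aln$score, e_value = aln$e_value,
    gc = vapply(seq_len(nrow(aln)), function(i)
      gcContent(extractArc(mtS, aln$q_start[i], aln$q_end[i])), 0),
    age = NA_character_, cp_region = NA_character_,
    stringsAsFactors = FALSE)
}

.emptyHits <- function() {
  data.frame(mt_start = integer(), mt_end = integer(),
             cp_start = integer(), cp_end = integer(), strand = character(),
             identity = numeric(), aligned_length = integer(),
             score = numeric(), e_value = numeric(), gc = numeric(),
             age = character(), cp_region = character())
}

# greedy resolution of overlapping mt intervals: best score, then
# longest, then leftmost
.mergeMtHits <- function(aln) {
  aln <- aln[order(-aln$score, -aln$aligned_length, aln$q_start), ,
             drop = FALSE]
  keep <- logical(nrow(aln))
  ivs <- matrix(0L, 0, 2)
  for (i in seq_len(nrow(aln))) {
    s <- aln$q_start[i]; e <- aln$q_end[i]
    if (nrow(ivs) == 0L || all(e < ivs[, 1] | s > ivs[, 2])) {
      keep[i] <- TRUE
      ivs <- rbind(ivs, c(s, e))
    }
  }
  out <- aln[keep, , drop = FALSE]
  out[order(out$q_start), , drop = FALSE]
}

#' Classify insertion hits as old or new against a panel of mt genomes
#'
#' An insertion is \emph{old} when its mt-side sequence has at least one
#' homolog in the mt genomes of other species (alignment passing the
#' identity/E-value thresholds and covering >= `min_coverage` of the
#' hit), and \emph{new} when no panel genome carries a homolog. An empty
#' panel leaves all hits unclassified.
#'
#' @param hits output of [findCpDerived()].
#' @param mt the mt genome the hits were found in (sequence source).
#' @param panel list of [AnnotatedGenome-class]/[CircularSequence-class]
#'   mt genomes of other species.
#' @param params an [alignmentParams()].
#' @return `hits` with the `age` column set.
#' @export
classifyAge <- function(hits, mt, panel, params = alignmentParams()) {
  if (nrow(hits) == 0L) return(hits)
  if (length(panel) == 0L) {
    hits$age <- "unclassified"
    return(hits)
  }
  mtS <- if (is(mt, "AnnotatedGenome")) mt@seq else mt
  panelSeq <- lapply(panel, function(g)
    dnaSequence(if (is(g, "AnnotatedGenome")) g@seq else g))
  hits$age <- vapply(seq_len(nrow(hits)), function(i) {
    qseq <- extractArc(mtS, hits$mt_start[i], hits$mt_end[i])
    for (ps in panelSeq) {
      aln <- .localAlignments(qseq, ps)
      ok <- aln$identity >= params$min_identity &
        aln$e_value <= params$max_evalue &
        (aln$q_end - aln$q_start + 1L) >= params$min_coverage * nchar(qseq)
      if (any(ok)) return("old")
    }
    "new"
  }, "")
  hits
}

#' Chloroplast region of origin of insertion hits
#'
#' Assigns each hit to the cp region (LSC, SSC or IR) containing the
#' midpoint of its cp-side interval; hits straddling a junction are
#' assigned by midpoint.
#'
#' @param hits output of [findCpDerived()].
#' @param map [QuadripartiteMap-class] of the cp genome.
#' @return `hits` with the `cp_region` column set.
#' @export
regionOfOrigin <- function(hits, map) {
  if (nrow(hits) == 0L) return(hits)
  N <- map@genomeLength
  contains <- function(iv, p) ((p - iv[1]) %% N) <= ((iv[2] - iv[1]) %% N)
  hits$cp_region <- vapply(seq_len(nrow(hits)), function(i) {
    span <- (hits$cp_end[i] - hits$cp_start[i]) %% N
    mid <- .norm1(hits$cp_start[i] + span %/% 2L, N)
    if (contains(map@lsc, mid)) "LSC"
    else if (contains(map@ssc, mid)) "SSC"
    else "IR"
  }, "")
  hits
}

#' Summary statistics of plastid-derived sequence content
#'
#' @param hits output of [findCpDerived()] (ages assigned for the
#'   old/new breakdown to be meaningful).
#' @param mtLength mt genome length in bp.
#' @return list of class "TransferSummary": `n_hits`, `total_bp`,
#'   `fraction_of_mt`, `n_old`, `n_new`, `n_unclassified`, `gc_old`,
#'   `gc_new` (length-weighted GC of each class, percent) and
#'   `region_counts` (named vector over LSC/SSC/IR).
#' @export
summarizeTransfer <- function(hits, mtLength) {
  lens <- if (nrow(hits)) hits$mt_end - hits$mt_start + 1L else integer()
  wgc <- function(sel) {
    if (!any(sel)) return(NA_real_)
    100 * sum(hits$gc[sel] * lens[sel]) / sum(lens[sel])
  }
  isOld <- !is.na(hits$age) & hits$age == "old"
  isNew <- !is.na(hits$age) & hits$age == "new"
  rc <- c(LSC = sum(hits$cp_region == "LSC", na.rm = TRUE),
          SSC = sum(hits$cp_region == "SSC", na.rm = TRUE),
          IR = sum(hits$cp_region == "IR", na.rm = TRUE))
  total <- sum(lens)
  stopifnot(total <= mtLength)
  structure(list(
    n_hits = nrow(hits), total_bp = total,
    fraction_of_mt = total / mtLength,
    n_old = sum(isOld), n_new = sum(isNew),
    n_unclassified = nrow(hits) - sum(isOld) - sum(isNew),
    gc_old = wgc(isOld), gc_new = wgc(isNew),
    region_counts = rc), class = "TransferSummary")
}

#' @export
print.TransferSummary <- function(x, ...) {
  cat(sprintf("%d cp-derived fragments, %s bp (%.1f%% of the mt genome)\n",
              x$n_hits, format(x$total_bp, big.mark = ","),
              100 * x$fraction_of_mt))
  cat(sprintf("  old %d (GC %.2f%%), new %d (GC %.2f%%), unclassified %d\n",
              x$n_old, x$gc_old, x$n_new, x$gc_new, x$n_unclassified))
  cat(sprintf("  cp region of origin: LSC %d, SSC %d, IR %d\n",
              x$region_counts[["LSC"]], x$region_counts[["SSC"]],
              x$region_counts[["IR"]]))
  invisible(x)
}

#' Pearson correlation with missing-value handling
#'
#' Sample Pearson correlation coefficient after dropping pairs with
#' missing values; requires >= 3 complete pairs and non-zero variance in
#' both vectors (otherwise `NA`).
#'
#' @param x,y numeric vectors of equal length.
#' @return coefficient in `[-1, 1]`, or `NA_real_`.
#' @export
pearsonR <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L)
    stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Welch two-sample t test
#'
#' Welch statistic and two-sided p-value (Welch-Satterthwaite degrees
#' of freedom) via [stats::t.test()]. Degenerate zero-variance samples
#' are reported as an infinite statistic (p = 0) when the means differ
#' and 0 (p = 1) when they do not.
#'
#' @param x,y numeric samples with >= 2 values each.
#' @return list with `statistic`, `p_value`, `df`.
#' @export
welchT <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) stop("each sample needs >= 2 values")
  tt <- tryCatch(stats::t.test(x, y, var.equal = FALSE),
                 error = function(e) NULL)
  if (is.null(tt)) {                       # essentially constant data
    if (isTRUE(all.equal(mean(x), mean(y))))
      return(list(statistic = 0, p_value = 1, df = NA_real_))
    return(list(statistic = sign(mean(x) - mean(y)) * Inf, p_value = 0,
                df = NA_real_))
  }
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter))
}

#' Classify mitochondrial tRNAs as plastid-derived or native
#'
#' A mitochondrial tRNA is cp-derived when its best local alignment to
#' any tRNA of the same species' cp genome passes the identity and
#' E-value thresholds with coverage >= `min_coverage` of the mt tRNA;
#' otherwise it is native. Short sequences are aligned directly (no
#' seeding).
#'
#' @param mtTrnas named character vector of mt tRNA gene sequences.
#' @param cpTrnas named character vector of cp tRNA gene sequences of
#'   the same species.
#' @param params an [alignmentParams()].
#' @return data.frame with columns `trna`, `origin` ("cp-derived" /
#'   "native"), `best_match`, `identity`, `coverage`; the fraction
#'   cp-derived is in `attr(, "fraction_cp")`.
#' @export
classifyTrnas <- function(mtTrnas, cpTrnas, params = alignmentParams()) {
  if (length(cpTrnas) == 0L) {
    warning("empty cp tRNA set; all mt tRNAs reported native")
    out <- data.frame(trna = names(mtTrnas), origin = "native",
                      best_match = NA_character_, identity = NA_real_,
                      coverage = NA_real_, stringsAsFactors = FALSE)
    attr(out, "fraction_cp") <- 0
    return(out)
  }
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 2,
                                                     mismatch = -3)
  dbn <- sum(nchar(cpTrnas))
  rows <- lapply(seq_along(mtTrnas), function(i) {
    q <- mtTrnas[[i]]
    best <- list(id = 0, cov = 0, match = NA_character_, score = -Inf)
    for (j in seq_along(cpTrnas)) {
      for (s in c(cpTrnas[[j]], revComp(cpTrnas[[j]]))) {
        al <- Biostrings::pairwiseAlignment(q, s, type = "local",
          substitutionMatrix = submat, gapOpening = 5, gapExtension = 2)
        pr <- Biostrings::pattern(al)
        cov <- (Biostrings::end(pr@range) - Biostrings::start(pr@range) +
                  1L) / nchar(q)
        id <- Biostrings::pid(al, type = "PID1") / 100
        sc <- Biostrings::score(al)
        ok <- id >= params$min_identity && cov >= params$min_coverage &&
          .kaEvalue(sc, nchar(q), dbn) <= params$max_evalue
        if (ok && sc > best$score)
          best <- list(id = id, cov = cov, match = names(cpTrnas)[j],
                       score = sc)
      }
    }
    data.frame(trna = names(mtTrnas)[i],
               origin = if (!is.na(best$match)) "cp-derived" else "native",
               best_match = best$match, identity = if (!is.na(best$match))
                 best$id else NA_real_,
               coverage = if (!is.na(best$match)) best$cov else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "fraction_cp") <- mean(out$origin == "cp-derived")
  out
}
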