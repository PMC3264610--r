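# force x[p2] (or its complement for palindromic relations) to differ
# from x[p1], deterministically, so a planted repeat cannot extend
.breakMatch <- function(x, p1, p2, complemented) {
  b2 <- if (complemented) chartr("ACGT", "TGCA", x[p2]) else x[p2]
  if (x[p1] == b2) {
    repl <- setdiff(c("A", "C", "G", "T"), x[p1])[1L]
    x[p2] <- if (complemented) chartr("ACGT", "TGCA", repl) else repl
  }
  x
}

# run expr with a locally seeded RNG, restoring global RNG state
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else on.exit(rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Random DNA background
#'
#' i.i.d. bases at the requested GC content (G and C equiprobable, A and
#' T equiprobable). Never emits N.
#'
#' @param n length in bp.
#' @param gc target GC fraction.
#' @param seed optional RNG seed (global RNG state is restored).
#' @return DNA string.
#' @export
randomDNA <- function(n, gc = 0.40, seed = NULL) {
  .withSeed(seed, paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
                               prob = c((1 - gc) / 2, (1 - gc) / 2,
                                        gc / 2, gc / 2)),
                        collapse = ""))
}

#' Simulate a circular genome with planted repeat pairs
#'
#' Generates an i.i.d. background at the given GC and plants each
#' requested repeat by copying the block at `start1` to `start2`
#' (forward orientation) or inserting its reverse complement there
#' (palindromic). The returned truth table is a valid repeat-pair table
#' for [decomposeSegments()] and a recall target for
#' [findMaximalRepeats()].
#'
#' @param length genome length in bp.
#' @param repeats data.frame with columns `length`, `start1`, `start2`,
#'   `orientation` ("F"/"P"); may have zero rows. Planted copies must
#'   not overlap and must fit without wrapping the origin.
#' @param gc background GC fraction (default 0.43, typical of seed-plant
#'   mitochondrial genomes).
#' @param seed RNG seed; the same seed reproduces the same genome.
#' @return list with `genome` ([CircularSequence-class]) and `truth`
#'   (the repeat table).
#' @export
simulateRepeatGenome <- function(length, repeats = NULL, gc = 0.43,
                                 seed = NULL) {
  N <- as.integer(length)
  if (!is.null(repeats) && nrow(repeats)) {
    ends <- c(repeats$start1 + repeats$length - 1L,
              repeats$start2 + repeats$length - 1L)
    if (any(ends > N) || any(c(repeats$start1, repeats$start2) < 1L))
      stop("planted repeat does not fit in the genome")
    .checkNoOverlap(.repeatCopies(repeats, N), N)
  }
  s <- .withSeed(seed, {
    x <- strsplit(randomDNA(N, gc), "")[[1]]
    if (!is.null(repeats) && nrow(repeats)) {
      for (i in seq_len(nrow(repeats))) {
        L <- repeats$length[i]
        blk <- x[repeats$start1[i]:(repeats$start1[i] + L - 1L)]
        if (repeats$orientation[i] == "P")
          blk <- rev(chartr("ACGT", "TGCA", blk))
        x[repeats$start2[i]:(repeats$start2[i] + L - 1L)] <- blk
      }
      # break chance flank matches so each planted pair is exactly
      # maximal at its planted length (keeps the truth table exact)
      for (i in seq_len(nrow(repeats))) {
        L <- repeats$length[i]
        s1 <- repeats$start1[i]; s2 <- repeats$start2[i]
        if (repeats$orientation[i] == "F") {
          x <- .breakMatch(x, .norm1(s1 - 1L, N), .norm1(s2 - 1L, N), FALSE)
          x <- .breakMatch(x, .norm1(s1 + L, N), .norm1(s2 + L, N), FALSE)
        } else {
          x <- .breakMatch(x, .norm1(s1 - 1L, N), .norm1(s2 + L, N), TRUE)
          x <- .breakMatch(x, .norm1(s1 + L, N), .norm1(s2 - 1L, N), TRUE)
        }
      }
    }
    paste(x, collapse = "")
  })
  truth <- if (is.null(repeats)) {
    data.frame(length = integer(), start1 = integer(), start2 = integer(),
               orientation = character())
  } else repeats
  list(genome = circularSequence(s, id = sprintf("sim%s",
         if (is.null(seed)) "" else seed)), truth = truth)
}

#' Simulate a chloroplast-like quadripartite genome
#'
#' Lays out LSC + IRa + SSC + IRb around a circle, with IRb the exact
#' reverse complement of IRa, and returns the true region map.
#'
#' @param lsc,ir,ssc region lengths in bp (LSC >= SSC required).
#' @param gc background GC fraction (default 0.37, typical of
#'   angiosperm plastomes).
#' @param seed RNG seed.
#' @return list with `genome` ([CircularSequence-class]), `map`
#'   ([QuadripartiteMap-class]) and `regions` (coordinate table).
#' @export
simulateQuadripartiteGenome <- function(lsc = 8000L, ir = 2000L,
                                        ssc = 1500L, gc = 0.37,
                                        seed = NULL) {
  stopifnot(lsc >= ssc, ir >= 1L)
  lsc <- as.integer(lsc); ir <- as.integer(ir); ssc <- as.integer(ssc)
  N <- lsc + 2L * ir + ssc
  s <- .withSeed(seed, {
    lscS <- randomDNA(lsc, gc)
    iraS <- randomDNA(ir, gc)
    sscS <- randomDNA(ssc, gc)
    x <- strsplit(paste0(lscS, iraS, sscS, revComp(iraS)), "")[[1]]
    # pin the IR boundaries: the planted palindrome must not extend
    x <- .breakMatch(x, lsc, 1L, TRUE)                     # LSC/IRa vs IRb/LSC
    x <- .breakMatch(x, lsc + ir + 1L, lsc + ir + ssc, TRUE)  # SSC ends
    paste(x, collapse = "")
  })
  map <- new("QuadripartiteMap",
             ira = c(lsc + 1L, lsc + ir),
             irb = c(lsc + ir + ssc + 1L, N),
             lsc = c(1L, lsc),
             ssc = c(lsc + ir + 1L, lsc + ir + ssc),
             genomeLength = as.integer(N))
  list(genome = circularSequence(s, id = sprintf("simCp%s",
         if (is.null(seed)) "" else seed)),
       map = map, regions = quadripartiteRegions(map))
}

#' Mutate a sequence to an exact target identity
#'
#' Applies exactly `round((1 - identity) * nchar(seq))` substitutions at
#' uniformly drawn distinct positions, never substituting a base for
#' itself, so the Hamming identity of the output is the requested value
#' up to rounding. No indels (identity of the planted signal stays
#' exact, which keeps recall/precision checks deterministic).
#'
#' @param seq DNA string.
#' @param identity target identity in `[0.5, 1]`.
#' @param seed RNG seed.
#' @return mutated DNA string.
#' @export
mutateToIdentity <- function(seq, identity, seed = NULL) {
  if (identity < 0.5 || identity > 1)
    stop("identity must be in [0.5, 1]")
  n <- nchar(seq)
  nmut <- round((1 - identity) * n)
  if (nmut == 0L) return(seq)
  .withSeed(seed, {
    x <- strsplit(seq, "")[[1]]
    pos <- sample.int(n, nmut)
    for (p in pos) {
      x[p] <- sample(setdiff(c("A", "C", "G", "T"), x[p]), 1L)
    }
    paste(x, collapse = "")
  })
}

#' Simulate an mt/cp genome pair with planted plastid insertions
#'
#' Builds a quadripartite cp-like genome, an mt-like background at its
#' own GC, and overwrites mt loci with cp fragments mutated to the
#' requested identities. The truth table records the planted mt
#' interval, cp source interval, identity and cp region of origin, and
#' is the oracle for [findCpDerived()] recovery tests. Planted
#' intervals are kept disjoint and separated by at least 200 bp so
#' detected hits map one-to-one onto planted fragments.
#'
#' @param mtLength mt genome length in bp.
#' @param insertions data.frame with columns `cp_start`, `length`,
#'   `identity`, `mt_start`; or an integer n to draw that many random
#'   fragments (lengths 60-3000 bp, identities 0.82-1).
#' @param cpLayout list with lsc/ir/ssc lengths for the cp simulator.
#' @param mtGc,cpGc background GC fractions.
#' @param seed RNG seed.
#' @return list with `mt`, `cp` ([AnnotatedGenome-class]), `cpMap`
#'   ([QuadripartiteMap-class]) and `truth`.
#' @export
simulateTransferPair <- function(mtLength = 60000L, insertions = 5L,
                                 cpLayout = list(lsc = 8000L, ir = 2000L,
                                                 ssc = 1500L),
                                 mtGc = 0.43, cpGc = 0.37, seed = NULL) {
  .withSeed(seed, {
    cpSim <- simulateQuadripartiteGenome(cpLayout$lsc, cpLayout$ir,
                                         cpLayout$ssc, gc = cpGc)
    Ncp <- seqLength(cpSim$genome)
    if (is.numeric(insertions) && length(insertions) == 1L &&
        is.null(dim(insertions))) {
      n <- as.integer(insertions)
      lens <- pmax(60L, pmin(3000L, as.integer(round(
        stats::rlnorm(n, log(300), 1)))))
      insertions <- data.frame(
        cp_start = sample.int(Ncp - max(lens), n),
        length = lens,
        identity = stats::runif(n, 0.82, 1),
        mt_start = .spacedStarts(n, lens, mtLength))
    }
    if (any(insertions$identity < 0.5))
      stop("requested identity < 0.5 is outside the mutation model")
    if (any(insertions$mt_start + insertions$length - 1L > mtLength) ||
        any(insertions$cp_start + insertions$length - 1L > Ncp))
      stop("planted insertion does not fit")
    ord <- order(insertions$mt_start)
    iv <- insertions[ord, ]
    if (any(diff(iv$mt_start) < utils::head(iv$length, -1) + 200L))
      stop("planted mt intervals overlap or are closer than 200 bp")
    mt <- strsplit(randomDNA(mtLength, mtGc), "")[[1]]
    truth <- insertions
    truth$mt_end <- truth$mt_start + truth$length - 1L
    truth$cp_end <- truth$cp_start + truth$length - 1L
    truth$gc <- NA_real_
    truth$terminal_clean <- NA_integer_
    for (i in seq_len(nrow(truth))) {
      frag0 <- substr(dnaSequence(cpSim$genome), truth$cp_start[i],
                      truth$cp_end[i])
      frag <- mutateToIdentity(frag0, truth$identity[i])
      truth$gc[i] <- gcContent(frag)
      # unmutated run length at the fragment ends: detected boundaries
      # can only be exact where the terminal bases still match the source
      mut <- which(strsplit(frag, "")[[1]] != strsplit(frag0, "")[[1]])
      truth$terminal_clean[i] <- if (!length(mut)) truth$length[i] else
        min(mut[1L] - 1L, truth$length[i] - mut[length(mut)])
      mt[truth$mt_start[i]:truth$mt_end[i]] <- strsplit(frag, "")[[1]]
    }
    dummy <- data.frame(mt_start = truth$mt_start, mt_end = truth$mt_end,
                        cp_start = truth$cp_start, cp_end = truth$cp_end)
    truth$cp_region <- regionOfOrigin(
      cbind(dummy, strand = "+", identity = truth$identity,
            aligned_length = truth$length, score = NA_real_,
            e_value = NA_real_, gc = truth$gc, age = NA_character_,
            cp_region = NA_character_), cpSim$map)$cp_region
    list(mt = annotatedGenome(paste(mt, collapse = ""), id = "simMt"),
         cp = annotatedGenome(cpSim$genome),
         cpMap = cpSim$map, truth = truth)
  })
}

.spacedStarts <- function(n, lens, N, gap = 300L) {
  # random disjoint start positions with a minimum inter-fragment gap
  for (try in 1:200) {
    st <- sort(sample.int(N - max(lens) - gap, n))
    ok <- n == 1L || all(diff(st) >= lens[-n] + gap)
    if (ok) return(st)
  }
  stop("could not place fragments without overlap; genome too small")
}

#' Simulate a mitochondrial tRNA set with known plastid origins
#'
#' Generates `nCp` cp tRNA genes (random sequences), copies `nDerived`
#' of them into the mt set with point mutations at `mutationRate`, and
#' adds `nNative` unrelated native mt tRNAs. Truth is in the names.
#'
#' @param nNative,nCp,nDerived counts of native mt tRNAs, cp tRNAs and
#'   cp-derived mt tRNAs (`nDerived <= nCp`).
#' @param trnaLength gene length in bp (default 75, a typical tRNA).
#' @param mutationRate per-base substitution rate applied to derived
#'   copies (default 0.02).
#' @param seed RNG seed.
#' @return list with `mtTrnas`, `cpTrnas` (named character vectors) and
#'   `truth` (data.frame trna/origin).
#' @export
simulateTrnaSet <- function(nNative = 6L, nCp = 8L, nDerived = 4L,
                            trnaLength = 75L, mutationRate = 0.02,
                            seed = NULL) {
  stopifnot(nDerived <= nCp)
  .withSeed(seed, {
    cp <- stats::setNames(
      vapply(seq_len(nCp), function(i) randomDNA(trnaLength, 0.5), ""),
      paste0("cp_trna", seq_len(nCp)))
    derived <- vapply(seq_len(nDerived), function(i)
      mutateToIdentity(cp[[i]], 1 - mutationRate), "")
    native <- vapply(seq_len(nNative), function(i)
      randomDNA(trnaLength, 0.5), "")
    mt <- stats::setNames(c(derived, native),
                          c(paste0("mt_trna_cp", seq_len(nDerived)),
                            paste0("mt_trna_nat", seq_len(nNative))))
    list(mtTrnas = mt, cpTrnas = cp,
         truth = data.frame(
           trna = names(mt),
           origin = rep(c("cp-derived", "native"), c(nDerived, nNative)),
           stringsAsFactors = FALSE))
  })
}
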