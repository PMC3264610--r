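#' Decompose a master circle into inter-repeat segments
#'
#' Given a circular genome length and a set of non-overlapping repeat
#' pairs, returns the segments lying between consecutive repeat copies
#' in circular order. Segments are labelled A, B, ... alphabetically
#' starting from the segment with the smallest start coordinate. Both
#' the inclusive base count and the "printed" length (plain coordinate
#' difference `end - start mod N`, the convention of published segment
#' tables) are reported; inclusive segment lengths plus twice the repeat
#' lengths tile the circle exactly.
#'
#' @param N genome length in bp.
#' @param pairs data.frame with columns `length`, `start1`, `start2`,
#'   `orientation` ("F"/"P"); typically a subset of
#'   [findMaximalRepeats()] output (recombinationally active pairs are a
#'   user selection, since activity is established by sequencing
#'   evidence, not sequence alone).
#' @return data.frame with columns `label`, `start`, `end`,
#'   `printed_length`, `inclusive_length`.
#' @examples
#' decomposeSegments(510519, boeaRecombinationPairs())
#' @export
decomposeSegments <- function(N, pairs) {
  N <- as.integer(N)
  if (is.null(pairs) || nrow(pairs) == 0L) {
    return(data.frame(label = "A", start = 1L, end = N,
                      printed_length = N - 1L, inclusive_length = N,
                      stringsAsFactors = FALSE))
  }
  copies <- .repeatCopies(pairs, N)
  .checkNoOverlap(copies, N)
  copies <- copies[order(copies$start), ]
  n <- nrow(copies)
  segs <- list()
  for (i in seq_len(n)) {
    from <- .norm1(copies$end[i] + 1L, N)
    nxt <- if (i == n) 1L else i + 1L
    to <- .norm1(copies$start[nxt] - 1L, N)
    gap <- (copies$start[nxt] - copies$end[i] - 1L) %% N
    if (gap == 0L) next                     # adjacent copies: no segment
    segs[[length(segs) + 1L]] <- data.frame(
      start = from, end = to,
      printed_length = arcLength(from, to, N, "printed"),
      inclusive_length = arcLength(from, to, N, "inclusive"))
  }
  out <- do.call(rbind, segs)
  out <- out[order(out$start), , drop = FALSE]
  out <- cbind(label = LETTERS[seq_len(nrow(out))], out,
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  stopifnot(sum(out$inclusive_length) + 2L * sum(pairs$length) == N)
  out
}

.repeatCopies <- function(pairs, N) {
  id <- .pairIds(pairs)
  data.frame(
    pair = rep(id, 2L),
    copy = rep(1:2, each = nrow(pairs)),
    start = c(pairs$start1, pairs$start2),
    end = .norm1(c(pairs$start1, pairs$start2) + rep(pairs$length, 2L) - 1L, N),
    len = rep(pairs$length, 2L),
    orientation = rep(pairs$orientation, 2L),
    stringsAsFactors = FALSE)
}

.pairIds <- function(pairs) {
  if (!is.null(pairs$pair_id)) return(as.character(pairs$pair_id))
  make.unique(paste0("r", pairs$length), sep = "_")
}

.checkNoOverlap <- function(copies, N) {
  n <- nrow(copies)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    # circular interval overlap: distance between starts shorter than a copy
    d1 <- (copies$start[j] - copies$start[i]) %% N
    d2 <- (copies$start[i] - copies$start[j]) %% N
    if (d1 < copies$len[i] || d2 < copies$len[j])
      stop(sprintf("repeat copies overlap: %s copy %d and %s copy %d",
                   copies$pair[i], copies$copy[i],
                   copies$pair[j], copies$copy[j]))
  }
  invisible(TRUE)
}

#' Build the master-circle molecule state
#'
#' Arranges repeat copies and segments in genomic order into a
#' [MoleculeState-class]. All units carry strand + except the second
#' copy of each palindromic pair, which is the reverse complement of the
#' first and therefore carries strand -.
#'
#' @param segments output of [decomposeSegments()].
#' @param pairs the same repeat pair table.
#' @param N genome length (only needed to order units; inferred from
#'   segments and pairs when omitted).
#' @return a [MoleculeState-class].
#' @export
buildMasterState <- function(segments, pairs, N = NULL) {
  if (is.null(N))
    N <- sum(segments$inclusive_length) + 2L * sum(pairs$length)
  if (is.null(pairs) || nrow(pairs) == 0L) {
    return(new("MoleculeState",
               units = data.frame(type = "segment", id = segments$label,
                                  strand = 1L, stringsAsFactors = FALSE),
               provenance = character()))
  }
  copies <- .repeatCopies(pairs, N)
  units <- rbind(
    data.frame(type = "repeat", id = copies$pair,
               strand = ifelse(copies$orientation == "P" & copies$copy == 2L,
                               -1L, 1L),
               start = copies$start, stringsAsFactors = FALSE),
    data.frame(type = "segment", id = segments$label, strand = 1L,
               start = segments$start, stringsAsFactors = FALSE))
  units <- units[order(units$start), c("type", "id", "strand")]
  rownames(units) <- NULL
  st <- new("MoleculeState", units = units, provenance = character())
  validObject(st)
  st
}

#' @rdname buildMasterState
#' @param units data.frame with columns type/id/strand (cyclic order).
#' @param provenance character vector of applied events.
#' @export
moleculeState <- function(units, provenance = character()) {
  units$strand <- as.integer(units$strand)
  st <- new("MoleculeState",
            units = units[, c("type", "id", "strand")],
            provenance = provenance)
  validObject(st)
  st
}

setMethod("show", "MoleculeState", function(object) {
  u <- object@units
  cat("MoleculeState:", paste0(u$id, ifelse(u$strand > 0, "+", "-"),
                               collapse = " "), "\n")
  if (length(object@provenance))
    cat("  events:", paste(object@provenance, collapse = " ; "), "\n")
})

#' Units of a molecule state
#' @param state a [MoleculeState-class].
#' @export
moleculeUnits <- function(state) state@units

#' Current orientation of a repeat pair within a molecule
#'
#' A pair is \emph{inverted} iff its two copies carry opposite strand
#' signs in the current state (recombination across it yields one
#' rearranged circle), and \emph{direct} iff they carry the same sign
#' (recombination excises two subcircles). Orientation can change after
#' prior inversions carry one copy onto the other strand.
#'
#' @param state a [MoleculeState-class].
#' @param pairId repeat pair identifier (e.g. "r1474").
#' @return "inverted" or "direct".
#' @export
pairOrientation <- function(state, pairId) {
  i <- which(state@units$type == "repeat" & state@units$id == pairId)
  if (length(i) != 2L)
    stop("pair '", pairId, "' does not occur exactly twice in this molecule")
  if (state@units$strand[i[1]] != state@units$strand[i[2]]) "inverted"
  else "direct"
}

#' Intra-molecular recombination across a repeat pair
#'
#' Applies one recombination event between the two copies of `pairId`.
#' If the pair is currently inverted, the product is a single isomeric
#' circle: one arc between the two copies is reversed and every unit in
#' it strand-flipped (both arc choices yield the same molecule up to a
#' whole-molecule flip; this is asserted, not assumed). If the pair is
#' direct, the products are the two subgenomic circles obtained by
#' excision, each retaining one repeat copy.
#'
#' @param state a [MoleculeState-class].
#' @param pairId repeat pair identifier.
#' @return list with `kind` ("isomer" or "excision") and `products`
#'   (list of 1 or 2 [MoleculeState-class] objects).
#' @export
recombine <- function(state, pairId) {
  u <- state@units
  pos <- which(u$type == "repeat" & u$id == pairId)
  if (length(pos) != 2L)
    stop("pair '", pairId, "' does not occur exactly twice in this molecule")
  p1 <- pos[1]; p2 <- pos[2]
  n <- nrow(u)
  ev <- paste0("recombine(", pairId, ")")
  if (pairOrientation(state, pairId) == "inverted") {
    prodA <- .invertArc(u, p1, p2, n)
    prodB <- .invertArc(u, p2, p1, n)
    sA <- moleculeState(prodA, c(state@provenance, ev))
    sB <- moleculeState(prodB, c(state@provenance, ev))
    if (canonicalKey(sA) != canonicalKey(sB))
      stop("internal error: the two inversion arcs gave different molecules")
    list(kind = "isomer", products = list(sA))
  } else {
    idx1 <- .cycleRange(p1, p2 - 1L, n)     # copy at p1 plus arc to p2
    idx2 <- .cycleRange(p2, p1 - 1L, n)     # copy at p2 plus the rest
    list(kind = "excision",
         products = list(
           moleculeState(u[idx1, , drop = FALSE], c(state@provenance, ev)),
           moleculeState(u[idx2, , drop = FALSE], c(state@provenance, ev))))
  }
}

.cycleRange <- function(from, to, n) {
  from <- ((from - 1L) %% n) + 1L
  to <- ((to - 1L) %% n) + 1L
  if (from <= to) from:to else c(from:n, 1:to)
}

.invertArc <- function(u, p1, p2, n) {
  # reverse and strand-flip the units strictly between p1 and p2
  arc <- if (((p1 %% n) + 1L) == p2)
    integer(0) else .cycleRange(p1 + 1L, p2 - 1L, n)
  if (length(arc)) {
    u[arc, ] <- u[rev(arc), ]
    u$strand[arc] <- -u$strand[arc]
  }
  rownames(u) <- NULL
  u
}

#' Canonical text key of a molecule
#'
#' Unique identifier of a circular signed molecule: the lexicographic
#' minimum over all rotations of the unit string and all rotations of
#' the whole-molecule flip (order reversed, all strands flipped). Two
#' states describe the same molecule iff their keys are equal.
#'
#' @param state a [MoleculeState-class].
#' @return character key.
#' @export
canonicalKey <- function(state) {
  u <- state@units
  tok <- paste0(u$id, ifelse(u$strand > 0, "+", "-"))
  flip <- rev(paste0(u$id, ifelse(u$strand > 0, "-", "+")))
  n <- length(tok)
  best <- NULL
  for (v in list(tok, flip)) for (r in seq_len(n)) {
    key <- paste(v[c(r:n, seq_len(r - 1L))], collapse = "|")
    if (is.null(best) || key < best) best <- key
  }
  best
}

#' Enumerate the isomeric molecules reachable from a master circle
#'
#' Breadth-first closure of the inversion operation: starting from the
#' master circle, [recombine()] is applied at every currently-inverted
#' pair of every reached single-circle state until no new canonical
#' molecule appears. Excision products of direct pairs are recorded but
#' not expanded further (subgenomic circles are reported separately, not
#' counted as isomers). The master circle itself is excluded from the
#' isomer set.
#'
#' @param mc master-circle [MoleculeState-class] from
#'   [buildMasterState()].
#' @param maxStates safety cap on the BFS frontier.
#' @return list with `isomers` (named list of [MoleculeState-class],
#'   keyed by canonical key), `excisions` (list of excision outcomes,
#'   each with the state it arose from and its two products) and
#'   `masterKey`.
#' @examples
#' pairs <- boeaRecombinationPairs()
#' segs <- decomposeSegments(510519, pairs)
#' mc <- buildMasterState(segs, pairs)
#' length(enumerateIsomers(mc)$isomers)   # 4
#' @export
enumerateIsomers <- function(mc, maxStates = 10000L) {
  mcKey <- canonicalKey(mc)
  seen <- list()
  seen[[mcKey]] <- mc
  queue <- list(mc)
  excisions <- list()
  excSeen <- character()
  while (length(queue)) {
    st <- queue[[1L]]; queue <- queue[-1L]
    pairIds <- unique(st@units$id[st@units$type == "repeat"])
    pairIds <- pairIds[vapply(pairIds, function(p)
      sum(st@units$type == "repeat" & st@units$id == p) == 2L, TRUE)]
    for (p in pairIds) {
      out <- recombine(st, p)
      if (out$kind == "isomer") {
        prod <- out$products[[1L]]
        key <- canonicalKey(prod)
        if (is.null(seen[[key]])) {
          seen[[key]] <- prod
          queue[[length(queue) + 1L]] <- prod
          if (length(seen) > maxStates) stop("state space exceeds maxStates")
        }
      } else {
        ek <- paste(sort(vapply(out$products, canonicalKey, "")),
                    collapse = " // ")
        if (!ek %in% excSeen) {
          excSeen <- c(excSeen, ek)
          excisions[[length(excisions) + 1L]] <-
            list(from = canonicalKey(st), products = out$products)
        }
      }
    }
  }
  isomers <- seen[setdiff(names(seen), mcKey)]
  list(isomers = isomers, excisions = excisions, masterKey = mcKey)
}

#' Per-gene exon strand pattern within a molecule
#'
#' Places each exon feature into the segment (or repeat copy) containing
#' it on the master circle, then applies the molecule's segment strands
#' to produce the ordered exon strand pattern of each gene as a "+/-"
#' string in exon order. Genes with exons on both strands are flagged
#' cross-strand (their mature transcript requires trans-splicing); exons
#' whose segment is absent from the molecule (e.g. on an excised
#' subcircle) are flagged missing ("." in the pattern).
#'
#' @param state a [MoleculeState-class].
#' @param exons data.frame of exon features: columns `name` (gene),
#'   `start`, `end`, `strand` ("+"/"-" on the master circle),
#'   `exon_index`.
#' @param segments [decomposeSegments()] output for the master circle.
#' @param pairs repeat pair table (needed to place exons inside repeat
#'   copies); may be NULL if no exon lies in a repeat.
#' @param N genome length.
#' @return data.frame with columns `gene`, `pattern`, `cross_strand`,
#'   `n_missing`.
#' @export
moleculeGeneReport <- function(state, exons, segments, pairs = NULL,
                               N = NULL) {
  if (is.null(N))
    N <- sum(segments$inclusive_length) +
      (if (is.null(pairs)) 0L else 2L * sum(pairs$length))
  # strand multiplier of each unit in this state, relative to the MC
  # (segments are all + in the MC, so the state strand IS the flip)
  u <- state@units
  segFlip <- structure(u$strand[u$type == "segment"],
                       names = u$id[u$type == "segment"])
  contains <- function(a, b, p) {            # [a,b] circular contains p?
    ((p - a) %% N) <= ((b - a) %% N)
  }
  within <- function(a, b, s, e) {           # [s,e] inside [a,b], circularly
    contains(a, b, s) && contains(a, b, e) &&
      ((s - a) %% N) <= ((e - a) %% N)
  }
  place <- function(s, e) {
    for (i in seq_len(nrow(segments)))
      if (within(segments$start[i], segments$end[i], s, e))
        return(segments$label[i])
    if (!is.null(pairs) && nrow(pairs)) {
      copies <- .repeatCopies(pairs, N)
      for (i in seq_len(nrow(copies)))
        if (within(copies$start[i], copies$end[i], s, e))
          return(copies$pair[i])
    }
    NA_character_
  }
  res <- lapply(split(exons, exons$name), function(g) {
    g <- g[order(g$exon_index), , drop = FALSE]
    pat <- vapply(seq_len(nrow(g)), function(i) {
      seg <- place(g$start[i], g$end[i])
      if (is.na(seg))
        stop("exon ", g$name[i], " e", g$exon_index[i],
             " spans a segment boundary")
      if (!seg %in% names(segFlip)) {
        if (seg %in% u$id[u$type == "repeat"]) {
          # exon inside a repeat copy: use that copy's strand
          flip <- u$strand[u$type == "repeat" & u$id == seg][1L]
        } else return(".")                   # segment not in this molecule
      } else flip <- segFlip[[seg]]
      base <- if (g$strand[i] == "+") 1L else -1L
      if (base * flip > 0) "+" else "-"
    }, "")
    data.frame(gene = g$name[1L], pattern = paste(pat, collapse = ""),
               cross_strand = all(c("+", "-") %in% pat),
               n_missing = sum(pat == "."), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
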