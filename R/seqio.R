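#' Construct a CircularSequence
#'
#' @param sequence DNA string (character scalar) over A/C/G/T/N; lower
#'   case is accepted and uppercased.
#' @param id sequence identifier.
#' @param circular logical; default TRUE (organellar genomes map as
#'   circles).
#' @return a [CircularSequence-class] object.
#' @examples
#' g <- circularSequence("ACGTACGT", id = "toy")
#' seqLength(g)
#' @export
circularSequence <- function(sequence, id = "seq", circular = TRUE) {
  new("CircularSequence", id = as.character(id),
      sequence = toupper(as.character(sequence)),
      circular = isTRUE(circular))
}

#' @rdname circularSequence
#' @param x a CircularSequence or AnnotatedGenome.
#' @export
seqLength <- function(x) {
  if (is(x, "AnnotatedGenome")) x <- x@seq
  nchar(x@sequence)
}

#' @rdname circularSequence
#' @export
seqId <- function(x) {
  if (is(x, "AnnotatedGenome")) x <- x@seq
  x@id
}

#' @rdname circularSequence
#' @export
isCircular <- function(x) {
  if (is(x, "AnnotatedGenome")) x <- x@seq
  x@circular
}

#' @rdname circularSequence
#' @export
dnaSequence <- function(x) {
  if (is(x, "AnnotatedGenome")) x <- x@seq
  x@sequence
}

setMethod("show", "CircularSequence", function(object) {
  cat(sprintf("CircularSequence '%s': %s bp (%s)\n", object@id,
      format(nchar(object@sequence), big.mark = ","),
      if (object@circular) "circular" else "linear"))
})

setMethod("show", "AnnotatedGenome", function(object) {
  show(object@seq)
  cat(sprintf("  %d features\n", nrow(object@features)))
})

setMethod("show", "QuadripartiteMap", function(object) {
  N <- object@genomeLength
  fmt <- function(name, iv) {
    L <- arcLength(iv[1], iv[2], N, "inclusive")
    cat(sprintf("  %-4s %9d..%-9d %7d bp  (%.1f%%)\n", name, iv[1], iv[2],
                L, 100 * L / N))
  }
  cat(sprintf("QuadripartiteMap on a %s bp genome\n", format(N, big.mark = ",")))
  fmt("LSC", object@lsc); fmt("IRa", object@ira)
  fmt("SSC", object@ssc); fmt("IRb", object@irb)
})

#' Accessors for AnnotatedGenome
#'
#' @param x an [AnnotatedGenome-class].
#' @return `features()` returns the feature data.frame; `genomeSeq()`
#'   the underlying [CircularSequence-class].
#' @export
features <- function(x) x@features

#' @rdname features
#' @export
genomeSeq <- function(x) x@seq

#' Build an AnnotatedGenome from parts
#'
#' @param seq a [CircularSequence-class] (or DNA string).
#' @param features feature data.frame (see [AnnotatedGenome-class]);
#'   empty by default.
#' @param id,circular passed to [circularSequence()] when `seq` is a
#'   plain string.
#' @export
annotatedGenome <- function(seq, features = emptyFeatures(), id = "seq",
                            circular = TRUE) {
  if (is.character(seq)) seq <- circularSequence(seq, id, circular)
  new("AnnotatedGenome", seq = seq, features = as.data.frame(features))
}

#' @rdname annotatedGenome
#' @export
emptyFeatures <- function() {
  data.frame(name = character(), kind = character(), start = integer(),
             end = integer(), strand = character(), exon_index = integer(),
             stringsAsFactors = FALSE)
}

#' Arc length on a circle under two coordinate conventions
#'
#' Length of the arc running clockwise from `start` to `end` on a circle
#' of `N` bases. The \strong{inclusive} convention counts both endpoints,
#' `((end - start) mod N) + 1`; the \strong{printed} convention is the
#' plain coordinate difference `(end - start) mod N`, the convention used
#' by published segment tables where inter-repeat segment lengths plus
#' twice the repeat lengths must tile the genome exactly. Arcs wrap the
#' origin whenever `end < start`.
#'
#' @param start,end 1-based positions in `[1, N]`.
#' @param N circle length in bp.
#' @param convention "inclusive" or "printed".
#' @return integer number of bases.
#' @examples
#' arcLength(405602, 42272, 510519, "printed")  # wraps the origin
#' arcLength(5, 5, 100, "inclusive")            # a single base
#' @export
arcLength <- function(start, end, N, convention = c("inclusive", "printed")) {
  convention <- match.arg(convention)
  if (any(start < 1L | start > N | end < 1L | end > N))
    stop("positions must lie in [1, ", N, "]")
  d <- (end - start) %% N
  as.integer(if (convention == "inclusive") d + 1L else d)
}

#' GC content of a DNA string
#'
#' Fraction (G + C) / (A + C + G + T); ambiguous N bases are excluded
#' from numerator and denominator. A sequence of only N characters has
#' undefined GC and is reported as `NA`.
#'
#' @param seq DNA string (character scalar), or a
#'   [CircularSequence-class].
#' @return fraction in `[0, 1]`, or `NA_real_`.
#' @examples
#' gcContent("ATGCN")  # 0.5
#' @export
gcContent <- function(seq) {
  if (is(seq, "CircularSequence")) seq <- seq@sequence
  if (!nzchar(seq)) stop("empty sequence")
  f <- Biostrings::letterFrequency(Biostrings::DNAString(seq),
                                   c("A", "C", "G", "T"))
  tot <- sum(f)
  if (tot == 0) return(NA_real_)
  unname((f[["C"]] + f[["G"]]) / tot)
}

#' Reverse complement of a DNA string
#'
#' @param seq DNA string over A/C/G/T/N.
#' @return reverse-complemented string.
#' @export
revComp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Extract a (possibly origin-wrapping) arc of a sequence
#'
#' @param x [CircularSequence-class] (or [AnnotatedGenome-class]).
#' @param start,end 1-based inclusive positions; `start > end` wraps the
#'   origin and is only valid on circular sequences.
#' @return character substring.
#' @export
extractArc <- function(x, start, end) {
  if (is(x, "AnnotatedGenome")) x <- x@seq
  N <- nchar(x@sequence)
  if (start < 1L || start > N || end < 1L || end > N)
    stop("positions must lie in [1, ", N, "]")
  if (start <= end) return(substr(x@sequence, start, end))
  if (!x@circular) stop("arc wraps the origin of a linear sequence")
  paste0(substr(x@sequence, start, N), substr(x@sequence, 1L, end))
}

#' Rotate a circular sequence
#'
#' Returns the same circle read from a new origin, so that old position
#' `offset + 1` becomes position 1. Structural results (repeats,
#' segments, isomer counts) are invariant under rotation.
#'
#' @param x [CircularSequence-class].
#' @param offset integer in `[0, N)`.
#' @export
rotateSequence <- function(x, offset) {
  N <- nchar(x@sequence)
  offset <- offset %% N
  if (offset == 0) return(x)
  circularSequence(paste0(substr(x@sequence, offset + 1L, N),
                          substr(x@sequence, 1L, offset)),
                   id = x@id, circular = x@circular)
}

#' Load a genome from FASTA or GenBank
#'
#' FASTA reading is delegated to Biostrings; GenBank flat files are
#' parsed directly (LOCUS line, FEATURES table with
#' `join()`/`complement()` locations, ORIGIN sequence). Circularity is
#' taken from the GenBank LOCUS line when present, else from the
#' `circular` argument.
#'
#' `join()` locations are mapped to one feature row per component with
#' `exon_index` 1, 2, ...; a two-component join that abuts the origin of
#' a circular sequence (`a..N, 1..b`) is merged into a single
#' origin-wrapping row (`start > end`), so both split and wrapped
#' encodings of origin-spanning features load identically.
#'
#' @param path file path.
#' @param format "auto" (by extension), "fasta" or "genbank".
#' @param circular fallback circularity flag for FASTA input.
#' @param record for multi-record FASTA, index or name of the record to
#'   annotate (all records are still checked to parse); default 1.
#' @return an [AnnotatedGenome-class].
#' @export
loadGenome <- function(path, format = c("auto", "fasta", "genbank"),
                       circular = TRUE, record = 1L) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(gb|gbk|genbank)$", path, ignore.case = TRUE))
      "genbank" else "fasta"
  }
  if (format == "fasta") {
    set <- tryCatch(Biostrings::readDNAStringSet(path),
                    error = function(e)
                      stop("cannot parse FASTA '", path, "': ",
                           conditionMessage(e)))
    if (length(set) == 0L) stop("no records in FASTA: ", path)
    s <- as.character(set[[record]])
    if (!nzchar(s)) stop("empty sequence in ", path)
    id <- sub("\\s.*", "", names(set)[record])
    annotatedGenome(circularSequence(s, id = id, circular = circular))
  } else {
    readGenBankFlat(path, circular = circular)
  }
}

#' Parse a GenBank flat file
#'
#' Minimal reader for annotated organellar genome records: understands
#' LOCUS (length, circular/linear), the FEATURES table for keys gene,
#' CDS, tRNA, rRNA and repeat_region (locations: `a..b`,
#' `complement(...)`, `join(...)`, partial markers `<`/`>`), and the
#' ORIGIN sequence block.
#'
#' @inheritParams loadGenome
#' @return an [AnnotatedGenome-class].
#' @export
readGenBankFlat <- function(path, circular = TRUE) {
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (length(locus)) {
    if (grepl("\\bcircular\\b", locus[1], ignore.case = TRUE)) circular <- TRUE
    if (grepl("\\blinear\\b", locus[1], ignore.case = TRUE)) circular <- FALSE
    id <- strsplit(trimws(sub("^LOCUS", "", locus[1])), "\\s+")[[1]][1]
  } else id <- basename(path)

  ori <- grep("^ORIGIN", lines)
  if (!length(ori))
    stop("GenBank parse error in '", path, "': no ORIGIN block")
  endr <- grep("^//", lines)
  endr <- if (length(endr)) endr[endr > ori[1]][1] else length(lines) + 1L
  seqlines <- if (endr - 1L > ori[1]) lines[(ori[1] + 1L):(endr - 1L)]
              else character()
  s <- toupper(gsub("[^acgtnACGTN]", "", paste(seqlines, collapse = "")))
  if (!nzchar(s)) stop("empty sequence in GenBank record: ", path)

  featStart <- grep("^FEATURES", lines)
  feats <- emptyFeatures()
  if (length(featStart)) {
    block <- lines[(featStart[1] + 1L):(ori[1] - 1L)]
    feats <- .parseFeatureBlock(block, nchar(s), circular, path)
  }
  annotatedGenome(circularSequence(s, id = id, circular = circular), feats)
}

.GB_KIND <- c(gene = "gene", CDS = "exon", tRNA = "tRNA", rRNA = "rRNA",
              repeat_region = "repeat")

.parseFeatureBlock <- function(block, N, circular, path) {
  # group physical lines into logical feature entries
  isKey <- grepl("^ {5}\\S", block)
  idx <- cumsum(isKey)
  out <- list()
  for (g in split(seq_along(block), idx)) {
    if (idx[g[1]] == 0L) next
    keyline <- block[g[1]]
    key <- sub("^ {5}(\\S+).*", "\\1", keyline)
    if (!key %in% names(.GB_KIND)) next
    rest <- c(sub("^ {5}\\S+\\s*", "", keyline), trimws(block[g[-1]]))
    qual1 <- grep("^/", rest)
    locstr <- paste(rest[seq_len(if (length(qual1)) qual1[1] - 1L
                                 else length(rest))], collapse = "")
    quals <- rest[grep("^/", rest)]
    getq <- function(q) {
      m <- grep(paste0("^/", q, "="), quals, value = TRUE)
      if (!length(m)) return(NA_character_)
      gsub('"', "", sub(paste0("^/", q, "="), "", m[1]))
    }
    name <- getq("gene")
    if (is.na(name)) name <- getq("locus_tag")
    if (is.na(name)) name <- getq("product")
    if (is.na(name)) name <- key
    loc <- .parseLocation(locstr, N, circular)
    if (is.null(loc))
      stop("GenBank parse error in '", path, "': bad location '", locstr, "'")
    kind <- .GB_KIND[[key]]
    nseg <- nrow(loc)
    out[[length(out) + 1L]] <- data.frame(
      name = name, kind = kind, start = loc$start, end = loc$end,
      strand = if (loc$complement[1]) "-" else "+",
      exon_index = if (kind %in% c("exon", "tRNA") && nseg > 1L)
        seq_len(nseg) else rep(NA_integer_, nseg),
      stringsAsFactors = FALSE)
  }
  if (!length(out)) return(emptyFeatures())
  do.call(rbind, out)
}

.parseLocation <- function(loc, N, circular) {
  loc <- gsub("\\s", "", loc)
  comp <- FALSE
  while (grepl("^complement\\(", loc)) {
    comp <- !comp
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^(join|order)\\(", loc))
    loc <- sub("^(join|order)\\((.*)\\)$", "\\2", loc)
  parts <- strsplit(loc, ",")[[1]]
  rng <- lapply(parts, function(p) {
    p <- gsub("[<>]", "", p)
    if (grepl("^\\d+$", p)) return(c(as.integer(p), as.integer(p)))
    m <- regmatches(p, regexec("^(\\d+)\\.\\.(\\d+)$", p))[[1]]
    if (length(m) != 3L) return(NULL)
    c(as.integer(m[2]), as.integer(m[3]))
  })
  if (any(vapply(rng, is.null, TRUE))) return(NULL)
  df <- data.frame(start = vapply(rng, `[`, 0L, 1),
                   end = vapply(rng, `[`, 0L, 2), complement = comp)
  # merge a split origin-spanning join (a..N, 1..b) into one wrapped row
  if (circular && nrow(df) == 2L && df$end[1] == N && df$start[2] == 1L) {
    df <- data.frame(start = df$start[1], end = df$end[2], complement = comp)
  }
  df
}

#' Write a genome to FASTA
#'
#' @param x [AnnotatedGenome-class] or [CircularSequence-class].
#' @param path output file.
#' @param width line width.
#' @export
writeGenomeFasta <- function(x, path, width = 70L) {
  if (is(x, "AnnotatedGenome")) x <- x@seq
  set <- Biostrings::DNAStringSet(x@sequence)
  names(set) <- x@id
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Write features as GFF3, BED or TSV
#'
#' GFF3 is 1-based inclusive; BED is 0-based half-open (converted at the
#' boundary). Features wrapping the origin are split into two lines
#' sharing one ID attribute (GFF3) or name (BED).
#'
#' @param x [AnnotatedGenome-class].
#' @param path output file.
#' @export
writeFeaturesGFF3 <- function(x, path) {
  ft <- .splitWrapped(x)
  lines <- c("##gff-version 3", sprintf(
    "%s\t%s\t%s\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
    seqId(x), "OrganelleDynamics", ft$kind, ft$start, ft$end, ft$strand,
    ft$id, ft$name))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeFeaturesGFF3
#' @export
writeFeaturesBED <- function(x, path) {
  ft <- .splitWrapped(x)
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s",
                   seqId(x), ft$start - 1L, ft$end, ft$name, ft$strand)
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeFeaturesGFF3
#' @export
writeFeaturesTSV <- function(x, path) {
  utils::write.table(x@features, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

.splitWrapped <- function(x) {
  ft <- x@features
  N <- seqLength(x)
  if (nrow(ft) == 0L)
    return(cbind(ft, id = character(0)))
  ft$id <- sprintf("feat%04d", seq_len(nrow(ft)))
  wrap <- which(ft$start > ft$end)
  if (length(wrap)) {
    first <- ft[wrap, ]; first$end <- N
    second <- ft[wrap, ]; second$start <- 1L
    ft <- rbind(ft[-wrap, ], first, second)
  }
  ft[order(ft$start), ]
}
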