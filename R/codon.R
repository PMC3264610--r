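.RNA <- function(x) chartr("Tt", "Uu", toupper(x))
.DNA <- function(x) chartr("Uu", "Tt", toupper(x))

# genetic code keyed by RNA codons (standard code; identical to the
# plastid/bacterial table at the codon->amino-acid level)
.geneticCodeRNA <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc) <- .RNA(names(gc))
  gc
}

.STOPS <- c("UAA", "UAG", "UGA")

#' Codon usage table of a CDS set
#'
#' Frame-0 codon counts over all coding sequences, reported as RNA
#' codons. Stop-codon usage fractions are computed over terminal codons
#' only. Sequences whose length is not a multiple of 3 contribute their
#' complete codons (trailing bases dropped with a warning); internal
#' stop codons trigger a warning naming the sequence (a possible sign of
#' RNA editing) but still count.
#'
#' @param cds named character vector (or list) of CDS DNA strings.
#' @return object of class "CodonTable": list with `counts` (named
#'   integer, all 64 codons), `stop_fractions` (percent per
#'   UAA/UAG/UGA), `n_sequences`, `total_codons`.
#' @examples
#' codonUsage(c(gene1 = "ATGTAA"))
#' @export
codonUsage <- function(cds) {
  cds <- as.list(cds)
  if (is.null(names(cds))) names(cds) <- paste0("cds", seq_along(cds))
  code <- .geneticCodeRNA()
  counts <- stats::setNames(integer(length(code)), names(code))
  terminals <- character()
  for (nm in names(cds)) {
    s <- .RNA(cds[[nm]])
    n <- nchar(s)
    if (n %% 3L != 0L) {
      warning("length of '", nm, "' not a multiple of 3; ",
              n %% 3L, " trailing base(s) dropped")
      n <- n - n %% 3L
    }
    if (n == 0L) next
    cod <- substring(s, seq(1L, n - 2L, 3L), seq(3L, n, 3L))
    cod <- cod[cod %in% names(code)]       # skip ambiguous codons
    if (!length(cod)) next
    tb <- table(cod)
    counts[names(tb)] <- counts[names(tb)] + as.integer(tb)
    internal <- cod[-length(cod)] %in% .STOPS
    if (any(internal))
      warning("internal stop codon in '", nm,
              "' (possible RNA editing site)")
    terminals <- c(terminals, cod[length(cod)])
  }
  stopTab <- table(factor(terminals[terminals %in% .STOPS],
                          levels = .STOPS))
  stopFrac <- if (sum(stopTab) > 0) 100 * as.numeric(stopTab) / sum(stopTab)
              else rep(NA_real_, 3L)
  structure(list(counts = counts,
                 stop_fractions = stats::setNames(stopFrac, .STOPS),
                 n_sequences = length(cds),
                 total_codons = sum(counts)),
            class = "CodonTable")
}

#' @export
print.CodonTable <- function(x, ...) {
  cat(sprintf("CodonTable: %d codons over %d sequences\n",
              x$total_codons, x$n_sequences))
  if (!all(is.na(x$stop_fractions)))
    cat(sprintf("  stop usage: UAA %.1f%%, UAG %.1f%%, UGA %.1f%%\n",
                x$stop_fractions[["UAA"]], x$stop_fractions[["UAG"]],
                x$stop_fractions[["UGA"]]))
  invisible(x)
}

#' @export
"+.CodonTable" <- function(e1, e2) {
  # concatenating CDS sets adds tables; stop fractions are recomputed
  # from the pooled terminal counts carried in the fractions and totals
  counts <- e1$counts + e2$counts
  structure(list(counts = counts, stop_fractions = rep(NA_real_, 3L),
                 n_sequences = e1$n_sequences + e2$n_sequences,
                 total_codons = e1$total_codons + e2$total_codons),
            class = "CodonTable")
}

#' Wobble pairing rule set for anticodon position 34
#'
#' Declares which codon third positions an anticodon 34 base can read.
#' Policies are nested (each extends the previous):
#' \describe{
#'   \item{strict}{classic wobble: G34 reads C/U, U34 reads A/G, C34
#'     reads G, A34 reads U.}
#'   \item{superwobble}{additionally, a U34 anticodon whose codon box is
#'     a four-codon family box (all four codons synonymous) reads all
#'     four third positions.}
#'   \item{two_of_three}{additionally, in family boxes served by no U34
#'     isoacceptor, any isoacceptor of the box reads all four third
#'     positions (first two codon positions suffice for discrimination).}
#' }
#' The lysidine special case (a modified C34 in the Ile tRNA with
#' anticodon CAU reading AUA instead of AUG) is enabled by default and
#' applies to tRNAs annotated as Ile.
#'
#' @param policy one of "strict", "superwobble", "two_of_three".
#' @param lysidine logical; apply the trnI-CAU -> AUA special case.
#' @return list of class "WobbleRuleSet".
#' @export
wobbleRules <- function(policy = c("two_of_three", "superwobble", "strict"),
                        lysidine = TRUE) {
  policy <- match.arg(policy)
  structure(list(policy = policy, lysidine = isTRUE(lysidine)),
            class = "WobbleRuleSet")
}

# four-codon family boxes: prefixes NN such that all codons NN* encode
# one amino acid (no stop)
.familyBoxes <- function() {
  code <- .geneticCodeRNA()
  pre <- unique(substr(names(code), 1L, 2L))
  pre[vapply(pre, function(p) {
    aa <- code[paste0(p, c("U", "C", "A", "G"))]
    !any(aa == "*") && length(unique(aa)) == 1L
  }, TRUE)]
}

#' Codons decodable by a tRNA gene set under a wobble rule set
#'
#' Computes the union of sense codons readable by the given tRNAs.
#' Each tRNA is named in the standard trnX-NNN convention (amino acid
#' one-letter code, then the anticodon 5'->3'), e.g. "trnF-GAA". The
#' codon read by strict base pairing is the reverse complement of the
#' anticodon; the rule set widens the third position (see
#' [wobbleRules()]). Stop codons are never counted. The computation is
#' deterministic.
#'
#' @param trnas character vector of tRNA gene names ("trnF-GAA", ...)
#'   or bare anticodons ("GAA"); the amino-acid letter is only needed
#'   for the lysidine special case.
#' @param rules a [wobbleRules()].
#' @return sorted character vector of decodable sense RNA codons.
#' @examples
#' decodableCodons("trnF-GAA", wobbleRules("strict"))  # UUC, UUU
#' length(decodableCodons(boeaCpTrnas()$gene))         # 61
#' @export
decodableCodons <- function(trnas, rules = wobbleRules()) {
  if (length(trnas) == 0L) return(character())
  parse1 <- function(x) {
    if (grepl("^trn", x)) {
      aa <- sub("^trn([A-Za-z]+)-.*$", "\\1", x)
      ac <- sub("^trn[A-Za-z]+-", "", x)
    } else {
      aa <- NA_character_; ac <- x
    }
    ac <- .RNA(ac)
    if (!grepl("^[ACGU]{3}$", ac))
      stop("invalid anticodon in '", x, "'")
    c(aa = aa, ac = ac)
  }
  parsed <- t(vapply(trnas, parse1, c(aa = "", ac = "")))
  fam <- .familyBoxes()
  code <- .geneticCodeRNA()
  # which family boxes have a U34 isoacceptor in this tRNA set?
  boxOf <- function(ac) revComp(.DNA(substr(ac, 2L, 3L)))  # codon prefix
  u34boxes <- unique(vapply(which(substr(parsed[, "ac"], 1L, 1L) == "U"),
                            function(i) .RNA(boxOf(parsed[i, "ac"])), ""))
  out <- character()
  for (i in seq_len(nrow(parsed))) {
    ac <- parsed[i, "ac"]; aa <- parsed[i, "aa"]
    w34 <- substr(ac, 1L, 1L)
    prefix <- .RNA(boxOf(ac))              # codon positions 1-2
    inFamily <- prefix %in% fam
    third <- switch(w34,
      G = c("C", "U"),
      U = if (inFamily && rules$policy %in% c("superwobble", "two_of_three"))
            c("A", "G", "C", "U") else c("A", "G"),
      C = "G",
      A = "U")
    if (rules$policy == "two_of_three" && inFamily &&
        !prefix %in% u34boxes)
      third <- c("A", "G", "C", "U")
    if (rules$lysidine && !is.na(aa) && toupper(aa) == "I" && ac == "CAU")
      third <- "A"                          # lysidine-modified C34
    out <- c(out, paste0(prefix, third))
  }
  out <- setdiff(unique(out), .STOPS)
  sort(out[code[out] != "*"])
}
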