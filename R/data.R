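.extdata <- function(file) {
  path <- system.file("extdata", file, package = "OrganelleDynamics")
  if (!nzchar(path)) stop("missing extdata file: ", file)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Published repeat pairs of the Boea hygrometrica mt genome
#'
#' The 14 repeat pairs (>= 50 bp) reported for the 510,519 bp
#' B. hygrometrica mitochondrial master circle, with the printed
#' coordinates, orientations (F = forward, P = palindromic) and
#' published E-values. The three recombinationally active pairs
#' (confirmed by mate-pair sequencing evidence) are flagged in the
#' `recombinant` column; [boeaRecombinationPairs()] returns just those
#' three, the input for the segment decomposition and isomer
#' enumeration of the master circle.
#'
#' @return data.frame with columns `length`, `start1`, `orientation`,
#'   `start2`, `e_value_published`, `recombinant`.
#' @export
boeaMtRepeats <- function() .extdata("boea_mt_repeats.tsv")

#' @rdname boeaMtRepeats
#' @export
boeaRecombinationPairs <- function() {
  x <- boeaMtRepeats()
  x <- x[x$recombinant, c("length", "start1", "start2", "orientation")]
  rownames(x) <- NULL
  x
}

#' Published GC statistics of plastid-derived sequences across plants
#'
#' Per-species GC content of the cp and mt genomes, counts and total
#' length of chloroplast-derived mt insertions (mtpt), their old/new
#' breakdown and the average GC of each age class, for eleven plant
#' species from green algae to angiosperms. `group` distinguishes seed
#' plants from the two lower plants (whose mtpt are all ancient).
#' Missing New-GC values (species without new insertions) are NA.
#'
#' @return data.frame, one row per species.
#' @export
plantOrganelleGC <- function() .extdata("plant_organelle_gc.tsv")

#' Published tRNA gene sets of the Boea hygrometrica organelles
#'
#' `boeaCpTrnas()`: the 27 distinct chloroplast tRNA genes (trnX-NNN
#' naming carries the anticodon) with their copy numbers; the gene set
#' whose anticodons decode all 61 sense codons under the default wobble
#' rules. `boeaMtTrnas()`: the mitochondrial tRNA genes with their
#' origin (native mitochondrial vs chloroplast-derived) as published.
#'
#' @return data.frame with columns `gene`, `copies` (and `origin` for
#'   the mt set).
#' @export
boeaCpTrnas <- function() .extdata("boea_cp_trna.tsv")

#' @rdname boeaCpTrnas
#' @export
boeaMtTrnas <- function() .extdata("boea_mt_trna.tsv")

#' Published exon strand patterns of trans-spliced mt genes
#'
#' Ordered exon strand patterns ("+"/"-" per exon, "*" marking genes
#' without exon-intron structure) of the nad1, nad2 and nad5 genes
#' across 15 plant mitochondrial genomes, as printed in the comparative
#' structure table. For B. hygrometrica the patterns refer to the
#' master-circle arrangement.
#'
#' @return data.frame with columns `species`, `nad1`, `nad2`, `nad5`.
#' @export
transSplicingPatterns <- function() .extdata("trans_splicing_patterns.tsv")
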