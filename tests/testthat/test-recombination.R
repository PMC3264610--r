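# the three recombinant repeat pairs of the Boea hygrometrica master
# circle; every published segment coordinate below derives from them
.boeaPairs <- function() boeaRecombinationPairs()
.BOEA_N <- 510519L

test_that("segment decomposition reproduces the published six segments", {
  segs <- decomposeSegments(.BOEA_N, .boeaPairs())
  expect_equal(segs$label, LETTERS[1:6])
  expect_equal(segs$start, c(43116L, 53183L, 108935L, 153964L, 233871L,
                             405602L))
  expect_equal(segs$end, c(51708L, 108091L, 153741L, 232396L, 405379L,
                           42272L))
  expect_equal(segs$printed_length,
               c(8592L, 54908L, 44806L, 78432L, 171508L, 147189L))
  expect_equal(segs$inclusive_length, segs$printed_length + 1L)
  # tiling: segments plus two copies of each repeat cover the circle
  expect_equal(sum(segs$inclusive_length) + 2L * sum(.boeaPairs()$length),
               .BOEA_N)
})

test_that("decomposition handles edge cases", {
  s0 <- decomposeSegments(1000, NULL)
  expect_equal(nrow(s0), 1L)
  expect_equal(c(s0$start, s0$end, s0$inclusive_length), c(1L, 1000L, 1000L))
  # one forward pair splits the circle in two
  s1 <- decomposeSegments(100, data.frame(length = 10, start1 = 1,
                                          start2 = 51, orientation = "F"))
  expect_equal(s1$start, c(11L, 61L))
  expect_equal(s1$end, c(50L, 100L))
  expect_equal(sum(s1$inclusive_length) + 20L, 100L)
  # overlapping copies are refused with the collision named
  expect_error(decomposeSegments(100, data.frame(
    length = c(10, 10), start1 = c(1, 5), start2 = c(51, 71),
    orientation = "F")), "overlap")
})

test_that("the master state lists copies and segments in genomic order", {
  pairs <- .boeaPairs()
  segs <- decomposeSegments(.BOEA_N, pairs)
  mc <- buildMasterState(segs, pairs)
  u <- moleculeUnits(mc)
  expect_equal(paste0(u$id, ifelse(u$strand > 0, "+", "-")),
               c("r843+", "A+", "r1474+", "B+", "r843-", "C+",
                 "r222+", "D+", "r1474-", "E+", "r222+", "F+"))
  # second copy of each palindromic pair is on the minus strand
  expect_equal(pairOrientation(mc, "r1474"), "inverted")
  expect_equal(pairOrientation(mc, "r843"), "inverted")
  expect_equal(pairOrientation(mc, "r222"), "direct")
  expect_error(pairOrientation(mc, "r999"), "twice")
})

test_that("single-pair master states are built correctly", {
  s1 <- decomposeSegments(100, data.frame(length = 10, start1 = 1,
                                          start2 = 51, orientation = "F"))
  mc <- buildMasterState(s1, data.frame(length = 10, start1 = 1,
                                        start2 = 51, orientation = "F"))
  u <- moleculeUnits(mc)
  expect_equal(u$type, c("repeat", "segment", "repeat", "segment"))
  expect_true(all(u$strand == 1L))
  mc0 <- buildMasterState(decomposeSegments(500, NULL), NULL)
  expect_equal(nrow(moleculeUnits(mc0)), 1L)
})

test_that("canonical keys identify molecules up to rotation and flip", {
  pairs <- .boeaPairs()
  segs <- decomposeSegments(.BOEA_N, pairs)
  mc <- buildMasterState(segs, pairs)
  u <- moleculeUnits(mc)
  for (r in c(3L, 7L)) {
    rot <- moleculeState(u[c(r:nrow(u), seq_len(r - 1L)), ])
    expect_identical(canonicalKey(rot), canonicalKey(mc))
  }
  flip <- u[rev(seq_len(nrow(u))), ]
  flip$strand <- -flip$strand
  expect_identical(canonicalKey(moleculeState(flip)), canonicalKey(mc))
  inv <- recombine(mc, "r1474")$products[[1]]
  expect_false(canonicalKey(inv) == canonicalKey(mc))
})

test_that("inversion at an inverted pair is an involution", {
  pairs <- .boeaPairs()
  segs <- decomposeSegments(.BOEA_N, pairs)
  mc <- buildMasterState(segs, pairs)
  for (p in c("r1474", "r843")) {
    out <- recombine(mc, p)
    expect_equal(out$kind, "isomer")
    back <- recombine(out$products[[1]], p)
    expect_identical(canonicalKey(back$products[[1]]), canonicalKey(mc))
  }
})

test_that("excision at a direct pair conserves the segment multiset", {
  pairs <- .boeaPairs()
  segs <- decomposeSegments(.BOEA_N, pairs)
  mc <- buildMasterState(segs, pairs)
  out <- recombine(mc, "r222")
  expect_equal(out$kind, "excision")
  expect_equal(length(out$products), 2L)
  segsOf <- function(st) {
    u <- moleculeUnits(st)
    sort(u$id[u$type == "segment"])
  }
  expect_equal(sort(c(segsOf(out$products[[1]]), segsOf(out$products[[2]]))),
               LETTERS[1:6])
  # the published subcircles: one carries D,E and the other A,B,C,F
  parts <- lapply(out$products, segsOf)
  expect_true(any(vapply(parts, function(p) identical(p, c("D", "E")), TRUE)))
  # each product retains one copy of the mediating repeat
  for (pr in out$products)
    expect_equal(sum(moleculeUnits(pr)$id == "r222"), 1L)
})

test_that("isomer enumeration matches the published count of four", {
  pairs <- .boeaPairs()
  segs <- decomposeSegments(.BOEA_N, pairs)
  mc <- buildMasterState(segs, pairs)
  iso <- enumerateIsomers(mc)
  expect_equal(length(iso$isomers), 4L)
  expect_false(iso$masterKey %in% names(iso$isomers))
  # excisions recorded separately, never expanded into the isomer set
  expect_gte(length(iso$excisions), 1L)
})

test_that("single-pair circles behave as the recombination model predicts", {
  segsP <- decomposeSegments(200, data.frame(length = 20, start1 = 1,
                                             start2 = 101,
                                             orientation = "P"))
  mcP <- buildMasterState(segsP, data.frame(length = 20, start1 = 1,
                                            start2 = 101,
                                            orientation = "P"))
  isoP <- enumerateIsomers(mcP)
  expect_equal(length(isoP$isomers), 1L)    # inversion is an involution
  segsF <- decomposeSegments(200, data.frame(length = 20, start1 = 1,
                                             start2 = 101,
                                             orientation = "F"))
  mcF <- buildMasterState(segsF, data.frame(length = 20, start1 = 1,
                                            start2 = 101,
                                            orientation = "F"))
  isoF <- enumerateIsomers(mcF)
  expect_equal(length(isoF$isomers), 0L)    # direct pairs only excise
  expect_equal(length(isoF$excisions), 1L)
  expect_equal(length(isoF$excisions[[1]]$products), 2L)
})

# exon fixtures for the trans-splicing report: placements follow the
# published segment assignments, strands chosen to reproduce the
# published master-circle patterns (nad1 "---++", nad2 "-----",
# nad5 "+++++")
.nadExons <- function(segs) {
  at <- function(lab, off, len = 100L) {
    st <- segs$start[segs$label == lab] + off
    c(st, st + len - 1L)
  }
  rows <- list(
    c("nad1", at("F", 500), "-", 1L), c("nad1", at("D", 5000), "-", 2L),
    c("nad1", at("D", 9000), "-", 3L), c("nad1", at("A", 1000), "+", 4L),
    c("nad1", at("A", 3000), "+", 5L),
    c("nad2", at("D", 200), "-", 1L), c("nad2", at("D", 2000), "-", 2L),
    c("nad2", at("B", 1000), "-", 3L), c("nad2", at("B", 8000), "-", 4L),
    c("nad2", at("B", 20000), "-", 5L),
    c("nad5", at("B", 40000), "+", 1L), c("nad5", at("D", 30000), "+", 2L),
    c("nad5", at("D", 60000), "+", 3L), c("nad5", at("E", 1000), "+", 4L),
    c("nad5", at("E", 90000), "+", 5L))
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(df) <- c("name", "start", "end", "strand", "exon_index")
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  df$exon_index <- as.integer(df$exon_index)
  df
}

test_that("gene report reproduces the published master-circle patterns", {
  pairs <- .boeaPairs()
  segs <- decomposeSegments(.BOEA_N, pairs)
  mc <- buildMasterState(segs, pairs)
  rep <- moleculeGeneReport(mc, .nadExons(segs), segs, pairs)
  pat <- setNames(rep$pattern, rep$gene)
  expect_equal(pat[["nad1"]], "---++")
  expect_equal(pat[["nad2"]], "-----")
  expect_equal(pat[["nad5"]], "+++++")
  expect_true(rep$cross_strand[rep$gene == "nad1"])
  expect_false(rep$cross_strand[rep$gene == "nad5"])
})

test_that("gene report tracks segment flips, absences and bad exons", {
  pairs <- .boeaPairs()
  segs <- decomposeSegments(.BOEA_N, pairs)
  mc <- buildMasterState(segs, pairs)
  exons <- .nadExons(segs)
  # a single-exon gene on a segment flipped by recombination reads "-"
  single <- data.frame(name = "toy", start = segs$start[2] + 10L,
                       end = segs$start[2] + 59L, strand = "+",
                       exon_index = 1L)
  inv <- recombine(mc, "r1474")$products[[1]]   # flips the B..D arc
  rep1 <- moleculeGeneReport(inv, single, segs, pairs)
  expect_equal(rep1$pattern, "-")
  # exons on an excised subcircle are missing from the complement circle
  exc <- recombine(mc, "r222")$products
  noDE <- exc[[which(vapply(exc, function(p)
    !"D" %in% moleculeUnits(p)$id, TRUE))]]
  rep2 <- moleculeGeneReport(noDE, exons, segs, pairs)
  expect_gt(sum(rep2$n_missing), 0L)
  expect_match(rep2$pattern[rep2$gene == "nad2"], "\\.")
  # an exon spanning a segment boundary is a hard error naming the exon
  bad <- data.frame(name = "badgene", start = segs$end[1] - 10L,
                    end = segs$end[1] + 800L, strand = "+", exon_index = 1L)
  expect_error(moleculeGeneReport(mc, bad, segs, pairs), "badgene")
})

test_that("isomer enumeration is invariant under genome rotation", {
  # same configuration expressed from a rotated origin
  pairs <- .boeaPairs()
  segs <- decomposeSegments(.BOEA_N, pairs)
  iso0 <- enumerateIsomers(buildMasterState(segs, pairs))
  rotBy <- 100000L
  rp <- pairs
  rp$start1 <- ((pairs$start1 - 1L - rotBy) %% .BOEA_N) + 1L
  rp$start2 <- ((pairs$start2 - 1L - rotBy) %% .BOEA_N) + 1L
  # keep start1 < start2 convention
  swap <- rp$start1 > rp$start2
  tmp <- rp$start1[swap]; rp$start1[swap] <- rp$start2[swap]
  rp$start2[swap] <- tmp
  segsR <- decomposeSegments(.BOEA_N, rp)
  isoR <- enumerateIsomers(buildMasterState(segsR, rp))
  expect_equal(length(isoR$isomers), length(iso0$isomers))
  expect_equal(length(isoR$excisions), length(iso0$excisions))
})

test_that("BFS closure equals brute-force event enumeration on small cases", {
  # exhaustive oracle: apply all inversion sequences up to depth 6
  bruteForce <- function(mc, depth = 6L) {
    seen <- character()
    frontier <- list(mc)
    for (d in seq_len(depth)) {
      nxt <- list()
      for (st in frontier) {
        ids <- unique(moleculeUnits(st)$id[moleculeUnits(st)$type == "repeat"])
        for (p in ids) {
          if (sum(moleculeUnits(st)$id == p) != 2L) next
          if (pairOrientation(st, p) != "inverted") next
          pr <- recombine(st, p)$products[[1]]
          k <- canonicalKey(pr)
          if (!k %in% seen) {
            seen <- c(seen, k)
            nxt[[length(nxt) + 1L]] <- pr
          }
        }
      }
      frontier <- nxt
      if (!length(frontier)) break
    }
    setdiff(seen, canonicalKey(mc))
  }
  set.seed(42)
  for (rep in 1:6) {
    nPairs <- sample(2:4, 1)
    # random non-overlapping copies on a 10 kb circle
    L <- sample(20:60, nPairs, replace = TRUE)
    starts <- sort(sample(seq(1, 9000, by = 600), 2 * nPairs))
    pairs <- data.frame(length = L, start1 = starts[seq_len(nPairs)],
                        start2 = starts[nPairs + seq_len(nPairs)],
                        orientation = sample(c("F", "P"), nPairs,
                                             replace = TRUE))
    segs <- decomposeSegments(10000, pairs)
    mc <- buildMasterState(segs, pairs)
    iso <- enumerateIsomers(mc)
    expect_setequal(names(iso$isomers), bruteForce(mc))
  }
})
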