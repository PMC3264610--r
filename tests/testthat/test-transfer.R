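test_that("five planted insertions spanning the identity range are found", {
  ins <- data.frame(cp_start = c(500, 3000, 8200, 10200, 12000),
                    length = c(3000, 1200, 600, 150, 60),
                    identity = c(0.82, 0.85, 0.90, 0.95, 1.0),
                    mt_start = c(2000, 9000, 15000, 25000, 40000))
  tp <- simulateTransferPair(mtLength = 60000, insertions = ins, seed = 8)
  hits <- findCpDerived(tp$mt, tp$cp)
  expect_equal(nrow(hits), 5L)
  # every planted fragment is recovered (reciprocal overlap >= 80%),
  # and nothing spurious is reported
  for (i in seq_len(nrow(tp$truth))) {
    ovl <- vapply(seq_len(nrow(hits)), function(j)
      .ovBases(tp$truth$mt_start[i], tp$truth$mt_end[i],
               hits$mt_start[j], hits$mt_end[j]), 0)
    expect_gte(max(ovl), 0.8 * tp$truth$length[i])
  }
  expect_true(all(hits$identity >= 0.80))
  expect_true(all(hits$aligned_length >= 50))
  expect_true(all(hits$e_value <= 1e-5))
  # detected identities track the planted divergence
  ord <- order(hits$mt_start)
  expect_equal(hits$identity[ord], tp$truth$identity,
               tolerance = 0.03)
})

test_that("unrelated GC-matched genomes give no hits", {
  mt <- annotatedGenome(randomDNA(30000, gc = 0.40, seed = 51), id = "mt")
  cp <- annotatedGenome(randomDNA(12000, gc = 0.40, seed = 52), id = "cp")
  hits <- findCpDerived(mt, cp)
  expect_equal(nrow(hits), 0L)
})

test_that("sub-threshold divergence is rejected", {
  # planted at identity 0.70, well under the 0.80 threshold
  ins <- data.frame(cp_start = 2000, length = 60, identity = 0.70,
                    mt_start = 10000)
  tp <- simulateTransferPair(mtLength = 30000, insertions = ins, seed = 9)
  hits <- findCpDerived(tp$mt, tp$cp)
  expect_false(.anyHitOverlaps(hits, 10000L, 10059L))
})

test_that("genomes shorter than the length cutoff warn and return empty", {
  mt <- annotatedGenome("ACGTACGTAC", id = "mt")
  cp <- annotatedGenome(randomDNA(5000, seed = 1), id = "cp")
  expect_warning(hits <- findCpDerived(mt, cp), "min_length")
  expect_equal(nrow(hits), 0L)
})

test_that("age classification separates panel homologs from novelties", {
  tp <- simulateTransferPair(mtLength = 40000, insertions = data.frame(
    cp_start = c(1000, 5000), length = c(400, 300),
    identity = c(0.95, 0.95), mt_start = c(5000, 20000)), seed = 12)
  hits <- findCpDerived(tp$mt, tp$cp)
  expect_equal(nrow(hits), 2L)
  hits <- hits[order(hits$mt_start), ]
  # panel genome carries a verbatim copy of the first hit only
  homolog <- extractArc(genomeSeq(tp$mt), hits$mt_start[1], hits$mt_end[1])
  panelG <- annotatedGenome(paste0(randomDNA(6000, seed = 77), homolog,
                                   randomDNA(6000, seed = 78)),
                            id = "panel1")
  cls <- classifyAge(hits, tp$mt, list(panelG))
  cls <- cls[order(cls$mt_start), ]
  expect_equal(cls$age, c("old", "new"))
  # an empty panel leaves hits unclassified
  un <- classifyAge(hits, tp$mt, list())
  expect_true(all(un$age == "unclassified"))
})

test_that("region of origin follows the cp-side midpoint", {
  sim <- simulateQuadripartiteGenome(8000, 2000, 1500, seed = 4)
  map <- sim$map
  mk <- function(cp_start, cp_end) {
    data.frame(mt_start = 1L, mt_end = 10L, cp_start = cp_start,
               cp_end = cp_end, strand = "+", identity = 1,
               aligned_length = 10L, score = 1, e_value = 0, gc = 0.5,
               age = NA_character_, cp_region = NA_character_)
  }
  # wholly inside SSC
  h1 <- regionOfOrigin(mk(10200L, 10400L), map)
  expect_equal(h1$cp_region, "SSC")
  # straddles LSC/IRa with midpoint in LSC
  h2 <- regionOfOrigin(mk(7900L, 8060L), map)
  expect_equal(h2$cp_region, "LSC")
  # straddles LSC/IRa with midpoint in IRa
  h3 <- regionOfOrigin(mk(7990L, 8500L), map)
  expect_equal(h3$cp_region, "IR")
  # counts over random intervals agree with direct interval arithmetic
  set.seed(5)
  for (i in 1:10) {
    a <- sample(13000, 1); b <- min(13500L, a + sample(50:400, 1))
    h <- regionOfOrigin(mk(a, b), map)
    mid <- (a + b) %/% 2L
    wantIR <- (mid >= 8001 && mid <= 10000) || mid >= 11501
    want <- if (wantIR) "IR" else if (mid <= 8000) "LSC" else "SSC"
    expect_equal(h$cp_region, want)
  }
})

test_that("transfer summaries aggregate counts, lengths and GC", {
  hits <- data.frame(
    mt_start = c(1001L, 5001L), mt_end = c(1100L, 5300L),
    cp_start = c(1L, 1L), cp_end = c(100L, 300L), strand = "+",
    identity = 1, aligned_length = c(100L, 300L), score = 1, e_value = 0,
    gc = c(0.40, 0.30), age = c("old", "new"),
    cp_region = c("LSC", "SSC"))
  s <- summarizeTransfer(hits, 10000L)
  expect_equal(s$n_hits, 2L)
  expect_equal(s$total_bp, 400L)
  expect_equal(s$fraction_of_mt, 0.04)
  expect_equal(s$gc_old, 40)
  expect_equal(s$gc_new, 30)
  expect_equal(s$region_counts, c(LSC = 1L, SSC = 1L, IR = 0L))
  # totals are additive under concatenation of hit lists
  hits2 <- hits
  hits2$mt_start <- hits$mt_start + 6000L
  hits2$mt_end <- hits$mt_end + 6000L
  s2 <- summarizeTransfer(rbind(hits, hits2), 20000L)
  expect_equal(s2$total_bp, 2L * s$total_bp)
  expect_equal(s2$n_old, 2L * s$n_old)
  zero <- summarizeTransfer(hits[0, ], 1000L)
  expect_equal(zero$n_hits, 0L)
  expect_equal(zero$total_bp, 0L)
})

test_that("summary GC equals the planted fragment GC on recovered hits", {
  tp <- simulateTransferPair(mtLength = 50000, insertions = data.frame(
    cp_start = c(600, 4000, 9000), length = c(800, 500, 300),
    identity = c(0.95, 0.9, 1.0), mt_start = c(4000, 15000, 30000)),
    seed = 33)
  hits <- findCpDerived(tp$mt, tp$cp)
  hits <- hits[order(hits$mt_start), ]
  for (i in seq_len(nrow(tp$truth))) {
    if (abs(hits$mt_start[i] - tp$truth$mt_start[i]) <= 5 &&
        abs(hits$mt_end[i] - tp$truth$mt_end[i]) <= 5)
      expect_equal(hits$gc[i], tp$truth$gc[i], tolerance = 0.01)
  }
})

test_that("pearsonR matches the closed formula and handles degeneracy", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearsonR(x, 2 * x + 1), 1.0)
  set.seed(9)
  for (i in 1:5) {
    a <- rnorm(5); b <- rnorm(5)
    byHand <- sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
    expect_equal(pearsonR(a, b), byHand, tolerance = 1e-12)
  }
  # NA pairs are dropped before computing
  expect_equal(pearsonR(c(x, NA), c(2 * x + 1, 5)), 1.0)
  expect_error(pearsonR(c(1, 2), c(3, 4)), "3 complete pairs")
  expect_true(is.na(pearsonR(c(1, 1, 1), c(1, 2, 3))))
})

test_that("welchT reproduces the textbook statistic", {
  expect_equal(welchT(c(1, 2, 3), c(1, 2, 3))$statistic, 0)
  # forced separation is significant
  set.seed(2)
  out <- welchT(rnorm(10, 10, 1), rnorm(10, 50, 1))
  expect_lt(out$p_value, 0.01)
  # hand-computed Welch value for a small fixed pair
  x <- c(19.8, 20.4, 19.6, 17.8, 18.5, 18.9, 18.3, 18.9, 19.5, 22.0)
  y <- c(28.2, 26.6, 20.1, 23.3, 25.2, 22.1, 17.7, 27.6, 20.6, 13.7,
         23.2, 17.5, 20.6, 18.0, 23.9, 21.6, 24.3, 20.4, 24.0, 13.2)
  t_hand <- (mean(x) - mean(y)) /
    sqrt(var(x) / length(x) + var(y) / length(y))
  out2 <- welchT(x, y)
  expect_equal(out2$statistic, t_hand, tolerance = 1e-12)
  df_hand <- (var(x) / 10 + var(y) / 20)^2 /
    ((var(x) / 10)^2 / 9 + (var(y) / 20)^2 / 19)
  expect_equal(out2$df, df_hand, tolerance = 1e-9)
  # degenerate zero-variance samples
  expect_equal(welchT(c(1, 1), c(2, 2))$statistic, -Inf)
  expect_equal(welchT(c(1, 1), c(1, 1))$statistic, 0)
})

test_that("tRNA origin classification separates copies from natives", {
  sim <- simulateTrnaSet(nNative = 6, nCp = 8, nDerived = 4,
                         mutationRate = 0.03, seed = 6)
  cls <- classifyTrnas(sim$mtTrnas, sim$cpTrnas)
  expect_equal(attr(cls, "fraction_cp"), 0.4)
  merged <- merge(cls, sim$truth, by = "trna")
  expect_equal(merged$origin.x, merged$origin.y)
  # an identical copy is cp-derived; 60% identity stays native
  one <- sim$cpTrnas[1]
  cls2 <- classifyTrnas(c(ident = unname(one)), sim$cpTrnas)
  expect_equal(cls2$origin, "cp-derived")
  far <- mutateToIdentity(one, 0.60, seed = 3)
  cls3 <- classifyTrnas(c(far = far), sim$cpTrnas)
  expect_equal(cls3$origin, "native")
  expect_warning(cls4 <- classifyTrnas(sim$mtTrnas, character()), "empty")
  expect_true(all(cls4$origin == "native"))
})

test_that("alignment parameters are validated", {
  expect_error(alignmentParams(min_identity = 1.5), "identity")
  expect_error(alignmentParams(min_identity = 0), "identity")
  expect_error(alignmentParams(min_length = 0), "min_length")
  expect_error(alignmentParams(max_evalue = -1), "evalue")
})
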