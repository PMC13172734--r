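rm_out_fixture <- function() {
  lines <- c(
    "   SW   perc perc perc  query     position in query    matching  repeat",
    "score   div. del. ins.  sequence  begin end (left)     repeat    class/family",
    "",
    "  283   12.5  0.0  0.0  ctg1      100   550  (9450) +  Mar1      DNA/TcMar-Tc1      1  450 (0)  1",
    "  190    3.1  0.2  0.0  ctg1      900  1100  (8900) C  Gyp1      LTR/Gypsy          1  200 (0)  2",
    "   88   22.0  0.0  0.0  ctg2       10   300  (9700) +  Line2     LINE/R2            1  290 (0)  3",
    "   50    8.0  0.0  0.0  ctg2      400   420  (9580) +  Weird     Unknown            1   20 (0)  4")
  tf <- tempfile(fileext = ".out")
  writeLines(lines, tf)
  tf
}

test_that("RepeatMasker .out and BED readers normalize annotations", {
  tes <- read_repeatmasker(rm_out_fixture())
  expect_equal(nrow(tes), 4L)
  expect_equal(tes$contig, c("ctg1", "ctg1", "ctg2", "ctg2"))
  expect_equal(tes$te_class, c("II", "I", "I", "unknown"))
  expect_equal(tes$superfamily[1], "TcMar-Tc1")
  expect_equal(tes$divergence, c(12.5, 3.1, 22.0, 8.0))

  bf <- tempfile(fileext = ".bed")
  writeLines(c("ctg1\t99\t550\tMar1#DNA/TcMar-Tc1\t12.5\t+",
               "ctg1\t899\t1100\tGyp1#LTR/Gypsy\t3.1\t-"), bf)
  bed <- read_te_bed(bf)
  expect_equal(bed$start, c(100L, 900L))   # 0-based half-open -> 1-based
  expect_equal(bed$end, c(550L, 1100L))
  expect_equal(bed$te_class, c("II", "I"))
})

test_that("flank densities follow the coverage definition and exclusions", {
  genes <- data.frame(gene_id = c("g1", "g2", "g3"),
                      contig = c("c1", "c1", "c1"),
                      start = c(6001, 6001, 100),
                      end = c(8000, 8000, 400))
  clen <- c(c1 = 20000)
  # g3 lacks a full left flank and must be excluded
  no_te <- flank_te_density(genes[1, ], knotarch:::empty_te(), 5000, clen)
  expect_equal(no_te$densities$density, 0)

  # one TE covering the entire left flank of g1: density 0.5
  tes <- as_te_annotation(data.frame(contig = "c1", start = 1001, end = 6000,
                                     family = "f", superfamily = "s",
                                     te_class = "II", divergence = 0))
  half <- flank_te_density(genes, tes, 5000, clen)
  expect_equal(half$densities$density[half$densities$gene_id == "g1"], 0.5)
  expect_equal(half$excluded, "g3")
  expect_setequal(c(half$densities$gene_id, half$excluded), genes$gene_id)
  # class splits: class II only
  expect_equal(half$densities$density_II[1], 0.5)
  expect_equal(half$densities$density_I[1], 0)

  expect_error(flank_te_density(genes, tes, 0, clen), "positive")
})

test_that("flank density equals brute-force union coverage on random layouts", {
  set.seed(20)
  for (rep in 1:20) {
    n_te <- sample(5:40, 1)
    tes <- as_te_annotation(data.frame(
      contig = "c", start = s <- sample(1:19000, n_te, TRUE),
      end = s + sample(50:800, n_te, TRUE),
      family = "f", superfamily = "s",
      te_class = sample(c("I", "II"), n_te, TRUE), divergence = 0))
    gene <- data.frame(gene_id = "g", contig = "c", start = 7000, end = 9000)
    d <- flank_te_density(gene, tes, 5000, c(c = 20000))$densities$density
    want <- (oracle_coverage(tes, 2000, 6999) +
               oracle_coverage(tes, 9001, 14000)) / 10000
    expect_equal(d, want)
    # order independence
    d2 <- flank_te_density(gene, tes[sample(nrow(tes)), ], 5000,
                           c(c = 20000))$densities$density
    expect_equal(d2, d)
  }
})

test_that("permutation flank test is reproducible and correctly guarded", {
  set.seed(21)
  ick <- runif(20, 0.2, 0.4)
  bg <- runif(30, 0.1, 0.3)
  r1 <- permutation_flank_test(ick, bg, reps = 200, seed = 99)
  r2 <- permutation_flank_test(ick, bg, reps = 200, seed = 99)
  expect_identical(r1$perm, r2$perm)
  expect_identical(r1$p, r2$p)
  expect_gt(r1$p, 0)          # +1 correction: never exactly zero
  expect_lte(r1$p, 1)
  expect_equal(r1$observed, mean(ick) - mean(bg))

  expect_error(permutation_flank_test(ick, bg, reps = 0), "reps")
  expect_error(permutation_flank_test(ick, bg[1:5]), "smaller")
  expect_error(permutation_flank_test(numeric(0), bg), "non-empty")

  # p converges on fixed data as reps grows
  ps <- vapply(c(100, 1000, 10000), function(R)
    permutation_flank_test(ick, bg, reps = R, seed = 1)$p, numeric(1))
  expect_lt(abs(ps[2] - ps[3]), 0.05)
})

test_that("windowed density tracks conserve coverage", {
  tes <- as_te_annotation(data.frame(contig = "c", start = 5101, end = 5200,
                                     family = "f", superfamily = "s",
                                     te_class = "II", divergence = 0))
  tr <- window_density_track("c", 5001, 5400, tes, window_bp = 100,
                             flank_bp = 0, contig_length = 10000)
  expect_equal(tr$windows$density, c(0, 1, 0, 0))
  expect_equal(tr$contig_mean, 100 / 10000)

  set.seed(22)
  for (rep in 1:10) {
    n_te <- sample(3:25, 1)
    tes <- as_te_annotation(data.frame(
      contig = "c", start = s <- sample(1:9000, n_te, TRUE),
      end = pmin(s + sample(20:500, n_te, TRUE), 10000),
      family = "f", superfamily = "s", te_class = "I", divergence = 0))
    tr <- window_density_track("c", 3000, 6000, tes, window_bp = 100,
                               flank_bp = 1000, contig_length = 10000)
    expect_equal(sum(tr$windows$covered),
                 oracle_coverage(tes, 2000, 7000))
    per_win <- vapply(seq_len(nrow(tr$windows)), function(i)
      oracle_coverage(tes, tr$windows$start[i], tr$windows$end[i]),
      numeric(1))
    expect_equal(tr$windows$covered, as.integer(per_win))
  }
})

test_that("the divergence landscape is a simple binned summary", {
  tes <- as_te_annotation(data.frame(
    contig = "c", start = c(1, 100, 200, 300), end = c(50, 180, 220, 420),
    family = "f", superfamily = "s", te_class = c("II", "II", "I", "I"),
    divergence = c(0.4, 1.2, 1.9, 10.3)))
  h <- te_divergence_landscape(tes, bin_width = 1)
  expect_equal(h$bin_lo, c(0, 1, 10))
  expect_equal(h$n, c(1L, 2L, 1L))
  expect_equal(h$bp, c(50L, 81L + 21L, 121L))
  hc <- te_divergence_landscape(tes, bin_width = 1, by_class = TRUE)
  expect_equal(sum(hc$n), 4L)
})

test_that("shared TE families are plain set intersections over regions", {
  tes <- as_te_annotation(data.frame(
    contig = "c",
    start = c(100, 300, 500, 5100, 5300, 5500),
    end = c(200, 400, 600, 5200, 5400, 5600),
    family = c("A", "B", "C", "B", "C", "D"),
    superfamily = "s", te_class = "II", divergence = 0))
  rA <- list(contig = "c", start = 1, end = 1000)
  rB <- list(contig = "c", start = 5000, end = 6000)
  sh <- shared_te_families(rA, rB, tes)
  expect_equal(sh$shared_count, 2L)
  expect_equal(sh$total_a, 3L)
  expect_equal(sh$total_b, 3L)
  expect_setequal(sh$shared_families, c("B", "C"))

  none <- shared_te_families(rA, list(contig = "c", start = 9000, end = 9500),
                             tes)
  expect_equal(none$shared_count, 0L)

  # pairwise-exclusive sharing among 3 regions
  tes2 <- rbind(tes, as_te_annotation(data.frame(
    contig = "c", start = 8100, end = 8200, family = "B",
    superfamily = "s", te_class = "II", divergence = 0)))
  rC <- list(contig = "c", start = 8000, end = 8500)
  excl <- te_family_sharing(list(a = rA, b = rB, c = rC), tes2)
  # B is in all three regions, so only C remains exclusive to the a/b pair
  ab <- excl[excl$region_a == "a" & excl$region_b == "b", ]
  expect_equal(ab$shared_exclusive, 1L)
  expect_equal(ab$families, "C")
})
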