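test_that("PSSM construction matches hand-computed log-odds", {
  aln <- c(s1 = "ACGT", s2 = "ACGA", s3 = "ACTT")
  p <- build_pssm(aln, pseudocount = 0.5)
  expect_equal(p$length, 4L)
  # hand calculation, column 1: counts A=3, pseudo 0.5 each, bg from all 12
  # residues
  bg_counts <- table(factor(strsplit(paste(aln, collapse = ""), "")[[1]],
                            levels = c("A", "C", "G", "T")))
  bg <- (as.numeric(bg_counts) + 0.5) / (12 + 2)
  pA1 <- (3 + 0.5) / (3 + 2)
  expect_equal(unname(p$log_odds["A", 1]), unname(log2(pA1 / bg[1])))
  pT4 <- (2 + 0.5) / (3 + 2)
  expect_equal(unname(p$log_odds["T", 4]), unname(log2(pT4 / bg[4])))

  # consensus dominance: an all-A column scores A highest
  expect_equal(which.max(p$log_odds[, 1]), c(A = 1L))
  # a duplicated single sequence scores itself at the column maxima
  p2 <- build_pssm(c(a = "ACGT", b = "ACGT"))
  expect_equal(pssm_score(p2, "ACGT"), sum(apply(p2$log_odds, 2, max)))

  expect_error(build_pssm(c(a = "ACGT", b = "ACG")), "ragged")
  expect_error(build_pssm(c(a = "ACGT")), ">= 2")
})

test_that("dinucleotide shuffle preserves dinucleotide composition exactly", {
  set.seed(8)
  for (i in 1:10) {
    s <- rand_dna(sample(50:200, 1))
    sh <- dinuc_shuffle(s)
    expect_equal(nchar(sh), nchar(s))
    dinucs <- function(x) {
      ch <- strsplit(x, "")[[1]]
      sort(paste0(ch[-length(ch)], ch[-1]))
    }
    expect_identical(dinucs(sh), dinucs(s))
    expect_identical(substr(sh, 1, 1), substr(s, 1, 1))
  }
  # long sequences are actually permuted, not returned verbatim
  s <- rand_dna(300)
  expect_false(all(vapply(1:5, function(i) dinuc_shuffle(s) == s,
                          logical(1))))
})

test_that("UTR remnant scan finds planted domains and validates inputs", {
  set.seed(12)
  donor <- rand_dna(72)
  # plant a 10%-diverged copy of the donor inside a 3'UTR
  cfg <- sim_config()
  planted <- knotarch:::evolve_nt(donor, 0.10)
  cds <- paste0("ATG", rand_dna(87), "TAA")
  query <- paste0(cds, rand_dna(25), planted, rand_dna(40))
  sc <- scan_utr_remnant(query, cds_end = nchar(cds), donor = donor,
                         null_shuffles = 150, seed = 1)
  expect_s3_class(sc, "remnant_scan")
  expect_true(nrow(sc$hits) >= 1)
  hit <- sc$hits[sc$hits$channel == "nt", ][1, ]
  expect_true(hit$in_utr)
  plant_lo <- nchar(cds) + 26; plant_hi <- plant_lo + 71
  overlap <- min(hit$end, plant_hi) - max(hit$start, plant_lo) + 1
  expect_gte(overlap / (hit$end - hit$start + 1), 0.8)

  expect_error(scan_utr_remnant(query, NA, donor), "cds_end")
  expect_error(scan_utr_remnant(query, 90, donor, null_shuffles = 10),
               ">= 100")
})

test_that("crossover breakpoints are located with honest ambiguity", {
  set.seed(14)
  for (i in 1:10) {
    d1 <- rand_dna(90)
    d2 <- knotarch:::evolve_nt(d1, 0.2)   # ~20%-diverged copies
    b <- sample(25:65, 1)
    chim <- paste0(substr(d1, 1, b), substr(d2, b + 1, 90))
    bp <- locate_crossover_breakpoint(chim, d1, d2)
    expect_true(bp$breakpoint_interval[1] <= b &&
                  b <= bp$breakpoint_interval[2],
                info = sprintf("b=%d int=%d-%d", b,
                               bp$breakpoint_interval[1],
                               bp$breakpoint_interval[2]))
  }
  # identical donors: the split is unidentifiable in principle
  d <- rand_dna(60)
  amb <- locate_crossover_breakpoint(d, d, d)
  expect_true(amb$unidentifiable)
  expect_true(amb$no_chimeric_signal)
  expect_error(locate_crossover_breakpoint("", "A", "A"), "empty")
})

test_that("crossover byproducts obey exchange arithmetic", {
  d <- rand_dna(40)
  out <- crossover_byproducts(d, d, 20)
  expect_identical(out$contracted, d)

  set.seed(15)
  d1 <- rand_dna(60)
  d2 <- knotarch:::evolve_nt(d1, 0.2)
  linker <- rand_dna(12)
  r <- crossover_byproducts(d1, d2, 33, linker = linker)
  # reciprocal products conserve total length exactly
  expect_equal(nchar(r$contracted) + nchar(r$expanded),
               2 * (nchar(d1) + nchar(d2) + nchar(linker)))
  # the expanded product carries both original domains verbatim
  expect_true(grepl(d1, r$expanded, fixed = TRUE))
  expect_true(grepl(d2, r$expanded, fixed = TRUE))
})

test_that("loss calls recover each synthetic mechanism with usable evidence", {
  cfg <- sim_config()
  set.seed(16)

  r <- loss_with_retry("nonsense_point", cfg)
  cl <- classify_loss_mechanism(r$loss$precursor, r$biv)
  expect_equal(cl$mechanism, "nonsense_point")
  ev <- cl$evidence
  expect_true(ev$codon_to %in% c("TAA", "TAG", "TGA"))
  expect_equal(sum(strsplit(ev$codon_from, "")[[1]] !=
                     strsplit(ev$codon_to, "")[[1]]), 1L)
  # re-checkable: applying the substitution to the ancestor recreates the
  # stop at the reported position
  anc_cds <- r$biv$cds
  patched <- paste0(substr(anc_cds, 1, ev$ancestor_position - 1),
                    ev$codon_to,
                    substr(anc_cds, ev$ancestor_position + 3, nchar(anc_cds)))
  pep <- translate_seq(substr(patched, 1, ev$stop_interval[2]), 1)
  expect_equal(substr(pep, nchar(pep), nchar(pep)), "*")
  expect_true(ev$stop_position_bp >= ev$stop_interval[1] &&
                ev$stop_position_bp <= ev$stop_interval[2])

  r2 <- loss_with_retry("deletion_stop", cfg)
  cl2 <- classify_loss_mechanism(r2$loss$precursor, r2$biv)
  expect_equal(cl2$mechanism, "deletion_stop")
  ev2 <- cl2$evidence
  # re-checkable: deleting the reported span reproduces the stop interval
  anc2 <- r2$biv$cds
  del <- paste0(substr(anc2, 1, ev2$deletion_interval[1] - 1),
                substr(anc2, ev2$deletion_interval[2] + 1, nchar(anc2)))
  expect_true(substr(del, ev2$stop_interval[1], ev2$stop_interval[2]) %in%
                c("TAA", "TAG", "TGA"))

  r3 <- loss_with_retry("fusion_crossover", cfg)
  cl3 <- classify_loss_mechanism(r3$loss$precursor, r3$biv)
  expect_equal(cl3$mechanism, "fusion_crossover")
  expect_false(is.null(cl3$evidence$facilitating))

  r4 <- loss_with_retry("te_disruption", cfg)
  cl4 <- classify_loss_mechanism(r4$loss$precursor, r4$biv,
                                 tes = r4$loss$te)
  expect_equal(cl4$mechanism, "te_disruption")
  expect_equal(cl4$evidence$te$family, r4$loss$te$family)

  mono <- partition_architecture("CAAACAAAAAACCACAAAAC")
  m1 <- toxin_precursor("m", paste0("ATG", rand_dna(30), "TAA"))
  expect_error(classify_loss_mechanism(m1, m1), "monovalent|valency")
})
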