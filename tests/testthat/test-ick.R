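test_that("framework scanner handles canonical and degenerate peptides", {
  m <- scan_ick_frameworks("CAACAAACCACAAAC")  # minimal spacings 2,3,1,3
  expect_length(m, 1L)
  expect_equal(m[[1]]$start, 1L)
  expect_equal(m[[1]]$end, 15L)
  expect_equal(m[[1]]$spacings, c(2L, 3L, 1L, 3L))

  expect_length(scan_ick_frameworks("AAAAA"), 0L)
  expect_error(scan_ick_frameworks(""), "empty")

  # every match has 6 cysteines at its recorded positions with a CC pair
  set.seed(2)
  for (i in 1:50) {
    pep <- rand_pep(60, pool = c(strsplit("ARNDQEGHILK", "")[[1]],
                                 rep("C", 6)))
    for (h in scan_ick_frameworks(pep, all_matches = TRUE)) {
      ch <- strsplit(pep, "")[[1]]
      expect_true(all(ch[h$cys_positions] == "C"))
      expect_equal(h$cys_positions[4] - h$cys_positions[3], 1L)
    }
  }
})

test_that("framework scanner agrees with the nested-loop enumerator", {
  set.seed(4)
  pool <- c(strsplit("ARNDQEGHILKMFPSTWYV", "")[[1]], rep("C", 7))
  for (i in 1:200) {
    pep <- rand_pep(sample(20:80, 1), pool = pool)
    got_all <- scan_ick_frameworks(pep, all_matches = TRUE)
    want_all <- oracle_scan_all(pep)
    expect_equal(length(got_all), length(want_all), info = pep)
    if (length(got_all)) {
      key <- function(h) paste(h$start, h$end,
                               paste(h$spacings, collapse = "."))
      expect_setequal(vapply(got_all, key, character(1)),
                      vapply(want_all, function(h)
                        paste(h$start, h$end,
                              paste(h$spacings, collapse = ".")),
                        character(1)))
    }
    got <- scan_ick_frameworks(pep)
    want <- oracle_scan_greedy(pep)
    expect_equal(vapply(got, `[[`, integer(1), "start"),
                 vapply(want, function(h) as.integer(h$start), integer(1)),
                 info = pep)
    expect_equal(vapply(got, `[[`, integer(1), "end"),
                 vapply(want, function(h) as.integer(h$end), integer(1)),
                 info = pep)
  }
})

test_that("architecture partition reconstructs the mature peptide exactly", {
  dom <- "CAAACAAAAAACCACAAAAC"
  one <- partition_architecture(dom)
  expect_equal(one$valency, 1L)
  expect_length(one$linkers, 0L)

  spacer <- "VPISQR"
  biv <- partition_architecture(paste0("GG", dom, spacer, dom, "VPIS"))
  expect_equal(biv$valency, 2L)
  expect_equal(biv$linkers, spacer)
  expect_equal(biv$leader, "GG")
  expect_equal(biv$tail, "VPIS")

  none <- partition_architecture("MKVLAAA")
  expect_equal(none$valency, 0L)
  expect_false(none$is_ick)

  # reconstruction is character-exact for arbitrary peptides
  set.seed(6)
  pool <- c(strsplit("ARNDQEGHILKMFPSTWYV", "")[[1]], rep("C", 8))
  for (i in 1:100) {
    pep <- rand_pep(sample(15:120, 1), pool = pool)
    a <- partition_architecture(pep)
    pieces <- a$leader
    if (a$valency > 0) {
      doms <- vapply(a$domains, function(d) substr(pep, d$start, d$end),
                     character(1))
      for (j in seq_len(a$valency)) {
        pieces <- paste0(pieces, doms[j],
                         if (j < a$valency) a$linkers[j] else "")
      }
      pieces <- paste0(pieces, a$tail)
    }
    expect_identical(pieces, pep)
    if (a$valency >= 1) expect_length(a$linkers, a$valency - 1L)
  }
})

test_that("linker conservation reports per-position agreement", {
  mk <- function(linker) {
    dom <- "CAAACAAAAAACCACAAAAC"
    partition_architecture(paste0(dom, linker, dom, "APIT"))
  }
  same <- lapply(c("VPISQ", "VPISQ", "VPISQ"), mk)
  r <- linker_conservation(same)
  expect_true(all(r$table$conserved))
  expect_equal(r$mean_pairwise_identity, 1.0)

  mixed <- lapply(c("VPISQ", "VPIAR", "VPITQ"), mk)
  r2 <- linker_conservation(mixed)
  expect_equal(r2$table$conserved[1:3], c(TRUE, TRUE, TRUE))
  expect_false(r2$table$conserved[4])
  expect_equal(r2$table$residue[1:3], c("V", "P", "I"))

  expect_error(linker_conservation(list(mk("VPISQ"))), ">= 2 multivalent")
})

test_that("linker/tail homology captures the tail exaptation signature", {
  dom <- "CAAACAAAAAACCACAAAAC"
  fresh <- partition_architecture(paste0(dom, "VPIS", dom, "VPIS"))
  expect_equal(linker_tail_homology(fresh)$identity, 1.0)

  hc1a_like <- partition_architecture(paste0(dom, "VPIS", dom, "APIT"))
  h <- linker_tail_homology(hc1a_like)
  expect_equal(h$matches, 2L)
  expect_equal(h$columns, 4L)
  expect_equal(h$identity, 0.5)

  mono <- partition_architecture(dom)
  expect_error(linker_tail_homology(mono), "multivalent")
})

test_that("gene structure validation checks the 3-exon knottin layout", {
  set.seed(10)
  a <- make_ancestor(sim_config(seed = 10))
  sr <- validate_gene_structure(a$gene, a$contig, a$mature_arch)
  expect_equal(sr$exon_count, 3L)
  expect_equal(sr$intron_phases, c(1L, 2L))
  expect_true(sr$mature_in_last_exon)
  expect_false(sr$interdomain_intron)
  expect_true(all(sr$verdicts))

  # 2-exon gene fails the exon-count verdict
  two <- data.frame(type = c("CDS", "CDS"), start = c(1, 200),
                    end = c(60, 259), strand = "+")
  genome2 <- paste0(rand_dna(300))
  sr2 <- validate_gene_structure(two, genome2)
  expect_false(sr2$verdicts[["exon_count"]])

  # frame inconsistency errors with coordinates
  bad <- data.frame(type = "CDS", start = 1, end = 4, strand = "+")
  expect_error(validate_gene_structure(bad, "ACGTACGT"), "frame")
})

test_that("gene models round-trip through GFF3", {
  set.seed(11)
  a <- make_ancestor(sim_config(seed = 11))
  tf <- tempfile(fileext = ".gff3")
  write_gff3(a$gene, tf)
  back <- read_gff3(tf)
  expect_equal(back$type, a$gene$type)
  expect_equal(back$start, a$gene$start)
  expect_equal(back$end, a$gene$end)
  # the re-read model validates identically
  sr <- validate_gene_structure(back, a$contig, a$mature_arch)
  expect_true(all(sr$verdicts))
})

test_that("an intron between domains is flagged (exon-shuffling signature)", {
  # bivalent mature peptide split by an intron inside the linker
  dom <- "CAAACAAAAAACCACAAAAC"
  mature <- paste0(dom, "VPISQR", dom, "VPIS")
  arch <- partition_architecture(mature)
  cds <- paste0("ATG", rev_translate_test(mature), "TAA")
  # place the junction between the two domain-coding segments
  break_at <- 3 + (nchar(dom) + 3) * 3   # inside the linker codons
  intron <- paste0("GT", rand_dna(50), "AG")
  genome <- paste0(substr(cds, 1, break_at), intron,
                   substr(cds, break_at + 1, nchar(cds)))
  gene <- data.frame(type = c("CDS", "CDS"),
                     start = c(1, break_at + nchar(intron) + 1),
                     end = c(break_at, nchar(genome)), strand = "+")
  sr <- validate_gene_structure(gene, genome, arch)
  expect_true(sr$interdomain_intron)
  expect_false(sr$verdicts[["no_interdomain_intron"]])
})
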