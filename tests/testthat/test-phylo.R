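test_that("distance matrices reproduce closed-form values", {
  aln <- c(a = "ACGT", b = "ACGA", c = "ACGT")
  dm <- distance_matrix(aln, "p_distance")
  expect_equal(dm$d["a", "b"], 0.25)
  expect_equal(dm$d["a", "c"], 0)
  expect_true(isSymmetric(dm$d))

  # K2P closed form for 1 transition + 1 transversion over 20 sites
  x <- strsplit(strrep("A", 20), "")[[1]]
  y <- x; y[1] <- "G"; y[2] <- "C"      # A->G transition, A->C transversion
  aln2 <- c(a = paste(x, collapse = ""), b = paste(y, collapse = ""),
            c = paste(x, collapse = ""))
  P <- 1 / 20; Q <- 1 / 20
  k2p <- -0.5 * log((1 - 2 * P - Q) * sqrt(1 - 2 * Q))
  expect_equal(distance_matrix(aln2, "K2P")$d["a", "b"], k2p,
               tolerance = 1e-10)

  expect_error(distance_matrix(aln[1:2]), ">= 3")
})

test_that("NJ is exact on additive distances", {
  # known additive 4-taxon matrix, quartet (a,b | c,d)
  d <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  d["a", "b"] <- d["b", "a"] <- 3   # 1 + 2
  d["a", "c"] <- d["c", "a"] <- 7   # 1 + 2(int) + 4
  d["a", "d"] <- d["d", "a"] <- 6   # 1 + 2 + 3
  d["b", "c"] <- d["c", "b"] <- 8
  d["b", "d"] <- d["d", "b"] <- 7
  d["c", "d"] <- d["d", "c"] <- 7
  tr <- nj_tree(d)
  # path lengths equal the additive input exactly, which pins the quartet
  expect_equal(as.matrix(ape::cophenetic.phylo(tr))[rownames(d), rownames(d)],
               d, tolerance = 1e-10)
  # and (a,b) form a cherry
  rooted <- ape::root(tr, outgroup = c("c", "d"), resolve.root = TRUE)
  expect_true(ape::is.monophyletic(rooted, c("a", "b")))

  # random additive trees: path-length matrix is recovered exactly
  set.seed(30)
  for (i in 1:10) {
    src <- ape::rtree(8)
    dm <- as.matrix(ape::cophenetic.phylo(src))
    out <- nj_tree(dm)
    expect_equal(as.matrix(ape::cophenetic.phylo(out))[rownames(dm),
                                                       colnames(dm)],
                 dm, tolerance = 1e-8)
  }
  expect_error(nj_tree(d[1:2, 1:2]), ">= 3")
})

test_that("bootstrap support behaves at the degenerate limits", {
  set.seed(31)
  # fully congruent, homoplasy-free signal: four clean clades
  block <- function(ch, n) strrep(ch, n)
  mk <- function(p1, p2, p3) paste0(block(p1, 30), block(p2, 30),
                                    block(p3, 30))
  aln <- c(t1 = mk("A", "A", "C"), t2 = mk("A", "A", "G"),
           t3 = mk("T", "C", "C"), t4 = mk("T", "C", "G"),
           t5 = mk("T", "G", "A"))
  bs <- bootstrap_support(aln, reps = 50, seed = 1)
  expect_true(all(bs$support[!is.na(bs$support)] >= 0 &
                    bs$support[!is.na(bs$support)] <= 100))

  one <- bootstrap_support(aln, reps = 1, seed = 2)
  expect_true(all(one$support %in% c(0, 100)))

  # taxon input order does not change supports for a fixed seed
  b1 <- bootstrap_support(aln, reps = 20, seed = 3)
  b2 <- bootstrap_support(aln[c(3, 1, 5, 2, 4)], reps = 20, seed = 3)
  expect_equal(sort(b1$support), sort(b2$support))
})

test_that("domain clade separation detects the C vs N+single split", {
  tr <- ape::read.tree(text = "((c1,(c2,c3)),((n1,n2),(s1,n3)));")
  labels <- c(c1 = "C", c2 = "C", c3 = "C", n1 = "N", n2 = "N", n3 = "N",
              s1 = "single")
  r <- domain_clade_separation(tr, labels)
  expect_true(r$separation)
  expect_true(r$monophyly[["C"]])

  # break the split: move a C tip among the Ns
  labels2 <- labels; labels2["n1"] <- "C"
  r2 <- domain_clade_separation(tr, labels2)
  expect_false(r2$separation)

  expect_error(domain_clade_separation(tr, labels[-1]), "missing")

  # separation verdict agrees with explicit bipartition enumeration
  set.seed(32)
  for (i in 1:20) {
    tr8 <- ape::rtree(8)
    lab <- setNames(sample(c("C", "N", "single"), 8, TRUE), tr8$tip.label)
    want <- FALSE
    parts <- ape::prop.part(tr8)
    ctips <- sort(tr8$tip.label[lab[tr8$tip.label] == "C"])
    for (p in parts) {
      side <- sort(tr8$tip.label[p])
      if (identical(side, ctips) ||
          identical(sort(setdiff(tr8$tip.label, side)), ctips)) want <- TRUE
    }
    got <- domain_clade_separation(tr8, lab)$separation
    expect_equal(got, want, info = paste("case", i))
  }
})

test_that("valency event counts match exhaustive enumeration", {
  # star tree, all tips bivalent: one gain, zero losses
  star <- ape::read.tree(text = "(a,b,c,d);")
  st <- c(a = 2, b = 2, c = 2, d = 2)
  ec <- count_valency_events(star, st, "dollo_single_gain")
  expect_equal(ec$losses, 0L)
  expect_equal(ec$gains, 1L)

  all_mono <- count_valency_events(star, st * 0 + 1, "dollo_single_gain")
  expect_equal(all_mono$changes, 0L)

  # a valency_tree bundle is accepted directly
  vt <- valency_tree(star, st)
  expect_equal(count_valency_events(vt, model = "dollo_single_gain")$losses,
               ec$losses)

  expect_error(count_valency_events(star, st[-1]), "missing")

  set.seed(33)
  for (i in 1:30) {
    n <- sample(4:8, 1)
    tr <- ape::rtree(n)
    states <- setNames(sample(1:2, n, TRUE), tr$tip.label)
    fitch <- count_valency_events(tr, states, "fitch")
    expect_equal(fitch$changes, oracle_min_changes(tr, states),
                 info = paste("fitch case", i))
    dollo <- count_valency_events(tr, states, "dollo_single_gain")
    if (any(states >= 2)) {
      expect_equal(dollo$losses, oracle_dollo_losses(tr, states),
                   info = paste("dollo case", i))
    }
    # Dollo total changes never beat the unconstrained minimum
    expect_gte(dollo$changes, fitch$changes)
    # independent implementation cross-check (phangorn parsimony score)
    pd <- phangorn::phyDat(matrix(ifelse(states[tr$tip.label] >= 2, "a", "c"),
                                  ncol = 1,
                                  dimnames = list(tr$tip.label, NULL)),
                           type = "USER", levels = c("a", "c"))
    expect_equal(fitch$changes, as.integer(phangorn::parsimony(tr, pd)),
                 info = paste("phangorn case", i))
  }
})

test_that("rooting enumeration brackets the loss count", {
  # all tips in the same state: every rooting is event-free
  tr <- ape::rtree(6)
  st <- setNames(rep(2, 6), tr$tip.label)
  en <- enumerate_rootings(tr, st)
  expect_equal(en$min_losses, 0)
  expect_equal(en$max_losses, 0)

  # 4 tips, alternating states: hand enumeration gives 1 or 2 losses
  q <- ape::read.tree(text = "((a,b),(c,d));")
  st2 <- c(a = 2, b = 1, c = 2, d = 1)
  en2 <- enumerate_rootings(q, st2)
  expect_equal(en2$min_losses, 1)
  expect_equal(en2$max_losses, 2)

  # every rooting's change count is bounded below by the Fitch minimum
  set.seed(34)
  for (i in 1:10) {
    tr8 <- ape::rtree(7)
    st8 <- setNames(sample(1:2, 7, TRUE), tr8$tip.label)
    if (!any(st8 >= 2)) next
    fmin <- count_valency_events(tr8, st8, "fitch")$changes
    en8 <- enumerate_rootings(tr8, st8)
    expect_true(all(en8$per_rooting$losses + en8$per_rooting$gains >= fmin))
  }
})
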