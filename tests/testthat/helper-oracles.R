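# Independent brute-force oracles and fixture generators. Every oracle here
# deliberately uses a different algorithm than the package implementation.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

rand_pep <- function(n, pool = strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]) {
  paste(sample(pool, n, TRUE), collapse = "")
}

# --- ICK framework scanner oracle: four nested loops over spacing values ---
oracle_scan_all <- function(pep) {
  ch <- strsplit(pep, "")[[1]]
  n <- length(ch)
  hits <- list()
  for (s in seq_len(n)) {
    if (ch[s] != "C") next
    for (x1 in 2:7) for (x2 in 3:10) for (x3 in 1:4) for (x4 in 3:13) {
      p <- c(s, s + x1 + 1, s + x1 + x2 + 2, s + x1 + x2 + 3,
             s + x1 + x2 + x3 + 4, s + x1 + x2 + x3 + x4 + 5)
      if (p[6] > n) next
      if (all(ch[p] == "C")) {
        hits[[length(hits) + 1]] <- list(start = p[1], end = p[6],
                                         cys = p, spacings = c(x1, x2, x3, x4))
      }
    }
  }
  hits
}

oracle_scan_greedy <- function(pep) {
  hits <- oracle_scan_all(pep)
  if (!length(hits)) return(hits)
  st <- vapply(hits, `[[`, numeric(1), "start")
  en <- vapply(hits, `[[`, numeric(1), "end")
  sel <- list()
  last <- 0
  for (i in order(st, en - st)) {
    if (st[i] > last) {
      sel[[length(sel) + 1]] <- hits[[i]]
      last <- en[i]
    }
  }
  sel
}

# --- ungapped local match oracle: enumerate every segment pair ------------
oracle_local_match <- function(a, b, min_len = 1) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  best <- NULL
  for (i in seq_len(n)) for (j in seq_len(m)) {
    maxL <- min(n - i, m - j) + 1
    if (maxL < min_len) next
    eq <- ca[i:(i + maxL - 1)] == cb[j:(j + maxL - 1)] &
      !(ca[i:(i + maxL - 1)] %in% c("N", "X", "-"))
    sc <- cumsum(ifelse(eq, 1, -1))
    for (L in min_len:maxL) {
      s <- sc[L]
      if (s <= 0) next
      cand <- list(a_start = i, a_end = i + L - 1, b_start = j,
                   b_end = j + L - 1, length = L, score = s,
                   matches = sum(eq[1:L]))
      if (is.null(best) || s > best$score ||
          (s == best$score && (L > best$length ||
            (L == best$length && (i < best$a_start ||
              (i == best$a_start && j < best$b_start)))))) best <- cand
    }
  }
  best
}

# --- inverted repeat oracle: enumerate all arm pairs, check maximality ----
oracle_inverted_repeats <- function(s, min_arm = 3, max_mm = 0) {
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  ch <- strsplit(s, "")[[1]]
  n <- length(ch)
  mm <- function(l1, l2, c) {
    # mismatches of arm pair (l1..l2) vs (c-l2..c-l1)
    sum(vapply(l1:l2, function(a) {
      b <- c - a
      cm <- comp[ch[a]]
      is.na(cm) || cm != ch[b]
    }, logical(1)))
  }
  hits <- list()
  for (c in 3:(2 * n - 1)) {
    t_lo <- max(1, c - n); t_hi <- (c - 1) %/% 2
    if (t_hi - t_lo + 1 < min_arm) next
    for (l1 in t_lo:t_hi) for (l2 in l1:t_hi) {
      if (l2 - l1 + 1 < min_arm) next
      if (mm(l1, l2, c) > max_mm) next
      # maximal: no extension outward or inward stays within budget
      ext_out <- l1 - 1 >= t_lo && mm(l1 - 1, l2, c) <= max_mm
      ext_in <- l2 + 1 <= t_hi && mm(l1, l2 + 1, c) <= max_mm
      if (ext_out || ext_in) next
      hits[[length(hits) + 1]] <- c(left_start = l1, left_end = l2,
                                    right_start = c - l2, right_end = c - l1,
                                    arm_length = l2 - l1 + 1,
                                    mismatches = mm(l1, l2, c))
    }
  }
  if (!length(hits)) {
    return(data.frame(left_start = integer(0), left_end = integer(0),
                      right_start = integer(0), right_end = integer(0),
                      arm_length = integer(0), mismatches = integer(0)))
  }
  df <- as.data.frame(do.call(rbind, hits))
  df[order(df$left_start, df$right_start), ]
}

# --- parsimony oracles: exhaustive internal-state enumeration -------------
oracle_min_changes <- function(tree, tip_states) {
  n_tip <- length(tree$tip.label)
  internal <- (n_tip + 1):max(tree$edge)
  states <- as.integer(tip_states[tree$tip.label] >= 2)
  best <- Inf
  for (mask in 0:(2^length(internal) - 1)) {
    st <- c(states, as.integer(intToBits(mask))[seq_along(internal)])
    ch <- sum(st[tree$edge[, 1]] != st[tree$edge[, 2]])
    best <- min(best, ch)
  }
  best
}

oracle_dollo_losses <- function(tree, tip_states) {
  n_tip <- length(tree$tip.label)
  internal <- (n_tip + 1):max(tree$edge)
  states <- as.integer(tip_states[tree$tip.label] >= 2)
  if (!any(states == 1)) return(0L)
  root <- n_tip + 1
  best <- Inf
  for (mask in 0:(2^length(internal) - 1)) {
    st <- c(states, as.integer(intToBits(mask))[seq_along(internal)])
    gains <- sum(st[tree$edge[, 1]] == 0 & st[tree$edge[, 2]] == 1) +
      (st[root] == 1)                     # a gain on the root edge counts
    if (gains != 1) next
    losses <- sum(st[tree$edge[, 1]] == 1 & st[tree$edge[, 2]] == 0)
    best <- min(best, losses)
  }
  best
}

# --- interval-union coverage oracle: per-base-pair counting ---------------
oracle_coverage <- function(tes, lo, hi) {
  covered <- logical(hi - lo + 1)
  for (i in seq_len(nrow(tes))) {
    s <- max(tes$start[i], lo); e <- min(tes$end[i], hi)
    if (s <= e) covered[(s - lo + 1):(e - lo + 1)] <- TRUE
  }
  sum(covered)
}

rev_translate_test <- function(pep) knotarch:::rev_translate(pep)

# a bivalent precursor diverged by `div` subs/site, for forensic tests
make_diverged_bivalent <- function(cfg = sim_config(), div = 0.08) {
  a <- make_ancestor(cfg)
  biv <- apply_duplication(a)$precursor
  st <- knotarch:::evolve_state(biv$state, div, cfg)
  knotarch:::assemble_precursor(st, "biv")
}

# retry helper: some sequences admit no valid event of a given mechanism
loss_with_retry <- function(mech, cfg = sim_config(), div = 0.08,
                            max_try = 20) {
  for (i in seq_len(max_try)) {
    biv <- make_diverged_bivalent(cfg, div)
    l <- tryCatch(apply_loss(biv, mech, cfg), error = function(e) NULL)
    if (!is.null(l)) return(list(biv = biv, loss = l))
  }
  stop("could not generate a ", mech, " event")
}
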