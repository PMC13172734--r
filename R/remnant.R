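#' Build a position-specific scoring matrix from a pre-aligned set
#'
#' Column frequencies receive an additive pseudocount and are converted to
#' log-odds against a background estimated from the whole input set (also
#' pseudocounted). Gap characters are excluded from the counts. A PSSM with
#' a defined shuffle null stands in for the profile-HMM search used at
#' genome scale; the detection task is the same at desk scale.
#'
#' @param aligned Named character vector of aligned sequences (equal
#'   lengths; may contain `-`).
#' @param pseudocount Additive pseudocount weight per symbol.
#' @return A `pssm` list: `alphabet`, `length`, `log_odds` (symbol x column
#'   matrix), `background`, `pseudocount`.
#' @export
build_pssm <- function(aligned, pseudocount = 0.5) {
  if (length(aligned) < 2) stop("need >= 2 aligned sequences")
  lens <- nchar(aligned)
  if (length(unique(lens)) != 1) {
    stop("ragged alignment: lengths ", paste(unique(lens), collapse = ", "))
  }
  alphabet <- if (guess_alphabet(aligned) == "dna") c("A", "C", "G", "T") else
    setdiff(AA_CHARS, c("X", "*"))
  mat <- do.call(rbind, strsplit(aligned, ""))
  ncol_a <- ncol(mat)
  bg_counts <- table(factor(mat[mat %in% alphabet], levels = alphabet))
  background <- (as.numeric(bg_counts) + pseudocount) /
    (sum(bg_counts) + pseudocount * length(alphabet))
  names(background) <- alphabet
  log_odds <- vapply(seq_len(ncol_a), function(j) {
    cnt <- table(factor(mat[mat[, j] %in% alphabet, j], levels = alphabet))
    p <- (as.numeric(cnt) + pseudocount) /
      (sum(cnt) + pseudocount * length(alphabet))
    log2(p / background)
  }, numeric(length(alphabet)))
  rownames(log_odds) <- alphabet
  structure(list(alphabet = alphabet, length = ncol_a, log_odds = log_odds,
                 background = background, pseudocount = pseudocount),
            class = "pssm")
}

#' Score a full-length sequence against a PSSM
#' @param pssm A `pssm`.
#' @param seq Sequence of length `pssm$length`.
#' @return Summed log-odds score. Symbols outside the alphabet score the
#'   column minimum.
#' @export
pssm_score <- function(pssm, seq) {
  if (nchar(seq) != pssm$length) stop("sequence length != pssm length")
  ch <- strsplit(seq, "")[[1]]
  sum(vapply(seq_along(ch), function(j) {
    if (ch[j] %in% pssm$alphabet) pssm$log_odds[ch[j], j]
    else min(pssm$log_odds[, j])
  }, numeric(1)))
}

#' Best-scoring window of a sequence under a PSSM
#' @param pssm A `pssm`.
#' @param seq Sequence (length >= `pssm$length`).
#' @return List `start`, `end`, `score` of the best window.
#' @export
pssm_scan <- function(pssm, seq) {
  L <- pssm$length
  n <- nchar(seq)
  if (n < L) stop("sequence shorter than pssm")
  scores <- vapply(seq_len(n - L + 1L),
                   function(s) pssm_score(pssm, substr(seq, s, s + L - 1L)),
                   numeric(1))
  s <- which.max(scores)
  list(start = s, end = s + L - 1L, score = scores[s])
}

#' Dinucleotide-preserving shuffle (Altschul-Erickson)
#'
#' Shuffles a DNA sequence while preserving its exact dinucleotide counts,
#' via a uniformly sampled Eulerian path in the dinucleotide multigraph:
#' a random arborescence toward the final symbol is drawn by backward
#' random walks, fixed as each vertex's last exit, and the remaining edges
#' are permuted.
#'
#' @param seq DNA string (length >= 3).
#' @return Shuffled string with identical dinucleotide composition.
#' @export
dinuc_shuffle <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  if (n < 3) return(seq)
  verts <- unique(ch)
  from <- ch[-n]; to <- ch[-1]
  last <- ch[n]
  edges <- split(to, factor(from, levels = verts))
  # sample an arborescence toward `last` by loop-erased-style random walks
  last_edge <- setNames(rep(NA_character_, length(verts)), verts)
  for (v in setdiff(verts, last)) {
    u <- v
    while (u != last) {
      nxt <- edges[[u]][sample.int(length(edges[[u]]), 1L)]
      last_edge[u] <- nxt
      u <- nxt
    }
  }
  # permute the remaining out-edges of each vertex, appending the fixed one
  pools <- lapply(verts, function(v) {
    e <- edges[[v]]
    if (!is.na(last_edge[v])) {
      drop <- match(last_edge[v], e)
      e <- e[-drop]
    }
    c(if (length(e)) e[sample.int(length(e))] else character(0),
      if (!is.na(last_edge[v])) last_edge[v] else character(0))
  })
  names(pools) <- verts
  ptr <- setNames(rep(1L, length(verts)), verts)
  out <- character(n)
  out[1] <- ch[1]
  u <- ch[1]
  for (i in 2:n) {
    nxt <- pools[[u]][ptr[u]]
    ptr[u] <- ptr[u] + 1L
    out[i] <- nxt
    u <- nxt
  }
  paste(out, collapse = "")
}

#' Scan a transcript for 3'UTR remnants of a lost domain
#'
#' Searches the query transcript (CDS plus 3'UTR) for traces of the donor
#' (lost-domain CDS): the best ungapped local nucleotide match and the best
#' translated match over all six reading frames. Significance is an
#' empirical p-value from rescoring dinucleotide-preserving shuffles of the
#' query; hits with p below the threshold are reported and annotated with
#' whether they overlap the 3'UTR.
#'
#' @param query Transcript sequence (CDS + 3'UTR).
#' @param cds_end 1-based position of the last CDS base in `query`.
#' @param donor Lost-domain CDS (character) or a nucleotide `pssm`.
#' @param null_shuffles Number of shuffles for the null (>= 100).
#' @param p_threshold Report hits with `empirical_p < p_threshold`.
#' @param seed Optional RNG seed for the shuffles.
#' @return A `remnant_scan` list with `hits` (data frame: `channel`,
#'   `start`, `end`, `length`, `frame`, `score`, `empirical_p`, `in_utr`)
#'   and the per-channel observed scores and p-values.
#' @export
scan_utr_remnant <- function(query, cds_end, donor, null_shuffles = 1000,
                             p_threshold = 0.01, seed = NULL) {
  if (missing(cds_end) || is.null(cds_end) || is.na(cds_end) ||
      cds_end < 1 || cds_end > nchar(query)) {
    stop("cds_end must mark the CDS/UTR boundary within the query")
  }
  if (null_shuffles < 100) stop("null_shuffles must be >= 100")
  if (!is.null(seed)) set.seed(seed)
  use_pssm <- inherits(donor, "pssm")

  dpep <- if (use_pssm) NULL else fast_translate(donor, 1)
  score_query <- function(q) {
    if (use_pssm) {
      nt <- if (nchar(q) >= donor$length) pssm_scan(donor, q)$score else -Inf
      return(c(nt = nt, aa = -Inf))
    }
    nt <- cpp_best_local_score(q, donor)
    peps <- fast_six_frame(q)
    aa <- max(vapply(peps, function(p) {
      if (nchar(p) == 0) 0 else cpp_best_local_score(p, dpep)
    }, numeric(1)))
    c(nt = nt, aa = aa)
  }
  obs <- score_query(query)
  null_mat <- vapply(seq_len(null_shuffles),
                     function(i) score_query(dinuc_shuffle(query)),
                     numeric(2))
  pvals <- vapply(c("nt", "aa"), function(k) {
    (1 + sum(null_mat[k, ] >= obs[[k]])) / (null_shuffles + 1)
  }, numeric(1))

  hits <- data.frame(channel = character(0), start = integer(0),
                     end = integer(0), length = integer(0),
                     frame = character(0), score = numeric(0),
                     empirical_p = numeric(0), in_utr = logical(0))
  if (!use_pssm) {
    if (pvals["nt"] < p_threshold) {
      h <- cpp_best_local_match(query, donor, 1L)
      if (length(h)) {
        hits <- rbind(hits, data.frame(
          channel = "nt", start = h[1], end = h[2], length = h[2] - h[1] + 1L,
          frame = "nt", score = obs[["nt"]], empirical_p = pvals[["nt"]],
          in_utr = h[2] > cds_end))
      }
    }
    if (pvals["aa"] < p_threshold) {
      peps <- fast_six_frame(query)
      sc <- vapply(peps, function(p) cpp_best_local_score(p, dpep), numeric(1))
      fr <- names(which.max(sc))
      h <- cpp_best_local_match(peps[[fr]], dpep, 1L)
      if (length(h)) {
        # map peptide window back to query nucleotide coordinates
        off <- as.integer(substr(fr, 2, 2)) - 1L
        if (startsWith(fr, "F")) {
          nt_start <- off + (h[1] - 1L) * 3L + 1L
          nt_end <- off + h[2] * 3L
        } else {
          n <- nchar(query)
          nt_end <- n - off - (h[1] - 1L) * 3L
          nt_start <- n - off - h[2] * 3L + 1L
        }
        hits <- rbind(hits, data.frame(
          channel = "aa", start = nt_start, end = nt_end,
          length = nt_end - nt_start + 1L, frame = fr, score = obs[["aa"]],
          empirical_p = pvals[["aa"]], in_utr = nt_end > cds_end))
      }
    }
  } else if (pvals["nt"] < p_threshold) {
    w <- pssm_scan(donor, query)
    hits <- rbind(hits, data.frame(
      channel = "pssm", start = w$start, end = w$end,
      length = w$end - w$start + 1L, frame = "nt", score = obs[["nt"]],
      empirical_p = pvals[["nt"]], in_utr = w$end > cds_end))
  }
  structure(list(hits = hits, observed = obs, p_values = pvals,
                 null_shuffles = null_shuffles, p_threshold = p_threshold),
            class = "remnant_scan")
}
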