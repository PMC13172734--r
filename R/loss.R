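#' Construct a toxin precursor record
#'
#' Bundles the nucleotide CDS (and optional 3'UTR) of a toxin precursor
#' with its translation and the ICK domain architecture detected in the
#' translated CDS. The architecture is scanned over the whole translated
#' precursor, so domain coordinates map directly onto CDS nucleotides.
#'
#' @param id Record id.
#' @param cds Coding sequence (including the stop codon when present).
#' @param utr3 Optional 3'UTR sequence appended to the transcript.
#' @param species,family Optional labels.
#' @param meta Optional named list of extra annotations.
#' @return A `toxin_precursor` list with `id`, `cds`, `utr3`, `transcript`,
#'   `peptide`, `architecture`, `valency`.
#' @export
toxin_precursor <- function(id, cds, utr3 = "", species = NA_character_,
                            family = NA_character_, meta = list()) {
  if (!nzchar(cds)) stop("empty CDS")
  pep <- translate_seq(cds, 1)
  pep_nostop <- sub("\\*.*$", "", pep)
  arch <- partition_architecture(if (nzchar(pep_nostop)) pep_nostop else pep,
                                 id = id)
  structure(list(id = id, cds = toupper(cds), utr3 = toupper(utr3),
                 transcript = paste0(toupper(cds), toupper(utr3)),
                 peptide = pep, architecture = arch, valency = arch$valency,
                 species = species, family = family, meta = meta),
            class = "toxin_precursor")
}

#' @export
print.toxin_precursor <- function(x, ...) {
  cat(sprintf("toxin precursor %s: CDS %d bp, 3'UTR %d bp, valency %d\n",
              x$id, nchar(x$cds), nchar(x$utr3), x$valency))
  invisible(x)
}

# 1-based CDS nucleotide spans of the framework domains of a precursor
precursor_domain_nt <- function(prec) {
  arch <- prec$architecture
  if (arch$valency == 0) {
    return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("start", "end"))))
  }
  st <- vapply(arch$domains, `[[`, integer(1), "start")
  en <- vapply(arch$domains, `[[`, integer(1), "end")
  cbind(start = (st - 1L) * 3L + 1L, end = en * 3L)
}

str_rev <- function(x) paste(rev(strsplit(x, "")[[1]]), collapse = "")

#' Locate an unequal-crossing-over breakpoint in a chimeric CDS
#'
#' For every split point *b* of the chimera the score is the number of
#' identical columns in the match-maximising global alignment of the prefix
#' against donor domain 1 plus that of the suffix against donor domain 2.
#' The argmax defines the breakpoint; consecutive maxima form the ambiguity
#' interval (a point breakpoint is unidentifiable in principle when the
#' donors are locally identical). The best ungapped local match between the
#' donors is returned as the putative recombination-facilitating stretch.
#'
#' @param chimera Chimeric CDS (the putative fusion product).
#' @param d1,d2 CDS of the ancestral N- and C-terminal domains.
#' @return A `crossover_breakpoint` list: `breakpoint_interval` (crossover
#'   lies after a chimera position within this 1-based interval), `score`,
#'   `support` (score gain over the best single-donor explanation),
#'   `no_chimeric_signal`, `unidentifiable`, `facilitating` (a
#'   `local_match` between `d1` and `d2`), `scores` (per split point).
#' @export
locate_crossover_breakpoint <- function(chimera, d1, d2) {
  if (!nzchar(chimera) || !nzchar(d1) || !nzchar(d2)) stop("empty input")
  n <- nchar(chimera)
  M1 <- cpp_lcs_prefix(chimera, d1)              # index b+1 <-> prefix b
  R  <- cpp_lcs_prefix(str_rev(chimera), str_rev(d2))
  Tb <- vapply(0:n, function(b) M1[b + 1L] + R[n - b + 1L], numeric(1))
  mx <- max(Tb)
  B <- which(Tb == mx) - 1L
  no_signal <- (0L %in% B) || (n %in% B)
  interval <- c(min(B), max(B))
  support <- mx - max(M1[n + 1L], R[n + 1L])
  structure(list(
    breakpoint_interval = interval, score = mx, support = support,
    no_chimeric_signal = no_signal,
    unidentifiable = diff(interval) > n / 2,
    facilitating = best_local_match(d1, d2, min_length = 5),
    scores = Tb
  ), class = "crossover_breakpoint")
}

#' Reciprocal products of an unequal crossing-over between tandem domains
#'
#' Emits both recombination products of a misaligned exchange between the
#' two domains of a bivalent gene: the contracted single-domain fusion
#' (domain 1 prefix joined to domain 2 suffix) and the expanded
#' three-domain product whose middle domain is the mirror fusion.
#'
#' @param d1,d2 Domain sequences.
#' @param breakpoint A `crossover_breakpoint` or an integer split position
#'   (crossover after this position of each domain).
#' @param linker Interdomain linker sequence of the source gene.
#' @return List `contracted`, `expanded`, `fused_domain`, `b`.
#' @export
crossover_byproducts <- function(d1, d2, breakpoint, linker = "") {
  b <- if (inherits(breakpoint, "crossover_breakpoint")) {
    as.integer(floor(mean(breakpoint$breakpoint_interval)))
  } else as.integer(breakpoint)
  if (b < 0 || b > min(nchar(d1), nchar(d2))) stop("breakpoint out of range")
  contracted <- paste0(substr(d1, 1, b), substr(d2, b + 1L, nchar(d2)))
  fused <- paste0(substr(d2, 1, b), substr(d1, b + 1L, nchar(d1)))
  expanded <- paste0(d1, linker, fused, linker, d2)
  list(contracted = contracted, expanded = expanded, fused_domain = fused,
       b = b)
}

#' Classify the molecular mechanism behind a domain loss
#'
#' Compares a reduced-valency precursor with its higher-valency ancestor
#' and reconstructs how the domain was lost. The decision cascade:
#' a transposable-element annotation overlapping the region where the
#' missing domain should lie calls `te_disruption`; a single substitution
#' that converts an ancestral codon into the in-frame stop truncating the
#' ORF at the observed CDS/UTR boundary calls `nonsense_point`; an
#' alignment gap whose removal from the ancestor recreates the observed
#' premature stop calls `deletion_stop`; a chimeric CDS whose prefix
#' matches ancestral domain 1 and suffix domain 2 calls `fusion_crossover`;
#' otherwise `unresolved`. All checks are evaluated and retained; the call
#' is the best-supported explanation, ranked by the fewest mutational
#' events it requires.
#'
#' @param mono Reduced-valency `toxin_precursor` (transcript may include a
#'   3'UTR carrying the domain remnant).
#' @param ancestor Ancestral `toxin_precursor` with `valency >= mono + 1`.
#' @param tes Optional TE annotation data frame (columns `start`, `end` in
#'   mono transcript coordinates, plus family columns) for the TE check.
#' @return A `loss_call` list: `mechanism`, `evidence`, `checks`.
#' @export
classify_loss_mechanism <- function(mono, ancestor, tes = NULL) {
  if (ancestor$valency < 2) stop("ancestor is monovalent")
  if (ancestor$valency < mono$valency + 1) {
    stop("ancestor valency must exceed the reduced precursor's")
  }
  transcript <- mono$transcript
  cds_end <- nchar(mono$cds)
  checks <- list()

  # (1) TE disruption: annotation overlapping where the missing domain
  # should lie (from the end of the last intact domain to transcript end)
  dom_mono <- precursor_domain_nt(mono)
  region_start <- if (nrow(dom_mono)) dom_mono[nrow(dom_mono), "end"] + 1L else 1L
  te_hit <- NULL
  if (!is.null(tes) && nrow(tes)) {
    ov <- tes$end >= region_start & tes$start <= nchar(transcript)
    if (any(ov)) te_hit <- tes[which(ov)[1], , drop = FALSE]
  }
  checks$te_disruption <- list(valid = !is.null(te_hit), te = te_hit,
                               disrupted_region = c(region_start, nchar(transcript)))

  # global alignment of the mono transcript against the ancestor CDS;
  # the transcript is truncated just past the ancestor's length so that
  # unrelated downstream 3'UTR sequence cannot distort the alignment
  al_len <- min(nchar(transcript), nchar(ancestor$cds) + 30L)
  al <- cpp_nw_align(substr(transcript, 1L, al_len), ancestor$cds)
  a_ch <- strsplit(al$a, "")[[1]]
  b_ch <- strsplit(al$b, "")[[1]]
  a_pos <- cumsum(a_ch != "-")          # mono position per column
  b_pos <- cumsum(b_ch != "-")          # ancestor position per column

  # (2) nonsense point mutation at the observed stop
  nonsense <- list(valid = FALSE)
  stop_cols <- which(a_ch != "-" & a_pos >= cds_end - 2L & a_pos <= cds_end)
  mono_stop <- substr(mono$cds, cds_end - 2L, cds_end)
  if (length(stop_cols) == 3L && mono_stop %in% c("TAA", "TAG", "TGA") &&
      all(b_ch[stop_cols] != "-")) {
    anc_first <- b_pos[stop_cols[1]]
    anc_codon <- paste(b_ch[stop_cols], collapse = "")
    in_frame <- (anc_first - 1L) %% 3L == 0L &&
      (anc_first - (cds_end - 2L)) %% 3L == 0L
    ndiff <- sum(strsplit(anc_codon, "")[[1]] != strsplit(mono_stop, "")[[1]])
    if (in_frame && ndiff == 1L && !(anc_codon %in% STOP_CODONS)) {
      # guard: the putative remnant downstream of the stop must still
      # track the ancestor in the same frame (a frameshifted transcript
      # would show background-level identity here)
      w <- min(60L, nchar(transcript) - cds_end,
               nchar(ancestor$cds) - (anc_first + 2L))
      remnant_ok <- TRUE
      if (w >= 15L) {
        remnant_ok <- ungapped_matches(
          substr(transcript, cds_end + 1L, cds_end + w),
          substr(ancestor$cds, anc_first + 3L, anc_first + 2L + w)) / w >= 0.6
      }
      if (remnant_ok) {
        mut <- which(strsplit(anc_codon, "")[[1]] != strsplit(mono_stop, "")[[1]])
        nonsense <- list(valid = TRUE, codon_from = anc_codon,
                         codon_to = mono_stop,
                         stop_position_bp = cds_end - 3L + mut,
                         stop_interval = c(cds_end - 2L, cds_end),
                         ancestor_position = anc_first)
      }
    }
  }
  checks$nonsense_point <- nonsense

  # (3) deletion re-framing a downstream stop: direct search for the
  # ancestor span whose removal recreates the observed stop (every call is
  # re-checkable by construction: deleting the reported span from the
  # ancestor CDS reproduces an in-frame stop at the reported interval)
  deletion <- list(valid = FALSE)
  if (mono_stop %in% STOP_CODONS && cds_end >= 6L) {
    anc_len <- nchar(ancestor$cds)
    anc_ch <- strsplit(ancestor$cds, "")[[1]]
    mono_ch <- strsplit(substr(mono$cds, 1L, cds_end), "")[[1]]
    s_lo <- max(1L, cds_end - 75L)
    s_hi <- min(anc_len - 1L, cds_end + 3L)
    cand <- list()
    for (s in s_lo:s_hi) {
      for (k in 1:30) {
        if (s + k - 1L > anc_len || anc_len - k < cds_end) next
        # anc_del position p maps to ancestor position p (p < s) or p + k
        idx <- seq_len(cds_end)
        idx[idx >= s] <- idx[idx >= s] + k
        del_ch <- anc_ch[idx]
        if (!paste(del_ch[(cds_end - 2L):cds_end], collapse = "") %in%
              STOP_CODONS) next
        ident <- sum(del_ch == mono_ch & !(del_ch %in% c("N", "-"))) / cds_end
        if (ident < 0.8) next
        # remnant guard: downstream of the stop the transcript must keep
        # tracking the (frameshifted) ancestor -- the pseudogenized rest of
        # the lost domain; a fusion product has no such remnant
        w <- min(60L, nchar(transcript) - cds_end, anc_len - k - cds_end)
        if (w >= 15L) {
          down_idx <- (cds_end + 1L):(cds_end + w)
          down_idx[down_idx >= s] <- down_idx[down_idx >= s] + k
          down_ident <- sum(anc_ch[down_idx] ==
                              strsplit(substr(transcript, cds_end + 1L,
                                              cds_end + w), "")[[1]]) / w
          if (down_ident < 0.6) next
        }
        cand[[length(cand) + 1L]] <- list(s = s, k = k, ident = ident,
                                          seq = paste(del_ch, collapse = ""))
      }
    }
    if (length(cand)) {
      ord <- order(-vapply(cand, `[[`, numeric(1), "ident"),
                   vapply(cand, `[[`, numeric(1), "k"))
      for (i in ord) {
        # must be the FIRST in-frame stop of the reconstructed ORF
        pep <- translate_seq(cand[[i]]$seq, 1)
        if (regexpr("*", pep, fixed = TRUE) == nchar(pep)) {
          best <- cand[[i]]
          deletion <- list(valid = TRUE,
                           deletion_interval = c(best$s, best$s + best$k - 1L),
                           deletion_length = best$k,
                           stop_interval = c(cds_end - 2L, cds_end),
                           stop_codon = mono_stop,
                           reconstruction_identity = best$ident)
          break
        }
      }
    }
  }
  checks$deletion_stop <- deletion

  # (4) chimeric fusion by unequal crossing-over
  crossover <- list(valid = FALSE)
  dom_anc <- precursor_domain_nt(ancestor)
  if (nrow(dom_mono) >= 1 && nrow(dom_anc) >= 2) {
    chim <- substr(mono$cds, dom_mono[1, "start"], dom_mono[1, "end"])
    d1 <- substr(ancestor$cds, dom_anc[1, "start"], dom_anc[1, "end"])
    d2 <- substr(ancestor$cds, dom_anc[nrow(dom_anc), "start"],
                 dom_anc[nrow(dom_anc), "end"])
    bp <- locate_crossover_breakpoint(chim, d1, d2)
    crossover <- list(valid = !bp$no_chimeric_signal && bp$support >= 1,
                      breakpoint = bp,
                      breakpoint_interval = bp$breakpoint_interval +
                        dom_mono[1, "start"] - 1L,
                      facilitating = bp$facilitating)
  }
  checks$fusion_crossover <- crossover

  # fewest-mutational-events ranking: a TE insertion visible in the
  # annotation, then one substitution, then one deletion, then one
  # recombination event
  mechanism <- if (checks$te_disruption$valid) "te_disruption"
  else if (nonsense$valid) "nonsense_point"
  else if (deletion$valid) "deletion_stop"
  else if (crossover$valid) "fusion_crossover"
  else "unresolved"
  evidence <- switch(mechanism,
    te_disruption = checks$te_disruption,
    nonsense_point = nonsense,
    deletion_stop = deletion,
    fusion_crossover = crossover,
    unresolved = list(valid = FALSE))
  structure(list(mechanism = mechanism, evidence = evidence, checks = checks,
                 mono_id = mono$id, ancestor_id = ancestor$id),
            class = "loss_call")
}

#' @export
print.loss_call <- function(x, ...) {
  cat(sprintf("loss call %s vs %s: %s\n", x$mono_id, x$ancestor_id,
              x$mechanism))
  invisible(x)
}
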