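NT <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

random_dna <- function(n) paste(sample(NT, n, replace = TRUE), collapse = "")

# reverse-translate a peptide, sampling uniformly among synonymous codons
rev_translate <- function(pep) {
  gc <- Biostrings::GENETIC_CODE
  by_aa <- split(names(gc), gc)
  ch <- strsplit(pep, "")[[1]]
  paste(vapply(ch, function(a) {
    cods <- by_aa[[a]]
    cods[sample.int(length(cods), 1L)]
  }, character(1)), collapse = "")
}

# random coding stretch of n_aa residues with no stop and, optionally, no C
random_cds_aa <- function(n_aa, no_cys = FALSE) {
  aa_pool <- setdiff(AA_CHARS, c("X", "*", if (no_cys) "C"))
  pep <- paste(sample(aa_pool, n_aa, replace = TRUE), collapse = "")
  list(pep = pep, cds = rev_translate(pep))
}

#' Default TE family catalogue of the simulator
#'
#' Superfamily weights follow the repeat landscape the analysis assumes:
#' class II DNA elements dominate, with the Tc1/Mariner superfamily alone
#' the largest fraction, followed by LINEs and Gypsy-type LTR
#' retroelements.
#'
#' @return Data frame `family`, `superfamily`, `te_class`, `weight`.
#' @export
default_te_catalogue <- function() {
  sf <- list(
    list(superfamily = "TcMar-Tc1", te_class = "II", weight = 31.5, n = 6,
         prefix = "Mar"),
    list(superfamily = "hAT", te_class = "II", weight = 11.1, n = 3,
         prefix = "hAT"),
    list(superfamily = "LINE-R2", te_class = "I", weight = 12.4, n = 3,
         prefix = "Line"),
    list(superfamily = "Gypsy", te_class = "I", weight = 7.0, n = 2,
         prefix = "Gyp"))
  do.call(rbind, lapply(sf, function(s) {
    data.frame(family = paste0(s$prefix, seq_len(s$n)),
               superfamily = s$superfamily, te_class = s$te_class,
               weight = s$weight / s$n)
  }))
}

#' Simulation configuration for synthetic toxin families
#'
#' Defaults encode the stated world the analysis assumes: a 3-exon
#' precursor gene (signal and propeptide in exons 1-2, separated from each
#' other by a phase 1 intron and from the mature-peptide exon by a phase 2
#' intron; the mature ICK peptide wholly in exon 3 with a short C-terminal
#' tail), moderate sequence divergence under a K2P substitution process
#' with purifying selection on the framework cysteines, an elevated
#' substitution rate in 3'UTRs, and a TE landscape dominated by class II
#' Tc1/Mariner elements with flank enrichment around toxin genes.
#'
#' @param seed RNG seed for [simulate_family()].
#' @param n_tips Number of tips when no tree is supplied.
#' @param tree Optional newick string.
#' @param tree_depth Expected substitutions/site from root to tip used to
#'   rescale generated trees.
#' @param kappa Transition:transversion rate ratio (default 2).
#' @param spacings Inter-cysteine gaps of the template domain.
#' @param tail_aa C-terminal tail length (residues).
#' @param exon_cds CDS lengths of exons 1 and 2 (chosen to give intron
#'   phases 1 and 2).
#' @param exon3_pre Propeptide bases completing the prepro region in
#'   exon 3.
#' @param intron_lengths,utr3_len,flank_len Non-coding segment lengths.
#' @param protect_cys Protect framework cysteine codons from substitution.
#' @param utr_rate_mult Rate multiplier for 3'UTR (released constraint).
#' @param events Scripted event list; each element is
#'   `list(node =, type = "duplication"|"loss", mechanism =)` where `node`
#'   is a tip label, internal node number, or `"root"`.
#' @param te TE landscape parameters (`bg_per_kb`, `enrichment`,
#'   `mean_len`, `sd_len`, `catalogue`).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1, n_tips = 8, tree = NULL, tree_depth = 0.05,
                       kappa = 2, spacings = c(3L, 6L, 2L, 6L), tail_aa = 4,
                       exon_cds = c(55L, 34L), exon3_pre = 4L,
                       intron_lengths = c(200L, 180L), utr3_len = 150L,
                       flank_len = 6000L, protect_cys = TRUE,
                       utr_rate_mult = 2, events = list(),
                       te = list()) {
  lo <- c(2L, 3L, 1L, 3L); hi <- c(7L, 10L, 4L, 13L)
  if (any(spacings < lo) || any(spacings > hi)) {
    stop("framework spacings outside the ICK ranges")
  }
  if (sum(exon_cds[1]) %% 3L != 1L || sum(exon_cds) %% 3L != 2L) {
    stop("exon CDS lengths must give intron phases 1 and 2")
  }
  if ((sum(exon_cds) + exon3_pre) %% 3L != 0L) {
    stop("prepropeptide length must be a whole number of codons")
  }
  te_def <- list(bg_per_kb = 0.5, enrichment = 3, mean_len = 225,
                 sd_len = 180, catalogue = default_te_catalogue())
  te <- utils::modifyList(te_def, te)
  structure(list(seed = seed, n_tips = n_tips, tree = tree,
                 tree_depth = tree_depth, kappa = kappa,
                 spacings = as.integer(spacings), tail_aa = tail_aa,
                 exon_cds = as.integer(exon_cds),
                 exon3_pre = as.integer(exon3_pre),
                 intron_lengths = as.integer(intron_lengths),
                 utr3_len = as.integer(utr3_len),
                 flank_len = as.integer(flank_len),
                 protect_cys = protect_cys, utr_rate_mult = utr_rate_mult,
                 events = events, te = te),
            class = "sim_config")
}

# K2P substitution process with optional protected sites; coding sequences
# never acquire an in-frame stop (purifying selection)
evolve_nt <- function(seq, t, kappa = 2, protected = integer(0),
                      coding = FALSE) {
  if (t <= 0 || !nzchar(seq)) return(seq)
  ch <- strsplit(seq, "")[[1]]
  L <- length(ch)
  n_ev <- rpois(1, L * t)
  if (n_ev == 0) return(seq)
  ts_map <- c(A = "G", G = "A", C = "T", T = "C")
  prot <- logical(L); prot[protected] <- TRUE
  for (k in seq_len(n_ev)) {
    pos <- sample.int(L, 1L)
    if (prot[pos]) next
    cur <- ch[pos]
    if (!cur %in% NT) next
    new <- if (runif(1) < kappa / (kappa + 2)) ts_map[[cur]] else
      sample(setdiff(NT, c(cur, ts_map[[cur]])), 1L)
    if (coding) {
      c0 <- pos - (pos - 1L) %% 3L
      if (c0 + 2L <= L) {
        cod <- ch[c0:(c0 + 2L)]
        cod[pos - c0 + 1L] <- new
        if (paste(cod, collapse = "") %in% STOP_CODONS) next
      }
    }
    ch[pos] <- new
  }
  paste(ch, collapse = "")
}

# positions to shield in a CDS: framework cysteine codons + terminal stop
protected_cds_positions <- function(cds, protect_cys = TRUE) {
  n <- nchar(cds)
  prot <- (n - 2L):n
  if (protect_cys) {
    pep <- translate_seq(cds, 1)
    arch <- partition_architecture(sub("\\*.*$", "", pep))
    if (arch$valency > 0) {
      cys_aa <- unlist(lapply(arch$domains, `[[`, "cys_positions"))
      prot <- c(prot, as.vector(vapply(cys_aa, function(a) {
        ((a - 1L) * 3L + 1L):(a * 3L)
      }, integer(3))))
    }
  }
  unique(prot)
}

# gene-state record: the evolving sequences of one precursor gene
new_state <- function(cds, utr3, intron1, intron2, flank5, flank3, config) {
  list(cds = cds, utr3 = utr3, intron1 = intron1, intron2 = intron2,
       flank5 = flank5, flank3 = flank3,
       exon_cds = config$exon_cds, exon3_pre = config$exon3_pre)
}

#' Generate the ancestral single-domain precursor gene
#'
#' Builds a monovalent precursor whose mature peptide matches the ICK
#' framework, embedded in a 3-exon gene with intron phases 1 and 2 and the
#' mature peptide encoded wholly by exon 3.
#'
#' @param config A [sim_config()].
#' @return A `toxin_precursor` with extra fields `gene` (feature data
#'   frame), `contig` and `state`.
#' @export
make_ancestor <- function(config = sim_config()) {
  sp <- config$spacings
  dom_pep <- paste0("C", rand_spacer(sp[1]), "C", rand_spacer(sp[2]), "CC",
                    rand_spacer(sp[3]), "C", rand_spacer(sp[4]), "C")
  tail_pep <- rand_spacer(config$tail_aa)
  prepro_len_aa <- (sum(config$exon_cds) + config$exon3_pre) / 3L
  prepro <- random_cds_aa(prepro_len_aa, no_cys = TRUE)
  # keep the prepropeptide start codon canonical
  prepro_cds <- paste0("ATG", substr(prepro$cds, 4L, nchar(prepro$cds)))
  mature_cds <- rev_translate(paste0(dom_pep, tail_pep))
  cds <- paste0(prepro_cds, mature_cds, "TAA")
  state <- new_state(cds, random_dna(config$utr3_len),
                     random_dna(config$intron_lengths[1]),
                     random_dna(config$intron_lengths[2]),
                     random_dna(config$flank_len),
                     random_dna(config$flank_len), config)
  assemble_precursor(state, "ancestor")
}

rand_spacer <- function(n) {
  if (n == 0) return("")
  pool <- setdiff(AA_CHARS, c("X", "*", "C"))
  paste(sample(pool, n, replace = TRUE), collapse = "")
}

# build contig + gene model + precursor object from a gene state
assemble_precursor <- function(state, id) {
  e1 <- substr(state$cds, 1L, state$exon_cds[1])
  e2 <- substr(state$cds, state$exon_cds[1] + 1L, sum(state$exon_cds))
  e3c <- substr(state$cds, sum(state$exon_cds) + 1L, nchar(state$cds))
  exon3 <- paste0(e3c, state$utr3)
  contig <- paste0(state$flank5, e1, state$intron1, e2, state$intron2,
                   exon3, state$flank3)
  o <- nchar(state$flank5)
  s1 <- o + 1L; e1e <- o + nchar(e1)
  s2 <- e1e + nchar(state$intron1) + 1L; e2e <- s2 + nchar(e2) - 1L
  s3 <- e2e + nchar(state$intron2) + 1L; e3e <- s3 + nchar(exon3) - 1L
  cds3e <- s3 + nchar(e3c) - 1L
  gene <- data.frame(
    seqid = id, type = c("gene", "mRNA", "exon", "exon", "exon",
                         "CDS", "CDS", "CDS"),
    start = c(s1, s1, s1, s2, s3, s1, s2, s3),
    end = c(e3e, e3e, e1e, e2e, e3e, e1e, e2e, cds3e),
    strand = "+",
    phase = c(NA, NA, NA, NA, NA, 0L, 2L, 1L))
  p <- toxin_precursor(id, state$cds, state$utr3)
  p$gene <- gene
  p$contig <- contig
  p$state <- state
  # mature-relative architecture (cleavage boundary is simulator truth)
  prepro_aa <- (sum(state$exon_cds) + state$exon3_pre) %/% 3L
  pep <- sub("\\*.*$", "", p$peptide)
  if (nchar(pep) > prepro_aa) {
    p$mature_peptide <- substr(pep, prepro_aa + 1L, nchar(pep))
    p$mature_arch <- partition_architecture(p$mature_peptide, id)
  } else {
    p$mature_peptide <- ""
    p$mature_arch <- NULL
  }
  p
}

# evolve a whole gene state along a branch of length t (subs/site)
evolve_state <- function(state, t, config) {
  prot <- protected_cds_positions(state$cds, config$protect_cys)
  state$cds <- evolve_nt(state$cds, t, config$kappa, prot, coding = TRUE)
  state$utr3 <- evolve_nt(state$utr3, t * config$utr_rate_mult, config$kappa)
  state$intron1 <- evolve_nt(state$intron1, t, config$kappa)
  state$intron2 <- evolve_nt(state$intron2, t, config$kappa)
  state$flank5 <- evolve_nt(state$flank5, t, config$kappa)
  state$flank3 <- evolve_nt(state$flank3, t, config$kappa)
  state
}

#' Tandem domain duplication within exon 3
#'
#' Duplicates the last domain-plus-tail coding unit of the mature peptide
#' in place, so the ancestral C-terminal tail becomes the new interdomain
#' linker and valency increases by one. No intron is introduced.
#'
#' @param prec A `toxin_precursor` produced by the simulator.
#' @return List `precursor` (the duplicated gene) and `event` (truth
#'   record with before/after sequences).
#' @export
apply_duplication <- function(prec) {
  state <- prec$state
  arch <- prec$architecture
  if (arch$valency < 1) stop("no domain to duplicate")
  last_dom <- arch$domains[[arch$valency]]
  dom_start_nt <- (last_dom$start - 1L) * 3L + 1L
  body_end <- nchar(state$cds) - 3L
  unit <- substr(state$cds, dom_start_nt, body_end)
  before <- list(cds = state$cds, utr3 = state$utr3)
  state$cds <- paste0(substr(state$cds, 1L, dom_start_nt - 1L), unit, unit,
                      substr(state$cds, body_end + 1L, nchar(state$cds)))
  newp <- assemble_precursor(state, prec$id)
  list(precursor = newp,
       event = list(type = "duplication", mechanism = NA_character_,
                    node = prec$id, unit_span = c(dom_start_nt, body_end),
                    before = before,
                    after = list(cds = state$cds, utr3 = state$utr3)))
}

#' Apply a scripted domain loss by a chosen mechanism
#'
#' Implements the four loss routes: `nonsense_point` substitutes one base
#' in the last interdomain linker to create an in-frame stop (the lost
#' domain survives as a 3'UTR remnant); `deletion_stop` removes 1-30 bp so
#' a downstream stop is re-framed; `fusion_crossover` recombines the first
#' and last domains at a breakpoint sampled inside their best local match;
#' `te_disruption` inserts a catalogue TE immediately before the last
#' domain, pseudogenizing it.
#'
#' @param prec A multivalent `toxin_precursor` from the simulator.
#' @param mechanism One of the four mechanisms.
#' @param config A [sim_config()] (TE catalogue, etc.).
#' @return List `precursor`, `event` (truth record) and, for TE losses,
#'   `te` (annotation row in transcript coordinates).
#' @export
apply_loss <- function(prec, mechanism = c("nonsense_point", "deletion_stop",
                                           "fusion_crossover",
                                           "te_disruption"),
                       config = sim_config()) {
  mechanism <- match.arg(mechanism)
  state <- prec$state
  arch <- prec$architecture
  if (arch$valency < 2) stop("precursor is not multivalent")
  v <- arch$valency
  dom_nt <- precursor_domain_nt(prec)
  linker_aa <- c(arch$domains[[v - 1]]$end + 1L, arch$domains[[v]]$start - 1L)
  linker_nt <- c((linker_aa[1] - 1L) * 3L + 1L, linker_aa[2] * 3L)
  before <- list(cds = state$cds, utr3 = state$utr3)
  te_row <- NULL
  detail <- list()

  if (mechanism == "nonsense_point") {
    # the stop may fall in the linker or early in the last domain; either
    # way the remainder of the domain survives as a 3'UTR remnant
    dom_aa <- c(arch$domains[[v]]$start, arch$domains[[v]]$end)
    last_ok <- dom_aa[1] + (dom_aa[2] - dom_aa[1]) %/% 3L
    cand <- list()
    for (aa in linker_aa[1]:last_ok) {
      c0 <- (aa - 1L) * 3L + 1L
      codon <- substr(state$cds, c0, c0 + 2L)
      for (stp in STOP_CODONS) {
        diff <- which(strsplit(codon, "")[[1]] != strsplit(stp, "")[[1]])
        if (length(diff) == 1L) {
          cand[[length(cand) + 1L]] <- list(c0 = c0, codon = codon,
                                            stop = stp, off = diff)
        }
      }
    }
    if (!length(cand)) stop("no stop creatable by one substitution in the linker")
    ch <- cand[[sample.int(length(cand), 1L)]]
    cds_ch <- strsplit(state$cds, "")[[1]]
    cds_ch[ch$c0 + ch$off - 1L] <- substr(ch$stop, ch$off, ch$off)
    full <- paste(cds_ch, collapse = "")
    new_cds <- substr(full, 1L, ch$c0 + 2L)
    state$utr3 <- paste0(substr(full, ch$c0 + 3L, nchar(full)), state$utr3)
    state$cds <- new_cds
    detail <- list(codon_from = ch$codon, codon_to = ch$stop,
                   stop_position_bp = ch$c0 + ch$off - 1L,
                   stop_interval = c(ch$c0, ch$c0 + 2L))
  } else if (mechanism == "deletion_stop") {
    found <- FALSE
    dom_end_nt <- dom_nt[v, "end"]
    tries <- expand.grid(start = linker_nt[1]:linker_nt[2], k = 1:30)
    tries <- tries[tries$k %% 3L != 0L, , drop = FALSE]
    tries <- tries[sample.int(nrow(tries)), , drop = FALSE]
    for (r in seq_len(nrow(tries))) {
      st <- tries$start[r]; k <- tries$k[r]
      if (st + k - 1L > nchar(state$cds) - 3L) next
      new_full <- paste0(substr(state$cds, 1L, st - 1L),
                         substr(state$cds, st + k, nchar(state$cds)))
      pep <- translate_seq(new_full, 1)
      stop_aa <- regexpr("*", pep, fixed = TRUE)
      if (stop_aa < 1) next
      stop_nt <- c((stop_aa - 1L) * 3L + 1L, stop_aa * 3L)
      # premature (before the reframed last domain would end) but after the
      # intact upstream domains
      if (stop_nt[2] >= dom_end_nt - k || stop_nt[2] <= dom_nt[v - 1, "end"]) next
      state$utr3 <- paste0(substr(new_full, stop_nt[2] + 1L, nchar(new_full)),
                           state$utr3)
      state$cds <- substr(new_full, 1L, stop_nt[2])
      detail <- list(deletion_interval = c(st, st + k - 1L),
                     deletion_length = k, stop_interval = stop_nt,
                     stop_codon = substr(new_full, stop_nt[1], stop_nt[2]))
      found <- TRUE
      break
    }
    if (!found) stop("no frameshifting deletion produced a usable stop")
  } else if (mechanism == "fusion_crossover") {
    d1 <- substr(state$cds, dom_nt[1, "start"], dom_nt[1, "end"])
    d2 <- substr(state$cds, dom_nt[v, "start"], dom_nt[v, "end"])
    lm <- best_local_match(d1, d2, min_length = 5)
    if (is.null(lm)) stop("no facilitating similarity between the domains")
    b <- sample(lm$a_start:lm$a_end, 1L)
    fused <- paste0(substr(d1, 1L, b), substr(d2, b + 1L, nchar(d2)))
    state$cds <- paste0(substr(state$cds, 1L, dom_nt[1, "start"] - 1L), fused,
                        substr(state$cds, dom_nt[v, "end"] + 1L,
                               nchar(state$cds)))
    detail <- list(breakpoint = b,
                   breakpoint_transcript = dom_nt[1, "start"] - 1L + b,
                   facilitating = lm[c("a_start", "a_end", "matches",
                                       "length", "identity")])
  } else { # te_disruption
    cat_df <- config$te$catalogue
    fam <- cat_df[sample.int(nrow(cat_df), 1L, prob = cat_df$weight), ]
    te_len <- max(50L, round(rnorm(1, config$te$mean_len, config$te$sd_len)))
    te_seq <- random_dna(te_len)
    ins <- dom_nt[v, "start"]
    full <- paste0(substr(state$cds, 1L, ins - 1L), te_seq,
                   substr(state$cds, ins, nchar(state$cds)), state$utr3)
    pep <- translate_seq(full, 1)
    stop_aa <- regexpr("*", pep, fixed = TRUE)
    stop_nt <- if (stop_aa > 0) stop_aa * 3L else nchar(full)
    state$cds <- substr(full, 1L, stop_nt)
    state$utr3 <- substr(full, stop_nt + 1L, nchar(full))
    te_row <- data.frame(contig = prec$id, start = ins,
                         end = ins + te_len - 1L, family = fam$family,
                         superfamily = fam$superfamily,
                         te_class = fam$te_class, divergence = 0)
    detail <- list(te_interval = c(ins, ins + te_len - 1L),
                   family = fam$family, superfamily = fam$superfamily)
  }
  newp <- assemble_precursor(state, prec$id)
  list(precursor = newp, te = te_row,
       event = c(list(type = "loss", mechanism = mechanism, node = prec$id,
                      before = before,
                      after = list(cds = state$cds, utr3 = state$utr3)),
                 detail))
}

#' Simulate a toxin gene family along a phylogeny
#'
#' Evolves the ancestral gene along a tree under the K2P process, applying
#' scripted duplication/loss events on the branches leading to the named
#' nodes, and scatters TE annotations over each tip contig with
#' class-II-dominated composition and configurable enrichment in the toxin
#' gene's flanks and introns. Same seed, same bundle, byte for byte.
#'
#' @param config A [sim_config()].
#' @return A `sim_family` list: `tree`, `precursors` (per tip),
#'   `tip_states` (valency), `te_annotations`, `truth_log`, `config`.
#' @export
simulate_family <- function(config = sim_config()) {
  set.seed(config$seed)
  tree <- if (!is.null(config$tree)) ape::read.tree(text = config$tree) else {
    tr <- ape::rtree(config$n_tips)
    tr$edge.length <- tr$edge.length * config$tree_depth /
      mean(ape::node.depth.edgelength(tr)[seq_len(config$n_tips)])
    tr
  }
  if (is.null(tree$edge.length)) {
    tree$edge.length <- rep(config$tree_depth, nrow(tree$edge))
  }
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  events <- config$events
  node_of <- function(ev) {
    if (identical(ev$node, "root")) return(root)
    if (is.character(ev$node)) return(match(ev$node, tree$tip.label))
    as.integer(ev$node)
  }
  log <- list()
  te_rows <- list()
  te_tx_rows <- list()  # TE insertions in transcript coordinates

  anc <- make_ancestor(config)
  log[[length(log) + 1L]] <- list(type = "ancestor", node = root,
                                  after = list(cds = anc$state$cds,
                                               utr3 = anc$state$utr3))
  # root-scripted events
  for (ev in events) {
    if (node_of(ev) == root) {
      res <- if (ev$type == "duplication") apply_duplication(anc) else
        apply_loss(anc, ev$mechanism, config)
      anc <- res$precursor
      res$event$node <- root
      log[[length(log) + 1L]] <- res$event
    }
  }
  states <- vector("list", max(tree$edge))
  states[[root]] <- anc$state
  edge_cw <- stats::reorder(tree, "cladewise")
  precursors <- list()
  for (e in seq_len(nrow(edge_cw$edge))) {
    p <- edge_cw$edge[e, 1]; ch <- edge_cw$edge[e, 2]
    t_len <- edge_cw$edge.length[e]
    id <- if (ch <= n_tip) tree$tip.label[ch] else paste0("node", ch)
    branch_events <- Filter(function(ev) node_of(ev) == ch, events)
    # some mechanisms are infeasible for a given realized sequence (e.g. no
    # linker codon one substitution away from a stop); resample the branch
    # substitutions until the scripted events apply
    for (try in 1:25) {
      st <- evolve_state(states[[p]], t_len, config)
      prec <- assemble_precursor(st, id)
      branch_rec <- list(type = "branch", node = ch, parent = p,
                         length = t_len,
                         after = list(cds = st$cds, utr3 = st$utr3))
      ev_log <- list()
      te_new <- list()
      ok <- TRUE
      for (ev in branch_events) {
        res <- tryCatch(
          if (ev$type == "duplication") apply_duplication(prec) else
            apply_loss(prec, ev$mechanism, config),
          error = function(e) NULL)
        if (is.null(res)) { ok <- FALSE; break }
        prec <- res$precursor
        res$event$node <- ch
        ev_log[[length(ev_log) + 1L]] <- res$event
        if (!is.null(res$te)) te_new[[length(te_new) + 1L]] <- res$te
      }
      if (ok) break
      if (try == 25) stop("scripted event(s) at node ", ch,
                          " remained infeasible after resampling")
    }
    log[[length(log) + 1L]] <- branch_rec
    for (r in ev_log) log[[length(log) + 1L]] <- r
    for (r in te_new) te_tx_rows[[length(te_tx_rows) + 1L]] <- r
    states[[ch]] <- prec$state
    if (ch <= n_tip) precursors[[id]] <- prec
  }
  # TE landscape per tip contig (annotations; enrichment around the gene)
  for (id in names(precursors)) {
    prec <- precursors[[id]]
    te_rows[[length(te_rows) + 1L]] <-
      scatter_tes(id, nchar(prec$contig),
                  gene_span = range(prec$gene$start, prec$gene$end),
                  config$te)
  }
  te_annotations <- do.call(rbind, te_rows)
  if (is.null(te_annotations)) te_annotations <- empty_te()
  tip_states <- vapply(precursors, `[[`, integer(1), "valency")
  structure(list(tree = tree,
                 precursors = precursors,
                 tip_states = tip_states[tree$tip.label],
                 te_annotations = as_te_annotation(te_annotations),
                 te_transcript = if (length(te_tx_rows))
                   as_te_annotation(do.call(rbind, te_tx_rows)) else empty_te(),
                 truth_log = log, config = config),
            class = "sim_family")
}

# Poisson TE placement with flank enrichment around one gene span
scatter_tes <- function(contig_id, contig_len, gene_span, te_cfg) {
  place <- function(n, lo, hi) {
    if (n == 0) return(NULL)
    starts <- sample(lo:hi, n, replace = TRUE)
    lens <- pmax(50L, round(rnorm(n, te_cfg$mean_len, te_cfg$sd_len)))
    fam <- te_cfg$catalogue[sample.int(nrow(te_cfg$catalogue), n,
                                       replace = TRUE,
                                       prob = te_cfg$catalogue$weight), ]
    data.frame(contig = contig_id, start = starts,
               end = pmin(starts + lens - 1L, contig_len),
               family = fam$family, superfamily = fam$superfamily,
               te_class = fam$te_class,
               divergence = round(runif(n, 0, 25), 1))
  }
  n_bg <- rpois(1, te_cfg$bg_per_kb * contig_len / 1000)
  out <- place(n_bg, 1L, contig_len)
  extra_rate <- (te_cfg$enrichment - 1) * te_cfg$bg_per_kb
  flank <- 5000L
  lo <- max(1L, gene_span[1] - flank); hi <- min(contig_len, gene_span[2] + flank)
  n_extra <- rpois(1, extra_rate * (hi - lo + 1L) / 1000)
  rbind(out, place(n_extra, lo, hi))
}

#' Verify a simulation truth log
#'
#' Checks that every event record's before-state matches the preceding
#' after-state on its lineage and that replaying the log reproduces every
#' tip transcript exactly.
#'
#' @param bundle A `sim_family`.
#' @return `TRUE` (invisibly); stops with a message on any mismatch.
#' @export
replay_truth_log <- function(bundle) {
  cur <- list()  # per-node (cds, utr3)
  for (rec in bundle$truth_log) {
    if (rec$type == "ancestor") {
      cur[[as.character(rec$node)]] <- rec$after
    } else if (rec$type == "branch") {
      cur[[as.character(rec$node)]] <- rec$after
    } else {
      key <- as.character(rec$node)
      prev <- cur[[key]]
      if (is.null(prev)) stop("truth log event precedes its branch state")
      if (!identical(prev$cds, rec$before$cds) ||
          !identical(prev$utr3, rec$before$utr3)) {
        stop("truth log mismatch before event at node ", node)
      }
      cur[[key]] <- rec$after
    }
  }
  for (id in names(bundle$precursors)) {
    key <- as.character(match(id, bundle$tree$tip.label))
    prec <- bundle$precursors[[id]]
    if (!identical(cur[[key]]$cds, prec$cds) ||
        !identical(cur[[key]]$utr3, prec$utr3)) {
      stop("replayed state does not reproduce tip ", id)
    }
  }
  invisible(TRUE)
}

#' Simulate a TE landscape over ICK and non-ICK gene sets
#'
#' Places each gene on its own contig, scatters background TE insertions
#' everywhere and enriches the flanks of the ICK genes by the configured
#' factor, for power/calibration studies of the flank-density permutation
#' test.
#'
#' @param n_ick,n_nonick Genes per group.
#' @param enrichment Flank insertion-rate multiplier for ICK genes
#'   (1 = null).
#' @param bg_per_kb Background insertions per kb.
#' @param flank_bp Flank size.
#' @param gene_len Gene length (bp).
#' @param te Optional overrides (`mean_len`, `sd_len`, `catalogue`).
#' @return List `genes` (with `is_ick`), `tes`, `contig_lengths`.
#' @export
simulate_te_landscape <- function(n_ick = 40, n_nonick = 40, enrichment = 3,
                                  bg_per_kb = 0.5, flank_bp = 5000,
                                  gene_len = 2000, te = list()) {
  te_cfg <- utils::modifyList(
    list(bg_per_kb = bg_per_kb, enrichment = enrichment, mean_len = 225,
         sd_len = 180, catalogue = default_te_catalogue()), te)
  contig_len <- gene_len + 2L * (flank_bp + 500L)
  n <- n_ick + n_nonick
  genes <- data.frame(gene_id = paste0(c(rep("ick", n_ick),
                                         rep("bg", n_nonick)),
                                       seq_len(n)),
                      contig = paste0("ctg", seq_len(n)),
                      start = flank_bp + 501L,
                      end = flank_bp + 500L + gene_len,
                      is_ick = rep(c(TRUE, FALSE), c(n_ick, n_nonick)))
  te_cfg_flat <- te_cfg
  rows <- lapply(seq_len(n), function(i) {
    te_cfg_i <- te_cfg_flat
    te_cfg_i$enrichment <- if (genes$is_ick[i]) te_cfg$enrichment else 1
    scatter_tes(genes$contig[i], contig_len,
                c(genes$start[i], genes$end[i]), te_cfg_i)
  })
  tes <- as_te_annotation(do.call(rbind, rows))
  list(genes = genes, tes = tes,
       contig_lengths = setNames(rep(contig_len, n), genes$contig))
}
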