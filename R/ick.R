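# Default inter-cysteine spacing ranges of the ICK framework
# C-X(2-7)-C-X(3-10)-C-C-X(1-4)-C-X(3-13)-C (gaps between the six framework
# cysteines; the third and fourth cysteines are adjacent).
ICK_SPACINGS <- list(c(2L, 7L), c(3L, 10L), c(1L, 4L), c(3L, 13L))

#' Scan a peptide for ICK cysteine frameworks
#'
#' Enumerates all placements of six cysteines compatible with the framework
#' spacing ranges (extra cysteines inside the X-spacers are allowed). By
#' default the non-overlapping set is chosen greedily left to right, with
#' the shortest total span winning among matches sharing a start; with
#' `all_matches = TRUE` every (start, spacing) combination is returned.
#'
#' @param peptide Peptide string.
#' @param all_matches Return every combination instead of the greedy set.
#' @param spacings List of 4 integer ranges for the inter-cysteine gaps.
#' @return List of `framework_match` records (`start`, `end`,
#'   `cys_positions`, `spacings`), possibly empty.
#' @export
scan_ick_frameworks <- function(peptide, all_matches = FALSE,
                                spacings = ICK_SPACINGS) {
  if (!nzchar(peptide)) stop("empty peptide")
  ch <- strsplit(peptide, "")[[1]]
  cys <- which(ch == "C")
  hits <- list()
  if (length(cys) >= 6) {
    s <- spacings
    for (c1 in cys) {
      c2s <- cys[cys >= c1 + s[[1]][1] + 1 & cys <= c1 + s[[1]][2] + 1]
      for (c2 in c2s) {
        c3s <- cys[cys >= c2 + s[[2]][1] + 1 & cys <= c2 + s[[2]][2] + 1]
        for (c3 in c3s) {
          c4 <- c3 + 1L
          if (!(c4 %in% cys)) next
          c5s <- cys[cys >= c4 + s[[3]][1] + 1 & cys <= c4 + s[[3]][2] + 1]
          for (c5 in c5s) {
            c6s <- cys[cys >= c5 + s[[4]][1] + 1 & cys <= c5 + s[[4]][2] + 1]
            for (c6 in c6s) {
              pos <- c(c1, c2, c3, c4, c5, c6)
              hits[[length(hits) + 1L]] <- structure(list(
                start = c1, end = c6, cys_positions = pos,
                spacings = diff(pos)[-3] - 1L
              ), class = "framework_match")
            }
          }
        }
      }
    }
  }
  if (all_matches || length(hits) == 0) return(hits)
  greedy_nonoverlap(hits)
}

# greedy leftmost selection; ties on start resolved by shortest span
greedy_nonoverlap <- function(hits) {
  st <- vapply(hits, `[[`, integer(1), "start")
  en <- vapply(hits, `[[`, integer(1), "end")
  ord <- order(st, en - st)
  sel <- list()
  last_end <- 0L
  for (i in ord) {
    if (st[i] > last_end) {
      sel[[length(sel) + 1L]] <- hits[[i]]
      last_end <- en[i]
    }
  }
  sel
}

#' Partition a mature peptide into domains, linkers and tail
#'
#' Valency is the number of non-overlapping framework matches. Each domain
#' spans its first to last framework cysteine; linker *i* is the residues
#' strictly between domain *i* and domain *i+1*; the leader precedes the
#' first domain and the tail follows the last. The pieces reconstruct the
#' mature peptide exactly.
#'
#' @param mature Mature peptide string.
#' @param id Optional precursor id carried through to reports.
#' @return A `domain_architecture` list: `precursor_id`, `valency`,
#'   `domains`, `leader`, `linkers`, `tail`, `mature`, `is_ick`.
#' @export
partition_architecture <- function(mature, id = NULL) {
  if (!nzchar(mature)) stop("empty mature peptide")
  dom <- scan_ick_frameworks(mature)
  v <- length(dom)
  if (v == 0) {
    return(structure(list(precursor_id = id, valency = 0L, domains = list(),
                          leader = mature, linkers = character(0), tail = "",
                          mature = mature, is_ick = FALSE),
                     class = "domain_architecture"))
  }
  st <- vapply(dom, `[[`, integer(1), "start")
  en <- vapply(dom, `[[`, integer(1), "end")
  leader <- substr(mature, 1L, st[1] - 1L)
  linkers <- if (v > 1) {
    vapply(seq_len(v - 1),
           function(i) substr(mature, en[i] + 1L, st[i + 1] - 1L), character(1))
  } else character(0)
  structure(list(
    precursor_id = id, valency = v, domains = dom, leader = leader,
    linkers = linkers, tail = substr(mature, en[v] + 1L, nchar(mature)),
    mature = mature, is_ick = TRUE
  ), class = "domain_architecture")
}

#' @export
print.domain_architecture <- function(x, ...) {
  cat(sprintf("domain architecture%s: valency %d%s\n",
              if (is.null(x$precursor_id)) "" else paste0(" [", x$precursor_id, "]"),
              x$valency, if (x$is_ick) "" else " (non-ICK)"))
  invisible(x)
}

# domain substrings of an architecture
architecture_domains <- function(arch) {
  vapply(arch$domains,
         function(d) substr(arch$mature, d$start, d$end), character(1))
}

#' Linker conservation across multivalent architectures
#'
#' Linkers are compared left-aligned and ungapped (no internal alignment):
#' position *j* is fully conserved when a single residue occupies it in
#' every linker of length >= *j*. Mean pairwise identity is computed over
#' ungapped shared prefixes.
#'
#' @param architectures List of `domain_architecture` objects (>= 2 must be
#'   multivalent).
#' @return List with a per-position `table` data frame (`position`,
#'   `residue`, `conserved`, `n`), `mean_pairwise_identity`, and the linker
#'   set used.
#' @export
linker_conservation <- function(architectures) {
  linkers <- unlist(lapply(architectures, function(a) {
    if (a$valency >= 2) a$linkers else character(0)
  }), use.names = FALSE)
  multiv <- sum(vapply(architectures, function(a) a$valency >= 2, logical(1)))
  if (multiv < 2) stop("need >= 2 multivalent architectures")
  maxlen <- max(nchar(linkers))
  tab <- do.call(rbind, lapply(seq_len(maxlen), function(j) {
    res <- substr(linkers[nchar(linkers) >= j], j, j)
    data.frame(position = j,
               residue = if (length(unique(res)) == 1) res[1] else NA_character_,
               conserved = length(unique(res)) == 1,
               n = length(res))
  }))
  pr <- utils::combn(length(linkers), 2)
  pid <- apply(pr, 2, function(ij) {
    L <- min(nchar(linkers[ij[1]]), nchar(linkers[ij[2]]))
    if (L == 0) return(NA_real_)
    ungapped_matches(substr(linkers[ij[1]], 1, L),
                     substr(linkers[ij[2]], 1, L)) / L
  })
  list(table = tab, mean_pairwise_identity = mean(pid, na.rm = TRUE),
       linkers = linkers)
}

#' Linker-versus-tail homology of a multivalent architecture
#'
#' In the intra-exon duplication model the interdomain linker descends from
#' the ancestral C-terminal tail, so residual linker/tail identity is the
#' signature of the exaptation (e.g. VPIS vs APIT). Compares the last
#' linker's prefix against the equally long suffix of the tail, ungapped,
#' over `min(nchar(linker), nchar(tail))` residues.
#'
#' @param arch A `domain_architecture` with valency >= 2 and non-empty tail.
#' @return An `identity_result`.
#' @export
linker_tail_homology <- function(arch) {
  if (arch$valency < 2) stop("architecture is not multivalent")
  linker <- arch$linkers[length(arch$linkers)]
  if (!nzchar(linker)) stop("empty linker")
  if (!nzchar(arch$tail)) stop("empty tail")
  L <- min(nchar(linker), nchar(arch$tail))
  a <- substr(linker, 1L, L)
  b <- substr(arch$tail, nchar(arch$tail) - L + 1L, nchar(arch$tail))
  pairwise_identity(a, b, "ungapped")
}

#' Read a GFF3 file into a gene-feature data frame
#'
#' Thin wrapper over `rtracklayer::import` returning the columns the
#' structure validator consumes (`seqid`, `type`, `start`, `end`,
#' `strand`, `phase`), 1-based inclusive.
#'
#' @param path Path to a GFF3 file.
#' @return Feature data frame.
#' @export
read_gff3 <- function(path) {
  g <- rtracklayer::import(path, format = "gff3")
  df <- data.frame(seqid = as.character(GenomicRanges::seqnames(g)),
                   type = as.character(g$type),
                   start = BiocGenerics::start(g),
                   end = BiocGenerics::end(g),
                   strand = as.character(BiocGenerics::strand(g)))
  df$phase <- if (!is.null(g$phase)) as.integer(g$phase) else NA_integer_
  df
}

#' Write a gene-feature data frame as GFF3
#'
#' @param gene Feature data frame (`seqid`, `type`, `start`, `end`,
#'   `strand`, optional `phase`).
#' @param path Output path.
#' @param source Source column value.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(gene, path, source = "knotarch") {
  phase <- if ("phase" %in% names(gene)) ifelse(is.na(gene$phase), ".",
                                                gene$phase) else "."
  lines <- sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t%s\tID=%s%d",
                   gene$seqid, source, gene$type, gene$start, gene$end,
                   gene$strand, phase, tolower(gene$type),
                   seq_len(nrow(gene)))
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Validate the conserved 3-exon toxin gene structure
#'
#' Checks the precursor gene model for the canonical knottin layout: three
#' exons; a phase 1 intron between the signal- and propeptide exons and a
#' phase 2 intron between the propeptide and mature-peptide exons (phase =
#' cumulative CDS length mod 3 at the junction); the mature peptide encoded
#' entirely by the last exon; and no intron between two domain-coding
#' segments (which would indicate exon shuffling rather than intra-exon
#' duplication).
#'
#' @param gene Data frame of features with columns `type` (must include
#'   `"CDS"` rows), `start`, `end`, `strand` (all on one contig, 1-based
#'   inclusive).
#' @param genome Contig sequence the coordinates refer to.
#' @param arch Optional `domain_architecture` of the mature peptide; when
#'   supplied, mature-peptide and interdomain verdicts are computed.
#' @return A `structure_report` list: `exon_count`, `intron_phases`,
#'   `mature_in_last_exon`, `interdomain_intron`, and `verdicts`.
#' @export
validate_gene_structure <- function(gene, genome, arch = NULL) {
  cds <- gene[gene$type == "CDS", , drop = FALSE]
  if (nrow(cds) == 0) stop("gene model has no CDS features")
  strand <- cds$strand[1]
  cds <- cds[order(cds$start, decreasing = identical(strand, "-")), , drop = FALSE]
  widths <- cds$end - cds$start + 1L
  if (sum(widths) %% 3L != 0L) {
    stop("CDS frame inconsistency: total CDS length ", sum(widths),
         " not a multiple of 3 (junction after position ",
         cds$end[1], ")")
  }
  phases <- cumsum(widths)[-length(widths)] %% 3L
  cds_seq <- paste(vapply(seq_len(nrow(cds)), function(i) {
    s <- substr(genome, cds$start[i], cds$end[i])
    if (identical(strand, "-")) revcomp(s) else s
  }, character(1)), collapse = "")
  pep <- translate_seq(cds_seq, 1)

  mature_in_last <- NA
  interdomain <- NA
  if (!is.null(arch)) {
    hit <- regexpr(arch$mature, pep, fixed = TRUE)
    if (hit == -1) stop("mature peptide not found in translated CDS")
    aa0 <- as.integer(hit)
    mat_nt <- c((aa0 - 1L) * 3L + 1L, (aa0 - 1L + nchar(arch$mature)) * 3L)
    # CDS-relative exon extents
    ends <- cumsum(widths)
    starts <- c(1L, head(ends, -1L) + 1L)
    last <- length(widths)
    mature_in_last <- mat_nt[1] >= starts[last] && mat_nt[2] <= ends[last]
    interdomain <- FALSE
    if (arch$valency >= 2 && length(ends) > 1) {
      dst <- vapply(arch$domains, `[[`, integer(1), "start")
      den <- vapply(arch$domains, `[[`, integer(1), "end")
      dom_nt_end <- mat_nt[1] - 1L + den * 3L
      dom_nt_start <- mat_nt[1] - 1L + (dst - 1L) * 3L + 1L
      for (j in seq_len(length(ends) - 1L)) {
        junction <- ends[j]  # intron after this CDS position
        for (i in seq_len(arch$valency - 1L)) {
          if (junction >= dom_nt_end[i] && junction < dom_nt_start[i + 1L]) {
            interdomain <- TRUE
          }
        }
      }
    }
  }
  verdicts <- c(
    exon_count = length(widths) == 3L,
    intron_phases = length(phases) == 2L && all(phases == c(1L, 2L)),
    mature_in_last_exon = isTRUE(mature_in_last),
    no_interdomain_intron = isFALSE(interdomain)
  )
  structure(list(exon_count = length(widths), intron_phases = phases,
                 mature_in_last_exon = mature_in_last,
                 interdomain_intron = interdomain, verdicts = verdicts),
            class = "structure_report")
}
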