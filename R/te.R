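# classify a RepeatMasker-style "class/family" string into TE class I/II
te_class_of <- function(class_family) {
  top <- toupper(sub("/.*$", "", class_family))
  ifelse(grepl("^DNA|^RC|^TIR", top), "II",
         ifelse(grepl("^LTR|^LINE|^SINE|^RETRO|^PLE", top), "I", "unknown"))
}

#' Read a RepeatMasker `.out` annotation file
#'
#' Tolerates the standard fixed-width dialect (3 header lines, whitespace-
#' separated fields). Families are compared at the level of the repeat
#' name; the class/family column supplies superfamily and class I/II.
#'
#' @param path Path to a RepeatMasker `.out` file.
#' @return TE annotation data frame: `contig`, `start`, `end`, `family`,
#'   `superfamily`, `te_class`, `divergence`.
#' @export
read_repeatmasker <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*$", lines)]
  lines <- lines[!grepl("^\\s*(SW|score|there were no)", lines)]
  if (!length(lines)) return(empty_te())
  f <- strsplit(trimws(lines), "\\s+")
  as_te_annotation(data.frame(
    contig = vapply(f, `[[`, character(1), 5),
    start = as.integer(vapply(f, `[[`, character(1), 6)),
    end = as.integer(vapply(f, `[[`, character(1), 7)),
    family = vapply(f, `[[`, character(1), 10),
    class_family = vapply(f, `[[`, character(1), 11),
    divergence = as.numeric(vapply(f, `[[`, character(1), 2))))
}

#' Read TE annotations from a BED file
#'
#' Expects BED4+ with the name field in RepeatMasker style
#' `family#class/superfamily` (e.g. `Mar1#DNA/TcMar-Tc1`) and the score
#' column carrying percent divergence to consensus. BED intervals are
#' 0-based half-open and are converted to 1-based inclusive.
#'
#' @param path Path to a BED file.
#' @return TE annotation data frame (see [read_repeatmasker()]).
#' @export
read_te_bed <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE, comment.char = "",
                   stringsAsFactors = FALSE)
  name <- if (ncol(df) >= 4) df[[4]] else "unknown#Unknown"
  as_te_annotation(data.frame(
    contig = df[[1]], start = df[[2]] + 1L, end = df[[3]],
    family = sub("#.*$", "", name),
    class_family = ifelse(grepl("#", name), sub("^.*#", "", name), "Unknown"),
    divergence = if (ncol(df) >= 5) as.numeric(df[[5]]) else NA_real_))
}

#' Normalise a data frame of TE intervals into the annotation schema
#'
#' @param df Data frame with `contig`, `start`, `end` and either a
#'   `class_family` string column or explicit `superfamily`/`te_class`.
#' @return TE annotation data frame.
#' @export
as_te_annotation <- function(df) {
  stopifnot(all(c("contig", "start", "end") %in% names(df)))
  if (any(df$start > df$end)) stop("TE interval with start > end")
  if (!"family" %in% names(df)) df$family <- "unknown"
  if ("class_family" %in% names(df)) {
    df$superfamily <- sub("^[^/]*/?", "", df$class_family)
    df$superfamily[!nzchar(df$superfamily)] <-
      df$class_family[!nzchar(df$superfamily)]
    df$te_class <- te_class_of(df$class_family)
    df$class_family <- NULL
  }
  if (!"superfamily" %in% names(df)) df$superfamily <- "Unknown"
  if (!"te_class" %in% names(df)) df$te_class <- "unknown"
  if (!"divergence" %in% names(df)) df$divergence <- NA_real_
  df[, c("contig", "start", "end", "family", "superfamily", "te_class",
         "divergence")]
}

empty_te <- function() {
  data.frame(contig = character(0), start = integer(0), end = integer(0),
             family = character(0), superfamily = character(0),
             te_class = character(0), divergence = numeric(0))
}

# union coverage (bp) of TE intervals clipped to a set of windows
covered_bp <- function(tes_contig, windows) {
  if (!nrow(tes_contig)) return(0L)
  red <- IRanges::reduce(IRanges::IRanges(tes_contig$start, tes_contig$end))
  sum(IRanges::width(IRanges::intersect(red, windows)))
}

#' Repeat-landscape histogram over the divergence column
#'
#' Bins TE annotations by percent divergence to their consensus and sums
#' the covered base pairs per bin — the summary behind repeat-landscape
#' plots. Annotation-level only; no landscape construction.
#'
#' @param tes TE annotation data frame.
#' @param bin_width Divergence bin width in percent.
#' @param by_class Split counts by TE class.
#' @return Data frame `bin_lo`, `bin_hi`, (`te_class`,) `n`, `bp`.
#' @export
te_divergence_landscape <- function(tes, bin_width = 1, by_class = FALSE) {
  tes <- tes[!is.na(tes$divergence), , drop = FALSE]
  b <- floor(tes$divergence / bin_width) * bin_width
  grp <- if (by_class) interaction(b, tes$te_class, drop = TRUE) else
    factor(b)
  agg <- do.call(rbind, lapply(split(seq_len(nrow(tes)), grp), function(i) {
    data.frame(bin_lo = min(b[i]), bin_hi = min(b[i]) + bin_width,
               te_class = if (by_class) tes$te_class[i[1]] else NA_character_,
               n = length(i), bp = sum(tes$end[i] - tes$start[i] + 1L))
  }))
  rownames(agg) <- NULL
  if (!by_class) agg$te_class <- NULL
  agg[order(agg$bin_lo), , drop = FALSE]
}

#' TE density in the flanking regions of genes
#'
#' For each gene the density is the union-merged TE coverage of the two
#' flanks (gene boundaries +/- `flank_bp`) divided by `2 * flank_bp`.
#' Genes without a full flank on both sides (contig too short) are excluded
#' and listed. Per-class densities use only TEs of that class.
#'
#' @param genes Data frame with `gene_id`, `contig`, `start`, `end`.
#' @param tes TE annotation data frame.
#' @param flank_bp Flank size in bp (default 5000).
#' @param contig_lengths Named vector of contig lengths (required to apply
#'   the right-flank exclusion rule).
#' @return List with `densities` (data frame: `gene_id`, `density`,
#'   `density_I`, `density_II`) and `excluded` (gene ids).
#' @export
flank_te_density <- function(genes, tes, flank_bp = 5000, contig_lengths) {
  if (flank_bp <= 0) stop("flank_bp must be positive")
  clen <- contig_lengths[genes$contig]
  ok <- genes$start - flank_bp >= 1 & genes$end + flank_bp <= clen
  ok[is.na(ok)] <- FALSE
  excluded <- genes$gene_id[!ok]
  kept <- genes[ok, , drop = FALSE]
  dens <- function(te_sub) {
    vapply(seq_len(nrow(kept)), function(i) {
      g <- kept[i, ]
      win <- IRanges::IRanges(c(g$start - flank_bp, g$end + 1L),
                              c(g$start - 1L, g$end + flank_bp))
      covered_bp(te_sub[te_sub$contig == g$contig, , drop = FALSE], win) /
        (2 * flank_bp)
    }, numeric(1))
  }
  densities <- data.frame(
    gene_id = kept$gene_id,
    density = dens(tes),
    density_I = dens(tes[tes$te_class == "I", , drop = FALSE]),
    density_II = dens(tes[tes$te_class == "II", , drop = FALSE]))
  list(densities = densities, excluded = excluded)
}

#' Permutation test for TE flank-density enrichment
#'
#' Tests whether ICK-gene flank densities differ from non-ICK flank
#' densities. Following the resampling design of comparing the ICK genes
#' with equally many randomly selected non-ICK genes, the null is built by
#' drawing equal-size subsets without replacement from the pooled
#' densities (the exact label-permutation null); the statistic is the
#' difference in group means and the two-sided empirical p-value carries
#' the +1 correction, so it is never zero.
#'
#' @param ick_densities,nonick_densities Numeric density vectors.
#' @param reps Number of resamplings (default 1000).
#' @param seed Optional RNG seed; recorded in the result.
#' @return A `flank_density_result` list: group means, `observed`
#'   difference, `p`, `reps`, `seed`, `perm` (null statistics).
#' @export
permutation_flank_test <- function(ick_densities, nonick_densities,
                                   reps = 1000, seed = NULL) {
  if (!length(ick_densities) || !length(nonick_densities)) {
    stop("both groups must be non-empty")
  }
  if (reps < 1) stop("reps must be >= 1")
  if (length(nonick_densities) < length(ick_densities)) {
    stop("non-ICK pool smaller than the ICK set")
  }
  if (!is.null(seed)) set.seed(seed)
  n1 <- length(ick_densities)
  pool <- c(ick_densities, nonick_densities)
  obs <- mean(ick_densities) - mean(nonick_densities)
  perm <- vapply(seq_len(reps), function(r) {
    idx <- sample.int(length(pool), n1)
    mean(pool[idx]) - mean(pool[-idx])
  }, numeric(1))
  p <- (1 + sum(abs(perm) >= abs(obs))) / (reps + 1)
  structure(list(mean_ick = mean(ick_densities),
                 mean_nonick = mean(nonick_densities),
                 observed = obs, p = p, reps = reps, seed = seed,
                 perm = perm),
            class = "flank_density_result")
}

#' @export
print.flank_density_result <- function(x, ...) {
  cat(sprintf("flank TE density: ICK %.4f vs non-ICK %.4f (diff %+.4f), p = %.4g (%d reps)\n",
              x$mean_ick, x$mean_nonick, x$observed, x$p, x$reps))
  invisible(x)
}

#' Windowed TE-density track over a gene region
#'
#' Tiles the region (gene span extended by `flank_bp` on both sides,
#' clipped to the contig) into non-overlapping windows of `window_bp` and
#' reports the TE-covered fraction per window, together with the mean TE
#' density of the whole contig as the comparison baseline.
#'
#' @param contig Contig name.
#' @param start,end 1-based gene span on the contig.
#' @param tes TE annotation data frame.
#' @param window_bp Window size (default 100).
#' @param flank_bp Flank extension (default 5000).
#' @param contig_length Contig length (for clipping and the baseline).
#' @param te_class Optional class filter (`"I"` or `"II"`).
#' @return List with `windows` (data frame: `start`, `end`, `covered`,
#'   `density`), `contig_mean`, `region`.
#' @export
window_density_track <- function(contig, start, end, tes, window_bp = 100,
                                 flank_bp = 5000, contig_length,
                                 te_class = NULL) {
  sub <- tes[tes$contig == contig, , drop = FALSE]
  if (!is.null(te_class)) sub <- sub[sub$te_class == te_class, , drop = FALSE]
  r0 <- max(1L, start - flank_bp)
  r1 <- min(contig_length, end + flank_bp)
  starts <- seq(r0, r1, by = window_bp)
  ends <- pmin(starts + window_bp - 1L, r1)
  red <- if (nrow(sub)) IRanges::reduce(IRanges::IRanges(sub$start, sub$end))
         else IRanges::IRanges()
  win <- IRanges::IRanges(starts, ends)
  ov <- IRanges::findOverlaps(win, red)
  covered <- integer(length(win))
  if (length(ov)) {
    inter_w <- pmin(ends[S4Vectors::queryHits(ov)],
                    IRanges::end(red)[S4Vectors::subjectHits(ov)]) -
      pmax(starts[S4Vectors::queryHits(ov)],
           IRanges::start(red)[S4Vectors::subjectHits(ov)]) + 1L
    agg <- tapply(inter_w, S4Vectors::queryHits(ov), sum)
    covered[as.integer(names(agg))] <- as.integer(agg)
  }
  contig_mean <- covered_bp(sub, IRanges::IRanges(1L, contig_length)) /
    contig_length
  list(windows = data.frame(start = starts, end = ends, covered = covered,
                            density = covered / (ends - starts + 1L)),
       contig_mean = contig_mean, region = c(r0, r1))
}

#' Shared TE families between two gene regions
#'
#' Compares the distinct TE family sets overlapping two gene regions (gene
#' span plus flank), as in synteny comparisons of paralog neighbourhoods.
#'
#' @param regionA,regionB Lists with `contig`, `start`, `end`.
#' @param tes TE annotation data frame.
#' @return List `shared_count`, `total_a`, `total_b`, `shared_families`.
#' @export
shared_te_families <- function(regionA, regionB, tes) {
  fams <- function(r) {
    sub <- tes[tes$contig == r$contig & tes$end >= r$start &
                 tes$start <= r$end, , drop = FALSE]
    unique(sub$family)
  }
  fa <- fams(regionA); fb <- fams(regionB)
  shared <- intersect(fa, fb)
  list(shared_count = length(shared), total_a = length(fa),
       total_b = length(fb), shared_families = shared)
}

#' Pairwise-exclusive TE family sharing among several gene regions
#'
#' For every pair of regions, reports the TE families shared by exactly
#' that pair and by no other region (the "shared between at least 2 genes
#' but not all" filter used when comparing paralog neighbourhoods).
#'
#' @param regions Named list of regions (`contig`, `start`, `end`).
#' @param tes TE annotation data frame.
#' @return Data frame `region_a`, `region_b`, `shared_exclusive`, `families`.
#' @export
te_family_sharing <- function(regions, tes) {
  fam_sets <- lapply(regions, function(r) {
    sub <- tes[tes$contig == r$contig & tes$end >= r$start &
                 tes$start <= r$end, , drop = FALSE]
    unique(sub$family)
  })
  nm <- names(regions)
  pairs <- utils::combn(length(regions), 2)
  do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    others <- unlist(fam_sets[-c(i, j)], use.names = FALSE)
    excl <- setdiff(intersect(fam_sets[[i]], fam_sets[[j]]), others)
    data.frame(region_a = nm[i], region_b = nm[j],
               shared_exclusive = length(excl),
               families = paste(excl, collapse = ","))
  }))
}
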