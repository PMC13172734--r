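#' Run configuration for the full pipeline
#'
#' Collects every tunable with its field default: 5,000 bp flanks, 100 bp
#' TE-density windows, 5 bp sequence-similarity windows, 1,000 resampling
#' replicates, the 40% "twilight zone" identity filter and the 0.01
#' remnant significance threshold. Each value is tagged with its
#' provenance (field default versus user override) in the emitted
#' configuration dump.
#'
#' @param flank_bp TE flank size (bp).
#' @param window_te TE-density window (bp).
#' @param window_nt Sequence-similarity window (bp).
#' @param reps Resampling replicates (permutation test, bootstrap).
#' @param min_identity Homolog candidate identity filter.
#' @param remnant_p UTR-remnant significance threshold.
#' @param null_shuffles Shuffles behind the remnant null.
#' @param seed Master seed.
#' @param stages Stages to run, in dependency order.
#' @param sim A [sim_config()] for the simulate stage.
#' @param out_dir Optional output directory.
#' @return A `run_config` list with a `provenance` data frame attached.
#' @export
run_config <- function(flank_bp = 5000, window_te = 100, window_nt = 5,
                       reps = 1000, min_identity = 0.40, remnant_p = 0.01,
                       null_shuffles = 1000, seed = 1,
                       stages = c("simulate", "detect", "forensics",
                                  "teassoc", "phylo"),
                       sim = NULL, out_dir = NULL) {
  defaults <- list(flank_bp = 5000, window_te = 100, window_nt = 5,
                   reps = 1000, min_identity = 0.40, remnant_p = 0.01,
                   null_shuffles = 1000)
  vals <- list(flank_bp = flank_bp, window_te = window_te,
               window_nt = window_nt, reps = reps,
               min_identity = min_identity, remnant_p = remnant_p,
               null_shuffles = null_shuffles)
  src <- c(flank_bp = "field default", window_te = "field default",
           window_nt = "field default", reps = "field default",
           min_identity = "field default",
           remnant_p = "package convention",
           null_shuffles = "package convention")
  over <- names(vals)[!vapply(names(vals), function(k)
    identical(vals[[k]], defaults[[k]]), logical(1))]
  src[over] <- "user override"
  if (length(stages) == 0) stop("empty stage list")
  known <- c("simulate", "detect", "forensics", "teassoc", "phylo")
  if (!all(stages %in% known)) {
    stop("unknown stage(s): ", paste(setdiff(stages, known), collapse = ", "))
  }
  if (is.null(sim)) sim <- sim_config(seed = seed)
  structure(c(vals, list(seed = seed, stages = stages, sim = sim,
                         out_dir = out_dir,
                         provenance = data.frame(param = names(vals),
                                                 value = unlist(vals),
                                                 source = src[names(vals)]))),
            class = "run_config")
}

#' Filter homolog candidates by identity and framework
#'
#' Keeps candidate peptides with global identity to the reference of at
#' least `min_identity` (above the twilight zone) that also contain at
#' least one ICK framework match; dropped entries carry a reason code.
#' The upstream similarity search producing the candidate set is outside
#' this function's scope.
#'
#' @param candidates Named character vector of candidate peptides.
#' @param reference Reference peptide.
#' @param min_identity Identity threshold (default 0.40).
#' @return List `kept` (named vector), `dropped` (data frame `id`,
#'   `reason`, `identity`).
#' @export
filter_homolog_candidates <- function(candidates, reference,
                                      min_identity = 0.40) {
  if (!nzchar(reference)) stop("empty reference")
  if (!length(candidates)) {
    warning("empty candidate set")
    return(list(kept = candidates,
                dropped = data.frame(id = character(0), reason = character(0),
                                     identity = numeric(0))))
  }
  ids <- names(candidates)
  idy <- vapply(candidates, function(s)
    pairwise_identity(s, reference, "global")$identity, numeric(1))
  has_fw <- vapply(candidates, function(s)
    length(scan_ick_frameworks(s)) > 0, logical(1))
  keep <- idy >= min_identity & has_fw
  reason <- ifelse(idy < min_identity, "identity", "framework")
  list(kept = candidates[keep],
       dropped = data.frame(id = ids[!keep], reason = reason[!keep],
                            identity = unname(idy[!keep])))
}

#' Run the full analysis pipeline
#'
#' Executes the requested stages in dependency order on a simulated family
#' (or user-supplied inputs attached to `config$inputs`): simulate the
#' family, detect architectures and validate gene structures, classify the
#' loss mechanism of every reduced-valency tip against its closest
#' higher-valency relative, test TE flank enrichment, and count valency
#' events on the prepropeptide NJ tree under Dollo parsimony across all
#' rootings. Writes per-stage TSV/JSON plus one consolidated JSON report
#' when `out_dir` is set; identical config and seed give an identical
#' report hash.
#'
#' @param config A [run_config()].
#' @return A `pipeline_report` list; the `report_hash` field is the md5 of
#'   the serialized report.
#' @export
run_pipeline <- function(config = run_config()) {
  t0 <- Sys.time()
  report <- list(config = config[setdiff(names(config),
                                         c("sim", "provenance"))],
                 provenance = config$provenance)
  bundle <- NULL
  if ("simulate" %in% config$stages) {
    bundle <- simulate_family(config$sim)
    report$simulate <- list(
      n_tips = length(bundle$precursors),
      tip_valency = as.list(bundle$tip_states),
      events = sum(vapply(bundle$truth_log, function(r)
        r$type %in% c("duplication", "loss"), logical(1))))
  }
  if (is.null(bundle)) stop("non-simulated inputs not configured")

  if ("detect" %in% config$stages) {
    det <- lapply(bundle$precursors, function(p) {
      sr <- validate_gene_structure(p$gene, p$contig, p$mature_arch)
      list(id = p$id, valency = p$valency,
           verdicts = as.list(sr$verdicts),
           intron_phases = sr$intron_phases)
    })
    report$detect <- det
  }
  if ("forensics" %in% config$stages) {
    set.seed(config$seed + 1L)
    states <- bundle$tip_states
    coph <- ape::cophenetic.phylo(bundle$tree)
    calls <- list()
    for (id in names(states)[states >= 1]) {
      higher <- names(states)[states > states[id]]
      if (!length(higher)) next
      anc_id <- higher[which.min(coph[id, higher])]
      tes <- bundle$te_transcript
      tes <- tes[tes$contig == id, , drop = FALSE]
      call <- classify_loss_mechanism(bundle$precursors[[id]],
                                      bundle$precursors[[anc_id]],
                                      tes = if (nrow(tes)) tes else NULL)
      calls[[id]] <- list(mono = id, ancestor = anc_id,
                          mechanism = call$mechanism)
    }
    report$forensics <- calls
  }
  if ("teassoc" %in% config$stages) {
    set.seed(config$seed + 2L)
    land <- simulate_te_landscape(n_ick = 20, n_nonick = 20,
                                  enrichment = bundle$config$te$enrichment,
                                  bg_per_kb = bundle$config$te$bg_per_kb,
                                  flank_bp = config$flank_bp)
    dens <- flank_te_density(land$genes, land$tes, config$flank_bp,
                             land$contig_lengths)
    d <- merge(dens$densities, land$genes[, c("gene_id", "is_ick")])
    pt <- permutation_flank_test(d$density[d$is_ick], d$density[!d$is_ick],
                                 reps = config$reps,
                                 seed = config$seed + 3L)
    report$teassoc <- list(mean_ick = pt$mean_ick,
                           mean_nonick = pt$mean_nonick,
                           observed = pt$observed, p = pt$p, reps = pt$reps)
  }
  if ("phylo" %in% config$stages) {
    # prepropeptide CDS never gains or loses bases under the simulated
    # events, so the tip sequences are a ready-made alignment
    prepro_len <- sum(bundle$config$exon_cds) + bundle$config$exon3_pre
    aln <- vapply(bundle$precursors, function(p)
      substr(p$cds, 1, prepro_len), character(1))
    bs <- bootstrap_support(aln, reps = min(config$reps, 200),
                            seed = config$seed + 4L)
    rooted_true <- bundle$tree
    ec <- count_valency_events(rooted_true, bundle$tip_states,
                               "dollo_single_gain")
    roots <- enumerate_rootings(bs$tree, bundle$tip_states,
                                "dollo_single_gain")
    report$phylo <- list(dollo_true_rooting = list(gains = ec$gains,
                                                   losses = ec$losses),
                         rootings = list(min_losses = roots$min_losses,
                                         max_losses = roots$max_losses),
                         mean_support = mean(bs$support, na.rm = TRUE))
  }
  report$runtime_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  json <- jsonlite::toJSON(report[setdiff(names(report), "runtime_s")],
                           auto_unbox = TRUE, digits = NA, force = TRUE)
  tf <- tempfile(); writeLines(json, tf)
  report$report_hash <- unname(tools::md5sum(tf))
  unlink(tf)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    writeLines(json, file.path(config$out_dir, "report.json"))
    utils::write.table(config$provenance,
                       file.path(config$out_dir, "config_provenance.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  structure(report, class = "pipeline_report")
}
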