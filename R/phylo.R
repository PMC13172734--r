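#' Pairwise distance matrix from an alignment
#'
#' p-distance (mismatch fraction over comparable, non-gap column pairs) or
#' Kimura 2-parameter distance, with pairwise deletion of gap columns.
#' Saturated pairs (undefined K2P logarithm) raise an error naming the
#' pair.
#'
#' @param aln Named character vector of aligned nucleotide sequences.
#' @param model `"p_distance"` or `"K2P"`.
#' @return A `distance_matrix` list: `taxa`, `d` (symmetric matrix),
#'   `model`.
#' @export
distance_matrix <- function(aln, model = c("p_distance", "K2P")) {
  model <- match.arg(model)
  if (length(aln) < 3) stop("need >= 3 taxa")
  if (length(unique(nchar(aln))) != 1) stop("alignment is ragged")
  bin <- ape::as.DNAbin(do.call(rbind, strsplit(tolower(aln), "")))
  rownames(bin) <- names(aln)
  d <- as.matrix(ape::dist.dna(bin,
                               model = if (model == "K2P") "K80" else "raw",
                               pairwise.deletion = TRUE))
  if (any(!is.finite(d))) {
    bad <- which(!is.finite(d), arr.ind = TRUE)[1, ]
    stop("saturated/incomparable pair: ", rownames(d)[bad[1]], " vs ",
         colnames(d)[bad[2]])
  }
  structure(list(taxa = names(aln), d = d, model = model),
            class = "distance_matrix")
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor joining; taxa are sorted lexicographically first so
#' the result is independent of input order.
#'
#' @param dm A `distance_matrix` or a plain symmetric matrix with
#'   dimnames.
#' @return Unrooted `phylo` tree.
#' @export
nj_tree <- function(dm) {
  d <- if (inherits(dm, "distance_matrix")) dm$d else as.matrix(dm)
  if (nrow(d) < 3) stop("need >= 3 taxa")
  ord <- order(rownames(d))
  ape::nj(d[ord, ord])
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Classical nonparametric bootstrap: alignment columns are resampled with
#' replacement, the NJ tree is rebuilt per replicate, and each internal
#' edge of the point-estimate tree receives the percentage of replicates
#' containing its bipartition.
#'
#' @param aln Named character vector of aligned sequences.
#' @param reps Bootstrap replicates (>= 1).
#' @param seed Optional RNG seed.
#' @param model Distance model passed to [distance_matrix()].
#' @return List `tree` (point-estimate `phylo` with support as node
#'   labels) and `support` (percent per internal node).
#' @export
bootstrap_support <- function(aln, reps = 1000, seed = NULL,
                              model = "p_distance") {
  if (reps < 1) stop("reps must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  ref <- nj_tree(distance_matrix(aln, model))
  ncol_a <- nchar(aln[[1]])
  mat <- do.call(rbind, strsplit(aln, ""))
  boot <- lapply(seq_len(reps), function(r) {
    cols <- sample.int(ncol_a, ncol_a, replace = TRUE)
    res <- apply(mat[, cols, drop = FALSE], 1, paste, collapse = "")
    nj_tree(distance_matrix(setNames(res, names(aln)), model))
  })
  counts <- ape::prop.clades(ref, boot, rooted = FALSE)
  counts[is.na(counts)] <- 0
  support <- round(100 * counts / reps, 1)
  ref$node.label <- as.character(support)
  list(tree = ref, support = support)
}

# tip labels on the child side of each internal edge of an unrooted tree
tree_bipartitions <- function(tree) {
  n_tip <- length(tree$tip.label)
  internal_edges <- which(tree$edge[, 2] > n_tip)
  lapply(internal_edges, function(e) {
    node <- tree$edge[e, 2]
    tree$tip.label[unlist(phangorn_free_descendants(tree, node))]
  })
}

# tip indices below `node` (simple stack walk; avoids extra deps)
phangorn_free_descendants <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    v <- stack[[1]]; stack <- stack[-1]
    if (v <= n_tip) out <- c(out, v)
    else stack <- c(stack, tree$edge[tree$edge[, 1] == v, 2])
  }
  out
}

#' Test N-/C-domain clade separation on a domain tree
#'
#' Reports whether some edge of the unrooted tree bipartitions the
#' C-terminal domains from everything else (N-terminal domains plus
#' single-domain toxins) -- the signature of a single ancient domain
#' duplication -- together with the supporting edge's bootstrap value and
#' rooted monophyly of each label set.
#'
#' @param tree `phylo` tree (node labels, when present, are read as
#'   bootstrap support).
#' @param labels Named vector over tips with values `"N"`, `"C"`,
#'   `"single"`.
#' @return List `separation` (logical), `support` (of the separating
#'   edge, if labelled), `monophyly` (per label, on the tree as given).
#' @export
domain_clade_separation <- function(tree, labels) {
  if (!all(tree$tip.label %in% names(labels))) {
    missing <- setdiff(tree$tip.label, names(labels))
    stop("missing label for tip(s): ", paste(missing, collapse = ", "))
  }
  labels <- labels[tree$tip.label]
  c_tips <- sort(tree$tip.label[labels == "C"])
  all_tips <- tree$tip.label
  sep <- FALSE; support <- NA_real_
  n_tip <- length(all_tips)
  internal <- which(tree$edge[, 2] > n_tip)
  for (e in internal) {
    node <- tree$edge[e, 2]
    side <- sort(all_tips[phangorn_free_descendants(tree, node)])
    other <- sort(setdiff(all_tips, side))
    if (identical(side, c_tips) || identical(other, c_tips)) {
      sep <- TRUE
      if (!is.null(tree$node.label)) {
        support <- suppressWarnings(
          as.numeric(tree$node.label[node - n_tip]))
      }
      break
    }
  }
  mono <- vapply(unique(labels), function(l) {
    tips <- names(labels)[labels == l]
    length(tips) <= 1 || ape::is.monophyletic(tree, tips)
  }, logical(1))
  list(separation = sep, support = support, monophyly = mono)
}

#' Count valency gain/loss events on a rooted tree
#'
#' Tip states are collapsed to binary (multivalent, valency >= 2, versus
#' monovalent). `dollo_single_gain` places one gain on the edge above the
#' most recent common ancestor of all multivalent tips and counts the
#' minimum number of losses below it; `fitch` returns the unconstrained
#' minimum-change count (unit-cost Sankoff, so multifurcations are
#' handled).
#'
#' @param tree Rooted `phylo` tree.
#' @param tip_states Named vector of valency counts (or 0/1 states).
#' @param model `"dollo_single_gain"` or `"fitch"`.
#' @return An `event_count` list: `gains`, `losses`, `changes`, `events`
#'   (per-edge assignments), `model`.
#' @export
count_valency_events <- function(tree, tip_states,
                                 model = c("dollo_single_gain", "fitch")) {
  if (inherits(tree, "valency_tree")) {
    if (missing(tip_states)) tip_states <- tree$tip_states
    tree <- tree$tree
  }
  model <- match.arg(model)
  if (!all(tree$tip.label %in% names(tip_states))) {
    stop("states missing for tip(s): ",
         paste(setdiff(tree$tip.label, names(tip_states)), collapse = ", "))
  }
  states <- as.integer(tip_states[tree$tip.label] >= 2)
  names(states) <- tree$tip.label
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L

  if (model == "fitch") {
    # unit-cost Sankoff over binary states
    n_node <- max(tree$edge)
    cost <- matrix(Inf, n_node, 2)
    cost[cbind(seq_len(n_tip), states + 1L)] <- 0
    children <- split(tree$edge[, 2], tree$edge[, 1])
    # process nodes children-first (postorder over edges lists every
    # parent only after all its descendant edges)
    post_nodes <- unique(tree$edge[ape::postorder(tree), 1])
    for (v in post_nodes) {
      for (s in 1:2) {
        cost[v, s] <- sum(vapply(children[[as.character(v)]], function(ch) {
          min(cost[ch, s], cost[ch, 3 - s] + 1)
        }, numeric(1)))
      }
    }
    changes <- min(cost[root, ])
    # traceback for per-edge assignment
    assign_state <- integer(n_node)
    assign_state[root] <- which.min(cost[root, ])
    events <- data.frame(parent = integer(0), child = integer(0),
                         event = character(0))
    edge_cw <- stats::reorder(tree, "cladewise")$edge  # parents first
    for (e in seq_len(nrow(edge_cw))) {
      p <- edge_cw[e, 1]; ch <- edge_cw[e, 2]
      s <- assign_state[p]
      keep <- cost[ch, s]
      flip <- cost[ch, 3 - s] + 1
      assign_state[ch] <- if (keep <= flip) s else 3 - s
      if (assign_state[ch] != s) {
        events <- rbind(events, data.frame(
          parent = p, child = ch,
          event = if (s == 1) "gain" else "loss"))
      }
    }
    return(structure(list(gains = sum(events$event == "gain"),
                          losses = sum(events$event == "loss"),
                          changes = changes, events = events,
                          model = model),
                     class = "event_count"))
  }

  # Dollo with a single gain
  multi_tips <- which(states == 1L)
  if (!length(multi_tips)) {
    return(structure(list(gains = 0L, losses = 0L, changes = 0L,
                          events = data.frame(parent = integer(0),
                                              child = integer(0),
                                              event = character(0)),
                          model = model),
                     class = "event_count"))
  }
  mrca <- if (length(multi_tips) == 1) multi_tips else
    ape::getMRCA(tree, multi_tips)
  # all-monovalent status per node
  n_node <- max(tree$edge)
  all0 <- logical(n_node)
  all0[seq_len(n_tip)] <- states == 0L
  post_nodes <- unique(tree$edge[ape::postorder(tree), 1])
  children <- split(tree$edge[, 2], tree$edge[, 1])
  for (v in post_nodes) {
    all0[v] <- all(all0[children[[as.character(v)]]])
  }
  clade <- phangorn_free_descendants_all(tree, mrca)
  events <- data.frame(parent = NA_integer_, child = mrca, event = "gain")
  for (v in clade) {
    if (v == mrca) next
    p <- tree$edge[tree$edge[, 2] == v, 1]
    if (all0[v] && !all0[p]) {
      events <- rbind(events, data.frame(parent = p, child = v,
                                         event = "loss"))
    }
  }
  structure(list(gains = 1L, losses = sum(events$event == "loss"),
                 changes = 1L + sum(events$event == "loss"),
                 events = events, model = model),
            class = "event_count")
}

# all nodes (tips + internal) in the clade rooted at `node`
phangorn_free_descendants_all <- function(tree, node) {
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    v <- stack[[1]]; stack <- stack[-1]
    out <- c(out, v)
    stack <- c(stack, tree$edge[tree$edge[, 1] == v, 2])
  }
  out
}

#' @export
print.event_count <- function(x, ...) {
  cat(sprintf("%s: %d gain(s), %d loss(es)\n", x$model, x$gains, x$losses))
  invisible(x)
}

#' Count valency events under every candidate rooting
#'
#' Roots the unrooted tree on each edge in turn, counts events under the
#' requested model, and summarises the range of loss counts across
#' rootings (the "either 3 or 4 losses depending on the rooting" style of
#' robustness check).
#'
#' @param tree Unrooted `phylo` tree.
#' @param tip_states Named valency states.
#' @param model Event model (see [count_valency_events()]).
#' @return List `per_rooting` (data frame: `edge`, `gains`, `losses`),
#'   `min_losses`, `max_losses`.
#' @export
enumerate_rootings <- function(tree, tip_states,
                               model = "dollo_single_gain") {
  utree <- ape::unroot(tree)
  n_tip <- length(utree$tip.label)
  res <- lapply(seq_len(nrow(utree$edge)), function(e) {
    child <- utree$edge[e, 2]
    side <- utree$tip.label[phangorn_free_descendants(utree, child)]
    if (length(side) == 0 || length(side) == n_tip) return(NULL)
    rooted <- tryCatch(
      ape::root(utree, outgroup = side, resolve.root = TRUE),
      error = function(err) NULL)
    if (is.null(rooted)) return(NULL)
    ec <- count_valency_events(rooted, tip_states, model)
    data.frame(edge = e, gains = ec$gains, losses = ec$losses)
  })
  per <- do.call(rbind, res)
  list(per_rooting = per, min_losses = min(per$losses),
       max_losses = max(per$losses))
}

#' Bundle a tree with tip valency states
#'
#' @param tree `phylo` tree.
#' @param tip_states Named valency counts covering every tip.
#' @param support Optional per-edge bootstrap percentages.
#' @return A `valency_tree` list.
#' @export
valency_tree <- function(tree, tip_states, support = NULL) {
  if (!all(tree$tip.label %in% names(tip_states))) {
    stop("every tip needs a valency state")
  }
  if (!is.null(support) && any(support < 0 | support > 100, na.rm = TRUE)) {
    stop("support values must lie in [0, 100]")
  }
  structure(list(tree = tree, tip_states = tip_states[tree$tip.label],
                 support = support),
            class = "valency_tree")
}
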