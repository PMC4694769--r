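#' Parse a Newick tree
#'
#' Thin validated wrapper around [ape::read.tree()]: checks parenthesis
#' balance before parsing (reporting the character position of the first
#' imbalance) and rejects duplicate leaf labels. The tree is treated as
#' rooted as written; polytomies are allowed. Branch lengths, if present,
#' are kept but ignored by the parsimony routines.
#'
#' @param text a Newick string.
#' @return An [ape::read.tree()] `phylo` object.
#' @export
parse_newick <- function(text) {
  depth <- 0L
  chars <- strsplit(text, "")[[1L]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (depth < 0L) stop("unbalanced ')' at position ", i)
  }
  if (depth != 0L) stop("unbalanced '(': ", depth, " unclosed at end")
  tree <- ape::read.tree(text = text)
  if (is.null(tree)) stop("could not parse Newick string")
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate leaf label: ",
         tree$tip.label[duplicated(tree$tip.label)][1L])
  }
  tree
}

#' Binarise a continuous resistance phenotype
#'
#' Splits strains into resistant and sensitive by thresholding a
#' continuous effect measure (e.g. the [effect_logratio()] of the toxin's
#' effect on growth relative to a reference). With `threshold = "auto"`,
#' the threshold is placed at the midpoint of the largest gap in the
#' sorted values — the natural 1-D two-cluster split; this needs at least
#' 3 strains and a nonzero gap.
#'
#' @param effect_logratios named numeric vector, one value per strain.
#' @param threshold numeric cut point, or `"auto"` (default).
#' @param resistant `"lower"` if smaller values mean resistance (the
#'   growth-reduction log-ratio convention: a strain less impaired than
#'   the reference scores negative), `"higher"` otherwise.
#' @return Named character vector of `"resistant"` / `"sensitive"` states.
#' @export
binarize_resistance <- function(effect_logratios, threshold = "auto",
                                resistant = c("lower", "higher")) {
  resistant <- match.arg(resistant)
  vals <- effect_logratios
  if (length(vals) < 2L) stop("need at least 2 strains")
  if (identical(threshold, "auto")) {
    if (length(vals) < 3L) stop("auto threshold needs at least 3 strains")
    sv <- sort(vals)
    gaps <- diff(sv)
    if (max(gaps) == 0) stop("all values equal; no gap to split on")
    g <- which.max(gaps)
    threshold <- (sv[g] + sv[g + 1L]) / 2
  }
  low <- vals < threshold
  states <- ifelse(if (resistant == "lower") low else !low,
                   "resistant", "sensitive")
  names(states) <- names(vals)
  states
}

# Per-node children list from a phylo edge matrix.
.children_of <- function(tree) {
  n_nodes <- ape::Ntip(tree) + tree$Nnode
  kids <- vector("list", n_nodes)
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1L]
    kids[[p]] <- c(kids[[p]], tree$edge[i, 2L])
  }
  kids
}

# Internal nodes ordered by depth from the root (BFS); processing them in
# reverse guarantees children before parents regardless of edge ordering.
.internal_by_depth <- function(tree, kids) {
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  depth <- rep(NA_integer_, ntip + tree$Nnode)
  depth[root] <- 0L
  queue <- root
  order_out <- integer(0)
  while (length(queue) > 0L) {
    v <- queue[1L]; queue <- queue[-1L]
    if (v > ntip) order_out <- c(order_out, v)
    for (c_ in kids[[v]]) {
      depth[c_] <- depth[v] + 1L
      queue <- c(queue, c_)
    }
  }
  order_out  # parents before children
}

# Sankoff-style dynamic program over a rooted (possibly multifurcating)
# tree with a 2x2 substitution cost. Returns the per-node subtree cost
# matrix (rows = nodes in phylo numbering, cols = states).
.parsimony_down <- function(tree, states, levels, cost) {
  ntip <- ape::Ntip(tree)
  n_nodes <- ntip + tree$Nnode
  down <- matrix(Inf, n_nodes, length(levels))
  for (i in seq_len(ntip)) {
    st <- states[[tree$tip.label[i]]]
    down[i, match(st, levels)] <- 0
  }
  kids <- .children_of(tree)
  ord <- rev(.internal_by_depth(tree, kids))  # children before parents
  for (v in ord) {
    for (s in seq_along(levels)) {
      tot <- 0
      for (c_ in kids[[v]]) {
        tot <- tot + min(down[c_, ] + cost[s, ])
      }
      down[v, s] <- tot
    }
  }
  down
}

#' Minimum number of trait changes on a tree (generalised Fitch)
#'
#' Small-parsimony count of the minimum number of state changes of a
#' binary trait over a rooted phylogeny, computed by dynamic programming
#' (a Sankoff-style pass that reduces to the Fitch union/intersection rule
#' on bifurcations and generalises it to polytomies). Gain and loss can be
#' weighted asymmetrically; the default is the unweighted 1:1 cost.
#'
#' @param tree a rooted `phylo` ([parse_newick()]); polytomies allowed.
#' @param states named vector of leaf states (exactly 2 distinct values
#'   overall); every leaf of the tree must have a state.
#' @param levels optional length-2 character vector fixing the state order
#'   as (absent, present); defaults to the sorted unique states. A gain is
#'   `levels[1] -> levels[2]`.
#' @param gain_weight,loss_weight costs of a gain and a loss (default 1).
#' @return List with `min_changes` (the weighted minimum), `node_states`
#'   (list per node of the states that occur in at least one minimal
#'   reconstruction) and `levels`.
#' @export
fitch_min_changes <- function(tree, states, levels = NULL,
                              gain_weight = 1, loss_weight = 1) {
  stopifnot(inherits(tree, "phylo"))
  states <- unlist(states)
  missing_leaves <- setdiff(tree$tip.label, names(states))
  if (length(missing_leaves) > 0L) {
    stop("no state for leaf '", missing_leaves[1L], "'")
  }
  if (is.null(levels)) levels <- sort(unique(as.character(states)))
  if (length(levels) > 2L) stop("trait must be binary")
  if (length(levels) == 1L) levels <- c(levels, paste0("not_", levels))
  cost <- matrix(c(0, loss_weight, gain_weight, 0), 2, 2)
  down <- .parsimony_down(tree, states, levels, cost)
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  min_changes <- min(down[root, ])

  # up-pass: cost of the rest of the tree given each node state; a state
  # is in some minimal reconstruction iff down + up attains the optimum
  n_nodes <- ntip + tree$Nnode
  up <- matrix(Inf, n_nodes, 2L)
  up[root, ] <- 0
  kids <- .children_of(tree)
  ord <- .internal_by_depth(tree, kids)  # parents before children
  for (v in ord) {
    for (c_ in kids[[v]]) {
      sib_sum <- function(s) {
        tot <- 0
        for (w in kids[[v]]) {
          if (w != c_) tot <- tot + min(down[w, ] + cost[s, ])
        }
        tot
      }
      for (t in 1:2) {
        up[c_, t] <- min(vapply(1:2, function(s) {
          up[v, s] + cost[s, t] + sib_sum(s)
        }, numeric(1)))
      }
    }
  }
  node_states <- lapply(seq_len(n_nodes), function(v) {
    levels[which(down[v, ] + up[v, ] <= min_changes + 1e-9)]
  })
  list(min_changes = min_changes, node_states = node_states,
       levels = levels)
}

#' Enumerate all most-parsimonious reconstructions
#'
#' Backtracks through the parsimony dynamic program to list every
#' assignment of ancestral states achieving the minimal change count, each
#' annotated with its gain and loss events per branch. Ambiguity in where
#' changes fall (e.g. one loss deep in a clade versus several independent
#' losses) shows up as multiple reconstructions of equal cost.
#'
#' @inheritParams fitch_min_changes
#' @param cap maximum number of reconstructions to return before erroring
#'   (default 1e4).
#' @return List of class `mpr_set`: `min_changes`, `levels`, and
#'   `reconstructions`, a list in which each element has `node_states`
#'   (state per node, leaves included) and `events` (data frame `parent`,
#'   `child`, `type` with type `"gain"` or `"loss"`).
#' @export
enumerate_mprs <- function(tree, states, levels = NULL,
                           gain_weight = 1, loss_weight = 1, cap = 1e4) {
  stopifnot(inherits(tree, "phylo"))
  states <- unlist(states)
  if (is.null(levels)) levels <- sort(unique(as.character(states)))
  if (length(levels) == 1L) levels <- c(levels, paste0("not_", levels))
  cost <- matrix(c(0, loss_weight, gain_weight, 0), 2, 2)
  down <- .parsimony_down(tree, states, levels, cost)
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  opt <- min(down[root, ])
  kids <- .children_of(tree)
  n_nodes <- ntip + tree$Nnode

  assignments <- list()
  assign_rec <- function(partial, frontier) {
    if (length(frontier) == 0L) {
      if (length(assignments) >= cap) {
        stop("more than ", cap,
             " most-parsimonious reconstructions; raise cap")
      }
      assignments[[length(assignments) + 1L]] <<- partial
      return(invisible())
    }
    v <- frontier[1L]
    rest <- frontier[-1L]
    s <- partial[v]
    # enumerate optimal child-state combinations for node v
    child_opts <- lapply(kids[[v]], function(c_) {
      tot <- down[c_, ] + cost[s, ]
      which(tot <= min(tot) + 1e-9)
    })
    combos <- expand.grid(child_opts, KEEP.OUT.ATTRS = FALSE)
    for (r in seq_len(nrow(combos))) {
      p2 <- partial
      new_frontier <- rest
      for (j in seq_along(kids[[v]])) {
        c_ <- kids[[v]][j]
        p2[c_] <- combos[r, j]
        if (c_ > ntip) new_frontier <- c(new_frontier, c_)
      }
      assign_rec(p2, new_frontier)
    }
    invisible()
  }
  for (s_root in which(down[root, ] <= opt + 1e-9)) {
    partial <- rep(NA_integer_, n_nodes)
    partial[root] <- s_root
    assign_rec(partial, root)
  }

  recon <- lapply(assignments, function(a) {
    ev <- NULL
    for (i in seq_len(nrow(tree$edge))) {
      p <- tree$edge[i, 1L]; c_ <- tree$edge[i, 2L]
      if (a[p] != a[c_]) {
        type <- if (a[p] == 1L && a[c_] == 2L) "gain" else "loss"
        ev <- rbind(ev, data.frame(parent = p, child = c_, type = type,
                                   stringsAsFactors = FALSE))
      }
    }
    if (is.null(ev)) {
      ev <- data.frame(parent = integer(0), child = integer(0),
                       type = character(0), stringsAsFactors = FALSE)
    }
    list(node_states = levels[a], events = ev)
  })
  structure(list(min_changes = opt, levels = levels,
                 reconstructions = recon),
            class = "mpr_set")
}
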