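# Linear (Wagner) parsimony for meristic characters: the cost of changing
# copy count i to j along a branch is |i - j|. Ancestral counts minimize the
# total absolute change over the tree. Branch lengths are ignored.

# min-plus convolution of a cost vector with the linear cost |i - j|,
# computed by the classic two-pass distance transform in O(S).
linear_dt <- function(v) {
  n <- length(v)
  if (n < 2L) return(v)
  for (i in 2:n) if (v[i - 1L] + 1 < v[i]) v[i] <- v[i - 1L] + 1
  for (i in (n - 1L):1L) if (v[i + 1L] + 1 < v[i]) v[i] <- v[i + 1L] + 1
  v
}

check_states <- function(phy, x) {
  tips <- phy$tip.label
  if (!all(tips %in% names(x)))
    stop("missing leaf state for: ",
         paste(setdiff(tips, names(x)), collapse = ", "))
  x <- x[tips]
  if (any(is.na(x)) || any(x < 0) || any(x != round(x)))
    stop("leaf states must be non-negative integers")
  as.integer(x)
}

#' Farris down-pass for Wagner parsimony (binary trees)
#'
#' Post-order pass computing each node's Farris interval: a leaf's interval
#' is `[x, x]`; an internal node's interval is the intersection of its two
#' children's intervals when non-empty, otherwise the gap between them, with
#' the parsimony cost incremented by the width of that gap. The returned
#' cost is the minimum total absolute change over all ancestral assignments.
#'
#' @param phy rooted binary `phylo` with node labels (see [parse_newick()]).
#' @param x named integer vector of leaf states (domain copy counts).
#' @return list with `interval` (matrix, one row per node label, columns
#'   `lo`/`hi`) and `cost` (integer parsimony length), class `wagner_down`.
#' @examples
#' t <- parse_newick("((A,B),(C,D));")
#' wagner_down_pass(t, c(A = 0, B = 1, C = 4, D = 4))$cost  # 4
#' @export
wagner_down_pass <- function(phy, x) {
  deg <- tabulate(phy$edge[, 1L], nbins = ape::Ntip(phy) + phy$Nnode)
  if (any(deg[ape::Ntip(phy) + seq_len(phy$Nnode)] != 2L))
    stop("tree is not binary; use sankoff_linear() for multifurcations")
  xs <- check_states(phy, x)
  labs <- node_labels(phy)
  ntot <- ape::Ntip(phy) + phy$Nnode
  lo <- hi <- rep(NA_integer_, ntot)
  lo[seq_along(xs)] <- hi[seq_along(xs)] <- xs
  cost <- 0L
  edge <- ape::reorder.phylo(phy, "postorder")$edge
  # postorder: every edge inside a child's subtree precedes the edge to it,
  # so a child's interval is final when its incoming edge is visited
  pending <- vector("list", ntot)
  for (e in seq_len(nrow(edge))) {
    p <- edge[e, 1L]; ch <- edge[e, 2L]
    pending[[p]] <- c(pending[[p]], ch)
    if (length(pending[[p]]) == 2L) {
      c1 <- pending[[p]][1L]; c2 <- pending[[p]][2L]
      il <- max(lo[c1], lo[c2]); ih <- min(hi[c1], hi[c2])
      if (il <= ih) {
        lo[p] <- il; hi[p] <- ih
      } else {                    # disjoint: take the gap, pay its width
        lo[p] <- ih; hi[p] <- il
        cost <- cost + (il - ih)
      }
    }
  }
  interval <- cbind(lo = lo, hi = hi)
  rownames(interval) <- labs
  structure(list(interval = interval, cost = cost), class = "wagner_down")
}

#' Sankoff dynamic programme with linear costs
#'
#' General post-order DP over states `0..max_state` with transition cost
#' `|i - j|`; handles multifurcations. Each node's vector entry `s` is the
#' minimum cost of its subtree given the node is in state `s`; the returned
#' cost is the minimum over root states. Agrees with [wagner_down_pass()]
#' on binary trees. Bounding states by the observed leaf maximum never
#' changes the optimum for linear costs.
#'
#' @param phy rooted `phylo` with node labels.
#' @param x named integer vector of leaf states.
#' @param max_state DP state bound; defaults to the maximum leaf state.
#' @return list with `scores` (node x state matrix of subtree costs, row
#'   names = node labels, column names = states), `cost`, and `max_state`;
#'   class `sankoff_linear`.
#' @examples
#' t <- parse_newick("(A,B,C);")
#' sankoff_linear(t, c(A = 0, B = 1, C = 5))$cost  # 5 (deviations from median)
#' @export
sankoff_linear <- function(phy, x, max_state = NULL) {
  xs <- check_states(phy, x)
  if (is.null(max_state)) max_state <- max(xs)
  if (max_state < max(xs))
    stop("max_state (", max_state, ") below maximum leaf state (",
         max(xs), ")")
  S <- max_state + 1L
  ntip <- ape::Ntip(phy)
  ntot <- ntip + phy$Nnode
  M <- matrix(0, nrow = ntot, ncol = S)
  M[seq_len(ntip), ] <- Inf
  M[cbind(seq_len(ntip), xs + 1L)] <- 0
  edge <- ape::reorder.phylo(phy, "postorder")$edge
  for (e in seq_len(nrow(edge))) {
    p <- edge[e, 1L]; ch <- edge[e, 2L]
    M[p, ] <- M[p, ] + linear_dt(M[ch, ])
  }
  labs <- node_labels(phy)
  dimnames(M) <- list(labs, 0:max_state)
  structure(list(scores = M, cost = as.integer(min(M[root_node(phy), ])),
                 max_state = max_state),
            class = "sankoff_linear")
}

#' Canonical most-parsimonious ancestral assignment
#'
#' Pre-order traversal turning a DP result into one most-parsimonious
#' reconstruction. The root takes the smallest (policy `"root-smallest"`,
#' default) or largest (`"root-largest"`) state in its optimal set; every
#' other node takes the state minimising its subtree cost plus the linear
#' distance to its parent's assigned state, ties broken toward the smaller
#' state. The realized assignment achieves the DP minimum exactly. Among
#' the generally many most-parsimonious reconstructions, the default policy
#' biases toward low ancestral copy counts (gains/duplications over losses
#' near the root).
#'
#' @param phy rooted `phylo` with node labels.
#' @param down a `sankoff_linear` result for `phy`.
#' @param policy root tie-break, `"root-smallest"` or `"root-largest"`.
#' @param domain optional domain name attached to the result.
#' @return list with `domain`, `state` (named integer vector over all node
#'   labels) and `cost`; class `ancestral_assignment`.
#' @export
assign_states <- function(phy, down, policy = c("root-smallest",
                                                "root-largest"),
                          domain = NA_character_) {
  policy <- match.arg(policy)
  stopifnot(inherits(down, "sankoff_linear"))
  M <- down$scores
  labs <- node_labels(phy)
  ntot <- length(labs)
  state <- rep(NA_integer_, ntot)
  root <- root_node(phy)
  opt <- which(M[root, ] == min(M[root, ])) - 1L
  state[root] <- if (policy == "root-smallest") min(opt) else max(opt)
  edge <- ape::reorder.phylo(phy, "cladewise")$edge   # parents before kids
  s_all <- 0:down$max_state
  for (e in seq_len(nrow(edge))) {
    p <- edge[e, 1L]; ch <- edge[e, 2L]
    tot <- M[ch, ] + abs(s_all - state[p])
    state[ch] <- s_all[which.min(tot)]   # which.min takes the smaller tie
  }
  realized <- sum(abs(state[edge[, 2L]] - state[edge[, 1L]]))
  structure(list(domain = domain,
                 state = stats::setNames(state, labs),
                 cost = as.integer(realized)),
            class = "ancestral_assignment")
}

#' Exhaustive parsimony oracle
#'
#' Enumerates every assignment of states `0..max_state` to internal nodes
#' and returns the minimum total absolute change. Exponential; guarded to
#' trees with at most 8 internal nodes. Used to validate the DP.
#'
#' @param phy rooted `phylo`.
#' @param x named integer vector of leaf states.
#' @param max_state enumeration bound; defaults to the maximum leaf state.
#' @return integer minimum cost.
#' @export
brute_force_parsimony <- function(phy, x, max_state = NULL) {
  xs <- check_states(phy, x)
  if (is.null(max_state)) max_state <- max(xs)
  k <- phy$Nnode
  if (k > 8L) stop("tree too large for brute force (", k, " internal nodes)")
  S <- max_state + 1L
  ntip <- ape::Ntip(phy)
  combos <- as.matrix(expand.grid(rep(list(0:max_state), k)))
  full <- cbind(matrix(rep(xs, each = nrow(combos)), nrow = nrow(combos)),
                combos)
  cost <- numeric(nrow(combos))
  for (e in seq_len(nrow(phy$edge))) {
    cost <- cost + abs(full[, phy$edge[e, 2L]] - full[, phy$edge[e, 1L]])
  }
  as.integer(min(cost))
}

#' Reconstruct ancestral counts for every domain of a matrix
#'
#' Runs the linear-parsimony DP and the canonical assignment for each
#' domain column independently (characters are treated independently).
#'
#' @param phy rooted `phylo` with node labels; tips must match matrix rows.
#' @param m taxa x domain count matrix.
#' @param policy root tie-break policy, see [assign_states()].
#' @param domains subset of domain columns (default: all).
#' @return named list of `ancestral_assignment` objects, one per domain.
#' @export
reconstruct_asr <- function(phy, m, policy = "root-smallest",
                            domains = NULL) {
  if (is.null(domains)) domains <- colnames(m)
  missing <- setdiff(phy$tip.label, rownames(m))
  if (length(missing) > 0L)
    stop("matrix lacks rows for tree leaves: ",
         paste(missing, collapse = ", "))
  out <- lapply(domains, function(d) {
    x <- extract_character(m, d)
    down <- sankoff_linear(phy, x)
    assign_states(phy, down, policy = policy, domain = d)
  })
  stats::setNames(out, domains)
}

#' Tabulate ancestral assignments
#'
#' @param assignments list of `ancestral_assignment` objects.
#' @return data frame `domain`, `node`, `state`, `cost` (one row per node
#'   and domain), suitable for TSV export.
#' @export
asr_table <- function(assignments) {
  do.call(rbind, lapply(assignments, function(a) {
    data.frame(domain = a$domain, node = names(a$state),
               state = as.integer(a$state), cost = a$cost,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}
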