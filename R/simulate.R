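#' Simulate a Yule (pure-birth) tree
#'
#' Starts with two lineages at the root; while `k` lineages are extant the
#' waiting time to the next speciation is exponential with rate
#' `birth_rate * k`, and a uniformly chosen lineage splits. After the n-th
#' lineage appears one further waiting time is drawn and the tree is cut
#' there, so the root height is a sum of Exp(k * birth_rate) variables for
#' k = 2..n with expectation `sum(1/(k * birth_rate))`. The result is a
#' rooted binary ultrametric tree with tips labeled `T1..Tn` and internal
#' nodes auto-labeled `n2, n3, ...` in preorder.
#'
#' @param n_leaves number of tips (>= 2).
#' @param birth_rate speciation rate per lineage per unit time.
#' @param seed integer seed for byte-identical output, or `NULL`.
#' @return a `phylo` object.
#' @examples
#' simulate_yule_tree(5, 1, seed = 1)
#' @export
simulate_yule_tree <- function(n_leaves, birth_rate = 1, seed = NULL) {
  if (n_leaves < 2L) stop("n_leaves must be at least 2")
  stopifnot(birth_rate > 0)
  with_seed(seed, {
    parent <- c(NA_integer_, 1L, 1L)
    birth <- c(0, 0, 0)
    split_time <- rep(NA_real_, 3L)
    active <- c(2L, 3L)
    t <- 0; k <- 2L
    repeat {
      t <- t + stats::rexp(1L, birth_rate * k)
      if (k == n_leaves) break
      j <- active[sample.int(length(active), 1L)]
      split_time[j] <- t
      id1 <- length(parent) + 1L; id2 <- id1 + 1L
      parent[c(id1, id2)] <- j
      birth[c(id1, id2)] <- t
      split_time[c(id1, id2)] <- NA_real_
      active <- c(active[active != j], id1, id2)
      k <- k + 1L
    }
    children <- split(seq_along(parent)[-1L], parent[-1L])
    nwk <- function(i) {
      ch <- children[[as.character(i)]]
      len <- if (i == 1L) NULL
             else (if (i %in% active) t else split_time[i]) - birth[i]
      if (is.null(ch)) {
        paste0("L", i, ":", format(len, digits = 17))
      } else {
        core <- paste0("(", nwk(ch[1L]), ",", nwk(ch[2L]), ")")
        if (i == 1L) core else paste0(core, ":", format(len, digits = 17))
      }
    }
    phy <- ape::read.tree(text = paste0(nwk(1L), ";"))
    phy$tip.label <- paste0("T", seq_along(phy$tip.label))
    autolabel_nodes(phy)
  })
}

#' Parameters for repertoire evolution simulation
#'
#' Event model: along a branch, gains arise at `gain_rate` per unit time
#' (drawing a fresh name from `domain_pool`), while each existing domain
#' copy duplicates at `dup_rate` and is lost at `loss_rate` per unit time.
#' Rates are re-evaluated after every event (continuous-time Markov
#' process), so a loss can never drive a count negative.
#'
#' @param gain_rate gains per unit branch length.
#' @param dup_rate duplications per copy per unit branch length.
#' @param loss_rate losses per copy per unit branch length.
#' @param root_repertoire named integer vector of copy counts at the root.
#' @param domain_pool names available for gained domains.
#' @param seed integer seed or `NULL`.
#' @return list of class `evolution_params`.
#' @export
evolution_params <- function(gain_rate = 0.1, dup_rate = 0.2,
                             loss_rate = 0.2,
                             root_repertoire = c(Ca_hom_mod = 1L),
                             domain_pool = sprintf("novel%03d", 1:200),
                             seed = NULL) {
  stopifnot(gain_rate >= 0, dup_rate >= 0, loss_rate >= 0)
  root_repertoire <- root_repertoire[root_repertoire > 0]
  structure(list(gain_rate = gain_rate, dup_rate = dup_rate,
                 loss_rate = loss_rate,
                 root_repertoire = root_repertoire,
                 domain_pool = domain_pool, seed = seed),
            class = "evolution_params")
}

#' Simulate domain repertoire evolution along a tree
#'
#' Gillespie simulation of the gain/duplication/loss process of
#' [evolution_params()] down every branch, starting from the root
#' repertoire. Every unit event is recorded in a truth log; replaying the
#' log from the root reproduces every leaf repertoire exactly.
#'
#' @param phy rooted `phylo` with branch lengths and node labels.
#' @param params an `evolution_params` object.
#' @return list with `leaf_repertoires` (list of `domain_repertoire`, one
#'   per tip) and `truth_log` (data frame `child`, `domain`, `event`,
#'   `count`, in simulation order).
#' @export
simulate_repertoire_evolution <- function(phy, params) {
  stopifnot(inherits(params, "evolution_params"))
  if (is.null(phy$edge.length))
    stop("tree must have branch lengths")
  with_seed(params$seed, {
    labs <- node_labels(phy)
    ntip <- ape::Ntip(phy)
    states <- vector("list", ntip + phy$Nnode)
    root_counts <- params$root_repertoire
    states[[root_node(phy)]] <-
      stats::setNames(as.integer(root_counts), names(root_counts))
    pool <- params$domain_pool
    pool_i <- 1L
    log_child <- character(0); log_domain <- character(0)
    log_event <- character(0)
    ph <- ape::reorder.phylo(phy, "cladewise")
    for (e in seq_len(nrow(ph$edge))) {
      p <- ph$edge[e, 1L]; ch <- ph$edge[e, 2L]
      len <- ph$edge.length[e]
      cnt <- states[[p]]
      tcur <- 0
      repeat {
        copies <- sum(cnt)
        rate <- params$gain_rate +
          (params$dup_rate + params$loss_rate) * copies
        if (rate <= 0) break
        tcur <- tcur + stats::rexp(1L, rate)
        if (tcur > len) break
        u <- stats::runif(1L) * rate
        if (u < params$gain_rate) {
          if (pool_i > length(pool)) stop("domain_pool exhausted")
          d <- pool[pool_i]; pool_i <- pool_i + 1L
          cnt[d] <- 1L
          type <- "gain"
        } else if (u < params$gain_rate + params$dup_rate * copies) {
          d <- pick_domain(cnt)
          cnt[d] <- cnt[d] + 1L
          type <- "duplication"
        } else {
          d <- pick_domain(cnt)
          cnt[d] <- cnt[d] - 1L
          if (cnt[d] == 0L) cnt <- cnt[names(cnt) != d]
          type <- "loss"
        }
        log_child <- c(log_child, labs[ch])
        log_domain <- c(log_domain, d)
        log_event <- c(log_event, type)
      }
      states[[ch]] <- cnt
    }
    leaves <- lapply(seq_len(ntip), function(i)
      domain_repertoire(phy$tip.label[i], states[[i]]))
    list(leaf_repertoires = leaves,
         truth_log = data.frame(child = log_child, domain = log_domain,
                                event = log_event,
                                count = rep(1L, length(log_child)),
                                stringsAsFactors = FALSE))
  })
}

# copy-count weighted domain draw
pick_domain <- function(cnt) {
  if (length(cnt) == 1L) return(names(cnt))
  sample(names(cnt), 1L, prob = cnt)
}

#' Replay a truth log from the root
#'
#' Applies the logged unit events branch by branch down the tree and
#' returns the implied leaf repertoires; used to verify that a truth log
#' and leaf repertoires are mutually consistent.
#'
#' @param phy rooted `phylo` with node labels.
#' @param root_repertoire named counts at the root.
#' @param truth_log data frame `child`, `domain`, `event`, `count`.
#' @return list of `domain_repertoire`, one per tip.
#' @export
replay_truth_log <- function(phy, root_repertoire, truth_log) {
  labs <- node_labels(phy)
  ntip <- ape::Ntip(phy)
  states <- vector("list", ntip + phy$Nnode)
  root_repertoire <- root_repertoire[root_repertoire > 0]
  states[[root_node(phy)]] <-
    stats::setNames(as.integer(root_repertoire), names(root_repertoire))
  ph <- ape::reorder.phylo(phy, "cladewise")
  for (e in seq_len(nrow(ph$edge))) {
    p <- ph$edge[e, 1L]; ch <- ph$edge[e, 2L]
    cnt <- states[[p]]
    ev <- truth_log[truth_log$child == labs[ch], , drop = FALSE]
    for (k in seq_len(nrow(ev))) {
      d <- ev$domain[k]
      delta <- switch(ev$event[k], gain = , duplication = ev$count[k],
                      loss = -ev$count[k],
                      stop("unknown event type: ", ev$event[k]))
      cur <- if (d %in% names(cnt)) cnt[[d]] else 0L
      new <- cur + delta
      if (new < 0L) stop("truth log drives count of '", d, "' negative")
      cnt[d] <- new
      if (new == 0L) cnt <- cnt[names(cnt) != d]
    }
    states[[ch]] <- cnt
  }
  lapply(seq_len(ntip), function(i)
    domain_repertoire(phy$tip.label[i], states[[i]]))
}

#' Plant at most one unit event per domain on a tree
#'
#' Constrained generator for recovery testing: each affected domain
#' experiences exactly one unit event (gain, duplication or loss) on one
#' branch, so leaf repertoires determine the history. Branches are drawn
#' with probability proportional to branch length. Loss events are planted
#' only on branches **not** incident to the root: a single unit loss on a
#' root-incident branch admits two most-parsimonious readings (a loss
#' there, or a duplication on its sister branch), so such histories are not
#' identifiable from leaf counts; all other single-event placements have a
#' unique most-parsimonious reconstruction, which the root-smallest
#' assignment policy recovers exactly.
#'
#' @param phy rooted `phylo` with branch lengths and node labels.
#' @param root_repertoire named counts at the root; domains for
#'   duplication/loss events are drawn from it.
#' @param n_gains,n_dups,n_losses number of events of each type
#'   (`n_dups + n_losses` must not exceed the root repertoire size).
#' @param domain_pool names for gained domains.
#' @param seed integer seed or `NULL`.
#' @return list with `leaf_repertoires` and `truth_log` as in
#'   [simulate_repertoire_evolution()].
#' @export
simulate_single_event_history <- function(phy, root_repertoire,
                                          n_gains = 2L, n_dups = 2L,
                                          n_losses = 2L,
                                          domain_pool =
                                            sprintf("novel%03d", 1:50),
                                          seed = NULL) {
  stopifnot(!is.null(phy$edge.length))
  root_repertoire <- root_repertoire[root_repertoire > 0]
  if (n_dups + n_losses > length(root_repertoire))
    stop("root repertoire too small for requested duplication/loss events")
  if (n_gains > length(domain_pool)) stop("domain_pool exhausted")
  with_seed(seed, {
    labs <- node_labels(phy)
    ph <- ape::reorder.phylo(phy, "cladewise")
    nonroot_edges <- which(ph$edge[, 1L] != root_node(phy))
    draw_edge <- function(idx) {
      if (length(idx) == 1L) return(idx)
      idx[sample.int(length(idx), 1L, prob = ph$edge.length[idx])]
    }
    pick <- sample(names(root_repertoire), n_dups + n_losses)
    dup_domains <- if (n_dups > 0L) pick[seq_len(n_dups)] else character(0)
    loss_domains <- if (n_losses > 0L) pick[n_dups + seq_len(n_losses)]
                    else character(0)
    gain_domains <- if (n_gains > 0L) sample(domain_pool, n_gains)
                    else character(0)
    events <- data.frame(
      domain = c(gain_domains, dup_domains, loss_domains),
      event = rep(c("gain", "duplication", "loss"),
                  c(n_gains, n_dups, n_losses)),
      stringsAsFactors = FALSE)
    events$edge <- NA_integer_
    for (k in seq_len(nrow(events))) {
      events$edge[k] <- if (events$event[k] == "loss")
        draw_edge(nonroot_edges) else draw_edge(seq_len(nrow(ph$edge)))
    }
    events$child <- labs[ph$edge[events$edge, 2L]]
    events$count <- 1L
    # leaf repertoires: root counts, adjusted for tips below each event
    ntip <- ape::Ntip(phy)
    tipsets <- tips_below(ph, ntip)
    leaves <- lapply(seq_len(ntip), function(i) {
      cnt <- stats::setNames(as.integer(root_repertoire),
                             names(root_repertoire))
      for (k in seq_len(nrow(events))) {
        if (!(i %in% tipsets[[ph$edge[events$edge[k], 2L]]])) next
        d <- events$domain[k]
        cur <- if (d %in% names(cnt)) cnt[[d]] else 0L
        cnt[d] <- cur + if (events$event[k] == "loss") -1L else 1L
      }
      domain_repertoire(phy$tip.label[i], cnt)
    })
    list(leaf_repertoires = leaves,
         truth_log = events[c("child", "domain", "event", "count")])
  })
}

# tip ids below each node (index = ape node id)
tips_below <- function(phy, ntip) {
  ntot <- ntip + phy$Nnode
  sets <- vector("list", ntot)
  for (i in seq_len(ntip)) sets[[i]] <- i
  edge <- ape::reorder.phylo(phy, "postorder")$edge
  for (e in seq_len(nrow(edge))) {
    p <- edge[e, 1L]; ch <- edge[e, 2L]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  sets
}
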