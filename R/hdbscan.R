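# Hierarchical density-based clustering (epsilon-free), internal engine.
#
# Classic pipeline: k-th-nearest-neighbour core distances, mutual
# reachability distances, minimum spanning tree, single-linkage hierarchy,
# condensed tree at min_cluster_size, and excess-of-mass cluster
# extraction. O(n^2) memory/time: intended for the thousands of nuclei per
# image this package deals with, not for bulk point clouds.

hdbscan_fit <- function(X, min_cluster_size = 5L, min_samples = NULL,
                        allow_single_cluster = TRUE) {
  X <- as.matrix(X)
  n <- nrow(X)
  min_cluster_size <- as.integer(min_cluster_size)
  if (is.null(min_samples)) min_samples <- min_cluster_size
  if (n < 2L || min_cluster_size > n)
    return(list(labels = rep(-1L, max(n, 0L)), n_clusters = 0L))
  D <- as.matrix(dist(X))
  k <- min(min_samples, n - 1L)
  core <- apply(D, 1L, function(d) sort(d, partial = k + 1L)[k + 1L])
  # mutual reachability
  M <- pmax(D, outer(core, core, pmax))
  diag(M) <- 0

  # Prim's MST on the dense mutual-reachability matrix
  in_tree <- rep(FALSE, n)
  best <- rep(Inf, n); parent <- rep(NA_integer_, n)
  in_tree[1L] <- TRUE
  best <- M[1L, ]; parent[] <- 1L
  best[1L] <- Inf
  edges <- matrix(0, n - 1L, 3L) # from, to, weight
  for (e in seq_len(n - 1L)) {
    v <- which.min(ifelse(in_tree, Inf, best))
    edges[e, ] <- c(parent[v], v, best[v])
    in_tree[v] <- TRUE
    upd <- !in_tree & M[v, ] < best
    best[upd] <- M[v, upd]
    parent[upd] <- v
  }
  edges <- edges[order(edges[, 3L]), , drop = FALSE]

  # single-linkage hierarchy via union-find; internal nodes n+1 .. 2n-1
  uf_parent <- seq_len(2L * n - 1L)
  comp_of <- seq_len(n) # current tree node representing each root
  sizes <- c(rep(1L, n), rep(0L, n - 1L))
  children <- matrix(0L, n - 1L, 2L)
  lambda_birth_node <- numeric(2L * n - 1L) # merge distance of each node
  find <- function(x) {
    while (uf_parent[x] != x) {
      uf_parent[x] <<- uf_parent[uf_parent[x]]
      x <- uf_parent[x]
    }
    x
  }
  node_dist <- numeric(2L * n - 1L)
  nxt <- n
  for (e in seq_len(nrow(edges))) {
    a <- find(edges[e, 1L]); b <- find(edges[e, 2L])
    na <- comp_of[a]; nb <- comp_of[b]
    nxt <- nxt + 1L
    children[nxt - n, ] <- c(na, nb)
    node_dist[nxt] <- edges[e, 3L]
    sizes[nxt] <- sizes[na] + sizes[nb]
    uf_parent[a] <- b
    comp_of[b] <- nxt
  }
  root <- 2L * n - 1L

  # condense: walk from the root; a child spawns a new cluster only when
  # both children of a split have >= min_cluster_size points, otherwise its
  # points fall out of the running cluster at this lambda.
  pt_cluster <- integer(n) # condensed cluster id per point
  pt_lambda <- numeric(n)  # lambda at which the point left its cluster
  cl_parent <- integer(0); cl_birth <- numeric(0); cl_children <- list()
  new_cluster <- function(parent, lambda) {
    cl_parent[length(cl_parent) + 1L] <<- parent
    cl_birth[length(cl_birth) + 1L] <<- lambda
    cl_children[[length(cl_birth)]] <<- integer(0)
    id <- length(cl_birth)
    split_stab[id] <<- 0
    if (parent > 0L)
      cl_children[[parent]] <<- c(cl_children[[parent]], id)
    id
  }
  leaves_under <- function(node) {
    out <- integer(0); stack <- node
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (v <= n) out <- c(out, v)
      else stack <- c(stack, children[v - n, ])
    }
    out
  }
  split_stab <- numeric(0) # per-cluster stability from surviving to a split
  root_cl <- new_cluster(0L, 0)
  # stack of (tree node, condensed cluster id)
  stack_node <- root; stack_cl <- root_cl
  while (length(stack_node)) {
    v <- stack_node[length(stack_node)]
    cl <- stack_cl[length(stack_cl)]
    stack_node <- stack_node[-length(stack_node)]
    stack_cl <- stack_cl[-length(stack_cl)]
    repeat {
      if (v <= n) { # singleton leaf: falls out at +Inf density
        pt_cluster[v] <- cl; pt_lambda[v] <- Inf
        break
      }
      lam <- if (node_dist[v] > 0) 1 / node_dist[v] else Inf
      ch <- children[v - n, ]
      big <- sizes[ch] >= min_cluster_size
      if (all(big)) {
        # `cl` dies here: its surviving points contribute up to this lambda
        split_stab[cl] <- split_stab[cl] + sizes[v] * (lam - cl_birth[cl])
        for (c2 in ch) {
          id2 <- new_cluster(cl, lam)
          stack_node <- c(stack_node, c2)
          stack_cl <- c(stack_cl, id2)
        }
        break
      }
      # points of small children fall out of `cl` at lambda
      for (c2 in ch[!big]) {
        lv <- leaves_under(c2)
        pt_cluster[lv] <- cl
        pt_lambda[lv] <- lam
      }
      if (!any(big)) break
      v <- ch[big][1L] # continue down the surviving child as the same cluster
    }
  }

  n_cl <- length(cl_birth)
  # stability = sum over noise-fallout points of (lambda_p - lambda_birth)
  # plus the split-survival term, with infinite lambdas clipped to the
  # largest finite lambda observed
  lam_cap <- suppressWarnings(max(pt_lambda[is.finite(pt_lambda)],
                                  cl_birth, 0))
  lamp <- ifelse(is.finite(pt_lambda), pt_lambda, lam_cap)
  stability <- split_stab
  for (i in seq_len(n)) {
    cl <- pt_cluster[i]
    stability[cl] <- stability[cl] + (lamp[i] - cl_birth[cl])
  }
  stability[!is.finite(stability)] <- lam_cap
  # a cluster's points also include those of its descendants while it lived
  subtree_pts <- vector("list", n_cl)
  for (i in seq_len(n))
    subtree_pts[[pt_cluster[i]]] <- c(subtree_pts[[pt_cluster[i]]], i)
  order_depth <- rev(seq_len(n_cl)) # children have larger ids than parents
  full_stability <- stability
  # excess of mass: select bottom-up
  selected <- rep(FALSE, n_cl)
  for (cl in order_depth) {
    ch <- cl_children[[cl]]
    if (length(ch) == 0L) {
      selected[cl] <- cl != root_cl || allow_single_cluster
      next
    }
    child_sum <- sum(full_stability[ch])
    root_may_win <- cl != root_cl || allow_single_cluster
    if (root_may_win && stability[cl] >= child_sum) {
      selected[cl] <- TRUE
      # deselect all descendants
      stack <- ch
      while (length(stack)) {
        v <- stack[length(stack)]; stack <- stack[-length(stack)]
        selected[v] <- FALSE
        stack <- c(stack, cl_children[[v]])
      }
      full_stability[cl] <- stability[cl]
    } else {
      full_stability[cl] <- child_sum
    }
  }

  labels <- rep(-1L, n)
  next_lab <- 0L
  for (cl in seq_len(n_cl)) {
    if (!selected[cl]) next
    next_lab <- next_lab + 1L
    # members: points recorded in cl or any descendant
    stack <- cl; members <- integer(0)
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      members <- c(members, subtree_pts[[v]])
      stack <- c(stack, cl_children[[v]])
    }
    labels[members] <- next_lab
  }
  list(labels = labels, n_clusters = next_lab,
       diagnostics = list(birth = cl_birth, parent = cl_parent,
                          stability = stability, selected = selected))
}
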