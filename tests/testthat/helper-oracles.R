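# Independent brute-force oracles used to validate the package's graph and
# correlation machinery. Deliberately naive implementations: exhaustive path
# enumeration with the textbook blocking rules, and full permutation
# enumeration for the Spearman p-value.

# all simple undirected paths between x and y in the skeleton of `dag`
.oracle_paths <- function(dag, x, y) {
  n <- length(dag$nodes)
  A <- matrix(FALSE, n, n, dimnames = list(dag$nodes, dag$nodes))
  A[cbind(match(dag$edges$from, dag$nodes),
          match(dag$edges$to, dag$nodes))] <- TRUE
  skel <- A | t(A)
  paths <- list()
  walk <- function(path) {
    last <- path[length(path)]
    if (last == y) {
      paths[[length(paths) + 1]] <<- path
      return(invisible())
    }
    for (nxt in dag$nodes[skel[last, ]]) {
      if (!nxt %in% path) walk(c(path, nxt))
    }
  }
  walk(x)
  list(paths = paths, A = A)
}

.oracle_descendants <- function(A, v) {
  nodes <- rownames(A)
  seen <- v
  frontier <- v
  while (length(frontier)) {
    frontier <- setdiff(nodes[colSums(A[frontier, , drop = FALSE]) > 0], seen)
    seen <- c(seen, frontier)
  }
  seen
}

# textbook path-blocking d-separation: every path must contain a blocked node
oracle_d_separated <- function(dag, x, y, given = character()) {
  pp <- .oracle_paths(dag, x, y)
  A <- pp$A
  for (path in pp$paths) {
    open <- TRUE
    if (length(path) > 2) {
      for (i in 2:(length(path) - 1)) {
        a <- path[i - 1]; v <- path[i]; b <- path[i + 1]
        collider <- A[a, v] && A[b, v]
        blocked <- if (collider) {
          # collider blocks unless it or a descendant is conditioned on
          !any(.oracle_descendants(A, v) %in% given)
        } else {
          v %in% given
        }
        if (blocked) { open <- FALSE; break }
      }
    }
    if (open) return(FALSE)
  }
  TRUE
}

# exact permutation distribution of the Spearman coefficient
oracle_spearman_p <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  rs_obs <- cor(rx, ry)
  perms <- .all_perms(length(y))
  rs_all <- apply(perms, 1, function(p) cor(rx, ry[p]))
  mean(abs(rs_all) >= abs(rs_obs) - 1e-12)
}

.all_perms <- function(n) {
  if (n == 1) return(matrix(1L))
  sub <- .all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

# enumerate every DAG on `n` labelled nodes in canonical topological order
# (edges only i -> j for i < j); d-separation is invariant to relabelling,
# so this covers all DAG structures on n nodes
canonical_dags <- function(n, nodes = letters[seq_len(n)]) {
  prs <- t(utils::combn(n, 2))
  m <- nrow(prs)
  roles <- stats::setNames(c(rep("confounder", n - 1), "outcome"), nodes)
  lapply(0:(2^m - 1), function(g) {
    on <- as.logical(intToBits(g))[seq_len(m)]
    e <- prs[on, , drop = FALSE]
    causal_dag(data.frame(from = nodes[e[, 1]], to = nodes[e[, 2]]), roles)
  })
}

# run implementation vs oracle over every node pair and conditioning set
compare_dsep_exhaustive <- function(dag) {
  nodes <- dag$nodes
  n <- length(nodes)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    others <- nodes[-c(i, j)]
    for (s in 0:(2^length(others) - 1)) {
      Z <- others[as.logical(intToBits(s))[seq_along(others)]]
      got <- d_separated(dag, nodes[i], nodes[j], Z)
      want <- oracle_d_separated(dag, nodes[i], nodes[j], Z)
      if (!identical(got, want)) {
        return(list(ok = FALSE, x = nodes[i], y = nodes[j], Z = Z))
      }
    }
  }
  list(ok = TRUE)
}
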