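#' Causal directed acyclic graph with node roles
#'
#' A lightweight DAG representation for backdoor identification. Each node
#' carries a role: `treatment`, `outcome`, `confounder`, or `unobserved`.
#' Unobserved nodes may appear in the graph (they shape identification) but
#' are never eligible for an adjustment set. Exactly one node must have the
#' `outcome` role.
#'
#' @param edges two-column `data.frame` (or matrix) of directed edges,
#'   `from -> to`.
#' @param roles named character vector mapping every node name to its role.
#' @return an object of class `causal_dag`.
#' @export
causal_dag <- function(edges, roles) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  colnames(edges) <- c("from", "to")
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  nodes <- names(roles)
  if (anyDuplicated(nodes)) stop("duplicated node names")
  ok_roles <- c("treatment", "outcome", "confounder", "unobserved")
  if (!all(roles %in% ok_roles))
    stop("roles must be one of: ", paste(ok_roles, collapse = ", "))
  if (sum(roles == "outcome") != 1)
    stop("the DAG must have exactly one outcome node")
  missing <- setdiff(c(edges$from, edges$to), nodes)
  if (length(missing))
    stop("edge endpoints without a role: ", paste(missing, collapse = ", "))
  if (any(edges$from == edges$to)) stop("self-loops are not allowed")
  dag <- structure(list(nodes = nodes, roles = roles, edges = edges),
                   class = "causal_dag")
  if (!is_acyclic(dag)) stop("the graph contains a directed cycle")
  dag
}

#' @export
print.causal_dag <- function(x, ...) {
  cat("Causal DAG: ", length(x$nodes), " nodes, ", nrow(x$edges), " edges\n",
      sep = "")
  for (r in c("treatment", "outcome", "confounder", "unobserved")) {
    nn <- x$nodes[x$roles == r]
    if (length(nn)) cat(sprintf("  %-11s %s\n", paste0(r, ":"),
                                paste(nn, collapse = ", ")))
  }
  invisible(x)
}

.dag_check_nodes <- function(dag, nodes) {
  unknown <- setdiff(nodes, dag$nodes)
  if (length(unknown))
    stop("unknown node(s): ", paste(unknown, collapse = ", "))
}

.parents <- function(dag, nodes)
  unique(dag$edges$from[dag$edges$to %in% nodes])
.children <- function(dag, nodes)
  unique(dag$edges$to[dag$edges$from %in% nodes])

.ancestors <- function(dag, nodes, inclusive = TRUE) {
  seen <- nodes
  frontier <- nodes
  while (length(frontier)) {
    frontier <- setdiff(.parents(dag, frontier), seen)
    seen <- c(seen, frontier)
  }
  if (inclusive) seen else setdiff(seen, nodes)
}

.descendants <- function(dag, nodes, inclusive = TRUE) {
  seen <- nodes
  frontier <- nodes
  while (length(frontier)) {
    frontier <- setdiff(.children(dag, frontier), seen)
    seen <- c(seen, frontier)
  }
  if (inclusive) seen else setdiff(seen, nodes)
}

#' Test acyclicity of a directed graph
#'
#' Kahn's topological-sort check: repeatedly remove in-degree-zero nodes;
#' the graph is acyclic iff every node is removed.
#'
#' @param dag a [causal_dag()] (or a bare list with `nodes` and `edges`).
#' @return `TRUE` iff the graph has no directed cycle.
#' @export
is_acyclic <- function(dag) {
  nodes <- dag$nodes
  edges <- dag$edges
  indeg <- table(factor(edges$to, levels = nodes))
  queue <- nodes[indeg == 0]
  removed <- 0L
  indeg <- as.integer(indeg)
  names(indeg) <- nodes
  while (length(queue)) {
    v <- queue[1]
    queue <- queue[-1]
    removed <- removed + 1L
    out <- edges$to[edges$from == v]
    for (w in out) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
    edges <- edges[edges$from != v, , drop = FALSE]
  }
  removed == length(nodes)
}

#' d-separation in a causal DAG
#'
#' Decides whether `x` and `y` are d-separated given a conditioning set,
#' using the moralized-ancestral-graph construction: restrict to ancestors
#' of `{x, y} ∪ given`, marry co-parents, drop edge directions, delete
#' the conditioned nodes, and test undirected connectivity. This is
#' equivalent to the path-wise chain/fork/collider blocking rules (a
#' collider unblocks when it or any descendant is conditioned on).
#'
#' @param dag a [causal_dag()].
#' @param x,y distinct node names, neither in `given`.
#' @param given character vector of conditioned nodes (possibly empty).
#' @return `TRUE` iff every path between `x` and `y` is blocked.
#' @export
d_separated <- function(dag, x, y, given = character()) {
  .dag_check_nodes(dag, c(x, y, given))
  if (x == y) stop("'x' and 'y' must be distinct")
  if (x %in% given || y %in% given)
    stop("'x' and 'y' may not appear in the conditioning set")
  n <- length(dag$nodes)
  A <- matrix(FALSE, n, n, dimnames = list(dag$nodes, dag$nodes))
  A[cbind(match(dag$edges$from, dag$nodes),
          match(dag$edges$to, dag$nodes))] <- TRUE
  ix <- match(x, dag$nodes); iy <- match(y, dag$nodes)
  ig <- match(given, dag$nodes)

  # ancestral closure of {x, y} union given
  anc <- logical(n)
  anc[c(ix, iy, ig)] <- TRUE
  repeat {
    more <- (A %*% anc) > 0 & !anc
    if (!any(more)) break
    anc <- anc | more
  }
  A[!anc, ] <- FALSE
  A[, !anc] <- FALSE

  # moralize: undirect and marry co-parents
  M <- A | t(A)
  for (v in which(colSums(A) > 1)) {
    pa <- which(A[, v])
    M[pa, pa] <- TRUE
  }
  diag(M) <- FALSE
  # delete conditioned nodes, then test undirected connectivity x -- y
  M[ig, ] <- FALSE
  M[, ig] <- FALSE
  reach <- logical(n)
  reach[ix] <- TRUE
  repeat {
    more <- (M %*% reach) > 0 & !reach
    if (!any(more)) break
    reach <- reach | more
  }
  !reach[iy]
}

#' Backdoor adjustment set
#'
#' Identifies the causal effect of one or more treatments on the outcome by
#' the backdoor criterion. The canonical candidate is the set of observed,
#' non-treatment parents of the treatments that are not descendants of any
#' treatment. The candidate is then verified: in the graph with all edges
#' out of the treatments removed, every treatment must be d-separated from
#' the outcome given the candidate. If verification fails (for instance
#' when an unobserved node is a parent of both a treatment and the
#' outcome), the effect is not identified by this construction and `NULL`
#' is returned -- no adjustment set is fabricated.
#'
#' @param dag a [causal_dag()].
#' @param treatments character vector of treatment node names (defaults to
#'   all nodes with role `treatment`).
#' @param outcome the outcome node (defaults to the DAG's outcome).
#' @return a character vector of adjustment nodes (possibly empty, meaning
#'   no adjustment is needed), or `NULL` when the effect is not identified.
#' @export
backdoor_set <- function(dag, treatments = NULL, outcome = NULL) {
  if (is.null(treatments)) treatments <- dag$nodes[dag$roles == "treatment"]
  if (is.null(outcome)) outcome <- dag$nodes[dag$roles == "outcome"]
  if (!length(treatments)) stop("'treatments' must be nonempty")
  .dag_check_nodes(dag, c(treatments, outcome))
  if (outcome %in% treatments)
    stop("the outcome cannot also be a treatment")

  parents <- .parents(dag, treatments)
  candidate <- setdiff(parents, treatments)
  candidate <- candidate[dag$roles[candidate] != "unobserved"]
  candidate <- setdiff(candidate, .descendants(dag, treatments,
                                               inclusive = FALSE))
  candidate <- sort(candidate)

  # verify in the intervention graph (edges out of treatments removed)
  g <- dag
  g$edges <- g$edges[!g$edges$from %in% treatments, , drop = FALSE]
  blocked <- vapply(treatments, function(t)
    d_separated(g, t, outcome, setdiff(candidate, t)), logical(1))
  if (all(blocked)) candidate else NULL
}

# ---- model builders ---------------------------------------------------------

CONFOUNDER_VARS <- c("humidity", "temperature", "sea_level_pressure",
                     "wind_speed")
TREATMENT_VARS <- c("visibility", "precipitation", "AQI", "PM2.5", "PM10",
                    "SO2", "NO2", "CO")

#' Build the multiple-treatment causal model
#'
#' The joint model: 8 environmental treatments (visibility, precipitation,
#' AQI, PM2.5, PM10, SO2, NO2, CO), one count outcome (`visits`), four
#' observed meteorological confounders (humidity, temperature, sea-level
#' pressure, wind speed) and an unobserved confounder `U`. The observed
#' confounders point at every treatment and at the outcome; precipitation
#' additionally settles the six pollutant treatments; pollutants
#' interconvert along SO2/NO2/CO -> PM2.5 -> PM10 -> AQI; all treatments
#' point at the outcome (the edges under test); by default `U` points only
#' at the outcome. Setting `u_to_treatments = TRUE` adds `U ->` every
#' treatment, a configuration in which the backdoor criterion correctly
#' reports the effect as not identified.
#'
#' @param u_to_treatments should the unobserved confounder also cause the
#'   treatments? Default `FALSE`.
#' @return a [causal_dag()] with 14 nodes.
#' @export
build_multiple_treatment_dag <- function(u_to_treatments = FALSE) {
  edge <- function(from, to) expand.grid(from = from, to = to,
                                         stringsAsFactors = FALSE)
  edges <- rbind(
    edge(CONFOUNDER_VARS, TREATMENT_VARS),
    edge(CONFOUNDER_VARS, "visits"),
    edge("precipitation", c("PM2.5", "PM10", "SO2", "NO2", "CO", "AQI")),
    edge(c("SO2", "NO2", "CO"), "PM2.5"),
    edge("PM2.5", "PM10"),
    edge("PM10", "AQI"),
    edge(TREATMENT_VARS, "visits"),
    edge("U", "visits"))
  if (u_to_treatments) edges <- rbind(edges, edge("U", TREATMENT_VARS))
  roles <- c(setNames(rep("treatment", length(TREATMENT_VARS)),
                      TREATMENT_VARS),
             visits = "outcome",
             setNames(rep("confounder", length(CONFOUNDER_VARS)),
                      CONFOUNDER_VARS),
             U = "unobserved")
  causal_dag(unique(edges), roles)
}

#' Build a single-treatment causal model
#'
#' One treatment, the count outcome, and 12 confounders: the 7 remaining
#' environmental treatments, the 4 meteorological variables, and the
#' unobserved `U`. Observed confounders are common causes of treatment and
#' outcome. With `include_indirect = FALSE` the four meteorological
#' variables -- indirect causes that act on the treatments but not directly
#' on the outcome -- are removed, leaving 8 confounders.
#'
#' @param treatment one of the 8 treatment variables.
#' @param include_indirect keep the four meteorological confounders?
#' @param u_to_treatments add `U -> treatment`? Default `FALSE`.
#' @return a [causal_dag()] (14 nodes with indirect causes, 10 without).
#' @export
build_single_treatment_dag <- function(treatment, include_indirect = TRUE,
                                       u_to_treatments = FALSE) {
  if (!treatment %in% TREATMENT_VARS)
    stop("unknown treatment '", treatment, "'; must be one of: ",
         paste(TREATMENT_VARS, collapse = ", "))
  others <- setdiff(TREATMENT_VARS, treatment)
  observed_conf <- if (include_indirect) c(others, CONFOUNDER_VARS) else others
  edge <- function(from, to) expand.grid(from = from, to = to,
                                         stringsAsFactors = FALSE)
  edges <- rbind(
    edge(observed_conf, treatment),
    edge(observed_conf, "visits"),
    edge(treatment, "visits"),
    edge("U", "visits"))
  if (u_to_treatments) edges <- rbind(edges, edge("U", treatment))
  roles <- c(setNames("treatment", treatment),
             visits = "outcome",
             setNames(rep("confounder", length(observed_conf)), observed_conf),
             U = "unobserved")
  causal_dag(unique(edges), roles)
}

# ---- serialization ----------------------------------------------------------

#' Write and read a DAG as an edge-list text file
#'
#' Format: a `# roles` block of `node: role` lines followed by a `# edges`
#' block of `cause -> effect` lines.
#'
#' @param dag a [causal_dag()].
#' @param path file path.
#' @return `write_dag` returns `path` invisibly; `read_dag` a
#'   [causal_dag()].
#' @export
write_dag <- function(dag, path) {
  lines <- c("# roles",
             paste0(names(dag$roles), ": ", dag$roles),
             "# edges",
             paste(dag$edges$from, "->", dag$edges$to))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_dag
#' @export
read_dag <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  mode <- NA_character_
  roles <- character()
  from <- character(); to <- character()
  for (ln in lines) {
    if (ln == "# roles") { mode <- "roles"; next }
    if (ln == "# edges") { mode <- "edges"; next }
    if (startsWith(ln, "#")) next
    if (identical(mode, "roles")) {
      parts <- strsplit(ln, ":", fixed = TRUE)[[1]]
      if (length(parts) != 2) stop("bad role line: ", ln)
      roles[trimws(parts[1])] <- trimws(parts[2])
    } else if (identical(mode, "edges")) {
      parts <- strsplit(ln, "->", fixed = TRUE)[[1]]
      if (length(parts) != 2) stop("bad edge line: ", ln)
      from <- c(from, trimws(parts[1]))
      to <- c(to, trimws(parts[2]))
    } else stop("content before any '# roles' / '# edges' header: ", ln)
  }
  causal_dag(data.frame(from = from, to = to), roles)
}
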