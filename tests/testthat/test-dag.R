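chain_dag <- causal_dag(data.frame(from = c("X", "M"), to = c("M", "Y")),
                        c(X = "treatment", M = "confounder", Y = "outcome"))
collider_dag <- causal_dag(data.frame(from = c("X", "Y"), to = c("C", "C")),
                           c(X = "treatment", C = "confounder",
                             Y = "outcome"))

test_that("acyclicity detection and constructor invariants", {
  expect_true(is_acyclic(chain_dag))
  expect_error(causal_dag(data.frame(from = c("A", "B"), to = c("B", "A")),
                          c(A = "confounder", B = "outcome")),
               "cycle")
  expect_error(causal_dag(data.frame(from = "A", to = "B"),
                          c(A = "confounder", B = "confounder")),
               "exactly one outcome")
  expect_error(causal_dag(data.frame(from = "A", to = "A"),
                          c(A = "outcome")), "self-loop")
  expect_true(is_acyclic(build_multiple_treatment_dag()))
})

test_that("d-separation encodes chain, fork and collider semantics", {
  expect_true(d_separated(chain_dag, "X", "Y", "M"))
  expect_false(d_separated(chain_dag, "X", "Y"))

  expect_true(d_separated(collider_dag, "X", "Y"))
  expect_false(d_separated(collider_dag, "X", "Y", "C"))

  # conditioning on a collider's descendant also opens the path
  desc <- causal_dag(data.frame(from = c("X", "Y", "C"),
                                to = c("C", "C", "D")),
                     c(X = "treatment", C = "confounder", D = "confounder",
                       Y = "outcome"))
  expect_false(d_separated(desc, "X", "Y", "D"))

  expect_error(d_separated(chain_dag, "X", "Q"), "unknown node")
  expect_error(d_separated(chain_dag, "X", "Y", "X"), "conditioning set")
})

test_that("d-separation agrees with the path-enumeration oracle (4 nodes)", {
  for (dag in canonical_dags(4)) {
    res <- compare_dsep_exhaustive(dag)
    expect_true(res$ok,
                info = paste("disagreement:", res$x, res$y,
                             paste(res$Z, collapse = ",")))
  }
})

test_that("backdoor identification on the textbook graphs", {
  triangle <- causal_dag(data.frame(from = c("Z", "Z", "T"),
                                    to = c("T", "Y", "Y")),
                         c(Z = "confounder", T = "treatment", Y = "outcome"))
  expect_equal(backdoor_set(triangle), "Z")

  direct <- causal_dag(data.frame(from = "T", to = "Y"),
                       c(T = "treatment", Y = "outcome"))
  expect_equal(backdoor_set(direct), character(0))

  expect_error(backdoor_set(triangle, treatments = c("T", "Y")),
               "outcome cannot also be")
})

test_that("any returned adjustment set actually blocks the backdoor paths", {
  # oracle check: with edges out of the treatment removed, treatment and
  # outcome must be d-separated given the returned set
  for (seed in 1:30) {
    set.seed(seed)
    n <- 5
    nodes <- c("T", "Y", "a", "b", "c")
    prs <- t(combn(n, 2))
    on <- runif(nrow(prs)) < 0.5
    e <- prs[on, , drop = FALSE]
    dag <- causal_dag(data.frame(from = nodes[e[, 1]], to = nodes[e[, 2]]),
                      c(T = "treatment", Y = "outcome", a = "confounder",
                        b = "confounder", c = "confounder"))
    z <- backdoor_set(dag, "T", "Y")
    if (is.null(z)) next
    g <- dag
    g$edges <- g$edges[g$edges$from != "T", , drop = FALSE]
    expect_true(oracle_d_separated(g, "T", "Y", z))
  }
})

test_that("study DAG builders have the published structure", {
  m <- build_multiple_treatment_dag()
  expect_equal(length(m$nodes), 14)  # 8 treatments + outcome + 5 confounders
  expect_equal(sum(m$roles == "treatment"), 8)
  expect_equal(sum(m$roles == "unobserved"), 1)
  expect_setequal(backdoor_set(m),
                  c("humidity", "temperature", "sea_level_pressure",
                    "wind_speed"))

  s <- build_single_treatment_dag("CO", include_indirect = TRUE)
  expect_equal(length(s$nodes), 14)  # 1 treatment + 12 confounders + outcome
  expect_equal(sum(s$roles %in% c("confounder", "unobserved")), 12)

  s0 <- build_single_treatment_dag("CO", include_indirect = FALSE)
  expect_equal(sum(s0$roles %in% c("confounder", "unobserved")), 8)
  expect_true(is_acyclic(s0))

  expect_error(build_single_treatment_dag("O3"), "unknown treatment")
})

test_that("an unobserved cause of the treatments defeats identification", {
  expect_null(backdoor_set(build_multiple_treatment_dag(
    u_to_treatments = TRUE)))
  expect_null(backdoor_set(build_single_treatment_dag(
    "SO2", u_to_treatments = TRUE)))
  # whereas U -> outcome alone does not
  expect_false(is.null(backdoor_set(build_single_treatment_dag("SO2"))))
})

test_that("edge-list serialization round-trips", {
  path <- withr::local_tempfile(fileext = ".dag")
  dag <- build_single_treatment_dag("SO2", include_indirect = FALSE)
  write_dag(dag, path)
  back <- read_dag(path)
  expect_setequal(back$nodes, dag$nodes)
  expect_equal(back$roles[dag$nodes], dag$roles)
  expect_equal(nrow(back$edges), nrow(dag$edges))
  expect_setequal(paste(back$edges$from, back$edges$to),
                  paste(dag$edges$from, dag$edges$to))
})
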