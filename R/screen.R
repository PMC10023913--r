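#' Spearman rank correlation with a t-approximate p-value
#'
#' `rs` is the Pearson correlation of average-ranked data (ties receive
#' average ranks); the two-sided p-value comes from
#' `t = rs * sqrt((n - 2) / (1 - rs^2))` on `n - 2` degrees of freedom, the
#' standard large-sample approximation (exact at |rs| = 1, where p is 0 up
#' to floating point). Used rather than a normality-assuming coefficient
#' because daily visit counts are markedly non-normal.
#'
#' For `n <= 8` an exact two-sided permutation p-value is available
#' (`method = "exact"`): the proportion of all `n!` rank assignments whose
#' |rs| reaches the observed one.
#'
#' @param x,y numeric vectors of equal length >= 4; neither constant.
#' @param method `"t"` (default) or `"exact"` (permutation, `n <= 8`).
#' @return a list with elements `rs`, `p`, and `n`.
#' @export
spearman_cor <- function(x, y, method = c("t", "exact")) {
  method <- match.arg(method)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("spearman_cor needs at least 4 paired finite values")
  if (length(unique(x)) == 1 || length(unique(y)) == 1)
    stop("correlation undefined for a constant vector")
  rx <- rank(x); ry <- rank(y)
  rs <- stats::cor(rx, ry)
  if (method == "exact") {
    if (n > 8) stop("exact permutation p-value limited to n <= 8")
    perms <- .permutations(n)
    rs_perm <- apply(perms, 1, function(p) stats::cor(rx, ry[p]))
    p <- mean(abs(rs_perm) >= abs(rs) - 1e-12)
  } else if (abs(rs) >= 1) {
    p <- 0
  } else {
    tstat <- rs * sqrt((n - 2) / (1 - rs^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rs = rs, p = p, n = n)
}

.permutations <- function(n) {
  if (n == 1) return(matrix(1L))
  sub <- .permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

#' Lagged Spearman screening of environmental variables
#'
#' Computes, for every environmental variable and every lag `0..max_lag`,
#' the Spearman correlation between the variable lagged by `k` days and the
#' daily visit counts, each cell on its own lag-aligned sample. Every
#' variable therefore receives `max_lag + 1` association tests. No
#' multiple-testing correction is applied across the grid; each cell is
#' judged at `alpha` on its own.
#'
#' @param env an [env_series()].
#' @param visits a [visit_series()].
#' @param max_lag largest lag in days (default 6).
#' @param alpha per-cell significance level (default 0.05).
#' @return an object of class `lag_screen` -- a `data.frame` with columns
#'   `variable`, `lag`, `rs`, `p`, `n`, `significant`, and attributes
#'   `max_lag` and `alpha`.
#' @export
lag_screen <- function(env, visits, max_lag = 6, alpha = 0.05) {
  stopifnot(inherits(env, "env_series"), inherits(visits, "visit_series"))
  if (max_lag < 0 || max_lag != round(max_lag))
    stop("'max_lag' must be a non-negative integer")
  if (max_lag >= min(nrow(env), nrow(visits)))
    stop("'max_lag' must be smaller than the series length")
  vars <- setdiff(colnames(env), "date")
  rows <- vector("list", length(vars) * (max_lag + 1))
  i <- 0L
  for (k in 0:max_lag) {
    tab <- lag_align(env, visits, k)
    for (v in vars) {
      s <- spearman_cor(tab[[v]], tab$visits)
      i <- i + 1L
      rows[[i]] <- data.frame(variable = v, lag = k, rs = s$rs, p = s$p,
                              n = s$n, significant = s$p < alpha)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(match(out$variable, vars), out$lag), ]
  rownames(out) <- NULL
  attr(out, "max_lag") <- as.integer(max_lag)
  attr(out, "alpha") <- alpha
  class(out) <- c("lag_screen", "data.frame")
  out
}

#' @export
print.lag_screen <- function(x, digits = 3, ...) {
  cat("Lagged Spearman screen: ", length(unique(x$variable)),
      " variables x lags 0-", attr(x, "max_lag"),
      " (alpha = ", attr(x, "alpha"), ")\n", sep = "")
  wide <- stats::reshape(as.data.frame(x)[, c("variable", "lag", "rs")],
                         idvar = "variable", timevar = "lag",
                         direction = "wide")
  colnames(wide) <- sub("^rs\\.", "lag", colnames(wide))
  print(wide, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Select candidate treatments from a screening grid
#'
#' `"all_lags"` (the default) keeps variables significant at every lag of
#' the grid -- the selection that, on the study data, yields the nine
#' variables carried into the causal models. `"any_lag"` keeps variables
#' significant at one or more lags.
#'
#' @param result a [lag_screen()] result.
#' @param rule `"all_lags"` or `"any_lag"`.
#' @return a character vector of variable names, in the grid's variable
#'   order (deterministic).
#' @export
select_treatments <- function(result, rule = c("all_lags", "any_lag")) {
  stopifnot(inherits(result, "lag_screen"))
  rule <- match.arg(rule)
  vars <- unique(result$variable)
  keep <- vapply(vars, function(v) {
    sig <- result$significant[result$variable == v]
    if (rule == "all_lags") all(sig) else any(sig)
  }, logical(1))
  vars[keep]
}

#' Export a screening grid as long-format CSV
#'
#' @param result a [lag_screen()] result.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_screen_csv <- function(result, path) {
  utils::write.csv(as.data.frame(result), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
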