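# Rank-based group comparisons used throughout the analysis:
# Kruskal-Wallis omnibus test (tie-corrected, chi-square approximation)
# and Dunn's pairwise post hoc z tests with Sidak family-wise correction.

#' Kruskal-Wallis omnibus test
#'
#' Tie-corrected Kruskal-Wallis statistic (mid-ranks) with the chi-square
#' approximation on k-1 degrees of freedom, computed via
#' [stats::kruskal.test()]. The degenerate case of all observations equal
#' is reported as H = 0, p = 1 (no evidence of any difference).
#'
#' @param groups list of numeric vectors (>= 2 groups, each non-empty,
#'   total N >= 3)
#' @return list with `H`, `p`, `df`.
#' @export
kruskal_wallis <- function(groups) {
  groups <- lapply(groups, as.numeric)
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(vapply(groups, length, 0L) == 0)) stop("empty group")
  x <- unlist(groups)
  if (length(x) < 3) stop("need at least 3 observations in total")
  g <- factor(rep(seq_along(groups), vapply(groups, length, 0L)))
  if (length(unique(x)) == 1)
    return(list(H = 0, p = 1, df = length(groups) - 1L))
  kt <- stats::kruskal.test(x, g)
  list(H = unname(kt$statistic), p = unname(kt$p.value),
       df = unname(kt$parameter))
}

# tie-corrected H statistic from raw data (used by the permutation test)
.kw_H <- function(x, g) {
  N <- length(x)
  r <- rank(x)
  Rj <- tapply(r, g, sum)
  nj <- tabulate(g)
  H <- 12 / (N * (N + 1)) * sum(Rj^2 / nj) - 3 * (N + 1)
  t <- table(x)
  corr <- 1 - sum(t^3 - t) / (N^3 - N)
  if (corr == 0) return(0)
  H / corr
}

#' Exact permutation p-value for the Kruskal-Wallis statistic
#'
#' Enumerates every assignment of the pooled observations to the observed
#' group sizes and reports the fraction with H at least the observed H.
#' Feasible for small N (the analysis has 2-5 replicates per group);
#' guarded at `max_n`.
#'
#' @param groups list of numeric vectors
#' @param max_n enumeration guard on the total N (default 10)
#' @return list with `H`, `p_exact`, and the number of `arrangements`.
#' @export
kw_exact_p <- function(groups, max_n = 10) {
  x <- unlist(lapply(groups, as.numeric))
  sizes <- vapply(groups, length, 0L)
  N <- length(x)
  if (N > max_n) stop("exact enumeration limited to N <= ", max_n)
  g_obs <- rep(seq_along(sizes), sizes)
  H_obs <- .kw_H(x, g_obs)
  count <- 0L; total <- 0L
  recurse <- function(avail, assignment, gi) {
    if (gi > length(sizes)) {
      total <<- total + 1L
      if (.kw_H(x, assignment) >= H_obs - 1e-9) count <<- count + 1L
      return(invisible())
    }
    picks <- utils::combn(avail, sizes[gi], simplify = FALSE)
    for (pk in picks) {
      assignment[pk] <- gi
      recurse(setdiff(avail, pk), assignment, gi + 1L)
    }
  }
  recurse(seq_len(N), integer(N), 1L)
  list(H = H_obs, p_exact = count / total, arrangements = total)
}

#' Dunn's post hoc pairwise tests with Sidak correction
#'
#' For each pair of groups, Dunn's z statistic on the joint mid-ranks with
#' the tie correction,
#' `z = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - sum(t^3-t)/(12(N-1))) (1/n_i + 1/n_j))`,
#' two-sided normal p-values, and the Sidak family-wise adjustment
#' `p_adj = 1 - (1 - p)^m` over the m = k(k-1)/2 comparisons (Bonferroni
#' available behind `method`).
#'
#' @param groups named list of numeric vectors; empty groups are dropped
#'   with a warning
#' @param method `"sidak"` (default) or `"bonferroni"`
#' @return data frame `group_a`, `group_b`, `z`, `p_raw`, `p_adjusted`.
#' @export
dunn_sidak <- function(groups, method = c("sidak", "bonferroni")) {
  method <- match.arg(method)
  if (is.null(names(groups)))
    names(groups) <- paste0("group", seq_along(groups))
  empty <- vapply(groups, length, 0L) == 0
  if (any(empty)) {
    warning("dropping empty group(s): ", paste(names(groups)[empty], collapse = ", "))
    groups <- groups[!empty]
  }
  k <- length(groups)
  if (k < 2) stop("need at least 2 non-empty groups")
  x <- unlist(lapply(groups, as.numeric))
  g <- rep(seq_len(k), vapply(groups, length, 0L))
  N <- length(x)
  r <- rank(x)
  Rbar <- tapply(r, g, mean)
  nj <- tabulate(g)
  t <- table(x)
  tie_term <- sum(t^3 - t) / (12 * (N - 1))
  v0 <- N * (N + 1) / 12 - tie_term
  m <- k * (k - 1) / 2
  out <- NULL
  for (i in 1:(k - 1)) for (j in (i + 1):k) {
    se <- sqrt(v0 * (1 / nj[i] + 1 / nj[j]))
    z <- if (se > 0) (Rbar[i] - Rbar[j]) / se else 0
    p <- 2 * stats::pnorm(-abs(z))
    p_adj <- switch(method,
                    sidak = 1 - (1 - p)^m,
                    bonferroni = m * p)
    out <- rbind(out, data.frame(
      group_a = names(groups)[i], group_b = names(groups)[j],
      z = unname(z), p_raw = unname(p),
      p_adjusted = min(1, max(0, p_adj)), stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Omnibus plus post hoc group comparison
#'
#' Kruskal-Wallis across all groups followed by Dunn-Sidak pairwise
#' tests — the comparison applied to regional or marker-specific editing
#' levels and ratios across replicates.
#'
#' @param values numeric observations (per-replicate levels or ratios)
#' @param labels group labels, same length
#' @param method correction passed to [dunn_sidak()]
#' @return list of class `group_comparison`: `groups`, `H`, `p_omnibus`,
#'   `pairwise`.
#' @export
group_comparison <- function(values, labels, method = "sidak") {
  keep <- !is.na(values) & !is.na(labels)
  values <- values[keep]; labels <- as.character(labels[keep])
  groups <- split(values, labels)
  kw <- kruskal_wallis(groups)
  pw <- dunn_sidak(groups, method = method)
  structure(list(groups = names(groups), H = kw$H, p_omnibus = kw$p,
                 pairwise = pw),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis across %d groups: H = %.4f, p = %.4g\n",
              length(x$groups), x$H, x$p_omnibus))
  cat("post hoc Dunn-Sidak:\n")
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}
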