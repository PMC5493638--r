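#' Construct a 2x2 subset-by-status contingency table
#'
#' Layout: rows are subset membership (reduced, normal-like), columns are
#' disease status (case, control): `a` = case & reduced, `b` = case &
#' normal-like, `c` = control & reduced, `d` = control & normal-like.
#'
#' @param a,b,c,d non-negative integer counts.
#' @return 2x2 integer matrix of class `contingency_2x2`.
#' @export
contingency_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (sum(counts) == 0) stop("table total must be positive", call. = FALSE)
  structure(matrix(as.integer(c(a, b, c, d)), nrow = 2, byrow = TRUE,
                   dimnames = list(subset = c("reduced", "normal-like"),
                                   status = c("case", "control"))),
            class = c("contingency_2x2", "matrix", "array"))
}

#' Tabulate subset labels against disease status
#'
#' @param subset named character vector, sample id -> `"reduced"` or
#'   `"normal-like"` (e.g. `label_clusters(...)$subset`).
#' @param status sample metadata with control/case groups.
#' @return a [contingency_2x2()]; samples missing either label are dropped
#'   with a warning (count recorded in attribute `n_dropped`).
#' @export
contingency_from_labels <- function(subset, status) {
  ids <- union(names(subset), status$sample_id)
  sub <- subset[match(ids, names(subset))]
  grp <- as.character(status$group[match(ids, status$sample_id)])
  ok <- !is.na(sub) & !is.na(grp)
  if (any(!ok))
    warning("dropped ", sum(!ok),
            " sample(s) missing a subset label or a status", call. = FALSE)
  sub <- sub[ok]; grp <- grp[ok]
  if (!length(sub)) stop("no samples with both labels", call. = FALSE)
  if (!all(sub %in% c("reduced", "normal-like")))
    stop("subset labels must be 'reduced' or 'normal-like'", call. = FALSE)
  t <- contingency_2x2(sum(grp == "case" & sub == "reduced"),
                       sum(grp == "case" & sub == "normal-like"),
                       sum(grp == "control" & sub == "reduced"),
                       sum(grp == "control" & sub == "normal-like"))
  attr(t, "n_dropped") <- sum(!ok)
  t
}

cells <- function(t) list(a = t[1, 1], b = t[1, 2], c = t[2, 1], d = t[2, 2])

#' Cross-product odds ratio of a 2x2 table
#'
#' `(a*d) / (b*c)`. When exactly one of b, c is zero the ratio is infinite
#' (flagged, not an error); `haldane = TRUE` adds 0.5 to every cell of a
#' table containing a zero before computing.
#'
#' @param t a [contingency_2x2()].
#' @param haldane apply the Haldane-Anscombe +0.5 correction when a zero
#'   cell exists.
#' @return the odds ratio (possibly `Inf` or `NaN`).
#' @export
odds_ratio <- function(t, haldane = FALSE) {
  x <- cells(t)
  v <- unlist(x)
  if (haldane && any(v == 0)) v <- v + 0.5
  unname((v["a"] * v["d"]) / (v["b"] * v["c"]))
}

#' Woolf confidence interval for the odds ratio
#'
#' `exp(log(OR) +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`. Tables with a zero
#' cell get the Haldane-Anscombe +0.5 correction, flagged in the result.
#'
#' @param t a [contingency_2x2()].
#' @param level confidence level; `level = 0` degenerates to `(OR, OR)`.
#' @return list with `low`, `high`, `odds_ratio`, `method`,
#'   `haldane_applied`.
#' @export
or_confidence_interval <- function(t, level = 0.95) {
  v <- unlist(cells(t))
  haldane <- any(v == 0)
  if (haldane) v <- v + 0.5
  or <- (v["a"] * v["d"]) / (v["b"] * v["c"])
  z <- stats::qnorm(1 - (1 - level) / 2)
  se <- sqrt(sum(1 / v))
  list(low = unname(exp(log(or) - z * se)),
       high = unname(exp(log(or) + z * se)),
       odds_ratio = unname(or),
       method = if (haldane) "woolf_haldane" else "woolf",
       haldane_applied = haldane)
}

#' Association p-value for a 2x2 table
#'
#' `chisq`: Pearson X^2 with 1 df, no continuity correction (upper tail);
#' `chisq_yates`: with Yates continuity correction; `fisher`: two-sided
#' exact p, summing the hypergeometric probabilities of all tables with the
#' same margins whose probability does not exceed the observed one.
#'
#' @param t a [contingency_2x2()].
#' @param method `"chisq"`, `"chisq_yates"` or `"fisher"`.
#' @return p-value in `[0, 1]`.
#' @export
association_pvalue <- function(t, method = c("chisq", "chisq_yates",
                                             "fisher")) {
  method <- match.arg(method)
  x <- cells(t)
  n <- x$a + x$b + x$c + x$d
  if (method %in% c("chisq", "chisq_yates")) {
    r1 <- x$a + x$b; r2 <- x$c + x$d; c1 <- x$a + x$c; c2 <- x$b + x$d
    if (any(c(r1, r2, c1, c2) == 0))
      stop("a margin is zero: expected counts are 0; use method = 'fisher'",
           call. = FALSE)
    expected <- outer(c(r1, r2), c(c1, c2)) / n
    obs <- matrix(c(x$a, x$b, x$c, x$d), nrow = 2, byrow = TRUE)
    dev <- abs(obs - expected)
    if (method == "chisq_yates") dev <- pmax(dev - 0.5, 0)
    x2 <- sum(dev^2 / expected)
    return(stats::pchisq(x2, df = 1, lower.tail = FALSE))
  }
  # fisher: condition on both margins; the free cell a is hypergeometric
  r1 <- x$a + x$b; r2 <- x$c + x$d; c1 <- x$a + x$c
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(support, r1, r2, c1)
  p_obs <- stats::dhyper(x$a, r1, r2, c1)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Full association summary for a 2x2 table
#'
#' Bundles the odds ratio, its Woolf confidence interval and an association
#' p-value into one result.
#'
#' @param t a [contingency_2x2()].
#' @param level CI confidence level.
#' @param p_method passed to [association_pvalue()].
#' @return object of class `association_result`.
#' @export
associate <- function(t, level = 0.95, p_method = "chisq") {
  ci <- or_confidence_interval(t, level)
  structure(list(odds_ratio = unname(odds_ratio(t, haldane = ci$haldane_applied)),
                 ci_low = ci$low, ci_high = ci$high, ci_level = level,
                 ci_method = ci$method,
                 p_value = association_pvalue(t, p_method),
                 p_method = p_method,
                 table = t),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("OR %.3g (%d%% CI %.3g-%.3g, %s), p = %.3g (%s)\n",
              x$odds_ratio, round(100 * x$ci_level), x$ci_low, x$ci_high,
              x$ci_method, x$p_value, x$p_method))
  invisible(x)
}
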