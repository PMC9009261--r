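# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    stop2("`", name, "` must be TRUE or FALSE")
  }
}

check_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    stop2("`", name, "` must be a single integer >= ", min)
  }
}

check_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max) {
    stop2("`", name, "` must be a single number in [", min, ", ", max, "]")
  }
}

# Row-wise z-score of a genes x samples matrix; errors on zero-variance rows
# unless na_action = "drop".
zscore_rows <- function(x, na_action = c("error", "drop")) {
  na_action <- match.arg(na_action)
  mu <- rowMeans(x)
  s <- apply(x, 1L, sd)
  bad <- s == 0 | !is.finite(s)
  if (any(bad)) {
    if (na_action == "error") {
      stop2("zero-variance gene(s): ", paste(head(rownames(x)[bad], 5), collapse = ", "))
    }
    x <- x[!bad, , drop = FALSE]
    mu <- mu[!bad]
    s <- s[!bad]
  }
  (x - mu) / s
}

#' Adjusted Rand index between two partitions
#'
#' Hubert-Arabie chance-corrected agreement between two labelings of the same
#' items; 1 for identical partitions, about 0 for independent ones.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return A single number in \[-1, 1\].
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop2("label vectors differ in length")
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(0)
  (sum_ij - expected) / (max_idx - expected)
}

# Co-membership indicator matrix of a label vector.
comembership <- function(labels) {
  outer(labels, labels, `==`) * 1
}
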