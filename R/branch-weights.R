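# Coalescent branch-length weights B_i(j) for a sample of n alleles.
#
# The expected unfolded spectrum under a stepwise size history is a linear
# combination of exponentials e^{-choose(j,2) s} weighted by B_i(j), where
# B_i(j) = W_{i,j}/(j(j-1)) and W_{i,j} satisfies the Polanski-Kimmel
# recursion.  The direct alternating-sum representation of B_i(j) suffers
# catastrophic cancellation in double precision (hundreds of decimal digits
# are needed at n = 1000), so the recursion is the production path and the
# direct sum is evaluated in exact big-integer arithmetic as a reference
# oracle for small n (the entire sum is a ratio of integers; rounding occurs
# only in the final conversion to double).

#' Alternating product coefficient of the direct branch-weight sum
#'
#' Computes `C(b, j) = prod_{l = b..n, l != j} l(l-1) / (l(l-1) - j(j-1))`,
#' the coefficient appearing in the direct (non-recursive) expression for the
#' branch-length weights `B_i(j)`.  The empty product (`b = j = n`) is 1.
#'
#' @param b Integer, lower limit of the product, `2 <= b <= j`.
#' @param j Integer, excluded index, `b <= j <= n`.
#' @param n Integer sample size (number of alleles), `n >= 2`.
#' @return A length-one numeric value.
#' @seealso [branch_weight_direct()], [branch_weights()]
#' @export
#' @examples
#' coefficient_C(2, 2, 4)  # 1.5 * 1.2 = 1.8
coefficient_C <- function(b, j, n) {
  if (length(b) != 1L || length(j) != 1L || length(n) != 1L)
    stop("b, j and n must be scalars")
  if (n < 2 || b < 2 || b > j || j > n)
    stop("require 2 <= b <= j <= n")
  l <- seq.int(b, n)
  l <- l[l != j]
  if (!length(l)) return(1)
  prod(l * (l - 1) / (l * (l - 1) - j * (j - 1)))
}

## ---- exact big-integer helpers --------------------------------------------
## Nonnegative magnitudes as little-endian limb vectors in base 2^20, with a
## separate sign.  Only the operations the direct-sum oracle needs.

.bi_base <- 2^20

.bi_carry <- function(v) {
  repeat {
    q <- floor(v / .bi_base)
    if (all(q == 0)) break
    v <- v - q * .bi_base
    add <- c(0, q)
    L <- max(length(v), length(add))
    v <- c(v, rep(0, L - length(v))) + c(add, rep(0, L - length(add)))
  }
  while (length(v) > 1L && v[length(v)] == 0) v <- v[-length(v)]
  v
}

.bi_mul_small <- function(v, m) {  # magnitude times integer double < 2^40
  if (m == 0) return(0)
  lo <- m %% .bi_base
  hi <- m %/% .bi_base
  out <- v * lo
  if (hi > 0) {
    shifted <- c(0, v * hi)
    L <- max(length(out), length(shifted))
    out <- c(out, rep(0, L - length(out))) + c(shifted, rep(0, L - length(shifted)))
  }
  .bi_carry(out)
}

.bi_mag_mul <- function(u, v) {  # full magnitude product
  res <- 0
  for (k in seq_along(v)) {
    if (v[k] == 0) next
    res <- .bi_mag_add(res, c(rep(0, k - 1L), .bi_mul_small(u, v[k])))
  }
  res
}

.bi_mag_cmp <- function(u, v) {
  if (length(u) != length(v)) return(sign(length(u) - length(v)))
  for (k in rev(seq_along(u))) if (u[k] != v[k]) return(sign(u[k] - v[k]))
  0
}

.bi_mag_add <- function(u, v) {
  L <- max(length(u), length(v))
  .bi_carry(c(u, rep(0, L - length(u))) + c(v, rep(0, L - length(v))))
}

.bi_mag_sub <- function(u, v) {  # assumes u >= v
  L <- max(length(u), length(v))
  w <- c(u, rep(0, L - length(u))) - c(v, rep(0, L - length(v)))
  for (k in seq_len(L - 1L)) {
    if (w[k] < 0) { w[k] <- w[k] + .bi_base; w[k + 1L] <- w[k + 1L] - 1 }
  }
  while (length(w) > 1L && w[length(w)] == 0) w <- w[-length(w)]
  w
}

.bi_signed_add <- function(a, b) {  # a, b = list(s = sign, v = magnitude)
  if (a$s == 0) return(b)
  if (b$s == 0) return(a)
  if (a$s == b$s) return(list(s = a$s, v = .bi_mag_add(a$v, b$v)))
  cmp <- .bi_mag_cmp(a$v, b$v)
  if (cmp == 0) return(list(s = 0, v = 0))
  if (cmp > 0) list(s = a$s, v = .bi_mag_sub(a$v, b$v))
  else list(s = b$s, v = .bi_mag_sub(b$v, a$v))
}

.bi_to_d <- function(v) {  # magnitude -> double (rounded once, ~1e-16)
  x <- 0
  for (k in rev(seq_along(v))) x <- x * .bi_base + v[k]
  x
}

## ---- direct-sum oracle -----------------------------------------------------

## Exact signed numerators Q_b = Num_b * P_b for b = 2..j, plus the common
## denominator magnitude and its sign, where
##   Num_b = prod_{l=b..n, l != j} l(l-1),
##   P_b   = prod_{l=2..b-1} (l(l-1) - j(j-1))      (all l < j here),
##   Den   = prod_{l=2..n, l != j} (l(l-1) - j(j-1)).
## Then C(b, j) = Q_b / (Num_b-free part): sum_b w_b C(b,j) = [sum w_b Q_b]/Den.
.direct_j_tables <- function(j, n) {
  jj <- j * (j - 1)
  ## Num_b, descending from b = j
  num <- vector("list", j - 1L)            # index b - 1
  cur <- if (j < n) {
    v <- 1
    for (l in seq.int(j + 1L, n)) v <- .bi_mul_small(v, l * (l - 1))
    v
  } else 1
  num[[j - 1L]] <- cur
  if (j > 2L) {
    for (b in seq.int(j, 3L)) {
      cur <- .bi_mul_small(cur, (b - 1) * (b - 2))
      num[[b - 2L]] <- cur
    }
  }
  ## P_b, ascending; track sign (all factors l < j have l(l-1) - jj < 0)
  Q <- vector("list", j - 1L)
  pv <- 1; ps <- 1
  for (b in seq.int(2L, j)) {
    Q[[b - 1L]] <- list(s = ps, v = .bi_mag_mul(num[[b - 1L]], pv))
    if (b < j) {
      d <- b * (b - 1) - jj                # negative for b < j
      pv <- .bi_mul_small(pv, abs(d))
      ps <- ps * sign(d)
    }
  }
  ## common denominator
  dv <- 1; ds <- 1
  for (l in seq.int(2L, n)) {
    if (l == j) next
    d <- l * (l - 1) - jj
    dv <- .bi_mul_small(dv, abs(d))
    ds <- ds * sign(d)
  }
  list(Q = Q, den = .bi_to_d(dv) * ds)
}

.direct_B_ij <- function(i, tab, j, n) {
  acc <- list(s = 0, v = 0)
  for (b in seq.int(2L, j)) {
    w <- choose(n - b, i - 1)              # exact in double for n <= ~50
    if (w == 0) next
    q <- tab$Q[[b - 1L]]
    acc <- .bi_signed_add(acc, list(s = q$s, v = .bi_mul_small(q$v, w)))
  }
  num <- .bi_to_d(acc$v) * acc$s
  num / tab$den / (i * choose(n - 1, i))
}

#' Direct-sum branch-length weight (exact-arithmetic oracle)
#'
#' Evaluates `B_i(j)` by the direct alternating sum
#' `B_i(j) = (1/i) choose(n-1, i)^{-1} sum_{b=2}^{j} choose(n-b, i-1) C(b, j)`.
#' The alternating coefficients `C(b, j)` cancel catastrophically in floating
#' point, so the sum is carried out in exact big-integer arithmetic over a
#' common denominator; the only rounding is the final conversion to double
#' (relative error of order 1e-16).  Intended as a small-sample reference
#' (`n` up to ~40) for validating the production recursion, not for
#' production use.
#'
#' @param i Integer derived-allele count, `1 <= i <= n - 1`.
#' @param j Integer number of ancestral lines, `2 <= j <= n`.
#' @param n Integer sample size, `n >= 2` (practical upper limit ~45 before
#'   the exact integers overflow double range).
#' @return A length-one numeric value.
#' @seealso [branch_weights()] for the numerically stable recursion.
#' @export
branch_weight_direct <- function(i, j, n) {
  if (length(i) != 1L || length(j) != 1L || length(n) != 1L)
    stop("i, j and n must be scalars")
  if (n < 2 || i < 1 || i > n - 1 || j < 2 || j > n)
    stop("require 1 <= i <= n-1 and 2 <= j <= n")
  tab <- .direct_j_tables(as.integer(j), as.integer(n))
  .direct_B_ij(as.integer(i), tab, as.integer(j), as.integer(n))
}

## Full direct-sum table, for tests.  Returns (n-1) x (n-1) matrix, rows
## i = 1..n-1, columns j = 2..n.
.branch_weights_direct_table <- function(n) {
  stopifnot(n >= 2)
  B <- matrix(0, n - 1L, n - 1L)
  for (j in seq.int(2L, n)) {
    tab <- .direct_j_tables(j, n)
    for (i in seq_len(n - 1L)) B[i, j - 1L] <- .direct_B_ij(i, tab, j, n)
  }
  B
}

.bw_cache <- new.env(parent = emptyenv())

#' Branch-length weights by the stable recursion
#'
#' Builds the full table of `W_{i,j}` (Polanski-Kimmel recursion) and
#' `B_i(j) = W_{i,j} / (j(j-1))` for a sample of `n` alleles.  The recursion
#' runs in standard double precision, is numerically stable, and remains
#' finite for `n` in the thousands; results satisfy the identity
#' `sum_j B_i(j) = 1/i`.
#'
#' Tables are cached per `n` (they are pure functions of `n`).
#'
#' @param n Integer sample size (alleles), `n >= 2`.
#' @param cache Logical; reuse/populate the per-session cache (default TRUE).
#' @return An object of class `"branch_weights"`: a list with elements `n`,
#'   `j` (the column index `2..n`), `binom2` (`choose(j, 2)`), `W` and `B`
#'   (`(n-1) x (n-1)` matrices, rows indexed by derived-allele count `i`).
#' @export
#' @examples
#' bw <- branch_weights(10)
#' max(abs(rowSums(bw$B) - 1 / (1:9)))  # ~ 0
branch_weights <- function(n, cache = TRUE) {
  if (length(n) != 1L || is.na(n) || n < 2)
    stop("n must be a single integer >= 2")
  n <- as.integer(n)
  key <- as.character(n)
  if (cache && !is.null(.bw_cache[[key]])) return(.bw_cache[[key]])
  i <- seq_len(n - 1L)
  W <- matrix(0, n - 1L, n - 1L)  # columns j = 2..n
  W[, 1L] <- 6 / (n + 1)
  if (n >= 3L)
    W[, 2L] <- 30 * (n - 2 * i) / ((n + 1) * (n + 2))
  if (n >= 4L) {
    for (j in seq.int(2L, n - 2L)) {
      W[, j + 1L] <-
        -((1 + j) * (3 + 2 * j) * (n - j) / (j * (2 * j - 1) * (n + j + 1))) * W[, j - 1L] +
        ((3 + 2 * j) * (n - 2 * i) / (j * (n + j + 1))) * W[, j]
    }
  }
  jj <- seq.int(2L, n)
  B <- sweep(W, 2L, jj * (jj - 1), "/")
  out <- structure(
    list(n = n, j = jj, binom2 = choose(jj, 2), W = W, B = B),
    class = "branch_weights")
  if (cache) .bw_cache[[key]] <- out
  out
}

#' @export
print.branch_weights <- function(x, ...) {
  cat("Branch-length weights for n =", x$n, "alleles\n")
  dev <- max(abs(rowSums(x$B) - 1 / seq_len(x$n - 1L)) * seq_len(x$n - 1L))
  cat(sprintf("  max relative deviation of sum_j B_i(j) from 1/i: %.3g\n", dev))
  invisible(x)
}
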