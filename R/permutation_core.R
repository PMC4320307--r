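#' Permutation systems and negation operators
#'
#' An n-valued permutation system consists of the n! arrangements of the
#' integers 1..n, ordered lexicographically, together with n-1 negation
#' operators \eqn{N_1, \dots, N_{n-1}}. Operator \eqn{N_i} exchanges the two
#' neighboring values i and i+1 inside a permutation ("value-swap"
#' semantics); the alternative "position-swap" semantics exchanges the
#' entries at positions i and i+1. Both are involutions and generate
#' isomorphic adjacency structures (the isomorphism is permutation
#' inversion), so the default follows the value-exchange reading.
#'
#' @name permutation_core
NULL

# Hard guard against combinatorial blow-up; raise explicitly via max_n.
.pg_default_max_n <- 8L

.check_n <- function(n, min_n = 1L, max_n = .pg_default_max_n) {
  if (length(n) != 1L || is.na(n) || n != as.integer(n))
    stop("valuedness `n` must be a single integer", call. = FALSE)
  n <- as.integer(n)
  if (n < min_n || n > max_n)
    stop(sprintf("valuedness n = %d out of supported range [%d, %d]",
                 n, min_n, max_n), call. = FALSE)
  n
}

#' Validate a permutation of 1..n
#'
#' @param p integer vector; must contain each of 1..length(p) exactly once.
#' @return `p` as an integer vector, invisibly checked.
#' @export
validate_permutation <- function(p) {
  p <- as.integer(p)
  n <- length(p)
  if (n < 1L || anyNA(p) || !setequal(p, seq_len(n)))
    stop("not a permutation of 1..n: [", paste(p, collapse = " "), "]",
         call. = FALSE)
  p
}

#' Construct a permutation-system descriptor
#'
#' @param n valuedness (number of values), an integer >= 1.
#' @param max_n upper bound on `n` (default 8); raising it is an explicit
#'   opt-in to factorial growth.
#' @return an object of class `permutation_system` with fields `n`,
#'   `size` (= n!) and `operator_count` (= n - 1).
#' @examples
#' permutation_system(4)$size        # 24
#' permutation_system(5)$operator_count  # 4
#' @export
permutation_system <- function(n, max_n = .pg_default_max_n) {
  n <- .check_n(n, max_n = max_n)
  structure(
    list(n = n, size = factorial(n), operator_count = n - 1L),
    class = "permutation_system"
  )
}

#' @export
print.permutation_system <- function(x, ...) {
  cat(sprintf("<permutation system> n = %d, %d permutations, %d negation operators\n",
              x$n, x$size, x$operator_count))
  invisible(x)
}

#' All permutations of 1..n in lexicographic order
#'
#' @inheritParams permutation_system
#' @return an integer matrix with n! rows and n columns; row k is the
#'   permutation of lexicographic rank k (row 1 = identity, row n! = the
#'   reversed identity).
#' @examples
#' nrow(all_permutations(4))  # 24
#' all_permutations(3)
#' @export
all_permutations <- function(n, max_n = .pg_default_max_n) {
  n <- .check_n(n, max_n = max_n)
  if (n == 1L) return(matrix(1L, 1L, 1L))
  gen <- function(vals) {
    if (length(vals) == 1L) return(matrix(vals, 1L, 1L))
    blocks <- lapply(seq_along(vals), function(i) {
      sub <- gen(vals[-i])
      cbind(vals[i], sub, deparse.level = 0L)
    })
    do.call(rbind, blocks)
  }
  m <- gen(seq_len(n))       # recursion on the leading value is lex order
  storage.mode(m) <- "integer"
  dimnames(m) <- NULL
  m
}

#' Lexicographic rank of a permutation
#'
#' Rank is 1-based: the identity has rank 1 and the reversed identity has
#' rank n!. Computed from the Lehmer code.
#'
#' @param p a permutation of 1..n.
#' @return integer rank in 1..n!.
#' @examples
#' lex_rank(c(1, 2, 3, 4))       # 1
#' lex_rank(c(1, 3, 2, 4, 5))    # 7
#' @export
lex_rank <- function(p) {
  p <- validate_permutation(p)
  n <- length(p)
  r <- 0
  for (j in seq_len(n - 1L)) {
    smaller_after <- sum(p[(j + 1L):n] < p[j])
    r <- r + smaller_after * factorial(n - j)
  }
  as.integer(r + 1)
}

#' Permutation of a given lexicographic rank
#'
#' Inverse of [lex_rank()].
#'
#' @param k rank in 1..n!.
#' @param n valuedness.
#' @return the k-th permutation of 1..n in lexicographic order.
#' @examples
#' lex_unrank(7, 5)   # 1 3 2 4 5
#' @export
lex_unrank <- function(k, n) {
  n <- .check_n(n)
  if (length(k) != 1L || is.na(k) || k != as.integer(k) ||
      k < 1L || k > factorial(n))
    stop(sprintf("rank k = %s out of range 1..%d", format(k), factorial(n)),
         call. = FALSE)
  k0 <- as.integer(k) - 1L
  avail <- seq_len(n)
  p <- integer(n)
  for (j in seq_len(n)) {
    f <- factorial(n - j)
    idx <- k0 %/% f
    k0 <- k0 %% f
    p[j] <- avail[idx + 1L]
    avail <- avail[-(idx + 1L)]
  }
  p
}

#' Apply a negation operator to a permutation
#'
#' Under `"value"` semantics \eqn{N_i} exchanges the entries holding the
#' values i and i+1, wherever they stand; under `"position"` semantics it
#' exchanges the entries at positions i and i+1. Either way the operator is
#' an involution.
#'
#' @param p a permutation of 1..n.
#' @param i operator index in 1..n-1.
#' @param semantics `"value"` (default) or `"position"`.
#' @return the negated permutation.
#' @examples
#' apply_negation(c(1, 2, 3, 4, 5), 2)  # 1 3 2 4 5
#' @export
apply_negation <- function(p, i, semantics = c("value", "position")) {
  p <- validate_permutation(p)
  semantics <- match.arg(semantics)
  n <- length(p)
  if (length(i) != 1L || is.na(i) || i != as.integer(i) || i < 1L || i >= n)
    stop(sprintf("operator index i = %s out of range 1..%d", format(i), n - 1L),
         call. = FALSE)
  i <- as.integer(i)
  q <- p
  if (semantics == "value") {
    a <- which(p == i)
    b <- which(p == i + 1L)
    q[a] <- i + 1L
    q[b] <- i
  } else {
    q[c(i, i + 1L)] <- p[c(i + 1L, i)]
  }
  q
}

#' Serialize / parse permutations
#'
#' Permutations are written as digit strings ("1234") for n <= 9 and as
#' comma-separated integers otherwise.
#'
#' @param p a permutation of 1..n.
#' @return `perm_to_string()`: a character scalar; `string_to_perm()`: an
#'   integer vector.
#' @examples
#' perm_to_string(c(1, 3, 2, 4))  # "1324"
#' string_to_perm("1324")
#' @export
perm_to_string <- function(p) {
  p <- validate_permutation(p)
  if (length(p) <= 9L) paste(p, collapse = "") else paste(p, collapse = ",")
}

#' @rdname perm_to_string
#' @param s a string produced by [perm_to_string()].
#' @export
string_to_perm <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  p <- if (grepl(",", s, fixed = TRUE)) {
    as.integer(strsplit(s, ",", fixed = TRUE)[[1L]])
  } else {
    as.integer(strsplit(s, "", fixed = TRUE)[[1L]])
  }
  validate_permutation(p)
}
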