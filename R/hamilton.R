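#' Hamilton loops
#'
#' A Hamilton loop is a closed walk on the permutograph that visits every
#' permutation exactly once and returns to its start; it is the formal
#' carrier of one intentional program / behavior mode. A loop is stored as
#' a start permutation plus a sequence of n! operator indices. Because the
#' permutograph is bipartite, valid loops have even length.
#'
#' @name hamilton
NULL

#' Construct a Hamilton-loop object
#'
#' Structural constructor only: the ops sequence must have length n! and
#' valid operator indices, but Hamiltonicity is checked separately by
#' [verify_loop()].
#'
#' @param start start permutation (integer vector or digit string).
#' @param ops integer vector of n! operator indices in 1..n-1.
#' @param direction +1 or -1, bookkeeping for reversals.
#' @param semantics operator semantics, `"value"` or `"position"`.
#' @return an object of class `hamilton_loop`.
#' @examples
#' fig_loop <- hamilton_loop(1:4, rep(c(1, 2, 3, 2, 3, 2, 1, 2), 3))
#' verify_loop(fig_loop)$valid
#' @export
hamilton_loop <- function(start, ops, direction = 1L,
                          semantics = c("value", "position")) {
  if (is.character(start)) start <- string_to_perm(start)
  start <- validate_permutation(start)
  semantics <- match.arg(semantics)
  n <- length(start)
  ops <- as.integer(ops)
  if (length(ops) != factorial(n))
    stop(sprintf("ops must have length n! = %d, got %d",
                 factorial(n), length(ops)), call. = FALSE)
  if (anyNA(ops) || any(ops < 1L) || any(ops > n - 1L))
    stop("operator indices must lie in 1..n-1", call. = FALSE)
  if (!direction %in% c(1L, -1L))
    stop("direction must be +1 or -1", call. = FALSE)
  structure(
    list(n = n, start = start, ops = ops, direction = as.integer(direction),
         semantics = semantics),
    class = "hamilton_loop"
  )
}

#' @export
print.hamilton_loop <- function(x, ...) {
  cat(sprintf("<hamilton loop> n = %d, start %s, %d ops (%s-swap, dir %+d)\n",
              x$n, perm_to_string(x$start), length(x$ops), x$semantics,
              x$direction))
  invisible(x)
}

#' Verify that a loop is Hamiltonian
#'
#' Walks the ops sequence from the start permutation and checks that all
#' n! intermediate permutations are distinct and that the final step
#' returns to the start.
#'
#' @param loop a `hamilton_loop`.
#' @return a list: `valid` (logical); on failure `step` (1-based index of
#'   the violating op) and `kind` (`"revisit"` or `"not-closed"`); on
#'   success `visits`, the integer vector of n! ranks in visit order
#'   beginning with the start's rank.
#' @export
verify_loop <- function(loop) {
  stopifnot(inherits(loop, "hamilton_loop"))
  m <- length(loop$ops)
  start_rank <- lex_rank(loop$start)
  visits <- integer(m)
  visits[1L] <- start_rank
  seen <- logical(factorial(loop$n))
  seen[start_rank] <- TRUE
  p <- loop$start
  for (k in seq_len(m)) {
    p <- apply_negation(p, loop$ops[k], loop$semantics)
    r <- lex_rank(p)
    if (k < m) {
      if (seen[r])
        return(list(valid = FALSE, step = k, kind = "revisit",
                    rank = r))
      seen[r] <- TRUE
      visits[k + 1L] <- r
    } else if (r != start_rank) {
      return(list(valid = FALSE, step = k, kind = "not-closed", rank = r))
    }
  }
  list(valid = TRUE, visits = visits)
}

# Plain-changes (Steinhaus-Johnson-Trotter) sequence of swap POSITIONS for
# 1..n; consecutive permutations differ by one adjacent-position swap and
# the last differs from the first the same way, closing the cycle.
.sjt_positions <- function(n) {
  if (n == 1L) return(integer(0))
  if (n == 2L) return(c(1L, 1L))           # 12 -> 21 -> 12, the 2-cycle
  inner <- .sjt_positions(n - 1L)          # positions for n-1 symbols
  out <- integer(0)
  pos_of_n <- n                            # n starts at the right end
  direction <- -1L                         # sweeping left
  for (k in seq_len(factorial(n - 1L))) {
    # sweep n across: n-1 adjacent swaps
    for (s in seq_len(n - 1L)) {
      swap_at <- if (direction < 0L) pos_of_n - 1L else pos_of_n
      out <- c(out, swap_at)
      pos_of_n <- pos_of_n + direction
    }
    direction <- -direction
    if (k < factorial(n - 1L)) {
      # inner move happens while n sits at an end; shift position if n at left
      shift <- if (pos_of_n == 1L) 1L else 0L
      out <- c(out, inner[k] + shift)
    }
  }
  # closing move of the inner cycle, n parked at the right end
  c(out, inner[factorial(n - 1L)])
}

#' Construct one Hamilton loop deterministically
#'
#' Uses the plain-change (Steinhaus-Johnson-Trotter) order, which visits
#' all n! permutations by adjacent-position swaps and closes back to the
#' identity. For value-swap semantics the position-swap sequence is
#' reversed: a sequence of transpositions multiplying to the identity is a
#' valid value-swap loop exactly when its reversal is a valid
#' position-swap loop (inversion maps one walk onto the other).
#'
#' @param n valuedness, 2..7.
#' @param semantics operator semantics, `"value"` (default) or `"position"`.
#' @return a verified `hamilton_loop` starting at the identity.
#' @examples
#' verify_loop(construct_loop(5))$valid  # TRUE, 120 steps
#' @export
construct_loop <- function(n, semantics = c("value", "position")) {
  n <- .check_n(n, min_n = 2L, max_n = 7L)
  semantics <- match.arg(semantics)
  ops <- .sjt_positions(n)
  if (semantics == "value") ops <- rev(ops)
  loop <- hamilton_loop(seq_len(n), ops, semantics = semantics)
  v <- verify_loop(loop)
  if (!v$valid) stop("internal error: constructed loop failed verification")
  loop
}

#' Reverse a Hamilton loop
#'
#' Traverses the same vertex cycle in the opposite direction; the ops
#' sequence is the reversal of the original (each operator is an
#' involution, so the reversed sequence retraces the edges backwards).
#'
#' @param loop a valid `hamilton_loop`.
#' @return the reversed `hamilton_loop` (direction flipped).
#' @export
reverse_loop <- function(loop) {
  v <- verify_loop(loop)
  if (!v$valid)
    stop(sprintf("cannot reverse an invalid loop (%s at step %d)",
                 v$kind, v$step), call. = FALSE)
  hamilton_loop(loop$start, rev(loop$ops), direction = -loop$direction,
                semantics = loop$semantics)
}

# Rotate a loop so that it starts at the vertex of the given rank.
.rotate_loop_to <- function(loop, visits, target_rank) {
  j <- match(target_rank, visits)
  m <- length(loop$ops)
  if (j == 1L) return(loop)
  ops <- c(loop$ops[j:m], loop$ops[seq_len(j - 1L)])
  hamilton_loop(lex_unrank(target_rank, loop$n), ops,
                direction = loop$direction, semantics = loop$semantics)
}

#' Canonical key of a Hamilton loop
#'
#' Directed counting rotates the cycle so that it starts at rank 1 and
#' keys on the resulting op sequence; undirected counting additionally
#' takes the lexicographically smaller of the two directions' rotated op
#' sequences, so a loop and its reversal share one key.
#'
#' @param loop a valid `hamilton_loop`.
#' @param counting `"undirected"` (default) or `"directed"`.
#' @return a character key, e.g. `"n4:1,2,3,..."`.
#' @export
canonicalize_loop <- function(loop, counting = c("undirected", "directed")) {
  counting <- match.arg(counting)
  v <- verify_loop(loop)
  if (!v$valid)
    stop(sprintf("cannot canonicalize an invalid loop (%s at step %d)",
                 v$kind, v$step), call. = FALSE)
  key_of <- function(lp, visits) {
    rot <- .rotate_loop_to(lp, visits, 1L)
    sprintf("n%d:%s", lp$n, paste(rot$ops, collapse = ","))
  }
  k1 <- key_of(loop, v$visits)
  if (counting == "directed") return(k1)
  rl <- hamilton_loop(loop$start, rev(loop$ops), direction = -loop$direction,
                      semantics = loop$semantics)
  k2 <- key_of(rl, verify_loop(rl)$visits)
  min(k1, k2)
}

#' Rotate a valid loop to a canonical start at rank 1
#'
#' @param loop a valid `hamilton_loop`.
#' @return the same directed cycle restarted at the identity permutation.
#' @export
rotate_to_rank1 <- function(loop) {
  v <- verify_loop(loop)
  if (!v$valid) stop("cannot rotate an invalid loop", call. = FALSE)
  .rotate_loop_to(loop, v$visits, 1L)
}

#' Exhaustively enumerate Hamilton loops
#'
#' Backtracking search over the permutograph, anchored at vertex rank 1 to
#' quotient out rotations. Undirected counting identifies each cycle with
#' its reversal; directed counting keeps both directions (and is exactly
#' twice the undirected count). Enumeration is refused for n >= 5, where
#' the cycle count explodes beyond desk-scale computability.
#'
#' @param n valuedness, 2..4.
#' @param counting `"undirected"` (default) or `"directed"`.
#' @param semantics operator semantics.
#' @return a list with `count`, `keys` (sorted canonical keys) and `loops`
#'   (canonical `hamilton_loop` objects, sorted by key; directed loops are
#'   rotated to start at rank 1).
#' @examples
#' enumerate_loops(4)$count            # 44
#' enumerate_loops(4, "directed")$count  # 88
#' @export
enumerate_loops <- function(n, counting = c("undirected", "directed"),
                            semantics = c("value", "position")) {
  counting <- match.arg(counting)
  semantics <- match.arg(semantics)
  if (length(n) != 1L || is.na(n) || n != as.integer(n))
    stop("valuedness `n` must be a single integer", call. = FALSE)
  n <- as.integer(n)
  if (n < 2L) stop("enumeration requires n >= 2", call. = FALSE)
  if (n >= 5L) {
    cond <- simpleError(sprintf(
      "refusing to enumerate Hamilton loops for n = %d: beyond the quadrivalent system the count is not desk-computable", n))
    class(cond) <- c("pg_refusal", class(cond))
    stop(cond)
  }
  g <- build_permutograph(n, semantics)
  size <- nrow(g$perms)
  adj <- g$adj
  # directed cycles anchored at vertex 1; each undirected cycle appears twice
  found_ops <- list()
  path_ops <- integer(size)
  used <- logical(size)
  used[1L] <- TRUE
  dfs <- function(v, depth) {
    if (depth == size) {
      back <- which(adj[v, ] == 1L)
      if (length(back) == 1L) {
        path_ops[size] <<- back
        found_ops[[length(found_ops) + 1L]] <<- path_ops
      }
      return(invisible())
    }
    for (i in seq_len(ncol(adj))) {
      w <- adj[v, i]
      if (!used[w]) {
        used[w] <<- TRUE
        path_ops[depth] <<- i
        dfs(w, depth + 1L)
        used[w] <<- FALSE
      }
    }
  }
  dfs(1L, 1L)
  loops <- lapply(found_ops, function(o)
    hamilton_loop(seq_len(n), o, semantics = semantics))
  keys <- vapply(loops, canonicalize_loop, character(1L), counting = counting)
  keep <- !duplicated(keys)
  loops <- loops[keep]
  keys <- keys[keep]
  ord <- order(keys)
  list(count = length(keys), keys = keys[ord], loops = loops[ord],
       counting = counting, n = n)
}

#' Günther matrix of a Hamilton loop
#'
#' For each choice of starting permutation (one row per rank, 1..n!), the
#' matrix records the 1-based visit order of every permutation column when
#' the cycle is entered at that start. Rows are cyclic relabelings of one
#' another: displacing the start by k positions along the loop shifts the
#' visit orders by -k modulo n!.
#'
#' @param loop a valid `hamilton_loop`.
#' @return an n! x n! integer matrix of class `guenther_matrix`; rows are
#'   start ranks, columns are permutation ranks, entries are visit orders.
#' @examples
#' gm <- guenther_matrix(construct_loop(4))
#' dim(gm)  # 24 x 24
#' @export
guenther_matrix <- function(loop) {
  v <- verify_loop(loop)
  if (!v$valid)
    stop(sprintf("cannot tabulate an invalid loop (%s at step %d)",
                 v$kind, v$step), call. = FALSE)
  m <- length(v$visits)
  # order1[col] = visit order of permutation rank `col` when starting at visits[1]
  order1 <- integer(m)
  order1[v$visits] <- seq_len(m)
  gm <- matrix(NA_integer_, m, m)
  for (r in seq_len(m)) {
    shift <- order1[r] - 1L          # start at rank r = displace by its order
    gm[r, ] <- ((order1 - 1L - shift) %% m) + 1L
  }
  dimnames(gm) <- list(start_rank = seq_len(m), perm_rank = seq_len(m))
  class(gm) <- c("guenther_matrix", class(gm))
  gm
}

#' @export
print.guenther_matrix <- function(x, ...) {
  cat(sprintf("<Guenther matrix> %d Hamilton loop rows x %d permutations\n",
              nrow(x), ncol(x)))
  print(unclass(x)[seq_len(min(6L, nrow(x))), , drop = FALSE])
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}
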