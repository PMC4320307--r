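# Independent brute-force oracles. Deliberately naive and structurally
# different from the package implementation: permutations come from
# filtering the full n^n grid, ranks from table lookup, Hamiltonian
# cycles from a vertex-sequence DFS canonicalized on vertex cycles (the
# package canonicalizes on operator sequences).

oracle_lex_perms <- function(n) {
  grid <- as.matrix(expand.grid(rev(replicate(n, seq_len(n),
                                              simplify = FALSE))))[, n:1,
                                                                   drop = FALSE]
  keep <- apply(grid, 1L, function(r) length(unique(r)) == n)
  m <- grid[keep, , drop = FALSE]
  m <- m[do.call(order, as.data.frame(m)), , drop = FALSE]
  dimnames(m) <- NULL
  storage.mode(m) <- "integer"
  m
}

oracle_rank <- function(p, tab) {
  which(apply(tab, 1L, function(r) all(r == p)))
}

oracle_value_swap <- function(p, i) {
  q <- p
  q[p == i] <- i + 1L
  q[p == i + 1L] <- i
  q
}

# adjacency list under value-swap semantics, built from the oracle pieces
oracle_adjacency <- function(n) {
  tab <- oracle_lex_perms(n)
  lapply(seq_len(nrow(tab)), function(v) {
    vapply(seq_len(n - 1L), function(i)
      oracle_rank(oracle_value_swap(tab[v, ], i), tab), integer(1L))
  })
}

# all directed Hamiltonian vertex cycles anchored at vertex 1
oracle_hamiltonian_cycles <- function(adj) {
  size <- length(adj)
  cycles <- list()
  path <- integer(size)
  path[1L] <- 1L
  used <- logical(size)
  used[1L] <- TRUE
  dfs <- function(depth) {
    v <- path[depth]
    if (depth == size) {
      if (1L %in% adj[[v]]) cycles[[length(cycles) + 1L]] <<- path
      return(invisible())
    }
    for (w in adj[[v]]) {
      if (!used[w]) {
        used[w] <<- TRUE
        path[depth + 1L] <<- w
        dfs(depth + 1L)
        used[w] <<- FALSE
      }
    }
  }
  dfs(1L)
  cycles
}

# canonical key of a vertex cycle anchored at vertex 1: the smaller of the
# forward and reversed sequence strings (undirected), or forward (directed)
oracle_cycle_key <- function(cycle, counting = "undirected") {
  fwd <- paste(cycle, collapse = ",")
  if (counting == "directed") return(fwd)
  bwd <- paste(c(cycle[1L], rev(cycle[-1L])), collapse = ",")
  min(fwd, bwd)
}

# vertex cycle of a package loop, rotated to start at rank 1
loop_vertex_key <- function(loop, counting = "undirected") {
  visits <- verify_loop(loop)$visits
  j <- match(1L, visits)
  rotated <- c(visits[j:length(visits)], visits[seq_len(j - 1L)])
  oracle_cycle_key(rotated, counting)
}

fig_loop_ops <- rep(c(1L, 2L, 3L, 2L, 3L, 2L, 1L, 2L), 3L)
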