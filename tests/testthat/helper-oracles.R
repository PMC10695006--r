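# Independent brute-force oracle for atom symmetry classes: enumerates all
# colour- and bond-preserving vertex permutations by backtracking over the
# adjacency matrix, entirely separate from the BLISS-based implementation.

brute_force_orbits <- function(smiles) {
  g <- pocvae:::mol_graph(canonical_smiles(smiles))
  bcol <- pocvae:::.bond_colors(g)
  n <- length(g$elements)
  A <- matrix(0L, n, n)
  for (k in seq_len(nrow(g$bonds))) {
    i <- g$bonds$i[k]; j <- g$bonds$j[k]
    A[i, j] <- bcol[k]; A[j, i] <- bcol[k]
  }
  vcol <- g$elements
  deg <- rowSums(A > 0)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  unite <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[ra] <<- rb
  }
  assign <- integer(n)
  used <- logical(n)
  rec <- function(i) {
    if (i > n) {
      for (v in seq_len(n)) unite(v, assign[v])
      return(invisible(NULL))
    }
    for (j in seq_len(n)) {
      if (used[j] || vcol[j] != vcol[i] || deg[j] != deg[i]) next
      ok <- TRUE
      for (k in seq_len(i - 1L)) {
        if (A[i, k] != A[j, assign[k]]) { ok <- FALSE; break }
      }
      if (!ok) next
      assign[i] <<- j; used[j] <<- TRUE
      rec(i + 1L)
      used[j] <<- FALSE
    }
  }
  rec(1L)
  roots <- vapply(seq_len(n), find, 1L)
  list(orbits = as.integer(factor(roots)), elements = g$elements)
}

brute_force_symmetric <- function(smiles) {
  o <- brute_force_orbits(smiles)
  sites <- which(o$elements == "Lr")
  stopifnot(length(sites) == 2L)
  o$orbits[sites[1]] == o$orbits[sites[2]]
}
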