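# Independent oracles used across the suite.

# Benjamini-Hochberg step-up, computed directly from the definition:
# adjusted p at rank k is min over j >= k of m * p_(j) / j, capped at 1.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- rev(cummin(rev(p[o] * m / seq_len(m))))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# One-sided Fisher enrichment p-value by brute-force hypergeometric tail
# summation over all tables with the observed margins and count >= a.
fisher_tail_oracle <- function(a, b, c, d) {
  m <- a + b            # probe A = i margin
  n <- c + d
  k <- a + c            # probe B = j margin
  hi <- min(m, k)
  sum(dhyper(a:hi, m, n, k))
}

# Small helper: a bare cell_realization from explicit point sets.
make_cell <- function(a_xyz, a_protein, b_xyz, b_protein, n_proteins,
                      a_ns = rep(FALSE, length(a_protein)),
                      b_ns = rep(FALSE, length(b_protein)),
                      a_pair = rep(0L, length(a_protein)),
                      b_pair = rep(0L, length(b_protein))) {
  structure(
    list(a = list(xyz = a_xyz, protein = as.integer(a_protein),
                  ns = a_ns, pair = as.integer(a_pair)),
         b = list(xyz = b_xyz, protein = as.integer(b_protein),
                  ns = b_ns, pair = as.integer(b_pair)),
         drawn_a = tabulate(a_protein, n_proteins),
         drawn_b = tabulate(b_protein, n_proteins),
         drawn_c = matrix(0L, n_proteins, n_proteins),
         n_proteins = as.integer(n_proteins)),
    class = "cell_realization")
}

# PLA count matrix with the full 2-protein product panel, identical rows.
panel2 <- c("P1:P1", "P1:P2", "P2:P1", "P2:P2")
rep_cells <- function(row, n_cells, panel = panel2) {
  matrix(rep(row, each = n_cells), n_cells,
         dimnames = list(sprintf("cell%d", seq_len(n_cells)), panel))
}
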