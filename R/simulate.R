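#' Realize the probe point sets of one simulated cell
#'
#' Draws the per-cell probe counts and places every probe as a point on the
#' cell sphere.  Non-interacting probe-A points of protein i are placed
#' first, then non-interacting probe-B points, then each complex i:j
#' contributes one probe-A point (label i) and one probe-B point (label j)
#' at identical coordinates, appended to both probe sets.  Every point then
#' receives an independent Bernoulli(`nonspecific_prob`) nonspecific flag
#' for its antibody; the flag does not alter the spatial placement.
#'
#' Counts are drawn per [sim_config()]'s `variance_mode`.  The caller is
#' responsible for seeding the RNG ([simulate_population()] seeds one
#' deterministic substream per cell).
#'
#' @param config a [sim_config()] object.
#' @return a `cell_realization`: lists `a` and `b` with elements `xyz`
#'   (points), `protein` (integer label), `ns` (nonspecific flag) and
#'   `pair` (complex instance id, 0 for non-interacting probes), plus the
#'   drawn counts `drawn_a`, `drawn_b` and `drawn_c`.
#' @export
realize_cell <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- length(config$protein_names)
  A <- config$probe_a_means
  B <- config$probe_b_means
  C <- config$complex_means
  if (config$variance_mode == "none") {
    At <- as.integer(round(A))
    Bt <- as.integer(round(B))
    Ct <- matrix(as.integer(round(C)), n, n)
  } else {
    At <- vapply(A, function(m) sample_nb_count(1L, m, config$nb_dispersion),
                 integer(1))
    Bt <- integer(n)
    pos <- A > 0
    Bt[pos] <- as.integer(round(B[pos] / A[pos] * At[pos]))
    Ct <- matrix(0L, n, n)
    for (i in seq_len(n)) for (j in seq_len(n))
      Ct[i, j] <- sample_nb_count(1L, C[i, j], config$nb_dispersion)
  }

  R <- config$radius
  a_xyz <- vector("list", n)
  b_xyz <- vector("list", n)
  for (i in seq_len(n)) a_xyz[[i]] <- sample_sphere_points(At[i], R)
  for (i in seq_len(n)) b_xyz[[i]] <- sample_sphere_points(Bt[i], R)
  a_protein <- rep.int(seq_len(n), At)
  b_protein <- rep.int(seq_len(n), Bt)
  a_pair <- integer(sum(At))
  b_pair <- integer(sum(Bt))

  # complex points: one coincident A/B pair per instance
  pair_id <- 0L
  cx_xyz <- vector("list", n * n)
  cx_a_protein <- cx_b_protein <- cx_pair <- vector("list", n * n)
  k <- 0L
  for (i in seq_len(n)) for (j in seq_len(n)) {
    m <- Ct[i, j]
    if (m == 0L) next
    k <- k + 1L
    pts <- sample_sphere_points(m, R)
    cx_xyz[[k]] <- pts
    cx_a_protein[[k]] <- rep.int(i, m)
    cx_b_protein[[k]] <- rep.int(j, m)
    cx_pair[[k]] <- pair_id + seq_len(m)
    pair_id <- pair_id + m
  }
  if (k > 0L) {
    cxm <- do.call(rbind, cx_xyz[seq_len(k)])
    a_xyz <- rbind(do.call(rbind, a_xyz), cxm)
    b_xyz <- rbind(do.call(rbind, b_xyz), cxm)
    a_protein <- c(a_protein, unlist(cx_a_protein[seq_len(k)]))
    b_protein <- c(b_protein, unlist(cx_b_protein[seq_len(k)]))
    a_pair <- c(a_pair, unlist(cx_pair[seq_len(k)]))
    b_pair <- c(b_pair, unlist(cx_pair[seq_len(k)]))
  } else {
    a_xyz <- do.call(rbind, a_xyz)
    b_xyz <- do.call(rbind, b_xyz)
  }

  p_ns <- config$nonspecific_prob
  a_ns <- runif(length(a_protein)) < p_ns[a_protein]
  b_ns <- runif(length(b_protein)) < p_ns[b_protein]

  structure(
    list(a = list(xyz = a_xyz, protein = a_protein, ns = a_ns, pair = a_pair),
         b = list(xyz = b_xyz, protein = b_protein, ns = b_ns, pair = b_pair),
         drawn_a = At, drawn_b = Bt, drawn_c = Ct,
         n_proteins = n),
    class = "cell_realization")
}

# Candidate (A, B) pairs with chord distance <= d, as a 2-column index
# matrix in canonical (A index, then B index) order.  The binned search
# partitions points by floor(z / d) so only neighbouring slabs need a full
# distance computation; the candidate set is identical to the brute-force
# all-pairs search (|dz| <= d is implied by distance <= d).
find_candidate_pairs <- function(a_xyz, b_xyz, d, method = c("binned",
                                                             "brute"),
                                 dense_limit = 3e4) {
  method <- match.arg(method)
  na <- nrow(a_xyz); nb <- nrow(b_xyz)
  if (na == 0L || nb == 0L)
    return(matrix(integer(0), 0L, 2L))
  d2 <- d * d
  if (method == "brute") {
    cross <- outer(rowSums(a_xyz^2), rowSums(b_xyz^2), "+") -
      2 * tcrossprod(a_xyz, b_xyz)
    hit <- which(cross <= d2, arr.ind = TRUE, useNames = FALSE)
    pairs <- hit
  } else {
    a_sq <- rowSums(a_xyz^2)
    b_sq <- rowSums(b_xyz^2)
    res_a <- list(); res_b <- list(); r <- 0L
    dense <- function(ai, bi) {
      cross <- outer(a_sq[ai], b_sq[bi], "+") -
        2 * tcrossprod(a_xyz[ai, , drop = FALSE],
                       b_xyz[bi, , drop = FALSE])
      hit <- which(cross <= d2, arr.ind = TRUE, useNames = FALSE)
      if (nrow(hit) > 0L) {
        r <<- r + 1L
        res_a[[r]] <<- ai[hit[, 1L]]
        res_b[[r]] <<- bi[hit[, 2L]]
      }
    }
    # a pair within distance d differs by at most d in every coordinate,
    # so slabs of width >= d with +-1 neighbours cover all candidates
    neighbours <- function(idx, key) {
      unlist(idx[as.character(c(key - 1L, key, key + 1L))],
             use.names = FALSE)
    }
    abin <- as.integer(floor(a_xyz[, 3L] / d))
    bbin <- as.integer(floor(b_xyz[, 3L] / d))
    bidx <- split(seq_len(nb), bbin)
    wx <- 4 * d                      # second-level slab width on x
    for (grp in split(seq_len(na), abin)) {
      cand <- neighbours(bidx, abin[grp[1L]])
      if (length(cand) == 0L) next
      if (length(grp) * length(cand) <= dense_limit) {
        dense(grp, cand)
      } else {                       # large slab pair: subdivide on x
        bx <- split(cand, as.integer(floor(b_xyz[cand, 1L] / wx)))
        ax <- split(grp, as.integer(floor(a_xyz[grp, 1L] / wx)))
        for (g2 in ax) {
          c2 <- neighbours(bx, as.integer(floor(a_xyz[g2[1L], 1L] / wx)))
          if (length(c2)) dense(g2, c2)
        }
      }
    }
    if (r == 0L) return(matrix(integer(0), 0L, 2L))
    pairs <- cbind(unlist(res_a), unlist(res_b))
  }
  pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
}

#' Ligate the probes of one cell
#'
#' Computes all probe A / probe B pairs whose 3-D Euclidean (chord) distance
#' is at most `d`, visits them in uniformly random order, and greedily
#' ligates each pair whose two probes are still free: each probe A and each
#' probe B is used at most once.  When one probe A lies within `d` of
#' several free probes B, the random visiting order picks one of them at
#' random.  Ligated pairs are tallied into PLA product counts by the two
#' probes' protein labels and into binding categories from their
#' nonspecific flags (neither flagged = both-specific, one = one-specific,
#' both = nonspecific).  Unligated probes are returned as non-proximal
#' ("free oligo") counts.
#'
#' @param cell a [realize_cell()] result.
#' @param d ligation distance (> 0), in the same units as the coordinates.
#' @param matching `"binned"` (z-slab spatial index, default) or `"brute"`
#'   (all-pairs).  Both give identical results under the same RNG state.
#' @return list with `x` (n x n PLA count matrix, `x[i, j]` = count of
#'   product i:j), category count matrices `both_specific`, `one_specific`,
#'   `nonspecific`, `complex_ligated` (ligations where both probes came
#'   from the same complex instance), and non-proximal per-protein counts
#'   `np_a`, `np_b`.
#' @export
ligate <- function(cell, d, matching = c("binned", "brute")) {
  stopifnot(inherits(cell, "cell_realization"), d > 0)
  matching <- match.arg(matching)
  n <- cell$n_proteins
  na <- length(cell$a$protein); nb <- length(cell$b$protein)
  pairs <- find_candidate_pairs(cell$a$xyz, cell$b$xyz, d, matching)
  np <- nrow(pairs)
  zero <- matrix(0L, n, n)
  out <- list(x = zero, both_specific = zero, one_specific = zero,
              nonspecific = zero, complex_ligated = zero,
              np_a = tabulate(cell$a$protein, n),
              np_b = tabulate(cell$b$protein, n))
  if (np == 0L) return(out)
  ord <- sample.int(np)
  ia <- pairs[ord, 1L]; ib <- pairs[ord, 2L]
  used_a <- logical(na); used_b <- logical(nb)
  keep <- logical(np)
  for (k in seq_len(np)) {
    a <- ia[k]; b <- ib[k]
    if (used_a[a] || used_b[b]) next
    used_a[a] <- TRUE; used_b[b] <- TRUE
    keep[k] <- TRUE
  }
  ma <- ia[keep]; mb <- ib[keep]
  pa <- cell$a$protein[ma]; pb <- cell$b$protein[mb]
  pidx <- (pa - 1L) * n + pb        # row-major product index for [i, j]
  tally <- function(sel) matrix(tabulate(pidx[sel], n * n), n, n,
                                byrow = TRUE)
  nsa <- cell$a$ns[ma]; nsb <- cell$b$ns[mb]
  out$x <- tally(TRUE)
  out$both_specific <- tally(!nsa & !nsb)
  out$one_specific <- tally(xor(nsa, nsb))
  out$nonspecific <- tally(nsa & nsb)
  same <- cell$a$pair[ma] > 0L & cell$a$pair[ma] == cell$b$pair[mb]
  out$complex_ligated <- tally(same)
  out$np_a <- tabulate(cell$a$protein[!used_a], n)
  out$np_b <- tabulate(cell$b$protein[!used_b], n)
  out
}

# deterministic per-cell seed derived from the population seed, so earlier
# cells are unchanged when n_cells grows
cell_seed <- function(seed, t) {
  as.integer((as.double(seed) + 48271 * as.double(t)) %% 2147483647)
}

#' Simulate a Prox-seq cell population
#'
#' Repeats [realize_cell()] and [ligate()] for `config$n_cells` cells, each
#' on its own deterministic RNG substream derived from `config$seed`.  The
#' run is fully reproducible, and earlier cells are unchanged if `n_cells`
#' is increased.
#'
#' @param config a [sim_config()] object.
#' @param matching candidate-pair search passed to [ligate()].
#' @return an object of class `proxseq_sim` with components
#'   \describe{
#'     \item{pla}{cells x PLA products UMI count matrix; columns named
#'       `"<proteinA>:<proteinB>"` over all ordered pairs.}
#'     \item{nonproximal}{cells x 2n matrix of unligated probe counts;
#'       columns `"<p>:free_oligo_B"` hold the non-proximal probe-A count
#'       of protein p and `"free_oligo_A:<p>"` the non-proximal probe-B
#'       count, matching the free-oligo naming of the assay.}
#'     \item{truth}{cells x products matrix of drawn complex counts
#'       `c_ij(t)` (ground truth, pre-ligation).}
#'     \item{complex_ligated}{cells x products matrix of ligations whose
#'       two probes came from the same complex instance; the difference to
#'       `truth` is the competition loss.}
#'     \item{categories}{list of three cells x products matrices splitting
#'       `pla` by binding category.}
#'     \item{config}{the input configuration.}
#'   }
#' @examples
#' cfg <- sim_config(probe_a_means = c(300, 200), n_cells = 5, seed = 7)
#' sim <- simulate_population(cfg)
#' dim(sim$pla)
#' @export
simulate_population <- function(config, matching = c("binned", "brute")) {
  stopifnot(inherits(config, "sim_config"))
  matching <- match.arg(matching)
  n <- length(config$protein_names)
  nc <- config$n_cells
  prods <- as.vector(t(outer(config$protein_names, config$protein_names,
                             paste, sep = ":")))
  cells <- sprintf("cell%d", seq_len(nc))
  P <- n * n
  pla <- truth <- cxl <- matrix(0L, nc, P, dimnames = list(cells, prods))
  cat_bs <- cat_os <- cat_ns <- matrix(0L, nc, P,
                                       dimnames = list(cells, prods))
  np <- matrix(0L, nc, 2L * n,
               dimnames = list(cells,
                               c(paste0(config$protein_names,
                                        ":free_oligo_B"),
                                 paste0("free_oligo_A:",
                                        config$protein_names))))
  for (t in seq_len(nc)) {
    set.seed(cell_seed(config$seed, t))
    cell <- realize_cell(config)
    lig <- ligate(cell, config$ligation_distance, matching)
    pla[t, ] <- as.vector(t(lig$x))
    truth[t, ] <- as.vector(t(cell$drawn_c))
    cxl[t, ] <- as.vector(t(lig$complex_ligated))
    cat_bs[t, ] <- as.vector(t(lig$both_specific))
    cat_os[t, ] <- as.vector(t(lig$one_specific))
    cat_ns[t, ] <- as.vector(t(lig$nonspecific))
    np[t, ] <- c(lig$np_a, lig$np_b)
  }
  structure(
    list(pla = pla, nonproximal = np, truth = truth,
         complex_ligated = cxl,
         categories = list(both_specific = cat_bs, one_specific = cat_os,
                           nonspecific = cat_ns),
         config = config),
    class = "proxseq_sim")
}

#' @export
print.proxseq_sim <- function(x, ...) {
  cat("Simulated Prox-seq population:", nrow(x$pla), "cells x",
      ncol(x$pla), "PLA products\n")
  cat("  total UMIs:", sum(x$pla), " (complex-derived:",
      sum(x$complex_ligated), ")\n")
  invisible(x)
}
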