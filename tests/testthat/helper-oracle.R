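# Independent brute-force oracle: recomputes degrees and scores from a
# dense adjacency matrix, sharing no code with the package's degree or
# exclusion logic.

# Adjacency matrix over ALL nodes (attachments included), entry = bond order.
oracle_adjacency <- function(g) {
  n <- nrow(g$nodes)
  A <- matrix(0, n, n)
  if (nrow(g$edges) > 0) {
    for (i in seq_len(nrow(g$edges))) {
      A[g$edges$from[i], g$edges$to[i]] <- g$edges$order[i]
      A[g$edges$to[i], g$edges$from[i]] <- g$edges$order[i]
    }
  }
  A
}

# MC1/MC2 by direct matrix scan.
oracle_scores <- function(g) {
  A <- oracle_adjacency(g)
  real <- which(!g$nodes$is_attachment)
  deg <- rowSums(A > 0)                    # neighbour count, any bond order
  hac <- length(real)
  fdv <- sum(deg[real] == 2) / hac
  excluded <- logical(nrow(A))
  for (c_idx in real) {
    if (g$nodes$element[c_idx] != "C") next
    nb <- which(A[c_idx, ] > 0)
    nb_real <- setdiff(nb, which(g$nodes$is_attachment))
    dbl_o <- nb_real[A[c_idx, nb_real] == 2 & g$nodes$element[nb_real] == "O"]
    x <- nb_real[A[c_idx, nb_real] == 1 & g$nodes$element[nb_real] %in% c("N", "O")]
    if (length(dbl_o) >= 1 && length(x) >= 1) {
      excluded[c_idx] <- TRUE
      excluded[min(dbl_o)] <- TRUE
    }
  }
  nondiv <- real[deg[real] != 2]
  list(hac = hac, mc1 = 1 - fdv, mc2 = sum(!excluded[nondiv]))
}

# Random connected graph on <= n_max nodes: a random tree plus extra edges.
oracle_random_graph <- function(n, seed, extra_edges = 0L) {
  set.seed(seed)
  nodes <- tibble::tibble(node_id = seq_len(n), element = "C",
                          formal_charge = 0L, is_attachment = FALSE)
  edges <- if (n > 1) {
    tibble::tibble(from = vapply(2:n, function(i) sample.int(i - 1L, 1L), integer(1)),
                   to = 2:n, order = 1)
  } else {
    tibble::tibble(from = integer(), to = integer(), order = numeric())
  }
  if (extra_edges > 0 && n > 2) {
    have <- paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to))
    for (i in seq_len(extra_edges)) {
      cand <- sort(sample.int(n, 2))
      key <- paste(cand[1], cand[2])
      if (!key %in% have) {
        edges <- dplyr::bind_rows(edges, tibble::tibble(from = cand[1], to = cand[2], order = 1))
        have <- c(have, key)
      }
    }
  }
  mol_graph(nodes, edges, source = list(text = sprintf("random(%d,%d)", n, seed),
                                        fmt = "fixture"))
}

# Brute-force pairwise-complete Pearson r^2 via the covariance formula.
oracle_r2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  sxx <- sum((x - mean(x))^2)
  syy <- sum((y - mean(y))^2)
  (sxy / sqrt(sxx * syy))^2
}

# Repeat units used for polymer-convention tests (paper-named polymers).
REPEAT_UNITS <- c(
  pla = "[*]OC(C)C([*])=O",
  pp = "[*]CC(C)[*]",
  kevlar = "[*]Nc1ccc(NC(=O)c2ccc(C([*])=O)cc2)cc1",
  pet = "[*]OCCOC(=O)c1ccc(C([*])=O)cc1",
  ps = "[*]CC([*])c1ccccc1",
  nylon6 = "[*]NCCCCCC([*])=O",
  pe = "[*]CC[*]",
  peg = "[*]OCC[*]"
)
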