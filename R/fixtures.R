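# Deterministic synthetic-structure generators with closed-form expected
# scores. Used by tests and by the comparison harness; also exportable as
# SMILES line files.

hydrocarbon_nodes <- function(n) {
  tibble::tibble(node_id = seq_len(n), element = "C",
                 formal_charge = 0L, is_attachment = FALSE)
}

#' Generate a synthetic fixture structure
#'
#' Deterministic generator for graphs with known complexity: the same
#' `(kind, n, seed)` always yields an identical structure. For `chain`,
#' `cycle` and `star` the closed-form expected scores are returned
#' alongside the graph (chain of n: MC1 = 2/n, MC2 = 2; cycle: MC1 = 0,
#' MC2 = 0; star of n: MC1 = 1, MC2 = n).
#'
#' @param kind `"chain"`, `"cycle"`, `"star"`, `"random_tree"`,
#'   `"decorated"` or `"oligomer"`.
#' @param n Size parameter: total node count (chain >= 2, cycle >= 3,
#'   star >= 2, random_tree >= 1, decorated >= 2).
#' @param seed RNG seed for the random kinds (local to the call).
#' @param unit Repeat-unit SMILES with two attachment points (oligomer).
#' @param k Repeat count (oligomer, >= 1).
#' @return A list with `graph` (a [mol_graph()]) and `expected` (a tibble
#'   with `mc1`, `mc2`, `hac` for the closed-form kinds, otherwise `NULL`).
#' @examples
#' \donttest{
#' generate_fixture("chain", 10)$expected   # mc1 0.2, mc2 2
#' }
#' @export
generate_fixture <- function(kind = c("chain", "cycle", "star", "random_tree",
                                      "decorated", "oligomer"),
                             n = NULL, seed = 1L, unit = NULL, k = NULL) {
  kind <- match.arg(kind)
  chk <- function(cond, msg) if (!cond) rlang::abort(msg, class = "molcomplex_fixture_error")
  out <- switch(kind,
    chain = {
      chk(!is.null(n) && n >= 2, "chain requires n >= 2")
      edges <- tibble::tibble(from = seq_len(n - 1), to = seq_len(n - 1) + 1L, order = 1)
      list(graph = mol_graph(hydrocarbon_nodes(n), edges,
                             source = list(text = sprintf("chain(%d)", n), fmt = "fixture")),
           expected = tibble::tibble(mc1 = 2 / n, mc2 = 2L, hac = as.integer(n)))
    },
    cycle = {
      chk(!is.null(n) && n >= 3, "cycle requires n >= 3")
      edges <- tibble::tibble(from = seq_len(n), to = c(seq_len(n - 1) + 1L, 1L), order = 1)
      list(graph = mol_graph(hydrocarbon_nodes(n), edges,
                             source = list(text = sprintf("cycle(%d)", n), fmt = "fixture")),
           expected = tibble::tibble(mc1 = 0, mc2 = 0L, hac = as.integer(n)))
    },
    star = {
      chk(!is.null(n) && n >= 2, "star requires n >= 2")
      edges <- tibble::tibble(from = 1L, to = seq_len(n)[-1], order = 1)
      # n = 3 degenerates to a 3-chain: the hub is divalent, not a branch point
      expected <- if (n == 3) {
        tibble::tibble(mc1 = 2 / 3, mc2 = 2L, hac = 3L)
      } else {
        tibble::tibble(mc1 = 1, mc2 = as.integer(n), hac = as.integer(n))
      }
      list(graph = mol_graph(hydrocarbon_nodes(n), edges,
                             source = list(text = sprintf("star(%d)", n), fmt = "fixture")),
           expected = expected)
    },
    random_tree = {
      chk(!is.null(n) && n >= 1, "random_tree requires n >= 1")
      list(graph = random_tree_graph(n, seed), expected = NULL)
    },
    decorated = {
      chk(!is.null(n) && n >= 2, "decorated requires n >= 2")
      list(graph = decorated_graph(n, seed), expected = NULL)
    },
    oligomer = {
      chk(!is.null(unit) && !is.null(k), "oligomer requires unit and k")
      list(graph = oligomerize(unit, k), expected = NULL)
    }
  )
  out
}

# Uniform random recursive tree: node i attaches to a uniformly chosen
# earlier node. Seeded and local (does not disturb the caller's RNG).
random_tree_graph <- function(n, seed) {
  parents <- if (n > 1) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    }, add = TRUE)
    set.seed(seed)
    vapply(2:n, function(i) sample.int(i - 1L, 1L), integer(1))
  } else integer(0)
  edges <- tibble::tibble(from = parents, to = seq_len(n)[-1], order = 1)
  if (n == 1) edges <- tibble::tibble(from = integer(), to = integer(), order = numeric())
  mol_graph(hydrocarbon_nodes(n), edges,
            source = list(text = sprintf("random_tree(%d, seed=%d)", n, seed),
                          fmt = "fixture"))
}

# Random tree decorated with heteroatoms and double bonds, valence-safe so
# it can round-trip through SMILES. Used for hydrocarbon-reduction tests.
decorated_graph <- function(n, seed) {
  g <- random_tree_graph(n, seed)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed + 104729L)
  deg <- node_degrees(g$nodes, g$edges)
  max_valence <- c(C = 4L, N = 3L, O = 2L, S = 2L, F = 1L, Cl = 1L)
  elems <- names(max_valence)
  elem <- vapply(g$nodes$node_id, function(v) {
    ok <- elems[max_valence >= deg[as.character(v)]]
    if (length(ok) == 0) return("C")  # hub degree > 4: leave it carbon
    ok[sample.int(length(ok), 1L)]
  }, character(1))
  g$nodes$element <- elem
  # promote some bonds to double where both endpoints have spare valence
  spare <- max_valence[elem] - deg
  if (nrow(g$edges) > 0) {
    for (i in sample(seq_len(nrow(g$edges)))) {
      a <- g$edges$from[i]; b <- g$edges$to[i]
      if (spare[a] >= 1 && spare[b] >= 1 && stats::runif(1) < 0.3) {
        g$edges$order[i] <- 2
        spare[a] <- spare[a] - 1L
        spare[b] <- spare[b] - 1L
      }
    }
  }
  g$source$text <- sprintf("decorated(%d, seed=%d)", n, seed)
  g
}

#' Concatenate a polymer repeat unit into an oligomer
#'
#' Builds a k-mer by joining copies of a two-attachment repeat unit head to
#' tail: each junction bonds the atom adjacent to one copy's exit
#' attachment to the atom adjacent to the next copy's entry attachment.
#' Chain-end attachments are removed, i.e. the ends are hydrogen-capped, so
#' end units intentionally differ from interior units. The per-node unit
#' index is kept in the `unit` column of the nodes table, so the interior
#' units that validate the attachment-point convention can be read back.
#'
#' @param unit Repeat-unit SMILES with exactly two attachment points.
#' @param k Number of repeats (>= 1).
#' @return A [mol_graph()] whose nodes carry a `unit` column (1..k).
#' @examples
#' \donttest{
#' oligomerize("[*]OCC[*]", 5)  # a 15-atom PEG chain
#' }
#' @export
oligomerize <- function(unit, k) {
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k != round(k)) {
    rlang::abort("k must be a positive integer", class = "molcomplex_fixture_error")
  }
  g <- parse_structure(unit, fmt = "smiles")
  att <- g$nodes$node_id[g$nodes$is_attachment]
  if (length(att) != 2) {
    rlang::abort(sprintf("repeat unit must have exactly 2 attachment points, found %d",
                         length(att)), class = "molcomplex_fixture_error")
  }
  # atoms bonded to the entry (lower-id) and exit attachment of the unit
  neighbour_of <- function(a) {
    nb <- c(g$edges$to[g$edges$from == a], g$edges$from[g$edges$to == a])
    nb[1]
  }
  entry <- neighbour_of(min(att))
  exit <- neighbour_of(max(att))
  real <- g$nodes[!g$nodes$is_attachment, ]
  real_edges <- dplyr::filter(g$edges, !.data$from %in% att, !.data$to %in% att)
  n_real <- nrow(real)
  remap <- stats::setNames(seq_len(n_real), as.character(real$node_id))
  nodes <- purrr::map(seq_len(k), function(i) {
    u <- real
    u$node_id <- unname(remap[as.character(u$node_id)]) + (i - 1L) * n_real
    u$unit <- i
    u
  })
  edges <- purrr::map(seq_len(k), function(i) {
    e <- real_edges
    e$from <- unname(remap[as.character(e$from)]) + (i - 1L) * n_real
    e$to <- unname(remap[as.character(e$to)]) + (i - 1L) * n_real
    e
  })
  junctions <- if (k > 1) {
    tibble::tibble(
      from = unname(remap[as.character(exit)]) + (seq_len(k - 1) - 1L) * n_real,
      to = unname(remap[as.character(entry)]) + seq_len(k - 1) * n_real,
      order = 1
    )
  } else NULL
  mol_graph(dplyr::bind_rows(nodes), dplyr::bind_rows(c(edges, list(junctions))),
            source = list(text = sprintf("%s x%d", unit, k), fmt = "oligomer"))
}

#' Degree multiset of one unit inside an oligomer
#'
#' Reads back the degrees of the atoms belonging to unit `which` of an
#' oligomer built by [oligomerize()]. For any interior unit of a k >= 3
#' oligomer this equals the attachment-mode degree multiset of the lone
#' repeat unit — the correctness argument for scoring polymers by their
#' repeat unit with attachment points.
#'
#' @param olig A [mol_graph()] from [oligomerize()].
#' @param which Unit index (1..k).
#' @return A sorted integer vector of degrees.
#' @export
unit_degree_multiset <- function(olig, which) {
  stopifnot(inherits(olig, "mol_graph"), "unit" %in% names(olig$nodes))
  ids <- olig$nodes$node_id[olig$nodes$unit == which]
  if (length(ids) == 0) {
    rlang::abort("no such unit in oligomer", class = "molcomplex_fixture_error")
  }
  deg <- node_degrees(olig$nodes, olig$edges)
  sort(unname(deg[as.character(ids)]))
}

#' Build a fixture score table for the comparison harness
#'
#' Generates a reproducible mixed set of fixture structures (chains,
#' cycles, stars, random trees) and scores them, yielding a
#' molecules-by-measures table suitable for [pairwise_r2()] and
#' [distribution_summary()].
#'
#' @param n_each Number of structures per kind.
#' @param seed RNG seed controlling the random trees.
#' @return A tibble of complexity records with a `kind` column.
#' @export
fixture_score_table <- function(n_each = 25, seed = 1L) {
  specs <- dplyr::bind_rows(
    tibble::tibble(kind = "chain", n = seq(2, length.out = n_each)),
    tibble::tibble(kind = "cycle", n = seq(3, length.out = n_each)),
    tibble::tibble(kind = "star", n = seq(2, length.out = n_each)),
    tibble::tibble(kind = "random_tree", n = 4 + (seq_len(n_each) %% 9))
  )
  recs <- purrr::pmap(specs, function(kind, n) {
    g <- generate_fixture(kind, n = n, seed = seed + n)$graph
    prof <- degree_profile(g)
    excl <- detect_excluded_carbonyls(g, prof)
    fdv <- length(prof$divalent_ids) / prof$hac
    tibble::tibble(kind = kind, hac = prof$hac, fdv = fdv, mc1 = 1 - fdv,
                   mc2 = mc2(prof, excl))
  })
  dplyr::bind_rows(recs) |>
    dplyr::mutate(id = sprintf("%s_%02d", .data$kind, dplyr::row_number()),
                  .by = "kind") |>
    dplyr::select("id", "kind", "hac", "fdv", "mc1", "mc2")
}

#' Export fixtures as a SMILES line file
#'
#' Writes one SMILES per line (tab-separated id column) for a list of
#' fixture graphs, for CLI round-trip tests.
#'
#' @param graphs A list of [mol_graph()] objects.
#' @param path Output file path.
#' @param ids Optional identifiers (defaults to `fix_1`, `fix_2`, ...).
#' @return `path`, invisibly.
#' @export
write_fixture_smiles <- function(graphs, path, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("fix_%d", seq_along(graphs))
  smi <- vapply(graphs, mol_graph_to_smiles, character(1))
  readr::write_lines(paste(smi, ids, sep = "\t"), path)
  invisible(path)
}
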