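# MC1/MC2 scoring and the carbonyl exclusion rule.

test_that("carbonyl exclusion matches carboxyl derivatives only", {
  # one (C, O) pair per group for each carboxyl derivative
  carboxyl <- c(
    amide = "CC(N)=O",
    ester = "CC(=O)OC",
    acid = "CC(=O)O",
    carbamate = "CNC(=O)OC",
    carbonate = "COC(=O)OC",
    urea = "CNC(=O)NC"
  )
  for (nm in names(carboxyl)) {
    g <- parse_structure(carboxyl[[nm]])
    excl <- detect_excluded_carbonyls(g)
    expect_equal(nrow(excl$matched_groups), 1, info = nm)
    expect_length(excl$excluded_ids, 2)
    elems <- g$nodes$element[excl$excluded_ids]
    expect_setequal(elems, c("C", "O"))
  }

  # counted groups: no exclusion
  counted <- c(
    ketone = "CC(C)=O",
    aldehyde = "CC=O",
    thioester = "CC(=O)SC",
    thione = "CC(=S)C",
    sulfonamide = "CS(=O)(=O)N",
    amidine = "CC(=N)N",
    guanidine = "NC(=N)N"
  )
  for (nm in names(counted)) {
    excl <- detect_excluded_carbonyls(parse_structure(counted[[nm]]))
    expect_equal(length(excl$excluded_ids), 0, info = nm)
  }
})

test_that("a carbon matching through several X neighbours is excluded once", {
  # urea-like: C(=O) flanked by two N; malonamide-style double match on C
  g <- parse_structure("NC(N)=O")
  excl <- detect_excluded_carbonyls(g)
  expect_length(excl$excluded_ids, 2)
  expect_equal(nrow(excl$matched_groups), 1)
  expect_length(excl$matched_groups$x_ids[[1]], 2)

  # carboxylate anion treated like the acid
  excl_anion <- detect_excluded_carbonyls(parse_structure("CC(=O)[O-]"))
  expect_length(excl_anion$excluded_ids, 2)
})

test_that("excluded atoms are never sulfur or phosphorus", {
  for (smi in c("CC(=O)SC", "CP(=O)(O)O", "CS(=O)(=O)O", "O=C(O)CSC(=O)C")) {
    g <- parse_structure(smi)
    excl <- detect_excluded_carbonyls(g)
    expect_false(any(g$nodes$element[excl$excluded_ids] %in% c("S", "P")),
                 info = smi)
  }
})

test_that("mc1 and mc2 reproduce hand-counted examples", {
  expect_equal(mc1(parse_structure("OC(=O)C(F)(F)F")), 1)       # TFA
  expect_equal(mc1(parse_structure("[*]CC(C)[*]")), 2 / 3)      # polypropylene
  expect_equal(mc1(parse_structure("C1CCCCC1")), 0)             # cyclohexane

  expect_equal(mc2(parse_structure("CCCCCC")), 2)               # hexane: 2 ends
  expect_equal(mc2(parse_structure("C1CCCCC1")), 0)             # cyclohexane
  # acetamide: CH3 and NH2 counted, C=O pair excluded
  g <- parse_structure("CC(N)=O")
  expect_equal(mc2(degree_profile(g), detect_excluded_carbonyls(g)), 2)
  # methane: smallest molecule scores as-is
  expect_equal(mc1(parse_structure("C")), 1)
  expect_equal(mc2(parse_structure("C")), 1)
})

test_that("record fields are internally consistent", {
  rec <- score_molecule("CC(=O)Nc1ccc(O)cc1", id = "paracetamol")
  expect_equal(rec$mc1, 1 - rec$fdv)
  expect_gte(rec$mc2, 0)
  expect_lte(rec$mc2, rec$hac)
  expect_equal(rec$status, "ok")
  expect_equal(rec$hac, 11)
  expect_equal(rec$n_excluded, 2)

  # failure path yields a skip record, not an error
  bad <- score_molecule("not_a_smiles")
  expect_equal(bad$status, "skip")
  expect_match(bad$message, "parse failure")
  expect_true(is.na(bad$mc1))

  # small-molecule warning threshold annotates the message
  warned <- score_molecule("CC(C)(C)O", min_hac_warn = 10)
  expect_equal(warned$status, "ok")
  expect_match(warned$message, "uninformative")
})

test_that("closed forms hold for chains and cycles up to n = 50", {
  for (n in 2:50) {
    g <- generate_fixture("chain", n)$graph
    expect_equal(mc1(g), 2 / n)
    expect_equal(mc2(g), 2)
  }
  for (n in 3:50) {
    g <- generate_fixture("cycle", n)$graph
    expect_equal(mc1(g), 0)
    expect_equal(mc2(g), 0)
  }
  # stars: MC1 = 1 except n = 3, where the "star" degenerates to a 3-chain
  for (n in c(2, 4:50)) {
    expect_equal(mc1(generate_fixture("star", n)$graph), 1)
  }
  expect_equal(mc1(generate_fixture("star", 3)$graph), 2 / 3)
})

test_that("inserting a divalent node decreases MC1 and fixes MC2", {
  # subdividing any edge adds one divalent node: MC1 strictly down, MC2 same
  for (seed in 1:15) {
    g <- oracle_random_graph(4 + seed %% 8, seed, extra_edges = seed %% 2)
    e <- 1 + seed %% nrow(g$edges)
    new_id <- nrow(g$nodes) + 1L
    nodes <- dplyr::bind_rows(g$nodes, tibble::tibble(
      node_id = new_id, element = "C", formal_charge = 0L, is_attachment = FALSE))
    edges <- dplyr::bind_rows(
      g$edges[-e, ],
      tibble::tibble(from = c(g$edges$from[e], new_id),
                     to = c(new_id, g$edges$to[e]), order = 1))
    g2 <- mol_graph(nodes, edges, source = g$source)
    if (mc1(g) > 0) {
      expect_lt(mc1(g2), mc1(g))  # k/n > k/(n+1) needs k >= 1 non-divalent nodes
    } else {
      expect_equal(mc1(g2), 0)
    }
    expect_equal(mc2(g2), mc2(g))
  }
})

test_that("attaching a pendant node to a divalent node raises MC2 by 2", {
  for (seed in 1:15) {
    g <- generate_fixture("chain", 4 + seed %% 10)$graph
    prof <- degree_profile(g)
    target <- prof$divalent_ids[1 + seed %% length(prof$divalent_ids)]
    new_id <- nrow(g$nodes) + 1L
    nodes <- dplyr::bind_rows(g$nodes, tibble::tibble(
      node_id = new_id, element = "C", formal_charge = 0L, is_attachment = FALSE))
    edges <- dplyr::bind_rows(g$edges,
                              tibble::tibble(from = target, to = new_id, order = 1))
    g2 <- mol_graph(nodes, edges, source = g$source)
    expect_equal(mc2(g2), mc2(g) + 2)  # new branch point + new monovalent node
  }
})

test_that("pipeline scores equal the brute-force adjacency oracle", {
  n_cases <- 0
  for (seed in 1:120) {
    n <- 2 + seed %% 11                      # up to 12 nodes
    for (extra in 0:1) {
      g <- oracle_random_graph(n, seed * 7 + extra, extra_edges = extra * (seed %% 3))
      ref <- oracle_scores(g)
      prof <- degree_profile(g)
      expect_equal(mc1(prof), ref$mc1)
      expect_equal(mc2(prof, detect_excluded_carbonyls(g, prof)), ref$mc2)
      n_cases <- n_cases + 1
    }
  }
  expect_gte(n_cases, 200)
})

test_that("oracle agreement extends to heteroatom-decorated molecules", {
  for (seed in 1:30) {
    g <- generate_fixture("decorated", 5 + seed %% 8, seed = seed)$graph
    ref <- oracle_scores(g)
    prof <- degree_profile(g)
    expect_equal(mc1(prof), ref$mc1)
    expect_equal(mc2(prof, detect_excluded_carbonyls(g, prof)), ref$mc2)
  }
})

test_that("MC1 is invariant under the hydrocarbon reduction, and MC2 when no carbonyl is excluded", {
  for (seed in 1:25) {
    g <- generate_fixture("decorated", 4 + seed %% 9, seed = seed)$graph
    h <- hydrocarbon_reduction(g)
    expect_equal(mc1(h), mc1(g))
    if (length(detect_excluded_carbonyls(g)$excluded_ids) == 0) {
      expect_equal(mc2(h), mc2(g))
    }
  }
})

test_that("batch scoring preserves input order and honours fail policy", {
  df <- tibble::tibble(name = c("tfa", "peg", "bad"),
                       smiles = c("OC(=O)C(F)(F)F", "[*]OCC[*]", "not_a_smiles"))
  res <- mc_score(df, id_col = "name")
  expect_equal(res$id, df$name)
  expect_equal(res$status, c("ok", "ok", "skip"))
  expect_equal(round(res$mc1[1:2], 2), c(1, 0))

  expect_error(mc_score(df, id_col = "name", fail = "abort"),
               class = "molcomplex_score_error")
  expect_error(mc_score(df, smiles_col = "nope"),
               class = "molcomplex_input_error")

  # bare character vector input
  vec <- mc_score(c("CCO", "CCC"))
  expect_equal(vec$id, c("1", "2"))
})

test_that("the published exclusion pattern is a documented SMARTS string", {
  pat <- mc2_exclusion_pattern()
  expect_type(pat, "character")
  expect_match(pat, "=\\[OX1\\]")
  expect_match(pat, "#7")
})
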