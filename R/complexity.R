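# MC1 and MC2: graph-degree molecular complexity with the carbonyl
# exclusion rule for carboxyl derivatives.

#' The carbonyl exclusion pattern used by MC2
#'
#' MC2 does not count the C=O pair of carboxyl derivatives (acids, esters,
#' amides, carbonates, carbamates, ureas): a carbon double-bonded to a
#' terminal oxygen that also carries at least one single-bonded nitrogen or
#' oxygen neighbour. Sulfur and phosphorus analogues (thioesters, thiones,
#' sulfonamides, amidines, guanidines, ...) never match and their atoms are
#' counted normally.
#'
#' @return The SMARTS string equivalent to the matching rule, for audit.
#'   The rule itself is applied on the heavy-atom graph: a real carbon with
#'   >= 1 double bond to oxygen and >= 1 single bond to N or O is excluded
#'   together with its (lowest-index) double-bonded oxygen.
#' @export
mc2_exclusion_pattern <- function() {
  "[#6](=[OX1])[#7,#8]"
}

#' Detect carbonyl groups excluded from MC2
#'
#' Matches every real carbon bearing a double bond to oxygen together with
#' at least one single-bonded N or O neighbour (the X in X-C=O), and marks
#' that carbon plus its double-bonded oxygen as excluded. Only the C and
#' the doubly bonded O are excluded; the X atom is judged by its own degree
#' (ester O and amide N are divalent anyway; an acid hydroxyl O is
#' monovalent and still counts toward MC2). A carbon matching through
#' several X neighbours (e.g. urea) is excluded once. Aromatic bonds (order
#' 4 in raw SDF input) are not double bonds, so aromatic ring oxygens never
#' match; SMILES input is kekulized at parse time, which makes lactam and
#' vinylogous C=O bonds explicit before matching.
#'
#' @param g A [mol_graph()].
#' @param profile Optional [degree_profile()] of `g` (computed if missing).
#' @return An object of class `exclusion_set`: list with `excluded_ids`
#'   (integer node ids) and `matched_groups` (tibble with `carbon_id`,
#'   `oxygen_id`, `x_ids` list-column).
#' @examples
#' \donttest{
#' detect_excluded_carbonyls(parse_structure("CC(N)=O"))  # acetamide: 1 group
#' detect_excluded_carbonyls(parse_structure("CC(C)=O"))  # acetone: none
#' }
#' @export
detect_excluded_carbonyls <- function(g, profile = degree_profile(g)) {
  stopifnot(inherits(g, "mol_graph"))
  nodes <- g$nodes
  edges <- g$edges
  empty <- structure(list(
    excluded_ids = integer(0),
    matched_groups = tibble::tibble(carbon_id = integer(), oxygen_id = integer(),
                                    x_ids = list())
  ), class = "exclusion_set")
  if (nrow(edges) == 0) return(empty)

  elem <- stats::setNames(nodes$element, as.character(nodes$node_id))
  is_att <- stats::setNames(nodes$is_attachment, as.character(nodes$node_id))
  # both directions of each bond, so neighbours can be read per atom
  half <- tibble::tibble(
    a = c(edges$from, edges$to),
    b = c(edges$to, edges$from),
    order = c(edges$order, edges$order)
  )
  carbons <- nodes$node_id[nodes$element == "C" & !nodes$is_attachment]
  groups <- purrr::map(carbons, function(cid) {
    nb <- half[half$a == cid, ]
    dbl_o <- nb$b[nb$order == 2 & elem[as.character(nb$b)] == "O" &
                    !is_att[as.character(nb$b)]]
    if (length(dbl_o) == 0) return(NULL)
    x <- nb$b[nb$order == 1 & elem[as.character(nb$b)] %in% c("N", "O") &
                !is_att[as.character(nb$b)]]
    if (length(x) == 0) return(NULL)
    list(carbon_id = cid, oxygen_id = min(dbl_o), x_ids = sort(x))
  })
  groups <- purrr::compact(groups)
  if (length(groups) == 0) return(empty)
  matched <- tibble::tibble(
    carbon_id = purrr::map_int(groups, "carbon_id"),
    oxygen_id = purrr::map_int(groups, "oxygen_id"),
    x_ids = purrr::map(groups, "x_ids")
  )
  structure(list(
    excluded_ids = sort(unique(c(matched$carbon_id, matched$oxygen_id))),
    matched_groups = matched
  ), class = "exclusion_set")
}

#' @export
print.exclusion_set <- function(x, ...) {
  cat(sprintf("<exclusion_set> %d excluded atoms in %d carbonyl group(s)\n",
              length(x$excluded_ids), nrow(x$matched_groups)))
  invisible(x)
}

#' MC1: fraction of non-divalent nodes in the molecular graph
#'
#' `MC1 = 1 - FDV`, where FDV is the fraction of divalent heavy atoms.
#' Size-independent and blind to element identity and bond order; every
#' branching point (trivalent or tetravalent node) raises it. Values for
#' very small molecules (methane, trifluoroacetic acid, tert-butanol all
#' score 1) and for polymers are not informative of synthetic difficulty.
#'
#' @param profile A [degree_profile()] (or a [mol_graph()], profiled on the
#'   fly).
#' @return A fraction in `[0, 1]`.
#' @examples
#' \donttest{
#' mc1(parse_structure("C1CCCCC1"))  # cyclohexane: 0
#' mc1(parse_structure("OC(=O)C(F)(F)F"))  # trifluoroacetic acid: 1
#' }
#' @export
mc1 <- function(profile) {
  if (inherits(profile, "mol_graph")) profile <- degree_profile(profile)
  stopifnot(inherits(profile, "degree_profile"))
  1 - length(profile$divalent_ids) / profile$hac
}

#' MC2: number of non-divalent nodes, carbonyls of carboxyl derivatives
#' excluded
#'
#' Counts non-divalent heavy atoms, skipping the C and double-bonded O of
#' every matched X-C=O group (X = N or O; see
#' [detect_excluded_carbonyls()]). Size-dependent: large linear molecules
#' stay simple, branched polycyclic ones score high. Attachment points are
#' never counted.
#'
#' @param profile A [degree_profile()] (or a [mol_graph()]).
#' @param excl An `exclusion_set`; computed from `profile`'s graph when a
#'   [mol_graph()] is given.
#' @return A non-negative integer.
#' @examples
#' \donttest{
#' g <- parse_structure("CC(N)=O")  # acetamide
#' mc2(degree_profile(g), detect_excluded_carbonyls(g))  # 2
#' }
#' @export
mc2 <- function(profile, excl = NULL) {
  if (inherits(profile, "mol_graph")) {
    g <- profile
    profile <- degree_profile(g)
    if (is.null(excl)) excl <- detect_excluded_carbonyls(g, profile)
  }
  stopifnot(inherits(profile, "degree_profile"))
  excluded <- if (is.null(excl)) integer(0) else excl$excluded_ids
  length(setdiff(profile$nondivalent_ids, excluded))
}

#' Score a single structure
#'
#' The full pipeline for one molecule: parse, apply the fragment policy,
#' profile degrees, detect excluded carbonyls, and assemble a one-row
#' record. Parse and empty-molecule failures yield a `status = "skip"` row
#' rather than an error, so batch runs never crash on a bad input line.
#'
#' @param text SMILES string or SDF record text.
#' @param id Molecule identifier carried into the output row.
#' @param fmt `"smiles"` or `"sdf_record"`.
#' @param fragment_policy Passed to [select_fragment()].
#' @param min_hac_warn Heavy-atom count below which a note is appended to
#'   the record message (MC1 is uninformative for very small molecules).
#' @return A one-row tibble with columns `id`, `smiles`, `hac`, `fdv`,
#'   `mc1`, `mc2`, `n_excluded`, `n_attachments`, `status`, `message`.
#'   `mc1 = 1 - fdv` exactly; rounding happens only at write time.
#' @export
score_molecule <- function(text, id = NA_character_, fmt = c("smiles", "sdf_record"),
                           fragment_policy = c("largest", "whole", "error_on_multi"),
                           min_hac_warn = 0L) {
  fmt <- match.arg(fmt)
  fragment_policy <- match.arg(fragment_policy)
  skip_row <- function(msg) {
    tibble::tibble(
      id = as.character(id), smiles = as.character(text),
      hac = NA_integer_, fdv = NA_real_, mc1 = NA_real_, mc2 = NA_integer_,
      n_excluded = NA_integer_, n_attachments = NA_integer_,
      status = "skip", message = msg
    )
  }
  res <- tryCatch({
    g <- parse_structure(text, fmt = fmt)
    g <- select_fragment(g, policy = fragment_policy)
    prof <- degree_profile(g)
    excl <- detect_excluded_carbonyls(g, prof)
    fdv <- length(prof$divalent_ids) / prof$hac
    msg <- if (prof$hac < min_hac_warn) {
      sprintf("hac %d below warning threshold %d: MC1 uninformative for very small molecules",
              prof$hac, min_hac_warn)
    } else ""
    tibble::tibble(
      id = as.character(id), smiles = as.character(text),
      hac = prof$hac, fdv = fdv, mc1 = 1 - fdv,
      mc2 = mc2(prof, excl),
      n_excluded = length(excl$excluded_ids),
      n_attachments = prof$n_attachments,
      status = "ok", message = msg
    )
  }, molcomplex_parse_error = function(e) skip_row(conditionMessage(e)),
     molcomplex_empty_error = function(e) skip_row(conditionMessage(e)),
     molcomplex_fragment_error = function(e) skip_row(conditionMessage(e)))
  res
}

#' Score a table (or vector) of structures
#'
#' The main batch verb: takes a data frame with a SMILES column (or a bare
#' character vector of SMILES) and returns one complexity record per row,
#' in input order, ready for piping into the comparison harness.
#'
#' @param data A data frame with a structure column, or a character vector.
#' @param smiles_col Name of the structure column (default `"smiles"`).
#' @param id_col Optional name of an identifier column; row numbers are
#'   used when absent.
#' @param fmt,fragment_policy,min_hac_warn Passed to [score_molecule()].
#' @param fail `"skip"` keeps failed rows as `status = "skip"` records;
#'   `"abort"` raises on the first failure.
#' @return A tibble of complexity records (see [score_molecule()]).
#' @examples
#' \donttest{
#' tibble::tibble(smiles = c("OC(=O)C(F)(F)F", "[*]OCC[*]")) |> mc_score()
#' }
#' @export
mc_score <- function(data, smiles_col = "smiles", id_col = NULL,
                     fmt = c("smiles", "sdf_record"),
                     fragment_policy = c("largest", "whole", "error_on_multi"),
                     fail = c("skip", "abort"), min_hac_warn = 0L) {
  fmt <- match.arg(fmt)
  fragment_policy <- match.arg(fragment_policy)
  fail <- match.arg(fail)
  if (is.character(data)) data <- tibble::tibble(smiles = data)
  stopifnot(is.data.frame(data))
  if (!smiles_col %in% names(data)) {
    rlang::abort(sprintf("column '%s' not found in input", smiles_col),
                 class = "molcomplex_input_error")
  }
  ids <- if (!is.null(id_col)) {
    if (!id_col %in% names(data)) {
      rlang::abort(sprintf("column '%s' not found in input", id_col),
                   class = "molcomplex_input_error")
    }
    as.character(data[[id_col]])
  } else {
    as.character(seq_len(nrow(data)))
  }
  out <- purrr::map2(data[[smiles_col]], ids, function(s, i) {
    rec <- score_molecule(s, id = i, fmt = fmt, fragment_policy = fragment_policy,
                          min_hac_warn = min_hac_warn)
    if (fail == "abort" && rec$status == "skip") {
      rlang::abort(sprintf("scoring failed for id '%s': %s", i, rec$message),
                   class = "molcomplex_score_error")
    }
    rec
  })
  dplyr::bind_rows(out)
}
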