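# Heavy-atom molecular graphs: ingestion from SMILES/SDF, fragment policy,
# degree profiles. All downstream scoring reads only this representation.

#' Construct a molecular graph object
#'
#' Low-level constructor for the heavy-atom graph that the complexity scores
#' are computed on. Most users should call [parse_structure()] instead.
#'
#' @param nodes A tibble with columns `node_id` (integer), `element`
#'   (character; periodic-table symbol or `"*"` for a polymer attachment
#'   point), `formal_charge` (integer) and `is_attachment` (logical).
#' @param edges A tibble with columns `from`, `to` (integer node ids) and
#'   `order` (numeric bond order: 1, 2, 3, or 4 for an aromatic bond read
#'   verbatim from an SDF record).
#' @param source A list tagging the original input (`text`, `fmt`).
#'
#' @details Invariants enforced: every edge references two distinct existing
#' node ids, there are no duplicate edges, hydrogens never appear as nodes,
#' and an attachment node has exactly one neighbour.
#'
#' @return An object of class `mol_graph`.
#' @export
mol_graph <- function(nodes, edges, source = list(text = NA_character_, fmt = NA_character_)) {
  nodes <- tibble::as_tibble(nodes)
  edges <- tibble::as_tibble(edges)
  stopifnot(
    all(c("node_id", "element", "formal_charge", "is_attachment") %in% names(nodes)),
    all(c("from", "to", "order") %in% names(edges))
  )
  if (anyDuplicated(nodes$node_id)) {
    rlang::abort("duplicate node ids in molecular graph", class = "molcomplex_graph_error")
  }
  if (nrow(edges) > 0) {
    if (any(edges$from == edges$to)) {
      rlang::abort("self-loop edge in molecular graph", class = "molcomplex_graph_error")
    }
    if (!all(c(edges$from, edges$to) %in% nodes$node_id)) {
      rlang::abort("edge references unknown node id", class = "molcomplex_graph_error")
    }
    key <- paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to))
    if (anyDuplicated(key)) {
      rlang::abort("duplicate edge in molecular graph", class = "molcomplex_graph_error")
    }
  }
  att <- nodes$node_id[nodes$is_attachment]
  if (length(att) > 0) {
    deg <- node_degrees(nodes, edges)
    if (any(deg[as.character(att)] != 1L)) {
      rlang::abort("attachment point must have exactly one neighbour",
                   class = "molcomplex_graph_error")
    }
  }
  structure(list(nodes = nodes, edges = edges, source = source), class = "mol_graph")
}

# Degree of every node (attachment nodes included here; callers filter).
node_degrees <- function(nodes, edges) {
  deg <- stats::setNames(integer(nrow(nodes)), as.character(nodes$node_id))
  if (nrow(edges) > 0) {
    tab <- table(factor(as.character(c(edges$from, edges$to)), levels = names(deg)))
    deg <- stats::setNames(as.integer(tab), names(deg))
  }
  deg
}

#' @export
print.mol_graph <- function(x, ...) {
  n_att <- sum(x$nodes$is_attachment)
  cat(sprintf("<mol_graph> %d heavy atoms, %d bonds%s\n",
              nrow(x$nodes) - n_att, nrow(x$edges),
              if (n_att > 0) sprintf(", %d attachment points", n_att) else ""))
  if (!is.na(x$source$text)) cat("  source:", x$source$text, "\n")
  invisible(x)
}

# Symbols treated as hydrogen (removed at ingestion) and as attachment dummies.
HYDROGEN_SYMBOLS <- c("H", "D", "T")
ATTACHMENT_SYMBOLS <- c("*", "R", "R#", "Du")

# MDL legacy charge codes (atom-block field) -> formal charge.
mdl_charge <- function(code) {
  map <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L, `5` = -1L, `6` = -2L, `7` = -3L)
  out <- unname(map[as.character(code)])
  out[is.na(out)] <- 0L
  out
}

#' Parse a structure into a heavy-atom molecular graph
#'
#' Reads a single SMILES string or an SDF (V2000) record, suppresses
#' hydrogens, applies aromatic perception (SMILES input is kekulized through
#' OpenBabel so that carbonyl double bonds are explicit), and flags dummy
#' atoms (`[*]`) as polymer attachment points.
#'
#' @param text A non-empty SMILES string, or the full text of one SDF record.
#' @param fmt `"smiles"` or `"sdf_record"`.
#'
#' @return A [mol_graph()] object.
#' @examples
#' \donttest{
#' parse_structure("CCC")            # 3-node path
#' parse_structure("[*]CC(C)[*]")    # polypropylene repeat unit
#' }
#' @export
parse_structure <- function(text, fmt = c("smiles", "sdf_record")) {
  fmt <- match.arg(fmt)
  if (!is.character(text) || length(text) != 1 || is.na(text) || !nzchar(trimws(text))) {
    rlang::abort("input structure text must be a non-empty string",
                 class = "molcomplex_parse_error")
  }
  sdf_text <- if (fmt == "smiles") {
    out <- tryCatch(ChemmineOB::convertFormat("SMI", "SDF", text),
                    error = function(e) "")
    if (!nzchar(out)) {
      rlang::abort(sprintf("SMILES parse failure for input '%s'", text),
                   class = "molcomplex_parse_error")
    }
    out
  } else {
    text
  }
  sdf_to_mol_graph(sdf_text, source = list(text = text, fmt = fmt))
}

# Build a mol_graph from one V2000 record (text), dropping hydrogens.
sdf_to_mol_graph <- function(sdf_text, source) {
  lines <- strsplit(sdf_text, "\n", fixed = TRUE)[[1]]
  sdfset <- tryCatch(
    suppressWarnings(ChemmineR::read.SDFset(ChemmineR::read.SDFstr(lines))),
    error = function(e) NULL
  )
  if (is.null(sdfset) || length(sdfset) == 0) {
    rlang::abort("SDF record failed to parse as a V2000 molecule",
                 class = "molcomplex_parse_error")
  }
  ab <- ChemmineR::atomblock(sdfset[[1]])
  bb <- ChemmineR::bondblock(sdfset[[1]])
  if (is.null(ab) || nrow(ab) == 0) {
    rlang::abort("SDF record has no atom block", class = "molcomplex_parse_error")
  }
  # a bond-less molecule yields a single all-zero bond row; drop such rows
  if (!is.null(bb) && nrow(bb) > 0) {
    bb <- bb[bb[, "C1"] > 0 & bb[, "C2"] > 0, , drop = FALSE]
  }
  element <- sub("_\\d+$", "", rownames(ab))
  charge_code <- if ("C6" %in% colnames(ab)) ab[, "C6"] else rep(0, nrow(ab))
  nodes <- tibble::tibble(
    node_id = seq_len(nrow(ab)),
    element = ifelse(element %in% ATTACHMENT_SYMBOLS, "*", element),
    formal_charge = mdl_charge(charge_code),
    is_attachment = element %in% ATTACHMENT_SYMBOLS
  )
  edges <- if (is.null(bb) || nrow(bb) == 0) {
    tibble::tibble(from = integer(), to = integer(), order = numeric())
  } else {
    tibble::tibble(from = as.integer(bb[, "C1"]), to = as.integer(bb[, "C2"]),
                   order = as.numeric(bb[, "C3"]))
  }
  # hydrogen suppression: drop H/D/T nodes and their bonds, renumber
  is_h <- nodes$element %in% HYDROGEN_SYMBOLS
  if (any(is_h)) {
    keep <- nodes$node_id[!is_h]
    edges <- dplyr::filter(edges, .data$from %in% keep, .data$to %in% keep)
    nodes <- nodes[!is_h, ]
    remap <- stats::setNames(seq_along(keep), as.character(keep))
    nodes$node_id <- unname(remap[as.character(nodes$node_id)])
    edges$from <- unname(remap[as.character(edges$from)])
    edges$to <- unname(remap[as.character(edges$to)])
  }
  if (sum(!nodes$is_attachment) == 0) {
    rlang::abort("no heavy atoms left after hydrogen suppression",
                 class = "molcomplex_empty_error")
  }
  mol_graph(nodes, edges, source = source)
}

#' Select a fragment from a multi-component structure
#'
#' Salt and mixture handling. Under `"largest"` the connected component with
#' the greatest heavy-atom count is kept (ties broken by the component whose
#' canonical SMILES sorts first); `"whole"` returns the graph unchanged;
#' `"error_on_multi"` fails on more than one component.
#'
#' @param g A [mol_graph()].
#' @param policy One of `"largest"`, `"whole"`, `"error_on_multi"`.
#' @return A [mol_graph()] restricted to the selected component.
#' @export
select_fragment <- function(g, policy = c("largest", "whole", "error_on_multi")) {
  policy <- match.arg(policy)
  if (policy == "whole") return(g)
  comp <- graph_components(g)
  n_comp <- length(unique(comp))
  if (policy == "error_on_multi") {
    if (n_comp > 1) {
      rlang::abort(sprintf("input has %d disconnected components", n_comp),
                   class = "molcomplex_fragment_error")
    }
    return(g)
  }
  if (n_comp == 1) return(g)
  # component size = heavy atoms excluding attachment points
  sizes <- tapply(!g$nodes$is_attachment, comp, sum)
  best <- names(sizes)[sizes == max(sizes)]
  if (length(best) > 1) {
    smi <- vapply(best, function(cid) {
      sub <- subset_graph(g, g$nodes$node_id[comp == cid])
      tryCatch(mol_graph_to_smiles(sub), error = function(e) sub$source$text)
    }, character(1))
    best <- best[order(smi)][1]
  }
  subset_graph(g, g$nodes$node_id[comp == best[1]])
}

# Connected-component labels, one per node, by BFS over the adjacency list.
graph_components <- function(g) {
  ids <- g$nodes$node_id
  comp <- stats::setNames(rep(NA_integer_, length(ids)), as.character(ids))
  adj <- split(c(g$edges$to, g$edges$from), as.character(c(g$edges$from, g$edges$to)))
  label <- 0L
  for (v in ids) {
    if (!is.na(comp[as.character(v)])) next
    label <- label + 1L
    queue <- v
    comp[as.character(v)] <- label
    while (length(queue) > 0) {
      u <- queue[1]; queue <- queue[-1]
      for (w in adj[[as.character(u)]]) {
        if (is.na(comp[as.character(w)])) {
          comp[as.character(w)] <- label
          queue <- c(queue, w)
        }
      }
    }
  }
  unname(comp[as.character(ids)])
}

# Restrict a graph to a node subset and renumber ids 1..n.
subset_graph <- function(g, keep_ids) {
  nodes <- g$nodes[g$nodes$node_id %in% keep_ids, ]
  edges <- dplyr::filter(g$edges, .data$from %in% keep_ids, .data$to %in% keep_ids)
  remap <- stats::setNames(seq_len(nrow(nodes)), as.character(nodes$node_id))
  nodes$node_id <- unname(remap[as.character(nodes$node_id)])
  edges$from <- unname(remap[as.character(edges$from)])
  edges$to <- unname(remap[as.character(edges$to)])
  mol_graph(nodes, edges, source = g$source)
}

#' Compute the degree profile of a molecular graph
#'
#' Degrees are heavy-neighbour counts on the reduced molecular graph: bond
#' orders are ignored (a double bond contributes one neighbour) and element
#' identity plays no role. Attachment points contribute +1 to the degree of
#' the real atom they are bonded to but are excluded from the heavy atom
#' count and from the divalent/non-divalent partition.
#'
#' @param g A [mol_graph()] with at least one real (non-attachment) node.
#' @return An object of class `degree_profile`: a list with `degree` (named
#'   integer vector over real node ids), `hac` (heavy atom count),
#'   `divalent_ids`, `nondivalent_ids` (partition of real nodes by
#'   degree == 2) and `n_attachments`.
#' @examples
#' \donttest{
#' degree_profile(parse_structure("CCC"))  # degrees 1,2,1
#' }
#' @export
degree_profile <- function(g) {
  stopifnot(inherits(g, "mol_graph"))
  real <- g$nodes$node_id[!g$nodes$is_attachment]
  if (length(real) == 0) {
    rlang::abort("graph has no real heavy atoms", class = "molcomplex_empty_error")
  }
  deg_all <- node_degrees(g$nodes, g$edges)
  deg <- deg_all[as.character(real)]
  divalent <- real[deg == 2L]
  structure(list(
    degree = deg,
    hac = length(real),
    divalent_ids = divalent,
    nondivalent_ids = setdiff(real, divalent),
    n_attachments = sum(g$nodes$is_attachment)
  ), class = "degree_profile")
}

#' @export
print.degree_profile <- function(x, ...) {
  cat(sprintf("<degree_profile> hac %d, %d divalent, %d non-divalent%s\n",
              x$hac, length(x$divalent_ids), length(x$nondivalent_ids),
              if (x$n_attachments > 0) sprintf(", %d attachment points", x$n_attachments) else ""))
  invisible(x)
}

#' Reduce a molecule to its hydrocarbon graph
#'
#' The conceptual reduction behind MC1: every heavy atom is replaced by
#' carbon and every bond by a single bond. The degree profile, and hence
#' MC1, is invariant under this operation.
#'
#' @param g A [mol_graph()].
#' @return A [mol_graph()] with all real elements set to `"C"` and all bond
#'   orders set to 1. Attachment points are preserved.
#' @export
hydrocarbon_reduction <- function(g) {
  stopifnot(inherits(g, "mol_graph"))
  nodes <- g$nodes
  nodes$element[!nodes$is_attachment] <- "C"
  nodes$formal_charge <- 0L
  edges <- g$edges
  edges$order <- rep(1, nrow(edges))
  mol_graph(nodes, edges, source = g$source)
}

#' Serialize a molecular graph back to canonical SMILES
#'
#' Round-trips through a V2000 record and OpenBabel canonicalization. Used
#' to export generated fixtures as SMILES line files.
#'
#' @param g A [mol_graph()].
#' @return A canonical SMILES string.
#' @export
mol_graph_to_smiles <- function(g) {
  out <- tryCatch(ChemmineOB::convertFormat("SDF", "CAN", mol_graph_to_sdf(g)),
                  error = function(e) "")
  out <- trimws(sub("\t.*$", "", out))
  if (!nzchar(out)) {
    rlang::abort("could not serialize graph to SMILES", class = "molcomplex_parse_error")
  }
  out
}

# Minimal V2000 writer (coordinates zeroed; charges via M CHG).
mol_graph_to_sdf <- function(g) {
  n <- nrow(g$nodes); m <- nrow(g$edges)
  header <- c("molcomplex", "  molcomplex", "",
              sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, m))
  atoms <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                   0, 0, 0, g$nodes$element)
  bonds <- if (m > 0) {
    sprintf("%3d%3d%3d  0  0  0  0", g$edges$from, g$edges$to, as.integer(g$edges$order))
  } else character(0)
  chg <- which(g$nodes$formal_charge != 0)
  chg_lines <- if (length(chg) > 0) {
    vapply(chg, function(i) sprintf("M  CHG  1 %3d %3d", i, g$nodes$formal_charge[i]),
           character(1))
  } else character(0)
  paste(c(header, atoms, bonds, chg_lines, "M  END", "$$$$", ""), collapse = "\n")
}
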