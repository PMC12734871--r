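## molgraph: SMILES -> heavy-atom molecular graphs with node and edge
## features suitable for graph neural networks.

HYBRIDIZATIONS <- c("sp", "sp2", "sp3", "other")
BOND_TYPES <- c("single", "double", "triple", "aromatic")

#' Convert SMILES strings to molecular graphs
#'
#' Parses each SMILES through OpenBabel (via ChemmineR) into a heavy-atom
#' graph: hydrogens are implicit, atoms become nodes and bonds undirected
#' edges. Node features: element symbol, degree (heavy-bond count),
#' hybridization (`sp`/`sp2`/`sp3`/`other`), formal charge, aromaticity.
#' Edge features: bond type (`single`/`double`/`triple`/`aromatic`) and
#' conjugation.
#'
#' Aromaticity is perceived on rings; bonds between two atoms of the same
#' aromatic ring are typed `aromatic`. Hybridization is derived from bond
#' orders (any triple or two doubles -> sp; any double or aromatic -> sp2;
#' otherwise sp3 for main-group organics). A bond is flagged conjugated when
#' both endpoints are sp- or sp2-hybridized, which covers aromatic systems
#' and alternating ene/carbonyl chains. Stereochemistry is ignored.
#'
#' @param smiles character vector of SMILES strings.
#' @param names molecule names (defaults to names of `smiles` or `mol<i>`).
#' @return a list of `mol_graph` objects: each a list with `name`, `smiles`,
#'   `nodes` (data.frame: element, degree, hybridization, formal_charge,
#'   aromatic) and `edges` (data.frame: i, j, bond_type, conjugated) with
#'   1-based node indices, i < j, no self-loops.
#' @export
#' @examples
#' \donttest{
#' g <- smiles_to_graphs("Cc1cc2C(=O)c3cc(O)cc(O)c3C(=O)c2c(O)c1", "emodin")[[1]]
#' nrow(g$nodes) # 20 heavy atoms for C15H10O5
#' }
smiles_to_graphs <- function(smiles, names = NULL) {
  smiles <- as.character(smiles)
  if (length(smiles) == 0) return(list())
  nm <- names %||% base::names(smiles) %||% paste0("mol", seq_along(smiles))
  if (any(is.na(smiles) | !nzchar(smiles)))
    had_stop("empty or NA SMILES string", "hadmet_parse_error")
  sm <- stats::setNames(smiles, make.unique(nm))
  ## smiles2sdf flags zero-bond molecules as "invalid SDFs"; single heavy
  ## atoms are legitimate, so validity is checked on atom counts instead.
  sdfset <- tryCatch(suppressWarnings(ChemmineR::smiles2sdf(sm)),
                     error = function(e)
                       had_stop(paste("SMILES parse failed:",
                                      conditionMessage(e)), "hadmet_parse_error"))
  n_atoms <- vapply(seq_along(sdfset), function(k)
    nrow(ChemmineR::atomblock(sdfset[[k]])), integer(1))
  if (length(sdfset) != length(sm) || any(n_atoms < 1))
    had_stop(paste("invalid SMILES (failed sanitization):",
                   paste(smiles[n_atoms < 1], collapse = ", ")),
             "hadmet_parse_error")
  lapply(seq_along(sdfset), function(k)
    sdf_to_graph(sdfset[[k]], nm[k], smiles[k]))
}

#' @rdname smiles_to_graphs
#' @param name molecule name for the single-molecule variant.
#' @export
smiles_to_graph <- function(smiles, name = "mol") {
  smiles_to_graphs(smiles[1], names = name)[[1]]
}

## SDF charge codes (V2000 field 4): 1..7 -> +3..-3 around 0, 4 = radical.
sdf_charge <- function(code) {
  map <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L,
           `5` = -1L, `6` = -2L, `7` = -3L)
  out <- map[as.character(code)]
  out[is.na(out)] <- 0L
  unname(out)
}

sdf_to_graph <- function(sdf, name, smiles) {
  ## ChemmineR's SDF parser garbles 1-atom/0-bond blocks; recover the single
  ## heavy atom from the SMILES itself (element symbol, optional charge).
  counts <- suppressWarnings(as.integer(strsplit(
    trimws(ChemmineR::header(sdf)[["Counts_Line"]]), "[[:space:]]+")[[1]][1:2]))
  if (!anyNA(counts) && counts[1] == 1 && counts[2] == 0)
    return(single_atom_graph(smiles, name))
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  n_atoms <- nrow(ab)
  element <- sub("_.*$", "", rownames(ab))
  charge <- if ("C6" %in% colnames(ab)) sdf_charge(ab[, "C6"]) else
    integer(n_atoms)

  ## zero-bond molecules carry a placeholder all-zero bond row
  if (!is.null(bb) && nrow(bb))
    bb <- bb[bb[, "C1"] >= 1 & bb[, "C2"] >= 1 &
               bb[, "C1"] != bb[, "C2"], , drop = FALSE]
  if (is.null(bb) || nrow(bb) == 0) {
    edges <- data.frame(i = integer(0), j = integer(0),
                        bond_type = character(0), conjugated = logical(0),
                        stringsAsFactors = FALSE)
    order <- integer(0)
  } else {
    i <- pmin(bb[, "C1"], bb[, "C2"])
    j <- pmax(bb[, "C1"], bb[, "C2"])
    order <- as.integer(bb[, "C3"])
    edges <- data.frame(i = as.integer(i), j = as.integer(j),
                        bond_type = BOND_TYPES[pmin(order, 3L)],
                        conjugated = FALSE, stringsAsFactors = FALSE)
  }

  ## aromatic perception: atoms/bonds belonging to rings OpenBabel marks
  ## aromatic (ring search bounded at 8-membered rings)
  aromatic_atom <- logical(n_atoms)
  if (n_atoms >= 3 && nrow(edges) >= 3) {
    rr <- tryCatch(ChemmineR::rings(sdf, upper = 8, type = "all", arom = TRUE),
                   error = function(e) NULL)
    if (!is.null(rr) && length(rr$RINGS)) {
      for (ri in which(unlist(rr$AROMATIC))) {
        idx <- as.integer(sub("^.*_", "", rr$RINGS[[ri]]))
        aromatic_atom[idx] <- TRUE
        in_ring <- edges$i %in% idx & edges$j %in% idx
        edges$bond_type[in_ring] <- "aromatic"
      }
    }
  }

  degree <- tabulate(c(edges$i, edges$j), nbins = n_atoms)
  ## bond-order environment per atom, counting aromatic as order 1.5
  n_double <- tabulate(c(edges$i[edges$bond_type == "double"],
                         edges$j[edges$bond_type == "double"]), nbins = n_atoms)
  n_triple <- tabulate(c(edges$i[edges$bond_type == "triple"],
                         edges$j[edges$bond_type == "triple"]), nbins = n_atoms)
  organic <- element %in% c("C", "N", "O", "S", "P", "B", "Si")
  hyb <- ifelse(n_triple > 0 | n_double >= 2, "sp",
         ifelse(n_double > 0 | aromatic_atom, "sp2",
         ifelse(organic, "sp3", "other")))
  unsat <- hyb %in% c("sp", "sp2")
  if (nrow(edges)) edges$conjugated <- unsat[edges$i] & unsat[edges$j]

  nodes <- data.frame(element = element, degree = degree,
                      hybridization = hyb, formal_charge = charge,
                      aromatic = aromatic_atom, stringsAsFactors = FALSE)
  structure(list(name = name, smiles = unname(smiles), nodes = nodes,
                 edges = edges),
            class = "mol_graph")
}

single_atom_graph <- function(smiles, name) {
  m <- regmatches(smiles, regexec(
    "^\\[?([A-Z][a-z]?)H?[0-9]?([+-][0-9]?)?\\]?$", smiles))[[1]]
  if (length(m) < 2 || !nzchar(m[2]))
    had_stop(paste("cannot interpret single-atom SMILES:", smiles),
             "hadmet_parse_error")
  element <- m[2]
  charge <- if (length(m) >= 3 && nzchar(m[3])) {
    sign <- if (substr(m[3], 1, 1) == "+") 1L else -1L
    mag <- suppressWarnings(as.integer(substr(m[3], 2, 2)))
    sign * (if (is.na(mag)) 1L else mag)
  } else 0L
  organic <- element %in% c("C", "N", "O", "S", "P", "B", "Si")
  structure(list(
    name = name, smiles = unname(smiles),
    nodes = data.frame(element = element, degree = 0L,
                       hybridization = if (organic) "sp3" else "other",
                       formal_charge = charge, aromatic = FALSE,
                       stringsAsFactors = FALSE),
    edges = data.frame(i = integer(0), j = integer(0),
                       bond_type = character(0), conjugated = logical(0),
                       stringsAsFactors = FALSE)),
    class = "mol_graph")
}

#' @export
print.mol_graph <- function(x, ...) {
  cat(sprintf("mol_graph '%s': %d atoms, %d bonds (%s)\n", x$name,
              nrow(x$nodes), nrow(x$edges), x$smiles))
  invisible(x)
}

## ---------------------------------------------------------------------------
## Batched numeric encoding for the GIN.

#' Build (or reuse) a feature vocabulary from molecular graphs
#'
#' The vocabulary fixes the one-hot layout of the numeric node features:
#' observed elements plus an `"other"` bucket, degree buckets 1..6, the four
#' hybridization states, formal charges {-1, 0, +1, other} and an aromatic
#' flag, followed by counts of incident bond types and conjugated bonds
#' (how edge features enter the node representation). Persist it with
#' trained models so inference uses the same layout.
#'
#' @param graphs list of `mol_graph`.
#' @return a `graph_vocab`.
#' @export
build_vocab <- function(graphs) {
  elements <- sort(unique(unlist(lapply(graphs, function(g) g$nodes$element))))
  structure(list(elements = c(elements, "other"),
                 max_degree = 6L,
                 hybridizations = HYBRIDIZATIONS,
                 charges = c(-1L, 0L, 1L)),
            class = "graph_vocab")
}

one_hot <- function(values, levels, other = TRUE) {
  idx <- match(values, levels)
  if (other) idx[is.na(idx)] <- length(levels) else
    idx[is.na(idx)] <- 1L  # not reached when levels cover values
  m <- matrix(0, length(values), length(levels))
  m[cbind(seq_along(values), idx)] <- 1
  m
}

#' Encode molecular graphs as a numeric batch
#'
#' Produces the fixed-width node feature matrix, block-diagonal sparse
#' adjacency, and sum-pooling matrix that the GIN consumes. Out-of-vocabulary
#' elements are mapped to the `"other"` bucket with a warning.
#'
#' @param graphs nonempty list of `mol_graph`.
#' @param vocab a `graph_vocab`; built from `graphs` when `NULL`.
#' @return a `graph_batch`: list with `X` (total-nodes x d feature matrix),
#'   `A` (sparse symmetric adjacency over all nodes), `P` (sparse
#'   n-graphs x total-nodes sum-pooling matrix), `graph_names`, `n_nodes`,
#'   and `vocab`.
#' @export
featurize_batch <- function(graphs, vocab = NULL) {
  if (length(graphs) == 0)
    had_stop("cannot featurize an empty graph list", "hadmet_domain_error")
  if (inherits(graphs, "mol_graph")) graphs <- list(graphs)
  vocab <- vocab %||% build_vocab(graphs)

  n_nodes <- vapply(graphs, function(g) nrow(g$nodes), integer(1))
  offset <- cumsum(c(0L, n_nodes[-length(n_nodes)]))
  total <- sum(n_nodes)

  blocks <- vector("list", length(graphs))
  ei <- ej <- vector("list", length(graphs))
  oov <- FALSE
  for (k in seq_along(graphs)) {
    g <- graphs[[k]]
    nd <- g$nodes
    if (any(!nd$element %in% vocab$elements)) oov <- TRUE
    deg <- pmin(nd$degree, vocab$max_degree)
    bt <- g$edges$bond_type
    count_inc <- function(sel) tabulate(c(g$edges$i[sel], g$edges$j[sel]),
                                        nbins = nrow(nd))
    blocks[[k]] <- cbind(
      one_hot(nd$element, vocab$elements),
      one_hot(deg, seq_len(vocab$max_degree), other = FALSE),
      one_hot(nd$hybridization, vocab$hybridizations),
      cbind(one_hot(nd$formal_charge, vocab$charges, other = FALSE) *
              (nd$formal_charge %in% vocab$charges),
            as.numeric(!nd$formal_charge %in% vocab$charges)),
      as.numeric(nd$aromatic),
      count_inc(bt == "single"), count_inc(bt == "double"),
      count_inc(bt == "triple"), count_inc(bt == "aromatic"),
      count_inc(g$edges$conjugated))
    if (nrow(g$edges)) {
      ei[[k]] <- offset[k] + c(g$edges$i, g$edges$j)
      ej[[k]] <- offset[k] + c(g$edges$j, g$edges$i)
    } else ei[[k]] <- ej[[k]] <- integer(0)
  }
  if (oov)
    warning("element(s) outside the feature vocabulary mapped to 'other'")
  X <- do.call(rbind, blocks)
  A <- Matrix::sparseMatrix(i = unlist(ei), j = unlist(ej), x = 1,
                            dims = c(total, total))
  P <- Matrix::sparseMatrix(i = rep(seq_along(graphs), n_nodes),
                            j = seq_len(total), x = 1,
                            dims = c(length(graphs), total))
  structure(list(X = X, A = A, P = P,
                 graph_names = vapply(graphs, `[[`, character(1), "name"),
                 n_nodes = n_nodes, vocab = vocab),
            class = "graph_batch")
}
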