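#' @importFrom stats quantile rnorm runif rbinom sd t.test setNames complete.cases
#' @importFrom utils head read.csv
#' @importFrom Matrix sparseMatrix
NULL

#' Bond type vocabulary
#'
#' The four bond types a molecular graph may carry.
#' @export
BOND_TYPES <- c("single", "double", "triple", "aromatic")

#' Default atom vocabulary for synthetic populations
#'
#' Five atom types mirroring the composition of small organic molecules
#' (hydrogen plus the four heavy elements of exhaustively enumerated
#' small-molecule sets).
#' @export
DEFAULT_ATOM_VOCAB <- c("H", "C", "N", "O", "F")

#' Construct a molecular graph
#'
#' A molecular graph is a set of typed nodes (atoms) and typed undirected
#' edges (bonds). Edges are stored once with `u < v`; message passing and
#' degree computations expand them to both directions internally.
#'
#' @param nodes character vector of atom-type codes, one per atom.
#' @param edges a data.frame with integer columns `u`, `v` (1-based node
#'   indices, `u < v`) and character column `type` (one of [BOND_TYPES]),
#'   or `NULL` for an edgeless single-atom graph.
#' @param id molecule identifier (string).
#' @return an object of class `mol_graph`.
#' @examples
#' g <- mol_graph(c("C", "C", "O"),
#'                data.frame(u = c(1, 2), v = c(2, 3),
#'                           type = c("single", "double")), id = "m1")
#' validate_graph(g)
#' @export
mol_graph <- function(nodes, edges = NULL, id = "") {
  if (is.null(edges) || nrow(as.data.frame(edges)) == 0L) {
    edges <- data.frame(u = integer(0), v = integer(0),
                        type = character(0), stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(u = as.integer(edges$u), v = as.integer(edges$v),
                        type = as.character(edges$type),
                        stringsAsFactors = FALSE)
    swap <- edges$u > edges$v
    if (any(swap)) {
      tmp <- edges$u[swap]; edges$u[swap] <- edges$v[swap]; edges$v[swap] <- tmp
    }
  }
  structure(list(nodes = as.character(nodes), edges = edges,
                 id = as.character(id)), class = "mol_graph")
}

#' @export
print.mol_graph <- function(x, ...) {
  cat(sprintf("<mol_graph '%s': %d atoms, %d bonds>\n",
              x$id, length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Number of atoms in a graph
#' @param g a [mol_graph].
#' @export
n_atoms <- function(g) length(g$nodes)

#' Validate a molecular graph
#'
#' Checks the structural invariants: at least one node, edge endpoints in
#' range, no self-loops, no duplicate edges, known bond types, and
#' connectivity. Violations are returned as messages, never raised.
#'
#' @param g a [mol_graph].
#' @param bond_vocab allowed bond types.
#' @return character vector of violation descriptions; empty if valid.
#' @export
validate_graph <- function(g, bond_vocab = BOND_TYPES) {
  v <- character(0)
  n <- length(g$nodes)
  if (n < 1L) v <- c(v, "graph has no nodes")
  e <- g$edges
  if (nrow(e) > 0L) {
    if (any(e$u < 1L | e$u > n | e$v < 1L | e$v > n))
      v <- c(v, "edge endpoint out of range")
    if (any(e$u == e$v)) v <- c(v, "self-loop edge")
    key <- paste(pmin(e$u, e$v), pmax(e$u, e$v))
    if (anyDuplicated(key)) v <- c(v, "duplicate edge")
    bad <- setdiff(unique(e$type), bond_vocab)
    if (length(bad))
      v <- c(v, paste0("unknown bond type: ", paste(bad, collapse = ", ")))
  }
  if (n >= 1L && !length(v) && !is_connected_graph(n, e))
    v <- c(v, "graph not connected")
  v
}

# breadth-first connectivity over the undirected edge list
is_connected_graph <- function(n, edges) {
  if (n <= 1L) return(TRUE)
  adj <- vector("list", n)
  for (i in seq_len(nrow(edges))) {
    u <- edges$u[i]; v <- edges$v[i]
    adj[[u]] <- c(adj[[u]], v); adj[[v]] <- c(adj[[v]], u)
  }
  seen <- logical(n); seen[1L] <- TRUE; queue <- 1L
  while (length(queue)) {
    cur <- queue[1L]; queue <- queue[-1L]
    nb <- adj[[cur]]
    new <- nb[!seen[nb]]
    seen[new] <- TRUE
    queue <- c(queue, new)
  }
  all(seen)
}

#' One-hot encode the atoms of a graph
#'
#' @param g a [mol_graph].
#' @param vocab character vector of atom-type codes; every node code must
#'   appear in it.
#' @return a `|V| x |vocab|` numeric matrix; row `v` is the one-hot
#'   indicator of node `v`'s atom type (row sums are all 1).
#' @export
encode_atoms <- function(g, vocab) {
  idx <- match(g$nodes, vocab)
  if (anyNA(idx)) {
    stop("atom code(s) not in vocabulary: ",
         paste(unique(g$nodes[is.na(idx)]), collapse = ", "))
  }
  m <- matrix(0, nrow = length(idx), ncol = length(vocab),
              dimnames = list(NULL, vocab))
  m[cbind(seq_along(idx), idx)] <- 1
  m
}

#' Decode one-hot atom features back to codes
#' @param m one-hot matrix as produced by [encode_atoms()].
#' @param vocab the vocabulary used to encode.
#' @export
decode_atoms <- function(m, vocab) vocab[max.col(m)]

#' Construct a molecular dataset
#'
#' Bundles graphs with a per-molecule property table and the atom/bond
#' vocabularies that cover all codes in use.
#'
#' @param graphs list of [mol_graph] objects with unique ids.
#' @param properties a data.frame with an `id` column and one numeric
#'   column per property, or `NULL`.
#' @param atom_vocab,bond_vocab vocabularies; defaults cover the graphs.
#' @return an object of class `mol_dataset`.
#' @export
mol_dataset <- function(graphs, properties = NULL,
                        atom_vocab = NULL, bond_vocab = BOND_TYPES) {
  ids <- vapply(graphs, function(g) g$id, character(1))
  if (anyDuplicated(ids)) stop("molecule ids are not unique")
  if (is.null(atom_vocab)) {
    atom_vocab <- sort(unique(unlist(lapply(graphs, `[[`, "nodes"))))
  }
  if (is.null(properties)) {
    properties <- data.frame(id = ids, stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(properties), "id" %in% names(properties))
  structure(list(graphs = graphs, properties = properties,
                 atom_vocab = atom_vocab, bond_vocab = bond_vocab),
            class = "mol_dataset")
}

#' @export
print.mol_dataset <- function(x, ...) {
  cat(sprintf("<mol_dataset: %d molecules, %d atom types, properties: %s>\n",
              length(x$graphs), length(x$atom_vocab),
              paste(setdiff(names(x$properties), "id"), collapse = ", ")))
  invisible(x)
}

#' @export
length.mol_dataset <- function(x) length(x$graphs)

dataset_ids <- function(ds) vapply(ds$graphs, function(g) g$id, character(1))

#' Extract property values aligned to a set of molecule ids
#'
#' @param ds a [mol_dataset].
#' @param name property column name.
#' @param ids molecule ids; defaults to all molecules in dataset order.
#' @return numeric vector of property values in the order of `ids`.
#' @export
property_values <- function(ds, name, ids = dataset_ids(ds)) {
  if (!name %in% names(ds$properties))
    stop("property column not found: ", name)
  i <- match(ids, ds$properties$id)
  if (anyNA(i)) stop("ids missing from property table")
  ds$properties[[name]][i]
}

#' Subset a dataset by molecule ids
#' @param ds a [mol_dataset].
#' @param ids molecule ids to keep, in the order requested.
#' @export
subset_dataset <- function(ds, ids) {
  all_ids <- dataset_ids(ds)
  i <- match(ids, all_ids)
  if (anyNA(i)) stop("unknown molecule id(s)")
  mol_dataset(ds$graphs[i],
              ds$properties[match(ids, ds$properties$id), , drop = FALSE],
              atom_vocab = ds$atom_vocab, bond_vocab = ds$bond_vocab)
}

#' Write a dataset as JSON lines
#'
#' The native serialization is one molecule per line:
#' `{"id": ..., "nodes": [...], "edges": [[u, v, "type"], ...],
#'   "properties": {...}}` with 1-based node indices. The format is
#' self-contained and needs no chemistry toolkit to read back.
#'
#' @param ds a [mol_dataset].
#' @param path output file path.
#' @export
write_dataset_jsonl <- function(ds, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  prop_cols <- setdiff(names(ds$properties), "id")
  for (g in ds$graphs) {
    props <- as.list(ds$properties[match(g$id, ds$properties$id),
                                   prop_cols, drop = FALSE])
    edges <- unname(lapply(seq_len(nrow(g$edges)), function(i) {
      list(g$edges$u[i], g$edges$v[i], g$edges$type[i])
    }))
    rec <- list(id = g$id, nodes = as.list(g$nodes), edges = edges,
                properties = props)
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' Read a JSON-lines dataset
#' @param path file written by [write_dataset_jsonl()].
#' @return a [mol_dataset].
#' @export
read_dataset_jsonl <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  graphs <- vector("list", length(lines))
  props <- vector("list", length(lines))
  for (k in seq_along(lines)) {
    rec <- jsonlite::fromJSON(lines[k], simplifyVector = FALSE)
    ed <- if (length(rec$edges)) {
      data.frame(
        u = vapply(rec$edges, function(e) as.integer(e[[1]]), integer(1)),
        v = vapply(rec$edges, function(e) as.integer(e[[2]]), integer(1)),
        type = vapply(rec$edges, function(e) as.character(e[[3]]),
                      character(1)),
        stringsAsFactors = FALSE)
    } else NULL
    graphs[[k]] <- mol_graph(unlist(rec$nodes), ed, id = rec$id)
    props[[k]] <- c(list(id = rec$id), lapply(rec$properties, as.numeric))
  }
  prop_df <- do.call(rbind, lapply(props, function(p)
    as.data.frame(p, stringsAsFactors = FALSE)))
  mol_dataset(graphs, prop_df)
}

# implicit hydrogen counts from standard valences; charges ignored
.default_valence <- c(H = 1, C = 4, N = 3, O = 2, F = 1,
                      Cl = 1, Br = 1, I = 1, S = 2, P = 3)

#' Read a SMILES CSV into a molecular dataset
#'
#' Parses a CSV with a SMILES column plus numeric property columns using
#' the ChemmineR toolkit. Hydrogens are made explicit by filling each
#' heavy atom to its standard valence (H1 C4 N3 O2 F1 S2 P3, halogens 1)
#' given the bond orders in the parsed structure, so atom counts match
#' the all-atom convention used by the size-based sampling scenario.
#' Rows that fail to parse are skipped and counted.
#'
#' @param path CSV file path.
#' @param target_column name of the target property column.
#' @param aux_columns optional further numeric property columns to carry.
#' @param smiles_column name of the SMILES column (default "smiles").
#' @return a [mol_dataset]; attribute `n_skipped` holds the skip count.
#' @export
read_smiles_csv <- function(path, target_column, aux_columns = character(0),
                            smiles_column = "smiles") {
  if (!requireNamespace("ChemmineR", quietly = TRUE))
    stop("read_smiles_csv requires the ChemmineR package")
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c(smiles_column, target_column, aux_columns)
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  graphs <- list(); keep <- integer(0)
  n_skipped <- 0L
  for (i in seq_len(nrow(df))) {
    g <- tryCatch(smiles_to_graph(df[[smiles_column]][i], id = paste0("m", i)),
                  error = function(e) NULL)
    if (is.null(g) || length(validate_graph(g)) > 0L) {
      n_skipped <- n_skipped + 1L
      next
    }
    graphs[[length(graphs) + 1L]] <- g
    keep <- c(keep, i)
  }
  if (!length(graphs)) stop("no SMILES row could be parsed")
  if (n_skipped > 0L)
    message(sprintf("read_smiles_csv: skipped %d unparseable row(s)", n_skipped))
  props <- data.frame(id = vapply(graphs, `[[`, character(1), "id"),
                      stringsAsFactors = FALSE)
  for (col in c(target_column, aux_columns)) props[[col]] <- as.numeric(df[[col]][keep])
  ds <- mol_dataset(graphs, props)
  attr(ds, "n_skipped") <- n_skipped
  ds
}

smiles_to_graph <- function(smiles, id = "") {
  sdf <- ChemmineR::smiles2sdf(smiles)[[1]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elems <- sub("_.*$", "", rownames(ab))
  nodes <- elems
  if (nrow(bb) > 0L) {
    u <- as.integer(bb[, 1]); v <- as.integer(bb[, 2])
    ord <- as.integer(bb[, 3])
  } else {
    u <- integer(0); v <- integer(0); ord <- integer(0)
  }
  type <- c("single", "double", "triple", "aromatic")[pmin(ord, 4L)]
  # fill implicit hydrogens up to standard valence
  val <- .default_valence[elems]
  bond_sum <- numeric(length(elems))
  for (k in seq_along(u)) {
    o <- if (ord[k] == 4L) 1.5 else ord[k]
    bond_sum[u[k]] <- bond_sum[u[k]] + o
    bond_sum[v[k]] <- bond_sum[v[k]] + o
  }
  n_h <- pmax(0, round(ifelse(is.na(val), 0, val) - bond_sum))
  nodes_all <- nodes
  uu <- u; vv <- v; tt <- type
  for (a in seq_along(elems)) {
    if (n_h[a] > 0) for (j in seq_len(n_h[a])) {
      nodes_all <- c(nodes_all, "H")
      uu <- c(uu, a); vv <- c(vv, length(nodes_all)); tt <- c(tt, "single")
    }
  }
  ed <- if (length(uu)) data.frame(u = uu, v = vv, type = tt,
                                   stringsAsFactors = FALSE) else NULL
  mol_graph(nodes_all, ed, id = id)
}

# run code under a temporary RNG state derived from `seed`, restoring
# the caller's .Random.seed afterwards (keeps generators pure)
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# deterministic sub-stream seeds, kept within 32-bit integer range
derive_seed <- function(seed, k) {
  (as.double(seed) * 48271 + 1664525 * as.double(k)) %% 2147483587 + 1
}
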