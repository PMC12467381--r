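## Compound featurisation: SMILES -> molecular graph -> Morgan (circular)
## fingerprint. SMILES parsing and kekulisation are delegated to OpenBabel
## (via ChemmineOB); the iterative circular-environment hashing is done
## here so that radius and bit width are fully configurable.

# standard valences used to infer implicit hydrogen counts from a
# kekulized connection table
.default_valence <- c(
  H = 1, B = 3, C = 4, N = 3, O = 2, F = 1,
  P = 3, S = 2, Cl = 1, Br = 1, I = 1
)

#' Parse a SMILES string into a molecular graph
#'
#' Uses OpenBabel to parse (and kekulize) the SMILES, then reads the
#' resulting V2000 connection table into atom and bond tables. Implicit
#' hydrogen counts are inferred from standard valences, bond orders and
#' formal charges.
#'
#' @param smiles a single SMILES string.
#' @return a list with elements `atoms` (data.frame: `element`, `charge`,
#'   `degree`, `order_sum`, `n_h`) and `bonds` (data.frame: `a1`, `a2`,
#'   `order`; 1-based atom indices).
#' @export
parse_smiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(trimws(smiles))) {
    stop("invalid SMILES input: expected one non-empty string")
  }
  sdf <- suppressWarnings(
    ChemmineOB::convertFormat("SMI", "SDF", source = paste0(smiles, "\tmol\n"))
  )
  lines <- strsplit(sdf, "\n", fixed = TRUE)[[1]]
  if (length(lines) < 4L || !grepl("V2000", lines[4])) {
    stop("invalid SMILES string: ", sQuote(smiles))
  }
  n_atoms <- as.integer(substr(lines[4], 1L, 3L))
  n_bonds <- as.integer(substr(lines[4], 4L, 6L))
  if (is.na(n_atoms) || n_atoms < 1L) {
    stop("invalid SMILES string: ", sQuote(smiles))
  }
  atom_lines <- lines[4L + seq_len(n_atoms)]
  element <- trimws(substr(atom_lines, 32L, 34L))
  charge <- rep(0L, n_atoms)
  bonds <- data.frame(a1 = integer(0), a2 = integer(0), order = integer(0))
  if (n_bonds > 0L) {
    bond_lines <- lines[4L + n_atoms + seq_len(n_bonds)]
    bonds <- data.frame(
      a1 = as.integer(substr(bond_lines, 1L, 3L)),
      a2 = as.integer(substr(bond_lines, 4L, 6L)),
      order = as.integer(substr(bond_lines, 7L, 9L))
    )
  }
  # formal charges live in "M  CHG" property lines (count, then pairs)
  for (ln in grep("^M  CHG", lines, value = TRUE)) {
    f <- as.integer(strsplit(trimws(substr(ln, 7L, nchar(ln))), "\\s+")[[1]])
    n <- f[1]
    for (i in seq_len(n)) charge[f[2 * i]] <- f[2 * i + 1]
  }
  degree <- tabulate(c(bonds$a1, bonds$a2), nbins = n_atoms)
  order_sum <- rep(0, n_atoms)
  for (i in seq_len(nrow(bonds))) {
    order_sum[bonds$a1[i]] <- order_sum[bonds$a1[i]] + bonds$order[i]
    order_sum[bonds$a2[i]] <- order_sum[bonds$a2[i]] + bonds$order[i]
  }
  val <- .default_valence[element]
  val[is.na(val)] <- 0
  n_h <- pmax(0, val + charge - order_sum)
  list(
    atoms = data.frame(
      element = element, charge = charge, degree = degree,
      order_sum = order_sum, n_h = n_h, stringsAsFactors = FALSE
    ),
    bonds = bonds
  )
}

#' Morgan (circular) fingerprint of a molecule
#'
#' Iteratively hashes circular atom environments up to `radius` bonds and
#' folds the resulting environment identifiers into a binary vector of
#' length `n_bits`. The initial atom invariant is (element, heavy-atom
#' degree, bond-order sum, formal charge, implicit hydrogen count);
#' neighbour contributions are sorted before hashing, so the fingerprint
#' is invariant to atom ordering in the input SMILES. Duplicate
#' environments (identical covered bond sets) are emitted once, at their
#' smallest radius.
#'
#' @param smiles SMILES string of the molecule.
#' @param radius maximum environment radius in bonds (default 2, the
#'   ECFP4-like setting).
#' @param n_bits fingerprint width (default 2048).
#' @return integer vector of 0/1 of length `n_bits`.
#' @export
morgan_fingerprint <- function(smiles, radius = 2L, n_bits = 2048L) {
  stopifnot(radius >= 0L, n_bits >= 1L)
  mol <- parse_smiles(smiles)
  n <- nrow(mol$atoms)
  bonds <- mol$bonds

  # adjacency: for each atom, (neighbour index, bond order, bond index)
  nbr <- vector("list", n)
  for (i in seq_len(n)) nbr[[i]] <- cbind(integer(0), integer(0), integer(0))
  if (nrow(bonds) > 0L) {
    for (b in seq_len(nrow(bonds))) {
      nbr[[bonds$a1[b]]] <- rbind(nbr[[bonds$a1[b]]], c(bonds$a2[b], bonds$order[b], b))
      nbr[[bonds$a2[b]]] <- rbind(nbr[[bonds$a2[b]]], c(bonds$a1[b], bonds$order[b], b))
    }
  }

  ids <- poly_hash(sprintf(
    "%s|%d|%d|%d|%g", mol$atoms$element, mol$atoms$degree,
    mol$atoms$order_sum, mol$atoms$charge, mol$atoms$n_h
  ))
  # bond sets covered by each atom's environment at the current radius,
  # grown by breadth-first expansion
  atom_sets <- lapply(seq_len(n), function(i) integer(0))
  frontier <- as.list(seq_len(n))

  features <- ids # radius-0 identifiers, always emitted
  seen_sets <- character(0)

  r <- 0L
  while (r < radius) {
    r <- r + 1L
    new_ids <- numeric(n)
    new_sets <- vector("list", n)
    new_frontier <- vector("list", n)
    for (i in seq_len(n)) {
      nb <- nbr[[i]]
      if (nrow(nb) == 0L) {
        new_ids[i] <- ids[i]
        new_sets[[i]] <- atom_sets[[i]]
        new_frontier[[i]] <- integer(0)
        next
      }
      contrib <- sprintf("%d:%.0f", nb[, 2], ids[nb[, 1]])
      new_ids[i] <- poly_hash(paste0(
        r, "|", sprintf("%.0f", ids[i]), "|",
        paste(sort(contrib), collapse = ",")
      ))
      # expand covered bonds one shell outwards
      grow <- integer(0)
      nxt <- integer(0)
      for (f in frontier[[i]]) {
        fb <- nbr[[f]]
        if (nrow(fb) > 0L) {
          grow <- c(grow, fb[, 3])
          nxt <- c(nxt, fb[, 1])
        }
      }
      new_sets[[i]] <- sort(unique(c(atom_sets[[i]], grow)))
      new_frontier[[i]] <- setdiff(unique(nxt), i)
    }
    # candidates of this radius, grouped by covered bond set; the kept
    # identifier per new bond set is the group minimum, so the result is
    # independent of atom ordering (symmetric ring positions produce the
    # same bond set from several centers)
    cand_key <- character(0)
    cand_id <- numeric(0)
    for (i in seq_len(n)) {
      if (length(new_sets[[i]]) == 0L) next
      if (length(new_sets[[i]]) == length(atom_sets[[i]])) next # env stopped growing
      key <- paste(new_sets[[i]], collapse = ",")
      if (key %in% seen_sets) next
      cand_key <- c(cand_key, key)
      cand_id <- c(cand_id, new_ids[i])
    }
    if (length(cand_key)) {
      keep <- vapply(split(cand_id, cand_key), min, numeric(1))
      seen_sets <- c(seen_sets, names(keep))
      features <- c(features, unname(keep))
    }
    ids <- new_ids
    atom_sets <- new_sets
    frontier <- new_frontier
  }

  fp <- integer(n_bits)
  fp[(features %% n_bits) + 1L] <- 1L
  fp
}

#' Build compound records with fingerprints
#'
#' @param compound_id character vector of compound identifiers.
#' @param smiles character vector of SMILES strings (same length).
#' @param radius,n_bits fingerprint parameters, see [morgan_fingerprint()].
#' @return a `compound_set`: list with `ids`, `smiles` and a binary
#'   fingerprint matrix `features` (compounds in rows).
#' @export
compound_records <- function(compound_id, smiles, radius = 2L, n_bits = 2048L) {
  stopifnot(length(compound_id) == length(smiles))
  if (anyDuplicated(compound_id)) stop("duplicate compound ids")
  feats <- matrix(0L, length(smiles), n_bits,
                  dimnames = list(compound_id, NULL))
  for (i in seq_along(smiles)) {
    feats[i, ] <- morgan_fingerprint(smiles[i], radius = radius, n_bits = n_bits)
  }
  structure(
    list(ids = compound_id, smiles = stats::setNames(smiles, compound_id),
         features = feats, radius = radius, n_bits = n_bits),
    class = "compound_set"
  )
}

#' Read a compound table (delimited id + SMILES, or .smi)
#'
#' Accepts two-column delimited text with a `compound_id,smiles` header,
#' or a `.smi` file (SMILES first, optional id second, whitespace
#' separated, no header).
#'
#' @param path file path.
#' @return data.frame with columns `compound_id`, `smiles`.
#' @export
read_compound_table <- function(path) {
  if (grepl("\\.smi$", path, ignore.case = TRUE)) {
    raw <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                             col.names = c("smiles", "compound_id")[1:2],
                             fill = TRUE)
    if (ncol(raw) == 1L) raw$compound_id <- sprintf("cmpd_%d", seq_len(nrow(raw)))
    raw$compound_id[!nzchar(raw$compound_id) | is.na(raw$compound_id)] <-
      sprintf("cmpd_%d", which(!nzchar(raw$compound_id) | is.na(raw$compound_id)))
    return(raw[, c("compound_id", "smiles")])
  }
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, comment.char = "#")
  need <- c("compound_id", "smiles")
  if (!all(need %in% names(df))) {
    stop("compound table ", path, " must have columns: ",
         paste(need, collapse = ", "))
  }
  df[, need]
}

#' Subset a compound set by id
#'
#' @param x a `compound_set`.
#' @param ids compound ids to keep (order preserved).
#' @return a `compound_set` with the selected records.
#' @export
subset_compound_set <- function(x, ids) {
  missing <- setdiff(ids, x$ids)
  if (length(missing)) {
    stop("unknown compound ids: ", paste(utils::head(missing, 3), collapse = ", "))
  }
  keep <- match(ids, x$ids)
  structure(list(ids = x$ids[keep], smiles = x$smiles[keep],
                 features = x$features[keep, , drop = FALSE],
                 radius = x$radius, n_bits = x$n_bits),
            class = "compound_set")
}
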