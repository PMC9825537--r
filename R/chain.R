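# Chain and StructureModel containers.
#
# A Chain stores, per residue, all heavy atoms plus one representative point:
# the C-beta atom, or C-alpha for glycine and for residues lacking a C-beta.
# Interface detection and Q scores run on representative points; atomic
# contacts use all heavy atoms.

#' Construct a Chain
#'
#' @param chain_id chain identifier, unique within an entry.
#' @param sequence one-letter amino-acid string (length = number of residues).
#' @param atoms data.frame with columns `seq_pos` (1-based author position,
#'   strictly increasing across residues), `atom` (atom name, e.g. "CA"),
#'   `x`, `y`, `z` (Angstroms). Heavy atoms only.
#' @param entity_key optional sequence-entity label (e.g. a UniProt name);
#'   `NA` means unassigned (a sequence-identity fallback can assign one).
#' @return object of class `qc_chain`.
#' @export
new_chain <- function(chain_id, sequence, atoms, entity_key = NA_character_) {
  stopifnot(is.character(chain_id), nchar(chain_id) >= 1,
            is.character(sequence),
            is.data.frame(atoms),
            all(c("seq_pos", "atom", "x", "y", "z") %in% names(atoms)))
  pos <- sort(unique(atoms$seq_pos))
  if (length(pos) != nchar(sequence))
    qc_stop("qc_chain_error",
            "chain %s: %d residues with atoms but sequence length %d",
            chain_id, length(pos), nchar(sequence))
  ch <- structure(list(
    chain_id   = chain_id,
    entity_key = entity_key,
    sequence   = sequence,
    atoms      = atoms[order(atoms$seq_pos), , drop = FALSE]
  ), class = "qc_chain")
  ch$rep <- representative_points(ch)
  ch
}

# Representative point per residue: CB, else CA (glycine / missing CB).
representative_points <- function(chain) {
  a <- chain$atoms
  pos <- sort(unique(a$seq_pos))
  out <- matrix(NA_real_, length(pos), 3, dimnames = list(pos, c("x", "y", "z")))
  for (i in seq_along(pos)) {
    sub <- a[a$seq_pos == pos[i], , drop = FALSE]
    k <- match("CB", sub$atom)
    if (is.na(k)) k <- match("CA", sub$atom)
    if (is.na(k)) k <- 1L  # any heavy atom as last resort
    out[i, ] <- as.numeric(sub[k, c("x", "y", "z")])
  }
  list(seq_pos = pos, xyz = out)
}

chain_length <- function(chain) length(chain$rep$seq_pos)

chain_xyz <- function(chain) as.matrix(chain$atoms[, c("x", "y", "z")])

#' Apply a rigid-body operator to a chain
#'
#' Maps every coordinate x to `rot %*% x + trans`. The returned chain keeps
#' the sequence and numbering and gets a new chain_id with an operator suffix
#' so instantiated copies stay distinguishable.
#'
#' @param chain a `qc_chain`.
#' @param rot 3 x 3 proper rotation (orthonormal within 1e-6).
#' @param trans length-3 translation (Angstroms).
#' @param id_suffix suffix recording the operator (default a counter-free
#'   fingerprint of the transform).
#' @return transformed `qc_chain`.
#' @export
apply_operator <- function(chain, rot, trans = c(0, 0, 0), id_suffix = NULL) {
  if (!is_orthonormal(rot))
    qc_stop("qc_operator_error", "rotation matrix is not orthonormal")
  trans <- as.numeric(trans)
  stopifnot(length(trans) == 3)
  identity_op <- max(abs(rot - diag(3))) < 1e-12 && all(abs(trans) < 1e-12)
  xyz <- chain_xyz(chain)
  new_xyz <- sweep(xyz %*% t(rot), 2, trans, `+`)
  atoms <- chain$atoms
  atoms$x <- new_xyz[, 1]; atoms$y <- new_xyz[, 2]; atoms$z <- new_xyz[, 3]
  if (is.null(id_suffix)) {
    id_suffix <- if (identity_op) "" else
      paste0("@", sprintf("%06x", as.integer((sum(abs(c(rot, trans))) * 1e6) %% 2^24)))
  }
  new_chain(paste0(chain$chain_id, id_suffix), chain$sequence, atoms,
            entity_key = chain$entity_key)
}

#' Construct a StructureModel (one experiment / one entry)
#'
#' @param entry_id entry identifier (PDB-id-like string).
#' @param chains list of `qc_chain`; chain ids must be unique. Chains with
#'   fewer than 3 resolved residues are dropped (they cannot support interface
#'   detection or superposition).
#' @param method one of "XRAY", "EM", "NMR", "OTHER".
#' @param space_group Hermann-Mauguin symbol (required for XRAY).
#' @param cell numeric length 6: a, b, c (Angstroms), alpha, beta, gamma
#'   (degrees); required for XRAY.
#' @param deposited_assemblies list of operator specs (see
#'   [operator_spec()]); may be empty.
#' @return object of class `qc_structure`.
#' @export
new_structure_model <- function(entry_id, chains, method = "XRAY",
                                space_group = NA_character_, cell = NULL,
                                deposited_assemblies = list()) {
  method <- match.arg(method, c("XRAY", "EM", "NMR", "OTHER"))
  chains <- Filter(function(ch) chain_length(ch) >= 3, chains)
  if (length(chains) == 0)
    qc_stop("qc_empty_structure", "entry %s: no polymer chain with >=3 resolved residues", entry_id)
  ids <- vapply(chains, `[[`, "", "chain_id")
  if (anyDuplicated(ids))
    qc_stop("qc_structure_error", "entry %s: duplicate chain ids", entry_id)
  names(chains) <- ids
  if (method == "XRAY") {
    if (is.na(space_group) || is.null(cell) || length(cell) != 6)
      qc_stop("qc_structure_error",
              "entry %s: XRAY entries require space group and 6 cell parameters", entry_id)
  }
  structure(list(
    entry_id = entry_id, chains = chains, method = method,
    space_group = space_group,
    cell = if (is.null(cell)) NULL else as.numeric(cell),
    deposited_assemblies = deposited_assemblies
  ), class = "qc_structure")
}

#' Operator specification for instantiating an assembly
#'
#' A list of (chain_id, rotation, translation) triples; applying them to the
#' named chains of a structure yields the assembly's chain set.
#'
#' @param chain_ids character vector (a chain may appear several times under
#'   different operators).
#' @param rots list of 3 x 3 rotations (same length as `chain_ids`).
#' @param transs list of length-3 translations.
#' @return object of class `qc_operator_spec`.
#' @export
operator_spec <- function(chain_ids, rots = NULL, transs = NULL) {
  n <- length(chain_ids)
  if (is.null(rots)) rots <- rep(list(diag(3)), n)
  if (is.null(transs)) transs <- rep(list(c(0, 0, 0)), n)
  stopifnot(length(rots) == n, length(transs) == n)
  for (r in rots) if (!is_orthonormal(r))
    qc_stop("qc_operator_error", "operator spec holds a non-orthonormal rotation")
  structure(list(chain_ids = as.character(chain_ids), rots = rots, transs = transs),
            class = "qc_operator_spec")
}

#' @export
print.qc_chain <- function(x, ...) {
  cat(sprintf("<chain %s: %d residues, %d atoms, entity %s>\n",
              x$chain_id, chain_length(x), nrow(x$atoms),
              ifelse(is.na(x$entity_key), "?", x$entity_key)))
  invisible(x)
}

#' @export
print.qc_structure <- function(x, ...) {
  cat(sprintf("<structure %s: %d chains, %s%s>\n", x$entry_id, length(x$chains),
              x$method,
              if (!is.na(x$space_group)) paste0(", ", x$space_group) else ""))
  invisible(x)
}
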