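# Assemblies: instantiation from operator specs, connectivity, and the
# reduction of an assembly to its unique interfaces and unique connecting
# interfaces.
#
# Unique interfaces: single-linkage clusters of the assembly's interfaces at
# pairwise Q >= 0.75 (identity position mapping within one entry), each
# represented by its smallest interface id, ordered by descending area.
# Connecting interfaces: the subset of representatives accumulated while
# sweeping each cluster's member interfaces to grow a connected chain set
# until every chain is covered.

#' Construct an Assembly
#'
#' @param assembly_id identifier.
#' @param chains named list of `qc_chain` (names = chain ids).
#' @param entry_id entry the assembly derives from.
#' @param source "GENERATED", "DEPOSITED" or "FIXTURE".
#' @param interfaces optional precomputed interface list; computed via
#'   [find_interfaces()] when NULL.
#' @param method,space_group,cell experiment provenance (carried through to
#'   crystal-form grouping and file output).
#' @return object of class `qc_assembly`. Stoichiometry, symmetry and the
#'   architecture string are unset until [annotate_assembly()] fills them.
#' @export
new_assembly <- function(assembly_id, chains, entry_id = assembly_id,
                         source = c("GENERATED", "DEPOSITED", "FIXTURE"),
                         interfaces = NULL, method = "OTHER",
                         space_group = NA_character_, cell = NULL) {
  source <- match.arg(source)
  if (is.null(names(chains)))
    names(chains) <- vapply(chains, `[[`, "", "chain_id")
  asm <- structure(list(
    assembly_id = assembly_id, source = source, chains = chains,
    entry_id = entry_id, method = method, space_group = space_group,
    cell = if (is.null(cell)) NULL else as.numeric(cell),
    stoichiometry = NA_character_, symmetry = NA_character_,
    pfam_assembly_arch = NA_character_
  ), class = "qc_assembly")
  asm$interfaces <- interfaces %||% find_interfaces(asm)
  asm
}

#' @export
print.qc_assembly <- function(x, ...) {
  cat(sprintf("<assembly %s: %d chains, %d interfaces%s%s>\n",
              x$assembly_id, length(x$chains), length(x$interfaces),
              if (!is.na(x$stoichiometry)) paste0(", ", x$stoichiometry) else "",
              if (!is.na(x$symmetry)) paste0(", ", x$symmetry) else ""))
  invisible(x)
}

#' Instantiate an assembly from a structure and an operator spec
#'
#' Each (chain_id, rotation, translation) triple of the spec produces one
#' chain via [apply_operator()]; interfaces are then computed. Stoichiometry
#' and symmetry are left unset (see [annotate_assembly()]).
#'
#' @param structure a `qc_structure`.
#' @param spec a `qc_operator_spec`; default = identity on all chains (the
#'   asymmetric unit as deposited).
#' @param assembly_id identifier; default derived from the entry.
#' @param source provenance label.
#' @return a `qc_assembly`.
#' @export
build_assembly <- function(structure, spec = NULL, assembly_id = NULL,
                           source = "GENERATED") {
  if (is.null(spec)) spec <- operator_spec(names(structure$chains))
  missing <- setdiff(spec$chain_ids, names(structure$chains))
  if (length(missing))
    qc_stop("qc_spec_error", "operator spec names unknown chains: %s",
            paste(missing, collapse = ", "))
  chains <- list()
  seen <- character(0)
  for (k in seq_along(spec$chain_ids)) {
    cid <- spec$chain_ids[k]
    n_prev <- sum(seen == cid)
    seen <- c(seen, cid)
    suffix <- if (n_prev == 0) "" else sprintf("_%d", n_prev + 1L)
    ch <- apply_operator(structure$chains[[cid]], spec$rots[[k]],
                         spec$transs[[k]], id_suffix = suffix)
    chains[[ch$chain_id]] <- ch
  }
  new_assembly(assembly_id %||% paste0(structure$entry_id, "-asm"),
               chains, entry_id = structure$entry_id, source = source,
               method = structure$method, space_group = structure$space_group,
               cell = structure$cell)
}

#' Is the assembly's chain/interface graph connected?
#'
#' Chains are nodes, interfaces edges. Assemblies failing this test are
#' excluded from clustering (a lattice fragment or a stray peptide is not a
#' candidate biological assembly). A single chain is connected.
#'
#' @param assembly a `qc_assembly`.
#' @return logical.
#' @export
is_connected <- function(assembly) {
  ids <- names(assembly$chains)
  if (length(ids) <= 1) return(TRUE)
  if (length(assembly$interfaces) == 0) return(FALSE)
  pairs <- t(vapply(assembly$interfaces,
                    function(f) match(f$chain_pair, ids), integer(2)))
  length(unique(single_linkage(length(ids), pairs))) == 1
}

# Pairwise Q matrix of an assembly's interfaces (identity position mapping).
interface_q_matrix <- function(assembly, weight_mode = "jaccard") {
  fs <- assembly$interfaces
  n <- length(fs)
  q <- diag(1, n)
  if (n >= 2) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      v <- qscore(fs[[i]], fs[[j]], weight_mode = weight_mode)$value
      q[i, j] <- q[j, i] <- v
    }
  }
  q
}

#' Unique interfaces of an assembly
#'
#' Single-linkage clusters of the assembly's interfaces at pairwise
#' Q >= `q_within`, each represented by its smallest interface id;
#' representatives are returned in descending order of the area proxy (ties:
#' smaller interface id first).
#'
#' @param assembly a `qc_assembly` with >= 1 interface.
#' @param q_within within-assembly clustering threshold (default 0.75).
#' @param weight_mode Q-score weighting, see [qscore()].
#' @return object of class `qc_interface_clusters`: list with `clusters`
#'   (list of integer interface-id vectors, ordered as `representatives`),
#'   `representatives` (integer), `connecting` (NULL until
#'   [connecting_interfaces()]).
#' @export
unique_interfaces <- function(assembly, q_within = 0.75, weight_mode = "jaccard") {
  fs <- assembly$interfaces
  if (length(fs) == 0) qc_stop("qc_assembly_error", "assembly has no interfaces")
  q <- interface_q_matrix(assembly, weight_mode)
  n <- length(fs)
  linked <- which(q >= q_within & upper.tri(q), arr.ind = TRUE)
  memb <- single_linkage(n, linked)
  ids <- vapply(fs, `[[`, integer(1), "interface_id")
  area <- vapply(fs, `[[`, numeric(1), "area_proxy")
  clusters <- lapply(sort(unique(memb)), function(m) sort(ids[memb == m]))
  reps <- vapply(clusters, min, integer(1))
  rep_area <- area[match(reps, ids)]
  ord <- order(-rep_area, reps)
  structure(list(clusters = clusters[ord], representatives = reps[ord],
                 connecting = NULL),
            class = "qc_interface_clusters")
}

#' Unique connecting interfaces of an assembly
#'
#' Walks the unique-interface clusters in descending area order. Each
#' cluster's representative is added to the connecting set, then the
#' cluster's member interfaces are swept to grow the set of connected chains:
#' the first interface seeds two chains; a later interface is consumed only
#' when exactly one of its endpoints is already connected. The sweep repeats
#' over unconsumed members until a fixed point, so termination does not
#' depend on member order. The walk stops as soon as every chain is covered.
#'
#' @param assembly a connected `qc_assembly`.
#' @param q_within,weight_mode see [unique_interfaces()].
#' @return a `qc_interface_clusters` with `connecting` populated (ordered
#'   integer vector of representative interface ids).
#' @export
connecting_interfaces <- function(assembly, q_within = 0.75, weight_mode = "jaccard") {
  if (!is_connected(assembly))
    qc_stop("qc_assembly_error", "assembly %s is not connected", assembly$assembly_id)
  ucs <- unique_interfaces(assembly, q_within, weight_mode)
  fs <- assembly$interfaces
  ids <- vapply(fs, `[[`, integer(1), "interface_id")
  all_chains <- names(assembly$chains)
  connected <- character(0)
  connecting <- integer(0)
  for (k in seq_along(ucs$clusters)) {
    if (length(connected) == length(all_chains) && length(connecting) > 0) break
    connecting <- c(connecting, ucs$representatives[k])
    members <- fs[match(ucs$clusters[[k]], ids)]
    consumed <- rep(FALSE, length(members))
    repeat {
      progress <- FALSE
      for (m in seq_along(members)) {
        if (consumed[m]) next
        pair <- members[[m]]$chain_pair
        if (length(connected) == 0) {
          connected <- pair; consumed[m] <- TRUE; progress <- TRUE
        } else {
          inset <- pair %in% connected
          if (sum(inset) == 1) {
            connected <- c(connected, pair[!inset]); consumed[m] <- TRUE; progress <- TRUE
          } else if (all(inset)) {
            consumed[m] <- TRUE  # redundant edge inside the connected set
          }
        }
        if (length(connected) == length(all_chains)) break
      }
      if (!progress || length(connected) == length(all_chains)) break
    }
    if (length(connected) == length(all_chains)) break
  }
  if (length(all_chains) > 1 && length(connected) < length(all_chains))
    qc_stop("qc_internal_error",
            "connecting-interface sweep stranded %d chains of %s",
            length(all_chains) - length(connected), assembly$assembly_id)
  ucs$connecting <- connecting
  ucs
}

#' Deduplicate a pool of candidate assemblies from one entry
#'
#' Two candidates are duplicates iff they share stoichiometry and symmetry
#' and [assembly_similarity()] returns 1 (identity position maps: same
#' entry). On a duplicate the GENERATED candidate is kept over the DEPOSITED
#' one.
#'
#' @param candidates list of annotated `qc_assembly` from one entry.
#' @param q_match cross-assembly interface-match threshold (default 0.5).
#' @return deduplicated list.
#' @export
merge_candidates <- function(candidates, q_match = 0.5) {
  if (length(candidates) <= 1) return(candidates)
  keep <- rep(TRUE, length(candidates))
  src_rank <- function(a) match(a$source, c("GENERATED", "FIXTURE", "DEPOSITED"))
  for (i in seq_along(candidates)) {
    if (!keep[i]) next
    for (j in seq_along(candidates)) {
      if (j <= i || !keep[j]) next
      a <- candidates[[i]]; b <- candidates[[j]]
      if (!identical(a$stoichiometry, b$stoichiometry) ||
          !identical(a$symmetry, b$symmetry)) next
      same <- tryCatch(assembly_similarity(a, b, q_match = q_match)$s == 1,
                       error = function(e) FALSE)
      if (same) {
        if (src_rank(b) < src_rank(a)) { keep[i] <- FALSE; break } else keep[j] <- FALSE
      }
    }
  }
  candidates[keep]
}
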