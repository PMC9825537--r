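# Chain-chain interface detection and the interface Q score.
#
# A chain pair is an interface when it has at least ten representative-point
# (C-beta) pairs within 12 A and at least one heavy-atom contact within 5 A,
# or at least five heavy-atom contacts within 5 A. The Q score of two
# interfaces is the (optionally distance-weighted) count of shared contacting
# residue pairs over the union of pairs, computed in a shared homologous
# position coordinate.

CB_CUTOFF <- 12
ATOMIC_CUTOFF <- 5
MIN_CB_PAIRS <- 10
MIN_ATOMIC_ALONE <- 5

cross_dist <- function(a, b) {
  # euclidean distances between rows of a (n x 3) and rows of b (m x 3)
  d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

#' Contact pairs between two chains
#'
#' @param chainA,chainB `qc_chain` objects with coordinates.
#' @return list with `cb_pairs` (data.frame pos_i, pos_j, d: all residue pairs
#'   whose representative points are within 12 A) and `atomic5_pairs`
#'   (data.frame pos_i, pos_j: residue pairs with any heavy-atom contact
#'   within 5 A). Empty data frames when the chains are apart.
#' @export
contact_pairs <- function(chainA, chainB) {
  da <- cross_dist(chainA$rep$xyz, chainB$rep$xyz)
  hit <- which(da <= CB_CUTOFF, arr.ind = TRUE)
  cb <- data.frame(pos_i = chainA$rep$seq_pos[hit[, 1]],
                   pos_j = chainB$rep$seq_pos[hit[, 2]],
                   d = da[hit])
  cb <- cb[order(cb$pos_i, cb$pos_j), , drop = FALSE]
  # atomic contacts: restrict the all-atom scan to residues already within
  # CB_CUTOFF + slack of each other (atoms cannot bridge further than their
  # residues' representative points by more than the side-chain span)
  xa <- chain_xyz(chainA); xb <- chain_xyz(chainB)
  dd <- cross_dist(xa, xb)
  ahit <- which(dd <= ATOMIC_CUTOFF, arr.ind = TRUE)
  ap <- unique(data.frame(pos_i = chainA$atoms$seq_pos[ahit[, 1]],
                          pos_j = chainB$atoms$seq_pos[ahit[, 2]]))
  ap <- ap[order(ap$pos_i, ap$pos_j), , drop = FALSE]
  rownames(cb) <- rownames(ap) <- NULL
  list(cb_pairs = cb, atomic5_pairs = ap)
}

#' Interface criterion for a chain pair
#'
#' True iff the pair has >= 10 representative-point pairs within 12 A together
#' with >= 1 atomic contact within 5 A, or >= 5 atomic contacts within 5 A.
#'
#' @param chainA,chainB `qc_chain` objects, or a precomputed [contact_pairs()]
#'   result passed as `cp`.
#' @param cp optional precomputed contact pairs.
#' @return logical.
#' @export
is_interface <- function(chainA, chainB, cp = NULL) {
  if (is.null(cp)) cp <- contact_pairs(chainA, chainB)
  n_cb <- nrow(cp$cb_pairs); n_at <- nrow(cp$atomic5_pairs)
  (n_cb >= MIN_CB_PAIRS && n_at >= 1) || n_at >= MIN_ATOMIC_ALONE
}

new_interface <- function(id, chain_a, chain_b, cp) {
  structure(list(
    interface_id = id,
    chain_pair = c(chain_a, chain_b),
    contact_pairs = cp$cb_pairs,
    n_cb_12A = nrow(cp$cb_pairs),
    n_atomic_5A = nrow(cp$atomic5_pairs),
    area_proxy = nrow(cp$cb_pairs)
  ), class = "qc_interface")
}

#' Find all chain-chain interfaces in an assembly
#'
#' Scans every unordered chain pair; pairs passing [is_interface()] become
#' Interface records. Interface ids follow lexicographic chain-pair order.
#' The area proxy is the representative-point pair count (a descending sort
#' key standing in for buried surface area).
#'
#' @param assembly a `qc_assembly` or any list with a `chains` element.
#' @return list of `qc_interface`.
#' @export
find_interfaces <- function(assembly) {
  chains <- assembly$chains
  ids <- names(chains)
  out <- list()
  k <- 0L
  if (length(ids) >= 2) {
    ord <- order(ids)
    for (ii in seq_along(ord)) {
      for (jj in seq_along(ord)) {
        if (jj <= ii) next
        a <- ids[ord[ii]]; b <- ids[ord[jj]]
        cp <- contact_pairs(chains[[a]], chains[[b]])
        if (is_interface(cp = cp)) {
          k <- k + 1L
          out[[k]] <- new_interface(k, a, b, cp)
        }
      }
    }
  }
  out
}

# Map an interface's contact pairs into a homologous column coordinate.
# map_a / map_b: named integer vectors seq_pos -> column; NULL = identity.
mapped_pairs <- function(iface, map_a = NULL, map_b = NULL) {
  cp <- iface$contact_pairs
  ci <- if (is.null(map_a)) cp$pos_i else unname(map_a[as.character(cp$pos_i)])
  cj <- if (is.null(map_b)) cp$pos_j else unname(map_b[as.character(cp$pos_j)])
  keep <- !is.na(ci) & !is.na(cj)
  data.frame(ci = ci[keep], cj = cj[keep], d = cp$d[keep])
}

qscore_from_sets <- function(p1, p2, weight_mode, sigma) {
  k1 <- paste(p1$ci, p1$cj); k2 <- paste(p2$ci, p2$cj)
  common <- intersect(k1, k2)
  n_union <- length(union(k1, k2))
  if (length(common) == 0)
    return(list(value = 0, n_common = 0L, n_union = n_union))
  if (weight_mode == "jaccard") {
    val <- length(common) / n_union
  } else {
    dd <- abs(p1$d[match(common, k1)] - p2$d[match(common, k2)])
    val <- sum(exp(-dd^2 / (2 * sigma^2))) / n_union
  }
  list(value = val, n_common = length(common), n_union = n_union)
}

#' Q score between two interfaces
#'
#' Shared contacting residue pairs over the union of pairs, after mapping
#' both interfaces' residue positions into a common homologous coordinate
#' (HMM match-state columns or alignment columns; identity within one entry).
#' In "distance" mode each common pair is weighted by
#' `exp(-dd^2 / (2 sigma^2))` where dd is the difference of the pair's
#' representative-point distances in the two interfaces; "jaccard" mode
#' weights every common pair 1. When both interfaces join chains of one
#' architecture the pair orientation is ambiguous (isologous case), so both
#' orientations are scored and the larger value returned.
#'
#' @param i1,i2 `qc_interface`.
#' @param map1,map2 lists with elements `a` and `b`: named integer vectors
#'   (seq_pos -> column) for each interface's two chains; NULL = identity.
#' @param weight_mode "jaccard" (reference behaviour) or "distance".
#' @param sigma distance-weight width in Angstroms (default 3).
#' @param try_swap also score the swapped orientation of `i2` (default TRUE;
#'   callers may disable when chain architectures differ).
#' @return object of class `qc_qscore`: list(value, n_common, n_union).
#' @export
qscore <- function(i1, i2, map1 = NULL, map2 = NULL,
                   weight_mode = c("jaccard", "distance"), sigma = 3,
                   try_swap = TRUE) {
  weight_mode <- match.arg(weight_mode)
  p1 <- mapped_pairs(i1, map1$a, map1$b)
  p2 <- mapped_pairs(i2, map2$a, map2$b)
  if (nrow(p1) == 0 && nrow(p2) == 0)
    qc_stop("qc_qscore_undefined", "both mapped contact-pair sets are empty")
  # canonical orientation: unordered pairs compared with ci<->cj both ways
  best <- qscore_from_sets(p1, p2, weight_mode, sigma)
  if (try_swap) {
    p2s <- data.frame(ci = p2$cj, cj = p2$ci, d = p2$d)
    alt <- qscore_from_sets(p1, p2s, weight_mode, sigma)
    if (alt$value > best$value) best <- alt
  }
  structure(best, class = "qc_qscore")
}
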