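# Crystal forms: grouping entries of one architecture group into
# independent experiments. Two X-ray entries share a crystal form when their
# space groups are identical and each of the six cell parameters differs by
# at most 5% (relative to the larger value). Every EM or NMR entry is its
# own crystal form.

#' Do two X-ray entries share a crystal form?
#'
#' @param entry_a,entry_b `qc_structure` (or any list with `space_group`,
#'   `cell`, `method`).
#' @param cell_tol relative per-parameter tolerance (default 0.05).
#' @return logical.
#' @export
same_crystal_form <- function(entry_a, entry_b, cell_tol = 0.05) {
  if (is.null(entry_a$cell) || is.null(entry_b$cell))
    qc_stop("qc_cf_error", "crystal-form comparison requires unit cells")
  if (!identical(entry_a$space_group, entry_b$space_group)) return(FALSE)
  pa <- entry_a$cell; pb <- entry_b$cell
  all(abs(pa - pb) / pmax(pa, pb) <= cell_tol)
}

#' Group entries into crystal forms
#'
#' X-ray entries are grouped by single linkage over [same_crystal_form()];
#' each EM/NMR/other entry is its own crystal form. Crystal-form ids are
#' deterministic: forms sorted by their lexicographically smallest entry id.
#'
#' @param entries list of `qc_structure` from one architecture group.
#' @param cell_tol see [same_crystal_form()].
#' @return list of `qc_crystal_form`: list(cf_id, entry_ids, space_group,
#'   representative_cell).
#' @export
group_crystal_forms <- function(entries, cell_tol = 0.05) {
  if (length(entries) == 0) return(list())
  ids <- vapply(entries, `[[`, "", "entry_id")
  methods <- vapply(entries, `[[`, "", "method")
  xray <- which(methods == "XRAY")
  groups <- list()
  if (length(xray) > 0) {
    n <- length(xray)
    pairs <- NULL
    if (n >= 2) {
      for (i in 1:(n - 1)) for (j in (i + 1):n) {
        if (same_crystal_form(entries[[xray[i]]], entries[[xray[j]]], cell_tol))
          pairs <- rbind(pairs, c(i, j))
      }
    }
    memb <- single_linkage(n, pairs %||% matrix(integer(0), 0, 2))
    for (m in sort(unique(memb)))
      groups[[length(groups) + 1L]] <- xray[memb == m]
  }
  for (k in which(methods != "XRAY")) groups[[length(groups) + 1L]] <- k
  # deterministic order: by smallest entry id within each form
  first_id <- vapply(groups, function(g) min(ids[g]), "")
  groups <- groups[order(first_id)]
  lapply(seq_along(groups), function(k) {
    g <- groups[[k]]
    e1 <- entries[[g[1]]]
    structure(list(
      cf_id = k,
      entry_ids = sort(ids[g]),
      space_group = if (e1$method == "XRAY") e1$space_group else e1$method,
      representative_cell = e1$cell
    ), class = "qc_crystal_form")
  })
}

#' Crystal-form id per entry
#'
#' @param cfs result of [group_crystal_forms()].
#' @return named integer vector entry_id -> cf_id.
#' @export
cf_assignment <- function(cfs) {
  out <- integer(0)
  for (cf in cfs) out[cf$entry_ids] <- cf$cf_id
  out
}
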