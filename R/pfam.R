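# Pfam architecture strings and homologous residue-position maps.
#
# A chain architecture lists the chain's Pfam domains N-to-C, each in
# parentheses, joined by underscores: "(Cyclin_N)_(Cyclin_C)". A domain split
# by insertions is rendered with residue ranges, e.g. "(IMPDH[1-82])". The
# entry architecture concatenates the unique chain architectures
# (lexicographic order); the assembly architecture adds copy counts, e.g.
# "(Pkinase)2". Position maps send residue positions to Pfam match-state
# columns (from a supplied assignment table) or to alignment columns of a
# pairwise global alignment when no table is available.

#' Read a domain-assignment table
#'
#' TSV with columns entry_id, chain_id, pfam_id, seq_start, seq_end and an
#' optional `hmm_map` column of comma-separated `seqpos:column` pairs (an
#' absent map means the identity map onto match states 1..length).
#'
#' @param path TSV path.
#' @return data.frame of assignments with an `hmm_map` list-column of named
#'   integer vectors.
#' @export
read_assignments <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("entry_id", "chain_id", "pfam_id", "seq_start", "seq_end")
  if (!all(need %in% names(df)))
    qc_stop("qc_io_error", "assignment table lacks columns: %s",
            paste(setdiff(need, names(df)), collapse = ", "))
  df$hmm_map <- lapply(seq_len(nrow(df)), function(i) {
    raw <- if ("hmm_map" %in% names(df)) df$hmm_map[[i]] else NA
    if (is.null(raw) || is.na(raw) || !nzchar(raw)) {
      pos <- df$seq_start[i]:df$seq_end[i]
      return(stats::setNames(seq_along(pos), pos))
    }
    kv <- strsplit(strsplit(raw, ",")[[1]], ":")
    stats::setNames(as.integer(vapply(kv, `[`, "", 2)),
                    vapply(kv, `[`, "", 1))
  })
  df
}

validate_chain_assignments <- function(asg, max_overlap = 10) {
  if (nrow(asg) == 0) return(asg)
  asg <- asg[order(asg$seq_start, asg$seq_end), , drop = FALSE]
  if (any(asg$seq_start > asg$seq_end))
    qc_stop("qc_assignment_error", "assignment with seq_start > seq_end")
  if (nrow(asg) >= 2) {
    for (i in 2:nrow(asg)) {
      ov <- asg$seq_end[i - 1] - asg$seq_start[i] + 1
      if (ov > max_overlap)
        qc_stop("qc_assignment_error",
                "assignments %s and %s overlap by %d residues (>%d)",
                asg$pfam_id[i - 1], asg$pfam_id[i], ov, max_overlap)
    }
  }
  asg
}

#' Chain Pfam architecture from one chain's assignments
#'
#' Domains are concatenated N-to-C. Multiple segments of the same Pfam with
#' another domain between them are rendered as a split domain with residue
#' ranges (`(IMPDH[1-82])_(CBS)_(CBS)_(IMPDH[83-345])`); the ranges are the
#' match-state (column) spans of each segment.
#'
#' @param assignments data.frame rows for one chain (see
#'   [read_assignments()]).
#' @return architecture string; "(NA)" when no assignment.
#' @export
chain_architecture <- function(assignments) {
  if (is.null(assignments) || nrow(assignments) == 0) return("(NA)")
  asg <- validate_chain_assignments(assignments)
  # a repeated Pfam is a tandem repeat when its segments span the same HMM
  # columns (full copies) and a split domain when the spans are complementary
  is_split <- rep(FALSE, nrow(asg))
  for (p in names(which(table(asg$pfam_id) > 1))) {
    rows <- which(asg$pfam_id == p)
    spans <- lapply(asg$hmm_map[rows], function(m) range(m))
    overlap <- function(a, b) {
      ov <- min(a[2], b[2]) - max(a[1], b[1]) + 1
      ov / min(a[2] - a[1] + 1, b[2] - b[1] + 1)
    }
    pairwise <- outer(seq_along(rows), seq_along(rows), Vectorize(function(i, j)
      if (i == j) 1 else overlap(spans[[i]], spans[[j]])))
    if (any(pairwise < 0.5)) is_split[rows] <- TRUE
  }
  parts <- vapply(seq_len(nrow(asg)), function(i) {
    if (is_split[i]) {
      cols <- asg$hmm_map[[i]]
      sprintf("(%s[%d-%d])", asg$pfam_id[i], min(cols), max(cols))
    } else sprintf("(%s)", asg$pfam_id[i])
  }, "")
  paste(parts, collapse = "_")
}

#' Entry Pfam architecture
#'
#' Concatenation of the unique chain architectures of the entry, in
#' lexicographic order (a canonical order so the string can serve as a
#' grouping key).
#'
#' @param chain_archs character vector of per-chain architecture strings
#'   (chains without a Pfam hit contribute "(NA)").
#' @return entry architecture string.
#' @export
entry_architecture <- function(chain_archs) {
  paste(sort(unique(chain_archs)), collapse = "")
}

assembly_architecture_from_chains <- function(chain_archs) {
  tab <- table(chain_archs)
  u <- sort(names(tab))
  paste0(vapply(u, function(a) {
    n <- as.integer(tab[[a]])
    paste0(a, if (n > 1) n else "")
  }, ""), collapse = "")
}

#' Assembly Pfam architecture
#'
#' Unique chain architectures with copy counts: a kinase homodimer is
#' "(Pkinase)2", a 2:2 kinase/cyclin assembly
#' "(Cyclin_N)_(Cyclin_C)2(Pkinase)2".
#'
#' @param assembly a `qc_assembly`, or NULL when `chain_archs` is given.
#' @param chain_archs named chain_id -> architecture vector; default taken
#'   from the assembly's chains.
#' @return assembly architecture string.
#' @export
assembly_architecture <- function(assembly = NULL, chain_archs = NULL) {
  if (is.null(chain_archs)) {
    chain_archs <- vapply(assembly$chains,
                          function(ch) ch$pfam_arch %||% "(NA)", "")
  }
  assembly_architecture_from_chains(chain_archs)
}

#' Residue-position to HMM-column map for one chain
#'
#' Union of the per-domain maps; positions outside any domain (or inside
#' insertions dropped from the HMM map) stay unmapped. Columns are made
#' globally unique across domains by prefixing the Pfam id.
#'
#' @param assignments data.frame rows for one chain.
#' @return named character vector seq_pos -> "pfam:column".
#' @export
residue_to_hmm_map <- function(assignments) {
  if (is.null(assignments) || nrow(assignments) == 0) return(stats::setNames(character(0), character(0)))
  asg <- validate_chain_assignments(assignments)
  out <- character(0)
  for (i in seq_len(nrow(asg))) {
    m <- asg$hmm_map[[i]]
    vals <- sprintf("%s:%d", asg$pfam_id[i], unname(m))
    pos <- names(m)
    clash <- intersect(pos, names(out))
    if (length(clash) > 0 && any(out[clash] != vals[match(clash, pos)]))
      qc_stop("qc_assignment_error",
              "conflicting HMM columns for positions: %s",
              paste(utils::head(clash, 3), collapse = ", "))
    out[pos] <- vals
  }
  out
}

# amino-acid substitution matrix: match 1, mismatch -1
aa_sub_matrix <- function() {
  ab <- c(Biostrings::AA_STANDARD, "X", "U", "O", "B", "Z", "*")
  m <- matrix(-1, length(ab), length(ab), dimnames = list(ab, ab))
  diag(m) <- 1
  m
}

align_global <- function(seq_a, seq_b) {
  Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    type = "global", substitutionMatrix = aa_sub_matrix(),
    gapOpening = 10, gapExtension = 0.5)
}

#' Pairwise position map from a global alignment
#'
#' Fallback homologous coordinate when no HMM assignment table is supplied:
#' global Needleman-Wunsch alignment (match 1, mismatch -1, gap open 10, gap
#' extend 0.5); aligned non-gap columns define the map from positions of
#' `seq_a` to positions of `seq_b`.
#'
#' @param seq_a,seq_b one-letter amino-acid strings.
#' @return list with `map` (named integer vector posA -> posB) and
#'   `identity` (fraction in [0,1] over alignment columns).
#' @export
pairwise_position_map <- function(seq_a, seq_b) {
  if (!nzchar(seq_a) || !nzchar(seq_b))
    qc_stop("qc_alignment_error", "empty sequence")
  if (identical(seq_a, seq_b)) {
    n <- nchar(seq_a)
    return(list(map = stats::setNames(seq_len(n), seq_len(n)), identity = 1))
  }
  pa <- align_global(seq_a, seq_b)
  sa <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  sb <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  ia <- 0L; ib <- 0L
  from <- integer(0); to <- integer(0); nid <- 0L
  for (k in seq_along(sa)) {
    ga <- sa[k] == "-"; gb <- sb[k] == "-"
    if (!ga) ia <- ia + 1L
    if (!gb) ib <- ib + 1L
    if (!ga && !gb) {
      from <- c(from, ia); to <- c(to, ib)
      if (sa[k] == sb[k]) nid <- nid + 1L
    }
  }
  list(map = stats::setNames(to, from), identity = nid / length(sa))
}

#' Build homologous position maps for a set of chains
#'
#' Every chain gets a named map seq_pos -> global column (character), either
#' from HMM assignments (columns "pfam:col") or, in the fallback, alignment
#' positions onto the longest chain of its architecture group.
#'
#' @param chains named list of `qc_chain` (names may repeat entry-qualified
#'   ids; keys of the result follow `names(chains)`).
#' @param archs named architecture per chain (defaults to one group).
#' @param assignments optional assignment data.frame with `key` column
#'   matching `names(chains)`.
#' @return named list of maps.
#' @export
build_position_maps <- function(chains, archs = NULL, assignments = NULL) {
  keys <- names(chains)
  if (is.null(archs)) archs <- stats::setNames(rep("(NA)", length(keys)), keys)
  maps <- vector("list", length(keys)); names(maps) <- keys
  if (!is.null(assignments)) {
    for (k in keys) {
      rows <- assignments[assignments$key == k, , drop = FALSE]
      maps[[k]] <- residue_to_hmm_map(rows)
    }
    return(maps)
  }
  for (g in unique(archs)) {
    members <- keys[archs[keys] == g]
    seqs <- vapply(chains[members], `[[`, "", "sequence")
    ref <- members[order(-nchar(seqs), members)][1]
    for (k in members) {
      mp <- pairwise_position_map(chains[[k]]$sequence, chains[[ref]]$sequence)
      maps[[k]] <- stats::setNames(sprintf("%s:%d", g, unname(mp$map)), names(mp$map))
    }
  }
  maps
}
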