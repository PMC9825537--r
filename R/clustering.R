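# Binary assembly similarity, single-linkage assembly clustering within
# (architecture, stoichiometry, symmetry) cells, and cluster evidence
# statistics (R_CF_UNPclus, annotation agreement, sequence-identity
# distributions).

# position maps for every chain of a set of assemblies, keyed
# "<assembly_id>:<chain_id>"
assembly_chain_maps <- function(assemblies, assignments = NULL) {
  chains <- list(); archs <- character(0)
  for (a in assemblies) {
    for (cid in names(a$chains)) {
      key <- paste0(a$assembly_id, ":", cid)
      chains[[key]] <- a$chains[[cid]]
      archs[key] <- (a$chain_archs %||% stats::setNames(rep("(NA)", length(a$chains)),
                                                        names(a$chains)))[cid]
    }
  }
  build_position_maps(chains, archs, assignments)
}

iface_maps <- function(assembly, iface, maps) {
  list(a = maps[[paste0(assembly$assembly_id, ":", iface$chain_pair[1])]],
       b = maps[[paste0(assembly$assembly_id, ":", iface$chain_pair[2])]])
}

# cache connecting/unique interface sets on the assembly
iface_clusters_of <- function(assembly, q_within, weight_mode) {
  assembly$iface_clusters %||%
    connecting_interfaces(assembly, q_within = q_within, weight_mode = weight_mode)
}

#' Binary similarity of two assemblies
#'
#' Assemblies must share assembly architecture (with copy counts) and
#' symmetry label; comparing across those cells is an error. S12 = 1 iff
#' every unique connecting interface of assembly 1 (checked from largest to
#' smallest) matches some unique interface of assembly 2 with Q >= `q_match`
#' in the shared homologous coordinate; S21 symmetric; S = S12 * S21.
#'
#' @param a1,a2 annotated `qc_assembly`.
#' @param maps named chain position maps (see internals); built on the fly
#'   from pairwise alignments when NULL.
#' @param q_match cross-assembly interface-match threshold (default 0.5).
#' @param q_within within-assembly clustering threshold (default 0.75).
#' @param weight_mode Q-score weighting.
#' @return list(s12, s21, s) of 0/1 integers.
#' @export
assembly_similarity <- function(a1, a2, maps = NULL, q_match = 0.5,
                                q_within = 0.75, weight_mode = "jaccard") {
  if (!identical(a1$pfam_assembly_arch, a2$pfam_assembly_arch) ||
      !identical(a1$symmetry, a2$symmetry))
    qc_stop("qc_incomparable",
            "assemblies %s and %s are in different (architecture, symmetry) cells",
            a1$assembly_id, a2$assembly_id)
  if (is.null(maps)) maps <- assembly_chain_maps(list(a1, a2))
  ic1 <- iface_clusters_of(a1, q_within, weight_mode)
  ic2 <- iface_clusters_of(a2, q_within, weight_mode)
  get_iface <- function(a, id) {
    ids <- vapply(a$interfaces, `[[`, integer(1), "interface_id")
    a$interfaces[[match(id, ids)]]
  }
  one_way <- function(ax, icx, ay, icy) {
    for (rid in icx$connecting) {     # already in descending area order
      fx <- get_iface(ax, rid)
      found <- FALSE
      for (uid in icy$representatives) {
        fy <- get_iface(ay, uid)
        v <- tryCatch(
          qscore(fx, fy, map1 = iface_maps(ax, fx, maps),
                 map2 = iface_maps(ay, fy, maps),
                 weight_mode = weight_mode)$value,
          qc_qscore_undefined = function(e) 0)
        if (v >= q_match) { found <- TRUE; break }
      }
      if (!found) return(0L)
    }
    1L
  }
  s12 <- one_way(a1, ic1, a2, ic2)
  s21 <- one_way(a2, ic2, a1, ic1)
  list(s12 = s12, s21 = s21, s = s12 * s21)
}

#' Cluster assemblies across crystal forms
#'
#' Within each (assembly architecture, symmetry) cell — the architecture
#' string carries the stoichiometry copy counts — assemblies with mutual
#' binary similarity 1 are merged by single linkage. Clusters are sorted by
#' (#CFs, #entries) descending and numbered deterministically.
#'
#' @param assemblies list of annotated, connected `qc_assembly`.
#' @param cf_ids named integer vector entry_id -> crystal-form id (see
#'   [cf_assignment()]); entries missing from it get one CF each.
#' @param q_match,q_within,weight_mode see [assembly_similarity()].
#' @param assignments optional HMM assignment table for position maps.
#' @return list of `qc_assembly_cluster`.
#' @export
cluster_assemblies <- function(assemblies, cf_ids = NULL, q_match = 0.5,
                               q_within = 0.75, weight_mode = "jaccard",
                               assignments = NULL) {
  if (length(assemblies) == 0) return(list())
  # deterministic processing order regardless of input order
  aid <- vapply(assemblies, `[[`, "", "assembly_id")
  assemblies <- assemblies[order(aid)]
  entry <- vapply(assemblies, `[[`, "", "entry_id")
  if (is.null(cf_ids))
    cf_ids <- stats::setNames(seq_along(unique(entry)), sort(unique(entry)))
  arch <- vapply(assemblies, `[[`, "", "pfam_assembly_arch")
  sym <- vapply(assemblies, `[[`, "", "symmetry")
  cellkey <- paste(arch, sym, sep = "|")
  clusters <- list()
  for (cell in sort(unique(cellkey))) {
    idx <- which(cellkey == cell)
    sub <- assemblies[idx]
    maps <- assembly_chain_maps(sub, assignments)
    for (k in seq_along(sub))
      sub[[k]]$iface_clusters <- connecting_interfaces(sub[[k]], q_within, weight_mode)
    n <- length(sub)
    pairs <- NULL
    if (n >= 2) {
      for (i in 1:(n - 1)) for (j in (i + 1):n) {
        s <- assembly_similarity(sub[[i]], sub[[j]], maps = maps,
                                 q_match = q_match, q_within = q_within,
                                 weight_mode = weight_mode)
        if (s$s == 1) pairs <- rbind(pairs, c(i, j))
      }
    }
    memb <- single_linkage(n, pairs %||% matrix(integer(0), 0, 2))
    for (m in sort(unique(memb))) {
      members <- lapply(which(memb == m), function(k) {
        a <- sub[[k]]
        list(assembly = a, entry_id = a$entry_id,
             cf_id = unname(cf_ids[a$entry_id]),
             entity_keys = unique(unname(a$entities %||%
                                           assign_entities(a$chains))))
      })
      mids <- vapply(members, function(x) x$assembly$assembly_id, "")
      members <- members[order(mids)]
      unps <- unique(unlist(lapply(members, `[[`, "entity_keys")))
      clusters[[length(clusters) + 1L]] <- structure(list(
        cluster_id = NA_character_,
        arch = sub[[1]]$pfam_assembly_arch,
        stoichiometry = sub[[1]]$stoich_by_arch %||% sub[[1]]$stoichiometry,
        symmetry = sub[[1]]$symmetry,
        members = members,
        n_cfs = length(unique(vapply(members, `[[`, integer(1), "cf_id"))),
        n_entries = length(unique(vapply(members, `[[`, "", "entry_id"))),
        n_unps = sum(!is.na(unps)),
        representative = sort(mids)[1]
      ), class = "qc_assembly_cluster")
    }
  }
  ord <- order(-vapply(clusters, `[[`, integer(1), "n_cfs"),
               -vapply(clusters, `[[`, integer(1), "n_entries"),
               vapply(clusters, `[[`, "", "representative"))
  clusters <- clusters[ord]
  for (k in seq_along(clusters))
    clusters[[k]]$cluster_id <- sprintf("clus%03d", k)
  clusters
}

#' @export
print.qc_assembly_cluster <- function(x, ...) {
  cat(sprintf("<cluster %s: %s %s %s; %d members, %d CFs, %d entries, %d UniProts>\n",
              x$cluster_id, x$arch, x$stoichiometry, x$symmetry,
              length(x$members), x$n_cfs, x$n_entries, x$n_unps))
  invisible(x)
}

#' R_CF_UNPclus evidence statistic for a cluster
#'
#' For each entity (UniProt) in the cluster: the number of crystal forms in
#' the cluster containing that entity (CF_UNPclus) over the number of crystal
#' forms of that entity-and-architecture combination in the whole corpus
#' (CF_UNParch). The cluster-level ratio is the sum of cluster CFs over the
#' sum of corpus CFs across the cluster's entities with defined keys.
#'
#' @param cluster a `qc_assembly_cluster`.
#' @param corpus_cfs named integer vector entity_key -> corpus CF count for
#'   the cluster's architecture.
#' @return object of class `qc_cluster_stats`: list(per_unp data.frame,
#'   r_cf_unpclus, text = 2-decimal rendering).
#' @export
r_cf_unpclus <- function(cluster, corpus_cfs) {
  rows <- list()
  for (m in cluster$members) {
    for (u in m$entity_keys) {
      if (is.na(u)) next
      rows[[length(rows) + 1L]] <- data.frame(unp = u, cf_id = m$cf_id)
    }
  }
  if (length(rows) == 0)
    qc_stop("qc_stats_error", "cluster has no members with defined entity keys")
  df <- unique(do.call(rbind, rows))
  per <- do.call(rbind, lapply(split(df, df$unp), function(d) {
    u <- d$unp[1]
    n_clus <- length(unique(d$cf_id))
    n_arch <- corpus_cfs[u]
    if (is.na(n_arch) || n_arch == 0)
      qc_stop("qc_data_inconsistency", "no corpus CF count for entity %s", u)
    if (n_clus > n_arch)
      qc_stop("qc_data_inconsistency",
              "entity %s: cluster CFs (%d) exceed corpus CFs (%d)", u, n_clus, n_arch)
    data.frame(unp = u, cf_unpclus = n_clus, cf_unparch = as.integer(n_arch),
               r_cf_unpclus = n_clus / n_arch, stringsAsFactors = FALSE)
  }))
  per <- per[order(per$unp), , drop = FALSE]
  rownames(per) <- NULL
  r <- sum(per$cf_unpclus) / sum(per$cf_unparch)
  structure(list(per_unp = per, r_cf_unpclus = r,
                 text = sprintf("%.2f", r)),
            class = "qc_cluster_stats")
}

#' Agreement of external biological-assembly annotations with a cluster
#'
#' Counts, per annotation source, the cluster's member entries whose labeled
#' assembly matches the cluster member of the same entry under
#' [assembly_similarity()] (gated on architecture and symmetry; a gate
#' violation, e.g. a half-tetramer annotation on a tetramer cluster, counts
#' as no match).
#'
#' @param cluster a `qc_assembly_cluster`.
#' @param annotations list of list(entry_id, source, assembly) where
#'   `assembly` is an annotated `qc_assembly`; NULL when no table was
#'   supplied.
#' @param q_match,q_within,weight_mode see [assembly_similarity()].
#' @return named integer vector of per-source counts, or NULL when
#'   `annotations` is NULL (absence, not zero).
#' @export
annotation_agreement <- function(cluster, annotations, q_match = 0.5,
                                 q_within = 0.75, weight_mode = "jaccard") {
  if (is.null(annotations)) return(NULL)
  member_entries <- vapply(cluster$members, `[[`, "", "entry_id")
  sources <- sort(unique(vapply(annotations, `[[`, "", "source")))
  counts <- stats::setNames(integer(length(sources)), sources)
  for (ann in annotations) {
    if (!ann$entry_id %in% member_entries) next
    m <- cluster$members[[match(ann$entry_id, member_entries)]]
    same <- tryCatch(
      assembly_similarity(m$assembly, ann$assembly, q_match = q_match,
                          q_within = q_within, weight_mode = weight_mode)$s == 1,
      qc_incomparable = function(e) FALSE,
      qc_assembly_error = function(e) FALSE)
    if (same) counts[ann$source] <- counts[ann$source] + 1L
  }
  counts
}

#' Intra- and inter-cluster sequence-identity distributions
#'
#' For clusters of one architecture with at least `min_cfs` crystal forms:
#' intra = per cluster with >= 2 distinct entities, the mean pairwise global
#' identity between its distinct entity sequences; inter = per cluster pair,
#' the mean identity between entities of the two clusters. Identities in
#' [0, 100].
#'
#' @param clusters list of `qc_assembly_cluster` from one architecture.
#' @param min_cfs minimum #CFs per cluster (default 3).
#' @return list(intra, inter) of numeric vectors (possibly empty).
#' @export
identity_stats <- function(clusters, min_cfs = 3) {
  clusters <- Filter(function(cl) cl$n_cfs >= min_cfs, clusters)
  # one representative sequence per entity per cluster
  entity_seqs <- lapply(clusters, function(cl) {
    out <- character(0)
    for (m in cl$members) {
      ents <- m$assembly$entities %||% assign_entities(m$assembly$chains)
      for (cid in names(m$assembly$chains)) {
        u <- ents[cid]
        if (is.na(u) || u %in% names(out)) next
        out[u] <- m$assembly$chains[[cid]]$sequence
      }
    }
    out
  })
  intra <- numeric(0)
  for (seqs in entity_seqs) {
    if (length(seqs) < 2) next
    v <- numeric(0)
    for (i in 1:(length(seqs) - 1)) for (j in (i + 1):length(seqs))
      v <- c(v, sequence_identity(seqs[i], seqs[j]))
    intra <- c(intra, mean(v))
  }
  inter <- numeric(0)
  if (length(entity_seqs) >= 2) {
    for (i in 1:(length(entity_seqs) - 1)) for (j in (i + 1):length(entity_seqs)) {
      sa <- entity_seqs[[i]]; sb <- entity_seqs[[j]]
      sb <- sb[setdiff(names(sb), names(sa))]
      if (length(sa) == 0 || length(sb) == 0) next
      v <- numeric(0)
      for (x in sa) for (y in sb) v <- c(v, sequence_identity(x, y))
      inter <- c(inter, mean(v))
    }
  }
  list(intra = intra, inter = inter)
}
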