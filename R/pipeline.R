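# End-to-end orchestration: read candidate assemblies, annotate, group
# crystal forms, cluster, and write reports.
#
# Input layout: a directory of structure files, one candidate assembly per
# file, named `<entry>__<label>.cif` (the entry id is also read from the
# file header). Optional sidecar tables: a domain-assignment TSV and an
# entity TSV (entry_id, chain_id, unp).

#' Pipeline configuration
#'
#' Thresholds and paths for [run_pipeline()]. Defaults mirror the package's
#' analysis defaults: within-assembly interface clustering at Q >= 0.75,
#' cross-assembly interface match at Q >= 0.5, 5% unit-cell tolerance, 95%
#' sequence identity for entity assignment.
#'
#' @param input_dir directory of candidate assembly files (mmCIF/PDB).
#' @param out_dir report directory.
#' @param assignments optional domain-assignment TSV path.
#' @param entities optional entity TSV path (entry_id, chain_id, unp).
#' @param q_within,q_match,cf_cell_tol,entity_identity thresholds.
#' @param weight_mode Q-score weighting ("jaccard" or "distance").
#' @param rmsd_tol,angle_tol,axis_tol symmetry-detector tolerances.
#' @param seed RNG seed recorded in the report (the pipeline itself is
#'   deterministic).
#' @param write_bundles also write per-cluster coordinate bundles and PyMOL
#'   alignment scripts.
#' @return a `qc_config` list.
#' @export
run_config <- function(input_dir, out_dir = file.path(input_dir, "report"),
                       assignments = NULL, entities = NULL,
                       q_within = 0.75, q_match = 0.5, cf_cell_tol = 0.05,
                       entity_identity = 0.95, weight_mode = "jaccard",
                       rmsd_tol = 3.0, angle_tol = 8, axis_tol = 10,
                       seed = 1L, write_bundles = FALSE) {
  stopifnot(q_within > 0, q_within <= 1, q_match > 0, q_match <= 1,
            cf_cell_tol >= 0, cf_cell_tol < 1,
            entity_identity > 0, entity_identity <= 1)
  structure(as.list(environment()), class = "qc_config")
}

#' Run the assembly-clustering pipeline
#'
#' Reads every structure file in `input_dir` as one candidate assembly,
#' deduplicates candidates per entry, excludes (and logs) assemblies whose
#' chain graph is not connected, annotates stoichiometry / symmetry /
#' architecture, groups entries into crystal forms per entry architecture,
#' clusters assemblies within (architecture, symmetry) cells, and computes
#' per-cluster statistics. Writes `report.json`, `clusters.tsv` and
#' `log.txt` under `out_dir`; the configuration is serialized alongside the
#' report. Re-running with the same inputs and configuration yields an
#' identical report.
#'
#' @param config a `qc_config` from [run_config()].
#' @return invisibly, list(clusters, crystal_forms, excluded, stats, report).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "qc_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- character(0)
  note <- function(...) logf <<- c(logf, sprintf(...))

  files <- sort(list.files(config$input_dir,
                           pattern = "\\.(cif|mmcif|pdb|ent)$",
                           full.names = TRUE))
  ent_tab <- if (!is.null(config$entities))
    utils::read.delim(config$entities, stringsAsFactors = FALSE) else NULL
  asg_tab <- if (!is.null(config$assignments))
    read_assignments(config$assignments) else NULL

  assemblies <- list(); structures <- list()
  for (f in files) {
    st <- tryCatch(read_structure(f), quatclust_error = function(e) {
      note("skip %s: %s", basename(f), conditionMessage(e)); NULL
    })
    if (is.null(st)) next
    label <- sub("\\.[^.]*$", "", basename(f))
    # entity keys from the sidecar table
    if (!is.null(ent_tab)) {
      for (cid in names(st$chains)) {
        hit <- ent_tab$unp[ent_tab$entry_id == st$entry_id &
                             ent_tab$chain_id == cid]
        if (length(hit) == 1) st$chains[[cid]]$entity_key <- hit
      }
    }
    asm <- build_assembly(st, assembly_id = label, source = "GENERATED")
    if (!is_connected(asm)) {
      note("excluded %s: assembly components not connected", label)
      next
    }
    # chain architectures from assignments
    archs <- NULL
    if (!is.null(asg_tab)) {
      archs <- stats::setNames(vapply(names(asm$chains), function(cid) {
        rows <- asg_tab[asg_tab$entry_id == st$entry_id &
                          asg_tab$chain_id == cid, , drop = FALSE]
        chain_architecture(rows)
      }, ""), names(asm$chains))
    }
    asm <- annotate_assembly(asm, archs = archs,
                             rmsd_tol = config$rmsd_tol,
                             angle_tol = config$angle_tol,
                             axis_tol = config$axis_tol)
    assemblies[[label]] <- asm
    if (!st$entry_id %in% names(structures)) structures[[st$entry_id]] <- st
  }

  # deduplicate candidates per entry
  by_entry <- split(assemblies,
                    vapply(assemblies, `[[`, "", "entry_id"))
  assemblies <- list()
  for (e in names(by_entry)) {
    merged <- merge_candidates(unname(by_entry[[e]]), q_match = config$q_match)
    for (a in merged) assemblies[[a$assembly_id]] <- a
  }
  note("loaded %d candidate assemblies from %d entries",
       length(assemblies), length(structures))

  # crystal forms per entry architecture
  entry_arch <- vapply(structures, function(st) {
    cls <- vapply(names(st$chains), function(cid) {
      if (is.null(asg_tab)) return("(NA)")
      chain_architecture(asg_tab[asg_tab$entry_id == st$entry_id &
                                   asg_tab$chain_id == cid, , drop = FALSE])
    }, "")
    entry_architecture(cls)
  }, "")
  cfs <- list(); cf_ids <- integer(0); cf_offset <- 0L
  for (g in sort(unique(entry_arch))) {
    grp <- group_crystal_forms(structures[entry_arch == g], config$cf_cell_tol)
    for (cf in grp) {
      cf$cf_id <- cf$cf_id + cf_offset
      cfs[[length(cfs) + 1L]] <- cf
      cf_ids[cf$entry_ids] <- cf$cf_id
    }
    cf_offset <- cf_offset + length(grp)
  }

  clusters <- cluster_assemblies(unname(assemblies), cf_ids = cf_ids,
                                 q_match = config$q_match,
                                 q_within = config$q_within,
                                 weight_mode = config$weight_mode)

  # corpus CF counts per entity (within this input set) for R_CF_UNPclus
  entity_cf <- list()
  for (a in assemblies) {
    ents <- a$entities
    for (u in unique(ents[!is.na(ents)]))
      entity_cf[[u]] <- union(entity_cf[[u]], cf_ids[a$entry_id])
  }
  corpus_cfs <- vapply(entity_cf, length, integer(1))

  stats <- lapply(clusters, function(cl) {
    tryCatch(r_cf_unpclus(cl, corpus_cfs), quatclust_error = function(e) NULL)
  })

  cluster_rows <- do.call(rbind, lapply(seq_along(clusters), function(k) {
    cl <- clusters[[k]]
    data.frame(cluster_id = cl$cluster_id, arch = cl$arch,
               stoichiometry = cl$stoichiometry, symmetry = cl$symmetry,
               n_cfs = cl$n_cfs, n_entries = cl$n_entries, n_unps = cl$n_unps,
               r_cf_unpclus = if (is.null(stats[[k]])) NA_real_
                              else round(stats[[k]]$r_cf_unpclus, 2),
               members = paste(vapply(cl$members,
                                      function(m) m$assembly$assembly_id, ""),
                               collapse = ","),
               stringsAsFactors = FALSE)
  }))

  report <- list(
    config = config[c("q_within", "q_match", "cf_cell_tol", "entity_identity",
                      "weight_mode", "rmsd_tol", "angle_tol", "axis_tol", "seed")],
    n_entries = length(structures),
    n_assemblies = length(assemblies),
    n_crystal_forms = length(cfs),
    clusters = cluster_rows %||% list()
  )
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(cluster_rows))
    utils::write.table(cluster_rows, file.path(config$out_dir, "clusters.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  writeLines(logf, file.path(config$out_dir, "log.txt"))

  if (isTRUE(config$write_bundles)) {
    for (cl in clusters) {
      bdir <- file.path(config$out_dir, cl$cluster_id)
      manifest <- write_cluster_bundle(cl, bdir)
      write_alignment_script(cl, file.path(bdir, "align.pml"),
                             files = basename(manifest))
    }
  }
  if (length(files) == 0) warning("no structure files under ", config$input_dir)

  invisible(list(clusters = clusters, crystal_forms = cfs,
                 excluded = grep("^excluded", logf, value = TRUE),
                 stats = stats, report = report))
}
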