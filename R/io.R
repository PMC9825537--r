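# Structure file I/O.
#
# mmCIF is read and written with a focused atom_site implementation (header
# items _entry, _cell, _symmetry, _exptl plus a standard atom_site loop); PDB
# format goes through bio3d. Only heavy atoms of polymer residues are loaded;
# waters, other heteroatoms and hydrogens are excluded, altlocs resolved to
# the highest-occupancy conformer, and only model 1 of multi-model (NMR)
# files is read by default.

AA3to1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
            GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
            MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
            TYR = "Y", VAL = "V", MSE = "M", SEC = "U", PYL = "O")
AA1to3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
            E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
            M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
            Y = "TYR", V = "VAL", U = "SEC", O = "PYL", X = "UNK")

method_from_string <- function(s) {
  if (is.na(s) || !nzchar(s)) return("OTHER")
  s <- toupper(s)
  if (grepl("X-RAY|XRAY", s)) "XRAY"
  else if (grepl("ELECTRON MICROSCOPY|CRYO-?EM", s)) "EM"
  else if (grepl("NMR", s)) "NMR"
  else "OTHER"
}
method_to_string <- function(m) {
  switch(m, XRAY = "X-RAY DIFFRACTION", EM = "ELECTRON MICROSCOPY",
         NMR = "SOLUTION NMR", "OTHER")
}

# Tokenize one CIF line, honouring single/double quotes.
cif_tokens <- function(line) {
  out <- character(0); i <- 1L; n <- nchar(line)
  while (i <= n) {
    ch <- substr(line, i, i)
    if (ch %in% c(" ", "\t")) { i <- i + 1L; next }
    if (ch %in% c("'", '"')) {
      j <- i + 1L
      while (j <= n && substr(line, j, j) != ch) j <- j + 1L
      out <- c(out, substr(line, i + 1L, j - 1L)); i <- j + 1L
    } else {
      j <- i
      while (j <= n && !substr(line, j, j) %in% c(" ", "\t")) j <- j + 1L
      out <- c(out, substr(line, i, j - 1L)); i <- j
    }
  }
  out
}

read_mmcif_raw <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines)]
  items <- list()
  atom <- NULL
  i <- 1L
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) { i <- i + 1L; next }
    if (identical(ln, "loop_")) {
      cols <- character(0); i <- i + 1L
      while (i <= length(lines) && grepl("^_", trimws(lines[i]))) {
        cols <- c(cols, trimws(lines[i])); i <- i + 1L
      }
      rows <- list()
      while (i <= length(lines)) {
        l2 <- trimws(lines[i])
        if (!nzchar(l2) || grepl("^(_|loop_|data_)", l2)) break
        rows[[length(rows) + 1L]] <- cif_tokens(l2)
        i <- i + 1L
      }
      if (any(grepl("^_atom_site\\.", cols))) {
        ok <- lengths(rows) == length(cols)
        m <- do.call(rbind, rows[ok])
        atom <- as.data.frame(m, stringsAsFactors = FALSE)
        names(atom) <- sub("^_atom_site\\.", "", cols)
      }
      next
    }
    if (grepl("^_", ln)) {
      tk <- cif_tokens(ln)
      if (length(tk) >= 2) items[[tk[1]]] <- tk[2]
      else if (length(tk) == 1 && i < length(lines)) {   # value on next line
        items[[tk[1]]] <- cif_tokens(trimws(lines[i + 1L]))[1]
        i <- i + 1L
      }
    }
    i <- i + 1L
  }
  list(items = items, atom = atom)
}

# Build qc_chain objects from a normalized atom table.
chains_from_atom_table <- function(at) {
  # at: chain, resno (int), resid (3-letter), atom, elem, x, y, z, occ, alt
  # drop hydrogens, waters/hetero handled upstream
  at <- at[!(at$elem %in% c("H", "D")), , drop = FALSE]
  if (nrow(at) == 0) return(list())
  chains <- list()
  for (cid in unique(at$chain)) {
    sub <- at[at$chain == cid, , drop = FALSE]
    # altloc: keep highest occupancy (ties -> first alphabetically) per atom
    if (any(nzchar(sub$alt))) {
      key <- paste(sub$resno, sub$atom)
      ord <- order(key, -sub$occ, sub$alt)
      sub <- sub[ord, , drop = FALSE]
      sub <- sub[!duplicated(paste(sub$resno, sub$atom)), , drop = FALSE]
    }
    pos <- sort(unique(sub$resno))
    if (length(pos) < 1) next
    res3 <- vapply(pos, function(p) sub$resid[match(p, sub$resno)], "")
    seq1 <- paste(ifelse(is.na(AA3to1[res3]), "X", AA3to1[res3]), collapse = "")
    atoms <- data.frame(seq_pos = as.integer(sub$resno), atom = sub$atom,
                        x = sub$x, y = sub$y, z = sub$z,
                        stringsAsFactors = FALSE)
    chains[[cid]] <- new_chain(cid, seq1, atoms)
  }
  chains
}

#' Read a structure file into a StructureModel
#'
#' Loads all polymer chains with at least one resolved residue; waters and
#' other non-polymer groups are excluded, as are hydrogens. Method, unit cell
#' and space group are populated when present in the file.
#'
#' @param path file path.
#' @param format "mmCIF", "PDB" or "auto" (by extension; `.cif`/`.mmcif`
#'   versus anything else).
#' @param model model number to read from multi-model files (default 1).
#' @return a `qc_structure`.
#' @export
read_structure <- function(path, format = c("auto", "mmCIF", "PDB"), model = 1L) {
  format <- match.arg(format)
  if (!file.exists(path)) qc_stop("qc_io_error", "file not found: %s", path)
  if (format == "auto")
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)) "mmCIF" else "PDB"
  if (format == "mmCIF") read_structure_mmcif(path, model) else read_structure_pdb(path, model)
}

read_structure_mmcif <- function(path, model = 1L) {
  raw <- tryCatch(read_mmcif_raw(path),
                  error = function(e) qc_stop("qc_format_error", "cannot parse mmCIF %s: %s",
                                              path, conditionMessage(e)))
  a <- raw$atom
  if (is.null(a) || nrow(a) == 0)
    qc_stop("qc_empty_structure", "no atom_site records in %s", path)
  getcol <- function(nm, alt = NULL, default = NA) {
    if (nm %in% names(a)) a[[nm]] else if (!is.null(alt) && alt %in% names(a)) a[[alt]]
    else rep(default, nrow(a))
  }
  grp <- getcol("group_PDB", default = "ATOM")
  mdl <- suppressWarnings(as.integer(getcol("pdbx_PDB_model_num", default = "1")))
  mdl[is.na(mdl)] <- 1L
  keep <- grp == "ATOM" & mdl == model
  alt <- getcol("label_alt_id", default = ".")
  alt[alt %in% c(".", "?")] <- ""
  at <- data.frame(
    chain = getcol("auth_asym_id", "label_asym_id"),
    resno = suppressWarnings(as.integer(getcol("auth_seq_id", "label_seq_id"))),
    resid = getcol("label_comp_id", "auth_comp_id"),
    atom  = getcol("label_atom_id", "auth_atom_id"),
    elem  = toupper(getcol("type_symbol", default = "")),
    x = as.numeric(getcol("Cartn_x")), y = as.numeric(getcol("Cartn_y")),
    z = as.numeric(getcol("Cartn_z")),
    occ = suppressWarnings(as.numeric(getcol("occupancy", default = "1"))),
    alt = alt, stringsAsFactors = FALSE)[keep, , drop = FALSE]
  at$occ[is.na(at$occ)] <- 1
  at <- at[!is.na(at$resno) & at$resid != "HOH", , drop = FALSE]
  chains <- chains_from_atom_table(at)
  it <- raw$items
  cell <- suppressWarnings(as.numeric(c(
    it[["_cell.length_a"]], it[["_cell.length_b"]], it[["_cell.length_c"]],
    it[["_cell.angle_alpha"]], it[["_cell.angle_beta"]], it[["_cell.angle_gamma"]])))
  if (length(cell) != 6 || anyNA(cell)) cell <- NULL
  sg <- it[["_symmetry.space_group_name_H-M"]] %||%
    it[["_space_group.name_H-M_alt"]] %||% NA_character_
  method <- method_from_string(it[["_exptl.method"]] %||% NA_character_)
  entry <- it[["_entry.id"]] %||% sub("\\.[^.]*$", "", basename(path))
  if (length(chains) == 0)
    qc_stop("qc_empty_structure", "no polymer chains in %s", path)
  new_structure_model(entry, chains, method = method,
                      space_group = if (method == "XRAY") sg else NA_character_,
                      cell = if (method == "XRAY") cell else NULL)
}

read_structure_pdb <- function(path, model = 1L) {
  pdb <- tryCatch(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE),
                  error = function(e) qc_stop("qc_format_error", "cannot parse PDB %s: %s",
                                              path, conditionMessage(e)))
  a <- pdb$atom
  a <- a[a$type == "ATOM" & a$resid != "HOH", , drop = FALSE]
  if (nrow(a) == 0) qc_stop("qc_empty_structure", "no polymer atoms in %s", path)
  elem <- a$elesy
  if (is.null(elem) || all(is.na(elem)))
    elem <- toupper(substr(gsub("[0-9]", "", a$elety), 1, 1))
  at <- data.frame(chain = a$chain, resno = a$resno, resid = a$resid,
                   atom = a$elety, elem = toupper(trimws(elem)),
                   x = a$x, y = a$y, z = a$z,
                   occ = ifelse(is.na(a$o), 1, a$o),
                   alt = ifelse(is.na(a$alt) | a$alt %in% c("", "."), "", a$alt),
                   stringsAsFactors = FALSE)
  chains <- chains_from_atom_table(at)
  if (length(chains) == 0) qc_stop("qc_empty_structure", "no polymer chains in %s", path)
  # header records bio3d does not surface
  lines <- readLines(path, warn = FALSE)
  cr <- grep("^CRYST1", lines, value = TRUE)
  cell <- NULL; sg <- NA_character_
  if (length(cr)) {
    cr <- cr[1]
    cell <- as.numeric(c(substr(cr, 7, 15), substr(cr, 16, 24), substr(cr, 25, 33),
                         substr(cr, 34, 40), substr(cr, 41, 47), substr(cr, 48, 54)))
    sg <- trimws(substr(cr, 56, 66))
  }
  ex <- grep("^EXPDTA", lines, value = TRUE)
  method <- method_from_string(if (length(ex)) substr(ex[1], 11, 79) else NA)
  if (method == "OTHER" && !is.null(cell)) method <- "XRAY"
  entry <- sub("\\.[^.]*$", "", basename(path))
  new_structure_model(entry, chains, method = method,
                      space_group = if (method == "XRAY") sg else NA_character_,
                      cell = if (method == "XRAY") cell else NULL)
}

# Flatten an assembly (or bare chain list) into one atom table for writing.
assembly_atom_table <- function(chains) {
  do.call(rbind, lapply(chains, function(ch) {
    a <- ch$atoms
    pos <- ch$rep$seq_pos
    aa <- strsplit(ch$sequence, "")[[1]]
    res3 <- AA1to3[aa]; res3[is.na(res3)] <- "UNK"
    data.frame(chain = ch$chain_id, resno = a$seq_pos,
               resid = res3[match(a$seq_pos, pos)],
               atom = a$atom, x = a$x, y = a$y, z = a$z,
               stringsAsFactors = FALSE)
  }))
}

atom_elem <- function(atom_name) {
  e <- toupper(substr(gsub("[0-9]", "", atom_name), 1, 1))
  ifelse(e %in% c("C", "N", "O", "S", "P"), e, "C")
}

#' Write an assembly's coordinates to mmCIF or PDB
#'
#' The written file is re-readable by [read_structure()]; chain count,
#' residue counts and coordinates (to 0.001 Angstrom) are preserved. PDB
#' format is refused for assemblies with more than 62 chains (the one-letter
#' chain id space); use mmCIF for those.
#'
#' @param assembly a `qc_assembly` (or a `qc_structure`, written as-is).
#' @param path output path.
#' @param format "mmCIF" or "PDB".
#' @param method,space_group,cell header fields; default taken from the
#'   assembly's provenance when available.
#' @return `path`, invisibly.
#' @export
write_assembly <- function(assembly, path, format = c("mmCIF", "PDB"),
                           method = NULL, space_group = NULL, cell = NULL) {
  format <- match.arg(format)
  chains <- assembly$chains
  if (length(chains) == 0) qc_stop("qc_io_error", "assembly has no chains")
  method <- method %||% assembly$method %||% "OTHER"
  space_group <- space_group %||% assembly$space_group %||% NA_character_
  cell <- cell %||% assembly$cell
  entry <- assembly$entry_id %||% assembly$assembly_id %||% "XXXX"
  at <- assembly_atom_table(chains)
  if (format == "PDB") {
    if (length(chains) > 62)
      qc_stop("qc_io_error",
              ">62 chains cannot be written in PDB format; use mmCIF")
    write_pdb_file(at, path, entry, method, space_group, cell, names(chains))
  } else {
    write_mmcif_file(at, path, entry, method, space_group, cell)
  }
  invisible(path)
}

write_mmcif_file <- function(at, path, entry, method, space_group, cell) {
  con <- file(path, "w"); on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("data_%s", entry)
  w("_entry.id %s", entry)
  w("_exptl.method '%s'", method_to_string(method))
  if (!is.null(space_group) && !is.na(space_group))
    w("_symmetry.space_group_name_H-M '%s'", space_group)
  if (!is.null(cell) && length(cell) == 6) {
    nms <- c("length_a", "length_b", "length_c", "angle_alpha", "angle_beta", "angle_gamma")
    for (k in 1:6) w("_cell.%s %.3f", nms[k], cell[k])
  }
  w("loop_")
  for (f in c("group_PDB", "id", "type_symbol", "label_atom_id", "label_alt_id",
              "label_comp_id", "label_asym_id", "label_seq_id", "auth_asym_id",
              "auth_seq_id", "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
              "B_iso_or_equiv", "pdbx_PDB_model_num"))
    w("_atom_site.%s", f)
  for (i in seq_len(nrow(at)))
    w("ATOM %d %s %s . %s %s %d %s %d %.3f %.3f %.3f 1.00 0.00 1",
      i, atom_elem(at$atom[i]), at$atom[i], at$resid[i],
      gsub("[^A-Za-z0-9]", "", at$chain[i]), at$resno[i],
      at$chain[i], at$resno[i], at$x[i], at$y[i], at$z[i])
  w("#")
}

write_pdb_file <- function(at, path, entry, method, space_group, cell, chain_ids) {
  # PDB chain ids are single characters; map assembly chain ids onto A-Z a-z 0-9
  alphabet <- c(LETTERS, letters, 0:9)
  cmap <- stats::setNames(alphabet[seq_along(chain_ids)], chain_ids)
  lines <- character(0)
  lines <- c(lines, sprintf("EXPDTA    %s", method_to_string(method)))
  if (!is.null(cell) && length(cell) == 6)
    lines <- c(lines, sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s",
                              cell[1], cell[2], cell[3], cell[4], cell[5], cell[6],
                              ifelse(is.na(space_group), "P 1", space_group)))
  for (i in seq_len(nrow(at))) {
    an <- at$atom[i]
    an_fmt <- if (nchar(an) < 4) sprintf(" %-3s", an) else sprintf("%-4s", an)
    lines <- c(lines, sprintf("ATOM  %5d %s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                              i %% 100000, an_fmt, at$resid[i], cmap[at$chain[i]],
                              at$resno[i], at$x[i], at$y[i], at$z[i], 1, 0,
                              atom_elem(an)))
  }
  writeLines(c(lines, "END"), path)
}

#' Write a PyMOL alignment script for an assembly cluster
#'
#' Emits a `.pml` script that loads each member's coordinate file and
#' superposes every non-representative member onto the cluster
#' representative. File names default to the ones [write_cluster_bundle()]
#' produces.
#'
#' @param cluster a `qc_assembly_cluster`.
#' @param path output `.pml` path.
#' @param files named character vector assembly_id -> coordinate file; default
#'   `<cluster_id>_<assembly_id>.cif` next to `path`.
#' @return `path`, invisibly.
#' @export
write_alignment_script <- function(cluster, path, files = NULL) {
  ids <- vapply(cluster$members, function(m) m$assembly$assembly_id, "")
  if (length(ids) == 0) qc_stop("qc_io_error", "empty cluster")
  if (is.null(files))
    files <- stats::setNames(sprintf("%s_%s.cif", cluster$cluster_id, ids), ids)
  if (is.null(names(files))) names(files) <- ids
  rep_id <- cluster$representative
  obj <- function(id) gsub("[^A-Za-z0-9_]", "_", id)
  lines <- sprintf("load %s, %s", files[ids], obj(ids))
  others <- setdiff(ids, rep_id)
  lines <- c(lines, sprintf("align %s, %s", obj(others), obj(rep_id)))
  writeLines(c("# cluster alignment script", lines, "zoom"), path)
  invisible(path)
}

#' Write coordinate files for every member of a cluster
#'
#' @param cluster a `qc_assembly_cluster`.
#' @param dir output directory (created if needed).
#' @param format passed to [write_assembly()].
#' @return named character vector assembly_id -> file path (the manifest).
#' @export
write_cluster_bundle <- function(cluster, dir, format = "mmCIF") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (format == "mmCIF") "cif" else "pdb"
  out <- character(0)
  for (m in cluster$members) {
    id <- m$assembly$assembly_id
    f <- file.path(dir, sprintf("%s_%s.%s", cluster$cluster_id, id, ext))
    write_assembly(m$assembly, f, format = format)
    out[id] <- f
  }
  out
}
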