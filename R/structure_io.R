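# Structure input/output: PDB reading (via bio3d, plus hand parsing of
# SSBOND records, which bio3d does not expose), fixed-width PDB writing
# with HELIX/SHEET/SSBOND headers, residue-numbering maps, and C-alpha
# extraction.

#' Read a protein structure from a PDB file
#'
#' Parses ATOM records into a `structure` object holding all heavy atoms
#' of the selected chain(s), along with secondary-structure spans from
#' HELIX/SHEET records and disulfide pairs from SSBOND records. Hydrogens,
#' waters and all other HETATM records are dropped. Where alternate
#' locations exist for an atom, the highest-occupancy altloc is kept (ties
#' broken by file order).
#'
#' @param path path to a PDB file containing at least one ATOM record.
#' @param chain optional chain identifier (single letter); `NULL` keeps
#'   every chain.
#' @param sse_override optional path to a 4-column whitespace/tab-delimited
#'   table (`chain start end kind`, 1-based inclusive residue numbers,
#'   kind `helix` or `sheet`) replacing the HELIX/SHEET records.
#' @return an object of class `structure`: a list with
#'   \describe{
#'     \item{atoms}{data frame with columns `atom` (PDB atom name),
#'       `element`, `resname`, `chain`, `resno`, `ins` (insertion code,
#'       `""` if none), `x`, `y`, `z` (angstrom), `altloc`, `occupancy`.}
#'     \item{sse}{data frame `kind` (`"helix"`/`"sheet"`), `chain`,
#'       `start`, `end` (residue numbers, inclusive).}
#'     \item{disulfides}{data frame `chain1`, `res1`, `chain2`, `res2`,
#'       one row per SS bond.}
#'     \item{source}{free-text identifier (the file path).}
#'   }
#' @export
read_pdb <- function(path, chain = NULL, sse_override = NULL) {
  if (!file.exists(path)) {
    stop("PDB file not found: ", path)
  }
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, verbose = FALSE,
                                     rm.alt = FALSE)),
    error = function(e) stop("failed to parse PDB file ", path, ": ",
                             conditionMessage(e))
  )
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) {
    stop("no ATOM records in PDB file: ", path)
  }
  if (!is.null(chain)) {
    if (!chain %in% at$chain) {
      stop("chain '", chain, "' not found in ", path,
           " (chains present: ", paste(unique(at$chain), collapse = ", "), ")")
    }
    at <- at[at$chain == chain, , drop = FALSE]
  }
  # drop hydrogens (element H or D); element from column when present,
  # else from the atom name
  elem <- at$elesy
  elem[is.na(elem) | elem == ""] <- guess_element(at$elety[is.na(elem) | elem == ""])
  keep <- !(toupper(trimws(elem)) %in% c("H", "D"))
  at <- at[keep, , drop = FALSE]
  elem <- trimws(elem[keep])

  atoms <- data.frame(
    atom = trimws(at$elety),
    element = toupper(elem),
    resname = trimws(at$resid),
    chain = at$chain,
    resno = at$resno,
    ins = ifelse(is.na(at$insert) | at$insert == "", "", at$insert),
    x = at$x, y = at$y, z = at$z,
    altloc = ifelse(is.na(at$alt) | at$alt == "", "", at$alt),
    occupancy = ifelse(is.na(at$o), 1, at$o),
    stringsAsFactors = FALSE
  )
  atoms <- resolve_altloc(atoms)

  sse <- if (is.null(sse_override)) {
    sse_from_bio3d(pdb, chains = unique(atoms$chain))
  } else {
    read_sse_table(sse_override)
  }
  # keep only spans whose chain is present
  sse <- sse[sse$chain %in% unique(atoms$chain), , drop = FALSE]

  dis <- parse_ssbond(path)
  dis <- dis[dis$chain1 %in% unique(atoms$chain) &
               dis$chain2 %in% unique(atoms$chain), , drop = FALSE]

  new_structure(atoms, sse, dis, source = path)
}

new_structure <- function(atoms, sse, disulfides, source = "") {
  stopifnot(all(is.finite(atoms$x)), all(is.finite(atoms$y)),
            all(is.finite(atoms$z)))
  if (nrow(disulfides)) {
    same <- disulfides$chain1 == disulfides$chain2 &
      disulfides$res1 == disulfides$res2
    if (any(same)) stop("disulfide pair references the same residue")
  }
  structure(
    list(atoms = atoms, sse = sse, disulfides = disulfides, source = source),
    class = "structure"
  )
}

#' @export
print.structure <- function(x, ...) {
  nres <- nrow(unique(x$atoms[, c("chain", "resno", "ins")]))
  cat("<structure> ", x$source, "\n",
      "  ", nrow(x$atoms), " heavy atoms, ", nres, " residues, chains: ",
      paste(unique(x$atoms$chain), collapse = " "), "\n",
      "  ", nrow(x$sse), " SSE spans, ", nrow(x$disulfides),
      " disulfide pairs\n", sep = "")
  invisible(x)
}

# Keep, per (chain, resno, ins, atom name), the highest-occupancy altloc;
# ties broken by original file order.
resolve_altloc <- function(atoms) {
  key <- paste(atoms$chain, atoms$resno, atoms$ins, atoms$atom, sep = "\r")
  ord <- order(key, -atoms$occupancy, seq_len(nrow(atoms)))
  first <- !duplicated(key[ord])
  keep <- sort(ord[first])
  atoms[keep, , drop = FALSE]
}

guess_element <- function(atom_names) {
  nm <- trimws(atom_names)
  el <- substr(gsub("[0-9']", "", nm), 1L, 1L)
  el[nm %in% c("FE", "ZN", "MG", "MN", "CA")] <- nm[nm %in% c("FE", "ZN", "MG", "MN", "CA")]
  el
}

sse_from_bio3d <- function(pdb, chains) {
  out <- data.frame(kind = character(), chain = character(),
                    start = integer(), end = integer(),
                    stringsAsFactors = FALSE)
  for (what in c("helix", "sheet")) {
    h <- pdb[[what]]
    if (!is.null(h) && length(h$start)) {
      out <- rbind(out, data.frame(
        kind = what,
        chain = as.character(h$chain),
        start = as.integer(h$start),
        end = as.integer(h$end),
        stringsAsFactors = FALSE
      ))
    }
  }
  rownames(out) <- NULL
  out
}

read_sse_table <- function(path) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("chain", "start", "end", "kind"))
  bad <- !tab$kind %in% c("helix", "sheet")
  if (any(bad)) {
    stop("SSE override kinds must be 'helix' or 'sheet'; got: ",
         paste(unique(tab$kind[bad]), collapse = ", "))
  }
  data.frame(kind = tab$kind, chain = as.character(tab$chain),
             start = as.integer(tab$start), end = as.integer(tab$end),
             stringsAsFactors = FALSE)
}

# SSBOND records, PDB fixed columns: chains at 16 and 30, resno at 18-21
# and 32-35.
parse_ssbond <- function(path) {
  lines <- readLines(path, warn = FALSE)
  ss <- lines[startsWith(lines, "SSBOND")]
  if (!length(ss)) {
    return(data.frame(chain1 = character(), res1 = integer(),
                      chain2 = character(), res2 = integer(),
                      stringsAsFactors = FALSE))
  }
  data.frame(
    chain1 = trimws(substr(ss, 16, 16)),
    res1 = as.integer(substr(ss, 18, 21)),
    chain2 = trimws(substr(ss, 30, 30)),
    res2 = as.integer(substr(ss, 32, 35)),
    stringsAsFactors = FALSE
  )
}

#' Write a structure (or bare coordinates) to a PDB file
#'
#' Emits HELIX, SHEET and SSBOND header records followed by fixed-width
#' ATOM records, so that written files round-trip through [read_pdb()]
#' with coordinates preserved to PDB precision (1e-3 angstrom).
#'
#' @param x a `structure` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(x, path) {
  stopifnot(inherits(x, "structure"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(format_header_records(x), con)
  writeLines(format_atom_records(x$atoms), con)
  writeLines("END", con)
  invisible(path)
}

format_header_records <- function(x) {
  out <- character()
  hel <- x$sse[x$sse$kind == "helix", , drop = FALSE]
  if (nrow(hel)) {
    out <- c(out, sprintf(
      "HELIX  %3d %3s %3s %s %4d  %3s %s %4d  1%36s",
      seq_len(nrow(hel)), sprintf("H%02d", seq_len(nrow(hel))),
      "ALA", hel$chain, hel$start, "ALA", hel$chain, hel$end, ""))
  }
  sh <- x$sse[x$sse$kind == "sheet", , drop = FALSE]
  if (nrow(sh)) {
    out <- c(out, sprintf(
      "SHEET  %3d %3s%2d %3s %s%4d  %3s %s%4d  0",
      seq_len(nrow(sh)), sprintf("S%02d", seq_len(nrow(sh))), 1L,
      "ALA", sh$chain, sh$start, "ALA", sh$chain, sh$end))
  }
  di <- x$disulfides
  if (nrow(di)) {
    out <- c(out, sprintf(
      "SSBOND %3d CYS %s %4d    CYS %s %4d %40s",
      seq_len(nrow(di)), di$chain1, di$res1, di$chain2, di$res2, ""))
  }
  out
}

format_atom_records <- function(atoms) {
  # PDB atom-name column convention: names of 1-3 characters whose element
  # symbol is one character start in column 14
  nm <- atoms$atom
  nm4 <- ifelse(nchar(nm) >= 4L, substr(nm, 1L, 4L), sprintf(" %-3s", nm))
  sprintf(
    "ATOM  %5d %4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(atoms)) %% 100000L, nm4,
    ifelse(atoms$altloc == "", " ", atoms$altloc),
    atoms$resname, atoms$chain, atoms$resno,
    ifelse(atoms$ins == "", " ", atoms$ins),
    atoms$x, atoms$y, atoms$z, atoms$occupancy, 0,
    atoms$element)
}

#' Write a C-alpha trajectory as a multi-model PDB file
#'
#' @param traj a `trajectory` object (see [mode_trajectory()]).
#' @param labels optional data frame of bead labels (`resno`, `resname`,
#'   `chain`) as carried by a `calpha_model`; defaults to sequential ALA.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_pdb <- function(traj, path, labels = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  n <- dim(traj$coords)[2]
  if (is.null(labels)) {
    labels <- data.frame(resno = seq_len(n), resname = "ALA", chain = "A",
                         stringsAsFactors = FALSE)
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(dim(traj$coords)[1])) {
    writeLines(sprintf("MODEL     %4d", f), con)
    atoms <- data.frame(
      atom = "CA", element = "C", resname = labels$resname,
      chain = labels$chain, resno = labels$resno, ins = "",
      x = traj$coords[f, , 1], y = traj$coords[f, , 2],
      z = traj$coords[f, , 3],
      altloc = "", occupancy = 1, stringsAsFactors = FALSE)
    writeLines(format_atom_records(atoms), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a multi-model PDB file as a C-alpha trajectory
#'
#' Keeps one CA atom per residue per model; all models must share the
#' same bead count.
#'
#' @param path multi-model PDB file.
#' @param chain optional chain filter.
#' @return a `trajectory` object (unaligned, reference frame 1).
#' @export
read_trajectory_pdb <- function(path, chain = NULL) {
  if (!file.exists(path)) stop("trajectory file not found: ", path)
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE))
  sel <- bio3d::atom.select(pdb, elety = "CA", verbose = FALSE)
  if (!is.null(chain)) {
    sel <- bio3d::atom.select(pdb, elety = "CA", chain = chain,
                              verbose = FALSE)
  }
  xyz <- pdb$xyz[, sel$xyz, drop = FALSE]
  if (nrow(xyz) < 1L) stop("no models in ", path)
  n <- ncol(xyz) / 3L
  coords <- array(NA_real_, dim = c(nrow(xyz), n, 3L))
  for (f in seq_len(nrow(xyz))) coords[f, , ] <- xyz_mat(xyz[f, ])
  new_trajectory(coords, phase = rep(NA_real_, nrow(xyz)),
                 reference = 1L, aligned = FALSE)
}

#' Residue-numbering map between PDB and mature-protein numbering
#'
#' Crystallographic numbering often differs from the numbering of the
#' mature secreted protein by a constant offset (plus occasional
#' insertion-code exceptions). The map adds `offset` to each PDB residue
#' number; `overrides` handles insertion-coded residues explicitly.
#'
#' @param chain chain the map applies to.
#' @param offset integer added to PDB residue numbers to obtain mature
#'   numbering (default 0: PDB numbering taken as already mature).
#' @param overrides optional named integer vector mapping
#'   `"resno|ins"` keys (e.g. `"27|A"`) to explicit mature numbers.
#' @return an object of class `numbering_map`.
#' @export
numbering_map <- function(chain = NULL, offset = 0L, overrides = NULL) {
  stopifnot(length(offset) == 1L, offset == as.integer(offset))
  structure(list(chain = chain, offset = as.integer(offset),
                 overrides = overrides),
            class = "numbering_map")
}

apply_numbering <- function(map, resno, ins) {
  out <- resno + map$offset
  if (!is.null(map$overrides)) {
    key <- paste(resno, ins, sep = "|")
    hit <- key %in% names(map$overrides)
    out[hit] <- as.integer(map$overrides[key[hit]])
  }
  if (anyDuplicated(out)) stop("numbering map is not injective over the chain")
  out
}

#' Extract the one-bead-per-residue C-alpha model from a structure
#'
#' Beads are ordered by chain, then residue number, then insertion code.
#' Each bead carries a mature-protein residue label obtained through the
#' numbering map; disulfide pairs are re-expressed as bead indices; SSE
#' membership is flagged per bead.
#'
#' @param struct a `structure` from [read_pdb()].
#' @param numbering a [numbering_map()] (default: identity).
#' @return an object of class `calpha_model`: list with `xyz` (N x 3
#'   matrix), `labels` (data frame `resno` mature numbering, `resname`,
#'   `chain`, `pdb_resno`, `ins`), `in_sse` / `sse_kind` per bead,
#'   `disulfide_beads` (2-column matrix of bead indices), `k` (pairwise
#'   force constants; `NULL` until [build_force_constants()] is run) and
#'   `params` (force-field record).
#' @export
extract_calpha <- function(struct, numbering = numbering_map()) {
  stopifnot(inherits(struct, "structure"))
  at <- struct$atoms
  res_key <- paste(at$chain, at$resno, at$ins, sep = "\r")
  ca <- at[at$atom == "CA" & at$element == "C", , drop = FALSE]
  all_res <- unique(res_key)
  ca_key <- paste(ca$chain, ca$resno, ca$ins, sep = "\r")
  missing <- setdiff(all_res, ca_key)
  if (length(missing)) {
    pretty <- gsub("\r", ":", missing)
    stop("residues missing a C-alpha atom: ", paste(pretty, collapse = ", "))
  }
  if (anyDuplicated(ca_key)) {
    dup <- gsub("\r", ":", unique(ca_key[duplicated(ca_key)]))
    stop("duplicate C-alpha after altloc resolution for: ",
         paste(dup, collapse = ", "))
  }
  ord <- order(ca$chain, ca$resno, ca$ins)
  ca <- ca[ord, , drop = FALSE]

  mature <- apply_numbering(numbering, ca$resno, ca$ins)
  labels <- data.frame(resno = mature, resname = ca$resname,
                       chain = ca$chain, pdb_resno = ca$resno, ins = ca$ins,
                       stringsAsFactors = FALSE)

  in_sse <- rep(FALSE, nrow(ca))
  sse_kind <- rep(NA_character_, nrow(ca))
  if (nrow(struct$sse)) {
    for (i in seq_len(nrow(struct$sse))) {
      s <- struct$sse[i, ]
      hit <- ca$chain == s$chain & ca$resno >= s$start & ca$resno <= s$end
      in_sse[hit] <- TRUE
      sse_kind[hit] <- s$kind
    }
  }

  db <- matrix(integer(), ncol = 2L)
  if (nrow(struct$disulfides)) {
    key <- paste(ca$chain, ca$resno, sep = "\r")
    i1 <- match(paste(struct$disulfides$chain1, struct$disulfides$res1, sep = "\r"), key)
    i2 <- match(paste(struct$disulfides$chain2, struct$disulfides$res2, sep = "\r"), key)
    ok <- !is.na(i1) & !is.na(i2)
    db <- cbind(i1[ok], i2[ok])
  }

  # mature-numbering SSE spans travel with the model for later exclusion
  sse_spans <- struct$sse
  if (nrow(sse_spans)) {
    sse_spans$start <- sse_spans$start + numbering$offset
    sse_spans$end <- sse_spans$end + numbering$offset
  }

  structure(
    list(xyz = unname(as.matrix(ca[, c("x", "y", "z")])), labels = labels,
         in_sse = in_sse, sse_kind = sse_kind, disulfide_beads = db,
         sse_spans = sse_spans, k = NULL, params = NULL,
         source = struct$source),
    class = "calpha_model"
  )
}

#' @export
print.calpha_model <- function(x, ...) {
  cat("<calpha_model> ", nrow(x$xyz), " beads",
      if (!is.null(x$k)) ", force constants built" else "",
      "\n", sep = "")
  invisible(x)
}

#' Locate a locally available PDB file by accession
#'
#' Looks for `<id>.pdb` (case-insensitive id) in the package's `extdata`
#' directory, the current working directory, and `~/structures`. The
#' package ships no crystallographic coordinates, so validation runs
#' against a real entry require the user to place the file in one of
#' these locations.
#'
#' @param id PDB accession, e.g. `"1UEA"`.
#' @return the path if found, otherwise `NA_character_`.
#' @export
locate_structure <- function(id) {
  cands <- c(
    system.file("extdata", paste0(id, ".pdb"), package = "hingescan"),
    system.file("extdata", paste0(tolower(id), ".pdb"), package = "hingescan"),
    file.path(getwd(), paste0(id, ".pdb")),
    file.path(getwd(), paste0(tolower(id), ".pdb")),
    file.path(path.expand("~"), "structures", paste0(id, ".pdb"))
  )
  cands <- cands[nzchar(cands)]
  hit <- cands[file.exists(cands)]
  if (length(hit)) hit[[1]] else NA_character_
}
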