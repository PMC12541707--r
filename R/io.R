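# Snapshot I/O: multi-model PDB / XYZ coordinate files plus a JSON
# manifest carrying molecule identity (kind, sequence or drug name) and
# provenance. The coordinate formats keep only positions; atom typing is
# reconstructed from the manifest through the package's own molecule
# templates, so a round-trip restores the full typed snapshot to format
# precision (PDB: 1e-3 A).

aa3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
         E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
         M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
         Y = "TYR", V = "VAL")

.chain_ids <- c(LETTERS, letters, 0:9)

.resname_of <- function(kind, label, rescode) {
  if (kind == "peptide") return(aa3[[rescode]])
  if (kind == "zn") return("ZN")
  if (kind == "no3") return("NO3")
  toupper(substr(gsub("[^A-Za-z0-9]", "", label), 1, 3))
}

# manifest entry list for one snapshot
.build_manifest <- function(snap, seed = NULL, generator = NULL,
                            config_hash = NULL) {
  mols <- lapply(seq_len(nrow(snap$molecules)), function(i) {
    m <- snap$molecules[i, ]
    entry <- list(molecule_id = m$mol_id, kind = m$kind, label = m$label,
                  n_atoms = sum(snap$atoms$mol_id == m$mol_id))
    if (m$kind == "peptide") {
      a <- snap$atoms[snap$atoms$mol_id == m$mol_id, ]
      entry$sequence <- paste(a$rescode[match(1:4, a$resid)], collapse = "")
      entry$c_terminus <- if (any(a$name == "OXT")) "carboxylate" else "amidated"
    }
    entry
  })
  list(version = "1.0", seed = seed, generator = generator,
       config_hash = config_hash, molecules = mols)
}

#' Write a trajectory as multi-model PDB or XYZ plus manifest
#'
#' All frames must share the molecule table of the first frame. PDB
#' output uses MODEL/ENDMDL records, HETATM for drugs and ions, a chain
#' identifier per molecule (cycling), and the molecule id in the segid
#' column; XYZ output is the plain element-x-y-z multi-frame format.
#'
#' @param trajectory A [snapshot()] or nonempty list of snapshots.
#' @param path Output coordinate file; format chosen by extension
#'   (`.pdb` or `.xyz`).
#' @param manifest_path Output JSON manifest; defaults to `path` with a
#'   `.manifest.json` extension.
#' @param seed,generator,config_hash Optional provenance recorded in the
#'   manifest.
#' @return Invisibly, the manifest path.
#' @export
write_snapshot <- function(trajectory, path, manifest_path = NULL,
                           seed = NULL, generator = NULL, config_hash = NULL) {
  if (inherits(trajectory, "snapshot")) trajectory <- list(trajectory)
  if (length(trajectory) == 0) stop("nothing to write: empty trajectory")
  if (is.null(manifest_path))
    manifest_path <- sub("\\.(pdb|xyz)$", ".manifest.json", path)
  ref <- trajectory[[1]]
  fmt <- tolower(tools::file_ext(path))
  if (!fmt %in% c("pdb", "xyz")) stop("unsupported format: .", fmt)
  lines <- character(0)
  for (f in seq_along(trajectory)) {
    snap <- trajectory[[f]]
    if (!identical(snap$molecules, ref$molecules))
      stop("frame ", f, " has a different molecule table")
    a <- snap$atoms
    kind_of <- stats::setNames(ref$molecules$kind, ref$molecules$mol_id)
    label_of <- stats::setNames(ref$molecules$label, ref$molecules$mol_id)
    if (fmt == "pdb") {
      lines <- c(lines, sprintf("MODEL     %4d", f))
      mol_index <- match(a$mol_id, ref$molecules$mol_id)
      chain <- .chain_ids[(mol_index - 1L) %% length(.chain_ids) + 1L]
      rec <- ifelse(kind_of[as.character(a$mol_id)] == "peptide", "ATOM  ", "HETATM")
      resname <- vapply(seq_len(nrow(a)), function(i)
        .resname_of(kind_of[[as.character(a$mol_id[i])]],
                    label_of[[as.character(a$mol_id[i])]],
                    a$rescode[i]), character(1))
      resseq <- ifelse(is.na(a$resid), 1L, a$resid)
      name4 <- ifelse(nchar(a$name) < 4, paste0(" ", a$name), a$name)
      lines <- c(lines, sprintf(
        "%s%5d %-4s %-3s%2s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f      %-4s%2s",
        rec, a$atom_id %% 100000L, substr(name4, 1, 4), resname, chain, resseq,
        a$x, a$y, a$z, 1, 0, paste0("M", a$mol_id),
        substr(a$element, 1, 2)))
      lines <- c(lines, "ENDMDL")
    } else {
      lines <- c(lines, as.character(nrow(a)), paste0("frame ", f))
      lines <- c(lines, sprintf("%-2s %12.6f %12.6f %12.6f", a$element, a$x, a$y, a$z))
    }
  }
  if (fmt == "pdb") lines <- c(lines, "END")
  writeLines(lines, path)
  jsonlite::write_json(.build_manifest(ref, seed, generator, config_hash),
                       manifest_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(manifest_path)
}

# typed template atoms for one manifest molecule entry
.template_atoms <- function(entry) {
  switch(entry$kind,
    peptide = peptide_atoms(peptide(entry$sequence,
                                    termini_spec(entry$c_terminus))),
    drug = drug_atoms(drug_spec(entry$label)),
    zn = zn_atoms(),
    no3 = no3_atoms(),
    stop("unknown kind in manifest: ", entry$kind))
}

#' Read a trajectory written by [write_snapshot()]
#'
#' Reconstructs fully typed snapshots: coordinates come from the PDB
#' (via [bio3d::read.pdb()]) or XYZ file, molecule identity and typing
#' from the manifest and the package's molecule templates.
#'
#' @param path Multi-model PDB or XYZ file.
#' @param manifest_path JSON manifest; defaults to `path` with a
#'   `.manifest.json` extension.
#' @return List of [snapshot()]s, one per model/frame, in file order.
#' @export
read_snapshot <- function(path, manifest_path = NULL) {
  if (is.null(manifest_path))
    manifest_path <- sub("\\.(pdb|xyz)$", ".manifest.json", path)
  if (!file.exists(path)) stop("no such file: ", path)
  if (!file.exists(manifest_path)) stop("no such manifest: ", manifest_path)
  man <- jsonlite::read_json(manifest_path)
  entries <- man$molecules
  fmt <- tolower(tools::file_ext(path))
  frames_xyz <- if (fmt == "pdb") .read_pdb_frames(path) else .read_xyz_frames(path)
  n_man <- sum(vapply(entries, `[[`, integer(1), "n_atoms"))
  lapply(seq_along(frames_xyz), function(f) {
    xyz <- frames_xyz[[f]]
    if (nrow(xyz$coords) != n_man)
      stop("manifest/coordinate mismatch in frame ", f, ": manifest has ",
           n_man, " atoms, file has ", nrow(xyz$coords))
    snap <- empty_snapshot()
    at <- 0L
    for (entry in entries) {
      tmpl <- .template_atoms(entry)
      n <- entry$n_atoms
      if (nrow(tmpl) != n)
        stop("manifest/coordinate mismatch for molecule id ",
             entry$molecule_id, ": template has ", nrow(tmpl),
             " atoms, manifest says ", n)
      if (!is.null(xyz$mol_tag)) {
        tags <- unique(xyz$mol_tag[(at + 1L):(at + n)])
        if (!identical(tags, paste0("M", entry$molecule_id)))
          stop("manifest/coordinate mismatch: expected molecule id ",
               entry$molecule_id, ", file has segment ",
               paste(tags, collapse = ","))
      }
      tmpl[, c("x", "y", "z")] <- xyz$coords[(at + 1L):(at + n), , drop = FALSE]
      snap <- add_molecule(snap, entry$kind, entry$label, tmpl)
      at <- at + n
    }
    validate_snapshot(snap)
    snap
  })
}

.read_pdb_frames <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  lapply(seq_len(nrow(xyz)), function(f)
    list(coords = matrix(xyz[f, ], ncol = 3, byrow = TRUE),
         mol_tag = trimws(pdb$atom$segid)))
}

.read_xyz_frames <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stop("malformed XYZ atom count at line ", i)
    if (i + 1L + n > length(lines)) stop("truncated XYZ frame at line ", i)
    body <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(trimws(body), "[[:space:]]+")
    bad <- which(vapply(parts, length, integer(1)) < 4)
    if (length(bad)) stop("malformed XYZ record at line ", i + 1L + bad[1])
    coords <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    frames[[length(frames) + 1]] <- list(coords = coords, mol_tag = NULL)
    i <- i + 2L + n
  }
  if (length(frames) == 0) stop("no frames in ", path)
  frames
}

# ---------------------------------------------------------------------------
# run configuration

.config_keys <- function() list(
  scoring = names(formals(scoring_params)),
  design = c("budget", "stall", "seed", "temperature", "n_poses"),
  analysis = c("cutoff", "probe_radius", "n_points", "hbond_dist",
               "angle_min", "axis_tol", "min_hbonds"),
  fixtures = c("box", "min_separation", "n_copies", "spacing", "contact"),
  output_dir = NULL)

#' Default run configuration
#'
#' @return Nested list with `scoring`, `design`, `analysis`, `fixtures`
#'   and `output_dir` sections, populated with the package defaults.
#' @export
default_config <- function() {
  list(scoring = unclass(scoring_params()),
       design = list(budget = 500L, stall = 200L, seed = 1L,
                     temperature = 1, n_poses = 4L),
       analysis = list(cutoff = 4.5, probe_radius = 1.4, n_points = 960,
                       hbond_dist = 3.5, angle_min = 140, axis_tol = 30,
                       min_hbonds = 2L),
       fixtures = list(box = NULL, min_separation = 3, n_copies = 1L,
                       spacing = 20, contact = 3),
       output_dir = ".")
}

#' Read and validate a YAML run configuration
#'
#' Unknown sections or keys are rejected; values present in the file
#' override the defaults.
#'
#' @param path YAML file.
#' @return Validated nested configuration list.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_config()
  known <- .config_keys()
  bad <- setdiff(names(cfg), names(known))
  if (length(bad)) stop("unknown config section(s): ", paste(bad, collapse = ", "))
  for (sec in names(cfg)) {
    if (sec == "output_dir") { base$output_dir <- cfg[[sec]]; next }
    keys <- setdiff(names(cfg[[sec]]), known[[sec]])
    if (length(keys)) stop("unknown key(s) in section '", sec, "': ",
                           paste(keys, collapse = ", "))
    base[[sec]][names(cfg[[sec]])] <- cfg[[sec]]
  }
  base
}

#' Stable hash of a configuration
#'
#' FNV-1a over the canonical JSON serialization; used to stamp outputs
#' for reproducibility.
#'
#' @param cfg Configuration list.
#' @return 8-character hexadecimal string.
#' @export
config_hash <- function(cfg) {
  bytes <- utf8ToInt(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA,
                                      null = "null"))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(low, b %% 256)
    # 32-bit modular multiply by the FNV prime, in exact double arithmetic
    h1 <- h %/% 65536; h0 <- h %% 65536
    h <- (((h1 * 16777619) %% 65536) * 65536 + h0 * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
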