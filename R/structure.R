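#' Read atomic coordinates from a PDB or mmCIF file
#'
#' Minimal coordinate reader covering what distance validation needs: ATOM
#' (and HETATM) records with chain, author residue number, residue name,
#' atom name and Cartesian coordinates. Alternate locations other than the
#' first (' ' or 'A' in PDB; '.' or 'A' in mmCIF) are skipped; only the
#' first model of a multi-model file is read. The format is chosen by
#' content (an `_atom_site` loop marks mmCIF) unless forced.
#'
#' @param path Path to a `.pdb` or `.cif` file.
#' @param format `"auto"` (default), `"pdb"` or `"cif"`.
#' @return A data.frame of class `structure_coords` with columns `chain`,
#'   `resid` (integer author numbering), `resname`, `atom`, `x`, `y`, `z`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (format == "auto") {
    format <- if (any(grepl("^_atom_site\\.", lines))) "cif" else "pdb"
  }
  out <- if (format == "pdb") parse_pdb_atoms(lines) else
    parse_cif_atoms(lines)
  if (nrow(out) == 0L)
    stop("no atom records found in ", path, call. = FALSE)
  class(out) <- c("structure_coords", class(out))
  out
}

# PDB v3.3 fixed-width ATOM/HETATM records
parse_pdb_atoms <- function(lines) {
  endmdl <- grep("^ENDMDL", lines)
  if (length(endmdl)) lines <- lines[seq_len(endmdl[1L] - 1L)]
  rec <- lines[grepl("^(ATOM  |HETATM)", lines)]
  if (!length(rec))
    return(data.frame(chain = character(), resid = integer(),
                      resname = character(), atom = character(),
                      x = numeric(), y = numeric(), z = numeric()))
  fld <- function(a, b) trimws(substr(rec, a, b))
  altloc <- fld(17, 17)
  keep <- altloc %in% c("", "A")
  df <- data.frame(chain = fld(22, 22), resid = as.integer(fld(23, 26)),
                   resname = fld(18, 20), atom = fld(13, 16),
                   x = as.numeric(fld(31, 38)), y = as.numeric(fld(39, 46)),
                   z = as.numeric(fld(47, 54)), stringsAsFactors = FALSE)
  df[keep, , drop = FALSE]
}

# mmCIF _atom_site loop; whitespace-tokenised (adequate for coordinate
# loops, whose fields never contain embedded blanks)
parse_cif_atoms <- function(lines) {
  empty <- data.frame(chain = character(), resid = integer(),
                      resname = character(), atom = character(),
                      x = numeric(), y = numeric(), z = numeric())
  hdr_idx <- grep("^_atom_site\\.", lines)
  if (!length(hdr_idx)) return(empty)
  fields <- sub("^_atom_site\\.", "", trimws(lines[hdr_idx]))
  body <- lines[(max(hdr_idx) + 1L):length(lines)]
  stop_at <- grep("^(loop_|_[A-Za-z]|#)", body)
  if (length(stop_at)) body <- body[seq_len(stop_at[1L] - 1L)]
  body <- body[nzchar(trimws(body))]
  if (!length(body)) return(empty)
  toks <- strsplit(trimws(body), "[[:space:]]+")
  ok <- lengths(toks) == length(fields)
  toks <- toks[ok]
  mat <- do.call(rbind, toks)
  colnames(mat) <- fields
  pick <- function(...) {
    for (nm in c(...)) if (nm %in% fields) return(mat[, nm])
    stop("mmCIF _atom_site loop lacks required item(s): ",
         paste(c(...), collapse = "/"), call. = FALSE)
  }
  alt <- if ("label_alt_id" %in% fields) mat[, "label_alt_id"] else "."
  model <- if ("pdbx_PDB_model_num" %in% fields)
    mat[, "pdbx_PDB_model_num"] else "1"
  keep <- alt %in% c(".", "?", "A") & model == model[1L]
  df <- data.frame(chain = pick("auth_asym_id", "label_asym_id"),
                   resid = as.integer(pick("auth_seq_id", "label_seq_id")),
                   resname = pick("auth_comp_id", "label_comp_id"),
                   atom = gsub('"', "", pick("auth_atom_id",
                                             "label_atom_id")),
                   x = as.numeric(pick("Cartn_x")),
                   y = as.numeric(pick("Cartn_y")),
                   z = as.numeric(pick("Cartn_z")), stringsAsFactors = FALSE)
  df[keep, , drop = FALSE]
}

#' Write a minimal PDB coordinate file
#'
#' Emits standards-conforming fixed-width ATOM records (one model, no
#' header) -- enough for [read_structure()] and any conventional PDB reader.
#' Used by the fixture generator.
#'
#' @param coords A data.frame with `chain`, `resid`, `resname`, `atom`,
#'   `x`, `y`, `z`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(coords, path) {
  lines <- vapply(seq_len(nrow(coords)), function(i) {
    atom <- coords$atom[i]
    # atom-name column rule: 1-2 char element names start in column 14
    aname <- if (nchar(atom) < 4L) sprintf(" %-3s", atom) else atom
    sprintf("ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
            i, aname, coords$resname[i], coords$chain[i], coords$resid[i],
            coords$x[i], coords$y[i], coords$z[i])
  }, character(1))
  writeLines(c(lines, "END"), path)
  invisible(path)
}
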