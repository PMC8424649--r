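#' Read a crosslink identification table
#'
#' Consumes an xQuest/xProphet-style tab-delimited table of residue-pair
#' identifications. Crosslink chemistry (BS3) reacts with K, S, T, Y side
#' chains and the protein N terminus; records whose residue letters fall
#' outside that set at a non-terminal position are kept but flagged with a
#' warning.
#'
#' @param path Tab-delimited file with a header.
#' @param columns Named list mapping fields to header names; defaults:
#'   `protein_a`, `res_a`, `letter_a`, `protein_b`, `res_b`, `letter_b`,
#'   `score`.
#' @return A data.frame of class `crosslink_table` with the seven mapped
#'   columns plus `kind` (`"intra"` iff the two proteins are identical,
#'   `"inter"` otherwise).
#' @export
read_crosslinks <- function(path,
                            columns = list(protein_a = "protein1",
                                           res_a = "residue1",
                                           letter_a = "letter1",
                                           protein_b = "protein2",
                                           res_b = "residue2",
                                           letter_b = "letter2",
                                           score = "score")) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- data.table::fread(path, sep = "\t", header = TRUE,
                           data.table = FALSE)
  missing_cols <- setdiff(unlist(columns), names(raw))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  df <- data.frame(protein_a = as.character(raw[[columns$protein_a]]),
                   res_a = as.integer(raw[[columns$res_a]]),
                   letter_a = toupper(as.character(raw[[columns$letter_a]])),
                   protein_b = as.character(raw[[columns$protein_b]]),
                   res_b = as.integer(raw[[columns$res_b]]),
                   letter_b = toupper(as.character(raw[[columns$letter_b]])),
                   score = as.numeric(raw[[columns$score]]),
                   stringsAsFactors = FALSE)
  if (any(df$res_a < 1L) || any(df$res_b < 1L))
    stop("residue positions must be >= 1", call. = FALSE)
  df$kind <- ifelse(df$protein_a == df$protein_b, "intra", "inter")
  bad <- (!df$letter_a %in% c("K", "S", "T", "Y") & df$res_a != 1L) |
    (!df$letter_b %in% c("K", "S", "T", "Y") & df$res_b != 1L)
  if (any(bad))
    warning(sum(bad), " record(s) with residue letters outside the ",
            "crosslinkable set {K,S,T,Y, N-terminus}", call. = FALSE)
  class(df) <- c("crosslink_table", class(df))
  df
}

#' Filter crosslinks by identification score
#'
#' Keeps records scoring *strictly higher* than `min_score` (default 20, the
#' validation cutoff applied to xProphet identifications).
#'
#' @param records A crosslink data.frame (see [read_crosslinks()]).
#' @param min_score Score cutoff (exclusive).
#' @return The filtered data.frame.
#' @export
filter_by_score <- function(records, min_score = 20) {
  records[records$score > min_score, , drop = FALSE]
}

#' Count unique crosslinked residue pairs per protein pair
#'
#' Protein pairs are unordered (FAN1-MLH1 and MLH1-FAN1 pool together) and a
#' residue pair observed in several records counts once.
#'
#' @param records A crosslink data.frame.
#' @return A data.frame `protein_a`, `protein_b` (alphabetical within pair),
#'   `n_links`.
#' @export
count_pairs <- function(records) {
  if (nrow(records) == 0L)
    return(data.frame(protein_a = character(), protein_b = character(),
                      n_links = integer(), stringsAsFactors = FALSE))
  swap <- records$protein_a > records$protein_b |
    (records$protein_a == records$protein_b & records$res_a > records$res_b)
  pa <- ifelse(swap, records$protein_b, records$protein_a)
  ra <- ifelse(swap, records$res_b, records$res_a)
  pb <- ifelse(swap, records$protein_a, records$protein_b)
  rb <- ifelse(swap, records$res_a, records$res_b)
  key <- paste(pa, ra, pb, rb, sep = "\r")
  uniq <- !duplicated(key)
  tab <- table(paste(pa[uniq], pb[uniq], sep = "\r"))
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  data.frame(protein_a = vapply(parts, `[[`, character(1), 1L),
             protein_b = vapply(parts, `[[`, character(1), 2L),
             n_links = as.integer(tab), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Chain/numbering map from protein sequences onto a structure
#'
#' Deposited structures rarely number residues identically to the full
#' protein sequence; the map assigns each protein to a chain and an additive
#' offset so that sequence position `p` corresponds to structure residue
#' `p + offset` on that chain.
#'
#' @param chains Named list/vector: protein id -> chain id.
#' @param offsets Named list/vector: protein id -> integer offset (default 0
#'   for every mapped protein).
#' @param structure_id Free-text identifier of the structure (e.g. a PDB
#'   code).
#' @return An object of class `structure_map`.
#' @export
structure_map <- function(chains, offsets = NULL, structure_id = "") {
  chains <- as.list(chains)
  if (is.null(offsets)) offsets <- stats::setNames(
    as.list(rep(0L, length(chains))), names(chains))
  offsets <- as.list(offsets)
  stopifnot(all(names(chains) %in% names(offsets) |
                  lengths(offsets) == 0))
  structure(list(structure_id = structure_id, chains = chains,
                 offsets = offsets), class = "structure_map")
}

#' Calpha-Calpha distance of a crosslinked residue pair on a structure
#'
#' Euclidean distance between the alpha-carbon atoms of the two residues,
#' after mapping sequence positions to structure numbering via the
#' [structure_map()]. Residues absent from the model (unstructured or
#' unmodelled regions) give status `"unresolved"` with an `NA` distance --
#' this is the expected outcome for crosslinks in disordered regions, not an
#' error. An unmapped protein/chain is an error.
#'
#' @param record A one-row crosslink data.frame, or a list with `protein_a`,
#'   `res_a`, `protein_b`, `res_b`.
#' @param structure A coordinate data.frame from [read_structure()].
#' @param map A [structure_map()].
#' @return A list with `distance` (Angstrom or `NA`) and `status`
#'   (`"resolved"`/`"unresolved"`).
#' @export
map_distance <- function(record, structure, map) {
  stopifnot(inherits(map, "structure_map"))
  ca <- function(protein, pos) {
    chain <- map$chains[[protein]]
    if (is.null(chain))
      stop("protein ", protein, " has no chain assignment in the map",
           call. = FALSE)
    off <- map$offsets[[protein]]
    if (is.null(off)) off <- 0L
    hit <- structure$chain == chain & structure$resid == pos + off &
      structure$atom == "CA"
    if (!any(hit)) return(NULL)
    as.numeric(structure[which(hit)[1L], c("x", "y", "z")])
  }
  a <- ca(record$protein_a, record$res_a)
  b <- ca(record$protein_b, record$res_b)
  if (is.null(a) || is.null(b))
    return(list(distance = NA_real_, status = "unresolved"))
  list(distance = sqrt(sum((a - b)^2)), status = "resolved")
}

#' Annotate a crosslink table with structural distances
#'
#' Unlike the strict single-pair [map_distance()], records involving a
#' protein absent from the map (no chain in the structure at all) are
#' annotated as unresolved rather than raising an error, since a typical
#' table mixes proteins with and without deposited coordinates.
#'
#' @param records A crosslink data.frame.
#' @param structure,map See [map_distance()].
#' @param max_dist Consistency cutoff passed to [flag_consistency()].
#' @return `records` with added columns `distance` and `consistent`.
#' @export
map_distances <- function(records, structure, map, max_dist = 30) {
  res <- lapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    if (is.null(map$chains[[r$protein_a]]) ||
        is.null(map$chains[[r$protein_b]]))
      return(list(distance = NA_real_, status = "unresolved"))
    map_distance(r, structure, map)
  })
  records$distance <- vapply(res, `[[`, numeric(1), "distance")
  records$consistent <- ifelse(is.na(records$distance), NA,
                               flag_consistency(records$distance, max_dist))
  records
}

#' Is a crosslink distance consistent with the crosslinker geometry?
#'
#' BS3 bridges primary amines up to roughly 30 Angstrom apart in Calpha
#' terms; distances at or below the cutoff (inclusive) are consistent.
#'
#' @param distance Distance(s) in Angstrom, >= 0.
#' @param max_dist Cutoff in Angstrom.
#' @return Logical vector.
#' @export
flag_consistency <- function(distance, max_dist = 30) {
  stopifnot(all(distance >= 0, na.rm = TRUE))
  distance <= max_dist
}

#' Per-column consensus of a protein alignment
#'
#' For each alignment column, the most frequent non-gap residue and its
#' fraction of the non-gap rows. All-gap columns have `NA` consensus.
#'
#' @param alignment A character vector of equal-length aligned sequences, a
#'   named list thereof, or a `Biostrings::AAStringSet`.
#' @return A data.frame of class `consensus_profile` with `position`,
#'   `residue`, `fraction`, `n_nongap`.
#' @export
consensus_profile <- function(alignment) {
  seqs <- as_seq_vector(alignment)
  if (length(seqs) < 2L)
    stop("an alignment needs >= 2 sequences", call. = FALSE)
  if (length(unique(nchar(seqs))) != 1L)
    stop("ragged alignment: sequences differ in length", call. = FALSE)
  mat <- do.call(rbind, strsplit(toupper(seqs), ""))
  gap <- c("-", ".")
  out <- data.frame(position = seq_len(ncol(mat)),
                    residue = NA_character_, fraction = NA_real_,
                    n_nongap = 0L, stringsAsFactors = FALSE)
  for (j in seq_len(ncol(mat))) {
    col <- mat[, j]
    col <- col[!col %in% gap]
    if (length(col) == 0L) next
    tab <- sort(table(col), decreasing = TRUE)
    out$residue[j] <- names(tab)[1L]
    out$fraction[j] <- as.integer(tab[1L]) / length(col)
    out$n_nongap[j] <- length(col)
  }
  class(out) <- c("consensus_profile", class(out))
  out
}

#' @rdname consensus_profile
#' @param profile A `consensus_profile`.
#' @param fraction_threshold Highlight columns with consensus fraction
#'   *strictly above* this value (default 0.80).
#' @return `highlight_consensus()`: integer vector of highlighted column
#'   positions.
#' @export
highlight_consensus <- function(profile, fraction_threshold = 0.80) {
  stopifnot(inherits(profile, "consensus_profile"))
  profile$position[!is.na(profile$fraction) &
                     profile$fraction > fraction_threshold]
}

as_seq_vector <- function(x) {
  if (inherits(x, "AAStringSet") || inherits(x, "XStringSet"))
    return(as.character(x))
  if (is.list(x)) return(vapply(x, as.character, character(1)))
  as.character(x)
}

#' Read sequences from a FASTA file
#'
#' Thin wrapper over `Biostrings::readAAStringSet()` returning a plain named
#' character vector.
#'
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("reading FASTA requires the Biostrings package", call. = FALSE)
  ss <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
}

#' Locate a motif in a protein sequence
#'
#' All exact (possibly overlapping) occurrences of a plain-residue motif,
#' 1-based. The motif of interest here is the MLH1-interacting SPYF
#' (MIP-box-like) motif.
#'
#' @param sequence A single protein sequence (character).
#' @param motif Plain residue string, e.g. `"SPYF"`.
#' @return Integer vector of 1-based start positions (possibly empty).
#' @export
find_motif <- function(sequence, motif = "SPYF") {
  sequence <- toupper(as.character(sequence)[1L])
  motif <- toupper(as.character(motif)[1L])
  if (is.na(motif) || !nzchar(motif) || grepl("[^A-Z]", motif))
    stop("`motif` must be a non-empty string of residue letters",
         call. = FALSE)
  hits <- gregexpr(paste0("(?=", motif, ")"), sequence, perl = TRUE)[[1L]]
  if (hits[1L] == -1L) return(integer())
  as.integer(hits)
}

#' Length of an inclusive 1-based residue span
#'
#' @param start,end 1-based residue positions with `start <= end`.
#' @return `end - start + 1`.
#' @export
span_length <- function(start, end) {
  if (any(start < 1L) || any(start > end))
    stop("need 1 <= start <= end", call. = FALSE)
  as.integer(end - start + 1L)
}
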