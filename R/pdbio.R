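#' Read a multi-model PDB trajectory
#'
#' Frames are delimited by \code{MODEL}/\code{ENDMDL} records; a file without
#' \code{MODEL} records is read as a single frame. Coordinates are parsed
#' from the fixed PDB columns at their native 3-decimal precision. Alternate
#' locations \code{' '} and \code{'A'} are kept, all others dropped with a
#' warning. Occupancy and B-factor columns are ignored. Nonbonded parameters
#' are left at zero until \code{\link{assign_parameters}} is called.
#'
#' @param source path to a PDB file, or a character vector of PDB lines
#'   (a single string containing newlines is also accepted)
#' @param frame_interval time between models, ps (default 100)
#' @param replica_id integer replica label attached to the trajectory
#' @return a \code{\link{trajectory}}
#' @export
read_pdb <- function(source, frame_interval = 100, replica_id = 1L) {
  if (length(source) == 1L && !grepl("\n", source) && file.exists(source)) {
    lines <- readLines(source, warn = FALSE)
  } else {
    lines <- unlist(strsplit(source, "\n", fixed = TRUE), use.names = FALSE)
  }
  is_atom <- startsWith(lines, "ATOM  ") | startsWith(lines, "HETATM")
  is_model <- startsWith(lines, "MODEL")
  if (!any(is_atom)) stop("read_pdb(): no ATOM/HETATM records found")

  # model id per line: 0 before any MODEL record (implicit single frame)
  model_no <- cumsum(is_model)
  atom_lines <- lines[is_atom]
  atom_model <- model_no[is_atom]
  atom_lineno <- which(is_atom)

  # altloc filter
  altloc <- substr(atom_lines, 17, 17)
  keep <- altloc %in% c(" ", "A", "")
  if (!all(keep)) {
    warning("read_pdb(): dropped ", sum(!keep),
            " atoms with alternate location other than ' '/'A'")
    atom_lines <- atom_lines[keep]
    atom_model <- atom_model[keep]
    atom_lineno <- atom_lineno[keep]
  }

  models <- unique(atom_model)
  counts <- tabulate(match(atom_model, models))
  if (length(unique(counts)) != 1L) {
    bad <- models[which(counts != counts[1L])[1L]]
    stop(sprintf(
      "read_pdb(): inconsistent atom count in MODEL %d (%d atoms, expected %d)",
      bad, counts[which(models == bad)], counts[1L]))
  }
  n_at <- counts[1L]
  n_fr <- length(models)

  xs <- suppressWarnings(as.numeric(substr(atom_lines, 31, 38)))
  ys <- suppressWarnings(as.numeric(substr(atom_lines, 39, 46)))
  zs <- suppressWarnings(as.numeric(substr(atom_lines, 47, 54)))
  bad_xyz <- which(is.na(xs) | is.na(ys) | is.na(zs))
  if (length(bad_xyz) > 0L) {
    stop("read_pdb(): unparseable coordinate field at line ",
         atom_lineno[bad_xyz[1L]])
  }

  first <- atom_model == models[1L]
  serial <- suppressWarnings(as.integer(substr(atom_lines[first], 7, 11)))
  if (anyNA(serial)) serial <- seq_len(n_at)
  element <- trimws(substr(atom_lines[first], 77, 78))
  name <- trimws(substr(atom_lines[first], 13, 16))
  if (any(element == "")) {
    # fall back to the leading letter(s) of the atom name
    guess <- sub("^[0-9]*", "", name)
    element <- ifelse(element == "", toupper(substr(guess, 1, 1)), element)
  }
  res_seq <- suppressWarnings(as.integer(substr(atom_lines[first], 23, 26)))
  if (anyNA(res_seq)) {
    stop("read_pdb(): unparseable residue number at line ",
         atom_lineno[first][which(is.na(res_seq))[1L]])
  }
  top <- topology(data.frame(
    serial = serial,
    name = name,
    element = element,
    res_name = trimws(substr(atom_lines[first], 18, 21)),
    res_seq = res_seq,
    chain_id = substr(atom_lines[first], 22, 22),
    stringsAsFactors = FALSE))

  coords <- array(NA_real_, dim = c(n_at, 3L, n_fr))
  coords[, 1L, ] <- xs
  coords[, 2L, ] <- ys
  coords[, 3L, ] <- zs
  trajectory(top, coords, frame_interval = frame_interval,
             replica_id = replica_id)
}

#' Write frames of a trajectory as multi-model PDB text
#'
#' One \code{MODEL}/\code{ENDMDL} block is emitted per requested frame;
#' output round-trips through \code{\link{read_pdb}} with coordinates equal
#' at the 3-decimal PDB column precision and topology identical.
#'
#' @param traj a \code{\link{trajectory}}
#' @param frame_indices frames to write (1-based); defaults to all frames
#' @param file optional path; when given, text is written there
#' @return character vector of PDB lines (invisibly when \code{file} is set)
#' @export
write_pdb <- function(traj, frame_indices = seq_len(n_frames(traj)),
                      file = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  if (length(frame_indices) == 0L) {
    stop("write_pdb(): empty frame index list")
  }
  if (any(frame_indices < 1L) || any(frame_indices > n_frames(traj))) {
    stop("write_pdb(): frame index out of range 1..", n_frames(traj))
  }
  top <- traj$topology
  std_aa <- standard_amino_acids()
  record <- ifelse(top$res_name %in% std_aa, "ATOM  ", "HETATM")
  # PDB convention: names of 1-3 characters start in column 14
  name_fmt <- ifelse(nchar(top$name) < 4L,
                     sprintf(" %-3s", top$name), top$name)
  serial <- ((seq_len(nrow(top)) - 1L) %% 99999L) + 1L
  prefix <- sprintf("%s%5d %4s %-4s%1s%4d    ",
                    record, serial, name_fmt, top$res_name,
                    top$chain_id, top$res_seq)
  suffix <- sprintf("  1.00  0.00          %2s", top$element)
  out <- vector("list", length(frame_indices))
  for (k in seq_along(frame_indices)) {
    i <- frame_indices[k]
    xyz <- traj$coords[, , i, drop = TRUE]
    body <- paste0(prefix,
                   sprintf("%8.3f%8.3f%8.3f", xyz[, 1], xyz[, 2], xyz[, 3]),
                   suffix)
    out[[k]] <- c(sprintf("MODEL     %4d", k), body, "ENDMDL")
  }
  lines <- c(unlist(out, use.names = FALSE), "END")
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}

#' Read a nonbonded parameter table
#'
#' The table is a CSV with header
#' \code{res_name,atom_name,charge,sigma,epsilon}: partial charge in
#' elementary units, Lennard-Jones sigma in Angstrom and epsilon in
#' kcal/mol, keyed by residue and atom name.
#'
#' @param path CSV file path
#' @return data.frame of parameters
#' @export
read_nonbonded_params <- function(path) {
  params <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("res_name", "atom_name", "charge", "sigma", "epsilon")
  if (!all(required %in% names(params))) {
    stop("read_nonbonded_params(): header must contain ",
         paste(required, collapse = ","))
  }
  params
}

#' Assign nonbonded parameters to a topology
#'
#' Atoms are matched by \code{(res_name, atom_name)}; unmatched atoms keep
#' zero charge/sigma/epsilon and a warning lists the unmatched keys.
#'
#' @param top a \code{topology} or \code{trajectory}
#' @param params data.frame from \code{\link{read_nonbonded_params}}
#' @return the input with parameter columns filled
#' @export
assign_parameters <- function(top, params) {
  if (inherits(top, "trajectory")) {
    top$topology <- assign_parameters(top$topology, params)
    return(top)
  }
  stopifnot(inherits(top, "topology"))
  key <- paste(top$res_name, top$name, sep = "\r")
  pkey <- paste(params$res_name, params$atom_name, sep = "\r")
  idx <- match(key, pkey)
  hit <- !is.na(idx)
  top$charge[hit] <- params$charge[idx[hit]]
  top$sigma[hit] <- params$sigma[idx[hit]]
  top$epsilon[hit] <- params$epsilon[idx[hit]]
  top$charge[!hit] <- 0
  top$sigma[!hit] <- 0
  top$epsilon[!hit] <- 0
  if (any(!hit)) {
    misses <- unique(sub("\r", "/", key[!hit]))
    warning("assign_parameters(): no parameters for ",
            length(misses), " atom type(s): ",
            paste(utils::head(misses, 10L), collapse = ", "))
  }
  top
}
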