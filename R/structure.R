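#' Read a protein structure ensemble from PDB
#'
#' Reads one multi-MODEL PDB file, or several single-model files sharing the
#' same topology, into a `structure_ensemble`: an ordered residue table, a
#' fixed atom topology, and one coordinate set (in nm) per frame. Only
#' amino-acid residues are kept (the 20 standard names plus common
#' protonation variants); waters, ions and other heteroatoms are dropped.
#' Hydrogens are retained when present. For alternate locations only the
#' highest-occupancy conformer is kept so every frame shares one topology.
#'
#' @param path one PDB file (possibly multi-MODEL) or a character vector of
#'   single-model PDB files sharing topology, one frame each.
#' @param frame_selection optional integer vector of frame (MODEL) indices,
#'   1-based, to retain.
#' @return an object of class `structure_ensemble` with elements `residues`
#'   (tibble, see [residue_table()]), `atoms` (tibble: `residue_index`,
#'   `name`, `element`) and `frames` (list of n_atoms x 3 coordinate
#'   matrices, nm).
#' @export
read_structure <- function(path, frame_selection = NULL) {
  stopifnot(is.character(path), length(path) >= 1)
  parts <- lapply(path, .read_structure_one)
  ens <- parts[[1L]]
  if (length(parts) > 1L) {
    for (k in seq_along(parts)[-1L]) {
      .check_same_topology(ens, parts[[k]], path[1L], path[k])
      ens$frames <- c(ens$frames, parts[[k]]$frames)
    }
  }
  if (!is.null(frame_selection)) {
    frame_selection <- as.integer(frame_selection)
    if (any(frame_selection < 1L | frame_selection > length(ens$frames))) {
      abort(sprintf("frame_selection out of range 1..%d", length(ens$frames)))
    }
    ens$frames <- ens$frames[frame_selection]
  }
  ens
}

.read_structure_one <- function(path) {
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) abort(sprintf("cannot parse PDB '%s': %s", path, conditionMessage(e)))
  )
  at <- pdb$atom
  keep <- at$type == "ATOM" & at$resid %in% .accepted_residue_names()
  skipped <- unique(at$resid[at$type == "ATOM" & !keep])
  if (length(skipped)) {
    warn(sprintf("skipping non-amino-acid residues in '%s': %s",
                 path, paste(skipped, collapse = ", ")))
  }
  if (!any(keep)) abort(sprintf("no amino-acid residues in '%s'", path))
  at <- at[keep, , drop = FALSE]
  rowid <- which(keep)

  ins <- at$insert
  ins[!is.na(ins) & ins == ""] <- NA_character_
  rkey <- paste(at$chain, at$resno, ifelse(is.na(ins), "", ins), sep = "\r")

  # alternate locations: keep highest-occupancy conformer per atom site
  alt <- at$alt
  if (any(!is.na(alt) & alt != "")) {
    occ <- ifelse(is.na(at$o), 1, at$o)
    site <- paste(rkey, at$elety, sep = "\r")
    ord <- order(site, -occ, seq_len(nrow(at)))
    first <- !duplicated(site[ord])
    sel <- sort(ord[first])
    at <- at[sel, , drop = FALSE]
    rowid <- rowid[sel]
    ins <- ins[sel]
    rkey <- rkey[sel]
  }

  # residues ordered by chain, then file order within chain
  first_row <- !duplicated(rkey)
  res_chain <- at$chain[first_row]
  res_order <- order(res_chain, seq_len(sum(first_row)))
  res <- residue_table(
    chain = res_chain[res_order],
    seq_number = at$resno[first_row][res_order],
    insertion_code = ins[first_row][res_order],
    name = at$resid[first_row][res_order]
  )
  res_index <- match(rkey, unique(rkey)[res_order])

  atom_order <- order(res_index, seq_len(nrow(at)))
  at <- at[atom_order, , drop = FALSE]
  rowid <- rowid[atom_order]
  res_index <- res_index[atom_order]

  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem))) elem <- substr(gsub("[0-9]", "", at$elety), 1, 1)
  atoms <- tibble(
    residue_index = as.integer(res_index),
    name = at$elety,
    element = toupper(trimws(ifelse(is.na(elem) | elem == "",
                                    substr(gsub("[0-9]", "", at$elety), 1, 1), elem)))
  )

  nmod <- nrow(pdb$xyz)
  cols <- bio3d::atom2xyz(rowid)
  frames <- lapply(seq_len(nmod), function(m) {
    xyz <- matrix(pdb$xyz[m, cols], ncol = 3, byrow = TRUE) / 10  # Angstrom -> nm
    if (any(!is.finite(xyz))) {
      abort(sprintf("non-finite coordinates in model %d of '%s'", m, path))
    }
    xyz
  })

  structure(
    list(residues = res, atoms = atoms, frames = frames),
    class = "structure_ensemble"
  )
}

.check_same_topology <- function(a, b, path_a, path_b) {
  if (!identical(a$residues$label, b$residues$label)) {
    i <- which(!(a$residues$label[seq_len(min(nrow(a$residues), nrow(b$residues)))] ==
                   b$residues$label[seq_len(min(nrow(a$residues), nrow(b$residues)))]))
    div <- if (length(i)) a$residues$label[i[1]] else
      a$residues$label[min(nrow(a$residues), nrow(b$residues)) + 1L]
    abort(sprintf("topology mismatch between '%s' and '%s' at residue %s",
                  path_a, path_b, div))
  }
  if (!identical(a$atoms$name, b$atoms$name) ||
      !identical(a$atoms$residue_index, b$atoms$residue_index)) {
    abort(sprintf("atom topology mismatch between '%s' and '%s'", path_a, path_b))
  }
}

#' @export
print.structure_ensemble <- function(x, ...) {
  cat(sprintf("<structure_ensemble> %d residues, %d atoms, %d frame(s)\n",
              nrow(x$residues), nrow(x$atoms), length(x$frames)))
  invisible(x)
}

#' Write a structure ensemble as a multi-MODEL PDB file
#'
#' Frames become MODEL/ENDMDL blocks; coordinates are converted from nm to
#' Angstrom. Intended for the synthetic toy ensembles; it writes plain ATOM
#' records only.
#'
#' @param ensemble a `structure_ensemble`.
#' @param path output file path.
#' @export
write_ensemble_pdb <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "structure_ensemble"))
  res <- ensemble$residues
  at <- ensemble$atoms
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (m in seq_along(ensemble$frames)) {
    xyz <- ensemble$frames[[m]] * 10
    writeLines(sprintf("MODEL     %4d", m), con)
    name4 <- ifelse(nchar(at$name) < 4, sprintf(" %-3s", at$name), at$name)
    lines <- sprintf(
      "ATOM  %5d %4s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nrow(at)), name4, res$name[at$residue_index],
      res$chain[at$residue_index], res$seq_number[at$residue_index],
      ifelse(is.na(res$insertion_code[at$residue_index]), " ",
             res$insertion_code[at$residue_index]),
      xyz[, 1], xyz[, 2], xyz[, 3], 1, 0, at$element
    )
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
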