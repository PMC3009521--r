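#' @importFrom tibble tibble as_tibble
#' @importFrom rlang abort warn .data
NULL

# The 20 standard amino acids plus common protonation-variant names.
# Variants map to their parent residue for parameter lookup.
.standard_aa <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL"
)

.aa_variant_map <- c(
  HID = "HIS", HIE = "HIS", HIP = "HIS",
  HSD = "HIS", HSE = "HIS", HSP = "HIS",
  ASH = "ASP", GLH = "GLU", LYN = "LYS",
  CYX = "CYS", CYM = "CYS", ARN = "ARG"
)

.accepted_residue_names <- function() c(.standard_aa, names(.aa_variant_map))

# Parent residue name used for force-field parameter lookup.
.normalize_residue_name <- function(name) {
  hit <- .aa_variant_map[name]
  ifelse(is.na(hit), name, unname(hit))
}

#' Build a residue table
#'
#' Residue identity follows author (PDB "auth") numbering: chain, residue
#' number and insertion code. A dense 1-based `index` orders residues by
#' chain and then file order; all matrices in the package are indexed by it
#' and labelled externally with `label` strings of the form
#' `"<chain>:<number><insertion>:<name>"` (e.g. `"A:42:LEU"`).
#'
#' @param chain character vector of single-character chain identifiers.
#' @param seq_number integer author residue numbers.
#' @param insertion_code character insertion codes (`NA` when absent).
#' @param name 3-letter residue names.
#' @return a tibble with columns `index`, `chain`, `seq_number`,
#'   `insertion_code`, `name`, `label`.
#' @export
residue_table <- function(chain, seq_number, insertion_code = NA_character_, name) {
  n <- length(seq_number)
  tb <- tibble(
    index = seq_len(n),
    chain = rep_len(as.character(chain), n),
    seq_number = as.integer(seq_number),
    insertion_code = rep_len(as.character(insertion_code), n),
    name = rep_len(as.character(name), n)
  )
  key <- paste(tb$chain, tb$seq_number, ifelse(is.na(tb$insertion_code), "", tb$insertion_code))
  if (anyDuplicated(key)) {
    abort(paste0("duplicate residue identity: ", key[duplicated(key)][1]))
  }
  tb$label <- residue_label(tb)
  tb
}

#' @rdname residue_table
#' @param residues a residue table.
#' @export
residue_label <- function(residues) {
  ins <- ifelse(is.na(residues$insertion_code) | residues$insertion_code == "",
                "", residues$insertion_code)
  sprintf("%s:%d%s:%s", residues$chain, residues$seq_number, ins, residues$name)
}

# Parse labels back into a residue table; unparseable labels fall back to a
# generic single-chain numbering so matrices from other tools still load.
.parse_residue_labels <- function(labels) {
  m <- regmatches(labels, regexec("^([^:]+):([0-9]+)([A-Za-z]?):(.+)$", labels))
  ok <- vapply(m, length, 1L) == 5L
  if (all(ok)) {
    residue_table(
      chain = vapply(m, `[`, "", 2L),
      seq_number = as.integer(vapply(m, `[`, "", 3L)),
      insertion_code = ifelse(vapply(m, `[`, "", 4L) == "", NA_character_,
                              vapply(m, `[`, "", 4L)),
      name = vapply(m, `[`, "", 5L)
    )
  } else {
    residue_table(chain = "A", seq_number = seq_along(labels),
                  insertion_code = NA_character_, name = "UNK")
  }
}
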