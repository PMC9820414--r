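#' Standard amino-acid residue names
#'
#' The twenty standard residues plus the ACE/NME capping groups used when
#' receptor models are truncated after TM7.
#' @return character vector
#' @export
standard_amino_acids <- function() {
  c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
    "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL",
    "ACE", "NME")
}

#' Default environment-group classification rules
#'
#' Residue-name sets mapping non-protein residues to the membrane, water
#' and ion groups used by the energy decomposition. The defaults cover the
#' POPC bilayer, the common water residue names and monatomic ions.
#'
#' @return named list of character vectors (\code{membrane}, \code{water},
#'   \code{ion})
#' @export
default_group_rules <- function() {
  list(membrane = c("POPC", "POPE", "POPS", "DPPC", "DOPC", "LIP"),
       water = c("HOH", "TIP3", "T3P", "WAT", "SPC", "SOL"),
       ion = c("NA", "CL", "K", "MG", "ZN", "CA2", "SOD", "CLA", "POT"))
}

#' Label every atom with its environment group
#'
#' Protein atoms (standard amino-acid residues) are labelled
#' \code{protein:<chain_id>}; other residues are classified by the rule
#' sets. Energy decomposition and interface analysis require groups to be
#' assigned first.
#'
#' @param top a \code{topology} or \code{trajectory}
#' @param rules named list of residue-name vectors for \code{membrane},
#'   \code{water} and \code{ion}; see \code{\link{default_group_rules}}
#' @return the input with the \code{group} column filled
#' @export
assign_groups <- function(top, rules = default_group_rules()) {
  if (inherits(top, "trajectory")) {
    top$topology <- assign_groups(top$topology, rules)
    return(top)
  }
  stopifnot(inherits(top, "topology"))
  group <- rep(NA_character_, nrow(top))
  is_prot <- top$res_name %in% standard_amino_acids()
  group[is_prot] <- paste0("protein:", top$chain_id[is_prot])
  for (g in c("membrane", "water", "ion")) {
    hit <- !is_prot & top$res_name %in% rules[[g]]
    group[hit] <- g
  }
  if (anyNA(group)) {
    stop("assign_groups(): unclassified residue name(s): ",
         paste(unique(top$res_name[is.na(group)]), collapse = ", "))
  }
  top$group <- group
  top
}
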