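# Pharmacophore channel typing. The bundled rule table maps (residue, atom
# name) to channel flags, approximating AutoDock-style atom typing; it is a
# package choice, editable by the user, and deliberately conservative: atoms
# not covered by any rule carry only the excluded-volume flag.

.rulesCache <- new.env(parent = emptyenv())

#' Pharmacophore channel typing rules
#'
#' Loads the channel rule table: a list with `metal_elements`, `backbone`
#' (atom-name rules shared by all residues) and `residues` (per-residue
#' side-chain rules), each mapping channel names to PDB atom names. The
#' bundled default approximates AutoDock-style typing; pass a path to an
#' edited copy to override.
#'
#' @param path path to a rules JSON file; default = the bundled table.
#' @return the rule list.
#' @export
channelRules <- function(path = NULL) {
  if (is.null(path)) {
    if (is.null(.rulesCache$default)) {
      .rulesCache$default <- jsonlite::read_json(
        system.file("extdata", "channel_rules.json", package = "DockSelect"),
        simplifyVector = TRUE)
    }
    return(.rulesCache$default)
  }
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Assign pharmacophore channel flags to pocket atoms
#'
#' Sets the 8 channel flags of every pocket atom from the typing rules:
#' metals by element; backbone nitrogen/oxygen donors and acceptors by atom
#' name; side-chain channels by (residue, atom name). The excluded-volume
#' flag is set for every heavy atom. Atoms covered by no rule keep only the
#' excluded-volume flag; this is reported once per call via a message.
#'
#' @param pocket a [PocketStructure-class].
#' @param rules rule list from [channelRules()].
#' @return the pocket with its channel flags replaced.
#' @export
assignChannels <- function(pocket, rules = channelRules()) {
  stopifnot(is(pocket, "PocketStructure"))
  n <- nAtoms(pocket)
  ch <- matrix(FALSE, n, 8, dimnames = list(NULL, channelNames()))
  if (n == 0) {
    pocket@channels <- ch
    return(pocket)
  }
  ch[, "excluded_volume"] <- TRUE
  el <- .normElement(pocket@elements)
  res <- toupper(pocket@resnames)
  atn <- toupper(pocket@atomnames)
  covered <- rep(FALSE, n)

  metal <- el %in% rules$metal_elements
  ch[metal, "metallic"] <- TRUE
  covered <- covered | metal

  # backbone rules apply to amino-acid residues only
  aa <- res %in% names(rules$residues)
  for (channel in names(rules$backbone)) {
    hit <- aa & atn %in% unlist(rules$backbone[[channel]])
    ch[hit, channel] <- TRUE
    covered <- covered | hit
  }
  # CA and backbone C are covered (excluded volume only) by design
  covered <- covered | (aa & atn %in% c("CA", "C"))

  for (resname in unique(res[aa])) {
    rr <- rules$residues[[resname]]
    sel <- res == resname
    for (channel in names(rr)) {
      hit <- sel & atn %in% unlist(rr[[channel]])
      ch[hit, channel] <- TRUE
      covered <- covered | hit
    }
  }
  if (any(!covered))
    message(sum(!covered), " pocket atom(s) matched no typing rule; ",
            "flagged as excluded volume only")
  pocket@channels <- ch
  validObject(pocket)
  pocket
}
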