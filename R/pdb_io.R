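## Minimal fixed-width PDB ATOM/HETATM I/O. No pre-installed R package parses
## PDB, so the standard column layout is implemented directly (and checked
## against Biopython in the test suite).

#' Read ATOM/HETATM records from a PDB file
#'
#' @param path path to a PDB-format file.
#' @return data.frame with columns record, serial, atom, resname, chain,
#'   resid, x, y, z, element.
#' @export
read_pdb <- function(path) {
  lines <- readLines(path)
  lines <- lines[startsWith(lines, "ATOM") | startsWith(lines, "HETATM")]
  if (!length(lines)) stop("no ATOM/HETATM records in ", path)
  fw <- function(l, a, b) trimws(substr(l, a, b))
  el <- vapply(lines, function(l) fw(l, 77, 78), "", USE.NAMES = FALSE)
  nm <- vapply(lines, function(l) fw(l, 13, 16), "", USE.NAMES = FALSE)
  ## fall back to first letter of the atom name when element column is blank
  el[el == ""] <- gsub("[^A-Za-z].*$", "", gsub("^[0-9]", "", nm[el == ""]))
  data.frame(
    record  = vapply(lines, function(l) fw(l, 1, 6), "", USE.NAMES = FALSE),
    serial  = as.integer(vapply(lines, function(l) fw(l, 7, 11), "", USE.NAMES = FALSE)),
    atom    = nm,
    resname = vapply(lines, function(l) fw(l, 18, 20), "", USE.NAMES = FALSE),
    chain   = vapply(lines, function(l) fw(l, 22, 22), "", USE.NAMES = FALSE),
    resid   = as.integer(vapply(lines, function(l) fw(l, 23, 26), "", USE.NAMES = FALSE)),
    x = as.numeric(vapply(lines, function(l) fw(l, 31, 38), "", USE.NAMES = FALSE)),
    y = as.numeric(vapply(lines, function(l) fw(l, 39, 46), "", USE.NAMES = FALSE)),
    z = as.numeric(vapply(lines, function(l) fw(l, 47, 54), "", USE.NAMES = FALSE)),
    element = toupper(el),
    stringsAsFactors = FALSE)
}

#' Write an atom table as PDB ATOM/HETATM records
#'
#' @param atoms data.frame with columns atom, resname, resid, element, x, y,
#'   z; optional record, chain, serial.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_pdb <- function(atoms, path) {
  n <- nrow(atoms)
  record <- atoms$record %||% rep("ATOM", n)
  chain <- atoms$chain %||% rep("A", n)
  serial <- atoms$serial %||% seq_len(n)
  name <- vapply(seq_len(n), function(i) {
    a <- atoms$atom[i]
    ## standard alignment: element right-justified in cols 13-14
    if (nchar(a) < 4 && nchar(atoms$element[i]) == 1) paste0(" ", a) else a
  }, "")
  lines <- sprintf("%-6s%5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   record, serial, name, atoms$resname, chain, atoms$resid,
                   atoms$x, atoms$y, atoms$z, 1, 0, atoms$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}
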