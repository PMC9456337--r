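#' Read assigned chemical shifts from an NMR-STAR v3 file
#'
#' Parses the `_Atom_chem_shift` loop of an NMR-STAR v3.x entry (the format
#' used for BMRB chemical-shift depositions) into a shift table. Only the
#' assigned-chemical-shift loop is read; residue numbering follows the
#' entry's own sequence indices (`Comp_index_ID`).
#'
#' @param path NMR-STAR file.
#' @return tibble with columns `resno`, `resname`, `atom`, `nucleus`
#'   (`H`/`C`/`N`), `shift` (ppm).
#' @export
read_nmrstar_shifts <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  loops <- which(trimws(lines) == "loop_")
  if (!length(loops)) abort(sprintf("'%s': no loop_ blocks found", path))
  for (start in loops) {
    i <- start + 1L
    tags <- character(0)
    while (i <= length(lines) && grepl("^\\s*_", lines[i])) {
      tags <- c(tags, trimws(lines[i]))
      i <- i + 1L
    }
    if (!any(grepl("^_Atom_chem_shift\\.", tags))) next
    # collect data rows until stop_
    rows <- list()
    while (i <= length(lines) && trimws(lines[i]) != "stop_") {
      ln <- trimws(lines[i])
      if (nzchar(ln) && !startsWith(ln, "#")) {
        rows[[length(rows) + 1L]] <- strsplit(ln, "\\s+")[[1]]
      }
      i <- i + 1L
    }
    if (!length(rows)) abort(sprintf("'%s': empty _Atom_chem_shift loop", path))
    bad <- which(lengths(rows) != length(tags))
    if (length(bad)) {
      abort(sprintf("'%s': shift-loop row %d has %d field(s), expected %d",
                    path, bad[1], lengths(rows)[bad[1]], length(tags)))
    }
    mat <- do.call(rbind, rows)
    colnames(mat) <- sub("^_Atom_chem_shift\\.", "", tags)
    need <- function(nm, alt = NULL) {
      hit <- intersect(c(nm, alt), colnames(mat))
      if (!length(hit)) abort(sprintf("'%s': shift loop lacks tag %s", path, nm))
      mat[, hit[1]]
    }
    resno <- as.integer(need("Comp_index_ID", "Seq_ID"))
    resname <- need("Comp_ID")
    atom <- need("Atom_ID")
    nucleus <- toupper(need("Atom_type"))
    shift <- as.numeric(need("Val"))
    if (any(is.na(shift))) {
      abort(sprintf("'%s': non-numeric shift value in _Atom_chem_shift loop", path))
    }
    out <- tibble(resno = resno, resname = resname, atom = atom,
                  nucleus = nucleus, shift = shift)
    # nucleus must be consistent with the atom-name element
    mismatch <- substr(out$atom, 1L, 1L) != out$nucleus &
      !(out$nucleus == "H" & grepl("^[0-9]*H", out$atom))
    if (any(mismatch)) {
      warn(sprintf("read_nmrstar_shifts: %d row(s) where Atom_type disagrees with the atom name", sum(mismatch)))
    }
    return(out)
  }
  abort(sprintf("'%s': no _Atom_chem_shift loop found", path))
}
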