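#' Read a (multi-model) structure from PDB or mmCIF
#'
#' Parsing is delegated to \pkg{bio3d}; the result is converted to the
#' package's long atom table (one row per atom per model). Hetero groups
#' (heme, metal ions) are retained. When alternate locations are present only
#' the highest-occupancy conformer is kept and a message reports the discard.
#' Residue numbering is taken verbatim from the file.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"pdb"` or `"mmcif"`.
#' @return an atom table (see [as_structure()]); `source_id` records the file.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  }
  pdb <- tryCatch(
    if (format == "pdb") bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    else suppressWarnings(bio3d::read.cif(path, verbose = FALSE)),
    error = function(e) abort(sprintf("failed to parse %s file '%s': %s",
                                      format, path, conditionMessage(e)))
  )
  at <- pdb$atom
  # altloc: keep the highest-occupancy conformer per atom site
  if (any(nzchar(at$alt) & !is.na(at$alt))) {
    occ <- ifelse(is.na(at$o), 1, at$o)
    key <- paste(at$chain, at$resno, at$elety)
    ord <- order(key, -occ)
    keep_idx <- ord[!duplicated(key[ord])]
    keep <- sort(keep_idx)
    n_drop <- nrow(at) - length(keep)
    if (n_drop > 0) {
      inform(sprintf("read_structure: dropped %d alternate-location atom(s), keeping highest occupancy", n_drop))
    }
  } else {
    keep <- seq_len(nrow(at))
  }
  elem <- at$elesy
  if (is.null(elem)) elem <- NA_character_
  elem <- toupper(trimws(elem))
  base <- tibble(
    chain = ifelse(is.na(at$chain) | !nzchar(at$chain), "A", at$chain),
    resno = as.integer(at$resno),
    resname = trimws(at$resid),
    atom = trimws(at$elety),
    element = ifelse(is.na(elem) | !nzchar(elem), NA_character_, elem),
    hetero = at$type == "HETATM"
  )[keep, ]

  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  nmod <- nrow(xyz)
  per_model <- map(seq_len(nmod), function(m) {
    mat <- matrix(xyz[m, ], ncol = 3L, byrow = TRUE)[keep, , drop = FALSE]
    mutate(base, model = m, x = mat[, 1], y = mat[, 2], z = mat[, 3])
  })
  as_structure(bind_rows(per_model), source_id = basename(path))
}

#' Write a structure ensemble to PDB or minimal mmCIF
#'
#' Coordinates are written to three decimals. Multi-model ensembles use
#' MODEL/ENDMDL records (PDB) or the `pdbx_PDB_model_num` field (mmCIF).
#'
#' @param struct an atom table.
#' @param path output path.
#' @param format `"auto"`, `"pdb"` or `"mmcif"`.
#' @return `path`, invisibly.
#' @export
write_structure <- function(struct, path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  }
  struct <- as_structure(struct)
  lines <- if (format == "pdb") format_pdb_lines(struct) else format_cif_lines(struct)
  writeLines(lines, path)
  invisible(path)
}

format_pdb_lines <- function(struct) {
  models <- sort(unique(struct$model))
  multi <- length(models) > 1L
  out <- character(0)
  for (m in models) {
    s <- struct[struct$model == m, ]
    rec <- ifelse(s$hetero, "HETATM", "ATOM  ")
    name <- vapply(seq_len(nrow(s)), function(i) {
      a <- s$atom[i]
      if (nchar(a) >= 4L || nchar(s$element[i]) >= 2L) {
        sprintf("%-4s", substr(a, 1L, 4L))
      } else sprintf(" %-3s", a)
    }, character(1))
    body <- sprintf("%s%5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                    rec, seq_len(nrow(s)) %% 100000L, name,
                    substr(s$resname, 1L, 3L), substr(s$chain, 1L, 1L),
                    s$resno, s$x, s$y, s$z, 1, 0, s$element)
    if (multi) out <- c(out, sprintf("MODEL     %4d", m), body, "ENDMDL")
    else out <- c(out, body)
  }
  c(out, "END")
}

format_cif_lines <- function(struct) {
  hdr <- c("data_etbridge",
           "loop_",
           "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
           "_atom_site.label_atom_id", "_atom_site.label_alt_id",
           "_atom_site.label_comp_id", "_atom_site.label_asym_id",
           "_atom_site.label_entity_id", "_atom_site.label_seq_id",
           "_atom_site.pdbx_PDB_ins_code",
           "_atom_site.Cartn_x", "_atom_site.Cartn_y", "_atom_site.Cartn_z",
           "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
           "_atom_site.auth_seq_id", "_atom_site.auth_comp_id",
           "_atom_site.auth_asym_id", "_atom_site.auth_atom_id",
           "_atom_site.pdbx_PDB_model_num")
  rows <- sprintf("%s %d %s %s . %s %s 1 %d ? %.3f %.3f %.3f 1.00 0.00 %d %s %s %s %d",
                  ifelse(struct$hetero, "HETATM", "ATOM"),
                  seq_len(nrow(struct)), struct$element, struct$atom,
                  struct$resname, struct$chain, struct$resno,
                  struct$x, struct$y, struct$z,
                  struct$resno, struct$resname, struct$chain, struct$atom,
                  struct$model)
  c(hdr, rows, "#")
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA file.
#' @return a named character vector of sequences (one element per record).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  recs <- tryCatch(seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                                      seqonly = FALSE),
                   error = function(e) abort(sprintf("failed to parse FASTA '%s': %s",
                                                    path, conditionMessage(e))))
  setNames(toupper(vapply(recs, `[[`, character(1), 1L)), names(recs))
}
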