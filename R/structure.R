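#' Atom-table representation of a (possibly multi-model) structure
#'
#' Structures are kept as long tibbles with one row per atom per model:
#' columns `model` (integer, >= 1), `chain`, `resno`, `resname`, `atom`,
#' `element`, `x`, `y`, `z` (Angstrom) and `hetero` (logical). All models of
#' an ensemble share an identical atom topology (same rows in the same order
#' apart from coordinates). The source identifier, when known, is stored in
#' the `source_id` attribute.
#'
#' @param df a data frame with at least the coordinate columns; missing
#'   `model`, `chain` or `hetero` columns are filled with defaults (model 1,
#'   chain "A", non-hetero). Missing `element` is inferred from atom names.
#' @param source_id optional identifier recorded on the returned object.
#' @return a tibble of atom records (class `et_structure` prepended).
#' @export
as_structure <- function(df, source_id = NULL) {
  df <- as_tibble(df)
  if (!"model" %in% names(df)) df$model <- 1L
  if (!"chain" %in% names(df)) df$chain <- "A"
  if (!"hetero" %in% names(df)) df$hetero <- FALSE
  if (!"resname" %in% names(df)) df$resname <- "UNK"
  if (!"element" %in% names(df)) df$element <- NA_character_
  assert_cols(df, c("model", "chain", "resno", "resname", "atom",
                    "element", "x", "y", "z", "hetero"), "structure table")
  df$model <- as.integer(df$model)
  df$resno <- as.integer(df$resno)
  need <- is.na(df$element) | !nzchar(df$element)
  if (any(need)) df$element[need] <- infer_element(df$atom[need])
  validate_structure(df)
  df <- df[, c("model", "chain", "resno", "resname", "atom", "element",
               "x", "y", "z", "hetero")]
  attr(df, "source_id") <- source_id %||% attr(df, "source_id")
  class(df) <- unique(c("et_structure", class(df)))
  df
}

validate_structure <- function(df) {
  if (!nrow(df)) abort("structure has no atoms")
  if (any(!is.finite(df$x) | !is.finite(df$y) | !is.finite(df$z))) {
    abort("structure contains non-finite coordinates")
  }
  if (any(is.na(df$element) | !nzchar(df$element))) {
    bad <- unique(df$atom[is.na(df$element) | !nzchar(df$element)])
    abort(sprintf("element could not be resolved for atom name(s): %s",
                  paste(head(bad, 5L), collapse = ", ")))
  }
  key <- paste(df$model, df$chain, df$resno, df$atom)
  if (anyDuplicated(key)) {
    abort("duplicate (model, chain, residue, atom) records in structure")
  }
  counts <- table(df$model)
  if (length(unique(counts)) > 1L) {
    abort("models differ in atom count; ensemble topology must be shared")
  }
  invisible(df)
}

# element from atom-name leading characters (PDB convention); errors upstream
# when nothing matches
infer_element <- function(atom) {
  two <- c("FE", "CU", "ZN", "MG", "MN", "NA", "CL", "CA2", "BR", "SE")
  up <- toupper(sub("^[0-9']+", "", atom))
  out <- character(length(atom))
  lead2 <- substr(up, 1L, 2L)
  lead1 <- substr(up, 1L, 1L)
  is_metal <- lead2 %in% c("FE", "CU", "ZN", "MG", "MN", "SE", "BR")
  out[is_metal] <- lead2[is_metal]
  known1 <- lead1 %in% c("C", "N", "O", "S", "H", "P")
  out[!is_metal & known1] <- lead1[!is_metal & known1]
  out[out == ""] <- NA_character_
  out
}

#' Number of models in a structure ensemble
#' @param struct an atom table from [as_structure()] or [read_structure()].
#' @return integer model count.
#' @export
n_models <- function(struct) length(unique(struct$model))

#' Select atoms from a structure table
#'
#' Thin filtering helper used wherever the pipeline needs an atom selection
#' (donor/acceptor sets, superposition cores, restraint end points). All
#' arguments are optional; each given argument keeps matching rows.
#'
#' @param struct an atom table.
#' @param model,chain,resno,resname,atom,element vectors of admissible values.
#' @param hetero if not `NULL`, keep only rows with this hetero flag.
#' @return the filtered atom table (possibly zero rows).
#' @export
atom_select <- function(struct, model = NULL, chain = NULL, resno = NULL,
                        resname = NULL, atom = NULL, element = NULL,
                        hetero = NULL) {
  keep <- rep(TRUE, nrow(struct))
  if (!is.null(model))   keep <- keep & struct$model %in% model
  if (!is.null(chain))   keep <- keep & struct$chain %in% chain
  if (!is.null(resno))   keep <- keep & struct$resno %in% resno
  if (!is.null(resname)) keep <- keep & struct$resname %in% resname
  if (!is.null(atom))    keep <- keep & struct$atom %in% atom
  if (!is.null(element)) keep <- keep & struct$element %in% element
  if (!is.null(hetero))  keep <- keep & struct$hetero == hetero
  struct[keep, , drop = FALSE]
}

# coordinates of one model as an n x 3 matrix, rows in topology order
coords_matrix <- function(struct, model = NULL) {
  if (!is.null(model)) struct <- struct[struct$model == model, , drop = FALSE]
  cbind(struct$x, struct$y, struct$z)
}
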