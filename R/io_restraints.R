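#' Distance-restraint records and the CNS/HADDOCK .tbl writer
#'
#' A restraint table has one row per restraint: `kind` (`"ambiguous"` or
#' `"unambiguous"`), list-columns `sel_a` and `sel_b` holding CNS selection
#' strings (ambiguous records carry several partner selections in `sel_b`,
#' serialized as OR-ed alternatives), and `target`, `lower`, `upper` bounds
#' in Angstrom.
#'
#' @param kind restraint kind.
#' @param sel_a,sel_b character vectors of CNS selection strings; `sel_a`
#'   must be a single selection.
#' @param target,lower,upper distance and bounds, Angstrom, with
#'   `lower <= target <= upper`.
#' @return a one-row restraint tibble.
#' @export
restraint_record <- function(kind = c("unambiguous", "ambiguous"),
                             sel_a, sel_b, target, lower, upper) {
  kind <- match.arg(kind)
  if (!length(sel_a) || !length(sel_b)) abort("restraint selections must be non-empty")
  if (length(sel_a) != 1L) abort("sel_a must be a single selection")
  assert_scalar_num(target, "target")
  if (!(lower <= target && target <= upper)) {
    abort("restraint bounds must satisfy lower <= target <= upper")
  }
  if (kind == "unambiguous" && length(sel_b) != 1L) {
    abort("unambiguous restraints take exactly one partner selection")
  }
  tibble(kind = kind, sel_a = list(as.character(sel_a)),
         sel_b = list(as.character(sel_b)),
         target = target, lower = lower, upper = upper)
}

#' Build a CNS atom-selection string
#' @param segid chain/segment id, or `NULL`.
#' @param resid residue number, or `NULL`.
#' @param name atom name, or `NULL`.
#' @return a selection string such as `"segid A and resid 83"`.
#' @export
cns_sel <- function(segid = NULL, resid = NULL, name = NULL) {
  parts <- c(if (!is.null(segid)) sprintf("segid %s", segid),
             if (!is.null(resid)) sprintf("resid %d", as.integer(resid)),
             if (!is.null(name)) sprintf("name %s", name))
  if (!length(parts)) abort("cns_sel: at least one of segid/resid/name required")
  paste(parts, collapse = " and ")
}

#' Serialize restraints as CNS/HADDOCK `assign` statements
#'
#' Each record becomes one `assign (sel_a) (sel_b) d dminus dplus` line where
#' `dminus = target - lower` and `dplus = upper - target`. Ambiguous records
#' OR their partner selections inside a single parenthesized group.
#'
#' @param records a restraint tibble (rows from [restraint_record()]).
#' @param path output `.tbl` path.
#' @param dialect only `"cns_tbl"` is supported.
#' @return `path`, invisibly.
#' @export
write_restraints <- function(records, path, dialect = "cns_tbl") {
  if (!identical(dialect, "cns_tbl")) abort("unsupported restraint dialect")
  header <- c("! distance restraints (CNS/HADDOCK tbl dialect)",
              sprintf("! %d record(s)", if (is.null(records)) 0L else nrow(records)))
  if (is.null(records) || !nrow(records)) {
    writeLines(header, path)
    return(invisible(path))
  }
  lines <- pmap(records, function(kind, sel_a, sel_b, target, lower, upper) {
    b <- if (length(sel_b) > 1L) {
      sprintf("(%s)", paste(sprintf("(%s)", sel_b), collapse = " or "))
    } else sprintf("(%s)", sel_b)
    sprintf("assign (%s) %s %.2f %.2f %.2f",
            sel_a, b, target, target - lower, upper - target)
  })
  writeLines(c(header, unlist(lines)), path)
  invisible(path)
}
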