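
# Mass units convert freely among themselves; activity units (IU) form their
# own family and never convert to mass without a drug-specific potency, which
# this package deliberately does not guess.
.unit_table <- c(mg = 1, g = 1000, mcg = 1e-3, ug = 1e-3, "µg" = 1e-3,
                 iu = 1, IU = 1)
.unit_family <- c(mg = "mass", g = "mass", mcg = "mass", ug = "mass",
                  "µg" = "mass", iu = "activity", IU = "activity")

#' Convert an amount between strength units
#'
#' Supports the mass family (`mg`, `g`, `mcg`/`ug`) and the activity family
#' (`IU`). Conversion across families is an error: it would require a potency
#' assumption.
#'
#' @param value Numeric vector of amounts.
#' @param from,to Character unit names (recycled against `value`).
#' @return Numeric vector of amounts expressed in `to`.
#' @examples
#' convert_units(c(0.5, 250), c("g", "mg"), "mg")
#' @export
convert_units <- function(value, from, to) {
  n <- max(length(value), length(from), length(to))
  value <- rep_len(value, n)
  from <- rep_len(as.character(from), n)
  to <- rep_len(as.character(to), n)
  bad <- !(from %in% names(.unit_table)) | !(to %in% names(.unit_table))
  if (any(bad)) {
    u <- unique(c(from[bad], to[bad]))
    u <- u[!u %in% names(.unit_table)]
    rlang::abort(paste0("unknown unit(s): ", paste(u, collapse = ", ")))
  }
  cross <- .unit_family[from] != .unit_family[to]
  if (any(cross)) {
    i <- which(cross)[1]
    rlang::abort(paste0(
      "cannot convert '", from[i], "' to '", to[i],
      "': incompatible unit families"
    ))
  }
  value * unname(.unit_table[from]) / unname(.unit_table[to])
}
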