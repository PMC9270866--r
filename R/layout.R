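#' Crystal layout: roles and ordering of implanted crystals
#'
#' Describes how the implanted sonomicrometry crystals map onto the
#' anatomy: an ordered ring of 6 crystals around the tricuspid annulus,
#' 13 free-wall crystals on three circumferential parallels (basal, mid
#' and lower rows), and a single apex crystal. Circumferential order
#' within each row is the order of the label vectors; it fixes polygon
#' orientation, mesh connectivity and region assignment downstream.
#'
#' The split of the 13 free-wall crystals into rows of 5/4/4 is a
#' package convention (only the total is anatomically fixed); pass
#' different row vectors to override it.
#'
#' @param annular character vector of exactly 6 labels in
#'   circumferential order around the annulus.
#' @param basal,mid,lower character vectors of free-wall labels per
#'   parallel, circumferentially ordered; together exactly 13 labels.
#' @param apex single label of the apical crystal.
#' @return An object of class `crystal_layout`.
#' @examples
#' lay <- crystal_layout()
#' layout_labels(lay)
#' @export
crystal_layout <- function(annular = paste0("A", 1:6),
                           basal = paste0("B", 1:5),
                           mid = paste0("M", 1:4),
                           lower = paste0("L", 1:4),
                           apex = "AP") {
  layout <- structure(
    list(annular = as.character(annular),
         parallels = list(basal = as.character(basal),
                          mid = as.character(mid),
                          lower = as.character(lower)),
         apex = as.character(apex)),
    class = "crystal_layout")
  problems <- layout_invariant_violations(layout)
  if (length(problems)) stopf("invalid layout: %s", paste(problems, collapse = "; "))
  layout
}

layout_invariant_violations <- function(layout) {
  v <- character()
  if (length(layout$annular) != 6)
    v <- c(v, sprintf("annular count %d != 6", length(layout$annular)))
  n_par <- sum(lengths(layout$parallels))
  if (n_par != 13)
    v <- c(v, sprintf("free-wall parallel count %d != 13", n_par))
  if (any(lengths(layout$parallels) < 3))
    v <- c(v, "each parallel needs >= 3 crystals")
  if (length(layout$apex) != 1)
    v <- c(v, sprintf("apex count %d != 1", length(layout$apex)))
  labs <- layout_labels(layout)
  dup <- unique(labs[duplicated(labs)])
  if (length(dup))
    v <- c(v, sprintf("duplicated label(s): %s", paste(dup, collapse = ", ")))
  v
}

#' All crystal labels of a layout, in canonical order
#'
#' Order: annular ring, basal row, mid row, lower row, apex. This is
#' the vertex order of meshes built from the layout.
#'
#' @param layout a `crystal_layout`.
#' @return character vector of 20 labels.
#' @export
layout_labels <- function(layout) {
  c(layout$annular, layout$parallels$basal, layout$parallels$mid,
    layout$parallels$lower, layout$apex)
}

#' Check a layout against a recording
#'
#' Reports every violated invariant: wrong counts, duplicated labels,
#' and layout labels absent from the recording. An empty character
#' vector means layout and recording are mutually consistent.
#'
#' @param layout a `crystal_layout`.
#' @param rec a `channel_recording` (optional; omit to check the layout
#'   alone).
#' @return character vector of human-readable violations (empty if ok).
#' @export
validate_layout <- function(layout, rec = NULL) {
  v <- layout_invariant_violations(layout)
  if (!is.null(rec)) {
    missing <- setdiff(layout_labels(layout), names(rec$crystals))
    if (length(missing))
      v <- c(v, sprintf("label(s) missing from recording: %s",
                        paste(missing, collapse = ", ")))
  }
  v
}

#' @export
print.crystal_layout <- function(x, ...) {
  cat("Crystal layout: 6 annular + ",
      paste(lengths(x$parallels), collapse = "/"),
      " free wall + 1 apex\n", sep = "")
  invisible(x)
}
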