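#' FDI tooth codes
#'
#' Permanent-dentition teeth are addressed by their two-digit FDI code: the
#' first digit is the quadrant (1 = upper right, 2 = upper left, 3 = lower
#' left, 4 = lower right) and the second the position from the midline
#' (1 = central incisor ... 8 = third molar). These helpers validate codes
#' and map them onto tooth classes; all dentition accounting in the package
#' uses this single coordinate system.
#'
#' @param code integer vector of two-digit FDI codes (e.g. 12, 35).
#' @return `fdi_valid()` a logical vector; `fdi_quadrant()`/`fdi_position()`
#'   integer vectors; `is_third_molar()` a logical vector; `tooth_class()` a
#'   character vector over the eight position classes; `tooth_group()` the
#'   coarser incisor/canine/premolar/molar grouping.
#' @examples
#' fdi_valid(c(11, 48, 59))
#' tooth_class(c(12, 22, 35))
#' @name fdi
NULL

#' @rdname fdi
#' @export
fdi_valid <- function(code) {
  code <- suppressWarnings(as.integer(code))
  !is.na(code) &
    code %/% 10L %in% 1:4 &
    code %% 10L %in% 1:8
}

#' @rdname fdi
#' @export
fdi_quadrant <- function(code) {
  stopifnot(all(fdi_valid(code)))
  as.integer(code) %/% 10L
}

#' @rdname fdi
#' @export
fdi_position <- function(code) {
  stopifnot(all(fdi_valid(code)))
  as.integer(code) %% 10L
}

#' @rdname fdi
#' @export
is_third_molar <- function(code) {
  fdi_position(code) == 8L
}

.tooth_classes <- c(
  "central_incisor", "lateral_incisor", "canine", "first_premolar",
  "second_premolar", "first_molar", "second_molar", "third_molar"
)

#' @rdname fdi
#' @export
tooth_class <- function(code) {
  .tooth_classes[fdi_position(code)]
}

#' @rdname fdi
#' @export
tooth_group <- function(code) {
  grp <- c("incisor", "incisor", "canine", "premolar",
           "premolar", "molar", "molar", "molar")
  grp[fdi_position(code)]
}

#' @rdname fdi
#' @export
is_maxillary <- function(code) {
  fdi_quadrant(code) %in% c(1L, 2L)
}
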