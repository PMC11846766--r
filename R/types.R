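#' Cell-type codes
#'
#' Integer codes for the cell types carried by material points. The taxonomy
#' covers the chondrocyte lineage (quiescent through hypertrophic and the two
#' terminal calcified states), the perichondrial lineage (perichondrium and
#' bone collar), and the two dedicated PTHrP-producing types: resting-zone
#' producers (otherwise quiescent) and periarticular producers (otherwise
#' perichondrial).
#'
#' @format Named integer vector.
#' @export
cell_type_codes <- c(
  quiescent          = 1L,
  proliferative      = 2L,
  prehypertrophic    = 3L,
  hypertrophic       = 4L,
  apoptotic          = 5L,
  matrix             = 6L,
  perichondrium      = 7L,
  bone_collar        = 8L,
  resting_pthrp      = 9L,
  periarticular_pthrp = 10L
)

# internal shorthands
.ct <- cell_type_codes

#' Map type codes to names
#' @param code integer vector of cell-type codes.
#' @return character vector of type names.
#' @export
cell_type_name <- function(code) {
  names(cell_type_codes)[match(code, cell_type_codes)]
}

# cells counted as calcified bone when detecting ossification-center fusion
.calcified_codes <- c(5L, 6L)

# chondrocytes whose presence inside the resting band counts as penetration
.penetrating_codes <- c(2L, 3L, 4L)

# types eligible for the quiescent -> proliferative Ihh threshold
.quiescent_like <- c(1L, 9L)

# perichondrial lineage eligible for bone-collar formation
.perichondrial_like <- c(7L, 10L)
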