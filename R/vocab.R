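#' Attribute vocabularies for molecular graph featurization
#'
#' Fixed integer-coded vocabularies for every node and edge attribute used by
#' the graph encoder. Each vocabulary carries one appended `"MASK"` sentinel as
#' its final category; masked atoms and bonds are featurized with the sentinel
#' id of every attribute, so the sentinel can never collide with a real
#' chemical value.
#'
#' Node attributes: element (common-organic element set plus `"other"`),
#' formal charge in -2..+2, aromatic flag, chirality tag, hydrogen count 0-4.
#' Edge attributes: bond order (single/double/triple/aromatic) and stereo tag.
#'
#' @return A named list with `node` and `edge` vocabularies (each a named list
#'   of character vectors ending in `"MASK"`) and `sentinel` ids per attribute.
#' @examples
#' v <- attribute_vocabularies()
#' names(v$node)
#' v$sentinel$element
#' @export
attribute_vocabularies <- function() {
  node <- list(
    element   = c("B", "C", "N", "O", "F", "Si", "P", "S", "Cl", "Br", "I",
                  "other", "MASK"),
    charge    = c("-2", "-1", "0", "1", "2", "MASK"),
    aromatic  = c("FALSE", "TRUE", "MASK"),
    chirality = c("none", "CW", "CCW", "other", "MASK"),
    hcount    = c("0", "1", "2", "3", "4", "MASK")
  )
  edge <- list(
    order  = c("single", "double", "triple", "aromatic", "MASK"),
    stereo = c("none", "Z", "E", "cis", "trans", "any", "MASK")
  )
  sentinel <- c(lapply(node, length), lapply(edge, length))
  list(node = node, edge = edge, sentinel = sentinel)
}

# Elements considered part of the standard organic set for SMILES purposes.
.organic_subset <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
.aromatic_organic <- c("b", "c", "n", "o", "p", "s")

# Default valences used for implicit-hydrogen derivation (smallest first).
.default_valences <- list(
  B = 3, C = 4, N = c(3, 5), O = 2, P = c(3, 5), S = c(2, 4, 6),
  F = 1, Cl = c(1, 3, 5, 7), Br = c(1, 3, 5, 7), I = c(1, 3, 5, 7), Si = 4
)

# Maximum permitted valence per element for sanitization, by formal charge.
# Returns NULL when the element/charge combination is not covered, in which
# case the valence check is skipped (permissive outside common chemistry).
.max_valence <- function(element, charge) {
  base <- switch(element,
    B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4, P = 5, S = 6,
    Cl = 1, Br = 1, I = 1, NULL)
  if (is.null(base)) return(NULL)
  if (charge == 0) return(base)
  if (element %in% c("N", "O", "P", "S") && charge > 0) return(base + charge)
  if (element %in% c("C", "B") && charge != 0) return(base - abs(charge))
  if (charge < 0) return(base + charge)
  NULL
}
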