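#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Largest-remainder apportionment of integer ratio parts
#'
#' Distributes `total` items over categories in proportion to `parts`,
#' using the largest-remainder (Hamilton) method so that the counts sum
#' exactly to `total`.  Ties in the remainders are broken by category
#' order, which keeps the result deterministic.
#'
#' @param parts named non-negative numeric vector of ratio parts.
#' @param total integer total to distribute.
#' @return named integer vector summing to `total`.
#' @examples
#' largest_remainder(c(POPC = 25, DOPC = 25, POPE = 8, DOPE = 7,
#'                     CHOL = 25, DPG3 = 10), 1000)
#' @export
largest_remainder <- function(parts, total) {
  stopifnot(is.numeric(parts), length(parts) >= 1L)
  if (any(parts < 0)) stop("ratio parts must be >= 0")
  if (sum(parts) <= 0) stop("at least one ratio part must be positive")
  total <- as.integer(total)
  if (total < 0) stop("total must be >= 0")
  quota <- parts / sum(parts) * total
  base <- floor(quota)
  short <- total - sum(base)
  if (short > 0) {
    ord <- order(quota - base, decreasing = TRUE)
    base[ord[seq_len(short)]] <- base[ord[seq_len(short)]] + 1
  }
  stats::setNames(as.integer(base), names(parts))
}

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues' formula; `axis` need not be normalised.
#'
#' @param angle_deg rotation angle in degrees.
#' @param axis length-3 numeric axis direction.
#' @return a 3x3 rotation matrix.
#' @export
rotation_matrix <- function(angle_deg, axis) {
  stopifnot(length(axis) == 3, all(is.finite(axis)))
  n <- sqrt(sum(axis^2))
  if (n == 0) stop("rotation axis must be non-zero")
  u <- axis / n
  th <- angle_deg * pi / 180
  ct <- cos(th); st <- sin(th)
  ux <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
               3, 3, byrow = TRUE)
  ct * diag(3) + st * ux + (1 - ct) * tcrossprod(u)
}

# Minimum-image displacement along one periodic dimension.
min_image <- function(d, L) d - L * round(d / L)

# Pairwise distances between two point sets (rows), optionally applying
# the minimum-image convention in x and y (membrane-plane periodicity).
# Used by small-N paths; the neighbour search in contacts.R is the
# production path.
pair_dist <- function(a, b, box = NULL, min_image_xy = FALSE) {
  a <- as.matrix(a); b <- as.matrix(b)
  dx <- outer(a[, 1], b[, 1], "-")
  dy <- outer(a[, 2], b[, 2], "-")
  dz <- outer(a[, 3], b[, 3], "-")
  if (min_image_xy) {
    if (is.null(box)) stop("box required for minimum-image distances")
    dx <- min_image(dx, box[1])
    dy <- min_image(dy, box[2])
  }
  sqrt(dx^2 + dy^2 + dz^2)
}

# Species alias table: the CG residue names used in trajectories vs the
# common lipid names.  Matching is symmetric.
.species_aliases <- c(GM3 = "DPG3", PIP2 = "POP2")

#' Canonical species matching with GM3/DPG3 and PIP2/POP2 aliases
#'
#' @param stored character vector of species labels as stored in a frame.
#' @param query character vector of species names to match.
#' @return logical vector: does each `stored` label match any `query` name?
#' @export
species_matches <- function(stored, query) {
  expand <- function(x) {
    extra <- c(.species_aliases[x], names(.species_aliases)[match(x, .species_aliases)])
    unique(c(x, extra[!is.na(extra)]))
  }
  stored %in% expand(query)
}
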