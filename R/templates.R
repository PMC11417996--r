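# Rigid molecular templates: internal site geometry + atom-type binding.
# TIP4P/2005 water (O, H, H and the massless M site on the HOH bisector)
# and the rigid hydroxide ion (d_OH = 0.98 A).

#' Create a rigid molecular template
#'
#' @param name Molecule name (GRO residue name, <= 5 chars).
#' @param sites `data.frame` with columns `site` (site name), `type`
#'   (atom-type name), `x`, `y`, `z` (internal coordinates, A).
#' @param constraints `data.frame` with columns `i`, `j` (site indices) and
#'   `length` (A) describing the rigid bond network (informational; the
#'   geometry itself is fixed by `sites`).
#' @return Object of class `"rigid_template"`.
#' @export
rigid_template <- function(name, sites, constraints = NULL) {
  stopifnot(is.data.frame(sites),
            all(c("site", "type", "x", "y", "z") %in% names(sites)))
  structure(list(name = name, sites = sites, constraints = constraints),
            class = "rigid_template")
}

#' TIP4P/2005 water template
#'
#' Four sites: oxygen at the origin, two hydrogens at 0.9572 A with an HOH
#' angle of 104.52 deg, and the massless charged M site at 0.1546 A along
#' the bisector. The M position is an exact linear combination of the three
#' atomic sites, so it is always rederived from them on file input.
#'
#' @return A `"rigid_template"`.
#' @export
tip4p2005_template <- function() {
  tp <- .TIP4P2005
  half <- tp$ang_HOH / 2 * pi / 180
  h1 <- c(tp$d_OH * sin(half), 0, tp$d_OH * cos(half))
  h2 <- c(-tp$d_OH * sin(half), 0, tp$d_OH * cos(half))
  msite <- c(0, 0, tp$d_OM)
  sites <- data.frame(
    site = c("OW", "HW1", "HW2", "MW"),
    type = c("O_w", "H_w", "H_w", "M_w"),
    x = c(0, h1[1], h2[1], msite[1]),
    y = c(0, h1[2], h2[2], msite[2]),
    z = c(0, h1[3], h2[3], msite[3]),
    stringsAsFactors = FALSE
  )
  cons <- data.frame(i = c(1L, 1L, 2L), j = c(2L, 3L, 3L),
                     length = c(tp$d_OH, tp$d_OH, sqrt(sum((h1 - h2)^2))))
  rigid_template("SOL", sites, cons)
}

#' Rigid hydroxide template
#'
#' Two interaction sites, oxygen at the origin and hydrogen at the fixed
#' bond length 0.98 A.
#'
#' @return A `"rigid_template"`.
#' @export
hydroxide_template <- function() {
  sites <- data.frame(site = c("O1", "H1"), type = c("O_oh", "H_oh"),
                      x = c(0, 0), y = c(0, 0), z = c(0, .OH_D_OH),
                      stringsAsFactors = FALSE)
  rigid_template("OHX", sites, data.frame(i = 1L, j = 2L, length = .OH_D_OH))
}

#' Monatomic ion template
#'
#' @param ion Atom-type name, one of `"Li"`, `"Na"`, `"K"`.
#' @return A `"rigid_template"` with a single site.
#' @export
ion_template <- function(ion = c("Li", "Na", "K")) {
  ion <- match.arg(ion)
  rigid_template(toupper(ion),
                 data.frame(site = toupper(ion), type = ion,
                            x = 0, y = 0, z = 0, stringsAsFactors = FALSE))
}

## uniform random rotation matrix from a quaternion
.random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Place a rigid template at a pose
#'
#' @param template A `"rigid_template"`.
#' @param center Length-3 translation (A).
#' @param rotation 3x3 rotation matrix, or `NULL` for identity.
#' @return Matrix (n_sites x 3) of coordinates.
#' @export
place_template <- function(template, center = c(0, 0, 0), rotation = NULL) {
  xyz <- as.matrix(template$sites[, c("x", "y", "z")])
  if (!is.null(rotation)) xyz <- xyz %*% t(rotation)
  sweep(xyz, 2, center, `+`)
}

## Recompute M-site positions from O, H1, H2 (never trusted from file).
## r_M = r_O + d_OM * unit bisector of the two O->H vectors.
.derive_msites <- function(config) {
  idx <- which(config$type == "M_w")
  for (i in idx) {
    mol <- which(config$mol_id == config$mol_id[i])
    o <- mol[config$type[mol] == "O_w"]
    h <- mol[config$type[mol] == "H_w"]
    if (length(o) != 1L || length(h) != 2L) next
    b <- .min_image(config$xyz[h[1], ] - config$xyz[o, ], config$box) +
         .min_image(config$xyz[h[2], ] - config$xyz[o, ], config$box)
    b <- b / sqrt(sum(b^2))
    pos <- config$xyz[o, ] + .TIP4P2005$d_OM * b
    config$xyz[i, ] <- pos - config$box * floor(pos / config$box)
  }
  config
}
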