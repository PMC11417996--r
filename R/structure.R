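# Structural estimators: radial distribution functions, coordination
# integrals (contact ion pairs, hydration numbers), the distance-angle
# joint distribution around the hydroxide O-H axis, and geometric
# hydrogen-bond counts.

.resolve_selection <- function(config, sel, what = "selection") {
  idx <- if (is.character(sel)) which(config$type %in% sel | config$site %in% sel)
         else if (is.logical(sel)) which(sel)
         else as.integer(sel)
  if (!length(idx))
    .stopf("empty %s ('%s' matches no site)", what,
           paste(as.character(sel), collapse = ","))
  idx
}

#' Site-site radial distribution function
#'
#' Standard pair-histogram RDF normalized by ideal-gas shell counts and the
#' partner number density, honouring per-frame volumes (NpT trajectories).
#' Self pairs and intramolecular pairs are excluded.
#'
#' @param traj An `"md_traj"` (or single `"md_config"`).
#' @param sel_a,sel_b Selections: atom-type names, site names, logical or
#'   integer site indices.
#' @param dr Bin width, A (default 0.02, fine enough to resolve peak
#'   positions at the 0.1 A level).
#' @param r_max Histogram range, A; default `min(12, L/2)`. Must not exceed
#'   half the shortest box edge.
#' @return Object of class `"rdf"`: bin centers `r` (A), `g`, partner
#'   density `rho` (A^-3), raw pair `counts`, `n_frames`, `n_a`, and the
#'   selection labels.
#' @export
compute_rdf <- function(traj, sel_a, sel_b, dr = 0.02, r_max = NULL) {
  traj <- .as_traj(traj)
  Lmin <- min(vapply(traj$frames, function(f) min(f$box), 0))
  if (is.null(r_max)) r_max <- min(12, Lmin / 2)
  if (r_max > Lmin / 2 + 1e-9)
    .stopf("r_max %.3f A exceeds half the shortest box edge (%.3f A)", r_max, Lmin / 2)
  edges <- seq(0, r_max, by = dr)
  if (edges[length(edges)] < r_max) edges <- c(edges, edges[length(edges)] + dr)
  nb <- length(edges) - 1L
  counts <- numeric(nb)
  sum_rho <- 0; n_a_tot <- 0
  for (f in traj$frames) {
    ia <- .resolve_selection(f, sel_a, "selection A")
    ib <- .resolve_selection(f, sel_b, "selection B")
    V <- prod(f$box)
    ## ordered pairs (a in A, b in B), excluding identical sites and
    ## intramolecular partners
    same_mol <- outer(f$mol_id[ia], f$mol_id[ib], `==`)
    keep <- !same_mol
    if (!any(keep)) { n_a_tot <- n_a_tot + length(ia); next }
    d2 <- 0
    for (dd in 1:3) {
      del <- outer(f$xyz[ia, dd], f$xyz[ib, dd], `-`)
      del <- del - round(del / f$box[dd]) * f$box[dd]
      d2 <- d2 + del^2
    }
    r <- sqrt(d2[keep])
    r <- r[r < r_max]
    counts <- counts + tabulate(pmin(floor(r / dr) + 1L, nb), nbins = nb)
    ## partner density seen by an A site (exclude its own molecule's B's)
    n_b_eff <- length(ib) - mean(rowSums(same_mol))
    sum_rho <- sum_rho + n_b_eff / V
    n_a_tot <- n_a_tot + length(ia)
  }
  nf <- length(traj$frames)
  rho <- sum_rho / nf
  r_mid <- (edges[-1] + edges[-length(edges)]) / 2
  shell <- (4 / 3) * pi * (edges[-1]^3 - edges[-length(edges)]^3)
  n_a_mean <- n_a_tot / nf
  g <- counts / nf / (n_a_mean * rho * shell)
  structure(list(r = r_mid, g = g, rho = rho, counts = counts,
                 n_frames = nf, n_a = n_a_mean, dr = dr,
                 sel_a = paste(as.character(sel_a), collapse = ","),
                 sel_b = paste(as.character(sel_b), collapse = ",")),
            class = "rdf")
}

#' @export
print.rdf <- function(x, ...) {
  cat(sprintf("<rdf> %s - %s: %d bins (dr = %.3g A), %d frame(s), rho = %.4g A^-3\n",
              x$sel_a, x$sel_b, length(x$r), x$dr, x$n_frames, x$rho))
  if (any(x$g > 0)) {
    imax <- which.max(x$g)
    cat(sprintf("  first/global maximum: g = %.3f at r = %.2f A\n", x$g[imax], x$r[imax]))
  }
  invisible(x)
}

#' @export
plot.rdf <- function(x, ...) {
  plot(x$r, x$g, type = "l", xlab = "r (Å)", ylab = "g(r)",
       main = sprintf("%s – %s", x$sel_a, x$sel_b), ...)
  graphics::abline(h = 1, lty = 3)
  invisible(x)
}

#' Coordination number from an RDF
#'
#' The coordination integral `4 pi rho int_0^{r_min} g(r) r^2 dr` by
#' trapezoidal quadrature on the bin grid (with linear interpolation of the
#' final partial bin). With the cation-anion RDF and the ion density this
#' is the contact-ion-pair count CIP; with the hydroxide-water RDF and the
#' water density it is the hydration number.
#'
#' @param rdf An `"rdf"` object.
#' @param r_min Upper integration limit, A (the first RDF minimum).
#' @param rho Partner number density, A^-3; defaults to the density stored
#'   in `rdf`.
#' @return Coordination number (dimensionless count).
#' @export
coordination_number <- function(rdf, r_min, rho = NULL) {
  stopifnot(inherits(rdf, "rdf"))
  if (is.null(rho)) rho <- rdf$rho
  if (!is.finite(r_min) || r_min <= 0) .stopf("r_min must be > 0")
  if (r_min > rdf$r[length(rdf$r)] + rdf$dr / 2)
    .stopf("r_min = %.3f A lies beyond the RDF grid (max %.3f A)",
           r_min, rdf$r[length(rdf$r)] + rdf$dr / 2)
  r <- c(0, rdf$r)
  y <- c(0, rdf$g * rdf$r^2)
  keep <- r <= r_min
  rr <- r[keep]; yy <- y[keep]
  if (rr[length(rr)] < r_min) {   # partial last bin by interpolation
    y_end <- stats::approx(r, y, xout = r_min, rule = 2)$y
    rr <- c(rr, r_min); yy <- c(yy, y_end)
  }
  integral <- sum(diff(rr) * (yy[-1] + yy[-length(yy)]) / 2)
  4 * pi * rho * integral
}

#' Locate the first RDF minimum after the first maximum
#'
#' g(r) is smoothed with a 5-bin moving average before the extremum search
#' (bin noise otherwise creates spurious minima). Errors if no interior
#' minimum exists, in which case an explicit `r_min` must be supplied to
#' the coordination wrappers.
#'
#' @param rdf An `"rdf"` object.
#' @param window Moving-average window (bins, odd).
#' @return Position of the first minimum, A.
#' @export
first_shell_minimum <- function(rdf, window = 5L) {
  stopifnot(inherits(rdf, "rdf"))
  g <- stats::filter(rdf$g, rep(1 / window, window), sides = 2)
  g <- as.numeric(g)
  ok <- which(!is.na(g))
  g <- g[ok]; r <- rdf$r[ok]
  n <- length(g)
  dg <- diff(g)
  imax <- which(dg[-1] <= 0 & dg[-(n - 1)] > 0) + 1L  # local maxima
  imax <- imax[g[imax] > 1]                           # a real first peak
  if (!length(imax)) .stopf("no first maximum detected; supply r_min explicitly")
  i0 <- imax[1]
  imin <- which(dg[-1] >= 0 & dg[-(n - 1)] < 0) + 1L  # local minima
  imin <- imin[imin > i0]
  if (!length(imin)) .stopf("no first minimum detected after the maximum; supply r_min explicitly")
  r[imin[1]]
}

.ion_density <- function(traj, type) {
  mean(vapply(traj$frames, function(f) sum(f$type == type) / prod(f$box), 0))
}

#' Contact ion pairs, hydroxide-hydroxide contacts and hydration number
#'
#' Thin wrappers binding species pairs and densities to
#' [coordination_number()]:
#' `cip_pm()` integrates the cation-anion RDF with the ion density
#' rho_+-; `cip_oh()` the O_oh-O_oh RDF with the hydroxide density; and
#' `hydration_number()` the O_oh-O_w RDF with the water density. When
#' `r_min` is omitted it is auto-detected with [first_shell_minimum()].
#' For `cip_oh()` the upper integration limit materially changes the count
#' when the first shell is a shoulder, which is why it is an explicit
#' parameter.
#'
#' @param traj An `"md_traj"`.
#' @param salt Salt identity (fixes the cation type for `cip_pm`).
#' @param r_min Upper integration limit, A (`NULL` = auto-detect).
#' @param dr,r_max RDF binning, passed to [compute_rdf()].
#' @return Coordination count, with the RDF and `r_min` attached as
#'   attributes.
#' @export
cip_pm <- function(traj, salt = c("NaOH", "LiOH", "KOH"), r_min = NULL,
                   dr = 0.02, r_max = NULL) {
  salt <- match.arg(salt)
  traj <- .as_traj(traj)
  cation <- .salt_cation(salt)
  rdf <- compute_rdf(traj, cation, "O_oh", dr = dr, r_max = r_max)
  if (is.null(r_min)) r_min <- first_shell_minimum(rdf)
  out <- coordination_number(rdf, r_min, rho = .ion_density(traj, "O_oh"))
  structure(out, rdf = rdf, r_min = r_min)
}

#' @rdname cip_pm
#' @export
cip_oh <- function(traj, r_min = NULL, dr = 0.02, r_max = NULL) {
  traj <- .as_traj(traj)
  rdf <- compute_rdf(traj, "O_oh", "O_oh", dr = dr, r_max = r_max)
  if (is.null(r_min)) r_min <- first_shell_minimum(rdf)
  out <- coordination_number(rdf, r_min, rho = .ion_density(traj, "O_oh"))
  structure(out, rdf = rdf, r_min = r_min)
}

#' @rdname cip_pm
#' @export
hydration_number <- function(traj, r_min = NULL, dr = 0.02, r_max = NULL) {
  traj <- .as_traj(traj)
  rdf <- compute_rdf(traj, "O_oh", "O_w", dr = dr, r_max = r_max)
  if (is.null(r_min)) r_min <- first_shell_minimum(rdf)
  out <- coordination_number(rdf, r_min, rho = .ion_density(traj, "O_w"))
  structure(out, rdf = rdf, r_min = r_min)
}

#' Joint distance-angle distribution around the hydroxide axis
#'
#' 2D histogram of (r, theta) over hydroxide-water pairs, where r is the
#' O_oh...O_w distance and theta the angle at the hydroxide oxygen between
#' the O-H bond and the O_oh -> O_w direction (vertex at O_oh). Normalized
#' to unit total mass over the histogram domain. Degrees at the interface,
#' radians internally.
#'
#' @param traj An `"md_traj"` containing hydroxide and water.
#' @param r_max Radial range, A.
#' @param r_bins,theta_bins Number of bins in r and theta.
#' @return Object of class `"angular_joint"`: `r` and `theta` bin centers,
#'   probability matrix `p` (r x theta), and counts.
#' @export
angular_joint <- function(traj, r_max = 4.0, r_bins = 40L, theta_bins = 36L) {
  traj <- .as_traj(traj)
  p <- matrix(0, r_bins, theta_bins)
  dr <- r_max / r_bins; dth <- 180 / theta_bins
  for (f in traj$frames) {
    io <- which(f$type == "O_oh"); iw <- which(f$type == "O_w")
    if (!length(io) || !length(iw))
      .stopf("angular_joint needs both hydroxide and water oxygens in the trajectory")
    for (o in io) {
      h <- which(f$mol_id == f$mol_id[o] & f$type == "H_oh")
      if (length(h) != 1L) .stopf("hydroxide molecule %d lacks a unique H site", f$mol_id[o])
      u <- .min_image(f$xyz[h, ] - f$xyz[o, ], f$box)
      nu <- sqrt(sum(u^2))
      if (nu < 1e-9) .stopf("degenerate hydroxide geometry (zero-length O-H bond)")
      v <- .min_image(f$xyz[iw, , drop = FALSE] - matrix(f$xyz[o, ], length(iw), 3, byrow = TRUE), f$box)
      r <- sqrt(rowSums(v^2))
      sel <- r < r_max & r > 1e-9
      if (!any(sel)) next
      cth <- pmin(1, pmax(-1, (v[sel, , drop = FALSE] %*% u) / (r[sel] * nu)))
      th <- acos(cth) * 180 / pi
      ir <- pmin(floor(r[sel] / dr) + 1L, r_bins)
      it <- pmin(floor(th / dth) + 1L, theta_bins)
      for (k in seq_along(ir)) p[ir[k], it[k]] <- p[ir[k], it[k]] + 1
    }
  }
  tot <- sum(p)
  if (tot == 0) .stopf("no hydroxide-water pairs found within r_max = %.2f A", r_max)
  structure(list(r = (seq_len(r_bins) - 0.5) * dr,
                 theta = (seq_len(theta_bins) - 0.5) * dth,
                 p = p / tot, counts = p), class = "angular_joint")
}

#' @export
print.angular_joint <- function(x, ...) {
  idx <- which(x$p == max(x$p), arr.ind = TRUE)[1, ]
  cat(sprintf("<angular_joint> %d x %d bins; mode at r = %.2f A, theta = %.0f deg\n",
              length(x$r), length(x$theta), x$r[idx[1]], x$theta[idx[2]]))
  invisible(x)
}

#' @export
plot.angular_joint <- function(x, ...) {
  graphics::image(x$r, x$theta, x$p, xlab = "r (Å)", ylab = expression(theta ~ "(deg)"),
                  col = grDevices::hcl.colors(64, "Blue-Red"), ...)
  invisible(x)
}

#' Geometric hydrogen-bond counts
#'
#' A donor-acceptor pair is hydrogen bonded when the O...O distance is at
#' most `r_cut` and the angle criterion holds. Two conventions are
#' selectable: `"HOO"` (default) requires the angle H-O_d...O_a at the
#' donor oxygen to be at most `angle_cut`; `"OHO"` requires the angle
#' O_d-H...O_a at the hydrogen to be at least `180 - angle_cut` degrees.
#' Optionally H-bonds are split into strong/weak populations by a second
#' distance threshold (first shell below `strong_cut`, weak between
#' `strong_cut` and `r_cut`).
#'
#' @param config An `"md_config"` (or 1-frame trajectory).
#' @param r_cut O...O distance cutoff, A (default 3.5).
#' @param angle_cut Angular cutoff, degrees (default 30).
#' @param convention `"HOO"` or `"OHO"` (see above).
#' @param strong_cut Optional strong/weak distance split, A (e.g. 3.0);
#'   `NULL` disables the classification.
#' @return List: `n_hbonds` total count, `bonds` data.frame (donor/
#'   acceptor site indices, distance, angle, class), and `per_species`
#'   mean number of H-bonds each molecule of a species participates in.
#' @export
count_hbonds <- function(config, r_cut = 3.5, angle_cut = 30,
                         convention = c("HOO", "OHO"), strong_cut = NULL) {
  if (inherits(config, "md_traj")) config <- config$frames[[1]]
  stopifnot(inherits(config, "md_config"))
  convention <- match.arg(convention)
  ox <- which(config$type %in% c("O_w", "O_oh"))
  don <- list(); k <- 0L
  for (o in ox) {
    hs <- which(config$mol_id == config$mol_id[o] & config$type %in% c("H_w", "H_oh"))
    for (h in hs) { k <- k + 1L; don[[k]] <- c(o, h) }
  }
  res <- list(); nb <- 0L
  for (dk in don) {
    o <- dk[1]; h <- dk[2]
    acc <- ox[config$mol_id[ox] != config$mol_id[o]]
    if (!length(acc)) next
    doa <- .min_image(config$xyz[acc, , drop = FALSE] -
                        matrix(config$xyz[o, ], length(acc), 3, byrow = TRUE), config$box)
    r <- sqrt(rowSums(doa^2))
    near <- which(r <= r_cut)
    if (!length(near)) next
    u <- .min_image(config$xyz[h, ] - config$xyz[o, ], config$box)
    for (m in near) {
      a <- acc[m]
      if (convention == "HOO") {
        cth <- sum(u * doa[m, ]) / (sqrt(sum(u^2)) * r[m])
        ang <- acos(pmin(1, pmax(-1, cth))) * 180 / pi
        ok <- ang <= angle_cut
      } else {
        v1 <- -u                                   # H -> O_d
        v2 <- .min_image(config$xyz[a, ] - config$xyz[h, ], config$box)  # H -> O_a
        cth <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
        ang <- acos(pmin(1, pmax(-1, cth))) * 180 / pi
        ok <- ang >= 180 - angle_cut
      }
      if (ok) {
        nb <- nb + 1L
        cls <- if (is.null(strong_cut)) NA_character_
               else if (r[m] < strong_cut) "strong" else "weak"
        res[[nb]] <- data.frame(donor = o, hydrogen = h, acceptor = a,
                                r_oo = r[m], angle = ang, class = cls,
                                stringsAsFactors = FALSE)
      }
    }
  }
  bonds <- if (nb) do.call(rbind, res)
           else data.frame(donor = integer(0), hydrogen = integer(0),
                           acceptor = integer(0), r_oo = numeric(0),
                           angle = numeric(0), class = character(0))
  ## mean H-bonds per molecule, per species (donor or acceptor role)
  species <- unique(config$mol_name)
  per_species <- vapply(species, function(sp) {
    mols <- unique(config$mol_id[config$mol_name == sp])
    if (!nb) return(0)
    cnt <- sum(config$mol_id[bonds$donor] %in% mols) +
           sum(config$mol_id[bonds$acceptor] %in% mols)
    cnt / length(mols)
  }, 0)
  list(n_hbonds = nb, bonds = bonds, per_species = per_species)
}
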