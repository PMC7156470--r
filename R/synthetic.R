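## synthetic_data: generators for every fixture the pipeline needs (periodic
## solvated-protein supercell with one disulfide bridge, isolated disulfide in
## vacuum, Wilson-distributed reference intensities) plus a PDB cut-out reader.

## Ideal cystine-like Cb-Sg-Sg-Cb geometry: S-S along x with the requested bond
## length, C-S 1.81 A, C-S-S angle 104 deg, C-S-S-C dihedral 90 deg (standard
## stereochemistry; only the S-S distance is a model input).
.disulfide_motif <- function(ss_bond_length) {
  d  <- ss_bond_length
  cs <- 1.81
  th <- 104 * pi / 180
  s1 <- c(0, 0, 0)
  s2 <- c(d, 0, 0)
  c1 <- s1 + cs * c(cos(pi - th), sin(pi - th), 0)   # angle C1-S1-S2 = 104 deg
  c2 <- s2 + cs * c(-cos(pi - th), 0, sin(pi - th))  # 104 deg, dihedral 90 deg
  pos <- rbind(c1, s1, s2, c2)
  rownames(pos) <- NULL
  list(elements = c("C", "S", "S", "C"), pos = pos, bridge = c(2L, 3L))
}

.new_sim_cell <- function(elements, pos, edge_length, periodic, free_radius,
                          bridge, ss_bond_length) {
  .check_elements(elements)
  n <- length(elements)
  stopifnot(nrow(pos) == n, length(bridge) == 2)
  mid <- colMeans(pos[bridge, , drop = FALSE])
  if (periodic) {
    d2 <- .minimage_dist(pos, mid, edge_length)
  } else {
    d2 <- sqrt(rowSums(sweep(pos, 2, mid)^2))
  }
  atoms <- data.frame(
    element = elements,
    mass = unname(.atomic_masses[elements]),
    x = pos[, 1], y = pos[, 2], z = pos[, 3],
    vx = 0, vy = 0, vz = 0,
    charge = 0,
    mobile = d2 <= free_radius,
    stringsAsFactors = FALSE
  )
  out <- list(edge_length = edge_length, periodic = periodic,
              free_radius = free_radius, atoms = atoms,
              bridge = as.integer(bridge), ss_bond_length = ss_bond_length)
  class(out) <- "sim_cell"
  out
}

## minimum-image distance of each row of pos to point ref in a cubic cell
.minimage_dist <- function(pos, ref, L) {
  d <- sweep(pos, 2, ref)
  d <- d - L * round(d / L)
  sqrt(rowSums(d^2))
}

#' Tracked S-S bridge distance of a cell
#'
#' Minimum-image distance (when periodic) between the two sulfurs flagged as
#' the tracked disulfide bridge.
#'
#' @param cell a `sim_cell`
#' @return distance in Angstrom
#' @export
ss_distance <- function(cell) {
  stopifnot(inherits(cell, "sim_cell"))
  p <- as.matrix(cell$atoms[cell$bridge, c("x", "y", "z")])
  d <- p[1, ] - p[2, ]
  if (cell$periodic) d <- d - cell$edge_length * round(d / cell$edge_length)
  sqrt(sum(d^2))
}

#' @export
print.sim_cell <- function(x, ...) {
  cat(sprintf("<sim_cell> %d atoms%s, edge %.4g A, free radius %.3g A\n",
              nrow(x$atoms), if (x$periodic) " (periodic)" else " (vacuum)",
              x$edge_length, x$free_radius))
  tab <- table(x$atoms$element)
  cat("  composition:", paste(names(tab), tab, sep = ":", collapse = "  "), "\n")
  cat(sprintf("  tracked S-S bridge: atoms %d-%d at %.4f A (%d mobile atoms)\n",
              x$bridge[1], x$bridge[2], ss_distance(x), sum(x$atoms$mobile)))
  invisible(x)
}

#' @export
as.data.frame.sim_cell <- function(x, ...) x$atoms

## allocate n slots among the composition fractions by largest remainder
.allocate <- function(n, fractions) {
  raw <- fractions / sum(fractions) * n
  cnt <- floor(raw)
  short <- n - sum(cnt)
  if (short > 0) {
    o <- order(raw - cnt, decreasing = TRUE)
    cnt[o[seq_len(short)]] <- cnt[o[seq_len(short)]] + 1
  }
  cnt
}

#' Generate a synthetic solvated-protein supercell with one disulfide bridge
#'
#' Builds a cubic periodic cell with a central cystine-like Cb-Sg-Sg-Cb motif
#' (S-S at `ss_bond_length`) embedded in randomly packed H/C/N/O atoms at the
#' implied density, with the sulfur-to-light-atom ratio set by
#' `sulfur_fraction`.  Hydrogens are included: ~300 atoms in a (14 A)^3 box
#' only matches solvated-protein density when hydrogens are counted.
#'
#' @param edge_length cubic cell edge, A (default 14)
#' @param target_atom_count requested total atom count (default 300)
#' @param sulfur_fraction fraction of atoms that are sulfur, in (0, 0.2]
#'   (default 2/300: one bridge per ~300 atoms, the crystal's sulfur density)
#' @param ss_bond_length tracked S-S bond length, A (default 2.08)
#' @param seed integer seed; the generator is bit-reproducible for a fixed seed
#' @param composition relative H/C/N/O abundances of the non-sulfur atoms
#'   (default solvated-protein average, hydrogens included)
#' @param min_dist flat minimum inter-atom placement distance, A (default
#'   1.0); in addition, atoms are always placed outside the collision-wall
#'   contact radius of each existing atom (sum of covalent radii), so that no
#'   random pair is born inside the short-range repulsive wall
#' @param free_radius radius of the mobile sphere centred on the S-S midpoint,
#'   A (default 4.5, two coordination shells around the bridge); must not
#'   exceed `edge_length/2`
#' @return a `sim_cell`
#' @export
generate_supercell <- function(edge_length = 14, target_atom_count = 300,
                               sulfur_fraction = 2 / 300,
                               ss_bond_length = 2.08, seed = NULL,
                               composition = c(H = 0.52, C = 0.15,
                                               N = 0.04, O = 0.29),
                               min_dist = 1.0, free_radius = 4.5) {
  stopifnot(edge_length > 2 * ss_bond_length,
            sulfur_fraction > 0, sulfur_fraction <= 0.2,
            target_atom_count >= 4,    # 4 = the bare bridge motif
            free_radius <= edge_length / 2)
  L <- edge_length
  n_S <- max(2L, as.integer(round(sulfur_fraction * target_atom_count)))
  n_extra <- max(0L, target_atom_count - 4L - (n_S - 2L))
  cnt <- .allocate(n_extra, composition[c("H", "C", "N", "O")])
  extra_elems <- c(rep("H", cnt[1]), rep("C", cnt[2]), rep("N", cnt[3]),
                   rep("O", cnt[4]), rep("S", n_S - 2L))

  motif <- .disulfide_motif(ss_bond_length)
  centre <- c(L, L, L) / 2
  shift <- centre - colMeans(motif$pos[motif$bridge, ])
  pos <- sweep(motif$pos, 2, shift, `+`)
  elements <- motif$elements

  with_seed(seed, {
    for (el in sample(extra_elems)) {
      placed <- FALSE
      for (try in seq_len(400L)) {
        p <- runif(3, 0, L)
        dd <- .minimage_dist(pos, p, L)
        ## keep every new atom outside the ionic collision walls (contact
        ## radius = sum of covalent radii) as well as the flat floor, so the
        ## packed cell is force-free at any ionization state at t = 0
        floor_d <- pmax(min_dist,
                        .covalent_radii[[el]] + .covalent_radii[elements])
        if (all(dd >= floor_d)) {
          pos <- rbind(pos, p)
          elements <- c(elements, el)
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        cond <- structure(
          class = c("plasmaMD_packing_error", "error", "condition"),
          list(message = sprintf(
            "infeasible packing: placed %d of %d atoms at min distance %.2f A",
            length(elements), target_atom_count, min_dist),
            call = sys.call(-1), achieved = length(elements)))
        stop(cond)
      }
    }
  })
  .new_sim_cell(elements, pos, L, periodic = TRUE, free_radius = free_radius,
                bridge = motif$bridge, ss_bond_length = ss_bond_length)
}

#' Generate an isolated disulfide moiety in vacuum
#'
#' Non-periodic four-atom Cb-Sg-Sg-Cb cell, all atoms mobile, zero initial
#' velocity, centre of mass at the origin.
#'
#' @param ss_bond_length S-S bond length, A
#' @return a `sim_cell` with `periodic = FALSE`
#' @export
generate_vacuum_disulfide <- function(ss_bond_length = 2.08) {
  stopifnot(ss_bond_length > 0)
  motif <- .disulfide_motif(ss_bond_length)
  m <- .atomic_masses[motif$elements]
  com <- colSums(motif$pos * m) / sum(m)
  pos <- sweep(motif$pos, 2, com)
  .new_sim_cell(motif$elements, pos, edge_length = Inf, periodic = FALSE,
                free_radius = Inf, bridge = motif$bridge,
                ss_bond_length = ss_bond_length)
}

#' Cut a cubic simulation subunit out of a PDB structure
#'
#' Extracts a cube of the requested edge centred on the S-S midpoint of the
#' named cystine bridge; atoms outside the cube are discarded and coordinates
#' re-wrapped to the cell convention (origin at the corner, half-open
#' `[0, edge)` per axis: an atom exactly on the upper boundary is excluded).
#'
#' @param pdb_source path to a PDB file, or a character vector of PDB-format
#'   lines
#' @param bridge_selector integer vector of the two cysteine residue numbers
#'   forming the bridge
#' @param edge_length cube edge, A
#' @param free_radius mobile-sphere radius, A (default 5)
#' @return a `sim_cell`
#' @export
cutout_from_pdb <- function(pdb_source, bridge_selector, edge_length,
                            free_radius = 4.5) {
  stopifnot(length(bridge_selector) == 2, edge_length > 0)
  path <- pdb_source
  if (length(pdb_source) > 1 || !file.exists(pdb_source[1])) {
    path <- tempfile(fileext = ".pdb")
    writeLines(pdb_source, path)
    on.exit(unlink(path))
  }
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  sg <- which(at$resid == "CYS" & at$elety == "SG" &
                at$resno %in% bridge_selector)
  if (length(sg) != 2)
    stop("bridge selector CYS ", paste(bridge_selector, collapse = "-"),
         ": expected the two cysteine SG atoms, found ", length(sg))
  xyz <- cbind(at$x, at$y, at$z)
  mid <- colMeans(xyz[sg, , drop = FALSE])
  span <- sqrt(sum((xyz[sg[1], ] - xyz[sg[2], ])^2))
  if (span >= edge_length)
    stop("edge_length (", edge_length, " A) smaller than the extent of bridge CYS ",
         paste(bridge_selector, collapse = "-"), " (", round(span, 2), " A)")
  lo <- mid - edge_length / 2
  rel <- sweep(xyz, 2, lo)
  keep <- rowSums(rel >= 0 & rel < edge_length) == 3
  if (!all(keep[sg])) stop("bridge atoms fall outside the requested cube")
  elem <- at$elesy[keep]
  if (all(is.na(elem)) || is.null(elem))
    elem <- substr(trimws(at$elety[keep]), 1, 1)
  elem <- trimws(elem)
  elem[elem == ""] <- substr(trimws(at$elety[keep])[elem == ""], 1, 1)
  known <- elem %in% .element_symbols
  if (any(!known)) {
    warning("dropping ", sum(!known), " atom(s) of unsupported element(s): ",
            paste(unique(elem[!known]), collapse = ", "))
  }
  pos <- rel[keep, , drop = FALSE][known, , drop = FALSE]
  elem <- elem[known]
  bridge_new <- match(sg, which(keep)[known])
  .new_sim_cell(elem, pos, edge_length, periodic = TRUE,
                free_radius = min(free_radius, edge_length / 2),
                bridge = bridge_new, ss_bond_length = span)
}

#' Write a cell (or any atom table) as XYZ
#'
#' @param cell a `sim_cell`
#' @param path output path
#' @param comment second-line comment
#' @return `path`, invisibly
#' @export
write_xyz <- function(cell, path, comment = "plasmaMD cell") {
  a <- cell$atoms
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(as.character(nrow(a)), comment), con)
  writeLines(sprintf("%-2s %12.6f %12.6f %12.6f", a$element, a$x, a$y, a$z), con)
  invisible(path)
}

#' Read an XYZ file written by [write_xyz()] back into an atom table
#'
#' @param path XYZ file path
#' @return data.frame with columns element, x, y, z
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  n <- as.integer(lines[1])
  rec <- strsplit(trimws(lines[3:(2 + n)]), "[[:space:]]+")
  data.frame(element = vapply(rec, `[`, "", 1),
             x = as.numeric(vapply(rec, `[`, "", 2)),
             y = as.numeric(vapply(rec, `[`, "", 3)),
             z = as.numeric(vapply(rec, `[`, "", 4)),
             stringsAsFactors = FALSE)
}

#' Generate Wilson-distributed reference reflection intensities
#'
#' Draws `n` reflections with scattering parameter `s = sin(theta)/lambda`
#' uniform in reciprocal volume (uniform in s^3) over `s_range`, and acentric
#' Wilson (exponential) intensities with mean proportional to
#' `exp(-2 * wilson_b * s^2)`.
#'
#' @param n number of reflections
#' @param wilson_b Wilson B-factor of the generated set, A^2
#' @param s_range range of s, A^-1, within (0, 1]
#' @param seed integer seed
#' @return a `reflection_set`: data.frame with columns `s`, `intensity`
#' @export
generate_reference_intensities <- function(n, wilson_b = 20,
                                           s_range = c(0.05, 0.5),
                                           seed = NULL) {
  stopifnot(n > 0, s_range[1] > 0, s_range[2] <= 1, s_range[1] < s_range[2])
  with_seed(seed, {
    s <- (runif(n, s_range[1]^3, s_range[2]^3))^(1 / 3)
    mu <- exp(-2 * wilson_b * s^2)
    I <- rexp(n) * mu
  })
  out <- data.frame(s = s, intensity = I)
  class(out) <- c("reflection_set", "data.frame")
  attr(out, "wilson_b") <- wilson_b
  out
}

#' Read / write a reflection set as CSV
#'
#' CSV with header columns `s,intensity` and optional `h,k,l`.
#'
#' @param x a `reflection_set` (for writing)
#' @param path file path
#' @return `read_reflections` returns a `reflection_set`; `write_reflections`
#'   returns `path` invisibly
#' @export
write_reflections <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_reflections
#' @export
read_reflections <- function(path) {
  out <- utils::read.csv(path)
  if (!all(c("s", "intensity") %in% names(out)))
    stop("reflection CSV must have columns 's' and 'intensity'")
  if (any(out$intensity < 0) || any(out$s <= 0))
    stop("invalid reflection set: intensities must be >= 0 and s > 0")
  class(out) <- c("reflection_set", "data.frame")
  out
}

## composition table of a cell, ordered as .element_symbols
cell_composition <- function(cell) {
  tab <- table(factor(cell$atoms$element, levels = .element_symbols))
  stats::setNames(as.integer(tab), .element_symbols)
}
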